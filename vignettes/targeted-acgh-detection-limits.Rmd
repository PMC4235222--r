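---
title: "Modelling the detection limit of intragenic deletions on targeted aCGH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the detection limit of intragenic deletions on targeted aCGH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exoncgh)
```

## What the package models

Gene-targeted comparative genomic hybridization arrays tile 60-mer
probes over the exons (plus a flanking margin) of disease genes and read
copy number as the per-probe log2 ratio of patient versus same-sex
reference signal. Deletions larger than a few probes produce segments
near the heterozygous value of −1 and are called automatically. The
interesting regime is below that: lesions comparable to, or smaller
than, a single probe footprint attenuate — rather than abolish —
hybridization, and survive only as one or two modestly depressed probes
that a calling threshold will never catch. `exoncgh` implements the
whole chain (design, simulation, segmentation, QC, calling, manual
review, breakpoint bounding, junction analysis) so that this regime can
be studied quantitatively, and ships a twelve-case synthetic suite
reproducing a documented spectrum of lesions from ~58 kb down to 12 bp,
plus three false-positive mechanisms.

## The hybridization-attenuation model

For a probe footprint of length $L$ (60 bp) and one allele, let $f$ be
the disrupted fraction of the footprint:

* deleted bases overlapping the footprint;
* a window of $w_\mathrm{snv}$ bases (default 15) around a
  single-nucleotide variant;
* for an insertion splitting the footprint, everything outside the
  longest contiguous stretch of still-matching bases.

The allele hybridizes with efficiency $(1-f)^\alpha$. The probe's
expected ratio is
$\log_2\!\big(\max(\sum_a e_a,\ \varepsilon)/\mathrm{ploidy}\big)$ with
a background floor $\varepsilon$, plus i.i.d. Gaussian probe noise.

Parameter choices, all exposed in `attenuation_params()` and
`noise_model()`:

| parameter | default | units | why |
|---|---|---|---|
| `alpha` | 2 | — | a 60-mer loses hybridization faster than linearly in the disrupted fraction; with $\alpha=2$ a 12/60-base loss on one allele gives $\log_2((1+0.64)/2)\approx-0.29$, a visibly depressed but sub-threshold probe, matching the qualitative behaviour this class of arrays shows for sub-probe lesions |
| `w_snv` | 15 | bp | a single mismatch destabilizes a region of the duplex, not one base; 15 bp yields mild, review-level depression for heterozygous variants and $\approx-0.8$ for hemizygous ones |
| `eps` | 0.1 | copies | keeps hemizygous deletions finite at $\approx-3.3$, "well below" any threshold, without $-\infty$ |
| `probe_sd` | 0.12 | log2 | mid-point of the accepted DLR quality band (0.08–0.19) |

The generator emulates: per-probe ratios under deletions, duplications,
insertions and point variants; sense/antisense duplicated footprints;
spike-in control probes at 0; per-probe "dropout to normal" masks (for
the empirically observed probes inside confirmed deletions that
nevertheless hybridize normally). It does **not** emulate dye bias, GC
waves, spatial artifacts, cross-hybridization or intensity-level
(pre-ratio) effects — so a passing suite shows the *analysis logic*
behaves as documented under calibrated noise, not that the noise model
captures every failure mode of real arrays.

## Segmentation and baseline

Circular binary segmentation is implemented from scratch (the arc scan
in compiled code): every circular arc $(i,j]$ is scored with
$T=(\bar{x}_{in}-\bar{x}_{out})\big/\big(s\sqrt{1/n_{in}+1/n_{out}}\big)$
(pooled residual $s$), and the maximal $|T|$ split is accepted when its
within-chromosome permutation p-value beats `alpha`. Defaults
(`cbs_params()`): `alpha = 0.01`, `n_permutations = 1000`,
`min_split_width = 2`, `prune_sd = 1.5`, explicit seed. Ties break to
the smallest $(i,j)$; a perfect noiseless split (pooled $s=0$) gets a
large sentinel statistic; permutation counting stops early once
significance is impossible. Adjacent segments closer than `prune_sd`
residual standard deviations are merged. Segments smaller than four
probes are deliberately *retained*: the four-probe minimum is a calling
rule, and applying it at segmentation would hide exactly the two-probe
events manual review exists to catch.

The baseline deserves a note. Probe-median centering fails on targeted
designs whenever a deletion covers most of a small gene's probes (the
median lands on the deleted level and the profile inverts). The
pipeline therefore re-baselines after segmentation on the median of the
segment means weighted by genomic span: the normal-copy state occupies
most of a locus even when it carries a minority of probes, and span
weighting is also immune to the segmenter fragmenting one lesion into
several segments. `median_center()` (probe median) is kept as a
harmless, shift-invariant first pass.

## QC, calling and review

The derivative log ratio is the spread of probe-to-probe first
differences divided by $\sqrt 2$, measured with the scaled median
absolute deviation. The robust estimator matters on per-gene manifests:
a hemizygous deletion contributes steps of $|\Delta|\approx3.3$ among
only hundreds of differences, enough to push a standard-deviation DLR
past the 0.30 rejection bound and reject precisely the arrays that
carry lesions; the MAD form ignores the handful of breakpoint steps
while recovering the probe noise (within ±10% at $n=10^4$ in the test
suite). `compute_dlr(robust = FALSE, derivative = FALSE)` restores the
naive variants.

Calling uses the documented thresholds: deletion at mean log2 ≤ −0.6
(deliberately looser than the theoretical −1), duplication at ≥ +0.4,
four probes minimum. An X-chromosome deletion call in an XY sample with
mean above −2.5 (the expected hemizygous depth under $\varepsilon=0.1$)
is flagged `hemizygous_underdepth` — such calls are usually sequence
variants under the probes, not deletions.

Manual review is modelled as: every maximal run of probes below
`review_log2_threshold` (default −0.25) is escalated if at least one of
the four documented criteria holds (two-probe evidence — including a
sense/antisense pair on one footprint —, sequencing-primer overlap,
recessive gene with one known mutation, dominant gene with clinical
suspicion). The −0.25 default is a *surrogate* for "arouses suspicion
upon manual review", chosen to sit between the two-probe 12-bp
signature (−0.29) and accepted-quality noise; it is config-exposed and
reported as a surrogate, since no quantitative rule for human review
exists.

## Breakpoints and junctions

Deviant probes give an inner (minimally deleted) and outer (maximally
deleted) interval; on overlapping probe designs the outer bound is
clamped to contain the inner one, since a flanking normal probe's
footprint can reach inside the deviant span. Breakpoints recovered from
probe evidence understate deletions that run past probe coverage — the
walking-primer planner and junction analysis exist for that reason.
Junction analysis aligns reference and rearranged sequence by longest
shared flanks; the overlap of maximal prefix and suffix measures the
microhomology (breakpoints are reported left-aligned, homology length
separate, an HGVS-like convention chosen because junction reports are
otherwise ambiguous under homology). Inserted bases are classified by
ordered tests: reverse-complement match within 500 bp of a breakpoint
(locally inverted), exact match in a supplied search set (distally
templated; exact matching only — alignment heuristics are out of
scope), flanking direct repeat of ≥ 6 bp (mobile element with
target-site duplication), else unknown. Equal-length
substitution-only differences classify as `substitution_only`, which is
how sequence-variant false positives are recognized. Simulated sequence
follow-up (`resolve_candidate()`) widens its window until every
overlapping event is fully contained — emulating outward primer walking
— because a junction read against a truncated lesion reports a wrong
length.

## The twelve-case suite

`build_case_suite()` instantiates synthetic replicas of twelve cases on
ten fixture genes with invented but size-realistic exon geometries:
heterozygous deletions of 58 kb, 19 kb, 3.7 kb; a hemizygous 2,319-bp
deletion with a 69-bp distally templated insert; 1,325-bp and 971-bp
deletions with 4- and 3-base microhomology whose calls stay above −0.6
because interleaved probes inside the deletion hybridize normally (the
dropout mask); an 801-bp partial-exon deletion with an 11-base locally
inverted insert and a MIRb element 32 bp from the intronic breakpoint;
a hemizygous 267-bp deletion carried by sense/antisense pair evidence;
a compound-heterozygous pair of ~3.6 kb (given as "> 3.5 kb" in the
source material) plus a 12-bp intronic deletion under a duplicated
footprint overlapping the sequencing primer; and three false positives
(349-base insertion with a 16-base target-site duplication, hemizygous
SNV, compound-heterozygous SNVs in trans). Per-gene probe spacing
(15–120 bp), flanks and antisense duplication are design choices of the
replica, documented in `gene_geometry()`; the source design is only
characterized qualitatively, so densities were fixed once at values a
targeted diagnostic array would plausibly use and not tuned thereafter.
Microhomologies and insert origins are *planted* in the random fixture
sequences with guard bases that make them exact, so junction round-trip
tests can assert equality rather than tolerance.

Problem sizes are kept at desk scale on purpose: per-gene manifests of
roughly 50–900 probes and fixture sequences of 25–165 kb, which the
full twelve-case evaluation traverses in well under a minute per run.

## Numerical and degenerate-input choices

* All internal coordinates are 0-based half-open (BED convention);
  1-based inclusive appears only in human-readable reports.
* Probe placement is deterministic left-anchored tiling with a tail
  probe so region ends stay covered; sub-probe exons get one centered
  probe.
* Constant profiles are never split; permutation seeds are threaded
  explicitly and every simulation takes an integer seed, so suite
  construction and evaluation are bit-reproducible.
* The permutation p-value is $(1+\#\{|T^\ast|\ge|T|\})/(1+B)$ with
  early stopping once the count precludes significance.
* Melting temperatures use a per-base GC formula — adequate to pick
  plausible primers, deliberately not a thermodynamic model.
* An all-degenerate (`N`) reference yields an empty primer plan with
  warnings; junction analysis of sequences sharing no flank returns an
  explicit `none` report with a warning rather than guessing.

## Known limitations

* The attenuation exponent and SNV window are calibration knobs, not
  measured chemistry; conclusions about absolute (rather than relative)
  detection rates should not be read off the simulator.
* Probe-evidence breakpoint bounds assume all-or-nothing hybridization
  at the flanks; a breakpoint a few bases inside a flanking probe can
  escape the outer interval (the partial signal is too weak to mark the
  probe deviant).
* Review criteria are gene-level; in a gene qualifying under the
  recessive-one-mutation rule, every noise run below the review
  threshold becomes a candidate, as in practice — the workload is
  bounded by the follow-up stage, which resolves such runs as
  `unresolved`.
* The false-positive resolution relies on simulated sequence follow-up;
  with real data this step is PCR and Sanger sequencing, whose failure
  modes (allelic dropout above all) are represented only through the
  primer-overlap review criterion.
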