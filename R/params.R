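#' Array design parameters
#'
#' Parameter record controlling exon-centric probe placement. Probes are
#' 60-mers by convention on gene-targeted oligo arrays; exons are tiled
#' together with a flanking margin so that intronic breakpoints close to an
#' exon still fall under probes.
#'
#' @param probe_length Probe footprint length in bp (fixed-length oligos).
#' @param exon_flank_bp Intronic margin tiled on each side of every exon, bp.
#' @param target_spacing_bp Start-to-start spacing of target probes, bp.
#'   Spacing at or below `probe_length` guarantees every exon base is covered.
#' @param antisense_duplication If `TRUE`, every target footprint is probed
#'   once per strand (two probes with identical coordinates, `+` and `-`),
#'   the redundant configuration that makes two-probe manual-review evidence
#'   possible for sub-probe-size deletions.
#' @param backbone_spacing_bp Spacing of backbone (normalization/context)
#'   probes placed outside the targeted regions, bp.
#' @param backbone_margin_bp How far beyond the outermost exons backbone
#'   probes extend, bp.
#' @return A list of class `design_params`.
#' @export
design_params <- function(probe_length = 60L,
                          exon_flank_bp = 200L,
                          target_spacing_bp = 30L,
                          antisense_duplication = FALSE,
                          backbone_spacing_bp = 5000L,
                          backbone_margin_bp = 10000L) {
  stopifnot(probe_length > 0, exon_flank_bp >= 0, target_spacing_bp > 0,
            backbone_spacing_bp > 0, backbone_margin_bp >= 0,
            is.logical(antisense_duplication))
  structure(list(probe_length = as.integer(probe_length),
                 exon_flank_bp = as.integer(exon_flank_bp),
                 target_spacing_bp = as.integer(target_spacing_bp),
                 antisense_duplication = isTRUE(antisense_duplication),
                 backbone_spacing_bp = as.integer(backbone_spacing_bp),
                 backbone_margin_bp = as.integer(backbone_margin_bp)),
            class = "design_params")
}

#' Probe-level noise model
#'
#' Independent Gaussian noise added to each probe's log2 ratio. The default
#' standard deviation of 0.12 sits in the middle of the accepted derivative
#' log ratio quality band (0.08-0.19).
#'
#' @param probe_sd Per-probe log2 standard deviation (>= 0).
#' @param seed Integer seed; simulation is bit-reproducible for a fixed seed.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(probe_sd = 0.12, seed = 1L) {
  stopifnot(is.numeric(probe_sd), probe_sd >= 0, is.numeric(seed))
  structure(list(probe_sd = probe_sd, seed = as.integer(seed)),
            class = "noise_model")
}

#' Circular binary segmentation parameters
#'
#' @param alpha Permutation significance level for accepting a split.
#' @param n_permutations Number of within-chromosome permutations (>= 100).
#' @param min_split_width Minimum arc width considered by the scan.
#' @param prune_sd Adjacent segments whose means differ by less than
#'   `prune_sd` residual standard deviations are merged after splitting.
#' @param seed Integer seed for the permutation shuffles.
#' @return A list of class `cbs_params`.
#' @export
cbs_params <- function(alpha = 0.01, n_permutations = 1000L,
                       min_split_width = 2L, prune_sd = 1.5, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, n_permutations >= 100,
            min_split_width >= 1, prune_sd >= 0)
  structure(list(alpha = alpha,
                 n_permutations = as.integer(n_permutations),
                 min_split_width = as.integer(min_split_width),
                 prune_sd = prune_sd,
                 seed = as.integer(seed)),
            class = "cbs_params")
}

#' Segment calling thresholds
#'
#' Deletion calls at a segment mean log2 ratio of -0.6 (less stringent than
#' the theoretical heterozygous value of -1), duplications at +0.4, both
#' requiring a minimum of four probes per segment. X-chromosome deletion
#' calls in an XY sample that do not reach `hemizygous_max` are flagged as
#' suspiciously shallow for a hemizygous loss (a sequence-variant suspect).
#'
#' @param deletion Log2 threshold at or below which a segment is a deletion.
#' @param duplication Log2 threshold at or above which a segment is a
#'   duplication.
#' @param min_probes Minimum probes per segment for an automatic call.
#' @param hemizygous_max Expected upper bound of a true hemizygous deletion's
#'   log2 ratio under the simulator's background floor.
#' @return A list of class `call_thresholds`.
#' @export
call_thresholds <- function(deletion = -0.6, duplication = 0.4,
                            min_probes = 4L, hemizygous_max = -2.5) {
  stopifnot(deletion < 0, duplication > 0, min_probes >= 1)
  structure(list(deletion = deletion, duplication = duplication,
                 min_probes = as.integer(min_probes),
                 hemizygous_max = hemizygous_max),
            class = "call_thresholds")
}

#' Manual-review context
#'
#' Gene-level knowledge and laboratory context consulted when escalating
#' sub-threshold probe runs to manual-review candidates: inheritance mode,
#' how many pathogenic mutations are already known in the gene for this
#' patient, clinical suspicion, and the intervals of the primers used in
#' sequencing (a deletion under a primer causes allelic dropout, so such
#' overlaps warrant investigation).
#'
#' @param gene_info Data frame with columns `gene_symbol`, `inheritance`
#'   (one of `"AD"`, `"AR"`, `"XL"`), `known_mutation_count`,
#'   `clinical_suspicion`.
#' @param primer_intervals Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) of sequencing primer binding sites, or `NULL`.
#' @param review_log2_threshold Probe-level log2 value below which a probe is
#'   considered deviant during manual review. The default of -0.25 is a
#'   surrogate for "arouses suspicion upon manual review": it catches the
#'   two-probe evidence left by a 12-bp deletion under a 60-mer (model value
#'   about -0.29) while ignoring probe noise at accepted array quality.
#' @return A list of class `review_context`.
#' @export
review_context <- function(gene_info = NULL, primer_intervals = NULL,
                           review_log2_threshold = -0.25) {
  if (!is.null(gene_info)) {
    stopifnot(is.data.frame(gene_info),
              all(c("gene_symbol", "inheritance", "known_mutation_count",
                    "clinical_suspicion") %in% names(gene_info)),
              all(gene_info$inheritance %in% c("AD", "AR", "XL")))
  }
  if (!is.null(primer_intervals)) {
    stopifnot(is.data.frame(primer_intervals),
              all(c("chrom", "start", "end") %in% names(primer_intervals)),
              all(primer_intervals$end > primer_intervals$start))
  }
  stopifnot(review_log2_threshold < 0)
  structure(list(gene_info = gene_info,
                 primer_intervals = primer_intervals,
                 review_log2_threshold = review_log2_threshold),
            class = "review_context")
}

#' Junction-analysis parameters
#'
#' @param inverted_window Window (bp) on each side of a breakpoint searched
#'   for a reverse-complement match when classifying inserted sequence as
#'   locally inverted.
#' @param tsd_min Minimum direct-repeat length accepted as a target-site
#'   duplication flanking a mobile-element insertion.
#' @param repeat_window Closed window (bp) around an interval within which
#'   repeat-track elements are reported.
#' @return A list of class `junction_params`.
#' @export
junction_params <- function(inverted_window = 500L, tsd_min = 6L,
                            repeat_window = 1000L) {
  stopifnot(inverted_window > 0, tsd_min >= 2, repeat_window >= 0)
  structure(list(inverted_window = as.integer(inverted_window),
                 tsd_min = as.integer(tsd_min),
                 repeat_window = as.integer(repeat_window)),
            class = "junction_params")
}

#' Attenuation model parameters
#'
#' How lesions under a probe reduce its hybridization. A probe with matched
#' footprint fraction `1 - f` hybridizes with efficiency `(1 - f)^alpha`;
#' a single-nucleotide mismatch destabilizes a window of `w_snv` bases; a
#' signal below `eps` copies is clamped to the background floor so that
#' hemizygous deletions land near log2(eps) rather than -Inf.
#'
#' @param alpha Destabilization exponent applied to the matched fraction.
#' @param w_snv Disruption window of a single-nucleotide variant, bp.
#' @param eps Background hybridization floor, in copy units.
#' @return A list of class `attenuation_params`.
#' @export
attenuation_params <- function(alpha = 2, w_snv = 15L, eps = 0.1) {
  stopifnot(alpha > 0, w_snv >= 1, eps > 0, eps < 1)
  structure(list(alpha = alpha, w_snv = as.integer(w_snv), eps = eps),
            class = "attenuation_params")
}
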