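#' Ground-truth events and genotypes
#'
#' Constructors for the events a simulated genome can carry. Coordinates are
#' 0-based half-open; an insertion is a zero-width event at `pos`; `allele`
#' assigns the event to allele 1 or 2 (X-linked events in an XY sample must
#' sit on allele 1, the single X).
#'
#' @param chrom Chromosome.
#' @param start,end Deletion / duplication footprint.
#' @param allele 1 or 2.
#' @param insert Bases inserted between the deletion breakpoints (optional).
#' @return A list of class `event`.
#' @export
ev_deletion <- function(chrom, start, end, allele = 1L, insert = "") {
  stopifnot(end - start >= 1)
  structure(list(kind = "deletion", chrom = chrom, start = as.integer(start),
                 end = as.integer(end), allele = as.integer(allele),
                 insert = insert),
            class = "event")
}

#' @rdname ev_deletion
#' @export
ev_duplication <- function(chrom, start, end, allele = 1L) {
  stopifnot(end - start >= 1)
  structure(list(kind = "duplication", chrom = chrom,
                 start = as.integer(start), end = as.integer(end),
                 allele = as.integer(allele), insert = ""),
            class = "event")
}

#' @rdname ev_deletion
#' @param pos Insertion point / variant position.
#' @param seq Inserted sequence.
#' @export
ev_insertion <- function(chrom, pos, seq, allele = 1L) {
  stopifnot(nchar(seq) >= 1)
  structure(list(kind = "insertion", chrom = chrom, start = as.integer(pos),
                 end = as.integer(pos), allele = as.integer(allele),
                 insert = seq),
            class = "event")
}

#' @rdname ev_deletion
#' @param alt Alternate base of a single-nucleotide variant.
#' @export
ev_snv <- function(chrom, pos, alt, allele = 1L) {
  stopifnot(nchar(alt) == 1)
  structure(list(kind = "snv", chrom = chrom, start = as.integer(pos),
                 end = as.integer(pos) + 1L, allele = as.integer(allele),
                 insert = alt),
            class = "event")
}

#' Genotype specification
#'
#' @param sample_sex `"XX"` or `"XY"`.
#' @param events List of [ev_deletion()]-family events.
#' @return A list of class `genotype_spec`.
#' @export
genotype_spec <- function(sample_sex = c("XX", "XY"), events = list()) {
  sample_sex <- match.arg(sample_sex)
  stopifnot(all(vapply(events, inherits, logical(1), "event")))
  for (e in events) {
    if (chrom_ploidy(e$chrom, sample_sex) == 1 && e$allele != 1L) {
      stop("events on a hemizygous chromosome must sit on allele 1")
    }
  }
  structure(list(sample_sex = sample_sex, events = events),
            class = "genotype_spec")
}

## copies of a chromosome carried by a sample of the given sex
chrom_ploidy <- function(chrom, sex) {
  base <- sub("^chr", "", chrom)
  if (base == "X") return(if (sex == "XY") 1L else 2L)
  if (base == "Y") return(if (sex == "XY") 1L else 0L)
  2L
}

#' Theoretical copy-ratio log2 value
#'
#' The expected log2(test/reference) at a locus with `copies_test` copies in
#' the test sample against `copies_ref` in the reference: -1 for a
#' heterozygous deletion (1 vs 2), 0 for no change (2 vs 2), +0.585 for a
#' heterozygous duplication (3 vs 2). Zero test copies are clamped at the
#' background-hybridization floor `eps` instead of -Inf.
#'
#' @param copies_test Integer >= 0.
#' @param copies_ref Integer >= 1.
#' @param eps Background floor in copy units.
#' @return The log2 ratio.
#' @export
expected_log2 <- function(copies_test, copies_ref = 2L, eps = 0.1) {
  if (any(copies_test < 0) || any(copies_ref < 1)) {
    stop("copy numbers must be non-negative (reference >= 1)")
  }
  log2(pmax(copies_test, eps) / copies_ref)
}

## positions covered by the SNV disruption window, centered on the variant
snv_window <- function(pos, w) {
  c(pos - (w %/% 2L), pos - (w %/% 2L) + w)  # [start, end)
}

#' Hybridization efficiency of a probe over one allele
#'
#' Computes the fraction `f` of the probe footprint disrupted by the allele's
#' events — deleted bases, the single-nucleotide disruption window, and, for
#' insertions splitting the footprint, everything outside the longest
#' contiguous stretch of matching bases — and returns `(1 - f)^alpha`.
#' A probe untouched by any event has efficiency 1.
#'
#' @param probe_start,probe_end Probe footprint (0-based half-open).
#' @param events List of events on this allele and chromosome.
#' @param att [attenuation_params()].
#' @return Efficiency in `[0, 1]`.
#' @export
probe_efficiency <- function(probe_start, probe_end, events,
                             att = attenuation_params()) {
  L <- probe_end - probe_start
  stopifnot(L > 0)
  disrupted <- rep(FALSE, L)
  splits <- integer(0)
  for (e in events) {
    if (e$kind %in% c("deletion", "snv")) {
      win <- if (e$kind == "snv") snv_window(e$start, att$w_snv)
             else c(e$start, e$end)
      lo <- max(win[1], probe_start); hi <- min(win[2], probe_end)
      if (hi > lo) disrupted[(lo - probe_start + 1):(hi - probe_start)] <- TRUE
    } else if (e$kind == "insertion") {
      if (e$start > probe_start && e$start < probe_end) {
        splits <- c(splits, e$start - probe_start)  # break after this base
      }
    }
  }
  if (length(splits) == 0) {
    matched <- sum(!disrupted)
  } else {
    # contiguous homology runs are bounded by disrupted bases and split points
    run_id <- cumsum(seq_len(L) %in% (splits + 1L))
    ok <- !disrupted
    matched <- 0L
    for (r in unique(run_id)) {
      v <- ok[run_id == r]
      if (!any(v)) next
      runs <- rle(v)
      matched <- max(matched, max(runs$lengths[runs$values]))
    }
  }
  (matched / L)^att$alpha
}

## extra signal contributed by duplications overlapping the probe
probe_dup_gain <- function(probe_start, probe_end, events, att) {
  g <- 0
  L <- probe_end - probe_start
  for (e in events) {
    if (e$kind == "duplication") {
      ov <- min(e$end, probe_end) - max(e$start, probe_start)
      if (ov > 0) g <- g + (ov / L)^att$alpha
    }
  }
  g
}

#' Simulate a probe-level log2-ratio profile
#'
#' Per probe, the test signal is the sum over the sample's alleles of the
#' allele's hybridization efficiency (plus any duplication gain); the
#' reference signal is the locus ploidy of the same-sex reference. The
#' emitted value is `log2(max(signal, eps)/reference)` plus i.i.d. Gaussian
#' probe noise. Control probes emit pure noise around 0. Probes listed in
#' `dropout_normal` hybridize normally regardless of underlying events (the
#' unexplained normal-signal probes seen inside some confirmed deletions).
#'
#' @param manifest A `probe_manifest`.
#' @param genotype A [genotype_spec()].
#' @param noise A [noise_model()].
#' @param att [attenuation_params()].
#' @param reference_sex Reference pool sex; must equal the sample sex
#'   (same-sex control hybridization).
#' @param dropout_normal Character vector of probe ids forced to normal
#'   hybridization.
#' @return An `array_profile`: data frame (`probe_id`, `log2_ratio`) aligned
#'   with the manifest rows, with sex and noise metadata attached.
#' @export
simulate_profile <- function(manifest, genotype, noise = noise_model(),
                             att = attenuation_params(),
                             reference_sex = genotype$sample_sex,
                             dropout_normal = character(0)) {
  stopifnot(inherits(manifest, "probe_manifest"),
            inherits(genotype, "genotype_spec"),
            inherits(noise, "noise_model"))
  if (reference_sex != genotype$sample_sex) {
    stop("reference must be a same-sex control")
  }
  man_chroms <- unique(manifest$chrom)
  for (e in genotype$events) {
    if (!e$chrom %in% man_chroms) {
      stop("event chromosome ", e$chrom, " absent from manifest")
    }
  }
  n <- nrow(manifest)
  log2r <- numeric(n)
  sex <- genotype$sample_sex
  # group events by (chrom, allele); only probes near events need evaluation
  for (chrom in man_chroms) {
    if (chrom == "chrCTRL") next
    pl <- chrom_ploidy(chrom, sex)
    idx <- which(manifest$chrom == chrom & manifest$category != "control")
    if (pl == 0 || length(idx) == 0) next
    evs <- Filter(function(e) e$chrom == chrom, genotype$events)
    if (length(evs) == 0) next
    ps <- manifest$start[idx]; pe <- manifest$end[idx]
    touched <- rep(FALSE, length(idx))
    for (e in evs) {
      pad <- if (e$kind == "snv") att$w_snv else 0L
      touched <- touched | (ps < e$end + pad & pe > e$start - pad)
    }
    for (k in which(touched)) {
      signal <- 0
      for (a in seq_len(pl)) {
        aev <- Filter(function(e) e$allele == a, evs)
        signal <- signal +
          probe_efficiency(ps[k], pe[k], aev, att) +
          probe_dup_gain(ps[k], pe[k], aev, att)
      }
      log2r[idx[k]] <- log2(max(signal, att$eps) / pl)
    }
  }
  if (length(dropout_normal)) {
    log2r[manifest$probe_id %in% dropout_normal] <- 0
  }
  if (noise$probe_sd > 0) {
    log2r <- log2r + withr::with_seed(noise$seed,
                                      rnorm(n, 0, noise$probe_sd))
  }
  structure(data.frame(probe_id = manifest$probe_id, log2_ratio = log2r,
                       stringsAsFactors = FALSE),
            sample_sex = sex, reference_sex = reference_sex,
            noise = noise, attenuation = att,
            class = c("array_profile", "data.frame"))
}

#' Reference-sequence fixture
#'
#' A chromosome slice with a genomic offset, used in place of a genome for
#' sequence-level follow-up of simulated calls.
#'
#' @param chrom Chromosome name.
#' @param start Genomic start of the slice (0-based).
#' @param seq Sequence string.
#' @return A list of class `seq_fixture`.
#' @export
seq_fixture <- function(chrom, start, seq) {
  structure(list(chrom = chrom, start = as.integer(start), seq = seq,
                 end = as.integer(start) + nchar(seq)),
            class = "seq_fixture")
}

#' Deterministic random DNA
#'
#' @param n Sequence length.
#' @param seed Integer seed.
#' @return A sequence string of length `n`.
#' @export
random_dna <- function(n, seed) {
  paste(withr::with_seed(seed,
        sample(c("A", "C", "G", "T"), n, replace = TRUE)), collapse = "")
}

## fixture lookup: first fixture fully containing [start, end) on chrom
find_fixture <- function(fixtures, chrom, start, end) {
  if (inherits(fixtures, "seq_fixture")) fixtures <- list(fixtures)
  for (fx in fixtures) {
    if (fx$chrom == chrom && fx$start <= start && fx$end >= end) return(fx)
  }
  NULL
}

#' Emit per-allele sample sequences over a region
#'
#' Applies the genotype's events (deletions with optional inserted bases,
#' insertions, single-nucleotide variants, tandem duplications) to the
#' reference fixture over `region` and returns one sequence per allele.
#' Events extending past the region are clipped to it; an insert between
#' deletion breakpoints is retained when the left breakpoint lies inside
#' the region. Stands in for the PCR/Sanger follow-up of a real workflow.
#'
#' @param genotype A [genotype_spec()].
#' @param fixtures A `seq_fixture` or list of them.
#' @param region `list(chrom=, start=, end=)`, 0-based half-open.
#' @return Named list (`allele1`, and `allele2` where the locus is diploid)
#'   of sequence strings.
#' @export
emit_local_sequence <- function(genotype, fixtures, region) {
  fx <- find_fixture(fixtures, region$chrom, region$start, region$end)
  if (is.null(fx)) stop("region is not covered by any sequence fixture")
  ref <- substr(fx$seq, region$start - fx$start + 1,
                region$end - fx$start)
  pl <- chrom_ploidy(region$chrom, genotype$sample_sex)
  if (pl == 0) stop("sample carries no copy of ", region$chrom)
  out <- list()
  for (a in seq_len(pl)) {
    evs <- Filter(function(e) {
      e$chrom == region$chrom && e$allele == a &&
        e$end >= region$start && e$start <= region$end
    }, genotype$events)
    s <- ref
    # apply right-to-left so earlier coordinates stay valid
    if (length(evs)) {
      ord <- order(vapply(evs, function(e) e$start, numeric(1)),
                   decreasing = TRUE)
      for (e in evs[ord]) {
        ls <- max(e$start, region$start) - region$start  # local, 0-based
        le <- min(e$end, region$end) - region$start
        if (e$kind == "deletion") {
          ins <- if (e$start >= region$start) e$insert else ""
          s <- paste0(substr(s, 1, ls), ins,
                      substr(s, le + 1, nchar(s)))
        } else if (e$kind == "insertion") {
          s <- paste0(substr(s, 1, ls), e$insert,
                      substr(s, ls + 1, nchar(s)))
        } else if (e$kind == "snv") {
          substr(s, ls + 1, ls + 1) <- e$insert
        } else if (e$kind == "duplication") {
          s <- paste0(substr(s, 1, le), substr(s, ls + 1, le),
                      substr(s, le + 1, nchar(s)))
        }
      }
    }
    out[[paste0("allele", a)]] <- s
  }
  out
}
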