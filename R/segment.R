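#' Median-center an array profile
#'
#' Subtracts, per chromosome, the median probe log2 ratio, so that segment
#' means are read against a zero baseline (the median of all probes on the
#' chromosome). Control probes are left untouched.
#'
#' @param profile An `array_profile`.
#' @param manifest The matching `probe_manifest` (provides chromosome
#'   grouping for the probes).
#' @return The centered `array_profile`.
#' @export
median_center <- function(profile, manifest) {
  stopifnot(inherits(profile, "array_profile"),
            nrow(profile) == nrow(manifest),
            all(profile$probe_id == manifest$probe_id))
  for (chrom in unique(manifest$chrom)) {
    idx <- which(manifest$chrom == chrom & manifest$category != "control")
    if (length(idx) == 0) next
    profile$log2_ratio[idx] <-
      profile$log2_ratio[idx] - median(profile$log2_ratio[idx])
  }
  profile
}

#' Best circular-arc split of an ordered signal
#'
#' Scans every arc `(i, j]` (0-based boundaries; the arc covers probes
#' `i+1 .. j` in 1-based indexing) with both arc and complement at least
#' `min_split_width` probes, and returns the arc maximizing the absolute
#' two-sample t-like statistic, ties broken by the smallest `(i, j)`.
#'
#' @param values Numeric vector of ordered log2 ratios (length at least
#'   `2 * min_split_width`).
#' @param min_split_width Minimum arc / complement width.
#' @return `list(i=, j=, t=)`; `t` is signed (arc mean minus complement
#'   mean, standardized). A constant input yields `t = 0`.
#' @export
best_split <- function(values, min_split_width = 2L) {
  stopifnot(length(values) >= 2 * min_split_width)
  cbs_scan_arcs(as.numeric(values), as.integer(min_split_width))
}

## recursive splitting of one chromosome's values; returns integer vector of
## segment end positions (1-based, cumulative)
cbs_recurse <- function(x, params) {
  n <- length(x)
  if (n < 2 * params$min_split_width || diff(range(x)) < 1e-12) return(n)
  sc <- cbs_scan_arcs(x, params$min_split_width)
  if (sc$i < 0 || abs(sc$t) == 0) return(n)
  max_exceed <- ceiling(params$alpha * (params$n_permutations + 1))
  pc <- cbs_perm_count(x, params$min_split_width, abs(sc$t),
                       params$n_permutations, max_exceed)
  p <- (1 + pc[1]) / (1 + pc[2])
  if (p >= params$alpha) return(n)
  bounds <- unique(c(sc$i, sc$j)[c(sc$i, sc$j) > 0 & c(sc$i, sc$j) < n])
  pieces <- c(0L, bounds, n)
  ends <- integer(0)
  for (k in seq_len(length(pieces) - 1)) {
    lo <- pieces[k] + 1L; hi <- pieces[k + 1]
    ends <- c(ends, pieces[k] + cbs_recurse(x[lo:hi], params))
  }
  ends
}

## merge adjacent segments whose means differ by < prune_sd * residual sd
cbs_merge <- function(x, ends, prune_sd) {
  repeat {
    if (length(ends) < 2) return(ends)
    starts <- c(1L, head(ends, -1) + 1L)
    means <- vapply(seq_along(ends), function(k) {
      mean(x[starts[k]:ends[k]])
    }, numeric(1))
    resid <- x - rep(means, ends - starts + 1L)
    s <- sd(resid)
    if (!is.finite(s) || s < 1e-12) return(ends)
    d <- abs(diff(means))
    k <- which.min(d)
    if (d[k] >= prune_sd * s) return(ends)
    ends <- ends[-k]
  }
}

#' Circular binary segmentation of an array profile
#'
#' Recursively splits each chromosome's probe-ordered, median-centered log2
#' ratios at the arc maximizing the |T| statistic whenever the permutation
#' p-value of the observed maximum is below `alpha`, then merges adjacent
#' segments whose means differ by less than `prune_sd` residual standard
#' deviations. Segments smaller than the calling minimum of four probes are
#' produced and retained: the probe-count rule belongs to calling, so that
#' two-probe events stay visible to manual review. Control probes are
#' excluded.
#'
#' @param profile A median-centered `array_profile`.
#' @param manifest The matching `probe_manifest`.
#' @param params A [cbs_params()] record.
#' @return Data frame of segments: `chrom`, `start`, `end` (genomic span of
#'   the probe footprints), `first_probe`, `last_probe` (manifest row
#'   indices), `n_probes`, `mean_log2`.
#' @export
cbs_segment <- function(profile, manifest, params = cbs_params()) {
  stopifnot(inherits(profile, "array_profile"),
            nrow(profile) == nrow(manifest),
            all(profile$probe_id == manifest$probe_id))
  out <- list()
  withr::with_seed(params$seed, {
    for (chrom in setdiff(unique(manifest$chrom), "chrCTRL")) {
      idx <- which(manifest$chrom == chrom & manifest$category != "control")
      if (length(idx) == 0) next
      x <- profile$log2_ratio[idx]
      ends <- cbs_recurse(x, params)
      ends <- cbs_merge(x, ends, params$prune_sd)
      starts <- c(1L, head(ends, -1) + 1L)
      out[[chrom]] <- data.frame(
        chrom = chrom,
        start = manifest$start[idx[starts]],
        end = manifest$end[idx[ends]],
        first_probe = idx[starts],
        last_probe = idx[ends],
        n_probes = ends - starts + 1L,
        mean_log2 = vapply(seq_along(ends), function(k) {
          mean(x[starts[k]:ends[k]])
        }, numeric(1)),
        stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## median of v weighted by w
weighted_median <- function(v, w) {
  o <- order(v)
  v <- v[o]; w <- w[o]
  v[which(cumsum(w) >= sum(w) / 2)[1]]
}

#' Re-baseline a profile on the median of its segments
#'
#' Averaging of segments uses the median value of all segments on a
#' chromosome as the baseline: the median of the segment means, weighted by
#' the genomic span each segment covers, is subtracted from every probe and
#' segment mean on that chromosome. Unlike a probe-level median, this
#' baseline is not dragged toward a deletion that covers most of a small
#' gene's probes — on an exon-centric design the normal-copy state occupies
#' most of the genomic span even when it carries a minority of the probes —
#' and, unlike an unweighted segment median, it is not swayed when the
#' segmenter fragments one lesion into several small segments.
#' Segmentation itself is shift-invariant, so it is valid to segment first
#' and set the baseline afterwards.
#'
#' @param profile The `array_profile` that was segmented.
#' @param manifest The matching `probe_manifest`.
#' @param segments Output of [cbs_segment()] on `profile`.
#' @return `list(profile=, segments=)`, both re-baselined.
#' @export
segment_median_baseline <- function(profile, manifest, segments) {
  for (chrom in unique(segments$chrom)) {
    on_chrom <- segments$chrom == chrom
    base <- weighted_median(segments$mean_log2[on_chrom],
                            pmax(1, segments$end[on_chrom] -
                                   segments$start[on_chrom]))
    idx <- which(manifest$chrom == chrom & manifest$category != "control")
    profile$log2_ratio[idx] <- profile$log2_ratio[idx] - base
    segments$mean_log2[segments$chrom == chrom] <-
      segments$mean_log2[segments$chrom == chrom] - base
  }
  list(profile = profile, segments = segments)
}
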