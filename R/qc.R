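#' Derivative log ratio quality score
#'
#' The array quality gate: the spread of probe-to-probe log2 differences
#' divided by `sqrt(2)`, which estimates the per-probe noise standard
#' deviation while being insensitive to true copy-number structure (a plain
#' standard deviation would conflate the two; set `derivative = FALSE` to
#' use it anyway). The spread is measured robustly (scaled median absolute
#' deviation) by default, so that the few large probe-to-probe steps at
#' real breakpoints — extreme on a targeted design with only hundreds of
#' probes per gene — do not reject an otherwise clean array; set
#' `robust = FALSE` for the plain standard deviation of differences.
#' Status follows the conventional bands: below 0.20 accepted, 0.20-0.29
#' borderline, 0.30 and above rejected.
#'
#' @param profile An `array_profile` (at least 2 probes).
#' @param manifest Optional matching `probe_manifest`; when supplied,
#'   control probes are excluded and differences are taken within
#'   chromosomes.
#' @param derivative Use first differences (default) or the plain spread.
#' @param robust Use the scaled median absolute deviation (default) or the
#'   standard deviation.
#' @return `list(dlr_value=, status=)` of class `dlr_report`.
#' @export
compute_dlr <- function(profile, manifest = NULL, derivative = TRUE,
                        robust = TRUE) {
  stopifnot(inherits(profile, "array_profile"))
  x <- profile$log2_ratio
  if (!is.null(manifest)) {
    keep <- manifest$category != "control"
    grp <- manifest$chrom[keep]
    x <- x[keep]
  } else {
    grp <- rep("all", length(x))
  }
  if (length(x) < 2) stop("DLR needs at least 2 probes")
  spread <- if (robust) function(v) stats::mad(v) else sd
  if (derivative) {
    d <- unlist(lapply(split(x, grp), diff), use.names = FALSE)
    dlr <- spread(d) / sqrt(2)
  } else {
    dlr <- spread(x)
  }
  status <- if (dlr >= 0.30) "rejected"
            else if (dlr >= 0.20) "borderline"
            else "accepted"
  structure(list(dlr_value = dlr, status = status), class = "dlr_report")
}

#' Threshold calling on segments
#'
#' Automatic deletion calls for segments with mean log2 at or below the
#' deletion threshold (-0.6), duplications at or above +0.4, each requiring
#' a minimum of four probes. X-chromosome deletion calls in an XY sample
#' whose mean does not reach the expected hemizygous depth are flagged
#' `hemizygous_underdepth` (a sequence-variant suspect: a true hemizygous
#' loss falls far below -1).
#'
#' @param segments Segment data frame from [cbs_segment()].
#' @param sample_sex `"XX"` or `"XY"`.
#' @param thresholds A [call_thresholds()] record.
#' @return The segments augmented with `call_class` (deletion / duplication
#'   / none), `auto` (logical), and `review_flags` (comma-joined).
#' @export
call_segments <- function(segments, sample_sex = "XX",
                          thresholds = call_thresholds()) {
  cls <- rep("none", nrow(segments))
  cls[segments$mean_log2 <= thresholds$deletion] <- "deletion"
  cls[segments$mean_log2 >= thresholds$duplication] <- "duplication"
  auto <- cls != "none" & segments$n_probes >= thresholds$min_probes
  flags <- character(nrow(segments))
  hemi <- cls == "deletion" & auto & sample_sex == "XY" &
    sub("^chr", "", segments$chrom) == "X" &
    segments$mean_log2 > thresholds$hemizygous_max
  flags[hemi] <- "hemizygous_underdepth"
  out <- segments
  out$call_class <- cls
  out$auto <- auto
  out$review_flags <- flags
  out
}

## evaluate review criteria (a)-(d) for a run of manifest probes
run_flags <- function(probes, run_chrom, run_start, run_end, context) {
  flags <- character(0)
  if (nrow(probes) >= 2) {
    # (a) two entirely non-overlapping probes, or a same-footprint +/- pair
    non_ov <- max(probes$start) >= min(probes$end)
    key <- paste(probes$start, probes$end)
    as_pair <- any(tapply(probes$strand, key,
                          function(s) length(unique(s)) > 1))
    if (non_ov || as_pair) flags <- c(flags, "two_probe_evidence")
  }
  ctx_p <- context$primer_intervals
  if (!is.null(ctx_p)) {
    hit <- ctx_p$chrom == run_chrom & ctx_p$start < run_end &
      ctx_p$end > run_start
    if (any(hit)) flags <- c(flags, "primer_dropout")  # (b)
  }
  gi <- context$gene_info
  gene <- setdiff(unique(probes$gene_symbol), "")
  if (!is.null(gi) && length(gene)) {
    row <- gi[gi$gene_symbol %in% gene, , drop = FALSE]
    if (nrow(row)) {
      if (any(row$inheritance == "AR" & row$known_mutation_count >= 1)) {
        flags <- c(flags, "recessive_one_mutation")  # (c)
      }
      if (any(row$inheritance == "AD" & row$clinical_suspicion)) {
        flags <- c(flags, "dominant_suspicion")  # (d)
      }
    }
  }
  flags
}

#' Manual-review escalation of sub-threshold probe runs
#'
#' Scans the (centered) profile for maximal runs of consecutive probes below
#' the review threshold and escalates a run to a review candidate when at
#' least one criterion holds: (a) the evidence includes two entirely
#' non-overlapping probes or a sense/antisense pair sharing one footprint,
#' (b) the run overlaps a sequencing primer (possible allelic dropout),
#' (c) the gene is recessive with one mutation already identified, or
#' (d) the gene is dominant with strong clinical suspicion. Automatic calls
#' are passed through, so the reported set always contains them.
#'
#' @param profile A median-centered `array_profile`.
#' @param manifest The matching `probe_manifest`.
#' @param calls Output of [call_segments()].
#' @param context A [review_context()].
#' @return Data frame of reported calls and candidates with columns
#'   `chrom`, `start`, `end`, `first_probe`, `last_probe`, `n_probes`,
#'   `mean_log2`, `call_class`, `auto`, `review_flags`.
#' @export
review_candidates <- function(profile, manifest, calls,
                              context = review_context()) {
  stopifnot(nrow(profile) == nrow(manifest))
  thr <- context$review_log2_threshold
  cand <- list()
  for (chrom in setdiff(unique(manifest$chrom), "chrCTRL")) {
    idx <- which(manifest$chrom == chrom & manifest$category != "control")
    if (length(idx) == 0) next
    below <- profile$log2_ratio[idx] < thr
    r <- rle(below)
    pos_end <- cumsum(r$lengths)
    pos_start <- pos_end - r$lengths + 1L
    for (k in which(r$values)) {
      run_idx <- idx[pos_start[k]:pos_end[k]]
      probes <- manifest[run_idx, , drop = FALSE]
      rs <- min(probes$start); re <- max(probes$end)
      flags <- run_flags(probes, chrom, rs, re, context)
      if (length(flags) == 0) next
      cand[[length(cand) + 1]] <- data.frame(
        chrom = chrom, start = rs, end = re,
        first_probe = run_idx[1], last_probe = run_idx[length(run_idx)],
        n_probes = length(run_idx),
        mean_log2 = mean(profile$log2_ratio[run_idx]),
        call_class = "deletion", auto = FALSE,
        review_flags = paste(sort(unique(flags)), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  cols <- c("chrom", "start", "end", "first_probe", "last_probe",
            "n_probes", "mean_log2", "call_class", "auto", "review_flags")
  auto_calls <- calls[calls$auto, cols, drop = FALSE]
  cand_df <- if (length(cand)) do.call(rbind, cand) else
    auto_calls[0, cols, drop = FALSE]
  # drop candidates that duplicate an auto call's probe range
  if (nrow(cand_df) && nrow(auto_calls)) {
    dup <- vapply(seq_len(nrow(cand_df)), function(i) {
      any(auto_calls$chrom == cand_df$chrom[i] &
            auto_calls$first_probe <= cand_df$first_probe[i] &
            auto_calls$last_probe >= cand_df$last_probe[i])
    }, logical(1))
    cand_df <- cand_df[!dup, , drop = FALSE]
  }
  out <- rbind(auto_calls, cand_df)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
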