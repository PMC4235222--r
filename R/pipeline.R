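## dominant gene symbol of a call's probe run
call_gene <- function(call, manifest) {
  g <- manifest$gene_symbol[call$first_probe:call$last_probe]
  g <- g[g != ""]
  if (length(g)) names(sort(table(g), decreasing = TRUE))[1] else ""
}

#' Run the full aCGH analysis pipeline on one hybridization
#'
#' Quality control first: a rejected derivative log ratio aborts the run
#' with no calls. Otherwise the profile is median-centered, segmented with
#' circular binary segmentation, thresholded into automatic calls, and
#' scanned for manual-review candidates; breakpoint bounds are attached to
#' every reported call. With `gene_mask` set, calls and candidates outside
#' the ordered gene are suppressed (data for other genes is masked and not
#' analyzed).
#'
#' @param manifest A `probe_manifest`.
#' @param profile The matching `array_profile`.
#' @param context A [review_context()].
#' @param cbs A [cbs_params()] record.
#' @param thresholds A [call_thresholds()] record.
#' @param gene_mask Optional gene symbol restricting the analysis.
#' @return A list of class `acgh_report`: `status` (`"ok"` or
#'   `"rejected"`), `dlr`, `segments`, `calls` (all segments with call
#'   columns), `reported` (auto calls plus review candidates), and
#'   `bounds` (one `breakpoint_bounds` per reported row).
#' @export
run_pipeline <- function(manifest, profile, context = review_context(),
                         cbs = cbs_params(), thresholds = call_thresholds(),
                         gene_mask = NULL) {
  dlr <- compute_dlr(profile, manifest)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), first_probe = integer(0),
                      last_probe = integer(0), n_probes = integer(0),
                      mean_log2 = numeric(0), call_class = character(0),
                      auto = logical(0), review_flags = character(0))
  if (dlr$status == "rejected") {
    return(structure(list(status = "rejected", dlr = dlr, segments = NULL,
                          calls = empty, reported = empty, bounds = list()),
                     class = "acgh_report"))
  }
  centered <- median_center(profile, manifest)
  segs <- cbs_segment(centered, manifest, cbs)
  rb <- segment_median_baseline(centered, manifest, segs)
  centered <- rb$profile
  segs <- rb$segments
  calls <- call_segments(segs, attr(profile, "sample_sex"), thresholds)
  reported <- review_candidates(centered, manifest, calls, context)
  if (!is.null(gene_mask) && nrow(reported)) {
    keep <- vapply(seq_len(nrow(reported)), function(i) {
      call_gene(reported[i, ], manifest) == gene_mask
    }, logical(1))
    reported <- reported[keep, , drop = FALSE]
  }
  bounds <- lapply(seq_len(nrow(reported)), function(i) {
    bound_breakpoints(reported[i, ], manifest)
  })
  structure(list(status = "ok", dlr = dlr, segments = segs, calls = calls,
                 reported = reported, bounds = bounds),
            class = "acgh_report")
}

## does call row overlap interval [s, e) on chrom?
call_overlaps <- function(calls, chrom, s, e) {
  nrow(calls) > 0 & calls$chrom == chrom & calls$start < e & calls$end > s
}

#' Evaluate the twelve-case replication suite end to end
#'
#' Runs every case through quality control, segmentation, calling and
#' manual review, resolves each reported call with simulated sequence
#' follow-up, and scores detection against the case's ground truth. The
#' summary reports the smallest deletion confirmed by junction analysis
#' across the suite and the resolution class of each false-positive
#' mechanism.
#'
#' @param suite Output of [build_case_suite()].
#' @param cbs A [cbs_params()] record (the seed is re-derived per case from
#'   the suite seed for reproducibility).
#' @param thresholds A [call_thresholds()] record.
#' @param junction [junction_params()].
#' @param resolve_flank Passed to [resolve_candidate()].
#' @return `list(outcomes=, summary=)`; `outcomes` has one record per case
#'   (`detected` is auto_call / review_candidate / missed per truth event),
#'   `summary` contains `smallest_confirmed_deletion`, per-case confirmed
#'   sizes and the false-positive resolutions.
#' @export
evaluate_suite <- function(suite, cbs = cbs_params(),
                           thresholds = call_thresholds(),
                           junction = junction_params(),
                           resolve_flank = 2500L) {
  stopifnot(inherits(suite, "acgh_case_suite"))
  base_seed <- attr(suite, "seed")
  outcomes <- lapply(suite, function(cs) {
    cbs_cs <- cbs
    cbs_cs$seed <- base_seed * 131L + cs$case_id * 17L + 3L
    rep_ <- run_pipeline(cs$manifest, cs$profile, cs$context, cbs_cs,
                         thresholds, gene_mask = cs$gene)
    reported <- rep_$reported
    res <- lapply(seq_len(nrow(reported)), function(i) {
      resolve_candidate(reported[i, ], cs$manifest, cs$genotype,
                        cs$fixtures, cs$search_fixture, junction,
                        resolve_flank)
    })
    confirmed <- unique(unlist(lapply(res, function(r) {
      if (r$resolution == "confirmed_deletion") r$junction$deletion_length
    })))
    resolutions <- unique(vapply(res, `[[`, character(1), "resolution"))
    # detection status per truth copy-number event
    dels <- Filter(function(e) e$kind == "deletion", cs$genotype$events)
    detected <- vapply(dels, function(e) {
      ov <- call_overlaps(reported, e$chrom, e$start, e$end)
      if (any(ov & reported$auto)) "auto_call"
      else if (any(ov)) "review_candidate"
      else "missed"
    }, character(1))
    flags <- unique(unlist(strsplit(reported$review_flags, ",")))
    list(case_id = cs$case_id, gene = cs$gene,
         truth_class = cs$truth$class,
         truth_sizes = cs$truth$sizes,
         dlr = rep_$dlr$dlr_value, dlr_status = rep_$dlr$status,
         n_auto = sum(reported$auto), n_reported = nrow(reported),
         detected = detected,
         confirmed_sizes = sort(confirmed),
         resolutions = resolutions,
         flags = flags[flags != ""])
  })
  all_confirmed <- unlist(lapply(outcomes, `[[`, "confirmed_sizes"))
  fp <- lapply(outcomes, function(o) {
    if (o$truth_class == "no_deletion") {
      setdiff(o$resolutions, c("unresolved", "confirmed_deletion"))
    }
  })
  names(fp) <- vapply(outcomes, `[[`, character(1), "gene")
  summary <- list(
    n_cases = length(outcomes),
    smallest_confirmed_deletion =
      if (length(all_confirmed)) min(all_confirmed) else NA_integer_,
    confirmed_sizes = sort(unique(all_confirmed)),
    fp_resolutions = Filter(Negate(is.null), fp))
  list(outcomes = outcomes, summary = summary)
}

#' Detection-power analysis over deletion size, probe density and noise
#'
#' For each grid cell, simulates heterozygous deletions of the given size on
#' a uniformly tiled single-target design at the given probe spacing and
#' noise level, runs segmentation, calling and review, and reports the
#' fraction of replicates yielding an automatic call and the fraction
#' yielding at least a review candidate over the deleted interval. A
#' deletion size of 0 measures the false-positive rate (any call at all).
#'
#' @param deletion_sizes Vector of deletion sizes, bp (0 allowed).
#' @param spacings Vector of probe spacings, bp.
#' @param noise_sds Vector of per-probe noise standard deviations.
#' @param n_reps Replicates per cell.
#' @param seed Master seed.
#' @param cbs,thresholds Pipeline parameter records.
#' @return Data frame (class `power_curve`): `deletion_size`, `spacing`,
#'   `probe_sd`, `n_probes_over` (probes fully inside the deletion),
#'   `frac_auto`, `frac_review`.
#' @export
power_analysis <- function(deletion_sizes, spacings = 30L,
                           noise_sds = 0.12, n_reps = 20L, seed = 1L,
                           cbs = cbs_params(), thresholds = call_thresholds()) {
  stopifnot(length(deletion_sizes) >= 1, n_reps >= 1)
  region_len <- max(6000L, 4L * max(deletion_sizes))
  tx <- 1000000L
  ctr <- tx + region_len %/% 2L
  grid <- expand.grid(deletion_size = deletion_sizes, spacing = spacings,
                      probe_sd = noise_sds, KEEP.OUT.ATTRS = FALSE)
  ctx <- review_context(gene_info = gene_info_row("SIM", "AR", 1L, FALSE))
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    sz <- grid$deletion_size[g]
    gm <- gene_model("SIM", "chr1", "+", tx, tx + region_len, "AR", 1L)
    man <- build_manifest(list(gm), design_params(
      exon_flank_bp = 0L, target_spacing_bp = grid$spacing[g]))
    ds <- ctr - sz %/% 2L; de <- ds + sz
    n_over <- sum(man$start >= ds & man$end <= de)
    events <- if (sz > 0) list(ev_deletion("chr1", ds, de, 1L)) else list()
    auto_hits <- review_hits <- 0L
    for (r in seq_len(n_reps)) {
      rseed <- seed * 7919L + g * 211L + r
      prof <- simulate_profile(man, genotype_spec("XX", events),
                               noise_model(grid$probe_sd[g], rseed))
      cbs_r <- cbs; cbs_r$seed <- rseed + 1L
      rep_ <- run_pipeline(man, prof, ctx, cbs_r, thresholds)
      if (sz > 0) {
        ov <- call_overlaps(rep_$reported, "chr1", ds, de)
        auto_hits <- auto_hits + any(ov & rep_$reported$auto)
        review_hits <- review_hits + (sum(ov) > 0)
      } else {
        auto_hits <- auto_hits + (sum(rep_$reported$auto) > 0)
        review_hits <- review_hits + (nrow(rep_$reported) > 0)
      }
    }
    data.frame(deletion_size = sz, spacing = grid$spacing[g],
               probe_sd = grid$probe_sd[g], n_probes_over = n_over,
               frac_auto = auto_hits / n_reps,
               frac_review = review_hits / n_reps)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("power_curve", "data.frame")
  out
}
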