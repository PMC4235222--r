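test_that("the derivative log ratio is zero on a constant profile and needs two probes", {
  man <- flat_manifest(10)
  rep_ <- compute_dlr(profile_from_values(man, rep(0.4, 10)), man)
  expect_equal(rep_$dlr_value, 0)
  expect_identical(rep_$status, "accepted")
  man1 <- flat_manifest(2)
  expect_error(compute_dlr(profile_from_values(man1[1, ], 0)), "2 probes")
})

test_that("the estimator recovers the probe noise level and honors the quality bands", {
  man <- flat_manifest(20000)
  for (sd_true in c(0.12, 0.25, 0.31)) {
    set.seed(round(sd_true * 1000))
    rep_ <- compute_dlr(profile_from_values(man, rnorm(20000, 0, sd_true)),
                        man)
    expect_lt(abs(rep_$dlr_value - sd_true), 0.05 * sd_true)
    expect_identical(rep_$status,
                     if (sd_true >= 0.30) "rejected"
                     else if (sd_true >= 0.20) "borderline" else "accepted")
  }
})

test_that("copy-number steps do not reject an otherwise clean array", {
  man <- flat_manifest(120, chrom = "chrX")
  set.seed(8)
  x <- rnorm(120, 0, 0.12)
  x[50:60] <- x[50:60] - 3.3  # hemizygous deletion
  rep_ <- compute_dlr(profile_from_values(man, x, sex = "XY"), man)
  expect_identical(rep_$status, "accepted")
  # the plain-sd variant conflates the step with noise
  rep_sd <- compute_dlr(profile_from_values(man, x, sex = "XY"), man,
                        robust = FALSE)
  expect_gt(rep_sd$dlr_value, rep_$dlr_value)
})

test_that("threshold calling requires four probes and -0.6 / +0.4 crossings", {
  seg <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr1"),
                    start = c(0, 1000, 2000, 3000),
                    end = c(900, 1900, 2900, 3900),
                    first_probe = c(1L, 11L, 21L, 31L),
                    last_probe = c(5L, 13L, 30L, 40L),
                    n_probes = c(5L, 3L, 10L, 10L),
                    mean_log2 = c(-1, -1, 0.5, -0.59))
  calls <- call_segments(seg, "XX")
  expect_identical(calls$call_class, c("deletion", "deletion",
                                       "duplication", "none"))
  expect_identical(calls$auto, c(TRUE, FALSE, TRUE, FALSE))
})

test_that("shallow X deletions in males carry the hemizygous-underdepth flag", {
  seg <- data.frame(chrom = "chrX", start = 0, end = 900,
                    first_probe = 1L, last_probe = 8L, n_probes = 8L,
                    mean_log2 = -1.2)
  calls_xy <- call_segments(seg, "XY")
  expect_match(calls_xy$review_flags, "hemizygous_underdepth")
  expect_identical(call_segments(seg, "XX")$review_flags, "")
  # a true hemizygous loss is deep enough not to be flagged
  seg$mean_log2 <- -3.2
  expect_identical(call_segments(seg, "XY")$review_flags, "")
})

test_that("a duplicated-footprint pair with recessive context is escalated for review", {
  gm <- gene_model("DBTLIKE", "chr1", "+", 1000000, 1000060, "AR", 1L)
  man <- build_manifest(list(gm), design_params(
    exon_flank_bp = 120, target_spacing_bp = 60,
    antisense_duplication = TRUE, backbone_margin_bp = 0))
  x <- rep(0, nrow(man))
  pair <- which(man$start == 1000000)
  x[pair] <- -0.29
  prof <- profile_from_values(man, x)
  segs <- cbs_segment(prof, man, cbs_params(seed = 1))
  calls <- call_segments(segs, "XX")
  ctx <- review_context(gene_info = data.frame(
    gene_symbol = "DBTLIKE", inheritance = "AR",
    known_mutation_count = 1L, clinical_suspicion = FALSE))
  rep_ <- review_candidates(prof, man, calls, ctx)
  expect_identical(nrow(rep_), 1L)
  flags <- strsplit(rep_$review_flags, ",")[[1]]
  expect_true(all(c("two_probe_evidence", "recessive_one_mutation")
                  %in% flags))
  expect_false(rep_$auto)
})

test_that("a sub-threshold 15-probe run with dominant suspicion is escalated without an auto call", {
  man <- flat_manifest(60)
  x <- rep(0, 60)
  x[20:34] <- -0.45  # below review threshold, above -0.6
  prof <- profile_from_values(man, x)
  segs <- cbs_segment(prof, man, cbs_params(seed = 2))
  calls <- call_segments(segs, "XX")
  expect_identical(sum(calls$auto), 0L)
  ctx <- review_context(gene_info = data.frame(
    gene_symbol = "SIM", inheritance = "AD",
    known_mutation_count = 0L, clinical_suspicion = TRUE))
  rep_ <- review_candidates(prof, man, calls, ctx)
  expect_identical(nrow(rep_), 1L)
  expect_identical(rep_$first_probe, 20L)
  expect_identical(rep_$last_probe, 34L)
  expect_match(rep_$review_flags, "dominant_suspicion")
})

test_that("a lone deviant probe with no context produces no candidate", {
  man <- flat_manifest(30)
  x <- rep(0, 30)
  x[15] <- -0.5
  prof <- profile_from_values(man, x)
  segs <- cbs_segment(prof, man, cbs_params(seed = 3))
  calls <- call_segments(segs, "XX")
  expect_identical(nrow(review_candidates(prof, man, calls,
                                          review_context())), 0L)
})

test_that("auto calls are always part of the reported set and candidates grow with a looser threshold", {
  man <- flat_manifest(80)
  set.seed(21)
  x <- rnorm(80, 0, 0.12)
  x[30:45] <- x[30:45] - 1
  prof <- profile_from_values(man, x)
  segs <- cbs_segment(prof, man, cbs_params(seed = 4))
  calls <- call_segments(segs, "XX")
  expect_gte(sum(calls$auto), 1L)
  ctx_strict <- review_context(gene_info = data.frame(
    gene_symbol = "SIM", inheritance = "AR", known_mutation_count = 1L,
    clinical_suspicion = FALSE), review_log2_threshold = -0.35)
  ctx_loose <- ctx_strict
  ctx_loose$review_log2_threshold <- -0.25
  rep_s <- review_candidates(prof, man, calls, ctx_strict)
  rep_l <- review_candidates(prof, man, calls, ctx_loose)
  # every auto call is reported under both contexts
  for (rep_ in list(rep_s, rep_l)) {
    auto <- calls[calls$auto, ]
    expect_true(all(auto$first_probe %in% rep_$first_probe))
  }
  # each strict-threshold candidate stays covered under the looser one
  for (i in seq_len(nrow(rep_s))) {
    expect_true(any(rep_l$first_probe <= rep_s$first_probe[i] &
                      rep_l$last_probe >= rep_s$last_probe[i]))
  }
})
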