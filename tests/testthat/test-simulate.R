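test_that("theoretical copy-ratio values match the calling model", {
  expect_identical(expected_log2(1, 2), -1)
  expect_identical(expected_log2(2, 2), 0)
  expect_equal(expected_log2(3, 2), log2(3 / 2))
  expect_equal(round(expected_log2(3, 2), 2), 0.58, tolerance = 0.011)
  # background floor instead of -Inf
  expect_equal(expected_log2(0, 1, eps = 0.1), log2(0.1))
  expect_error(expected_log2(-1, 2), "non-negative")
  expect_error(expected_log2(1, 0), "non-negative")
})

test_that("probe efficiency follows the (1-f)^alpha attenuation model", {
  att <- attenuation_params(alpha = 2)
  # fully deleted footprint
  expect_equal(probe_efficiency(100, 160, list(ev_deletion("c", 50, 300)),
                                att), 0)
  # untouched footprint
  expect_equal(probe_efficiency(100, 160, list(ev_deletion("c", 300, 400)),
                                att), 1)
  expect_equal(probe_efficiency(100, 160, list(), att), 1)
  # 12 of 60 bases deleted: (48/60)^2
  expect_equal(probe_efficiency(100, 160, list(ev_deletion("c", 120, 132)),
                                att), 0.64)
  # insertion splits the footprint; longest contiguous match survives
  expect_equal(probe_efficiency(100, 160, list(ev_insertion("c", 140, "AA")),
                                att), (40 / 60)^2)
  # a variant disrupts its window clipped to the footprint
  eff <- probe_efficiency(100, 160, list(ev_snv("c", 130, "A")), att)
  expect_equal(eff, (45 / 60)^2)
})

test_that("heterozygous deletions emit -1 and hemizygous losses fall to the floor", {
  man <- flat_manifest(30, spacing = 60)
  ds <- man$start[11]; de <- man$end[20]
  gt <- genotype_spec("XX", list(ev_deletion("chr1", ds, de, 1)))
  prof <- simulate_profile(man, gt, noise_model(0, 1))
  expect_equal(prof$log2_ratio[11:20], rep(-1, 10))
  expect_equal(prof$log2_ratio[-(11:20)], rep(0, 20))
  # hemizygous: XY sample, chrX locus
  manx <- flat_manifest(10, spacing = 60, chrom = "chrX")
  gtx <- genotype_spec("XY", list(ev_deletion("chrX", manx$start[5],
                                              manx$end[5], 1)))
  profx <- simulate_profile(manx, gtx, noise_model(0, 1))
  expect_lte(profx$log2_ratio[5], -3)
})

test_that("a 12-bp deletion under a duplicated-footprint pair leaves the documented two-probe signature", {
  gm <- gene_model("DBTLIKE", "chr1", "+", 1000000, 1000060, "AR")
  man <- build_manifest(list(gm), design_params(
    exon_flank_bp = 0, target_spacing_bp = 60, antisense_duplication = TRUE,
    backbone_margin_bp = 0))
  expect_identical(nrow(man), 2L)
  gt <- genotype_spec("XX", list(ev_deletion("chr1", 1000010, 1000022, 1)))
  prof <- simulate_profile(man, gt, noise_model(0, 1))
  expect_equal(prof$log2_ratio, rep(log2((1 + 0.64) / 2), 2))
  expect_equal(prof$log2_ratio[1], -0.2863041, tolerance = 1e-6)
})

test_that("a heterozygous duplication raises the ratio to log2(3/2)", {
  man <- flat_manifest(10, spacing = 60)
  gt <- genotype_spec("XX", list(ev_duplication("chr1", man$start[4],
                                                man$end[6], 1)))
  prof <- simulate_profile(man, gt, noise_model(0, 1))
  expect_equal(prof$log2_ratio[5], log2(3 / 2))
})

test_that("no events and zero noise conserve an exactly flat profile", {
  man <- flat_manifest(25)
  prof <- simulate_profile(man, genotype_spec("XX", list()),
                           noise_model(0, 1))
  expect_identical(prof$log2_ratio, rep(0, 25))
})

test_that("probe log2 is non-increasing in the deleted footprint fraction", {
  att <- attenuation_params()
  vals <- vapply(0:60, function(k) {
    if (k == 0) return(0)
    ev <- list(ev_deletion("chr1", 100, 100 + k))
    log2((probe_efficiency(100, 160, ev, att) + 1) / 2)
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("profiles are bit-reproducible for a fixed seed and sex-symmetric on autosomes", {
  man <- flat_manifest(40)
  gt_xx <- genotype_spec("XX", list(ev_deletion("chr1", man$start[5],
                                                man$end[9], 1)))
  gt_xy <- genotype_spec("XY", gt_xx$events)
  p1 <- simulate_profile(man, gt_xx, noise_model(0.12, 7))
  p2 <- simulate_profile(man, gt_xx, noise_model(0.12, 7))
  p3 <- simulate_profile(man, gt_xx, noise_model(0.12, 8))
  p4 <- simulate_profile(man, gt_xy, noise_model(0.12, 7))
  expect_identical(p1$log2_ratio, p2$log2_ratio)
  expect_false(identical(p1$log2_ratio, p3$log2_ratio))
  expect_identical(p1$log2_ratio, p4$log2_ratio)
})

test_that("events on a hemizygous chromosome must sit on the single allele", {
  expect_error(genotype_spec("XY", list(ev_deletion("chrX", 10, 20, 2))),
               "hemizygous")
  expect_silent(genotype_spec("XX", list(ev_deletion("chrX", 10, 20, 2))))
})

test_that("emitted local sequences apply deletions, inserts and variants", {
  fx <- seq_fixture("chr1", 1000, random_dna(6000, 3))
  region <- list(chrom = "chr1", start = 1500, end = 6500)
  # no events: both alleles equal the reference slice
  al0 <- emit_local_sequence(genotype_spec("XX", list()), fx, region)
  expect_identical(al0$allele1, al0$allele2)
  expect_identical(nchar(al0$allele1), 5000L)
  # a 971-bp deletion shortens one allele by exactly 971 bases
  gt1 <- genotype_spec("XX", list(ev_deletion("chr1", 2000, 2971, 1)))
  al1 <- emit_local_sequence(gt1, fx, region)
  expect_identical(nchar(al1$allele1), 5000L - 971L)
  expect_identical(al1$allele2, al0$allele2)
  # an 801-bp deletion with an 11-base insert nets -801 + 11
  gt2 <- genotype_spec("XX", list(
    ev_deletion("chr1", 2000, 2801, 1, insert = strrep("A", 11))))
  al2 <- emit_local_sequence(gt2, fx, region)
  expect_identical(nchar(al2$allele1), 5000L - 801L + 11L)
  # a variant substitutes in place
  gt3 <- genotype_spec("XX", list(ev_snv("chr1", 1500, "A", 1)))
  al3 <- emit_local_sequence(gt3, fx, region)
  expect_identical(nchar(al3$allele1), 5000L)
  expect_identical(substr(al3$allele1, 1, 1), "A")
  # uncovered region errors
  expect_error(emit_local_sequence(gt3, fx,
                                   list(chrom = "chr2", start = 1500,
                                        end = 2000)), "fixture")
})
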