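test_that("breakpoint bounds bracket the deviant probes with the flanking normals", {
  man <- flat_manifest(10, spacing = 100)
  # probes 3..5 deviant
  call <- data.frame(chrom = "chr1", first_probe = 3L, last_probe = 5L)
  b <- bound_breakpoints(call, man)
  expect_equal(b$inner, c(man$start[3], man$end[5]))
  expect_equal(b$outer, c(man$end[2], man$start[6]))
  # first probe on the chromosome: outer starts at the chromosome start
  call1 <- data.frame(chrom = "chr1", first_probe = 1L, last_probe = 2L)
  b1 <- bound_breakpoints(call1, man)
  expect_identical(b1$outer[1], 0L)
  # last probe: outer end unknown (chromosome end)
  call2 <- data.frame(chrom = "chr1", first_probe = 9L, last_probe = 10L)
  expect_true(is.na(bound_breakpoints(call2, man)$outer[2]))
})

test_that("true breakpoints of a simulated deletion lie between the inner and outer bounds", {
  man <- flat_manifest(60, spacing = 90)
  # breakpoints inside the inter-probe gaps (spacing 90, 60-mers)
  ds <- man$start[25] - 15L
  de <- man$end[33] + 10L
  gt <- genotype_spec("XX", list(ev_deletion("chr1", ds, de, 1)))
  prof <- simulate_profile(man, gt, noise_model(0, 1))
  segs <- cbs_segment(prof, man, cbs_params(seed = 6))
  calls <- call_segments(segs, "XX")
  del <- calls[calls$auto & calls$call_class == "deletion", ]
  expect_identical(nrow(del), 1L)
  b <- bound_breakpoints(del, man)
  expect_true(b$outer[1] <= ds && ds <= b$inner[1])
  expect_true(b$inner[2] <= de && de <= b$outer[2])
})

test_that("walking primers flank the lesion at widening offsets and predict junction amplicons", {
  fx <- seq_fixture("chr1", 0, random_dna(20000, 13))
  b <- structure(list(chrom = "chr1", inner = c(8000L, 11000L),
                      outer = c(7800L, 11200L)),
                 class = "breakpoint_bounds")
  plan <- design_walking_primers(b, fx, step_bp = 250, n_steps = 3)
  expect_gte(nrow(plan), 1L)
  expect_true(all(plan$fwd_end <= 8000))
  expect_true(all(plan$rev_start >= 11000))
  expect_true(all(diff(plan$fwd_start) < 0))  # steps widen outward
  expect_true(all(plan$fwd_tm >= 52 & plan$fwd_tm <= 62))
  # a 2,319-bp deletion with a 69-bp insert shortens the product by 2,250
  expect_equal(predict_amplicon(plan, 2319, 69),
               plan$amplicon_normal - 2250)
})

test_that("an unsequencable reference yields an empty plan with warnings", {
  fx <- seq_fixture("chr1", 0, strrep("N", 5000))
  b <- structure(list(chrom = "chr1", inner = c(2000L, 2500L),
                      outer = c(1900L, 2600L)),
                 class = "breakpoint_bounds")
  w <- testthat::capture_warnings(
    plan <- design_walking_primers(b, fx, step_bp = 200, n_steps = 2))
  expect_gte(length(w), 1L)
  expect_true(all(grepl("no admissible", w)))
  expect_identical(nrow(plan), 0L)
})

test_that("identical sequences yield an empty junction report", {
  s <- random_dna(500, 2)
  jr <- analyze_junction(s, s)
  expect_identical(jr$event_class, "none")
  expect_identical(jr$deletion_length, 0L)
  expect_identical(jr$microhomology_length, 0L)
  expect_identical(jr$inserted_seq, "")
})

test_that("junction analysis recovers constructed deletion and microhomology lengths exactly", {
  for (del in c(1L, 12L, 100L, 971L, 1325L, 2319L)) {
    for (m in 0:10) {
      fixt <- make_junction_fixture(del, m, seed = del + m)
      jr <- analyze_junction(fixt$ref, fixt$alt)
      expect_identical(jr$event_class, "deletion",
                       label = sprintf("del %d mh %d class", del, m))
      expect_identical(jr$deletion_length, del,
                       label = sprintf("del %d mh %d len", del, m))
      expect_identical(jr$microhomology_length, m,
                       label = sprintf("del %d mh %d mh", del, m))
    }
  }
})

test_that("microhomology calls are invariant under reverse complement", {
  for (m in c(0L, 2L, 4L, 7L)) {
    fixt <- make_junction_fixture(250L, m, seed = 77 + m)
    jr <- analyze_junction(fixt$ref, fixt$alt)
    jr_rc <- analyze_junction(revcomp(fixt$ref), revcomp(fixt$alt))
    expect_identical(jr_rc$microhomology_length, jr$microhomology_length)
    expect_identical(jr_rc$deletion_length, jr$deletion_length)
  }
})

test_that("an insert matching the reverse complement of a breakpoint flank is classed inverted_local", {
  fixt0 <- make_junction_fixture(801L, 0L, ins = "ACGTACGTACG", seed = 5)
  ins <- revcomp(substr(fixt0$ref, 80 + 801 + 1, 80 + 801 + 11))
  fixt <- make_junction_fixture(801L, 0L, ins = ins, seed = 5)
  jr <- analyze_junction(fixt$ref, fixt$alt)
  expect_identical(jr$event_class, "deletion_with_insert")
  expect_identical(jr$deletion_length, 801L)
  expect_identical(nchar(jr$inserted_seq), 11L)
  expect_identical(jr$insert_origin, "inverted_local")
})

test_that("an insert found verbatim in the search set is classed distal_templated", {
  donor <- random_dna(300, 31)
  ins <- substr(donor, 100, 168)  # 69 bases
  fixt <- make_junction_fixture(2319L, 0L, ins = ins, seed = 8)
  jr <- analyze_junction(fixt$ref, fixt$alt,
                         search_fixture = seq_fixture("chr5", 0, donor))
  expect_identical(jr$deletion_length, 2319L)
  expect_identical(nchar(jr$inserted_seq), 69L)
  expect_identical(jr$insert_origin, "distal_templated")
  # without the donor sequence the origin stays unknown
  jr2 <- analyze_junction(fixt$ref, fixt$alt)
  expect_identical(jr2$insert_origin, "unknown")
})

test_that("a flanking direct repeat marks a mobile-element insertion with its TSD", {
  set.seed(19)
  ref <- random_dna(900, 19)
  p <- 450L
  tsd <- substr(ref, p - 15L, p)
  u <- random_dna(333, 20)
  if (substr(u, 1, 1) == substr(ref, p + 1, p + 1)) {
    substr(u, 1, 1) <- setdiff(c("A", "C", "G", "T"),
                               substr(ref, p + 1, p + 1))[1]
  }
  if (substr(u, 333, 333) == substr(ref, p - 16L, p - 16L)) {
    substr(u, 333, 333) <- setdiff(c("A", "C", "G", "T"),
                                   substr(ref, p - 16L, p - 16L))[1]
  }
  alt <- paste0(substr(ref, 1, p), u, tsd, substr(ref, p + 1, 900))
  jr <- analyze_junction(ref, alt)
  expect_identical(jr$event_class, "insertion")
  expect_identical(jr$deletion_length, 0L)
  expect_identical(nchar(jr$inserted_seq), 349L)
  expect_identical(jr$insert_origin, "mobile_element_with_TSD")
  expect_identical(jr$tsd_length, 16L)
})

test_that("repeat annotation reports distances to the nearest breakpoint with a closed window", {
  track <- data.frame(chrom = "chr12",
                      start = c(5000, 2000, 9000),
                      end = c(5120, 2100, 9100),
                      name = c("MIRb", "AluSx", "L1ME"))
  # MIRb inside the deletion, 32 bases from the right breakpoint
  hits <- annotate_repeats("chr12", 4000, 5152, track, window = 500)
  expect_identical(hits$name, "MIRb")
  expect_identical(hits$distance, 32L)
  # empty track
  expect_identical(nrow(annotate_repeats("chr12", 0, 100,
                                         track[0, ])), 0L)
  # repeat exactly at the window edge is included, one base beyond is not
  edge <- annotate_repeats("chr12", 2600, 2700, track, window = 500)
  expect_identical(edge$name, "AluSx")
  expect_identical(edge$distance, -500L)
  expect_identical(nrow(annotate_repeats("chr12", 2601, 2700, track,
                                         window = 500)), 0L)
})

test_that("resolve_candidate confirms a simulated deletion from sequence follow-up", {
  man <- flat_manifest(40, spacing = 80)
  fx <- seq_fixture("chr1", man$start[1] - 3000L, random_dna(10000, 55))
  ds <- man$start[15]; de <- man$end[20]
  gt <- genotype_spec("XX", list(ev_deletion("chr1", ds, de, 1)))
  prof <- simulate_profile(man, gt, noise_model(0, 1))
  segs <- cbs_segment(prof, man, cbs_params(seed = 7))
  calls <- call_segments(segs, "XX")
  del <- calls[calls$auto, ]
  res <- resolve_candidate(del[1, ], man, gt, fx)
  expect_identical(res$resolution, "confirmed_deletion")
  expect_identical(res$junction$deletion_length, de - ds)
  # substitutions only: sequence-variant false positive
  alt_at <- function(pos) {
    setdiff(c("A", "C", "G", "T"),
            substr(fx$seq, pos - fx$start + 1, pos - fx$start + 1))[1]
  }
  p1 <- man$start[15] + 30L; p2 <- man$start[15] + 41L
  gt2 <- genotype_spec("XX", list(ev_snv("chr1", p1, alt_at(p1), 1),
                                  ev_snv("chr1", p2, alt_at(p2), 2)))
  res2 <- resolve_candidate(del[1, ], man, gt2, fx)
  expect_identical(res2$resolution, "sequence_variant_fp")
})
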