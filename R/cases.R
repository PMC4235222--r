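## Invented but size-realistic exon geometries for the ten fixture genes.
## Coordinates are synthetic; inheritance modes follow the diseases the
## genes cause (MSUD, HLRCC, Lesch-Nyhan, Peutz-Jeghers, PKU, EDMD, WWS,
## X-linked intellectual disability, galactosemia).
gene_geometry <- function() {
  list(
    BCKDHB = list(chrom = "chr6", tx = 1000000L, exon_len = 150L,
                  introns = c(rep(3000L, 7), 29500L, 29500L, 3000L),
                  inheritance = "AR", spacing = 30L, flank = 200L,
                  antisense = FALSE, margin = 40000L),
    FH = list(chrom = "chr1", tx = 1000000L, exon_len = 150L,
              introns = rep(2300L, 9), inheritance = "AD",
              spacing = 30L, flank = 200L, antisense = FALSE,
              margin = 20000L),
    DBT = list(chrom = "chr1", tx = 5000000L, exon_len = 140L,
               introns = rep(4000L, 11), inheritance = "AR",
               spacing = 15L, flank = 200L, antisense = TRUE),
    HPRT1 = list(chrom = "chrX", tx = 2000000L, exon_len = 150L,
                 introns = rep(2200L, 8), inheritance = "XL",
                 spacing = 30L, flank = 200L, antisense = FALSE),
    STK11 = list(chrom = "chr19", tx = 1000000L, exon_len = 160L,
                 introns = rep(1800L, 9), inheritance = "AD",
                 spacing = 30L, flank = 200L, antisense = FALSE),
    PAH = list(chrom = "chr12", tx = 1000000L, exon_len = 140L,
               introns = rep(1500L, 12), inheritance = "AR",
               spacing = 20L, flank = 200L, antisense = FALSE),
    EMD = list(chrom = "chrX", tx = 3000000L, exon_len = 120L,
               introns = rep(900L, 5), inheritance = "XL",
               spacing = 120L, flank = 100L, antisense = TRUE),
    POMT1 = list(chrom = "chr9", tx = 1000000L, exon_len = 150L,
                 introns = rep(1200L, 4), inheritance = "AR",
                 spacing = 15L, flank = 150L, antisense = FALSE),
    SLC9A6 = list(chrom = "chrX", tx = 5000000L, exon_len = 150L,
                  introns = rep(1300L, 7), inheritance = "XL",
                  spacing = 15L, flank = 200L, antisense = TRUE),
    GALT = list(chrom = "chr9", tx = 4000000L, exon_len = 140L,
                introns = rep(1000L, 5), inheritance = "AR",
                spacing = 30L, flank = 150L, antisense = FALSE))
}

geometry_exons <- function(g) {
  n <- length(g$introns) + 1L
  starts <- g$tx + cumsum(c(0L, g$introns + g$exon_len))[seq_len(n)]
  list(starts = starts, ends = starts + g$exon_len)
}

#' Fixture gene models
#'
#' Ten single-gene models with invented but size-realistic exon geometries,
#' matching the genes of the deletion case suite.
#'
#' @param known_mutation_count,clinical_suspicion Optional per-gene context
#'   overrides (named vectors); defaults are 0 / FALSE.
#' @return Named list of [gene_model()] objects.
#' @export
example_gene_models <- function(known_mutation_count = NULL,
                                clinical_suspicion = NULL) {
  geo <- gene_geometry()
  out <- lapply(names(geo), function(nm) {
    g <- geo[[nm]]
    ex <- geometry_exons(g)
    gene_model(nm, g$chrom, "+", ex$starts, ex$ends, g$inheritance,
               known_mutation_count =
                 if (nm %in% names(known_mutation_count))
                   known_mutation_count[[nm]] else 0L,
               clinical_suspicion =
                 if (nm %in% names(clinical_suspicion))
                   clinical_suspicion[[nm]] else FALSE)
  })
  stats::setNames(out, names(geo))
}

## force the base at 0-based local position i to differ from `other`
## (a base character); deterministic
force_base_diff <- function(seq, i, other) {
  cur <- substr(seq, i + 1, i + 1)
  if (cur != other) return(seq)
  repl <- setdiff(c("A", "C", "G", "T"), c(cur, other))[1]
  substr(seq, i + 1, i + 1) <- repl
  seq
}

## plant an exact m-base microhomology at a deletion's breakpoints
## (local 0-based [s, e)) and make it maximal on both sides
plant_microhomology <- function(seq, s, e, m) {
  if (m > 0) substr(seq, s + 1, s + m) <- substr(seq, e + 1, e + m)
  seq <- force_base_diff(seq, s + m, substr(seq, e + m + 1, e + m + 1))
  if (s >= 1) seq <- force_base_diff(seq, s - 1, substr(seq, e, e))
  seq
}

## make sure an insert cannot extend the shared flanks of a deletion
guard_insert_flanks <- function(seq, s, e, ins) {
  seq <- force_base_diff(seq, s, substr(ins, 1, 1))
  force_base_diff(seq, e - 1, substr(ins, nchar(ins), nchar(ins)))
}

snv_alt <- function(seq, i) {
  setdiff(c("A", "C", "G", "T"), substr(seq, i + 1, i + 1))[1]
}

case_manifest <- function(gene_name, ctx_count = 0L, ctx_susp = FALSE) {
  g <- gene_geometry()[[gene_name]]
  ex <- geometry_exons(g)
  gm <- gene_model(gene_name, g$chrom, "+", ex$starts, ex$ends,
                   g$inheritance, ctx_count, ctx_susp)
  man <- build_manifest(list(gm), design_params(
    exon_flank_bp = g$flank, target_spacing_bp = g$spacing,
    antisense_duplication = g$antisense,
    backbone_margin_bp = if (is.null(g$margin)) 10000L else g$margin))
  list(geometry = g, exons = ex, gene = gm, manifest = man)
}

case_fixture <- function(g, ex, seed) {
  pad <- (if (is.null(g$margin)) 10000L else g$margin) + 5000L
  lo <- g$tx - pad
  hi <- max(ex$ends) + pad
  seq_fixture(g$chrom, lo, random_dna(hi - lo, seed))
}

gene_info_row <- function(gene, inheritance, count, susp) {
  data.frame(gene_symbol = gene, inheritance = inheritance,
             known_mutation_count = count, clinical_suspicion = susp,
             stringsAsFactors = FALSE)
}

#' Build the twelve-case intragenic-deletion replication suite
#'
#' Constructs synthetic replicas of twelve diagnostic cases: heterozygous
#' deletions of about 58 kb, 19 kb and 3.7 kb; a hemizygous 2,319-bp
#' deletion carrying a 69-bp distally templated insert; 1,325-bp and 971-bp
#' deletions with 4- and 3-base breakpoint microhomology; an 801-bp partial
#' exon deletion with an 11-base locally inverted insert; a hemizygous
#' 267-bp deletion evidenced by a sense/antisense probe pair; a
#' compound-heterozygous pair (about 3.6 kb plus a 12-bp intronic deletion
#' under a duplicated-footprint probe pair); and three false-positive
#' lesions (a 349-base mobile-element-like insertion with a 16-base
#' target-site duplication, a hemizygous single-nucleotide variant, and
#' compound-heterozygous missense variants). Each case carries its per-gene
#' manifest, genotype, simulated profile, sequence fixtures, review context
#' and truth record.
#'
#' @param seed Master integer seed; all per-case noise and fixture seeds are
#'   derived from it.
#' @param noise_sd Per-probe log2 noise standard deviation.
#' @param att [attenuation_params()].
#' @return List of 12 case objects (class `acgh_case_suite`).
#' @export
build_case_suite <- function(seed = 1L, noise_sd = 0.12,
                             att = attenuation_params()) {
  seed <- as.integer(seed)
  cseed <- function(case, k = 0L) seed * 131L + case * 17L + k
  suite <- vector("list", 12L)

  add_case <- function(case_id, gene, sex, events, fixtures, truth,
                       count = 0L, susp = FALSE, primers = NULL,
                       dropout = character(0), search_fixture = NULL,
                       repeat_track = NULL, cm = NULL) {
    gt <- genotype_spec(sex, events)
    prof <- simulate_profile(cm$manifest, gt,
                             noise_model(noise_sd, cseed(case_id, 1L)),
                             att, dropout_normal = dropout)
    ctx <- review_context(
      gene_info = gene_info_row(gene, cm$geometry$inheritance, count, susp),
      primer_intervals = primers)
    list(case_id = case_id, gene = gene, manifest = cm$manifest,
         genotype = gt, profile = prof, fixtures = fixtures,
         context = ctx, search_fixture = search_fixture,
         repeat_track = repeat_track, truth = truth)
  }

  ## case 1: ~58-kb heterozygous deletion around exon 9 (BCKDHB, AR,
  ## one sequencing mutation already known)
  cm <- case_manifest("BCKDHB")
  fx <- case_fixture(cm$geometry, cm$exons, cseed(1L))
  ds <- cm$exons$starts[9] + 75L - 29000L
  de <- ds + 58000L
  fx$seq <- plant_microhomology(fx$seq, ds - fx$start, de - fx$start, 2L)
  suite[[1]] <- add_case(1L, "BCKDHB", "XX",
    list(ev_deletion("chr6", ds, de, 1L)), fx,
    list(class = "deletion", sizes = 58000L), count = 1L, cm = cm)

  ## case 2: ~19-kb heterozygous deletion of exons 2-9 (FH, AD, strong
  ## clinical suspicion)
  cm <- case_manifest("FH")
  fx <- case_fixture(cm$geometry, cm$exons, cseed(2L))
  ds <- cm$geometry$tx + 1500L
  de <- ds + 19000L
  fx$seq <- plant_microhomology(fx$seq, ds - fx$start, de - fx$start, 3L)
  suite[[2]] <- add_case(2L, "FH", "XY",
    list(ev_deletion("chr1", ds, de, 1L)), fx,
    list(class = "deletion", sizes = 19000L), susp = TRUE, cm = cm)

  ## case 3: ~3.7-kb heterozygous deletion around exon 5 (DBT, AR, one
  ## known nonsense mutation)
  cm3 <- case_manifest("DBT")
  fx <- case_fixture(cm3$geometry, cm3$exons, cseed(3L))
  ds <- cm3$exons$starts[5] + 70L - 1850L
  de <- ds + 3700L
  fx$seq <- plant_microhomology(fx$seq, ds - fx$start, de - fx$start, 2L)
  suite[[3]] <- add_case(3L, "DBT", "XX",
    list(ev_deletion("chr1", ds, de, 1L)), fx,
    list(class = "deletion", sizes = 3700L), count = 1L, cm = cm3)

  ## case 4: hemizygous 2,319-bp deletion of exon 5 with a 69-bp insert
  ## templated from another chromosome (HPRT1, XL male)
  cm <- case_manifest("HPRT1")
  fx <- case_fixture(cm$geometry, cm$exons, cseed(4L))
  chr5 <- seq_fixture("chr5", 40844150L, random_dna(300L, cseed(4L, 2L)))
  ins69 <- substr(chr5$seq, 40844201L - chr5$start + 1L,
                  40844269L - chr5$start + 1L)
  ds <- cm$exons$starts[5] - 1000L
  de <- ds + 2319L
  fx$seq <- guard_insert_flanks(fx$seq, ds - fx$start, de - fx$start, ins69)
  suite[[4]] <- add_case(4L, "HPRT1", "XY",
    list(ev_deletion("chrX", ds, de, 1L, insert = ins69)),
    list(fx, chr5),
    list(class = "deletion", sizes = 2319L, insert_len = 69L),
    search_fixture = list(chr5), cm = cm)

  ## cases 5/6: STK11 deletions whose calls stay above the -0.6 threshold
  ## because some probes inside the deletion hybridize normally; escalated
  ## by dominant-disease clinical suspicion
  cm56 <- case_manifest("STK11")
  for (cc in list(list(id = 5L, exon = 8L, off = -600L, size = 1325L,
                       mh = 4L),
                  list(id = 6L, exon = 3L, off = -405L, size = 971L,
                       mh = 3L))) {
    fx <- case_fixture(cm56$geometry, cm56$exons, cseed(cc$id))
    ds <- cm56$exons$starts[cc$exon] + cc$off
    de <- ds + cc$size
    fx$seq <- plant_microhomology(fx$seq, ds - fx$start, de - fx$start,
                                  cc$mh)
    man <- cm56$manifest
    inside <- man$probe_id[man$category == "target" &
                             man$start >= ds & man$end <= de]
    dropout <- inside[seq_along(inside) %% 2L == 0L]
    suite[[cc$id]] <- add_case(cc$id, "STK11", "XX",
      list(ev_deletion("chr19", ds, de, 1L)), fx,
      list(class = "deletion", sizes = cc$size, microhomology = cc$mh),
      susp = TRUE, dropout = dropout, cm = cm56)
  }

  ## case 7: 801-bp deletion removing the 3' part of exon 6 plus flanking
  ## intron, with an 11-base insert matching the reverse complement of the
  ## intronic breakpoint flank (PAH, AR, one known missense); a MIRb SINE
  ## sits inside the deletion 32 bases from the intronic breakpoint
  cm <- case_manifest("PAH")
  fx <- case_fixture(cm$geometry, cm$exons, cseed(7L))
  ds <- cm$exons$starts[6] + 70L
  de <- ds + 801L
  ins11 <- revcomp(substr(fx$seq, de - fx$start + 1L, de - fx$start + 11L))
  fx$seq <- guard_insert_flanks(fx$seq, ds - fx$start, de - fx$start, ins11)
  mir <- data.frame(chrom = "chr12", start = de - 152L, end = de - 32L,
                    name = "MIRb", stringsAsFactors = FALSE)
  suite[[7]] <- add_case(7L, "PAH", "XX",
    list(ev_deletion("chr12", ds, de, 1L, insert = ins11)), fx,
    list(class = "deletion", sizes = 801L, insert_len = 11L),
    count = 1L, repeat_track = mir, cm = cm)

  ## case 8: hemizygous 267-bp deletion of exon 2 (EMD, XL male); two
  ## footprints inside the deletion hybridize normally, leaving
  ## sense/antisense pair evidence
  cm <- case_manifest("EMD")
  fx <- case_fixture(cm$geometry, cm$exons, cseed(8L))
  ds <- cm$exons$starts[2] - 80L
  de <- ds + 267L
  fx$seq <- plant_microhomology(fx$seq, ds - fx$start, de - fx$start, 2L)
  man <- cm$manifest
  dropout <- man$probe_id[man$category == "target" &
                            man$start %in% (cm$exons$starts[2] + c(20L, 140L))]
  suite[[8]] <- add_case(8L, "EMD", "XY",
    list(ev_deletion("chrX", ds, de, 1L)), fx,
    list(class = "deletion", sizes = 267L, microhomology = 2L),
    dropout = dropout, cm = cm)

  ## case 9: compound-heterozygous DBT pair: ~3.6-kb deletion clipping the
  ## 5' end of exon 11, plus a 12-bp intronic deletion three bases from the
  ## exon 5 splice acceptor, under a duplicated-footprint +/- probe pair;
  ## the sequencing primer overlapped the small deletion (allelic dropout)
  fx <- case_fixture(cm3$geometry, cm3$exons, cseed(9L))
  d1e <- cm3$exons$starts[11] + 70L
  d1s <- d1e - 3600L
  d2s <- cm3$exons$starts[5] - 15L
  d2e <- d2s + 12L
  fx$seq <- plant_microhomology(fx$seq, d1s - fx$start, d1e - fx$start, 2L)
  fx$seq <- plant_microhomology(fx$seq, d2s - fx$start, d2e - fx$start, 1L)
  primers <- data.frame(chrom = "chr1", start = d2s - 15L, end = d2s + 20L,
                        stringsAsFactors = FALSE)
  suite[[9]] <- add_case(9L, "DBT", "XX",
    list(ev_deletion("chr1", d1s, d1e, 1L),
         ev_deletion("chr1", d2s, d2e, 2L)), fx,
    list(class = "compound_deletion", sizes = c(3600L, 12L)),
    count = 1L, primers = primers, cm = cm3)

  ## case 10: false positive -- a 349-base mobile-element-like insertion
  ## in exon 3 with a 16-base target-site duplication (POMT1, AR, one
  ## known frameshift mutation)
  cm <- case_manifest("POMT1")
  fx <- case_fixture(cm$geometry, cm$exons, cseed(10L))
  p <- cm$exons$starts[3] + 40L
  pl <- p - fx$start
  tsd <- substr(fx$seq, pl - 16L + 1L, pl)
  u <- random_dna(333L, cseed(10L, 2L))
  # the insert's unique part must not extend the matched flanks
  if (substr(u, 1L, 1L) == substr(fx$seq, pl + 1L, pl + 1L)) {
    substr(u, 1L, 1L) <- setdiff(c("A", "C", "G", "T"),
                                 substr(fx$seq, pl + 1L, pl + 1L))[1]
  }
  if (substr(u, 333L, 333L) == substr(fx$seq, pl - 16L, pl - 16L)) {
    substr(u, 333L, 333L) <- setdiff(c("A", "C", "G", "T"),
                                     substr(fx$seq, pl - 16L, pl - 16L))[1]
  }
  suite[[10]] <- add_case(10L, "POMT1", "XX",
    list(ev_insertion("chr9", p, paste0(u, tsd), 1L)), fx,
    list(class = "no_deletion", mechanism = "mobile_element_insertion",
         insert_len = 349L, tsd = 16L),
    count = 1L, cm = cm)

  ## case 11: false positive -- hemizygous intronic SNV under the probes
  ## (SLC9A6, XL male)
  cm <- case_manifest("SLC9A6")
  fx <- case_fixture(cm$geometry, cm$exons, cseed(11L))
  p <- cm$exons$ends[6] + 31L
  suite[[11]] <- add_case(11L, "SLC9A6", "XY",
    list(ev_snv("chrX", p, snv_alt(fx$seq, p - fx$start), 1L)), fx,
    list(class = "no_deletion", mechanism = "hemizygous_snv"), cm = cm)

  ## case 12: false positive -- compound-heterozygous missense changes in
  ## trans, 11 bp apart (GALT, AR, one known mutation)
  cm <- case_manifest("GALT")
  fx <- case_fixture(cm$geometry, cm$exons, cseed(12L))
  p1 <- cm$exons$starts[5] + 50L
  p2 <- p1 + 11L
  suite[[12]] <- add_case(12L, "GALT", "XX",
    list(ev_snv("chr9", p1, snv_alt(fx$seq, p1 - fx$start), 1L),
         ev_snv("chr9", p2, snv_alt(fx$seq, p2 - fx$start), 2L)), fx,
    list(class = "no_deletion", mechanism = "compound_het_snv"),
    count = 1L, cm = cm)

  structure(suite, class = "acgh_case_suite", seed = seed)
}
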