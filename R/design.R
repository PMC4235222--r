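#' Gene model
#'
#' A single-gene exon structure with the clinical context used by the
#' manual-review criteria. Coordinates are 0-based half-open.
#'
#' @param gene_symbol Gene symbol.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends Parallel integer vectors of exon intervals,
#'   sorted and non-overlapping, all on `chrom`.
#' @param inheritance Inheritance mode, one of `"AD"`, `"AR"`, `"XL"`.
#' @param known_mutation_count Number of pathogenic mutations already
#'   identified in this gene for the patient (context for review criteria).
#' @param clinical_suspicion Whether there is strong clinical suspicion of
#'   disease involving this gene.
#' @return A list of class `gene_model`.
#' @export
gene_model <- function(gene_symbol, chrom, strand = "+",
                       exon_starts, exon_ends,
                       inheritance = c("AR", "AD", "XL"),
                       known_mutation_count = 0L,
                       clinical_suspicion = FALSE) {
  inheritance <- match.arg(inheritance)
  exon_starts <- as.integer(exon_starts)
  exon_ends <- as.integer(exon_ends)
  stopifnot(length(exon_starts) >= 1,
            length(exon_starts) == length(exon_ends),
            all(exon_ends > exon_starts),
            strand %in% c("+", "-"),
            known_mutation_count >= 0)
  if (length(exon_starts) > 1) {
    stopifnot(!is.unsorted(exon_starts, strictly = TRUE),
              all(exon_starts[-1] >= exon_ends[-length(exon_ends)]))
  }
  structure(list(gene_symbol = gene_symbol, chrom = chrom, strand = strand,
                 exon_starts = exon_starts, exon_ends = exon_ends,
                 inheritance = inheritance,
                 known_mutation_count = as.integer(known_mutation_count),
                 clinical_suspicion = isTRUE(clinical_suspicion)),
            class = "gene_model")
}

## merge sorted possibly-overlapping intervals into disjoint ones
merge_intervals <- function(starts, ends) {
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out_s <- integer(0); out_e <- integer(0)
  for (k in seq_along(starts)[-1]) {
    if (starts[k] <= me) {
      me <- max(me, ends[k])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[k]; me <- ends[k]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

## left-anchored tiling of [rs, re); regions shorter than L get one probe
## centered on the region (clamped at 0)
tile_region <- function(rs, re, L, spacing) {
  if (re - rs <= L) {
    return(max(0L, rs + as.integer(floor((re - rs - L) / 2))))
  }
  starts <- seq.int(rs, re - L, by = spacing)
  if (starts[length(starts)] < re - L) starts <- c(starts, re - L)
  starts
}

#' Build an exon-centric probe manifest
#'
#' Tiles every exon of every gene, plus `exon_flank_bp` of flanking intron,
#' with fixed-length probes at `target_spacing_bp`, optionally probing each
#' footprint on both strands, and places sparse backbone probes across the
#' rest of each gene's locus. Placement is deterministic (left-anchored),
#' so the manifest is a pure function of its inputs.
#'
#' @param genes A list of [gene_model()] objects (at least one).
#' @param params A [design_params()] record.
#' @return A `probe_manifest`: a data frame with columns `chrom`, `start`,
#'   `end`, `probe_id`, `category` (target/backbone/control), `strand`,
#'   `gene_symbol`, sorted by (chrom, start), with the design parameters
#'   attached as the `design_params` attribute.
#' @export
build_manifest <- function(genes, params = design_params()) {
  if (inherits(genes, "gene_model")) genes <- list(genes)
  if (length(genes) == 0) stop("at least one gene model is required")
  stopifnot(all(vapply(genes, inherits, logical(1), "gene_model")),
            inherits(params, "design_params"))
  L <- params$probe_length
  pieces <- lapply(genes, function(g) {
    reg <- merge_intervals(pmax(0L, g$exon_starts - params$exon_flank_bp),
                           g$exon_ends + params$exon_flank_bp)
    starts <- unlist(lapply(seq_len(nrow(reg)), function(i) {
      tile_region(reg$start[i], reg$end[i], L, params$target_spacing_bp)
    }))
    starts <- sort(unique(starts))
    tgt <- data.frame(chrom = g$chrom, start = starts, end = starts + L,
                      probe_id = sprintf("%s_t%05d", g$gene_symbol,
                                         seq_along(starts)),
                      category = "target", strand = "+",
                      gene_symbol = g$gene_symbol,
                      stringsAsFactors = FALSE)
    if (params$antisense_duplication) {
      anti <- tgt
      anti$strand <- "-"
      anti$probe_id <- paste0(tgt$probe_id, "_as")
      tgt <- rbind(tgt, anti)
    }
    span0 <- max(0L, min(g$exon_starts) - params$backbone_margin_bp)
    span1 <- max(g$exon_ends) + params$backbone_margin_bp
    bb_starts <- seq.int(span0, span1, by = params$backbone_spacing_bp)
    # backbone probes live outside the targeted regions
    in_target <- vapply(bb_starts, function(s) {
      any(s < reg$end & (s + L) > reg$start)
    }, logical(1))
    bb_starts <- bb_starts[!in_target]
    bb <- if (length(bb_starts)) {
      data.frame(chrom = g$chrom, start = bb_starts, end = bb_starts + L,
                 probe_id = sprintf("%s_bb%04d", g$gene_symbol,
                                    seq_along(bb_starts)),
                 category = "backbone", strand = "+",
                 gene_symbol = "",
                 stringsAsFactors = FALSE)
    } else NULL
    rbind(tgt, bb)
  })
  man <- do.call(rbind, pieces)
  man <- man[order(man$chrom, man$start, man$end, man$strand), ]
  rownames(man) <- NULL
  if (anyDuplicated(man$probe_id)) stop("duplicate probe ids in manifest")
  structure(man, design_params = params,
            class = c("probe_manifest", "data.frame"))
}

#' Append spike-in control probes to a manifest
#'
#' Control probes model per-array spike-in features; they carry no genomic
#' signal (expected log2 ratio 0) and are excluded from segmentation,
#' calling and review. They are placed on a reserved `chrCTRL` contig.
#'
#' @param manifest A `probe_manifest`.
#' @param n Number of control probes.
#' @return The manifest with `n` control probes appended.
#' @export
add_control_probes <- function(manifest, n = 5L) {
  stopifnot(inherits(manifest, "probe_manifest"), n >= 1)
  L <- attr(manifest, "design_params")$probe_length
  ctl <- data.frame(chrom = "chrCTRL",
                    start = seq_len(n) * 1000L, end = seq_len(n) * 1000L + L,
                    probe_id = sprintf("CTRL_%03d", seq_len(n)),
                    category = "control", strand = "+", gene_symbol = "",
                    stringsAsFactors = FALSE)
  out <- rbind(as.data.frame(manifest), ctl)
  out <- out[order(out$chrom, out$start, out$end, out$strand), ]
  rownames(out) <- NULL
  structure(out, design_params = attr(manifest, "design_params"),
            class = c("probe_manifest", "data.frame"))
}
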