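#' Write / read a probe manifest as BED-like TSV
#'
#' Six columns without header: chrom, start, end, probe_id, category, strand
#' (0-based half-open, BED convention). The gene symbol is recovered on read
#' from the probe id prefix (`<GENE>_t...` / `<GENE>_bb...`).
#'
#' @param manifest A `probe_manifest`.
#' @param path Output file path.
#' @return `write_manifest_bed` returns `path` invisibly;
#'   `read_manifest_bed` returns a `probe_manifest`.
#' @export
write_manifest_bed <- function(manifest, path) {
  stopifnot(inherits(manifest, "probe_manifest"))
  write.table(manifest[, c("chrom", "start", "end", "probe_id",
                           "category", "strand")],
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest_bed
#' @param params Design parameters to attach to the manifest read back.
#' @export
read_manifest_bed <- function(path, params = design_params()) {
  d <- read.delim(path, header = FALSE,
                  col.names = c("chrom", "start", "end", "probe_id",
                                "category", "strand"),
                  stringsAsFactors = FALSE)
  d$gene_symbol <- ifelse(d$category == "target",
                          sub("_(t|bb)[0-9]+.*$", "", d$probe_id), "")
  d <- d[order(d$chrom, d$start, d$end, d$strand), ]
  rownames(d) <- NULL
  structure(d, design_params = params,
            class = c("probe_manifest", "data.frame"))
}

#' Write / read gene models as TSV
#'
#' One row per gene: gene, chrom, strand, comma-separated exon starts and
#' ends, inheritance, known_mutation_count, clinical_suspicion.
#'
#' @param genes List of [gene_model()] objects.
#' @param path File path.
#' @return `write_gene_models` returns `path` invisibly; `read_gene_models`
#'   returns a list of `gene_model`s.
#' @export
write_gene_models <- function(genes, path) {
  rows <- lapply(genes, function(g) {
    data.frame(gene = g$gene_symbol, chrom = g$chrom, strand = g$strand,
               exon_starts = paste(g$exon_starts, collapse = ","),
               exon_ends = paste(g$exon_ends, collapse = ","),
               inheritance = g$inheritance,
               known_mutation_count = g$known_mutation_count,
               clinical_suspicion = g$clinical_suspicion,
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_models
#' @export
read_gene_models <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(d)), function(i) {
    gene_model(d$gene[i], d$chrom[i], d$strand[i],
               as.integer(strsplit(d$exon_starts[i], ",")[[1]]),
               as.integer(strsplit(d$exon_ends[i], ",")[[1]]),
               d$inheritance[i], d$known_mutation_count[i],
               d$clinical_suspicion[i])
  })
}

#' Write / read an array profile as TSV
#'
#' Two tab-separated columns (`probe_id`, `log2_ratio`) plus a JSON sidecar
#' (`<path>.json`) holding sample/reference sex and noise metadata.
#'
#' @param profile An `array_profile`.
#' @param path Output TSV path.
#' @return `write_profile_tsv` returns `path` invisibly; `read_profile_tsv`
#'   returns an `array_profile`.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "array_profile"))
  write.table(profile[, c("probe_id", "log2_ratio")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  meta <- list(sample_sex = attr(profile, "sample_sex"),
               reference_sex = attr(profile, "reference_sex"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".json")
  sx <- rx <- NA_character_
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    sx <- meta$sample_sex; rx <- meta$reference_sex
  }
  structure(d, sample_sex = sx, reference_sex = rx,
            class = c("array_profile", "data.frame"))
}

#' Write segments or calls as BED-like TSV
#'
#' @param segments Data frame of segments or calls.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_segments_tsv <- function(segments, path) {
  write.table(segments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read sequences as FASTA
#'
#' Thin wrappers over Biostrings for named character vectors of DNA.
#'
#' @param seqs Named character vector of sequences.
#' @param path FASTA file path.
#' @return `write_fasta` returns `path` invisibly; `read_fasta` returns a
#'   named character vector.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Read a BED repeat track
#'
#' Four columns: chrom, start, end, name (0-based half-open).
#'
#' @param path BED file path.
#' @return Data frame with columns `chrom`, `start`, `end`, `name`.
#' @export
read_repeat_bed <- function(path) {
  read.delim(path, header = FALSE,
             col.names = c("chrom", "start", "end", "name"),
             stringsAsFactors = FALSE)
}
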