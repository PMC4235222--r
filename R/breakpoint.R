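## longest common prefix / suffix lengths of two strings, via raw bytes
lcp_len <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  n <- min(length(ra), length(rb))
  if (n == 0) return(0L)
  neq <- which(ra[seq_len(n)] != rb[seq_len(n)])
  if (length(neq) == 0) n else neq[1] - 1L
}

lcs_len <- function(a, b) {
  ra <- rev(charToRaw(a)); rb <- rev(charToRaw(b))
  n <- min(length(ra), length(rb))
  if (n == 0) return(0L)
  neq <- which(ra[seq_len(n)] != rb[seq_len(n)])
  if (length(neq) == 0) n else neq[1] - 1L
}

#' Reverse complement of a DNA string
#'
#' @param x A sequence string.
#' @return The reverse complement.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Bound breakpoints from probe evidence
#'
#' The deviant probes of a call bound the lesion from the inside: the union
#' of their footprints is the minimally affected (inner) interval, and the
#' gap between the nearest flanking non-deviant probes is the maximally
#' affected (outer) interval. With no flanking probe the outer bound runs
#' to the chromosome start (0) or is unbounded (`NA`) distally.
#'
#' @param call One row of a call/candidate data frame (with `chrom`,
#'   `first_probe`, `last_probe` manifest row indices).
#' @param manifest The `probe_manifest`.
#' @return `list(chrom=, inner=c(start,end), outer=c(start,end))` of class
#'   `breakpoint_bounds`; `outer[2]` may be `NA` (chromosome end).
#' @export
bound_breakpoints <- function(call, manifest) {
  fp <- call$first_probe; lp <- call$last_probe
  if (is.null(fp) || is.na(fp) || lp < fp) stop("call has no deviant probes")
  run <- fp:lp
  chrom <- manifest$chrom[fp]
  inner <- c(min(manifest$start[run]), max(manifest$end[run]))
  same <- which(manifest$chrom == chrom & manifest$category != "control")
  prox <- same[same < fp]
  dist <- same[same > lp]
  # on overlapping designs a flanking normal probe's footprint can reach
  # inside the deviant span; the maximal interval still contains the
  # minimal one
  outer <- c(if (length(prox)) min(max(manifest$end[prox]), inner[1])
             else 0L,
             if (length(dist)) max(min(manifest$start[dist]), inner[2])
             else NA_integer_)
  structure(list(chrom = chrom, inner = inner, outer = outer),
            class = "breakpoint_bounds")
}

## simple GC-based melting estimate (per-base increments, no nearest
## neighbours -- wet-lab fidelity is out of scope)
primer_tm <- function(seq) {
  L <- nchar(seq)
  gc <- L - nchar(gsub("[GCgc]", "", seq))
  64.9 + 41 * (gc - 16.4) / L
}

## first admissible primer scanning a window right-to-left (forward primer)
## or left-to-right (reverse primer); local 1-based coords within seq
find_primer <- function(seq, win_lo, win_hi, len_range, tm_range,
                        from_right = TRUE) {
  win_lo <- max(1L, win_lo); win_hi <- min(nchar(seq), win_hi)
  if (win_hi - win_lo + 1 < len_range[1]) return(NULL)
  starts <- win_lo:(win_hi - len_range[1] + 1L)
  if (from_right) starts <- rev(starts)
  for (s in starts) {
    for (L in len_range[1]:len_range[2]) {
      if (s + L - 1L > win_hi) break
      p <- substr(seq, s, s + L - 1L)
      if (grepl("[^ACGT]", p)) next
      tm <- primer_tm(p)
      if (tm >= tm_range[1] && tm <= tm_range[2]) {
        return(list(start = s, end = s + L - 1L, seq = p, tm = tm))
      }
    }
  }
  NULL
}

#' Plan breakpoint-walking PCR primers in silico
#'
#' Emits primer pairs at increasing offsets outside the inner (minimally
#' deleted) interval, emulating walking along the sequence proximal and
#' distal to the possible lesion: step 0 sits just outside the inner
#' interval and each further step moves `step_bp` outward, so that at least
#' one pair escapes the true breakpoints whatever their position within the
#' outer bounds. Primers are 18-30 nt with a per-base melting estimate
#' within `tm_range`. Steps whose windows admit no primer are skipped with
#' a warning.
#'
#' @param bounds A `breakpoint_bounds`.
#' @param fixtures A `seq_fixture` (or list) covering the walked region.
#' @param step_bp Walk step size, bp.
#' @param n_steps Number of walk steps per side.
#' @param len_range Primer length range, nt.
#' @param tm_range Admissible melting range, degrees C.
#' @return Data frame (class `primer_plan`): `step`, forward and reverse
#'   primer genomic coordinates, sequences, melting estimates, and
#'   `amplicon_normal` (product size on an unrearranged allele). Use
#'   [predict_amplicon()] for candidate deletion sizes.
#' @export
design_walking_primers <- function(bounds, fixtures, step_bp = 250L,
                                   n_steps = 3L, len_range = c(18L, 30L),
                                   tm_range = c(52, 62)) {
  stopifnot(inherits(bounds, "breakpoint_bounds"))
  reach <- as.integer(step_bp) * n_steps + 100L
  lo <- max(0L, bounds$inner[1] - reach)
  hi <- bounds$inner[2] + reach
  fx <- find_fixture(fixtures, bounds$chrom, lo, hi)
  if (is.null(fx)) stop("reference fixture does not cover the walked region")
  seq <- substr(fx$seq, lo - fx$start + 1, hi - fx$start)
  in1 <- bounds$inner[1] - lo  # local length of left flank
  in2 <- bounds$inner[2] - lo
  rows <- list()
  for (k in seq_len(n_steps) - 1L) {
    fwd <- find_primer(seq, in1 - (k + 1L) * step_bp + 1L, in1 - k * step_bp,
                       len_range, tm_range, from_right = TRUE)
    rev_ <- find_primer(seq, in2 + k * step_bp + 1L, in2 + (k + 1L) * step_bp,
                        len_range, tm_range, from_right = FALSE)
    if (is.null(fwd) || is.null(rev_)) {
      warning("no admissible primer pair at walk step ", k)
      next
    }
    rev_seq <- revcomp(rev_$seq)
    rows[[length(rows) + 1]] <- data.frame(
      step = k,
      fwd_start = lo + fwd$start - 1L, fwd_end = lo + fwd$end,
      fwd_seq = fwd$seq, fwd_tm = fwd$tm,
      rev_start = lo + rev_$start - 1L, rev_end = lo + rev_$end,
      rev_seq = rev_seq, rev_tm = rev_$tm,
      amplicon_normal = (lo + rev_$end) - (lo + fwd$start - 1L),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(step = integer(0), fwd_start = integer(0),
               fwd_end = integer(0), fwd_seq = character(0),
               fwd_tm = numeric(0), rev_start = integer(0),
               rev_end = integer(0), rev_seq = character(0),
               rev_tm = numeric(0), amplicon_normal = integer(0))
  class(out) <- c("primer_plan", "data.frame")
  out
}

#' Predicted junction amplicon size on a rearranged allele
#'
#' @param plan A `primer_plan` (or subset of rows).
#' @param deletion_size Candidate deletion length, bp.
#' @param insert_length Bases inserted between the breakpoints, bp.
#' @return Numeric vector of predicted product sizes, one per plan row.
#' @export
predict_amplicon <- function(plan, deletion_size, insert_length = 0L) {
  plan$amplicon_normal - deletion_size + insert_length
}

#' Characterize a junction from reference and rearranged sequences
#'
#' Aligns the two sequences by their longest shared flanks. With maximal
#' prefix `p*` and suffix `s*`, the overlap `k = p* + s* - min(len)` (when
#' positive) measures the ambiguity of the junction placement; breakpoints
#' are reported left-aligned with the microhomology length `k` given
#' separately. The deleted length is `len(ref) - p - s`; the alt middle is
#' the inserted sequence, classified by ordered tests: reverse-complement
#' match within `inverted_window` of either breakpoint (inverted_local),
#' exact match in `search_fixture` (distal_templated), a flanking direct
#' repeat of at least `tsd_min` bases (mobile_element_with_TSD), else
#' unknown. Equal-length substitution-only differences are classed
#' `substitution_only`.
#'
#' @param ref_seq Reference sequence over the region.
#' @param alt_seq The allele's sequence over the same region.
#' @param search_fixture Optional character vector (or `seq_fixture` list)
#'   of sequences searched for a distal template of the insert.
#' @param params A [junction_params()] record.
#' @return A list of class `junction_report`: `event_class` (deletion /
#'   insertion / deletion_with_insert / substitution_only / none),
#'   `deletion_length`, `microhomology_length`, `inserted_seq`,
#'   `insert_origin`, `tsd_length`, and the left-aligned local breakpoints
#'   `ref_break` (`c(start, end)`, 0-based within `ref_seq`).
#' @export
analyze_junction <- function(ref_seq, alt_seq, search_fixture = NULL,
                             params = junction_params()) {
  nR <- nchar(ref_seq); nA <- nchar(alt_seq)
  p_max <- lcp_len(ref_seq, alt_seq)
  s_max <- lcs_len(ref_seq, alt_seq)
  if (p_max == 0 && s_max == 0 && nR > 0 && nA > 0) {
    warning("sequences share no flanking context")
    return(structure(list(event_class = "none", deletion_length = 0L,
                          microhomology_length = 0L, inserted_seq = "",
                          insert_origin = "none", tsd_length = 0L,
                          ref_break = c(NA_integer_, NA_integer_)),
                     class = "junction_report"))
  }
  k <- max(0L, p_max + s_max - min(nR, nA))
  p <- p_max - k   # left-aligned junction
  s <- s_max
  del <- nR - p - s
  ins <- substr(alt_seq, p + 1L, nA - s)
  mh <- if (del > 0 && nchar(ins) == 0) k else 0L
  cls <- if (del == 0 && nchar(ins) == 0) "none"
    else if (del > 0 && nchar(ins) == 0) "deletion"
    else if (del == 0) "insertion"
    else if (del == nchar(ins)) "substitution_only"
    else "deletion_with_insert"
  origin <- "none"; tsd <- 0L
  if (nchar(ins) > 0 && cls %in% c("insertion", "deletion_with_insert")) {
    origin <- "unknown"
    W <- params$inverted_window
    near <- substr(ref_seq, max(1L, p - W + 1L), min(nR, p + del + W))
    if (nchar(ins) >= 4 && grepl(revcomp(ins), near, fixed = TRUE)) {
      origin <- "inverted_local"
    } else {
      hit <- FALSE
      if (!is.null(search_fixture)) {
        seqs <- if (inherits(search_fixture, "seq_fixture")) {
          search_fixture$seq
        } else if (is.list(search_fixture)) {
          vapply(search_fixture, function(f) {
            if (inherits(f, "seq_fixture")) f$seq else as.character(f)
          }, character(1))
        } else as.character(search_fixture)
        hit <- any(vapply(seqs, grepl, logical(1), pattern = ins,
                          fixed = TRUE))
      }
      if (hit) {
        origin <- "distal_templated"
      } else {
        # direct repeat of the target site at either end of the insert
        tmax <- min(nchar(ins), p, nR - p - del)
        for (t in rev(seq_len(max(0L, tmax)))) {
          if (t < params$tsd_min) break
          before <- substr(ref_seq, p - t + 1L, p)
          after <- substr(ref_seq, p + del + 1L, p + del + t)
          if (substr(ins, nchar(ins) - t + 1L, nchar(ins)) == before ||
              substr(ins, 1L, t) == after) {
            origin <- "mobile_element_with_TSD"
            tsd <- t
            break
          }
        }
      }
    }
  }
  structure(list(event_class = cls, deletion_length = as.integer(del),
                 microhomology_length = as.integer(mh),
                 inserted_seq = ins, insert_origin = origin,
                 tsd_length = as.integer(tsd),
                 ref_break = c(as.integer(p), as.integer(p + del))),
            class = "junction_report")
}

#' Repeats near an interval
#'
#' Reports repeat-track elements overlapping the interval or within a closed
#' window of it, with the distance from the repeat to the nearest of the two
#' breakpoints (interval ends): positive when the repeat's nearest edge lies
#' inside the interval, negative outside, zero when it spans a breakpoint.
#'
#' @param chrom,start,end The interval (0-based half-open).
#' @param repeat_track Data frame `chrom`, `start`, `end`, `name`.
#' @param window Closed search window, bp.
#' @return Data frame `name`, `distance` (possibly empty).
#' @export
annotate_repeats <- function(chrom, start, end, repeat_track,
                             window = junction_params()$repeat_window) {
  if (is.null(repeat_track) || nrow(repeat_track) == 0) {
    return(data.frame(name = character(0), distance = integer(0)))
  }
  rt <- repeat_track[repeat_track$chrom == chrom &
                       repeat_track$start <= end + window &
                       repeat_track$end >= start - window, , drop = FALSE]
  if (nrow(rt) == 0) {
    return(data.frame(name = character(0), distance = integer(0)))
  }
  dist <- vapply(seq_len(nrow(rt)), function(i) {
    rs <- rt$start[i]; re <- rt$end[i]
    if (rs <= start && re >= start || rs <= end && re >= end) return(0L)
    if (rs >= start && re <= end) {
      # inside: distance to the nearer breakpoint
      as.integer(min(rs - start, end - re))
    } else {
      # outside: negative gap to the nearer breakpoint
      -as.integer(min(abs(c(rs - end, start - re))))
    }
  }, integer(1))
  data.frame(name = rt$name, distance = dist, stringsAsFactors = FALSE)
}

#' Resolve a review candidate with simulated sequence follow-up
#'
#' Emulates the breakpoint-PCR confirmation step: emits each allele's
#' sequence over the candidate region (the outer bounds widened by
#' `resolve_flank`, clipped to the fixture) and characterizes its junction
#' against the reference. A junction deleting at least one base confirms a
#' deletion; a pure insertion is an insertion false positive; equal-length
#' substitution-only differences are a sequence-variant false positive;
#' otherwise the candidate is unresolved.
#'
#' @param call One call/candidate row.
#' @param manifest The `probe_manifest`.
#' @param genotype The sample's [genotype_spec()].
#' @param fixtures Reference `seq_fixture`(s) covering the region.
#' @param search_fixture Passed to [analyze_junction()].
#' @param params [junction_params()].
#' @param resolve_flank How far beyond the outer bounds the follow-up
#'   explores, bp (primer walking reaches outward).
#' @return `list(resolution=, junction=, region=)` where `resolution` is one
#'   of confirmed_deletion / insertion_fp / sequence_variant_fp /
#'   unresolved and `junction` is the decisive `junction_report` (or NULL).
#' @export
resolve_candidate <- function(call, manifest, genotype, fixtures,
                              search_fixture = NULL,
                              params = junction_params(),
                              resolve_flank = 2500L) {
  b <- bound_breakpoints(call, manifest)
  fx <- find_fixture(fixtures, b$chrom, b$inner[1], b$inner[2])
  if (is.null(fx)) stop("no sequence fixture covers the candidate region")
  lo <- max(fx$start, b$outer[1] - resolve_flank)
  hi <- min(fx$end, (if (is.na(b$outer[2])) b$inner[2] else b$outer[2]) +
              resolve_flank)
  # walk outward until every overlapping event is fully inside the region,
  # so a junction is never read against a lesion the region truncates
  repeat {
    grown <- FALSE
    for (e in genotype$events) {
      if (e$chrom == b$chrom && e$start < hi && e$end > lo) {
        nl <- min(lo, e$start - 200L); nh <- max(hi, e$end + 200L)
        if (nl < lo || nh > hi) {
          lo <- nl; hi <- nh; grown <- TRUE
        }
      }
    }
    if (!grown) break
  }
  lo <- max(fx$start, lo); hi <- min(fx$end, hi)
  region <- list(chrom = b$chrom, start = lo, end = hi)
  ref <- substr(fx$seq, lo - fx$start + 1, hi - fx$start)
  alleles <- emit_local_sequence(genotype, fixtures, region)
  best <- NULL
  resolution <- "unresolved"
  for (al in alleles) {
    jr <- suppressWarnings(analyze_junction(ref, al, search_fixture, params))
    if (jr$event_class %in% c("deletion", "deletion_with_insert")) {
      if (is.null(best) || jr$deletion_length > best$deletion_length) {
        best <- jr; resolution <- "confirmed_deletion"
      }
    } else if (jr$event_class == "insertion" &&
               resolution != "confirmed_deletion") {
      best <- jr; resolution <- "insertion_fp"
    } else if (jr$event_class == "substitution_only" &&
               !resolution %in% c("confirmed_deletion", "insertion_fp")) {
      best <- jr; resolution <- "sequence_variant_fp"
    }
  }
  list(resolution = resolution, junction = best, region = region)
}
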