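# Independent oracles and fixture builders used across the test files.

## brute-force exon tiler: merges intervals by sweeping, then walks each
## region emitting probe starts; independent of the package's tiling code
brute_tile_count <- function(starts, ends, L, spacing, flank) {
  s <- pmax(0, starts - flank); e <- ends + flank
  o <- order(s)
  s <- s[o]; e <- e[o]
  regions <- list(c(s[1], e[1]))
  for (k in seq_along(s)[-1]) {
    last <- regions[[length(regions)]]
    if (s[k] <= last[2]) {
      regions[[length(regions)]][2] <- max(last[2], e[k])
    } else {
      regions[[length(regions) + 1]] <- c(s[k], e[k])
    }
  }
  total <- 0L
  for (r in regions) {
    if (r[2] - r[1] <= L) {
      total <- total + 1L
      next
    }
    pos <- r[1]
    placed <- c()
    while (pos <= r[2] - L) {
      placed <- c(placed, pos)
      pos <- pos + spacing
    }
    if (max(placed) < r[2] - L) placed <- c(placed, r[2] - L)
    total <- total + length(unique(placed))
  }
  total
}

## exhaustive arc search with the statistic computed from raw group sums,
## iterating i ascending then j ascending, first maximum kept
brute_best_split <- function(x, min_width = 2L) {
  n <- length(x)
  best <- list(i = -1L, j = -1L, t = 0)
  best_abs <- -1
  for (i in 0:(n - min_width)) {
    for (j in (i + min_width):min(n, i + n - min_width)) {
      inx <- x[(i + 1):j]
      outx <- x[-((i + 1):j)]
      m1 <- mean(inx); m2 <- mean(outx)
      ss <- sum((inx - m1)^2) + sum((outx - m2)^2)
      s2 <- if (n > 2) ss / (n - 2) else 0
      den <- sqrt(s2 * (1 / length(inx) + 1 / length(outx)))
      t <- if (den < 1e-14) {
        if (abs(m1 - m2) > 1e-14) sign(m1 - m2) * 1e18 else 0
      } else (m1 - m2) / den
      if (abs(t) > best_abs) {
        best_abs <- abs(t)
        best <- list(i = i, j = j, t = t)
      }
    }
  }
  best
}

## junction fixture builder: a deletion of del_len with an exact
## microhomology of mh bases (possibly longer than the deletion, via a
## periodic stretch) or an insert between the breakpoints; returns the
## reference and rearranged sequence with all flank-extension guards set
pick_other <- function(avoid) setdiff(c("A", "C", "G", "T"), avoid)[1]

make_junction_fixture <- function(del_len, mh = 0L, ins = "",
                                  flank = 80L, seed = 1L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  A <- sample(bases, flank, replace = TRUE)
  tl <- sample(bases, flank, replace = TRUE)
  if (mh > 0) {
    stopifnot(nchar(ins) == 0)
    P <- sample(bases, del_len, replace = TRUE)
    stretch <- P[((seq_len(del_len + mh) - 1) %% del_len) + 1]
    tl[1] <- pick_other(P[(mh %% del_len) + 1])  # break the period
    A[flank] <- pick_other(P[del_len])           # no left extension
  } else {
    stretch <- sample(bases, del_len, replace = TRUE)
    if (nchar(ins) > 0) {
      stretch[1] <- pick_other(substr(ins, 1, 1))
      stretch[del_len] <- pick_other(substr(ins, nchar(ins), nchar(ins)))
    } else {
      tl[1] <- pick_other(stretch[1])
    }
    A[flank] <- pick_other(stretch[del_len])
  }
  ref <- paste(c(A, stretch, tl), collapse = "")
  post <- substr(ref, flank + del_len + 1, nchar(ref))
  alt <- paste0(paste(A, collapse = ""), ins, post)
  list(ref = ref, alt = alt)
}

## uniform single-target manifest with exactly n probes and no backbone
flat_manifest <- function(n, spacing = 60L, chrom = "chr1",
                          tx = 1000000L) {
  gm <- gene_model("SIM", chrom, "+", tx,
                   tx + (n - 1L) * spacing + 60L, "AR", 1L)
  man <- build_manifest(list(gm), design_params(
    exon_flank_bp = 0L, target_spacing_bp = spacing,
    backbone_margin_bp = 0L))
  man <- man[man$category == "target", ]
  rownames(man) <- NULL
  stopifnot(nrow(man) == n)
  man
}

## array profile wrapping explicit values
profile_from_values <- function(manifest, values, sex = "XX") {
  structure(data.frame(probe_id = manifest$probe_id, log2_ratio = values,
                       stringsAsFactors = FALSE),
            sample_sex = sex, reference_sex = sex,
            class = c("array_profile", "data.frame"))
}

## the case suite and its evaluation are expensive; cache per seed so the
## workbench and acceptance files share one build
.exoncgh_cache <- new.env(parent = emptyenv())

cached_suite <- function(seed = 1L) {
  key <- paste0("suite", seed)
  if (is.null(.exoncgh_cache[[key]])) {
    .exoncgh_cache[[key]] <- build_case_suite(seed = seed)
  }
  .exoncgh_cache[[key]]
}

cached_eval <- function(seed = 1L) {
  key <- paste0("eval", seed)
  if (is.null(.exoncgh_cache[[key]])) {
    .exoncgh_cache[[key]] <- evaluate_suite(cached_suite(seed))
  }
  .exoncgh_cache[[key]]
}
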