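# Independent brute-force oracles used to cross-check the pipeline.

# O(n^2) tricube smoother, one chromosome at a time
naive_tricube <- function(chrom, pos, y, window_bp) {
  out <- numeric(length(pos))
  for (i in seq_along(pos)) {
    w <- numeric(length(pos))
    for (j in seq_along(pos)) {
      if (chrom[j] != chrom[i]) next
      d <- abs(pos[j] - pos[i]) / window_bp
      if (d < 1) w[j] <- (1 - d^3)^3
    }
    out[i] <- sum(w * y) / sum(w)
  }
  out
}

# explicit run scan for above-threshold intervals
naive_intervals <- function(chrom, pos, fitted, threshold, merge_gap_bp) {
  rows <- list()
  for (chr in unique(chrom)) {
    idx <- which(chrom == chr)
    above <- idx[fitted[idx] > threshold]
    if (!length(above)) next
    start <- pos[above[1]]; prev <- pos[above[1]]; peak <- fitted[above[1]]
    for (k in above[-1]) {
      if (pos[k] - prev >= merge_gap_bp) {
        rows[[length(rows) + 1]] <- data.frame(chrom = chr, start = start,
                                               end = prev, peak_ed_fitted = peak)
        start <- pos[k]; peak <- fitted[k]
      } else peak <- max(peak, fitted[k])
      prev <- pos[k]
    }
    rows[[length(rows) + 1]] <- data.frame(chrom = chr, start = start,
                                           end = prev, peak_ed_fitted = peak)
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      peak_ed_fitted = numeric()))
  }
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# minimum spanning-tree weight by exhaustive enumeration (<= 7 nodes)
brute_mst_weight <- function(d) {
  n <- nrow(d)
  if (n == 1) return(0)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  best <- Inf
  for (sel in utils::combn(nrow(pairs), n - 1, simplify = FALSE)) {
    comp <- seq_len(n)
    find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
    ok <- TRUE
    for (e in sel) {
      ri <- find(pairs[e, 1]); rj <- find(pairs[e, 2])
      if (ri == rj) { ok <- FALSE; break }
      comp[ri] <- rj
    }
    if (ok) best <- min(best, sum(d[pairs[sel, , drop = FALSE]]))
  }
  best
}

# mean pairwise per-site difference among haplotype sequences
pi_pairwise_oracle <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  n <- nrow(mat)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(i - 1)) {
    tot <- tot + sum(mat[i, ] != mat[j, ])
  }
  tot / choose(n, 2) / ncol(mat)
}

# Jaccard overlap between two interval sets on one chromosome
jaccard_intervals <- function(a, b) {
  cov <- function(x) {
    if (!nrow(x)) return(integer(0))
    unlist(lapply(seq_len(nrow(x)), function(i) x$start[i]:x$end[i]))
  }
  ca <- unique(cov(a)); cb <- unique(cov(b))
  if (!length(ca) && !length(cb)) return(NA_real_)
  length(intersect(ca, cb)) / length(union(ca, cb))
}

rdirichlet_test <- function(k) {
  x <- stats::rgamma(k, 1)
  x / sum(x)
}

path_table1 <- function() {
  system.file("extdata", "guiping_locus_diversity.tsv", package = "pcampr")
}
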