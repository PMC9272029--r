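#' Frequency-weighted ABBA/BABA site-pattern counts
#'
#' For the four-taxon topology (((P1, P2), P3), Outgroup), each biallelic
#' site contributes frequency-weighted pattern mass:
#' ABBA += (1 - p1) p2 p3 (1 - p4) and BABA += p1 (1 - p2) p3 (1 - p4),
#' with p_i the derived-allele frequency in population i. Contributions are
#' accumulated per genomic block for the jackknife.
#'
#' @param p1,p2,p3,p4 Numeric vectors of allele frequencies per site.
#' @param blocks Vector of block ids per site (factor/character/integer);
#'   default puts all sites in one block.
#' @return Object of class `site_pattern_counts`: list with totals `abba`,
#'   `baba`, `n_blocks`, and per-block matrices.
#' @export
site_patterns <- function(p1, p2, p3, p4, blocks = NULL) {
  n <- length(p1)
  stopifnot(length(p2) == n, length(p3) == n, length(p4) == n, n >= 1)
  if (is.null(blocks)) blocks <- rep(1L, n)
  stopifnot(length(blocks) == n)
  abba <- (1 - p1) * p2 * p3 * (1 - p4)
  baba <- p1 * (1 - p2) * p3 * (1 - p4)
  b <- factor(blocks)
  per_block <- cbind(abba = tapply(abba, b, sum),
                     baba = tapply(baba, b, sum))
  structure(list(abba = sum(abba), baba = sum(baba),
                 n_blocks = nlevels(b), per_block = per_block),
            class = "site_pattern_counts")
}

#' D statistic from site-pattern counts
#'
#' D = (ABBA - BABA) / (ABBA + BABA), in [-1, 1]. Positive D indicates
#' excess allele sharing between P2 and P3 (gene flow), negative between P1
#' and P3.
#'
#' @param counts A `site_pattern_counts` object.
#' @return The D statistic, or `NA` with a warning when no informative
#'   pattern mass is present.
#' @export
d_statistic <- function(counts) {
  tot <- counts$abba + counts$baba
  if (tot <= 0) {
    warning("d_statistic: no informative sites; D undefined")
    return(NA_real_)
  }
  (counts$abba - counts$baba) / tot
}

#' Block-jackknife significance of the D statistic
#'
#' Delete-one-block jackknife: D is recomputed leaving out each block in
#' turn; SE^2 = (B - 1)/B * sum((D_-j - mean(D_-j))^2) over the B blocks,
#' and Z = D / SE.
#'
#' @param counts A `site_pattern_counts` with at least 2 blocks.
#' @return List with elements `d`, `se`, `z`, `n_blocks`.
#' @export
jackknife_z <- function(counts) {
  stopifnot(inherits(counts, "site_pattern_counts"))
  if (counts$n_blocks < 2L) stop("jackknife_z: need at least 2 blocks")
  d <- d_statistic(counts)
  pb <- counts$per_block
  loo <- vapply(seq_len(nrow(pb)), function(j) {
    a <- counts$abba - pb[j, "abba"]
    b <- counts$baba - pb[j, "baba"]
    if (a + b <= 0) return(NA_real_)
    (a - b) / (a + b)
  }, numeric(1))
  loo <- loo[!is.na(loo)]
  B <- length(loo)
  se <- sqrt((B - 1) / B * sum((loo - mean(loo))^2))
  list(d = d, se = se, z = if (se > 0) d / se else NA_real_, n_blocks = B)
}

#' ABBA-BABA test on a four-population frequency table
#'
#' Convenience wrapper: assigns sites to physical blocks of `block_bp`
#' (per chromosome), accumulates frequency-weighted pattern counts and
#' returns the D statistic with its block-jackknife Z score.
#'
#' @param panel Data frame with columns chrom, pos, p1, p2, p3, p4.
#' @param block_bp Jackknife block size in bp (default 1e6).
#' @return List with `abba`, `baba`, `d`, `se`, `z`, `n_blocks`.
#' @export
abba_baba <- function(panel, block_bp = 1e6) {
  stopifnot(all(c("chrom", "pos", "p1", "p2", "p3", "p4") %in% names(panel)))
  blocks <- paste(panel$chrom, (panel$pos - 1) %/% block_bp, sep = ":")
  counts <- site_patterns(panel$p1, panel$p2, panel$p3, panel$p4, blocks)
  jk <- jackknife_z(counts)
  c(list(abba = counts$abba, baba = counts$baba), jk)
}
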