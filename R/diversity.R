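#' Allele frequencies at one locus
#'
#' Counts allele copies over the typed (non-missing) individuals only; each
#' typed individual contributes two copies.
#'
#' @param matrix A `marker_genotype_matrix`.
#' @param locus Locus name or index.
#' @return Named numeric vector of allele frequencies (sums to 1), with
#'   attribute `n_typed` giving the number of typed individuals.
#' @export
allele_frequencies <- function(matrix, locus) {
  stopifnot(inherits(matrix, "marker_genotype_matrix"))
  a1 <- matrix$allele1[, locus]
  a2 <- matrix$allele2[, locus]
  typed <- !is.na(a1)
  if (!any(typed)) stop("allele_frequencies: no typed individuals at locus ", locus)
  tab <- table(c(a1[typed], a2[typed]))
  freqs <- as.numeric(tab) / sum(tab)
  names(freqs) <- names(tab)
  attr(freqs, "n_typed") <- sum(typed)
  freqs
}

#' Nei's gene diversity
#'
#' 1 - sum(p_i^2): the expected heterozygosity under random union of
#' gametes, uncorrected for sample size.
#'
#' @param freqs Numeric vector of allele frequencies.
#' @return Gene diversity in [0, 1).
#' @export
nei_gene_diversity <- function(freqs) 1 - sum(freqs^2)

#' Effective number of alleles
#'
#' 1 / sum(p_i^2): the number of equifrequent alleles giving the same
#' expected homozygosity. Satisfies Ae = 1 / (1 - Nei) exactly.
#'
#' @param freqs Numeric vector of allele frequencies.
#' @return Effective allele number >= 1.
#' @export
effective_alleles <- function(freqs) 1 / sum(freqs^2)

#' Shannon-Weaver information index
#'
#' -sum(p_i ln p_i) over allele frequencies, natural logarithm, with
#' 0 ln 0 = 0.
#'
#' @param freqs Numeric vector of allele frequencies.
#' @return Index in [0, ln(number of alleles)].
#' @export
shannon_index <- function(freqs) {
  as.numeric(vegan::diversity(matrix(freqs, nrow = 1), index = "shannon"))
}

#' Observed heterozygosity at one locus
#'
#' Fraction of typed individuals carrying two distinct alleles.
#'
#' @param matrix A `marker_genotype_matrix`.
#' @param locus Locus name or index.
#' @return Proportion in [0, 1].
#' @export
observed_heterozygosity <- function(matrix, locus) {
  a1 <- matrix$allele1[, locus]
  a2 <- matrix$allele2[, locus]
  typed <- !is.na(a1)
  if (!any(typed)) stop("observed_heterozygosity: no typed individuals")
  mean(a1[typed] != a2[typed])
}

#' Unbiased expected heterozygosity
#'
#' Nei's sample-size-corrected expected heterozygosity,
#' (2n / (2n - 1)) * (1 - sum p_i^2), with n the number of typed diploid
#' individuals.
#'
#' @param freqs Numeric vector of allele frequencies.
#' @param n_typed Number of typed individuals.
#' @return Unbiased expected heterozygosity.
#' @export
expected_heterozygosity_unbiased <- function(freqs, n_typed) {
  stopifnot(n_typed >= 1)
  (2 * n_typed / (2 * n_typed - 1)) * (1 - sum(freqs^2))
}

#' Back-solve biallelic allele frequencies from gene diversity
#'
#' For a biallelic locus, gene diversity 2pq determines the frequency pair:
#' p^2 + q^2 = 1 - nei and p + q = 1 give p = (1 + sqrt(1 - 2*nei)) / 2.
#' Returns p >= q deterministically.
#'
#' @param nei Nei's gene diversity, in [0, 0.5].
#' @return Numeric vector c(p, q) with p >= q.
#' @export
solve_biallelic_freqs <- function(nei) {
  stopifnot(nei >= 0, nei <= 0.5 + 1e-12)
  disc <- max(0, 1 - 2 * nei)
  p <- (1 + sqrt(disc)) / 2
  c(p = p, q = 1 - p)
}

#' Per-locus diversity report with mean row
#'
#' Computes, for each locus, the number of typed individuals, allele count,
#' observed heterozygosity (Ho_obs), unbiased expected heterozygosity
#' (He_exp), Nei's gene diversity, effective allele number (Ae) and the
#' Shannon-Weaver index (I), and appends an unweighted arithmetic mean row.
#' Loci with fewer than 2 typed individuals are flagged in the `flag` column
#' rather than dropped.
#'
#' @param matrix A `marker_genotype_matrix`.
#' @return Data frame, one row per locus plus a final "Mean" row.
#' @export
locus_report <- function(matrix) {
  stopifnot(inherits(matrix, "marker_genotype_matrix"))
  if (!length(matrix$loci)) stop("locus_report: empty matrix")
  rows <- lapply(matrix$loci, function(loc) {
    f <- allele_frequencies(matrix, loc)
    n <- attr(f, "n_typed")
    data.frame(
      locus = loc,
      chromosome = unname(matrix$chromosomes[loc]),
      n_typed = n,
      n_alleles = length(f),
      ho_obs = observed_heterozygosity(matrix, loc),
      he_exp = expected_heterozygosity_unbiased(f, n),
      nei = nei_gene_diversity(f),
      ae = effective_alleles(f),
      shannon = shannon_index(f),
      flag = if (n < 2) "n_typed<2" else ""
    )
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, summarize_locus_table(out))
  rownames(out) <- NULL
  out
}

#' Append an unweighted mean row to a per-locus table
#'
#' The mean row is the plain arithmetic mean of each numeric column over
#' loci (each locus weighted equally, regardless of sample size).
#'
#' @param table Data frame of per-locus statistics.
#' @return One-row data frame with locus = "Mean".
#' @export
summarize_locus_table <- function(table) {
  num <- vapply(table, is.numeric, logical(1))
  means <- lapply(names(table), function(cn) {
    if (num[[cn]]) mean(table[[cn]]) else if (cn == "locus") "Mean" else NA
  })
  names(means) <- names(table)
  as.data.frame(means, stringsAsFactors = FALSE)
}

#' Nucleotide diversity (pi) from biallelic site frequencies
#'
#' Unbiased per-site nucleotide diversity over a region:
#' pi = sum over variable sites of 2 p (1 - p) * n / (n - 1), divided by the
#' total number of assayed sites. Equals the mean pairwise per-site
#' difference among the n haplotypes.
#'
#' @param p Numeric vector of derived-allele frequencies at the variable
#'   sites (monomorphic sites may be included as 0 or 1).
#' @param n Number of haplotypes sampled.
#' @param total_sites Total number of assayed sites (>= number of variable
#'   sites).
#' @return Nucleotide diversity per site.
#' @export
nucleotide_diversity_pi <- function(p, n, total_sites) {
  stopifnot(n >= 2, total_sites >= length(p[p > 0 & p < 1]))
  sum(2 * p * (1 - p)) * n / (n - 1) / total_sites
}

#' Nucleotide diversity from aligned haplotype sequences
#'
#' Convenience wrapper: tabulates per-column allele frequencies from an
#' aligned set of haplotype sequences and applies the frequency form of pi.
#'
#' @param seqs Named character vector of equal-length sequences.
#' @return Nucleotide diversity per site.
#' @export
pi_from_sequences <- function(seqs) {
  stopifnot(length(seqs) >= 2)
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  n <- nrow(mat)
  p <- apply(mat, 2, function(col) {
    tab <- table(col)
    if (length(tab) == 1L) return(0)
    if (length(tab) > 2L) stop("pi_from_sequences: site with >2 alleles")
    tab[[1]] / n
  })
  nucleotide_diversity_pi(p, n, ncol(mat))
}
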