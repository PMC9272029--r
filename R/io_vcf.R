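#' Variant-quality filter criteria
#'
#' The four-criterion quality filter applied to raw variant calls before any
#' downstream analysis: (1) missing rate strictly below `max_missing_rate`;
#' (2) read depth of every called sample at least `min_depth`; (3) biallelic
#' position; (4) genotype quality of every called sample strictly above
#' `min_gq`. Defaults are 0.2, 5, TRUE and 20.
#'
#' @param max_missing_rate Maximum allowed fraction of missing samples,
#'   exclusive bound (default 0.2).
#' @param min_depth Minimum per-sample read depth, inclusive (default 5).
#' @param require_biallelic Keep only sites with exactly one ALT (default TRUE).
#' @param min_gq Minimum per-sample genotype quality, exclusive (default 20).
#' @return Object of class `filter_criteria`.
#' @export
filter_criteria <- function(max_missing_rate = 0.2, min_depth = 5L,
                            require_biallelic = TRUE, min_gq = 20L) {
  stopifnot(max_missing_rate >= 0, is.logical(require_biallelic))
  structure(list(max_missing_rate = max_missing_rate, min_depth = min_depth,
                 require_biallelic = require_biallelic, min_gq = min_gq),
            class = "filter_criteria")
}

#' Construct a variant record
#'
#' In-memory representation of one VCF record: position, alleles, and one
#' entry per sample carrying allele depths (REF first, then ALTs), genotype
#' quality and a called flag. A sample is treated as missing when it is
#' uncalled or its allele depths are absent.
#'
#' @param chrom Chromosome id.
#' @param pos 1-based position.
#' @param ref REF allele string.
#' @param alts Character vector of ALT alleles.
#' @param samples List of per-sample lists with elements `ad` (integer
#'   vector, length 1 + number of ALTs when called), `gq` (integer) and
#'   `called` (logical).
#' @return Object of class `variant_record`.
#' @export
variant_record <- function(chrom, pos, ref, alts, samples) {
  stopifnot(pos >= 1)
  for (s in samples) {
    if (isTRUE(s$called) && !is.null(s$ad)) {
      stopifnot(all(s$ad >= 0), length(s$ad) == 1L + length(alts))
    }
  }
  structure(list(chrom = chrom, pos = pos, ref = ref, alts = alts,
                 samples = samples), class = "variant_record")
}

#' Apply the four variant-quality filters
#'
#' Retains exactly the records where the missing fraction over all samples is
#' strictly below the criterion, every called sample has total allele depth
#' at least `min_depth`, the site has exactly one ALT allele (when
#' `require_biallelic`), and every called sample has genotype quality
#' strictly above `min_gq`. Input order is preserved.
#'
#' @param records List of `variant_record` objects.
#' @param criteria A [filter_criteria()] object.
#' @return The filtered list.
#' @export
apply_variant_filters <- function(records, criteria = filter_criteria()) {
  stopifnot(inherits(criteria, "filter_criteria"))
  keep <- vapply(records, function(r) {
    miss <- vapply(r$samples, function(s) !isTRUE(s$called) || is.null(s$ad),
                   logical(1))
    if (length(miss) && mean(miss) >= criteria$max_missing_rate) return(FALSE)
    if (criteria$require_biallelic && length(r$alts) != 1L) return(FALSE)
    for (s in r$samples[!miss]) {
      if (sum(s$ad) < criteria$min_depth) return(FALSE)
      if (is.null(s$gq) || s$gq <= criteria$min_gq) return(FALSE)
    }
    TRUE
  }, logical(1))
  records[keep]
}

#' Parse a VCF file into variant records
#'
#' Reads a VCF (via vcfR) and returns the list of `variant_record` objects
#' that [apply_variant_filters()] consumes. Requires the per-sample AD
#' (allele depth) FORMAT field; GQ is taken when present.
#'
#' @param path Path to a VCF file.
#' @return List of `variant_record` objects.
#' @export
read_variant_records <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  n <- nrow(v@fix)
  if (n == 0L) return(list())
  has_samples <- ncol(v@gt) > 1L
  if (has_samples && !any(grepl("AD", v@gt[, "FORMAT"]))) {
    stop("read_variant_records: VCF lacks the AD FORMAT field")
  }
  ad <- if (has_samples) vcfR::extract.gt(v, "AD") else NULL
  gq <- if (has_samples) suppressWarnings(vcfR::extract.gt(v, "GQ", as.numeric = TRUE)) else NULL
  gt <- if (has_samples) vcfR::extract.gt(v, "GT") else NULL
  lapply(seq_len(n), function(i) {
    alts <- strsplit(v@fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    samples <- if (has_samples) {
      lapply(seq_len(ncol(ad)), function(j) {
        called <- !is.na(gt[i, j]) && !grepl("^\\.([/|]\\.)?$", gt[i, j]) &&
          !is.na(ad[i, j])
        list(
          ad = if (called) as.integer(strsplit(ad[i, j], ",", fixed = TRUE)[[1]]) else NULL,
          gq = if (!is.null(gq) && !is.na(gq[i, j])) as.integer(gq[i, j]) else NULL,
          called = called
        )
      })
    } else list()
    if (has_samples) names(samples) <- colnames(ad)
    variant_record(v@fix[i, "CHROM"], as.integer(v@fix[i, "POS"]),
                   v@fix[i, "REF"], alts, samples)
  })
}

#' Pool site table
#'
#' Container for per-site, per-pool base depths: a `sites` data frame
#' (chrom, pos, class in {"SNP","InDel"}, sorted by chrom then pos) and a
#' 3-d `depths` array [site, pool, 4 base slots A/C/G/T]. For InDel sites the
#' REF allele occupies slot 1 and the ALT allele slot 2, so the ED formula
#' applies unchanged to both variant classes.
#'
#' @param sites Data frame with columns chrom, pos, class.
#' @param depths Numeric array, dim = c(nrow(sites), n_pools, 4).
#' @param pools Character vector of pool names.
#' @return Object of class `pool_site_table`.
#' @export
pool_site_table <- function(sites, depths, pools) {
  stopifnot(is.data.frame(sites), all(c("chrom", "pos", "class") %in% names(sites)),
            length(dim(depths)) == 3L, dim(depths)[1] == nrow(sites),
            dim(depths)[2] == length(pools), dim(depths)[3] == 4L,
            all(depths >= 0), all(sites$class %in% c("SNP", "InDel")))
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  depths <- depths[ord, , , drop = FALSE]
  dimnames(depths) <- list(NULL, pools, c("A", "C", "G", "T"))
  structure(list(sites = sites, depths = depths, pools = pools),
            class = "pool_site_table")
}

pool_index <- function(table, pool) {
  if (is.numeric(pool)) {
    stopifnot(pool >= 1, pool <= length(table$pools))
    return(as.integer(pool))
  }
  i <- match(pool, table$pools)
  if (is.na(i)) stop("unknown pool name: ", pool)
  i
}

#' @export
print.pool_site_table <- function(x, ...) {
  cat("pool_site_table:", nrow(x$sites), "sites x", length(x$pools), "pools\n")
  cat("  SNP:", sum(x$sites$class == "SNP"),
      "| InDel:", sum(x$sites$class == "InDel"), "\n")
  invisible(x)
}

BASES <- c("A", "C", "G", "T")

#' Read pooled allele depths from a VCF into a pool site table
#'
#' For each biallelic record, the per-pool AD counts are placed on base
#' slots: SNP records (single-base REF and ALT) put the REF count on the REF
#' base slot and the ALT count on the ALT base slot; InDel records (alleles
#' of unequal length) put REF on slot 1 (A) and ALT on slot 2 (C). Records
#' with more than one ALT are dropped (the scan operates on biallelic sites).
#'
#' @param path Path to a VCF file with per-sample AD.
#' @param pool_names Character vector naming the pools; must be a subset of
#'   the VCF sample names.
#' @return A [pool_site_table()].
#' @export
read_pool_vcf <- function(path, pool_names) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0L) {
    return(pool_site_table(
      data.frame(chrom = character(), pos = integer(), class = character()),
      array(0, dim = c(0L, length(pool_names), 4L)), pool_names))
  }
  if (!any(grepl("AD", v@gt[, "FORMAT"]))) {
    stop("read_pool_vcf: VCF lacks the AD FORMAT field")
  }
  ad <- vcfR::extract.gt(v, "AD")
  missing_pools <- setdiff(pool_names, colnames(ad))
  if (length(missing_pools)) {
    stop("read_pool_vcf: pool name(s) not in VCF samples: ",
         paste(missing_pools, collapse = ", "))
  }
  alt <- v@fix[, "ALT"]
  ref <- v@fix[, "REF"]
  biallelic <- !is.na(alt) & !grepl(",", alt, fixed = TRUE)
  idx <- which(biallelic)
  n <- length(idx)
  depths <- array(0, dim = c(n, length(pool_names), 4L))
  class <- ifelse(nchar(ref[idx]) == 1L & nchar(alt[idx]) == 1L, "SNP", "InDel")
  for (k in seq_len(n)) {
    i <- idx[k]
    slots <- if (class[k] == "SNP") {
      s <- c(match(ref[i], BASES), match(alt[i], BASES))
      if (anyNA(s)) c(1L, 2L) else s
    } else c(1L, 2L)
    for (j in seq_along(pool_names)) {
      cell <- ad[i, pool_names[j]]
      if (is.na(cell)) next
      counts <- as.integer(strsplit(cell, ",", fixed = TRUE)[[1]])
      if (length(counts) != 2L) next
      depths[k, j, slots[1]] <- depths[k, j, slots[1]] + counts[1]
      depths[k, j, slots[2]] <- depths[k, j, slots[2]] + counts[2]
    }
  }
  pool_site_table(
    data.frame(chrom = v@fix[idx, "CHROM"], pos = as.integer(v@fix[idx, "POS"]),
               class = class),
    depths, pool_names)
}
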