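#' Per-site base frequencies from read depths
#'
#' Converts a vector of four base-supporting read counts (A, C, G, T slots;
#' for InDel sites the REF allele occupies slot 1 and the ALT allele slot 2)
#' into a frequency vector. A site with zero total depth has no defined
#' frequency and is flagged rather than set to zero.
#'
#' @param depths Numeric vector of length 4, non-negative read counts.
#' @return Numeric vector of length 4 summing to 1, or a vector of `NA` with
#'   attribute `undefined = TRUE` when total depth is zero.
#' @export
base_frequencies <- function(depths) {
  stopifnot(length(depths) == 4L, all(depths >= 0))
  total <- sum(depths)
  if (total == 0) {
    out <- rep(NA_real_, 4L)
    attr(out, "undefined") <- TRUE
    return(out)
  }
  depths / total
}

#' Euclidean-distance statistic between two pools at one site
#'
#' ED = sqrt((A1-A2)^2 + (C1-C2)^2 + (G1-G2)^2 + (T1-T2)^2) over the two
#' pools' base-frequency vectors. Symmetric, zero iff the frequencies are
#' equal, bounded above by sqrt(2).
#'
#' @param p,q Base-frequency vectors (length 4, summing to 1).
#' @return The ED value in [0, sqrt(2)].
#' @export
ed_site <- function(p, q) {
  if (isTRUE(attr(p, "undefined")) || isTRUE(attr(q, "undefined")) ||
      anyNA(p) || anyNA(q)) {
    stop("ed_site: undefined frequency vector; site must be skipped upstream")
  }
  sqrt(sum((p - q)^2))
}

#' Power correction of the ED statistic
#'
#' Raising ED to the k-th power (k = 5 by default) suppresses background
#' noise: small EDs from sampling variance shrink towards zero while EDs near
#' the sqrt(2) maximum are amplified.
#'
#' @param ed Numeric vector of raw ED values.
#' @param k Integer power, default 5.
#' @return `ed^k`.
#' @export
ed_power <- function(ed, k = 5L) {
  stopifnot(k >= 1)
  ed^k
}

#' Distance-weighted smoothing of powered ED values along a chromosome
#'
#' Fits each site's powered ED by a tricube distance-weighted local average
#' over physical position: sites within `window_bp` of the focal site get
#' weight w(d) = (1 - (d/window_bp)^3)^3, sites at or beyond the window get
#' zero. The focal site always contributes with weight 1. Smoothing is done
#' per chromosome; a chromosome with a single site keeps its own value.
#' `method = "median"` replaces the weighted mean by a moving median over the
#' same window.
#'
#' @param chrom Character vector of chromosome ids per site.
#' @param pos Integer vector of 1-based positions, sorted within chromosome.
#' @param ed_powered Numeric vector of powered ED values per site.
#' @param window_bp Positive window half-width in bp (default 1e6).
#' @param method "tricube" (default) or "median".
#' @return Numeric vector of fitted values, same length and order as input.
#' @export
fit_ed_profile <- function(chrom, pos, ed_powered, window_bp = 1e6,
                           method = c("tricube", "median")) {
  method <- match.arg(method)
  stopifnot(window_bp > 0, length(chrom) == length(pos),
            length(pos) == length(ed_powered))
  fitted <- numeric(length(pos))
  for (chr in unique(chrom)) {
    idx <- which(chrom == chr)
    p <- pos[idx]
    if (is.unsorted(p)) stop("fit_ed_profile: positions must be sorted within chromosome")
    y <- ed_powered[idx]
    # window bounds via binary search on the sorted positions
    lo <- findInterval(p - window_bp, p, left.open = TRUE) + 1L
    hi <- findInterval(p + window_bp, p, left.open = TRUE)
    out <- numeric(length(p))
    for (i in seq_along(p)) {
      j <- lo[i]:hi[i]
      d <- abs(p[j] - p[i]) / window_bp
      keep <- d < 1
      j <- j[keep]
      if (method == "tricube") {
        w <- (1 - d[keep]^3)^3
        out[i] <- sum(w * y[j]) / sum(w)
      } else {
        out[i] <- stats::median(y[j])
      }
    }
    fitted[idx] <- out
  }
  fitted
}

#' Genome-wide significance threshold for fitted ED values
#'
#' The threshold is the median of the fitted values plus three population
#' (n-denominator) standard deviations, computed over all sites genome-wide.
#'
#' @param ed_fitted Numeric vector of fitted ED values (>= 2 sites).
#' @return The threshold value.
#' @export
ed_threshold <- function(ed_fitted) {
  ed_fitted <- ed_fitted[!is.na(ed_fitted)]
  if (length(ed_fitted) < 2L) stop("ed_threshold: need at least 2 fitted values")
  n <- length(ed_fitted)
  sd_pop <- sqrt(sum((ed_fitted - mean(ed_fitted))^2) / n)
  stats::median(ed_fitted) + 3 * sd_pop
}

#' Candidate intervals from a thresholded ED profile
#'
#' Finds maximal runs of consecutive sites whose fitted ED strictly exceeds
#' the threshold (ties at the threshold do not qualify); runs on the same
#' chromosome separated by less than `merge_gap_bp` are merged. Each interval
#' spans the first to the last qualifying site (1-based inclusive).
#'
#' @param chrom,pos,ed_fitted Per-site profile, sorted within chromosome.
#' @param threshold Numeric threshold (see [ed_threshold()]).
#' @param merge_gap_bp Gap below which adjacent runs merge (default 1e5).
#' @return Data frame with columns chrom, start, end, peak_ed_fitted.
#' @export
extract_candidate_intervals <- function(chrom, pos, ed_fitted, threshold,
                                        merge_gap_bp = 1e5) {
  res <- list()
  for (chr in unique(chrom)) {
    idx <- which(chrom == chr & ed_fitted > threshold)
    if (!length(idx)) next
    p <- pos[idx]
    v <- ed_fitted[idx]
    # split qualifying sites wherever the gap to the previous one is >= merge_gap_bp
    brk <- c(TRUE, diff(p) >= merge_gap_bp)
    grp <- cumsum(brk)
    res[[chr]] <- data.frame(
      chrom = chr,
      start = tapply(p, grp, min),
      end = tapply(p, grp, max),
      peak_ed_fitted = tapply(v, grp, max),
      row.names = NULL
    )
  }
  if (!length(res)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      peak_ed_fitted = numeric()))
  }
  out <- do.call(rbind, res)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Intersection of two interval sets
#'
#' Standard per-chromosome interval intersection of 1-based inclusive
#' intervals; the result is sorted and non-overlapping.
#'
#' @param a,b Data frames with columns chrom, start, end.
#' @return Data frame with columns chrom, start, end.
#' @export
intersect_intervals <- function(a, b) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer())
  if (!nrow(a) || !nrow(b)) return(empty)
  res <- list()
  for (chr in intersect(unique(a$chrom), unique(b$chrom))) {
    ra <- IRanges::reduce(IRanges::IRanges(a$start[a$chrom == chr], a$end[a$chrom == chr]))
    rb <- IRanges::reduce(IRanges::IRanges(b$start[b$chrom == chr], b$end[b$chrom == chr]))
    ri <- IRanges::intersect(ra, rb)
    if (length(ri)) {
      res[[chr]] <- data.frame(chrom = chr, start = IRanges::start(ri),
                               end = IRanges::end(ri))
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' ED scan for a single pool pair and variant class
#'
#' Runs the per-comparison chain: drop sites with zero depth in either pool
#' (their frequencies are undefined), compute raw ED, raise to the k-th
#' power, smooth along each chromosome, set the genome-wide median + 3 SD
#' threshold, and extract candidate intervals.
#'
#' @param table A `pool_site_table`.
#' @param pool_a,pool_b Pool names or indices.
#' @param variant_class "SNP" or "InDel" (NULL = all sites together).
#' @param power ED power correction exponent (default 5).
#' @param window_bp Smoothing window (default 1e6).
#' @param merge_gap_bp Run-merging gap (default 1e5).
#' @param method Smoothing method passed to [fit_ed_profile()].
#' @return List with `profile` (data frame: chrom, pos, ed_raw, ed_powered,
#'   ed_fitted), `threshold`, and `intervals`.
#' @export
ed_scan <- function(table, pool_a, pool_b, variant_class = NULL, power = 5L,
                    window_bp = 1e6, merge_gap_bp = 1e5,
                    method = c("tricube", "median")) {
  method <- match.arg(method)
  stopifnot(inherits(table, "pool_site_table"))
  ia <- pool_index(table, pool_a)
  ib <- pool_index(table, pool_b)
  keep <- rep(TRUE, nrow(table$sites))
  if (!is.null(variant_class)) keep <- table$sites$class == variant_class
  da <- table$depths[, ia, , drop = TRUE]
  db <- table$depths[, ib, , drop = TRUE]
  if (is.null(dim(da))) { da <- matrix(da, nrow = 1); db <- matrix(db, nrow = 1) }
  ta <- rowSums(da); tb <- rowSums(db)
  keep <- keep & ta > 0 & tb > 0
  if (!any(keep)) {
    return(list(profile = data.frame(chrom = character(), pos = integer(),
                                     ed_raw = numeric(), ed_powered = numeric(),
                                     ed_fitted = numeric()),
                threshold = NA_real_,
                intervals = data.frame(chrom = character(), start = integer(),
                                       end = integer(), peak_ed_fitted = numeric())))
  }
  fa <- da[keep, , drop = FALSE] / ta[keep]
  fb <- db[keep, , drop = FALSE] / tb[keep]
  ed_raw <- sqrt(rowSums((fa - fb)^2))
  ed_pow <- ed_power(ed_raw, power)
  chrom <- table$sites$chrom[keep]
  pos <- table$sites$pos[keep]
  ed_fit <- fit_ed_profile(chrom, pos, ed_pow, window_bp, method)
  thr <- ed_threshold(ed_fit)
  list(profile = data.frame(chrom = chrom, pos = pos, ed_raw = ed_raw,
                            ed_powered = ed_pow, ed_fitted = ed_fit),
       threshold = thr,
       intervals = extract_candidate_intervals(chrom, pos, ed_fit, thr,
                                               merge_gap_bp))
}

#' Pair-wise comparison analysis for multiple pool-seq (PCAMP)
#'
#' Runs the full multi-pool bulked-segregant scan: for every unordered pool
#' pair, SNP and InDel sites are analysed separately (ED, power correction,
#' distance-weighted fit, genome-wide median + 3 SD threshold, candidate
#' intervals) and the comparison's final regions are the SNP-InDel
#' intersection. A summary counts, for each genomic region, in how many
#' comparisons it recurs; regions recurring in at least `min_recurrence`
#' comparisons are flagged as final candidates.
#'
#' @param table A `pool_site_table` with at least two pools.
#' @param power,window_bp,merge_gap_bp,method See [ed_scan()].
#' @param min_recurrence Comparisons a region must recur in to be flagged
#'   (default 2).
#' @return Object of class `pcamp_result`: list with `comparisons` (named
#'   list of per-pair results, each holding the two per-class scans and the
#'   intersected `final` intervals) and `summary` (data frame of merged
#'   regions with recurrence counts and a `candidate` flag).
#' @export
run_pcamp <- function(table, power = 5L, window_bp = 1e6, merge_gap_bp = 1e5,
                      min_recurrence = 2L, method = c("tricube", "median")) {
  method <- match.arg(method)
  stopifnot(inherits(table, "pool_site_table"))
  pools <- table$pools
  if (length(pools) < 2L) stop("run_pcamp: need at least 2 pools")
  pairs <- utils::combn(pools, 2L, simplify = FALSE)
  comparisons <- list()
  for (pr in pairs) {
    id <- paste(pr, collapse = "-")
    usable <- vapply(pr, function(p) {
      any(rowSums(table$depths[, pool_index(table, p), , drop = TRUE]) > 0)
    }, logical(1))
    if (!all(usable)) {
      warning("run_pcamp: pool with zero usable sites, skipping comparison ", id)
      next
    }
    snp <- ed_scan(table, pr[1], pr[2], "SNP", power, window_bp, merge_gap_bp, method)
    indel <- ed_scan(table, pr[1], pr[2], "InDel", power, window_bp, merge_gap_bp, method)
    final <- intersect_intervals(snp$intervals, indel$intervals)
    final$comparison <- rep(id, nrow(final))
    comparisons[[id]] <- list(pools = pr, snp = snp, indel = indel, final = final)
  }
  all_final <- do.call(rbind, c(lapply(comparisons, `[[`, "final"),
                                make.row.names = FALSE))
  summary <- recurrence_summary(all_final, min_recurrence)
  structure(list(comparisons = comparisons, summary = summary,
                 params = list(power = power, window_bp = window_bp,
                               merge_gap_bp = merge_gap_bp,
                               min_recurrence = min_recurrence)),
            class = "pcamp_result")
}

# Merge every comparison's final intervals and count, per merged region, the
# number of distinct comparisons overlapping it.
recurrence_summary <- function(all_final, min_recurrence) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      recurrence = integer(), comparisons = character(),
                      candidate = logical())
  if (is.null(all_final) || !nrow(all_final)) return(empty)
  res <- list()
  for (chr in unique(all_final$chrom)) {
    sub <- all_final[all_final$chrom == chr, , drop = FALSE]
    merged <- IRanges::reduce(IRanges::IRanges(sub$start, sub$end))
    hits <- IRanges::findOverlaps(merged, IRanges::IRanges(sub$start, sub$end))
    rec <- vapply(seq_along(merged), function(i) {
      length(unique(sub$comparison[S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]]))
    }, integer(1))
    cmp <- vapply(seq_along(merged), function(i) {
      paste(sort(unique(sub$comparison[S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]])),
            collapse = ",")
    }, character(1))
    res[[chr]] <- data.frame(chrom = chr, start = IRanges::start(merged),
                             end = IRanges::end(merged), recurrence = rec,
                             comparisons = cmp)
  }
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$candidate <- out$recurrence >= min_recurrence
  rownames(out) <- NULL
  out
}

#' @export
print.pcamp_result <- function(x, ...) {
  cat("PCAMP multi-pool ED scan\n")
  cat("  comparisons:", length(x$comparisons), "\n")
  cat("  merged regions:", nrow(x$summary),
      "| final candidates (recurrence >=", x$params$min_recurrence, "):",
      sum(x$summary$candidate), "\n")
  invisible(x)
}
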