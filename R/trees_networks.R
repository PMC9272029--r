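#' Nei's standard genetic distance between two populations
#'
#' D = -ln( Jxy / sqrt(Jx * Jy) ), where Jxy is the mean over loci of
#' sum(x_i * y_i), and Jx, Jy the mean over loci of sum(x_i^2), sum(y_i^2).
#' Allele vectors at each locus are aligned on the union of the two
#' populations' allele alphabets. When the populations share no alleles at
#' any locus (Jxy = 0) the distance is `Inf`.
#'
#' @param freqs_x,freqs_y Lists (one element per locus) of named allele
#'   frequency vectors.
#' @return Nei's standard distance (>= 0, possibly `Inf`).
#' @export
nei_standard_distance <- function(freqs_x, freqs_y) {
  stopifnot(length(freqs_x) == length(freqs_y), length(freqs_x) >= 1)
  jxy <- jx <- jy <- numeric(length(freqs_x))
  for (l in seq_along(freqs_x)) {
    alleles <- union(names(freqs_x[[l]]), names(freqs_y[[l]]))
    x <- setNames(rep(0, length(alleles)), alleles)
    y <- x
    x[names(freqs_x[[l]])] <- freqs_x[[l]]
    y[names(freqs_y[[l]])] <- freqs_y[[l]]
    jxy[l] <- sum(x * y)
    jx[l] <- sum(x^2)
    jy[l] <- sum(y^2)
  }
  J <- mean(jxy) / sqrt(mean(jx) * mean(jy))
  if (J <= 0) return(Inf)
  -log(J)
}

#' Pairwise Nei distance matrix between groups of individuals
#'
#' Splits a marker genotype matrix by group labels, computes per-group,
#' per-locus allele frequencies and returns the symmetric matrix of Nei's
#' standard distances.
#'
#' @param matrix A `marker_genotype_matrix`.
#' @param groups Character/factor vector of group labels, one per
#'   individual. With `groups = NULL`, every individual is its own group
#'   (individual-level distances from single-genotype "frequencies").
#' @return Symmetric matrix with zero diagonal, labelled by group.
#' @export
marker_nei_distance <- function(matrix, groups = NULL) {
  stopifnot(inherits(matrix, "marker_genotype_matrix"))
  if (is.null(groups)) groups <- matrix$individuals
  stopifnot(length(groups) == length(matrix$individuals))
  groups <- as.character(groups)
  labs <- sort(unique(groups))
  freqs <- lapply(labs, function(g) {
    idx <- which(groups == g)
    lapply(matrix$loci, function(loc) {
      a <- c(matrix$allele1[idx, loc], matrix$allele2[idx, loc])
      a <- a[!is.na(a)]
      if (!length(a)) return(setNames(numeric(0), character(0)))
      tab <- table(a)
      setNames(as.numeric(tab) / sum(tab), names(tab))
    })
  })
  d <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (i in seq_along(labs)) for (j in seq_len(i - 1L)) {
    d[i, j] <- d[j, i] <- nei_standard_distance(freqs[[i]], freqs[[j]])
  }
  d
}

#' UPGMA dendrogram from a distance matrix
#'
#' Unweighted pair group method with arithmetic mean: repeatedly merges the
#' closest pair of clusters; the distance from a merged cluster to any other
#' is the size-weighted arithmetic mean of its members' distances, and each
#' merge node sits at height d/2, so the output is ultrametric. Ties are
#' broken by merging the pair whose (lexicographically smallest) leaf labels
#' sort first, making the dendrogram deterministic.
#'
#' @param d Symmetric numeric matrix with labels, zero diagonal, finite
#'   entries (prune infinite-distance taxa first).
#' @return An ultrametric rooted tree of class `phylo`.
#' @export
upgma <- function(d) {
  d <- as.matrix(d)
  labs <- rownames(d)
  n <- nrow(d)
  stopifnot(n >= 2, !is.null(labs), isTRUE(all.equal(d, t(d))))
  if (any(!is.finite(d))) {
    stop("upgma: infinite distances present; prune the affected taxa first")
  }
  size <- rep(1L, n)
  height <- rep(0, n)
  rep_lab <- labs            # lexicographically smallest leaf per cluster
  merge <- matrix(0L, n - 1L, 2L)
  merge_height <- numeric(n - 1L)
  id <- -seq_len(n)          # hclust convention: negatives = leaves
  active <- seq_len(n)
  for (step in seq_len(n - 1L)) {
    best <- NULL
    for (ii in seq_along(active)) for (jj in seq_len(ii - 1L)) {
      i <- active[ii]; j <- active[jj]
      key <- sort(c(rep_lab[i], rep_lab[j]))
      cand <- list(d = d[i, j], key = key, i = i, j = j)
      if (is.null(best) || cand$d < best$d ||
          (cand$d == best$d && (key[1] < best$key[1] ||
             (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- cand
      }
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    merge[step, ] <- sort(c(id[i], id[j]))
    merge_height[step] <- best$d  # as.phylo.hclust halves -> node height d/2
    # size-weighted average distance to the merged cluster
    for (k in setdiff(active, c(i, j))) {
      d[i, k] <- d[k, i] <- (size[i] * d[i, k] + size[j] * d[j, k]) /
        (size[i] + size[j])
    }
    size[i] <- size[i] + size[j]
    rep_lab[i] <- min(rep_lab[i], rep_lab[j])
    height[i] <- h
    id[i] <- step
    active <- setdiff(active, j)
  }
  hc <- structure(list(merge = merge, height = merge_height,
                       order = upgma_order(merge, n), labels = labs,
                       method = "upgma", call = match.call(),
                       dist.method = "user"),
                  class = "hclust")
  ape::as.phylo(hc)
}

# leaf ordering for the hclust object (left-to-right traversal)
upgma_order <- function(merge, n) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(nrow(merge))
}

#' Collapse aligned sequences into haplotype nodes
#'
#' Alignment columns containing any gap ("-") or ambiguity character
#' (anything outside A/C/G/T) in any sequence are masked network-wide;
#' sequences identical over the remaining columns collapse to one haplotype
#' node carrying the total count and per-group composition.
#'
#' @param seqs Named character vector of equal-length aligned sequences,
#'   one per sample.
#' @param groups Optional vector of group labels per sample.
#' @param mask_ambiguous Mask gap/ambiguity columns (default TRUE).
#' @return Object of class `haplotype_nodes`: data frame with columns
#'   haplotype (H1, H2, ... in order of first appearance), sequence (masked),
#'   count, plus one count column per group; attribute `members` lists the
#'   sample names per node.
#' @export
collapse_haplotypes <- function(seqs, groups = NULL, mask_ambiguous = TRUE) {
  stopifnot(length(seqs) >= 1, length(unique(nchar(seqs))) == 1L)
  if (is.null(groups)) groups <- rep("all", length(seqs))
  stopifnot(length(groups) == length(seqs))
  mat <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  if (mask_ambiguous) {
    ok <- apply(mat, 2, function(col) all(col %in% c("A", "C", "G", "T")))
    mat <- mat[, ok, drop = FALSE]
  }
  key <- apply(mat, 1, paste, collapse = "")
  uniq <- unique(key)
  nodes <- data.frame(haplotype = paste0("H", seq_along(uniq)), sequence = uniq,
                      count = as.integer(table(key)[uniq]))
  for (g in sort(unique(as.character(groups)))) {
    nodes[[g]] <- vapply(uniq, function(u) sum(key == u & groups == g), integer(1))
  }
  members <- lapply(uniq, function(u) names(seqs)[key == u])
  names(members) <- nodes$haplotype
  attr(nodes, "members") <- members
  class(nodes) <- c("haplotype_nodes", "data.frame")
  nodes
}

hamming_matrix <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  n <- nrow(mat)
  d <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    d[i, j] <- d[j, i] <- sum(mat[i, ] != mat[j, ])
  }
  d
}

#' Minimum-spanning haplotype network
#'
#' Builds the network over pairwise Hamming distances between haplotype
#' nodes. With `epsilon = 0` this is a minimum spanning tree (Kruskal's
#' algorithm, edges processed in ascending (weight, label, label) order so
#' ties resolve deterministically; a tied edge enters only when needed for
#' connectivity). With `epsilon > 0`, alternative edges are retained in the
#' minimum-spanning-network manner: an edge (u, v) is kept whenever its
#' weight is at most epsilon above the distance class at which u and v first
#' became connected.
#'
#' @param nodes A `haplotype_nodes` object (or data frame with columns
#'   haplotype, sequence).
#' @param epsilon Non-negative integer tolerance (default 0 = pure MST).
#' @return Object of class `haplotype_network`: list with `nodes` and
#'   `edges` (data frame from, to, distance) plus `total_weight` of the MST.
#' @export
minimum_spanning_network <- function(nodes, epsilon = 0L) {
  stopifnot(nrow(nodes) >= 1, epsilon >= 0)
  labs <- nodes$haplotype
  n <- length(labs)
  if (n == 1L) {
    return(structure(list(nodes = nodes,
                          edges = data.frame(from = character(), to = character(),
                                             distance = integer()),
                          total_weight = 0L),
                     class = "haplotype_network"))
  }
  d <- hamming_matrix(nodes$sequence)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ord <- order(d[pairs], labs[pairs[, 1]], labs[pairs[, 2]])
  pairs <- pairs[ord, , drop = FALSE]
  w <- d[pairs]
  comp <- seq_len(n)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  mst_edges <- integer(0)
  connect_level <- matrix(NA_real_, n, n)  # distance class joining u,v
  for (e in seq_len(nrow(pairs))) {
    i <- pairs[e, 1]; j <- pairs[e, 2]
    ri <- find(i); rj <- find(j)
    if (ri != rj) {
      comp[ri] <- rj
      mst_edges <- c(mst_edges, e)
    }
  }
  # recompute connection levels by replaying edge classes in ascending order
  comp <- seq_len(n)
  for (cls in sort(unique(w))) {
    in_cls <- which(w == cls)
    roots_before <- vapply(seq_len(n), function(k) find(k), integer(1))
    for (e in in_cls) {
      ri <- find(pairs[e, 1]); rj <- find(pairs[e, 2])
      if (ri != rj) comp[ri] <- rj
    }
    for (u in seq_len(n - 1L)) for (v in (u + 1L):n) {
      if (is.na(connect_level[u, v]) && roots_before[u] != roots_before[v] &&
          find(u) == find(v)) {
        connect_level[u, v] <- cls
      }
    }
  }
  keep <- mst_edges
  if (epsilon > 0) {
    extra <- which(vapply(seq_len(nrow(pairs)), function(e) {
      u <- min(pairs[e, ]); v <- max(pairs[e, ])
      !is.na(connect_level[u, v]) && w[e] <= connect_level[u, v] + epsilon
    }, logical(1)))
    keep <- sort(union(mst_edges, extra))
  }
  edges <- data.frame(from = labs[pmin(pairs[keep, 1], pairs[keep, 2])],
                      to = labs[pmax(pairs[keep, 1], pairs[keep, 2])],
                      distance = w[keep])
  edges <- edges[order(edges$distance, edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 total_weight = sum(w[mst_edges])),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("haplotype_network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges; MST weight", x$total_weight, "\n")
  invisible(x)
}

#' Write a haplotype network as node and edge tables
#'
#' @param network A `haplotype_network`.
#' @param nodes_path,edges_path Output TSV paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_network_tables <- function(network, nodes_path, edges_path) {
  utils::write.table(as.data.frame(network$nodes), nodes_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(network$edges, edges_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(nodes = nodes_path, edges = edges_path))
}
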