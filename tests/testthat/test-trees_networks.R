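test_that("Nei's standard distance matches hand arithmetic and edge cases", {
  expect_equal(nei_standard_distance(list(c(a = 1, b = 0)),
                                     list(c(a = 0.5, b = 0.5))),
               -log(0.5 / sqrt(0.5)))
  same <- list(c(a = 0.3, b = 0.7), c(x = 1))
  expect_equal(nei_standard_distance(same, same), 0)
  expect_equal(nei_standard_distance(list(c(a = 1)), list(c(b = 1))), Inf)
  # invariant to allele relabeling
  x <- list(c(a = 0.2, b = 0.8)); y <- list(c(a = 0.6, b = 0.4))
  xr <- list(c(z = 0.2, w = 0.8)); yr <- list(c(z = 0.6, w = 0.4))
  expect_equal(nei_standard_distance(x, y), nei_standard_distance(xr, yr))
})

test_that("group-level Nei distances are symmetric with zero diagonal", {
  m <- simulate_marker_population(marker_sim_config(n_individuals = 60,
                                                    n_loci = 12, n_subpops = 3,
                                                    divergence = 0.15, seed = 4))
  d <- marker_nei_distance(m, attr(m, "subpop"))
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_true(all(d >= 0))
})

test_that("UPGMA matches hand computation and breaks ties lexicographically", {
  d2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- upgma(d2)
  expect_equal(unname(t2$edge.length), c(0.5, 0.5))
  labs <- c("A", "B", "C")
  d3 <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, 3, dimnames = list(labs, labs))
  t3 <- upgma(d3)
  expect_equal(ape::write.tree(t3), "(C:3,(B:1,A:1):2);")
  # tie: d(A,B) = d(C,D) = 1; the A-B pair must merge first
  labs4 <- c("D", "C", "B", "A")
  d4 <- matrix(4, 4, 4, dimnames = list(labs4, labs4))
  diag(d4) <- 0
  d4["A", "B"] <- d4["B", "A"] <- 1
  d4["C", "D"] <- d4["D", "C"] <- 1
  t4 <- upgma(d4)
  first_pair <- sort(ape::extract.clade(t4, ape::getMRCA(t4, c("A", "B")))$tip.label)
  expect_equal(first_pair, c("A", "B"))
  expect_error(upgma(matrix(c(0, Inf, Inf, 0), 2, 2,
                            dimnames = list(c("A", "B"), c("A", "B")))),
               "prune")
})

test_that("UPGMA is ultrametric and agrees with average-linkage clustering", {
  set.seed(12)
  for (i in 1:5) {
    # random ultrametric matrix from a random tree's cophenetic distances
    tr <- ape::rcoal(6)
    tr$tip.label <- paste0("t", 1:6)
    d <- ape::cophenetic.phylo(tr)
    d <- d[order(rownames(d)), order(colnames(d))]
    fit <- upgma(d)
    # root-to-leaf heights all equal
    depths <- ape::node.depth.edgelength(fit)[seq_along(fit$tip.label)]
    expect_equal(max(depths) - min(depths), 0, tolerance = 1e-10)
    # on an already-ultrametric matrix UPGMA recovers the generating topology
    expect_equal(ape::dist.topo(ape::unroot(fit), ape::unroot(tr)), 0,
                 ignore_attr = TRUE)
    # and its cophenetic distances reproduce the input
    expect_equal(ape::cophenetic.phylo(fit)[rownames(d), colnames(d)], d,
                 tolerance = 1e-10)
    # cross-check merge heights against stats::hclust average linkage
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    ours <- sort(ape::branching.times(fit))
    expect_equal(unname(sort(hc$height / 2)), unname(ours), tolerance = 1e-10)
  }
})

test_that("haplotype collapsing conserves samples and masks ambiguity", {
  seqs <- setNames(rep("ACGT", 5), paste0("s", 1:5))
  nodes <- collapse_haplotypes(seqs)
  expect_equal(nrow(nodes), 1L)
  expect_equal(nodes$count, 5L)
  two <- c(s1 = "ACGT", s2 = "ACGA")
  expect_equal(nrow(collapse_haplotypes(two)), 2L)
  # N at the only differing column -> merged under masking
  amb <- c(s1 = "ACGT", s2 = "ACGN")
  masked <- collapse_haplotypes(amb)
  expect_equal(nrow(masked), 1L)
  expect_equal(masked$count, 2L)
  expect_equal(nrow(collapse_haplotypes(amb, mask_ambiguous = FALSE)), 2L)
  # group composition columns
  g <- collapse_haplotypes(c(s1 = "AC", s2 = "AC", s3 = "AG"),
                           groups = c("x", "y", "y"))
  expect_equal(sum(g$count), 3L)
  expect_equal(g$x, c(1L, 0L))
  expect_equal(g$y, c(1L, 1L))
})

test_that("minimum spanning network recovers simulated genealogies", {
  chain <- simulate_haplotypes(3, 50, 1, topology = "chain", seed = 21)
  nodes <- collapse_haplotypes(chain$samples)
  net <- minimum_spanning_network(nodes)
  expect_equal(net$edges$distance, c(1L, 1L))
  expect_equal(net$total_weight, 2L)
  expect_equal(sort(paste(net$edges$from, net$edges$to)),
               sort(paste(chain$truth_edges$from, chain$truth_edges$to)))

  star <- simulate_haplotypes(4, 50, 2, topology = "star", seed = 22)
  net2 <- minimum_spanning_network(collapse_haplotypes(star$samples))
  expect_equal(nrow(net2$edges), 3L)
  expect_true(all(net2$edges$from == "H1"))
  expect_true(all(net2$edges$distance == 2L))

  single <- minimum_spanning_network(collapse_haplotypes(c(a = "ACGT")))
  expect_equal(nrow(single$edges), 0L)
})

test_that("MST weight equals the exhaustive minimum over spanning trees", {
  set.seed(33)
  for (i in 1:5) {
    n <- sample(4:7, 1)
    sim <- simulate_haplotypes(n, 40, sample(1:2, 1),
                               topology = sample(c("chain", "star"), 1),
                               seed = 100 + i)
    # perturb: draw extra random sequences so distances are irregular
    nodes <- collapse_haplotypes(sim$haplotypes)
    net <- minimum_spanning_network(nodes)
    d <- matrix(0L, n, n)
    m <- do.call(rbind, strsplit(nodes$sequence, ""))
    for (a in seq_len(n)) for (b in seq_len(n)) d[a, b] <- sum(m[a, ] != m[b, ])
    expect_equal(net$total_weight, brute_mst_weight(d))
    # spanning and connected: n - 1 edges touching every node
    expect_equal(nrow(net$edges), n - 1L)
    expect_setequal(unique(c(net$edges$from, net$edges$to)), nodes$haplotype)
  }
})

test_that("epsilon > 0 adds near-minimal alternative edges only", {
  # square: A-B=1, B-C=1, C-D=1, D-A=1, diagonals 2
  seqs <- c(A = "AAAA", B = "AAAC", C = "AACC", D = "AAAG")
  nodes <- collapse_haplotypes(seqs)
  mst <- minimum_spanning_network(nodes, epsilon = 0)
  expect_equal(nrow(mst$edges), 3L)
  msn <- minimum_spanning_network(nodes, epsilon = 1)
  expect_gte(nrow(msn$edges), nrow(mst$edges))
  expect_true(all(mst$edges$distance %in% msn$edges$distance))
  expect_equal(msn$total_weight, mst$total_weight)  # MST weight unchanged
})
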