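#' Configuration for the pool-seq simulator
#'
#' Defaults emulate a four-bulk field design: four phenotype pools of 30
#' individuals each, ~48.5x mean sequencing depth, with one planted causal
#' region in which the allele frequencies of the two contrasted pools are
#' displaced in opposite directions by `effect`.
#'
#' @param n_pools Number of phenotype bulks (default 4).
#' @param individuals_per_pool Diploid individuals per bulk (default 30).
#' @param n_sites Number of variant sites (default 5000).
#' @param chrom_lengths Named vector of chromosome lengths in bp
#'   (default c(chr1 = 25e6)).
#' @param causal_regions Data frame with columns chrom, start, end, effect
#'   (allele-frequency displacement in [0, 1] between the contrasted pools).
#'   Default: one 1-Mb region, effect 0.8.
#' @param contrast Indices of the two pools displaced in the causal regions
#'   (default the first and the last pool).
#' @param mean_depth Mean per-pool sequencing depth (default 48.5).
#' @param indel_fraction Fraction of sites flagged InDel (default 0.25).
#' @param beta_shape Shape of the symmetric Beta site-frequency spectrum
#'   (default 0.5).
#' @param seed Integer seed.
#' @return Object of class `pool_sim_config`.
#' @export
pool_sim_config <- function(n_pools = 4L, individuals_per_pool = 30L,
                            n_sites = 5000L,
                            chrom_lengths = c(chr1 = 25e6),
                            causal_regions = data.frame(
                              chrom = "chr1", start = 12e6, end = 13e6,
                              effect = 0.8),
                            contrast = c(1L, n_pools),
                            mean_depth = 48.5, indel_fraction = 0.25,
                            beta_shape = 0.5, seed = 1L) {
  stopifnot(n_pools >= 2, individuals_per_pool >= 1, n_sites >= 1,
            mean_depth > 0, indel_fraction >= 0, indel_fraction <= 1,
            length(contrast) == 2L, all(contrast %in% seq_len(n_pools)))
  if (nrow(causal_regions)) {
    stopifnot(all(causal_regions$effect >= 0), all(causal_regions$effect <= 1))
    known <- causal_regions$chrom %in% names(chrom_lengths)
    if (!all(known)) stop("pool_sim_config: causal region on unknown chromosome")
    if (any(causal_regions$start < 1 |
            causal_regions$end > chrom_lengths[causal_regions$chrom])) {
      stop("pool_sim_config: causal region outside chromosome bounds")
    }
  }
  structure(list(n_pools = n_pools, individuals_per_pool = individuals_per_pool,
                 n_sites = n_sites, chrom_lengths = chrom_lengths,
                 causal_regions = causal_regions, contrast = as.integer(contrast),
                 mean_depth = mean_depth, indel_fraction = indel_fraction,
                 beta_shape = beta_shape, seed = as.integer(seed)),
            class = "pool_sim_config")
}

#' Simulate pooled sequencing of phenotype bulks
#'
#' Each site gets a baseline population allele frequency drawn from a
#' symmetric Beta spectrum. Inside a causal region, the two contrasted
#' pools' target frequencies are displaced by +/- effect/2 (clipped to
#' [0, 1]). Each pool's realized frequency is a binomial draw of its
#' 2 x individuals_per_pool allele copies; read depth is Poisson around
#' `mean_depth` and alt-supporting read counts are binomial in that
#' frequency. SNP sites place REF/ALT counts on two random distinct base
#' slots, InDel sites on slots 1 and 2. Deterministic given the config seed.
#'
#' @param config A [pool_sim_config()].
#' @return List with `table` (a [pool_site_table()] with pools R01, R02,
#'   ...) and `truth` (the causal-regions data frame).
#' @export
simulate_pool_seq <- function(config) {
  stopifnot(inherits(config, "pool_sim_config"))
  set.seed(config$seed)
  n_chrom <- length(config$chrom_lengths)
  prop <- config$chrom_lengths / sum(config$chrom_lengths)
  per_chrom <- diff(round(c(0, cumsum(prop * config$n_sites))))
  chrom <- rep(names(config$chrom_lengths), per_chrom)
  pos <- unlist(lapply(seq_len(n_chrom), function(i) {
    sort(sample.int(config$chrom_lengths[i], per_chrom[i]))
  }), use.names = FALSE)
  n <- length(pos)
  class <- ifelse(stats::runif(n) < config$indel_fraction, "InDel", "SNP")
  p0 <- stats::rbeta(n, config$beta_shape, config$beta_shape)
  in_causal <- rep(FALSE, n)
  effect <- rep(0, n)
  for (r in seq_len(nrow(config$causal_regions))) {
    cr <- config$causal_regions[r, ]
    hit <- chrom == cr$chrom & pos >= cr$start & pos <= cr$end
    in_causal <- in_causal | hit
    effect[hit] <- pmax(effect[hit], cr$effect)
  }
  pools <- sprintf("R%02d", seq_len(config$n_pools))
  two_n <- 2L * config$individuals_per_pool
  depths <- array(0, dim = c(n, config$n_pools, 4L))
  # per-site REF/ALT base slots
  slots <- t(vapply(seq_len(n), function(i) {
    if (class[i] == "SNP") sample.int(4L, 2L) else c(1L, 2L)
  }, integer(2)))
  for (j in seq_len(config$n_pools)) {
    target <- p0
    if (j == config$contrast[1]) target <- pmin(1, p0 + effect / 2)
    if (j == config$contrast[2]) target <- pmax(0, p0 - effect / 2)
    pool_freq <- stats::rbinom(n, two_n, target) / two_n
    depth <- stats::rpois(n, config$mean_depth)
    alt <- stats::rbinom(n, depth, pool_freq)
    for (i in seq_len(n)) {
      depths[i, j, slots[i, 2]] <- depths[i, j, slots[i, 2]] + alt[i]
      depths[i, j, slots[i, 1]] <- depths[i, j, slots[i, 1]] + depth[i] - alt[i]
    }
  }
  list(table = pool_site_table(data.frame(chrom = chrom, pos = pos, class = class),
                               depths, pools),
       truth = config$causal_regions)
}

#' Configuration for the structured selfing marker-population simulator
#'
#' Defaults mirror a marker survey of a large selfing-prone wild population:
#' 184 individuals, 40 co-dominant loci, 5 subpopulations, with partial
#' selfing depressing observed heterozygosity via the equilibrium inbreeding
#' coefficient F = s / (2 - s).
#'
#' @param n_individuals Number of individuals (default 184).
#' @param n_loci Number of loci (default 40).
#' @param n_subpops Number of subpopulations (default 5).
#' @param selfing_rate Selfing rate s in [0, 1] (default 0.5).
#' @param allele_counts Integer vector (recycled over loci) of allele numbers
#'   per locus (default c(2, 2, 3)).
#' @param divergence Subpopulation divergence parameter in [0, 1): Fst-like;
#'   0 means identical subpopulation frequencies (default 0.1).
#' @param seed Integer seed.
#' @return Object of class `marker_sim_config`.
#' @export
marker_sim_config <- function(n_individuals = 184L, n_loci = 40L,
                              n_subpops = 5L, selfing_rate = 0.5,
                              allele_counts = c(2L, 2L, 3L),
                              divergence = 0.1, seed = 1L) {
  stopifnot(n_individuals >= 1, n_loci >= 1, n_subpops >= 1,
            selfing_rate >= 0, selfing_rate <= 1,
            all(allele_counts >= 2), divergence >= 0, divergence < 1)
  structure(list(n_individuals = n_individuals, n_loci = n_loci,
                 n_subpops = n_subpops, selfing_rate = selfing_rate,
                 allele_counts = rep_len(allele_counts, n_loci),
                 divergence = divergence, seed = as.integer(seed)),
            class = "marker_sim_config")
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Simulate a structured, partially selfing marker population
#'
#' Global allele frequencies per locus are drawn from a flat Dirichlet;
#' subpopulation frequencies from a Dirichlet centred on the global ones
#' with concentration (1 - divergence) / divergence (Balding-Nichols), so
#' `divergence` acts as an Fst-like parameter. Genotypes are drawn with the
#' partial-selfing equilibrium inbreeding coefficient F = s / (2 - s): with
#' probability F an individual is autozygous (one allele drawn and
#' duplicated), otherwise the two alleles are drawn independently.
#'
#' @param config A [marker_sim_config()].
#' @return A [marker_genotype_matrix()] with attribute `subpop` giving each
#'   individual's subpopulation.
#' @export
simulate_marker_population <- function(config) {
  stopifnot(inherits(config, "marker_sim_config"))
  set.seed(config$seed)
  f_inb <- config$selfing_rate / (2 - config$selfing_rate)
  subpop <- rep_len(seq_len(config$n_subpops), config$n_individuals)
  loci <- sprintf("L%02d", seq_len(config$n_loci))
  geno <- matrix(NA_character_, config$n_individuals, config$n_loci)
  for (l in seq_len(config$n_loci)) {
    k <- config$allele_counts[l]
    global <- rdirichlet1(rep(1, k))
    sub_freq <- lapply(seq_len(config$n_subpops), function(s) {
      if (config$divergence == 0) return(global)
      rdirichlet1(global * (1 - config$divergence) / config$divergence)
    })
    for (i in seq_len(config$n_individuals)) {
      p <- sub_freq[[subpop[i]]]
      if (stats::runif(1) < f_inb) {
        a <- sample.int(k, 1L, prob = p)
        pair <- c(a, a)
      } else {
        pair <- sample.int(k, 2L, replace = TRUE, prob = p)
      }
      geno[i, l] <- paste(sort(pair), collapse = "/")
    }
  }
  out <- marker_genotype_matrix(sprintf("ind%03d", seq_len(config$n_individuals)),
                                loci, geno)
  attr(out, "subpop") <- subpop
  out
}

#' Simulate haplotypes with a known genealogy
#'
#' Generates a random root sequence and derives the remaining haplotypes
#' along a chain (each child differs from its parent by exactly
#' `mutation_steps` substitutions) or a star (each leaf differs from the
#' centre haplotype by `mutation_steps`). Mutated positions are distinct
#' across the whole genealogy, so pairwise Hamming distances are additive
#' along the true edges.
#'
#' @param n_haplotypes Number of distinct haplotypes (>= 1).
#' @param length Alignment length in bp.
#' @param mutation_steps Substitutions per edge (default 1).
#' @param counts Integer vector of per-haplotype sample counts (default 1).
#' @param topology "chain" or "star".
#' @param seed Integer seed.
#' @return List with `haplotypes` (named character vector H1, H2, ...),
#'   `counts`, `truth_edges` (data frame from, to, steps), and `samples`
#'   (per-sample sequences, haplotypes replicated by count).
#' @export
simulate_haplotypes <- function(n_haplotypes, length, mutation_steps = 1L,
                                counts = NULL, topology = c("chain", "star"),
                                seed = 1L) {
  topology <- match.arg(topology)
  stopifnot(n_haplotypes >= 1, mutation_steps >= 1,
            length >= (n_haplotypes - 1L) * mutation_steps)
  if (is.null(counts)) counts <- rep(1L, n_haplotypes)
  stopifnot(length(counts) == n_haplotypes, all(counts >= 1))
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  root <- sample(bases, length, replace = TRUE)
  haps <- list(root)
  free <- sample.int(length)   # positions never mutated twice
  used <- 0L
  edges <- NULL
  for (h in seq_len(n_haplotypes - 1L)) {
    parent_idx <- if (topology == "chain") h else 1L
    child <- haps[[parent_idx]]
    sites <- free[used + seq_len(mutation_steps)]
    used <- used + mutation_steps
    for (s in sites) {
      child[s] <- sample(setdiff(bases, child[s]), 1L)
    }
    haps[[h + 1L]] <- child
    edges <- rbind(edges, data.frame(from = paste0("H", parent_idx),
                                     to = paste0("H", h + 1L),
                                     steps = mutation_steps))
  }
  seqs <- vapply(haps, paste, character(1), collapse = "")
  names(seqs) <- paste0("H", seq_len(n_haplotypes))
  samples <- rep(seqs, counts)
  names(samples) <- unlist(lapply(seq_len(n_haplotypes), function(i) {
    sprintf("H%d_s%d", i, seq_len(counts[i]))
  }))
  list(haplotypes = seqs, counts = counts,
       truth_edges = if (is.null(edges)) {
         data.frame(from = character(), to = character(), steps = integer())
       } else edges,
       samples = samples)
}

#' Simulate a four-taxon allele-frequency panel for ABBA-BABA
#'
#' Ancestral frequencies are drawn from a Beta(0.5, 0.5) spectrum; each
#' population's frequency drifts around the ancestral one via a
#' Balding-Nichols Beta draw with Fst-like parameter `drift`. With
#' `gene_flow = 0`, P1 and P2 are exchangeable so E[ABBA] = E[BABA]; with
#' `gene_flow = m > 0`, P2's frequency is pulled towards P3 by the mixing
#' fraction m, inflating ABBA.
#'
#' @param n_sites Number of biallelic sites (>= 1).
#' @param gene_flow Mixing fraction from P3 into P2, in [0, 1] (default 0).
#' @param drift Fst-like drift parameter in (0, 1) (default 0.2).
#' @param spacing_bp Distance between adjacent sites in bp (default 1000),
#'   which sets how many jackknife blocks a given block size yields.
#' @param seed Integer seed.
#' @return Data frame with columns chrom, pos, p1, p2, p3, p4.
#' @export
simulate_dstat_panel <- function(n_sites, gene_flow = 0, drift = 0.2,
                                 spacing_bp = 1000L, seed = 1L) {
  if (n_sites < 1) stop("simulate_dstat_panel: n_sites must be >= 1")
  stopifnot(gene_flow >= 0, gene_flow <= 1, drift > 0, drift < 1)
  set.seed(seed)
  p_anc <- stats::rbeta(n_sites, 0.5, 0.5)
  conc <- (1 - drift) / drift
  drifted <- function(p) stats::rbeta(n_sites, p * conc, (1 - p) * conc)
  p1 <- drifted(p_anc)
  p2 <- drifted(p_anc)
  p3 <- drifted(p_anc)
  p4 <- drifted(p_anc)
  p2 <- (1 - gene_flow) * p2 + gene_flow * p3
  data.frame(chrom = "chr1", pos = seq_len(n_sites) * spacing_bp,
             p1 = p1, p2 = p2, p3 = p3, p4 = p4)
}

#' Write a simulated pool table as a minimal VCF
#'
#' Serializes a `pool_site_table` to a VCF with per-pool AD fields so the
#' reader path can be exercised end-to-end. SNP sites use the two occupied
#' base slots as REF/ALT; InDel sites write REF "A" / ALT "AT" to mark the
#' class by allele length.
#'
#' @param table A `pool_site_table`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_pool_vcf <- function(table, path) {
  stopifnot(inherits(table, "pool_site_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", table$pools), collapse = "\t")), con)
  for (i in seq_len(nrow(table$sites))) {
    d <- matrix(table$depths[i, , ], nrow = length(table$pools))
    occ <- which(colSums(d) > 0)
    if (length(occ) < 2L) occ <- sort(unique(c(occ, setdiff(1:2, occ))))[1:2]
    occ <- occ[1:2]
    if (table$sites$class[i] == "SNP") {
      ref <- BASES[occ[1]]; alt <- BASES[occ[2]]
    } else {
      ref <- "A"; alt <- "AT"
    }
    ad <- vapply(seq_along(table$pools), function(j) {
      paste(d[j, occ[1]], d[j, occ[2]], sep = ",")
    }, character(1))
    writeLines(paste(c(table$sites$chrom[i], table$sites$pos[i], ".", ref, alt,
                       ".", "PASS", ".", "GT:AD",
                       paste("0/1", ad, sep = ":")), collapse = "\t"), con)
  }
  invisible(path)
}
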