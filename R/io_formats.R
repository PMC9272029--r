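#' Read a co-dominant marker genotype table
#'
#' Expects a delimited text file with a header row of locus names, an `id`
#' column of individual ids (first column), and genotype cells written as
#' "a/b" allele codes; "NA", "./." or empty cells are missing. Locus
#' chromosome labels may be supplied separately. Duplicated individual ids
#' are kept (field designs resample ramets) with a warning.
#'
#' @param path Path to a TSV/CSV file.
#' @param sep Field separator (default tab).
#' @param chromosomes Optional named vector mapping locus -> chromosome.
#' @return Object of class `marker_genotype_matrix`: list with `individuals`,
#'   `loci`, `chromosomes`, and two character matrices `allele1`, `allele2`
#'   (NA where missing).
#' @export
read_marker_table <- function(path, sep = "\t", chromosomes = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(parts)
  if (length(unique(widths)) != 1L) {
    stop("read_marker_table: ragged rows (", paste(unique(widths), collapse = "/"),
         " fields)")
  }
  header <- parts[[1]]
  loci <- header[-1]
  body <- parts[-1]
  ids <- vapply(body, `[[`, character(1), 1L)
  geno <- do.call(rbind, lapply(body, function(x) x[-1]))
  marker_genotype_matrix(ids, loci, geno, chromosomes)
}

#' Construct a marker genotype matrix
#'
#' @param individuals Character vector of individual ids.
#' @param loci Character vector of locus names.
#' @param genotypes Character matrix (individuals x loci) of "a/b" cells;
#'   "NA", "./.", "" or NA mark missing.
#' @param chromosomes Optional named vector mapping locus -> chromosome.
#' @return Object of class `marker_genotype_matrix`.
#' @export
marker_genotype_matrix <- function(individuals, loci, genotypes,
                                   chromosomes = NULL) {
  genotypes <- matrix(as.character(genotypes), nrow = length(individuals),
                      ncol = length(loci), dimnames = list(individuals, loci))
  if (anyDuplicated(individuals)) {
    warning("duplicated individual id(s): ",
            paste(unique(individuals[duplicated(individuals)]), collapse = ", "),
            "; all rows kept")
  }
  missing <- is.na(genotypes) | genotypes %in% c("NA", "./.", "")
  bad <- !missing & !grepl("/", genotypes, fixed = TRUE)
  if (any(bad)) stop("marker_genotype_matrix: genotype cells must be 'a/b'")
  split2 <- function(k) {
    out <- matrix(NA_character_, nrow(genotypes), ncol(genotypes),
                  dimnames = dimnames(genotypes))
    out[!missing] <- vapply(strsplit(genotypes[!missing], "/", fixed = TRUE),
                            `[[`, character(1), k)
    out
  }
  chrom <- if (is.null(chromosomes)) setNames(rep(NA_character_, length(loci)), loci)
           else setNames(as.character(chromosomes[loci]), loci)
  structure(list(individuals = individuals, loci = loci, chromosomes = chrom,
                 allele1 = split2(1L), allele2 = split2(2L)),
            class = "marker_genotype_matrix")
}

#' @export
print.marker_genotype_matrix <- function(x, ...) {
  cat("marker_genotype_matrix:", length(x$individuals), "individuals x",
      length(x$loci), "loci;",
      sum(is.na(x$allele1)), "missing cells\n")
  invisible(x)
}

#' Write candidate intervals as a BED file
#'
#' Internal coordinates are 1-based inclusive; BED output is 0-based
#' half-open (start = start - 1, end unchanged). The name column is
#' "comparison|variant_class" when those columns are present. Output is
#' sorted by (chrom, start); exact duplicate intervals are written once with
#' a message.
#'
#' @param intervals Data frame with columns chrom, start, end and optionally
#'   comparison, variant_class, peak_ed_fitted.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_candidate_bed <- function(intervals, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# candidate intervals (BED: 0-based half-open)", con)
  if (nrow(intervals)) {
    name <- paste(
      if ("comparison" %in% names(intervals)) intervals$comparison else ".",
      if ("variant_class" %in% names(intervals)) intervals$variant_class else ".",
      sep = "|")
    bed <- data.frame(chrom = intervals$chrom,
                      start = as.integer(intervals$start) - 1L,
                      end = as.integer(intervals$end),
                      name = name)
    dup <- duplicated(bed)
    if (any(dup)) {
      message("write_candidate_bed: ", sum(dup), " duplicate interval(s) collapsed")
      bed <- bed[!dup, , drop = FALSE]
    }
    bed <- bed[order(bed$chrom, bed$start), , drop = FALSE]
    utils::write.table(bed, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a candidate BED file back to 1-based inclusive intervals
#'
#' @param path Path to a BED file written by [write_candidate_bed()].
#' @return Data frame with columns chrom, start, end, name (1-based inclusive).
#' @export
read_candidate_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(chrom = vapply(f, `[[`, character(1), 1L),
             start = as.integer(vapply(f, `[[`, character(1), 2L)) + 1L,
             end = as.integer(vapply(f, `[[`, character(1), 3L)),
             name = vapply(f, function(x) if (length(x) >= 4) x[[4]] else ".",
                           character(1)))
}

#' Read an aligned FASTA file
#'
#' Sequences intended for haplotype-network building must share a common
#' alignment length; unequal lengths raise an error.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  w <- Biostrings::width(seqs)
  if (length(seqs) > 1L && length(unique(w)) != 1L) {
    stop("read_fasta: sequences are not aligned (lengths ",
         paste(unique(w), collapse = ", "), ")")
  }
  setNames(toupper(as.character(seqs)), names(seqs))
}

#' Write aligned sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Write a tree in Newick format
#'
#' Thin wrapper over [ape::write.tree()]; round-trips with
#' [ape::read.tree()] up to branch-length formatting.
#'
#' @param tree An object of class `phylo`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}
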