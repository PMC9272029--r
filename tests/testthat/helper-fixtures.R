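# In-code fixtures: small VCF / marker-table writers used across tests.

write_toy_vcf <- function(path, records) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", attr(records, "samples")), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

vcf_line <- function(chrom, pos, ref, alt, cells) {
  paste(c(chrom, pos, ".", ref, alt, "50", "PASS", ".", "GT:AD:GQ", cells),
        collapse = "\t")
}

# The five-record toy set exercising each of the four quality criteria:
# rec1 triallelic, rec2 one sample at depth 4, rec3 one sample at GQ 20,
# rec4 missing rate exactly 0.2 (1 of 5 samples), rec5 clean.
toy_filter_records <- function() {
  s <- function(ad, gq, called = TRUE) list(ad = if (called) ad else NULL,
                                            gq = gq, called = called)
  ok <- function() s(c(10L, 10L), 60L)
  ok3 <- function() s(c(10L, 5L, 5L), 60L)
  list(
    variant_record("chr1", 100, "A", c("C", "G"),
                   list(ok3(), ok3(), ok3(), ok3(), ok3())),
    variant_record("chr1", 200, "A", "C",
                   list(s(c(2L, 2L), 60L), ok(), ok(), ok(), ok())),
    variant_record("chr1", 300, "A", "C",
                   list(s(c(10L, 10L), 20L), ok(), ok(), ok(), ok())),
    variant_record("chr1", 400, "A", "C",
                   list(s(NULL, NULL, called = FALSE), ok(), ok(), ok(), ok())),
    variant_record("chr1", 500, "A", "C",
                   list(ok(), ok(), ok(), ok(), ok()))
  )
}

write_marker_tsv <- function(path, ids, loci, cells) {
  lines <- c(paste(c("id", loci), collapse = "\t"),
             vapply(seq_along(ids), function(i) {
               paste(c(ids[i], cells[i, ]), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  path
}
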