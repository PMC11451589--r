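# Deterministic hand-built micro-gene used across unit tests: 30 bp 5'UTR
# (first 12 bp flagged functional), 30 bp coding exon 1, 21 bp intron,
# 30 bp coding exon 2, 24 bp 3'UTR.  CDS = ATG + 18 non-stop codons + TAA.
micro_gene <- function() {
  utr5 <- "GATTACAGATTACAGATTACAGATTACAGA"            # 30
  ex1  <- "ATGCATGAAGTCCTGGACAAGCGGATCCTA"            # 30: ATG + 9 codons
  intr <- "GTAAGTCCCTTTAAACCCGGG"                     # 21
  ex2  <- "GCTGTTCCAGAAACCCTGCGAGATCGCTAA"            # 30: 9 codons + TAA
  utr3 <- "CCTCCTCCTCCTCCTCCTCCTCCT"                  # 24
  wt <- paste0(utr5, ex1, intr, ex2, utr3)
  gene_def("KIRM1DL1", "KIRM1DL1*001", wt,
           exons = data.frame(start = c(30L, 81L), end = c(60L, 111L)),
           phase = 0L,
           functional_utr = data.frame(start = 0L, end = 12L))
}

# write a fixture database directory for a toy db and return its path
write_toy_db_dir <- function(td, dir = tempfile("dbdir")) {
  write_allele_db(td$db, dir)
  dir
}

# standard plant set used by the end-to-end tests: >= 6 copies including a
# minus-strand copy, a head-truncated copy and a copy with a novel core
# (nonsense) variant.
standard_plants <- function() {
  data.frame(
    allele = c("KIRT1DL1*001", "KIRT1DL1*002", "KIRT2DL1*003",
               "KIRT2DL1*001", "KIRT1DL1*003", "KIRT2DL1*001"),
    strand = c("+", "-", "+", "+", "+", "+"),
    trunc_head = c(0L, 0L, 0L, 60L, 0L, 0L),
    novel = c("", "", "", "", "", "nonsense"),
    contig = c("ctg1", "ctg1", "ctg1", "ctg2", "ctg2", "ctg2"),
    stringsAsFactors = FALSE)
}

standard_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      td <- make_toy_database(2, 4, seed = 7, include_cdna = TRUE)
      syn <- make_synthetic_assembly(td$db, standard_plants(), seed = 11)
      cache <<- list(td = td, db = td$db, syn = syn)
    }
    cache
  }
})

# synthetic EMBL-style flat file exercising the ipd_flatfile dialect
# (synthetic stand-in for a repository release; two genomic alleles with
# two exons each and one cDNA-only allele)
write_synthetic_flatfile <- function(path = tempfile(fileext = ".dat")) {
  g <- micro_gene()
  wt <- g$wildtype_seq
  v <- variant_table(40L, substr(wt, 41L, 41L),
                     setdiff(c("A", "C", "G", "T"), substr(wt, 41L, 41L))[1])
  alt_seq <- apply_variants(wt, v)
  cdna <- paste0(substr(wt, 31L, 60L), substr(wt, 82L, 111L))
  fmt_rec <- function(name, seq, exons = NULL) {
    ft <- character()
    if (!is.null(exons)) {
      ft <- c(sprintf("FT   exon            %d..%d",
                      exons$start + 1L, exons$end),
              "FT   CDS             join(31..60,82..111)",
              "FT                   /codon_start=1")
    } else {
      ft <- c(sprintf("FT   exon            1..%d", nchar(seq)))
    }
    c(sprintf("ID   %s; SV 1; standard; DNA; HUM; %d BP.",
              sub(".*\\*", "KIRX", name), nchar(seq)),
      sprintf("DE   %s, synthetic test allele", name),
      ft,
      sprintf("SQ   Sequence %d BP;", nchar(seq)),
      paste("    ", tolower(seq)),
      "//")
  }
  writeLines(c(fmt_rec("KIRM1DL1*001", wt, g$exons),
               fmt_rec("KIRM1DL1*002", alt_seq, g$exons),
               fmt_rec("KIRM1DL1*003", cdna)),
             path)
  path
}
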