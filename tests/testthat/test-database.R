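# Allele database loading, cDNA genomic inference and the core index.

test_that("fixture database preserves gene and allele counts", {
  td <- make_toy_database(2, 3, seed = 3)
  db <- td$db
  expect_length(db$genes, 2L)
  expect_equal(sum(vapply(db$genes, function(g) length(g$alleles),
                          integer(1))), 6L)
  for (g in db$genes) {
    expect_equal(g$def$wildtype_allele, names(g$alleles)[1])
    # the wildtype allele of a gene has no variants
    expect_equal(nrow(g$alleles[[g$def$wildtype_allele]]$variants), 0L)
  }
})

test_that("alleles identical to the wildtype have empty variant lists", {
  g <- micro_gene()
  dir <- tempfile("iddb"); dir.create(dir)
  writeLines(c(">KIRM1DL1*001 kind=genomic", g$wildtype_seq,
               ">KIRM1DL1*002 kind=genomic", g$wildtype_seq),
             file.path(dir, "alleles.fa"))
  writeLines(c("gene\twildtype\texons\tphase\tfunctional_utr\tpseudogene",
               "KIRM1DL1\tKIRM1DL1*001\t31-60,82-111\t0\t1-12\t0"),
             file.path(dir, "genes.tsv"))
  db <- load_allele_db(dir, "fixture")
  for (a in db$genes$KIRM1DL1$alleles)
    expect_equal(nrow(a$variants), 0L)
  expect_length(db$genes$KIRM1DL1$core_index, 0L)
})

test_that("database variant sets reconstruct each allele sequence", {
  td <- make_toy_database(2, 4, seed = 5)
  for (g in td$db$genes) {
    for (a in g$alleles) {
      if (isTRUE(a$flagged)) next
      expect_equal(oracle_apply_variants(g$def$wildtype_seq, a$variants),
                   a$genomic_seq, info = a$name)
    }
  }
})

test_that("cDNA equal to the spliced wildtype infers the wildtype genome", {
  g <- micro_gene()
  cdna <- paste0(substr(g$wildtype_seq, 31, 60),
                 substr(g$wildtype_seq, 82, 111))
  wt_name <- g$wildtype_allele
  gseqs <- stats::setNames(g$wildtype_seq, wt_name)
  expect_equal(infer_genomic_sequence(cdna, g, gseqs), g$wildtype_seq)
})

test_that("one exonic substitution in the cDNA lifts to the genome", {
  g <- micro_gene()
  wt <- g$wildtype_seq
  cdna <- paste0(substr(wt, 31, 60), substr(wt, 82, 111))
  # substitute spliced position 40 (1-based) = exon2 offset 10 ->
  # genomic 0-based coordinate via the exon table oracle:
  exons <- g$exons
  lift_spliced <- function(sp) {           # 0-based spliced -> genomic
    off <- 0L
    for (i in seq_len(nrow(exons))) {
      len <- exons$end[i] - exons$start[i]
      if (sp < off + len) return(exons$start[i] + (sp - off))
      off <- off + len
    }
    stop("out of spliced range")
  }
  sp <- 39L
  gpos <- lift_spliced(sp)
  old <- substr(cdna, sp + 1, sp + 1)
  new <- setdiff(c("A", "C", "G", "T"), old)[1]
  cdna2 <- paste0(substr(cdna, 1, sp), new, substr(cdna, sp + 2, nchar(cdna)))
  got <- infer_genomic_sequence(cdna2, g,
                                stats::setNames(wt, g$wildtype_allele))
  want <- oracle_apply_variants(wt, variant_table(gpos, old, new))
  expect_equal(got, want)
})

test_that("the nearest backbone is chosen by spliced edit distance", {
  g <- micro_gene()
  wt <- g$wildtype_seq
  # backbone B: wildtype with 5 exonic substitutions
  set.seed(17)
  ppos <- c(33L, 44L, 50L, 85L, 100L)
  vB <- variant_table(ppos,
                      vapply(ppos, function(p) substr(wt, p + 1, p + 1), ""),
                      vapply(ppos, function(p)
                        setdiff(c("A", "C", "G", "T"),
                                substr(wt, p + 1, p + 1))[1], ""))
  B <- apply_variants(wt, vB)
  # cDNA = spliced B with ONE further substitution: 1 edit from B, ~6 from wt
  splicedB <- paste0(substr(B, 31, 60), substr(B, 82, 111))
  cdna <- paste0("T", substr(splicedB, 2, nchar(splicedB)))
  if (substr(splicedB, 1, 1) == "T")
    cdna <- paste0("A", substr(splicedB, 2, nchar(splicedB)))
  gseqs <- c("KIRM1DL1*001" = wt, "KIRM1DL1*002" = B)
  gvars <- list("KIRM1DL1*001" = variant_table(),
                "KIRM1DL1*002" = vB)
  got <- infer_genomic_sequence(cdna, g, gseqs, gvars)
  # introns must come from B, exons from the cDNA
  expect_equal(substr(got, 61, 81), substr(B, 61, 81))
  expect_equal(paste0(substr(got, 31, 60), substr(got, 82, 111)), cdna)
})

test_that("length-incompatible cDNA is flagged with a warning, not fatal", {
  g <- micro_gene()
  cdna <- paste0(substr(g$wildtype_seq, 31, 60), "ACGT")   # wrong length
  expect_warning(
    res <- infer_genomic_sequence(cdna, g,
                                  stats::setNames(g$wildtype_seq,
                                                  g$wildtype_allele)),
    "incompatible")
  expect_true(is.na(res))
})

test_that("core index honors per-base indel footprints and set semantics", {
  mk <- function(name, variants) {
    list(name = name, gene = "G", variants = variants, flagged = FALSE)
  }
  a <- mk("G*002", variant_table(120L, "C", "G", effect = "missense",
                                 core = TRUE))
  b_v <- variant_table(c(120L, 10521L), c("C", "AAA"), c("G", ""),
                       effect = c("missense", "frameshift"),
                       core = c(TRUE, TRUE))
  b <- mk("G*003", b_v)
  expect_equal(build_core_index(list(a, b)),
               c(120L, 10521L, 10522L, 10523L))
  # shared identical core SNP dedupes
  expect_equal(build_core_index(list(a, a)), 120L)
  # silent-only alleles contribute nothing
  s <- mk("G*004", variant_table(7L, "A", "T", effect = "synonymous",
                                 core = FALSE))
  expect_length(build_core_index(list(s)), 0L)
  # monotone: adding an allele never removes positions
  expect_true(all(build_core_index(list(a)) %in%
                    build_core_index(list(a, b, s))))
})

test_that("database round-trips through the fixture dialect", {
  td <- make_toy_database(2, 3, seed = 9, include_cdna = TRUE)
  dir <- tempfile("rt")
  write_allele_db(td$db, dir)
  db2 <- load_allele_db(dir, "fixture")
  expect_equal(names(db2$genes), names(td$db$genes))
  for (gn in names(td$db$genes)) {
    expect_equal(db2$genes[[gn]]$core_index, td$db$genes[[gn]]$core_index)
    for (an in names(td$db$genes[[gn]]$alleles))
      expect_equal(db2$genes[[gn]]$alleles[[an]]$variants,
                   td$db$genes[[gn]]$alleles[[an]]$variants)
  }
})

test_that("loading errors name the offending file", {
  dir <- tempfile("bad"); dir.create(dir)
  writeLines(c(">BROKENHEADER", "ACGT"), file.path(dir, "alleles.fa"))
  writeLines(c("gene\twildtype\texons\tphase\tfunctional_utr\tpseudogene",
               "G\tG*001\t1-4\t0\t.\t0"),
             file.path(dir, "genes.tsv"))
  expect_error(load_allele_db(dir, "fixture"), "alleles.fa")
})

test_that("a gene with no genomic allele cannot anchor a wildtype", {
  g <- micro_gene()
  cdna <- paste0(substr(g$wildtype_seq, 31, 60), substr(g$wildtype_seq, 82, 111))
  dir <- tempfile("nog"); dir.create(dir)
  writeLines(c(">KIRM1DL1*001 kind=cdna", cdna),
             file.path(dir, "alleles.fa"))
  writeLines(c("gene\twildtype\texons\tphase\tfunctional_utr\tpseudogene",
               "KIRM1DL1\tKIRM1DL1*001\t31-60,82-111\t0\t1-12\t0"),
             file.path(dir, "genes.tsv"))
  expect_error(load_allele_db(dir, "fixture"))
})
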