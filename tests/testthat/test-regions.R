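# Region consolidation, gene assignment by prevalence, wildtype boundary
# refinement.

mk_mapping <- function(contig, start, end, strand = "+", gene = "G1",
                       allele = paste0(gene, "*001"), score = 100) {
  data.frame(allele = allele, gene = gene, contig = contig,
             start = as.integer(start), end = as.integer(end),
             strand = strand, score = score, clip5 = 0L, clip3 = 0L,
             stringsAsFactors = FALSE)
}

empty_mappings_for_test <- function() {
  mk_mapping("c", 1, 2)[0, ]
}

test_that("overlapping same-strand mappings merge to the union span", {
  m <- rbind(mk_mapping("c", 100, 500), mk_mapping("c", 400, 900))
  r <- consolidate(m)
  expect_length(r, 1L)
  expect_equal(r[[1]]$start, 100L)
  expect_equal(r[[1]]$end, 900L)
  expect_equal(r[[1]]$support$n, 2L)
})

test_that("strands never merge and empty input gives empty output", {
  expect_length(consolidate(empty_mappings_for_test()), 0L)
  m <- rbind(mk_mapping("c", 100, 500, "+"), mk_mapping("c", 400, 900, "-"))
  r <- consolidate(m)
  expect_length(r, 2L)
  expect_setequal(vapply(r, `[[`, character(1), "strand"), c("+", "-"))
})

test_that("adjacent-but-disjoint mappings are not merged by default", {
  m <- rbind(mk_mapping("c", 100, 500), mk_mapping("c", 500, 900))
  expect_length(consolidate(m), 2L)
  expect_length(consolidate(m, gap_merge = 10L), 1L)
})

test_that("consolidation is idempotent", {
  set.seed(61)
  m <- do.call(rbind, lapply(1:30, function(i)
    mk_mapping(sample(c("c1", "c2"), 1), s <- sample(1:5000, 1),
               s + sample(200:800, 1), sample(c("+", "-"), 1),
               gene = sample(c("G1", "G2"), 1))))
  r1 <- consolidate(m)
  # reinterpret regions as mappings and consolidate again
  m2 <- do.call(rbind, lapply(r1, function(r)
    mk_mapping(r$contig, r$start, r$end, r$strand)))
  r2 <- consolidate(m2)
  expect_equal(length(r2), length(r1))
  expect_equal(vapply(r2, `[[`, integer(1), "start"),
               vapply(r1, `[[`, integer(1), "start"))
  expect_equal(vapply(r2, `[[`, integer(1), "end"),
               vapply(r1, `[[`, integer(1), "end"))
})

test_that("gene assignment is by count, then score, then name", {
  m <- rbind(
    do.call(rbind, replicate(7, mk_mapping("c", 0, 1000, gene = "GA"),
                             simplify = FALSE)),
    do.call(rbind, replicate(2, mk_mapping("c", 0, 1000, gene = "GB"),
                             simplify = FALSE)))
  expect_equal(assign_gene(consolidate(m)[[1]]), "GA")
  # single-gene support
  expect_equal(assign_gene(consolidate(mk_mapping("c", 0, 1000,
                                                  gene = "GZ"))[[1]]), "GZ")
  # tied counts: higher summed score wins
  m2 <- rbind(mk_mapping("c", 0, 1000, gene = "GA", score = 200),
              mk_mapping("c", 0, 1000, gene = "GA", score = 210),
              mk_mapping("c", 0, 1000, gene = "GB", score = 200),
              mk_mapping("c", 0, 1000, gene = "GB", score = 180))
  expect_equal(assign_gene(consolidate(m2)[[1]]), "GA")
  # full tie: lexicographic
  m3 <- rbind(mk_mapping("c", 0, 1000, gene = "GB", score = 100),
              mk_mapping("c", 0, 1000, gene = "GA", score = 100))
  expect_equal(assign_gene(consolidate(m3)[[1]]), "GA")
})

test_that("weak regions are filtered by support and length", {
  m <- rbind(mk_mapping("c", 0, 1000), mk_mapping("c", 100, 900),
             mk_mapping("c", 5000, 5300), mk_mapping("c", 5000, 5300),
             mk_mapping("c", 9000, 9900))
  r <- filter_regions(consolidate(m), min_support = 2L, min_len = 500L)
  expect_length(r, 1L)
  expect_equal(r[[1]]$start, 0L)
})

test_that("wildtype refinement recovers planted bounds, both strands", {
  scene <- standard_scene()
  db <- scene$db
  syn <- scene$syn
  m <- map_alleles(db, syn$contigs)
  regions <- filter_regions(consolidate(m))
  tr <- syn$truth[syn$truth$trunc_head == 0 & syn$truth$novel == "", ]
  for (i in seq_len(nrow(tr))) {
    want <- tr[i, ]
    reg <- Filter(function(r) r$contig == want$contig &&
                    r$strand == want$strand &&
                    r$start < want$end && r$end > want$start, regions)
    expect_length(reg, 1L)
    g <- db$genes[[assign_gene(reg[[1]])]]
    copy <- refine_region_bounds(reg[[1]], g$def, syn$contigs)
    expect_equal(copy$start, want$start)
    expect_equal(copy$end, want$end)
    # extracted sequence is the oriented assembly substring
    want_seq <- substr(syn$contigs[[want$contig]], want$start + 1,
                       want$end)
    if (want$strand == "-")
      want_seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(want_seq)))
    expect_equal(copy$seq, want_seq)
  }
})

test_that("an unmappable wildtype drops the region with a warning", {
  set.seed(62)
  g <- micro_gene()
  ctg <- random_seq(3000)
  region <- structure(list(contig = "c", start = 1000L, end = 1800L,
                           strand = "+",
                           support = data.frame(gene = g$name, n = 2L,
                                                score = 10,
                                                stringsAsFactors = FALSE)),
                      class = "candidate_region")
  expect_warning(
    res <- refine_region_bounds(region, g, c(c = ctg), min_identity = 0.9),
    "failed to map")
  expect_null(res)
})
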