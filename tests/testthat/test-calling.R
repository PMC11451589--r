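# Core-variant Hamming scoring and allele ranking.

toy_scoring_gene <- function() {
  set.seed(71)
  wt <- random_seq(400)
  g <- list(name = "GS", wildtype_seq = wt)
  class(g) <- "gene_def"
  g
}

mk_allele <- function(gene, name, variants) {
  list(name = name, gene = gene$name, variants = variants, flagged = FALSE)
}

core_v <- function(pos, ref, alt) {
  variant_table(pos, ref, alt, effect = "missense", core = TRUE)
}

silent_v <- function(pos, ref, alt) {
  variant_table(pos, ref, alt, effect = "synonymous", core = FALSE)
}

test_that("full core agreement with no novelty scores exactly zero", {
  g <- toy_scoring_gene()
  v <- rbind(core_v(120L, substr(g$wildtype_seq, 121, 121), "G"),
             silent_v(300L, substr(g$wildtype_seq, 301, 301), "T"))
  a <- mk_allele(g, "GS*002", v)
  idx <- build_core_index(list(a))
  s <- score_allele(v, a, idx, g)
  expect_identical(s$core_score, 0)
  expect_length(s$missing_core, 0L)
  expect_length(s$novel_core, 0L)
  expect_identical(s$silent_jaccard, 0)
})

test_that("one core-position mismatch over an index of 4 scores 0.25", {
  g <- toy_scoring_gene()
  wt <- g$wildtype_seq
  ref_at <- function(p) substr(wt, p + 1, p + 1)
  av <- rbind(core_v(10L, ref_at(10L), "A" ), core_v(50L, ref_at(50L), "C"),
              core_v(90L, ref_at(90L), "G"), core_v(130L, ref_at(130L), "T"))
  av$alt <- mapply(function(p, a) setdiff(c("A","C","G","T"),
                                          c(ref_at(p), a))[1],
                   av$pos, av$alt)            # ensure alt != ref
  a <- mk_allele(g, "GS*002", av)
  idx <- build_core_index(list(a))
  expect_length(idx, 4L)
  cv <- av[-1, ]                              # copy lacks the variant at 10
  s <- score_allele(cv, a, idx, g)
  expect_equal(s$core_score, 0.25)
  expect_length(s$missing_core, 1L)
})

test_that("novel core variants add 1 each to the score", {
  g <- toy_scoring_gene()
  wt <- g$wildtype_seq
  a <- mk_allele(g, "GS*002",
                 core_v(10L, substr(wt, 11, 11),
                        setdiff(c("A","C","G","T"), substr(wt, 11, 11))[1]))
  idx <- build_core_index(list(a))
  cv <- rbind(a$variants,
              core_v(200L, substr(wt, 201, 201),
                     setdiff(c("A","C","G","T"), substr(wt, 201, 201))[1]),
              core_v(250L, substr(wt, 251, 251),
                     setdiff(c("A","C","G","T"), substr(wt, 251, 251))[1]))
  s <- score_allele(cv, a, idx, g)
  expect_equal(s$core_score, 2)
  expect_length(s$novel_core, 2L)
})

test_that("each deleted base counts independently in the index", {
  g <- toy_scoring_gene()
  wt <- g$wildtype_seq
  del <- variant_table(100L, substr(wt, 101, 103), "",
                       effect = "frameshift", core = TRUE)
  snps <- rbind(core_v(10L, substr(wt, 11, 11), "A"),
                core_v(20L, substr(wt, 21, 21), "A"),
                core_v(30L, substr(wt, 31, 31), "A"))
  snps$alt <- mapply(function(p) setdiff(c("A","C","G","T"),
                                         substr(wt, p + 1, p + 1))[1],
                     snps$pos)
  a_del <- mk_allele(g, "GS*002", rbind(snps, del))
  idx <- build_core_index(list(a_del))
  expect_length(idx, 6L)                      # 3 snps + 3 deleted bases
  cv <- snps                                  # copy has the snps, not the del
  s <- score_allele(cv, a_del, idx, g)
  expect_equal(s$core_score, 3 / 6)
})

test_that("an empty core index scores zero by convention", {
  g <- toy_scoring_gene()
  a <- mk_allele(g, "GS*002", variant_table())
  s <- score_allele(variant_table(), a, integer(), g)
  expect_identical(s$core_score, 0)
})

test_that("silent Jaccard follows set arithmetic", {
  sa <- c("1:A>C", "2:C>G")
  expect_equal(silent_jaccard(sa, sa), 0)
  expect_equal(silent_jaccard(sa, c("9:G>T", "10:T>A")), 1)
  expect_equal(silent_jaccard(c("1:A>C", "2:C>G", "3:G>T"),
                              c("1:A>C", "2:C>G", "4:T>A")), 0.5)
  expect_equal(silent_jaccard(character(), character()), 0)
})

test_that("core_score matches the enumeration oracle on random triples", {
  set.seed(73)
  g <- toy_scoring_gene()
  wt <- g$wildtype_seq
  for (i in 1:200) {
    av <- random_variant_set(wt)
    cv <- random_variant_set(wt)
    a <- mk_allele(g, "GS*099", av)
    idx <- build_core_index(list(a, mk_allele(g, "GS*098", cv)))
    s <- score_allele(cv, a, idx, g)
    expect_equal(s$core_score, oracle_core_score(cv, av, idx, wt),
                 info = paste("triple", i))
    expect_gte(s$core_score, 0)
    expect_gte(s$silent_jaccard, 0)
    expect_lte(s$silent_jaccard, 1)
  }
})

test_that("ranking is core-first with silent Jaccard and suffix tie-breaks", {
  g <- toy_scoring_gene()
  wt <- g$wildtype_seq
  ref_at <- function(p) substr(wt, p + 1, p + 1)
  alt_at <- function(p) setdiff(c("A","C","G","T"), ref_at(p))[1]
  core1 <- core_v(10L, ref_at(10L), alt_at(10L))
  sil1 <- silent_v(200L, ref_at(200L), alt_at(200L))
  sil2 <- silent_v(220L, ref_at(220L), alt_at(220L))
  dbg <- list(
    def = g,
    alleles = list(
      # *002: core match, silent mismatch;  *003: core mismatch, silent match
      "GS*002" = mk_allele(g, "GS*002", rbind(core1, sil2)),
      "GS*003" = mk_allele(g, "GS*003", sil1)),
    core_index = integer())
  dbg$core_index <- build_core_index(dbg$alleles)
  copy <- rbind(core1, sil1)
  res <- call_allele(copy, dbg)
  # *003 has the smaller silent Jaccard but a core mismatch: *002 must win
  expect_equal(res$call, "GS*002")
  expect_true(res$scores$core_score[1] < res$scores$core_score[2])
  # suffix tie-break: identical alleles, lower number first
  dbg2 <- list(def = g,
               alleles = list("GS*010" = mk_allele(g, "GS*010", core1),
                              "GS*004" = mk_allele(g, "GS*004", core1)),
               core_index = build_core_index(list(mk_allele(g, "x*1",
                                                            core1))))
  res2 <- call_allele(copy, dbg2)
  expect_equal(res2$call, "GS*004")
  # single-allele gene: that allele regardless of score
  dbg3 <- list(def = g,
               alleles = list("GS*007" = mk_allele(g, "GS*007", sil2)),
               core_index = integer())
  expect_equal(call_allele(copy, dbg3)$call, "GS*007")
})

test_that("top-5 retention caps the score table", {
  g <- toy_scoring_gene()
  alleles <- lapply(1:8, function(i)
    mk_allele(g, sprintf("GS*%03d", i), variant_table()))
  names(alleles) <- vapply(alleles, `[[`, "", "name")
  dbg <- list(def = g, alleles = alleles, core_index = integer())
  res <- call_allele(variant_table(), dbg)
  expect_equal(nrow(res$scores), 5L)
  dbg$alleles <- alleles[1:2]
  expect_equal(nrow(call_allele(variant_table(), dbg)$scores), 2L)
})
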