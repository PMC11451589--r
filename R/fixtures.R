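## Deterministic generator of toy KIR-like allele databases and synthetic
## assemblies with a known truth table.  Every planted variant's intended
## effect class is certified by the same mutate-splice-translate oracle the
## caller will use, so fixture truth and classification can never drift
## apart silently.  A single integer seed controls all randomness; the RNG
## state of the session is left untouched.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.rand_bases <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## random CDS: ATG + non-stop codons + TAA
.rand_cds <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- character(n_codons - 2L)
  i <- 1L
  while (i <= length(codons)) {
    cd <- .rand_bases(3L)
    if (!(cd %in% stops)) { codons[i] <- cd; i <- i + 1L }
  }
  paste0("ATG", paste0(codons, collapse = ""), "TAA")
}

## search for a single variant of the requested effect class on `gene`,
## with footprint disjoint from `avoid` (0-based positions)
.plant_variant <- function(gene, class, avoid = integer(), tries = 400L) {
  wt <- gene$wildtype_seq
  n <- nchar(wt)
  exons <- gene$exons
  bases <- c("A", "C", "G", "T")
  for (t in seq_len(tries)) {
    cand <- switch(class,
      missense = , nonsense = , synonymous = {
        ex <- exons[sample(nrow(exons), 1L), ]
        p <- sample(ex$start:(ex$end - 1L), 1L)
        list(pos = p, ref = substr(wt, p + 1L, p + 1L),
             alt = sample(setdiff(bases, substr(wt, p + 1L, p + 1L)), 1L))
      },
      frameshift = {
        ex <- exons[sample(nrow(exons), 1L), ]
        p <- sample((ex$start + 3L):(ex$end - 4L), 1L)
        if (stats::runif(1) < 0.5)
          list(pos = p, ref = substr(wt, p + 1L, p + 1L), alt = "")
        else list(pos = p, ref = "", alt = .rand_bases(1L))
      },
      start_loss = {
        p <- exons$start[1] + gene$phase + sample(0:2, 1L)
        list(pos = p, ref = substr(wt, p + 1L, p + 1L),
             alt = sample(setdiff(bases, substr(wt, p + 1L, p + 1L)), 1L))
      },
      intronic = {
        if (nrow(exons) < 2L) stop("no intron available")
        p <- sample((exons$end[1] + 2L):(exons$start[2] - 3L), 1L)
        list(pos = p, ref = substr(wt, p + 1L, p + 1L),
             alt = sample(setdiff(bases, substr(wt, p + 1L, p + 1L)), 1L))
      },
      utr_functional = {
        iv <- gene$functional_utr
        if (nrow(iv) == 0L) stop("gene has no functional UTR interval")
        p <- sample(iv$start[1]:(iv$end[1] - 1L), 1L)
        list(pos = p, ref = substr(wt, p + 1L, p + 1L),
             alt = sample(setdiff(bases, substr(wt, p + 1L, p + 1L)), 1L))
      },
      utr_silent = {
        p <- sample(0:(min(exons$start) - 2L), 1L)
        list(pos = p, ref = substr(wt, p + 1L, p + 1L),
             alt = sample(setdiff(bases, substr(wt, p + 1L, p + 1L)), 1L))
      },
      del_inframe = {
        ex <- exons[sample(nrow(exons), 1L), ]
        p <- sample((ex$start + 3L):(ex$end - 7L), 1L)
        list(pos = p, ref = substr(wt, p + 1L, p + 3L), alt = "")
      },
      stop("unknown variant class: ", class))
    fp <- variant_footprint(cand$pos, cand$ref, cand$alt)
    if (any(fp %in% avoid) || any(fp < 0L) || any(fp >= n)) next
    want <- if (class == "del_inframe") c("missense", "nonsense") else class
    got <- classify_effect(cand$pos, cand$ref, cand$alt, gene)
    if (got %in% want) {
      cand$effect <- got
      return(cand)
    }
  }
  stop("could not plant a ", class, " variant on gene ", gene$name,
       " after ", tries, " tries")
}

#' Generate a toy allele database with known truth
#'
#' Builds `n_genes` toy genes (~1 kb: 5' UTR, two coding exons around one
#' intron, 3' UTR; the first gene carries a functional-UTR interval) and
#' `alleles_per_gene` alleles each.  Allele `*001` is the wildtype; the
#' others carry 1-3 planted variants drawn from missense / synonymous /
#' intronic / nonsense / frameshift classes, every one certified by
#' [classify_effect()].  Optionally one extra cDNA-only allele per gene
#' (a spliced transcript with one exonic substitution).
#'
#' @param n_genes,alleles_per_gene Positive counts.
#' @param seed Integer seed; the same seed reproduces the database
#'   byte-for-byte.
#' @param include_cdna Add one cDNA-only allele per gene.
#' @return list with `db` (a `kir_db`), `truth` (data.frame: allele, gene,
#'   planted variant, intended class, core flag) and `raw` (the in-memory
#'   gene definitions and allele sequences).
#' @export
make_toy_database <- function(n_genes = 2L, alleles_per_gene = 3L, seed = 1L,
                              include_cdna = FALSE) {
  stopifnot(n_genes >= 1L, alleles_per_gene >= 1L)
  .with_seed(seed, {
    classes <- c("missense", "synonymous", "intronic", "nonsense",
                 "frameshift")
    truth <- NULL
    fa <- character()
    meta <- NULL
    for (gi in seq_len(n_genes)) {
      gname <- sprintf("KIRT%dDL1", gi)
      utr5 <- 120L; ex1 <- 210L; intr <- 180L; ex2 <- 243L; utr3 <- 120L
      cds <- .rand_cds((ex1 + ex2) %/% 3L)
      wt <- paste0(.rand_bases(utr5), substr(cds, 1L, ex1),
                   .rand_bases(intr),
                   substr(cds, ex1 + 1L, ex1 + ex2), .rand_bases(utr3))
      exons <- data.frame(start = c(utr5, utr5 + ex1 + intr),
                          end = c(utr5 + ex1, utr5 + ex1 + intr + ex2))
      futr <- if (gi == 1L) data.frame(start = 10L, end = 40L)
              else data.frame(start = integer(), end = integer())
      def <- gene_def(gname, sprintf("%s*001", gname), wt, exons,
                      phase = 0L, functional_utr = futr)

      wt_name <- sprintf("%s*001", gname)
      fa <- c(fa, paste0(">", wt_name, " kind=genomic"), wt)
      meta <- rbind(meta, data.frame(
        gene = gname, wildtype = wt_name,
        exons = .format_intervals(exons), phase = 0L,
        functional_utr = .format_intervals(futr), pseudogene = 0L,
        stringsAsFactors = FALSE))

      for (ai in seq_len(alleles_per_gene - 1L)) {
        aname <- sprintf("%s*%03d", gname, ai + 1L)
        nv <- sample(1:3, 1L)
        avoid <- integer()
        vs <- NULL
        for (vi in seq_len(nv)) {
          cl <- sample(classes, 1L)
          v <- .plant_variant(def, cl, avoid = avoid)
          # keep footprints well separated so alignment recovers each
          avoid <- c(avoid, (min(variant_footprint(v$pos, v$ref, v$alt)) -
                               10L):(max(variant_footprint(v$pos, v$ref,
                                                           v$alt)) + 10L))
          vs <- rbind(vs, data.frame(pos = v$pos, ref = v$ref, alt = v$alt,
                                     effect = v$effect,
                                     stringsAsFactors = FALSE))
        }
        vs <- vs[order(vs$pos), , drop = FALSE]
        aseq <- apply_variants(wt, variant_table(vs$pos, vs$ref, vs$alt))
        fa <- c(fa, paste0(">", aname, " kind=genomic"), aseq)
        truth <- rbind(truth, data.frame(
          allele = aname, gene = gname, pos = vs$pos, ref = vs$ref,
          alt = vs$alt, effect = vs$effect,
          core = vs$effect %in% CORE_EFFECTS, stringsAsFactors = FALSE))
      }

      if (include_cdna) {
        aname <- sprintf("%s*%03d", gname, alleles_per_gene + 1L)
        v <- .plant_variant(def, "missense")
        mutant <- apply_variants(wt, variant_table(v$pos, v$ref, v$alt))
        cdna <- .splice_cds(mutant, exons, 0L)
        fa <- c(fa, paste0(">", aname, " kind=cdna"), cdna)
        truth <- rbind(truth, data.frame(
          allele = aname, gene = gname, pos = v$pos, ref = v$ref,
          alt = v$alt, effect = v$effect, core = TRUE,
          stringsAsFactors = FALSE))
      }
    }
    dir <- tempfile("toydb")
    dir.create(dir)
    writeLines(fa, file.path(dir, "alleles.fa"))
    utils::write.table(meta, file.path(dir, "genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    db <- load_allele_db(dir, "fixture")
    unlink(dir, recursive = TRUE)
    list(db = db, truth = truth)
  })
}

## spacer free of any k-mer shared with the allele set (either strand)
.make_spacer <- function(len, allele_kmers, k = 21L, tries = 50L) {
  for (t in seq_len(tries)) {
    sp <- .rand_bases(len)
    if (!any(.kmerize(sp, k) %in% allele_kmers)) return(sp)
  }
  stop("could not generate a clean intergenic spacer")
}

#' Build a synthetic assembly with planted gene copies
#'
#' Contigs carry the requested allele copies -- optionally
#' reverse-complemented, truncated by a stated head/tail length, or with
#' planted novel variants (classes as in [make_toy_database()]; novelty is
#' guaranteed by requiring the footprint to avoid the gene's core index) --
#' separated by >= 2 kb of random intergenic sequence rejection-sampled to
#' share no 21-mer with any database allele, so the builtin mapper cannot
#' seed spurious regions.
#'
#' @param db A `kir_db`.
#' @param plants data.frame with columns `allele`, and optionally `contig`
#'   (default `"ctg1"`), `strand` (`"+"`), `trunc_head`, `trunc_tail`
#'   (bases removed from the gene 5'/3' end, default 0) and `novel`
#'   (character effect class, `""` for none).
#' @param seed Integer seed.
#' @param spacer Intergenic spacer length (>= 2000).
#' @return list with `contigs` (named character), `truth` (data.frame:
#'   contig, start, end (0-based half-open, forward strand), strand, gene,
#'   allele, novel class and its wildtype-coordinate position or NA).
#' @export
make_synthetic_assembly <- function(db, plants, seed = 1L, spacer = 2000L) {
  stopifnot(spacer >= 2000L, nrow(plants) >= 1L)
  plants <- as.data.frame(plants, stringsAsFactors = FALSE)
  if (is.null(plants$contig)) plants$contig <- "ctg1"
  if (is.null(plants$strand)) plants$strand <- "+"
  if (is.null(plants$trunc_head)) plants$trunc_head <- 0L
  if (is.null(plants$trunc_tail)) plants$trunc_tail <- 0L
  if (is.null(plants$novel)) plants$novel <- ""
  seqs <- db_allele_seqs(db)

  .with_seed(seed, {
    kmers <- unique(unlist(lapply(seqs, function(s)
      c(.kmerize(s, 21L), .kmerize(.revcomp(s), 21L)))))
    contigs <- character(); truth <- NULL
    for (ct in unique(plants$contig)) {
      ps <- plants[plants$contig == ct, , drop = FALSE]
      parts <- .make_spacer(spacer, kmers)
      pos <- nchar(parts)
      for (i in seq_len(nrow(ps))) {
        aname <- ps$allele[i]
        if (!aname %in% names(seqs)) stop("unknown allele: ", aname)
        gname <- allele_gene(aname)
        dbg <- db$genes[[gname]]
        s <- seqs[[aname]]
        novel_cl <- ps$novel[i]; novel_pos <- NA_integer_
        if (nzchar(novel_cl)) {
          if (!identical(dbg$alleles[[aname]]$name,
                         dbg$def$wildtype_allele) &&
              any(dbg$alleles[[aname]]$variants$kind != "snp"))
            stop("novel variants may only be planted on alleles without ",
                 "indels (coordinate lift would be ambiguous)")
          avoid <- unique(c(dbg$core_index,
                            dbg$alleles[[aname]]$variants$pos))
          v <- .plant_variant(dbg$def, novel_cl, avoid = avoid)
          p2 <- lift_coord(v$pos, dbg$alleles[[aname]]$variants)
          s <- apply_variants(s, variant_table(p2, v$ref, v$alt))
          novel_pos <- v$pos
        }
        th <- ps$trunc_head[i]; tt <- ps$trunc_tail[i]
        if (th + tt >= nchar(s)) stop("truncation longer than the allele")
        s <- substr(s, th + 1L, nchar(s) - tt)
        if (ps$strand[i] == "-") s <- .revcomp(s)
        parts <- paste0(parts, s)
        truth <- rbind(truth, data.frame(
          contig = ct, start = pos, end = pos + nchar(s),
          strand = ps$strand[i], gene = gname, allele = aname,
          trunc_head = th, trunc_tail = tt,
          novel = novel_cl, novel_pos = novel_pos,
          stringsAsFactors = FALSE))
        pos <- pos + nchar(s)
        sp <- .make_spacer(spacer, kmers)
        parts <- paste0(parts, sp)
        pos <- pos + nchar(sp)
      }
      contigs[[ct]] <- parts
    }
    ## planted intervals are non-overlapping by construction (sequential
    ## append); verify anyway
    for (ct in unique(truth$contig)) {
      tt <- truth[truth$contig == ct, , drop = FALSE]
      tt <- tt[order(tt$start), , drop = FALSE]
      if (nrow(tt) > 1L &&
          any(utils::head(tt$end, -1) > utils::tail(tt$start, -1)))
        stop("internal error: overlapping plants")
    }
    list(contigs = contigs, truth = truth)
  })
}

#' Write contigs as a FASTA file
#' @param contigs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path) {
  writeLines(paste0(">", names(contigs), "\n", unname(contigs)), path)
  invisible(path)
}
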