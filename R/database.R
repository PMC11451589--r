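## Allele database: per-gene wildtype + exon model, every allele's genomic
## sequence (inferred from a backbone for cDNA-only alleles) and its
## variant set against the wildtype, split into core and silent, plus the
## per-gene core-position index.

#' Construct a gene definition
#'
#' @param name Gene symbol (e.g. `"KIR2DL4"`).
#' @param wildtype_allele Allele identifier designated as the per-gene
#'   reference.
#' @param wildtype_seq Wildtype nucleotide string.
#' @param exons data.frame(start, end): coding exons, 0-based half-open on
#'   wildtype coordinates, sorted and non-overlapping.
#' @param phase CDS phase of the first coding exon (bases to skip, 0-2).
#' @param functional_utr data.frame(start, end) of expression-relevant UTR
#'   intervals (may be empty).
#' @param pseudogene Logical.
#' @return A `gene_def` object.
#' @export
gene_def <- function(name, wildtype_allele, wildtype_seq, exons,
                     phase = 0L, functional_utr = NULL, pseudogene = FALSE) {
  wildtype_seq <- toupper(wildtype_seq)
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons$start <- as.integer(exons$start); exons$end <- as.integer(exons$end)
  if (is.null(functional_utr))
    functional_utr <- data.frame(start = integer(), end = integer())
  n <- nchar(wildtype_seq)
  if (nrow(exons) == 0L) stop("gene ", name, ": no exons")
  if (any(exons$start >= exons$end) || any(exons$start < 0L) ||
      any(exons$end > n))
    stop("gene ", name, ": exon intervals outside [0, wildtype length)")
  if (is.unsorted(exons$start, strictly = TRUE) ||
      any(utils::head(exons$end, -1) > utils::tail(exons$start, -1)))
    stop("gene ", name, ": exons must be sorted and non-overlapping")
  g <- structure(list(name = name, wildtype_allele = wildtype_allele,
                      wildtype_seq = wildtype_seq, exons = exons,
                      phase = as.integer(phase),
                      functional_utr = functional_utr,
                      pseudogene = isTRUE(pseudogene)),
                 class = "gene_def")
  if (!g$pseudogene) {
    cds_len <- sum(exons$end - exons$start) - g$phase
    if (cds_len %% 3L != 0L)
      stop("gene ", name, ": CDS length not a multiple of 3 after phase")
  }
  g
}

#' @export
print.gene_def <- function(x, ...) {
  cat("Gene", x$name, if (x$pseudogene) "(pseudogene)" else "",
      "- wildtype", x$wildtype_allele, ",",
      nchar(x$wildtype_seq), "bp,", nrow(x$exons), "exons\n")
  invisible(x)
}

#' Numeric suffix of an allele name
#'
#' `"KIR2DL4*0050101"` has suffix 50101.  Used for deterministic
#' tie-breaking throughout.
#'
#' @param name Allele name(s), `GENE*NNN` form.
#' @return Integer vector.
#' @export
allele_suffix <- function(name) {
  as.integer(sub(".*\\*", "", name))
}

allele_gene <- function(name) sub("\\*.*$", "", name)

#' Infer the genomic sequence of a cDNA-only allele
#'
#' Picks the backbone among the gene's genomic alleles whose spliced exon
#' sequence is closest to the cDNA by edit distance (ties: lowest allele
#' number), then substitutes the cDNA bases into the backbone's exons,
#' leaving introns untouched.  A cDNA whose length does not match the
#' chosen backbone's spliced length cannot be placed base-per-base and is
#' flagged (`NA` returned); callers exclude such alleles from mapping.
#'
#' @param cdna_seq cDNA nucleotide string.
#' @param gene A `gene_def`.
#' @param genomic_alleles Named character vector of genomic sequences
#'   (names are allele names) with at least one entry.
#' @param genomic_variants Optional named list of variant tables for the
#'   backbones (used to shift the wildtype exon table onto each backbone);
#'   defaults to treating each backbone as exon-structure-identical to the
#'   wildtype when lengths agree.
#' @return Genomic nucleotide string, or `NA_character_` when flagged.
#' @export
infer_genomic_sequence <- function(cdna_seq, gene, genomic_alleles,
                                   genomic_variants = NULL) {
  stopifnot(length(genomic_alleles) >= 1L)
  cdna_seq <- toupper(cdna_seq)
  exon_tbl <- function(nm) {
    v <- genomic_variants[[nm]]
    if (is.null(v)) gene$exons else shift_intervals(gene$exons, v)
  }
  spliced <- vapply(names(genomic_alleles), function(nm)
    .splice_cds(genomic_alleles[[nm]], exon_tbl(nm), 0L), character(1))
  d <- as.integer(utils::adist(cdna_seq, spliced))
  ord <- order(d, allele_suffix(names(genomic_alleles)))
  pick <- names(genomic_alleles)[ord[1]]
  backbone <- genomic_alleles[[pick]]
  ex <- exon_tbl(pick)
  if (nchar(cdna_seq) != sum(ex$end - ex$start)) {
    warning("cDNA allele length incompatible with backbone ", pick,
            " exon structure; allele flagged", call. = FALSE)
    return(NA_character_)
  }
  out <- backbone
  off <- 0L
  for (i in seq_len(nrow(ex))) {
    len <- ex$end[i] - ex$start[i]
    chunk <- substr(cdna_seq, off + 1L, off + len)
    out <- paste0(substr(out, 1L, ex$start[i]), chunk,
                  substr(out, ex$end[i] + 1L, nchar(out)))
    off <- off + len
  }
  out
}

#' Build the core-position index of a gene
#'
#' Union of the wildtype positions touched by any allele's core variants:
#' one position per SNP, one per deleted base, the anchor for an insertion.
#' This index is the denominator of the allele-scoring formula.
#'
#' @param alleles List of allele records (each with a classified `variants`
#'   table); flagged alleles are skipped.
#' @return Sorted unique integer vector of 0-based wildtype positions.
#' @export
build_core_index <- function(alleles) {
  pos <- integer()
  for (a in alleles) {
    if (isTRUE(a$flagged)) next
    v <- a$variants
    cv <- v[which(v$core), , drop = FALSE]
    for (i in seq_len(nrow(cv)))
      pos <- c(pos, variant_footprint(cv$pos[i], cv$ref[i], cv$alt[i]))
  }
  sort(unique(as.integer(pos)))
}

.make_allele <- function(name, gene, seq, kind, genomic_seq,
                         variants, flagged = FALSE) {
  list(name = name, gene = gene, seq = seq, kind = kind,
       genomic_seq = genomic_seq, variants = variants, flagged = flagged)
}

.finalize_db_gene <- function(def, raw_alleles, scoring) {
  ## raw_alleles: list(name=, seq=, kind=) -- wildtype must be genomic
  genomic <- Filter(function(a) a$kind == "genomic", raw_alleles)
  if (length(genomic) == 0L)
    stop("gene ", def$name, ": no genomic allele; cannot anchor wildtype")
  gseqs <- vapply(genomic, `[[`, character(1), "seq")
  names(gseqs) <- vapply(genomic, `[[`, character(1), "name")

  # variants of the genomic alleles first (needed to place cDNA exons)
  gvar <- lapply(gseqs, function(s)
    call_variants(def, s, scoring)$variants)

  alleles <- list()
  for (a in raw_alleles) {
    if (a$kind == "genomic") {
      alleles[[a$name]] <- .make_allele(a$name, def$name, a$seq, "genomic",
                                        a$seq, gvar[[a$name]])
    } else {
      gs <- infer_genomic_sequence(a$seq, def, gseqs, gvar)
      if (is.na(gs)) {
        alleles[[a$name]] <- .make_allele(a$name, def$name, a$seq, "cdna",
                                          NA_character_, empty_variants(),
                                          flagged = TRUE)
      } else {
        alleles[[a$name]] <- .make_allele(a$name, def$name, a$seq, "cdna",
                                          gs,
                                          call_variants(def, gs,
                                                        scoring)$variants)
      }
    }
  }
  alleles <- alleles[order(allele_suffix(names(alleles)))]
  list(def = def, alleles = alleles, core_index = build_core_index(alleles))
}

#' Load an allele database
#'
#' Two dialects are supported.  `fixture`: a directory holding
#' `alleles.fa` (headers `GENE*NNN kind=genomic|cdna`) and `genes.tsv`
#' (columns gene, wildtype, exons, phase, functional_utr, pseudogene;
#' interval lists are 1-based inclusive `start-end` comma-separated, `.`
#' for none).  `ipd_flatfile`: an EMBL-style flat file as distributed by
#' allele repositories (ID/DE/FT/SQ records); the lowest-numbered
#' full-length genomic allele of each gene is taken as wildtype.
#'
#' On load every allele receives a genomic sequence (cDNA-only alleles via
#' [infer_genomic_sequence()]), a classified variant table against the
#' gene wildtype, and each gene its core-position index.
#'
#' @param path Fixture directory or flat-file path.
#' @param dialect `"fixture"` or `"ipd_flatfile"`.
#' @param scoring Alignment scoring scheme for variant pre-computation.
#' @return A `kir_db` object: list of per-gene entries `def`, `alleles`,
#'   `core_index`.
#' @export
load_allele_db <- function(path, dialect = c("fixture", "ipd_flatfile"),
                           scoring = default_scoring()) {
  dialect <- match.arg(dialect)
  raw <- if (dialect == "fixture") .parse_fixture_db(path)
         else .parse_ipd_flatfile(path)
  genes <- lapply(raw, function(g)
    .finalize_db_gene(g$def, g$alleles, scoring))
  structure(list(genes = genes, scoring = scoring), class = "kir_db")
}

#' @export
print.kir_db <- function(x, ...) {
  n_all <- sum(vapply(x$genes, function(g) length(g$alleles), integer(1)))
  cat("Allele database:", length(x$genes), "genes,", n_all, "alleles\n")
  for (g in x$genes)
    cat("  ", g$def$name, ": ", length(g$alleles), " alleles, |core index| = ",
        length(g$core_index), "\n", sep = "")
  invisible(x)
}

#' All mappable allele sequences of a database
#'
#' @param db A `kir_db`.
#' @return Named character vector (names `GENE*NNN`) of genomic sequences,
#'   excluding flagged alleles.
#' @export
db_allele_seqs <- function(db) {
  out <- character()
  for (g in db$genes)
    for (a in g$alleles)
      if (!isTRUE(a$flagged)) out[a$name] <- a$genomic_seq
  out
}

.parse_intervals <- function(x) {
  ## file syntax is 1-based inclusive "s-e,s-e"; internal 0-based half-open
  if (is.na(x) || x == "." || x == "")
    return(data.frame(start = integer(), end = integer()))
  parts <- strsplit(strsplit(x, ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
  data.frame(start = vapply(parts, function(p) as.integer(p[1]), 1L) - 1L,
             end = vapply(parts, function(p) as.integer(p[2]), 1L))
}

.format_intervals <- function(iv) {
  if (nrow(iv) == 0L) return(".")
  paste0(iv$start + 1L, "-", iv$end, collapse = ",")
}

.parse_fixture_db <- function(dir) {
  fa <- file.path(dir, "alleles.fa")
  tsv <- file.path(dir, "genes.tsv")
  if (!file.exists(fa) || !file.exists(tsv))
    stop("fixture database needs ", fa, " and ", tsv)
  seqs <- Biostrings::readDNAStringSet(fa)
  meta <- utils::read.delim(tsv, stringsAsFactors = FALSE,
                            colClasses = "character")
  need <- c("gene", "wildtype", "exons", "phase", "functional_utr",
            "pseudogene")
  if (!all(need %in% names(meta)))
    stop("genes.tsv (", tsv, "): missing columns ",
         paste(setdiff(need, names(meta)), collapse = ", "))

  hdr <- names(seqs)
  allele <- sub("\\s.*$", "", hdr)
  kind <- ifelse(grepl("kind=cdna", hdr), "cdna",
                 ifelse(grepl("kind=genomic", hdr), "genomic", NA))
  if (anyNA(kind))
    stop("alleles.fa (", fa, "): header without kind= tag: ",
         hdr[which(is.na(kind))[1]])
  bad <- !grepl("^[^*]+\\*[0-9]+$", allele)
  if (any(bad))
    stop("alleles.fa (", fa, "): malformed allele name: ",
         allele[which(bad)[1]])

  out <- list()
  for (i in seq_len(nrow(meta))) {
    gname <- meta$gene[i]
    idx <- which(allele_gene(allele) == gname)
    if (length(idx) == 0L) stop("gene ", gname, " has no alleles in ", fa)
    wt_name <- meta$wildtype[i]
    wt_i <- idx[allele[idx] == wt_name]
    if (length(wt_i) != 1L || kind[wt_i] != "genomic")
      stop("gene ", gname, ": wildtype ", wt_name,
           " missing or not genomic in ", fa)
    def <- gene_def(gname, wt_name, as.character(seqs[[wt_i]]),
                    .parse_intervals(meta$exons[i]),
                    phase = as.integer(meta$phase[i]),
                    functional_utr = .parse_intervals(meta$functional_utr[i]),
                    pseudogene = meta$pseudogene[i] %in% c("1", "TRUE",
                                                           "true"))
    out[[gname]] <- list(
      def = def,
      alleles = lapply(idx, function(j)
        list(name = allele[j], seq = as.character(seqs[[j]]),
             kind = kind[j])))
  }
  out
}

#' Write a database in the fixture dialect
#'
#' Serializes a loaded database back to `alleles.fa` + `genes.tsv`
#' (genomic sequences for every non-flagged allele; flagged cDNA alleles
#' keep their cDNA sequence and tag).  Reloading yields identical variant
#' sets and core indices, which makes the dump usable as a cache.
#'
#' @param db A `kir_db`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_allele_db <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- character(); meta <- NULL
  for (g in db$genes) {
    for (a in g$alleles) {
      if (isTRUE(a$flagged)) {
        fa <- c(fa, paste0(">", a$name, " kind=cdna"), a$seq)
      } else {
        fa <- c(fa, paste0(">", a$name, " kind=", a$kind),
                if (a$kind == "cdna") a$seq else a$genomic_seq)
      }
    }
    d <- g$def
    meta <- rbind(meta, data.frame(
      gene = d$name, wildtype = d$wildtype_allele,
      exons = .format_intervals(d$exons), phase = d$phase,
      functional_utr = .format_intervals(d$functional_utr),
      pseudogene = as.integer(d$pseudogene), stringsAsFactors = FALSE))
  }
  writeLines(fa, file.path(dir, "alleles.fa"))
  utils::write.table(meta, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
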