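## Allele calling: core-variant-first distance.  For each gene the core
## position index (union of all alleles' core-variant footprints) defines
## the comparison universe; a candidate allele and the assembly copy are
## compared nucleotide-by-nucleotide at those positions (Hamming), the
## count is normalized by the index size and the number of novel core
## variants in the copy is added.  Silent variants only ever break ties,
## via Jaccard distance on exact variant identity.

.implied_tokens <- function(variants, positions, wildtype) {
  tok <- substring(wildtype, positions + 1L, positions + 1L)
  names(tok) <- as.character(positions)
  if (nrow(variants) == 0L) return(tok)
  for (i in seq_len(nrow(variants))) {
    p <- variants$pos[i]; ref <- variants$ref[i]; alt <- variants$alt[i]
    if (ref == "") {                    # insertion marks its anchor
      hit <- match(as.character(p), names(tok))
      if (!is.na(hit)) tok[hit] <- paste0(tok[hit], "+", alt)
    } else if (alt == "") {             # deletion marks every base
      for (fp in variant_footprint(p, ref, alt)) {
        hit <- match(as.character(fp), names(tok))
        if (!is.na(hit)) tok[hit] <- "-"
      }
    } else {
      hit <- match(as.character(p), names(tok))
      if (!is.na(hit)) tok[hit] <- sub("^.", alt, tok[hit])
    }
  }
  tok
}

#' Score a candidate allele against a gene copy
#'
#' Implements the core-variant Hamming score: `h / |index| + n`, where `h`
#' counts index positions at which the nucleotide implied by the allele's
#' variant set differs from the one implied by the copy's (the wildtype
#' base when neither is touched; each position of an indel independently),
#' and `n` is the number of novel core variants in the copy -- core
#' variants whose footprint lies entirely outside the index.  When the
#' index is empty the ratio is defined as 0.
#'
#' @param copy_variants Classified variant table of the assembly copy.
#' @param allele An allele record (from a `kir_db` gene entry).
#' @param index Core-position index (sorted 0-based positions).
#' @param gene The `gene_def` the index was built for.
#' @return An `allele_score`: list with `allele_name`, `core_score`,
#'   `silent_jaccard`, `missing_core` and `novel_core` (1-based rendered
#'   variants).
#' @export
score_allele <- function(copy_variants, allele, index, gene) {
  if (!identical(allele$gene, gene$name))
    stop("allele ", allele$name, " does not belong to gene ", gene$name)
  av <- allele$variants
  cv <- copy_variants
  h <- 0L
  if (length(index) > 0L) {
    ta <- .implied_tokens(av, index, gene$wildtype_seq)
    tc <- .implied_tokens(cv, index, gene$wildtype_seq)
    h <- sum(ta != tc)
  }
  copy_core <- cv[which(cv$core), , drop = FALSE]
  novel <- logical(nrow(copy_core))
  for (i in seq_len(nrow(copy_core)))
    novel[i] <- !any(variant_footprint(copy_core$pos[i], copy_core$ref[i],
                                       copy_core$alt[i]) %in% index)
  n_novel <- sum(novel)
  core_ratio <- if (length(index) > 0L) h / length(index) else 0
  allele_core <- av[which(av$core), , drop = FALSE]
  missing <- allele_core[!(variant_key(allele_core) %in% variant_key(cv)), ,
                         drop = FALSE]
  structure(list(
    allele_name = allele$name,
    core_score = core_ratio + n_novel,
    silent_jaccard = silent_jaccard(cv, av),
    missing_core = format_variants(missing),
    novel_core = format_variants(copy_core[novel, , drop = FALSE])),
    class = "allele_score")
}

#' Jaccard distance between silent variant sets
#'
#' `1 - |A n B| / |A u B|` on exact variant identity (pos, ref, alt) of
#' the silent (non-core) variants; two empty sets have distance 0.
#'
#' @param a,b Classified variant tables (full tables; core rows are
#'   dropped internally) or plain character vectors of variant keys.
#' @return Numeric in `[0, 1]`.
#' @export
silent_jaccard <- function(a, b) {
  keyize <- function(x) {
    if (is.data.frame(x)) variant_key(x[which(!x$core), , drop = FALSE])
    else as.character(x)
  }
  ka <- unique(keyize(a)); kb <- unique(keyize(b))
  u <- length(union(ka, kb))
  if (u == 0L) return(0)
  1 - length(intersect(ka, kb)) / u
}

#' Call the closest allele for a gene copy
#'
#' Candidates are ranked by `(core_score, silent_jaccard, numeric allele
#' suffix)` ascending; the first is the call and (up to) the top 5 are
#' retained for reporting.  Flagged alleles (cDNA that could not be placed
#' on a genomic backbone) are excluded.
#'
#' @param copy_variants Classified variant table of the copy.
#' @param db_gene A gene entry of a `kir_db` (`def`, `alleles`,
#'   `core_index`).
#' @return list with `call` (allele name) and `scores` (data.frame of the
#'   ranked top 5: allele, core_score, silent_jaccard, n_missing_core,
#'   n_novel_core, plus the rendered variant lists as list columns).
#' @export
call_allele <- function(copy_variants, db_gene) {
  cands <- Filter(function(a) !isTRUE(a$flagged), db_gene$alleles)
  if (length(cands) == 0L) stop("gene ", db_gene$def$name,
                                ": no usable alleles")
  sc <- lapply(cands, function(a)
    score_allele(copy_variants, a, db_gene$core_index, db_gene$def))
  tbl <- data.frame(
    allele = vapply(sc, `[[`, character(1), "allele_name"),
    core_score = vapply(sc, `[[`, numeric(1), "core_score"),
    silent_jaccard = vapply(sc, `[[`, numeric(1), "silent_jaccard"),
    n_missing_core = vapply(sc, function(s) length(s$missing_core),
                            integer(1)),
    n_novel_core = vapply(sc, function(s) length(s$novel_core), integer(1)),
    stringsAsFactors = FALSE)
  tbl$missing_core <- lapply(sc, `[[`, "missing_core")
  tbl$novel_core <- lapply(sc, `[[`, "novel_core")
  ord <- order(tbl$core_score, tbl$silent_jaccard,
               allele_suffix(tbl$allele))
  tbl <- tbl[ord, , drop = FALSE]
  rownames(tbl) <- NULL
  list(call = tbl$allele[1],
       scores = utils::head(tbl, 5L))
}
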