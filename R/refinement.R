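## Region refinement: a prefix or suffix deletion in the called variants
## usually means the mapper clipped the gene during extraction rather than
## that the assembly truly lacks the gene head/tail.  The copy is
## re-extracted with bounds pushed outward by the net terminal indel
## length, variants are re-called, and whichever variant set is less
## complex is kept (ties keep the original for stability).  One refinement
## round only, which also makes the operation idempotent.

#' Does a variant set require boundary refinement?
#'
#' True iff some deletion's footprint includes wildtype position 0 or the
#' last wildtype position.
#'
#' @param variants Variant table.
#' @param wildtype_len Wildtype length.
#' @return Logical scalar.
#' @export
needs_refinement <- function(variants, wildtype_len) {
  del <- variants[variants$kind == "del", , drop = FALSE]
  if (nrow(del) == 0L) return(FALSE)
  any(del$pos == 0L) ||
    any(del$pos + nchar(del$ref) == wildtype_len)
}

#' Complexity of a variant set
#'
#' Lexicographic pair: number of variants, then total edited bases
#' (`sum(max(|ref|, |alt|))`).  Smaller is less complex.
#'
#' @param variants Variant table.
#' @return Numeric vector of length 2.
#' @export
complexity <- function(variants) {
  c(nrow(variants),
    if (nrow(variants) == 0L) 0L
    else sum(pmax(nchar(variants$ref), nchar(variants$alt))))
}

#' Is complexity `a` strictly less than `b`?
#' @param a,b Complexity pairs from [complexity()].
#' @return Logical scalar.
#' @export
complexity_less <- function(a, b) {
  a[1] < b[1] || (a[1] == b[1] && a[2] < b[2])
}

.terminal_dels <- function(variants, wildtype_len) {
  del <- variants[variants$kind == "del", , drop = FALSE]
  pre <- del[del$pos == 0L, , drop = FALSE]
  suf <- del[del$pos + nchar(del$ref) == wildtype_len, , drop = FALSE]
  ins <- variants[variants$kind == "ins", , drop = FALSE]
  list(prefix = if (nrow(pre)) nchar(pre$ref[1]) else 0L,
       suffix = if (nrow(suf)) nchar(suf$ref[1]) else 0L,
       # insertions anchored at the extreme wildtype bases absorb part of
       # the apparent clipping
       prefix_ins = sum(nchar(ins$alt[ins$pos == 0L])),
       suffix_ins = sum(nchar(ins$alt[ins$pos == wildtype_len - 1L])))
}

#' Refine a gene copy with terminal deletions
#'
#' When [needs_refinement()] holds, the copy bounds are extended outward
#' by the net terminal indel length (prefix-deletion length minus prefix
#' insertions; symmetrically for the suffix), clamped to the contig, the
#' sequence is re-extracted and variants re-called.  The refined variant
#' set replaces the original only when strictly less complex; otherwise
#' the original bounds and variants are kept (a genuinely truncated gene
#' re-calls the same terminal deletion and ties).
#'
#' @param copy A `gene_copy` with `variants` filled in.
#' @param gene A `gene_def`.
#' @param contigs Named character vector of assembly contigs.
#' @param scoring Alignment scoring scheme.
#' @return The (possibly refined) `gene_copy`.
#' @export
refine_gene_copy <- function(copy, gene, contigs, scoring = default_scoring()) {
  wl <- nchar(gene$wildtype_seq)
  if (!needs_refinement(copy$variants, wl)) return(copy)
  td <- .terminal_dels(copy$variants, wl)
  ext5 <- max(0L, td$prefix - td$prefix_ins)   # gene 5' side
  ext3 <- max(0L, td$suffix - td$suffix_ins)
  if (copy$strand == "+") {
    ns <- copy$start - ext5; ne <- copy$end + ext3
  } else {
    ns <- copy$start - ext3; ne <- copy$end + ext5
  }
  clen <- nchar(contigs[[copy$contig]])
  if (ns < 0L || ne > clen) {
    warning("refined bounds clamped to contig ", copy$contig, call. = FALSE)
    ns <- max(0L, ns); ne <- min(clen, ne)
  }
  seq2 <- extract_copy_seq(contigs, copy$contig, ns, ne, copy$strand)
  cv <- call_variants(gene, seq2, scoring)
  if (complexity_less(complexity(cv$variants), complexity(copy$variants))) {
    # trim the re-extraction to the aligned target span
    ts <- cv$aln$target_start; te <- cv$aln$target_end
    if (copy$strand == "+") {
      copy$start <- as.integer(ns + ts); copy$end <- as.integer(ns + te)
    } else {
      copy$start <- as.integer(ne - te); copy$end <- as.integer(ne - ts)
    }
    copy$seq <- substr(seq2, ts + 1L, te)
    copy$variants <- cv$variants
  }
  copy
}
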