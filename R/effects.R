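## Coding-consequence classification.
##
## The gene model is deliberately simple: the exon table holds the coding
## exons (CDS = concatenated exon sequence, minus `phase` leading bases of
## the first exon); positions between exons are intronic; positions outside
## the exon span are UTR, functional only when covered by a declared
## functional-UTR interval.  Each variant is applied to the wildtype
## INDEPENDENTLY -- compound effects of co-occurring variants are not
## evaluated jointly.

.splice_cds <- function(seq, exons, phase = 0L) {
  parts <- vapply(seq_len(nrow(exons)), function(i)
    substr(seq, exons$start[i] + 1L, exons$end[i]), character(1))
  cds <- paste0(parts, collapse = "")
  if (phase > 0L) cds <- substr(cds, phase + 1L, nchar(cds))
  cds
}

.translate_cds <- function(cds) {
  n3 <- (nchar(cds) %/% 3L) * 3L
  if (n3 < 3L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1L, n3)),
    no.init.codon = TRUE, if.fuzzy.codon = "X"))
}

.first_stop <- function(prot) {
  hit <- regexpr("*", prot, fixed = TRUE)
  if (hit < 0L) Inf else as.integer(hit)
}

.trunc_at_stop <- function(prot) sub("\\*.*$", "", prot)

.in_intervals <- function(pos, iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(rep(FALSE, length(pos)))
  vapply(pos, function(p) any(p >= iv$start & p < iv$end), logical(1))
}

#' Classify the functional effect of one variant
#'
#' Applies the variant alone to the gene wildtype, re-splices the CDS from
#' the shifted exon table, translates it with the standard genetic code and
#' compares proteins (truncated at the first stop).  Effects: `missense`,
#' `nonsense` (premature stop), `frameshift` (exonic indel of length not
#' divisible by 3), `start_loss`, `synonymous`, `intronic`,
#' `utr_functional` (inside a declared expression-relevant UTR interval,
#' core) and `utr_silent`.  A variant downstream of the wildtype stop is
#' synonymous unless it falls in a functional UTR interval.
#'
#' @param pos,ref,alt A single variant in 0-based wildtype coordinates.
#' @param gene A `gene_def` (see [gene_def()]).
#' @return Effect label (character scalar).
#' @export
classify_effect <- function(pos, ref, alt, gene) {
  wt <- gene$wildtype_seq
  fp <- variant_footprint(pos, ref, alt)
  if (any(fp < 0L) || any(fp >= nchar(wt)))
    stop("variant footprint outside wildtype bounds")

  if (any(.in_intervals(fp, gene$functional_utr)))
    return("utr_functional")

  exons <- gene$exons
  if (ref == "") {
    # inserted bases are exonic when they land strictly inside an exon
    exonic_n <- if (any(pos >= exons$start & pos + 1L < exons$end))
      nchar(alt) else 0L
  } else {
    exonic_n <- sum(.in_intervals(fp, exons))
  }

  if (exonic_n == 0L) {
    span <- c(min(exons$start), max(exons$end))
    if (all(fp >= span[1] & fp < span[2])) return("intronic")
    return("utr_silent")
  }

  ## coding path: mutate, shift exons, splice, translate
  v <- variant_table(pos, ref, alt)
  mut <- apply_variants(wt, v)
  ex2 <- shift_intervals(exons, v)
  wt_cds <- .splice_cds(wt, exons, gene$phase)
  mut_cds <- .splice_cds(mut, ex2, gene$phase)

  if (substr(wt_cds, 1L, 3L) == "ATG" && substr(mut_cds, 1L, 3L) != "ATG")
    return("start_loss")

  indel_delta <- if (ref == "") nchar(alt) else if (alt == "") -exonic_n else 0L
  if (indel_delta %% 3L != 0L) return("frameshift")

  wt_prot <- .translate_cds(wt_cds)
  mut_prot <- .translate_cds(mut_cds)
  wt_stop <- .first_stop(wt_prot)
  mut_stop <- .first_stop(mut_prot)
  # where the stop would sit if the (in-frame) edit did not create one
  expected_stop <- wt_stop + indel_delta / 3L
  if (mut_stop < expected_stop) return("nonsense")
  if (.trunc_at_stop(mut_prot) != .trunc_at_stop(wt_prot)) return("missense")
  "synonymous"
}

#' Classify every variant in a table
#'
#' @param variants Variant table.
#' @param gene A `gene_def`.
#' @return The table with `effect` and `core` filled in (`core` is true for
#'   missense, nonsense, frameshift, start-loss and functional-UTR
#'   variants).
#' @export
classify_effects <- function(variants, gene) {
  if (nrow(variants) == 0L) return(variants)
  variants$effect <- vapply(seq_len(nrow(variants)), function(i)
    classify_effect(variants$pos[i], variants$ref[i], variants$alt[i], gene),
    character(1))
  variants$core <- variants$effect %in% CORE_EFFECTS
  variants
}

#' Align a target to the gene wildtype and call classified variants
#'
#' Convenience wrapper: [semiglobal_align()] then [extract_variants()] then
#' [classify_effects()].
#'
#' @param gene A `gene_def`.
#' @param target Nucleotide string (e.g. an extracted assembly copy or a
#'   database allele).
#' @param scoring Alignment scoring scheme.
#' @return list with `variants` (classified table) and `aln`.
#' @export
call_variants <- function(gene, target, scoring = default_scoring()) {
  aln <- semiglobal_align(gene$wildtype_seq, target, scoring)
  v <- classify_effects(extract_variants(aln), gene)
  list(variants = v, aln = aln)
}
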