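## Variant tables: one row per difference against the gene wildtype.
## Internal coordinates are 0-based; `pos` is the first wildtype base of a
## SNP/deletion, or the wildtype base immediately PRECEDING an insertion
## (the insertion's anchor).  User-facing renderings are 1-based.

CORE_EFFECTS <- c("missense", "nonsense", "frameshift", "start_loss",
                  "utr_functional")
SILENT_EFFECTS <- c("synonymous", "intronic", "utr_silent")

#' Construct a variant table
#'
#' @param pos Integer vector, 0-based wildtype coordinates (anchor for
#'   insertions).
#' @param ref Wildtype bases (`""` for an insertion).
#' @param alt Observed bases (`""` for a deletion).
#' @param effect Optional effect labels (see [classify_effects()]).
#' @param core Optional logical core flags.
#' @return data.frame with columns pos, ref, alt, kind, effect, core.
#' @export
variant_table <- function(pos = integer(), ref = character(),
                          alt = character(), effect = NA_character_,
                          core = NA) {
  stopifnot(length(pos) == length(ref), length(ref) == length(alt))
  kind <- ifelse(ref == "", "ins", ifelse(alt == "", "del", "snp"))
  bad <- kind == "snp" & (nchar(ref) != 1L | nchar(alt) != 1L)
  if (any(bad))
    stop("substitutions must be single-base; split multi-base mismatches")
  data.frame(pos = as.integer(pos), ref = as.character(ref),
             alt = as.character(alt), kind = kind,
             effect = rep_len(as.character(effect), length(pos)),
             core = rep_len(as.logical(core), length(pos)),
             stringsAsFactors = FALSE)
}

empty_variants <- function() variant_table()

#' Footprint of a variant on wildtype coordinates
#'
#' A SNP touches one position, a deletion one position per deleted base,
#' an insertion only its anchor.
#'
#' @param pos,ref,alt Fields of a single variant.
#' @return Integer vector of 0-based wildtype positions.
#' @export
variant_footprint <- function(pos, ref, alt) {
  if (ref == "") return(as.integer(pos))          # insertion: anchor only
  seq.int(pos, pos + nchar(ref) - 1L)
}

variant_key <- function(v) {
  if (nrow(v) == 0L) return(character())
  paste0(v$pos, ":", v$ref, ">", v$alt)
}

#' Render variants as 1-based "pos REF>ALT" strings
#'
#' Insertions render as `pos ->ALT`, deletions as `pos REF>-`, matching the
#' human-readable convention of the YAML report (a SNP at internal 0-based
#' 10520 prints as `10521 C>G`).
#'
#' @param v Variant table.
#' @return Character vector.
#' @export
format_variants <- function(v) {
  if (nrow(v) == 0L) return(character())
  ref <- ifelse(v$ref == "", "-", v$ref)
  alt <- ifelse(v$alt == "", "-", v$alt)
  # insertions are anchored on the preceding base; print that base's 1-based
  # coordinate, SNP/deletion print their first affected base
  paste0(v$pos + 1L, " ", ref, ">", alt)
}

#' Apply a variant table to a sequence
#'
#' Variants must have disjoint footprints (as produced by
#' [extract_variants()]); they are applied right-to-left so original
#' coordinates stay valid.
#'
#' @param seq Wildtype nucleotide string.
#' @param variants Variant table in wildtype coordinates.
#' @return Edited nucleotide string.
#' @export
apply_variants <- function(seq, variants) {
  if (nrow(variants) == 0L) return(seq)
  ord <- order(variants$pos, decreasing = TRUE)
  for (i in ord) {
    p <- variants$pos[i]        # 0-based
    ref <- variants$ref[i]; alt <- variants$alt[i]
    if (ref == "") {            # insertion after base p
      seq <- paste0(substr(seq, 1L, p + 1L), alt,
                    substr(seq, p + 2L, nchar(seq)))
    } else {
      stopifnot(substr(seq, p + 1L, p + nchar(ref)) == ref)
      seq <- paste0(substr(seq, 1L, p), alt,
                    substr(seq, p + nchar(ref) + 1L, nchar(seq)))
    }
  }
  seq
}

#' Lift a wildtype coordinate through a variant table
#'
#' Maps a 0-based boundary coordinate on the wildtype to the corresponding
#' coordinate on the edited sequence (positions inside a deletion collapse
#' onto its start).  Used to shift exon tables when a variant is applied.
#'
#' @param x Integer vector of 0-based coordinates (interval bounds).
#' @param variants Variant table.
#' @return Shifted integer vector.
#' @export
lift_coord <- function(x, variants) {
  out <- as.integer(x)
  if (nrow(variants) == 0L) return(out)
  for (i in seq_len(nrow(variants))) {
    p <- variants$pos[i]
    ref <- variants$ref[i]; alt <- variants$alt[i]
    if (ref == "") {                      # insertion of nchar(alt) after p
      out <- out + ifelse(x > p, nchar(alt), 0L)
    } else if (alt == "") {               # deletion of nchar(ref) at p
      L <- nchar(ref)
      out <- out - ifelse(x >= p + L, L, pmax(0L, x - p))
    }
  }
  as.integer(out)
}

shift_intervals <- function(iv, variants) {
  if (nrow(iv) == 0L) return(iv)
  iv$start <- lift_coord(iv$start, variants)
  iv$end <- lift_coord(iv$end, variants)
  iv
}

## Left-align one indel: shift to the smallest wildtype position that
## preserves the edited sequence (classical VCF-style normalization).
## `floor` is the smallest wildtype position the indel may touch -- the
## position just past the previous variant's footprint -- so that shifting
## never crosses another edit (which would make the variants of one
## alignment non-independent).
.left_align_one <- function(wt, pos, ref, alt, floor = 0L) {
  if (ref == "") {                        # insertion after `pos`
    s <- alt
    # inserting S after wt[pos] equals inserting rot-right(S) after
    # wt[pos-1] whenever wt[pos] == last base of S; the examined context
    # base wt[pos] must itself be unedited (pos >= floor)
    while (pos >= max(1L, floor) &&
           substr(wt, pos + 1L, pos + 1L) == substr(s, nchar(s), nchar(s))) {
      s <- paste0(substr(s, nchar(s), nchar(s)),
                  substr(s, 1L, nchar(s) - 1L))
      pos <- pos - 1L
    }
    list(pos = pos, ref = "", alt = s)
  } else {                                # deletion of `ref` at `pos`
    L <- nchar(ref)
    while (pos > floor &&
           substr(wt, pos, pos) == substr(wt, pos + L, pos + L)) {
      pos <- pos - 1L
    }
    list(pos = pos, ref = substr(wt, pos + 1L, pos + L), alt = "")
  }
}

#' Extract variants from a semi-global alignment
#'
#' Walks the alignment operations and emits one SNP per mismatched base,
#' one insertion per contiguous inserted run (anchored at the preceding
#' wildtype position) and one deletion per contiguous deleted run.  Indels
#' are left-aligned.  Effects are left unset; see [classify_effects()].
#'
#' @param aln A `pairwise_alignment` from [semiglobal_align()].
#' @return Variant table (effect/core `NA`).
#' @export
extract_variants <- function(aln) {
  wt <- aln$ref; tg <- aln$target
  i <- 0L                       # wildtype cursor (0-based)
  j <- aln$target_start         # target cursor
  floor <- 0L                   # first position the next indel may touch
  pos <- integer(); ref <- character(); alt <- character()
  for (k in seq_len(nrow(aln$ops))) {
    op <- aln$ops$op[k]; len <- aln$ops$len[k]
    if (op == "=") {
      i <- i + len; j <- j + len
    } else if (op == "X") {
      for (b in seq_len(len)) {
        pos <- c(pos, i); ref <- c(ref, substr(wt, i + 1L, i + 1L))
        alt <- c(alt, substr(tg, j + 1L, j + 1L))
        i <- i + 1L; j <- j + 1L
      }
      floor <- i
    } else if (op == "I") {
      la <- .left_align_one(wt, i - 1L, "", substr(tg, j + 1L, j + len),
                            floor)
      pos <- c(pos, la$pos); ref <- c(ref, ""); alt <- c(alt, la$alt)
      floor <- la$pos + 1L
      j <- j + len
    } else {                    # D
      la <- .left_align_one(wt, i, substr(wt, i + 1L, i + len), "", floor)
      pos <- c(pos, la$pos); ref <- c(ref, la$ref); alt <- c(alt, "")
      floor <- la$pos + len
      i <- i + len
    }
  }
  v <- variant_table(pos, ref, alt)
  ## apply order at a shared position: substitution first, then insertion
  v[order(v$pos, match(v$kind, c("del", "snp", "ins"))), , drop = FALSE]
}
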