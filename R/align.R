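#' Default alignment scoring scheme
#'
#' Variant-calling-grade affine-gap parameters: match +1, mismatch -4,
#' gap open -6, gap extend -1 (a length-L gap costs `gap_open + L *
#' gap_extend`, so a 1-bp gap scores -7).  The high mismatch and open
#' penalties favour contiguous indels over scattered edits, which keeps
#' called variants parsimonious.
#'
#' @return A named list with integer fields `match`, `mismatch`,
#'   `gap_open`, `gap_extend` (penalties positive).
#' @export
default_scoring <- function() {
  list(match = 1L, mismatch = -4L, gap_open = 6L, gap_extend = 1L)
}

.check_sequence <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || !nzchar(x))
    stop(what, " must be a non-empty character scalar", call. = FALSE)
  x <- toupper(x)
  if (grepl("[^ACGTN]", x))
    stop(what, " contains non-IUPAC characters (allowed: A, C, G, T, N)",
         call. = FALSE)
  x
}

#' Semi-global pairwise alignment
#'
#' Aligns a reference sequence (typically a gene wildtype) against a target
#' (an extracted assembly region) with affine gap costs.  Every reference
#' base is accounted for -- a truncated target surfaces as penalized
#' terminal deletion runs -- while target overhangs beyond the aligned span
#' are free, so a region extraction that overshoots the gene costs nothing.
#'
#' @param ref Reference nucleotide string (alphabet A/C/G/T/N).
#' @param target Target nucleotide string.
#' @param scoring Scoring scheme, see [default_scoring()].
#' @return A `pairwise_alignment` object: list with `score` (integer),
#'   `ops` (data.frame of run-length CIGAR-style operations, `op` in
#'   `=`/`X`/`I`/`D` and `len`), `target_start`/`target_end` (0-based
#'   half-open span of the target actually aligned) and the two sequences.
#' @seealso [extract_variants()]
#' @export
semiglobal_align <- function(ref, target, scoring = default_scoring()) {
  ref <- .check_sequence(ref, "ref")
  target <- .check_sequence(target, "target")
  res <- .semiglobal_align_cpp(ref, target,
                               as.integer(scoring$match),
                               as.integer(scoring$mismatch),
                               as.integer(scoring$gap_open),
                               as.integer(scoring$gap_extend))
  structure(list(
    score = as.integer(res$score),
    ops = data.frame(op = as.character(res$op), len = as.integer(res$len),
                     stringsAsFactors = FALSE),
    target_start = as.integer(res$target_start),
    target_end = as.integer(res$target_end),
    ref = ref, target = target
  ), class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Semi-global alignment: score", x$score,
      " target span [", x$target_start, ",", x$target_end, ")\n", sep = "")
  cat("  CIGAR:", alignment_cigar(x), "\n")
  invisible(x)
}

#' CIGAR string of an alignment
#'
#' @param aln A `pairwise_alignment`.
#' @return Single string, e.g. `"120=1X30=3D50="`.
#' @export
alignment_cigar <- function(aln) {
  paste0(aln$ops$len, aln$ops$op, collapse = "")
}

#' Number of matched bases in an alignment
#' @param aln A `pairwise_alignment`.
#' @return Integer count of `=` bases.
#' @export
alignment_matches <- function(aln) {
  sum(aln$ops$len[aln$ops$op == "="])
}
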