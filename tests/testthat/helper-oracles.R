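# Independent oracles used to cross-check the package implementation.
# Each is written from the definition, not by calling the code under test.

# Brute-force affine-gap semi-global DP, score only.  Free terminal gaps in
# the target; every reference base consumed (terminal reference deletions
# penalized).  Gap of length L costs open + L * extend.
oracle_semiglobal_score <- function(ref, target, scoring = list(
    match = 1, mismatch = -4, gap_open = 6, gap_extend = 1)) {
  a <- strsplit(ref, "")[[1]]
  b <- strsplit(target, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  D <- matrix(NEG, n + 1, m + 1)
  I <- matrix(NEG, n + 1, m + 1)
  M[1, ] <- 0
  for (i in 2:(n + 1))
    D[i, 1] <- -(scoring$gap_open + scoring$gap_extend * (i - 1))
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (a[i - 1] == "N" || b[j - 1] == "N") scoring$mismatch
           else if (a[i - 1] == b[j - 1]) scoring$match else scoring$mismatch
      M[i, j] <- max(M[i - 1, j - 1], D[i - 1, j - 1], I[i - 1, j - 1]) + s
      D[i, j] <- max(
        max(M[i - 1, j], I[i - 1, j]) - scoring$gap_open - scoring$gap_extend,
        D[i - 1, j] - scoring$gap_extend)
      I[i, j] <- max(
        max(M[i, j - 1], D[i, j - 1]) - scoring$gap_open - scoring$gap_extend,
        I[i, j - 1] - scoring$gap_extend)
    }
  }
  max(M[n + 1, ], D[n + 1, ], I[n + 1, ])
}

# Apply a variant table to a sequence using character vectors: each
# original position carries its replacement string; deletions blank it,
# insertions append after the anchor.
oracle_apply_variants <- function(seq, variants) {
  ch <- strsplit(seq, "")[[1]]
  out <- as.list(ch)
  for (i in seq_len(nrow(variants))) {
    p <- variants$pos[i]; ref <- variants$ref[i]; alt <- variants$alt[i]
    if (ref == "") {
      out[[p + 1]] <- paste0(out[[p + 1]], alt)
    } else if (alt == "") {
      for (q in p:(p + nchar(ref) - 1)) out[[q + 1]] <- ""
    } else {
      out[[p + 1]] <- alt
    }
  }
  paste0(unlist(out), collapse = "")
}

# Position-by-position core scoring oracle.  Builds, for each variant set,
# an annotation of every index position: the base seen there ("-" if
# deleted, base+inserted-suffix if an insertion is anchored there), then
# counts disagreements, divides by |index| and adds the number of copy
# core variants whose whole footprint avoids the index.
oracle_core_score <- function(copy_variants, allele_variants, index, wt) {
  annotate <- function(v) {
    sapply(index, function(p) {
      base <- substr(wt, p + 1, p + 1)
      for (i in seq_len(nrow(v))) {
        if (v$ref[i] == "") {
          if (v$pos[i] == p) base <- paste0(base, "+", v$alt[i])
        } else if (v$alt[i] == "") {
          if (p >= v$pos[i] && p < v$pos[i] + nchar(v$ref[i])) base <- "-"
        } else if (v$pos[i] == p) {
          base <- sub("^.", v$alt[i], base)
        }
      }
      base
    })
  }
  h <- if (length(index) == 0) 0 else
    sum(annotate(allele_variants) != annotate(copy_variants))
  cc <- copy_variants[copy_variants$core %in% TRUE, , drop = FALSE]
  n_novel <- 0
  for (i in seq_len(nrow(cc))) {
    fp <- if (cc$ref[i] == "") cc$pos[i] else
      cc$pos[i]:(cc$pos[i] + nchar(cc$ref[i]) - 1)
    if (!any(fp %in% index)) n_novel <- n_novel + 1
  }
  (if (length(index) > 0) h / length(index) else 0) + n_novel
}

# Independent mutate-splice-translate: protein of `seq` spliced over
# `exons` (0-based half-open), translated via the standard genetic code,
# truncated at the first stop.
oracle_protein <- function(seq, exons, phase = 0) {
  cds <- paste0(mapply(function(s, e) substr(seq, s + 1, e),
                       exons$start, exons$end),
                collapse = "")
  cds <- substr(cds, phase + 1, nchar(cds))
  n3 <- (nchar(cds) %/% 3) * 3
  codons <- substring(cds, seq(1, n3, 3), seq(3, n3, 3))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  prot <- paste0(aa, collapse = "")
  sub("\\*.*$", "", prot)
}

# random variant table generator for property tests (footprints disjoint)
random_variant_set <- function(wt, n_max = 4, core_prob = 0.5) {
  n <- sample(0:n_max, 1)
  used <- integer()
  rows <- NULL
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(n)) {
    for (try in 1:50) {
      kind <- sample(c("snp", "ins", "del"), 1)
      p <- sample(0:(nchar(wt) - 5), 1)
      fp <- if (kind == "del") p:(p + sample(1:3, 1) - 1) else p
      if (any(fp %in% used)) next
      used <- c(used, (min(fp) - 1):(max(fp) + 1))
      if (kind == "snp") {
        ref <- substr(wt, p + 1, p + 1)
        rows <- rbind(rows, data.frame(
          pos = p, ref = ref, alt = sample(setdiff(bases, ref), 1),
          kind = "snp", stringsAsFactors = FALSE))
      } else if (kind == "ins") {
        rows <- rbind(rows, data.frame(
          pos = p, ref = "",
          alt = paste0(sample(bases, sample(1:3, 1), TRUE), collapse = ""),
          kind = "ins", stringsAsFactors = FALSE))
      } else {
        rows <- rbind(rows, data.frame(
          pos = p, ref = substr(wt, min(fp) + 1, max(fp) + 1), alt = "",
          kind = "del", stringsAsFactors = FALSE))
      }
      break
    }
  }
  if (is.null(rows))
    return(variant_table())
  rows <- rows[order(rows$pos), , drop = FALSE]
  out <- variant_table(rows$pos, rows$ref, rows$alt)
  out$core <- sample(c(TRUE, FALSE), nrow(out), TRUE,
                     prob = c(core_prob, 1 - core_prob))
  out$effect <- ifelse(out$core, "missense", "synonymous")
  out
}

random_seq <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
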