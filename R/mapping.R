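## Locus discovery, stage 1: map every database allele onto the assembly.
## The mapper is a pluggable contract producing PAF-like records; the
## builtin deterministic k-mer seed + extension mapper needs no external
## binary and is what the test suite runs.  A minimap2 adapter is provided
## for real assemblies and falls back to the builtin mapper with a warning
## when the binary is missing.

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.kmerize <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  substring(seq, 1:(n - k + 1L), k:n)
}

empty_mappings <- function() {
  data.frame(allele = character(), gene = character(), contig = character(),
             start = integer(), end = integer(), strand = character(),
             score = numeric(), clip5 = integer(), clip3 = integer(),
             stringsAsFactors = FALSE)
}

## Seed hits of one oriented query against one contig index, clustered by
## diagonal and contig proximity into candidate mappings.
.cluster_hits <- function(qpos, cpos, qlen, k, diag_band = 50L,
                          max_gap = 1000L) {
  d <- cpos - qpos
  ord <- order(d, cpos)
  d <- d[ord]; qpos <- qpos[ord]; cpos <- cpos[ord]
  grp <- cumsum(c(1L, diff(d) > diag_band))
  out <- NULL
  for (g in unique(grp)) {
    sel <- grp == g
    cp <- cpos[sel]; qp <- qpos[sel]
    o2 <- order(cp)
    cp <- cp[o2]; qp <- qp[o2]
    sub <- cumsum(c(1L, diff(cp) > max_gap))
    for (s in unique(sub)) {
      s2 <- sub == s
      out <- rbind(out, data.frame(
        start = min(cp[s2]), end = max(cp[s2]) + k,
        clip5 = min(qp[s2]), clip3 = qlen - (max(qp[s2]) + k),
        score = length(unique(qp[s2]))))
    }
  }
  out
}

#' Builtin exact-seed mapper
#'
#' Deterministic k-mer seed + extension mapper: exact k-mer matches between
#' query and contig are clustered by diagonal (band 50 bp, so moderate
#' indels stay in one cluster) and contig proximity; each cluster becomes
#' one mapping whose score is the number of distinct seeded query
#' positions.  Both strands are searched; coordinates are always on the
#' forward contig and clips are reported in query orientation.
#'
#' @param queries Named character vector of query sequences.
#' @param contigs Named character vector of contig sequences.
#' @param k K-mer size (default 21).
#' @param min_seeds Minimum seeded positions for a mapping to be reported.
#' @return Mapping table: allele, gene, contig, start, end (0-based
#'   half-open), strand, score, clip5, clip3.
#' @export
builtin_map <- function(queries, contigs, k = 21L, min_seeds = 5L) {
  res <- empty_mappings()
  for (cname in names(contigs)) {
    ckmer <- .kmerize(contigs[[cname]], k)
    if (length(ckmer) == 0L) next
    cindex <- split(seq_along(ckmer) - 1L, ckmer)
    for (qname in names(queries)) {
      for (strand in c("+", "-")) {
        q <- if (strand == "+") queries[[qname]]
             else .revcomp(queries[[qname]])
        qk <- .kmerize(q, k)
        if (length(qk) == 0L) next
        hit_l <- cindex[qk]
        nhits <- lengths(hit_l)
        if (sum(nhits) == 0L) next
        qpos <- rep.int(seq_along(qk) - 1L, nhits)
        cpos <- unlist(hit_l, use.names = FALSE)
        cl <- .cluster_hits(qpos, cpos, nchar(q), k)
        cl <- cl[cl$score >= min_seeds, , drop = FALSE]
        if (nrow(cl) == 0L) next
        clip5 <- if (strand == "+") cl$clip5 else cl$clip3
        clip3 <- if (strand == "+") cl$clip3 else cl$clip5
        res <- rbind(res, data.frame(
          allele = qname, gene = allele_gene(qname), contig = cname,
          start = cl$start, end = cl$end, strand = strand,
          score = cl$score, clip5 = clip5, clip3 = clip3,
          stringsAsFactors = FALSE))
      }
    }
  }
  rownames(res) <- NULL
  res
}

#' Read mappings from a PAF file
#'
#' @param path PAF path (12 mandatory columns; extra columns ignored).
#' @return Mapping table as in [builtin_map()] (score = residue matches).
#' @export
read_paf <- function(path) {
  ln <- readLines(path, warn = FALSE)
  if (length(ln) == 0L) return(empty_mappings())
  f <- strsplit(ln, "\t", fixed = TRUE)
  data.frame(
    allele = vapply(f, `[[`, "", 1L),
    gene = allele_gene(vapply(f, `[[`, "", 1L)),
    contig = vapply(f, `[[`, "", 6L),
    start = as.integer(vapply(f, `[[`, "", 8L)),
    end = as.integer(vapply(f, `[[`, "", 9L)),
    strand = vapply(f, `[[`, "", 5L),
    score = as.numeric(vapply(f, `[[`, "", 10L)),
    clip5 = as.integer(vapply(f, `[[`, "", 3L)),
    clip3 = as.integer(vapply(f, `[[`, "", 2L)) -
      as.integer(vapply(f, `[[`, "", 4L)),
    stringsAsFactors = FALSE)
}

#' Write mappings as PAF
#'
#' Query length is reconstructed as `clip5 + aligned span + clip3`; the
#' residue-match and block-length columns carry the mapper score and span.
#'
#' @param mappings Mapping table.
#' @param path Output path.
#' @export
write_paf <- function(mappings, path) {
  if (nrow(mappings) == 0L) { writeLines(character(), path); return(invisible(path)) }
  span <- mappings$end - mappings$start
  qlen <- mappings$clip5 + span + mappings$clip3
  ln <- paste(mappings$allele, qlen, mappings$clip5, mappings$clip5 + span,
              mappings$strand, mappings$contig, ".", mappings$start,
              mappings$end, round(mappings$score), span, 60L, sep = "\t")
  writeLines(ln, path)
  invisible(path)
}

.minimap2_map <- function(queries, contigs, args = c("-c", "--secondary=yes",
                                                     "-k", "15", "-w", "5")) {
  qf <- tempfile(fileext = ".fa"); tf <- tempfile(fileext = ".fa")
  on.exit(unlink(c(qf, tf)), add = TRUE)
  writeLines(paste0(">", names(queries), "\n", unname(queries)), qf)
  writeLines(paste0(">", names(contigs), "\n", unname(contigs)), tf)
  out <- tempfile(fileext = ".paf")
  on.exit(unlink(out), add = TRUE)
  status <- suppressWarnings(system2("minimap2", c(args, tf, qf),
                                     stdout = out, stderr = FALSE))
  if (!identical(status, 0L)) stop("minimap2 failed with status ", status)
  read_paf(out)
}

#' Map database alleles onto an assembly
#'
#' @param db A `kir_db`.
#' @param contigs Named character vector of assembly contigs (or a
#'   `DNAStringSet`).
#' @param mapper `"builtin"` (deterministic, default) or `"minimap2"`
#'   (external binary; falls back to builtin with a warning if absent).
#' @param k K-mer size for the builtin mapper.
#' @return Mapping table; secondary and heavily clipped mappings are
#'   retained since clips carry structural-variant signal.
#' @export
map_alleles <- function(db, contigs, mapper = c("builtin", "minimap2"),
                        k = 21L) {
  mapper <- match.arg(mapper)
  if (methods::is(contigs, "DNAStringSet")) {
    nm <- names(contigs)
    contigs <- as.character(contigs)
    names(contigs) <- sub("\\s.*$", "", nm)
  }
  if (length(contigs) == 0L) stop("assembly has no contigs")
  queries <- db_allele_seqs(db)
  if (mapper == "minimap2") {
    if (nzchar(Sys.which("minimap2"))) {
      return(.minimap2_map(queries, contigs))
    }
    warning("minimap2 not found on PATH; using builtin mapper",
            call. = FALSE)
  }
  builtin_map(queries, contigs, k = k)
}
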