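## Locus discovery, stages 2-3: consolidate overlapping mappings into
## candidate regions, pick a gene per region by mapping prevalence, then
## refine preliminary bounds by aligning the gene wildtype back to the
## (flanked) region.

#' Consolidate mappings into candidate regions
#'
#' Same-contig, same-strand mappings whose intervals overlap by at least
#' one base are merged transitively (adjacent-but-disjoint mappings are
#' NOT merged unless `gap_merge` is raised); the region interval is the
#' union span and per-gene support (mapping count, summed score) is
#' aggregated.
#'
#' @param mappings Mapping table from [map_alleles()].
#' @param gap_merge Merge mappings separated by less than this many bases
#'   (default 0: only true overlaps merge).
#' @return List of `candidate_region` objects (contig, start, end, strand,
#'   `support` data.frame with columns gene, n, score).
#' @export
consolidate <- function(mappings, gap_merge = 0L) {
  if (nrow(mappings) == 0L) return(list())
  out <- list()
  for (key in unique(paste(mappings$contig, mappings$strand))) {
    sel <- paste(mappings$contig, mappings$strand) == key
    m <- mappings[sel, , drop = FALSE]
    ir <- IRanges::IRanges(start = m$start + 1L, end = m$end)
    red <- IRanges::reduce(ir, min.gapwidth = as.integer(gap_merge))
    ov <- IRanges::findOverlaps(ir, red)
    for (ri in seq_along(red)) {
      mm <- m[S4Vectors_from(ov)[S4Vectors_to(ov) == ri], , drop = FALSE]
      agg_n <- tapply(rep(1L, nrow(mm)), mm$gene, sum)
      agg_s <- tapply(mm$score, mm$gene, sum)
      genes <- sort(names(agg_n))
      out[[length(out) + 1L]] <- structure(list(
        contig = mm$contig[1],
        start = as.integer(IRanges::start(red)[ri] - 1L),
        end = as.integer(IRanges::end(red)[ri]),
        strand = mm$strand[1],
        support = data.frame(gene = genes,
                             n = as.integer(agg_n[genes]),
                             score = as.numeric(agg_s[genes]),
                             stringsAsFactors = FALSE),
        mappings = mm), class = "candidate_region")
    }
  }
  ## deterministic order
  ord <- order(vapply(out, `[[`, character(1), "contig"),
               vapply(out, `[[`, integer(1), "start"),
               vapply(out, `[[`, character(1), "strand"))
  out[ord]
}

# IRanges::findOverlaps accessors without attaching S4Vectors
S4Vectors_from <- function(h) methods::slot(h, "from")
S4Vectors_to <- function(h) methods::slot(h, "to")

#' Drop weakly supported candidate regions
#'
#' Regions backed by fewer than `min_support` mappings or shorter than
#' `min_len` bases are discarded, suppressing spurious fragments from
#' pseudogene-like cross-mapping.
#'
#' @param regions List of `candidate_region`.
#' @param min_support Minimum total mapping count (default 2).
#' @param min_len Minimum region length in bp (default 500).
#' @return Filtered list.
#' @export
filter_regions <- function(regions, min_support = 2L, min_len = 500L) {
  Filter(function(r) {
    sum(r$support$n) >= min_support && (r$end - r$start) >= min_len
  }, regions)
}

#' Assign a gene to a candidate region
#'
#' Prevalence vote: the gene with the most mappings wins; ties break by
#' larger summed mapper score, then lexicographically by gene name.
#'
#' @param region A `candidate_region`.
#' @return Gene symbol.
#' @export
assign_gene <- function(region) {
  s <- region$support
  if (nrow(s) == 0L) stop("region has no support")
  ord <- order(-s$n, -s$score, s$gene)
  s$gene[ord[1]]
}

#' Refine region bounds with the gene wildtype
#'
#' The wildtype of the assigned gene is aligned (semi-globally, free
#' target overhangs) against the region padded by `flank` bases on each
#' side; the aligned target span becomes the refined bounds and the
#' oriented extracted sequence.  A wildtype that fails to map -- fewer
#' than `min_identity` of its bases matching -- drops the region.
#'
#' @param region A `candidate_region` with a gene assigned (or pass
#'   `gene_name`).
#' @param gene A `gene_def`.
#' @param contigs Named character vector of assembly contigs.
#' @param flank Padding in bp on each side (default 1000).
#' @param min_identity Minimum fraction of wildtype bases matched.
#' @param scoring Alignment scoring scheme.
#' @return A `gene_copy` (contig, gene, strand, start, end on the forward
#'   contig, `seq` oriented to the wildtype strand), or `NULL` with a
#'   warning when the wildtype fails to map.
#' @export
refine_region_bounds <- function(region, gene, contigs, flank = 1000L,
                                 min_identity = 0.3,
                                 scoring = default_scoring()) {
  ctg <- contigs[[region$contig]]
  s0 <- max(0L, region$start - flank)
  s1 <- min(nchar(ctg), region$end + flank)
  slice <- substr(ctg, s0 + 1L, s1)
  if (region$strand == "-") slice <- .revcomp(slice)
  aln <- semiglobal_align(gene$wildtype_seq, slice, scoring)
  if (alignment_matches(aln) < min_identity * nchar(gene$wildtype_seq)) {
    warning("wildtype of ", gene$name, " failed to map in region ",
            region$contig, ":", region$start + 1L, "-", region$end,
            "; region dropped", call. = FALSE)
    return(NULL)
  }
  ts <- aln$target_start; te <- aln$target_end
  if (region$strand == "+") {
    rs <- s0 + ts; re <- s0 + te
  } else {
    rs <- s1 - te; re <- s1 - ts
  }
  structure(list(contig = region$contig, gene = gene$name,
                 strand = region$strand,
                 start = as.integer(rs), end = as.integer(re),
                 seq = substr(slice, ts + 1L, te),
                 region = region,
                 variants = NULL, allele_call = NULL, score_table = NULL),
            class = "gene_copy")
}

#' @export
print.gene_copy <- function(x, ...) {
  cat("Gene copy ", x$gene, " @ ", x$contig, ":", x$start + 1L, "-", x$end,
      " (", x$strand, ")", sep = "")
  if (!is.null(x$allele_call)) cat("  call:", x$allele_call)
  cat("\n")
  invisible(x)
}

## oriented extraction of [start, end) on the forward contig
extract_copy_seq <- function(contigs, contig, start, end, strand) {
  s <- substr(contigs[[contig]], start + 1L, end)
  if (strand == "-") .revcomp(s) else s
}
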