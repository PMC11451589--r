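## Minimal EMBL-style flat-file adapter for allele repositories that ship
## one record per allele (ID / DE / FT / SQ blocks, "//" separators).  Only
## the fields the pipeline needs are read: allele name (first DE token),
## exon feature intervals, the CDS codon_start and the sequence.  An
## allele is treated as cDNA-only when its exon features tile the sequence
## with no intervening intronic gaps.

.parse_ipd_flatfile <- function(path) {
  if (!file.exists(path)) stop("flat file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  recs <- list(); cur <- character()
  for (ln in lines) {
    if (startsWith(ln, "//")) {
      if (length(cur)) recs[[length(recs) + 1L]] <- cur
      cur <- character()
    } else cur <- c(cur, ln)
  }
  if (length(cur)) recs[[length(recs) + 1L]] <- cur

  parsed <- lapply(seq_along(recs), function(ri) {
    rec <- recs[[ri]]
    de <- grep("^DE ", rec, value = TRUE)
    if (length(de) == 0L)
      stop("flat file ", path, ", record ", ri, ": missing DE line")
    allele <- sub("[,;].*$", "", trimws(sub("^DE +", "", de[1])))
    if (!grepl("^[^*]+\\*[0-9]+$", allele))
      stop("flat file ", path, ", record ", ri,
           ": cannot parse allele name from DE: ", de[1])

    ft <- grep("^FT ", rec, value = TRUE)
    exon_ln <- grep("^FT +exon +[<>]?[0-9]+\\.\\.[<>]?[0-9]+", ft,
                    value = TRUE)
    exons <- NULL
    for (e in exon_ln) {
      m <- regmatches(e, regexec("([0-9]+)\\.\\.[<>]?([0-9]+)", e))[[1]]
      exons <- rbind(exons, data.frame(start = as.integer(m[2]) - 1L,
                                       end = as.integer(m[3])))
    }
    cs <- grep("codon_start", ft, value = TRUE)
    phase <- if (length(cs))
      as.integer(sub(".*codon_start=([0-9]+).*", "\\1", cs[1])) - 1L else 0L

    sq_at <- grep("^SQ", rec)
    if (length(sq_at) == 0L)
      stop("flat file ", path, ", record ", ri, " (", allele,
           "): missing SQ block")
    seq <- toupper(gsub("[^acgtnACGTN]", "",
                        paste(rec[(sq_at[1] + 1L):length(rec)],
                              collapse = "")))
    if (!nzchar(seq))
      stop("flat file ", path, ", record ", ri, " (", allele,
           "): empty sequence")

    kind <- "genomic"
    if (!is.null(exons) && nrow(exons) >= 1L) {
      exons <- exons[order(exons$start), , drop = FALSE]
      gaps <- utils::tail(exons$start, -1) - utils::head(exons$end, -1)
      contiguous <- nrow(exons) == 1L || all(gaps <= 0L)
      if (contiguous && sum(exons$end - exons$start) >= nchar(seq))
        kind <- "cdna"
    }
    list(allele = allele, gene = allele_gene(allele), seq = seq,
         kind = kind, exons = exons, phase = phase)
  })

  genes <- split(parsed, vapply(parsed, `[[`, character(1), "gene"))
  lapply(genes, function(recs) {
    genomic <- Filter(function(r) r$kind == "genomic", recs)
    if (length(genomic) == 0L)
      stop("gene ", recs[[1]]$gene,
           ": no genomic allele; cannot anchor wildtype")
    # wildtype: lowest-numbered full-length genomic allele
    glen <- vapply(genomic, function(r) nchar(r$seq), integer(1))
    full <- genomic[glen >= 0.9 * max(glen)]
    wt <- full[[order(vapply(full, function(r) allele_suffix(r$allele),
                             integer(1)))[1]]]
    if (is.null(wt$exons))
      stop("wildtype record ", wt$allele, " has no exon features")
    def <- gene_def(wt$gene, wt$allele, wt$seq, wt$exons, phase = wt$phase)
    list(def = def,
         alleles = lapply(recs, function(r)
           list(name = r$allele, seq = r$seq, kind = r$kind)))
  })
}
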