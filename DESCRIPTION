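Package: kirannot
Title: Functionally-Aware KIR Gene and Allele Annotation for Phased
    Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Annotates killer-cell immunoglobulin-like receptor (KIR) gene
    copies in haplotype-resolved genome assemblies. Database alleles are
    mapped onto the assembly to discover candidate loci, each locus is
    assigned a gene by mapping prevalence, the gene wildtype is aligned to
    the extracted copy by affine-gap semi-global alignment, and every
    variant is classified as functionally relevant ("core": missense,
    nonsense, frameshift, start-loss, functional-UTR) or silent
    (synonymous, intronic, silent-UTR) by mutate-splice-translate. Allele
    calls rank candidates by a core-variant Hamming score with a silent
    Jaccard tie-break, so calls reflect protein-level agreement rather
    than raw edit distance. Includes a deterministic generator of toy
    allele databases and synthetic assemblies with known truth, a TSV/YAML
    reporter and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
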