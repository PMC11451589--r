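# kirannot

Functionally-aware annotation of killer-cell immunoglobulin-like receptor
(KIR) genes in haplotype-resolved genome assemblies.

The KIR locus (chromosome 19) carries ~17 highly polymorphic,
copy-number-variable genes regulating natural-killer-cell activity; a
single haplotype may hold 8–14 copies in varying combinations.  Given a
phased assembly FASTA and an allele database, `kirannot` locates every
KIR gene copy, calls its variants against the gene's wildtype allele,
classifies each variant as **core** (missense, nonsense, frameshift,
start-loss, functional-UTR — anything that changes the protein or its
expression) or **silent** (synonymous, intronic, silent-UTR), and assigns
the closest allele *core-variants-first* rather than by raw edit
distance.  It is aimed at immunogenetics researchers annotating
pangenome-grade assemblies, where minimum-edit-distance callers are
routinely dragged to the wrong allele by functionally irrelevant intronic
differences.

## The scoring at the core

For each gene, the *core-position index* `I` is the union of wildtype
positions touched by any database allele's core variants (one position
per SNP, one per deleted base, the anchor for an insertion).  A candidate
allele `a` is scored against an assembly copy `c` as

    score(a, c) = h(a, c) / |I|  +  n(c)

where `h` is the Hamming count over `I` of positions at which the
nucleotide implied by `a`'s variant set differs from the one implied by
`c`'s (the wildtype base where neither has a variant), and `n(c)` is the
number of the copy's *novel* core variants, whose footprint lies entirely
outside `I`.  Candidates are ranked by
`(score, silent Jaccard distance, numeric allele suffix)`; silent
variants only ever break ties.

The pipeline around this: map all database alleles onto the assembly
(builtin deterministic k-mer mapper, or minimap2), merge overlapping
mappings into candidate regions, vote the gene by mapping prevalence,
re-align the gene wildtype to fix the copy bounds, call variants by
affine-gap semi-global alignment (free target overhangs, fully penalized
wildtype), classify every variant by mutate–splice–translate, repair
mapper-clipped bounds when terminal deletions appear, then score and rank
alleles.  Every step is deterministic.

## Worked example

```r
library(kirannot)

td  <- make_toy_database(2, 4, seed = 7, include_cdna = TRUE)
td$db
#> Allele database: 2 genes, 10 alleles
#>   KIRT1DL1: 5 alleles, |core index| = 3
#>   KIRT2DL1: 5 alleles, |core index| = 4

plants <- data.frame(
  allele = c("KIRT1DL1*001", "KIRT1DL1*002", "KIRT2DL1*001"),
  strand = c("+", "-", "+"),
  novel  = c("", "", "nonsense"))
syn    <- make_synthetic_assembly(td$db, plants, seed = 11)
copies <- annotate_assembly(syn$contigs, td$db)
write_copy_tsv(copies, "toy.tsv")
```

`toy.tsv`:

```
contig  gene      allele_call   start  end   strand  core_score  n_missing_core  n_novel_core  n_novel_silent
ctg1    KIRT1DL1  KIRT1DL1*001  2001   2873  +       0           0               0             0
ctg1    KIRT1DL1  KIRT1DL1*002  4874   5746  -       0           0               0             0
ctg1    KIRT2DL1  KIRT2DL1*001  7747   8619  +       1           0               1             0
```

All three planted copies are recovered with their source alleles: the
reverse-complemented plant comes back on the minus strand with forward
coordinates, and the copy carrying a planted novel nonsense variant is
called with `core_score` elevated by exactly the one novel core variant
(`n_novel_core = 1`).  An allele whose core variants fully agree with the
copy's scores exactly `0`.  `write_copy_yaml()` adds the full variant
list and the score breakdown of the five closest alleles per copy.

A command-line driver is installed with the package:

```sh
$(Rscript -e 'cat(system.file("cli", "kirannot", package = "kirannot"))') \
    annotate assembly.fa --db DBDIR --out prefix
```

Databases are read either from the packaged fixture dialect (`alleles.fa`
+ `genes.tsv`, see `?load_allele_db`) or from an EMBL-style flat file
(`dialect = "ipd_flatfile"`).

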