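---
title: "Core-variant-first annotation of KIR genes in phased assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core-variant-first annotation of KIR genes in phased assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kirannot)
```

## The problem

The killer-cell immunoglobulin-like receptor (KIR) locus on chromosome 19
holds around 17 highly polymorphic genes (15 coding, 2 pseudogenes) with
extensive copy-number variation: a haplotype may carry anywhere from 8 to
14 gene copies, in varying combinations.  Haplotype-resolved assemblies
make it possible to read each copy directly, but annotating them is hard:
alleles of different KIR genes are similar enough to cross-map, copies may
be truncated or carry structural variants, and a naive
minimum-edit-distance allele assignment is easily dominated by intronic
differences that have no functional consequence.

`kirannot` instead ranks candidate alleles by agreement on *core
variants* -- the variants that change the downstream protein or its
expression (missense, nonsense, frameshift, start-loss and
expression-relevant UTR changes) -- and uses silent variants (synonymous,
intronic, silent-UTR) only to break ties.  Two alleles that differ by
dozens of intronic bases but encode the same protein are treated as the
near-equals they functionally are.

## Pipeline

1. **Locus discovery.**  Every database allele is mapped onto the
   assembly.  Same-contig, same-strand mappings overlapping by at least
   one base are merged transitively into candidate regions
   (`consolidate()`, backed by `IRanges::reduce`); heavily clipped and
   secondary mappings are kept because clipping is exactly the signal a
   structurally variant copy leaves.  Regions with fewer than
   `min_region_support` mappings (default 2) or shorter than
   `min_region_len` (default 500 bp) are dropped.
2. **Gene identification.**  Each region is assigned the gene with the
   most supporting mappings; ties break by summed mapper score, then gene
   name (`assign_gene()`).  The gene's wildtype is then aligned back to
   the region padded by `flank_bp` (default 1000 bp) and the aligned span
   becomes the preliminary copy bounds (`refine_region_bounds()`).
3. **Variant calling.**  The wildtype is aligned to the extracted copy by
   affine-gap semi-global alignment (`semiglobal_align()`): target
   overhangs are free (extraction may overshoot), while every wildtype
   base is accounted for, so a missing gene head surfaces as a penalized
   terminal deletion.  Mismatches become SNPs, each contiguous gap run a
   single left-aligned indel (`extract_variants()`), and each variant is
   classified by applying it *alone* to the wildtype, re-splicing the CDS
   from the shifted exon table, translating, and comparing proteins
   (`classify_effects()`).
4. **Boundary refinement.**  A deletion whose footprint touches wildtype
   position 0 or the last position usually means the mapper clipped the
   copy.  Bounds are pushed outward by the net terminal indel length,
   variants are re-called, and the less complex variant set -- fewer
   variants, then fewer edited bases -- wins; ties keep the original, so
   a genuinely truncated gene is left alone (`refine_gene_copy()`).  One
   round only, which makes refinement idempotent and trivially
   terminating.
5. **Allele calling.**  For each gene the *core-position index* is the
   union of wildtype positions touched by any allele's core variants (one
   per SNP, one per deleted base, the anchor for an insertion).  A
   candidate allele is scored as `h / |index| + n`: `h` counts index
   positions where allele and copy imply different nucleotides, `n`
   counts the copy's novel core variants (footprint entirely outside the
   index).  Candidates are ranked by `(core_score, silent_jaccard,
   numeric allele suffix)`; the top five are reported
   (`score_allele()`, `call_allele()`).

## Model assumptions and conventions

* **Gene model.**  Exon intervals in the database are the *coding* exons;
  positions between exons are intronic and positions outside the exon
  span are UTR, functional only when covered by a declared
  `functional_utr` interval.  UTR relevance is an explicit database
  annotation, not an inference -- there is no accepted rule for deriving
  it from sequence.
* **Wildtype designation.**  The fixture dialect names the wildtype
  explicitly; for EMBL-style flat files the lowest-numbered full-length
  genomic allele of each gene is chosen -- deterministic and consistent
  with nomenclature convention.
* **cDNA-only alleles** receive a genomic sequence by choosing the
  genomic backbone whose spliced exons are nearest by edit distance (ties
  to the lowest allele number) and substituting the cDNA bases into the
  backbone's exons.  A cDNA whose length is incompatible with the
  backbone's exon structure cannot be placed base-per-base; it is flagged
  with a warning and excluded from mapping rather than failing the load.
* **Per-variant independence.**  Effects are classified one variant at a
  time, per the mutate-and-translate definition; compound consequences of
  co-occurring frameshifts are *not* evaluated jointly.  This is a
  documented limitation, shared with the functional-variant-first
  genotyping approach the scoring follows.
* **Stop handling.**  Proteins are compared truncated at their first
  stop; a premature stop is nonsense, and an exonic change downstream of
  the wildtype stop is synonymous by definition unless it falls in a
  functional UTR interval.
* **Coordinates.**  Internal coordinates are 0-based half-open
  everywhere; every user-facing rendering (TSV, YAML, `format_variants()`)
  is 1-based inclusive, so an internal SNP at 10520 prints as
  `10521 C>G`.

## Numerical choices

* **Alignment scoring** (`default_scoring()`): match +1, mismatch -4, gap
  open -6, gap extend -1, with a length-`L` gap costing `open + L *
  extend`.  These are standard variant-calling-grade parameters that
  favour one contiguous indel over scattered edits.  Determinism is
  pinned down explicitly: state preference match > deletion > insertion,
  gap extension preferred over a fresh open on ties, and the smallest end
  column chosen among tied terminal maxima.
* **`N` never matches** and scores as a mismatch; calls whose alternate
  contains `N` are flagged `low_confidence` in the YAML.
* **Indel normalization**: indels are shifted to the smallest wildtype
  position that preserves the edited sequence, but never across another
  variant of the same alignment, so the variant set always reapplies
  cleanly.
* **Empty core index**: `h / |index|` is defined as 0, keeping
  pseudogene-like genes (no core variants anywhere) well-defined.
* **Mapper**: the builtin mapper seeds exact 21-mers, clusters them by
  diagonal (band 50 bp) and contig proximity (gap 1 kb), and scores a
  cluster by its distinct seeded query positions.  It is fully
  deterministic and adequate for assemblies, where copies are near-exact;
  a minimap2 adapter is available for production use and falls back to
  the builtin mapper with a warning when the binary is absent.

## What the synthetic data emulates -- and what it does not

`make_toy_database()` builds genes of about 0.9 kb (5'UTR, two coding
exons around one intron, 3'UTR; one gene carries a functional-UTR
interval), each with a wildtype, alleles holding 1-3 planted variants
drawn from the missense / synonymous / intronic / nonsense / frameshift
classes, and optionally a cDNA-only allele.  Every planted variant is
certified by `classify_effect()` before emission, so fixture truth cannot
drift from the classifier.  `make_synthetic_assembly()` plants exact,
reverse-complemented, head/tail-truncated or novel-variant-bearing copies
separated by at least 2 kb of intergenic sequence rejection-sampled to
share no 21-mer with any allele, so the builtin mapper cannot seed
spurious regions.  A single integer seed controls all randomness and the
session RNG state is restored afterwards.

Real KIR data differs in ways the fixtures deliberately do not model:
genes are 4-16 kb with up to nine exons, alleles of *different* genes
share long near-identical stretches (the cross-mapping that makes
prevalence voting necessary), assemblies contain base errors, and fusion
or deleted-exon copies occur.  Passing the fixture suite therefore
demonstrates the correctness of the machinery -- scoring, classification,
refinement, orientation handling -- not recall on real assemblies, which
depends on database completeness and mapper sensitivity.

Test and example problem sizes (toy genes under 1 kb, assemblies of a few
tens of kb, 500 alignment-oracle pairs up to 200 bp, 1000 scoring
triples) were chosen as the smallest scales at which every code path --
both strands, truncation, novelty, cDNA inference -- is exercised.

## Worked example

```{r example, eval = FALSE}
td <- make_toy_database(2, 4, seed = 7, include_cdna = TRUE)
plants <- data.frame(
  allele = c("KIRT1DL1*001", "KIRT1DL1*002", "KIRT2DL1*001"),
  strand = c("+", "-", "+"),
  novel  = c("", "", "nonsense"))
syn <- make_synthetic_assembly(td$db, plants, seed = 11)
copies <- annotate_assembly(syn$contigs, td$db)
write_copy_tsv(copies, "toy.tsv")
```

The copy planted with a novel nonsense variant is reported with
`n_novel_core = 1` and a core score elevated by exactly 1; the exact
plants score 0 against their source alleles.

## Known limitations

* The full dynamic-programming matrix is kept in memory; for wildtypes
  beyond ~20 kb a banded alignment would be needed.
* Gene copies absent from the database (novel genes) are out of scope;
  so are haplotype phasing and assembly QC.
* "Prevalence" in gene assignment is mapping count; base-coverage
  weighting would be a config alternative if count ties become common on
  real data.
* The EMBL-style flat-file reader covers the record fields the pipeline
  needs (ID/DE/FT exon/CDS/SQ) and is exercised against a small synthetic
  file; release-specific quirks of real repository dumps may need
  adapter work.
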