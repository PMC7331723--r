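---
title: "Autozygosity mapping and hand anthropometry with rohmapper"
author: "rohmapper authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autozygosity mapping and hand anthropometry with rohmapper}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohmapper)
```

## The problem

When a fully penetrant autosomal recessive disorder segregates in a
family whose parents are related, affected children are expected to be
homozygous by descent (autozygous) for the causal allele: both copies
descend from a single ancestral haplotype carried through the
consanguinity loop. This turns gene discovery into an intersection
problem over three independent evidence layers:

1. **Runs of homozygosity (ROH).** The causal variant must sit inside a
   genomic segment that is homozygous in every affected individual. We
   call an ROH as a span of at least `min_snps = 25` genotyped SNPs of
   which at most `max_het = 2` are called heterozygous, then intersect
   the per-sample regions across the sequenced affected siblings.
2. **An exclusion cascade for exome variants.** Candidate variants must
   survive five rules applied in a fixed order: (1) at least 3 reads
   supporting the alternate allele in every sequenced affected; (2)
   population allele frequency at most 0.05 *and* at most 30 carriers in
   an in-house cohort of roughly 1000 exomes; (3) no homozygotes in the
   reference population; (4) not synonymous; (5) not 5' UTR and not
   intronic beyond the splice-site window.
3. **Co-segregation.** Under full penetrance, affected individuals are
   homozygous for the alternate allele, unaffected individuals are not,
   and typed unaffected parents of affecteds are obligate heterozygous
   carriers; child genotypes must also be reachable from their parents'
   (Mendelian consistency).

The package implements each layer as an independently testable module,
plus a hand-anthropometry module that standardizes metacarpophalangeal
bone lengths into age- and sex-corrected z-profiles, and a simulator
that generates full synthetic study families with exact ground truth.

## The simulator: what it emulates

No individual-level sequencing data are distributable for this kind of
family study, so the package treats the simulator as a first-class
module. `simulateFamily()` generates, from one master seed:

* **A consanguineous pedigree** (`buildPedigree()`): by default eight
  children of first-cousin parents, the weakest loop that still makes
  25-SNP ROH detection reliable at exome-like marker density. The
  first-cousin graph has 16 members: the shared ancestral couple, their
  two sibling children with two married-in spouses, the two first
  cousins, and the sibship.
* **Gene dropping with recombination** (`geneDrop()`): founder
  haplotypes are uniquely labelled; each meiosis draws a Poisson number
  of crossovers per chromosome (Haldane model, no interference — the
  simplest model with closed-form expectations) at uniform physical
  positions. Identity by descent is exact, not inferred: a marker is
  autozygous when both origin labels coincide, which gives the truth
  record its IBD segments. The default map is 4 chromosomes x 120 Mb x
  1.2 Morgans with 1000 markers each — exome-scale marker density per
  unit genetic length, scaled to a quarter-genome so that a full
  simulate-to-candidates run takes under a second.
* **A planted recessive variant** (`plantVariant()`): one copy on a
  founder haplotype inside the loop, full penetrance (affected iff
  homozygous for the planted allele). To reproduce the study family
  structure (exactly 5 of 8 children affected), meioses are redrawn by
  rejection sampling, bounded at 10,000 attempts. The sampler is
  two-stage but exact: inheritance at the planted locus alone is drawn
  and screened first (cheap), then full chromosomes are drawn
  conditional on the accepted single-locus inheritance. This is
  distribution-identical to naive whole-genome rejection because the
  Haldane start phase is uniform and independent of the crossover
  positions.
* **Read-level noise** (`emitVariants()`): per-site depth ~
  Poisson(40), het alternate reads ~ Binomial(depth, 0.5), homozygous
  sites with a 0.005 error floor, and a symmetric genotype miscall rate
  of 0.002 — typical exome-quality values. Background founder allele
  frequencies come from a two-component mixture (70% common ~
  U(0.05, 0.5), 30% rare ~ U(0, 0.001)); annotations (consequence
  class, population AF and homozygote count, in-house carriers) are
  drawn so every branch of the exclusion cascade is exercised. The
  planted variant is annotated as a very rare missense variant (3 of
  187,624 alleles, no homozygotes, absent in-house).
* **Hand measurements** (`simulateMeasurements()`): per bone and side,
  a z-score uniform in [-1, 1] for unaffected and [-3, -1] for affected
  subjects, with two fixed unilateral outliers (left first metacarpal
  at -7 SD, right first proximal phalanx at -5.3 SD) planted in the
  first two affected siblings; lengths are mean + z x SD under the norm
  table.

Randomness is split from the master seed in a documented order (map,
meioses, noise, measurements), so each stage is reproducible in
isolation and `runPipeline()` is byte-deterministic per seed.

**What the simulator does not emulate** — and hence what passing tests
do not show about real data: clustered exonic marker spacing, linkage
disequilibrium among founder haplotypes, crossover interference,
batch-varying depth, multi-allelic or indel sites, annotation error,
and population stratification of allele frequencies. The recovery rates
reported by the acceptance script are properties of this generative
model, not of any particular exome pipeline.

## Numerical and design choices

* **ROH "span" semantics.** The published rule fixes the thresholds but
  not the span semantics; we enumerate *maximal* qualifying intervals
  (extendable in neither direction) and, for reporting, merge
  overlapping maximal spans — a merged region's heterozygote total may
  then exceed `max_het`. Both layers are retrievable
  (`callROH(layer =)`) so either reading can be reproduced, and the
  maximal layer is what the O(n^2) brute-force oracle checks exactly.
* **Missing genotypes** neither break an ROH span nor count toward the
  25: exome missingness would otherwise shatter spans.
* **Coordinates** are 1-based inclusive in every file format (VCF
  convention); interval intersection is delegated to
  GenomicRanges/IRanges.
* **Rule 1 scope.** The read-support rule is evaluated per sequenced
  affected sample and fails if *any* of them has fewer than 3 alternate
  reads; a missing call counts as zero supporting reads.
* **Rule 2** joins its two clauses (population AF, in-house count) by
  OR, matching the cascade's sentence structure; **rule 5** read
  literally drops 5' UTR but not 3' UTR variants — a config switch
  (`exclude_utr3`) adds the stricter reading. The splice-site window
  defaults to +/-2 bp (the canonical dinucleotide), configurable
  because the source protocol never defines it.
* **Attribution** is first-failing-rule in the published order, which
  makes the attrition ledger conservation-testable (counts always sum
  to the input count); permuting the rule order provably changes only
  attribution, never the surviving set, and a test asserts this.
* **Segregation constraints** apply only to typed individuals: missing
  genotypes and untyped relatives impose none (the study family's
  father was untyped), matching clinical practice for partially typed
  families.
* **Anthropometry thresholds.** No numeric brachydactyly cutoff is
  standard; we flag brachydactyly when the affected-minus-unaffected
  group mean z difference is at most -1.0 SD, chosen because the two
  groups' bands ([-1, 1] vs [-3, -1]) differ by exactly that much in
  expectation. "Markedly shortened" defaults to z <= -5, which captures
  the planted -7 and -5.3 outliers and nothing inside the [-3, -1]
  band. Both are arguments of `compareProfiles()`.
* **Norm lookup** interpolates linearly in (possibly fractional) age
  between tabulated rows and refuses to extrapolate beyond the table;
  reference atlases tabulate discrete ages. The bundled
  `makeNormTable()` is a synthetic stand-in for an external reference
  atlas — z-scores are only as good as the norms supplied.
* **Degenerate inputs.** Zero children, founder-only pedigrees, empty
  measurement tables and empty shared-ROH sets all return empty results
  rather than erroring; an empty marker set, unsorted positions, an
  unknown consequence class, or a genotyped individual absent from the
  pedigree are errors that name the offender.

## A worked run

```{r, eval = FALSE}
cfg <- pipelineConfig(outdir = "wms_run", seed = 11)
res <- runPipeline(cfg)
res$candidates          # the planted variant, typically alone
res$segregation         # consistent with AR transmission
res$comparison$difference   # approx -2 SD, brachydactyly flagged
```

Problem sizes used by the test-suite and acceptance checks: ROH oracle
equivalence on 100 random instances of up to 200 SNPs; exhaustive trio
enumeration (54 cases); 1000 gene-drop replicates for the inbreeding
coefficient (expected F = 1/16 for first-cousin offspring); 100
end-to-end seeded simulations for planted-variant recovery, asserted at
>= 95%. These sizes keep the whole suite in a few minutes on one core
while leaving Monte-Carlo error well inside the asserted bounds.

## Known limitations

* X-linked and dominant models, penetrance estimation, and linkage LOD
  scores are out of scope; only the fully penetrant AR model is checked.
* ROH calling is threshold-based, not likelihood-based (no
  PLINK-style LOD weighting), and no population-level ROH statistics
  (e.g. genomic inbreeding coefficients from ROH) are computed.
* The VCF layer handles bi-allelic SNVs with GT:AD:DP only.
* Candidate prioritization requires the sequenced affecteds to be
  homozygous-alt at the causal site; a miscalled genotype there (rate
  ~0.002 per sample by default) is an accepted source of the few
  percent of recovery failures.
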