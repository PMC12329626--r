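---
title: "Genomic compatibility metrics for assisted gene flow: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic compatibility metrics for assisted gene flow: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gencompat)
library(dplyr)
```

## The problem

Assisted gene flow — translocating individuals from a large "donor"
population into a small, isolated "recipient" population — is a standard
management option for inbred populations of threatened species. Whether it
helps depends on what the donor genomes actually carry: they may mask
deleterious alleles that the recipient currently expresses as homozygotes,
but they may also introduce novel deleterious mutations, expose deleterious
alleles the recipient keeps safely heterozygous, or disrupt local
adaptation. `gencompat` quantifies these effects locus by locus from a
multi-sample SNP VCF, a sample-to-population map, and per-variant
functional annotations, and ships a synthetic-cohort generator whose truth
values every metric can be checked against.

## Variant classes

Variants are classified from upstream effect annotations (SnpEff-style
terms) and PROVEAN protein-impact scores; neither tool is re-implemented,
their outputs are ingested as a TSV (or parsed from coordinates supplied by
the user). The classes are:

* **LoF** — nonsense and splice-disrupting consequences. The default term
  set is `r paste(lof_effect_terms(), collapse = ", ")` and is
  configurable, because different annotation pipelines emit different
  vocabularies for loss of function.
* **Damaging missense** — missense variants with PROVEAN score strictly
  below −2.5. The threshold is the PROVEAN authors' recommended operating
  point; the inequality is strict, so a score of exactly −2.5 is neutral.
  Missense variants without a finite score stay neutral and are counted,
  so they can never silently enter the deleterious set.
* **Deleterious** = LoF ∪ damaging missense.
* **Adaptive** — non-synonymous variants inside genes independently
  inferred to be under positive selection (the gene list is an input; a
  Direction-of-Selection utility, `compute_dos()`, is provided for users
  who derive such lists, DoS = Dn/(Dn+Ds) − Pn/(Pn+Ps)). By default only
  missense variants qualify; `include_lof = TRUE` extends the definition,
  since either convention is defensible.
* **Gene desert** — intergenic variants at least 100 kb (configurable)
  from the nearest annotated gene on the same chromosome. These are the
  neutral reference for the F~ST~ screen; the distance is deliberately a
  prominent knob because "outside physical linkage" depends on the
  recombination landscape of the study system. The boundary is inclusive
  (exactly 100 kb qualifies) and distance is counted in base pairs from
  the nearest gene boundary, genes being 1-based closed intervals.

The ALT allele is treated as the derived (and, for deleterious classes,
the harmful) allele throughout. When an `AA` INFO key is present,
`read_vcf(polarize = TRUE)` flips dosage at loci where the ancestral allele
is the ALT, but no polarisation is attempted by default because most
restoration-genomics call sets are not polarised.

## Filters

Two filter stages reproduce a conventional GATK-style workflow:

1. **Hard filters**: a locus is removed when any of QD < 2.0, MQ < 20.0,
   |MQRankSum| > 3.0, |ReadPosRankSum| > 3.0, SOR > 5.0 fires. A missing
   INFO statistic simply skips that rule for that locus (counted in the
   report) — absence of evidence is not treated as failure.
2. **Site filters**: missingness strictly above 20% of the analysed
   samples (so exactly 20% is kept), singletons (derived allele count 1),
   and private doubletons. "Private doubleton" is not a standardised term;
   here it means allele count 2 with both copies in one individual — a
   homozygous singleton, the definition that matches VCFTools-based
   workflows — with a `private_scope = "population"` switch for the
   both-copies-in-one-population reading. Missingness is assessed on the
   analysed cohort, not on whatever larger panel the VCF came from, so
   subsetting samples changes the filter, which is exposed rather than
   hidden.

All site-filter rules are per-locus predicates evaluated on the input
table, so the surviving set is independent of rule order; the report
attributes each removed locus to the first rule that fires so that its
accounting identity (sites in − sites removed = sites out) holds exactly.

## Mutation load

For each genome and class, the masked load `l_mask` is the number of
heterozygous loci and the realised load `l_realised` the number of
homozygous-derived loci; `carried = l_mask + l_realised`. Counts are
absolute per genome: a missing genotype contributes to no count and does
not rescale the others, but per-sample missing counts are emitted so users
can judge comparability between genomes. Population load is the mean
individual load over members, reported with the sample (n−1) standard
deviation, absent for single-member populations. Because per-genome counts
of carrier loci and allele-dosage sums answer subtly different questions,
both are reported for the adaptive class.

## Genomic compatibility: M~add~ and P~mask~

Both metrics compare genotype identities between donor and recipient
genomes at functional loci, assuming Mendelian segregation in a single F1
generation (no F2+ dynamics, no mate choice, all donor×recipient pairs
weighted equally).

**Mutations added.** `M_add` counts class loci where a donor genome
carries at least one derived allele that is absent from the recipient
population (derived allele count zero over all called recipient genomes).
This population-level novelty is the headline mode; a pairwise mode judges
novelty against a single recipient genome for users who want per-pair
resolution. A self-comparison (donor population equals recipient
population) is necessarily zero. `relative_m_add_pct` expresses the mean
M~add~ against the number of class loci segregating (allele count ≥ 1) in
the recipient population — a per-population baseline for "how much new
material is this, relative to what is already there".

**Masking potential.** At a locus where the recipient is homozygous for a
deleterious allele, the probability that an F1 offspring is heterozygous
(the allele is masked) is 1 for a homozygous-reference donor and 1/2 for a
heterozygous donor. At a locus where the recipient is heterozygous, the
probability that the F1 is homozygous-derived (the allele is exposed) is
1/2 for a homozygous-derived donor and 1/4 for a heterozygous donor. These
four numbers are not parameters; they are forced by gamete enumeration,
and the package computes them that way (`f1_genotype_distribution()` works
in integer quarters, so probabilities are exact, and the masking /
unmasking helpers are tested against the enumeration over all nine parent
genotype pairs). The pair score is the cumulative signed sum

P~mask~ = 1·n(masked at 1) + 0.5·n(masked at 0.5) − 0.5·n(unmasked at 0.5) − 0.25·n(unmasked at 0.25),

positive when the cross nets toward masking. It is a sum, not a mean, to
keep the "cumulative score" reading; a per-comparable-locus normalised
version is emitted alongside for cross-cohort comparison, and the
zero-probability genotype combinations are tallied for completeness. Loci
missing in either genome are skipped and counted. Note that a genome
crossed with itself has P~mask~ = −0.25·h (h its heterozygous deleterious
loci): its homozygous loci meet a homozygous donor and cannot be masked,
while every shared heterozygote can be exposed at 1/4.

No fitness weighting is applied: the framework counts mutations, it does
not claim to know their selection coefficients. An optional per-class
weight vector would be a thin extension, but the defaults deliberately
report raw counts.

Scenario summaries average M~add~ over donor genomes and the pair-level
quantities over all donor×recipient pairs (mean ± SD over pairs is the
headline; per-donor sums are also emitted since either aggregation is
defensible). `net_impact_summary()` then averages scenarios across
recipient populations per donor and reports the ratio of deleterious to
adaptive additions.

## The F~ST~ outlier screen

Local adaptation would make introduced "adaptive" alleles a mixed
blessing, so adaptive loci are screened against a neutral null: per-SNP
Weir & Cockerham (1984) θ across the analysed populations, compared with
the distribution of θ at gene-desert loci. The estimator was implemented
from the variance components (a, b, c); no installed R package provides
it, and the test suite checks it against an independently coded
enumeration to 10⁻¹² as well as against the analytically forced θ = 1 at a
fixed difference. Conventions, each fixed so cutoffs are reproducible:

* negative estimates are retained — clamping at zero would bias the
  null percentile upward;
* a locus needs ≥ 2 populations with ≥ 2 called genotypes; loci failing
  this, or monomorphic over the analysed samples, carry an `NA` sentinel
  and are excluded from null and test sets symmetrically;
* the cutoff is the 95th percentile of the neutral distribution under
  linear interpolation between order statistics (`quantile(type = 7)`,
  also numpy's default) — for 100 uniformly spaced values 0.00…0.99 this
  gives 0.9405;
* outlier calls use a strict `>`.

A caution for users: the mean of per-SNP θ is a biased estimator of the
differentiation parameter (a mean of ratios), which is why
`multilocus_fst()` — the ratio of summed components — is provided and used
when comparing against an island-model target; the per-SNP values are the
right objects for the percentile screen itself.

## The synthetic generator and what it does (and does not) show

`simulate_cohort()` draws unlinked diploid genotypes independently per
locus and individual under Hardy–Weinberg equilibrium at each population's
true allele frequency. Frequency models per class:

* fixed frequencies by role or population — the defaults put deleterious
  alleles at 0.03 in donors and 0.10 in recipients, emulating drift-driven
  load accumulation in small isolated populations, with damaging-missense
  loci five times as numerous as LoF loci and adaptive variants at
  intermediate frequency (0.25);
* Balding–Nichols island-model frequencies (Beta with parameter F around
  a per-locus ancestral frequency drawn uniformly on [0.1, 0.9]), default
  F = 0.1, for the neutral gene-desert class;
* a divergent-selection overlay giving a configured fraction of adaptive
  loci independent per-population frequencies on [0.05, 0.95].

The generator lays out a genome (2 kb genes separated by 10 kb gaps;
intergenic loci in the gaps; gene-desert loci beyond the configured
distance from the last gene; adaptive loci in dedicated genes so the
adaptive-gene list is clean), writes every input format the tool consumes
(VCF with INFO statistics drawn from passing ranges unless a failure
fraction is planted, popmap TSV, annotation TSV, BED gene models,
adaptive-gene list, truth JSON), and PROVEAN scores are drawn on
[−10, −2.6] for damaging and [−2.4, 5] for neutral missense, avoiding the
threshold by construction so label recovery is exact. Everything is
deterministic under the configured seed.

`closed_form_expectations()` is the oracle: per locus,
E[L~mask~] = 2q(1−q), E[L~realised~] = q²,
E[M~add~ per donor genome] = (1−(1−q~D~)²)(1−q~R~)^(2n~R~), and
E[P~mask~ per pair] = q~R~²(1−q~D~) − (1−q~R~)q~R~q~D~, summed over loci.
These are verified in the tests against brute-force enumeration over all
3×3 genotype pairs, and the simulated cohorts recover them within three
standard errors (for M~add~, whose donors share one recipient panel, the
standard error is computed from the exact per-locus sampling variance
rather than across donors).

What passing these tests shows: the counting, the Mendelian arithmetic and
the estimators are correct. What it does not show: real cohorts violate
the generator's assumptions — loci are linked, genotypes are missing
non-randomly, populations are not at HWE, annotation pipelines mislabel
variants, and deleterious allele-frequency spectra are not single-valued.
The metrics remain simple counts under those violations, but their
closed-form expectations do not apply.

## Problem sizes and numerical choices

The validation suites use cohorts of 2 populations × 25 diploids with 10⁴
loci per functional class for the closed-form recovery checks, and 10⁴
neutral plus 10³ adaptive loci over three populations of 20 for the screen
calibration (where, under exchangeability, the expected outlier fraction
is 0.05 and the observed fraction is required to sit inside the binomial
99% interval; with 10% of adaptive loci divergent, enrichment above that
band and enrichment of truth-labelled divergent loci among the flags are
both required). These sizes make the Monte-Carlo standard errors small
relative to the effects being checked while keeping the default test run
fast on a laptop. Probabilities inside the F1 machinery are integer
quarters; P~mask~ is therefore exact, and the decomposition test asserts
identity, not approximate equality. Degenerate inputs (empty tables,
zero-comparable-locus pairs, populations without members, monomorphic
loci) return zeroed reports or `NA` sentinels with warnings rather than
propagating silent zeros.

## Known limitations

* Strictly single-generation (F1) arithmetic: no recombination, linkage,
  or multi-generation forward simulation.
* No phasing, indels, or multiallelic decomposition; records that are not
  biallelic SNPs are dropped (and counted) at ingest.
* Equal weighting of variants within a class; no distribution of fitness
  effects.
* The gene-desert null inherits the demography of the analysed samples
  but is not a demographically calibrated null model; it is an empirical
  percentile.
* `M_add` novelty is judged against the sampled recipient genomes; rare
  alleles present in the unsampled population will occasionally be
  miscounted as novel, an unavoidable sampling effect that shrinks as
  recipient sample size grows (the (1−q~R~)^(2n~R~) factor).

## A worked example

```{r example}
cfg <- scenario_config(seed = 11L)
coh <- simulate_cohort(cfg)
coh$table

population_load(coh$table, coh$popmap, classes = "LOF") |>
  arrange(population)

res <- population_compatibility(coh$table, coh$popmap, "D1", "R1")
res |> select(class, m_add_mean, relative_m_add_pct, p_mask_mean)

screen <- fst_outlier_screen(coh$table, coh$popmap)
screen
```
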