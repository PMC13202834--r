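---
title: "Methods: integrated trio genome and transcriptome diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated trio genome and transcriptome diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cptriomics)
```

# The diagnostic problem

Cerebral palsy (CP) is a clinically defined, genetically heterogeneous group
of non-progressive motor disorders. In a trio design (affected child plus
both asymptomatic parents) three molecular readouts complement one another:

1. **DNA, hypothesis-driven** — rare variants in genes previously associated
   with CP, classified into the five ACMG/AMP tiers from asserted evidence
   codes.
2. **DNA, hypothesis-free** — damaging *de novo* variants anywhere in the
   genome, found by the trio genotype pattern plus deleteriousness scores.
3. **RNA, cohort-as-control** — genes, splice junction clusters and whole
   pathways in which one proband is an outlier against the remaining
   probands. Because CP genetics is heterogeneous, the other probands are a
   serviceable control group: no single molecular lesion recurs often enough
   to contaminate the reference.

`cptriomics` implements all three plus their integration (one report per
proband, with DNA-by-pathway cross-evidence links), and a synthetic cohort
generator whose planted events make every stage testable end to end without
patient data.

# Stage models and parameters

## Damaging de novo screen

A variant is **de novo** when the proband is heterozygous or homozygous for
the alternate allele and *both* parents are confirmed homozygous reference.
A missing parental genotype means "not wild-type-confirmed" and the variant
is never called de novo. Hemizygous male X genotypes count as carrying the
variant; the genotype rule mentions zygosity classes only, so X variants
with confirmed wild-type parents are de novo like any other.

A de novo variant is **damaging** when all three hold:

* CADD phred **strictly greater than 20** (the wording "greater than" is
  taken literally; 20.0 fails);
* SIFT result Deleterious — when only a score is available the standard
  cutoff (score ≤ 0.05) derives the call; a given categorical call always
  wins over a contradicting score;
* PolyPhen-2 probably or possibly damaging (HumDiv score cutoffs 0.909 and
  0.447 when only a score is available).

A required score that is absent fails the filter — absence is explicit
missingness, never zero. Gene-level recurrence (`recurrentGenes`) uses an
**inclusive** threshold ("two or more") by default, exposed as a parameter
because exclusive readings exist.

## ACMG evidence combination

`classifyEvidence` applies the ACMG/AMP combining rules to evidence codes
whose strength may be re-weighted by a modifier suffix (`_S` strong, `_M`
moderate, `_P` supporting). Counting uses the **applied** strength only: a
`PVS1_S` is one strong, a `PS2_M` one moderate. Two very strong criteria
are pathogenic (the combination is not in the original rule list, but
omitting it would let a strength upgrade *downgrade* a verdict, violating
monotonicity). Conflicting pathogenic- and benign-side evidence collapses
to uncertain significance. The engine never asserts codes from prediction
scores: which codes apply to a variant is a clinical judgment supplied by
the user, and the candidate filter likewise takes co-segregation and
phenotype correlation as caller-supplied booleans.

The candidate filter's frequency criterion reads "less than 0.05% in
(four databases)" as: the **maximum** observed frequency across databases
must pass, with absent frequencies counting as 0. That is the strict
rare-disease reading; the permissive any-database reading is available via
`maf_rule = "any"`.

## Expression outliers

Each proband is compared with the remaining probands on log2(TPM+1):
`z = (x − median_ref) / (1.4826 × MAD_ref)`. The tested sample never enters
its own reference. Genes whose leave-one-out reference median TPM is below
`min_expression` (default 1) or whose MAD is zero are skipped for that
sample. Default flagging threshold `z_min = 3`.

**Numerical choice — the p-value reference.** With 26 reference samples the
MAD is a noisy scale estimate (its Gaussian asymptotic efficiency is 0.37),
so the null robust z is t-like, not Gaussian: Monte Carlo at this design
gives P(|z|>4) ≈ 3.2×10⁻³ against 6.3×10⁻⁵ for a Gaussian. p-values
therefore use a t reference with df = 0.367 × (reference size) ≈ 9, which
matches the simulated null tail within ~20% over |z| in 3–5. A practical
consequence: in a 27-sample cohort a z = 5 outlier is real but cannot be
*certified* at FDR 0.05 among hundreds of genes; the `significant` column
(per-sample BH on the t-based p) is deliberately stricter than the flag
threshold.

## Splicing outliers

Junctions sharing a donor or acceptor position (same chromosome and strand)
are clustered by connected components; singleton clusters and clusters with
fewer than `min_cluster_reads = 30` cohort-wide reads are dropped. For each
(sample, cluster) a likelihood-ratio test compares the sample's junction
usage with the pooled remaining probands under a Dirichlet-multinomial
(DM): both groups' proportions are profiled out at a fixed concentration
and the statistic is referred to χ² with J−1 degrees of freedom. Samples
with fewer than `min_sample_reads = 10` reads in a cluster are skipped;
the concentration is floored at 10⁻³ so small-count tests stay defined.

**Numerical choice — the concentration.** A per-cluster method-of-moments
concentration from 26 reference samples is noisy enough to make the χ²
reference anticonservative exactly where multiple-testing bites (simulated
family-wise per-sample BH rate 0.089 at nominal 0.05, although the test is
well calibrated when the true concentration is plugged in). The default is
therefore a **cohort-consensus concentration** — the median of per-cluster
moment estimates, robust to a contaminated cluster — which restores
calibration (simulated family-wise rate 0.054, n = 1080 samples). This is
the dispersion-moderation convention of count-based genomics; per-cluster
estimation remains available (`concentration_method = "per_cluster"`) for
cohorts with genuinely heterogeneous dispersion.

BH adjustment is **per sample** by default: the design tests each proband
against the rest, so each proband owns a family of tests. Cohort-wide
adjustment is available via `adjust_scope`. Significant clusters are then
intersected with the candidate set (CP genes ∪ damaging de novo genes;
both the unfiltered and filtered lists are returned). SpliceAI delta
scores are annotation passthroughs used only for reporting concordant DNA
evidence; 0.8 is the reporting threshold for a highly reliable prediction.

## Pathway outliers (GSVA)

The expression matrix is converted to gene-set × sample scores:

1. Per gene, a Gaussian-kernel CDF estimate of each sample's expression
   against the cohort (bandwidth = per-gene SD / 4), on log2(TPM+1);
   zero-variance genes are dropped.
2. Per sample, kernel CDF values become centered ranks
   (rank − (p+1)/2), so genes at either expression extreme carry the
   largest absolute weight. The symmetric centering (rather than |p/2 −
   rank|) makes ranking reversal negate the statistic exactly, which gives
   the score an exact antisymmetry.
3. Per (set, sample), a weighted KS random walk down the sample's gene
   ranking: members step up by |stat|^τ (τ = 1), non-members step down by
   1/(p − m); the score is max positive + min negative deviation
   ("maxdiff"), automatically bounded in [−1, 1].

Sets are restricted to 5–500 matrix members before scoring. A pathway is
**aberrant** when at least one proband's score lies outside the Tukey
fences Q1 − 1.5·IQR, Q3 + 1.5·IQR computed over samples with type-7
(linear-interpolation) quartiles — the fence is sensitive to the quartile
convention, so the convention is fixed and exposed. With n = 27 samples
the fence exceedance rate for exchangeable scores is a few percent per
observation, far above the textbook large-n Gaussian rate; the null-
calibration test bands reflect Monte Carlo at n = 27, not the asymptote.

Because the scores are built from within-sample ranks of per-gene
kernel-CDF values, they are exactly invariant to order-preserving *affine*
per-gene transforms (the bandwidth scales with the SD). Full monotone-
transform invariance would require the pure ECDF variant; the Gaussian
kernel trades that for smoothness.

## Exact 2×2 statistics

`fisherExact` enumerates the hypergeometric support: the two-sided p sums
probabilities of tables no more probable than the one observed; the primary
odds-ratio estimate is the conditional MLE under the noncentral
hypergeometric, with an exact conditional 95% CI from inverting the
one-sided tails at 0.025. The sample cross-product ratio with its Wald
interval is also reported because clinical papers usually print that pair —
on the cohort's birth table the printed OR (47.5) and CI (3.55–636.20) are
the cross-product/Wald pair on the all-27 table while the printed P
(0.0034) is the exact test on the 23 children with recorded birth weight.
Mid-p variants are out of scope.

# The synthetic cohort: what it emulates, what it does not

`generateCohort` draws, under one mandatory seed that feeds four named
substreams (genotype, annotation, expression, splicing):

* **Genotypes** — 27 trios; 60 inherited background variants per trio
  (carrier parent het, proband inherits with probability ½, so every
  inherited alt allele is in ≥1 parent); Poisson(2) background de novo
  variants per trio whose CADD is drawn below 20 (they must fail the
  damaging filter, as registered); 12 planted damaging de novo variants
  cohort-wide with scores drawn inside the passing region (CADD 25–40,
  SIFT ≤ 0.03, PolyPhen ≥ 0.92). Because the filter is exact on exact
  scores, recovery of planted events is deterministic — the recovery test
  checks the plumbing, not statistical power.
* **Expression** — per-gene log-normal TPM, meanlog ~ U(0, 5) (natural
  log), sdlog 0.4: heavy-tailed abundance with a tractable robust-z ground
  truth. Planted expression outliers are written at an *exact*
  leave-one-out robust-z magnitude (drawn from U(5, 8)) on the log2 scale,
  so the recovered z equals the registered magnitude.
* **Splicing** — 40 clusters of 2–4 junctions inside the deterministic
  gene layout (`syntheticGeneRanges`); per-sample depth NB(mean 200,
  size 5, floored at 10); counts Dirichlet-multinomial with concentration
  50 (overdispersion comparable to real split-read data, so the
  homogeneity test is non-trivially exercised). A planted shift moves 0.4
  of usage from the major to the least-used junction in one sample.
* **Pathways** — 40 gene sets of 10–30 genes; a planted shift offsets all
  member genes of one set by ±2 log2 units in one sample. The first
  planted damaging de novo gene is coupled into the first shifted set so
  the pipeline's DNA × pathway cross-link path is exercised.

Not emulated: linkage disequilibrium and sequence content, read-level
noise, covariate structure (sex, batch, cell composition), gene–gene
correlation beyond the planted pathway blocks, annotation errors, and any
realistic effect-size distribution — planted magnitudes are calibration
knobs chosen to be detectable by design, not estimates of CP biology.
Passing recovery tests therefore demonstrates that the statistical
machinery does what it claims on data matching its assumptions; it says
nothing about sensitivity on real cohorts.

# Test problem sizes

The suite exercises the end-to-end pipeline on the default 27-trio cohort
(600 genes, 40 clusters, 40 sets); null-calibration runs use 27 trios with
the non-splicing layers minimized (60 genes, 30 clusters) across 50 seeds;
exact-test agreement is exhaustive over all 2×2 tables with total ≤ 60;
GSVA oracle checks use 5-gene toys where the walk can be followed by hand.
These sizes were chosen so each property is measured with useful precision
while the whole suite stays quick to run.

# Known limitations

* The expression-outlier method is the package's own stand-in (the
  simplest defensible cohort-as-control scheme); the study it follows does
  not describe its expression method, only the count of findings.
* The splicing test replaces a regression framework with a one-vs-rest DM
  LRT; covariates cannot be adjusted for.
* ACMG classification is only as good as the asserted evidence codes;
  nothing is auto-asserted from scores or databases.
* With 27 samples, fence-based pathway calls and robust-z outliers have
  materially higher null rates than their large-n idealizations; the
  defaults and documentation reflect the n = 27 reality.
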