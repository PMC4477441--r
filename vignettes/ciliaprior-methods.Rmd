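---
title: "Methods: balanced-forest gene prioritization and exome intersection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: balanced-forest gene prioritization and exome intersection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliaprior)
```

# The model and its assumptions

`ciliaprior` treats disease-gene discovery for recessive ciliopathies as two
coupled ranking problems. First, a supervised phenotype model: given
image-derived knockdown features for (almost) every gene, plus orthogonal
functional-genomics features, how ciliary does each gene look? Second, a
variant-prioritization model: among the homozygous and potentially
compound-heterozygous variants surviving a standard exome filter cascade,
which genes recur across unrelated families once the search space is
restricted to the phenotype model's high-confidence candidates?

The phenotype model makes three assumptions worth stating:

* **Training labels are noisy but directionally correct.** Gold-standard
  ciliary genes and metabolic/housekeeping genes are used as positives and
  negatives only after cross-filtering against an independent evidence
  knowledge base (per-gene counts of supporting studies, "NOE"). The
  operational rule is the minimal reading of "remove conflicting
  annotation": a positive-source gene must have at least one evidence, a
  negative-source gene must have none, and a gene on both source lists is
  dropped. Genes absent from the evidence table count as zero evidences —
  absence of evidence is treated as no evidence, which is the only choice
  that lets large negative catalogs be usable at all. Whether the positive
  filter should use any-species or human-only evidence is not decidable from
  first principles; any-species is the default (`evidence_column`
  argument), since the knowledge base is built from many model organisms and
  the cilium is deeply conserved.
* **Class imbalance must be neutralized per tree, not by reweighting.**
  Negatives outnumber positives roughly 7:1 in a curated training set. Every
  tree of the forest is grown on a bag holding the positives bootstrapped to
  their own count *n*₊ plus exactly *n*₊ negatives drawn without
  replacement. Each tree therefore sees a balanced problem and the vote
  fraction is interpretable as a score with a 0.5 null, while across many
  trees the whole negative pool is still exploited.
* **Honest scores for training genes require out-of-bag bookkeeping.** A
  training gene's score averages only the trees whose bag excluded it. This
  is the forest's built-in cross-validation and is what makes the
  score-based FDR below meaningful. Because no pre-installed R forest
  exposes per-tree bags reliably enough for this contract, the bagging loop
  and the CART learner are implemented in the package itself (`src/forest.cpp`):
  Gini-split trees grown to purity, `mtry` features re-sampled at every node
  (square-root rule by default), deterministic given the seed.

# The score-based FDR

The selection rule needs a per-gene error estimate, and the only ingredients
available are the scores and the training labels. For a threshold *t*,

FDR(t) = #(training negatives with score ≥ t) / #(training genes with score ≥ t),

optionally multiplied by a prior ratio (default 1, i.e. the plain negative
proportion among selected training genes). Each gene is evaluated at its own
score, then a step-down pass (running maximum from the top score downward)
enforces monotonicity: a higher-scoring gene can never report a larger FDR.
The step-down direction is deliberate — it is the conservative resolution,
because a noisy dip in the raw estimate at a high threshold is overridden by
the worse estimate above it. If no training gene reaches a threshold the raw
value there is 0 by convention (nothing selected, nothing false). The
high-confidence set is `fdr < 0.1` by default.

This estimator is honest but crude: it ignores the positive/negative prior in
the unlabeled pool (the `prior_ratio` knob exposes exactly that correction)
and is granular at the top of the ranking where few training genes remain.
Both properties are inherent to estimating an FDR from ~2,000 training points
and are why the cutoff is a configuration value, not logic.

# Feature construction choices

**Quantile normalization** (`quantile_normalize`) forces each column of a
batch onto the across-column rank-mean distribution. Ties receive the mean of
the reference values over the tied positions, so ties stay ties and ranks are
preserved. The screen's two replicates are treated as two batches (each
replicate normalized internally); whether the original analysis normalized
per replicate or jointly is not stated anywhere usable, and per-replicate is
the choice that keeps the cross-replicate training protocol clean — the
`group_by` argument makes the alternative a one-liner.

**Reagent aggregation** (`aggregate_reagents`). Multiple siRNA reagents per
gene disagree when some have off-target effects. The consistency-weighted
median gives reagent *i* the weight 1 / (ε + |xᵢ − median(x₋ᵢ)|), with
ε = 0.05 × IQR of the gene's scores (floored at machine-precision scale),
then takes the weighted median — defined as the smallest score whose
cumulative weight reaches half the total. The cited aggregation method is
not restated in any published formula; this inverse-deviation rule is the
package's own closed, testable operationalization of "down-weight discordant
reagents" and is deliberately simple: a single concordant pair beats a lone
outlier ([1, 1, 9] aggregates to 1).

**Expression signatures** (`expression_signature_features`). Samples with an
RNA-quality score below `quality_min` are excluded (default 6.0 on the 1–10
RIN scale; the printed cutoff "0.6" in the source material is read as a typo
for 6.0, since 0.6 is outside the RIN scale and would exclude nobody), the
matrix is quantile normalized across all surviving samples, and each tissue
contributes its per-gene median plus the gene loadings of the smallest
leading-PC set reaching 95% cumulative variance (capped at 7). Loadings are
unit-norm with the largest-magnitude entry oriented positive, which makes
results invariant to sample order up to nothing at all — a pure convention,
tested as such. A zero-variance tissue contributes only its median; a
two-sample tissue contributes at most the (closed-form) difference direction.

**Assembly** (`assemble_features`) inner-joins all blocks on gene identifier
and refuses missing values: genes not covered by every source are dropped and
counted in a join report, mirroring how multi-source fusion actually loses
coverage. No imputation is offered on purpose; an imputed screen phenotype is
not a phenotype.

# Validation statistics

The ranking is validated against ordinal evidence counts without using them
for training: scores are binned by NOE (bins 0–7 then ≥8 for any-species
evidence, 0–3 then ≥4 for human-only; printed bin labels like ">8" are read
as "≥8", otherwise the count 8 would have no bin), training genes can be
excluded, each non-zero bin is compared to the zero bin by a one-tailed
Wilcoxon rank-sum test, and the overall ordered trend is tested by
Jonckheere–Terpstra. Both tests have dual code paths — exact by enumeration
(all C(N, n) label assignments, resp. all multinomial group assignments) for
small tie-free inputs, and a tie-corrected normal approximation with a 0.5
continuity correction otherwise — and the switchover sizes (12 and 10) are
small enough that the exact path is itself testable by brute force. Gene-set
enrichment uses the upper-tail hypergeometric p with Benjamini–Hochberg
control, testing only sets of background-intersected size 5–400 with overlap
at least 3.

# The variant cascade

Filters are applied in a fixed order but the record-level ones commute (a
tested invariant): autosomal; population allele frequency < 1%; CADD-phred
≥ 10 for everything except frameshifts, which instead need GERP ≥ 4 (CADD is
not defined cleanly for indels); homozygous genotypes must be inherited from
two carrier parents where parents were sequenced (a homozygous proband with a
homozygous-reference parent is a Mendelian violation and is dropped with a
flag, not silently); families without parental data pass through flagged
"unphased". Compound-het candidates are all unordered pairs of distinct
heterozygous variants in one gene and family; phase is inferred by descent
when parental genotypes identify each variant's origin, cis pairs are
excluded, and unknown-phase pairs are kept as "potential" — the convention
that matches how such pairs are tabulated in practice. Control-database
subtraction removes a homozygous variant only if a control carries it
homozygous (heterozygous healthy carriers must not disqualify a recessive
allele — the planted common frameshift is carried by ~1/300 healthy
individuals by design) and removes a pair only when both members co-occur in
the same control individual (a true biallelic control); a looser any-control
mode exists behind `require_same_individual = FALSE`. After intersection with
the prioritized gene list (coding and canonical-splice consequences only), a
gene is flagged when qualifying biallelic genotypes occur in more than two
families, each family counted once per gene. Because the count convention
for "variants" is genuinely ambiguous when pairs are involved, the summary
reports both: pairs as single units and pairs as two member variants.

X-linked inheritance is excluded by the autosomal filter; that is a known
limitation of the cascade (JS has X-linked causes), kept because the cascade
is defined as autosomal.

# Cohort statistics

Allele frequencies are printed as half-even two-decimal percents. The Fisher
test is exact on the 2×2 allele table with the probability-mass two-sided
rule (sum of all tables with the observed margins no more probable than the
observed one) — documented because mid-p and doubling conventions differ.
The odds ratio is the plain cross-product on allele counts, with the Haldane
0.5 correction only when a cell is zero. On the 17/326 vs 2/536 table the
cross-product is ≈ 14.69; published round-numbers for such tables sometimes
disagree with the cross-product (13.51 has been printed for this very
table), and the package reports the arithmetic it can defend rather than
reverse-engineering someone else's calculator.

# The synthetic world

The generators state one fixed world; they are not tuned to make tests pass.

* Screen: `n_params = 31` image parameters in 2 replicates; independent
  Gaussian per-gene features (no published screen noise model exists, so the
  simplest model sufficient for classifier testing is used); truly ciliary
  genes (`frac_positive`, default 0.1) shifted by `effect_size` (default 2)
  standard deviations on 10 informative parameters; replicate r offset by
  `batch_shift`·(r−1), default 0.5. 80% of ciliary genes become training
  positives, the rest are held-out benchmark candidates; 30% of remaining
  genes are known negatives, the rest unknown — roughly the label coverage a
  curated training set achieves.
* Evidence: NOE_any ~ Poisson(3) for ciliary, Poisson(0.2) otherwise;
  NOE_human a binomial thinning, so NOE_human ≤ NOE_any by construction.
* Expression: log-normal RPKM-like values with tissue-specific per-gene
  profiles; ciliary genes share a shift in half the tissues so expression
  features carry signal; 5% of samples get sub-cutoff quality scores.
* Cohort: 20 families; one causal gene with 2 homozygous families and 2
  compound-het families sharing a frameshift allele at population frequency
  0.0036 (each compound het one paternal and one maternal variant);
  background families carry variants that each fail at least one filter,
  plus occasional qualifying but non-recurrent biallelic genotypes in random
  genes; controls carry common variants only.

Every generator draws from its own stream (`seed` plus a fixed per-generator
offset), so adding a call to one generator never perturbs another, and
identical configuration yields byte-identical written outputs.

What a green test does **not** establish: the synthetic screen has none of
the real data's plate/edge effects, feature correlation structure, or
heavy-tailed phenotypes; the variant tables contain no alignment or calling
artifacts and the control database is clean by construction. Green tests
establish that the machinery implements its stated contracts and recovers
planted signal of the stated size — not that the real-data operating
characteristics (AUCs near 0.86, 591-gene candidate sets, specific trend
p-values) are reproduced, which would require the original proprietary
inputs.

# Numerical choices and degenerate inputs

* Tie handling: rank means averaged over tied positions (quantile
  normalization); ties counted ½ (AUC, rank tests, JT).
* Exact-path switchovers: rank-sum at pooled n ≤ 12, JT at n ≤ 10 — small
  enough to enumerate in tests, large enough to cover the regimes where the
  normal approximation is worst. The approximation uses tie-corrected
  variance and a 0.5 continuity correction; near the switchover it agrees
  with enumeration within 0.02.
* Forest determinism: all sampling uses a Mersenne Twister seeded from the
  configuration, with raw-stream modulo reduction rather than
  `std::uniform_int_distribution` (whose output is implementation-defined).
* Degenerate FDR inputs: no training gene above a threshold gives raw FDR 0;
  all-negatives-on-top gives FDR 1 at the top after monotonization.
* Weighted median on even counts with equal weights returns the lower
  median — a consequence of the "smallest score reaching half the total
  weight" definition, asserted rather than averaged away.
* `reduction_percentage` reports one decimal, matching how such reductions
  are printed.

# Known limitations

* The FDR estimator conditions only on training labels; calibration on the
  unlabeled pool is unverifiable without external truth.
* The consistency-weight rule for reagents is one defensible
  operationalization among several; it is configurable at the code level but
  there is no per-reagent quality input.
* Phase-by-descent cannot detect cis pairs when only one parent carries
  both variants' alleles ambiguously; such pairs stay "unknown/potential",
  which overcounts compound hets exactly the way purely computational
  tabulations do.
* The cascade ignores X-linked and de novo dominant architectures by
  construction.
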