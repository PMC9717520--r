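---
title: "Statistical methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(micromat)
```

`micromat` implements the statistics of a longitudinal sow–piglet probiotic
study design: a 2×2 layout (maternal dietary supplementation × oral dosing of
the piglet) sampled at days 0, 3, 7, 14, 21 and 28 of life, with 16S feature
tables, an untargeted serum peak matrix, daily health records, and litter as
the natural blocking unit. This vignette documents the models, the defaults
and why they were chosen, what the synthetic-data generators do and do not
emulate, and the numerical decisions a maintainer would want written down.

## Feature-table preprocessing

Counts live in a samples × taxa matrix with an optional semicolon-delimited
lineage per taxon. Rarefaction is subsampling **without replacement**
(hypergeometric) to a fixed depth — the default depth of 27,226 reads matches
a cohort sequenced at 43,559 ± 7,824 reads — and samples below depth are
dropped and reported rather than silently kept. The rare-taxon filter removes
a taxon only when it fails **both** thresholds (mean relative abundance
< 0.01% **and** prevalence < 20%): the rule's wording joins the clauses with
"and", so the conjunctive reading is the default and `rule = "or"` is a flag.
Prevalence counts strictly positive entries of the unfiltered relative table;
the filter is idempotent.

## Diversity, ordination, and rank tests

Richness, Shannon entropy (nats) and the Gini–Simpson index `1 − Σp²` are
computed on the rarefied table; the inverse-Simpson variant is a flag because
"Simpson" alone is ambiguous in the field. PCoA retains negative eigenvalues
in the report but excludes them from the proportion-explained denominator (no
Lingoes/Cailliez correction — axes are for display, tests run on the
distances themselves). PERMANOVA delegates to the adonis-style partition with
the add-one permutation p-value; permutations are unrestricted by default
because repeated measures per subject were left unmodelled in the study
design this package mirrors, but a `strata` argument restricts permutation
within litters when that is the right unit. The Scheirer–Ray–Hare test ranks
the pooled response, pushes the ranks through the two-way ANOVA partition,
scales by the rank mean square `n(n+1)/12` with a tie correction, and refers
each effect to chi-square; with a single-level second factor it reduces
exactly to Kruskal–Wallis, which is tested.

## LEfSe-style differential abundance

Stage one is a per-feature Kruskal–Wallis screen (mid-rank ties; constant
features get p = 1 with a warning). Stage two puts relative abundances on the
per-million scale, draws 30 bootstrap rounds of two-thirds of each class,
fits a one-axis linear discriminant per round (tiny jitter keeps the
within-class covariance invertible; rounds where the fit degenerates fall
back to the raw mean difference), and scores each feature as
`log10(1 + mean effect)`, where the effect averages the feature's
contribution along the unit-norm discriminant axis with its raw group-mean
difference. A feature passes at `kw_p < 0.05` and score > 2.0. The subclass
(within-class consistency) stage of the canonical procedure is omitted: the
designs here have no subclass factor. n_boot and the subsample fraction are
exposed; raw screen p-values are used for thresholding with BH available as
an option.

## SparCC networks

SparCC infers correlations of unobserved basis abundances from compositions:
fractions are drawn from a Dirichlet posterior (pseudocount 1), the variation
matrix `T_ij = var(log f_i/f_j)` is formed, basis variances solve the linear
system implied by `T_ij ≈ ω_i + ω_j` under sparsity, and the most strongly
correlated pair above 0.1 is excluded from the system for up to 10 rounds
(a pair is never excluded if it would drop a component's usable degree below
two). Twenty inner Dirichlet iterations are averaged, clipped to [−1, 1].
Pseudo-p-values permute each taxon's counts across samples independently —
the reference procedure's "bootstrap" — with the add-one convention, so the
smallest attainable p is `1/(n_boot+1)`. One numerical consequence worth
knowing: with `n_boot = 19` the smallest p equals exactly 0.05 and a strict
`p < 0.05` threshold can never fire; calibration checks therefore use
`n_boot = 99` (rejection region p ≤ 0.04). Networks keep edges with
`|r| > 0.7` and `p < 0.05` as strict inequalities; isolated nodes are
retained. Topology metrics use plain unweighted definitions; average path
length is computed on the largest connected component rather than set to
infinity; "transitivity centrality" is read as the per-node local clustering
coefficient. Two-network comparison reports both the KS test on the original
node-attribute vectors and the median p over resampled vectors, because the
bootstrap-KS protocol is ambiguous in the field and the two can disagree.

## Metabolomics

Peaks missing in more than 80% of biological **or** 50% of QC samples are
removed; remaining missing values are imputed at half the peak's minimum
observed intensity (the standard below-detection-limit default — the choice
is logged per peak). Total-intensity normalization rescales every sample to
the cohort's median total, which preserves within-sample ratios exactly.

OPLS-DA is implemented as orthogonal signal correction against the class
vector (one orthogonal component by default) followed by a single predictive
PLS component on unit-variance-scaled peaks; VIP is computed on the
predictive component only, so `mean(VIP²) = 1` holds as an algebraic
identity and is asserted on every run. Selection requires `VIP > 1` and a
BH-adjusted two-sided t-test `p < 0.05`. The BH family is **all** peaks, not
the VIP > 1 subset: VIP correlates with the t statistic under the null, so
adjusting within the selected subset is selection-biased (measured on null
data it produces a ~20% family-wise false-selection rate, versus the nominal
5% with the global family).

Coabundance modules: peaks are correlated with the biweight midcorrelation
(robustness constant 9, Pearson fallback when the MAD is zero), turned into
a signed adjacency `((1+r)/2)^β` with β = 8 (the scale-free topology choice,
fixed rather than re-estimated per dataset), converted to topological
overlap, and clustered by average linkage on `1 − TOM` with a **static** cut
at height 0.75 — a deliberate simplification of dynamic tree cutting; at
these scales the minimum-module-size rule (5) dominates the outcome, and the
height is exposed. Sub-minimum clusters are relabeled grey and grey peaks
are excluded from module tests. Eigenmetabolites are unit-norm first
principal components of the standardized module peaks, sign-oriented to
correlate positively with the module mean so downstream Wilcoxon contrasts
are deterministic. Modules are labeled M01, M02, … by decreasing size.
Intensities should be analyzed on the log scale (the pipeline does);
correlation structure planted on the log scale is attenuated on the raw
scale by the lognormal transform and by imputation outliers.

## Microbiota age and relative maturity

A random forest (500 trees, package defaults otherwise, mandatory seed)
regresses chronological age on the relative abundances of the reference arm
— the piglets that received neither dietary nor oral supplementation. Taxa
are ranked by permutation importance; repeated k-fold cross-validation (10
folds × 5 repeats by default; CV forests use 100 trees for speed) scans
nested importance-ordered subsets, and the selected size is the global
minimum of the mean CV-error curve (MSE; a 1-SE rule is a flag). When
trajectories overlap, the argmin legitimately sits below the number of
planted taxa — the extra taxa add no out-of-sample information — so subset
sizes of 7–12 against 10 planted taxa are the expected behaviour, not a
defect. The final forest is refitted on the selected taxa; a cubic smoothing
spline with GCV-chosen smoothness maps chronological age to expected
microbiota age on the reference arm (with ≤ 6 distinct ages this approaches
interpolation of per-age means, which is acceptable here). Relative maturity
is the forest prediction minus the spline expectation; it is mean-zero on
the reference samples by construction, and ages outside the spline support
extrapolate linearly (natural-spline behaviour) with a warning. The
microbiota-age-for-Z variant is deliberately not part of the default
outputs.

## Multi-omics coupling

Co-inertia analysis replaces each table by its Bray–Curtis PCoA coordinates
(all positive axes, capped at n − 1) before the cross-covariance SVD; a
raw-table route (`via_pcoa = FALSE`) serves matrices that are not
abundances. The RV coefficient
`trace(XᵀY YᵀX)/√(trace((XᵀX)²)·trace((YᵀY)²))` is 1 under any orthogonal
transform of either centered table. The Monte Carlo test permutes rows of Y
with the add-one convention. Spearman association matrices use mid-ranks,
t-approximation p-values, and BH across the **full** matrix (not per row).
RDA dummy-codes factors against a first-level baseline and drops aliased
constraints.

## Diarrhea labels, panel selection, and evaluation

Daily health records are collapsed to sampling days: diarrhea on the
sampling day, or an episode of ≥ 2 consecutive days since the previous
sampling day (assigned forward), labels the sample; undecidable gaps yield
"unknown". Incidence is `events / (piglets × days) × 100`.

mRMR discretizes features into quantile tertiles (invariant to monotone
transforms, so the skew of relative abundances is immaterial) and greedily
maximizes label relevance minus mean redundancy (MID criterion; quotient is
a flag); ties break by column order and constant features sort last.
Incremental feature selection trains an SVM on each ranked prefix under
leave-one-out cross-validation and picks the prefix maximizing the MCC of
the pooled held-out predictions (ties to the smallest panel). The default
kernel is radial basis with C = 1 since the kernel is unstated in this
class of study; the linear kernel is exposed and is the right choice when
the decision boundary is known to be linear, as in the separable synthetic
fixtures. Features are standardized once up front; the zero-denominator MCC
convention is 0. ROC/AUC uses trapezoidal integration (identical to the
normalized Mann–Whitney U, asserted to 1e-9) with a percentile-bootstrap CI
over test samples.

## Synthetic data: what it emulates, and what it does not

`simulate_cohort` draws Dirichlet-multinomial counts (concentration 50 —
realistic 16S overdispersion) around
`softmax(base + age trajectory + diet shift + litter offset)` with lognormal
library sizes; the default design is the study's: 4 litters × 3 piglets per
arm, six sampling ages. Age-linked taxa follow logistic trajectories
(amplitude 3 log units, varied slopes, midpoints tiling the age axis) and
are planted at moderate baseline abundance: a planted taxon that is absent
from 95% of samples carries no recoverable signal at realistic depth, and
varied slopes keep the taxa complementary rather than redundant — both
choices serve the generators' purpose of planting *recoverable* structure.
A per-arm "maturity shift" advances or delays the age entering the
trajectories; maturity tests plant it on the oral arm of the control diet so
acceleration is not confounded with composition shifts (planting both on one
arm biases the forest through closure renormalization — a real phenomenon,
but not the one under test). `simulate_metabolome` uses a one-factor
Gaussian model per module on the log scale, pooled-mean QC replicates, and
MCAR missingness. `simulate_diarrhea_labels` draws Bernoulli labels with a
logit linear in standardized panel abundances, the panel drawn from
prevalent (≥ 50%) taxa; the logit scale is the dial between a pure null
(0) and near-separable labels (≫ 10). `simulate_linked_tables` shares
latent factor scores between two noisy linear images.

What the generators do **not** emulate: phylogenetic correlation among taxa,
compositional interactions beyond closure, batch and run-order effects in
the peak matrix, informative (intensity-dependent) missingness, label noise
from imperfect clinical scoring, or inter-cohort heterogeneity — the known
reason a classifier's AUC drops on an external validation cohort. Passing
recovery tests on these simulations therefore demonstrates correctness of
the machinery, not expected field performance on real data.

## Test and acceptance problem sizes

The suite exercises each stage at deliberately modest scales chosen for a
single CPU: calibration checks use 200 null replicates (199-permutation
PERMANOVA/Monte Carlo runs; 99-bootstrap SparCC on 12 taxa × 40 samples);
SparCC recovery uses 50 taxa × 200 samples at depth 50,000; module recovery
uses 95 peaks × 60 biological samples (correlation-network inference below
~30 samples is unreliable, so the recovery fixture sits above that);
maturity recovery runs ten cohorts of 100 taxa × 288 samples with
10-fold × 3-repeat CV; LEfSe and OPLS-DA recovery use 20
seeds each; the classifier uses 192 samples × 60 taxa with a 15-prefix IFS
scan; the demo pipeline completes in well under ten minutes. Every random
draw flows through an explicit seed argument (`withr::with_seed`
internally), so the global RNG stream of the caller is never consumed:
identical configs are bit-identical, which the pipeline manifest checksums
verify.
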