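---
title: "Integral genomic signature modeling of therapeutic response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integral genomic signature modeling of therapeutic response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Predicting a binary therapeutic endpoint — pathological complete response
(pCR) versus residual disease after neoadjuvant therapy — from multi-omics
tumor profiles faces four structural obstacles: feature counts in the
thousands against cohorts of a few hundred patients; strong multicollinearity
from co-expression and co-occurring genetic events; noisy, platform-dependent
feature calls; and the clinical requirement that a model be auditable.
Sparse learners answer the dimensionality problem by discarding correlated
features, which makes them brittle exactly where genomic data are weakest:
a feature dropped or spuriously added by sequencing error cannot be
compensated by the redundant features that carried the same signal.

The integral-signature approach implemented here takes the opposite route.
It **keeps** every feature whose association with response clears a
significance threshold — the integral genomic signature — and controls the
resulting redundancy per patient, using co-occurrence structure estimated
from a large *unlabeled* reference cohort. Redundant features then act like
redundant steel rods in a pillar: any one may fail, the aggregate signal
persists.

## The model

All features are binary patient attributes: mutation status (`MUT:<gene>`),
adjacent gene rearrangements (`AGR:<a>-<b>`), and nested differential
expression levels (`EXPR:<gene>|Up_Lk`, `Down_Lk`, k = 1..12, see below).

**Weights.** For feature *i*, the weight is the phi coefficient (the Pearson
correlation of two 0/1 variables),

$$\omega_i = \frac{n_{11}n_{00}-n_{10}n_{01}}
                 {\sqrt{n_{1\cdot}\,n_{0\cdot}\,n_{\cdot 1}\,n_{\cdot 0}}},$$

computed between the feature column and the pCR label. Features with
$|\omega_i| < 0.13$ are discarded; the survivors with $\omega_i>0$ form the
*sensitive* class and those with $\omega_i<0$ the *resistant* class. The
cutoff is applied symmetrically to both signs — the feature universe should
describe resistance as richly as sensitivity. Two pruning rules precede
retention: level-1 expression features are always removed (the weakest level
carries nearly no effect and only adds noise), and any gene whose retained Up and
Down features predict the *same* response direction is internally
inconsistent, so all its expression features are removed.

**Redundancy penalty.** From the unlabeled reference cohort the package
computes the Otsuka–Ochiai coefficient between features — the cosine
similarity of their carrier sets,

$$K_{ij} = \frac{|A_i \cap A_j|}{\sqrt{|A_i|\,|A_j|}}.$$

For a patient carrying retained features $1..n$, each feature's penalty is
the sum of its similarities to the patient's other features **within its own
cluster**,

$$\varepsilon_i = \sum_{j \in C(i)} K_{ij} \;\ge\; 1,$$

where clusters come from ward.D2 hierarchical clustering of the patient's
features on distance $1-K$, cut with a hybrid dynamic tree cut (deepSplit 2,
minimum cluster size 2; unassigned features become singletons). The cluster
gate exists because weak but nonzero similarities between unrelated features
would otherwise accumulate over hundreds of features and swamp the penalty;
only similarity inside a feature's own co-occurrence module counts.
$K_{ii}=1$ is included, so $\varepsilon_i = 1$ means "no redundancy" and
division is always safe.

**Scores.** Each feature contributes an effective weight
$EW_i = \omega_i/\varepsilon_i$: a feature duplicated $k$ times contributes
$k \cdot \omega/k = \omega$ in aggregate, exactly once. The effective
feature number $EFN = n/\bar\varepsilon$ plays the same role for the
denominator — it counts the patient's features after collapsing redundancy.
The two class scores of a patient are

$$S = \frac{\sum_{i \in \text{sensitive}} |\omega_i|/\varepsilon_i}{EFN},
\qquad
R = \frac{\sum_{i \in \text{resistant}} |\omega_i|/\varepsilon_i}{EFN},$$

where $n$, the clustering, and $\bar\varepsilon$ are **patient-level**
quantities over *all* of the patient's retained features, shared by both
class scores. This is a deliberate design choice. The total feature count
"associated with a patient" is a property of the patient, not of a response
class, and sharing $EFN$ puts $S$ and $R$ on a common per-effective-feature
scale, so their comparison measures the *balance* of sensitive versus
resistant evidence. The alternative — normalizing each class by its own
feature count — collapses each class score to the mean $|\omega|$ of that
class's carried features; since marginally significant features of a class
are, by construction, carried slightly more often by patients of that very
class, the per-class mean is diluted for exactly the patients it should
flag, and the score loses (and can even invert) its discriminative
direction. With the shared denominator the closed-form limits still hold:
when a patient's carried features all belong to one class and the reference
makes them orthogonal, that class score is the plain mean $|\omega|$; k-fold
duplication never changes any score.

**Decision rule.** Patients live in the $(R, S)$ plane. A dividing line
(D-line) $S = mR$ through the origin is fitted on training data by scanning
angles $\theta \in \{0.5^\circ, 1^\circ, \ldots, 89.5^\circ\}$ and keeping
the slope maximizing the Youden index $J = TPR - FPR$ of the rule
$S > \tan(\theta) R$ (ties break to the smallest angle; a degenerate cloud
of identical score pairs falls back to slope 1 with a warning). The final
score of a patient is the signed perpendicular distance

$$d = \frac{S - mR}{\sqrt{1+m^2}},$$

positive above the line; `predicted = 1` iff $d > 0$.

**Leave-one-out training scores.** A training patient's own label must not
inform its score, or the D-line overfits. When scoring training patients,
weights (and hence retention and class membership, within the trained
feature universe) are recomputed with that patient held out. External
cohorts are scored with full-cohort weights — this is the only reading that
changes training scores while leaving test-time scoring untouched.

## Expression levels

Continuous expression enters as twelve nested binary levels per direction.
A patient's within-cohort percentile of a gene (average ranks, ties shared,
scaled to (0, 100]) is compared to cutoffs, by default 52, 56, ..., 96 for
`Up_L1..L12` and mirrored 48, ..., 4 for `Down`. Membership is cumulative —
`Up_L7` implies `Up_L1..L6` — so a patient's carried level depth encodes
*how extreme* its expression is, and the per-gene feature ladder is exactly
the kind of redundant, graded structure the penalty is built for. The
cutoffs are evenly spaced stand-ins (configurable in `level_scheme()`):
nothing downstream depends on their exact values beyond monotone nesting.
Percentiles are computed within-cohort; no external reference distribution
is assumed.

## The dynamic tree cut

The hybrid dynamic branch cut is implemented inside the package. A static
cut at 99% of the dendrogram height defines coarse branches; each branch is
then recursively split at its top merge when both sub-branches look like
genuine clusters — internally tight (normalized mean merge height, "core
scatter", at most 0.82 for deepSplit 2) and well separated from the merge
point (normalized gap at least $(1-0.82)\cdot 3/4$). The deepSplit level
maps to the scatter threshold through the published ladder (0.64, 0.73,
0.82, 0.91, 0.95). A sub-branch smaller than the minimum cluster size that
is well separated from a qualifying sibling is peeled off as an outlier;
outliers become singleton clusters, so every feature always has a label and
$\varepsilon_i=1$ degrades gracefully for isolated features. The reference
algorithm's final PAM-style reassignment stage is intentionally omitted:
for penalty gating, conservative cluster membership (leaving a doubtful
feature as a singleton) is the safe direction, and the omission keeps the
per-patient cut cheap enough to recompute for every patient.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `cutoff` | 0.13 | retention threshold on the absolute phi coefficient |
| `level_scheme()` | 52..96 / 48..4 | percentile cutoffs of the 12 nested expression levels |
| `deep_split` | 2 | aggressiveness of the dynamic cut (0–4) |
| `min_cluster_size` | 2 | smallest cluster the cut may emit |
| `cut_height_frac` | 0.99 | static cut height as a fraction of tree height |
| `angle_grid_deg` | 0.5 | D-line angle grid step, degrees |

The 0.13 cutoff is the model's single most influential parameter; it was
adopted as the standard operating point of the method and is exposed for
re-tuning on new treatment contexts via internal train/test splits. The
distance transform $1-K$ and the minimum cluster size are not dictated by
the method definition and are kept configurable; the angle grid is finer
than any Youden plateau reachable at cohort sizes of a few hundred.

## The synthetic cohort generator

Real trial cohorts with pCR endpoints are controlled-access, so the package
ships a generator (`sim_config()`, `simulate_cohorts()`) that reproduces the
two structures the method exploits and nothing else:

* **redundant feature blocks** — features come in blocks (default 40 blocks
  of 25) driven by a per-patient latent Bernoulli state; features copy their
  block's driver with a small independent flip noise, creating strong
  within-block co-occurrence in every cohort drawn from the model;
* **a transferable unlabeled reference** — the reference cohort (default
  1,000 patients) is drawn from the same block model with label-marginalized
  driver probabilities, so co-occurrence estimated on it applies to the
  labeled cohort (default 200 patients, balanced labels).

Predictive blocks (default 8) alternate direction: odd blocks use the
`effect` carriage pair (0.7 given pCR, 0.2 given non-pCR) and even blocks
the swapped pair, so both response classes have planted signal and the
$(R,S)$ geometry is exercised symmetrically. Non-predictive blocks carry at
a background rate of 0.15, typical of recurrent alteration prevalences. The
per-feature flip noise defaults to 0.02, a sequencing-error-scale rate; with
25-feature blocks this keeps a driver-off patient's stray features below one
per block on average. A much larger flip rate would give every patient a few
features of *every* block — and because the reference places those strays
inside the block's cluster, every patient would carry every co-occurrence
module at the effective level, erasing the latent block structure that any
scorer (this one or a baseline) could use.

What the generator does **not** emulate: graded effect sizes and nested
level ladders (all features of a block share one effect), batch effects,
platform differences between labeled and reference cohorts, missing-feature
censoring, class imbalance, and correlation *between* blocks beyond chance
co-occurrence. Tests passing on this generator therefore demonstrate the
algorithm's mechanics — recovery of planted signal, redundancy invariance,
chance-level behavior under label permutation, robustness ranking against a
sparse baseline — not clinical performance on real trials.

Error injection (`inject_errors()`) emulates feature-call errors at rates
up to 0.25: false negatives clear set bits independently at the given rate;
false positives set clear bits at a rate normalized to the matrix's set-bit
count, because binary genomic matrices are sparse and unnormalized per-zero
flipping would dwarf any realistic error process; mode `both` applies each
mechanism at half the rate.

## Numerical choices and degenerate inputs

* Constant feature columns get $\omega = 0$ (not NaN) and fall to the
  cutoff; constant genes emit no expression features.
* Features absent from the reference cohort get $K_{ii}=1$, $K_{ij}=0$:
  unobserved features are treated as non-redundant.
* A patient with no retained features scores $(0, 0)$, final score 0,
  predicted non-sensitive.
* Removing a held-out patient must leave both classes non-empty, else
  leave-one-out scoring is a hard error.
* The similarity matrix is stored dense up to 5,000 features and sparse
  (coefficients below 0.01 dropped) beyond — a memory contract only.
* All randomness flows from explicit integer seeds; generator output,
  weight tables and score files are byte-reproducible under a fixed seed.

## Problem sizes

The test-suite and the acceptance script run the full pipeline at the
default generator scale (200 labeled patients, 1,000 reference patients,
1,000 features), with 10 stratified 90/10 splits for held-out performance,
100 (tests) or 30 (script) label permutations for the null, and 5 error
seeds per rate for the robustness contrast. Unit fixtures use smaller
cohorts (tens of patients) built in code.

## Known limitations

* The penalty treats co-occurrence as the only source of redundancy;
  features that are biologically coupled but anti-correlated in carriers are
  not penalized together.
* The D-line is constrained through the origin; cohorts whose class-score
  clouds are offset from the origin would need an intercept.
* Per-patient clustering makes $\varepsilon$ adaptive but also means a
  feature's penalty varies across patients; scores are comparable between
  patients only through the shared EFN normalization.
* The lasso baseline uses internal cross-validation on the training split
  only; it is a robustness comparator, not a tuned competitor.
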