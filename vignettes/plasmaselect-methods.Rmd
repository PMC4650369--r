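---
title: "Supervised analysis of plasma miRNA arrays: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised analysis of plasma miRNA arrays: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The problem

Plasma circulating miRNAs are candidate minimally-invasive biomarkers, but
hybridization-array measurements of them are noisy, lack agreed housekeeping
normalizers, and typically come with many more features than samples.
`plasmaselect` implements a complete supervised strategy for this setting,
exercised here on the hemolysis problem: red-blood-cell lysis releases
erythrocyte miRNAs into plasma, so hemolyzed samples ("cases", hemolysis
score HS > 0.14) show up-regulated miRNA signatures relative to
not-hemolyzed samples ("controls", HS <= 0.057; intermediate samples are
excluded). Because the ground truth for hemolysis-related miRNAs is
comparatively well established, this context doubles as a validation bed
for the strategy itself.

The pipeline stages are:

1. **Cohort construction.** Cases and controls may be imbalanced in
   disease status, age at blood drawing, and drawing year. A logistic
   propensity model on those three covariates supplies a propensity score
   (PS); each case is greedily matched to the two nearest available
   controls on the logit-PS scale, accepting only controls within a
   caliper of 0.2 standard deviations of the logit PS. Whole matched
   triplets are then randomized in half into training and validation sets,
   preserving the 1:2 class ratio in each.
2. **Pre-processing.** Features detected in fewer than 90 % of the
   reference samples are dropped. Ratio normalization then uses every
   retained feature in turn as a normalizer: one log2 ratio per unordered
   feature pair (n features give n(n-1)/2 ratios; 88 give 3828), so no
   housekeeping gene is needed and each differential feature can
   "auto-select" its own normalizer.
3. **Class comparison.** Each feature is tested with a two-sample t-test
   (location) and the two-sample Anderson-Darling (AD) test (an omnibus
   test weighting the distribution tails). The two p-value families are
   adjusted separately by Benjamini-Hochberg; a feature is significant when
   either adjusted p-value is below 5 % (the union rule). Features are also
   classified into concordance quadrants (both / t-only / AD-only /
   neither).
4. **Class prediction, step 1 — bootstrap ranking.** Over stratified
   bootstrap replicates of the training set, three conceptually different
   selectors run on each replicate: nearest shrunken centroids (PAM),
   random forests with the Boruta all-relevant procedure, and an Elastic
   SCAD SVM. A feature scores an occurrence when **all three** select it in
   the same replicate; features are ranked by occurrence count and pairwise
   co-occurrences define a network (the "egg-shaped plot" data, edges
   filtered at a minimum co-occurrence, 300 at B = 1000).
5. **Class prediction, step 2 — classifier selection.** Linear SVMs over
   the top-k ranked features (k forward-inclusive), a grid of costs and
   class weights, are each scored by leave-one-out cross-validated
   sensitivity, specificity and Youden index J = sens + spec - 1. Models
   sharing an exact (FPR, TPR) point form a group; groups are ranked by J,
   and within a group the parsimonious model (fewest features, then
   smallest cost, then most balanced weights) is the representative, which
   is finally evaluated on the validation set with stratified bootstrap
   95 % percentile confidence intervals.

# The Anderson-Darling test, asymptotic with ties correction

The two-sample statistic is the tie-adjusted midrank ("discrete plus
continuity correction") form: with pooled distinct values $z_j$ of
multiplicity $l_j$, pooled midrank counts $B_{aj}$ and per-sample midrank
counts $M_{aij}$,

$$A^2 = \frac{N-1}{N}\sum_{i=1}^{2}\frac{1}{n_i}\sum_j \frac{l_j}{N}
\frac{(N M_{aij} - n_i B_{aj})^2}{B_{aj}(N-B_{aj}) - N l_j/4}.$$

Strata with a non-positive denominator are skipped; a fully constant pooled
sample returns statistic 0 and p = 1 (as does a constant feature in
`compare_classes()`, which keeps feature indexing stable).

The statistic is standardized as $T = (A^2 - 1)/\sigma_N$ with the exact
finite-N standard deviation $\sigma_N$ (the published variance polynomial
in N for k = 2 samples). For the p-value we use the fact that for two
samples the limit law of $A^2$ is the classical Anderson-Darling limit
$\sum_j \lambda_j Z_j^2$ with $\lambda_j = 1/(j(j+1))$: the published
critical-point fits at k = 2 are quantiles of exactly this law (e.g.
$1 + 1.961\,\sigma_\infty = 2.493$ against the classical 5 % point 2.492,
and the 1 % point 3.857 reproduced exactly, with
$\sigma_\infty = \sqrt{2(\pi^2/3 - 3)} \approx 0.7614$). We therefore
evaluate the limit CDF directly by Imhof inversion (400 terms, remainder
folded in as its mean) on a fixed grid, interpolated by a monotone spline
of log p. Compared with interpolating a handful of tabulated critical
points, this gives a p-value that is smooth and accurate over the *whole*
range — the package's permutation-oracle tests require agreement within
0.02 everywhere, including mid-range p. Reported p-values are clipped to
[1e-7, 1]; the clip only binds for standardized statistics beyond roughly
$A^2 = 12.5$.

# The three selectors

The analysis framework fixes the three algorithm families but none of
their hyperparameters; the defaults below are this package's own choices,
surfaced in the API.

**Nearest shrunken centroids.** Standardized centroid differences
$d_{kj} = (\bar x_{kj} - \bar x_j) / (m_k (s_j + s_0))$ with
$m_k = \sqrt{1/n_k - 1/n}$ and the usual offset $s_0$ = median of the
per-feature pooled SDs, soft-thresholded at $\Delta$. $\Delta$ is chosen by
stratified cross-validated misclassification over a grid from 0 to the
largest $|d|$ (30 points stand-alone); ties resolve to the **larger**
$\Delta$, i.e. the sparser model.

**Boruta random forests.** Each iteration appends a shuffled shadow copy of
every active feature, fits a random forest (gini splits,
mtry = sqrt(p), OOB permutation importance — implemented in C++ and
restricted to features a tree actually uses), and scores a hit when a real
feature's importance beats the best shadow. Two-sided binomial tests at a
Bonferroni-corrected 5 % level (over the input feature count) mark features
Confirmed or Rejected; Rejected features leave the design (concentrating
the forest), and features still Tentative at `max_iter` count as *not*
selected — a strict reading that favors stability of the three-way
intersection. Stand-alone default: 500 trees, 50 iterations.

**Elastic SCAD SVM.** A linear SVM with mean hinge loss and penalty
$\sum_j \mathrm{SCAD}_{\lambda_1}(w_j) + \lambda_2 \lVert w\rVert^2$
(SCAD shape a = 3.7). The ridge term keeps groups of correlated features
together (the "elastic" grouping effect); SCAD prunes with little bias on
large weights. Fitting uses successive local quadratic (LQA) surrogates of
the SCAD term: each surrogate is a weighted-ridge hinge SVM solved exactly
by dual coordinate descent after per-feature rescaling, iterated until the
weight change falls below 1e-4 (at most 200 surrogates; non-convergence is
flagged in the tuning record, returning the best iterate). Because LQA
cannot produce exact zeros, weights below 1e-3 of the largest are snapped
to zero after convergence; the selection threshold |w| > 1e-8 then acts on
genuinely zeroed coefficients. $(\lambda_1, \lambda_2)$ come from a
stratified-CV grid (5 x 6 log-spaced points spanning $2^{-8}..2^0$ and
$2^{-8}..2^2$ stand-alone) — a deliberate simplification of the original
interval-search tuner; the bootstrap wrapper is the robustness mechanism.
CV ties resolve toward the sparser penalty (larger $\lambda_1$, then
larger $\lambda_2$). The mean (1/n) loss scaling keeps the grids on a
sample-size-free scale.

Inside the bootstrap driver the selectors run with a reduced profile
(`bootstrap_control()`: Boruta 100 trees / 25 iterations, SCAD 3 x 3 grid
with 3-fold CV and 30 surrogates, NSC 15 grid points / 3-fold CV) so that
the reference workload — B = 200 replicates across 20 repeated cohorts — is
feasible on a single CPU within a test run. The reduction costs per-replicate
selection power, which the B-fold replication is designed to absorb; the
stand-alone defaults remain the richer ones.

# The linear SVM and its conventions

The classifier stage uses an L1-loss (hinge) linear SVM solved by dual
coordinate descent with a tight tolerance, so refits are deterministic and
independent of sample ordering up to that tolerance. The bias is carried by
an augmented constant feature (so it is mildly regularized; at these sample
sizes the effect is negligible, and the package's hand-enumerable LOOCV
test pins the resulting geometry exactly). Class weights
$(w_{case}, w_{control})$ summing to 1 scale the per-class costs as
$2 \cdot \mathrm{cost} \cdot w$: equal weights reduce exactly to the plain
SVM cost. The positive class is the case (hemolyzed) class throughout, so
sensitivity is the case-detection rate. Default grids mirror the values
the workflow explores: cost in {0.01, 0.1, 1, 10, 100},
weights in {(0.5,0.5), (0.4,0.6), (0.3,0.7), (0.2,0.8)}, k = 1..min(50,
available). ROC-space grouping uses exact (FPR, TPR) equality, well defined
because both are rationals with denominator n.

# The synthetic cohort generator

`sim_spec()` / `generate_cohort()` emulate the data structure the strategy
assumes, with defaults mirroring a typical hemolysis case-control design: 13 cases
vs 26 controls (the training-set sizes), 50 features (the 88-retained-miRNA
scale, capped for test speed), five case-up-regulated features of which
four share a correlated block (the erythrocyte-miRNA cluster) and one is
weaker (log2 shifts 1.5, 1.5, 1.5, 1.5, 0.75 at unit feature SD), plus two
equal-mean features with case-only variance inflation (ratio 9) that only
the omnibus test can flag — modeling signals confined to patient subsets
away from the distribution center. A two-component mixture shape
(mean-centered, weight 0.4, gap 2) is available as an alternative shape
alternative. The correlated block uses a **unit-variance factor model**
(pairwise correlation r = 0.6, latent factor explaining a fraction r of the
variance), so that planted log2 shifts stay in feature-SD units. Detection
flags follow a logistic intensity model (midpoint 4, slope 1.5 on the log2
scale), emulating low-intensity dropout; hemolysis scores are
class-conditional normals (means 0.25 / 0.03, SD 0.04, clipped at 0), so a
small fraction of generated cases can fall into the excluded HS band — as
in real data. `generate_matching_pool()` plants class-covariate
associations (default: +1 log-odds disease, +5 years age, +1.5 years
drawing year) so that matching has imbalance to repair.

What the generator does **not** emulate: probe-level Agilent signals,
spike-in chemistry, batch effects, heavy-tailed baseline noise, or
inter-feature correlation outside the single block. A green recovery test
therefore establishes that the pipeline ranks planted mean-shift signals
above exchangeable Gaussian noise at these sample sizes — not that it
would do so under every real-data pathology.

# Numerical and procedural choices

* **Detection-filter reference set**: the Methods wording says "all
  samples" but the Results describe filtering on the training set; the
  package takes the reference set as an argument (`reference_ids`),
  defaulting to all samples in the object passed, and the workflow passes
  the training samples — the leak-free reading.
* **Ratio orientation**: numerator precedes denominator in input feature
  order; flipping the input order negates every ratio (tested property).
  Ratios are built only among retained features.
* **Matching order and replacement**: greedy matching processes cases in
  descending logit-PS distance from the mean (ties by id) and never reuses
  a control; both choices are fixed so that results are reproducible. A case with fewer than two in-caliper controls is reported
  unmatched, consuming none.
* **Truncated percentages**: the reporting layer truncates percentages to
  one decimal rather than rounding (4/88 -> 4.5 %, 224/3828 -> 5.8 %),
  the truncating convention common in clinical reports.
* **Pooled t by default**: the classical pooled-variance two-sample t is
  the default (the fold-change framing's classical companion); Welch is a
  flag.
* **Bootstrap bookkeeping**: replicate b is a pure function of
  (master seed, b), so runs are deterministic, order-independent and
  parallelizable in principle; a replicate on which any selector errors is
  redrawn with a fresh sub-seed (counted), and more than 10 % failures
  abort. Co-occurrence counts joint membership of both features in the
  same replicate's three-way intersection.
* **Ranking ties**: occurrence desc, then total co-occurrence desc, then
  id; never-selected features are dropped from the ranking.
* **Parsimony with ratio features**: the feature count of a ratio model is
  the ratio count; the distinct constituent miRNAs are reported alongside
  (`ratio_constituents()`) but do not drive the choice.

# Known limitations

* The AD p-value is asymptotic; at very small samples (n < 8 per group) the
  permutation check's 0.02 agreement is not guaranteed.
* LQA-based SCAD fitting can freeze a coefficient at zero once it crosses
  the snap threshold within an iteration path; the CV wrapper and the
  bootstrap replication mask, but do not eliminate, this path dependence.
* Boruta's binomial decisions at a Bonferroni-corrected level are
  conservative by construction; with the reduced in-bootstrap iteration
  budget, moderately informative features are often Tentative in a given
  replicate. The ranking depends only on *relative* joint-selection
  frequency, which is why this is acceptable there.
* Exact (FPR, TPR) grouping presumes all models are scored on the same
  sample set; do not mix LOOCV performances computed on different subsets.
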