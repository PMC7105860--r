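---
title: "Predictive-oriented construction of binary psychometric scales"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive-oriented construction of binary psychometric scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaleforge)
```

## The problem

Classical psychometric scale development is explanatory: items are written
from theory, factor-analysed, and retained when they load cleanly on the
intended construct. That workflow says little about how well the resulting
scale *predicts* a clinical outcome for a new patient. scaleforge implements
the complementary, predictive-oriented workflow for dichotomous (yes/no)
questionnaires with a binary diagnostic label: a neural classifier is built
over all candidate items, its out-of-sample predictive power becomes the
selection criterion for items, and the classical explanatory toolkit
(principal components, Varimax rotation, Cronbach's α, KMO) is then used to
check that the predictively selected pool still has an interpretable factor
structure.

The intended data shape is a cohort of a few hundred subjects answering a
few hundred binary items organised in three theory-defined *areas*
(emotional characteristics, dissociative phenomena, psychopathological
traits), with a known binary diagnosis (1 = unhealthy, the positive class)
and a small set of theory-anchored items that must never be dropped.

## The classifier and its trainer

The predictive model is a fully connected feed-forward network with one
logistic output node and a single hidden layer of logistic units
(`n_hidden = 0` means direct input-to-output connections, i.e. logistic
regression-like). Every neuron computes

$$o_j = \frac{1}{1 + e^{-x_j}}, \qquad x_j = \sum_i i_i w_{ij} - b_j,$$

so scores are strictly in (0, 1). Training minimises the sum of squared
errors over the full batch with **resilient backpropagation** (RPROP). RPROP
keeps a per-connection step size $\Delta_{ij}$ and uses only the *sign* of
the partial derivative:

* consecutive gradients with the same sign grow the step,
  $\Delta \leftarrow \min(\eta^+ \Delta, \Delta_{max})$;
* a sign flip shrinks it, $\Delta \leftarrow \max(\eta^- \Delta,
  \Delta_{min})$, zeroes the gradient memory, and (in the default RPROP+
  variant) undoes the previous step for that connection;
* otherwise the step is unchanged;

and weights move by $\Delta w_{ij} = -\mathrm{sign}(\partial E / \partial
w_{ij})\,\Delta_{ij}$.

Defaults follow the study settings: $\eta^- = 0.5$, $\eta^+ = 1.2$, at most
5000 epochs, weights initialised as standard-normal draws clipped to
$[-4, 4]$, and stopping when every component of the error gradient is below
$5\times10^{-4}$ in absolute value. Three points deserve comment because the
source description is ambiguous and we had to fix a convention:

* *"normal distribution in the range [−4, 4]"* is contradictory as stated;
  we resolve it as standard-normal draws clipped to that interval.
* The *stopping criterion 0.0005* is read as a threshold on the largest
  absolute partial derivative of the error — the convention of the R
  ecosystem's standard RPROP trainer, which is what that parameter controls
  there.
* Whether weight backtracking (RPROP+) was used is unstated; both variants
  are implemented (`train_config(backtrack =)`), RPROP+ being the default
  as in the reference trainer.

Step-size bounds $\Delta_0 = 0.1$, $\Delta_{min} = 10^{-6}$,
$\Delta_{max} = 50$ are the canonical RPROP values; they are not stated in
the source and rarely need changing.

A practical caution verified by our test suite: on tiny discrete problems
(the XOR benchmark) a 2-hidden-unit logistic network trained this way lands
in a well-known local minimum for roughly half to two-thirds of random
initialisations, with the squared error plateauing near the
one-misclassified-pattern level. This is a property of the XOR error
landscape, not of the trainer: an independent re-implementation reproduces
the same success rate under every variant of the error function,
initialisation scale and step-size schedule we probed. On the
high-dimensional questionnaire problems the package targets, restarts
across Monte-Carlo iterations make this a non-issue, but single small runs
should not be expected to succeed deterministically.

## Evaluation design

Because the cohort is imbalanced (about one third unhealthy), the held-out
**test set is class-balanced**: 20% of the unhealthy subjects (rounded) plus
an equal number of healthy ones, which for a 604/196 cohort gives 39 + 39 =
78 subjects, about 13% of the cohort. The remaining subjects are repeatedly
split 80/20 into training and validation sets (**Monte-Carlo
cross-validation**, independent random partitions rather than k-fold). The
validation set exists for runtime monitoring; model selection uses the test
set, mirroring the original design. The number of Monte-Carlo iterations is
unstated in the source; the package default is 10, and the desk-scale runs
in this package's tests and acceptance script use 2, which we found
sufficient to rank architectures at these problem sizes.

The **architecture search** trains one network per (hidden-unit count, CV
iteration) pair, scores the test set, picks the cutoff by ROC, and retains
the architecture with the highest mean test accuracy, breaking ties toward
fewer hidden units. The full per-fit record is kept (`tidy()` on the search
object) so the accuracy/AUC profile over architectures can be inspected.

ROC analysis uses the convention *score ≥ threshold ⟹ predicted unhealthy*
— worth stating explicitly because optimal cutoffs for imbalanced training
targets are routinely far below 0.5. The cutoff is chosen by the **(0,1)
criterion**: the candidate threshold whose (FPR, TPR) point minimises the
Euclidean distance to the perfect-classifier corner (0, 1), with ties
broken toward higher sensitivity and then toward the lower threshold. AUC
is computed by trapezoidal integration, which the test suite verifies to be
identical to Mann–Whitney pair counting (ties counted ½).

## Randomized knowledge-based item selection

Item selection is a wrapper search that reuses the trained network without
retraining. A candidate item subset is evaluated by **masking**: columns
outside the subset are set to 0 (the "no" answer), so the input layout is
unchanged. The source does not state how excluded items are encoded; zero
is the natural choice under yes/no coding and is our documented assumption
(`mask_to_subset()`), with retraining available for comparison via the
package API.

Each step samples `n_samples_per_step` random subsets — every candidate item
included independently with probability 0.5 (the sampling law is unstated
in the source; independent inclusion is uniform over subsets and adds no
size bias) — always containing the current fixed set. The subsets attaining
the step's minimum test error are the "best solutions"; the items common to
all of them become fixed for the next step, so the fixed set grows
monotonically from the theory-anchored items. The loop stops at the first
step whose best error fails to *strictly* improve (ties stop too), and the
reported answer is the *best-parsimonious* solution: the smallest item set
among all step-best solutions attaining the overall minimum error, with a
lexicographic tie-break for exact reproducibility.

The original procedure sampled 5,000,000 subsets per step (about ten
hours); the package default is 2,000, which keeps a full desk run under ten
seconds while leaving the full-scale setting one configuration value away.
Because the selection criterion is the test error itself, the selected-set
error is optimistically biased — the procedure trades a clean error
estimate for a concrete item pool, exactly as in the original design; an
untouched confirmation sample would be needed for an unbiased estimate of
the final scale's accuracy.

## Explanatory layer

Per area, the package computes Pearson correlations (phi coefficients for
binary items — tetrachorics are deliberately *not* the default, matching
the source's analysis of binary variables and its caveat that explained
variance on binary data is pessimistically low), eigendecomposes the
correlation matrix, retains a theory-fixed number of components (7/3/7 by
default for the emotional/dissociative/psychopathological areas; the
dissociative count is a per-run choice since both 2 and 3 appear in
published analyses), applies Varimax rotation with Kaiser normalization,
and reports:

* eigenvalues, percent and cumulative percent explained variance;
* each item's dominant component and signed loading, graded `negative`
  (< 0), `very_low` (|loading| < 0.4), `low` (< 0.5) or `adequate`;
* a cross-loading flag when a secondary loading reaches 75% of the primary
  (the source flags such items without stating a cutoff; 0.75 is our
  configurable default);
* Cronbach's α and the KMO sampling-adequacy index.

Component signs are normalised (dominant item positive) and components
re-ordered by rotated variance, so reports are deterministic. One
mathematical note: for vanishing correlations KMO tends to ½, not 0 —
partials equal marginals in that limit — so "low adequacy" readings sit
between ~0.5 and 0, not near 0 for merely uncorrelated items.

## The synthetic-data generator

Real cohorts of this kind are not publicly depositable, so the generator is
a first-class module and defines the package's study conditions: 604
subjects; 157/24/79 items across the three areas; orthogonal latent factors
(7/3/7 per area) with every item loading 0.6 on exactly one factor
(thresholded-Gaussian responses, ~50% endorsement); a diagnosis whose
log-odds are β = 2 per endorsed informative item over 15 informative items
drawn from the first ("pathology") factor of each area, with the intercept
bisected so the expected prevalence is 0.325; 21 theory-anchored items of
which 5 overlap the informative set (so theory is partially right and the
search has signal left to discover); and 0.1% MCAR missingness. The
loading, informative-effect and fixed-overlap values are the generator's
own calibration choices — the source states the structural counts and
prevalence but not these — fixed once at values a psychometrician would
call realistic for a clinical instrument.

What the generator does *not* emulate: item-wording effects, correlated
factors (available via `factor_cor` for robustness checks but off by
default), item-difficulty spread beyond the common endorsement threshold,
informative items spread across several factors, and any non-MCAR
missingness. Tests passing on this generator therefore certify the
*algorithms* — balanced splitting, training, thresholding, selection,
recovery of planted structure — not clinical performance on real cohorts.

Missing answers are imputed by **predictive mean matching**: one OLS model
per incomplete item on all complete items, each missing cell filled by the
observed value of one of the `k_donors = 5` nearest-prediction donors.
A single completed dataset is produced — the original analysis pipes one
completed matrix into PCA and the classifier and never pools estimates, so
multiple-imputation pooling would add machinery without a consumer. At 0.1%
missingness the choice of imputation model is immaterial; PMM's donor
property (binary in, binary out) is what matters.

## Seeds, determinism and numerical choices

Every stochastic stage takes a seed; `run_pipeline()` derives per-stage
seeds from one global seed via a 32-bit string hash, so stages are
reproducible independently and jointly. Ties are broken deterministically
everywhere (donor pools by row index, thresholds toward higher sensitivity
then lower value, architectures toward fewer hidden units, item sets
lexicographically). Degenerate inputs fail loudly: constant items in
correlation matrices, single-class labels, fully missing columns,
non-invertible correlation matrices for KMO.

Desk problem sizes used by the test suite and acceptance script, chosen as
the package's own scaled-down study conditions: the full 604 × 260 default
simulation for the acceptance run (thinned hidden-unit grid over 0–50, 2 CV
iterations, 2,000 subsets per selection step); 604 × 100 with 15 informative
items for the ten-seed selection experiment; n = 2000 with loading 0.8 for
the seven-factor recovery check.

## Limitations

* The selected-set accuracy is test-set-optimistic by construction (see
  above); treat it as a search criterion, not an unbiased estimate.
* Phi-based PCA on binary items underestimates explained variance; the
  reports are for structure inspection, not variance bookkeeping.
* The trainer is full-batch and single-hidden-layer by design; it is not a
  general-purpose deep-learning tool.
* With hundreds of items and two-digit test sets, many subsets tie at the
  minimum test error; the common-items rule and parsimony tie-break resolve
  this deterministically, but the specific selected set can be
  seed-sensitive even when its error is stable.
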