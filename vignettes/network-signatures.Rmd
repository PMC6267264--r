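---
title: "Deriving brain networks from task-independent connectivity and establishing their cognitive signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving brain networks from task-independent connectivity and establishing their cognitive signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connsig)
```

## The problem

Resting-state fMRI and diffusion tractography both yield "task-independent"
descriptions of how cortical regions are wired together, and graph-theory
community detection turns either into a set of candidate brain networks.
What such analyses rarely do is test, formally, what those networks are
*for*. `connsig` implements a complete pipeline that (1) derives networks
from structural and functional connectivity over a fixed set of regions of
interest (ROIs), (2) verifies that the derived networks have non-random
(small-world) topology, (3) profiles each network's activity across task
contrasts (its *cognitive signature*), and (4) quantifies the match between
connectivity-derived networks and task-evoked activity patterns with
network-level representational similarity analysis (RSA).

Because subject-level imaging data cannot ship with a package, `connsig`
includes a planted-partition synthetic-data generator that emulates the
statistical structure every stage assumes. All claims the test suite makes
are claims about recovery of known ground truth under that generator.

## Connectome construction

**Structural branch.** Probabilistic tractography between ROI pairs is
summarized as an integer count in `[0, 20000]` per ordered pair (20,000
Monte Carlo streamlines per seed). Two estimates exist per pair (tracking
runs in both directions); `combine_directional()` averages them (the
arithmetic mean is the symmetric, unbiased choice; `max` is available
because the combination rule is a genuine methodological fork). The
combined matrix then passes a *double threshold*:

1. *Individual threshold.* A Poisson rate $\lambda$ is fitted to the
   subject's off-diagonal connection values and an entry survives iff its
   count $v$ satisfies $P(X \ge v \mid \mathrm{Pois}(\lambda)) < 0.05$.
   We estimate $\lambda$ as the mean of the *nonzero* entries by default:
   thresholded streamline matrices are sparse, and including the zeros
   would collapse the rate toward 0 and keep every spurious streamline.
   The all-entries mean is available (`lambda_estimator = "all_mean"`).
   `poisson_threshold_value()` is exact (no normal approximation is
   needed; R's `ppois` is numerically stable at the rates that occur) and
   is tested against a brute-force tail scan over a grid of rates, e.g.
   $\lambda = 3 \to v^* = 7$ and $\lambda = 10 \to v^* = 16$.
2. *Group threshold.* An edge enters the group binary connectome iff
   present in at least `ceiling(0.5 * n)` subjects — the inclusive
   convention, so 12 of 24 subjects suffice.

**Functional branch.** Subjects whose head-motion summaries exceed 3 mm
translation or 1 degree rotation (strict inequalities) are censored before
any matrix is computed. Each remaining subject contributes a full
ROI-to-ROI Pearson correlation matrix of BOLD time series; group averaging
happens in Fisher-z space (`atanh`, mean across subjects, `tanh` back),
with r clipped at $\pm(1 - 10^{-6})$ so perfectly correlated synthetic
series stay finite. Negative group correlations are set to 0 (not removed
as nodes): their physiological meaning is contested and the downstream
weighted analysis assumes nonnegative weights. For a single-subject group
the function returns the input with negatives zeroed directly rather than
round-tripping through `atanh`/`tanh`; this makes the identity exact at
the bit level instead of exact up to 1 ulp.

## Graph analysis

Module detection maximizes Newman–Girvan modularity
$$Q = \sum_c \left[\frac{W_c}{v} - \left(\frac{k_c}{v}\right)^2\right]$$
over partitions, where $W_c$ is the weight inside module $c$, $k_c$ its
total degree and $v$ the total weight. The optimizer is restarted Louvain:
each restart permutes the node order (the heuristic's only source of
variation), and the best-Q partition over `n_iter` restarts wins, ties
going to the first encountered — so results are a deterministic function
of the seed. The default of 1000 restarts matches standard practice for
this heuristic; the demo pipeline uses 100, which is far past convergence
for 43-node planted graphs (the test suite checks the optimizer against
exhaustive enumeration of all partitions on graphs of up to 8 nodes).
"Iterations" for this family of optimizers can also be read as consensus
clustering across runs; we implement restarts-with-max-Q and note the
alternative. The returned Q is always recomputed independently from the
assignment and the matrix, never taken from the optimizer.

Small-world verification compares mean clustering coefficient $C$ and
characteristic path length $L$ against 20 degree-preserving rewired null
graphs (double edge swaps, $10\times|E|$ swaps per null):
$\gamma = C/C_{rand}$, $\lambda = L/L_{rand}$,
$\sigma = \gamma/\lambda$. Disconnected node pairs are excluded from $L$
with a warning and a reported count (global efficiency is provided as the
robust alternative that keeps disconnected pairs at contribution 0). The
weighted clustering coefficient uses the Onnela geometric-mean form,
normalized by the maximum weight; the weighted variant was an open choice
and is configurable in spirit — the binary form is what the verification
stage uses after density thresholding.

Density thresholding keeps the top $\lfloor d \cdot n(n-1)/2 \rfloor$
positive weights; ties at the cut break by lexicographic ROI-pair order so
repeated runs are identical.

Between-cohort differences in any metric are tested by permutation:
subjects are pooled, labels reassigned preserving cohort sizes, and the
group network rebuilt from scratch for each of the (default 1000)
permutations at each density; the two-sided p is
$(1 + \#\{|d_{perm}| \ge |d_{obs}|\})/(n_{perm}+1)$ and the confidence
band is the 2.5/97.5 percentile range of the permutation distribution
(the original toolbox's exact band construction is not restated anywhere
we could verify, so the permutation percentiles are used). Cohorts of
unequal size are handled by permuting the pooled list while preserving
the original sizes.

## Cognitive signatures

For each task study, ROI activity is extracted under three contrasts
(semantic > control, rest > semantic, control > rest), averaged within
each network module per subject, and tested against zero with two-tailed
one-sample t-tests on the subject-level module means (the random-effects
reading; the unit of analysis was not pinned down by convention, and
subject-level means are the standard choice). The displayed pattern is
z-scored. The z-scoring scope is genuinely ambiguous in this kind of
figure; the default standardizes across all module-by-contrast cells
within a study, and a per-contrast scope is available
(`zscore_scope = "contrast"`). Zero-variance cells yield `t = ±Inf` with
`p = NA` and a degeneracy flag — never a fabricated p-value.

## Representational similarity analysis

Each subject's activation RDM is the ROI-by-ROI matrix of
$1 - r_{\mathrm{Pearson}}$ across the three contrast values (entries in
$[0,2]$, zero diagonal). A partition induces a binary model RDM: 0 for
same-module pairs, 1 otherwise. The second-order statistic is Spearman's
correlation over the strict upper triangle (903 pairs at 43 ROIs) with
average-rank tie handling — consequential here because model RDMs are
binary and massively tied; the diagonal is excluded because it is
structurally zero and would inflate the correlation.

Group inference correlates each subject's RDM with the model, then runs a
two-tailed one-sample t-test on the Fisher-z transformed rhos; the
reported `mean_rho` is the mean of raw rhos, the comparable summary when a
single correlation per study is quoted. Bonferroni correction defaults to
a family of 6 (two model RDMs by three studies). Model-to-model
comparisons report both a parametric p (t approximation on the 903 pairs)
and a Mantel-style permutation p (ROI labels of one RDM permuted jointly
over rows and columns, default $10^5$ permutations); the two can disagree
because RDM entries are not independent, which is why both are reported
and neither is silently preferred.

**The no-correspondence control.** The pipeline contrasts the true-model
RSA with a label-shuffled control. A *single* shuffled partition is a poor
control: it retains a small but systematic chance overlap with the truth
(expected rho of order ±0.02 at 43 ROIs), and a well-powered subject-level
t-test will correctly flag that overlap as non-zero. The control therefore
shuffles the model's ROI labels independently per subject
(`group_rsa(..., shuffle_labels = TRUE)`), which destroys the
model-to-data correspondence while preserving module sizes and makes the
control rhos exactly mean-zero by symmetry — the standard exchangeability
argument behind Mantel-type nulls.

## The synthetic-data generator

The generator is the package's ground-truth instrument; its defaults are
fixed once and define the conditions under which every recovery claim is
made:

* **Planted partition**: 43 ROIs in 5 modules (sizes 9, 9, 9, 8, 8), the
  scale of an associative-cortex parcellation and its typical module
  count.
* **Structural cohort** (24 subjects): for each unordered ROI pair an
  edge is present with probability 0.9 within modules and 0.05 between;
  present edges produce counts near the 20,000-streamline ceiling
  (binomial with per-streamline loss rate `lambda_noise / 20000`), absent
  edges a Poisson noise floor with rate `lambda_noise = 2` — far below any
  plausible individual threshold, mimicking the bimodal
  "high-probability vs noise floor" structure the double threshold
  assumes. Setting `lambda_noise = 0` makes counts exactly 0 or 20,000,
  which the exactness tests exploit.
* **Functional cohort** (78 subjects, 128 volumes): the shared-latent-
  signal model
  $x_i(t) = \sqrt{\rho}\, s_{m(i)}(t) + \sqrt{1-\rho}\,\varepsilon_i(t)$
  with $\rho = 0.8$, the standard generative model for block-structured
  correlation matrices: expected correlation $\rho$ within modules, 0
  between. Motion summaries are half-normal (sd 1.5 mm translation,
  0.45 degrees rotation), calibrated so roughly 8% of subjects exceed the
  3 mm / 1 degree censoring rule — matching the exclusion rate such rules
  produce in practice (6 of 78 in the motivating cohort).
* **Task betas** (3 studies, 20 subjects each): ROI activity is the
  module's 3-contrast profile plus N(0, 0.5) noise. Default profiles
  place the modules at equally spaced angles in the 2-dimensional plane
  of centered 3-vectors, so every pair of module profiles is distinct
  (pairwise correlations $\cos(2\pi k/5)$) without privileging any
  module.

One master seed drives everything; per-subject sub-seeds are drawn from
named streams so that, for example, adding task studies never perturbs the
structural cohort. Identical designs and seeds give bit-identical output.

What the generator does *not* emulate: spatial structure and voxel-level
noise, hemodynamic autocorrelation, distance-dependent connectivity,
scanner drift, or heavy-tailed motion. Passing recovery tests therefore
demonstrates that the pipeline's logic is correct and well-calibrated on
data with the assumed block structure — not that real acquisitions of any
particular cohort would yield the same networks.

## Numerical choices and degenerate inputs

* All group matrices are asserted symmetric with zero diagonal on every
  call; negative weights are rejected by the graph layer.
* `atanh` clipping at $1 - 10^{-6}$ (connectomes) and $1 - 10^{-12}$
  (subject rhos) keeps transforms finite without visibly moving any
  realistic value.
* All-zero matrices: Poisson thresholding warns and returns all-zero;
  module detection warns and returns a single module with Q = 0; path
  length on an edgeless graph is an error.
* Zero-variance inputs produce named errors (constant time series,
  constant activity profiles, single-module model RDMs) or flagged
  `t = ±Inf` with `p = NA` — never silent NaNs or invented p-values.
* Ties: density thresholding breaks ties lexicographically; Spearman uses
  average ranks; the modularity optimizer keeps the first-encountered
  best partition in seed order.

## Problem sizes in the shipped checks

The test suite and acceptance script run the full 43-ROI pipeline (24/78/
3x20 subjects) end to end 100 times for the recovery rate, calibrate the
permutation test with 200 replicates of 200 permutations at one density,
and check the modularity optimizer against exhaustive enumeration up to
8 nodes (4140 partitions). These sizes were chosen to give stable Monte
Carlo estimates while keeping a complete run of everything within a few
minutes on one core.

## Known limitations

* The exact Poisson-fit procedure used historically for the individual
  threshold is delegated to earlier work and not restated; the
  nonzero-mean MLE here is a documented assumption, with the all-entries
  mean one flag away.
* Whether group functional averaging should exclude censored subjects
  before or after matrix computation is not fixed by convention; we
  exclude before.
* Module detection on weighted graphs uses the same modularity objective
  with weights; resolution-limit issues of modularity (small modules in
  large graphs) are inherited from the method itself.
* The package deliberately stops at the ROI level: no tractography, image
  registration, nuisance regression, filtering, or voxelwise GLMs — those
  belong to acquisition-specific preprocessing, and their outputs are this
  package's inputs.

## A worked run

```{r, eval = FALSE}
library(connsig)
bundle <- run_pipeline(run_config(seed = 1))
bundle$structural$ari        # 1: planted modules recovered from streamlines
bundle$functional$ari        # 1: and from BOLD correlations
bundle$verification$functional$sigma  # > 1: small-world vs rewired nulls
bundle$rsa$study1$true_model          # significant cognitive signature
bundle$model_comparison$rho           # agreement of the two derived models
```
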