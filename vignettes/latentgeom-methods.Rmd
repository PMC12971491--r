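---
title: "Methods: population geometry and multitask readout error"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population geometry and multitask readout error}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latentgeom)
```

## The model

We study an agent that learns many binary classification tasks from a
shared neural representation. Each stimulus has latent coordinates
$z \in \mathbb{R}^d$ and evokes a population response $x \in \mathbb{R}^n$.
A task is a random hyperplane through latent space: teacher vector
$T \sim \mathcal{N}(0, I_d)$, labels $y = \mathrm{sign}(T \cdot z)$.
Learning uses the supervised Hebbian rule
$w = \tfrac{1}{p}\sum_\mu y_\mu x_\mu$, prediction
$\hat y = \mathrm{sign}(w \cdot x)$. Ties ($w \cdot x = 0$) are mapped to
$+1$: the event has measure zero under continuous responses, and a
deterministic rule keeps every simulation bit-reproducible.

Under the Gaussian model — $(x, z)$ jointly zero-mean Gaussian with
$\Psi = E[xx^\top]$, $\Phi = E[xz^\top]$, $\Omega = E[zz^\top]$ — the
task-averaged generalization error has the closed form implemented in
`theoretical_error()`:
$$E_g = \frac{1}{\pi}\arctan\sqrt{\frac{\pi}{2p\,c^2\,\mathrm{PR}(\Psi)}
 + \frac{1}{f} + \frac{1}{s} - 1},$$
with the four statistics computed by `geometry_summary()`. The formula is
an asymptotic result (large $n$, $d$, $p$ of comparable size); the Gaussian
experiment below quantifies how well it holds at $n = 80$, $d = 40$,
$p \ge 20$. Because the tasks shatter the latent space isotropically,
higher-variance latent directions are on average more informative; users
who want all latents weighted equally should z-score them
(`zscore_columns()`) before analysis.

Key assumptions worth keeping in mind:

* Only second moments enter. Non-Gaussian codes are handled through
  Gaussian equivalence — estimate $(\Psi, \Phi, \Omega)$ from data with
  `estimate_covariances()` and apply the formula — which is an
  approximation we test empirically (the MLP experiment), not a theorem
  we rely on.
* The error is averaged over tasks. Single fixed-task errors are outside
  the package's scope.
* No class balancing is applied: the Hebbian rule is used verbatim
  whatever the label balance, which `empirical_task_error()` reports as a
  diagnostic.

## Numerical conventions in the geometry module

* **Trace convention.** In the factorization statistics the squared trace
  $[\mathrm{Tr}(\Phi\Phi^\top)]^2$ is used (not the trace of the square).
  Only this reading yields $f \le 1$ with equality exactly for whitened
  signal ($\Phi^\top\Phi \propto \Omega$, the Cauchy–Schwarz equality
  case), which is what makes $f$ interpretable as a factorization index.
* **Degenerate latent covariance.** $\Omega^{-1}$ is a pseudo-inverse via
  eigendecomposition with a relative cutoff of $10^{-10}$ times the
  leading eigenvalue; centering or z-scoring pipelines can legitimately
  produce rank-deficient latents.
* **PSD tolerance.** Sample covariances are PSD only up to round-off;
  validation in `gaussian_code()` accepts eigenvalues down to
  $-10^{-8}\lambda_{\max}$ and treats them as zeros.
* **Noiseless codes.** When the noise trace
  $\mathrm{Tr}(\Phi^\top(\Psi - \Phi\Omega^{-1}\Phi^\top)\Phi)$ is at or
  below round-off, $s = \infty$ is returned explicitly and contributes
  exactly $1/s = 0$ to the error.
* **Radicand clamping.** Near-perfect codes can push the radicand a hair
  below zero in floating point; it is clamped at zero (error 0) with a
  warning. A substantially negative radicand signals an inconsistent
  summary and warns differently.
* **Chance codes.** $c = 0$ (i.e. $\Phi = 0$) short-circuits to error 0.5
  with a `chance` flag rather than dividing by zero.

## The optimal code

At fixed $\Omega$ and sample budget $p$, minimizing $E_g$ over realizable
codes gives cross-covariance singular vectors aligned with the
eigenvectors of $\Psi$ (left) and $\Omega$ (right) and neural eigenvalues
$$\psi_i = C\,\frac{\omega_i}{2p\,\omega_i + \pi\sum_k \omega_k}.$$
`build_optimal_code()` constructs this code explicitly: noiseless,
rank-$d$, with the canonical coordinate embedding for the neural
eigenbasis (any orthogonal rotation is equivalent; the deterministic
choice aids reproducibility). The closed form guarantees at least $d$
non-zero eigenvalues; whether spreading variance into the remaining
$n - d$ directions can ever help is not decidable from the main result,
so the constructed code is exactly rank $d$ (extra units carry zero
variance) — a choice, flagged here, not a theorem.

`numerical_optimal_code()` validates the closed form by direct
minimization. The joint covariance is parameterized through its block
factor $L = [[\Omega^{1/2}, 0], [X_1, X_2]]$, so $LL^\top$ is PSD for
*any* unconstrained $(X_1, X_2)$ and $\Phi = X_1\Omega^{1/2}$,
$\Psi = X_1X_1^\top + X_2X_2^\top$ (the noise covariance is then exactly
$X_2X_2^\top$). Numerical choices:

* The objective is the radicand argument $w$ rather than $E_g$ itself —
  $E_g$ is monotone in $w$, and $w$ has better-conditioned gradients near
  the optimum.
* Analytic gradients (verified against finite differences in the test
  suite) with L-BFGS-B, 5 random restarts against permutation saddles,
  convergence tolerance `factr = 1e4` (objective changes of order
  $10^{-12}$).
* The objective is scale-invariant (the gauge freedom in $C$); the
  returned code is normalized to $\mathrm{Tr}(\Psi) = 1$ after the fact.
  Non-convergence of every restart is flagged in the diagnostics and
  warned about, never silent.

## Synthetic ensembles

The generators' defaults are the package's study conditions:

* **Gaussian grid.** Latent eigenvalues $\omega_i = 5 i^{-\alpha}$ for
  $\alpha \in \{0, 0.5, 1\}$, $d = 40$ latents, $n = 80$ units; codes are
  random linear ($x = Az$, $A$ i.i.d. standard Gaussian) or whitening
  ($x = \Omega^{-1/2}z$); 300 tasks, 1000 test points, 30 repeats per
  cell, $p \in \{20, 50, 100, 300\}$. Within each grid cell the mixing
  matrix is drawn once and the Monte-Carlo average runs over fresh tasks,
  training and test sets, so the simulation estimates the error of *that*
  code, the quantity the closed form predicts. The test-set size is not
  pinned down by the protocol; 1000 is the package default.
* **Hidden-manifold MLP.** Latents with spectrum $k^{-0.2}$ feed a random
  expanding perceptron (widths doubling per layer, weights
  $\mathcal{N}(0, 1/\text{fan-in})$, zero biases — the scale is a
  standard choice, and the latent covariance is left diagonal by
  default); its outputs and the labels of random shattering tasks train a
  three-hidden-layer linear–batchnorm–ReLU network with one linear
  readout per task from the shared penultimate layer, by minibatch Adam
  (rate $10^{-3}$, batch 128) on the task-averaged logistic loss for one
  epoch. No deep-learning framework is required: forward, batchnorm
  backward and Adam are implemented directly in matrix code, which keeps
  the dependency footprint at base R and makes every step seedable.
  Batch-normalization statistics are frozen (running averages) at
  evaluation time so representations are deterministic functions of the
  input. The default profile is desk-scale — $d = 20$, $2\times10^4$
  samples, 100 training tasks — with evaluation on $10^3$ fresh latents
  and 300 fresh tasks at $p = 300$ (train/test split 300/700), averaged
  over 5 splits; the full-scale profile ($d = 40$, $5\times10^5$, 500
  tasks) is available by config override.
* **Tuned Poisson population.** A smooth reflected random walk in a
  square arena (position + velocity latents), per-unit log-linear tuning
  from Gaussian place-field bumps plus a linear velocity preference, and
  Poisson counts at 0.5 s bins. It is a synthetic stand-in for a
  navigational recording session, built so that the ground-truth
  conditional-mean rates — and hence the true signal-subspace dimension —
  are known exactly.

What these generators deliberately do *not* emulate: spike-sorting
artifacts, non-stationarity across a session, behavioral sampling biases,
or image-computable stimuli. Passing tests therefore certify the
estimators and the theory under the stated generative conditions, not
performance on any particular real recording.

## Covariance estimation and preprocessing

`estimate_covariances()` centers both matrices and uses the unbiased
$1/(p-1)$ normalization (the choice is not dictated by the theory; at the
sample sizes used the difference is negligible, and unbiasedness is the
conventional default). `random_projection()` provides the
Gaussian-projection device used to compare representations of different
widths; `zscore_columns(sd_floor = )` implements standardization with a
small additive floor so that near-silent units are not massively
overweighted.

## The signal-subspace module

The task-relevant dimension of a population is the participation ratio of
the covariance of conditional-mean rates $v(z) = E[x \mid z]$, with $v$
z-scored per unit and the expectation over $z$ taken under the empirical
latent distribution (a grid-evaluation alternative exists but is off by
default — the empirical distribution is what the estimator is defined
on). $v$ is estimated per unit by ℓ2-regularized Poisson regression with
exponential link on Gaussian basis features: 2-D isotropic bumps tiling
position bins occupied for more than 20 time bins, 1-D bumps tiling each
velocity axis, duplicated per trajectory type when one is supplied. Basis
widths default to the bin size; a grid search is available but optional.

Model selection and the null rule:

* The regularization strength is chosen per unit by 10-fold
  cross-validated Poisson deviance over 10 log-spaced values spanning
  $10^{-4}$–$10^2$, using the one-standard-error rule (the strongest
  regularization within one SE of the minimum) — the canonical
  conservative choice.
* Fit quality is $D^2 = 1 - \mathrm{dev}(\text{model}) /
  \mathrm{dev}(\text{null})$, the fraction of Poisson deviance explained
  relative to a constant-rate null model, evaluated on held-out folds.
* A unit is replaced by the null model unless it beats the null clearly:
  cross-validated $D^2$ above a tie tolerance (`d2_tol`, default
  $10^{-3}$) *and* a deviance improvement exceeding one SE of the
  fold-wise improvements. The tolerance matters: selecting the best of
  several regularizers gives even untuned units a tiny positive bias
  (cross-validated $D^2$ of order $10^{-5}$), and without the tie rule
  such units occasionally leak through and dilute the dimension estimate
  with z-scored noise. Genuinely tuned units in the validation
  simulations sit at $D^2 \gtrsim 0.1$, orders of magnitude above the
  tolerance; setting `d2_tol = 0` restores the strict sign rule.
* Units whose optimizer fails are null-flagged with a warning, never a
  crash; null-flagged units have constant predicted rates and are
  excluded from the dimension (a constant column carries no signal).

## Problem sizes and validation

The package validates itself end to end at the following scales, chosen
as the smallest that make the comparisons statistically meaningful: the
full Gaussian grid (24 cells, 30 repeats each); optimal-code recovery at
$d = 5$, $n = 10$, $p \in \{5, 50, 500\}$; a $10^5$-sample generative
round trip of all metrics; the desk-scale MLP sweep; and signal-subspace
recovery at 30 units × 5000 bins with 20% pure-noise units. The
acceptance script (`scripts/acceptance.R`) re-runs all of these from a
single seed and reports the resulting gaps, alignments and recovery
errors as JSON.

## Known limitations

* The error formula is asymptotic; at very small $p$, $n$ or $d$ the
  Monte-Carlo error and the prediction can differ beyond the few-thousandths
  level seen at the default scales.
* Gaussian equivalence is an approximation: on strongly non-Gaussian
  codes the theory tracks but need not match the empirical error
  point-wise (the layer-sweep $R^2$ quantifies this).
* The GLM module assumes the latent trajectory explores the space well;
  occupancy gaps remove basis centers and can bias $v(z)$ where data are
  thin.
* `train_multitask_mlp()` supports the ReLU nonlinearity (the
  random-network path also offers tanh); convolutional or recurrent
  architectures are out of scope.
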