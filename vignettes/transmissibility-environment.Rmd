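---
title: "The transmissibility model with environment: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The transmissibility model with environment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transenv)
```

## The model

Quantitative genetics attributes the resemblance between relatives to DNA,
but epigenetic marks, microbiota and learned behaviour are also transmitted
vertically, and — unlike DNA — they respond to the environment an animal
experiences.  The transmissibility model replaces the additive genetic
value with a *global transmissible potential* $t_i$ that pools every
vertically transmitted source:

$$y_i = \mathbf{x}_i'\boldsymbol\beta + t_i + e_i, \qquad
t_i = \omega_s t_{s(i)} + \omega_d t_{d(i)} + \varepsilon_i,$$

where $\omega_s$ and $\omega_d$ are the sire and dam *path coefficients of
transmission* ($0 \le \omega_s, \omega_d$, $\omega_s + \omega_d \le 1$) and
$\varepsilon_i$ is the transmissibility sampling, the analogue of Mendelian
sampling.  Its relative variance $\delta_i$ depends only on which parents
are known: $1 - \omega_s^2 - \omega_d^2$ (both known), $1 - \omega_d^2$
(sire unknown), $1 - \omega_s^2$ (dam unknown), $1$ (neither).  Setting
$\omega_s = \omega_d = 0.5$ recovers the additive (numerator) relationship
matrix on a non-inbred pedigree.  Writing $\mathbf{t} \sim
N(0, \mathbf{M}\sigma_t^2)$, the inverse of the transmission relationship
matrix factorizes as $\mathbf{M}^{-1} = \mathbf{L}'\mathbf{D}^{-1}\mathbf{L}$,
with $\mathbf{L}$ unit lower triangular carrying $-\omega_s$ and
$-\omega_d$ at the parent positions — the transmissibility analogue of the
Henderson rules, and the reason everything here scales to large pedigrees.

The extension implemented by this package lets the shared environment
enter the transmissible potential itself.  The sampling is decomposed as
$\varepsilon_{ik} = \xi_i + \theta_k$, where $\theta_k$ is a random effect
of environment $k$ with variance $\sigma_\theta^2 = r\,\sigma_t^2$.  Two
animals sharing an environment then have
$\mathrm{cov}(\varepsilon_{ik}, \varepsilon_{i'k}) = r\,\sigma_t^2$, so
$\mathbf{D}$ becomes block diagonal ($\mathbf{D}_E$): within each shared
environment, $\delta_i$ on the diagonal and $r$ off it.  The parameter

$$r = \sigma_\theta^2 / \sigma_t^2, \qquad
\rho = \frac{r}{1 - \omega_d^2 - \omega_s^2} \le 1$$

is the proportion of transmissibility variance explained by the
environment; $\rho$ is the correlation between samplings of co-environed
known-parent animals, which bounds $r$ by $1 - \omega_d^2 - \omega_s^2$.
Because $\theta_k$ sits inside the transmission recursion, its effect is
inherited and diluted by $\omega_s + \omega_d$ per generation — this is
what distinguishes a *transmitted* environmental effect from an ordinary
fixed effect on the phenotype, and what the boundary likelihood-ratio test
below detects.

Each compound-symmetry block $(\delta - r)I_m + rJ_m$ has the closed-form
inverse $\frac{1}{\delta - r}\bigl[I_m - \frac{r}{\delta + (m-1)r}
J_m\bigr]$, positive definite iff $\delta - r > 0$ and
$\delta + (m-1)r > 0$.  This closed form requires a common $\delta$ within
the block, i.e. all members must share the same parental-knowledge status;
`build_DE()` treats a violation as a fatal error by default (the
restriction belongs to the block-inversion shortcut, not to the model) and
offers `heterogeneous = "dense"` to invert such blocks numerically
instead.  `build_ME_inverse()` assembles
$\mathbf{M}_E^{-1} = \mathbf{L}'\mathbf{D}_E^{-1}\mathbf{L}$ without ever
forming $\mathbf{M}_E$.

A bookkeeping point worth stating precisely: the decomposition conserves
each animal's *sampling* variance — $\mathrm{diag}(\mathbf{D}_E) =
\mathrm{diag}(\mathbf{D})$, since $\delta_i\sigma_t^2 = \sigma_{\xi i}^2 +
\sigma_\theta^2$ — but not necessarily $\mathrm{diag}(\mathbf{M}_E)$.
When two co-environed animals are mated, the covariance $r$ between their
samplings propagates through $\mathbf{L}^{-1}$ and raises their
descendants' total variance.  The mirrored design below does exactly that
in its exposed line, so the package tests assert diagonal conservation of
$\mathbf{D}_E$ always, and of $\mathbf{M}_E$ only on pedigrees without
co-environed matings.

## REML estimation

The parameters $(\omega_s, \omega_d, \sigma_t^2, \sigma_e^2, r)$ are
estimated by restricted maximum likelihood.  `neg2_restricted_loglik()`
evaluates

$$-2\log L_R = \log|\mathbf{V}| + \log|\mathbf{X}'\mathbf{V}^{-1}\mathbf{X}|
  + \mathbf{y}'\mathbf{P}\mathbf{y} + (n_{obs} - p)\log 2\pi,
  \qquad \mathbf{V} = \mathbf{Z}\mathbf{M}_E\mathbf{Z}'\sigma_t^2 +
  \mathbf{I}\sigma_e^2,$$

through the mixed-model-equations identity $\log|\mathbf{V}| +
\log|\mathbf{X}'\mathbf{V}^{-1}\mathbf{X}| = \log|\mathbf{R}| +
\log|\mathbf{G}| + \log|\mathbf{C}|$: one sparse Cholesky factorization of
the MME coefficient matrix $\mathbf{C}$ per evaluation yields both
determinants, the BLUE/BLUP solutions and $\mathbf{y}'\mathbf{P}\mathbf{y}$.
$\log|\mathbf{M}_E| = \log|\mathbf{D}_E|$ is a sum of scalar logs because
$|\mathbf{L}| = 1$.  The additive constant is included identically in both
models, so differences of fitted minima are valid LRT statistics.  Animals
without phenotypes contribute through the pedigree via the incidence
matrix $\mathbf{Z}$.

`fit_reml()` maximizes over the constraint region through a smooth
bijection onto unconstrained coordinates: logistic-stick coordinates for
$(\omega_s + \omega_d)$ and its split, a logistic fraction of
$1 - \omega_s^2 - \omega_d^2$ for $r$ (which keeps every visited point
feasible, including the block positive-definiteness conditions, since for
known-parent blocks $\delta$ equals the upper bound of $r$), and log
coordinates for the variances.  Internally the optimizer works on the
likelihood *profiled* in $\sigma_e^2$ — the residual variance has a closed
form at every $(\omega_s, \omega_d, r, \lambda = \sigma_t^2/\sigma_e^2)$ —
which removes one dimension at no cost; the same device is standard in
`lme4`.  The exported evaluator keeps all five parameters so that the
profile can be cross-checked against a dense textbook implementation.

Numerical choices, all adjustable via `reml_control()`:

* **Starts.**  Three canonical start points: the interior default
  $\omega_s = \omega_d = 0.25$ with $r$ mid-range, a near-zero-transmission
  start, and a near-additive start ($\omega_s + \omega_d \approx 1$, even
  split).  Variances start at a half/half split of the phenotypic variance
  ($\lambda = 1$) — the order of magnitude a practitioner would assume
  without knowing the truth.  The experiment runner warm-starts the
  environment model from the fitted null model (once with $r$ mid-range,
  once with $r$ near zero), which on the mirrored design recovers the same
  optimum as the full multistart at less than half the cost and guarantees
  the nesting inequality in practice.
* **Optimizer.**  `stats::nlminb` (quasi-Newton with finite-difference
  gradients) with a relative tolerance of $10^{-8}$ on $-2\log L_R$ and
  per-start budgets of 200 evaluations / 80 iterations; occasional flat
  ridges otherwise consume thousands of evaluations without changing the
  optimum beyond $10^{-5}$.
* **Boundary.**  Estimates of $r$ below $10^{-6}$ are reported as exactly
  0 with a boundary flag — under the null about half the fits end there,
  which is precisely the point mass the mixture LRT expects.
* **Reproducibility.**  The fit is deterministic.  The restricted
  likelihood at the optimum is invariant to reordering the animals to
  about $10^{-6}$; the estimates themselves only to $\sim 10^{-3}$ on
  small datasets, because the profile around the optimum is flat in
  directions the data barely inform — a property of the model, not of the
  optimizer.
* **Infeasible points** (a block with $r \ge \delta$, reachable only with
  user-supplied parameters) evaluate to a large sentinel rather than an
  error, so the optimizer treats them as rejected points.

## Testing for a transmitted environmental effect

The null hypothesis $r = 0$ lies on the boundary of the parameter space,
so the LRT comparing the classical fit with the environment fit is
asymptotically a 50:50 mixture of a point mass at zero and $\chi^2_1$:
`lrt_mixture()` uses $p = \tfrac12 P(\chi^2_1 > \mathrm{LRT})$ and the 5%
critical value 2.706.  A raw statistic below $-10^{-6}$ (the alternative
ending *above* the null) is flagged as an optimizer failure and clamped.

The baseline the model is compared against, `paired_line_ttest()`, is the
classical phenotype-level check: a paired two-sided T-test on the line
contrast of the last generation.  Two-sided because no direction is
specified for a line difference a priori.  Two pairing units are
implemented.  The default pairs mirrored *animals* by construction
position ($N \cdot$ `n_off` pairs): this is the test as practised in
phenotype-level comparisons, and because it treats relatives as
independent pairs it is anti-conservative under transmissibility drift —
its realized type-I error on the default design is about 15% at a nominal
5%, which is precisely the failure mode that motivates the model-based
LRT.  Pairing mirrored *family means* instead (`unit = "family"`, $N$
pairs) restores approximate calibration at the cost of power; it is kept
as an option for users who want the drift-robust variant of the baseline.

## The simulated study

`mirrored_design()` builds the two-line experiment: $N$ founder couples
(G0) each produce `n_off` offspring (G1); one G1 male per family is mated
to two sisters of the next family (rotation $f \to f+1 \bmod N$), giving
two groups per family at G2; one group per family is exposed to a common
environment and founds line E+, the other founds E−; each line is then
bred for three further generations by single-pair matings using the first
two offspring of the corresponding mating, so the two pedigrees stay
exactly parallel and any systematic line contrast must come from the
exposure.  The default $N = 20$, `n_off = 10` gives 1840 animals with 200
exposed.  Two conventions complete the unspecified corners: the rotation
target ($f+1$; any derangement works) and the single-pair parents (first
two offspring of a mating — full sibs; the sampling-variance rules ignore
inbreeding by the model's own convention, so simulation and estimation
remain mutually consistent).  With `n_off = 2` an animal can appear in
both parental roles (roles, not sexes); realistic designs use
`n_off >= 3`.

`simulate_replicate()` draws phenotypes under the two study scenarios,
with truth $\sigma_t^2 = 5$, $\sigma_e^2 = 10$ and the exposure constant
$\theta_0\sigma_t = \sqrt{r}\,\sigma_t$:

* **Scenario 1** — the environment shifts the *phenotype* of exposed
  animals only; transmissible potentials follow the classical recursion.
  Nothing is inherited, so a correct test should stay at its nominal
  level.
* **Scenario 2** — the constant enters the *transmissible potential* of
  exposed animals, whose remaining sampling variance drops to
  $(\delta_i - r)\sigma_t^2$; the induced line contrast decays by
  $\omega_s + \omega_d$ per generation (`dilution_factor()`), reaching
  27% (Sets 1–3) or 34% (Set 4) of its initial size after three
  generations — which is why phenotype-level T-tests lose power while the
  LRT, which pools covariance information across all generations, does
  not.

The four truth sets (`parameter_sets()`) span $\rho$ from 0.30 to 0.70.
In both scenarios the exposure indicator is included as a fixed effect in
both fitted models, so the LRT responds to the *covariance* signature of
transmission, not to the mean shift.  `simulate_generic_environments()`
generalizes to any pedigree with many shared environments by drawing
$\theta_k \sim N(0, r\sigma_t^2)$ per environment.

What the generator does *not* emulate: selection, non-random mating beyond
the fixed design, inbreeding-adjusted sampling variances, heterogeneous
environment sizes, or a genetic component separate from the transmissible
potential (the two are not jointly identifiable from phenotypes and
pedigree alone).  Passing tests therefore demonstrate correctness of the
machinery and calibration *under the model*, not robustness to model
misspecification in real data.

`run_experiment()` ties it together — simulate, fit both models, test,
aggregate — with one master seed driving a per-(set, scenario, replicate)
seed table, so results are identical whatever subset or order is run;
per-replicate rows are persisted before aggregation (100 REML fits are the
dominant cost, and a crash should not lose them).  Replicates whose fit
did not converge are excluded from estimate summaries and counted.  The
package's own acceptance checks run every cell at 25 replicates (the
published study used 100) and compare rejection rates through exact
binomial confidence intervals at the replicate count actually run;
estimate means are compared within three Monte-Carlo standard errors using
the published across-replicate standard deviations.

## Known limitations

* The closed-form block inverse requires homogeneous parental knowledge
  within each shared environment; the dense fallback removes the
  restriction at a cost quadratic in block size.
* Across-replicate standard deviations are the only uncertainty measure
  produced; no information-matrix standard errors are computed.
* $\widehat{r}$ carries large sampling variance even at the default
  design — detecting transmitted environmental effects needs many
  phenotyped animals, and numbers per generation matter more than extra
  generations because of the dilution factor.
* One REML fit on the default design takes a few seconds; the model is a
  detection tool, not a routine evaluation engine for very large
  populations.
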