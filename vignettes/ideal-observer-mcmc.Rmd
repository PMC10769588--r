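---
title: "Estimating the Bayesian Ideal Observer by MCMC: models, samplers and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the Bayesian Ideal Observer by MCMC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(idealobserver)
```

## The detection task and the ideal observer

The package addresses binary signal detection in the
signal-known-exactly / background-known-statistically (SKE/BKS) setting.
A measurement is

$$
H_0: \; g = b + n, \qquad H_1: \; g = b + s + n,
$$

where $b$ is the image of a random background object, $s$ is the image
of a deterministic signal, and $n$ is i.i.d. Gaussian noise with
standard deviation $\sigma$ per (real) component.  Complex k-space data
are handled throughout as stacked real/imaginary vectors, so one real
Gaussian likelihood covers both measurement models.

The Bayesian ideal observer decides with the likelihood ratio
$\Lambda(g) = p(g \mid H_1)/p(g \mid H_0)$, the statistic that
maximizes the area under the ROC curve among all observers.  When the
background is only accessible through a stochastic object model (SOM)
with parameters $\theta$ (or a generative model with latent vector
$z$), $\Lambda$ is an intractable marginal.  It can, however, be
written as a posterior expectation of the *background-known-exactly*
(BKE) ratio, which for Gaussian noise has the closed form

$$
\Lambda_{\mathrm{BKE}}(g \mid b)
  = \exp\!\big( (g - b - s/2)^{\mathsf T} s / \sigma^2 \big),
\qquad
\Lambda(g) = \mathbb E\!\left[ \Lambda_{\mathrm{BKE}}(g \mid b(\theta))
  \,\middle|\, g, H_0 \right].
$$

The package's core is the Monte-Carlo evaluation of this expectation:
run a Metropolis–Hastings chain targeting $p(\theta \mid g, H_0)$ and
average $\Lambda_{\mathrm{BKE}}$ along it.  Every iteration contributes
— a rejected proposal repeats the current state's value — which is the
standard Metropolis–Hastings estimator of a posterior mean.  The
average is formed in the log domain (log-mean-exp), so the method is
stable even when the BKE exponents reach $O(10^3)$, as they do for
$\sigma = 1$ on a 64×64 image.

## The two sampling engines

### Object-domain chains for lumpy backgrounds

The lumpy background is a superposition of $N_b \sim
\mathrm{Poisson}(\bar N)$ isotropic Gaussian lumps with amplitude $a$
and width $w_b$, centered uniformly in the field of view.  Its
parameters $\theta = (N_b, \{r_n\})$ are sampled by a mixture of three
reversible moves:

* **center move** (probability 0.8): one uniformly chosen lump center
  is perturbed by an isotropic Gaussian step (default $w_b/4$); a
  proposal outside the field of view has zero prior density and is
  rejected;
* **birth** (probability 0.1): a lump is added at a uniform position;
* **death** (probability 0.1): a uniformly chosen lump is removed.

On the ordered center list with a uniform insertion slot, the birth
prior-times-proposal ratio reduces to $\bar N/(n+1)$ (and $n/\bar N$
for a death), so the acceptance rule needs only the likelihood ratio
and the Poisson count ratio.  A death proposed on an empty
configuration is auto-rejected (the reverse move has probability
zero); a center move on an empty configuration is a self-loop.  The
move mixture and step size are configurable; the defaults were chosen
once as a conventional balance between local exploration and
trans-dimensional mixing, and are recorded with every chain.

The chain's inner loop is written in C++ and exploits two structural
facts: the measurement grid is a tensor product, so each lump's imaged
field is the outer product of two one-dimensional Gaussian vectors;
and each move touches one lump, so the background image, residual and
signal inner product are updated incrementally.  A unit test verifies
that the incrementally maintained BKE value agrees with a from-scratch
recomputation at the final state to near machine precision.

### Latent-space chains for generative models

Any SOM expressible as a deterministic continuous map from
$z \sim \mathcal N(0, I_k)$ to a background image satisfies the
package's `latent_generator` contract — a trained GAN generator is the
motivating case, and the analytic fixture generators below are drop-in
instances.  The sampler proposes with the preconditioned
Crank–Nicolson (pCN) rule

$$
\tilde z = \sqrt{1 - \beta^2}\, z_j + \beta\, \xi, \qquad
\xi \sim \mathcal N(0, I_k),
$$

which leaves the latent prior invariant, so the acceptance probability
is the bare ratio of $H_0$ likelihoods.  Chains on simulated
measurements are initialized at the latent vector (or lump
configuration) that generated the measurement; for measurements
without known truth a bounded least-squares latent fit under $H_0$ is
used, falling back to a prior draw.

**Step size.**  The pCN literature gives no universal $\beta$, and its
efficiency is strongly problem dependent.  The default policy adapts
$\beta$ during burn-in toward a 20–40% acceptance band (multiplicative
updates every 50 iterations), then freezes it for the averaging phase;
the frozen value is recorded in the chain result.  A fixed-$\beta$ mode
is available by switching adaptation off.  Freezing after burn-in keeps
the averaging phase a genuine Markov chain.

**Chain length.**  The defaults (200,000 iterations, the first 10,000
discarded, five parallel chains for diagnostics) follow common practice
for these estimators.  The test suite uses shorter chains scaled to
each fixture's mixing time — its sizes (20,000–150,000 iterations,
studies of 50–200 images per hypothesis) were chosen as the smallest
that keep the Monte-Carlo error well inside each test's tolerance.

## Reference observers and oracles

Three independent routes validate the samplers:

* **Closed form.**  For the linear-Gaussian generator
  $b(z) = b_0 + A z$, the measurement is Gaussian under both
  hypotheses with covariance $K_g = A A^{\mathsf T} + \sigma^2 I$, and
  the exact IO is linear: $\log \Lambda = (g - b_0 -
  s/2)^{\mathsf T} K_g^{-1} s$.  The Hotelling observer on this task is
  affinely related to the IO, so their empirical AUCs agree exactly —
  both facts are asserted in the acceptance tests.
* **Deterministic quadrature.**  For generators with $k \le 3$
  (the nonlinear blob fixture has $k = 2$ or $3$), the prior-form
  ratio $\log \mathbb E_z[p(g \mid b(z), H_1)] - \log \mathbb E_z[p(g
  \mid b(z), H_0)]$ is evaluated on a tensor grid with standard-normal
  weights.  A uniform grid over $\pm 6$ prior standard deviations is
  used: for integrands of this form (smooth and rapidly decaying) the
  rectangle rule converges superalgebraically, and each call can
  report the change under grid doubling as its accuracy certificate.
* **Prior-sampling Monte Carlo.**  The same ratio estimated with
  shared standard-normal draws, with a jackknife standard error.  It
  is unbiased but heavy-tailed; it serves as a cross-check of the
  quadrature, not as a primary oracle.

The Hotelling observer is built by covariance decomposition: the
background-image covariance $K_b$ is estimated from noiseless
simulated backgrounds (streaming accumulation, so the sample matrix is
never materialized), the template solves $(K_b + \sigma^2 I) w = s$ by
Cholesky factorization, and a ridge of $10^{-6}\,\mathrm{tr}(K_g)/M$
is added — and reported — only if the factorization fails or is
numerically singular.  The default of 20,000 covariance samples for
the 64×64 task makes the covariance estimation error a minor
contributor to the Hotelling AUC's uncertainty.

## Monte-Carlo standard errors

The log likelihood-ratio estimate from a chain carries a standard
error computed from the autocorrelated weight series
$w_j = \exp(\log \Lambda_{\mathrm{BKE},j} - \max)$ by Geyer's
initial-positive-sequence estimator of the asymptotic variance, mapped
to the log scale by the delta method.  Batch means were considered and
rejected: for the skewed weight series arising here they underestimate
the error at practical chain lengths, which would make "agreement
within $k$ standard errors" checks anti-conservative.  The estimator
is reliable when the chain is long relative to its integrated
autocorrelation time; the oracle-equivalence tests therefore use
chains of 120,000–150,000 iterations, at which the observed error
distribution against the deterministic oracle is well calibrated.

## The convergence diagnostic

The potential scale reduction factor is computed across $M$ parallel
chains of length $N_c$ as

$$
\mathrm{PSRF} = \frac{N_c - 1}{N_c} + \frac{B}{N_c\, W},
$$

with $W$ the mean within-sequence variance and $B$ the
between-sequence variance of the chain means.  Note the form: it is
the variance-ratio statistic *without* the square root of the
classical Gelman–Rubin $\hat R$, and at $B = 0$ (identical chains) it
equals $(N_c-1)/N_c$, slightly below one.  This printed form is the
package default for comparability with the convergence curves reported
for this estimator family; `sqrt_form = TRUE` gives the square-root
variant.  The diagnostic is evaluated on the log-BKE series (a
monotone transform of the quantity being averaged, and immune to
overflow); the conventional convergence threshold 1.01 is the default.
Chains whose within-sequence variance is exactly zero (e.g. a
posterior concentrated on the empty lump configuration) are reported
as degenerate rather than silently passed, since the statistic is
uninformative there.

## The synthetic data and what passing tests show

All studies are simulation studies; the package generates its own
data.  The reference lumpy task (Poisson mean 6, $a = 1$, $w_b = 8$,
64×64 field of view; PRF $h = 35$, $w_h = 2$; signal $a_s = 0.3$,
$w_s = 2.5$ centered; $\sigma = 20$) exercises a genuinely
trans-dimensional posterior with realistic nuisance structure.  The
fixture generators emulate the *interface* and the mathematical
structure of a trained deep generative model — a smooth nonconvex map
from a normal latent space, with exactly known reference solutions —
but not its capacity: passing the equivalence tests shows the sampler
and estimator are correct for any generator honoring the contract, not
that any particular trained generator captures real object
variability.  Assessing a trained generator is a separate problem; the
radially averaged power-spectrum utility supports first-order checks
of ensemble statistics, and nothing more.

Coordinates follow the pixel-center convention $0, \dots, L-1$ with
continuous lump centers in $[0, L)^2$; lump centers are never snapped
to the grid.  The analytic imaging formulas are exact
Gaussian–Gaussian convolutions — background terms use the lump width
consistently in prefactor and exponent, signal terms the signal width
— and are validated against brute-force quadrature convolution in the
tests.  The k-space operator uses the unitary DFT normalization so
that noise levels are stated in measurement units; the
variable-density Poisson-disc mask is generated by dart throwing with
an exclusion radius linear in k-space radius, a fully sampled central
calibration disc, and a bisection on a global density scale to hit the
target sampling fraction of 1/acceleration (the literature specifies
the sampler only by name, so the radius profile and calibration-disc
size are package choices, recorded with every mask).

## Known limitations

* The latent-space sampler uses only pCN proposals; gradient-based
  samplers (MALA, HMC) for differentiable generators are out of scope.
* The empirical (Mann–Whitney) AUC with Hanley–McNeil standard errors
  replaces parametric ROC curve fitting; with 200 + 200 images the
  difference between the empirical and fitted AUC is well inside one
  standard error, but very small studies may prefer a parametric fit.
* Chains persist state snapshots at a configurable stride, not every
  iteration, to bound memory; the log-BKE series is always kept in
  full.
* The Hotelling observer for complex k-space data stacks real and
  imaginary components; observers exploiting complex structure
  directly are not implemented.
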