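---
title: "Latent heritable confounder MR: model, likelihood and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent heritable confounder MR: model, likelihood and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Two standardized complex traits $X$ (exposure) and $Y$ (outcome) are
modelled jointly with a latent heritable confounder $U$:

$$X = q_x U + \alpha_{y\to x} Y + G\gamma_x + e_x,\qquad
  Y = q_y U + \alpha_{x\to y} X + G\gamma_y + e_y,\qquad
  U = G\gamma_u + e_u,$$

where $G$ holds $M$ standardized genotypes and the direct effects follow
spike-and-slab mixtures: a fraction $\pi_x$ of markers affects $X$
directly with per-SNP variance $\sigma_x^2 = h^2_x/(M\pi_x)$ (likewise
$Y$ and $U$), and the three active sets overlap only randomly. Solving
the structural equations expresses each observed marginal GWAS effect
$\hat\beta^x_k = g_k'x/n_x$ as a confounder component, two direct
components carried through local LD $\rho_k$, and bivariate Gaussian
sampling noise with variances $i_x/n_x$, $i_y/n_y$ and covariance
$i_{xy}/\sqrt{n_x n_y}$; $i_x$, $i_y$ play the role of (per-trait)
LD-score regression intercepts and $i_{xy}$ of the cross-trait
intercept induced by sample overlap.

Because $\sigma_u$ and $q_x, q_y$ enter the observable distribution
only through their product, the confounder is parameterised by
$t_x = q_x\sqrt{h^2_u}$ and $t_y = q_y\sqrt{h^2_u}$ (so the
u-component of the likelihood uses unit slab scale with $(t_x, t_y)$ as
loadings), $t_x \ge 0$ fixes the sign indeterminacy of $U$, and the
confounder polygenicity $\pi_u$ is not identifiable and is held at 0.1.
The estimable vector is
$\{\pi_x,\pi_y,h^2_x,h^2_y,t_x,t_y,\alpha_{x\to y},\alpha_{y\to x},
i_x,i_y,i_{xy}\}$.

## Likelihood by characteristic-function inversion

A SNP's genetic signal for one trait, $z = \rho_k'\gamma$, is a sum of
$M$ products of two independent spike-and-slab variables once the local
correlations are themselves approximated by a spike-and-slab law with
per-SNP parameters $(\pi_k, \sigma_k)$ (fraction and RMS of non-zero
correlations). Each product term has the product-normal characteristic
function, giving the closed form

$$\varphi_z(t) = \exp\!\Big(M\,\mathrm{log1p}\big({-\pi_k\pi_t}
  (1 - (1+\sigma_k^2\sigma_t^2 t^2)^{-1/2})\big)\Big),$$

which the test suite verifies against a Monte-Carlo empirical
characteristic function before anything is built on it. The joint CF of
$(\hat\beta^x_k, \hat\beta^y_k)$ is the product of three such factors
(confounder, direct-$X$, direct-$Y$) at loading-transformed arguments
and the Gaussian noise CF; it is real and positive because every
component is symmetric. The bivariate density is recovered on a
$2^7\times 2^7$ grid by 2-D FFT inversion, SNPs are binned on a
$10\times10$ equidistant $(\pi_k,\sigma_k)$ lattice (min-max-scaled
nearest-centre assignment, one grid per non-empty bin and per likelihood
evaluation), and the composite log-likelihood is the restricted-LD-score
weighted sum $\sum_k w_k \log f_k$ with $w_k$ the inverse of the LD
score taken over analysed SNPs only.

Numerical choices, all configurable:

* **Grid extent.** Half-width per axis is the larger of 8 robust SDs
  (MAD about zero) of the observed estimates and 1.05 times the largest
  observed estimate. Covering the extremes matters: flooring the
  largest-effect SNPs (the most informative ones) visibly biases the
  heritability downward, which we measured during development and
  which motivated the max-term.
* **Interpolation** is bilinear on the log-density; out-of-grid points
  and negative FFT ripple are floored at a density of $10^{-30}$
  (configurable), keeping the objective finite everywhere in the box.
* **Inversion accuracy.** In the zero-heritability limit the grid
  matches the analytic bivariate normal log-density to better than
  $10^{-3}$ centrally, and densities integrate to $1\pm0.02$; both are
  enforced by tests. A boundary-mass check widens the grid
  automatically if more than 1% of mass sits in the outer ring.
* **Frequency-domain pruning.** Grid cells where the noise CF alone is
  below $e^{-60}$ are skipped (the signal factors are bounded by 1);
  this is exact to ~1e-26 and saves about two-thirds of the work.

## Two-step estimation

Step 1 fits each trait alone (1-D analogue of the same FFT likelihood)
for $(\pi, h^2_{\rm total}, i)$ over $\pi\in[10^{-5},1]$ (searched
log-uniformly — polygenicity spans orders of magnitude, so uniform
sampling of the range would almost never propose realistic values),
$h^2\in[0,1]$, $i\in(0,3]$. The fitted $\pi$ and $i$ are frozen; step 2
maximises the bivariate likelihood over the seven free parameters
$\{h^2_x,h^2_y,t_x,t_y,\alpha_{x\to y},\alpha_{y\to x},i_{xy}\}$ under
their box constraints with `stats::optim` (L-BFGS-B, numerical
gradients, convergence tolerance $10^{-6}$ relative on the
log-likelihood, at most 500 iterations). Multiple starting points are
drawn uniformly within the ranges; the causal-effect and cross-trait
intercept coordinates are anchored at IVW estimates (both directions)
and the cross-trait LD-score regression intercept plus $U(-0.1, 0.1)$
noise, which speeds convergence without changing the optimum. Equal
log-likelihood ties (within $10^{-4}$) resolve to the smallest
$|\alpha_{x\to y}|+|\alpha_{y\to x}|$, preferring the less extreme
causal explanation.

### The mirror optimum

The likelihood surface has two equivalent optima: the exposure's direct
genetic axis and the confounder axis can be interchanged. Writing
$T_x = t_x + \alpha_{y\to x} t_y$, $T_y = t_y + \alpha_{x\to y} t_x$,
$D = 1 - \alpha_{x\to y}\alpha_{y\to x}$ and $h = \sqrt{h^2}$, the
component-swap map implemented here is

$$\alpha'_{x\to y} = T_y/T_x,\quad \alpha'_{y\to x} = \alpha_{y\to x},
\quad h'_x = T_x D'/D,\quad h'_y = h_y D'/D,\quad t'_x = h_x,\quad
t'_y = -h_x t_y/T_x,$$

with $D' = 1-\alpha'_{x\to y}\alpha'_{y\to x}$. We derived this form by
requiring that the three genetic component loading vectors of the joint
CF are mapped onto each other exactly, which makes the map an involution
and distribution-preserving; the widely quoted simpler form
($h'_x = t_x + t_y\alpha_{y\to x}$, $t'_x = h_x(1+\alpha_{y\to x}w)$,
$t'_y = -h_x w$ with $w = t_y/t_x$) coincides with it when
$\alpha_{y\to x} = 0$ but does not preserve the model-implied second
moments otherwise, which we take to be a typo in its statement. The
test suite verifies involution algebraically and fit-equivalence by a
likelihood-equality oracle. Exact likelihood equality requires the
swapped components to carry the same polygenicity ($\pi_x$ equal to the
fixed $\pi_u$); away from that the two optima remain numerically close
because the likelihood is insensitive to the polygenicities, and the
oracle test evaluates at $\pi_x = \pi_u$ where equality is exact. A
mirror landing outside the parameter ranges is excluded automatically;
otherwise the solution with $h^2_x > t_x^2$ (direct heritability
exceeding confounder-driven heritability) is labelled primary.

## Inference

Standard errors come from a block jackknife: the position-sorted SNPs
are cut into contiguous blocks of near-equal count (200 by default),
with boundaries snapped to LD-block boundaries so no LD straddles a
jackknife block; each leave-one-block-out refit warm-starts at the
full-data optimum (with random fallback starts, and a variance
rescaling if a leave-out fit fails). The variance is the plain sum of
squared deviations of leave-out estimates from the full-data estimate —
the usual jackknife prefactor is identically 1 for equal blocks, which
the code asserts. Wald Z-tests with Bonferroni control give p-values;
for 13 traits tested in both directions (156 tests) the threshold is
$3.2\times10^{-4}$. Exposures whose estimated total heritability falls
below 2.5% are flagged, as instrumenting a barely heritable exposure is
questionable.

The model also implies a genetic correlation
$$r_g = \frac{T_x T_y + \alpha_{y\to x}h^2_y + \alpha_{x\to y}h^2_x}
{\sqrt{(T_x^2+\alpha_{y\to x}^2 h^2_y+h^2_x)
       (T_y^2+\alpha_{x\to y}^2 h^2_x+h^2_y)}},$$
whose numerator splits exactly into a confounder-led term $T_xT_y$ and
a causal-led term $\alpha_{y\to x}h^2_y + \alpha_{x\to y}h^2_x$
(`decompose_rg()`), each normalised by the same denominator.

## The simulator and what it emulates

`simulate_pair()` generates marginal effect estimates directly at the
summary-statistic level: exact $z = R\gamma$ products within
block-diagonal LD, the model's confounder/causal loadings, and sampling
noise that is, by default, correlated across SNPs of a block with the
block's own correlation structure (reflecting the $G'\epsilon/n$ origin
of the noise; a flag disables it). Error variances are solved so every
trait has unit variance, and the implied intercepts $i_x$, $i_y$,
$i_{xy}$ are recorded as ground truth. Scenario presets reproduce the
benchmark settings (standard, null causal, null confounder, small or
reverse causal effects, strong/opposite/two-fold confounding, high
polygenicity, non-Gaussian slabs of kurtosis 2-10 via moment-matched
symmetric Pearson members — scaled beta below 3, scaled Student-t above
— and a three-component exposure architecture). Presets quoted via
$t$ values back-solve $q = t/\sqrt{h^2_u}$ with $h^2_u = 0.3$,
$\pi_u = 0.05$ as in the standard setting.

The synthetic reference panel (`synth_ld_panel()`) uses AR(1) blocks of
50 SNPs with decay rates jittered uniformly in $(0.42, 0.98)$, chosen
once so that restricted LD scores span roughly 1-30 as in imputed
cohort data. Two features of real panels are deliberately absent:
long-range and between-block LD (blocks are independent, which also
gives clean jackknife units), and variation in the *fraction* of
non-zero local correlations (with exact block LD, $\pi_k$ is constant
and the likelihood bins span $\sigma_k$ only). Consequently passing
simulation benchmarks here demonstrates correctness of the estimator
under its own model with realistic LD-score spread — not robustness to
mis-specified real-panel LD profiles, which enter the method through
externally supplied $(\pi_k,\sigma_k,w_k)$ files. We also observed
during development that a panel with (near-)constant LD scores leaves
$(t_x, t_y)$ and $i_{xy}$ nearly unidentifiable — both then induce an
LD-independent cross-trait covariance — so LD-score spread in the
panel is a requirement for separating confounding from sample overlap,
not a nicety.

## Study scale

Replicated benchmark studies in the tests and the acceptance script run
at 50,000 markers with per-SNP slab variances $h^2/(M\pi)$ rescaled so
heritabilities are preserved, 6-20 replicate data generations per
scenario and 2-5 anchored starting points per fit (20 replicates /
5 starts in the acceptance script; full-scale analyses would use the
50-start protocol that `lhc_mr()` defaults to). These sizes are the
package's own choice of a desk-scale study; at this scale the estimator
is substantially *more* precise than the full-scale benchmarks (RMSE of
the forward causal effect near 0.01-0.02 against a benchmark of 0.13),
because the synthetic panel is cleaner than real LD, so error-style
benchmarks are read as upper bounds.

## Known limitations

* $\pi_u$ is fixed, not estimated; reverse causal effects onto $U$ are
  absorbed into the causal parameters (not identifiable).
* The composite likelihood treats SNPs as independent after weighting;
  the weights correct over-counting on average but inference relies on
  the block jackknife, not the curvature of the composite likelihood.
* The intercepts absorb spike-and-slab-approximation error in the LD
  profile; in simulations with exact block LD the fitted $i_x$ runs
  ~0.1 above its generative value while causal effects stay unbiased.
* Strand-ambiguous (A/T, C/G) SNPs are dropped during harmonization
  rather than frequency-resolved; duplicate rsids keep the first
  occurrence.
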