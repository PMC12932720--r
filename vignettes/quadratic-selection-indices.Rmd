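---
title: "Quadratic and linear selection indices: models, estimation, and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quadratic and linear selection indices: models, estimation, and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadindex)
```

## The quadratic net genetic merit

Multi-trait breeding ranks candidates by an economic aggregate of their
genetic values. For a candidate with (centered) true genetic values
$g \in \mathbb{R}^t$, the package models the net merit as the quadratic form

$$H_q = w'g + g'Wg,$$

where $w$ carries linear economic weights (merit units per trait unit) and
the symmetric matrix $W$ weights squared and cross-product terms (merit per
squared trait unit). $W$ captures interactions and nonlinear merit —
intermediate optima, stabilizing or disruptive preferences, trait-by-trait
synergies — that a purely linear merit cannot express. $W = 0$ recovers the
classical linear net merit of Smith–Hazel theory.

Because experimental reports rarely state a quadratic weight matrix,
`economic_weights()` defaults to $W = 0$ and offers two explicit
constructors: `rank1` ($W = ww'/2$, reinforcing the direction of $w$) and an
arbitrary user matrix. Every downstream summary records which $W$ was used;
the package never invents one silently.

## Four index predictors

An index scores a candidate from an observable vector $x$ (phenotype entry
means or GEBVs) as $I(x) = a'x + x'Qx + c$. Under joint multivariate
normality the minimum-MSPE predictor of $H_q$ is the conditional expectation
$E[H_q \mid x]$, which stays within this quadratic family:

* **LPSI** (linear phenotypic): $a = P^{-1}Gw$, $Q=0$. The Smith–Hazel
  solution; maximizes the correlation with $w'g$.
* **QPSI** (quadratic phenotypic): with $\mathrm{Cov}(y)=P$,
  $\mathrm{Cov}(g)=\mathrm{Cov}(g,y)=G$,
  $$E[H_q\mid y] = w'G P^{-1} y \;+\; y'P^{-1}GWG P^{-1}y \;+\;
    \mathrm{tr}\!\left(W(G - GP^{-1}G)\right).$$
  The offset is the conditional-variance trace; with $W=0$ the QPSI
  collapses exactly to the LPSI (nesting is asserted in the tests).
* **LGSI** (linear genomic): $I = w'\hat\gamma$ on GEBVs directly.
* **QGSI** (quadratic genomic): under the classical genomic-index assumption
  $\mathrm{Cov}(\hat\gamma) = \mathrm{Cov}(\hat\gamma, g) = \Gamma$, the
  regression of $g$ on $\hat\gamma$ has identity coefficient, so the
  minimum-MSPE predictor takes the economic weights unchanged:
  $I_{qg} = w'\hat\gamma + \hat\gamma' W \hat\gamma$.

**Centering convention.** All scored inputs are mean-centered before
evaluation and the closed-form moments assume zero-mean normals; offsets
carry the expectation of quadratic terms where it matters. For finite
populations this means genetic values are treated as deviations from the
current population mean — the standard definition of a breeding value — and
the recurrent-selection driver re-centers each cycle.

**Moments.** For $x \sim N(0,\Sigma)$,
$E[I] = \mathrm{tr}(Q\Sigma) + c$ and
$\mathrm{Var}[I] = a'\Sigma a + 2\,\mathrm{tr}(Q\Sigma Q\Sigma)$; the linear
and quadratic parts are uncorrelated because odd normal moments vanish.
These identities (e.g. $E[I_{qg}] = \mathrm{tr}(W\Gamma)$,
$\mathrm{Var}[I_{qg}] = w'\Gamma w + 2\,\mathrm{tr}(W\Gamma W\Gamma)$) are
validated against million-draw Monte-Carlo in the test suite. A sometimes
quoted variant of the variance with a realized GEBV vector in the first term
is not a population quantity; the package uses the standard quadratic-form
result throughout.

## Covariance estimation

`estimate_P_G()` uses multivariate method-of-moments (MANOVA cross-products)
on the two-way model *value = trait mean + genotype effect + residual*. On
the genotype entry-mean basis, $P$ is the covariance of entry means and
$G = P - E/r$ with $E$ the residual mean cross-product matrix and $r$ the
replicate count (harmonic mean when unbalanced). For balanced designs this
coincides with the ML estimator; we document it as the fixed analysis basis
rather than exposing REML machinery for arbitrary designs. Estimates are
clamped to the PSD cone by eigenvalue truncation, jointly so that $P - G$
stays PSD; per-trait broad-sense heritability is the univariate component
ratio $h^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_e / r)$. Missing cells are
dropped pairwise with a warning; no imputation. $\Gamma$ is simply the
sample covariance of the GEBV matrix, clamped to PSD.

## GEBV engines

**GBLUP.** Markers coded 0/1/2 are standardized to $2-2p$, $1-2p$, $-2p$
using training-set allele frequencies; those frequencies are *frozen* and
reused in later cycles (frequencies drift under selection, and re-estimating
them would silently change the model). Multi-trait GBLUP is per-trait ridge
regression on entry means, $\beta_t = (X'X + \lambda_t I)^{-1}X'\bar y_t$ —
the stacked multi-trait design is block diagonal, so per-trait solving is
exact, and cross-trait information enters through $\Gamma$. The default
$\lambda_t = c\,(1-h^2_t)/h^2_t$ with $c = 2\sum p(1-p)$ makes the ridge
identical to the GRM mixed-model equations; marker-form and kernel-form
GEBVs agree to numerical precision (a test asserts 1e-8).

**Gaussian-kernel RKHS.** `fit_rkhs_multitrait()` is a Gibbs sampler for
$Y = 1\mu' + U + E$ with $U \sim MN(0, K, \Sigma_u)$,
$E \sim MN(0, I, \Sigma_e)$ and inverse-Wishart priors
$IW(t+2, \mathrm{diag}(v/2))$ on both components ($v$ = observed trait
variances; an even-split, weakly informative center — the exact
hyperparameters are an implementation choice, documented here). The kernel
$K_{ij} = \exp(-d^2_{ij}/(h\,q))$ uses the median of nonzero squared
distances as the default scale. Computation eigendecomposes $K$ once and
simultaneously diagonalizes $(\Sigma_u, \Sigma_e)$ each sweep, so an
iteration costs $O(nt)$ plus a $t\times t$ eigendecomposition; kernel
eigenvalues are floored at 1e-8 so rank-deficient GRMs still give proper
conditionals. Defaults: 4000 iterations, 1000 burn-in, thin 5, and a
**required** seed (chains are bit-identical under a fixed seed; there is no
silent default). Fixing the variance components (`fix_variance`) turns the
posterior mean into exactly the BLUP with the matched variance ratio, which
is how the GBLUP-equivalence property is tested.

## Selection response and gains

With selected proportion $p$, the selection intensity is
$k = \phi(z_p)/p$ ($k(0.10) = 1.755$). All second moments of $(H_q, I)$ come
from exact quadratic-form identities, giving
$\mathrm{SCor} = \mathrm{Cov}(H_q,I)^2/(\mathrm{Var}H_q\,\mathrm{Var}I)$ and
$\mathrm{SR\text{-}MSPE} = \sqrt{\mathrm{Var}H_q -
\mathrm{Cov}(H_q,I)^2/\mathrm{Var}I}$ (zero in the complete-information
genomic limit $\hat\gamma \equiv g$). Pearson $r^2$ is reported even for
quadratic merit, with the explicit caveat that it is a linear accuracy
measure.

For the response $R = E[H_q \mid \text{selected}] - E[H_q]$:

* **Linear index kinds** admit an exact closed form even under quadratic
  merit. With $c = \mathrm{Cov}(g, I)$ and truncation point $z_p$,
  $$R = k\,\frac{w'c}{\sigma_I} + z_p\,k\,\frac{c'Wc}{\sigma_I^2},$$
  the second term coming from the truncated-normal second moment
  $E[Z^2 \mid Z > z_p] = 1 + z_p k$ (the pair $(g_j, I)$ is bivariate normal
  because both are linear in the underlying normals).
* **Quadratic index kinds** are quadratic forms, hence not normal, and no
  elementary closed form for the truncated mean exists. The package's
  contract is explicit: such responses are computed by the seeded
  high-precision truncation oracle `mc_truncation_oracle()` (default $10^6$
  draws) and flagged `method_R = "mc"` with a Monte-Carlo standard error.
  Verifiability was chosen over false precision; every output records which
  path produced it.

**Per-trait expected gains** always use the closed form
$k\,\mathrm{Cov}(g, a'x)/\mathrm{sd}(a'x)$ built on the index's *linear
kernel*: under zero-mean normality the quadratic term has zero covariance
with every individual trait, so matched linear and quadratic indices report
identical per-trait gains (LPSI = QPSI, LGSI = QGSI) — asserted exactly in
the tests. Realized gains in `empirical_summary()` are unscaled
selected-minus-population trait means, with the nominal intensity and the
realized intensity recorded as attributes.

## The breeding-cycle simulator

`build_genome()` places markers uniformly and QTL uniform-randomly on a
configurable map (default 10 chromosomes of 100 cM, Haldane map function, no
interference). Traits receive random QTL subsets of the configured sizes, so
traits share QTL; pleiotropy is the only source of genetic correlation.
Effects are calibrated so the *expected* founder genetic covariance
$2p(1-p)\,A'A$ hits the target correlation/variance structure: a
sign-consistent initialization (a one-factor sign vector read off the target
correlations) followed by quasi-Newton minimization of the squared Frobenius
gap over the masked effect entries. On the simulated-maize design (2806
markers, 315 QTL, per-trait counts 300/100/60/40, targets
$-0.5, 0.4, 0.3, -0.3, -0.2, 0.1$) the achieved expected correlations are
exact to three decimals and 2000 founders realize the $T_1,T_2$ correlation
within $\pm 0.03$ across seeds. Infeasible targets (e.g. single-QTL traits
asked for $r = 0.9$) error with the achieved matrix, rather than silently
shipping a different genome.

Design simplifications, stated plainly: founders are drawn with independent
loci at frequency 0.5 (no ancestral LD; LD then accrues through selection
and drift), there is no mutation and mating is random among selected
parents. The indices consume covariances, not LD structure, so these
simplifications do not touch what the package is testing; they do mean the
simulator's absolute per-cycle responses are *not* comparable to any
specific published experiment, and the package treats cross-index ordering
and arithmetic — not absolute levels — as the reproducible quantities.
Per-plot heritabilities (default 0.5 per trait; configurable) convert
realized genetic variance to residual variance as
$\sigma^2_e = \sigma^2_g(1-h^2)/h^2$.

Meiosis is simulated per adjacent-locus interval with Haldane switch
probability $r = (1 - e^{-2d/100})/2$ and cumulative-XOR source tracking —
exactly equivalent to Poisson crossover counts with uniform positions, but
vectorizable across thousands of gametes; a test checks realized switch
rates against the map.

`run_recurrent_selection()` wires everything together: phenotypic kinds are
re-phenotyped and re-estimated every cycle; genomic kinds train once at
cycle 0 and then run phenotype-free on frozen marker effects and allele
frequencies, re-estimating only $\Gamma$ from current GEBVs. For the
Gaussian-kernel engine, later-cycle GEBVs come from kernel regression
against the training genotypes with the training bandwidth scale.

## Normality suite

The closed forms lean on (multivariate) normality, so the package ships the
tests used to audit that assumption: univariate Shapiro–Wilk (delegated to
`stats::shapiro.test`; the classical published example with $W = 0.79$
reproduces), Mardia's skewness ($nb_1/6 \sim \chi^2$) and kurtosis
(two-sided normal reference), Henze–Zirkler (one-sided, log-normal
approximation, standard smoothing parameter), and a generalized multivariate
Shapiro–Wilk on standardized principal scores with Fisher-combined p-values,
documented as an approximation. All multivariate statistics are exactly
affine invariant; simulation shows type-I error within $[0.03, 0.07]$ at
$\alpha = 0.05$, $n = 500$, for every implemented test.
`bivariate_merit_normality()` applies the multivariate tests to the pair
$(H_q, I)$ — the hypothesis under which the linear truncation formula for
the response is exact — and reports p-values without imposing a decision.
Royston and Henze–Wagner variants are named in the report schema but not
implemented: their published constants are not documented well enough to
reimplement verifiably.

## Numerical choices and degenerate inputs

* PSD repair is eigenvalue truncation at zero with symmetric reassembly;
  symmetry checks use a 1e-10 relative tolerance. Clamping is idempotent.
* Singular $P$ errors with its condition number; rank-deficient systems that
  are legitimately solvable (degenerate $\Gamma$ from few markers) go
  through a pseudo-inverse with a logged rank report.
* Truncation ties are broken deterministically by ascending candidate id.
* Monomorphic markers are excluded with a warning; all-missing columns
  error. Missing marker codes are column-mean imputed before centering.
* Every stochastic routine takes an explicit seed; identical seeds give
  bit-identical populations, chains, oracles and summaries.

## Problem sizes used by the test suite

The shipped tests run covariance recovery at 100–2000 genotypes, GBLUP
instances around 30–60 genotypes with 20–80 markers, RKHS chains of 400–4000
iterations at up to 50 genotypes, Monte-Carlo oracles at $10^5$–$10^6$
draws, normality calibration at 1000 replicates of $n = 500$, and ten-seed,
ten-cycle recurrent-selection experiments at the full simulated-maize scale
(500 genotypes × 4 replicates, 2806 markers). These sizes were chosen so the
whole suite exercises every claim at meaningful precision while staying
comfortably runnable on a laptop.

## Known limitations

* Heritability is defined only for the linear indices
  (`index_heritability()`); no heritability is reported for quadratic
  indices, since no accepted definition exists for them.
* The MANOVA estimator does not adjust for spatial field structure or
  genotype-by-environment covariance.
* Marker codings are additive; dominance and epistasis enter only through
  the Gaussian kernel and the quadratic index terms, not the simulator's
  truth model.
* The QPSI/QGSI closed forms assume joint normality; under strong
  non-normality the oracle path remains correct for the stated model but
  the model itself may misfit — which is exactly what the normality suite
  is for.
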