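---
title: "Partitioning variance in ultrasound carcass traits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning variance in ultrasound carcass traits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ultravar)
```

## The problem

Ultrasound measurements of longissimus muscle area (LMA, cm²), subcutaneous
fat depth (SFD, mm) and percent intramuscular fat (IMF, %) are indicator
traits in U.S. beef cattle genetic evaluation. Images are collected in the
field by certified technicians and interpreted centrally by one of three
imaging laboratories. National evaluations treat technician and laboratory
as part of the fixed contemporary-group effect and assume homogeneous
additive-genetic and residual variances. `ultravar` implements the machinery
needed to interrogate those assumptions: it partitions phenotypic variance
into technician, contemporary-group-within-technician, additive genetic and
residual components per laboratory, tests homogeneity of residuals across
technicians, and treats the same trait interpreted by different laboratories
as distinct traits to estimate between-laboratory genetic correlations.

## The univariate animal model

For one trait under one laboratory,

$$y_{ijk} = \mu + t_i + c_{ij} + a_{ijk} + e_{ijk},$$

with technician $t \sim N(0, I\sigma_t^2)$, contemporary group within
technician $c \sim N(0, I\sigma_c^2)$, additive genetic effect
$a \sim N(0, A\sigma_a^2)$ over **all** pedigree animals (recorded or not),
and residual $e \sim N(0, I\sigma_e^2)$. $\mu$ is the only fixed effect:
scan age enters the analysis exclusively through the breed acceptance
window (a record filter), not as a covariate. Contemporary groups are
nested in technicians because a group is scanned by a single technician;
the nesting is validated, not assumed (`validate_structure()`).

$A$ is the numerator relationship matrix. `build_A()` implements the
tabular recurrence (with inbreeding on the diagonal), and
`build_A_inverse()` implements Henderson's sparse rules in two modes:
sire–dam, and sire–maternal-grandsire with relationship weights $1/2$ and
$1/4$ and Mendelian-sampling variances $11/16$, $3/4$, $15/16$, $1$. The
sire–MGS mode ignores inbreeding because the maternal line is untracked; in
the default sire–dam mode inbreeding adjustment of the Mendelian-sampling
variances is optional and off by default, matching analyses of populations
where inbreeding is negligible. A point worth documenting: Henderson's
no-inbreeding rules invert the *implied* gene-flow covariance
$T D T{}'$ exactly; when some parents are themselves related, that implied
matrix has diagonal entries above 1 and differs from the unit-diagonal
display convention. The test suite distinguishes the two objects
explicitly.

## Restricted likelihood and the derivative-free fit

`reml_neg2_loglik()` returns $-2\log L_R$ up to an additive constant, via
the mixed-model-equations identity

$$\log|V| + \log|X'V^{-1}X| = \log|R| + \log|G| + \log|C|,$$

where $C$ is Henderson's coefficient matrix. $C$ has a fixed sparsity
pattern across variance-component values, so the package assembles it once
into a slot-by-class scatter matrix (one sparse matrix–vector product per
evaluation) and reuses the supernodal symbolic factorisation across the
thousands of evaluations a derivative-free fit needs. Equality with a dense
generalized-least-squares oracle (to the constant $\log|A|$) is asserted in
the tests on random small instances.

`fit_univariate()` minimises $-2\log L_R$ with a Nelder–Mead simplex over
*log* variances, so components stay positive without constraints; a floor
of $10^{-8}$ times the phenotypic variance stands in for the zero boundary.
Convergence follows the derivative-free REML convention: stop when the
sample variance of $-2\log L$ across the simplex vertices falls below
$10^{-10}$ (configurable via `reml_options()`, evaluation cap 5,000).
After the first run the fit restarts from the converged components scaled
by 0.5 and 2 and records the spread of the minima — the practical check
that different starting values reach a common optimum. Standard errors of
variance-component *percentages* and of heritability are obtained by the
delta method on the inverse of half the central-difference Hessian of
$-2\log L_R$ at the optimum; this is standard asymptotic REML practice,
chosen here because the original software's standard-error method is not
described — these SEs are not claimed to reproduce the published ones.

EBVs come from the mixed-model-equation solution at the fitted components;
prediction-error variances are the animal-block diagonal of $C^{-1}$
(computed by blocked column solves) and accuracy is
$r_i = \sqrt{1 - \mathrm{PEV}_i/\sigma_a^2}$.

## The trivariate laboratory-as-trait model

To ask whether laboratories measure the *same* genetic trait, the records
of one trait are stacked by laboratory with one mean per lab, per-lab
technician, contemporary-group and residual variances, and genetic
covariance $A \otimes G_0$ with $G_0$ the $3\times 3$ genetic covariance.
Cross-laboratory covariances of technician, contemporary-group and
residual effects are structurally zero: no technician, group or record
appears under two laboratories. The only information about the
off-diagonals of $G_0$ flows through the pedigree — chiefly sires with
recorded progeny under more than one laboratory — and
`lab_pair_links()` flags pairs with no such links as unidentifiable.

$G_0$ is parameterised by its Cholesky factor with log diagonal, so the
estimate is positive semidefinite by construction and
$|r_g| \le 1$ always holds. The fit (15 parameters) uses the same simplex
and convergence rule, started from the univariate fits per laboratory and
a neutral $r_g = 0.5$ for the off-diagonals; whether per-lab technician
and contemporary-group variances should be re-estimated jointly was an
open design choice, resolved here in favour of joint re-estimation because
the stacked model as written includes them. Genetic correlations are
$r_{g,ij} = \sigma_{a(i,j)}/\sqrt{\sigma_{ai}^2 \sigma_{aj}^2}$, tested
against 1 with a two-sided z-test at 5% (sidedness is a convention choice;
two-sided is the default adopted).

The standard error attached to $r_g$ uses the accuracy-driven
approximation

$$SE(r_g) = \sqrt{\frac{1/(r_{ik}^2 r_{jk}^2) +
 (1 + \tfrac12 r_{ik}^4 + \tfrac12 r_{jk}^4 - 2r_{ik}^2 - 2r_{jk}^2)r_g^2 +
 r_g^4}{N-1}},$$

where $r_{ik}$, $r_{jk}$ are average sire-EBV accuracies under the two
laboratories and $N$ the number of common sires. The printed form of this
formula is typographically ambiguous about grouping; the reconstruction
above was adopted because it collapses to the classical
$(1-r_g^2)/\sqrt{N-1}$ at unit accuracies, which the tests verify
symbolically and numerically. The sire set is "sires with at least one
recorded progeny under each laboratory of the pair", accuracies averaged
arithmetically (the mean type was unspecified). Spearman rank correlations
of sire EBVs between laboratories use the per-laboratory univariate EBVs —
using the trivariate EBVs would couple the two rankings through the very
$G_0$ being assessed.

## Downstream statistics

* Heritability is computed *within* contemporary group,
  $h^2 = \sigma_a^2/(\sigma_a^2+\sigma_e^2)$; technician and group
  variances are excluded from the denominator, so $h^2$ always exceeds the
  additive percentage of total phenotypic variance.
* Component percentages are $100\,\sigma_x^2/\sum\sigma^2$, displayed as
  integers; $h^2$ and $r_g$ display at 2 decimals.
* Across-laboratory spread is summarised as $100(\max-\min)/\text{mean}$.
* Residual homogeneity across technicians uses Bartlett's test (with the
  Box correction) on records centred at their contemporary-group mean.
  "After correction for contemporary-group effects" is read as fixed
  CG-mean centring, not BLUP residuals — an interpretive choice; singleton
  groups carry no within-group deviation and are dropped with a count.

A note on the published reference tables shipped in
`published_variance_components()` / `published_heritabilities()`: the
components are printed at two decimals, and recomputing derived statistics
from them reproduces most but not all printed cells. All 18 range/mean
dispersion percentages reproduce exactly. Heritabilities reproduce exactly
in 18 of 27 cells (all Simmental cells, all Angus cells except LMA lab 3,
and Hereford LMA lab 3); the remaining Hereford cells and Angus LMA lab 3
differ by 0.01–0.05, consistent with rounding of the published components.
Integer percentages reproduce exactly in 17 of 27 rows and within one
point in all but one cell (the published Hereford IMF lab-1
contemporary-group percentage, 34, is three points from the 36.6% its own
printed components imply). The acceptance machinery asserts exactness only
where the published numbers are internally consistent.

## The synthetic-data generator

The study's raw data are proprietary, so `simulate_dataset()` generates
datasets with the exact structure the models assume: technicians assigned
to one laboratory, contemporary groups to one technician, each recorded
animal in one group; founder sires and dams unrelated; recorded animals
from random sire-by-dam matings giving paternal half-sib families;
optional third generation (dams with their own founder parents, disjoint
from the sire pool so the pedigree stays non-inbred); scan ages uniform
inside the breed window. Dams are assigned to a single laboratory (herds
report to one lab), so *sires alone* create cross-laboratory genetic
links and `sire_sharing = 0` makes cross-lab covariances structurally
unidentifiable, which the trivariate fit flags. Breeding values follow the
pedigree recursion: parent average plus Mendelian sampling with variance
1/2, 3/4 or 1 times the genetic (co)variance for 2/1/0 known parents. One
master seed is split into independent substreams (design, breeding values,
effects, ages) so changing one configuration field perturbs only that
component. Contemporary-group sizes are fixed by default; a
negative-binomial option emulates the skewed sizes of real data (the study
reports only mean sizes, 8.2–12.8 animals).

Defaults emulate the published Angus LMA lab-1 cell: true components
$(\sigma_t^2, \sigma_c^2, \sigma_a^2, \sigma_e^2) =
(53.98, 124.13, 16.87, 35.06)$ around a mean of 78.2 cm².

What the generator does *not* emulate: selection, assortative mating,
overlapping generations, heterogeneous residuals within laboratory,
age trends, or breed admixture. Recovery of true parameters from these
simulations therefore demonstrates correctness of the estimation
machinery under the model's own assumptions, not robustness to the ways
real association data violate them.

## Simulation scales and numerical choices

Monte-Carlo checks run at deliberately modest sizes chosen as a
compromise between sampling error and runtime on a single core:

* Univariate recovery: 10 technicians × 8 groups × 10 animals
  (800 records, ~80 paternal half-sib families) per replicate, 20
  replicates, under the Angus LMA lab-1 truth. At this size the
  technician variance (10 realised technician effects) and the additive
  variance are the hard components, hence the wider tolerance used for
  them (35% on the across-replicate mean) than for the contemporary-group
  and residual variances (15%).
* Trivariate recovery: 100 shared sires with ~18 recorded progeny each
  spread over 3 laboratories (1,800 records), per-lab variances set to
  the published Angus IMF components — a realistic high-heritability cell
  chosen because cross-laboratory genetic information scales with sire
  EBV accuracy — and $G_0$ with $r_g = 0.90$ between all pairs. At this
  scale single-replicate $r_g$ estimates scatter around the truth with
  spread ≈ 0.08 and a small downward shrinkage typical of ML correlation
  estimates near a boundary; the across-replicate mean is the quantity
  checked. Simulation loops skip the confirmation restarts (the
  multi-start property is tested separately) to keep runtime near one
  minute per replicate.
* Bartlett calibration: 1,000 null replicates of 8 technician groups.

Other numerical choices: optimisation in log-variance space with floor
$10^{-8}\times$ phenotypic variance; supernodal sparse Cholesky with
cached symbolic analysis; fill-reducing permutation left to CHOLMOD (the
contract is numerical equality with the dense oracle, not a particular
ordering); simplex step 0.4 on the log scale; ties in Spearman ranks
averaged. Degenerate inputs are handled explicitly: zero-variance groups
make Bartlett's statistic infinite (flagged, $p = 0$); $\sigma_a^2 = 0$
yields zero accuracies; $se = 0$ in the z-test yields $z = 0$ (at
$r_g = 1$) or an infinite-z rejection flag.

## Known limitations

* Percentage and $h^2$ standard errors use the asymptotic
  observed-information approximation; for components near the boundary
  they are optimistic.
* The derivative-free simplex, even with restarts, cannot guarantee a
  global optimum in the 15-parameter trivariate problem; flat likelihood
  surfaces (weak cross-lab links) can leave $r_g$ effectively
  data-undetermined, which mirrors the behaviour reported for real
  Hereford SFD data.
* Heterogeneous-variance *modelling* (fitting distinct residual variances
  within one analysis by technician) is out of scope: heterogeneity is
  assessed, not corrected.
* Only three "laboratory traits" are supported in the stacked model;
  maternal effects and repeated records are not.

## End-to-end pipeline

`run_study()` chains the stages on any one breed: age-window filter,
structural validation, one univariate fit per trait-by-laboratory cell, a
trivariate fit per trait, and the diagnostics tables, with per-fit
likelihood minima and restart spreads retained as convergence evidence,
and optional strict mode that fails on violations or non-convergence.
`write_study_report()` emits a Markdown digest, the result tables as CSV
and per-fit JSON. The package is function-first: scripts and the examples
here are the command-line surface.

```{r example, eval = FALSE}
ds <- simulate_dataset(sim_config(n_labs = 3, technicians_per_lab = 3,
                                  cgs_per_technician = 4, animals_per_cg = 6,
                                  n_sires = 22, n_dams = 66, seed = 1))
report <- run_study(ds, options = reml_options(n_restarts = 1))
print(report)
```
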