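---
title: "Modeling composites in SEM with the Henseler-Ogasawara specification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling composites in SEM with the Henseler-Ogasawara specification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compositeSEM)
```

## Composites, and why the common approaches fall short

Ecologists and other applied researchers frequently summarize a set of
observed variables as a *composite* — a weighted linear combination
$c = w'x$ that carries the collective effect of its components $x$ (soil
condition built from texture, moisture and pH; land-use history built from
stand age and isolation distance; climate built from temperature and
precipitation).  Two approaches dominate practice:

* the **two-step approach** computes composite scores (usually unweighted
  sums) before the analysis and fits the structural model to the scores.
  The formation of the composite is never part of the model, so misfit in
  the component block is invisible, and weights cannot be estimated;
* the **one-step approach** models the composite as a dependent latent
  variable whose disturbance variance is fixed to 0.  The composite is now
  in the model, but as a dependent variable it can neither receive effects
  from other variables nor covary with anything — a covariance between two
  such composites cannot even be written down.

The **Henseler-Ogasawara (H-O) specification** removes both limitations by
extracting, from a block of $k$ components, not one but $k$ composites: the
composite of interest $c$ plus $k-1$ auxiliary *excrescent* variables $\nu$
that span the remainder of the components' space,

$$\begin{pmatrix} c \\ \nu \end{pmatrix} = W'x
 \qquad\Longleftrightarrow\qquad x = (W')^{-1}
 \begin{pmatrix} c \\ \nu \end{pmatrix}
 = \Lambda \begin{pmatrix} c \\ \nu \end{pmatrix}.$$

Written in loading form, $c$ becomes an ordinary exogenous (or endogenous)
model variable, and the weights are recovered after estimation as the first
row of $\Lambda^{-1}$.

## Identification rules and the three variants

`hoSpecification()` emits one parameter row per model-matrix entry,
following the refined identification rules:

1. the scale of $c$ is fixed — by default *effects coding* (its loadings
   sum to 1); the reference-variable and variance-standardization methods
   are available as options and give the same fit;
2. each excrescent variable loads on exactly two components: the block's
   *shared* component and one *reference* component; no two excrescent
   variables touch the same pair, and no component is a reference twice;
3. the reference loading is fixed to 1; the shared loading is free
   (free-weight composite) or fixed to $-1$ (unit-weight composite, so each
   excrescent column sums to 0 and $c$ is exactly the sum of its
   components);
4. $\mathrm{cov}(c, \nu) = 0$ within a block (emitted as explicit fixed
   rows);
5. a free-weight composite must be connected to at least one other model
   variable, otherwise its weights have nothing to be estimated from (the
   builder raises an identification error).

Component error variances are always emitted as explicit rows fixed to 0,
and the covariances among a block's excrescent variables are free — without
them the composites could not reproduce the components' covariance matrix,
and the degrees of freedom of the seven-variable example below would not
come out as 11/8/3.

Three variants differ only in which of these rows are free:

* **unit**: shared loadings fixed at $-1$ — a fixed-weight (sum) composite;
* **free**: shared loadings free — an unknown-weight composite;
* **relaxed**: additionally frees the covariances between each block's
  excrescent variables and every *other* block's composite and excrescent
  variables, dropping the assumption that the composites carry all
  cross-block covariance.  The set of added rows (five for the example) is
  exactly all cross-block excrescent-composite and excrescent-excrescent
  pairs; own-block $\mathrm{cov}(c,\nu)$ stays 0.

The defaults take the *first* declared component as the shared component
and the remaining components, in declared order, as references.  The
choice is a labeling convention, not a substantive assumption: re-specifying
shared/reference assignments or the scaling method changes the row pattern
but neither $q$, nor $\chi^2$, nor the standardized solution (this is
tested, to 1e-6).

`oneStepSpecification()` and `twoStepSpecification()` (with
`twoStepReduce()`) provide the two baselines in the same parameter-table
form.  On one data set, the unit-weight H-O variant reproduces the two-step
standardized structural solution, and the relaxed variant reproduces the
one-step fit ($\chi^2$, df and standardized paths agree to numerical
precision); both equivalences are part of the test suite.  For the one-step
builder the scale-fixing weight is the block's *last* declared component
(pH and dist in the example), overridable per block.

## Estimation

`fitML()` minimizes the normal-theory discrepancy

$$F(\theta) = \ln|\Sigma(\theta)| + \mathrm{tr}\,(S\,\Sigma(\theta)^{-1})
  - \ln|S| - p$$

over the free parameters of the table.  Implementation choices that matter:

* **All-endogenous representation.**  Every model variable — observed,
  composite, excrescent, latent — lives in one coefficient matrix $B$ with
  exogenous covariance matrix $\Psi$, so that
  $\Sigma = G\,(I-B)^{-1}\Psi(I-B)^{-T}G'$.  Loadings and structural paths
  are handled uniformly.
* **Constraints by substitution.**  Affine constraints (the sum-to-1 and
  sum-to-0 rules) are resolved exactly at every evaluation by substituting
  the constrained entries out; no Lagrange multipliers, so the constraints
  hold to machine precision at every iterate.
* **Analytic gradients.**  $\partial F/\partial B$ and
  $\partial F/\partial\Psi$ have closed forms; the chain rule through the
  affine constraint map is a constant matrix computed once per table.  A
  quasi-Newton run (`nlminb`) is followed by damped Newton polishing with a
  finite-difference Hessian until the gradient max-norm falls below 1e-9,
  which makes equivalence comparisons at 1e-6 on $\chi^2$ meaningful.
* **Starting values.**  Free composite loadings start at 0, which works
  well under effects coding because the constrained loading then starts at
  1.  Free *shared* excrescent loadings instead start at $-1$ (the
  unit-weight value): a 0 start would make the loading matrix singular and
  the discrepancy undefined.  Under variance standardization the composite
  loadings start at $1/k$ for the same reason.  Variance parameters start
  at sample-based values (unit-weight combination variances for composites,
  $S_{rr}+S_{ss}-2S_{rs}$ for excrescent variables).  On failure up to
  three deterministic jittered restarts are tried.
* **Divisor convention.**  The discrepancy and $\chi^2 = n\hat F$ use the
  divisor-$n$ (ml) covariance; an unbiased matrix is rescaled by
  $(n-1)/n$ on entry.
* **Variances are unbounded**, matching common SEM software: Heywood cases
  are possible and produce a warning, not an error, so that published
  solutions remain attainable.
* **Non-convergence** lowers the `converged` flag; it never raises.

Standard errors use the *expected* information matrix,
$\mathrm{acov}(\hat\theta) = \tfrac{2}{n}
\{\mathrm{tr}(\Sigma^{-1}\Sigma_i\Sigma^{-1}\Sigma_j)\}^{-1}$, with the
derivative matrices $\Sigma_i$ computed from the same closed forms.
Derived quantities — recovered weights, standardized weights
($w_i\,\mathrm{sd}(x_i)/\mathrm{sd}(c)$ with the model-implied composite
sd), and the standardized solution — get delta-method standard errors with
numerically differentiated gradients (central differences, relative step
1e-6).  The test suite checks the delta-method weight SEs against a
parametric bootstrap (300 refits at $n=180$, fixed seed) at 15%.

## Fit assessment

`chiSquareTest()`, `fitIndices()`, `informationCriteria()` and
`chiSquareDifference()` use the conventional definitions: RMSEA
$\sqrt{\max((\chi^2-df)/(df\,n),0)}$; SRMR over all $p(p+1)/2$ unique
residuals standardized by the sample standard deviations (diagonal
included); CFI/TLI against the independence baseline (all covariances 0,
variances free, no fixed error components — $df_b = p(p-1)/2 = 21$ for the
seven-variable example); AIC $=-2\log L + 2q$, BIC with $\ln n$, and the
sample-size-adjusted BIC with penalty $\ln((n+2)/24)$.  For a saturated
model (df = 0) with a perfect fit, RMSEA is reported as 0 and TLI as 1; a
nonzero $\chi^2$ at df = 0 leaves them undefined (`NA`).  Nested pairs are
verified structurally (the restricted model's free labels must be a subset
of the full model's) before $\Delta\chi^2$ is computed; $\chi^2$
additivity is exact by construction.

## The synthetic population and what it does (not) show

`illustrativeFixture()` builds a free-weight population over the seven
variables of `illustrativeSpec()` — blocks Soil{text, mois, pH} and
Land{age, dist}, single-indicator latents Comp (cover) and Colo (colf), a
saturated structural model and a Soil-Land covariance — emulating the
structure of the forest-herb colonization example that Grace & Bollen
(2008) used to introduce the one-step approach.  The true values are
documented constants in the source, *not* fitted to any data set: unequal
Soil loadings (0.2, 0.5, 0.3 with shared-component excrescent loadings
-0.8, -1.2) so that the free- and unit-weight variants are
distinguishable, and indicator error variances set self-consistently to
$\mathrm{var}(\text{latent})/9$ so the assumed reliability of 0.9 is exact
— rebuilding the table from the population standard deviations reproduces
the same fixed values, and a free-weight fit to the population covariance
returns $\chi^2 = 0$ at df = 8 with all parameters recovered.

`simulateSample()` draws multivariate-normal data (the ML estimator's
assumption; non-normal generators are out of scope) with a local,
restorable seed; `recoveryStudy()` derives per-replicate seeds
deterministically from one master seed, counts and excludes non-converged
replicates, and reports bias, RMSE and delta-method confidence-interval
coverage for the standardized structural paths, plus weight recovery on
the sum-to-one scale (the overall scale of free weights is a convention).

Passing tests on this fixture show that the estimator, the identification
rules, the equivalences between variants and baselines, and the standard
errors behave correctly *under the model's own assumptions* at the stated
sizes.  They do not show robustness to non-normality, missing data,
ordinal indicators, or structural misspecification beyond the
unit-vs-free-weight contrast built into the fixture.

## Problem sizes used by the checks

The test suite exercises: one simulated sample of $n = 180$ (the example's
sample size) for all variant comparisons; a recovery study at
$n = 10{,}000$ with 200 replicates (|bias| of standardized paths below
0.02); coverage at $n = 1{,}000$ with 200 replicates (nominal 95% CIs
within [0.92, 0.98]); $\chi^2$ calibration of the relaxed model at
$n = 180$ over 500 replicates (rejection rate within 0.05 of $\pm$0.03);
a $10^6$-draw agreement check between the implied and simulated
covariance; and a 300-replicate parametric bootstrap for the weight SEs.

## Numerical details and limitations

The local-identification diagnostic (`checkLocalIdentification()`)
computes the rank of the Jacobian of $\mathrm{vech}\,\Sigma(\theta)$ by
central differences (relative step 1e-6) at the supplied point plus two
random perturbations, treating singular values below 1e-8 of the largest
as zero, and names the parameters spanning any null space.

Out of scope by design: mean/intercept structures; raw-data FIML for
missing values; robust (sandwich) or weighted least-squares estimators and
ordinal indicators; multiplicative composites; fixed weights at unequal
values; multi-indicator latent measurement models beyond the
single-indicator-with-fixed-reliability case; cyclic structural graphs.
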