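---
title: "Genetic mediation analysis with bivariate GREML: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic mediation analysis with bivariate GREML: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magreml)
```

## The question the package answers

Complex traits are heritable, but heritability estimates are silent about
*mechanism*. When a plausible intermediate trait exists — say educational
attainment between genotype and later-life health — the mechanistic question
is how much of the outcome's additive SNP-based genetic variance is
transmitted *through* that mediator. Polygenic-score mediation regressions
understate this, because a score captures only part of the additive genetic
component. `magreml` instead works at the level of the full additive genetic
factor, via variance-component estimation on a genomic relatedness matrix
(GRM), so no polygenic predictor is needed.

## The structural model

For mediator $M$ and outcome $Y$ on $n$ genotyped individuals (fixed-effect
covariates concentrated out):

$$M = Ga + G^*g + E^*f, \qquad Y = Gc + Mb + Ee,$$

where $G$ and $G^*$ are latent additive genetic factors whose covariance
across individuals is the GRM, and $E$, $E^*$ are independent standard-normal
environmental factors. $G$ may affect the outcome both directly ($c$) and
through the mediator ($ab$); $G^*$ acts on the outcome only through the
mediator. Both genetic factors are needed: dropping $G$ would force full
mediation, dropping $G^*$ would force a perfect genetic correlation between
the traits.

The implied variance components (VCs) are

| VC | value |
|----|-------|
| $\sigma^G_{MM}$ | $a^2+g^2$ |
| $\sigma^G_{MY}$ | $(a^2+g^2)b + ac$ |
| $\sigma^G_{YY}$ | $(a^2+g^2)b^2 + c^2 + 2abc$ |
| $\sigma^E_{MM}$ | $f^2$ |
| $\sigma^E_{MY}$ | $f^2 b$ |
| $\sigma^E_{YY}$ | $f^2 b^2 + e^2$ |

and the quantities of interest are recovered in closed form:

$$b = \frac{\sigma^E_{MY}}{\sigma^E_{MM}}, \qquad
\text{indirect} = \sigma^G_{MM}\, b^2, \qquad
\text{direct} = \sigma^G_{YY} + \sigma^G_{MM} b^2 - 2\sigma^G_{MY} b .$$

The decomposition $\sigma^G_{YY} = \text{direct} + \text{indirect} + 2abc$
holds exactly; the cross term $2abc$ arises whenever the same genetic factor
acts on the outcome along both paths, and is reported separately rather than
attributed to either effect. Individual loadings are not always separately
identified (under full mediation $a^2$ and $g^2$ are not), but $b$, the
indirect and the direct effect are, whenever the mediator retains
environmental variance.

### Assumptions, and which ones the software can check

1. the heritability model behind the GRM is correctly specified;
2. the mediator precedes the outcome, with a homogeneous effect $b$;
3. environmental influences on the mediator affect the outcome only through
   the mediator;
4. environmental confounders that would violate (3) are measured and
   supplied as covariates (and contain no colliders);
5. the mediator has nonzero environmental variance.

Only (5) is verifiable from a fit: `mediation_effects()` refuses to divide
by an environmental mediator variance below `floor_frac` (default $10^{-6}$)
times the mediator's total variance, because $b$ is a ratio with
$\sigma^E_{MM}$ in the denominator. (1)–(4) are scientific commitments;
identification of $b$ through the *environmental* covariance is exactly what
(3)+(4) buy, since any remaining environmental path from mediator to outcome
is then the causal one. The command-line log restates this so it travels
with the results.

## Estimation

### Restricted likelihood and the canonical transformation

The stacked trait vector follows
$\mathrm{N}(X\beta,\; \Sigma_G \otimes A + \Sigma_E \otimes I)$ with $A$ the
GRM. After rotating phenotypes and covariates by the eigenvectors of
$A = U\,\mathrm{diag}(d)\,U'$, the covariance block-diagonalizes into
per-individual $2\times 2$ blocks $V_i = d_i \Sigma_G + \Sigma_E$, so one
evaluation of the restricted log-likelihood

$$\ell_R = -\tfrac12\left[\,(N - p)\log 2\pi + \log|V| + \log|X'V^{-1}X| +
y'Py\,\right]$$

costs $O(n)$ after the one-off eigendecomposition. Fixed effects (intercept,
covariates, optional GRM principal components, separately per trait) are
concentrated out by REML. The same likelihood is also implemented densely
(`O(n^3)`, arbitrary per-trait missingness); the test suite checks the two
agree to $10^{-8}$ on random instances, using an independently written dense
oracle.

**Missing data.** Individuals observed for only one trait break the
Kronecker structure that the canonical transformation exploits. Rather than
approximating, the package switches to the exact dense evaluation whenever
any per-trait missingness is present. This is a deliberate
correctness-over-speed choice: the dense path is quadratic in memory and
cubic in time, so it suits the moderate sample sizes where a desk analysis
with substantial one-trait missingness is realistic; for large samples the
practical advice is to analyse the complete-case subset and compare.

### Parameterization and optimizer

$\Sigma_G$ and $\Sigma_E$ are parameterized through their $2\times2$
lower-triangular Cholesky factors, which keeps both matrices positive
semi-definite without explicit constraints and makes the two null spaces of
the mediation test *linear* restrictions: zeroing the mediator row of the
genetic factor ($\lambda_1=\lambda_2=0$, two parameters) forces
$\sigma^G_{MM}=\sigma^G_{MY}=0$; zeroing the off-diagonal environmental
loading ($\mu_2=0$, one parameter) forces $\sigma^E_{MY}=0$, i.e. $b=0$.

Optimization is BFGS with analytic gradients (validated against central
finite differences in the tests), run from three starts: a Haseman–Elston
moment estimate computed from the rotated data, an equal split of the
residual phenotypic covariance into genetic and environmental halves, and a
seed-controlled random split. The best optimum is kept. A fit is flagged
`converged` when the optimizer reports success and the gradient
infinity-norm is below $10^{-6}\max(1,|\ell_R|)$; non-convergence is
reported, never silently accepted.

### Sampling covariance of the variance components

The $6\times6$ sampling covariance of the VCs is the inverse observed
information, obtained by central finite differences of the analytic
gradient *in VC space* at the optimum (relative step $10^{-4}$, with a
forward-difference fallback next to the PSD boundary and a clipped
pseudo-inverse if the information is singular). Differentiating the analytic
gradient, rather than twice-differentiating the likelihood, keeps the
Hessian accurate at modest step sizes; the simulation tests verify that the
resulting delta-method intervals attain close to nominal coverage.

### Delta-method standard errors

The estimands are smooth functions of the VCs, so their standard errors
follow from the analytic Jacobian, e.g.
$\partial b/\partial(\sigma^E_{MM},\sigma^E_{MY}) =
(-\sigma^E_{MY}/(\sigma^E_{MM})^2,\; 1/\sigma^E_{MM})$; the Jacobians are
re-derived from the closed forms above and cross-validated against
numerical differentiation. Two "proportion mediated" summaries are
reported — indirect over the outcome's genetic variance, and indirect over
(indirect + direct) — because the cross term makes the denominators differ
and either convention may be wanted downstream.

## Testing the indirect effect

The indirect effect $\sigma^G_{MM} b^2$ is zero on a set that touches the
boundary of the parameter space, and a Wald statistic for it is not
invariant to reparameterization, so Wald output is labelled diagnostic. The
primary test is a likelihood-ratio test against the null *union*: either the
mediator has no genetic variance ($P_a$, two restrictions) or no effect on
the outcome ($P_b$, one restriction). Both constrained models are fitted
(warm-started from the unconstrained solution projected onto each
constraint, plus the generic starts), the larger constrained optimum is the
null log-likelihood, and the degrees of freedom follow the active space: 2
if $P_a$, 1 if $P_b$. Exact ties (within $10^{-8}$) resolve to $P_b$; this
is deterministic and, for a given statistic, the less conservative choice,
but ties arise only in degenerate fixtures. No chi-bar-square boundary
mixture is applied beyond the two-space construction itself. A negative
statistic beyond $-10^{-5}\max(1,|\ell_R|)$ aborts with an optimizer-failure
error; small negative rounding is clipped to zero.

Calibration behaviour, reproduced by the test suite: when the mediator is
heritable but inert ($b=0$), p-values are uniform; when the mediator has no
genetic variance, the null optimum typically falls in $P_a$ and the test is
conservative — a reduced false-positive rate, at the price of reduced power
for mediators with very small heritability, which is the regime a practical
analysis would avoid anyway.

### Power

The power to detect the mediator's heritability bounds the power to detect
the indirect effect (detecting the environmental covariance is comparatively
easy when the trait overlap is large). `greml_power()` uses the standard
GREML approximation $\mathrm{var}(\hat h^2) = 2/(N^2 \mathrm{var}(A_{jk}))$
with default off-diagonal relatedness variance $2\times10^{-5}$ and a
noncentral-$\chi^2(1)$ tail at two-sided $\alpha = 0.05$. This
parameterization reproduces the reference calculator's published values
(97.7% at $h^2=12.5\%$, 49.0% at $6.125\%$, 100% at $25\%$, all at
$N=10{,}000$), and that agreement is itself a test in the suite.

## The genomic relatedness matrix

`compute_grm()` uses the equal-variance-per-SNP standardization
$A_{jk} = m^{-1}\sum_i (x_{ij}-2p_i)(x_{ik}-2p_i)/(2p_i(1-p_i))$.
Allele frequencies default to the analysis sample's (missing dosages are
ignored when computing them); missing dosages then drop out of a pair's sum
and decrement that pair's SNP count, matching the semantics of the GCTA
`.grm.N.bin` file (a flag selects a global denominator instead). Monomorphic
SNPs are always excluded; MAF/missingness thresholds are exposed through
`filter_snps()` but nothing is filtered by default, since quality control is
dataset-specific. Relatedness pruning is greedy — repeatedly drop the
individual in the most pairs above the threshold (ties: more missing
phenotypes first, then the larger sample index) — which removes a minimal
set on hub-like relatedness graphs and is idempotent. Principal components
use a fixed sign convention (largest-magnitude entry positive) so output is
platform-reproducible. Genotypes are read from a plain dosage text format;
GRMs round-trip through the GCTA binary triplet to float32 precision.

## What the simulator emulates — and what it does not

`simulate_dataset()` draws SNP-wise Hardy–Weinberg genotypes with allele
frequencies uniform on (0.05, 0.95), builds $G$ and $G^*$ as independent
random linear combinations of the sample-standardized SNPs with effects
$\mathrm{N}(0, 1/m)$ — so the realized GRM is exactly the covariance model
of the latent factors — and assembles phenotypes from the structural
equations. The named verification scenarios fix the standard coefficient
patterns (Baseline $a^2+g^2=2, b=1, c^2=1$; (i) no mediator heritability;
(ii) no mediator effect; (iii) neither; (iv) full mediation $c^2=0$) with
$f=e=1$ and the $a^2+g^2$ mass split equally between $a$ and $g$. The equal
split is a convention: every reported estimand depends on the loadings only
through $a^2+g^2$ except the cross term, which also involves $a$, so the
convention is stated here and exposed as an option.

The replicated studies run at $n=2000$ individuals and $m=2500$ SNPs with
100 replicates — sizes chosen so a complete verification (five scenarios,
three fits per replicate for the LRT) runs on a single desk CPU — and each
replicate draws a fresh genotype panel whose eigendecomposition is shared by
all scenarios. Standard errors at this scale are several-fold larger than in
large-biobank applications; verification therefore targets the *means* of
the estimators across replicates (with Monte-Carlo tolerances) and the
calibration of the test, not the reference standard errors.

The simulator does not emulate: linkage disequilibrium or MAF-dependent
genetic architecture (the GRM weighting is the equal-variance one), assortative
mating, genetic nurture (parental-genotype environmental effects, which can
bias mediation estimates), shared environment between relatives, or
non-Gaussian phenotypes. Passing verification here shows the estimator and
test are correct *under the model's own assumptions*; it cannot certify
those assumptions in real data.

## Known limitations

* Two traits, one GRM: no partitioned or multi-matrix variance components,
  and no more-than-bivariate models.
* The dense missing-data path is exact but cubic; very large samples with
  heavy one-trait missingness are outside the intended envelope.
* The LRT's conservativeness when the mediator's heritability is near zero
  is inherent to the boundary construction, not a bug.
* Estimates of $a$, $g$, $c$ individually are deliberately not returned —
  they are not identified in general.
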