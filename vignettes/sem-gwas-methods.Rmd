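---
title: "Causal networks and SNP-effect decomposition in multi-trait GWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal networks and SNP-effect decomposition in multi-trait GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semgwas)
```

## The model

`semgwas` works with $t$ quantitative traits on $n$ genotyped
individuals. The baseline is the multi-trait animal model

$$ Y = 1\mu' + g + \varepsilon, \qquad
   \mathrm{vec}(g) \sim N(0,\ \Sigma_g \otimes K), \qquad
   \mathrm{vec}(\varepsilon) \sim N(0,\ \Sigma_\varepsilon \otimes I), $$

where $K$ is a relationship matrix — either the pedigree numerator
matrix $A$ (tabular method) or the VanRaden genomic matrix
$G = MM' / (2\sum_j p_j q_j)$ with $M$ the dosage matrix centered by
twice the allele frequency per SNP. $\Sigma_g$ and $\Sigma_\varepsilon$
are free $t \times t$ covariance matrices.

The structural extension lets traits act on each other through a
coefficient matrix $\Lambda$ with zero diagonal:

$$ Y = Y\Lambda' + 1\mu' + W s + g + \varepsilon . $$

We only consider *recursive* systems: the nonzero pattern of $\Lambda$
is a DAG over the traits, so some ordering makes $\Lambda$ strictly
lower-triangular and $(I - \Lambda)$ invertible. Two assumptions carry
the causal reading:

* **Diagonal residual covariance.** $\Psi =
  \mathrm{diag}(\psi_1, \dots, \psi_t)$. Without it the structural
  coefficients are not likelihood-identifiable — an unstructured
  residual covariance can absorb any $\Lambda$. `fit_sem()` refuses a
  request for an unstructured $\Psi$ for exactly this reason.
* **Causal sufficiency at the residual level.** Associations between
  traits are attributed to the trait-to-trait links plus the correlated
  polygenic effects; the polygenic term is what absorbs the genetic
  confounding.

On the reduced form $y = (I-\Lambda)^{-1}(Ws + g + \varepsilon)$ a fully
recursive SEM is a smooth reparameterization of the MTM (the map
$(\Lambda, \Sigma_g, \Psi) \mapsto (B\Sigma_g B', B\Psi B')$ with
$B = (I-\Lambda)^{-1}$ is onto the unrestricted covariance pair), so the
two models reach the same maximum likelihood. This equivalence is a
property we test rather than assume: the saturated `fit_sem()` must
match `fit_mtm_reml()` to about $10^{-4}$ log-likelihood units.

## Learning the trait network

The network is inferred in two stages, using the *residual* covariance
so that genetic confounding between traits is already controlled:

1. A Gibbs sampler for the multi-trait model draws
   $(\Sigma_g, \Sigma_\varepsilon)$ from inverse-Wishart full
   conditionals and the location terms from normals. Priors are weakly
   informative inverse-Wisharts (df $t + 2$, scale $0.5I$) — the data
   sets of interest have $n$ in the hundreds to thousands, where this
   prior is immaterial.
2. For every trait pair and every conditioning subset of the remaining
   traits, the posterior draws of the residual partial correlation
   $\rho(y_t, y_{t'} \mid h)$ are summarized by a highest-posterior-
   density interval; the pair is declared conditionally dependent when
   the interval excludes zero. These decisions drive the
   inductive-causation (IC) algorithm: skeleton, v-structure
   orientation, and the three standard propagation rules.

Choices worth stating:

* **HPD definition.** Shortest contiguous window of the sorted draws
  containing $\lceil \text{coverage} \times S \rceil$ of $S$ draws; ties
  are broken toward the lowest starting index, so the interval is a
  deterministic function of the draw set.
* **Coverage grid.** 0.75, 0.85 and 0.95 are the conventional operating
  points; a wider interval declares fewer dependencies, so edge sets are
  nested across the grid (a property the tests assert on fixed draws).
* **Exhaustive conditioning.** With $t \le 10$ traits every subset is
  enumerated; no PC-style shortcut is taken, and the first separating
  set found (smallest cardinality) is recorded for the v-structure
  stage.
* **DAG completion.** IC returns a partially directed graph; a complete
  skeleton with no v-structure (common with three strongly related
  traits) carries no orientation information at all. Rather than guess,
  `orient_with_order()` makes the completion explicit: the user supplies
  a causal order (biological knowledge — e.g. an early-life measurement
  preceding a lifetime production total) and every undirected edge is
  oriented along it. The default order in the CLI is the column order
  of the phenotype file, which is logged.
* **A detection-rate ceiling.** Declaring independence when an HPD
  interval of coverage $c$ contains zero inherits the frequentist
  behaviour of credible intervals: when a partial correlation is truly
  zero, the interval excludes zero in roughly $1 - c$ of repeated
  samples, no matter how large $n$ is. Exact-skeleton recovery in
  repeated simulations is therefore capped near $c$ (≈85% at the 0.85
  level) even though the true edges themselves are found essentially
  always. Raising the coverage trades this false-edge rate against
  sensitivity to weak paths — precisely the trade-off seen across the
  0.75/0.85/0.95 grid.

## Fitting machinery

All (restricted) likelihood work happens after two one-time
transformations: projection onto the orthogonal complement of the
intercept (REML contrasts), and the eigendecomposition of the projected
kinship matrix. The rotated data rows are then independent with
covariance $d_i \Sigma_g + \Sigma_\varepsilon$, and each likelihood
evaluation costs $O(nt)$ after a $t \times t$ simultaneous
diagonalization.

* `fit_mtm_reml()` runs EM — whose restricted likelihood is provably
  non-decreasing, asserted over the stored trace — until the relative
  change drops below $10^{-10}$ (cap 1000 iterations), then polishes
  with L-BFGS-B on the log-Cholesky scale (`factr = 1e3`), which
  supplies the final digits EM converges to slowly.
* `fit_sem()` maximizes the same restricted likelihood over
  $(\lambda_\text{edges}, \Sigma_g, \Psi)$ through the reduced form. For
  a fully recursive DAG the optimizer is started at the exact
  reparameterization of the MTM solution (an LDL-style regression of
  each trait on its parents in $\hat\Sigma_\varepsilon$); otherwise the
  same construction restricted to the DAG's edges provides the start.
  Standard errors for $\hat\lambda$ come from the observed information
  (numerical Hessian) at the optimum.
* Degenerate inputs: kinship eigenvalues are floored at zero; records
  with zero genetic eigenvalue simply contribute no genetic term; a
  kinship matrix whose smallest eigenvalue is below $-10^{-8}$ is
  repaired by a logged diagonal jitter; monomorphic SNPs are excluded
  from the VanRaden denominator, and a completely monomorphic panel is
  an error rather than a zero division.
* Missing data: phenotypes are handled by listwise deletion; dosages
  surviving QC are mean-imputed per SNP before any kinship or scan
  computation (fractional dosages are intended).

## The scan and the decomposition

Variance components (and for the SEM, $\Lambda$) are estimated once on
the no-SNP model and held fixed while each marker enters as a fixed
covariate — the scan strategy long used for large panels. The SEM scan
solves the per-SNP generalized least squares problem on the *reduced
form*, whose coefficients are the total effects; premultiplying by
$(I - \Lambda)$ recovers the direct effects and their covariance. This
joint formulation (rather than trait-by-trait scans of each structural
equation) keeps the cross-trait genetic covariances in play; a
trait-wise scan conditioning on parent phenotypes would ignore the
correlation between a trait's polygenic term and its parents'
phenotypes and lose the exact MTM/SEM total-effect correspondence.

For a SNP with direct effects $d$ the decomposition follows the path
rules on the DAG: each directed path from a trait $u$ into target $\tau$
contributes $d_u \prod \lambda$ along the path; the indirect effect is
the sum over paths and the total is direct + indirect. As an internal
cross-check the package also computes totals by the matrix route
$T = (I-\Lambda)^{-1} d$ — path enumeration and the reduced form must
agree to $10^{-12}$, and the test suite verifies this on random
recursive systems up to six traits.

Standard errors of indirect and total effects use a first-order delta
method treating the direct-effect block (diagonal covariance) and the
$\hat\lambda$ block (full covariance from the fit) as independent. This
is an approximation — direct effects across traits are correlated
through the joint GLS — and its p-values should be read as first-order.
Two-sided p-values throughout use the standard normal reference, since
$n$ is large in the intended applications; q-values are
Benjamini–Hochberg within each effect type, and the conventional
$-\log_{10} p$ significance line for an FDR level is reported from the
largest rejected p-value.

Model comparison reports $\log L$, $-\tfrac12\mathrm{AIC} = \log L - k$
and $-\tfrac12\mathrm{BIC} = \log L - \tfrac{k}{2}\log n$. Parameter
counts are explicit: $k = t(t+1)$ for the MTM, and
$k = \#\text{edges} + t(t+1)/2 + t$ for a SEM, so a non-saturated SEM is
rewarded for its sparsity even at equal likelihood. (Published tables
sometimes hold $k$ fixed across such comparisons; `model_fit_stats()`
takes a `k` override for that convention.)

## What the generator simulates — and what it does not

`sim_config()` / `make_fixture()` produce data *from the model the
method assumes*: founders in Hardy–Weinberg proportions at independent
SNPs (MAF uniform on a stated range, default 0.05–0.5), full-sib
families via per-SNP Mendelian sampling from family-specific unrelated
parents, polygenic effects with covariance $\Sigma_g \otimes K$,
independent Gaussian trait residuals, QTL with direct effects on chosen
traits, and phenotypes through the reduced form.

Default study conditions mirror a broiler-chicken setting scaled to
desk size: three traits; structural coefficients
$(\lambda_{21}, \lambda_{31}, \lambda_{32}) = (2.13, -0.17, -0.27)$ for
the fully recursive fixture and $(2.14, -0.31)$ for the chain, taken
from a published chicken analysis as ground truth; unit residual
variances, so effect sizes read in residual-SD units; genetic variances
$0.43$ with correlations $0.5$ (heritability ≈ 0.3 per trait, genetic
correlation 0.5 between the first two traits); the `paper_like` fixture
uses $n = 1000$ in 100 full-sib families of 10, 500 SNPs and six QTL
(0.4–0.6 residual SD) of mixed direct/indirect signature.

The generator deliberately omits: linkage disequilibrium (SNPs are
independent, so scans have no local correlation structure), shared
parents across families, selection, genotyping error, and non-Gaussian
residuals. Passing tests on these fixtures therefore demonstrates
correctness of the estimators and procedures *under the model's own
assumptions*; they say nothing about robustness to LD-induced signal
smearing or model misspecification on real data.

Problem sizes used by the test and acceptance runs — chosen as the
smallest at which the asymptotic statements are visibly sharp:
$n = 600$ fixtures for unit tests; $n = 1000$, 500 SNPs for the
MTM/SEM concordance and coefficient-recovery checks; $n = 2000$ with 50
replicate Gibbs chains (2000 iterations each) for end-to-end structure
discovery; 2000 null SNPs at $n = 1000$ for scan calibration.

## Known limitations

* Trait count is bounded (exhaustive conditioning, $t \le 10$); no
  latent variables, no cyclic (non-recursive) systems, no bidirected
  edges.
* The scan holds components fixed; re-estimating per SNP would matter
  only for very large single-SNP effects.
* Delta-method errors for indirect/total effects ignore cross-trait
  correlation of the direct-effect estimates.
* Gibbs mixing between $\Sigma_g$ and $\Sigma_\varepsilon$ is slow when
  the family structure weakly separates them; the Geweke diagnostic is
  exposed (`geweke_z()`) and the default chain length (10000) is sized
  for the shipped fixtures.
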