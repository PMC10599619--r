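---
title: "Measuring elaboration and innovation along phylogenetic major axes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring elaboration and innovation along phylogenetic major axes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macroaxes)
```

## The question and the model

Quantitative-genetic theory predicts that phenotypic evolution follows lines
of least resistance: directions of trait space holding the most variation. At
macroevolutionary scales the analogous object is the **evolutionary rate
matrix** `R` — the covariance of among-species trait divergence per unit
branch length, estimated with the phylogeny explicitly incorporated — and its
leading eigenvector, the **phylogenetic major axis**. `macroaxes` asks, for
every species and clade, whether divergence runs *along* that axis
(elaboration) or *away* from it (innovation).

The generative model is a multivariate phylogenetic mixed model. For species
$i$ with $k$-dimensional trait vector $y_i$,

$$ y_i = \mu + u_{\text{class},i} + \sum_{c} u_{c,i} + e_i,
   \qquad e_i \sim N(0, E), $$

where each random term $t$ contributes effects only to its member tips and the
stacked effects follow a matrix-normal $MN(0, A_t, R_t)$: $A_t$ is the
shared-path-length matrix of the term's subtree and $R_t$ the term's rate
matrix. Assumptions worth making explicit:

* **Brownian covariance.** Each term is a homogeneous multivariate Brownian
  process on its subtree; rate heterogeneity *within* a modeled clade is not
  represented (it is absorbed into the clade's $R_t$ and the residual).
* **Clade terms are deviation processes.** A clade's Brownian term starts at
  zero at the clade's MRCA rather than re-rooting the process, matching the
  additive random-effect structure: a clade effect is the clade's *departure*
  from the class-wide process.
* **Residuals are estimated.** The residual covariance $E$ is a free
  inverse-Wishart-updated parameter. An alternative reading of "error in the
  dataset as residuals" would fix a known measurement-error covariance; we
  estimate it, and a fixed-$E$ variant would amount to skipping one Gibbs
  block.
* **Intercept only.** The single fixed effect is the trait-space mean $\mu$
  (flat prior); the model statement includes no other fixed effects.

## Gibbs sampler and numerical choices

The sampler alternates conjugate blocks: (a) matrix-normal updates of each
term's tip effects, (b) inverse-Wishart updates of each $R_t$ and of $E$, and
(c) a normal update of $\mu$. The effect update diagonalizes $A_t$ once per
tree ($A_t = Q \Lambda Q'$) and, per iteration, solves the generalized
eigenproblem of the two $k \times k$ precisions ($W'E^{-1}W = I$,
$W'R_t^{-1}W = D$), after which all $n_t$ component draws are dense matrix
products. A sweep over 200 tips and $k = 4$ costs a few milliseconds, so the
sampler runs comfortably at the problem sizes used throughout (tens to a few
hundred tips, $k \le 8$).

* **Priors.** "Flat prior with belief $b$" maps to an inverse-Wishart with
  degree of belief $\nu = b \, k$ and scale $\nu V$, $V = I$ by default. The
  belief convention (fraction times trait dimension) is a documented choice —
  the phrase does not pin down a parameterization — and is configurable via
  `prior_spec()`. Defaults: 2% for parameterization chains, 5% for informed
  mini-chain priors.
* **Tree scaling.** Trees are rescaled to unit root-to-tip depth before
  covariances are built (`scale_height = TRUE`), so rate matrices are
  comparable across trees of a distribution; recovery tests simulate on
  unit-height trees for the same reason.
* **Inverse-Wishart draws** use `stats::rWishart` on the inverted scale; all
  returned samples are symmetrized, and the posterior degrees of freedom
  $\nu + n_t$ always exceed $k - 1$ because modeled clades must have more
  than `min_size` (default 15) members.
* **Likelihood trace.** The burn-in rule needs a "posterior likelihood"; the
  package uses the conditional log-likelihood of the traits given the current
  parameters, which is monotone-related to the deviance and cheap to track.

## The mini-chains protocol

`minichain_config()` defaults are the protocol's published operating point:
three parameterization chains of 50,000 generations, burn-in factor 1.1,
beliefs of 2% and 5%, 400 trees with 10 exploitable samples each, and an
effective-sample-size target of 200. Tests and the demo pipeline override the
*sizes* (chains of a few hundred generations, 5–20 trees) — the package's
choice of desk-scale problem sizes — while keeping every rule identical.

* **Burn-in** is $\lceil 1.1 \times \max_c(\text{first iteration at which
  chain } c \text{ reaches its own median log-likelihood}) \rceil$, computed
  with a $10^{-9}$ guard so that $1.1 \times 200$ is 220 and not 221 under
  floating point.
* **Informed priors** are the elementwise median posterior matrices pooled
  across parameterization chains, projected back onto the PSD cone by
  eigenvalue clipping (an elementwise median of PSD matrices need not be PSD).
* **Thinning** inside mini chains (`minichain_thin`) spreads the kept samples
  over the post-burn-in window evenly.
* **Effective sample size** is Geyer's initial monotone positive sequence
  estimator (autocovariance pair sums, first nonpositive cutoff, running
  minimum), capped at $n$. On white noise it sits within a few percent of
  $n$; on AR(1) with $\rho = 0.9$ near the analytic
  $n(1-\rho)/(1+\rho)$.
* **Seeding** is a counter-based splitter from one master seed, so per-chain
  streams do not depend on execution order and identical configs are
  bit-identical end to end.
* **Consensus tree**: rooted majority-rule topology; each retained clade's
  branch length is the mean over trees containing that clade; polytomies are
  resolved deterministically with zero-length edges.

## Projection/rejection scores

For a posterior sample $R$ of a reference term, the major axis has direction
$v_1(R)$ (sign fixed by forcing the largest-magnitude component positive; a
tied leading eigenvalue falls back to the lowest coordinate axis reachable in
the tied eigenspace, with a warning) and half-length
$\sqrt{\lambda_1 \, \chi^2_{k,0.95}}$. With $d$ the entity's offset from the
axis centre,

$$ \text{elaboration} = \frac{|\langle d, v_1\rangle|}{\text{half-length}},
   \qquad
   \text{innovation} = \frac{\lVert d - \langle d, v_1\rangle v_1 \rVert}
                            {\text{half-length}}, $$

so elaboration² + innovation² equals the squared scaled distance to the
centre, both scores are nonnegative, and values in $[0, 1]$ lie within the
95% extent of the rate matrix. Choices the literature leaves open, exposed as
arguments:

* **Centre.** A clade term's axis is anchored at the mean trait vector of its
  member species (the clade's position in the shape space); the class-wide
  axis at the grand mean. `centre = "origin"` is available.
* **Chi-square degrees of freedom.** $df = k$ (the full trait dimension) by
  default, treating the extent as a multivariate ellipsoid quantile;
  `df = 1` (a univariate extent along the axis) is the documented
  alternative. Both scores share one half-length so the $[0,1]$
  "nonexceptional" reading applies to both.
* **Clade scores** translate the child axis onto the parent's centre and
  project its endpoint, so a child identical to its parent scores (1, 0) and
  an orthogonal child of equal half-length scores (0, 1).

Scores are computed per posterior sample (never on a posterior-mean matrix)
and summarized as medians with 50% and 95% credible bounds.

## Orthogonality, overlap, correlations, signal, PGLS

* **Folded angles** between leading eigenvectors live in $[0°, 90°]$;
  orthogonality is angle/90. The posterior probability that a clade's
  orientation differs from its parent's is $P(\text{between-draw} >
  \text{within-draw})$, exhaustive when both angle sets are small (at most
  2500 pairs), matched random draws otherwise. Ties count for neither side;
  the distribution-overlap alternative was considered and rejected as further
  from a direct posterior-probability reading. Angles, not orthogonality
  values, enter the comparison (the map is monotone, so ranking is
  unaffected).
* **Bhattacharyya overlap** uses histogram masses on shared equal-width bins
  spanning the pooled range (default 100 bins): exact $[0,1]$ bounds, no
  bandwidth choice, and exact 1/0 endpoints for identical/disjoint samples.
  Scores are first scaled by their group maximum so species-level and
  clade-level densities are comparable despite different sample sizes.
* **Posterior correlations** between elaboration and innovation within a
  clade are computed per posterior sample (Pearson by default, Spearman
  optional) and classified: *clear* (95% CI excludes 0), *somewhat* (50% CI
  excludes 0), *none*. The calibration test endows each replicate's
  correlation posterior with Fisher-z sampling uncertainty around the
  observed correlation of independently simulated scores — a calibrated
  posterior — because a posterior whose samples are fresh independent score
  draws has near-certain, not 95%, coverage of zero; the construction feeds
  exact-correlation score sets end-to-end through the classifier.
* **Pagel's λ** is profiled by bounded search on $[0, 1]$ (tolerance
  $10^{-6}$) with the mean and rate eliminated analytically; endpoints are
  always evaluated, and a star tree (λ-independent likelihood) returns a
  flat-likelihood flag.
* **PGLS** fits GLS under $C(\lambda)$ (off-diagonal shared paths times λ)
  with exact ML log-likelihood; AIC counts coefficients, the rate, and λ when
  estimated. The 12-model suite uses a common λ (fixed at 1 by default, or
  the two-pass "minimum estimated λ" mode) so AIC comparison is meaningful;
  ΔAIC is reported as $AIC - AIC_{\min} \ge 0$ with exactly one zero.
  Predictors are per-species posterior medians, clade scores broadcast to
  member species; a standardization switch is deliberately absent from the
  default path (predictors enter on their natural $[0,1]$-anchored scale).

## The synthetic-data generator

`simulate_yule_tree()` (forward pure-birth, ultrametric),
`simulate_tree_set()` (lognormal branch-length jitter of a fixed topology —
topology is held so modeled clades stay monophyletic in every tree, as a
published tree distribution holds named clades), `carve_clades()` (seeded
randomized selection of nested disjoint monophyletic clades, failing loudly
when infeasible) and `simulate_traits()` (class-wide Brownian + per-clade
deviation Brownian + i.i.d. residual) generate data with exactly the model's
statistical structure, plus recorded ground truth for recovery tests.

What it emulates: an ordinated trait space (default $k = 8$ in spirit; tests
mostly use $k = 2$–4 for speed) evolving by nested multivariate Brownian
motion with clade-specific rate matrices and independent residual noise; a
Yule tree gives realistic nested clade sizes, and the inference never depends
on the tree prior. What it does not emulate: rate heterogeneity within
clades, non-ultrametric trees, fossil tips, selection regimes, or
landmark-level morphometric error. Passing recovery tests therefore show the
estimator is correct *under its own assumptions*, not that real shape spaces
satisfy them.

## Problem sizes and limitations

The test suite and demo pipeline run at desk scale by design: 20,000-draw
conjugate checks ($k=4$, $n=100$), rate-matrix recovery on 200 tips, mini
chains over 5–20 trees, a 64-tip/4-trait/3-clade demo pipeline. Published
headline numbers from museum-scale datasets (thousands of species, 1000-tree
distributions) are not reproducible at these sizes and are not targeted;
correctness is asserted against closed forms, planted structure, and
independent implementations (`nlme::gls` with a fixed-λ correlation,
`phytools::phylosig`) instead.

Known limitations: the class-wide term and the residual are unidentifiable on
a star tree (their sum is; the package's tests check exactly that); posterior
medians of matrices are PSD-projected before eigen-analysis; mini-chain
posteriors concatenate short chains, so per-entry ESS — reported against the
target — is the honest measure of their information content; and the PGLS
suite inherits the usual caveat that fixing λ trades bias for AIC
comparability.
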