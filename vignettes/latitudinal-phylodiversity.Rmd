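---
title: "Methods: latitudinal gradients in community phylogenetic diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latitudinal gradients in community phylogenetic diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latphylodiv)
```

## The problem

Species richness famously declines from the equator to the poles, but
richness says nothing about how *related* the coexisting species are. Two
communities of thirty species each can sit at opposite ends of the
relatedness spectrum: one a cluster of congeners assembled by environmental
filtering or recent in-situ diversification, the other a phylogenetically
scattered set drawing on many distant lineages. `latphylodiv` provides the
machinery to quantify that relatedness for large compilations of plant
community species lists and to model how it changes with latitude,
vegetation type, biogeographic realm, and sampling-unit size, with studies
as a grouping level.

The pipeline has five stages, each usable on its own:

1. **Names and grafting** — canonicalize species names against a local
   synonym table and attach species missing from the dated reference
   phylogeny inside their genus or family.
2. **Community filtering** — validate membership and covariate tables,
   reclassify vegetation labels, drop communities that are too small or mix
   growth forms.
3. **Diversity** — compute mpd and mntd per community, and their
   standardized effect sizes (SES) against richness-matched randomization
   nulls.
4. **Modelling** — fit a candidate set of linear mixed-effects models of
   SES against latitude and covariates, rank by AICc, refit the winner by
   REML, and report Wald tests and marginal/conditional R².
5. **Synthesis** — generate synthetic phylogenies and communities with
   known ground truth so that every stage above can be verified.

## Diversity indices and the null model

For a community of $n$ species with patristic distances $d_{ij}$ (sums of
branch lengths along tree paths),

$$\mathrm{mpd} = \binom{n}{2}^{-1} \sum_{i<j} d_{ij}, \qquad
  \mathrm{mntd} = \frac{1}{n}\sum_i \min_{j \ne i} d_{ij}.$$

mpd integrates relatedness over the whole tree depth; mntd only sees the
distance to each species' closest relative. Both depend strongly on
richness, so each observed value is standardized against a null
distribution obtained by assembling communities of the *same richness* by
uniform draws from the species pool:

$$\mathrm{SES} = \frac{\mathrm{obs} - \overline{\mathrm{null}}}{\mathrm{sd}(\mathrm{null})}.$$

Negative SES means the community is more clustered on the phylogeny than a
random assemblage of equal richness; positive SES means overdispersion.

Choices that the definition above leaves open, fixed as follows:

* **Null model.** Uniform sampling of richness-matched tip sets from the
  stratum pool. For presence/absence data this is equivalent to shuffling
  tip labels. It is the minimal model satisfying "random assembly at equal
  richness"; no attempt is made to preserve occupancy frequencies.
* **Pool.** The union of species observed across the stratum's communities
  — i.e. the tips of the stratum tree after pruning. A per-study pool can
  be emulated by running `ses_table()` per study.
* **Randomizations.** Default 999, the conventional default of this tool
  family. An exhaustive mode enumerates every richness-subset when
  $\binom{|\text{pool}|}{n}$ is below a threshold; it defines exactly what
  the sampled mode estimates and is used throughout the tests.
* **Standard deviation.** The sample ($n-1$) standard deviation of the
  null draws.
* **Degenerate nulls.** When the null has zero spread (e.g. the community
  equals the pool), SES is undefined; the row is flagged and excluded from
  modelling.
* **Seeds.** Each community's null draws are seeded by hashing the master
  seed with the community id, so results are independent of community
  order and reproducible community-by-community. One subset draw serves
  both metrics, which halves the work without coupling the two SES values
  beyond their shared null communities.

## Grafting missing species

Reference megaphylogenies never contain every name in a community
compilation. Missing species are attached *within taxa of known branch
lengths*:

* genus present with $\ge 2$ sampled species → attach at the genus crown
  (the MRCA of the congeners) with a pendant branch equal to the crown's
  age, forming polytomies when several species attach at one node;
* genus present with exactly one sampled species → the congener's pendant
  edge is split at half its depth (configurable fraction) to create a
  genus crown, and the new tip attaches there;
* genus absent, family present → the same rules at the family crown;
* neither present → the taxon is reported unplaceable and dropped, with
  the community re-checked against the minimum-richness rule.

The half-depth rule for lone congeners is a declared convention (the
mid-point binding common in practice), not an inference about any
particular published pipeline: nothing in the crown-attachment idea fixes
that depth. All grafting preserves the distances among pre-existing tips
exactly and keeps ultrametric trees ultrametric — both properties are
enforced by randomized tests.

Node-age interpolation (`interpolate_node_ages()`) implements the
BLADJ-style rule: an undated node takes its age from linear interpolation
between its nearest dated ancestor and its nearest dated descendant
(fewest intervening edges, ties broken by the first found), spacing the
undated nodes on the path evenly. Tips default to age zero and the root
age must be fixed.

## The model set

For each response (SES~mpd~ or SES~mntd~) and growth-form stratum, four
candidate models are fitted, all containing latitude, latitude², and
log₁₀ sampling-unit size, and differing in the categorical terms:
none, realm, vegetation, realm + vegetation. No interactions. Each model
is

$$y_{gi} = \mathbf{x}_{gi}^\top\beta + b_g + \varepsilon_{gi}, \qquad
  b_g \sim N(0, \sigma^2_{\text{study}}),$$

with an optional exponential spatial correlation within studies,
$\mathrm{cor}(\varepsilon_{gi}, \varepsilon_{gj}) = \exp(-d_{ij}/\rho)$
with $d_{ij}$ the great-circle distance in km (no nugget).

The marginal likelihood is implemented directly in the package
(`lmm_loglik()`): the covariance of study $g$ is
$V_g = \sigma^2_{\text{study}} J + \sigma^2_{\text{resid}} R_g$,
assembled and factorized per block. The REML criterion adds the usual
$-\tfrac12 \log|X^\top V^{-1} X|$ correction and drops the fixed-effect
dimensions from the constant. `fit_lmm()` profiles $\beta$ and the
residual variance analytically and optimizes only the log variance ratio
(and log $\rho$ when spatial correlation is on) by bounded quasi-Newton
from three starting points. The test suite verifies the likelihood against
a dense multivariate-normal computation and the whole fit against an
independent mixed-model implementation.

Conventions that the standard formulas leave open:

* **Standardization.** Continuous predictors are centred and scaled by the
  sample ($n-1$) standard deviation. Latitude² is the square of the
  *standardized* latitude and is not itself re-standardized, keeping the
  linear/quadratic pair interpretable on one scale.
* **Signed vs absolute latitude.** Both hemispheres are represented in the
  kind of data this pipeline targets, and a quadratic in signed latitude
  accommodates them symmetrically; signed is the default, with
  `abs_latitude = TRUE` available wherever latitude enters. The end-to-end
  recovery analyses in the tests use absolute latitude because the
  generating gradient is symmetric about the equator there.
* **AICc.** $-2\ell + 2k + 2k(k+1)/(n-k-1)$ with $n$ the number of
  communities and $k$ counting every estimated parameter: fixed
  coefficients, both variance components, and $\rho$ when present.
  Candidates whose $k$ the sample cannot support ($n \le k+1$) are
  dropped with a warning; non-converged candidates are excluded from the
  Akaike-weight normalization.
* **R².** Marginal $= \sigma^2_f / (\sigma^2_f + \sigma^2_{\text{study}} +
  \sigma^2_{\text{resid}})$ and conditional $= (\sigma^2_f +
  \sigma^2_{\text{study}}) / (\cdot)$, with $\sigma^2_f$ the variance of
  the fitted fixed-effect predictor.
* **Degrees of freedom.** Wald tests use denominator df
  $n - \mathrm{rank}(X) - (\text{number of studies}) + 1$, a declared
  grouped-data convention (`df_resid` is overridable). Different software
  families resolve this differently; the choice is documented rather than
  hidden.

## The synthetic-data generator

`assemble_communities()` inverts the pattern the analysis is meant to
detect. Each community grows from a uniformly drawn focal tip; the other
members are drawn without replacement with probability
$\propto \exp(-d(\text{focal}, \cdot)/\tau)$. Small $\tau$ confines the
community to the focal clade (strongly negative SES); $\tau \to \infty$
recovers uniform assembly (SES calibrated around zero — verified by the
calibration test). $\tau$ is expressed as a multiple of the pool's median
pairwise distance and interpolated log-linearly in $|$latitude$|$ between
its equatorial and polar values, so either an equatorward or a poleward
clustering gradient (or none) can be generated.

Defaults were chosen once to emulate the shape of a global community
compilation: 40 studies × 10 communities, richness 5–25, latitudes
spanning 55°S–61°N, six realms (one per study — realms are contiguous
regions), three vegetation classes with weights 0.4/0.4/0.2, sampling
units spanning 1 m² to 1 km², and $\tau$ ranging from 0.1 (equator) to 2
(poles) median-distances under the equatorward-clustering profile.
Synthetic temperature and precipitation covariates decline monotonically
with $|$latitude$|$ so the Pearson collinearity screen has the signal it
exists to detect.

What the generator deliberately does *not* emulate: occupancy-frequency
structure (all tips are equally available), realistic biogeography (realms
are labels, not geometry), trait-based assembly, or abundances (the
pipeline is presence/absence throughout). Passing tests therefore certify
the statistical machinery — not that any particular empirical dataset
will show a given gradient.

One consequence of per-study realm assignment matters for validation
design: a covariate that is constant within studies competes with the
study random intercept, and model selection will legitimately spend extra
parameters on it when it soaks up between-study variance. The
model-recovery simulations therefore draw realm independently per
community, isolating the selection machinery from that confounding; the
end-to-end fixtures keep the realistic per-study realms.

## Numerical choices and degenerate inputs

* Branch lengths of zero are legal everywhere (grafting can require them);
  negative or missing lengths are rejected at parse time.
* Ultrametricity is judged on the relative spread of root-to-tip depths
  with default tolerance 10⁻⁶.
* Polytomies are first-class; nothing ever forces binary resolution.
* Duplicate (community, species) rows collapse with a warning; duplicate
  tip labels are an error.
* Variance parameters are optimized on the log scale with bounds
  $e^{\pm 20}$; a variance ratio at the lower bound reproduces ordinary
  least squares to optimizer precision.
* Zero-variance predictors, empty designs, rank-deficient designs, and
  single-level factors raise immediate, named errors.

## Problem sizes used in validation

The test suite exercises: the distance oracle on 100 random trees of up to
12 tips; exhaustive nulls on pools up to 12 tips; SES calibration with 200
communities of richness 8 on a 64-tip pool at 999 randomizations;
parameter recovery over 100 simulated datasets of 25 studies × 20
communities; model recovery over 100 replicates at n = 400; and end-to-end
gradient recovery on 500-tip, 400-community fixtures in both gradient
directions. These sizes were chosen as the smallest at which the
Monte-Carlo error of each check is comfortably below the property being
asserted.

## Known limitations

* The null model ignores occupancy frequency; SES values from this null
  are not comparable to nulls that preserve species' prevalence.
* Family-level grafting requires a genus→family map (or per-taxon family
  records); without one, unknown genera are unplaceable.
* The spatial correlation has no nugget term, and spatial and
  study-intercept structure are additive — confounded when studies are
  spatially compact.
* AICc uses the community count as $n$; if communities within studies are
  strongly dependent this overstates the effective sample size, as it
  does in every comparable pipeline.
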