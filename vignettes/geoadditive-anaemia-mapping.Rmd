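---
title: "Methods: Bayesian geoadditive mapping of childhood anaemia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian geoadditive mapping of childhood anaemia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`geoanaemia` fits a hierarchical Bayesian geoadditive logistic regression for
a binary child-health outcome — anaemia, defined by the WHO rule as
altitude-adjusted haemoglobin strictly below 11 g/dL for children aged 6–59
months — observed in a stratified two-stage cluster survey. For child $k$ in
household $j$, cluster $i$ and district $h$,
$Y_{hijk} \sim \mathrm{Bernoulli}(\pi_{hijk})$ with

$$
\mathrm{logit}(\pi_{hijk}) =
  \mathbf{x}'_{hijk}\boldsymbol\beta
  + f_{\text{age}}(\mathrm{age}_{hijk})
  + f_{\text{str}}(s_h) + f_{\text{unstr}}(s_h).
$$

The three parts of the predictor are:

* **Linear fixed effects** $\boldsymbol\beta$ of dummy-coded categorical
  covariates (gender, malaria RDT result, residence, mother's education,
  gender of household head, toilet facility, with the references male /
  negative / urban / no education / male / no facilities) and of continuous
  covariates entered per unit and unstandardised (household size, wealth
  index, cluster altitude in 100 m units, EVI, LST), so that
  $\exp(\beta)$ is directly the adjusted odds ratio (AOR) per level or unit.
* **A P-spline smooth of age.** $f_{\text{age}}(z) = \sum_m \alpha_m B_m(z)$
  with cubic B-splines on equally spaced knots and a random-walk prior on the
  coefficients. The prior density is the improper Gaussian
  $\propto \exp(-\tfrac{\tau^2_r}{2}\,\boldsymbol\alpha' K \boldsymbol\alpha)$
  with $K = D_d'D_d$, $D_d$ the $d$-th difference operator. Second-order
  differences (RW2) and degree-3 splines are the defaults; RW1 is available.
* **A BYM-type spatial effect** per district, split into a structured
  component with an intrinsic CAR (ICAR) prior — each district's effect,
  given the rest, is Gaussian around the mean of its neighbours with
  precision $n_h \tau^2_{\text{str}}$, neighbours being districts that share
  a boundary (rook rule) — and an unstructured iid Gaussian component with
  precision $\tau^2_{\text{unstr}}$, capturing district-specific
  heterogeneity that does not transcend boundaries.

Priors: $N(0, 1000)$ (precision 0.001) on every fixed effect including the
intercept; Gamma$(a, b)$ with $a = 1$, $b = 0.001$ on each precision
$\tau^2$ (the log-gamma convention on the log-precision scale). Sum-to-zero
constraints identify the intercept against the smooth (centred over the
observed ages), the structured effect (per connected component of the
adjacency graph) and the unstructured effect (overall).

Three nested model classes mirror the usual model-building sequence:
`m1` (GLM, all covariates linear, including age), `m2` (GAM, age as a
smooth), `m3` (geoadditive, adding the spatial effects). They are compared
by the Deviance Information Criterion, $\mathrm{DIC} = \bar D + p_D$ with
$p_D = \bar D - D(\bar\theta)$; the plug-in deviance uses the posterior mean
of all latent quantities on the linear-predictor scale, the standard
convention. A negative $p_D$ raises a warning rather than an error.

## Posterior computation

Inference is fully Bayesian via a Pólya-Gamma data-augmentation Gibbs
sampler, implemented in compiled code:

1. **Augmentation.** Each observation receives
   $\omega_i \sim \mathrm{PG}(1, \eta_i)$, drawn exactly with the Devroye
   alternating-series rejection sampler. Given $\boldsymbol\omega$, the
   logistic likelihood is conditionally Gaussian with working response
   $\kappa_i = y_i - 1/2$.
2. **Joint latent block.** All fixed effects, spline coefficients and both
   spatial components are drawn in one block from their conditionally
   Gaussian law with precision $X'\Omega X + P(\boldsymbol\tau^2)$. The
   district blocks enter through sparse incidence structure, so the per-sweep
   cost is dominated by the dense fixed + spline cross-product rather than by
   the district count.
3. **Constraints.** The sum-to-zero constraints $A\theta = 0$ are imposed
   exactly by conditioning the Gaussian draw on the constraints
   (conditioning by kriging): draw unconstrained, then subtract
   $C^{-1}A'(AC^{-1}A')^{-1}A\theta$. This is exact Gibbs for the
   constrained target and — unlike centring each block and absorbing the
   shift into the intercept — remains likelihood-preserving when the
   adjacency graph has several connected components, where a single
   intercept cannot absorb per-component shifts. Every stored draw satisfies
   the constraints to machine precision. Because the improper RW/ICAR priors
   leave the joint precision exactly singular along directions that the
   constraints remove, $\lambda A'A$ (with $\lambda = n$) is added before
   factorisation; on the constraint manifold this changes nothing, so the
   constrained draws stay exact while the Cholesky factorisation is well
   conditioned.
4. **Precisions.** Each $\tau^2$ has a conjugate full conditional
   Gamma$(a + r/2,\; b + q/2)$ where $q$ is the prior quadratic form and $r$
   the rank of the prior precision *restricted to the constrained subspace*:
   $M - d$ for a RW$d$ smooth with $M$ basis functions, $n - c$ for the ICAR
   over $n$ districts in $c$ components, and $n - 1$ for the sum-to-zero
   unstructured block. Using $n$ rather than $n - 1$ for the unstructured
   block introduces a spurious $\tau^{1/2}$ factor that measurably biases
   the spatial decomposition toward collapsing the unstructured component.
5. **Mode-swap move.** The BYM decomposition is weakly identified: the
   likelihood sees only $f_{\text{str}} + f_{\text{unstr}}$, and a plain
   Gibbs chain can be trapped in the minor posterior mode in which the ICAR
   slot absorbs an iid district pattern. Each sweep therefore proposes
   exchanging the two vectors while redrawing both precisions from their
   conjugate conditionals; the Gamma proposal densities cancel against the
   target, leaving the closed-form Metropolis ratio
   $$
   \alpha = \frac{(b + q^{Q}_{\text{str}}/2)^{a + r/2}\,
                  (b + q^{I}_{\text{unstr}}/2)^{a + (n-1)/2}}
                 {(b + q^{Q}_{\text{unstr}}/2)^{a + r/2}\,
                  (b + q^{I}_{\text{str}}/2)^{a + (n-1)/2}},
   $$
   with $q^{Q}$ and $q^{I}$ the ICAR and identity quadratic forms of the
   current structured/unstructured vectors. The move leaves the likelihood
   and the constraints invariant and is skipped for graphs with more than
   one connected component, where the swapped unstructured vector need not
   satisfy the per-component constraints of the structured slot.

Chains are deterministic functions of the configured seed; multiple chains
(seeds `seed + chain - 1`) are pooled. Defaults
(`mcmc_config()`: 4,000 sweeps, 1,000 burn-in, thin 2) suit the package's
standard problem size; the package's own validation studies use 600–1,600
sweeps per fit at $n \approx 7{,}800$, where one sweep costs a few
milliseconds, and 50,000 kept draws for the small-instance quadrature
comparison.

## The synthetic survey generator

The real surveys behind analyses of this kind (DHS/MIS) are access
restricted, so the package carries a generator that is simply the model run
forwards over a two-stage cluster design: districts on a rook grid (or
ring), clusters nested in districts, households in clusters, children aged
6–59 months (uniform) in households. Covariates are drawn at their natural
hierarchy level; survey weights are the inverse of a synthetic cluster
selection probability, constant within cluster, and are used only by the
weighted-prevalence descriptives — the model likelihood is unweighted, as is
standard for these analyses.

Default conditions (chosen once, as the package's study conditions):

* 60 districts × 4 clusters × 25 households × mean 1.3 children
  ($n \approx 7{,}800$) — large enough that district effects and the age
  smooth are well identified, small enough that a full three-model
  comparison runs in well under a minute;
* true coefficients equal to the log AORs a multi-country anaemia analysis
  reports (malaria positive $\log 4.401$, female $\log 0.873$, wealth
  $\log 0.858$ per unit, altitude $\log 0.974$ per 100 m, …);
* $\tau^2_{\text{str}} = 853.58$, $\tau^2_{\text{unstr}} = 3.84$: a nearly
  flat structured surface and strong district-specific heterogeneity
  (unstructured standard deviation $\approx 0.5$ on the log-odds scale);
* an age curve rising from 6 months to a peak of about $+0.5$ log-odds at
  10 months and declining thereafter, centred on the integer age grid — the
  well-documented pattern attributed to depletion of neonatal iron stores;
* intercept 0.17, giving a marginal prevalence near 54%;
* EVI on a 0–10 scale and LST in °C, so that near-1 per-unit odds ratios
  are meaningful (published analyses do not state their rescaling);
* category probabilities for gender, malaria, residence, education, head
  gender and toilet type set to field-plausible values — published tables do
  not include the full covariate distributions, so these are stand-ins.

ICAR truth is drawn in the positive-eigenvalue subspace of $Q$
(`generate_spatial_effects()`), which makes each connected component sum to
zero exactly and handles the improperness of the ICAR density; isolated
districts get a structured effect of exactly zero.

What the generator deliberately does **not** emulate: non-response and
post-stratification, country-realistic joint covariate distributions,
household- or cluster-level random effects in the outcome (the fitted model
has none either), spatial structure in covariates, or measurement error in
haemoglobin. Passing recovery tests on these data therefore shows that the
estimator is correct *for its own model class at survey scale* — not that
the model is adequate for any particular country's data. The optional
synthetic haemoglobin values exist only to exercise the 11 g/dL
classification rule and are generated consistently with the Bernoulli
outcome, which is the generative truth.

## Pre-modelling pipeline

`classify_anaemia()` applies the strict `hb < 11` rule.
`weighted_prevalence()` estimates $100\sum w_iy_i / \sum w_i$ with a
logit-scale Wald interval at the effective sample size
$(\sum w)^2/\sum w^2$; this is bounded inside $(0, 100)$, reduces exactly to
the unweighted proportion under constant weights, and is invariant to weight
rescaling. Exact one-sided bounds replace the Wald interval at boundary
estimates. A full Taylor-linearised survey variance is out of scope.
`univariate_screen()` uses a likelihood-ratio test of each covariate alone
against the intercept-only model — a single well-defined test also for
multi-level factors — with inclusion at the 10% level; complete separation
is flagged and the covariate kept with a warning. `vif_table()` computes
$1/(1-R^2)$ over the continuous covariates only, flagging values at or
above 4.

## Reporting conventions

Credible intervals are 95% equal-tailed (percentiles of the draws), the
default convention of the software this analysis style comes from. The AOR
point estimate is the posterior mean of $\exp(\beta)$ (configurable to
$\exp$ of the posterior mean). Significance stars mean the interval excludes
1 (odds ratios) or 0 (effects) at the 5% level. Variance-component tables
report precisions; between the two spatial components the one with the
*lower* precision (larger variance) is reported as dominant. District
summaries classify each district as significantly positive / negative /
null per component, with class counts and the range of posterior means;
they export to CSV always and to GeoJSON when district polygons are
supplied, flagging polygons without data.

## Numerical choices and edge cases

* 20 cubic basis functions (17 interior intervals) for the age smooth by
  default: standard P-spline practice of a generous basis with the penalty
  controlling effective smoothness; the knot count used in published fits
  of this kind is typically unstated, so smooth-term results are comparable
  in shape, not in knot-level detail.
* Clamped (repeated) boundary knots make the basis well defined at both
  endpoints; evaluation outside the knot span is an error, never
  extrapolation.
* Rook contiguity (shared edge, not corner) operationalises "share a common
  boundary", both on generated grids and for GeoJSON polygons, where shared
  boundaries are detected as collinear segment overlaps of positive length.
* Isolated districts: structured effect pinned at 0 (the ICAR conditional
  is undefined at degree 0), unstructured effect still estimated.
* Missing covariate values: rows dropped with a message; no imputation.
* Complete separation: the sampler aborts with a diagnostic if the linear
  predictor becomes non-finite; screening flags separation and keeps the
  covariate.
* `pD < 0` warns; DIC identities hold exactly by construction.
* Model comparison refuses fits whose stored row count or outcome checksum
  differ.

## Known limitations

* The spatial decomposition is reported on the natural BYM scale; no
  scaled-BYM2 reparameterisation is offered.
* The likelihood ignores the survey design (no weights, no cluster random
  effects), matching the analysis style it implements; design-based
  variance estimation is out of scope.
* GeoJSON contiguity assumes coordinates of neighbouring polygons match
  along shared boundaries to within a small tolerance, as in clean
  administrative boundary files; heavily simplified or mismatched geometry
  may need a pre-snapped input.
* DIC values depend on the data at hand; only the model ordering, not the
  magnitude, is comparable across data sets of different size.
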