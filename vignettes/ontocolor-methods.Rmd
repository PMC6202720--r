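---
title: "Models and methods behind ontocolor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ontocolor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontocolor)
```

# The scientific problem

Many insects switch colour-defense strategy as they develop: a caterpillar
that masquerades as a bird dropping while small may become cryptic or
aposematic once it is large enough that masquerade no longer works.
`ontocolor` packages the comparative machinery needed to study such
*ontogenic colour change* across a radiation: it scores how strongly each
lifestage contrasts with its visual background, classifies the strategy
(masquerade, crypsis, aposematism), reconstructs how the strategies evolved
along a phylogeny, and asks whether host-plant chemistry and vegetation
structure predict the phenotype once shared ancestry is accounted for.

The package operates on three inputs: per-lifestage colour compositions
(palettes with relative proportions, either supplied as tables or extracted
from cut-out PNG images), a rooted phylogeny with branch lengths, and a
species table of host and distribution characters. A seeded generator
produces all three with known ground truth, so every stage of the pipeline is
testable without any external data.

# Colour quantification

## Palette extraction

`extract_color_gamut()` quantizes an image region into at most `max_colors`
palette entries by k-means in raw RGB space (default `k = 8`), merging
clusters below 1% into their nearest centroid. Pixels are canonically sorted
before clustering so the result cannot depend on pixel order, and the seed
fixes the k-means initialisation, making extraction fully reproducible.
Fully transparent pixels are treated as the cut-out mask and excluded, which
is how background-separated lifestage photographs are handled.

We work in raw RGB deliberately: the method is a coarse, robust contrast
score for heterogeneous field photographs, not a model of predator vision.
Perceptual spaces (CIELAB, receptor-noise models) are out of scope.

## Dominant colours and delta RGB

The *dominant colour* of a region is its largest palette entry, required to
exceed 25% of the region (configurable); if no colour passes, the image
cannot be scored and an error is raised. Ties are broken by the
lexicographically smallest RGB triplet so the rule is deterministic.

The contrast statistic is **delta RGB**: the per-channel absolute difference
between the dominant colour of the background and that of the lifestage,

$$\Delta RGB = (|R_b - R_l|,\; |G_b - G_l|,\; |B_b - B_l|).$$

Absolute values are used because conspicuousness is a magnitude; signed
differences would conflate the direction of the difference with its size.
Delta RGB is symmetric in its arguments, zero iff the dominant colours agree,
and bounded by (255, 255, 255).

## Apparency and background-matching statistics

`apparency_test()` runs a PCA on the three delta channels — centred but not
rescaled, because the channels share the 0–255 unit — and compares PC1
between apparent (masquerade + aposematism) and nonapparent (crypsis)
species with a two-sided Mann–Whitney test. PCA component signs are
arbitrary, so each component is oriented to have a positive loading sum;
since every channel measures contrast positively, PC1 then increases with
conspicuousness and the W statistic has a stable interpretation across
datasets (apparent species rank high). The reported `W` is the U
statistic of the apparent group (rank sum minus its minimum), the convention
of R's `wilcox.test`; exact p-values are used for small untied samples and
the tie-corrected normal approximation otherwise. `pupa_match_test()`
compares pupal and background channels with per-channel two-group
Kruskal–Wallis tests; the per-channel structure is one of two readings of an
ambiguous design and is the one consistent with reporting a p-value per
channel. No multiple-testing correction is applied across lifestages or
channels; p-values are reported raw.

## Strategy classification

`classify_strategy()` operationalises the verbal decision rule:

* **crypsis** — the Euclidean norm of delta RGB falls below the apparency
  threshold (default 60 on the 0–255 scale);
* **masquerade** — apparent, but every palette colour is a shade of white or
  gray: channel spread at most 30 and mean channel at least 100 (both
  configurable), optionally extended by proximity to a supplied reference
  palette such as a bird-dropping image;
* **aposematism** — apparent with any non-gray colour (in practice dark
  bases with red/yellow warning colours).

The apparency threshold has no empirical analogue — field classifications
combine natural history with the PC1 statistics — so it is exposed in the
configuration; 60 cleanly separates the generator's cryptic jitter
(norm ≤ √3·10 ≈ 17) from its apparent scenes (norm ≳ 100). Masquerade and
aposematism can only be emitted for apparent inputs, matching the
apparent/nonapparent binarization used downstream.

# Character evolution

## Mk likelihood

Discrete strategies evolve under the Mk model: a continuous-time Markov
chain with rate matrix $Q$ (ER: one rate; SYM: one per unordered pair;
ARD: one per ordered pair). `mk_loglik()` implements the pruning algorithm:
partial likelihoods are propagated from the tips with per-branch transition
matrices $P(t) = e^{Qt}$ and per-node rescaling to avoid underflow.
Transition matrices come from a single eigendecomposition of $Q$ when the
eigenvector basis is well conditioned and from `Matrix::expm` otherwise;
rows are clamped and renormalised against round-off. Zero-length branches
(including those created when polytomies are resolved) contribute identity
transition matrices, which is why the likelihood is invariant to the
resolution order.

`fit_mk()` maximises the likelihood on the log-rate scale (Brent search for
ER, L-BFGS-B for SYM/ARD) from the documented start of `k / total tree
length`. ER is the default model class: with three states on a ~60-tip tree
richer classes are weakly identified, and a single symmetric rate is the
conventional choice. An invariant character drives the rate to the lower
search bound (1e-9) with a boundary warning. The root prior defaults to
equal state probabilities, with stationary, data-estimated, and
user-supplied options.

## Stochastic character mapping

`sample_maps()` draws complete character histories conditional on the tips:
node states are sampled pre-order from their conditional distributions
(using the pruning partials), then each branch history is sampled
conditional on its endpoints by rejection: simulate the chain forward and
keep paths that hit the required end state, conditioning on at least one
change (first event time from a truncated exponential) when the endpoints
differ. Rejection was chosen over uniformization for transparency; a
per-branch attempt cap (default $10^6$) turns pathological cases (huge
rate–length products) into an informative error rather than a hang.

The default of 2000 maps is the point at which node-state frequencies of a
variable character stabilise. `node_state_summary()` gives the per-node
empirical state frequencies (the "pie chart" values) and converges to
`marginal_ancestral()`, which computes the analytic marginals by a second,
pre-order pass; both are provided because summaries of mapped histories and
analytic marginals are both in common use.

`count_origins()` counts, per map, transitions into a target state; a root
already in the state counts as one origin by default, because the question
is how many times the state was gained independently (a flag disables
this). Note a structural limit validated in the tests: stochastic maps are
conditioned on tip data, so gains in the true history that leave no tip
descendants are invisible to them. On synthetic data the modal origin count
therefore tracks, but can undershoot by 1–2, the generator's full event
count; exact recovery holds when the seeded gains are tip-visible (the
irreversible-gain test).

# Phylogenetic logistic regression

Because discrete phylogenetic regression handles binary responses, the
3-state phenotype is collapsed to *apparent* (masquerade, aposematism) vs
*nonapparent* (crypsis). The model is the evolving-binary-trait logistic
model: tip $i$ has $\Pr(y_i = 1) = \mathrm{logit}^{-1}(x_i'\beta)$, and
shared ancestry induces correlation that decays with patristic distance
$d_{ij}$ as $\exp(-\alpha d_{ij})$, where $\alpha > 0$ is the phylogenetic
signal parameter (small $\alpha$: strong signal; large $\alpha$: the trait
forgets its history).

Estimation, `fit_phyloglm()`:

1. given $\alpha$, solve the Firth-penalized estimating equations
   $X^\top D V^{-1}(y - p) + a(\beta) = 0$ with working covariance
   $V = D^{1/2} R(\alpha) D^{1/2}$, $D = \mathrm{diag}(p_i(1-p_i))$ and
   $a_r = \tfrac12\,\mathrm{tr}(I^{-1}\partial I/\partial\beta_r)$,
   $I = X^\top D V^{-1} D X$, by damped Newton iteration warm-started from
   the independence (ordinary Firth) solution;
2. given $\beta$, choose $\alpha$ on its bounded range (default
   $[10^{-7}, 50]$ divided by tree height) by maximising the Gaussian
   pseudo-likelihood of the standardized residuals under $R(\alpha)$ (a
   REML-style restriction term was evaluated and rejected: on degenerate
   distance structures such as star trees it invents correlation in iid
   data and biases the intercept);
3. alternate to convergence. Standard errors come from the information
   $I$ at the optimum; z-scores are coefficient/SE with two-sided normal
   p-values.

Estimating $\alpha$ from *residuals* rather than from the marginal response
is deliberate: when the response tracks a clade-structured predictor, its
marginal phylogenetic signal is high even though, conditional on the
predictor, little signal remains. A marginal estimator (e.g. the
exact-likelihood switching rate of $y$ itself) is better calibrated under
the null but attributes genuinely host-driven variation to phylogeny and
loses most of its power exactly where the biological signal is strongest;
the residual-based joint estimator trades a small amount of null
calibration for that power. Both behaviours were measured on seeded
simulations and the trade-off is fundamental: with a single realized
phylogeny, the evidence separating "predictor effect" from "shared
ancestry" resides in the minority of tips whose response mismatches their
clade, and no estimator can be simultaneously exactly calibrated and fully
powered at comparative sample sizes.

Two properties anchor this design. With $R = I$ the penalized equations
reduce *exactly* to Firth logistic regression (the adjustment term becomes
Firth's classic leverage correction), so on a star phylogeny — no shared
history — the fit agrees with an ordinary penalized logistic fit; this is
verified against an independent numerical oracle. And the Firth penalty
keeps estimates finite under complete separation, which matters here because
strongly host-structured phenotypes are near-separable. Calibration under
tree-structured null data is only asymptotic; seeded simulations in the
test suite document a type-I error of roughly 7–11% at the nominal 5% level
(an unpenalized, phylogeny-free logistic test measures ~21% on the same
draws, and a test with the generating $\alpha$ known ~6%).

`predictor_correlation()` applies the same model to test association between
two binary characters (here host toxicity and vegetation density) and also
reports their ordinary squared correlation as a descriptive summary. When
two predictors are this strongly associated (r² near 0.9), only one should
enter the regression; the pipeline uses vegetation. The 3-level distribution
label (temperate/tropical/both) is encoded tropical-vs-not with "both"
counted as tropical; this is one documented choice among several
defensible ones and is configurable upstream of the model call.

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated; its defaults are fixed once and are not tuned to tests:

* **Tree** — birth–death (birth 1.0, death 0.3 per lineage), conditioned on
  63 tips, rescaled to height 1. Sixty-three matches the representative-tip
  scale of the motivating radiation; moderate extinction gives realistic
  branch-length heterogeneity.
* **Host toxicity** — symmetric 2-state Markov character at rate 0.25 per
  unit height, so host shifts are clade-structured and number a handful per
  tree; histories are redrawn until each host type covers ≥ 15% of tips,
  emulating a radiation where both host classes are well represented (a
  regression needs both levels present).
* **Vegetation density** — copies toxicity (toxic = sparse) and is flipped
  per tip with probability $(1 - c)/2$, $c$ = `host_correlation` (default
  0.9), giving expected tip concordance 0.95 and correlation ≈ 0.9. (The
  target is the correlation, not the squared correlation; at these values
  r² ≈ 0.81–0.9 depending on tip-state balance.)
* **Distribution** — a Brownian latitude-like value thresholded at ±0.5
  into temperate / both / tropical.
* **Phenotypes** — toxic-host tips are aposematic at both instar stages,
  nontoxic-host tips masquerade early and are cryptic late, each with
  probability $1-\varepsilon$ (default $\varepsilon = 0.05$); exceptions
  switch apparency (apparent → crypsis, crypsis → aposematism), the
  direction real exceptions take. All pupae are cryptic.
* **Scenes** — green-dominated backgrounds; cryptic foregrounds within ±10
  per channel of the background dominant, masquerading foregrounds
  white/gray (spread ≤ 20, mean ≥ 150), aposematic foregrounds dark with
  red/yellow secondaries. Dominant proportions always exceed 0.25 and the
  classifier recovers the generating strategy at the default thresholds.

What the generator does **not** emulate: lighting and camera variation,
within-species polymorphism, non-green backgrounds (soil, bark) beyond the
palette families above, gradual (non-threshold) host effects, and
state-dependent diversification. Passing recovery tests therefore shows the
pipeline is correct under its stated model, not that the thresholds are
optimal for arbitrary field imagery.

# Numerical choices and problem sizes

Determinism: every stochastic routine accepts a seed, saves and restores the
caller's RNG state, and is byte-reproducible under a fixed seed. Matrix
exponentials fall back from eigendecomposition to `Matrix::expm` when the
eigenbasis condition number exceeds 1e8. Likelihood underflow is prevented
by per-node rescaling. Rate optimisation is bounded to
$[10^{-9}, 10^4/\text{tree length}]$ on the log scale. The phyloglm
correlation matrix receives a 1e-9 ridge before Cholesky factorisation.

The validation suite sizes were chosen to give tight Monte-Carlo bounds at
interactive run times: exhaustive-enumeration checks on 200 random trees of
up to 6 tips; 2000 stochastic maps against analytic marginals on a 20-tip
tree; 50 rate-recovery replicates on 200-tip trees; 50–100 replicates for
the regression power and calibration checks; 50 end-to-end replicates at
the default 63-tip conditions.

# Known limitations

* Raw RGB contrast ignores predator visual systems and luminance/chromatic
  separation.
* The Mk machinery assumes the tree is known without error; uncertainty in
  the phylogeny is not propagated.
* No hidden-rate or correlated-evolution (dependent-character) models.
* The MPLE working covariance is the exponential-decay approximation to the
  evolving-binary-trait process; its z-tests are asymptotically, not
  exactly, calibrated — a caveat shared by this model family generally.
* Origin counts are estimates of tip-visible history (see above).
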