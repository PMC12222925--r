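---
title: "Inferring the order of environmental and pollinator shifts: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the order of environmental and pollinator shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pollshift)
```

This vignette is the package's account of its science: what is being
modelled, which knobs matter, what the synthetic data do and do not emulate,
and where a genuinely open design choice was settled and why. Nothing here
reports an empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## The inference problem

Two binary facts about a lineage — "has it left the ancestral environment?"
and "has it left the ancestral pollination system?" — each evolve along a
dated phylogeny. If environmental change destabilizes the ancestral
plant–pollinator interaction, environment shifts should be reconstructed at
older nodes than pollinator shifts; if pollinator shifts license range
expansion, the reverse; if the two change together, neither should lead.
The package turns that verbal expectation into a classifier on ancestral
state reconstructions.

The observable characters are richer than binary: a four-state pollination
syndrome (`bee`, `generalist`, `nectar_vertebrate`, `foodbody_vertebrate`;
bee is ancestral in buzz-pollinated groups) and a four-bin elevation
category (E1 <500 m, E2 500–1000 m, E3 1000–1500 m, E4 ≥1500 m, left-closed
on every boundary). Reconstruction runs on the multi-state characters;
binarization happens only when probabilities are read off:
x = 1 − P(bee), and y = the summed probability of the bins above a cutoff
(500, 1000 or 1500 m). Running all three cutoffs is itself part of the
method — the binarization of a continuous niche axis is arbitrary, and
cutoff-robustness is evidence.

## Likelihood machinery

**Mk models.** The pruning (Felsenstein) likelihood with per-branch
`P(t) = exp(Qt)` is implemented in C++ (dense matrix exponentials by
scaling-and-squaring; state spaces here are at most 16). Polytomies are
supported natively — partial likelihoods multiply over any number of
children — because summary trees often contain them. Partial likelihoods
are rescaled per edge with the log accumulated, so 300-tip trees with small
rates do not underflow. Missing tip states enter as uniform partials.
Marginal ancestral probabilities use the standard two-pass conditioning
(equivalently, rerooting) construction; the test suite holds it to
exhaustive enumeration over all internal-state assignments on random small
trees at 1e-8.

**Root prior.** `fitzjohn` (each root state weighted by its share of the
root partial likelihood) is the default, matching common practice in
diversification software; `uniform`, `stationary`, and explicit vectors are
selectable. The choice is config-exposed because reconstructions near the
root can be sensitive to it.

**Rate schemes.** SYM ties opposing rates (k(k−1)/2 free parameters), ARD
frees all k(k−1), and CONSTRAINED takes a user-supplied zero mask — the
mask is data, not code, because biologically motivated forbidden
transitions (for example, no direct vertebrate→generalist moves) are a
modelling claim the user should own. Optimization is bounded L-BFGS on log
rates (bounds 1e-9 to 100 per Myr), multi-start (a height-scaled heuristic
start, deterministic magnitude multipliers, then seeded random
perturbations). Zero-length branches are nudged to 1e-8 × tree height
before fitting; exact zeros make transition matrices singular at the tips.

**State-dependent diversification.** The MuSSE-style likelihood integrates
the standard coupled ODEs for D (clade likelihood) and E (extinction
probability) per branch with an adaptive solver (relative tolerance 1e-8,
absolute 1e-10, checkpointed at nodes). Node joining multiplies by λ for
states with λ > 0 only; with all λ = 0 the branching factor vanishes and
the likelihood is exactly the Mk likelihood — this convention is what makes
the degenerate limit well-defined (a literal λ factor would annihilate the
likelihood) and it is verified to 1e-6 in the tests, alongside the k = 1
closed-form birth–death check. The scenario pipeline defaults to the Mk
engine: only node state probabilities feed the classifier, the Mk path is
orders of magnitude faster, and its agreement with enumeration is provable;
the SSE engine stays available behind `engine = "sse"` for users who want
state-dependent λ/μ as nuisance parameters.

## Shift paths and the 1:1-line classifier

A *shifted clade* is a maximal monophyletic group whose MRCA and all
descendants are non-bee; isolated shifted tips count as singleton clades.
From each clade the extractor walks rootward collecting (x, y, node age)
triples. Two numerical choices here are the package's most consequential:

- **`tau_shift` = 0.95.** The walk starts at the most rootward node still
  on the high-probability plateau (x ≥ τ) and stops at the first node with
  P(bee) ≥ τ. Maximum-likelihood marginals essentially never reach exactly
  1, so "100% probability" must mean a plateau; 0.95 is the default, and a
  sensitivity sweep over {0.90, 0.95, 0.99} is built into every report.
- **`delta` = 0.10.** The margin that separates "on the y-axis" from "near
  the origin" and "above the 1:1 line" from "near it". Visual categories on
  a probability plot need a declared width; 0.10 is config-exposed.

Per lineage, the ancestral endpoint gives the axis category (y-axis /
origin / x-axis / interior) and the mean signed deviation of y − x over the
deduplicated path gives the line position. Both are reported because they
answer different questions: the endpoint is "where was the lineage when the
syndrome was still ancestral", the mean deviation is "which character led
along the whole path".

**The verdict rule.** Because the walk ends only when the ancestral
syndrome is near-certain, the ancestral endpoint always has x ≤ 1 − τ:
pollinator-first lineages end *near the origin* after tracking the x-axis,
never *on* the x-axis, so no rule demanding x-axis endpoints can ever
return a pollinator-first verdict. The ordering signal lives in the line
position. Lineages hugging the 1:1 line carry no ordering information
either way, so the verdict is a strict majority among the lineages that
deviate from the line (ABOVE vs BELOW counts); ties, or no deviating
lineages, read as SIMULTANEOUS, and no shifted clades at all reads
UNDEFINED. This matches how practitioners actually argue from these plots:
conclusions are drawn from the lineages that left the line, and a clear
plurality of lines above it is read as support even when the uninformative
middle keeps it short of an absolute majority.

**Known limitation.** Truly simultaneous histories produce small
above/below imbalances (reconstruction smoothing acts differently on a
reversible environment character and an irreversible syndrome character),
so near-simultaneous data are frequently read as weakly directional. The
classifier separates environment-first from pollinator-first orderings
reliably (the acceptance run measures both recovery rates at ~90% or above
over 50 simulated datasets each); it is not a calibrated test for
simultaneity. A formal test of ordering is deliberately out of scope — the
correlation module compares independent vs dependent product-space Mk
models, nothing more.

## Niche summarization

Occurrence records (with pre-extracted elevation, mean annual temperature
bio1, annual precipitation bio12) are deduplicated on exact coordinates,
thinned to one record per species per 1/120° grid cell (≈1 km at the
equator, matching 30 arc-second climate rasters; no projection, since cell
size is chosen to mirror the raster grid, and the thinning is deterministic
under a (lon, lat, elevation) sort so results are invariant to input
order), then summarized as per-species medians. Latitude is summarized as
the median of |latitude| by default — niche expectations are symmetric
about the equator — with signed latitude available by flag. Elevation and
temperature are refused in the same model by default (|r| > 0.8 in real
layers; the guard is overridable).

Whittaker biomes are assigned by point-in-polygon in the temperature ×
precipitation plane against a polygon file shipped with the package. The
file is a simplified, straight-edged synthetic digitization of the classic
nine-biome diagram (−15..30 °C × 0..4500 mm), versioned with the package so
assignments are reproducible; points outside every polygon take the nearest
biome (axes normalized by the diagram ranges) and are flagged as
extrapolated. Group × biome contingency uses the Pearson chi-squared with
standardized residuals r = (O − E)/√(E(1 − row/n)(1 − col/n)); |r| > 2
flags a strongly contributing cell. The sum of squared standardized
residuals under this definition does not equal the chi-squared statistic,
so residuals are checked cell-by-cell against the formula, never against
the statistic.

## Phylogenetic statistics

The binary GLMM follows the penalized-quasi-likelihood (Ives–Garland)
formulation via `ape::binaryPGLMM`, with predictors standardized internally
and estimates, standard errors and z-based p-values mapped back to the
input scale through the exact linear reparameterization of the coefficient
covariance. The GLS linear model uses the Brownian covariance scaled to
unit height, with t-based p-values on n − p degrees of freedom, so on a
star tree it reproduces ordinary least squares to machine precision. The
phylogenetic ANOVA is the classic simulation procedure: observed F on the
tips, null F from Brownian simulations at the ML rate estimated from the
GLS residuals of the group model, p = (1 + #{F_sim ≥ F_obs})/(nsim + 1).
Stepwise reduction drops the least significant droppable term with p > α
(default 0.05, the conventional reading of "retain only significant
parameters"), never orphaning an interaction's main effects, with
deterministic tie-breaking toward the later term. The resampling procedure
redraws one occurrence per species per iteration (seeded), refits the
binary GLMM and reports the percentage of iterations with p < 0.05, with
failed iterations tallied rather than dropped.

## What the generator emulates — and what it does not

`simulate_joint_history` runs an exact event-driven (Gillespie) simulation
of a coupled two-character process along every branch, root fixed at
(lowland, bee): the environment flips at base rates 0.05 up / 0.02 down per
Myr and the pollinator shifts irreversibly at 0.001 + 0.05·1[montane] per
Myr under the environment-first scenario; the pollinator-first scenario
mirrors the roles (leading rate 0.05 on the syndrome, boosted uphill rate
on the environment); the simultaneous scenario moves both characters in a
single coupled jump at the leading rate with only baseline environmental
wobble; the independent scenario removes the coupling (for correlation
tests its baseline shift rate is raised to 0.02 so both characters carry
comparable variation). Exact event semantics make Poisson-count oracles
valid, and every event time is recorded so the true per-lineage ordering is
known.

Companion trees are constant-rate birth–death (λ = 0.2, μ = 0.05 per Myr),
conditioned on the tip count and rescaled to a fixed height of 25 Myr. The
rescaling is a deliberate part of the study conditions: the per-Myr trait
rates above define shift frequencies only relative to tree depth, and at
25 Myr they produce datasets resembling the empirical regime this method
targets — roughly 15–40% of tips shifted, 30–70% montane, shifted clades
usually containing multiple species. Draws outside a non-degenerate window
(2–60% shifted, 5–75% montane) are resimulated under a shifted seed,
exactly as birth–death trees are conditioned on survival: a tree on which
(almost) every lineage has shifted carries no ordering signal and cannot
test ordering recovery.

Binary histories are expanded to the observable four-state characters
(lowland → E1/E2, montane → E3/E4 with equal probability; shifted → one of
three syndromes by configurable weights), so binarizing at 1000 m recovers
the binary truth exactly. Occurrence clouds are Normal around species
optima, with temperature tied to each record's elevation through a lapse
rate (−5.5 °C/km from a 27 °C sea-level baseline) so the strong negative
elevation–temperature correlation of real climate layers is reproduced.

What the generator does **not** emulate: spatially autocorrelated sampling
effort, taxonomic misidentification, coordinate error, range maps, biome
geometry of real continents, diversification rate differences between
states (trait-independent birth–death only), rate heterogeneity through
time, or reversals to the ancestral syndrome. Passing the recovery tests
therefore shows that the inference chain is sound when its model class
matches the generating process — not that any empirical dataset satisfies
those assumptions.

## End-to-end recovery and problem sizes

`recover_scenario()` is the measured inference chain: binarize both
characters at the generating cutoff, fit Mk models (SYM for the syndrome,
ARD for elevation — the same scheme pair selected for the empirical
characters, and the pair that behaves sensibly when shifted tips are few:
an unconstrained reversal rate can explain isolated shifted tips as noise
and erase the plateau the path extractor needs), reconstruct, classify.
Recovery runs on the binarized characters rather than the four-state
expansion because the verdict depends only on P(bee) and P(montane);
per-edge cost scales with k², and the four-state path is exercised
separately by the pipeline tests.

Problem sizes used by the suite and the acceptance script are the
package's own choices: 100 random trees of ≤6 tips and ≤3 states for the
enumeration equivalence; 50 random trees for the SSE reductions; 50
datasets of 150 tips per generating scenario for recovery and 50 of 100
tips for the correlation preference; 200 Brownian null replicates (199
simulations each) for the ANOVA type-I error; 100 resampling iterations on
70 species for the strong/null contrast. These sizes give stable rates
while keeping a full run in minutes.

## Degenerate inputs and numerical conventions

Single observed states drive rates to the lower bound with a warning, never
an error; non-converged optimizations are flagged on the fit object.
Negative elevations (coastal raster artifacts) bin to E1 with a warning.
Negative precipitation is an error. Empty contingency rows/columns are
dropped with a warning before the chi-squared. Ultrametricity is checked at
relative tolerance 1e-4 and only warned about — dated summary trees are
near- but rarely exactly ultrametric — while all likelihood code accepts
the tree as given. Ties in stepwise elimination break toward the
later-indexed term, and grid thinning sorts deterministically, so every
pipeline output is reproducible byte-for-byte given the config and seed;
stage outputs are cached under the output directory keyed by the config
hash.
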