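---
title: "Methods: conifer xylem hydraulics and pit anatomy, comparatively"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conifer xylem hydraulics and pit anatomy, comparatively}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xylemcomp)
```

## The scientific question

Water in a transpiring conifer moves under tension through dead tracheids
connected by bordered pits. Under drought the tension grows until air is
aspirated through a pit into a water-filled tracheid — embolism — and the
conduit is lost. Two species-level quantities summarise a species' hydraulic
strategy: embolism resistance, |P50| (the tension at which half the
conductance is gone), and hydraulic efficiency, Ks (specific conductivity
near zero tension). The package implements the analysis chain that asks how
these two quantities are predicted by pit and tracheid anatomy across a
species set sharing a phylogeny, and how strongly each trait is
phylogenetically conserved.

## Vulnerability curves

A centrifuge-based conductance series for one branch holds replicate
conductances at a sequence of increasingly negative xylem pressures,
starting at −0.8 MPa. `compute_plc()` converts these to percent loss of
conductance relative to the first (least negative) step,

$$\mathrm{PLC}(P) = 100\,(1 - \bar k(P)/k_{\max}),$$

and `fit_vc()` fits the two-parameter sigmoid

$$\mathrm{PLC}(P) = \frac{100}{1 + \exp[(S/25)(P - P_{50})]},$$

whose inflection sits exactly at (P50, 50%) with slope −S (% MPa⁻¹). Ks is
`kmax·L/A` by default ("standard" mode); a "literal" mode `kmax/(L·A)` is
selectable and recorded in metadata, because the defining sentence of the
source protocol is ambiguous between the two (they differ by L²). The
printed conductance units in that protocol are dimensionally inconsistent
with Ks under either convention; the package stores units as column-name
metadata and does not attempt to resolve this.

Numerical choices, all tested:

* **kmax reference.** The replicate mean at the first step (−0.8 MPa), not
  the running maximum, because specific conductivity is defined near zero
  tension; `kmax_rule = "max"` is available. Negative PLC from small flow
  increases is clamped to 0 — noise, not recovery.
* **Optimiser.** Bounded least squares by L-BFGS-B with
  `P50 ∈ [min(P) − 2, −0.1]`, `S ∈ (0, 500]`; start values from linear
  interpolation of the 50% crossing and the 20–80% secant; three jittered
  restarts on non-convergence, and a `converged` flag rather than silent
  `NaN`. On noiseless sigmoid data the optimum is recovered to 1e-6 (P50)
  over a 3 × 3 grid of true values.
* **A deliberate, documented bias.** Because PLC is referenced to the
  −0.8 MPa step and the sigmoid has non-zero loss there (fat tails at low
  S), even noise-free generated conductances yield fitted P50 values offset
  by up to ~0.01 MPa. The laboratory protocol shares this truncation; the
  tests assert the honest bound (< 0.02 MPa) instead of pretending exact
  recovery.
* **Aggregation.** Branch fits are averaged per species with equal weights;
  |P50| is the sign convention used downstream.

## Pit and tracheid traits

From pit membrane, torus and aperture diameters (µm), per pit:
`TO = (DT − DPA)/DT`, `MF = (DPM − DT)/DPM`, `VE = TO·MF`. Pits violating
`DPA < DT < DPM` are flagged and excluded from branch means (counted, never
silently dropped); aggregation is per pit → branch → species, which is how
the published subfamily tables are best reproduced.

Pit aperture resistance treats the aperture as a Poiseuille channel of
length `T_pa = 0.81·2·Tw` plus an orifice entry term:

$$R_{PA} = \frac{128\,T_{pa}\,\eta}{(\pi D_{PA})^4} + \frac{24\,\eta}{D_{PA}^3},$$

with lengths converted to metres and η = 0.001 Pa s (20 °C) held in MPa·s
so the result lands in MPa s m⁻³. Note the first denominator: the *product*
π·DPA is raised to the fourth power. This is hydrodynamically unconventional
(the classical channel term has π·DPA⁴, i.e. π¹ not π⁴) but it is the form
that reproduces the published subfamily values within 5%; the conventional
form misses them by ~π³ ≈ 31× on the channel term and is available behind
`convention = "conventional"`, clearly documented as not matching those
values. The wall thickness entering `T_pa` defaults to the earlywood value,
where pits are measured; a switch allows the whole-section mean.

Tracheid summaries: diameters from lumen areas assuming circular sections,
`Di = 2√(a/π)`; hydraulic diameter `Dh = (mean Di⁴)^{1/4}` (Hagen–Poiseuille
weighting, computed on the whole radial section by default);
`TD = count/area` (mm⁻²); `TSR = (2Tw/D)²`. Sections with fewer than 200
tracheids are summarised but flagged, mirroring the usual minimum for trait
averaging. Earlywood, latewood and whole-section values are carried side by
side (`_E`, `_L` suffixes).

## Comparative statistics

* **Correlations.** Pairwise complete-case Pearson r with two-sided t-based
  p-values; no multiple-testing correction (raw α = 0.05 flags, matching
  the way such trait matrices are conventionally reported).
* **Independent contrasts.** Felsenstein pruning; at each node the contrast
  `(x_i − x_j)/√(v_i + v_j)`, ancestral values 1/v-weighted, parent edge
  extended by `v_i v_j/(v_i + v_j)`. Contrast association is the
  through-origin correlation with `n_contrasts − 1` df. Polytomies are
  resolved arbitrarily with zero-length edges plus a warning
  (`strict = TRUE` errors instead); the GLS identity
  `Σc² = (x − â)ᵀV⁻¹(x − â)` is property-tested on random trees.
* **Blomberg's K.** With `V` the Brownian tip covariance,
  `K = (MSE0/MSE) / [(tr V − n/(1ᵀV⁻¹1))/(n − 1)]`, the observed-to-expected
  ratio of ordinary to phylogenetically whitened mean squares around the
  GLS mean. Significance is a tip-shuffling permutation test on MSE with
  observed-inclusive denominator, so p has resolution `1/(n_perm + 1)`
  (999 permutations by default). The permutation stream is privately
  seeded and the caller's RNG state is restored — a detail that matters
  when K is computed inside larger seeded simulations. Calibration (part
  of the acceptance suite): pure Brownian traits on fresh 28-tip Yule
  trees give mean K ≈ 1.0 over 500 replicates; white noise gives mean
  K ≈ 0.14 with non-significant p in well over 90% of replicates.
* **ANOVA + Tukey.** `stats::aov`/`TukeyHSD`, with a compact letter display
  computed by greedy insert–absorb (groups sharing no letter differ at
  α = 0.05; ties broken by group order). Degenerate all-equal data return
  F = 0 rather than NaN. When no grouping is supplied, the pipeline derives
  clade groups by cutting the cophenetic dendrogram.
* **PCA and VIF.** PCA on the correlation matrix of complete cases
  (constant traits dropped with a warning); `VIF_j = 1/(1 − R²_j)` with an
  explicit screen at the conventional VIF < 5 cut.

### AICc multimodel selection

All 2^p OLS submodels of the z-standardised response (including the null)
are fitted;
`logLik = −n/2 [ln 2π + ln(RSS/n) + 1]`, `k = slopes + intercept + σ²`,
`AICc = −2 logLik + 2k + 2k(k+1)/(n−k−1)`. Akaike weights are normalised
over all candidates; the selected set is ΔAICc < 2. Averaged coefficients
use zero-substitution ("full") averaging with weights renormalised over the
selected set — the convention whose arithmetic reproduces the published
selection table, including an unprinted null-model weight implied by the
printed importances. Per-variable p-values use the unconditional
model-averaged standard error.

Two importance measures are reported deliberately:

* `importance` — weight sum over selected models containing the variable,
  renormalised (the published-table convention). It saturates at exactly
  1.0 for any variable present in *every* selected model, so two variables
  can tie at the ceiling.
* `importance_full` — the field-standard Akaike-weight sum over *all*
  candidate models. It cannot tie at the ceiling and is the measure the
  acceptance suite uses for the planted-signal exceedance test; with the
  selected-set measure, ~12% of seeded runs end in exact 1.0-vs-1.0 ties
  and strict exceedance becomes undecidable.

### Recursive path analysis

Path models are plain-text equation sets (`"VE ~ TO + MF"`), required to be
acyclic. All variables are z-standardised; each equation is estimated by
least squares, which is maximum-likelihood-equivalent for recursive models
with uncorrelated errors — the only class the bundled diagrams need; this
is a documented limitation for non-recursive extensions. Exogenous
covariances are fixed at sample values (saturated exogenous block). The
implied covariance `Σ = (I−B)⁻¹Ψ(I−B)⁻ᵀ` (with residual variances on the
N−1 scale so a saturated model reproduces the sample covariance exactly)
enters the Wishart discrepancy `F = ln|Σ| + tr(SΣ⁻¹) − ln|S| − p`,
`χ² = (N−1)F`, `df = p(p+1)/2 − free parameters`. Effects decompose by
path tracing (powers of the nilpotent coefficient matrix): direct = edge,
indirect = sum of products over all longer directed paths; the
decomposition is property-tested against brute-force path enumeration.
The bundled `p50` and `ks` presets transcribe the hypothesised causal
diagrams (pit dimensions → TO/MF → VE → |P50|; DPA, Tw → R_PA → |P50|;
Dh, TD, Tw, R_PA → Ks) as far as a figure permits: the exact free exogenous
covariances behind the published df values cannot be reconstructed from a
caption, so the presets are best-effort and editable.

## The synthetic world

The generator emulates the sampling design the analysis assumes: 28 species
on an ultrametric Yule tree (unit depth), 5 branches per species for
curves, 3 for anatomy, 10 pits per branch, pressure steps from −0.8 MPa in
−0.3 MPa decrements for vulnerable species (species-level P50 above
−4 MPa) and −0.8 MPa for resistant ones, replicate conductances with 5%
multiplicative noise. Species trait values evolve by Brownian motion with
a tunable white-noise fraction λ (`λ = 0` pure BM, expected K ≈ 1; `λ = 1`
pure noise, K ≈ 0). Range-bounded traits (P50 −7.8 to −3.0 MPa, DPM
9–15 µm, TO 0.27–0.41, MF 0.45–0.57, Tw 2.3–3.0 µm, WD 0.46–0.60 g cm⁻³ —
the published subfamily extremes) are evolved on a logistic scale and
mapped into their ranges, preserving the Brownian covariance without
truncation artefacts. Pit geometry is built multiplicatively
(`DT = DPM(1−MF)`, `DPA = DT(1−TO)`), so the ordering `DPA < DT < DPM`
holds by construction. Tracheid lumen areas are lognormal; density follows
the packing trade-off `TD = c/D²` with `c = 4.3×10⁵` µm² mm⁻² chosen to
match published density–diameter magnitudes. Within-species noise levels
(cv 2–5%) are not reported in the source study; they are stated
placeholders, labelled as such in `truth.json`, chosen once at values a
field hydraulics lab would consider realistic, and not tuned thereafter.

What a green test does establish: the pipeline recovers generating
parameters (P50 rank order at Spearman ρ > 0.95 under 5% noise; sealing
ratios within ±0.02; planted regression signals; K calibration). What it
does not: the generator has no measurement-operator realism (no image
segmentation error, no species-specific step protocols beyond the P50
class, no curve cleaning), no outlier contamination — the package applies
no automatic outlier removal, it only logs |z| > 3 values, with an optional
3-SD trim — and no real taxonomy: clade "subfamilies" for the group ANOVA
are tree cuts, not named lineages.

One master seed drives named substreams (`substream_seed(seed, "p50")`,
…), so any one component can be re-randomised without disturbing the rest,
and every emitted file is listed with its MD5 hash in the run manifest.

## Open choices made here

* The published phylogeny includes a non-conifer outgroup used for rooting;
  whether it was pruned before computing K is unstated. Pruning is exposed
  as an explicit option (`match_tree_species(strict = FALSE)`); the
  synthetic world has no outgroup, so defaults are unaffected.
* Group ANOVAs can be run at species level (one mean per species — the
  published df convention for the subfamily table) or at branch level;
  both granularities are supported, species level is the pipeline default.
* Whether the −0.3 vs −0.8 MPa step decrement depended on species P50
  class is unstated; the generator's `pressure_step = "auto"` makes the
  dependency explicit and overridable.

## Known limitations

No P12/P88 thresholds, temperature/viscosity corrections, torus pore
statistics, tree inference or dating, latent-variable or non-recursive
path models, or fit indices beyond χ²/df/p. Plots are not part of the
contract; all outputs are plain CSV/JSON.
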