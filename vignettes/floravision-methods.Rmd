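---
title: "Modeling pollinator-perceived floral colour variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling pollinator-perceived floral colour variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floravision)
```

## The question

Pollinator-mediated stabilizing selection is expected to limit how much
flower colour varies *within* a plant population — but "colour" only exists
inside a viewer's visual system. A bee and a hummingbird looking at the same
fifteen conspecific flowers can disagree wildly about how many of them look
different from one another. floravision quantifies that disagreement: it
maps reflectance spectra into the colour space of each viewer, scores every
within-population flower pair against the viewer's behavioural
discrimination threshold, and asks whether the *fraction of discriminable
pairs* depends on the interaction between the visual system doing the
looking (bee vs. bird) and the pollination system of the plant (bee- vs.
bird-pollinated).

## Visual models

**Quantum catches.** For receptor $i$ with spectral sensitivity
$S_i(\lambda)$ viewing a flower with reflectance $R(\lambda)$ under
illuminant $I(\lambda)$, the catch is

$$Q_i = \int_{300}^{700} R(\lambda)\, I(\lambda)\, S_i(\lambda)\,
  d\lambda,$$

evaluated by trapezoid summation on a 1 nm grid (the grid is dense enough
that rectangle vs. trapezoid differences are negligible; trapezoid is pinned
for reproducibility). Catches are von-Kries adapted,
$q_i = Q_i / Q_i^{\mathrm{bg}}$, against an adaptation background, which
makes $q$ invariant to the illuminant's overall scale and sends the
background itself to $q = (1, \dots, 1)$.

**Bee colour hexagon.** The honeybee trichromat (receptor peaks 344, 436,
544 nm) maps adapted catches through the half-maximal transform
$E_i = q_i / (q_i + 1)$ — the background sits at $E = 0.5$ — and then to
plane coordinates

$$x = \tfrac{\sqrt{3}}{2} (E_g - E_{uv}), \qquad
  y = E_b - \tfrac{E_{uv} + E_g}{2}.$$

Hue is the angle $\mathrm{atan2}(y, x)$, saturation the distance from the
origin (at most 1). Behavioural work places the discrimination threshold at
0.11 hexagon units; pairs at Euclidean distance $\le 0.11$ are treated as
indiscriminable (strictly greater counts as discriminable — the threshold
itself is not).

**Receptor-noise limited (RNL) model.** Birds are modelled as tetrachromats
(average violet-sensitive phenotype by default, peaks 416/478/542/607 nm;
the UV-sensitive phenotype 372/456/544/609 nm is available for robustness
runs). Receptor noise follows the Weber rule scaled by relative receptor
density $\eta$: $e_i = \omega \sqrt{\eta_{\max}/\eta_i}$ with densities
1:2:2:4 and $\omega = 0.1$ for the densest (long-wave) class, independent of
stimulus magnitude. With log receptor contrasts
$\Delta f_i = \ln(q_i^a / q_i^b)$, the colour distance for $n$ receptors is

$$\Delta S^2 = \frac{\sum_{i<j} (\Delta f_i - \Delta f_j)^2
  \prod_{k \neq i,j} e_k^2}{\sum_i \prod_{k \neq i} e_k^2},$$

which reduces to the familiar dichromat form
$|\Delta f_1 - \Delta f_2| / \sqrt{e_1^2 + e_2^2}$ and to the standard
tri-/tetrachromat expressions. One just-noticeable difference
($\Delta S = 1$) is the conservative threshold for diurnal birds. Log (not
linear) contrasts are used because the Weber-fraction formulation of the
model is defined on log contrast for ecologically relevant stimuli.

**Receptor sensitivities.** Curves are generated from the Govardovskii A1
pigment nomogram (alpha plus beta band) at the phenotype's peak wavelengths.
The beta band is included only for pigments peaking at 400 nm or above: for
a UV pigment the beta band coincides with the alpha peak and would displace
the summed maximum by ~2 nm, breaking the peak-placement contract of the
template. Literature sensitivity tabulations (e.g. including oil-droplet or
ocular-media filtering, which the nomogram does not model) can be supplied
as a matrix via `buildViewer(sensitivities = )`; peak wavelengths and
densities are configuration (a packaged CSV), not hard-coded constants.

**Illuminant and background.** D65 ships as the standard CIE relative-energy
table at 10 nm, converted to relative quanta (energy × wavelength) and
interpolated to the working grid. The default adaptation background is flat
achromatic reflectance 0.5: the paper trail for field studies rarely states
the background, and a flat background makes the achromatic fixed point exact
and testable ($q \equiv 1$, hexagon centre, $\Delta S = 0$). A synthetic
green-foliage curve is packaged as an alternative, and any two-column CSV is
accepted.

## From spectra to the analysis table

Spectra are read from wide CSV (first column `wl`, one column per flower),
auto-rescaled from percent when any value exceeds 1.5 (overridable), trimmed
to 300–700 nm, linearly interpolated to the 1 nm grid and negative readings
clamped to zero. Linear (not spline) interpolation is deliberate: it is
monotone and artifact-free, and floral reflectance is smooth at this
resolution. Values above 1 (white-standard overshoot) are kept — only
negatives are spurious.

For each population and viewer, all $\binom{n}{2}$ pairwise distances (105
for the standard 15 flowers) are compared to the threshold, giving the
fraction discriminable. Species-level summaries average their 1–3
populations (the SE is undefined for single-population species and reported
as `NA`). Study-wide means are reported both across populations and across
species means, because the two conventions differ whenever species
contribute unequal population counts.

## Inference

The analysis table has one row per population × viewer. The primary model is
a linear mixed-effects model fit by maximum likelihood (`lme4`):

```
fraction ~ visual_system * pollination_system +
  (1 | species) + (1 | species:population)
```

Terms are tested by likelihood-ratio chi-square between nested ML fits (df =
difference in fixed-effect parameters); REML is off for all comparisons.
Cell contrasts use estimated marginal means with Satterthwaite degrees of
freedom and unadjusted p-values (the design has one planned contrast per
viewer; a multiplicity adjustment flag is deliberately not applied by
default). Fractions are analysed untransformed on [0, 1] as is conventional
for this design; an empirical-logit option exists (`logit = TRUE`) but is
off by default. The contrast degrees-of-freedom method is a documented
choice — Satterthwaite, falling back to asymptotic if unavailable — since
different software defaults differ here.

The main analysis keeps only pure `Bee` and `Bird` pollination systems.
Mixed-system species are folded back in by three documented regroupings
(`Bee/Bird` with `Bee`; `Bee/Bird` with `Bird`; `Bee/Fly` and `Bee/Hawkmoth`
with `Bee`) via `regroupMixedSystems()`, for robustness refits.

Cross-space correlation is tested by regressing bird fraction discriminable
on bee fraction discriminable per population, comparing slope-only,
plus-pollination-system, and plus-interaction candidates by
$\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$.

**Saturation.** Bee saturation is the hexagon origin distance. The bird
analogue is not canonically defined; we use the RNL distance from the
stimulus to the adaptation background (the achromatic point), the natural
origin-distance analogue — a documented package choice, not a literature
standard. Because hexagon units (≤ 1) and JND (often 5–20) are
incommensurable, a single-residual-variance model over both spaces would let
the bird space swamp any bee-space signal; `fitSaturationModel()` therefore
z-scores saturation within each visual system by default. Within-system
contrasts and the interaction remain meaningful; the visual-system main
effect is removed by construction and must not be interpreted under scaling.

## The synthetic study generator

`simulateStudy()` stands in for field data with the same statistical
skeleton: 24 bee-pollinated species with Gaussian-peak reflectance
(centres drawn once per species from U(400, 560) nm, widths U(30, 60) nm,
amplitudes U(0.4, 0.8), baselines U(0.02, 0.08), 30% of species carrying a
secondary UV bump) and 7 bird-pollinated species with red long-pass sigmoid
reflectance (inflections U(600, 640) nm, steepness U(10, 20) nm, amplitudes
U(0.5, 0.8), baselines U(0.01, 0.04), never a UV bump — red bird flowers in
this guild are characteristically UV-free, which renders them nearly
achromatic in bee space). Two populations per species receive a normal
population-level parameter shift; 15 flowers per population receive
independent normal parameter jitter, truncated to keep spectra valid.
Normal, independent, per-parameter jitter is the simplest variance structure
that produces "intrapopulation variation" without asserting a biological
noise model.

The shipped flower-level jitter (Gaussian type: centre 6 nm, width 4 nm,
amplitude 0.09, baseline 0.02; long-pass type: inflection 8 nm, steepness
2 nm, amplitude 0.09, baseline 0.02) was calibrated once to the qualitative
regime reported for montane bee/hummingbird communities — bee-perceived
fractions mostly under 10% and statistically indistinguishable between plant
guilds, bird-perceived fractions above 50% for bird flowers and intermediate
for bee flowers — and is frozen in `defaultStudyConfig()`. The mechanism is
the interesting part: jitter on a red flower's long-wavelength edge moves
the bird's $\Delta S$ across 1 JND while the bee's hexagon position barely
moves, because variation confined to the "red arm" falls where bee
sensitivity is lowest.

What the generator does **not** emulate: heterogeneity between species in
overall variability (all species share one jitter scale, so the cross-space
regression shows only a weak positive slope, unlike real communities where
species differ strongly in how variable they are in *every* space);
correlated parameter variation (pigment concentration changes amplitude and
shape together); phylogenetic structure; and measurement noise from the
spectrometer. Passing tests on synthetic data therefore demonstrate that the
pipeline detects the perceptual mechanism when present — not that any
particular field system exhibits it.

## Numerical choices and degenerate inputs

- Integration: trapezoid weights on the working grid; 1 nm default step.
- Strict threshold inequality: a pair at exactly the threshold is
  indiscriminable, for both 0.11 hexagon units and 1 JND.
- RNL distances require strictly positive catches (log contrasts); a zero
  catch is an error, as is a background giving zero catch in any receptor.
- Cleaning rejects spectra that do not cover 300–700 nm, naming the gap;
  interpolation never extrapolates.
- The hexagon accepts zero catches (black maps to the centre).
- `simulateStudy()` draws everything from one seeded RNG stream, so a
  configuration plus seed reproduces the dataset bit for bit;
  `simulatePopulation(seed = )` seeds locally for standalone use.
- Mixed-model fits use `lme4` with singular-fit checks silenced (population
  variance components can legitimately collapse to zero on null data);
  likelihood-ratio statistics are floored at zero.

## Problem sizes used in the shipped tests

The test suite exercises the full 62-population, 930-flower design for the
end-to-end pattern checks, 200 random small populations (n ≤ 8) for the
brute-force oracle comparisons, and 500 replicate null fits at the
62-population design for the size of the interaction test. These sizes give
stable Monte-Carlo behaviour while keeping a full run in the low minutes on
one core.

## Known limitations

- The achromatic (luminance) channel is not modelled; discrimination is
  purely chromatic, as in the threshold literature the models come from.
- Avian oil-droplet filtering is not generated from first principles; users
  wanting filtered sensitivities must supply them as curves.
- The bird "saturation" metric is a package definition (see above).
- Fractions are modelled with Gaussian errors on [0, 1]; with many
  populations at the boundaries a binomial-type model would be more
  defensible (the logit option mitigates but does not resolve this).
- Categorical colour perception, detectability against backgrounds, and
  between-species colour distances are out of scope.
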