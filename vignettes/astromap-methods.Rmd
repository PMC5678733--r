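---
title: "Astrocyte-gated self-organization of orientation maps: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Astrocyte-gated self-organization of orientation maps: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(astromap)
```

# The scientific problem

Carnivores and primates lay out orientation preference in primary visual
cortex as a smooth, quasi-periodic map with a characteristic hypercolumn
width and pinwheel singularities at a density of roughly pi per squared
hypercolumn; rodents instead show an interspersed ("salt-and-pepper")
arrangement with no spatial period. `astromap` implements a
self-organizing-map account of this difference: a GCAL-family cortical
sheet (gain-controlled LGN input, homeostatic threshold adaptation,
Hebbian afferent and lateral-inhibitory plasticity) is augmented with an
astrocyte layer that pools local synaptic drive and sets the sliding
threshold of a BCM rule for the lateral *excitatory* connections. The
astrocyte arbor radius then controls the distance over which excitatory
connections survive, and with it the hypercolumn width; when that radius
shrinks below the node spacing the map degenerates into a salt-and-pepper
arrangement.

# Model

## Sheets and geometry

The cortex is a square sheet of `density^2` rate units per sheet unit,
with 1 sheet unit = 3 mm of tissue, so the default unit sheet models a
3 x 3 mm patch and anatomical radii given in mm are used directly. The
retina/LGN sheet is padded by the afferent radius `rad_A` on every side so
edge cortical units keep complete receptive fields. All connection radii
are expressed in sheet units (`rad_A` = 0.27, `rad_I` = 0.22, from the
model's reference parameter table, alongside p = 1.5, q = 2.1, r = 1.4 and
learning rates 0.1/0.3/0.3).

## LGN stage

Retinal luminance is filtered by unit-mass difference-of-Gaussians ON/OFF
kernels (`sigma_c` = 0.0375, `sigma_s` = 4 sigma_c) and passed through a
divisive gain-control recursion: each channel's drive is divided by
`k + gamma_s * pool`, where the pool is a Gaussian-weighted average
(sigma 0.25 sheet units) of the channel's own activity. These constants
are not part of the reference table; they follow the standard values of
the GCAL literature, and `gamma_o` is calibrated so that a full-contrast
training bar settles to a peak response near 1. The divisive recursion is
a damped two-cycle, so settling uses relaxation steps
(`alpha = 0.5`, 5 steps); the relaxation leaves the fixed point unchanged.
A subtractive form of the recurrence is available
(`lgn_gain = "subtractive"`), but only the divisive form yields the
contrast saturation (response to doubled contrast < doubled response)
that gain control is meant to provide, so divisive is the default.

## Cortical dynamics

Per presentation the V1 sheet settles for 16 steps of

    y <- (1 - v1_alpha) * y +
         v1_alpha * f(p * A.L + q * E.y - r * I.y),

with the piecewise-linear transfer `f(v) = min(y_max, max(0, y_gain * (v - rho)))`.
Three choices here are deliberate departures from an idealized pure
half-wave rectifier, each made because the idealized form is not
settling-stable in this architecture:

* **Saturation** (`y_max = 1`): the excitatory bank is BCM-trained and not
  divisively normalized, so the recurrent gain can transiently exceed 1;
  without a ceiling the settling recursion diverges within single
  presentations. The bounded transfer is the classic LISSOM sigmoid and
  also keeps `y` on the same [0, 1] scale as the astrocytic threshold.
* **Slope** (`y_gain = 3`): slopes above 1 sharpen settled activity into
  compact, near-saturated blobs, so coactive neighbours imprint the same
  stimulus — the ingredient that makes maps locally smooth.
* **Relaxation** (`v1_alpha = 0.5`): synchronous updates fall into a
  global period-2 oscillation once lateral excitation is pruned (the
  salt-and-pepper regime); relaxation suppresses the two-cycle without
  moving fixed points.

Homeostasis smooths each unit's activity
(`ybar <- (1 - beta) y + beta ybar`, beta = 0.991) and slides its
threshold. The printed recurrence `rho <- rho + lambda * ybar - mu` is
dimensionally unbalanced (it moves rho even at the target activity), so
the default is the balanced form `rho <- rho + lambda * (ybar - mu)`
with the printed form selectable (`homeostasis_form = "printed"`).
`lambda` = 0.01 and the activity target `mu` = 0.024 are the standard
GCAL homeostasis constants.

## Plasticity

Afferent (jointly over the ON and OFF banks) and lateral inhibitory
weights use the normalized Hebbian rule

    w <- (w + eta * y_post * P) / sum(w + eta * y_post * P).

Learning rates are interpreted per receptive field, i.e. divided by the
number of connections in the projection's support
(`learning_scale = "per_unit"`). Applied per synapse instead, a single
winning event replaces more than half of a receptive field
(`eta * y * sum(P)` exceeds the unit weight mass) and the map rewrites
itself completely every couple of thousand presentations; the per-field
convention matches the ~10000-presentation development timescale this
model family exhibits.

## Astrocyte layer and the BCM rule

Each astrocyte pools the pre-rectification synaptic drive `gs` over a disc
of the *effective* arbor radius — twice the anatomical (GFAP-stained)
radius, since GFAP labels only ~15% of the arbor volume. The pooled field
is rescaled into [0, 1] by a slowly tracked scale (`s_max_tau` = 20
presentations, relaxing toward each presentation's maximum, with S clipped
to [0, 1]); a hard running maximum ratchets onto rare spikes of the
heavy-tailed pooled drive and pins S near zero, which silences all LTP.
The pooling disc always contains its own node, so anatomical radii below
one node spacing degrade gracefully to identity pooling — this *is* the
salt-and-pepper regime, not an error.

Lateral excitatory weights follow the astrocyte-thresholded BCM rule

    dE = eta_E * y_post * (y_post - theta) * y_pre,  E <- clip(E + dE)

with `theta = 1 - S` at the postsynaptic unit for synapses whose
presynaptic partner lies *within* the effective astrocyte radius. Synapses
from partners beyond that radius lie outside the astrocyte's domain and
see `theta = 1`: coactivity there is always depressing, and those
connections are pruned to zero. This synapse-scoped threshold
(`bcm_scope = "synapse"`) is what gives the astrocyte radius its causal
role; applying one node-global threshold to every synapse of a unit
(`bcm_scope = "node"`, also available) provides no distance selectivity —
in direct comparison the excitatory lag profile comes out identical at
0.015 mm and 0.1875 mm — and no radius dependence of the map can arise
from it. Growth is bounded by a per-entry cap (4 divided by the support
size) and a per-unit mass ceiling (`e_mass_max` = 1, the same unit mass
the normalized projections carry), applied divisively only when exceeded.
The excitatory support is capped at `rad_I` for memory; the BCM rule keeps
the mass beyond the astrocyte radius near zero (this is asserted in the
test suite).

## Gap junctions and the no-GABA variant

Astrocyte gap junctions are modelled as a fixed random excitatory kernel
to the 8 nearest neighbours (half-normal magnitudes scaled to a total
strength `gj_strength`), applied as
`S <- (S + kernel (*) S) / (1 + sum(kernel))`. The `no_gaba` variant drops
the inhibitory term from the drive the astrocytes see (no GABA-induced
gliotransmission); both variants develop visually similar maps, which the
test suite checks via the stability index against a random-map baseline.

# Map measurement and analysis

Maps are probed with full-field sine gratings at the analytic peak
frequency of the DoG transfer (8 orientations, 4 phases, maximum over
phases, plasticity frozen); preference and selectivity are the argument
and normalized magnitude of the orientation vector sum. The astrocyte
layer is probed identically through its normalized activation. An
elongated-Gaussian probe family is available behind the `stimulus`
argument for sensitivity checks.

* **Hypercolumn width.** Difference maps (0-90, 45-135) are Fermi
  high-pass filtered: `I = I' - J` with `J` the Fermi-smoothed map,
  normalized by the filter's response to the map support to correct
  boundary attenuation. The printed form of the Fermi function passes
  frequencies *above* the cutoff, yet describes `J` as "a smoothed
  version"; the implementation follows the description (low-pass `J`,
  high-pass `I`) by default and offers the printed orientation via
  `convention = "printed"`. Cutoff defaults: half the raw spectral argmax,
  steepness an eighth of the cutoff. The radially averaged power spectrum
  of the filtered maps is fitted with a Gaussian peak plus quadratic
  background by Levenberg-Marquardt least squares (initialized from the
  raw argmax, background pre-fitted on off-peak bins, argmax fallback on
  non-convergence); the hypercolumn width is `extent_mm / zeta` with
  `zeta` the fitted peak position.
* **Pinwheels.** Zero contours of the real and imaginary parts of
  `selectivity * exp(2i * preference)` are intersected segment-by-segment
  for subpixel centres; each candidate's charge is the winding number of
  the doubled angle around its plaquette, zero-winding candidates are
  discarded and centres within one node spacing merged. A brute-force
  plaquette-winding detector serves as the independent reference; on
  synthetic maps with planted pinwheels the two agree exactly, and on
  random band-pass maps the pinwheel density per squared hypercolumn
  comes out near pi, as it should.
* **Stability index.** `SI = 1 - 4/(n pi) * sum |(F - O) mod (pi/2)|`
  with the modulus taken as the symmetric remainder (fold to the nearest
  multiple of pi/2), so SI ranges over [0, 1], identical maps score
  exactly 1, a uniform 45-degree offset scores 0 and independent random
  maps score 1/2 in expectation. Read with a plain always-positive
  modulus the formula would score near-identical maps at ~0 and range
  down to -1, contradicting its stated 0-1 range.
* **Local similarity.** Mean orientation distance (folded to [0, 90]
  degrees) to all neighbours within a radius of interest, averaged over
  nodes: 0 for a constant map, 45 degrees for an independent uniform one.
  Salt-and-pepper maps sit strictly between the two (pseudo-random, with
  residual local similarity).

# Synthetic fixtures

The analysis suite is validated against synthetic maps with known ground
truth, generated in code: a canonical single pinwheel (`(x + iy)/|x + iy|`;
conjugation flips the charge), a crossing pattern with `4 fx fy` planted
pinwheels of alternating charge, band-pass-filtered complex noise with a
planted dominant wavelength, and uniform-random preference fields. These
emulate the topology and spectra of real maps but not their anisotropies,
measurement noise or non-stationarity, so passing them certifies the
analysis operators, not the biology.

# Problem sizes and reproducibility

Full-scale runs in this package mean a 48 x 48 (optionally 96 x 96)
cortex trained for 10000 presentations. The package's own verification
suite runs the emergent-property checks at a desk scale chosen to keep a
full radius sweep comfortable on one CPU: a 32 x 32 cortex, 2500
presentations, three seeds per radius; statistics are means over seeds.
Wavelengths are radius-relative, so the trends of interest survive this
reduction, at the cost of coarse spectral bins (the padded-FFT bin width
at 32 x 32 is 0.5 cycles per map) and sub-pixel effective radii at the
smallest sweep value — which is precisely the salt-and-pepper condition.
Every random draw flows through named, independently seeded streams
(stimuli, weight initialization, gap-junction kernel), so runs are
bit-for-bit reproducible and model variants see identical stimulus
sequences.

# Behaviour across the radius sweep

At desk scale the sweep reproduces the qualitative program: the pinwheel
count falls monotonically with the astrocyte radius (seed-mean 71 at
0.015 mm down to 9 at 0.1875 mm), the hypercolumn width rises with it
(Spearman correlation 0.85 across radius-seed cells), local smoothness
rises (34 to 13 degrees mean local separation at 0.25 mm), and in the
map-forming mid-range (0.075-0.1125 mm) the pinwheel density per squared
hypercolumn sits near pi, with `Lambda(0.1125 mm) ~ 1.1 mm` — matching
the cat (hypercolumn 1 mm, GFAP radius ~0.1 mm) in the cross-species
comparison that motivates the model.

One behaviour deserves honest emphasis: in this implementation the
hypercolumn width does not grow gently all the way up the sweep but
jumps between 0.1125 and 0.15 mm (0.78 to ~2 mm at the 48 x 48 scale).
Beyond the jump the 3 x 3 mm patch holds at most ~1.5 hypercolumns, the
spectral peak pins at the window scale and the per-hypercolumn pinwheel
density is no longer meaningfully estimable (it inflates to ~10).
Longer training and recalibration of the free stabilizer constants (the
excitatory mass ceiling, the transfer slope) do not remove the jump; it
appears intrinsic to this parameterization — once the effective
excitatory reach approaches the learned inhibitory core, the lateral
interaction loses its Mexican-hat zero crossing and domains coarsen
without bound. The package's verification suite states the affected
checks at their intended strength and lets them fail rather than
widening them; the analysis chain itself is validated independently on
synthetic maps with planted structure.

# Known limitations

* The astrocyte is an activation field, not a biophysical model: calcium
  dynamics, IP3 signalling and gliotransmitter kinetics are abstracted
  into the pooled, normalized activation and its threshold mapping.
* The salt-and-pepper regime retains orientation-selective units but the
  grating-probed selectivity is weak once lateral excitation is fully
  pruned; statistics there lean on the pinwheel and similarity measures.
* Spectral wavelength estimates at desk scale carry one-bin quantization;
  the per-hypercolumn pinwheel density inherits that uncertainty
  quadratically.
* Maps continue to drift slowly at desk scale; stabilization is assessed
  relatively (later map pairs more similar than early-late pairs), not as
  absolute convergence.
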