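---
title: "Models and methods in protonQA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in protonQA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protonQA)
```

# Scope

protonQA implements the computational core of a patient-specific quality
assurance (PSQA) program for spot-scanning proton therapy: an independent
analytical pencil-beam dose engine in a water phantom, a γ-index comparison
cascade with clinical criteria and action levels, spot-delivery log
analytics, and synthetic-data generators that produce every input with
controlled ground truth. Clinical measurement hardware, EMR/accelerator
integration, CT-based dose calculation and Monte Carlo transport are out of
scope; the engine computes model dose per monitor unit (MU) in water, which
is the configuration in which planar QA measurements are made.

# The depth-dose model

The integral depth dose (IDD) of a monoenergetic pencil beam is the
analytical Bortfeld Bragg curve: a power-law stopping term
$(R_0-z)^{1/p-1}$ plus a fluence-reduction term $\propto (R_0-z)^{1/p}$,
convolved with a Gaussian range-straggling kernel of width $\sigma$.
Constants $\beta = 0.012\,\mathrm{cm^{-1}}$ (fluence reduction) and
$\gamma = 0.6$ (locally absorbed fraction of nuclear secondaries) take their
conventional water values. A low-energy tail term weighted by
$\varepsilon \in [0,1)$ adds $\varepsilon\,p/R_0$ to the fluence-reduction
coefficient; it is the pluggable "modification" hook, since the published
description of the source program cites a modified formula without printing
it. The convolution is evaluated by deterministic quadrature after the
substitution $v = (R_0-u)^{1/p}$, which removes the integrable singularity
at the range; the quadrature step keeps the induced depth step below
$\sigma/6$ and the Gaussian window is truncated at $\pm 7\sigma$ (relative
error $<10^{-11}$). Beyond $R_0 + 10\sigma$ the curve is Gaussian-extinct
($<10^{-6}$ of the peak).

## Range–energy law and the simultaneous fit

Range and energy are tied by $R = \alpha E^{p}$. The two-point calibration
to the machine's endpoints (72.5 MeV → 4.0 g/cm², 221.8 MeV → 30.6 g/cm²)
is exactly solvable and gives $p \approx 1.82$.

`fit_bortfeld()` fits several measured Bragg curves simultaneously. The
shared quantities are $\alpha$ and $p$; the coupling is implemented as
$R_{0,i} = \alpha E_i^{p}$, because with per-curve free ranges $\alpha$
enters the curve shape only as a scale degenerate with the fluence scale
$\phi$ and would be unidentifiable. $\phi$ and $\phi\varepsilon$ enter the
model linearly and are profiled out analytically at every objective
evaluation (a 2-variable constrained least squares per curve), leaving only
$(\alpha, p)$ and the per-curve straggling widths as nonlinear parameters.
Two numerical choices matter:

* the shared law is parameterized as $(\log R_0(E_\mathrm{ref}),\,p)$ with
  $E_\mathrm{ref}$ the geometric-mean energy — in $(\log\alpha, p)$ the
  likelihood valley is extremely narrow and curved and quasi-Newton
  optimization stalls;
* initialization is deterministic: $R_0$ from the distal-80% depth of each
  curve, $\sigma = 1\%$ of $R_0$, law coefficients from a log-log
  regression. No randomness is used anywhere in the fit.

With `share = "none"` each curve is fit independently and $\alpha$ is held
at its initial value (documented identifiability limitation).

# The lateral kernel

The lateral spread at depth $z$ is a weighted sum of two Gaussians
(multiple Coulomb scattering core, weight $1-w_2-w_{cl}$ and $w_2$) and a
radial Cauchy-Lorentz component for large-angle/nuclear halo scatter:
$$f(r) = \frac{1}{\pi s^2}\left(1 + (r/s)^2\right)^{-2}.$$
A plain 2D Lorentzian is not normalizable; this squared form is the minimal
modification with the same heavy power-law tail and unit plane integral.
(The build contract's example used $2/(\pi s^2)$, which integrates to 2;
the unit-integral constant is used so the kernel satisfies its own
normalization invariant.) Gaussian widths grow with depth and are tied in
quadrature to the in-air spot fluence double Gaussian at the surface:
$\sigma_k(z) = \sqrt{\sigma_{air,k}^2 + (a_{k1} z + a_{k2} z^2)^2}$.
Low-order polynomial growth is standard for scattering-width
parameterizations and keeps the model identifiable; weights are constant in
depth by default.

# The dose engine

$$D(x,y;z) = \sum_i MU_i \cdot IDD(E_i, z_{\mathrm{eff}}) \cdot
K\!\left(\|(x,y)-(x_i,y_i)\|;\, z_{\mathrm{eff}}, E_i\right)$$

Conventions: x/y in mm at isocenter, parallel-beam (no divergence — the QA
geometry gives no source-axis distance and divergence is second order at QA
depths); plane depth is water-equivalent depth in g/cm²; grids are
corner-origin with rows indexing y. The kernel normalizes over mm², so the
plane integral of a single-spot field in mm² equals MU × IDD — the
factorization checked by the quadrature oracle in the tests. The kernel is
truncated at $r = 8\sigma_2 + 5s$ and the truncated mass renormalized
analytically, keeping the integral error well below the 0.5% tolerance.
Multiplication order is `mu * (idd * kernel)`, which makes dose bit-exactly
linear in each spot's MU.

A range shifter is modeled as a water-equivalent depth shift `rs_wet`
(default mapping the shallowest configured range to 0.3 g/cm², i.e. 3.7
g/cm² for a 4.0 g/cm² minimum range). Both the IDD and the kernel are
evaluated at the effective depth; evaluating the kernel at
$z + \mathrm{rs{:}wet}$ reproduces the extra lateral spread a degrader adds
downstream and stands in for per-energy "with-RS" kernel variants.

# γ-index analysis

For each reference point at or above the low-dose threshold (default 10% of
the global normalization, i.e. the reference maximum),
$$\gamma = \min_{\Delta r}\sqrt{\frac{\|\Delta r\|^2}{\delta_{DTA}^2} +
\frac{(D_{ref}-D_{eval}(r+\Delta r))^2}{\delta_D^2}},$$
with $\delta_D$ the dose criterion as a percent of the global
normalization. Points below the threshold enter neither the numerator nor
the denominator of the pass rate. $\gamma \le 1$ counts as a pass, so a
uniform exact-3% offset at the 3% criterion passes; a small $10^{-9}$ slack
absorbs floating-point residue at this boundary.

The fast implementation interpolates the evaluated plane bilinearly and
minimizes in three vectorized stages: a coarse lattice of pitch
$\delta_{DTA}/10$ within a $3\delta_{DTA}$ radius (tracking the best nodes
of the two best basins more than $\delta_{DTA}/4$ apart), a dense local
scan at 1/30 of the coarse pitch around each basin node, and a halving-step
pattern search. The dense scan exists because bilinear interpolation makes
kinked micro-valleys at grid-cell boundaries that are narrower than the
coarse pitch; descent alone can converge to the wrong micro-basin and
overestimate γ by ~0.05. The independent oracle
(`gamma_2d_bruteforce`) uses a per-point exhaustive $\delta_{DTA}/20$
lattice followed by Nelder–Mead polish from up to three distinct basins;
fast and oracle agree to 0.02 per point on random smooth plane pairs.

The 2.5D analysis compares one measured plane against calculated planes at
depths shifted by up to ±3 mm (1 mm water = 0.1 g/cm²) in steps of 1 mm
(the clinical figure pair suggests 2 mm was used; 1 mm is the safer
default), reporting the per-depth pass-rate table and the best depth, with
ties broken toward the nominal depth (the null hypothesis of correct
range). The 3D variant searches laterally within each evaluated slice
(continuously) and discretely across slices with the physical 3D distance
in the DTA term; no inter-slice depth interpolation is performed — the
slices are the data.

The QA cascade applies the 90% action level: pass at 2%/2 mm; else review
at 3%/3 mm; else run the 2.5D search and pass/fail on its best rate.

# Log-file analytics

The vendor log format is proprietary, so a documented CSV schema carries
exactly the analyzed quantities: planned and recorded position and MU per
spot per fraction. Deviations are recorded − planned at isocenter.
Multi-burst deliveries are MU-weighted pre-aggregated. Reproducibility is
the per-spot cross-fraction SD, pooled per axis with its degrees of
freedom, so tests can check it against the exact χ² sampling interval.
Histograms use 0.1 mm bins (resolving the 0.2 mm reproducibility scale) and
the range auto-extends so every record is counted. Pattern QA lays spots on
square or diagonal lattices with known perturbations of 1, 2 and 3 mm and
flags spots whose mean recorded deviation exceeds 0.5 mm; at the clinically
observed jitter (≤ 0.15 mm) detection is exact.

# The synthetic world

The generators state the world the tests live in:

* machine model: 94 energies, nominal ranges 4.0–30.6 g/cm² evenly spaced,
  range–energy law from the endpoint calibration; straggling
  $\sigma = 0.012 R_0^{0.935}$ (the empirical ~1.2% of range rule); in-air
  spot σ shrinking 6 → 3 mm with energy; in-water scattering growth
  reaching 2.1% of range at the range, split 40/60 linear/quadratic; halo
  weight 3%, scale 10 mm + 0.3 mm/(g/cm²).
* measurement noise default 1% multiplicative; delivery jitter default
  0.2 mm per axis and 0.5% MU — the clinically reported scales.
* SFUD fields: spots on a square lattice, layer weights from Lawson–Hanson
  nonnegative least squares against the engine's own central-axis
  depth-dose basis, flattening the span [target − modulation, target].
  Layer selection extends ~2 straggling widths beyond the target so a
  Bragg peak sits just past the distal edge; without it dose at the deepest
  selected peak cannot be held flat and the distal end of the span ripples
  by ~10%. Achieved flatness with 2.5 mm layer spacing is ~0.2%.
* IMPT-like fields multiply SFUD weights by a smoothed log-normal field
  with configurable correlation length.

What a green test establishes is internal consistency of the full chain on
physically scaled synthetic data — not agreement with any clinical
measurement. Detector spatial response, ionization-chamber volume
averaging, setup errors beyond rigid shifts, and beam-model mismatch
between "measured" and calculated planes are deliberately absent unless
injected through the noise model.

# Numerical choices and degenerate inputs

* Quadrature and truncation tolerances as above; all engine paths are
  deterministic and seed-free, all generators are pure functions of
  (parameters, seed).
* Sub-threshold-only comparisons return `n_evaluated = 0` with a warning,
  not an error; disjoint grids are an error.
* Reference points whose location falls outside the evaluated grid are
  excluded like sub-threshold points.
* Depths beyond the deepest configured range yield a valid near-zero plane
  flagged `beyond_range`.
* The acceptance-report target list of the build contract is empty; the
  acceptance suite is property-based (`test-acceptance.R`) and
  `scripts/acceptance.R` emits an empty JSON object after an end-to-end
  smoke run.

# Known limitations

Parallel-beam geometry; water only; no nuclear-halo Monte Carlo; constant
kernel weights in depth; discrete depth slices in 3D γ; `share = "none"`
fits cannot identify α. The 2.5D depth step actually used clinically is not
published; it is a parameter (default 1 mm).
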