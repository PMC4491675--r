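# protonQA

Patient-specific quality assurance (PSQA) tooling for spot-scanning proton
therapy, in R.

In spot scanning, a treatment field is delivered as thousands of
magnetically steered monoenergetic pencil beams ("spots"), each defined by
an energy layer, a lateral position (x, y) at isocenter, and a monitor-unit
(MU) weight. Before a patient's first treatment, physicists verify each
field: an independent dose calculation is compared against the treatment
planning system and against planar measurements, and after treatment the
machine's spot-delivery logs are checked against the plan. protonQA
implements that computational chain end-to-end on a water phantom, together
with synthetic-data generators so every analysis can be exercised against
known ground truth — no clinical data required.

## What's inside

* **Beam model** — the analytical Bortfeld Bragg curve
  `D(z) = phi * [a1 (R0 − z)^(1/p−1) + a2 (R0 − z)^(1/p)] ⊛ N(0, sigma²)`
  as the integral depth dose (IDD); the range–energy power law
  `R = alpha E^p` (calibrated exactly through the machine endpoints
  72.5 MeV → 4.0 g/cm², 221.8 MeV → 30.6 g/cm²); simultaneous multi-curve
  fitting with shared `alpha, p` (`fit_bortfeld`); a lateral kernel of two
  Moliere-scattering Gaussians plus a normalizable radial Cauchy–Lorentz
  halo term.
* **Dose engine** — `D(x,y) = Σ_i MU_i · IDD(E_i, z_eff) · K(r_i; z_eff)`
  on arbitrary planar grids and depth-dose lines, with range-shifter
  support as a water-equivalent depth shift (`compute_dose_plane`,
  `compute_depth_dose`).
* **γ-index analysis** — the dose-difference / distance-to-agreement
  metric with global normalization and low-dose threshold (`gamma_2d`), a
  brute-force oracle (`gamma_2d_bruteforce`), the depth-searched "2.5D"
  analysis (`gamma_2p5d`), 3D γ on plane stacks (`gamma_3d`), and the
  clinical decision cascade at the 90% action level (`qa_disposition`):
  pass at 2%/2 mm, review at 3%/3 mm, rescue via 2.5D.
* **Log analytics** — spot-log CSV parsing, deviation statistics with
  cross-fraction reproducibility, delivered-dose reconstruction from
  recorded spots/MUs, and pattern-based periodic QA (squares/diagonals with
  1, 2, 3 mm perturbations) (`deviation_stats`, `planned_vs_delivered_dose`,
  `pattern_qa_check`).
* **Synthetic data** — beam libraries, SFUD/IMPT-like fields with
  NNLS-solved layer weights, simulated measurements and delivery logs, all
  pure functions of (parameters, seed) with ground truth returned
  alongside (`make_beam_library`, `make_uniform_field`, `simulate_log`, ...).

See `vignettes/protonQA-methods.Rmd` for the models, parameter defaults,
numerical choices and limitations.

## Worked example

```r
library(protonQA)

lib <- make_beam_library(n_energies = 94)          # 4.0-30.6 g/cm2 machine
uf  <- make_uniform_field(lib, target_range = 15, modulation = 4,
                          field_size_mm = 60, spot_pitch_mm = 6)
grid <- list(origin = c(-25, -25), spacing = 2.5, shape = c(21, 21))
calc <- compute_dose_plane(uf$field, lib, NULL, depth = 13, grid)
meas <- simulate_measurement(calc, noise_model(multiplicative_sd = 0.01, seed = 7))

g33 <- gamma_2d(calc, meas, gamma_criteria(3, 3, 10))
g22 <- gamma_2d(calc, meas, gamma_criteria(2, 2, 10))
qa_disposition(g22$pass_rate, g33$pass_rate)$status

recs <- simulate_log(uf$field, jitter_model(random_sd = 0.2, mu_sd = 0.005,
                                            n_fractions = 33, seed = 7))
deviation_stats(recs)
```

prints

```
SFUD field: 1815 spots, 15 layers, flatness 1.28%
Dose plane 21x21, spacing 2.50 mm, depth 13.000 g/cm^2, max 1.332
Gamma 3%/3 mm (threshold 10%): pass rate 100.0% (441 points)
disposition: pass (route 2%/2mm)
Spot-log deviation report: 59895 records
  dx: mean -0.000 mm, SD 0.200 mm, max |dev| 0.808 mm
  dy: mean -0.000 mm, SD 0.200 mm, max |dev| 0.901 mm
  MU: mean -0.002%, SD 0.501%
  reproducibility (pooled SD across fractions): x 0.200 mm, y 0.200 mm
```

The SFUD field is flat to ~1% over its modulated span; a 1%-noise
"measurement" of the mid-span plane passes 2%/2 mm outright, so the cascade
stops at its first gate; and the simulated 33-fraction log recovers the
injected 0.2 mm spot-position jitter and 0.5% MU noise exactly at the
pooled-SD level — the closed loops the test suite checks at tighter
tolerances.

## Command line

```sh
Rscript -e 'protonQA::pqa_cli()' fixtures --out demo --seed 7
Rscript -e 'protonQA::pqa_cli()' compare \
    --reference demo/measured_plane.txt --evaluated demo/calculated_plane.txt \
    --out demo/report.json --markdown demo/report.md
Rscript -e 'protonQA::pqa_cli()' analyze-log --log demo/spot_log.csv \
    --out demo/deviations.json
Rscript -e 'protonQA::pqa_cli()' pattern-qa --log demo/pattern_log.csv \
    --kind square --pitch 10 --extent 100 --out demo/pattern.json
```

Subcommands: `fixtures`, `compute-dose`, `compare`, `gamma25d`,
`analyze-log`, `pattern-qa`, `report`. Exit codes: 0 ok, 1 validation
failure, 2 usage error.

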