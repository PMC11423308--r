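# redordyn

Site-resolved protein dynamics from REDOR dephasing curves.

`redordyn` is for solid-state NMR spectroscopists who measure effective
heteronuclear dipolar couplings in large protein assemblies — viral
capsids, fibrils, membrane proteins — with pseudo-3D REDOR experiments
(a REDOR dephasing block combined with 2D ¹³C–¹³C mixing such as DARR,
RFDR or INADEQUATE). It turns per-crosspeak intensity tables S(t), S₀(t)
into effective ¹³C–¹⁵N dipolar coupling constants, order parameters and
cone-model motional amplitudes, and provides the supporting machinery:
validation simulations, a structure-based axial-rotation predictor, and a
double-quantum assignment-table generator for scalar-based DQ/SQ spectra.

## The model

For an isolated spin-1/2 pair under ideal rotor-synchronized π pulses the
powder-averaged REDOR dephasing depends only on λ = d·t:

    ΔS/S₀(λ) = 1 − (√2 π/4) · J_{1/4}(√2 λ) · J_{−1/4}(√2 λ)

with J quarter-order Bessel functions, d the effective dipolar coupling
(Hz) and t the dephasing time. Per-crosspeak buildup curves are fit to
this universal curve by χ² minimization, with uncertainties from the
Δχ² = 1 profile interval and replicate crosspeaks pooled per site. The
order parameter of each bond is

    S = d / d_rigid,    d_rigid = (μ₀/4π) · γ_I γ_S ħ / (2π r³)

(1005 Hz for the 1.45 Å Cα–N bond), and motional amplitudes follow from
inverting S = (3cos²θ − 1)/2 (diffusion on a cone) or
S = cosθ(1 + cosθ)/2 (wobbling in a cone) on [0°, 90°].

An explicit powder-integration oracle, an ideal-pulse multi-spin
simulator (for the CαN₂ three-spin validation), and a seeded synthetic
data generator emulating the experimental intensity tables make every
stage testable without spectrometer data. See the vignette
`vignettes/redor-dynamics.Rmd` for the full methods account.

## Worked example

```r
library(redordyn)
cfg <- synthetic_config(seed = 42)
records <- synth_intensities(make_profile(cfg), cfg)

# joint fit of the three crosspeaks reporting on residue 20's CA-N bond
site20 <- Filter(function(r) r$site == "20.CA-N", records)
fit <- combine_site(site20)
fit
#> coupling fit: d = 682.0 +/- 34.6 Hz (reduced chi2 0.69, n = 12)

op <- order_parameter(fit, d_rigid = rigid_coupling(1.45))
round(c(S = op$S, sigma = op$sigma), 3)
#>     S sigma
#> 0.679 0.034
round(c(on_cone = amplitude_on_cone(op$S), in_cone = amplitude_in_cone(op$S)), 1)
#> on_cone in_cone
#>    27.6    39.8

# dephasing time at which a rigid CA-N bond is 80% suppressed
t80 <- redor_filter_time(rigid_coupling(1.45), 0.8, rotor_period = 71.4e-6)
c(time_us = t80 * 1e6, rotor_periods = t80 / 71.4e-6)
#>       time_us rotor_periods
#>        1142.4          16.0
```

The fitted coupling of 682 ± 35 Hz corresponds to an order parameter of
0.68 ± 0.03 (true value for this site: 0.66), i.e. a uniform ~28° motion
under the on-a-cone model or wobbling up to ~40° in a cone. The filter
time says a REDOR filter of 16 rotor periods (1.14 ms at 14 kHz MAS)
suppresses rigid Cα signals by ≥ 80%, leaving mobile sites and sidechains
visible.

A command-line front end covering the whole pipeline (simulate / fit /
dq-assign / predict-axis / filter-time / report) is installed at
`inst/scripts/redor`:

```sh
Rscript inst/scripts/redor simulate --out runs/sim --seed 1
Rscript inst/scripts/redor fit --table runs/sim/intensities.csv --out runs/fit
```

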