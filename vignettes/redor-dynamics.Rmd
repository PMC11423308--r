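---
title: "Measuring C-N bond dynamics from REDOR dephasing curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring C-N bond dynamics from REDOR dephasing curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redordyn)
```

## The measurement and the model

Rotational-echo double resonance (REDOR) recouples a heteronuclear dipolar
interaction under magic-angle spinning by applying rotor-synchronized pi
pulses to the coupled spin. Two experiments are recorded at each dephasing
time $t$: a reference echo ($S_0$) and a dephased experiment ($S$). For an
isolated $^{13}$C-$^{15}$N pair under ideal, instantaneous pulses the
powder-averaged dephasing fraction depends only on the product
$\lambda = d\,t$ of the effective dipolar coupling constant $d$ (Hz) and
the dephasing time:

$$\frac{\Delta S}{S_0}(\lambda) \;=\; 1 -
  \frac{\sqrt{2}\,\pi}{4}\,
  J_{1/4}\!\left(\sqrt{2}\lambda\right)
  J_{-1/4}\!\left(\sqrt{2}\lambda\right),$$

the closed-form solution of the powder average of the first-order MAS
dipolar phase, with $J_{\pm 1/4}$ quarter-order Bessel functions
(`redor_universal()`). The package also carries a first-principles oracle,
`redor_powder()`, which accumulates the sign-toggled per-crystallite phase
$\Delta\Phi = 4\sqrt{2}\, d\, t\,\sin\beta\cos\beta\sin\gamma$ and averages
$\cos\Delta\Phi$ over a Gauss-Legendre-in-$\cos\beta$ $\times$
uniform-$\gamma$ grid. The two agree to machine precision, which pins down
every convention (prefactor, phase normalization) at once; the test suite
asserts agreement below $10^{-3}$ on a $10^4$-orientation grid over
$\lambda \in [0, 3]$.

Motion faster than the inverse coupling ($\lesssim$ ms here) scales the
effective coupling by the order parameter

$$S \;=\; \frac{d}{d_\mathrm{rigid}},
\qquad d_\mathrm{rigid} \;=\;
\frac{\mu_0}{4\pi}\,\frac{\gamma_I \gamma_S \hbar}{2\pi r^3},$$

with CODATA constants ($\gamma_{^{13}\mathrm{C}} = 6.728284\times 10^7$,
$\gamma_{^{15}\mathrm{N}} = -2.7126\times 10^7$ rad s$^{-1}$ T$^{-1}$,
magnitudes used). A 1.45 Å C$\alpha$-N bond gives 1005 Hz and the 1.40 Å
tryptophan C$\varepsilon_2$-N$\varepsilon_1$ bond 1116 Hz, both rounded to
integer Hz. Amplitudes of motion are reported under two standard cone
models, inverted on $[0°, 90°]$ from $|S|$ (the experiment is insensitive
to the interaction's sign):

* diffusion **on** a cone: $S = P_2(\cos\theta) = (3\cos^2\theta - 1)/2$,
  inverted as $\theta = \arccos\sqrt{(2|S|+1)/3}$;
* diffusion (wobbling) **in** a cone of maximal angle $\theta$:
  $S = \cos\theta\,(1+\cos\theta)/2$, inverted through the positive root of
  the quadratic in $\cos\theta$.

The negative $P_2$ branch ($\theta > 54.7°$, only meaningful for
$|S| \le 0.5$) is available behind an explicit flag and never reported by
default.

## From intensities to couplings

`assemble_buildup()` converts per-crosspeak intensity tables to fractions
$f_i = 1 - S_i/S_{0,i}$ with first-order error propagation of the spectral
RMS noise $\sigma$ through the ratio,
$\sigma_f = \sqrt{(\sigma/S_0)^2 + (S\sigma/S_0^2)^2}$. Points whose
reference intensity falls below an SNR floor (default $S_0/\sigma \ge 3$;
the experimental contour floors of 6-10 guided the synthetic defaults) are
dropped, and fewer than three surviving points is an error rather than a
silent bad fit.

`fit_coupling()` minimizes
$\chi^2(d) = \sum_i (f_i - \Delta S/S_0(d t_i))^2/\sigma_i^2$ by a coarse
scan (default 0-1200 Hz in 2 Hz steps, covering plausible one-bond C-N
couplings) followed by local refinement. Flat valleys are broken towards
the smallest coupling within 0.01 $\chi^2$ units. The uncertainty is the
symmetric-ized $\Delta\chi^2 = 1$ profile interval; a minimum at the grid
edge raises a warning and is flagged. All points are used by default; an
optional `fraction_cap = 0.6` restricts the fit to the initial rise, which
suffices for well-resolved 1D work, but pseudo-3D data extend beyond the
rise and benefit from the full curve.

Replicate crosspeaks reporting on one bond are combined by
`combine_site()`, by default pooling all points into one joint fit (the
uncertainty then shrinks like $1/\sqrt{n}$, which the tests check on
simulation); inverse-variance averaging of per-crosspeak fits is available
as an alternative. Overlapped crosspeaks whose assignment is ambiguous
between two sites are fitted to a single dephasing curve and flagged; the
synthetic generator builds such pairs with equal true couplings, matching
the experimental observation that ambiguous pairs share order parameters.

## The three-spin validation

The two-spin fit assumes an isolated pair, but a backbone C$\alpha$ also
couples to the next residue's amide nitrogen (about 2.43 Å away, roughly a
200 Hz coupling). `redor_multispin()` simulates the ideal-pulse dephasing
of a spin coupled to several heteronuclear spin-1/2 partners. Because the
per-partner Hamiltonians commute and each partner is independently up or
down, the exact ideal-pulse signal is the powder average of the *product*
of per-partner cosines, $\langle\prod_k\cos\Delta\Phi_k\rangle$ — not the
cosine of the summed phase, which would correspond to both partners
flipping coherently and misestimates couplings by up to $\pm 20\%$
depending on geometry. The two-angle powder grid is augmented internally
with a uniform average over the third Euler angle, on which only the
*relative* azimuths of multiple bond vectors depend; a single-partner
cluster reduces to the two-spin result exactly.

For the C$\alpha$N$_2$ cluster built from the ideal-helix geometry
(couplings 1005 and 200 Hz, bond vectors at about 90° to each other),
fitting the simulated curve on the experimental dephasing-time grid with
the two-spin universal curve overestimates the strong coupling by about
11.6 Hz (1.2%) — computed by the acceptance script at run time. That bias
is physical for ideal pulses (a first-order perturbation estimate gives
the same scale) and is comparable to, and smaller than, the 5-10% fit
error from experimental noise, so the two-spin treatment remains adequate;
note that finite pulses, deliberately not modelled here (they
underestimate couplings by roughly 2% at these conditions), act in the
opposite direction. Homonuclear partners are refused explicitly: their
recoupling does not commute and needs full density-matrix propagation,
which is out of scope.

## Predicting order parameters from structure

A plausible global motion for a filamentous assembly is fast uniaxial
rotation about the filament axis. `bond_axis_angles()` computes, per
residue, the angle of the C$\alpha\to$N bond vector (direction is
irrelevant: $P_2$ is a rank-2 property) to an axis — by fiber-deposition
convention the z axis, overridable — and the order parameter
$|P_2(\cos\theta)|$ that such a rotation would impose.
`compare_to_experiment()` joins these predictions with measured order
parameters and reports the RMS discrepancy and both profiles' ranges,
leaving the scientific judgement to the reader.

One geometric subtlety matters for the desk-scale reproduction: in an
ideal helix *aligned* with the rotation axis all residues are related by a
rotation about that axis, so every C$\alpha$-N bond makes the same angle
to it and the predicted profile is flat. The large residue-to-residue
oscillations seen for the real coat protein arise because its helix is
tilted (about 20°) from the virion axis. The tests and the acceptance
script therefore evaluate the synthetic helix against an axis tilted 20°
from the helix axis, which makes the bond-to-axis angle sweep a wide range
every helical turn: the predicted $|S|$ then spans more than 0.5 while a
uniform experimental profile at 0.66 spans essentially zero — the
structure of the rejection argument. Periodicity is detected on the angle
series (3.57 residues for an ideal helix, the 100°-per-residue twist)
because taking $|P_2|$ folds the oscillation wherever it crosses the magic
angle and moves spectral weight to harmonics.

## Double-quantum assignment tables

Scalar-based INADEQUATE-type spectra disperse crosspeaks by the
double-quantum frequency of directly bonded carbon pairs, which is exactly
the sum of the two single-quantum shifts. `parse_assignments()` reads the
chemical-shift loop of an NMR-STAR 3.x file (a minimal loop tokenizer,
scoped to `_Atom_chem_shift` tags, written here because no installed R
package reads NMR-STAR), retaining carbon and nitrogen rows and rejecting
duplicate assignments. `enumerate_dq()` walks a built-in one-bond
carbon-carbon topology for the 20 standard residue types — backbone
C$'$ bonded to C$\alpha$, sidechain carbonyls included, aromatic rings per
standard bonding, no two-bond pairs — and emits *two* peaks per bonded
pair with both members assigned (each member appears once in the SQ
dimension, as both crosspeaks show in the spectra); pairs with a missing
member are skipped and counted. `write_peaklists()` writes Sparky-style
lists and a CSV twin with byte-stable ordering so downstream peak-analysis
tools see deterministic input.

## What the synthetic data emulate — and what they do not

`synthetic_config()` fixes the study conditions: 50 residues; a monotone
linear ramp of the order parameter from 0.16 at residue 1 to the 0.66
plateau at residue 6 (flexible N-terminus, uniform helix); rotor period
71.4 μs (14 kHz MAS) with dephasing times of {6, 8, 16, 24} rotor periods
(429-1714 μs, even rotor multiples as REDOR requires); SNR 10; three
crosspeaks per bond (the experiments yielded 148 crosspeaks over about 42
sites); 4% of sites ambiguity-paired (6 of 148). Reference amplitudes are
drawn uniformly in [50, 150] arbitrary units and noise is *additive
Gaussian on the intensities* with SD $A/\mathrm{SNR}$ — spectral noise,
which is where RMS noise actually enters — not on the fractions. Every
draw is governed by a single recorded seed.

The generator does **not** emulate: finite-pulse effects, relaxation
losses during the REDOR echo trains, homonuclear couplings and dipolar
truncation, spinning-speed instability, lineshapes, peak overlap beyond
the explicit ambiguity pairs, or 2D peak picking. Passing tests therefore
demonstrate that the *analysis* recovers what the generative model puts
in at realistic noise; they do not certify performance against
instrumental imperfections, which enter real data as part of the quoted
5-10% fit error.

## Numerical choices and problem sizes

* Powder scheme: Gauss-Legendre in $\cos\beta$ crossed with uniform
  midpoint $\gamma$, 64 × 64 by default — deterministic, and refinement
  convergence is testable; the oracle-equivalence test uses 100 × 100.
* Multi-spin third-angle average: 16 uniform points; doubling changes the
  C$\alpha$N$_2$ result by well under 0.1 Hz.
* $\lambda = 0$ is returned exactly as 0 (the Bessel product is an
  indeterminate form there); the curve's first maximum, needed by the
  filter-time search, is located once by bounded optimization.
* `redor_filter_time()` inverts the initial rise by root bracketing and
  rounds *up* to an even rotor-period multiple, so the realized dephasing
  meets or exceeds the target; because the first maximum is about 1.04,
  every target below 1 is reachable.
* Degenerate inputs fail loudly: empty or unnormalized powder grids,
  non-unit bond vectors, homonuclear clusters, duplicate shift
  assignments, conflicting site assignments, all-dropped buildup points.
* Test problem sizes: 100 synthetic sites for recovery, $10^4$ powder
  orientations for oracle equivalence, 50-residue helices for geometry —
  each runs in seconds while leaving no parameter at a toy scale.

## Known limitations

Order parameters above 1 (possible under noise) are retained and flagged
rather than clipped, except inside the cone-angle columns of the site
table, where $S$ is capped at 1 to keep the inversion defined. The
NMR-STAR reader handles the common single-loop v3.x layout, not the full
STAR grammar. The ideal-pulse multi-spin simulator is exact for
heteronuclear spin-1/2 partners but the ~1% C$\alpha$N$_2$ fit bias it
reveals is inherent to the two-spin approximation at these couplings, and
users fitting very precise data may wish to subtract it. The axial
prediction uses a single chain and does not expand fiber symmetry.
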