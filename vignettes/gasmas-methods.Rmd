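---
title: "Methods: simulating and inverting GASMAS measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and inverting GASMAS measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gasmas)
```

## The measurement model

Gas in scattering media absorption spectroscopy (GASMAS) senses free gas
enclosed in a turbid object by scanning a narrow-linewidth laser across a
single molecular absorption line. Solid tissue attenuates broadly and
smoothly; the gas imprints a spectrally sharp dip. The package models a
dual-laser instrument with one oxygen A-band channel near 764 nm and one
water-vapour channel near 820 nm, spectrally close enough that both colours
share one optical pathlength through the gas.

For a single line, the detected intensity along the scan detuning
$\Delta\nu$ is

$$I(\Delta\nu) = I_0\,B(\Delta\nu)\,T_{tissue}\,
  e^{-\mu_a(\Delta\nu)\,l},$$

where $B$ is the slowly varying injection-current baseline, $T_{tissue}$
the scalar broadband tissue transmission, $\mu_a$ the gas absorption
coefficient (cm$^{-1}$) and $l$ the gas pathlength (cm). The inversion is
the classical two-step GASMAS inference:

1. **Pathlength from humidity.** The administered gas is saturated
   (RH = 100%), so the water-vapour density is known from temperature alone:
   the Arden Buck equation gives the saturation vapour pressure
   $e_s(T) = 611.21\,\exp[(18.678 - t/234.5)\,t/(257.14+t)]$ Pa ($t$ in
   °C; Buck's 1996 over-liquid fit, no enhancement factor — the factor is
   below 0.5% at ambient pressure, far under the other uncertainties), the
   ideal gas law converts the partial pressure $e_w' = RH\cdot e_s$ to a
   number density $N = e_w'/(k_B T)$, and the HITRAN-style line strength
   and shape give the peak absorption coefficient
   $\mu_a^{peak} = N S \phi_V(0)$. The fitted 820 nm peak absorbance then
   yields $l = A_{820}/\mu_a^{peak}$.
2. **Oxygen from the shared pathlength.** On the 764 nm channel,
   $c_{O_2} = A_{764}/(l\,\kappa)$ with
   $\kappa = N_{dry} S_{O_2} \phi_V(0)$ the peak absorption per unit mole
   fraction. The oxygen fraction is defined on the **dry-gas basis**
   ($N_{dry} = (P - e_w')/(k_B T)$): delivered gas mixtures are specified
   before humidification, so "100% O₂" means oxygen occupying everything
   that is not water vapour. Estimates are deliberately not clipped to
   $[0,1]$; impossible values are informative downstream.

All inversions use the **peak** (line-centre) absorbance rather than the
integrated line area, consistent with quoting a peak $\mu_a$ for the
reference gas. Internally SI units are used; spectroscopic axes and
absorption coefficients are in cm$^{-1}$ and reported pathlengths in
metres/millimetres.

## Line shapes and the packaged line fixtures

Absorption lines are Voigt profiles: a Doppler (Gaussian) core of standard
deviation $\sigma_G = \nu_0\sqrt{k_B T/(m c^2)}$ convolved with a pressure
(Lorentzian) component whose half width scales linearly with total
pressure. The profile is evaluated through the complex Faddeeva function
$w(z)$ using Weideman's rational approximation with 32 terms, accurate to
about $10^{-12}$ relative over the needed domain (validated against
brute-force quadrature in the test suite); the line-centre value uses the
exact identity $\phi_V(0) = \mathrm{erfcx}(\gamma/\sigma\sqrt2)/
(\sigma\sqrt{2\pi})$.

The package ships one representative single-line fixture per channel in a
plain-text constants file (`inst/extdata/spectral_lines.txt`): a
water-vapour line at 12195.1 cm$^{-1}$ (820.0 nm) and an oxygen A-band
line at 13092.4 cm$^{-1}$ (763.8 nm). Strengths and air-broadened widths
are representative of these bands and calibrated so that the fixtures
reproduce the two accepted anchor values for this instrument class:
saturated water vapour at 293 K gives a peak $\mu_a$ of
$3.04\times10^{-5}$ cm$^{-1}$ (accepted value $3.1\times10^{-5}$), and
ambient air (21% O₂) gives $2.6\times10^{-4}$ cm$^{-1}$ on the A band.
Every function accepts caller-supplied `spectral_line()` objects, so no
analysis depends on the fixtures. Multi-line spectra, full HITRAN record
parsing and temperature scaling of line strengths are out of scope — the
instrument operates in a single ambient-temperature regime.

One numerical caveat worth stating: Lorentzian wings are fat. At the
820 nm line's pressure width ($\gamma = 0.05$ cm$^{-1}$) about 5% of the
unit area lies beyond the ±0.6 cm$^{-1}$ scan window, and even ±10 half
widths still miss ~6%. Area-normalisation checks therefore integrate on a
wide grid (±100 Lorentz widths); the scan window itself only needs to
cover the line *core*, and a diagnostic warns when a grid is narrower than
±10 Voigt half widths (Olivero–Longbothum approximation).

## What the synthetic generator emulates

`default_design()` reproduces the phantom measurement protocol: 30
source–detector configurations (15 tracheal transmittance + 15 dermal
remittance), 21 replicate detector reattachments per configuration, and
nominal O₂ concentrations of 21, 30, 50 and 100% administered in that
order. Detector positions 10/11 and 14/15 within each arm are deliberate
repeats of one physical position (a reproducibility control) and share one
ground truth. Geometry (two thorax anatomies), phantom optical-property
set (764 vs 820 nm) and body side are assigned deterministically from the
position index; the assignment is arbitrary but fixed, since only the
per-configuration truth matters to the statistics.

`sample_truth()` draws, per physical position:

* a true pathlength uniform on **0.01–0.20 m**, reused across all
  concentrations (the upper edge sits below the 0.23 m outlier bound so
  honest inversions rarely trip the filter);
* a tissue transmission $\exp(-\mu_{eff} d)$ with
  $\mu_{eff} = \sqrt{3\mu_a(\mu_a+\mu_s')}$ from the phantom muscle
  optical properties at the configuration's wavelength set
  (2.93 cm$^{-1}$ at 764 nm, 2.79 cm$^{-1}$ at 820 nm) and an effective
  layer thickness uniform on 5–25 mm. The multi-organ thorax is collapsed
  to this single scalar: it reproduces the signal-strength-vs-geometry
  phenomenology without photon transport, which is deliberately out of
  scope;
* two configurations (default) are forced to a transmission of $10^{-7}$,
  far below the detector floor, to populate the failed-inversion/outlier
  class the protocol anticipates.

`simulate_scan()` then builds each record on a 512-point grid spanning
±0.6 cm$^{-1}$ with a mild quadratic baseline
$B(u) = 1 + 0.15u - 0.05u^2$ (the scan-ramp shape is not critical; any
smooth low-order curve exercises the same fitting problem).

**Noise model.** Additive Gaussian noise with standard deviation

$$\sigma(\Delta\nu) = \texttt{noise\_rel}\cdot I_0 B(\Delta\nu)\,
  (T_{tissue} + \texttt{dark\_frac}),$$

with `noise_rel` $=10^{-5}$ and `dark_frac` $=10^{-4}$ by default. For
ordinary transmissions this is simply noise proportional to the local
intensity — the usual TDLAS absorbance sensitivity of ~$10^{-5}$ — while
the `dark_frac` term models the detector's dark/electronic floor, which
dominates when the sample transmits almost nothing. This floor is what
makes strongly attenuated placements genuinely fail (their effective
relative noise grows as $1/T_{tissue}$) and makes replicate scatter shrink
as transmission grows; without it, a purely proportional noise would make
every placement equally measurable, which is not how detectors behave.
Intensities are clipped at a positive floor ($10^{-6} I_0$) and flagged;
a clipped record is treated as undetected in the inversion, because a
flat clipped stretch can fit arbitrarily well and its SNR is meaningless.

**Seeds.** Every record's noise draw is governed by a 31-bit hash of
(master seed, configuration, replicate, concentration, channel), so a
single record can be regenerated in isolation and the full dataset is
byte-identical under a fixed master seed. The generator restores the
caller's RNG state.

**Gas-mixing bias.** Imperfect purging mixes each administered gas with
what the cavities already hold:
$c^{eff}_k = (1-\beta)c^{nom}_k + \beta c^{eff}_{k-1}$, anchored at air
(21%). With $\beta = 0.2$ the effective sequence for 21/30/50/100% is
21/28.2/45.6/89.1% — a negligible shift at 21%, under 2 percentage points
at 30%, and an 11-point shortfall at 100%, which is exactly the
qualitative pattern of concentration underestimation the protocol
attributes to insufficient purging. The generator knows the effective
truth, so recovery can be scored against it.

## The absorbance fit

`extract_absorbance()` fits $I = B(\Delta\nu)\,e^{-A\psi(\Delta\nu)}$ with
a polynomial baseline (order 2, matching the generator's ramp; the order
is a parameter) and $\psi$ the unit-peak Voigt shape implied by the
ambient conditions. The absorbance enters through a profiled 1-D
optimisation: for fixed $A$ the baseline is an exact linear least-squares
solve (on the deconvolved signal $I e^{A\psi}$), so `optimize()` searches
a single smooth coordinate on $[-0.05, 0.5]$ with tolerance $10^{-10}$ and
cannot diverge on noisy data. Initialisation is therefore a non-issue.
Negative optima beyond $10^{-6}$ are clipped to zero and flagged
non-converged, as is an optimum at the search bound.

The reported SNR is the fitted line depth at centre over the residual RMS
(per grid point). An estimate is *detected* when the fit converged and
SNR ≥ 3 — the conventional detection limit, configurable. A failed or
undetected 820 nm fit maps to **pathlength 0**, not missing, so the
protocol's "0 m" outlier class is populated identically; a failed 764 nm
fit keeps the pathlength but invalidates the O₂ estimate.

At default noise the per-replicate absorbance error is
$\sigma_A \approx 2\times10^{-6}$, i.e. sub-1% pathlength scatter for
typical (≥ 3 cm) pathlengths. A consequence worth knowing: a configuration
whose true pathlength sits near 1 cm has $A_{820}\approx 3\times10^{-5}$,
right at the SNR-3 detection limit, and the validity gate then truncates
the low side of the replicate distribution, biasing the surviving mean
upward by a few percent. This is real detection-limit behaviour, not a
fitting artefact; it is visible in the acceptance quantities for truth
draws that place a configuration at the bottom of the pathlength support.

## Outliers, aggregation, comparability

The protocol's outlier rule is applied verbatim: a replicate is an outlier
when its pathlength is 0 m (within $10^{-12}$ m) or **strictly** above
0.23 m, or when its inversion failed. Means and sample SDs (n−1) per
configuration are computed over the surviving replicates — exclusion is
the only reading that keeps aggregated means inside the physical range —
and configurations whose replicates are all excluded are reported as
empty rather than NaN.

Configuration comparability uses a from-scratch two-sample
Kolmogorov–Smirnov test ("KS t-test" in protocol parlance can only mean
this — there is no KS variant of a t-test): $D$ is the supremum ECDF
distance over pooled points (tie-safe), and the two-sided p-value uses the
Kolmogorov series with the effective-sample-size correction
$\lambda = (\sqrt{n_e} + 0.12 + 0.11/\sqrt{n_e})D$, truncated at terms
below $10^{-10}$. The statistic is validated against exhaustive
permutation enumeration, and it matches exactly. The **p-value** is a
large-sample approximation: at the replicate sizes this pipeline uses
(n = 21 per group, $n_e = 10.5$) it tracks the exact permutation
distribution to within ~0.07 with a null rejection rate of ~4% at the
0.05 level, which is fit for purpose; below roughly $n_e = 4$ (e.g. both
samples ≤ 6) the approximation departs from the exact p by amounts that
can exceed 0.5 and should not be used for inference. Comparisons carry no
multiple-testing correction by default, matching the protocol's
per-comparison p > 0.05 practice; Holm correction is available via a
flag. The *comparability rate* across the design is defined here as the
share of all per-configuration concentration-pair comparisons with
p > 0.05 (a per-comparison quantity, null expectation ≈ 95%); a
per-configuration "all six pairs" reading would impose a familywise
requirement the protocol never states.

Concentration box summaries use the linear-interpolation quantile
convention (R type 7) with 1.5 IQR whiskers; the convention is stated
because box statistics are not unique.

## Problem sizes and determinism

The default design produces 30 × 21 × 4 × 2 = 5040 scan records and 2520
inversions; simulating takes well under a minute and the full inversion a
few seconds per thousand records on one core. The test suite exercises the
full default design for the end-to-end checks and smaller crossed designs
(2–6 configurations, 2–5 replicates) for unit-level properties; the
KS-versus-permutation validation enumerates all assignments for sample
sizes up to 6 per group. `run_pipeline()` is byte-deterministic under a
fixed configuration (content-hashed manifest; the manifest's timestamp and
wall time are the only varying fields).

## What passing tests do and do not show

The generator reproduces the *structure* of the phantom experiment — the
design, the Beer–Lambert physics, humidity-referenced inversion, noise
scaling with attenuation, the mixing-bias direction — with known ground
truth, so the tests demonstrate that the inference chain is correct and
well-calibrated under its own assumptions. They do not certify behaviour
on real instrument data: real scans carry wavelength-modulation harmonics,
étalon fringes, baseline drift correlated across replicates, multi-line
interference and speckle, none of which are modelled. The scalar
tissue-transmission stand-in reproduces signal-strength phenomenology but
not the geometry dependence a photon-transport model would give; the
shared-pathlength assumption is taken as exact, as the inversion itself
does. Ingesting real instrument data is a documented extension point
(`read_dataset()` accepts any conforming JSON-lines/CSV pair).
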