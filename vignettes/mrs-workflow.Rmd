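---
title: "Models and numerical choices in mrsproc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical choices in mrsproc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsproc)
```

This vignette documents the scientific models the package implements, the
conventions and numerical choices behind them, and the limits of what the
test suite demonstrates. It is the reference for every decision a user or
reviewer might want to interrogate.

## Data model and transform conventions

An MRS dataset is a complex cube of repetitions x receive channels x FID
points, plus an acquisition header: transmitter (Larmor) frequency in MHz,
spectral width in Hz (dwell time `1/bw`), number of complex points, and the
ppm calibration of the carrier (`center_ppm`, typically water at 4.65 ppm
for in vivo 1H work).

The forward transform is the plain DFT scaled by `1/N` and rotated so the
carrier sits at the center bin; the ppm axis is stored ascending, with the
carrier bin carrying `center_ppm` exactly and the axis spanning
`center_ppm + [-bw/2, bw/2)/larmor`. This scaling makes amplitude and noise
bookkeeping explicit: a constant FID of value A becomes a single bin of
height A, and white time-domain noise of SD `sigma` becomes spectral noise
of SD `sigma/sqrt(N)` per point. Parseval then reads
`sum |fid|^2 = N sum |spec|^2`, and both identities are enforced by tests.

The first FID point is *not* halved before the transform by default. Halving
it removes the well-known constant offset that a sampled decaying
exponential otherwise leaves across the spectrum (about `A/(2N)` per bin),
but it is a modeling choice, not part of the transform, so it is exposed as
`to_spectrum(..., first_point_half = TRUE)` and off by default. Several
tests use it where a clean off-peak baseline is the point of the check.

Phases are degrees at every interface and radians internally. First-order
phase is linear in ppm about an explicit pivot (default: the carrier ppm),
so a pivot is never hidden in a convention. Frequency shifts are exact
time-domain phase ramps, not circular bin shifts.

## Preprocessing

**Eddy-current / phase correction.** The pointwise method multiplies the
metabolite FID by `exp(-i arg(water_n))`; any phase corruption common to
metabolite and water cancels identically, which the tests verify to 1e-12.
Water points of exactly zero magnitude contribute phase 0 with a warning.
The first-point variant applies a single global rotation and coincides with
the pointwise method when the water phase is time-constant.

**Channel combination.** Each channel is phase-corrected with its own water
reference and averaged with weights `w_c = |water_c(0)|` (sensitivity
weighting) or uniformly. With equal channel noise this weighting is
proportional to the matched-filter weight and yields the expected
`sqrt(2)` SNR gain for two equal channels.

**Alignment.** Repetitions are aligned to a reference (default: the mean of
all traces, which has the best SNR) by exhaustive grid search. The score

S(df, phi) = sum_k |R_k| Re( e^{-i phi} conj(R_k) T_k(df) ) /
sqrt( sum_k |R_k|^2 sum_k |T_k|^2 )

is evaluated over the user's frequency windows, where `R` is the reference
spectrum and `T(df)` the candidate trace shifted by `df`. The published
description of the underlying tool names an "amplitude-weighted
cross-correlation" without giving its formula; the normalization above is
this package's own definition and is stated as such. The search is a joint
product grid over `df` (range and resolution in Hz) and `phi` (step in
degrees); because the cross term `C(df) = sum_k |R_k| conj(R_k) T_k(df)`
does not depend on `phi`, the phase leg costs one complex rotation per grid
point, which is the "analytically assisted" fast path — it enumerates the
same grid and returns the same answer as the naive double loop. Ties break
toward smaller `|df|`, then smaller `|phi|`, making results deterministic.
Amplitude alignment fits a real polynomial over ppm (order 0 = a single
scale factor, the default and the conservative reading of "polynomial order
for amplitude alignment") by least squares inside the windows.
Metric-only preprocessing (line broadening, cut, zero-fill) sharpens the
score without ever leaking into the output data. A practical note from the
estimator's behavior: a residual frequency error `e` biases the phase
estimate by roughly `2 pi e t_bar`, where `t_bar` is the signal's
amplitude-weighted mean time; moderate metric line broadening (a few Hz)
shrinks `t_bar` and thus decouples the two, at some cost in frequency
precision. The recovery tests use 3 Hz.

The correction table reports, per repetition, the frequency shift *applied*
(`df_hz`), the phase offset *detected* relative to the reference
(`phi0_deg`, removed from the trace), and the amplitude coefficients.

**JDE.** Editing conditions differ in spectral content by design, so every
correction runs separately per condition against condition-specific
references before the two averages and their difference are formed
(`DIFF = ON - OFF`, first label minus second).

**QA.** Six statistics (min, max, mean, median, SD, integral) of the real
part in any ppm window, per repetition; the integral is a Riemann sum times
the ppm bin width. Thresholds produce pass/fail flags but nothing is
discarded automatically — outlier rejection is the user's decision.

## Spectral processing

**HSVD.** The FID is embedded in a Hankel matrix split at `ceiling(N/2)`
rows, truncated to rank K by SVD; signal poles come from the least-squares
shift invariance of the truncated left singular vectors (Kung's method),
amplitudes and phases from a linear fit. Components are reported as
frequency (Hz from the carrier), Lorentzian damping (FWHM in Hz), amplitude
and phase; growing components (negative damping) are kept but flagged. On
noiseless sums of at most K damped exponentials the reconstruction is exact
to better than 1e-8 relative, which is the test's oracle. Water removal
subtracts the components whose frequency falls in the user's band (e.g.
4.2–5.1 ppm around water at 4.65 ppm).

**Advanced two-spectrum alignment.** Up to 8 aspects — frequency shift,
zero- and first-order phase, Lorentzian and Gaussian broadening, amplitude
scale, constant offset, polynomial baseline — are fit by Levenberg–Marquardt
on the windowed complex residual, with a numerically estimated Jacobian,
objective and step tolerances of 1e-8, and a multi-start from identity plus
a coarse frequency scan (the frequency/phase ambiguity is the classic local
minimum here). The transform applies broadening, shift and scale in the
time domain, then phase, offset and baseline in the frequency domain.
Broadenings are bounded below by zero — a spectrum can be broadened to
match, never sharpened — so in JDE use the *sharper* condition should be
aligned onto the broader one. The returned solution never has a larger
windowed residual than the identity parameters; if the optimizer fails to
improve, identity is returned with a warning. The exact list and order of
the 8 aspects is this package's reading of the published summary, which
does not enumerate them.

**Metrics.** SNR is the real-part maximum in the signal window divided by
the SD of the real part in the noise window after first-order detrending,
with no factor-of-2 convention — published SNR conventions vary and the
underlying tool's is not documented, so the definition here is stated
explicitly and no printed SNR value from the literature is used as a
target. FWHM interpolates the half-maximum crossings of the tallest
real-part peak linearly; on a coarse grid, zero-fill first. Integrals are
Riemann sums times the ppm bin width.

## Synthesis and the fixture generator

Singlets are exponentially damped complex sinusoids
`A e^{i 2 pi (ppm - center) larmor t} e^{-pi lw t}`, giving Lorentzian lines
of FWHM `lw` Hz at the stated ppm. Noise is added *in the frequency domain*
(independent Gaussian per real/imaginary component of every point, seeded)
on the synthesis path, matching how the synthesis workflow is described;
the raw-data fixture generator instead adds noise *in the time domain*,
which is the physically realistic channel model. Both paths exist, are
labeled, and are parameterized by an explicit SD, because the source
material is internally inconsistent about the domain and never defines the
scale of its noise parameter.

The fixture generator emulates, per trace: channel sensitivity and receiver
phase, per-repetition frequency drift (Gaussian, default SD 2 Hz, the scale
of slow scanner drift) and phase instability (default SD 15 degrees,
respiration-scale), additive complex noise, alternating ON/OFF labels with
an edited resonance present only in ON, and consistent noiseless water
references (50x the strongest metabolite). Defaults — 16 repetitions, 4
channels with sensitivities 1/0.6/0.3/0.15 and phases 0/120/240/60 degrees,
noise SD 0.5 — are chosen once as a realistic surface-coil-array scenario
in which phasing, weighting and alignment each have visible work to do.
What the generator does *not* emulate: lineshape distortions beyond
Lorentzian, macromolecule backgrounds, frequency-dependent coil phase,
motion-correlated amplitude changes, and non-white noise. Passing tests
therefore demonstrate correctness of the algorithms under their stated
models, not robustness to every artifact of real data.

Every generator is a pure function of (parameters, seed): the same seed
reproduces the same dataset bit for bit.

## Density-matrix simulation

Spin systems are defined by chemical shifts (ppm) and a symmetric J matrix
(Hz); equivalent sites enter as a group multiplicity `scale`. The free
Hamiltonian uses the full strong-coupling form. Operators are built by
tensor products of Pauli/2 matrices (dimension `2^n`, capped at n = 8);
propagators come from eigendecomposition of the Hermitian Hamiltonian —
exact, no series truncation. Detection is `Tr(rho F+)`, normalized so one
uncoupled proton yields amplitude 1.0 at t = 0; relaxation is ignored
during the sequence (standard basis-simulation practice) and lineshape is
applied afterwards by apodization.

Ideal pulses are exact rotations and need no coherence selection. Shaped
pulses are piecewise-constant waveforms; during a selective pulse the
Hamiltonian gains `2 pi offset Fz` for the gradient-encoded position, and
after each such pulse the density matrix is projected onto the stated
coherence order (projection, not phase cycling — the published description
does not say which the original uses; projection is deterministic and
cheaper). Localization modes: `ideal` (no spatial dimension), `sep1d`
(each selective-pulse dimension averaged independently immediately after
its pulse — exact for independent per-axis offsets because expectation and
sequential superoperator application commute), and `full3d` (explicit
triple loop, bounded to 32^3). Per-(pulse, offset) propagators are memoized;
the cache changes nothing numerically, which is verified by comparing
cached and uncached full-3D runs (max difference below 1e-8 on a 2-spin
system over an 8^3 grid — the desk-scale problem size used throughout).

The weak-coupling J-modulation oracle (`cos(pi J TE)` for an AX doublet
under a three-pulse echo) is checked in a deliberately deep weak-coupling
regime (shift difference / J = 400), where agreement is at the 1e-5 level;
at ratios near 100, genuine strong-coupling corrections of order J/Delta-nu
(about 1%) appear — a physical effect, not a numerical error. The in-phase
doublet amplitude is read out by HSVD of the simulated FID, which is exact
for these noiseless signals.

The shipped spin-system file (`inst/extdata/spin_systems.json`) compiles
approximate shifts and couplings for ten common brain metabolites from the
standard literature tables; values are package defaults for simulation and
teaching, users supply their own files for quantitative work, and the file
format (JSON groups of shifts, J matrix, multiplicity) is documented in the
file itself.

## Linear combination modeling

The model, bounds and error machinery are described in the README; choices
that were genuinely open:

* **Fit domain.** Complex (stacked real and imaginary residuals) by
  default; real-only is available. Complex fitting uses all information and
  makes the phase parameters identifiable without a separate convention.
* **Per-metabolite vs global lineshape.** Per-metabolite Lorentzian
  `lambda_m` with one global Gaussian `gamma` (together a Voigt profile),
  switchable; this matches common practice and keeps the parameter count
  linear in the basis size.
* **Baseline.** Polynomial up to order 10 in `(ppm - center)` and/or a
  cubic b-spline over the fit window with knot interval `kappa` (ppm) and
  smoothing weight `w`. The smoothing enters as penalty rows
  `sqrt(w) D2 c` appended to the residual vector (a quadratic penalty on
  second differences of the spline coefficients); the penalty rows are
  excluded from the Fisher matrix used for the reported CRLBs, since
  whether regularization belongs in the error model is itself an open
  question — excluding it is the conservative choice for metabolite errors.
  The baseline is real-valued and enters the real channel of the residual.
* **Noise SD.** Estimated as the SD of the real residual in a user noise
  window when one is configured, else `sqrt(RSS/(n - p))`. CRLBs are
  exactly proportional to this sigma, so rescaling is cheap and exact.
* **Optimizer.** Bound-constrained Levenberg–Marquardt with objective and
  step tolerances defaulting to 1e-8 and a cap on iterations and residual
  evaluations; hitting the iteration cap sets a status flag rather than
  throwing. The reported Jacobian is central-difference with per-parameter
  relative step 1e-6, clipped at the bounds. A singular Fisher matrix falls
  back to the eigendecomposition pseudo-inverse with the unidentifiable
  parameters named in the result.
* **Monte-Carlo.** Parametric bootstrap: replicates are the fitted model
  plus fresh noise at sigma, refit from the estimate; residual resampling
  would entangle baseline misfit with noise. Non-convergent replicates are
  excluded and counted. Deterministic given the seed.
* **First-order phase** is part of the model (not pre-applied), bounded to
  ±10 degrees/ppm by default.

Test problem sizes: 512-point spectra, three-singlet bases, noise at
spectral SNR near 50, 100 seeded fit replicates and 100 Monte-Carlo
replicates — small enough to run the whole closed loop in seconds, large
enough that the CRLB/Monte-Carlo comparison (ratios within 25%) is
meaningful.

## Formats and protocols

The LCModel-style `.raw`/`.basis` readers accept the namelist dialect this
package emits (and bare numeric files with a user-supplied header); they
are deliberately a canonical subset, since dialects in the wild vary.
Vendor binary formats are out of scope and rejected with a pointer to the
native container. The native container and the protocol files are JSON:
human-diffable, schema-tagged (`mrsproc-native-1`, `mrsproc-protocol-1`),
with complex data as parallel real/imaginary arrays and an append-only
processing log. Protocol loading validates keys against the full parameter
tree: unknown keys are an error naming them, missing sections fall back to
defaults and are recorded, and a schema mismatch sets an explicit warning
field. Protocol-driven runs reproduce flag-driven runs byte for byte given
the same seed, which is the property the round-trip tests assert.

## Known limitations

* Relaxation during sequences, B0 inhomogeneity and frequency drift are not
  simulated; vendor pulse waveforms are not bundled (supply your own).
* The HSVD water filter assumes the water resonance is well modeled by a
  few damped exponentials; pathological lineshapes may leave residuals.
* Absolute quantification (water scaling, relaxation correction to mM) is
  out of scope; amplitudes are in basis-relative units.
* The amplitude-weighted alignment score and the 8-aspect list are this
  package's own formalizations of published one-line descriptions, as noted
  above.
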