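#' Singlet definition
#'
#' A parametric singlet, the triple `[frequency amplitude linewidth]`:
#' frequency in ppm, amplitude in arbitrary units, Lorentzian linewidth
#' (FWHM) in Hz.
#'
#' @param frequency_ppm Resonance position in ppm.
#' @param amplitude Peak amplitude in arbitrary units.
#' @param linewidth_hz Lorentzian FWHM in Hz (> 0).
#' @return A `singlet_def` object.
#' @export
singlet_def <- function(frequency_ppm, amplitude, linewidth_hz) {
  if (!is.finite(linewidth_hz) || linewidth_hz <= 0)
    stop("parameter error: 'linewidth_hz' must be > 0", call. = FALSE)
  structure(list(frequency_ppm = frequency_ppm, amplitude = amplitude,
                 linewidth_hz = linewidth_hz), class = "singlet_def")
}

#' Simulate a sum of singlets as a FID
#'
#' Each singlet contributes `A * exp(i*2*pi*df*t) * exp(-pi*lw*t)` with
#' `df = (ppm - center_ppm) * larmor_mhz` Hz, producing a Lorentzian line of
#' FWHM `lw` Hz at the stated ppm.
#'
#' @param defs List of [singlet_def()] objects (possibly empty).
#' @param header An [acq_header()].
#' @return An [mrs_fid()].
#' @examples
#' hdr <- acq_header(298.1, 5000, 2048, center_ppm = 4.65)
#' fid <- simulate_singlets(list(singlet_def(3, 30, 4)), hdr)
#' @export
simulate_singlets <- function(defs, header) {
  stopifnot_header(header)
  if (inherits(defs, "singlet_def")) defs <- list(defs)
  t <- time_axis(header)
  s <- complex(real = numeric(header$n_points))
  ax <- ppm_axis(header)
  for (d in defs) {
    if (!inherits(d, "singlet_def")) stop("'defs' must be singlet_def objects", call. = FALSE)
    if (d$frequency_ppm < min(ax) || d$frequency_ppm > max(ax))
      warning(sprintf("singlet at %.3f ppm lies outside the spectral window (aliased)",
                      d$frequency_ppm))
    df <- (d$frequency_ppm - header$center_ppm) * header$larmor_mhz
    s <- s + d$amplitude * exp(1i * 2 * pi * df * t) * exp(-pi * d$linewidth_hz * t)
  }
  mrs_fid(s, header)
}

#' Add complex Gaussian noise in the frequency domain
#'
#' Independent Gaussian noise of the stated SD is added to the real and
#' imaginary part of every spectral point. Deterministic given `seed`.
#'
#' @param spec An [mrs_spectrum()].
#' @param sd Noise SD per real/imaginary component of each spectral point
#'   (>= 0).
#' @param seed Integer seed.
#' @return The noisy [mrs_spectrum()].
#' @export
add_noise <- function(spec, sd, seed = 1L) {
  if (!inherits(spec, "mrs_spectrum")) stop("'spec' must be an mrs_spectrum", call. = FALSE)
  if (!is.finite(sd) || sd < 0) stop("parameter error: 'sd' must be >= 0", call. = FALSE)
  if (sd == 0) return(spec)
  n <- length(spec$values)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  noise <- complex(real = stats::rnorm(n, 0, sd), imaginary = stats::rnorm(n, 0, sd))
  mrs_spectrum(spec$values + noise, spec$header)
}

#' Add a polynomial baseline
#'
#' Adds `sum_j c_j * (ppm - center_ppm)^j` to the real part of the spectrum.
#'
#' @param spec An [mrs_spectrum()].
#' @param coeffs Numeric polynomial coefficients `c_0, c_1, ...` in ascending
#'   order of `(ppm - center)`.
#' @return The [mrs_spectrum()] with baseline added.
#' @export
add_baseline <- function(spec, coeffs) {
  if (!inherits(spec, "mrs_spectrum")) stop("'spec' must be an mrs_spectrum", call. = FALSE)
  if (length(coeffs) == 0L) return(spec)
  x <- spec$ppm - spec$header$center_ppm
  b <- numeric(length(x))
  for (j in seq_along(coeffs)) b <- b + coeffs[j] * x^(j - 1)
  mrs_spectrum(spec$values + b, spec$header)
}

#' Synthesize a composite (brain-like) spectrum from a basis set
#'
#' Amplitude-weighted sum of basis responses: the linear-combination forward
#' model without lineshape or phase adjustments. Useful for SNR studies and
#' for closed-loop checks of the LCM fit.
#'
#' @param basis A [basis_set()].
#' @param concentrations Named numeric vector of amplitudes; names must be
#'   basis entries.
#' @return An [mrs_spectrum()].
#' @export
synth_brain <- function(basis, concentrations) {
  if (!inherits(basis, "basis_set")) stop("'basis' must be a basis_set", call. = FALSE)
  bad <- setdiff(names(concentrations), names(basis$entries))
  if (length(bad)) stop("unknown metabolite name(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  h <- basis$header
  acc <- complex(real = numeric(h$n_points))
  for (nm in names(concentrations))
    acc <- acc + concentrations[[nm]] * basis$entries[[nm]]
  to_spectrum(mrs_fid(acc, h))
}

#' Default brain-phantom amplitudes
#'
#' Literature-style relative amplitudes for a synthetic 1H brain spectrum
#' (artifact defaults, versioned in `inst/extdata/brain_phantom.csv`).
#'
#' @return Named numeric vector.
#' @export
brain_phantom_amplitudes <- function() {
  p <- system.file("extdata", "brain_phantom.csv", package = "mrsproc", mustWork = TRUE)
  tab <- utils::read.csv(p, stringsAsFactors = FALSE)
  stats::setNames(tab$amplitude, tab$name)
}

# seeding helpers: set a temporary RNG state and restore the caller's
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Ground truth for a synthetic raw dataset
#'
#' Defines everything [make_raw_fixture()] needs to emulate a multi-channel
#' in vivo acquisition: singlet content, per-channel sensitivity and phase,
#' per-repetition frequency drift and phase instability, time-domain noise
#' and (for J-difference editing) an edited resonance present in only one
#' condition.
#'
#' @param singlets List of [singlet_def()] giving the metabolite content.
#' @param n_reps,n_channels Repetitions and receive channels.
#' @param channel_sens Numeric vector of per-channel sensitivities
#'   (length `n_channels`).
#' @param channel_phase_deg Per-channel receiver phases in degrees.
#' @param drift_sd_hz SD of the per-repetition frequency drift (Hz).
#' @param rep_phase_sd_deg SD of the per-repetition phase instability (deg).
#' @param noise_sd Time-domain complex noise SD per component.
#' @param jde If `TRUE`, label repetitions alternately ON/OFF and add
#'   `edited_singlet` to ON repetitions only.
#' @param edited_singlet A [singlet_def()] used when `jde = TRUE`.
#' @param seed Integer seed; the fixture is a pure function of
#'   (parameters, seed).
#' @return A `fixture_truth` object; pass to [make_raw_fixture()].
#' @export
fixture_truth <- function(singlets,
                          n_reps = 16L, n_channels = 4L,
                          channel_sens = c(1, 0.6, 0.3, 0.15)[seq_len(n_channels)],
                          channel_phase_deg = c(0, 120, 240, 60)[seq_len(n_channels)],
                          drift_sd_hz = 2, rep_phase_sd_deg = 15,
                          noise_sd = 0.5, jde = FALSE,
                          edited_singlet = singlet_def(3.01, 3, 12),
                          seed = 1L) {
  if (length(channel_sens) != n_channels || length(channel_phase_deg) != n_channels)
    stop("parameter error: channel vectors must have length n_channels", call. = FALSE)
  structure(list(singlets = if (inherits(singlets, "singlet_def")) list(singlets) else singlets,
                 n_reps = as.integer(n_reps), n_channels = as.integer(n_channels),
                 channel_sens = channel_sens, channel_phase_deg = channel_phase_deg,
                 drift_sd_hz = drift_sd_hz, rep_phase_sd_deg = rep_phase_sd_deg,
                 noise_sd = noise_sd, jde = isTRUE(jde), edited_singlet = edited_singlet,
                 seed = as.integer(seed)),
            class = "fixture_truth")
}

#' Generate a synthetic multi-channel raw dataset with known ground truth
#'
#' Each trace is the singlet sum times the channel sensitivity and receiver
#' phase, times the repetition's frequency-drift phase ramp and instability
#' phase, plus complex time-domain noise. Water references are generated
#' consistently (scaled singlet at the carrier per channel, sharing the
#' channel phase, noiseless). Fully determined by the seed.
#'
#' @param truth A [fixture_truth()].
#' @param header An [acq_header()].
#' @return List with elements `dataset` (an [mrs_dataset()]) and `draws`
#'   (realized per-repetition drifts and phases).
#' @export
make_raw_fixture <- function(truth, header) {
  if (!inherits(truth, "fixture_truth")) stop("'truth' must be a fixture_truth", call. = FALSE)
  stopifnot_header(header)
  old <- local_seed(truth$seed)
  on.exit(restore_seed(old))
  n <- header$n_points
  t <- time_axis(header)
  base <- simulate_singlets(truth$singlets, header)$samples
  edited <- if (truth$jde) simulate_singlets(truth$edited_singlet, header)$samples else NULL
  drifts <- stats::rnorm(truth$n_reps, 0, truth$drift_sd_hz)
  phases <- stats::rnorm(truth$n_reps, 0, truth$rep_phase_sd_deg)
  labels <- if (truth$jde) rep(c("ON", "OFF"), length.out = truth$n_reps)
            else rep("none", truth$n_reps)
  cube <- array(0 + 0i, c(truth$n_reps, truth$n_channels, n))
  for (r in seq_len(truth$n_reps)) {
    sig <- base
    if (truth$jde && labels[r] == "ON") sig <- sig + edited
    mod <- exp(1i * 2 * pi * drifts[r] * t) * exp(1i * phases[r] * pi / 180)
    for (c in seq_len(truth$n_channels)) {
      tr <- sig * truth$channel_sens[c] * exp(1i * truth$channel_phase_deg[c] * pi / 180) * mod
      if (truth$noise_sd > 0)
        tr <- tr + complex(real = stats::rnorm(n, 0, truth$noise_sd),
                           imaginary = stats::rnorm(n, 0, truth$noise_sd))
      cube[r, c, ] <- tr
    }
  }
  water_amp <- 50 * max(vapply(truth$singlets, function(d) abs(d$amplitude), numeric(1)), 1)
  water_base <- simulate_singlets(singlet_def(header$center_ppm, water_amp, 8), header)$samples
  water <- matrix(0 + 0i, truth$n_channels, n)
  for (c in seq_len(truth$n_channels))
    water[c, ] <- water_base * truth$channel_sens[c] *
      exp(1i * truth$channel_phase_deg[c] * pi / 180)
  list(dataset = mrs_dataset(cube, header, labels, water),
       draws = list(drift_hz = drifts, phase_deg = phases, labels = labels))
}
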