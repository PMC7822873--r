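#' Acquisition header
#'
#' Bundles the acquisition parameters every FID or spectrum carries: the
#' transmitter (Larmor) frequency, spectral width, number of complex points
#' and the ppm calibration of the synthesizer (carrier) frequency. Sequence
#' timings are optional metadata.
#'
#' @param larmor_mhz Transmitter frequency in MHz (e.g. 298.1 at 7 T for 1H).
#' @param bandwidth_hz Spectral width in Hz; the dwell time is
#'   `1/bandwidth_hz`.
#' @param n_points Number of complex FID points.
#' @param center_ppm Chemical shift at the carrier frequency (synthesizer
#'   calibration), in ppm. Water at 4.65 ppm is a common 1H choice.
#' @param te_ms,tr_ms,tm_ms Optional echo, repetition and mixing times in ms.
#' @return An object of class `acq_header`.
#' @examples
#' hdr <- acq_header(298.1, 5000, 2048, center_ppm = 4.65)
#' range(ppm_axis(hdr))
#' @export
acq_header <- function(larmor_mhz, bandwidth_hz, n_points, center_ppm = 4.65,
                       te_ms = NA_real_, tr_ms = NA_real_, tm_ms = NA_real_) {
  if (!is.numeric(larmor_mhz) || length(larmor_mhz) != 1L || !is.finite(larmor_mhz) ||
      larmor_mhz <= 0)
    stop("invalid header: 'larmor_mhz' must be a single positive number", call. = FALSE)
  if (!is.numeric(bandwidth_hz) || length(bandwidth_hz) != 1L || !is.finite(bandwidth_hz) ||
      bandwidth_hz <= 0)
    stop("invalid header: 'bandwidth_hz' must be a single positive number", call. = FALSE)
  n_points <- as.integer(n_points)
  if (length(n_points) != 1L || is.na(n_points) || n_points < 2L)
    stop("invalid header: 'n_points' must be an integer >= 2", call. = FALSE)
  if (!is.numeric(center_ppm) || length(center_ppm) != 1L || !is.finite(center_ppm))
    stop("invalid header: 'center_ppm' must be a finite number", call. = FALSE)
  structure(
    list(larmor_mhz = as.numeric(larmor_mhz),
         bandwidth_hz = as.numeric(bandwidth_hz),
         n_points = n_points,
         center_ppm = as.numeric(center_ppm),
         te_ms = as.numeric(te_ms), tr_ms = as.numeric(tr_ms), tm_ms = as.numeric(tm_ms),
         b0_tesla = as.numeric(larmor_mhz) / 42.577478),
    class = "acq_header")
}

#' @export
print.acq_header <- function(x, ...) {
  cat(sprintf("<acq_header> %.4f MHz, bw %.1f Hz, %d pts, carrier %.3f ppm\n",
              x$larmor_mhz, x$bandwidth_hz, x$n_points, x$center_ppm))
  if (is.finite(x$te_ms)) cat(sprintf("  TE %.1f ms\n", x$te_ms))
  invisible(x)
}

stopifnot_header <- function(header) {
  if (!inherits(header, "acq_header")) stop("'header' must be an acq_header", call. = FALSE)
  header
}

#' Time axis of a FID
#'
#' @param header An [acq_header()].
#' @return Sampling times `t_n = n / bandwidth_hz`, starting at 0, in seconds.
#' @export
time_axis <- function(header) {
  stopifnot_header(header)
  (seq_len(header$n_points) - 1) / header$bandwidth_hz
}

# FFT-grid frequency offsets in Hz, ascending, spanning [-bw/2, bw/2).
# Zero frequency (the carrier) sits at index floor(n/2)+1.
freq_grid_hz <- function(header) {
  n <- header$n_points
  (seq_len(n) - 1 - floor(n / 2)) * header$bandwidth_hz / n
}

#' Chemical-shift axis
#'
#' Ascending ppm coordinates on the FFT grid: `center_ppm + f / larmor_mhz`
#' with `f` spanning `[-bw/2, bw/2)` in Hz. The carrier bin carries exactly
#' `center_ppm`.
#'
#' @inheritParams time_axis
#' @return Numeric vector of ppm values, length `n_points`, strictly
#'   increasing.
#' @export
ppm_axis <- function(header) {
  stopifnot_header(header)
  header$center_ppm + freq_grid_hz(header) / header$larmor_mhz
}

carrier_index <- function(n) floor(n / 2) + 1L

fftshift <- function(x) {
  n <- length(x)
  x[c((floor(n / 2) + 1L):n, seq_len(floor(n / 2)))]
}

ifftshift <- function(x) {
  n <- length(x)
  x[c((n - floor(n / 2) + 1L):n, seq_len(n - floor(n / 2)))]
}

#' Complex time-domain FID
#'
#' @param samples Complex vector of length `header$n_points`.
#' @param header An [acq_header()].
#' @return An object of class `mrs_fid` with elements `samples` and `header`.
#' @export
mrs_fid <- function(samples, header) {
  stopifnot_header(header)
  samples <- as.complex(samples)
  if (length(samples) != header$n_points)
    stop("invalid data: FID length does not match header n_points", call. = FALSE)
  if (anyNA(samples) || any(!is.finite(Re(samples))) || any(!is.finite(Im(samples))))
    stop("invalid data: FID contains non-finite values", call. = FALSE)
  structure(list(samples = samples, header = header), class = "mrs_fid")
}

#' @export
print.mrs_fid <- function(x, ...) {
  cat(sprintf("<mrs_fid> %d complex points, dwell %.3g s\n",
              x$header$n_points, 1 / x$header$bandwidth_hz))
  invisible(x)
}

#' Complex frequency-domain spectrum
#'
#' @param values Complex spectral points.
#' @param header An [acq_header()] whose grid matches `values`.
#' @return An object of class `mrs_spectrum` with elements `values`,
#'   `ppm` (ascending axis) and `header`.
#' @export
mrs_spectrum <- function(values, header) {
  stopifnot_header(header)
  values <- as.complex(values)
  if (length(values) != header$n_points)
    stop("invalid data: spectrum length does not match header n_points", call. = FALSE)
  if (anyNA(values) || any(!is.finite(Re(values))) || any(!is.finite(Im(values))))
    stop("invalid data: spectrum contains non-finite values", call. = FALSE)
  structure(list(values = values, ppm = ppm_axis(header), header = header),
            class = "mrs_spectrum")
}

#' @export
print.mrs_spectrum <- function(x, ...) {
  cat(sprintf("<mrs_spectrum> %d points, %.3f..%.3f ppm\n",
              x$header$n_points, min(x$ppm), max(x$ppm)))
  invisible(x)
}

#' Fourier transform a FID to a spectrum
#'
#' Forward DFT scaled by `1/N` and frequency-shifted so the carrier sits at
#' the center bin; the returned ppm axis is ascending. With this convention a
#' constant FID of value A transforms to a single bin of height A at the
#' carrier, and white time-domain noise of SD sigma gives spectral noise of
#' SD `sigma/sqrt(N)` per point.
#'
#' @param fid An [mrs_fid()].
#' @param first_point_half If `TRUE`, halve the first FID point before the
#'   transform (a common baseline-offset correction). Default `FALSE`: the
#'   plain transform.
#' @return An [mrs_spectrum()].
#' @export
to_spectrum <- function(fid, first_point_half = FALSE) {
  if (!inherits(fid, "mrs_fid")) stop("'fid' must be an mrs_fid", call. = FALSE)
  s <- fid$samples
  if (isTRUE(first_point_half)) s[1] <- s[1] / 2
  v <- fftshift(stats::fft(s)) / length(s)
  mrs_spectrum(v, fid$header)
}

#' Inverse transform a spectrum to a FID
#'
#' Exact inverse of [to_spectrum()] (round trip is identity to machine
#' precision).
#'
#' @param spec An [mrs_spectrum()].
#' @return An [mrs_fid()].
#' @export
to_fid <- function(spec) {
  if (!inherits(spec, "mrs_spectrum")) stop("'spec' must be an mrs_spectrum", call. = FALSE)
  mrs_fid(stats::fft(ifftshift(spec$values), inverse = TRUE), spec$header)
}

#' Lorentzian/Gaussian apodization
#'
#' Multiplies the FID by `exp(-pi*lorentz_hz*t) * exp(-(pi*gauss_hz*t)^2/(4 ln 2))`.
#' Each filter alone adds exactly its argument to the spectral FWHM of a pure
#' singlet of the matching lineshape.
#'
#' @param fid An [mrs_fid()].
#' @param lorentz_hz Lorentzian line broadening in Hz (>= 0).
#' @param gauss_hz Gaussian line broadening (FWHM contribution) in Hz (>= 0).
#' @return The apodized [mrs_fid()].
#' @export
apodize <- function(fid, lorentz_hz = 0, gauss_hz = 0) {
  if (!inherits(fid, "mrs_fid")) stop("'fid' must be an mrs_fid", call. = FALSE)
  if (!is.finite(lorentz_hz) || lorentz_hz < 0)
    stop("parameter error: 'lorentz_hz' must be >= 0", call. = FALSE)
  if (!is.finite(gauss_hz) || gauss_hz < 0)
    stop("parameter error: 'gauss_hz' must be >= 0", call. = FALSE)
  t <- time_axis(fid$header)
  w <- exp(-pi * lorentz_hz * t) * exp(-(pi * gauss_hz * t)^2 / (4 * log(2)))
  mrs_fid(fid$samples * w, fid$header)
}

#' Zero-fill or cut a FID
#'
#' `n_target > N` appends zeros (zero-filling, halving the spectral bin
#' spacing per doubling); `n_target < N` truncates (cut). The header point
#' count follows.
#'
#' @param fid An [mrs_fid()].
#' @param n_target Desired number of complex points (>= 2).
#' @return The resized [mrs_fid()].
#' @export
resize_fid <- function(fid, n_target) {
  if (!inherits(fid, "mrs_fid")) stop("'fid' must be an mrs_fid", call. = FALSE)
  n_target <- as.integer(n_target)
  if (length(n_target) != 1L || is.na(n_target) || n_target < 2L)
    stop("parameter error: 'n_target' must be an integer >= 2", call. = FALSE)
  n <- fid$header$n_points
  s <- if (n_target <= n) fid$samples[seq_len(n_target)]
       else c(fid$samples, complex(real = numeric(n_target - n)))
  h <- fid$header
  h$n_points <- n_target
  mrs_fid(s, h)
}

#' Zero- and first-order phase correction
#'
#' Multiplies the spectrum by `exp(i*(phi0 + phi1*(ppm - pivot))*pi/180)`.
#' The first-order term is linear in ppm about an explicit pivot (default:
#' the carrier ppm). Norm preserving.
#'
#' @param spec An [mrs_spectrum()].
#' @param phi0_deg Zero-order phase in degrees.
#' @param phi1_deg_per_ppm First-order phase in degrees per ppm.
#' @param pivot_ppm Pivot for the first-order term; defaults to the header's
#'   `center_ppm`.
#' @return The phased [mrs_spectrum()].
#' @export
phase_correct <- function(spec, phi0_deg = 0, phi1_deg_per_ppm = 0, pivot_ppm = NULL) {
  if (!inherits(spec, "mrs_spectrum")) stop("'spec' must be an mrs_spectrum", call. = FALSE)
  if (is.null(pivot_ppm)) pivot_ppm <- spec$header$center_ppm
  if (!all(is.finite(c(phi0_deg, phi1_deg_per_ppm, pivot_ppm))))
    stop("parameter error: phase parameters must be finite", call. = FALSE)
  ph <- (phi0_deg + phi1_deg_per_ppm * (spec$ppm - pivot_ppm)) * pi / 180
  mrs_spectrum(spec$values * exp(1i * ph), spec$header)
}

#' Frequency shift, amplitude scale and spectral offset
#'
#' Applies `samples * scale * exp(i*2*pi*df_hz*t)` in the time domain (an
#' exact phase-ramp shift), then adds the complex constant `offset` to every
#' point of the corresponding spectrum.
#'
#' @param fid An [mrs_fid()].
#' @param df_hz Frequency shift in Hz (positive moves peaks to higher ppm).
#' @param scale Real amplitude multiplier.
#' @param offset Complex constant added in the frequency domain.
#' @return The transformed [mrs_fid()].
#' @export
shift_scale_offset <- function(fid, df_hz = 0, scale = 1, offset = 0 + 0i) {
  if (!inherits(fid, "mrs_fid")) stop("'fid' must be an mrs_fid", call. = FALSE)
  if (!all(is.finite(c(df_hz, scale, Re(offset), Im(offset)))))
    stop("parameter error: parameters must be finite", call. = FALSE)
  t <- time_axis(fid$header)
  s <- fid$samples * scale * exp(1i * 2 * pi * df_hz * t)
  if (offset != 0 + 0i) {
    # adding a constant to every spectral bin equals adding N*offset to the
    # first time-domain point under the 1/N forward convention
    s[1] <- s[1] + length(s) * offset
  }
  mrs_fid(s, fid$header)
}

#' Export one trace as two-column text
#'
#' Writes `real imaginary` pairs, one complex point per line.
#'
#' @param fid An [mrs_fid()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_trace_txt <- function(fid, path) {
  if (!inherits(fid, "mrs_fid")) stop("'fid' must be an mrs_fid", call. = FALSE)
  m <- cbind(Re(fid$samples), Im(fid$samples))
  utils::write.table(format(m, digits = 12, scientific = TRUE), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Multi-repetition, multi-channel FID dataset
#'
#' The raw-data container: a complex cube of `n_reps x n_channels x n_points`
#' plus the acquisition header, optional per-repetition editing-condition
#' labels (for J-difference editing) and optional per-channel water-reference
#' FIDs used for phase correction and sensitivity weighting.
#'
#' @param data Complex array `n_reps x n_channels x n_points`.
#' @param header An [acq_header()] with matching `n_points`.
#' @param condition_labels Optional character vector of length `n_reps`
#'   (e.g. `"ON"`/`"OFF"`); default `"none"` for all repetitions.
#' @param water_refs Optional complex matrix `n_channels x n_points` of
#'   water-reference FIDs.
#' @return An object of class `mrs_dataset`.
#' @export
mrs_dataset <- function(data, header, condition_labels = NULL, water_refs = NULL) {
  stopifnot_header(header)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("invalid data: 'data' must be an n_reps x n_channels x n_points array", call. = FALSE)
  if (dim(data)[3] != header$n_points)
    stop("invalid data: third dimension must equal header n_points", call. = FALSE)
  storage.mode(data) <- "complex"
  if (is.null(condition_labels)) condition_labels <- rep("none", dim(data)[1])
  if (length(condition_labels) != dim(data)[1])
    stop("invalid data: 'condition_labels' length must equal n_reps", call. = FALSE)
  if (!is.null(water_refs)) {
    water_refs <- as.matrix(water_refs)
    if (!all(dim(water_refs) == c(dim(data)[2], header$n_points)))
      stop("invalid data: 'water_refs' must be n_channels x n_points", call. = FALSE)
    storage.mode(water_refs) <- "complex"
  }
  structure(list(data = data, header = header,
                 condition_labels = as.character(condition_labels),
                 water_refs = water_refs),
            class = "mrs_dataset")
}

#' @export
print.mrs_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mrs_dataset> %d reps x %d channels x %d points", d[1], d[2], d[3]))
  if (length(unique(x$condition_labels)) > 1L)
    cat(sprintf(" [conditions: %s]", paste(unique(x$condition_labels), collapse = "/")))
  cat(if (is.null(x$water_refs)) "\n" else " (+water refs)\n")
  invisible(x)
}

#' Extract one trace of a dataset as an [mrs_fid()]
#'
#' @param ds An [mrs_dataset()].
#' @param rep,channel Repetition and channel indices.
#' @return An [mrs_fid()].
#' @export
dataset_trace <- function(ds, rep = 1L, channel = 1L) {
  if (!inherits(ds, "mrs_dataset")) stop("'ds' must be an mrs_dataset", call. = FALSE)
  mrs_fid(ds$data[rep, channel, ], ds$header)
}

#' Concatenate scan series along repetitions
#'
#' Long scans are often split into smaller series to allow intermittent
#' frequency adjustment; series with identical headers concatenate along the
#' repetition dimension.
#'
#' @param ... Two or more [mrs_dataset()] objects with identical headers.
#' @return One [mrs_dataset()].
#' @export
concat_datasets <- function(...) {
  dss <- list(...)
  if (length(dss) < 2L) stop("need at least two datasets", call. = FALSE)
  h0 <- dss[[1]]$header
  for (ds in dss) {
    if (!inherits(ds, "mrs_dataset")) stop("'...' must be mrs_dataset objects", call. = FALSE)
    h <- ds$header
    if (h$larmor_mhz != h0$larmor_mhz || h$bandwidth_hz != h0$bandwidth_hz ||
        h$n_points != h0$n_points || h$center_ppm != h0$center_ppm)
      stop("invalid data: cannot concatenate datasets with mismatched headers", call. = FALSE)
  }
  nrep <- sum(vapply(dss, function(d) dim(d$data)[1], integer(1)))
  out <- array(0 + 0i, c(nrep, dim(dss[[1]]$data)[2], h0$n_points))
  labels <- character(0)
  at <- 1L
  for (ds in dss) {
    k <- dim(ds$data)[1]
    out[at:(at + k - 1L), , ] <- ds$data
    labels <- c(labels, ds$condition_labels)
    at <- at + k
  }
  mrs_dataset(out, h0, labels, dss[[1]]$water_refs)
}

# window helpers ------------------------------------------------------------

#' Frequency window in ppm
#'
#' @param lo_ppm,hi_ppm Inclusive ppm bounds, `lo_ppm < hi_ppm`.
#' @return A `freq_window` object.
#' @export
freq_window <- function(lo_ppm, hi_ppm) {
  if (!is.finite(lo_ppm) || !is.finite(hi_ppm) || lo_ppm >= hi_ppm)
    stop("parameter error: need lo_ppm < hi_ppm", call. = FALSE)
  structure(list(lo_ppm = lo_ppm, hi_ppm = hi_ppm), class = "freq_window")
}

as_windows <- function(windows) {
  if (inherits(windows, "freq_window")) return(list(windows))
  if (!is.list(windows) || !all(vapply(windows, inherits, logical(1), "freq_window")))
    stop("parameter error: 'windows' must be freq_window objects", call. = FALSE)
  windows
}

window_index <- function(ppm, window) {
  which(ppm >= window$lo_ppm & ppm <= window$hi_ppm)
}

windows_index <- function(ppm, windows) {
  idx <- sort(unique(unlist(lapply(as_windows(windows), window_index, ppm = ppm))))
  if (length(idx) == 0L) stop("empty window: no axis points inside", call. = FALSE)
  idx
}
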