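#' Eddy-current / phase correction after Klose
#'
#' Removes the time-dependent phase of a water-reference FID pointwise:
#' `s_n -> s_n * exp(-i * arg(water_n))`. Any phase corruption common to the
#' metabolite and water signal (eddy currents, receiver phase) cancels
#' exactly. Water points of zero magnitude contribute phase 0 and raise a
#' warning.
#'
#' @param fid Metabolite [mrs_fid()].
#' @param water Water-reference [mrs_fid()] of equal length.
#' @return The corrected [mrs_fid()].
#' @export
klose_correct <- function(fid, water) {
  if (!inherits(fid, "mrs_fid") || !inherits(water, "mrs_fid"))
    stop("'fid' and 'water' must be mrs_fid objects", call. = FALSE)
  if (length(fid$samples) != length(water$samples))
    stop("invalid data: FID and water reference lengths differ", call. = FALSE)
  ph <- Arg(water$samples)
  zero <- Mod(water$samples) == 0
  if (any(zero)) {
    warning(sprintf("%d water point(s) with zero magnitude; using phase 0 there", sum(zero)))
    ph[zero] <- 0
  }
  mrs_fid(fid$samples * exp(-1i * ph), fid$header)
}

#' First-point phase correction
#'
#' Applies one global rotation `exp(-i * arg(water_1))` taken from the first
#' water-reference point. Coincides with [klose_correct()] when the water
#' phase is constant in time.
#'
#' @inheritParams klose_correct
#' @return The corrected [mrs_fid()].
#' @export
first_point_phase <- function(fid, water) {
  if (!inherits(fid, "mrs_fid") || !inherits(water, "mrs_fid"))
    stop("'fid' and 'water' must be mrs_fid objects", call. = FALSE)
  if (Mod(water$samples[1]) == 0)
    stop("invalid data: first water point has zero magnitude", call. = FALSE)
  mrs_fid(fid$samples * exp(-1i * Arg(water$samples[1])), fid$header)
}

#' Combine receive channels
#'
#' Phase-corrects each channel with its own water reference (Klose pointwise
#' or first-point), then averages channels with sensitivity weights
#' `w_c = |water_c(0)|` or uniform weights: `combined = sum(w_c * fid_c) / sum(w_c)`.
#' With `method = "none"` channels are summed without phase correction
#' (receiver phases then interfere destructively).
#'
#' @param ds An [mrs_dataset()] with water references (required unless
#'   `method = "none"` and `weighting = "uniform"`).
#' @param method `"klose"`, `"first_point"` or `"none"`.
#' @param weighting `"sensitivity"` or `"uniform"`.
#' @return List with `reps` (list of combined [mrs_fid()], one per
#'   repetition) and `corrections` (per-channel weight and phase, degrees).
#' @export
combine_channels <- function(ds, method = c("klose", "first_point", "none"),
                             weighting = c("sensitivity", "uniform")) {
  if (!inherits(ds, "mrs_dataset")) stop("'ds' must be an mrs_dataset", call. = FALSE)
  method <- match.arg(method)
  weighting <- match.arg(weighting)
  d <- dim(ds$data)
  need_water <- method != "none" || weighting == "sensitivity"
  if (need_water && is.null(ds$water_refs))
    stop("invalid data: water references required for method '", method,
         "' / weighting '", weighting, "'", call. = FALSE)
  w <- if (weighting == "sensitivity") Mod(ds$water_refs[, 1]) else rep(1, d[2])
  if (need_water) {
    z <- Mod(ds$water_refs[, 1]) == 0
    if (method == "first_point" && any(z))
      stop("invalid data: zero first water point on channel ", which(z)[1], call. = FALSE)
  }
  reps <- vector("list", d[1])
  for (r in seq_len(d[1])) {
    acc <- complex(real = numeric(d[3]))
    for (c in seq_len(d[2])) {
      tr <- mrs_fid(ds$data[r, c, ], ds$header)
      if (method != "none") {
        wref <- mrs_fid(ds$water_refs[c, ], ds$header)
        tr <- if (method == "klose") klose_correct(tr, wref) else first_point_phase(tr, wref)
      }
      acc <- acc + w[c] * tr$samples
    }
    reps[[r]] <- mrs_fid(acc / sum(w), ds$header)
  }
  phase_deg <- if (need_water) Arg(ds$water_refs[, 1]) * 180 / pi else rep(0, d[2])
  list(reps = reps,
       corrections = data.frame(channel = seq_len(d[2]), weight = w, phase_deg = phase_deg))
}

#' Quality-assessment statistics over a frequency window
#'
#' Computes, on the real part of each trace within the window: minimum,
#' maximum, mean, median, standard deviation, and integral (Riemann sum
#' times the ppm bin width). Optional thresholds produce pass/fail flags.
#'
#' @param reps List of [mrs_spectrum()] (or [mrs_fid()], transformed
#'   internally).
#' @param window A [freq_window()].
#' @param thresholds Optional named list, e.g.
#'   `list(max = c(lo, hi), sd = c(lo, hi))`; a trace passes when every
#'   thresholded statistic lies inside its interval.
#' @return A data.frame (class `qa_report`), one row per trace, with the six
#'   statistics, the window bounds and a `pass` flag.
#' @export
qa_stats <- function(reps, window, thresholds = NULL) {
  if (inherits(reps, "mrs_spectrum") || inherits(reps, "mrs_fid")) reps <- list(reps)
  reps <- lapply(reps, function(r) if (inherits(r, "mrs_fid")) to_spectrum(r) else r)
  if (!all(vapply(reps, inherits, logical(1), "mrs_spectrum")))
    stop("'reps' must be mrs_spectrum or mrs_fid objects", call. = FALSE)
  ax <- reps[[1]]$ppm
  idx <- window_index(ax, window)
  if (length(idx) == 0L) stop("empty window: no axis points inside", call. = FALSE)
  dppm <- ax[2] - ax[1]
  rows <- lapply(seq_along(reps), function(i) {
    x <- Re(reps[[i]]$values[idx])
    data.frame(trace = i, min = min(x), max = max(x), mean = mean(x),
               median = stats::median(x), sd = stats::sd(x), integral = sum(x) * dppm)
  })
  out <- do.call(rbind, rows)
  out$lo_ppm <- window$lo_ppm
  out$hi_ppm <- window$hi_ppm
  pass <- rep(TRUE, nrow(out))
  if (!is.null(thresholds)) {
    for (nm in names(thresholds)) {
      if (!nm %in% c("min", "max", "mean", "median", "sd", "integral"))
        stop("parameter error: unknown threshold '", nm, "'", call. = FALSE)
      b <- thresholds[[nm]]
      pass <- pass & out[[nm]] >= b[1] & out[[nm]] <= b[2]
    }
  }
  out$pass <- pass
  class(out) <- c("qa_report", "data.frame")
  out
}

#' Alignment configuration
#'
#' Parameters of the amplitude-weighted cross-correlation alignment: the
#' frequency search half-range and grid resolution in Hz, the phase grid
#' step in degrees, the amplitude polynomial order (0 = single scale
#' factor), the spectral windows the metric is evaluated on, and optional
#' metric-only preprocessing (line broadening / cut / zero-fill) that never
#' leaks into the output data.
#'
#' @param windows List of [freq_window()] (non-empty).
#' @param freq_range_hz Search half-range in Hz.
#' @param freq_resolution_hz Frequency grid step in Hz (> 0).
#' @param phase_step_deg Phase grid step in degrees (> 0).
#' @param amp_poly_order Amplitude polynomial order (>= 0; 0 = scalar).
#' @param reference Repetition index, or `"mean"` for the mean of all traces
#'   (improved SNR).
#' @param preproc Optional list with `lorentz_hz`, `gauss_hz`, `cut`,
#'   `zero_fill` applied only inside the metric.
#' @return An `align_config` object.
#' @export
align_config <- function(windows, freq_range_hz = 10, freq_resolution_hz = 0.5,
                         phase_step_deg = 2, amp_poly_order = 0L,
                         reference = "mean", preproc = NULL) {
  windows <- as_windows(windows)
  if (length(windows) == 0L) stop("parameter error: need at least one window", call. = FALSE)
  if (freq_resolution_hz <= 0 || phase_step_deg <= 0 || freq_range_hz < 0)
    stop("parameter error: grid resolutions must be positive", call. = FALSE)
  if (amp_poly_order < 0) stop("parameter error: 'amp_poly_order' must be >= 0", call. = FALSE)
  structure(list(windows = windows, freq_range_hz = freq_range_hz,
                 freq_resolution_hz = freq_resolution_hz,
                 phase_step_deg = phase_step_deg,
                 amp_poly_order = as.integer(amp_poly_order),
                 reference = reference, preproc = preproc),
            class = "align_config")
}

metric_spectrum <- function(fid, preproc) {
  if (!is.null(preproc)) {
    if (!is.null(preproc$cut)) fid <- resize_fid(fid, preproc$cut)
    if (!is.null(preproc$lorentz_hz) || !is.null(preproc$gauss_hz))
      fid <- apodize(fid, preproc$lorentz_hz %||% 0, preproc$gauss_hz %||% 0)
    if (!is.null(preproc$zero_fill)) fid <- resize_fid(fid, preproc$zero_fill)
  }
  to_spectrum(fid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Align repetitions by amplitude-weighted cross-correlation
#'
#' For every trace, the frequency shift is searched on the grid
#' `seq(-freq_range, freq_range, freq_resolution)` and the zero-order phase
#' on the grid of step `phase_step_deg`, jointly maximizing the normalized
#' amplitude-weighted correlation
#' `S(df, phi) = sum_k |R_k| Re(exp(-i phi) Conj(R_k) T_k(df)) /
#' sqrt(sum |R_k|^2 * sum |T_k|^2)` over the window bins; the amplitude
#' polynomial (order 0 = scalar) is then fit by least squares within the
#' windows. Ties break toward smaller `|df|`, then smaller `|phi|`.
#' Corrections are applied to the unfiltered data.
#'
#' @param reps List of [mrs_fid()] repetitions.
#' @param cfg An [align_config()].
#' @return List with `reps` (aligned [mrs_fid()]s) and `corrections`
#'   (data.frame of `df_hz`, `phi0_deg`, `scale` and polynomial
#'   coefficients per repetition).
#' @export
align_reps <- function(reps, cfg) {
  if (!inherits(cfg, "align_config")) stop("'cfg' must be an align_config", call. = FALSE)
  if (!is.list(reps) || !all(vapply(reps, inherits, logical(1), "mrs_fid")))
    stop("'reps' must be a list of mrs_fid", call. = FALSE)
  header <- reps[[1]]$header
  # reference trace (in the metric space)
  ref_fid <- if (identical(cfg$reference, "mean")) {
    acc <- Reduce(`+`, lapply(reps, `[[`, "samples")) / length(reps)
    mrs_fid(acc, header)
  } else reps[[as.integer(cfg$reference)]]
  ref_spec <- metric_spectrum(ref_fid, cfg$preproc)
  idx <- windows_index(ref_spec$ppm, cfg$windows)
  R <- ref_spec$values[idx]
  if (all(Mod(R) == 0)) stop("invalid data: reference is zero within windows", call. = FALSE)
  df_grid <- seq(-cfg$freq_range_hz, cfg$freq_range_hz, by = cfg$freq_resolution_hz)
  if (length(df_grid) == 0L) stop("parameter error: empty frequency grid", call. = FALSE)
  phi_grid <- seq(-180, 180 - cfg$phase_step_deg, by = cfg$phase_step_deg)
  # tie-break ordering: prefer smaller |df| then smaller |phi|
  df_ord <- order(abs(df_grid), df_grid)
  phi_ord <- order(abs(phi_grid), phi_grid)
  wR <- Mod(R)
  normR <- sum(wR^2)
  t <- time_axis(header)
  out <- vector("list", length(reps))
  corr <- data.frame(rep = seq_along(reps), df_hz = 0, phi0_deg = 0, scale = 1)
  poly_coefs <- NULL
  for (r in seq_along(reps)) {
    best <- c(score = -Inf, df = 0, phi = 0)
    for (df in df_grid[df_ord]) {
      shifted <- mrs_fid(reps[[r]]$samples * exp(1i * 2 * pi * df * t), header)
      Tk <- metric_spectrum(shifted, cfg$preproc)$values[idx]
      normT <- sum(Mod(Tk)^2)
      if (normT == 0) next
      # C collects the amplitude-weighted cross term; the phi grid then
      # evaluates Re(exp(-i phi) C) without recomputing the FFT
      C <- sum(wR * Conj(R) * Tk)
      sc <- Re(exp(-1i * phi_grid * pi / 180) * C) / sqrt(normR * normT)
      j <- phi_ord[which.max(sc[phi_ord])]
      if (sc[j] > best["score"] + 1e-15) best <- c(score = sc[j], df = df, phi = phi_grid[j])
    }
    # apply frequency and phase to the unfiltered trace
    aligned <- reps[[r]]$samples * exp(1i * 2 * pi * best["df"] * t) *
      exp(-1i * best["phi"] * pi / 180)
    # amplitude alignment: real polynomial over ppm within windows, LS fit
    Ts <- to_spectrum(mrs_fid(aligned, header))
    idx_raw <- windows_index(Ts$ppm, cfg$windows)
    x <- Ts$ppm[idx_raw] - header$center_ppm
    Tk <- Ts$values[idx_raw]
    Rk_raw <- to_spectrum(ref_fid)$values[idx_raw]
    p <- cfg$amp_poly_order
    X <- outer(x, 0:p, `^`)
    A <- rbind(X * Re(Tk), X * Im(Tk))
    y <- c(Re(Rk_raw), Im(Rk_raw))
    cf <- tryCatch(stats::lm.fit(A, y)$coefficients, error = function(e) c(1, numeric(p)))
    cf[is.na(cf)] <- 0
    if (p == 0L) {
      aligned <- aligned * cf[1]
    } else {
      poly_ppm <- outer(Ts$ppm - header$center_ppm, 0:p, `^`) %*% cf
      aligned <- to_fid(mrs_spectrum(Ts$values * as.numeric(poly_ppm), header))$samples
    }
    out[[r]] <- mrs_fid(aligned, header)
    corr$df_hz[r] <- best["df"]
    corr$phi0_deg[r] <- best["phi"]
    corr$scale[r] <- cf[1]
    if (p > 0L) poly_coefs <- rbind(poly_coefs, cf)
  }
  if (!is.null(poly_coefs)) corr$poly <- I(split(poly_coefs, row(poly_coefs)))
  list(reps = out, corrections = corr)
}

#' Average repetitions
#'
#' Arithmetic mean of the selected traces; white noise SD drops as
#' `1/sqrt(n)`.
#'
#' @param reps List of [mrs_fid()].
#' @param selection Indices to keep (default: all).
#' @return The averaged [mrs_fid()].
#' @export
average_reps <- function(reps, selection = seq_along(reps)) {
  if (!is.list(reps) || !all(vapply(reps, inherits, logical(1), "mrs_fid")))
    stop("'reps' must be a list of mrs_fid", call. = FALSE)
  if (length(selection) == 0L) stop("parameter error: empty selection", call. = FALSE)
  acc <- Reduce(`+`, lapply(reps[selection], `[[`, "samples")) / length(selection)
  mrs_fid(acc, reps[[1]]$header)
}

#' Condition-specific processing of J-difference edited data
#'
#' Runs channel combination, alignment and averaging separately per editing
#' condition (each condition aligned against its own reference, since ON and
#' OFF spectra are inherently distinct), then forms the difference spectrum
#' `DIFF = spectrum(ON) - spectrum(OFF)`.
#'
#' @param ds An [mrs_dataset()] whose `condition_labels` contain at least
#'   two conditions (conventionally `"ON"`/`"OFF"`).
#' @param cfg An [align_config()]; set to `NULL` to skip alignment.
#' @param method,weighting Passed to [combine_channels()].
#' @return List with per-condition averaged FIDs (named by label), and
#'   `diff`, an [mrs_spectrum()] of ON minus OFF (first minus second label
#'   in `c("ON","OFF")` order when present, else alphabetical).
#' @export
jde_process <- function(ds, cfg, method = "klose", weighting = "sensitivity") {
  if (!inherits(ds, "mrs_dataset")) stop("'ds' must be an mrs_dataset", call. = FALSE)
  labs <- unique(ds$condition_labels)
  if (length(labs) < 2L)
    stop("invalid data: need at least two editing conditions", call. = FALSE)
  labs <- if (all(c("ON", "OFF") %in% labs)) c("ON", "OFF", setdiff(labs, c("ON", "OFF")))
          else sort(labs)
  combined <- combine_channels(ds, method, weighting)
  avg <- list()
  for (lab in labs) {
    sel <- which(ds$condition_labels == lab)
    if (length(sel) == 0L) stop("invalid data: condition '", lab, "' has no repetitions",
                                call. = FALSE)
    reps <- combined$reps[sel]
    if (!is.null(cfg)) reps <- align_reps(reps, cfg)$reps
    avg[[lab]] <- average_reps(reps)
  }
  diff <- mrs_spectrum(to_spectrum(avg[[labs[1]]])$values - to_spectrum(avg[[labs[2]]])$values,
                       ds$header)
  c(avg, list(diff = diff))
}
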