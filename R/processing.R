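#' Polynomial baseline correction over anchor windows
#'
#' Fits a polynomial (least squares) to the real part of the spectrum within
#' the anchor windows and subtracts it from the whole axis.
#'
#' @param spec An [mrs_spectrum()].
#' @param anchor_windows List of [freq_window()] regions assumed free of
#'   signal.
#' @param order Polynomial order (0..10).
#' @return List with `corrected` ([mrs_spectrum()]) and `baseline` (numeric
#'   vector over the full axis).
#' @export
baseline_poly <- function(spec, anchor_windows, order = 2L) {
  if (!inherits(spec, "mrs_spectrum")) stop("'spec' must be an mrs_spectrum", call. = FALSE)
  order <- as.integer(order)
  if (order < 0L || order > 10L)
    stop("parameter error: 'order' must be in 0..10", call. = FALSE)
  idx <- windows_index(spec$ppm, anchor_windows)
  if (length(idx) < order + 1L)
    stop("rank-deficient baseline fit: fewer anchor points than order + 1; ",
         "use a lower order or wider anchors", call. = FALSE)
  x <- spec$ppm - spec$header$center_ppm
  X <- outer(x[idx], 0:order, `^`)
  cf <- stats::lm.fit(X, Re(spec$values[idx]))$coefficients
  if (anyNA(cf))
    stop("rank-deficient baseline fit; use a lower order", call. = FALSE)
  base <- as.numeric(outer(x, 0:order, `^`) %*% cf)
  list(corrected = mrs_spectrum(spec$values - base, spec$header), baseline = base)
}

#' HSVD decomposition of a FID into damped complex exponentials
#'
#' Models the FID as `sum_k a_k exp(i phi_k) exp((i 2 pi f_k - pi d_k) t)`
#' via the Hankel singular value decomposition: a Hankel matrix of size
#' `ceiling(N/2) x (N + 1 - ceiling(N/2))` is truncated to rank K, signal
#' poles follow from the least-squares shift invariance of the truncated
#' left singular vectors (Kung's method), and amplitudes/phases from a
#' linear fit. Exact on noiseless sums of at most K damped exponentials.
#'
#' @param fid An [mrs_fid()].
#' @param model_order K, the number of exponential components (`K < N/2`).
#' @return A data.frame (one row per component, sorted by amplitude,
#'   descending) with `frequency_hz` (offset from the carrier),
#'   `damping_hz` (Lorentzian FWHM; negative = growing, flagged via the
#'   `growing` column), `amplitude`, `phase_deg`.
#' @export
hsvd_decompose <- function(fid, model_order) {
  if (!inherits(fid, "mrs_fid")) stop("'fid' must be an mrs_fid", call. = FALSE)
  n <- fid$header$n_points
  K <- as.integer(model_order)
  if (K < 1L || K >= n / 2) stop("parameter error: need 1 <= K < N/2", call. = FALSE)
  L <- ceiling(n / 2)
  M <- n + 1L - L
  H <- matrix(0 + 0i, L, M)
  for (j in seq_len(M)) H[, j] <- fid$samples[(j):(j + L - 1L)]
  sv <- svd(H, nu = K, nv = 0)
  U <- sv$u
  # shift invariance: U_bottom ~= U_top %*% Z
  Ut <- U[seq_len(L - 1L), , drop = FALSE]
  Ub <- U[2:L, , drop = FALSE]
  Z <- qr.solve(Ut, Ub)
  z <- eigen(Z, only.values = TRUE)$values
  dt <- 1 / fid$header$bandwidth_hz
  freq <- Arg(z) / (2 * pi * dt)
  damp <- -log(Mod(z)) / (pi * dt)      # Lorentzian FWHM in Hz
  # linear LS for complex amplitudes
  tt <- time_axis(fid$header)
  B <- exp(outer(tt, (1i * 2 * pi * freq - pi * damp)))
  cf <- qr.solve(qr(B, LAPACK = TRUE), fid$samples)
  out <- data.frame(frequency_hz = freq, damping_hz = damp,
                    amplitude = Mod(cf), phase_deg = Arg(cf) * 180 / pi)
  out$growing <- out$damping_hz < 0
  out[order(-out$amplitude), , drop = FALSE]
}

hsvd_reconstruct <- function(components, header, subset = seq_len(nrow(components))) {
  tt <- time_axis(header)
  acc <- complex(real = numeric(header$n_points))
  for (k in subset) {
    acc <- acc + components$amplitude[k] * exp(1i * components$phase_deg[k] * pi / 180) *
      exp((1i * 2 * pi * components$frequency_hz[k] - pi * components$damping_hz[k]) * tt)
  }
  mrs_fid(acc, header)
}

#' Remove spectral components in a band by HSVD filtering
#'
#' Decomposes the FID with [hsvd_decompose()] and subtracts the modeled
#' components whose frequency lies inside `remove_band` (typically the
#' residual water around 4.65 ppm). Out-of-band resonances are untouched up
#' to the model residual.
#'
#' @param fid An [mrs_fid()].
#' @param model_order K passed to [hsvd_decompose()].
#' @param remove_band A [freq_window()] in ppm.
#' @return The filtered [mrs_fid()].
#' @export
hsvd_filter <- function(fid, model_order, remove_band) {
  if (!inherits(remove_band, "freq_window"))
    stop("'remove_band' must be a freq_window", call. = FALSE)
  comp <- hsvd_decompose(fid, model_order)
  f_ppm <- fid$header$center_ppm + comp$frequency_hz / fid$header$larmor_mhz
  inside <- which(f_ppm >= remove_band$lo_ppm & f_ppm <= remove_band$hi_ppm)
  if (length(inside) == 0L) return(fid)
  rem <- hsvd_reconstruct(comp, fid$header, inside)
  mrs_fid(fid$samples - rem$samples, fid$header)
}

# --- advanced two-spectrum alignment ---------------------------------------

advanced_aspects <- c("freq", "phase0", "phase1", "lorentz", "gauss",
                      "scale", "offset", "baseline")

# apply the transform chain to mov (an mrs_fid) for a named parameter vector
apply_advanced <- function(mov_fid, par, baseline_order, header) {
  t <- time_axis(header)
  s <- mov_fid$samples
  lb <- max(par["lorentz"] %||na% 0, 0)
  gb <- max(par["gauss"] %||na% 0, 0)
  if (lb > 0 || gb > 0)
    s <- s * exp(-pi * lb * t) * exp(-(pi * gb * t)^2 / (4 * log(2)))
  df <- par["freq"] %||na% 0
  if (df != 0) s <- s * exp(1i * 2 * pi * df * t)
  sc <- par["scale"] %||na% 1
  s <- s * sc
  spec <- to_spectrum(mrs_fid(s, header))
  v <- spec$values
  ph0 <- par["phase0"] %||na% 0
  ph1 <- par["phase1"] %||na% 0
  if (ph0 != 0 || ph1 != 0) {
    ph <- (ph0 + ph1 * (spec$ppm - header$center_ppm)) * pi / 180
    v <- v * exp(1i * ph)
  }
  off <- par["offset"] %||na% 0
  v <- v + off
  if (baseline_order >= 0) {
    x <- spec$ppm - header$center_ppm
    for (j in 0:baseline_order) {
      cj <- par[paste0("b", j)] %||na% 0
      if (cj != 0) v <- v + cj * x^j
    }
  }
  mrs_spectrum(v, header)
}

`%||na%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else unname(a)

#' Advanced alignment of two spectra by nonlinear least squares
#'
#' Aligns a moving spectrum onto a reference by minimizing the windowed
#' squared residual over up to 8 aspects of spectral processing: frequency
#' shift (Hz), zero-order phase (deg), first-order phase (deg/ppm),
#' Lorentzian and Gaussian broadening (Hz), amplitude scale, constant
#' offset, and a polynomial baseline. The transform applies broadening,
#' shift and scale in the time domain, then phase, offset and baseline in
#' the frequency domain. Levenberg-Marquardt with a numeric Jacobian,
#' multi-started from identity plus a grid-scanned frequency optimum; the
#' returned solution never has a larger windowed residual than the identity
#' parameters.
#'
#' @param ref Reference [mrs_spectrum()].
#' @param mov Moving [mrs_spectrum()] on the same grid.
#' @param windows List of [freq_window()] over which residuals are computed
#'   (regions expected to be condition-independent in JDE use).
#' @param aspects Character vector out of
#'   `c("freq","phase0","phase1","lorentz","gauss","scale","offset","baseline")`.
#' @param baseline_order Polynomial order when `"baseline"` is enabled.
#' @param tol Convergence tolerance on objective and step (default 1e-8).
#' @param max_iter Maximum optimizer iterations.
#' @return List with `aligned` ([mrs_spectrum()]), `par` (named fitted
#'   values), `objective`, `objective_identity` and `converged`.
#' @export
advanced_align <- function(ref, mov, windows, aspects = c("freq", "phase0"),
                           baseline_order = 2L, tol = 1e-8, max_iter = 200L) {
  if (!inherits(ref, "mrs_spectrum") || !inherits(mov, "mrs_spectrum"))
    stop("'ref' and 'mov' must be mrs_spectrum objects", call. = FALSE)
  aspects <- match.arg(aspects, advanced_aspects, several.ok = TRUE)
  if (length(aspects) == 0L) stop("parameter error: enable at least one aspect", call. = FALSE)
  header <- mov$header
  idx <- windows_index(ref$ppm, windows)
  mov_fid <- to_fid(mov)
  refv <- ref$values[idx]
  b_ord <- if ("baseline" %in% aspects) as.integer(baseline_order) else -1L
  par0 <- c(freq = 0, phase0 = 0, phase1 = 0, lorentz = 0, gauss = 0,
            scale = 1, offset = 0)
  if (b_ord >= 0) par0 <- c(par0, stats::setNames(numeric(b_ord + 1L),
                                                  paste0("b", 0:b_ord)))
  free <- aspects[aspects != "baseline"]
  if (b_ord >= 0) free <- c(free, paste0("b", 0:b_ord))
  resid_fn <- function(p_free) {
    par <- par0
    par[names(p_free)] <- p_free
    v <- apply_advanced(mov_fid, par, b_ord, header)$values[idx]
    r <- refv - v
    c(Re(r), Im(r))
  }
  obj <- function(p_free) sum(resid_fn(p_free)^2)
  lower <- stats::setNames(rep(-Inf, length(free)), free)
  upper <- stats::setNames(rep(Inf, length(free)), free)
  lower[free %in% c("lorentz", "gauss")] <- 0
  starts <- list(par0[free])
  if ("freq" %in% free) {
    # coarse grid scan for the frequency start (phase/freq ambiguity)
    grid <- seq(-10, 10, by = 0.5)
    sc <- vapply(grid, function(g) {
      p <- par0[free]; p["freq"] <- g; obj(p)
    }, numeric(1))
    p2 <- par0[free]
    p2["freq"] <- grid[which.min(sc)]
    starts <- c(starts, list(p2))
  }
  best <- NULL
  conv <- FALSE
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower[names(st)], upper = upper[names(st)],
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           ftol = tol, ptol = tol, maxiter = max_iter)),
      error = function(e) NULL)
    if (is.null(fit)) next
    o <- sum(fit$fvec^2)
    if (is.null(best) || o < best$o) {
      best <- list(par = fit$par, o = o)
      conv <- fit$info %in% 1:4
    }
  }
  o_id <- obj(par0[free])
  if (is.null(best) || best$o > o_id) {
    best <- list(par = par0[free], o = o_id)
    conv <- FALSE
    warning("advanced_align: optimizer did not improve on identity; returning identity")
  }
  par <- par0
  par[names(best$par)] <- best$par
  list(aligned = apply_advanced(mov_fid, par, b_ord, header),
       par = par, objective = best$o, objective_identity = o_id, converged = conv)
}

# --- spectral quality metrics ----------------------------------------------

#' Signal-to-noise ratio over user-defined windows
#'
#' Maximum of the real part in the signal window divided by the SD of the
#' real part in the noise window after first-order polynomial detrending of
#' the noise window (no factor 2 convention).
#'
#' @param spec An [mrs_spectrum()].
#' @param signal_window,noise_window Disjoint [freq_window()]s.
#' @return The SNR as a single number.
#' @export
snr <- function(spec, signal_window, noise_window) {
  if (!inherits(spec, "mrs_spectrum")) stop("'spec' must be an mrs_spectrum", call. = FALSE)
  if (signal_window$hi_ppm > noise_window$lo_ppm && noise_window$hi_ppm > signal_window$lo_ppm)
    stop("parameter error: signal and noise windows must be disjoint", call. = FALSE)
  si <- window_index(spec$ppm, signal_window)
  ni <- window_index(spec$ppm, noise_window)
  if (length(si) == 0L || length(ni) == 0L) stop("empty window", call. = FALSE)
  noise <- Re(spec$values[ni])
  if (stats::var(noise) == 0)
    stop("invalid data: zero-variance noise window", call. = FALSE)
  x <- spec$ppm[ni]
  det <- stats::lm.fit(cbind(1, x), noise)$residuals
  s <- stats::sd(det)
  if (s == 0) stop("invalid data: zero-variance noise window", call. = FALSE)
  max(Re(spec$values[si])) / s
}

#' Full width at half maximum of the tallest peak in a window
#'
#' Finds the real-part maximum inside the window and linearly interpolates
#' the half-maximum crossings on both sides.
#'
#' @param spec An [mrs_spectrum()].
#' @param peak_window A [freq_window()].
#' @return List with `fwhm_hz` and `fwhm_ppm`.
#' @export
fwhm <- function(spec, peak_window) {
  if (!inherits(spec, "mrs_spectrum")) stop("'spec' must be an mrs_spectrum", call. = FALSE)
  idx <- window_index(spec$ppm, peak_window)
  if (length(idx) < 3L) stop("empty window", call. = FALSE)
  y <- Re(spec$values)
  x <- spec$ppm
  k <- idx[which.max(y[idx])]
  half <- y[k] / 2
  # walk left
  i <- k
  while (i > 1 && y[i] > half) i <- i - 1
  if (y[i] > half) stop("half-maximum not bracketed on the left", call. = FALSE)
  xl <- x[i] + (half - y[i]) / (y[i + 1] - y[i]) * (x[i + 1] - x[i])
  j <- k
  n <- length(y)
  while (j < n && y[j] > half) j <- j + 1
  if (y[j] > half) stop("half-maximum not bracketed on the right", call. = FALSE)
  xr <- x[j - 1] + (half - y[j - 1]) / (y[j] - y[j - 1]) * (x[j] - x[j - 1])
  w_ppm <- xr - xl
  list(fwhm_hz = w_ppm * spec$header$larmor_mhz, fwhm_ppm = w_ppm)
}

#' Peak integral over a window
#'
#' Riemann sum of the real part times the ppm bin width (multiply by
#' `larmor_mhz` for Hz units).
#'
#' @param spec An [mrs_spectrum()].
#' @param window A [freq_window()].
#' @return The integral (real part, ppm units).
#' @export
integral <- function(spec, window) {
  if (!inherits(spec, "mrs_spectrum")) stop("'spec' must be an mrs_spectrum", call. = FALSE)
  idx <- window_index(spec$ppm, window)
  if (length(idx) == 0L) stop("empty window", call. = FALSE)
  sum(Re(spec$values[idx])) * (spec$ppm[2] - spec$ppm[1])
}
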