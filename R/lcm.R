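#' Linear combination model specification
#'
#' Defines the parametric forward model fit to a spectrum: per metabolite an
#' amplitude `a_m >= 0`, a frequency shift `delta_m` (Hz, bounded) and a
#' Lorentzian broadening `lambda_m` (Hz, >= 0); globally a Gaussian
#' broadening `gamma` (Voigt in combination), zero- and first-order phase;
#' and a baseline (polynomial of order <= 10 and/or a cubic b-spline with
#' knot interval `kappa` ppm and smoothing weight `w`). The model spectrum is
#'
#' `S(nu) = exp(i(phi0 + phi1 (nu - pivot)) pi/180) * sum_m a_m
#'   FFT{ b_m(t) exp(i 2 pi delta_m t) exp(-pi lambda_m t)
#'        exp(-(pi gamma t)^2 / (4 ln 2)) }(nu) + poly(nu) + spline(nu)`
#'
#' and is linear in each amplitude and baseline coefficient. Residuals are
#' evaluated on the fit window(s), stacking real and imaginary parts
#' (`domain = "complex"`, the default) or real only.
#'
#' @param basis A [basis_set()].
#' @param fit_windows List of [freq_window()] (or one window).
#' @param baseline_order Polynomial baseline order, or `NULL` for none
#'   (<= 10).
#' @param spline Optional list `list(knot_ppm = kappa, weight = w)` enabling
#'   a cubic b-spline baseline over the fit window.
#' @param domain `"complex"` or `"real"`.
#' @param fit Named logical vector switching parameter classes:
#'   `shifts`, `lorentz` (per metabolite), `gauss`, `phase0`, `phase1`
#'   (global).
#' @param bounds Named list overriding defaults `shift_hz = 5 * B0/3T`,
#'   `lorentz_hz = c(0, 20)`, `gauss_hz = c(0, 20)`, `phase0_deg = c(-180,
#'   180)`, `phase1_deg_per_ppm = c(-10, 10)`.
#' @param noise_window Optional [freq_window()] for the residual-based noise
#'   SD estimate (fallback: RSS-based).
#' @return An `lcm_model` object.
#' @export
lcm_model <- function(basis, fit_windows, baseline_order = 2L, spline = NULL,
                      domain = c("complex", "real"),
                      fit = c(shifts = TRUE, lorentz = TRUE, gauss = FALSE,
                              phase0 = TRUE, phase1 = FALSE),
                      bounds = list(), noise_window = NULL) {
  if (!inherits(basis, "basis_set")) stop("'basis' must be a basis_set", call. = FALSE)
  domain <- match.arg(domain)
  fit_windows <- as_windows(fit_windows)
  if (!is.null(baseline_order)) {
    baseline_order <- as.integer(baseline_order)
    if (baseline_order < 0L || baseline_order > 10L)
      stop("parameter error: baseline order must be in 0..10", call. = FALSE)
  }
  if (!is.null(spline)) {
    if (is.null(spline$knot_ppm) || spline$knot_ppm <= 0)
      stop("parameter error: spline knot interval must be > 0", call. = FALSE)
    spline$weight <- spline$weight %||% 0
    if (spline$weight < 0) stop("parameter error: spline weight must be >= 0", call. = FALSE)
  }
  f0 <- c(shifts = TRUE, lorentz = TRUE, gauss = FALSE, phase0 = TRUE, phase1 = FALSE)
  f0[names(fit)] <- fit
  b0tesla <- basis$header$larmor_mhz / 42.577478
  b <- list(shift_hz = 5 * b0tesla / 3, lorentz_hz = c(0, 20), gauss_hz = c(0, 20),
            phase0_deg = c(-180, 180), phase1_deg_per_ppm = c(-10, 10))
  b[names(bounds)] <- bounds
  structure(list(basis = basis, fit_windows = fit_windows,
                 baseline_order = baseline_order, spline = spline,
                 domain = domain, fit = f0, bounds = b,
                 noise_window = noise_window),
            class = "lcm_model")
}

# parameter packing: th = (a_m..., d_m..., l_m..., gamma, phi0, phi1, poly..., spl...)
lcm_par_info <- function(model, ppm_fit) {
  mets <- names(model$basis$entries)
  M <- length(mets)
  nm <- c(paste0("a_", mets))
  lo <- rep(0, M)
  hi <- rep(Inf, M)
  init <- rep(1, M)
  if (model$fit[["shifts"]]) {
    nm <- c(nm, paste0("d_", mets))
    lo <- c(lo, rep(-model$bounds$shift_hz, M))
    hi <- c(hi, rep(model$bounds$shift_hz, M))
    init <- c(init, rep(0, M))
  }
  if (model$fit[["lorentz"]]) {
    nm <- c(nm, paste0("l_", mets))
    lo <- c(lo, rep(model$bounds$lorentz_hz[1], M))
    hi <- c(hi, rep(model$bounds$lorentz_hz[2], M))
    init <- c(init, rep(0.5, M))
  }
  if (model$fit[["gauss"]]) {
    nm <- c(nm, "gamma")
    lo <- c(lo, model$bounds$gauss_hz[1])
    hi <- c(hi, model$bounds$gauss_hz[2])
    init <- c(init, 0.5)
  }
  if (model$fit[["phase0"]]) {
    nm <- c(nm, "phi0")
    lo <- c(lo, model$bounds$phase0_deg[1])
    hi <- c(hi, model$bounds$phase0_deg[2])
    init <- c(init, 0)
  }
  if (model$fit[["phase1"]]) {
    nm <- c(nm, "phi1")
    lo <- c(lo, model$bounds$phase1_deg_per_ppm[1])
    hi <- c(hi, model$bounds$phase1_deg_per_ppm[2])
    init <- c(init, 0)
  }
  if (!is.null(model$baseline_order)) {
    nb <- model$baseline_order + 1L
    nm <- c(nm, paste0("b", 0:model$baseline_order))
    lo <- c(lo, rep(-Inf, nb))
    hi <- c(hi, rep(Inf, nb))
    init <- c(init, rep(0, nb))
  }
  spl_basis <- NULL
  if (!is.null(model$spline)) {
    rng <- range(ppm_fit)
    knots <- seq(rng[1] - 2 * model$spline$knot_ppm, rng[2] + 2 * model$spline$knot_ppm,
                 by = model$spline$knot_ppm)
    spl_basis <- splines::splineDesign(knots, ppm_fit, ord = 4, outer.ok = TRUE)
    ns <- ncol(spl_basis)
    nm <- c(nm, paste0("s", seq_len(ns)))
    lo <- c(lo, rep(-Inf, ns))
    hi <- c(hi, rep(Inf, ns))
    init <- c(init, rep(0, ns))
  }
  list(names = nm, lower = stats::setNames(lo, nm), upper = stats::setNames(hi, nm),
       init = stats::setNames(init, nm), mets = mets, spl_basis = spl_basis)
}

#' Evaluate the LCM forward model
#'
#' @param model An [lcm_model()].
#' @param theta Named parameter vector (`a_<met>`, optionally `d_<met>`,
#'   `l_<met>`, `gamma`, `phi0`, `phi1`, `b0..`, `s1..`); missing names take
#'   amplitude 0 / neutral values.
#' @return An [mrs_spectrum()] of the model over the full axis (spline
#'   baseline evaluated within the fit window, zero outside).
#' @export
model_eval <- function(model, theta) {
  if (!inherits(model, "lcm_model")) stop("'model' must be an lcm_model", call. = FALSE)
  h <- model$basis$header
  ax <- ppm_axis(h)
  idx <- windows_index(ax, model$fit_windows)
  info <- lcm_par_info(model, ax[idx])
  th <- info$init * 0
  th[names(th)] <- 0
  th[paste0("a_", info$mets)] <- 0
  ok <- intersect(names(theta), names(th))
  th[ok] <- theta[ok]
  v <- lcm_model_values(model, th, info, ax, idx)
  mrs_spectrum(v, h)
}

# full-axis complex model values
lcm_model_values <- function(model, th, info, ax, idx) {
  h <- model$basis$header
  t <- time_axis(h)
  n <- h$n_points
  acc <- complex(real = numeric(n))
  gam <- if (model$fit[["gauss"]]) th[["gamma"]] else 0
  gw <- if (gam > 0) exp(-(pi * gam * t)^2 / (4 * log(2))) else 1
  for (m in info$mets) {
    a <- th[[paste0("a_", m)]]
    if (a == 0) next
    s <- model$basis$entries[[m]]
    d <- if (model$fit[["shifts"]]) th[[paste0("d_", m)]] else 0
    l <- if (model$fit[["lorentz"]]) th[[paste0("l_", m)]] else 0
    w <- gw
    if (d != 0) w <- w * exp(1i * 2 * pi * d * t)
    if (l > 0) w <- w * exp(-pi * l * t)
    acc <- acc + a * s * w
  }
  v <- fftshift(stats::fft(acc)) / n
  phi0 <- if (model$fit[["phase0"]]) th[["phi0"]] else 0
  phi1 <- if (model$fit[["phase1"]]) th[["phi1"]] else 0
  if (phi0 != 0 || phi1 != 0)
    v <- v * exp(1i * (phi0 + phi1 * (ax - h$center_ppm)) * pi / 180)
  if (!is.null(model$baseline_order)) {
    x <- ax - h$center_ppm
    for (j in 0:model$baseline_order) {
      cj <- th[[paste0("b", j)]]
      if (cj != 0) v <- v + cj * x^j
    }
  }
  if (!is.null(info$spl_basis)) {
    sc <- th[grep("^s[0-9]+$", names(th))]
    if (any(sc != 0)) v[idx] <- v[idx] + as.numeric(info$spl_basis %*% sc)
  }
  v
}

lcm_residual_fn <- function(model, spec, info, ax, idx) {
  data <- spec$values[idx]
  pen <- NULL
  if (!is.null(model$spline) && model$spline$weight > 0) {
    ns <- ncol(info$spl_basis)
    D2 <- diff(diag(ns), differences = 2)
    pen <- sqrt(model$spline$weight) * D2
  }
  function(th) {
    v <- lcm_model_values(model, th, info, ax, idx)[idx]
    r <- data - v
    out <- if (model$domain == "complex") c(Re(r), Im(r)) else Re(r)
    if (!is.null(pen)) {
      sc <- th[grep("^s[0-9]+$", names(th))]
      out <- c(out, as.numeric(pen %*% sc))
    }
    out
  }
}

#' Fit the linear combination model
#'
#' Bound-constrained Levenberg-Marquardt least squares on the stacked
#' real+imaginary (or real-only) residuals over the fit windows, with
#' user-set tolerances and iteration/evaluation budgets. Non-convergence is
#' reported in the `status` field, not thrown. The result carries CRLBs for
#' every parameter, the full correlation matrix and Hessian standard
#' errors; see [crlb()], [combined_crlb()], [monte_carlo()].
#'
#' @param model An [lcm_model()].
#' @param spec The measured [mrs_spectrum()] (grid must match the basis;
#'   a mismatched grid is an error).
#' @param start Optional named start values overriding the defaults.
#' @param tol_fun,tol_step Objective and step tolerances (default 1e-8).
#' @param max_iter Maximum iterations (default 100).
#' @param max_fun_evals Maximum residual evaluations (default 10000).
#' @return An object of class `lcm_fit`: estimates (`par`), `model_spectrum`,
#'   `baseline`, `residual`, `sigma` (noise SD estimate), `crlb`,
#'   `crlb_pct` (amplitudes), `correlation`, `hessian_se`, convergence
#'   diagnostics, and the inputs needed for error propagation.
#' @export
lcm_fit <- function(model, spec, start = NULL, tol_fun = 1e-8, tol_step = 1e-8,
                    max_iter = 100L, max_fun_evals = 10000L) {
  if (!inherits(model, "lcm_model")) stop("'model' must be an lcm_model", call. = FALSE)
  if (!inherits(spec, "mrs_spectrum")) stop("'spec' must be an mrs_spectrum", call. = FALSE)
  h <- model$basis$header
  if (spec$header$n_points != h$n_points ||
      abs(spec$header$bandwidth_hz - h$bandwidth_hz) > 1e-9 ||
      abs(spec$header$larmor_mhz - h$larmor_mhz) > 1e-9)
    stop("invalid data: spectrum grid does not match basis grid", call. = FALSE)
  ax <- spec$ppm
  idx <- windows_index(ax, model$fit_windows)
  info <- lcm_par_info(model, ax[idx])
  th0 <- info$init
  # data-scaled amplitude start
  amp0 <- max(Re(spec$values[idx])) /
    max(vapply(model$basis$entries, function(s) max(Mod(fftshift(stats::fft(s)) / h$n_points)),
               numeric(1)))
  th0[paste0("a_", info$mets)] <- max(amp0, .Machine$double.eps)
  if (!is.null(start)) {
    ok <- intersect(names(start), names(th0))
    th0[ok] <- start[ok]
  }
  th0 <- pmin(pmax(th0, info$lower), info$upper)
  fn <- lcm_residual_fn(model, spec, info, ax, idx)
  res <- minpack.lm::nls.lm(par = th0, lower = info$lower, upper = info$upper, fn = fn,
                            control = minpack.lm::nls.lm.control(
                              ftol = tol_fun, ptol = tol_step,
                              maxiter = as.integer(max_iter),
                              maxfev = as.integer(max_fun_evals)))
  th <- res$par
  status <- if (res$info %in% 1:4) "converged"
            else if (res$info == 5) "max_iter" else paste0("info_", res$info)
  vfull <- lcm_model_values(model, th, info, ax, idx)
  # baseline alone (amplitudes off, phases neutral)
  thb <- th
  thb[paste0("a_", info$mets)] <- 0
  if (model$fit[["phase0"]]) thb[["phi0"]] <- 0
  if (model$fit[["phase1"]]) thb[["phi1"]] <- 0
  baseline <- Re(lcm_model_values(model, thb, info, ax, idx))
  residual <- spec$values - vfull
  n_res <- if (model$domain == "complex") 2L * length(idx) else length(idx)
  p <- length(th)
  rss_vec <- fn(th)
  rss <- sum(rss_vec[seq_len(n_res)]^2)
  sigma <- if (!is.null(model$noise_window)) {
    ni <- window_index(ax, model$noise_window)
    stats::sd(Re(residual[ni]))
  } else sqrt(rss / max(n_res - p, 1))
  # numeric Jacobian of the model (central differences, relative step 1e-6)
  J <- lcm_jacobian(fn, th, info)
  fit <- structure(list(par = th, model = model, spec = spec, info = info,
                        idx = idx, model_spectrum = mrs_spectrum(vfull, h),
                        baseline = baseline, residual = residual,
                        sigma = sigma, rss = rss, n_res = n_res,
                        status = status, iterations = res$niter,
                        objective = res$deviance, jacobian = J),
                   class = "lcm_fit")
  eb <- crlb(fit, sigma)
  fit$crlb <- eb$crlb
  fit$crlb_pct <- eb$crlb_pct
  fit$correlation <- eb$correlation
  fit$unidentifiable <- eb$unidentifiable
  fit$hessian_se <- hessian_errors(fit)
  fit
}

# central-difference Jacobian of the residual vector (sign: d resid / d th)
lcm_jacobian <- function(fn, th, info) {
  p <- length(th)
  r0 <- fn(th)
  J <- matrix(0, length(r0), p)
  for (k in seq_len(p)) {
    step <- max(abs(th[k]), 1) * 1e-6
    tp <- th
    tm <- th
    tp[k] <- min(th[k] + step, info$upper[k])
    tm[k] <- max(th[k] - step, info$lower[k])
    d <- tp[k] - tm[k]
    if (d == 0) next
    J[, k] <- (fn(tp) - fn(tm)) / d
  }
  colnames(J) <- names(th)
  J
}

#' @export
print.lcm_fit <- function(x, ...) {
  cat(sprintf("<lcm_fit> %s after %d iterations, sigma = %.4g\n",
              x$status, x$iterations, x$sigma))
  a <- x$par[paste0("a_", x$info$mets)]
  tab <- data.frame(metabolite = x$info$mets, amplitude = unname(a),
                    crlb = unname(x$crlb[paste0("a_", x$info$mets)]),
                    crlb_pct = unname(x$crlb_pct))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Cramer-Rao lower bounds and correlation matrix
#'
#' From the numeric Jacobian J of the stacked residuals, the Fisher matrix
#' is `F = J'J / sigma^2`; `CRLB_k = sqrt((F^-1)_kk)`, the correlation
#' matrix is the normalized `F^-1`, and relative amplitude CRLBs are
#' `CRLB(a_m)/a_m * 100`. CRLBs scale exactly linearly in sigma. A singular
#' Fisher matrix falls back to the pseudo-inverse with the unidentifiable
#' parameters flagged. The spline-penalty rows (if any) are excluded.
#'
#' @param fitresult An `lcm_fit`.
#' @param noise_sd Noise SD estimate; defaults to the fit's `sigma`.
#' @return List with `crlb` (named), `crlb_pct` (amplitudes), `correlation`,
#'   `fisher` and `unidentifiable` (names, possibly empty).
#' @export
crlb <- function(fitresult, noise_sd = fitresult$sigma) {
  if (!inherits(fitresult, "lcm_fit")) stop("'fitresult' must be an lcm_fit", call. = FALSE)
  J <- fitresult$jacobian[seq_len(fitresult$n_res), , drop = FALSE]
  Fm <- crossprod(J) / noise_sd^2
  inv <- tryCatch(solve(Fm), error = function(e) NULL)
  unident <- character(0)
  if (is.null(inv)) {
    e <- eigen(Fm, symmetric = TRUE)
    tol <- max(e$values) * 1e-12
    keep <- e$values > tol
    inv <- e$vectors[, keep, drop = FALSE] %*%
      ((1 / e$values[keep]) * t(e$vectors[, keep, drop = FALSE]))
    null_w <- rowSums(abs(e$vectors[, !keep, drop = FALSE]))
    unident <- names(fitresult$par)[null_w > 1e-6]
    warning("singular Fisher matrix; pseudo-inverse used; unidentifiable: ",
            paste(unident, collapse = ", "))
  }
  cr <- sqrt(pmax(diag(inv), 0))
  names(cr) <- names(fitresult$par)
  a <- fitresult$par[paste0("a_", fitresult$info$mets)]
  pct <- 100 * cr[paste0("a_", fitresult$info$mets)] / ifelse(a > 0, a, NA)
  corr <- inv / outer(sqrt(pmax(diag(inv), .Machine$double.xmin)),
                      sqrt(pmax(diag(inv), .Machine$double.xmin)))
  dimnames(corr) <- list(names(fitresult$par), names(fitresult$par))
  list(crlb = cr, crlb_pct = stats::setNames(unname(pct), fitresult$info$mets),
       correlation = corr, fisher = Fm, unidentifiable = unident)
}

#' CRLB of linear parameter combinations via the prior-knowledge matrix
#'
#' For a combination vector (or matrix of rows) L, `var(L theta) =
#' L F^-1 L'`; with a reduced parameterization `theta = P theta_red` the
#' reduced Fisher matrix is `F' = P' F P`. Summed estimates such as
#' NAA+NAAG or Glu+Gln are rows of L selecting the amplitudes.
#'
#' @param fitresult An `lcm_fit`.
#' @param L Numeric vector or matrix; columns must match the parameter
#'   count. Convenience: a character vector of metabolite names builds the
#'   amplitude-sum row.
#' @param P Optional prior-knowledge reparameterization matrix (full
#'   parameters x reduced parameters, full column rank).
#' @param noise_sd Noise SD; defaults to the fit's estimate.
#' @return Named numeric vector of combined CRLBs (one per row of L).
#' @export
combined_crlb <- function(fitresult, L, P = NULL, noise_sd = fitresult$sigma) {
  if (!inherits(fitresult, "lcm_fit")) stop("'fitresult' must be an lcm_fit", call. = FALSE)
  p <- length(fitresult$par)
  if (is.character(L)) {
    row <- stats::setNames(numeric(p), names(fitresult$par))
    row[paste0("a_", L)] <- 1
    L <- matrix(row, 1, dimnames = list("combined", names(fitresult$par)))
  }
  if (is.vector(L) && is.numeric(L)) L <- matrix(L, 1)
  if (ncol(L) != p && is.null(P)) stop("dimension mismatch: L has wrong length", call. = FALSE)
  J <- fitresult$jacobian[seq_len(fitresult$n_res), , drop = FALSE]
  Fm <- crossprod(J) / noise_sd^2
  if (!is.null(P)) {
    P <- as.matrix(P)
    if (nrow(P) != p) stop("dimension mismatch: P must have one row per parameter",
                           call. = FALSE)
    if (qr(P)$rank < ncol(P)) stop("parameter error: P must have full column rank",
                                   call. = FALSE)
    Fm <- t(P) %*% Fm %*% P
    if (ncol(L) == p) L <- L %*% P
    if (ncol(L) != ncol(P)) stop("dimension mismatch: L vs reduced parameters",
                                 call. = FALSE)
  }
  inv <- solve(Fm)
  v <- diag(L %*% inv %*% t(L))
  stats::setNames(sqrt(pmax(v, 0)), rownames(L))
}

#' Monte-Carlo error estimation (parametric bootstrap)
#'
#' Generates `n_reps` replicates of the fitted model plus complex Gaussian
#' noise of SD `sigma`, refits each starting from the estimate, and reports
#' the per-parameter SD and bias (replicate mean minus estimate).
#' Non-convergent replicates are excluded and counted. Deterministic given
#' `seed`.
#'
#' @param fitresult An `lcm_fit`.
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @param sigma Noise SD; defaults to the fit's estimate.
#' @return List with `sd` and `bias` (named vectors), `n_used`,
#'   `n_failed`.
#' @export
monte_carlo <- function(fitresult, n_reps = 50L, seed = 1L, sigma = fitresult$sigma) {
  if (!inherits(fitresult, "lcm_fit")) stop("'fitresult' must be an lcm_fit", call. = FALSE)
  model <- fitresult$model
  h <- model$basis$header
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  base <- fitresult$model_spectrum$values
  n <- length(base)
  draws <- matrix(NA_real_, n_reps, length(fitresult$par))
  failed <- 0L
  for (r in seq_len(n_reps)) {
    noisy <- base
    if (sigma > 0)
      noisy <- noisy + complex(real = stats::rnorm(n, 0, sigma),
                               imaginary = stats::rnorm(n, 0, sigma))
    f <- tryCatch(lcm_fit(model, mrs_spectrum(noisy, h), start = fitresult$par),
                  error = function(e) NULL)
    if (is.null(f) || f$status != "converged") {
      failed <- failed + 1L
      next
    }
    draws[r, ] <- f$par
  }
  used <- stats::complete.cases(draws)
  sds <- apply(draws[used, , drop = FALSE], 2, stats::sd)
  bias <- colMeans(draws[used, , drop = FALSE]) - fitresult$par
  names(sds) <- names(bias) <- names(fitresult$par)
  if (sigma == 0) sds[] <- 0
  list(sd = sds, bias = bias, n_used = sum(used), n_failed = failed)
}

#' Hessian-based standard errors
#'
#' `sqrt(diag((J'J)^-1) * RSS / (n - p))`: equal to the CRLBs when the
#' noise variance is estimated as `RSS / (n - p)`.
#'
#' @param fitresult An `lcm_fit`.
#' @return Named numeric vector of standard errors.
#' @export
hessian_errors <- function(fitresult) {
  if (!inherits(fitresult, "lcm_fit")) stop("'fitresult' must be an lcm_fit", call. = FALSE)
  n <- fitresult$n_res
  p <- length(fitresult$par)
  if (n <= p) stop("invalid data: fewer residuals than parameters", call. = FALSE)
  J <- fitresult$jacobian[seq_len(n), , drop = FALSE]
  JtJ <- crossprod(J)
  inv <- tryCatch(solve(JtJ), error = function(e) MASS_ginv(JtJ))
  se <- sqrt(pmax(diag(inv), 0) * fitresult$rss / (n - p))
  stats::setNames(se, names(fitresult$par))
}

# minimal pseudo-inverse (avoids a MASS dependency for one fallback)
MASS_ginv <- function(X) {
  s <- svd(X)
  tol <- max(s$d) * 1e-12
  keep <- s$d > tol
  s$v[, keep, drop = FALSE] %*% ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

#' Export fit results as tables
#'
#' Writes a per-metabolite CSV (name, amplitude, CRLB, CRLB%, Hessian SE)
#' plus optional combined-estimate rows, and the full parameter correlation
#' matrix as a second CSV (`<path base>_correlation.csv`).
#'
#' @param fitresult An `lcm_fit`.
#' @param path Output CSV path.
#' @param combinations Optional named list of metabolite-name vectors, e.g.
#'   `list(Glx = c("Glu", "Gln"))`, appended as combined rows.
#' @return Invisibly, the main table as a data.frame.
#' @export
export_results <- function(fitresult, path, combinations = NULL) {
  if (!inherits(fitresult, "lcm_fit")) stop("'fitresult' must be an lcm_fit", call. = FALSE)
  mets <- fitresult$info$mets
  a <- fitresult$par[paste0("a_", mets)]
  tab <- data.frame(name = mets,
                    amplitude = unname(a),
                    crlb = unname(fitresult$crlb[paste0("a_", mets)]),
                    crlb_pct = unname(fitresult$crlb_pct),
                    hessian_se = unname(fitresult$hessian_se[paste0("a_", mets)]))
  if (!is.null(combinations)) {
    for (nm in names(combinations)) {
      who <- combinations[[nm]]
      cc <- combined_crlb(fitresult, who)
      amp <- sum(fitresult$par[paste0("a_", who)])
      tab <- rbind(tab, data.frame(name = nm, amplitude = amp, crlb = unname(cc),
                                   crlb_pct = 100 * unname(cc) / amp,
                                   hessian_se = NA_real_))
    }
  }
  utils::write.csv(format(tab, digits = 10), path, row.names = FALSE)
  cor_path <- sub("\\.csv$", "_correlation.csv", path)
  if (cor_path == path) cor_path <- paste0(path, "_correlation.csv")
  utils::write.csv(format(as.data.frame(fitresult$correlation), digits = 10), cor_path)
  invisible(tab)
}
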