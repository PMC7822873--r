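test_that("HSVD is exact on noiseless sums of damped exponentials", {
  h <- hdr_small(256)
  t <- time_axis(h)
  truth <- data.frame(f = c(-120, 35, 210), d = c(6, 3, 12), a = c(4, 2, 1),
                      ph = c(20, -50, 100))
  s <- complex(real = numeric(256))
  for (k in 1:3)
    s <- s + truth$a[k] * exp(1i * truth$ph[k] * pi / 180) *
      exp((1i * 2 * pi * truth$f[k] - pi * truth$d[k]) * t)
  comp <- hsvd_decompose(mrs_fid(s, h), 3)
  ord <- order(-comp$amplitude)
  expect_equal(comp$frequency_hz, truth$f, tolerance = 1e-6)
  expect_equal(comp$damping_hz, truth$d, tolerance = 1e-6)
  expect_equal(comp$amplitude, truth$a, tolerance = 1e-6)
  rec <- mrsproc:::hsvd_reconstruct(comp, h)
  expect_lt(max(Mod(rec$samples - s)) / max(Mod(s)), 1e-8)
  # single on-resonance exponential -> dominant component at 0 Hz
  one <- mrs_fid(exp(-pi * 5 * t), h)
  c1 <- hsvd_decompose(one, 2)
  expect_lt(abs(c1$frequency_hz[1]), 1e-6)
  expect_error(hsvd_decompose(one, 200), "parameter error")
})

test_that("HSVD does not hallucinate structure in pure noise", {
  h <- hdr_small(256)
  set.seed(12)
  noise <- rand_fid(h, 12)
  comp <- hsvd_decompose(noise, 5)
  rec <- mrsproc:::hsvd_reconstruct(comp, h)
  expect_lt(sum(Mod(rec$samples)^2), 0.5 * sum(Mod(noise$samples)^2))
})

test_that("HSVD water filtering preserves out-of-band metabolites", {
  h <- hdr_small(1024)
  water <- singlet_def(4.65, 100, 6)
  naa <- singlet_def(2.008, 1, 4)
  fid <- simulate_singlets(list(water, naa), h)
  band <- freq_window(4.2, 5.1)
  filt <- hsvd_filter(fid, 12, band)
  sp0 <- to_spectrum(fid)
  sp1 <- to_spectrum(filt)
  sp_naa <- to_spectrum(simulate_singlets(list(naa), h))
  nwin <- freq_window(1.85, 2.15)
  # water residual < 1% of original
  expect_lt(max(abs(Re(sp1$values[sp1$ppm >= 4.4 & sp1$ppm <= 4.9]))),
            0.01 * max(Re(sp0$values)))
  # NAA amplitude/integral within 1% of the water-free truth
  expect_lt(abs(integral(sp1, nwin) - integral(sp_naa, nwin)) /
              abs(integral(sp_naa, nwin)), 0.01)
  # empty band -> identity
  expect_equal(hsvd_filter(fid, 8, freq_window(8, 9))$samples, fid$samples)
  # band covering everything with sufficient order -> near-zero output
  all_gone <- hsvd_filter(fid, 8, freq_window(min(sp0$ppm), max(sp0$ppm)))
  expect_lt(max(Mod(all_gone$samples)), 1e-6 * max(Mod(fid$samples)))
})

test_that("polynomial baseline fitting is exact for representable baselines", {
  h <- hdr_small(256)
  zero <- to_spectrum(simulate_singlets(list(), h))
  cubic <- add_baseline(zero, c(1, 0.5, -0.2, 0.05))
  out <- baseline_poly(cubic, list(freq_window(-3, 12)), order = 3)
  expect_lt(max(abs(Re(out$corrected$values))), 1e-10)
  # order 0 on a constant subtracts it
  const <- add_baseline(zero, 4)
  expect_lt(max(abs(Re(baseline_poly(const, list(freq_window(0, 2)), 0)$corrected$values))),
            1e-10)
  # a peak outside the anchors is untouched beyond the baseline value
  pk <- add_baseline(to_spectrum(simulate_singlets(list(singlet_def(2, 10, 4)), h)), c(2))
  out2 <- baseline_poly(pk, list(freq_window(5, 12)), order = 0)
  win <- out2$corrected$ppm >= 1.8 & out2$corrected$ppm <= 2.2
  # Lorentzian tails leak slightly into the anchors; agreement to ~2%
  expect_lt(max(abs(Re(out2$corrected$values[win]) - (Re(pk$values[win]) - 2))), 0.05)
  expect_error(baseline_poly(cubic, list(freq_window(11.9, 12)), order = 10),
               "lower order")
})

test_that("advanced alignment recovers known transform parameters", {
  h <- hdr_small(512)
  base <- simulate_singlets(list(singlet_def(2, 20, 4), singlet_def(3.2, 15, 4)), h)
  ref <- to_spectrum(base)
  # fixed point: identity parameters
  out0 <- advanced_align(ref, ref, list(freq_window(1.5, 3.6)),
                         aspects = c("freq", "phase0", "scale"))
  expect_equal(unname(out0$par["freq"]), 0, tolerance = 1e-4)
  expect_equal(unname(out0$par["scale"]), 1, tolerance = 1e-4)
  # known df/phi0/scale perturbation recovered to 1%
  t <- time_axis(h)
  mov <- mrs_fid(0.95 * base$samples * exp(1i * 2 * pi * 2 * t), h)
  mov_sp <- phase_correct(to_spectrum(mov), 20, 0)
  out <- advanced_align(ref, mov_sp, list(freq_window(1.5, 3.6)),
                        aspects = c("freq", "phase0", "scale"))
  expect_equal(unname(out$par["freq"]), -2, tolerance = 0.01)
  expect_equal(unname(out$par["phase0"]), -20, tolerance = 0.2)
  expect_equal(unname(out$par["scale"]), 1 / 0.95, tolerance = 0.01)
  # objective never worse than identity
  expect_lte(out$objective, out$objective_identity)
  expect_lt(max(Mod(out$aligned$values - ref$values)), 1e-3 * max(Mod(ref$values)))
})

test_that("advanced alignment suppresses JDE subtraction artifacts >= 10x", {
  h <- hdr_3t(1024)
  peaks <- list(singlet_def(0.3, 8, 10), singlet_def(3.03, 30, 5),
                singlet_def(3.19, 12, 5), singlet_def(3.91, 10, 5))
  off <- simulate_singlets(peaks, h)
  # ON condition: global lineshape/scale/phase/shift perturbation
  t <- time_axis(h)
  on_fid <- apodize(mrs_fid(0.97 * off$samples * exp(1i * 2 * pi * 1.5 * t), h), 1.2, 0)
  on_sp <- phase_correct(to_spectrum(on_fid), 3, 0)
  off_sp <- to_spectrum(off)
  wins <- list(freq_window(0, 0.5), freq_window(3.15, 3.5), freq_window(3.87, 4.2))
  art <- function(d) sqrt(mean(Re(d$values[d$ppm >= 2.9 & d$ppm <= 3.12])^2))
  # align the sharper OFF onto the broadened ON (broadening can only be added)
  freq_only <- advanced_align(on_sp, off_sp, wins, aspects = "freq")
  full <- advanced_align(on_sp, off_sp, wins,
                         aspects = c("freq", "phase0", "lorentz", "scale", "offset"))
  expect_equal(unname(full$par["lorentz"]), 1.2, tolerance = 0.01)
  expect_equal(unname(full$par["scale"]), 0.97, tolerance = 0.01)
  d1 <- mrs_spectrum(on_sp$values - freq_only$aligned$values, h)
  d2 <- mrs_spectrum(on_sp$values - full$aligned$values, h)
  expect_gt(art(d1) / art(d2), 10)
})

test_that("snr, fwhm and integral match brute-force definitions", {
  h <- hdr_small(2048)
  A <- 12
  sigma <- 0.02
  sp <- add_noise(to_spectrum(simulate_singlets(list(singlet_def(2, A, 6)), h)),
                  sigma, seed = 21)
  sw <- freq_window(1.7, 2.3)
  nw <- freq_window(6, 9)
  got <- snr(sp, sw, nw)
  # oracle: peak over detrended noise SD
  x <- sp$ppm[sp$ppm >= 6 & sp$ppm <= 9]
  y <- Re(sp$values[sp$ppm >= 6 & sp$ppm <= 9])
  res <- resid(lm(y ~ x))
  expect_equal(got, max(Re(sp$values[sp$ppm >= 1.7 & sp$ppm <= 2.3])) / sd(res),
               tolerance = 1e-10)
  # approximate expected value A_peak/sigma, doubling amplitude doubles SNR
  sp2 <- add_noise(to_spectrum(simulate_singlets(list(singlet_def(2, 2 * A, 6)), h)),
                   sigma, seed = 21)
  expect_equal(snr(sp2, sw, nw) / got, 2, tolerance = 0.05)
  expect_error(snr(sp, freq_window(1, 7), nw), "disjoint")
  expect_error(snr(mrs_spectrum(rep(1 + 0i, h$n_points), h), sw, nw), "zero-variance")
  # integral: linear, and window off the peak ~ 0
  spc <- to_spectrum(simulate_singlets(list(singlet_def(2, A, 6)), h))
  expect_equal(integral(to_spectrum(simulate_singlets(list(singlet_def(2, 2 * A, 6)), h)),
                        sw), 2 * integral(spc, sw), tolerance = 1e-9)
  # with first-point half-scaling the off-peak window carries only the tail
  spc_h <- to_spectrum(simulate_singlets(list(singlet_def(2, A, 6)), h),
                       first_point_half = TRUE)
  expect_lt(abs(integral(spc_h, freq_window(8, 10))), 0.01 * abs(integral(spc_h, sw)))
  # gaussian FWHM equals its nominal width within a bin
  gf <- apodize(simulate_singlets(list(singlet_def(2, 1, 0.01)), h), 0, 8)
  expect_equal(fwhm(to_spectrum(resize_fid(gf, 8192)), sw)$fwhm_hz, 8,
               tolerance = h$bandwidth_hz / h$n_points / 8)
})

test_that("full-axis singlet integral matches the FID first point bookkeeping", {
  h <- hdr_small(512)
  fid <- simulate_singlets(list(singlet_def(2, 7, 5)), h)
  sp <- to_spectrum(fid)
  full <- freq_window(min(sp$ppm) - 1e-9, max(sp$ppm) + 1e-9)
  # sum(Re(spec)) * dppm = Re(fid[1]) / N * (N * dppm)
  dppm <- sp$ppm[2] - sp$ppm[1]
  expect_equal(integral(sp, full), Re(fid$samples[1]) * dppm, tolerance = 1e-9)
})
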