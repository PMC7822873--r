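test_that("klose correction removes any common multiplicative phase exactly", {
  h <- hdr_small(256)
  metab <- simulate_singlets(list(singlet_def(2, 10, 4)), h)
  # water positive real constant -> identity
  water <- mrs_fid(rep(5 + 0i, 256), h)
  expect_equal(klose_correct(metab, water)$samples, metab$samples)
  # random smooth common phase cancels exactly
  set.seed(3)
  theta <- cumsum(rnorm(256, 0, 0.05))
  corrupt <- exp(1i * theta)
  m2 <- mrs_fid(metab$samples * corrupt, h)
  w2 <- mrs_fid((5 + 0i) * corrupt, h)
  out <- klose_correct(m2, w2)
  expect_lt(max(Mod(out$samples - metab$samples)), 1e-12)
  # zero-magnitude water point -> phase 0 with warning
  w3 <- w2
  w3$samples[10] <- 0
  expect_warning(klose_correct(m2, w3), "zero magnitude")
})

test_that("first-point phasing rotates globally and matches klose for constant phase", {
  h <- hdr_small(128)
  f <- rand_fid(h, 4)
  wat <- mrs_fid(rep(3 + 0i, 128) * exp(1i * pi / 2), h)
  out <- first_point_phase(f, wat)
  expect_equal(out$samples, f$samples * exp(-1i * pi / 2), tolerance = 1e-12)
  expect_equal(out$samples, klose_correct(f, wat)$samples, tolerance = 1e-12)
  expect_error(first_point_phase(f, mrs_fid(c(0, rep(1 + 0i, 127)), h)), "zero magnitude")
})

test_that("channel combination phases, weights and gains SNR", {
  h <- hdr_small(512)
  # 1 channel, uniform, no water -> identity
  cube <- array(rand_fid(h, 1)$samples, c(1, 1, 512))
  ds1 <- mrs_dataset(cube, h)
  out1 <- combine_channels(ds1, method = "none", weighting = "uniform")
  expect_equal(out1$reps[[1]]$samples, cube[1, 1, ])
  # channels at 0/120/240 deg: unphased sum cancels, phased adds
  tr <- fixture_truth(singlet_def(3, 20, 5), n_reps = 1, n_channels = 3,
                      channel_sens = c(1, 1, 1), channel_phase_deg = c(0, 120, 240),
                      drift_sd_hz = 0, rep_phase_sd_deg = 0, noise_sd = 0, seed = 2)
  ds <- make_raw_fixture(tr, h)$dataset
  raw_sum <- combine_channels(ds, "none", "uniform")$reps[[1]]
  phased <- combine_channels(ds, "klose", "uniform")$reps[[1]]
  expect_lt(max(Mod(raw_sum$samples)), 1e-9 * max(Mod(phased$samples)))
  expect_equal(max(Mod(phased$samples)), 20, tolerance = 0.01)
  # two equal channels with independent noise: SNR gain ~ sqrt(2)
  gains <- replicate(20, {
    seed <- sample.int(1e6, 1)
    tr2 <- fixture_truth(singlet_def(3, 10, 5), n_reps = 1, n_channels = 2,
                         channel_sens = c(1, 1), channel_phase_deg = c(0, 0),
                         drift_sd_hz = 0, rep_phase_sd_deg = 0, noise_sd = 0.3,
                         seed = seed)
    d2 <- make_raw_fixture(tr2, h)$dataset
    sw <- freq_window(2.7, 3.3)
    nw <- freq_window(5.5, 8)
    one <- snr(to_spectrum(dataset_trace(d2, 1, 1)), sw, nw)
    comb <- snr(to_spectrum(combine_channels(d2, "klose", "uniform")$reps[[1]]), sw, nw)
    comb / one
  })
  expect_equal(mean(gains), sqrt(2), tolerance = 0.1)
  # missing water reference is an error
  ds_nw <- mrs_dataset(ds$data, h)
  expect_error(combine_channels(ds_nw, "klose", "sensitivity"), "water")
})

test_that("qa statistics match a brute-force oracle", {
  h <- hdr_small(256)
  # constant real spectrum in window
  spc <- mrs_spectrum(rep(2.5 + 0i, 256), h)
  q <- qa_stats(spc, freq_window(0, 2.1))
  expect_equal(q$min, 2.5)
  expect_equal(q$max, 2.5)
  expect_equal(q$mean, 2.5)
  expect_equal(q$median, 2.5)
  expect_equal(q$sd, 0)
  # random spectra against direct recomputation
  set.seed(8)
  reps <- lapply(1:3, function(i) to_spectrum(rand_fid(h, i + 10)))
  w <- freq_window(0, 2.1)
  q <- qa_stats(reps, w)
  for (i in 1:3) {
    x <- Re(reps[[i]]$values[reps[[i]]$ppm >= 0 & reps[[i]]$ppm <= 2.1])
    expect_equal(q$min[i], min(x))
    expect_equal(q$sd[i], sd(x))
    expect_equal(q$integral[i], sum(x) * diff(reps[[i]]$ppm[1:2]))
  }
  # thresholds produce pass/fail flags
  qt <- qa_stats(reps, w, thresholds = list(sd = c(0, 1e-9)))
  expect_true(all(!qt$pass))
  expect_error(qa_stats(reps, freq_window(20, 21)), "empty window")
})

test_that("alignment recovers injected frequency and phase offsets", {
  h <- hdr_small(512)
  base <- simulate_singlets(list(singlet_def(2, 20, 4), singlet_def(3, 25, 4)), h)
  t <- time_axis(h)
  cfg <- align_config(list(freq_window(1.5, 3.5)), freq_range_hz = 6,
                      freq_resolution_hz = 0.2, phase_step_deg = 1,
                      reference = 1L)
  # fixed point: trace equal to reference
  out <- align_reps(list(base, base), cfg)
  expect_equal(out$corrections$df_hz[2], 0)
  expect_equal(out$corrections$phi0_deg[2], 0)
  expect_equal(out$corrections$scale[2], 1, tolerance = 1e-9)
  # known injected offsets recovered within one grid step
  mov <- mrs_fid(base$samples * exp(1i * 2 * pi * -4.2 * t) * exp(1i * 37 * pi / 180), h)
  out <- align_reps(list(base, mov), cfg)
  expect_lt(abs(out$corrections$df_hz[2] - 4.2), cfg$freq_resolution_hz + 1e-9)
  # phi0 records the detected phase offset of the trace relative to the reference
  expect_lt(abs(out$corrections$phi0_deg[2] - 37) %% 360, cfg$phase_step_deg + 1e-9)
  expect_lt(max(Mod(out$reps[[2]]$samples - base$samples)) / max(Mod(base$samples)), 0.05)
})

test_that("alignment windows shield the metric from out-of-window artifacts", {
  h <- hdr_7t(1024)
  base <- simulate_singlets(list(singlet_def(1.3, 15, 6), singlet_def(3.7, 10, 6),
                                 singlet_def(8, 12, 6)), h)
  t <- time_axis(h)
  mov_clean <- mrs_fid(base$samples * exp(1i * 2 * pi * -3 * t), h)
  # artifact at 5.5 ppm, outside all three windows
  artifact <- simulate_singlets(list(singlet_def(5.5, 40, 20)), h)$samples
  mov_art <- mrs_fid(mov_clean$samples + artifact, h)
  cfg <- align_config(list(freq_window(0, 2.1), freq_window(3.3, 4.1),
                           freq_window(7.1, 9.1)),
                      freq_range_hz = 5, freq_resolution_hz = 0.25,
                      phase_step_deg = 2, reference = 1L)
  d1 <- align_reps(list(base, mov_clean), cfg)$corrections$df_hz[2]
  d2 <- align_reps(list(base, mov_art), cfg)$corrections$df_hz[2]
  expect_equal(d1, d2)
  expect_equal(d1, 3, tolerance = 0.26)
})

test_that("averaging reduces white noise as 1/sqrt(n)", {
  h <- hdr_small(1024)
  expect_error(average_reps(list(), integer(0)), "empty selection")
  f <- rand_fid(h, 1)
  expect_equal(average_reps(list(f))$samples, f$samples)
  expect_true(all(average_reps(list(f, mrs_fid(-f$samples, h)))$samples == 0))
  set.seed(5)
  reps <- lapply(1:64, function(i) rand_fid(h, 100 + i))
  one_sd <- sd(Re(to_spectrum(reps[[1]])$values))
  avg_sd <- sd(Re(to_spectrum(average_reps(reps))$values))
  expect_equal(avg_sd / one_sd, 1 / 8, tolerance = 0.15)
})

test_that("JDE processing is condition-specific and label-invariant", {
  h <- hdr_small(512)
  trj <- fixture_truth(list(singlet_def(2, 20, 5), singlet_def(3.03, 25, 5)),
                       n_reps = 8, n_channels = 2,
                       channel_sens = c(1, 0.6), channel_phase_deg = c(0, 90),
                       drift_sd_hz = 0, rep_phase_sd_deg = 0, noise_sd = 0,
                       jde = TRUE, edited_singlet = singlet_def(3.01, 4, 10), seed = 5)
  ds <- make_raw_fixture(trj, h)$dataset
  out <- jde_process(ds, cfg = NULL)
  # identical ON/OFF content -> diff shows only the edited peak
  pk_ppm <- out$diff$ppm[which.max(Re(out$diff$values))]
  expect_lt(abs(pk_ppm - 3.01), 0.05)
  # permuting labels leaves per-condition averages unchanged
  perm <- c(which(ds$condition_labels == "ON"), which(ds$condition_labels == "OFF"))
  ds2 <- mrs_dataset(ds$data[perm, , , drop = FALSE], h,
                     ds$condition_labels[perm], ds$water_refs)
  out2 <- jde_process(ds2, cfg = NULL)
  expect_equal(out2$ON$samples, out$ON$samples)
  expect_equal(out2$OFF$samples, out$OFF$samples)
  # identical ON/OFF data -> zero difference
  ds3 <- mrs_dataset(ds$data[c(2, 2, 4, 4), , , drop = FALSE], h,
                     c("ON", "OFF", "ON", "OFF"), ds$water_refs)
  out3 <- jde_process(ds3, cfg = NULL)
  expect_lt(max(Mod(out3$diff$values)), 1e-12)
  expect_error(jde_process(mrs_dataset(ds$data, h), NULL), "two editing conditions")
})
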