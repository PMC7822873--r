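test_that("spin operators satisfy the angular momentum algebra", {
  ops1 <- spin_operators(1)
  # single spin: Pauli/2
  expect_equal(ops1$x[[1]], matrix(c(0, 0.5, 0.5, 0), 2, 2), tolerance = 1e-15)
  expect_lt(abs(sum(diag(ops1$z[[1]]))), 1e-15)
  for (n in 1:3) {
    ops <- spin_operators(n)
    for (i in seq_len(n)) {
      comm <- ops$x[[i]] %*% ops$y[[i]] - ops$y[[i]] %*% ops$x[[i]]
      expect_lt(max(Mod(comm - 1i * ops$z[[i]])), 1e-12)
      expect_lt(abs(sum(diag(ops$z[[i]]))), 1e-15)
    }
    if (n >= 2) {
      cross <- ops$x[[1]] %*% ops$y[[2]] - ops$y[[2]] %*% ops$x[[1]]
      expect_lt(max(Mod(cross)), 1e-14)
    }
  }
  expect_error(spin_operators(9), "parameter error")
})

test_that("free Hamiltonian has the correct structure and limits", {
  h <- hdr_small(64)
  # single spin at the carrier: H = 0
  s0 <- spin_system("x", h$center_ppm)
  expect_lt(max(Mod(free_hamiltonian(s0, h))), 1e-12)
  # two uncoupled spins: eigenvalues are +-pi nu1 +- pi nu2
  s2 <- spin_system("xy", c(5.65, 3.65))
  nu <- (c(5.65, 3.65) - 4.65) * h$larmor_mhz
  ev <- sort(Re(eigen(free_hamiltonian(s2, h), symmetric = TRUE, only.values = TRUE)$values))
  want <- sort(c(pi * (nu[1] + nu[2]), pi * (nu[1] - nu[2]),
                 pi * (-nu[1] + nu[2]), -pi * (nu[1] + nu[2])))
  expect_equal(ev, want, tolerance = 1e-9)
  # weak-coupling AX: first-order doublet positions nu +- J/2
  J <- 7
  sax <- spin_system("ax", c(1.0, 8.0), matrix(c(0, J, J, 0), 2))
  hd <- free_hamiltonian(sax, h)
  fid <- simulate_sequence(sax, seq_def(list(ev_pulse(90, 0), ev_acquire())),
                           loc_config("ideal"), header = hdr_small(2048))
  sp <- to_spectrum(fid)
  pk <- sp$ppm[order(-Re(sp$values))[1:4]]
  nu_a <- (1.0 - 4.65) * h$larmor_mhz
  lines_a <- sort((nu_a + c(-J / 2, J / 2)) / h$larmor_mhz + 4.65)
  near_a <- sort(pk[pk < 4])[1:2]
  expect_equal(sort(near_a), lines_a, tolerance = 0.01)
  expect_error(spin_system("bad", c(1, 2), matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("evolution is unitary and periodic", {
  h <- hdr_small(64)
  ops <- spin_operators(1)
  H <- 2 * pi * 10 * ops$z[[1]]   # nu = 10 Hz
  rho <- ops$x[[1]]
  expect_equal(evolve(rho, H, 0), rho)
  fwd <- evolve(rho, H, 0.013)
  expect_lt(max(Mod(evolve(fwd, -H, 0.013) - rho)), 1e-12)
  # Ix precesses with period 0.1 s
  expect_lt(max(Mod(evolve(rho, H, 0.1) - rho)), 1e-10)
  half <- evolve(rho, H, 0.05)
  expect_lt(max(Mod(half + rho)), 1e-10)
  # trace and eigenvalues preserved
  expect_lt(abs(sum(diag(fwd)) - sum(diag(rho))), 1e-12)
  expect_error(evolve(rho, H, -1), "parameter error")
})

test_that("ideal pulses are exact rotations", {
  ops <- spin_operators(2)
  rho0 <- Reduce(`+`, ops$z)
  r90 <- ideal_pulse(rho0, 90, 0, ops)
  expect_lt(max(Mod(r90 - (-Reduce(`+`, ops$y)))), 1e-12)
  expect_lt(max(Mod(ideal_pulse(rho0, 360, 45, ops) - rho0)), 1e-12)
  r2x180 <- ideal_pulse(ideal_pulse(rho0, 180, 0, ops), 180, 0, ops)
  expect_lt(max(Mod(r2x180 - rho0)), 1e-12)
})

test_that("uncoupled spins give the analytic FID through any ideal sequence", {
  h <- hdr_small(512)
  s <- spin_system("s", 3.2)
  nu <- (3.2 - h$center_ppm) * h$larmor_mhz
  t <- time_axis(h)
  analytic <- exp(1i * 2 * pi * nu * t)
  # pulse-acquire
  f1 <- simulate_sequence(s, seq_def(list(ev_pulse(90, 0), ev_acquire())),
                          loc_config("ideal"), header = h)
  expect_lt(max(Mod(f1$samples - analytic)), 1e-10)
  expect_equal(Mod(f1$samples[1]), 1, tolerance = 1e-12)  # unit amplitude at t=0
  # ideal PRESS at any TE refocuses to the same analytic singlet
  f2 <- simulate_sequence(s, seq_press(30), loc_config("ideal"), header = h)
  expect_lt(max(Mod(f2$samples - analytic)), 1e-10)
  f3 <- simulate_sequence(s, seq_press(144), loc_config("ideal"), header = h)
  expect_lt(max(Mod(f3$samples - analytic)), 1e-10)
})

test_that("AX doublet follows cos(pi J TE) J-modulation under PRESS", {
  h <- acq_header(500, 5000, 1024, 4.65)
  J <- 5
  # deep weak-coupling regime: Delta_nu / J = 400
  sax <- spin_system("ax", c(2.65, 6.65), matrix(c(0, J, J, 0), 2))
  nu_a <- (2.65 - 4.65) * h$larmor_mhz
  # in-phase doublet amplitude read out by HSVD on the acquired FID
  inphase <- function(te_ms) {
    f <- simulate_sequence(sax, seq_press(te_ms), loc_config("ideal"), header = h)
    cp <- hsvd_decompose(apodize(f, 1, 0), 4)
    sel <- abs(cp$frequency_hz - nu_a) < 2 * J
    sum(cp$amplitude[sel] * cos(cp$phase_deg[sel] * pi / 180))
  }
  a0 <- inphase(0.02)
  for (te in c(40, 90, 144)) {
    expect_equal(inphase(te) / a0, cos(pi * J * te / 1000), tolerance = 0.005)
  }
  # antiphase at TE = 1/(2J): in-phase amplitude ~ 0
  expect_lt(abs(inphase(1000 / (2 * J)) / a0), 0.005)
})

test_that("lactate CH3 doublet inverts between short and long TE", {
  h <- acq_header(123.2, 2000, 1024, 4.65)
  lac <- load_spin_systems(names = "Lac")$Lac
  win <- freq_window(1.1, 1.5)
  sim <- function(te) {
    f <- simulate_sequence(lac, seq_press(te), loc_config("ideal"), header = h)
    to_spectrum(apodize(f, 0, 1), first_point_half = TRUE)  # 1-Hz Gaussian display filter
  }
  s30 <- sim(30)
  s144 <- sim(144)
  expect_gt(integral(s30, win), 0)
  expect_lt(integral(s144, win), 0)   # inverted doublet near TE = 1/J
})

test_that("shaped pulses match ideal rotations and refocus within their band", {
  h <- hdr_small(64)
  ops <- spin_operators(1)
  H0 <- matrix(0 + 0i, 2, 2)
  # constant waveform = hard pulse: 90 deg when nu1 * tau = 1/4
  tau <- 1e-3
  nu1 <- 0.25 / tau
  wf <- list(amp_hz = rep(nu1, 16), phase_deg = rep(0, 16))
  U <- shaped_pulse_propagator(wf, tau, 0, H0, ops)[[1]]
  rho0 <- ops$z[[1]]
  got <- U %*% rho0 %*% t(Conj(U))
  want <- ideal_pulse(rho0, 90, 0, ops)
  expect_lt(max(Mod(got - want)), 1e-10)
  # unitarity across offsets
  offs <- seq(-2000, 2000, length.out = 21)
  Us <- shaped_pulse_propagator(wf, tau, offs, H0, ops)
  for (U in Us) expect_lt(max(Mod(t(Conj(U)) %*% U - diag(2))), 1e-10)
  # cache returns identical propagators
  cache <- new.env(parent = emptyenv())
  U1 <- shaped_pulse_propagator(wf, tau, offs, H0, ops, cache)
  U2 <- shaped_pulse_propagator(wf, tau, offs, H0, ops, cache)
  for (k in seq_along(offs)) {
    expect_identical(U1[[k]], U2[[k]])
    expect_lt(max(Mod(U1[[k]] - Us[[k]])), 1e-15)
  }
  # 180-deg refocusing profile falls off monotonically with offset magnitude
  wf180 <- list(amp_hz = rep(0.5 / tau, 16), phase_deg = rep(0, 16))
  eff <- vapply(shaped_pulse_propagator(wf180, tau, c(0, 400, 1200, 3000), H0, ops),
                function(U) Mod(U[2, 1])^2, numeric(1))
  expect_true(all(diff(eff) < 0))
})

test_that("coherence filter is an idempotent complete decomposition", {
  ops <- spin_operators(2)
  rho <- ideal_pulse(Reduce(`+`, ops$z), 90, 0, ops)
  f1 <- coherence_filter(rho, 1)
  expect_equal(coherence_filter(f1, 1), f1)
  parts <- lapply(-2:2, function(p) coherence_filter(rho, p))
  expect_lt(max(Mod(Reduce(`+`, parts) - rho)), 1e-14)
  # after a 90 on Iz, all transverse magnetization sits in orders +-1
  expect_lt(max(Mod(coherence_filter(rho, 0) - diag(diag(rho)))), 1e-12)
  expect_gt(max(Mod(f1)), 0.1)
})

test_that("sep1d and cached full3d agree with brute force on a 2-spin system", {
  h <- hdr_small(128)
  s2 <- spin_system("ax", c(2.0, 3.5), matrix(c(0, 7, 7, 0), 2))
  tau <- 0.8e-3
  wf90 <- list(amp_hz = rep(0.25 / tau, 8), phase_deg = rep(0, 8))
  wf180 <- list(amp_hz = rep(0.5 / tau, 8), phase_deg = rep(90, 8))
  te <- 0.03
  events <- list(ev_shaped(wf90, tau, "x"), ev_delay(te / 4),
                 ev_shaped(wf180, tau, "y"), ev_delay(te / 2),
                 ev_shaped(wf180, tau, "z"), ev_delay(te / 4),
                 ev_acquire())
  sq <- seq_def(events, coherence_pathway = c(-1L, 1L, -1L))
  loc <- loc_config("full3d", n_spatial = 8, offset_range_hz = 600)
  f_cache <- simulate_sequence(s2, sq, loc, header = h, use_cache = TRUE)
  f_brute <- simulate_sequence(s2, sq, loc, header = h, use_cache = FALSE)
  expect_lt(max(Mod(f_cache$samples - f_brute$samples)), 1e-8)
  f_sep <- simulate_sequence(s2, sq, loc_config("sep1d", 8, 600), header = h)
  sp <- function(f) to_spectrum(f)$values
  expect_lt(max(Mod(sp(f_sep) - sp(f_brute))), 1e-8)
})

test_that("spectra are covariant under a global chemical-shift change", {
  h <- hdr_small(256)
  s <- spin_system("ax", c(2.0, 3.0), matrix(c(0, 7, 7, 0), 2))
  delta <- 0.5
  s_shift <- spin_system("ax", c(2.5, 3.5), matrix(c(0, 7, 7, 0), 2))
  f1 <- simulate_sequence(s, seq_press(30), loc_config("ideal"), header = h)
  f2 <- simulate_sequence(s_shift, seq_press(30), loc_config("ideal"), header = h)
  t <- time_axis(h)
  counter <- f2$samples * exp(-1i * 2 * pi * delta * h$larmor_mhz * t)
  expect_lt(max(Mod(counter - f1$samples)), 1e-8)
})

test_that("generate_basis is deterministic with shared grid and metadata", {
  h <- hdr_small(256)
  systems <- load_spin_systems(names = c("Cr", "Lac"))
  b1 <- generate_basis(systems, seq_press(30), loc_config("ideal"), h, vendor = "v")
  b2 <- generate_basis(systems, seq_press(30), loc_config("ideal"), h, vendor = "v")
  expect_identical(b1$entries, b2$entries)
  expect_equal(names(b1$entries), c("Cr", "Lac"))
  expect_equal(b1$metadata$te_ms, 30)
  expect_equal(b1$metadata$sequence, "press")
  # Cr: 3 + 2 equivalent protons -> FID amplitude 5 at t=0
  expect_equal(Mod(b1$entries$Cr[1]), 5, tolerance = 1e-9)
  expect_error(generate_basis(list(A = systems$Cr, A = systems$Lac),
                              seq_press(30), loc_config("ideal"), h), "duplicate")
})

test_that("Glu dominates Gln in the 2.2-2.5 ppm region at literature amplitudes", {
  h <- acq_header(123.2, 2000, 1024, 4.65)
  systems <- load_spin_systems(names = c("Glu", "Gln"))
  b <- generate_basis(systems, seq_press(30), loc_config("ideal"), h)
  win <- freq_window(2.2, 2.5)
  conc <- c(Glu = 10.2, Gln = 2.5)
  glu_part <- abs(integral(synth_brain(basis_set(b$entries["Glu"], h), conc["Glu"]), win))
  gln_part <- abs(integral(synth_brain(basis_set(b$entries["Gln"], h), conc["Gln"]), win))
  expect_gt(glu_part, 2 * gln_part)
})
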