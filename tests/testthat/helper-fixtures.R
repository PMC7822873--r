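# Shared fixtures: headers and simple signals built in code.

hdr_7t <- function(n = 2048) acq_header(298.1, 5000, n, center_ppm = 4.65)
hdr_3t <- function(n = 1024) acq_header(123.2, 2000, n, center_ppm = 4.65)

# small grid for fast tests
hdr_small <- function(n = 512) acq_header(123.2, 2000, n, center_ppm = 4.65)

rand_fid <- function(header, seed = 1) {
  set.seed(seed)
  mrs_fid(complex(real = rnorm(header$n_points), imaginary = rnorm(header$n_points)),
          header)
}

# Small, well-conditioned fixture shared by the LCM tests: three distinct
# singlet "metabolites" on a short grid.
lcm_fixture <- function(n = 512, lw = c(4, 5, 6)) {
  h <- hdr_small(n)
  entries <- list(
    A = simulate_singlets(list(singlet_def(1.3, 1, lw[1])), h)$samples,
    B = simulate_singlets(list(singlet_def(2.0, 1, lw[2])), h)$samples,
    C = simulate_singlets(list(singlet_def(3.0, 1, lw[3])), h)$samples)
  basis_set(entries, h, metadata = list(sequence = "synthetic"))
}

lcm_truth <- c(a_A = 3, a_B = 5, a_C = 2, d_A = 0.5, d_B = -0.8, d_C = 0.2,
               l_A = 1.2, l_B = 0.7, l_C = 2.0, phi0 = 8)

make_lcm_data <- function(basis, theta = lcm_truth, sigma = 0, seed = 1) {
  model <- lcm_model(basis, freq_window(0.8, 3.6), baseline_order = NULL,
                     noise_window = freq_window(6, 9))
  sp <- model_eval(model, theta)
  if (sigma > 0) sp <- add_noise(sp, sigma, seed)
  list(model = model, spec = sp)
}

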