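# Despiking, denoising, baseline estimation, normalization, Matrigel
# rejection and the composed pipeline.

test_that("spike detection follows the 3.5x-mean rule", {
  y <- c(rep(1, 9), 10) # mean 1.9, threshold 6.65
  expect_equal(detect_spikes(y), 10L)
  expect_length(detect_spikes(rep(2, 50)), 0) # flat
  expect_length(detect_spikes(rep(0, 50)), 0) # all-zero guard
})

test_that("injected spikes are recovered exactly on synthetic data", {
  ds <- simulate_dataset(make_class_profiles(0.5),
                         sim_config(n_per_class = 10, spike_rate = 1,
                                    spike_factor = 4, seed = 31))
  hits <- misses <- 0
  for (id in ds$truth$spectrum_id) {
    found <- detect_spikes(spectrum_at(ds$matrix, id), spike_factor = 3.5)
    truth <- ds$spikes[[id]]
    expect_setequal(found, truth)
    hits <- hits + length(intersect(found, truth))
  }
  expect_gt(hits, 10) # the draw actually injected spikes
})

test_that("spike replacement bridges from the nearest clean neighbours", {
  y <- c(rep(1, 9), 10)
  expect_equal(remove_spikes(y, 10L)[10], 1) # boundary: single neighbour
  y2 <- c(1, 1, 50, 1, 1)
  expect_equal(remove_spikes(y2, 3L), c(1, 1, 1, 1, 1))
  expect_identical(remove_spikes(y2, integer(0)), y2) # no indices: identity
  # adjacent flagged points on a ramp interpolate across the flanks
  ramp <- c(0, 1, 99, 98, 4, 5)
  expect_equal(remove_spikes(ramp, c(3L, 4L)), c(0, 1, 2, 3, 4, 5))
  # unflagged points are never modified
  set.seed(1); yr <- runif(100)
  out <- remove_spikes(yr, c(10L, 50L))
  expect_identical(out[-c(10, 50)], yr[-c(10, 50)])
})

test_that("the isolation guard spares broad bands but keeps narrow spikes", {
  ps <- make_class_profiles(0.5, amplitude_cv = 0)
  cfg <- sim_config(baseline_coeffs = 0, baseline_jitter = 0, noise_sd = 0,
                    spike_rate = 0)
  clean <- analytic_spectrum(ps$control, cfg$grid)
  # cleaned, normalized spectra: plain rule flags the phenylalanine band...
  expect_gt(length(detect_spikes(clean)), 0)
  # ...the guard does not
  expect_length(detect_spikes(clean, isolation_guard = TRUE), 0)
  spiked <- clean
  spiked[200] <- 4 * mean(clean)
  expect_equal(detect_spikes(spiked, isolation_guard = TRUE), 200L)
})

test_that("denoising reproduces polynomials and matches a local OLS oracle", {
  g <- default_grid("fixed")
  line <- 2 + 0.01 * seq_along(g)
  expect_equal(denoise(line, 1, 5), line, tolerance = 1e-10)
  expect_equal(denoise(rep(3, 100), 1, 5), rep(3, 100))

  set.seed(8)
  y <- runif(60)
  sm <- denoise(y, 1, 5)
  # interior point oracle: OLS line over the window, evaluated at the centre
  for (i in c(3, 17, 40, 58)) {
    win <- (i - 2):(i + 2)
    fit <- lm(y[win] ~ win)
    expect_equal(sm[i], unname(predict(fit, data.frame(win = i))),
                 tolerance = 1e-10)
  }
  expect_error(denoise(y, 1, 61), "larger than spectrum")
  expect_error(denoise(y, 2, 2), "order")
})

test_that("baseline estimation is exact on matching-degree polynomials", {
  sp <- poly2_spectrum()
  b <- estimate_baseline(sp, degree = 2, n_points = 256)
  expect_lt(max(abs(sp$intensity - b)), 1e-6 * max(sp$intensity))
  expect_true(attr(b, "converged"))
  z <- estimate_baseline(rep(0, 100), degree = 2, n_points = 50)
  expect_equal(as.numeric(z), rep(0, 100))
})

test_that("baseline under a narrow band recovers the band within 5%", {
  g <- default_grid("fixed")
  t <- (g - min(g)) / diff(range(g))
  base_true <- 2 + 0.5 * t + 0.3 * t^2
  amp <- 1.2
  y <- base_true + amp * lorentz(g, 1124, 8)
  b <- estimate_baseline(y, degree = 2, n_points = 256, wavenumber = g)
  resid <- y - b
  apex <- which.min(abs(g - 1124))
  expect_lt(abs(resid[apex] - amp), 0.05 * amp)
})

test_that("baseline subtraction is linear and length-checked", {
  y <- c(1, 2, 3)
  expect_equal(as.numeric(subtract_baseline(y, y)), c(0, 0, 0))
  expect_equal(as.numeric(subtract_baseline(y, rep(0, 3))), y)
  b1 <- c(0.1, 0.2, 0.3); b2 <- c(1, 1, 1)
  expect_equal(as.numeric(subtract_baseline(y, b1 + b2)),
               as.numeric(subtract_baseline(subtract_baseline(y, b1), b2)))
  expect_error(subtract_baseline(y, 1:2), "lengths differ")
})

test_that("phenylalanine normalization scales to a unit window maximum", {
  g <- default_grid("fixed")
  y <- 0.5 * lorentz(g, 1003, 5)
  sp <- raman_spectrum(g, y)
  out <- normalize_phenylalanine(sp)
  win <- g >= 995 & g <= 1011
  expect_identical(max(out$intensity[win]), 1)
  # division by the on-grid window maximum (apex is slightly off-grid)
  expect_equal(out$intensity, y / max(y[win]))
  # idempotence and scale invariance
  expect_equal(normalize_phenylalanine(out)$intensity, out$intensity)
  sp7 <- raman_spectrum(g, 7.3 * y)
  expect_equal(normalize_phenylalanine(sp7)$intensity, out$intensity)
  expect_error(normalize_phenylalanine(raman_spectrum(g, rep(0, length(g)))),
               "non-positive")
})

test_that("Matrigel rejection matches contamination truth in both modes", {
  for (mode in c("fixed", "live")) {
    ds <- small_dataset(n_per_class = 12, seed = 17, mode = mode,
                        matrigel_fraction = 0.15)
    rej <- reject_matrigel(ds$matrix, preprocess_config(mode))
    got <- rej$report$verdicts$verdict != "kept"
    want <- ds$truth$contaminated[match(rej$report$verdicts$spectrum_id,
                                        ds$truth$spectrum_id)]
    expect_identical(got, want)
    expect_equal(sum(rej$report$counts), n_spectra(ds$matrix))
    lab <- if (mode == "fixed") "rejected_saturation" else "rejected_background"
    expect_true(all(rej$report$verdicts$verdict[got] == lab))
  }
  # all-rejected guard
  sat <- spectra_matrix(default_grid("fixed"),
                        matrix(10, 750, 2),
                        data.frame(spectrum_id = c("a", "b"),
                                   treatment = "control"))
  expect_error(reject_matrigel(sat, preprocess_config("fixed")),
               "all spectra rejected")
})

test_that("the pipeline equals the normalized forward model when the noise stages are idle", {
  ps <- make_class_profiles(0.5, amplitude_cv = 0)
  cfg <- sim_config(n_per_class = 3, baseline_coeffs = 0, baseline_jitter = 0,
                    noise_sd = 0, spike_rate = 0, seed = 5)
  ds <- simulate_dataset(ps, cfg)
  pc <- preprocess_config("fixed", denoise_window = NA, baseline_degree = NA)
  pp <- preprocess_pipeline(ds$matrix, pc)
  for (cl in names(ps)) {
    truth <- analytic_spectrum(ps[[cl]], cfg$grid)
    win <- cfg$grid >= 995 & cfg$grid <= 1011
    truth <- truth / max(truth[win])
    j <- which(treatments(pp$matrix) == cl)[1]
    expect_equal(pp$matrix$intensities[, j], truth, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("a second pipeline pass is stable on cleaned spectra", {
  ds <- small_dataset(n_per_class = 6, seed = 9)
  pc <- preprocess_config("fixed")
  once <- preprocess_pipeline(ds$matrix, pc)

  # despiking and normalization are exactly idempotent on cleaned data
  pc_id <- preprocess_config("fixed", denoise_window = NA,
                             baseline_degree = NA)
  again <- preprocess_pipeline(once$matrix, pc_id)
  expect_identical(again$matrix$intensities, once$matrix$intensities)
  expect_equal(sum(again$log$n_spikes), 0)

  # with smoothing on, the second pass re-smooths the narrow reference band
  # (half-width ~2.5 grid steps), bounding the change at the ~10% level
  twice <- preprocess_pipeline(once$matrix, pc)
  expect_equal(n_spectra(twice$matrix), n_spectra(once$matrix))
  rel <- abs(twice$matrix$intensities - once$matrix$intensities) /
    max(once$matrix$intensities)
  expect_lt(max(rel), 0.15)
})

test_that("pipeline output is normalized exactly and logged per spectrum", {
  ds <- small_dataset(n_per_class = 8, seed = 12, matrigel_fraction = 0.15,
                      spike_rate = 0.3)
  pp <- preprocess_pipeline(ds$matrix, preprocess_config("fixed"))
  g <- pp$matrix$wavenumber
  win <- g >= 995 & g <= 1011
  mx <- apply(pp$matrix$intensities[win, ], 2, max)
  expect_true(all(mx == 1))
  expect_equal(nrow(pp$log), n_spectra(pp$matrix))
  expect_true(all(pp$log$baseline_converged))
})
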