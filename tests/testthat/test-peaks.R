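# Peak extraction, group statistics, and the blinded majority-vote
# procedure, including the published worked example.

test_that("peak extraction returns the window maximum", {
  g <- default_grid("fixed")
  sp <- raman_spectrum(g, 2 * lorentz(g, 1003, 5))
  apex <- extract_peak_intensity(sp, 1003, 8)
  expect_equal(apex, max(2 * lorentz(g, 1003, 5)))
  flat <- raman_spectrum(g, rep(0.7, length(g)))
  expect_equal(extract_peak_intensity(flat, 1446), 0.7)
  expect_error(extract_peak_intensity(sp, 3000, 5), "does not intersect")
})

test_that("extracted panel intensities match the analytic forward model", {
  ps <- make_class_profiles(0.5, amplitude_cv = 0)
  cfg <- sim_config(n_per_class = 1, baseline_coeffs = 0, baseline_jitter = 0,
                    noise_sd = 0, spike_rate = 0, seed = 1)
  sp <- simulate_spectrum(ps$EGF, cfg)
  truth <- analytic_spectrum(ps$EGF, cfg$grid)
  panel <- peak_panel()
  for (ctr in panel$centers) {
    win <- which(cfg$grid >= ctr - panel$half_window &
                   cfg$grid <= ctr + panel$half_window)
    expect_equal(extract_peak_intensity(sp, ctr, panel$half_window),
                 max(truth[win]))
  }
})

test_that("the peak table has one row per kept spectrum in panel order", {
  ds <- small_dataset(n_per_class = 5, seed = 2, matrigel_fraction = 0.3)
  pp <- preprocess_pipeline(ds$matrix, preprocess_config("fixed"))
  tab <- build_peak_table(pp$matrix)
  expect_equal(dim(tab), c(n_spectra(pp$matrix), 11L))
  expect_equal(as.numeric(peak_columns <- setdiff(names(tab), c("spectrum_id", "treatment"))),
               diagnostic_centers())
  # rejected spectra absent
  rejected <- ds$truth$spectrum_id[ds$truth$contaminated]
  expect_false(any(tab$spectrum_id %in% rejected))
  # values invariant to input column permutation (tracked by id)
  set.seed(5)
  perm <- sample(n_spectra(pp$matrix))
  tab2 <- build_peak_table(pp$matrix[perm])
  cols <- as.character(diagnostic_centers())
  expect_equal(as.matrix(tab2[match(tab$spectrum_id, tab2$spectrum_id), cols]),
               as.matrix(tab[, cols]), ignore_attr = TRUE)
})

test_that("group statistics handle the degenerate and textbook cases", {
  mk <- function(vals) {
    out <- data.frame(spectrum_id = sprintf("s%d", seq_along(vals)),
                      treatment = rep(c("control", "EGF", "FGF2"),
                                      each = length(vals) / 3),
                      `1003` = vals, check.names = FALSE)
    attr(out, "centers") <- 1003
    class(out) <- c("peak_table", "data.frame")
    out
  }
  # three identical groups: F = 0, p = 1, Dunnett p = 1
  gs0 <- group_statistics(mk(rep(c(1, 2, 3), times = 3)))
  expect_equal(gs0$anova$F, 0)
  expect_equal(gs0$anova$p, 1)
  expect_true(all(gs0$dunnett$p_adj == 1))

  # textbook two-sample pooled t: {1,2,3} vs {4,5,6} -> t = -3.674
  tab2 <- data.frame(spectrum_id = sprintf("s%d", 1:6),
                     treatment = rep(c("control", "EGF"), each = 3),
                     `1003` = c(1, 2, 3, 4, 5, 6), check.names = FALSE)
  attr(tab2, "centers") <- 1003
  class(tab2) <- c("peak_table", "data.frame")
  gs2 <- group_statistics(tab2)
  expect_equal(gs2$pairwise$t, -3.674, tolerance = 1e-3)
  expect_equal(gs2$pairwise$p_bonf, gs2$pairwise$p_raw) # one pair: factor 1
  # CIs contain their means; adjusted >= raw
  expect_true(all(gs2$means$ci_lo <= gs2$means$mean &
                    gs2$means$mean <= gs2$means$ci_hi))

  expect_error(group_statistics(mk(rep(1, 3))[c(1, 2, 4), ]), "fewer than 2")
})

test_that("Dunnett-adjusted p-values dominate per-comparison p-values under the null", {
  set.seed(33)
  n_bad <- 0
  for (r in 1:200) {
    y <- rnorm(15)
    g <- rep(c("control", "EGF", "FGF2"), each = 5)
    tab <- data.frame(spectrum_id = sprintf("s%d", 1:15), treatment = g,
                      `569` = y, check.names = FALSE)
    attr(tab, "centers") <- 569
    class(tab) <- c("peak_table", "data.frame")
    gs <- group_statistics(tab)
    # unadjusted per-comparison p from the same pooled model, by hand
    gm <- tapply(y, g, mean)
    s2 <- sum((y - ave(y, g))^2) / 12
    tt <- (gm[c("EGF", "FGF2")] - gm["control"]) / sqrt(2 * s2 / 5)
    raw <- 2 * pt(-abs(tt), 12)
    ord <- match(paste(c("EGF", "FGF2"), "- control"), gs$dunnett$comparison)
    # allow the multivariate-t quadrature a hair of slack
    if (any(gs$dunnett$p_adj[ord] < raw - 1e-3)) n_bad <- n_bad + 1
  }
  expect_equal(n_bad, 0)
})

test_that("peak assignment is a nearest-mean argmin with tie flagging", {
  means <- c(control = 0.5, EGF = 0.7, FGF2 = 1.0)
  expect_equal(assign_peak(0.95, means)$label, "FGF2")
  tie <- assign_peak(0.6, means)
  expect_true(tie$ambiguous)
  expect_setequal(tie$candidates, c("control", "EGF"))
  expect_error(assign_peak(1, c(a = 1)), ">= 2 groups")

  set.seed(21)
  for (r in 1:1000) {
    gm <- setNames(runif(3), c("control", "EGF", "FGF2"))
    u <- runif(1)
    got <- assign_peak(u, gm)$label
    expect_identical(got, names(gm)[which.min(abs(u - gm))])
  }
})

test_that("majority voting reproduces the published blinded vote table", {
  path <- system.file("extdata", "blinded_peak_assignments.tsv",
                      package = "ramanoid")
  tab <- read.delim(path)
  v1 <- majority_vote(tab$unknown1)
  v2 <- majority_vote(tab$unknown2)
  v3 <- majority_vote(tab$unknown3)
  expect_equal(v1$winner, "FGF2");    expect_equal(v1$count, 7L)
  expect_equal(v2$winner, "control"); expect_equal(v2$count, 7L)
  expect_equal(v3$winner, "EGF");     expect_equal(v3$count, 5L)
  expect_equal(v1$n, 9L)
  # unanimity, order invariance, ties
  vu <- majority_vote(rep("control", 9))
  expect_equal(vu$winner, "control"); expect_equal(vu$count, 9L)
  expect_equal(majority_vote(rev(tab$unknown3))$winner, "EGF")
  vt <- majority_vote(c("EGF", "FGF2"))
  expect_true(vt$tie); expect_true(is.na(vt$winner))
})

test_that("blinded peak voting recovers the class of synthetic unknowns", {
  ps <- make_class_profiles(0.5)
  ds <- simulate_dataset(ps, sim_config(n_per_class = 30, noise_sd = 0.02,
                                        seed = 41))
  pp <- preprocess_pipeline(ds$matrix, preprocess_config("fixed"))
  ktab <- build_peak_table(pp$matrix)
  cfgu <- sim_config(n_per_class = 10, noise_sd = 0.02, seed = 43)
  for (cl in c("control", "FGF2")) {
    du <- simulate_dataset(ps[cl], cfgu)
    ppu <- preprocess_pipeline(du$matrix, preprocess_config("fixed"))
    res <- classify_blinded_by_peaks(ppu$matrix, ktab)
    expect_equal(res$verdict$winner, cl)
    expect_equal(nrow(res$assignments), 9)
  }
  # null profiles: behaviour is defined (verdict or tie), never an error
  ps0 <- make_class_profiles(0)
  du0 <- simulate_dataset(ps0["EGF"], cfgu)
  ppu0 <- preprocess_pipeline(du0$matrix, preprocess_config("fixed"))
  res0 <- classify_blinded_by_peaks(ppu0$matrix, ktab)
  expect_s3_class(res0$verdict, "vote_verdict")
  expect_true(res0$verdict$tie || res0$verdict$winner %in%
                c("control", "EGF", "FGF2"))
})
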