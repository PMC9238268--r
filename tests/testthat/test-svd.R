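# SVD decomposition invariants, scores, the bisector separation statistic
# (vs a nearest-centroid oracle) and codistribution assignment.

test_that("decomposition satisfies orthonormality and reconstruction", {
  set.seed(3)
  M <- matrix(runif(40 * 12), 40, 12)
  res <- compute_svd(M)
  k <- length(res$d)
  expect_lt(max(abs(crossprod(res$u) - diag(k))), 1e-8)
  expect_lt(max(abs(crossprod(res$v) - diag(k))), 1e-8)
  rec <- res$u %*% diag(res$d) %*% t(res$v)
  expect_lt(norm(rec - M, "F") / norm(M, "F"), 1e-8)
  expect_true(all(diff(res$d) <= 0))
  expect_error(compute_svd(matrix(c(1, NA, 2, 3), 2)), "non-finite")
})

test_that("analytic cases: identity and rank-1 matrices", {
  res <- compute_svd(diag(2))
  expect_equal(res$d, c(1, 1))
  r1 <- outer(runif(30), runif(5))
  res1 <- compute_svd(r1)
  expect_lt(res1$d[2] / res1$d[1], 1e-10)
})

test_that("squared singular values match an independent eigendecomposition", {
  set.seed(11)
  for (r in 1:25) {
    n <- sample(5:100, 1); m <- sample(3:50, 1)
    M <- matrix(rnorm(n * m), n, m)
    d2 <- compute_svd(M)$d^2
    ev <- sort(eigen(crossprod(M), symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)[seq_along(d2)]
    expect_lt(max(abs(d2 - ev)) / max(ev), 1e-8)
  }
})

test_that("scores scale V by the singular values and track duplicates", {
  res <- compute_svd(diag(3))
  sc <- svd_scores(res, c(1, 2))
  expect_equal(abs(sc), diag(3)[, 1:2], ignore_attr = TRUE)
  M <- matrix(runif(20 * 4), 20, 4)
  M <- cbind(M, M[, 2]) # duplicated spectrum
  sc2 <- svd_scores(compute_svd(M), c(1, 2))
  expect_equal(sc2[2, ], sc2[5, ], ignore_attr = TRUE)
  expect_error(svd_scores(compute_svd(M), c(1, 1)), "distinct")
  expect_error(svd_scores(compute_svd(M), c(1, 99)), "out of range")
})

test_that("sign convention is deterministic across reruns", {
  set.seed(6)
  M <- matrix(rnorm(200), 20, 10)
  r1 <- compute_svd(M); r2 <- compute_svd(M + 0)
  expect_identical(r1$u, r2$u)
  for (j in seq_along(r1$d))
    expect_gt(r1$u[which.max(abs(r1$u[, j])), j], 0)
})

test_that("bisector sides follow the hand-checkable x = 1 boundary", {
  # group A means to (0, 0), group B to (2, 0): boundary is x = 1
  sc <- rbind(c(1, 2), c(-1, 1), c(0, -3),    # A (includes an on-line point)
              c(1.7, -4), c(2.3, 4))          # B
  labels <- c("A", "A", "A", "B", "B")
  sep <- separation_analysis(sc, labels)
  expect_equal(as.character(sep$side), c("on_line", "A", "A", "B", "B"))
  # means equidistant from boundary by construction
  expect_equal(sum(sep$percentages["A", ]), 100)
  expect_error(separation_analysis(rbind(c(0, 0), c(0, 0)), c("A", "B")),
               "coincident")
})

test_that("bisector assignment equals nearest-of-two-means classification", {
  set.seed(14)
  for (r in 1:200) {
    sc <- matrix(rnorm(40), 20, 2)
    lb <- rep(c("A", "B"), each = 10)
    sep <- separation_analysis(sc, lb)
    mA <- colMeans(sc[1:10, ]); mB <- colMeans(sc[11:20, ])
    dA <- sqrt(colSums((t(sc) - mA)^2)); dB <- sqrt(colSums((t(sc) - mB)^2))
    oracle <- ifelse(dA < dB, "A", ifelse(dB < dA, "B", "on_line"))
    expect_identical(as.character(sep$side), oracle)
  }
})

test_that("separation percentages are invariant to column order within groups", {
  ds <- small_dataset(n_per_class = 10, seed = 19)
  pp <- preprocess_pipeline(ds$matrix, preprocess_config("fixed"))
  sub <- pp$matrix[treatments(pp$matrix) %in% c("control", "FGF2")]
  sep1 <- separation_analysis(svd_scores(compute_svd(sub)),
                              groups = c("control", "FGF2"))
  set.seed(2)
  perm <- sample(n_spectra(sub))
  sep2 <- separation_analysis(svd_scores(compute_svd(sub[perm])),
                              groups = c("control", "FGF2"))
  expect_equal(sep1$percentages, sep2$percentages)
})

test_that("codistribution counts unknown spectra per side and flags 50/50", {
  sc <- rbind(matrix(c(rep(0, 5), rnorm(5, sd = .1)), 5, 2),   # A at x ~ 0
              matrix(c(rep(4, 5), rnorm(5, sd = .1)), 5, 2),   # B at x ~ 4
              cbind(c(3.5, 3.8, 4.1, 3.9), rnorm(4, sd = .1))) # unknowns near B
  lb <- c(rep("A", 5), rep("B", 5), rep("unknown", 4))
  cd <- codistribution_assign(sc, lb)
  expect_equal(cd$assigned, "B")
  expect_equal(unname(cd$percent["B"]), 100)
  expect_equal(sum(cd$percent) + cd$on_line, 100)
  # 9/1 split
  sc2 <- rbind(sc[1:10, ], cbind(c(rep(4, 9), 0), 0))
  lb2 <- c(rep("A", 5), rep("B", 5), rep("unknown", 10))
  cd2 <- codistribution_assign(sc2, lb2)
  expect_equal(unname(cd2$percent), c(10, 90))
  expect_equal(cd2$assigned, "B")
  # exact tie
  sc3 <- rbind(sc[1:10, ], cbind(c(0, 4), 0))
  cd3 <- codistribution_assign(sc3, c(rep("A", 5), rep("B", 5), rep("unknown", 2)))
  expect_true(cd3$tie)
  expect_error(codistribution_assign(sc[1:10, ], lb[1:10]), "unknown")
})

test_that("component report captures variance and band loadings", {
  ds <- small_dataset(n_per_class = 6, seed = 23)
  pp <- preprocess_pipeline(ds$matrix, preprocess_config("fixed"))
  res <- compute_svd(pp$matrix)
  rep3 <- component_report(res, 3)
  expect_equal(names(rep3)[1], "wavenumber")
  expect_equal(ncol(rep3), 4)
  # rank-3 matrix: top 3 components capture everything
  M3 <- matrix(rnorm(60), 20, 3) %*% matrix(rnorm(24), 3, 8)
  r3 <- compute_svd(M3)
  expect_equal(sum(r3$d[1:3]^2) / sum(r3$d^2), 1, tolerance = 1e-12)
  # a one-band dataset loads component 1 at the band position
  g <- default_grid("fixed")
  one <- vapply(1:6, function(i) (1 + 0.05 * i) * lorentz(g, 1248, 9),
                numeric(length(g)))
  rb <- compute_svd(one)
  expect_equal(g[which.max(abs(rb$u[, 1]))], 1248, tolerance = 3)
})

test_that("synthetic class structure separates in (2,3) score space", {
  ds <- small_dataset(n_per_class = 15, seed = 27)
  pp <- preprocess_pipeline(ds$matrix, preprocess_config("fixed"))
  sub <- pp$matrix[treatments(pp$matrix) %in% c("EGF", "FGF2")]
  sc <- svd_scores(compute_svd(sub), c(2, 3))
  lb <- attr(sc, "labels")
  mE <- colMeans(sc[lb == "EGF", ]); mF <- colMeans(sc[lb == "FGF2", ])
  between <- sqrt(sum((mE - mF)^2))
  within <- mean(c(sd(sc[lb == "EGF", 1]), sd(sc[lb == "FGF2", 1]),
                   sd(sc[lb == "EGF", 2]), sd(sc[lb == "FGF2", 2])))
  expect_gt(between, within)
})
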