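# Robust (ramp-loss) support vector machine classification with
# per-wavenumber min-max normalization and repeated stratified train/test
# evaluation.

#' RSVM configuration
#'
#' Defaults reproduce the evaluation protocol: per-wavenumber min-max
#' normalization of the assembled comparison dataset, a linear-kernel
#' ramp-loss (truncated hinge) SVM with C = 1 and truncation at s = -1, a
#' 100/120 train fraction (83--90% is the accepted band; values outside it
#' trigger a warning) and 4000 repetitions.
#'
#' @param loss `"ramp"` (truncated hinge, outlier-resistant) or `"hinge"`.
#' @param truncation_s Ramp truncation point (<= 0).
#' @param C Regularization weight (> 0).
#' @param kernel Only `"linear"` is supported.
#' @param train_fraction Fraction of each class used for training.
#' @param n_reps Number of stratified split repetitions.
#' @param seed Integer seed making [repeated_accuracy()] reproducible.
#' @param normalization `"combined"` computes min-max statistics on the full
#'   comparison dataset before splitting (the published protocol);
#'   `"train_only"` is the leakage-free variant (test values clipped to
#'   [0, 1]), recommended for new studies.
#' @return An `rsvm_config` list.
#' @export
rsvm_config <- function(loss = c("ramp", "hinge"), truncation_s = -1, C = 1,
                        kernel = "linear", train_fraction = 100 / 120,
                        n_reps = 4000, seed = NULL,
                        normalization = c("combined", "train_only")) {
  loss <- match.arg(loss)
  normalization <- match.arg(normalization)
  if (kernel != "linear") stop("only the linear kernel is supported", call. = FALSE)
  if (truncation_s > 0) stop("truncation_s must be <= 0", call. = FALSE)
  if (C <= 0) stop("C must be positive", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  if (train_fraction < 0.83 || train_fraction > 0.90)
    warning("train_fraction outside the 83-90% band", call. = FALSE)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  structure(list(loss = loss, truncation_s = truncation_s, C = C,
                 kernel = kernel, train_fraction = train_fraction,
                 n_reps = n_reps, seed = seed, normalization = normalization),
            class = "rsvm_config")
}

#' Per-feature min-max normalization
#'
#' At each wavenumber the feature minimum is subtracted and the difference is
#' divided by the feature range, so the scaled reference values lie in
#' [0, 1]; constant features map to 0. Statistics are computed on `train`
#' (pass the full comparison dataset as `train` for the combined protocol);
#' `test` rows are scaled with the same statistics and, when `clip = TRUE`,
#' clipped to [0, 1].
#'
#' @param train Numeric matrix, spectra as rows.
#' @param test Optional matrix with the same columns.
#' @param clip Clip scaled test values to [0, 1].
#' @return List with `train`, `test` (NULL if absent), `min`, `range`.
#' @export
minmax_normalize <- function(train, test = NULL, clip = FALSE) {
  train <- as.matrix(train)
  if (nrow(train) == 0 || ncol(train) == 0) stop("empty input", call. = FALSE)
  mins <- apply(train, 2, min)
  rngs <- apply(train, 2, max) - mins
  scale_one <- function(m) {
    m <- sweep(as.matrix(m), 2, mins)
    m <- sweep(m, 2, ifelse(rngs > 0, rngs, 1), `/`)
    m[, rngs == 0] <- 0
    m
  }
  tr <- scale_one(train)
  te <- if (!is.null(test)) {
    if (ncol(as.matrix(test)) != ncol(train))
      stop("test feature width differs from train", call. = FALSE)
    x <- scale_one(test)
    if (clip) x <- pmin(pmax(x, 0), 1)
    x
  }
  list(train = tr, test = te, min = mins, range = rngs)
}

ramp_objective <- function(w, b, X, y, C, s) {
  f <- drop(X %*% w) + b
  margins <- y * f
  0.5 * sum(w^2) + 0.5 * b^2 +
    C * sum(pmin(pmax(0, 1 - margins), 1 - s))
}

#' Train a (robust) linear SVM
#'
#' The ramp loss min(max(0, 1 - yf), 1 - s) caps the penalty of far-side
#' points, making the learned classifier resistant to outliers. It is
#' optimized by the concave-convex procedure: the loss splits into a hinge
#' minus a shifted hinge, and each iteration solves a convex weighted
#' hinge-loss SVM (dual coordinate descent with per-point box constraints
#' shifted by the current outlier set, the points with y f(x) < s).
#' Iterations stop when the outlier set is unchanged (or after 50). The bias
#' is carried as an augmented, regularized constant feature.
#' `loss = "hinge"` performs a single unshifted iteration (a standard SVM).
#'
#' @param x Feature matrix, spectra as rows.
#' @param y Labels: a two-level factor (second level = positive class) or a
#'   vector coercible to -1/+1.
#' @param config An [rsvm_config()].
#' @return An `rsvm_model`: weights `w`, bias `b`, factor `levels`, CCCP
#'   `iterations` and the (non-increasing) ramp `objective` trace.
#' @export
rsvm_train <- function(x, y, config = rsvm_config()) {
  x <- as.matrix(x)
  if (is.factor(y) || is.character(y)) {
    y <- factor(y)
    if (nlevels(y) != 2) stop("need exactly two classes", call. = FALSE)
    lev <- levels(y)
    yy <- ifelse(y == lev[2], 1, -1)
  } else {
    yy <- as.numeric(y)
    if (!all(yy %in% c(-1, 1))) stop("numeric labels must be -1/+1", call. = FALSE)
    lev <- c("-1", "1")
  }
  if (length(unique(yy)) < 2)
    stop("training set contains a single class", call. = FALSE)
  n <- nrow(x)
  Xa <- cbind(x, 1) # augmented, regularized bias
  K <- tcrossprod(Xa)
  Q <- K * tcrossprod(yy)
  C <- config$C; s <- config$truncation_s
  beta <- rep(0, n)
  alpha <- rep(0, n)
  obj <- numeric(0)
  it <- 0L
  repeat {
    it <- it + 1L
    alpha <- svm_dcd(Q, lo = -beta, hi = C - beta, alpha0 = alpha)
    wa <- drop(crossprod(Xa, alpha * yy))
    w <- wa[-length(wa)]; b <- wa[length(wa)]
    obj <- c(obj, ramp_objective(w, b, x, yy, C, s))
    if (config$loss == "hinge") break
    margins <- yy * (drop(x %*% w) + b)
    new_beta <- ifelse(margins < s, C, 0)
    if (identical(new_beta, beta) || it >= 50) break
    beta <- new_beta
  }
  structure(list(w = w, b = b, levels = lev, iterations = it,
                 objective = obj, config = config),
            class = "rsvm_model")
}

#' Predict class labels with a trained RSVM
#'
#' Sign of the linear decision function; a decision value of exactly 0 is
#' assigned to the positive class (deterministic tie rule).
#'
#' @param model An `rsvm_model`.
#' @param x Feature matrix with the training feature width.
#' @return Factor of predicted labels with the training levels.
#' @export
rsvm_predict <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(model$w))
    stop("feature width differs from training (", length(model$w), ")",
         call. = FALSE)
  f <- drop(x %*% model$w) + model$b
  factor(ifelse(f >= 0, model$levels[2], model$levels[1]),
         levels = model$levels)
}

#' Repeated stratified train/test RSVM evaluation
#'
#' For each repetition: a stratified random split at `train_fraction` per
#' class, min-max normalization (combined or train-only per the
#' configuration), ramp-SVM training, and test-set accuracy. With two groups
#' of 60 spectra and the default fraction this is the 120-spectra,
#' 100-train/20-test protocol.
#'
#' @param matrix A [spectra_matrix()] (spectra as columns) or a feature
#'   matrix with spectra as rows.
#' @param labels Per-spectrum labels; exactly two groups are compared
#'   (subset with `groups`).
#' @param config An [rsvm_config()]; `config$seed` makes the split sequence
#'   reproducible.
#' @param groups Optional two group labels selecting the comparison.
#' @return An `accuracy_distribution`: per-repetition accuracies, mean, sd,
#'   and a kernel-density summary for violin plots.
#' @export
repeated_accuracy <- function(matrix, labels = NULL, config = rsvm_config(),
                              groups = NULL) {
  if (inherits(matrix, "spectra_matrix")) {
    labels <- labels %||% matrix$meta$treatment
    feats <- t(matrix$intensities)
  } else {
    feats <- as.matrix(matrix)
    if (is.null(labels)) stop("labels required for a plain matrix", call. = FALSE)
  }
  labels <- as.character(labels)
  groups <- groups %||% unique(labels)
  if (length(groups) != 2)
    stop("exactly two groups must be compared (pass `groups`)", call. = FALSE)
  sel <- labels %in% groups
  feats <- feats[sel, , drop = FALSE]
  y <- factor(labels[sel], levels = groups)
  sizes <- table(y)
  if (any(sizes < 2)) stop("need >= 2 spectra per group", call. = FALSE)
  n_train <- round(as.numeric(sizes) * config$train_fraction)
  if (any(n_train >= sizes) || any(n_train < 1))
    stop("train_fraction leaves an empty train or test set", call. = FALSE)
  if (config$normalization == "combined")
    feats <- minmax_normalize(feats)$train
  if (!is.null(config$seed)) set.seed(config$seed)
  idx_by_class <- split(seq_along(y), y)
  acc <- vapply(seq_len(config$n_reps), function(r) {
    tr <- unlist(lapply(seq_along(idx_by_class), function(k)
      sample(idx_by_class[[k]], n_train[k])))
    te <- setdiff(seq_along(y), tr)
    if (config$normalization == "train_only") {
      nm <- minmax_normalize(feats[tr, , drop = FALSE],
                             feats[te, , drop = FALSE], clip = TRUE)
      xtr <- nm$train; xte <- nm$test
    } else {
      xtr <- feats[tr, , drop = FALSE]; xte <- feats[te, , drop = FALSE]
    }
    model <- rsvm_train(xtr, y[tr], config)
    mean(rsvm_predict(model, xte) == y[te])
  }, numeric(1))
  dens <- density(acc, from = 0, to = 1)
  structure(list(accuracies = acc, mean = mean(acc), sd = sd(acc),
                 groups = groups, n_reps = config$n_reps,
                 violin = data.frame(accuracy = dens$x, density = dens$y),
                 config = config),
            class = "accuracy_distribution")
}

#' @export
print.accuracy_distribution <- function(x, ...) {
  cat(sprintf("<accuracy_distribution> %s vs %s: mean %.3f, sd %.3f (%d reps)\n",
              x$groups[1], x$groups[2], x$mean, x$sd, x$n_reps))
  invisible(x)
}

#' Violin-style plot of an accuracy distribution
#'
#' @param x An `accuracy_distribution`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.accuracy_distribution <- function(x, ...) {
  d <- x$violin
  graphics::plot(NULL, xlim = c(-1, 1) * max(d$density) * 1.1,
                 ylim = c(0, 1), xlab = "density", ylab = "accuracy",
                 main = sprintf("%s vs %s", x$groups[1], x$groups[2]), ...)
  graphics::polygon(c(d$density, -rev(d$density)), c(d$accuracy, rev(d$accuracy)),
                    col = "grey80")
  graphics::abline(h = x$mean, lty = 2)
  invisible(x)
}
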