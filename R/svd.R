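# SVD scatter analysis: decomposition of the stacked spectra matrix, score
# plots, the perpendicular-bisector separation statistic, and the blinded
# codistribution assignment.

#' Stack group matrices (and an optional unknown block) into one input matrix
#'
#' Columns are stacked in the given group order with the unknown block last,
#' mirroring the stacked-matrix convention (e.g. control columns 1--50, EGF
#' columns 51--100, unknown columns 101--110). All inputs must share the
#' grid; resample first with [resample_to_grid()] if they do not.
#'
#' @param groups List of [spectra_matrix()] objects (one per known group).
#' @param unknown Optional [spectra_matrix()] of unknown spectra; its labels
#'   are set to `"unknown"`.
#' @return A [spectra_matrix()] with contiguous group blocks.
#' @export
build_input_matrix <- function(groups, unknown = NULL) {
  if (inherits(groups, "spectra_matrix")) groups <- list(groups)
  all_parts <- c(groups, if (!is.null(unknown)) list(unknown))
  grid <- all_parts[[1]]$wavenumber
  for (p in all_parts[-1])
    if (length(p$wavenumber) != length(grid) ||
        max(abs(p$wavenumber - grid)) > 1e-9)
      stop("grid mismatch between blocks; resample_to_grid() first", call. = FALSE)
  ints <- do.call(cbind, lapply(all_parts, function(p) p$intensities))
  meta <- do.call(rbind, lapply(all_parts, function(p) p$meta))
  if (!is.null(unknown)) {
    n_unknown <- n_spectra(unknown)
    meta$treatment[(nrow(meta) - n_unknown + 1):nrow(meta)] <- "unknown"
  }
  spectra_matrix(grid, ints, meta)
}

#' Singular value decomposition of a stacked spectra matrix
#'
#' Thin SVD of the raw n x m matrix (no centering by default: with
#' non-negative spectra the first component captures the shared mean shape,
#' which is informative in the component report). Columns of U hold the
#' spectral loadings ("SVD components"); rows of V give per-spectrum
#' coordinates. The sign ambiguity is fixed deterministically: each U
#' column's largest-magnitude element is made positive, with V adjusted
#' accordingly.
#'
#' @param matrix A [spectra_matrix()] or plain numeric matrix (n points x m
#'   spectra).
#' @param k Optional rank (number of retained components).
#' @param center Subtract the row (wavenumber-wise) mean first; off by
#'   default.
#' @return A `raman_svd`: list with `u` (n x k), `d` (singular values,
#'   non-increasing), `v` (m x k), `labels`, `wavenumber`, `centered`.
#' @export
compute_svd <- function(matrix, k = NULL, center = FALSE) {
  if (inherits(matrix, "spectra_matrix")) {
    M <- matrix$intensities
    labels <- matrix$meta$treatment
    w <- matrix$wavenumber
  } else {
    M <- as.matrix(matrix)
    labels <- colnames(M) %||% rep("unknown", ncol(M))
    w <- seq_len(nrow(M))
  }
  if (nrow(M) < 2 || ncol(M) < 2) stop("need n >= 2 and m >= 2", call. = FALSE)
  if (any(!is.finite(M))) stop("matrix contains non-finite values", call. = FALSE)
  if (center) M <- M - rowMeans(M)
  kk <- min(nrow(M), ncol(M))
  if (!is.null(k)) kk <- min(kk, k)
  sv <- svd(M, nu = kk, nv = kk)
  sv$d <- sv$d[seq_len(kk)]
  for (j in seq_len(kk)) {
    s <- sign(sv$u[which.max(abs(sv$u[, j])), j])
    if (s < 0) { sv$u[, j] <- -sv$u[, j]; sv$v[, j] <- -sv$v[, j] }
  }
  structure(list(u = sv$u, d = sv$d, v = sv$v, labels = labels,
                 wavenumber = w, centered = center),
            class = "raman_svd")
}

#' @export
print.raman_svd <- function(x, ...) {
  cat(sprintf("<raman_svd> %d x %d, %d components; leading singular values: %s\n",
              nrow(x$u), nrow(x$v), length(x$d),
              paste(signif(utils::head(x$d, 4), 4), collapse = ", ")))
  invisible(x)
}

#' Per-spectrum scores for a scatter plot
#'
#' Rows of V at the chosen component pair, scaled by the corresponding
#' singular values by default (so scores carry variance weight). The default
#' pair (2, 3) reflects that, without centering, component 1 is the shared
#' mean spectrum shape.
#'
#' @param result A [compute_svd()] result.
#' @param component_pair Two distinct component indices.
#' @param scale Scale V rows by the singular values (default TRUE).
#' @return An m x 2 score matrix with the per-spectrum labels in
#'   `attr(, "labels")` and the pair in `attr(, "components")`.
#' @export
svd_scores <- function(result, component_pair = c(2, 3), scale = TRUE) {
  k <- length(result$d)
  if (length(component_pair) != 2 || component_pair[1] == component_pair[2])
    stop("component_pair must be two distinct indices", call. = FALSE)
  if (any(component_pair < 1) || any(component_pair > k))
    stop("component index out of range (k = ", k, ")", call. = FALSE)
  sc <- result$v[, component_pair, drop = FALSE]
  if (scale) sc <- sweep(sc, 2, result$d[component_pair], `*`)
  colnames(sc) <- paste0("comp", component_pair)
  attr(sc, "labels") <- result$labels
  attr(sc, "components") <- component_pair
  sc
}

bisector_sides <- function(scores, mean_a, mean_b) {
  dir <- mean_b - mean_a
  if (sqrt(sum(dir^2)) == 0)
    stop("coincident group means; no defined bisector", call. = FALSE)
  mid <- (mean_a + mean_b) / 2
  drop(sweep(scores, 2, mid) %*% dir) # <0: side A, >0: side B, 0: on line
}

#' Perpendicular-bisector separation between two groups in score space
#'
#' The boundary is the line perpendicular to and equidistant from the two
#' group means; each spectrum is assigned to the side its score falls on
#' (equivalent to two-class nearest-centroid classification). Points exactly
#' on the boundary are counted in an `on_line` bucket rather than silently
#' assigned.
#'
#' @param scores Score matrix from [svd_scores()].
#' @param labels Per-spectrum labels (defaults to `attr(scores, "labels")`).
#' @param groups The two group labels to compare (defaults to the two labels
#'   present).
#' @return An `svd_separation`: group means, per-spectrum side factor, and a
#'   per-group percentage table (own side / other side / on line).
#' @export
separation_analysis <- function(scores, labels = attr(scores, "labels"),
                                groups = NULL) {
  labels <- as.character(labels)
  if (is.null(groups)) {
    groups <- unique(labels)
    if (length(groups) != 2)
      stop("scores must contain exactly two labeled groups (or pass `groups`)",
           call. = FALSE)
  }
  sel <- labels %in% groups
  sc <- scores[sel, , drop = FALSE]
  lb <- labels[sel]
  mean_a <- colMeans(sc[lb == groups[1], , drop = FALSE])
  mean_b <- colMeans(sc[lb == groups[2], , drop = FALSE])
  s <- bisector_sides(sc, mean_a, mean_b)
  side <- factor(ifelse(s < 0, groups[1], ifelse(s > 0, groups[2], "on_line")),
                 levels = c(groups, "on_line"))
  pct <- t(vapply(groups, function(g) {
    tab <- table(side[lb == g])
    100 * as.numeric(tab) / sum(tab)
  }, numeric(3)))
  colnames(pct) <- c(paste0("side_", groups), "on_line")
  rownames(pct) <- groups
  structure(list(groups = groups, mean_a = mean_a, mean_b = mean_b,
                 side = side, labels = lb, percentages = pct),
            class = "svd_separation")
}

#' @export
print.svd_separation <- function(x, ...) {
  cat(sprintf("<svd_separation> %s vs %s\n", x$groups[1], x$groups[2]))
  print(round(x$percentages, 1))
  invisible(x)
}

#' Codistribution assignment of an unknown block
#'
#' The bisector boundary is computed from the two known group means only;
#' unknown spectra are then assigned to sides, and the verdict is the side
#' holding the strict majority of the unknown population (a 50/50 split sets
#' the tie flag). Percentages sum to 100 (on-line points reported
#' separately).
#'
#' @param scores Score matrix covering knowns and unknowns.
#' @param labels Per-spectrum labels (two known groups + the unknown label).
#' @param unknown_label Label marking the unknown block (default
#'   `"unknown"`).
#' @return A `codistribution_verdict`: per-side percentages of the unknown
#'   population and the assigned label.
#' @export
codistribution_assign <- function(scores, labels = attr(scores, "labels"),
                                  unknown_label = "unknown") {
  labels <- as.character(labels)
  known <- setdiff(unique(labels), unknown_label)
  if (length(known) != 2)
    stop("need exactly two known groups beside the unknown block", call. = FALSE)
  if (!any(labels == unknown_label)) stop("empty unknown block", call. = FALSE)
  mean_a <- colMeans(scores[labels == known[1], , drop = FALSE])
  mean_b <- colMeans(scores[labels == known[2], , drop = FALSE])
  s <- bisector_sides(scores[labels == unknown_label, , drop = FALSE],
                      mean_a, mean_b)
  n_a <- sum(s < 0); n_b <- sum(s > 0); n_on <- sum(s == 0)
  pct <- 100 * c(n_a, n_b) / length(s)
  names(pct) <- known
  verdict <- if (n_a == n_b) NA_character_ else known[which.max(c(n_a, n_b))]
  structure(list(percent = pct, on_line = 100 * n_on / length(s),
                 assigned = verdict, tie = n_a == n_b,
                 n_unknown = length(s)),
            class = "codistribution_verdict")
}

#' @export
print.codistribution_verdict <- function(x, ...) {
  cat(sprintf("<codistribution> %s: %.0f%% / %s: %.0f%% -> %s\n",
              names(x$percent)[1], x$percent[1],
              names(x$percent)[2], x$percent[2],
              if (x$tie) "tie" else x$assigned))
  invisible(x)
}

#' Leading-component report
#'
#' Exports the leading U columns (spectral loadings over wavenumber) with
#' their singular values and variance shares, for plotting and
#' region-of-interest inspection.
#'
#' @param result A [compute_svd()] result.
#' @param top_k Number of leading components (<= available rank).
#' @return Data frame `wavenumber` + one column per component; singular
#'   values and variance fractions in attributes.
#' @export
component_report <- function(result, top_k = 3) {
  if (top_k > length(result$d)) stop("top_k exceeds available components", call. = FALSE)
  out <- data.frame(wavenumber = result$wavenumber,
                    result$u[, seq_len(top_k), drop = FALSE])
  names(out)[-1] <- paste0("component", seq_len(top_k))
  attr(out, "singular_values") <- result$d[seq_len(top_k)]
  attr(out, "variance_fraction") <- result$d[seq_len(top_k)]^2 / sum(result$d^2)
  out
}

#' Blinded classification of an unknown batch by SVD codistribution
#'
#' For every pair of known groups, the unknown block is stacked after the two
#' group blocks, the combined matrix is decomposed (the unknown block
#' participates in the decomposition but not in the boundary), and the
#' codistribution verdict is recorded. The overall assignment is the label
#' winning the most pairwise verdicts (the true class appears in two of the
#' three pairs, so a consistent signal wins 2 to 1).
#'
#' @param known [spectra_matrix()] of the preprocessed known spectra (>= 2
#'   groups).
#' @param unknown [spectra_matrix()] of the preprocessed unknown batch.
#' @param component_pair Score components (default `c(2, 3)`).
#' @param scale Singular-value scaling of scores.
#' @return A `blinded_svd_result`: per-pair `codistribution_verdict`s and the
#'   overall `winner` (NA on a tie).
#' @export
classify_blinded_by_svd <- function(known, unknown, component_pair = c(2, 3),
                                    scale = TRUE) {
  groups <- unique(known$meta$treatment)
  if (length(groups) < 2) stop("need at least two known groups", call. = FALSE)
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  verdicts <- lapply(pairs, function(pr) {
    gmats <- lapply(pr, function(g) known[known$meta$treatment == g])
    stacked <- build_input_matrix(gmats, unknown = unknown)
    res <- compute_svd(stacked)
    sc <- svd_scores(res, component_pair, scale = scale)
    codistribution_assign(sc)
  })
  names(verdicts) <- vapply(pairs, paste, "", collapse = "_vs_")
  wins <- table(unlist(lapply(verdicts, `[[`, "assigned")))
  winner <- if (length(wins) == 0 || sum(wins == max(wins)) > 1) NA_character_
            else names(wins)[which.max(wins)]
  structure(list(verdicts = verdicts, winner = winner),
            class = "blinded_svd_result")
}

#' @export
print.blinded_svd_result <- function(x, ...) {
  cat("<blinded_svd_result> winner:",
      if (is.na(x$winner)) "tie" else x$winner, "\n")
  for (nm in names(x$verdicts)) { cat(" ", nm, ": "); print(x$verdicts[[nm]]) }
  invisible(x)
}
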