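# Diagnostic peak-intensity extraction, group statistics (one-way ANOVA with
# Dunnett's post hoc and Bonferroni-corrected pairwise t-tests), and the
# blinded minimum-mean-difference peak-vote classifier.

#' Diagnostic peak panel
#'
#' The default panel holds the nine diagnostic band centers
#' (569, 621, 676, 1124, 1248, 1335, 1446, 1654, 1926 cm^-1). Intensities
#' are extracted as the maximum within `center +- half_window`.
#'
#' @param centers Ordered distinct wavenumbers (cm^-1).
#' @param half_window Extraction half-window (cm^-1, default 6, i.e. about
#'   three grid steps).
#' @return A `peak_panel` list.
#' @export
peak_panel <- function(centers = diagnostic_centers(), half_window = 6) {
  if (anyDuplicated(centers)) stop("panel centers must be distinct", call. = FALSE)
  if (half_window <= 0) stop("half_window must be positive", call. = FALSE)
  structure(list(centers = as.numeric(centers), half_window = half_window),
            class = "peak_panel")
}

#' Extract a peak intensity from one spectrum
#'
#' Maximum intensity over the grid points within `center +- half_window`.
#'
#' @param spectrum A `raman_spectrum`.
#' @param center Band center (cm^-1).
#' @param half_window Half-window (cm^-1).
#' @return Scalar intensity.
#' @export
extract_peak_intensity <- function(spectrum, center, half_window = 6) {
  w <- spectrum$wavenumber
  idx <- which(w >= center - half_window & w <= center + half_window)
  if (length(idx) == 0)
    stop("window around ", center, " cm^-1 does not intersect the grid",
         call. = FALSE)
  max(spectrum$intensity[idx])
}

#' Build the spectra-by-panel peak intensity table
#'
#' One row per kept (non-rejected) spectrum, one column per panel center, in
#' panel order; values are the window maxima of the (normalized) spectra.
#'
#' @param matrix A preprocessed [spectra_matrix()].
#' @param panel A [peak_panel()].
#' @return A `peak_table` data frame with columns `spectrum_id`, `treatment`
#'   and one numeric column per center (named by the wavenumber); panel
#'   centers are kept in `attr(, "centers")`.
#' @export
build_peak_table <- function(matrix, panel = peak_panel()) {
  keep <- which(!matrix$meta$rejected)
  vals <- vapply(keep, function(j) {
    sp <- spectrum_at(matrix, j)
    vapply(panel$centers, extract_peak_intensity, numeric(1),
           spectrum = sp, half_window = panel$half_window)
  }, numeric(length(panel$centers)))
  if (is.null(dim(vals))) dim(vals) <- c(length(panel$centers), length(keep))
  vals <- t(vals)
  colnames(vals) <- as.character(panel$centers)
  out <- data.frame(spectrum_id = matrix$meta$spectrum_id[keep],
                    treatment = matrix$meta$treatment[keep],
                    vals, check.names = FALSE, stringsAsFactors = FALSE)
  attr(out, "centers") <- panel$centers
  class(out) <- c("peak_table", "data.frame")
  out
}

peak_columns <- function(table) {
  as.character(attr(table, "centers") %||%
                 setdiff(names(table), c("spectrum_id", "treatment")))
}

#' Per-peak group statistics
#'
#' For every panel center: per-group mean with 95% confidence interval
#' (mean +- t(0.975, n-1) * SE), one-way ANOVA across groups, Dunnett's post
#' hoc comparisons against the control group, and all pairwise pooled-variance
#' t-tests with Bonferroni correction (factor = number of pairs).
#'
#' When all group means coincide (zero between-group sum of squares) the
#' ANOVA F is reported as 0 with p = 1.
#'
#' @param table A [build_peak_table()] result (>= 2 groups, >= 2 spectra per
#'   group).
#' @param control Reference group label for the Dunnett contrasts.
#' @return A `group_stats` list of data frames: `means`, `anova`, `dunnett`,
#'   `pairwise`.
#' @export
group_statistics <- function(table, control = "control") {
  centers <- peak_columns(table)
  groups <- factor(table$treatment)
  if (nlevels(groups) < 2) stop("need at least two groups", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 2))
    stop("group with fewer than 2 spectra: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  if (!control %in% levels(groups))
    stop("control group '", control, "' not present", call. = FALSE)
  groups <- stats::relevel(groups, ref = control)
  pairs <- utils::combn(levels(groups), 2)
  n_pairs <- ncol(pairs)

  means <- list(); anov <- list(); dun <- list(); pw <- list()
  for (ctr in centers) {
    y <- table[[ctr]]
    gm <- tapply(y, groups, mean)
    gs <- tapply(y, groups, sd)
    gn <- as.numeric(table(groups))
    ci <- qt(0.975, gn - 1) * gs / sqrt(gn)
    means[[ctr]] <- data.frame(center = as.numeric(ctr),
                               group = levels(groups), n = gn,
                               mean = as.numeric(gm),
                               ci_lo = as.numeric(gm - ci),
                               ci_hi = as.numeric(gm + ci),
                               stringsAsFactors = FALSE)
    ssb <- sum(gn * (gm - mean(y))^2)
    if (ssb <= 1e-12 * max(sum((y - mean(y))^2), .Machine$double.eps)) {
      Fv <- 0; pv <- 1
      dun_p <- rep(1, nlevels(groups) - 1)
      dun_est <- as.numeric(gm[-1] - gm[1])
      fit <- NULL
    } else {
      fit <- aov(y ~ g, data = data.frame(y = y, g = groups))
      at <- summary(fit)[[1]]
      Fv <- at[["F value"]][1]; pv <- at[["Pr(>F)"]][1]
      gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
      sm <- summary(gl)
      dun_p <- as.numeric(sm$test$pvalues)
      dun_est <- as.numeric(sm$test$coefficients)
    }
    anov[[ctr]] <- data.frame(center = as.numeric(ctr), F = Fv, p = pv)
    dun[[ctr]] <- data.frame(center = as.numeric(ctr),
                             comparison = paste(levels(groups)[-1], "-", control),
                             estimate = dun_est, p_adj = pmin(dun_p, 1),
                             stringsAsFactors = FALSE)
    pw[[ctr]] <- do.call(rbind, lapply(seq_len(n_pairs), function(k) {
      a <- pairs[1, k]; b <- pairs[2, k]
      ya <- y[groups == a]; yb <- y[groups == b]
      tt <- if (sd(c(ya, yb)) == 0)
        list(statistic = 0, p.value = 1)
      else t.test(ya, yb, var.equal = TRUE)
      data.frame(center = as.numeric(ctr), group_a = a, group_b = b,
                 t = unname(tt$statistic), p_raw = tt$p.value,
                 p_bonf = min(1, tt$p.value * n_pairs),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(means = do.call(rbind, means),
                 anova = do.call(rbind, anov),
                 dunnett = do.call(rbind, dun),
                 pairwise = do.call(rbind, pw),
                 control = control),
            class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat("<group_stats>", length(unique(x$anova$center)), "peaks,",
      length(unique(x$means$group)), "groups; ANOVA:\n")
  print(x$anova, row.names = FALSE)
  invisible(x)
}

#' Assign one peak to the nearest group mean
#'
#' Returns the label minimizing the absolute difference between the unknown
#' mean intensity and the group means. An exact tie is flagged `ambiguous`
#' with every tied label recorded; ambiguous peaks cast no vote.
#'
#' @param unknown_mean Scalar intensity from the unknown batch.
#' @param group_means Named numeric vector of known group means (>= 2).
#' @return List with `label` (NA when ambiguous), `ambiguous` and
#'   `candidates` (tied labels).
#' @export
assign_peak <- function(unknown_mean, group_means) {
  if (length(group_means) < 2 || is.null(names(group_means)))
    stop("group_means must be a named vector with >= 2 groups", call. = FALSE)
  d <- abs(unknown_mean - group_means)
  hit <- names(group_means)[d == min(d)]
  if (length(hit) > 1)
    list(label = NA_character_, ambiguous = TRUE, candidates = hit)
  else
    list(label = hit, ambiguous = FALSE, candidates = hit)
}

#' Majority vote over per-peak assignments
#'
#' The winner is the plurality label, reported as "k out of n" with n the
#' full assignment count (ambiguous/NA assignments cast no vote but count
#' toward n). A tie between top labels sets the tie flag and no winner.
#'
#' @param assignments Character vector of per-peak labels (NA = no vote).
#' @return A `vote_verdict`: list with `winner`, `count`, `n`, `tie`,
#'   `counts`.
#' @export
majority_vote <- function(assignments) {
  if (length(assignments) == 0) stop("no assignments", call. = FALSE)
  counts <- table(assignments[!is.na(assignments)])
  if (length(counts) == 0)
    return(structure(list(winner = NA_character_, count = 0L,
                          n = length(assignments), tie = TRUE,
                          counts = counts), class = "vote_verdict"))
  top <- max(counts)
  leaders <- names(counts)[counts == top]
  tie <- length(leaders) > 1
  structure(list(winner = if (tie) NA_character_ else leaders,
                 count = as.integer(top), n = length(assignments),
                 tie = tie, counts = counts),
            class = "vote_verdict")
}

#' @export
print.vote_verdict <- function(x, ...) {
  if (x$tie) cat("<vote_verdict> tie --", paste(names(x$counts)[x$counts == max(x$counts)], collapse = " / "), "\n")
  else cat(sprintf("<vote_verdict> %s (%d out of %d peaks)\n", x$winner, x$count, x$n))
  invisible(x)
}

#' Blinded classification of an unknown batch by the peak-vote procedure
#'
#' The unknown spectra are averaged and normalized to the phenylalanine peak,
#' panel intensities are extracted from the averaged spectrum, each peak is
#' assigned to the nearest known group mean, and a simple majority determines
#' the verdict. With `average_first = FALSE` intensities are instead
#' extracted per spectrum and then averaged.
#'
#' A secondary annotation records, per peak, every non-assigned group whose
#' 95% confidence interval contains the unknown mean (overlapping ranges);
#' the annotation never affects the vote.
#'
#' @param unknown_matrix Preprocessed [spectra_matrix()] of the unknown batch.
#' @param known_table [build_peak_table()] of the known groups (>= 2 groups).
#' @param panel A [peak_panel()].
#' @param phe_window Normalization window for the averaged spectrum.
#' @param average_first Average spectra before extraction (default) or
#'   average per-spectrum intensities.
#' @return A `blinded_peak_result`: list with `verdict` (a `vote_verdict`)
#'   and `assignments` (per-peak data frame: center, unknown mean, assigned
#'   label, ambiguity, overlapping groups).
#' @export
classify_blinded_by_peaks <- function(unknown_matrix, known_table,
                                      panel = peak_panel(),
                                      phe_window = c(995, 1011),
                                      average_first = TRUE) {
  centers <- peak_columns(known_table)
  if (length(unique(known_table$treatment)) < 2)
    stop("known table must contain at least two groups", call. = FALSE)
  keep <- which(!unknown_matrix$meta$rejected)
  if (length(keep) == 0) stop("unknown batch has no kept spectra", call. = FALSE)
  if (average_first) {
    avg <- raman_spectrum(unknown_matrix$wavenumber,
                          rowMeans(unknown_matrix$intensities[, keep, drop = FALSE]),
                          spectrum_id = "unknown_mean")
    avg <- normalize_phenylalanine(avg, phe_window)
    unknown_means <- vapply(as.numeric(centers), extract_peak_intensity,
                            numeric(1), spectrum = avg,
                            half_window = panel$half_window)
  } else {
    sub <- unknown_matrix[keep]
    tab <- build_peak_table(sub, panel)
    unknown_means <- colMeans(as.matrix(tab[, centers]))
  }
  names(unknown_means) <- centers

  stats <- group_statistics_means(known_table)
  rows <- lapply(centers, function(ctr) {
    gm <- stats$mean[stats$center == as.numeric(ctr)]
    names(gm) <- stats$group[stats$center == as.numeric(ctr)]
    asg <- assign_peak(unknown_means[[ctr]], gm)
    lo <- stats$ci_lo[stats$center == as.numeric(ctr)]
    hi <- stats$ci_hi[stats$center == as.numeric(ctr)]
    inside <- names(gm)[unknown_means[[ctr]] >= lo & unknown_means[[ctr]] <= hi]
    overlap <- setdiff(inside, asg$label)
    data.frame(center = as.numeric(ctr), unknown_mean = unknown_means[[ctr]],
               assigned = asg$label, ambiguous = asg$ambiguous,
               overlap = paste(overlap, collapse = ","),
               stringsAsFactors = FALSE)
  })
  assignments <- do.call(rbind, rows)
  structure(list(verdict = majority_vote(assignments$assigned),
                 assignments = assignments),
            class = "blinded_peak_result")
}

# per-group per-peak mean and 95% CI of a peak table (helper shared with the
# blinded procedure; full inferential output lives in group_statistics()).
group_statistics_means <- function(table) {
  centers <- peak_columns(table)
  groups <- factor(table$treatment)
  out <- lapply(centers, function(ctr) {
    y <- table[[ctr]]
    gm <- tapply(y, groups, mean)
    gs <- tapply(y, groups, sd)
    gn <- as.numeric(table(groups))
    ci <- qt(0.975, pmax(gn - 1, 1)) * gs / sqrt(gn)
    ci[is.na(ci)] <- 0
    data.frame(center = as.numeric(ctr), group = levels(groups),
               mean = as.numeric(gm),
               ci_lo = as.numeric(gm - ci), ci_hi = as.numeric(gm + ci),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.blinded_peak_result <- function(x, ...) {
  print(x$verdict)
  print(x$assignments, row.names = FALSE)
  invisible(x)
}
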