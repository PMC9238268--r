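# End-to-end orchestration: simulate (or load) -> preprocess -> peak
# statistics / SVD separations / RSVM accuracies -> optional blinded
# verdicts, consolidated into a machine-readable report.

#' Run configuration for the end-to-end pipeline
#'
#' @param mode Acquisition mode (propagated to the stage configs).
#' @param sim A [sim_config()] (used when no input matrix is given).
#' @param prep A [preprocess_config()].
#' @param panel A [peak_panel()].
#' @param component_pair SVD score components.
#' @param rsvm An [rsvm_config()].
#' @param effect_size,amplitude_cv Class profile parameters for simulation.
#' @param blinded Number of spectra to exclude per class into blinded unknown
#'   batches (0 disables the blinded stage).
#' @param seed Global seed; propagated to every stochastic stage.
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("fixed", "live"), sim = NULL, prep = NULL,
                       panel = peak_panel(), component_pair = c(2, 3),
                       rsvm = NULL, effect_size = 0.5, amplitude_cv = 0.1,
                       blinded = 0, seed = 1) {
  mode <- match.arg(mode)
  sim <- sim %||% sim_config(mode = mode, seed = seed)
  sim$seed <- sim$seed %||% seed
  prep <- prep %||% preprocess_config(mode = mode)
  rsvm <- rsvm %||% rsvm_config(n_reps = 200, seed = seed + 1L)
  structure(list(mode = mode, sim = sim, prep = prep, panel = panel,
                 component_pair = component_pair, rsvm = rsvm,
                 effect_size = effect_size, amplitude_cv = amplitude_cv,
                 blinded = blinded, seed = seed),
            class = "run_config")
}

#' Split a labeled dataset into known data and blinded unknown batches
#'
#' Removes `n_excluded` (non-contaminated) spectra per class into anonymized
#' unknown batches named `unknown 1`, `unknown 2`, ... in a seed-shuffled
#' order; the answer key maps batches back to their true class for post-hoc
#' unblinding.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param n_excluded Spectra excluded per class (default 10); must be
#'   positive and below the smallest class size.
#' @param seed Optional seed for the draw and the batch shuffle.
#' @return List with `known` (a [spectra_matrix()]), `unknowns` (named list
#'   of [spectra_matrix()] batches with labels set to `"unknown"`) and `key`
#'   (data frame: batch, true_label).
#' @export
make_blinded_fixture <- function(dataset, n_excluded = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_excluded < 1) stop("n_excluded must be >= 1 (no unknowns otherwise)",
                           call. = FALSE)
  mat <- dataset$matrix
  truth <- dataset$truth
  classes <- unique(truth$label)
  take <- list()
  for (cl in classes) {
    pool <- truth$spectrum_id[truth$label == cl & !truth$contaminated]
    if (n_excluded >= length(pool))
      stop("n_excluded >= usable class size for ", cl, call. = FALSE)
    take[[cl]] <- sample(pool, n_excluded)
  }
  order_cl <- sample(classes)
  unknowns <- list()
  for (k in seq_along(order_cl)) {
    sub <- mat[match(take[[order_cl[k]]], mat$meta$spectrum_id)]
    sub$meta$treatment <- "unknown"
    sub$meta$spectrum_id <- sprintf("unknown%d_%02d", k, seq_len(n_spectra(sub)))
    colnames(sub$intensities) <- sub$meta$spectrum_id
    unknowns[[sprintf("unknown %d", k)]] <- sub
  }
  known_ids <- setdiff(mat$meta$spectrum_id, unlist(take))
  list(known = mat[match(known_ids, mat$meta$spectrum_id)],
       unknowns = unknowns,
       key = data.frame(batch = sprintf("unknown %d", seq_along(order_cl)),
                        true_label = order_cl, stringsAsFactors = FALSE))
}

#' Score blinded verdicts against the answer key
#'
#' @param verdicts Named list (by batch) of assigned labels (NA = tie).
#' @param key Answer key from [make_blinded_fixture()].
#' @return Data frame with batch, assigned, true label and correctness.
#' @export
unblind_report <- function(verdicts, key) {
  assigned <- vapply(key$batch, function(b) {
    v <- verdicts[[b]]
    if (is.null(v) || is.na(v)) NA_character_ else as.character(v)
  }, character(1))
  data.frame(batch = key$batch, assigned = assigned,
             true_label = key$true_label,
             correct = !is.na(assigned) & assigned == key$true_label,
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Simulates a dataset (or takes one provided), preprocesses it, computes the
#' diagnostic peak table and group statistics, the three pairwise SVD
#' separations, the three pairwise RSVM accuracy distributions and, when
#' requested, the blinded peak-vote and SVD-codistribution verdicts per
#' unknown batch. Identical configurations produce identical reports (modulo
#' the timestamp).
#'
#' @param config A [run_config()].
#' @param dataset Optional pre-built [simulate_dataset()] result; otherwise
#'   one is simulated from `config`.
#' @param out_dir Optional directory: writes `report.json`, the clean spectra
#'   and peak table as TSV.
#' @return A `run_report` list with per-stage summaries.
#' @export
run_pipeline <- function(config = run_config(), dataset = NULL,
                         out_dir = NULL) {
  profiles <- make_class_profiles(config$effect_size, config$amplitude_cv)
  dataset <- dataset %||% simulate_dataset(profiles, config$sim)
  prep <- preprocess_pipeline(dataset$matrix, config$prep)
  clean <- prep$matrix
  table <- build_peak_table(clean, config$panel)
  stats <- group_statistics(table, control = "control")
  groups <- unique(clean$meta$treatment)
  pairs <- utils::combn(groups, 2, simplify = FALSE)

  seps <- lapply(pairs, function(pr) {
    sub <- clean[clean$meta$treatment %in% pr]
    sc <- svd_scores(compute_svd(sub), config$component_pair)
    separation_analysis(sc)
  })
  names(seps) <- vapply(pairs, paste, "", collapse = "_vs_")

  accs <- lapply(pairs, function(pr)
    repeated_accuracy(clean, config = config$rsvm, groups = pr))
  names(accs) <- names(seps)

  blinded <- NULL
  if (config$blinded > 0) {
    fx <- make_blinded_fixture(dataset, config$blinded,
                               seed = config$seed + 2L)
    kp <- preprocess_pipeline(fx$known, config$prep)
    ktab <- build_peak_table(kp$matrix, config$panel)
    votes <- list(); svds <- list()
    for (b in names(fx$unknowns)) {
      up <- preprocess_pipeline(fx$unknowns[[b]], config$prep)
      votes[[b]] <- classify_blinded_by_peaks(up$matrix, ktab, config$panel)
      svds[[b]] <- classify_blinded_by_svd(kp$matrix, up$matrix,
                                           config$component_pair)
    }
    blinded <- list(
      peak_vote = votes, svd = svds, key = fx$key,
      unblinding = list(
        peak_vote = unblind_report(lapply(votes, function(v) v$verdict$winner),
                                   fx$key),
        svd = unblind_report(lapply(svds, `[[`, "winner"), fx$key)))
  }

  report <- structure(list(
    version = as.character(packageVersion("ramanoid")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    n_simulated = n_spectra(dataset$matrix),
    rejections = prep$report,
    n_kept = n_spectra(clean),
    group_stats = stats,
    svd_separations = seps,
    rsvm = accs,
    blinded = blinded), class = "run_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_spectra_table(clean, file.path(out_dir, "clean.tsv"))
    write.table(table, file.path(out_dir, "peak_table.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report_to_list(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# flatten a run_report into plain lists for JSON serialization
report_to_list <- function(report) {
  list(
    version = report$version,
    timestamp = report$timestamp,
    seed = report$config$seed,
    mode = report$config$mode,
    n_simulated = report$n_simulated,
    n_kept = report$n_kept,
    rejections = as.list(report$rejections$counts),
    anova = report$group_stats$anova,
    dunnett = report$group_stats$dunnett,
    svd_separations = lapply(report$svd_separations, function(s)
      as.data.frame.matrix(s$percentages)),
    rsvm = lapply(report$rsvm, function(a)
      list(mean = a$mean, sd = a$sd, n_reps = a$n_reps)),
    blinded = if (!is.null(report$blinded)) list(
      peak_vote = report$blinded$unblinding$peak_vote,
      svd = report$blinded$unblinding$svd))
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> ramanoid %s, %d spectra simulated, %d kept\n",
              x$version, x$n_simulated, x$n_kept))
  cat("RSVM mean accuracies:\n")
  for (nm in names(x$rsvm))
    cat(sprintf("  %-20s %.3f (sd %.3f)\n", nm, x$rsvm[[nm]]$mean, x$rsvm[[nm]]$sd))
  if (!is.null(x$blinded)) {
    cat("blinded unblinding (peak vote / svd):\n")
    print(x$blinded$unblinding$peak_vote, row.names = FALSE)
    print(x$blinded$unblinding$svd, row.names = FALSE)
  }
  invisible(x)
}

#' Scatter plot of an SVD separation with the bisector boundary
#'
#' @param x An `svd_separation`.
#' @param scores The score matrix the separation was computed from.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.svd_separation <- function(x, scores = NULL, ...) {
  if (is.null(scores)) stop("pass the score matrix used for the separation",
                            call. = FALSE)
  cols <- c("grey40", "forestgreen")[match(x$labels, x$groups)]
  graphics::plot(scores[, 1], scores[, 2], col = cols, pch = 19,
                 xlab = colnames(scores)[1], ylab = colnames(scores)[2], ...)
  mid <- (x$mean_a + x$mean_b) / 2
  dir <- x$mean_b - x$mean_a
  graphics::abline(a = mid[2] + mid[1] * dir[1] / dir[2],
                   b = -dir[1] / dir[2], lty = 2)
  graphics::points(rbind(x$mean_a, x$mean_b), pch = 4, cex = 2, lwd = 2)
  invisible(x)
}
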