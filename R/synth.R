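# Synthetic Raman spectrum generator. Emulates the study conditions the
# analysis assumes: class-specific Lorentzian band intensities over a shared
# peak library, a smooth fluorescence background, additive Gaussian noise,
# rare high-amplitude single-point spikes, and Matrigel-contaminated spectra
# (saturating in fixed mode, high-background/low-signal in live mode).

#' Reference library of Raman bands used throughout the package
#'
#' Band centers (cm^-1) covering the quantified peaks: the nine diagnostic
#' panel bands (569, 621, 676, 1124, 1248, 1335, 1446, 1654, 1926), the
#' phenylalanine normalization anchor at 1003 cm^-1, and two additional
#' shared bands (745, 920). Default half-widths are conventional for
#' condensed-phase Raman bands; the default line shape is Lorentzian.
#'
#' @return Data frame with columns `center`, `width` (half-width at
#'   half-maximum, cm^-1) and `shape`.
#' @export
default_peak_library <- function() {
  data.frame(
    center = c(569, 621, 676, 745, 920, 1003, 1124, 1248, 1335, 1446, 1654, 1926),
    width  = c(8,   6,   8,   8,   9,   5,    8,    9,    10,   10,   11,   9),
    shape  = "lorentzian",
    stringsAsFactors = FALSE)
}

#' Diagnostic peak centers used for group statistics and the blinded vote
#' @return Numeric vector of the nine panel wavenumbers (cm^-1).
#' @export
diagnostic_centers <- function() c(569, 621, 676, 1124, 1248, 1335, 1446, 1654, 1926)

peak_shape <- function(x, center, width, shape = "lorentzian") {
  u <- (x - center) / width
  if (shape == "gaussian") exp(-0.5 * u^2) else 1 / (1 + u^2)
}

#' Class amplitude profiles for the three treatment groups
#'
#' Builds control/EGF/FGF2 amplitude profiles over the shared peak library.
#' All classes share the phenylalanine anchor amplitude (so reference
#' normalization is meaningful) and the two non-diagnostic bands; the nine
#' diagnostic bands are modulated class-specifically. Roles rotate in triples
#' of (high, mid, low) = (1, 0.5, 0) across the panel so that every pair of
#' classes differs at every diagnostic band, with the maximum per-pair
#' relative amplitude difference equal to `effect_size` by construction.
#'
#' @param effect_size Relative amplitude separation (>= 0); 0 gives three
#'   identical profiles (the null).
#' @param amplitude_cv Coefficient of variation of the per-spectrum,
#'   per-band amplitude jitter.
#' @param base_amplitude Diagnostic-band base amplitude (arbitrary units,
#'   relative to the anchor amplitude of 1).
#' @param library Peak library, see [default_peak_library()].
#' @return Named list of three `class_profile` objects (control, EGF, FGF2),
#'   each a list with `label`, `amplitudes` (named by center) and
#'   `amplitude_cv`.
#' @export
make_class_profiles <- function(effect_size = 0.5, amplitude_cv = 0.1,
                                base_amplitude = 0.4,
                                library = default_peak_library()) {
  if (!is.numeric(effect_size) || length(effect_size) != 1 || effect_size < 0)
    stop("effect_size must be a single non-negative number", call. = FALSE)
  if (amplitude_cv < 0) stop("amplitude_cv must be >= 0", call. = FALSE)
  diag <- diagnostic_centers()
  # role pattern (rows = panel bands, cols = control, EGF, FGF2)
  pattern <- rbind(
    matrix(rep(c(1, 0.5, 0), each = 3), nrow = 3, byrow = FALSE),
    matrix(rep(c(0, 1, 0.5), each = 3), nrow = 3, byrow = FALSE),
    matrix(rep(c(0.5, 0, 1), each = 3), nrow = 3, byrow = FALSE))
  colnames(pattern) <- TREATMENTS
  amp0 <- setNames(rep(0.3, nrow(library)), as.character(library$center))
  amp0["1003"] <- 1
  profiles <- lapply(TREATMENTS, function(cl) {
    a <- amp0
    a[as.character(diag)] <- base_amplitude * (1 + effect_size * pattern[, cl])
    structure(list(label = cl, amplitudes = a, amplitude_cv = amplitude_cv),
              class = "class_profile")
  })
  names(profiles) <- TREATMENTS
  profiles
}

default_baseline_coeffs <- function(mode) {
  # Polynomial in t = (w - min) / span, coefficients in increasing power.
  # Live-mode background is steeper and higher (stronger fluorescence).
  if (mode == "fixed") c(0.5, -0.2, 0.15)
  else c(1.5, -1.2, 0.8, -0.3, 0.25, 0.15)
}

polyval_t <- function(coeffs, t) {
  acc <- rep(0, length(t))
  for (k in rev(seq_along(coeffs))) acc <- acc * t + coeffs[k]
  acc
}

baseline_curve <- function(wavenumber, coeffs) {
  t <- (wavenumber - min(wavenumber)) / diff(range(wavenumber))
  polyval_t(coeffs, t)
}

#' Simulation configuration
#'
#' @param mode Acquisition mode; sets the default grid and background shape.
#' @param grid Wavenumber grid.
#' @param n_per_class Clean spectra per treatment class (default 50,
#'   within the 40--60 spectra per treatment collected per experiment).
#' @param baseline_coeffs Fluorescence background polynomial coefficients
#'   (increasing power, argument scaled to [0, 1] across the grid).
#' @param baseline_jitter Half-range of the per-spectrum multiplicative
#'   background scale (uniform in `1 +- baseline_jitter`).
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param spike_rate Expected spikes per spectrum (Poisson).
#' @param spike_factor Spike amplitude as a multiple of the spectrum mean.
#' @param matrigel_fraction Expected fraction of Matrigel-contaminated extra
#'   spectra per class (binomial draw).
#' @param saturation_level Detector ceiling; intensities are clipped here and
#'   fixed-mode contaminated spectra saturate at it.
#' @param seed Integer seed; fully determines [simulate_dataset()] output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(mode = c("fixed", "live"), grid = NULL,
                       n_per_class = 50,
                       baseline_coeffs = NULL, baseline_jitter = 0.2,
                       noise_sd = 0.02, spike_rate = 0.05, spike_factor = 8,
                       matrigel_fraction = 0, saturation_level = 10,
                       seed = NULL) {
  mode <- match.arg(mode)
  grid <- grid %||% default_grid(mode)
  validate_grid(grid)
  baseline_coeffs <- baseline_coeffs %||% default_baseline_coeffs(mode)
  stopifnot(n_per_class >= 1, noise_sd >= 0, spike_rate >= 0,
            spike_factor >= 0, saturation_level > 0)
  if (matrigel_fraction < 0 || matrigel_fraction > 1)
    stop("matrigel_fraction must be in [0, 1]", call. = FALSE)
  structure(list(mode = mode, grid = grid, n_per_class = n_per_class,
                 baseline_coeffs = baseline_coeffs,
                 baseline_jitter = baseline_jitter,
                 noise_sd = noise_sd, spike_rate = spike_rate,
                 spike_factor = spike_factor,
                 matrigel_fraction = matrigel_fraction,
                 saturation_level = saturation_level, seed = seed),
            class = "sim_config")
}

#' Analytic (noiseless, baseline-free) spectrum of a class profile
#'
#' The deterministic forward model: the sum of the library band shapes at the
#' profile amplitudes. Used as the oracle for generator and pipeline tests.
#'
#' @param profile A `class_profile`.
#' @param grid Wavenumber grid.
#' @param library Peak library.
#' @return Numeric intensity vector on `grid`.
#' @export
analytic_spectrum <- function(profile, grid = default_grid("fixed"),
                              library = default_peak_library()) {
  y <- rep(0, length(grid))
  for (k in seq_len(nrow(library))) {
    a <- profile$amplitudes[as.character(library$center[k])]
    y <- y + a * peak_shape(grid, library$center[k], library$width[k],
                            library$shape[k])
  }
  unname(y)
}

#' Simulate one Raman spectrum
#'
#' Intensity = class band sum (with per-band amplitude jitter) + fluorescence
#' background + additive Gaussian noise; then with Poisson(`spike_rate`)
#' count, isolated points are set to `spike_factor` times the pre-spike
#' spectrum mean; finally values are clipped to `[0, saturation_level]`.
#'
#' @param profile A `class_profile`.
#' @param config A [sim_config()].
#' @param spectrum_id,organoid_id Identifiers for the metadata.
#' @param seed Optional seed for a reproducible single draw.
#' @param library Peak library.
#' @return A `raman_spectrum`; injected spike indices are recorded in
#'   `attr(, "spikes")`.
#' @export
simulate_spectrum <- function(profile, config, spectrum_id = "s1",
                              organoid_id = NA_character_, seed = NULL,
                              library = default_peak_library()) {
  if (!is.null(seed)) set.seed(seed)
  grid <- config$grid
  y <- rep(0, length(grid))
  cv <- profile$amplitude_cv
  for (k in seq_len(nrow(library))) {
    a <- profile$amplitudes[as.character(library$center[k])]
    if (cv > 0) a <- a * max(0, 1 + cv * rnorm(1))
    y <- y + a * peak_shape(grid, library$center[k], library$width[k],
                            library$shape[k])
  }
  bscale <- if (config$baseline_jitter > 0)
    1 + runif(1, -config$baseline_jitter, config$baseline_jitter) else 1
  y <- y + bscale * baseline_curve(grid, config$baseline_coeffs)
  if (config$noise_sd > 0) y <- y + rnorm(length(grid), 0, config$noise_sd)
  spikes <- integer(0)
  n_sp <- if (config$spike_rate > 0) rpois(1, config$spike_rate) else 0L
  if (n_sp > 0) {
    spikes <- sort(sample.int(length(grid), min(n_sp, length(grid))))
    y[spikes] <- config$spike_factor * mean(y)
  }
  y <- pmin(pmax(y, 0), config$saturation_level)
  out <- raman_spectrum(grid, y, spectrum_id = spectrum_id,
                        treatment = profile$label, organoid_id = organoid_id,
                        mode = config$mode)
  attr(out, "spikes") <- spikes
  out
}

simulate_matrigel_spectrum <- function(profile, config, spectrum_id,
                                       organoid_id = NA_character_,
                                       library = default_peak_library()) {
  grid <- config$grid
  # weak cellular residual over a strongly elevated background
  y <- 0.2 * analytic_spectrum(profile, grid, library)
  y <- y + 5 * baseline_curve(grid, config$baseline_coeffs) *
    (1 + runif(1, -0.1, 0.1))
  if (config$noise_sd > 0) y <- y + rnorm(length(grid), 0, config$noise_sd)
  if (config$mode == "fixed") {
    # detector saturation over a short run of points
    start <- sample.int(length(grid) - 4L, 1)
    y[start:(start + sample(2:4, 1))] <- config$saturation_level
  }
  y <- pmin(pmax(y, 0), config$saturation_level)
  raman_spectrum(grid, y, spectrum_id = spectrum_id,
                 treatment = profile$label, organoid_id = organoid_id,
                 mode = config$mode)
}

#' Simulate a labeled multi-class dataset
#'
#' Generates `n_per_class` clean spectra per class plus, when
#' `matrigel_fraction > 0`, a binomial number of Matrigel-contaminated extra
#' spectra per class. Group blocks are contiguous in the order control, EGF,
#' FGF2; contaminated spectra sit at the end of their class block and are
#' flagged in the ground truth (not in the working metadata, whose rejection
#' flags belong to preprocessing).
#'
#' @param profiles Named list of three class profiles, see
#'   [make_class_profiles()].
#' @param config A [sim_config()]; `config$seed` fully determines the output.
#' @param library Peak library.
#' @return A `labeled_dataset`: list with `matrix` (a [spectra_matrix()]),
#'   `truth` (data frame: `spectrum_id`, `label`, `contaminated`), `spikes`
#'   (named list of injected spike indices) and `config`.
#' @export
simulate_dataset <- function(profiles, config,
                             library = default_peak_library()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  cols <- list(); meta <- list(); truth <- list(); spikes <- list()
  for (cl in names(profiles)) {
    n_cont <- if (config$matrigel_fraction > 0)
      rbinom(1, config$n_per_class, config$matrigel_fraction) else 0L
    orgs <- rep(sprintf("%s_org%d", cl, 1:3),
                length.out = config$n_per_class + n_cont)
    for (i in seq_len(config$n_per_class)) {
      id <- sprintf("%s_%03d", cl, i)
      sp <- simulate_spectrum(profiles[[cl]], config, spectrum_id = id,
                              organoid_id = orgs[i], library = library)
      cols[[id]] <- sp$intensity
      meta[[id]] <- data.frame(spectrum_id = id, treatment = cl,
                               organoid_id = orgs[i], mode = config$mode,
                               stringsAsFactors = FALSE)
      truth[[id]] <- data.frame(spectrum_id = id, label = cl,
                                contaminated = FALSE, stringsAsFactors = FALSE)
      spikes[[id]] <- attr(sp, "spikes")
    }
    for (i in seq_len(n_cont)) {
      id <- sprintf("%s_mg%03d", cl, i)
      sp <- simulate_matrigel_spectrum(profiles[[cl]], config, id,
                                       orgs[config$n_per_class + i], library)
      cols[[id]] <- sp$intensity
      meta[[id]] <- data.frame(spectrum_id = id, treatment = cl,
                               organoid_id = orgs[config$n_per_class + i],
                               mode = config$mode, stringsAsFactors = FALSE)
      truth[[id]] <- data.frame(spectrum_id = id, label = cl,
                                contaminated = TRUE, stringsAsFactors = FALSE)
      spikes[[id]] <- integer(0)
    }
  }
  mat <- spectra_matrix(config$grid, do.call(cbind, cols),
                        do.call(rbind, meta))
  structure(list(matrix = mat,
                 truth = do.call(rbind, truth),
                 spikes = spikes,
                 config = config),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d spectra (%d contaminated), mode %s\n",
              nrow(x$truth), sum(x$truth$contaminated), x$config$mode))
  invisible(x)
}
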