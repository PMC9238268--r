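# Data model for point spectra and stacked spectra matrices, plus the
# TSV/CSV readers and writers every other stage consumes.

#' Default wavenumber grid for an acquisition mode
#'
#' Fixed-mode acquisitions span 500--2000 cm^-1 on a 750-point grid
#' (~2 cm^-1 spacing); live-mode acquisitions span 600--2000 cm^-1 on a
#' 700-point grid. Real grids read from disk are taken as given and are not
#' assumed uniform.
#'
#' @param mode `"fixed"` or `"live"`.
#' @return Numeric vector of wavenumbers (cm^-1), strictly increasing.
#' @export
default_grid <- function(mode = c("fixed", "live")) {
  mode <- match.arg(mode)
  if (mode == "fixed") seq(500, 2000, length.out = 750)
  else seq(600, 2000, length.out = 700)
}

validate_grid <- function(wavenumber) {
  if (!is.numeric(wavenumber) || length(wavenumber) < 2)
    stop("wavenumber grid must be numeric with at least 2 points", call. = FALSE)
  if (anyNA(wavenumber) || any(!is.finite(wavenumber)))
    stop("wavenumber grid contains missing or non-finite values", call. = FALSE)
  if (any(diff(wavenumber) <= 0))
    stop("wavenumber grid must be strictly increasing", call. = FALSE)
  invisible(wavenumber)
}

#' Construct a single Raman spectrum
#'
#' @param wavenumber Strictly increasing numeric grid (cm^-1).
#' @param intensity Numeric intensities, same length as `wavenumber`.
#' @param spectrum_id Unique identifier.
#' @param treatment Treatment label (`"control"`, `"EGF"`, `"FGF2"` or
#'   `"unknown"`).
#' @param organoid_id Organoid of origin (free text).
#' @param mode Acquisition mode, `"fixed"` or `"live"`.
#' @param rejected Logical rejection flag; rejected spectra carry a `reason`.
#' @param reason Rejection reason (empty string when kept).
#' @return An object of class `raman_spectrum`: a list with elements
#'   `wavenumber`, `intensity` and `meta`.
#' @export
raman_spectrum <- function(wavenumber, intensity, spectrum_id = "s1",
                           treatment = "unknown", organoid_id = NA_character_,
                           mode = "fixed", rejected = FALSE, reason = "") {
  validate_grid(wavenumber)
  if (length(intensity) != length(wavenumber))
    stop("intensity and wavenumber lengths differ", call. = FALSE)
  if (anyNA(intensity)) stop("intensity contains missing values", call. = FALSE)
  if (isTRUE(rejected) && !nzchar(reason))
    stop("rejected spectra must carry a non-empty reason", call. = FALSE)
  structure(
    list(wavenumber = as.numeric(wavenumber),
         intensity = as.numeric(intensity),
         meta = list(spectrum_id = spectrum_id, treatment = treatment,
                     organoid_id = organoid_id, mode = mode,
                     rejected = rejected, reason = reason)),
    class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %s [%s, %s] %d points, %.1f-%.1f cm^-1\n",
              x$meta$spectrum_id, x$meta$treatment, x$meta$mode,
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

default_meta <- function(spectrum_id, treatment = "unknown", mode = "fixed") {
  data.frame(spectrum_id = spectrum_id,
             treatment = treatment,
             organoid_id = NA_character_,
             mode = mode,
             x = NA_real_, y = NA_real_, z = NA_real_,
             rejected = FALSE, reason = "",
             stringsAsFactors = FALSE)
}

#' Construct a stacked spectra matrix
#'
#' The container mirrors the analysis convention of stacking spectra as an
#' n x m matrix: n spectral points as rows, one column per spectrum, with
#' treatment group blocks kept contiguous in the supplied column order.
#'
#' @param wavenumber Shared grid (rows), strictly increasing.
#' @param intensities Numeric n x m matrix of intensities.
#' @param meta Data frame with one row per column; must contain
#'   `spectrum_id` and `treatment`. Missing bookkeeping columns
#'   (`organoid_id`, `mode`, `x`, `y`, `z`, `rejected`, `reason`) are filled
#'   with defaults.
#' @return An object of class `spectra_matrix`.
#' @export
spectra_matrix <- function(wavenumber, intensities, meta = NULL) {
  validate_grid(wavenumber)
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != length(wavenumber))
    stop("intensities must have one row per wavenumber", call. = FALSE)
  if (anyNA(intensities))
    stop("intensities contain missing values", call. = FALSE)
  m <- ncol(intensities)
  if (is.null(meta)) {
    ids <- colnames(intensities) %||% sprintf("s%03d", seq_len(m))
    meta <- default_meta(ids)
  }
  if (!all(c("spectrum_id", "treatment") %in% names(meta)))
    stop("meta must contain spectrum_id and treatment", call. = FALSE)
  if (nrow(meta) != m)
    stop("meta must have one row per spectrum column", call. = FALSE)
  if (anyDuplicated(meta$spectrum_id))
    stop("duplicate spectrum ids: ",
         paste(unique(meta$spectrum_id[duplicated(meta$spectrum_id)]),
               collapse = ", "), call. = FALSE)
  if (!"rejected" %in% names(meta)) meta$rejected <- FALSE
  if (!"reason" %in% names(meta)) meta$reason <- ""
  if (!"organoid_id" %in% names(meta)) meta$organoid_id <- NA_character_
  if (!"mode" %in% names(meta)) meta$mode <- "fixed"
  for (col in c("x", "y", "z")) if (!col %in% names(meta)) meta[[col]] <- NA_real_
  meta$reason[is.na(meta$reason)] <- ""
  colnames(intensities) <- meta$spectrum_id
  rownames(meta) <- NULL
  structure(list(wavenumber = as.numeric(wavenumber),
                 intensities = intensities,
                 meta = meta),
            class = "spectra_matrix")
}

#' @export
print.spectra_matrix <- function(x, ...) {
  tab <- table(x$meta$treatment)
  cat(sprintf("<spectra_matrix> %d points x %d spectra (%s), %.1f-%.1f cm^-1\n",
              nrow(x$intensities), ncol(x$intensities),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              min(x$wavenumber), max(x$wavenumber)))
  if (any(x$meta$rejected))
    cat(sprintf("  %d rejected\n", sum(x$meta$rejected)))
  invisible(x)
}

#' Number of spectra in a spectra matrix
#' @param x A `spectra_matrix`.
#' @return Integer count of spectrum columns.
#' @export
n_spectra <- function(x) ncol(x$intensities)

#' Treatment labels of a spectra matrix
#' @param x A `spectra_matrix`.
#' @return Character vector of per-column treatment labels.
#' @export
treatments <- function(x) x$meta$treatment

#' Subset the columns (spectra) of a spectra matrix
#' @param x A `spectra_matrix`.
#' @param j Column index (integer, logical, or spectrum id).
#' @param ... Unused.
#' @return A `spectra_matrix` with the selected columns, order preserved.
#' @export
`[.spectra_matrix` <- function(x, j, ...) {
  if (is.character(j)) j <- match(j, x$meta$spectrum_id)
  spectra_matrix(x$wavenumber, x$intensities[, j, drop = FALSE],
                 x$meta[j, , drop = FALSE])
}

#' Extract one spectrum from a spectra matrix
#' @param x A `spectra_matrix`.
#' @param j Column index or spectrum id.
#' @return A `raman_spectrum`.
#' @export
spectrum_at <- function(x, j) {
  if (is.character(j)) j <- match(j, x$meta$spectrum_id)
  m <- x$meta[j, ]
  raman_spectrum(x$wavenumber, x$intensities[, j],
                 spectrum_id = m$spectrum_id, treatment = m$treatment,
                 organoid_id = m$organoid_id, mode = m$mode,
                 rejected = m$rejected, reason = m$reason)
}

sep_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a spectra matrix from a wide TSV/CSV table
#'
#' The on-disk contract is a wavenumber-indexed wide table: first column the
#' wavenumber in cm^-1, one named column per spectrum. Rows are sorted
#' ascending by wavenumber on read. An optional metadata table (TSV/CSV with
#' columns `spectrum_id`, `treatment`, and optionally `organoid_id`, `mode`,
#' `x`, `y`, `z`, `rejected`, `reason`) is keyed on spectrum id; without it
#' every label defaults to `"unknown"`.
#'
#' @param path Path to the spectra table.
#' @param meta_path Optional path to the metadata table.
#' @return A [spectra_matrix()].
#' @export
read_spectra_table <- function(path, meta_path = NULL) {
  df <- read.table(path, header = TRUE, sep = sep_for(path),
                   check.names = FALSE, colClasses = "character",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("spectra table needs a wavenumber column plus at least one spectrum", call. = FALSE)
  ids <- names(df)[-1]
  if (anyDuplicated(ids))
    stop("duplicate spectrum ids in header: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  num <- vapply(seq_along(df), function(k) {
    v <- suppressWarnings(as.numeric(df[[k]]))
    bad <- which(is.na(v) & !is.na(df[[k]]) & nzchar(df[[k]])) # locate parse failures
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at data row %d, column '%s'",
                   df[[k]][bad[1]], bad[1], names(df)[k]), call. = FALSE)
    if (anyNA(v))
      stop(sprintf("missing value at data row %d, column '%s'",
                   which(is.na(v))[1], names(df)[k]), call. = FALSE)
    v
  }, numeric(nrow(df)))
  num <- matrix(num, nrow = nrow(df))
  w <- num[, 1]
  if (anyDuplicated(w)) stop("duplicate wavenumbers in table", call. = FALSE)
  ord <- order(w)
  mat <- num[ord, -1, drop = FALSE]
  colnames(mat) <- ids
  meta <- default_meta(ids)
  if (!is.null(meta_path)) {
    md <- read.table(meta_path, header = TRUE, sep = sep_for(meta_path),
                     check.names = FALSE, stringsAsFactors = FALSE)
    if (!all(c("spectrum_id", "treatment") %in% names(md)))
      stop("metadata table must contain spectrum_id and treatment", call. = FALSE)
    idx <- match(ids, md$spectrum_id)
    if (anyNA(idx))
      stop("metadata missing spectrum ids: ",
           paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
    md <- md[idx, , drop = FALSE]
    for (col in intersect(names(md), names(meta))) meta[[col]] <- md[[col]]
    meta$rejected <- as.logical(meta$rejected)
    meta$reason[is.na(meta$reason)] <- ""
  }
  spectra_matrix(w[ord], mat, meta)
}

#' Write a spectra matrix to a wide TSV/CSV table
#'
#' Writes intensities at full (17 significant digit) precision so that a
#' read/write round trip is lossless, plus a companion metadata table
#' carrying labels, acquisition mode and rejection flags.
#'
#' @param x A `spectra_matrix`.
#' @param path Output path for the spectra table (`.tsv` or `.csv`).
#' @param meta_path Output path for the metadata table; defaults to
#'   `<path without extension>_meta.tsv`.
#' @return Invisibly, `path`.
#' @export
write_spectra_table <- function(x, path,
                                meta_path = paste0(sub("\\.[^.]+$", "", path),
                                                   "_meta.tsv")) {
  sep <- sep_for(path)
  chr <- cbind(formatC(x$wavenumber, digits = 17, format = "g", width = 1),
               apply(x$intensities, 2, formatC,
                     digits = 17, format = "g", width = 1))
  colnames(chr) <- c("wavenumber", colnames(x$intensities))
  ok <- tryCatch({
    write.table(chr, path, sep = sep, quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write '", path, "': ",
                              conditionMessage(e), call. = FALSE))
  write.table(x$meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Resample a spectrum onto a target wavenumber grid
#'
#' Linear interpolation at the target wavenumbers; used to stack fixed-mode
#' (500--2000 cm^-1) and live-mode (600--2000 cm^-1) acquisitions onto a
#' common grid. Extrapolation is refused.
#'
#' @param spectrum A `raman_spectrum`.
#' @param target Target grid, must lie within the source range.
#' @return A `raman_spectrum` on `target`, metadata carried over.
#' @export
resample_to_grid <- function(spectrum, target) {
  validate_grid(target)
  w <- spectrum$wavenumber
  if (min(target) < min(w) || max(target) > max(w))
    stop("target grid extends beyond source range; no extrapolation", call. = FALSE)
  yi <- approx(w, spectrum$intensity, xout = target, method = "linear")$y
  out <- spectrum
  out$wavenumber <- as.numeric(target)
  out$intensity <- yi
  out
}
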