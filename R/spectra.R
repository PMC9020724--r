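#' Wavelength grid for reflectance spectra
#'
#' The handheld spectroreflectometer samples reflectance on a regular
#' wavelength grid, by default 380--790 nm in 2 nm steps (206 channels).
#' A `wavelength_grid` records that grid and is attached to every
#' [spectrum_set()] so all records are guaranteed to share it.
#'
#' @param start,stop First and last wavelength in nm.
#' @param step Grid spacing in nm; `(stop - start)` must be divisible by it.
#' @return An object of class `wavelength_grid` with elements `start`, `stop`,
#'   `step` and the derived `wavelengths` vector.
#' @examples
#' g <- wavelength_grid()
#' length(g$wavelengths) # 206
#' @export
wavelength_grid <- function(start = 380, stop = 790, step = 2) {
  if (step <= 0) stop_spec("grid step must be > 0")
  if (stop <= start) stop_spec("grid stop must exceed start")
  if (abs((stop - start) %% step) > 1e-9) {
    stop_spec("(stop - start) must be divisible by step")
  }
  structure(
    list(start = start, stop = stop, step = step,
         wavelengths = seq(start, stop, by = step)),
    class = "wavelength_grid"
  )
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %g-%g nm by %g nm (%d channels)\n",
              x$start, x$stop, x$step, length(x$wavelengths)))
  invisible(x)
}

grid_equal <- function(a, b) {
  isTRUE(all.equal(a$wavelengths, b$wavelengths, tolerance = 1e-9))
}

#' Container for a set of reflectance spectra
#'
#' Couples a sample metadata table with a reflectance matrix whose columns are
#' aligned to a [wavelength_grid()]. Reflectance is stored as a fraction of
#' incident light in \[0, 1\]; percent-scale input (any value > 1.5) is
#' detected and divided by 100 with a warning.
#'
#' @param meta A data.frame with columns `sample_id`, `accession_id`,
#'   `treatment` (one of `"P100"`, `"P5"`, `"P0.25"`), `block`, `replicate`.
#' @param reflectance Numeric matrix, one row per row of `meta`, one column
#'   per grid wavelength.
#' @param grid A [wavelength_grid()].
#' @return An object of class `spectrum_set` with elements `grid`, `meta`,
#'   `reflectance`.
#' @export
spectrum_set <- function(meta, reflectance, grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  reflectance <- as.matrix(reflectance)
  storage.mode(reflectance) <- "double"
  if (nrow(meta) != nrow(reflectance)) {
    stop_spec("meta and reflectance row counts differ (",
              nrow(meta), " vs ", nrow(reflectance), ")")
  }
  if (ncol(reflectance) != length(grid$wavelengths)) {
    stop_spec("reflectance has ", ncol(reflectance),
              " channels but the grid declares ", length(grid$wavelengths))
  }
  need <- c("sample_id", "accession_id", "treatment", "block", "replicate")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0) {
    stop_spec("meta is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyNA(reflectance)) stop_spec("reflectance contains missing values")
  if (max(reflectance) > 1.5) {
    warning("reflectance values > 1.5 detected; assuming percent scale, dividing by 100",
            call. = FALSE)
    reflectance <- reflectance / 100
  }
  if (min(reflectance) < 0) stop_spec("negative reflectance values present")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  meta$treatment <- as_treatment(meta$treatment)
  rownames(reflectance) <- NULL
  colnames(reflectance) <- paste0("R", grid$wavelengths)
  structure(list(grid = grid, meta = meta, reflectance = reflectance),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra, %d channels (%g-%g nm)\n",
              nrow(x$meta), length(x$grid$wavelengths), x$grid$start, x$grid$stop))
  tab <- table(x$meta$treatment)
  cat("  treatments:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.spectrum_set <- function(x) dim(x$reflectance)

subset_spectra <- function(set, idx) {
  spectrum_set(set$meta[idx, , drop = FALSE],
               set$reflectance[idx, , drop = FALSE], set$grid)
}

#' Read reflectance spectra from a wide CSV export
#'
#' Expects the device-export layout: metadata columns (`sample_id`,
#' `accession_id`, `treatment`, `block`, `replicate`) followed by one column
#' per wavelength named `R<nm>` (e.g. `R420`). The header wavelengths must
#' match `grid` exactly.
#'
#' @param path CSV file path.
#' @param grid Expected [wavelength_grid()]; default 380--790 nm by 2 nm.
#' @return A [spectrum_set()]; row order of the file is preserved.
#' @export
read_spectra <- function(path, grid = wavelength_grid()) {
  if (!file.exists(path)) stop_spec("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop_spec("no records in ", path)
  is_wl <- grepl("^R[0-9]+$", names(df))
  wl <- as.numeric(sub("^R", "", names(df)[is_wl]))
  if (length(wl) == 0) stop_spec("no wavelength columns (R<nm>) in header of ", path)
  if (length(wl) != length(grid$wavelengths) ||
      any(abs(wl - grid$wavelengths) > 1e-9)) {
    stop_spec(sprintf(
      "wavelength grid mismatch in %s: file has %d channels (%g-%g), expected %d (%g-%g by %g)",
      path, length(wl), min(wl), max(wl),
      length(grid$wavelengths), grid$start, grid$stop, grid$step))
  }
  refl <- as.matrix(df[, is_wl, drop = FALSE])
  if (!is.numeric(refl)) {
    bad <- which(!vapply(df[, is_wl, drop = FALSE], is.numeric, logical(1)))[1]
    stop_spec("non-numeric reflectance in column ", names(df)[is_wl][bad])
  }
  meta <- df[, !is_wl, drop = FALSE]
  key <- paste(meta$sample_id, meta$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop_spec("duplicate sample_id+replicate at row ",
              which(duplicated(key))[1])
  }
  spectrum_set(meta, refl, grid)
}

#' Write a spectrum set to a wide CSV
#' @param set A [spectrum_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(set, path) {
  df <- cbind(set$meta, as.data.frame(set$reflectance, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Average technical replicates channel by channel
#'
#' The two scans taken from each leaf are technical replicates; they are
#' collapsed to one spectrum per `sample_id` by the channelwise arithmetic
#' mean. Metadata is taken from the first replicate; the replicate index is
#' set to 1. Idempotent, and a single replicate passes through unchanged.
#'
#' @param set A [spectrum_set()].
#' @return A [spectrum_set()] with one record per `sample_id`, in first-seen
#'   order.
#' @export
average_replicates <- function(set) {
  ids <- set$meta$sample_id
  first <- !duplicated(ids)
  ord_ids <- ids[first]
  f <- factor(ids, levels = ord_ids)
  refl <- rowsum(set$reflectance, f) / as.vector(table(f))
  meta <- set$meta[first, , drop = FALSE]
  meta$replicate <- 1L
  spectrum_set(meta, refl[as.character(ord_ids), , drop = FALSE], set$grid)
}

#' Restrict spectra to a clean wavelength range
#'
#' The short-wavelength end of the scan (380--410 nm) is dominated by device
#' noise — adjacent channels there barely correlate — and is excluded before
#' any analysis. The default keep-range 420--790 nm at 2 nm leaves 186
#' channels.
#'
#' @param set A [spectrum_set()].
#' @param keep_start,keep_stop Retained range in nm (inclusive).
#' @return A [spectrum_set()] on the truncated grid.
#' @export
exclude_noisy_band <- function(set, keep_start = 420, keep_stop = 790) {
  wl <- set$grid$wavelengths
  keep <- wl >= keep_start & wl <= keep_stop
  if (!any(keep)) stop_spec("keep range is empty on this grid")
  new_grid <- wavelength_grid(min(wl[keep]), max(wl[keep]), set$grid$step)
  spectrum_set(set$meta, set$reflectance[, keep, drop = FALSE], new_grid)
}

#' Standardize spectra to zero mean and unit variance per wavelength
#'
#' Channel means and standard deviations are computed on `train` only and
#' applied to both `train` and `newdata`, so that validation/test spectra are
#' transformed with training statistics and no information leaks across the
#' split.
#'
#' @param train A [spectrum_set()] used to estimate channel statistics.
#' @param newdata Optional [spectrum_set()] to transform with the training
#'   statistics; defaults to `train`.
#' @return A list with `set` (standardized `newdata`), `center` and `scale`
#'   (named per-channel vectors). Standardized values are plain numbers, not
#'   reflectance; the returned set bypasses the \[0,1\] range check.
#' @export
standardize_spectra <- function(train, newdata = NULL) {
  if (nrow(train$meta) < 2) {
    stop_spec("need at least 2 training spectra to estimate channel variances")
  }
  newdata <- newdata %||% train
  if (!grid_equal(train$grid, newdata$grid)) {
    stop_spec("train and newdata are on different wavelength grids")
  }
  center <- colMeans(train$reflectance)
  scale <- apply(train$reflectance, 2, stats::sd)
  if (any(scale < 1e-12)) {
    stop_spec("zero-variance channel at ",
              colnames(train$reflectance)[which(scale < 1e-12)[1]])
  }
  z <- sweep(sweep(newdata$reflectance, 2, center, "-"), 2, scale, "/")
  out <- newdata
  out$reflectance <- z
  out$standardized <- TRUE
  list(set = out, center = center, scale = scale)
}

#' Wavelength-by-wavelength correlation within spectra
#'
#' Correlates reflectance at every pair of wavelengths across the records of
#' `set`. On leaf spectra this shows two internally coherent blocks — the
#' visible region (~420--720 nm) and the NIR region (~730--790 nm) — that are
#' only weakly correlated with each other, which motivates summarising a
#' spectrum by one NIR/VIS ratio.
#'
#' @param set A [spectrum_set()] with at least 3 records.
#' @param method Correlation method, `"spearman"` (default) or `"pearson"`.
#' @return A symmetric channels-by-channels correlation matrix.
#' @export
within_spectrum_correlation <- function(set, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (nrow(set$meta) < 3) stop_spec("need at least 3 spectra")
  stats::cor(set$reflectance, method = method)
}
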