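#' The 7 x 31 grid of NIR/VIS reflectance-ratio keys
#'
#' Reflectance ratios are formed from one NIR band (730, 740, ..., 790 nm)
#' over one visible band (420, 430, ..., 720 nm), at 10 nm intervals:
#' 7 x 31 = 217 ratios in total. Keys are ordered lexicographically by
#' (nir, vis), so the first key is (730, 420).
#'
#' @return data.frame with columns `nir_nm`, `vis_nm` and `key` (label of the
#'   form `"R730/R420"`), 217 rows.
#' @examples
#' nrow(build_ratio_grid()) # 217
#' @export
build_ratio_grid <- function() {
  nir <- seq(730, 790, by = 10)
  vis <- seq(420, 720, by = 10)
  g <- expand.grid(vis_nm = vis, nir_nm = nir, KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$nir_nm, g$vis_nm), c("nir_nm", "vis_nm")]
  rownames(g) <- NULL
  g$key <- sprintf("R%d/R%d", g$nir_nm, g$vis_nm)
  g
}

#' Compute all 217 NIR/VIS reflectance ratios per spectrum
#'
#' Each ratio is the reflectance at the NIR band divided by the reflectance
#' at the VIS band of the (possibly replicate-averaged) spectrum. Ratios are
#' scale-invariant: multiplying a spectrum by a positive constant leaves
#' them unchanged.
#'
#' @param set A [spectrum_set()] whose grid covers 420--790 nm at a spacing
#'   that includes the 10-nm ratio bands.
#' @return data.frame: `sample_id` plus one column per ratio key
#'   (`"R730/R420"`, ...), 217 ratio columns.
#' @export
compute_ratios <- function(set) {
  grid_keys <- build_ratio_grid()
  wl <- set$grid$wavelengths
  bands <- sort(unique(c(grid_keys$nir_nm, grid_keys$vis_nm)))
  idx <- match(bands, wl)
  if (anyNA(idx)) {
    stop_spec("spectrum grid does not contain band(s): ",
              paste(bands[is.na(idx)], collapse = ", "))
  }
  band_refl <- set$reflectance[, idx, drop = FALSE]
  colnames(band_refl) <- paste0("R", bands)
  zero <- which(band_refl == 0, arr.ind = TRUE)
  if (nrow(zero) > 0) {
    stop_spec("zero reflectance in denominator band R",
              bands[zero[1, 2]], " (sample ", set$meta$sample_id[zero[1, 1]], ")")
  }
  num <- band_refl[, paste0("R", grid_keys$nir_nm), drop = FALSE]
  den <- band_refl[, paste0("R", grid_keys$vis_nm), drop = FALSE]
  out <- as.data.frame(num / den, check.names = FALSE)
  names(out) <- grid_keys$key
  cbind(data.frame(sample_id = set$meta$sample_id, stringsAsFactors = FALSE), out)
}

#' Spearman screen of every ratio index against a trait
#'
#' Correlates each of the 217 ratio indices with a trait (leaf Pi content,
#' shoot biomass, PUtE, ...) across samples. In the source design the screen
#' is run on plants pooled from the two deficient treatments (P5 and P0.25),
#' where reflectance actually responds to Pi.
#'
#' @param ratios data.frame from [compute_ratios()] (must contain every key).
#' @param trait Numeric vector, one value per row of `ratios`, paired by
#'   position.
#' @param method `"spearman"` (default; average ranks for ties) or
#'   `"pearson"`.
#' @return data.frame with columns `nir_nm`, `vis_nm`, `key`, `rho`, sorted
#'   as [build_ratio_grid()].
#' @export
correlate_with_trait <- function(ratios, trait, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  keys <- build_ratio_grid()
  miss <- setdiff(keys$key, names(ratios))
  if (length(miss) > 0) {
    stop_spec("ratio table is missing key(s): ", paste(miss[1:min(3, length(miss))],
                                                       collapse = ", "))
  }
  if (length(trait) != nrow(ratios)) {
    stop_spec("trait length (", length(trait), ") does not match ratio rows (",
              nrow(ratios), ")")
  }
  ok <- is.finite(trait)
  if (sum(ok) < 3) stop_spec("need at least 3 paired finite observations")
  m <- as.matrix(ratios[ok, keys$key, drop = FALSE])
  keys$rho <- as.vector(stats::cor(m, trait[ok], method = method))
  keys
}

#' Mean-normalized spectral-ratio (SR) traits for association mapping
#'
#' For each accession, divides the mean of each reflectance ratio under the
#' severe-deficiency treatment by the corresponding mean under the control
#' treatment. A value of 1 means the ratio is unchanged by deficiency. The
#' 217 normalized values per accession are the SR traits used in GWAS.
#'
#' @param means_deficient,means_control data.frames of accession-level ratio
#'   means (as from [accession_ratio_means()]): column `accession_id` plus
#'   the 217 ratio keys. Both must cover the same accessions.
#' @return data.frame: `accession_id` plus 217 normalized trait columns,
#'   accessions in the order of `means_deficient`.
#' @export
normalize_sr_traits <- function(means_deficient, means_control) {
  keys <- build_ratio_grid()$key
  for (d in list(means_deficient, means_control)) {
    miss <- setdiff(keys, names(d))
    if (length(miss) > 0) {
      stop_spec("ratio-mean table is missing key(s): ", miss[1])
    }
  }
  missing_acc <- c(
    setdiff(means_deficient$accession_id, means_control$accession_id),
    setdiff(means_control$accession_id, means_deficient$accession_id)
  )
  if (length(missing_acc) > 0) {
    stop_spec("accessions present on one side only: ",
              paste(unique(missing_acc), collapse = ", "))
  }
  ctrl <- means_control[match(means_deficient$accession_id,
                              means_control$accession_id), , drop = FALSE]
  out <- as.data.frame(as.matrix(means_deficient[, keys, drop = FALSE]) /
                         as.matrix(ctrl[, keys, drop = FALSE]),
                       check.names = FALSE)
  cbind(data.frame(accession_id = means_deficient$accession_id,
                   stringsAsFactors = FALSE), out)
}

#' Accession-level means of the ratio indices for one treatment
#'
#' Averages each ratio over all plants of an accession in the given
#' treatment (pooling blocks), after technical-replicate averaging. This is
#' the mean-of-ratios convention: ratios are computed per plant first, then
#' averaged.
#'
#' @param set A [spectrum_set()] (replicates are averaged internally).
#' @param treatment Treatment label to subset to, or `NULL` for all records.
#' @return data.frame: `accession_id`, `n_plants`, plus the 217 ratio keys.
#' @export
accession_ratio_means <- function(set, treatment = NULL) {
  set <- average_replicates(set)
  if (!is.null(treatment)) {
    keep <- set$meta$treatment == treatment
    if (!any(keep)) stop_spec("no records for treatment ", treatment)
    set <- subset_spectra(set, keep)
  }
  ratios <- compute_ratios(set)
  keys <- build_ratio_grid()$key
  acc <- set$meta$accession_id
  f <- factor(acc, levels = unique(acc))
  m <- rowsum(as.matrix(ratios[, keys, drop = FALSE]), f) /
    as.vector(table(f))
  data.frame(accession_id = levels(f),
             n_plants = as.vector(table(f)),
             m, check.names = FALSE, stringsAsFactors = FALSE)
}
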