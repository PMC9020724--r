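#' Convert leaf Pi from nmol/mm^2 to mg Pi per g dry weight
#'
#' Areal Pi content is converted to a mass concentration by multiplying by
#' the molecular weight of the phosphate ion and dividing by the areal dry
#' mass of the leaf tissue: `mg/g = pi * mw / (1000 * areal_dry_mass)`
#' (1 nmol/mm^2 at 0.05 mg/mm^2 areal dry mass is 1.8994 mg/g).
#'
#' @param pi_content Pi in nmol/mm^2 (vectorized).
#' @param areal_dry_mass Leaf areal dry mass in mg/mm^2 (dry weight of discs
#'   of known area); must be > 0.
#' @param mw Molecular weight of PO4^3-, g/mol.
#' @return Pi concentration in mg per g dry weight.
#' @export
pi_to_mg_per_g <- function(pi_content, areal_dry_mass, mw = 94.97) {
  if (any(!is.finite(areal_dry_mass)) || any(areal_dry_mass <= 0)) {
    stop_spec("areal_dry_mass must be positive")
  }
  pi_content * mw / (1000 * areal_dry_mass)
}

#' Phosphorus utilization efficiency (PUtE)
#'
#' PUtE is shoot biomass divided by the leaf Pi concentration of the same
#' plant: grams of biomass produced per unit tissue Pi (g per mg/g).
#'
#' @param biomass Shoot dry weight in g.
#' @param pi_mg_per_g Leaf Pi concentration in mg/g (see [pi_to_mg_per_g()]);
#'   must be > 0.
#' @return PUtE values.
#' @export
compute_pute <- function(biomass, pi_mg_per_g) {
  if (any(!is.finite(pi_mg_per_g)) || any(pi_mg_per_g <= 0)) {
    stop_spec("PUtE is undefined for non-positive Pi concentration")
  }
  biomass / pi_mg_per_g
}

#' Mean fold decrease between two treatments
#'
#' Pairs values (by accession, by default) and averages the high/low ratio
#' over pairs — e.g. leaf Pi falls ~15.6-fold from P100 to P5 and a further
#' ~3.2-fold from P5 to P0.25 in the source panel. Pairs with a zero
#' denominator are excluded with a message.
#'
#' @param values_high,values_low Named numeric vectors (names are the pairing
#'   key, typically accession IDs), or unnamed vectors of equal length that
#'   are paired by position.
#' @return Mean fold change (scalar).
#' @export
fold_change <- function(values_high, values_low) {
  if (!is.null(names(values_high)) && !is.null(names(values_low))) {
    common <- intersect(names(values_high), names(values_low))
    if (length(common) == 0) stop_spec("no common pairing keys")
    values_high <- values_high[common]
    values_low <- values_low[common]
  } else if (length(values_high) != length(values_low)) {
    stop_spec("unnamed value vectors must have equal length")
  }
  bad <- values_low == 0
  if (any(bad)) {
    message(sum(bad), " pair(s) with zero denominator excluded from fold change")
  }
  mean(values_high[!bad] / values_low[!bad])
}

#' Descriptive statistics by trait and treatment
#'
#' Table-style summary of phenotypic values: mean, SD (n-1 denominator),
#' range, and coefficient of variation (CV% = 100 * SD / mean) per
#' trait-by-treatment cell. By convention the summary is computed over
#' accession means (one value per accession), obtained by averaging plants
#' within accession and treatment first; set `level = "plant"` to summarise
#' raw per-plant values instead.
#'
#' @param phenotypes data.frame with columns `accession_id`, `treatment`,
#'   and the trait columns named in `traits`.
#' @param traits Character vector of trait column names.
#' @param level `"accession"` (default) or `"plant"`.
#' @return data.frame with columns `trait`, `treatment`, `n`, `mean`, `sd`,
#'   `min`, `max`, `cv_pct`. `cv_pct` is `NA` when the mean is 0.
#' @export
descriptive_table <- function(phenotypes, traits,
                              level = c("accession", "plant")) {
  level <- match.arg(level)
  miss <- setdiff(c("accession_id", "treatment", traits), names(phenotypes))
  if (length(miss) > 0) stop_spec("missing column(s): ", paste(miss, collapse = ", "))
  rows <- list()
  for (trait in traits) {
    for (tr in levels(as_treatment(phenotypes$treatment))) {
      sub <- phenotypes[phenotypes$treatment == tr, , drop = FALSE]
      if (nrow(sub) == 0) next
      if (level == "accession") {
        v <- tapply(sub[[trait]], sub$accession_id, mean)
        v <- as.numeric(v[!is.na(v)])
      } else {
        v <- sub[[trait]]
      }
      if (length(v) < 2) stop_spec("need >= 2 values in cell ", trait, " x ", tr)
      m <- mean(v); s <- stats::sd(v)
      rows[[length(rows) + 1L]] <- data.frame(
        trait = trait, treatment = tr, n = length(v),
        mean = m, sd = s, min = min(v), max = max(v),
        cv_pct = if (abs(m) < 1e-300) NA_real_ else 100 * s / abs(m),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Derive full per-plant phenotypes from a panel phenotype table
#'
#' Adds `pi_mg_per_g` and `pute` columns; PUtE at P100 is computed but
#' flagged (`pute_in_mapping = FALSE`) because at over-sufficient supply
#' leaf Pi is dominated by vacuolar storage and is not physiologically
#' related to growth, so that trait is excluded from association mapping.
#'
#' @param phenotypes data.frame with `pi_content`, `biomass`,
#'   `areal_dry_mass`, `treatment`.
#' @return The input with `pi_mg_per_g`, `pute`, `pute_in_mapping` appended.
#' @export
derive_phenotypes <- function(phenotypes) {
  phenotypes$pi_mg_per_g <- pi_to_mg_per_g(phenotypes$pi_content,
                                           phenotypes$areal_dry_mass)
  phenotypes$pute <- compute_pute(phenotypes$biomass, phenotypes$pi_mg_per_g)
  phenotypes$pute_in_mapping <- phenotypes$treatment != "P100"
  phenotypes
}
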