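#' Configuration for the synthetic hydroponic phosphorus panel
#'
#' Describes a rice diversity panel grown under three phosphate supplies
#' (P100 = overly sufficient, P5 = mildly deficient, P0.25 = severely
#' deficient). Defaults reproduce the study design the analyses assume:
#' 172 accessions, 3 plants per accession per treatment per block, 3 blocks
#' (independent experiments), 2 technical scans per leaf, and per-treatment
#' Pi distributions with mean +/- SD of 3.60 +/- 1.74 (P100), 0.22 +/- 0.07
#' (P5) and 0.07 +/- 0.03 (P0.25) nmol/mm^2 across accession means.
#'
#' Pi is generated on a lognormal scale (it is positive and right-skewed,
#' markedly so under P100). The across-accession log-variance for each
#' treatment is split into a shared accession effect (`accession_effect_sd`,
#' on the log scale, carried across treatments so that accessions keep their
#' identity) and an accession-by-treatment residual; individual plants
#' scatter around their accession-by-treatment mean with log-SD
#' `plant_pi_sdlog`, reflecting the substantial within-accession variability
#' seen between individual plants.
#'
#' Spectra are linked to Pi through a per-wavelength exponential decay law
#' `R(lambda) = a(lambda) + b(lambda) * exp(-c * Pi)`: as Pi falls the
#' visible region brightens (`b > 0`, chlorophyll loss) and the NIR region
#' darkens (`b < 0`, thinner leaves). See [default_decay_link()] for how the
#' default coefficients are calibrated.
#'
#' @param n_accessions Number of accessions.
#' @param plants_per_accession_per_treatment Plants per accession, treatment
#'   and block.
#' @param n_blocks Independent experiment blocks.
#' @param n_replicates Technical scans per leaf (averaged downstream).
#' @param treatment_pi_params Named list (`P100`, `P5`, `P0.25`) of
#'   `c(mean, sd)` of Pi in nmol/mm^2 across accession means; means must be
#'   ordered P100 > P5 > P0.25.
#' @param accession_effect_sd Log-scale SD of the accession effect on Pi,
#'   shared across treatments. Dimensionless.
#' @param plant_pi_sdlog Log-scale SD of individual plants around their
#'   accession-by-treatment mean Pi.
#' @param block_pi_sdlog Log-scale SD of the multiplicative block effect.
#' @param technical_noise_sd Per-channel Gaussian scan noise, reflectance
#'   units. Channels below 420 nm receive `uv_noise_factor` times this SD,
#'   emulating the unstable short-wavelength end of the device.
#' @param uv_noise_factor Noise inflation below 420 nm.
#' @param accession_spectral_sd SD of the additive per-accession spectral
#'   amplitude shift, reflectance units.
#' @param accession_response_sdlog Log-scale SD of the per-accession
#'   multiplier on the deficiency deviation term: accessions differ in how
#'   strongly severe deficiency remodels their spectrum (the premise of
#'   mapping SR traits). Inflates the ratio dispersion specifically under
#'   deficiency, as in the severe-deficiency rows of the reference
#'   descriptive table.
#' @param accession_red_edge_sd SD (nm) of the per-accession red-edge
#'   wavelength shift, implemented by evaluating the decay-link curves at
#'   shifted wavelengths; dominates ratio variation for red-edge
#'   denominators (e.g. R700).
#' @param plant_spectral_sd,plant_response_sdlog,plant_red_edge_sd The
#'   plant-level analogues of the three accession components (leaf angle,
#'   measurement spot, leaf thickness vary between plants of one
#'   accession).
#' @param decay_link_params Per-wavelength decay coefficients as returned by
#'   [default_decay_link()] (data.frame with columns `wavelength`, `a`, `b`,
#'   `c`), or `NULL` for the calibrated default.
#' @param biomass_params Named list of `c(mean, sd)` of shoot dry weight (g)
#'   across accession means per treatment.
#' @param areal_dry_mass_params `c(mean, sd)` of leaf-disc areal dry mass in
#'   mg/mm^2 (used for Pi unit conversion).
#' @param grid [wavelength_grid()] for the generated spectra.
#' @param seed Root seed; every stream the generator uses is derived from it.
#' @return An object of class `panel_config` (a validated list).
#' @seealso [generate_panel()]
#' @export
panel_config <- function(n_accessions = 172,
                         plants_per_accession_per_treatment = 3,
                         n_blocks = 3,
                         n_replicates = 2,
                         treatment_pi_params = list(
                           P100  = c(mean = 3.60, sd = 1.74),
                           P5    = c(mean = 0.22, sd = 0.07),
                           P0.25 = c(mean = 0.07, sd = 0.03)),
                         accession_effect_sd = 0.20,
                         plant_pi_sdlog = 0.35,
                         block_pi_sdlog = 0.05,
                         technical_noise_sd = 0.01,
                         uv_noise_factor = 8,
                         accession_spectral_sd = 0.012,
                         accession_response_sdlog = 0.3,
                         accession_red_edge_sd = 1.2,
                         plant_spectral_sd = 0.010,
                         plant_response_sdlog = 0.2,
                         plant_red_edge_sd = 1.0,
                         decay_link_params = NULL,
                         biomass_params = list(
                           P100  = c(mean = 0.32, sd = 0.06),
                           P5    = c(mean = 0.29, sd = 0.05),
                           P0.25 = c(mean = 0.16, sd = 0.03)),
                         areal_dry_mass_params = c(mean = 0.034, sd = 0.0034),
                         grid = wavelength_grid(),
                         seed = 20220420) {
  cfg <- list(
    n_accessions = check_count(n_accessions, "n_accessions"),
    plants_per_accession_per_treatment =
      check_count(plants_per_accession_per_treatment,
                  "plants_per_accession_per_treatment"),
    n_blocks = check_count(n_blocks, "n_blocks"),
    n_replicates = check_count(n_replicates, "n_replicates"),
    treatment_pi_params = treatment_pi_params,
    accession_effect_sd = check_nonneg(accession_effect_sd, "accession_effect_sd"),
    plant_pi_sdlog = check_nonneg(plant_pi_sdlog, "plant_pi_sdlog"),
    block_pi_sdlog = check_nonneg(block_pi_sdlog, "block_pi_sdlog"),
    technical_noise_sd = check_nonneg(technical_noise_sd, "technical_noise_sd"),
    uv_noise_factor = check_nonneg(uv_noise_factor, "uv_noise_factor"),
    accession_spectral_sd = check_nonneg(accession_spectral_sd, "accession_spectral_sd"),
    accession_response_sdlog = check_nonneg(accession_response_sdlog,
                                            "accession_response_sdlog"),
    accession_red_edge_sd = check_nonneg(accession_red_edge_sd,
                                         "accession_red_edge_sd"),
    plant_spectral_sd = check_nonneg(plant_spectral_sd, "plant_spectral_sd"),
    plant_response_sdlog = check_nonneg(plant_response_sdlog,
                                        "plant_response_sdlog"),
    plant_red_edge_sd = check_nonneg(plant_red_edge_sd, "plant_red_edge_sd"),
    biomass_params = biomass_params,
    areal_dry_mass_params = areal_dry_mass_params,
    grid = grid,
    seed = as.integer(seed)
  )
  for (nm in TREATMENTS) {
    p <- treatment_pi_params[[nm]]
    if (is.null(p) || length(p) != 2 || any(!is.finite(p)) || any(p[1] <= 0) || p[2] < 0) {
      stop_spec("treatment_pi_params$", nm, " must be c(mean > 0, sd >= 0)",
                class = "specphos_config_error")
    }
    b <- biomass_params[[nm]]
    if (is.null(b) || length(b) != 2 || any(!is.finite(b)) || b[1] <= 0 || b[2] < 0) {
      stop_spec("biomass_params$", nm, " must be c(mean > 0, sd >= 0)",
                class = "specphos_config_error")
    }
  }
  means <- vapply(treatment_pi_params[TREATMENTS], `[`, numeric(1), 1)
  if (!(means[1] > means[2] && means[2] > means[3])) {
    stop_spec("treatment_pi_params means must be ordered P100 > P5 > P0.25",
              class = "specphos_config_error")
  }
  cfg$decay_link_params <- decay_link_params %||%
    default_decay_link(grid, treatment_pi_params)
  dl <- cfg$decay_link_params
  if (!all(c("wavelength", "a", "b", "c") %in% names(dl)) ||
      nrow(dl) != length(grid$wavelengths) ||
      any(abs(dl$wavelength - grid$wavelengths) > 1e-9)) {
    stop_spec("decay_link_params must give (a, b, c) for every grid wavelength",
              class = "specphos_config_error")
  }
  structure(cfg, class = "panel_config")
}

# Smooth healthy-leaf baseline: blue and red chlorophyll-absorption troughs,
# green bump, sharp red edge, NIR plateau. Anchor reflectances are chosen so
# that the baseline ratios match the panel's P100 treatment means
# (R740/R560 ~ 2.94, R750/R700 = 2.53), since at high Pi the decay term
# vanishes and the baseline is what a P-sufficient leaf reflects.
leaf_baseline <- function(wavelengths) {
  anchors_nm <- c(380, 400, 420, 450, 480, 500, 530, 550, 560, 580, 600,
                  630, 650, 670, 680, 690, 700, 710, 720, 730, 740, 750,
                  760, 770, 780, 790)
  anchors_r <- c(0.090, 0.075, 0.062, 0.055, 0.060, 0.080, 0.115, 0.135,
                 0.138, 0.130, 0.110, 0.085, 0.070, 0.055, 0.062, 0.105,
                 0.166, 0.235, 0.305, 0.365, 0.405, 0.420, 0.430, 0.435,
                 0.437, 0.438)
  f <- stats::splinefun(anchors_nm, anchors_r, method = "monoH.FC")
  f(wavelengths)
}

# Unit-height deficiency-deviation profile: positive over the visible range
# (reflectance rises as chlorophyll is lost, most strongly in green-yellow
# and at the red edge), negative and flat over the NIR plateau (leaves
# thin out). Zero-crossing sits just shy of 730 nm.
deficiency_profile <- function(wavelengths) {
  anchors_nm <- c(380, 420, 450, 500, 530, 560, 600, 630, 650, 670, 680,
                  690, 700, 710, 718, 724, 728, 732, 740, 750, 790)
  anchors_w <- c(0.10, 0.15, 0.20, 0.45, 0.80, 1.00, 0.90, 0.75, 0.60,
                 0.50, 0.55, 0.80, 1.00, 0.90, 0.55, 0.20, 0.02, -0.30,
                 -0.95, -1.00, -1.00)
  f <- stats::splinefun(anchors_nm, anchors_w, method = "monoH.FC")
  f(wavelengths)
}

#' Default per-wavelength decay-law coefficients linking reflectance to Pi
#'
#' Builds the generator's spectral link `R(lambda) = a + b * exp(-c * Pi)`.
#' `a(lambda)` is a smooth healthy-leaf baseline whose band ratios match the
#' P100 treatment means; `b(lambda)` is a fixed deficiency profile (positive
#' VIS, negative NIR) scaled by two amplitudes that are solved so that, at
#' the expected decay attenuation of the P0.25 Pi distribution, the model's
#' R740/R560 and R750/R700 equal the P0.25 treatment means (2.43 and 2.12
#' under the default panel); the expectation `E[exp(-c Pi)]` is taken over
#' the configured lognormal accession-mean distribution rather than at its
#' mean, since the attenuation is convex in Pi. The decay rate `c = 20`
#' per nmol/mm^2 puts essentially all spectral change below Pi ~ 0.15
#' nmol/mm^2, so mildly deficient (P5) leaves are spectrally almost
#' indistinguishable from P100 leaves while severely deficient leaves
#' respond strongly — the observed pattern.
#'
#' @param grid A [wavelength_grid()].
#' @param treatment_pi_params Per-treatment Pi `c(mean, sd)` (see
#'   [panel_config()]); only the P0.25 mean enters the calibration.
#' @param decay_rate Decay constant `c`, per nmol/mm^2.
#' @param target_ratios Calibration targets at the P0.25 mean Pi:
#'   named vector with `r740_560` and `r750_700`.
#' @return data.frame with columns `wavelength`, `a`, `b`, `c`.
#' @export
default_decay_link <- function(grid = wavelength_grid(),
                               treatment_pi_params = list(
                                 P100  = c(mean = 3.60, sd = 1.74),
                                 P5    = c(mean = 0.22, sd = 0.07),
                                 P0.25 = c(mean = 0.07, sd = 0.03)),
                               decay_rate = 20,
                               target_ratios = c(r740_560 = 2.43,
                                                 r750_700 = 2.12)) {
  wl <- grid$wavelengths
  base <- leaf_baseline(wl)
  prof <- deficiency_profile(wl)
  tp <- treatment_pi_params[["P0.25"]]
  sdlog <- sqrt(log1p((tp[2] / tp[1])^2))
  meanlog <- log(tp[1]) - sdlog^2 / 2
  # mean attenuation over the P0.25 accession-mean Pi distribution
  # (quantile-grid expectation; exp(-c Pi) is convex, so evaluating at the
  # mean Pi would understate it)
  qs <- stats::qlnorm((seq_len(999)) / 1000, meanlog, sdlog)
  q <- mean(exp(-decay_rate * qs))
  bval <- function(nm) {
    i <- which.min(abs(wl - nm))
    c(base = base[i], prof = prof[i])
  }
  # Solve for (amp_vis, amp_nir):
  #   (B_nir + A_n * w_nir * q) / (B_vis + A_v * w_vis * q) = target
  # for the two headline ratios -> linear 2x2 system.
  mk_row <- function(nir_nm, vis_nm, target) {
    n <- bval(nir_nm); v <- bval(vis_nm)
    # target * w_vis * q * A_v - w_nir * q * A_n = B_nir - target * B_vis
    c(coef_v = target * v["prof"] * q,
      coef_n = -n["prof"] * q,
      rhs = unname(n["base"] - target * v["base"]))
  }
  r1 <- mk_row(740, 560, target_ratios[["r740_560"]])
  r2 <- mk_row(750, 700, target_ratios[["r750_700"]])
  A <- rbind(r1[1:2], r2[1:2])
  amps <- solve(A, c(r1[3], r2[3]))
  amp_vis <- amps[1]; amp_nir <- amps[2]
  b <- ifelse(prof >= 0, amp_vis * prof, amp_nir * prof)
  data.frame(wavelength = wl, a = base, b = b, c = decay_rate)
}

# Evaluate curve v (tabulated on the grid) at wavelengths shifted by d[i]
# nm per row, by linear interpolation with boundary clamping. d = 0 is the
# exact identity.
shift_rows <- function(v, d, step) {
  nW <- length(v)
  n <- length(d)
  f <- -d / step
  lo <- floor(f)
  w <- f - lo
  j <- seq_len(nW)
  out <- matrix(0, n, nW)
  for (i in seq_len(n)) {
    i1 <- pmin(pmax(j + lo[i], 1), nW)
    i2 <- pmin(pmax(j + lo[i] + 1, 1), nW)
    out[i, ] <- (1 - w[i]) * v[i1] + w[i] * v[i2]
  }
  out
}

#' Noiseless decay-law spectrum at a given Pi content
#'
#' @param pi_content Pi in nmol/mm^2 (vectorized).
#' @param link data.frame from [default_decay_link()].
#' @return Matrix, one row per element of `pi_content`, one column per
#'   wavelength.
#' @export
decay_law_spectrum <- function(pi_content, link) {
  decay <- exp(-outer(pi_content, link$c))
  sweep(decay * matrix(link$b, nrow = length(pi_content), ncol = nrow(link),
                       byrow = TRUE), 2, link$a, "+")
}

#' Generate a synthetic phosphorus panel
#'
#' Draws a full panel under the configured study design: accession Pi
#' effects shared across treatments, accession-by-treatment means whose
#' across-accession distribution matches the configured Table-style
#' mean/SD per treatment, plant-level lognormal scatter, block effects,
#' spectra tied to each plant's Pi through the decay-law link with a
#' per-accession additive amplitude shift, and per-scan Gaussian channel
#' noise (inflated below 420 nm, where the device is unstable). Biomass is
#' drawn per treatment with the same shared accession effect (at half
#' weight), which induces the positive Pi-biomass association seen across
#' accessions; areal dry mass is drawn once per plant for unit conversions.
#'
#' The generation is deterministic given `config$seed`: equal configurations
#' yield identical panels.
#'
#' @param config A [panel_config()].
#' @return An object of class `synthetic_panel`: list with `spectra` (a
#'   [spectrum_set()] including technical replicates), `phenotypes` (one row
#'   per plant: `sample_id`, `accession_id`, `treatment`, `block`,
#'   `pi_content`, `biomass`, `areal_dry_mass`) and `truth` (the generating
#'   parameters and latent effects, for recovery tests).
#' @examples
#' cfg <- panel_config(n_accessions = 8, n_blocks = 1, seed = 1)
#' panel <- generate_panel(cfg)
#' panel$spectra
#' @export
generate_panel <- function(config) {
  if (!inherits(config, "panel_config")) {
    stop_spec("config must be a panel_config object",
              class = "specphos_config_error")
  }
  with_seed(config$seed, generate_panel_impl(config))
}

generate_panel_impl <- function(cfg) {
  nA <- cfg$n_accessions
  nP <- cfg$plants_per_accession_per_treatment
  nB <- cfg$n_blocks
  nR <- cfg$n_replicates
  wl <- cfg$grid$wavelengths
  nW <- length(wl)
  acc_ids <- sprintf("ACC%03d", seq_len(nA))

  s_a <- cfg$accession_effect_sd
  # shared accession effect on log-Pi (and, at half weight, log-biomass)
  z_acc <- stats::rnorm(nA)
  acc_spec_shift <- stats::rnorm(nA, 0, cfg$accession_spectral_sd)
  acc_resp <- stats::rnorm(nA, 0, cfg$accession_response_sdlog)
  acc_redge <- stats::rnorm(nA, 0, cfg$accession_red_edge_sd)
  block_eff <- stats::rnorm(nB, 0, cfg$block_pi_sdlog)

  plants <- expand.grid(plant = seq_len(nP), block = seq_len(nB),
                        accession = seq_len(nA), treatment = TREATMENTS,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_plants <- nrow(plants)

  # accession x treatment mean Pi: total across-accession log-variance per
  # treatment is set by the configured mean/SD; the shared accession effect
  # uses s_a of it and an accession-by-treatment residual supplies the rest.
  pi_at <- matrix(NA_real_, nA, length(TREATMENTS),
                  dimnames = list(acc_ids, TREATMENTS))
  bio_at <- pi_at
  for (j in seq_along(TREATMENTS)) {
    tp <- cfg$treatment_pi_params[[TREATMENTS[j]]]
    sdlog_tot <- sqrt(log1p((tp[2] / tp[1])^2))
    if (s_a > sdlog_tot) {
      stop_spec("accession_effect_sd exceeds the total log-SD implied by ",
                "treatment_pi_params for ", TREATMENTS[j],
                class = "specphos_config_error")
    }
    s_res <- sqrt(max(sdlog_tot^2 - s_a^2, 0))
    meanlog <- log(tp[1]) - sdlog_tot^2 / 2
    pi_at[, j] <- exp(meanlog + s_a * z_acc + stats::rnorm(nA, 0, s_res))

    bp <- cfg$biomass_params[[TREATMENTS[j]]]
    sdlog_b <- sqrt(log1p((bp[2] / bp[1])^2))
    s_share <- min(0.5 * s_a, sdlog_b)
    s_bres <- sqrt(max(sdlog_b^2 - s_share^2, 0))
    bio_at[, j] <- exp(log(bp[1]) - sdlog_b^2 / 2 +
                         s_share * z_acc + stats::rnorm(nA, 0, s_bres))
  }

  ti <- match(plants$treatment, TREATMENTS)
  mu <- pi_at[cbind(plants$accession, ti)]
  pi_plant <- mu * exp(block_eff[plants$block] - cfg$plant_pi_sdlog^2 / 2 +
                         stats::rnorm(n_plants, 0, cfg$plant_pi_sdlog))
  bio_plant <- bio_at[cbind(plants$accession, ti)] *
    exp(stats::rnorm(n_plants, 0, 0.10) - 0.10^2 / 2)
  adm <- cfg$areal_dry_mass_params
  sdlog_adm <- sqrt(log1p((adm[2] / adm[1])^2))
  adm_plant <- exp(log(adm[1]) - sdlog_adm^2 / 2 +
                     stats::rnorm(n_plants, 0, sdlog_adm))

  sample_id <- sprintf("%s_%s_B%d_p%d", acc_ids[plants$accession],
                       plants$treatment, plants$block, plants$plant)
  phenotypes <- data.frame(
    sample_id = sample_id,
    accession_id = acc_ids[plants$accession],
    treatment = as_treatment(plants$treatment),
    block = plants$block,
    pi_content = pi_plant,
    biomass = bio_plant,
    areal_dry_mass = adm_plant,
    stringsAsFactors = FALSE
  )

  # per-plant spectral curve: red-edge-shifted baseline and deviation
  # profile, deficiency response scaled per accession and plant, plus
  # additive amplitude shifts
  link <- cfg$decay_link_params
  redge_shift <- acc_redge[plants$accession] +
    stats::rnorm(n_plants, 0, cfg$plant_red_edge_sd)
  resp_mult <- exp(acc_resp[plants$accession] +
                     stats::rnorm(n_plants, 0, cfg$plant_response_sdlog) -
                     (cfg$accession_response_sdlog^2 +
                        cfg$plant_response_sdlog^2) / 2)
  add_shift <- acc_spec_shift[plants$accession] +
    stats::rnorm(n_plants, 0, cfg$plant_spectral_sd)
  Ash <- shift_rows(link$a, redge_shift, cfg$grid$step)
  Bsh <- shift_rows(link$b, redge_shift, cfg$grid$step)
  clean <- Ash + resp_mult * exp(-outer(pi_plant, link$c)) * Bsh + add_shift
  noise_sd <- rep(cfg$technical_noise_sd, nW)
  noise_sd[wl < 420] <- noise_sd[wl < 420] * cfg$uv_noise_factor

  refl <- matrix(NA_real_, n_plants * nR, nW)
  meta <- vector("list", nR)
  for (r in seq_len(nR)) {
    rows <- (r - 1L) * n_plants + seq_len(n_plants)
    eps <- matrix(stats::rnorm(n_plants * nW), n_plants, nW) *
      matrix(noise_sd, n_plants, nW, byrow = TRUE)
    refl[rows, ] <- clean + eps
    meta[[r]] <- data.frame(
      sample_id = sample_id,
      accession_id = acc_ids[plants$accession],
      treatment = plants$treatment,
      block = plants$block,
      replicate = r,
      stringsAsFactors = FALSE
    )
  }
  meta <- do.call(rbind, meta)
  ord <- order(match(meta$sample_id, sample_id), meta$replicate)
  meta <- meta[ord, , drop = FALSE]
  refl <- refl[ord, , drop = FALSE]
  refl <- pmin(pmax(refl, 1e-4), 1 - 1e-4)

  structure(list(
    spectra = spectrum_set(meta, refl, cfg$grid),
    phenotypes = phenotypes,
    truth = list(config = cfg,
                 accession_log_effect = stats::setNames(s_a * z_acc, acc_ids),
                 accession_spectral_shift = stats::setNames(acc_spec_shift, acc_ids),
                 block_log_effect = block_eff,
                 pi_accession_treatment = pi_at)
  ), class = "synthetic_panel")
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat("<synthetic_panel>\n")
  cat(sprintf("  %d plants (%d accessions x %s treatments x %d blocks x %d plants)\n",
              nrow(x$phenotypes), x$truth$config$n_accessions,
              length(TREATMENTS), x$truth$config$n_blocks,
              x$truth$config$plants_per_accession_per_treatment))
  cat(sprintf("  %d spectra on %d channels\n", nrow(x$spectra$meta),
              length(x$spectra$grid$wavelengths)))
  invisible(x)
}
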