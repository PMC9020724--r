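#' Configuration for a full synthetic-panel pipeline run
#'
#' Bundles every stage's settings with the field constants surfaced as
#' explicit keys: Pi trimming threshold 0.02 nmol/mm^2, augmentation noise
#' SD 0.01, reconstruction weight 0.5, MAF filter 0.05, alpha 0.05, locus
#' window 300 kb, LD candidate distance 100 kb and r^2 cutoff 0.50.
#'
#' @param out_dir Run directory (created if needed).
#' @param seed Root seed for all stages.
#' @param panel Arguments forwarded to [panel_config()] (list).
#' @param gwas Arguments forwarded to [gwas_config()] (list), or `NULL` to
#'   skip the association stages.
#' @param decay_keys Ratio keys fitted by the calibration stage.
#' @param trim_below,maf_threshold,alpha,locus_window,ld_dist,ld_r2,
#'   augment_sd,recon_weight Field constants (see description).
#' @param train `NULL` to skip model training, or a list of overrides for
#'   [train_spec_cnn()] (e.g. `list(epochs = 30, multitask = TRUE)`).
#' @param stages Character vector of stages to run, in order.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, panel = list(),
                            gwas = list(), decay_keys = c("R750/R700",
                                                          "R740/R560"),
                            trim_below = 0.02, maf_threshold = 0.05,
                            alpha = 0.05, locus_window = 300000,
                            ld_dist = 100000, ld_r2 = 0.50,
                            augment_sd = 0.01, recon_weight = 0.5,
                            train = NULL,
                            stages = c("simulate", "preprocess", "indices",
                                       "decayfit", "summarize", "train",
                                       "gwaspost")) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), panel = panel,
                 gwas = gwas, decay_keys = decay_keys,
                 trim_below = trim_below, maf_threshold = maf_threshold,
                 alpha = alpha, locus_window = locus_window,
                 ld_dist = ld_dist, ld_r2 = ld_r2, augment_sd = augment_sd,
                 recon_weight = recon_weight, train = train,
                 stages = stages),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML or JSON file
#'
#' @param path `.yaml`/`.yml` (requires the yaml package) or `.json` file
#'   whose top-level keys are [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_spec("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_spec("reading YAML configs requires the yaml package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, raw)
}

#' Run the synthetic-panel analysis pipeline
#'
#' Executes the configured stages in order — simulate, preprocess, indices,
#' decayfit, summarize, train (optional) and gwaspost — writing each
#' stage's artifacts under its own subdirectory of `out_dir` plus a
#' `manifest.json` recording package version, seed, configuration checksum
#' and per-stage outputs. Stages are deterministic given the seed; a stage
#' failure leaves a `<stage>.failed` marker with the error message and
#' rethrows.
#'
#' @param config A [pipeline_config()].
#' @return The manifest (list), invisibly; artifacts on disk in
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop_spec("config must be a pipeline_config")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(config[setdiff(names(config), "train")], cfg_path,
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  manifest <- list(
    package = "specphos",
    version = as.character(utils::packageVersion("specphos")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    stages = list()
  )
  state <- new.env(parent = emptyenv())

  runners <- list(simulate = stage_simulate, preprocess = stage_preprocess,
                  indices = stage_indices, decayfit = stage_decayfit,
                  summarize = stage_summarize, train = stage_train,
                  gwaspost = stage_gwaspost)
  for (stage in config$stages) {
    fn <- runners[[stage]]
    if (is.null(fn)) stop_spec("unknown stage: ", stage)
    if (stage == "train" && is.null(config$train)) next
    if (stage == "gwaspost" && is.null(config$gwas)) next
    sdir <- file.path(config$out_dir, stage)
    dir.create(sdir, showWarnings = FALSE)
    res <- tryCatch(fn(config, state, sdir), error = function(e) e)
    if (inherits(res, "error")) {
      writeLines(conditionMessage(res), file.path(config$out_dir,
                                                  paste0(stage, ".failed")))
      stop_spec("stage '", stage, "' failed: ", conditionMessage(res))
    }
    manifest$stages[[stage]] <- res
  }
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

stage_outputs <- function(...) {
  files <- c(...)
  list(outputs = basename(files), md5 = unname(tools::md5sum(files)))
}

stage_simulate <- function(config, state, sdir) {
  pargs <- config$panel
  pargs$seed <- pargs$seed %||% sub_seed(config$seed, 11)
  state$panel <- generate_panel(do.call(panel_config, pargs))
  f1 <- file.path(sdir, "spectra.csv")
  write_spectra(state$panel$spectra, f1)
  f2 <- file.path(sdir, "phenotypes.tsv")
  utils::write.table(state$panel$phenotypes, f2, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  f3 <- file.path(sdir, "truth.json")
  tr <- state$panel$truth
  jsonlite::write_json(list(accession_log_effect = tr$accession_log_effect,
                            block_log_effect = tr$block_log_effect),
                       f3, auto_unbox = TRUE, digits = NA)
  files <- c(f1, f2, f3)
  if (!is.null(config$gwas)) {
    gargs <- config$gwas
    gargs$seed <- gargs$seed %||% sub_seed(config$seed, 12)
    state$gwas <- generate_gwas(do.call(gwas_config, gargs))
    assoc <- naive_assoc(state$gwas$genotypes, state$gwas$trait,
                         state$gwas$snp_info)
    f4 <- file.path(sdir, "assoc.tsv")
    gemma <- data.frame(chr = assoc$chromosome, rs = assoc$snp_id,
                        ps = assoc$position, af = assoc$maf,
                        p_wald = assoc$p_value)
    utils::write.table(gemma, f4, sep = "\t", row.names = FALSE, quote = FALSE)
    f5 <- file.path(sdir, "ld.tsv")
    utils::write.table(state$gwas$ld, f5, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    files <- c(files, f4, f5)
  }
  stage_outputs(files)
}

stage_preprocess <- function(config, state, sdir) {
  if (is.null(state$panel)) stop_spec("preprocess needs the simulate stage")
  set <- exclude_noisy_band(average_replicates(state$panel$spectra))
  state$processed <- set
  f <- file.path(sdir, "spectra_processed.csv")
  write_spectra(set, f)
  stage_outputs(f)
}

stage_indices <- function(config, state, sdir) {
  set <- state$processed %||% stop_spec("indices needs the preprocess stage")
  ph <- state$panel$phenotypes
  ratios <- compute_ratios(set)
  state$ratios <- ratios
  f1 <- file.path(sdir, "ratios.tsv")
  utils::write.table(ratios, f1, sep = "\t", row.names = FALSE, quote = FALSE)

  idx <- match(ratios$sample_id, ph$sample_id)
  pooled <- ph$treatment[idx] %in% c("P5", "P0.25")
  screen <- correlate_with_trait(ratios[pooled, , drop = FALSE],
                                 ph$pi_content[idx][pooled])
  state$screen <- screen
  # heatmap layout: rows = VIS bands, columns = NIR bands
  wide <- stats::reshape(screen[, c("vis_nm", "nir_nm", "rho")],
                         idvar = "vis_nm", timevar = "nir_nm",
                         direction = "wide")
  names(wide) <- sub("^rho\\.", "R", names(wide))
  f2 <- file.path(sdir, "pi_correlation_grid.tsv")
  utils::write.table(wide, f2, sep = "\t", row.names = FALSE, quote = FALSE)

  sr <- normalize_sr_traits(
    accession_ratio_means(state$panel$spectra, "P0.25"),
    accession_ratio_means(state$panel$spectra, "P100"))
  state$sr_traits <- sr
  f3 <- file.path(sdir, "sr_traits.tsv")
  utils::write.table(sr, f3, sep = "\t", row.names = FALSE, quote = FALSE)
  stage_outputs(f1, f2, f3)
}

stage_decayfit <- function(config, state, sdir) {
  set <- state$processed %||% stop_spec("decayfit needs the preprocess stage")
  ph <- state$panel$phenotypes
  out <- list()
  for (key in config$decay_keys) {
    for (lvl in c("individual", "accession")) {
      fit <- fit_by_level(set, ph, key, level = lvl,
                          trim_below = config$trim_below)
      s <- summary(fit)
      out[[paste(key, lvl, sep = " @ ")]] <- list(
        key = key, level = lvl,
        estimates = as.list(fit$coefficients),
        std_errors = as.list(stats::setNames(s$coefficients$std_error,
                                             c("a", "b", "c"))),
        cv_pct = as.list(stats::setNames(s$coefficients$cv_pct,
                                         c("a", "b", "c"))),
        r_squared = fit$r_squared, n_used = fit$n_used)
    }
  }
  state$decay <- out
  f <- file.path(sdir, "decay_fits.json")
  jsonlite::write_json(out, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage_outputs(f)
}

stage_summarize <- function(config, state, sdir) {
  ph <- derive_phenotypes(state$panel$phenotypes)
  set <- state$processed
  ratios <- state$ratios
  idx <- match(ph$sample_id, ratios$sample_id)
  ph$r740_560 <- ratios[["R740/R560"]][idx]
  ph$r750_700 <- ratios[["R750/R700"]][idx]
  tab <- descriptive_table(ph, c("pi_content", "biomass", "pute",
                                 "r740_560", "r750_700"))
  state$summary <- tab
  f <- file.path(sdir, "descriptive_table.tsv")
  utils::write.table(tab, f, sep = "\t", row.names = FALSE, quote = FALSE)
  stage_outputs(f)
}

stage_train <- function(config, state, sdir) {
  dat <- prepare_cnn_data(state$panel, "classify")
  args <- config$train
  args$x <- dat$x; args$y <- dat$y
  args$wavelengths <- dat$wavelengths
  args$seed <- args$seed %||% sub_seed(config$seed, 13)
  args$augment_sd <- args$augment_sd %||% config$augment_sd
  args$recon_weight <- args$recon_weight %||% config$recon_weight
  fit <- do.call(train_spec_cnn, args)
  state$cnn <- fit
  f1 <- file.path(sdir, "metrics.json")
  jsonlite::write_json(list(accuracy = fit$metrics$accuracy,
                            confusion = as.data.frame(fit$metrics$confusion),
                            best_epoch = fit$best_epoch),
                       f1, auto_unbox = TRUE, digits = NA)
  cam <- grad_cam(fit, dat$x[fit$split$test, , drop = FALSE])
  f2 <- file.path(sdir, "cam_test_mean.tsv")
  utils::write.table(
    data.frame(wavelength = dat$wavelengths, attribution = colMeans(cam)),
    f2, sep = "\t", row.names = FALSE, quote = FALSE)
  stage_outputs(f1, f2)
}

stage_gwaspost <- function(config, state, sdir) {
  if (is.null(state$gwas)) stop_spec("gwaspost needs the simulate stage")
  assoc <- read_gemma_assoc(file.path(config$out_dir, "simulate", "assoc.tsv"))
  assoc <- maf_filter(assoc, config$maf_threshold)
  thr <- bonferroni_log_threshold(nrow(assoc), config$alpha)
  sig <- call_significant(assoc, thr)
  loci <- group_loci(sig, window = config$locus_window, trait = "Pi")
  f1 <- file.path(sdir, "loci.tsv")
  write_locus_table(loci, f1)
  ld <- read_ld_pairs(file.path(config$out_dir, "simulate", "ld.tsv"))
  windows <- lapply(seq_len(nrow(loci)), function(i) {
    lead <- list(snp_id = loci$lead_snp[i], chromosome = loci$chromosome[i],
                 position = loci$lead_position[i])
    w <- ld_candidate_window(lead, assoc, ld,
                             dist = config$ld_dist, r2_min = config$ld_r2)
    if (nrow(w) > 0) cbind(locus = loci$name[i], w) else NULL
  })
  windows <- do.call(rbind, windows)
  f2 <- file.path(sdir, "candidate_windows.tsv")
  utils::write.table(windows %||% data.frame(), f2, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  f3 <- file.path(sdir, "manhattan.tsv")
  utils::write.table(manhattan_data(assoc), f3, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  f4 <- file.path(sdir, "qq.tsv")
  utils::write.table(qq_data(assoc$p_value), f4, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  state$loci <- loci
  res <- stage_outputs(f1, f2, f3, f4)
  res$n_tests <- nrow(assoc)
  res$log_threshold <- thr
  res$n_significant <- nrow(sig)
  res$n_loci <- nrow(loci)
  res
}
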