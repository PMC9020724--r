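test_that("panel generation is deterministic for a fixed seed", {
  cfg <- panel_config(n_accessions = 6, n_blocks = 1,
                      plants_per_accession_per_treatment = 2, seed = 7)
  p1 <- generate_panel(cfg)
  p2 <- generate_panel(cfg)
  expect_identical(p1$spectra$reflectance, p2$spectra$reflectance)
  expect_identical(p1$phenotypes, p2$phenotypes)
})

test_that("with all noise terms at zero, spectra equal the decay-law curve", {
  cfg <- panel_config(
    n_accessions = 4, n_blocks = 1, plants_per_accession_per_treatment = 2,
    accession_effect_sd = 0, plant_pi_sdlog = 0, block_pi_sdlog = 0,
    technical_noise_sd = 0, accession_spectral_sd = 0,
    accession_response_sdlog = 0, accession_red_edge_sd = 0,
    plant_spectral_sd = 0, plant_response_sdlog = 0, plant_red_edge_sd = 0,
    seed = 3)
  panel <- generate_panel(cfg)
  expected <- decay_law_spectrum(panel$phenotypes$pi_content,
                                 cfg$decay_link_params)
  idx <- match(panel$spectra$meta$sample_id, panel$phenotypes$sample_id)
  expect_equal(unname(panel$spectra$reflectance),
               unname(expected[idx, ]), tolerance = 1e-12)
})

test_that("invalid panel configurations are rejected naming the field", {
  expect_error(panel_config(n_accessions = 0), "n_accessions")
  expect_error(panel_config(technical_noise_sd = -1), "technical_noise_sd")
  expect_error(panel_config(treatment_pi_params = list(
    P100 = c(0.1, 0.05), P5 = c(0.22, 0.07), P0.25 = c(0.07, 0.03))),
    "ordered")
  expect_error(panel_config(treatment_pi_params = list(
    P100 = c(3.6, 1.74), P5 = c(-1, 0.07), P0.25 = c(0.07, 0.03))),
    "P5")
})

test_that("per-treatment Pi means match the configured targets", {
  # >= 500 plants per treatment
  cfg <- panel_config(n_accessions = 60, n_blocks = 1,
                      plants_per_accession_per_treatment = 9, seed = 11)
  panel <- generate_panel(cfg)
  ph <- panel$phenotypes
  for (tr in c("P100", "P5", "P0.25")) {
    sub <- ph[ph$treatment == tr, ]
    target <- cfg$treatment_pi_params[[tr]][1]
    # plants within an accession are correlated, so the standard error is
    # taken across accession means
    am <- tapply(sub$pi_content, sub$accession_id, mean)
    se <- sd(am) / sqrt(length(am))
    expect_lt(abs(mean(sub$pi_content) - target), 3 * se)
  }
})

test_that("generated reflectance lies in (0,1), Pi positive, spectra smooth", {
  panel <- small_panel()
  expect_true(all(panel$spectra$reflectance > 0 &
                    panel$spectra$reflectance < 1))
  expect_true(all(panel$phenotypes$pi_content > 0))
  # smoothness of the noiseless component: each plant's curve correlates
  # almost perfectly with its own 2-nm shift across the retained band
  link <- panel$truth$config$decay_link_params
  clean <- decay_law_spectrum(panel$phenotypes$pi_content, link)
  keep <- which(link$wavelength >= 420)
  adj <- vapply(seq_len(nrow(clean)), function(i) {
    cor(clean[i, keep[-1]], clean[i, keep[-length(keep)]])
  }, numeric(1))
  expect_true(all(adj >= 0.99))
})

test_that("noiseless generation lets the decay fit recover the link exactly", {
  link <- default_decay_link()
  i <- which(link$wavelength == 740)
  pi_v <- seq(0.03, 0.6, length.out = 60)
  resp <- link$a[i] + link$b[i] * exp(-link$c[i] * pi_v)
  fit <- fit_decay(pi_v, resp)
  expect_equal(unname(coef(fit)),
               unname(c(link$a[i], link$b[i], link$c[i])),
               tolerance = 1e-6)
})

test_that("the synthetic R740/R560 ratio tracks Pi in deficient plants", {
  panel <- study_panel()
  set <- exclude_noisy_band(average_replicates(panel$spectra))
  ratios <- compute_ratios(set)
  ph <- panel$phenotypes
  idx <- match(ratios$sample_id, ph$sample_id)
  pool <- ph$treatment[idx] %in% c("P5", "P0.25")
  rho <- cor(ratios[["R740/R560"]][pool], ph$pi_content[idx][pool],
             method = "spearman")
  expect_gt(rho, 0.6)
})

test_that("synthetic genotypes are reproducible and carry planted effects", {
  loci <- data.frame(chromosome = c(2, 5), position = c(1e6, 2e7),
                     effect = c(1.2, 1.0))
  cfg <- gwas_config(n_snps = 400, n_accessions = 120, planted_loci = loci,
                     seed = 9)
  g1 <- generate_gwas(cfg)
  g2 <- generate_gwas(cfg)
  expect_identical(g1$genotypes, g2$genotypes)
  expect_identical(g1$trait, g2$trait)

  assoc <- naive_assoc(g1$genotypes, g1$trait, g1$snp_info)
  top <- assoc$snp_id[which.min(assoc$p_value)]
  # minimum p at a causal SNP or one of its tight LD copies
  lead_ld <- g1$ld[g1$ld$snp_a %in% g1$truth$causal_snp |
                     g1$ld$snp_b %in% g1$truth$causal_snp, ]
  linked <- unique(c(g1$truth$causal_snp, lead_ld$snp_a, lead_ld$snp_b))
  expect_true(top %in% linked)
})

test_that("null synthetic genotypes give calibrated association p-values", {
  cfg <- gwas_config(n_snps = 1000, n_accessions = 150, seed = 21)
  g <- generate_gwas(cfg)
  assoc <- naive_assoc(g$genotypes, g$trait, g$snp_info)
  frac <- mean(assoc$p_value < 0.05)
  # binomial tolerance: 0.05 +/- 4 * sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(frac - 0.05), 4 * sqrt(0.05 * 0.95 / 1000))
})

test_that("planting an effect on a filter-failing SNP warns", {
  loci <- data.frame(chromosome = 1, position = 5e6, effect = 1)
  cfg <- gwas_config(n_snps = 100, n_accessions = 80, planted_loci = loci,
                     maf_range = c(0.01, 0.02), seed = 2)
  expect_warning(generate_gwas(cfg), "MAF")
})

test_that("gwas configuration validates its geometry", {
  expect_error(gwas_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(gwas_config(planted_loci = data.frame(
    chromosome = 1, position = 9e9, effect = 1)), "within chromosome")
  expect_error(gwas_config(planted_loci = data.frame(
    chromosome = 99, position = 100, effect = 1)), "chromosome")
})
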