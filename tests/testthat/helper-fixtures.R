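# Shared fixtures. Panels are cached per session so several test files can
# reuse one generation.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# Small panel at study-like structure (scaled down for runtime)
small_panel <- function() {
  memo("small_panel", generate_panel(
    panel_config(n_accessions = 24, n_blocks = 2,
                 plants_per_accession_per_treatment = 2, seed = 101)))
}

# Full-size panel at the default (study) conditions
study_panel <- function() {
  memo("study_panel", generate_panel(panel_config()))
}

# Panel whose three treatments are spectrally well separated: a slower decay
# rate places P100, P5 and P0.25 at three distinct attenuation levels, and
# response-strength noise is reduced.
separable_panel <- function() {
  memo("separable_panel", {
    link <- default_decay_link(decay_rate = 5)
    generate_panel(panel_config(
      n_accessions = 36, n_blocks = 1,
      plants_per_accession_per_treatment = 3,
      decay_link_params = link,
      treatment_pi_params = list(P100 = c(mean = 3.60, sd = 0.50),
                                 P5 = c(mean = 0.22, sd = 0.03),
                                 P0.25 = c(mean = 0.07, sd = 0.01)),
      accession_effect_sd = 0.05, plant_pi_sdlog = 0.10,
      accession_response_sdlog = 0.1, plant_response_sdlog = 0.1,
      accession_spectral_sd = 0.004, plant_spectral_sd = 0.004,
      accession_red_edge_sd = 0.4, plant_red_edge_sd = 0.4,
      seed = 202))
  })
}

subset_spectra_for_test <- function(set, idx) {
  specphos:::subset_spectra(set, idx)
}

# Classifier trained on spectra whose two classes differ only at
# 680-700 nm, for attribution-recovery checks.
planted_band_fit <- function() {
  memo("planted_band_fit", {
    set.seed(31)
    wl <- seq(420, 790, by = 2)
    n_per <- 120
    base <- 0.25 + 0.05 * sin(wl / 60)
    bump <- ifelse(wl >= 680 & wl <= 700, 0.06, 0)
    x <- rbind(
      matrix(rep(base, n_per), n_per, byrow = TRUE),
      matrix(rep(base + bump, n_per), n_per, byrow = TRUE)
    ) + matrix(rnorm(2 * n_per * length(wl), 0, 0.01), 2 * n_per)
    y <- factor(rep(c("flat", "bump"), each = n_per))
    fit <- train_spec_cnn(x, y, task = "classify", epochs = 20,
                          batch_size = 120, patience = 20, seed = 4,
                          wavelengths = wl)
    list(fit = fit, x = x, y = y, wl = wl)
  })
}

# Weakly separated classification panel: the three treatments are
# distinguishable in principle (slow decay rate) but noise is raised and
# the panel is small, leaving the classifier genuine headroom.
weak_panel <- function() {
  memo("weak_panel", {
    link <- default_decay_link(decay_rate = 5)
    generate_panel(panel_config(
      n_accessions = 20, n_blocks = 1,
      plants_per_accession_per_treatment = 2,
      decay_link_params = link,
      technical_noise_sd = 0.02, plant_spectral_sd = 0.02,
      seed = 404))
  })
}

# Hand-built spectrum set: reflectance rows supplied directly
make_set <- function(refl, sample_id = paste0("s", seq_len(nrow(refl))),
                     accession_id = sample_id, treatment = "P5",
                     replicate = 1L, block = 1L,
                     grid = wavelength_grid()) {
  meta <- data.frame(sample_id = sample_id, accession_id = accession_id,
                     treatment = treatment, block = block,
                     replicate = replicate, stringsAsFactors = FALSE)
  spectrum_set(meta, refl, grid)
}

# Dense grid-search oracle for the decay fit: best constrained SS over a
# box of (a, b, c) values. Independent of the fitting code.
decay_grid_oracle <- function(x, y, n_a = 31, n_b = 31, n_c = 41) {
  a_grid <- seq(max(-1, min(y) - 2 * diff(range(y)) - 0.5),
                max(y) + 2 * diff(range(y)) + 0.5, length.out = n_a)
  bmax <- 3 * diff(range(y)) + 1
  b_grid <- seq(-bmax, bmax, length.out = n_b)
  c_grid <- c(0, exp(seq(log(0.01 / stats::median(x)),
                         log(100 / stats::median(x)), length.out = n_c - 1)))
  best <- Inf
  for (cc in c_grid) {
    E <- exp(-cc * x)
    for (aa in a_grid) {
      r0 <- y - aa
      # SS(b) = sum((r0 - b E)^2), quadratic in b; evaluate on the grid only
      for (bb in b_grid) {
        ss <- sum((r0 - bb * E)^2)
        if (ss < best) best <- ss
      }
    }
  }
  best
}

# Brute-force transitive-closure clustering oracle for locus grouping:
# SNPs are nodes, edges join significant SNPs on the same chromosome within
# the window; loci are connected components.
locus_oracle <- function(records, window) {
  n <- nrow(records)
  if (n == 0) return(list())
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && records$chromosome[i] == records$chromosome[j] &&
          abs(records$position[i] - records$position[j]) <= window) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  unname(split(records$snp_id, comp))
}

# Canonical form for comparing locus memberships
canon_loci <- function(member_list) {
  sets <- lapply(member_list, function(s) sort(unlist(s)))
  sets[order(vapply(sets, paste, character(1), collapse = ","))]
}
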