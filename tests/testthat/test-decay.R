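test_that("noiseless decay data is recovered exactly", {
  pi_v <- seq(0.03, 0.5, length.out = 50)
  y <- 0.5 + 2 * exp(-10 * pi_v)
  fit <- fit_decay(pi_v, y)
  expect_equal(unname(coef(fit)), c(0.5, 2, 10), tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$n_used, 50)
})

test_that("points below the Pi trimming threshold are excluded", {
  pi_v <- c(0.01, 0.015, seq(0.03, 0.5, length.out = 30))
  y <- 0.5 + 2 * exp(-10 * pi_v)
  fit <- fit_decay(pi_v, y)
  expect_equal(fit$n_used, 30)
  expect_equal(fit$n_input, 32)
  expect_true(all(fit$data$pi_content >= 0.02))
})

test_that("degenerate inputs raise fit errors", {
  expect_error(fit_decay(c(0.1, 0.2, 0.3), c(1, 2, 3)), "at least 4")
  expect_error(fit_decay(rep(0.1, 10), runif(10)), "degenerate")
  expect_error(fit_decay(c(-0.1, 0.2, 0.3, 0.4), 1:4), "positive")
  expect_error(fit_decay(seq(0.001, 0.019, length.out = 10), runif(10)),
               "at least 4")
})

test_that("increasing responses fit with negative b under the constraints", {
  set.seed(4)
  pi_v <- seq(0.03, 0.6, length.out = 40)
  y <- 1.5 - 0.8 * exp(-6 * pi_v) + rnorm(40, 0, 0.01)
  fit <- fit_decay(pi_v, y)
  expect_lt(coef(fit)["b"], 0)
  expect_gte(coef(fit)["c"], 0)
  expect_gte(coef(fit)["a"], -1)
  expect_lte(fit$ss_res, decay_grid_oracle(fit$data$pi_content,
                                           fit$data$response) + 1e-9)
})

test_that("fitted residual sum of squares never loses to the grid oracle", {
  set.seed(77)
  for (case in 1:6) {
    n <- sample(10:50, 1)
    pi_v <- sort(runif(n, 0.025, 0.8))
    a <- runif(1, -0.5, 2); b <- runif(1, -2, 2); cc <- runif(1, 0.5, 20)
    y <- a + b * exp(-cc * pi_v) + rnorm(n, 0, runif(1, 0, 0.1))
    fit <- suppressWarnings(fit_decay(pi_v, y))
    oracle <- decay_grid_oracle(pi_v, y)
    expect_lte(fit$ss_res, oracle + 1e-9)
  }
})

test_that("reported R-squared matches an independent recomputation", {
  set.seed(12)
  pi_v <- seq(0.03, 0.7, length.out = 45)
  y <- 0.3 + 1.1 * exp(-8 * pi_v) + rnorm(45, 0, 0.05)
  fit <- fit_decay(pi_v, y)
  p <- coef(fit)
  resid <- y - (p["a"] + p["b"] * exp(-p["c"] * pi_v))
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  expect_equal(fit$r_squared, unname(r2), tolerance = 1e-9)
})

test_that("adding a constant to the response shifts only the offset", {
  set.seed(5)
  pi_v <- seq(0.03, 0.5, length.out = 40)
  y <- 0.4 + 1.5 * exp(-9 * pi_v) + rnorm(40, 0, 0.02)
  f1 <- fit_decay(pi_v, y)
  f2 <- fit_decay(pi_v, y + 0.7)
  expect_equal(coef(f2)["a"], coef(f1)["a"] + 0.7, tolerance = 1e-4)
  expect_equal(coef(f2)[c("b", "c")], coef(f1)[c("b", "c")],
               tolerance = 1e-4)
})

test_that("summary reports standard errors and coefficient CVs", {
  set.seed(9)
  pi_v <- seq(0.03, 0.6, length.out = 80)
  y <- 0.5 + 2 * exp(-10 * pi_v) + rnorm(80, 0, 0.02)
  fit <- fit_decay(pi_v, y)
  s <- summary(fit)
  expect_equal(s$coefficients$cv_pct,
               100 * s$coefficients$std_error / abs(s$coefficients$estimate))
  expect_true(all(is.finite(s$coefficients$std_error)))
  # tight noiseless-ish design: parameter CVs are small
  expect_true(all(s$coefficients$cv_pct < 10))
  # model-object surface
  expect_equal(fitted(fit) + residuals(fit), fit$data$response)
  expect_equal(predict(fit, 0.1),
               unname(coef(fit)["a"] + coef(fit)["b"] *
                        exp(-coef(fit)["c"] * 0.1)))
  expect_equal(dim(vcov(fit)), c(3L, 3L))
  expect_output(print(fit), "R-squared")
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(fit$n_used, 2L))
})

test_that("accession-level fits average cells first and tighten the fit", {
  panel <- small_panel()
  set <- exclude_noisy_band(average_replicates(panel$spectra))
  ph <- panel$phenotypes

  fi <- suppressWarnings(fit_by_level(set, ph, "R750/R700", "individual"))
  fa <- suppressWarnings(fit_by_level(set, ph, "R750/R700", "accession"))
  expect_equal(fa$level, "accession")
  expect_lte(fa$n_used, 2 * panel$truth$config$n_accessions)
  expect_gte(fa$r_squared, fi$r_squared)

  # with one plant per accession the two levels coincide
  one <- generate_panel(panel_config(
    n_accessions = 30, n_blocks = 1,
    plants_per_accession_per_treatment = 1, seed = 13))
  set1 <- exclude_noisy_band(average_replicates(one$spectra))
  f_ind <- suppressWarnings(fit_by_level(set1, one$phenotypes,
                                         "R750/R700", "individual"))
  f_acc <- suppressWarnings(fit_by_level(set1, one$phenotypes,
                                         "R750/R700", "accession"))
  expect_equal(coef(f_acc), coef(f_ind), tolerance = 1e-6)

  # single-wavelength responses work too
  fw <- suppressWarnings(fit_by_level(set, ph, 740, "accession"))
  expect_s3_class(fw, "decay_fit")
})
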