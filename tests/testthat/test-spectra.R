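test_that("wavelength grid derives its channel count and validates inputs", {
  g <- wavelength_grid()
  expect_length(g$wavelengths, 206)
  expect_equal(g$wavelengths[1], 380)
  expect_error(wavelength_grid(380, 790, 0), "step")
  expect_error(wavelength_grid(380, 791, 2), "divisible")
  expect_error(wavelength_grid(790, 380), "exceed")
})

test_that("spectra round-trip through the wide CSV layout", {
  g <- wavelength_grid()
  refl <- matrix(runif(2 * 206, 0.05, 0.5), 2)
  set <- make_set(refl, sample_id = c("a", "b"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(set, path)
  rt <- read_spectra(path, g)
  expect_equal(rt$reflectance, set$reflectance, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rt$meta$sample_id, c("a", "b"))
  expect_length(rt$grid$wavelengths, 206)
})

test_that("spectra reader rejects malformed files with located errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("sample_id,accession_id,treatment,block,replicate,R420,R425",
             path)
  expect_error(read_spectra(path), "no records")

  # 5-nm grid when 2-nm declared
  wl5 <- seq(420, 790, by = 5)
  df <- data.frame(sample_id = "s1", accession_id = "a1", treatment = "P5",
                   block = 1, replicate = 1)
  df[paste0("R", wl5)] <- 0.3
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_spectra(path, wavelength_grid(420, 790, 2)), "mismatch")

  # duplicate sample_id + replicate
  g <- wavelength_grid(420, 430, 2)
  df <- data.frame(sample_id = c("s1", "s1"), accession_id = "a1",
                   treatment = "P5", block = 1, replicate = 1)
  df[paste0("R", g$wavelengths)] <- 0.3
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_spectra(path, g), "duplicate")
})

test_that("percent-scale reflectance is detected and rescaled", {
  refl <- matrix(runif(3 * 206, 5, 50), 3)  # percent scale
  expect_warning(set <- make_set(refl), "percent")
  expect_true(all(set$reflectance <= 0.5))
})

test_that("replicate averaging is the channelwise mean and is idempotent", {
  g <- wavelength_grid(420, 428, 2)
  refl <- rbind(rep(0.2, 5), rep(0.4, 5), rep(0.3, 5))
  set <- make_set(refl, sample_id = c("s1", "s1", "s2"),
                  replicate = c(1L, 2L, 1L), grid = g)
  avg <- average_replicates(set)
  expect_equal(nrow(avg$meta), 2)
  expect_equal(unname(avg$reflectance[1, 1]), 0.3)
  expect_equal(unname(avg$reflectance[2, 1]), 0.3)  # single replicate passes
  expect_equal(average_replicates(avg)$reflectance, avg$reflectance)

  # 10 samples x 2 replicates -> 10 records
  refl2 <- matrix(runif(20 * 5, 0.1, 0.5), 20)
  set2 <- make_set(refl2, sample_id = rep(paste0("p", 1:10), each = 2),
                   replicate = rep(1:2, 10), grid = g)
  expect_equal(nrow(average_replicates(set2)$meta), 10)
})

test_that("noisy-band exclusion truncates 206 channels to 186", {
  set <- make_set(matrix(0.3, 2, 206))
  cut <- exclude_noisy_band(set)
  expect_length(cut$grid$wavelengths, 186)
  expect_equal(cut$grid$start, 420)
  ident <- exclude_noisy_band(set, 380, 790)
  expect_equal(ident$reflectance, set$reflectance)
  expect_error(exclude_noisy_band(set, 800, 900), "empty")

  # commutes with replicate averaging
  refl <- matrix(runif(4 * 206, 0.1, 0.5), 4)
  reps <- make_set(refl, sample_id = c("a", "a", "b", "b"),
                   replicate = c(1L, 2L, 1L, 2L))
  expect_equal(
    exclude_noisy_band(average_replicates(reps))$reflectance,
    average_replicates(exclude_noisy_band(reps))$reflectance)
})

test_that("standardization uses training statistics only", {
  g <- wavelength_grid(420, 438, 2)
  train <- make_set(matrix(runif(8 * 10, 0.1, 0.6), 8), grid = g)
  out <- standardize_spectra(train)
  expect_equal(unname(colMeans(out$set$reflectance)), rep(0, 10),
               tolerance = 1e-9)
  expect_equal(unname(apply(out$set$reflectance, 2, sd)), rep(1, 10),
               tolerance = 1e-9)

  # applying to new data uses the train center/scale, not its own
  new <- make_set(matrix(runif(4 * 10, 0.4, 0.9), 4),
                  sample_id = paste0("n", 1:4), grid = g)
  ap <- standardize_spectra(train, new)
  manual <- sweep(sweep(new$reflectance, 2, out$center, "-"), 2, out$scale, "/")
  expect_equal(ap$set$reflectance, manual)
  expect_false(all(abs(colMeans(ap$set$reflectance)) < 0.1))

  single <- make_set(matrix(0.3, 1, 10), grid = g)
  expect_error(standardize_spectra(single), "2 training spectra")
  const <- make_set(cbind(matrix(runif(8 * 9), 8), 0.25), grid = g)
  expect_error(standardize_spectra(const), "R438")
})

test_that("within-spectrum correlation is symmetric with unit diagonal", {
  g <- wavelength_grid(420, 428, 2)
  base <- runif(6, 0.1, 0.3)
  refl <- cbind(base, 2 * base, matrix(runif(6 * 3, 0.1, 0.5), 6))
  set <- make_set(refl, grid = g)
  cm <- within_spectrum_correlation(set)
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), rep(1, 5))
  expect_true(all(cm >= -1 & cm <= 1))
  expect_equal(unname(cm[1, 2]), 1)  # monotone pair
  expect_error(within_spectrum_correlation(make_set(refl[1:2, , drop = FALSE],
                                                    grid = g)),
               "at least 3")
})

test_that("VIS and NIR form coherent, weakly cross-linked correlation blocks", {
  set <- exclude_noisy_band(average_replicates(small_panel()$spectra))
  cm <- within_spectrum_correlation(set)
  wl <- set$grid$wavelengths
  vis <- wl >= 430 & wl <= 700
  nir <- wl >= 740 & wl <= 790
  within_vis <- cm[vis, vis][upper.tri(cm[vis, vis])]
  cross <- as.vector(cm[vis, nir])
  expect_gt(median(within_vis), median(cross))
})
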