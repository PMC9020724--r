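test_that("loss functions reproduce their hand-computed values", {
  expect_equal(classification_loss(matrix(c(1, 0, 0), 1), 1L), 0,
               tolerance = 1e-9)
  expect_equal(classification_loss(matrix(rep(1 / 3, 3), 1), 2L), log(3),
               tolerance = 1e-9)
  expect_equal(classification_loss(matrix(c(0.5, 0.25, 0.25), 1), 1L),
               log(2), tolerance = 1e-9)
  expect_message(
    expect_equal(classification_loss(matrix(c(0, 1, 0), 1), 1L),
                 -log(1e-12), tolerance = 1e-6),
    "clamped")

  x <- matrix(runif(2 * 10), 2)
  expect_equal(reconstruction_loss(x, x), 0)
  one <- matrix(0.5, 1, 10)
  expect_equal(reconstruction_loss(one, one + 0.1), 0.01, tolerance = 1e-12)
  # two samples with per-sample MSE 0.01 and 0.03 sum to 0.04
  obs <- matrix(0, 2, 4)
  rec <- rbind(rep(0.1, 4), rep(sqrt(0.03), 4))
  expect_equal(reconstruction_loss(obs, rec), 0.04, tolerance = 1e-12)
  expect_error(reconstruction_loss(matrix(0, 2, 3), matrix(0, 2, 4)),
               "shapes")

  expect_equal(combined_loss(1.0, 0.4), 1.2)
  expect_equal(combined_loss(0.7, 5, recon_weight = 0), 0.7)
  expect_equal(combined_loss(0, 0), 0)
})

test_that("the model emits proper class distributions and reconstructions", {
  cfg <- spec_cnn_config(input_channels = 186, multitask = TRUE)
  model <- build_spec_cnn(cfg, seed = 2)
  X <- matrix(rnorm(5 * 186), 5)
  fw <- specphos:::spec_cnn_forward(model, X)
  expect_equal(unname(rowSums(fw$output)), rep(1, 5), tolerance = 1e-6)
  expect_true(all(fw$output >= 0))
  expect_equal(dim(fw$recon), dim(X))
  # encoder block sizes: (16, k8) then (32, k8)
  expect_equal(dim(model$params$conv1_W), c(8L, 16L))
  expect_equal(dim(model$params$conv2_W), c(8L * 16L, 32L))
  expect_equal(cfg$pooled_length, (186 - 4) %/% 3 + 1)

  reg <- build_spec_cnn(spec_cnn_config(head = "regress"), seed = 2)
  fw_r <- specphos:::spec_cnn_forward(reg, X)
  expect_length(fw_r$output, 5)

  expect_error(spec_cnn_config(dropout_rate = 1), "dropout_rate")
  expect_error(spec_cnn_config(input_channels = 2), "pooling")
  expect_error(specphos:::spec_cnn_forward(model, matrix(0, 2, 10)),
               "channels")
})

test_that("analytic gradients match finite differences", {
  set.seed(1)
  cfg <- spec_cnn_config(input_channels = 20, fc_hidden = 6,
                         conv1_filters = 3, conv2_filters = 4,
                         multitask = TRUE, dropout_rate = 0)
  model <- build_spec_cnn(cfg, seed = 5)
  n <- 3
  X <- matrix(rnorm(n * 20), n)
  y <- c(1L, 3L, 2L)
  loss_fn <- function(m) {
    fw <- specphos:::spec_cnn_forward(m, X, training = TRUE)
    classification_loss(fw$output, y) +
      0.5 * reconstruction_loss(X, fw$recon) / n
  }
  fw <- specphos:::spec_cnn_forward(model, X, training = TRUE)
  dlogits <- fw$output
  dlogits[cbind(1:n, y)] <- dlogits[cbind(1:n, y)] - 1
  dlogits <- dlogits / n
  drecon <- 0.5 * 2 * (fw$recon - X) / (n * 20)
  gr <- specphos:::spec_cnn_backward(model, fw, dlogits, drecon)
  eps <- 1e-5
  for (nm in names(model$params)) {
    P <- model$params[[nm]]
    for (i in sample(length(P), min(3, length(P)))) {
      m2 <- model; m2$params[[nm]][i] <- P[i] + eps
      m3 <- model; m3$params[[nm]][i] <- P[i] - eps
      num <- (loss_fn(m2) - loss_fn(m3)) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4,
                   label = paste("grad", nm))
    }
  }
})

test_that("augmentation keeps flagged originals and unbiased noise", {
  x <- matrix(runif(3 * 10), 3)
  a0 <- augment_spectra(x, sd = 0, copies = 2)
  expect_equal(nrow(a0$x), 9)
  expect_equal(a0$x[4:9, ], rbind(x, x), ignore_attr = TRUE)
  expect_equal(a0$augmented, rep(c(FALSE, TRUE), c(3, 6)))

  one <- matrix(0.4, 1, 8)
  aa <- augment_spectra(one, sd = 0.01, copies = 10000, seed = 1)
  noisy_mean <- colMeans(aa$x[aa$augmented, , drop = FALSE])
  expect_true(all(abs(noisy_mean - 0.4) < 3 * 0.01 / sqrt(10000)))
})

test_that("splits are disjoint, exhaustive and respect accession grouping", {
  sp <- split_data(6258, c(0.7, 0.15, 0.15), seed = 4)
  expect_equal(sort(c(sp$train, sp$val, sp$test)), 1:6258)
  expect_lt(abs(length(sp$train) - 4379), 4)
  expect_lt(abs(length(sp$val) - 939), 4)
  expect_lt(abs(length(sp$test) - 940), 4)
  expect_identical(sp, split_data(6258, c(0.7, 0.15, 0.15), seed = 4))

  acc <- rep(paste0("A", 1:40), each = 9)
  gp <- split_data(accession = acc, seed = 7)
  for (pair in list(c("train", "val"), c("train", "test"), c("val", "test"))) {
    expect_length(intersect(unique(acc[gp[[pair[1]]]]),
                            unique(acc[gp[[pair[2]]]])), 0)
  }
  expect_equal(sort(c(gp$train, gp$val, gp$test)), seq_along(acc))

  big <- c(rep("A1", 95), rep("A2", 5))
  expect_error(split_data(accession = big, seed = 1), "training fraction")
  expect_error(split_data(100, c(0.5, 0.2, 0.2)), "summing to 1")
})

test_that("a zero reconstruction weight reproduces the single-task trajectory", {
  panel <- separable_panel()
  dat <- prepare_cnn_data(panel, "classify")
  idx <- seq_len(120)
  args <- list(x = dat$x[idx, ], y = dat$y[idx], task = "classify",
               epochs = 3, batch_size = 64, patience = 10, seed = 5,
               augment_copies = 1)
  single <- do.call(train_spec_cnn, c(args, multitask = FALSE))
  multi0 <- do.call(train_spec_cnn, c(args, multitask = TRUE,
                                      recon_weight = 0))
  expect_equal(multi0$history$train_loss, single$history$train_loss,
               tolerance = 1e-8)
  expect_equal(multi0$history$val_loss, single$history$val_loss,
               tolerance = 1e-8)
})

test_that("training is seed-reproducible and dropout is off at inference", {
  panel <- separable_panel()
  dat <- prepare_cnn_data(panel, "classify")
  idx <- seq_len(90)
  args <- list(x = dat$x[idx, ], y = dat$y[idx], task = "classify",
               epochs = 2, batch_size = 64, patience = 5, seed = 3)
  f1 <- do.call(train_spec_cnn, args)
  f2 <- do.call(train_spec_cnn, args)
  expect_identical(f1$history, f2$history)
  p1 <- predict(f1, dat$x[1:5, ])
  p2 <- predict(f1, dat$x[1:5, ])
  expect_identical(p1, p2)
  expect_equal(unname(rowSums(p1)), rep(1, 5), tolerance = 1e-6)
  # confusion matrix covers the full test split
  expect_equal(sum(f1$metrics$confusion), length(f1$split$test))
})
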