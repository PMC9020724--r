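#' Cross-entropy classification loss
#'
#' Categorical cross-entropy `-sum_i y_i log p_i` per sample, averaged over
#' the batch. Probabilities of the true class below 1e-12 are clamped (with
#' a message) so the loss stays finite.
#'
#' @param probs Matrix (n, K) of predicted class probabilities, rows on the
#'   simplex.
#' @param labels Integer class indices (1..K) or a factor of length n.
#' @return Non-negative scalar; 0 iff every true class has probability 1.
#' @export
classification_loss <- function(probs, labels) {
  probs <- rbind(probs)
  if (is.factor(labels)) labels <- as.integer(labels)
  if (length(labels) != nrow(probs)) stop_spec("probs/labels length mismatch")
  p_true <- probs[cbind(seq_len(nrow(probs)), labels)]
  if (any(p_true < 1e-12)) {
    message(sum(p_true < 1e-12),
            " true-class probabilities < 1e-12 clamped in cross-entropy")
    p_true <- pmax(p_true, 1e-12)
  }
  -mean(log(p_true))
}

#' Spectral reconstruction loss
#'
#' Sum over samples of the per-sample mean squared channel error:
#' `sum_i (1/n_channels) sum_j (s_ij - shat_ij)^2`.
#'
#' @param observed,reconstructed Matrices of identical shape
#'   (samples x channels).
#' @return Non-negative scalar; 0 iff the reconstruction is exact.
#' @export
reconstruction_loss <- function(observed, reconstructed) {
  observed <- rbind(observed)
  reconstructed <- rbind(reconstructed)
  if (!all(dim(observed) == dim(reconstructed))) {
    stop_spec("observed and reconstructed shapes differ")
  }
  sum(rowMeans((observed - reconstructed)^2))
}

#' Combined multi-task loss
#'
#' Classification weight 1.0, reconstruction weight `recon_weight`
#' (default 0.5).
#'
#' @param class_loss,recon_loss Non-negative loss terms.
#' @param recon_weight Reconstruction weight.
#' @return `class_loss + recon_weight * recon_loss`.
#' @export
combined_loss <- function(class_loss, recon_loss, recon_weight = 0.5) {
  1.0 * class_loss + recon_weight * recon_loss
}

#' Gaussian-noise augmentation of spectra
#'
#' Creates noisy copies of each spectrum by adding i.i.d. Gaussian noise
#' (SD `sd`, reflectance units) per channel. The originals are retained and
#' every row is flagged, so augmented rows can be confined to training and
#' excluded from any performance evaluation.
#'
#' @param x Spectra matrix (samples x channels).
#' @param sd Noise standard deviation.
#' @param copies Number of noisy copies per spectrum.
#' @param seed Optional seed for reproducible noise.
#' @return List: `x` ((1 + copies) * n rows, originals first), `augmented`
#'   (logical flag per row), `origin` (source row index per row).
#' @export
augment_spectra <- function(x, sd = 0.01, copies = 1, seed = NULL) {
  if (sd < 0) stop_spec("sd must be >= 0")
  copies <- check_count(copies, "copies", min = 0L)
  draw <- function() {
    out <- vector("list", copies)
    for (i in seq_len(copies)) {
      out[[i]] <- x + matrix(stats::rnorm(length(x), 0, sd), nrow(x))
    }
    out
  }
  noisy <- if (is.null(seed)) draw() else with_seed(seed, draw())
  list(
    x = do.call(rbind, c(list(x), noisy)),
    augmented = rep(c(FALSE, TRUE), c(nrow(x), copies * nrow(x))),
    origin = rep(seq_len(nrow(x)), 1L + copies)
  )
}

#' Train/validation/test split, optionally grouped by accession
#'
#' Splits sample indices into three disjoint, exhaustive sets. With
#' `group_by_accession = TRUE` (the convention for the Pi-regression task)
#' all samples of an accession land in the same set, so the test measures
#' generalization to unseen accessions; splits are then only approximately
#' at the requested fractions.
#'
#' @param n Number of samples, or ignored if `accession` is given.
#' @param fractions Length-3 numeric (train, val, test) summing to 1.
#' @param accession Optional accession ID per sample (length n).
#' @param group_by_accession Keep accessions intact across the split?
#' @param seed Seed for the shuffle.
#' @return List of integer index vectors `train`, `val`, `test`.
#' @export
split_data <- function(n = NULL, fractions = c(0.7, 0.15, 0.15),
                       accession = NULL, group_by_accession = !is.null(accession),
                       seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8 || length(fractions) != 3 ||
      any(fractions < 0)) {
    stop_spec("fractions must be 3 non-negative numbers summing to 1")
  }
  if (group_by_accession && is.null(accession)) {
    stop_spec("group_by_accession requires accession IDs")
  }
  n <- n %||% length(accession)
  if (!is.null(accession) && length(accession) != n) {
    stop_spec("accession length must equal n")
  }
  with_seed(seed, {
    if (!group_by_accession) {
      ord <- sample.int(n)
      n_train <- floor(n * fractions[1])
      n_val <- floor(n * fractions[2])
      list(train = sort(ord[seq_len(n_train)]),
           val = sort(ord[n_train + seq_len(n_val)]),
           test = sort(ord[(n_train + n_val + 1):n]))
    } else {
      acc <- as.character(accession)
      sizes <- table(acc)
      if (max(sizes) > ceiling(n * fractions[1])) {
        stop_spec("accession ", names(sizes)[which.max(sizes)],
                  " alone exceeds the training fraction")
      }
      shuffled <- sample(names(sizes))
      target <- n * fractions
      got <- c(0, 0, 0)
      assign_to <- integer(0)
      assignment <- stats::setNames(integer(length(shuffled)), shuffled)
      for (a in shuffled) {
        deficit <- (target - got) / pmax(target, 1e-12)
        j <- which.max(deficit)
        assignment[a] <- j
        got[j] <- got[j] + sizes[[a]]
      }
      grp <- unname(assignment[acc])
      list(train = which(grp == 1L), val = which(grp == 2L),
           test = which(grp == 3L))
    }
  })
}

#' Extract model-ready data from a synthetic panel
#'
#' Replicate-averages the spectra, drops the noisy 380--410 nm band, and
#' pairs each spectrum with its label (treatment) or regression target
#' (log10 Pi). The regression task uses only the deficient treatments
#' (P5 and P0.25), since including over-sufficient P100 plants — whose
#' surplus Pi sits in vacuolar storage and leaves the spectrum unchanged —
#' degrades the regression. Non-positive Pi values are excluded with a
#' message.
#'
#' @param panel A [generate_panel()] result, or a list with `spectra`
#'   ([spectrum_set()]) and `phenotypes`.
#' @param task `"classify"` or `"regress"`.
#' @param keep_start,keep_stop Retained wavelength range, nm.
#' @return List: `x` (reflectance matrix), `y` (factor or numeric),
#'   `accession` (per row), `wavelengths`.
#' @export
prepare_cnn_data <- function(panel, task = c("classify", "regress"),
                             keep_start = 420, keep_stop = 790) {
  task <- match.arg(task)
  set <- exclude_noisy_band(average_replicates(panel$spectra),
                            keep_start, keep_stop)
  ph <- panel$phenotypes
  idx <- match(set$meta$sample_id, ph$sample_id)
  if (anyNA(idx)) stop_spec("spectra contain sample_ids absent from phenotypes")
  ph <- ph[idx, , drop = FALSE]
  if (task == "classify") {
    keep <- rep(TRUE, nrow(ph))
    y <- as_treatment(ph$treatment)
  } else {
    keep <- ph$treatment %in% c("P5", "P0.25")
    bad <- keep & ph$pi_content <= 0
    if (any(bad)) {
      message(sum(bad), " samples with non-positive Pi excluded from regression")
      keep <- keep & !bad
    }
    y <- log10(ph$pi_content)
  }
  list(x = set$reflectance[keep, , drop = FALSE],
       y = if (task == "classify") y[keep] else y[keep],
       accession = ph$accession_id[keep],
       wavelengths = set$grid$wavelengths)
}

#' Train a 1D convolutional spectra model
#'
#' Fits the classification (P100/P5/P0.25) or log10-Pi regression model,
#' optionally with the multi-task reconstruction decoder. Training follows
#' the reference recipe: per-channel standardization using training-split
#' statistics only; Gaussian-noise augmentation (SD 0.01, fresh draws each
#' epoch) applied to training spectra only; Adam on mini-batches;
#' classification loss weight 1.0 and reconstruction weight
#' `recon_weight` (0.5); best epoch chosen by validation loss with early
#' stopping; metrics reported on the untouched test split.
#'
#' @param x Raw reflectance matrix (samples x channels), e.g. from
#'   [prepare_cnn_data()].
#' @param y Factor of class labels (classification) or numeric targets
#'   (regression, log10 Pi).
#' @param task `"classify"` or `"regress"`.
#' @param multitask Attach the spectral-reconstruction decoder?
#' @param accession Optional accession IDs; enables the grouped split.
#' @param split A [split_data()] result, or `NULL` to split here.
#' @param fractions,group_by_accession Passed to [split_data()] when
#'   `split` is `NULL`.
#' @param fc_hidden,dropout_rate,recon_weight Architecture settings (see
#'   [spec_cnn_config()]).
#' @param epochs,batch_size,lr,patience Optimization settings; early
#'   stopping monitors validation loss with the given patience.
#' @param augment_copies,augment_sd Noisy copies per training spectrum per
#'   epoch and their noise SD (reflectance units).
#' @param seed Root seed: weight initialization, splitting, augmentation,
#'   batch order and dropout all derive from it.
#' @param wavelengths Optional wavelength vector stored for attribution.
#' @param verbose Print per-epoch losses?
#' @return An object of class `spec_cnn_fit`: the trained `model`, the
#'   standardization `center`/`scale`, per-epoch `history`, `metrics` on
#'   the test split (accuracy + 3x3 confusion matrix, or R^2 + MAE),
#'   `split` indices, `best_epoch` and `seed`. Supports `print`,
#'   `summary`, `predict`, `plot` and [grad_cam()].
#' @export
train_spec_cnn <- function(x, y, task = c("classify", "regress"),
                           multitask = FALSE, accession = NULL,
                           split = NULL, fractions = c(0.7, 0.15, 0.15),
                           group_by_accession = !is.null(accession) &&
                             task == "regress",
                           fc_hidden = 64, dropout_rate = 0.2,
                           recon_weight = 0.5, epochs = 100,
                           batch_size = 64, lr = 1e-3, patience = 20,
                           augment_copies = 1, augment_sd = 0.01,
                           seed = 1L, wavelengths = NULL, verbose = FALSE) {
  task <- match.arg(task)
  x <- as.matrix(x)
  n <- nrow(x)
  if (task == "classify") {
    y <- as.factor(y)
    if (length(y) != n) stop_spec("x and y lengths differ")
    classes <- levels(y)
    yi <- as.integer(y)
  } else {
    if (!is.numeric(y) || length(y) != n) stop_spec("y must be numeric, length nrow(x)")
    classes <- NULL
    yi <- as.numeric(y)
  }
  split <- split %||% split_data(n, fractions, accession = accession,
                                 group_by_accession = group_by_accession,
                                 seed = sub_seed(seed, 1))
  cfg <- spec_cnn_config(
    input_channels = ncol(x), fc_hidden = fc_hidden,
    n_classes = if (task == "classify") length(classes) else 3L,
    dropout_rate = dropout_rate, multitask = multitask,
    recon_weight = recon_weight, head = task)
  model <- build_spec_cnn(cfg, seed = sub_seed(seed, 2))

  center <- colMeans(x[split$train, , drop = FALSE])
  scl <- apply(x[split$train, , drop = FALSE], 2, stats::sd)
  if (any(scl < 1e-12)) {
    stop_spec("zero-variance channel in training split at index ",
              which(scl < 1e-12)[1])
  }
  stdz <- function(m) sweep(sweep(m, 2, center, "-"), 2, scl, "/")
  x_val <- stdz(x[split$val, , drop = FALSE])
  x_test <- stdz(x[split$test, , drop = FALSE])
  y_val <- yi[split$val]; y_test <- yi[split$test]

  eval_loss <- function(mdl, xs, ys) {
    fw <- spec_cnn_forward(mdl, xs, training = FALSE)
    task_loss <- if (task == "classify") {
      classification_loss(fw$output, ys)
    } else {
      mean((fw$output - ys)^2)
    }
    if (multitask) {
      task_loss + recon_weight * reconstruction_loss(xs, fw$recon) / nrow(xs)
    } else task_loss
  }

  opt <- adam_init(model$params)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(val = Inf, params = model$params, bn = model$bn, epoch = 0L)
  wait <- 0L

  with_seed(sub_seed(seed, 3), {
    for (ep in seq_len(epochs)) {
      aug <- augment_spectra(x[split$train, , drop = FALSE],
                             sd = augment_sd, copies = augment_copies)
      xe <- stdz(aug$x)
      ye <- yi[split$train][aug$origin]
      ord <- sample.int(nrow(xe))
      ep_loss <- 0; n_seen <- 0
      for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
        xb <- xe[b, , drop = FALSE]
        yb <- ye[b]
        nb <- length(b)
        fw <- spec_cnn_forward(model, xb, training = TRUE)
        if (task == "classify") {
          loss <- classification_loss(fw$output, yb)
          dlogits <- fw$output
          dlogits[cbind(seq_len(nb), yb)] <- dlogits[cbind(seq_len(nb), yb)] - 1
          dlogits <- dlogits / nb
        } else {
          loss <- mean((fw$output - yb)^2)
          dlogits <- matrix(2 * (fw$output - yb) / nb, ncol = 1)
        }
        drecon <- NULL
        if (multitask) {
          loss <- loss + recon_weight * reconstruction_loss(xb, fw$recon) / nb
          drecon <- recon_weight * 2 * (fw$recon - xb) / (nb * ncol(xb))
        }
        if (!is.finite(loss)) {
          stop_spec("non-finite loss at epoch ", ep,
                    " (batch of ", nb, "); try a lower learning rate",
                    class = "specphos_train_error")
        }
        gr <- spec_cnn_backward(model, fw, dlogits, drecon)
        upd <- adam_step(model$params, gr, opt, lr = lr)
        model$params <- upd$params
        opt <- upd$state
        for (nm in names(fw$bn_updates)) {
          if (!is.null(fw$bn_updates[[nm]])) model$bn[[nm]] <- fw$bn_updates[[nm]]
        }
        ep_loss <- ep_loss + loss * nb
        n_seen <- n_seen + nb
      }
      val_loss <- eval_loss(model, x_val, y_val)
      history[nrow(history) + 1L, ] <- list(ep, ep_loss / n_seen, val_loss)
      if (verbose) {
        cat(sprintf("epoch %3d  train %.4f  val %.4f\n",
                    ep, ep_loss / n_seen, val_loss))
      }
      if (val_loss < best$val - 1e-6) {
        best <- list(val = val_loss, params = model$params, bn = model$bn,
                     epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  })
  model$params <- best$params
  model$bn <- best$bn

  fw_test <- spec_cnn_forward(model, x_test, training = FALSE)
  metrics <- if (task == "classify") {
    pred <- max.col(fw_test$output)
    cm <- table(factor(classes[y_test], levels = classes),
                factor(classes[pred], levels = classes),
                dnn = c("truth", "predicted"))
    list(accuracy = mean(pred == y_test), confusion = cm)
  } else {
    resid <- y_test - fw_test$output
    list(r_squared = 1 - sum(resid^2) / sum((y_test - mean(y_test))^2),
         mae = mean(abs(resid)))
  }

  structure(list(model = model, center = center, scale = scl,
                 classes = classes, task = task, multitask = multitask,
                 recon_weight = recon_weight, history = history,
                 metrics = metrics, split = split,
                 best_epoch = best$epoch, best_val_loss = best$val,
                 wavelengths = wavelengths, seed = seed),
            class = "spec_cnn_fit")
}

#' @export
print.spec_cnn_fit <- function(x, ...) {
  cat(sprintf("Trained spectra model: %s%s\n", x$task,
              if (x$multitask) " + reconstruction" else ""))
  cat(sprintf("  best epoch %d (val loss %.4f), %d/%d/%d train/val/test\n",
              x$best_epoch, x$best_val_loss, length(x$split$train),
              length(x$split$val), length(x$split$test)))
  if (x$task == "classify") {
    cat(sprintf("  test accuracy: %.4f\n", x$metrics$accuracy))
  } else {
    cat(sprintf("  test R-squared: %.4f   MAE: %.4f\n",
                x$metrics$r_squared, x$metrics$mae))
  }
  invisible(x)
}

#' @export
summary.spec_cnn_fit <- function(object, ...) {
  print(object)
  if (object$task == "classify") {
    cat("Confusion matrix (test):\n")
    print(object$metrics$confusion)
  }
  invisible(object)
}

#' @export
plot.spec_cnn_fit <- function(x, ...) {
  graphics::matplot(x$history$epoch,
                    cbind(x$history$train_loss, x$history$val_loss),
                    type = "l", lty = 1, col = c(1, 2),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("train", "validation"), col = c(1, 2), lty = 1)
  invisible(x)
}

#' Predict from a trained spectra model
#'
#' @param object A [train_spec_cnn()] fit.
#' @param newdata Raw reflectance matrix (samples x channels) or a
#'   [spectrum_set()] on the model's wavelength range; standardized
#'   internally with the stored training statistics.
#' @param type `"response"` (class probabilities or regression values),
#'   `"class"` (classification only).
#' @param ... Unused.
#' @export
predict.spec_cnn_fit <- function(object, newdata,
                                 type = c("response", "class"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "spectrum_set")) newdata$reflectance else as.matrix(newdata)
  xs <- sweep(sweep(x, 2, object$center, "-"), 2, object$scale, "/")
  fw <- spec_cnn_forward(object$model, xs, training = FALSE)
  if (object$task == "regress") return(fw$output)
  probs <- fw$output
  colnames(probs) <- object$classes
  if (type == "class") {
    factor(object$classes[max.col(probs)], levels = object$classes)
  } else probs
}

#' Gradient-weighted class activation maps over wavelengths
#'
#' Attributes a model decision to input wavelengths: the gradient of the
#' class score (or the regression output) is taken with respect to the
#' activations of the last convolutional block, the activations are
#' weighted by their gradients element-wise, and the result is summed over
#' feature maps to give a per-position importance signal. Keeping the
#' gradient weights at full positional resolution (rather than averaging
#' them over positions first) preserves localization when the
#' discriminative region is a narrow waveband. Only positions with a
#' positive effect on the targeted score are kept (rectification), and the
#' map is normalized to sum to 1 within each sample. Dropout is disabled,
#' so the map is deterministic; an all-zero map falls back to uniform with
#' a message. Because the convolutions preserve length, the map is already
#' at input resolution (it would otherwise be linearly interpolated up).
#'
#' @param fit A [train_spec_cnn()] result.
#' @param newdata Raw reflectance matrix or [spectrum_set()].
#' @param target Class index (or label) to explain; default is each
#'   sample's predicted class. Ignored for regression fits.
#' @return Matrix (samples x channels) of non-negative attributions, rows
#'   summing to 1; wavelengths as column names when known.
#' @export
grad_cam <- function(fit, newdata, target = NULL) {
  if (!inherits(fit, "spec_cnn_fit")) stop_spec("fit must be a spec_cnn_fit")
  x <- if (inherits(newdata, "spectrum_set")) newdata$reflectance else rbind(newdata)
  xs <- sweep(sweep(x, 2, fit$center, "-"), 2, fit$scale, "/")
  model <- fit$model
  cfg <- model$config
  fw <- spec_cnn_forward(model, xs, training = FALSE)
  n <- nrow(xs)
  if (fit$task == "classify") {
    if (is.null(target)) {
      tgt <- max.col(fw$output)
    } else {
      if (is.character(target)) target <- match(target, fit$classes)
      tgt <- rep_len(as.integer(target), n)
      if (anyNA(tgt) || any(tgt < 1) || any(tgt > cfg$n_out)) {
        stop_spec("invalid target class")
      }
    }
    dlogits <- matrix(0, n, cfg$n_out)
    dlogits[cbind(seq_len(n), tgt)] <- 1
  } else {
    dlogits <- matrix(1, n, 1)
  }
  p <- model$params
  ca <- fw$cache
  dh <- relu_bwd(dlogits %*% t(p$fc2_W), ca$h)
  dflat <- dh %*% t(p$fc1_W)
  dpool <- array(dflat, c(n, cfg$pooled_length, cfg$conv2_filters))
  dA <- avgpool_bwd(dpool, cfg$pool_window, cfg$pool_stride,
                    cfg$input_channels)
  # gradient-weighted activations, summed over feature maps at each position
  A <- fw$conv_features
  cam <- matrix(0, n, cfg$input_channels)
  for (kk in seq_len(cfg$conv2_filters)) {
    cam <- cam + matrix(dA[, , kk] * A[, , kk], n, cfg$input_channels)
  }
  cam[cam < 0] <- 0
  sums <- rowSums(cam)
  flat_rows <- sums <= 0
  if (any(flat_rows)) {
    message(sum(flat_rows), " all-zero activation map(s) set to uniform")
    cam[flat_rows, ] <- 1 / cfg$input_channels
    sums[flat_rows] <- 1
  }
  cam <- cam / sums
  if (!is.null(fit$wavelengths)) colnames(cam) <- fit$wavelengths
  cam
}
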