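#' Configure the 1D convolutional spectra model
#'
#' Architecture for classifying phosphorus-deficiency level (P100/P5/P0.25)
#' or regressing log10 Pi from a standardized reflectance spectrum. The
#' encoder is two convolutional blocks — (16 filters, kernel 8) then
#' (32 filters, kernel 8), each 1D convolution + batch normalization + ReLU
#' with length-preserving padding — followed by average pooling (window 4,
#' stride 3), flattening, and two fully connected layers (hidden width
#' `fc_hidden`, then `n_classes` class scores or one linear output for
#' regression) with dropout 0.2 before each.
#'
#' With `multitask = TRUE` a spectral-reconstruction decoder is attached to
#' the flattened encoding: a fully connected layer back to
#' `pooled_length x 32`, reshaped, then two blocks of (conv + batch norm +
#' ReLU + 2x nearest upsampling) with 32 and 16 filters (kernel 8), and a
#' final 1-filter convolution of kernel 4. The decoder's fully connected
#' width is derived from the encoder's actual pooled length at construction
#' time, and the upsampled output is mapped back onto the input grid by a
#' fixed linear interpolation, so the architecture is consistent for any
#' input length. The reconstruction objective pushes the encoding to retain
#' the whole spectrum, not only class-discriminative bands.
#'
#' @param input_channels Spectrum length (186 for 420--790 nm at 2 nm).
#' @param fc_hidden Width of the first fully connected layer (64 by default;
#'   the useful sweep range is roughly 32--1024).
#' @param n_classes Number of classes for the classification head.
#' @param dropout_rate Dropout probability before the dense layers.
#' @param multitask Attach the reconstruction decoder?
#' @param recon_weight Weight of the reconstruction term in the combined
#'   loss (classification keeps weight 1).
#' @param head `"classify"` or `"regress"`.
#' @param conv1_filters,conv2_filters,kernel_size,pool_window,pool_stride
#'   Encoder hyperparameters; defaults are the reference architecture.
#' @return An object of class `spec_cnn_config`.
#' @export
spec_cnn_config <- function(input_channels = 186, fc_hidden = 64,
                            n_classes = 3, dropout_rate = 0.2,
                            multitask = FALSE, recon_weight = 0.5,
                            head = c("classify", "regress"),
                            conv1_filters = 16, conv2_filters = 32,
                            kernel_size = 8, pool_window = 4,
                            pool_stride = 3) {
  head <- match.arg(head)
  cfg <- list(
    input_channels = check_count(input_channels, "input_channels"),
    fc_hidden = check_count(fc_hidden, "fc_hidden"),
    n_classes = check_count(n_classes, "n_classes"),
    dropout_rate = dropout_rate,
    multitask = isTRUE(multitask),
    recon_weight = check_nonneg(recon_weight, "recon_weight"),
    head = head,
    conv1_filters = check_count(conv1_filters, "conv1_filters"),
    conv2_filters = check_count(conv2_filters, "conv2_filters"),
    kernel_size = check_count(kernel_size, "kernel_size"),
    pool_window = check_count(pool_window, "pool_window"),
    pool_stride = check_count(pool_stride, "pool_stride")
  )
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_spec("dropout_rate must be in [0, 1)", class = "specphos_config_error")
  }
  if (cfg$input_channels < cfg$pool_window) {
    stop_spec("construction error at pooling layer: input length ",
              cfg$input_channels, " < window ", cfg$pool_window,
              class = "specphos_config_error")
  }
  cfg$pooled_length <-
    (cfg$input_channels - cfg$pool_window) %/% cfg$pool_stride + 1L
  cfg$flat_dim <- cfg$pooled_length * cfg$conv2_filters
  cfg$n_out <- if (head == "classify") cfg$n_classes else 1L
  structure(cfg, class = "spec_cnn_config")
}

he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

#' Build an untrained spectra model
#'
#' Initializes all weights (He initialization, seeded) for the architecture
#' described by [spec_cnn_config()].
#'
#' @param config A [spec_cnn_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `spec_cnn`: list with `config`, `params`
#'   (weights) and `bn` (batch-norm running statistics).
#' @export
build_spec_cnn <- function(config, seed = 1L) {
  stopifnot(inherits(config, "spec_cnn_config"))
  k <- config$kernel_size
  with_seed(seed, {
    params <- list(
      conv1_W = he_init(k * 1L, config$conv1_filters, k),
      conv1_b = numeric(config$conv1_filters),
      bn1_gamma = rep(1, config$conv1_filters),
      bn1_beta = numeric(config$conv1_filters),
      conv2_W = he_init(k * config$conv1_filters, config$conv2_filters,
                        k * config$conv1_filters),
      conv2_b = numeric(config$conv2_filters),
      bn2_gamma = rep(1, config$conv2_filters),
      bn2_beta = numeric(config$conv2_filters),
      fc1_W = he_init(config$flat_dim, config$fc_hidden, config$flat_dim),
      fc1_b = numeric(config$fc_hidden),
      fc2_W = he_init(config$fc_hidden, config$n_out, config$fc_hidden),
      fc2_b = numeric(config$n_out)
    )
    if (config$multitask) {
      params <- c(params, list(
        dec_fc_W = he_init(config$flat_dim, config$flat_dim, config$flat_dim),
        dec_fc_b = numeric(config$flat_dim),
        dconv1_W = he_init(k * config$conv2_filters, config$conv2_filters,
                           k * config$conv2_filters),
        dconv1_b = numeric(config$conv2_filters),
        dbn1_gamma = rep(1, config$conv2_filters),
        dbn1_beta = numeric(config$conv2_filters),
        dconv2_W = he_init(k * config$conv2_filters, config$conv1_filters,
                           k * config$conv2_filters),
        dconv2_b = numeric(config$conv1_filters),
        dbn2_gamma = rep(1, config$conv1_filters),
        dbn2_beta = numeric(config$conv1_filters),
        dconv3_W = he_init(4L * config$conv1_filters, 1L,
                           4L * config$conv1_filters),
        dconv3_b = numeric(1L)
      ))
    }
    bn_state <- list(
      bn1_mean = numeric(config$conv1_filters),
      bn1_var = rep(1, config$conv1_filters),
      bn2_mean = numeric(config$conv2_filters),
      bn2_var = rep(1, config$conv2_filters)
    )
    if (config$multitask) {
      bn_state <- c(bn_state, list(
        dbn1_mean = numeric(config$conv2_filters),
        dbn1_var = rep(1, config$conv2_filters),
        dbn2_mean = numeric(config$conv1_filters),
        dbn2_var = rep(1, config$conv1_filters)
      ))
      up_len <- 4L * config$pooled_length
      config$resize <- interp_matrix(up_len, config$input_channels)
    }
    structure(list(config = config, params = params, bn = bn_state),
              class = "spec_cnn")
  })
}

#' @export
print.spec_cnn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<spec_cnn> %s%s head, input %d channels\n", cfg$head,
              if (cfg$multitask) " + reconstruction" else "",
              cfg$input_channels))
  cat(sprintf("  conv(%d,k%d)-BN-ReLU | conv(%d,k%d)-BN-ReLU | avgpool(%d,%d) -> %d x %d\n",
              cfg$conv1_filters, cfg$kernel_size, cfg$conv2_filters,
              cfg$kernel_size, cfg$pool_window, cfg$pool_stride,
              cfg$pooled_length, cfg$conv2_filters))
  cat(sprintf("  fc %d -> %d -> %d (dropout %.1f)\n", cfg$flat_dim,
              cfg$fc_hidden, cfg$n_out, cfg$dropout_rate))
  cat(sprintf("  parameters: %d\n",
              sum(vapply(x$params, length, integer(1)))))
  invisible(x)
}

# Full forward pass. X is (n, input_channels). Returns output (class
# probabilities or regression values), logits, reconstruction, and the
# cache needed for the backward pass. Dropout consumes the current RNG
# stream, so callers wrap training in with_seed().
spec_cnn_forward <- function(model, X, training = FALSE) {
  cfg <- model$config
  p <- model$params
  n <- nrow(X)
  if (ncol(X) != cfg$input_channels) {
    stop_spec("input has ", ncol(X), " channels; model expects ",
              cfg$input_channels)
  }
  k <- cfg$kernel_size
  X3 <- array(X, c(n, cfg$input_channels, 1L))

  c1 <- conv1d_fwd(X3, p$conv1_W, p$conv1_b, k)
  b1 <- bn_fwd(c1$Y, p$bn1_gamma, p$bn1_beta, model$bn$bn1_mean,
               model$bn$bn1_var, training)
  a1 <- relu_fwd(b1$Y)
  c2 <- conv1d_fwd(a1, p$conv2_W, p$conv2_b, k)
  b2 <- bn_fwd(c2$Y, p$bn2_gamma, p$bn2_beta, model$bn$bn2_mean,
               model$bn$bn2_var, training)
  a2 <- relu_fwd(b2$Y)
  pl <- avgpool_fwd(a2, cfg$pool_window, cfg$pool_stride)
  flat <- matrix(pl$Y, n, cfg$flat_dim)

  dr1 <- dropout_fwd(flat, cfg$dropout_rate, training)
  h <- relu_fwd(dense_fwd(dr1$Y, p$fc1_W, p$fc1_b))
  dr2 <- dropout_fwd(h, cfg$dropout_rate, training)
  logits <- dense_fwd(dr2$Y, p$fc2_W, p$fc2_b)
  output <- if (cfg$head == "classify") softmax(logits) else logits[, 1L]

  recon <- NULL
  dec <- NULL
  if (cfg$multitask) {
    z <- dense_fwd(flat, p$dec_fc_W, p$dec_fc_b)
    z3 <- array(z, c(n, cfg$pooled_length, cfg$conv2_filters))
    dc1 <- conv1d_fwd(z3, p$dconv1_W, p$dconv1_b, k)
    db1 <- bn_fwd(dc1$Y, p$dbn1_gamma, p$dbn1_beta, model$bn$dbn1_mean,
                  model$bn$dbn1_var, training)
    da1 <- relu_fwd(db1$Y)
    u1 <- upsample2_fwd(da1)
    dc2 <- conv1d_fwd(u1, p$dconv2_W, p$dconv2_b, k)
    db2 <- bn_fwd(dc2$Y, p$dbn2_gamma, p$dbn2_beta, model$bn$dbn2_mean,
                  model$bn$dbn2_var, training)
    da2 <- relu_fwd(db2$Y)
    u2 <- upsample2_fwd(da2)
    dc3 <- conv1d_fwd(u2, p$dconv3_W, p$dconv3_b, 4L)
    up_out <- matrix(dc3$Y, n, dim(dc3$Y)[2])
    recon <- up_out %*% t(cfg$resize)
    dec <- list(z3 = z3, dc1 = dc1, db1 = db1, da1 = da1, u1 = u1,
                dc2 = dc2, db2 = db2, da2 = da2, u2 = u2, dc3 = dc3,
                up_out = up_out)
  }

  list(output = output, logits = logits, recon = recon,
       conv_features = a2,
       cache = list(X3 = X3, c1 = c1, b1 = b1, a1 = a1, c2 = c2, b2 = b2,
                    a2 = a2, pl = pl, flat = flat, dr1 = dr1, h = h,
                    dr2 = dr2, dec = dec, n = n),
       bn_updates = list(
         bn1_mean = b1$run_mean, bn1_var = b1$run_var,
         bn2_mean = b2$run_mean, bn2_var = b2$run_var,
         dbn1_mean = if (cfg$multitask) dec_bn(dec, "db1", "run_mean"),
         dbn1_var = if (cfg$multitask) dec_bn(dec, "db1", "run_var"),
         dbn2_mean = if (cfg$multitask) dec_bn(dec, "db2", "run_mean"),
         dbn2_var = if (cfg$multitask) dec_bn(dec, "db2", "run_var")))
}

dec_bn <- function(dec, layer, field) if (is.null(dec)) NULL else dec[[layer]][[field]]

# Backward pass: dlogits is (n, n_out) gradient of the loss wrt the final
# dense output; drecon (n, input_channels) or NULL. Returns gradients for
# every parameter.
spec_cnn_backward <- function(model, fw, dlogits, drecon = NULL) {
  cfg <- model$config
  p <- model$params
  ca <- fw$cache
  n <- ca$n
  k <- cfg$kernel_size
  g <- list()

  d2 <- dense_bwd(dlogits, ca$dr2$Y, p$fc2_W)
  g$fc2_W <- d2$dW; g$fc2_b <- d2$db
  dh <- dropout_bwd(d2$dX, ca$dr2$mask)
  dh <- relu_bwd(dh, ca$h)
  d1 <- dense_bwd(dh, ca$dr1$Y, p$fc1_W)
  g$fc1_W <- d1$dW; g$fc1_b <- d1$db
  dflat <- dropout_bwd(d1$dX, ca$dr1$mask)

  if (cfg$multitask && !is.null(drecon)) {
    dec <- ca$dec
    dup_out <- drecon %*% cfg$resize
    ddc3 <- array(dup_out, c(n, ncol(dup_out), 1L))
    bb3 <- conv1d_bwd(ddc3, dec$dc3$Xcol, p$dconv3_W, 4L, n,
                      dim(dec$u2)[2], cfg$conv1_filters)
    g$dconv3_W <- bb3$dW; g$dconv3_b <- bb3$db
    du2 <- upsample2_bwd(bb3$dX)
    du2 <- relu_bwd(du2, dec$da2)
    bnb2 <- bn_bwd(du2, dec$db2$cache, p$dbn2_gamma)
    g$dbn2_gamma <- bnb2$dgamma; g$dbn2_beta <- bnb2$dbeta
    bb2 <- conv1d_bwd(bnb2$dX, dec$dc2$Xcol, p$dconv2_W, k, n,
                      dim(dec$u1)[2], cfg$conv2_filters)
    g$dconv2_W <- bb2$dW; g$dconv2_b <- bb2$db
    du1 <- upsample2_bwd(bb2$dX)
    du1 <- relu_bwd(du1, dec$da1)
    bnb1 <- bn_bwd(du1, dec$db1$cache, p$dbn1_gamma)
    g$dbn1_gamma <- bnb1$dgamma; g$dbn1_beta <- bnb1$dbeta
    bb1 <- conv1d_bwd(bnb1$dX, dec$dc1$Xcol, p$dconv1_W, k, n,
                      cfg$pooled_length, cfg$conv2_filters)
    g$dconv1_W <- bb1$dW; g$dconv1_b <- bb1$db
    dz <- matrix(bb1$dX, n, cfg$flat_dim)
    dfc <- dense_bwd(dz, ca$flat, p$dec_fc_W)
    g$dec_fc_W <- dfc$dW; g$dec_fc_b <- dfc$db
    dflat <- dflat + dfc$dX
  }

  dpool <- array(dflat, c(n, cfg$pooled_length, cfg$conv2_filters))
  da2 <- avgpool_bwd(dpool, cfg$pool_window, cfg$pool_stride,
                     cfg$input_channels)
  da2 <- relu_bwd(da2, ca$a2)
  bnb <- bn_bwd(da2, ca$b2$cache, p$bn2_gamma)
  g$bn2_gamma <- bnb$dgamma; g$bn2_beta <- bnb$dbeta
  cb2 <- conv1d_bwd(bnb$dX, ca$c2$Xcol, p$conv2_W, k, n,
                    cfg$input_channels, cfg$conv1_filters)
  g$conv2_W <- cb2$dW; g$conv2_b <- cb2$db
  da1 <- relu_bwd(cb2$dX, ca$a1)
  bnb1e <- bn_bwd(da1, ca$b1$cache, p$bn1_gamma)
  g$bn1_gamma <- bnb1e$dgamma; g$bn1_beta <- bnb1e$dbeta
  cb1 <- conv1d_bwd(bnb1e$dX, ca$c1$Xcol, p$conv1_W, k, n,
                    cfg$input_channels, 1L)
  g$conv1_W <- cb1$dW; g$conv1_b <- cb1$db
  g$input <- matrix(cb1$dX, n, cfg$input_channels)
  g
}
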