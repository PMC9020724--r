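#' Fit a constrained exponential-decay calibration curve
#'
#' Models a reflectance characteristic (a single band or a band ratio) as a
#' function of leaf Pi content:
#' \deqn{y = a + b \, e^{-c \cdot Pi}}
#' by least squares with box constraints `a >= -1` (reflectance-derived
#' responses are bounded) and `c >= 0` (the curve must be a decay); `b` is
#' free, its sign encoding whether the response rises (`b < 0`) or falls
#' (`b > 0`) with decreasing Pi. The decay form captures the sharp spectral
#' response below ~0.1 nmol/mm^2 Pi and the saturation above ~0.2.
#'
#' Data points with Pi below `trim_below` (default 0.02 nmol/mm^2) are
#' dropped before fitting, as measurements that low are dominated by assay
#' noise.
#'
#' The objective is non-convex, so the optimizer is multi-started: the
#' initial offset is `min(y)` (or `max(y)` when the Pi-response rank
#' correlation is positive, i.e. the curve rises towards an upper asymptote),
#' the initial multiplier is the signed response range, and the initial rate
#' is `1/median(Pi)` scaled by 0.1, 1 and 10; the start with the lowest
#' residual sum of squares wins. Fitting uses `stats::nls` (`"port"`
#' algorithm, honoring the bounds) with an `optim(L-BFGS-B)` fallback.
#'
#' @param pi_content Pi contents, nmol/mm^2 (> 0).
#' @param response Response values, same length.
#' @param trim_below Pi trimming threshold; points with `pi < trim_below`
#'   are excluded (the boundary value is kept).
#' @param level Provenance label, `"individual"` or `"accession"`; stored on
#'   the result.
#' @return An object of class `decay_fit` with components `coefficients`
#'   (named `a`, `b`, `c`), `vcov` (3x3, from the final Jacobian),
#'   `r_squared`, `sigma`, `n_used`, `n_input`, `fitted.values`,
#'   `residuals`, `data` (trimmed `pi_content`/`response`), `trim_below`,
#'   `level`. Supports `print`, `summary`, `coef`, `vcov`, `predict`,
#'   `fitted`, `residuals`, `plot` and `simulate`.
#' @examples
#' pi <- seq(0.03, 0.5, length.out = 50)
#' y <- 0.5 + 2 * exp(-10 * pi)
#' fit <- fit_decay(pi, y)
#' coef(fit) # ~ (0.5, 2, 10)
#' @export
fit_decay <- function(pi_content, response, trim_below = 0.02,
                      level = c("individual", "accession")) {
  level <- match.arg(level)
  if (length(pi_content) != length(response)) {
    stop_spec("pi_content and response lengths differ")
  }
  ok <- is.finite(pi_content) & is.finite(response)
  if (any(pi_content[ok] <= 0)) {
    stop_spec("pi_content must be positive", class = "specphos_fit_error")
  }
  n_input <- sum(ok)
  keep <- ok & pi_content >= trim_below
  x <- pi_content[keep]
  y <- response[keep]
  n <- length(x)
  if (n < 4) {
    stop_spec("need at least 4 points after trimming (have ", n, ")",
              class = "specphos_fit_error")
  }
  if (max(x) - min(x) < 1e-6) {
    stop_spec("degenerate Pi range after trimming",
              class = "specphos_fit_error")
  }

  rho <- suppressWarnings(stats::cor(x, y, method = "spearman"))
  if (!is.finite(rho)) rho <- 0
  rng <- max(y) - min(y)
  if (rho > 0) {
    a0 <- max(y); b0 <- -max(rng, 1e-8)
  } else {
    a0 <- min(y); b0 <- max(rng, 1e-8)
  }
  a0 <- max(a0, -1)
  c0 <- 1 / stats::median(x)
  starts <- lapply(c(0.1, 1, 10), function(f) c(a = a0, b = b0, c = c0 * f))

  ss <- function(p) sum((y - p[1] - p[2] * exp(-p[3] * x))^2)
  best <- NULL
  for (st in starts) {
    # convergence warnings from individual starts are expected noise: every
    # candidate is polished and judged on its residual sum of squares
    fit <- tryCatch(
      suppressWarnings(
        stats::nls(y ~ a + b * exp(-c * x), start = as.list(st),
                   lower = c(a = -1, b = -Inf, c = 0), upper = rep(Inf, 3),
                   algorithm = "port",
                   control = stats::nls.control(maxiter = 1000,
                                                warnOnly = TRUE))),
      error = function(e) NULL)
    p <- if (!is.null(fit)) stats::coef(fit) else NULL
    if (is.null(p)) {
      op <- tryCatch(
        stats::optim(st, ss, method = "L-BFGS-B",
                     lower = c(-1, -Inf, 0), upper = rep(Inf, 3),
                     control = list(maxit = 10000, factr = 1e2)),
        error = function(e) NULL)
      p <- if (!is.null(op)) op$par else NULL
    }
    if (!is.null(p)) {
      # polish: a short bounded refinement from the candidate
      op2 <- tryCatch(
        stats::optim(p, ss, method = "L-BFGS-B",
                     lower = c(-1, -Inf, 0), upper = rep(Inf, 3),
                     control = list(maxit = 10000, factr = 1e2)),
        error = function(e) NULL)
      if (!is.null(op2) && op2$value <= ss(p)) p <- op2$par
      val <- ss(p)
      if (is.null(best) || val < best$ss) best <- list(par = p, ss = val)
    }
  }
  if (is.null(best)) {
    stop_spec("decay fit failed from all starts", class = "specphos_fit_error")
  }

  p <- stats::setNames(as.numeric(best$par), c("a", "b", "c"))
  fitted <- p["a"] + p["b"] * exp(-p["c"] * x)
  resid <- y - fitted
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  sigma2 <- ss_res / max(n - 3, 1)
  ez <- exp(-p["c"] * x)
  J <- cbind(a = rep(1, n), b = ez, c = -p["b"] * x * ez)
  vc <- tryCatch(sigma2 * solve(crossprod(J)),
                 error = function(e) matrix(NA_real_, 3, 3))
  dimnames(vc) <- list(c("a", "b", "c"), c("a", "b", "c"))

  structure(list(
    coefficients = p, vcov = vc, r_squared = unname(r2),
    sigma = sqrt(sigma2), n_used = n, n_input = n_input,
    fitted.values = unname(fitted), residuals = unname(resid),
    data = data.frame(pi_content = x, response = y),
    trim_below = trim_below, level = level,
    ss_res = unname(ss_res)
  ), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Exponential-decay calibration (%s level)\n", x$level))
  cat("  response = a + b * exp(-c * Pi)\n")
  print(round(x$coefficients, digits))
  cat(sprintf("  R-squared: %.*f   n used: %d (of %d; trim Pi < %g)\n",
              digits, x$r_squared, x$n_used, x$n_input, x$trim_below))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) object$coefficients

#' @export
vcov.decay_fit <- function(object, ...) object$vcov

#' @export
fitted.decay_fit <- function(object, ...) object$fitted.values

#' @export
residuals.decay_fit <- function(object, ...) object$residuals

#' Summary of a decay calibration fit
#'
#' Adds standard errors (from the Jacobian-based covariance) and the
#' coefficient of variation of each estimate (CV% = 100 * SE / |estimate|),
#' the fit-quality measure used to judge whether accession-level parameters
#' are stable.
#'
#' @param object A [fit_decay()] result.
#' @param ... Unused.
#' @export
summary.decay_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  tab <- data.frame(
    estimate = object$coefficients,
    std_error = se,
    cv_pct = 100 * se / abs(object$coefficients)
  )
  out <- list(coefficients = tab, r_squared = object$r_squared,
              sigma = object$sigma, n_used = object$n_used,
              level = object$level)
  class(out) <- "summary.decay_fit"
  out
}

#' @export
print.summary.decay_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Exponential-decay calibration (%s level), n = %d\n",
              x$level, x$n_used))
  print(round(x$coefficients, digits))
  cat(sprintf("R-squared: %.*f   residual sigma: %.*g\n",
              digits, x$r_squared, digits, x$sigma))
  invisible(x)
}

#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$pi_content
       else if (is.numeric(newdata)) newdata
       else newdata$pi_content
  p <- object$coefficients
  unname(p["a"] + p["b"] * exp(-p["c"] * x))
}

#' @export
simulate.decay_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n_used
  out <- as.data.frame(replicate(nsim, object$fitted.values +
                                   stats::rnorm(n, 0, object$sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.decay_fit <- function(x, ...) {
  ord <- order(x$data$pi_content)
  graphics::plot(x$data$pi_content, x$data$response,
                 xlab = "Pi content (nmol/mm^2)", ylab = "response",
                 main = sprintf("decay fit (R2 = %.2f)", x$r_squared), ...)
  graphics::lines(x$data$pi_content[ord], x$fitted.values[ord], col = 2, lwd = 2)
  invisible(x)
}

#' Decay calibration at individual-plant or accession level
#'
#' Extracts the response named by `key` from the spectra (a ratio such as
#' `"R750/R700"` or a single wavelength in nm), pairs it with per-plant Pi
#' content, restricts to the deficient treatments (P5 and P0.25 by default,
#' pooled into one regression), and fits [fit_decay()]. At `"accession"`
#' level, Pi and response are first averaged within each accession-by-
#' treatment cell and the cell means are fitted; averaging removes much of
#' the plant-to-plant scatter, so accession-level fits are typically much
#' tighter than individual-level ones.
#'
#' @param set A [spectrum_set()] (technical replicates averaged internally).
#' @param phenotypes data.frame with `sample_id`, `accession_id`,
#'   `treatment`, `pi_content`.
#' @param key Ratio label `"R<nir>/R<vis>"` or a single wavelength (nm).
#' @param level `"individual"` or `"accession"`.
#' @param treatments Treatments pooled into the regression.
#' @param trim_below Pi trimming threshold (see [fit_decay()]).
#' @return A [fit_decay()] object.
#' @export
fit_by_level <- function(set, phenotypes, key,
                         level = c("individual", "accession"),
                         treatments = c("P5", "P0.25"),
                         trim_below = 0.02) {
  level <- match.arg(level)
  set <- average_replicates(set)
  idx <- match(set$meta$sample_id, phenotypes$sample_id)
  if (anyNA(idx)) stop_spec("spectra contain sample_ids absent from phenotypes")
  ph <- phenotypes[idx, , drop = FALSE]
  response <- extract_response(set, key)
  keep <- ph$treatment %in% treatments
  pi_v <- ph$pi_content[keep]
  resp <- response[keep]
  if (level == "accession") {
    cell <- interaction(ph$accession_id[keep], ph$treatment[keep], drop = TRUE)
    pi_v <- as.numeric(tapply(pi_v, cell, mean))
    resp <- as.numeric(tapply(resp, cell, mean))
  }
  fit_decay(pi_v, resp, trim_below = trim_below, level = level)
}

extract_response <- function(set, key) {
  wl <- set$grid$wavelengths
  if (is.numeric(key)) {
    i <- match(key, wl)
    if (is.na(i)) stop_spec("wavelength ", key, " not on the grid")
    return(set$reflectance[, i])
  }
  m <- regmatches(key, regexec("^R([0-9]+)/R([0-9]+)$", key))[[1]]
  if (length(m) != 3) stop_spec("key must be a wavelength or 'R<nir>/R<vis>'")
  i <- match(as.numeric(m[2]), wl)
  j <- match(as.numeric(m[3]), wl)
  if (is.na(i) || is.na(j)) stop_spec("ratio bands of ", key, " not on the grid")
  set$reflectance[, i] / set$reflectance[, j]
}
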