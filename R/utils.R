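# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_spec <- function(..., class = "specphos_error", call. = FALSE) {
  cond <- structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = NULL)
  )
  stop(cond)
}

#' Evaluate code with a fixed RNG state, then restore the caller's state
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_spec("'seed' must be a single integer")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic stream splitting: child seeds derived from one root seed so
# that independent stages never share an RNG stream. Kept below 2^31 - 1.
sub_seed <- function(root, k) {
  root <- as.double(root)
  as.integer((root * 48271 + 7919 * as.double(k)) %% 2147483629) + 1L
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop_spec(sprintf("'%s' must be an integer >= %d", name, min),
              class = "specphos_config_error")
  }
  as.integer(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    stop_spec(sprintf("'%s' must be a single non-negative number", name),
              class = "specphos_config_error")
  }
  as.numeric(x)
}

TREATMENTS <- c("P100", "P5", "P0.25")

as_treatment <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), TREATMENTS)
  if (length(bad) > 0) {
    stop_spec("unknown treatment label(s): ", paste(bad, collapse = ", "))
  }
  factor(x, levels = TREATMENTS)
}
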