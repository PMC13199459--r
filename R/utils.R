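# Internal helpers shared across modules: classed conditions, seed
# sub-streams, quasi-random sequences and Gauss-Hermite rules.

stop_schema <- function(msg, ...) {
  abort(msg, class = "fevcrash_schema_error", ...)
}

stop_parameter <- function(msg, ...) {
  abort(msg, class = "fevcrash_parameter_error", ...)
}

stop_validation <- function(msg, ...) {
  abort(msg, class = "fevcrash_validation_error", ...)
}

stop_config <- function(msg, ...) {
  abort(msg, class = "fevcrash_config_error", ...)
}

# One master seed -> independent integer sub-seeds, so that e.g. covariate
# sampling, random-coefficient draws and latent noise use separate streams.
# Sub-seeds stay below .Machine$integer.max (2^31 - 1).
seed_substreams <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_parameter(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    stop_parameter(sprintf(
      "`%s` must lie in [%s, %s], got %s.", name,
      format(lower), format(upper), format(x)
    ))
  }
  invisible(x)
}

check_columns_present <- function(data, cols, what = "column") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    stop_schema(sprintf(
      "Missing %s%s: %s.", what, if (length(missing) > 1L) "s" else "",
      paste0("`", missing, "`", collapse = ", ")
    ))
  }
  invisible(data)
}

#' Van der Corput / Halton radical-inverse sequence
#'
#' Returns the first `n` points (after skipping `burn` initial points) of the
#' one-dimensional Halton sequence in the given prime base, i.e. the radical
#' inverse of the integers `burn + 1, ..., burn + n`.  In base 2 the sequence
#' begins 1/2, 1/4, 3/4, 1/8, 5/8, ...
#'
#' @param n Number of points.
#' @param base Integer base (a prime; default 2).
#' @param burn Number of initial points to discard (default 0).
#' @return Numeric vector of `n` values in (0, 1).
#' @examples
#' halton_sequence(5)
#' @export
halton_sequence <- function(n, base = 2L, burn = 0L) {
  n <- as.integer(n)
  base <- as.integer(base)
  burn <- as.integer(burn)
  if (n < 1L) stop_parameter("`n` must be at least 1.")
  if (base < 2L) stop_parameter("`base` must be at least 2.")
  idx <- burn + seq_len(n)
  out <- numeric(n)
  n_digits <- ceiling(log(max(idx) + 1) / log(base))
  denom <- 1
  for (b in seq_len(n_digits)) {
    denom <- denom * base
    out <- out + ((idx %/% (denom / base)) %% base) / denom
  }
  out
}

# Gauss-Hermite nodes/weights (physicists' convention: integrates
# exp(-x^2) f(x)) via the Golub-Welsch eigen decomposition of the Jacobi
# matrix.  Used by the quadrature likelihood oracle.
gauss_hermite <- function(n) {
  n <- as.integer(n)
  if (n < 1L) stop_parameter("`nodes` must be at least 1.")
  if (n == 1L) {
    return(list(nodes = 0, weights = sqrt(pi)))
  }
  off <- sqrt(seq_len(n - 1L) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- off
  J[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- off
  eig <- eigen(J, symmetric = TRUE)
  ord <- order(eig$values)
  list(
    nodes = eig$values[ord],
    weights = sqrt(pi) * eig$vectors[1L, ord]^2
  )
}

# Standardized CDF/PDF pair used throughout the ordered model.  "logistic"
# is the canonical choice (it is what makes the ordered model a logit);
# "gumbel" is exposed for sensitivity analyses.
latent_cdf <- function(x, cdf = c("logistic", "gumbel")) {
  cdf <- match.arg(cdf)
  if (cdf == "logistic") plogis(x) else exp(-exp(-x))
}

latent_pdf <- function(x, cdf = c("logistic", "gumbel")) {
  cdf <- match.arg(cdf)
  if (cdf == "logistic") dlogis(x) else exp(-x - exp(-x))
}

severity_labels <- function() c("PDO", "Injury", "Fatal")
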