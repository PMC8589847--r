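#' Logistic mixing probability of the ZIP model
#'
#' The zero-inflation structure depends on the effective distance through a
#' logistic function, `q_s = 1 / (1 + exp(b1 - b2 d*))`: with `b2 > 0`, `q_s`
#' increases with distance from the source. How `q_s` maps to the
#' Poisson-component weight is set by the `zip_weight` convention of the
#' model spec (see [model_spec()]).
#'
#' @param d_star effective distance(s) in meters.
#' @param b1,b2 logistic intercept and distance slope.
#' @return Probabilities in (0, 1).
#' @export
mixing_weight <- function(d_star, b1, b2) {
  stats::plogis(-(b1 - b2 * d_star))
}

#' Zero-inflated Poisson probability mass function
#'
#' Mixture of a point mass at zero and a Poisson distribution:
#' `P(Y = 0) = (1 - w) + w exp(-lambda)` and `P(Y = y) = w Pois(y; lambda)`
#' for `y > 0`, where `w` is the Poisson-component weight.
#'
#' @param y non-negative integer count(s).
#' @param w Poisson-component weight(s) in \[0, 1\].
#' @param lambda Poisson mean(s), >= 0.
#' @param log return log probabilities?
#' @return Probability (or log probability) of each `y`.
#' @examples
#' dzip(0, w = 0.5, lambda = 1)  # 0.5 + 0.5 * exp(-1)
#' @export
dzip <- function(y, w, lambda, log = FALSE) {
  if (any(y < 0) || any(y != round(y))) {
    stop("y must be non-negative integers", call. = FALSE)
  }
  stopifnot(all(w >= 0 & w <= 1), all(lambda >= 0))
  n <- max(length(y), length(w), length(lambda))
  y <- rep_len(y, n); w <- rep_len(w, n); lambda <- rep_len(lambda, n)
  lp <- log(w) + stats::dpois(y, lambda, log = TRUE)
  zero <- y == 0
  if (any(zero)) {
    # log((1-w) + w e^-lambda), stable when either component underflows
    a <- log1p(-w[zero])
    b <- log(w[zero]) - lambda[zero]
    m <- pmax(a, b)
    lz <- ifelse(is.infinite(m) & m < 0, -Inf,
                 m + log(exp(a - m) + exp(b - m)))
    lp[zero] <- lz
  }
  if (log) lp else exp(lp)
}

#' Draw from the zero-inflated Poisson distribution
#'
#' @param n number of draws.
#' @param w Poisson-component weight(s).
#' @param lambda Poisson mean(s).
#' @return Integer vector of counts.
#' @export
rzip <- function(n, w, lambda) {
  stopifnot(all(w >= 0 & w <= 1), all(lambda >= 0))
  pois <- stats::runif(n) < w
  out <- integer(n)
  out[pois] <- stats::rpois(sum(pois), rep_len(lambda, n)[pois])
  out
}

# per-record model quantities: d*, gamma, lambda, and w for ZIP specs
model_moments <- function(dataset, spec, params) {
  spec <- model_spec(spec)
  params <- check_params(params, spec)
  d_star <- effective_distance(dataset$distance, dataset$fb_width, spec)
  g <- kernel_value(d_star, dataset$fb_width, spec, params)
  lambda <- expected_cp_grains(g, k_grains(dataset))
  w <- NULL
  if (spec$obs == "zip") {
    q <- mixing_weight(d_star, params[["b1"]], params[["b2"]])
    w <- if (spec$zip_weight == "complement") 1 - q else q
  }
  list(d_star = d_star, gamma = g, lambda = lambda, w = w)
}

# fast log-likelihood closure: precomputes effective distances, sqrt(FB) and
# observed counts once; used inside the optimiser, the sampler and DIC where
# the same dataset is evaluated many thousands of times. Parameter validation
# is the caller's job; zero-probability observations yield -Inf, not an error.
make_loglik <- function(dataset, spec) {
  spec <- model_spec(spec)
  d_star <- effective_distance(dataset$distance, dataset$fb_width, spec)
  sfb <- sqrt(dataset$fb_width)
  y <- dataset$cp_grains
  zero <- y == 0
  K <- k_grains(dataset)
  is_expo <- spec$kernel == "expo"
  is_zip <- spec$obs == "zip"
  complement <- spec$zip_weight == "complement"
  fb_on <- spec$fb_effect
  function(p) {
    g <- if (is_expo) {
      near <- d_star <= p[["D"]]
      out <- numeric(length(d_star))
      out[near] <- p[["Ke"]] * exp(-p[["a1"]] * d_star[near])
      out[!near] <- p[["Ke"]] * exp(-p[["a1"]] * p[["D"]] -
                                      p[["a2"]] * (d_star[!near] - p[["D"]]))
      out
    } else {
      near <- d_star <= p[["D"]]
      out <- numeric(length(d_star))
      out[near] <- p[["beta"]]^2 + d_star[near]^2
      out[!near] <- p[["beta"]]^2 + p[["D"]]^2 +
        p[["c1"]] * (d_star[!near] - p[["D"]])^2
      2 * p[["beta"]] / (pi * out)
    }
    if (fb_on) g <- g * exp(-p[["k"]] * sfb)
    lambda <- K * g
    if (is_zip) {
      q <- stats::plogis(-(p[["b1"]] - p[["b2"]] * d_star))
      w <- if (complement) 1 - q else q
      lp <- log(w) + stats::dpois(y, lambda, log = TRUE)
      if (any(zero)) {
        a <- log1p(-w[zero]); b <- log(w[zero]) - lambda[zero]
        m <- pmax(a, b)
        lp[zero] <- ifelse(is.infinite(m) & m < 0, -Inf,
                           m + log(exp(a - m) + exp(b - m)))
      }
      sum(lp)
    } else {
      sum(stats::dpois(y, lambda, log = TRUE))
    }
  }
}

#' Log-likelihood of a dispersal model on a dataset
#'
#' Composes the kernel chain (effective distance, pollen density, expected
#' count `lambda = K * gamma`) with the observation model and sums the log
#' probability mass of the observed per-cob CP grain counts.
#'
#' @param dataset an `fb_dataset`.
#' @param spec model specification (or code).
#' @param params named parameter vector for `spec`.
#' @return The log-likelihood (scalar). `-Inf` is returned when some
#'   observation has probability zero under the parameters; `NaN`/`NA`
#'   intermediates raise an error naming the offending record.
#' @export
log_likelihood <- function(dataset, spec, params) {
  spec <- model_spec(spec)
  mm <- model_moments(dataset, spec, params)
  y <- dataset$cp_grains
  lp <- if (spec$obs == "zip") {
    dzip(y, mm$w, mm$lambda, log = TRUE)
  } else {
    stats::dpois(y, mm$lambda, log = TRUE)
  }
  if (any(is.na(lp))) {
    i <- which(is.na(lp))[1L]
    stop(sprintf("non-finite log-likelihood contribution at record %d (y=%d, lambda=%g)",
                 i, y[i], mm$lambda[i]), call. = FALSE)
  }
  sum(lp)
}
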