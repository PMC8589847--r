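#' Compound exponential dispersal kernel
#'
#' Relative donor pollen density at effective distance `d*` from the nearest
#' source. The decline is exponential with rate `a1` out to a break distance
#' `D` and continues with a (usually smaller) rate `a2` beyond it, so the
#' kernel is continuous at `D`:
#' \deqn{\gamma(d^*) = K_e e^{-a_1 d^*} \quad (d^* \le D), \qquad
#'       \gamma(d^*) = K_e e^{-a_1 D - a_2 (d^* - D)} \quad (d^* > D).}
#' With the field-border effect the whole kernel is attenuated by
#' \eqn{e^{-k\sqrt{FB}}}, an exponential decrease of first-row pollen density
#' in the square root of the border width.
#'
#' @param d_star effective distance(s) in meters, >= 0 (see
#'   [effective_distance()]).
#' @param fb_width field-border width(s) in meters.
#' @param params named vector/list with `Ke`, `a1`, `a2`, `D` (all > 0) and,
#'   if `fb_effect`, `k` (>= 0).
#' @param fb_effect apply the FB attenuation factor?
#' @return Pollen density gamma, a non-negative dimensionless vector.
#' @examples
#' kernel_expo(0, 0, c(Ke = 0.676, a1 = 0.6073, a2 = 0.0506, k = 0.3552, D = 2.848),
#'             fb_effect = TRUE)  # = Ke
#' @export
kernel_expo <- function(d_star, fb_width = 0, params, fb_effect = TRUE) {
  p <- as.list(unlist(params))
  if (any(d_star < 0)) stop("d_star must be >= 0", call. = FALSE)
  g <- ifelse(d_star <= p$D,
              p$Ke * exp(-p$a1 * d_star),
              p$Ke * exp(-p$a1 * p$D - p$a2 * (d_star - p$D)))
  if (fb_effect) g <- g * exp(-p$k * sqrt(fb_width))
  g
}

#' Modified Cauchy dispersal kernel
#'
#' A fat-tailed kernel built on the Cauchy density, modified so that beyond a
#' break distance `D` the quadratic term grows with a separate coefficient
#' `c1`, which slows (c1 < 1) or speeds the decline of pollen density at
#' longer range:
#' \deqn{\gamma(d^*) = \frac{2\beta}{\pi[\beta^2 + {d^*}^2]} \quad (d^* \le D), \qquad
#'       \gamma(d^*) = \frac{2\beta}{\pi[\beta^2 + D^2 + c_1 (d^* - D)^2]} \quad (d^* > D),}
#' with the same \eqn{e^{-k\sqrt{FB}}} field-border factor as the
#' exponential kernel when `fb_effect` is on.
#'
#' @inheritParams kernel_expo
#' @param params named vector/list with `beta`, `c1`, `D` (> 0) and, if
#'   `fb_effect`, `k` (>= 0).
#' @return Pollen density gamma, non-negative.
#' @export
kernel_cauchy <- function(d_star, fb_width = 0, params, fb_effect = TRUE) {
  p <- as.list(unlist(params))
  if (any(d_star < 0)) stop("d_star must be >= 0", call. = FALSE)
  denom <- ifelse(d_star <= p$D,
                  p$beta^2 + d_star^2,
                  p$beta^2 + p$D^2 + p$c1 * (d_star - p$D)^2)
  g <- 2 * p$beta / (pi * denom)
  if (fb_effect) g <- g * exp(-p$k * sqrt(fb_width))
  g
}

# dispatch on the spec's kernel family; params validated upstream
kernel_value <- function(d_star, fb_width, spec, params) {
  if (spec$kernel == "expo") {
    kernel_expo(d_star, fb_width, params, fb_effect = spec$fb_effect)
  } else {
    kernel_cauchy(d_star, fb_width, params, fb_effect = spec$fb_effect)
  }
}

#' Expected CP grain count at a location
#'
#' The kernel output is a relative donor pollen density; multiplying by the
#' average grain number per cob K gives the expected number of
#' cross-pollinated grains on a cob at that location: `lambda = K * gamma`.
#'
#' @param gamma kernel value(s), >= 0.
#' @param k_grains average grain number per cob (K), positive.
#' @return Expected CP grain count(s) `lambda`.
#' @examples
#' expected_cp_grains(0.25, 400)  # 100
#' @export
expected_cp_grains <- function(gamma, k_grains) {
  stopifnot(is.numeric(gamma), all(gamma >= 0),
            is.numeric(k_grains), length(k_grains) == 1L, k_grains > 0)
  k_grains * gamma
}

#' Model-mean predicted CP rate at given locations
#'
#' The predicted CP rate at a location is the observation-model mean count
#' expressed as a percentage of K: `100 * E[Y]/K`. For Poisson models this is
#' `100 * gamma`; for ZIP models the mean is deflated by the
#' Poisson-component weight `w`, giving `100 * w * gamma`.
#'
#' @param spec model specification (or code).
#' @param params named parameter vector for `spec`.
#' @param distance raw distance(s) in meters (FB included).
#' @param fb_width FB width(s) in meters.
#' @param clip clip the reported rate to \[0, 100\]? The kernel itself is not
#'   normalised, so predicted rates can marginally exceed 100 near the
#'   source; clipping affects reporting only.
#' @return Predicted CP rate(s) in percent.
#' @export
predict_cp <- function(spec, params, distance, fb_width, clip = TRUE) {
  spec <- model_spec(spec)
  params <- check_params(params, spec)
  d_star <- effective_distance(distance, fb_width, spec)
  g <- kernel_value(d_star, fb_width, spec, params)
  mean_frac <- if (spec$obs == "zip") {
    q <- mixing_weight(d_star, params[["b1"]], params[["b2"]])
    w <- if (spec$zip_weight == "complement") 1 - q else q
    w * g
  } else {
    g
  }
  out <- 100 * mean_frac
  if (clip) out <- pmin(pmax(out, 0), 100)
  out
}
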