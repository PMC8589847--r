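#' MCMC run settings
#'
#' The `"paper"` profile mirrors the published analysis: 500,000 iterations,
#' 450,000 burn-in, thinning 25 (2,000 retained draws) and 200,000
#' posterior-predictive samples. The `"test"` profile (default) is a scaled
#' version for routine use: 20,000 iterations, 10,000 burn-in, thinning 5,
#' 20,000 predictive draws.
#'
#' @param n_iter total Markov chain iterations.
#' @param burn_in iterations discarded (and used for proposal adaptation).
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param seed integer seed; the full chain is reproducible from it.
#' @param adapt adapt proposal scales during burn-in (frozen afterwards)?
#' @param proposal_scale optional named vector of initial random-walk
#'   standard deviations on the transformed scale.
#' @param n_predictive posterior-predictive sample size used by
#'   [posterior_predictive_band()] when not overridden there.
#' @param profile `"test"` or `"paper"`; explicit arguments override the
#'   profile values.
#' @return A list of class `fb_mcmc_settings`.
#' @export
mcmc_settings <- function(n_iter = NULL, burn_in = NULL, thin = NULL,
                          seed = 1, adapt = TRUE, proposal_scale = NULL,
                          n_predictive = NULL,
                          profile = c("test", "paper")) {
  profile <- match.arg(profile)
  def <- if (profile == "paper") {
    list(n_iter = 5e5, burn_in = 4.5e5, thin = 25, n_predictive = 2e5)
  } else {
    list(n_iter = 2e4, burn_in = 1e4, thin = 5, n_predictive = 2e4)
  }
  s <- list(
    n_iter = if (is.null(n_iter)) def$n_iter else n_iter,
    burn_in = if (is.null(burn_in)) def$burn_in else burn_in,
    thin = if (is.null(thin)) def$thin else thin,
    seed = as.integer(seed),
    adapt = isTRUE(adapt),
    proposal_scale = proposal_scale,
    n_predictive = if (is.null(n_predictive)) def$n_predictive else n_predictive,
    profile = profile
  )
  stopifnot(s$burn_in < s$n_iter, s$thin >= 1)
  class(s) <- "fb_mcmc_settings"
  s
}

#' Componentwise adaptive random-walk Metropolis sampler
#'
#' Generic Metropolis sampler used by [run_mcmc()] and usable on any target
#' log-density. One parameter is updated at a time with a Gaussian random
#' walk; during burn-in each proposal scale is tuned toward a 44% acceptance
#' rate (the optimal rate for one-dimensional updates) and frozen at the end
#' of burn-in, so the retained chain is a valid Markov chain.
#'
#' @param log_post function of a numeric parameter vector returning the log
#'   target density (may be `-Inf`).
#' @param init numeric initial parameter vector (finite log-posterior).
#' @param settings an [mcmc_settings()] object.
#' @return List with `draws` (matrix, retained draws by parameters),
#'   `acceptance_rate` (post-burn-in, overall), `scales` (final proposal
#'   scales) and `settings`.
#' @export
adaptive_metropolis <- function(log_post, init, settings = mcmc_settings()) {
  p <- length(init)
  lp <- log_post(init)
  if (!is.finite(lp)) {
    stop("log posterior is not finite at the initial point; ",
         "initialise from the MLE", call. = FALSE)
  }
  set.seed(settings$seed)
  scales <- settings$proposal_scale
  if (is.null(scales)) scales <- rep(0.1, p)
  scales <- rep_len(scales, p)
  n_keep <- (settings$n_iter - settings$burn_in) %/% settings$thin
  draws <- matrix(NA_real_, n_keep, p)
  if (!is.null(names(init))) colnames(draws) <- names(init)
  theta <- init
  acc_win <- integer(p); try_win <- integer(p)
  acc_post <- 0L; try_post <- 0L
  kept <- 0L
  adapt_every <- 50L
  for (it in seq_len(settings$n_iter)) {
    for (j in seq_len(p)) {
      prop <- theta
      prop[j] <- prop[j] + stats::rnorm(1, sd = scales[j])
      lp_prop <- log_post(prop)
      accept <- is.finite(lp_prop) && (log(stats::runif(1)) < lp_prop - lp)
      if (accept) { theta <- prop; lp <- lp_prop }
      if (it <= settings$burn_in) {
        try_win[j] <- try_win[j] + 1L
        acc_win[j] <- acc_win[j] + accept
      } else {
        try_post <- try_post + 1L
        acc_post <- acc_post + accept
      }
    }
    if (settings$adapt && it <= settings$burn_in && it %% adapt_every == 0L) {
      rate <- ifelse(try_win > 0, acc_win / pmax(try_win, 1L), 0.44)
      scales <- scales * exp(1.5 * (rate - 0.44))
      scales <- pmin(pmax(scales, 1e-5), 10)
      acc_win[] <- 0L; try_win[] <- 0L
    }
    if (it > settings$burn_in && (it - settings$burn_in) %% settings$thin == 0L) {
      kept <- kept + 1L
      draws[kept, ] <- theta
    }
  }
  list(draws = draws,
       acceptance_rate = acc_post / max(try_post, 1L),
       scales = scales,
       settings = settings)
}

#' Bayesian estimation of a ZIP dispersal model
#'
#' Samples the posterior of one of the four ZIP dispersal models with a
#' componentwise adaptive random-walk Metropolis algorithm on the
#' transformed parameter scale. The default "noninformative" prior is flat
#' on the log of each positivity-constrained parameter and flat on `b1`,
#' `b2`, with wide guard bounds (|log param| <= 20, |b| <= 100) keeping the
#' posterior proper in practice.
#'
#' @param dataset an `fb_dataset`.
#' @param spec a ZIP model specification or code (`ZExpoN`, `ZExpoB`,
#'   `ZCauchyN`, `ZCauchyB`).
#' @param settings an [mcmc_settings()] object.
#' @param init `"mle"` (default: a quick maximum-likelihood fit supplies the
#'   starting point) or a named parameter vector.
#' @param log_prior optional function of the transformed parameter vector
#'   returning a log prior density, replacing the flat default.
#' @return An object of class `fb_posterior`: list with `draws` (retained
#'   draws on the natural scale), `posterior_mean`, `posterior_sd`, `dic`,
#'   `acceptance_rate`, `spec`, `settings` and `k_grains`.
#' @export
run_mcmc <- function(dataset, spec, settings = mcmc_settings(),
                     init = "mle", log_prior = NULL) {
  spec <- model_spec(spec)
  if (spec$obs != "zip") {
    stop("Bayesian estimation is provided for the ZIP models ",
         "(ZExpoN, ZExpoB, ZCauchyN, ZCauchyB); got ", spec$code,
         call. = FALSE)
  }
  nm <- param_names(spec)
  start <- if (identical(init, "mle")) {
    fit_mle(dataset, spec, n_starts = 3, seed = settings$seed)$estimates
  } else {
    check_params(init, spec)
  }
  th0 <- to_transformed(start, spec)
  ll_fun <- make_loglik(dataset, spec)
  log_post <- function(theta) {
    names(theta) <- nm
    if (!transformed_in_bounds(theta, spec)) return(-Inf)
    ll <- ll_fun(from_transformed(theta, spec))
    if (!is.finite(ll)) return(-Inf)
    if (!is.null(log_prior)) ll <- ll + log_prior(theta)
    ll
  }
  chain <- adaptive_metropolis(log_post, th0, settings)
  nat <- t(apply(chain$draws, 1, function(th) {
    from_transformed(stats::setNames(th, nm), spec)
  }))
  colnames(nat) <- nm
  res <- structure(list(
    draws = nat,
    posterior_mean = colMeans(nat),
    posterior_sd = apply(nat, 2, stats::sd),
    dic = NA_real_,
    acceptance_rate = chain$acceptance_rate,
    proposal_scales = chain$scales,
    spec = spec,
    settings = settings,
    k_grains = k_grains(dataset)
  ), class = "fb_posterior")
  res$dic <- dic(res, dataset)
  res
}

#' @export
print.fb_posterior <- function(x, digits = 4, ...) {
  cat("Posterior for", x$spec$code,
      sprintf("(%d retained draws, acceptance %.2f)\n",
              nrow(x$draws), x$acceptance_rate))
  print(round(rbind(mean = x$posterior_mean, sd = x$posterior_sd), digits))
  cat(sprintf("DIC %.2f\n", x$dic))
  invisible(x)
}

#' Deviance information criterion
#'
#' `DIC = Dbar + pD` with `Dbar` the posterior mean deviance and
#' `pD = Dbar - D(theta_bar)` the effective number of parameters evaluated
#' at the posterior mean on the sampling (natural) scale — the classical
#' Spiegelhalter form.
#'
#' @param result an `fb_posterior`.
#' @param dataset the dataset the posterior was fitted to.
#' @return The DIC (scalar), with attributes `p_d` and `mean_deviance`.
#'   A negative `pD` (poorly identified posterior) triggers a warning but
#'   the value is still returned.
#' @export
dic <- function(result, dataset) {
  ll_fun <- make_loglik(dataset, result$spec)
  dev <- -2 * apply(result$draws, 1, ll_fun)
  dbar <- mean(dev)
  dhat <- -2 * ll_fun(result$posterior_mean)
  p_d <- dbar - dhat
  if (p_d < 0) warning("negative effective parameter count pD = ",
                       signif(p_d, 3), "; posterior poorly identified",
                       call. = FALSE)
  structure(dbar + p_d, p_d = p_d, mean_deviance = dbar)
}

#' Posterior-predictive credible band for the CP rate
#'
#' For each distance on a grid, repeatedly (i) draw a parameter vector from
#' the retained posterior draws with replacement, (ii) simulate a per-cob CP
#' grain count from the observation model at that distance, and (iii)
#' convert it to a CP rate as `100 * y / K`. The band is the empirical 2.5th
#' and 97.5th percentile of the simulated rates and `mean_cp` their average.
#'
#' @param result an `fb_posterior`.
#' @param distance_grid raw distances (m, FB included) to predict at.
#' @param fb_width FB width of the field condition being predicted (scalar).
#' @param k_grains average grains per cob; defaults to the fitted dataset's.
#' @param n_draws number of posterior-predictive samples per distance
#'   (>= 1000); defaults to the settings' `n_predictive`.
#' @param cobs_per_grid if > 1, predict the CP rate of a grid mean of that
#'   many cobs instead of a single cob.
#' @return An object of class `fb_band`: data.frame with columns `distance`,
#'   `fb_width`, `mean_cp`, `lower_2_5`, `upper_97_5`, `n_draws`.
#' @export
posterior_predictive_band <- function(result, distance_grid, fb_width,
                                      k_grains = NULL, n_draws = NULL,
                                      cobs_per_grid = 1L) {
  stopifnot(inherits(result, "fb_posterior"))
  if (is.null(k_grains)) k_grains <- result$k_grains
  if (is.null(n_draws)) n_draws <- result$settings$n_predictive
  if (n_draws < 1000) stop("n_draws must be >= 1000", call. = FALSE)
  spec <- result$spec
  set.seed(result$settings$seed + 1L)
  rows <- lapply(distance_grid, function(d) {
    d_star <- effective_distance(d, fb_width, spec)   # errors if below valid range
    i <- sample.int(nrow(result$draws), n_draws, replace = TRUE)
    dr <- result$draws[i, , drop = FALSE]
    if (spec$kernel == "expo") {
      g <- ifelse(d_star <= dr[, "D"],
                  dr[, "Ke"] * exp(-dr[, "a1"] * d_star),
                  dr[, "Ke"] * exp(-dr[, "a1"] * dr[, "D"] -
                                     dr[, "a2"] * (d_star - dr[, "D"])))
    } else {
      g <- ifelse(d_star <= dr[, "D"],
                  2 * dr[, "beta"] / (pi * (dr[, "beta"]^2 + d_star^2)),
                  2 * dr[, "beta"] / (pi * (dr[, "beta"]^2 + dr[, "D"]^2 +
                                              dr[, "c1"] * (d_star - dr[, "D"])^2)))
    }
    if (spec$fb_effect) g <- g * exp(-dr[, "k"] * sqrt(fb_width))
    lam <- k_grains * g
    q <- mixing_weight(d_star, dr[, "b1"], dr[, "b2"])
    w <- if (spec$zip_weight == "complement") 1 - q else q
    ysim <- if (cobs_per_grid > 1L) {
      rowMeans(matrix(rzip(n_draws * cobs_per_grid,
                           rep(w, cobs_per_grid), rep(lam, cobs_per_grid)),
                      nrow = n_draws))
    } else {
      rzip(n_draws, w, lam)
    }
    cp <- 100 * ysim / k_grains
    qs <- stats::quantile(cp, c(0.025, 0.975), names = FALSE, type = 7)
    data.frame(distance = d, fb_width = fb_width, mean_cp = mean(cp),
               lower_2_5 = qs[1], upper_97_5 = qs[2], n_draws = n_draws)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fb_band", "data.frame")
  out
}

#' Plot a posterior-predictive CP band
#'
#' @param x an `fb_band`.
#' @param observed optional data.frame with `distance` and `cp_pct` columns
#'   (e.g. from [grid_summary()]) overlaid as points.
#' @param ... passed to [plot()].
#' @export
plot.fb_band <- function(x, observed = NULL, ...) {
  ylim <- range(0, x$upper_97_5, if (!is.null(observed)) observed$cp_pct)
  plot(x$distance, x$mean_cp, type = "n", ylim = ylim,
       xlab = "Distance from donor (m)", ylab = "CP rate (%)", ...)
  graphics::polygon(c(x$distance, rev(x$distance)),
                    c(x$lower_2_5, rev(x$upper_97_5)),
                    col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  graphics::lines(x$distance, x$mean_cp, col = "steelblue4", lwd = 2)
  if (!is.null(observed)) {
    graphics::points(observed$distance, observed$cp_pct, pch = 16, cex = 0.6)
  }
  invisible(x)
}
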