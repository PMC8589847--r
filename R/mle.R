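# ---- parameter transforms -------------------------------------------------
# positivity-constrained parameters are optimised on the log scale; the
# logistic coefficients b1, b2 stay on the natural scale

to_transformed <- function(params, spec) {
  pos <- param_positive(spec)
  th <- params
  # k = 0 is a valid boundary value; keep it strictly inside on the log scale
  th[pos] <- log(pmax(params[pos], 1e-8))
  th
}

from_transformed <- function(theta, spec) {
  pos <- param_positive(spec)
  p <- theta
  p[pos] <- exp(theta[pos])
  p
}

# guard bounds on the transformed scale keep the optimiser and the flat
# "noninformative" posterior proper in practice
GUARD_LOG <- 20
GUARD_B <- 100

transformed_in_bounds <- function(theta, spec) {
  pos <- param_positive(spec)
  all(abs(theta[pos]) <= GUARD_LOG) && all(abs(theta[!pos]) <= GUARD_B)
}

neg_loglik_factory <- function(dataset, spec) {
  nm <- param_names(spec)
  ll_fun <- make_loglik(dataset, spec)
  function(theta) {
    names(theta) <- nm
    if (!transformed_in_bounds(theta, spec)) return(1e12)
    ll <- ll_fun(from_transformed(theta, spec))
    if (!is.finite(ll)) return(1e12)
    -ll
  }
}

# ---- automatic initialisation ---------------------------------------------
# rough moment-based starting values: decline rate from a log-linear
# regression of nonzero grid CP rates on distance, source strength from the
# first-row CP rate, FB coefficient from the first-row ratio between
# experiments with and without a border

auto_init <- function(dataset, spec) {
  spec <- model_spec(spec)
  gs <- grid_summary(dataset)
  frac <- gs$cp_pct / 100
  nz <- frac > 0
  a1 <- 0.5
  if (sum(nz) >= 3 && stats::var(gs$distance[nz]) > 0) {
    sl <- stats::coef(stats::lm(log(frac[nz]) ~ gs$distance[nz]))[[2]]
    if (is.finite(sl) && sl < 0) a1 <- min(max(-sl, 0.02), 5)
  }
  # first-row CP fraction per experiment
  first <- do.call(rbind, lapply(split(gs, gs$experiment_id), function(g) {
    g[which.min(g$distance), c("fb_width", "cp_pct")]
  }))
  src <- min(max(max(first$cp_pct) / 100, 1e-3), 2)
  k0 <- 0.3
  has_fb <- first$fb_width > 0
  if (any(has_fb) && any(!has_fb)) {
    ratio <- mean(first$cp_pct[has_fb]) / max(mean(first$cp_pct[!has_fb]), 1e-6)
    fbw <- mean(first$fb_width[has_fb])
    if (is.finite(ratio) && ratio > 0 && ratio < 1) {
      k0 <- min(max(-log(ratio) / sqrt(fbw), 0.01), 2)
    }
  }
  init <- if (spec$kernel == "expo") {
    c(Ke = src, a1 = a1, a2 = a1 / 5)
  } else {
    c(beta = min(max(2 / (pi * src), 0.2), 10), c1 = 0.3)
  }
  if (spec$fb_effect) init <- c(init, k = k0)
  init <- c(init, D = 3)
  if (spec$obs == "zip") init <- c(init, b1 = 2, b2 = 0.03)
  init[param_names(spec)]
}

# ---- maximum-likelihood fitting -------------------------------------------

#' Fit a dispersal model by maximum likelihood
#'
#' Maximises the per-cob log-likelihood of one of the eight dispersal models
#' over its free parameters. Positivity-constrained parameters are optimised
#' on the log scale. A multi-start strategy (the base initial values plus
#' jittered copies) guards against local optima; each start is run through
#' Nelder-Mead and polished with BFGS, and the best likelihood wins (ties
#' broken by the smaller transformed-parameter norm).
#'
#' @param dataset an `fb_dataset`.
#' @param spec model specification or code (one of [MODEL_CODES]).
#' @param init `"auto"` (moment-based starting values, see Details in the
#'   methods vignette) or a named parameter vector.
#' @param n_starts number of optimiser starts (>= 1); starts beyond the first
#'   jitter the initial values on the transformed scale.
#' @param jitter_sd standard deviation of the transformed-scale jitter.
#' @param maxit maximum Nelder-Mead iterations per start.
#' @param reltol relative convergence tolerance on the objective.
#' @param seed optional seed making the jittered starts reproducible.
#' @return An object of class `fb_fit`: list with `spec`, `estimates`
#'   (natural scale), `log_likelihood`, `aic`, `deviance`, `r_squared`
#'   (grid-level, see [fit_metrics()]), `converged`, `n_obs`, `k_grains`,
#'   `n_params` and `starts` (per-start diagnostics).
#' @export
fit_mle <- function(dataset, spec, init = "auto", n_starts = 5,
                    jitter_sd = 0.3, maxit = 3000, reltol = 1e-10,
                    seed = NULL) {
  spec <- model_spec(spec)
  if (nrow(dataset) == 0L) stop("empty dataset", call. = FALSE)
  nm <- param_names(spec)
  base <- if (identical(init, "auto")) auto_init(dataset, spec)
          else check_params(init, spec)
  th0 <- to_transformed(base, spec)
  nll <- neg_loglik_factory(dataset, spec)
  if (!is.null(seed)) set.seed(seed)
  starts <- c(list(th0), lapply(seq_len(max(0L, n_starts - 1L)), function(i) {
    th0 + stats::rnorm(length(th0), sd = jitter_sd)
  }))
  runs <- lapply(starts, function(th) {
    nm_fit <- tryCatch(
      stats::optim(th, nll, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL
    )
    if (is.null(nm_fit)) return(NULL)
    polish <- tryCatch(
      stats::optim(nm_fit$par, nll, method = "BFGS",
                   control = list(maxit = 200, reltol = reltol)),
      error = function(e) NULL
    )
    best <- nm_fit
    if (!is.null(polish) && polish$value <= nm_fit$value) best <- polish
    best
  })
  runs <- Filter(function(r) !is.null(r) && is.finite(r$value) && r$value < 1e11,
                 runs)
  if (length(runs) == 0L) {
    stop("all optimiser starts failed for model ", spec$code,
         " (non-finite likelihood everywhere tried); supply init= manually",
         call. = FALSE)
  }
  vals <- vapply(runs, `[[`, numeric(1), "value")
  norms <- vapply(runs, function(r) sum(r$par^2), numeric(1))
  best <- runs[[order(vals, norms)[1L]]]
  est <- from_transformed(stats::setNames(best$par, nm), spec)
  ll <- -best$value
  fit <- structure(list(
    spec = spec,
    estimates = est,
    log_likelihood = ll,
    deviance = -2 * ll,
    aic = -2 * ll + 2 * length(nm),
    r_squared = NA_real_,
    converged = best$convergence == 0,
    n_obs = nrow(dataset),
    n_params = length(nm),
    k_grains = k_grains(dataset),
    init = base,
    starts = data.frame(value = vals, norm = norms)
  ), class = "fb_fit")
  fit$r_squared <- fit_metrics(fit, dataset)$r_squared
  if (max(model_moments(dataset, spec, est)$gamma) > 1) {
    warning("fitted kernel density gamma exceeds 1 at some locations; ",
            "the kernel is not normalised, predicted CP rates are clipped ",
            "to [0, 100] only for reporting", call. = FALSE)
  }
  fit
}

#' @export
print.fb_fit <- function(x, digits = 4, ...) {
  cat("Dispersal model fit:", x$spec$code,
      sprintf("(n = %d cobs, K = %g)\n", x$n_obs, x$k_grains))
  print(round(x$estimates, digits))
  cat(sprintf("logLik %.2f | AIC %.2f | deviance %.2f | R2 %.3f | converged: %s\n",
              x$log_likelihood, x$aic, x$deviance, x$r_squared, x$converged))
  invisible(x)
}

#' Fit metrics of a dispersal model
#'
#' AIC and deviance follow from the log-likelihood (`AIC = -2 ll + 2p`,
#' `deviance = -2 ll`). The coefficient of determination is computed between
#' observed and model-predicted grid-level CP rates as
#' `R2 = 1 - SSE/SST`.
#'
#' @param fit an `fb_fit`.
#' @param dataset the dataset to evaluate grid-level R-squared on.
#' @return List with `aic`, `deviance`, `r_squared` (NA when the observed
#'   grid CP rates have zero variance).
#' @export
fit_metrics <- function(fit, dataset) {
  gs <- grid_summary(dataset)
  pred <- predict_cp(fit$spec, fit$estimates, gs$distance, gs$fb_width,
                     clip = FALSE)
  sst <- sum((gs$cp_pct - mean(gs$cp_pct))^2)
  r2 <- if (sst <= 0) NA_real_ else 1 - sum((gs$cp_pct - pred)^2) / sst
  list(aic = fit$aic, deviance = fit$deviance, r_squared = r2)
}

#' Predictive correlation on a validation set
#'
#' Pearson correlation between observed grid-level CP rates in a validation
#' dataset and the fitted model's mean predicted CP rates at the same
#' locations; the measure of predictive ability used in model comparison.
#'
#' @param fit an `fb_fit`.
#' @param validation an `fb_dataset` whose grids were not used for fitting.
#' @return Pearson correlation coefficient `r`.
#' @export
predictive_r <- function(fit, validation) {
  gs <- grid_summary(validation)
  if (nrow(gs) < 3L) stop("need at least 3 validation grids", call. = FALSE)
  pred <- predict_cp(fit$spec, fit$estimates, gs$distance, gs$fb_width,
                     clip = FALSE)
  stats::cor(gs$cp_pct, pred)
}

# ---- grouped threefold cross-validation -----------------------------------

# stratified partition: observations sharing (experiment, distance) form a
# group; each group is split as evenly as possible across the three folds
crossval_partition <- function(dataset, seed, n_folds = 3L) {
  set.seed(seed)
  key <- paste(dataset$experiment_id, dataset$distance, sep = " @ ")
  idx <- split(seq_len(nrow(dataset)), key)
  small <- names(idx)[lengths(idx) < n_folds]
  if (length(small)) {
    stop("group(s) with fewer than ", n_folds, " observations: ",
         paste(utils::head(small, 5), collapse = "; "), call. = FALSE)
  }
  fold <- integer(nrow(dataset))
  for (i in idx) {
    fold[sample(i)] <- rep_len(seq_len(n_folds), length(i))
  }
  fold
}

#' Grouped threefold cross-validation of a dispersal model
#'
#' Observations sharing the same field design and distance form a group;
#' each group is partitioned into three parts so that every sub-dataset
#' contains a share of every group (avoiding heterogeneity between folds).
#' Each fold in turn serves as the validation set for a model fitted on the
#' other two; training-set AIC, deviance and R-squared and validation-set
#' predictive correlation `r` are reported per fold and as mean and SD
#' across the three folds.
#'
#' @param dataset an `fb_dataset` (typically several experiments combined).
#' @param spec model specification or code.
#' @param seed integer seed controlling the partition and optimiser jitter.
#' @param ... further arguments passed to [fit_mle()].
#' @return An object of class `fb_crossval`: list with `spec`, `fold`
#'   (per-record fold assignment), `per_fold` (list of fits, validation `r`
#'   and fold metrics) and `summary` (data.frame of mean and SD of AIC,
#'   deviance, R-squared and r across folds).
#' @export
crossval_threefold <- function(dataset, spec, seed = 1, ...) {
  spec <- model_spec(spec)
  fold <- crossval_partition(dataset, seed = seed)
  k <- k_grains(dataset)
  per_fold <- lapply(1:3, function(f) {
    train <- fb_dataset(as.data.frame(dataset)[fold != f, , drop = FALSE], k)
    valid <- fb_dataset(as.data.frame(dataset)[fold == f, , drop = FALSE], k)
    fit <- fit_mle(train, spec, seed = seed + f, ...)
    list(fit = fit, r = predictive_r(fit, valid),
         aic = fit$aic, deviance = fit$deviance, r_squared = fit$r_squared)
  })
  metr <- vapply(per_fold, function(pf) {
    c(aic = pf$aic, deviance = pf$deviance, r_squared = pf$r_squared, r = pf$r)
  }, numeric(4))
  out <- structure(list(
    spec = spec,
    fold = fold,
    per_fold = per_fold,
    summary = data.frame(
      metric = rownames(metr),
      mean = rowMeans(metr),
      sd = apply(metr, 1, stats::sd),
      row.names = NULL
    )
  ), class = "fb_crossval")
  out
}

#' @export
print.fb_crossval <- function(x, digits = 4, ...) {
  cat("Threefold grouped cross-validation of", x$spec$code, "\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-10s %s ± %s\n", s$metric[i],
                signif(s$mean[i], digits), signif(s$sd[i], 3)))
  }
  invisible(x)
}
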