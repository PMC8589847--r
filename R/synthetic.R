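#' Default synthetic truth parameters
#'
#' Kernel and zero-inflation parameters used as the default generating truth
#' of the synthetic experiment suite: a compound-exponential ZIP model with
#' the field-border effect (ZExpoB) at the posterior-mean estimates obtained
#' from the original field data.
#'
#' @return Named numeric vector of ZExpoB parameters.
#' @export
default_truth_params <- function() {
  c(Ke = 0.6760, a1 = 0.6073, a2 = 0.0506, k = 0.3552, D = 2.8480,
    b1 = 2.7621, b2 = 0.0275)
}

#' Layout presets of the emulated field experiments
#'
#' Four layouts mimic the geometry of the original maize field experiments:
#' `"2009-1"` and `"2009-2A"` (no field border, 82 recipient rows, first row
#' 0.75 m from the donor), `"2009-2B"` (6.75 m FB, 82 rows, first row at the
#' border edge, 6.75 m) and `"2010-1"` (7.5 m FB, 91 rows, first row 7.5 m).
#' Row spacing is 0.75 m and in-row plant spacing 0.25 m throughout.
#'
#' @param name one of `"2009-1"`, `"2009-2A"`, `"2009-2B"`, `"2010-1"`.
#' @return An [experiment_layout()] object.
#' @export
make_layout_preset <- function(name) {
  presets <- list(
    "2009-1"  = list(fb = 0,    rows = 82L),
    "2009-2A" = list(fb = 0,    rows = 82L),
    "2009-2B" = list(fb = 6.75, rows = 82L),
    "2010-1"  = list(fb = 7.5,  rows = 91L)
  )
  if (!name %in% names(presets)) {
    stop("unknown layout preset ", deparse(name), "; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  p <- presets[[name]]
  experiment_layout(name, fb_width = p$fb, n_recipient_rows = p$rows)
}

#' Configuration of one synthetic experiment
#'
#' @param layout an [experiment_layout()].
#' @param truth_spec generating model specification or code.
#' @param truth_params named parameter vector for `truth_spec`.
#' @param k_grains average grain number per cob (K).
#' @param cobs_per_grid cobs sampled per grid (one grid per recipient row).
#' @param seed integer seed.
#' @return A list of class `fb_sim_config`.
#' @export
sim_config <- function(layout, truth_spec = "ZExpoB",
                       truth_params = default_truth_params(),
                       k_grains = 400, cobs_per_grid = 5, seed = 1) {
  stopifnot(inherits(layout, "fb_layout"), cobs_per_grid >= 1)
  truth_spec <- model_spec(truth_spec)
  truth_params <- check_params(truth_params, truth_spec)
  structure(list(layout = layout, truth_spec = truth_spec,
                 truth_params = truth_params, k_grains = k_grains,
                 cobs_per_grid = as.integer(cobs_per_grid),
                 seed = as.integer(seed)),
            class = "fb_sim_config")
}

#' Simulate a synthetic field experiment
#'
#' Generates per-cob CP grain counts by composing the dispersal model
#' forward: for each grid (one per recipient row) the effective distance,
#' pollen density, expected count `lambda = K * gamma` and, for ZIP truth,
#' the mixing weight are computed under the generating model, and counts
#' are drawn from the observation model. Records carry raw distances (FB
#' included), so all eight model variants can be fitted to the same dataset.
#'
#' @param config an [sim_config()] object.
#' @return An `fb_dataset`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "fb_sim_config"))
  lay <- config$layout
  spec <- config$truth_spec
  set.seed(config$seed)
  d <- lay$row_distances
  fb <- rep(lay$fb_width, length(d))
  d_star <- effective_distance(d, fb, spec)
  g <- kernel_value(d_star, fb, spec, config$truth_params)
  lambda <- expected_cp_grains(g, config$k_grains)
  if (any(!is.finite(lambda))) {
    stop("non-finite expected count at grid row ",
         which(!is.finite(lambda))[1L], call. = FALSE)
  }
  n_grid <- length(d)
  m <- config$cobs_per_grid
  lam_all <- rep(lambda, each = m)
  counts <- if (spec$obs == "zip") {
    q <- mixing_weight(d_star, config$truth_params[["b1"]],
                       config$truth_params[["b2"]])
    w <- if (spec$zip_weight == "complement") 1 - q else q
    rzip(n_grid * m, rep(w, each = m), lam_all)
  } else {
    stats::rpois(n_grid * m, lam_all)
  }
  fb_dataset(data.frame(
    experiment_id = lay$experiment_id,
    grid_id = sprintf("R%03d", rep(seq_len(n_grid), each = m)),
    distance = rep(d, each = m),
    fb_width = rep(fb, each = m),
    cp_grains = counts,
    stringsAsFactors = FALSE
  ), k_grains = config$k_grains)
}

#' Simulate the three-experiment suite
#'
#' Bundles synthetic versions of the three field experiments (2009-1,
#' 2009-2A with 2009-2B, and 2010-1) generated under a common truth,
#' suitable for fitting all eight models and for grouped cross-validation.
#'
#' @param seed integer seed; each experiment derives its own sub-seed.
#' @param truth_spec,truth_params generating model and parameters
#'   (default: ZExpoB at [default_truth_params()]).
#' @param k_grains average grains per cob.
#' @param cobs_per_grid cobs per grid.
#' @return Named list of three `fb_dataset`s: `"2009-1"`, `"2009-2"`
#'   (A and B combined), `"2010-1"`. Combine with [combine_datasets()].
#' @export
paper_scale_suite <- function(seed = 1, truth_spec = "ZExpoB",
                              truth_params = default_truth_params(),
                              k_grains = 400, cobs_per_grid = 5) {
  sims <- lapply(seq_along(SUITE_PRESETS), function(i) {
    simulate_experiment(sim_config(
      make_layout_preset(SUITE_PRESETS[i]),
      truth_spec = truth_spec, truth_params = truth_params,
      k_grains = k_grains, cobs_per_grid = cobs_per_grid,
      seed = (seed %% 1000003L) * 131L + i
    ))
  })
  names(sims) <- SUITE_PRESETS
  list(
    "2009-1" = sims[["2009-1"]],
    "2009-2" = combine_datasets(sims[["2009-2A"]], sims[["2009-2B"]]),
    "2010-1" = sims[["2010-1"]]
  )
}

SUITE_PRESETS <- c("2009-1", "2009-2A", "2009-2B", "2010-1")
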