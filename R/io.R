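#' Read a per-cob CP dataset from CSV
#'
#' The dataset format is comma-separated with header, "." decimal, UTF-8,
#' one row per cob and columns `experiment_id`, `grid_id`, `distance_m`,
#' `fb_width_m`, `cp_grains` and optionally `total_grains`.
#'
#' @param path path to the CSV file.
#' @param k_grains average grain number per cob attached to the dataset.
#' @return An `fb_dataset`.
#' @export
read_dataset <- function(path, k_grains = 400) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  req <- c("experiment_id", "grid_id", "distance_m", "fb_width_m", "cp_grains")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("dataset file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) stop("dataset file ", path, " has a header but no records",
                           call. = FALSE)
  names(df)[names(df) == "distance_m"] <- "distance"
  names(df)[names(df) == "fb_width_m"] <- "fb_width"
  fb_dataset(df, k_grains = k_grains)
}

#' Write a per-cob CP dataset to CSV
#'
#' @param dataset an `fb_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  df <- as.data.frame(dataset)
  names(df)[names(df) == "distance"] <- "distance_m"
  names(df)[names(df) == "fb_width"] <- "fb_width_m"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write model parameters as YAML
#'
#' Parameter sets (and other small key-value configuration) are stored as
#' flat YAML mappings.
#'
#' @param params named numeric vector.
#' @param path file path.
#' @return `read_params` returns a named numeric vector.
#' @export
write_params <- function(params, path) {
  yaml::write_yaml(as.list(params), path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  unlist(yaml::read_yaml(path))
}

#' Run one pipeline stage from a configuration
#'
#' A thin driver tying the modules into a reproducible pipeline. The
#' configuration is a list (or path to a YAML file) with at least `task`,
#' one of `"simulate"`, `"fit"`, `"crossval"`, `"mcmc"`, `"predict-band"`,
#' `"diagnose"`, plus task-specific fields: `model` (model code), `seed`,
#' `k_grains`, `input` (dataset CSV for analysis tasks), `output_dir`, and
#' for `"predict-band"` `fb_width` and optionally `distances`. Every stage
#' writes its result as CSV files plus a `run_log.txt` recording the task,
#' model code, seed and package version, so any output can be regenerated
#' from its logged configuration.
#'
#' @param config list or path to a YAML configuration.
#' @return Invisibly, a character vector of the files written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$task))
  task <- match.arg(config$task, c("simulate", "fit", "crossval", "mcmc",
                                   "predict-band", "diagnose"))
  out_dir <- if (is.null(config$output_dir)) "." else config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  kg <- if (is.null(config$k_grains)) 400 else config$k_grains
  model <- if (is.null(config$model)) "ZExpoB" else config$model
  files <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(format(df, digits = 6, trim = TRUE), p,
                     row.names = FALSE, quote = FALSE)
    files <<- c(files, p)
    p
  }
  load_input <- function() {
    if (is.null(config$input)) stop("task '", task, "' needs an input dataset",
                                    call. = FALSE)
    read_dataset(config$input, k_grains = kg)
  }

  if (task == "simulate") {
    suite <- paper_scale_suite(seed = seed, truth_spec = model, k_grains = kg)
    for (nm in names(suite)) {
      p <- file.path(out_dir, paste0("sim_", nm, ".csv"))
      write_dataset(suite[[nm]], p)
      files <- c(files, p)
    }
  } else if (task == "fit") {
    fit <- fit_mle(load_input(), model, seed = seed)
    emit(data.frame(parameter = names(fit$estimates),
                    estimate = unname(fit$estimates)), "fit_params.csv")
    emit(data.frame(metric = c("log_likelihood", "aic", "deviance", "r_squared"),
                    value = c(fit$log_likelihood, fit$aic, fit$deviance,
                              fit$r_squared)), "fit_metrics.csv")
  } else if (task == "crossval") {
    cv <- crossval_threefold(load_input(), model, seed = seed)
    emit(cv$summary, "crossval_summary.csv")
  } else if (task == "mcmc") {
    settings <- mcmc_settings(seed = seed,
                              profile = if (is.null(config$profile)) "test"
                                        else config$profile)
    post <- run_mcmc(load_input(), model, settings)
    emit(as.data.frame(post$draws), "chain.csv")
    emit(data.frame(parameter = names(post$posterior_mean),
                    mean = unname(post$posterior_mean),
                    sd = unname(post$posterior_sd)), "posterior_summary.csv")
    emit(data.frame(metric = c("dic", "acceptance_rate"),
                    value = c(as.numeric(post$dic), post$acceptance_rate)),
         "mcmc_metrics.csv")
  } else if (task == "predict-band") {
    settings <- mcmc_settings(seed = seed,
                              profile = if (is.null(config$profile)) "test"
                                        else config$profile)
    dataset <- load_input()
    post <- run_mcmc(dataset, model, settings)
    fbw <- if (is.null(config$fb_width)) 0 else config$fb_width
    dgrid <- if (is.null(config$distances)) {
      lo <- max(fbw, if (model_spec(model)$kernel == "cauchy" &&
                         !model_spec(model)$fb_effect) 0.75 else 0, 0.75)
      seq(lo, max(dataset$distance), length.out = 40)
    } else {
      unlist(config$distances)
    }
    band <- posterior_predictive_band(post, dgrid, fbw)
    emit(as.data.frame(band), "predictive_band.csv")
  } else if (task == "diagnose") {
    ze <- zero_excess(load_input())
    emit(ze$per_distance, "zero_excess_by_distance.csv")
    emit(data.frame(experiment_id = names(ze$percent),
                    percent_zero_excess = unname(ze$percent)),
         "zero_excess_by_experiment.csv")
  }

  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(c(
    paste("task:", task),
    paste("model:", model),
    paste("seed:", seed),
    paste("k_grains:", kg),
    paste("input:", if (is.null(config$input)) "-" else config$input),
    paste("pollenFB version:",
          as.character(utils::packageVersion("pollenFB")))
  ), log_path)
  invisible(c(files, log_path))
}
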