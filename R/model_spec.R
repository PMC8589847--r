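#' Dispersal model codes
#'
#' The eight dispersal models are combinations of an observation model
#' (Poisson `P` or zero-inflated Poisson `Z`), a dispersal kernel
#' (compound exponential `Expo` or modified Cauchy `Cauchy`) and a
#' field-border effect flag (`B` = with FB effect, `N` = without).
#'
#' @format A character vector of the eight model codes.
#' @export
MODEL_CODES <- c(
  "PExpoN", "PExpoB", "PCauchyN", "PCauchyB",
  "ZExpoN", "ZExpoB", "ZCauchyN", "ZCauchyB"
)

#' Construct a dispersal model specification
#'
#' A model specification selects the observation model, the kernel family and
#' whether the field-border (FB) effect enters the kernel (and, for ZIP
#' models, the zero-inflation logistic).
#'
#' @param code one of the eight model codes, e.g. `"ZExpoB"`; see
#'   [MODEL_CODES].
#' @param zip_weight convention for the Poisson-component weight `w` of the
#'   ZIP mixture. `"complement"` (default) takes `w = 1 - q_s` with `q_s` the
#'   logistic of distance, so that structural zeros become more frequent far
#'   from the pollen source; `"literal"` takes `w = q_s`. See the methods
#'   vignette for why the default matches the published parameter estimates.
#' @return An object of class `fb_model_spec`: a list with elements `code`,
#'   `obs` (`"poisson"` or `"zip"`), `kernel` (`"expo"` or `"cauchy"`),
#'   `fb_effect` (logical) and `zip_weight`.
#' @examples
#' model_spec("ZExpoB")
#' @export
model_spec <- function(code, zip_weight = c("complement", "literal")) {
  if (inherits(code, "fb_model_spec")) return(code)
  zip_weight <- match.arg(zip_weight)
  if (!is.character(code) || length(code) != 1L || !(code %in% MODEL_CODES)) {
    stop("unknown model code ", deparse(code), "; must be one of: ",
         paste(MODEL_CODES, collapse = ", "), call. = FALSE)
  }
  spec <- list(
    code = code,
    obs = if (startsWith(code, "Z")) "zip" else "poisson",
    kernel = if (grepl("Cauchy", code, fixed = TRUE)) "cauchy" else "expo",
    fb_effect = endsWith(code, "B"),
    zip_weight = zip_weight
  )
  class(spec) <- "fb_model_spec"
  spec
}

#' @export
print.fb_model_spec <- function(x, ...) {
  cat("Dispersal model", x$code, "\n")
  cat("  observation model:", if (x$obs == "zip") "zero-inflated Poisson" else "Poisson", "\n")
  cat("  kernel:", if (x$kernel == "expo") "compound exponential" else "modified Cauchy", "\n")
  cat("  field-border effect:", if (x$fb_effect) "yes" else "no", "\n")
  if (x$obs == "zip") cat("  ZIP Poisson-weight convention:", x$zip_weight, "\n")
  invisible(x)
}

#' Parameter names of a dispersal model
#'
#' @param spec an `fb_model_spec` or model code.
#' @return Character vector of free parameter names, in the canonical order
#'   used by all fitting functions: kernel parameters (`Ke, a1, a2, D` or
#'   `beta, c1, D`, plus `k` for FB-effect models), then `b1, b2` for ZIP
#'   models.
#' @export
param_names <- function(spec) {
  spec <- model_spec(spec)
  p <- if (spec$kernel == "expo") c("Ke", "a1", "a2") else c("beta", "c1")
  if (spec$fb_effect) p <- c(p, "k")
  p <- c(p, "D")
  if (spec$obs == "zip") p <- c(p, "b1", "b2")
  p
}

# TRUE for parameters constrained positive (fitted on the log scale);
# the logistic coefficients b1, b2 are unconstrained.
param_positive <- function(spec) {
  nm <- param_names(spec)
  stats::setNames(!(nm %in% c("b1", "b2")), nm)
}

# validate and order a named parameter vector against a spec
check_params <- function(params, spec) {
  spec <- model_spec(spec)
  nm <- param_names(spec)
  params <- unlist(params)
  if (is.null(names(params)) || !all(nm %in% names(params))) {
    stop("parameters for ", spec$code, " must be named and include: ",
         paste(nm, collapse = ", "), call. = FALSE)
  }
  params <- params[nm]
  if (any(!is.finite(params))) stop("non-finite parameter value", call. = FALSE)
  pos <- param_positive(spec)
  bad <- pos & (params <= 0) & names(params) != "k"
  if (any(bad)) {
    stop("parameter(s) must be > 0: ", paste(names(params)[bad], collapse = ", "),
         call. = FALSE)
  }
  if ("k" %in% names(params) && params[["k"]] < 0) {
    stop("parameter k must be >= 0", call. = FALSE)
  }
  params
}
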