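#' Describe a field-experiment layout
#'
#' A layout records the geometry of one donor/recipient field pair: the width
#' of the field border (FB, an unplanted strip such as a roadway between the
#' donor and recipient plots), the row and in-row plant spacing, and the
#' distance of every recipient row from the nearest donor edge. Distances are
#' stored raw, i.e. with the FB width included, as planted; FB subtraction
#' happens later in [effective_distance()] so that one dataset serves all
#' eight model variants.
#'
#' When an FB is present the first recipient row sits at the far edge of the
#' border, so its distance to the nearest donor equals the FB width; without
#' an FB the first row is one row spacing from the donor edge.
#'
#' @param experiment_id label for the experiment.
#' @param fb_width FB width in meters (>= 0; 0 means no border).
#' @param n_recipient_rows number of recipient rows.
#' @param row_spacing distance between rows in meters.
#' @param plant_spacing distance between plants within a row in meters.
#' @return An object of class `fb_layout`: a list with the arguments plus
#'   `row_distances`, the strictly increasing distances of the recipient rows.
#' @seealso [make_layout_preset()] for the built-in experiment presets.
#' @export
experiment_layout <- function(experiment_id, fb_width, n_recipient_rows,
                              row_spacing = 0.75, plant_spacing = 0.25) {
  stopifnot(length(experiment_id) == 1L, is.numeric(fb_width), fb_width >= 0,
            n_recipient_rows >= 1, row_spacing > 0, plant_spacing > 0)
  first <- if (fb_width > 0) fb_width else row_spacing
  out <- list(
    experiment_id = as.character(experiment_id),
    fb_width = fb_width,
    row_spacing = row_spacing,
    plant_spacing = plant_spacing,
    n_recipient_rows = as.integer(n_recipient_rows),
    row_distances = first + row_spacing * (seq_len(n_recipient_rows) - 1L)
  )
  class(out) <- "fb_layout"
  out
}

#' @export
print.fb_layout <- function(x, ...) {
  cat("Field layout", x$experiment_id, "\n")
  cat(sprintf("  FB width %.2f m, %d recipient rows, rows %.2f-%.2f m from donor\n",
              x$fb_width, x$n_recipient_rows,
              min(x$row_distances), max(x$row_distances)))
  invisible(x)
}

#' Assemble a per-cob CP dataset
#'
#' The unit of observation is one recipient cob: its cross-pollinated (CP)
#' grain count, the shortest distance from its grid to the nearest donor
#' (raw, FB included) and the FB width of its experiment. `k_grains` is the
#' average total grain number per cob (K), the dataset-level constant that
#' converts kernel output (pollen density) to an expected CP grain count and
#' CP counts to CP rates.
#'
#' @param records a data.frame with columns `experiment_id`, `grid_id`,
#'   `distance` (m, > 0), `fb_width` (m, >= 0), `cp_grains` (non-negative
#'   integer) and optionally `total_grains`.
#' @param k_grains average grain number per cob (K), positive.
#' @return An `fb_dataset` (a data.frame with attribute `k_grains`).
#' @export
fb_dataset <- function(records, k_grains = 400) {
  stopifnot(is.data.frame(records), is.numeric(k_grains),
            length(k_grains) == 1L, k_grains > 0)
  req <- c("experiment_id", "grid_id", "distance", "fb_width", "cp_grains")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (nrow(records) == 0L) stop("dataset has no records", call. = FALSE)
  bad <- which(!is.finite(records$distance) | records$distance <= 0)
  if (length(bad)) stop("non-positive distance in row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(records$fb_width) | records$fb_width < 0)
  if (length(bad)) stop("negative FB width in row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  cp <- records$cp_grains
  bad <- which(!is.finite(cp) | cp < 0 | cp != round(cp))
  if (length(bad)) stop("cp_grains must be non-negative integers; bad row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  records$experiment_id <- as.character(records$experiment_id)
  records$grid_id <- as.character(records$grid_id)
  records$cp_grains <- as.integer(round(cp))
  # a grid must have a single location
  key <- paste(records$experiment_id, records$grid_id, sep = "\r")
  for (col in c("distance", "fb_width")) {
    n_per <- tapply(records[[col]], key, function(v) length(unique(v)))
    if (any(n_per > 1L)) stop("grid with inconsistent ", col, ": ",
                              sub("\r", "/", names(n_per)[n_per > 1L][1L]),
                              call. = FALSE)
  }
  structure(as.data.frame(records), k_grains = as.numeric(k_grains),
            class = c("fb_dataset", "data.frame"))
}

#' @rdname fb_dataset
#' @param dataset an `fb_dataset`.
#' @export
k_grains <- function(dataset) {
  k <- attr(dataset, "k_grains")
  if (is.null(k)) stop("not an fb_dataset: no k_grains attribute", call. = FALSE)
  k
}

#' Combine datasets from several experiments
#'
#' @param ... `fb_dataset` objects sharing the same `k_grains`.
#' @return A single `fb_dataset`.
#' @export
combine_datasets <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) && !is.data.frame(parts[[1]])) {
    parts <- parts[[1]]
  }
  ks <- vapply(parts, k_grains, numeric(1))
  if (length(unique(ks)) != 1L) stop("datasets differ in k_grains", call. = FALSE)
  fb_dataset(do.call(rbind, lapply(parts, as.data.frame)), k_grains = ks[[1]])
}

#' Effective distance entering a kernel
#'
#' The kernels operate on an effective distance `d*`, derived from the raw
#' shortest distance between a recipient and the nearest donor. Models with
#' the FB effect subtract the FB width (so the first row behind the border is
#' at `d* = 0`); the no-FB compound-exponential models use the raw distance
#' unchanged; the no-FB modified-Cauchy models subtract one row spacing
#' (0.75 m).
#'
#' @param distance raw distance(s) in meters, FB included.
#' @param fb_width FB width(s) in meters (recycled).
#' @param spec model specification (or code) selecting the convention.
#' @param row_spacing row spacing subtracted by the no-FB Cauchy convention.
#' @return Numeric vector of effective distances, all >= 0.
#' @examples
#' effective_distance(7.5, 6.75, "ZExpoB")   # 0.75
#' effective_distance(0.75, 0, "ZExpoN")     # 0.75 (unchanged)
#' effective_distance(7.5, 0, "ZCauchyN")    # 6.75
#' @export
effective_distance <- function(distance, fb_width, spec, row_spacing = 0.75) {
  spec <- model_spec(spec)
  stopifnot(is.numeric(distance), is.numeric(fb_width))
  d <- if (spec$fb_effect) {
    distance - fb_width
  } else if (spec$kernel == "cauchy") {
    distance - row_spacing
  } else {
    distance
  }
  # allow exact zero (first recipient row at the FB edge); tiny negatives are
  # floating-point noise from the layout arithmetic
  d[d < 0 & d > -1e-9] <- 0
  if (any(d < 0)) {
    i <- which(d < 0)[1L]
    stop(sprintf(paste0("effective distance is negative (%.3f m) for model %s: ",
                        "raw distance %.3f m is smaller than the subtracted amount ",
                        "(geometry/variant mismatch)"),
                 d[i], spec$code, distance[min(i, length(distance))]),
         call. = FALSE)
  }
  d
}

#' Cross-pollination rate of a set of cobs
#'
#' The CP rate of a grid is the total CP grain count over the maximum
#' attainable count: `CP% = 100 * sum(cp) / (n * K)` with `n` cobs and `K`
#' average grains per cob.
#'
#' @param cp_grain_counts non-negative integer CP grain counts, one per cob.
#' @param k_grains average grain number per cob (K), positive.
#' @return CP rate in percent.
#' @examples
#' cp_rate(c(50, 150), 400)  # 25
#' @export
cp_rate <- function(cp_grain_counts, k_grains) {
  if (length(cp_grain_counts) == 0L) stop("empty cob list", call. = FALSE)
  stopifnot(is.numeric(cp_grain_counts), all(cp_grain_counts >= 0),
            is.numeric(k_grains), length(k_grains) == 1L, k_grains > 0)
  100 * sum(cp_grain_counts) / (length(cp_grain_counts) * k_grains)
}

#' Per-grid summary of a dataset
#'
#' Aggregates a per-cob dataset to its sampling grids: one row per
#' (experiment, grid) with the grid's distance, FB width, number of cobs and
#' observed CP rate.
#'
#' @param dataset an `fb_dataset`.
#' @return A data.frame with columns `experiment_id`, `grid_id`, `distance`,
#'   `fb_width`, `n_cobs`, `cp_pct`, ordered by experiment then distance.
#' @export
grid_summary <- function(dataset) {
  k <- k_grains(dataset)
  df <- as.data.frame(dataset)
  key <- interaction(df$experiment_id, df$grid_id, drop = TRUE, sep = "\r")
  idx <- split(seq_len(nrow(df)), key)
  out <- do.call(rbind, lapply(idx, function(i) {
    data.frame(
      experiment_id = df$experiment_id[i[1L]],
      grid_id = df$grid_id[i[1L]],
      distance = df$distance[i[1L]],
      fb_width = df$fb_width[i[1L]],
      n_cobs = length(i),
      cp_pct = cp_rate(df$cp_grains[i], k),
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(out$experiment_id, out$distance, out$grid_id), ]
  rownames(out) <- NULL
  out
}
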