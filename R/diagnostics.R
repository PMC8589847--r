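#' Zero-excess assessment against the Poisson expectation
#'
#' For every (experiment, distance) group the observed fraction of zero-CP
#' cobs is compared with the zero probability of a Poisson distribution at
#' the group's mean count (`exp(-lambda_hat)`, the Poisson MLE). A group is
#' flagged zero-excess when the observed fraction strictly exceeds the
#' Poisson probability; the experiment-level zero-excess level is the
#' percentage of flagged distance groups.
#'
#' @param dataset an `fb_dataset`.
#' @param unit `"cob"` (default) treats each cob as one observation;
#'   `"grid"` uses grid-total counts instead.
#' @return An object of class `fb_zero_excess`: list with `per_distance`
#'   (data.frame: experiment, distance, n, observed zero fraction, Poisson
#'   zero probability, flag) and `percent` (named vector, per-experiment
#'   percentage of flagged groups).
#' @export
zero_excess <- function(dataset, unit = c("cob", "grid")) {
  unit <- match.arg(unit)
  df <- as.data.frame(dataset)
  if (unit == "grid") {
    key <- paste(df$experiment_id, df$grid_id, sep = "\r")
    df <- do.call(rbind, lapply(split(df, key), function(g) {
      data.frame(experiment_id = g$experiment_id[1], distance = g$distance[1],
                 cp_grains = sum(g$cp_grains))
    }))
  }
  grp <- split(df, paste(df$experiment_id, df$distance, sep = "\r"))
  per <- do.call(rbind, lapply(grp, function(g) {
    lam <- mean(g$cp_grains)
    data.frame(
      experiment_id = g$experiment_id[1],
      distance = g$distance[1],
      n = nrow(g),
      zero_fraction = mean(g$cp_grains == 0),
      poisson_p0 = exp(-lam),
      lambda_hat = lam,
      stringsAsFactors = FALSE
    )
  }))
  per$zero_excess <- per$zero_fraction > per$poisson_p0
  per <- per[order(per$experiment_id, per$distance), ]
  rownames(per) <- NULL
  pct <- vapply(split(per$zero_excess, per$experiment_id),
                function(z) 100 * mean(z), numeric(1))
  structure(list(per_distance = per, percent = pct),
            class = "fb_zero_excess")
}

#' @export
print.fb_zero_excess <- function(x, ...) {
  cat("Zero-excess assessment (observed zero fraction vs Poisson P(0))\n")
  for (e in names(x$percent)) {
    n <- sum(x$per_distance$experiment_id == e)
    cat(sprintf("  %-10s %5.1f%% of %d distance groups flagged\n",
                e, x$percent[[e]], n))
  }
  invisible(x)
}
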