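# Fixtures and independent oracles used across the suite. The oracle code
# deliberately re-derives every quantity from the model definitions with
# plain scalar arithmetic, sharing no code path with the package internals
# it is used to check.

# six-cob toy dataset spanning a field without and a field with a border
make_toy_dataset <- function(k_grains = 400) {
  fb_dataset(data.frame(
    experiment_id = c("A", "A", "A", "B", "B", "B"),
    grid_id = c("g1", "g2", "g3", "g1", "g2", "g3"),
    distance = c(0.75, 1.5, 3.0, 6.75, 7.5, 9.0),
    fb_width = c(0, 0, 0, 6.75, 6.75, 6.75),
    cp_grains = c(120L, 60L, 25L, 40L, 18L, 5L)
  ), k_grains = k_grains)
}

# a small custom layout for cheap simulations
small_layout <- function(id = "S", fb = 0, rows = 10) {
  experiment_layout(id, fb_width = fb, n_recipient_rows = rows)
}

# --- independent scalar likelihood oracle ----------------------------------

oracle_gamma <- function(d_star, fb, p, kernel, fb_effect) {
  g <- if (kernel == "expo") {
    if (d_star <= p[["D"]]) {
      p[["Ke"]] * exp(-p[["a1"]] * d_star)
    } else {
      p[["Ke"]] * exp(-p[["a1"]] * p[["D"]] - p[["a2"]] * (d_star - p[["D"]]))
    }
  } else {
    den <- if (d_star <= p[["D"]]) {
      p[["beta"]]^2 + d_star^2
    } else {
      p[["beta"]]^2 + p[["D"]]^2 + p[["c1"]] * (d_star - p[["D"]])^2
    }
    2 * p[["beta"]] / (pi * den)
  }
  if (fb_effect) g <- g * exp(-p[["k"]] * sqrt(fb))
  g
}

# per-record log pmf product, scalar loop, own d* and pmf arithmetic
oracle_loglik <- function(dataset, code, params) {
  kernel <- if (grepl("Cauchy", code)) "cauchy" else "expo"
  fb_eff <- endsWith(code, "B")
  zip <- startsWith(code, "Z")
  K <- attr(dataset, "k_grains")
  total <- 0
  for (i in seq_len(nrow(dataset))) {
    d <- dataset$distance[i]; fb <- dataset$fb_width[i]
    d_star <- if (fb_eff) d - fb else if (kernel == "cauchy") d - 0.75 else d
    lam <- K * oracle_gamma(d_star, fb, params, kernel, fb_eff)
    y <- dataset$cp_grains[i]
    pois <- lam^y * exp(-lam) / factorial(y)
    pr <- if (zip) {
      q <- 1 / (1 + exp(params[["b1"]] - params[["b2"]] * d_star))
      w <- 1 - q
      if (y == 0) (1 - w) + w * exp(-lam) else w * pois
    } else {
      pois
    }
    total <- total + log(pr)
  }
  total
}

# coarse grid search over a parameter box; returns the best log-likelihood
oracle_grid_search <- function(dataset, code, box) {
  grid <- expand.grid(box, KEEP.OUT.ATTRS = FALSE)
  best <- -Inf
  for (i in seq_len(nrow(grid))) {
    p <- unlist(grid[i, ])
    ll <- oracle_loglik(dataset, code, p)
    if (is.finite(ll) && ll > best) best <- ll
  }
  best
}

# coarse parameter boxes per model family for the grid oracle
oracle_box <- function(code) {
  box <- if (grepl("Cauchy", code)) {
    list(beta = c(0.5, 1, 2), c1 = c(0.1, 0.3, 1), D = c(2, 4))
  } else {
    list(Ke = c(0.3, 0.7, 1.2), a1 = c(0.3, 0.6, 1.2), a2 = c(0.03, 0.1), D = c(2, 4))
  }
  if (endsWith(code, "B")) box$k <- c(0.1, 0.35, 0.8)
  if (startsWith(code, "Z")) { box$b1 <- c(1.5, 3); box$b2 <- c(0.01, 0.05) }
  box
}

# batch-means Monte-Carlo standard error for an autocorrelated chain
batch_se <- function(x, n_batch = 20) {
  n <- length(x)
  b <- floor(n / n_batch)
  means <- vapply(seq_len(n_batch), function(i) mean(x[((i - 1) * b + 1):(i * b)]),
                  numeric(1))
  stats::sd(means) / sqrt(n_batch)
}

# truth-model mean CP rate (percent) at raw distances, scalar oracle
oracle_mean_cp <- function(distance, fb, params, code) {
  kernel <- if (grepl("Cauchy", code)) "cauchy" else "expo"
  fb_eff <- endsWith(code, "B")
  vapply(seq_along(distance), function(i) {
    d_star <- if (fb_eff) distance[i] - fb else if (kernel == "cauchy")
      distance[i] - 0.75 else distance[i]
    g <- oracle_gamma(d_star, fb, params, kernel, fb_eff)
    if (startsWith(code, "Z")) {
      q <- 1 / (1 + exp(params[["b1"]] - params[["b2"]] * d_star))
      100 * (1 - q) * g
    } else {
      100 * g
    }
  }, numeric(1))
}
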