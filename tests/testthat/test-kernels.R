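table3_expo <- c(Ke = 0.6760, a1 = 0.6073, a2 = 0.0506, k = 0.3552, D = 2.8480)
table4_cauchy <- c(beta = 1.10, c1 = 0.2832, k = 0.0632, D = 3.5803)

test_that("compound exponential kernel matches hand-computed values", {
  # at the source with no border, every exponential factor is 1
  expect_equal(kernel_expo(0, 0, table3_expo, fb_effect = TRUE), 0.6760)
  # independent scalar evaluation: exp(-0.5*1) * exp(-0.25*sqrt(4))
  expect_equal(
    kernel_expo(1, 4, c(Ke = 1, a1 = 0.5, a2 = 0.1, k = 0.25, D = 2),
                fb_effect = TRUE),
    0.367879441171442, tolerance = 1e-12
  )
  expect_error(kernel_expo(-1, 0, table3_expo), "d_star")
})

test_that("modified Cauchy kernel matches hand-computed values", {
  # closed form at the origin: 2 / (pi * beta)
  p <- c(beta = 1.7, c1 = 0.3, k = 0.1, D = 3)
  expect_equal(kernel_cauchy(0, 0, p, fb_effect = TRUE), 2 / (pi * 1.7))
  # independent scalar evaluation at published parameter magnitudes
  expect_equal(
    kernel_cauchy(5, 7.5, table4_cauchy, fb_effect = TRUE),
    0.0403432997838372, tolerance = 1e-12
  )
  expect_error(kernel_cauchy(-0.1, 0, p), "d_star")
})

test_that("both kernels are continuous at the break distance D", {
  set.seed(41)
  for (i in 1:20) {
    pe <- c(Ke = runif(1, 0.1, 2), a1 = runif(1, 0.05, 2),
            a2 = runif(1, 0.01, 1), k = runif(1, 0, 1), D = runif(1, 0.5, 8))
    lhs <- pe[["Ke"]] * exp(-pe[["a1"]] * pe[["D"]])
    rhs <- pe[["Ke"]] * exp(-pe[["a1"]] * pe[["D"]] - pe[["a2"]] * 0)
    expect_equal(lhs, rhs, tolerance = 1e-12)
    expect_equal(kernel_expo(pe[["D"]], 2, pe, TRUE),
                 kernel_expo(pe[["D"]] + 1e-12, 2, pe, TRUE),
                 tolerance = 1e-9)
    pc <- c(beta = runif(1, 0.2, 3), c1 = runif(1, 0.05, 2),
            k = runif(1, 0, 1), D = runif(1, 0.5, 8))
    expect_equal(kernel_cauchy(pc[["D"]], 2, pc, TRUE),
                 kernel_cauchy(pc[["D"]] + 1e-12, 2, pc, TRUE),
                 tolerance = 1e-9)
  }
})

test_that("the field-border factor multiplies the borderless kernel exactly", {
  d <- c(0, 0.5, 2, 5, 20)
  fb <- 6.75
  ge0 <- kernel_expo(d, 0, table3_expo, fb_effect = TRUE)
  gef <- kernel_expo(d, fb, table3_expo, fb_effect = TRUE)
  expect_equal(gef, ge0 * exp(-table3_expo[["k"]] * sqrt(fb)))
  gc0 <- kernel_cauchy(d, 0, table4_cauchy, fb_effect = TRUE)
  gcf <- kernel_cauchy(d, fb, table4_cauchy, fb_effect = TRUE)
  expect_equal(gcf, gc0 * exp(-table4_cauchy[["k"]] * sqrt(fb)))
})

test_that("kernels decline with distance and with border width", {
  d <- seq(0, 30, by = 0.25)
  expect_true(all(diff(kernel_expo(d, 3, table3_expo, TRUE)) < 0))
  expect_true(all(diff(kernel_cauchy(d, 3, table4_cauchy, TRUE)) < 0))
  fbs <- seq(0, 12, by = 0.5)
  expect_true(all(diff(kernel_expo(2, fbs, table3_expo, TRUE)) < 0))
})

test_that("k = 0 collapses a with-FB kernel onto its borderless form", {
  p0 <- table3_expo; p0[["k"]] <- 0
  d <- c(0, 1, 4, 10)
  expect_equal(kernel_expo(d, 6.75, p0, fb_effect = TRUE),
               kernel_expo(d, 6.75, p0, fb_effect = FALSE))
  c0 <- table4_cauchy; c0[["k"]] <- 0
  expect_equal(kernel_cauchy(d, 6.75, c0, fb_effect = TRUE),
               kernel_cauchy(d, 6.75, c0, fb_effect = FALSE))
})

test_that("expected CP grains scale the kernel by K", {
  expect_equal(expected_cp_grains(0, 400), 0)
  expect_equal(expected_cp_grains(0.25, 400), 100)
  expect_equal(expected_cp_grains(0.6760, 400), 270.4)
  expect_error(expected_cp_grains(-0.1, 400))
})

test_that("predicted CP rate is the model mean over K, clipped for reporting", {
  # Poisson models: mean CP% = 100 * gamma
  p <- c(Ke = 0.5, a1 = 0.6, a2 = 0.05, D = 3)
  expect_equal(predict_cp("PExpoN", p, 1, 0),
               100 * kernel_expo(1, 0, c(p, k = 0), fb_effect = FALSE))
  # ZIP models deflate by the Poisson-component weight
  z <- c(p, k = 0.3552, b1 = 2.7621, b2 = 0.0275)
  d <- 7.5; fbw <- 6.75
  dstar <- d - fbw
  q <- 1 / (1 + exp(z[["b1"]] - z[["b2"]] * dstar))
  expect_equal(predict_cp("ZExpoB", z, d, fbw),
               100 * (1 - q) * kernel_expo(dstar, fbw, z, TRUE))
  # an unnormalised kernel can exceed 100%; reporting clips
  big <- c(Ke = 1.6, a1 = 0.1, a2 = 0.05, D = 3)
  expect_equal(predict_cp("PExpoN", big, 0.75, 0), 100)
  expect_gt(predict_cp("PExpoN", big, 0.75, 0, clip = FALSE), 100)
})
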