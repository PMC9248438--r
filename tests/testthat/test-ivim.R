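test_that("the biexponential signal model evaluates its closed form", {
  expect_equal(ivim_signal(0, 1e-3, 2e-3, 0.3), 1)
  expect_equal(ivim_signal(500, 1e-3, 2e-3, 1), exp(-500 * 2e-3))
  # normal-brain parameters at b = 2000: frozen closed-form value
  expect_equal(ivim_signal(2000, 414.21e-6, 2755.02e-6, 0.4629),
               0.2364453, tolerance = 1e-6)
  # strictly decreasing in b, in (0, 1]
  s <- ivim_signal(protocol_b, tumor_pars$D, tumor_pars$Dstar, tumor_pars$f)
  expect_true(all(diff(s) < 0))
  expect_true(all(s > 0 & s <= 1))
  expect_error(ivim_signal(100, -1e-3, 2e-3, 0.3), "D must")
  expect_error(ivim_signal(100, 2e-3, 1e-3, 0.3), "Dstar")
  expect_error(ivim_signal(100, 1e-3, 2e-3, 1.3), "f must")
})

test_that("perfusion is the product f x D*", {
  expect_equal(compute_perfusion(0, 5e-3), 0)
  expect_equal(compute_perfusion(1, 5e-3), 5e-3)
  # Table-scale product; a mean of products differs from this product of
  # means, so only the direct product is asserted
  expect_equal(compute_perfusion(0.5109, 2850.23e-6), 1456.1825e-6,
               tolerance = 1e-7)
})

test_that("noiseless series are recovered to high precision by both fitters", {
  s <- ivim_signal(protocol_b, tumor_pars$D, tumor_pars$Dstar, tumor_pars$f)
  for (fitter in list(fit_ivim_segmented, fit_ivim_full)) {
    fit <- fitter(1000 * s, protocol_b)
    expect_true(fit$converged)
    expect_lt(abs(fit$D - tumor_pars$D) / tumor_pars$D, 1e-6)
    expect_lt(abs(fit$Dstar - tumor_pars$Dstar) / tumor_pars$Dstar, 1e-6)
    expect_lt(abs(fit$f - tumor_pars$f) / tumor_pars$f, 1e-6)
    expect_equal(fit$perfusion, fit$f * fit$Dstar)
  }
})

test_that("a mono-exponential series fits with f near zero", {
  s <- 800 * exp(-protocol_b * 500e-6)
  fit <- fit_ivim_segmented(s, protocol_b)
  expect_lt(fit$f, 0.005)
  expect_lt(abs(fit$D - 500e-6) / 500e-6, 0.005)
  full <- fit_ivim_full(s, protocol_b)
  expect_lt(full$f, 0.005)
})

test_that("fitting is deterministic and the full fit never increases the RSS", {
  set.seed(77)
  s <- ivim_signal(protocol_b, tumor_pars$D, tumor_pars$Dstar, tumor_pars$f)
  noisy <- t(replicate(30, sqrt((1000 * s + rnorm(11, 0, 20))^2 +
                                  rnorm(11, 0, 20)^2)))
  f1 <- fit_ivim_segmented(noisy, protocol_b)
  f2 <- fit_ivim_segmented(noisy, protocol_b)
  expect_identical(f1, f2)
  full <- fit_ivim_full(noisy, protocol_b, init = f1)
  ok <- full$converged | full$fallback
  expect_true(all(full$rss[ok] <= f1$rss[ok] * (1 + 1e-9)))
})

test_that("steeper high-b decay increases the fitted diffusion coefficient", {
  s <- ivim_signal(protocol_b, tumor_pars$D, tumor_pars$Dstar, tumor_pars$f)
  eps <- 1e-4
  fit0 <- fit_ivim_segmented(s, protocol_b)
  fit1 <- fit_ivim_segmented(s * exp(-eps * protocol_b), protocol_b)
  expect_gt(fit1$D, fit0$D)
  expect_lt(abs((fit1$D - fit0$D) - eps) / eps, 0.05)
})

test_that("the full fit agrees with a dense grid-search oracle", {
  set.seed(12)
  gD <- seq(300e-6, 600e-6, by = 5e-6)
  gDs <- seq(2000e-6, 4000e-6, by = 50e-6)
  gf <- seq(0.3, 0.7, by = 0.01)
  grid <- expand.grid(D = gD, Ds = gDs, f = gf)
  gsig <- (1 - grid$f) * exp(-outer(grid$D, protocol_b)) +
    grid$f * exp(-outer(grid$Ds, protocol_b))
  for (k in 1:20) {
    D <- runif(1, 350e-6, 550e-6); Ds <- runif(1, 2200e-6, 3800e-6)
    f <- runif(1, 0.35, 0.65)
    y <- ivim_signal(protocol_b, D, Ds, f)
    rss_grid <- min(rowSums(sweep(gsig, 2, y)^2))
    fit <- fit_ivim_full(y, protocol_b)
    # the fit must be at least as good as the best grid point, and on
    # noiseless data it must sit at the generating parameters
    expect_lte(fit$rss / fit$S0^2, rss_grid + 1e-12)
    expect_lt(abs(fit$D - D) / D, 1e-5)
    expect_lt(abs(fit$Dstar - Ds) / Ds, 1e-5)
    expect_lt(abs(fit$f - f), 1e-5)
  }
})

test_that("parameter bias vanishes as the noise level goes to zero", {
  s <- 1000 * ivim_signal(protocol_b, tumor_pars$D, tumor_pars$Dstar,
                          tumor_pars$f)
  med_err <- sapply(c(0, 0.005, 0.02), function(sg) {
    noisy <- if (sg == 0) matrix(s, 50, 11, byrow = TRUE) else
      add_rician_noise(matrix(s, 50, 11, byrow = TRUE), 1000 * sg, seed = 99)
    fit <- fit_ivim_segmented(noisy, protocol_b)
    median(abs(fit$D - tumor_pars$D) / tumor_pars$D, na.rm = TRUE)
  })
  expect_lt(med_err[1], 1e-6)
  expect_lt(med_err[2], med_err[3])
})

test_that("degenerate inputs are flagged or rejected", {
  s <- ivim_signal(protocol_b, tumor_pars$D, tumor_pars$Dstar, tumor_pars$f)
  expect_error(fit_ivim_segmented(s[-1], protocol_b[-1]), "b = 0")
  expect_error(fit_ivim_segmented(s[1:7], protocol_b[1:7]), ">= 2 b-values")
  bad <- s; bad[10] <- -0.01
  fit <- fit_ivim_segmented(bad, protocol_b)
  expect_false(fit$converged)
  expect_true(is.na(fit$D))
})

test_that("map-level outputs are converged-in-bounds or flagged", {
  set.seed(31)
  s <- 1000 * ivim_signal(protocol_b, tumor_pars$D, tumor_pars$Dstar,
                          tumor_pars$f)
  noisy <- add_rician_noise(matrix(s, 200, 11, byrow = TRUE), 25, seed = 4)
  fit <- fit_ivim_full(noisy, protocol_b)
  cfg <- ivim_fit_config()
  conv <- fit$converged
  expect_true(all(is.finite(fit$D[conv])))
  expect_true(all(fit$D[conv] >= cfg$D_bounds[1] - 1e-15 &
                    fit$D[conv] <= cfg$D_bounds[2] + 1e-15))
  expect_true(all(fit$Dstar[conv] >= fit$D[conv] - 1e-12))
  expect_true(all(fit$f[conv] >= 0 & fit$f[conv] <= 1))
})
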