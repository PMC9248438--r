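test_that("the exact Mann-Whitney test matches enumeration and wilcox.test", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)  # 2 of the 20 assignments are as extreme
  # identical multisets: U = n^2 / 2, p = 1
  r2 <- mann_whitney_u(c(1, 2, 2, 5), c(1, 2, 2, 5))
  expect_equal(r2$U, 8)
  expect_equal(r2$p, 1)
  # tie-free random samples against wilcox.test's exact p
  set.seed(10)
  for (k in 1:10) {
    x <- rnorm(4); y <- rnorm(5)
    expect_equal(mann_whitney_u(x, y)$p,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # with ties the enumeration oracle is the reference
  set.seed(11)
  for (k in 1:10) {
    x <- sample(1:4, 4, replace = TRUE); y <- sample(1:4, 4, replace = TRUE)
    expect_equal(mann_whitney_u(x, y, mode = "exact")$p, mw_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("exact and normal-approximation p-values agree for moderate n", {
  set.seed(12)
  x <- rnorm(30); y <- rnorm(30, 0.3)
  pe <- mann_whitney_u(x, y, mode = "exact")$p
  pn <- mann_whitney_u(x, y, mode = "normal")$p
  expect_lt(abs(pe - pn), 0.01)
})

test_that("the U statistic is symmetric and p label-swap invariant", {
  set.seed(13)
  x <- rnorm(8); y <- rnorm(6)
  a <- mann_whitney_u(x, y); b <- mann_whitney_u(y, x)
  expect_equal(a$U + b$U, length(x) * length(y))
  expect_equal(a$p, b$p)
  expect_true(a$p >= 0 && a$p <= 1)
  d <- mann_whitney_u(rep(2, 5), rep(2, 7))
  expect_true(d$degenerate)
  expect_equal(d$p, 1)
})

test_that("Spearman uses mid-ranks and the Pearson-on-ranks identity", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$rho, -1)
  # hand computation: d^2 = (1,1,1,1), rho = 1 - 6*4/(4*15) = 0.6
  expect_equal(spearman_cor(1:4, c(2, 1, 4, 3))$rho, 0.6)
  set.seed(14)
  for (k in 1:10) {
    x <- sample(1:6, 15, replace = TRUE); y <- rnorm(15)
    s <- spearman_cor(x, y)
    expect_equal(s$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
    expect_equal(s$rho, pearson_cor(rank(x), rank(y))$r, tolerance = 1e-12)
  }
  expect_false(spearman_cor(rep(1, 5), rnorm(5))$valid)
})

test_that("Pearson correlation behaves at its limits", {
  x <- rnorm(20)
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  set.seed(15)
  r <- pearson_cor(rnorm(1e4), rnorm(1e4))
  expect_lt(abs(r$r), 0.05)
  expect_equal(pearson_cor(rank(x), rank(x))$r, 1)
})

test_that("least squares matches the normal-equations oracle", {
  x <- seq(-3, 5, length.out = 40)
  f <- suppressWarnings(linear_fit(x, 3 * x - 2))
  expect_equal(f$slope, 3, tolerance = 1e-12)
  expect_equal(f$intercept, -2, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  xc <- x - mean(x)
  y <- rnorm(40)
  expect_equal(linear_fit(xc, y)$intercept, mean(y), tolerance = 1e-12)
  set.seed(16)
  for (k in 1:10) {
    xx <- rnorm(25); yy <- rnorm(25)
    beta <- solve(crossprod(cbind(1, xx)), crossprod(cbind(1, xx), yy))
    f <- linear_fit(xx, yy)
    expect_lt(abs(f$intercept - beta[1]), 1e-10)
    expect_lt(abs(f$slope - beta[2]), 1e-10)
    # residuals orthogonal to x
    expect_lt(abs(sum((yy - f$intercept - f$slope * xx) * xx)), 1e-8)
  }
  expect_error(linear_fit(rep(1, 5), rnorm(5)), "variance")
})

test_that("reports are deterministic functions of the ROI table", {
  set.seed(17)
  n <- 60
  roi <- data.frame(
    analyzed = TRUE,
    tissue = rep(c("tumor", "normal"), c(40, 20)),
    region = c(rep(c("central", "peripheral"), 20), rep("normal", 20)),
    R2star = rnorm(n, 38, 5), D = rnorm(n, 4e-4, 5e-5),
    Dstar = rnorm(n, 2.8e-3, 3e-4), f = runif(n, 0.4, 0.6),
    perfusion = rnorm(n, 1.4e-3, 2e-4),
    hif_score = c(runif(40, 50, 250), runif(20, 0, 60)))
  roi$hif_label <- ifelse(roi$hif_score > 150, "high", "low")
  r1 <- build_report(roi)
  r2 <- build_report(roi)
  expect_identical(report_to_markdown(r1), report_to_markdown(r2))
  # display units: diffusivities in 1e-6 mm^2/s, f in percent
  tvn <- r1$comparisons$tumor_vs_normal
  expect_gt(tvn$mean1[tvn$parameter == "D"], 100)
  expect_gt(tvn$mean1[tvn$parameter == "f"], 10)
  expect_true(all(tvn$p >= 0 & tvn$p <= 1))
  expect_equal(tvn$significant, tvn$p < 0.05)
})
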