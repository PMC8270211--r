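# Normal product tail, variance estimation, composite-null product test.

test_that("normal product tail matches adaptive quadrature to 1e-12 relative", {
  us <- c(0.01, 0.1, 0.3, 0.7, 0.99, 1, 1.3, 2, 3.7, 5, 8, 12, 20, 35, 50)
  for (u in us) {
    expect_equal(normal_product_tail(u), npt_integrate(u),
                 tolerance = 1e-12, label = paste("F at u =", u))
  }
  expect_equal(normal_product_tail(0), 1)
  expect_equal(normal_product_tail(-2), normal_product_tail(2))
})

test_that("normal product tail reproduces frozen quadrature fixtures", {
  for (u in names(NPT_FIXTURES)) {
    expect_equal(normal_product_tail(as.numeric(u)),
                 unname(NPT_FIXTURES[u]), tolerance = 1e-12)
  }
})

test_that("normal product tail is monotone, vectorized and log-stable", {
  u <- seq(0, 40, by = 0.25)
  f <- normal_product_tail(u)
  expect_true(all(diff(f) < 0))
  expect_equal(normal_product_tail(c(0.5, 2)),
               c(normal_product_tail(0.5), normal_product_tail(2)))
  # far beyond double-precision underflow the log branch still works
  lf <- normal_product_tail(c(800, 900), log.p = TRUE)
  expect_true(all(is.finite(lf)))
  expect_lt(lf[2], lf[1])
  expect_error(normal_product_tail(Inf), "finite")
  expect_error(normal_product_tail(NA_real_), "finite")
})

test_that("variance estimation recovers the marginal second moment", {
  # tiny exact case (no screening triggered)
  est <- suppressWarnings(estimate_var_z(c(1, -1, 1, -1), method = "naive"))
  expect_equal(est$var_z, 1)
  expect_equal(est$tau_sq, 0)

  # standard-normal panel: var -> 1 within sampling error of the second moment
  set.seed(301)
  z <- rnorm(1e6)
  for (m in c("naive", "truncated")) {
    est <- estimate_var_z(z, method = m)
    expect_lt(abs(est$var_z - 1), 3 * sqrt(2 / 1e6))
    expect_gte(est$var_z, 1)
  }

  # inflated panel: the naive estimator matches the truncated-normal moment
  # computed by numeric integration; the corrected estimator recovers v
  v_true <- 1.5^2
  z2 <- rnorm(1e6, 0, sqrt(v_true))
  cc <- qnorm(1 - 1e-4 / 2)
  trunc_moment <- integrate(function(x) x^2 * dnorm(x, 0, sqrt(v_true)),
                            -cc, cc, rel.tol = 1e-12)$value /
    (2 * pnorm(cc / sqrt(v_true)) - 1)
  est_naive <- estimate_var_z(z2, method = "naive")
  expect_equal(est_naive$var_z, trunc_moment, tolerance = 0.01)
  est_corr <- estimate_var_z(z2, method = "truncated")
  expect_equal(est_corr$var_z, v_true, tolerance = 0.02)

  expect_warning(estimate_var_z(rnorm(100)), "noisy")
  expect_error(estimate_var_z(numeric(0)), "numeric")
  expect_error(suppressWarnings(estimate_var_z(c(10, -12), p_screen = 0.5)),
               "no variants retained")
})

test_that("composite-null model validates its variances", {
  expect_error(composite_null_model(0.8, 1), ">= 1")
  m <- composite_null_model(1.5, 2)
  expect_equal(m$tau1_sq, 0.5)
  expect_equal(m$tau2_sq, 1)
})

test_that("product test reduces to the plain tail under unit variances", {
  z1 <- c(4, -2, 0.3); z2 <- c(3, 1.5, -2)
  out <- placo_test(z1, z2)
  expect_identical(out$t, z1 * z2)
  expect_identical(out$p, normal_product_tail(z1 * z2))
  expect_equal(placo_test(4, 3)$p, unname(NPT_FIXTURES["12"]),
               tolerance = 1e-12)
})

test_that("a zero Z-score can never reject the composite null", {
  m <- composite_null_model(2.5, 1.3)
  expect_equal(placo_test(0, 5, model = m)$p, 1)
  expect_equal(placo_test(0, 0)$p, 1)
})

test_that("product test is symmetric and monotone in |t|", {
  m <- composite_null_model(1.8, 1.2)
  swapped <- composite_null_model(1.2, 1.8)
  expect_equal(placo_test(3, -2, model = m)$p,
               placo_test(-3, 2, model = m)$p)
  expect_equal(placo_test(3, -2, model = m)$p,
               placo_test(-2, 3, model = swapped)$p)
  z <- seq(0.5, 6, by = 0.5)
  p <- placo_test(z, rep(2, length(z)), model = m)$p
  expect_true(all(diff(p) < 0))
})

test_that("variance scaling uses the standard deviation (with a literal-variance fallback)", {
  # if Z1 ~ N(0, v) and Z2 ~ N(0,1), then Z1 Z2 / sqrt(v) is a standard
  # normal product: Monte Carlo check of the sd scaling
  set.seed(302)
  v <- 2.25
  t_mc <- rnorm(2e6, 0, sqrt(v)) * rnorm(2e6)
  m <- composite_null_model(var_z1 = v, var_z2 = 1)
  u <- placo_threshold(0.01, m)
  emp <- mean(abs(t_mc) >= u)
  expect_lt(abs(emp - 0.01), 3 * sqrt(0.01 * 0.99 / 2e6))
  # literal-variance reading is more conservative at the same t
  p_sd <- placo_test(3, 2, model = m)$p
  p_var <- placo_test(3, 2, model = m, scaling = "variance")$p
  expect_gt(p_var, p_sd)
})

test_that("threshold inversion agrees with the p-value computation", {
  for (m in list(composite_null_model(),
                 composite_null_model(2.4, 1.1))) {
    for (a in c(1e-3, 1e-5, 5e-8)) {
      u <- placo_threshold(a, m)
      expect_equal(placo_test(u, 1, model = m)$p, a, tolerance = 1e-8)
    }
  }
})

test_that("genome-wide scan estimates the model and calibrates under the global null", {
  set.seed(303)
  z1 <- rnorm(1e5); z2 <- rnorm(1e5)
  fit <- placo_genomewide(z1, z2)
  expect_lt(abs(fit$model$var_z1 - 1), 0.02)
  k <- sum(fit$stats$p < 1e-3)
  expect_gte(k, qbinom(0.005, 1e5, 1e-3))
  expect_lte(k, qbinom(0.995, 1e5, 1e-3))
  # a zeroed column forces p = 1 everywhere
  fit0 <- suppressWarnings(placo_genomewide(rep(0, 2000), rnorm(2000)))
  expect_true(all(fit0$stats$p == 1))
})
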