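test_that("the truncated likelihood reduces to the plain exponential at zero dead time", {
  d <- c(0.05, 0.1, 0.4, 0.22)
  k <- 6.5
  expect_equal(loglik_truncated_mixture(d, k, 1, 0),
               sum(log(k) - k * d), tolerance = 1e-12)
})

test_that("durations below the dead time are a pipeline bug, not data", {
  expect_error(loglik_truncated_mixture(c(0.01, 0.2), 5, 1, 0.015), "excluded")
})

test_that("the likelihood is invariant under permutation and component swap", {
  d <- sample_durations(c(20, 3), c(0.8, 0.2), 500, 0.01, seed = 4)
  l1 <- loglik_truncated_mixture(d, c(20, 3), c(0.8, 0.2), 0.01)
  expect_equal(loglik_truncated_mixture(rev(d), c(20, 3), c(0.8, 0.2), 0.01), l1)
  expect_equal(loglik_truncated_mixture(d, c(3, 20), c(0.2, 0.8), 0.01), l1)
  ## amplitude 1 on one component reduces continuously to a single exponential
  expect_equal(loglik_truncated_mixture(d, c(20, 3), c(1, 0), 0.01),
               loglik_truncated_mixture(d, 20, 1, 0.01), tolerance = 1e-12)
})

test_that("the numerical order-1 MLE equals the closed form to 1e-6", {
  for (s in 1:4) {
    k_true <- c(2, 10, 60, 150)[s]
    d <- sample_durations(k_true, 1, 800, dead_time = 0.015, seed = 100 + s)
    fit <- fit_lifetimes(d, 0.015, max_order = 1)$order1
    k_cf <- 1 / (mean(d) - 0.015)
    expect_equal(fit$k1, k_cf, tolerance = 1e-6)
  }
})

test_that("rate recovery is nearly unbiased across the physiological range", {
  for (k_true in c(5, 50, 200)) {
    d <- sample_durations(k_true, 1, 2000, dead_time = 0.015, seed = k_true)
    fit <- fit_lifetimes(d, 0.015, max_order = 1)$order1
    expect_lt(abs(fit$k1 - k_true) / k_true, 0.05)
  }
})

test_that("two-component fits recover a saturating-ATP-like mixture", {
  d <- sample_durations(c(54.4, 7.5), c(0.97, 0.03), 5000,
                        dead_time = 0.015, seed = 11)
  fits <- fit_lifetimes(d, 0.015)
  f2 <- fits$order2
  expect_equal(f2$k1, 54.4, tolerance = 0.10)
  expect_equal(f2$k2, 7.5, tolerance = 0.5)
  expect_equal(f2$amplitude_A, 0.97, tolerance = 0.05)
  expect_gt(f2$amplitude_A, 0.5)  # dominant-component labeling
  sel <- select_model(fits$order1, fits$order2)
  expect_identical(sel$chosen$model_order, 2L)
})

test_that("degenerate input is flagged without a fit", {
  expect_warning(res <- fit_lifetimes(rep(0.2, 50), 0.015), "degenerate")
  expect_true(res$order1$degenerate)
})

test_that("model selection uses the chi-squared LRT with two degrees of freedom", {
  d <- sample_durations(8, 1, 400, 0.01, seed = 2)
  fits <- fit_lifetimes(d, 0.01)
  sel <- select_model(fits$order1, fits$order2)
  D <- 2 * (fits$order2$log_likelihood - fits$order1$log_likelihood)
  expect_equal(sel$p_value, pchisq(max(D, 0), 2, lower.tail = FALSE))
  ## D = 0 gives p = 1 and order 1
  f1 <- fits$order1; f2 <- fits$order2
  f2$log_likelihood <- f1$log_likelihood
  s0 <- select_model(f1, f2)
  expect_equal(s0$p_value, 1)
  expect_identical(s0$chosen$model_order, 1L)
})

test_that("bootstrap confidence intervals behave and are deterministic", {
  d <- sample_durations(6.9, 1, 1500, dead_time = 0.015, seed = 21)
  fit <- fit_lifetimes(d, 0.015, max_order = 1)$order1
  b1 <- bootstrap_ci(d, 0.015, fit, n_boot = 200, seed = 3)
  b2 <- bootstrap_ci(d, 0.015, fit, n_boot = 200, seed = 3)
  expect_identical(b1$ci_95, b2$ci_95)
  ## the point estimate lies inside its own interval, which brackets truth
  expect_gt(fit$k1, b1$ci_95$k1[1]); expect_lt(fit$k1, b1$ci_95$k1[2])
  expect_gt(6.9, b1$ci_95$k1[1] * 0.9); expect_lt(6.9, b1$ci_95$k1[2] * 1.1)

  ## width shrinks roughly as 1/sqrt(n) when n grows 4-fold
  d4 <- sample_durations(6.9, 1, 6000, dead_time = 0.015, seed = 22)
  fit4 <- fit_lifetimes(d4, 0.015, max_order = 1)$order1
  b4 <- bootstrap_ci(d4, 0.015, fit4, n_boot = 200, seed = 4)
  ratio <- diff(b1$ci_95$k1) / diff(b4$ci_95$k1)
  expect_gt(ratio, 1.4); expect_lt(ratio, 2.9)
  expect_error(bootstrap_ci(d, 0.015, fit, n_boot = 50, seed = 1), ">= 200")
})

test_that("the molecule filter keeps > 75 events only", {
  counts <- list(a = 75L, b = 76L, c = 200L, d = 10L)
  res <- filter_molecules(counts)
  expect_setequal(res$included, c("b", "c"))
  expect_setequal(res$excluded$molecule_id, c("a", "d"))
  expect_true(all(res$excluded$reason == "fewer_than_min_events"))
  ## empty input gives empty output
  expect_length(filter_molecules(list())$included, 0)
})

test_that("duty ratio is v_max over the detachment rate", {
  d <- duty_ratio(54.4, 5.1)
  expect_equal(d$value, 5.1 / 54.4, tolerance = 1e-12)
  expect_equal(duty_ratio(69.7, 5.7)$value, 5.7 / 69.7, tolerance = 1e-12)
  expect_warning(duty_ratio(5, 5), "nonphysical")
})
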