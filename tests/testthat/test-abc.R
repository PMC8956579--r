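make_series <- function(t, a, b) data.frame(time = t, x = a, y = b)

test_that("distance_rho is the summed absolute deviation", {
  t <- 0:4
  a <- make_series(t, c(1, 2, 3, 4, 5), c(0, 1, 0, 1, 0))
  expect_equal(distance_rho(a, a), 0)
  b <- a; b$x[3] <- b$x[3] + 1
  expect_equal(distance_rho(a, b), 1)
  set.seed(61)
  for (i in 1:20) {
    r1 <- make_series(t, runif(5, 0, 5), runif(5, 0, 5))
    r2 <- make_series(t, runif(5, 0, 5), runif(5, 0, 5))
    r3 <- make_series(t, runif(5, 0, 5), runif(5, 0, 5))
    expect_lte(distance_rho(r1, r3), distance_rho(r1, r2) + distance_rho(r2, r3) + 1e-12)
  }
  expect_error(distance_rho(a, make_series(t + 0.5, a$x, a$y)),
               class = "embedstable_input_error")
})

test_that("simulate_observables integrates accurately", {
  p <- example_xy_params()
  tp <- seq(0, 10, by = 1)
  # zero initial state stays zero (no basal production)
  z <- simulate_observables(p, tp, c(0, 0))
  expect_true(all(z$x == 0) && all(z$y == 0))
  tr <- simulate_observables(p, tp, c(0.5, 0.3))
  expect_true(all(tr$x >= 0 & tr$y >= 0))
  # step-halving oracle: dt and dt/2 agree to 1e-6; and the compiled RK4
  # matches a plain-R reference integrator
  tr2 <- simulate_observables(p, tp, c(0.5, 0.3), dt = 0.005)
  expect_equal(tr$x, tr2$x, tolerance = 1e-6)
  ref <- rk4_reference(function(s) twonode_rhs(s, p), c(0.5, 0.3), 10, 0.01)
  expect_equal(unlist(tr[nrow(tr), c("x", "y")]), ref,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(simulate_observables(p, c(0, 0, 1), c(1, 1)),
               class = "embedstable_input_error")
})

test_that("synth_target adds truncated Gaussian noise of the right size", {
  p <- example_xy_params()
  tp <- seq(0, 18, length.out = 10)
  clean <- simulate_observables(p, tp, c(0.5, 0.3))
  s0 <- synth_target(p, tp, c(0.5, 0.3), noise_sd = 0, seed = 5)
  expect_equal(s0$x, clean$x)
  expect_equal(s0$y, clean$y)
  # Monte-Carlo: residual sd matches noise_sd (values are far from the
  # truncation boundary at 0, so truncation bias is negligible for x)
  res <- unlist(lapply(1:300, function(i) {
    synth_target(p, tp, c(2, 0.1), noise_sd = 0.15, seed = i)$x -
      simulate_observables(p, tp, c(2, 0.1))$x
  }))
  expect_equal(sd(res), 0.15, tolerance = 0.05)
  expect_true(all(synth_target(p, tp, c(0.5, 0.3), noise_sd = 5, seed = 1)$y >= 0))
})

test_that("abc_rejection accepts by tolerance and by quantile", {
  data <- synth_target(example_xy_params(), seed = 2)
  cfg_all <- abc_config(tolerance = Inf, quantile = NULL, n_draws = 200, seed = 3)
  res_all <- abc_rejection(data, cfg_all)
  expect_equal(res_all$acceptance_rate, 1)
  cfg_q <- abc_config(quantile = 0.05, n_draws = 200, seed = 3)
  res_q <- abc_rejection(data, cfg_q)
  expect_equal(nrow(res_q$accepted), 10)
  # posterior values lie inside the prior box
  expect_true(all(res_q$accepted[embedstable:::PARAM_SLOTS] >= 0 &
                    res_q$accepted[embedstable:::PARAM_SLOTS] <= 100))
  # shrinking the tolerance never increases the maximum accepted distance
  d_loose <- max(abc_rejection(data, abc_config(tolerance = 50, quantile = NULL,
                                                n_draws = 200, seed = 3))$accepted$distance)
  suppressWarnings({
    res_tight <- abc_rejection(data, abc_config(tolerance = 20, quantile = NULL,
                                                n_draws = 200, seed = 3))
  })
  if (nrow(res_tight$accepted) > 0)
    expect_lte(max(res_tight$accepted$distance), d_loose)
  expect_warning(abc_rejection(data, abc_config(tolerance = 1e-9, quantile = NULL,
                                                n_draws = 50, seed = 3)),
                 "empty posterior")
  expect_error(abc_config(tolerance = 1, quantile = 0.1),
               class = "embedstable_input_error")
})

test_that("posterior_median and zu_observables behave", {
  data <- synth_target(example_xy_params(), seed = 2)
  res <- abc_rejection(data, abc_config(quantile = 0.05, n_draws = 200, seed = 3))
  med <- posterior_median(res)
  expect_s3_class(med, "twonode_params")
  expect_equal(med$gain1, median(res$accepted$gain1))
  d3 <- data.frame(time = 0:2, gata2 = c(5, 4, 3), gata1 = c(1, 2, 3),
                   pu1 = c(0.5, 0.5, 0.5))
  zu <- zu_observables(d3)
  expect_equal(zu$u, c(1.5, 2.5, 3.5))
  expect_equal(zu$z, c(5, 4, 3))
})
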