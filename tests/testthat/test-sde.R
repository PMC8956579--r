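quad_fix <- function() example_quad_params()
sched_fix <- function(k0 = 0.52) switch_schedule(k0, 500, 3500, 5e-4)

test_that("sde_step implements the semi-implicit scheme", {
  qp <- quad_fix()
  sc <- sched_fix()
  s <- c(1, 2, 3)
  # zero increments: the deterministic semi-implicit step, checked manually
  nxt <- sde_step(s, t = 1000, dt = 0.01, qp, sc, noise_params(), dW = c(0, 0, 0))
  ks <- 0.52
  prodx <- (qp$alpha0 + qp$alpha1 * 1) / (1 + qp$beta1 * 1) / (1 + qp$beta2 * 2) *
    (1 + qp$d_star * 3) / (1 + qp$d2 * 3) + sc$psi * ks * 3
  expect_equal(nxt[1], (1 + 0.01 * prodx) / (1 + 0.01 * qp$k3))
  # the implicit discretisation is exact for pure decay as dt -> 0
  expect_error(sde_step(s, 0, -0.1, qp, sc, noise_params()),
               class = "embedstable_input_error")
  # zero state with zero basal rates stays at zero
  q0 <- quad_params(example_tristable_params())
  nxt0 <- sde_step(c(0, 0, 0), 1000, 0.01, q0, sc, noise_params())
  expect_equal(nxt0, c(0, 0, 0))
  # R step and compiled path agree for one step under the same RNG draws
  set.seed(77)
  cfg <- sde_config(dt = 0.01, t_end = 0.01, init = s, sched = sc,
                    noise = noise_params(), seed = 77)
  tr <- simulate_sde(cfg, qp, save_every = 1)
  set.seed(77)
  nxtR <- sde_step(s, 0, 0.01, qp, sc, noise_params())
  expect_equal(unlist(tr[2, c("x", "y", "z")]), nxtR, ignore_attr = TRUE)
})

test_that("simulate_sde is reproducible, non-negative, with N(0, dt) increments", {
  qp <- quad_fix()
  cfg <- sde_config(dt = 0.01, t_end = 50, init = c(0.5, 0.5, 4),
                    sched = sched_fix(), noise = noise_params(), seed = 11)
  tr1 <- simulate_sde(cfg, qp)
  tr2 <- simulate_sde(cfg, qp)
  expect_identical(tr1, tr2)
  expect_true(all(as.matrix(tr1[, c("x", "y", "z")]) >= 0))
  # Wiener increments: mean 0, variance dt over 15000 draws
  cfg2 <- sde_config(dt = 0.02, t_end = 100, init = c(0.5, 0.5, 4),
                     sched = sched_fix(), noise = noise_params(), seed = 12)
  tr <- simulate_sde(cfg2, qp, return_increments = TRUE)
  inc <- attr(tr, "increments")
  expect_equal(nrow(inc), 5000)
  # 3 sigma for a sample variance over n draws is ~ 3*sqrt(2/n) relative
  expect_equal(var(as.numeric(inc)), 0.02, tolerance = 3 * sqrt(2 / 15000))
  expect_lt(abs(mean(as.numeric(inc))), 3 * sqrt(0.02 / length(inc)))
})

test_that("zero-noise SDE reduces to the ODE solution", {
  qp <- quad_fix()
  sc <- sched_fix()
  cfg <- sde_config(dt = 0.01, t_end = 200, init = c(0.5, 0.5, 4), sched = sc,
                    noise = noise_params(0, 0, 0), seed = 1)
  tr <- simulate_sde(cfg, qp, save_every = 100)
  ode <- simulate_observables(qp, seq(0, 200, by = 1), c(0.5, 0.5, 4),
                              dt = 0.005, sched = sc)
  fin_sde <- unlist(tr[nrow(tr), c("x", "y", "z")])
  fin_ode <- unlist(ode[nrow(ode), c("x", "y", "z")])
  expect_equal(fin_sde, fin_ode, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("ensemble mean approaches the ODE as noise shrinks", {
  qp <- quad_fix()
  sc <- sched_fix(0)          # autonomous: no switching window
  # init chosen inside a single basin: near a separatrix the ensemble splits
  # between attractors and its mean cannot approach the single ODE solution
  init <- c(4, 0.5, 1)
  ode <- simulate_observables(qp, c(0, 20), init, dt = 0.01)
  target <- unlist(ode[2, c("x", "y", "z")])
  errs <- vapply(c(0.2, 0.05), function(w) {
    cfg <- sde_config(dt = 0.01, t_end = 20, init = init, sched = sc,
                      noise = noise_params(w, w, w), seed = 21)
    ens <- run_ensemble(200, cfg, qp,
                        stable_states = data.frame(x = 1, y = 1, z = 1,
                                                   label = "G2H"))
    mean(abs(colMeans(ens$final_states) - target))
  }, numeric(1))
  expect_lt(errs[2], errs[1] + 0.02)
  expect_lt(errs[2], 0.1)
})

test_that("classify_endpoint uses nearest log-scale stable state", {
  ss <- data.frame(x = c(0.1, 8, 0.1, 1), y = c(0.1, 0.1, 8, 1),
                   z = c(8, 0.1, 0.1, 1),
                   label = c("G2H", "G1H", "P1H", "LE3G"))
  expect_equal(classify_endpoint(c(0.1, 0.1, 8), ss), "G2H")
  expect_equal(classify_endpoint(c(7, 0.2, 0.3), ss), "G1H")
  expect_equal(classify_endpoint(c(1.2, 1.1, 0.9), ss), "LE3G")
  # matrix input
  expect_equal(classify_endpoint(rbind(c(0.1, 0.1, 8), c(0.3, 7, 0.2)), ss),
               c("G2H", "P1H"))
  # equidistant tie resolves to the earlier row
  ss2 <- data.frame(x = c(1, 3), y = c(1, 1), z = c(3, 1),
                    label = c("G2H", "G1H"))
  expect_equal(classify_endpoint(c(2, 1, 2), ss2), "G2H")
  # cutoff and in-window rules
  expect_equal(classify_endpoint(c(100, 100, 100), ss, cutoff = 0.5), "unclassified")
  expect_equal(classify_endpoint(c(0.1, 0.1, 8), ss, final_time = 1000,
                                 sched = sched_fix()), "unclassified")
  expect_error(classify_endpoint(c(1, 1, 1), data.frame()),
               class = "embedstable_input_error")
})

test_that("label_stable_states identifies the four state types", {
  m <- rbind(c(0.2, 0.3, 9), c(7, 0.2, 0.4), c(0.3, 8, 0.2), c(1, 1, 1.5))
  lab <- label_stable_states(m)
  expect_equal(lab$label, c("G2H", "G1H", "P1H", "LE3G"))
})

test_that("run_ensemble frequencies are consistent", {
  qp <- quad_fix()
  ss <- label_stable_states(find_equilibria(qp))
  cfg <- sde_config(dt = 0.02, t_end = 30, init = c(2, 2, 2), sched = sched_fix(0),
                    noise = noise_params(), seed = 31)
  ens <- run_ensemble(60, cfg, qp, ss)
  expect_equal(sum(ens$frequencies), 1)
  expect_equal(sum(ens$counts), 60)
  # zero noise: every replicate identical, a single label
  cfg0 <- sde_config(dt = 0.02, t_end = 30, init = c(2, 2, 2), sched = sched_fix(0),
                     noise = noise_params(0, 0, 0), seed = 32)
  ens0 <- run_ensemble(5, cfg0, qp, ss)
  expect_length(unique(ens0$labels), 1)
  expect_equal(max(ens0$counts), 5)
})

test_that("expression_distributions groups log-transformed endpoint values", {
  qp <- quad_fix()
  ss <- label_stable_states(find_equilibria(qp))
  cfg <- sde_config(dt = 0.02, t_end = 20, init = c(2, 2, 2), sched = sched_fix(0),
                    noise = noise_params(0, 0, 0), seed = 33)
  ens <- run_ensemble(4, cfg, qp, ss)
  dist <- expression_distributions(ens)
  expect_equal(nrow(dist$values), 12)  # 4 replicates x 3 genes
  expect_equal(dist$values$value,
               log1p(as.numeric(ens$final_states[, c("x", "y", "z")])))
  # all-equal values (zero noise) give zero interquartile range
  expect_true(all(dist$summary$q75 - dist$summary$q25 < 1e-12))
  expect_equal(log1p(0), 0)
})

test_that("sweep_switching reports per-cell metrics with sound edge cases", {
  qp <- quad_fix()
  ss <- label_stable_states(find_equilibria(qp))
  g2h <- ss[ss$label == "G2H", ]
  init <- if (nrow(g2h) == 1) as.numeric(g2h[1, 1:3]) else c(0.2, 0.2, 3)
  cfg <- sde_config(dt = 0.02, t_end = 120, init = init,
                    sched = switch_schedule(0.5, 20, 60, 5e-4),
                    noise = noise_params(0, 0, 0), seed = 41)
  res <- sweep_switching(c(0, 0.5), c(0, 5e-4), n_per_cell = 3, cfg, qp, ss)
  expect_equal(nrow(res), 4)
  # k0* = 0: no displacement, nothing switches, ratio undefined
  zero_rows <- res[res$k0_star == 0, ]
  expect_true(all(zero_rows$switched == 0))
  expect_true(all(is.na(zero_rows$gmp_mep_ratio)))
  expect_true(all(res$switched >= 0 & res$switched <= 1))
})
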