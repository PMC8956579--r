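test_that("toggle_rhs matches the closed-form vector field", {
  p <- toggle_params()
  expect_equal(toggle_rhs(c(0, 0), p), c(4.2, 4.2))
  # symmetric fixed point: s solves s = 0.2 + 4/(1 + s^3) (scalar root oracle)
  s_star <- uniroot(function(s) 0.2 + 4 / (1 + s^3) - s, c(0.1, 5),
                    tol = 1e-12)$root
  expect_equal(toggle_rhs(c(s_star, s_star), p), c(0, 0), tolerance = 1e-9)
  # strong repression limit: dz/dt -> basal - z
  expect_equal(toggle_rhs(c(0.2, 1e8), p)[1], 0, tolerance = 1e-12)
})

test_that("twonode_rhs has the analytic equilibria and matches the flow", {
  p <- xy_params(2, 1, 0.5, 1, 3, 2, 0.7, 1)
  expect_equal(twonode_rhs(c(0, 0), p), c(0, 0))
  xe <- (p$gain1 - p$deg1) / (p$deg1 * p$sat1)
  expect_equal(twonode_rhs(c(xe, 0), p), c(0, 0), tolerance = 1e-12)
  # derivative equals the integrated flow's difference quotient
  set.seed(41)
  for (i in 1:20) {
    pp <- random_twonode()
    s0 <- runif(2, 0, 5)
    h <- 1e-4
    phi_h <- rk4_reference(function(s) twonode_rhs(s, pp), s0, h, h / 10)
    expect_equal((phi_h - s0) / h, twonode_rhs(s0, pp), tolerance = 1e-2)
  }
})

test_that("k_star is the closed-window indicator", {
  sc <- switch_schedule(0.52, 500, 3500, 5e-4)
  expect_equal(k_star(500, sc), 0.52)
  expect_equal(k_star(3500, sc), 0.52)
  expect_equal(k_star(3500.0001, sc), 0)
  expect_equal(k_star(499.9999, sc), 0)
  sc0 <- switch_schedule(0, 500, 3500, 5e-4)
  expect_equal(k_star(c(0, 1000, 5000), sc0), c(0, 0, 0))
})

test_that("gata_switch_rhs reduces to twonode and transfers mass at ratio psi", {
  zu <- example_zu_params()
  sc0 <- switch_schedule(0, 500, 3500, 0.1)
  sc <- switch_schedule(0.52, 500, 3500, 0.3)
  set.seed(42)
  for (i in 1:10) {
    s <- runif(2, 0, 5)
    expect_identical(gata_switch_rhs(s, zu, sc0, t = 1000), twonode_rhs(s, zu))
    # switching terms: du gain / dz loss = psi
    base <- twonode_rhs(s, zu)
    sw <- gata_switch_rhs(s, zu, sc, t = 1000) - base
    if (s[1] > 0) expect_equal(sw[2] / -sw[1], sc$psi, tolerance = 1e-12)
  }
  # outside the window nothing happens
  s <- c(2, 1)
  expect_identical(gata_switch_rhs(s, zu, sc, t = 4000), twonode_rhs(s, zu))
  # z > 0, u = 0 inside the window: positive GATA1 source
  expect_gt(gata_switch_rhs(c(2, 0), zu, sc, t = 1000)[2], 0)
})

test_that("tristable_rhs restricts correctly to the invariant planes", {
  tri <- example_tristable_params()
  xy <- example_xy_params()
  set.seed(43)
  for (i in 1:10) {
    s2 <- runif(2, 0, 5)
    # z = 0 plane: x-y components equal the subsystem field
    expect_equal(tristable_rhs(c(s2, 0), tri)[1:2], twonode_rhs(s2, xy))
    # x = y = 0 line: z component is the z-node equation with no repression
    z <- s2[1]
    expect_equal(tristable_rhs(c(0, 0, z), tri)[3],
                 tri$a1 * z / (1 + tri$b1 * z) - tri$k1 * z)
  }
  # Theorem-4 axis lift
  xe <- (tri$alpha1 - tri$k3) / (tri$k3 * tri$beta1)
  expect_equal(tristable_rhs(c(xe, 0, 0), tri), c(0, 0, 0), tolerance = 1e-12)
  ze <- (tri$a1 - tri$k1) / (tri$k1 * tri$b1)
  expect_equal(tristable_rhs(c(0, 0, ze), tri), c(0, 0, 0), tolerance = 1e-12)
})

test_that("quad_rhs reduces to tristable_rhs and handles the z factor", {
  tri <- example_tristable_params()
  q0 <- quad_params(tri)  # all modifications zero
  set.seed(44)
  for (i in 1:10) {
    s <- runif(3, 0, 5)
    expect_identical(quad_rhs(s, q0), tristable_rhs(s, tri))
  }
  # basal constants make the origin a source in all components
  qb <- quad_params(tri, alpha0 = 0.1, gamma0 = 0.2, a0 = 0.3)
  expect_true(all(quad_rhs(c(0, 0, 0), qb) > 0))
  # d_star = d2: the z factor in dx/dt cancels
  qd <- quad_params(tri, d_star = tri$d2)
  s <- c(1.3, 0.7, 2.1)
  dx_manual <- qd$alpha1 * s[1] / (1 + qd$beta1 * s[1]) / (1 + qd$beta2 * s[2]) -
    qd$k3 * s[1]
  expect_equal(quad_rhs(s, qd)[1], dx_manual, tolerance = 1e-14)
})

test_that("all vector fields are forward invariant on the boundary", {
  set.seed(45)
  sc <- switch_schedule(0.52, 0, 100, 5e-4)
  for (i in 1:40) {
    p2 <- random_twonode()
    tri <- tristable_params(random_twonode(), runif(1, 0, 10), runif(1, 0, 10),
                            runif(1, 0, 10), runif(1, 0.05, 10), runif(1, 0, 10))
    qp <- quad_params(tri, runif(1, 0, 1), runif(1, 0, 1), runif(1, 0, 1),
                      runif(1, 0, 2))
    j2 <- sample(2, 1); j3 <- sample(3, 1)
    s2 <- runif(2, 0, 5); s2[j2] <- 0
    s3 <- runif(3, 0, 5); s3[j3] <- 0
    expect_gte(twonode_rhs(s2, p2)[j2], 0)
    expect_gte(toggle_rhs(s2, toggle_params())[j2], 0)
    expect_gte(gata_switch_rhs(s2, p2, sc, t = 50)[j2], 0)
    expect_gte(tristable_rhs(s3, tri)[j3], 0)
    expect_gte(quad_rhs(s3, qp, sc, t = 50)[j3], 0)
  }
})

test_that("parameter validation rejects invalid input", {
  expect_error(toggle_params(basal = -1), class = "embedstable_input_error")
  expect_error(twonode_params(1, 1, -2, 1, 1, 1, 1, 1),
               class = "embedstable_input_error")
  expect_error(twonode_params(1, 1, 1, 0, 1, 1, 1, 1),
               class = "embedstable_input_error")  # degradation must be > 0
  expect_error(switch_schedule(0.5, t1 = 10, t2 = 5),
               class = "embedstable_input_error")
  expect_error(noise_params(omega1 = -0.1), class = "embedstable_input_error")
  expect_error(twonode_rhs(c(1, 2, 3), example_xy_params()),
               class = "embedstable_input_error")
  expect_error(toggle_rhs(c(1, 2, 3)), class = "embedstable_input_error")
})

test_that("model configuration files round-trip", {
  cfg <- tempfile(fileext = ".json")
  sections <- list(xy = example_xy_params(), zu = example_zu_params(),
                   quad = example_quad_params(), schedule = switch_schedule(),
                   noise = noise_params(), toggle = toggle_params())
  write_model_config(sections, cfg)
  back <- read_model_config(cfg)
  expect_named(back, names(sections))
  for (nm in names(sections)) expect_equal(back[[nm]], sections[[nm]])
  expect_error(read_model_config(tempfile()), class = "embedstable_input_error")
})
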