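# Shared oracles and fixture builders, independent of the implementation
# paths they check.

# Plain-R RK4 with fixed step, for step-halving and reference solves.
rk4_reference <- function(f, init, t_end, dt) {
  n <- ceiling(t_end / dt)
  h <- t_end / n
  s <- init
  for (k in seq_len(n)) {
    k1 <- f(s)
    k2 <- f(s + h / 2 * k1)
    k3 <- f(s + h / 2 * k2)
    k4 <- f(s + h * k3)
    s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  s
}

# Hand-derived analytic Jacobian of the two-node Shea-Ackers model.
twonode_jacobian_analytic <- function(p, s) {
  x <- s[1]; y <- s[2]
  d1 <- (1 + p$sat1 * x) * (1 + p$rep1 * y)
  d2 <- (1 + p$sat2 * y) * (1 + p$rep2 * x)
  matrix(c(
    p$gain1 / ((1 + p$sat1 * x)^2 * (1 + p$rep1 * y)) - p$deg1,
    -p$gain1 * x * p$rep1 / ((1 + p$sat1 * x) * (1 + p$rep1 * y)^2),
    -p$gain2 * y * p$rep2 / ((1 + p$sat2 * y) * (1 + p$rep2 * x)^2),
    p$gain2 / ((1 + p$sat2 * y)^2 * (1 + p$rep2 * x)) - p$deg2
  ), 2, 2, byrow = TRUE)
}

# A random valid twonode parameter draw (uniform over [0, A]); degradation
# bounded away from 0 so closed-form expressions stay well-conditioned.
random_twonode <- function(A = 10, deg_min = 0.05) {
  p <- runif(8, 0, A)
  p[4] <- max(p[4], deg_min)
  p[8] <- max(p[8], deg_min)
  twonode_params(p[1], p[2], p[3], p[4], p[5], p[6], p[7], p[8])
}

# Rejection-sample a draw that has at least one interior equilibrium
# (roughly 1 in 120 uniform draws qualifies).
random_twonode_with_interior <- function(max_tries = 5000) {
  for (i in seq_len(max_tries)) {
    p <- random_twonode()
    if (length(interior_equilibria_2d(p)) > 0) return(p)
  }
  stop("no interior-equilibrium draw found")
}

# Embedded toggle system (z-u primary with u substituted by x + y).
embedded_toggle <- function(params = toggle_params()) {
  embed(toggle_subsystem(params, vars = c("z", "u"), aux = "u"),
        toggle_subsystem(params, vars = c("x", "y")),
        list(u = c(x = 1, y = 1)))
}

# Hand-coded embedded-toggle vector field, written straight from the coupled
# three-gene equations (independent of the embedding machinery).
eq3_rhs <- function(s, a = 0.2, b = 4, n = 3) {
  x <- s[1]; y <- s[2]; z <- s[3]
  c(a + b / ((1 + y^n) * (1 + z^n)) - x,
    a + b / ((1 + x^n) * (1 + z^n)) - y,
    a + b / (1 + (x + y)^n) - z)
}
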