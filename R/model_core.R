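#' Right-hand sides of the regulatory-network models
#'
#' Every model in the package is exposed as an evaluatable vector field
#' `f(state, ...) -> derivative`.  States are non-negative concentration
#' vectors; none of the RHS functions clamp or project their input (clamping
#' happens only inside the stochastic integrator).
#'
#' @name model-core
NULL

#' Toggle-switch vector field
#'
#' The symmetric two-gene toggle switch with Hill cross-repression:
#' \deqn{dz/dt = a + b/(1 + u^n) - z, \quad du/dt = a + b/(1 + z^n) - u}
#' with `a = basal`, `b = strength`, `n = hill`.
#'
#' @param state numeric length-2 non-negative state `(z, u)`
#' @param params a [toggle_params()] object
#' @return numeric length-2 derivative
#' @examples
#' toggle_rhs(c(0, 0), toggle_params())   # c(4.2, 4.2)
#' @export
toggle_rhs <- function(state, params = toggle_params()) {
  stopifnot(inherits(params, "toggle_params"))
  s <- check_state(state, 2L, allow_negative = TRUE)
  c(params$basal + params$strength / (1 + s[2]^params$hill) - s[1],
    params$basal + params$strength / (1 + s[1]^params$hill) - s[2])
}

#' Two-node Shea-Ackers vector field
#'
#' Double-negative feedback with positive autoregulation:
#' \deqn{dx/dt = \alpha_1 x /((1+\beta_1 x)(1+\beta_2 y)) - k_3 x}
#' \deqn{dy/dt = \gamma_1 y /((1+\sigma_1 y)(1+\sigma_2 x)) - k_4 y}
#' The origin is always an equilibrium: every term is proportional to its own
#' variable.
#'
#' @param state numeric length-2 non-negative state
#' @param params a [twonode_params()] object ([xy_params()] / [zu_params()])
#' @return numeric length-2 derivative
#' @export
twonode_rhs <- function(state, params) {
  stopifnot(inherits(params, "twonode_params"))
  s <- check_state(state, 2L, allow_negative = TRUE)
  c(params$gain1 * s[1] / ((1 + params$sat1 * s[1]) * (1 + params$rep1 * s[2])) -
      params$deg1 * s[1],
    params$gain2 * s[2] / ((1 + params$sat2 * s[2]) * (1 + params$rep2 * s[1])) -
      params$deg2 * s[2])
}

#' Time-dependent GATA-switching rate
#'
#' Returns `k0_star` when `t` lies in the closed window `[t1, t2]` and 0
#' otherwise.  Boundary ties resolve to `k0_star`.  Vectorised over `t`.
#'
#' @param t numeric time(s)
#' @param sched a [switch_schedule()] object
#' @return numeric rate(s), same length as `t`
#' @examples
#' k_star(500, switch_schedule(0.52, 500, 3500, 5e-4))  # 0.52
#' @export
k_star <- function(t, sched) {
  stopifnot(inherits(sched, "switch_schedule"))
  ifelse(t >= sched$t1 & t <= sched$t2, sched$k0_star, 0)
}

#' GATA-switching module vector field
#'
#' The Z-U Shea-Ackers module augmented with displacement of chromatin-bound
#' GATA2 (z) at rate `k_star(t)` and proportional release of GATA1 into u at
#' rate `psi * k_star(t) * z`:
#' \deqn{dz/dt = a_1 z/((1+b_1 z)(1+b_2 u)) - k_1 z - k^*(t) z}
#' \deqn{du/dt = c_1 u/((1+d_1 u)(1+d_2 z)) - k_2 u + \psi k^*(t) z}
#' With `k0_star = 0` this is exactly [twonode_rhs()].
#'
#' @param state numeric length-2 non-negative state `(z, u)`
#' @param params a [zu_params()] (`twonode_params`) object
#' @param sched a [switch_schedule()] object
#' @param t time at which to evaluate the schedule
#' @return numeric length-2 derivative
#' @export
gata_switch_rhs <- function(state, params, sched, t = 0) {
  base <- twonode_rhs(state, params)
  ks <- k_star(t, sched)
  base + c(-ks * state[1], sched$psi * ks * state[1])
}

#' Embedded three-gene (tristable) vector field
#'
#' The X-Y subsystem embedded into the Z-U subsystem via u = x + y.  Both x
#' and y production terms inherit the factor `1/(1 + d2 z)`; the z production
#' is repressed by the sum `x + y`:
#' \deqn{dx/dt = \alpha_1 x/((1+\beta_1 x)(1+\beta_2 y)(1+d_2 z)) - k_3 x}
#' \deqn{dy/dt = \gamma_1 y/((1+\sigma_1 y)(1+\sigma_2 x)(1+d_2 z)) - k_4 y}
#' \deqn{dz/dt = a_1 z/((1+b_1 z)(1+b_2 (x+y))) - k_1 z}
#'
#' @param state numeric length-3 non-negative state `(x, y, z)`
#' @param params a [tristable_params()] object
#' @return numeric length-3 derivative
#' @export
tristable_rhs <- function(state, params) {
  stopifnot(inherits(params, "tristable_params"))
  s <- check_state(state, 3L, allow_negative = TRUE)
  x <- s[1]; y <- s[2]; z <- s[3]
  # evaluation order matches quad_rhs exactly, so that the quad model with
  # zero basal constants reduces to this function bitwise
  c((0 + params$alpha1 * x) / (1 + params$beta1 * x) /
      (1 + params$beta2 * y) * (1 + 0 * z) / (1 + params$d2 * z) -
      params$k3 * x,
    (0 + params$gamma1 * y) / (1 + params$sigma1 * y) /
      (1 + params$sigma2 * x) / (1 + params$d2 * z) - params$k4 * y,
    (0 + params$a1 * z) / (1 + params$b1 * z) /
      (1 + params$b2 * (x + y)) - params$k1 * z)
}

#' Quad-stable GATA1-GATA2-PU.1 vector field
#'
#' The modified embedded model with basal production constants, a weak
#' positive regulation from GATA2 (z) to GATA1 (x), and GATA-switching terms:
#' \deqn{dx/dt = \frac{\alpha_0+\alpha_1 x}{1+\beta_1 x}
#'   \frac{1}{1+\beta_2 y}\frac{1+d^* z}{1+d_2 z} - k_3 x + \psi k^*(t) z}
#' \deqn{dy/dt = \frac{\gamma_0+\gamma_1 y}{1+\sigma_1 y}
#'   \frac{1}{1+\sigma_2 x}\frac{1}{1+d_2 z} - k_4 y}
#' \deqn{dz/dt = \frac{a_0+a_1 z}{1+b_1 z}\frac{1}{1+b_2(x+y)}
#'   - k_1 z - k^*(t) z}
#' With `alpha0 = gamma0 = a0 = d_star = 0` and no schedule this reduces
#' exactly to [tristable_rhs()].
#'
#' @param state numeric length-3 non-negative state `(x, y, z)`
#' @param params a [quad_params()] object
#' @param sched a [switch_schedule()] object, or `NULL` for `k_star = 0`
#' @param t time at which to evaluate the schedule
#' @return numeric length-3 derivative
#' @export
quad_rhs <- function(state, params, sched = NULL, t = 0) {
  stopifnot(inherits(params, "quad_params"))
  s <- check_state(state, 3L, allow_negative = TRUE)
  x <- s[1]; y <- s[2]; z <- s[3]
  ks <- if (is.null(sched)) 0 else k_star(t, sched)
  psi <- if (is.null(sched)) 0 else sched$psi
  c((params$alpha0 + params$alpha1 * x) / (1 + params$beta1 * x) /
      (1 + params$beta2 * y) * (1 + params$d_star * z) / (1 + params$d2 * z) -
      params$k3 * x + psi * ks * z,
    (params$gamma0 + params$gamma1 * y) / (1 + params$sigma1 * y) /
      (1 + params$sigma2 * x) / (1 + params$d2 * z) - params$k4 * y,
    (params$a0 + params$a1 * z) / (1 + params$b1 * z) /
      (1 + params$b2 * (x + y)) - params$k1 * z - ks * z)
}

# Numeric model ids shared with the C++ integrators; parameter vector layouts
# must match src/integrators.cpp.
MODEL_TOGGLE <- 1L
MODEL_TWONODE <- 2L
MODEL_TRISTABLE <- 3L
MODEL_QUAD <- 4L

model_id <- function(params) {
  if (inherits(params, "quad_params")) MODEL_QUAD
  else if (inherits(params, "tristable_params")) MODEL_TRISTABLE
  else if (inherits(params, "twonode_params")) MODEL_TWONODE
  else if (inherits(params, "toggle_params")) MODEL_TOGGLE
  else stop_input("unsupported parameter object for compiled integration")
}

param_vec <- function(params) {
  if (inherits(params, "quad_params"))
    with(params, c(alpha1, beta1, beta2, k3, gamma1, sigma1, sigma2, k4,
                   a1, b1, b2, k1, d2, alpha0, gamma0, a0, d_star))
  else if (inherits(params, "tristable_params"))
    with(params, c(alpha1, beta1, beta2, k3, gamma1, sigma1, sigma2, k4,
                   a1, b1, b2, k1, d2, 0, 0, 0, 0))
  else if (inherits(params, "twonode_params"))
    with(params, c(gain1, sat1, rep1, deg1, gain2, sat2, rep2, deg2))
  else if (inherits(params, "toggle_params"))
    with(params, c(basal, strength, hill))
  else stop_input("unsupported parameter object for compiled integration")
}

model_dim <- function(params) {
  if (inherits(params, c("quad_params", "tristable_params"))) 3L else 2L
}

# Generic RHS closure for a parameter object (used by the equilibrium finder).
rhs_function <- function(params, sched = NULL, t = 0) {
  if (inherits(params, "quad_params")) {
    function(s) quad_rhs(s, params, sched, t)
  } else if (inherits(params, "tristable_params")) {
    function(s) tristable_rhs(s, params)
  } else if (inherits(params, "twonode_params")) {
    if (is.null(sched)) function(s) twonode_rhs(s, params)
    else function(s) gata_switch_rhs(s, params, sched, t)
  } else if (inherits(params, "toggle_params")) {
    function(s) toggle_rhs(s, params)
  } else stop_input("unsupported parameter object")
}
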