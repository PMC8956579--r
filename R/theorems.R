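#' Closed-form equilibria and stability conditions for the two-node and
#' embedded three-node Shea-Ackers models
#'
#' The two-node double-negative feedback model admits at most five
#' non-negative equilibria: the origin, two axis states, and up to two
#' interior states whose abscissae solve a quadratic in `m = beta1 * x`.
#' The embedded three-node model inherits these equilibria (lifted with z = 0,
#' or on the z axis), with closed-form stability conditions for each.
#' These functions evaluate the printed formulas exactly; the numerical
#' counterpart is [find_equilibria()].
#'
#' @name closed-form-theory
NULL

#' Axis equilibria of the two-node model
#'
#' Returns the origin (always an equilibrium), `(x_e, 0)` with
#' `x_e = (gain1 - deg1) / (deg1 * sat1)` when `gain1 > deg1` and `sat1 > 0`,
#' and `(0, y_e)` with `y_e = (gain2 - deg2) / (deg2 * sat2)` when
#' `gain2 > deg2` and `sat2 > 0`.  Each point is classified from its Jacobian.
#'
#' @param params a [twonode_params()] object (degradation rates must be > 0)
#' @return an `equilibrium_set` with 1-3 points
#' @export
axis_equilibria_2d <- function(params) {
  stopifnot(inherits(params, "twonode_params"))
  f <- rhs_function(params)
  pts <- list(c(0, 0))
  if (params$gain1 > params$deg1 && params$sat1 > 0)
    pts <- c(pts, list(c((params$gain1 - params$deg1) / (params$deg1 * params$sat1), 0)))
  if (params$gain2 > params$deg2 && params$sat2 > 0)
    pts <- c(pts, list(c(0, (params$gain2 - params$deg2) / (params$deg2 * params$sat2))))
  structure(lapply(pts, function(p) make_equilibrium(f, p)),
            class = "equilibrium_set")
}

# Quadratic coefficients in m = beta1 * x for the interior equilibria,
# using A1 = beta2/sigma1, A2 = gain1/deg1, B1 = sigma2/beta1, B2 = gain2/deg2.
quadratic_coefficients <- function(params) {
  A1 <- params$rep1 / params$sat2
  A2 <- params$gain1 / params$deg1
  B1 <- params$rep2 / params$sat1
  B2 <- params$gain2 / params$deg2
  list(A = A1 * B1 - B1,
       B = A1 - B1 - 1 + A1 * B1 - A1 * B2 + A2 * B1,
       C = A1 + A2 - 1 - A1 * B2,
       A1 = A1, A2 = A2, B1 = B1, B2 = B2)
}

#' Interior (positive) equilibria of the two-node model
#'
#' Solves the quadratic `A m^2 + B m + C = 0` in `m = sat1 * x` built from the
#' substitutions `A1 = rep1/sat2`, `A2 = gain1/deg1`, `B1 = rep2/sat1`,
#' `B2 = gain2/deg2` (in X-Y symbols: `A1 = beta2/sigma1`, `A2 = alpha1/k3`,
#' `B1 = sigma2/beta1`, `B2 = gamma1/k4`), subject to the existence gates
#' `-B/A > 0`, `C/A > 0`, `B^2 - 4AC >= 0`.  The ordinate is back-solved from
#' the x-nullcline, and only roots with `x > 0`, `y > 0` that satisfy the
#' positivity condition `x < (A2-1)/sat1` or `x < (B2-1)/rep2` are kept.
#' A degenerate linear case (`A = 0`) is solved directly.
#'
#' @param params a [twonode_params()] object; self-saturations must be > 0
#'   for the substitution to be defined (otherwise an empty set is returned)
#' @param gate if `TRUE`, apply the printed sign gates `-B/A > 0`, `C/A > 0`
#'   before solving.  The gates are sufficient for *two* positive roots but
#'   not necessary for one, so the default `FALSE` solves unconditionally and
#'   keeps every root with `x > 0`, `y > 0` — the complete interior set,
#'   which is what the closed-form/multistart equivalence checks require
#' @return an `equilibrium_set` with 0-2 interior points
#' @export
interior_equilibria_2d <- function(params, gate = FALSE) {
  stopifnot(inherits(params, "twonode_params"))
  empty <- structure(list(), class = "equilibrium_set")
  if (params$sat1 <= 0 || params$sat2 <= 0) return(empty)
  qc <- quadratic_coefficients(params)
  A <- qc$A; B <- qc$B; C <- qc$C
  roots <- if (abs(A) < 1e-14) {
    if (abs(B) < 1e-14) numeric(0) else -C / B
  } else {
    if (gate && !(-B / A > 0 && C / A > 0)) return(empty)
    disc <- B^2 - 4 * A * C
    if (disc < 0) return(empty)
    (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  }
  roots <- roots[is.finite(roots) & roots > 0]
  if (length(roots) == 0) return(empty)
  f <- rhs_function(params)
  pts <- list()
  for (m in roots) {
    x <- m / params$sat1
    # x-nullcline: gain1 / ((1+m)(1+rep1*y)) = deg1
    y <- (qc$A2 / (1 + m) - 1) / params$rep1
    if (!is.finite(y) || y <= 0) next
    if (!(x < (qc$A2 - 1) / params$sat1 || x < (qc$B2 - 1) / params$rep2)) next
    pts <- c(pts, list(c(x, y)))
  }
  structure(lapply(pts, function(p) make_equilibrium(f, p)),
            class = "equilibrium_set")
}

#' Stability of the two-node axis equilibria (closed form)
#'
#' Evaluates the printed inequalities: the origin is *unstable* iff
#' `gain1 > deg1` and `gain2 > deg2`; `(x_e, 0)` is *stable* iff
#' `gain2 / (1 + rep2 x_e) < deg2`; `(0, y_e)` is *stable* iff
#' `gain1 / (1 + rep1 y_e) < deg1`.  All inequalities are strict.
#'
#' @param params a [twonode_params()] object
#' @param which one of `"origin"`, `"x_axis"`, `"y_axis"`
#' @return logical: for `"origin"`, whether the origin is unstable; for the
#'   axis states, whether the state is stable
#' @export
check_theorem2 <- function(params, which = c("origin", "x_axis", "y_axis")) {
  stopifnot(inherits(params, "twonode_params"))
  which <- match.arg(which)
  switch(which,
    origin = params$gain1 > params$deg1 && params$gain2 > params$deg2,
    x_axis = {
      xe <- (params$gain1 - params$deg1) / (params$deg1 * params$sat1)
      params$gain2 / (1 + params$rep2 * xe) < params$deg2
    },
    y_axis = {
      ye <- (params$gain2 - params$deg2) / (params$deg2 * params$sat2)
      params$gain1 / (1 + params$rep1 * ye) < params$deg1
    })
}

#' Stability condition for interior equilibria of the two-node model
#'
#' Evaluates, at a positive interior equilibrium `(x, y)`,
#' \deqn{\beta_1\sigma_1\eta_y\xi_x - \beta_2\sigma_2\theta_x\rho_y > 0}
#' with `theta_x = 1 + beta1 x`, `eta_y = 1 + beta2 y`, `rho_y = 1 + sigma1 y`,
#' `xi_x = 1 + sigma2 x` (neutral slots: beta1 = sat1, beta2 = rep1,
#' sigma1 = sat2, sigma2 = rep2).
#'
#' @param params a [twonode_params()] object
#' @param point numeric length-2 positive interior equilibrium
#' @return logical
#' @export
check_theorem3 <- function(params, point) {
  stopifnot(inherits(params, "twonode_params"))
  x <- point[1]; y <- point[2]
  theta_x <- 1 + params$sat1 * x
  eta_y <- 1 + params$rep1 * y
  rho_y <- 1 + params$sat2 * y
  xi_x <- 1 + params$rep2 * x
  params$sat1 * params$sat2 * eta_y * xi_x -
    params$rep1 * params$rep2 * theta_x * rho_y > 0
}

#' Stability of the embedded three-node axis equilibria (closed form)
#'
#' Given that the corresponding subsystem state is already stable, the lifted
#' state is stable iff the transverse direction decays: `(x_e, 0, 0)` iff
#' `a1 / (1 + b2 x_e) < k1`; `(0, y_e, 0)` iff `a1 / (1 + b2 y_e) < k1`;
#' `(0, 0, z_e)` iff `alpha1 / (1 + d2 z_e) < k3` *and*
#' `gamma1 / (1 + d2 z_e) < k4`, with `z_e = (a1 - k1)/(k1 b1)`.
#'
#' @param params a [tristable_params()] object
#' @param which one of `"x_axis"`, `"y_axis"`, `"z_axis"`
#' @return logical
#' @export
check_theorem5 <- function(params, which = c("x_axis", "y_axis", "z_axis")) {
  stopifnot(inherits(params, "tristable_params"))
  which <- match.arg(which)
  switch(which,
    x_axis = {
      xe <- (params$alpha1 - params$k3) / (params$k3 * params$beta1)
      params$a1 / (1 + params$b2 * xe) < params$k1
    },
    y_axis = {
      ye <- (params$gamma1 - params$k4) / (params$k4 * params$sigma1)
      params$a1 / (1 + params$b2 * ye) < params$k1
    },
    z_axis = {
      ze <- (params$a1 - params$k1) / (params$k1 * params$b1)
      params$alpha1 / (1 + params$d2 * ze) < params$k3 &&
        params$gamma1 / (1 + params$d2 * ze) < params$k4
    })
}

#' Stability of lifted interior equilibria of the embedded model (closed form)
#'
#' A stable interior state `(x*, y*)` of the X-Y subsystem lifts to a stable
#' state `(x*, y*, 0)` of the embedded system iff
#' `a1 / (1 + b2 (x* + y*)) < k1`.
#'
#' @param params a [tristable_params()] object
#' @param point_xy numeric length-2 stable interior state of the X-Y subsystem
#' @return logical
#' @export
check_theorem6 <- function(params, point_xy) {
  stopifnot(inherits(params, "tristable_params"))
  params$a1 / (1 + params$b2 * (point_xy[1] + point_xy[2])) < params$k1
}
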