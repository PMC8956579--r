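#' Parameter containers for the regulatory-network models
#'
#' All models in this package are parameterised by small named lists with a
#' class attribute and strict validation at construction time.  Parameters are
#' stored per named symbol, never positionally, to avoid cross-subsystem
#' confusion.  The symbol correspondence between the two double-negative
#' feedback subsystems is:
#'
#' | role                | Z-U module (GATA2-GATA1) | X-Y module (GATA1-PU.1) |
#' |---------------------|--------------------------|-------------------------|
#' | production gain     | `a1` / `c1`              | `alpha1` / `gamma1`     |
#' | self-saturation     | `b1` / `d1`              | `beta1` / `sigma1`      |
#' | cross-repression    | `b2` / `d2`              | `beta2` / `sigma2`      |
#' | degradation         | `k1` / `k2`              | `k3` / `k4`             |
#'
#' Internally a [twonode_params()] object uses the neutral slot names
#' `gain1, sat1, rep1, deg1` (first node) and `gain2, sat2, rep2, deg2`
#' (second node); [xy_params()] and [zu_params()] are thin constructors that
#' accept the field symbols above.
#'
#' @name embedstable-params
NULL

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("embedstable_input_error", "error")))
}

check_num <- function(x, name, lower = -Inf, strict = FALSE, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x) || any(!is.finite(x)))
    stop_input("'", name, "' must be a finite numeric of length ", len)
  if (strict && any(x <= lower))
    stop_input("'", name, "' must be > ", lower)
  if (!strict && any(x < lower))
    stop_input("'", name, "' must be >= ", lower)
  as.numeric(x)
}

#' Toggle-switch parameters
#'
#' Parameters of the symmetric two-gene toggle switch with Hill repression,
#' `d z/dt = basal + strength / (1 + u^hill) - z` (and symmetrically for `u`).
#' The defaults are the classic bistable operating point used throughout the
#' package examples.
#'
#' @param basal basal production rate (must be > 0)
#' @param strength repression-controlled production strength (> 0)
#' @param hill Hill exponent of the cross-repression (> 0, finite)
#' @return an object of class `toggle_params`
#' @examples
#' toggle_params()                 # a = 0.2, b = 4, hill = 3
#' @export
toggle_params <- function(basal = 0.2, strength = 4, hill = 3) {
  out <- list(
    basal = check_num(basal, "basal", 0, strict = TRUE),
    strength = check_num(strength, "strength", 0, strict = TRUE),
    hill = check_num(hill, "hill", 0, strict = TRUE)
  )
  structure(out, class = "toggle_params")
}

#' Two-node Shea-Ackers subsystem parameters
#'
#' Parameters of a double-negative feedback loop with positive autoregulation
#' in the Shea-Ackers (thermodynamic) formalism:
#' \deqn{dx_1/dt = gain_1 x_1 / ((1 + sat_1 x_1)(1 + rep_1 x_2)) - deg_1 x_1}
#' and symmetrically for node 2.  `rep1` is the repression of node 1 *by node
#' 2* and vice versa.
#'
#' @param gain1,sat1,rep1,deg1 production gain, self-saturation,
#'   cross-repression and degradation rate of the first node
#' @param gain2,sat2,rep2,deg2 the same for the second node
#' @param vars character vector of length 2 naming the two nodes
#' @return an object of class `twonode_params`
#' @seealso [xy_params()], [zu_params()] for the field-symbol constructors
#' @export
twonode_params <- function(gain1, sat1, rep1, deg1,
                           gain2, sat2, rep2, deg2,
                           vars = c("x", "y")) {
  if (!is.character(vars) || length(vars) != 2L || anyDuplicated(vars))
    stop_input("'vars' must be two distinct variable names")
  out <- list(
    gain1 = check_num(gain1, "gain1", 0), sat1 = check_num(sat1, "sat1", 0),
    rep1 = check_num(rep1, "rep1", 0), deg1 = check_num(deg1, "deg1", 0, strict = TRUE),
    gain2 = check_num(gain2, "gain2", 0), sat2 = check_num(sat2, "sat2", 0),
    rep2 = check_num(rep2, "rep2", 0), deg2 = check_num(deg2, "deg2", 0, strict = TRUE),
    vars = vars
  )
  structure(out, class = "twonode_params")
}

#' @param alpha1,beta1,beta2,k3 GATA1 (x) gain, self-saturation,
#'   cross-repression by PU.1, degradation
#' @param gamma1,sigma1,sigma2,k4 PU.1 (y) gain, self-saturation,
#'   cross-repression by GATA1, degradation
#' @rdname twonode_params
#' @export
xy_params <- function(alpha1, beta1, beta2, k3, gamma1, sigma1, sigma2, k4) {
  twonode_params(alpha1, beta1, beta2, k3, gamma1, sigma1, sigma2, k4,
                 vars = c("x", "y"))
}

#' @param a1,b1,b2,k1 GATA2 (z) gain, self-saturation, cross-repression by the
#'   auxiliary node u, degradation
#' @param c1,d1,d2,k2 auxiliary node (u = GATA1 + PU.1) gain, self-saturation,
#'   cross-repression by GATA2, degradation
#' @rdname twonode_params
#' @export
zu_params <- function(a1, b1, b2, k1, c1, d1, d2, k2) {
  twonode_params(a1, b1, b2, k1, c1, d1, d2, k2, vars = c("z", "u"))
}

#' GATA-switching schedule
#'
#' The time-dependent displacement rate of chromatin-bound GATA2 by GATA1:
#' `k_star(t) = k0_star` for `t` in the closed window `[t1, t2]` and 0
#' otherwise.  `psi` controls the availability of displaced GATA1 protein:
#' GATA1 gains expression at rate `psi * k_star(t) * z`.
#'
#' @param k0_star displacement rate during the switching window (>= 0)
#' @param t1,t2 window start/end, `t1 <= t2`, finite
#' @param psi GATA1 availability control parameter (>= 0)
#' @return an object of class `switch_schedule`
#' @export
switch_schedule <- function(k0_star = 0.52, t1 = 500, t2 = 3500, psi = 5e-4) {
  t1 <- check_num(t1, "t1"); t2 <- check_num(t2, "t2")
  if (t1 > t2) stop_input("'t1' must be <= 't2'")
  structure(list(
    k0_star = check_num(k0_star, "k0_star", 0),
    t1 = t1, t2 = t2,
    psi = check_num(psi, "psi", 0)
  ), class = "switch_schedule")
}

#' Embedded three-gene model parameters
#'
#' Parameters of the tristable model obtained by embedding the X-Y
#' (GATA1-PU.1) subsystem into the Z-U (GATA-switching) subsystem through
#' u = x + y.  The x and y equations keep the X-Y symbols
#' (`alpha1, beta1, beta2, k3`; `gamma1, sigma1, sigma2, k4`), the z equation
#' keeps the Z-U symbols (`a1, b1, b2, k1`), and `d2` is the repression of the
#' auxiliary node by z inherited from the Z-U module: each x/y production term
#' is multiplied by `1 / (1 + d2 z)`.
#'
#' @param xy a [xy_params()] (or any `twonode_params`) object for the X-Y pair
#' @param a1,b1,b2,k1 z-node (GATA2) gain, self-saturation, cross-repression
#'   by x + y, degradation
#' @param d2 induced repression coefficient of x and y production by z
#' @return an object of class `tristable_params`
#' @export
tristable_params <- function(xy, a1, b1, b2, k1, d2) {
  stopifnot(inherits(xy, "twonode_params"))
  structure(list(
    alpha1 = xy$gain1, beta1 = xy$sat1, beta2 = xy$rep1, k3 = xy$deg1,
    gamma1 = xy$gain2, sigma1 = xy$sat2, sigma2 = xy$rep2, k4 = xy$deg2,
    a1 = check_num(a1, "a1", 0), b1 = check_num(b1, "b1", 0),
    b2 = check_num(b2, "b2", 0), k1 = check_num(k1, "k1", 0, strict = TRUE),
    d2 = check_num(d2, "d2", 0)
  ), class = "tristable_params")
}

#' Quad-stable GATA1-GATA2-PU.1 model parameters
#'
#' The modified embedded model: the tristable model plus (i) basal production
#' constants `alpha0`, `gamma0`, `a0` so no gene has a zero basal expression
#' level, and (ii) a weak positive regulation `d_star` from GATA2 to GATA1
#' entering the x production as the factor `(1 + d_star z) / (1 + d2 z)`.
#' States are ordered `(x, y, z)` = (GATA1, PU.1, GATA2).
#'
#' @param tri a [tristable_params()] object
#' @param alpha0,gamma0,a0 basal production constants of x, y, z (>= 0)
#' @param d_star weak positive-regulation coefficient of x production by z
#' @return an object of class `quad_params`
#' @export
quad_params <- function(tri, alpha0 = 0, gamma0 = 0, a0 = 0, d_star = 0) {
  stopifnot(inherits(tri, "tristable_params"))
  out <- unclass(tri)
  out$alpha0 <- check_num(alpha0, "alpha0", 0)
  out$gamma0 <- check_num(gamma0, "gamma0", 0)
  out$a0 <- check_num(a0, "a0", 0)
  out$d_star <- check_num(d_star, "d_star", 0)
  structure(out, class = c("quad_params", "tristable_params"))
}

#' Multiplicative noise strengths of the stochastic model
#'
#' `omega1`, `omega2`, `omega3` scale the diffusion terms on the GATA1, PU.1
#' and GATA2 equations respectively; each diffusion multiplies the full
#' degradation(+switching) flux of its gene.
#'
#' @param omega1,omega2,omega3 noise strengths (>= 0)
#' @return an object of class `noise_params`
#' @export
noise_params <- function(omega1 = 0.04, omega2 = 0.08, omega3 = 0.08) {
  structure(list(
    omega1 = check_num(omega1, "omega1", 0),
    omega2 = check_num(omega2, "omega2", 0),
    omega3 = check_num(omega3, "omega3", 0)
  ), class = "noise_params")
}

check_state <- function(state, dim, allow_negative = FALSE) {
  if (!is.numeric(state) || length(state) != dim || anyNA(state))
    stop_input("state must be a numeric vector of length ", dim)
  if (!allow_negative && any(state < 0))
    stop_input("state components must be non-negative")
  as.numeric(state)
}

#' @export
print.toggle_params <- function(x, ...) {
  cat(sprintf("Toggle-switch parameters: basal=%g strength=%g hill=%g\n",
              x$basal, x$strength, x$hill))
  invisible(x)
}

#' @export
print.twonode_params <- function(x, ...) {
  cat(sprintf("Two-node Shea-Ackers parameters (%s-%s):\n", x$vars[1], x$vars[2]))
  cat(sprintf("  %s: gain=%g sat=%g rep=%g deg=%g\n", x$vars[1],
              x$gain1, x$sat1, x$rep1, x$deg1))
  cat(sprintf("  %s: gain=%g sat=%g rep=%g deg=%g\n", x$vars[2],
              x$gain2, x$sat2, x$rep2, x$deg2))
  invisible(x)
}

#' @export
print.tristable_params <- function(x, ...) {
  cat("Embedded three-gene model parameters:\n")
  cat(sprintf("  x: alpha1=%g beta1=%g beta2=%g k3=%g\n", x$alpha1, x$beta1, x$beta2, x$k3))
  cat(sprintf("  y: gamma1=%g sigma1=%g sigma2=%g k4=%g\n", x$gamma1, x$sigma1, x$sigma2, x$k4))
  cat(sprintf("  z: a1=%g b1=%g b2=%g k1=%g  d2=%g\n", x$a1, x$b1, x$b2, x$k1, x$d2))
  invisible(x)
}

#' @export
print.quad_params <- function(x, ...) {
  NextMethod()
  cat(sprintf("  basal: alpha0=%g gamma0=%g a0=%g  d_star=%g\n",
              x$alpha0, x$gamma0, x$a0, x$d_star))
  invisible(x)
}

param_type <- function(p) {
  if (inherits(p, "quad_params")) "quad"
  else if (inherits(p, "tristable_params")) "tristable"
  else if (inherits(p, "twonode_params")) "twonode"
  else if (inherits(p, "toggle_params")) "toggle"
  else if (inherits(p, "switch_schedule")) "schedule"
  else if (inherits(p, "noise_params")) "noise"
  else stop_input("unknown parameter object")
}

params_from_list <- function(type, lst) {
  lst <- lapply(lst, function(v) if (is.list(v)) unlist(v) else v)
  switch(type,
    toggle = toggle_params(lst$basal, lst$strength, lst$hill),
    twonode = twonode_params(lst$gain1, lst$sat1, lst$rep1, lst$deg1,
                             lst$gain2, lst$sat2, lst$rep2, lst$deg2,
                             vars = if (is.null(lst$vars)) c("x", "y") else lst$vars),
    tristable = tristable_params(
      xy_params(lst$alpha1, lst$beta1, lst$beta2, lst$k3,
                lst$gamma1, lst$sigma1, lst$sigma2, lst$k4),
      lst$a1, lst$b1, lst$b2, lst$k1, lst$d2),
    quad = quad_params(
      tristable_params(
        xy_params(lst$alpha1, lst$beta1, lst$beta2, lst$k3,
                  lst$gamma1, lst$sigma1, lst$sigma2, lst$k4),
        lst$a1, lst$b1, lst$b2, lst$k1, lst$d2),
      alpha0 = lst$alpha0, gamma0 = lst$gamma0, a0 = lst$a0, d_star = lst$d_star),
    schedule = switch_schedule(lst$k0_star, lst$t1, lst$t2, lst$psi),
    noise = noise_params(lst$omega1, lst$omega2, lst$omega3),
    stop_input("unknown parameter section type '", type, "'")
  )
}

#' Read and write model configuration files
#'
#' Configurations are JSON files with one section per subsystem (flat
#' key-to-number maps) plus optional `"schedule"` and `"noise"` sections.
#' Section names are free, but each section must carry a `"type"` key naming
#' its parameter family (`"toggle"`, `"twonode"`, `"tristable"`, `"quad"`,
#' `"schedule"`, `"noise"`).  `read_model_config()` returns a named list of
#' reconstructed parameter objects.
#'
#' @param sections a named list of parameter objects created by the
#'   constructors in this package
#' @param path file path of the JSON configuration
#' @return `read_model_config()`: named list of parameter objects;
#'   `write_model_config()`: `path`, invisibly.
#' @examples
#' cfg <- tempfile(fileext = ".json")
#' write_model_config(list(toggle = toggle_params()), cfg)
#' read_model_config(cfg)$toggle
#' @export
write_model_config <- function(sections, path) {
  stopifnot(is.list(sections), !is.null(names(sections)))
  enc <- lapply(sections, function(p) c(list(type = param_type(p)), unclass(p)))
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(raw, function(sec) {
    if (is.null(sec$type)) stop_input("config section lacks a 'type' key")
    params_from_list(sec$type, sec[setdiff(names(sec), "type")])
  })
  out
}
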