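#' Random-parameter bistability screening and perturbation robustness
#'
#' The two-node Shea-Ackers model is screened for bistability by drawing all
#' eight parameters i.i.d. from a uniform distribution (default U\[0, 10\]),
#' classifying the closed-form equilibria, and cataloguing the pattern of
#' stable states.  Three bistable patterns occur:
#' *case 1*: both axis states `(x_e, 0)` and `(0, y_e)` stable;
#' *case 2*: `(x_e, 0)` plus a stable interior state;
#' *case 3*: `(0, y_e)` plus a stable interior state.
#' Perturbing a case-1 parameter set coefficient-wise by
#' `c* = [eps * (P - 0.5) + 1] * c`, `P ~ U[0, 1]`, can move it into case 2
#' or 3, demonstrating robustness of bistability under parameter variation.
#'
#' @name bistability-search
NULL

#' Draw a random two-node parameter set
#'
#' All eight coefficients i.i.d. uniform over `bounds`.  Draws use the current
#' RNG stream (seed it with [set.seed()] for reproducibility).
#'
#' @param bounds length-2 numeric, lower/upper bound (default `c(0, 10)`)
#' @param vars variable names for the resulting [twonode_params()]
#' @return a `twonode_params` object
#' @export
sample_params <- function(bounds = c(0, 10), vars = c("x", "y")) {
  if (length(bounds) != 2 || bounds[1] < 0 || bounds[2] <= bounds[1])
    stop_input("'bounds' must be an increasing non-negative pair")
  repeat {
    p <- stats::runif(8, bounds[1], bounds[2])
    if (p[4] > 0 && p[8] > 0) break  # degradation must be positive (a.s. true)
  }
  twonode_params(p[1], p[2], p[3], p[4], p[5], p[6], p[7], p[8], vars = vars)
}

#' Classify the bistability pattern of a two-node parameter set
#'
#' Combines [axis_equilibria_2d()] and [interior_equilibria_2d()], then labels
#' the draw `"case1"`, `"case2"`, `"case3"`, `"none"` (fewer than two stable
#' states) or `"other"` (any marginal classification, or a stable pattern
#' outside cases 1-3 — including a hypothetical tristable draw, which would be
#' surfaced here rather than suppressed).
#'
#' @param params a [twonode_params()] object
#' @return list with `label`, `n_stable`, and the classified `equilibria`
#' @export
classify_bistability <- function(params) {
  eqs <- c(axis_equilibria_2d(params), interior_equilibria_2d(params))
  cls <- vapply(eqs, function(e) e$classification, character(1))
  states <- lapply(eqs, function(e) e$state)
  on_x <- vapply(states, function(s) s[1] > 0 && s[2] == 0, logical(1))
  on_y <- vapply(states, function(s) s[1] == 0 && s[2] > 0, logical(1))
  interior <- vapply(states, function(s) all(s > 0), logical(1))
  stable <- cls == "stable"
  n_stable <- sum(stable)
  label <- if (any(cls == "marginal")) "other"
    else if (n_stable < 2) "none"
    else if (n_stable == 2 && any(stable & on_x) && any(stable & on_y)) "case1"
    else if (n_stable == 2 && any(stable & on_x) && any(stable & interior)) "case2"
    else if (n_stable == 2 && any(stable & on_y) && any(stable & interior)) "case3"
    else "other"
  list(label = label, n_stable = n_stable,
       equilibria = structure(eqs, class = "equilibrium_set"))
}

#' Screen random parameter draws for bistability
#'
#' Draws `n_samples` parameter sets uniformly over `bounds`, classifies each
#' with [classify_bistability()], and returns the catalogue.  Reproducible
#' given `(n_samples, bounds, seed)`.
#'
#' @param n_samples number of draws (>= 0)
#' @param bounds uniform sampling interval, default `c(0, 10)`
#' @param seed integer seed
#' @param keep_equilibria keep the classified equilibria of every draw
#'   (memory-heavy for large screens; bistable draws are always kept)
#' @return object of class `bistability_catalogue`: list with `draws` (one
#'   record per draw: `id`, `params`, `label`, `n_stable`, and for bistable
#'   draws `equilibria`), `counts` (table of labels) and the call settings
#' @export
screen_bistability <- function(n_samples, bounds = c(0, 10), seed = 1L,
                               keep_equilibria = FALSE) {
  if (n_samples < 0) stop_input("'n_samples' must be >= 0")
  rs <- local_rng(seed)
  on.exit(restore_rng(rs))
  draws <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    p <- sample_params(bounds)
    cb <- classify_bistability(p)
    rec <- list(id = i, params = p, label = cb$label, n_stable = cb$n_stable)
    if (keep_equilibria || cb$label %in% c("case1", "case2", "case3"))
      rec$equilibria <- cb$equilibria
    draws[[i]] <- rec
  }
  labels <- vapply(draws, function(d) d$label, character(1))
  structure(list(draws = draws,
                 counts = table(factor(labels, levels = c("case1", "case2",
                                                          "case3", "none", "other"))),
                 n_samples = n_samples, bounds = bounds, seed = seed),
            class = "bistability_catalogue")
}

#' @export
print.bistability_catalogue <- function(x, ...) {
  cat(sprintf("Bistability screen: %d draws over [%g, %g], seed %d\n",
              x$n_samples, x$bounds[1], x$bounds[2], x$seed))
  print(x$counts)
  invisible(x)
}

#' Convert a bistability catalogue to a data frame
#'
#' One row per draw: id, the eight parameters, label, number of stable
#' states, and the coordinates of up to two stable states.
#'
#' @param x a `bistability_catalogue`
#' @param row.names,optional,... unused
#' @return a `data.frame`
#' @export
as.data.frame.bistability_catalogue <- function(x, row.names = NULL,
                                                optional = FALSE, ...) {
  rows <- lapply(x$draws, function(d) {
    p <- d$params
    stab <- if (!is.null(d$equilibria)) {
      st <- Filter(function(e) e$classification == "stable", d$equilibria)
      unlist(lapply(st[seq_len(min(2, length(st)))], function(e) e$state))
    } else numeric(0)
    stab <- c(stab, rep(NA_real_, 4 - length(stab)))[1:4]
    data.frame(id = d$id, gain1 = p$gain1, sat1 = p$sat1, rep1 = p$rep1,
               deg1 = p$deg1, gain2 = p$gain2, sat2 = p$sat2, rep2 = p$rep2,
               deg2 = p$deg2, label = d$label, n_stable = d$n_stable,
               s1_x = stab[1], s1_y = stab[2], s2_x = stab[3], s2_y = stab[4])
  })
  do.call(rbind, rows)
}

#' Perturb a parameter set coefficient-wise
#'
#' Each coefficient `c` is replaced by `c* = [epsilon * (P - 0.5) + 1] * c`
#' with an independent `P ~ U[0, 1]` per coefficient, i.e. scaled uniformly
#' into `[(1 - epsilon/2) c, (1 + epsilon/2) c]`.  Uses the current RNG
#' stream.
#'
#' @param params a [twonode_params()] object
#' @param epsilon perturbation strength (>= 0)
#' @return a perturbed `twonode_params` object
#' @export
perturb <- function(params, epsilon) {
  stopifnot(inherits(params, "twonode_params"))
  epsilon <- check_num(epsilon, "epsilon", 0)
  co <- unlist(params[c("gain1", "sat1", "rep1", "deg1",
                        "gain2", "sat2", "rep2", "deg2")])
  co <- (epsilon * (stats::runif(8) - 0.5) + 1) * co
  twonode_params(co[1], co[2], co[3], co[4], co[5], co[6], co[7], co[8],
                 vars = params$vars)
}

#' Perturbation robustness study of a case-1 bistable parameter set
#'
#' Perturbs a case-1 draw `n` times at each strength in `epsilon` and
#' tabulates the fraction of perturbed sets landing in each bistability case.
#' For suitable strengths this demonstrates that case-2/3 bistability (one
#' stable state off the axis) arises from purely axis-stable (case 1)
#' parameter sets.
#'
#' @param params a [twonode_params()] object that classifies as case 1
#' @param epsilon numeric vector of perturbation strengths
#' @param n perturbed replicates per strength
#' @param seed integer seed
#' @return a `data.frame` with one row per strength and one column per label
#'   fraction (`case1`, `case2`, `case3`, `none`, `other`); fractions sum
#'   to 1 within each row
#' @export
perturbation_study <- function(params, epsilon = c(0.05, 0.1, 0.2), n = 200L,
                               seed = 1L) {
  if (classify_bistability(params)$label != "case1")
    stop_input("'params' must classify as case 1 (both stable states on the axes)")
  rs <- local_rng(seed)
  on.exit(restore_rng(rs))
  lev <- c("case1", "case2", "case3", "none", "other")
  out <- lapply(epsilon, function(eps) {
    labels <- vapply(seq_len(n), function(i) {
      classify_bistability(perturb(params, eps))$label
    }, character(1))
    frac <- table(factor(labels, levels = lev)) / n
    data.frame(epsilon = eps, t(as.numeric(frac)) |> as.data.frame() |>
                 stats::setNames(lev))
  })
  do.call(rbind, out)
}
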