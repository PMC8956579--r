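#' ABC-rejection parameter estimation
#'
#' Likelihood-free fitting of the two-node Shea-Ackers model to two-gene
#' expression time courses.  Parameter vectors are drawn from independent
#' uniform priors, the model is solved forward deterministically, and draws
#' are accepted whose simulated series lie within a distance tolerance of the
#' observations — or, in quantile mode, the best fraction of all draws.  The
#' distance is the summed absolute deviation over both genes and all time
#' points.
#'
#' Time-series data are data frames with a `time` column followed by two
#' value columns.  For fitting the GATA-switching (Z-U) module, the auxiliary
#' observable u is the sum of the GATA1 and PU.1 series; see [zu_observables()].
#'
#' @name abc-inference
NULL

check_series <- function(d, name = "data") {
  if (!is.data.frame(d) || ncol(d) < 3 || names(d)[1] != "time")
    stop_input("'", name, "' must be a data.frame: time column plus two gene columns")
  if (nrow(d) < 1 || any(d[[2]] < 0, na.rm = TRUE) || any(d[[3]] < 0, na.rm = TRUE))
    stop_input("'", name, "' must have m >= 1 rows of non-negative values")
  d
}

#' Summed absolute deviation between two time series
#'
#' \deqn{\rho(X, X^*) = \sum_{i=1}^m [|x_i - x_i^*| + |y_i - y_i^*|]}
#'
#' @param observed,simulated data frames with identical `time` grids and two
#'   value columns each
#' @return non-negative scalar distance
#' @export
distance_rho <- function(observed, simulated) {
  check_series(observed, "observed"); check_series(simulated, "simulated")
  if (nrow(observed) != nrow(simulated) ||
      max(abs(observed$time - simulated$time)) > 1e-9)
    stop_input("time grids of the two series do not match")
  sum(abs(observed[[2]] - simulated[[2]])) + sum(abs(observed[[3]] - simulated[[3]]))
}

#' Deterministic forward simulation sampled at data times
#'
#' Integrates the model with a fixed-step RK4 scheme (internal step `dt`) and
#' returns the trajectory at `timepoints`.  The first time point carries the
#' initial condition.
#'
#' @param params a parameter object ([twonode_params()], [toggle_params()],
#'   [tristable_params()], [quad_params()])
#' @param timepoints strictly increasing numeric vector (first entry is the
#'   initial time)
#' @param init initial state (non-negative, model dimension)
#' @param dt internal integration step
#' @param sched optional [switch_schedule()] (3-gene models only)
#' @return data.frame: `time` plus one column per state variable
#' @export
simulate_observables <- function(params, timepoints, init, dt = 0.01,
                                 sched = NULL) {
  if (any(diff(timepoints) <= 0)) stop_input("'timepoints' must be increasing")
  dim <- model_dim(params)
  init <- check_state(init, dim)
  sc <- if (is.null(sched)) numeric(0) else
    c(sched$k0_star, sched$t1, sched$t2, sched$psi)
  tr <- cpp_integrate(model_id(params), param_vec(params), sc, init,
                      as.numeric(timepoints), dt)
  vars <- if (dim == 3) c("x", "y", "z")
    else if (inherits(params, "twonode_params")) params$vars else c("z", "u")
  out <- data.frame(time = as.numeric(timepoints))
  for (j in seq_len(dim)) out[[vars[j]]] <- tr[, j]
  out
}

#' Synthetic two-gene target data
#'
#' Forward-simulates the model at known `true_params` and adds independent
#' Gaussian measurement noise, truncated at zero.  Stands in for experimental
#' erythropoiesis/granulopoiesis time courses in parameter-recovery studies.
#'
#' @param true_params a [twonode_params()] object
#' @param timepoints sampling times (default 10 points over \[0, 18\])
#' @param init initial state
#' @param noise_sd Gaussian noise standard deviation (>= 0); the default 0.2
#'   is about 5 percent of the trajectories' dynamic range
#' @param seed integer seed
#' @param dt internal integration step
#' @return data.frame with columns `time` and the two gene values
#' @export
synth_target <- function(true_params, timepoints = seq(0, 18, length.out = 10),
                         init = c(0.5, 0.3), noise_sd = 0.2, seed = 1L,
                         dt = 0.01) {
  noise_sd <- check_num(noise_sd, "noise_sd", 0)
  clean <- simulate_observables(true_params, timepoints, init, dt = dt)
  rs <- local_rng(seed)
  on.exit(restore_rng(rs))
  for (j in 2:3)
    clean[[j]] <- pmax(clean[[j]] + stats::rnorm(nrow(clean), 0, noise_sd), 0)
  clean
}

#' Configuration for ABC rejection
#'
#' Exactly one of `tolerance` (absolute distance cut) or `quantile` (accepted
#' fraction of draws) must be set.
#'
#' @param prior_lower,prior_upper per-parameter uniform prior bounds; scalars
#'   are recycled to all 8 parameters (default prior U\[0, 100\])
#' @param tolerance absolute acceptance threshold on the distance, or `NULL`
#' @param quantile accepted fraction of draws (e.g. 0.001 = best 0.1
#'   percent), or `NULL`
#' @param n_draws number of prior draws
#' @param seed integer seed
#' @param init initial state of the forward solve
#' @param dt internal integration step
#' @return an `abc_config` object
#' @export
abc_config <- function(prior_lower = 0, prior_upper = 100, tolerance = NULL,
                       quantile = 0.001, n_draws = 5e4, seed = 1L,
                       init = c(0.5, 0.3), dt = 0.01) {
  if (is.null(tolerance) == is.null(quantile))
    stop_input("set exactly one of 'tolerance' and 'quantile'")
  lo <- rep_len(prior_lower, 8); hi <- rep_len(prior_upper, 8)
  if (any(lo >= hi)) stop_input("prior lower bounds must be below upper bounds")
  structure(list(prior_lower = lo, prior_upper = hi, tolerance = tolerance,
                 quantile = quantile, n_draws = as.integer(n_draws),
                 seed = as.integer(seed), init = check_state(init, 2L),
                 dt = dt),
            class = "abc_config")
}

PARAM_SLOTS <- c("gain1", "sat1", "rep1", "deg1", "gain2", "sat2", "rep2", "deg2")

#' ABC-rejection fit of the two-node model
#'
#' Draws `n_draws` parameter vectors from the uniform prior, solves the model
#' forward on the data's time grid, computes the summed-absolute-deviation
#' distance, and accepts draws by tolerance or by best quantile.  Draws whose
#' forward solve diverges get infinite distance (never accepted in quantile
#' mode before any finite-distance draw).
#'
#' @param data observed series (data.frame: `time` + two gene columns)
#' @param config an [abc_config()]
#' @return object of class `abc_result`: `accepted` (data.frame of the eight
#'   parameters plus `distance`), `n_draws`, `acceptance_rate`, `config`
#' @export
abc_rejection <- function(data, config = abc_config()) {
  check_series(data)
  stopifnot(inherits(config, "abc_config"))
  rs <- local_rng(config$seed)
  on.exit(restore_rng(rs))
  n <- config$n_draws
  par_mat <- matrix(stats::runif(n * 8, rep(config$prior_lower, each = n),
                                 rep(config$prior_upper, each = n)),
                    nrow = n, ncol = 8)
  dmat <- as.matrix(data[, 2:3])
  dist <- cpp_abc_distances(par_mat, dmat, config$init,
                            as.numeric(data$time), config$dt)
  if (!is.null(config$tolerance)) {
    keep <- which(dist <= config$tolerance)
    if (length(keep) == 0)
      warning("empty posterior: no draw within tolerance ", config$tolerance)
  } else {
    n_keep <- max(1L, floor(n * config$quantile))
    keep <- order(dist)[seq_len(n_keep)]
    keep <- keep[is.finite(dist[keep])]
  }
  acc <- as.data.frame(par_mat[keep, , drop = FALSE])
  names(acc) <- PARAM_SLOTS
  acc$distance <- dist[keep]
  structure(list(accepted = acc, n_draws = n,
                 acceptance_rate = length(keep) / n, config = config),
            class = "abc_result")
}

#' @export
print.abc_result <- function(x, ...) {
  cat(sprintf("ABC rejection: %d draws, %d accepted (rate %.4g)\n",
              x$n_draws, nrow(x$accepted), x$acceptance_rate))
  if (nrow(x$accepted) > 0)
    cat(sprintf("  distance range of accepted: [%.4g, %.4g]\n",
                min(x$accepted$distance), max(x$accepted$distance)))
  invisible(x)
}

#' Per-parameter posterior median of an ABC result
#'
#' @param result an `abc_result`
#' @return a [twonode_params()] object built from the medians
#' @export
posterior_median <- function(result) {
  stopifnot(inherits(result, "abc_result"))
  if (nrow(result$accepted) == 0) stop_input("empty posterior")
  med <- vapply(result$accepted[PARAM_SLOTS], stats::median, numeric(1))
  twonode_params(med[1], med[2], med[3], med[4], med[5], med[6], med[7], med[8])
}

#' Form Z-U module observables from three-gene data
#'
#' The GATA-switching module's auxiliary variable u is the sum of GATA1 and
#' PU.1; its z variable is GATA2.  Given a series with columns
#' `time, gata2, gata1, pu1`, returns the two-column series `(z, u)` that
#' [abc_rejection()] can fit.
#'
#' @param data data.frame with columns `time`, GATA2, GATA1, PU.1 (in order)
#' @return data.frame with columns `time`, `z`, `u`
#' @export
zu_observables <- function(data) {
  if (!is.data.frame(data) || ncol(data) < 4 || names(data)[1] != "time")
    stop_input("'data' must have columns time, gata2, gata1, pu1")
  data.frame(time = data$time, z = data[[2]], u = data[[3]] + data[[4]])
}
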