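#' Stochastic simulation of the quad-stable model
#'
#' The quad-stable GATA1-PU.1-GATA2 model as an Ito stochastic differential
#' equation: the drift is the deterministic vector field and each gene's
#' diffusion multiplies its full degradation(+switching) flux,
#' \deqn{dX = f_x\,dt + \omega_1 (k_3 X + \psi k^* Z)\,dW^1}
#' \deqn{dY = f_y\,dt + \omega_2 k_4 Y\,dW^2}
#' \deqn{dZ = f_z\,dt + \omega_3 (k_1 + k^*) Z\,dW^3}
#' integrated with the semi-implicit Euler method: production and switching
#' source terms explicit, linear losses implicit (division by `1 + k dt`),
#' Wiener increments `N(0, dt)`, and states clamped at zero after each step
#' (absorbing-at-zero-then-release: the drift can regrow basal expression).
#'
#' @name stochastic-ensemble
NULL

#' SDE simulation configuration
#'
#' @param dt step size (> 0); default 0.01
#' @param t_end final time (> 0); default 10000 with the switching window at
#'   \[500, 3500\]
#' @param init non-negative initial state `(x, y, z)`; typically the G2H
#'   (HSC) stable state
#' @param sched a [switch_schedule()]
#' @param noise a [noise_params()]
#' @param seed integer seed
#' @return an `sde_config` object
#' @export
sde_config <- function(dt = 0.01, t_end = 10000, init, sched = switch_schedule(),
                       noise = noise_params(), seed = 1L) {
  stopifnot(inherits(sched, "switch_schedule"), inherits(noise, "noise_params"))
  if (dt <= 0) stop_input("'dt' must be > 0")
  if (t_end <= 0) stop_input("'t_end' must be > 0")
  structure(list(dt = dt, t_end = t_end, init = check_state(init, 3L),
                 sched = sched, noise = noise, seed = as.integer(seed)),
            class = "sde_config")
}

sched_vec <- function(sched) c(sched$k0_star, sched$t1, sched$t2, sched$psi)
noise_vec <- function(noise) c(noise$omega1, noise$omega2, noise$omega3)

#' One semi-implicit Euler step (reference R implementation)
#'
#' The compiled integrator uses the identical scheme; this R version exists
#' for inspection and unit testing.  Uses the current RNG stream for the
#' three independent `N(0, dt)` Wiener increments.
#'
#' @param state non-negative length-3 state `(x, y, z)`
#' @param t current time
#' @param dt step size (> 0)
#' @param params a [quad_params()] object
#' @param sched a [switch_schedule()]
#' @param noise a [noise_params()]
#' @param dW optional length-3 Wiener increments (for deterministic testing);
#'   drawn from `N(0, dt)` when `NULL`
#' @return the next state, clamped at zero componentwise
#' @export
sde_step <- function(state, t, dt, params, sched, noise, dW = NULL) {
  stopifnot(inherits(params, "quad_params"))
  if (dt <= 0) stop_input("'dt' must be > 0")
  s <- check_state(state, 3L)
  if (is.null(dW)) dW <- stats::rnorm(3, 0, sqrt(dt))
  ks <- k_star(t, sched)
  x <- s[1]; y <- s[2]; z <- s[3]
  prodx <- (params$alpha0 + params$alpha1 * x) / (1 + params$beta1 * x) /
    (1 + params$beta2 * y) * (1 + params$d_star * z) / (1 + params$d2 * z) +
    sched$psi * ks * z
  prody <- (params$gamma0 + params$gamma1 * y) / (1 + params$sigma1 * y) /
    (1 + params$sigma2 * x) / (1 + params$d2 * z)
  prodz <- (params$a0 + params$a1 * z) / (1 + params$b1 * z) /
    (1 + params$b2 * (x + y))
  xn <- (x + dt * prodx + noise$omega1 * (params$k3 * x + sched$psi * ks * z) * dW[1]) /
    (1 + dt * params$k3)
  yn <- (y + dt * prody + noise$omega2 * params$k4 * y * dW[2]) /
    (1 + dt * params$k4)
  zn <- (z + dt * prodz + noise$omega3 * (params$k1 + ks) * z * dW[3]) /
    (1 + dt * (params$k1 + ks))
  pmax(c(xn, yn, zn), 0)
}

#' Simulate one stochastic trajectory
#'
#' Seeded, reproducible semi-implicit Euler path of the quad-model SDE.
#'
#' @param config an [sde_config()]
#' @param params a [quad_params()] object
#' @param save_every save the state every this many steps (the initial state
#'   is always kept)
#' @param return_increments also return the per-step Wiener increments
#'   (memory-heavy; for diagnostics)
#' @return data.frame `time, x, y, z`; with `return_increments`, the
#'   increments matrix is attached as attribute `"increments"`
#' @export
simulate_sde <- function(config, params, save_every = 100L,
                         return_increments = FALSE) {
  stopifnot(inherits(config, "sde_config"), inherits(params, "quad_params"))
  rs <- local_rng(config$seed)
  on.exit(restore_rng(rs))
  res <- cpp_sde_path(param_vec(params), sched_vec(config$sched),
                      noise_vec(config$noise), config$init, config$t_end,
                      config$dt, as.integer(save_every), return_increments)
  out <- data.frame(time = res$time, x = res$states[, 1], y = res$states[, 2],
                    z = res$states[, 3])
  if (return_increments) attr(out, "increments") <- res$increments
  out
}

STATE_LABELS <- c("G2H", "G1H", "P1H", "LE3G")

#' Label stable states by their dominant gene
#'
#' Gene g is "high" in a stable state when its value exceeds half the maximum
#' of g across all stable states, and that maximum is itself at least 5
#' percent of the largest expression value anywhere (a gene that is low in
#' every state is never "high").  A state with exactly one high gene is
#' labelled by it — `G1H` for x (GATA1), `P1H` for y (PU.1), `G2H` for z
#' (GATA2); a state with no high gene is the low-expression state `LE3G`;
#' anything else is `unclassified`.
#'
#' @param states numeric matrix (one stable state per row, columns x, y, z)
#'   or an `equilibrium_set` whose stable members are used
#' @return a `data.frame` with columns `x, y, z, label`
#' @export
label_stable_states <- function(states) {
  if (inherits(states, "equilibrium_set")) {
    keep <- vapply(states, function(e) e$classification == "stable", logical(1))
    states <- do.call(rbind, lapply(states[keep], function(e) e$state))
  }
  states <- as.matrix(states)
  if (is.null(states) || nrow(states) == 0) stop_input("no stable states supplied")
  hi <- apply(states, 2, max)
  floor <- 0.05 * max(hi)
  lab <- apply(states, 1, function(s) {
    high <- s > 0.5 * hi & hi > floor
    if (sum(high) == 1) c("G1H", "P1H", "G2H")[which(high)]
    else if (sum(high) == 0) "LE3G"
    else "unclassified"
  })
  data.frame(x = states[, 1], y = states[, 2], z = states[, 3], label = lab)
}

#' Classify a simulation endpoint against the stable-state set
#'
#' Assigns the label of the nearest stable state in Euclidean distance on
#' `ln(value + 1)`-transformed coordinates.  Ties resolve deterministically
#' to the earlier row of `stable_states` (order rows G2H, G1H, P1H, LE3G for
#' the documented tie-break).  Returns `"unclassified"` when the distance
#' exceeds `cutoff` or when `final_time` lies inside the switching window of
#' `sched`.
#'
#' @param final_state numeric length-3 state (or a matrix of states, one per
#'   row)
#' @param stable_states a labelled stable-state table from
#'   [label_stable_states()]
#' @param cutoff maximum log-scale distance for classification (default
#'   `Inf`: always classify)
#' @param final_time,sched optional: when given and `final_time` is within
#'   `[sched$t1, sched$t2]`, everything is `"unclassified"`
#' @return character vector of labels
#' @export
classify_endpoint <- function(final_state, stable_states, cutoff = Inf,
                              final_time = NULL, sched = NULL) {
  if (!is.data.frame(stable_states) || nrow(stable_states) == 0)
    stop_input("'stable_states' must be a non-empty labelled table")
  if (!is.null(final_time) && !is.null(sched) &&
      final_time >= sched$t1 && final_time <= sched$t2) {
    n <- if (is.matrix(final_state)) nrow(final_state) else 1L
    return(rep("unclassified", n))
  }
  fs <- if (is.matrix(final_state)) final_state else matrix(final_state, nrow = 1)
  ref <- log1p(as.matrix(stable_states[, c("x", "y", "z")]))
  lf <- log1p(fs)
  vapply(seq_len(nrow(lf)), function(i) {
    d <- sqrt(rowSums((ref - matrix(lf[i, ], nrow(ref), 3, byrow = TRUE))^2))
    j <- which.min(d)
    if (d[j] > cutoff) "unclassified" else stable_states$label[j]
  }, character(1))
}

#' Run an ensemble of stochastic replicates
#'
#' Simulates `n_replicates` independent seeded trajectories and classifies
#' each endpoint.
#'
#' @param n_replicates number of replicates (>= 1)
#' @param config an [sde_config()]
#' @param params a [quad_params()] object
#' @param stable_states labelled stable-state table ([label_stable_states()]);
#'   computed from the deterministic model (`k* = 0`) when `NULL`
#' @param cutoff classification distance cutoff, see [classify_endpoint()]
#' @return object of class `ensemble_result`: `final_states` (n x 3 matrix),
#'   `labels`, `counts`, `frequencies` (sum to 1), `stable_states`, `config`
#' @export
run_ensemble <- function(n_replicates, config, params, stable_states = NULL,
                         cutoff = Inf) {
  stopifnot(inherits(config, "sde_config"), inherits(params, "quad_params"))
  if (n_replicates < 1) stop_input("'n_replicates' must be >= 1")
  if (is.null(stable_states))
    stable_states <- label_stable_states(find_equilibria(params))
  rs <- local_rng(config$seed)
  on.exit(restore_rng(rs))
  fin <- cpp_sde_final(param_vec(params), sched_vec(config$sched),
                       noise_vec(config$noise), config$init, config$t_end,
                       config$dt, as.integer(n_replicates))
  colnames(fin) <- c("x", "y", "z")
  labels <- classify_endpoint(fin, stable_states, cutoff = cutoff,
                              final_time = config$t_end, sched = config$sched)
  lev <- c(STATE_LABELS, "unclassified")
  counts <- table(factor(labels, levels = lev))
  structure(list(final_states = fin, labels = labels, counts = counts,
                 frequencies = counts / n_replicates,
                 n_replicates = n_replicates,
                 stable_states = stable_states, config = config),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("Stochastic ensemble: %d replicates (seed %d)\n",
              x$n_replicates, x$config$seed))
  print(round(x$frequencies, 4))
  invisible(x)
}

#' Sweep the switching parameters (k0*, psi)
#'
#' Runs an ensemble for every grid cell and summarises: the fraction of
#' replicates with successful switching (endpoint label different from G2H;
#' LE3G endpoints count as switched but are also reported separately), the
#' GMP:MEP ratio (P1H count / G1H count) among switched replicates (`NA` when
#' no replicate switched or no G1H endpoint exists), whether all four states
#' coexist among the endpoints, and the LE3G frequency.
#'
#' @param k0_star_values,psi_values grid values (the study range is
#'   k0* in \[0.04, 1\], psi in \[0, 0.001\])
#' @param n_per_cell replicates per grid cell
#' @param config an [sde_config()]; its schedule supplies the window, and its
#'   seed is advanced per cell for independence
#' @param params a [quad_params()] object
#' @param stable_states optional labelled stable-state table
#' @return a long-format `data.frame` with one row per cell: `k0_star`,
#'   `psi`, `switched`, `gmp_mep_ratio`, `four_states`, `freq_LE3G`,
#'   `freq_G2H`, `freq_G1H`, `freq_P1H`, `seed`
#' @export
sweep_switching <- function(k0_star_values, psi_values, n_per_cell, config,
                            params, stable_states = NULL) {
  stopifnot(inherits(config, "sde_config"))
  if (is.null(stable_states))
    stable_states <- label_stable_states(find_equilibria(params))
  cells <- expand.grid(k0_star = k0_star_values, psi = psi_values)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sc <- switch_schedule(cells$k0_star[i], config$sched$t1, config$sched$t2,
                          cells$psi[i])
    cfg <- sde_config(config$dt, config$t_end, config$init, sc, config$noise,
                      seed = config$seed + i)
    ens <- run_ensemble(n_per_cell, cfg, params, stable_states)
    fr <- as.numeric(ens$frequencies)
    names(fr) <- names(ens$frequencies)
    switched_n <- sum(ens$labels != "G2H" & ens$labels != "unclassified")
    g1h <- sum(ens$labels == "G1H"); p1h <- sum(ens$labels == "P1H")
    rows[[i]] <- data.frame(
      k0_star = cells$k0_star[i], psi = cells$psi[i],
      switched = switched_n / ens$n_replicates,
      gmp_mep_ratio = if (switched_n == 0 || g1h == 0) NA_real_ else p1h / g1h,
      four_states = all(STATE_LABELS %in% ens$labels),
      freq_LE3G = fr[["LE3G"]], freq_G2H = fr[["G2H"]],
      freq_G1H = fr[["G1H"]], freq_P1H = fr[["P1H"]],
      seed = cfg$seed)
  }
  do.call(rbind, rows)
}

#' Per-state, per-gene expression distributions
#'
#' Endpoint expression values on the `ln(value + 1)` scale, grouped by
#' endpoint label and gene — the data behind violin-style distribution plots
#' — plus summary quantiles.
#'
#' @param ensemble an `ensemble_result`
#' @return list with `values` (long data.frame: `label`, `gene`, `value`) and
#'   `summary` (per label/gene: q25, median, q75)
#' @export
expression_distributions <- function(ensemble) {
  stopifnot(inherits(ensemble, "ensemble_result"))
  genes <- c(x = "GATA1", y = "PU.1", z = "GATA2")
  vals <- do.call(rbind, lapply(seq_along(genes), function(j) {
    data.frame(label = ensemble$labels, gene = genes[[j]],
               value = log1p(ensemble$final_states[, j]))
  }))
  agg <- stats::aggregate(value ~ label + gene, data = vals, FUN = function(v)
    c(q25 = unname(stats::quantile(v, 0.25)), median = stats::median(v),
      q75 = unname(stats::quantile(v, 0.75)), var = stats::var(v)))
  summary <- cbind(agg[c("label", "gene")], as.data.frame(agg$value))
  list(values = vals, summary = summary)
}
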