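#' Numerical equilibrium analysis
#'
#' Multistart root finding, finite-difference Jacobians and eigenvalue-based
#' stability classification for the 2-D and 3-D vector fields in this package
#' (or any user-supplied vector field `f(state) -> derivative`).
#'
#' @name equilibrium-analysis
NULL

#' Finite-difference Jacobian of a vector field
#'
#' Central (symmetric) differences with per-component step
#' `h * max(1, |point|)`; truncation error is O(h^2).
#'
#' @param f vector field, `f(state) -> derivative` of the same length
#' @param point numeric state at which to differentiate
#' @param h relative step size
#' @return square numeric matrix `J[i, j] = d f_i / d x_j`
#' @export
jacobian <- function(f, point, h = 1e-6) {
  n <- length(point)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    hj <- h * max(1, abs(point[j]))
    up <- point; up[j] <- up[j] + hj
    dn <- point; dn[j] <- dn[j] - hj
    J[, j] <- (f(up) - f(dn)) / (2 * hj)
  }
  J
}

#' Classify an equilibrium from its Jacobian eigenvalues
#'
#' All real parts below `-tol`: `"stable"`; at least one above `tol` and one
#' below `-tol`: `"saddle"`; all above `tol`: `"unstable"`; any real part
#' within `[-tol, tol]`: `"marginal"` (reported, never silently coerced).
#'
#' @param eigenvalues complex (or numeric) vector of Jacobian eigenvalues
#' @param tol tolerance on the eigenvalue real parts
#' @return one of `"stable"`, `"saddle"`, `"unstable"`, `"marginal"`
#' @export
classify <- function(eigenvalues, tol = 1e-8) {
  if (length(eigenvalues) == 0) stop_input("empty eigenvalue list")
  re <- Re(eigenvalues)
  if (any(abs(re) <= tol)) return("marginal")
  if (all(re < 0)) return("stable")
  if (all(re > 0)) return("unstable")
  "saddle"
}

make_equilibrium <- function(f, state, tol = 1e-8) {
  res <- max(abs(f(state)))
  ev <- eigen(jacobian(f, state), only.values = TRUE)$values
  list(state = as.numeric(state), residual = res, eigenvalues = ev,
       classification = classify(ev, tol))
}

# Damped Newton iteration with projection of negative components to zero.
# Returns the converged point or NULL.
newton_root <- function(f, x0, tol = 1e-10, maxit = 60L) {
  x <- pmax(x0, 0)
  for (it in seq_len(maxit)) {
    fx <- f(x)
    nf <- max(abs(fx))
    if (!is.finite(nf)) return(NULL)
    if (nf < tol) return(x)
    J <- jacobian(f, x)
    step <- tryCatch(solve(J, fx), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    lambda <- 1
    improved <- FALSE
    for (half in 1:8) {
      xn <- pmax(x - lambda * step, 0)
      fn <- f(xn)
      if (all(is.finite(fn)) && max(abs(fn)) < nf) {
        x <- xn; improved <- TRUE; break
      }
      lambda <- lambda / 2
    }
    if (!improved) {
      # full step anyway: Newton may need to pass through a worse iterate
      x <- pmax(x - step, 0)
    }
  }
  if (max(abs(f(x))) < tol) x else NULL
}

#' Find all non-negative equilibria of a vector field by multistart Newton
#'
#' Starts a damped Newton iteration (with projection of negative components to
#' zero) from a regular `5^dim` grid over the search box plus `n_starts`
#' seeded uniform random starts, deduplicates converged points within
#' `dedup_radius` (relative to the box diagonal), and classifies each
#' equilibrium from its Jacobian eigenvalues.  Deterministic given
#' `(box, n_starts, seed)`.
#'
#' @param f vector field `f(state) -> derivative`, or a parameter object
#'   (e.g. [toggle_params()], [tristable_params()]) whose RHS is used
#' @param box numeric matrix `dim x 2` of lower/upper search bounds, or a
#'   single upper bound applied to all coordinates (lower bound 0)
#' @param n_starts number of random starts added to the regular grid
#' @param tol residual tolerance (max-norm of the RHS)
#' @param dedup_radius merge radius as a fraction of the box diagonal
#' @param seed integer seed for the random starts
#' @param stability_tol eigenvalue tolerance passed to [classify()]
#' @return object of class `equilibrium_set`: a list of equilibria, each with
#'   `state`, `residual`, `eigenvalues`, `classification`
#' @examples
#' eq <- find_equilibria(toggle_params(), box = 6)
#' summary_counts(eq)  # 2 stable, 1 saddle
#' @export
find_equilibria <- function(f, box, n_starts = 100L, tol = 1e-10,
                            dedup_radius = 1e-6, seed = 1L,
                            stability_tol = 1e-8) {
  pdim <- NULL
  pobj <- NULL  # built-in parameter object -> compiled Newton fast path
  if (!is.function(f)) {
    if (inherits(f, "subsystem_spec")) {
      pdim <- length(f$vars)
      f <- subsystem_rhs(f)
      if (missing(box)) stop_input("a search box is required for subsystem specs")
    } else {
      pobj <- f
      pdim <- model_dim(f)
      if (missing(box)) box <- default_box(f)
      f <- rhs_function(f)
    }
  }
  if (is.matrix(box)) {
    lo <- box[, 1]; hi <- box[, 2]
  } else if (length(box) == 1) {
    if (is.null(pdim)) pdim <- probe_dim(f)
    lo <- rep(0, pdim); hi <- rep(as.numeric(box), pdim)
  } else {
    lo <- rep(0, length(box)); hi <- as.numeric(box)
  }
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(lo < 0) || any(hi <= lo))
    stop_input("search box must be finite, non-negative, with upper > lower")
  dim <- length(lo)
  diag_len <- sqrt(sum((hi - lo)^2))

  # 5^dim grid with log-style spacing: equilibria of saturating-production
  # models sit at widely different scales, and an anisotropic box makes
  # linearly spaced starts miss small-coordinate states
  axes <- lapply(seq_len(dim), function(i)
    lo[i] + c(0, 0.01, 0.1, 0.5, 1) * (hi[i] - lo[i]))
  grid <- as.matrix(expand.grid(axes))
  colnames(grid) <- NULL
  starts <- grid
  if (n_starts > 0) {
    rs <- local_rng(seed)
    rnd <- matrix(stats::runif(n_starts * dim, rep(lo, each = n_starts),
                               rep(hi, each = n_starts)), ncol = dim)
    restore_rng(rs)
    starts <- rbind(starts, rnd)
  }

  converged <- if (is.null(pobj)) {
    lapply(seq_len(nrow(starts)), function(i) newton_root(f, starts[i, ], tol = tol))
  } else {
    rm <- cpp_newton_multistart(model_id(pobj), param_vec(pobj), starts, tol, 60L)
    lapply(seq_len(nrow(rm)), function(i) {
      r <- rm[i, ]
      if (anyNA(r)) NULL else r
    })
  }
  roots <- list()
  for (i in seq_along(converged)) {
    r <- converged[[i]]
    if (is.null(r)) next
    if (any(r < lo - 1e-9) || any(r > hi + diag_len * 0.5)) next
    dup <- FALSE
    for (q in roots) {
      if (sqrt(sum((q - r)^2)) < dedup_radius * max(diag_len, 1)) { dup <- TRUE; break }
    }
    if (!dup) roots[[length(roots) + 1L]] <- r
  }
  eqs <- lapply(roots, function(r) make_equilibrium(f, r, tol = stability_tol))
  structure(eqs, class = "equilibrium_set")
}

#' @export
print.equilibrium_set <- function(x, ...) {
  cat(sprintf("Equilibrium set: %d point(s)\n", length(x)))
  for (e in x) {
    cat(sprintf("  (%s)  residual=%.2e  %s\n",
                paste(sprintf("%.6g", e$state), collapse = ", "),
                e$residual, e$classification))
  }
  invisible(x)
}

#' Tabulate stability classes of an equilibrium set
#'
#' @param eqs an `equilibrium_set` (from [find_equilibria()] and friends)
#' @return named integer vector with counts for stable, saddle, unstable,
#'   marginal
#' @export
summary_counts <- function(eqs) {
  cls <- vapply(eqs, function(e) e$classification, character(1))
  c(stable = sum(cls == "stable"), saddle = sum(cls == "saddle"),
    unstable = sum(cls == "unstable"), marginal = sum(cls == "marginal"))
}

#' Convert an equilibrium set to a data frame
#'
#' One row per equilibrium: coordinates, residual, eigenvalue real/imaginary
#' parts, classification.  Suitable for writing with [utils::write.csv()].
#'
#' @param x an `equilibrium_set`
#' @param row.names,optional,... passed through (unused)
#' @return a `data.frame`
#' @export
as.data.frame.equilibrium_set <- function(x, row.names = NULL, optional = FALSE, ...) {
  if (length(x) == 0) {
    return(data.frame(residual = numeric(0), classification = character(0)))
  }
  dim <- length(x[[1]]$state)
  coord <- t(vapply(x, function(e) e$state, numeric(dim)))
  colnames(coord) <- paste0("x", seq_len(dim))
  ev_re <- t(vapply(x, function(e) Re(e$eigenvalues), numeric(dim)))
  ev_im <- t(vapply(x, function(e) Im(e$eigenvalues), numeric(dim)))
  colnames(ev_re) <- paste0("eig_re", seq_len(dim))
  colnames(ev_im) <- paste0("eig_im", seq_len(dim))
  data.frame(coord,
             residual = vapply(x, function(e) e$residual, numeric(1)),
             ev_re, ev_im,
             classification = vapply(x, function(e) e$classification, character(1)))
}

#' Default search box for a parameter object
#'
#' Per-variable upper bound `1.5 x` the largest value the variable's
#' nullcline can reach: repression factors only shrink production, so at any
#' equilibrium `deg * v * (1 + sat * v) <= basal + gain * v`, whose positive
#' root bounds `v`.  For the toggle model the bound is
#' `basal + strength` (decay rate 1).
#'
#' @param params a parameter object
#' @return a `dim x 2` matrix of bounds
#' @export
default_box <- function(params) {
  sa_bound <- function(gain, sat, deg, basal = 0) {
    if (sat > 0)
      (gain - deg + sqrt((gain - deg)^2 + 4 * deg * sat * basal)) /
        (2 * deg * sat)
    else if (deg > gain) basal / (deg - gain)
    else 10 * (gain + basal + 1) / deg  # unbounded nullcline: generous cap
  }
  if (inherits(params, "toggle_params")) {
    hi <- rep(params$basal + params$strength, 2)
  } else if (inherits(params, c("quad_params", "tristable_params"))) {
    basal <- if (inherits(params, "quad_params"))
      c(params$alpha0, params$gamma0, params$a0) else c(0, 0, 0)
    hi <- c(sa_bound(params$alpha1, params$beta1, params$k3, basal[1]),
            sa_bound(params$gamma1, params$sigma1, params$k4, basal[2]),
            sa_bound(params$a1, params$b1, params$k1, basal[3]))
  } else if (inherits(params, "twonode_params")) {
    hi <- c(sa_bound(params$gain1, params$sat1, params$deg1),
            sa_bound(params$gain2, params$sat2, params$deg2))
  } else stop_input("unsupported parameter object")
  hi <- 1.5 * pmax(hi, 1)
  cbind(rep(0, length(hi)), hi)
}

#' Distances between stable states and saddle points
#'
#' Euclidean distance from each stable equilibrium to each saddle, plus the
#' per-stable-state minimum — a proxy for the size of the basin of attraction.
#'
#' @param eqs a classified `equilibrium_set`
#' @return a list with `matrix` (stable x saddle distances, dimnames by
#'   coordinates) and `min_distance` (named numeric, one entry per stable
#'   state); both empty (with a warning) when there are no saddles
#' @export
saddle_distances <- function(eqs) {
  cls <- vapply(eqs, function(e) e$classification, character(1))
  stables <- eqs[cls == "stable"]
  saddles <- eqs[cls == "saddle"]
  lbl <- function(e) paste0("(", paste(sprintf("%.4g", e$state), collapse = ","), ")")
  if (length(saddles) == 0 || length(stables) == 0) {
    warning("no saddle (or no stable) states: empty distance table")
    return(list(matrix = matrix(numeric(0), 0, 0), min_distance = numeric(0)))
  }
  m <- matrix(0, length(stables), length(saddles),
              dimnames = list(vapply(stables, lbl, character(1)),
                              vapply(saddles, lbl, character(1))))
  for (i in seq_along(stables))
    for (j in seq_along(saddles))
      m[i, j] <- sqrt(sum((stables[[i]]$state - saddles[[j]]$state)^2))
  list(matrix = m, min_distance = apply(m, 1, min))
}
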