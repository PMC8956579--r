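#' The embedding transform
#'
#' A multistable system is built from two bistable subsystems by declaring
#' one or more *auxiliary* variables of the primary subsystem to be functions
#' of the secondary subsystem's variables (here non-negative linear
#' combinations, `u = mu x + delta y`).  The transform
#' 1. drops the auxiliary equations from the primary subsystem,
#' 2. substitutes the linear combination for every occurrence of an auxiliary
#'    variable in the remaining primary equations, and
#' 3. multiplies every *production term* of the secondary equations by the
#'    repression factors that acted on the auxiliary's own production in the
#'    primary subsystem (the regulation the substitution induces: if z
#'    repressed u, z now represses everything u stood for).
#'
#' Embedding is performed structurally on term descriptors — production
#' factors, additive basal constants, linear decay — not by symbolic algebra,
#' so the result is exactly evaluatable.  Two term families are supported:
#' Shea-Ackers saturating production and Hill-repression production; other
#' shapes raise an unsupported-form error.
#'
#' @name embedding
NULL

# ---- term descriptors -------------------------------------------------------

as_lincomb <- function(vars) {
  if (is.character(vars)) vars <- stats::setNames(rep(1, length(vars)), vars)
  if (is.null(names(vars)) || any(names(vars) == "") || any(vars < 0))
    stop_input("a linear combination needs named, non-negative coefficients")
  vars
}

#' Repression-factor descriptors
#'
#' A repressor contributes the multiplicative factor
#' `1 / (1 + (coef * L)^hill)` to a production term, where `L` is a
#' non-negative linear combination of variables.  `shea_repressor(var, coef)`
#' is the Shea-Ackers case (`hill = 1`); `hill_repressor(var, hill)` is the
#' toggle-switch case (`coef = 1`).
#'
#' @param vars variable name(s), or a named non-negative coefficient vector
#'   defining the linear combination `L`
#' @param coef repression coefficient (>= 0)
#' @param hill Hill exponent (> 0)
#' @return a `repressor` descriptor
#' @export
repressor <- function(vars, coef = 1, hill = 1) {
  structure(list(vars = as_lincomb(vars),
                 coef = check_num(coef, "coef", 0),
                 hill = check_num(hill, "hill", 0, strict = TRUE)),
            class = "repressor")
}

#' @rdname repressor
#' @export
shea_repressor <- function(vars, coef) repressor(vars, coef = coef, hill = 1)

#' @rdname repressor
#' @export
hill_repressor <- function(vars, hill) repressor(vars, coef = 1, hill = hill)

repressor_value <- function(rep, state) {
  L <- sum(rep$vars * state[names(rep$vars)])
  1 / (1 + (rep$coef * L)^rep$hill)
}

#' Production-term descriptors
#'
#' `sa_production()` is a Shea-Ackers saturating production
#' `(num0 + gain * self) / (1 + sat * self)` times its repression factors;
#' `hill_production()` is a constant strength times its repression factors
#' (the toggle-switch form `b / (1 + u^n)`).
#'
#' @param gain production gain (>= 0)
#' @param sat self-saturation coefficient (>= 0)
#' @param self name of the autoregulating variable
#' @param repressors list of [repressor()] descriptors
#' @param num0 additive numerator constant (basal production through the same
#'   saturating unit; 0 for the plain model)
#' @param strength production strength of the Hill form (>= 0)
#' @return a `production_term` descriptor
#' @export
sa_production <- function(gain, sat, self, repressors = list(), num0 = 0) {
  structure(list(kind = "shea", gain = check_num(gain, "gain", 0),
                 sat = check_num(sat, "sat", 0), self = self,
                 num0 = check_num(num0, "num0", 0),
                 repressors = repressors),
            class = "production_term")
}

#' @rdname sa_production
#' @export
hill_production <- function(strength, repressors = list()) {
  structure(list(kind = "hill", strength = check_num(strength, "strength", 0),
                 repressors = repressors),
            class = "production_term")
}

term_value <- function(term, state) {
  base <- switch(term$kind,
    shea = {
      v <- state[[term$self]]
      (term$num0 + term$gain * v) / (1 + term$sat * v)
    },
    hill = term$strength,
    stop_input("unsupported production-term kind '", term$kind, "'"))
  for (rep in term$repressors) base <- base * repressor_value(rep, state)
  base
}

#' Equation and subsystem descriptors
#'
#' An equation is `d var/dt = const + sum(production terms) - decay * var`.
#' A subsystem is an ordered set of equations, with a (possibly empty) subset
#' of its variables declared auxiliary — these are the variables that an
#' embedding will substitute away.
#'
#' @param var variable name
#' @param const additive basal constant (not subject to induced regulation)
#' @param terms list of production terms
#' @param decay linear degradation rate
#' @return `reg_equation()`: an equation descriptor
#' @export
reg_equation <- function(var, const = 0, terms = list(), decay = 0) {
  structure(list(var = var, const = check_num(const, "const", 0),
                 terms = terms, decay = check_num(decay, "decay", 0)),
            class = "reg_equation")
}

equation_value <- function(eq, state) {
  v <- eq$const - eq$decay * state[[eq$var]]
  for (tm in eq$terms) v <- v + term_value(tm, state)
  v
}

#' @param vars ordered character vector of variable names
#' @param equations list of [reg_equation()]s, one per variable, same order
#' @param aux character vector of auxiliary variable names (subset of `vars`)
#' @rdname reg_equation
#' @export
subsystem_spec <- function(vars, equations, aux = character()) {
  if (length(vars) != length(equations) ||
      !identical(vars, vapply(equations, function(e) e$var, character(1))))
    stop_input("'equations' must match 'vars' one-to-one, in order")
  if (!all(aux %in% vars))
    stop_input("auxiliary names must be a subset of the variable list")
  structure(list(vars = vars, equations = stats::setNames(equations, vars),
                 aux = aux),
            class = "subsystem_spec")
}

#' Evaluate a subsystem (or embedded system) as a vector field
#'
#' @param spec a `subsystem_spec` or `embedded_system`
#' @return function `f(state) -> derivative` (state positional in `spec$vars`
#'   order, or named)
#' @export
subsystem_rhs <- function(spec) {
  vars <- spec$vars
  eqs <- spec$equations
  function(state) {
    if (is.null(names(state))) names(state) <- vars
    vapply(eqs, equation_value, numeric(1), state = state, USE.NAMES = FALSE)
  }
}

# ---- prebuilt subsystems ----------------------------------------------------

#' Toggle-switch and two-node Shea-Ackers subsystem descriptors
#'
#' Build the structural (term-descriptor) form of the package's two bistable
#' families, ready for [embed()].
#'
#' @param params a [toggle_params()] / [twonode_params()] object
#' @param vars the two variable names
#' @param aux auxiliary variable names to expose for embedding
#' @return a `subsystem_spec`
#' @export
toggle_subsystem <- function(params = toggle_params(), vars = c("z", "u"),
                             aux = character()) {
  stopifnot(inherits(params, "toggle_params"))
  eq <- function(v, other) reg_equation(
    v, const = params$basal,
    terms = list(hill_production(params$strength,
                                 list(hill_repressor(other, params$hill)))),
    decay = 1)
  subsystem_spec(vars, list(eq(vars[1], vars[2]), eq(vars[2], vars[1])), aux)
}

#' @rdname toggle_subsystem
#' @export
shea_subsystem <- function(params, vars = params$vars, aux = character()) {
  stopifnot(inherits(params, "twonode_params"))
  eq1 <- reg_equation(vars[1], terms = list(
    sa_production(params$gain1, params$sat1, vars[1],
                  list(shea_repressor(vars[2], params$rep1)))),
    decay = params$deg1)
  eq2 <- reg_equation(vars[2], terms = list(
    sa_production(params$gain2, params$sat2, vars[2],
                  list(shea_repressor(vars[1], params$rep2)))),
    decay = params$deg2)
  subsystem_spec(vars, list(eq1, eq2), aux)
}

# ---- the embedding transform ------------------------------------------------

subst_lincomb <- function(coefs, map) {
  out <- numeric(0)
  for (nm in names(coefs)) {
    if (nm %in% names(map)) {
      add <- coefs[[nm]] * map[[nm]]
      for (mn in names(add)) out[mn] <- (if (mn %in% names(out)) out[[mn]] else 0) + add[[mn]]
    } else {
      out[nm] <- (if (nm %in% names(out)) out[[nm]] else 0) + coefs[[nm]]
    }
  }
  out
}

subst_term <- function(term, map) {
  if (term$kind == "shea" && term$self %in% names(map))
    stop_input("auxiliary variable appears as an autoregulating production ",
               "variable; only repressor occurrences can be substituted")
  term$repressors <- lapply(term$repressors, function(rep) {
    rep$vars <- subst_lincomb(rep$vars, map)
    rep
  })
  term
}

#' Apply an induced regulation factor to a production term
#'
#' When an auxiliary variable u is substituted by `H(Y)`, every regulation
#' that the primary subsystem exerted on u's *production* is inherited by the
#' production terms of the secondary subsystem: the term is multiplied by the
#' corresponding repression factor (Shea-Ackers `1/(1 + coef z)` or Hill
#' `1/(1 + z^n)`).
#'
#' @param term a `production_term`
#' @param rep a [repressor()] descriptor (the factor to inherit)
#' @return the transformed `production_term`
#' @examples
#' tm <- hill_production(4, list(hill_repressor("y", 3)))
#' induced_regulation_factor(tm, hill_repressor("z", 3))
#' # 4 / ((1 + y^3)(1 + z^3))
#' @export
induced_regulation_factor <- function(term, rep) {
  if (!inherits(term, "production_term"))
    stop_input("unsupported term shape: expected a 'production_term' ",
               "(Shea-Ackers or Hill-repression family)")
  stopifnot(inherits(rep, "repressor"))
  term$repressors <- c(term$repressors, list(rep))
  term
}

#' Embed a secondary bistable subsystem into a primary one
#'
#' Couples two subsystems by substituting each auxiliary variable of the
#' primary with a non-negative linear combination of secondary variables and
#' propagating the induced regulations (see the module description under
#' `?embedding`).  With no auxiliaries the result is the disjoint union of
#' the two subsystems.
#'
#' @param primary a `subsystem_spec` whose `aux` variables will be substituted
#' @param secondary a `subsystem_spec` (no auxiliaries expected)
#' @param map named list: auxiliary name -> named non-negative coefficient
#'   vector over secondary variables, e.g. `list(u = c(x = 1, y = 1))`
#' @return an object of class `embedded_system` with `vars` (primary
#'   non-auxiliary variables followed by secondary variables), `equations`,
#'   and `rhs` (the combined vector field)
#' @examples
#' prim <- toggle_subsystem(vars = c("z", "u"), aux = "u")
#' sec  <- toggle_subsystem(vars = c("x", "y"))
#' sys  <- embed(prim, sec, list(u = c(x = 1, y = 1)))
#' sys$rhs(c(x = 0, y = 0, z = 0))  # c(4.2, 4.2, 4.2)
#' @export
embed <- function(primary, secondary, map = list()) {
  stopifnot(inherits(primary, "subsystem_spec"), inherits(secondary, "subsystem_spec"))
  if (!setequal(names(map), primary$aux))
    stop_input("map must provide exactly one rule per auxiliary variable (",
               paste(primary$aux, collapse = ", "), ")")
  map <- lapply(map, as_lincomb)
  for (rule in map) {
    if (!all(names(rule) %in% secondary$vars))
      stop_input("map references variables not in the secondary subsystem")
  }
  if (any(secondary$vars %in% setdiff(primary$vars, primary$aux)))
    stop_input("variable names of the two subsystems must be disjoint")

  keep <- setdiff(primary$vars, primary$aux)
  # primary equations with auxiliaries substituted
  prim_eqs <- lapply(primary$equations[keep], function(eq) {
    eq$terms <- lapply(eq$terms, subst_term, map = map)
    eq
  })
  # regulation factors induced on the secondary by each auxiliary's equation
  induced <- list()
  for (a in primary$aux) {
    for (tm in primary$equations[[a]]$terms) {
      for (rep in tm$repressors) {
        if (all(names(rep$vars) %in% keep))
          induced <- c(induced, list(rep))
      }
    }
  }
  sec_eqs <- lapply(secondary$equations, function(eq) {
    eq$terms <- lapply(eq$terms, function(tm) {
      for (rep in induced) tm <- induced_regulation_factor(tm, rep)
      tm
    })
    eq
  })
  vars <- c(secondary$vars, keep)
  eqs <- c(sec_eqs, prim_eqs)[vars]
  out <- structure(list(vars = vars, equations = eqs, aux_map = map,
                        primary_kept = keep),
                   class = c("embedded_system", "subsystem_spec"))
  out$rhs <- subsystem_rhs(out)
  out
}

#' @export
print.embedded_system <- function(x, ...) {
  cat(sprintf("Embedded system with variables (%s); substituted auxiliaries: %s\n",
              paste(x$vars, collapse = ", "),
              paste(names(x$aux_map), collapse = ", ")))
  invisible(x)
}
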