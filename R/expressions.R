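#' Symbolic steady-state state probabilities
#'
#' Sums directional-diagram rate-products by target state: `Omega_i` is the
#' unnormalized probability of state i, `Sigma = sum_i Omega_i` the
#' normalization factor, and `p_i = Omega_i / Sigma`. The default output
#' keeps the (numerator, Sigma) pair unreduced: downstream ratios cancel
#' Sigma exactly, which avoids expression blow-up.
#'
#' @param diagram a `kinetic_diagram`.
#' @param directionals optional precomputed
#'   [enumerate_directional_diagrams()] output.
#' @return object of class `rate_expression_set` with fields `states`,
#'   `omega` (named list of `kpoly`) and `sigma` (`kpoly`).
#' @export
state_probability_expressions <- function(diagram,
                                          directionals = enumerate_directional_diagrams(diagram)) {
  states <- diagram$states
  coef <- rep(1, length(directionals))
  keys <- vapply(directionals, function(d) paste(d$rates, collapse = "*"),
                 character(1))
  tgt <- vapply(directionals, function(d) d$target, character(1))
  omega <- lapply(states, function(s) {
    sel <- tgt == s
    kp_from_terms(coef[sel], keys[sel])
  })
  names(omega) <- states
  sigma <- kp_from_terms(coef, keys)
  structure(list(states = states, omega = omega, sigma = sigma),
            class = "rate_expression_set")
}

#' @export
print.rate_expression_set <- function(x, ...) {
  cat("<rate_expression_set> ", length(x$states), " states; Sigma has ",
      kp_n_terms(x$sigma), " terms\n", sep = "")
  invisible(x)
}

#' Symbolic net cycle flux
#'
#' `J_K = (Pi_plus - Pi_minus) * Sigma_K / Sigma` where `Pi_plus`
#' (`Pi_minus`) is the product of rates along (against) the cycle's positive
#' direction and `Sigma_K` is the feeder factor from the flux diagrams.
#'
#' @param diagram a `kinetic_diagram`.
#' @param cycle a `kcycle` with its positive direction encoded in the node
#'   order.
#' @param sigma optional `kpoly` normalization factor (computed from the
#'   directional diagrams when omitted).
#' @return object of class `cycle_flux_expression` with fields `cycle`,
#'   `pi_plus`, `pi_minus`, `sigma_K`, `numerator` and `denominator`.
#' @export
net_cycle_flux_expression <- function(diagram, cycle, sigma = NULL) {
  nodes <- .check_cycle(diagram, cycle$nodes)
  nxt <- c(nodes[-1], nodes[1])
  fwd <- vapply(seq_along(nodes),
                function(q) rate_symbol(diagram, nodes[q], nxt[q]), character(1))
  rev_ <- vapply(seq_along(nodes),
                 function(q) rate_symbol(diagram, nxt[q], nodes[q]), character(1))
  sigma_K <- flux_sigma(diagram, nodes)
  numerator <- kp_mul(kp_sub(kp_monomial(fwd), kp_monomial(rev_)), sigma_K)
  if (is.null(sigma)) sigma <- state_probability_expressions(diagram)$sigma
  structure(list(cycle = cycle,
                 pi_plus = kp_monomial(fwd), pi_minus = kp_monomial(rev_),
                 sigma_K = sigma_K, numerator = numerator, denominator = sigma),
            class = "cycle_flux_expression")
}

#' @export
print.cycle_flux_expression <- function(x, ...) {
  cat("<cycle_flux_expression> cycle (",
      paste(x$cycle$nodes, collapse = ","), "): numerator ",
      kp_n_terms(x$numerator), " term(s) / Sigma (",
      kp_n_terms(x$denominator), " terms)\n", sep = "")
  invisible(x)
}

#' Symbolic net transition flux
#'
#' `J_ij = k_ij p_i - k_ji p_j` over the symbolic state probabilities;
#' antisymmetry `J_ij = -J_ji` holds by construction.
#'
#' @param diagram a `kinetic_diagram`.
#' @param i,j state labels of a transition.
#' @param probs optional precomputed [state_probability_expressions()].
#' @return object of class `transition_flux_expression` with fields `from`,
#'   `to`, `numerator` and `denominator`.
#' @export
net_transition_flux_expression <- function(diagram, i, j,
                                           probs = state_probability_expressions(diagram)) {
  i <- as.character(i); j <- as.character(j)
  kij <- rate_symbol(diagram, i, j)
  kji <- rate_symbol(diagram, j, i)
  numerator <- kp_sub(kp_mul(kp_sym(kij), probs$omega[[i]]),
                      kp_mul(kp_sym(kji), probs$omega[[j]]))
  structure(list(from = i, to = j, numerator = numerator,
                 denominator = probs$sigma),
            class = "transition_flux_expression")
}

#' @export
print.transition_flux_expression <- function(x, ...) {
  cat("<transition_flux_expression> J_", x$from, ",", x$to, ": ",
      kp_n_terms(x$numerator), " numerator term(s)\n", sep = "")
  invisible(x)
}

# directed unbinding edges of `ligand` on `side`, as a two-column matrix
.unbinding_edges <- function(diagram, ligand, side) {
  e <- diagram$edges
  sel <- !is.na(e$ligand) & e$ligand == ligand &
    e$process == "unbinding" & e$side == side
  cbind(e$from[sel], e$to[sel])
}

#' Symbolic operational flux of a ligand
#'
#' The operational flux is the observable transport rate of a ligand. Two
#' equivalent constructions are available: the *cycles* route sums the
#' signed net cycle fluxes of all cycles with nonzero net transport of the
#' ligand; the *transitions* route sums the net transition fluxes of the
#' ligand's unbinding transitions on the side the ligand is delivered to
#' (the net appearance rate of the ligand on that side). Both produce the
#' same rational expression over Sigma.
#'
#' @param diagram a `kinetic_diagram` with ligand annotations.
#' @param ligand ligand label.
#' @param route `"cycles"` or `"transitions"`.
#' @param positive_direction transport direction counted positive,
#'   `"ext_to_int"` or `"int_to_ext"`.
#' @param probs optional precomputed [state_probability_expressions()].
#' @param cycles optional precomputed [enumerate_cycles()] output.
#' @return object of class `operational_flux_expression` with fields
#'   `ligand`, `route`, `components` (signed pieces), `numerator`,
#'   `denominator`.
#' @export
operational_flux <- function(diagram, ligand,
                             route = c("cycles", "transitions"),
                             positive_direction = c("ext_to_int", "int_to_ext"),
                             probs = NULL, cycles = NULL) {
  route <- match.arg(route)
  positive_direction <- match.arg(positive_direction)
  known <- unique(stats::na.omit(diagram$edges$ligand))
  if (!ligand %in% known) stop("ligand without annotated binding edges: ", ligand)
  if (is.null(probs)) probs <- state_probability_expressions(diagram)
  numerator <- kpoly()
  components <- list()
  if (route == "cycles") {
    if (is.null(cycles)) cycles <- enumerate_cycles(diagram)
    contrib <- contributing_cycles(diagram, cycles, ligand, positive_direction)
    for (ct in contrib) {
      cf <- net_cycle_flux_expression(diagram, ct$cycle, sigma = probs$sigma)
      numerator <- kp_add(numerator, kp_mul(cf$numerator, ct$coefficient))
      components[[length(components) + 1L]] <-
        list(label = paste(ct$cycle$nodes, collapse = ","),
             coefficient = ct$coefficient, expression = cf)
    }
  } else {
    side <- if (positive_direction == "ext_to_int") "int" else "ext"
    ed <- .unbinding_edges(diagram, ligand, side)
    if (nrow(ed) == 0L) {
      stop("no annotated ", side, "-side unbinding transitions for ligand ",
           ligand)
    }
    for (q in seq_len(nrow(ed))) {
      tf <- net_transition_flux_expression(diagram, ed[q, 1], ed[q, 2],
                                           probs = probs)
      numerator <- kp_add(numerator, tf$numerator)
      components[[length(components) + 1L]] <-
        list(label = paste0("J_", ed[q, 1], ",", ed[q, 2]),
             coefficient = 1, expression = tf)
    }
  }
  structure(list(ligand = ligand, route = route,
                 positive_direction = positive_direction,
                 components = components,
                 numerator = numerator, denominator = probs$sigma),
            class = "operational_flux_expression")
}

#' @export
print.operational_flux_expression <- function(x, ...) {
  cat("<operational_flux_expression> J_", x$ligand, " via ", x$route, ": ",
      length(x$components), " signed component(s)\n", sep = "")
  invisible(x)
}

.as_ratio <- function(x) {
  if (kp_is(x)) return(list(num = x, den = kp_const(1)))
  if (is.list(x) && !is.null(x$numerator)) {
    den <- if (is.null(x$denominator)) kp_const(1) else x$denominator
    return(list(num = x$numerator, den = den))
  }
  if (is.numeric(x) && length(x) == 1L) {
    return(list(num = kp_const(x), den = kp_const(1)))
  }
  stop("cannot interpret object of class ", class(x)[1], " as an expression")
}

#' Prove two expressions equal
#'
#' Expressions (polynomials or rational flux/probability expressions) are
#' compared exactly: equal denominators reduce the check to an exact
#' polynomial identity on numerators, otherwise cross-multiplication is
#' used. If a finite `time_budget` is given and the estimated
#' cross-multiplication size is too large for it, the check falls back to
#' evaluation at `n_random` random positive rate points (relative tolerance
#' `tol`) and the result carries `attr(, "proof") == "numeric"` instead of
#' `"symbolic"`.
#'
#' @param a,b expressions over the same symbol universe.
#' @param time_budget seconds allowed for the symbolic proof (default
#'   `Inf`).
#' @param n_random,tol numeric-fallback controls.
#' @param seed seed for the numeric fallback.
#' @return logical with attribute `proof` in `c("symbolic", "numeric")`.
#' @export
symbolically_equal <- function(a, b, time_budget = Inf, n_random = 50,
                               tol = 1e-9, seed = 1L) {
  ra <- .as_ratio(a); rb <- .as_ratio(b)
  same_den <- kp_equal(ra$den, rb$den)
  cost <- if (same_den) 0 else
    as.numeric(kp_n_terms(ra$num)) * kp_n_terms(rb$den) +
    as.numeric(kp_n_terms(rb$num)) * kp_n_terms(ra$den)
  if (is.finite(time_budget) && cost > 2e5 * time_budget) {
    syms <- sort(unique(c(kp_symbols(ra$num), kp_symbols(ra$den),
                          kp_symbols(rb$num), kp_symbols(rb$den))))
    fa_n <- kp_compile(ra$num, syms); fa_d <- kp_compile(ra$den, syms)
    fb_n <- kp_compile(rb$num, syms); fb_d <- kp_compile(rb$den, syms)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    ok <- TRUE
    for (q in seq_len(n_random)) {
      v <- stats::runif(length(syms), 0.1, 10)
      va <- fa_n(v) / fa_d(v)
      vb <- fb_n(v) / fb_d(v)
      if (abs(va - vb) > tol * max(abs(va), abs(vb), 1)) { ok <- FALSE; break }
    }
    return(structure(ok, proof = "numeric"))
  }
  res <- if (same_den) kp_equal(ra$num, rb$num) else
    kp_equal(kp_mul(ra$num, rb$den), kp_mul(rb$num, ra$den))
  structure(res, proof = "symbolic")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Substitute model parameters into an expression
#'
#' Applies a symbol map (rate symbol -> polynomial in model parameters,
#' e.g. an intrinsic on-rate times a concentration symbol for
#' pseudo-first-order edges) to a polynomial or to every polynomial field
#' of a rational expression object. Unmapped symbols pass through.
#'
#' @param x a `kpoly` or any expression object of this package.
#' @param map named list of replacements (see [kp_substitute()]).
#' @return object of the same shape with substituted polynomials.
#' @export
substitute_rates <- function(x, map) {
  if (kp_is(x)) return(kp_substitute(x, map))
  if (is.list(x)) {
    for (f in c("numerator", "denominator", "sigma", "sigma_K",
                "pi_plus", "pi_minus")) {
      if (!is.null(x[[f]]) && kp_is(x[[f]])) x[[f]] <- kp_substitute(x[[f]], map)
    }
    if (!is.null(x$omega)) x$omega <- lapply(x$omega, kp_substitute, map = map)
    return(x)
  }
  stop("cannot substitute into object of class ", class(x)[1])
}

#' Compile an expression for fast numeric evaluation
#'
#' All free symbols must be covered by `symbol_order` (missing symbols error
#' at compile time). The returned evaluator takes a numeric vector in that
#' order; for rational expressions it returns numerator/denominator.
#'
#' @param x a `kpoly` or rational expression object.
#' @param symbol_order character vector of symbol names.
#' @return function(numeric) -> numeric.
#' @export
compile_numeric <- function(x, symbol_order) {
  r <- .as_ratio(x)
  fn <- kp_compile(r$num, symbol_order)
  fd <- kp_compile(r$den, symbol_order)
  function(values) fn(values) / fd(values)
}

#' Compile all state probabilities of an expression set
#'
#' @param probs a `rate_expression_set`.
#' @param symbol_order character vector of symbol names.
#' @return function(numeric) -> numeric vector of probabilities (sums to 1).
#' @export
compile_state_probabilities <- function(probs, symbol_order) {
  fo <- lapply(probs$omega, kp_compile, symbol_order = symbol_order)
  fs <- kp_compile(probs$sigma, symbol_order)
  function(values) {
    om <- vapply(fo, function(f) f(values), numeric(1))
    om / fs(values)
  }
}
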