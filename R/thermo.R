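#' Kinetic cycle closure residual
#'
#' Thermodynamic consistency (the Wegscheider condition) requires the
#' product of *intrinsic* (concentration-stripped) forward rates around any
#' cycle to equal the product of the intrinsic reverse rates. The residual
#' `ln(Pi_plus / Pi_minus)` is zero for a consistent rate set; kT = 1
#' throughout, so residuals and driving forces are in kT units.
#'
#' @param diagram a `kinetic_diagram`.
#' @param intrinsic_rates named numeric vector (rate symbol -> intrinsic
#'   rate, i.e. second-order on-rates without their concentration factor).
#' @param cycle a `kcycle`.
#' @return numeric residual in kT units.
#' @export
closure_residual <- function(diagram, intrinsic_rates, cycle) {
  nodes <- .check_cycle(diagram, cycle$nodes)
  nxt <- c(nodes[-1], nodes[1])
  lr <- 0
  for (q in seq_along(nodes)) {
    kf <- intrinsic_rates[[rate_symbol(diagram, nodes[q], nxt[q])]]
    kr <- intrinsic_rates[[rate_symbol(diagram, nxt[q], nodes[q])]]
    if (is.null(kf) || is.null(kr) || is.na(kf) || is.na(kr)) {
      stop("missing intrinsic rate on cycle edge ", nodes[q], "-", nxt[q])
    }
    if (kf <= 0 || kr <= 0) stop("nonpositive intrinsic rate")
    lr <- lr + log(kf) - log(kr)
  }
  lr
}

#' Chemical driving force of a cycle
#'
#' `chi = ln(X_plus / X_minus)` in kT units, where `X_plus` (`X_minus`) is
#' the product of the excess-reactant concentrations on the
#' pseudo-first-order edges traversed along (against) the cycle's positive
#' direction. Zero when all paired concentrations are equal (equilibrium).
#'
#' @param diagram a `kinetic_diagram` whose order-2 edges carry
#'   concentration symbols.
#' @param cycle a `kcycle`.
#' @param concentrations named numeric vector (concentration symbol ->
#'   molar value).
#' @return numeric driving force in kT units.
#' @export
driving_force <- function(diagram, cycle, concentrations) {
  nodes <- .check_cycle(diagram, cycle$nodes)
  nxt <- c(nodes[-1], nodes[1])
  chi <- 0
  grab <- function(from, to, sgn) {
    row <- diagram$edges[.edge_row(diagram, from, to), ]
    if (row$order == 2L) {
      if (is.na(row$concentration)) {
        stop("order-2 edge ", from, "->", to, " lacks a concentration symbol")
      }
      idx <- match(row$concentration, names(concentrations))
      if (is.na(idx) || is.na(concentrations[[idx]])) {
        stop("missing concentration: ", row$concentration)
      }
      cc <- concentrations[[idx]]
      if (cc <= 0) stop("nonpositive concentration: ", row$concentration)
      chi <<- chi + sgn * log(cc)
    }
  }
  for (q in seq_along(nodes)) {
    grab(nodes[q], nxt[q], +1)
    grab(nxt[q], nodes[q], -1)
  }
  chi
}

#' Convert pH to a proton concentration
#'
#' `[H+] = 10^(-pH)` in molar units; applied at substitution time wherever a
#' fixture takes pH inputs.
#'
#' @param pH numeric.
#' @return molar concentration.
#' @export
ph_to_concentration <- function(pH) 10^(-pH)

#' Generate a random detailed-balanced kinetic diagram
#'
#' Samples an Erdos-Renyi graph at the requested edge density (resampling
#' until connected), draws node potentials `u_i ~ U(-3, 3)` and symmetric
#' edge barriers `b_ij ~ U(0, 3)`, and sets `k_ij = exp(u_i - b_ij)`. The
#' construction satisfies detailed balance `k_ij / k_ji = exp(u_j - u_i)`
#' inverted appropriately, has stationary distribution proportional to
#' `exp(-u_i)` (Boltzmann weights), and every cycle closure residual is zero
#' to machine precision. Identical seeds give identical output.
#'
#' @param n_states number of states (>= 3).
#' @param edge_density Erdos-Renyi edge probability.
#' @param seed integer seed.
#' @param max_tries resampling attempts before giving up.
#' @return list with fields `diagram` (rates set as edge values), `rates`
#'   (named numeric), `potentials` (named by state), `barriers` (named by
#'   transition "i-j"), `seed`.
#' @export
generate_equilibrium_diagram <- function(n_states, edge_density = 0.3,
                                         seed = 1L, max_tries = 1000L) {
  stopifnot(n_states >= 3)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  pairs <- utils::combn(n_states, 2L)
  edges <- NULL
  for (try in seq_len(max_tries)) {
    sel <- stats::runif(ncol(pairs)) < edge_density
    if (sum(sel) < n_states - 1L) next
    cand <- data.frame(from = as.character(pairs[1, sel]),
                       to = as.character(pairs[2, sel]),
                       stringsAsFactors = FALSE)
    cand <- rbind(cand, data.frame(from = cand$to, to = cand$from))
    d <- tryCatch(kinetic_diagram(cand, states = as.character(seq_len(n_states))),
                  error = function(e) NULL)
    if (!is.null(d)) { edges <- d; break }
  }
  if (is.null(edges)) {
    stop("could not sample a connected diagram at density ", edge_density)
  }
  d <- edges
  u <- stats::runif(n_states, -3, 3)
  names(u) <- d$states
  tr <- transitions(d)
  b <- stats::runif(nrow(tr), 0, 3)
  names(b) <- paste(tr$i, tr$j, sep = "-")
  vals <- numeric(nrow(d$edges))
  for (q in seq_len(nrow(d$edges))) {
    from <- d$edges$from[q]; to <- d$edges$to[q]
    key <- if (match(from, d$states) < match(to, d$states))
      paste(from, to, sep = "-") else paste(to, from, sep = "-")
    vals[q] <- exp(u[[from]] - b[[key]])
  }
  d$edges$value <- vals
  list(diagram = d,
       rates = stats::setNames(vals, d$edges$rate),
       potentials = u, barriers = b, seed = seed)
}
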