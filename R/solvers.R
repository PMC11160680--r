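#' Numerical steady state of the master equations
#'
#' The master equations `dp_i/dt = sum_j (k_ji p_j - k_ij p_i)` are linear,
#' `dp/dt = A p` with `A[i,j] = k_ji` off-diagonal and
#' `A[i,i] = -sum_j k_ij`. For a connected diagram with positive rates A has
#' rank N-1; the solvers return the unique probability vector in its null
#' space.
#'
#' @name solvers
NULL

.rate_matrix <- function(diagram, rates) {
  n <- n_states(diagram)
  if (is.null(rates)) rates <- rate_values(diagram)
  k <- rates[diagram$edges$rate]
  if (anyNA(k)) stop("missing numeric rate value(s)")
  if (any(!is.finite(k)) || any(k <= 0)) stop("rates must be positive and finite")
  A <- matrix(0, n, n)
  fi <- match(diagram$edges$from, diagram$states)
  ti <- match(diagram$edges$to, diagram$states)
  for (q in seq_along(k)) {
    A[ti[q], fi[q]] <- A[ti[q], fi[q]] + k[q]
    A[fi[q], fi[q]] <- A[fi[q], fi[q]] - k[q]
  }
  A
}

.steady_state_obj <- function(diagram, p, method, A) {
  p <- as.numeric(p)
  names(p) <- diagram$states
  structure(list(p = p, method = method,
                 diagnostics = list(max_dpdt = max(abs(A %*% p)),
                                    norm_error = abs(sum(p) - 1))),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat("<steady_state> (", x$method, ") p = ",
      paste(format(x$p, digits = 6), collapse = ", "),
      "  max|dp/dt| = ", format(x$diagnostics$max_dpdt, digits = 3), "\n",
      sep = "")
  invisible(x)
}

#' Steady state by direct linear solve
#'
#' Singular value decomposition identifies the one linearly dependent master
#' equation (singular values below `1e-12` times the largest mark the rank
#' deficiency); that row is replaced by the probability normalization
#' constraint and the resulting full-rank system is solved directly.
#'
#' @param diagram a `kinetic_diagram`.
#' @param rates named numeric vector (rate symbol -> value); defaults to the
#'   values stored on the diagram.
#' @return object of class `steady_state`.
#' @export
steady_state_matrix <- function(diagram, rates = NULL) {
  A <- .rate_matrix(diagram, rates)
  n <- nrow(A)
  sv <- svd(A)
  tiny <- sv$d < 1e-12 * max(sv$d)
  if (sum(tiny) != 1L) {
    stop("rate matrix rank deficiency is ", sum(tiny),
         " (expected 1); is the diagram connected with positive rates?")
  }
  # the left singular vector of the tiny singular value identifies the
  # dependent equation; replace the row where it loads most
  drop_row <- which.max(abs(sv$u[, n]))
  M <- A
  M[drop_row, ] <- 1
  rhs <- rep(0, n)
  rhs[drop_row] <- 1
  p <- solve(M, rhs)
  .steady_state_obj(diagram, p, "matrix", A)
}

#' Steady state by integrating the master equations
#'
#' Uses matrix-exponential stepping `p(t + dt) = expm(A dt) p(t)` with
#' doubling step sizes, which is exact for the linear master equations and
#' unconditionally stable (so stiffness, the usual difficulty of chemical
#' kinetics ODEs, poses no problem). Integration stops once
#' `max |dp_i/dt| < tol`; exceeding `horizon` raises an error carrying the
#' diagnostics.
#'
#' @param diagram a `kinetic_diagram`.
#' @param rates named numeric rates (default: stored edge values).
#' @param p0 initial probabilities on the simplex (default uniform).
#' @param horizon maximum integration time.
#' @param tol convergence tolerance on `max |dp_i/dt|`. For stiff rate sets
#'   the attainable residual floor is the matrix norm times machine epsilon,
#'   so integration also stops once the iteration reaches a fixed point to
#'   machine precision (the steady state of the exact propagator).
#' @return object of class `steady_state`.
#' @export
steady_state_ode <- function(diagram, rates = NULL, p0 = NULL,
                             horizon = 1e15, tol = 1e-12) {
  A <- .rate_matrix(diagram, rates)
  n <- nrow(A)
  if (is.null(p0)) p0 <- rep(1 / n, n)
  if (length(p0) != n) stop("p0 has wrong length")
  if (any(p0 < 0) || abs(sum(p0) - 1) > 1e-9) stop("p0 must lie on the simplex")
  p <- as.numeric(p0)
  t <- 0
  dt <- 0.1 / max(abs(diag(A)))
  # one short-time propagator, then repeated squaring of the propagator;
  # columns are renormalized after each squaring (the exact propagator is
  # column-stochastic) so probability is conserved even for stiff rate sets
  P <- as.matrix(Matrix::expm(Matrix::Matrix(A * dt)))
  P <- sweep(P, 2, colSums(P), "/")
  while (max(abs(A %*% p)) >= tol) {
    if (t > horizon) {
      stop("steady_state_ode did not converge within horizon; max|dp/dt| = ",
           format(max(abs(A %*% p)), digits = 4), " at t = ", format(t))
    }
    p_new <- as.numeric(P %*% p)
    delta <- max(abs(p_new - p))
    p <- p_new
    t <- t + dt
    dt <- dt * 2
    P <- P %*% P
    P <- sweep(P, 2, colSums(P), "/")
    if (delta < 1e-15) break  # fixed point reached to machine precision
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop("probability not conserved during integration")
  }
  .steady_state_obj(diagram, p, "ode", A)
}

#' Steady state from compiled symbolic expressions
#'
#' Convenience wrapper evaluating the diagram-method probability expressions
#' at numeric rates; the counterpart of the numeric solvers for
#' cross-validation.
#'
#' @param diagram a `kinetic_diagram`.
#' @param rates named numeric rates (default: stored edge values).
#' @param probs optional precomputed [state_probability_expressions()].
#' @return object of class `steady_state` with method `"symbolic"`.
#' @export
steady_state_symbolic <- function(diagram, rates = NULL, probs = NULL) {
  if (is.null(rates)) rates <- rate_values(diagram)
  if (is.null(probs)) probs <- state_probability_expressions(diagram)
  f <- compile_state_probabilities(probs, names(rates))
  A <- .rate_matrix(diagram, rates)
  .steady_state_obj(diagram, f(rates), "symbolic", A)
}

#' Root-mean-square deviation between probability vectors
#' @param pA,pB numeric vectors of equal length.
#' @return nonnegative scalar; zero iff identical.
#' @export
rmsd <- function(pA, pB) {
  if (length(pA) != length(pB)) stop("length mismatch")
  sqrt(mean((pA - pB)^2))
}

#' Numeric net transition flux at steady state
#'
#' @param diagram a `kinetic_diagram`.
#' @param rates named numeric rates.
#' @param p steady-state probabilities named by state.
#' @param from,to state labels.
#' @return numeric `k_ij p_i - k_ji p_j`.
#' @export
transition_flux_value <- function(diagram, rates, p, from, to) {
  kij <- rates[[rate_symbol(diagram, from, to)]]
  kji <- rates[[rate_symbol(diagram, to, from)]]
  kij * p[[as.character(from)]] - kji * p[[as.character(to)]]
}
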