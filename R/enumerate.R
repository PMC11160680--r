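#' Count spanning trees by the matrix-tree theorem
#'
#' Returns the determinant of an (N-1)x(N-1) principal minor of the
#' undirected graph Laplacian, i.e. the number of partial diagrams
#' (spanning trees) of the kinetic diagram. Serves as the independent
#' oracle for [enumerate_partial_diagrams()].
#'
#' @param diagram a `kinetic_diagram`.
#' @return positive integer.
#' @export
kirchhoff_count <- function(diagram) {
  n <- n_states(diagram)
  if (n == 1L) return(1L)
  tr <- transitions(diagram)
  ii <- match(tr$i, diagram$states)
  jj <- match(tr$j, diagram$states)
  L <- matrix(0, n, n)
  for (k in seq_along(ii)) {
    L[ii[k], jj[k]] <- L[ii[k], jj[k]] - 1
    L[jj[k], ii[k]] <- L[jj[k], ii[k]] - 1
    L[ii[k], ii[k]] <- L[ii[k], ii[k]] + 1
    L[jj[k], jj[k]] <- L[jj[k], jj[k]] + 1
  }
  as.integer(round(det(L[-1, -1, drop = FALSE])))
}

#' Enumerate partial diagrams (spanning trees)
#'
#' "Test and select": all combinations of N-1 transitions are generated in
#' lexicographic order over the canonical transition list and each is kept
#' iff it is a spanning tree (covers all states and is acyclic). The result
#' count always equals [kirchhoff_count()] and the output order is
#' deterministic.
#'
#' @param diagram a `kinetic_diagram`.
#' @return list of `partial_diagram` objects, each with an `edges`
#'   data.frame of unordered state pairs (`i`, `j`).
#' @export
enumerate_partial_diagrams <- function(diagram) {
  n <- n_states(diagram)
  tr <- transitions(diagram)
  m <- nrow(tr)
  ii <- match(tr$i, diagram$states)
  jj <- match(tr$j, diagram$states)
  if (n == 1L) return(list())
  combos <- utils::combn(m, n - 1L)
  keep <- vector("list", ncol(combos))
  cnt <- 0L
  for (c0 in seq_len(ncol(combos))) {
    sel <- combos[, c0]
    # union-find acyclicity + coverage check
    parent <- seq_len(n)
    find <- function(x) {
      while (parent[x] != x) {
        parent[x] <<- parent[parent[x]]
        x <- parent[x]
      }
      x
    }
    ok <- TRUE
    for (e in sel) {
      a <- find(ii[e]); b <- find(jj[e])
      if (a == b) { ok <- FALSE; break }
      parent[a] <- b
    }
    if (ok) {
      cnt <- cnt + 1L
      keep[[cnt]] <- sel
    }
  }
  keep <- keep[seq_len(cnt)]
  lapply(keep, function(sel) {
    structure(list(edges = tr[sel, , drop = FALSE],
                   transition_index = sel),
              class = "partial_diagram")
  })
}

#' @export
print.partial_diagram <- function(x, ...) {
  cat("<partial_diagram> edges:",
      paste(paste0(x$edges$i, "-", x$edges$j), collapse = ", "), "\n")
  invisible(x)
}

# orient a spanning tree toward `target` (state index); returns integer
# parent vector over state indices (parent of target = NA)
.orient_tree <- function(n, ei, ej, target) {
  adj <- vector("list", n)
  for (k in seq_along(ei)) {
    adj[[ei[k]]] <- c(adj[[ei[k]]], ej[k])
    adj[[ej[k]]] <- c(adj[[ej[k]]], ei[k])
  }
  parent <- rep(NA_integer_, n)
  seen <- logical(n)
  seen[target] <- TRUE
  queue <- target
  while (length(queue) > 0L) {
    v <- queue[1L]
    queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        parent[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  parent
}

#' Enumerate directional diagrams
#'
#' Each partial diagram yields one directional diagram per target state by
#' orienting every tree edge along the unique path toward the target. The
#' rate-product of a directional diagram (the product of `k_from_to` over
#' its directed edges) is one additive term of the target state's
#' unnormalized probability.
#'
#' @param diagram a `kinetic_diagram`.
#' @param partials optional precomputed [enumerate_partial_diagrams()] output.
#' @return list of `directional_diagram` objects ordered partial-major then
#'   by target state; fields: `target`, `edges` (directed `from`/`to`),
#'   `rates` (character vector, the rate-product), `parent` (partial index).
#' @export
enumerate_directional_diagrams <- function(diagram,
                                           partials = enumerate_partial_diagrams(diagram)) {
  n <- n_states(diagram)
  states <- diagram$states
  out <- vector("list", n * length(partials))
  k <- 0L
  for (pidx in seq_along(partials)) {
    pd <- partials[[pidx]]
    ei <- match(pd$edges$i, states)
    ej <- match(pd$edges$j, states)
    for (t in seq_len(n)) {
      parent <- .orient_tree(n, ei, ej, t)
      vs <- setdiff(seq_len(n), t)
      from <- states[vs]
      to <- states[parent[vs]]
      rates <- vapply(seq_along(vs),
                      function(q) rate_symbol(diagram, from[q], to[q]),
                      character(1))
      k <- k + 1L
      out[[k]] <- structure(list(target = states[t],
                                 edges = data.frame(from = from, to = to,
                                                    stringsAsFactors = FALSE),
                                 rates = sort(rates),
                                 parent = pidx),
                            class = "directional_diagram")
    }
  }
  out
}

#' @export
print.directional_diagram <- function(x, ...) {
  cat("<directional_diagram> target ", x$target, ": ",
      paste(x$rates, collapse = "*"), "\n", sep = "")
  invisible(x)
}

.check_cycle <- function(diagram, target_cycle) {
  nodes <- as.character(target_cycle)
  if (length(nodes) < 3L) stop("a cycle needs at least 3 states")
  if (anyDuplicated(nodes)) stop("cycle nodes must be distinct")
  if (!all(nodes %in% diagram$states)) stop("cycle references unknown state")
  nxt <- c(nodes[-1L], nodes[1L])
  key <- paste(diagram$edges$from, diagram$edges$to, sep = "\r")
  if (!all(paste(nodes, nxt, sep = "\r") %in% key)) {
    stop("target_cycle is not a cycle of the diagram")
  }
  nodes
}

#' Enumerate flux diagrams for a target cycle
#'
#' A flux diagram consists of the target cycle (kept bidirectional) plus one
#' outgoing directed feeder edge per non-cycle state, such that following
#' feeder edges from any state reaches the cycle (no second loop). The sum
#' over flux diagrams of the feeder rate-products is the cycle's
#' multiplicity factor `Sigma_K`; for a Hamiltonian target cycle the list is
#' empty and `Sigma_K = 1`.
#'
#' @param diagram a `kinetic_diagram`.
#' @param target_cycle ordered vector of state labels forming a simple cycle.
#' @return list of `flux_diagram` objects; fields: `target_cycle`, `feeder`
#'   (directed `from`/`to` data.frame) and `rates` (feeder rate-product).
#' @export
enumerate_flux_diagrams <- function(diagram, target_cycle) {
  nodes <- .check_cycle(diagram, target_cycle)
  states <- diagram$states
  n <- n_states(diagram)
  cyc_idx <- match(nodes, states)
  outside <- setdiff(seq_len(n), cyc_idx)
  if (length(outside) == 0L) return(list())
  adj <- .adjacency(diagram)
  choices <- lapply(outside, function(v) adj[[v]])
  # cartesian product over per-vertex outgoing-edge choices, in order
  counts <- lengths(choices)
  total <- prod(counts)
  on_cycle <- logical(n)
  on_cycle[cyc_idx] <- TRUE
  out <- list()
  pick <- rep(1L, length(outside))
  for (iter in seq_len(total)) {
    succ <- rep(NA_integer_, n)
    for (q in seq_along(outside)) succ[outside[q]] <- choices[[q]][pick[q]]
    # acyclicity: walk from each outside vertex; must reach the cycle
    ok <- TRUE
    for (v in outside) {
      cur <- v
      steps <- 0L
      while (!on_cycle[cur]) {
        cur <- succ[cur]
        steps <- steps + 1L
        if (steps > n) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) {
      from <- states[outside]
      to <- states[succ[outside]]
      rates <- vapply(seq_along(outside),
                      function(q) rate_symbol(diagram, from[q], to[q]),
                      character(1))
      out[[length(out) + 1L]] <-
        structure(list(target_cycle = nodes,
                       feeder = data.frame(from = from, to = to,
                                           stringsAsFactors = FALSE),
                       rates = sort(rates)),
                  class = "flux_diagram")
    }
    # advance mixed-radix counter
    q <- length(pick)
    while (q >= 1L) {
      pick[q] <- pick[q] + 1L
      if (pick[q] <= counts[q]) break
      pick[q] <- 1L
      q <- q - 1L
    }
  }
  out
}

#' @export
print.flux_diagram <- function(x, ...) {
  cat("<flux_diagram> cycle (", paste(x$target_cycle, collapse = ","),
      ") feeders: ", paste(x$rates, collapse = "*"), "\n", sep = "")
  invisible(x)
}

#' Feeder multiplicity factor of a cycle
#'
#' @param diagram a `kinetic_diagram`.
#' @param target_cycle ordered state labels.
#' @param flux_diagrams optional precomputed [enumerate_flux_diagrams()]
#'   output.
#' @return a `kpoly`: sum of feeder rate-products, or the constant 1 when
#'   there are no flux diagrams.
#' @export
flux_sigma <- function(diagram, target_cycle,
                       flux_diagrams = enumerate_flux_diagrams(diagram, target_cycle)) {
  if (length(flux_diagrams) == 0L) return(kp_const(1))
  acc <- kpoly()
  for (fd in flux_diagrams) acc <- kp_add(acc, kp_monomial(fd$rates))
  acc
}
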