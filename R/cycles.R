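#' Kinetic cycles
#'
#' A cycle is stored as its ordered node sequence; traversing the sequence
#' (and closing back to the first node) is the cycle's *positive* direction.
#' The positive direction of a cycle is declared by an ordered node pair
#' (two consecutive cycle nodes) rather than a figure-dependent
#' "counter-clockwise" convention, which is undefined for non-planar
#' diagrams.
#'
#' @param nodes ordered state labels (length >= 3).
#' @return object of class `kcycle`.
#' @export
kcycle <- function(nodes) {
  nodes <- as.character(nodes)
  if (length(nodes) < 3L) stop("a cycle needs at least 3 states")
  if (anyDuplicated(nodes)) stop("cycle nodes must be distinct")
  structure(list(nodes = nodes), class = "kcycle")
}

#' @export
print.kcycle <- function(x, ...) {
  cat("<kcycle> ", paste(x$nodes, collapse = " -> "), " -> ",
      x$nodes[1], "\n", sep = "")
  invisible(x)
}

#' Declare the positive direction of a cycle
#'
#' Rotates/reflects the stored node sequence so that traversal runs through
#' `pair[1]` immediately followed by `pair[2]`.
#'
#' @param cycle a `kcycle`.
#' @param pair ordered vector of two adjacent cycle nodes.
#' @return the reoriented `kcycle`.
#' @export
orient_cycle <- function(cycle, pair) {
  pair <- as.character(pair)
  nodes <- cycle$nodes
  i <- match(pair[1], nodes)
  if (is.na(i) || !pair[2] %in% nodes) stop("orientation pair not in cycle")
  fwd <- c(nodes[i:length(nodes)], nodes[seq_len(i - 1L)])
  if (fwd[2] == pair[2]) return(kcycle(fwd))
  bwd <- c(fwd[1], rev(fwd[-1]))
  if (bwd[2] == pair[2]) return(kcycle(bwd))
  stop("orientation pair is not a consecutive pair of the cycle")
}

#' Reverse a cycle's positive direction
#' @param cycle a `kcycle`.
#' @return the reversed `kcycle`.
#' @export
reverse_cycle <- function(cycle) {
  kcycle(c(cycle$nodes[1], rev(cycle$nodes[-1])))
}

.canonical_cycle <- function(nodes, state_order) {
  idx <- match(nodes, state_order)
  start <- which.min(idx)
  fwd <- c(nodes[start:length(nodes)], nodes[seq_len(start - 1L)])
  bwd <- c(fwd[1], rev(fwd[-1]))
  if (match(bwd[2], state_order) < match(fwd[2], state_order)) bwd else fwd
}

#' Enumerate all simple cycles of a kinetic diagram
#'
#' Each undirected simple cycle is reported exactly once, in canonical form:
#' the lowest-indexed state first, followed by the lower-indexed of its two
#' cycle neighbors. Output is sorted by cycle length, then lexicographically
#' by node indices, so enumeration is deterministic.
#'
#' @param diagram a `kinetic_diagram`.
#' @return list of `kcycle` objects.
#' @export
enumerate_cycles <- function(diagram) {
  n <- n_states(diagram)
  adj <- .adjacency(diagram)
  states <- diagram$states
  found <- list()
  path <- integer(0)
  on_path <- logical(n)
  dfs <- function(v, start) {
    path[length(path) + 1L] <<- v
    on_path[v] <<- TRUE
    for (w in adj[[v]]) {
      if (w == start && length(path) >= 3L) {
        # avoid reporting each cycle twice (two traversal directions)
        if (path[2] < path[length(path)]) {
          found[[length(found) + 1L]] <<- path
        }
      } else if (w > start && !on_path[w]) {
        dfs(w, start)
      }
    }
    on_path[v] <<- FALSE
    path <<- path[-length(path)]
  }
  for (s in seq_len(n)) dfs(s, s)
  ord <- order(lengths(found),
               vapply(found, function(p) paste(sprintf("%06d", p), collapse = ","),
                      character(1)))
  lapply(found[ord], function(p) kcycle(states[p]))
}

#' Net transport signature of a cycle
#'
#' Walks the cycle once in its positive direction and accumulates, per
#' ligand, the net number of molecules moved from the external to the
#' internal side: +1 for each external binding, -1 for each external
#' unbinding (internal events are implied by conservation, since every
#' molecule bound during a completion is also released).
#'
#' @param diagram a `kinetic_diagram` with ligand/side annotations on its
#'   binding and unbinding edges.
#' @param cycle a `kcycle`.
#' @return named integer vector (one entry per annotated ligand of the
#'   diagram); positive counts mean net ext -> int transport per positive
#'   cycle completion.
#' @export
classify_cycle_transport <- function(diagram, cycle) {
  .check_cycle(diagram, cycle$nodes)
  ligands <- sort(unique(stats::na.omit(diagram$edges$ligand)))
  sig <- stats::setNames(integer(length(ligands)), ligands)
  nodes <- cycle$nodes
  nxt <- c(nodes[-1], nodes[1])
  for (q in seq_along(nodes)) {
    row <- diagram$edges[.edge_row(diagram, nodes[q], nxt[q]), ]
    if (!row$process %in% c("binding", "unbinding")) next
    if (is.na(row$ligand) || row$side == "none") {
      stop("binding/unbinding edge ", row$from, "->", row$to,
           " lacks ligand or side annotation")
    }
    delta <- if (row$side == "ext") 1L else 0L
    if (row$process == "unbinding") delta <- -delta
    sig[row$ligand] <- sig[row$ligand] + delta
  }
  sig
}

#' Cycles contributing to a ligand's operational flux
#'
#' Selects the cycles with nonzero net transport of `ligand` and signs each
#' by agreement between its transport signature and the declared positive
#' transport direction. The coefficient is the signed molecule count per
#' positive completion (usually +1 or -1).
#'
#' @param diagram a `kinetic_diagram`.
#' @param cycles list of `kcycle` objects (e.g. [enumerate_cycles()]).
#' @param ligand ligand label.
#' @param positive_direction direction counted as positive operational flux:
#'   `"ext_to_int"` or `"int_to_ext"`.
#' @return list of entries `list(cycle = , coefficient = )`.
#' @export
contributing_cycles <- function(diagram, cycles, ligand,
                                positive_direction = c("ext_to_int", "int_to_ext")) {
  positive_direction <- match.arg(positive_direction)
  known <- unique(stats::na.omit(diagram$edges$ligand))
  if (!ligand %in% known) stop("unknown ligand: ", ligand)
  out <- list()
  for (cy in cycles) {
    sig <- classify_cycle_transport(diagram, cy)[[ligand]]
    if (sig == 0L) next
    coefficient <- if (positive_direction == "ext_to_int") sig else -sig
    out[[length(out) + 1L]] <- list(cycle = cy, coefficient = coefficient)
  }
  out
}
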