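#' Kinetic diagrams
#'
#' A kinetic diagram is a connected simple graph whose nodes are discrete
#' biochemical states and whose edges are reversible transitions. Each
#' directed edge i->j carries a rate symbol (canonically `k_<i>_<j>`),
#' optionally a numeric value, and optional annotations used for transport
#' bookkeeping and thermodynamics:
#' \describe{
#'   \item{process}{`"binding"`, `"unbinding"`, `"conformational"` or
#'     `"leakage"`; a binding edge i->j implies its reverse is unbinding.}
#'   \item{ligand}{ligand label for binding/unbinding edges.}
#'   \item{side}{membrane side the ligand comes from / goes to:
#'     `"ext"`, `"int"` or `"none"`.}
#'   \item{order}{reaction order: 2 for a pseudo-first-order binding step
#'     whose rate is an intrinsic on-rate times a held-fixed concentration,
#'     else 1.}
#'   \item{concentration}{concentration symbol for order-2 edges.}
#' }
#'
#' @param edges data.frame with columns `from`, `to` and optionally `rate`,
#'   `value`, `process`, `ligand`, `side`, `order`, `concentration`. One row
#'   per directed edge; every edge must be declared in both directions.
#' @param states optional ordered vector of state labels; defaults to the
#'   sorted labels appearing in `edges`.
#' @return an object of class `kinetic_diagram`.
#' @export
kinetic_diagram <- function(edges, states = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to") %in% names(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (is.null(states)) {
    labs <- unique(c(edges$from, edges$to))
    num <- suppressWarnings(as.numeric(labs))
    states <- if (!anyNA(num)) labs[order(num)] else sort(labs)
  } else {
    states <- as.character(states)
  }
  if (anyDuplicated(states)) stop("duplicate state labels")
  unknown <- setdiff(c(edges$from, edges$to), states)
  if (length(unknown) > 0L) stop("edge references unknown state: ",
                                 paste(unknown, collapse = ", "))

  defaults <- list(rate = NA_character_, value = NA_real_,
                   process = "conformational", ligand = NA_character_,
                   side = "none", order = 1L, concentration = NA_character_)
  for (col in names(defaults)) {
    if (is.null(edges[[col]])) edges[[col]] <- defaults[[col]]
  }
  miss <- is.na(edges$rate) | edges$rate == ""
  edges$rate[miss] <- paste0("k_", edges$from[miss], "_", edges$to[miss])
  edges$order <- as.integer(edges$order)

  if (any(edges$from == edges$to)) stop("self-loop declared")
  key <- paste(edges$from, edges$to, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate edge declaration")
  rkey <- paste(edges$to, edges$from, sep = "\r")
  if (!all(rkey %in% key)) {
    bad <- edges[!(rkey %in% key), c("from", "to")]
    stop("missing reverse rate for transition(s): ",
         paste(paste0(bad$from, "->", bad$to), collapse = ", "))
  }
  if (!all(edges$process %in% c("binding", "unbinding", "conformational",
                                "leakage"))) {
    stop("unknown process annotation")
  }
  if (!all(edges$side %in% c("ext", "int", "none"))) stop("unknown side annotation")
  if (!all(edges$order %in% c(1L, 2L))) stop("reaction order must be 1 or 2")

  fi <- match(edges$from, states)
  ti <- match(edges$to, states)
  edges <- edges[order(fi, ti), , drop = FALSE]
  rownames(edges) <- NULL

  d <- structure(list(states = states, edges = edges), class = "kinetic_diagram")
  if (!.is_connected(d)) stop("kinetic diagram is disconnected")
  d
}

#' @export
print.kinetic_diagram <- function(x, ...) {
  cat("<kinetic_diagram> ", n_states(x), " states, ",
      nrow(transitions(x)), " reversible transitions\n", sep = "")
  invisible(x)
}

#' Number of states
#' @param diagram a `kinetic_diagram`.
#' @return integer.
#' @export
n_states <- function(diagram) length(diagram$states)

#' Reversible transitions as unordered pairs
#'
#' Pairs are reported with the lower-indexed state first, sorted
#' lexicographically by state index (the canonical edge enumeration order).
#'
#' @param diagram a `kinetic_diagram`.
#' @return data.frame with character columns `i`, `j`.
#' @export
transitions <- function(diagram) {
  fi <- match(diagram$edges$from, diagram$states)
  ti <- match(diagram$edges$to, diagram$states)
  keep <- fi < ti
  tr <- data.frame(i = diagram$edges$from[keep], j = diagram$edges$to[keep],
                   stringsAsFactors = FALSE)
  tr[order(match(tr$i, diagram$states), match(tr$j, diagram$states)), ,
     drop = FALSE] -> tr
  rownames(tr) <- NULL
  tr
}

.edge_row <- function(diagram, from, to) {
  hit <- which(diagram$edges$from == as.character(from) &
               diagram$edges$to == as.character(to))
  if (length(hit) != 1L) {
    stop("no transition ", from, " -> ", to, " in diagram")
  }
  hit
}

#' Rate symbol of a directed edge
#' @param diagram a `kinetic_diagram`.
#' @param from,to state labels.
#' @return character rate symbol.
#' @export
rate_symbol <- function(diagram, from, to) {
  diagram$edges$rate[.edge_row(diagram, from, to)]
}

#' Numeric rate values declared on the diagram
#' @param diagram a `kinetic_diagram`.
#' @return named numeric vector (rate symbol -> value), `NA` where absent.
#' @export
rate_values <- function(diagram) {
  stats::setNames(diagram$edges$value, diagram$edges$rate)
}

#' Replace numeric rate values
#' @param diagram a `kinetic_diagram`.
#' @param values named numeric vector keyed by rate symbol.
#' @return the updated diagram.
#' @export
set_rate_values <- function(diagram, values) {
  hit <- match(diagram$edges$rate, names(values))
  diagram$edges$value[!is.na(hit)] <- values[hit[!is.na(hit)]]
  diagram
}

# adjacency list over state indices (undirected)
.adjacency <- function(diagram) {
  n <- n_states(diagram)
  tr <- transitions(diagram)
  ii <- match(tr$i, diagram$states)
  jj <- match(tr$j, diagram$states)
  adj <- vector("list", n)
  for (k in seq_along(ii)) {
    adj[[ii[k]]] <- c(adj[[ii[k]]], jj[k])
    adj[[jj[k]]] <- c(adj[[jj[k]]], ii[k])
  }
  lapply(adj, sort)
}

.is_connected <- function(diagram) {
  n <- n_states(diagram)
  if (n <= 1L) return(TRUE)
  adj <- .adjacency(diagram)
  seen <- logical(n)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        stack <- c(stack, w)
      }
    }
  }
  all(seen)
}

#' Load a kinetic diagram from a rate matrix or an edge list
#'
#' A square matrix (numeric: nonzero entries are rates; character: nonempty
#' entries are rate symbols) defines directed edges by its nonzero pattern;
#' row/column names, if present, are the state labels. A data.frame is
#' interpreted as an edge list as in [kinetic_diagram()]. Every declared
#' edge must have its reverse declared (reversibility), otherwise an error
#' is raised.
#'
#' @param x square matrix or edge-list data.frame.
#' @return a `kinetic_diagram`.
#' @export
load_diagram <- function(x) {
  if (is.data.frame(x)) return(kinetic_diagram(x))
  if (is.matrix(x)) {
    if (nrow(x) != ncol(x)) stop("rate matrix must be square")
    labs <- rownames(x)
    if (is.null(labs)) labs <- as.character(seq_len(nrow(x)))
    present <- if (is.numeric(x)) x != 0 else !is.na(x) & x != ""
    idx <- which(present, arr.ind = TRUE)
    if (nrow(idx) == 0L) stop("rate matrix declares no edges")
    edges <- data.frame(from = labs[idx[, 1]], to = labs[idx[, 2]],
                        stringsAsFactors = FALSE)
    if (is.numeric(x)) {
      edges$value <- x[idx]
    } else {
      edges$rate <- x[idx]
    }
    return(kinetic_diagram(edges, states = labs))
  }
  stop("cannot interpret model description of class ", class(x)[1])
}

#' Read / write the JSON model format
#'
#' The JSON model file is
#' `{"states": [...], "edges": [{"from":, "to":, "rate":, "value":,
#' "process":, "ligand":, "side":, "order":, "concentration":}, ...]}`.
#' `write_model_json` / `read_model_json` round-trip a diagram exactly.
#'
#' @param path file path.
#' @return `read_model_json`: a `kinetic_diagram`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  kinetic_diagram(obj$edges, states = as.character(obj$states))
}

#' @rdname read_model_json
#' @param diagram a `kinetic_diagram`.
#' @export
write_model_json <- function(diagram, path) {
  obj <- list(states = diagram$states, edges = diagram$edges)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a CSV rate matrix
#'
#' Expects a header row and first column of state labels; empty or zero
#' cells mean "no edge".
#'
#' @param path file path.
#' @return a `kinetic_diagram`.
#' @export
read_rate_matrix_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labs <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  m[is.na(m)] <- 0
  rownames(m) <- labs
  colnames(m) <- as.character(colnames(tab)[-1])
  if (!identical(rownames(m), colnames(m))) {
    stop("rate matrix CSV row and column labels disagree")
  }
  load_diagram(m)
}
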