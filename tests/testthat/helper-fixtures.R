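# shared fixtures and independent oracles for the test suite

triangle_diagram <- function() {
  kinetic_diagram(data.frame(from = c(1, 2, 2, 3, 3, 1),
                             to   = c(2, 1, 3, 2, 1, 3)))
}

complete_diagram <- function(n) {
  pairs <- utils::combn(n, 2)
  kinetic_diagram(data.frame(from = c(pairs[1, ], pairs[2, ]),
                             to   = c(pairs[2, ], pairs[1, ])))
}

# random connected simple graph as a diagram, with positive random rates
random_diagram <- function(n, density, seed) {
  g <- generate_equilibrium_diagram(n, density, seed = seed)
  g$diagram
}

# Independent simple-cycle count oracle: for every vertex subset, count
# Hamiltonian cycles of the induced subgraph by direct permutation search.
# Exponential, fine for n <= 8; deliberately unrelated to the DFS-based
# enumerate_cycles() implementation.
oracle_count_cycles <- function(diagram) {
  n <- n_states(diagram)
  tr <- transitions(diagram)
  adj <- matrix(FALSE, n, n)
  ii <- match(tr$i, diagram$states)
  jj <- match(tr$j, diagram$states)
  adj[cbind(ii, jj)] <- TRUE
  adj[cbind(jj, ii)] <- TRUE
  total <- 0L
  lengths_found <- integer(0)
  for (size in 3:n) {
    subsets <- utils::combn(n, size)
    for (c0 in seq_len(ncol(subsets))) {
      S <- subsets[, c0]
      # count Hamiltonian cycles of induced subgraph: fix first vertex,
      # permute the rest, divide reflections by 2
      rest <- S[-1]
      perms <- function(v) {
        if (length(v) <= 1L) return(list(v))
        out <- list()
        for (q in seq_along(v)) {
          for (p in perms(v[-q])) out[[length(out) + 1L]] <- c(v[q], p)
        }
        out
      }
      cnt <- 0L
      for (p in perms(rest)) {
        path <- c(S[1], p)
        edges_ok <- all(adj[cbind(path, c(path[-1], path[1]))])
        if (edges_ok) cnt <- cnt + 1L
      }
      stopifnot(cnt %% 2L == 0L)
      total <- total + cnt %/% 2L
      lengths_found <- c(lengths_found, rep(size, cnt %/% 2L))
    }
  }
  list(total = total, lengths = lengths_found)
}

# memoized heavyweight EmrE symbolic machinery shared across test files
.emre_cache <- new.env(parent = emptyenv())
emre_machinery <- function() {
  if (is.null(.emre_cache$m)) {
    model <- build_emre()
    d <- model$diagram
    probs <- state_probability_expressions(d)
    cycles <- enumerate_cycles(d)
    .emre_cache$m <- list(model = model, diagram = d, probs = probs,
                          cycles = cycles)
  }
  .emre_cache$m
}
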