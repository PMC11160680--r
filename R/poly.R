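#' @title Sparse multilinear polynomials over rate symbols
#'
#' @description
#' Every expression produced by the diagram method -- unnormalized state
#' probabilities, cycle-flux numerators, the normalization factor -- is a sum
#' of products of distinct rate symbols with integer coefficients, i.e. a
#' sparse multilinear polynomial. After parameter substitution the terms stay
#' monomials (possibly with repeated symbols and real coefficients). A small
#' exact polynomial type is therefore sufficient for all symbolic work:
#' a `kpoly` is a named numeric vector whose names are canonical monomial
#' keys (symbols sorted and joined by `*`; the empty string is the constant
#' monomial) and whose values are the coefficients. Canonical keys make
#' addition, equality testing and printing deterministic and byte-stable.
#'
#' @name kpoly
NULL

.kp_canon_key <- function(symbols) {
  if (length(symbols) == 0L) return("")
  paste(sort(symbols), collapse = "*")
}

#' Construct a polynomial
#'
#' @param coef numeric coefficients, one per monomial.
#' @param monomials list of character vectors of symbol names (may be empty
#'   vectors for constant terms). Repeated symbols denote powers.
#' @return a `kpoly`.
#' @export
kpoly <- function(coef = numeric(), monomials = list()) {
  stopifnot(length(coef) == length(monomials))
  keys <- vapply(monomials, .kp_canon_key, character(1))
  kp_from_terms(coef, keys)
}

kp_from_terms <- function(coef, keys) {
  if (length(coef) == 0L) {
    x <- numeric(0)
    class(x) <- "kpoly"
    return(x)
  }
  agg <- rowsum(coef, group = keys, reorder = TRUE)
  x <- as.numeric(agg)
  names(x) <- rownames(agg)
  x <- x[x != 0]
  if (is.null(names(x))) names(x) <- character(0)
  class(x) <- "kpoly"
  x
}

#' Polynomial from a single symbol, or a numeric constant
#' @param sym symbol name.
#' @return a `kpoly`.
#' @export
kp_sym <- function(sym) kp_from_terms(1, sym)

#' @rdname kp_sym
#' @param value numeric constant.
#' @export
kp_const <- function(value) kp_from_terms(value, "")

#' Polynomial that is a single product of symbols
#' @param symbols character vector of symbol names.
#' @param coef coefficient (default 1).
#' @return a `kpoly`.
#' @export
kp_monomial <- function(symbols, coef = 1) kp_from_terms(coef, .kp_canon_key(symbols))

kp_is <- function(x) inherits(x, "kpoly")

#' Arithmetic on `kpoly` objects
#' @param a,b polynomials (`kp_mul` also accepts numerics for `b`).
#' @return a `kpoly`.
#' @export
kp_add <- function(a, b) {
  kp_from_terms(c(unclass(a), unclass(b)), c(names(a), names(b)))
}

#' @rdname kp_add
#' @export
kp_sub <- function(a, b) kp_add(a, kp_neg(b))

#' @rdname kp_add
#' @export
kp_neg <- function(a) {
  x <- -unclass(a)
  class(x) <- "kpoly"
  x
}

#' @rdname kp_add
#' @export
kp_mul <- function(a, b) {
  if (is.numeric(b) && !kp_is(b)) {
    x <- unclass(a) * b
    class(x) <- "kpoly"
    return(kp_from_terms(unclass(x), names(x)))
  }
  if (kp_n_terms(a) == 0L || kp_n_terms(b) == 0L) return(kpoly())
  asym <- strsplit(names(a), "*", fixed = TRUE)
  bsym <- strsplit(names(b), "*", fixed = TRUE)
  n <- length(asym) * length(bsym)
  coef <- numeric(n)
  keys <- character(n)
  k <- 0L
  av <- unclass(a); bv <- unclass(b)
  for (i in seq_along(asym)) {
    for (j in seq_along(bsym)) {
      k <- k + 1L
      coef[k] <- av[i] * bv[j]
      keys[k] <- .kp_canon_key(c(asym[[i]], bsym[[j]]))
    }
  }
  kp_from_terms(coef, keys)
}

#' Number of additive terms in a polynomial
#' @param a a `kpoly`.
#' @return integer term count (zero polynomial has 0 terms).
#' @export
kp_n_terms <- function(a) length(unclass(a))

#' Exact zero / equality tests
#'
#' Equality is exact comparison of canonical term maps; for integer
#' coefficients (all diagram-method outputs before substitution) this is an
#' exact symbolic proof.
#' @param a,b polynomials.
#' @return logical.
#' @export
kp_is_zero <- function(a) kp_n_terms(a) == 0L

#' @rdname kp_is_zero
#' @export
kp_equal <- function(a, b) kp_is_zero(kp_sub(a, b))

#' Free symbols of a polynomial
#' @param a a `kpoly`.
#' @return sorted character vector.
#' @export
kp_symbols <- function(a) {
  if (kp_n_terms(a) == 0L) return(character(0))
  sort(unique(unlist(strsplit(names(a)[names(a) != ""], "*", fixed = TRUE))))
}

#' Substitute symbols by polynomials
#'
#' Unmapped symbols pass through unchanged; map values may be `kpoly`
#' objects, symbol names (character) or numeric constants.
#'
#' @param a a `kpoly`.
#' @param map named list mapping symbol names to replacements.
#' @return a `kpoly`.
#' @export
kp_substitute <- function(a, map) {
  if (kp_n_terms(a) == 0L) return(a)
  map <- lapply(map, function(v) {
    if (kp_is(v)) v else if (is.character(v)) kp_sym(v) else kp_const(v)
  })
  out <- kpoly()
  syms <- strsplit(names(a), "*", fixed = TRUE)
  av <- unclass(a)
  for (i in seq_along(syms)) {
    term <- kp_const(av[i])
    for (s in syms[[i]]) {
      term <- kp_mul(term, if (!is.null(map[[s]])) map[[s]] else kp_sym(s))
    }
    out <- kp_add(out, term)
  }
  out
}

#' Factor out the largest common monomial
#'
#' Returns the greatest common monomial divisor of all terms and the
#' remaining cofactor polynomial, so that
#' `a == kp_mul(kp_monomial(common), rest)`.
#'
#' @param a a nonzero `kpoly`.
#' @return list with elements `common` (character vector of symbols, possibly
#'   repeated) and `rest` (a `kpoly`).
#' @export
kp_factor_common <- function(a) {
  if (kp_n_terms(a) == 0L) stop("cannot factor the zero polynomial")
  syms <- strsplit(names(a), "*", fixed = TRUE)
  common <- syms[[1]]
  for (s in syms[-1]) {
    if (length(common) == 0L) break
    keep <- character(0)
    pool <- s
    for (x in common) {
      hit <- match(x, pool)
      if (!is.na(hit)) {
        keep <- c(keep, x)
        pool <- pool[-hit]
      }
    }
    common <- keep
  }
  rest_keys <- vapply(syms, function(s) {
    pool <- s
    for (x in common) pool <- pool[-match(x, pool)]
    .kp_canon_key(pool)
  }, character(1))
  list(common = sort(common), rest = kp_from_terms(unclass(a), rest_keys))
}

#' Evaluate a polynomial at numeric symbol values
#'
#' @param a a `kpoly`.
#' @param values named numeric vector covering all free symbols of `a`.
#' @return numeric scalar.
#' @export
kp_eval <- function(a, values) {
  kp_compile(a, names(values))(values)
}

#' Compile a polynomial to a fast evaluator
#'
#' All free symbols must appear in `symbol_order`; the returned closure takes
#' a numeric vector in that order (names, if present, are ignored) and is
#' side-effect free. Missing symbols error at compile time.
#'
#' @param a a `kpoly`.
#' @param symbol_order character vector of symbol names.
#' @return function(numeric) -> numeric.
#' @export
kp_compile <- function(a, symbol_order) {
  missing <- setdiff(kp_symbols(a), symbol_order)
  if (length(missing) > 0L) {
    stop("symbols absent from symbol order: ", paste(missing, collapse = ", "))
  }
  if (kp_n_terms(a) == 0L) return(function(values) 0)
  syms <- strsplit(names(a), "*", fixed = TRUE)
  idx <- lapply(syms, function(s) match(s, symbol_order))
  coef <- unclass(a)
  # group terms by monomial degree so each group evaluates as a vectorized
  # running product over an index matrix (fast for the large Sigma sums)
  deg <- lengths(idx)
  groups <- lapply(sort(unique(deg)), function(L) {
    sel <- which(deg == L)
    list(L = L, coef = coef[sel],
         mat = if (L > 0) matrix(unlist(idx[sel]), nrow = L) else NULL)
  })
  force(groups)
  function(values) {
    tot <- 0
    for (g in groups) {
      if (g$L == 0L) {
        tot <- tot + sum(g$coef)
      } else {
        prods <- values[g$mat[1L, ]]
        if (g$L > 1L) for (r in 2:g$L) prods <- prods * values[g$mat[r, ]]
        tot <- tot + sum(g$coef * prods)
      }
    }
    tot
  }
}

#' Render a polynomial as text, LaTeX or a JSON term list
#'
#' @param a a `kpoly`.
#' @param format one of `"text"`, `"latex"`, `"json"`.
#' @return character scalar.
#' @export
kp_format <- function(a, format = c("text", "latex", "json")) {
  format <- match.arg(format)
  if (kp_n_terms(a) == 0L) {
    return(switch(format, text = "0", latex = "0",
                  json = as.character(jsonlite::toJSON(list()))))
  }
  syms <- strsplit(names(a), "*", fixed = TRUE)
  coef <- unclass(a)
  if (format == "json") {
    terms <- lapply(seq_along(coef), function(i) {
      list(coefficient = coef[i], symbols = as.list(syms[[i]]))
    })
    return(as.character(jsonlite::toJSON(terms, auto_unbox = TRUE, digits = NA)))
  }
  render_sym <- function(s) {
    if (format == "text") return(s)
    # k_1_2 -> k_{1,2}; other symbols escape underscores
    m <- regmatches(s, regexec("^k_([0-9]+)_([0-9]+)$", s))[[1]]
    if (length(m) == 3L) return(sprintf("k_{%s,%s}", m[2], m[3]))
    gsub("_", "\\\\_", s)
  }
  pieces <- vapply(seq_along(coef), function(i) {
    mono <- if (length(syms[[i]]) == 0L) "1" else {
      sep <- if (format == "latex") " " else "*"
      paste(vapply(syms[[i]], render_sym, character(1)), collapse = sep)
    }
    cc <- coef[i]
    body <- if (abs(cc) == 1 && length(syms[[i]]) > 0L) mono else {
      sep <- if (format == "latex") " " else "*"
      paste0(format(abs(cc), digits = 12), if (length(syms[[i]])) paste0(sep, mono) else "")
    }
    paste0(if (cc < 0) "-" else "+", body)
  }, character(1))
  out <- paste(pieces, collapse = " ")
  sub("^\\+", "", out)
}

#' @export
print.kpoly <- function(x, ...) {
  cat("<kpoly> ", kp_n_terms(x), " term(s): ", kp_format(x), "\n", sep = "")
  invisible(x)
}
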