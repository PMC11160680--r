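#' @title Command-line interface
#'
#' @description
#' A small subcommand-style CLI over the library:
#' `count`, `cycles`, `probs`, `cycleflux`, `opflux`, `solve`, `validate`,
#' `model`. Tabular output is TSV with a `#`-prefixed header recording the
#' package version, seed and configuration; structured output is JSON;
#' floats are emitted with 12 significant digits. Logging goes to stderr.
#'
#' @name cli
NULL

.fixtures <- function() {
  list(four_state = build_four_state,
       six_state = function() build_six_state(with_leak = FALSE),
       six_state_leak = function() build_six_state(with_leak = TRUE),
       emre = build_emre)
}

.resolve_model <- function(spec) {
  fx <- .fixtures()
  if (spec %in% names(fx)) return(fx[[spec]]())
  if (!file.exists(spec)) stop("model not found: ", spec)
  d <- if (grepl("\\.json$", spec)) read_model_json(spec)
       else read_rate_matrix_csv(spec)
  list(diagram = d, ligands = list())
}

.parse_args <- function(argv) {
  if (length(argv) == 0L) stop("no subcommand given")
  cmd <- argv[1]
  argv <- argv[-1]
  opts <- list()
  pos <- character(0)
  q <- 1L
  while (q <= length(argv)) {
    a <- argv[q]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (q == length(argv) || startsWith(argv[q + 1L], "--")) {
        opts[[key]] <- TRUE
        q <- q + 1L
      } else {
        opts[[key]] <- argv[q + 1L]
        q <- q + 2L
      }
    } else {
      pos <- c(pos, a)
      q <- q + 1L
    }
  }
  list(cmd = cmd, opts = opts, pos = pos)
}

.fmt_num <- function(x) formatC(x, digits = 12, format = "g")

.emit <- function(lines, out = NULL) {
  if (is.null(out)) {
    writeLines(lines)
  } else {
    writeLines(lines, out)
  }
}

.header <- function(opts) {
  # --out is excluded so identical configs give byte-identical artifacts
  # regardless of where they are written
  shown <- opts[setdiff(names(opts), "out")]
  cfg <- paste(names(shown), vapply(shown, function(v) paste(v, collapse = ","),
                                    character(1)),
               sep = "=", collapse = " ")
  c(paste0("# diagramflux ",
           as.character(utils::packageVersion("diagramflux"))),
    paste0("# seed=", if (is.null(opts$seed)) "NA" else opts$seed,
           " config: ", cfg))
}

.tsv <- function(df) {
  c(paste(names(df), collapse = "\t"),
    apply(df, 1, function(r) paste(r, collapse = "\t")))
}

#' Run the command-line interface
#'
#' @param argv character vector of arguments (subcommand first), e.g.
#'   `c("count", "--model", "four_state")`.
#' @return exit status (0 on success), invisibly. Artifacts are written to
#'   stdout or to `--out`.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    .run_cli_inner(argv)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

.run_cli_inner <- function(argv) {
  pa <- .parse_args(argv)
  opts <- pa$opts
  out <- if (is.null(opts$out)) NULL else as.character(opts$out)
  known <- c("count", "cycles", "probs", "cycleflux", "opflux", "solve",
             "validate", "model")
  if (!pa$cmd %in% known) {
    stop("unknown subcommand '", pa$cmd, "' (expected one of ",
         paste(known, collapse = ", "), ")")
  }
  model_spec <- if (!is.null(opts$model)) as.character(opts$model)
                else if (length(pa$pos) > 0L) pa$pos[1] else NULL

  if (pa$cmd == "count") {
    m <- .resolve_model(model_spec)
    d <- m$diagram
    partials <- enumerate_partial_diagrams(d)
    directionals <- enumerate_directional_diagrams(d, partials)
    cycles <- enumerate_cycles(d)
    fx <- sum(vapply(cycles, function(cy)
      length(enumerate_flux_diagrams(d, cy$nodes)), integer(1)))
    df <- data.frame(quantity = c("states", "transitions", "kirchhoff",
                                  "partial", "directional", "cycles",
                                  "flux_diagrams"),
                     value = c(n_states(d), nrow(transitions(d)),
                               kirchhoff_count(d), length(partials),
                               length(directionals), length(cycles), fx))
    .emit(c(.header(opts), .tsv(df)), out)
  } else if (pa$cmd == "cycles") {
    m <- .resolve_model(model_spec)
    d <- m$diagram
    cycles <- enumerate_cycles(d)
    ligs <- sort(unique(stats::na.omit(d$edges$ligand)))
    rows <- lapply(cycles, function(cy) {
      sig <- if (length(ligs)) classify_cycle_transport(d, cy) else integer(0)
      c(cycle = paste(cy$nodes, collapse = ","), as.list(sig))
    })
    df <- as.data.frame(do.call(rbind, rows))
    .emit(c(.header(opts), .tsv(df)), out)
  } else if (pa$cmd == "probs") {
    m <- .resolve_model(model_spec)
    d <- m$diagram
    fmt <- if (is.null(opts$format)) "text" else as.character(opts$format)
    probs <- state_probability_expressions(d)
    lines <- c(vapply(d$states, function(s)
      paste0("Omega_", s, " = ", kp_format(probs$omega[[s]], fmt)),
      character(1)),
      paste0("Sigma = ", kp_format(probs$sigma, fmt)))
    .emit(c(.header(opts), lines), out)
  } else if (pa$cmd == "cycleflux") {
    m <- .resolve_model(model_spec)
    d <- m$diagram
    if (is.null(opts$cycle)) stop("cycleflux requires --cycle i,j,k,...")
    nodes <- strsplit(as.character(opts$cycle), ",")[[1]]
    fmt <- if (is.null(opts$format)) "text" else as.character(opts$format)
    cf <- net_cycle_flux_expression(d, kcycle(nodes))
    .emit(c(.header(opts),
            paste0("numerator = ", kp_format(cf$numerator, fmt)),
            paste0("Sigma_K = ", kp_format(cf$sigma_K, fmt)),
            paste0("Sigma = ", kp_format(cf$denominator, fmt))), out)
  } else if (pa$cmd == "opflux") {
    m <- .resolve_model(model_spec)
    d <- m$diagram
    if (is.null(opts$ligand)) stop("opflux requires --ligand")
    lig <- as.character(opts$ligand)
    route <- if (is.null(opts$route)) "cycles" else as.character(opts$route)
    dir <- if (!is.null(opts$direction)) as.character(opts$direction)
           else if (!is.null(m$ligands[[lig]])) m$ligands[[lig]]
           else "ext_to_int"
    fmt <- if (is.null(opts$format)) "text" else as.character(opts$format)
    op <- operational_flux(d, lig, route, dir)
    comp <- vapply(op$components, function(cc)
      paste0(if (cc$coefficient >= 0) "+" else "-",
             abs(cc$coefficient), "*(", cc$label, ")"), character(1))
    .emit(c(.header(opts),
            paste0("components: ", paste(comp, collapse = " ")),
            paste0("numerator = ", kp_format(op$numerator, fmt)),
            paste0("Sigma = ", kp_format(op$denominator, fmt))), out)
  } else if (pa$cmd == "solve") {
    m <- .resolve_model(model_spec)
    d <- m$diagram
    rates <- rate_values(d)
    if (!is.null(opts$params)) {
      pv <- utils::read.csv(as.character(opts$params),
                            stringsAsFactors = FALSE)
      rates[pv[[1]]] <- pv[[2]]
    }
    if (anyNA(rates)) stop("model has missing numeric rates; supply --params")
    ss <- steady_state_matrix(d, rates)
    tr <- transitions(d)
    jrow <- vapply(seq_len(nrow(tr)), function(q)
      transition_flux_value(d, rates, ss$p, tr$i[q], tr$j[q]), numeric(1))
    lines <- c(.header(opts),
               "state\tprobability",
               paste(names(ss$p), .fmt_num(ss$p), sep = "\t"),
               "transition\tnet_flux",
               paste(paste0(tr$i, "->", tr$j), .fmt_num(jrow), sep = "\t"))
    .emit(lines, out)
  } else if (pa$cmd == "validate") {
    n_diagrams <- if (is.null(opts$n)) 10L else as.integer(opts$n)
    max_states <- if (is.null(opts[["max-states"]])) 8L
                  else as.integer(opts[["max-states"]])
    seed <- if (is.null(opts$seed)) 1L else as.integer(opts$seed)
    rep <- validate_random_diagrams(n_diagrams, max_states, seed)
    .emit(c(.header(opts), .tsv(format(rep, digits = 6))), out)
  } else if (pa$cmd == "model") {
    if (is.null(model_spec)) stop("model subcommand requires a fixture name")
    sweep <- if (is.null(opts$sweep)) stop("model requires --sweep")
             else as.character(opts$sweep)
    grid <- if (!is.null(opts$grid)) {
      gg <- strsplit(as.character(opts$grid), ":")[[1]]
      if (gg[1] != "log") stop("grid must be log:<from>:<to>:<n>")
      10^seq(as.numeric(gg[2]), as.numeric(gg[3]),
             length.out = as.integer(gg[4]))
    } else NULL
    res <- switch(sweep,
      leak = if (is.null(grid)) sweep_leak() else sweep_leak(grid),
      raa = if (is.null(grid)) sweep_raa() else sweep_raa(grid),
      roff = {
        kaa <- if (is.null(opts$kaa)) 100 else as.numeric(opts$kaa)
        if (is.null(grid)) sweep_roff(kAA = kaa)
        else sweep_roff(grid, kAA = kaa)
      },
      stop("unknown sweep: ", sweep))
    df <- as.data.frame(lapply(res, .fmt_num), check.names = FALSE)
    .emit(c(.header(opts), .tsv(df)), out)
  }
  invisible(NULL)
}

#' Random-diagram validation report
#'
#' Generates detailed-balanced random diagrams and checks, per diagram, the
#' matrix-tree count against the enumeration, the maximum absolute net
#' transition and net cycle flux at equilibrium, and the RMSD between the
#' symbolic and matrix-solver state probabilities.
#'
#' @param n_diagrams number of random diagrams.
#' @param max_states states are drawn uniformly from 3..`max_states`.
#' @param seed integer seed.
#' @param density_range edge-density sampling interval.
#' @return data.frame with one row per diagram.
#' @export
validate_random_diagrams <- function(n_diagrams = 10, max_states = 8,
                                     seed = 1L,
                                     density_range = c(0.2, 0.35)) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sub_seeds <- sample.int(2^31 - 2, n_diagrams)
  ns <- sample(3:max_states, n_diagrams, replace = TRUE)
  dens <- stats::runif(n_diagrams, density_range[1], density_range[2])
  rows <- lapply(seq_len(n_diagrams), function(q) {
    g <- generate_equilibrium_diagram(ns[q], dens[q], seed = sub_seeds[q])
    d <- g$diagram
    kc <- kirchhoff_count(d)
    partials <- enumerate_partial_diagrams(d)
    probs <- state_probability_expressions(
      d, enumerate_directional_diagrams(d, partials))
    p_sym <- steady_state_symbolic(d, g$rates, probs)$p
    p_mat <- steady_state_matrix(d, g$rates)$p
    cycles <- enumerate_cycles(d)
    max_cycle_flux <- if (length(cycles) == 0L) 0 else
      max(vapply(cycles, function(cy) {
        abs(compile_numeric(
          net_cycle_flux_expression(d, cy, sigma = probs$sigma),
          names(g$rates))(g$rates))
      }, numeric(1)))
    tr <- transitions(d)
    max_trans_flux <- max(vapply(seq_len(nrow(tr)), function(r)
      abs(transition_flux_value(d, g$rates, p_mat, tr$i[r], tr$j[r])),
      numeric(1)))
    max_closure <- if (length(cycles) == 0L) 0 else
      max(vapply(cycles, function(cy)
        abs(closure_residual(d, g$rates, cy)), numeric(1)))
    data.frame(n_states = ns[q], n_transitions = nrow(tr),
               kirchhoff = kc, n_partial = length(partials),
               count_ok = length(partials) == kc,
               n_cycles = length(cycles),
               max_closure_residual = max_closure,
               max_cycle_flux = max_cycle_flux,
               max_transition_flux = max_trans_flux,
               rmsd_sym_vs_matrix = rmsd(p_sym, p_mat),
               boltzmann_rmsd = rmsd(p_mat, exp(-g$potentials) /
                                              sum(exp(-g$potentials))))
  })
  do.call(rbind, rows)
}

#' Export enumerated diagrams as edge-list files
#'
#' Writes one TSV edge list per diagram; filenames encode the family, index
#' and target (state or cycle). An empty family writes no files and logs an
#' informational line.
#'
#' @param diagrams list of `partial_diagram`, `directional_diagram` or
#'   `flux_diagram` objects.
#' @param path output directory (created if needed).
#' @param family optional family name override used in filenames.
#' @return invisibly, the written file paths.
#' @export
export_diagrams <- function(diagrams, path, family = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (length(diagrams) == 0L) {
    message("export_diagrams: empty family, nothing written")
    return(invisible(character(0)))
  }
  files <- character(length(diagrams))
  for (q in seq_along(diagrams)) {
    dg <- diagrams[[q]]
    if (inherits(dg, "partial_diagram")) {
      fam <- family %||% "partial"
      fn <- sprintf("%s_%03d.tsv", fam, q)
      df <- data.frame(i = dg$edges$i, j = dg$edges$j)
    } else if (inherits(dg, "directional_diagram")) {
      fam <- family %||% "directional"
      fn <- sprintf("%s_%03d_target%s.tsv", fam, q, dg$target)
      df <- data.frame(from = dg$edges$from, to = dg$edges$to)
    } else if (inherits(dg, "flux_diagram")) {
      fam <- family %||% "flux"
      fn <- sprintf("%s_%03d_cycle%s.tsv", fam, q,
                    paste(dg$target_cycle, collapse = "-"))
      nodes <- dg$target_cycle
      nxt <- c(nodes[-1], nodes[1])
      df <- rbind(data.frame(from = c(nodes, nxt), to = c(nxt, nodes),
                             role = "cycle"),
                  data.frame(from = dg$feeder$from, to = dg$feeder$to,
                             role = "feeder"))
    } else {
      stop("cannot export object of class ", class(dg)[1])
    }
    files[q] <- file.path(path, fn)
    utils::write.table(df, files[q], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(files)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
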