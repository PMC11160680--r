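test_that("load_diagram accepts rate matrices and rejects bad input", {
  m <- matrix(0, 4, 4)
  for (p in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1), c(2, 4))) {
    m[p[1], p[2]] <- 1
    m[p[2], p[1]] <- 1
  }
  d <- load_diagram(m)
  expect_equal(n_states(d), 4)
  expect_equal(nrow(transitions(d)), 5)

  m2 <- matrix(c(0, 2, 3, 0), 2, 2, byrow = TRUE)
  d2 <- load_diagram(m2)
  expect_equal(nrow(transitions(d2)), 1)
  expect_length(enumerate_cycles(d2), 0)

  m3 <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE)
  expect_error(load_diagram(m3), "missing reverse rate")
  expect_error(load_diagram(matrix(1, 2, 3)), "square")
  expect_error(kinetic_diagram(data.frame(from = 1, to = 1)), "self-loop")
  expect_error(kinetic_diagram(data.frame(from = c(1, 1, 2), to = c(2, 2, 1))),
               "duplicate edge")
  expect_error(kinetic_diagram(data.frame(from = c(1, 2, 3, 4),
                                          to = c(2, 1, 4, 3))),
               "disconnected")
})

test_that("kirchhoff_count matches closed forms", {
  expect_equal(kirchhoff_count(triangle_diagram()), 3)
  expect_equal(kirchhoff_count(build_four_state()$diagram), 8)
  expect_equal(kirchhoff_count(complete_diagram(4)), 16)  # Cayley: 4^2
  expect_equal(kirchhoff_count(complete_diagram(5)), 125)
})

test_that("partial diagram enumeration agrees with the matrix-tree oracle", {
  d4 <- build_four_state()$diagram
  partials <- enumerate_partial_diagrams(d4)
  expect_length(partials, 8)
  expect_true(all(vapply(partials, function(p) nrow(p$edges), integer(1)) == 3))
  # distinctness
  keys <- vapply(partials, function(p)
    paste(p$edges$i, p$edges$j, sep = "-", collapse = ";"), character(1))
  expect_false(anyDuplicated(keys) > 0)

  d6 <- build_six_state(with_leak = FALSE)$diagram
  expect_length(enumerate_partial_diagrams(d6), 6)

  dem <- emre_machinery()$diagram
  expect_equal(length(enumerate_partial_diagrams(dem)), kirchhoff_count(dem))

  for (seed in c(3, 14, 159)) {
    n <- 3 + (seed %% 6)
    d <- random_diagram(n, 0.45, seed)
    expect_equal(length(enumerate_partial_diagrams(d)), kirchhoff_count(d),
                 info = paste("seed", seed))
  }
})

test_that("directional diagrams are rooted arborescences, N per tree", {
  d <- build_four_state()$diagram
  partials <- enumerate_partial_diagrams(d)
  dirs <- enumerate_directional_diagrams(d, partials)
  expect_length(dirs, 32)
  expect_length(enumerate_directional_diagrams(triangle_diagram()), 9)

  tgt <- vapply(dirs, function(x) x$target, character(1))
  expect_true(all(table(tgt) == 8))
  parent <- vapply(dirs, function(x) x$parent, integer(1))
  expect_true(all(table(parent) == 4))

  for (dd in dirs) {
    # every non-target state has exactly one outgoing edge, target none
    expect_setequal(dd$edges$from, setdiff(d$states, dd$target))
    # following edges reaches the target
    succ <- stats::setNames(dd$edges$to, dd$edges$from)
    for (s in dd$edges$from) {
      cur <- s
      for (q in seq_len(n_states(d))) {
        if (cur == dd$target) break
        cur <- succ[[cur]]
      }
      expect_identical(cur, dd$target)
    }
  }
})

test_that("flux diagrams reproduce the 4-state feeder structure", {
  d <- build_four_state()$diagram
  expect_length(enumerate_flux_diagrams(d, c("1", "2", "3", "4")), 0)
  fb <- enumerate_flux_diagrams(d, c("1", "2", "4"))
  expect_length(fb, 2)
  expect_setequal(vapply(fb, function(x) x$rates, character(1)),
                  c("k_3_2", "k_3_4"))
  fc <- enumerate_flux_diagrams(d, c("2", "3", "4"))
  expect_length(fc, 2)
  expect_setequal(vapply(fc, function(x) x$rates, character(1)),
                  c("k_1_2", "k_1_4"))
  expect_true(kp_equal(flux_sigma(d, c("1", "2", "4")),
                       kp_add(kp_sym("k_3_2"), kp_sym("k_3_4"))))
  expect_true(kp_equal(flux_sigma(d, c("1", "2", "3", "4")), kp_const(1)))
  expect_error(enumerate_flux_diagrams(d, c("1", "2", "3")), "not a cycle")
})

test_that("flux diagram feeders avoid cycle transitions and count correctly", {
  dem <- emre_machinery()$diagram
  cyc4 <- emre_machinery()$cycles[[1]]
  fds <- enumerate_flux_diagrams(dem, cyc4$nodes)
  expect_gt(length(fds), 0)
  cyc_pairs <- c(paste(cyc4$nodes, c(cyc4$nodes[-1], cyc4$nodes[1])),
                 paste(c(cyc4$nodes[-1], cyc4$nodes[1]), cyc4$nodes))
  for (fd in fds) {
    expect_equal(nrow(fd$feeder), n_states(dem) - length(cyc4$nodes))
    expect_false(any(paste(fd$feeder$from, fd$feeder$to) %in% cyc_pairs))
    expect_setequal(fd$feeder$from, setdiff(dem$states, cyc4$nodes))
  }
  keys <- vapply(fds, function(x)
    paste(x$feeder$from, x$feeder$to, collapse = ";"), character(1))
  expect_false(anyDuplicated(keys) > 0)
})

test_that("enumeration is deterministic across runs", {
  d <- build_six_state(with_leak = TRUE)$diagram
  a <- enumerate_partial_diagrams(d)
  b <- enumerate_partial_diagrams(d)
  expect_identical(a, b)
  expect_identical(enumerate_directional_diagrams(d, a),
                   enumerate_directional_diagrams(d, b))
  expect_identical(enumerate_flux_diagrams(d, c("1", "2", "3", "4")),
                   enumerate_flux_diagrams(d, c("1", "2", "3", "4")))
})
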