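# frozen oracle for the 4-state model: the eight state-1 rate-products,
# written out from the directional diagrams by hand
omega1_4state <- function() {
  kpoly(rep(1, 8), list(
    c("k_2_1", "k_3_2", "k_4_1"), c("k_2_1", "k_3_2", "k_4_2"),
    c("k_2_1", "k_3_2", "k_4_3"), c("k_2_1", "k_3_4", "k_4_1"),
    c("k_2_1", "k_3_4", "k_4_2"), c("k_2_3", "k_3_4", "k_4_1"),
    c("k_2_4", "k_3_2", "k_4_1"), c("k_2_4", "k_3_4", "k_4_1")))
}

test_that("state-1 probability of the 4-state model matches the printed sum", {
  d <- build_four_state()$diagram
  probs <- state_probability_expressions(d)
  expect_true(kp_equal(probs$omega[["1"]], omega1_4state()))
  expect_equal(kp_n_terms(probs$omega[["1"]]), 8)
  expect_equal(kp_n_terms(probs$sigma), 32)
})

test_that("triangle probabilities match hand enumeration of spanning trees", {
  d <- triangle_diagram()
  probs <- state_probability_expressions(d)
  want <- kpoly(rep(1, 3), list(c("k_2_1", "k_3_1"), c("k_3_2", "k_2_1"),
                                c("k_2_3", "k_3_1")))
  expect_true(kp_equal(probs$omega[["1"]], want))
})

test_that("probabilities normalize symbolically and have legal terms", {
  for (d in list(triangle_diagram(), build_four_state()$diagram,
                 build_six_state(TRUE)$diagram,
                 random_diagram(6, 0.4, seed = 5))) {
    probs <- state_probability_expressions(d)
    total <- Reduce(kp_add, probs$omega)
    expect_true(kp_equal(total, probs$sigma))  # sum_i p_i == 1
    n <- n_states(d)
    for (om in probs$omega) {
      for (key in names(om)) {
        syms <- strsplit(key, "*", fixed = TRUE)[[1]]
        expect_length(syms, n - 1)
        expect_false(anyDuplicated(syms) > 0)
        # no term may contain a rate and its own reverse
        rev_syms <- sub("^k_([0-9]+)_([0-9]+)$", "k_\\2_\\1", syms)
        expect_length(intersect(syms, rev_syms), 0)
      }
    }
  }
})

test_that("net cycle flux expressions match the printed 4-state forms", {
  d <- build_four_state()$diagram
  probs <- state_probability_expressions(d)
  a <- orient_cycle(kcycle(c("1", "2", "3", "4")), c("1", "2"))
  ja <- net_cycle_flux_expression(d, a, sigma = probs$sigma)
  want_a <- kp_sub(kp_monomial(c("k_1_2", "k_2_3", "k_3_4", "k_4_1")),
                   kp_monomial(c("k_1_4", "k_4_3", "k_3_2", "k_2_1")))
  expect_true(kp_equal(ja$numerator, want_a))

  b <- orient_cycle(kcycle(c("1", "2", "4")), c("1", "2"))
  jb <- net_cycle_flux_expression(d, b, sigma = probs$sigma)
  want_b <- kp_mul(kp_sub(kp_monomial(c("k_1_2", "k_2_4", "k_4_1")),
                          kp_monomial(c("k_1_4", "k_4_2", "k_2_1"))),
                   kp_add(kp_sym("k_3_2"), kp_sym("k_3_4")))
  expect_true(kp_equal(jb$numerator, want_b))
})

test_that("transition fluxes decompose into cycle fluxes symbolically", {
  d <- build_four_state()$diagram
  probs <- state_probability_expressions(d)
  ja <- net_cycle_flux_expression(d, orient_cycle(kcycle(c("1", "2", "3", "4")),
                                                  c("1", "2")),
                                  sigma = probs$sigma)
  jb <- net_cycle_flux_expression(d, orient_cycle(kcycle(c("1", "2", "4")),
                                                  c("1", "2")),
                                  sigma = probs$sigma)
  jc <- net_cycle_flux_expression(d, orient_cycle(kcycle(c("2", "3", "4")),
                                                  c("2", "3")),
                                  sigma = probs$sigma)
  j24 <- net_transition_flux_expression(d, "2", "4", probs)
  j12 <- net_transition_flux_expression(d, "1", "2", probs)
  # J_24 = J_b - J_c and J_12 = J_a + J_b (shared denominator Sigma)
  expect_true(kp_equal(j24$numerator, kp_sub(jb$numerator, jc$numerator)))
  expect_true(kp_equal(j12$numerator, kp_add(ja$numerator, jb$numerator)))
  # antisymmetry J_ij = -J_ji
  j42 <- net_transition_flux_expression(d, "4", "2", probs)
  expect_true(kp_equal(j24$numerator, kp_neg(j42$numerator)))
})

test_that("every 4-state and 6-state transition flux equals its signed cycle sum", {
  for (model in list(build_four_state(), build_six_state(TRUE))) {
    d <- model$diagram
    probs <- state_probability_expressions(d)
    cyc <- enumerate_cycles(d)
    cfs <- lapply(cyc, net_cycle_flux_expression, diagram = d,
                  sigma = probs$sigma)
    tr <- transitions(d)
    for (q in seq_len(nrow(tr))) {
      i <- tr$i[q]; j <- tr$j[q]
      jij <- net_transition_flux_expression(d, i, j, probs)
      acc <- kpoly()
      for (w in seq_along(cyc)) {
        nodes <- cyc[[w]]$nodes
        nxt <- c(nodes[-1], nodes[1])
        if (any(nodes == i & nxt == j)) {
          acc <- kp_add(acc, cfs[[w]]$numerator)
        } else if (any(nodes == j & nxt == i)) {
          acc <- kp_sub(acc, cfs[[w]]$numerator)
        }
      }
      expect_true(kp_equal(jij$numerator, acc),
                  info = paste("transition", i, j))
    }
  }
})

test_that("detailed-balanced rates zero out all fluxes", {
  g <- generate_equilibrium_diagram(5, 0.5, seed = 8)
  d <- g$diagram
  probs <- state_probability_expressions(d)
  for (cy in enumerate_cycles(d)) {
    f <- compile_numeric(net_cycle_flux_expression(d, cy, sigma = probs$sigma),
                         names(g$rates))
    expect_lt(abs(f(g$rates)), 1e-12)
  }
  tr <- transitions(d)
  for (q in seq_len(nrow(tr))) {
    f <- compile_numeric(net_transition_flux_expression(d, tr$i[q], tr$j[q],
                                                        probs),
                         names(g$rates))
    expect_lt(abs(f(g$rates)), 1e-12)
  }
})

test_that("parameter substitution reproduces the simplified 4-state forms", {
  m <- build_four_state()
  d <- m$diagram
  probs <- state_probability_expressions(d)
  om1 <- substitute_rates(probs$omega[["1"]], m$param_map)
  want <- kp_mul(kp_monomial(c("L_off", "R_on")),
                 kpoly(c(1, 1, 2, 2, 2),
                       list(c("L_ext", "L_on", "R_int"),
                            c("L_int", "L_on", "R_ext"),
                            c("R_ext", "R_int", "R_on"),
                            c("R_ext", "k_leak"),
                            c("R_int", "k_leak"))))
  expect_true(kp_equal(om1, want))
  f <- kp_factor_common(om1)
  expect_true(all(c("L_off", "R_on") %in% f$common))

  a <- orient_cycle(kcycle(c("1", "2", "3", "4")), c("1", "2"))
  ja <- net_cycle_flux_expression(d, a, sigma = probs$sigma)
  num <- substitute_rates(ja$numerator, m$param_map)
  want_num <- kp_mul(kp_monomial(c("L_off", "L_on", "R_off", "R_on")),
                     kp_sub(kp_monomial(c("L_int", "R_ext")),
                            kp_monomial(c("L_ext", "R_int"))))
  expect_true(kp_equal(num, want_num))

  # identity map leaves the expression unchanged
  expect_true(kp_equal(substitute_rates(ja$numerator, list()), ja$numerator))
})

test_that("symbolic equality distinguishes different fluxes and proves routes", {
  m <- build_four_state()
  d <- m$diagram
  probs <- state_probability_expressions(d)
  ja <- net_cycle_flux_expression(d, orient_cycle(kcycle(c("1", "2", "3", "4")),
                                                  c("1", "2")),
                                  sigma = probs$sigma)
  jb <- net_cycle_flux_expression(d, orient_cycle(kcycle(c("1", "2", "4")),
                                                  c("1", "2")),
                                  sigma = probs$sigma)
  expect_false(as.logical(symbolically_equal(ja, jb)))
  for (lig in names(m$ligands)) {
    oc <- operational_flux(d, lig, "cycles", m$ligands[[lig]], probs = probs)
    ot <- operational_flux(d, lig, "transitions", m$ligands[[lig]],
                           probs = probs)
    res <- symbolically_equal(oc, ot)
    expect_true(as.logical(res))
    expect_identical(attr(res, "proof"), "symbolic")
  }
  # constrained budget + distinct denominators fall back to the
  # random-evaluation proof
  lhs <- list(numerator = probs$omega[["1"]], denominator = probs$sigma)
  rhs <- list(numerator = kp_mul(probs$omega[["1"]], 2),
              denominator = kp_mul(probs$sigma, 2))
  res <- symbolically_equal(lhs, rhs, time_budget = 1e-9)
  expect_true(as.logical(res))
  expect_identical(attr(res, "proof"), "numeric")
})

test_that("single-transition operational fluxes of the 4-state model agree", {
  m <- build_four_state()
  d <- m$diagram
  probs <- state_probability_expressions(d)
  jr <- operational_flux(d, "R", "cycles", "ext_to_int", probs = probs)
  j41 <- net_transition_flux_expression(d, "4", "1", probs)
  j12 <- net_transition_flux_expression(d, "1", "2", probs)
  expect_true(kp_equal(jr$numerator, j41$numerator))  # J_R = J_4,1
  expect_true(kp_equal(jr$numerator, j12$numerator))  # J_R = J_1,2
  jl <- operational_flux(d, "L", "cycles", "int_to_ext", probs = probs)
  j23 <- net_transition_flux_expression(d, "2", "3", probs)
  j34 <- net_transition_flux_expression(d, "3", "4", probs)
  expect_true(kp_equal(jl$numerator, j23$numerator))  # J_L = J_2,3
  expect_true(kp_equal(jl$numerator, j34$numerator))  # J_L = J_3,4
})

test_that("compiled evaluators satisfy symmetry, normalization, equilibrium", {
  d3 <- triangle_diagram()
  probs3 <- state_probability_expressions(d3)
  syms <- d3$edges$rate
  p <- compile_state_probabilities(probs3, syms)(rep(2.5, length(syms)))
  expect_equal(unname(p), rep(1 / 3, 3), tolerance = 1e-12)

  d4 <- build_four_state()$diagram
  probs4 <- state_probability_expressions(d4)
  set.seed(21)
  vals <- stats::setNames(10^stats::runif(nrow(d4$edges), -2, 2),
                          d4$edges$rate)
  p4 <- compile_state_probabilities(probs4, names(vals))(vals)
  expect_equal(sum(p4), 1, tolerance = 1e-12)
  # compiled evaluation agrees with substitution + constant folding
  direct <- kp_eval(probs4$omega[["2"]], vals) / kp_eval(probs4$sigma, vals)
  expect_equal(unname(p4[2]), direct, tolerance = 1e-12)
})
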