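test_that("derived rate constants reproduce the published table values", {
  kon_H <- disk_flux_on_rate(5, 9.3e11)
  kon_Na <- disk_flux_on_rate(5, 2.5e11)
  expect_equal(signif(kon_H, 4), 1.120e10)
  expect_equal(signif(kon_Na, 4), 3.011e9)
  expect_equal(signif(off_rate(kon_H, "pKa", 6.8), 4), 1.775e3)
  expect_equal(signif(off_rate(kon_Na, "KD", 0.030), 4), 9.033e7)
  expect_equal(off_rate(123, "KD", 1), 123)
  expect_error(disk_flux_on_rate(5, 0), "positive")
  expect_error(off_rate(-1, "pKa", 7), "positive")
  expect_error(off_rate(10, "KD", -2), "positive")
})

test_that("4-state fixture wiring matches the published structure", {
  m <- build_four_state()
  d <- m$diagram
  expect_equal(n_states(d), 4)
  expect_equal(nrow(transitions(d)), 5)
  expect_length(enumerate_cycles(d), 3)
  expect_length(enumerate_partial_diagrams(d), 8)
  # symmetric leak in the parameter map
  expect_true(kp_equal(m$param_map$k_2_4, m$param_map$k_4_2))
})

test_that("6-state fixture has the published ring, rates and cycle counts", {
  ctrl <- build_six_state(with_leak = FALSE)
  expect_equal(nrow(transitions(ctrl$diagram)), 6)
  expect_length(enumerate_cycles(ctrl$diagram), 1)
  leak <- build_six_state(with_leak = TRUE)
  cyc <- enumerate_cycles(leak$diagram)
  expect_length(cyc, 3)
  labs <- vapply(cyc, function(c) paste(c$nodes, collapse = "-"), character(1))
  expect_setequal(labs, c("1-2-3-4", "1-4-5-6", "1-2-3-4-5-6"))

  r <- six_state_rate_values(six_state_parameters(k_leak = 2))
  expect_equal(signif(r[["k_2_1"]], 4), 1.775e3)   # proton off
  expect_equal(signif(r[["k_6_1"]], 4), 9.033e7)   # sodium off
  expect_equal(r[["k_2_3"]], 69)
  expect_equal(r[["k_5_6"]], 350)
  expect_equal(r[["k_1_4"]], 2)
  expect_equal(r[["k_1_2"]], disk_flux_on_rate(5, 9.3e11) * 10^-5.5)
  expect_error(six_state_parameters(k_leak = 0), "positive")
})

test_that("EmrE fixture is the 12-transition cube with 16-term flux sums", {
  m <- emre_machinery()
  d <- m$diagram
  expect_equal(n_states(d), 8)
  expect_equal(nrow(transitions(d)), 12)
  degree <- table(c(transitions(d)$i, transitions(d)$j))
  expect_true(all(degree == 3))
  expect_length(m$cycles, 28)
  opH <- operational_flux(d, "H", "cycles", "int_to_ext",
                          probs = m$probs, cycles = m$cycles)
  opD <- operational_flux(d, "D", "cycles", "int_to_ext",
                          probs = m$probs, cycles = m$cycles)
  expect_length(opH$components, 16)
  expect_length(opD$components, 16)
  procs <- table(d$edges$process[d$edges$process != "unbinding"])
  expect_equal(unname(procs[c("binding", "conformational")]),
               array(c(8L, 8L)), ignore_attr = TRUE)
})

test_that("leak sweep uncouples transport as the leak rate grows", {
  sw <- sweep_leak(10^seq(-2, 2, length.out = 9))
  # control: single cycle, locked 1:1
  expect_equal(sw$J_H_control, sw$J_Na_control, tolerance = 1e-12)
  expect_equal(sw$stoichiometry_control, rep(1, nrow(sw)), tolerance = 1e-12)
  # leak model: stoichiometry decreases monotonically and crosses zero
  expect_true(all(diff(sw$stoichiometry) < 0))
  expect_gt(sw$stoichiometry[1], 0.99)
  expect_lt(sw$stoichiometry[nrow(sw)], 0)
  # sign change happens exactly when the sodium leak cycle overcomes the
  # coupled cycle (J_B + J_C < 0 in canonical orientations)
  jna_cycles <- sw[["J_cycle_1-4-5-6"]] + sw[["J_cycle_1-2-3-4-5-6"]]
  expect_equal(sign(sw$stoichiometry), sign(jna_cycles))
  expect_equal(sw$J_Na, jna_cycles, tolerance = 1e-9)
  expect_equal(sw$J_H, sw[["J_cycle_1-2-3-4"]] + sw[["J_cycle_1-2-3-4-5-6"]],
               tolerance = 1e-9)
  expect_error(sweep_leak(c(1, -1)), "positive")
})

test_that("alternating-access biasing switches the EmrE phenotype", {
  grid <- c(1e-8, 1e-2, 1, 1e2, 1e8)
  sw <- sweep_raa(grid)
  at1 <- which(sw$R_AA == 1)
  expect_equal(sw$J_D[at1], 0, tolerance = 1e-12)
  expect_equal(which.max(sw$J_H), at1)   # peak proton flux when unbiased
  expect_true(all(sw$J_D[sw$R_AA < 1] > 0))   # symport: same sign as J_H
  expect_true(all(sw$J_D[sw$R_AA > 1] < 0))   # antiport: opposite sign
  expect_true(all(sw$J_H > 0))
  # reciprocal biasing mirrors the drug flux (approximate: the proton
  # gradient breaks the exact graph symmetry at the few-1e-4 level)
  expect_equal(sw$J_D[1], -sw$J_D[5], tolerance = 1e-3)
  expect_equal(sw$J_D[2], -sw$J_D[4], tolerance = 1e-3)
  expect_error(sweep_raa(1e9), "1e-8..1e8")
})

test_that("off-rate biasing saturates antiport and passes through zero", {
  sw <- sweep_roff(c(1e-10, 1e-9, 1, 1e2, 1e10), kAA = 100)
  at1 <- which(sw$R_off == 1)
  expect_equal(sw$J_D[at1], 0, tolerance = 1e-12)
  expect_equal(sw$stoichiometry[at1], 0, tolerance = 1e-12)
  # antiport plateau: drug flux saturates for strongly biased off-rates
  expect_equal(sw$J_D[1], sw$J_D[2], tolerance = 0.05)
  expect_lt(sw$J_D[1], 0)
  # dominant drug-transporting cycle at extreme bias is a coupled antiport
  # cycle (nonzero transport of both ligands, in opposite directions)
  mach <- emre_machinery()
  labs <- attr(sw, "cycle_labels")
  sigs <- lapply(mach$cycles, classify_cycle_transport, diagram = mach$diagram)
  names(sigs) <- vapply(mach$cycles, function(c)
    paste(c$nodes, collapse = "-"), character(1))
  drug_cols <- labs[vapply(labs, function(l) sigs[[l]][["D"]] != 0, logical(1))]
  fluxes <- unlist(sw[1, paste0("J_cycle_", drug_cols)])
  dom <- drug_cols[which.max(abs(fluxes))]
  expect_true(sigs[[dom]][["H"]] != 0 && sigs[[dom]][["D"]] != 0)
  expect_true(sigs[[dom]][["H"]] * sigs[[dom]][["D"]] < 0)
  expect_error(sweep_roff(1, kAA = 7), "kAA")
  expect_error(sweep_roff(1e11), "1e-10..1e10")
})
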