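#' @title Transporter fixture models
#'
#' @description
#' Builders for the three membrane-transporter case studies: a pedagogical
#' 4-state antiporter with a leak transition, a 6-state sodium/proton
#' antiporter (single productive ring, optionally with a leak transition
#' 1<->4), and the 8-state free-exchange model of the multidrug transporter
#' EmrE. Each builder returns the kinetic diagram with full per-edge
#' annotations plus the conventions (ligand transport directions, parameter
#' maps) used by the sweep experiments. These fixtures double as the
#' synthetic-input generators for the test suite.
#'
#' @name transporter_models
NULL

.AVOGADRO <- 6.02214076e23

#' Diffusion-limited on-rate from the flux-through-a-disk formula
#'
#' `kon = 4 R D N_A` converted to per-molar per-second with
#' 1 liter = 1e27 cubic Angstrom.
#'
#' @param radius_angstrom capture disk radius in Angstrom.
#' @param diffusion_coeff ligand diffusion coefficient in Angstrom^2/s.
#' @return on-rate constant in 1/(M s).
#' @export
disk_flux_on_rate <- function(radius_angstrom, diffusion_coeff) {
  if (radius_angstrom <= 0 || diffusion_coeff <= 0) {
    stop("radius and diffusion coefficient must be positive")
  }
  4 * radius_angstrom * diffusion_coeff * .AVOGADRO / 1e27
}

#' Dissociation (off) rate from an on-rate and an affinity
#'
#' `koff = kon * 10^(-pKa)` (proton) or `koff = kon * KD` (general ligand).
#'
#' @param kon on-rate constant in 1/(M s), positive.
#' @param mode `"pKa"` or `"KD"`.
#' @param value the pKa (dimensionless) or KD (molar).
#' @return off-rate in 1/s.
#' @export
off_rate <- function(kon, mode = c("pKa", "KD"), value) {
  mode <- match.arg(mode)
  if (kon <= 0) stop("kon must be positive")
  switch(mode,
         pKa = kon * 10^(-value),
         KD = { if (value <= 0) stop("KD must be positive"); kon * value })
}

# ---------------------------------------------------------------------------
# 4-state antiporter

#' Build the 4-state antiporter fixture
#'
#' States: 1 driving-ion (R) bound, 2 inward-facing empty, 3 substrate (L)
#' bound, 4 outward-facing empty; transitions 1-2, 2-3, 3-4, 4-1 plus the
#' leak 2-4. The productive Hamiltonian cycle moves R from outside to inside
#' while exporting L. The symbolic parameter map implements the symmetric
#' assumptions: equal on/off rates on both membrane sides
#' (`R_on`, `R_off`, `L_on`, `L_off`) and a symmetric leak `k_leak`.
#'
#' @return list with `diagram`, `param_map` (rate symbol -> `kpoly` in the
#'   model parameters) and `ligands` (positive transport direction per
#'   ligand).
#' @export
build_four_state <- function() {
  e <- function(from, to, process, ligand = NA, side = "none", order = 1L,
                concentration = NA) {
    data.frame(from = from, to = to, process = process, ligand = ligand,
               side = side, order = order, concentration = concentration,
               stringsAsFactors = FALSE)
  }
  edges <- rbind(
    e(1, 2, "unbinding", "R", "int"),
    e(2, 1, "binding", "R", "int", 2L, "R_int"),
    e(2, 3, "binding", "L", "int", 2L, "L_int"),
    e(3, 2, "unbinding", "L", "int"),
    e(3, 4, "unbinding", "L", "ext"),
    e(4, 3, "binding", "L", "ext", 2L, "L_ext"),
    e(4, 1, "binding", "R", "ext", 2L, "R_ext"),
    e(1, 4, "unbinding", "R", "ext"),
    e(2, 4, "leakage"),
    e(4, 2, "leakage"))
  diagram <- kinetic_diagram(edges, states = as.character(1:4))
  param_map <- list(
    k_1_2 = kp_sym("R_off"),
    k_2_1 = kp_monomial(c("R_on", "R_int")),
    k_2_3 = kp_monomial(c("L_on", "L_int")),
    k_3_2 = kp_sym("L_off"),
    k_3_4 = kp_sym("L_off"),
    k_4_3 = kp_monomial(c("L_on", "L_ext")),
    k_4_1 = kp_monomial(c("R_on", "R_ext")),
    k_1_4 = kp_sym("R_off"),
    k_2_4 = kp_sym("k_leak"),
    k_4_2 = kp_sym("k_leak"))
  list(diagram = diagram, param_map = param_map,
       ligands = list(R = "ext_to_int", L = "int_to_ext"))
}

# ---------------------------------------------------------------------------
# 6-state sodium/proton antiporter

#' Parameters of the 6-state sodium/proton antiporter
#'
#' On-rates are diffusion-limited estimates from the flux-through-a-disk
#' formula (R = 5 Angstrom; D = 9.3e11 and 2.5e11 Angstrom^2/s for H+ and
#' Na+), off-rates follow from pKa 6.8 (proton) and KD 30 mM (sodium);
#' alternating-access rates are 69 1/s (proton branch) and 350 1/s (sodium
#' branch). Gradients: pH 5.5 outside / 8.5 inside, Na+ 150 mM outside /
#' 10 mM inside. The leak rate is symmetric and swept over 1e-2..1e2 1/s.
#'
#' @param k_leak leak transition rate in 1/s.
#' @return named list of rates (1/s or 1/(M s)) and concentrations (M).
#' @export
six_state_parameters <- function(k_leak = 1) {
  if (k_leak <= 0) stop("k_leak must be positive")
  kon_H <- disk_flux_on_rate(5, 9.3e11)
  kon_Na <- disk_flux_on_rate(5, 2.5e11)
  list(kon_H = kon_H,
       koff_H = off_rate(kon_H, "pKa", 6.8),
       kon_Na = kon_Na,
       koff_Na = off_rate(kon_Na, "KD", 0.030),
       kAA_H = 69, kAA_Na = 350, k_leak = k_leak,
       pH_ext = 5.5, pH_int = 8.5,
       c_H_ext = ph_to_concentration(5.5),
       c_H_int = ph_to_concentration(8.5),
       c_Na_ext = 0.150, c_Na_int = 0.010)
}

#' Build the 6-state antiporter fixture
#'
#' Ring 1-2-3-4-5-6-1: proton binds outside (1->2), crosses (2<->3) and is
#' released inside (3->4); sodium binds inside (4->5), crosses (5<->6) and
#' is released outside (6->1). `with_leak` adds the symmetric leak
#' transition 1<->4, creating proton (A: 1,2,3,4) and sodium (B: 1,4,5,6)
#' leakage cycles alongside the coupled ring cycle C.
#'
#' @param with_leak logical.
#' @return list with `diagram`, `ligands` (H: ext -> int positive, Na:
#'   int -> ext positive).
#' @export
build_six_state <- function(with_leak = TRUE) {
  e <- function(from, to, process, ligand = NA, side = "none", order = 1L,
                concentration = NA) {
    data.frame(from = from, to = to, process = process, ligand = ligand,
               side = side, order = order, concentration = concentration,
               stringsAsFactors = FALSE)
  }
  edges <- rbind(
    e(1, 2, "binding", "H", "ext", 2L, "c_H_ext"),
    e(2, 1, "unbinding", "H", "ext"),
    e(2, 3, "conformational"),
    e(3, 2, "conformational"),
    e(3, 4, "unbinding", "H", "int"),
    e(4, 3, "binding", "H", "int", 2L, "c_H_int"),
    e(4, 5, "binding", "Na", "int", 2L, "c_Na_int"),
    e(5, 4, "unbinding", "Na", "int"),
    e(5, 6, "conformational"),
    e(6, 5, "conformational"),
    e(6, 1, "unbinding", "Na", "ext"),
    e(1, 6, "binding", "Na", "ext", 2L, "c_Na_ext"))
  if (with_leak) {
    edges <- rbind(edges, e(1, 4, "leakage"), e(4, 1, "leakage"))
  }
  diagram <- kinetic_diagram(edges, states = as.character(1:6))
  list(diagram = diagram,
       ligands = list(H = "ext_to_int", Na = "int_to_ext"))
}

#' Numeric rate values for the 6-state fixture
#'
#' Pseudo-first-order binding rates are intrinsic on-rates times the fixed
#' concentrations.
#'
#' @param params output of [six_state_parameters()].
#' @param with_leak logical (must match the diagram used).
#' @return named numeric vector keyed by rate symbol.
#' @export
six_state_rate_values <- function(params = six_state_parameters(),
                                  with_leak = TRUE) {
  v <- c(k_1_2 = params$kon_H * params$c_H_ext,
         k_2_1 = params$koff_H,
         k_2_3 = params$kAA_H, k_3_2 = params$kAA_H,
         k_3_4 = params$koff_H,
         k_4_3 = params$kon_H * params$c_H_int,
         k_4_5 = params$kon_Na * params$c_Na_int,
         k_5_4 = params$koff_Na,
         k_5_6 = params$kAA_Na, k_6_5 = params$kAA_Na,
         k_6_1 = params$koff_Na,
         k_1_6 = params$kon_Na * params$c_Na_ext)
  if (with_leak) v <- c(v, k_1_4 = params$k_leak, k_4_1 = params$k_leak)
  v
}

#' Intrinsic (concentration-stripped) rates of the 6-state fixture
#' @inheritParams six_state_rate_values
#' @return named numeric vector keyed by rate symbol.
#' @export
six_state_intrinsic_rates <- function(params = six_state_parameters(),
                                      with_leak = TRUE) {
  v <- six_state_rate_values(params, with_leak)
  v["k_1_2"] <- params$kon_H
  v["k_4_3"] <- params$kon_H
  v["k_4_5"] <- params$kon_Na
  v["k_1_6"] <- params$kon_Na
  v
}

# ---------------------------------------------------------------------------
# 8-state EmrE free-exchange model

#' Parameters of the 8-state EmrE free-exchange model
#'
#' States combine membrane side (outward 1-4, inward 5-8), protonation and
#' drug occupancy: 3/5 empty (E), 1/7 proton-bound (EH), 4/6 drug-bound
#' (ED), 2/8 doubly bound (EHD). Proton binding is external on 3->1 and
#' 4->2, internal on 5->7 and 6->8; drug binding is external on 1->2 and
#' 3->4, internal on 5->6 and 7->8; alternating access connects 1<->7,
#' 2<->8, 3<->5, 4<->6. pH is 7.5 outside / 6.5 inside and the drug
#' concentration is 25 nM on both sides.
#'
#' @param kAA_EH,kAA_ED,kAA_E,kAA_EHD alternating-access rates (1/s),
#'   symmetric in both directions.
#' @param koff_H_EH,koff_H_EHD proton off-rates from the singly and doubly
#'   bound states (1/s).
#' @param koff_D_ED,koff_D_EHD drug off-rates (1/s).
#' @param kon_H,kon_D second-order on-rates (1/(M s)).
#' @param pH_ext,pH_int fixed pH on each side.
#' @param c_D_ext,c_D_int drug concentrations (M).
#' @return named list of parameters.
#' @export
emre_parameters <- function(kAA_EH = 10, kAA_ED = 10, kAA_E = 10,
                            kAA_EHD = 10,
                            koff_H_EH = 1e3, koff_H_EHD = 1e3,
                            koff_D_ED = 1, koff_D_EHD = 1,
                            kon_H = 1e10, kon_D = 1e7,
                            pH_ext = 7.5, pH_int = 6.5,
                            c_D_ext = 25e-9, c_D_int = 25e-9) {
  list(kAA_EH = kAA_EH, kAA_ED = kAA_ED, kAA_E = kAA_E, kAA_EHD = kAA_EHD,
       koff_H_EH = koff_H_EH, koff_H_EHD = koff_H_EHD,
       koff_D_ED = koff_D_ED, koff_D_EHD = koff_D_EHD,
       kon_H = kon_H, kon_D = kon_D,
       pH_ext = pH_ext, pH_int = pH_int,
       c_H_ext = ph_to_concentration(pH_ext),
       c_H_int = ph_to_concentration(pH_int),
       c_D_ext = c_D_ext, c_D_int = c_D_int)
}

#' Build the EmrE free-exchange fixture
#'
#' 8 states and 12 reversible transitions (4 proton-binding, 4 drug-binding,
#' 4 alternating-access) wired as in [emre_parameters()]; the topology is
#' the 3-dimensional cube graph. Both ligands flow down their gradients
#' outward at the reference condition, so the positive operational-flux
#' direction is int -> ext for both.
#'
#' @return list with `diagram` and `ligands`.
#' @export
build_emre <- function() {
  e <- function(from, to, process, ligand = NA, side = "none", order = 1L,
                concentration = NA) {
    data.frame(from = from, to = to, process = process, ligand = ligand,
               side = side, order = order, concentration = concentration,
               stringsAsFactors = FALSE)
  }
  edges <- rbind(
    # proton binding/unbinding
    e(3, 1, "binding", "H", "ext", 2L, "c_H_ext"),
    e(1, 3, "unbinding", "H", "ext"),
    e(4, 2, "binding", "H", "ext", 2L, "c_H_ext"),
    e(2, 4, "unbinding", "H", "ext"),
    e(5, 7, "binding", "H", "int", 2L, "c_H_int"),
    e(7, 5, "unbinding", "H", "int"),
    e(6, 8, "binding", "H", "int", 2L, "c_H_int"),
    e(8, 6, "unbinding", "H", "int"),
    # drug binding/unbinding
    e(1, 2, "binding", "D", "ext", 2L, "c_D_ext"),
    e(2, 1, "unbinding", "D", "ext"),
    e(3, 4, "binding", "D", "ext", 2L, "c_D_ext"),
    e(4, 3, "unbinding", "D", "ext"),
    e(5, 6, "binding", "D", "int", 2L, "c_D_int"),
    e(6, 5, "unbinding", "D", "int"),
    e(7, 8, "binding", "D", "int", 2L, "c_D_int"),
    e(8, 7, "unbinding", "D", "int"),
    # alternating access
    e(1, 7, "conformational"), e(7, 1, "conformational"),
    e(2, 8, "conformational"), e(8, 2, "conformational"),
    e(3, 5, "conformational"), e(5, 3, "conformational"),
    e(4, 6, "conformational"), e(6, 4, "conformational"))
  diagram <- kinetic_diagram(edges, states = as.character(1:8))
  list(diagram = diagram,
       ligands = list(H = "int_to_ext", D = "int_to_ext"))
}

#' Numeric rate values for the EmrE fixture
#' @param params output of [emre_parameters()].
#' @return named numeric vector keyed by rate symbol.
#' @export
emre_rate_values <- function(params = emre_parameters()) {
  c(k_3_1 = params$kon_H * params$c_H_ext, k_1_3 = params$koff_H_EH,
    k_4_2 = params$kon_H * params$c_H_ext, k_2_4 = params$koff_H_EHD,
    k_5_7 = params$kon_H * params$c_H_int, k_7_5 = params$koff_H_EH,
    k_6_8 = params$kon_H * params$c_H_int, k_8_6 = params$koff_H_EHD,
    k_1_2 = params$kon_D * params$c_D_ext, k_2_1 = params$koff_D_EHD,
    k_3_4 = params$kon_D * params$c_D_ext, k_4_3 = params$koff_D_ED,
    k_5_6 = params$kon_D * params$c_D_int, k_6_5 = params$koff_D_ED,
    k_7_8 = params$kon_D * params$c_D_int, k_8_7 = params$koff_D_EHD,
    k_1_7 = params$kAA_EH, k_7_1 = params$kAA_EH,
    k_2_8 = params$kAA_EHD, k_8_2 = params$kAA_EHD,
    k_3_5 = params$kAA_E, k_5_3 = params$kAA_E,
    k_4_6 = params$kAA_ED, k_6_4 = params$kAA_ED)
}

#' Intrinsic (concentration-stripped) rates of the EmrE fixture
#' @param params output of [emre_parameters()].
#' @return named numeric vector keyed by rate symbol.
#' @export
emre_intrinsic_rates <- function(params = emre_parameters()) {
  v <- emre_rate_values(params)
  v[c("k_3_1", "k_4_2", "k_5_7", "k_6_8")] <- params$kon_H
  v[c("k_1_2", "k_3_4", "k_5_6", "k_7_8")] <- params$kon_D
  v
}

# ---------------------------------------------------------------------------
# sweep machinery

# compiled operational-flux and per-cycle evaluators for a fixture
.sweep_machinery <- function(model) {
  d <- model$diagram
  probs <- state_probability_expressions(d)
  cycles <- enumerate_cycles(d)
  symorder <- d$edges$rate
  fden <- kp_compile(probs$sigma, symorder)
  ops <- lapply(names(model$ligands), function(lig) {
    op <- operational_flux(d, lig, "cycles", model$ligands[[lig]],
                           probs = probs, cycles = cycles)
    kp_compile(op$numerator, symorder)
  })
  names(ops) <- names(model$ligands)
  cyc_funs <- lapply(cycles, function(cy) {
    kp_compile(net_cycle_flux_expression(d, cy, sigma = probs$sigma)$numerator,
               symorder)
  })
  list(diagram = d, probs = probs, cycles = cycles, symorder = symorder,
       fden = fden, ops = ops, cyc_funs = cyc_funs)
}

.sweep_eval <- function(mach, rates) {
  v <- rates[mach$symorder]
  den <- mach$fden(v)
  list(op = vapply(mach$ops, function(f) f(v) / den, numeric(1)),
       cyc = vapply(mach$cyc_funs, function(f) f(v) / den, numeric(1)))
}

.cycle_labels <- function(cycles) {
  vapply(cycles, function(cy) paste(cy$nodes, collapse = "-"), character(1))
}

#' Leak-rate sweep of the 6-state antiporter
#'
#' Evaluates the operational fluxes of the control (no-leak) and leak
#' models over a grid of leak rates at the fixed concentration gradients of
#' [six_state_parameters()]. Stoichiometry is the signed ratio
#' `J_Na / J_H` (sodium ions transported outward per proton transported
#' inward).
#'
#' @param k_leak_grid positive leak rates in 1/s.
#' @return object of class `sweep_result`: a data.frame with per-point
#'   fluxes (control and leak model) and stoichiometries; per-cycle net
#'   cycle fluxes of the leak model are attached as attribute
#'   `cycle_fluxes`.
#' @export
sweep_leak <- function(k_leak_grid = 10^seq(-2, 2, length.out = 25)) {
  if (any(k_leak_grid <= 0)) stop("k_leak must be positive")
  ctrl <- .sweep_machinery(build_six_state(with_leak = FALSE))
  leak <- .sweep_machinery(build_six_state(with_leak = TRUE))
  rows <- lapply(k_leak_grid, function(kl) {
    params <- six_state_parameters(k_leak = kl)
    rc <- .sweep_eval(ctrl, six_state_rate_values(params, with_leak = FALSE))
    rl <- .sweep_eval(leak, six_state_rate_values(params, with_leak = TRUE))
    c(k_leak = kl,
      J_H_control = rc$op[["H"]], J_Na_control = rc$op[["Na"]],
      stoichiometry_control = rc$op[["Na"]] / rc$op[["H"]],
      J_H = rl$op[["H"]], J_Na = rl$op[["Na"]],
      stoichiometry = rl$op[["Na"]] / rl$op[["H"]],
      rl$cyc)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab)[8:ncol(tab)] <- paste0("J_cycle_", .cycle_labels(leak$cycles))
  structure(tab, class = c("sweep_result", "data.frame"),
            cycle_labels = .cycle_labels(leak$cycles))
}

.emre_sweep <- function(grid_name, grid, param_fun) {
  mach <- .sweep_machinery(build_emre())
  rows <- lapply(grid, function(g) {
    r <- .sweep_eval(mach, emre_rate_values(param_fun(g)))
    c(g, r$op[["H"]], r$op[["D"]], r$op[["D"]] / r$op[["H"]], r$cyc)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab) <- c(grid_name, "J_H", "J_D", "stoichiometry",
                  paste0("J_cycle_", .cycle_labels(mach$cycles)))
  structure(tab, class = c("sweep_result", "data.frame"),
            cycle_labels = .cycle_labels(mach$cycles))
}

#' Alternating-access rate biasing sweep of the EmrE model
#'
#' The antiport-type rates (`kAA_ED`, `kAA_EH`) are set to
#' `anchor * sqrt(R_AA)` and the symport-type rates (`kAA_E`, `kAA_EHD`) to
#' `anchor / sqrt(R_AA)`, so paired rates vary reciprocally about the fixed
#' geometric mean `anchor` (default 10 1/s) and span 1e-3..1e5 1/s at the
#' grid extremes 1e-8..1e8. Off-rates are held at their baseline values
#' (proton 1e3 1/s, drug 1 1/s). Closure holds at every grid point because
#' alternating-access rates are symmetric.
#'
#' @param r_aa_grid values of the bias ratio `R_AA` within 1e-8..1e8.
#' @param anchor geometric-mean anchor in 1/s.
#' @return a `sweep_result` with per-point `J_H`, `J_D`, stoichiometry
#'   `J_D / J_H`, and all 28 net cycle fluxes.
#' @export
sweep_raa <- function(r_aa_grid = 10^seq(-8, 8, length.out = 33),
                      anchor = 10) {
  if (any(r_aa_grid < 1e-8 - 1e-15) || any(r_aa_grid > 1e8 * (1 + 1e-12))) {
    stop("R_AA grid must lie within 1e-8..1e8")
  }
  .emre_sweep("R_AA", r_aa_grid, function(r) {
    emre_parameters(kAA_ED = anchor * sqrt(r), kAA_EH = anchor * sqrt(r),
                    kAA_E = anchor / sqrt(r), kAA_EHD = anchor / sqrt(r))
  })
}

#' Substrate off-rate biasing sweep of the EmrE model
#'
#' Off-rates vary reciprocally about fixed geometric means: drug off-rates
#' `koff_D_ED = 10 sqrt(R_off)`, `koff_D_EHD = 10 / sqrt(R_off)` and proton
#' off-rates `koff_H_EH = 1e3 sqrt(R_off)`,
#' `koff_H_EHD = 1e3 / sqrt(R_off)`, reproducing the admissible per-rate
#' ranges (drug 1e-4..1e6, proton 1e-2..1e8 1/s) at the grid extremes
#' 1e-10..1e10. All four alternating-access rates are set uniformly to
#' `kAA`. This pairing keeps every cycle closure residual exactly zero.
#'
#' @param r_off_grid values of the bias ratio `R_off` within 1e-10..1e10.
#' @param kAA uniform alternating-access rate, one of 1, 10, 100, 1000 1/s.
#' @return a `sweep_result` with per-point `J_H`, `J_D`, stoichiometry and
#'   all 28 net cycle fluxes.
#' @export
sweep_roff <- function(r_off_grid = 10^seq(-10, 10, length.out = 41),
                       kAA = 100) {
  if (!kAA %in% c(1, 10, 100, 1000)) {
    stop("kAA must be one of 1, 10, 100, 1000 (1/s)")
  }
  if (any(r_off_grid < 1e-10 * (1 - 1e-12)) ||
      any(r_off_grid > 1e10 * (1 + 1e-12))) {
    stop("R_off grid must lie within 1e-10..1e10")
  }
  .emre_sweep("R_off", r_off_grid, function(r) {
    emre_parameters(kAA_EH = kAA, kAA_ED = kAA, kAA_E = kAA, kAA_EHD = kAA,
                    koff_D_ED = 10 * sqrt(r), koff_D_EHD = 10 / sqrt(r),
                    koff_H_EH = 1e3 * sqrt(r), koff_H_EHD = 1e3 / sqrt(r))
  })
}
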