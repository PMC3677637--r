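#' Algebraic observables of the model
#'
#' Computes the algebraic layer on top of the 29-entry state: total volume,
#' internal/external osmotic pressure, turgor, the Hog1 input signal
#' (relative turgor loss), the specific growth rate, total Gpd1 and all
#' intracellular concentrations.
#'
#' Definitions (volumes fL, pressures Osm, time min):
#' \itemize{
#' \item `Vtot = Vb + Vos`
#' \item `Pi_i = 1e-3 * (n0 + sum of intracellular metabolite amounts) / Vos`
#' \item `Pi_e = Pi_e0 + i_vh * NaCle + 1e-3 * (Glce + Glye + EtOHe + AcOe + Tree)`
#' \item `Pi_t = clip(Pi_t0 * (Vos - V_lp) / (Vos0 - V_lp), 0, Pi_t0)`
#' \item `u = max(0, (Pi_t0 - Pi_t) / Pi_t0)`
#' \item `mu = mu0 * clip((Vos - V_gmin)/(Vos0 - V_gmin), 0, 1) *
#'        (1 - theta_H * Hog1PP / (K_gH + Hog1PP))`
#' \item `Gpd1tot = Gpd1m + 2 * Gpd1d`; `c_X = X / Vos` for intracellular X.
#' }
#'
#' @param state Named 29-entry state vector (see [hog_state_names()]).
#' @param params A `hog_params` vector.
#' @return Named numeric vector of 17 observables.
#' @export
compute_observables <- function(state, params) {
  s <- validate_state(state)
  p <- params
  if (s[["Vos"]] <= 0) stop("degenerate volume: Vos <= 0", call. = FALSE)
  Vos <- s[["Vos"]]
  osmo_amt <- p[["n0"]] + sum(s[c("Glci", "HexP", "FBP", "TriP", "G3P",
                                  "Glyi", "Pyr", "EtOHi", "AcOi", "Trei")])
  Pi_i <- 1e-3 * osmo_amt / Vos
  Pi_e <- p[["Pi_e0"]] + p[["i_vh"]] * s[["NaCle"]] +
    1e-3 * sum(s[c("Glce", "Glye", "EtOHe", "AcOe", "Tree")])
  Pi_t <- p[["Pi_t0"]] * (Vos - p[["V_lp"]]) / (p[["Vos0"]] - p[["V_lp"]])
  Pi_t <- min(max(Pi_t, 0), p[["Pi_t0"]])
  u <- max(0, (p[["Pi_t0"]] - Pi_t) / p[["Pi_t0"]])
  volf <- (Vos - p[["V_gmin"]]) / (p[["Vos0"]] - p[["V_gmin"]])
  volf <- min(max(volf, 0), 1)
  hogf <- 1 - p[["theta_H"]] * s[["Hog1PP"]] / (p[["K_gH"]] + s[["Hog1PP"]])
  mu <- p[["mu0"]] * volf * hogf
  conc <- s[c("Glci", "HexP", "FBP", "TriP", "G3P", "Glyi", "Pyr",
              "EtOHi", "AcOi", "Trei")] / Vos
  names(conc) <- paste0("c", names(conc))
  c(Vtot = unname(p[["Vb"]]) + Vos, Pi_i = Pi_i, Pi_e = Pi_e, Pi_t = Pi_t,
    u = u, mu = mu,
    Gpd1tot = unname(s[["Gpd1m"]] + 2 * s[["Gpd1d"]]),
    conc)
}

#' Flux (reaction rate) names
#' @return Character vector of the 20 per-cell reaction rates (amol/min).
#' @export
hog_flux_names <- function() {
  c("vHXT", "vHK", "vPFK", "vALD", "vLG", "vPDC", "vALD6",
    "vGPD1", "vGPD2", "vGPP", "vTPS", "vNTH",
    "vFPS", "vSTL", "vEtOHt", "vAcOt", "vTret", "vBM",
    "vPH", "vDP")
}

#' Per-cell reaction rates
#'
#' Evaluates every rate law at the given state: Michaelis-Menten for
#' enzymatic steps (Pfk1 with Vmax modulation by F26DP), mass action for
#' aldolase and trehalose mobilization, linear gradient-driven passive
#' transport for Fps1 and the ethanol/acetate/trehalose exchangers, and a
#' strictly irreversible Stl1 uptake. `vFPS` is signed with efflux
#' positive. Units: amol/min/cell.
#'
#' @inheritParams compute_observables
#' @return Named numeric vector of 20 reaction rates.
#' @export
reaction_fluxes <- function(state, params) {
  s <- validate_state(state)
  p <- params
  ob <- compute_observables(s, p)
  Vos <- s[["Vos"]]
  cGlci <- s[["Glci"]] / Vos; cHexP <- s[["HexP"]] / Vos
  cFBP <- s[["FBP"]] / Vos; cTriP <- s[["TriP"]] / Vos
  cG3P <- s[["G3P"]] / Vos; cGlyi <- s[["Glyi"]] / Vos
  cPyr <- s[["Pyr"]] / Vos; cEtOHi <- s[["EtOHi"]] / Vos
  cAcOi <- s[["AcOi"]] / Vos; cTrei <- s[["Trei"]] / Vos
  cF26 <- s[["F26DP"]] / Vos

  v <- c(
    vHXT = p[["kHXT"]] * s[["Glce"]] / (p[["KHXT"]] + s[["Glce"]]),
    vHK = p[["VmHK"]] * cGlci / (p[["KHK"]] + cGlci),
    vPFK = p[["VmPFK"]] * (1 + p[["aF"]] * cF26 / (p[["KF26"]] + cF26)) *
      cHexP / (p[["KPFK"]] + cHexP),
    vALD = p[["kALD"]] * s[["FBP"]],
    vLG = p[["VmLG"]] * cTriP / (p[["KLG"]] + cTriP),
    vPDC = p[["VmPDC"]] * cPyr / (p[["KPDC"]] + cPyr),
    vALD6 = p[["VmALD6"]] * cPyr / (p[["KALD6"]] + cPyr),
    vGPD1 = p[["kcatGpd1"]] * s[["Gpd1d"]] * cTriP / (p[["KGPD"]] + cTriP),
    vGPD2 = p[["kcatGpd2"]] * s[["Gpd2"]] * cTriP / (p[["KGPD"]] + cTriP),
    vGPP = p[["VmGPP"]] * cG3P / (p[["KGPP"]] + cG3P),
    vTPS = (p[["kTPS0"]] + p[["kTPSh"]] * s[["Hog1PP"]]) *
      cHexP / (p[["KTPS"]] + cHexP),
    vNTH = p[["kNTH"]] * s[["Trei"]],
    vFPS = p[["k_fps"]] * s[["Fps1o"]] * (cGlyi - s[["Glye"]]),
    vSTL = p[["VmSTL"]] * s[["Stl1"]] * s[["Glye"]] /
      (p[["KSTL"]] + s[["Glye"]]),
    vEtOHt = p[["k_tE"]] * (cEtOHi - s[["EtOHe"]]),
    vAcOt = p[["k_tA"]] * (cAcOi - s[["AcOe"]]),
    vTret = p[["k_tT"]] * (cTrei - s[["Tree"]]),
    vBM = p[["gamma_bm"]] * ob[["mu"]] * cHexP / (p[["K_bm"]] + cHexP),
    vPH = p[["k_ph"]] * ob[["u"]] * s[["Hog1u"]],
    vDP = p[["k_dp"]] * s[["Hog1PP"]]
  )
  v
}

# Stoichiometric matrix of the carbon-bearing reactions over metabolite
# species plus the virtual CO2 and biomass-carbon sinks. External species
# rows are applied with the cell-density factor in the rhs.
carbon_species <- function() {
  c(Glci = 6, HexP = 6, FBP = 6, TriP = 3, G3P = 3, Glyi = 3, Pyr = 3,
    EtOHi = 2, AcOi = 2, Trei = 12,
    Glce = 6, Glye = 3, EtOHe = 2, AcOe = 2, Tree = 12,
    CO2 = 1, BM = 6)
}

#' Stoichiometric matrix of the metabolic reactions
#'
#' Rows are metabolite species (intracellular pools, external pools and
#' the virtual CO2 / biomass-carbon sinks of the bookkeeping), columns are
#' the 18 carbon-bearing reactions. F26DP is catalytic and excluded.
#'
#' @return Integer matrix (17 species x 18 reactions).
#' @export
stoichiometry_matrix <- function() {
  sp <- names(carbon_species())
  rx <- setdiff(hog_flux_names(), c("vPH", "vDP"))
  S <- matrix(0L, nrow = length(sp), ncol = length(rx),
              dimnames = list(sp, rx))
  put <- function(r, ...) {
    st <- c(...)
    S[names(st), r] <<- as.integer(st)
  }
  put("vHXT", Glce = -1, Glci = 1)
  put("vHK", Glci = -1, HexP = 1)
  put("vPFK", HexP = -1, FBP = 1)
  put("vALD", FBP = -1, TriP = 2)
  put("vLG", TriP = -1, Pyr = 1)
  put("vPDC", Pyr = -1, EtOHi = 1, CO2 = 1)
  put("vALD6", Pyr = -1, AcOi = 1, CO2 = 1)
  put("vGPD1", TriP = -1, G3P = 1)
  put("vGPD2", TriP = -1, G3P = 1)
  put("vGPP", G3P = -1, Glyi = 1)
  put("vTPS", HexP = -2, Trei = 1)
  put("vNTH", Trei = -1, Glci = 2)
  put("vFPS", Glyi = -1, Glye = 1)
  put("vSTL", Glye = -1, Glyi = 1)
  put("vEtOHt", EtOHi = -1, EtOHe = 1)
  put("vAcOt", AcOi = -1, AcOe = 1)
  put("vTret", Trei = -1, Tree = 1)
  put("vBM", HexP = -1, BM = 1)
  S
}

#' Carbon closure of the stoichiometric matrix
#'
#' For each metabolic reaction, the carbon-weighted stoichiometric sum
#' (atoms created minus consumed). Decarboxylations are balanced through
#' the virtual CO2 species; the biomass drain counts 6 carbons per
#' glucose-equivalent. All entries must be zero for a carbon-closed model.
#'
#' @param params A `hog_params` vector (present for interface symmetry;
#'   the stoichiometry is parameter-free).
#' @return A tibble with columns `reaction` and `carbon_residual`.
#' @export
check_carbon_closure <- function(params = hog_params()) {
  S <- stoichiometry_matrix()
  cc <- carbon_species()
  if (!all(rownames(S) %in% names(cc))) {
    stop("missing carbon assignment for: ",
         paste(setdiff(rownames(S), names(cc)), collapse = ", "),
         call. = FALSE)
  }
  res <- as.numeric(crossprod(S, cc[rownames(S)]))
  tibble::tibble(reaction = colnames(S), carbon_residual = res)
}

#' Model right-hand side (reference implementation)
#'
#' Evaluates the time derivative of the 29-entry state. Metabolite
#' derivatives are assembled from the stoichiometric matrix and the rate
#' laws of [reaction_fluxes()]; every per-cell amount carries a growth
#' dilution term `-mu * X` (the Hog1 pool additionally carries a
#' homeostatic synthesis term `+mu * Hog1tot` so that the phospho-cycle
#' moiety is conserved under balanced growth); external pools evolve with
#' the cell-density corrected transport rates `CD * 1e-12 * v`; water flux
#' is `dVos/dt = Lp_A * (Pi_i - Pi_e - Pi_t)`.
#'
#' This is the readable reference implementation; simulation uses a
#' compiled equivalent that is pinned to it by a property test.
#'
#' @param state Named 29-entry state vector.
#' @param t Time (min); the autonomous system ignores it.
#' @param params A `hog_params` vector.
#' @param freeze_external If `TRUE`, derivatives of the external pools,
#'   NaCl and cell density are zeroed (used for pre-stress equilibration).
#' @return Named numeric vector of 29 derivatives.
#' @export
evaluate_rhs <- function(state, t = 0, params = hog_params(),
                         freeze_external = FALSE) {
  if (!is.finite(t)) stop("non-finite time", call. = FALSE)
  s <- validate_state(state)
  p <- params
  ob <- compute_observables(s, p)
  v <- reaction_fluxes(s, p)
  mu <- ob[["mu"]]
  u <- ob[["u"]]
  cd <- s[["CD"]] * 1e-12 # cells per fL of culture

  S <- stoichiometry_matrix()
  met_int <- c("Glci", "HexP", "FBP", "TriP", "G3P", "Glyi", "Pyr",
               "EtOHi", "AcOi", "Trei")
  met_ext <- c("Glce", "Glye", "EtOHe", "AcOe", "Tree")
  vmet <- v[colnames(S)]
  d_int <- as.numeric(S[met_int, ] %*% vmet) - mu * s[met_int]
  d_ext <- cd * as.numeric(S[met_ext, ] %*% vmet)

  cGlce <- s[["Glce"]]
  hterm <- if (p[["Hog1tot"]] > 0) {
    p[["k_cH"]] * s[["Hog1PP"]] / p[["Hog1tot"]]
  } else 0

  d <- c(
    Vos = p[["Lp_A"]] * (ob[["Pi_i"]] - ob[["Pi_e"]] - ob[["Pi_t"]]),
    Hog1u = -v[["vPH"]] + v[["vDP"]] + mu * (p[["Hog1tot"]] - s[["Hog1u"]]),
    Hog1PP = v[["vPH"]] - v[["vDP"]] - mu * s[["Hog1PP"]],
    mGPD1 = p[["k_b1"]] + p[["k_h1"]] * s[["Hog1PP"]] + p[["k_o1"]] * u -
      (p[["d_m1"]] + mu) * s[["mGPD1"]],
    Gpd1m = p[["ks1"]] * s[["mGPD1"]] - p[["kd1"]] * s[["Gpd1m"]] -
      2 * p[["k_dim"]] * s[["Gpd1m"]]^2 + 2 * p[["k_undim"]] * s[["Gpd1d"]] -
      mu * s[["Gpd1m"]],
    Gpd1d = p[["k_dim"]] * s[["Gpd1m"]]^2 - p[["k_undim"]] * s[["Gpd1d"]] -
      p[["kd1d"]] * s[["Gpd1d"]] - mu * s[["Gpd1d"]],
    Gpd2 = p[["k_b2"]] + p[["k_o2"]] * u - (p[["d2"]] + mu) * s[["Gpd2"]],
    mSTL1 = p[["k_s0"]] * p[["K_rep"]] / (p[["K_rep"]] + cGlce) +
      p[["k_s1"]] * s[["Hog1PP"]] - (p[["d_ms"]] + mu) * s[["mSTL1"]],
    Stl1 = p[["ks_s"]] * s[["mSTL1"]] - (p[["kd_s"]] + mu) * s[["Stl1"]],
    Pfk26a = p[["k_a26"]] * s[["Hog1PP"]] * (p[["PfkT"]] - s[["Pfk26a"]]) -
      p[["k_i26"]] * s[["Pfk26a"]],
    F26DP = p[["k_f26"]] * s[["Pfk26a"]] *
      (s[["HexP"]] / s[["Vos"]]) /
      (p[["K_f26s"]] + s[["HexP"]] / s[["Vos"]]) -
      (p[["d_f26"]] + mu) * s[["F26DP"]],
    Fps1o = p[["k_open"]] * (1 - s[["Fps1o"]]) -
      (p[["k_cT"]] * u + hterm) * s[["Fps1o"]]
  )
  d <- c(d, stats::setNames(d_int, met_int), stats::setNames(d_ext, met_ext),
         NaCle = 0, CD = mu * s[["CD"]])
  d <- d[hog_state_names()]
  if (freeze_external) {
    d[c(met_ext, "NaCle", "CD")] <- 0
  }
  d
}

# Hook for deSolve-style use of the reference implementation (tests).
rhs_desolve_ref <- function(t, y, parms) {
  list(evaluate_rhs(y, t, parms$params,
                    freeze_external = isTRUE(parms$freeze_external)))
}

#' Carbon-conservation audit of a closed simulation
#'
#' Integrates the stressed model together with culture-level CO2 and
#' biomass-carbon accumulators and returns the relative drift of total
#' carbon (medium + cells + CO2 + biomass, in carbon-amol per fL of
#' culture). With carbon-closed stoichiometry the drift is bounded by
#' integrator tolerance only.
#'
#' @param params A `hog_params` vector.
#' @param strain Strain name or spec.
#' @param t_end Horizon (min).
#' @param NaCl_step Salt step at t = 0 (M).
#' @param rtol,atol Solver tolerances (tight by default; this is an
#'   audit, not a production run).
#' @return Maximum relative drift of total carbon over `[0, t_end]`.
#' @export
carbon_conservation_drift <- function(params, strain = "WT", t_end = 180,
                                      NaCl_step = 0.4,
                                      rtol = 1e-10, atol = 1e-12) {
  if (!is.null(strain)) params <- apply_strain(params, strain)
  cc <- carbon_species()
  int_names <- c("Glci", "HexP", "FBP", "TriP", "G3P", "Glyi", "Pyr",
                 "EtOHi", "AcOi", "Trei")
  ext_names <- c("Glce", "Glye", "EtOHe", "AcOe", "Tree")
  i_int <- match(int_names, hog_state_names())
  i_ext <- match(ext_names, hog_state_names())
  i_cd <- match("CD", hog_state_names())
  w_int <- cc[int_names]; w_ext <- cc[ext_names]

  pv <- pvec_c(params, 0)
  aug <- function(t, y, dummy) {
    r <- .Call(C_hog_rhs_full, t, y[seq_len(29)], pv)
    cd <- y[i_cd] * 1e-12
    fl <- r$flux
    # flux order: see hog_flux_names(); PDC 6, ALD6 7, BM 18
    list(c(r$deriv, cd * (fl[6] + fl[7]), cd * 6 * fl[18]))
  }
  eq <- prestress_equilibrate(params)
  y0 <- c(eq[hog_state_names()], CO2C = 0, BMC = 0)
  y0[["NaCle"]] <- NaCl_step
  out <- deSolve::ode(y0, seq(0, t_end, by = 5), aug, NULL,
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 100000)
  if (nrow(out) < length(seq(0, t_end, by = 5))) {
    stop("carbon audit integration failed", call. = FALSE)
  }
  states <- out[, 1 + seq_len(31)]
  cd <- states[, i_cd] * 1e-12
  total <- as.numeric(states[, i_ext] %*% w_ext) +
    cd * as.numeric(states[, i_int] %*% w_int) +
    states[, 30] + states[, 31]
  max(abs(total - total[1])) / total[1]
}
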