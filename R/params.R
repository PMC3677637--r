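#' State variable names of the osmoadaptation model
#'
#' The model tracks exactly 29 dynamic quantities per cell and culture:
#' the osmotically active volume, the two-form Hog1 pool, the GPD1/GPD2,
#' STL1 and Pfk26/27 expression layer, the Fps1 open fraction, ten
#' intracellular metabolite pools (amol/cell; amount / Vos in fL gives mM),
#' five external concentrations (mM), the stepped external NaCl
#' concentration (M) and the cell density (cells/mL).
#'
#' @return Character vector of length 29, in canonical order.
#' @export
hog_state_names <- function() {
  c("Vos",
    "Hog1u", "Hog1PP",
    "mGPD1", "Gpd1m", "Gpd1d", "Gpd2",
    "mSTL1", "Stl1",
    "Pfk26a", "F26DP",
    "Fps1o",
    "Glci", "HexP", "FBP", "TriP", "G3P", "Glyi", "Pyr", "EtOHi", "AcOi",
    "Trei",
    "Glce", "Glye", "EtOHe", "AcOe", "Tree",
    "NaCle",
    "CD")
}

#' Parameter names of the osmoadaptation model
#'
#' @return Character vector of the 74 kinetic/biophysical parameter names,
#'   in the canonical order used by the compiled right-hand side.
#' @export
hog_param_names <- function() {
  c(# biophysics
    "Vb", "Vos0", "Lp_A", "Pi_t0", "V_lp", "n0", "i_vh", "Pi_e0",
    # Hog1 signalling (two reactions)
    "Hog1tot", "k_ph", "k_dp",
    # GPD1 expression, translation, dimerization
    "k_b1", "k_h1", "k_o1", "d_m1", "ks1", "kd1", "k_dim", "k_undim", "kd1d",
    # GPD2 protein pool
    "k_b2", "k_o2", "d2",
    # STL1 expression and translation
    "k_s0", "K_rep", "k_s1", "d_ms", "ks_s", "kd_s",
    # Pfk26/27 activation and F26DP
    "PfkT", "k_a26", "k_i26", "k_f26", "K_f26s", "d_f26",
    # Fps1 gating and permeability
    "k_open", "k_cT", "k_cH", "k_fps",
    # lumped glycolysis and branches
    "kHXT", "KHXT", "VmHK", "KHK", "VmPFK", "KPFK", "aF", "KF26",
    "kALD", "VmLG", "KLG", "VmPDC", "KPDC", "VmALD6", "KALD6",
    "kcatGpd1", "kcatGpd2", "KGPD", "VmGPP", "KGPP",
    "kTPS0", "kTPSh", "KTPS", "kNTH",
    "k_tE", "k_tA", "k_tT",
    "VmSTL", "KSTL",
    # growth
    "mu0", "theta_H", "K_gH", "V_gmin", "gamma_bm", "K_bm")
}

#' Reference parameterization of the wild-type model
#'
#' The calibrated reference parameter set. All strain variants are derived
#' from this single set by the edits in [apply_strain()]; the calibration
#' procedure (staged tuning of the pre-stress steady state, then signalling
#' kinetics, then fluxes) is described in the methods vignette. Units:
#' volumes in fL, amounts in amol/cell, concentrations in mM, osmotic
#' pressures in Osm, NaCl in M, time in min, cell density in cells/mL.
#'
#' @param ... Named overrides of individual parameter values.
#' @return A named numeric vector of class `hog_params` with one entry per
#'   name in [hog_param_names()].
#' @examples
#' p <- hog_params()
#' p[["Pi_t0"]]
#' p2 <- hog_params(NaCl = NULL) # no such parameter: error
#' @export
hog_params <- function(...) {
  p <- c(
    # --- biophysics ---
    Vb = 20, Vos0 = 35, Lp_A = 20, Pi_t0 = 0.6, V_lp = 30.8,
    n0 = 32131, i_vh = 2, Pi_e0 = 0.25,
    # --- signalling ---
    Hog1tot = 0.01, k_ph = 2, k_dp = 0.15,
    # --- GPD1 ---
    k_b1 = 0.001, k_h1 = 40, k_o1 = 0.001, d_m1 = 0.15,
    ks1 = 10, kd1 = 0.01, k_dim = 0.05, k_undim = 1, kd1d = 0.005,
    # --- GPD2 ---
    k_b2 = 0.03, k_o2 = 0.12, d2 = 0.004,
    # --- STL1 ---
    k_s0 = 1e-6, K_rep = 5, k_s1 = 30, d_ms = 0.15, ks_s = 5, kd_s = 0.02,
    # --- Pfk26/27, F26DP ---
    PfkT = 0.02, k_a26 = 50, k_i26 = 0.05, k_f26 = 200, K_f26s = 5,
    d_f26 = 0.1,
    # --- Fps1 ---
    k_open = 0.08, k_cT = 0.1, k_cH = 2.5, k_fps = 3.2,
    # --- glycolysis and branches ---
    kHXT = 3027, KHXT = 1, VmHK = 4590, KHK = 0.5,
    VmPFK = 4764, KPFK = 5, aF = 1.5, KF26 = 0.5,
    kALD = 13.6, VmLG = 12500, KLG = 2,
    VmPDC = 9028, KPDC = 2, VmALD6 = 300, KALD6 = 2,
    kcatGpd1 = 12, kcatGpd2 = 10, KGPD = 1,
    VmGPP = 2000, KGPP = 9.5,
    kTPS0 = 100, kTPSh = 40000, KTPS = 5, kNTH = 0.043,
    k_tE = 1000, k_tA = 100, k_tT = 0.8,
    VmSTL = 4, KSTL = 2,
    # --- growth ---
    mu0 = log(2) / 120, theta_H = 0.35, K_gH = 0.002, V_gmin = 29,
    gamma_bm = 1.4e5, K_bm = 2
  )
  dots <- list(...)
  if (length(dots)) {
    nm <- names(dots)
    bad <- setdiff(nm, names(p))
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    p[nm] <- vapply(dots, function(x) as.numeric(x)[1], numeric(1))
  }
  validate_params(p)
  structure(p, class = c("hog_params", "numeric"))
}

#' @export
print.hog_params <- function(x, ...) {
  cat("<hog_params> ", length(x), " parameters\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

validate_params <- function(p) {
  stopifnot(is.numeric(p))
  nm <- hog_param_names()
  if (!identical(sort(names(p)), sort(nm))) {
    missing <- setdiff(nm, names(p))
    extra <- setdiff(names(p), nm)
    stop("parameter set must contain exactly the canonical names",
         if (length(missing)) paste0("; missing: ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unknown: ",
                                   paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  if (any(!is.finite(p))) {
    stop("non-finite parameter(s): ",
         paste(names(p)[!is.finite(p)], collapse = ", "), call. = FALSE)
  }
  if (any(p < 0)) {
    stop("negative parameter(s): ",
         paste(names(p)[p < 0], collapse = ", "), call. = FALSE)
  }
  th <- p[["theta_H"]]
  if (th < 0 || th > 1) stop("theta_H must lie in [0, 1]", call. = FALSE)
  invisible(p)
}

# canonical order, as a plain numeric vector for the compiled code
params_vector <- function(params) {
  as.numeric(params[hog_param_names()])
}

#' Convert parameters to/from JSON
#'
#' Round-trippable JSON serialization of a parameter set, used for
#' structured run configuration.
#'
#' @param params A `hog_params` vector.
#' @param path File path to write to / read from.
#' @return `write_params_json()` returns `path` invisibly;
#'   `read_params_json()` returns a `hog_params` vector.
#' @export
write_params_json <- function(params, path) {
  validate_params(params)
  jsonlite::write_json(as.list(unclass(params)[hog_param_names()]), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(hog_params, as.list(lst))
}

#' Default initial guess for the pre-stress state
#'
#' A physiologically sensible starting point for the pre-stress
#' equilibration: unstressed volume, fully dephosphorylated Hog1, open
#' Fps1, mid-exponential external medium (2% glucose, traces of
#' fermentation products) and a cell density of 1.5e7 cells/mL.
#'
#' @param params A `hog_params` vector.
#' @return Named numeric state vector of length 29.
#' @export
hog_initial_guess <- function(params = hog_params()) {
  p <- params
  s <- c(
    Vos = unname(p[["Vos0"]]),
    Hog1u = unname(p[["Hog1tot"]]), Hog1PP = 0,
    mGPD1 = 0.013, Gpd1m = 6, Gpd1d = 2, Gpd2 = 20,
    mSTL1 = 0.003, Stl1 = 0.7,
    Pfk26a = 0, F26DP = 0,
    Fps1o = 1,
    Glci = 35, HexP = 175, FBP = 175, TriP = 35, G3P = 19,
    Glyi = 1140, Pyr = 70, EtOHi = 508, AcOi = 70, Trei = 700,
    Glce = 110, Glye = 0.1, EtOHe = 10, AcOe = 0.5, Tree = 0.1,
    NaCle = 0,
    CD = 4e6
  )
  s[hog_state_names()]
}

validate_state <- function(state, tol = 1e-9) {
  nm <- hog_state_names()
  if (length(state) != 29L) {
    stop("state vector must have exactly 29 entries", call. = FALSE)
  }
  if (is.null(names(state))) names(state) <- nm
  state <- state[nm]
  if (any(!is.finite(state))) {
    stop("non-finite state entry at: ",
         paste(nm[!is.finite(state)], collapse = ", "), call. = FALSE)
  }
  neg <- state < -tol
  if (any(neg)) {
    stop("negative state entry at: ", paste(nm[neg], collapse = ", "),
         call. = FALSE)
  }
  if (state[["Vos"]] <= 0) stop("Vos must be positive", call. = FALSE)
  if (state[["CD"]] <= 0) stop("CD must be positive", call. = FALSE)
  if (state[["Fps1o"]] > 1 + tol) {
    stop("Fps1o must lie in [0, 1]", call. = FALSE)
  }
  state
}
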