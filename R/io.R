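measurement_columns <- function() {
  c("strain", "variable", "compartment", "time_min", "replicate",
    "value", "unit", "method")
}

#' Validate a measurement table
#'
#' Enforces the tidy measurement schema: required columns, known
#' variables and compartments, non-negative values, and uniqueness of
#' (strain, variable, time, replicate).
#'
#' @param data A data frame of measurements.
#' @return The validated tibble, invisibly.
#' @export
validate_measurement_table <- function(data) {
  miss <- setdiff(setdiff(measurement_columns(), "method"), names(data))
  if (length(miss)) {
    stop("measurement table lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  known <- measured_variables()$variable
  badv <- setdiff(unique(data$variable), known)
  if (length(badv)) {
    stop("unknown variable(s): ", paste(badv, collapse = ", "),
         call. = FALSE)
  }
  neg <- which(data$value < 0 | !is.finite(data$value))
  if (length(neg)) {
    stop("negative or non-finite value(s) at row(s): ",
         paste(head(neg, 10), collapse = ", "), call. = FALSE)
  }
  key <- paste(data$strain, data$variable, data$time_min, data$replicate)
  if (anyDuplicated(key)) {
    d <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop("duplicate (strain, variable, time, replicate) at rows: ",
         paste(head(d, 10), collapse = ", "), call. = FALSE)
  }
  invisible(tibble::as_tibble(data))
}

#' Read / write tidy time-course CSV
#'
#' The single tabular dialect of the package: UTF-8, comma-separated,
#' `.` decimal, with columns
#' `strain, variable, compartment, time_min, replicate, value, unit,
#' method`. Reading validates the schema and reports offending data
#' lines (1-based, counting the header).
#'
#' @param path CSV file path.
#' @return A validated measurement tibble.
#' @export
read_timecourse_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            strain = readr::col_character(),
                            variable = readr::col_character(),
                            compartment = readr::col_character(),
                            time_min = readr::col_double(),
                            replicate = readr::col_integer(),
                            value = readr::col_double(),
                            unit = readr::col_character(),
                            method = readr::col_character()
                          ))
  miss <- setdiff(setdiff(measurement_columns(), "method"), names(data))
  if (length(miss)) {
    stop("malformed header; missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  badrow <- function(i) paste(i + 1, collapse = ", ") # header offset
  badv <- which(!data$variable %in% measured_variables()$variable)
  if (length(badv)) {
    stop("unknown variable(s) ",
         paste(unique(data$variable[badv]), collapse = ", "),
         " at line(s): ", badrow(head(badv, 10)), call. = FALSE)
  }
  neg <- which(data$value < 0 | !is.finite(data$value))
  if (length(neg)) {
    stop("negative or non-finite value(s) at line(s): ",
         badrow(head(neg, 10)), call. = FALSE)
  }
  key <- paste(data$strain, data$variable, data$time_min, data$replicate)
  if (anyDuplicated(key)) {
    d <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop("duplicate (strain, variable, time, replicate) at lines: ",
         badrow(head(d, 10)), call. = FALSE)
  }
  data
}

#' @rdname read_timecourse_csv
#' @param data A measurement table.
#' @export
write_timecourse_csv <- function(data, path) {
  validate_measurement_table(data)
  readr::write_csv(data, path)
  invisible(path)
}

#' Write a trajectory to long CSV
#'
#' Columns `time_min, variable, value` (states, observables and fluxes).
#'
#' @param sim A `hog_sim` object.
#' @param path CSV path.
#' @export
write_trajectory_csv <- function(sim, path) {
  readr::write_csv(tidy(sim)[, c("time_min", "variable", "value")], path)
  invisible(path)
}

# ---- SBML export ------------------------------------------------------

# R expression (string) -> MathML. Supports + - * / ^, numbers, symbols,
# and min/max (rendered as piecewise), which covers every rate rule.
expr_to_mathml <- function(text) {
  walk <- function(e) {
    if (is.numeric(e)) {
      return(paste0("<cn> ", format(e, digits = 17), " </cn>"))
    }
    if (is.name(e)) return(paste0("<ci> ", as.character(e), " </ci>"))
    if (is.call(e)) {
      op <- as.character(e[[1]])
      args <- as.list(e)[-1]
      if (op == "(") return(walk(args[[1]]))
      if (op == "-" && length(args) == 1) {
        return(paste0("<apply><minus/>", walk(args[[1]]), "</apply>"))
      }
      fun <- switch(op, "+" = "plus", "-" = "minus", "*" = "times",
                    "/" = "divide", "^" = "power", NA_character_)
      if (!is.na(fun)) {
        return(paste0("<apply><", fun, "/>",
                      paste(vapply(args, walk, character(1)),
                            collapse = ""), "</apply>"))
      }
      if (op %in% c("min", "max")) {
        a <- walk(args[[1]]); b <- walk(args[[2]])
        rel <- if (op == "min") "lt" else "gt"
        return(paste0("<piecewise><piece>", a, "<apply><", rel, "/>", a, b,
                      "</apply></piece><otherwise>", b,
                      "</otherwise></piecewise>"))
      }
      stop("cannot render '", op, "' as MathML", call. = FALSE)
    }
    stop("unsupported expression element", call. = FALSE)
  }
  paste0("<math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
         walk(str2lang(text)), "</math>")
}

sbml_rate_laws <- function(hog1_present) {
  hterm <- if (hog1_present) "k_cH * Hog1PP / Hog1tot" else "0"
  c(
    vHXT = "kHXT * Glce / (KHXT + Glce)",
    vHK = "VmHK * (Glci/Vos) / (KHK + Glci/Vos)",
    vPFK = paste("VmPFK * (1 + aF * (F26DP/Vos) / (KF26 + F26DP/Vos)) *",
                 "(HexP/Vos) / (KPFK + HexP/Vos)"),
    vALD = "kALD * FBP",
    vLG = "VmLG * (TriP/Vos) / (KLG + TriP/Vos)",
    vPDC = "VmPDC * (Pyr/Vos) / (KPDC + Pyr/Vos)",
    vALD6 = "VmALD6 * (Pyr/Vos) / (KALD6 + Pyr/Vos)",
    vGPD1 = "kcatGpd1 * Gpd1d * (TriP/Vos) / (KGPD + TriP/Vos)",
    vGPD2 = "kcatGpd2 * Gpd2 * (TriP/Vos) / (KGPD + TriP/Vos)",
    vGPP = "VmGPP * (G3P/Vos) / (KGPP + G3P/Vos)",
    vTPS = "(kTPS0 + kTPSh * Hog1PP) * (HexP/Vos) / (KTPS + HexP/Vos)",
    vNTH = "kNTH * Trei",
    vFPS = "k_fps * Fps1o * (Glyi/Vos - Glye)",
    vSTL = "VmSTL * Stl1 * Glye / (KSTL + Glye)",
    vEtOHt = "k_tE * (EtOHi/Vos - EtOHe)",
    vAcOt = "k_tA * (AcOi/Vos - AcOe)",
    vTret = "k_tT * (Trei/Vos - Tree)",
    vBM = "gamma_bm * mu * (HexP/Vos) / (K_bm + HexP/Vos)",
    vPH = "k_ph * u * Hog1u",
    vDP = "k_dp * Hog1PP",
    hterm_fps = hterm
  )
}

sbml_observable_rules <- function() {
  c(
    Pi_i = paste("0.001 * (n0 + Glci + HexP + FBP + TriP + G3P + Glyi +",
                 "Pyr + EtOHi + AcOi + Trei) / Vos"),
    Pi_e = paste("Pi_e0 + i_vh * NaCle +",
                 "0.001 * (Glce + Glye + EtOHe + AcOe + Tree)"),
    Pi_t = "min(max(Pi_t0 * (Vos - V_lp) / (Vos0 - V_lp), 0), Pi_t0)",
    u = "max(0, (Pi_t0 - Pi_t) / Pi_t0)",
    mu = paste("mu0 * min(max((Vos - V_gmin) / (Vos0 - V_gmin), 0), 1) *",
               "(1 - theta_H * Hog1PP / (K_gH + Hog1PP))")
  )
}

sbml_rate_rules <- function(laws) {
  c(
    Vos = "Lp_A * (Pi_i - Pi_e - Pi_t)",
    Hog1u = "0 - vPH + vDP + mu * (Hog1tot - Hog1u)",
    Hog1PP = "vPH - vDP - mu * Hog1PP",
    mGPD1 = "k_b1 + k_h1 * Hog1PP + k_o1 * u - (d_m1 + mu) * mGPD1",
    Gpd1m = paste("ks1 * mGPD1 - kd1 * Gpd1m - 2 * k_dim * Gpd1m^2 +",
                  "2 * k_undim * Gpd1d - mu * Gpd1m"),
    Gpd1d = paste("k_dim * Gpd1m^2 - k_undim * Gpd1d - kd1d * Gpd1d -",
                  "mu * Gpd1d"),
    Gpd2 = "k_b2 + k_o2 * u - (d2 + mu) * Gpd2",
    mSTL1 = paste("k_s0 * K_rep / (K_rep + Glce) + k_s1 * Hog1PP -",
                  "(d_ms + mu) * mSTL1"),
    Stl1 = "ks_s * mSTL1 - (kd_s + mu) * Stl1",
    Pfk26a = "k_a26 * Hog1PP * (PfkT - Pfk26a) - k_i26 * Pfk26a",
    F26DP = paste("k_f26 * Pfk26a * (HexP/Vos) / (K_f26s + HexP/Vos) -",
                  "(d_f26 + mu) * F26DP"),
    Fps1o = paste0("k_open * (1 - Fps1o) - (k_cT * u + ",
                   laws[["hterm_fps"]], ") * Fps1o"),
    Glci = "vHXT - vHK + 2 * vNTH - mu * Glci",
    HexP = "vHK - vPFK - 2 * vTPS - vBM - mu * HexP",
    FBP = "vPFK - vALD - mu * FBP",
    TriP = "2 * vALD - vLG - vGPD1 - vGPD2 - mu * TriP",
    G3P = "vGPD1 + vGPD2 - vGPP - mu * G3P",
    Glyi = "vGPP - vFPS + vSTL - mu * Glyi",
    Pyr = "vLG - vPDC - vALD6 - mu * Pyr",
    EtOHi = "vPDC - vEtOHt - mu * EtOHi",
    AcOi = "vALD6 - vAcOt - mu * AcOi",
    Trei = "vTPS - vNTH - vTret - mu * Trei",
    Glce = "0 - CD * 1e-12 * vHXT",
    Glye = "CD * 1e-12 * (vFPS - vSTL)",
    EtOHe = "CD * 1e-12 * vEtOHt",
    AcOe = "CD * 1e-12 * vAcOt",
    Tree = "CD * 1e-12 * vTret",
    NaCle = "0",
    CD = "mu * CD"
  )
}

#' Export a strain model as SBML Level 3 Version 1
#'
#' Serializes the (strain-edited) model: all 29 state variables as
#' species with their equilibrated initial values, every kinetic and
#' biophysical parameter under its canonical name, per-cell reaction
#' rates and algebraic observables as assignment-ruled parameters, the
#' full dynamics as rate rules, and the NaCl step as a timed event. The
#' output is deterministic: identical inputs give byte-identical
#' documents.
#'
#' @param params Wild-type `hog_params`.
#' @param strain Strain name or spec (`NULL`: export `params` as given).
#' @param path Optional file to write.
#' @param protocol Stress protocol encoded in the event.
#' @return The SBML document as a single character string (invisibly if
#'   `path` is given).
#' @export
export_sbml <- function(params, strain = "WT", path = NULL,
                        protocol = stress_protocol()) {
  if (!is.null(strain)) params <- apply_strain(params, strain)
  strain_name <- attr(params, "strain") %||% "custom"
  init <- prestress_equilibrate(params)
  model_id <- gsub("[^A-Za-z0-9_]", "_",
                   paste0("osmoadaptation_", strain_name))
  num <- function(x) format(x, digits = 17)

  sp <- vapply(hog_state_names(), function(n) {
    paste0("      <species id=\"", n, "\" compartment=\"cell\"",
           " initialAmount=\"", num(unname(init[[n]])), "\"",
           " hasOnlySubstanceUnits=\"true\" boundaryCondition=\"true\"",
           " constant=\"false\"/>")
  }, character(1))

  par <- vapply(hog_param_names(), function(n) {
    paste0("      <parameter id=\"", n, "\" value=\"",
           num(unname(params[[n]])), "\" constant=\"true\"/>")
  }, character(1))
  laws <- sbml_rate_laws(hog1_present = params[["Hog1tot"]] > 0)
  derived <- c(sbml_observable_rules(),
               laws[setdiff(names(laws), "hterm_fps")])
  dpar <- vapply(names(derived), function(n) {
    paste0("      <parameter id=\"", n, "\" value=\"0\"",
           " constant=\"false\"/>")
  }, character(1))

  arules <- vapply(names(derived), function(n) {
    paste0("      <assignmentRule variable=\"", n, "\">",
           expr_to_mathml(derived[[n]]), "</assignmentRule>")
  }, character(1))
  rr <- sbml_rate_rules(laws)
  rrules <- vapply(names(rr), function(n) {
    paste0("      <rateRule variable=\"", n, "\">",
           expr_to_mathml(rr[[n]]), "</rateRule>")
  }, character(1))

  event <- paste0(
    "      <event id=\"NaCl_step\" useValuesFromTriggerTime=\"true\">\n",
    "        <trigger initialValue=\"false\" persistent=\"true\">",
    "<math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
    "<apply><geq/><csymbol encoding=\"text\" definitionURL=",
    "\"http://www.sbml.org/sbml/symbols/time\"> t </csymbol>",
    "<cn> ", num(protocol$t_stress), " </cn></apply></math></trigger>\n",
    "        <listOfEventAssignments>\n",
    "          <eventAssignment variable=\"NaCle\">",
    expr_to_mathml(format(protocol$NaCl_step, digits = 17)),
    "</eventAssignment>\n",
    "        </listOfEventAssignments>\n",
    "      </event>")

  doc <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\"",
    " level=\"3\" version=\"1\">\n",
    "  <model id=\"", model_id, "\" name=\"", model_id, "\"",
    " timeUnits=\"time\" extentUnits=\"substance\">\n",
    "    <listOfUnitDefinitions>\n",
    "      <unitDefinition id=\"time\"><listOfUnits>",
    "<unit kind=\"second\" exponent=\"1\" scale=\"0\"",
    " multiplier=\"60\"/></listOfUnits></unitDefinition>\n",
    "      <unitDefinition id=\"substance\"><listOfUnits>",
    "<unit kind=\"mole\" exponent=\"1\" scale=\"-18\"",
    " multiplier=\"1\"/></listOfUnits></unitDefinition>\n",
    "    </listOfUnitDefinitions>\n",
    "    <listOfCompartments>\n",
    "      <compartment id=\"cell\" spatialDimensions=\"3\"",
    " size=\"1\" constant=\"true\"/>\n",
    "      <compartment id=\"medium\" spatialDimensions=\"3\"",
    " size=\"1\" constant=\"true\"/>\n",
    "    </listOfCompartments>\n",
    "    <listOfSpecies>\n", paste(sp, collapse = "\n"), "\n",
    "    </listOfSpecies>\n",
    "    <listOfParameters>\n", paste(par, collapse = "\n"), "\n",
    paste(dpar, collapse = "\n"), "\n",
    "    </listOfParameters>\n",
    "    <listOfRules>\n", paste(arules, collapse = "\n"), "\n",
    paste(rrules, collapse = "\n"), "\n",
    "    </listOfRules>\n",
    "    <listOfEvents>\n", event, "\n",
    "    </listOfEvents>\n",
    "  </model>\n",
    "</sbml>\n")
  if (!is.null(path)) {
    writeLines(doc, path, useBytes = TRUE)
    return(invisible(doc))
  }
  doc
}
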