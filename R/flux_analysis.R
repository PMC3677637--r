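#' Decompose the net intracellular glycerol flux
#'
#' Splits `d(cGlyi)/dt` (mM/min) into three mechanistic contributions:
#' \itemize{
#' \item `J_Gpd1`: Gpd1-attributed production — the glycerol-3-phosphatase
#'   flux attributed to Gpd1 in proportion to the upstream Gpd1-dimer vs
#'   Gpd2 dehydrogenase shares;
#' \item `J_Fps1`: channel exchange, `-vFPS / Vos` (influx positive);
#' \item `J_Others`: Gpd2-attributed production, Stl1 uptake, growth
#'   dilution, and the concentration effect of volume change
#'   `-cGlyi * (dVos/dt) / Vos`.
#' }
#' The three components sum to `d(cGlyi)/dt` identically. Relative
#' magnitudes `r_i = |J_i| / sum|J|` render both efflux and influx phases
#' on the ternary simplex.
#'
#' @param sim A `hog_sim` object.
#' @return Tibble with time, the three components, their sum, `dcGlyi`
#'   (from the model right-hand side), the relative magnitudes and a
#'   degeneracy flag for all-zero instants.
#' @export
decompose_glycerol_flux <- function(sim) {
  stopifnot(inherits(sim, "hog_sim"))
  need <- c("vGPD1", "vGPD2", "vGPP", "vFPS", "vSTL")
  if (!all(need %in% colnames(sim$flux))) {
    stop("simulation lacks flux columns: ",
         paste(setdiff(need, colnames(sim$flux)), collapse = ", "),
         call. = FALSE)
  }
  Vos <- sim$state[, "Vos"]
  cGlyi <- sim$obs[, "cGlyi"]
  mu <- sim$obs[, "mu"]
  dVos <- sim$deriv[, "dVos"]
  v1 <- sim$flux[, "vGPD1"]; v2 <- sim$flux[, "vGPD2"]
  tot12 <- v1 + v2
  share1 <- ifelse(tot12 > 0, v1 / tot12, 0)
  vGPP <- sim$flux[, "vGPP"]
  J_Gpd1 <- share1 * vGPP / Vos
  J_Fps1 <- -sim$flux[, "vFPS"] / Vos
  J_Others <- (1 - share1) * vGPP / Vos + sim$flux[, "vSTL"] / Vos -
    mu * cGlyi - cGlyi * dVos / Vos
  dcGlyi <- (sim$deriv[, "dGlyi"] - cGlyi * dVos) / Vos
  absum <- abs(J_Gpd1) + abs(J_Fps1) + abs(J_Others)
  zero <- absum == 0
  denom <- ifelse(zero, 1, absum)
  tibble::tibble(
    strain = sim$strain,
    time_min = sim$times,
    J_Gpd1 = J_Gpd1, J_Fps1 = J_Fps1, J_Others = J_Others,
    dcGlyi = dcGlyi,
    r_Gpd1 = ifelse(zero, 1 / 3, abs(J_Gpd1) / denom),
    r_Fps1 = ifelse(zero, 1 / 3, abs(J_Fps1) / denom),
    r_Others = ifelse(zero, 1 / 3, abs(J_Others) / denom),
    degenerate = zero
  )
}

#' Ternary coordinates of the flux decomposition
#'
#' @param decomp Output of [decompose_glycerol_flux()], or any tibble
#'   with `r_Fps1`, `r_Gpd1`, `r_Others` columns.
#' @return Tibble `(time_min, r_Fps1, r_Gpd1, r_Others, degenerate)`;
#'   each triple is non-negative and sums to one, with all-zero instants
#'   emitted as the centroid and flagged.
#' @export
ternary_coordinates <- function(decomp) {
  stopifnot(all(c("r_Fps1", "r_Gpd1", "r_Others") %in% names(decomp)))
  tibble::tibble(
    time_min = decomp$time_min,
    r_Fps1 = decomp$r_Fps1,
    r_Gpd1 = decomp$r_Gpd1,
    r_Others = decomp$r_Others,
    degenerate = decomp$degenerate %||% FALSE
  )
}

#' Ternary plot of relative glycerol-flux contributions
#'
#' Projects the simplex onto the plane (Fps1 left, Gpd1 right, Others
#' top), colouring the trajectory by time.
#'
#' @param coords Output of [ternary_coordinates()] (or a decomposition).
#' @return A ggplot object.
#' @export
plot_ternary <- function(coords) {
  if (!"r_Fps1" %in% names(coords)) coords <- ternary_coordinates(coords)
  xy <- tibble::tibble(
    time_min = coords$time_min,
    x = coords$r_Gpd1 + 0.5 * coords$r_Others,
    y = sqrt(3) / 2 * coords$r_Others
  )
  tri <- data.frame(x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0))
  lab <- data.frame(x = c(-0.03, 1.03, 0.5), y = c(-0.04, -0.04,
                                                   sqrt(3) / 2 + 0.05),
                    txt = c("Fps1", "Gpd1", "Others"))
  ggplot2::ggplot(xy, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(data = tri, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$time_min), size = 1) +
    ggplot2::scale_colour_viridis_c(name = "time (min)") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Doubling time from a cell-density window
#'
#' `ln(2)` divided by the slope of a least-squares fit of `ln(CD)`
#' against time on the window.
#'
#' @param sim A `hog_sim` object (its grid must cover the window with at
#'   least three points).
#' @param window Numeric `c(t0, t1)` in minutes.
#' @return Doubling time (min).
#' @export
doubling_time <- function(sim, window = c(0, 90)) {
  stopifnot(inherits(sim, "hog_sim"), length(window) == 2)
  keep <- sim$times >= window[1] & sim$times <= window[2]
  if (sum(keep) < 3) {
    stop("window must contain at least 3 grid points", call. = FALSE)
  }
  t <- sim$times[keep]
  cd <- sim$state[keep, "CD"]
  if (any(cd <= 0)) stop("CD must be positive on the window", call. = FALSE)
  slope <- unname(coef(lm(log(cd) ~ t))[2])
  log(2) / slope
}

#' Carbon shares of glucose uptake
#'
#' Carbon-weighted shares of the glucose-uptake carbon flux routed to the
#' biomass drain, the glycerol branch (dehydrogenase steps) and lower
#' glycolysis (towards pyruvate/ethanol/acetate), at one time point. The
#' remainder (`pool_change_share`) is carbon accumulating in (or drawn
#' from) the glycolytic and storage pools, including growth dilution.
#' The four shares sum to one exactly.
#'
#' @param sim A `hog_sim` object.
#' @param t Time (min), must be on the simulation grid.
#' @return One-row tibble of shares.
#' @export
flux_shares <- function(sim, t) {
  stopifnot(inherits(sim, "hog_sim"))
  i <- match(t, sim$times)
  if (is.na(i)) stop("time ", t, " not on the simulation grid",
                     call. = FALSE)
  v <- sim$flux[i, ]
  cin <- 6 * v[["vHXT"]]
  if (abs(cin) < 1e-12) {
    stop("glucose uptake is zero; shares undefined", call. = FALSE)
  }
  bm <- 6 * v[["vBM"]] / cin
  gly <- 3 * (v[["vGPD1"]] + v[["vGPD2"]]) / cin
  lg <- 3 * v[["vLG"]] / cin
  tibble::tibble(
    strain = sim$strain, time_min = t,
    biomass_share = bm, glycerol_share = gly,
    ethanol_acetate_share = lg,
    pool_change_share = 1 - bm - gly - lg
  )
}
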