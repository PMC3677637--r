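# parameter vector for the compiled rhs: canonical order + freeze flag
pvec_c <- function(params, freeze = 0) {
  c(params_vector(params), as.numeric(freeze))
}

rhs_c <- function(t, y, params, freeze = 0) {
  .Call(C_hog_deriv, as.numeric(t), as.numeric(y), pvec_c(params, freeze))
}

rhs_c_full <- function(t, y, params, freeze = 0) {
  .Call(C_hog_rhs_full, as.numeric(t), as.numeric(y),
        pvec_c(params, freeze))
}

integrate_c <- function(y0, times, params, rtol = 1e-8, atol = 1e-10,
                        freeze = 0, quiet = FALSE) {
  run <- function() {
    deSolve::ode(y = y0, times = times, func = "osmo_derivs",
                 parms = pvec_c(params, freeze), dllname = "hogadapt",
                 initfunc = "osmo_initmod", method = "lsoda",
                 rtol = rtol, atol = atol, maxsteps = 50000)
  }
  out <- if (quiet) suppressWarnings(run()) else run()
  if (nrow(out) < length(times)) {
    stop("integration failed; last valid time ",
         signif(out[nrow(out), 1], 6), " min", call. = FALSE)
  }
  out
}

#' Stress protocol
#'
#' A single hyperosmotic step: NaCl added to `NaCl_step` mol/L at
#' `t_stress`, output sampled on `t_grid` (default 1-min resolution from
#' `min(0, t_stress)` to `t_end`).
#'
#' @param t_stress Time of the salt step (min).
#' @param NaCl_step Added NaCl concentration (M).
#' @param t_end End of the simulation horizon (min).
#' @param t_grid Optional strictly increasing sample-time vector.
#' @return A `hog_protocol` list.
#' @export
stress_protocol <- function(t_stress = 0, NaCl_step = 0.4, t_end = 180,
                            t_grid = NULL) {
  if (is.null(t_grid)) t_grid <- seq(min(0, t_stress), t_end, by = 1)
  if (any(diff(t_grid) <= 0)) {
    stop("t_grid must be strictly increasing", call. = FALSE)
  }
  if (NaCl_step < 0) stop("NaCl_step must be >= 0", call. = FALSE)
  structure(list(t_stress = t_stress, NaCl_step = NaCl_step,
                 t_end = t_end, t_grid = t_grid),
            class = "hog_protocol")
}

#' Pre-stress equilibration
#'
#' Finds the adapted pre-stress state: external pools, NaCl and cell
#' density are held at their configured values while the intracellular
#' states are brought to a fixed point (long frozen-medium integration
#' followed by a damped Newton polish with a finite-difference Jacobian).
#'
#' @param params A `hog_params` vector (possibly strain-edited).
#' @param guess Initial full state guess; defaults to
#'   [hog_initial_guess()] with any strain-pinned states applied.
#' @param tol Convergence tolerance on `|dX/dt| / max(|X|, 1)`.
#' @param t_settle Length of the settling integration (min).
#' @param newton_first Try the Newton polish from `guess` before the
#'   settling integration (fast path for parameter fitting).
#' @return Named 29-entry state vector at the fixed point.
#' @export
prestress_equilibrate <- function(params, guess = NULL, tol = 1e-8,
                                  t_settle = 3000, newton_first = FALSE) {
  pinned <- attr(params, "pinned_states")
  if (is.null(guess)) guess <- hog_initial_guess(params)
  guess <- guess[hog_state_names()]
  guess[["NaCle"]] <- 0
  if (length(pinned)) guess[names(pinned)] <- pinned
  # gpd1-like variants: start the zeroed expression branch at zero
  if (params[["k_b1"]] == 0 && params[["k_h1"]] == 0 &&
      params[["k_o1"]] == 0) {
    guess[c("mGPD1", "Gpd1m", "Gpd1d")] <- 0
  }
  if (params[["Hog1tot"]] == 0) guess[c("Hog1u", "Hog1PP")] <- 0

  free <- setdiff(hog_state_names()[1:22], names(pinned))

  resid <- function(y) rhs_c(0, y, params, freeze = 1)[seq_len(22)][
    match(free, hog_state_names()[1:22])]
  relres <- function(y) {
    f <- rhs_c(0, y, params, freeze = 1)
    max(abs(f[seq_len(22)]) / pmax(abs(y[seq_len(22)]), 1))
  }

  newton <- function(y) {
    idx <- match(free, hog_state_names())
    for (it in seq_len(40)) {
      f <- resid(y)
      if (max(abs(f) / pmax(abs(y[idx]), 1)) < tol) return(y)
      J <- matrix(0, length(idx), length(idx))
      for (j in seq_along(idx)) {
        h <- 1e-6 * max(abs(y[idx[j]]), 1e-4)
        yp <- y; yp[idx[j]] <- yp[idx[j]] + h
        ym <- y; ym[idx[j]] <- ym[idx[j]] - h
        J[, j] <- (resid(yp) - resid(ym)) / (2 * h)
      }
      step <- tryCatch(solve(J, -f), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) return(NULL)
      lam <- 1
      repeat {
        ytry <- y
        ytry[idx] <- y[idx] + lam * step
        ok <- all(is.finite(ytry)) && ytry[["Vos"]] > 0 &&
          all(ytry[idx] > -1e-9)
        if (ok && relres(ytry) < relres(y) * (1 - 1e-4 * lam) + 1e-300) {
          y <- ytry; break
        }
        lam <- lam / 2
        if (lam < 1e-6) { # accept anyway; settling pass will help
          y[idx] <- pmax(y[idx] + 1e-6 * step, 0)
          break
        }
      }
    }
    if (relres(y) < tol) y else NULL
  }

  y <- guess
  if (newton_first) {
    yn <- newton(y)
    if (!is.null(yn)) return(finish_equilibrium(yn, pinned))
  }
  out <- integrate_c(y, c(0, t_settle / 2, t_settle), params,
                     rtol = 1e-9, atol = 1e-11, freeze = 1, quiet = TRUE)
  y <- out[nrow(out), 1 + seq_len(29)]
  names(y) <- hog_state_names()
  y[seq_len(22)] <- pmax(y[seq_len(22)], 0)
  yn <- newton(y)
  if (is.null(yn)) {
    r <- relres(y)
    if (r < 1e-6) {
      warning("equilibration converged to relative residual ", signif(r, 3))
      yn <- y
    } else {
      stop("pre-stress equilibration failed; relative residual ",
           signif(r, 3), call. = FALSE)
    }
  }
  finish_equilibrium(yn, pinned)
}

finish_equilibrium <- function(y, pinned) {
  if (length(pinned)) y[names(pinned)] <- pinned
  y[["NaCle"]] <- 0
  y
}

#' Simulate a strain through the osmotic-stress protocol
#'
#' Equilibrates the pre-stress state, integrates the stiff ODE system to
#' the stress time, applies the NaCl step with a solver restart (no
#' discontinuity smoothing), and integrates to the end of the protocol.
#' States, algebraic observables, per-cell reaction fluxes and state
#' derivatives are recorded on the protocol's time grid.
#'
#' @param params A `hog_params` vector (wild type).
#' @param strain A strain name, `hog_strain` spec, or `NULL` to simulate
#'   `params` as given.
#' @param protocol A [stress_protocol()].
#' @param init Optional pre-equilibrated initial state (skips
#'   equilibration; used heavily by the fitting loop).
#' @param rtol,atol Solver tolerances.
#' @return A `hog_sim` object; see [tidy.hog_sim()] / `as_tibble()`.
#' @export
hog_simulate <- function(params, strain = "WT",
                         protocol = stress_protocol(), init = NULL,
                         rtol = 1e-8, atol = 1e-10) {
  if (!is.null(strain)) {
    params <- apply_strain(params, strain)
  }
  strain_name <- attr(params, "strain") %||% "custom"
  tg <- protocol$t_grid
  ts <- protocol$t_stress
  if (is.null(init)) init <- prestress_equilibrate(params)
  y0 <- init[hog_state_names()]

  pre_t <- tg[tg < ts]
  post_t <- tg[tg >= ts]
  states <- NULL

  if (length(pre_t)) {
    times1 <- unique(c(pre_t, ts))
    out1 <- integrate_c(y0, times1, params, rtol, atol)
    y_at_stress <- out1[nrow(out1), 1 + seq_len(29)]
    states <- out1[out1[, 1] < ts, , drop = FALSE]
  } else {
    y_at_stress <- y0
  }
  names(y_at_stress) <- hog_state_names()

  y_post <- y_at_stress
  y_post[["NaCle"]] <- y_post[["NaCle"]] + protocol$NaCl_step
  if (length(post_t)) {
    times2 <- unique(c(ts, post_t))
    out2 <- integrate_c(y_post, times2, params, rtol, atol)
    keep <- out2[, 1] %in% post_t
    states <- rbind(states, out2[keep, , drop = FALSE])
  }
  times <- states[, 1]
  sm <- states[, -1, drop = FALSE]
  colnames(sm) <- hog_state_names()

  nf <- length(hog_flux_names())
  obs <- matrix(NA_real_, nrow(sm), 17)
  flux <- matrix(NA_real_, nrow(sm), nf)
  deriv <- matrix(NA_real_, nrow(sm), 29)
  for (i in seq_len(nrow(sm))) {
    r <- rhs_c_full(times[i], sm[i, ], params)
    deriv[i, ] <- r$deriv
    flux[i, ] <- r$flux
    obs[i, ] <- r$obs
  }
  colnames(obs) <- c("Vtot", "Pi_i", "Pi_e", "Pi_t", "u", "mu", "Gpd1tot",
                     paste0("c", c("Glci", "HexP", "FBP", "TriP", "G3P",
                                   "Glyi", "Pyr", "EtOHi", "AcOi", "Trei")))
  colnames(flux) <- hog_flux_names()
  colnames(deriv) <- paste0("d", hog_state_names())

  structure(list(strain = strain_name, params = params,
                 protocol = protocol, times = times,
                 state = sm, obs = obs, flux = flux, deriv = deriv),
            class = "hog_sim")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hog_sim <- function(x, ...) {
  cat("<hog_sim> strain ", x$strain, ", ", length(x$times),
      " time points (", min(x$times), "..", max(x$times), " min), ",
      "NaCl step ", x$protocol$NaCl_step, " M at t = ",
      x$protocol$t_stress, "\n", sep = "")
  invisible(x)
}

#' Wide tibble view of a simulation
#' @param x A `hog_sim` object.
#' @param ... Unused.
#' @return Tibble with `time_min`, all states, observables and fluxes.
#' @export
as_tibble.hog_sim <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(strain = x$strain, time_min = x$times),
    tibble::as_tibble(x$state), tibble::as_tibble(x$obs),
    tibble::as_tibble(x$flux)
  )
}

#' Tidy a simulation into long format
#'
#' @param x A `hog_sim` object.
#' @param ... Unused.
#' @return Tibble with columns `strain`, `time_min`, `variable`, `value`,
#'   `kind` (state / observable / flux).
#' @export
tidy.hog_sim <- function(x, ...) {
  long <- function(m, kind) {
    tibble::as_tibble(m) |>
      dplyr::mutate(time_min = x$times, .before = 1) |>
      tidyr::pivot_longer(-"time_min", names_to = "variable",
                          values_to = "value") |>
      dplyr::mutate(kind = kind)
  }
  dplyr::bind_rows(long(x$state, "state"), long(x$obs, "observable"),
                   long(x$flux, "flux")) |>
    dplyr::mutate(strain = x$strain, .before = 1)
}

# pull one column (state, observable or flux) as a numeric vector
sim_value <- function(sim, var) {
  for (m in list(sim$state, sim$obs, sim$flux, sim$deriv)) {
    if (var %in% colnames(m)) return(m[, var])
  }
  stop("unknown simulation variable: ", var, call. = FALSE)
}

#' Plot key variables of a simulation
#'
#' @param object A `hog_sim` object.
#' @param vars Variables to facet (states, observables or fluxes).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hog_sim <- function(object,
                             vars = c("Hog1PP", "cGlyi", "Fps1o", "Vtot",
                                      "Glce", "CD"),
                             ...) {
  df <- purrr::map_dfr(vars, function(v) {
    tibble::tibble(time_min = object$times, variable = v,
                   value = sim_value(object, v))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$time_min, .data$value)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time after stress (min)", y = NULL,
                  title = paste("Strain", object$strain)) +
    ggplot2::theme_minimal()
}
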