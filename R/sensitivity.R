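#' Forward sensitivities of the model trajectory
#'
#' Solves the forward sensitivity equations `dS/dt = J(t) S + df/dq`
#' along the simulated trajectory, with the Jacobian `J` obtained by
#' central finite differences of the right-hand side (relative step
#' 1e-6). Initial sensitivities account for the parameter dependence of
#' the equilibrated pre-stress state (re-equilibration differencing);
#' `init_sens = "zero"` starts from `S(0) = 0` instead.
#'
#' The pseudo-parameter `"NaCl_step"` (the stress magnitude) is
#' supported: its sensitivity is zero before the step and enters through
#' the stepped NaCl state at the stress event. A parameter whose value
#' is exactly zero in the (strain-edited) model is treated as
#' structurally absent and its sensitivities are identically zero.
#'
#' @param params Wild-type `hog_params`.
#' @param strain Strain name or spec (`NULL` to use `params` as given).
#' @param protocol A [stress_protocol()].
#' @param param_subset Character vector of parameter names (may include
#'   `"NaCl_step"`).
#' @param init_sens `"equilibrium"` (default) or `"zero"`.
#' @param rtol,atol Tolerances for the augmented system.
#' @return A `hog_sens` object: times, state matrix, array
#'   `S[time, state, parameter]`, parameter values, and the underlying
#'   simulation.
#' @export
compute_sensitivities <- function(params, strain = "WT",
                                  protocol = stress_protocol(),
                                  param_subset,
                                  init_sens = c("equilibrium", "zero"),
                                  rtol = 1e-7, atol = 1e-9) {
  init_sens <- match.arg(init_sens)
  if (length(param_subset) < 1) {
    stop("param_subset must be non-empty", call. = FALSE)
  }
  bad <- setdiff(param_subset, c(hog_param_names(), "NaCl_step"))
  if (length(bad)) stop("unknown parameter(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(strain)) params <- apply_strain(params, strain)
  P <- length(param_subset)
  qvals <- vapply(param_subset, function(q) {
    if (q == "NaCl_step") protocol$NaCl_step else unname(params[[q]])
  }, numeric(1))

  eq <- prestress_equilibrate(params)
  S0 <- matrix(0, 29, P)
  if (init_sens == "equilibrium") {
    for (j in seq_len(P)) {
      q <- param_subset[j]
      if (q == "NaCl_step" || qvals[j] == 0) next
      dq <- 1e-3 * qvals[j]
      pp <- params; pp[[q]] <- qvals[j] + dq
      pm <- params; pm[[q]] <- qvals[j] - dq
      ep <- prestress_equilibrate(pp, guess = eq, newton_first = TRUE)
      em <- prestress_equilibrate(pm, guess = eq, newton_first = TRUE)
      S0[, j] <- (ep - em) / (2 * dq)
    }
  }

  pv0 <- pvec_c(params, 0)
  # perturbed parameter vectors for df/dq, fixed across the run
  pidx <- match(param_subset, hog_param_names())
  pvp <- pvm <- vector("list", P)
  hq <- numeric(P)
  for (j in seq_len(P)) {
    if (param_subset[j] == "NaCl_step" || qvals[j] == 0) next
    hq[j] <- 1e-6 * qvals[j]
    pp <- pv0; pp[pidx[j]] <- pp[pidx[j]] + hq[j]
    pm <- pv0; pm[pidx[j]] <- pm[pidx[j]] - hq[j]
    pvp[[j]] <- pp; pvm[[j]] <- pm
  }

  aug_rhs <- function(t, yaug, dummy) {
    y <- yaug[seq_len(29)]
    S <- matrix(yaug[-seq_len(29)], 29, P)
    f0 <- .Call(C_hog_deriv, t, y, pv0)
    J <- matrix(0, 29, 29)
    for (k in seq_len(29)) {
      h <- 1e-6 * max(abs(y[k]), 1e-6)
      yp <- y; yp[k] <- yp[k] + h
      ym <- y; ym[k] <- ym[k] - h
      J[, k] <- (.Call(C_hog_deriv, t, yp, pv0) -
                   .Call(C_hog_deriv, t, ym, pv0)) / (2 * h)
    }
    dS <- J %*% S
    for (j in seq_len(P)) {
      if (is.null(pvp[[j]])) next
      dS[, j] <- dS[, j] +
        (.Call(C_hog_deriv, t, y, pvp[[j]]) -
           .Call(C_hog_deriv, t, y, pvm[[j]])) / (2 * hq[j])
    }
    list(c(f0, as.vector(dS)))
  }

  tg <- protocol$t_grid
  ts <- protocol$t_stress
  pre_t <- tg[tg < ts]
  post_t <- tg[tg >= ts]
  yaug <- c(eq[hog_state_names()], as.vector(S0))

  rows_t <- numeric(0)
  rows <- NULL
  if (length(pre_t)) {
    times1 <- unique(c(pre_t, ts))
    o1 <- deSolve::ode(yaug, times1, aug_rhs, NULL, method = "lsoda",
                       rtol = rtol, atol = atol, maxsteps = 50000)
    if (nrow(o1) < length(times1)) stop("sensitivity integration failed",
                                        call. = FALSE)
    keep <- o1[, 1] < ts
    rows <- o1[keep, -1, drop = FALSE]
    rows_t <- o1[keep, 1]
    yaug <- o1[nrow(o1), -1]
  }
  # stress event: step NaCl, add event sensitivity for NaCl_step
  i_na <- match("NaCle", hog_state_names())
  yaug[i_na] <- yaug[i_na] + protocol$NaCl_step
  for (j in seq_len(P)) {
    if (param_subset[j] == "NaCl_step") {
      yaug[29 + (j - 1) * 29 + i_na] <- yaug[29 + (j - 1) * 29 + i_na] + 1
    }
  }
  if (length(post_t)) {
    times2 <- unique(c(ts, post_t))
    o2 <- deSolve::ode(yaug, times2, aug_rhs, NULL, method = "lsoda",
                       rtol = rtol, atol = atol, maxsteps = 50000)
    if (nrow(o2) < length(times2)) stop("sensitivity integration failed",
                                        call. = FALSE)
    keep <- o2[, 1] %in% post_t
    rows <- rbind(rows, o2[keep, -1, drop = FALSE])
    rows_t <- c(rows_t, o2[keep, 1])
  }

  state <- rows[, seq_len(29), drop = FALSE]
  colnames(state) <- hog_state_names()
  Sarr <- array(rows[, -seq_len(29)],
                dim = c(nrow(rows), 29, P),
                dimnames = list(NULL, hog_state_names(), param_subset))
  structure(list(times = rows_t, state = state, S = Sarr,
                 params = params, q = qvals, strain = attr(params, "strain"),
                 protocol = protocol),
            class = "hog_sens")
}

#' @export
print.hog_sens <- function(x, ...) {
  cat("<hog_sens> ", length(x$times), " times x 29 states x ",
      dim(x$S)[3], " parameters (", paste(dimnames(x$S)[[3]],
                                          collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Scaled time-dependent response coefficients
#'
#' Converts raw sensitivities `S = dx/dq` into scaled response
#' coefficients `R(t) = (q / x(t)) * S(t)`, the relative change of the
#' time course per relative change of the parameter. Entries where
#' `|x(t)| < x_floor` are masked (`NA`) rather than clipped, so vanishing
#' denominators do not create spurious spikes.
#'
#' For a `hog_sens` object the result is a long tibble; the default
#' method scales plain numeric sensitivities.
#'
#' @param S A `hog_sens` object, or numeric sensitivities.
#' @param ... Method arguments; for the default method `x` (variable
#'   values) and `q` (parameter value).
#' @param x_floor Masking floor on `|x|` (per the variable's own unit).
#' @return Tibble `(time_min, variable, parameter, S, R)` or numeric.
#' @export
scale_rc <- function(S, ..., x_floor = 1e-9) UseMethod("scale_rc")

#' @rdname scale_rc
#' @param x Variable values matching `S`.
#' @param q Scalar parameter value.
#' @export
scale_rc.default <- function(S, x, q, ..., x_floor = 1e-9) {
  R <- ifelse(abs(x) >= x_floor, q * S / x, NA_real_)
  R
}

#' @rdname scale_rc
#' @export
scale_rc.hog_sens <- function(S, ..., x_floor = 1e-9) {
  sens <- S
  pn <- dimnames(sens$S)[[3]]
  purrr::map_dfr(seq_along(pn), function(j) {
    Sj <- sens$S[, , j]
    tibble::tibble(
      time_min = rep(sens$times, times = 29),
      variable = rep(colnames(sens$state), each = length(sens$times)),
      parameter = pn[j],
      S = as.vector(Sj),
      R = as.vector(scale_rc.default(Sj, sens$state, sens$q[j],
                                     x_floor = x_floor))
    )
  })
}

#' Finite-difference oracle for response coefficients
#'
#' Independent check of the forward-sensitivity route: runs two full
#' simulations (including re-equilibration) at `q (1 +/- delta_rel)` and
#' forms the central difference, scaled like [scale_rc()]. Works for any
#' recorded variable (state, observable or flux), which also makes it
#' the tool of choice for response coefficients of fluxes.
#'
#' @param params Wild-type `hog_params`.
#' @param strain Strain name or spec.
#' @param protocol A [stress_protocol()].
#' @param param Parameter name (or `"NaCl_step"`).
#' @param delta_rel Relative perturbation, in (0, 0.05].
#' @param vars Variables to report (default: all states).
#' @param x_floor Masking floor.
#' @param base Optional unperturbed `hog_sim` to scale against.
#' @return Tibble `(time_min, variable, parameter, R)`.
#' @export
fd_oracle_rc <- function(params, strain = "WT",
                         protocol = stress_protocol(), param,
                         delta_rel = 1e-3, vars = hog_state_names(),
                         x_floor = 1e-9, base = NULL) {
  stopifnot(length(param) == 1, delta_rel > 0, delta_rel <= 0.05)
  if (!is.null(strain)) params <- apply_strain(params, strain)
  simulate_at <- function(prm, proto) {
    hog_simulate(prm, strain = NULL, protocol = proto)
  }
  if (is.null(base)) base <- simulate_at(params, protocol)
  if (param == "NaCl_step") {
    q <- protocol$NaCl_step
    dq <- delta_rel * q
    pr_p <- protocol; pr_p$NaCl_step <- q + dq
    pr_m <- protocol; pr_m$NaCl_step <- q - dq
    sp <- simulate_at(params, pr_p)
    sm <- simulate_at(params, pr_m)
  } else {
    q <- unname(params[[param]])
    if (q == 0) {
      return(purrr::map_dfr(vars, function(v) tibble::tibble(
        time_min = base$times, variable = v, parameter = param, R = 0)))
    }
    dq <- delta_rel * q
    pp <- params; pp[[param]] <- q + dq
    pm <- params; pm[[param]] <- q - dq
    sp <- simulate_at(pp, protocol)
    sm <- simulate_at(pm, protocol)
  }
  purrr::map_dfr(vars, function(v) {
    x0 <- sim_value(base, v)
    Sv <- (sim_value(sp, v) - sim_value(sm, v)) / (2 * dq)
    tibble::tibble(time_min = base$times, variable = v, parameter = param,
                   R = scale_rc.default(Sv, x0, q, x_floor = x_floor))
  })
}

#' Plot response coefficients over time
#'
#' @param rc Long tibble from [scale_rc()] or [fd_oracle_rc()].
#' @param variables Optional subset of variables to show.
#' @return A ggplot object.
#' @export
plot_rc <- function(rc, variables = NULL) {
  if (!is.null(variables)) {
    rc <- dplyr::filter(rc, .data$variable %in% variables)
  }
  ggplot2::ggplot(rc, ggplot2::aes(.data$time_min, .data$R,
                                   colour = .data$variable)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "time after stress (min)",
                  y = "scaled response coefficient") +
    ggplot2::theme_minimal()
}
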