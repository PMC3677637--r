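#' Measured variables and their model mapping
#'
#' The 14 model variables that carry measurement mappings: relative
#' (arbitrary-unit) immunoblot/transcript signals and absolute metabolite
#' concentrations, external concentrations and cell density.
#'
#' @return Tibble with columns `variable`, `sim_var` (simulation column),
#'   `compartment`, `unit`, `relative`, `method`.
#' @export
measured_variables <- function() {
  tibble::tribble(
    ~variable, ~sim_var, ~compartment, ~unit, ~relative, ~method,
    "Hog1PP", "Hog1PP", "intracellular", "au", TRUE, "western_blot",
    "Gpd1tot", "Gpd1tot", "intracellular", "au", TRUE, "western_blot",
    "mGPD1", "mGPD1", "intracellular", "au", TRUE, "northern_blot",
    "mSTL1", "mSTL1", "intracellular", "au", TRUE, "northern_blot",
    "Glci", "cGlci", "intracellular", "mM", FALSE, "enzymatic_assay",
    "Glce", "Glce", "extracellular", "mM", FALSE, "enzymatic_assay",
    "Glyi", "cGlyi", "intracellular", "mM", FALSE, "enzymatic_assay",
    "Glye", "Glye", "extracellular", "mM", FALSE, "enzymatic_assay",
    "EtOHi", "cEtOHi", "intracellular", "mM", FALSE, "enzymatic_assay",
    "EtOHe", "EtOHe", "extracellular", "mM", FALSE, "enzymatic_assay",
    "AcOe", "AcOe", "extracellular", "mM", FALSE, "enzymatic_assay",
    "Trei", "cTrei", "intracellular", "mM", FALSE, "enzymatic_assay",
    "Tree", "Tree", "extracellular", "mM", FALSE, "enzymatic_assay",
    "CD", "CD", "total", "cells/mL", FALSE, "cell_counting"
  )
}

#' Optimal scaling factor for relative measurements
#'
#' The chi-square-minimizing scale `s` aligning a model prediction in
#' native units with data in arbitrary units:
#' `s = sum(y_m y_d / sigma^2) / sum(y_m^2 / sigma^2)`, clamped at zero
#' (a negative scale is never physical for blot intensities).
#'
#' @param y_model,y_data Equal-length numeric vectors.
#' @param sigma Positive per-point standard deviations (recycled).
#' @return Scalar scale factor `>= 0`.
#' @export
optimal_scaling <- function(y_model, y_data, sigma = 1) {
  stopifnot(length(y_model) == length(y_data))
  sigma <- rep_len(sigma, length(y_model))
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  den <- sum(y_model^2 / sigma^2)
  if (den == 0) stop("all-zero model prediction: scaling undefined",
                     call. = FALSE)
  max(0, sum(y_model * y_data / sigma^2) / den)
}

#' Assemble a multi-strain fitting problem
#'
#' Partitions a measurement table by (strain, variable), attaches
#' per-point standard deviations (`sigma_rel * |y|` with a per-dataset
#' floor of `sigma_floor_frac * mean(|y|)`), restricts the objective to
#' the fitting window `[0, t_max]`, and fixes the set of free parameters
#' with log10 box bounds around the reference values.
#'
#' @param data A measurement table (see [read_timecourse_csv()]).
#' @param fit_names Names of the free parameters.
#' @param ref Reference `hog_params` supplying all fixed parameters and
#'   the centre of the log10 box.
#' @param bound_decades Half-width of the log10 box.
#' @param sigma_rel Relative error assumed per point.
#' @param sigma_floor_frac Absolute floor as a fraction of the dataset
#'   mean.
#' @param sigma_min Detection-limit floor in the variable's own unit,
#'   so that numerically-zero signals (e.g. deleted genes) do not get
#'   dust-scaled weights.
#' @param t_max Fitting window end (min); later samples are excluded.
#' @return A `hog_fit_problem` object.
#' @export
fit_problem <- function(data, fit_names, ref = hog_params(),
                        bound_decades = 2, sigma_rel = 0.15,
                        sigma_floor_frac = 0.02, sigma_min = 1e-6,
                        t_max = 180) {
  validate_measurement_table(data)
  bad <- setdiff(fit_names, hog_param_names())
  if (length(bad)) stop("unknown fit parameter(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  centre <- vapply(fit_names, function(n) unname(ref[[n]]), numeric(1))
  if (any(centre <= 0)) {
    stop("free parameters must be positive at the reference", call. = FALSE)
  }
  mv <- measured_variables()
  data <- dplyr::filter(data, .data$time_min <= t_max)
  datasets <- data |>
    dplyr::inner_join(mv, by = c("variable", "compartment")) |>
    dplyr::group_by(.data$strain, .data$variable) |>
    dplyr::group_map(function(df, key) {
      ybar <- mean(abs(df$value))
      sig <- pmax(sigma_rel * abs(df$value), sigma_floor_frac * ybar,
                  sigma_min)
      list(strain = key$strain, variable = key$variable,
           sim_var = df$sim_var[1], relative = df$relative[1],
           t = df$time_min, y = df$value, sigma = sig)
    })
  strains <- unique(vapply(datasets, `[[`, character(1), "strain"))
  # pre-equilibrated reference states per strain: Newton warm starts
  eq0 <- lapply(strains, function(s) {
    prestress_equilibrate(apply_strain(ref, s))
  })
  names(eq0) <- strains
  structure(list(datasets = datasets, strains = strains,
                 fit_names = fit_names,
                 log10_centre = log10(centre),
                 lower = log10(centre) - bound_decades,
                 upper = log10(centre) + bound_decades,
                 ref = ref, eq0 = eq0, t_max = t_max),
            class = "hog_fit_problem")
}

#' @export
print.hog_fit_problem <- function(x, ...) {
  np <- sum(vapply(x$datasets, function(d) length(d$y), numeric(1)))
  cat("<hog_fit_problem> ", length(x$datasets), " datasets, ", np,
      " points, strains: ", paste(x$strains, collapse = ", "),
      "; free: ", paste(x$fit_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

problem_params <- function(problem, theta_log10) {
  p <- problem$ref
  p[problem$fit_names] <- 10^theta_log10
  p
}

simulate_problem_strains <- function(problem, p) {
  sims <- list()
  for (s in problem$strains) {
    ps <- apply_strain(p, s)
    tset <- sort(unique(c(0, unlist(
      lapply(problem$datasets,
             function(d) if (d$strain == s) d$t else NULL)))))
    sims[[s]] <- tryCatch(suppressWarnings({
      eq <- prestress_equilibrate(ps, guess = problem$eq0[[s]],
                                  newton_first = TRUE)
      hog_simulate(ps, strain = NULL,
                   protocol = stress_protocol(t_end = max(tset),
                                              t_grid = tset),
                   init = eq, rtol = 1e-7, atol = 1e-9)
    }), error = function(e) NULL)
    if (is.null(sims[[s]])) return(NULL)
  }
  sims
}

#' Weighted least-squares objective
#'
#' Simulates every strain in the problem once at the candidate
#' parameters, applies the analytic [optimal_scaling()] to each
#' relative-unit dataset, and returns the chi-square
#' `sum(((s y_m - y_d) / sigma)^2)`. Integration or equilibration
#' failures return a large penalized value (1e10 plus the residual
#' count) instead of throwing, so optimizers can continue.
#'
#' @param theta_log10 Free parameters, log10 scale, in
#'   `problem$fit_names` order.
#' @param problem A `hog_fit_problem`.
#' @return Scalar chi-square; attribute `"scalings"` carries the fitted
#'   per-dataset scale factors.
#' @export
fit_objective <- function(theta_log10, problem) {
  npt <- sum(vapply(problem$datasets, function(d) length(d$y), numeric(1)))
  if (any(!is.finite(theta_log10))) return(1e10 + npt)
  sims <- simulate_problem_strains(problem,
                                   problem_params(problem, theta_log10))
  if (is.null(sims)) return(1e10 + npt)
  chi2 <- 0
  scalings <- numeric(length(problem$datasets))
  for (i in seq_along(problem$datasets)) {
    d <- problem$datasets[[i]]
    sim <- sims[[d$strain]]
    ym <- sim_value(sim, d$sim_var)[match(d$t, sim$times)]
    if (any(!is.finite(ym))) return(1e10 + npt)
    s <- if (d$relative) {
      tryCatch(optimal_scaling(ym, d$y, d$sigma), error = function(e) 0)
    } else 1
    scalings[i] <- s
    chi2 <- chi2 + sum(((s * ym - d$y) / d$sigma)^2)
  }
  structure(chi2, scalings = scalings)
}

#' Residual vector of the fitting problem
#'
#' The signed, sigma-weighted residuals `(s y_m - y_d) / sigma` over all
#' datasets (with the analytic scaling applied to relative-unit data),
#' plus quadratic penalty terms for bound violations. Failures map to a
#' large flat residual vector so least-squares optimizers can continue.
#'
#' @inheritParams fit_objective
#' @return Numeric residual vector.
#' @export
fit_residuals <- function(theta_log10, problem) {
  npt <- sum(vapply(problem$datasets, function(d) length(d$y), numeric(1)))
  k <- length(problem$fit_names)
  fail <- rep(1e5, npt + 2 * k)
  if (any(!is.finite(theta_log10))) return(fail)
  pen <- c(sqrt(1e6) * pmax(theta_log10 - problem$upper, 0),
           sqrt(1e6) * pmax(problem$lower - theta_log10, 0))
  th <- pmin(pmax(theta_log10, problem$lower), problem$upper)
  sims <- simulate_problem_strains(problem, problem_params(problem, th))
  if (is.null(sims)) return(fail)
  res <- vector("list", length(problem$datasets))
  for (i in seq_along(problem$datasets)) {
    d <- problem$datasets[[i]]
    ym <- sim_value(sims[[d$strain]],
                    d$sim_var)[match(d$t, sims[[d$strain]]$times)]
    if (any(!is.finite(ym))) return(fail)
    s <- if (d$relative) {
      tryCatch(optimal_scaling(ym, d$y, d$sigma), error = function(e) 0)
    } else 1
    res[[i]] <- (s * ym - d$y) / d$sigma
  }
  c(unlist(res), pen)
}

#' Multistart parameter estimation
#'
#' Latin-hypercube start points in the log10 box (seeded and fully
#' reproducible) refined by Levenberg-Marquardt least squares on the
#' weighted residual vector. Every start receives a refinement pass; the
#' most promising starts are refined further, and the best is polished
#' to tight tolerances. The finite-difference step of the LM Jacobian is
#' set well above the integrator noise floor (`epsfcn`), which is what
#' makes derivative-based refinement reliable on ODE trajectories.
#'
#' @param problem A `hog_fit_problem`.
#' @param n_starts Number of multistarts.
#' @param seed Integer seed controlling the start points.
#' @param starts Optional matrix of log10 start points
#'   (`n_starts x n_params`), overriding the Latin hypercube.
#' @param refine_maxit LM iterations for every start.
#' @param deep_maxit Additional LM iterations for the `n_deep` best.
#' @param n_deep Number of starts receiving the deep pass.
#' @param polish_maxit LM iterations for the final polish of the best.
#' @return A `hog_fit` object.
#' @export
hog_fit <- function(problem, n_starts = 20, seed = 1, starts = NULL,
                    refine_maxit = 100, deep_maxit = 100, n_deep = 2,
                    polish_maxit = 200) {
  stopifnot(inherits(problem, "hog_fit_problem"), n_starts >= 1)
  k <- length(problem$fit_names)
  if (is.null(starts)) {
    set.seed(seed)
    u <- lhs::randomLHS(n_starts, k)
    starts <- sweep(sweep(u, 2, problem$upper - problem$lower, "*"),
                    2, problem$lower, "+")
  } else {
    starts <- matrix(starts, ncol = k)
    n_starts <- nrow(starts)
  }
  colnames(starts) <- problem$fit_names

  lm_ctl <- function(maxiter, ftol = 1e-8) {
    minpack.lm::nls.lm.control(maxiter = maxiter, epsfcn = 1e-6,
                               ftol = ftol)
  }
  runs <- purrr::map(seq_len(n_starts), function(i) {
    o <- minpack.lm::nls.lm(starts[i, ], fn = fit_residuals,
                            problem = problem,
                            control = lm_ctl(refine_maxit))
    list(start = i, par = o$par, value = o$deviance,
         niter = o$niter, info = o$info, rsstrace = o$rsstrace)
  })
  ord <- order(vapply(runs, `[[`, numeric(1), "value"))
  for (i in head(ord, n_deep)) {
    r <- runs[[i]]
    o <- minpack.lm::nls.lm(r$par, fn = fit_residuals, problem = problem,
                            control = lm_ctl(deep_maxit))
    if (o$deviance <= r$value) {
      runs[[i]] <- list(start = r$start, par = o$par, value = o$deviance,
                        niter = r$niter + o$niter, info = o$info,
                        rsstrace = c(r$rsstrace, o$rsstrace))
    }
  }
  ord <- order(vapply(runs, `[[`, numeric(1), "value"))
  runs <- runs[ord]
  best <- runs[[1]]
  if (polish_maxit > 0) {
    o <- minpack.lm::nls.lm(best$par, fn = fit_residuals,
                            problem = problem,
                            control = lm_ctl(polish_maxit, ftol = 1e-12))
    if (o$deviance <= best$value) {
      best <- list(start = best$start, par = o$par, value = o$deviance,
                   niter = best$niter + o$niter, info = o$info,
                   rsstrace = c(best$rsstrace, o$rsstrace))
      runs[[1]] <- best
    }
  }
  th <- pmin(pmax(best$par, problem$lower), problem$upper)
  final <- fit_objective(th, problem)
  structure(list(problem = problem, runs = runs, seed = seed,
                 starts = starts,
                 theta_hat = setNames(10^th, problem$fit_names),
                 objective = as.numeric(final),
                 scalings = attr(final, "scalings"),
                 convergence = best$info),
            class = "hog_fit")
}

#' @export
print.hog_fit <- function(x, ...) {
  cat("<hog_fit> ", length(x$runs), " starts, best chi-square ",
      signif(x$objective, 6), "\n", sep = "")
  print(signif(x$theta_hat, 4))
  invisible(x)
}

#' Tidy fitted parameters
#'
#' @param x A `hog_fit` object.
#' @param reference Optional named truth vector for relative errors.
#' @param ... Unused.
#' @return Tibble with `parameter`, `estimate`, `log10_estimate`, and,
#'   given a reference, `truth` and `rel_error`.
#' @export
tidy.hog_fit <- function(x, reference = NULL, ...) {
  out <- tibble::tibble(parameter = names(x$theta_hat),
                        estimate = unname(x$theta_hat),
                        log10_estimate = log10(unname(x$theta_hat)))
  if (!is.null(reference)) {
    tr <- vapply(out$parameter, function(n) unname(reference[[n]]),
                 numeric(1))
    out$truth <- tr
    out$rel_error <- abs(out$estimate - tr) / tr
  }
  out
}

#' One-line fit summary
#' @param x A `hog_fit` object.
#' @param ... Unused.
#' @export
glance.hog_fit <- function(x, ...) {
  vals <- vapply(x$runs, `[[`, numeric(1), "value")
  tibble::tibble(n_starts = length(x$runs),
                 objective = x$objective,
                 worst_objective = max(vals),
                 convergence = x$convergence,
                 seed = x$seed)
}
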