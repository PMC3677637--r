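#' Noise specification for synthetic measurements
#'
#' Multiplicative lognormal noise (preserving positivity) with an
#' optional additive floor, replicate count and seed. The lognormal is
#' parameterized so the mean factor is exactly 1 and the coefficient of
#' variation exactly `sigma_rel`.
#'
#' @param sigma_rel Relative (multiplicative) noise level.
#' @param sigma_abs Named or scalar additive noise floor (default 0).
#' @param n_rep Replicates per (strain, variable, time).
#' @param seed Integer seed.
#' @return A `hog_noise` list.
#' @export
noise_spec <- function(sigma_rel = 0.15, sigma_abs = 0, n_rep = 3,
                       seed = 1) {
  stopifnot(sigma_rel >= 0, n_rep >= 1)
  structure(list(sigma_rel = sigma_rel, sigma_abs = sigma_abs,
                 n_rep = as.integer(n_rep), seed = as.integer(seed)),
            class = "hog_noise")
}

default_schedule <- function(variable) {
  prot <- c("Hog1PP", "Gpd1tot", "mGPD1", "mSTL1")
  if (variable %in% prot) {
    c(0, 5, 10, 20, 30, 45, 60, 90, 120, 180)
  } else {
    c(0, 10, 30, 45, 60, 90, 120, 180, 240)
  }
}

apply_noise <- function(y, noise) {
  if (noise$sigma_rel > 0) {
    sdlog <- sqrt(log1p(noise$sigma_rel^2))
    y <- y * stats::rlnorm(length(y), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  if (any(noise$sigma_abs > 0)) {
    y <- pmax(y + rnorm(length(y), 0, noise$sigma_abs), 0)
  }
  y
}

#' Model-based synthetic measurement table
#'
#' Simulates each strain at the supplied parameters and samples the 14
#' measured variables on the measurement schedule, applying seeded
#' lognormal noise. With `sigma_rel = 0` and one replicate the table
#' reproduces the simulated observables exactly.
#'
#' @param params `hog_params` (typically the shipped reference set).
#' @param strains Character vector of strain names.
#' @param schedule Optional numeric sample times (min) used for all
#'   variables; default: per-variable schedules (denser early times for
#'   phospho/protein signals), all within 0-240 min.
#' @param noise A [noise_spec()].
#' @param protocol Stress protocol (end extended to cover the schedule).
#' @return A measurement table (tibble) passing
#'   [validate_measurement_table()].
#' @export
generate_model_based <- function(params = hog_params(),
                                 strains = c("WT", "gpd1Δ", "hog1Δ"),
                                 schedule = NULL,
                                 noise = noise_spec(),
                                 protocol = NULL) {
  strains <- vapply(strains, canonical_strain, character(1))
  mv <- measured_variables()
  sched <- lapply(mv$variable, function(v) {
    s <- if (is.null(schedule)) default_schedule(v) else schedule
    if (any(s < 0 | s > 240)) {
      stop("schedule must lie within [0, 240] min", call. = FALSE)
    }
    sort(unique(s))
  })
  names(sched) <- mv$variable
  all_t <- sort(unique(unlist(sched)))
  if (is.null(protocol)) {
    protocol <- stress_protocol(t_end = max(all_t), t_grid = all_t)
  }
  set.seed(noise$seed)
  out <- purrr::map_dfr(strains, function(s) {
    sim <- hog_simulate(params, s, protocol)
    purrr::map_dfr(seq_len(nrow(mv)), function(i) {
      v <- mv$variable[i]
      tt <- sched[[v]]
      # clamp integrator dust: measured quantities are non-negative
      y <- pmax(sim_value(sim, mv$sim_var[i])[match(tt, sim$times)], 0)
      purrr::map_dfr(seq_len(noise$n_rep), function(r) {
        tibble::tibble(strain = s, variable = v,
                       compartment = mv$compartment[i], time_min = tt,
                       replicate = r, value = apply_noise(y, noise),
                       unit = mv$unit[i], method = mv$method[i])
      })
    })
  })
  validate_measurement_table(out)
  out
}

#' Trehalose template curve
#'
#' Closed-form sum of two Gaussian bumps over a baseline, with modes
#' pinned at 45 and 180 min — the double-peaked intracellular trehalose
#' course of the wild-type time series the generator emulates.
#'
#' @param t Time (min) in `[0, 240]`.
#' @param base Baseline (mM).
#' @param amp1,amp2 Bump amplitudes (mM).
#' @param w1,w2 Bump widths (min, Gaussian sd).
#' @return Trehalose concentration (mM), differentiable in `t`.
#' @export
trehalose_template <- function(t, base = 18, amp1 = 9, amp2 = 13,
                               w1 = 16, w2 = 25) {
  if (any(t < 0 | t > 240)) stop("t must lie in [0, 240]", call. = FALSE)
  base + amp1 * exp(-(t - 45)^2 / (2 * w1^2)) +
    amp2 * exp(-(t - 180)^2 / (2 * w2^2))
}

pheno_templates <- function() {
  mu0 <- log(2) / 120
  list(
    Hog1PP = function(t) 1.0 * (t / 8) * exp(1 - t / 8),
    Gpd1tot = function(t) 0.05 + 0.95 * (1 - exp(-pmax(t - 5, 0) / 35)),
    mGPD1 = function(t) 0.02 + (t / 15) * exp(1 - t / 15),
    mSTL1 = function(t) 0.02 + (t / 18) * exp(1 - t / 18),
    Glci = function(t) rep(1.0, length(t)),
    Glce = function(t) 110 * exp(-t / 2400),
    Glyi = function(t) 6 + 850 * (t / 42)^2 * exp(2 * (1 - t / 42)),
    Glye = function(t) 0.1 + 1.4 * (t / 240)^1.2,
    EtOHi = function(t) 14 + 24 * (t / 240),
    EtOHe = function(t) 10 + 24 * (t / 240),
    AcOe = function(t) 0.5 + 1.5 * (t / 240),
    Trei = function(t) trehalose_template(t),
    Tree = function(t) 0.1 + 0.6 * (t / 240),
    CD = function(t) 4e6 * exp(mu0 * (t - 0.75 * 60 * (1 - exp(-t / 60))))
  )
}

#' Phenomenological synthetic measurement table
#'
#' Emits wild-type template curves reproducing the qualitative features
#' of the study's time series without running the model: strictly
#' decreasing external glucose; increasing external ethanol, acetate,
#' glycerol and cell density (with a stress-induced growth slowdown); a
#' single transient bump for phosphorylated Hog1 (peak before 15 min)
#' and intracellular glycerol (peak between 30 and 60 min); and a
#' double-peaked intracellular trehalose course with noise-free local
#' maxima exactly at 45 and 180 min.
#'
#' @param noise A [noise_spec()].
#' @param schedule Optional shared sample times; defaults as in
#'   [generate_model_based()].
#' @return A measurement table with the same schema as the model-based
#'   generator.
#' @export
generate_phenomenological <- function(noise = noise_spec(),
                                      schedule = NULL) {
  mv <- measured_variables()
  tmpl <- pheno_templates()
  set.seed(noise$seed)
  out <- purrr::map_dfr(seq_len(nrow(mv)), function(i) {
    v <- mv$variable[i]
    tt <- if (is.null(schedule)) default_schedule(v) else sort(unique(schedule))
    y <- tmpl[[v]](tt)
    purrr::map_dfr(seq_len(noise$n_rep), function(r) {
      tibble::tibble(strain = "WT", variable = v,
                     compartment = mv$compartment[i], time_min = tt,
                     replicate = r, value = apply_noise(y, noise),
                     unit = mv$unit[i], method = mv$method[i])
    })
  })
  validate_measurement_table(out)
  out
}
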