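test_that("optimal scaling solves the weighted 1-D least-squares exactly", {
  expect_equal(optimal_scaling(c(1, 2), c(2, 4), 1), 2)
  # anti-correlated data clamp at zero
  expect_equal(optimal_scaling(c(1, 2), c(-2, -4), 1), 0)
  expect_error(optimal_scaling(c(0, 0), c(1, 2), 1), "all-zero")
  expect_error(optimal_scaling(c(1, 2), c(1, 2), c(1, 0)), "positive")

  # random instances against a brute-force 1-D minimization
  set.seed(42)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    ym <- runif(n, 0.1, 5)
    yd <- runif(n, 0, 10)
    sg <- runif(n, 0.2, 2)
    s_hat <- optimal_scaling(ym, yd, sg)
    chi2 <- function(s) sum(((s * ym - yd) / sg)^2)
    s_opt <- optimize(chi2, c(0, 20), tol = 1e-10)$minimum
    expect_lt(abs(s_hat - s_opt), 1e-6)
  }
})

zero_noise_problem <- function(fitp = c("kcatGpd1", "k_dp", "mu0")) {
  if (is.null(.cache$zn_data)) {
    .cache$zn_data <- generate_model_based(
      ref_params(), c("WT", "gpd1Δ", "hog1Δ"),
      noise = noise_spec(sigma_rel = 0, n_rep = 1, seed = 1))
  }
  fit_problem(.cache$zn_data, fitp)
}

test_that("the objective vanishes at the generating parameters", {
  prob <- zero_noise_problem()
  expect_lt(as.numeric(fit_objective(prob$log10_centre, prob)), 1e-6)
})

test_that("the objective is invariant to the units of relative data", {
  prob <- zero_noise_problem()
  th <- prob$log10_centre + c(0.05, -0.05, 0.02)
  f1 <- as.numeric(fit_objective(th, prob))
  data2 <- .cache$zn_data
  rel_vars <- measured_variables()$variable[measured_variables()$relative]
  rel <- data2$variable %in% rel_vars
  data2$value[rel] <- data2$value[rel] * 7.3
  prob2 <- fit_problem(data2, c("kcatGpd1", "k_dp", "mu0"))
  f2 <- as.numeric(fit_objective(th, prob2))
  expect_equal(f1, f2, tolerance = 1e-6)
})

test_that("perturbing a glycerol parameter degrades the fit", {
  prob <- zero_noise_problem("kcatGpd1")
  f0 <- as.numeric(fit_objective(prob$log10_centre, prob))
  f2 <- as.numeric(fit_objective(prob$log10_centre + log10(2), prob))
  expect_gt(f2, f0 + 1)
})

test_that("the truth is a local optimum of the zero-noise objective", {
  prob <- zero_noise_problem()
  f0 <- as.numeric(fit_objective(prob$log10_centre, prob))
  for (j in seq_along(prob$fit_names)) {
    for (d in c(-0.02, 0.02)) {
      th <- prob$log10_centre
      th[j] <- th[j] + d
      expect_gte(as.numeric(fit_objective(th, prob)), f0)
    }
  }
})

test_that("fitting from the truth is a fixed point", {
  prob <- zero_noise_problem()
  fit <- hog_fit(prob, starts = matrix(prob$log10_centre, nrow = 1),
                 refine_maxit = 10, deep_maxit = 0, polish_maxit = 0)
  expect_lte(fit$objective, 1e-6)
  rel <- abs(fit$theta_hat - 10^prob$log10_centre) / 10^prob$log10_centre
  expect_lt(max(rel), 1e-3)
})

test_that("same seed gives bitwise-identical multistarts", {
  prob <- zero_noise_problem(c("kcatGpd1", "k_dp"))
  f1 <- hog_fit(prob, n_starts = 3, seed = 7, refine_maxit = 2,
                deep_maxit = 0, polish_maxit = 0)
  f2 <- hog_fit(prob, n_starts = 3, seed = 7, refine_maxit = 2,
                deep_maxit = 0, polish_maxit = 0)
  expect_identical(f1$starts, f2$starts)
  expect_identical(f1$theta_hat, f2$theta_hat)
  # refinement never ends above its start value
  for (r in f1$runs) {
    expect_lte(r$value, r$rsstrace[1] * (1 + 1e-12))
  }
  td <- tidy(f1, reference = ref_params())
  expect_true(all(c("estimate", "truth", "rel_error") %in% names(td)))
  expect_equal(glance(f1)$n_starts, 3)
})
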