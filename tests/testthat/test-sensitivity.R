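proto_short <- function() stress_protocol(t_end = 60,
                                          t_grid = seq(0, 60, 2))

test_that("scaling sensitivities recovers relative response coefficients", {
  # x = q * const  =>  R = 1 everywhere
  q <- 3.7
  x <- q * c(2, 5, 11)
  S <- c(2, 5, 11) # dx/dq
  expect_equal(scale_rc(S, x, q), c(1, 1, 1))
  # masking below the floor
  expect_true(is.na(scale_rc(1, 0, q)))
  expect_true(is.na(scale_rc(1, 1e-12, q, x_floor = 1e-9)))
})

test_that("forward sensitivities match the finite-difference oracle", {
  p <- ref_params()
  sens <- compute_sensitivities(p, "WT", proto_short(),
                                c("k_dp", "kcatGpd1"))
  rc <- scale_rc(sens)
  for (pn in c("k_dp", "kcatGpd1")) {
    fo <- fd_oracle_rc(p, "WT", proto_short(), pn)
    cmp <- dplyr::inner_join(
      dplyr::filter(rc, .data$parameter == pn), fo,
      by = c("time_min", "variable", "parameter"),
      suffix = c("_ode", "_fd"))
    cmp <- dplyr::filter(cmp, abs(.data$R_fd) > 0.05)
    expect_gt(nrow(cmp), 50)
    expect_lt(max(abs(cmp$R_ode - cmp$R_fd) / abs(cmp$R_fd)), 0.01)
  }
})

test_that("only the stress magnitude is causal across the step", {
  p <- ref_params()
  proto <- stress_protocol(t_end = 30,
                           t_grid = seq(-20, 30, 2))
  sens <- compute_sensitivities(p, "WT", proto, "NaCl_step")
  pre <- sens$times < 0
  expect_true(all(abs(sens$S[pre, , 1]) == 0))
  post <- sens$times >= 10
  expect_gt(max(abs(sens$S[post, "Glyi", 1])), 0)
})

test_that("a structurally absent parameter has identically zero sensitivity", {
  p <- ref_params()
  sens <- compute_sensitivities(p, "HOG1-att", proto_short(), "k_h1")
  expect_true(all(sens$S == 0))
  fo <- fd_oracle_rc(p, "HOG1-att", proto_short(), "k_h1",
                     vars = c("mGPD1", "Glyi"))
  expect_true(all(fo$R == 0))
})

test_that("the oracle is a second-order central difference", {
  p <- ref_params()
  base <- sim_ref("WT", t_end = 60, by = 2)
  f1 <- fd_oracle_rc(p, "WT", proto_short(), "k_dp", delta_rel = 1e-3,
                     vars = "Hog1PP", base = base)
  f2 <- fd_oracle_rc(p, "WT", proto_short(), "k_dp", delta_rel = 2e-3,
                     vars = "Hog1PP", base = base)
  keep <- abs(f1$R) > 0.05 & !is.na(f1$R)
  expect_lt(max(abs(f1$R[keep] - f2$R[keep]) / abs(f1$R[keep])), 1e-3)
})

test_that("Pfk26/27 activation reroutes flux without moving glycerol", {
  p <- ref_params()
  base <- sim_ref("WT", t_end = 60, by = 2)
  fo <- fd_oracle_rc(p, "WT", proto_short(), "k_a26",
                     vars = c("vLG", "vPDC", "vTPS", "vBM", "cGlyi"),
                     base = base)
  w <- fo$time_min >= 10 & fo$time_min <= 60
  pick <- function(v) fo$R[fo$variable == v & w]
  expect_true(all(pick("vLG") > 0)) # lower glycolysis up
  expect_true(all(pick("vPDC") > 0))
  expect_true(all(pick("vTPS") < 0)) # trehalose branch down
  expect_true(all(pick("vBM") < 0)) # biomass drain down
  expect_true(all(abs(pick("cGlyi")) < 0.1)) # glycerol barely moves
})

test_that("Stl1 expression matters early only without Gpd1", {
  p <- ref_params()
  proto <- stress_protocol(t_end = 90, t_grid = seq(0, 90, 5))
  fw <- fd_oracle_rc(p, "WT", proto, "k_s1", vars = "cGlyi")
  fg <- fd_oracle_rc(p, "gpd1Δ", proto, "k_s1", vars = "cGlyi")
  cmp <- dplyr::inner_join(fw, fg, by = c("time_min", "variable"),
                           suffix = c("_wt", "_gpd"))
  cmp <- dplyr::filter(cmp, .data$time_min > 0, .data$time_min < 90)
  expect_true(all(cmp$R_gpd > cmp$R_wt))
})
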