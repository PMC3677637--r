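test_that("state vector and parameter set have the canonical structure", {
  expect_length(hog_state_names(), 29L)
  p <- ref_params()
  expect_s3_class(p, "hog_params")
  expect_setequal(names(p), hog_param_names())
  expect_error(hog_params(not_a_param = 1), "unknown parameter")
  expect_error(hog_params(kHXT = -1), "negative")
})

test_that("observables satisfy their defining limits", {
  p <- ref_params()
  s <- hog_initial_guess(p)

  s[["Vos"]] <- p[["Vos0"]]
  ob <- compute_observables(s, p)
  expect_equal(ob[["Pi_t"]], p[["Pi_t0"]])
  expect_equal(ob[["u"]], 0)
  expect_equal(ob[["Vtot"]], p[["Vb"]] + p[["Vos0"]])

  s[["Vos"]] <- p[["V_lp"]]
  ob <- compute_observables(s, p)
  expect_equal(ob[["Pi_t"]], 0)
  expect_equal(ob[["u"]], 1)

  s[["Vos"]] <- p[["Vos0"]]
  s[["Hog1PP"]] <- 0
  ob <- compute_observables(s, p)
  expect_equal(ob[["mu"]], unname(p[["mu0"]]))

  s[["Vos"]] <- -1
  expect_error(compute_observables(s, p), "Vos")
})

test_that("rate laws behave in the no-activator, saturation and linear limits", {
  p <- ref_params()
  s <- hog_initial_guess(p)

  s[["F26DP"]] <- 0
  v0 <- reaction_fluxes(s, p)
  cHexP <- s[["HexP"]] / s[["Vos"]]
  expect_equal(v0[["vPFK"]],
               p[["VmPFK"]] * cHexP / (p[["KPFK"]] + cHexP))

  s[["F26DP"]] <- 1e9 # saturating activator
  vs <- reaction_fluxes(s, p)
  # the activator is itself osmotically inert in the rate law; the huge
  # amount only matters through cF26DP in the modulation factor
  expect_equal(vs[["vPFK"]] / v0[["vPFK"]], 1 + p[["aF"]],
               tolerance = 1e-6)

  s[["F26DP"]] <- 0
  s2 <- s
  s2[["Gpd1d"]] <- 2 * s[["Gpd1d"]]
  expect_equal(reaction_fluxes(s2, p)[["vGPD1"]], 2 * v0[["vGPD1"]])
})

test_that("closed Fps1 carries exactly zero flux", {
  p <- ref_params()
  s <- hog_initial_guess(p)
  s[["Fps1o"]] <- 0
  s[["Glyi"]] <- 500 * s[["Vos"]] # strong gradient
  v <- reaction_fluxes(s, p)
  expect_identical(v[["vFPS"]], 0)
  d <- evaluate_rhs(s, 0, p)
  expect_true(is.finite(d[["Glyi"]]))
})

test_that("the stoichiometric matrix is carbon-closed", {
  cl <- check_carbon_closure(ref_params())
  expect_equal(nrow(cl), 18L)
  expect_true(all(cl$carbon_residual == 0))
  S <- stoichiometry_matrix()
  # spot checks of the bookkeeping
  expect_equal(unname(S["FBP", "vALD"]), -1L)
  expect_equal(unname(S["TriP", "vALD"]), 2L)
  expect_equal(unname(S["HexP", "vTPS"]), -2L)
  expect_equal(unname(S["Trei", "vTPS"]), 1L)
})

test_that("compiled and reference right-hand sides agree on random states", {
  p <- ref_params()
  for (seed in 1:25) {
    s <- random_state(seed)
    dr <- evaluate_rhs(s, 0, p)
    dc <- hogadapt:::rhs_c(0, s, p)
    scale <- pmax(abs(dr), 1)
    expect_lt(max(abs(dr - dc) / scale), 1e-12)
  }
  # frozen-external variant agrees too
  s <- random_state(99)
  dr <- evaluate_rhs(s, 0, p, freeze_external = TRUE)
  dc <- hogadapt:::rhs_c(0, s, p, freeze = 1)
  expect_lt(max(abs(dr - dc)), 1e-9)
  expect_true(all(dr[c("Glce", "Glye", "EtOHe", "AcOe", "Tree", "NaCle",
                       "CD")] == 0))
})

test_that("rhs rejects invalid states with the offending entry named", {
  p <- ref_params()
  s <- hog_initial_guess(p)
  s[["Glyi"]] <- -1
  expect_error(evaluate_rhs(s, 0, p), "Glyi")
  s <- hog_initial_guess(p)
  s[["HexP"]] <- NaN
  expect_error(evaluate_rhs(s, 0, p), "HexP")
  expect_error(evaluate_rhs(hog_initial_guess(p)[1:28], 0, p), "29")
})

test_that("salt step raises external osmolarity and shrinks the cell", {
  p <- ref_params()
  eq <- eq_ref("WT")
  ob0 <- compute_observables(eq, p)
  d0 <- evaluate_rhs(eq, 0, p)
  # equilibrium: intracellular derivatives vanish
  expect_lt(max(abs(d0[1:22]) / pmax(abs(eq[1:22]), 1)), 1e-6)

  shocked <- eq
  shocked[["NaCle"]] <- 0.4
  ob1 <- compute_observables(shocked, p)
  expect_equal(ob1[["Pi_e"]] - ob0[["Pi_e"]],
               unname(p[["i_vh"]]) * 0.4)
  d1 <- evaluate_rhs(shocked, 0, p)
  expect_lt(d1[["Vos"]], 0)
})
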