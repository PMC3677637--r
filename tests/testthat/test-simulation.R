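test_that("pre-stress equilibration reaches a fixed point of the closed cell", {
  p <- ref_params()
  eq <- eq_ref("WT")
  r <- evaluate_rhs(eq, 0, p, freeze_external = TRUE)
  expect_lt(max(abs(r[1:22]) / pmax(abs(eq[1:22]), 1)), 1e-8)
  ob <- compute_observables(eq, p)
  expect_lt(ob[["u"]], 1e-6)
  expect_lt(eq[["Hog1PP"]], 0.05 * p[["Hog1tot"]]) # basal phospho-level
})

test_that("removing the unused Stl1 route leaves the fixed point unchanged", {
  p <- ref_params()
  eq1 <- eq_ref("WT")
  eq2 <- prestress_equilibrate(hog_params(VmSTL = 0))
  # pre-stress external glycerol is nearly absent, so Stl1 carries no flux
  expect_lt(max(abs(eq1 - eq2) / pmax(abs(eq1), 1)), 1e-6)
})

test_that("without a salt step the culture is quasi-steady", {
  sim <- sim_ref("WT", NaCl = 0)
  vos <- sim$state[, "Vos"]
  expect_lt(max(abs(vos / vos[1] - 1)), 0.005)
  expect_lt(max(sim$state[, "Hog1PP"]), 0.05 * ref_params()[["Hog1tot"]])
  # cells keep growing and consuming glucose
  expect_gt(sim$state[nrow(sim$state), "CD"], 2 * sim$state[1, "CD"])
  expect_true(all(diff(sim$state[, "Glce"]) < 0))
  # most intracellular concentrations stay within 2%; the ethanol and
  # acetate pools passively track their deliberately accumulating
  # external counterparts and are excluded from the 2% claim
  conc <- sim$obs[, setdiff(grep("^c", colnames(sim$obs), value = TRUE),
                            c("cEtOHi", "cAcOi"))]
  drift <- apply(conc, 2, function(x) max(abs(x / x[1] - 1)))
  expect_lt(max(drift), 0.02)
})

test_that("wild-type glycerol peaks late and the volume recovers imperfectly", {
  p <- ref_params()
  sim <- sim_ref("WT")
  gly <- sim$obs[, "cGlyi"]
  t <- sim$times
  expect_gte(t[which.max(gly)], 30) # Fps1 reopening sets the peak
  # total volume back within 10% of its pre-stress value at 180 min ...
  vt0 <- sim$obs[1, "Vtot"]
  expect_lt(abs(sim$obs[t == 180, "Vtot"] - vt0) / vt0, 0.10)
  # ... while expression, storage and growth stay displaced
  expect_gt(sim$obs[t == 180, "Gpd1tot"] / sim$obs[1, "Gpd1tot"], 2)
  expect_gt(abs(sim$obs[t == 180, "cTrei"] / sim$obs[1, "cTrei"] - 1), 0.02)
  expect_gt(abs(sim$obs[t == 180, "mu"] / sim$obs[1, "mu"] - 1), 0.02)
})

test_that("hog1 deletion accumulates glycerol late and low", {
  sim <- sim_ref("hog1Δ")
  gly <- sim$obs[, "cGlyi"]
  t <- sim$times
  half <- gly[t == 180] / 2
  expect_gte(t[which(gly > half)[1]], 60)
  wt <- sim_ref("WT")
  expect_gt(max(wt$obs[wt$times <= 60, "cGlyi"]),
            max(gly[t <= 60]))
})

test_that("open-channel mutant floods the medium with glycerol", {
  f <- sim_ref("FPS1-Δ1")
  w <- sim_ref("WT")
  expect_gt(f$state[f$times == 180, "Glye"],
            w$state[w$times == 180, "Glye"])
})

test_that("halving solver tolerances leaves glycerol unchanged to 0.1%", {
  p <- ref_params()
  proto <- stress_protocol(t_end = 120)
  eq <- eq_ref("WT")
  s1 <- hog_simulate(apply_strain(p, "WT"), NULL, proto, init = eq)
  s2 <- hog_simulate(apply_strain(p, "WT"), NULL, proto, init = eq,
                     rtol = 5e-9, atol = 5e-11)
  rel <- max(abs(s1$obs[, "cGlyi"] - s2$obs[, "cGlyi"])) /
    max(abs(s1$obs[, "cGlyi"]))
  expect_lt(rel, 1e-3)
})

test_that("trajectories are non-negative and tidy correctly", {
  sim <- sim_ref("WT")
  expect_gt(min(sim$state), -1e-9)
  td <- tidy(sim)
  expect_s3_class(td, "tbl_df")
  expect_setequal(unique(td$kind), c("state", "observable", "flux"))
  wide <- as_tibble(sim)
  expect_equal(nrow(wide), length(sim$times))
  expect_true(all(hog_state_names() %in% names(wide)))
})

test_that("protocols validate their grids", {
  expect_error(stress_protocol(t_grid = c(0, 0, 1)), "increasing")
  expect_error(stress_protocol(NaCl_step = -0.1), "NaCl_step")
  sim <- sim_ref("WT", t_end = 30)
  expect_error(doubling_time(sim, c(10, 11)), "3 grid points")
})
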