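test_that("decomposition components sum to the glycerol derivative", {
  p <- ref_params()
  for (s in c("WT", "hog1Δ", "FPS1-Δ1")) {
    sim <- sim_ref(s)
    d <- decompose_glycerol_flux(sim)
    # oracle: d(cGlyi)/dt straight from the reference right-hand side
    oracle <- vapply(seq_along(sim$times), function(i) {
      st <- pmax(sim$state[i, ], 0)
      r <- evaluate_rhs(st, sim$times[i], sim$params)
      (r[["Glyi"]] - st[["Glyi"]] / st[["Vos"]] * r[["Vos"]]) / st[["Vos"]]
    }, numeric(1))
    lhs <- d$J_Gpd1 + d$J_Fps1 + d$J_Others
    expect_lt(max(abs(lhs - oracle)), 1e-9)
    expect_lt(max(abs(lhs - d$dcGlyi)), 1e-9)
  }
})

test_that("decomposition matches finite differences of the trajectory", {
  p <- ref_params()
  sim <- hog_simulate(p, "WT",
                      stress_protocol(t_end = 30,
                                      t_grid = seq(0, 30, 0.1)))
  d <- decompose_glycerol_flux(sim)
  gly <- sim$obs[, "cGlyi"]
  n <- length(gly)
  fd <- (gly[3:n] - gly[1:(n - 2)]) / 0.2
  tot <- d$J_Gpd1 + d$J_Fps1 + d$J_Others
  expect_lt(max(abs(tot[2:(n - 1)] - fd)) / max(abs(fd)), 1e-3)
})

test_that("ternary coordinates form a proper simplex", {
  sim <- sim_ref("WT")
  tc <- ternary_coordinates(decompose_glycerol_flux(sim))
  expect_true(all(tc$r_Fps1 >= 0 & tc$r_Gpd1 >= 0 & tc$r_Others >= 0))
  expect_lt(max(abs(tc$r_Fps1 + tc$r_Gpd1 + tc$r_Others - 1)), 1e-12)

  # degenerate all-zero instant maps to the flagged centroid
  dz <- tibble::tibble(time_min = 0, J_Gpd1 = 0, J_Fps1 = 0, J_Others = 0,
                       dcGlyi = 0, r_Gpd1 = 1 / 3, r_Fps1 = 1 / 3,
                       r_Others = 1 / 3, degenerate = TRUE)
  tz <- ternary_coordinates(dz)
  expect_equal(unlist(tz[1, c("r_Fps1", "r_Gpd1", "r_Others")]),
               c(r_Fps1 = 1 / 3, r_Gpd1 = 1 / 3, r_Others = 1 / 3))
  expect_true(tz$degenerate[1])

  # single-component flux lands on the corresponding vertex, and a
  # permutation of components permutes the coordinates
  mk <- function(g, f, o) {
    tot <- abs(g) + abs(f) + abs(o)
    tibble::tibble(time_min = 0, J_Gpd1 = g, J_Fps1 = f, J_Others = o,
                   dcGlyi = g + f + o, r_Gpd1 = abs(g) / tot,
                   r_Fps1 = abs(f) / tot, r_Others = abs(o) / tot,
                   degenerate = FALSE)
  }
  v <- ternary_coordinates(mk(0, 0, 2.5))
  expect_equal(unname(unlist(v[1, c("r_Fps1", "r_Gpd1", "r_Others")])),
               c(0, 0, 1))
  a <- ternary_coordinates(mk(1, 2, 3))
  b <- ternary_coordinates(mk(2, 1, 3)) # swap Gpd1 and Fps1
  expect_equal(a$r_Gpd1, b$r_Fps1)
  expect_equal(a$r_Fps1, b$r_Gpd1)
  expect_equal(a$r_Others, b$r_Others)
})

test_that("early adaptation is volume- and channel-driven, production wins within 15 min", {
  d <- decompose_glycerol_flux(sim_ref("WT"))
  i1 <- which(d$time_min == 1)
  expect_lt(d$r_Gpd1[i1], d$r_Fps1[i1])
  expect_lt(d$r_Gpd1[i1], d$r_Others[i1])
  first <- d$time_min[which(d$r_Gpd1 > d$r_Fps1 &
                              d$r_Gpd1 > d$r_Others &
                              d$time_min >= 0)[1]]
  expect_lte(first, 15)
})

test_that("the open-channel mutant stays in sustained production late", {
  d <- decompose_glycerol_flux(sim_ref("FPS1-Δ1"))
  late <- d$time_min >= 120
  # a futile production/efflux cycle: Gpd1-attributed production remains
  # a dominant contribution and its absolute rate stays enormous
  expect_true(all(d$r_Gpd1[late] > 0.4))
  expect_true(all(d$r_Gpd1[late] > d$r_Others[late]))
  expect_gt(mean(d$J_Gpd1[late]), 100 * d$J_Gpd1[1])
})

test_that("doubling time matches the closed form for constant growth", {
  mu <- 0.004
  t <- seq(0, 120, 2)
  fake <- structure(list(times = t,
                         state = cbind(CD = 1e6 * exp(mu * t))),
                    class = "hog_sim")
  expect_equal(doubling_time(fake, c(0, 120)), log(2) / mu,
               tolerance = 1e-10)
})

test_that("stress slows growth; losing Gpd1 hurts less than losing Hog1", {
  dts <- vapply(c("WT", "gpd1Δ", "hog1Δ"), function(s) {
    sim <- sim_ref(s, t_end = 90, t0 = -60)
    c(pre = doubling_time(sim, c(-60, 0)),
      post = doubling_time(sim, c(0, 90)))
  }, numeric(2))
  ratio <- dts["post", ] / dts["pre", ]
  expect_gt(ratio[["WT"]], 1) # growth slows after the shock
  expect_lt(ratio[["gpd1Δ"]], ratio[["hog1Δ"]])
})

test_that("carbon shares audit the trade-off between growth and glycerol", {
  sim <- sim_ref("WT")
  pre <- flux_shares(sim, 0)
  expect_gt(pre$biomass_share, pre$glycerol_share)
  s20 <- flux_shares(sim, 20)
  expect_gt(s20$glycerol_share, s20$biomass_share)

  # bookkeeping identity: the residual share equals the carbon
  # accumulating in the glycolytic/storage pools, recomputed from the
  # reference right-hand side
  for (tt in c(0, 20, 90)) {
    i <- match(tt, sim$times)
    st <- pmax(sim$state[i, ], 0)
    r <- evaluate_rhs(st, tt, sim$params)
    v <- reaction_fluxes(st, sim$params)
    mu <- compute_observables(st, sim$params)[["mu"]]
    pools <- 6 * r[["Glci"]] + 6 * r[["HexP"]] + 6 * r[["FBP"]] +
      3 * r[["TriP"]] +
      mu * (6 * st[["Glci"]] + 6 * st[["HexP"]] + 6 * st[["FBP"]] +
              3 * st[["TriP"]]) +
      12 * v[["vTPS"]] - 12 * v[["vNTH"]]
    oracle <- pools / (6 * v[["vHXT"]])
    fs <- flux_shares(sim, tt)
    expect_lt(abs(fs$pool_change_share - oracle), 1e-9)
    expect_lt(abs(fs$biomass_share + fs$glycerol_share +
                    fs$ethanol_acetate_share + fs$pool_change_share - 1),
              1e-12)
  }

  # lower-glycolysis carbon flux is buffered through adaptation
  vlg <- sim$flux[, "vLG"]
  expect_lt(abs(vlg[sim$times == 20] / vlg[1] - 1), 0.15)
})
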