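test_that("noise-free generation reproduces the simulation bit for bit", {
  p <- ref_params()
  tab <- generate_model_based(p, "WT",
                              noise = noise_spec(sigma_rel = 0,
                                                 n_rep = 1, seed = 3))
  sched <- sort(unique(tab$time_min))
  sim <- hog_simulate(p, "WT",
                      stress_protocol(t_end = 240, t_grid = sched))
  mv <- measured_variables()
  for (i in seq_len(nrow(mv))) {
    sub <- tab[tab$variable == mv$variable[i], ]
    y <- pmax(hogadapt:::sim_value(sim, mv$sim_var[i])[
      match(sub$time_min, sim$times)], 0)
    expect_identical(sub$value, unname(y))
  }
})

test_that("generation is reproducible under a fixed seed", {
  p <- ref_params()
  ns <- noise_spec(sigma_rel = 0.2, n_rep = 2, seed = 11)
  t1 <- generate_model_based(p, "WT", schedule = c(0, 30, 60), noise = ns)
  t2 <- generate_model_based(p, "WT", schedule = c(0, 30, 60), noise = ns)
  expect_identical(t1, t2)
  t3 <- generate_model_based(p, "WT", schedule = c(0, 30, 60),
                             noise = noise_spec(0.2, n_rep = 2, seed = 12))
  expect_false(identical(t1$value, t3$value))
})

test_that("the multiplicative noise has the nominal coefficient of variation", {
  p <- ref_params()
  sr <- 0.15
  tab <- generate_model_based(p, "WT", schedule = c(0, 30),
                              noise = noise_spec(sigma_rel = sr,
                                                 n_rep = 1000, seed = 5))
  v <- tab$value[tab$variable == "Glyi" & tab$time_min == 30]
  expect_length(v, 1000)
  cv <- sd(v) / mean(v)
  se_cv <- sr / sqrt(2 * length(v))
  expect_lt(abs(cv - sr), 3 * se_cv)
  # lognormal factors are mean-one: the signal is unbiased
  expect_lt(abs(mean(v) / mean(tab$value[tab$variable == "Glyi" &
                                           tab$time_min == 30]) - 1), 0.02)
})

test_that("the trehalose template peaks exactly at 45 and 180 minutes", {
  t <- 0:240
  y <- trehalose_template(t)
  is_max <- which(diff(sign(diff(y))) == -2) + 1
  expect_equal(t[is_max], c(45, 180))
  expect_equal(t[which.max(y[t <= 120])], 45)
  expect_equal(120 + which.max(y[t >= 120]) - 1, 180)
  expect_lt(y[t == 0], y[t == 45])
  expect_error(trehalose_template(-5), "0, 240")
})

test_that("phenomenological templates reproduce the qualitative dataset", {
  tab <- generate_phenomenological(noise_spec(sigma_rel = 0, n_rep = 1,
                                              seed = 1),
                                   schedule = 0:240)
  expect_silent(validate_measurement_table(tab))
  get <- function(v) tab$value[tab$variable == v][order(
    tab$time_min[tab$variable == v])]
  expect_true(all(diff(get("Glce")) < 0)) # glucose strictly consumed
  for (v in c("Glye", "EtOHe", "AcOe", "Tree", "CD")) {
    expect_true(all(diff(get(v)) > 0))
  }
  hog <- get("Hog1PP")
  expect_lt(which.max(hog) - 1, 15) # transient pulse peaks early
  gly <- get("Glyi")
  pk <- which.max(gly) - 1
  expect_gte(pk, 30)
  expect_lte(pk, 60)
  tre <- get("Trei")
  im <- which(diff(sign(diff(tre))) == -2)
  expect_equal(im, c(45, 180))
})

test_that("both generators share one schema and one reader", {
  p <- ref_params()
  ns <- noise_spec(sigma_rel = 0.1, n_rep = 2, seed = 2)
  mb <- generate_model_based(p, "WT", schedule = c(0, 60), noise = ns)
  ph <- generate_phenomenological(ns)
  expect_identical(names(mb), names(ph))
  f <- tempfile(fileext = ".csv")
  write_timecourse_csv(ph, f)
  back <- read_timecourse_csv(f)
  expect_equal(as.data.frame(back), as.data.frame(ph))
})
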