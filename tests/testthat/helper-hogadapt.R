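# Shared fixtures. Simulations are cached in this environment so that
# test files can reuse the expensive trajectories.
.cache <- new.env(parent = emptyenv())

ref_params <- function() {
  if (is.null(.cache$params)) .cache$params <- hog_params()
  .cache$params
}

# memoised simulation at reference parameters
sim_ref <- function(strain = "WT", t_end = 180, t0 = 0, by = 1,
                    NaCl = 0.4) {
  key <- paste(strain, t_end, t0, by, NaCl, sep = "|")
  if (is.null(.cache[[key]])) {
    .cache[[key]] <- hog_simulate(
      ref_params(), strain,
      stress_protocol(NaCl_step = NaCl, t_end = t_end,
                      t_grid = seq(t0, t_end, by = by)))
  }
  .cache[[key]]
}

eq_ref <- function(strain = "WT") {
  key <- paste0("eq|", strain)
  if (is.null(.cache[[key]])) {
    .cache[[key]] <- prestress_equilibrate(apply_strain(ref_params(),
                                                        strain))
  }
  .cache[[key]]
}

# random valid state: multiplicative jitter around the initial guess
random_state <- function(seed) {
  set.seed(seed)
  s <- hog_initial_guess(ref_params())
  s <- s * exp(rnorm(length(s), 0, 0.3))
  s[["Fps1o"]] <- runif(1)
  s[["NaCle"]] <- runif(1, 0, 0.8)
  s
}
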