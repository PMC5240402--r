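# Shared fixtures: the reference two-pump set-up and cached heavy objects.

ud_std <- to_internal(6, "ml/h")     # green downstep magnitude
uf_std <- to_internal(6.5, "ml/h")   # stabilized total rate after the step
uR_std <- to_internal(0.5, "ml/h")
uold_std <- to_internal(12, "ml/h")
ufinG_std <- to_internal(6, "ml/h")

.test_cache <- new.env(parent = emptyenv())
memo <- function(name, thunk) {
  if (!exists(name, envir = .test_cache)) {
    assign(name, thunk(), envir = .test_cache)
  }
  get(name, envir = .test_cache)
}

std_flow <- function() memo("std_flow", function() {
  s <- standard_setup()
  t_max <- multinfusion:::t_max_horizon(s)
  state_space_simulate(s, multinfusion:::.default_grid(s, t_max))
})

std_trace <- function() memo("std_trace", function() {
  assemble_trace(standard_setup())
})

std_oracle <- function() memo("std_oracle", function() {
  oracle_simulate(standard_setup())
})

std_entry <- function(convention = "actual") {
  memo(paste0("std_entry_", convention), function() {
    entry_sequence(std_flow(), standard_setup()$catheter, uf_std,
                   lambda_convention = convention)
  })
}

# random two-pump set-up, log-uniform over a factor 10 around the standard
# values; returns the setup plus its canonical step sizes
random_draw <- function() {
  logu <- function(center) center * 10^stats::runif(1, -1, 1)
  u_old <- logu(12)
  u_final <- u_old * stats::runif(1, 0.1, 0.9)
  u_red <- logu(0.5)
  green <- pump_channel("green", compliance = logu(1.5e-5),
                        line_resistance = logu(23),
                        schedule = data.frame(time = c(-Inf, 0),
                                              rate = c(u_old, u_final)))
  red <- pump_channel("red", compliance = logu(1.5e-5),
                      line_resistance = logu(23),
                      schedule = data.frame(time = -Inf, rate = u_red))
  setup <- infusion_setup(list(green, red),
                          catheter_spec(logu(1145), volume = logu(1)))
  list(setup = setup,
       downstep = to_internal(u_old - u_final, "ml/h"),
       u_final = to_internal(u_final + u_red, "ml/h"))
}

# entry sequence built from the closed-form transient (no ODE run): cheap
# per-draw input for moment property tests
analytic_entry <- function(setup, downstep, u_final, n_vox = 1000L,
                           convention = "stabilized") {
  cath <- setup$catheter
  cath$n_voxels <- as.integer(n_vox)
  cath$gamma <- cath$length / n_vox
  tf <- transient_flow(setup, downstep)
  t_max <- max(10 * tf$theta_second, 3 * cath$volume / u_final)
  tg <- seq(0, t_max, length.out = 4000L)
  u <- u_m_diff(tf, tg)
  flow <- list(times = tg,
               u_diff = matrix(u, ncol = 1, dimnames = list(NULL, "red")),
               u_cath = u_final + u, labels = "red")
  entry_sequence(flow, cath, u_final, channel = "red",
                 lambda_convention = convention)
}
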