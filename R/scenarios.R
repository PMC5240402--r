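#' Scenario assembly and named runs
#'
#' [assemble_trace()] composes the full patient-facing dosing-error trace of
#' the monitored fluid for a single rate-step event: zero before the event,
#' the constant push-out deviation until the Poiseuille first arrival, and
#' the tip-composition bolus (compliance convolution plus remnant) after it.
#' Multi-event schedules are not composed analytically (the closed forms
#' assume a stabilized flow at the first arrival); they run through
#' [state_space_simulate()] / [oracle_simulate()].
#'
#' @name scenarios
NULL

# identify the single finite-time step event in a set-up
.find_event <- function(setup) {
  ev <- list()
  for (i in seq_along(setup$channels)) {
    ch <- setup$channels[[i]]
    ft <- ch$schedule$time[is.finite(ch$schedule$time)]
    for (t in ft) ev[[length(ev) + 1L]] <- list(channel = i, time = t)
    if (!is.null(ch$clamps))
      for (j in seq_len(nrow(ch$clamps)))
        ev[[length(ev) + 1L]] <- list(channel = i, time = ch$clamps$start[j],
                                      clamp = TRUE)
  }
  ev
}

#' Assemble the patient-facing dosing-error trace for a single step event
#'
#' @param setup two-channel [infusion_setup()] whose schedule contains
#'   exactly one rate change, at t = 0, on the non-monitored channel.
#' @param poiseuille if `TRUE` (default) the bolus uses the Poiseuille
#'   tip-composition model and the push-out branch ends at `t_delay / 2`;
#'   if `FALSE`, plug flow with push-out until `t_delay`.
#' @param monitored label of the monitored channel (default `"red"`).
#' @param fill stretch fill mode, see [stretch_sequence()].
#' @return object of class `dose_error_trace`: `times` (s), `beta` (ml/s),
#'   `branch` (factor: pre / pushout / compliance), `metrics`
#'   (a `bolus_metrics` of the post-delay bolus), `pushout_volume` (ml),
#'   `Q_closed` (ml, the closed-form compliance volume), `t_delay`,
#'   `t_delay_pois`, and the component objects.
#' @export
assemble_trace <- function(setup, poiseuille = TRUE, monitored = "red",
                           fill = "hold") {
  events <- .find_event(setup)
  labels <- vapply(setup$channels, `[[`, character(1), "label")
  mon_i <- if (is.character(monitored)) match(monitored, labels) else monitored
  if (is.na(mon_i)) stop("monitored channel '", monitored, "' not found",
                         call. = FALSE)
  if (length(events) > 1L)
    stop("more than one setting change: analytic superposition of ",
         "overlapping boluses is not supported; use oracle_simulate() or ",
         "state_space_simulate()", call. = FALSE)
  cath <- setup$catheter
  t_max <- t_max_horizon(setup)
  t_grid <- .default_grid(setup, t_max)
  if (length(events) == 0L) {
    return(structure(list(times = t_grid, beta = numeric(length(t_grid)),
                          branch = rep("pre", length(t_grid)),
                          metrics = NULL, pushout_volume = 0, Q_closed = 0,
                          t_delay = NA_real_, t_delay_pois = NA_real_,
                          setup_config = setup_to_config(setup)),
                     class = "dose_error_trace"))
  }
  ev <- events[[1L]]
  if (!is.null(ev$clamp))
    stop("clamp events are handled by syringe_exchange_error() or the ",
         "simulators, not by assemble_trace()", call. = FALSE)
  if (abs(ev$time) > 1e-12)
    stop("assemble_trace expects the step event at t = 0", call. = FALSE)
  if (ev$channel == mon_i)
    stop("the monitored channel's own rate changes; assemble_trace models ",
         "a step on the other channel", call. = FALSE)

  ch_ev <- setup$channels[[ev$channel]]
  u_old_G <- rate_at(ch_ev, -1e-9)
  u_final_G <- rate_at(ch_ev, 1e9)
  u_mon <- rate_at(setup$channels[[mon_i]], 1e9)
  u_final_tot <- u_final_G + u_mon
  downstep <- u_old_G - u_final_G

  flow <- state_space_simulate(setup, t_grid)
  t_delay <- delay_time(flow, cath)
  t_pois <- poiseuille_tip_delay(t_delay)
  # true first arrival of the parabola tip: half the dead volume displaced
  # (equals t_delay / 2 exactly only for constant flow)
  i0 <- which(flow$times >= 0)
  t_arr <- .invert_cum(flow$times[i0], flow$u_cath[i0], cath$volume / 2)
  push <- pushout_flow(u_mon, u_old_G, u_final_G)
  lam <- displacement(list(times = flow$times[i0], u_cath = flow$u_cath[i0]),
                      cath)

  entry <- entry_sequence(flow, cath, u_final = u_final_tot,
                          channel = labels[mon_i])
  t_head <- if (poiseuille) t_arr else t_delay
  times <- c(-rev(seq(1e-3, t_pois, length.out = 25L)), flow$times)
  beta <- numeric(length(times))
  branch <- rep("pre", length(times))
  in_push <- times >= 0 & times < t_head
  beta[in_push] <- push
  branch[in_push] <- "pushout"
  after <- times >= t_head
  branch[after] <- "compliance"
  lam_after <- stats::approx(lam$times, lam$lambda, xout = times[after],
                             rule = 2)$y

  if (poiseuille) {
    lam_end <- lam$lambda[length(lam$lambda)]
    k_max <- max(cath$n_voxels,
                 ceiling((2 * lam_end - cath$length) / cath$gamma))
    kernel <- poiseuille_kernel(cath, k_max)
    bolus <- tip_convolution(entry, kernel, u_pump_R = u_mon,
                             u_old_G = u_old_G, u_final_G = u_final_G,
                             fill = fill)
    psi <- bolus$psi_pois + bolus$psi_remnant
    # exit index advances with the actual displacement: gamma*k = 2*lambda - L
    k_t <- (2 * lam_after - cath$length) / cath$gamma
    beta[after] <- stats::approx(bolus$k, psi, xout = pmax(k_t, 0),
                                 rule = 2)$y * u_final_tot
    beta_pois <- numeric(length(times))
    beta_pois[after] <- stats::approx(bolus$k, bolus$psi_pois,
                                      xout = pmax(k_t, 0),
                                      rule = 2)$y * u_final_tot
    metrics <- discrete_moments(bolus, which = "patient")
  } else {
    bolus <- NULL
    beta_pois <- NULL
    # plug-flow exit: gamma*j = lambda - L
    j_t <- (lam_after - cath$length) / cath$gamma
    a_tail <- stats::approx(seq_along(entry$a_diff) - 1, entry$a_diff,
                            xout = pmax(j_t, 0), rule = 2)$y
    beta[after] <- a_tail * u_final_tot
    metrics <- discrete_moments(entry)
  }
  metrics$t_delay <- t_delay
  metrics$t_delay_pois <- t_pois
  structure(list(
    times = times, beta = beta, beta_pois = beta_pois, branch = branch,
    metrics = metrics,
    pushout_volume = push * t_head,
    Q_closed = dosing_error_volume(setup, downstep),
    t_delay = t_delay, t_delay_pois = t_pois, t_first_arrival = t_arr,
    entry = entry, bolus = bolus, flow = flow,
    setup_config = setup_to_config(setup)
  ), class = "dose_error_trace")
}

#' @export
as.data.frame.dose_error_trace <- function(x, ...) {
  data.frame(time_s = x$times, beta_ml_per_s = x$beta, branch = x$branch)
}

#' Run a named scenario
#'
#' * `"downstep"`: the reference green rate reduction; returns the assembled
#'   trace, discrete metrics and the closed-form Q, t_central, sigma.
#' * `"syringe_exchange"` (alias `"exchange_sweep"`): accumulated error vs
#'   exchange duration, with the compliance-only, pump-on-only and combined
#'   curves (the combined curve is their sum).
#' * `"parameter_sweep"`: transient deviation curves for the documented
#'   catheter resistance and compliance variants (R_cath x 3, x 2, x 1;
#'   C_red x 0.52, x 0.36), each with its dosing-error volume.
#'
#' @param name scenario name.
#' @param setup base set-up (default [standard_setup()]).
#' @param T_grid exchange durations, s (exchange scenarios).
#' @param t_grid evaluation times for transient curves, s.
#' @return a named list bundle; contents depend on the scenario.
#' @export
run_scenario <- function(name = c("downstep", "syringe_exchange",
                                  "parameter_sweep", "exchange_sweep"),
                         setup = standard_setup(),
                         T_grid = seq(0, 900, by = 5),
                         t_grid = seq(0, 900, by = 0.5)) {
  name <- match.arg(name)
  u_old <- rate_at(setup$channels[[1]], -1e-9)
  u_final <- rate_at(setup$channels[[1]], 1e9)
  downstep <- u_old - u_final
  u_mon <- rate_at(setup$channels[[2]], 1e9)
  switch(name,
    downstep = {
      trace <- assemble_trace(setup)
      list(trace = trace, metrics = trace$metrics,
           closed_form = list(
             Q = dosing_error_volume(setup, downstep),
             t_central = t_central_closed(setup, downstep,
                                          u_final + u_mon),
             sigma = sigma_closed(setup, downstep, u_final + u_mon),
             sigma_pois = sigma_closed(setup, downstep, u_final + u_mon,
                                       with_poiseuille = TRUE)))
    },
    syringe_exchange = ,
    exchange_sweep = {
      comp <- syringe_exchange_error(setup, T_grid, red_pump_on = FALSE)
      pump <- u_mon * T_grid
      list(T_exchange = T_grid,
           compliance_only = comp,
           pump_on_only = pump,
           combined = comp + pump)
    },
    parameter_sweep = {
      variants <- list(
        `1` = c(C_red = 1.00, R_cath = 3),
        `2` = c(C_red = 1.00, R_cath = 2),
        `3` = c(C_red = 1.00, R_cath = 1),
        `4` = c(C_red = 0.52, R_cath = 1),
        `5` = c(C_red = 0.36, R_cath = 1))
      curves <- lapply(variants, function(v) {
        s <- setup
        s$channels[[2]]$compliance <- s$channels[[2]]$compliance * v[["C_red"]]
        s$catheter$resistance <- s$catheter$resistance * v[["R_cath"]]
        tf <- transient_flow(s, downstep)
        list(setup = s, transient = tf,
             u_diff = u_m_diff(tf, t_grid),
             Q = dosing_error_volume(s, downstep))
      })
      list(times = t_grid, variants = curves)
    })
}

#' Generate deterministic fixture configurations
#'
#' Writes the standard set-up, the documented resistance/compliance sweep
#' variants, the two syringe-exchange variants (600 s clamp, red pump on or
#' off), and seeded random draws (log-uniform over a factor 10 around the
#' standard values) for property testing. Byte-identical for equal seeds.
#'
#' @param seed integer seed.
#' @param out_dir output directory (created if missing).
#' @param n_random number of random draws.
#' @return character vector of file paths, invisibly.
#' @export
generate_fixtures <- function(seed, out_dir, n_random = 10L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  paths <- character(0)
  emit <- function(setup, name) {
    p <- file.path(out_dir, paste0(name, ".yaml"))
    write_setup(setup, p)
    paths <<- c(paths, p)
  }
  std <- standard_setup()
  emit(std, "standard")
  sweep <- list(c(1, 3), c(1, 2), c(1, 1), c(0.52, 1), c(0.36, 1))
  for (i in seq_along(sweep)) {
    s <- std
    s$channels[[2]]$compliance <- s$channels[[2]]$compliance * sweep[[i]][1]
    s$catheter$resistance <- s$catheter$resistance * sweep[[i]][2]
    emit(s, sprintf("sweep_v%d", i))
  }
  for (pump_on in c(TRUE, FALSE)) {
    s <- std
    s$channels[[1]]$schedule <- data.frame(time = -Inf,
                                           rate = s$channels[[1]]$schedule$rate[1])
    s$channels[[1]]$clamps <- data.frame(start = 0, end = 600)
    if (!pump_on) {
      r0 <- s$channels[[2]]$schedule$rate[1]
      s$channels[[2]]$schedule <- data.frame(time = c(-Inf, 0, 600),
                                             rate = c(r0, 0, r0))
    }
    emit(s, if (pump_on) "exchange_pump_on" else "exchange_pump_off")
  }
  logu <- function(center) center * 10^stats::runif(1, -1, 1)
  for (i in seq_len(n_random)) {
    u_old <- logu(12); u_red <- logu(0.5)
    u_final <- u_old * stats::runif(1, 0.1, 0.9)
    green <- pump_channel("green", compliance = logu(1.5e-5),
                          line_resistance = logu(23),
                          schedule = data.frame(time = c(-Inf, 0),
                                                rate = c(u_old, u_final)),
                          rate_unit = "ml/h")
    red <- pump_channel("red", compliance = logu(1.5e-5),
                        line_resistance = logu(23),
                        schedule = data.frame(time = -Inf, rate = u_red))
    s <- infusion_setup(list(green, red),
                        catheter_spec(resistance = logu(1145),
                                      volume = logu(1)))
    emit(s, sprintf("random_%03d", i))
  }
  invisible(paths)
}
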