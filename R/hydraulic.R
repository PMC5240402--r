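#' Electric-analog (RC network) model of the set-up
#'
#' Each channel is modelled as a flow source in parallel with a capacitor
#' (the syringe compliance) feeding through its line resistance into the
#' mixing point M, from which the catheter resistance R_cath leads to a
#' zero-pressure sink at the tip P. For the two-pump case the mixing-point
#' deviation flow of the monitored (red) channel after a rate step of the
#' other (green) channel has a closed two-exponential form; the general case
#' is handled numerically by [state_space_simulate()].
#'
#' @name hydraulic_network
NULL

# quadratic coefficients of the second-order network (two-pump case);
# channel 1 = changed (green, C1/R1), channel 2 = monitored (red, C2/R2)
network_coefficients <- function(setup) {
  if (length(setup$channels) != 2L)
    stop("closed forms require exactly 2 channels; use state_space_simulate()",
         call. = FALSE)
  Rc <- setup$catheter$resistance
  R1 <- setup$channels[[1]]$line_resistance
  R2 <- setup$channels[[2]]$line_resistance
  C1 <- setup$channels[[1]]$compliance
  C2 <- setup$channels[[2]]$compliance
  a <- Rc * R1 + Rc * R2 + R1 * R2
  b <- C1 * (Rc + R1) + C2 * (Rc + R2)
  c <- C1 * C2
  list(a = a, b = b, c = c, Rc = Rc, R1 = R1, R2 = R2, C1 = C1, C2 = C2,
       disc_root = sqrt(max(b^2 - 4 * a * c, 0)))
}

#' Laplace-domain transfer description of the two-pump step response
#'
#' Second-order rational transfer from a green-pump rate step of size
#' `downstep` to the red mixing-point deviation flow: the denominator is
#' `s^2 * (a*c) + s * b + 1` with `a`, `b`, `c` the network coefficients and
#' the numerator proportional to `C2 * R_cath * downstep`.
#'
#' @param setup an [infusion_setup()] with exactly 2 channels.
#' @param downstep magnitude of the green rate decrease, ml/s (a positive
#'   value means a decrease and yields a positive red excess flow).
#' @return list with `numerator` (ml, the constant numerator coefficient)
#'   and `denominator` (coefficients of s^2, s^1, s^0; units s^2, s, 1).
#' @export
laplace_transfer_two_pump <- function(setup, downstep) {
  k <- network_coefficients(setup)
  list(numerator = k$C2 * k$Rc * downstep,
       denominator = c(k$a * k$c, k$b, 1))
}

#' Two-exponential transient of the red mixing-point deviation flow
#'
#' After the green pump steps down by `downstep` at t = 0, the excess flow
#' of red fluid entering the catheter is
#' `u_diff(t) = downstep * R_cath * C2 * (exp(-t/theta_second) - exp(-t/theta_first)) / sqrt(b^2 - 4ac)`
#' with time constants `theta_first <= theta_second` given by the roots of
#' the network quadratic. Evaluate with [u_m_diff()].
#'
#' @inheritParams laplace_transfer_two_pump
#' @return object of class `transient_flow` with fields `amplitude_factor`
#'   (ml, = downstep * R_cath * C2), `theta_first`, `theta_second`,
#'   `disc_root` (s), and coefficients `a`, `b`, `c`.
#' @export
transient_flow <- function(setup, downstep) {
  k <- network_coefficients(setup)
  if (k$Rc <= 0 || k$C1 <= 0 || k$C2 <= 0)
    stop("transient_flow requires positive R_cath and compliances", call. = FALSE)
  structure(list(
    amplitude_factor = downstep * k$Rc * k$C2,
    theta_first = (k$b - k$disc_root) / 2,
    theta_second = (k$b + k$disc_root) / 2,
    disc_root = k$disc_root,
    a = k$a, b = k$b, c = k$c,
    downstep = downstep
  ), class = "transient_flow")
}

#' Evaluate a two-exponential transient
#'
#' @param tf a [transient_flow()].
#' @param t times, s (vectorized); zero for t < 0.
#' @return red deviation flow, ml/s.
#' @export
u_m_diff <- function(tf, t) {
  out <- numeric(length(t))
  pos <- t >= 0
  e2 <- exp(-t[pos] / tf$theta_second)
  e1 <- if (tf$theta_first > 0) exp(-t[pos] / tf$theta_first) else
    ifelse(t[pos] > 0, 0, 1)
  out[pos] <- tf$amplitude_factor * (e2 - e1) / tf$disc_root
  out
}

#' Time of the transient's peak
#'
#' For the two-exponential form the maximum lies at
#' `t* = log(theta2/theta1) * theta1 * theta2 / (theta2 - theta1)`.
#'
#' @param tf a [transient_flow()].
#' @return time of maximum deviation, s.
#' @export
transient_peak_time <- function(tf) {
  t1 <- tf$theta_first; t2 <- tf$theta_second
  if (t1 <= 0) return(0)
  if (t1 == t2) return(t1)
  log(t2 / t1) * t1 * t2 / (t2 - t1)
}

#' Total volume of the dosing-error bolus
#'
#' `Q = C2 * R_cath * downstep`: the stored elastic volume released by the
#' red syringe when the mixing-point pressure drops. Independent of the line
#' resistances and of the shape of the transient.
#'
#' @inheritParams laplace_transfer_two_pump
#' @return dosing-error volume, ml.
#' @export
dosing_error_volume <- function(setup, downstep) {
  k <- network_coefficients(setup)
  k$C2 * k$Rc * downstep
}

#' Dosing error accumulated during a syringe exchange
#'
#' The green line is clamped over `[0, T_exchange]`. Undiluted red fluid
#' accumulates past the mixing point from two sources: the red pump itself
#' (if left running) and the discharge of the red syringe compliance driven
#' by the pressure drop. The compliance term is the time-integral of the
#' two-exponential transient with the full old green rate as step size; it
#' saturates at `C2 * R_cath * u_old` as `T_exchange -> Inf`.
#'
#' @param setup two-channel [infusion_setup()]; channel 1 green, channel 2 red.
#' @param T_exchange duration(s) of the exchange, s (vectorized).
#' @param red_pump_on if `TRUE` the red pump keeps running at its set rate
#'   during the exchange, adding `u_pump_R * T_exchange`.
#' @return accumulated excess red volume, ml.
#' @export
syringe_exchange_error <- function(setup, T_exchange, red_pump_on = TRUE) {
  if (any(T_exchange < 0)) stop("T_exchange must be >= 0", call. = FALSE)
  u_old <- rate_at(setup$channels[[1]], -1e-9)
  tf <- transient_flow(setup, downstep = u_old)
  t1 <- tf$theta_first; t2 <- tf$theta_second
  e1 <- if (t1 > 0) 1 - exp(-T_exchange / t1) else as.numeric(T_exchange > 0)
  compliance <- tf$amplitude_factor *
    (t2 * (1 - exp(-T_exchange / t2)) - t1 * e1) / tf$disc_root
  if (red_pump_on) {
    u_red <- rate_at(setup$channels[[2]], -1e-9)
    compliance + u_red * T_exchange
  } else {
    compliance
  }
}

## ---- general linear state-space engine -------------------------------------

#' Simulate the RC network for arbitrary channels and schedules
#'
#' Integrates the linear ODE system with one pressure state per syringe
#' compliance. Open branch i: `C_i dp_i/dt = u_i(t) - (p_i - p_M)/R_i`,
#' with the mixing-point pressure solved algebraically from Kirchhoff's
#' current law, `p_M * (1/R_cath + sum 1/R_i) = sum p_i/R_i`. A clamped
#' branch is an open circuit (removed from the network); its pump still
#' charges the compliance: `C_i dp_i/dt = u_i(t)`. The initial state is the
#' steady state for the rates just before `min(t_grid)`.
#'
#' Integration uses an adaptive stiff-capable scheme (`deSolve::lsoda`)
#' restarted at every schedule breakpoint and clamp edge, then sampled on
#' the caller's grid.
#'
#' @param setup an [infusion_setup()] (any number of channels).
#' @param t_grid times at which to report, s (increasing).
#' @param rtol,atol integration tolerances.
#' @return object of class `flow_trace`: list with `times`, matrix `q`
#'   (mixing-point inflow per channel, ml/s), matrix `u_set` (set rates),
#'   matrix `u_diff` (= q - u_set), vector `u_cath` (total catheter flow),
#'   matrix `p` (syringe pressures, Pa), vector `excess_volume` (exactly
#'   integrated cumulative `u_cath - sum(set rates)`, ml) and `labels`.
#' @export
state_space_simulate <- function(setup, t_grid, rtol = 1e-11, atol = 1e-13) {
  chans <- setup$channels
  n <- length(chans)
  Rc <- setup$catheter$resistance
  R <- vapply(chans, `[[`, numeric(1), "line_resistance")
  C <- vapply(chans, `[[`, numeric(1), "compliance")
  if (any(R <= 0) || any(C <= 0) || Rc <= 0)
    stop("state_space_simulate requires positive resistances and compliances",
         call. = FALSE)
  t0 <- t_grid[1]

  breaks <- sort(unique(c(
    t_grid[1], t_grid[length(t_grid)],
    unlist(lapply(chans, function(ch) {
      c(ch$schedule$time, if (!is.null(ch$clamps)) c(ch$clamps$start, ch$clamps$end))
    })))))
  breaks <- breaks[is.finite(breaks) & breaks >= t0 & breaks <= t_grid[length(t_grid)]]
  breaks <- sort(unique(c(t0, breaks, t_grid[length(t_grid)])))

  mix_pressure <- function(p, open) {
    sum(p[open] / R[open]) / (1 / Rc + sum(1 / R[open]))
  }
  # steady state just before t0 (all branches taken as open)
  u0 <- vapply(chans, rate_at, numeric(1), t = t0 - 1e-9)
  pM0 <- Rc * sum(u0)
  p <- c(pM0 + R * u0, 0)

  out_t <- numeric(0); out_p <- NULL
  for (seg in seq_len(length(breaks) - 1L)) {
    ta <- breaks[seg]; tb <- breaks[seg + 1L]
    tm <- (ta + tb) / 2
    u_seg <- vapply(chans, rate_at, numeric(1), t = tm)
    open <- !vapply(chans, is_clamped, logical(1), t = tm)
    deriv <- function(t, p, parms) {
      # states 1..n: syringe pressures; state n+1: exact cumulative excess
      # volume int(u_cath - sum of set rates) dt
      dp <- numeric(n + 1L)
      u_cath_t <- 0
      io <- which(open); ic <- which(!open)
      if (length(io)) {
        pM <- mix_pressure(p[seq_len(n)], open)
        dp[io] <- (u_seg[io] - (p[io] - pM) / R[io]) / C[io]
        u_cath_t <- pM / Rc
      }
      if (length(ic)) dp[ic] <- u_seg[ic] / C[ic]
      dp[n + 1L] <- u_cath_t - sum(u_seg)
      list(dp)
    }
    tt <- sort(unique(c(ta, t_grid[t_grid >= ta & t_grid <= tb], tb)))
    sol <- deSolve::lsoda(y = p, times = tt, func = deriv, parms = NULL,
                          rtol = rtol, atol = atol)
    p <- as.numeric(sol[nrow(sol), -1L])
    keep <- if (seg == 1L) seq_len(nrow(sol)) else -1L
    out_t <- c(out_t, sol[keep, 1L])
    out_p <- rbind(out_p, sol[keep, -1L, drop = FALSE])
  }
  # restrict to the caller's grid
  sel <- match(t_grid, out_t)
  if (anyNA(sel)) { # grid points interior to segments are all in out_t; guard anyway
    sel <- vapply(t_grid, function(t) which.min(abs(out_t - t)), integer(1))
  }
  times <- out_t[sel]
  P <- out_p[sel, seq_len(n), drop = FALSE]
  excess_volume <- out_p[sel, n + 1L]

  u_set <- vapply(chans, rate_at, numeric(length(times)), t = times)
  u_set <- matrix(u_set, ncol = n)
  clamped <- vapply(chans, is_clamped, logical(length(times)), t = times)
  clamped <- matrix(clamped, ncol = n)
  q <- matrix(0, nrow = length(times), ncol = n)
  u_cath <- numeric(length(times))
  for (i in seq_along(times)) {
    open <- !clamped[i, ]
    if (any(open)) {
      pM <- mix_pressure(P[i, ], open)
      q[i, open] <- (P[i, open] - pM) / R[open]
      u_cath[i] <- pM / Rc
    }
  }
  labels <- vapply(chans, `[[`, character(1), "label")
  colnames(q) <- colnames(u_set) <- colnames(P) <- labels
  structure(list(times = times, q = q, u_set = u_set, u_diff = q - u_set,
                 u_cath = u_cath, p = P, excess_volume = excess_volume,
                 labels = labels),
            class = "flow_trace")
}

#' @export
as.data.frame.flow_trace <- function(x, ...) {
  df <- data.frame(time_s = x$times)
  for (lb in x$labels) df[[paste0("u_M_diff_", lb, "_ml_per_s")]] <- x$u_diff[, lb]
  df$u_cath_ml_per_s <- x$u_cath
  df
}

#' Export a flow trace as CSV
#' @param x a `flow_trace`.
#' @param path output file.
#' @export
write_flow_trace <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

# default simulation horizon: generous multiple of the slow time constant
# and of the dead-volume turnover at the final rate
t_max_horizon <- function(setup, downstep = NULL) {
  k <- tryCatch(network_coefficients(setup), error = function(e) NULL)
  theta2 <- if (!is.null(k)) (k$b + k$disc_root) / 2 else {
    max(vapply(setup$channels, function(ch)
      ch$compliance * (setup$catheter$resistance + ch$line_resistance),
      numeric(1)))
  }
  t_end <- 1e9
  u_final <- sum(vapply(setup$channels, rate_at, numeric(1), t = t_end))
  max(10 * theta2, 3 * setup$catheter$volume / u_final)
}
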