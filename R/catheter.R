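#' Plug-flow voxel model of the catheter contents
#'
#' The catheter lumen between the mixing point M (voxel index k = N) and the
#' tip P (k = 0) acts as a FIFO memory: each voxel holds a composition vector
#' of fluid fractions that sums to one, advected toward the tip by the total
#' flow. The cumulative displacement `lambda_tot(t) = (L/V_cath) * int u_cath`
#' converts flow history into travel distance.
#'
#' @name catheter_memory
NULL

# cumulative trapezoid integral, same length as x, starting at 0
cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (y[-1] + y[-length(y)]) / 2))
}

#' Cumulative displacement of the catheter contents
#'
#' @param flow a `flow_trace` from [state_space_simulate()] (or any list with
#'   `times` and `u_cath`).
#' @param catheter a [catheter_spec()].
#' @return object of class `displacement_curve`: list with `times` and
#'   `lambda` (length units), non-decreasing with `lambda[1] = 0`.
#' @export
displacement <- function(flow, catheter) {
  lam <- catheter$length / catheter$volume * cumtrapz(flow$times, flow$u_cath)
  structure(list(times = flow$times, lambda = lam),
            class = "displacement_curve")
}

# Solve for the time within a trace at which the cumulative trapezoid
# integral of y reaches `target`; exact for piecewise-linear y.
.invert_cum <- function(times, y, target) {
  cum <- cumtrapz(times, y)
  if (target <= 0) return(times[1])
  if (max(cum) < target) return(NA_real_)
  j <- findInterval(target, cum, left.open = TRUE)
  if (cum[j] == target) return(times[j])
  h <- times[j + 1] - times[j]
  d <- target - cum[j]
  a <- (y[j + 1] - y[j]) / (2 * h)
  if (abs(a) < 1e-300) return(times[j] + d / y[j])
  # a x^2 + y_j x - d = 0, take the root in [0, h]
  x <- (-y[j] + sqrt(y[j]^2 + 4 * a * d)) / (2 * a)
  times[j] + x
}

#' Delay time: first passage of one dead volume
#'
#' Smallest t with `int_0^t u_cath = V_cath`. For constant flow this reduces
#' exactly to `V_cath / u_cath`; with a compliance discharge transiently
#' raising the flow it is slightly shorter.
#'
#' @inheritParams displacement
#' @return delay time, s.
#' @export
delay_time <- function(flow, catheter) {
  i0 <- which(flow$times >= 0)
  t <- .invert_cum(flow$times[i0], flow$u_cath[i0], catheter$volume)
  if (is.na(t))
    stop("insufficient horizon: cumulative volume never reaches V_cath",
         call. = FALSE)
  t
}

#' Poiseuille first-arrival delay
#'
#' The parabolic velocity profile moves the centerline at twice the average
#' speed, so the first new fluid reaches the tip at half the plug-flow delay.
#'
#' @param t_delay plug-flow delay time, s (>= 0).
#' @return `t_delay / 2`, s.
#' @export
poiseuille_tip_delay <- function(t_delay) {
  if (any(t_delay < 0)) stop("t_delay must be >= 0", call. = FALSE)
  t_delay / 2
}

#' Push-out deviation flow of the unchanged fluid
#'
#' While the old mixture is expelled at the new total rate, the unchanged
#' channel's fluid leaves the tip at
#' `u_unchanged + u_unchanged * (u_final_other - u_old_other) / (u_old_other + u_unchanged)`;
#' this function returns the deviation (second) term, valid on
#' `0 < t < t_delay^POIS`.
#'
#' @param u_unchanged set rate of the unchanged (monitored) pump, ml/s.
#' @param u_old_other,u_final_other other pump's rate before / after the
#'   change, ml/s.
#' @return deviation flow, ml/s (positive for a rate increase of the other
#'   pump, negative for a decrease).
#' @export
pushout_flow <- function(u_unchanged, u_old_other, u_final_other) {
  tot_old <- u_old_other + u_unchanged
  if (tot_old <= 0) stop("old total flow must be > 0", call. = FALSE)
  u_unchanged * (u_final_other - u_old_other) / tot_old
}

#' Concentration series along the catheter
#'
#' @param fractions matrix with `n_voxels + 1` rows (k = 0 at the tip P to
#'   k = N at the mixing point M) and one column per fluid; each row must lie
#'   on the simplex (entries in \[0, 1\] summing to 1).
#' @param fluids optional fluid names (defaults to column names).
#' @return object of class `concentration_series`.
#' @export
concentration_series <- function(fractions, fluids = colnames(fractions)) {
  fractions <- as.matrix(fractions)
  if (is.null(fluids)) fluids <- paste0("fluid", seq_len(ncol(fractions)))
  colnames(fractions) <- fluids
  if (any(fractions < -1e-12) || any(fractions > 1 + 1e-12))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (any(abs(rowSums(fractions) - 1) > 1e-9))
    stop("per-voxel fractions must sum to 1", call. = FALSE)
  structure(list(fractions = fractions, fluids = fluids),
            class = "concentration_series")
}

#' Uniform-mixture concentration series
#'
#' @param catheter a [catheter_spec()].
#' @param mix named numeric vector of fluid fractions (summing to 1).
#' @return a [concentration_series()] with every voxel at `mix`.
#' @export
uniform_series <- function(catheter, mix) {
  m <- matrix(rep(mix, each = catheter$n_voxels + 1L),
              nrow = catheter$n_voxels + 1L)
  colnames(m) <- names(mix)
  concentration_series(m)
}

#' Advect the catheter contents toward the tip
#'
#' Conservative donor-cell shift: the contents move `dlambda / gamma` voxels
#' toward P (integer part plus fractional linear carry); vacated voxels at M
#' are filled with `entry_fractions`, and the emitted volume at P is the
#' exact integral of the piecewise-constant contents over the shifted-out
#' interval, so per-fluid volume is conserved to rounding error.
#'
#' @param series a [concentration_series()].
#' @param entry_fractions composition entering at M during the step (simplex
#'   vector, one entry per fluid).
#' @param dlambda displacement during the step, length units (>= 0 and at
#'   most the catheter length `gamma * (N + 1)` in one step).
#' @param catheter the [catheter_spec()] the series lives on.
#' @return list with `series` (advected [concentration_series()]) and
#'   `emitted` (per-fluid emitted volume, ml).
#' @export
advect <- function(series, entry_fractions, dlambda, catheter) {
  if (dlambda < 0) stop("dlambda must be >= 0", call. = FALSE)
  gamma <- catheter$gamma
  nv <- nrow(series$fractions)
  s <- dlambda / gamma
  if (s > nv) stop("step too large: dlambda exceeds the catheter length", call. = FALSE)
  if (abs(sum(entry_fractions) - 1) > 1e-9)
    stop("entry_fractions must sum to 1", call. = FALSE)
  m <- floor(s); f <- s - m
  A <- series$fractions
  voxvol <- gamma * catheter$volume / catheter$length
  # emitted: cells 1..m fully, plus fraction f of cell m+1 (row 1 = tip)
  emitted <- numeric(ncol(A))
  if (m > 0) emitted <- colSums(A[seq_len(m), , drop = FALSE])
  if (f > 0 && m < nv) emitted <- emitted + f * A[m + 1L, ]
  emitted <- emitted * voxvol
  # padded old contents: beyond M, incoming entry composition
  pad <- matrix(rep(entry_fractions, each = m + 2L), nrow = m + 2L)
  Ax <- rbind(A, pad)
  idx <- seq_len(nv) + m
  newA <- (1 - f) * Ax[idx, , drop = FALSE] + f * Ax[idx + 1L, , drop = FALSE]
  colnames(newA) <- series$fluids
  list(series = concentration_series(newA, series$fluids),
       emitted = unname(emitted))
}

#' Entering-deviation sequence on the voxel index
#'
#' Resamples the red deviation fraction `u_M_diff(t) / u_cath(t)` onto the
#' entry-voxel index j via the displacement curve (`lambda(t_j) = j * gamma`),
#' the time-domain counterpart of the `z^(-lambda/gamma)` displacement rule.
#' The zeroth sum times `gamma * V_cath / L` recovers the bolus volume Q.
#'
#' Two displacement conventions are supported. `"actual"` (default) builds
#' the displacement from the full simulated total flow, the physically
#' transported distance (validated by the streamline oracle).
#' `"stabilized"` uses `u_final` plus the monitored channel's own deviation
#' only, the simplification under which the closed-form moment expressions
#' are derived (it neglects the displacement contributed by the other
#' syringe's discharge; exact in the limit of vanishing line resistance).
#'
#' @param flow a `flow_trace` with the monitored channel's deviation.
#' @param catheter a [catheter_spec()].
#' @param u_final stabilized total flow rate after the event, ml/s (sets the
#'   index-to-time spacing `dtau = gamma * V_cath / (L * u_final)`).
#' @param channel label or index of the monitored channel (default `"red"`,
#'   else channel 2).
#' @param lambda_convention `"actual"` or `"stabilized"`, see Details.
#' @return object of class `entry_sequence`: `a_diff` (deviation fraction per
#'   entry voxel j = 0, 1, ...), `dtau` (s per index), plus geometry fields.
#' @export
entry_sequence <- function(flow, catheter, u_final, channel = NULL,
                           lambda_convention = c("actual", "stabilized")) {
  lambda_convention <- match.arg(lambda_convention)
  if (is.null(channel)) {
    channel <- if ("red" %in% flow$labels) "red" else 2L
  }
  i0 <- which(flow$times >= 0)
  if (length(i0) < 2L) stop("insufficient horizon in flow trace", call. = FALSE)
  times <- flow$times[i0]
  u_diff <- flow$u_diff[i0, channel]
  u_cath <- if (lambda_convention == "actual") flow$u_cath[i0] else
    u_final + u_diff
  disp <- displacement(list(times = times, u_cath = u_cath), catheter)
  J <- floor(disp$lambda[length(disp$lambda)] / catheter$gamma)
  if (J < 1) stop("insufficient horizon: displacement under one voxel", call. = FALSE)
  # invert lambda (strictly increasing for positive flow)
  t_j <- stats::approx(disp$lambda, times, xout = (0:J) * catheter$gamma,
                       ties = "ordered")$y
  a_diff <- stats::approx(times, u_diff, xout = t_j)$y /
    stats::approx(times, u_cath, xout = t_j)$y
  structure(list(
    a_diff = a_diff,
    dtau = catheter$gamma * catheter$volume / (catheter$length * u_final),
    u_final = u_final, gamma = catheter$gamma,
    L = catheter$length, V_cath = catheter$volume
  ), class = "entry_sequence")
}

#' Export an emitted-concentration time series as CSV
#'
#' @param times times, s.
#' @param fractions matrix of emitted fractions per fluid.
#' @param u_cath total flow, ml/s.
#' @param path output file.
#' @export
write_emitted_series <- function(times, fractions, u_cath, path) {
  df <- data.frame(time_s = times)
  for (f in colnames(fractions)) {
    df[[paste0("fraction_", f)]] <- fractions[, f]
    df[[paste0("flow_", f, "_ml_per_s")]] <- fractions[, f] * u_cath
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
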