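#' Pump channel: one pump + syringe + feeding line
#'
#' A channel bundles the mechanical compliance of its syringe (the "capacitor"
#' of the electric analog), the hydraulic resistance of its feeding line, a
#' piecewise-constant flow-rate schedule, and any clamp intervals.
#'
#' @param label channel name (e.g. `"green"`, `"red"`).
#' @param compliance syringe compliance, ml/Pa.
#' @param line_resistance feeding-line resistance in the unit given by
#'   `resistance_unit` (default clinical Pa/(ml/h)).
#' @param schedule data.frame with columns `time` (s) and `rate` (in
#'   `rate_unit`); row 1 may have `time = -Inf` for the initial rate.
#'   Breakpoints must be strictly increasing and rates non-negative.
#' @param clamps optional data.frame with columns `start`, `end` (s) of
#'   non-overlapping intervals during which the line is clamped shut.
#' @param rate_unit,resistance_unit clinical unit tags understood by
#'   [to_internal()].
#' @return an object of class `pump_channel` (all fields canonical units).
#' @export
pump_channel <- function(label, compliance, line_resistance, schedule,
                         clamps = NULL,
                         rate_unit = "ml/h", resistance_unit = "Pa/(ml/h)") {
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.data.frame(schedule) || !all(c("time", "rate") %in% names(schedule)))
    stop("schedule must be a data.frame with columns time, rate", call. = FALSE)
  rate <- to_internal(schedule$rate, rate_unit)
  if (any(rate < 0)) stop("schedule rates must be >= 0", call. = FALSE)
  if (any(diff(schedule$time) <= 0))
    stop("schedule breakpoints must be strictly increasing", call. = FALSE)
  if (compliance < 0) stop("compliance must be >= 0", call. = FALSE)
  R <- to_internal(line_resistance, resistance_unit)
  if (R < 0) stop("line resistance must be >= 0", call. = FALSE)
  if (!is.null(clamps)) {
    stopifnot(is.data.frame(clamps), all(c("start", "end") %in% names(clamps)))
    cl <- clamps[order(clamps$start), , drop = FALSE]
    if (any(cl$end <= cl$start)) stop("clamp intervals must have end > start", call. = FALSE)
    if (nrow(cl) > 1L && any(cl$start[-1L] < cl$end[-nrow(cl)]))
      stop("clamp intervals must not overlap", call. = FALSE)
    clamps <- cl
  }
  structure(list(
    label = label,
    compliance = compliance,
    line_resistance = R,
    schedule = data.frame(time = schedule$time, rate = rate),
    clamps = clamps
  ), class = "pump_channel")
}

#' Set flow rate of a channel at given times
#'
#' Piecewise-constant (right-continuous) evaluation of the schedule; a
#' clamped interval does not alter the set rate (the pump may still run
#' against the clamp).
#'
#' @param channel a [pump_channel()].
#' @param t numeric vector of times, s.
#' @return set rate(s), ml/s.
#' @export
rate_at <- function(channel, t) {
  sched <- channel$schedule
  idx <- findInterval(t, sched$time)
  out <- numeric(length(t))
  out[idx > 0] <- sched$rate[idx[idx > 0]]
  out
}

#' Is a channel clamped at given times?
#' @inheritParams rate_at
#' @return logical vector.
#' @export
is_clamped <- function(channel, t) {
  out <- rep(FALSE, length(t))
  if (is.null(channel$clamps)) return(out)
  for (i in seq_len(nrow(channel$clamps))) {
    out <- out | (t >= channel$clamps$start[i] & t < channel$clamps$end[i])
  }
  out
}

#' Catheter geometry and hydraulics
#'
#' @param resistance catheter resistance, in `resistance_unit`.
#' @param volume internal (dead) volume between mixing point and tip, ml.
#' @param length catheter length in an arbitrary length unit (only ratios of
#'   lengths enter any result).
#' @param n_voxels number of voxels for the discrete contents model (>= 100).
#' @param resistance_unit clinical unit tag.
#' @return object of class `catheter_spec`; `gamma = length / n_voxels`.
#' @export
catheter_spec <- function(resistance, volume = 1.0, length = 1.0,
                          n_voxels = 10000L, resistance_unit = "Pa/(ml/h)") {
  if (volume <= 0) stop("catheter volume must be > 0", call. = FALSE)
  if (n_voxels < 100) stop("n_voxels must be >= 100", call. = FALSE)
  R <- to_internal(resistance, resistance_unit)
  if (R < 0) stop("catheter resistance must be >= 0", call. = FALSE)
  structure(list(
    resistance = R,
    volume = volume,
    length = length,
    n_voxels = as.integer(n_voxels),
    gamma = length / n_voxels
  ), class = "catheter_spec")
}

#' Complete multi-infusion set-up
#'
#' All channels join at a single mixing point M, from which one catheter of
#' resistance `R_cath` leads to the tip P (taken as the zero-pressure
#' reference; only pressure differences matter for the flows).
#'
#' @param channels list of [pump_channel()] objects (>= 2).
#' @param catheter a [catheter_spec()].
#' @return object of class `infusion_setup`.
#' @export
infusion_setup <- function(channels, catheter) {
  if (!is.list(channels) || length(channels) < 2L)
    stop("an infusion_setup needs at least 2 channels", call. = FALSE)
  if (!all(vapply(channels, inherits, logical(1), "pump_channel")))
    stop("channels must all be pump_channel objects", call. = FALSE)
  if (!inherits(catheter, "catheter_spec"))
    stop("catheter must be a catheter_spec", call. = FALSE)
  labels <- vapply(channels, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("channel labels must be unique", call. = FALSE)
  structure(list(channels = channels, catheter = catheter),
            class = "infusion_setup")
}

#' @export
print.infusion_setup <- function(x, ...) {
  cat("Multi-infusion set-up:", length(x$channels), "channels\n")
  for (ch in x$channels) {
    cat(sprintf("  %-8s C = %.3g ml/Pa, R = %.4g Pa/(ml/h), rate(0+) = %.4g ml/h\n",
                ch$label, ch$compliance,
                from_internal(ch$line_resistance, "Pa/(ml/h)"),
                from_internal(rate_at(ch, 0), "ml/h")))
  }
  cat(sprintf("  catheter R_cath = %.4g Pa/(ml/h), V_cath = %.3g ml, N = %d\n",
              from_internal(x$catheter$resistance, "Pa/(ml/h)"),
              x$catheter$volume, x$catheter$n_voxels))
  invisible(x)
}

#' Standard two-pump set-up
#'
#' The reference scenario: a "green" pump whose rate is lowered from 12 to
#' 6 ml/h at t = 0 and a "red" pump running constantly at 0.5 ml/h, with
#' R_cath = 1145 Pa/(ml/h), line resistances 23 Pa/(ml/h), and syringe
#' compliances 1.5e-5 ml/Pa. The catheter dead volume and length are
#' scenario-dependent and default to 1 ml / 1 length unit with 10^4 voxels.
#'
#' Channel 1 is the green (changed) channel; channel 2 the red (monitored)
#' one, matching the C1/R1 vs C2/R2 roles of the transfer function.
#'
#' @param V_cath catheter internal volume, ml.
#' @param L catheter length (arbitrary unit).
#' @param N number of voxels.
#' @return an [infusion_setup()].
#' @export
standard_setup <- function(V_cath = 1.0, L = 1.0, N = 10000L) {
  green <- pump_channel(
    label = "green", compliance = 1.5e-5, line_resistance = 23,
    schedule = data.frame(time = c(-Inf, 0), rate = c(12, 6)))
  red <- pump_channel(
    label = "red", compliance = 1.5e-5, line_resistance = 23,
    schedule = data.frame(time = -Inf, rate = 0.5))
  infusion_setup(
    channels = list(green, red),
    catheter = catheter_spec(resistance = 1145, volume = V_cath,
                             length = L, n_voxels = N))
}

## ---- configuration file round trip -----------------------------------------

.known_keys <- list(
  top      = c("setup"),
  setup    = c("channels", "catheter", "events", "units"),
  channel  = c("label", "C", "R", "schedule", "clamps"),
  sched    = c("t", "rate"),
  clamp    = c("start", "end"),
  catheter = c("R_cath", "V_cath", "L", "N")
)

.check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
}

#' Serialize a set-up to a configuration list
#'
#' The configuration uses the clinical units of the parameter table
#' (rates ml/h, resistances Pa/(ml/h), compliances ml/Pa, times s), so that
#' files are directly comparable to published values.
#'
#' @param setup an [infusion_setup()].
#' @return nested list suitable for [yaml::write_yaml()].
#' @export
setup_to_config <- function(setup) {
  chans <- lapply(setup$channels, function(ch) {
    out <- list(
      label = ch$label,
      C = ch$compliance,
      R = from_internal(ch$line_resistance, "Pa/(ml/h)"),
      schedule = lapply(seq_len(nrow(ch$schedule)), function(i) {
        list(t = ch$schedule$time[i],
             rate = from_internal(ch$schedule$rate[i], "ml/h"))
      }))
    if (!is.null(ch$clamps)) {
      out$clamps <- lapply(seq_len(nrow(ch$clamps)), function(i) {
        list(start = ch$clamps$start[i], end = ch$clamps$end[i])
      })
    }
    out
  })
  list(setup = list(
    channels = chans,
    catheter = list(
      R_cath = from_internal(setup$catheter$resistance, "Pa/(ml/h)"),
      V_cath = setup$catheter$volume,
      L = setup$catheter$length,
      N = setup$catheter$n_voxels)))
}

#' Build a set-up from a configuration list
#'
#' Unknown keys anywhere in the structure are rejected.
#'
#' @param config nested list as produced by [setup_to_config()] or read from
#'   a YAML file.
#' @return an [infusion_setup()].
#' @export
setup_from_config <- function(config) {
  .check_keys(config, .known_keys$top, "config")
  s <- config$setup
  .check_keys(s, .known_keys$setup, "setup")
  chans <- lapply(s$channels, function(ch) {
    .check_keys(ch, .known_keys$channel, paste0("channel '", ch$label, "'"))
    sched <- do.call(rbind, lapply(ch$schedule, function(e) {
      .check_keys(e, .known_keys$sched, "schedule entry")
      data.frame(time = e$t, rate = e$rate)
    }))
    clamps <- NULL
    if (!is.null(ch$clamps)) {
      clamps <- do.call(rbind, lapply(ch$clamps, function(e) {
        .check_keys(e, .known_keys$clamp, "clamp entry")
        data.frame(start = e$start, end = e$end)
      }))
    }
    pump_channel(ch$label, compliance = ch$C, line_resistance = ch$R,
                 schedule = sched, clamps = clamps)
  })
  .check_keys(s$catheter, .known_keys$catheter, "catheter")
  cath <- catheter_spec(resistance = s$catheter$R_cath,
                        volume = s$catheter$V_cath,
                        length = s$catheter$L, n_voxels = s$catheter$N)
  infusion_setup(chans, cath)
}

#' Read / write a set-up configuration file (YAML)
#'
#' @param path file path.
#' @return `read_setup()` returns an [infusion_setup()];
#'   `write_setup()` invisibly returns `path`.
#' @export
read_setup <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML has no -Inf literal guaranteed across emitters; accept the string
  cfg$setup$channels <- lapply(cfg$setup$channels, function(ch) {
    ch$schedule <- lapply(ch$schedule, function(e) {
      if (is.character(e$t)) e$t <- as.numeric(e$t)
      e
    })
    ch
  })
  setup_from_config(cfg)
}

#' @rdname read_setup
#' @param setup an [infusion_setup()].
#' @export
write_setup <- function(setup, path) {
  yaml::write_yaml(setup_to_config(setup), path)
  invisible(path)
}
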