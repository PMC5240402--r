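#' Moment-based bolus characterization
#'
#' A dosing-error bolus is summarized by its volume Q (zeroth moment), its
#' central time `t_central` (first moment over zeroth) and its width
#' parameter `sigma` (square root of the second central moment); the
#' clinically reported "duration" of the bolus is `2 * sigma`. Times are
#' measured in the tau frame, i.e. from the (Poiseuille) delay reference.
#'
#' @name error_metrics
NULL

.bolus_metrics <- function(Q, t_central, sigma, method,
                           t_delay = NA_real_, t_delay_pois = NA_real_,
                           truncation = NULL) {
  structure(list(Q = Q, t_central = t_central, sigma = sigma,
                 width = 2 * sigma, t_delay = t_delay,
                 t_delay_pois = t_delay_pois, method = method,
                 truncation = truncation),
            class = "bolus_metrics")
}

#' @export
print.bolus_metrics <- function(x, ...) {
  cat(sprintf("Dosing-error bolus (%s):\n", x$method))
  cat(sprintf("  Q         = %.6g ml\n", x$Q))
  cat(sprintf("  t_central = %.4g s\n", x$t_central))
  cat(sprintf("  sigma     = %.4g s  (width 2*sigma = %.4g s)\n",
              x$sigma, x$width))
  if (is.finite(x$t_delay))
    cat(sprintf("  t_delay   = %.4g s  (Poiseuille first arrival %.4g s)\n",
                x$t_delay, x$t_delay_pois))
  invisible(x)
}

#' Discrete moments of a bolus
#'
#' Computes Q, `t_central` and `sigma` from index-weighted sums (the
#' z-derivative-at-1 limit of the Z-domain moment theorems), with the
#' index-to-time mapping carried by the object: entry-sequence spacing
#' `dtau = gamma*V/(L*u_final)` for the plug-flow bolus, half that for the
#' Poiseuille-stretched tip bolus.
#'
#' @param x an [entry_sequence()], a `tip_bolus` or a sampled time series
#'   (list with `tau` and `value`, value in deviation-fraction units times
#'   `u_total`, or a flow in ml/s when `u_total = 1`).
#' @param ... passed to methods.
#' @return a `bolus_metrics` object (method tag `"discrete"`).
#' @export
discrete_moments <- function(x, ...) UseMethod("discrete_moments")

.moments_to_metrics <- function(m, dt, mass_to_ml, truncation) {
  if (abs(m[["m0"]]) < 1e-300)
    stop("zero total bolus mass: metrics undefined", call. = FALSE)
  mu <- m[["m1"]] / m[["m0"]]
  var <- m[["m2"]] / m[["m0"]] - mu^2
  .bolus_metrics(Q = m[["m0"]] * mass_to_ml,
                 t_central = mu * dt,
                 sigma = sqrt(max(var, 0)) * dt,
                 method = "discrete", truncation = truncation)
}

#' @rdname discrete_moments
#' @export
discrete_moments.entry_sequence <- function(x, ...) {
  m <- .index_moments(x$a_diff)
  .moments_to_metrics(m, dt = x$dtau,
                      mass_to_ml = x$gamma * x$V_cath / x$L,
                      truncation = list(n_index = length(x$a_diff)))
}

#' @rdname discrete_moments
#' @param which for tip boluses: `"pois"` (convolution term only, the
#'   compliance bolus as smeared by the Poiseuille profile), `"patient"`
#'   (convolution plus remnant) or `"remnant"`.
#' @export
discrete_moments.tip_bolus <- function(x, which = c("pois", "patient", "remnant"),
                                       ...) {
  which <- match.arg(which)
  v <- switch(which,
              pois = x$psi_pois,
              patient = x$psi_pois + x$psi_remnant,
              remnant = x$psi_remnant)
  m <- .index_moments(v)
  .moments_to_metrics(m, dt = x$dtau_half,
                      mass_to_ml = x$gamma * x$V_cath / (2 * x$L),
                      truncation = list(k_max = max(x$k),
                                        kernel_mass = x$kernel_mass,
                                        fill = x$fill, which = which))
}

#' @rdname discrete_moments
#' @export
discrete_moments.default <- function(x, ...) {
  stopifnot(is.list(x), !is.null(x$tau), !is.null(x$value))
  tau <- x$tau; v <- x$value
  m0 <- sum(diff(tau) * (v[-1] + v[-length(v)]) / 2)
  m1 <- sum(diff(tau) * ((tau * v)[-1] + (tau * v)[-length(v)]) / 2)
  m2 <- sum(diff(tau) * ((tau^2 * v)[-1] + (tau^2 * v)[-length(v)]) / 2)
  if (abs(m0) < 1e-300)
    stop("zero total bolus mass: metrics undefined", call. = FALSE)
  mu <- m1 / m0
  .bolus_metrics(Q = m0, t_central = mu,
                 sigma = sqrt(max(m2 / m0 - mu^2, 0)),
                 method = "discrete",
                 truncation = list(tau_max = max(tau)))
}

#' Closed-form central time of the plug-flow compliance bolus
#'
#' General two-pump form
#' `t_central = b + downstep/(4 u_final) * (sqrt(b^2-4ac) - 2 C2 R_cath + b + 2ac/b)`;
#' in the symmetric case `C1 = C2 = C`, `R1 = R2 = R` this reduces to
#' `2C(R_cath + R) + C*downstep*(2R_cath^2 + 6R_cath R + 3R^2)/(4 u_final (R_cath+R))`.
#' Measured in the tau frame (from the delay reference).
#'
#' @param setup two-channel [infusion_setup()].
#' @param downstep green rate decrease magnitude, ml/s.
#' @param u_final stabilized total flow rate after the event, ml/s.
#' @param form `"general"` (default) or `"symmetric"` (requires C1 = C2 and
#'   R1 = R2; both paths agree there).
#' @return central time, s.
#' @export
t_central_closed <- function(setup, downstep, u_final,
                             form = c("general", "symmetric")) {
  form <- match.arg(form)
  k <- network_coefficients(setup)
  if (form == "general") {
    k$b + downstep / (4 * u_final) *
      (k$disc_root - 2 * k$C2 * k$Rc + k$b + 2 * k$a * k$c / k$b)
  } else {
    if (abs(k$C1 - k$C2) > 1e-12 * k$C2 || abs(k$R1 - k$R2) > 1e-12 * max(k$R2, 1))
      stop("symmetric form requires C1 = C2 and R1 = R2", call. = FALSE)
    C <- k$C2; R <- k$R2; Rc <- k$Rc
    2 * C * (Rc + R) +
      C * downstep * (2 * Rc^2 + 6 * Rc * R + 3 * R^2) /
      (4 * u_final * (Rc + R))
  }
}

#' Closed-form width of the compliance bolus (symmetric case)
#'
#' Plug flow:
#' `sigma = C R_cath / (2 sqrt(3) u_final) * sqrt(downstep^2 + 12 downstep u_final + 48 u_final^2)`.
#' With Poiseuille mixing:
#' `sigma_POIS = 1/(sqrt(3) u_final) * sqrt(C^2 R_cath^2 (downstep^2 + 12 downstep u_final + 48 u_final^2) + 3 V_cath^2)`.
#' Both assume `C1 = C2 = C`, `R1 = R2 = R` and `R << R_cath` (a warning is
#' issued if `R > R_cath / 10`); for asymmetric parameters use the discrete
#' path ([discrete_moments()]).
#'
#' @inheritParams t_central_closed
#' @param with_poiseuille include the laminar-profile smearing term.
#' @param V_cath catheter internal volume, ml (defaults to the set-up's).
#' @return width parameter sigma, s (the reported bolus duration is 2*sigma).
#' @export
sigma_closed <- function(setup, downstep, u_final, with_poiseuille = FALSE,
                         V_cath = NULL) {
  k <- network_coefficients(setup)
  if (abs(k$C1 - k$C2) > 1e-12 * k$C2 || abs(k$R1 - k$R2) > 1e-12 * max(k$R2, 1))
    stop("closed-form sigma requires C1 = C2 and R1 = R2; ",
         "use discrete_moments() for the general case", call. = FALSE)
  if (k$R2 > k$Rc / 10)
    warning("line resistance is not small vs R_cath; closed form is approximate")
  C <- k$C2; Rc <- k$Rc
  poly <- downstep^2 + 12 * downstep * u_final + 48 * u_final^2
  if (!with_poiseuille) {
    C * Rc / (2 * sqrt(3) * u_final) * sqrt(poly)
  } else {
    if (is.null(V_cath)) V_cath <- setup$catheter$volume
    sqrt(C^2 * Rc^2 * poly + 3 * V_cath^2) / (sqrt(3) * u_final)
  }
}

#' Evaluate the documented limiting cases
#'
#' Each closed-form width has a printed asymptotic limit:
#' `sigma -> 2 C R_cath` for a vanishing step, `sigma_POIS -> 4 C R_cath`
#' when additionally the dead-volume term is negligible,
#' `sigma_POIS -> V_cath / u_final` when the compliance-resistance time is
#' negligible instead, and `t_delay_POIS = t_delay / 2` identically. The
#' limits are evaluated at small but finite parameter ratios.
#'
#' @param setup two-channel symmetric [infusion_setup()].
#' @param eps parameter ratio used to approach each limit.
#' @return data.frame with one row per limit: achieved ratio and target 1.
#' @export
limit_checks <- function(setup, eps = 1e-4) {
  k <- network_coefficients(setup)
  C <- k$C2; Rc <- k$Rc
  u_final <- sum(vapply(setup$channels, rate_at, numeric(1), t = 1e9))
  V <- setup$catheter$volume
  s1 <- sigma_closed(setup, downstep = eps * u_final, u_final = u_final) /
    (2 * C * Rc)
  s2 <- sigma_closed(setup, downstep = eps * u_final, u_final = u_final,
                     with_poiseuille = TRUE,
                     V_cath = eps * C * Rc * u_final) / (4 * C * Rc)
  # compliance-resistance term negligible: scale C down
  small <- setup
  small$channels[[1]]$compliance <- C * eps
  small$channels[[2]]$compliance <- C * eps
  s3 <- sigma_closed(small, downstep = eps * u_final, u_final = u_final,
                     with_poiseuille = TRUE, V_cath = V) * u_final / V
  s4 <- poiseuille_tip_delay(123.4) / (123.4 / 2)
  data.frame(
    limit = c("sigma -> 2 C R_cath", "sigma_POIS -> 4 C R_cath",
              "sigma_POIS -> V_cath / u_final", "t_delay_POIS = t_delay / 2"),
    achieved_ratio = c(s1, s2, s3, s4),
    target = 1,
    eps = eps
  )
}

#' Export bolus metrics as a JSON or CSV record
#'
#' @param metrics a `bolus_metrics`.
#' @param path output file; format chosen by extension (`.json` or `.csv`).
#' @export
write_metrics <- function(metrics, path) {
  rec <- list(Q_ml = metrics$Q, t_central_s = metrics$t_central,
              sigma_s = metrics$sigma, width_2sigma_s = metrics$width,
              t_delay_s = metrics$t_delay,
              t_delay_pois_s = metrics$t_delay_pois,
              method = metrics$method, truncation = metrics$truncation)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    utils::write.csv(as.data.frame(rec[!vapply(rec, is.list, logical(1))]),
                     path, row.names = FALSE)
  }
  invisible(path)
}
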