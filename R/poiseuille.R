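#' Poiseuille mixing operators
#'
#' The laminar parabolic velocity profile stretches every entering voxel into
#' a paraboloid sheet. The tip voxel then contains fluid from many original
#' voxels, with geometric weights `w_i = gamma * L / (gamma*i + L)^2`; the
#' centerline moving at twice the average speed stretches the entering
#' sequence two-fold. In the Z-domain the tip composition is the product
#' `Psi(z) = A_diff(z^2) * W(z)`, a discrete convolution in index space.
#'
#' Index convention: the stretched sequence `b` and the convolution index k
#' live on a grid with half the entry-sequence time spacing
#' (`dtau/2 = gamma * V_cath / (2 * L * u_final)` per index, counted from the
#' Poiseuille first-arrival time `t_delay / 2`). With this spacing the
#' cumulative kernel reproduces the volume-averaged tip concentration of the
#' parabolic profile, and the zero-order-hold stretch conserves bolus volume
#' exactly: `sum(psi) * gamma * V_cath / (2L) = Q * sum(w)`.
#'
#' @name poiseuille_mixing
NULL

#' Poiseuille tip-voxel weight kernel
#'
#' @param catheter a [catheter_spec()].
#' @param k_max truncation index (>= N); the kernel tail decays as 1/i^2, so
#'   `sum(w) = 1 - L / (gamma * k_max + L)` up to a discretization term of
#'   order `gamma / L`.
#' @return object of class `poiseuille_kernel`: `w` (weights for
#'   i = 0..k_max), `gamma`, `L`, `k_max`.
#' @export
poiseuille_kernel <- function(catheter, k_max) {
  if (k_max < catheter$n_voxels)
    stop("k_max must be at least the number of voxels N", call. = FALSE)
  i <- 0:k_max
  w <- catheter$gamma * catheter$length / (catheter$gamma * i + catheter$length)^2
  structure(list(w = w, gamma = catheter$gamma, L = catheter$length,
                 k_max = as.integer(k_max)),
            class = "poiseuille_kernel")
}

#' Two-fold stretch of the entering sequence
#'
#' `b[2j] = a_diff[j]` (centerline at twice the average speed). Odd indices
#' are filled by zero-order hold (`fill = "hold"`, the default: piecewise
#' constant over index pairs, which conserves bolus volume on the half-spaced
#' grid) or left at zero (`fill = "even"`, the literal even-index definition,
#' under which moment relations through `B(z) = A(z^2)` are exact).
#'
#' @param entry an [entry_sequence()] (or bare numeric vector).
#' @param fill `"hold"` or `"even"`.
#' @return numeric vector `b` of length `2 * length(a_diff)`.
#' @export
stretch_sequence <- function(entry, fill = c("hold", "even")) {
  fill <- match.arg(fill)
  a <- if (inherits(entry, "entry_sequence")) entry$a_diff else as.numeric(entry)
  if (!length(a)) return(numeric(0))
  if (fill == "hold") {
    rep(a, each = 2L)
  } else {
    b <- numeric(2L * length(a))
    b[seq(1L, length(b), by = 2L)] <- a
    b
  }
}

#' Tip composition: Poiseuille convolution plus remnant term
#'
#' `psi_pois[k] = sum_j b[k-j] * w[j]` (discrete convolution, truncated at
#' the kernel's `k_max`) is the compliance-driven part of the tip deviation
#' fraction; `psi_remnant[k] = L/(L + gamma*k) * u_R (u_final_G - u_old_G) /
#' ((u_final_G + u_R)(u_old_G + u_R))` is the slowly decaying old-mixture
#' fluid retained near the wall.
#'
#' @param entry an [entry_sequence()].
#' @param kernel a [poiseuille_kernel()] on the same catheter geometry.
#' @param u_pump_R set rate of the monitored (red) pump, ml/s.
#' @param u_old_G,u_final_G other pump's rate before / after the event, ml/s.
#' @param fill stretch fill mode, see [stretch_sequence()].
#' @return object of class `tip_bolus`: `psi_pois`, `psi_remnant` (index
#'   k = 0..k_max), `dtau_half` (s per index), `u_total` (ml/s), `fill`,
#'   `kernel_mass` (= sum(w), the truncation coverage).
#' @export
tip_convolution <- function(entry, kernel, u_pump_R, u_old_G, u_final_G,
                            fill = c("hold", "even")) {
  fill <- match.arg(fill)
  if (abs(entry$gamma - kernel$gamma) > 1e-12 * kernel$gamma ||
      abs(entry$L - kernel$L) > 1e-12 * kernel$L)
    stop("entry sequence and kernel are on different geometry grids", call. = FALSE)
  b <- stretch_sequence(entry, fill = fill)
  w <- kernel$w
  nk <- kernel$k_max + 1L
  full <- .conv_open(b, w)
  psi_pois <- full[seq_len(min(nk, length(full)))]
  if (length(psi_pois) < nk) psi_pois <- c(psi_pois, numeric(nk - length(psi_pois)))
  k <- 0:kernel$k_max
  remnant_amp <- u_pump_R * (u_final_G - u_old_G) /
    ((u_final_G + u_pump_R) * (u_old_G + u_pump_R))
  psi_remnant <- kernel$L / (kernel$L + kernel$gamma * k) * remnant_amp
  structure(list(
    psi_pois = psi_pois, psi_remnant = psi_remnant, k = k,
    dtau_half = entry$dtau / 2, u_total = entry$u_final,
    fill = fill, kernel_mass = sum(w),
    gamma = kernel$gamma, L = kernel$L, V_cath = entry$V_cath
  ), class = "tip_bolus")
}

# open (polynomial) convolution via FFT, numerically cleaned
.conv_open <- function(x, y) {
  n <- length(x) + length(y) - 1L
  nf <- stats::nextn(n, 2)
  xr <- c(x, numeric(nf - length(x)))
  yr <- c(y, numeric(nf - length(y)))
  out <- Re(stats::fft(stats::fft(xr) * stats::fft(yr), inverse = TRUE)) / nf
  out[seq_len(n)]
}

#' Export a tip bolus as CSV
#' @param bolus a `tip_bolus`.
#' @param path output file.
#' @export
write_tip_bolus <- function(bolus, path) {
  utils::write.csv(data.frame(
    k = bolus$k,
    tau_s = bolus$k * bolus$dtau_half,
    psi_pois = bolus$psi_pois,
    psi_remnant = bolus$psi_remnant
  ), path, row.names = FALSE)
  invisible(path)
}

# raw index moments m0 = sum v, m1 = sum k v, m2 = sum k^2 v  (k from 0)
.index_moments <- function(v) {
  k <- seq_along(v) - 1
  c(m0 = sum(v), m1 = sum(k * v), m2 = sum(k * k * v))
}

#' Moments of the Poiseuille convolution via the Z-domain product rule
#'
#' Computes the zeroth, first and second index moments of
#' `psi_pois = b * w` from the separate moments of the entry sequence and
#' the kernel, using the derivative-at-z-&#8594;-1 product rule for
#' `Psi(z) = B(z) W(z)` with `B(z) = A(z^2)` (`fill = "even"`) or
#' `B(z) = A(z^2)(1 + 1/z)` (`fill = "hold"`). Exactly equal (to rounding)
#' to the brute-force index sums over the truncated convolution, provided
#' the convolution support fits inside the kernel truncation.
#'
#' @inheritParams tip_convolution
#' @return named vector `m0`, `m1`, `m2` (index moments of `psi_pois`).
#' @export
z_product_moments <- function(entry, kernel, fill = c("hold", "even")) {
  fill <- match.arg(fill)
  mA <- .index_moments(entry$a_diff)
  mW <- .index_moments(kernel$w)
  if (fill == "even") {
    mB <- c(m0 = mA[["m0"]], m1 = 2 * mA[["m1"]], m2 = 4 * mA[["m2"]])
  } else {
    # value a_j at indices 2j and 2j+1
    mB <- c(m0 = 2 * mA[["m0"]],
            m1 = 4 * mA[["m1"]] + mA[["m0"]],
            m2 = 8 * mA[["m2"]] + 4 * mA[["m1"]] + mA[["m0"]])
  }
  c(m0 = mB[["m0"]] * mW[["m0"]],
    m1 = mB[["m1"]] * mW[["m0"]] + mB[["m0"]] * mW[["m1"]],
    m2 = mB[["m2"]] * mW[["m0"]] + 2 * mB[["m1"]] * mW[["m1"]] +
      mB[["m0"]] * mW[["m2"]])
}
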