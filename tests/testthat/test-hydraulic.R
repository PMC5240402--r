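test_that("transient time constants match the network eigenvalue problem", {
  s <- standard_setup()
  tf <- transient_flow(s, ud_std)
  # independent route: eigenvalues of the 2-state pressure system
  Rc <- s$catheter$resistance
  R <- vapply(s$channels, `[[`, numeric(1), "line_resistance")
  C <- vapply(s$channels, `[[`, numeric(1), "compliance")
  g <- 1 / Rc + sum(1 / R)
  A <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    A[i, j] <- ((i == j) * (-1 / R[i]) + (1 / R[i]) * (1 / R[j]) / g) / C[i]
  }
  taus <- sort(-1 / eigen(A)$values)
  expect_equal(tf$theta_first, taus[1], tolerance = 1e-12)
  expect_equal(tf$theta_second, taus[2], tolerance = 1e-12)
  expect_equal(tf$theta_first, 1.242, tolerance = 1e-3)
  expect_equal(tf$theta_second, 124.90, tolerance = 1e-4)
})

test_that("Laplace transfer has the documented coefficient structure", {
  s <- standard_setup()
  lt <- laplace_transfer_two_pump(s, ud_std)
  # s-coefficient: C1 R_cath + C1 R1 + C2 R_cath + C2 R2 = 0.03504 h
  expect_equal(lt$denominator[2] / 3600, 0.03504, tolerance = 1e-4)
  expect_equal(lt$denominator[3], 1)
  # no compliance or no catheter resistance -> no transfer
  s0 <- s; s0$channels[[2]]$compliance <- 0
  expect_equal(laplace_transfer_two_pump(s0, ud_std)$numerator, 0)
  s1 <- s; s1$catheter$resistance <- 0
  expect_equal(laplace_transfer_two_pump(s1, ud_std)$numerator, 0)
  s3 <- s; s3$channels <- c(s3$channels, s3$channels[1])
  s3$channels[[3]]$label <- "blue"
  expect_error(laplace_transfer_two_pump(s3, ud_std), "state_space_simulate")
})

test_that("degenerate zero line resistance collapses to a single exponential", {
  g <- pump_channel("green", 1.5e-5, 0,
                    data.frame(time = c(-Inf, 0), rate = c(12, 6)),
                    resistance_unit = "Pa/(ml/s)")
  r <- pump_channel("red", 1.5e-5, 0, data.frame(time = -Inf, rate = 0.5),
                    resistance_unit = "Pa/(ml/s)")
  s <- infusion_setup(list(g, r), catheter_spec(1145))
  tf <- transient_flow(s, ud_std)
  expect_equal(tf$theta_first, 0)
  expect_equal(tf$theta_second, 2 * 1.5e-5 * s$catheter$resistance)
})

test_that("the transient peaks where the two-exponential calculus says", {
  tf <- transient_flow(standard_setup(), ud_std)
  t_star <- transient_peak_time(tf)
  opt <- optimize(function(t) u_m_diff(tf, t), c(0, 50), maximum = TRUE)
  expect_equal(t_star, opt$maximum, tolerance = 1e-4)
  expect_gt(u_m_diff(tf, t_star), u_m_diff(tf, t_star * 0.9))
  expect_gt(u_m_diff(tf, t_star), u_m_diff(tf, t_star * 1.1))
})

test_that("bolus volume is C2 R_cath downstep and scales linearly", {
  s <- standard_setup()
  expect_equal(dosing_error_volume(s, ud_std), 0.10305, tolerance = 1e-10)
  expect_identical(dosing_error_volume(s, 0), 0)
  s2 <- s; s2$catheter$resistance <- 2 * s$catheter$resistance
  expect_equal(dosing_error_volume(s2, ud_std),
               2 * dosing_error_volume(s, ud_std))
  # quadrature of the transient recovers the closed form
  tf <- transient_flow(s, ud_std)
  q <- integrate(function(t) u_m_diff(tf, t), 0, Inf, rel.tol = 1e-11)$value
  expect_equal(q, 0.10305, tolerance = 1e-9)
})

test_that("Vieta relations hold for the time constants across random draws", {
  set.seed(42)
  for (i in 1:100) {
    d <- random_draw()
    tf <- transient_flow(d$setup, d$downstep)
    expect_equal(tf$theta_first * tf$theta_second, tf$a * tf$c,
                 tolerance = 1e-9)
    expect_equal(tf$theta_first + tf$theta_second, tf$b, tolerance = 1e-12)
    expect_true(tf$theta_first > 0 && tf$theta_first <= tf$theta_second)
  }
})

test_that("state-space ODE agrees with the closed-form transient", {
  s <- standard_setup()
  fl <- std_flow()
  tf <- transient_flow(s, ud_std)
  ana <- u_m_diff(tf, fl$times)
  expect_lt(max(abs(fl$u_diff[, "red"] - ana)) / max(ana), 1e-6)
})

test_that("constant schedules stay in equilibrium", {
  g <- pump_channel("green", 1.5e-5, 23, data.frame(time = -Inf, rate = 12))
  r <- pump_channel("red", 1.5e-5, 23, data.frame(time = -Inf, rate = 0.5))
  s <- infusion_setup(list(g, r), catheter_spec(1145))
  fl <- state_space_simulate(s, seq(0, 500, 1))
  expect_lt(max(abs(fl$u_diff)), 1e-12)
  expect_equal(fl$u_cath, rep(to_internal(12.5, "ml/h"), length(fl$times)),
               tolerance = 1e-10)
})

test_that("three equal channels respond symmetrically to a step on one", {
  mk <- function(lab, sched) pump_channel(lab, 1.5e-5, 23, sched)
  s <- infusion_setup(list(
    mk("a", data.frame(time = c(-Inf, 0), rate = c(12, 6))),
    mk("b", data.frame(time = -Inf, rate = 12)),
    mk("c", data.frame(time = -Inf, rate = 12))),
    catheter_spec(1145))
  fl <- state_space_simulate(s, seq(0, 600, 0.5))
  expect_equal(fl$u_diff[, "b"], fl$u_diff[, "c"], tolerance = 1e-10)
  expect_gt(max(fl$u_diff[, "b"]), 0)
})

test_that("volume is conserved between catheter outflow and elastic storage", {
  fl <- std_flow()
  excess <- fl$excess_volume[length(fl$excess_volume)]
  released <- sum(vapply(seq_len(ncol(fl$p)), function(i) {
    ch <- standard_setup()$channels[[i]]
    ch$compliance * (fl$p[1, i] - fl$p[nrow(fl$p), i])
  }, numeric(1)))
  expect_lt(abs(excess - released), 1e-8)
})

test_that("syringe exchange error accumulates and saturates as documented", {
  s <- standard_setup()
  expect_equal(syringe_exchange_error(s, 0, red_pump_on = FALSE), 0)
  # saturation at C2 R_cath u_old = 0.2061 ml
  expect_equal(syringe_exchange_error(s, 1e7, red_pump_on = FALSE), 0.2061,
               tolerance = 1e-9)
  Tg <- seq(0, 2000, 25)
  off <- syringe_exchange_error(s, Tg, red_pump_on = FALSE)
  on <- syringe_exchange_error(s, Tg, red_pump_on = TRUE)
  expect_true(all(diff(off) >= 0))
  expect_equal(on - off, uR_std * Tg, tolerance = 1e-12)
  expect_error(syringe_exchange_error(s, -5), ">= 0")
})
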