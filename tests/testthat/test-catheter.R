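test_that("displacement is the scaled cumulative flow integral", {
  cath <- catheter_spec(1145, volume = 1, length = 1)
  tg <- seq(0, 3600, 10)
  flow <- list(times = tg, u_cath = rep(to_internal(6.5, "ml/h"), length(tg)))
  d <- displacement(flow, cath)
  expect_equal(d$lambda, to_internal(6.5, "ml/h") * tg, tolerance = 1e-12)
  expect_identical(d$lambda[1], 0)
  # standard step trace: strictly increasing
  ds <- displacement(std_flow(), standard_setup()$catheter)
  expect_true(all(diff(ds$lambda) > 0))
})

test_that("delay time reduces exactly to V/u for constant flow", {
  cath <- catheter_spec(1145, volume = 1)
  tg <- seq(0, 1200, 7)   # grid points deliberately off the answer
  flow <- list(times = tg, u_cath = rep(to_internal(6.5, "ml/h"), length(tg)))
  expect_equal(delay_time(flow, cath), 3600 / 6.5, tolerance = 1e-12)
  flow2 <- list(times = tg, u_cath = rep(2 * to_internal(6.5, "ml/h"), length(tg)))
  expect_equal(delay_time(flow2, cath), 3600 / 13, tolerance = 1e-12)
  short <- list(times = seq(0, 10, 1), u_cath = rep(1e-3, 11))
  expect_error(delay_time(short, cath), "insufficient horizon")
})

test_that("compliance discharge transiently shortens the delay", {
  td <- delay_time(std_flow(), standard_setup()$catheter)
  expect_lt(td, 3600 / 6.5)          # below the V/u_final value
  expect_gt(td, 0.75 * 3600 / 6.5)   # but the effect is bounded
  # lambda at t_delay is one catheter length by definition
  ds <- displacement(std_flow(), standard_setup()$catheter)
  lam_td <- approx(ds$times, ds$lambda, xout = td)$y
  expect_equal(lam_td, standard_setup()$catheter$length, tolerance = 1e-6)
})

test_that("the Poiseuille first arrival halves the delay time", {
  expect_equal(poiseuille_tip_delay(553.85), 276.925)
  expect_identical(poiseuille_tip_delay(0), 0)
  expect_error(poiseuille_tip_delay(-1), ">= 0")
})

test_that("push-out flow matches the worked example and the standard values", {
  # both pumps at q, other pump to 5q: total unchanged-fluid outflow 3q
  q <- to_internal(6, "ml/h")
  expect_equal(pushout_flow(q, q, 5 * q) + q, 3 * q, tolerance = 1e-12)
  # no change in the other pump, no push-out
  expect_identical(pushout_flow(q, 3 * q, 3 * q), 0)
  # standard values 0.5, 12 -> 6 ml/h: -0.24 ml/h
  expect_equal(from_internal(pushout_flow(uR_std, uold_std, ufinG_std), "ml/h"),
               -0.24, tolerance = 1e-12)
  expect_error(pushout_flow(0, 0, 1), "> 0")
})

test_that("advection is an exact-FIFO conservative shift", {
  cath <- catheter_spec(1145, volume = 2, length = 1, n_voxels = 100)
  set.seed(7)
  A <- matrix(runif(3 * 101), ncol = 3)
  A <- A / rowSums(A)
  colnames(A) <- c("R", "G", "B")
  cs <- concentration_series(A)
  # zero shift is the identity
  r0 <- advect(cs, c(1, 0, 0), 0, cath)
  expect_equal(r0$series$fractions, cs$fractions)
  expect_equal(r0$emitted, c(0, 0, 0))
  # uniform contents with matching entry stay unchanged
  u <- uniform_series(cath, c(R = 0.2, G = 0.5, B = 0.3))
  ru <- advect(u, c(0.2, 0.5, 0.3), 0.37 * cath$gamma * 40, cath)
  expect_equal(ru$series$fractions, u$fractions, tolerance = 1e-12)
  # N whole-voxel shifts emit the original contents tip-first
  cur <- cs
  emitted <- NULL
  for (i in 1:101) {
    r <- advect(cur, c(1, 0, 0), cath$gamma, cath)
    emitted <- rbind(emitted, r$emitted / (cath$gamma * cath$volume / cath$length))
    cur <- r$series
  }
  expect_equal(unname(emitted), unname(A), tolerance = 1e-12)
  expect_true(all(abs(cur$fractions[, 1] - 1) < 1e-12))
  expect_error(advect(cs, c(1, 0, 0), 2 * cath$length, cath), "too large")
})

test_that("simplex and per-fluid volume are conserved over random schedules", {
  cath <- catheter_spec(1145, volume = 1, length = 1, n_voxels = 10000)
  set.seed(11)
  cur <- uniform_series(cath, c(R = 0.04, G = 0.96))
  voxvol <- cath$gamma * cath$volume / cath$length
  stored0 <- colSums(cur$fractions) * voxvol
  entered <- c(R = 0, G = 0)
  emitted <- c(R = 0, G = 0)
  for (step in 1:200) {
    fr <- runif(1)
    entry <- c(R = fr, G = 1 - fr)
    dl <- runif(1, 0, 0.9) * cath$gamma * 100
    r <- advect(cur, entry, dl, cath)
    expect_true(all(abs(rowSums(r$series$fractions) - 1) < 1e-9))
    expect_true(all(r$series$fractions >= -1e-12 &
                      r$series$fractions <= 1 + 1e-12))
    entered <- entered + entry * dl * cath$volume / cath$length
    emitted <- emitted + r$emitted
    cur <- r$series
  }
  stored <- colSums(cur$fractions) * voxvol
  drift <- stored0 + entered - emitted - stored
  expect_lt(max(abs(drift)), 1e-6)
})

test_that("entry sequence recovers the bolus volume and the step response", {
  en <- std_entry()
  Q <- sum(en$a_diff) * en$gamma * en$V_cath / en$L
  expect_equal(Q, 0.10305, tolerance = 0.005 * 0.10305)
  # all-zero deviation gives an all-zero sequence
  tg <- seq(0, 600, 0.5)
  flow0 <- list(times = tg,
                u_diff = matrix(0, length(tg), 1,
                                dimnames = list(NULL, "red")),
                u_cath = rep(uf_std, length(tg)), labels = "red")
  en0 <- entry_sequence(flow0, standard_setup()$catheter, uf_std)
  expect_true(all(en0$a_diff == 0))
  # constant total flow: the sequence is a uniform resampling of the
  # two-exponential transient
  tf <- transient_flow(standard_setup(), ud_std)
  u <- u_m_diff(tf, tg)
  flowc <- list(times = tg,
                u_diff = matrix(u, ncol = 1, dimnames = list(NULL, "red")),
                u_cath = rep(uf_std, length(tg)), labels = "red")
  enc <- entry_sequence(flowc, standard_setup()$catheter, uf_std)
  j <- seq_along(enc$a_diff) - 1
  # agreement limited by the linear resampling of the trace grid
  expect_equal(enc$a_diff, u_m_diff(tf, j * enc$dtau) / uf_std,
               tolerance = 2e-3)
})
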