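test_that("the assembled trace has bolus boundary behaviour", {
  tr <- std_trace()
  expect_true(all(tr$beta[tr$times < 0] == 0))
  peak <- max(abs(tr$beta))
  # the kernel's 1/x^2 tail bounds the convolution term at the horizon: the
  # end value sits on the tail envelope sum(b) * w(k_end), well below peak
  b_mass <- sum(stretch_sequence(tr$entry))
  w_end <- tr$bolus$gamma * tr$bolus$L /
    (tr$bolus$gamma * max(tr$bolus$k) + tr$bolus$L)^2
  u_tot <- tr$bolus$u_total
  expect_lt(abs(tr$beta_pois[length(tr$beta_pois)]),
            1.5 * u_tot * b_mass * w_end)
  expect_lt(abs(tr$beta[length(tr$beta)]), 0.05 * peak)
  expect_setequal(unique(tr$branch), c("pre", "pushout", "compliance"))
  # push-out branch carries the constant push-out deviation
  expect_equal(unique(tr$beta[tr$branch == "pushout"]),
               pushout_flow(uR_std, uold_std, ufinG_std))
})

test_that("a set-up with no event yields an identically zero trace", {
  g <- pump_channel("green", 1.5e-5, 23, data.frame(time = -Inf, rate = 12))
  r <- pump_channel("red", 1.5e-5, 23, data.frame(time = -Inf, rate = 0.5))
  tr <- assemble_trace(infusion_setup(list(g, r), catheter_spec(1145)))
  expect_true(all(tr$beta == 0))
})

test_that("multi-event schedules are routed to the simulators", {
  s <- standard_setup()
  s$channels[[1]]$schedule <- data.frame(time = c(-Inf, 0, 100),
                                         rate = to_internal(c(12, 6, 9), "ml/s"))
  expect_error(assemble_trace(s), "superposition")
})

test_that("the rigid-limit push-out example delivers 3r then r again", {
  # both pumps at q, one increased to 5q at t = 0, negligible compliance:
  # unchanged-fluid outflow is 3q during one delay interval, then q again
  q <- 6
  g <- pump_channel("green", 1e-10, 23,
                    data.frame(time = c(-Inf, 0), rate = c(q, 5 * q)))
  r <- pump_channel("red", 1e-10, 23, data.frame(time = -Inf, rate = q))
  s <- infusion_setup(list(g, r), catheter_spec(1145))
  tr <- assemble_trace(s, poiseuille = FALSE)
  qc <- to_internal(q, "ml/h")
  mid <- tr$times > 0.2 * tr$t_delay & tr$times < 0.8 * tr$t_delay
  expect_equal(unique(tr$beta[mid] + qc) / qc, 3, tolerance = 1e-6)
  late <- tr$times > 1.5 * tr$t_delay
  expect_lt(max(abs(tr$beta[late])), 1e-6 * qc)
})

test_that("the trace integral combines push-out and compliance volumes", {
  s <- standard_setup()
  tr <- assemble_trace(s, poiseuille = FALSE)
  trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  total <- trapz(tr$times, tr$beta)
  expect_lt(abs(total - (tr$pushout_volume + tr$Q_closed)) / tr$Q_closed,
            0.02)
  expect_equal(tr$Q_closed, 0.10305, tolerance = 1e-9)
})

test_that("named scenarios produce the documented relationships", {
  s <- standard_setup()
  f9 <- run_scenario("exchange_sweep", s, T_grid = seq(0, 600, 20))
  expect_equal(f9$combined, f9$pump_on_only + f9$compliance_only,
               tolerance = 1e-12)
  f8 <- run_scenario("parameter_sweep", s, t_grid = seq(0, 300, 1))
  Qs <- vapply(f8$variants, `[[`, numeric(1), "Q")
  expect_equal(unname(Qs[["1"]] / Qs[["3"]]), 3, tolerance = 1e-12)
  expect_equal(unname(Qs[["2"]] / Qs[["3"]]), 2, tolerance = 1e-12)
  # member 3 is the identity configuration
  expect_identical(setup_to_config(f8$variants[["3"]]$setup),
                   setup_to_config(s))
  expect_equal(unname(Qs[["4"]] / Qs[["3"]]), 0.52, tolerance = 1e-12)
  expect_error(run_scenario("unknown"), "arg")
})

test_that("fixture generation is deterministic and loadable", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- generate_fixtures(3, d1, n_random = 5)
  p2 <- generate_fixtures(3, d2, n_random = 5)
  expect_identical(lapply(p1, readLines), lapply(p2, readLines))
  expect_identical(setup_to_config(read_setup(file.path(d1, "standard.yaml"))),
                   setup_to_config(standard_setup()))
  for (p in p1) {
    s <- read_setup(p)   # constructor validation runs on load
    expect_s3_class(s, "infusion_setup")
  }
})

test_that("the CLI round-trips configs, metrics and fixtures", {
  d <- withr::local_tempdir()
  cli_main(c("fixtures", "--seed", "2", "--out", file.path(d, "fx")))
  cfg <- file.path(d, "fx", "standard.yaml")
  expect_true(file.exists(cfg))
  out <- file.path(d, "run")
  cli_main(c("simulate", "--config", cfg, "--out", out))
  expect_true(all(file.exists(file.path(out, c("trace.csv", "flow.csv",
                                               "metrics.json", "run.log")))))
  met <- jsonlite::read_json(file.path(out, "metrics.json"))
  expect_equal(met$Q_closed_form_ml, 0.10305, tolerance = 1e-9)
  txt <- capture.output(cli_main(c("metrics", "--config", cfg)))
  expect_match(paste(txt, collapse = ""), "t_central_s")
  expect_error(cli_main(c("simulate", "--config", cfg)), "--out")
  expect_error(cli_main(c("explode")), "unknown subcommand")
})
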