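test_that("coverage trajectories honor the scenario definitions", {
  times <- seq(0, 240, by = 1)
  # a very steep logistic approaches a step at its midpoint
  steep <- growth_scenario(growth_rate = 1e3, t0 = 2)
  traj <- simulate_ff_trajectory(times, "undifferentiated", steep)
  expect_lt(max(traj$coverage[times < 46]), 1e-6)
  expect_gt(min(traj$coverage[times > 50]), 0.95 - 1e-6)
  # defaults: confluent (ff >= 0.9) by day 5, seeded near 5% coverage
  def <- simulate_ff_trajectory(times, "undifferentiated")
  expect_gt(def$coverage[times == 120], 0.9)
  expect_equal(def$coverage[1], 0.05, tolerance = 1e-3)
  # medium-only wells carry no cells
  mo <- simulate_ff_trajectory(times, "medium_only")
  expect_true(all(mo$coverage == 0))
  # a zero-variance plateau draw reproduces the mean exactly
  d0 <- differentiation_scenario(plateau_sd = 0)
  expect_equal(draw_plateau(d0, 5), rep(0.8, 5))
  tr <- simulate_ff_trajectory(times, "differentiated", diff = d0)
  expect_equal(tr$events$plateau_duration_d, 0.8)
  expect_equal(tr$events$plateau_end_h, tr$events$medium_change_h + 0.8 * 24)
  # during the plateau the coverage is frozen at the 70% threshold
  inplat <- times > tr$events$medium_change_h & times < tr$events$plateau_end_h
  expect_true(all(tr$coverage[inplat] == 0.70))
  expect_error(simulate_ff_trajectory(c(0, 0, 1), "differentiated"), "increasing")
})

test_that("plateau draws have the stated ensemble moments", {
  set.seed(1)
  d <- draw_plateau(differentiation_scenario(), 200)
  expect_lt(abs(mean(d) - 0.8), 0.05)
  expect_lt(abs(sd(d) - 0.1), 0.03)
  expect_true(all(d >= 0))
})

test_that("a default study emits exactly the five monitored traces", {
  st <- simulate_study(noise = noise_spec(seed = 4), seed = 4)
  expect_named(st$traces, c("1", "2", "3", "5", "6"))
  expect_equal(st$traces[["1"]]$condition, "medium_only")
  expect_equal(st$traces[["6"]]$condition, "differentiated")
  # unmonitored wells 4 and 7 still carry ground truth, but no trace
  expect_false(st$truth[["4"]]$monitored)
  expect_null(st$traces[["4"]])
  # noise-free medium-only wells are exactly constant
  st0 <- simulate_study(noise = noise_spec(0, 0, seed = 4), seed = 4)
  expect_equal(length(unique(st0$traces[["1"]]$amplitude_v)), 1L)
  # and the constant equals the bare-electrode oscillation amplitude
  expect_equal(st0$traces[["1"]]$amplitude_v[1],
               predict_oscillation(st0$config, 0)$a_osc, tolerance = 1e-9)
  expect_error(simulate_study(layout = study_layout()[0, ]), "empty")
})

test_that("fixtures are deterministic, reloadable and accepted by the pipeline", {
  st <- simulate_study(noise = noise_spec(seed = 8), seed = 8)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture(st, d1)
  write_fixture(simulate_study(noise = noise_spec(seed = 8), seed = 8), d2)
  for (f in c("traces.csv", "truth.json", "config.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  # generator-pipeline closure: loaded without a single warning
  expect_no_warning(back <- load_traces(file.path(d1, "traces.csv")))
  expect_named(back, names(st$traces))
  expect_equal(back[["6"]]$amplitude_v, st$traces[["6"]]$amplitude_v,
               tolerance = 1e-12)
  fx <- load_fixture(d1)
  expect_equal(fx$truth[["6"]]$plateau_duration_d,
               st$truth[["6"]]$plateau_duration_d, tolerance = 1e-12)
  expect_equal(fx$config$circuit$R_gap, st$config$circuit$R_gap)

  # end-to-end smoke test: the pipeline consumes the fixture without error
  rep <- run_pipeline(back, st$config,
                      medium_change_time = fx$truth[["6"]]$medium_change_h)
  expect_s3_class(rep, "study_report")
  expect_equal(nrow(rep$deltas), 3)
  gaps <- rep$table2$R_gap_ohm[!rep$table2$differentiated]
  expect_lt(max(abs(gaps - 1000) / 1000), 0.05)
})

test_that("noiseless differentiated traces give back their plateau within one sample", {
  lay <- data.frame(well = c("a", "b"), condition = "differentiated",
                    monitored = TRUE)
  st <- simulate_study(layout = lay, noise = noise_spec(0, 0, seed = 6), seed = 6)
  for (w in c("a", "b")) {
    seg <- segment_phases(st$traces[[w]], st$truth[[w]]$medium_change_h)
    expect_lt(abs(seg$plateau_duration - st$truth[[w]]$plateau_duration_d),
              1 / 24 + 1e-9)
  }
})

test_that("interpolating generator mode is numerically equivalent to exact", {
  lay <- data.frame(well = "a", condition = "differentiated", monitored = TRUE)
  ex <- simulate_study(layout = lay, noise = noise_spec(0, 0, seed = 9),
                       seed = 9, solver = "exact")
  ip <- simulate_study(layout = lay, noise = noise_spec(0, 0, seed = 9),
                       seed = 9, solver = "interpolate")
  expect_lt(max(abs(ex$traces[["a"]]$amplitude_v - ip$traces[["a"]]$amplitude_v) /
                  ex$traces[["a"]]$amplitude_v), 1e-5)
})
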