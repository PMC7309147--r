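make_trace <- function(well = "w", n = 100, f = function(t) 0.01 + 1e-4 * t,
                       cond = "undifferentiated") {
  t <- seq(0, n - 1)
  amplitude_trace(well, t, f(t), cond)
}

test_that("trace construction and CSV round trip", {
  tr <- make_trace()
  expect_s3_class(tr, "amplitude_trace")
  expect_error(amplitude_trace("w", c(0, 1, 1), c(1, 2, 3)), "strictly increasing")
  expect_error(amplitude_trace("w", 0:2, c(1, 2)), "equal length")

  path <- withr::local_tempfile(fileext = ".csv")
  trs <- list(make_trace("a"), make_trace("b", cond = "differentiated"),
              make_trace("c", cond = "medium_only"))
  write_traces(trs, path)
  back <- load_traces(path)
  expect_length(back, 3)
  expect_equal(back[["b"]]$condition, "differentiated")
  expect_equal(back[["a"]]$amplitude_v, trs[[1]]$amplitude_v, tolerance = 1e-12)
  # write -> read -> write is byte-identical
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_traces(back, path2)
  expect_identical(readLines(path), readLines(path2))
  # a condition map overrides the stored column
  remap <- load_traces(path, conditions = c(a = "medium_only"))
  expect_equal(remap[["a"]]$condition, "medium_only")
})

test_that("malformed trace files are rejected with row-level diagnostics", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("well,time_h,amplitude_v", "w,0,0.1", "w,1,0.1", "w,1,0.2"), path)
  expect_error(load_traces(path), "duplicated timestamp")
  writeLines(c("well,amplitude_v", "w,0.1"), path)
  expect_error(load_traces(path), "misses columns")
  expect_error(load_traces("/nonexistent/file.csv"), "not found")
  # irregular sampling only warns
  writeLines(c("well,time_h,amplitude_v",
               paste("w", seq(0, 72, by = 1.5), 0.1, sep = ",")), path)
  expect_warning(load_traces(path), "deviates")
})

cfg <- default_obt_config()
cal <- build_calibration(cfg)

test_that("confluence-threshold detection finds the 70% crossing", {
  # trace always below threshold
  low <- make_trace(f = function(t) rep(predict_oscillation(cfg, 0.1)$a_osc, length(t)))
  expect_true(is.na(detect_confluence_threshold(low, cal)))
  # trace starting above threshold reports the first timestamp
  high <- make_trace(f = function(t) rep(predict_oscillation(cfg, 0.9)$a_osc, length(t)))
  expect_equal(detect_confluence_threshold(high, cal), 0)
  # generator ground truth: logistic growth with a known 70% crossing
  g <- growth_scenario()
  t_true <- 24 * (g$t0 + log(0.70 / (g$ff_max - 0.70)) / g$growth_rate)
  st <- simulate_study(noise = noise_spec(seed = 21), seed = 21)
  t_det <- detect_confluence_threshold(st$traces[["2"]], cal)
  expect_lt(abs(t_det - t_true), 1.0)
})

test_that("phase segmentation recovers a noiseless piecewise plateau", {
  t <- 0:240
  flat <- 0.01 + 72 * 1e-4
  a <- ifelse(t < 72, 0.01 + 1e-4 * t,
              ifelse(t < 72 + 0.8 * 24, flat, flat + 2e-4 * (t - 91.2)))
  tr <- amplitude_trace("x", t, a, "differentiated")
  seg <- segment_phases(tr, 72)
  expect_lt(abs(seg$plateau_duration - 0.8), 0.05)
  expect_equal(seg$delta_growth, 72 * 1e-4, tolerance = 1e-9)
  expect_equal(seg$delta_max, a[241] - a[1], tolerance = 1e-9)
  expect_gte(seg$delta_max, seg$delta_growth)
  expect_equal(seg$diff_slope, 2e-4 * 24, tolerance = 0.05)
  # the windowed slope-threshold alternate is coarser but finds the plateau
  seg_w <- segment_phases(tr, 72, method = "slope_window")
  expect_lt(abs(seg_w$plateau_duration - 0.8), 0.2)
  # a monotone rising trace has no plateau
  mono <- segment_phases(make_trace(n = 241), 72)
  expect_equal(mono$plateau_duration, 0)
  # guards
  expect_error(segment_phases(tr, 500), "outside trace span")
  expect_error(segment_phases(make_trace(n = 10), 5), "at least 24")
})

test_that("segmentation is affine-equivariant; deltas scale with the gain", {
  st <- simulate_study(noise = noise_spec(seed = 13), seed = 13)
  tr <- st$traces[["6"]]
  mc <- st$truth[["6"]]$medium_change_h
  s1 <- segment_phases(tr, mc)
  scaled <- amplitude_trace(tr$well, tr$time_h, 2.5 * tr$amplitude_v + 0.04,
                            tr$condition)
  s2 <- segment_phases(scaled, mc)
  expect_equal(s2$plateau_duration, s1$plateau_duration, tolerance = 1e-9)
  expect_equal(s2$delta_growth, 2.5 * s1$delta_growth, tolerance = 1e-9)
  expect_equal(s2$delta_max, 2.5 * s1$delta_max, tolerance = 1e-9)
  expect_equal(s2$diff_slope, 2.5 * s1$diff_slope, tolerance = 1e-9)
  # delta_max dominates delta_growth on every generator trace
  for (w in names(st$traces)) {
    if (st$traces[[w]]$condition == "medium_only") next
    s <- segment_phases(st$traces[[w]], mc)
    expect_gte(s$delta_max, s$delta_growth - 1e-12)
  }
})

test_that("exact rank-sum test matches brute-force enumeration and handles ties", {
  # identical groups: all midranks tie, p = 1
  expect_equal(group_compare(c(1, 1, 1), c(1, 1, 1))$p_value, 1)
  # most extreme 3 vs 3 arrangement: two-sided p = 2/20
  expect_equal(group_compare(c(10, 11, 12), c(1, 2, 3))$p_value, 0.1)
  expect_equal(rank_sum_exact(c(10, 11, 12), c(1, 2, 3))$statistic, 15)
  set.seed(77)
  for (rep in 1:40) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- round(rnorm(nx), 1); y <- round(rnorm(ny, sample(0:1, 1)), 1)
    expect_equal(rank_sum_exact(x, y)$p_value, oracle_ranksum_p(x, y),
                 tolerance = 1e-12)
  }
  expect_error(group_compare(1, c(1, 2)), "at least 2")
  w <- group_compare(c(3, 4, 5), c(1, 2, 2.5), method = "welch")
  expect_equal(w$method, "welch")
  expect_true(w$p_value > 0 && w$p_value < 1)
})

test_that("the resistance table applies the bulk-mean rule per experiment", {
  rgap <- data.frame(experiment = c(1, 1, 2, 2), well = c("2", "3", "2", "3"),
                     R_gap_ohm = c(1017.6, 1009.2, 845.3, 846))
  tab <- build_table2(rgap)
  expect_s3_class(tab, "study_table")
  expect_equal(nrow(tab), 4)
  # single-well experiments are flagged n=1 and R_bulk equals that well
  tab1 <- build_table2(data.frame(experiment = 1, well = "2", R_gap_ohm = 950))
  expect_equal(tab1$flag, "n=1")

  # with differentiated observations, R_bulk is the experiment mean and
  # R_tissue is recovered from the tissue forward model
  truth_rt <- 158.92
  tm <- tissue_model(1013.4, truth_rt, R_ct = cfg$circuit$R_ct,
                     C_dl = cfg$circuit$C_dl, R_s = cfg$circuit$R_s,
                     include_R_s = TRUE)
  a6 <- solve_oscillation(cfg$bandpass, cfg$bioimpedance, cfg$comparator, tm)$a_osc
  diff_obs <- data.frame(experiment = 1, well = "6", a_osc_volt = rep(a6, 5))
  tab2 <- build_table2(rgap[rgap$experiment == 1, ], diff_obs, cfg)
  w6 <- tab2[tab2$differentiated, ]
  expect_equal(w6$R_bulk_ohm, 1013.4)
  expect_lt(abs(w6$R_tissue_ohm - truth_rt) / truth_rt, 1e-6)
})
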