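test_that("fill factor from counts: hand arithmetic, overflow flag, linearity", {
  expect_equal(as.numeric(fill_factor_from_counts(0, 400, 0.8)), 0)
  # 400 um^2 x 1e4 cells in a 0.8 cm^2 well
  expect_equal(as.numeric(fill_factor_from_counts(1e4, 400, 0.8)), 0.05)
  expect_warning(over <- fill_factor_from_counts(2.5e5, 400, 0.8),
                 "supra-confluent")
  expect_equal(as.numeric(over), 1.25)
  expect_true(attr(over, "overflow"))
  expect_error(fill_factor_from_counts(1e4, 400, 0), "a_p_cm2")
  expect_error(fill_factor_from_counts(-5, 400, 0.8), "n_cell")
  # linear in N_cell and A_cell, inverse in A_p (randomized scaling)
  set.seed(31)
  for (rep in 1:50) {
    n <- runif(1, 1, 1e5); ac <- runif(1, 100, 1000); ap <- runif(1, 0.5, 10)
    s <- runif(1, 0.1, 5)
    base <- as.numeric(suppressWarnings(fill_factor_from_counts(n, ac, ap)))
    expect_equal(as.numeric(suppressWarnings(fill_factor_from_counts(s * n, ac, ap))),
                 s * base, tolerance = 1e-12)
    expect_equal(as.numeric(suppressWarnings(fill_factor_from_counts(n, s * ac, ap))),
                 s * base, tolerance = 1e-12)
    expect_equal(as.numeric(suppressWarnings(fill_factor_from_counts(n, ac, s * ap))),
                 base / s, tolerance = 1e-12)
  }
})

cfg <- default_obt_config()
cal <- build_calibration(cfg)

test_that("the default calibration curve is strictly monotone and consistent", {
  expect_true(attr(cal, "monotone"))
  expect_equal(nrow(cal), 21)
  s0 <- predict_oscillation(cfg, 0)
  expect_equal(cal$a_osc_volt[1], s0$a_osc)
  expect_equal(cal$f_osc_hz[1], s0$f_osc)
  # degenerate single-point grid is monotone vacuously
  single <- build_calibration(cfg, ff = 0.5)
  expect_true(attr(single, "monotone"))
  expect_equal(amplitude_to_ff(single$a_osc_volt, single), 0.5)
  # a non-oscillating configuration fails loudly, naming the grid point
  bad <- obt_config(comparator = comparator_spec(loop_sign = +1))
  expect_error(build_calibration(bad, ff = 0.25), "ff = 0.25")
})

test_that("amplitude inversion round-trips and guards its domain", {
  expect_equal(amplitude_to_ff(cal$a_osc_volt[1], cal), 0)
  a37 <- predict_oscillation(cfg, 0.37)$a_osc
  expect_lt(abs(amplitude_to_ff(a37, cal) - 0.37), 1e-6)
  # the 2% end band clamps to the endpoint; beyond it is a range error
  expect_equal(amplitude_to_ff(cal$a_osc_volt[1] * 0.99, cal), 0)
  expect_error(amplitude_to_ff(cal$a_osc_volt[1] * 0.9, cal), "below")
  expect_error(amplitude_to_ff(max(cal$a_osc_volt) * 1.1, cal), "above")
  fake <- cal
  fake$a_osc_volt[3] <- fake$a_osc_volt[5]  # break monotonicity
  attr(fake, "monotone") <- FALSE
  expect_error(amplitude_to_ff(0.01, fake), "monotone")
})

test_that("gap-resistance fitting recovers truth exactly from noiseless data", {
  truth <- interface_params(R_gap = 1234)
  cfg_t <- obt_config(circuit = truth)
  obs <- data.frame(ff = seq(0.3, 0.95, length.out = 6))
  obs$a_osc_volt <- vapply(obs$ff, function(f)
    predict_oscillation(cfg_t, f)$a_osc, numeric(1))
  # fit starting from the (wrong) default R_gap = 1000
  fit <- fit_interface_params(obs, cfg, free = "R_gap")
  expect_true(fit$converged)
  expect_lt(abs(fit$values[["R_gap"]] - 1234) / 1234, 1e-6)
  expect_error(fit_interface_params(obs[1:1, ][0, ], cfg, free = "R_gap"),
               "at least as many")
  expect_error(fit_interface_params(obs, cfg, free = "R_nothing"), "subset")
})

test_that("fitted standard errors shrink like 1/sqrt(n)", {
  set.seed(202)
  ff <- 0.8
  a_true <- predict_oscillation(cfg, ff)$a_osc
  ns <- c(5, 20, 80)
  fits <- lapply(ns, function(n) {
    obs <- data.frame(ff = rep(ff, n),
                      a_osc_volt = a_true * (1 + rnorm(n, 0, 0.01)))
    fit_interface_params(obs, cfg, free = "R_gap")
  })
  se <- vapply(fits, function(f) f$se[["R_gap"]], numeric(1))
  sig <- vapply(seq_along(ns), function(i)
    fits[[i]]$residual_norm / sqrt(ns[i] - 1), numeric(1))
  ## conditional on the realized noise level, se scales as sigma_hat/sqrt(n)
  norm_se <- se * sqrt(ns) / sig
  expect_lt(max(norm_se) / min(norm_se), 1.2)
  ## and the 16x replication gap dominates any plausible sigma_hat sampling
  expect_lt(se[3], se[1])
})

test_that("derive_rbulk is the arithmetic mean with guards", {
  expect_equal(derive_rbulk(c(1017.6, 1009.2)), 1013.4)
  expect_equal(derive_rbulk(c(845.3, 846)), 845.65)
  expect_equal(derive_rbulk(650), 650)
  expect_error(derive_rbulk(numeric(0)), "non-empty")
  expect_error(derive_rbulk(c(100, -5)), "positive")
})

test_that("derive_rtissue recovers the generating tissue resistance exactly", {
  for (case in list(c(1013.4, 158.92), c(845.65, 114.87))) {
    tm <- tissue_model(case[1], case[2], R_ct = cfg$circuit$R_ct,
                       C_dl = cfg$circuit$C_dl, R_s = cfg$circuit$R_s,
                       include_R_s = TRUE)
    a <- solve_oscillation(cfg$bandpass, cfg$bioimpedance, cfg$comparator, tm)$a_osc
    fit <- derive_rtissue(rep(a, 3), cfg, R_bulk = case[1])
    expect_true(fit$converged)
    expect_lt(abs(fit$R_tissue - case[2]) / case[2], 1e-6)
  }
  expect_error(derive_rtissue(numeric(0), cfg, 1000), "positive finite")
})
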