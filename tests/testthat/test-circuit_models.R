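test_that("electrode geometry derives the sensing area and guards its invariants", {
  g <- electrode_geometry()
  expect_equal(g$sensing_area_cm2, 10 * pi * 125^2 / 1e8)
  expect_lt(g$sensing_area_cm2, g$well_area_cm2)
  expect_error(electrode_geometry(n_electrodes = 0), "n_electrodes")
  expect_error(electrode_geometry(electrode_diameter_um = -1))
  # discs larger than the well are rejected
  expect_error(electrode_geometry(n_electrodes = 10, electrode_diameter_um = 250,
                                  well_area_cm2 = 1e-4), "smaller than the well")
})

test_that("bare-electrode impedance: DC limit, capacitor short, frozen value", {
  p <- interface_params(R_ct = 1e6, C_dl = 4e-9)
  expect_identical(bare_electrode_impedance(p, 0), 1e6 + 0i)
  expect_lt(Mod(bare_electrode_impedance(p, 1e12)), 1e-3)
  # omega * R_ct * C_dl = 1 exactly at omega = 250: Z = 1e6/(1+1i)
  expect_equal(bare_electrode_impedance(p, 250), 5e5 - 5e5i, tolerance = 1e-12)
  expect_error(bare_electrode_impedance(p, -1), "omega")
  expect_error(bare_electrode_impedance(p, Inf), "omega")
})

test_that("fill-factor split keeps equal branch time constants and the stated trends", {
  p <- interface_params()
  ffs <- seq(0.05, 0.95, by = 0.05)
  models <- lapply(ffs, cell_electrode_model, params = p)
  tau <- vapply(models, function(m) m$R_1 * m$C_1, numeric(1))
  tau2 <- vapply(models, function(m) m$R_2 * m$C_2, numeric(1))
  expect_equal(tau, rep(p$R_ct * p$C_dl, length(ffs)), tolerance = 1e-14)
  expect_equal(tau2, rep(p$R_ct * p$C_dl, length(ffs)), tolerance = 1e-14)
  # R_1, C_2 strictly increase with coverage; C_1, R_2 strictly decrease
  expect_true(all(diff(vapply(models, `[[`, numeric(1), "R_1")) > 0))
  expect_true(all(diff(vapply(models, `[[`, numeric(1), "C_2")) > 0))
  expect_true(all(diff(vapply(models, `[[`, numeric(1), "C_1")) < 0))
  expect_true(all(diff(vapply(models, `[[`, numeric(1), "R_2")) < 0))
  expect_error(cell_electrode_model(p, 1.2), "ff")
  expect_error(cell_electrode_model(p, -0.1), "ff")
})

test_that("covered-electrode impedance reduces exactly to the limits at ff = 0 and 1", {
  p <- interface_params(R_s = 500, R_ct = 1e6, C_dl = 50e-9, R_gap = 1000)
  omega <- 2 * pi * 10^seq(0, 6, length.out = 50)
  z0 <- cell_electrode_impedance(cell_electrode_model(p, 0), omega)
  z1 <- cell_electrode_impedance(cell_electrode_model(p, 1), omega)
  expect_lt(max(Mod(z0 - (p$R_s + bare_electrode_impedance(p, omega))) / Mod(z0)),
            1e-10)
  expect_lt(max(Mod(z1 - (p$R_s + p$R_gap + bare_electrode_impedance(p, omega))) /
                  Mod(z1)), 1e-10)
  # DC limits
  expect_equal(cell_electrode_impedance(cell_electrode_model(p, 0), 0),
               p$R_s + p$R_ct + 0i)
  expect_equal(cell_electrode_impedance(cell_electrode_model(p, 1), 0),
               p$R_s + p$R_gap + p$R_ct + 0i)
})

test_that("covered-electrode impedance matches the independent nodal oracle", {
  # frozen spot value (nodal solve, ff = 0.5, f = 1 kHz)
  m <- cell_electrode_model(interface_params(R_s = 500, R_ct = 1e6,
                                             C_dl = 4e-9, R_gap = 1000), 0.5)
  expect_equal(cell_electrode_impedance(m, 2 * pi * 1000),
               2330.5687665215428 - 39727.414010662949i, tolerance = 1e-12)
  # property: oracle equivalence over ff x omega grids, random parameters
  set.seed(42)
  for (rep in 1:25) {
    R_s <- runif(1, 10, 5e3); R_gap <- runif(1, 50, 5e3)
    R_ct <- 10^runif(1, 4, 7); C_dl <- 10^runif(1, -9, -7)
    p <- interface_params(R_s, R_ct, C_dl, R_gap)
    for (ff in c(0, 0.1, 0.37, 0.5, 0.82, 1)) {
      mdl <- cell_electrode_model(p, ff)
      for (f in 10^seq(1, 6, length.out = 7)) {
        z <- cell_electrode_impedance(mdl, 2 * pi * f)
        zo <- oracle_cell_impedance(R_s, R_gap, R_ct, C_dl, ff, 2 * pi * f)
        expect_lt(Mod(z - zo) / Mod(zo), 1e-10)
      }
    }
  }
})

test_that("DC resistance is non-decreasing in coverage for any positive parameters", {
  set.seed(7)
  ffs <- seq(0, 1, by = 0.05)
  for (rep in 1:500) {
    p <- interface_params(R_s = runif(1, 1, 1e4), R_ct = 10^runif(1, 3, 7),
                          C_dl = 10^runif(1, -10, -6),
                          R_gap = 10^runif(1, 1, 4))
    re0 <- vapply(ffs, function(ff)
      Re(cell_electrode_impedance(cell_electrode_model(p, ff), 0)), numeric(1))
    expect_true(all(diff(re0) >= -1e-9 * max(re0)))
  }
})

test_that("tissue impedance: DC and high-frequency limits, frozen spectrum value", {
  tm <- tissue_model(R_bulk = 1013.4, R_tissue = 158.92, R_ct = 1e6,
                     C_dl = 4e-9)
  # capacitor-short limit equals the series sum of the two resistances
  expect_equal(Mod(tissue_impedance(tm, 1e15)), 1013.4 + 158.92,
               tolerance = 1e-6)
  expect_equal(tissue_impedance(tm, 0), 1013.4 + 158.92 + 1e6 + 0i)
  tm2 <- tissue_model(845.65, 114.87, 1e6, 4e-9)
  expect_equal(tissue_impedance(tm2, 2 * pi * 1e4),
               976.35118431375076 - 3978.8105870164204i, tolerance = 1e-12)
  with_rs <- tissue_model(845.65, 114.87, 1e6, 4e-9, R_s = 500,
                          include_R_s = TRUE)
  expect_equal(tissue_impedance(with_rs, 0) - tissue_impedance(tm2, 0), 500 + 0i)
  expect_error(tissue_model(-1, 100), "R_bulk")
})

test_that("full-coverage cell model and tissue model agree when the series sums match", {
  p <- interface_params(R_s = 500, R_ct = 1e6, C_dl = 50e-9,
                        R_gap = 1013.4 + 158.92)
  cm <- cell_electrode_model(p, 1)
  tm <- tissue_model(1013.4, 158.92, R_ct = p$R_ct, C_dl = p$C_dl,
                     R_s = p$R_s, include_R_s = TRUE)
  chk <- consistency_check(cm, tm)
  expect_lt(chk$max_residual_ohm, 1e-9)
  expect_length(chk$mismatches, 0)

  # a series-sum mismatch shows up as a constant real offset, not an error
  tm_off <- tissue_model(1013.4, 100, R_ct = p$R_ct, C_dl = p$C_dl,
                         R_s = p$R_s, include_R_s = TRUE)
  chk2 <- consistency_check(cm, tm_off)
  expect_true("R_gap != R_bulk + R_tissue" %in% chk2$mismatches)
  expect_equal(chk2$residual_ohm,
               rep(158.92 - 100, length(chk2$freq_hz)), tolerance = 1e-9)

  # randomized property: zero residual whenever the shared parameters match
  set.seed(11)
  for (rep in 1:100) {
    rb <- runif(1, 100, 2000); rt <- runif(1, 10, 500)
    pp <- interface_params(R_s = runif(1, 100, 1000), R_ct = 10^runif(1, 4, 7),
                           C_dl = 10^runif(1, -9, -7), R_gap = rb + rt)
    ck <- consistency_check(
      cell_electrode_model(pp, 1),
      tissue_model(rb, rt, pp$R_ct, pp$C_dl, pp$R_s, include_R_s = TRUE))
    expect_lt(ck$max_residual_ohm, 1e-9)
  }
  expect_error(consistency_check(cell_electrode_model(p, 0.5), tm), "ff = 1")
})

test_that("impedance spectra round-trip through CSV", {
  m <- cell_electrode_model(interface_params(), 0.3)
  spec <- impedance_spectrum(m, freq_hz = 10^seq(2, 5, length.out = 13))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(spec, path)
  back <- read_spectrum(path)
  expect_equal(back, spec, tolerance = 1e-12)
  write.csv(spec[1:2], path, row.names = FALSE)
  expect_error(read_spectrum(path), "misses columns")
})
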