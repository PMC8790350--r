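test_that("finite cylinder agrees with the weak-scatterer Born oracle", {
  med <- default_medium()
  # weak contrasts so the Born approximation is itself exact enough
  g <- 1.002; h <- 1.003
  rho <- g * med$density_water
  cf <- h * med$sound_speed_water
  med_weak <- acoustic_medium(sound_speed_fish = cf)
  for (sl in c(10, 15, 20, 25, 30)) {
    for (lwr in c(8, 10, 12, 14, 16)) {
      prof <- taxon_profile("WK", rho, lwr, "FC", 1e-5, 3,
                            gas_bearing = FALSE)
      ts_pkg <- finite_cylinder_ts(prof, sl, med_weak)
      ts_orc <- dwba_cylinder_ts(sl, lwr, g, h, med_weak)
      expect_lt(abs(ts_pkg - ts_orc), 0.1,
                label = sprintf("SL %g LWR %g: |%.3f - %.3f|",
                                sl, lwr, ts_pkg, ts_orc))
    }
  }
})

test_that("finite cylinder TS is monotone in length and handles degeneracy", {
  prof <- fc_profile()
  ts <- finite_cylinder_ts(prof, seq(30, 160, by = 10))
  expect_true(all(diff(ts) >= 0))
  # no impedance contrast, no echo
  med0 <- acoustic_medium(sound_speed_fish = 1465.836)
  prof0 <- taxon_profile("NUL", 1027.4, 10, "FC", 1e-5, 3,
                         gas_bearing = FALSE)
  expect_equal(finite_cylinder_ts(prof0, 80, med0), -Inf)
  expect_error(finite_cylinder_ts(prof, -5))
  expect_error(finite_cylinder_ts(ps_profile(), 50), "requires model FC")
})

test_that("prolate spheroid TS follows the buoyancy-volume geometry", {
  med <- default_medium()
  prof <- ps_profile()
  sl <- 43
  ts <- prolate_spheroid_ts(prof, sl, med, aspect_ratio = 3)
  # independent reconstruction: solve the spheroid semi-axes from the gas
  # volume by numerical inversion, then apply the specular-return formula
  mass <- prof$lw_a * sl^prof$lw_b
  v_m3 <- gas_volume_neutral_buoyancy(mass, prof$tissue_density,
                                      med$density_water) * 1e-6
  b_min <- uniroot(function(b) 4 / 3 * pi * (3 * b) * b^2 - v_m3,
                   c(1e-6, 1e-1), tol = 1e-15)$root
  expect_equal(ts, 10 * log10((3 * b_min)^2 / 4), tolerance = 1e-6)

  # monotone in length; increasing with aspect ratio
  expect_true(all(diff(prolate_spheroid_ts(prof, c(35, 45, 55), med)) > 0))
  expect_lt(prolate_spheroid_ts(prof, sl, med, aspect_ratio = 2),
            prolate_spheroid_ts(prof, sl, med, aspect_ratio = 4))
  # vanishing gas volume -> no target
  light <- taxon_profile("LGT", 1020, 10, "PS", 1e-5, 3,
                         gas_bearing = TRUE, water_density = 1010)
  expect_warning(ts0 <- prolate_spheroid_ts(light, 50, med))
  expect_equal(ts0, -Inf)
  expect_error(prolate_spheroid_ts(fc_profile(), 50, med),
               "requires model PS")
})

test_that("SDWBA krill TS is reproducible, convergent and guarded", {
  med <- default_medium()
  t1 <- sdwba_krill_ts(45, med, seed = 11)
  t2 <- sdwba_krill_ts(45, med, seed = 11)
  expect_identical(t1, t2)
  # ensemble-mean convergence: doubling realizations moves TS < 0.1 dB
  p200 <- krill_parameters(n_realizations = 200)
  p400 <- krill_parameters(n_realizations = 400)
  expect_lt(abs(sdwba_krill_ts(45, med, p200, seed = 2) -
                  sdwba_krill_ts(45, med, p400, seed = 2)), 0.1)
  # no contrast, no echo
  expect_equal(sdwba_krill_ts(45, med, krill_parameters(g = 1, h = 1)),
               -Inf)
  expect_error(sdwba_krill_ts(95, med), "length outside")
  expect_error(sdwba_krill_ts(45, acoustic_medium(frequency = 5000)),
               "unsupported frequency")
  # TS increases with length over the survey size range
  ts <- sdwba_krill_ts(c(35, 45, 55), med, seed = 3)
  expect_true(all(diff(ts) > 0))
})

test_that("TS table is complete, column-monotone and order-invariant", {
  tax <- scotia_sea_taxa()
  tt <- build_ts_table(tax$profiles, tax$stats, seed = 1)
  expect_equal(nrow(tt), 13)
  expect_true(all(tt[, c("p25", "mean", "median", "p75")] < 0))
  # TS non-decreasing from p25 to p75 within each row
  expect_true(all(tt$p25 <= tt$median + 1e-9))
  expect_true(all(tt$median <= tt$p75 + 1e-9))

  # permuting input rows leaves values unchanged
  ord <- rev(names(tax$profiles))
  tt2 <- build_ts_table(tax$profiles[ord], tax$stats[ord], seed = 1)
  m1 <- tt[match(ord, tt$taxon), c("p25", "mean", "median", "p75")]
  rownames(m1) <- NULL
  m2 <- tt2[, c("p25", "mean", "median", "p75")]
  expect_equal(m1, m2)

  # all statistics equal -> identical TS values
  one <- list(GYR = tax$profiles$GYR)
  st <- list(GYR = length_stats(86, 86, 86, 86))
  flat <- build_ts_table(one, st)
  expect_equal(length(unique(as.numeric(flat[1, c("p25", "mean", "median",
                                                  "p75")]))), 1)
  expect_error(build_ts_table(tax$profiles, tax$stats[-1]),
               "missing length statistics")
})

test_that("gas-bearing median TS dominates bladderless median TS by > 8 dB", {
  tax <- scotia_sea_taxa()
  tt <- build_ts_table(tax$profiles, tax$stats, seed = 1)
  gas <- tt$median[tt$model == "PS"]
  nongas <- tt$median[tt$model == "FC"]
  expect_gt(min(gas) - max(nongas), 8)
})
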