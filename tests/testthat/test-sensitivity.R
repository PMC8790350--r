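test_that("the permutation sampler is exhaustive, distinct and seeded", {
  d <- sample_draws(27, c("A", "B", "C"), seed = 5)
  expect_equal(nrow(d), 27)
  expect_equal(nrow(unique(as.data.frame(unclass(d)))), 27)  # all combos once
  expect_true(all(d %in% c("p25", "median", "p75")))

  taxa11 <- paste0("T", 1:11)
  d2 <- sample_draws(2000, taxa11, seed = 1)
  expect_equal(nrow(unique(as.data.frame(unclass(d2)))), 2000)
  d3 <- sample_draws(2000, taxa11, seed = 1)
  expect_identical(d2, d3)
  expect_false(identical(d2, sample_draws(2000, taxa11, seed = 2)))
  expect_error(sample_draws(28, c("A", "B", "C")), "cannot draw")
})

test_that("krill NASC adjustment is the forward relation, floored at zero", {
  sigma <- 10^(-79.90 / 10)
  out <- krill_adjusted_nasc(c(100, 20), 64, sigma)
  nasc_krill <- 64 * sigma * 4 * pi * 1852^2
  expect_equal(nasc_krill, 28.2, tolerance = 2e-3)
  expect_equal(as.numeric(out), c(100 - nasc_krill, 0))
  expect_equal(attr(out, "n_floored"), 1)
  # density zero is the identity
  expect_equal(as.numeric(krill_adjusted_nasc(c(5, 7), 0, sigma)), c(5, 7))
  # linearity before flooring
  expect_equal(attr(krill_adjusted_nasc(1e6, 128, sigma), "nasc_krill"),
               2 * attr(krill_adjusted_nasc(1e6, 64, sigma), "nasc_krill"))
  expect_error(krill_adjusted_nasc(10, -1, sigma))
})

test_that("krill-as-taxon mechanism reduces to the subtraction rule", {
  sigma_k <- 1e-8
  s_f <- 3.2e-5   # fish composition backscatter, arbitrary scale
  nasc <- c(0.5, 5, 50, 500)
  sub <- krill_adjusted_nasc(nasc, 64, sigma_k)
  tax <- krill_as_taxon_nasc(nasc, 64, sigma_k, s_f)
  expect_equal(as.numeric(tax), as.numeric(sub), tolerance = 1e-10)
  # scale of the fish composition is irrelevant
  tax2 <- krill_as_taxon_nasc(nasc, 64, sigma_k, s_f * 1e3)
  expect_equal(as.numeric(tax2), as.numeric(tax), tolerance = 1e-10)
})

test_that("degenerate and scenario properties of the sensitivity run hold", {
  w <- small_world()
  taxa <- colnames(w$comp)
  krill_code <- "KRI"
  draw_taxa <- c(taxa, krill_code)

  # all draws forced to median -> zero spread, equal to the point estimate
  forced <- matrix("median", nrow = 5, ncol = length(draw_taxa),
                   dimnames = list(NULL, draw_taxa))
  res <- run_sensitivity(w$sim$grid, w$comp, w$tax$profiles, w$tax$stats,
                         krill_densities = c(0, 64), draws = forced,
                         seed = 3)
  expect_true(all(res$sd_mt == 0))

  # fish-only (density 0) scenario equals the no-krill run
  res0 <- run_sensitivity(w$sim$grid, w$comp, w$tax$profiles, w$tax$stats,
                          krill_densities = 0, draws = forced, seed = 3)
  expect_equal(res$mean_mt[res$krill_density == 0],
               res0$mean_mt, tolerance = 1e-12)

  # krill monotonicity: fish biomass non-increasing in krill density
  d <- sample_draws(50, draw_taxa, seed = 7)
  res2 <- run_sensitivity(w$sim$grid, w$comp, w$tax$profiles, w$tax$stats,
                          krill_densities = c(0, 32, 64, 128), draws = d,
                          seed = 7)
  for (r in unique(res2$region)) for (ts in unique(res2$taxa_set)) {
    v <- res2$mean_mt[res2$region == r & res2$taxa_set == ts]
    expect_true(all(diff(v) <= 1e-12),
                label = paste("monotone", r, ts))
  }

  # bit-reproducibility under a fixed seed
  resA <- run_sensitivity(w$sim$grid, w$comp, w$tax$profiles, w$tax$stats,
                          n_draws = 40, seed = 11, krill_densities = c(0, 64))
  resB <- run_sensitivity(w$sim$grid, w$comp, w$tax$profiles, w$tax$stats,
                          n_draws = 40, seed = 11, krill_densities = c(0, 64))
  expect_identical(resA, resB)

  # myctophid subset never exceeds the all-fish total
  expect_true(all(res2$mean_mt[res2$taxa_set == "myctophids"] <=
                    res2$mean_mt[res2$taxa_set == "all_fish"] + 1e-12))
})

test_that("the IQR brackets the median point estimate on permuted draws", {
  w <- small_world()
  draw_taxa <- c(colnames(w$comp), "KRI")
  d <- sample_draws(200, draw_taxa, seed = 13)
  res <- run_sensitivity(w$sim$grid, w$comp, w$tax$profiles, w$tax$stats,
                         krill_densities = 0, draws = d, seed = 13)
  forced <- matrix("median", 1, length(draw_taxa),
                   dimnames = list(NULL, draw_taxa))
  point <- run_sensitivity(w$sim$grid, w$comp, w$tax$profiles, w$tax$stats,
                           krill_densities = 0, draws = forced, seed = 13)
  so <- res$region == "southern_ocean" & res$taxa_set == "all_fish"
  expect_lt(res$p25_mt[so], point$mean_mt[point$region == "southern_ocean" &
                                            point$taxa_set == "all_fish"])
  expect_gt(res$p75_mt[so], point$mean_mt[point$region == "southern_ocean" &
                                            point$taxa_set == "all_fish"])
})
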