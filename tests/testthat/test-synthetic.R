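test_that("simulated lengths hit the solved lognormal percentiles", {
  st <- length_stats(67, 84.22, 86, 103)      # a strongly skewed target
  x <- simulate_lengths(1e4, st, seed = 2)
  q <- quantile(x, c(0.5, 0.75), names = FALSE)
  expect_lt(abs(q[1] / st$median - 1), 0.05)
  expect_lt(abs(q[2] / st$p75 - 1), 0.05)
  expect_true(all(x > 0))
  expect_identical(simulate_lengths(1e3, st, seed = 9),
                   simulate_lengths(1e3, st, seed = 9))
  expect_length(simulate_lengths(1, st, seed = 1), 1)
  bad <- st; bad$p25 <- 110
  expect_error(simulate_lengths(10, bad), "infeasible")
})

test_that("net-sample simulation respects the gradient and its limits", {
  tax <- scotia_sea_taxa()
  gradient <- default_sst_gradient(tax$profiles)
  s <- simulate_net_samples(300, gradient, seed = 4)
  fish <- setdiff(names(tax$profiles), "KRI")
  expect_true(all(fish %in% names(s)))
  expect_true(all(as.matrix(s[fish]) >= 0))
  expect_identical(simulate_net_samples(50, gradient, seed = 8),
                   simulate_net_samples(50, gradient, seed = 8))

  # a taxon with zero expected abundance stays zero everywhere
  zero_grad <- function(sst) c(A = 10 * exp(-(sst - 2)^2 / 8), B = 0)
  sz <- simulate_net_samples(200, zero_grad, seed = 5)
  expect_true(all(sz$B == 0))

  # Poisson limit: dispersion Inf gives variance ~ mean
  flat_grad <- function(sst) c(A = 20)
  sp <- simulate_net_samples(4000, flat_grad, dispersion = Inf, seed = 6)
  expect_lt(abs(var(sp$A) / mean(sp$A) - 1), 0.15)
  snb <- simulate_net_samples(4000, flat_grad, dispersion = 2, seed = 6)
  expect_gt(var(snb$A) / mean(snb$A), 5)     # overdispersed

  # estimator recovery: binned means match the gradient within 2 SE
  big <- simulate_net_samples(1400, gradient, sst_range = c(-1, 6),
                              dispersion = 20, seed = 10)
  tab <- group_mean_abundance(big, fish)
  mids <- seq(-0.5, 5.5, by = 1)
  nb <- attr(tab, "n_samples")
  for (b in seq_along(mids)) {
    truth <- gradient(mids[b])
    # bin means average the gradient over the bin, approximated by its
    # midpoint; allow 2 SE plus a 10% midpoint-approximation margin
    se <- sqrt(pmax(truth, 1e-6) / nb[b])
    expect_true(all(abs(tab[b, fish] - truth) < 2 * se + 0.1 * truth + 0.5),
                label = paste("bin", b))
  }
})

test_that("the survey grid simulator is deterministic and self-consistent", {
  w1 <- small_world(seed = 3)
  w2 <- small_world(seed = 3)
  expect_identical(w1$sim, w2$sim)

  g <- w1$sim$grid
  expect_equal(nrow(g), 20 * 20)
  expect_true(all(diff(sort(unique(g$lat))) - 0.25 < 1e-9))
  # forward conservation: NASC equals the backscatter of the truth field
  nasc <- backtransform_nasc(g$log_e_nasc)
  expected <- as.numeric(w1$sim$truth$rho %*% w1$sim$truth$sigma_bs) *
    4 * pi * 1852^2
  expect_equal(nasc, expected, tolerance = 1e-9)
  # SST declines poleward
  fit <- coef(lm(g$sst ~ g$lat))
  expect_gt(fit[2], 0)
  # noise seed honoured
  wn <- small_world(noise_sd = 0.3, seed = 3)
  expect_false(identical(wn$sim$grid$log_e_nasc, g$log_e_nasc))
})
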