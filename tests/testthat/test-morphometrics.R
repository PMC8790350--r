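test_that("length-weight fit recovers exact and noisy power laws", {
  sl <- seq(30, 120, by = 5)
  fit <- fit_length_weight(sl, 1e-5 * sl^3)
  expect_equal(fit$a, 1e-5, tolerance = 1e-9)
  expect_equal(fit$b, 3, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  set.seed(7)
  sl2 <- runif(200, 30, 120)
  w2 <- 2e-6 * sl2^3.2 * exp(rnorm(200, 0, 0.1))
  fit2 <- fit_length_weight(sl2, w2)
  expect_lt(abs(fit2$b - 3.2), 0.05)

  expect_error(fit_length_weight(c(40, 50), c(1, 2)), "at least 3")
  expect_message(
    fit3 <- fit_length_weight(c(sl, 50, -1), c(1e-5 * sl^3, -2, 1)),
    "rejected")
  expect_equal(fit3$n_rejected, 2)
  expect_warning(fit_length_weight(sl, 5 * sl^0.5), "outside plausible")
})

test_that("weight at length follows the power law", {
  fit <- list(a = 1e-5, b = 3)
  expect_equal(weight_at_length(fit, 50), 1.25)
  expect_equal(weight_at_length(list(a = 2, b = 0), c(10, 200)), c(2, 2))
  w <- weight_at_length(fit, c(40, 60, 90))
  expect_true(all(diff(w) > 0))
  expect_error(weight_at_length(fit, -5))
})

test_that("length percentiles use the documented interpolation convention", {
  st <- length_percentiles(c(40, 44, 45, 50))
  # frozen from the linear-interpolation (type 7) definition:
  # h = (n-1)p + 1 over the sorted sample
  expect_equal(st$p25, 43)
  expect_equal(st$median, 44.5)
  expect_equal(st$p75, 46.25)
  expect_equal(st$mean, 44.75)
  expect_equal(st$n, 4L)

  same <- length_percentiles(rep(62, 9))
  expect_equal(c(same$p25, same$mean, same$median, same$p75), rep(62, 4))

  set.seed(3)
  x <- rlnorm(101, log(60), 0.2)
  a <- length_percentiles(x)
  b <- length_percentiles(sample(x))
  expect_equal(a, b)
  expect_error(length_percentiles(numeric(0)))
})

test_that("tissue density assignment honours measurements and group means", {
  measured <- c(ELC = 1061.44, KRA = 1038.39, PRM = 1061.67,
                GYR = 1028.94, GYF = 1064.14, BAX = 1037.05)
  membership <- c(ELC = TRUE, KRA = TRUE, PRM = TRUE,
                  GYR = FALSE, GYF = FALSE, BAX = FALSE)
  pre <- assign_tissue_density("PRE", measured, TRUE, membership)
  expect_equal(pre$tissue_density, 1053.83, tolerance = 1e-5)
  expect_equal(pre$provenance, "group_mean")
  gyn <- assign_tissue_density("GYN", measured, FALSE, membership)
  expect_equal(gyn$tissue_density, 1043.38, tolerance = 1e-5)
  # measured taxa pass through unchanged (idempotence)
  kra <- assign_tissue_density("KRA", measured, TRUE, membership)
  expect_equal(kra$tissue_density, 1038.39)
  expect_equal(kra$provenance, "measured")
  expect_error(assign_tissue_density("X", c(A = 1030), TRUE, c(A = FALSE)),
               "no measured taxa")
})

test_that("E. antarctica size split partitions lengths at 51.378 mm", {
  expect_equal(electrona_class(46), "gas_small")
  expect_equal(electrona_class(74), "nongas_large")
  expect_equal(electrona_class(51.378), "nongas_large")  # inclusive boundary
  sl <- seq(1, 160, by = 0.377)
  cls <- electrona_class(sl)
  expect_true(all(cls %in% c("gas_small", "nongas_large")))
  expect_true(all((cls == "gas_small") == (sl < 51.378)))
  expect_error(electrona_class(0))
})
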