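test_that("proportional response fits exactly on model data", {
  # single point: density 50 at 1:20 extrapolates to k = 1000
  expect_equal(fit_proportional_response(
    data.frame(dilution_factor = 20, density = 50)), 1000)
  grid <- c(10, 20, 40, 100)
  series <- data.frame(dilution_factor = grid, density = 1000 / grid)
  expect_equal(fit_proportional_response(series), 1000)
  expect_error(fit_proportional_response(
    data.frame(dilution_factor = grid, density = 0)), "all densities are zero")
})

test_that("log-median fit matches a brute-force L1 minimiser under noise", {
  set.seed(21)
  grid <- rep(c(10, 20, 40, 100), 3)
  sdlog <- sqrt(log1p(0.1^2))
  dens <- 1000 / grid * rlnorm(12, -sdlog^2 / 2, sdlog)
  series <- data.frame(dilution_factor = grid, density = dens)
  k_hat <- fit_proportional_response(series)
  # oracle: dense grid scan minimising summed |log residuals|; with an even
  # number of points the L1 minimiser is an interval, so compare losses
  loss <- function(k) sum(abs(log(dens) - log(k / grid)))
  cand <- exp(seq(log(400), log(2500), length.out = 40001))
  grid_min <- min(vapply(cand, loss, numeric(1)))
  expect_lte(loss(k_hat), grid_min + 1e-8)
  expect_lt(abs(k_hat - 1000) / 1000, 0.10)
})

test_that("matching-dilution selection agrees with an exhaustive scan", {
  grid <- c(10, 20, 40, 100)
  series <- data.frame(dilution_factor = grid, density = 1000 / grid)
  # reference exactly at a grid point
  expect_equal(select_matching_dilution(series, 50), 20)
  # reference between two grid points at distances 3 and 7 -> nearer point
  expect_equal(select_matching_dilution(series, 28), 40) # |25-28|=3, |50-28|=22
  # exhaustive-scan oracle over random references
  set.seed(8)
  for (ref in runif(25, 8, 120)) {
    means <- tapply(series$density, series$dilution_factor, mean)
    dev <- abs(as.numeric(means) - ref)
    keep <- which(dev == min(dev))
    oracle <- max(as.numeric(names(means))[keep])
    expect_equal(select_matching_dilution(series, ref), oracle)
  }
})

test_that("selection ties break toward the larger dilution factor", {
  series <- data.frame(dilution_factor = c(10, 20), density = c(60, 40))
  expect_equal(select_matching_dilution(series, 50), 20)
})

test_that("selection is invariant to a common scale factor", {
  set.seed(13)
  grid <- c(10, 20, 40, 100)
  series <- data.frame(dilution_factor = rep(grid, 2),
                       density = 800 / rep(grid, 2) * runif(8, 0.8, 1.2))
  for (s in c(0.01, 1, 250)) {
    scaled <- transform(series, density = density * s)
    expect_equal(select_matching_dilution(scaled, 40 * s),
                 select_matching_dilution(series, 40))
  }
})

test_that("refined dilution is the exact fixed point of the model", {
  expect_equal(propose_refined_dilution(1000, 50), 20)
  expect_equal(propose_refined_dilution(1000, 1000), 1)
  expect_error(propose_refined_dilution(-5, 50), "positive")
  expect_error(propose_refined_dilution(1000, 0), "positive")
  # monotonicity: lower reference signal -> stronger dilution
  expect_gt(propose_refined_dilution(1000, 25), propose_refined_dilution(1000, 50))
})

test_that("noiseless simulator round trip reproduces the reference signal", {
  stds <- grk_standards()
  tag <- grk_antibodies()[[5]]
  sc <- blot_scenario(grk_panel(), grk_antibodies(), stds,
                      n_blots = 1, noise_cv = 0, gain_log_sd = 0, seed = 1)
  cal <- simulate_calibration_study(stds, c(10, 20, 40, 100), tag, sc)
  ref <- mean(cal$density[cal$standard_isoform == "GRK2" &
                            cal$dilution_factor == 20])
  for (iso in c("GRK3", "GRK5", "GRK6")) {
    k <- fit_proportional_response(cal[cal$standard_isoform == iso, ])
    f <- propose_refined_dilution(k, ref)
    s <- stds[[match(iso, vapply(stds, `[[`, "", "standard_isoform"))]]
    s$dilution_factor <- f
    expect_equal(expected_signal(s, tag, 1, sc), ref, tolerance = 1e-9)
  }
})

test_that("standard-set validation applies both gates", {
  # identical signals: trivial pass, zero deviation, p = 1 by convention
  d <- data.frame(isoform = rep(c("GRK2", "GRK3"), each = 3), density = 100)
  r <- validate_standard_set(d)
  expect_true(r$pass)
  expect_equal(r$max_pairwise_rel_dev, 0)
  expect_equal(r$anova_p, 1)

  # means [100, 95, 105, 100]: max pairwise deviation 10/95 = 10.5% <= 15%
  means <- c(GRK2 = 100, GRK3 = 95, GRK5 = 105, GRK6 = 100)
  d <- data.frame(isoform = rep(names(means), each = 2),
                  density = as.vector(rbind(means - 8, means + 8)))
  r <- validate_standard_set(d, reference_isoform = "GRK2")
  expect_equal(r$max_pairwise_rel_dev, 10 / 95, tolerance = 1e-12)
  expect_lt(r$max_pairwise_rel_dev, 0.15)   # the deviation gate passes
  expect_s3_class(r, "validation_report")
  expect_equal(unname(r$mean_rel_dev_from_reference),
               c(0, 0.05, 0.05, 0))
  expect_true(is.data.frame(r$tukey))

  # one standard at twice the others: both gates fail
  d2 <- data.frame(isoform = rep(c("GRK2", "GRK3", "GRK5"), each = 4),
                   density = rep(c(100, 100, 200), each = 4) + rnorm(12, 0, 3))
  r2 <- validate_standard_set(d2)
  expect_false(r2$pass)
  expect_gt(r2$max_pairwise_rel_dev, 0.15)
  expect_lt(r2$anova_p, 0.05)
})

test_that("single-replicate validation skips the ANOVA and flags it", {
  d <- data.frame(isoform = c("GRK2", "GRK3"), density = c(100, 104))
  r <- validate_standard_set(d)
  expect_true(r$anova_skipped)
  expect_true(is.na(r$anova_p))
  expect_true(r$pass)  # deviation gate only
})

test_that("per-blot normalisation removes gain before validation", {
  # same true signals on three blots, exposed at 1x / 3x / 0.4x
  set.seed(33)
  base <- c(GRK2 = 100, GRK3 = 97, GRK5 = 103, GRK6 = 100)
  gains <- c(b1 = 1, b2 = 3, b3 = 0.4)
  d <- do.call(rbind, lapply(names(gains), function(b) {
    data.frame(blot_id = b, isoform = names(base),
               density = gains[[b]] * base * exp(rnorm(4, 0, 0.03)))
  }))
  r <- validate_standard_set(d, reference_isoform = "GRK2")
  expect_true(r$pass)
  expect_lt(r$max_pairwise_rel_dev, 0.10)
  # without normalisation the gain spread dominates the within-group spread
  raw_sd <- tapply(d$density, d$isoform, sd) / tapply(d$density, d$isoform, mean)
  expect_true(all(raw_sd > 0.5))
})

test_that("build_standard_set calibrates a full panel", {
  stds <- grk_standards()
  tag <- grk_antibodies()[[5]]
  sc <- blot_scenario(grk_panel(), grk_antibodies(), stds,
                      n_blots = 3, noise_cv = 0, gain_log_sd = 0.3, seed = 6)
  cal <- normalize_to_reference(
    simulate_calibration_study(stds, c(10, 20, 40, 100), tag, sc), "GRK2", 20)
  series <- split(as.data.frame(cal), cal$standard_isoform)
  ss <- build_standard_set(series, "GRK2", 20)
  expect_s3_class(ss, "standard_set")
  expect_equal(ss$table$selected_dilution[match(c("GRK2", "GRK3", "GRK5", "GRK6"),
                                                ss$table$isoform)],
               c(20, 10, 20, 40))
  # refined dilutions reproduce the reference signal exactly (noiseless)
  expect_equal(ss$table$predicted_density,
               rep(ss$reference_density, 4), tolerance = 1e-9)
})
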