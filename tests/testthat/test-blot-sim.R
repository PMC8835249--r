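test_that("forward model matches hand arithmetic in the linear regime", {
  sc <- toy_scenario()
  # affinity 2, abundances {a: 0.5, b: 0.25}, cross {a: 1, b: 0.33}:
  # 2 * (0.5 + 0.33 * 0.25) = 1.165
  expect_equal(expected_signal(toy_sample(), toy_antibody(), 1, sc), 1.165)
  # gain and dilution scale linearly
  expect_equal(expected_signal(toy_sample(), toy_antibody(), 3, sc), 3 * 1.165)
  expect_equal(expected_signal(toy_sample(dilution = 5), toy_antibody(), 1, sc),
               1.165 / 5)
  # zero abundance, zero background -> zero density
  expect_equal(simulate_signal(toy_sample(0, 0), toy_antibody(), 1, sc), 0)
})

test_that("saturation is bounded by gain * v_max and off by default", {
  sat <- list(v_max = 100, k_half = 1)
  sc <- toy_scenario(saturation = sat)
  huge <- lysate_sample("H", c(a = 1e9))
  expect_equal(expected_signal(huge, toy_antibody(), 2, sc), 200,
               tolerance = 1e-6)
  sc_bg <- toy_scenario(saturation = sat, background = 7)
  expect_equal(expected_signal(huge, toy_antibody(), 2, sc_bg), 207,
               tolerance = 1e-6)
  # linear scenario is unbounded
  expect_gt(expected_signal(huge, toy_antibody(), 1, toy_scenario()), 1e8)
})

test_that("invalid forward-model inputs are rejected", {
  expect_error(expected_signal(toy_sample(), toy_antibody(), -1, toy_scenario()),
               "positive")
  expect_error(lysate_sample("U", c(a = -0.1)), ">= 0")
  expect_error(antibody_model("x", "a", affinity = 0), "positive")
  expect_error(antibody_model("x", "a", 1, cross_reactivity = c(b = -0.2)),
               ">= 0")
})

test_that("dilution series follow 1/factor and the row-count contract", {
  std <- lysate_sample("S", c(a = 10), is_standard = TRUE)
  tag <- antibody_model("anti-tag", "TAG", 100, cross_reactivity = c(a = 1))
  sc <- toy_scenario(n_blots = 1, samples = list(std))
  tab <- simulate_dilution_series(std, c(10, 20, 40, 100), tag, sc)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$density / tab$density[1], c(1, 1 / 2, 1 / 4, 1 / 10))
  expect_true(all(diff(tab$density) < 0))

  sc3 <- toy_scenario(n_blots = 3, noise_cv = 0.2, gain_log_sd = 0.1,
                      samples = list(std), seed = 7)
  t1 <- simulate_dilution_series(std, c(10, 20, 40, 100), tag, sc3)
  t2 <- simulate_dilution_series(std, c(10, 20, 40, 100), tag, sc3)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 12)

  expect_error(simulate_dilution_series(std, numeric(0), tag, sc), "nonempty")
  expect_error(simulate_dilution_series(std, c(20, 10), tag, sc),
               "strictly increasing")
})

test_that("a standard must be a single-isoform lysate", {
  expect_error(lysate_sample("S", c(a = 1, b = 1), is_standard = TRUE),
               "exactly one")
  expect_error(lysate_sample("S", c(a = 0, b = 0), is_standard = TRUE),
               "exactly one")
})

test_that("simulate_study emits one row per blot x antibody x sample", {
  sc <- default_study_scenario(seed = 3)
  st <- simulate_study(sc)
  expect_equal(nrow(st$signals), 5 * 13 * 3)
  expect_equal(dplyr::n_distinct(st$signals$blot_id), 3)
  # bit-reproducible under the same seed
  expect_identical(st$signals, simulate_study(sc)$signals)
  # truth covers unknowns only, in standard-load units
  expect_equal(nrow(st$truth), 9 * 4)
  hek <- st$truth[st$truth$sample_id == "HEK293", ]
  expect_equal(hek$y_true[hek$isoform == "GRK6"] /
                 hek$y_true[hek$isoform == "GRK2"], 0.83)
})

test_that("degenerate noise makes replicate blots identical", {
  sc <- default_study_scenario(seed = 5, noise_cv = 0, gain_log_sd = 0)
  st <- simulate_study(sc)
  w <- tidyr::pivot_wider(st$signals[, c("blot_id", "antibody_id", "sample_id", "density")],
                          names_from = "blot_id", values_from = "density")
  expect_equal(w$blot_1, w$blot_2)
  expect_equal(w$blot_1, w$blot_3)
})

test_that("band noise is lognormal with the stated CV and unit mean", {
  sc <- toy_scenario(noise_cv = 0.1)
  set.seed(99)
  draws <- replicate(10000, simulate_signal(toy_sample(), toy_antibody(), 1, sc))
  ratio <- draws / 1.165
  expect_lt(abs(sd(draws) / mean(draws) - 0.1), 0.01)   # empirical CV within 10%
  expect_lt(abs(mean(ratio) - 1), 0.005)                # unbiased multiplicative
  expect_lt(abs(mean(log(ratio)) + log1p(0.1^2) / 2), 0.005)
})

test_that("only gain x affinity x abundance products are observable", {
  s <- 3.7
  sc1 <- toy_scenario(noise_cv = 0.15, seed = 11)
  sc2 <- toy_scenario(noise_cv = 0.15, seed = 11,
                      antibodies = list(toy_antibody(affinity = 2 / s)),
                      samples = list(toy_sample(0.5 * s, 0.25 * s)))
  st1 <- simulate_study(sc1)
  st2 <- simulate_study(sc2)
  expect_equal(st1$signals$density, st2$signals$density, tolerance = 1e-12)
})

test_that("shared-blot calibration tables cancel gain after normalisation", {
  stds <- grk_standards()
  tag <- grk_antibodies()[[5]]
  sc <- blot_scenario(grk_panel(), grk_antibodies(), stds,
                      n_blots = 3, gain_log_sd = 0.5, noise_cv = 0, seed = 2)
  cal <- simulate_calibration_study(stds, c(10, 20, 40, 100), tag, sc)
  expect_equal(nrow(cal), 4 * 4 * 3)
  norm <- normalize_to_reference(cal, "GRK2", 20)
  # noiseless: normalised densities identical across blots despite gain
  w <- tidyr::pivot_wider(
    norm[, c("blot_id", "standard_isoform", "dilution_factor", "density")],
    names_from = "blot_id", values_from = "density")
  expect_equal(w$blot_1, w$blot_3, tolerance = 1e-12)
})
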