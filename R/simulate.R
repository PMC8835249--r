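# Forward model of a densitometry band:
#   density = gain * saturate(affinity * sum_i cr[i] * abundance[i] / dilution)
#             * lognormal_noise(cv) + background
# The noise multiplies the signal term only; background is noiseless.

saturate <- function(x, saturation) {
  if (is.null(saturation)) x else saturation$v_max * x / (x + saturation$k_half)
}

# Unbiased lognormal factors: sdlog chosen so CV(noise) = cv, meanlog chosen
# so E[noise] = 1 (mean of the multiplicative ratio is 1).
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Noiseless specific signal of one (antibody, sample) band, before gain,
# saturation and background.
specific_load <- function(sample, antibody) {
  cr <- antibody$cross_reactivity
  common <- intersect(names(cr), names(sample$true_abundance))
  antibody$affinity *
    sum(cr[common] * sample$true_abundance[common]) / sample$dilution_factor
}

#' Expected (noiseless) band density
#'
#' Deterministic part of the forward model: per-blot gain times the
#' (optionally saturating) specific signal, plus additive background.
#'
#' @param sample A [lysate_sample()].
#' @param antibody An [antibody_model()].
#' @param blot_gain Positive multiplicative blot gain.
#' @param scenario A [blot_scenario()] (supplies saturation and background).
#' @return Nonnegative expected density.
#' @export
expected_signal <- function(sample, antibody, blot_gain, scenario) {
  stopifnot(inherits(sample, "lysate_sample"), inherits(antibody, "antibody_model"))
  if (!is.finite(blot_gain) || blot_gain <= 0) {
    stop("blot_gain must be a positive finite number", call. = FALSE)
  }
  blot_gain * saturate(specific_load(sample, antibody), scenario$saturation) +
    scenario$background
}

#' Simulate one band density
#'
#' Draws a single band density from the forward model, applying unbiased
#' lognormal multiplicative noise (CV = `scenario$noise_cv`) to the signal
#' term. Uses the current RNG state; call `set.seed()` (or use
#' [simulate_study()]) for reproducibility.
#'
#' @inheritParams expected_signal
#' @return Nonnegative simulated density.
#' @export
simulate_signal <- function(sample, antibody, blot_gain, scenario) {
  expected <- expected_signal(sample, antibody, blot_gain, scenario)
  signal <- expected - scenario$background
  signal * lognormal_noise(1L, scenario$noise_cv) + scenario$background
}

signal_table_row_order <- c("blot_id", "lane", "antibody_id", "sample_id",
                            "sample_role", "standard_isoform",
                            "dilution_factor", "density")

#' Simulate an anti-tag dilution series of one standard
#'
#' Emulates the calibration experiment in which serial dilutions of a tagged
#' single-isoform lysate are blotted and probed with the anti-tag antibody,
#' one series per replicate blot. In the linear, noiseless regime densities
#' are proportional to 1/dilution_factor.
#'
#' @param standard A [lysate_sample()] with `is_standard = TRUE`.
#' @param dilution_grid Strictly increasing dilution factors, all >= 1.
#' @param anti_tag The anti-tag [antibody_model()].
#' @param scenario A [blot_scenario()] supplying `n_blots`, noise and gain
#'   parameters.
#' @param seed Seed (defaults to the scenario's).
#' @return A signal-table tibble with one row per (blot, dilution).
#' @export
simulate_dilution_series <- function(standard, dilution_grid, anti_tag,
                                     scenario, seed = scenario$seed) {
  stopifnot(inherits(standard, "lysate_sample"), standard$is_standard)
  grid <- as.numeric(dilution_grid)
  if (length(grid) == 0) stop("dilution_grid must be nonempty", call. = FALSE)
  if (any(grid < 1) || any(diff(grid) <= 0)) {
    stop("dilution_grid must be strictly increasing factors >= 1", call. = FALSE)
  }
  set.seed(seed)
  gains <- exp(stats::rnorm(scenario$n_blots, 0, scenario$gain_log_sd))
  rows <- lapply(seq_len(scenario$n_blots), function(b) {
    dens <- vapply(grid, function(f) {
      s <- standard
      s$dilution_factor <- f
      simulate_signal(s, anti_tag, gains[b], scenario)
    }, numeric(1))
    tibble::tibble(
      blot_id = sprintf("blot_%d", b),
      lane = seq_along(grid),
      antibody_id = anti_tag$antibody_id,
      sample_id = standard$sample_id,
      sample_role = "standard",
      standard_isoform = standard$standard_isoform,
      dilution_factor = grid,
      density = dens
    )
  })
  dplyr::bind_rows(rows)
}

#' Simulate a full multi-blot study
#'
#' Generates the complete densitometry table of a study in which every blot
#' carries every sample (standards and unknowns) and is probed with every
#' antibody, as required for within-blot normalisation. Returns the table
#' together with the ground truth, expressed in units where each standard
#' loads exactly one molar unit of its target isoform (i.e. the true value
#' of the relative abundance y that the pipeline should recover).
#'
#' @param scenario A [blot_scenario()].
#' @return A list with elements `signals` (signal-table tibble, one row per
#'   blot x antibody x sample), `truth` (tibble `sample_id`, `isoform`,
#'   `y_true`, unknowns only) and `gains` (the per-blot gain factors drawn).
#' @export
simulate_study <- function(scenario) {
  stopifnot(inherits(scenario, "blot_scenario"))
  iso <- scenario$panel$isoform_ids
  abs_ <- scenario$antibodies
  sam <- scenario$samples
  # tolerate scenarios whose lists were rebuilt without names
  names(abs_) <- vapply(abs_, `[[`, "", "antibody_id")
  names(sam) <- vapply(sam, `[[`, "", "sample_id")

  # noiseless specific load matrix, antibodies x samples
  M <- vapply(sam, function(s) {
    vapply(abs_, function(a) specific_load(s, a), numeric(1))
  }, numeric(length(abs_)))
  M <- matrix(M, nrow = length(abs_),
              dimnames = list(names(abs_), names(sam)))

  set.seed(scenario$seed)
  gains <- exp(stats::rnorm(scenario$n_blots, 0, scenario$gain_log_sd))

  sample_meta <- tibble::tibble(
    sample_id = names(sam),
    lane = seq_along(sam),
    sample_role = ifelse(vapply(sam, `[[`, TRUE, "is_standard"),
                         "standard", "unknown"),
    standard_isoform = vapply(sam, `[[`, "", "standard_isoform"),
    dilution_factor = vapply(sam, `[[`, 1, "dilution_factor")
  )

  blots <- lapply(seq_len(scenario$n_blots), function(b) {
    expected <- gains[b] * saturate(M, scenario$saturation)
    noise <- matrix(lognormal_noise(length(M), scenario$noise_cv),
                    nrow = nrow(M))
    dens <- expected * noise + scenario$background
    tibble::tibble(
      blot_id = sprintf("blot_%d", b),
      antibody_id = rep(rownames(M), times = ncol(M)),
      sample_id = rep(colnames(M), each = nrow(M)),
      density = as.vector(dens)
    )
  })
  signals <- dplyr::bind_rows(blots) |>
    dplyr::left_join(sample_meta, by = "sample_id") |>
    dplyr::select(dplyr::all_of(signal_table_row_order))

  # ground truth: one molar unit == the amount the isoform's standard loads
  std <- sam[vapply(sam, `[[`, TRUE, "is_standard")]
  std_load <- vapply(std, function(s) {
    s$true_abundance[s$standard_isoform] / s$dilution_factor
  }, numeric(1))
  names(std_load) <- vapply(std, `[[`, "", "standard_isoform")
  missing_std <- setdiff(iso, names(std_load))
  unknowns <- sam[!vapply(sam, `[[`, TRUE, "is_standard")]
  truth <- dplyr::bind_rows(lapply(unknowns, function(s) {
    tibble::tibble(
      sample_id = s$sample_id,
      isoform = iso,
      y_true = ifelse(iso %in% missing_std, NA_real_,
                      unname(ifelse(iso %in% names(s$true_abundance),
                                    s$true_abundance[iso], 0) /
                               s$dilution_factor / std_load[iso]))
    )
  }))

  list(signals = signals, truth = truth, gains = gains)
}

#' Simulate a shared-blot calibration study
#'
#' Emulates the calibration experiment in which the dilution series of
#' *all* tagged standards are run side by side on the same replicate blots
#' and probed with the anti-tag antibody. Because the series share each
#' blot's gain, normalising every blot to its own reference lane removes
#' the between-blot exposure differences before dilutions are compared.
#'
#' @param standards List of standard [lysate_sample()]s (one per isoform).
#' @param dilution_grid Strictly increasing dilution factors >= 1.
#' @param anti_tag The anti-tag [antibody_model()].
#' @param scenario A [blot_scenario()] supplying `n_blots`, noise and gain.
#' @param seed Seed (defaults to the scenario's).
#' @return Signal-table tibble with one row per (blot, standard, dilution).
#' @export
simulate_calibration_study <- function(standards, dilution_grid, anti_tag,
                                       scenario, seed = scenario$seed) {
  stopifnot(all(vapply(standards, inherits, TRUE, "lysate_sample")),
            all(vapply(standards, `[[`, TRUE, "is_standard")))
  grid <- as.numeric(dilution_grid)
  if (length(grid) == 0) stop("dilution_grid must be nonempty", call. = FALSE)
  if (any(grid < 1) || any(diff(grid) <= 0)) {
    stop("dilution_grid must be strictly increasing factors >= 1", call. = FALSE)
  }
  set.seed(seed)
  gains <- exp(stats::rnorm(scenario$n_blots, 0, scenario$gain_log_sd))
  rows <- list()
  for (b in seq_len(scenario$n_blots)) {
    lane <- 0L
    for (s in standards) {
      for (f in grid) {
        lane <- lane + 1L
        s2 <- s
        s2$dilution_factor <- f
        rows[[length(rows) + 1L]] <- tibble::tibble(
          blot_id = sprintf("blot_%d", b),
          lane = lane,
          antibody_id = anti_tag$antibody_id,
          sample_id = s$sample_id,
          sample_role = "standard",
          standard_isoform = s$standard_isoform,
          dilution_factor = f,
          density = simulate_signal(s2, anti_tag, gains[b], scenario)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Normalise a calibration table to a per-blot reference lane
#'
#' Divides every density by the same blot's mean density of the reference
#' isoform at the reference dilution, so that pooled dilution series are
#' free of between-blot gain. The reference lane itself maps to 1.
#'
#' @param calibration Table from [simulate_calibration_study()] (or a real
#'   table with the same columns).
#' @param reference_isoform,reference_dilution The reference lane.
#' @return The table with `density` rescaled per blot.
#' @export
normalize_to_reference <- function(calibration, reference_isoform,
                                   reference_dilution) {
  d <- tibble::as_tibble(calibration)
  ref <- d |>
    dplyr::filter(.data$standard_isoform == reference_isoform,
                  .data$dilution_factor == reference_dilution) |>
    dplyr::group_by(.data$blot_id) |>
    dplyr::summarise(ref_density = mean(.data$density), .groups = "drop")
  if (nrow(ref) == 0 || any(ref$ref_density <= 0)) {
    stop("reference lane absent or zero on some blot", call. = FALSE)
  }
  missing <- setdiff(unique(d$blot_id), ref$blot_id)
  if (length(missing) > 0) {
    stop("reference lane missing on blot ", missing[1], call. = FALSE)
  }
  d |>
    dplyr::inner_join(ref, by = "blot_id") |>
    dplyr::mutate(density = .data$density / .data$ref_density) |>
    dplyr::select(-"ref_density")
}
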