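# File formats: the signal-table CSV schema shared by simulator,
# calibration and quantification; the TSV report; YAML configs.

SIGNAL_TABLE_HEADER <- c("blot_id", "lane", "antibody_id", "sample_id",
                         "sample_role", "standard_isoform",
                         "dilution_factor", "density")

#' Validate a signal table
#'
#' Enforces the table contract: required columns, nonnegative finite
#' densities, `sample_role` in {standard, unknown}, `standard_isoform`
#' present exactly for standards, and uniqueness of (blot, lane, antibody).
#'
#' @param signals Data frame.
#' @return The table as a tibble with normalised types.
#' @export
validate_signal_table <- function(signals) {
  d <- tibble::as_tibble(signals)
  missing <- setdiff(SIGNAL_TABLE_HEADER, names(d))
  if (length(missing) > 0) {
    stop("signal table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  d$density <- as.numeric(d$density)
  d$dilution_factor <- as.numeric(d$dilution_factor)
  if (any(!is.finite(d$density)) || any(d$density < 0)) {
    stop("density must be finite and >= 0", call. = FALSE)
  }
  if (!all(d$sample_role %in% c("standard", "unknown"))) {
    stop("sample_role must be 'standard' or 'unknown'", call. = FALSE)
  }
  si <- ifelse(is.na(d$standard_isoform), "", as.character(d$standard_isoform))
  if (any(d$sample_role == "standard" & !nzchar(si))) {
    stop("standard rows must carry standard_isoform", call. = FALSE)
  }
  if (any(d$sample_role == "unknown" & nzchar(si))) {
    stop("unknown rows must have empty standard_isoform", call. = FALSE)
  }
  d$standard_isoform <- ifelse(nzchar(si), si, NA_character_)
  key <- paste(d$blot_id, d$lane, d$antibody_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (blot_id, lane, antibody_id) key at row ",
         which(duplicated(key))[1], call. = FALSE)
  }
  d
}

#' Read a signal table from CSV
#'
#' The header must match the schema byte-for-byte:
#' `blot_id,lane,antibody_id,sample_id,sample_role,standard_isoform,dilution_factor,density`.
#' Malformed rows are reported with their file line number.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_signal_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (!identical(header, paste(SIGNAL_TABLE_HEADER, collapse = ","))) {
    stop("bad signal-table header in ", path, call. = FALSE)
  }
  d <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (nrow(d) == 0) {
    return(tibble::tibble(
      blot_id = character(), lane = integer(), antibody_id = character(),
      sample_id = character(), sample_role = character(),
      standard_isoform = character(), dilution_factor = numeric(),
      density = numeric()
    ))
  }
  num <- function(col, min_ok) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) | v < min_ok)
    if (length(bad) > 0) {
      stop(sprintf("malformed %s at line %d of %s", col, bad[1] + 1L, path),
           call. = FALSE)
    }
    v
  }
  d$density <- num("density", 0)
  d$dilution_factor <- num("dilution_factor", 0)
  d$lane <- as.integer(num("lane", 1))
  bad_role <- which(!d$sample_role %in% c("standard", "unknown"))
  if (length(bad_role) > 0) {
    stop(sprintf("invalid sample_role at line %d of %s", bad_role[1] + 1L, path),
         call. = FALSE)
  }
  key <- paste(d$blot_id, d$lane, d$antibody_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop(sprintf("duplicate (blot_id, lane, antibody_id) at line %d of %s",
                 dup[1] + 1L, path), call. = FALSE)
  }
  validate_signal_table(d)
}

#' Write a signal table to CSV
#'
#' Writes the exact schema header; `standard_isoform` is empty for
#' unknowns. Two writes of the same table are byte-identical.
#'
#' @param signals Signal table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(signals, path) {
  d <- validate_signal_table(signals)
  d$standard_isoform <- ifelse(is.na(d$standard_isoform), "", d$standard_isoform)
  d <- as.data.frame(d)[, SIGNAL_TABLE_HEADER]
  utils::write.table(d, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Write the abundance report as TSV
#'
#' Columns: sample_id, isoform, y_uncorrected_mean, y_corrected_mean, sd,
#' n_blots, negative_flag. Rows are ordered by sample then isoform
#' (lexicographic) and floats are printed with 6 significant digits, so two
#' runs on the same inputs produce byte-identical files.
#'
#' @param result A `starpa_result` or its `estimates` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  est <- if (inherits(result, "starpa_result")) result$estimates else
    tibble::as_tibble(result)
  if (nrow(est) == 0) stop("empty report", call. = FALSE)
  est <- dplyr::arrange(est, .data$sample_id, .data$isoform)
  fmt <- function(x) {
    ifelse(is.na(x), "NA", vapply(signif(x, 6), format, "", scientific = FALSE))
  }
  out <- data.frame(
    sample_id = est$sample_id,
    isoform = est$isoform,
    y_uncorrected_mean = fmt(est$y_uncorrected_mean),
    y_corrected_mean = fmt(est$y_corrected_mean),
    sd = fmt(est$sd),
    n_blots = est$n_blots,
    negative_flag = est$negative_flag
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
  invisible(path)
}

# ---- configuration ---------------------------------------------------------

scenario_config_keys <- c("isoforms", "antibodies", "samples", "n_blots",
                          "gain_log_sd", "noise_cv", "saturation",
                          "background", "seed")

#' Read a simulation scenario from a YAML config
#'
#' Recognised top-level keys: `isoforms` (map isoform -> molecular weight in
#' kDa, or a plain list of names), `antibodies` (map antibody -> `target`,
#' `affinity`, optional `cross_reactivity` map), `samples` (map sample ->
#' `abundance` map, optional `is_standard`, `dilution_factor`), `n_blots`,
#' `gain_log_sd`, `noise_cv`, `saturation` (`v_max`, `k_half`),
#' `background`, `seed`. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A [blot_scenario()].
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), scenario_config_keys)
  if (length(unknown) > 0) {
    stop("unknown scenario config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  iso <- cfg$isoforms
  panel <- if (is.null(names(iso))) {
    isoform_panel(unlist(iso))
  } else {
    isoform_panel(names(iso), molecular_weight_kda = unlist(iso))
  }
  antibodies <- lapply(names(cfg$antibodies), function(id) {
    a <- cfg$antibodies[[id]]
    antibody_model(id, a$target, a$affinity,
                   cross_reactivity = unlist(a$cross_reactivity))
  })
  samples <- lapply(names(cfg$samples), function(id) {
    s <- cfg$samples[[id]]
    lysate_sample(id, unlist(s$abundance),
                  is_standard = isTRUE(s$is_standard),
                  dilution_factor = s$dilution_factor %||% 1)
  })
  blot_scenario(panel, antibodies, samples,
                n_blots = cfg$n_blots %||% 3,
                gain_log_sd = cfg$gain_log_sd %||% 0,
                noise_cv = cfg$noise_cv %||% 0,
                saturation = cfg$saturation,
                background = cfg$background %||% 0,
                seed = cfg$seed %||% 1L)
}

run_config_keys <- c("signals", "report", "antibody_targets",
                     "detect_threshold", "cv_tolerance", "alpha",
                     "background_subtraction", "solver_mode", "seed")

#' Read a quantification run config (paths + options) from YAML
#'
#' Recognised keys: `signals` and `report` (paths), `antibody_targets`
#' (map antibody -> isoform), `detect_threshold`, `cv_tolerance`, `alpha`,
#' `background_subtraction` (numeric level, 0 = off), `solver_mode`
#' (`sequential` or `solver`), `seed`. Unknown keys are rejected and
#' thresholds are range-checked.
#'
#' @param path YAML file path.
#' @return Named list of validated options.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown) > 0) {
    stop("unknown run config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg$detect_threshold <- cfg$detect_threshold %||% 0.05
  cfg$cv_tolerance <- cfg$cv_tolerance %||% 0.15
  cfg$alpha <- cfg$alpha %||% 0.05
  cfg$background_subtraction <- cfg$background_subtraction %||% 0
  cfg$solver_mode <- cfg$solver_mode %||% "sequential"
  if (cfg$detect_threshold < 0 || cfg$detect_threshold >= 1) {
    stop("detect_threshold must be in [0, 1)", call. = FALSE)
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (cfg$cv_tolerance <= 0) stop("cv_tolerance must be > 0", call. = FALSE)
  if (cfg$background_subtraction < 0) {
    stop("background_subtraction must be >= 0", call. = FALSE)
  }
  if (!cfg$solver_mode %in% c("sequential", "solver")) {
    stop("solver_mode must be 'sequential' or 'solver'", call. = FALSE)
  }
  cfg$antibody_targets <- unlist(cfg$antibody_targets)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
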