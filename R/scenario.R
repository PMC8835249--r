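#' Define an isoform panel
#'
#' The panel lists the protein isoforms quantified by the pipeline, e.g. the
#' four ubiquitously expressed G protein-coupled receptor kinases (GRK2, GRK3,
#' GRK5, GRK6). Molecular weights are cosmetic metadata used only for display
#' and for positioning bands in rendered blot images.
#'
#' @param isoform_ids Character vector of unique, non-empty isoform names.
#' @param molecular_weight_kda Optional positive numeric vector of apparent
#'   molecular weights in kDa, one per isoform.
#' @return An object of class `isoform_panel`.
#' @examples
#' isoform_panel(c("GRK2", "GRK3", "GRK5", "GRK6"),
#'               molecular_weight_kda = c(80, 80, 68, 66))
#' @export
isoform_panel <- function(isoform_ids, molecular_weight_kda = NULL) {
  isoform_ids <- as.character(isoform_ids)
  if (length(isoform_ids) == 0 || anyNA(isoform_ids) || any(!nzchar(isoform_ids))) {
    stop("isoform_ids must be non-empty strings", call. = FALSE)
  }
  if (anyDuplicated(isoform_ids)) {
    stop("isoform_ids must be unique", call. = FALSE)
  }
  if (is.null(molecular_weight_kda)) {
    molecular_weight_kda <- rep(NA_real_, length(isoform_ids))
  } else {
    molecular_weight_kda <- as.numeric(molecular_weight_kda)
    if (length(molecular_weight_kda) != length(isoform_ids) ||
        any(!is.na(molecular_weight_kda) & molecular_weight_kda <= 0)) {
      stop("molecular_weight_kda must be positive, one value per isoform",
           call. = FALSE)
    }
  }
  structure(
    list(isoform_ids = isoform_ids,
         molecular_weight_kda = stats::setNames(molecular_weight_kda, isoform_ids)),
    class = "isoform_panel"
  )
}

#' Define an antibody model
#'
#' An antibody is characterised by its target isoform, an affinity (signal
#' produced per unit molar abundance of the target, in arbitrary densitometry
#' units) and a cross-reactivity map giving, for each isoform, the fraction of
#' the target affinity with which the antibody also binds that isoform. The
#' target always maps to 1 by definition. An anti-tag antibody (target
#' `"TAG"` by convention) binds all tagged standards equally: one tag epitope
#' per molecule makes its signal a molar readout.
#'
#' @param antibody_id Antibody name.
#' @param target_isoform Isoform (or tag) the antibody is raised against.
#' @param affinity Positive signal-per-unit-abundance for the target.
#' @param cross_reactivity Named numeric vector of off-target binding
#'   fractions (>= 0); isoforms not named are assumed 0. The target entry is
#'   forced to 1.
#' @return An object of class `antibody_model`.
#' @examples
#' antibody_model("anti-GRK2", "GRK2", affinity = 500,
#'                cross_reactivity = c(GRK3 = 0.33))
#' @export
antibody_model <- function(antibody_id, target_isoform, affinity,
                           cross_reactivity = NULL) {
  stopifnot(is.character(antibody_id), length(antibody_id) == 1L, nzchar(antibody_id))
  stopifnot(is.character(target_isoform), length(target_isoform) == 1L)
  affinity <- as.numeric(affinity)
  if (!is.finite(affinity) || affinity <= 0) {
    stop("affinity must be a positive finite number", call. = FALSE)
  }
  cr <- c()
  if (!is.null(cross_reactivity)) {
    cr <- as.numeric(cross_reactivity)
    names(cr) <- names(cross_reactivity)
    if (is.null(names(cr)) || any(!nzchar(names(cr)))) {
      stop("cross_reactivity must be a named vector (isoform -> fraction)",
           call. = FALSE)
    }
    if (any(!is.finite(cr)) || any(cr < 0)) {
      stop("cross_reactivity fractions must be finite and >= 0", call. = FALSE)
    }
  }
  cr[target_isoform] <- 1
  structure(
    list(antibody_id = antibody_id,
         target_isoform = target_isoform,
         affinity = affinity,
         cross_reactivity = cr),
    class = "antibody_model"
  )
}

#' Define a lysate sample
#'
#' A sample carries the (simulator ground-truth) molar abundance of every
#' isoform, in arbitrary molar units. Standards are lysates of a single
#' tagged isoform (e.g. overexpressed in a quadruple-knockout background, so
#' no untagged protein is present) and are loaded at a dilution chosen during
#' calibration; unknowns are loaded undiluted by default.
#'
#' @param sample_id Sample name.
#' @param true_abundance Named numeric vector, isoform -> relative molar
#'   amount (>= 0).
#' @param is_standard Logical; `TRUE` for a tagged single-isoform standard.
#' @param standard_isoform For standards, the single isoform present;
#'   defaults to the unique isoform with nonzero abundance.
#' @param dilution_factor Dilution factor >= 1 (1 = undiluted).
#' @return An object of class `lysate_sample`.
#' @export
lysate_sample <- function(sample_id, true_abundance, is_standard = FALSE,
                          standard_isoform = NULL, dilution_factor = 1) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L, nzchar(sample_id))
  ab <- as.numeric(true_abundance)
  names(ab) <- names(true_abundance)
  if (is.null(names(ab)) || any(!nzchar(names(ab)))) {
    stop("true_abundance must be a named vector (isoform -> amount)", call. = FALSE)
  }
  if (any(!is.finite(ab)) || any(ab < 0)) {
    stop("true_abundance must be finite and >= 0", call. = FALSE)
  }
  dilution_factor <- as.numeric(dilution_factor)
  if (!is.finite(dilution_factor) || dilution_factor < 1) {
    stop("dilution_factor must be >= 1", call. = FALSE)
  }
  if (isTRUE(is_standard)) {
    nz <- names(ab)[ab > 0]
    if (length(nz) != 1L) {
      stop("a standard must contain exactly one isoform with nonzero abundance",
           call. = FALSE)
    }
    if (is.null(standard_isoform)) standard_isoform <- nz
    if (!identical(standard_isoform, nz)) {
      stop("standard_isoform does not match the nonzero isoform", call. = FALSE)
    }
  } else {
    standard_isoform <- NA_character_
  }
  structure(
    list(sample_id = sample_id,
         true_abundance = ab,
         is_standard = isTRUE(is_standard),
         standard_isoform = standard_isoform,
         dilution_factor = dilution_factor),
    class = "lysate_sample"
  )
}

#' Define a blot simulation scenario
#'
#' Bundles the panel, antibody models, samples and the measurement-error
#' model of a simulated multi-blot study. Each blot receives a single
#' multiplicative gain factor `exp(N(0, gain_log_sd^2))` shared by all its
#' lanes (emulating exposure/developing-time differences between blots);
#' each band additionally receives unbiased lognormal multiplicative noise
#' with coefficient of variation `noise_cv`. Saturation, when enabled, maps
#' the noiseless signal x to `v_max * x / (x + k_half)` (bounded, monotone);
#' by default the response is linear. `background` is an additive, noiseless
#' floor added after the signal term.
#'
#' @param panel An [isoform_panel()].
#' @param antibodies List of [antibody_model()] objects (typically one per
#'   isoform plus one anti-tag antibody).
#' @param samples List of [lysate_sample()] objects (standards and unknowns).
#' @param n_blots Number of replicate blots (>= 1).
#' @param gain_log_sd SD of the per-blot log-gain (>= 0; 0 = identical blots).
#' @param noise_cv Per-band lognormal coefficient of variation (>= 0).
#' @param saturation `NULL` for a linear response, or `list(v_max=, k_half=)`.
#' @param background Additive noiseless background (>= 0).
#' @param seed Integer master seed for the simulation.
#' @return An object of class `blot_scenario`.
#' @seealso [simulate_study()], [default_study_scenario()]
#' @export
blot_scenario <- function(panel, antibodies, samples, n_blots = 3,
                          gain_log_sd = 0, noise_cv = 0, saturation = NULL,
                          background = 0, seed = 1L) {
  stopifnot(inherits(panel, "isoform_panel"))
  if (!is.list(antibodies) || !all(vapply(antibodies, inherits, TRUE, "antibody_model"))) {
    stop("antibodies must be a list of antibody_model objects", call. = FALSE)
  }
  if (!is.list(samples) || !all(vapply(samples, inherits, TRUE, "lysate_sample"))) {
    stop("samples must be a list of lysate_sample objects", call. = FALSE)
  }
  ab_ids <- vapply(antibodies, `[[`, "", "antibody_id")
  if (anyDuplicated(ab_ids)) stop("duplicate antibody_id", call. = FALSE)
  s_ids <- vapply(samples, `[[`, "", "sample_id")
  if (anyDuplicated(s_ids)) stop("duplicate sample_id", call. = FALSE)
  n_blots <- as.integer(n_blots)
  if (is.na(n_blots) || n_blots < 1L) stop("n_blots must be >= 1", call. = FALSE)
  for (nm in c("gain_log_sd", "noise_cv", "background")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop(nm, " must be a single nonnegative number", call. = FALSE)
    }
  }
  if (!is.null(saturation)) {
    if (!is.list(saturation) || is.null(saturation$v_max) || is.null(saturation$k_half) ||
        saturation$v_max <= 0 || saturation$k_half <= 0) {
      stop("saturation must be NULL or list(v_max > 0, k_half > 0)", call. = FALSE)
    }
  }
  names(antibodies) <- ab_ids
  names(samples) <- s_ids
  structure(
    list(panel = panel, antibodies = antibodies, samples = samples,
         n_blots = n_blots, gain_log_sd = gain_log_sd, noise_cv = noise_cv,
         saturation = saturation, background = background,
         seed = as.integer(seed)),
    class = "blot_scenario"
  )
}

#' @export
print.blot_scenario <- function(x, ...) {
  cat("<blot_scenario>", length(x$panel$isoform_ids), "isoforms,",
      length(x$antibodies), "antibodies,", length(x$samples), "samples,",
      x$n_blots, "blots\n")
  cat("  noise_cv =", x$noise_cv, " gain_log_sd =", x$gain_log_sd,
      " background =", x$background,
      if (is.null(x$saturation)) " (linear)" else " (saturating)", "\n")
  invisible(x)
}

# ---- bundled GRK study (synthetic emulation of a 9-cell-line panel) --------

#' Default GRK isoform panel
#' @return An [isoform_panel()] with GRK2, GRK3, GRK5, GRK6.
#' @export
grk_panel <- function() {
  isoform_panel(c("GRK2", "GRK3", "GRK5", "GRK6"),
                molecular_weight_kda = c(80, 80, 68, 66))
}

#' Default GRK antibody set
#'
#' Four isoform-specific antibodies plus one anti-tag antibody. The
#' anti-GRK2 antibody cross-reacts with GRK3 (fraction 0.33 of its target
#' signal at equal molar amounts) and the anti-GRK6 antibody with GRK5
#' (fraction 0.75); the anti-GRK3 and anti-GRK5 antibodies are clean. The
#' anti-tag antibody binds every isoform equally (one tag per molecule).
#'
#' @param c_grk2_grk3,c_grk6_grk5 Cross-reactivity fractions of the two
#'   contaminated antibodies.
#' @return Named list of [antibody_model()] objects.
#' @export
grk_antibodies <- function(c_grk2_grk3 = 0.33, c_grk6_grk5 = 0.75) {
  iso <- c("GRK2", "GRK3", "GRK5", "GRK6")
  tag_cr <- stats::setNames(rep(1, length(iso)), iso)
  list(
    antibody_model("anti-GRK2", "GRK2", affinity = 500,
                   cross_reactivity = c(GRK3 = c_grk2_grk3)),
    antibody_model("anti-GRK3", "GRK3", affinity = 420),
    antibody_model("anti-GRK5", "GRK5", affinity = 310),
    antibody_model("anti-GRK6", "GRK6", affinity = 460,
                   cross_reactivity = c(GRK5 = c_grk6_grk5)),
    antibody_model("anti-HA", "TAG", affinity = 350,
                   cross_reactivity = tag_cr)
  )
}

#' Default tagged standards
#'
#' One single-isoform tagged standard per GRK, with stock concentrations and
#' calibrated dilutions (GRK2 1:20 reference; GRK3 1:10, GRK5 1:20,
#' GRK6 1:40) such that every standard loads one molar unit of its isoform.
#'
#' @return Named list of [lysate_sample()] objects.
#' @export
grk_standards <- function() {
  mk <- function(iso, stock, dil) {
    lysate_sample(paste0("HA-", iso),
                  stats::setNames(stock, iso),
                  is_standard = TRUE, dilution_factor = dil)
  }
  list(mk("GRK2", 20, 20), mk("GRK3", 10, 10),
       mk("GRK5", 20, 20), mk("GRK6", 40, 40))
}

#' Synthetic ground-truth abundance profile of nine cell lines
#'
#' Relative molar GRK isoform abundances (units: one unit = the amount of
#' that isoform loaded by its calibrated standard) for nine commonly used
#' human cell lines. The values are synthetic: they were chosen once to echo
#' the qualitative pattern reported for such panels (GRK2 most abundant
#' everywhere, GRK6 second in most lines with a GRK6/GRK2 ratio ranging from
#' 0.18 to 0.83, sizeable GRK3 in Jurkat) and serve as simulator ground
#' truth, not as measured data.
#'
#' @return A tibble with columns `sample_id`, `isoform`, `abundance`.
#' @export
grk_cell_line_truth <- function() {
  lines <- c("HEK293", "HeLa", "HepG2", "Jurkat", "K562",
             "MCF-7", "Molm-13", "U2OS", "U-251MG")
  m <- rbind(
    GRK2 = c(1.00, 0.90, 0.80, 1.10, 0.95, 0.85, 1.00, 0.90, 1.05),
    GRK3 = c(0.15, 0.10, 0.08, 0.89, 0.40, 0.12, 0.30, 0.15, 0.20),
    GRK5 = c(0.10, 0.12, 0.05, 0.05, 0.08, 0.10, 0.06, 0.20, 0.15),
    GRK6 = c(0.83, 0.27, 0.20, 0.30, 0.50, 0.29, 0.18, 0.25, 0.55)
  )
  colnames(m) <- lines
  tibble::tibble(
    sample_id = rep(lines, each = nrow(m)),
    isoform = rep(rownames(m), times = length(lines)),
    abundance = as.vector(m)
  ) |>
    dplyr::arrange(.data$sample_id, .data$isoform)
}

#' Default simulated STARPA study scenario
#'
#' A ready-made scenario mirroring the bundled study design: 4 GRK isoforms,
#' 5 antibodies (4 isoform-specific, two of them cross-reactive, plus
#' anti-tag), 4 calibrated standards and 9 unknown cell-line lysates on each
#' of `n_blots` replicate blots.
#'
#' @param seed Master seed.
#' @param n_blots Number of replicate blots (default 3, as in a typical
#'   triplicate design).
#' @param noise_cv Per-band lognormal CV (default 0.10, a realistic
#'   densitometry repeatability).
#' @param gain_log_sd Per-blot log-gain SD (default 0.2, i.e. roughly
#'   20 percent exposure differences between blots).
#' @param ... Passed on to [blot_scenario()] (e.g. `saturation`,
#'   `background`).
#' @return A `blot_scenario`.
#' @export
default_study_scenario <- function(seed = 1L, n_blots = 3, noise_cv = 0.10,
                                   gain_log_sd = 0.2, ...) {
  truth <- grk_cell_line_truth()
  unknowns <- lapply(split(truth, truth$sample_id), function(d) {
    lysate_sample(d$sample_id[1], stats::setNames(d$abundance, d$isoform))
  })
  blot_scenario(
    panel = grk_panel(),
    antibodies = grk_antibodies(),
    samples = c(grk_standards(), unname(unknowns)),
    n_blots = n_blots, gain_log_sd = gain_log_sd, noise_cv = noise_cv,
    seed = seed, ...
  )
}
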