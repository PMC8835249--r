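# Calibration of tagged single-isoform standards: fit the dilution response,
# pick/refine the dilution factor that matches each standard's anti-tag
# signal to a common reference, and validate the final set.

#' Fit the proportional dilution response of a standard
#'
#' Assumes exact inverse proportionality, density = k / dilution_factor, and
#' estimates the response coefficient k (the extrapolated density of the
#' undiluted lysate) as `exp(median(log(density * dilution_factor)))`. The
#' log-domain median makes the fit robust to occasional outlier bands, which
#' are common in densitometry. Zero-density rows carry no information under
#' this model and are ignored.
#'
#' @param series Data frame with columns `dilution_factor` (>= 1) and
#'   `density` (>= 0); typically pooled over replicate blots.
#' @return The response coefficient k (> 0).
#' @export
fit_proportional_response <- function(series) {
  series <- as.data.frame(series)
  stopifnot(all(c("dilution_factor", "density") %in% names(series)))
  if (nrow(series) == 0) stop("empty dilution series", call. = FALSE)
  if (any(series$density < 0) || any(series$dilution_factor <= 0)) {
    stop("densities must be >= 0 and dilution factors > 0", call. = FALSE)
  }
  pos <- series$density > 0
  if (!any(pos)) {
    stop("unusable series: all densities are zero", call. = FALSE)
  }
  exp(stats::median(log(series$density[pos] * series$dilution_factor[pos])))
}

#' Select the measured dilution whose signal best matches a reference
#'
#' Returns the grid dilution whose mean density is closest (smallest
#' absolute difference) to `reference_density`. Ties are broken toward the
#' larger dilution factor, which consumes less lysate. The selection is
#' invariant to rescaling series and reference by a common factor.
#'
#' @param series Data frame with columns `dilution_factor`, `density`.
#' @param reference_density Positive target density.
#' @return One dilution factor from the measured grid.
#' @export
select_matching_dilution <- function(series, reference_density) {
  series <- as.data.frame(series)
  stopifnot(all(c("dilution_factor", "density") %in% names(series)))
  if (nrow(series) == 0) stop("empty dilution series", call. = FALSE)
  if (!is.finite(reference_density) || reference_density <= 0) {
    stop("reference_density must be positive", call. = FALSE)
  }
  means <- tapply(series$density, series$dilution_factor, mean)
  factors <- as.numeric(names(means))
  dev <- abs(as.numeric(means) - reference_density)
  best <- which(dev == min(dev))
  max(factors[best])
}

#' Propose a refined (continuous) matching dilution
#'
#' Under the proportional model density = k / factor, the factor at which
#' the predicted density equals the reference exactly is k / reference.
#' This mimics preparing a new, finer dilution from the same lysate after
#' the coarse grid pick.
#'
#' @param k Response coefficient from [fit_proportional_response()].
#' @param reference_density Positive target density.
#' @return Continuous dilution factor (> 0).
#' @export
propose_refined_dilution <- function(k, reference_density) {
  if (!is.finite(k) || k <= 0) stop("k must be positive", call. = FALSE)
  if (!is.finite(reference_density) || reference_density <= 0) {
    stop("reference_density must be positive", call. = FALSE)
  }
  k / reference_density
}

#' Validate a calibrated standard set
#'
#' Checks that the matched standards give equal anti-tag signals: the
#' maximum pairwise relative deviation of the per-isoform mean densities
#' must not exceed `cv_tolerance`, and a one-way ANOVA across isoforms must
#' be non-significant at `alpha`. Tukey's post-hoc comparisons are reported
#' descriptively but are not part of the gate. When `blot_id` is present and
#' a `reference_isoform` is given, each blot's signals are first normalised
#' to that blot's own reference signal, removing between-blot gain before
#' pooling.
#'
#' @param anti_tag_signals Data frame with columns `isoform`, `density` and
#'   optionally `blot_id`; at least two isoforms, and at least two
#'   replicates per isoform for the ANOVA branch (with a single replicate
#'   the ANOVA is skipped and flagged).
#' @param reference_isoform Optional isoform used for per-blot normalisation
#'   and as the baseline for per-isoform deviations (defaults to the first).
#' @param cv_tolerance Maximum allowed pairwise relative deviation of
#'   isoform means (default 0.15).
#' @param alpha ANOVA significance level (default 0.05).
#' @return A `validation_report` with the isoform means, deviations, ANOVA
#'   p-value (p = 1 by convention when all signals are identical), Tukey
#'   table and the overall `pass` flag.
#' @export
validate_standard_set <- function(anti_tag_signals, reference_isoform = NULL,
                                  cv_tolerance = 0.15, alpha = 0.05) {
  d <- as.data.frame(anti_tag_signals)
  stopifnot(all(c("isoform", "density") %in% names(d)))
  if (length(unique(d$isoform)) < 2) {
    stop("need at least two isoforms to validate", call. = FALSE)
  }
  if (any(d$density < 0)) stop("densities must be >= 0", call. = FALSE)
  if (is.null(reference_isoform)) reference_isoform <- d$isoform[1]
  if (!reference_isoform %in% d$isoform) {
    stop("reference_isoform not present in signals", call. = FALSE)
  }
  if ("blot_id" %in% names(d)) {
    ref <- tapply(d$density[d$isoform == reference_isoform],
                  d$blot_id[d$isoform == reference_isoform], mean)
    if (!all(d$blot_id %in% names(ref)) || any(ref <= 0)) {
      stop("each blot needs a positive reference-isoform signal", call. = FALSE)
    }
    d$density <- d$density / as.numeric(ref[as.character(d$blot_id)])
  }

  means <- tapply(d$density, d$isoform, mean)
  iso <- names(means)
  m <- as.numeric(means)
  pair_dev <- 0
  for (i in seq_along(m)) {
    for (j in seq_along(m)) {
      if (i < j) {
        pair_dev <- max(pair_dev, abs(m[i] - m[j]) / min(m[i], m[j]))
      }
    }
  }
  dev_from_ref <- abs(m - means[[reference_isoform]]) / means[[reference_isoform]]
  names(dev_from_ref) <- iso

  n_rep <- table(d$isoform)
  anova_skipped <- any(n_rep < 2)
  anova_p <- NA_real_
  tukey <- NULL
  if (!anova_skipped) {
    spread <- diff(range(d$density))
    if (spread <= 1e-9 * max(mean(d$density), .Machine$double.xmin)) {
      anova_p <- 1  # signals identical to float tolerance: nothing to distinguish
    } else {
      fit <- stats::aov(density ~ factor(isoform), data = d)
      tab <- summary(fit)[[1]]
      anova_p <- tab[["Pr(>F)"]][1]
      if (is.na(anova_p)) {
        # zero residual variance with distinct group means
        anova_p <- 0
      } else {
        tukey <- as.data.frame(stats::TukeyHSD(fit)[[1]])
      }
    }
  }
  pass <- pair_dev <= cv_tolerance && (anova_skipped || anova_p > alpha)

  structure(
    list(isoform_means = means,
         mean_rel_dev_from_reference = dev_from_ref,
         max_pairwise_rel_dev = pair_dev,
         anova_p = anova_p, anova_skipped = anova_skipped,
         tukey = tukey, pass = pass,
         reference_isoform = reference_isoform,
         cv_tolerance = cv_tolerance, alpha = alpha),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>", if (x$pass) "PASS" else "FAIL", "\n")
  cat("  max pairwise relative deviation:",
      sprintf("%.3f (tolerance %.3f)", x$max_pairwise_rel_dev, x$cv_tolerance), "\n")
  if (x$anova_skipped) {
    cat("  one-way ANOVA: skipped (single replicate)\n")
  } else {
    cat(sprintf("  one-way ANOVA p = %.4g (alpha %.2f)\n", x$anova_p, x$alpha))
  }
  invisible(x)
}

#' Build a calibrated standard set from dilution series
#'
#' Runs the full calibration for a panel of tagged standards: the reference
#' signal is the mean density of the reference isoform's series at the
#' chosen reference dilution; for every isoform the best-matching grid
#' dilution is selected and, from the fitted proportional response, a
#' refined continuous dilution predicted to reproduce the reference signal
#' exactly is proposed.
#'
#' @param series_list Named list (isoform -> data frame with
#'   `dilution_factor`, `density`, optionally `blot_id`) of anti-tag
#'   dilution series.
#' @param reference_isoform Isoform serving as reference (must be in
#'   `series_list`).
#' @param reference_dilution Grid dilution of the reference isoform that
#'   defines the target signal.
#' @param refine If `TRUE` (default) the chosen dilution is the refined
#'   proposal; otherwise the grid pick.
#' @return A `standard_set` with a per-isoform calibration table and a
#'   `validation` slot (filled by [validate_standard_set()], initially
#'   `NULL`).
#' @export
build_standard_set <- function(series_list, reference_isoform,
                               reference_dilution, refine = TRUE) {
  stopifnot(is.list(series_list), !is.null(names(series_list)))
  if (!reference_isoform %in% names(series_list)) {
    stop("reference_isoform has no dilution series", call. = FALSE)
  }
  ref_series <- as.data.frame(series_list[[reference_isoform]])
  ref_rows <- ref_series$dilution_factor == reference_dilution
  if (!any(ref_rows)) {
    stop("reference_dilution not present in the reference series", call. = FALSE)
  }
  reference_density <- mean(ref_series$density[ref_rows])
  if (reference_density <= 0) {
    stop("reference signal is zero; pick a usable reference dilution", call. = FALSE)
  }
  tab <- dplyr::bind_rows(lapply(names(series_list), function(isoform) {
    s <- series_list[[isoform]]
    k <- fit_proportional_response(s)
    selected <- select_matching_dilution(s, reference_density)
    refined <- propose_refined_dilution(k, reference_density)
    tibble::tibble(
      isoform = isoform,
      k = k,
      selected_dilution = selected,
      refined_dilution = refined,
      chosen_dilution = if (refine) refined else selected,
      predicted_density = k / (if (refine) refined else selected)
    )
  }))
  structure(
    list(table = tab,
         reference_isoform = reference_isoform,
         reference_dilution = reference_dilution,
         reference_density = reference_density,
         refine = refine,
         validation = NULL),
    class = "standard_set"
  )
}

#' @export
print.standard_set <- function(x, ...) {
  cat("<standard_set> reference:", x$reference_isoform,
      sprintf("1:%g (density %.4g)\n", x$reference_dilution, x$reference_density))
  print(as.data.frame(x$table), row.names = FALSE)
  if (!is.null(x$validation)) print(x$validation)
  invisible(x)
}
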