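# The STARPA core: within-blot ratios to the matched standard, the
# cross-reactivity coefficient estimator, the subtraction correction and its
# generalisation to a full linear crosstalk system.

#' Relative abundance of an isoform (standard-normalised ratio)
#'
#' The relative molar amount y of an isoform in an unknown sample is the
#' band density of the sample divided by the band density of that isoform's
#' calibrated standard, both measured with the same antibody on the same
#' blot: y = d_A(U) / d_A(S_a). Because both densities share the blot gain,
#' y is independent of exposure/developing time.
#'
#' @param d_unknown Band density (>= 0) of the unknown sample.
#' @param d_standard Band density (> 0) of the standard on the same blot.
#' @return The dimensionless molar ratio y (vectorised).
#' @examples
#' relative_abundance(415, 500) # 0.83
#' @export
relative_abundance <- function(d_unknown, d_standard) {
  if (any(!is.finite(d_unknown)) || any(d_unknown < 0)) {
    stop("unknown-sample density must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(d_standard)) || any(d_standard <= 0)) {
    stop("unusable standard: standard density must be > 0", call. = FALSE)
  }
  d_unknown / d_standard
}

#' Estimate the antibody cross-reactivity matrix from standard lanes
#'
#' For antibody B with target isoform b, the cross-reactivity coefficient
#' towards isoform a is c_B = d_B(S_a) / d_B(S_b): the signal the antibody
#' produces on the (molar-equalised) standard of a, as a fraction of its
#' signal on its own standard. Coefficients are computed per blot and
#' averaged across blots with their SD. Mean coefficients below
#' `detect_threshold` are treated as non-detectable and set to 0 (the raw
#' mean is retained in `raw`); each antibody's target entry is exactly 1.
#'
#' @param standard_signals Signal-table rows for standard lanes (columns
#'   `blot_id`, `antibody_id`, `standard_isoform`, `density`).
#' @param antibody_targets Named character vector, antibody_id -> target
#'   isoform, for the isoform-specific antibodies (anti-tag antibodies are
#'   simply omitted).
#' @param detect_threshold Detectability cutoff for a mean coefficient
#'   (default 0.05).
#' @return A `cross_reactivity_matrix` with elements `coef` (thresholded
#'   means), `sd`, `raw` (unthresholded means), `per_blot`, `targets`.
#' @export
estimate_cross_reactivity <- function(standard_signals, antibody_targets,
                                      detect_threshold = 0.05) {
  d <- dplyr::filter(tibble::as_tibble(standard_signals),
                     .data$antibody_id %in% names(antibody_targets),
                     !is.na(.data$standard_isoform), nzchar(.data$standard_isoform))
  isoforms <- sort(unique(d$standard_isoform))
  blots <- unique(d$blot_id)
  abs_ <- names(antibody_targets)
  if (!all(antibody_targets %in% isoforms)) {
    missing <- antibody_targets[!antibody_targets %in% isoforms]
    stop("missing standard lane for antibody target(s): ",
         paste(names(missing), "->", missing, collapse = ", "), call. = FALSE)
  }

  per_blot <- array(NA_real_, dim = c(length(abs_), length(isoforms), length(blots)),
                    dimnames = list(abs_, isoforms, blots))
  for (bl in blots) {
    db <- d[d$blot_id == bl, ]
    for (ab in abs_) {
      target <- antibody_targets[[ab]]
      for (a in isoforms) {
        rows <- db$antibody_id == ab & db$standard_isoform == a
        if (!any(rows)) {
          stop(sprintf("missing standard lane: antibody '%s' x standard '%s' on blot '%s'",
                       ab, a, bl), call. = FALSE)
        }
        per_blot[ab, a, bl] <- mean(db$density[rows])
      }
      denom <- per_blot[ab, target, bl]
      if (!is.finite(denom) || denom <= 0) {
        stop(sprintf("unusable standard: antibody '%s' has zero signal on its own standard '%s' (blot '%s')",
                     ab, target, bl), call. = FALSE)
      }
      per_blot[ab, , bl] <- per_blot[ab, , bl] / denom
    }
  }

  raw <- apply(per_blot, c(1, 2), mean)
  sds <- apply(per_blot, c(1, 2), stats::sd)
  coef <- ifelse(raw < detect_threshold, 0, raw)
  for (ab in abs_) coef[ab, antibody_targets[[ab]]] <- 1

  structure(
    list(coef = coef, sd = sds, raw = raw, per_blot = per_blot,
         targets = antibody_targets, detect_threshold = detect_threshold,
         n_blots = length(blots)),
    class = "cross_reactivity_matrix"
  )
}

#' @export
print.cross_reactivity_matrix <- function(x, ...) {
  cat("<cross_reactivity_matrix> mean of", x$n_blots,
      "blot(s), detect_threshold =", x$detect_threshold, "\n")
  print(round(x$coef, 4))
  invisible(x)
}

#' Correct a relative abundance for antibody cross-reactivity
#'
#' When antibody B (target b) also binds isoform a with coefficient c_B,
#' the uncorrected ratio overstates b by the contribution of a:
#' y_b = d_B(U)/d_B(S_b) - y_a * c_B. The amount y_a must itself have been
#' measured with an antibody without detectable cross-reactivity, otherwise
#' the subtraction propagates contamination — use
#' [solve_cross_reactivity_system()] in that case.
#'
#' @param y_b_uncorrected Uncorrected ratio(s) for isoform b (>= 0).
#' @param y_a Relative abundance(s) of the cross-reacting isoform a,
#'   measured with a clean antibody.
#' @param c_b Cross-reactivity coefficient of antibody B towards a (>= 0).
#' @param y_a_contaminated Set `TRUE` if y_a was measured with an antibody
#'   that itself has detectable cross-reactivity; this is an error.
#' @return A list with `y` (point estimate, floored at 0), `y_raw` (the
#'   possibly negative corrected value) and `negative_flag`.
#' @examples
#' correct_abundance(1.00, y_a = 0.89, c_b = 0.33)$y_raw # 0.7063
#' @export
correct_abundance <- function(y_b_uncorrected, y_a, c_b,
                              y_a_contaminated = FALSE) {
  if (isTRUE(y_a_contaminated)) {
    stop(paste("y_a was measured with a cross-reactive antibody;",
               "sequential subtraction is invalid -",
               "use solve_cross_reactivity_system()"), call. = FALSE)
  }
  stopifnot(all(y_b_uncorrected >= 0), all(y_a >= 0), all(c_b >= 0))
  y_raw <- y_b_uncorrected - y_a * c_b
  list(y = pmax(y_raw, 0), y_raw = y_raw, negative_flag = y_raw < 0)
}

#' Solve the full linear cross-reactivity system
#'
#' Generalises the pairwise subtraction to arbitrary crosstalk patterns.
#' With one antibody per isoform, the uncorrected ratio vector v satisfies
#' C y = v, where row B of C holds antibody B's coefficients against every
#' isoform (1 on its target); the corrected abundances are y = C^-1 v.
#'
#' @param C A `cross_reactivity_matrix` or a plain numeric matrix with
#'   antibody rows and isoform columns.
#' @param v Named numeric vector of uncorrected ratios per isoform (names
#'   matching isoforms), or unnamed in column order of C.
#' @param targets Named map antibody -> target isoform (taken from the
#'   matrix object when omitted). Each isoform must have exactly one
#'   antibody; aggregate replicate antibodies upstream.
#' @param max_condition Condition-number threshold above which the system
#'   is declared ill-conditioned (default 1e8).
#' @return Named numeric vector of corrected abundances.
#' @export
solve_cross_reactivity_system <- function(C, v, targets = NULL,
                                          max_condition = 1e8) {
  if (inherits(C, "cross_reactivity_matrix")) {
    if (is.null(targets)) targets <- C$targets
    C <- C$coef
  }
  stopifnot(is.matrix(C))
  if (is.null(targets)) {
    stop("targets (antibody -> isoform map) required for a plain matrix",
         call. = FALSE)
  }
  if (anyDuplicated(targets)) {
    stop("more than one antibody per isoform; aggregate replicate antibodies upstream",
         call. = FALSE)
  }
  isoforms <- colnames(C)
  if (!setequal(unname(targets), isoforms)) {
    stop("antibody targets do not cover the isoform set; system is not square",
         call. = FALSE)
  }
  # reorder antibody rows so row i targets isoform i
  row_for <- stats::setNames(names(targets), unname(targets))
  A <- C[row_for[isoforms], , drop = FALSE]
  if (!is.null(names(v))) v <- v[isoforms]
  if (anyNA(v)) stop("v is missing a value for some isoform", call. = FALSE)
  kappa_est <- kappa(A, exact = TRUE)
  if (!is.finite(kappa_est) || kappa_est > max_condition) {
    stop(sprintf("cross-reactivity system is singular or ill-conditioned (condition number %.3g)",
                 kappa_est), call. = FALSE)
  }
  y <- solve(A, as.numeric(v))
  stats::setNames(as.numeric(y), isoforms)
}

#' Aggregate per-blot estimates into mean and SD
#'
#' Arithmetic mean and sample SD (n - 1 denominator) across replicate
#' blots. With a single blot the SD is reported as `NA` and flagged.
#'
#' @param values Numeric vector of per-blot estimates (length >= 1).
#' @return A list with `mean`, `sd`, `n` and `sd_available`.
#' @export
aggregate_replicates <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("no replicate values to aggregate", call. = FALSE)
  list(mean = mean(values),
       sd = if (length(values) > 1) stats::sd(values) else NA_real_,
       n = length(values),
       sd_available = length(values) > 1)
}
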