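# End-to-end pipeline: per blot, ratios to that blot's own standard lanes;
# cross-reactivity from the same blots' standards; correction (sequential
# subtraction or full linear solve); aggregation across blots.

#' Run the full relative-abundance pipeline on a signal table
#'
#' Per blot, every sample's band density is divided by the density of the
#' matched standard for the same antibody on the same blot (within-blot
#' ratios cancel the blot gain). Cross-reactivity coefficients are
#' estimated from the standard lanes, averaged across blots (or kept per
#' blot), and removed: by default with the sequential subtraction, which
#' requires every contaminating isoform to be quantified by an antibody
#' without detectable cross-reactivity and is applied to those isoforms
#' first; or by solving the full linear crosstalk system. Per-blot
#' corrected ratios are then aggregated (mean, sample SD). Negative
#' corrected means are retained in `y_corrected_raw_mean`, floored to 0 in
#' the headline `y_corrected_mean` and flagged.
#'
#' @param signals Signal table (tibble or CSV-read data frame) satisfying
#'   the layout contract: every blot carrying unknowns also carries every
#'   standard for every antibody used on it.
#' @param antibody_targets Named character vector antibody_id -> target
#'   isoform for the isoform-specific antibodies (anti-tag lanes are used
#'   for calibration only and are ignored here).
#' @param detect_threshold Cross-reactivity detectability cutoff
#'   (default 0.05).
#' @param correction `"sequential"` (default) or `"solver"`.
#' @param cross_reactivity `"pooled"` (default; coefficients averaged
#'   across blots before correction) or `"per_blot"`.
#' @param background Constant additive background subtracted from every
#'   density before any ratio (default 0, i.e. no subtraction).
#' @param include_standards Also report the standards themselves (their own
#'   isoform quantifies to exactly 1; default `FALSE`).
#' @param max_condition Condition-number limit for the solver.
#' @return A `starpa_result` with `estimates` (one row per sample x
#'   isoform), `per_blot` (per-blot ratios) and `cross_reactivity`.
#' @export
run_starpa <- function(signals, antibody_targets,
                       detect_threshold = 0.05,
                       correction = c("sequential", "solver"),
                       cross_reactivity = c("pooled", "per_blot"),
                       background = 0,
                       include_standards = FALSE,
                       max_condition = 1e8) {
  correction <- match.arg(correction)
  cross_reactivity <- match.arg(cross_reactivity)
  signals <- validate_signal_table(signals)
  if (is.null(names(antibody_targets)) || anyDuplicated(names(antibody_targets))) {
    stop("antibody_targets must be uniquely named (antibody -> isoform)",
         call. = FALSE)
  }
  if (anyDuplicated(unname(antibody_targets))) {
    stop("more than one antibody per isoform; aggregate upstream", call. = FALSE)
  }
  if (background > 0) {
    signals$density <- pmax(signals$density - background, 0)
  }

  tbl <- signals |>
    dplyr::filter(.data$antibody_id %in% names(antibody_targets)) |>
    dplyr::mutate(isoform = unname(antibody_targets[.data$antibody_id]))
  if (nrow(tbl) == 0) stop("no rows for any mapped antibody", call. = FALSE)

  std <- tbl |>
    dplyr::filter(.data$sample_role == "standard",
                  .data$standard_isoform == .data$isoform) |>
    dplyr::group_by(.data$blot_id, .data$antibody_id) |>
    dplyr::summarise(d_standard = mean(.data$density), .groups = "drop")
  need <- tidyr::expand_grid(blot_id = unique(tbl$blot_id),
                             antibody_id = names(antibody_targets))
  missing <- dplyr::anti_join(need, std, by = c("blot_id", "antibody_id"))
  if (nrow(missing) > 0) {
    stop(sprintf("missing standard lane for antibody '%s' on blot '%s'",
                 missing$antibody_id[1], missing$blot_id[1]), call. = FALSE)
  }

  crm <- estimate_cross_reactivity(
    dplyr::filter(tbl, .data$sample_role == "standard"),
    antibody_targets, detect_threshold = detect_threshold
  )

  per_blot_unc <- tbl |>
    (\(d) if (include_standards) d else dplyr::filter(d, .data$sample_role == "unknown"))() |>
    dplyr::inner_join(std, by = c("blot_id", "antibody_id")) |>
    dplyr::group_by(.data$blot_id, .data$sample_id, .data$isoform) |>
    dplyr::summarise(
      y_uncorrected = mean(relative_abundance(.data$density, .data$d_standard)),
      .groups = "drop"
    )
  if (nrow(per_blot_unc) == 0) stop("no unknown samples to quantify", call. = FALSE)

  isoforms <- sort(unique(unname(antibody_targets)))
  # pattern check for the sequential route uses the pooled matrix
  A_pooled <- crosstalk_matrix(crm$coef, crm$targets, isoforms)
  if (correction == "sequential") {
    check_sequential_pattern(A_pooled)
  }

  corrected <- per_blot_unc |>
    dplyr::group_by(.data$blot_id) |>
    dplyr::group_modify(function(d, key) {
      Y <- tidyr::pivot_wider(d, names_from = "isoform",
                              values_from = "y_uncorrected")
      Ym <- as.matrix(Y[, isoforms, drop = FALSE])
      A <- if (cross_reactivity == "pooled") A_pooled else {
        pb <- crm$per_blot[, , key$blot_id]
        pb <- ifelse(pb < detect_threshold, 0, pb)
        for (ab in names(crm$targets)) pb[ab, crm$targets[[ab]]] <- 1
        crosstalk_matrix(pb, crm$targets, isoforms)
      }
      Yc <- if (correction == "solver") {
        kappa_est <- kappa(A, exact = TRUE)
        if (!is.finite(kappa_est) || kappa_est > max_condition) {
          stop("cross-reactivity system is singular or ill-conditioned",
               call. = FALSE)
        }
        t(solve(A, t(Ym)))
      } else {
        Ym - Ym %*% t(A - diag(nrow(A)))
      }
      colnames(Yc) <- isoforms
      dplyr::bind_cols(Y["sample_id"], tibble::as_tibble(Yc)) |>
        tidyr::pivot_longer(-"sample_id", names_to = "isoform",
                            values_to = "y_corrected")
    }) |>
    dplyr::ungroup()

  per_blot <- dplyr::left_join(
    per_blot_unc, corrected,
    by = c("blot_id", "sample_id", "isoform")
  )

  estimates <- per_blot |>
    dplyr::group_by(.data$sample_id, .data$isoform) |>
    dplyr::summarise(
      y_uncorrected_mean = mean(.data$y_uncorrected),
      y_corrected_raw_mean = mean(.data$y_corrected),
      sd = ifelse(dplyr::n() > 1, stats::sd(.data$y_corrected), NA_real_),
      n_blots = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      negative_flag = .data$y_corrected_raw_mean < 0,
      y_corrected_mean = pmax(.data$y_corrected_raw_mean, 0)
    ) |>
    dplyr::select("sample_id", "isoform", "y_uncorrected_mean",
                  "y_corrected_mean", "y_corrected_raw_mean", "sd",
                  "n_blots", "negative_flag") |>
    dplyr::arrange(.data$sample_id, .data$isoform)

  structure(
    list(estimates = estimates, per_blot = per_blot, cross_reactivity = crm,
         options = list(detect_threshold = detect_threshold,
                        correction = correction,
                        cross_reactivity = cross_reactivity,
                        background = background)),
    class = "starpa_result"
  )
}

# isoform x isoform crosstalk matrix A: row b = coefficients of the antibody
# targeting isoform b against every isoform (diagonal 1).
crosstalk_matrix <- function(coef, targets, isoforms) {
  row_for <- stats::setNames(names(targets), unname(targets))
  A <- coef[row_for[isoforms], isoforms, drop = FALSE]
  dimnames(A) <- list(isoforms, isoforms)
  A
}

# sequential subtraction is valid only when every contaminating isoform is
# itself measured by a clean antibody (one-level dependency graph)
check_sequential_pattern <- function(A) {
  off <- A - diag(nrow(A))
  for (b in seq_len(nrow(A))) {
    contaminants <- which(off[b, ] > 0)
    bad <- contaminants[rowSums(off[contaminants, , drop = FALSE] > 0) > 0]
    if (length(bad) > 0) {
      stop(sprintf(paste("isoform '%s' contaminates '%s' but is itself measured",
                         "with a cross-reactive antibody; sequential correction",
                         "is invalid - use correction = \"solver\""),
                   rownames(A)[bad[1]], rownames(A)[b]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.starpa_result <- function(x, ...) {
  cat("<starpa_result>", length(unique(x$estimates$sample_id)), "samples x",
      length(unique(x$estimates$isoform)), "isoforms,",
      x$cross_reactivity$n_blots, "blot(s);",
      "correction:", x$options$correction,
      sprintf("(%s c)\n", x$options$cross_reactivity))
  print(x$estimates, n = 20)
  invisible(x)
}
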