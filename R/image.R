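# Synthetic gel-image round trip: render band densities as Gaussian blobs,
# then recover them with a rolling-minimum background + integration
# densitometer. A demo front-end for the pipeline, not a real-scan processor.

#' Lane/band layout for a rendered blot image
#'
#' @param n_lanes Number of lanes.
#' @param lane_spacing Horizontal pixel spacing between lane centres.
#' @param lane_width Width in pixels of each lane box (must not exceed
#'   `lane_spacing`, otherwise lanes overlap).
#' @param height,margin Image height and left/right margin in pixels.
#' @param band_row Vertical centre of the band (default mid-height).
#' @param sigma_x,sigma_y Gaussian band profile SDs in pixels.
#' @param background Uniform background grey level.
#' @return A `blot_geometry` list, including `lane_boxes` usable with
#'   [quantify_blot_image()].
#' @export
blot_geometry <- function(n_lanes, lane_spacing = 40, lane_width = 36,
                          height = 80, margin = 20, band_row = NULL,
                          sigma_x = 4, sigma_y = 3, background = 0.05) {
  stopifnot(n_lanes >= 1, lane_spacing > 0, lane_width > 0,
            sigma_x > 0, sigma_y > 0, background >= 0)
  if (lane_width > lane_spacing) {
    stop("overlapping lane geometry: lane_width exceeds lane_spacing",
         call. = FALSE)
  }
  width <- 2 * margin + n_lanes * lane_spacing
  if (is.null(band_row)) band_row <- height / 2
  centers <- margin + lane_spacing * (seq_len(n_lanes) - 0.5)
  boxes <- data.frame(
    x0 = pmax(1, round(centers - lane_width / 2)),
    x1 = pmin(width, round(centers + lane_width / 2)),
    y0 = 1L, y1 = height
  )
  structure(
    list(n_lanes = n_lanes, width = width, height = height,
         lane_centers = centers, band_row = band_row,
         sigma_x = sigma_x, sigma_y = sigma_y, background = background,
         lane_boxes = boxes),
    class = "blot_geometry"
  )
}

#' Render band densities as a synthetic grayscale blot image
#'
#' Each band is a 2-D Gaussian-profile blob whose integrated intensity above
#' background equals its density (up to Gaussian tail truncation at the image
#' edge), centred on its lane at the geometry's band row.
#'
#' @param lane_densities Nonnegative densities, one per lane.
#' @param geometry A [blot_geometry()] with `n_lanes == length(lane_densities)`.
#' @return A numeric matrix (rows = y, columns = x) of grey values.
#' @export
render_blot_image <- function(lane_densities, geometry = blot_geometry(length(lane_densities))) {
  stopifnot(inherits(geometry, "blot_geometry"))
  d <- as.numeric(lane_densities)
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("lane_densities must be finite and >= 0", call. = FALSE)
  }
  if (length(d) != geometry$n_lanes) {
    stop("length(lane_densities) must equal geometry$n_lanes", call. = FALSE)
  }
  img <- matrix(geometry$background, nrow = geometry$height, ncol = geometry$width)
  ys <- seq_len(geometry$height)
  xs <- seq_len(geometry$width)
  gy <- stats::dnorm(ys, mean = geometry$band_row, sd = geometry$sigma_y)
  for (i in seq_len(geometry$n_lanes)) {
    if (d[i] == 0) next
    gx <- stats::dnorm(xs, mean = geometry$lane_centers[i], sd = geometry$sigma_x)
    img <- img + d[i] * outer(gy, gx)
  }
  img
}

#' Quantify lane densities from a blot image
#'
#' A minimal densitometer: within each lane box the vertical intensity
#' profile (row sums across the box width) is background-corrected by a
#' rolling minimum and the remaining intensity integrated.
#'
#' @param image Numeric matrix as returned by [render_blot_image()].
#' @param lane_boxes Data frame with columns `x0`, `x1`, `y0`, `y1` (pixel
#'   bounds, inclusive), one row per lane box.
#' @param bg_window Rolling-minimum window (rows); default spans the whole
#'   box, i.e. a global per-lane minimum.
#' @return Nonnegative densities, one per box, in box order.
#' @export
quantify_blot_image <- function(image, lane_boxes, bg_window = NULL) {
  stopifnot(is.matrix(image))
  lb <- as.data.frame(lane_boxes)
  stopifnot(all(c("x0", "x1", "y0", "y1") %in% names(lb)))
  if (any(lb$x0 < 1 | lb$y0 < 1 | lb$x1 > ncol(image) | lb$y1 > nrow(image) |
            lb$x0 > lb$x1 | lb$y0 > lb$y1)) {
    stop("lane box out of image bounds", call. = FALSE)
  }
  vapply(seq_len(nrow(lb)), function(i) {
    box <- image[lb$y0[i]:lb$y1[i], lb$x0[i]:lb$x1[i], drop = FALSE]
    profile <- rowSums(box)
    w <- if (is.null(bg_window)) length(profile) else bg_window
    bg <- rolling_min(profile, w)
    sum(pmax(profile - bg, 0))
  }, numeric(1))
}

rolling_min <- function(x, window) {
  n <- length(x)
  if (window >= n) return(rep(min(x), n))
  half <- floor(window / 2)
  vapply(seq_len(n), function(i) {
    min(x[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Write a rendered blot image to PNG
#'
#' Grey values are clipped to the 0-1 range after scaling by the image
#' maximum. Requires the `png` package.
#'
#' @param image Numeric matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_blot_png <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required to write PNG images", call. = FALSE)
  }
  mx <- max(image, 1e-12)
  png::writePNG(pmin(pmax(image / mx, 0), 1), path)
  invisible(path)
}
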