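#' Sample an intensity profile along a transect
#'
#' Bilinear interpolation of a rendered (or loaded) grayscale image along
#' the straight segment from `start` to `end`, at a fixed step in
#' micrometres. This is the raster-side counterpart of the line-based
#' estimators: spacings recovered from the profile should match the
#' geometric daily spacing.
#'
#' @param image A `section_image` (see [render_section_image()]).
#' @param start,end Numeric length-2 endpoints `c(u, v)` in micrometres.
#' @param step Sampling step along the transect, micrometres.
#' @return A tibble with `position` (micrometres from `start`) and
#'   `intensity`.
#' @export
sample_transect <- function(image, start, end, step = 0.25) {
  stopifnot(inherits(image, "section_image"), step > 0)
  tr <- image$transform
  img <- image$image
  L <- sqrt(sum((end - start)^2))
  pos <- seq(0, L, by = step)
  t <- if (L > 0) pos / L else 0
  uu <- start[1] + t * (end[1] - start[1])
  vv <- start[2] + t * (end[2] - start[2])
  rr <- (vv - tr$v0) * tr$px_per_um + 0.5
  cc <- (uu - tr$u0) * tr$px_per_um + 0.5
  if (any(rr < 1 | rr > nrow(img) | cc < 1 | cc > ncol(img))) {
    inside <- rr >= 1 & rr <= nrow(img) & cc >= 1 & cc <= ncol(img)
    stop(sprintf("transect leaves the image: only [%.2f, %.2f] um of [0, %.2f] um inside",
                 min(pos[inside]), max(pos[inside]), L))
  }
  r0 <- pmin(floor(rr), nrow(img) - 1L); c0 <- pmin(floor(cc), ncol(img) - 1L)
  fr <- rr - r0; fc <- cc - c0
  val <- img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    img[cbind(r0 + 1L, c0 + 1L)] * fr * fc
  tibble::tibble(position = pos, intensity = val)
}

#' Detect dark bands and their spacings in an intensity profile
#'
#' Incremental bands are intensity minima (they are darker than the
#' surrounding matrix), so bands are found as local minima of the profile
#' with prominence at least `min_prominence`; prominence-based selection is
#' robust to slow illumination gradients where a fixed threshold is not.
#'
#' @param profile A tibble from [sample_transect()] (columns `position`,
#'   `intensity`).
#' @param min_prominence Minimum prominence of a minimum, intensity units.
#' @return A list with `bands` (positions of detected band centres,
#'   micrometres), `spacings` (successive differences), and `flagged`
#'   (`TRUE` when fewer than 2 bands were found).
#' @export
detect_band_spacing <- function(profile, min_prominence = 0.1) {
  stopifnot(all(c("position", "intensity") %in% names(profile)),
            min_prominence >= 0)
  y <- -profile$intensity # minima of intensity = maxima of y
  n <- length(y)
  if (n < 3L) return(list(bands = numeric(0), spacings = numeric(0), flagged = TRUE))
  is_peak <- which(vapply(2:(n - 1L), function(i) {
    y[i] > y[i - 1L] && y[i] >= y[i + 1L]
  }, logical(1))) + 1L
  keep <- vapply(is_peak, function(i) peak_prominence(y, i) >= min_prominence,
                 logical(1))
  bands <- profile$position[is_peak[keep]]
  if (length(bands) < 2L) {
    return(list(bands = bands, spacings = numeric(0), flagged = TRUE))
  }
  list(bands = bands, spacings = diff(bands), flagged = FALSE)
}

# topographic prominence of a local maximum of y at index i: height above
# the higher of the two key saddles toward equal-or-higher terrain
peak_prominence <- function(y, i) {
  n <- length(y)
  left <- if (i == 1L) y[i] else {
    higher <- which(y[seq_len(i - 1L)] > y[i])
    lo <- if (length(higher)) max(higher) + 1L else 1L
    min(y[lo:i])
  }
  right <- if (i == n) y[i] else {
    higher <- which(y[(i + 1L):n] > y[i])
    hi <- if (length(higher)) i + min(higher) - 1L else n
    min(y[i:hi])
  }
  y[i] - max(left, right)
}

#' Recover the daily spacing of a section from its rendered image
#'
#' Convenience round-trip: renders transects perpendicular to the outer
#' enamel surface in mature enamel and pools band spacings detected in the
#' image.
#'
#' @param section An [enamel_section()].
#' @param image A `section_image` of that section.
#' @param n_transects Number of transects across the mature region.
#' @param min_prominence Passed to [detect_band_spacing()].
#' @return A list with `mean_spacing` (micrometres) and `spacings`.
#' @export
image_dsr <- function(section, image, n_transects = 5, min_prominence = 0.1) {
  edj <- section$edj
  edj_len <- polyline_length(edj)
  s_grid <- seq(0.1 * edj_len, 0.9 * edj_len, length.out = n_transects)
  base <- point_at_arc(edj, s_grid)
  thick <- project_onto_polyline(section$outer_surface, base)$dist
  mature <- thick >= 0.95 * max(thick)
  spac <- list()
  for (k in which(mature)) {
    origin <- as.numeric(base[k, ])
    dir <- transect_direction(section, origin, s_grid[k], "prismless")
    prof <- sample_transect(image, origin + 0.02 * dir * thick[k],
                            origin + dir * (thick[k] - 0.2),
                            step = 0.1 / image$transform$px_per_um)
    det <- detect_band_spacing(prof, min_prominence = min_prominence)
    if (!det$flagged) spac[[length(spac) + 1L]] <- det$spacings
  }
  spac <- unlist(spac)
  list(mean_spacing = if (length(spac)) mean(spac) else NA_real_, spacings = spac)
}
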