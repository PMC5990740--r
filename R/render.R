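#' Render a section as a grayscale band image
#'
#' Rasterizes a section the way it appears under transmitted polarized
#' light: a bright matrix crossed by regularly spaced dark bands roughly
#' parallel to the enamel surface. Each incremental line is drawn as a dark
#' band with a Gaussian cross-profile; long-period bands are darker than
#' short-period ones (both are darker than the surrounding matrix), and
#' i.i.d. Gaussian pixel noise is added on top.
#'
#' The returned transform maps between pixel indices and section
#' coordinates: pixel (row, col) has centre
#' `u = u0 + (col - 0.5) / px_per_um`, `v = v0 + (row - 0.5) / px_per_um`
#' (row 1 is the smallest v).
#'
#' @param section An [enamel_section()].
#' @param px_per_um Resolution, pixels per micrometre.
#' @param band_contrast Peak darkening of a long-period band, in intensity
#'   units (image background is 1, black is 0). Short-period bands are drawn
#'   at 55% of this contrast.
#' @param band_sd Gaussian cross-profile standard deviation, micrometres.
#' @param noise_sd Additive Gaussian pixel noise standard deviation.
#' @param margin Padding around the section bounding box, micrometres.
#' @param seed Seed for the pixel noise.
#' @param dentine Include dentine von Ebner bands.
#' @return A `section_image`: list with `image` (matrix in [0, 1], rows =
#'   v), `transform` (list `px_per_um`, `u0`, `v0`), and `merged_bands`
#'   (`TRUE` when the minimum daily spacing is under 2 pixels, i.e. the
#'   resolution cannot separate adjacent bands).
#' @export
render_section_image <- function(section, px_per_um = 4, band_contrast = 0.6,
                                 band_sd = 0.18, noise_sd = 0, margin = 2,
                                 seed = 1L, dentine = TRUE) {
  stopifnot(inherits(section, "enamel_section"), px_per_um > 0, band_sd > 0)
  set.seed(seed)
  lines <- section$enamel_lines
  if (dentine) lines <- c(lines, section$dentine_lines)
  all_pts <- do.call(rbind, c(list(unclass(section$edj), unclass(section$outer_surface)),
                              lapply(lines, function(l) unclass(l$path))))
  u0 <- min(all_pts[, 1]) - margin; v0 <- min(all_pts[, 2]) - margin
  u1 <- max(all_pts[, 1]) + margin; v1 <- max(all_pts[, 2]) + margin
  ncol_px <- max(ceiling((u1 - u0) * px_per_um), 2L)
  nrow_px <- max(ceiling((v1 - v0) * px_per_um), 2L)
  dark <- matrix(0, nrow_px, ncol_px)

  sigma_px <- band_sd * px_per_um
  halfwin <- max(ceiling(4 * sigma_px), 2L)
  for (l in lines) {
    amp <- band_contrast * switch(l$kind, long_period = 1, short_period = 0.55,
                                  von_ebner = 0.8)
    if (amp <= 0) next
    # resample the polyline densely so nearest-sample distance ~ curve distance
    path <- l$path
    total <- polyline_length(path)
    pts <- point_at_arc(path, seq(0, total, by = 0.25 / px_per_um))
    pc <- (pts[, 1] - u0) * px_per_um + 0.5 # pixel-space coordinates
    pr <- (pts[, 2] - v0) * px_per_um + 0.5
    c_base <- round(pc); r_base <- round(pr)
    for (dr in -halfwin:halfwin) {
      for (dc in -halfwin:halfwin) {
        rr <- r_base + dr; cc <- c_base + dc
        ok <- rr >= 1 & rr <= nrow_px & cc >= 1 & cc <= ncol_px
        if (!any(ok)) next
        d2 <- (rr[ok] - pr[ok])^2 + (cc[ok] - pc[ok])^2
        contrib <- amp * exp(-d2 / (2 * sigma_px^2))
        idx <- cbind(rr[ok], cc[ok])
        dark[idx] <- pmax(dark[idx], contrib)
      }
    }
  }
  img <- 1 - dark
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                                        nrow_px, ncol_px)
  img <- pmin(pmax(img, 0), 1)

  # flag resolutions at which adjacent daily bands merge
  day_arcs <- tryCatch({
    hits <- lapply(section$enamel_lines, intersect_with_edj, edj = section$edj)
    sort(vapply(hits[!vapply(hits, is.null, logical(1))],
                function(h) h$arc, numeric(1)))
  }, warning = function(w) numeric(0), error = function(e) numeric(0))
  spacing_px <- if (!is.null(section$truth)) {
    section$truth$dsr * px_per_um
  } else if (length(day_arcs) >= 2L) min(diff(day_arcs)) * px_per_um else NA_real_
  merged <- isTRUE(spacing_px < 2)
  if (merged) warning("daily band spacing below 2 px: adjacent bands merge at this resolution")

  structure(
    list(image = img, transform = list(px_per_um = px_per_um, u0 = u0, v0 = v0),
         merged_bands = merged),
    class = "section_image"
  )
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf("<section_image> %d x %d px at %g px/um%s\n",
              nrow(x$image), ncol(x$image), x$transform$px_per_um,
              if (x$merged_bands) " [bands merge at this resolution]" else ""))
  invisible(x)
}

# coordinate helpers: micrometre point -> fractional pixel (row, col)
um_to_px <- function(transform, pt) {
  c(row = (pt[2] - transform$v0) * transform$px_per_um + 0.5,
    col = (pt[1] - transform$u0) * transform$px_per_um + 0.5)
}

#' Write a section image to PNG
#'
#' @param image A `section_image`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_section_png <- function(image, path) {
  stopifnot(inherits(image, "section_image"))
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the png package is required to write PNG files")
  }
  # image rows run v-upward; PNG rows run top-down
  png::writePNG(image$image[rev(seq_len(nrow(image$image))), , drop = FALSE], path)
  invisible(path)
}
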