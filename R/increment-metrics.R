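#' Daily secretion rate from incremental line spacing
#'
#' Estimates the daily secretion rate (DSR) as the spacing between
#' consecutive daily incremental lines. In prismless enamel an ameloblast's
#' most likely path runs perpendicular to the outer enamel surface, so in
#' `"prismless"` mode spacings are measured along inward normals to the
#' outer surface; `"prism_path"` mode instead measures along trajectories
#' orthogonal to the forming fronts (the incremental lines themselves).
#' Transects are placed only where the enamel has reached at least 95% of
#' its maximum thickness, i.e. in mature enamel away from the still-forming
#' cervical wedge.
#'
#' Both short- and long-period enamel lines are daily positions of the
#' forming front (long-period lines are every R-th daily line), so the daily
#' sequence is their union.
#'
#' @param section An [enamel_section()].
#' @param mode `"prismless"` (perpendicular to the outer enamel surface) or
#'   `"prism_path"` (orthogonal to the forming fronts).
#' @param window Spacing between transects along the EDJ, micrometres; each
#'   transect yields one sample.
#' @param max_transects Upper bound on the number of transects; long
#'   sections are sampled at evenly spaced sites rather than exhaustively.
#' @return A `dsr_estimate`: list with `samples` (tibble with
#'   `edj_arc_position`, `spacing`, `n_gaps`), `gaps` (all individual gap
#'   widths), `mean_dsr` (grand mean of gaps, micrometres/day under the
#'   1-day reading of short-period lines), `mode`, and `flagged` (`TRUE`
#'   when fewer than 2 daily lines were available).
#' @examples
#' sec <- simulate_section(section_config(cer = 20, dsr = 1.5, n_days = 12))
#' measure_dsr(sec)$mean_dsr # 1.5
#' @export
measure_dsr <- function(section, mode = c("prismless", "prism_path"), window = 10,
                        max_transects = 48) {
  stopifnot(inherits(section, "enamel_section"), window > 0, max_transects >= 1)
  mode <- match.arg(mode)
  daily <- section_lines(section) # all enamel lines = daily sequence
  empty <- tibble::tibble(edj_arc_position = double(), spacing = double(),
                          n_gaps = integer())
  if (length(daily) < 2L) {
    return(structure(list(samples = empty, gaps = double(), mean_dsr = NA_real_,
                          mode = mode, flagged = TRUE), class = "dsr_estimate"))
  }
  edj <- section$edj
  oes <- section$outer_surface
  edj_len <- polyline_length(edj)
  # local thickness along the EDJ and the mature-enamel mask
  s_grid <- seq(0, edj_len, by = window)
  base <- point_at_arc(edj, s_grid)
  thick <- project_onto_polyline(oes, base)$dist
  max_th <- max(thick)
  mature <- thick >= 0.95 * max_th
  ray_len <- max_th * 1.5 + 2

  sites <- which(mature)
  if (length(sites) > max_transects) {
    sites <- sites[unique(round(seq(1, length(sites), length.out = max_transects)))]
  }
  rows <- list(); gaps_all <- list()
  for (k in sites) {
    origin <- base[k, ]
    dir <- transect_direction(section, origin, s_grid[k], mode)
    cross <- numeric(0)
    for (l in daily) {
      h <- ray_crossings(origin, dir, ray_len, l$path)
      if (nrow(h) > 0L) cross <- c(cross, h$arc_a[1])
    }
    cross <- sort(cross[cross > 1e-9])
    if (length(cross) >= 2L) {
      g <- diff(cross)
      g <- g[g > 1e-9]
      if (length(g) > 0L) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          edj_arc_position = s_grid[k], spacing = mean(g), n_gaps = length(g)
        )
        gaps_all[[length(gaps_all) + 1L]] <- g
      }
    }
  }
  samples <- if (length(rows)) dplyr::bind_rows(rows) else empty
  gaps <- unlist(gaps_all) %||% double()
  structure(
    list(samples = samples, gaps = gaps,
         mean_dsr = if (length(gaps)) mean(gaps) else NA_real_,
         mode = mode, flagged = length(gaps) == 0L),
    class = "dsr_estimate"
  )
}

#' @export
print.dsr_estimate <- function(x, ...) {
  cat(sprintf("<dsr_estimate> mode %s: mean DSR %.3f um/day over %d gaps (%d transects)%s\n",
              x$mode, x$mean_dsr, length(x$gaps), nrow(x$samples),
              if (x$flagged) " [flagged: insufficient lines]" else ""))
  invisible(x)
}

# Direction of a measurement transect starting on the EDJ at arc s.
transect_direction <- function(section, origin, s, mode) {
  if (mode == "prismless") {
    # locate the outer-surface point radially above the EDJ point, then use
    # the outer-surface normal there (nearest-point projection can snap to
    # the still-forming cervical wedge instead)
    edj_nrm <- as.numeric(normal_at_arc(section$edj, s)[1, ])
    bb <- apply(section$outer_surface, 2, range)
    reach <- sqrt(sum((bb[2, ] - bb[1, ])^2)) + 2
    hit <- ray_crossings(origin, edj_nrm, reach, section$outer_surface)
    if (nrow(hit) > 0L) {
      oes_arc <- hit$arc_b[1]
      oes_pt <- c(hit$u[1], hit$v[1])
    } else {
      pr <- project_onto_polyline(section$outer_surface, matrix(origin, ncol = 2))
      oes_arc <- pr$arc[1]
      oes_pt <- pr$point[1, ]
    }
    dir <- as.numeric(normal_at_arc(section$outer_surface, oes_arc)[1, ])
    if (sum((oes_pt - origin) * dir) < 0) dir <- -dir
    dir
  } else {
    # orthogonal to the local forming front: use the nearest incremental line
    daily <- section_lines(section)
    d_best <- Inf; tang <- c(1, 0)
    for (l in daily) {
      pr <- project_onto_polyline(l$path, matrix(origin, ncol = 2))
      if (pr$dist[1] < d_best) {
        d_best <- pr$dist[1]
        a <- pr$arc[1]
        p0 <- point_at_arc(l$path, max(a - 1, 0))
        p1 <- point_at_arc(l$path, a + 1)
        tang <- as.numeric(p1 - p0)
      }
    }
    tang <- tang / sqrt(sum(tang^2))
    dir <- c(-tang[2], tang[1])
    nrm <- as.numeric(normal_at_arc(section$edj, s)[1, ])
    if (sum(dir * nrm) < 0) dir <- -dir
    dir
  }
}

#' Crown extension rate by the cumulative-length method
#'
#' Implements the cumulative-length estimator of the crown extension rate
#' (CER) along the EDJ. Long-period (accentuated) lines serve as anchors.
#' Iterating from the cusp tip, for each consecutive anchor line B: the
#' growth trajectory is followed from the EDJ (at the previous anchor's EDJ
#' intersection, or the dentine-horn tip for the first segment) across the
#' daily incremental lines up to B, giving the trajectory length A and the
#' local mean daily spacing; the number of days is x = A / spacing; the EDJ
#' advance y is the arc distance between the successive EDJ intersections;
#' the segment extension rate is y/x. The section average is the pooled
#' ratio sum(y)/sum(x), and sum(x) is the crown formation time over the
#' measured EDJ.
#'
#' Under the 2-day reading of long-period lines (`p = 2`) every enamel line
#' is a daily position and the daily spacing is the short-period spacing;
#' under `p = 1` the long-period lines themselves are read as daily and the
#' short-period lines are treated as sub-daily and ignored. Consequently the
#' average CER under `p = 1` is exactly twice the average under `p = 2` on
#' the same section.
#'
#' @param section An [enamel_section()].
#' @param p Periodicity assumption: days per long-period increment (1 or 2).
#' @param span Optional numeric length-2 EDJ arc range (micrometres); when
#'   given, segments start at the first anchor inside the range instead of
#'   the cusp tip and stop at the last anchor inside it.
#' @return A `crown_growth_summary`: list with `segments` (tibble with
#'   columns `segment`, `arc_start`, `arc_end`, `trajectory_length_A`,
#'   `local_mean_dsr`, `days_x`, `edj_advance_y`, `extension_rate`),
#'   `sum_x`, `sum_y`, `average_cer`, `average_dsr`, `gaps`, and
#'   `periodicity_assumption`.
#' @examples
#' sec <- simulate_section(section_config(cer = 20, dsr = 1.5, n_days = 10))
#' cumulative_cer(sec, p = 2)$average_cer # 20
#' cumulative_cer(sec, p = 1)$average_cer # 40
#' @export
cumulative_cer <- function(section, p = 2, span = NULL) {
  stopifnot(inherits(section, "enamel_section"), p %in% c(1, 2))
  anchors <- section_lines(section, kind = "long_period")
  anchors <- anchors[vapply(anchors, function(l) l$accentuated, logical(1))]
  if (length(anchors) == 0L) stop("no accentuated long-period line intersects the EDJ")
  # daily lines under the assumed periodicity
  daily <- if (p == 2) section_lines(section) else anchors

  edj <- section$edj
  hits <- lapply(anchors, intersect_with_edj, edj = edj)
  keep <- !vapply(hits, is.null, logical(1))
  if (any(!keep)) {
    warning(sprintf("%d anchor line(s) without an EDJ intersection were skipped",
                    sum(!keep)))
  }
  anchors <- anchors[keep]; hits <- hits[keep]
  arcs <- vapply(hits, function(h) h$arc, numeric(1))
  ord <- order(arcs)
  anchors <- anchors[ord]; hits <- hits[ord]; arcs <- arcs[ord]
  if (!is.null(span)) {
    inside <- arcs >= span[1] & arcs <= span[2]
    if (sum(inside) < 2L) stop("fewer than two anchors inside the requested EDJ span")
    anchors <- anchors[inside]; hits <- hits[inside]; arcs <- arcs[inside]
    start_arc <- arcs[1]
    start_line <- anchors[[1]]
    seq_from <- 2L
  } else {
    start_arc <- 0
    start_line <- NULL
    seq_from <- 1L
  }
  if (length(anchors) < seq_from) stop("no measurable segment on this section")

  max_th <- max(project_onto_polyline(section$outer_surface,
                                      point_at_arc(edj, arcs))$dist)
  ray_len <- max_th * 1.5 + 2

  prev_arc <- start_arc
  prev_line <- start_line
  segs <- list(); gaps_all <- list()
  for (i in seq(seq_from, length(anchors))) {
    target <- anchors[[i]]
    res <- trajectory_segment(section, prev_arc, prev_line, target, daily, ray_len)
    if (is.null(res)) {
      warning(sprintf("segment ending at anchor %d skipped: trajectory does not reach it", i))
    } else {
      y <- arcs[i] - prev_arc
      if (res$x <= 0) stop("segment with zero formation days; check the section")
      segs[[length(segs) + 1L]] <- tibble::tibble(
        segment = length(segs) + 1L,
        arc_start = prev_arc, arc_end = arcs[i],
        trajectory_length_A = res$A,
        local_mean_dsr = res$spacing,
        days_x = res$x,
        edj_advance_y = y,
        extension_rate = y / res$x
      )
      gaps_all[[length(gaps_all) + 1L]] <- res$gaps
    }
    prev_arc <- arcs[i]
    prev_line <- target
  }
  if (length(segs) == 0L) stop("no measurable segment on this section")
  segments <- dplyr::bind_rows(segs)
  gaps <- unlist(gaps_all)
  sum_x <- sum(segments$days_x); sum_y <- sum(segments$edj_advance_y)
  structure(
    list(
      segments = segments, sum_x = sum_x, sum_y = sum_y,
      average_cer = sum_y / sum_x,
      average_dsr = mean(gaps), gaps = gaps,
      periodicity_assumption = p,
      specimen_id = section$specimen_id, cusp_id = section$cusp_id
    ),
    class = "crown_growth_summary"
  )
}

# One cumulative-length segment: march the growth trajectory (EDJ normal at
# the segment's starting intersection) across the daily lines to the target
# anchor. The previous anchor line itself is excluded from the crossing set,
# so the gap count equals the number of days elapsed.
trajectory_segment <- function(section, start_arc, start_line, target, daily, ray_len) {
  origin <- as.numeric(point_at_arc(section$edj, start_arc)[1, ])
  dir <- as.numeric(normal_at_arc(section$edj, start_arc)[1, ])
  ht <- ray_crossings(origin, dir, ray_len, target$path)
  ht <- ht[ht$arc_a > 1e-9, , drop = FALSE]
  if (nrow(ht) == 0L) return(NULL)
  A <- ht$arc_a[1]
  cross <- numeric(0)
  for (l in daily) {
    if (!is.null(start_line) && identical(l, start_line)) next
    h <- ray_crossings(origin, dir, ray_len, l$path)
    h <- h$arc_a[h$arc_a > 1e-9 & h$arc_a <= A + 1e-9]
    if (length(h) > 0L) cross <- c(cross, h[1])
  }
  cross <- sort(unique(cross))
  if (length(cross) == 0L) return(NULL)
  gaps <- diff(c(0, cross))
  n <- length(gaps)
  spacing <- A / n # local mean daily spacing along this trajectory
  list(A = A, spacing = spacing, x = A / spacing, gaps = gaps)
}

#' @export
print.crown_growth_summary <- function(x, ...) {
  cat(sprintf(
    "<crown_growth_summary> p = %d day(s) per long-period line\n  %d segments: sum(y) = %.1f um over sum(x) = %.1f days\n  average CER %.2f um/day, average DSR %.3f um/day\n",
    x$periodicity_assumption, nrow(x$segments), x$sum_y, x$sum_x,
    x$average_cer, x$average_dsr
  ))
  invisible(x)
}

#' Dentine extension rate along the EDJ
#'
#' Average extension rate computed from dentine lines of von Ebner in a
#' manner equivalent to the enamel estimator: the EDJ arc distance between
#' the first and last von Ebner intersections divided by the number of daily
#' intervals spanned. Since von Ebner lines are daily, this rate is
#' periodicity-free and serves as the independent benchmark in
#' [periodicity_concordance()].
#'
#' @param section An [enamel_section()] with von Ebner lines.
#' @return A list with `rate` (micrometres/day), `n_lines`, `span` (EDJ arc
#'   range covered, micrometres), and `mean_width` (mean spacing of the
#'   intersections along the EDJ).
#' @export
dentine_extension_rate <- function(section) {
  stopifnot(inherits(section, "enamel_section"))
  lines <- section_lines(section, dentine = TRUE)
  hits <- lapply(lines, intersect_with_edj, edj = section$edj)
  keep <- !vapply(hits, is.null, logical(1))
  if (sum(keep) < 2L) stop("need at least 2 von Ebner lines intersecting the EDJ")
  arcs <- sort(vapply(hits[keep], function(h) h$arc, numeric(1)))
  days <- vapply(lines[keep], function(l) l$day_index, integer(1))
  n_intervals <- if (!anyNA(days)) diff(range(days)) else length(arcs) - 1L
  # von Ebner increment width: perpendicular spacing of consecutive daily
  # lines, measured along an inward EDJ normal at mid-span
  s_mid <- mean(range(arcs))
  origin <- as.numeric(point_at_arc(section$edj, s_mid)[1, ])
  dir <- -as.numeric(normal_at_arc(section$edj, s_mid)[1, ])
  cross <- numeric(0)
  for (l in lines[keep]) {
    h <- ray_crossings(origin, dir, 250, l$path)
    h <- h$arc_a[h$arc_a > 1e-9]
    if (length(h) > 0L) cross <- c(cross, h[1])
  }
  widths <- diff(sort(cross))
  list(
    rate = diff(range(arcs)) / n_intervals,
    n_lines = length(arcs),
    span = range(arcs),
    mean_width = if (length(widths)) mean(widths) else NA_real_
  )
}

#' Pool cusp-level growth summaries into tooth-level averages
#'
#' The tooth-level (grand average) CER pools segments across cusps as
#' sum(y)/sum(x), weighting each cusp by its measured formation time; this
#' differs from the unweighted mean of per-cusp CERs whenever the cusps'
#' sum(x) differ. The grand average DSR is the mean of all individual daily
#' spacings.
#'
#' @param summaries A list of `crown_growth_summary` objects (one per cusp).
#' @return A one-row tibble with `average_cer`, `average_dsr`, `sum_x`,
#'   `sum_y`, `n_cusps`, `periodicity_assumption`.
#' @export
grand_average <- function(summaries) {
  if (inherits(summaries, "crown_growth_summary")) summaries <- list(summaries)
  stopifnot(length(summaries) >= 1L,
            all(vapply(summaries, inherits, logical(1), "crown_growth_summary")))
  p <- unique(vapply(summaries, function(s) s$periodicity_assumption, numeric(1)))
  if (length(p) != 1L) stop("summaries mix periodicity assumptions")
  sum_x <- sum(vapply(summaries, function(s) s$sum_x, numeric(1)))
  sum_y <- sum(vapply(summaries, function(s) s$sum_y, numeric(1)))
  gaps <- unlist(lapply(summaries, function(s) s$gaps))
  tibble::tibble(
    average_cer = sum_y / sum_x,
    average_dsr = mean(gaps),
    sum_x = sum_x, sum_y = sum_y,
    n_cusps = length(summaries),
    periodicity_assumption = p
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
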