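#' Configuration for the forward growth model
#'
#' Parameters of the incremental deposition model used by
#' [simulate_section()]. Enamel forms in two coupled processes: the
#' activation front of secretory ameloblasts advances along the
#' enamel-dentine junction (EDJ) at the crown extension rate `cer`
#' (micrometres of EDJ per day), and each activated EDJ point then accretes
#' enamel at the daily secretion rate `dsr` (micrometres per day, measured
#' along the local EDJ normal) for `secretion_duration` days. The enamel
#' forming front on day t is therefore a curve running from full-thickness
#' enamel back to the EDJ at arc position s(t) = integral of `cer`. Every
#' front is recorded as a daily incremental line; every `repeat_interval`-th
#' front is expressed as an accentuated long-period line, the remainder as
#' short-period lines. Odontoblasts differentiate on the same schedule, so
#' the dentine von Ebner line of day t meets the EDJ at the same arc
#' position and accretes inward at `dentine_rate`.
#'
#' @param cer Extension rate schedule, micrometres/day: a scalar (constant)
#'   or a vector of per-day rates of length `n_days`.
#' @param dsr Daily secretion rate, micrometres/day (scalar).
#' @param n_days Number of simulated days of crown extension.
#' @param repeat_interval Integer R >= 1: daily increments per long-period
#'   increment. The value observed across non-mammalian cynodonts is 2.
#' @param secretion_duration Days each ameloblast keeps secreting; sets the
#'   mature enamel thickness `dsr * secretion_duration`.
#' @param dentine_rate Daily von Ebner line spacing in dentine,
#'   micrometres/day.
#' @param dentine_days Depth of simulated dentine, in days of deposition
#'   (dentine is modelled only near the EDJ).
#' @param edj_shape `"straight"`, `"arc"`, or a matrix/data frame of control
#'   points for a custom EDJ.
#' @param edj_length Total EDJ length in micrometres, or `NULL` to cover the
#'   whole simulated extension. If the schedule runs past `edj_length` the
#'   simulation stops at the cervix and records the coverage day.
#' @param jitter_sd Standard deviation (micrometres) of Gaussian digitization
#'   noise applied to incremental-line vertices along their local normal.
#' @param grid_step Arc-length sampling step for polylines, micrometres.
#' @param seed Integer seed for the section's random stream.
#' @return A `section_config` object (a validated list).
#' @export
section_config <- function(cer = 20, dsr = 1.5, n_days = 16,
                           repeat_interval = 2L, secretion_duration = 8,
                           dentine_rate = 12, dentine_days = 4,
                           edj_shape = "straight", edj_length = NULL,
                           jitter_sd = 0, grid_step = 1, seed = 1L) {
  if (length(cer) == 1L) cer <- rep(cer, n_days)
  stopifnot(
    length(cer) == n_days, all(cer > 0), length(dsr) == 1L, dsr > 0,
    n_days >= 1, repeat_interval >= 1, secretion_duration >= 1,
    dentine_rate > 0, dentine_days >= 1, jitter_sd >= 0, grid_step > 0
  )
  structure(
    list(
      cer = as.double(cer), dsr = as.double(dsr), n_days = as.integer(n_days),
      repeat_interval = as.integer(repeat_interval),
      secretion_duration = as.double(secretion_duration),
      dentine_rate = as.double(dentine_rate),
      dentine_days = as.double(dentine_days),
      edj_shape = edj_shape, edj_length = edj_length,
      jitter_sd = as.double(jitter_sd), grid_step = as.double(grid_step),
      seed = as.integer(seed)
    ),
    class = "section_config"
  )
}

# EDJ polyline for a config: cusp tip at the origin, cervix toward +u.
# The +90-degree normal convention points into the enamel (+v).
build_edj <- function(config, length_um) {
  step <- config$grid_step
  n <- max(ceiling(length_um / step), 8L)
  s <- seq(0, length_um, length.out = n + 1L)
  if (is.character(config$edj_shape) && config$edj_shape == "straight") {
    pts <- cbind(u = s, v = rep(0, length(s)))
  } else if (is.character(config$edj_shape) && config$edj_shape == "arc") {
    # circular arc bending away from the enamel so offset curves stay simple
    radius <- max(length_um / (pi / 2), length_um)
    phi <- s / radius
    pts <- cbind(u = radius * sin(phi), v = radius * (cos(phi) - 1))
  } else {
    ctrl <- as_polyline(config$edj_shape)
    total <- polyline_length(ctrl)
    pts <- point_at_arc(ctrl, s / length_um * total)
  }
  as_polyline(pts)
}

#' Simulate a ground-truthed tooth section
#'
#' Runs the forward deposition model of [section_config()] and returns an
#' [enamel_section()] whose incremental lines carry their true day of
#' formation, with the generating configuration attached as `truth`.
#'
#' Each synthetic tracing is extended by a small overshoot past its EDJ tip,
#' the way hand-digitized tracings cross the junction slightly; this keeps
#' the geometric EDJ intersection well defined under vertex jitter.
#'
#' @param config A [section_config()].
#' @return An `enamel_section` with `truth = config`.
#' @examples
#' sec <- simulate_section(section_config(cer = 20, dsr = 1.5, n_days = 10))
#' sec
#' @export
simulate_section <- function(config) {
  stopifnot(inherits(config, "section_config"))
  set.seed(config$seed)
  s_days <- c(0, cumsum(config$cer)) # EDJ arc reached at end of each day
  n_days <- config$n_days
  coverage_day <- NA_integer_
  if (!is.null(config$edj_length) && s_days[n_days + 1L] >= config$edj_length) {
    coverage_day <- which(s_days[-1] >= config$edj_length - 1e-9)[1]
    n_days <- coverage_day
    s_days <- s_days[seq_len(n_days + 1L)]
    message(sprintf("extension reaches the cervix on day %d; simulation stops there",
                    coverage_day))
  }
  total_len <- s_days[n_days + 1L]
  edj <- build_edj(config, total_len)

  # continuous activation time a(s): inverse of the cumulative schedule
  a_of_s <- function(s) stats::approx(s_days, 0:n_days, xout = s, rule = 2)$y

  offset_line <- function(day, rate, duration, side, overshoot) {
    s_lo <- stats::approx(0:n_days, s_days, xout = max(day - duration, 0), rule = 2)$y
    s_hi <- s_days[day + 1L]
    s <- unique(c(seq(s_lo, s_hi, by = config$grid_step), s_hi))
    off <- rate * pmin(day - a_of_s(s), duration)
    # continue the parametric form past the EDJ tip so the tracing crosses
    # the junction by `overshoot` um (measured along the EDJ normal)
    c_loc <- config$cer[min(day, n_days)]
    ds_over <- overshoot / rate * c_loc
    s_ext <- setdiff(unique(c(seq(s_hi, s_hi + ds_over, by = config$grid_step),
                              s_hi + ds_over)), s_hi)
    off <- c(off, -rate * (s_ext - s_hi) / c_loc)
    s <- c(s, s_ext)
    # cuspal lead-in: lines reaching the dentine-horn tip also cross the
    # transect anchored exactly at the tip
    if (s_lo <= 1e-9) {
      s <- c(-overshoot, s)
      off <- c(off[1], off)
    }
    base <- point_at_arc_ext(edj, s)
    nrm <- normal_at_arc(edj, pmin(pmax(s, 0), total_len))
    pts <- base + side * nrm * off
    if (config$jitter_sd > 0) {
      tang <- rbind(pts[2, ] - pts[1, ], pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])
      tang <- tang / sqrt(rowSums(tang^2))
      nrml <- cbind(-tang[, 2], tang[, 1])
      pts <- pts + nrml * stats::rnorm(nrow(pts), 0, config$jitter_sd)
    }
    as_polyline(pts)
  }

  overshoot <- max(0.5, 3 * config$jitter_sd + 0.3)
  enamel_lines <- lapply(seq_len(n_days), function(t) {
    long <- (t %% config$repeat_interval) == 0L
    increment_line(
      offset_line(t, config$dsr, config$secretion_duration, +1, overshoot),
      kind = if (long) "long_period" else "short_period",
      day_index = t, accentuated = long
    )
  })
  dentine_lines <- lapply(seq_len(n_days), function(t) {
    increment_line(
      offset_line(t, config$dentine_rate, config$dentine_days, -1, overshoot),
      kind = "von_ebner", day_index = t
    )
  })

  # outer enamel surface: envelope of all deposition
  s <- unique(c(seq(0, total_len, by = config$grid_step), total_len))
  thick <- config$dsr * pmin(n_days - a_of_s(s), config$secretion_duration)
  oes <- as_polyline(point_at_arc(edj, s) + normal_at_arc(edj, s) * thick)

  sec <- enamel_section(
    edj = edj, outer_surface = oes,
    enamel_lines = enamel_lines, dentine_lines = dentine_lines,
    specimen_id = sprintf("synthetic-%d", config$seed),
    cusp_id = "A", species = "synthetic", truth = config
  )
  attr(sec, "coverage_day") <- coverage_day
  sec
}
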