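#' Incremental lines and digitized tooth sections
#'
#' `increment_line()` wraps a traced polyline with its interpretation:
#' `"long_period"` and `"short_period"` for enamel increments (the union of
#' the two is the daily sequence; long-period lines fall on every R-th daily
#' position, where R is the repeat interval), `"von_ebner"` for daily dentine
#' increments. `day_index` is only available for synthetic sections, where
#' the forward model knows the day each line formed; `accentuated` flags
#' lines usable as anchors for the cumulative-length extension-rate method.
#'
#' @param path A polyline (or coercible).
#' @param kind One of `"long_period"`, `"short_period"`, `"von_ebner"`.
#' @param day_index Integer day of formation, or `NA` for real tracings.
#' @param accentuated Logical; anchor candidate for extension-rate segments.
#' @return An `increment_line` object.
#' @export
increment_line <- function(path, kind = c("short_period", "long_period", "von_ebner"),
                           day_index = NA_integer_, accentuated = FALSE) {
  kind <- match.arg(kind)
  structure(
    list(
      path = as_polyline(path),
      kind = kind,
      day_index = as.integer(day_index),
      accentuated = isTRUE(accentuated)
    ),
    class = "increment_line"
  )
}

#' Assemble a digitized tooth section
#'
#' An `enamel_section` bundles the digitized geometry of one longitudinal
#' tooth section: the enamel-dentine junction (EDJ) oriented from the cusp
#' tip to the cervix, the outer enamel surface, the enamel incremental lines
#' and the dentine von Ebner lines, plus specimen metadata. Synthetic
#' sections produced by [simulate_section()] additionally carry the
#' generating `section_config()` in `truth`.
#'
#' @param edj EDJ polyline, first vertex at the cusp tip.
#' @param outer_surface Outer enamel surface polyline.
#' @param enamel_lines List of `increment_line`s of kind short/long period.
#' @param dentine_lines List of `increment_line`s of kind von_ebner.
#' @param specimen_id,cusp_id,species Metadata strings.
#' @param truth Optional [section_config()] for synthetic sections.
#' @return An `enamel_section` object.
#' @export
enamel_section <- function(edj, outer_surface, enamel_lines = list(),
                           dentine_lines = list(), specimen_id = NA_character_,
                           cusp_id = NA_character_, species = NA_character_,
                           truth = NULL) {
  edj <- as_polyline(edj)
  outer_surface <- as_polyline(outer_surface)
  stopifnot(
    all(vapply(enamel_lines, inherits, logical(1), "increment_line")),
    all(vapply(dentine_lines, inherits, logical(1), "increment_line"))
  )
  if (any(vapply(enamel_lines, function(l) l$kind == "von_ebner", logical(1)))) {
    stop("enamel_lines must be of kind short_period or long_period")
  }
  if (!all(vapply(dentine_lines, function(l) l$kind == "von_ebner", logical(1)))) {
    stop("dentine_lines must be of kind von_ebner")
  }
  structure(
    list(
      edj = edj, outer_surface = outer_surface,
      enamel_lines = enamel_lines, dentine_lines = dentine_lines,
      specimen_id = specimen_id, cusp_id = cusp_id, species = species,
      truth = truth
    ),
    class = "enamel_section"
  )
}

#' @export
print.enamel_section <- function(x, ...) {
  n_long <- sum(vapply(x$enamel_lines, function(l) l$kind == "long_period", logical(1)))
  cat(sprintf(
    "<enamel_section> %s / %s (%s)\n  EDJ %.1f um, %d enamel lines (%d long-period), %d dentine lines%s\n",
    x$specimen_id, x$cusp_id, x$species,
    polyline_length(x$edj), length(x$enamel_lines), n_long,
    length(x$dentine_lines),
    if (!is.null(x$truth)) ", synthetic (truth attached)" else ""
  ))
  invisible(x)
}

# enamel lines of a given kind; kind = NULL returns all (the daily sequence)
section_lines <- function(section, kind = NULL, dentine = FALSE) {
  lines <- if (dentine) section$dentine_lines else section$enamel_lines
  if (is.null(kind)) return(lines)
  lines[vapply(lines, function(l) l$kind %in% kind, logical(1))]
}

#' Flatten a section's lines into a tibble
#'
#' One row per polyline vertex, for plotting and export.
#'
#' @param section An `enamel_section`.
#' @return A tibble with columns `structure`, `kind`, `line_id`, `day_index`,
#'   `u`, `v`.
#' @export
section_as_tibble <- function(section) {
  stopifnot(inherits(section, "enamel_section"))
  base <- list(
    tibble::tibble(structure = "edj", kind = "edj", line_id = "edj",
                   day_index = NA_integer_,
                   u = section$edj[, 1], v = section$edj[, 2]),
    tibble::tibble(structure = "outer_surface", kind = "outer_surface",
                   line_id = "oes", day_index = NA_integer_,
                   u = section$outer_surface[, 1], v = section$outer_surface[, 2])
  )
  line_tbl <- function(lines, structure) {
    purrr::imap(lines, function(l, i) {
      tibble::tibble(structure = structure, kind = l$kind,
                     line_id = paste0(structure, "_", i),
                     day_index = l$day_index, u = l$path[, 1], v = l$path[, 2])
    })
  }
  dplyr::bind_rows(c(base, line_tbl(section$enamel_lines, "enamel"),
                     line_tbl(section$dentine_lines, "dentine")))
}

#' Plot a digitized section
#'
#' Draws the EDJ, the outer enamel surface, and the incremental lines,
#' coloured by kind (long-period lines darker than short-period ones).
#'
#' @param object An `enamel_section`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enamel_section <- function(object, ...) {
  df <- section_as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v, group = .data$line_id,
                                   colour = .data$kind)) +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::geom_path(data = df[df$structure %in% c("edj", "outer_surface"), ],
                       linewidth = 0.7) +
    ggplot2::scale_colour_manual(values = c(
      edj = "black", outer_surface = "grey40",
      long_period = "#7a1f1f", short_period = "#d98c8c", von_ebner = "#3b6fb5"
    )) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "u (µm, cusp → cervix)", y = "v (µm)",
                  colour = "line kind") +
    ggplot2::theme_minimal()
}
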