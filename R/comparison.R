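#' Phylogenetically corrected multi-group comparison of growth rates
#'
#' Runs the full comparative chain on a species trait table: log10 rates and
#' body mass; a PGLS regression of each log rate on log mass under Brownian
#' covariance, whose raw residuals are the body-mass-corrected rates; a
#' Box-Cox transformation of each residual vector toward normality; then a
#' two-response MANOVA (Wilks' lambda with the exact F transform) across
#' groups with pairwise two-group MANOVAs, univariate ANOVAs with pairwise
#' contrasts, and Kruskal-Wallis tests with Dunn post-hocs; every family of
#' pairwise p-values is Benjamini-Hochberg adjusted separately.
#'
#' Species can be excluded up front (e.g. taxa with an anomalous deposition
#' pattern), and group assignments overridden per species to probe the
#' placement of taxa of uncertain affinity.
#'
#' @param table A species table (tibble/data frame) with columns `species`,
#'   `group`, `body_mass_g`, `dsr_um_d`, `cer_um_d`, optionally `tooth_id`.
#' @param tree An `ape::phylo` containing every species in `table`.
#' @param exclude Character vector of species to drop before analysis.
#' @param assign Named character vector of group overrides
#'   (`c(species = "group")`).
#' @param unit `"species"` (per-tooth rows averaged per species before
#'   analysis, the default) or `"tooth"` (rows used as-is; the tree
#'   covariance then treats teeth of one species as exchangeable, so use
#'   with care).
#' @return A `group_comparison` object; see [tidy.group_comparison()] and
#'   [glance.group_comparison()].
#' @export
run_group_comparison <- function(table, tree, exclude = character(),
                                 assign = character(),
                                 unit = c("species", "tooth")) {
  unit <- match.arg(unit)
  stopifnot(inherits(tree, "phylo"))
  required <- c("species", "group", "body_mass_g", "dsr_um_d", "cer_um_d")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols) > 0L) {
    stop("species table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  tbl <- tibble::as_tibble(table)
  tbl <- tbl[!tbl$species %in% exclude, , drop = FALSE]
  if (length(assign) > 0L) {
    hit <- match(tbl$species, names(assign))
    tbl$group[!is.na(hit)] <- assign[hit[!is.na(hit)]]
  }
  if (unit == "species" && anyDuplicated(tbl$species)) {
    tbl <- dplyr::summarise(
      dplyr::group_by(tbl, .data$species, .data$group),
      body_mass_g = mean(.data$body_mass_g),
      dsr_um_d = mean(.data$dsr_um_d),
      cer_um_d = mean(.data$cer_um_d),
      .groups = "drop"
    )
  }
  not_in_tree <- setdiff(tbl$species, tree$tip.label)
  if (length(not_in_tree) > 0L) {
    stop("stage pgls: species not in the tree: ", paste(not_in_tree, collapse = ", "))
  }
  tree <- ape::keep.tip(tree, unique(tbl$species))
  if (unit == "tooth") {
    # expand the species covariance over repeated rows
    C_sp <- phylo_covariance(tree, tip_order = unique(tbl$species))
    idx <- match(tbl$species, unique(tbl$species))
    C <- C_sp[idx, idx, drop = FALSE]
    # a hair of independent tooth-level variance keeps C positive definite
    diag(C) <- diag(C) + 1e-6 * mean(diag(C_sp))
  } else {
    C <- phylo_covariance(tree, tip_order = tbl$species)
  }
  groups <- droplevels(as.factor(tbl$group))
  log_mass <- log10(tbl$body_mass_g)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage %s: %s", stage, conditionMessage(e)), call. = FALSE)
    })
  }
  per_variable <- list()
  transformed <- list()
  for (var in c("dsr", "cer")) {
    y <- log10(tbl[[paste0(var, "_um_d")]])
    pg <- run_stage(paste0("pgls_", var), pgls_fit(y, log_mass, C))
    bc <- run_stage(paste0("boxcox_", var),
                    boxcox_transform(pg$residuals, groups = groups))
    transformed[[var]] <- bc$transformed
    per_variable[[var]] <- list(
      pgls = pg, boxcox = bc,
      anova = run_stage(paste0("anova_", var), anova_oneway(bc$transformed, groups)),
      pairwise_anova = run_stage(paste0("pairwise_anova_", var),
                                 pairwise_anova(bc$transformed, groups)),
      kruskal = run_stage(paste0("kruskal_", var), kruskal_wallis(bc$transformed, groups)),
      dunn = run_stage(paste0("dunn_", var), dunn_pairwise(bc$transformed, groups))
    )
  }
  Y <- cbind(dsr = transformed$dsr, cer = transformed$cer)
  manova <- run_stage("manova", manova_wilks(Y, groups))
  pw_manova <- run_stage("pairwise_manova", pairwise_manova(Y, groups))

  data_out <- tbl
  data_out$log_mass <- log_mass
  data_out$dsr_mass_corrected <- per_variable$dsr$pgls$residuals
  data_out$cer_mass_corrected <- per_variable$cer$pgls$residuals
  data_out$dsr_transformed <- transformed$dsr
  data_out$cer_transformed <- transformed$cer

  structure(
    list(manova = manova, pairwise_manova = pw_manova,
         per_variable = per_variable, data = data_out,
         options = list(exclude = exclude, assign = assign, unit = unit)),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %d observations, %d groups (%s unit)\n",
    nrow(x$data), x$manova$n_groups, x$options$unit
  ))
  cat(sprintf(
    "  MANOVA: Wilks' lambda %.3f, F(%g, %g) = %.2f, p = %.3g, partial eta^2 = %.3f\n",
    x$manova$wilks_lambda, x$manova$df1, x$manova$df2, x$manova$F_stat,
    x$manova$p_value, x$manova$partial_eta_sq
  ))
  for (var in names(x$per_variable)) {
    a <- x$per_variable[[var]]$anova
    cat(sprintf("  ANOVA %s: F(%d, %d) = %.2f, p = %.3g, partial eta^2 = %.3f\n",
                toupper(var), a$df1, a$df2, a$F_stat, a$p_value, a$partial_eta_sq))
  }
  invisible(x)
}

#' Tidy a group comparison into a long table of tests
#'
#' One row per test: the overall MANOVA, each univariate ANOVA and
#' Kruskal-Wallis test, and every pairwise contrast (MANOVA, ANOVA, Dunn)
#' with raw and FDR-adjusted p-values.
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return A tibble with columns `family`, `variable`, `group1`, `group2`,
#'   `statistic`, `p_value`, `p_adjusted`, `effect_size`.
#' @export
tidy.group_comparison <- function(x, ...) {
  rows <- list(
    tibble::tibble(family = "manova", variable = "dsr+cer",
                   group1 = NA_character_, group2 = NA_character_,
                   statistic = x$manova$F_stat, p_value = x$manova$p_value,
                   p_adjusted = NA_real_, effect_size = x$manova$partial_eta_sq),
    dplyr::mutate(x$pairwise_manova$pairs, family = "pairwise_manova",
                  variable = "dsr+cer", p_value = .data$p_raw,
                  effect_size = NA_real_)
  )
  for (var in names(x$per_variable)) {
    pv <- x$per_variable[[var]]
    rows <- c(rows, list(
      tibble::tibble(family = "anova", variable = var,
                     group1 = NA_character_, group2 = NA_character_,
                     statistic = pv$anova$F_stat, p_value = pv$anova$p_value,
                     p_adjusted = NA_real_, effect_size = pv$anova$partial_eta_sq),
      dplyr::mutate(pv$pairwise_anova$pairs, family = "pairwise_anova",
                    variable = var, p_value = .data$p_raw, effect_size = NA_real_),
      tibble::tibble(family = "kruskal_wallis", variable = var,
                     group1 = NA_character_, group2 = NA_character_,
                     statistic = pv$kruskal$H, p_value = pv$kruskal$p_value,
                     p_adjusted = NA_real_, effect_size = NA_real_),
      dplyr::mutate(pv$dunn$pairs, family = "dunn", variable = var,
                    p_value = .data$p_raw, effect_size = NA_real_)
    ))
  }
  out <- dplyr::bind_rows(rows)
  dplyr::select(out, "family", "variable", "group1", "group2",
                "statistic", "p_value", "p_adjusted", "effect_size")
}

#' Glance at a group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return One-row tibble summarizing the overall MANOVA.
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(
    wilks_lambda = x$manova$wilks_lambda, F_stat = x$manova$F_stat,
    df1 = x$manova$df1, df2 = x$manova$df2, p_value = x$manova$p_value,
    partial_eta_sq = x$manova$partial_eta_sq,
    n = x$manova$n, n_groups = x$manova$n_groups
  )
}

#' @rdname tidy.group_comparison
#' @export
tidy.crown_growth_summary <- function(x, ...) x$segments

#' @rdname glance.group_comparison
#' @export
glance.crown_growth_summary <- function(x, ...) {
  tibble::tibble(
    average_cer = x$average_cer, average_dsr = x$average_dsr,
    sum_x = x$sum_x, sum_y = x$sum_y, n_segments = nrow(x$segments),
    periodicity_assumption = x$periodicity_assumption
  )
}

#' Growth-rate scatter plots
#'
#' `plot_growth_rates()` draws the raw DSR-CER scatter per group on log
#' scales; `autoplot.group_comparison()` draws the body-mass-corrected
#' (PGLS residual) version.
#'
#' @param table A species table with `dsr_um_d`, `cer_um_d`, `group`.
#' @return A ggplot object.
#' @export
plot_growth_rates <- function(table) {
  ggplot2::ggplot(table, ggplot2::aes(x = .data$dsr_um_d, y = .data$cer_um_d,
                                      colour = .data$group)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "average DSR (µm/day)", y = "average CER (µm/day)",
                  colour = "group") +
    ggplot2::theme_minimal()
}

#' @param object A `group_comparison`.
#' @param ... Unused.
#' @rdname plot_growth_rates
#' @export
autoplot.group_comparison <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$dsr_mass_corrected,
                               y = .data$cer_mass_corrected,
                               colour = .data$group)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(x = "body mass-corrected log10 DSR (PGLS residual)",
                  y = "body mass-corrected log10 CER (PGLS residual)",
                  colour = "group") +
    ggplot2::theme_minimal()
}
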