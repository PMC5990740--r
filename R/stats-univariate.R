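#' One-way ANOVA with partial eta-squared
#'
#' Standard one-way decomposition via [stats::lm()], augmented with the
#' effect size partial eta^2 = SS_effect / (SS_effect + SS_error), which for
#' a one-way design equals F * df_h / (F * df_h + df_e). Zero within-group
#' variance with unequal means yields an infinite F, flagged rather than
#' hidden.
#'
#' @param y Numeric response.
#' @param groups Group labels (coercible to factor), one per observation.
#' @return A one-row tibble: `F_stat`, `df1`, `df2`, `p_value`,
#'   `partial_eta_sq`, `ss_effect`, `ss_error`.
#' @export
anova_oneway <- function(y, groups) {
  groups <- droplevels(as.factor(groups))
  stopifnot(length(y) == length(groups), nlevels(groups) >= 2L)
  fit <- stats::lm(y ~ groups)
  if (sum(stats::residuals(fit)^2) < 1e-12 * max(sum(y^2), 1)) {
    # zero within-group variance: flag rather than divide by zero
    ss_h <- sum(tapply(y, groups, length) * (tapply(y, groups, mean) - mean(y))^2)
    return(tibble::tibble(
      F_stat = if (ss_h > 0) Inf else 0,
      df1 = nlevels(groups) - 1L, df2 = length(y) - nlevels(groups),
      p_value = if (ss_h > 0) 0 else 1,
      partial_eta_sq = if (ss_h > 0) 1 else 0,
      ss_effect = ss_h, ss_error = 0
    ))
  }
  tab <- stats::anova(fit)
  ss_h <- tab$`Sum Sq`[1]; ss_e <- tab$`Sum Sq`[2]
  tibble::tibble(
    F_stat = tab$`F value`[1], df1 = tab$Df[1], df2 = tab$Df[2],
    p_value = tab$`Pr(>F)`[1],
    partial_eta_sq = if (ss_h + ss_e == 0) 0 else ss_h / (ss_h + ss_e),
    ss_effect = ss_h, ss_error = ss_e
  )
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-squared p-value on g - 1 df,
#' via [stats::kruskal.test()]. All-tied data give H = 0.
#'
#' @inheritParams anova_oneway
#' @return A one-row tibble: `H`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(y, groups) {
  groups <- droplevels(as.factor(groups))
  stopifnot(length(y) == length(groups), nlevels(groups) >= 2L)
  if (diff(range(y)) == 0) {
    return(tibble::tibble(H = 0, df = nlevels(groups) - 1L, p_value = 1))
  }
  kt <- stats::kruskal.test(y, groups)
  tibble::tibble(H = unname(kt$statistic), df = unname(kt$parameter),
                 p_value = kt$p.value)
}

#' Dunn pairwise rank comparisons with FDR correction
#'
#' Post-hoc pairwise z tests on mean midranks following a Kruskal-Wallis
#' test: z_ij = (Rbar_i - Rbar_j) / sqrt((N (N + 1) / 12 - T) (1/n_i +
#' 1/n_j)), where T = sum(t^3 - t) / (12 (N - 1)) over tie groups of size t.
#' Two-sided normal p-values, Benjamini-Hochberg adjusted over all pairs.
#'
#' @inheritParams anova_oneway
#' @return A `pairwise_result` with the z statistic per pair.
#' @export
dunn_pairwise <- function(y, groups) {
  groups <- droplevels(as.factor(groups))
  stopifnot(length(y) == length(groups), nlevels(groups) >= 2L)
  sizes <- table(groups)
  if (any(sizes == 0L)) stop("empty group")
  N <- length(y)
  r <- rank(y) # midranks
  ties <- table(y)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_ranks <- tapply(r, groups, mean)
  levs <- levels(groups)
  combos <- utils::combn(levs, 2L)
  rows <- purrr::map(seq_len(ncol(combos)), function(k) {
    g1 <- combos[1L, k]; g2 <- combos[2L, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / sizes[[g1]] + 1 / sizes[[g2]]))
    z <- if (se == 0) 0 else (mean_ranks[[g1]] - mean_ranks[[g2]]) / se
    tibble::tibble(group1 = g1, group2 = g2, statistic = z,
                   p_raw = 2 * stats::pnorm(-abs(z)))
  })
  pairs <- dplyr::bind_rows(rows)
  pairs$p_adjusted <- bh_fdr(pairs$p_raw)
  structure(list(pairs = pairs, p_matrix = pairs_to_matrix(pairs, levs)),
            class = "pairwise_result")
}

#' Pairwise group contrasts with FDR correction
#'
#' Post-hoc pairwise comparisons following a one-way ANOVA: two-sided t
#' tests on group means with the pooled within-group standard deviation
#' (error df = N - g over all groups, as in [stats::pairwise.t.test()] with
#' `pool.sd = TRUE`), Benjamini-Hochberg adjusted over all pairs; the
#' univariate counterpart of [pairwise_manova()].
#'
#' @inheritParams anova_oneway
#' @return A `pairwise_result` with the t statistic per pair.
#' @export
pairwise_anova <- function(y, groups) {
  groups <- droplevels(as.factor(groups))
  stopifnot(length(y) == length(groups), nlevels(groups) >= 2L)
  levs <- levels(groups)
  n <- tapply(y, groups, length)
  m <- tapply(y, groups, mean)
  ss_e <- sum(tapply(y, groups, function(v) sum((v - mean(v))^2)))
  df_e <- length(y) - nlevels(groups)
  s2p <- ss_e / df_e
  combos <- utils::combn(levs, 2L)
  rows <- purrr::map(seq_len(ncol(combos)), function(k) {
    g1 <- combos[1L, k]; g2 <- combos[2L, k]
    se <- sqrt(s2p * (1 / n[[g1]] + 1 / n[[g2]]))
    t_stat <- if (se == 0) 0 else (m[[g1]] - m[[g2]]) / se
    tibble::tibble(
      group1 = g1, group2 = g2, statistic = t_stat,
      p_raw = 2 * stats::pt(-abs(t_stat), df_e)
    )
  })
  pairs <- dplyr::bind_rows(rows)
  pairs$p_adjusted <- bh_fdr(pairs$p_raw)
  structure(list(pairs = pairs, p_matrix = pairs_to_matrix(pairs, levs)),
            class = "pairwise_result")
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values via [stats::p.adjust()], with input validation.
#' Adjusted values are monotone in the raw p-values, never smaller than
#' them, capped at 1, and the adjustment is idempotent.
#'
#' @param p Numeric vector of p-values in [0, 1]; `NA`s pass through.
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
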