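#' Balanced two-factor observations
#'
#' Container for a balanced two-way design with replication: factor A
#' (datasets) x factor B (models), with exactly `r >= 2` observations per
#' cell. In the packaged performance fixture the four performance parameters
#' (macro recall, macro precision, macro F1, mean accuracy) serve as the 4
#' replicates per (dataset, model) cell — the only reading consistent with
#' the published degrees of freedom (1, 3, 3, 24, 31).
#'
#' @param df data frame of observations.
#' @param a_col,b_col,value_col column names for factor A, factor B and the
#'   response.
#' @param scale `"percent"` or `"fraction"`, recorded for reporting.
#' @return a `leafcnn_factorial` list.
#' @export
factorial_observations <- function(df, a_col = "dataset", b_col = "model",
                                   value_col = "value",
                                   scale = c("percent", "fraction")) {
  scale <- match.arg(scale)
  stopifnot(is.data.frame(df), all(c(a_col, b_col, value_col) %in% names(df)))
  a <- factor(df[[a_col]], levels = unique(df[[a_col]]))
  b <- factor(df[[b_col]], levels = unique(df[[b_col]]))
  y <- as.numeric(df[[value_col]])
  if (anyNA(y)) stop_leafcnn("missing observations")
  tab <- table(a, b)
  r <- unique(as.vector(tab))
  if (length(r) != 1) stop_leafcnn("unbalanced design: unequal cell counts")
  if (r < 2) stop_leafcnn("replicates_per_cell must be >= 2")
  structure(list(a = a, b = b, y = y,
                 factor_a_levels = levels(a), factor_b_levels = levels(b),
                 replicates_per_cell = as.integer(r), scale = scale),
            class = "leafcnn_factorial")
}

#' Two-way ANOVA with replication
#'
#' Standard fixed-effects decomposition of a balanced two-factor design:
#' `SS_A = b*r * sum((mean_a - grand)^2)`, `SS_B` analogously,
#' `SS_AB` from cell means, `SS_within` from residuals about the cell means.
#' F statistics divide each effect mean square by the within mean square;
#' p-values and critical values come from the F distribution with
#' `(df_effect, df_within)` degrees of freedom.
#'
#' @param obs a `leafcnn_factorial`.
#' @param alpha significance level for the F-critical column (default 0.05).
#' @param a_label,b_label row names for the two factors in the output.
#' @return a `leafcnn_anova`: data frame with rows factor A, factor B,
#'   interaction, within and total; columns `SS`, `df`, `MS`, `F`, `p`,
#'   `F_critical`, `significance`.
#' @export
two_way_anova <- function(obs, alpha = 0.05,
                          a_label = "Dataset", b_label = "Models") {
  stopifnot(inherits(obs, "leafcnn_factorial"))
  y <- obs$y; a <- obs$a; b <- obs$b
  n <- length(y)
  if (stats::var(y) == 0) stop_leafcnn("degenerate: all observations equal")
  na <- nlevels(a); nb <- nlevels(b); r <- obs$replicates_per_cell
  grand <- mean(y)
  mean_a <- tapply(y, a, mean)
  mean_b <- tapply(y, b, mean)
  mean_ab <- tapply(y, list(a, b), mean)
  ss_a <- nb * r * sum((mean_a - grand)^2)
  ss_b <- na * r * sum((mean_b - grand)^2)
  ss_cells <- r * sum((mean_ab - grand)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  cell_of <- mean_ab[cbind(as.integer(a), as.integer(b))]
  ss_within <- sum((y - cell_of)^2)
  ss_total <- sum((y - grand)^2)
  df_a <- na - 1L; df_b <- nb - 1L; df_ab <- df_a * df_b
  df_within <- na * nb * (r - 1L); df_total <- n - 1L
  ms_within <- ss_within / df_within
  eff <- function(ss, df) {
    ms <- ss / df
    f <- ms / ms_within
    p <- stats::pf(f, df, df_within, lower.tail = FALSE)
    c(ss, df, ms, f, p, f_critical(df, df_within, alpha))
  }
  rows <- rbind(eff(ss_a, df_a), eff(ss_b, df_b), eff(ss_ab, df_ab),
                c(ss_within, df_within, ms_within, NA, NA, NA),
                c(ss_total, df_total, NA, NA, NA, NA))
  tab <- data.frame(source = c(a_label, b_label,
                               paste(a_label, "x", b_label),
                               "Within", "Total"),
                    SS = rows[, 1], df = as.integer(rows[, 2]),
                    MS = rows[, 3], F = rows[, 4], p = rows[, 5],
                    F_critical = rows[, 6], stringsAsFactors = FALSE)
  tab$significance <- ifelse(is.na(tab$p), "",
                             vapply(tab$p, function(p)
                               if (is.na(p)) "" else significance_band(p),
                               character(1)))
  structure(list(table = tab, alpha = alpha, scale = obs$scale),
            class = "leafcnn_anova")
}

#' @export
print.leafcnn_anova <- function(x, ...) {
  cat(sprintf("<two-way ANOVA with replication (%s scale, alpha %.2f)>\n",
              x$scale, x$alpha))
  tab <- x$table
  tab$SS <- signif(tab$SS, 6); tab$MS <- signif(tab$MS, 6)
  tab$F <- round(tab$F, 3); tab$p <- signif(tab$p, 3)
  tab$F_critical <- round(tab$F_critical, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Upper-alpha critical value of the F distribution
#'
#' @param df1,df2 numerator and denominator degrees of freedom (>= 1).
#' @param alpha tail probability in (0, 1).
#' @return the upper-`alpha` quantile, rounded to 3 decimals.
#' @export
f_critical <- function(df1, df2, alpha = 0.05) {
  if (!is_count(df1, 1) || !is_count(df2, 1))
    stop_leafcnn("df1 and df2 must be positive integers")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop_leafcnn("alpha must be in (0, 1)")
  round(stats::qf(1 - alpha, df1, df2), 3)
}

#' Significance band for a p-value
#'
#' Follows the published table footnote convention:
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `NS` otherwise.
#'
#' @param p a probability in `[0, 1]`.
#' @return one of `"***"`, `"**"`, `"*"`, `"NS"`.
#' @export
significance_band <- function(p) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1)
    stop_leafcnn("p must be a probability in [0, 1]")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "NS"
}

#' Write an ANOVA table as CSV and JSON
#' @param anova a `leafcnn_anova`.
#' @param stem output path without extension; writes `<stem>.csv` and
#'   `<stem>.json`.
#' @export
write_anova <- function(anova, stem) {
  stopifnot(inherits(anova, "leafcnn_anova"))
  write.csv(anova$table, paste0(stem, ".csv"), row.names = FALSE)
  jsonlite::write_json(anova$table, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}
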