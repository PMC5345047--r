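anova_table_row <- function(effect, ss, df_num, df_den, f, p) {
  data.frame(effect = effect, sum_sq = ss, df_num = df_num, df_den = df_den,
             statistic = f, p_value = p)
}

#' Two-way between-subjects ANOVA
#'
#' Fits `value ~ A * B` and reports the two main effects, the interaction and
#' the residual. Type-II sums of squares are used, so unbalanced designs are
#' handled sensibly and balanced designs reproduce the classical (Type-I)
#' partition exactly.
#'
#' @param table long-format data frame with one row per animal.
#' @param factors character vector of the two between-subjects factor column
#'   names, e.g. `c("genotype", "sex")`.
#' @param response name of the value column (default `"value"`).
#' @return data frame of class `anova_table`: one row per effect with
#'   `effect`, `sum_sq`, `df_num`, `df_den`, `statistic` (F), `p_value`.
#' @export
two_way_anova <- function(table, factors, response = "value") {
  assert_that(length(factors) == 2 && all(factors %in% names(table)),
              "factors must name two columns of the table")
  assert_that(response %in% names(table), "response column not found")
  a <- factor(table[[factors[1]]]); b <- factor(table[[factors[2]]])
  assert_that(nlevels(a) >= 2 && nlevels(b) >= 2,
              "each factor needs at least 2 observed levels")
  cells <- table(a, b)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop(sprintf(
      "interaction not estimable: empty cell(s) %s",
      paste(sprintf("(%s=%s, %s=%s)", factors[1], rownames(cells)[empty[, 1]],
                    factors[2], colnames(cells)[empty[, 2]]),
            collapse = ", ")), call. = FALSE)
  }
  d <- data.frame(y = table[[response]], A = a, B = b)
  # Type-II sums of squares by explicit model comparison; a vanishing
  # residual yields an infinite F rather than an error
  rss <- function(f) sum(lm(f, data = d)$residuals^2)
  rss_ab <- rss(y ~ A + B)
  rss_full <- rss(y ~ A * B)
  ss <- c(rss(y ~ B) - rss_ab,        # A adjusted for B
          rss(y ~ A) - rss_ab,        # B adjusted for A
          rss_ab - rss_full,          # interaction
          rss_full)
  ss <- pmax(ss, 0)
  df_num <- c(nlevels(a) - 1, nlevels(b) - 1,
              (nlevels(a) - 1) * (nlevels(b) - 1))
  df_den <- nrow(d) - nlevels(a) * nlevels(b)
  mse <- ss[4] / df_den
  f <- (ss[1:3] / df_num) / mse
  p <- pf(f, df_num, df_den, lower.tail = FALSE)
  eff_names <- c(factors, paste(factors, collapse = ":"))
  out <- rbind(
    anova_table_row(eff_names[1], ss[1], df_num[1], df_den, f[1], p[1]),
    anova_table_row(eff_names[2], ss[2], df_num[2], df_den, f[2], p[2]),
    anova_table_row(eff_names[3], ss[3], df_num[3], df_den, f[3], p[3]),
    anova_table_row("Residuals", ss[4], df_den, NA, NA, NA))
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Mixed-design (repeated-measures) ANOVA
#'
#' Univariate repeated-measures decomposition for one between-subjects factor
#' and one within-subjects factor: the between effect is tested against the
#' subject-within-group stratum, the within effect and the interaction
#' against the subject-by-within residual. For `g` groups, `n` subjects in
#' total and `k` within levels this reproduces the classical df pattern
#' (between: `F(g-1, n-g)`; within and interaction: tested on
#' `(k-1)(n-g)` denominator df). Sphericity is assumed; no correction is
#' applied.
#'
#' @param table long-format data frame: one row per (subject, within-level).
#' @param between,within column names of the between- and within-subjects
#'   factors.
#' @param subject subject id column (default `"animal_id"`).
#' @param response value column (default `"value"`).
#' @return data frame of class `anova_table` (between, within, interaction
#'   rows plus the two error strata).
#' @export
mixed_anova <- function(table, between, within, subject = "animal_id",
                        response = "value") {
  assert_that(all(c(between, within, subject, response) %in% names(table)),
              "between, within, subject and response must be table columns")
  d <- data.frame(y = table[[response]],
                  B = factor(table[[between]]),
                  W = factor(table[[within]]),
                  S = factor(table[[subject]]))
  k <- nlevels(d$W)
  assert_that(nlevels(d$B) >= 2, "need at least 2 between-subject groups")
  assert_that(k >= 2, "need at least 2 within-subject levels")
  counts <- table(d$S, d$W)
  bad <- rownames(counts)[rowSums(counts == 1) != k]
  if (length(bad) > 0)
    stop("incomplete within-factor data for subject(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  n_per_group <- rowSums(table(d$B, d$S) > 0)
  if (any(n_per_group < 2))
    stop("singleton group(s): ",
         paste(names(n_per_group)[n_per_group < 2], collapse = ", "),
         call. = FALSE)
  fit <- aov(y ~ B * W + Error(S), data = d)
  s <- summary(fit)
  bet <- s[["Error: S"]][[1]]
  wit <- s[["Error: Within"]][[1]]
  rn <- function(x) trimws(rownames(x))
  bi <- match("B", rn(bet)); bres <- match("Residuals", rn(bet))
  wi <- match("W", rn(wit)); ii <- match("B:W", rn(wit))
  wres <- match("Residuals", rn(wit))
  rows <- list(
    anova_table_row(between, bet[bi, "Sum Sq"], bet[bi, "Df"],
                    bet[bres, "Df"], bet[bi, "F value"], bet[bi, "Pr(>F)"]),
    anova_table_row("Subjects(Residuals)", bet[bres, "Sum Sq"],
                    bet[bres, "Df"], NA, NA, NA),
    anova_table_row(within, wit[wi, "Sum Sq"], wit[wi, "Df"],
                    wit[wres, "Df"], wit[wi, "F value"], wit[wi, "Pr(>F)"]),
    anova_table_row(paste(between, within, sep = ":"), wit[ii, "Sum Sq"],
                    wit[ii, "Df"], wit[wres, "Df"], wit[ii, "F value"],
                    wit[ii, "Pr(>F)"]),
    anova_table_row("Subjects:Within(Residuals)", wit[wres, "Sum Sq"],
                    wit[wres, "Df"], NA, NA, NA))
  out <- do.call(rbind, rows)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Tukey HSD all-pairs comparisons
#'
#' Studentized-range-adjusted pairwise comparisons after a one-way fit, with
#' family-wise two-tailed alpha control. Reports the mean difference, the
#' studentized-range statistic `q` (Tukey-Kramer standard error for unequal
#' group sizes), the adjusted p-value and the simultaneous confidence
#' interval.
#'
#' @param values numeric response vector.
#' @param groups group labels (>= 2 groups, each with >= 2 observations).
#' @param conf_level family-wise confidence level (default 0.95).
#' @return data frame of class `tukey_hsd`: `group1`, `group2`, `diff`, `q`,
#'   `p_adj`, `lwr`, `upr`.
#' @export
tukey_hsd <- function(values, groups, conf_level = 0.95) {
  g <- factor(groups)
  assert_that(nlevels(g) >= 2, "need at least 2 groups")
  n_g <- table(g)
  assert_that(all(n_g >= 2), "every group needs at least 2 observations")
  d <- data.frame(y = values, g = g)
  fit <- aov(y ~ g, data = d)
  mse <- sum(fit$residuals^2) / fit$df.residual
  if (mse <= .Machine$double.eps)
    warning("zero within-group variance: comparisons are degenerate")
  th <- TukeyHSD(fit, conf.level = conf_level)$g
  prs <- strsplit(rownames(th), "-", fixed = TRUE)
  g1 <- vapply(prs, `[`, "", 1); g2 <- vapply(prs, `[`, "", 2)
  se <- sqrt(mse / 2 * (1 / n_g[g1] + 1 / n_g[g2]))
  out <- data.frame(group1 = g1, group2 = g2,
                    diff = th[, "diff"],
                    q = abs(th[, "diff"]) / as.numeric(se),
                    p_adj = th[, "p adj"],
                    lwr = th[, "lwr"], upr = th[, "upr"])
  rownames(out) <- NULL
  class(out) <- c("tukey_hsd", "data.frame")
  out
}
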