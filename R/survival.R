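validate_survival_records <- function(records) {
  assert_that(is.data.frame(records) && nrow(records) >= 1,
              "records must be a non-empty data frame")
  assert_that(all(c("age_days", "event") %in% names(records)),
              "records need columns age_days and event")
  assert_that(all(records$age_days >= 0), "age_days must be >= 0")
  assert_that(all(records$event %in% c("death", "censored")),
              "event must be 'death' or 'censored'")
  invisible(records)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator `S(t) = prod(1 - d_i/n_i)` over event ages up to
#' `t`. The day an animal was found dead counts as its day of death; the day
#' the censoring criterion was met counts as its censoring age, and animals
#' censored at an age are still at risk for that age's deaths (deaths precede
#' censorings at ties — the standard product-limit convention).
#'
#' @param records data frame of survival records with columns `age_days` and
#'   `event` (`"death"`/`"censored"`), e.g. from [generate_survival_cohort()].
#' @return data frame of class `survival_curve`: `time` (starting at 0),
#'   `surv`, `at_risk`, `n_events`.
#' @export
kaplan_meier <- function(records) {
  validate_survival_records(records)
  fit <- survival::survfit(
    survival::Surv(records$age_days, records$event == "death") ~ 1)
  out <- data.frame(time = c(0, fit$time),
                    surv = c(1, fit$surv),
                    at_risk = c(fit$n, fit$n.risk),
                    n_events = c(0, fit$n.event))
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Gehan-Breslow generalized Wilcoxon test
#'
#' Weighted log-rank comparison of survival functions between groups with
#' weight equal to the total number at risk at each event time (the Gehan-
#' Breslow reading of "generalized Wilcoxon", which emphasizes early
#' deaths). The statistic is `U' V^-1 U` over the first `g - 1` groups, where
#' `U_j = sum_i w_i (d_ij - n_ij d_i / n_i)` and `V` accumulates the
#' hypergeometric variance of each event time, and is chi-square distributed
#' with `g - 1` degrees of freedom under the null.
#'
#' @param records survival records with a grouping column (default
#'   `genotype`) plus `age_days` and `event`.
#' @param group name of the grouping column.
#' @param pairwise if `TRUE`, additionally run the test on every pair of
#'   groups.
#' @return object of class `gehan_wilcoxon`: `chisq`, `df`, `p_value`,
#'   `method`, group sizes and event counts; with `pairwise = TRUE`, a
#'   `pairwise` data frame.
#' @export
generalized_wilcoxon <- function(records, group = "genotype",
                                 pairwise = FALSE) {
  validate_survival_records(records)
  assert_that(group %in% names(records),
              sprintf("records need a '%s' column", group))
  g <- factor(records[[group]])
  levs <- levels(g)
  assert_that(length(levs) >= 2, "need at least 2 non-empty groups")
  age <- records$age_days
  death <- records$event == "death"

  event_times <- sort(unique(age[death]))
  k <- length(levs)
  U <- numeric(k)
  V <- matrix(0, k, k)
  for (t in event_times) {
    at_risk <- age >= t
    n_i <- sum(at_risk)
    if (n_i == 0) next
    n_ij <- vapply(levs, function(l) sum(at_risk & g == l), 0)
    d_ij <- vapply(levs, function(l) sum(death & age == t & g == l), 0)
    d_i <- sum(d_ij)
    w <- n_i
    U <- U + w * (d_ij - n_ij * d_i / n_i)
    if (n_i > 1) {
      hv <- d_i * (n_i - d_i) / (n_i - 1)
      V <- V + w^2 * hv * (diag(n_ij / n_i, k) -
                           outer(n_ij, n_ij) / n_i^2)
    }
  }
  sub <- seq_len(k - 1)
  Vs <- V[sub, sub, drop = FALSE]
  Us <- U[sub]
  chisq <- if (length(event_times) == 0) {
    0
  } else if (abs(det(Vs)) < .Machine$double.eps) {
    if (any(diag(V) == 0))
      warning("degenerate group (no events and no at-risk overlap); ",
              "using a generalized inverse")
    drop(t(Us) %*% MASS::ginv(Vs) %*% Us)
  } else {
    drop(t(Us) %*% solve(Vs, Us))
  }
  chisq <- max(0, chisq)
  df <- k - 1
  out <- list(chisq = chisq, df = df,
              p_value = pchisq(chisq, df, lower.tail = FALSE),
              method = "Gehan-Breslow generalized Wilcoxon (weight = number at risk)",
              groups = levs,
              scores = setNames(U, levs),
              n = table(g),
              n_events = tapply(death, g, sum))
  if (pairwise) {
    prs <- utils::combn(levs, 2)
    out$pairwise <- do.call(rbind, apply(prs, 2, function(pr) {
      sel <- records[[group]] %in% pr
      r <- generalized_wilcoxon(records[sel, , drop = FALSE], group = group)
      data.frame(group1 = pr[1], group2 = pr[2], chisq = r$chisq,
                 df = r$df, p_value = r$p_value)
    }))
  }
  class(out) <- "gehan_wilcoxon"
  out
}

#' @export
print.gehan_wilcoxon <- function(x, ...) {
  cat(sprintf("%s\nchisq(%d) = %.4g, p = %.4g\n",
              x$method, x$df, x$chisq, x$p_value))
  if (!is.null(x$pairwise)) {
    cat("pairwise:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Post-weaning subgroup
#'
#' Drops every record — death or censoring — with an age below 29 days; the
#' remaining ages are not shifted (the analysis is simply re-run on the
#' subset of animals that survived to weaning).
#'
#' @param records survival records.
#' @return the subset of `records` with `age_days >= 29`.
#' @export
postwean_subset <- function(records) {
  validate_survival_records(records)
  out <- records[records$age_days >= 29, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a survival comparison as a machine-readable JSON report
#'
#' @param test a `gehan_wilcoxon` object.
#' @param path output JSON path.
#' @export
write_survival_json <- function(test, path) {
  stopifnot(inherits(test, "gehan_wilcoxon"))
  jsonlite::write_json(
    list(method = test$method, chisq = test$chisq, df = test$df,
         p_value = test$p_value, n = as.list(test$n),
         n_events = as.list(test$n_events)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
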