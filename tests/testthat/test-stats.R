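balanced_2x2 <- function(n = 5, sd = 1, a_shift = 0, b_shift = 0,
                         ab_shift = 0, seed = 1) {
  generate_factorial_measurements(factorial_sim_params(
    factors = list(A = c("a1", "a2"), B = c("b1", "b2")),
    effects = list(A = c(a2 = a_shift), B = c(b2 = b_shift),
                   "A:B" = c("a2:b2" = ab_shift)),
    residual_sd = sd, n_per_cell = n, seed = seed))
}

test_that("balanced two-way ANOVA decomposes the total sum of squares", {
  d <- balanced_2x2(n = 5, sd = 2, a_shift = 1.5, b_shift = -0.5,
                    ab_shift = 0.8, seed = 42)
  at <- two_way_anova(d, c("A", "B"))
  ss_total <- sum((d$value - mean(d$value))^2)
  expect_equal(sum(at$sum_sq), ss_total, tolerance = 1e-10)
  expect_equal(at$df_num, c(1, 1, 1, 16))
  expect_equal(at$df_den[1:3], rep(16, 3))

  # hand-computed SS for the main effect of A on balanced data
  mA <- tapply(d$value, d$A, mean)
  ss_a <- sum(table(d$A) * (mA - mean(d$value))^2)
  expect_equal(at$sum_sq[at$effect == "A"], ss_a, tolerance = 1e-10)
})

test_that("Type-II sums of squares match an independent implementation when unbalanced", {
  d <- balanced_2x2(n = 6, sd = 1, a_shift = 1, b_shift = 0.5, seed = 13)
  d <- d[-c(1, 2, 8), ]
  at <- two_way_anova(d, c("A", "B"))
  ca <- car::Anova(lm(value ~ A * B, data = d), type = "II")
  expect_equal(at$sum_sq[1:3], ca[c("A", "B", "A:B"), "Sum Sq"],
               tolerance = 1e-10)
  expect_equal(at$p_value[1:3], ca[c("A", "B", "A:B"), "Pr(>F)"],
               tolerance = 1e-10)
})

test_that("a vanishing residual drives the targeted F to infinity-scale values", {
  d <- balanced_2x2(n = 5, sd = 1e-9, a_shift = 3, seed = 7)
  at <- two_way_anova(d, c("A", "B"))
  expect_gt(at$statistic[at$effect == "A"], 1e10)
  expect_lt(at$statistic[at$effect == "B"], 10)
})

test_that("empty cells raise an explicit error naming the cell", {
  d <- balanced_2x2(n = 3, seed = 2)
  d <- d[!(d$A == "a2" & d$B == "b2"), ]
  expect_error(two_way_anova(d, c("A", "B")), "a2.*b2|empty cell")
})

test_that("for two groups the main-effect F equals the squared pooled t", {
  d <- generate_factorial_measurements(factorial_sim_params(
    factors = list(genotype = c("wt", "ko"), sex = c("f", "m")),
    effects = list(genotype = c(ko = 0.8)), residual_sd = 1,
    n_per_cell = 8, seed = 3))
  # one-factor reading: pool over sex with a plain two-sample t-test
  tt <- t.test(value ~ genotype, data = d, var.equal = TRUE)
  one <- two_way_anova(d, c("genotype", "sex"))
  # in the balanced design the genotype SS is orthogonal to sex, so compare
  # against a model with genotype only
  fit <- anova(lm(value ~ genotype, data = d))
  expect_equal(fit[["F value"]][1], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(one$sum_sq[one$effect == "genotype"], fit[["Sum Sq"]][1],
               tolerance = 1e-10)
})

test_that("ANOVA p-values are invariant to affine rescaling of the response", {
  d <- balanced_2x2(n = 6, sd = 1.5, a_shift = 1, seed = 9)
  at1 <- two_way_anova(d, c("A", "B"))
  d$value <- 3.7 * d$value - 11
  at2 <- two_way_anova(d, c("A", "B"))
  expect_equal(at1$p_value, at2$p_value, tolerance = 1e-10)
})

test_that("two-way ANOVA has calibrated type-I error under the null", {
  rejections <- vapply(1:1000, function(i) {
    d <- balanced_2x2(n = 20, sd = 1, seed = i)
    at <- two_way_anova(d, c("A", "B"))
    at$p_value[at$effect == "A"] < 0.05
  }, TRUE)
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

mixed_table <- function(n_per_group = 4, k = 3, b_shift = 0, w_slope = 0,
                        int = 0, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    subj <- sprintf("s%02d", seq_len(2 * n_per_group))
    grp <- rep(c("wt", "ko"), each = n_per_group)
    d <- expand.grid(animal_id = subj, time = paste0("t", seq_len(k)),
                     stringsAsFactors = FALSE)
    d$genotype <- grp[match(d$animal_id, subj)]
    tnum <- as.integer(sub("t", "", d$time))
    d$value <- b_shift * (d$genotype == "ko") + w_slope * tnum +
      int * (d$genotype == "ko") * tnum + rnorm(nrow(d), 0, sd)
    d
  })
}

test_that("mixed ANOVA reproduces the repeated-measures df pattern", {
  d <- mixed_table(n_per_group = 4, k = 3, b_shift = 1, w_slope = 0.5,
                   seed = 5)
  at <- mixed_anova(d, between = "genotype", within = "time")
  n_total <- 8
  expect_equal(at$df_num[at$effect == "genotype"], 1)
  expect_equal(at$df_den[at$effect == "genotype"], n_total - 2)
  expect_equal(at$df_num[at$effect == "time"], 2)
  expect_equal(at$df_den[at$effect == "time"], 2 * (n_total - 2))
  expect_equal(at$df_num[at$effect == "genotype:time"], 2)
  expect_equal(at$df_den[at$effect == "genotype:time"], 2 * (n_total - 2))
})

test_that("mixed ANOVA F values equal the explicit SS partition", {
  d <- mixed_table(n_per_group = 4, k = 3, b_shift = 0.7, w_slope = 0.4,
                   int = 0.3, sd = 1, seed = 8)
  at <- mixed_anova(d, between = "genotype", within = "time")
  # explicit partition with subjects as blocks
  k <- 3
  gm <- mean(d$value)
  subj_mean <- tapply(d$value, d$animal_id, mean)
  grp_of <- tapply(d$genotype, d$animal_id, function(x) x[1])
  grp_mean <- tapply(d$value, d$genotype, mean)
  time_mean <- tapply(d$value, d$time, mean)
  cell_mean <- tapply(d$value, list(d$genotype, d$time), mean)
  n_subj <- length(subj_mean)
  ss_b <- k * sum((grp_mean[as.character(grp_of)] - gm)^2)
  ss_subj <- k * sum((subj_mean - grp_mean[as.character(grp_of)])^2)
  ss_w <- n_subj * sum((time_mean - gm)^2)
  ss_cells <- 0
  for (g in rownames(cell_mean)) for (t in colnames(cell_mean)) {
    n_gt <- sum(d$genotype == g & d$time == t)
    ss_cells <- ss_cells + n_gt *
      (cell_mean[g, t] - grp_mean[g] - time_mean[t] + gm)^2
  }
  ss_total <- sum((d$value - gm)^2)
  ss_resid <- ss_total - ss_b - ss_subj - ss_w - ss_cells
  f_b <- unname((ss_b / 1) / (ss_subj / (n_subj - 2)))
  f_w <- unname((ss_w / (k - 1)) / (ss_resid / ((k - 1) * (n_subj - 2))))
  f_i <- unname((ss_cells / (k - 1)) / (ss_resid / ((k - 1) * (n_subj - 2))))
  expect_equal(at$statistic[at$effect == "genotype"], f_b, tolerance = 1e-8)
  expect_equal(at$statistic[at$effect == "time"], f_w, tolerance = 1e-8)
  expect_equal(at$statistic[at$effect == "genotype:time"], f_i,
               tolerance = 1e-8)
})

test_that("a zero within-effect carries zero sum of squares in the noiseless limit", {
  d <- mixed_table(n_per_group = 4, k = 3, b_shift = 2, w_slope = 0,
                   sd = 0, seed = 4)
  # subject-level intercepts keep the between stratum non-degenerate
  ints <- withr::with_seed(2, rnorm(8, 0, 1))
  d$value <- d$value + ints[match(d$animal_id, unique(d$animal_id))]
  at <- mixed_anova(d, between = "genotype", within = "time")
  expect_lt(at$sum_sq[at$effect == "time"], 1e-16)
  expect_lt(at$sum_sq[at$effect == "genotype:time"], 1e-16)
})

test_that("mixed ANOVA validates completeness and group sizes", {
  d <- mixed_table(n_per_group = 3, k = 3, seed = 6)
  expect_error(mixed_anova(d[-1, ], between = "genotype", within = "time"),
               "incomplete")
  d1 <- mixed_table(n_per_group = 1, k = 3, seed = 6)
  expect_error(mixed_anova(d1, between = "genotype", within = "time"),
               "singleton")
})

test_that("Tukey HSD matches the studentized-range distribution", {
  withr::with_seed(10, {
    v <- c(rnorm(8, 0), rnorm(8, 1.2), rnorm(8, 0.4))
    g <- rep(c("a", "b", "c"), each = 8)
  })
  out <- tukey_hsd(v, g)
  # independent evaluation of the adjusted p from q via ptukey
  fit <- aov(v ~ factor(g))
  mse <- sum(fit$residuals^2) / fit$df.residual
  for (i in seq_len(nrow(out))) {
    m1 <- mean(v[g == out$group1[i]]); m2 <- mean(v[g == out$group2[i]])
    q <- abs(m1 - m2) / sqrt(mse / 8)
    expect_equal(out$q[i], q, tolerance = 1e-10)
    expect_equal(out$p_adj[i],
                 ptukey(q, nmeans = 3, df = 21, lower.tail = FALSE),
                 tolerance = 1e-8)
    # Tukey-adjusted p is never below the unadjusted pairwise t-test p
    # computed with the same pooled error term
    t_stat <- abs(m1 - m2) / sqrt(mse * (1 / 8 + 1 / 8))
    p_t <- 2 * pt(t_stat, df = 21, lower.tail = FALSE)
    expect_gte(out$p_adj[i] + 1e-12, p_t)
  }

  # identical groups: zero difference, adjusted p = 1
  v2 <- rep(c(1, 2, 3), 2); g2 <- rep(c("x", "y"), each = 3)
  out2 <- tukey_hsd(v2, g2)
  expect_equal(out2$diff, 0)
  expect_equal(out2$p_adj, 1)

  # degenerate zero variance is flagged
  expect_warning(tukey_hsd(rep(c(1, 2), each = 3), rep(c("x", "y"), each = 3)),
                 "degenerate")
})

test_that("factorial generator honours exact cell means in the noiseless limit", {
  p <- factorial_sim_params(factors = list(genotype = c("wt", "ko"),
                                           sex = c("f", "m")),
                            effects = list(genotype = c(ko = 1.5),
                                           sex = c(m = -0.5),
                                           "genotype:sex" = c("ko:m" = 2)),
                            grand_mean = 10, residual_sd = 0,
                            n_per_cell = 3, seed = 1)
  d <- generate_factorial_measurements(p)
  cm <- tapply(d$value, list(d$genotype, d$sex), mean)
  expect_equal(cm["wt", "f"], 10)
  expect_equal(cm["ko", "f"], 11.5)
  expect_equal(cm["wt", "m"], 9.5)
  expect_equal(cm["ko", "m"], 13)
  expect_identical(generate_factorial_measurements(p),
                   generate_factorial_measurements(p))
})

test_that("simulated genotype shifts reach closed-form noncentral-F power", {
  n <- 15; delta <- 1
  hits <- vapply(1:400, function(i) {
    d <- generate_factorial_measurements(factorial_sim_params(
      factors = list(genotype = c("wt", "ko"), sex = c("f", "m")),
      effects = list(genotype = c(ko = delta)), residual_sd = 1,
      n_per_cell = n, seed = 1000 + i))
    at <- two_way_anova(d, c("genotype", "sex"))
    at$p_value[at$effect == "genotype"] < 0.05
  }, TRUE)
  n_total <- 4 * n
  ncp <- n_total * (delta / 2)^2   # balanced two-level contrast
  fcrit <- qf(0.95, 1, n_total - 4)
  power <- 1 - pf(fcrit, 1, n_total - 4, ncp = ncp)
  mc_se <- sqrt(power * (1 - power) / 400)
  expect_lt(abs(mean(hits) - power), 3 * mc_se + 0.01)
})
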