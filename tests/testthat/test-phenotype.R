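make_session <- function(pa_mag, pp_mags, block_mag = 999) {
  # constant reading vectors so magnitudes are exact
  trials <- data.frame(order_index = seq_len(8 + length(pa_mag) +
                                             length(pp_mags)))
  types <- c(rep("pulse_alone_block", 4),
             rep("pulse_alone", length(pa_mag)),
             rep("prepulse_high", length(pp_mags)),
             rep("pulse_alone_block", 4))
  mags <- c(rep(block_mag, 4), pa_mag, pp_mags, rep(block_mag, 4))
  trials <- data.frame(order_index = seq_along(types), trial_type = types,
                       level = ifelse(types == "prepulse_high", "high", NA),
                       readings = I(lapply(mags, function(m) rep(m, 10))))
  startle_session("x", trials)
}

test_that("startle magnitude is the mean of the readings", {
  expect_equal(startle_magnitude(rep(5, 65)), 5)
  expect_equal(startle_magnitude(c(0, 10)), 5)
  expect_error(startle_magnitude(numeric(0)), "non-empty")
  set.seed(7)
  r <- rnorm(100)
  expect_equal(startle_magnitude(r), sum(r) / 100, tolerance = 1e-12)
})

test_that("%PPI uses middle-block pulse-alone baseline and is not clipped", {
  s <- make_session(pa_mag = rep(100, 16), pp_mags = rep(40, 10))
  out <- percent_ppi(s)
  expect_equal(unname(out$ppi["high"]), 60)
  expect_equal(out$startle_magnitude, 100)  # 999-blocks excluded

  s2 <- make_session(pa_mag = rep(100, 16), pp_mags = rep(100, 10))
  expect_equal(unname(percent_ppi(s2)$ppi["high"]), 0)

  # facilitation: PP > PA gives a negative value, reported as-is
  s3 <- make_session(pa_mag = rep(50, 16), pp_mags = rep(80, 10))
  expect_lt(unname(percent_ppi(s3)$ppi["high"]), 0)

  # zero baseline: undefined, with warning
  s4 <- make_session(pa_mag = rep(0, 16), pp_mags = rep(1, 4))
  expect_warning(out4 <- percent_ppi(s4), "zero")
  expect_true(is.na(out4$ppi["high"]))
})

test_that("simulated sessions reproduce the programmed %PPI", {
  # noiseless: exact at every level (weights 1/3, 2/3, 1 at effect 0.6)
  s <- generate_startle_session(effect = 0.6, noise_sd = 0, seed = 5)
  out <- percent_ppi(s)
  expect_equal(unname(out$ppi[c("low", "mid", "high")]), c(20, 40, 60),
               tolerance = 1e-9)
  # zero effect: %PPI 0 at all levels
  s0 <- generate_startle_session(effect = 0, noise_sd = 0, seed = 5)
  expect_equal(max(abs(percent_ppi(s0)$ppi)), 0, tolerance = 1e-9)
  # determinism
  expect_identical(generate_startle_session(effect = .4, noise_sd = 2, seed = 9),
                   generate_startle_session(effect = .4, noise_sd = 2, seed = 9))
})

test_that("stochastic startle sessions recover the generating %PPI", {
  top <- vapply(1:400, function(i) {
    s <- generate_startle_session(effect = 0.6, noise_sd = 10, seed = i)
    unname(percent_ppi(s)$ppi["high"])
  }, 0)
  se <- sd(top) / sqrt(length(top))
  expect_lt(abs(mean(top) - 60), 2 * se + 0.2)
})

test_that("odor scores follow the stated trial pairs and exclusion rule", {
  s <- odor_session("a", c(10, 6, 2, 8, 5, 2, 9), 12)
  sc <- odor_scores(list(s))$scores
  expect_equal(sc$hab_first, 9)
  expect_equal(sc$hab_last, 2)
  expect_equal(sc$dishab_last, 2)
  expect_equal(sc$dishab_novel, 8.5)

  flat <- odor_session("b", rep(4, 7), 10)
  scf <- odor_scores(list(flat))$scores
  expect_equal(scf$hab_first, scf$hab_last)
  expect_equal(scf$dishab_last, scf$dishab_novel)

  # two or fewer investigations: excluded
  lazy <- odor_session("c", rep(0, 7), 2)
  out <- odor_scores(list(s, lazy))
  expect_equal(out$excluded$animal_id, "c")
  expect_equal(nrow(out$scores), 1)
  # lowering the bar never excludes more animals
  out0 <- odor_scores(list(s, lazy), min_investigations = 0)
  expect_lte(nrow(out0$excluded), nrow(out$excluded))

  expect_error(odor_session("d", rep(1, 6), 5), "7 trials")
})

test_that("generated odor sessions recover effects and exercise the filter", {
  # exactly the non-engaged animals fail the filter
  ss <- generate_odor_sessions(10, engaged_fraction = 0.8,
                               habituation_effect = 0.5,
                               dishabituation_effect = 0.5, seed = 3)
  out <- odor_scores(ss)
  expect_equal(nrow(out$scores), 8)
  expect_equal(nrow(out$excluded), 2)

  # noiseless zero effects: flat investigation, zero score differences
  s0 <- generate_odor_sessions(3, habituation_effect = 0,
                               dishabituation_effect = 0, seed = 1)
  sc0 <- odor_scores(s0)$scores
  expect_equal(sc0$hab_first, sc0$hab_last, tolerance = 1e-12)

  # stochastic recovery of the generating effects
  ss2 <- generate_odor_sessions(200, habituation_effect = 0.7,
                                dishabituation_effect = 0.5,
                                base_time_s = 10, noise_sd = 0.8, seed = 11)
  sc <- odor_scores(ss2)$scores
  h_est <- 1 - sc$hab_last / sc$hab_first
  d_est <- (sc$dishab_novel - sc$dishab_last) / (10 - sc$dishab_last)
  expect_lt(abs(mean(h_est) - 0.7),
            2 * sd(h_est) / sqrt(length(h_est)) + 0.02)
  expect_lt(abs(mean(d_est) - 0.5),
            2 * sd(d_est) / sqrt(length(d_est)) + 0.02)
})

test_that("hot-plate latencies are clipped at the cutoff then averaged", {
  expect_equal(hotplate_latency(c(10, 20, 30)), 20)
  expect_warning(out <- hotplate_latency(c(40, 40, 40)), "clip")
  expect_equal(out, 30)
  expect_equal(hotplate_latency(12), 12)
  expect_error(hotplate_latency(c(-1, 5)), "> 0")
  expect_error(hotplate_latency(rep(10, 4)), "1-3")
})

test_that("foot-slip scores are plain means over all trials", {
  expect_equal(footslip_score(c(0, 0, 0)), 0)
  expect_equal(footslip_score(c(1, 2, 3)), 2)
  set.seed(4)
  counts <- rpois(9, 3)  # mouse protocol: 3 trials x 3 beams
  expect_equal(footslip_score(counts), sum(counts) / 9, tolerance = 1e-12)
  expect_error(footslip_score(c(-1, 2)), "non-negative")
  expect_error(footslip_score(c(1.5, 2)), "integers")
})

test_that("densitometric normalization sets the control mean to exactly 1", {
  rec <- data.frame(sample_id = 1:6,
                    genotype = rep(c("+/+", "-/-"), each = 3),
                    target_band = c(5, 5, 5, 2, 2, 2),
                    loading_band = rep(2.5, 6))
  out <- densitometry_normalize(rec)
  expect_equal(out$relative_expression[1:3], rep(1, 3))
  expect_equal(out$relative_expression[4:6], rep(0.4, 3))

  # null protein in knockouts
  rec$target_band[4:6] <- 0
  expect_equal(densitometry_normalize(rec)$relative_expression[4:6],
               rep(0, 3))

  # conservation property on random tables
  set.seed(9)
  r2 <- data.frame(sample_id = 1:20,
                   genotype = sample(c("+/+", "+/-", "-/-"), 20, TRUE),
                   target_band = runif(20, 0.1, 10),
                   loading_band = runif(20, 0.5, 5))
  r2$genotype[1:3] <- "+/+"
  out2 <- densitometry_normalize(r2)
  expect_equal(mean(out2$relative_expression[out2$genotype == "+/+"]), 1,
               tolerance = 1e-12)
  expect_error(densitometry_normalize(r2, control_genotype = "xx"),
               "control")
})
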