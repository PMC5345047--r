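#' Simulate one acoustic-startle session
#'
#' Emulates the standard session layout: a block of four pulse-alone trials
#' at session start and end (flagged `pulse_alone_block`, excluded from
#' magnitude statistics), and between them, in pseudorandom order, the
#' middle-block pulse-alone trials plus the prepulse trials. Each trial's
#' reading vector is a peaked startle waveform scaled so that pulse-alone
#' trials have mean magnitude `baseline_magnitude` and prepulse trials at
#' level `k` of `L` have mean `baseline_magnitude * (1 - effect * k/L)`
#' (inhibition weight increasing with prepulse intensity), plus Gaussian
#' sample noise.
#'
#' @param n_pulse_alone number of middle-block pulse-alone trials (default 16).
#' @param prepulse_levels character or numeric labels of the prepulse levels,
#'   ordered from low to high (default `c("low", "mid", "high")`).
#' @param n_per_level prepulse trials per level (default 10).
#' @param reading_length number of 1-ms samples per reading vector; 65 or 100
#'   by species convention (configurable).
#' @param effect generating PPI fraction at the top level, in `[0, 1]`.
#' @param noise_sd per-sample Gaussian noise (instrument units).
#' @param baseline_magnitude mean pulse-alone magnitude (instrument units).
#' @param animal_id identifier stored in the session.
#' @param seed integer seed.
#' @return a [startle_session()].
#' @export
generate_startle_session <- function(n_pulse_alone = 16L,
                                     prepulse_levels = c("low", "mid", "high"),
                                     n_per_level = 10L,
                                     reading_length = 100L,
                                     effect = 0.6,
                                     noise_sd = 0,
                                     baseline_magnitude = 100,
                                     animal_id = "sim",
                                     seed = 1L) {
  assert_that(reading_length %in% c(65L, 100L) || reading_length > 0,
              "reading_length must be a positive count")
  assert_that(effect >= 0 && effect <= 1, "effect must lie in [0, 1]")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  L <- length(prepulse_levels)
  local_seed(seed, {
    mid_types <- c(rep("pulse_alone", n_pulse_alone),
                   rep(paste0("prepulse_", prepulse_levels),
                       each = n_per_level))
    mid_levels <- c(rep(NA_character_, n_pulse_alone),
                    rep(as.character(prepulse_levels), each = n_per_level))
    ord <- sample(length(mid_types))
    types <- c(rep("pulse_alone_block", 4L), mid_types[ord],
               rep("pulse_alone_block", 4L))
    levels <- c(rep(NA_character_, 4L), mid_levels[ord],
                rep(NA_character_, 4L))
    # peaked waveform normalized to unit mean so trial magnitude equals the
    # programmed mean exactly in the noiseless limit
    i <- seq_len(reading_length)
    tpl <- exp(-0.5 * ((i - 0.2 * reading_length) /
                       (0.15 * reading_length))^2)
    tpl <- tpl / mean(tpl)
    w <- setNames(seq_len(L) / L, as.character(prepulse_levels))
    readings <- vector("list", length(types))
    for (t in seq_along(types)) {
      m <- if (is.na(levels[t])) baseline_magnitude
           else baseline_magnitude * (1 - effect * w[levels[t]])
      readings[[t]] <- m * tpl +
        if (noise_sd > 0) rnorm(reading_length, 0, noise_sd) else 0
    }
    startle_session(animal_id,
                    data.frame(order_index = seq_along(types),
                               trial_type = types, level = levels,
                               readings = I(readings)))
  })
}

#' Simulate odor habituation/dishabituation sessions
#'
#' Engaged animals start each odor block at an investigation level that
#' declines within the block by `habituation_effect` (the third presentation
#' is `1 - habituation_effect` times the first) and recovers at each odor
#' switch by `dishabituation_effect` of the lost interest (a fraction of the
#' gap back to the baseline time). Non-engaged animals (a
#' `1 - engaged_fraction` share, rounded) register two or fewer
#' investigations across the session, exercising the engagement exclusion.
#'
#' @param n_animals number of sessions.
#' @param engaged_fraction fraction of animals engaging in the task.
#' @param habituation_effect,dishabituation_effect generating effects in
#'   `[0, 1]`.
#' @param base_time_s baseline investigation time (s) of trial 1.
#' @param noise_sd additive Gaussian noise on per-trial times (s); results
#'   are truncated at 0.
#' @param seed integer seed.
#' @return list of [odor_session()]s; non-engaged sessions come last.
#' @export
generate_odor_sessions <- function(n_animals,
                                   engaged_fraction = 1,
                                   habituation_effect = 0.6,
                                   dishabituation_effect = 0.6,
                                   base_time_s = 10,
                                   noise_sd = 0,
                                   seed = 1L) {
  assert_that(engaged_fraction >= 0 && engaged_fraction <= 1,
              "engaged_fraction must lie in [0, 1]")
  assert_that(habituation_effect >= 0 && habituation_effect <= 1 &&
              dishabituation_effect >= 0 && dishabituation_effect <= 1,
              "effects must lie in [0, 1]")
  h <- habituation_effect; d <- dishabituation_effect
  n_eng <- round(n_animals * engaged_fraction)
  local_seed(seed, {
    sessions <- vector("list", n_animals)
    for (a in seq_len(n_animals)) {
      id <- sprintf("animal_%02d", a)
      if (a <= n_eng) {
        t <- numeric(7)
        s1 <- base_time_s
        t[1:3] <- s1 * c(1, 1 - h / 2, 1 - h)
        s2 <- t[3] + d * (base_time_s - t[3])
        t[4:6] <- s2 * c(1, 1 - h / 2, 1 - h)
        t[7] <- t[6] + d * (base_time_s - t[6])
        if (noise_sd > 0) t <- pmax(0, t + rnorm(7, 0, noise_sd))
        sessions[[a]] <- odor_session(id, t, 7L + rpois(1, 5))
      } else {
        n_inv <- sample(0:2, 1)
        t <- numeric(7)
        if (n_inv > 0)
          t[sample(7, n_inv)] <- runif(n_inv, 0, 0.5)
        sessions[[a]] <- odor_session(id, t, n_inv)
      }
    }
    sessions
  })
}
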