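#' Startle session container
#'
#' A startle session holds one trial table per animal. Reading vectors are
#' the 1-ms force-transducer samples collected from stimulus onset (65 or 100
#' samples by species convention). Trial types: `pulse_alone_block` (the
#' blocks of four pulse-alone trials at session start and end, excluded from
#' magnitude statistics), `pulse_alone` (the middle-block pulse-alone trials
#' that define baseline startle), and `prepulse_<level>` trials.
#'
#' @param animal_id animal identifier.
#' @param trials data frame with columns `order_index`, `trial_type`, `level`
#'   (`NA` for pulse-alone trials) and a list column `readings`.
#' @return object of class `startle_session`.
#' @export
startle_session <- function(animal_id, trials) {
  assert_that(is.data.frame(trials) &&
              all(c("order_index", "trial_type", "readings") %in%
                  names(trials)),
              "trials must have order_index, trial_type and readings")
  lens <- lengths(trials$readings)
  assert_that(all(lens > 0) && length(unique(lens)) == 1,
              "reading vectors must be non-empty and of equal length")
  structure(list(animal_id = animal_id, trials = trials),
            class = "startle_session")
}

#' Startle magnitude of one trial
#'
#' Arithmetic mean of the 1-ms readings collected from stimulus onset.
#'
#' @param readings numeric vector of force samples.
#' @return mean force (instrument units).
#' @export
startle_magnitude <- function(readings) {
  assert_that(is.numeric(readings) && length(readings) > 0,
              "readings must be a non-empty numeric vector")
  mean(readings)
}

#' Percent prepulse inhibition per level
#'
#' Baseline startle `PA` is the mean magnitude of the middle-block
#' pulse-alone trials (the four-trial blocks at session start and end measure
#' habituation, not baseline, and are excluded). For each prepulse level,
#' `%PPI = 100 * (PA - PP) / PA` where `PP` is the mean magnitude over that
#' level's trials. Negative values (facilitation) are reported as-is, never
#' clipped.
#'
#' @param session a [startle_session()].
#' @return list with `ppi` (named numeric, one entry per level; `NA` for a
#'   missing level or when `PA` is zero) and `startle_magnitude` (`PA`).
#' @export
percent_ppi <- function(session) {
  stopifnot(inherits(session, "startle_session"))
  tr <- session$trials
  mag <- vapply(tr$readings, startle_magnitude, 0)
  pa_idx <- tr$trial_type == "pulse_alone"
  assert_that(any(pa_idx), "session has no middle-block pulse-alone trials")
  pa <- mean(mag[pa_idx])
  levels <- unique(tr$level[!is.na(tr$level)])
  ppi <- setNames(rep(NA_real_, length(levels)), levels)
  if (pa == 0) {
    warning("baseline startle magnitude is zero; %PPI undefined")
  } else {
    for (lv in levels) {
      pp <- mean(mag[!is.na(tr$level) & tr$level == lv])
      ppi[as.character(lv)] <- 100 * (pa - pp) / pa
    }
  }
  list(ppi = ppi, startle_magnitude = pa)
}

#' Odor session container
#'
#' @param animal_id animal identifier.
#' @param investigation_time_s numeric vector of exactly 7 per-trial
#'   investigation times (s, >= 0). Odor schedule: trials 1-3 odor A,
#'   4-6 odor B, 7 odor C.
#' @param n_investigations total number of investigations across the session
#'   (used by the engagement exclusion rule).
#' @return object of class `odor_session`.
#' @export
odor_session <- function(animal_id, investigation_time_s, n_investigations) {
  assert_that(length(investigation_time_s) == 7,
              "an odor session has exactly 7 trials")
  assert_that(all(investigation_time_s >= 0),
              "investigation times must be >= 0")
  assert_that(n_investigations >= 0, "n_investigations must be >= 0")
  structure(list(animal_id = animal_id,
                 investigation_time_s = as.numeric(investigation_time_s),
                 n_investigations = as.integer(n_investigations)),
            class = "odor_session")
}

#' Odor habituation / dishabituation scores
#'
#' Habituation compares the average investigation time of the first
#' presentations of odors A and B (trials 1 and 4) with that of their last
#' presentations (trials 3 and 6); dishabituation compares the last
#' presentations (trials 3 and 6) with the first presentations of the
#' subsequent novel odors (trials 4 and 7). Animals that did not engage in
#' the task (`n_investigations` below `min_investigations`, default: two or
#' fewer investigations across the session) are excluded and listed.
#'
#' @param sessions list of [odor_session()]s.
#' @param min_investigations minimum session-wide investigation count for
#'   inclusion (default 3).
#' @return list with `scores` (data frame: `animal_id`, `hab_first`
#'   = mean(T1, T4), `hab_last` = mean(T3, T6), `dishab_last` = mean(T3, T6),
#'   `dishab_novel` = mean(T4, T7)) and `excluded` (data frame: `animal_id`,
#'   `reason`).
#' @export
odor_scores <- function(sessions, min_investigations = 3) {
  if (inherits(sessions, "odor_session")) sessions <- list(sessions)
  assert_that(all(vapply(sessions, inherits, TRUE, "odor_session")),
              "sessions must be odor_session objects")
  rows <- list(); excl <- list()
  for (s in sessions) {
    if (s$n_investigations < min_investigations) {
      excl[[length(excl) + 1]] <- data.frame(
        animal_id = s$animal_id,
        reason = sprintf("%d investigations (minimum %d)",
                         s$n_investigations, min_investigations))
      next
    }
    t <- s$investigation_time_s
    rows[[length(rows) + 1]] <- data.frame(
      animal_id = s$animal_id,
      hab_first = mean(t[c(1, 4)]), hab_last = mean(t[c(3, 6)]),
      dishab_last = mean(t[c(3, 6)]), dishab_novel = mean(t[c(4, 7)]))
  }
  empty_sc <- data.frame(animal_id = character(0), hab_first = numeric(0),
                         hab_last = numeric(0), dishab_last = numeric(0),
                         dishab_novel = numeric(0))
  empty_ex <- data.frame(animal_id = character(0), reason = character(0))
  list(scores = if (length(rows)) do.call(rbind, rows) else empty_sc,
       excluded = if (length(excl)) do.call(rbind, excl) else empty_ex)
}

#' Mean hot-plate response latency with cutoff
#'
#' Latencies are capped at the cutoff (the trial ends when the animal
#' responds or the cutoff is reached, whichever comes first) and then
#' averaged over the 1-3 trials.
#'
#' @param trials numeric vector of 1-3 response latencies (s, > 0).
#' @param cutoff_s trial cutoff in seconds (default 30).
#' @return mean latency (s).
#' @export
hotplate_latency <- function(trials, cutoff_s = 30) {
  assert_that(is.numeric(trials) && length(trials) >= 1 &&
              length(trials) <= 3, "1-3 latency trials expected")
  assert_that(all(trials > 0), "latencies must be > 0")
  if (any(trials > cutoff_s)) {
    warning(sprintf("%d latencies exceed the %g s cutoff; clipped",
                    sum(trials > cutoff_s), cutoff_s))
    trials <- pmin(trials, cutoff_s)
  }
  mean(trials)
}

#' Mean foot slips per balance-beam traverse
#'
#' Foot slips are counted over the 80 cm traverse toward the shelter and
#' averaged per trial (all trials and beams of one animal pooled).
#'
#' @param trials integer vector of per-trial foot-slip counts (>= 0).
#' @return mean slips per trial.
#' @export
footslip_score <- function(trials) {
  assert_that(is.numeric(trials) && length(trials) >= 1,
              "at least one trial required")
  assert_that(all(trials >= 0) && all(trials == round(trials)),
              "slip counts must be non-negative integers")
  mean(trials)
}

#' Densitometric normalization against a loading control
#'
#' Each sample's target-band intensity is divided by its loading-control band
#' (e.g. GAPDH or actin); the resulting ratios are then expressed relative to
#' the mean ratio of the control genotype, whose mean is therefore exactly
#' 1.0.
#'
#' @param records data frame with columns `sample_id`, `genotype`,
#'   `target_band`, `loading_band` (`loading_band` > 0).
#' @param control_genotype genotype label of the control group (default
#'   `"+/+"`).
#' @return `records` with added columns `ratio` and `relative_expression`.
#' @export
densitometry_normalize <- function(records, control_genotype = "+/+") {
  assert_that(is.data.frame(records) &&
              all(c("sample_id", "genotype", "target_band", "loading_band")
                  %in% names(records)),
              "records must have sample_id, genotype, target_band, loading_band")
  assert_that(all(records$loading_band > 0),
              "loading-control band intensities must be > 0")
  ctrl <- records$genotype == control_genotype
  assert_that(any(ctrl),
              sprintf("no records of control genotype '%s'", control_genotype))
  records$ratio <- records$target_band / records$loading_band
  records$relative_expression <- records$ratio / mean(records$ratio[ctrl])
  records
}
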