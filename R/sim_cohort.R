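#' Parameters for the synthetic survival cohort
#'
#' Ages at death follow a piecewise-exponential hazard per genotype with a
#' change-point at day 29 (the weaning cut used by the post-weaning subgroup
#' analysis), mirroring colonies in which mortality concentrates before
#' weaning. Observation is administratively censored at `max_followup_days`;
#' an additional random fraction of animals is censored earlier (transfer out
#' of the colony).
#'
#' @param genotypes genotype labels (e.g. `c("+/+", "+/-", "-/-")`).
#' @param n_per_group animals per genotype.
#' @param pre_wean_hazard,post_wean_hazard named numeric vectors (per
#'   genotype, names matching `genotypes`) of daily hazards before/after day
#'   29 (>= 0).
#' @param censor_rate fraction of animals censored at a uniform random age
#'   before `max_followup_days`, in `[0, 1]`.
#' @param max_followup_days administrative censoring age (days).
#' @param seed integer seed.
#' @return object of class `survival_sim_params`.
#' @export
survival_sim_params <- function(genotypes = c("+/+", "+/-", "-/-"),
                                n_per_group = 200L,
                                pre_wean_hazard = NULL,
                                post_wean_hazard = NULL,
                                censor_rate = 0,
                                max_followup_days = 300L,
                                seed = 1L) {
  if (is.null(pre_wean_hazard))
    pre_wean_hazard <- setNames(rep(0.002, length(genotypes)), genotypes)
  if (is.null(post_wean_hazard))
    post_wean_hazard <- setNames(rep(0.0005, length(genotypes)), genotypes)
  assert_that(n_per_group >= 2, "n_per_group must be >= 2")
  assert_that(all(genotypes %in% names(pre_wean_hazard)) &&
              all(genotypes %in% names(post_wean_hazard)),
              "hazards must be named by genotype")
  assert_that(all(pre_wean_hazard >= 0) && all(post_wean_hazard >= 0),
              "hazards must be >= 0")
  assert_that(censor_rate >= 0 && censor_rate <= 1,
              "censor_rate must lie in [0, 1]")
  assert_that(max_followup_days > 0, "max_followup_days must be > 0")
  structure(list(genotypes = genotypes,
                 n_per_group = as.integer(n_per_group),
                 pre_wean_hazard = pre_wean_hazard,
                 post_wean_hazard = post_wean_hazard,
                 censor_rate = censor_rate,
                 max_followup_days = max_followup_days,
                 change_point_days = 29,
                 seed = seed),
            class = "survival_sim_params")
}

# inverse-transform draw from a piecewise-exponential hazard with one
# change-point; h = 0 segments yield no events in that segment
rpiecewise_exp <- function(n, h1, h2, tau) {
  e <- -log(runif(n))
  pre <- h1 * tau
  t <- numeric(n)
  early <- h1 > 0 & e < pre
  t[early] <- e[early] / h1
  if (h2 > 0) {
    t[!early] <- tau + (e[!early] - pre) / h2
  } else {
    t[!early] <- Inf
  }
  t
}

#' Generate a synthetic survival cohort
#'
#' @param params a [survival_sim_params()].
#' @return data frame of survival records: `animal_id`, `genotype`,
#'   `age_days` (integer, days), `event` (`"death"` or `"censored"`).
#' @export
generate_survival_cohort <- function(params) {
  stopifnot(inherits(params, "survival_sim_params"))
  p <- params
  local_seed(p$seed, {
    out <- lapply(p$genotypes, function(g) {
      n <- p$n_per_group
      t_death <- rpiecewise_exp(n, p$pre_wean_hazard[[g]],
                                p$post_wean_hazard[[g]],
                                p$change_point_days)
      t_censor <- rep(p$max_followup_days, n)
      flagged <- runif(n) < p$censor_rate
      t_censor[flagged] <- runif(sum(flagged), 0, p$max_followup_days)
      age <- pmin(t_death, t_censor)
      data.frame(genotype = g,
                 age_days = as.integer(ceiling(age)),
                 event = ifelse(t_death <= t_censor, "death", "censored"))
    })
    out <- do.call(rbind, out)
    out <- cbind(animal_id = sprintf("animal_%05d", seq_len(nrow(out))), out)
    rownames(out) <- NULL
    out
  })
}

#' Parameters for synthetic factorial measurements
#'
#' A balanced crossed design (e.g. genotype x sex). Each observation is the
#' grand mean plus the per-factor level effects plus an optional interaction
#' cell effect plus Gaussian residual noise.
#'
#' @param factors named list of level vectors, e.g.
#'   `list(genotype = c("wt", "ko"), sex = c("f", "m"))` (>= 2 levels each).
#' @param effects named list of named numeric vectors giving mean shifts for
#'   factor levels (unnamed levels shift 0), e.g.
#'   `list(genotype = c(ko = 1))`. An entry named `"<A>:<B>"` with names
#'   `"<levelA>:<levelB>"` adds interaction cell shifts.
#' @param grand_mean baseline value.
#' @param residual_sd residual standard deviation (>= 0).
#' @param n_per_cell observations per design cell (>= 2 for variance-based
#'   tests).
#' @param seed integer seed.
#' @return object of class `factorial_sim_params`.
#' @export
factorial_sim_params <- function(factors = list(genotype = c("wt", "ko"),
                                                sex = c("f", "m")),
                                 effects = list(),
                                 grand_mean = 0,
                                 residual_sd = 1,
                                 n_per_cell = 10L,
                                 seed = 1L) {
  assert_that(length(factors) >= 1 &&
              all(vapply(factors, length, 0L) >= 2),
              "each factor needs at least 2 levels")
  assert_that(n_per_cell >= 2, "n_per_cell must be >= 2")
  assert_that(residual_sd >= 0, "residual_sd must be >= 0")
  structure(list(factors = factors, effects = effects,
                 grand_mean = grand_mean, residual_sd = residual_sd,
                 n_per_cell = as.integer(n_per_cell), seed = seed),
            class = "factorial_sim_params")
}

#' Generate a synthetic factorial measurement table
#'
#' @param params a [factorial_sim_params()].
#' @return long-format data frame: `animal_id`, one column per factor, and
#'   `value`.
#' @export
generate_factorial_measurements <- function(params) {
  stopifnot(inherits(params, "factorial_sim_params"))
  p <- params
  cells <- expand.grid(p$factors, stringsAsFactors = FALSE)
  local_seed(p$seed, {
    tab <- cells[rep(seq_len(nrow(cells)), each = p$n_per_cell), ,
                 drop = FALSE]
    mu <- rep(p$grand_mean, nrow(tab))
    for (f in names(p$factors)) {
      ef <- p$effects[[f]]
      if (!is.null(ef)) {
        shift <- ef[tab[[f]]]
        shift[is.na(shift)] <- 0
        mu <- mu + shift
      }
    }
    for (nm in names(p$effects)) {
      if (!grepl(":", nm, fixed = TRUE)) next
      fs <- strsplit(nm, ":", fixed = TRUE)[[1]]
      assert_that(all(fs %in% names(p$factors)),
                  sprintf("unknown factors in interaction effect '%s'", nm))
      key <- do.call(paste, c(tab[fs], sep = ":"))
      shift <- p$effects[[nm]][key]
      shift[is.na(shift)] <- 0
      mu <- mu + shift
    }
    out <- data.frame(animal_id = sprintf("animal_%04d", seq_len(nrow(tab))),
                      tab,
                      value = mu + if (p$residual_sd > 0)
                        rnorm(nrow(tab), 0, p$residual_sd) else 0)
    rownames(out) <- NULL
    out
  })
}
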