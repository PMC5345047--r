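#' Circular-equivalent diameter
#'
#' Diameter of the circle with the given area: `d = 2 * sqrt(A / pi)`. Used
#' to derive inner and outer fiber diameters from lumen and lumen-plus-myelin
#' areas under the assumption of circular cross-sections.
#'
#' @param area area in square microns (>= 0; vectorized).
#' @return diameter in microns.
#' @export
circular_equivalent_diameter <- function(area) {
  assert_that(is.numeric(area) && all(area >= 0),
              "area must be non-negative")
  2 * sqrt(area / pi)
}

#' Per-axon g-ratio from areas
#'
#' `g = d_inner / d_outer` where the diameters are circular-equivalent
#' diameters of the lumen area and of the total area (lumen + myelin sheath);
#' algebraically `g = sqrt(A_inner / (A_inner + A_myelin))`, in `(0, 1]`.
#'
#' @param lumen_area lumen (inner) area, square microns (> 0; vectorized).
#' @param myelin_area myelin sheath area, square microns (>= 0).
#' @return g-ratio, dimensionless.
#' @export
axon_g_ratio <- function(lumen_area, myelin_area) {
  assert_that(is.numeric(lumen_area) && all(lumen_area > 0),
              "lumen_area must be > 0")
  assert_that(is.numeric(myelin_area) && all(myelin_area >= 0),
              "myelin_area must be >= 0")
  sqrt(lumen_area / (lumen_area + myelin_area))
}

#' Axon density in an ROI
#'
#' @param n_axons axon count.
#' @param roi_area_mm2 ROI area in square millimetres (> 0).
#' @return axons per mm^2.
#' @export
roi_density <- function(n_axons, roi_area_mm2) {
  assert_that(is.numeric(roi_area_mm2) && all(roi_area_mm2 > 0),
              "roi_area_mm2 must be > 0")
  assert_that(all(n_axons >= 0), "n_axons must be >= 0")
  n_axons / roi_area_mm2
}

#' One nerve cross-section's measurements
#'
#' @param animal_id animal identifier.
#' @param section_id section identifier.
#' @param roi_area_mm2 analyzed ROI area, mm^2 (> 0).
#' @param axons per-axon data frame with columns `lumen_area_um2` and
#'   `myelin_area_um2` (e.g. the `axons` element of [detect_axons()]).
#' @return object of class `section_measurement`.
#' @export
section_measurement <- function(animal_id, section_id, roi_area_mm2, axons) {
  assert_that(roi_area_mm2 > 0, "roi_area_mm2 must be > 0")
  assert_that(is.data.frame(axons) &&
              all(c("lumen_area_um2", "myelin_area_um2") %in% names(axons)),
              "axons must have lumen_area_um2 and myelin_area_um2 columns")
  structure(list(animal_id = animal_id, section_id = section_id,
                 roi_area_mm2 = roi_area_mm2, axons = axons),
            class = "section_measurement")
}

#' Per-animal nerve morphometry summary
#'
#' Computes per-section means first, then averages sections with equal weight
#' (sections are technical replicates), yielding a single value per animal
#' for each endpoint: axon density (axons/mm^2), mean lumen area, mean myelin
#' area, mean total (outer) area, and mean g-ratio. The primary g-ratio is
#' the mean of per-axon g-ratios; the ratio of circular-equivalent diameters
#' of the mean areas (`sqrt(mean A_inner / mean A_outer)`) is also reported
#' (`g_ratio_of_means`) for sensitivity checks — the two differ only by a
#' Jensen gap. The per-animal record is the unit of observation for all
#' downstream statistics.
#'
#' @param sections list of [section_measurement()]s (1-3 per animal, same
#'   animal).
#' @param min_axons sampling target; a warning flag (`low_sampling`) is set
#'   when the total axon count falls below it (default 4000). The animal is
#'   never excluded on this basis.
#' @return one-row data frame: `animal_id`, `axon_density`,
#'   `mean_lumen_area_um2`, `mean_myelin_area_um2`, `mean_outer_area_um2`,
#'   `mean_g_ratio`, `g_ratio_of_means`, `n_axons_sampled`, `n_sections`,
#'   `low_sampling`.
#' @export
summarize_animal <- function(sections, min_axons = 4000) {
  if (inherits(sections, "section_measurement")) sections <- list(sections)
  assert_that(length(sections) >= 1, "at least one section is required")
  assert_that(all(vapply(sections, inherits, TRUE, "section_measurement")),
              "sections must be section_measurement objects")
  ids <- unique(vapply(sections, function(s) as.character(s$animal_id), ""))
  assert_that(length(ids) == 1, "all sections must belong to the same animal")
  per <- lapply(sections, function(s) {
    a <- s$axons
    assert_that(nrow(a) > 0,
                sprintf("section %s has no axons", s$section_id))
    g <- axon_g_ratio(a$lumen_area_um2, a$myelin_area_um2)
    data.frame(density = roi_density(nrow(a), s$roi_area_mm2),
               lumen = mean(a$lumen_area_um2),
               myelin = mean(a$myelin_area_um2),
               outer = mean(a$lumen_area_um2 + a$myelin_area_um2),
               g = mean(g), n = nrow(a))
  })
  per <- do.call(rbind, per)
  n_total <- sum(per$n)
  out <- data.frame(animal_id = ids,
                    axon_density = mean(per$density),
                    mean_lumen_area_um2 = mean(per$lumen),
                    mean_myelin_area_um2 = mean(per$myelin),
                    mean_outer_area_um2 = mean(per$outer),
                    mean_g_ratio = mean(per$g),
                    g_ratio_of_means = sqrt(mean(per$lumen) / mean(per$outer)),
                    n_axons_sampled = n_total,
                    n_sections = nrow(per),
                    low_sampling = n_total < min_axons)
  if (out$low_sampling)
    warning(sprintf("animal %s: only %d axons sampled (target %d)",
                    ids, n_total, min_axons))
  out
}

#' Score detections against generator ground truth
#'
#' One-to-one greedy matching: a detection can match a truth axon only if its
#' centroid falls inside the true lumen circle; candidate pairs are accepted
#' in order of increasing center distance (nearest-center tie-break), each
#' detection and each truth axon at most once. Order-invariant.
#'
#' @param detected per-axon data frame with `centroid_row`, `centroid_col`
#'   and `lumen_area_um2` (as produced by [detect_axons()]).
#' @param truth ground-truth data frame from [generate_nerve_image()].
#' @return list with `recall`, `precision` (`NULL` when there are no
#'   detections), `n_matched`, and `matches` (data frame with detection row,
#'   truth `axon_id`, center distance and relative lumen-area error).
#' @export
match_to_ground_truth <- function(detected, truth) {
  n_det <- nrow(detected); n_true <- nrow(truth)
  empty <- data.frame(det_row = integer(0), axon_id = integer(0),
                      dist_px = numeric(0), lumen_area_rel_error = numeric(0))
  if (n_det == 0 || n_true == 0) {
    return(list(recall = if (n_true > 0) 0 else NA_real_,
                precision = if (n_det > 0) 0 else NULL,
                n_matched = 0L, matches = empty))
  }
  d2 <- outer(detected$centroid_row, truth$center_row, "-")^2 +
        outer(detected$centroid_col, truth$center_col, "-")^2
  ok <- d2 <= matrix(truth$lumen_radius_px^2, n_det, n_true, byrow = TRUE)
  cand <- which(ok, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(list(recall = 0, precision = 0, n_matched = 0L, matches = empty))
  }
  dist <- sqrt(d2[ok])
  ord <- order(dist, cand[, 2], cand[, 1])
  cand <- cand[ord, , drop = FALSE]
  dist <- dist[ord]
  det_used <- logical(n_det); true_used <- logical(n_true)
  take <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!det_used[i] && !true_used[j]) {
      det_used[i] <- TRUE; true_used[j] <- TRUE; take[k] <- TRUE
    }
  }
  m <- cand[take, , drop = FALSE]
  matches <- data.frame(
    det_row = m[, 1],
    axon_id = truth$axon_id[m[, 2]],
    dist_px = dist[take],
    lumen_area_rel_error =
      (detected$lumen_area_um2[m[, 1]] - truth$true_lumen_area_um2[m[, 2]]) /
      truth$true_lumen_area_um2[m[, 2]])
  list(recall = nrow(m) / n_true, precision = nrow(m) / n_det,
       n_matched = nrow(m), matches = matches)
}
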