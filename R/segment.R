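#' Segmentation configuration
#'
#' Free parameters of the axon-detection operator chain. Defaults are sized
#' for brightfield whole-slide scans at ~0.23 microns/pixel where myelin
#' stains dark; every value can be overridden per image.
#'
#' @param rolling_ball_radius_px radius (px) of the non-flat ball structuring
#'   element used for background correction. Must exceed the largest expected
#'   lumen radius so that lumina are flattened into the background estimate.
#' @param gaussian_sigma_px sigma (px) of the Gaussian smoothing applied
#'   before thresholding and the Laplacian split.
#' @param threshold_method `"otsu"` (parameter-free, default) or `"fixed"`.
#' @param fixed_threshold gray-level threshold used when
#'   `threshold_method = "fixed"` (applied to the background-corrected image).
#' @param log_split_max pixels of the candidate mask whose
#'   Laplacian-of-Gaussian response exceeds this value (gray levels / px^2)
#'   are treated as merge necks and removed before seeding; touching lumina
#'   separate there and a seeded watershed reassigns the removed pixels.
#' @param min_lumen_area_um2,max_lumen_area_um2 lumen-area acceptance window.
#' @param min_shape_factor minimum circularity `4*pi*A/P^2` (Crofton
#'   perimeter), in `[0, 1]`.
#' @param max_mean_lumen_intensity_deviation maximum absolute deviation (gray
#'   levels) of an object's mean lumen intensity from the global mean over
#'   all candidate lumen pixels.
#' @param hsi_saturation_max saturation ceiling in `[0, 1]` for stain pixels;
#'   the stain is achromatic, so strongly colored pixels are excluded from
#'   both the lumen and the myelin class.
#' @param ring_width_px width (px) of the band just outside the lumen that is
#'   examined for the myelin ring. Keep at or below the thinnest expected
#'   sheath (about `lumen_radius * (1/g - 1)` px).
#' @param ring_completeness minimum fraction of band pixels that must belong
#'   to the myelin class for the ring to count as closed.
#' @return an object of class `segmentation_config`.
#' @export
segmentation_config <- function(rolling_ball_radius_px = 18,
                                gaussian_sigma_px = 1.5,
                                threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                log_split_max = 5,
                                min_lumen_area_um2 = 1.0,
                                max_lumen_area_um2 = 80,
                                min_shape_factor = 0.4,
                                max_mean_lumen_intensity_deviation = 60,
                                hsi_saturation_max = 0.25,
                                ring_width_px = 2,
                                ring_completeness = 0.7) {
  threshold_method <- match.arg(threshold_method)
  assert_that(rolling_ball_radius_px > 0, "rolling_ball_radius_px must be > 0")
  assert_that(gaussian_sigma_px > 0, "gaussian_sigma_px must be > 0")
  if (threshold_method == "fixed")
    assert_that(is.numeric(fixed_threshold) && length(fixed_threshold) == 1,
                "fixed_threshold must be a single number")
  assert_that(min_lumen_area_um2 < max_lumen_area_um2,
              "min_lumen_area_um2 must be < max_lumen_area_um2")
  assert_that(min_shape_factor >= 0 && min_shape_factor <= 1,
              "min_shape_factor must lie in [0, 1]")
  assert_that(hsi_saturation_max >= 0 && hsi_saturation_max <= 1,
              "hsi_saturation_max must lie in [0, 1]")
  assert_that(ring_width_px >= 1, "ring_width_px must be >= 1")
  assert_that(ring_completeness >= 0 && ring_completeness <= 1,
              "ring_completeness must lie in [0, 1]")
  structure(list(rolling_ball_radius_px = rolling_ball_radius_px,
                 gaussian_sigma_px = gaussian_sigma_px,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 log_split_max = log_split_max,
                 min_lumen_area_um2 = min_lumen_area_um2,
                 max_lumen_area_um2 = max_lumen_area_um2,
                 min_shape_factor = min_shape_factor,
                 max_mean_lumen_intensity_deviation =
                   max_mean_lumen_intensity_deviation,
                 hsi_saturation_max = hsi_saturation_max,
                 ring_width_px = ring_width_px,
                 ring_completeness = ring_completeness),
            class = "segmentation_config")
}

#' Luminance conversion (Rec. 601 weights)
#' @keywords internal
#' @noRd
rgb_to_gray <- function(pixels) {
  0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
}

# HSI decomposition (standard bi-cone): I = (R+G+B)/3, S = 1 - min/I.
# Hue is not needed: the stain is achromatic and pixels are classed on
# intensity with a saturation ceiling.
rgb_to_hsi <- function(pixels) {
  s <- pixels[, , 1] + pixels[, , 2] + pixels[, , 3]
  mn <- pmin(pixels[, , 1], pixels[, , 2], pixels[, , 3])
  sat <- ifelse(s > 0, 1 - 3 * mn / s, 0)
  list(intensity = s / 3, saturation = sat)
}

#' Rolling-ball background filtering
#'
#' Grayscale morphological opening with a non-flat (hemispherical) ball
#' structuring element of the given radius: the height of the ball at offset
#' `d` from its center is `sqrt(radius^2 - d^2)` gray levels. The opening is
#' the background estimate; subtracting it from the input flattens slow
#' illumination gradients and leaves bright structures smaller than the ball
#' (the lumina) standing.
#'
#' @param gray numeric matrix.
#' @param radius_px ball radius in pixels.
#' @return the opened image (background estimate), same shape as `gray`.
#' @export
rolling_ball_opening <- function(gray, radius_px) {
  assert_that(radius_px < min(dim(gray)),
              "rolling-ball radius must be smaller than the image")
  r <- radius_px
  off <- expand.grid(dy = -floor(r):floor(r), dx = -floor(r):floor(r))
  keep <- off$dy^2 + off$dx^2 <= r^2
  off <- off[keep, ]
  h <- sqrt(r^2 - off$dy^2 - off$dx^2)
  er <- ball_transform_cpp(gray, as.integer(off$dy), as.integer(off$dx), h,
                           TRUE)
  ball_transform_cpp(er, as.integer(off$dy), as.integer(off$dx), h, FALSE)
}

#' Background-corrected grayscale image
#'
#' Converts the RGB raster to luminance and subtracts the rolling-ball
#' background estimate. The result is non-negative, zero on flat background
#' and on structures wider than the ball, and bright exactly where small
#' bright structures (candidate lumina) sit.
#'
#' @param image a [nerve_image()].
#' @param config a [segmentation_config()].
#' @return numeric matrix, same height/width as the image.
#' @export
preprocess <- function(image, config = segmentation_config()) {
  stopifnot(inherits(image, "nerve_image"))
  gray <- rgb_to_gray(image$pixels)
  # the opening never exceeds the input, so the difference is non-negative up
  # to floating-point dust, which is clamped away
  pmax(gray - rolling_ball_opening(gray, config$rolling_ball_radius_px), 0)
}

# discrete 4-neighbour Laplacian
laplacian_kernel <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)

gblur_mat <- function(m, sigma) {
  as.matrix(EBImage::imageData(EBImage::gblur(EBImage::Image(m),
                                              sigma = sigma)))
}

# Three-class Otsu: exhaustive search for the two gray-level thresholds that
# maximize the between-class variance of a 256-bin histogram. The luminance
# histogram of a stained section is trimodal (dark myelin, intermediate
# lumen, bright background); a single Otsu split would land between the
# background and everything else and grossly over-count the stain class.
otsu_two_thresholds <- function(x) {
  h <- tabulate(pmin(256L, pmax(1L, floor(x) + 1L)), nbins = 256L)
  w <- h / sum(h)
  mu <- 0:255
  cw <- cumsum(w)
  cm <- cumsum(w * mu)
  mtot <- cm[256]
  best <- -Inf
  bt <- c(1L, 2L)
  for (t1 in 1:254) {
    w0 <- cw[t1]
    if (w0 == 0) next
    m0 <- cm[t1] / w0
    t2 <- (t1 + 1):255
    w1 <- cw[t2] - cw[t1]
    w2 <- 1 - cw[t2]
    ok <- w1 > 0 & w2 > 0
    if (!any(ok)) next
    m1 <- (cm[t2] - cm[t1]) / w1
    m2 <- (mtot - cm[t2]) / w2
    v <- w0 * (m0 - mtot)^2 + w1 * (m1 - mtot)^2 + w2 * (m2 - mtot)^2
    v[!ok] <- -Inf
    i <- which.max(v)
    if (v[i] > best) {
      best <- v[i]
      bt <- c(t1, t2[i])
    }
  }
  bt  # pixels < bt[1] are the dark class, >= bt[2] the bright class
}

# myelin-class pixel mask: dark, low-saturation pixels, classified on the
# raw luminance (so that thin sheaths are not washed out by smoothing) with
# the lower threshold of a three-class Otsu split.
myelin_mask <- function(image, config) {
  gray <- rgb_to_gray(image$pixels)
  if (diff(range(gray)) < .Machine$double.eps^0.5)
    return(matrix(FALSE, nrow(gray), ncol(gray)))
  th <- otsu_two_thresholds(gray)[1]
  sat <- rgb_to_hsi(image$pixels)$saturation
  gray < th & sat <= config$hsi_saturation_max
}

#' Candidate lumen segmentation
#'
#' The operator chain: (1) threshold the smoothed background-corrected image
#' (Otsu by default) to get bright lumen candidates; (2) apply the Laplacian
#' to the Gaussian-smoothed image and remove candidate pixels with a strongly
#' positive response (merge necks between touching lumina), which splits
#' merged candidates into separate seeds; (3) screen pixels in HSI space
#' (candidate lumen pixels must be achromatic, i.e. saturation below the
#' configured ceiling); (4) grow the seeds back over the candidate mask with
#' a seeded watershed on the smoothed intensity landscape
#' (`EBImage::propagate`), separating touching lumina at intensity ridges.
#'
#' @param image a [nerve_image()] (the RGB original; used for HSI screening).
#' @param gray the background-corrected grayscale from [preprocess()].
#' @param config a [segmentation_config()].
#' @return integer label matrix (0 = background) with attribute `threshold`.
#' @export
segment_candidates <- function(image, gray, config = segmentation_config()) {
  stopifnot(inherits(image, "nerve_image"))
  sm <- gblur_mat(gray, config$gaussian_sigma_px)
  rng <- range(sm)
  if (diff(rng) < .Machine$double.eps^0.5) {
    warning("uniform image: no threshold separates lumen from background; ",
            "returning empty labeling")
    out <- matrix(0L, nrow(sm), ncol(sm))
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  th <- switch(config$threshold_method,
               otsu = EBImage::otsu(EBImage::Image(sm), range = rng),
               fixed = config$fixed_threshold)
  cand <- sm > th
  sat_ok <- rgb_to_hsi(image$pixels)$saturation <= config$hsi_saturation_max
  cand <- cand & sat_ok
  if (!any(cand)) {
    warning("no pixels above threshold; returning empty labeling")
    out <- matrix(0L, nrow(sm), ncol(sm))
    attr(out, "threshold") <- th
    return(out)
  }
  lap <- as.matrix(EBImage::imageData(
    EBImage::filter2(EBImage::Image(sm), laplacian_kernel)))
  core <- cand & lap <= config$log_split_max
  seeds <- EBImage::bwlabel(EBImage::Image(core))
  labels <- EBImage::propagate(EBImage::Image(sm), seeds,
                               mask = EBImage::Image(cand))
  out <- matrix(as.integer(EBImage::imageData(labels)), nrow(sm), ncol(sm))
  attr(out, "threshold") <- th
  out
}

#' Per-label Crofton perimeter estimate
#'
#' Cauchy-Crofton estimate from boundary intercept counts in four directions
#' (0, 45, 90, 135 degrees): `P = (pi/8) * (n0 + n90 + (n45 + n135)/sqrt(2))`.
#'
#' @param labels integer label matrix.
#' @param nlab number of labels (defaults to `max(labels)`).
#' @return numeric vector of perimeters (px), one per label.
#' @export
crofton_perimeter <- function(labels, nlab = max(labels)) {
  if (nlab < 1) return(numeric(0))
  L <- labels
  nr <- nrow(L); nc <- ncol(L)
  pairs <- function(a, b) {
    d <- which(a != b)
    av <- a[d]; bv <- b[d]
    c(av[av > 0], bv[bv > 0])
  }
  tab <- function(v) if (length(v)) tabulate(v, nbins = nlab) else
    numeric(nlab)
  edge <- function(v) v[v > 0]
  n0 <- tab(c(pairs(L[, -nc, drop = FALSE], L[, -1, drop = FALSE]),
              edge(L[, 1]), edge(L[, nc])))
  n90 <- tab(c(pairs(L[-nr, , drop = FALSE], L[-1, , drop = FALSE]),
               edge(L[1, ]), edge(L[nr, ])))
  n45 <- tab(c(pairs(L[-nr, -nc, drop = FALSE], L[-1, -1, drop = FALSE]),
               edge(L[1, ]), edge(L[, 1]), edge(L[nr, ]), edge(L[, nc])))
  n135 <- tab(c(pairs(L[-nr, -1, drop = FALSE], L[-1, -nc, drop = FALSE]),
                edge(L[1, ]), edge(L[, nc]), edge(L[nr, ]), edge(L[, 1])))
  (pi / 8) * (n0 + n90 + (n45 + n135) / sqrt(2))
}

#' Object filtering and measurement
#'
#' Screens labeled lumen candidates and measures the survivors. A candidate
#' is kept iff, in order: its lumen area lies inside the configured window
#' (`"size"`), its circularity `4*pi*A/P^2` meets `min_shape_factor`
#' (`"shape"`), its mean lumen intensity is within the configured deviation
#' of the global lumen-class mean (`"intensity"`), and the band just outside
#' the lumen is covered by myelin-class pixels to at least
#' `ring_completeness` — a closed dark ring (`"no_myelin_ring"`). Filtering
#' never raises; every removal is returned with its reason code. Per-axon
#' myelin areas are measured by assigning each myelin-class pixel to its
#' nearest surviving lumen with a seeded watershed (constrained region
#' growing from the lumen seed under the dark-pixel mask).
#'
#' @param candidates integer label matrix from [segment_candidates()].
#' @param image the [nerve_image()] the candidates came from.
#' @param config a [segmentation_config()].
#' @return list with `axons` (data frame: `label`, `centroid_row`,
#'   `centroid_col`, `lumen_area_um2`, `myelin_area_um2`, `shape_factor`,
#'   `mean_lumen_intensity`) and `removed` (data frame: `label`, `reason`).
#' @export
filter_objects <- function(candidates, image,
                           config = segmentation_config()) {
  stopifnot(inherits(image, "nerve_image"))
  nlab <- max(candidates)
  empty_axons <- data.frame(label = integer(0), centroid_row = numeric(0),
                            centroid_col = numeric(0),
                            lumen_area_um2 = numeric(0),
                            myelin_area_um2 = numeric(0),
                            shape_factor = numeric(0),
                            mean_lumen_intensity = numeric(0))
  if (nlab < 1)
    return(list(axons = empty_axons,
                removed = data.frame(label = integer(0),
                                     reason = character(0))))
  px2 <- image$pixel_size_um^2
  nr <- nrow(candidates)
  idx <- which(candidates > 0)
  lab <- candidates[idx]
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  gray <- rgb_to_gray(image$pixels)
  mm <- myelin_mask(image, config)

  n_px <- tabulate(lab, nlab)
  present <- which(n_px > 0)
  cent_r <- rowsum(as.numeric(rows), lab)[, 1] / n_px[present]
  cent_c <- rowsum(as.numeric(cols), lab)[, 1] / n_px[present]
  centroid_row <- rep(NA_real_, nlab); centroid_row[present] <- cent_r
  centroid_col <- rep(NA_real_, nlab); centroid_col[present] <- cent_c
  # lumen area excludes myelin-class pixels: where the candidate label spills
  # over the blurred lumen/sheath edge, those dark pixels belong to the ring
  lum_sel <- !mm[idx]
  n_lum <- tabulate(lab[lum_sel], nlab)
  area_um2 <- n_lum * px2
  mean_int <- rep(NA_real_, nlab)
  has_lum <- which(n_lum > 0)
  if (length(has_lum))
    mean_int[has_lum] <- rowsum(gray[idx][lum_sel],
                                lab[lum_sel])[, 1] / n_lum[has_lum]
  global_mean <- if (any(lum_sel)) mean(gray[idx][lum_sel]) else
    mean(gray[idx])

  perim <- crofton_perimeter(candidates, nlab)
  shape <- ifelse(perim > 0, pmin(1, 4 * pi * n_px / perim^2), 0)

  # ring band: grayscale (max) dilation of the label image; band pixels carry
  # the label of the nearest lumen
  brush <- EBImage::makeBrush(2L * as.integer(config$ring_width_px) + 1L,
                              shape = "disc")
  dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(candidates),
                                            brush))
  band <- dil > 0 & candidates == 0
  band_lab <- as.integer(dil[band])
  band_n <- tabulate(band_lab, nlab)
  band_myelin <- tabulate(band_lab[mm[band]], nlab)
  ring_frac <- ifelse(band_n > 0, band_myelin / band_n, 0)

  reason <- rep(NA_character_, nlab)
  reason[is.na(reason) & (area_um2 < config$min_lumen_area_um2 |
                          area_um2 > config$max_lumen_area_um2)] <- "size"
  reason[is.na(reason) & shape < config$min_shape_factor] <- "shape"
  reason[is.na(reason) &
         abs(mean_int - global_mean) >
           config$max_mean_lumen_intensity_deviation] <- "intensity"
  reason[is.na(reason) &
         ring_frac < config$ring_completeness] <- "no_myelin_ring"
  reason[n_px == 0] <- "empty"
  keep <- present[is.na(reason[present])]

  # per-axon myelin area: seeded watershed of myelin-class pixels onto the
  # surviving lumina
  myelin_area <- numeric(nlab)
  if (length(keep) > 0 && any(mm)) {
    seeds <- candidates
    seeds[!(seeds %in% keep)] <- 0L
    sm <- gblur_mat(gray, config$gaussian_sigma_px)
    assign_lab <- EBImage::propagate(
      EBImage::Image(sm), EBImage::Image(seeds),
      mask = EBImage::Image(seeds > 0 | mm))
    am <- as.integer(EBImage::imageData(assign_lab))
    dim(am) <- dim(candidates)
    mye_lab <- am[mm & am > 0L]
    if (length(mye_lab))
      myelin_area <- tabulate(mye_lab, nlab) * px2
  }

  axons <- data.frame(label = keep,
                      centroid_row = centroid_row[keep],
                      centroid_col = centroid_col[keep],
                      lumen_area_um2 = area_um2[keep],
                      myelin_area_um2 = myelin_area[keep],
                      shape_factor = shape[keep],
                      mean_lumen_intensity = mean_int[keep])
  removed_lab <- present[!is.na(reason[present])]
  list(axons = axons,
       removed = data.frame(label = removed_lab,
                            reason = reason[removed_lab]))
}

#' Detect myelinated axons in a nerve cross-section image
#'
#' Composes [preprocess()], [segment_candidates()] and [filter_objects()],
#' restricted to the image's ROI polygon (detections whose lumen centroid
#' falls outside the ROI are dropped). Deterministic for a fixed image and
#' configuration: there is no randomness anywhere in the chain.
#'
#' @param image a [nerve_image()].
#' @param config a [segmentation_config()].
#' @return object of class `axon_detection`: list with `axons` (one row per
#'   detected myelinated axon, see [filter_objects()]) and `qc` (candidate /
#'   kept counts, removal reasons, threshold, ROI area in mm^2).
#' @export
detect_axons <- function(image, config = segmentation_config()) {
  stopifnot(inherits(image, "nerve_image"))
  gray <- preprocess(image, config)
  candidates <- segment_candidates(image, gray, config)
  filt <- filter_objects(candidates, image, config)
  axons <- filt$axons
  n_roi_dropped <- 0L
  if (!is.null(image$roi) && nrow(axons) > 0) {
    inside <- points_in_polygon(cbind(axons$centroid_row, axons$centroid_col),
                                image$roi)
    n_roi_dropped <- sum(!inside)
    axons <- axons[inside, , drop = FALSE]
    rownames(axons) <- NULL
  }
  qc <- list(n_candidates = length(unique(candidates[candidates > 0])),
             n_removed = nrow(filt$removed),
             removal_reasons = table(filt$removed$reason),
             n_outside_roi = n_roi_dropped,
             n_kept = nrow(axons),
             threshold = attr(candidates, "threshold"),
             roi_area_mm2 = roi_area_mm2(image))
  structure(list(axons = axons, qc = qc), class = "axon_detection")
}

#' @export
print.axon_detection <- function(x, ...) {
  cat(sprintf("axon_detection: %d axons kept of %d candidates (ROI %.4f mm^2)\n",
              x$qc$n_kept, x$qc$n_candidates, x$qc$roi_area_mm2))
  if (x$qc$n_removed > 0) {
    cat("removals:\n")
    print(x$qc$removal_reasons)
  }
  invisible(x)
}

#' Write the per-axon table and QC summary
#'
#' @param detection an `axon_detection` from [detect_axons()].
#' @param axons_csv,qc_json output paths (either may be `NULL` to skip).
#' @export
write_detection <- function(detection, axons_csv = NULL, qc_json = NULL) {
  stopifnot(inherits(detection, "axon_detection"))
  if (!is.null(axons_csv))
    write.csv(detection$axons, axons_csv, row.names = FALSE)
  if (!is.null(qc_json)) {
    qc <- detection$qc
    qc$removal_reasons <- as.list(qc$removal_reasons)
    jsonlite::write_json(qc, qc_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(detection)
}
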