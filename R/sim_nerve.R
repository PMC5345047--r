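#' Parameters for the synthetic nerve-image generator
#'
#' Defines the study conditions the generator emulates: a brightfield image of
#' a stained nerve cross-section in which myelin rings appear dark on a bright
#' background and each myelinated axon is an annulus (bright lumen inside a
#' dark sheath). Defaults model a whole-slide scan at 0.23 microns/pixel with
#' myelinated-fiber lumen radii drawn from a lognormal distribution and
#' g-ratios around 0.65, typical of peripheral nerve.
#'
#' @param image_size_px integer `(height, width)` of the frame.
#' @param pixel_size_um microns per pixel (default 0.23).
#' @param n_axons_target number of axons to place (>= 0).
#' @param lumen_radius_um `(mean, sd)` of the lognormal lumen-radius
#'   distribution, in microns (arithmetic mean/sd).
#' @param lumen_radius_range_um truncation bounds for the lumen radius;
#'   the default `[0.7, 3.5]` um restricts the draw to myelinated calibers
#'   and keeps the largest annulus well below the background-correction
#'   structuring element.
#' @param g_ratio `(mean, sd)` of the per-axon g-ratio, truncated to (0, 1).
#' @param myelin_intensity,lumen_intensity,background_intensity gray levels in
#'   `[0, 255]`; myelin must be darkest (the stain renders myelin dark).
#' @param noise_sd standard deviation of i.i.d. Gaussian pixel noise added
#'   independently per RGB channel (gray levels).
#' @param min_gap_px minimum spacing between the outer circles of two axons.
#' @param max_attempts rejection-sampling cap per axon before the generator
#'   aborts with an "unplaceable density" error.
#' @param seed integer seed; the same seed and parameters give bit-identical
#'   output.
#' @return an object of class `nerve_sim_params`.
#' @export
nerve_sim_params <- function(image_size_px = c(1024L, 1024L),
                             pixel_size_um = 0.23,
                             n_axons_target = 200L,
                             lumen_radius_um = c(1.5, 0.5),
                             lumen_radius_range_um = c(0.7, 3.5),
                             g_ratio = c(0.65, 0.05),
                             myelin_intensity = 70,
                             lumen_intensity = 165,
                             background_intensity = 195,
                             noise_sd = 8,
                             min_gap_px = 2,
                             max_attempts = 10000L,
                             seed = 1L) {
  assert_that(length(image_size_px) == 2 && all(image_size_px >= 16),
              "image_size_px must be (height, width), each >= 16")
  assert_that(pixel_size_um > 0, "pixel_size_um must be > 0")
  assert_that(n_axons_target >= 0, "n_axons_target must be >= 0")
  assert_that(length(lumen_radius_um) == 2 && all(lumen_radius_um >= 0) &&
              lumen_radius_um[1] > 0, "lumen_radius_um must be (mean > 0, sd >= 0)")
  assert_that(length(g_ratio) == 2 && g_ratio[1] > 0 && g_ratio[1] < 1 &&
              g_ratio[2] >= 0, "g_ratio mean must lie in (0, 1)")
  ints <- c(myelin_intensity, lumen_intensity, background_intensity)
  assert_that(all(ints >= 0 & ints <= 255), "intensities must lie in [0, 255]")
  assert_that(myelin_intensity < lumen_intensity &&
              myelin_intensity < background_intensity,
              "myelin must stain darker than lumen and background")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  assert_that(min_gap_px >= 0, "min_gap_px must be >= 0")
  structure(list(image_size_px = as.integer(image_size_px),
                 pixel_size_um = pixel_size_um,
                 n_axons_target = as.integer(n_axons_target),
                 lumen_radius_um = lumen_radius_um,
                 lumen_radius_range_um = lumen_radius_range_um,
                 g_ratio = g_ratio,
                 myelin_intensity = myelin_intensity,
                 lumen_intensity = lumen_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd,
                 min_gap_px = min_gap_px,
                 max_attempts = as.integer(max_attempts),
                 seed = seed),
            class = "nerve_sim_params")
}

# lognormal (meanlog, sdlog) from arithmetic mean/sd
lnorm_pars <- function(m, s) {
  if (s == 0) return(c(log(m), 0))
  sdlog <- sqrt(log(1 + (s / m)^2))
  c(log(m) - sdlog^2 / 2, sdlog)
}

# truncated draw by rejection; sd = 0 degenerates to the mean
rtrunc <- function(n, rfun, lower, upper) {
  out <- rfun(n)
  bad <- which(out < lower | out > upper)
  guard <- 0L
  while (length(bad) > 0) {
    out[bad] <- rfun(length(bad))
    bad <- bad[out[bad] < lower | out[bad] > upper]
    guard <- guard + 1L
    if (guard > 1000L) stop("truncation bounds reject almost all draws",
                            call. = FALSE)
  }
  out
}

#' Generate a ground-truthed synthetic nerve image
#'
#' Places non-overlapping annular axon profiles (concentric circles: a bright
#' lumen inside a dark myelin ring) by rejection sampling, rasterizes them on
#' a bright background, and adds Gaussian pixel noise clipped to `[0, 255]`.
#' Ground-truth areas are computed analytically from the generating radii
#' (`A = pi r^2`, scaled by `pixel_size_um^2`), not from the rasterization.
#'
#' @param params a [nerve_sim_params()].
#' @return a list with elements `image` (a [nerve_image()]) and `truth`
#'   (data frame with one row per axon: `axon_id`, `center_row`, `center_col`,
#'   `lumen_radius_px`, `outer_radius_px`, `true_lumen_area_um2`,
#'   `true_myelin_area_um2`, `true_g_ratio`).
#' @export
generate_nerve_image <- function(params) {
  stopifnot(inherits(params, "nerve_sim_params"))
  p <- params
  h <- p$image_size_px[1]; w <- p$image_size_px[2]
  local_seed(p$seed, {
    n <- p$n_axons_target
    base <- matrix(p$background_intensity, nrow = h, ncol = w)
    truth <- data.frame(axon_id = integer(0), center_row = numeric(0),
                        center_col = numeric(0), lumen_radius_px = numeric(0),
                        outer_radius_px = numeric(0),
                        true_lumen_area_um2 = numeric(0),
                        true_myelin_area_um2 = numeric(0),
                        true_g_ratio = numeric(0))
    if (n > 0) {
      lp <- lnorm_pars(p$lumen_radius_um[1], p$lumen_radius_um[2])
      r_lum_um <- rtrunc(n, function(k) rlnorm(k, lp[1], lp[2]),
                         p$lumen_radius_range_um[1], p$lumen_radius_range_um[2])
      g <- rtrunc(n, function(k) rnorm(k, p$g_ratio[1], p$g_ratio[2]),
                  .Machine$double.eps, 1 - .Machine$double.eps)
      r_lum <- r_lum_um / p$pixel_size_um
      r_out <- r_lum / g
      cy <- numeric(n); cx <- numeric(n)
      placed <- 0L
      for (i in seq_len(n)) {
        m <- r_out[i] + 1
        if (2 * m >= min(h, w)) {
          stop(sprintf(
            "unplaceable density: axon %d (outer radius %.1f px) cannot fit; %d axons placed so far",
            i, r_out[i], placed), call. = FALSE)
        }
        ok <- FALSE
        for (att in seq_len(p$max_attempts)) {
          y <- runif(1, m, h - m); x <- runif(1, m, w - m)
          if (placed == 0L ||
              all((cy[seq_len(placed)] - y)^2 + (cx[seq_len(placed)] - x)^2 >=
                  (r_out[seq_len(placed)] + r_out[i] + p$min_gap_px)^2)) {
            ok <- TRUE; break
          }
        }
        if (!ok) {
          stop(sprintf(
            "unplaceable density: gave up after %d attempts for axon %d; %d axons placed so far",
            p$max_attempts, i, placed), call. = FALSE)
        }
        cy[i] <- y; cx[i] <- x; placed <- placed + 1L
        # rasterize: myelin disk first, then lumen disk on top
        rows <- max(1L, floor(y - r_out[i])):min(h, ceiling(y + r_out[i]))
        cols <- max(1L, floor(x - r_out[i])):min(w, ceiling(x + r_out[i]))
        d2 <- outer((rows - y)^2, (cols - x)^2, "+")
        block <- base[rows, cols]
        block[d2 <= r_out[i]^2] <- p$myelin_intensity
        block[d2 <= r_lum[i]^2] <- p$lumen_intensity
        base[rows, cols] <- block
      }
      truth <- data.frame(
        axon_id = seq_len(n),
        center_row = cy, center_col = cx,
        lumen_radius_px = r_lum, outer_radius_px = r_out,
        true_lumen_area_um2 = pi * r_lum_um^2,
        true_myelin_area_um2 = pi * ((r_out * p$pixel_size_um)^2 - r_lum_um^2),
        true_g_ratio = g)
    }
    px <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      chan <- base
      if (p$noise_sd > 0) chan <- chan + rnorm(h * w, 0, p$noise_sd)
      px[, , ch] <- round(pmin(255, pmax(0, chan)))
    }
    list(image = nerve_image(px, pixel_size_um = p$pixel_size_um),
         truth = truth)
  })
}

#' Write / read the ground-truth axon table as CSV
#'
#' @param truth the `truth` data frame from [generate_nerve_image()].
#' @param path CSV file path.
#' @export
write_ground_truth_csv <- function(truth, path) {
  write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth_csv
#' @export
read_ground_truth_csv <- function(path) read.csv(path)
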