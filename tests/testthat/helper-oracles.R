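# Independent oracles, written as plain loops so they share no code path with
# the implementation they check.

# brute-force grayscale opening with a hemispherical ball structuring element
brute_ball_opening <- function(img, radius) {
  nr <- nrow(img); nc <- ncol(img)
  r <- floor(radius)
  offs <- list()
  for (dy in -r:r) for (dx in -r:r) {
    if (dy^2 + dx^2 <= radius^2)
      offs[[length(offs) + 1]] <- c(dy, dx, sqrt(radius^2 - dy^2 - dx^2))
  }
  er <- matrix(NA_real_, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    m <- Inf
    for (o in offs) {
      ii <- i + o[1]; jj <- j + o[2]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc)
        m <- min(m, img[ii, jj] - o[3])
    }
    er[i, j] <- m
  }
  op <- matrix(NA_real_, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    m <- -Inf
    for (o in offs) {
      ii <- i + o[1]; jj <- j + o[2]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc)
        m <- max(m, er[ii, jj] + o[3])
    }
    op[i, j] <- m
  }
  op
}

# naive Gehan-Breslow chi-square: risk sets recomputed by filtering at every
# event time, scalar accumulation
gehan_oracle <- function(records, group = "genotype") {
  g <- factor(records[[group]])
  levs <- levels(g)
  k <- length(levs)
  age <- records$age_days
  death <- records$event == "death"
  U <- numeric(k)
  V <- matrix(0, k, k)
  for (t in sort(unique(age[death]))) {
    n_i <- 0; n_ij <- numeric(k); d_ij <- numeric(k)
    for (r in seq_len(nrow(records))) {
      if (age[r] >= t) {
        n_i <- n_i + 1
        gi <- which(levs == g[r])
        n_ij[gi] <- n_ij[gi] + 1
        if (death[r] && age[r] == t) d_ij[gi] <- d_ij[gi] + 1
      }
    }
    d_i <- sum(d_ij)
    for (j in seq_len(k))
      U[j] <- U[j] + n_i * (d_ij[j] - n_ij[j] * d_i / n_i)
    if (n_i > 1) {
      for (j in seq_len(k)) for (l in seq_len(k)) {
        kr <- if (j == l) n_ij[j] / n_i - n_ij[j]^2 / n_i^2 else
          -n_ij[j] * n_ij[l] / n_i^2
        V[j, l] <- V[j, l] + n_i^2 * d_i * (n_i - d_i) / (n_i - 1) * kr
      }
    }
  }
  sub <- seq_len(k - 1)
  drop(t(U[sub]) %*% solve(V[sub, sub, drop = FALSE], U[sub]))
}

# pairwise Gehan score (Mann-Whitney form): an entirely different route to
# the test numerator for two groups
gehan_pair_score <- function(records, group = "genotype") {
  g <- factor(records[[group]])
  levs <- levels(g)
  age <- records$age_days
  death <- records$event == "death"
  a <- which(g == levs[1]); b <- which(g == levs[2])
  W <- 0
  for (i in a) for (j in b) {
    if (age[i] > age[j] && death[j]) W <- W + 1
    else if (age[i] < age[j] && death[i]) W <- W - 1
    else if (age[i] == age[j]) {
      if (death[j] && !death[i]) W <- W + 1
      if (death[i] && !death[j]) W <- W - 1
    }
  }
  W
}

# hand rasterizer for annuli (independent of the generator's drawing code)
draw_annulus <- function(canvas, cy, cx, r_lumen, r_outer,
                         lumen = 165, myelin = 70) {
  for (i in seq_len(nrow(canvas))) for (j in seq_len(ncol(canvas))) {
    d2 <- (i - cy)^2 + (j - cx)^2
    if (d2 <= r_lumen^2) canvas[i, j] <- lumen
    else if (d2 <= r_outer^2) canvas[i, j] <- myelin
  }
  canvas
}

# wrap a gray matrix as an achromatic nerve_image
gray_nerve_image <- function(m, pixel_size_um = 0.23, roi = NULL) {
  nerve_image(array(rep(m, 3), dim = c(dim(m), 3)),
              pixel_size_um = pixel_size_um, roi = roi)
}

# per-axon table with exact g-ratios, for morphometry tests
axon_table <- function(g, lumen = 1) {
  data.frame(lumen_area_um2 = rep(lumen, length(g)),
             myelin_area_um2 = lumen * (1 / g^2 - 1))
}
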