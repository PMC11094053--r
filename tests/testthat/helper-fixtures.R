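# Shared fixtures: small phantom frame sets and brute-force oracles.

# A set of single-frame image/mask pairs drawn from randomized small
# phantoms (clean, no degradation).
make_frame_set <- function(n, seed, image_size = 32) {
  withr::with_seed(seed, {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      r <- stats::runif(1, 0.2 * image_size, 0.33 * image_size)
      wall <- stats::runif(1, 0.1 * image_size, 0.15 * image_size)
      if (r + wall >= image_size / 2) r <- image_size / 2 - wall - 1
      cfg <- phantom_config(
        n_slices = 3, n_phases = 4, image_size = image_size,
        endo_radius_px = r, wall_thickness_px = wall,
        contraction_fraction = stats::runif(1, 0.2, 0.4),
        empty_slice_margin = 1, papillary = TRUE,
        seed = seed * 1000 + i)
      ph <- generate_phantom_stack(cfg)
      out[[i]] <- list(image = ph$stack[2, 1, , ],
                       mask = ph$ground_truth$masks[2, 1, , ])
    }
    out
  })
}

# A single simply-connected phantom mask.
make_phantom_mask <- function(r_endo = 10, wall = 5, size = 36) {
  cfg <- phantom_config(n_slices = 3, n_phases = 2, image_size = size,
                        endo_radius_px = r_endo, wall_thickness_px = wall,
                        contraction_fraction = 0.3, empty_slice_margin = 1,
                        seed = 1)
  generate_phantom_stack(cfg)$ground_truth$masks[2, 1, , ]
}

# Brute-force Dice over two logical matrices (explicit set counting).
brute_dice <- function(a, b) {
  inter <- 0L; na <- 0L; nb <- 0L
  for (i in seq_along(a)) {
    if (a[i]) na <- na + 1L
    if (b[i]) nb <- nb + 1L
    if (a[i] && b[i]) inter <- inter + 1L
  }
  2 * inter / (na + nb)
}

# Brute-force Hausdorff distance by exhaustive O(n^2) pairwise distances.
brute_hausdorff <- function(a, b) {
  dmin_over <- function(p, q) {
    best <- Inf
    for (j in seq_len(nrow(q))) {
      d <- sqrt(sum((p - q[j, ])^2))
      if (d < best) best <- d
    }
    best
  }
  da <- 0
  for (i in seq_len(nrow(a))) da <- max(da, dmin_over(a[i, ], b))
  db <- 0
  for (i in seq_len(nrow(b))) db <- max(db, dmin_over(b[i, ], a))
  max(da, db)
}

# Brute-force point-in-polygon (ray casting), for rasterization oracles.
brute_inside <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

# ICC(A,1) via an independent two-way ANOVA fit (stats::aov mean squares).
aov_icc <- function(x) {
  n <- nrow(x); k <- ncol(x)
  df <- data.frame(y = as.vector(x),
                   subject = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Perimeter of an implicitly closed polyline.
poly_perimeter <- function(poly) {
  p2 <- rbind(poly, poly[1, ])
  sum(sqrt(rowSums(diff(p2)^2)))
}
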