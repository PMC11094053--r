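# Synthetic short-axis cine phantoms with ground-truth masks.
#
# The phantom emulates a left ventricle in short-axis view: a bright blood
# pool (label 1) surrounded by an annular myocardium (label 2) on a dark
# background (label 0). The cavity radius contracts smoothly from its
# end-diastolic maximum to an end-systolic minimum over the cardiac cycle,
# basal/apical margin slices carry empty masks, and an optional infarct
# thins the wall over an angular sector. Image quality can be degraded on a
# 3-category ordinal scale (artefacts / noise / general).

#' Configuration for a synthetic short-axis cine phantom
#'
#' Defaults mirror a high-resolution small-animal acquisition: 0.4 x 0.4 mm
#' in-plane resolution, 6 mm slice thickness, 30 phases per cardiac cycle
#' and a stack of 13 slices of which the outermost carry no labelable left
#' ventricle. The default contraction fraction of 0.37 yields an analytic
#' ejection fraction of about 60%, matching a healthy baseline heart.
#'
#' @param n_slices Number of slices in the stack (typically 11-16).
#' @param n_phases Number of cardiac phases (>= 2).
#' @param image_size Image side length in pixels.
#' @param pixel_spacing_mm In-plane pixel spacing (isotropic), mm.
#' @param slice_thickness_mm Slice thickness, mm.
#' @param endo_radius_px End-diastolic endocardial radius per labeled slice
#'   in pixels. A scalar is recycled; `NULL` generates a base-to-apex linear
#'   taper scaled to the image size.
#' @param wall_thickness_px Myocardial wall thickness in pixels.
#' @param contraction_fraction Radial shrink of the cavity at end-systole,
#'   in `[0, 1)`. The analytic ejection fraction is
#'   `100 * (1 - (1 - contraction_fraction)^2)`.
#' @param infarct Optional [infarct_spec()] applied to the geometry.
#' @param empty_slice_margin Count of slices at each end of the stack
#'   (basal and apical) emitted with empty masks.
#' @param papillary Render papillary-muscle-like intensity features inside
#'   the cavity. They are never labeled as myocardium: the blood-pool label
#'   includes them, following the convention of not excluding papillary
#'   muscles from the blood pool.
#' @param seed Integer seed controlling the phantom's intensity texture.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(n_slices = 13, n_phases = 30, image_size = 160,
                           pixel_spacing_mm = 0.4, slice_thickness_mm = 6,
                           endo_radius_px = NULL, wall_thickness_px = 20,
                           contraction_fraction = 0.37, infarct = NULL,
                           empty_slice_margin = 1, papillary = TRUE,
                           seed = 1L) {
  stopifnot_scalar_num(n_slices, "n_slices", positive = TRUE)
  stopifnot_scalar_num(n_phases, "n_phases", positive = TRUE)
  if (n_phases < 2) stop("`n_phases` must be >= 2", call. = FALSE)
  stopifnot_scalar_num(image_size, "image_size", positive = TRUE)
  stopifnot_scalar_num(pixel_spacing_mm, "pixel_spacing_mm", positive = TRUE)
  stopifnot_scalar_num(slice_thickness_mm, "slice_thickness_mm", positive = TRUE)
  stopifnot_scalar_num(wall_thickness_px, "wall_thickness_px", positive = TRUE)
  stopifnot_scalar_num(contraction_fraction, "contraction_fraction")
  if (contraction_fraction < 0 || contraction_fraction >= 1)
    stop("`contraction_fraction` must lie in [0, 1)", call. = FALSE)
  if (empty_slice_margin < 0 || 2 * empty_slice_margin >= n_slices)
    stop("`empty_slice_margin` leaves no labeled slices", call. = FALSE)

  n_labeled <- n_slices - 2L * empty_slice_margin
  if (is.null(endo_radius_px)) {
    r_base <- 0.28 * image_size
    r_apex <- 0.14 * image_size
    endo_radius_px <- if (n_labeled == 1) r_base else
      seq(r_base, r_apex, length.out = n_labeled)
  }
  if (length(endo_radius_px) == 1L)
    endo_radius_px <- rep(endo_radius_px, n_labeled)
  if (length(endo_radius_px) != n_labeled)
    stop("`endo_radius_px` must have one entry per labeled slice (",
         n_labeled, ")", call. = FALSE)
  if (any(endo_radius_px <= 0))
    stop("`endo_radius_px` must be positive", call. = FALSE)
  if (max(endo_radius_px) + wall_thickness_px >= image_size / 2)
    stop("geometry exceeds image bounds: endo_radius_px + wall_thickness_px ",
         "must be < image_size / 2", call. = FALSE)
  if (!is.null(infarct)) validate_infarct_spec(infarct)

  structure(list(
    n_slices = as.integer(n_slices), n_phases = as.integer(n_phases),
    image_size = as.integer(image_size),
    pixel_spacing_mm = pixel_spacing_mm,
    slice_thickness_mm = slice_thickness_mm,
    endo_radius_px = endo_radius_px,
    wall_thickness_px = wall_thickness_px,
    contraction_fraction = contraction_fraction,
    infarct = infarct,
    empty_slice_margin = as.integer(empty_slice_margin),
    papillary = isTRUE(papillary),
    seed = as.integer(seed)
  ), class = "phantom_config")
}

#' Infarct specification: regional wall thinning over an angular sector
#'
#' @param sector_start_deg,sector_end_deg Sector limits in degrees,
#'   measured counter-clockwise from the positive x axis. A start greater
#'   than the end wraps around 360.
#' @param thinning_fraction Fraction of the wall thickness removed inside
#'   the sector, in `[0, 1)`.
#' @param affected_slices Integer indices of affected slices.
#' @return An `infarct_spec` list.
#' @export
infarct_spec <- function(sector_start_deg, sector_end_deg,
                         thinning_fraction, affected_slices) {
  spec <- structure(list(
    sector_start_deg = sector_start_deg %% 360,
    sector_end_deg = sector_end_deg %% 360,
    thinning_fraction = thinning_fraction,
    affected_slices = as.integer(affected_slices)
  ), class = "infarct_spec")
  validate_infarct_spec(spec)
  spec
}

validate_infarct_spec <- function(spec) {
  if (!is.numeric(spec$thinning_fraction) || spec$thinning_fraction < 0 ||
      spec$thinning_fraction >= 1)
    stop("`thinning_fraction` must lie in [0, 1)", call. = FALSE)
  arc <- (spec$sector_end_deg - spec$sector_start_deg) %% 360
  if (arc == 0 && spec$sector_end_deg != spec$sector_start_deg + 360)
    spec$full_circle <- FALSE
  if (length(spec$affected_slices) < 1)
    stop("`affected_slices` must name at least one slice", call. = FALSE)
  invisible(spec)
}

# Angular sector membership for angles in degrees (counter-clockwise from
# +x). A zero-width arc is interpreted as the full circle when start == end.
in_sector <- function(theta_deg, start, end) {
  theta <- theta_deg %% 360
  s <- start %% 360; e <- end %% 360
  if (s == e) return(rep(TRUE, length(theta)))  # full circle
  if (s < e) theta >= s & theta < e else theta >= s | theta < e
}

# Fraction of the full circle covered by the sector.
sector_fraction <- function(start, end) {
  s <- start %% 360; e <- end %% 360
  if (s == e) 1 else ((e - s) %% 360) / 360
}

# Smooth cyclic contraction weight: 0 at end-diastole (phase 1), 1 at
# end-systole, cosine interpolation in between and back.
phase_weight <- function(n_phases, es_phase) {
  p <- seq_len(n_phases)
  t <- (p - 1) / n_phases
  t_es <- (es_phase - 1) / n_phases
  w <- numeric(n_phases)
  up <- t <= t_es
  w[up] <- (1 - cos(pi * t[up] / t_es)) / 2
  w[!up] <- (1 + cos(pi * (t[!up] - t_es) / (1 - t_es))) / 2
  w
}

# Rasterize one slice/phase: labels by the pixel-center rule (a pixel
# belongs to a region iff its center lies inside the continuous boundary).
rasterize_lv <- function(size, r_endo, wall, infarct = NULL,
                         infarct_here = FALSE) {
  c0 <- (size + 1) / 2
  x <- matrix(rep(seq_len(size), each = size), size, size) - c0  # column
  y <- matrix(rep(seq_len(size), times = size), size, size) - c0 # row
  d <- sqrt(x^2 + y^2)
  wall_eff <- matrix(wall, size, size)
  if (!is.null(infarct) && infarct_here) {
    theta <- (atan2(y, x) * 180 / pi) %% 360
    sel <- in_sector(theta, infarct$sector_start_deg, infarct$sector_end_deg)
    wall_eff[sel] <- wall * (1 - infarct$thinning_fraction)
  }
  m <- matrix(0L, size, size)
  m[d < r_endo] <- 1L
  m[d >= r_endo & d < r_endo + wall_eff] <- 2L
  m
}

# Render image intensities from a label mask plus geometry. Papillary
# features are darker disks inside the cavity, labeled as blood pool.
render_slice <- function(mask, r_endo, papillary, texture) {
  size <- nrow(mask)
  img <- matrix(0.15, size, size)
  img[mask == 2L] <- 0.45
  img[mask == 1L] <- 0.95
  if (papillary && r_endo > 6) {
    c0 <- (size + 1) / 2
    x <- matrix(rep(seq_len(size), each = size), size, size) - c0
    y <- matrix(rep(seq_len(size), times = size), size, size) - c0
    for (ang in c(120, 240) * pi / 180) {
      px <- 0.55 * r_endo * cos(ang); py <- 0.55 * r_endo * sin(ang)
      pap <- sqrt((x - px)^2 + (y - py)^2) < 0.18 * r_endo
      img[pap & mask == 1L] <- 0.45
    }
  }
  img + texture
}

#' Generate a synthetic short-axis cine stack with ground truth
#'
#' Produces a 4D intensity stack (slice x phase x row x col) and matching
#' 3-class label masks (0 background, 1 blood pool, 2 myocardium), together
#' with analytic volumes computed from the continuous geometry
#' (sum over labeled slices of `pi * r^2 * thickness`).
#'
#' @param config A [phantom_config()].
#' @return A list with elements `stack` (4D numeric array) and
#'   `ground_truth`, a `ground_truth` object holding `masks` (4D integer
#'   array of the same slice/phase layout), `analytic_edv_ml`,
#'   `analytic_esv_ml`, `analytic_lv_mass_g`, `analytic_ef_percent`,
#'   `ed_phase`, `es_phase` and the generating geometry.
#' @export
generate_phantom_stack <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  S <- config$image_size
  ns <- config$n_slices; np <- config$n_phases
  margin <- config$empty_slice_margin
  labeled <- seq.int(margin + 1L, ns - margin)
  es_phase <- max(2L, as.integer(floor(np * 0.4)) + 1L)
  ed_phase <- 1L
  w <- phase_weight(np, es_phase)
  scale_p <- 1 - config$contraction_fraction * w

  radii <- rep(NA_real_, ns)
  radii[labeled] <- config$endo_radius_px

  stack <- array(0, dim = c(ns, np, S, S))
  masks <- array(0L, dim = c(ns, np, S, S))
  dx <- config$pixel_spacing_mm; dz <- config$slice_thickness_mm

  texture <- with_seed(derive_seed(config$seed, 1L),
                       matrix(stats::rnorm(S * S, sd = 0.02), S, S))
  inf <- config$infarct
  for (s in seq_len(ns)) {
    is_lab <- s %in% labeled
    inf_here <- !is.null(inf) && s %in% inf$affected_slices
    for (p in seq_len(np)) {
      if (is_lab) {
        r <- radii[s] * scale_p[p]
        m <- rasterize_lv(S, r, config$wall_thickness_px, inf, inf_here)
        masks[s, p, , ] <- m
        stack[s, p, , ] <- render_slice(m, r, config$papillary, texture)
      } else {
        stack[s, p, , ] <- 0.15 + texture
      }
    }
  }

  vol_ml <- function(scale) {
    r_mm <- radii[labeled] * scale * dx
    sum(pi * r_mm^2 * dz) / 1000
  }
  edv <- vol_ml(scale_p[ed_phase])
  esv <- vol_ml(scale_p[es_phase])
  mass <- analytic_mass_g(radii[labeled], config$wall_thickness_px,
                          dx, dz, inf, labeled)

  gt <- structure(list(
    masks = masks,
    analytic_edv_ml = edv, analytic_esv_ml = esv,
    analytic_lv_mass_g = mass,
    analytic_ef_percent = if (edv > 0) 100 * (edv - esv) / edv else NA_real_,
    ed_phase = ed_phase, es_phase = es_phase,
    geometry = list(
      radii_px = radii, labeled_slices = labeled,
      wall_thickness_px = config$wall_thickness_px,
      scale_p = scale_p, infarct = inf, config = config
    )
  ), class = "ground_truth")
  list(stack = stack, ground_truth = gt)
}

# Analytic myocardial mass at end-diastole: annulus area per slice, reduced
# proportionally inside an infarct sector, times thickness and density.
analytic_mass_g <- function(r_endo, wall, dx, dz, infarct, labeled,
                            density = 1.05) {
  area_px2 <- vapply(seq_along(r_endo), function(i) {
    r <- r_endo[i]
    full <- pi * ((r + wall)^2 - r^2)
    s <- labeled[i]
    if (!is.null(infarct) && s %in% infarct$affected_slices) {
      f <- sector_fraction(infarct$sector_start_deg, infarct$sector_end_deg)
      wt <- wall * (1 - infarct$thinning_fraction)
      thin <- pi * ((r + wt)^2 - r^2)
      (1 - f) * full + f * thin
    } else full
  }, numeric(1))
  sum(area_px2 * dx^2 * dz) * density / 1000
}

#' Apply regional wall thinning to a phantom's ground truth
#'
#' Re-rasterizes the affected slices with the wall thinned inside the
#' infarct sector. The cavity is unchanged; the myocardial pixel count
#' strictly decreases in affected slices for a positive thinning fraction.
#'
#' @param ground_truth A `ground_truth` object from [generate_phantom_stack()].
#' @param spec An [infarct_spec()].
#' @return A new `ground_truth` with updated masks and analytic mass.
#' @export
apply_infarct <- function(ground_truth, spec) {
  stopifnot(inherits(ground_truth, "ground_truth"))
  validate_infarct_spec(spec)
  geo <- ground_truth$geometry
  bad <- setdiff(spec$affected_slices, geo$labeled_slices)
  if (length(bad))
    stop("affected slices carry no labels: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (spec$thinning_fraction == 0) return(ground_truth)
  S <- geo$config$image_size
  gt <- ground_truth
  for (s in spec$affected_slices) {
    for (p in seq_along(geo$scale_p)) {
      r <- geo$radii_px[s] * geo$scale_p[p]
      gt$masks[s, p, , ] <- rasterize_lv(S, r, geo$wall_thickness_px,
                                         spec, TRUE)
    }
  }
  gt$geometry$infarct <- spec
  gt$analytic_lv_mass_g <- analytic_mass_g(
    geo$radii_px[geo$labeled_slices], geo$wall_thickness_px,
    geo$config$pixel_spacing_mm, geo$config$slice_thickness_mm,
    spec, geo$labeled_slices)
  gt
}

#' Image quality score on the 3-category ordinal scale
#'
#' Each category (artefacts, noise, general image quality) is rated from 1
#' (best) to 4 (worst); the total score is their sum, bounded by 3 and 12.
#'
#' @param artefacts,noise,general Integer ratings in 1..4.
#' @return A `quality_score` list.
#' @export
quality_score <- function(artefacts, noise, general) {
  for (v in list(artefacts = artefacts, noise = noise, general = general)) {
    if (!is.numeric(v) || length(v) != 1L || !(v %in% 1:4))
      stop("quality ratings must be integers in 1..4", call. = FALSE)
  }
  structure(list(artefacts = as.integer(artefacts),
                 noise = as.integer(noise),
                 general = as.integer(general)),
            class = "quality_score")
}

#' Total image quality score
#'
#' @param q A [quality_score()].
#' @return Integer sum of the three category ratings, in 3..12.
#' @export
total_quality_score <- function(q) {
  if (!inherits(q, "quality_score"))
    q <- quality_score(q$artefacts, q$noise, q$general)
  q$artefacts + q$noise + q$general
}

#' Degrade a cine stack according to a quality score
#'
#' A rating of 1 in a category leaves that degradation channel off; higher
#' ratings increase it monotonically. Channels: Gaussian background noise
#' (noise rating, sd `0.04 * (rating - 1)`), multiplicative low-frequency
#' shading bands emulating B0/B1 field inhomogeneity (artefact rating,
#' amplitude `0.12 * (rating - 1)`), and Gaussian blur (general rating,
#' sigma `0.6 * (rating - 1)` pixels). Ground-truth masks are untouched.
#'
#' @param stack 4D intensity array (slice x phase x row x col).
#' @param q A [quality_score()].
#' @param seed Integer seed; same stack, score and seed give identical output.
#' @return Degraded stack of the same dimensions.
#' @export
inject_degradation <- function(stack, q, seed = 1L) {
  if (!inherits(q, "quality_score"))
    q <- quality_score(q$artefacts, q$noise, q$general)
  if (q$artefacts == 1L && q$noise == 1L && q$general == 1L) return(stack)
  d <- dim(stack)
  S <- d[3]
  sigma_n <- 0.04 * (q$noise - 1)
  amp_a <- 0.12 * (q$artefacts - 1)
  sigma_b <- 0.6 * (q$general - 1)
  with_seed(seed, {
    out <- stack
    rows <- matrix(rep(seq_len(S), times = d[4]), S, d[4])
    cols <- matrix(rep(seq_len(d[4]), each = S), S, d[4])
    for (s in seq_len(d[1])) for (p in seq_len(d[2])) {
      img <- stack[s, p, , ]
      if (sigma_b > 0) img <- EBImage::gblur(img, sigma = sigma_b)
      if (amp_a > 0) {
        phi <- stats::runif(1, 0, 2 * pi)
        ang <- stats::runif(1, 0, pi)
        freq <- stats::runif(1, 1.5, 3)
        u <- cos(ang); v <- sin(ang)
        shade <- 1 + amp_a * sin(2 * pi * freq * (u * rows + v * cols) / S + phi)
        img <- img * shade
      }
      if (sigma_n > 0) img <- img + stats::rnorm(length(img), sd = sigma_n)
      out[s, p, , ] <- img
    }
    out
  })
}

#' Animal-wise, group-stratified dataset split
#'
#' Assigns whole animals to train/validation/test so that no animal's scans
#' straddle subsets, stratifying by experimental group (e.g., infarct vs.
#' sham) with largest-remainder apportionment of each group across subsets;
#' assignment within a group is random given the seed.
#'
#' @param animals Data frame with columns `id` and `group`.
#' @param counts Integer vector `c(train, validation, test)` of animal
#'   counts; must sum to `nrow(animals)`.
#' @param seed Integer seed for within-group shuffling.
#' @param quotas Optional 3-column matrix (groups x subsets) overriding the
#'   apportionment; rows must sum to group sizes, columns to `counts`.
#' @return A `dataset_split` list with elements `train`, `validation`,
#'   `test` (character id vectors) and `quotas`.
#' @export
split_animals <- function(animals, counts, seed = 1L, quotas = NULL) {
  stopifnot(is.data.frame(animals), all(c("id", "group") %in% names(animals)))
  if (anyDuplicated(animals$id)) stop("duplicate animal ids", call. = FALSE)
  counts <- as.integer(counts)
  if (length(counts) != 3L || any(counts < 0))
    stop("`counts` must be three non-negative integers", call. = FALSE)
  if (sum(counts) != nrow(animals))
    stop("`counts` must sum to the number of animals", call. = FALSE)
  groups <- unique(as.character(animals$group))
  sizes <- vapply(groups, function(g) sum(animals$group == g), integer(1))

  if (is.null(quotas)) {
    quotas <- matrix(0L, length(groups), 3,
                     dimnames = list(groups, c("train", "validation", "test")))
    n <- nrow(animals)
    for (gi in seq_along(groups)) {
      target <- counts * sizes[gi] / n
      fl <- floor(target)
      rem <- sizes[gi] - sum(fl)
      if (rem > 0) {
        ord <- order(target - fl, decreasing = TRUE)
        fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
      }
      quotas[gi, ] <- as.integer(fl)
    }
    # repair pass: column totals must match `counts`
    for (iter in seq_len(100)) {
      delta <- colSums(quotas) - counts
      if (all(delta == 0)) break
      over <- which(delta > 0)[1]; under <- which(delta < 0)[1]
      gi <- which(quotas[, over] > 0)[1]
      if (is.na(gi)) stop("infeasible split quotas", call. = FALSE)
      quotas[gi, over] <- quotas[gi, over] - 1L
      quotas[gi, under] <- quotas[gi, under] + 1L
    }
  } else {
    quotas <- as.matrix(quotas)
    if (!all(rowSums(quotas) == sizes) || !all(colSums(quotas) == counts))
      stop("infeasible split quotas", call. = FALSE)
  }

  assign <- with_seed(seed, {
    out <- list(train = character(), validation = character(),
                test = character())
    for (gi in seq_along(groups)) {
      ids <- sample(as.character(animals$id[animals$group == groups[gi]]))
      idx <- cumsum(c(0, quotas[gi, ]))
      for (k in 1:3) {
        take <- if (quotas[gi, k] > 0) ids[(idx[k] + 1):idx[k + 1]] else character()
        out[[k]] <- c(out[[k]], take)
      }
    }
    out
  })
  structure(c(assign, list(quotas = quotas)), class = "dataset_split")
}

#' Simulate an observer's segmentation by perturbing phantom geometry
#'
#' Re-rasterizes each labeled slice with the endocardial radius and wall
#' thickness jittered multiplicatively (lognormal-like, per slice) and an
#' optional systematic radial offset, emulating intra-/inter-observer
#' delineation variability.
#'
#' @param ground_truth A `ground_truth` object.
#' @param radius_sd,wall_sd Relative jitter SDs for radius and wall.
#' @param radius_bias Systematic multiplicative radius offset (e.g., 0.02
#'   for an observer drawing the endocardial contour 2% outward).
#' @param seed Integer seed.
#' @return A `ground_truth` with perturbed masks (analytic fields dropped).
#' @export
simulate_observer <- function(ground_truth, radius_sd = 0.03, wall_sd = 0.03,
                              radius_bias = 0, seed = 1L) {
  stopifnot(inherits(ground_truth, "ground_truth"))
  geo <- ground_truth$geometry
  S <- geo$config$image_size
  gt <- ground_truth
  gt$analytic_edv_ml <- gt$analytic_esv_ml <- NA_real_
  gt$analytic_lv_mass_g <- gt$analytic_ef_percent <- NA_real_
  with_seed(seed, {
    for (s in geo$labeled_slices) {
      fr <- (1 + radius_bias) * exp(stats::rnorm(1, sd = radius_sd))
      fw <- exp(stats::rnorm(1, sd = wall_sd))
      inf <- geo$infarct
      inf_here <- !is.null(inf) && s %in% inf$affected_slices
      for (p in seq_along(geo$scale_p)) {
        r <- geo$radii_px[s] * geo$scale_p[p] * fr
        gt$masks[s, p, , ] <- rasterize_lv(S, r, geo$wall_thickness_px * fw,
                                           inf, inf_here)
      }
    }
  })
  gt
}

#' Write a phantom scan to NIfTI files with a JSON ground-truth sidecar
#'
#' The 4D stack and masks are written with dimension order
#' row x col x slice x phase (documented in the NIfTI description field);
#' analytic ground truth and spacing go to a JSON sidecar.
#'
#' @param phantom List with `stack` and `ground_truth`, as returned by
#'   [generate_phantom_stack()].
#' @param dir Output directory (created if needed).
#' @param name Base file name.
#' @return Invisibly, the paths written.
#' @export
write_phantom_nifti <- function(phantom, dir, name = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gt <- phantom$ground_truth
  cfg <- gt$geometry$config
  reorder <- function(a) aperm(a, c(3, 4, 1, 2))
  paths <- c(
    stack = file.path(dir, paste0(name, "_stack.nii")),
    masks = file.path(dir, paste0(name, "_masks.nii")),
    json = file.path(dir, paste0(name, "_truth.json")))
  pd <- c(cfg$pixel_spacing_mm, cfg$pixel_spacing_mm,
          cfg$slice_thickness_mm, 1)
  img <- RNifti::asNifti(reorder(phantom$stack))
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, paths["stack"])
  msk <- RNifti::asNifti(reorder(gt$masks))
  RNifti::pixdim(msk) <- pd
  RNifti::writeNifti(msk, paths["masks"])
  jsonlite::write_json(list(
    analytic_edv_ml = gt$analytic_edv_ml,
    analytic_esv_ml = gt$analytic_esv_ml,
    analytic_lv_mass_g = gt$analytic_lv_mass_g,
    analytic_ef_percent = gt$analytic_ef_percent,
    ed_phase = gt$ed_phase, es_phase = gt$es_phase,
    pixel_spacing_mm = cfg$pixel_spacing_mm,
    slice_thickness_mm = cfg$slice_thickness_mm,
    dim_order = "row-col-slice-phase"
  ), paths["json"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
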