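# Synthetic cine phantom generator: geometry, contraction, infarct,
# degradation, quality scores and the animal-wise split.

test_that("rasterized cavity volume matches the closed-form disk volume", {
  cfg <- phantom_config(n_slices = 3, n_phases = 4, image_size = 48,
                        endo_radius_px = 8, wall_thickness_px = 5,
                        contraction_fraction = 0.3,
                        empty_slice_margin = 1, seed = 7)
  ph <- generate_phantom_stack(cfg)
  gt <- ph$ground_truth
  # one labeled slice: pi * (8 * 0.4 mm)^2 * 6 mm = 193.02 mm^3
  expect_equal(gt$analytic_edv_ml * 1000, pi * (8 * 0.4)^2 * 6,
               tolerance = 1e-12)
  vox_mm3 <- sum(gt$masks[, gt$ed_phase, , ] == 1L) * 0.4 * 0.4 * 6
  expect_lt(abs(vox_mm3 - gt$analytic_edv_ml * 1000) /
              (gt$analytic_edv_ml * 1000), 0.05)
  expect_equal(dim(ph$stack), c(3, 4, 48, 48))
  expect_true(all(gt$masks %in% 0:2))
})

test_that("zero contraction gives identical ED/ES masks and zero EF", {
  cfg <- phantom_config(n_slices = 3, n_phases = 6, image_size = 40,
                        endo_radius_px = 9, wall_thickness_px = 5,
                        contraction_fraction = 0, empty_slice_margin = 1,
                        seed = 2)
  gt <- generate_phantom_stack(cfg)$ground_truth
  expect_identical(gt$masks[, gt$ed_phase, , ], gt$masks[, gt$es_phase, , ])
  expect_equal(gt$analytic_ef_percent, 0)
})

test_that("phantom generation is bit-identical under the same seed", {
  cfg <- phantom_config(n_slices = 3, n_phases = 3, image_size = 32,
                        endo_radius_px = 8, wall_thickness_px = 4,
                        empty_slice_margin = 1, seed = 11)
  a <- generate_phantom_stack(cfg)
  b <- generate_phantom_stack(cfg)
  expect_identical(a$stack, b$stack)
  expect_identical(a$ground_truth$masks, b$ground_truth$masks)
})

test_that("geometry exceeding the image bounds is rejected", {
  expect_error(phantom_config(image_size = 32, endo_radius_px = 14,
                              wall_thickness_px = 4, n_slices = 3,
                              empty_slice_margin = 1),
               "exceeds image bounds")
})

test_that("rasterization error shrinks as pixel spacing is refined", {
  # same physical geometries at 1.2 vs 0.4 mm spacing; the discretization
  # error of any one circle is not monotone in the spacing, so compare the
  # mean relative error over several radii
  mean_err <- function(sp) {
    errs <- vapply(c(5.2, 6.4, 7.6, 8.8, 10.0), function(r_mm) {
      cfg <- phantom_config(n_slices = 3, n_phases = 2,
                            image_size = 2 * ceiling(16 / sp),
                            pixel_spacing_mm = sp,
                            endo_radius_px = r_mm / sp,
                            wall_thickness_px = 3.6 / sp,
                            contraction_fraction = 0.3,
                            empty_slice_margin = 1, seed = 5)
      gt <- generate_phantom_stack(cfg)$ground_truth
      vc <- volumetry_config(c(sp, sp), cfg$slice_thickness_mm)
      v <- blood_pool_volume(gt$masks[, gt$ed_phase, , , drop = FALSE], vc)
      abs(v - gt$analytic_edv_ml) / gt$analytic_edv_ml
    }, numeric(1))
    mean(errs)
  }
  expect_lt(mean_err(0.4), mean_err(1.2))
})

test_that("infarct thinning reduces the myocardium as the sector dictates", {
  cfg <- phantom_config(n_slices = 3, n_phases = 2, image_size = 64,
                        endo_radius_px = 14, wall_thickness_px = 8,
                        contraction_fraction = 0.3, empty_slice_margin = 1,
                        seed = 3)
  ph <- generate_phantom_stack(cfg)
  gt <- ph$ground_truth

  # identity for zero thinning
  same <- apply_infarct(gt, infarct_spec(0, 90, 0, affected_slices = 2))
  expect_identical(same$masks, gt$masks)

  # 90-degree sector, thinning 0.5: affected myocardial area drops by
  # about 1/4 * 1/2 = 12.5% of the annulus area
  spec <- infarct_spec(0, 90, 0.5, affected_slices = 2)
  out <- apply_infarct(gt, spec)
  before <- sum(gt$masks[2, 1, , ] == 2L)
  after <- sum(out$masks[2, 1, , ] == 2L)
  expect_lt(after, before)
  # annulus area shrinks towards the analytic sector prediction
  r <- 14; w <- 8
  annulus <- pi * ((r + w)^2 - r^2)
  removed_expect <- 0.25 * (pi * ((r + w)^2 - (r + w / 2)^2))
  expect_equal((before - after) / annulus, removed_expect / annulus,
               tolerance = 0.08)
  # cavity untouched
  expect_identical(out$masks[2, 1, , ] == 1L, gt$masks[2, 1, , ] == 1L)
  expect_true(all(out$masks %in% 0:2))

  # full-circle sector halves the wall thickness along a radial profile
  full <- apply_infarct(gt, infarct_spec(0, 360, 0.5, affected_slices = 2))
  row0 <- (64 + 1) / 2
  profile <- full$masks[2, 1, round(row0), ]
  run_len <- function(m) sum(m == 2L & seq_along(m) > row0)
  expect_equal(run_len(profile),
               run_len(gt$masks[2, 1, round(row0), ]) / 2,
               tolerance = 0.3)

  expect_error(infarct_spec(0, 90, 1.2, 2), "thinning_fraction")
  expect_error(apply_infarct(gt, infarct_spec(0, 90, 0.5, 99)),
               "no labels")
})

test_that("degradation respects the quality-score contract", {
  cfg <- phantom_config(n_slices = 3, n_phases = 2, image_size = 32,
                        endo_radius_px = 8, wall_thickness_px = 4,
                        empty_slice_margin = 1, seed = 4)
  ph <- generate_phantom_stack(cfg)

  # best score leaves the stack untouched
  expect_identical(inject_degradation(ph$stack, quality_score(1, 1, 1), 9),
                   ph$stack)
  # noise rating 4 produces more background spread than rating 2 (same seed)
  bg <- ph$ground_truth$masks[2, 1, , ] == 0L
  s2 <- inject_degradation(ph$stack, quality_score(1, 2, 1), 9)
  s4 <- inject_degradation(ph$stack, quality_score(1, 4, 1), 9)
  expect_gt(stats::sd(s4[2, 1, , ][bg]), stats::sd(s2[2, 1, , ][bg]))
  # seeded determinism
  expect_identical(inject_degradation(ph$stack, quality_score(3, 3, 3), 5),
                   inject_degradation(ph$stack, quality_score(3, 3, 3), 5))
  # masks live outside the stack and are therefore untouched by construction;
  # the degraded stack keeps its geometry
  expect_identical(dim(s4), dim(ph$stack))
})

test_that("quality scores are validated and summed", {
  expect_equal(total_quality_score(quality_score(1, 1, 1)), 3L)
  expect_equal(total_quality_score(quality_score(4, 4, 4)), 12L)
  expect_equal(total_quality_score(quality_score(2, 2, 2)), 6L)
  expect_error(quality_score(0, 2, 2), "1..4")
  expect_error(quality_score(2, 5, 2), "1..4")
})

test_that("animal-wise split reproduces the reference composition", {
  animals <- data.frame(id = sprintf("pig%02d", 1:11),
                        group = c(rep("infarct", 7), rep("sham", 4)))
  sp <- split_animals(animals, c(6, 2, 3), seed = 1)
  count <- function(ids, g) sum(animals$group[match(ids, animals$id)] == g)
  expect_equal(count(sp$train, "infarct"), 4)
  expect_equal(count(sp$train, "sham"), 2)
  expect_equal(count(sp$validation, "infarct"), 1)
  expect_equal(count(sp$validation, "sham"), 1)
  expect_equal(count(sp$test, "infarct"), 2)
  expect_equal(count(sp$test, "sham"), 1)
})

test_that("split is disjoint and stratified over many seeds", {
  animals <- data.frame(id = sprintf("pig%02d", 1:11),
                        group = c(rep("infarct", 7), rep("sham", 4)))
  for (seed in 1:100) {
    sp <- split_animals(animals, c(6, 2, 3), seed = seed)
    all_ids <- c(sp$train, sp$validation, sp$test)
    expect_equal(sort(all_ids), sort(animals$id))
    expect_equal(anyDuplicated(all_ids), 0L)
    expect_equal(sum(animals$group[match(sp$train, animals$id)] ==
                       "infarct"), 4)
  }
})

test_that("degenerate and infeasible splits behave", {
  animals <- data.frame(id = sprintf("pig%02d", 1:11),
                        group = c(rep("infarct", 7), rep("sham", 4)))
  sp <- split_animals(animals, c(11, 0, 0), seed = 2)
  expect_equal(sort(sp$train), sort(animals$id))
  expect_length(sp$validation, 0)
  expect_length(sp$test, 0)
  expect_error(split_animals(animals, c(5, 2, 3)), "sum")
  bad_quota <- matrix(c(7, 0, 0, 0, 2, 1), 2, 3, byrow = TRUE)
  expect_error(split_animals(animals, c(7, 2, 2), quotas = bad_quota),
               "infeasible")
})

test_that("NIfTI export round-trips the stack, masks and spacing", {
  cfg <- phantom_config(n_slices = 3, n_phases = 2, image_size = 24,
                        endo_radius_px = 6, wall_thickness_px = 3,
                        empty_slice_margin = 1, seed = 6)
  ph <- generate_phantom_stack(cfg)
  d <- withr::local_tempdir()
  paths <- write_phantom_nifti(ph, d, "scan1")
  img <- RNifti::readNifti(paths["stack"])
  expect_equal(dim(img), c(24, 24, 3, 2))
  expect_equal(as.array(img), aperm(ph$stack, c(3, 4, 1, 2)),
               ignore_attr = TRUE, tolerance = 1e-6)
  expect_equal(RNifti::pixdim(img)[1:3], c(0.4, 0.4, 6))
  truth <- jsonlite::read_json(paths["json"])
  expect_equal(truth$analytic_edv_ml, ph$ground_truth$analytic_edv_ml)
})
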