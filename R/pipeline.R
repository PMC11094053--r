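# End-to-end study orchestration over synthetic cohorts: generate ->
# observers -> split -> train -> predict -> contours -> function ->
# agreement -> statistics, with persisted intermediates and full
# determinism given the run seed.

#' Study run configuration
#'
#' Desk-scale defaults emulate the reference cohort's proportions: 11
#' animals (7 infarct, 4 sham) split animal-wise 6/2/3, each contributing
#' one cine scan, with only end-diastolic and end-systolic frames labeled
#' and evaluated (an `all_phases` flag enables all-phase prediction).
#'
#' @param n_animals,n_infarct Cohort size and infarct-group size.
#' @param split_counts Animal counts `c(train, validation, test)`.
#' @param phantom Named list of overrides passed to [phantom_config()]
#'   (per-animal seeds and geometry jitter are added internally).
#' @param input_size,base_filters Segmentation model geometry.
#' @param pretrain_epochs,pretrain_max_lr Source-distribution pretraining
#'   (emulating the transfer-learning starting point).
#' @param schedule A [train_schedule()].
#' @param policy An [augment_policy()] or NULL for no augmentation.
#' @param tau Myocardium-Dice threshold for correct/incorrect
#'   classification.
#' @param hd_units `"px"` or `"mm"` for Hausdorff distances.
#' @param overall_alpha,m_hypotheses Bonferroni inputs for the t-tests.
#' @param all_phases Predict and evaluate all phases, not only ED/ES.
#' @param seed Master seed; a run is reproducible from config + seed.
#' @param out_dir Output directory for persisted intermediates (NULL for
#'   none).
#' @return A `run_config` list.
#' @export
run_config <- function(n_animals = 11, n_infarct = 7,
                       split_counts = c(6, 2, 3),
                       phantom = list(n_slices = 7, n_phases = 8,
                                      image_size = 48,
                                      empty_slice_margin = 1),
                       input_size = 32, base_filters = 8,
                       pretrain_epochs = 2, pretrain_max_lr = 5e-3,
                       schedule = train_schedule(frozen_epochs = 6,
                                                 frozen_max_lr = 2e-2,
                                                 unfrozen_epochs = 4,
                                                 unfrozen_max_lr = 2e-3,
                                                 checkpoint_every = 2),
                       policy = NULL, tau = 0.5, hd_units = "px",
                       overall_alpha = 0.05, m_hypotheses = 4,
                       all_phases = FALSE, seed = 1L, out_dir = NULL) {
  if (n_infarct < 0 || n_infarct > n_animals)
    stop("`n_infarct` must lie between 0 and `n_animals`", call. = FALSE)
  split_counts <- as.integer(split_counts)
  if (sum(split_counts) != n_animals)
    stop("`split_counts` must sum to `n_animals`", call. = FALSE)
  if (any(split_counts[c(1, 2)] == 0) || split_counts[3] == 0)
    stop("train, validation and test sets must each contain at least one animal",
         call. = FALSE)
  structure(list(n_animals = as.integer(n_animals),
                 n_infarct = as.integer(n_infarct),
                 split_counts = split_counts, phantom = phantom,
                 input_size = as.integer(input_size),
                 base_filters = as.integer(base_filters),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 pretrain_max_lr = pretrain_max_lr,
                 schedule = schedule, policy = policy, tau = tau,
                 hd_units = hd_units, overall_alpha = overall_alpha,
                 m_hypotheses = as.integer(m_hypotheses),
                 all_phases = isTRUE(all_phases),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

# Build a phantom_config for one animal with deterministic per-animal
# geometry jitter; infarct animals get a thinned sector and a reduced
# contraction fraction (lower EF), mirroring post-infarction function.
animal_phantom_config <- function(cfg, animal_idx, group) {
  base <- cfg$phantom
  seed <- derive_seed(cfg$seed, 100L + animal_idx)
  jit <- with_seed(seed, stats::runif(3, 0.9, 1.1))
  size <- base$image_size %||% 48
  n_slices <- base$n_slices %||% 7
  margin <- base$empty_slice_margin %||% 1
  n_lab <- n_slices - 2 * margin
  r_base <- 0.26 * size * jit[1]
  r_apex <- 0.14 * size * jit[2]
  radii <- if (n_lab == 1) r_base else seq(r_base, r_apex,
                                           length.out = n_lab)
  contraction <- if (group == "infarct") 0.22 * jit[3] else 0.37 * jit[3]
  infarct <- if (group == "infarct") {
    mid <- ceiling(n_slices / 2)
    infarct_spec(20, 110, 0.4, affected_slices = unique(c(mid, mid + 1)))
  } else NULL
  args <- list(n_slices = n_slices,
               n_phases = base$n_phases %||% 8,
               image_size = size,
               pixel_spacing_mm = base$pixel_spacing_mm %||% 0.4,
               slice_thickness_mm = base$slice_thickness_mm %||% 6,
               endo_radius_px = radii,
               wall_thickness_px = (base$wall_thickness_px %||% (0.1 * size)) ,
               contraction_fraction = contraction,
               infarct = infarct,
               empty_slice_margin = margin,
               papillary = base$papillary %||% TRUE,
               seed = seed)
  do.call(phantom_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Collect labeled frames of one scan as a list of image/mask pairs keyed
# by "<scan>/s<slice>/p<phase>".
collect_frames <- function(scan_id, stack, masks, phases) {
  out <- list()
  for (s in seq_len(dim(stack)[1])) for (p in phases) {
    key <- sprintf("%s/s%02d/p%02d", scan_id, s, p)
    out[[key]] <- list(image = stack[s, p, , ], mask = masks[s, p, , ],
                       scan = scan_id, slice = s, phase = p)
  }
  out
}

#' Compare two labelings image by image
#'
#' Computes per-image Dice and Hausdorff agreement for every key present
#' in both labelings (supports observer-vs-observer, observer-vs-repeat
#' and observer-vs-model comparisons), plus the aggregate (mean Dice,
#' median HD over defined pairs).
#'
#' @param ref_masks,other_masks Named lists of 2D label masks with
#'   matching keys.
#' @param hd_units,pixel_spacing_mm Passed to [pairwise_agreement()].
#' @return List with `per_image` (data frame) and `aggregate` (one row).
#' @export
compare_labelings <- function(ref_masks, other_masks, hd_units = "px",
                              pixel_spacing_mm = 0.4) {
  keys <- intersect(names(ref_masks), names(other_masks))
  if (length(keys) == 0) stop("no common image keys", call. = FALSE)
  rows <- lapply(keys, function(k) {
    r <- pairwise_agreement(other_masks[[k]], ref_masks[[k]],
                            hd_units = hd_units,
                            pixel_spacing_mm = pixel_spacing_mm)
    cbind(data.frame(key = k), r)
  })
  per_image <- do.call(rbind, rows)
  list(per_image = per_image, aggregate = aggregate_agreement(per_image))
}

#' Run the full synthetic study
#'
#' Executes all stages in order: cohort generation with quality-graded
#' degradation, simulated observers (first observer, repeat, second
#' observer), animal-wise stratified split, source-distribution
#' pretraining plus two-step transfer training, test-set prediction,
#' contour export, cardiac-function computation with pinned ED/ES phases,
#' pairwise agreement and the reproducibility statistics. Identical
#' config and seed yield an identical report; intermediates are persisted
#' to `cfg$out_dir` when set.
#'
#' @param cfg A [run_config()].
#' @return A `study_report` list: `function_table`, `agreement_table`,
#'   `stats_table`, `status_tally`, `checkpoints`, `split`.
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  groups <- c(rep("infarct", cfg$n_infarct),
              rep("sham", cfg$n_animals - cfg$n_infarct))
  animals <- data.frame(id = sprintf("animal%02d", seq_len(cfg$n_animals)),
                        group = groups)

  # --- stage 1: cohort ---
  scans <- list()
  for (i in seq_len(cfg$n_animals)) {
    pcfg <- animal_phantom_config(cfg, i, animals$group[i])
    ph <- generate_phantom_stack(pcfg)
    q <- with_seed(derive_seed(cfg$seed, 200L + i),
                   quality_score(sample(2:3, 1), sample(1:3, 1),
                                 sample(1:3, 1)))
    stack <- inject_degradation(ph$stack, q,
                                seed = derive_seed(cfg$seed, 300L + i))
    scans[[animals$id[i]]] <- list(stack = stack, gt = ph$ground_truth,
                                   quality = q, group = animals$group[i])
  }

  # --- stage 2: simulated observers ---
  for (id in names(scans)) {
    i <- match(id, animals$id)
    sc <- scans[[id]]
    scans[[id]]$obs1 <- simulate_observer(sc$gt, 0.02, 0.02, 0,
                                          derive_seed(cfg$seed, 400L + i))
    scans[[id]]$obs1b <- simulate_observer(sc$gt, 0.02, 0.02, 0,
                                           derive_seed(cfg$seed, 500L + i))
    scans[[id]]$obs2 <- simulate_observer(sc$gt, 0.04, 0.04, 0.03,
                                          derive_seed(cfg$seed, 600L + i))
  }

  # --- stage 3: animal-wise split ---
  split <- split_animals(animals, cfg$split_counts,
                         seed = derive_seed(cfg$seed, 7L))

  frames_of <- function(ids, labeling = "obs1") {
    out <- list()
    for (id in ids) {
      sc <- scans[[id]]
      phases <- if (cfg$all_phases) seq_len(dim(sc$stack)[2]) else
        c(sc$gt$ed_phase, sc$gt$es_phase)
      out <- c(out, collect_frames(id, sc$stack, sc[[labeling]]$masks,
                                   phases))
    }
    out
  }
  train_set <- frames_of(split$train)
  val_set <- frames_of(split$validation)
  test_set <- frames_of(split$test)

  # --- stage 4: pretraining on a source distribution, then transfer ---
  model <- unet_init(cfg$input_size, cfg$base_filters,
                     seed = derive_seed(cfg$seed, 8L))
  if (cfg$pretrain_epochs > 0) {
    src <- source_distribution_set(cfg)
    model <- pretrain_model(model, src, epochs = cfg$pretrain_epochs,
                            max_lr = cfg$pretrain_max_lr,
                            batch_size = cfg$schedule$batch_size,
                            seed = derive_seed(cfg$seed, 9L))
  }
  run <- train_transfer(model, train_set, val_set, cfg$schedule,
                        policy = cfg$policy,
                        seed = derive_seed(cfg$seed, 10L))

  # --- stage 5: prediction + contours on the test set ---
  pred_masks <- lapply(test_set, function(ex)
    predict_mask(run$best_model, ex$image))
  ref_masks <- lapply(test_set, `[[`, "mask")

  contour_files <- NULL
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    contour_files <- write_prediction_contours(pred_masks, test_set, cfg,
                                               scans)
  }

  # --- stage 6: cardiac function per scan and labeling ---
  vcfg <- volumetry_config(
    pixel_spacing_mm = rep(cfg$phantom$pixel_spacing_mm %||% 0.4, 2),
    slice_thickness_mm = cfg$phantom$slice_thickness_mm %||% 6)
  labelings <- c("obs1", "obs1b", "obs2")
  fun_rows <- list()
  model_fun <- list()
  for (id in names(scans)) {
    sc <- scans[[id]]
    for (lab in labelings) {
      f <- compute_function(sc[[lab]]$masks, vcfg,
                            ed_phase = sc$gt$ed_phase,
                            es_phase = sc$gt$es_phase)
      fun_rows[[paste(id, lab)]] <- cbind(
        data.frame(scan = id, group = sc$group, labeling = lab),
        function_table(stats::setNames(list(f), id))[-1])
    }
  }
  for (id in split$test) {
    sc <- scans[[id]]
    d <- dim(sc$gt$masks)
    pm <- array(0L, d)
    for (s in seq_len(d[1])) for (p in c(sc$gt$ed_phase, sc$gt$es_phase)) {
      key <- sprintf("%s/s%02d/p%02d", id, s, p)
      if (!is.null(pred_masks[[key]])) pm[s, p, , ] <- pred_masks[[key]]
    }
    f <- compute_function(pm, vcfg, ed_phase = sc$gt$ed_phase,
                          es_phase = sc$gt$es_phase)
    model_fun[[id]] <- f
    fun_rows[[paste(id, "model")]] <- cbind(
      data.frame(scan = id, group = sc$group, labeling = "model"),
      function_table(stats::setNames(list(f), id))[-1])
  }
  function_tab <- do.call(rbind, fun_rows)
  rownames(function_tab) <- NULL

  # --- stage 7: agreement on masks ---
  all_masks <- function(labeling, ids) {
    out <- list()
    for (id in ids) {
      sc <- scans[[id]]
      phases <- c(sc$gt$ed_phase, sc$gt$es_phase)
      for (s in seq_len(dim(sc$stack)[1])) for (p in phases)
        out[[sprintf("%s/s%02d/p%02d", id, s, p)]] <-
          sc[[labeling]]$masks[s, p, , ]
    }
    out
  }
  sp <- cfg$phantom$pixel_spacing_mm %||% 0.4
  comparisons <- list(
    intra_observer = compare_labelings(all_masks("obs1", animals$id),
                                       all_masks("obs1b", animals$id),
                                       cfg$hd_units, sp),
    inter_observer = compare_labelings(all_masks("obs1", animals$id),
                                       all_masks("obs2", animals$id),
                                       cfg$hd_units, sp),
    model_vs_obs1 = compare_labelings(all_masks("obs1", split$test),
                                      pred_masks, cfg$hd_units, sp))
  agreement_tab <- do.call(rbind, lapply(names(comparisons), function(nm)
    cbind(data.frame(comparison = nm), comparisons[[nm]]$aggregate)))

  # --- stage 8: prediction status tally ---
  statuses <- vapply(names(pred_masks), function(k)
    classify_prediction(pred_masks[[k]], ref_masks[[k]], cfg$tau),
    character(1))
  tally <- prediction_status_tally(statuses)

  # --- stage 9: reproducibility statistics per parameter ---
  params <- c(ef_percent = "EF", sv_ml = "SV", lv_mass_g = "LV mass",
              edv_ml = "EDV", esv_ml = "ESV")
  series_for <- function(lab_a, lab_b, ids) {
    if (length(ids) < 2) {
      message("fewer than 2 scans in comparison ", lab_a, " vs ", lab_b,
              ": statistics skipped")
      return(NULL)
    }
    lapply(names(params), function(col) {
      a <- function_tab[function_tab$labeling == lab_a &
                          function_tab$scan %in% ids, col]
      b <- function_tab[function_tab$labeling == lab_b &
                          function_tab$scan %in% ids, col]
      paired_series(params[[col]], a, b, ids)
    })
  }
  stat_blocks <- list(
    intra_observer = series_for("obs1", "obs1b", animals$id),
    inter_observer = series_for("obs1", "obs2", animals$id),
    model_vs_obs1 = series_for("obs1", "model", split$test))
  stat_blocks <- Filter(Negate(is.null), stat_blocks)
  stats_tab <- do.call(rbind, lapply(names(stat_blocks), function(nm)
    do.call(rbind, lapply(stat_blocks[[nm]], function(s)
      cbind(data.frame(comparison = nm),
            suppressWarnings(agreement_stats(s, cfg$overall_alpha,
                                             cfg$m_hypotheses)))))))
  rownames(stats_tab) <- NULL

  report <- structure(list(function_table = function_tab,
                           agreement_table = agreement_tab,
                           agreement_per_image = lapply(comparisons,
                                                        `[[`, "per_image"),
                           stats_table = stats_tab,
                           status_tally = tally,
                           checkpoints = run$checkpoints,
                           split = split,
                           contour_files = contour_files),
                      class = "study_report")
  if (!is.null(cfg$out_dir)) persist_report(report, cfg)
  report
}

# Phantoms from a shifted source distribution (different geometry scale
# and no papillary features) used to emulate the pretrained starting
# point of transfer learning.
source_distribution_set <- function(cfg) {
  out <- list()
  size <- cfg$phantom$image_size %||% 48
  for (i in 1:3) {
    pcfg <- phantom_config(
      n_slices = 3, n_phases = 4, image_size = size,
      endo_radius_px = 0.2 * size * (0.8 + 0.15 * i),
      wall_thickness_px = 0.08 * size,
      contraction_fraction = 0.3, empty_slice_margin = 0,
      papillary = FALSE, seed = derive_seed(cfg$seed, 900L + i))
    ph <- generate_phantom_stack(pcfg)
    out <- c(out, collect_frames(sprintf("src%d", i), ph$stack,
                                 ph$ground_truth$masks, c(1, 2)))
  }
  out
}

write_prediction_contours <- function(pred_masks, test_set, cfg, scans) {
  sp <- cfg$phantom$pixel_spacing_mm %||% 0.4
  dz <- cfg$phantom$slice_thickness_mm %||% 6
  by_scan <- split(names(pred_masks),
                   vapply(test_set, `[[`, character(1), "scan"))
  paths <- character()
  for (scan_id in names(by_scan)) {
    cps <- lapply(by_scan[[scan_id]], function(k) {
      ex <- test_set[[k]]
      suppressMessages(mask_to_contours(pred_masks[[k]], ex$slice,
                                        ex$phase))
    })
    cf <- contour_file(scan_id, c(sp, sp, dz), cps)
    path <- file.path(cfg$out_dir, paste0(scan_id, "_dl.contxt"))
    write_contour_file(cf, path)
    paths <- c(paths, path)
  }
  paths
}

persist_report <- function(report, cfg) {
  d <- cfg$out_dir
  utils::write.csv(report$function_table,
                   file.path(d, "function_table.csv"), row.names = FALSE)
  utils::write.csv(report$agreement_table,
                   file.path(d, "agreement_aggregate.csv"),
                   row.names = FALSE)
  for (nm in names(report$agreement_per_image))
    utils::write.csv(report$agreement_per_image[[nm]],
                     file.path(d, paste0("agreement_", nm, ".csv")),
                     row.names = FALSE)
  utils::write.csv(report$stats_table, file.path(d, "stats_table.csv"),
                   row.names = FALSE)
  utils::write.csv(report$status_tally, file.path(d, "status_tally.csv"),
                   row.names = FALSE)
  utils::write.csv(report$checkpoints, file.path(d, "checkpoints.csv"),
                   row.names = FALSE)
  cfg_out <- cfg
  cfg_out$schedule <- unclass(cfg_out$schedule)
  cfg_out$policy <- if (is.null(cfg$policy)) NULL else unclass(cfg$policy)
  jsonlite::write_json(unclass(cfg_out), file.path(d, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(d)
}
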