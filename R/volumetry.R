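# ED/ES phase selection and cardiac function (EDV, ESV, SV, EF, LV mass)
# from 3-class label masks, by voxel counting.

#' Volumetry configuration
#'
#' @param pixel_spacing_mm In-plane pixel spacing `c(dx, dy)` in mm.
#' @param slice_thickness_mm Slice thickness in mm (no inter-slice gap is
#'   modeled).
#' @param myocardial_density_g_per_ml Myocardial density; the conventional
#'   constant 1.05 g/ml.
#' @return A `volumetry_config` list.
#' @export
volumetry_config <- function(pixel_spacing_mm = c(0.4, 0.4),
                             slice_thickness_mm = 6,
                             myocardial_density_g_per_ml = 1.05) {
  if (length(pixel_spacing_mm) == 1) pixel_spacing_mm <- rep(pixel_spacing_mm, 2)
  if (any(pixel_spacing_mm <= 0) || slice_thickness_mm <= 0 ||
      myocardial_density_g_per_ml <= 0)
    stop("all volumetry parameters must be positive", call. = FALSE)
  structure(list(pixel_spacing_mm = pixel_spacing_mm,
                 slice_thickness_mm = slice_thickness_mm,
                 myocardial_density_g_per_ml = myocardial_density_g_per_ml),
            class = "volumetry_config")
}

voxel_ml <- function(cfg) {
  cfg$pixel_spacing_mm[1] * cfg$pixel_spacing_mm[2] *
    cfg$slice_thickness_mm / 1000
}

# Count voxels with labels in `labels` across one phase's slices.
count_label_voxels <- function(masks, labels) {
  if (is.list(masks)) sum(vapply(masks, function(m) sum(m %in% labels),
                                 numeric(1)))
  else sum(masks %in% labels)
}

#' Blood-pool volume of one phase
#'
#' Sums the cavity voxels (label 1) over all slices of one phase and
#' multiplies by the voxel volume.
#'
#' @param masks 3D integer array (slice x row x col) or list of slice
#'   matrices for one phase.
#' @param cfg A [volumetry_config()].
#' @return Volume in ml (0 for empty masks).
#' @export
blood_pool_volume <- function(masks, cfg) {
  count_label_voxels(masks, 1L) * voxel_ml(cfg)
}

#' Select end-diastolic and end-systolic phases from per-phase volumes
#'
#' ED is the phase of largest, ES the phase of smallest blood-pool volume;
#' ties are broken by the earliest phase. A warning is emitted when all
#' volumes are equal.
#'
#' @param volumes Numeric vector of per-phase volumes (length >= 2).
#' @return List with integer `ed_phase` and `es_phase` (1-based).
#' @export
select_ed_es <- function(volumes) {
  if (length(volumes) < 2)
    stop("at least 2 phases are required", call. = FALSE)
  ed <- which.max(volumes)
  es <- which.min(volumes)
  if (max(volumes) == min(volumes))
    warning("all phase volumes are equal; ED and ES are degenerate")
  list(ed_phase = as.integer(ed), es_phase = as.integer(es))
}

#' Cardiac function from a stack of label masks
#'
#' Computes per-phase blood-pool volumes, selects ED/ES (or uses pinned
#' phases, mirroring workflows where ED and ES are fixed to the same
#' phases for all observers), and derives EDV, ESV, SV = EDV - ESV,
#' EF = 100 * SV / EDV, and LV mass as the difference between total
#' epicardial (labels 1 and 2) and endocardial (label 1) volume at
#' end-diastole times the myocardial density. Slices with entirely empty
#' masks at ED or ES contribute zero volume; their count is reported as
#' `n_missing_slices` since missing labels artificially reduce volumes.
#'
#' @param masks 4D integer array (slice x phase x row x col).
#' @param cfg A [volumetry_config()].
#' @param ed_phase,es_phase Optional pinned phase indices (1-based).
#' @return A `cardiac_function` list with `edv_ml`, `esv_ml`, `sv_ml`,
#'   `ef_percent` (NA and flagged when EDV is 0), `lv_mass_g`, `ed_phase`,
#'   `es_phase`, `n_missing_slices` and `phase_volumes_ml`.
#' @export
compute_function <- function(masks, cfg, ed_phase = NULL, es_phase = NULL) {
  stopifnot(length(dim(masks)) == 4)
  np <- dim(masks)[2]
  vols <- vapply(seq_len(np), function(p)
    blood_pool_volume(masks[, p, , , drop = FALSE], cfg), numeric(1))
  if (is.null(ed_phase) || is.null(es_phase)) {
    sel <- select_ed_es(vols)
    if (is.null(ed_phase)) ed_phase <- sel$ed_phase
    if (is.null(es_phase)) es_phase <- sel$es_phase
  }
  edv <- vols[ed_phase]
  esv <- vols[es_phase]
  sv <- edv - esv
  ef_flag <- edv == 0
  ef <- if (ef_flag) NA_real_ else 100 * sv / edv
  if (ef_flag)
    warning("EDV is 0: ejection fraction undefined (flagged, not 0)")
  epi_vox <- count_label_voxels(masks[, ed_phase, , , drop = FALSE], c(1L, 2L))
  endo_vox <- count_label_voxels(masks[, ed_phase, , , drop = FALSE], 1L)
  mass <- (epi_vox - endo_vox) * voxel_ml(cfg) * cfg$myocardial_density_g_per_ml
  ns <- dim(masks)[1]
  empty_at <- function(p) vapply(seq_len(ns), function(s)
    all(masks[s, p, , ] == 0L), logical(1))
  n_missing <- sum(empty_at(ed_phase)) + sum(empty_at(es_phase))
  structure(list(edv_ml = edv, esv_ml = esv, sv_ml = sv,
                 ef_percent = ef, lv_mass_g = mass,
                 ed_phase = as.integer(ed_phase),
                 es_phase = as.integer(es_phase),
                 ef_undefined = ef_flag,
                 n_missing_slices = as.integer(n_missing),
                 phase_volumes_ml = vols),
            class = "cardiac_function")
}

#' @export
print.cardiac_function <- function(x, ...) {
  cat(sprintf(
    "Cardiac function: EDV %.2f ml, ESV %.2f ml, SV %.2f ml, EF %s, LV mass %.2f g\n",
    x$edv_ml, x$esv_ml, x$sv_ml,
    if (x$ef_undefined) "undefined (EDV = 0)" else sprintf("%.1f%%", x$ef_percent),
    x$lv_mass_g))
  cat(sprintf("  ED phase %d, ES phase %d, empty-mask slices at ED/ES: %d\n",
              x$ed_phase, x$es_phase, x$n_missing_slices))
  invisible(x)
}

#' Tabulate cardiac function for several scans
#'
#' @param functions Named list of `cardiac_function` objects (names = scan
#'   ids).
#' @param meta Optional data frame with columns `scan`, `animal`, `group`,
#'   `timepoint` merged onto the table.
#' @return Data frame with one row per scan: EF, SV, LV mass, EDV, ESV and
#'   the missing-label slice count.
#' @export
function_table <- function(functions, meta = NULL) {
  df <- data.frame(
    scan = names(functions),
    ef_percent = vapply(functions, `[[`, numeric(1), "ef_percent"),
    sv_ml = vapply(functions, `[[`, numeric(1), "sv_ml"),
    lv_mass_g = vapply(functions, `[[`, numeric(1), "lv_mass_g"),
    edv_ml = vapply(functions, `[[`, numeric(1), "edv_ml"),
    esv_ml = vapply(functions, `[[`, numeric(1), "esv_ml"),
    n_missing_slices = vapply(functions, `[[`, integer(1),
                              "n_missing_slices"),
    row.names = NULL)
  if (!is.null(meta)) df <- merge(meta, df, by = "scan", sort = FALSE)
  df
}
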