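# Per-subject volumetrics: left/right/total volume, L-R asymmetry, the
# iliopsoas muscle index, and cohort-level quality-control screening.

#' Convert a binary mask to a volume in ml
#'
#' @param mask a [muscle_mask()] or binary 3-d array
#' @param voxel_mm voxel size in mm (taken from the mask object when
#'   present)
#' @return volume in ml (voxel count x voxel volume / 1000)
#' @export
mask_to_volume_ml <- function(mask, voxel_mm = NULL) {
  if (inherits(mask, "muscle_mask")) {
    if (is.null(voxel_mm)) voxel_mm <- mask$voxel_mm
    mask <- mask$data
  }
  if (is.null(voxel_mm)) stop("voxel_mm required for a bare array")
  if (!is_binary_array(mask)) stop("mask must be binary")
  sum(mask) * prod(voxel_mm) / 1000
}

#' Iliopsoas muscle index (IMI)
#'
#' Total iliopsoas volume divided by height squared, in ml/m^2.  Heights
#' above 3 are interpreted as centimetres and converted.
#'
#' @param total_ml total muscle volume in ml
#' @param height body height in metres (or centimetres, auto-detected)
#' @return IMI in ml/m^2
#' @export
compute_imi <- function(total_ml, height) {
  if (any(height <= 0)) stop("height must be positive")
  h_m <- ifelse(height > 3, height / 100, height)
  total_ml / h_m^2
}

#' Quantify one subject from its left and right masks
#'
#' @param left_mask,right_mask binary masks ([muscle_mask()] or arrays)
#'   on the same grid
#' @param demographics list or one-row data.frame with at least
#'   `subject_id`; `height_cm`, `gender`, `age_years`, `bmi`,
#'   `handedness` are carried through when present
#' @param voxel_mm voxel size in mm (default from the mask objects)
#' @param overlap_tolerance fraction of shared voxels (relative to the
#'   smaller mask) above which an overlap QC flag is raised (default 0)
#' @return one-row data.frame (a volume record): `subject_id`, `left_ml`,
#'   `right_ml`, `total_ml`, `lr_diff_ml` (= left - right; negative means
#'   the right muscle is larger), `imi`, demographics, `qc_flags`
#' @export
quantify_subject <- function(left_mask, right_mask, demographics = list(),
                             voxel_mm = NULL, overlap_tolerance = 0) {
  lm <- if (inherits(left_mask, "muscle_mask")) left_mask$data else left_mask
  rm_ <- if (inherits(right_mask, "muscle_mask")) right_mask$data else right_mask
  if (!identical(dim(lm), dim(rm_)))
    stop("left and right masks must be on the same grid")
  if (is.null(voxel_mm) && inherits(left_mask, "muscle_mask"))
    voxel_mm <- left_mask$voxel_mm
  left_ml <- mask_to_volume_ml(lm, voxel_mm)
  right_ml <- mask_to_volume_ml(rm_, voxel_mm)

  flags <- character(0)
  overlap <- sum(lm == 1 & rm_ == 1)
  if (overlap > overlap_tolerance * max(1, min(sum(lm), sum(rm_))))
    if (overlap > 0) flags <- c(flags, "mask_overlap")

  d <- as.list(demographics)
  height <- d$height_cm %||% d$height %||% NA_real_
  total <- left_ml + right_ml
  data.frame(
    subject_id = d$subject_id %||% NA_character_,
    gender = d$gender %||% NA_character_,
    age_years = d$age_years %||% NA_real_,
    height_cm = as.numeric(height),
    bmi = d$bmi %||% NA_real_,
    handedness = d$handedness %||% NA_character_,
    left_ml = left_ml, right_ml = right_ml, total_ml = total,
    lr_diff_ml = left_ml - right_ml,
    imi = if (is.finite(as.numeric(height))) compute_imi(total, as.numeric(height))
          else NA_real_,
    qc_flags = paste(flags, collapse = ";"),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build volume records directly from a generated cohort table
#'
#' Uses the cohort's target left/right volumes as measured volumes --
#' the idealized "perfect segmentation" path used for population-level
#' analyses that do not involve imaging.
#' @param cohort data.frame from [generate_cohort()]
#' @return data.frame of volume records as in [quantify_subject()]
#' @export
records_from_cohort <- function(cohort) {
  data.frame(
    subject_id = cohort$subject_id, gender = cohort$gender,
    age_years = cohort$age_years, height_cm = cohort$height_cm,
    bmi = cohort$bmi, handedness = cohort$handedness,
    left_ml = cohort$target_left_ml, right_ml = cohort$target_right_ml,
    total_ml = cohort$target_left_ml + cohort$target_right_ml,
    lr_diff_ml = cohort$target_left_ml - cohort$target_right_ml,
    imi = compute_imi(cohort$target_left_ml + cohort$target_right_ml,
                      cohort$height_cm),
    qc_flags = "", stringsAsFactors = FALSE)
}

#' Quality-control configuration
#'
#' @param min_ml,max_ml per-muscle plausibility bounds in ml (defaults
#'   100 and 800, outside the observed population ranges with margin)
#' @param max_asymmetry_fraction flag when `|left - right| / mean(sides)`
#'   exceeds this (default 0.25)
#' @param outlier_z flag when the within-gender z-score of total volume
#'   exceeds this in absolute value (default 4)
#' @return object of class `qc_config`
#' @export
qc_config <- function(min_ml = 100, max_ml = 800,
                      max_asymmetry_fraction = 0.25, outlier_z = 4) {
  if (min_ml >= max_ml) stop("min_ml must be below max_ml")
  if (max_asymmetry_fraction <= 0 || outlier_z <= 0)
    stop("thresholds must be positive")
  structure(list(min_ml = min_ml, max_ml = max_ml,
                 max_asymmetry_fraction = max_asymmetry_fraction,
                 outlier_z = outlier_z), class = "qc_config")
}

#' Screen volume records for implausible values
#'
#' Adds flags (never drops records): `volume_bounds` when either muscle is
#' outside `[min_ml, max_ml]`, `asymmetry` when the relative left-right
#' difference exceeds the threshold, `outlier` when the within-gender
#' z-score of total volume is extreme.
#'
#' @param records data.frame of volume records
#' @param config a [qc_config()]
#' @return `records` with updated `qc_flags` and a logical `qc_pass`
#' @export
qc_screen <- function(records, config = qc_config()) {
  stopifnot(inherits(config, "qc_config"))
  flags <- strsplit(records$qc_flags %||% rep("", nrow(records)), ";", fixed = TRUE)
  flags <- lapply(flags, function(f) f[nzchar(f)])

  oob <- records$left_ml < config$min_ml | records$left_ml > config$max_ml |
    records$right_ml < config$min_ml | records$right_ml > config$max_ml
  asym <- abs(records$lr_diff_ml) /
    ((records$left_ml + records$right_ml) / 2) > config$max_asymmetry_fraction

  z <- rep(0, nrow(records))
  for (g in unique(records$gender)) {
    sel <- which(records$gender %in% g)
    if (length(sel) > 1 && sd(records$total_ml[sel]) > 0)
      z[sel] <- (records$total_ml[sel] - mean(records$total_ml[sel])) /
        sd(records$total_ml[sel])
  }
  outl <- abs(z) > config$outlier_z

  for (i in seq_len(nrow(records))) {
    if (oob[i]) flags[[i]] <- c(flags[[i]], "volume_bounds")
    if (asym[i]) flags[[i]] <- c(flags[[i]], "asymmetry")
    if (outl[i]) flags[[i]] <- c(flags[[i]], "outlier")
  }
  records$qc_flags <- vapply(flags, paste, character(1), collapse = ";")
  records$qc_pass <- !vapply(flags, function(f) length(f) > 0, logical(1))
  records
}
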