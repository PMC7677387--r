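# Model-input preparation: landmark-anchored cropping, 99th-percentile
# intensity normalization, and mid-sagittal reflection so both muscles are
# presented to the network in a single (right-like) chirality.

#' Construct a muscle crop
#'
#' A fixed-shape intensity patch (values in [0, 1] once normalized) tied to
#' a side and reflection state, with the crop origin recorded so that the
#' patch can be re-embedded losslessly in its parent volume.
#' @param intensities 3-d array
#' @param mask optional binary 3-d array of the same shape
#' @param side `"left"` or `"right"`
#' @param reflected logical reflection state
#' @param source_offset 0-based voxel coordinates of the crop origin in the
#'   parent volume (may be negative when the crop was zero-padded)
#' @param voxel_mm voxel size in mm
#' @return object of class `muscle_crop`
#' @export
muscle_crop <- function(intensities, mask = NULL, side,
                        reflected = FALSE, source_offset = c(0L, 0L, 0L),
                        voxel_mm = c(2.232, 2.232, 3.0)) {
  stopifnot(length(dim(intensities)) == 3L, side %in% c("left", "right"))
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(intensities)))
      stop("mask and intensities must share a shape")
    if (!is_binary_array(mask)) stop("mask must be binary")
  }
  structure(list(intensities = intensities, mask = mask, side = side,
                 reflected = isTRUE(reflected),
                 source_offset = as.integer(source_offset),
                 voxel_mm = as.numeric(voxel_mm)),
            class = "muscle_crop")
}

#' @export
print.muscle_crop <- function(x, ...) {
  cat(sprintf("<muscle_crop> %s side=%s reflected=%s mask=%s offset=(%s)\n",
              paste(dim(x$intensities), collapse = "x"), x$side,
              x$reflected, !is.null(x$mask),
              paste(x$source_offset, collapse = ", ")))
  invisible(x)
}

# extract a zero-padded subarray [o, o + shape) (0-based origin o)
extract_padded <- function(data, origin, shape) {
  out <- array(0, dim = shape)
  d <- dim(data)
  lo_src <- pmax(origin, 0L); hi_src <- pmin(origin + shape, d)
  if (any(lo_src >= hi_src)) return(out)
  lo_dst <- lo_src - origin; hi_dst <- hi_src - origin
  out[(lo_dst[1] + 1):hi_dst[1], (lo_dst[2] + 1):hi_dst[2],
      (lo_dst[3] + 1):hi_dst[3]] <-
    data[(lo_src[1] + 1):hi_src[1], (lo_src[2] + 1):hi_src[2],
         (lo_src[3] + 1):hi_src[3]]
  out
}

#' Crop a fixed-shape region of interest around a landmark
#'
#' In-plane the crop is centred on the landmark; along the
#' inferior-superior axis the landmark sits at `anchor_frac[3]` of the crop
#' extent from the inferior face (default 25%, since the muscle extends
#' mostly superiorly from the hip landmark).  Voxels outside the parent
#' volume are zero-filled.
#'
#' @param volume a [dixon_volume()] (or bare 3-d array)
#' @param landmark 0-based voxel coordinate `(i, j, k)` inside the volume
#' @param crop_shape output shape (default `c(96, 96, 192)`)
#' @param anchor_frac landmark position as a fraction of the crop extent
#'   per axis (default `c(0.5, 0.5, 0.25)`)
#' @param mask optional mask (same grid) cropped identically
#' @param side side label carried by the crop
#' @return a [muscle_crop()] with `source_offset` set
#' @export
crop_to_roi <- function(volume, landmark, crop_shape = c(96L, 96L, 192L),
                        anchor_frac = c(0.5, 0.5, 0.25), mask = NULL,
                        side = "right") {
  data <- if (inherits(volume, "dixon_volume")) volume$data else volume
  voxel_mm <- if (inherits(volume, "dixon_volume")) volume$voxel_mm
              else c(2.232, 2.232, 3.0)
  landmark <- as.integer(round(landmark))
  d <- dim(data)
  if (any(landmark < 0L) || any(landmark >= d))
    stop(sprintf("landmark (%s) outside the volume grid %s",
                 paste(landmark, collapse = ", "),
                 paste(d, collapse = "x")))
  crop_shape <- as.integer(crop_shape)
  anchor <- as.integer(round(anchor_frac * (crop_shape - 1L)))
  origin <- landmark - anchor
  ints <- extract_padded(data, origin, crop_shape)
  mk <- NULL
  if (!is.null(mask)) {
    mdata <- if (inherits(mask, "muscle_mask")) mask$data else mask
    if (!identical(dim(mdata), d)) stop("mask grid differs from volume grid")
    mk <- extract_padded(mdata, origin, crop_shape)
  }
  muscle_crop(ints, mk, side = side, reflected = FALSE,
              source_offset = origin, voxel_mm = voxel_mm)
}

#' Re-embed a crop (or a predicted mask in crop space) in the parent grid
#'
#' Inverse of [crop_to_roi()]: places the crop's voxels at `source_offset`
#' in a zero parent-shaped grid, discarding out-of-bounds padding.
#' @param crop_data 3-d array in crop space
#' @param source_offset 0-based crop origin in the parent volume
#' @param parent_shape dimensions of the parent grid
#' @return 3-d array of `parent_shape`
#' @export
embed_crop <- function(crop_data, source_offset, parent_shape) {
  out <- array(0, dim = parent_shape)
  shape <- dim(crop_data)
  o <- as.integer(source_offset)
  lo_dst <- pmax(o, 0L); hi_dst <- pmin(o + shape, parent_shape)
  if (any(lo_dst >= hi_dst)) return(out)
  lo_src <- lo_dst - o; hi_src <- hi_dst - o
  out[(lo_dst[1] + 1):hi_dst[1], (lo_dst[2] + 1):hi_dst[2],
      (lo_dst[3] + 1):hi_dst[3]] <-
    crop_data[(lo_src[1] + 1):hi_src[1], (lo_src[2] + 1):hi_src[2],
              (lo_src[3] + 1):hi_src[3]]
  out
}

#' Normalize intensities to [0, 1] by the 99th percentile
#'
#' Maps the 99th percentile of the input to one and clips above it, so a
#' handful of intensity spikes cannot compress the dynamic range:
#' `out = min(in / p99, 1)`.  The percentile is the linear-interpolation
#' empirical quantile (type 7) over the supplied voxels.
#'
#' @param x numeric array (or [muscle_crop()]) of non-negative intensities
#' @param prob percentile used as the normalization ceiling (default 0.99)
#' @return object of the same kind with intensities in [0, 1]
#' @export
normalize_intensity <- function(x, prob = 0.99) {
  if (inherits(x, "muscle_crop")) {
    x$intensities <- normalize_intensity(x$intensities, prob)
    return(x)
  }
  if (any(x < 0)) stop("intensities must be non-negative")
  p <- quantile(x, prob, names = FALSE, type = 7)
  if (p <= 0)
    stop("degenerate input: the ", round(100 * prob),
         "th percentile is zero (all-zero crop?)")
  pmin(x / p, 1)
}

#' Reflect a crop about the mid-sagittal (first in-plane) axis
#'
#' Mirrors intensities and mask along axis 1, swaps the side label and
#' toggles the reflection flag.  Applying it twice is the identity.
#' @param crop a [muscle_crop()]
#' @return the reflected [muscle_crop()]
#' @export
reflect_crop <- function(crop) {
  stopifnot(inherits(crop, "muscle_crop"))
  n1 <- dim(crop$intensities)[1]
  crop$intensities <- crop$intensities[n1:1, , , drop = FALSE]
  if (!is.null(crop$mask)) crop$mask <- crop$mask[n1:1, , , drop = FALSE]
  crop$side <- if (crop$side == "left") "right" else "left"
  crop$reflected <- !crop$reflected
  crop
}

#' Prepare a subject's two model-input crops
#'
#' Crops around each hip landmark, carries the matching mask through the
#' identical geometry, normalizes each crop, and reflects the left crop so
#' both outputs are in right-like orientation.
#'
#' @param volume a [dixon_volume()]
#' @param landmarks list with `left_hip` and `right_hip` 0-based voxel
#'   coordinates; the left hip must have the larger first-axis index
#' @param masks optional list with `left` and `right` masks
#'   ([muscle_mask()] or array) on the volume grid
#' @param crop_shape,anchor_frac passed to [crop_to_roi()]
#' @return list with elements `left` and `right`, each a normalized
#'   [muscle_crop()] in right-like orientation
#' @export
prepare_subject <- function(volume, landmarks, masks = NULL,
                            crop_shape = c(96L, 96L, 192L),
                            anchor_frac = c(0.5, 0.5, 0.25)) {
  stopifnot(!is.null(landmarks$left_hip), !is.null(landmarks$right_hip))
  if (landmarks$left_hip[1] <= landmarks$right_hip[1])
    stop("left hip landmark must have the larger first-axis index")
  right <- crop_to_roi(volume, landmarks$right_hip, crop_shape, anchor_frac,
                       mask = masks$right, side = "right")
  left <- crop_to_roi(volume, landmarks$left_hip, crop_shape, anchor_frac,
                      mask = masks$left, side = "left")
  right <- normalize_intensity(right)
  left <- normalize_intensity(reflect_crop(left))
  list(left = left, right = right)
}
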