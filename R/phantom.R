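# Dixon-like phantom volumes with ground-truth bilateral muscle masks.
#
# Each muscle is a curved centerline (quadratic lateral bow in the coronal
# plane) swept with circular cross-sections whose radius follows a smooth
# taper peaking mid-length -- a fusiform tube.  The intensity model is
# water-image-like contrast without MR physics: muscle ~0.7, fat rind ~1.0,
# body background ~0.1, air 0, plus Gaussian edge blur and additive noise.

#' Specify a muscle phantom
#'
#' @param grid_shape voxels per axis (default `c(96, 96, 160)`)
#' @param voxel_mm physical voxel size in mm (default `c(2.232, 2.232, 3.0)`)
#' @param muscle_length_mm centerline length of each muscle (default 330)
#' @param max_radius_mm largest admissible mid-length radius; a sizing error
#'   is raised if a target volume needs more (default 45)
#' @param taper_q exponent of the taper profile
#'   `r(u) = r_max * sin(pi*u)^taper_q`, `u` the arclength fraction
#'   (default 0.5, giving a fusiform bulge peaking mid-length)
#' @param curvature_mm peak lateral bowing of the centerline (default 12)
#' @param lateral_offset_mm distance of each muscle base from the
#'   mid-sagittal plane (default 32)
#' @param noise_sd additive Gaussian intensity noise (default 0.05)
#' @param blur_mm Gaussian edge-smoothing sigma in mm (default 2)
#' @param background_structures add a spine-like cylinder and a fat rind
#'   (default TRUE)
#' @param seed integer; fixes all randomness of the phantom
#' @return an object of class `phantom_spec`
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L, 160L),
                         voxel_mm = c(2.232, 2.232, 3.0),
                         muscle_length_mm = 330,
                         max_radius_mm = 45,
                         taper_q = 0.5,
                         curvature_mm = 12,
                         lateral_offset_mm = 32,
                         noise_sd = 0.05,
                         blur_mm = 2,
                         background_structures = TRUE,
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8),
            length(voxel_mm) == 3L, all(voxel_mm > 0))
  assert_scalar_num(muscle_length_mm, "muscle_length_mm", positive = TRUE)
  assert_scalar_num(max_radius_mm, "max_radius_mm", positive = TRUE)
  fov_half <- grid_shape[1] * voxel_mm[1] / 2
  if (max_radius_mm >= fov_half)
    stop("max_radius_mm must be smaller than half the in-plane field of view")
  if (muscle_length_mm >= grid_shape[3] * voxel_mm[3])
    stop("muscle_length_mm exceeds the grid extent")
  if (noise_sd < 0 || blur_mm < 0) stop("noise_sd and blur_mm must be >= 0")
  structure(list(
    grid_shape = as.integer(grid_shape), voxel_mm = as.numeric(voxel_mm),
    muscle_length_mm = muscle_length_mm, max_radius_mm = max_radius_mm,
    taper_q = taper_q, curvature_mm = curvature_mm,
    lateral_offset_mm = lateral_offset_mm,
    noise_sd = noise_sd, blur_mm = blur_mm,
    background_structures = isTRUE(background_structures),
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

# integral of sin(pi*u)^(2q) over [0,1] (taper volume factor)
taper_integral <- function(q) {
  u <- seq(0, 1, length.out = 2001L)
  mean(sin(pi * u)^(2 * q))
}

# peak radius needed for a target volume (ml) under the taper profile
solve_peak_radius <- function(spec, target_ml) {
  # V = pi * r^2 * L * taper_integral
  r2 <- target_ml * 1000 / (pi * spec$muscle_length_mm * taper_integral(spec$taper_q))
  sqrt(r2)
}

# normalized radial distance field for one muscle; values <= 1 are inside
# the unit-scale tube.  side: +1 = left (higher first-axis index), -1 = right
phantom_tube_field <- function(spec, side, r_peak) {
  d <- spec$grid_shape; vox <- spec$voxel_mm
  # physical coordinates with x measured from the mid-sagittal plane
  x <- (seq_len(d[1]) - 1 - (d[1] - 1) / 2) * vox[1]
  y <- (seq_len(d[2]) - 1 - (d[2] - 1) / 2) * vox[2]
  z <- (seq_len(d[3]) - 1) * vox[3]
  z0 <- (d[3] * vox[3] - spec$muscle_length_mm) / 2
  u <- (z - z0) / spec$muscle_length_mm         # arclength fraction per slab
  inside_z <- u >= 0 & u <= 1
  ub <- pmin(pmax(u, 0), 1)
  cx <- side * (spec$lateral_offset_mm + spec$curvature_mm * (1 - (2 * ub - 1)^2))
  rz <- r_peak * sin(pi * ub)^spec$taper_q      # radius per slab
  rz[!inside_z] <- 0

  dx2 <- outer(x, rep(1, d[2]))                 # in-plane distance template
  dy2 <- outer(rep(1, d[1]), y)
  field <- array(Inf, dim = d)
  for (k in which(inside_z & rz > 0)) {
    dist <- sqrt((dx2 - cx[k])^2 + dy2^2)
    field[, , k] <- dist / rz[k]
  }
  list(field = field, z0 = z0, cx = cx, u = u)
}

# separable Gaussian blur, sigma in mm per axis
gaussian_blur3 <- function(x, sigma_mm, voxel_mm) {
  for (ax in 1:3) {
    s <- sigma_mm / voxel_mm[ax]
    if (s < 1e-6) next
    hw <- max(1L, ceiling(3 * s))
    w <- dnorm(seq(-hw, hw), sd = s); w <- w / sum(w)
    acc <- array(0, dim = dim(x))
    n <- dim(x)[ax]
    for (t in seq_along(w)) {
      off <- t - hw - 1L
      src <- pmin(pmax(seq_len(n) + off, 1L), n)  # replicate edges
      idx <- switch(ax,
                    quote(x[src, , , drop = FALSE]),
                    quote(x[, src, , drop = FALSE]),
                    quote(x[, , src, drop = FALSE]))
      acc <- acc + w[t] * eval(idx)
    }
    x <- acc
  }
  x
}

#' Generate one Dixon-like phantom subject
#'
#' Builds a noisy body-like volume containing two elongated, tapering,
#' parasagittally mirrored tubular bright structures whose ground-truth
#' masks hit the requested volumes, plus per-side hip landmarks at the
#' inferior end of each muscle.
#'
#' @param spec a [phantom_spec()]
#' @param target_left_ml,target_right_ml target muscle volumes in ml
#' @param subject_id identifier stored with the phantom (default "phantom")
#' @param seed overrides `spec$seed` when given
#' @return an object of class `phantom_subject`: fields `volume`
#'   ([dixon_volume()]), `left_mask`, `right_mask` ([muscle_mask()]),
#'   `landmarks` (list with `left_hip`, `right_hip`, 0-based voxel
#'   coordinates), `true_left_ml`, `true_right_ml`, `subject_id`
#' @export
generate_phantom <- function(spec, target_left_ml, target_right_ml,
                             subject_id = "phantom", seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  assert_scalar_num(target_left_ml, "target_left_ml", positive = TRUE)
  assert_scalar_num(target_right_ml, "target_right_ml", positive = TRUE)
  seed <- if (is.null(seed)) spec$seed else as.integer(seed)
  vox_ml <- prod(spec$voxel_mm) / 1000

  make_side <- function(side, target_ml) {
    r_peak <- solve_peak_radius(spec, target_ml)
    if (r_peak > spec$max_radius_mm)
      stop(sprintf(
        "target volume %.1f ml needs peak radius %.1f mm > max_radius_mm = %.1f mm",
        target_ml, r_peak, spec$max_radius_mm))
    if (r_peak > spec$lateral_offset_mm)
      stop("muscles would cross the mid-sagittal plane; reduce target volume")
    tube <- phantom_tube_field(spec, side, r_peak)
    target_vox <- target_ml / vox_ml
    # calibrate the radius scale so the voxelized volume matches the target
    lo <- 0.85; hi <- 1.15
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      cnt <- sum(tube$field <= mid)
      if (cnt < target_vox) lo <- mid else hi <- mid
      if (hi - lo < 1e-7) break
    }
    cs <- c(lo, hi)
    cnts <- vapply(cs, function(cc) sum(tube$field <= cc), numeric(1))
    cc <- cs[which.min(abs(cnts - target_vox))]
    mask <- (tube$field <= cc) * 1L
    achieved <- sum(mask) * vox_ml
    if (abs(achieved - target_ml) / target_ml > 0.03)
      stop(sprintf(
        "voxelization cannot reach target %.1f ml (achieved %.1f ml); grid too coarse",
        target_ml, achieved))
    # landmark: inferior end of the muscle centerline, 0-based voxel coords
    d <- spec$grid_shape; voxd <- spec$voxel_mm
    k0 <- max(0L, min(d[3] - 1L, as.integer(round(tube$z0 / voxd[3]))))
    cx0 <- tube$cx[k0 + 1L]
    i0 <- as.integer(round(cx0 / voxd[1] + (d[1] - 1) / 2))
    j0 <- as.integer(round((d[2] - 1) / 2))
    list(mask = mask, landmark = c(i0, j0, k0), achieved_ml = achieved)
  }

  left <- make_side(+1, target_left_ml)
  right <- make_side(-1, target_right_ml)
  if (any(left$mask & right$mask)) stop("left and right masks overlap")

  d <- spec$grid_shape; vox <- spec$voxel_mm
  img <- with_seed(seed, {
    img <- array(0, dim = d)
    x <- (seq_len(d[1]) - 1 - (d[1] - 1) / 2) * vox[1]
    y <- (seq_len(d[2]) - 1 - (d[2] - 1) / 2) * vox[2]
    ax <- d[1] * vox[1] / 2 - 2; by <- d[2] * vox[2] / 2 - 2
    body <- outer((x / ax)^2, (y / by)^2, `+`) <= 1      # elliptical body
    body3 <- array(rep(body, d[3]), dim = d)
    img[body3] <- 0.1
    if (spec$background_structures) {
      rind <- body & outer((x / (ax - 8))^2, (y / (by - 8))^2, `+`) > 1
      img[array(rep(rind, d[3]), dim = d)] <- 1.0        # fat rind
      spine <- outer(x^2, (y - by * 0.45)^2, `+`) <= 18^2
      img[array(rep(spine & body, d[3]), dim = d)] <- 0.45
    }
    img[left$mask == 1L] <- 0.7
    img[right$mask == 1L] <- 0.7
    if (spec$blur_mm > 0) img <- gaussian_blur3(img, spec$blur_mm, vox)
    if (spec$noise_sd > 0) img <- img + rnorm(length(img), sd = spec$noise_sd)
    pmax(img, 0)
  })

  structure(list(
    subject_id = subject_id,
    volume = dixon_volume(img, vox),
    left_mask = muscle_mask(left$mask, vox),
    right_mask = muscle_mask(right$mask, vox),
    landmarks = list(left_hip = left$landmark, right_hip = right$landmark),
    true_left_ml = left$achieved_ml,
    true_right_ml = right$achieved_ml
  ), class = "phantom_subject")
}

#' @export
print.phantom_subject <- function(x, ...) {
  cat(sprintf("<phantom_subject> %s: %s voxels, left %.1f ml, right %.1f ml\n",
              x$subject_id, paste(dim(x$volume$data), collapse = "x"),
              x$true_left_ml, x$true_right_ml))
  invisible(x)
}
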