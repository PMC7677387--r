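# Training-set expansion: reflections plus random translation/scaling.
#
# Per subject and muscle, the original and its reflection are each paired
# with `n_random_transforms` random affine resamplings (plus the untouched
# version), giving 2 muscles x 2 reflection states x (1 + n) samples --
# 32 per subject at the defaults, i.e. 2880 from 90 annotated subjects.

#' Specify the augmentation scheme
#'
#' @param n_random_transforms random transforms per reflection state
#'   (default 7)
#' @param max_shift_inplane maximum absolute translation, in voxels, along
#'   each in-plane axis (default 6)
#' @param max_shift_outplane maximum absolute inferior-superior translation
#'   in voxels (default 24)
#' @param scale_range_inplane relative scaling interval shared by the two
#'   in-plane axes (default `c(-0.25, 0.25)`, i.e. factors 0.75-1.25)
#' @param scale_range_outplane relative scaling interval for the
#'   inferior-superior axis (default `c(-0.5, 0.5)`); the larger
#'   out-of-plane ranges reflect the greater population variation in
#'   muscle length than width
#' @param seed integer seed fixing the transform draws
#' @return object of class `augmentation_spec`
#' @export
augmentation_spec <- function(n_random_transforms = 7L,
                              max_shift_inplane = 6L,
                              max_shift_outplane = 24L,
                              scale_range_inplane = c(-0.25, 0.25),
                              scale_range_outplane = c(-0.5, 0.5),
                              seed = 1L) {
  stopifnot(n_random_transforms >= 0L, max_shift_inplane >= 0L,
            max_shift_outplane >= 0L,
            length(scale_range_inplane) == 2L,
            length(scale_range_outplane) == 2L)
  if (any(c(scale_range_inplane, scale_range_outplane) <= -1))
    stop("scale ranges must exclude -1 (factors must stay positive)")
  if (diff(scale_range_inplane) < 0 || diff(scale_range_outplane) < 0)
    stop("scale ranges must be increasing intervals")
  structure(list(
    n_random_transforms = as.integer(n_random_transforms),
    max_shift_inplane = as.integer(max_shift_inplane),
    max_shift_outplane = as.integer(max_shift_outplane),
    scale_range_inplane = as.numeric(scale_range_inplane),
    scale_range_outplane = as.numeric(scale_range_outplane),
    seed = as.integer(seed)
  ), class = "augmentation_spec")
}

#' Draw one random transform from an augmentation spec
#'
#' Shifts are uniform integers within the per-axis bounds; scale factors
#' are uniform within the configured intervals, the two in-plane axes
#' sharing a single factor and the out-of-plane axis drawing its own.
#' Consumes R's current random stream.
#'
#' @param spec an [augmentation_spec()]
#' @return list with `shift` (3 integers) and `scale` (3 factors)
#' @export
sample_transform <- function(spec) {
  stopifnot(inherits(spec, "augmentation_spec"))
  si <- spec$max_shift_inplane; so <- spec$max_shift_outplane
  shift <- c(sample(seq(-si, si), 1L), sample(seq(-si, si), 1L),
             sample(seq(-so, so), 1L))
  s_in <- 1 + runif(1L, spec$scale_range_inplane[1], spec$scale_range_inplane[2])
  s_out <- 1 + runif(1L, spec$scale_range_outplane[1], spec$scale_range_outplane[2])
  list(shift = as.integer(shift), scale = c(s_in, s_in, s_out))
}

#' Apply a translation/scaling transform to a crop
#'
#' Scaling is about the crop centre, then translation; intensities are
#' resampled with trilinear interpolation and the mask (if any) with
#' nearest-neighbour under the identical geometric map, so labels stay
#' binary.  Voxels mapped from outside the field are zero.
#'
#' @param crop a [muscle_crop()]
#' @param params a transform from [sample_transform()] (or a list with
#'   `shift` and `scale`)
#' @return the transformed [muscle_crop()]
#' @export
apply_transform <- function(crop, params) {
  stopifnot(inherits(crop, "muscle_crop"),
            length(params$shift) == 3L, length(params$scale) == 3L)
  if (all(params$shift == 0L) && all(params$scale == 1)) return(crop)
  crop$intensities <- cpp_resample3d(crop$intensities,
                                     as.numeric(params$shift),
                                     as.numeric(params$scale), FALSE)
  if (!is.null(crop$mask))
    crop$mask <- cpp_resample3d(crop$mask, as.numeric(params$shift),
                                as.numeric(params$scale), TRUE)
  crop
}

#' Build the augmented training set
#'
#' @param subjects list of prepared crop pairs (each as returned by
#'   [prepare_subject()], with masks present on both crops)
#' @param spec an [augmentation_spec()]
#' @param lazy if TRUE (default) return sample descriptors without
#'   resampling any voxel data; call [materialize_sample()] to realize one
#' @return object of class `training_set`: list with `samples` (list of
#'   descriptors: subject index, muscle, reflection state, transform
#'   parameters) and `n_samples`
#' @export
build_training_set <- function(subjects, spec = augmentation_spec(),
                               lazy = TRUE) {
  stopifnot(inherits(spec, "augmentation_spec"), length(subjects) >= 1L)
  for (s in seq_along(subjects)) {
    pair <- subjects[[s]]
    if (is.null(pair$left$mask) || is.null(pair$right$mask))
      stop("subject ", s, " is missing a mask; training needs annotations")
  }
  samples <- with_seed(spec$seed, {
    out <- vector("list", 0L)
    for (s in seq_along(subjects)) {
      for (muscle in c("right", "left")) {
        for (refl in c(FALSE, TRUE)) {
          out[[length(out) + 1L]] <- list(subject = s, muscle = muscle,
                                          reflected = refl, transform = NULL)
          if (spec$n_random_transforms > 0L) {
            for (t in seq_len(spec$n_random_transforms)) {
              out[[length(out) + 1L]] <- list(subject = s, muscle = muscle,
                                              reflected = refl,
                                              transform = sample_transform(spec))
            }
          }
        }
      }
    }
    out
  })
  ts <- structure(list(samples = samples, n_samples = length(samples),
                       spec = spec, subjects = subjects),
                  class = "training_set")
  if (!lazy) ts$materialized <- lapply(seq_along(samples),
                                       function(i) materialize_sample(ts, i))
  ts
}

#' Realize one training sample from its descriptor
#'
#' @param ts a [build_training_set()] result
#' @param i sample index
#' @return a [muscle_crop()] with intensities and mask transformed
#' @export
materialize_sample <- function(ts, i) {
  stopifnot(inherits(ts, "training_set"), i >= 1L, i <= ts$n_samples)
  d <- ts$samples[[i]]
  crop <- ts$subjects[[d$subject]][[d$muscle]]
  if (d$reflected) crop <- reflect_crop(crop)
  if (!is.null(d$transform)) crop <- apply_transform(crop, d$transform)
  crop
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set> %d samples from %d subjects (%d random transforms)\n",
              x$n_samples, length(x$subjects), x$spec$n_random_transforms))
  invisible(x)
}
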