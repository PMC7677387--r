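# Desk-scale fixtures: small phantoms, crops and network specs that keep
# the suite within a CPU budget.  All fixtures are generated in code.

desk_phantom_spec <- function(grid = c(48L, 48L, 48L), seed = 1L, ...) {
  phantom_spec(grid_shape = grid, muscle_length_mm = 36,
               lateral_offset_mm = grid[1] * 2.232 / 4, curvature_mm = 3,
               max_radius_mm = 20, seed = seed, ...)
}

# a phantom subject prepared into desk-scale crops (32 x 32 x 16)
desk_subject <- function(i, seed = 100 + i, target_scale = 0.05,
                         crop = c(32L, 32L, 16L), cohort = NULL) {
  if (is.null(cohort))
    cohort <- generate_cohort(cohort_params(), 1, 1, seed = seed)
  spec <- desk_phantom_spec(seed = seed)
  ph <- generate_phantom(spec, cohort$target_left_ml[1] * target_scale,
                         cohort$target_right_ml[1] * target_scale,
                         subject_id = paste0("P", i), seed = seed)
  pair <- prepare_subject(ph$volume, ph$landmarks,
                          masks = list(left = ph$left_mask,
                                       right = ph$right_mask),
                          crop_shape = crop)
  list(id = paste0("P", i), pair = pair, phantom = ph,
       truth_left_ml = ph$true_left_ml, truth_right_ml = ph$true_right_ml)
}

desk_net_spec <- function(width = 0.125) network_spec(width_multiplier = width)

# tiny 16^3 annotated sample for fast optimizer tests
tiny_sample <- function(seed = 1) {
  set.seed(seed)
  x <- array(runif(16^3, 0, 0.2), dim = c(16, 16, 16))
  m <- array(0, dim = c(16, 16, 16))
  m[5:12, 5:12, 4:13] <- 1
  x[m == 1] <- x[m == 1] + 0.6
  list(x = pmin(x, 1), mask = m)
}

# all permutations of 1..n (n small), for exhaustive rank-statistic checks
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}
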