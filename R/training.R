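# Dice-loss training and the k-fold cross-validation protocol.

#' Training configuration
#'
#' Defaults are the full-scale recipe: Adam, learning rate 1e-4, batch
#' size 3, a fixed 100-epoch budget with best-loss checkpointing, and a
#' learning-rate sweep grid of 1e-1 ... 1e-6.
#'
#' @param learning_rate Adam step size (default 1e-4)
#' @param batch_size samples per optimizer step (default 3)
#' @param epochs training epochs (default 100)
#' @param beta1,beta2,adam_eps Adam moment decays and stabilizer (standard
#'   defaults)
#' @param dice_eps soft-Dice smoothing, in voxel-equivalents (default 1;
#'   avoids 0/0 on empty masks)
#' @param seed seed for initialization and batch shuffling
#' @param sweep_grid learning rates explored by [learning_rate_sweep()]
#' @return object of class `train_config`
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 3L,
                         epochs = 100L, beta1 = 0.9, beta2 = 0.999,
                         adam_eps = 1e-8, dice_eps = 1, seed = 1L,
                         sweep_grid = 10^-(1:6)) {
  assert_scalar_num(learning_rate, "learning_rate", positive = TRUE)
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (epochs < 1L) stop("epochs must be >= 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, dice_eps = dice_eps,
                 seed = as.integer(seed), sweep_grid = sweep_grid),
            class = "train_config")
}

#' Soft Dice loss
#'
#' `1 - (2*sum(p*m) + eps) / (sum(p) + sum(m) + eps)`: zero at perfect
#' overlap, one when prediction and mask are disjoint, differentiable in
#' the probabilities.
#'
#' @param probabilities numeric array in [0, 1]
#' @param mask binary array of the same shape
#' @param eps smoothing constant (default 1)
#' @param gradient also return the gradient w.r.t. `probabilities`
#' @return the loss, or (with `gradient = TRUE`) list `loss`, `grad`
#' @export
soft_dice_loss <- function(probabilities, mask, eps = 1, gradient = FALSE) {
  if (!identical(dim(probabilities), dim(mask)) ||
      length(probabilities) != length(mask))
    stop("probabilities and mask must share a shape")
  inter <- sum(probabilities * mask)
  denom <- sum(probabilities) + sum(mask) + eps
  loss <- 1 - (2 * inter + eps) / denom
  if (!gradient) return(loss)
  grad <- -(2 * mask * denom - (2 * inter + eps)) / denom^2
  list(loss = loss, grad = grad)
}

#' Partition subjects into cross-validation folds
#'
#' Unstratified seeded shuffle; test-set sizes differ by at most one and
#' every subject appears in exactly one test fold.
#'
#' @param subject_ids vector of identifiers
#' @param k number of folds
#' @param seed shuffle seed
#' @return list of `fold_split` objects: `fold_id`, `train_ids`, `test_ids`
#' @export
make_folds <- function(subject_ids, k, seed = 1L) {
  n <- length(subject_ids)
  if (k > n) stop("k = ", k, " exceeds the number of subjects (", n, ")")
  if (k < 2L) stop("k must be >= 2")
  perm <- with_seed(seed, sample(n))
  assignment <- rep(seq_len(k), length.out = n)[order(perm)]
  lapply(seq_len(k), function(f) {
    structure(list(fold_id = f,
                   train_ids = subject_ids[assignment != f],
                   test_ids = subject_ids[assignment == f]),
              class = "fold_split")
  })
}

sample_xy <- function(s) {
  if (inherits(s, "muscle_crop")) {
    if (is.null(s$mask)) stop("training sample has no mask")
    list(x = s$intensities, m = s$mask)
  } else list(x = s$x, m = s$mask)
}

adam_init <- function(params) {
  lapply(params, function(p) list(
    mw = matrix(0, nrow(p$w), ncol(p$w)), vw = matrix(0, nrow(p$w), ncol(p$w)),
    mb = numeric(length(p$b)), vb = numeric(length(p$b))))
}

adam_update <- function(network, state, grads, t, cfg) {
  b1 <- cfg$beta1; b2 <- cfg$beta2
  corr1 <- 1 - b1^t; corr2 <- 1 - b2^t
  for (id in names(network$params)) {
    g <- grads[[id]]; s <- state[[id]]
    s$mw <- b1 * s$mw + (1 - b1) * g$w
    s$vw <- b2 * s$vw + (1 - b2) * g$w^2
    s$mb <- b1 * s$mb + (1 - b1) * g$b
    s$vb <- b2 * s$vb + (1 - b2) * g$b^2
    network$params[[id]]$w <- network$params[[id]]$w -
      cfg$learning_rate * (s$mw / corr1) / (sqrt(s$vw / corr2) + cfg$adam_eps)
    network$params[[id]]$b <- network$params[[id]]$b -
      cfg$learning_rate * (s$mb / corr1) / (sqrt(s$vb / corr2) + cfg$adam_eps)
    state[[id]] <- s
  }
  list(network = network, state = state)
}

#' Train the segmentation network with soft Dice loss
#'
#' Adam optimization over shuffled mini-batches; the per-sample loss is
#' averaged within each batch.  Runs the full epoch budget and returns the
#' weights of the best (lowest mean training loss) epoch.
#'
#' @param samples list of annotated crops ([muscle_crop()] with masks, or
#'   bare `list(x, mask)`) — all shapes divisible by `2^network_depth`
#' @param config a [train_config()]
#' @param spec a [network_spec()] (ignored when `network` is given)
#' @param network optionally, a pre-built [build_network()] to continue
#' @param verbose print per-epoch losses
#' @return list with `network` (best epoch), `final_network`,
#'   `loss_history` (per-epoch mean training loss), `best_epoch`, `config`
#' @export
train_model <- function(samples, config = train_config(),
                        spec = network_spec(), network = NULL,
                        verbose = FALSE) {
  if (length(samples) < 1L) stop("need at least one training sample")
  stopifnot(inherits(config, "train_config"))
  if (is.null(network))
    network <- build_network(spec, seed = derive_seed(config$seed, "init"))
  state <- adam_init(network$params)
  n <- length(samples)
  loss_history <- numeric(config$epochs)
  best <- list(loss = Inf, weights = NULL, epoch = NA_integer_)
  t <- 0L

  with_seed(derive_seed(config$seed, "shuffle"), {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(n)
      epoch_losses <- numeric(0)
      for (b0 in seq(1L, n, by = config$batch_size)) {
        idx <- ord[b0:min(n, b0 + config$batch_size - 1L)]
        grads <- NULL
        batch_loss <- 0
        for (i in idx) {
          xy <- sample_xy(samples[[i]])
          fw <- net_forward(network, xy$x, cache = TRUE)
          dl <- soft_dice_loss(fw$y, xy$m, eps = config$dice_eps,
                               gradient = TRUE)
          batch_loss <- batch_loss + dl$loss
          g <- net_backward(network, fw$Tn, dl$grad / length(idx))
          grads <- if (is.null(grads)) g else {
            for (id in names(g)) {
              grads[[id]]$w <- grads[[id]]$w + g[[id]]$w
              grads[[id]]$b <- grads[[id]]$b + g[[id]]$b
            }
            grads
          }
        }
        t <- t + 1L
        upd <- adam_update(network, state, grads, t, config)
        network <- upd$network; state <- upd$state
        epoch_losses <- c(epoch_losses, batch_loss / length(idx))
      }
      loss_history[epoch] <- mean(epoch_losses)
      if (verbose)
        message(sprintf("epoch %3d  mean dice loss %.4f", epoch,
                        loss_history[epoch]))
      if (loss_history[epoch] < best$loss)
        best <- list(loss = loss_history[epoch],
                     weights = get_weights(network), epoch = epoch)
    }
  })
  list(network = set_weights(network, best$weights),
       final_network = network, loss_history = loss_history,
       best_epoch = best$epoch, config = config)
}

#' Learning-rate sweep
#'
#' Short fixed-epoch training runs across a rate grid; the selected rate
#' is the argmin of the final mean training loss.
#'
#' @param samples training samples as in [train_model()]
#' @param grid learning rates to try (default from [train_config()])
#' @param epochs epochs per probe run (default 10; the sweep uses
#'   truncated runs for tractability)
#' @param config base [train_config()] for everything but the rate
#' @param spec a [network_spec()]
#' @return list with `table` (data.frame `rate`, `final_loss`) and
#'   `selected` (the argmin rate)
#' @export
learning_rate_sweep <- function(samples, grid = NULL, epochs = 10L,
                                config = train_config(),
                                spec = network_spec()) {
  if (is.null(grid)) grid <- config$sweep_grid
  if (length(grid) < 1L) stop("rate grid must be non-empty")
  final_loss <- vapply(grid, function(lr) {
    cfg <- config; cfg$learning_rate <- lr; cfg$epochs <- as.integer(epochs)
    fit <- train_model(samples, cfg, spec)
    fit$loss_history[length(fit$loss_history)]
  }, numeric(1))
  tab <- data.frame(rate = grid, final_loss = final_loss)
  list(table = tab, selected = grid[which.min(final_loss)])
}

#' k-fold cross-validation of the segmentation model
#'
#' Trains one model per fold on its training subjects (optionally with
#' augmentation) and evaluates each held-out subject: per-muscle Dice
#' against the manual mask (averaged per subject by default) and
#' predicted-vs-manual muscle volumes for agreement analysis.
#'
#' @param subjects named or indexed list; each element has `id`, `pair`
#'   (prepared crops from [prepare_subject()], masks present) and
#'   optionally `truth_left_ml`, `truth_right_ml` (defaults to the crop
#'   masks' volumes)
#' @param k number of folds (default 6)
#' @param config a [train_config()]
#' @param spec a [network_spec()]
#' @param augment an [augmentation_spec()]; default uses reflections only
#'   (`n_random_transforms = 0`)
#' @param threshold probability cutoff (default 0.5)
#' @param dsc_pooling `"average"` (mean of the two per-muscle scores,
#'   default) or `"pooled"` (confusion counts summed over both muscles)
#' @return object of class `cv_report`: `per_fold` (data.frame),
#'   `per_subject` (data.frame with dsc and volume pairs), `pooled_mean`,
#'   `pooled_sd`, `folds`
#' @export
cross_validate <- function(subjects, k = 6L, config = train_config(),
                           spec = network_spec(),
                           augment = augmentation_spec(n_random_transforms = 0L),
                           threshold = 0.5, dsc_pooling = c("average", "pooled")) {
  dsc_pooling <- match.arg(dsc_pooling)
  for (s in subjects)
    if (is.null(s$pair$left$mask) || is.null(s$pair$right$mask))
      stop("cross-validation requires annotated (masked) subjects")
  ids <- vapply(subjects, function(s) as.character(s$id), character(1))
  if (anyDuplicated(ids)) stop("duplicate subject ids")
  folds <- make_folds(ids, k, seed = derive_seed(config$seed, "folds"))

  per_subject <- NULL
  per_fold <- NULL
  for (fold in folds) {
    stopifnot(!any(fold$test_ids %in% fold$train_ids))  # id audit
    train_subj <- subjects[match(fold$train_ids, ids)]
    aug <- augment; aug$seed <- derive_seed(config$seed,
                                            paste0("augment", fold$fold_id))
    ts <- build_training_set(lapply(train_subj, `[[`, "pair"), aug)
    train_samples <- lapply(seq_len(ts$n_samples),
                            function(i) materialize_sample(ts, i))
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0("fold", fold$fold_id))
    fit <- train_model(train_samples, cfg, spec)

    for (id in fold$test_ids) {
      subj <- subjects[[match(id, ids)]]
      vox_ml <- prod(subj$pair$right$voxel_mm) / 1000
      res <- lapply(c("left", "right"), function(muscle) {
        crop <- subj$pair[[muscle]]
        pred <- predict_mask(fit$network, crop, threshold)
        list(counts = confusion_counts(pred$mask, crop$mask),
             auto_ml = sum(pred$mask) * vox_ml,
             manual_ml = sum(crop$mask) * vox_ml)
      })
      names(res) <- c("left", "right")
      dsc_subj <- if (dsc_pooling == "average") {
        mean(c(dsc(res$left$counts), dsc(res$right$counts)))
      } else {
        cc <- mapply(function(a, b) a + b, res$left$counts, res$right$counts,
                     SIMPLIFY = FALSE)
        dsc(structure(cc, class = "confusion_counts"))
      }
      manual_left <- if (!is.null(subj$truth_left_ml)) subj$truth_left_ml
                     else res$left$manual_ml
      manual_right <- if (!is.null(subj$truth_right_ml)) subj$truth_right_ml
                      else res$right$manual_ml
      per_subject <- rbind(per_subject, data.frame(
        subject_id = id, fold = fold$fold_id, dsc = dsc_subj,
        auto_left_ml = res$left$auto_ml, manual_left_ml = manual_left,
        auto_right_ml = res$right$auto_ml, manual_right_ml = manual_right,
        auto_total_ml = res$left$auto_ml + res$right$auto_ml,
        manual_total_ml = manual_left + manual_right))
    }
    fs <- per_subject[per_subject$fold == fold$fold_id, ]
    per_fold <- rbind(per_fold, data.frame(
      fold = fold$fold_id, n_test = nrow(fs), mean_dsc = mean(fs$dsc),
      sd_dsc = if (nrow(fs) > 1) sd(fs$dsc) else NA_real_))
  }
  structure(list(per_fold = per_fold, per_subject = per_subject,
                 pooled_mean = mean(per_subject$dsc),
                 pooled_sd = sd(per_subject$dsc), folds = folds),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d folds, %d subjects, DSC %.4f +/- %.4f\n",
              nrow(x$per_fold), nrow(x$per_subject),
              x$pooled_mean, x$pooled_sd))
  invisible(x)
}
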