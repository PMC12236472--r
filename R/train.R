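#' Train the multimodal network
#'
#' Multi-task training with the weighted cross-entropy criterion, the
#' scheduled task weights of [lambda_schedule()], Adam optimization with
#' plateau learning-rate decay, global-norm gradient clipping, optional
#' on-the-fly augmentation, and checkpointing of the parameters with the
#' lowest validation loss. All randomness derives from `seed`.
#'
#' @param model a `voxel_model` from [build_model()].
#' @param dataset list of training samples; each sample is a list with
#'   `density` (w^3 array), `af3` (24 x w^3 array or NULL) and `masks`
#'   (a `label_masks` list).
#' @param val_dataset validation samples (same format); defaults to the
#'   training set when NULL (tiny-scale overfitting runs).
#' @param epochs number of epochs.
#' @param lr initial learning rate (Adam).
#' @param clip_norm global gradient-norm clipping threshold.
#' @param augment logical; apply [augment_batch()] to training windows.
#' @param lr_patience epochs without validation improvement before the
#'   learning rate is halved.
#' @param class_weights optional list with numeric vectors `backbone` (4),
#'   `calpha` (4), `amino` (21); defaults to inverse class frequencies
#'   computed from the training masks.
#' @param seed integer seed controlling shuffling, augmentation and dropout.
#' @param verbose print per-epoch losses.
#' @return Invisibly, a list with `model` (parameters set to the best
#'   checkpoint), `history` (data.frame: epoch, lambda, train/val losses,
#'   lr) and `best_epoch`.
#' @export
train_model <- function(model, dataset, val_dataset = NULL, epochs = 30L,
                        lr = 1e-4, clip_norm = 1.0, augment = FALSE,
                        lr_patience = 5L, class_weights = NULL, seed = 1L,
                        verbose = FALSE) {
  stopifnot(inherits(model, "voxel_model"))
  if (length(dataset) == 0L) stop("train_model: empty dataset")
  if (is.null(val_dataset)) val_dataset <- dataset
  set.seed(seed)

  if (is.null(class_weights)) {
    all_bb <- unlist(lapply(dataset, function(s) as.integer(s$masks$backbone)))
    all_ca <- unlist(lapply(dataset, function(s) as.integer(s$masks$calpha)))
    all_aa <- unlist(lapply(dataset, function(s) as.integer(s$masks$amino)))
    class_weights <- list(
      backbone = class_weights_from_labels(all_bb, 4L),
      calpha = class_weights_from_labels(all_ca, 4L),
      amino = class_weights_from_labels(all_aa, 21L))
  }

  refs <- param_refs(model$params)
  if (is.null(model$adam))
    model$adam <- lapply(refs, function(rf) {
      w <- get_by_path(model$params, rf)
      list(m = w * 0, v = w * 0)
    })

  history <- data.frame()
  best_val <- Inf; best_params <- NULL; best_epoch <- NA_integer_
  cur_lr <- lr; stall <- 0L

  for (epoch in seq_len(epochs)) {
    lam <- lambda_schedule(epoch - 1L)
    ord <- sample(seq_along(dataset))
    tr_loss <- 0
    for (s in ord) {
      smp <- dataset[[s]]
      if (augment) {
        aug <- augment_batch(smp$density, smp$af3, smp$masks,
                             rng_seed = sample.int(.Machine$integer.max, 1L))
        smp <- list(density = aug$density, af3 = aug$af3, masks = aug$masks)
      }
      st <- train_step(model, smp, lam, class_weights, cur_lr, clip_norm,
                       refs)
      tr_loss <- tr_loss + st
    }
    tr_loss <- tr_loss / length(dataset)

    val_loss <- mean(vapply(val_dataset, function(smp)
      eval_loss(model, smp, lam, class_weights), numeric(1)))

    history <- rbind(history, data.frame(
      epoch = epoch, lambda_b = lam[1], lambda_c = lam[2], lambda_a = lam[3],
      train_loss = tr_loss, val_loss = val_loss, lr = cur_lr))
    if (verbose)
      message(sprintf("epoch %3d  lambda=(%.2f,%.2f,%.2f)  train=%.4f  val=%.4f",
                      epoch, lam[1], lam[2], lam[3], tr_loss, val_loss))

    if (val_loss < best_val - 1e-9) {
      best_val <- val_loss
      best_params <- rapply(model$params, identity, how = "replace")
      best_epoch <- epoch
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= lr_patience) { cur_lr <- cur_lr / 2; stall <- 0L }
    }
  }
  if (!is.null(best_params)) model$params <- best_params
  invisible(list(model = model, history = history, best_epoch = best_epoch,
                 best_val = best_val, class_weights = class_weights))
}

# one optimization step on one window; returns the scalar training loss
train_step <- function(model, smp, lam, cw, lr, clip_norm, refs) {
  fw <- model_forward(model, smp$density, smp$af3, training = TRUE)
  loss <- window_loss(fw, smp$masks, lam, cw)
  backward(fw$tape, loss)

  # collect gradients from leaf nodes, clip by global norm, Adam update
  leaves <- fw$leaves
  grads <- lapply(refs, function(rf) {
    nd <- get_by_path(leaves, rf)
    if (is.null(nd$grad)) nd$val * 0 else nd$grad
  })
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  scale <- if (gn > clip_norm) clip_norm / gn else 1
  model$step <- model$step + 1L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (i in seq_along(refs)) {
    g <- grads[[i]] * scale
    st <- model$adam[[i]]
    st$m <- b1 * st$m + (1 - b1) * g
    st$v <- b2 * st$v + (1 - b2) * g^2
    model$adam[[i]] <- st
    mh <- st$m / (1 - b1^model$step)
    vh <- st$v / (1 - b2^model$step)
    w <- get_by_path(model$params, refs[[i]])
    model$params <- set_by_path(model$params, refs[[i]],
                                w - lr * mh / (sqrt(vh) + eps))
  }
  as.numeric(loss$val)
}

window_loss <- function(fw, masks, lam, cw) {
  tape <- fw$tape
  l_b <- t_wce(fw$backbone, as.integer(masks$backbone), cw$backbone, tape)
  l_c <- t_wce(fw$calpha, as.integer(masks$calpha), cw$calpha, tape)
  l_a <- t_wce(fw$amino, as.integer(masks$amino), cw$amino, tape)
  # lambda-weighted sum on the tape
  mix <- function(x, w) tnsr(x$val * w, c(1L, 1L, 1L), parents = list(x),
                             tape = tape, bw = function(g) acc_grad(x, g * w))
  t_add(mix(l_b, lam[1]), t_add(mix(l_c, lam[2]), mix(l_a, lam[3]), tape),
        tape)
}

eval_loss <- function(model, smp, lam, cw) {
  fw <- model_forward(model, smp$density, smp$af3, training = FALSE)
  l_b <- weighted_cross_entropy(fw$backbone$val,
                                as.integer(smp$masks$backbone), cw$backbone)
  l_c <- weighted_cross_entropy(fw$calpha$val,
                                as.integer(smp$masks$calpha), cw$calpha)
  l_a <- weighted_cross_entropy(fw$amino$val,
                                as.integer(smp$masks$amino), cw$amino)
  total_loss(l_b, l_c, l_a, lam)
}
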