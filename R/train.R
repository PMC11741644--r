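#' Training settings for candidate networks
#'
#' Bundles the optimisation hyperparameters of a single candidate training
#' run.  Defaults follow the study protocol: up to 200 epochs with early
#' stopping after 15 epochs without improvement of the monitored
#' segmentation quality, batches of 8 patches of extent 32x32x32.  One
#' epoch draws `batch_size` patches at random positions from the training
#' volumes and performs one optimisation step on them (patch-wise training,
#' the usual regime for volumetric segmentation).
#'
#' @param max_epochs maximum number of epochs (default 200).
#' @param patience_epochs epochs without improvement before early stopping
#'   (default 15; must not exceed `max_epochs`).
#' @param batch_size patches per batch (default 8).
#' @param patch_shape spatial extent of training patches; length 3 for 3-D
#'   models, length 2 for 2-D (default `c(32, 32, 32)`).  Each extent must
#'   be divisible by the network's downsampling factor (4).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed integer seed making the whole run deterministic.
#' @return A list of class `training_settings`.
#' @export
training_settings <- function(max_epochs = 200L, patience_epochs = 15L,
                              batch_size = 8L, patch_shape = c(32L, 32L, 32L),
                              learning_rate = 1e-3, seed = 1L) {
  if (patience_epochs > max_epochs) {
    stop("`patience_epochs` must not exceed `max_epochs`", call. = FALSE)
  }
  if (max_epochs < 1L || patience_epochs < 1L || batch_size < 1L) {
    stop("epochs, patience and batch size must be positive", call. = FALSE)
  }
  structure(
    list(max_epochs = as.integer(max_epochs),
         patience_epochs = as.integer(patience_epochs),
         batch_size = as.integer(batch_size),
         patch_shape = as.integer(patch_shape),
         learning_rate = learning_rate,
         seed = as.integer(seed)),
    class = "training_settings"
  )
}

# Draw a batch of (image, label) patches from a dataset of full volumes.
# dataset: list of list(image = (M, spatial), labels = (spatial)).
sample_patch_batch <- function(dataset, patch_shape, batch_size,
                               spatial_rank) {
  M <- dim(dataset[[1L]]$image)[1L]
  ps <- patch_shape
  if (spatial_rank == 2L && length(ps) > 2L) ps <- ps[1:2]
  d5 <- if (spatial_rank == 3L) c(M, ps, batch_size) else
    c(M, ps, 1L, batch_size)
  x <- array(0, d5)
  tshape <- if (spatial_rank == 3L) c(ps, batch_size) else
    c(ps, 1L, batch_size)
  t <- array(0L, tshape)
  for (bi in seq_len(batch_size)) {
    s <- dataset[[sample.int(length(dataset), 1L)]]
    lab <- as_label_array(s$labels)
    sp <- dim(lab)
    corner <- vapply(seq_along(ps), function(a) {
      if (sp[a] == ps[a]) 1L else sample.int(sp[a] - ps[a] + 1L, 1L)
    }, integer(1))
    if (spatial_rank == 3L) {
      ix <- lapply(1:3, function(a) corner[a] + seq_len(ps[a]) - 1L)
      x[, , , , bi] <- s$image[, ix[[1L]], ix[[2L]], ix[[3L]]]
      t[, , , bi] <- lab[ix[[1L]], ix[[2L]], ix[[3L]]]
    } else {
      ix <- lapply(1:2, function(a) corner[a] + seq_len(ps[a]) - 1L)
      x[, , , 1L, bi] <- s$image[, ix[[1L]], ix[[2L]]]
      t[, , 1L, bi] <- lab[ix[[1L]], ix[[2L]]]
    }
  }
  list(x = x, target = t)
}

# mean Dice of hard argmax predictions against integer labels, over the
# tissue classes present in the truth (background class 0 excluded)
batch_mean_dice <- function(probs, target, n_classes) {
  pm <- matrix(probs, n_classes)
  pred <- max.col(t(pm), ties.method = "first") - 1L
  tv <- as.integer(target)
  labs <- sort(unique(tv[tv > 0L]))
  if (length(labs) == 0L) return(NA_real_)
  mean(vapply(labs, function(l) {
    s <- pred == l; t <- tv == l
    denom <- sum(s) + sum(t)
    if (denom == 0L) 1 else 2 * sum(s & t) / denom
  }, numeric(1)))
}

#' Train a candidate network
#'
#' Optimises a built model on a dataset of labelled volumes with Adam,
#' minimising the sum of voxel-wise cross-entropy and a soft-Dice loss over
#' the tissue classes.  Each epoch samples a batch of patches, takes one
#' optimisation step, and monitors the batch mean Dice of the hard
#' predictions; training stops early after `patience_epochs` epochs without
#' strict improvement of the monitored metric.  The run is fully
#' deterministic given `settings$seed`.  A non-finite loss aborts training
#' and is reported through the `failed` flag (the configuration search maps
#' it to quality 0) rather than as an error.
#'
#' @param model a [build_model()] network.
#' @param dataset list of samples, each a list with `image`
#'   (`(n_modalities, spatial...)` numeric array) and `labels` (integer
#'   array over the same grid, 0 = background).
#' @param settings a [training_settings()] object.
#' @return A list with `model` (trained weights and batch-norm state),
#'   `history` (data.frame: epoch, loss, cross_entropy, dice_loss, metric),
#'   `failed` (logical) and `stopped_early` (logical).
#' @export
train_candidate <- function(model, dataset, settings = training_settings()) {
  stopifnot(inherits(model, "dense_seg_model"))
  if (length(dataset) == 0L) {
    stop("`dataset` is empty: at least one labelled volume is required",
         call. = FALSE)
  }
  set.seed(settings$seed)
  ps <- settings$patch_shape
  if (model$spatial_rank == 2L && length(ps) > 2L) ps <- ps[1:2]
  if (any(ps %% model$downsampling_factor != 0)) {
    stop("`patch_shape` must be divisible by the downsampling factor ",
         model$downsampling_factor, call. = FALSE)
  }
  opt <- adam_init(model$params)
  dice_classes <- 2:model$n_classes  # channel indices of the tissue classes
  best_metric <- -Inf
  stall <- 0L
  failed <- FALSE
  hist <- vector("list", settings$max_epochs)
  n_epochs <- 0L
  for (epoch in seq_len(settings$max_epochs)) {
    batch <- sample_patch_batch(dataset, ps, settings$batch_size,
                                model$spatial_rank)
    fwd <- model_forward(model, batch$x, training = TRUE)
    model$bn_state <- fwd$bn_state
    C <- model$n_classes
    pm <- matrix(fwd$probs, C)
    target <- as.integer(batch$target) + 1L   # labels 0.. -> classes 1..
    ls <- ce_dice_loss(pm, target, dice_classes)
    if (!is.finite(ls$loss)) {
      failed <- TRUE
      n_epochs <- epoch - 1L
      break
    }
    dz <- array(ls$dz, dim(fwd$probs))
    grads <- model_backward(model, fwd, dz)
    upd <- adam_step(model$params, grads, opt, lr = settings$learning_rate)
    model$params <- upd$params
    opt <- upd$state
    metric <- batch_mean_dice(fwd$probs, batch$target, C)
    hist[[epoch]] <- data.frame(epoch = epoch, loss = ls$loss,
                                cross_entropy = ls$ce,
                                dice_loss = ls$dice_loss, metric = metric)
    n_epochs <- epoch
    if (is.finite(metric) && metric > best_metric + 1e-8) {
      best_metric <- metric
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    if (stall >= settings$patience_epochs) break
  }
  history <- if (n_epochs > 0L) do.call(rbind, hist[seq_len(n_epochs)]) else
    data.frame(epoch = integer(), loss = numeric(),
               cross_entropy = numeric(), dice_loss = numeric(),
               metric = numeric())
  list(model = model, history = history, failed = failed,
       stopped_early = !failed & n_epochs < settings$max_epochs)
}

#' Export a training history as CSV
#'
#' @param history the `history` data.frame from [train_candidate()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_history_csv <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
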