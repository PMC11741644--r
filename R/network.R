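#' Build the configurable dense encoder-decoder segmentation network
#'
#' Instantiates the base CNN pattern for a given configuration genotype: six
#' dense blocks of three convolution -> batch-normalisation -> ReLU layers
#' each, with dense connectivity inside every block (each internal layer
#' receives the block input concatenated with all previous internal
#' outputs).  The encoder interleaves the first three blocks with the two
#' searchable pooling stages (each window-2 stride-2, max or average); the
#' decoder mirrors them with parameter-free nearest-neighbour upsampling, so
#' the output spatial extent equals the input extent.  The 19th configurable
#' convolution feeds a fixed 1x1(x1) class-projection convolution followed
#' by a per-voxel softmax.
#'
#' Filter length and width are the two in-plane kernel extents; for 3-D
#' inputs the through-plane kernel extent is `min(filter_length, 3)`, which
#' keeps 3-D kernels small.  All convolutions use same-padding.
#'
#' @param config a [assemble_configuration()] genotype.
#' @param n_modalities number of input image channels (2 for a T1/T2 pair).
#' @param n_classes number of output classes including background
#'   (default 4: background, CSF, GM, WM).
#' @param spatial_rank 2 or 3.
#' @param seed integer seed for weight initialisation (He-scaled normal).
#' @return An object of class `dense_seg_model`.
#' @examples
#' cfg <- assemble_configuration(rep(1, 19), c(0, 1))
#' m <- build_model(cfg, n_modalities = 2, n_classes = 4, spatial_rank = 2)
#' n_parameters(m)
#' @export
build_model <- function(config, n_modalities, n_classes = 4L,
                        spatial_rank = 3L, seed = 1L) {
  stopifnot(inherits(config, "network_configuration"))
  if (!spatial_rank %in% c(2L, 3L)) {
    stop("`spatial_rank` must be 2 or 3", call. = FALSE)
  }
  set.seed(seed)
  conv <- config$conv
  kernel_of <- function(l) {
    k3 <- if (spatial_rank == 3L) min(conv$filter_length[l], 3L) else 1L
    c(conv$filter_length[l], conv$filter_width[l], k3)
  }
  init_conv <- function(cin, cout, k) {
    fan_in <- cin * prod(k)
    list(
      w = array(stats::rnorm(cout * cin * prod(k), sd = sqrt(2 / fan_in)),
                c(cout, cin, k)),
      b = numeric(cout),
      gamma = rep(1, cout),
      beta = numeric(cout)
    )
  }
  params <- list(conv = vector("list", 19L))
  bn_state <- vector("list", 19L)
  # dense-block channel bookkeeping: layer l of a block sees the block input
  # plus every previous internal output
  in_ch <- n_modalities
  for (blk in 1:6) {
    layers <- (3L * (blk - 1L) + 1L):(3L * blk)
    prev <- integer(0)
    for (l in layers) {
      cin <- in_ch + sum(prev)
      params$conv[[l]] <- init_conv(cin, conv$n_filters[l], kernel_of(l))
      bn_state[[l]] <- list(mean = numeric(conv$n_filters[l]),
                            var = rep(1, conv$n_filters[l]))
      prev <- c(prev, conv$n_filters[l])
    }
    in_ch <- conv$n_filters[layers[3L]]
  }
  params$conv[[19L]] <- init_conv(in_ch, conv$n_filters[19L], kernel_of(19L))
  bn_state[[19L]] <- list(mean = numeric(conv$n_filters[19L]),
                          var = rep(1, conv$n_filters[19L]))
  params$head <- list(
    w = array(stats::rnorm(n_classes * conv$n_filters[19L], sd = 0.01),
              c(n_classes, conv$n_filters[19L], 1L, 1L, 1L)),
    b = numeric(n_classes)
  )
  structure(
    list(
      config = config,
      n_modalities = as.integer(n_modalities),
      n_classes = as.integer(n_classes),
      spatial_rank = as.integer(spatial_rank),
      params = params,
      bn_state = bn_state,
      downsampling_factor = 4L,
      seed = as.integer(seed)
    ),
    class = "dense_seg_model"
  )
}

#' @export
print.dense_seg_model <- function(x, ...) {
  cat("<dense_seg_model> rank-", x$spatial_rank, " encoder-decoder, ",
      x$n_modalities, " modalities -> ", x$n_classes, " classes, ",
      format(n_parameters(x), big.mark = ","), " parameters\n", sep = "")
  invisible(x)
}

#' Count trainable parameters
#'
#' @param model a [build_model()] network.
#' @return Total number of trainable scalars (weights, biases, batch-norm
#'   scale/shift).
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "dense_seg_model"))
  sum(rapply(model$params, length, how = "unlist"))
}

pool_window <- function(model) {
  if (model$spatial_rank == 3L) c(2L, 2L, 2L) else c(2L, 2L, 1L)
}

check_extent <- function(model, d_spatial) {
  f <- model$downsampling_factor
  need <- if (model$spatial_rank == 3L) d_spatial else d_spatial[1:2]
  if (any(need %% f != 0) || any(need < f)) {
    stop("input spatial extent (", paste(d_spatial, collapse = "x"),
         ") must be divisible by the network's total downsampling factor ",
         f, call. = FALSE)
  }
}

# Forward pass.  x is (n_modalities, H, W, D, B) with D = 1 for rank-2
# models.  Returns per-voxel class probabilities (n_classes, H, W, D, B)
# plus caches (training mode) and updated batch-norm running statistics.
model_forward <- function(model, x, training = FALSE) {
  d <- dim(x)
  if (length(d) != 5L || d[1L] != model$n_modalities) {
    stop("input must be a 5-D array (modalities, H, W, D, batch) with ",
         model$n_modalities, " modalities", call. = FALSE)
  }
  check_extent(model, d[2:4])
  bn_state <- model$bn_state
  conv <- model$config$conv
  win <- pool_window(model)
  caches <- list()

  layer_fwd <- function(l, input) {
    cv <- conv_fwd(input, model$params$conv[[l]]$w, model$params$conv[[l]]$b,
                   keep_cache = training)
    bn <- bn_fwd(cv$y, model$params$conv[[l]]$gamma,
                 model$params$conv[[l]]$beta,
                 bn_state[[l]]$mean, bn_state[[l]]$var, training)
    bn_state[[l]]$mean <<- bn$run_mean
    bn_state[[l]]$var <<- bn$run_var
    rl <- relu_fwd(bn$y)
    if (training) {
      caches[[paste0("conv", l)]] <<- list(conv = cv$cache, bn = bn$cache,
                                           relu = rl$cache)
    }
    rl$y
  }

  block_fwd <- function(blk, input) {
    layers <- (3L * (blk - 1L) + 1L):(3L * blk)
    feats <- list(input)
    for (l in layers) {
      y <- layer_fwd(l, ch_cat(feats))
      feats <- c(feats, list(y))
    }
    if (training) {
      caches[[paste0("block", blk)]] <<-
        list(chans = vapply(feats, function(a) dim(a)[1L], integer(1)))
    }
    feats[[4L]]
  }

  cur <- block_fwd(1L, x)
  p1 <- pool_fwd(cur, model$config$pooling[1L], win)
  if (training) caches$pool1 <- p1$cache
  cur <- block_fwd(2L, p1$y)
  p2 <- pool_fwd(cur, model$config$pooling[2L], win)
  if (training) caches$pool2 <- p2$cache
  cur <- block_fwd(3L, p2$y)
  cur <- block_fwd(4L, cur)
  if (training) caches$up1_in <- dim(cur)
  cur <- upsample_fwd(cur, win)
  cur <- block_fwd(5L, cur)
  if (training) caches$up2_in <- dim(cur)
  cur <- upsample_fwd(cur, win)
  cur <- block_fwd(6L, cur)
  cur <- layer_fwd(19L, cur)
  hd <- conv_fwd(cur, model$params$head$w, model$params$head$b,
                 keep_cache = training)
  if (training) caches$head <- hd$cache
  probs <- softmax_fwd(hd$y)
  list(probs = probs, logits = hd$y, caches = caches, bn_state = bn_state)
}

# Backward pass from the loss gradient with respect to the logits.
# Returns parameter gradients with the same structure as model$params.
model_backward <- function(model, fwd, dz) {
  caches <- fwd$caches
  win <- pool_window(model)
  grads <- list(conv = vector("list", 19L), head = NULL)

  layer_bwd <- function(l, dy) {
    cc <- caches[[paste0("conv", l)]]
    dy <- relu_bwd(dy, cc$relu)
    bb <- bn_bwd(dy, cc$bn)
    cb <- conv_bwd(bb$dx, cc$conv)
    grads$conv[[l]] <<- list(w = cb$dw, b = cb$db, gamma = bb$dgamma,
                             beta = bb$dbeta)
    cb$dx
  }

  block_bwd <- function(blk, dout) {
    layers <- (3L * (blk - 1L) + 1L):(3L * blk)
    chans <- caches[[paste0("block", blk)]]$chans
    # feats gradients: [block input, y1, y2, y3]
    dfeats <- vector("list", 4L)
    dfeats[[4L]] <- dout
    for (pos in 3:1) {
      l <- layers[pos]
      din <- layer_bwd(l, dfeats[[pos + 1L]])
      parts <- ch_split(din, chans[seq_len(pos)])
      for (j in seq_len(pos)) {
        dfeats[[j]] <- if (is.null(dfeats[[j]])) parts[[j]] else
          dfeats[[j]] + parts[[j]]
      }
    }
    dfeats[[1L]]
  }

  hb <- conv_bwd(dz, caches$head)
  grads$head <- list(w = hb$dw, b = hb$db)
  d <- layer_bwd(19L, hb$dx)
  d <- block_bwd(6L, d)
  d <- upsample_bwd(d, win, caches$up2_in)
  d <- block_bwd(5L, d)
  d <- upsample_bwd(d, win, caches$up1_in)
  d <- block_bwd(4L, d)
  d <- block_bwd(3L, d)
  d <- pool_bwd(d, caches$pool2)
  d <- block_bwd(2L, d)
  d <- pool_bwd(d, caches$pool1)
  d <- block_bwd(1L, d)
  grads
}

# promote a single (M, spatial...) image to the internal (M, H, W, D, B)
# layout; rank-2 images get a singleton third spatial axis
as_batch5d <- function(image, spatial_rank) {
  d <- dim(image)
  dim(image) <- if (spatial_rank == 3L) c(d, 1L) else c(d, 1L, 1L)
  image
}

#' Segment a multimodal volume with a built model
#'
#' Runs the network in inference mode (batch-norm running statistics) and
#' returns the per-voxel argmax label.  Labels are 0-based:
#' 0 = background, then tissue classes in channel order.
#'
#' @param model a [build_model()] network (typically after
#'   [train_candidate()]).
#' @param image numeric array `(n_modalities, H, W[, D])`; the spatial
#'   extent must be divisible by the network's downsampling factor.
#' @param spacing per-axis voxel size in mm (default 1).
#' @return A [label_volume()] with integer labels in `[0, n_classes)`.
#' @export
predict_segmentation <- function(model, image, spacing = NULL) {
  stopifnot(inherits(model, "dense_seg_model"))
  d <- dim(image)
  expected <- model$spatial_rank + 1L
  if (length(d) != expected || d[1L] != model$n_modalities) {
    stop("`image` must be (", model$n_modalities, ", spatial...) with ",
         model$spatial_rank, " spatial axes; got extent ",
         paste(d, collapse = "x"), call. = FALSE)
  }
  x <- as_batch5d(image, model$spatial_rank)
  fwd <- model_forward(model, x, training = FALSE)
  C <- model$n_classes
  pm <- matrix(fwd$probs, C)
  labels <- max.col(t(pm), ties.method = "first") - 1L
  sp_dims <- d[-1L]
  dim(labels) <- sp_dims
  if (is.null(spacing)) spacing <- rep(1, length(sp_dims))
  label_volume(labels, spacing = spacing)
}
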