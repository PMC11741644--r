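#' Specification of a synthetic multimodal tissue phantom
#'
#' The phantom emulates the statistical structure of a co-registered
#' T1/T2-like pair over the three tissue classes: nested tissue bands
#' (background envelope, CSF rim, GM ribbon, WM core) obtained by
#' thresholding a radial field perturbed by a smoothed random field, with
#' modality-dependent class contrast and additive Gaussian noise.  Default
#' intensities order the classes as in infant MRI: in modality 1 (T1-like)
#' CSF is the darkest tissue, while in modality 2 (T2-like) it is the
#' brightest, and the GM/WM mean separation is deliberately small compared
#' with the CSF/GM separation in both modalities (the low-contrast regime
#' that makes neonatal tissue segmentation hard).
#'
#' @param shape spatial extent, length 3 (or 2 for planar phantoms);
#'   default `c(32, 32, 32)`.
#' @param class_means 4 x M matrix of per-class (background, CSF, GM, WM)
#'   per-modality intensity means.
#' @param class_stds per-class intensity jitter (length 4).
#' @param noise_std additive Gaussian noise scale (default 0.05).
#' @param smoothness spatial correlation length (voxels) of the boundary
#'   perturbation field (default 4).
#' @param boundary_amplitude amplitude of the boundary perturbation
#'   relative to the radial field (default 0.25).
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32L, 32L, 32L),
                         class_means = default_class_means(),
                         class_stds = c(0.02, 0.02, 0.02, 0.02),
                         noise_std = 0.05,
                         smoothness = 4,
                         boundary_amplitude = 0.25) {
  if (!(length(shape) %in% c(2L, 3L)) || any(shape < 8L)) {
    stop("`shape` must give 2 or 3 spatial extents of at least 8 (the ",
         "network's downsampling factor times 2)", call. = FALSE)
  }
  # every tissue pair must be separable in at least one modality
  tiss <- class_means[-1L, , drop = FALSE]
  pair_sep <- apply(tiss, 2L, dist)
  if (any(apply(as.matrix(pair_sep), 1L, max) < 2 * noise_std - 1e-9)) {
    warning("some tissue classes are indistinguishable in every modality ",
            "given `noise_std`")
  }
  structure(list(shape = as.integer(shape), class_means = class_means,
                 class_stds = class_stds, noise_std = noise_std,
                 smoothness = smoothness,
                 boundary_amplitude = boundary_amplitude),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_class_means <- function() {
  # rows: background, CSF, GM, WM; columns: modality 1 (T1-like), 2 (T2-like)
  matrix(c(0.05, 0.20, 0.55, 0.65,
           0.05, 0.90, 0.50, 0.40),
         nrow = 4L, ncol = 2L,
         dimnames = list(c("background", "CSF", "GM", "WM"),
                         c("T1like", "T2like")))
}

# separable box-smoothing with edge replication, repeated to approximate a
# Gaussian of the requested correlation length
smooth_field <- function(x, radius, passes = 3L) {
  d <- dim(x)
  r <- max(1L, round(radius))
  for (pass in seq_len(passes)) {
    for (ax in seq_along(d)) {
      acc <- x
      for (s in seq_len(r)) {
        acc <- acc + shift_replicate(x, ax, s) + shift_replicate(x, ax, -s)
      }
      x <- acc / (2 * r + 1)
    }
  }
  x
}

shift_replicate <- function(x, ax, by) {
  d <- dim(x)
  idx <- lapply(d, seq_len)
  src <- pmin(pmax(idx[[ax]] - by, 1L), d[ax])
  idx[[ax]] <- src
  do.call(`[`, c(list(x), idx))
}

#' Generate one multimodal tissue phantom
#'
#' Produces a two-modality image and its tissue label map from a
#' [phantom_spec()].  Tissue geometry comes from thresholding
#' `radial field + boundary perturbation` at its own quantiles, giving a WM
#' core, a GM ribbon, a CSF rim and a background envelope with fixed,
#' non-degenerate volume fractions.  Each modality is the per-voxel class
#' mean plus class jitter plus Gaussian noise, then standardised to mean 0
#' and variance 1.  The output is fully determined by `seed`.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed.
#' @return A list with `image` (`(2, spatial...)` array, standardised per
#'   modality) and `labels` (a [label_volume()]; 0 = background, 1 = CSF,
#'   2 = GM, 3 = WM).
#' @export
generate_phantom <- function(spec = phantom_spec(), seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(seed)
  d <- spec$shape
  rank <- length(d)
  axes <- lapply(d, function(n) (seq_len(n) - (n + 1) / 2) / (n / 2))
  r2 <- array(0, d)
  for (ax in seq_len(rank)) {
    shp <- rep(1L, rank); shp[ax] <- d[ax]
    r2 <- r2 + array(rep(axes[[ax]]^2, each = prod(d[seq_len(ax - 1L)])), d)
  }
  radial <- sqrt(r2)
  noise_field <- smooth_field(array(stats::rnorm(prod(d)), d),
                              spec$smoothness)
  noise_field <- noise_field / max(stats::sd(noise_field), 1e-12)
  f <- radial + spec$boundary_amplitude * noise_field
  # nested bands at fixed volume fractions: WM core 25%, GM 30%, CSF 20%
  th <- stats::quantile(f, c(0.25, 0.55, 0.75), names = FALSE)
  labels <- array(0L, d)
  labels[f < th[3L]] <- 1L   # CSF rim
  labels[f < th[2L]] <- 2L   # GM ribbon
  labels[f < th[1L]] <- 3L   # WM core
  M <- ncol(spec$class_means)
  image <- array(0, c(M, d))
  class_of <- labels + 1L    # 1=background .. 4=WM
  for (m in seq_len(M)) {
    jitter <- stats::rnorm(4L, 0, spec$class_stds)
    vox <- spec$class_means[class_of, m] + jitter[class_of] +
      stats::rnorm(prod(d), 0, spec$noise_std)
    vox <- (vox - mean(vox)) / max(stats::sd(vox), 1e-12)
    image[slice.index(image, 1L) == m] <- vox
  }
  list(image = image, labels = label_volume(labels, spacing = rep(1, rank)))
}

#' Generate a dataset of independent phantoms
#'
#' @param n number of phantoms (at least 1).
#' @param spec a [phantom_spec()].
#' @param seed integer seed; phantom `i` uses an independent sub-seed
#'   derived from it, so the dataset is reproducible and its members are
#'   distinct.
#' @return A list of `n` samples, each a list with `image` and `labels` as
#'   in [generate_phantom()].
#' @export
generate_dataset <- function(n, spec = phantom_spec(), seed = 1L) {
  if (n < 1L) stop("`n` must be at least 1", call. = FALSE)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  lapply(sub_seeds, function(s) generate_phantom(spec, seed = s))
}

#' Stack samples into the B x M x H x W x L batch layout
#'
#' Returns the batch tensor in the conventional sample layout
#' (batch, modalities, sagittal, coronal, axial).
#'
#' @param dataset a [generate_dataset()] list.
#' @param indices which samples to stack (default: all).
#' @return A numeric array `(B, M, H, W, L)` (or `(B, M, H, W)` for planar
#'   phantoms).
#' @export
as_batch_tensor <- function(dataset, indices = seq_along(dataset)) {
  d_img <- dim(dataset[[1L]]$image)
  B <- length(indices)
  out <- array(0, c(B, d_img))
  for (i in seq_along(indices)) {
    out[slice.index(out, 1L) == i] <- dataset[[indices[i]]]$image
  }
  out
}

#' Deterministic oracle environment for search testing
#'
#' Builds a test-double environment that maps joint automata actions to a
#' scalar quality in `[0, 1]` in O(1), with a known optimum, so the
#' configuration search can be exercised without any network training.
#' `structure = "additive"` sums independent per-automaton utilities (a
#' separable, easy landscape); `structure = "single_peak"` concentrates
#' quality around one randomly placed joint action (quality decays
#' geometrically with the number of coordinates that differ from the
#' optimum).
#'
#' @param n_automata number of automata.
#' @param actions_per_automaton integer vector (recycled to `n_automata`)
#'   of action counts.
#' @param structure `"additive"` or `"single_peak"`.
#' @param seed integer seed.
#' @param utilities optional list of per-automaton utility vectors
#'   (additive structure only), overriding the random draw.
#' @return A list of class `oracle_environment` with elements `evaluate`
#'   (function from an integer action vector to quality), `n_automata`,
#'   `n_actions`, `known_optimum` (action vector) and `optimum_quality`.
#' @examples
#' env <- make_oracle_table(2, 2, utilities = list(c(0.1, 0.4), c(0.2, 0.1)))
#' env$known_optimum   # c(2, 1)
#' env$optimum_quality # 0.6
#' @export
make_oracle_table <- function(n_automata, actions_per_automaton,
                              structure = c("additive", "single_peak"),
                              seed = 1L, utilities = NULL) {
  structure <- match.arg(structure)
  n_actions <- rep_len(as.integer(actions_per_automaton), n_automata)
  if (prod(n_actions) > 1e6) {
    stop("joint action space larger than 1e6: exhaustive verification is ",
         "not feasible", call. = FALSE)
  }
  set.seed(seed)
  if (structure == "additive") {
    if (is.null(utilities)) {
      utilities <- lapply(n_actions, function(k) stats::runif(k) / n_automata)
    }
    stopifnot(length(utilities) == n_automata)
    evaluate <- function(actions) {
      sum(vapply(seq_len(n_automata),
                 function(i) utilities[[i]][actions[i]], numeric(1)))
    }
    known_optimum <- vapply(utilities, which.max, integer(1))
  } else {
    peak <- vapply(n_actions, function(k) sample.int(k, 1L), integer(1))
    evaluate <- function(actions) {
      mismatches <- sum(actions != peak)
      0.5^mismatches
    }
    known_optimum <- peak
  }
  env <- list(evaluate = evaluate, n_automata = n_automata,
              n_actions = n_actions, known_optimum = known_optimum,
              optimum_quality = evaluate(known_optimum),
              structure = structure)
  class(env) <- "oracle_environment"
  env
}

#' Enumerate every joint quality of an oracle environment
#'
#' Exhaustive evaluation of the full joint table; used to verify that the
#' recorded optimum really is the argmax and as a brute-force baseline for
#' search tests.
#'
#' @param env an [make_oracle_table()] environment.
#' @return A data.frame with one row per joint action: columns `a1..an` and
#'   `quality`.
#' @export
enumerate_oracle <- function(env) {
  stopifnot(inherits(env, "oracle_environment"))
  grid <- do.call(expand.grid, lapply(env$n_actions, seq_len))
  names(grid) <- paste0("a", seq_len(env$n_automata))
  grid$quality <- apply(grid, 1L, function(r) env$evaluate(as.integer(r)))
  grid
}
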