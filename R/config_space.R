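#' The convolution-layer action space
#'
#' Every configurable convolution layer chooses one action
#' \eqn{\langle N, L, W \rangle}: the number of filters `N` (a multiple of 16
#' between 32 and 256, 15 values), the filter length `L` and the filter
#' width `W` (odd integers from 1 to 9, 5 values each).  The space therefore
#' has 15 x 5 x 5 = 375 actions.  The enumeration order is frozen:
#' `n_filters` major, then `length`, then `width`, so index 1 is
#' \eqn{\langle 32, 1, 1 \rangle} and index 375 is
#' \eqn{\langle 256, 9, 9 \rangle}.
#'
#' @return A data.frame with 375 rows and columns `n_filters`,
#'   `filter_length`, `filter_width`, in the canonical order.
#' @examples
#' nrow(conv_action_space())  # 375
#' @export
conv_action_space <- function() {
  grid <- expand.grid(
    filter_width = seq(1L, 9L, by = 2L),
    filter_length = seq(1L, 9L, by = 2L),
    n_filters = seq(32L, 256L, by = 16L),
    KEEP.OUT.ATTRS = FALSE
  )
  grid[, c("n_filters", "filter_length", "filter_width")]
}

n_conv_actions <- function() 375L

#' Decode / encode convolution actions
#'
#' `decode_conv_action()` maps a 1-based action index to its
#' \eqn{\langle N, L, W \rangle} triple; `encode_conv_action()` is the
#' inverse.  The two form a bijection over all 375 actions under the frozen
#' ordering documented in [conv_action_space()].
#'
#' @param index action index in 1..375.
#' @return `decode_conv_action()`: a list with `n_filters`, `filter_length`,
#'   `filter_width`; `encode_conv_action()`: the integer index.
#' @examples
#' decode_conv_action(1)    # <32, 1, 1>
#' decode_conv_action(375)  # <256, 9, 9>
#' @export
decode_conv_action <- function(index) {
  if (length(index) != 1L || is.na(index) || index != round(index) ||
      index < 1 || index > 375) {
    stop("conv action index must be a single integer in [1, 375], got ",
         index, call. = FALSE)
  }
  i <- as.integer(index) - 1L
  list(
    n_filters = 32L + 16L * (i %/% 25L),
    filter_length = 1L + 2L * ((i %/% 5L) %% 5L),
    filter_width = 1L + 2L * (i %% 5L)
  )
}

#' @rdname decode_conv_action
#' @param n_filters,filter_length,filter_width a valid action triple.
#' @export
encode_conv_action <- function(n_filters, filter_length, filter_width) {
  if (!(n_filters %in% seq(32L, 256L, by = 16L))) {
    stop("`n_filters` must be a multiple of 16 in [32, 256]", call. = FALSE)
  }
  if (!(filter_length %in% c(1L, 3L, 5L, 7L, 9L))) {
    stop("`filter_length` must be an odd integer in [1, 9]", call. = FALSE)
  }
  if (!(filter_width %in% c(1L, 3L, 5L, 7L, 9L))) {
    stop("`filter_width` must be an odd integer in [1, 9]", call. = FALSE)
  }
  as.integer((n_filters - 32L) / 16L * 25L +
               (filter_length - 1L) / 2L * 5L +
               (filter_width - 1L) / 2L + 1L)
}

#' Pooling actions
#'
#' The two searchable encoder pooling stages each choose between max pooling
#' (code 0) and average pooling (code 1).
#'
#' @param code integer 0 (max) or 1 (average).
#' @return The pooling kind as a string, `"max"` or `"average"`.
#' @export
decode_pooling_action <- function(code) {
  if (!(length(code) == 1L && code %in% c(0, 1))) {
    stop("pooling action code must be 0 (max) or 1 (average)", call. = FALSE)
  }
  c("max", "average")[as.integer(code) + 1L]
}

#' Assemble a network configuration genotype
#'
#' A network configuration is the joint choice of all 21 automata: 19
#' convolution actions (18 dense-block convolutions plus the final feature
#' convolution before the class head) and 2 encoder pooling actions.  It
#' carries 19 x 3 + 2 = 59 scalar hyperparameters.
#'
#' @param conv_indices integer vector of 19 convolution action indices in
#'   1..375.
#' @param pooling_indices integer vector of 2 pooling codes in \{0, 1\}.
#' @return An object of class `network_configuration`: a list with
#'   `conv` (data.frame of 19 decoded actions), `conv_indices`,
#'   `pooling` (character vector of 2) and `pooling_indices`.
#' @examples
#' cfg <- assemble_configuration(rep(1, 19), c(0, 0))
#' n_hyperparameters(cfg)  # 59
#' @export
assemble_configuration <- function(conv_indices, pooling_indices) {
  if (length(conv_indices) != 19L) {
    stop("exactly 19 convolution action indices are required, got ",
         length(conv_indices), call. = FALSE)
  }
  if (length(pooling_indices) != 2L) {
    stop("exactly 2 pooling action indices are required, got ",
         length(pooling_indices), call. = FALSE)
  }
  actions <- lapply(conv_indices, decode_conv_action)
  pooling <- vapply(pooling_indices, decode_pooling_action, character(1))
  structure(
    list(
      conv = data.frame(
        n_filters = vapply(actions, `[[`, integer(1), "n_filters"),
        filter_length = vapply(actions, `[[`, integer(1), "filter_length"),
        filter_width = vapply(actions, `[[`, integer(1), "filter_width")
      ),
      conv_indices = as.integer(conv_indices),
      pooling = pooling,
      pooling_indices = as.integer(pooling_indices)
    ),
    class = "network_configuration"
  )
}

#' @export
print.network_configuration <- function(x, ...) {
  cat("<network_configuration> 19 conv actions + 2 pooling stages",
      "(59 scalar hyperparameters)\n")
  cat("  pooling:", paste(x$pooling, collapse = ", "), "\n")
  cat("  filters:", paste(x$conv$n_filters, collapse = " "), "\n")
  cat("  kernels:",
      paste(sprintf("%dx%d", x$conv$filter_length, x$conv$filter_width),
            collapse = " "), "\n")
  invisible(x)
}

#' Count the scalar hyperparameters of a configuration
#'
#' @param config a [assemble_configuration()] object.
#' @return The number of tunable scalars: 3 per convolution layer plus 1 per
#'   pooling stage (59 for every valid configuration).
#' @export
n_hyperparameters <- function(config) {
  stopifnot(inherits(config, "network_configuration"))
  3L * nrow(config$conv) + length(config$pooling)
}

#' Read and write the canonical configuration file
#'
#' The canonical interchange format between the search, the network builder
#' and the command line is a JSON document with the 19 decoded convolution
#' actions and the 2 pooling kinds.  The round trip is lossless.
#'
#' @param config a [assemble_configuration()] object.
#' @param path file to write to / read from.
#' @return `write_configuration()` returns `path` invisibly;
#'   `read_configuration()` returns the `network_configuration`.
#' @export
write_configuration <- function(config, path) {
  stopifnot(inherits(config, "network_configuration"))
  doc <- list(
    conv_layers = config$conv,
    conv_indices = config$conv_indices,
    pooling = config$pooling
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_configuration
#' @export
read_configuration <- function(path) {
  doc <- jsonlite::fromJSON(path)
  conv_idx <- if (!is.null(doc$conv_indices)) {
    as.integer(doc$conv_indices)
  } else {
    mapply(encode_conv_action, doc$conv_layers$n_filters,
           doc$conv_layers$filter_length, doc$conv_layers$filter_width)
  }
  pool_idx <- match(doc$pooling, c("max", "average")) - 1L
  if (anyNA(pool_idx)) {
    stop("pooling entries must be 'max' or 'average'", call. = FALSE)
  }
  assemble_configuration(conv_idx, pool_idx)
}

#' Restrict the convolution action space for desk-scale experiments
#'
#' Returns the indices (into the full 375-action space) of all actions whose
#' filter count, length and width fall in the given sets.  Desk-scale
#' searches on a CPU run the automata over such a subspace; the encoding and
#' the network builder are unchanged.
#'
#' @param n_filters,filter_lengths,filter_widths admissible values; defaults
#'   give the full space.
#' @return An integer vector of action indices, in canonical order.
#' @export
conv_action_subspace <- function(n_filters = seq(32L, 256L, by = 16L),
                                 filter_lengths = c(1L, 3L, 5L, 7L, 9L),
                                 filter_widths = c(1L, 3L, 5L, 7L, 9L)) {
  space <- conv_action_space()
  idx <- which(space$n_filters %in% n_filters &
                 space$filter_length %in% filter_lengths &
                 space$filter_width %in% filter_widths)
  if (length(idx) < 1L) stop("empty action subspace", call. = FALSE)
  as.integer(idx)
}
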