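#' Read and write image volumes
#'
#' Volumes are exchanged as NIfTI files (`.nii` / `.nii.gz`; ANALYZE
#' `.hdr`/`.img` pairs are read through the same reader).  `read_volume()`
#' returns the voxel array together with the spacing taken from the header;
#' `write_volume()` writes an array with its spacing.  Spacing entries
#' missing from a header default to 1 mm.
#'
#' @param path file to read or write.
#' @return `read_volume()`: a list with `data` (numeric array) and
#'   `spacing` (mm per axis).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) {
    stop("no such file: ", path, call. = FALSE)
  }
  img <- tryCatch(RNifti::readNifti(path), error = function(e) {
    stop("unsupported or corrupt volume format in '", path, "': ",
         conditionMessage(e), call. = FALSE)
  })
  data <- as.array(img)
  pd <- RNifti::pixdim(img)
  spacing <- rep(1, length(dim(data)))
  n <- min(length(pd), length(spacing))
  spacing[seq_len(n)] <- ifelse(pd[seq_len(n)] > 0, pd[seq_len(n)], 1)
  list(data = data, spacing = spacing)
}

#' @rdname read_volume
#' @param data numeric or integer array to write.
#' @param spacing mm per axis (default 1).
#' @export
write_volume <- function(data, path, spacing = rep(1, length(dim(data)))) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label volume with validation
#'
#' Reads a volume and validates that it is integer-valued and
#' non-negative, naming offending values otherwise.
#'
#' @inheritParams read_volume
#' @param label_names optional label-name map passed to [label_volume()].
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, label_names = c(`1` = "CSF", `2` = "GM",
                                                    `3` = "WM")) {
  v <- read_volume(path)
  vals <- as.vector(v$data)
  bad <- vals[!is.finite(vals) | vals != round(vals) | vals < 0]
  if (length(bad) > 0L) {
    stop("'", path, "' is not a valid label volume; offending values: ",
         paste(utils::head(unique(bad), 5L), collapse = ", "),
         call. = FALSE)
  }
  label_volume(array(as.integer(v$data), dim(v$data)), spacing = v$spacing,
               label_names = label_names)
}

#' Export a phantom as NIfTI files
#'
#' Writes each modality and the label map of one phantom sample so the
#' command-line pipeline round-trips through the same readers used for
#' real data.
#'
#' @param sample one element of a [generate_dataset()] list.
#' @param prefix output path prefix; files `<prefix>_mod1.nii.gz`,
#'   `<prefix>_mod2.nii.gz`, ... and `<prefix>_labels.nii.gz` are written.
#' @return The written paths, invisibly.
#' @export
write_phantom <- function(sample, prefix) {
  M <- dim(sample$image)[1L]
  rank <- length(dim(sample$image)) - 1L
  spacing <- sample$labels$spacing
  paths <- character(0)
  for (m in seq_len(M)) {
    vol <- if (rank == 3L) sample$image[m, , , ] else sample$image[m, , ]
    p <- paste0(prefix, "_mod", m, ".nii.gz")
    write_volume(vol, p, spacing)
    paths <- c(paths, p)
  }
  p <- paste0(prefix, "_labels.nii.gz")
  write_volume(sample$labels$labels, p, spacing)
  invisible(c(paths, p))
}

#' Locate the command-line interface script
#'
#' The package ships a thin command-line wrapper (subcommands `phantom`,
#' `search`, `train`, `evaluate`) over the package functions.  Run it as
#' `Rscript $(Rscript -e 'cat(laseg::laseg_cli_path())') <subcommand> ...`.
#'
#' @return Absolute path of the installed CLI script.
#' @export
laseg_cli_path <- function() {
  system.file("cli", "laseg.R", package = "laseg", mustWork = TRUE)
}
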