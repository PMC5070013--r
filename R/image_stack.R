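#' Multi-channel 3D image stack
#'
#' Container for an anisotropic 3D voxel grid with one or more named
#' channels (e.g. a DNA counterstain plus a chromosome-paint or probe
#' channel) and a physical voxel size in micrometres per axis. All
#' physical measurements (volumes, distances) are derived from the voxel
#' size, so anisotropic z-sampling is handled transparently.
#'
#' @param channels named list of numeric 3D arrays, all the same dimension.
#' @param voxel_size numeric length-3, micrometres per voxel along (x, y, z).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, voxel_size) {
  if (!is.list(channels) || length(channels) == 0L ||
      is.null(names(channels)) || any(names(channels) == "")) {
    stop_("channels must be a non-empty named list of 3D arrays")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L)) {
    stop_("every channel must be a 3D array")
  }
  if (length(unique(lapply(dims, as.integer))) != 1L) {
    stop_("all channels must share the same dimensions")
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    stop_("voxel_size must be three positive values (um per axis)")
  }
  structure(list(channels = channels, voxel_size = voxel_size),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("image_stack: %d x %d x %d voxels, %d channel(s) [%s], voxel %s um\n",
              d[1L], d[2L], d[3L], length(x$channels),
              paste(names(x$channels), collapse = ", "),
              paste(format(x$voxel_size, digits = 3), collapse = " x ")))
  invisible(x)
}

stack_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "image_stack"))
  if (!channel %in% names(stack$channels)) {
    stop_(sprintf("channel '%s' not found (have: %s)", channel,
                  paste(names(stack$channels), collapse = ", ")))
  }
  stack$channels[[channel]]
}

# Physical (um) coordinates of voxel centers along each axis of a grid.
voxel_centers <- function(dims, voxel_size) {
  lapply(1:3, function(a) (seq_len(dims[a]) - 0.5) * voxel_size[a])
}
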