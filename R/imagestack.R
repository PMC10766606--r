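#' Multi-dimensional fluorescence image container
#'
#' Minimal container for 2-4D intensity data with physical calibration.
#' The array layout is declared by `axes`, a string naming one letter per
#' array dimension, in order: `x`, `y` (spatial, mandatory, first two),
#' then any of `z` (axial slice), `f` (raw repeat frame within a
#' timepoint), `t` (time), `c` (channel, last when present).
#'
#' @param data non-negative numeric array; `dim(data)` must match `axes`.
#' @param axes character scalar, e.g. `"xyzc"`, `"xyt"`, `"xyft"`.
#' @param voxel_size numeric length-3, physical voxel pitch (x, y, z) in
#'   nanometres; all entries must be positive. For 2D data the z entry is
#'   the optical slice thickness (or 1 if meaningless).
#' @param frame_interval seconds between successive time frames (0 for
#'   single-timepoint data).
#' @param channel_names character vector naming the channel axis (length
#'   must equal the channel dimension; `NULL` when there is no channel
#'   axis).
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(data, axes, voxel_size = c(40, 40, 800),
                        frame_interval = 0, channel_names = NULL) {
  stopifnot(is.numeric(data), is.character(axes), length(axes) == 1L)
  ax <- strsplit(axes, "")[[1]]
  d <- dim(data)
  if (is.null(d)) d <- length(data)
  if (length(d) != length(ax))
    stop("dim(data) has ", length(d), " axes but `axes` declares ", length(ax))
  if (!identical(ax[1:2], c("x", "y")))
    stop("axes must start with 'xy'")
  if (anyDuplicated(ax)) stop("duplicated axis letter in `axes`")
  if (!all(ax %in% c("x", "y", "z", "f", "t", "c")))
    stop("unknown axis letter in `axes`")
  if (min(data, na.rm = TRUE) < 0) stop("intensities must be non-negative")
  if (length(voxel_size) != 3 || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive numbers (x, y, z) in nm")
  if ("c" %in% ax) {
    nc <- d[match("c", ax)]
    if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
    if (length(channel_names) != nc)
      stop("channel_names length must equal the channel dimension")
  }
  structure(list(data = data, axes = axes,
                 voxel_size = as.numeric(voxel_size),
                 frame_interval = as.numeric(frame_interval),
                 channel_names = channel_names),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat("<image_stack> axes:", x$axes,
      " dim:", paste(dim(x$data), collapse = "x"), "\n")
  cat("  voxel (nm):", paste(x$voxel_size, collapse = " x "),
      " frame interval (s):", x$frame_interval, "\n")
  if (!is.null(x$channel_names))
    cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

axis_index <- function(stack, letter) {
  match(letter, strsplit(stack$axes, "")[[1]])
}

#' Extract one channel of an image stack
#'
#' @param stack an [image_stack] with a channel axis.
#' @param channel channel name or index.
#' @return array with the channel axis dropped.
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "image_stack"))
  ci <- axis_index(stack, "c")
  if (is.na(ci)) stop("stack has no channel axis")
  if (is.character(channel)) {
    idx <- match(channel, stack$channel_names)
    if (is.na(idx)) stop("unknown channel: ", channel)
  } else idx <- as.integer(channel)
  nd <- length(dim(stack$data))
  args <- rep(list(quote(expr = )), nd)
  args[[ci]] <- idx
  out <- do.call(`[`, c(list(stack$data), args, list(drop = FALSE)))
  newd <- dim(out)[-ci]
  array(out, dim = newd)
}

#' Extract one time frame of an image stack
#'
#' @param stack an [image_stack] with a `t` axis.
#' @param t frame index (1-based).
#' @return array with the time axis dropped.
#' @export
get_frame <- function(stack, t) {
  stopifnot(inherits(stack, "image_stack"))
  ti <- axis_index(stack, "t")
  if (is.na(ti)) stop("stack has no time axis")
  nd <- length(dim(stack$data))
  args <- rep(list(quote(expr = )), nd)
  args[[ti]] <- as.integer(t)
  out <- do.call(`[`, c(list(stack$data), args, list(drop = FALSE)))
  array(out, dim = dim(out)[-ti])
}

#' Write an image stack to a multi-page TIFF with a JSON sidecar
#'
#' Pages enumerate all non-spatial dimensions in column-major order
#' (ImageJ-style: fastest over z/f, then t, then c). Intensities are
#' written as 32-bit floats; calibration and axis metadata go to
#' `<path>.json`.
#'
#' @param stack an [image_stack].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  npage <- prod(d[-(1:2)])
  scale <- max(stack$data, 1)
  flat <- array(stack$data / scale, dim = c(d[1], d[2], npage))
  # tiff wants row-major matrices (y rows) with values in [0, 1]
  pages <- lapply(seq_len(npage), function(i) t(flat[, , i]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(axes = stack$axes, dim = d,
               intensity_scale = scale,
               voxel_size_nm = stack$voxel_size,
               frame_interval_s = stack$frame_interval,
               channel_names = stack$channel_names)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' @param path TIFF path with an accompanying `<path>.json` sidecar.
#' @return an [image_stack].
#' @export
read_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- as.integer(meta$dim)
  scale <- if (is.null(meta$intensity_scale)) 1 else meta$intensity_scale
  flat <- array(0, dim = c(d[1], d[2], length(pages)))
  for (i in seq_along(pages)) flat[, , i] <- t(pages[[i]]) * scale
  image_stack(array(flat, dim = d), axes = meta$axes,
              voxel_size = meta$voxel_size_nm,
              frame_interval = meta$frame_interval_s,
              channel_names = meta$channel_names)
}
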