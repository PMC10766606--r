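# Photoactivation compartment analysis: per-frame compartment length,
# ROI fluorescence time course, and the F_60min/F_5min stability index.
#
# Timebase: t = 0 at the first acquired frame; the photoactivation pulse
# is at `activation_frame` (default 7, i.e. 3 min at 30-s intervals), and
# "5 min postactivation" means 5 min after the activation frame.

frame_at_minutes_post <- function(activation_frame, minutes, frame_interval_s) {
  activation_frame + as.integer(round(minutes * 60 / frame_interval_s))
}

# 8-connectivity labeling of a 2D mask via the 3D labeller
label2d <- function(mask) {
  lab <- .cc_label_3d(as.vector(mask), c(dim(mask), 1L), 26L)
  array(lab, dim(mask))
}

# Length of one connected 2D component, in pixels.
# "skeleton": Zhang-Suen medial axis; path length from pixel adjacencies
#   (1 per orthogonal step, sqrt(2) per diagonal step) plus the local
#   radius (euclidean distance map) at each skeleton end point, so a
#   capsule of planted extent L measures L.
# "axis_extent": extent of the voxel centres projected on the principal
#   axis, plus one pixel (straight compartments only).
component_length_px <- function(mask, method = c("skeleton", "axis_extent")) {
  method <- match.arg(method)
  if (!any(mask)) return(0)
  if (method == "axis_extent") {
    xy <- which(mask, arr.ind = TRUE)
    if (nrow(xy) == 1) return(1)
    xy <- sweep(xy, 2, colMeans(xy))
    v <- svd(xy, nu = 0, nv = 1)$v[, 1]
    proj <- xy %*% v
    return(diff(range(proj)) + 1)
  }
  skel <- .thin_2d(mask)
  pts <- which(skel, arr.ind = TRUE)
  if (nrow(pts) == 0) return(1)
  dmap <- EBImage::distmap(mask * 1)
  if (nrow(pts) == 1) return(2 * dmap[pts])
  # adjacency path length: each neighbouring skeleton pair counted once
  key <- pts[, 1] + 1i * pts[, 2]
  len <- 0
  set <- new.env(hash = TRUE)
  for (i in seq_len(nrow(pts)))
    assign(as.character(key[i]), i, envir = set)
  offs <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  for (i in seq_len(nrow(pts))) {
    for (k in 1:4) {
      nb <- as.character((pts[i, 1] + offs[k, 1]) + 1i * (pts[i, 2] + offs[k, 2]))
      if (exists(nb, envir = set, inherits = FALSE))
        len <- len + sqrt(sum(offs[k, ]^2))
    }
  }
  # end points: skeleton pixels with exactly one skeleton neighbour
  nnb <- vapply(seq_len(nrow(pts)), function(i) {
    s <- 0L
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      nb <- as.character((pts[i, 1] + dx) + 1i * (pts[i, 2] + dy))
      if (exists(nb, envir = set, inherits = FALSE)) s <- s + 1L
    }
    s
  }, 0L)
  ends <- which(nnb <= 1)
  len + sum(dmap[pts[ends, , drop = FALSE]])
}

#' Per-frame photoactivated compartment length
#'
#' For each post-activation frame, thresholds the (max-projected) frame,
#' keeps the suprathreshold components descending from the activation
#' region (tracked by spatial overlap with the previous frame's
#' component set), and sums their medial-axis lengths.
#'
#' @param timelapse an [image_stack] with axes `"xyt"` (or `"xyzt"`,
#'   max-projected over z).
#' @param threshold manual intensity threshold separating photoactivated
#'   signal from background.
#' @param activation_frame frame index of the photoactivation pulse.
#' @param min_size minimum component size in pixels.
#' @param method `"skeleton"` (medial axis plus end-point radii) or
#'   `"axis_extent"` (principal-axis extent; straight compartments).
#' @param presmooth_sigma Gaussian prefilter sigma in pixels applied
#'   before thresholding (0 disables); smooth masks keep the medial axis
#'   free of noise spurs.
#' @return numeric vector of lengths in micrometres, one per frame
#'   (0 before activation).
#' @export
compartment_length_series <- function(timelapse, threshold,
                                      activation_frame = 7, min_size = 10,
                                      method = c("skeleton", "axis_extent"),
                                      presmooth_sigma = 1) {
  method <- match.arg(method)
  stopifnot(inherits(timelapse, "image_stack"))
  ti <- axis_index(timelapse, "t")
  if (is.na(ti)) stop("timelapse must have a time axis")
  nt <- dim(timelapse$data)[ti]
  if (nt < activation_frame) stop("timelapse has fewer frames than activation_frame")
  px_um <- timelapse$voxel_size[1] / 1000
  lengths <- numeric(nt)
  prev <- NULL
  seen_any <- FALSE
  for (j in seq_len(nt)) {
    if (j < activation_frame) next
    fr <- get_frame(timelapse, j)
    if (length(dim(fr)) == 3) fr <- apply(fr, c(1, 2), max)
    if (presmooth_sigma > 0) fr <- EBImage::gblur(fr, sigma = presmooth_sigma)
    mask <- fr >= threshold
    lab <- label2d(mask)
    if (max(lab) > 0 && min_size > 1) {
      sizes <- tabulate(lab)
      mask <- lab > 0 & sizes[pmax(lab, 1)] >= min_size
      lab <- label2d(mask)
    }
    if (max(lab) == 0) { prev <- NULL; next }
    keep <- if (is.null(prev)) seq_len(max(lab)) else
      sort(unique(lab[prev & lab > 0]))
    if (!length(keep)) { prev <- NULL; next }
    sel <- array(lab %in% keep, dim(lab))
    total <- 0
    for (k in keep)
      total <- total + component_length_px(lab == k, method)
    lengths[j] <- total * px_um
    prev <- sel
    seen_any <- TRUE
  }
  if (!seen_any)
    warning("no suprathreshold signal after activation; zero-length series")
  lengths
}

#' Union-across-time compartment length
#'
#' Alternative compartment-length readout: the suprathreshold footprint
#' is accumulated over all post-activation frames (temporal maximum
#' projection) and the medial-axis length of that union is measured once.
#' For an immobile compartment this equals the per-frame length; for a
#' motile one it measures the territory the compartment visited.
#'
#' @inheritParams compartment_length_series
#' @return length in micrometres (scalar).
#' @export
compartment_length_union <- function(timelapse, threshold,
                                     activation_frame = 7, min_size = 10,
                                     method = c("skeleton", "axis_extent"),
                                     presmooth_sigma = 1) {
  method <- match.arg(method)
  stopifnot(inherits(timelapse, "image_stack"))
  ti <- axis_index(timelapse, "t")
  if (is.na(ti)) stop("timelapse must have a time axis")
  nt <- dim(timelapse$data)[ti]
  if (nt < activation_frame) stop("timelapse has fewer frames than activation_frame")
  px_um <- timelapse$voxel_size[1] / 1000
  mask <- NULL
  for (j in activation_frame:nt) {
    fr <- get_frame(timelapse, j)
    if (length(dim(fr)) == 3) fr <- apply(fr, c(1, 2), max)
    if (presmooth_sigma > 0) fr <- EBImage::gblur(fr, sigma = presmooth_sigma)
    m <- fr >= threshold
    mask <- if (is.null(mask)) m else (mask | m)
  }
  lab <- label2d(mask)
  if (max(lab) > 0 && min_size > 1) {
    sizes <- tabulate(lab)
    mask <- lab > 0 & sizes[pmax(lab, 1)] >= min_size
    lab <- label2d(array(mask, dim(lab)))
  }
  if (max(lab) == 0) {
    warning("no suprathreshold signal after activation")
    return(0)
  }
  total <- 0
  for (k in seq_len(max(lab)))
    total <- total + component_length_px(lab == k, method)
  total * px_um
}

#' ROI fluorescence time course of a photoactivated compartment
#'
#' Fixes an ROI at the compartment's footprint 5 min post-activation and
#' measures its background-subtracted mean intensity in every frame.
#' Background is the per-frame median of an annulus around the ROI
#' (between dilations of the ROI), outside the compartment.
#'
#' @param timelapse an [image_stack] with axes `"xyt"`.
#' @param threshold intensity threshold defining the compartment footprint.
#' @param activation_frame frame index of the photoactivation pulse.
#' @param roi `"auto"` (footprint at 5 min post-activation) or a logical
#'   matrix.
#' @param annulus_px inner/outer dilation radii (pixels) of the
#'   background annulus.
#' @return a [compartment_trace].
#' @export
roi_fluorescence_series <- function(timelapse, threshold,
                                    activation_frame = 7, roi = "auto",
                                    annulus_px = c(8, 16)) {
  stopifnot(inherits(timelapse, "image_stack"))
  ti <- axis_index(timelapse, "t")
  if (is.na(ti)) stop("timelapse must have a time axis")
  nt <- dim(timelapse$data)[ti]
  dt_s <- timelapse$frame_interval
  f5 <- frame_at_minutes_post(activation_frame, 5, dt_s)
  f60 <- frame_at_minutes_post(activation_frame, 60, dt_s)
  if (f5 > nt) stop("timelapse ends before 5 min post-activation")

  proj <- function(j) {
    fr <- get_frame(timelapse, j)
    if (length(dim(fr)) == 3) fr <- apply(fr, c(1, 2), max)
    fr
  }
  if (identical(roi, "auto")) {
    roi_mask <- proj(f5) >= threshold
    if (!any(roi_mask)) stop("no suprathreshold signal at the 5-min frame")
  } else {
    roi_mask <- roi
    stopifnot(is.logical(roi_mask), any(roi_mask))
  }
  mkbrush <- function(r) EBImage::makeBrush(2 * r + 1, "disc")
  inner <- EBImage::dilate(roi_mask * 1, mkbrush(annulus_px[1])) > 0
  outer_m <- EBImage::dilate(roi_mask * 1, mkbrush(annulus_px[2])) > 0
  annulus <- outer_m & !inner
  if (!any(annulus)) stop("background annulus is empty; shrink the ROI")

  f <- vapply(seq_len(nt), function(j) {
    fr <- proj(j)
    mean(fr[roi_mask]) - median(fr[annulus])
  }, 0)
  times_min <- (seq_len(nt) - 1) * dt_s / 60
  compartment_trace(times = times_min, roi_fluorescence = f,
                    activation_frame = activation_frame,
                    F_5min = f[f5],
                    F_60min = if (f60 <= nt) f[f60] else NA_real_,
                    lengths = NULL)
}

#' Photoactivated-compartment trace container
#'
#' @param times frame times in minutes (t = 0 at the first frame).
#' @param roi_fluorescence background-subtracted ROI intensity per frame.
#' @param activation_frame activation frame index.
#' @param F_5min,F_60min ROI fluorescence 5 and 60 min post-activation.
#' @param lengths optional per-frame compartment lengths, um.
#' @return a `compartment_trace`.
#' @export
compartment_trace <- function(times, roi_fluorescence, activation_frame,
                              F_5min, F_60min, lengths = NULL) {
  stopifnot(length(times) == length(roi_fluorescence),
            !is.unsorted(times, strictly = TRUE))
  if (!is.null(lengths) && any(lengths < 0)) stop("lengths must be >= 0")
  structure(list(times = times, roi_fluorescence = roi_fluorescence,
                 activation_frame = activation_frame,
                 F_5min = F_5min, F_60min = F_60min, lengths = lengths),
            class = "compartment_trace")
}

#' @export
print.compartment_trace <- function(x, ...) {
  cat("<compartment_trace>", length(x$times), "frames, activation at frame",
      x$activation_frame, "\n")
  cat("  F_5min:", signif(x$F_5min, 5), " F_60min:", signif(x$F_60min, 5), "\n")
  if (!is.na(x$F_5min) && !is.na(x$F_60min) && x$F_5min > 0)
    cat("  stability index:", signif(x$F_60min / x$F_5min, 5), "\n")
  invisible(x)
}

#' Compartment stability index
#'
#' Ratio of the photoactivated-compartment fluorescence 60 min
#' post-activation to that 5 min post-activation (F_60min / F_5min).
#' Values near 1 indicate a spatially stable compartment; values well
#' below 1 indicate destabilization.
#'
#' @param trace a [compartment_trace] with positive `F_5min`.
#' @return the ratio (non-negative; fluorescence at 60 min is floored at
#'   zero).
#' @export
stability_index <- function(trace) {
  stopifnot(inherits(trace, "compartment_trace"))
  if (is.na(trace$F_5min) || trace$F_5min <= 0)
    stop("F_5min must be positive to define the stability index")
  if (is.na(trace$F_60min)) stop("trace does not reach 60 min post-activation")
  max(trace$F_60min, 0) / trace$F_5min
}
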