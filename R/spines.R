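# Spine structural plasticity morphometry: frame averaging and
# rolling-ball style background subtraction, Gaussian-FWHM spine-head
# width, plasticity time courses, clustered-plasticity distance binning,
# mitochondrial length/density binning, spine-actin center-of-mass
# displacement, and knockdown percentage.

#' Average raw frames and subtract background
#'
#' Averages `n_average` raw frames of one timepoint and removes the
#' smooth background with a rolling-ball style filter: the background is
#' the grayscale morphological opening with a disc of radius
#' `rolling_ball_radius` pixels, which is then subtracted.
#'
#' @param frames an [image_stack] with axes `"xyf"` (raw frames of one
#'   timepoint) or a 3D array (x, y, frame); a 2D matrix is treated as a
#'   single frame.
#' @param n_average number of frames to average (uses the first
#'   `n_average`).
#' @param rolling_ball_radius disc radius in pixels; 0 skips background
#'   subtraction.
#' @return background-subtracted 2D matrix.
#' @export
preprocess_timepoint <- function(frames, n_average = 10,
                                 rolling_ball_radius = 50) {
  arr <- if (inherits(frames, "image_stack")) frames$data else frames
  if (is.matrix(arr)) arr <- array(arr, c(dim(arr), 1L))
  stopifnot(length(dim(arr)) == 3)
  n_average <- min(n_average, dim(arr)[3])
  avg <- apply(arr[, , seq_len(n_average), drop = FALSE], c(1, 2), mean)
  if (rolling_ball_radius > 0) {
    r <- as.integer(rolling_ball_radius)
    brush <- EBImage::makeBrush(2 * r + 1, "disc")
    rng <- range(avg)
    if (diff(rng) > 0) {
      # EBImage grayscale morphology works on [0, 1]; rescale around it
      sc <- (avg - rng[1]) / diff(rng)
      bg01 <- EBImage::dilate(EBImage::erode(sc, brush), brush)
      avg <- pmax(avg - (rng[1] + bg01 * diff(rng)), 0)
    } else {
      avg <- avg - rng[1]
    }
  }
  avg
}

#' Spine-head width from a Gaussian fit (FWHM)
#'
#' Samples the intensity along a line through the spine-head centre,
#' fits a Gaussian with offset
#' `I(s) = A * exp(-(s - mu)^2 / (2 sigma^2)) + c`, and reports
#' `FWHM = 2 sqrt(2 ln 2) sigma`. The FWHM is independent of intensity
#' scale, so the width is robust to fluctuating indicator brightness.
#'
#' @param image 2D matrix (x, y), e.g. the output of
#'   [preprocess_timepoint()].
#' @param center line centre (x, y) in pixel coordinates.
#' @param direction line direction (x, y); need not be normalized.
#' @param length_um line length in micrometres.
#' @param pixel_size_um pixel pitch in micrometres.
#' @return list with `fwhm_um`, `sigma_um`, `mu_um`, `amplitude`,
#'   `offset`, `r_squared`, `valid` (FALSE on non-convergence or when the
#'   fitted sigma exceeds the line length) and `profile` (sampled
#'   positions/values).
#' @export
spine_head_width <- function(image, center, direction = c(1, 0),
                             length_um = 3, pixel_size_um = 0.1) {
  stopifnot(is.matrix(image), length(center) == 2)
  dirv <- direction / sqrt(sum(direction^2))
  half <- (length_um / pixel_size_um) / 2
  offs <- seq(-half, half, by = 1)
  xs <- center[1] + offs * dirv[1]
  ys <- center[2] + offs * dirv[2]
  ok <- xs >= 1 & xs <= nrow(image) & ys >= 1 & ys <= ncol(image)
  xs <- xs[ok]; ys <- ys[ok]; pos <- offs[ok] * pixel_size_um
  vals <- pracma::interp2(seq_len(ncol(image)), seq_len(nrow(image)),
                          image, ys, xs)
  if (length(vals) < 5 || max(vals) == min(vals))
    return(list(fwhm_um = NA_real_, sigma_um = NA_real_, valid = FALSE,
                profile = list(positions = pos, values = vals)))

  # moment-based initialization
  w <- pmax(vals - min(vals), 0)
  mu0 <- sum(pos * w) / sum(w)
  s0 <- sqrt(sum((pos - mu0)^2 * w) / sum(w))
  s0 <- min(max(s0, 0.5 * pixel_size_um), length_um)
  gauss_resid <- function(par) {
    par[1] * exp(-(pos - par[2])^2 / (2 * par[3]^2)) + par[4] - vals
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(A = max(vals) - min(vals), mu = mu0, s = s0, c0 = min(vals)),
      fn = gauss_resid,
      lower = c(0, min(pos), 0.5 * pixel_size_um, -Inf),
      upper = c(Inf, max(pos), length_um, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4)
    return(list(fwhm_um = NA_real_, sigma_um = NA_real_, valid = FALSE,
                profile = list(positions = pos, values = vals)))
  cf <- fit$par
  ss_res <- sum(gauss_resid(cf)^2)
  ss_tot <- sum((vals - mean(vals))^2)
  sigma <- unname(cf[["s"]])
  valid <- is.finite(sigma) && sigma < length_um
  list(fwhm_um = 2 * sqrt(2 * log(2)) * sigma,
       sigma_um = sigma, mu_um = unname(cf[["mu"]]),
       amplitude = unname(cf[["A"]]), offset = unname(cf[["c0"]]),
       r_squared = 1 - ss_res / ss_tot, valid = valid,
       profile = list(positions = pos, values = vals))
}

#' Spine record
#'
#' Per-spine bookkeeping for plasticity experiments: role, distance from
#' the plasticity-induced spine, and FWHM widths per timepoint.
#'
#' @param spine_id identifier.
#' @param role `"induced"`, `"adjacent"` or `"control_uninduced"`.
#' @param distance_from_induced distance in micrometres (0 for the
#'   induced spine).
#' @param widths FWHM per timepoint, micrometres (positive; `NA` for
#'   missed timepoints).
#' @param timepoints acquisition times in minutes.
#' @return a `spine_record` with `widths_norm = widths / widths[1]`.
#' @export
spine_record <- function(spine_id, role = c("induced", "adjacent",
                                            "control_uninduced"),
                         distance_from_induced, widths,
                         timepoints = c(0, 2, 12, 22, 32, 42, 52, 62)) {
  role <- match.arg(role)
  stopifnot(length(widths) == length(timepoints),
            distance_from_induced >= 0)
  if (any(widths <= 0, na.rm = TRUE)) stop("widths must be positive")
  if (is.na(widths[1])) stop("baseline (first timepoint) width is required")
  structure(list(spine_id = spine_id, role = role,
                 distance_from_induced = distance_from_induced,
                 widths = widths, widths_norm = widths / widths[1],
                 timepoints = timepoints),
            class = "spine_record")
}

#' Group plasticity time course
#'
#' Mean normalized spine-head width (width / baseline width) per
#' timepoint with SEM and per-timepoint n. Spines missing a timepoint are
#' excluded from that timepoint's mean.
#'
#' @param records list of [spine_record]s sharing the same timepoints.
#' @return data.frame with `time_min`, `mean_norm`, `sem`, `n`.
#' @export
plasticity_time_course <- function(records) {
  stopifnot(length(records) >= 1)
  tp <- records[[1]]$timepoints
  for (r in records)
    if (!identical(r$timepoints, tp)) stop("records have differing timepoints")
  m <- do.call(rbind, lapply(records, function(r) r$widths_norm))
  data.frame(
    time_min = tp,
    mean_norm = apply(m, 2, function(v) mean(v, na.rm = TRUE)),
    sem = apply(m, 2, function(v) {
      v <- v[!is.na(v)]
      if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
    }),
    n = apply(m, 2, function(v) sum(!is.na(v))))
}

#' Bin adjacent spines by distance from the induced spine
#'
#' The induced spine forms its own "0" bin; adjacent spines are assigned
#' to right-closed distance bins (0, 15], (15, 30], (30, 45] micrometres
#' (so a spine at exactly 15 um falls in the first adjacent bin). Spines
#' beyond the last edge are excluded with a warning. For each bin the
#' normalized width change at the requested timepoints is summarized.
#'
#' @param records list of [spine_record]s.
#' @param bin_edges upper edges of the adjacent bins, micrometres.
#' @param at_times timepoints (minutes) to summarize.
#' @return data.frame with one row per bin x timepoint: `bin`,
#'   `time_min`, `mean_norm`, `sem`, `n`.
#' @export
bin_adjacent_spines <- function(records, bin_edges = c(15, 30, 45),
                                at_times = c(2, 62)) {
  stopifnot(length(records) >= 1, all(diff(bin_edges) > 0))
  tp <- records[[1]]$timepoints
  labels <- c("0", paste0("(", c(0, head(bin_edges, -1)), ",", bin_edges, "]"))
  assign_bin <- function(r) {
    if (r$role == "induced" || r$distance_from_induced == 0) return(1L)
    d <- r$distance_from_induced
    k <- which(d <= bin_edges)[1]
    if (is.na(k)) NA_integer_ else k + 1L
  }
  bins <- vapply(records, assign_bin, 0L)
  if (any(is.na(bins))) {
    warning(sum(is.na(bins)), " spine(s) beyond ", max(bin_edges),
            " um excluded")
  }
  out <- list()
  for (b in seq_along(labels)) {
    rs <- records[which(bins == b)]
    for (t in at_times) {
      ti <- match(t, tp)
      if (is.na(ti)) stop("timepoint ", t, " not in records")
      v <- vapply(rs, function(r) r$widths_norm[ti], 0)
      v <- v[!is.na(v)]
      out[[length(out) + 1]] <- data.frame(
        bin = labels[b], time_min = t,
        mean_norm = if (length(v)) mean(v) else NA_real_,
        sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
        n = length(v))
    }
  }
  do.call(rbind, out)
}

#' Mitochondrial trace
#'
#' A manually traced mitochondrion as a polyline along the dendrite.
#'
#' @param vertices n x 2 matrix of (position-along-dendrite, offset)
#'   coordinates in micrometres, or a numeric vector of positions for a
#'   straight trace.
#' @param partial was the mitochondrion truncated at the field edge? Its
#'   length is still included as the minimal measurable length.
#' @return a `mito_trace` with arc `length` in micrometres.
#' @export
mito_trace <- function(vertices, partial = FALSE) {
  if (is.null(dim(vertices))) vertices <- cbind(vertices, 0)
  vertices <- as.matrix(vertices)
  stopifnot(nrow(vertices) >= 2, ncol(vertices) == 2)
  len <- sum(sqrt(rowSums(diff(vertices)^2)))
  if (len <= 0) stop("trace has zero length")
  structure(list(vertices = vertices, length = len, partial = partial),
            class = "mito_trace")
}

#' Mitochondrial density in distance bins around a spine
#'
#' Partitions the dendrite into `segment_length`-micrometre bins on
#' either side of the spine (out to `max_distance`) and reports, per bin
#' and side, the summed in-bin mitochondrial trace length divided by the
#' segment length. Traces spanning a bin boundary contribute exactly
#' their in-bin portion, so summed binned length equals total in-range
#' length.
#'
#' @param traces list of [mito_trace]s; the first vertex column is the
#'   signed position along the dendrite relative to `spine_position`.
#' @param spine_position position of the spine along the dendrite, um.
#' @param segment_length bin width, um.
#' @param max_distance analysis range on either side, um.
#' @return data.frame with `side` ("left"/"right"), `bin`
#'   (e.g. "0-15"), `mito_length_um`, `density`.
#' @export
mito_density <- function(traces, spine_position = 0, segment_length = 15,
                         max_distance = 45) {
  stopifnot(segment_length > 0, max_distance >= segment_length)
  edges <- seq(0, max_distance, by = segment_length)
  n_bin <- length(edges) - 1
  acc <- matrix(0, nrow = 2, ncol = n_bin,
                dimnames = list(c("left", "right"), NULL))
  for (tr in traces) {
    stopifnot(inherits(tr, "mito_trace"))
    v <- tr$vertices
    for (k in seq_len(nrow(v) - 1)) {
      p1 <- v[k, ]; p2 <- v[k + 1, ]
      seg_len <- sqrt(sum((p2 - p1)^2))
      if (seg_len == 0) next
      x1 <- p1[1] - spine_position; x2 <- p2[1] - spine_position
      for (side in 1:2) {
        s <- if (side == 1) -1 else 1
        for (b in seq_len(n_bin)) {
          lo <- edges[b]; hi <- edges[b + 1]
          # portion of the segment whose signed position s*x is in [lo, hi)
          a1 <- s * x1; a2 <- s * x2
          if (a1 > a2) { tmp <- a1; a1 <- a2; a2 <- tmp }
          ov <- max(0, min(a2, hi) - max(a1, lo))
          if (a2 > a1) {
            acc[side, b] <- acc[side, b] + seg_len * ov / (a2 - a1)
          } else if (a1 >= lo && a1 < hi) {
            # segment perpendicular to the dendrite axis: assign whole
            acc[side, b] <- acc[side, b] + seg_len
          }
        }
      }
    }
  }
  labs <- paste0(edges[-length(edges)], "-", edges[-1])
  data.frame(side = rep(c("left", "right"), each = n_bin),
             bin = rep(labs, 2),
             mito_length_um = c(acc[1, ], acc[2, ]),
             density = c(acc[1, ], acc[2, ]) / segment_length)
}

#' Center-of-mass displacement of a spine
#'
#' Intensity-weighted centroid per frame; returns the Euclidean distance
#' between the centroid at `t_final` minutes and the first frame - the
#' spine actin displacement readout.
#'
#' @param mask_series an [image_stack] with axes `"xyt"` covering one
#'   spine.
#' @param t_final time of the comparison frame, minutes.
#' @return displacement in micrometres.
#' @export
com_displacement <- function(mask_series, t_final = 2) {
  stopifnot(inherits(mask_series, "image_stack"))
  ti <- axis_index(mask_series, "t")
  if (is.na(ti)) stop("series must have a time axis")
  nt <- dim(mask_series$data)[ti]
  dt_min <- mask_series$frame_interval / 60
  jf <- if (dt_min > 0) round(t_final / dt_min) + 1 else nt
  jf <- min(max(jf, 1), nt)
  px_um <- mask_series$voxel_size[1:2] / 1000
  com <- function(j) {
    fr <- get_frame(mask_series, j)
    while (length(dim(fr)) > 2) fr <- apply(fr, c(1, 2), max)
    w <- sum(fr)
    if (w == 0) stop("empty frame: center of mass undefined")
    c(sum(row(fr) * fr), sum(col(fr) * fr)) / w
  }
  d_px <- com(jf) - com(1)
  sqrt(sum((d_px * px_um)^2))
}

#' Knockdown percentage from soma fluorescence
#'
#' Mean background-subtracted fluorescence of transfected somas divided
#' by that of untransfected somas in the same field
#' (F_trans / F_untrans); 1 means no knockdown, 0.3 means a 70 percent
#' reduction.
#'
#' @param F_trans,F_untrans numeric vectors of soma intensities
#'   (background subtracted).
#' @return the ratio.
#' @export
knockdown_percentage <- function(F_trans, F_untrans) {
  if (!length(F_trans) || !length(F_untrans))
    stop("both intensity lists must be nonempty")
  m_un <- mean(F_untrans)
  if (m_un <= 0) stop("untransfected mean must be positive")
  mean(F_trans) / m_un
}
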