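# Synthetic data generators with planted ground truth.
#
# Each generator emulates one input modality of the quantification suite
# and records the *realized* planted values (what was actually drawn), so
# recovery tests compare estimates against the truth of the instance, not
# the nominal request. All generators are deterministic in (params, seed).

# Shared noise model: Poisson shot noise on (signal + background) plus
# additive Gaussian read noise. snr is defined as
# (peak signal - background) / sd(background), with
# sd(background) = sqrt(background + read_sd^2).
noise_sd_bg <- function(background, read_sd) sqrt(background + read_sd^2)

apply_noise <- function(signal, snr, background, read_sd) {
  img <- signal + background
  if (!is.finite(snr)) return(img)
  noisy <- rpois(length(img), lambda = as.vector(img)) +
    rnorm(length(img), 0, read_sd)
  out <- array(pmax(noisy, 0), dim = dim(img))
  out
}

signal_amplitude <- function(snr, background = 10, read_sd = 2) {
  if (!is.finite(snr)) return(100)
  snr * noise_sd_bg(background, read_sd)
}

#' Synthesize a two-channel 3D dendrite stack with planted colocalization
#'
#' Renders `n_mito` elongated mitochondria (capsules with hemispherical
#' caps, anisotropic in z) along a straight horizontal dendrite in channel
#' `"mito"`, and actin-interaction patches in channel `"actin"` covering a
#' planted fraction of the mitochondrial voxel volume. The ground truth
#' records the exact realized overlapping voxel count (brute-force count
#' of the noiseless masks), together with both masks.
#'
#' @param overlap_fraction fraction (0-1) of mitochondrial voxel volume
#'   covered by actin patches.
#' @param n_mito number of mitochondria.
#' @param snr peak-signal-to-background-noise ratio; `Inf` for noiseless.
#' @param voxel_size (x, y, z) voxel pitch in nm.
#' @param dims array dimensions (nx, ny, nz).
#' @param seed integer seed.
#' @return list with `stack` (an [image_stack], channels `mito`, `actin`)
#'   and `truth` (a [ground_truth] with `overlap_voxels`, `mito_voxels`,
#'   `overlap_pct`, and the noiseless masks `mito_mask`, `actin_mask`).
#' @export
gen_two_channel_stack <- function(overlap_fraction, n_mito = 3, snr = 10,
                                  voxel_size = c(40, 40, 800),
                                  dims = c(384, 48, 7), seed = 1) {
  assert_scalar_finite(overlap_fraction, "overlap_fraction", 0, 1)
  assert_scalar_finite(n_mito, "n_mito", 1)
  if (!is.numeric(snr) || length(snr) != 1L || is.na(snr) || snr <= 0)
    stop("`snr` must be a positive number (Inf for noiseless)")
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size must be positive and finite")
  dims <- as.integer(dims)
  r_xy_nm <- 500; r_z_nm <- 1200
  r_px <- r_xy_nm / voxel_size[1]
  min_len_px <- ceiling(2000 / voxel_size[1])  # shortest mitochondrion, 2 um
  if (dims[1] < (min_len_px + 2 * r_px) * n_mito || dims[2] < 2 * r_px + 8 ||
      dims[3] < 1)
    stop("image dimensions too small to place ", n_mito, " mitochondria")

  with_seed(seed, {
    nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
    y_mid <- (ny + 1) / 2; z_mid <- (nz + 1) / 2
    mito <- array(FALSE, dims)
    xs <- seq_len(nx); ys <- seq_len(ny); zs <- seq_len(nz)
    slot <- nx / n_mito
    capsule_ids <- vector("list", n_mito)
    for (i in seq_len(n_mito)) {
      len_nm <- runif(1, 2000, 4000)
      len_px <- len_nm / voxel_size[1]
      pad <- r_px + 1
      lo <- (i - 1) * slot + pad
      hi <- i * slot - pad - len_px
      x0 <- if (hi > lo) runif(1, lo, hi) else lo
      x1 <- x0 + len_px
      yc <- y_mid + runif(1, -3, 3)
      # capsule: anisotropic distance to the segment [x0,x1] at (yc, z_mid)
      dx <- outer(xs, rep(1, ny * nz))
      dim(dx) <- dims
      cx <- pmin(pmax(dx, x0), x1)
      ddx <- (dx - cx) * voxel_size[1]
      ddy <- aperm(array((ys - yc) * voxel_size[2], c(ny, nx, nz)), c(2, 1, 3))
      ddz <- aperm(array((zs - z_mid) * voxel_size[3], c(nz, nx, ny)), c(2, 3, 1))
      inside <- (ddx^2 + ddy^2) / r_xy_nm^2 + ddz^2 / r_z_nm^2 <= 1
      capsule_ids[[i]] <- which(inside & !mito)
      mito <- mito | inside
    }

    # actin patches: per capsule, a contiguous run (in x order) of exactly
    # round(f * V_i) voxels, dilated outward only (never into the
    # mitochondrial mask), so mito-and-actin overlap is the run itself.
    actin <- array(FALSE, dims)
    run_total <- 0L
    for (i in seq_len(n_mito)) {
      idx <- capsule_ids[[i]]
      if (!length(idx)) next
      coords <- arrayInd(idx, dims)
      ord <- order(coords[, 1], coords[, 2], coords[, 3])
      k <- round(overlap_fraction * length(idx))
      if (k > 0) {
        start <- if (k < length(idx)) sample.int(length(idx) - k + 1, 1) else 1L
        run <- idx[ord[start:(start + k - 1)]]
        actin[run] <- TRUE
        run_total <- run_total + length(run)
      }
    }
    if (any(actin)) {
      # dilate by 1 voxel in xy to give patches an extra-mitochondrial rim
      kern <- EBImage::makeBrush(3, "box")
      for (z in seq_len(nz)) {
        dil <- EBImage::dilate(actin[, , z] * 1, kern) > 0
        actin[, , z] <- actin[, , z] | (dil & !mito[, , z])
      }
    }

    overlap_voxels <- sum(mito & actin)
    mito_voxels <- sum(mito)

    amp <- signal_amplitude(snr)
    background <- 10; read_sd <- 2
    ch_m <- apply_noise(mito * amp, snr, background, read_sd)
    ch_a <- apply_noise(actin * amp, snr, background, read_sd)
    data <- array(0, c(dims, 2))
    data[, , , 1] <- ch_m; data[, , , 2] <- ch_a
    stack <- image_stack(data, axes = "xyzc", voxel_size = voxel_size,
                         channel_names = c("mito", "actin"))
    truth <- ground_truth("stack", list(
      overlap_fraction = overlap_fraction,
      overlap_voxels = overlap_voxels,
      mito_voxels = mito_voxels,
      overlap_pct = if (mito_voxels > 0) 100 * overlap_voxels / mito_voxels else NA_real_,
      n_mito = n_mito, snr = if (is.finite(snr)) snr else -1,
      amplitude = amp, background = background,
      mito_mask = mito, actin_mask = actin), seed)
    list(stack = stack, truth = truth)
  })
}

#' Synthesize a photoactivation time-lapse with planted decay
#'
#' Emulates a mitochondrial-matrix photoactivation experiment: frames are
#' acquired every `frame_interval` seconds; the first six frames contain
#' background only, a photoactivation pulse at frame `7` switches on a
#' fluorescent compartment of the planted length, whose intensity then
#' decays as `exp(-loss_rate * t)` with `t` in minutes post-activation.
#' If `motile`, the compartment fragments into two halves and one half
#' translocates away.
#'
#' @param compartment_length planted length in micrometres.
#' @param loss_rate fluorescence loss rate per minute (>= 0).
#' @param motile should the compartment fragment and move?
#' @param n_frames number of frames (>= 14).
#' @param frame_interval seconds between frames.
#' @param snr peak-signal-to-background-noise ratio; `Inf` for noiseless.
#' @param pixel_size_nm lateral pixel pitch in nm.
#' @param seed integer seed.
#' @return list with `stack` ([image_stack], axes `"xyt"`) and `truth`
#'   (planted `length_um` as realized on the pixel grid, `loss_rate`,
#'   `activation_frame`, `amplitude`, `stability_55min` =
#'   `exp(-55 * loss_rate)`).
#' @export
gen_photoactivation_series <- function(compartment_length, loss_rate,
                                       motile = FALSE, n_frames = 141,
                                       frame_interval = 30, snr = 20,
                                       pixel_size_nm = 200, seed = 1) {
  assert_scalar_finite(compartment_length, "compartment_length", 0.5)
  if (!is.numeric(loss_rate) || length(loss_rate) != 1L || !is.finite(loss_rate) ||
      loss_rate < 0)
    stop("`loss_rate` must be a finite non-negative number")
  n_frames <- as.integer(n_frames)
  if (n_frames < 14) stop("need n_frames >= 14 (pre-activation frames plus decay)")
  activation_frame <- 7L
  px_um <- pixel_size_nm / 1000
  len_px <- max(2L, round(compartment_length / px_um))
  nx <- max(300L, len_px + 80L); ny <- 40L
  half_h <- 3L
  background <- 10; read_sd <- 2
  amp <- signal_amplitude(snr, background, read_sd)

  with_seed(seed, {
    yc <- ny %/% 2
    x0 <- (nx - len_px) %/% 2
    data <- array(0, c(nx, ny, n_frames))
    for (j in seq_len(n_frames)) {
      sig <- matrix(0, nx, ny)
      if (j >= activation_frame) {
        t_min <- (j - activation_frame) * frame_interval / 60
        a <- amp * exp(-loss_rate * t_min)
        if (!motile || j < activation_frame + 13L) {
          sig[x0:(x0 + len_px - 1), (yc - half_h):(yc + half_h)] <- a
        } else {
          # fragment into two halves; the right half drifts rightward
          l1 <- len_px %/% 2; l2 <- len_px - l1
          shift <- min((j - activation_frame - 12L) %/% 2L + 2L, nx - (x0 + len_px) - 2L)
          sig[x0:(x0 + l1 - 1), (yc - half_h):(yc + half_h)] <- a
          xb <- x0 + l1 + shift
          sig[xb:(xb + l2 - 1), (yc - half_h):(yc + half_h)] <- a
        }
      }
      data[, , j] <- apply_noise(sig, snr, background, read_sd)
    }
    stack <- image_stack(data, axes = "xyt",
                         voxel_size = c(pixel_size_nm, pixel_size_nm, 1000),
                         frame_interval = frame_interval)
    truth <- ground_truth("photoactivation", list(
      length_um = len_px * px_um,
      loss_rate = loss_rate,
      activation_frame = activation_frame,
      amplitude = amp, background = background,
      motile = as.numeric(motile),
      stability_55min = exp(-55 * loss_rate)), seed)
    list(stack = stack, truth = truth)
  })
}

#' Synthesize a dendritic-spine structural-plasticity time-lapse
#'
#' Renders a horizontal dendrite shaft plus one spine whose head is an
#' isotropic 2D Gaussian of width `base_sigma * (1 + growth_profile[i])`
#' at timepoint `i`, with `n_raw` raw frames per timepoint for frame
#' averaging. The head sits well away from the shaft so a horizontal line
#' through its centre yields a clean Gaussian profile.
#'
#' @param base_sigma baseline Gaussian sigma of the spine head, um.
#' @param growth_profile fractional sigma increase per timepoint (same
#'   length as `timepoints`); all zeros means no plasticity.
#' @param timepoints acquisition times in minutes.
#' @param n_raw raw frames per timepoint.
#' @param snr peak-signal-to-background-noise ratio; `Inf` for noiseless.
#' @param pixel_size_nm lateral pixel pitch in nm.
#' @param seed integer seed.
#' @return list with `stack` ([image_stack], axes `"xyft"`) and `truth`
#'   (exact `sigma_um` and `fwhm_um` per timepoint, head centre, line
#'   geometry for width fitting).
#' @export
gen_spine_timelapse <- function(base_sigma = 0.25,
                                growth_profile = rep(0, 8),
                                timepoints = c(0, 2, 12, 22, 32, 42, 52, 62),
                                n_raw = 10, snr = 10, pixel_size_nm = 100,
                                seed = 1) {
  assert_scalar_finite(base_sigma, "base_sigma", 1e-6)
  if (length(growth_profile) != length(timepoints))
    stop("growth_profile and timepoints must have equal length")
  if (any(!is.finite(growth_profile)) || any(growth_profile < -0.9))
    stop("growth_profile entries must be finite and > -0.9")
  px_um <- pixel_size_nm / 1000
  sigma_um <- base_sigma * (1 + growth_profile)
  if (any(sigma_um / px_um < 1))
    stop("spine-head sigma below 1 pixel; increase base_sigma or resolution")
  nx <- 128L; ny <- 96L
  head_c <- c(64, 64)       # pixels
  shaft_y <- 24; shaft_sd <- 3
  background <- 10; read_sd <- 2
  amp <- signal_amplitude(snr, background, read_sd)

  with_seed(seed, {
    xs <- seq_len(nx); ys <- seq_len(ny)
    shaft <- 0.6 * amp * outer(rep(1, nx), exp(-(ys - shaft_y)^2 / (2 * shaft_sd^2)))
    neck <- 0.3 * amp * outer(exp(-(xs - head_c[1])^2 / (2 * 1.5^2)),
                              as.numeric(ys > shaft_y & ys < head_c[2]) *
                                exp(-0.5))
    nt <- length(timepoints)
    data <- array(0, c(nx, ny, n_raw, nt))
    for (i in seq_len(nt)) {
      s_px <- sigma_um[i] / px_um
      head <- amp * outer(exp(-(xs - head_c[1])^2 / (2 * s_px^2)),
                          exp(-(ys - head_c[2])^2 / (2 * s_px^2)))
      sig <- shaft + neck + head
      for (f in seq_len(n_raw))
        data[, , f, i] <- apply_noise(sig, snr, background, read_sd)
    }
    stack <- image_stack(data, axes = "xyft",
                         voxel_size = c(pixel_size_nm, pixel_size_nm, 1000),
                         frame_interval = 0)
    truth <- ground_truth("spine", list(
      sigma_um = sigma_um,
      fwhm_um = 2 * sqrt(2 * log(2)) * sigma_um,
      timepoints_min = as.numeric(timepoints),
      head_center_px = head_c,
      amplitude = amp, background = background), seed)
    list(stack = stack, truth = truth)
  })
}

#' Synthesize a pair of correlated line profiles
#'
#' Two non-negative intensity profiles drawn from a bivariate Gaussian
#' model with population correlation `rho` (values are affine transforms
#' of standard bivariate normals; Pearson r is invariant to the
#' transform).
#'
#' @param length number of positions.
#' @param rho population correlation, in -1..1.
#' @param step_um spacing between positions, um.
#' @param seed integer seed.
#' @return list with `a`, `b` (objects of class `profile`) and `truth`
#'   (planted `rho` and realized sample correlation `sample_r`).
#' @export
gen_line_profile_pair <- function(length = 200, rho = 0, step_um = 0.208,
                                  seed = 1) {
  assert_scalar_finite(rho, "rho", -1, 1)
  length <- as.integer(length)
  if (length < 3) stop("profile length must be >= 3")
  with_seed(seed, {
    z1 <- rnorm(length)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(length)
    a <- pmax(100 + 15 * z1, 0)
    b <- pmax(100 + 15 * z2, 0)
    pos <- (seq_len(length) - 1) * step_um
    pa <- new_profile(pos, a, width_um = 3)
    pb <- new_profile(pos, b, width_um = 3)
    truth <- ground_truth("profile", list(
      profile_rho = rho, sample_r = cor(a, b)), seed)
    list(a = pa, b = pb, truth = truth)
  })
}

#' Synthesize proximity-proteomics replicate and control tables
#'
#' Builds three experiment replicates and two control tables with a
#' planted category structure: `n_true` proteins present in at least two
#' experiment replicates and in no control; `n_control_contaminants`
#' proteins present in at least one control (at arbitrary intensity) and
#' also in experiments; `n_singletons` proteins present in exactly one
#' replicate. The annotation database assigns GO terms, cytoskeletal
#' interactor sets (with planted `actin_only` / `tubulin_only` / `both`
#' counts plus mRNA-binder exclusions), and an iBAQ-like abundance table
#' for the soluble-proteome overlap.
#'
#' @param n_true planted consensus proteins.
#' @param n_control_contaminants proteins appearing in controls.
#' @param n_singletons proteins in exactly one replicate.
#' @param frac_go_mito fraction of true proteins GO-annotated
#'   "mitochondrion".
#' @param interactor_structure named counts
#'   `c(actin_only=, tubulin_only=, both=)` among the true proteins.
#' @param n_mrna_excluded true proteins placed in the actin interactor set
#'   but voided by the mRNA-binder exclusion list.
#' @param frac_soluble_top fraction of true proteins planted into the top
#'   200 most abundant soluble neuropil proteins.
#' @param frac_soluble_all fraction planted into the full soluble set
#'   (includes the top fraction).
#' @param seed integer seed.
#' @return list with `experiments` (3 [replicate_table]s), `controls`
#'   (2 [replicate_table]s), `db` (an [annotation_db]) and `truth` (all
#'   planted category sets).
#' @export
gen_proteomics_tables <- function(n_true = 129, n_control_contaminants = 40,
                                  n_singletons = 30, frac_go_mito = 0.2,
                                  interactor_structure = c(actin_only = 13,
                                                           tubulin_only = 1,
                                                           both = 5),
                                  n_mrna_excluded = 2,
                                  frac_soluble_top = 0.17,
                                  frac_soluble_all = 0.24,
                                  seed = 1) {
  stopifnot(n_true >= 0, n_control_contaminants >= 0, n_singletons >= 0)
  assert_scalar_finite(frac_go_mito, "frac_go_mito", 0, 1)
  ist <- interactor_structure
  need <- c("actin_only", "tubulin_only", "both")
  if (!all(need %in% names(ist))) stop("interactor_structure needs counts ",
                                       paste(need, collapse = ", "))
  if (sum(ist[need]) + n_mrna_excluded > n_true)
    stop("interactor structure larger than n_true")
  if (frac_soluble_all < frac_soluble_top)
    stop("frac_soluble_all must be >= frac_soluble_top")

  with_seed(seed, {
    n_all <- n_true + n_control_contaminants + n_singletons
    ids <- sprintf("PROT%04d", seq_len(n_all))
    true_ids <- head(ids, n_true)
    cont_ids <- ids[seq_len(n_control_contaminants) + n_true]
    sing_ids <- ids[seq_len(n_singletons) + n_true + n_control_contaminants]

    ri <- function() exp(rnorm(1, log(1e6), 1))
    exp_members <- list(character(0), character(0), character(0))
    for (p in true_ids) {
      k <- sample(2:3, 1)
      for (r in sample(1:3, k)) exp_members[[r]] <- c(exp_members[[r]], p)
    }
    for (p in cont_ids) {                       # contaminants look convincing
      k <- sample(2:3, 1)
      for (r in sample(1:3, k)) exp_members[[r]] <- c(exp_members[[r]], p)
    }
    for (p in sing_ids) {
      r <- sample(1:3, 1)
      exp_members[[r]] <- c(exp_members[[r]], p)
    }
    experiments <- lapply(1:3, function(r) {
      m <- sort(exp_members[[r]])
      replicate_table(sample_id = paste0("rep", r), role = "experiment",
                      protein_id = m,
                      intensity = vapply(m, function(.) ri(), 0))
    })
    # each contaminant lands in >= 1 control; trace intensities allowed
    keep1 <- cont_ids[runif(length(cont_ids)) < 0.7]
    keep2 <- union(cont_ids[runif(length(cont_ids)) < 0.7],
                   setdiff(cont_ids, keep1))
    controls <- lapply(1:2, function(cnum) {
      keep <- sort(if (cnum == 1) keep1 else keep2)
      replicate_table(sample_id = paste0("ctrl", cnum), role = "control",
                      protein_id = keep,
                      intensity = vapply(keep, function(.) {
                        if (runif(1) < 0.2) 1e-3 else ri()
                      }, 0))
    })

    # annotation structure over the true (consensus) proteins
    pool <- sample(true_ids)
    take <- function(n) {
      out <- head(pool, n)
      if (n > 0) pool <<- pool[-seq_len(min(n, length(pool)))]
      out
    }
    set_actin_only <- take(ist[["actin_only"]])
    set_tub_only <- take(ist[["tubulin_only"]])
    set_both <- take(ist[["both"]])
    set_mrna <- take(n_mrna_excluded)
    go_mito <- sample(true_ids, round(frac_go_mito * n_true))
    go_er <- sample(true_ids, round(0.14 * n_true))

    actin_interactors <- c(set_actin_only, set_both, set_mrna)
    tubulin_interactors <- c(set_tub_only, set_both)

    # soluble neuropil proteome with iBAQ-like log2 abundances
    n_top <- round(frac_soluble_top * n_true)
    n_all_sol <- round(frac_soluble_all * n_true)
    sol_true_top <- sample(true_ids, n_top)
    sol_true_rest <- sample(setdiff(true_ids, sol_true_top), n_all_sol - n_top)
    n_np <- 400
    np_ids <- sprintf("NP%04d", seq_len(n_np))
    membrane_np <- sample(np_ids, 80)
    soluble_np <- setdiff(np_ids, membrane_np)
    # abundances: planted-top true proteins drawn from the high tail so
    # they rank within the top 200 soluble entries
    ab <- c(
      setNames(rnorm(length(soluble_np), 25, 3), soluble_np),
      setNames(rnorm(length(membrane_np), 25, 3), membrane_np),
      setNames(rnorm(length(sol_true_top), 36, 0.5), sol_true_top),
      setNames(rnorm(length(sol_true_rest), 18, 0.5), sol_true_rest))

    db <- annotation_db(go_mito = go_mito, go_er = go_er,
                        go_membrane = membrane_np,
                        actin_interactors = actin_interactors,
                        tubulin_interactors = tubulin_interactors,
                        mrna_binder_exclusions = set_mrna,
                        abundance = ab)

    soluble_ids <- setdiff(names(ab), membrane_np)
    top200 <- names(sort(ab[soluble_ids], decreasing = TRUE))[
      seq_len(min(200, length(soluble_ids)))]
    truth <- ground_truth("proteome", list(
      true_set = sort(true_ids), contaminants = sort(cont_ids),
      singletons = sort(sing_ids),
      go_mito = sort(go_mito), go_er = sort(go_er),
      actin_only = sort(set_actin_only),
      tubulin_only = sort(set_tub_only),
      both = sort(set_both), mrna_excluded = sort(set_mrna),
      soluble_top_overlap = sort(intersect(true_ids, top200)),
      soluble_all_overlap = sort(intersect(true_ids, soluble_ids))), seed)
    list(experiments = experiments, controls = controls, db = db,
         truth = truth)
  })
}

#' Synthesize a calcium trace with planted transients
#'
#' Baseline-normalized fluorescence trace (raw units, baseline mean 100)
#' with `n_peaks` planted transients of known times and amplitudes in
#' dF/F0 units. Transients have a fast rise and exponential decay with the
#' maximum exactly at the planted frame; in the noiseless case the dF/F0
#' value at each planted frame equals the planted amplitude exactly.
#'
#' @param n_peaks number of transients.
#' @param peak_sign +1 for positive-going transients (e.g. mitochondrial
#'   calcium influx), -1 for negative (e.g. ER calcium release).
#' @param snr planted amplitude over baseline noise SD; `Inf` noiseless.
#' @param baseline_frames frames before induction (the F0 window).
#' @param n_frames total frames.
#' @param frame_interval_s seconds per frame.
#' @param seed integer seed.
#' @return list with `raw` (trace), `times_s`, `baseline_window`
#'   (indices), and `truth` (planted `peak_frames`, `peak_times_s`,
#'   `amplitudes` in dF/F0 units).
#' @export
gen_calcium_trace <- function(n_peaks = 3, peak_sign = 1, snr = 5,
                              baseline_frames = 30, n_frames = 180,
                              frame_interval_s = 1, seed = 1) {
  stopifnot(n_peaks >= 0, peak_sign %in% c(-1, 1))
  if (!is.numeric(snr) || snr <= 0) stop("snr must be positive")
  baseline_frames <- as.integer(baseline_frames)
  if (baseline_frames < 2) stop("need >= 2 baseline frames")
  if (n_frames <= baseline_frames + 25 && n_peaks > 0)
    stop("trace too short for the requested peaks")

  with_seed(seed, {
    spacing <- 20L
    post <- seq(baseline_frames + 8L, n_frames - 14L)
    peak_frames <- integer(0)
    if (n_peaks > 0) {
      cand <- post
      for (i in seq_len(n_peaks)) {
        if (!length(cand)) stop("cannot place ", n_peaks, " peaks with spacing ",
                                spacing, " in ", n_frames, " frames")
        p <- sample(cand, 1)
        peak_frames <- c(peak_frames, p)
        cand <- cand[abs(cand - p) >= spacing]
      }
      peak_frames <- sort(peak_frames)
    }
    # amplitudes < 1 so negative-going transients stay physical (raw > 0)
    amplitudes <- if (n_peaks > 0) runif(n_peaks, 0.4, 0.9) else numeric(0)

    dff <- numeric(n_frames)
    for (i in seq_along(peak_frames)) {
      p <- peak_frames[i]
      dt <- seq_len(n_frames) - p
      kern <- ifelse(dt < 0, exp(dt / 1.2), exp(-dt / 4))
      kern[dt < -6 | dt > 12] <- 0
      dff <- dff + amplitudes[i] * kern
    }
    dff <- peak_sign * dff
    if (is.finite(snr)) {
      # snr anchored to the weakest planted transient
      sigma <- min(if (length(amplitudes)) amplitudes else 1) / snr
      dff <- dff + rnorm(n_frames, 0, sigma)
    }
    F0 <- 100
    raw <- pmax(F0 * (1 + dff), 0)
    truth <- ground_truth("calcium", list(
      peak_frames = peak_frames,
      peak_times_s = (peak_frames - 1) * frame_interval_s,
      amplitudes = peak_sign * amplitudes,
      peak_sign = peak_sign,
      F0 = F0), seed)
    list(raw = raw, times_s = (seq_len(n_frames) - 1) * frame_interval_s,
         baseline_window = seq_len(baseline_frames), truth = truth)
  })
}
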