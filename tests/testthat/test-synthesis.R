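# Ground-truth fidelity and determinism of the synthetic generators.

test_that("generators are deterministic in (params, seed)", {
  a <- gen_two_channel_stack(0.4, snr = 10, seed = 11)
  b <- gen_two_channel_stack(0.4, snr = 10, seed = 11)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth$params$overlap_voxels, b$truth$params$overlap_voxels)

  p1 <- gen_photoactivation_series(8, 0.01, n_frames = 30, snr = 15, seed = 3)
  p2 <- gen_photoactivation_series(8, 0.01, n_frames = 30, snr = 15, seed = 3)
  expect_identical(p1$stack$data, p2$stack$data)

  s1 <- gen_spine_timelapse(seed = 5, snr = 12)
  s2 <- gen_spine_timelapse(seed = 5, snr = 12)
  expect_identical(s1$stack$data, s2$stack$data)

  t1 <- gen_proteomics_tables(n_true = 20, seed = 9,
                              interactor_structure = c(actin_only = 3,
                                                       tubulin_only = 1,
                                                       both = 2))
  t2 <- gen_proteomics_tables(n_true = 20, seed = 9,
                              interactor_structure = c(actin_only = 3,
                                                       tubulin_only = 1,
                                                       both = 2))
  expect_identical(t1$experiments, t2$experiments)
  expect_identical(t1$db, t2$db)

  c1 <- gen_calcium_trace(seed = 2)
  c2 <- gen_calcium_trace(seed = 2)
  expect_identical(c1$raw, c2$raw)

  l1 <- gen_line_profile_pair(100, 0.5, seed = 4)
  l2 <- gen_line_profile_pair(100, 0.5, seed = 4)
  expect_identical(l1$a$values, l2$a$values)
})

test_that("generated intensities are non-negative across modalities", {
  expect_gte(min(gen_two_channel_stack(0.5, snr = 3, seed = 1)$stack$data), 0)
  expect_gte(min(gen_photoactivation_series(5, 0.02, n_frames = 20, snr = 3,
                                            seed = 1)$stack$data), 0)
  expect_gte(min(gen_spine_timelapse(snr = 3, seed = 1)$stack$data), 0)
  expect_gte(min(gen_calcium_trace(snr = 2, seed = 1)$raw), 0)
  expect_gte(min(gen_line_profile_pair(100, -0.9, seed = 1)$a$values), 0)
})

test_that("planted colocalization matches brute-force voxel enumeration", {
  g <- gen_two_channel_stack(0.5, snr = Inf, seed = 1)
  tp <- g$truth$params
  expect_equal(oracle_overlap_pct(tp$mito_mask, tp$actin_mask), tp$overlap_pct)
  # noiseless masks coincide with suprathreshold support
  amp_half <- tp$background + tp$amplitude / 2
  expect_identical(unname(g$stack$data[, , , 1] > amp_half),
                   unname(tp$mito_mask))

  g0 <- gen_two_channel_stack(0, snr = Inf, seed = 2)
  expect_identical(g0$truth$params$overlap_voxels, 0L)

  g1 <- gen_two_channel_stack(1, snr = Inf, seed = 3)
  t1 <- g1$truth$params
  expect_true(all(t1$actin_mask[t1$mito_mask]))
  expect_equal(t1$overlap_pct, 100)
})

test_that("two-channel stack rejects invalid parameters", {
  expect_error(gen_two_channel_stack(1.2), "overlap_fraction")
  expect_error(gen_two_channel_stack(NA), "overlap_fraction")
  expect_error(gen_two_channel_stack(0.5, snr = -1), "snr")
  expect_error(gen_two_channel_stack(0.5, dims = c(30, 10, 3)),
               "too small")
})

test_that("photoactivation series plants background-only frames then decay", {
  g <- gen_photoactivation_series(10, 0.01, n_frames = 30, snr = Inf, seed = 1)
  tp <- g$truth$params
  d <- g$stack$data
  expect_true(all(d[, , 1:6] == tp$background))
  # planted extent at frame 8, half-max threshold
  fr <- d[, , 8]
  cols <- which(apply(fr > tp$background + 1, 1, any))
  expect_equal(diff(range(cols)) + 1, round(tp$length_um / 0.2))
  # decay law on the peak intensity
  peak <- apply(d, 3, max)[7:30]
  t_min <- (0:23) * 30 / 60
  expect_equal(peak - tp$background,
               tp$amplitude * exp(-0.01 * t_min), tolerance = 1e-10)
  expect_error(gen_photoactivation_series(10, -0.1), "loss_rate")
  expect_error(gen_photoactivation_series(10, 0, n_frames = 10), "n_frames")
})

test_that("spine generator plants exact sigmas and rejects sub-pixel heads", {
  g <- gen_spine_timelapse(0.3, growth_profile = c(0, 0.2),
                           timepoints = c(0, 2), snr = Inf, seed = 1)
  tp <- g$truth$params
  expect_equal(tp$sigma_um, c(0.3, 0.36))
  expect_equal(tp$fwhm_um, 2 * sqrt(2 * log(2)) * c(0.3, 0.36))
  # all-zero growth keeps every timepoint identical (noiseless)
  g0 <- gen_spine_timelapse(0.3, growth_profile = c(0, 0),
                            timepoints = c(0, 2), snr = Inf, seed = 1)
  expect_identical(g0$stack$data[, , 1, 1], g0$stack$data[, , 1, 2])
  expect_error(gen_spine_timelapse(0.05, growth_profile = 0, timepoints = 0),
               "sigma")
  expect_error(gen_spine_timelapse(0.3, growth_profile = c(0, 0),
                                   timepoints = 0), "equal length")
})

test_that("profile pair plants the requested correlation", {
  g1 <- gen_line_profile_pair(200, 1, seed = 1)
  expect_equal(cor(g1$a$values, g1$b$values), 1)
  g0 <- gen_line_profile_pair(1e4, 0, seed = 1)
  expect_lt(abs(cor(g0$a$values, g0$b$values)), 0.05)
  rs <- vapply(1:200, function(s)
    gen_line_profile_pair(500, 0.8, seed = s)$truth$params$sample_r, 0)
  expect_lt(abs(mean(rs) - 0.8), 0.1)
})

test_that("proteomics generator plants category structure exactly", {
  st <- c(actin_only = 13, tubulin_only = 1, both = 5)
  g <- gen_proteomics_tables(n_true = 129, interactor_structure = st,
                             seed = 1)
  tp <- g$truth$params
  expect_length(tp$true_set, 129)
  expect_length(tp$actin_only, 13)
  expect_length(tp$tubulin_only, 1)
  expect_length(tp$both, 5)
  # unique protein IDs per table
  for (tab in c(g$experiments, g$controls))
    expect_false(anyDuplicated(tab$protein_id) > 0)
  # true proteins in >= 2 experiments and no control
  ctrl <- unique(unlist(lapply(g$controls, function(t) t$protein_id)))
  expect_length(intersect(tp$true_set, ctrl), 0)
  pres <- table(unlist(lapply(g$experiments, function(t) t$protein_id)))
  expect_true(all(pres[tp$true_set] >= 2))
  # contaminants appear in at least one control
  expect_setequal(intersect(tp$contaminants, ctrl), tp$contaminants)
  # singletons in exactly one replicate
  expect_true(all(pres[tp$singletons] == 1))

  empty <- gen_proteomics_tables(n_true = 0, n_control_contaminants = 3,
                                 n_singletons = 2,
                                 interactor_structure = c(actin_only = 0,
                                                          tubulin_only = 0,
                                                          both = 0),
                                 n_mrna_excluded = 0,
                                 frac_soluble_top = 0, frac_soluble_all = 0,
                                 seed = 1)
  expect_length(empty$truth$params$true_set, 0)
})

test_that("calcium generator plants exact peak values when noiseless", {
  g <- gen_calcium_trace(3, 1, snr = Inf, seed = 1)
  tp <- g$truth$params
  dff <- (g$raw - tp$F0) / tp$F0
  expect_equal(dff[tp$peak_frames], tp$amplitudes, tolerance = 1e-12)
  expect_equal(mean(dff[g$baseline_window]), 0, tolerance = 1e-12)
  g0 <- gen_calcium_trace(0, 1, snr = 5, seed = 1)
  expect_lt(abs(mean((g0$raw - 100) / 100)), 0.1)
  expect_length(g0$truth$params$peak_frames, 0)
})
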