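# Spine morphometry: preprocessing, Gaussian FWHM, time courses,
# distance binning, mitochondrial density, CoM displacement, knockdown.

test_that("preprocessing averages frames and removes flat background", {
  # constant stack -> all-zero output
  expect_true(all(preprocess_timepoint(array(5, c(40, 40, 10))) == 0))
  # point sources on flat background keep their peak height within 2%
  img <- matrix(10, 120, 120)
  img[60, 60] <- 110
  img[30, 90] <- 60
  out <- preprocess_timepoint(array(img, c(120, 120, 1)), n_average = 1,
                              rolling_ball_radius = 20)
  expect_lt(abs(out[60, 60] - 100) / 100, 0.02)
  expect_lt(abs(out[30, 90] - 50) / 50, 0.02)
  # n_average = 1 with no background step is the identity
  expect_equal(preprocess_timepoint(array(img, c(120, 120, 1)),
                                    n_average = 1, rolling_ball_radius = 0),
               img)
})

test_that("FWHM equals the closed form on exact Gaussian profiles", {
  for (s_px in c(2, 4, 8)) {
    img <- 80 * outer(exp(-((1:121) - 61)^2 / (2 * s_px^2)), rep(1, 31)) + 5
    f <- spine_head_width(img, c(61, 16), c(1, 0),
                          length_um = 8, pixel_size_um = 0.1)
    expect_true(f$valid)
    expect_equal(f$fwhm_um, 2 * sqrt(2 * log(2)) * s_px * 0.1,
                 tolerance = 1e-6 / f$fwhm_um)
    # intensity rescaling does not change the FWHM
    f10 <- spine_head_width(img * 10, c(61, 16), c(1, 0),
                            length_um = 8, pixel_size_um = 0.1)
    expect_equal(f10$fwhm_um, f$fwhm_um, tolerance = 1e-9)
  }
  # degenerate flat input is flagged invalid
  flat <- spine_head_width(matrix(3, 50, 50), c(25, 25))
  expect_false(flat$valid)
})

test_that("FWHM estimator is nearly unbiased at snr 10", {
  rel <- vapply(1:25, function(s) {
    g <- gen_spine_timelapse(0.25, growth_profile = 0, timepoints = 0,
                             snr = 10, seed = s)
    tp <- g$truth$params
    img <- preprocess_timepoint(array(g$stack$data[, , , 1],
                                      dim(g$stack$data)[1:3]))
    spine_head_width(img, tp$head_center_px)$fwhm_um / tp$fwhm_um[1]
  }, 0)
  expect_lt(abs(mean(rel) - 1), 0.02)
  expect_lt(sd(rel), 0.05)
})

test_that("spine records and time courses behave", {
  tp <- c(0, 2, 12, 22, 32, 42, 52, 62)
  flatrec <- spine_record("s1", "induced", 0, rep(0.5, 8), tp)
  expect_equal(flatrec$widths_norm, rep(1, 8))
  tc <- plasticity_time_course(list(flatrec))
  expect_equal(tc$mean_norm, rep(1, 8))
  expect_equal(tc$n, rep(1L, 8))
  # missing timepoint excluded from that mean, n reported
  w2 <- c(0.5, 0.7, NA, 0.7, 0.7, 0.7, 0.7, 0.7)
  rec2 <- spine_record("s2", "adjacent", 10, w2, tp)
  tc2 <- plasticity_time_course(list(flatrec, rec2))
  expect_equal(tc2$n[3], 1L)
  expect_equal(tc2$mean_norm[2], mean(c(1, 1.4)))
  expect_error(spine_record("x", "induced", 0, c(NA, rep(0.5, 7)), tp),
               "baseline")
  expect_error(spine_record("x", "induced", 0, rep(-1, 8), tp), "positive")
})

test_that("distance binning is right-closed with the induced spine at 0", {
  tp <- c(0, 2, 12, 22, 32, 42, 52, 62)
  mk <- function(id, role, d, g) spine_record(id, role, d,
    0.5 * c(1, rep(1 + g, 7)), tp)
  recs <- list(mk("i", "induced", 0, 0.5),
               mk("a15", "adjacent", 15, 0.3),   # boundary -> (0,15]
               mk("a20", "adjacent", 20, 0.2),
               mk("a45", "adjacent", 45, 0))
  out <- bin_adjacent_spines(recs, at_times = c(2, 62))
  b1 <- out[out$bin == "(0,15]" & out$time_min == 62, ]
  expect_equal(b1$mean_norm, 1.3)
  expect_equal(b1$n, 1L)
  expect_equal(out[out$bin == "0" & out$time_min == 62, "mean_norm"], 1.5)
  expect_equal(out[out$bin == "(30,45]" & out$time_min == 62, "mean_norm"], 1)
  # beyond the last edge -> excluded with a warning
  far <- c(recs, list(mk("a50", "adjacent", 50, 0.9)))
  expect_warning(out2 <- bin_adjacent_spines(far, at_times = 62), "excluded")
  expect_equal(out2[out2$bin == "(30,45]", "n"], 1L)
})

test_that("mitochondrial density splits straddling traces exactly", {
  # one 15-um mitochondrion filling the first bin -> density 1
  full <- mito_trace(cbind(c(0, 15), c(0, 0)))
  d1 <- mito_density(list(full), spine_position = 0)
  expect_equal(d1[d1$side == "right" & d1$bin == "0-15", "density"], 1)
  # 7.5-um mitochondrion straddling the 15-um boundary equally
  strad <- mito_trace(cbind(c(11.25, 18.75), c(0, 0)))
  d2 <- mito_density(list(strad), spine_position = 0)
  expect_equal(d2[d2$side == "right" & d2$bin == "0-15", "density"], 0.25)
  expect_equal(d2[d2$side == "right" & d2$bin == "15-30", "density"], 0.25)
  # conservation on random instances: summed binned length = in-range length
  set.seed(4)
  for (i in 1:25) {
    traces <- lapply(1:6, function(j) {
      x0 <- runif(1, -40, 40)
      mito_trace(cbind(c(x0, x0 + runif(1, 0.5, 12)), c(0, 0)))
    })
    dd <- mito_density(traces, spine_position = 0, max_distance = 45)
    in_range <- sum(vapply(traces, function(tr) {
      x <- sort(tr$vertices[, 1])
      max(0, min(x[2], 45) - max(x[1], -45))
    }, 0))
    expect_equal(sum(dd$mito_length_um), in_range, tolerance = 1e-9)
  }
})

test_that("CoM displacement and knockdown percentage are exact", {
  a <- array(0, c(64, 64, 2)); a[20, 20, 1] <- 1; a[23, 24, 2] <- 1
  st <- image_stack(a, "xyt", voxel_size = c(100, 100, 500),
                    frame_interval = 60)
  expect_equal(com_displacement(st, t_final = 1), 0.5)  # 3-4-5 triangle
  same <- array(1, c(10, 10, 3))
  st0 <- image_stack(same, "xyt", voxel_size = c(100, 100, 500),
                     frame_interval = 60)
  expect_equal(com_displacement(st0, t_final = 2), 0)
  # noisy static spine stays below the noise floor on average
  set.seed(8)
  disp <- vapply(1:50, function(i) {
    spine <- 100 * outer(exp(-((1:40) - 20)^2 / 8), exp(-((1:40) - 20)^2 / 8))
    arr <- array(rpois(40 * 40 * 2, spine + 10), c(40, 40, 2))
    com_displacement(image_stack(arr, "xyt", c(100, 100, 500), 60), 1)
  }, 0)
  expect_lt(mean(disp), 0.05)

  expect_equal(knockdown_percentage(c(10, 20), c(10, 20)), 1)
  expect_equal(knockdown_percentage(c(0, 0), c(5, 5)), 0)
  expect_equal(knockdown_percentage(3, 10), 0.3)
  expect_error(knockdown_percentage(numeric(0), 1), "nonempty")
})
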