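# 3D colocalization: segmentation, interaction percentage, masked Pearson.

test_that("segmentation handles degenerate and manual-threshold cases", {
  g <- gen_two_channel_stack(0.5, snr = Inf, seed = 1)
  # constant channel -> empty mask with a warning, not an error
  const <- image_stack(array(5, c(20, 20, 3, 1)), "xyzc",
                       channel_names = "flat")
  expect_warning(bv <- segment_channel(const, "flat", "otsu"), "constant|empty")
  expect_equal(sum(bv$mask), 0)
  # threshold above the global max -> empty mask
  expect_warning(bv2 <- segment_channel(g$stack, "mito", "manual",
                                        manual_threshold = 1e6), "empty")
  expect_equal(sum(bv2$mask), 0)
  expect_error(segment_channel(g$stack, "mito", "manual"), "manual_threshold")
  # half-max manual threshold recovers the planted mask exactly (noiseless)
  tp <- g$truth$params
  bv3 <- segment_channel(g$stack, "mito", "manual",
                         manual_threshold = tp$background + tp$amplitude / 2)
  expect_identical(unname(bv3$mask), unname(tp$mito_mask))
  expect_equal(bv3$label_count, tp$n_mito)
  expect_equal(volume_um3(bv3),
               sum(tp$mito_mask) * prod(c(40, 40, 800) / 1000))
})

test_that("interaction percentage is exact voxel arithmetic", {
  g <- gen_two_channel_stack(0.5, snr = Inf, seed = 1)
  tp <- g$truth$params
  thr <- tp$background + tp$amplitude / 2
  mito <- segment_channel(g$stack, "mito", "manual", manual_threshold = thr)
  actin <- segment_channel(g$stack, "actin", "manual", manual_threshold = thr)
  pct <- interaction_percentage(mito, actin)
  expect_equal(pct, oracle_overlap_pct(tp$mito_mask, tp$actin_mask))
  expect_equal(pct, tp$overlap_pct)
  # identity and disjoint masks
  expect_equal(interaction_percentage(mito, mito), 100)
  empty <- mito; empty$mask <- array(FALSE, dim(mito$mask))
  expect_equal(interaction_percentage(mito, empty), 0)
  expect_error(interaction_percentage(empty, mito), "empty")
  # intensity rescaling of a channel does not move the masks' percentage
  g2 <- g; g2$stack$data <- g$stack$data * 10
  m2 <- segment_channel(g2$stack, "mito", "manual",
                        manual_threshold = 10 * thr)
  a2 <- segment_channel(g2$stack, "actin", "manual",
                        manual_threshold = 10 * thr)
  expect_equal(interaction_percentage(m2, a2), pct)
  # monotonicity: adding actin voxels never decreases the percentage
  grown <- actin
  off <- which(!grown$mask)[1:500]
  grown$mask[off] <- TRUE
  expect_gte(interaction_percentage(mito, grown), pct)
})

test_that("interaction percentage recovers planted fractions under noise", {
  for (f in c(0.25, 0.75)) {
    g <- gen_two_channel_stack(f, snr = 10, seed = 21)
    mito <- segment_channel(g$stack, "mito", "otsu")
    actin <- segment_channel(g$stack, "actin", "otsu")
    expect_lt(abs(interaction_percentage(mito, actin) -
                    g$truth$params$overlap_pct), 3)
  }
})

test_that("masked Pearson hits the trivial and planted cases", {
  g <- gen_two_channel_stack(0.5, snr = 10, seed = 1)
  d <- g$stack$data
  dup <- image_stack(array(c(d[, , , 1], d[, , , 1]), dim(d)), "xyzc",
                     channel_names = c("a", "b"))
  expect_equal(masked_pearson(dup, "a", "b"), 1)
  neg <- d
  neg[, , , 2] <- max(d[, , , 1]) - d[, , , 1]
  st <- image_stack(neg, "xyzc", channel_names = c("a", "b"))
  expect_equal(masked_pearson(st, "a", "b", mask_from = "a"), -1)
  # planted in-mask correlation recovered on average
  rs <- vapply(1:50, function(s) {
    set.seed(s)
    mask_sig <- array(0, c(40, 40, 3))
    mask_sig[10:30, 10:30, 2] <- 100
    n <- sum(mask_sig > 0)
    z1 <- rnorm(length(mask_sig)); z2 <- 0.6 * z1 + sqrt(1 - 0.36) * rnorm(length(z1))
    a <- pmax(mask_sig + 10 + 3 * z1, 0)
    b <- pmax(mask_sig + 10 + 3 * z2, 0)
    st <- image_stack(array(c(mask_sig + 1, a, b), c(40, 40, 3, 3)), "xyzc",
                      channel_names = c("m", "a", "b"))
    masked_pearson(st, "a", "b", mask_from = "m")
  }, 0)
  expect_lt(abs(mean(rs) - 0.6), 0.1)
  # fewer than 3 mask voxels is an error
  tiny <- array(0, c(5, 5, 1, 2)); tiny[3, 3, 1, 1] <- 10
  tiny[, , , 2] <- runif(25)
  st2 <- image_stack(tiny, "xyzc", channel_names = c("m", "x"))
  expect_error(masked_pearson(st2, "m", "x", mask_from = "m"), "3")
})
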