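test_that("bandpass preserves DC, kills 1-px stripes, keeps 3-px fibrils", {
  const <- fibril_stack(matrix(3.7, 64, 64))
  out <- bandpass_filter(const)
  expect_equal(out$reflectance[, , 1], matrix(3.7, 64, 64), tolerance = 1e-8)

  # fixture: 3-px vertical bars + alternating-row stripe artefact
  n <- 128
  bars <- matrix(0, n, n)
  for (c0 in seq(10, n - 10, 16)) bars[, c0:(c0 + 2)] <- 1
  stripe <- matrix(rep(c(0.5, -0.5), length.out = n), n, n)
  img <- bars + stripe
  filt <- bandpass_filter(fibril_stack(img))$reflectance[, , 1]
  stripe_energy <- function(m) {
    # stripe lives at the Nyquist row frequency; measure via row-alternating
    # projection
    mean((m[seq(1, n, 2), ] - m[seq(2, n, 2), ])^2)
  }
  expect_gt(stripe_energy(img) / stripe_energy(filt), 10)
  contrast <- function(m) mean(m[bars == 1]) - mean(m[bars == 0])
  expect_gt(contrast(filt) / contrast(bars), 0.5)

  # near-idempotence: the transfer function is near-binary
  twice <- bandpass_filter(bandpass_filter(fibril_stack(img)))$reflectance
  once <- array(filt, c(n, n, 1))
  expect_lt(sqrt(sum((twice - once)^2) / sum(once^2)), 0.05)

  expect_error(bandpass_filter(fibril_stack(matrix(0, 32, 32))), "fit")
  expect_error(bandpass_filter(const, low_px = 50, high_px = 40), "low_px")
})

test_that("binarization separates a two-level image and tolerates flat slices", {
  img <- matrix(0, 20, 20)
  img[, 1:10] <- 100
  bin <- binarize(fibril_stack(img))
  expect_identical(bin$mask[, , 1], img == 100)

  expect_warning(b0 <- binarize(fibril_stack(matrix(0, 16, 16))), "variance")
  expect_false(any(b0$mask))

  # noiseless rendered fibrils: mask should recover the dilated centrelines
  nt <- network_truth(line_intensity = 0.4, fibril_width_px = 3,
                      psf_sigma_px = 0, noise_sd = 0, n_slices = 2,
                      image_shape = c(256, 256), seed = 4)
  st <- gen_fibril_stack(nt)
  bin2 <- binarize(st)
  for (z in 1:2) {
    truth_mask <- fibrilkit:::dilate_width(
      fibrilkit:::rasterize_segments(st$truth$centerlines[[z]], 256, 256), 3) > 0
    jac <- sum(bin2$mask[, , z] & truth_mask) /
      sum(bin2$mask[, , z] | truth_mask)
    expect_gte(jac, 0.9)
  }
})

test_that("fibril content is the pooled foreground fraction", {
  expect_equal(fibril_content(array(FALSE, c(5, 5, 2))), 0)
  expect_equal(fibril_content(array(TRUE, c(5, 5, 2))), 1)
  m <- matrix(FALSE, 10, 10)
  m[3, 7] <- TRUE
  expect_equal(fibril_content(array(m, c(10, 10, 1))), 0.01)
  # invariant to slice order
  a <- array(runif(16 * 16 * 3) > 0.7, c(16, 16, 3))
  expect_equal(fibril_content(a), fibril_content(a[, , 3:1]))
})

test_that("skeletonization resolves bars, crosses and fixture junctions", {
  bar <- matrix(0, 11, 31)
  bar[5:7, 3:28] <- 1
  sk <- skeletonize_network(bar)
  expect_equal(length(sk$components[[1]]), 1)
  expect_equal(nrow(sk$junctions[[1]]), 0)

  plus <- make_plus(21, 8)
  skp <- skeletonize_network(plus)
  expect_equal(nrow(skp$junctions[[1]]), 1)
  expect_equal(nrow(skp$branches), 4)

  # junction recovery on a rendered line process, borders excluded
  nt <- network_truth(line_intensity = 0.4, fibril_width_px = 3,
                      psf_sigma_px = 0, noise_sd = 0, n_slices = 3,
                      image_shape = c(256, 256), seed = 6)
  st <- gen_fibril_stack(nt)
  skel <- skeletonize_network(binarize(st))
  margin <- 6
  inside <- function(df) sum(df$x > margin & df$x <= 256 - margin &
                               df$y > margin & df$y <= 256 - margin)
  n_true <- sum(vapply(st$truth$junctions, inside, 0))
  n_det <- sum(vapply(skel$junctions, inside, 0))
  expect_lt(abs(n_det - n_true) / n_true, 0.2)
})

test_that("skeletonizing a skeleton returns it unchanged", {
  nt <- network_truth(line_intensity = 0.4, n_slices = 1,
                      image_shape = c(200, 200), seed = 12)
  skel <- skeletonize_network(binarize(gen_fibril_stack(nt)))
  again <- skeletonize_network(skel$skeleton)
  expect_identical(again$skeleton, skel$skeleton)
})

test_that("mesh size recovers known gap distributions", {
  # exponential gaps, ceiling-discretised: histogram is exactly geometric
  est <- vapply(1:5, function(s) {
    set.seed(s)
    mesh_size(make_exp_gap_matrix(), 0.1, directions = "x")$mesh_size_um
  }, 0)
  expect_lt(abs(mean(est) - 1.5) / 1.5, 0.1)

  # periodic vertical lines: single-bin histogram falls back to the sample
  # mean with a degenerate-fit flag
  m <- matrix(0, 100, 100)
  m[, seq(10, 90, 20)] <- 1
  ms <- mesh_size(m, 0.1)
  expect_true(ms$fit$degenerate)
  expect_equal(ms$mesh_size_um, 1.9)

  expect_error(mesh_size(matrix(1, 5, 5), 0.1), "insufficient gap sample")
})

test_that("connectivity counts junctions per qualifying component", {
  chain <- matrix(0, 9, 20)
  chain[5, 3:18] <- 1
  expect_equal(connectivity(skeletonize_network(chain)), 0)

  plus <- make_plus(21, 8)
  expect_equal(connectivity(skeletonize_network(plus)), 1)

  both <- matrix(0, 30, 60)
  both[5:25, 5:25][make_plus(21, 8) == 1] <- 1
  both[15, 40:55] <- 1
  expect_equal(connectivity(skeletonize_network(both)), 0.5)

  expect_error(connectivity(skeletonize_network(matrix(0, 8, 8))),
               "components")
})

test_that("branch lengths use geodesic steps and recover segment truth", {
  horiz <- matrix(0, 7, 15)
  horiz[4, 3:13] <- 1
  bl <- branch_lengths(skeletonize_network(horiz), 0.1)
  expect_equal(bl$mean_branch_length_um, 1.0)

  diag_m <- matrix(0, 15, 15)
  diag_m[cbind(3:13, 3:13)] <- 1
  bld <- branch_lengths(skeletonize_network(diag_m), 0.1)
  expect_equal(bld$mean_branch_length_um, sqrt(2), tolerance = 1e-9)

  # disjoint segments of known length, rendered at width 3
  segs <- list(matrix(c(20, 30, 120, 30,
                        20, 80, 120, 80,
                        20, 130, 100, 130), ncol = 4, byrow = TRUE,
                      dimnames = list(NULL, c("x0", "y0", "x1", "y1"))))
  nt <- network_truth(image_shape = c(160, 160), n_slices = 1, noise_sd = 0,
                      psf_sigma_px = 0, fibril_width_px = 3)
  st <- gen_fibril_stack(nt, segments = segs)
  blf <- branch_lengths(skeletonize_network(binarize(st)), nt$pixel_size)
  expect_lt(abs(blf$mean_branch_length_um - mean(c(10, 10, 8))) /
              mean(c(10, 10, 8)), 0.05)

  expect_error(branch_lengths(skeletonize_network(matrix(0, 8, 8)), 0.1),
               "branches")
})

test_that("analyze_network flags degenerate stacks and reacts to densification", {
  # a fibril-free stack: flat background with a few speckle pixels
  speckle <- array(0, c(64, 64, 2))
  speckle[cbind(c(10, 30, 50), c(12, 40, 20), c(1, 2, 1))] <- 5
  nm <- analyze_network(fibril_stack(speckle), bandpass = FALSE)
  expect_false(nm$complete)
  expect_lt(nm$fibril_content, 0.01)
  expect_true(is.na(nm$mesh_size_um))
  expect_true(any(grepl("insufficient gap sample", nm$flags)))

  denser_wins <- 0
  for (s in 1:10) {
    base <- analyze_network(gen_fibril_stack(
      network_truth(line_intensity = 0.3, n_slices = 2,
                    image_shape = c(256, 256), seed = s)))
    dense <- analyze_network(gen_fibril_stack(
      network_truth(line_intensity = 0.6, n_slices = 2,
                    image_shape = c(256, 256), seed = s)))
    if (dense$mesh_size_um < base$mesh_size_um &&
        dense$fibril_content > base$fibril_content &&
        dense$n_junctions > base$n_junctions) {
      denser_wins <- denser_wins + 1
    }
  }
  expect_gte(denser_wins, 9)
})

test_that("metrics are exactly invariant to 90-degree rotation", {
  nt <- network_truth(line_intensity = 0.4, n_slices = 2,
                      image_shape = c(200, 200), seed = 21)
  bin <- binarize(gen_fibril_stack(nt))
  skel <- skeletonize_network(bin)
  rot_mask <- array(FALSE, dim(bin$mask))
  rot_skel <- array(FALSE, dim(skel$skeleton))
  for (z in 1:2) {
    rot_mask[, , z] <- rot90(bin$mask[, , z])
    rot_skel[, , z] <- rot90(skel$skeleton[, , z])
  }
  expect_identical(fibril_content(rot_mask), fibril_content(bin$mask))

  skel_r <- skeletonize_network(rot_skel)
  # rotating a 1-px skeleton leaves it a fixed point of thinning
  expect_identical(skel_r$skeleton, rot_skel)
  expect_identical(mesh_size(skel_r, 0.1)$mesh_size_um,
                   mesh_size(skel, 0.1)$mesh_size_um)
  expect_identical(connectivity(skel_r), connectivity(skel))
})
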