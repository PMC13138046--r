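single_segment_stack <- function(nr = 128, nc = 128, n_slices = 1) {
  seg <- matrix(c(20, nr / 2, nc - 20, nr / 2), ncol = 4,
                dimnames = list(NULL, c("x0", "y0", "x1", "y1")))
  nt <- network_truth(image_shape = c(nr, nc), n_slices = n_slices,
                      noise_sd = 0, psf_sigma_px = 0, fibril_width_px = 1)
  gen_fibril_stack(nt, segments = rep(list(seg), n_slices))
}

test_that("particle detection finds binary centroids", {
  img <- array(0, c(12, 12, 1))
  img[4:6, 4:6, 1] <- 1
  st <- fibril_stack(img, fluorescence = img)
  p <- detect_particles(st)
  expect_equal(nrow(p), 1)
  expect_equal(c(p$x, p$y), c(5, 5))

  empty <- fibril_stack(img, fluorescence = array(0, c(12, 12, 1)))
  expect_equal(nrow(detect_particles(empty)), 0)

  expect_error(detect_particles(fibril_stack(img)), "fluorescence")
})

test_that("50 rendered particles are recovered with sub-pixel accuracy", {
  set.seed(3)
  grid <- expand.grid(x = seq(15, 240, 25), y = seq(15, 240, 25))
  grid <- grid[sample(nrow(grid), 50), ]
  x <- grid$x + runif(50, -3, 3)
  y <- grid$y + runif(50, -3, 3)
  fl <- render_spots(256, 256, x, y)
  st <- fibril_stack(array(0, c(256, 256, 1)),
                     fluorescence = array(fl, c(256, 256, 1)))
  p <- detect_particles(st)
  expect_equal(nrow(p), 50)
  err <- vapply(seq_len(50), function(i) {
    min(sqrt((p$x - x[i])^2 + (p$y - y[i])^2))
  }, 0)
  expect_lt(mean(err), 1)
})

test_that("nearest-fibril distances follow the in-plane pseudo-3D contract", {
  st <- single_segment_stack()
  skel <- truth_skeleton(st)

  on_pixel <- structure(data.frame(x = 64, y = 64, slice = 1L,
                                   area_px = 4L),
                        pixel_size = 0.1, n_slices = 1L,
                        class = c("particle_set", "data.frame"))
  expect_equal(nearest_fibril_distance(on_pixel, skel), 0)

  away <- structure(data.frame(x = 64, y = 74, slice = 1L, area_px = 4L),
                    pixel_size = 0.1, n_slices = 1L,
                    class = c("particle_set", "data.frame"))
  expect_equal(nearest_fibril_distance(away, skel), 1.0)
})

test_that("grid-indexed search equals brute force on random instances", {
  nt <- network_truth(line_intensity = 0.4, n_slices = 3,
                      image_shape = c(256, 256), seed = 8)
  st <- gen_fibril_stack(nt)
  skel <- skeletonize_network(binarize(st))
  set.seed(99)
  q <- cbind(runif(200, 1, 256), runif(200, 1, 256))
  coords <- fibrilkit:::skeleton_pixel_coords(skel)
  for (z in 1:3) {
    ref <- do.call(rbind, coords[max(1, z - 1):min(3, z + 1)])
    dg <- fibrilkit:::nn_dist_grid(q, ref)
    db <- fibrilkit:::nn_dist_brute(q, ref)
    expect_lt(max(abs(dg - db)), 1e-9)
  }
})

test_that("associated fraction uses an inclusive threshold and placement logic", {
  expect_equal(associated_fraction(c(0.49, 0.50, 0.51)), 2 / 3)
  expect_error(associated_fraction(numeric(0)), "no particles")
  expect_equal(associated_fraction(c(0.1, Inf)), 0.5)

  st <- single_segment_stack()
  skel <- truth_skeleton(st)
  onf <- place_particles(st, particle_placement("on_fibril", 30, seed = 5))
  d_on <- nearest_fibril_distance(
    structure(onf$placement$true_centroids,
              pixel_size = 0.1, class = c("particle_set", "data.frame")),
    skel)
  expect_equal(associated_fraction(d_on), 1.0)

  off <- place_particles(st, particle_placement("offset", 30, offset_um = 2,
                                                seed = 6))
  d_off <- nearest_fibril_distance(
    structure(off$placement$true_centroids,
              pixel_size = 0.1, class = c("particle_set", "data.frame")),
    skel)
  expect_equal(associated_fraction(d_off), 0.0)
})

test_that("junction distances separate junction-bound from fibril-bound particles", {
  # two crossing segments: junction at the centre
  segs <- list(matrix(c(14, 64, 114, 64, 64, 14, 64, 114), ncol = 4,
                      byrow = TRUE,
                      dimnames = list(NULL, c("x0", "y0", "x1", "y1"))))
  nt <- network_truth(image_shape = c(128, 128), n_slices = 1, noise_sd = 0,
                      psf_sigma_px = 0, fibril_width_px = 1)
  st <- gen_fibril_stack(nt, segments = segs)
  skel <- truth_skeleton(st)
  ps <- function(x, y) structure(
    data.frame(x = x, y = y, slice = 1L, area_px = 4L),
    pixel_size = 0.1, n_slices = 1L, class = c("particle_set", "data.frame"))

  at_j <- nearest_junction_distance(ps(64, 64), skel)
  expect_equal(at_j$junction_distances_um, 0)
  expect_equal(at_j$frac_junction_associated, 1)

  on_arm <- ps(114, 64)  # 5 um along the arm from the junction
  expect_lte(nearest_fibril_distance(on_arm, skel), 0.05)
  far <- nearest_junction_distance(on_arm, skel)
  expect_equal(far$junction_distances_um, 5.0)
  expect_equal(far$frac_junction_associated, 0)

  no_j <- truth_skeleton(single_segment_stack())
  expect_error(nearest_junction_distance(ps(64, 64), no_j), "junction")
})

test_that("at-junction placement with 0.2 um jitter stays mostly associated", {
  nt <- network_truth(line_intensity = 0.4, n_slices = 3,
                      image_shape = c(256, 256), noise_sd = 0,
                      psf_sigma_px = 0, fibril_width_px = 1, seed = 13)
  st <- gen_fibril_stack(nt)
  pp <- place_particles(st, particle_placement("at_junction", 100,
                                               jitter_um = 0.2, seed = 14))
  skel <- truth_skeleton(pp$stack)
  pset <- structure(pp$placement$true_centroids, pixel_size = 0.1,
                    n_slices = 3L, class = c("particle_set", "data.frame"))
  res <- nearest_junction_distance(pset, skel)
  expect_gte(res$frac_junction_associated, 0.9)
})

test_that("distances are invariant to joint translation", {
  st <- single_segment_stack()
  skel <- truth_skeleton(st)
  ps <- function(x, y) structure(
    data.frame(x = x, y = y, slice = 1L, area_px = 4L),
    pixel_size = 0.1, n_slices = 1L, class = c("particle_set", "data.frame"))
  d0 <- nearest_fibril_distance(ps(50, 70), skel)
  # shift skeleton and particle by the same integer offset
  shifted <- skel
  shifted$skeleton[, , 1] <- fibrilkit:::shift_mat(
    skel$skeleton[, , 1] * 1, -5L, -9L) > 0
  d1 <- nearest_fibril_distance(ps(50 + 9, 70 + 5), shifted)
  expect_equal(d0, d1)
})

test_that("coloc_report contrasts embedded-style vs uniform placement", {
  wins_dist <- 0
  wins_frac <- 0
  for (s in 1:10) {
    nt <- network_truth(line_intensity = 0.15, n_slices = 3,
                        image_shape = c(128, 128), seed = s)
    st <- gen_fibril_stack(nt)
    skel <- truth_skeleton(st)
    u <- place_particles(st, particle_placement("uniform", 40, seed = 100 + s))
    onf <- place_particles(st, particle_placement("on_fibril", 40,
                                                  jitter_um = 0.1,
                                                  seed = 100 + s))
    ru <- coloc_report(u$stack, skeleton = skel)
    rf <- coloc_report(onf$stack, skeleton = skel)
    mu <- mean(ru$distances_um[is.finite(ru$distances_um)])
    mf <- mean(rf$distances_um[is.finite(rf$distances_um)])
    if (mu > mf) wins_dist <- wins_dist + 1
    if (ru$frac_fibril_associated < rf$frac_fibril_associated) {
      wins_frac <- wins_frac + 1
    }
  }
  expect_gte(wins_dist, 9)
  expect_gte(wins_frac, 9)
})

test_that("associated fractions are monotone in the threshold", {
  nt <- network_truth(line_intensity = 0.3, n_slices = 2,
                      image_shape = c(128, 128), seed = 31)
  st <- gen_fibril_stack(nt)
  pp <- place_particles(st, particle_placement("uniform", 60, seed = 32))
  r <- coloc_report(pp$stack, skeleton = truth_skeleton(st))
  fr <- vapply(seq(0.1, 1, 0.1), function(th) {
    associated_fraction(r$distances_um, th)
  }, 0)
  expect_true(all(diff(fr) >= 0))
  # junction association cannot exceed fibril association when junctions
  # lie on the centrelines
  expect_lte(r$frac_junction_associated, r$frac_fibril_associated + 1e-12)
})

test_that("an empty particle channel raises a structured error", {
  st <- single_segment_stack()
  st$fluorescence <- array(0, dim(st$reflectance))
  expect_error(coloc_report(st, skeleton = truth_skeleton(st)),
               "no particles")
})
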