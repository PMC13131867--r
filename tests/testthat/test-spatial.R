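test_that("hemisphere pooling mirrors right-hemisphere x and is involutive", {
  g <- data.frame(patient_id = "P01", hemisphere = c("L", "R"),
                  contact = c(0, 0), x = c(-10, 10), y = 4, z = -4)
  p <- pool_hemispheres(g)
  expect_equal(p$x, c(-10, -10))
  expect_equal(pool_hemispheres(p)$x, p$x)  # flipped rows untouched
  expect_true(all(p$flipped == c(FALSE, TRUE)))
})

test_that("top-percentile centroids locate the spatial peak", {
  set.seed(23)
  coords <- matrix(rnorm(96 * 3, sd = 5), 96, 3)
  w <- rep(0.1, 96); w[40] <- 10
  d <- spatial_distribution(coords, w)
  expect_equal(top_percentile_centroid(d, 5), coords[40, ], ignore_attr = TRUE)

  coords2 <- rbind(matrix(0, 38, 3),
                   c(-8, 4, -4), c(-12, 4, -4))
  w2 <- c(rep(0, 38), 5, 5)
  d2 <- spatial_distribution(coords2, w2)
  expect_equal(top_percentile_centroid(d2, 5), c(-10, 4, -4),
               ignore_attr = TRUE)
})

test_that("moment of inertia matches closed forms and a two-pass loop oracle", {
  one <- spatial_distribution(matrix(rep(c(1, 2, 3), 4), 4, 3, byrow = TRUE),
                              c(1, 2, 3, 4))
  expect_equal(moment_of_inertia(one), 0)

  # two equal weights d apart: I = d^2/4
  two <- spatial_distribution(rbind(c(0, 0, 0), c(6, 0, 0)), c(1, 1))
  expect_equal(moment_of_inertia(two), 9)
  expect_equal(radius_of_gyration(moment_of_inertia(two)), 3)

  # brute-force two-pass loop on a random 96-point configuration
  set.seed(24)
  coords <- matrix(rnorm(96 * 3, sd = 4), 96, 3)
  w <- runif(96)
  d <- spatial_distribution(coords, w)
  ctr <- c(0, 0, 0)
  for (i in 1:96) ctr <- ctr + w[i] * coords[i, ]
  ctr <- ctr / sum(w)
  acc <- 0
  for (i in 1:96) acc <- acc + w[i] * sum((coords[i, ] - ctr)^2)
  expect_equal(moment_of_inertia(d), acc / sum(w), tolerance = 1e-10)

  expect_error(moment_of_inertia(spatial_distribution(coords, rep(0, 96))),
               "zero")
  expect_error(radius_of_gyration(-1), "nonnegative")
})

test_that("inertia is rigid-motion invariant and scales quadratically", {
  set.seed(25)
  coords <- matrix(rnorm(30 * 3), 30, 3)
  w <- runif(30)
  I0 <- moment_of_inertia(spatial_distribution(coords, w))
  # random rotation via QR
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  rot <- coords %*% Q + matrix(c(5, -2, 7), 30, 3, byrow = TRUE)
  expect_equal(moment_of_inertia(spatial_distribution(rot, w)), I0)
  expect_equal(moment_of_inertia(spatial_distribution(2.5 * coords, w)),
               2.5^2 * I0)
})

test_that("the focality permutation test detects planted concentration", {
  set.seed(26)
  # 24 leads of 4 contacts; weights decay from a hotspot
  hot <- c(-10, 4, -4)
  coords <- NULL; labs <- character(0)
  for (h in 1:24) {
    base <- hot + rnorm(3, sd = 2)
    dirv <- c(0.2, 0.1, 1); dirv <- dirv / sqrt(sum(dirv^2))
    coords <- rbind(coords, t(sapply(0:3, function(k) base + (k - 1.5) * 2 * dirv)))
    labs <- c(labs, rep(paste0("H", h), 4))
  }
  dvec <- sqrt(rowSums((coords - matrix(hot, 96, 3, byrow = TRUE))^2))
  w <- exp(-dvec^2 / (2 * 3^2)) + rnorm(96, sd = 0.01)
  res <- inertia_permutation_test(spatial_distribution(coords, w), labs,
                                  n_perm = 2000, seed = 7)
  expect_lt(res$p_value, 0.05)

  # identical weights: observed equals every null, p = 1
  flat <- inertia_permutation_test(spatial_distribution(coords, rep(1, 96)),
                                   labs, n_perm = 500, seed = 8)
  expect_equal(flat$p_value, 1)
})

test_that("the focality null is calibrated for unstructured weights", {
  set.seed(27)
  coords <- NULL; labs <- character(0)
  for (h in 1:12) {
    base <- rnorm(3, sd = 4)
    coords <- rbind(coords, t(sapply(0:3, function(k) base + c(0, 0, 2 * k))))
    labs <- c(labs, rep(paste0("H", h), 4))
  }
  n_rep <- 200
  pv <- vapply(seq_len(n_rep), function(r) {
    w <- runif(48, 0.5, 1.5)
    inertia_permutation_test(spatial_distribution(coords, w), labs,
                             n_perm = 500, seed = 3000 + r)$p_value
  }, numeric(1))
  ci <- qbinom(c(0.025, 0.975), n_rep, 0.05)
  expect_gte(sum(pv <= 0.05), ci[1])
  expect_lte(sum(pv <= 0.05), ci[2])
})

test_that("border distances agree with an exhaustive voxel scan", {
  # point-cloud structure
  cloud <- structure_geometry("BNST", points = rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_equal(border_distance(c(0, 0, 0), cloud), 0)
  expect_equal(border_distance(c(6, 0, 0), cloud), 3)

  # mask structure: a 5-voxel cube at 2 mm spacing
  mask <- array(FALSE, c(9, 9, 9))
  mask[3:7, 3:7, 3:7] <- TRUE
  affine <- rbind(cbind(diag(3) * 2, c(-8, -8, -8)), c(0, 0, 0, 1))
  st <- structure_geometry("GPe", mask = mask, affine = affine)
  # exhaustive scan over all mask voxels that touch the outside
  vox <- which(mask, arr.ind = TRUE)
  on_border <- apply(vox, 1, function(v) {
    any(vapply(1:3, function(ax) {
      vm <- v; vm[ax] <- vm[ax] - 1
      vp <- v; vp[ax] <- vp[ax] + 1
      !mask[vm[1], vm[2], vm[3]] || !mask[vp[1], vp[2], vp[3]]
    }, logical(1)))
  })
  bvox <- vox[on_border, , drop = FALSE]
  bmm <- t(apply(bvox, 1, function(v) (affine %*% c(v - 1, 1))[1:3]))
  pt <- c(12, 1, 0.5)
  brute <- sqrt(min(rowSums((bmm - matrix(pt, nrow(bmm), 3, byrow = TRUE))^2)))
  expect_equal(border_distance(pt, st), brute)

  # 1-Lipschitz property
  set.seed(28)
  for (i in 1:20) {
    a <- rnorm(3, sd = 8); b <- a + rnorm(3, sd = 1)
    expect_lte(abs(border_distance(a, st) - border_distance(b, st)),
               sqrt(sum((a - b)^2)) + 1e-12)
  }
})

test_that("2D heatmaps are uniform for uniform power and peak near hotspots", {
  set.seed(29)
  coords <- cbind(runif(40, -15, -5), runif(40, 0, 8), runif(40, -8, 0))
  flat <- heatmap_2d(spatial_distribution(coords, rep(2, 40)), "axial",
                     grid_step_mm = 0.5)
  inside <- flat$values[!is.na(flat$values)]
  expect_true(all(abs(inside - 2) < 1e-6))

  # smoothing approximately preserves the interior mean
  w <- runif(40, 1, 3)
  sm <- heatmap_2d(spatial_distribution(coords, w), "axial", grid_step_mm = 0.5)
  raw <- heatmap_2d(spatial_distribution(coords, w), "axial", fwhm = 0,
                    grid_step_mm = 0.5)
  expect_equal(mean(sm$values, na.rm = TRUE), mean(raw$values, na.rm = TRUE),
               tolerance = 0.01)

  # hotspot argmax lands within 2 grid cells of the planted peak
  hot <- c(-10, 4)
  whot <- exp(-((coords[, 1] - hot[1])^2 + (coords[, 2] - hot[2])^2) / (2 * 2^2))
  hm <- heatmap_2d(spatial_distribution(coords, whot), "axial",
                   grid_step_mm = 0.5)
  idx <- which(hm$values == max(hm$values, na.rm = TRUE), arr.ind = TRUE)
  peak_near <- coords[which.max(whot), 1:2]
  expect_lt(abs(hm$gx[idx[1]] - peak_near[1]), 1.01)
  expect_lt(abs(hm$gy[idx[2]] - peak_near[2]), 1.01)
})
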