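test_that("generation is deterministic and truth is self-consistent", {
  g1 <- generate_animal(animal_spec(points_per_m2 = 1000, seed = 9))
  g2 <- generate_animal(animal_spec(points_per_m2 = 1000, seed = 9))
  expect_identical(g1$cloud$points, g2$cloud$points)
  expect_identical(unclass(g1$parameters), unclass(g2$parameters))

  pr <- g1$profiles
  ag <- seq(0.01, pr$L - 0.01, length.out = 2000)
  expect_equal(g1$parameters$height, max(pr$t(ag)), tolerance = 1e-4)
  expect_equal(g1$parameters$depth,
               pr$t(pr$a1) - pr$d(pr$a1), tolerance = 1e-12)
  expect_gte(g1$parameters$diagonal_length,
             g1$parameters$horizontal_length)
  expect_equal(g1$keypoints$P6[2L], g1$parameters$height)
  # the animal stands on the ground plane
  expect_equal(min(g1$cloud$points[, 2L]), 0, tolerance = 0.05)
  expect_error(animal_spec(body_length = -1), "positive")
})

test_that("doubling the abdomen semi-axis doubles the abdominal width", {
  t1 <- generate_animal(animal_spec(points_per_m2 = 500))$parameters
  t2 <- generate_animal(animal_spec(points_per_m2 = 500,
                                    abdomen_radius_c = 0.55,
                                    shoulder_halfwidth = 0.43))$parameters
  expect_equal(t2$abdominal_width / t1$abdominal_width, 2, tolerance = 0.02)
})

test_that("split_views respects poses, culling and ground truth", {
  g <- generate_animal(animal_spec(points_per_m2 = 1200))
  # identity pose, no culling: view == cloud
  v0 <- split_views(g$cloud, list(rt_identity(), rt_identity()),
                    cull = FALSE)
  expect_equal(v0[[1L]]$points, g$cloud$points)

  L <- g$spec$body_length
  ctr <- c(L / 2, 0.5, 0)
  # opposing cameras, longitudinally offset so leg/tail faces pointing
  # along the body axis are seen by at least one of them
  poses <- list(camera_pose(c(0.1 * L, 1.6, 2.5), ctr),
                camera_pose(c(0.9 * L, 0.2, -2.5), ctr))
  views <- split_views(g$cloud, poses)
  n <- n_points(g$cloud)
  # each view is roughly a half, the union covers >= 95% of the surface
  for (v in views) expect_lt(n_points(v), 0.95 * n)
  seen <- rep(FALSE, n)
  for (i in 1:2) {
    keep <- rowSums(g$cloud$normals *
                      sweep(-g$cloud$points, 2L, -poses[[i]]$p)) > 0
    seen <- seen | keep
  }
  expect_gte(mean(seen), 0.95)

  # registering with the ground-truth transforms reproduces the original
  v2_in_1 <- apply_transform(relative_pose(poses[[2L]], poses[[1L]]),
                             views[[2L]])
  v2_direct <- apply_transform(invert_transform(poses[[1L]]),
                               subset_cloud(g$cloud, keep))
  expect_points_equal(v2_in_1$points, v2_direct$points, tol = 1e-9)
  expect_error(split_views(g$cloud, list(rt_identity())), "at least 2")
  non <- point_cloud(g$cloud$points)
  expect_error(split_views(non, poses), "normals")
})

test_that("railing occlusion deletes exactly the banded points", {
  cyl <- make_cylinder(r = 0.3, len = 0.5, ring_spacing = 0.02, b0 = 0.5)
  none <- add_railing_occlusion(cyl, "b", numeric(0), 0.05)
  expect_equal(none$cloud$points, cyl$points)
  expect_equal(n_points(none$removed), 0L)

  occ <- add_railing_occlusion(cyl, "b", bar_positions = 0.5,
                               bar_width = 0.06)
  expect_equal(n_points(occ$cloud) + n_points(occ$removed), n_points(cyl))
  expect_true(all(abs(occ$removed$points[, 2L] - 0.5) < 0.03))
  expect_true(all(abs(occ$cloud$points[, 2L] - 0.5) >= 0.03))
  # analytic area fraction: the band |b - b0| < h cuts arcs of the ring
  # (within one grid point per arc of the ring discretisation)
  frac <- n_points(occ$removed) / n_points(cyl)
  n_ring <- sum(abs(cyl$points[, 1L] - cyl$points[1L, 1L]) < 1e-12)
  expect_lt(abs(frac - 2 * asin(0.03 / 0.3) / pi), 2 / n_ring)
})

test_that("add_noise jitters, injects the exact outlier count, seeds", {
  cyl <- make_cylinder(r = 0.3, len = 0.3)
  expect_equal(add_noise(cyl, 0, 0)$points, cyl$points)
  n <- n_points(cyl)
  noisy <- add_noise(cyl, sigma = 0.001, outlier_fraction = 0.05,
                     seed = 10)
  expect_equal(sum(noisy$labels == "outlier"), round(0.05 * n))
  expect_identical(noisy$points,
                   add_noise(cyl, 0.001, 0.05, seed = 10)$points)
  expect_error(add_noise(cyl, -1, 0), "sigma")
})

test_that("the outlier filter recovers injected outliers", {
  g <- generate_animal(animal_spec(points_per_m2 = 1500))
  noisy <- add_noise(g$cloud, sigma = 0.001, outlier_fraction = 0.02,
                     seed = 11)
  kept <- statistical_outlier_filter(noisy, k = 20, alpha = 1)
  injected <- sum(noisy$labels == "outlier")
  surviving <- sum(kept$labels == "outlier")
  expect_gte((injected - surviving) / injected, 0.9)
})

test_that("ground-truth landmarks co-transform with the scene", {
  withr::local_seed(91)
  g <- generate_animal(animal_spec(points_per_m2 = 500))
  tf <- random_rigid()
  moved_p4 <- apply_transform(tf, rbind(g$keypoints$P4))
  moved_p5 <- apply_transform(tf, rbind(g$keypoints$P5))
  # lengths are invariant under the rigid map
  expect_equal(sqrt(sum((moved_p4 - moved_p5)^2)),
               g$parameters$diagonal_length, tolerance = 1e-9)
})
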