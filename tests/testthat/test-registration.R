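test_that("compose_stereo satisfies O1 = G O2 + p for world points", {
  # identity calibration -> identity transform; pure translation passes
  id <- compose_stereo(stereo_calibration(diag(3), c(1, 0, 0),
                                          diag(3), c(0, 0, 0)))
  expect_equal(id$G, diag(3))
  expect_equal(id$p, c(1, 0, 0))

  withr::local_seed(41)
  for (i in 1:10) {
    G1 <- random_rotation(); G2 <- random_rotation()
    p1 <- rnorm(3); p2 <- rnorm(3)
    tf <- compose_stereo(stereo_calibration(G1, p1, G2, p2))
    # oracle: push random world points through both camera equations
    W <- matrix(rnorm(30), ncol = 3L)
    O1 <- W %*% t(G1) + rep(p1, each = 10L)
    O2 <- W %*% t(G2) + rep(p2, each = 10L)
    expect_points_equal(O1, apply_transform(tf, O2), tol = 1e-9)
  }
  expect_error(stereo_calibration(matrix(1, 3, 3), 1:3, diag(3), 1:3),
               "orthonormal")
})

test_that("distance_ratio handles the collinear three-point case", {
  expect_equal(distance_ratio(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), 0.5)
})

test_that("base_ratios intersects the symmetric cross at its centre", {
  b <- base_ratios(U = c(0, 0, 0), V = c(1, 1, 0),
                   W = c(2, 0, 0), Q = c(1, -1, 0))
  expect_equal(b$H, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(b$g1, 0.5, tolerance = 1e-12)
  expect_equal(b$g2, 0.5, tolerance = 1e-12)
  expect_error(base_ratios(c(0, 0, 0), c(0, 1, 0), c(1, 0, 0), c(1, 1, 0)),
               "parallel")
  expect_error(base_ratios(c(0, 0, 0), c(0, 1, 5), c(1, 0, 0), c(1, 1, 5)),
               "skew|outside|parallel")
})

test_that("intersection ratios are affine invariant", {
  withr::local_seed(42)
  for (i in 1:25) {
    U <- rnorm(3); W <- U + rnorm(3)
    t1 <- runif(1, 0.2, 0.8); H <- U + t1 * (W - U)
    d2 <- rnorm(3); t2 <- runif(1, 0.2, 0.8)
    V <- H - t2 * d2; Q <- V + d2
    b0 <- base_ratios(U, V, W, Q)
    A <- matrix(rnorm(9), 3, 3)
    while (abs(det(A)) < 0.1) A <- matrix(rnorm(9), 3, 3)
    sft <- rnorm(3)
    m <- function(x) drop(A %*% x) + sft
    b1 <- base_ratios(m(U), m(V), m(W), m(Q), tol = 1e-6)
    expect_lt(abs(b1$g1 - b0$g1), 1e-10)
    expect_lt(abs(b1$g2 - b0$g2), 1e-10)
  }
})

test_that("candidate_intersections interpolates along s1 -> s2", {
  h <- candidate_intersections(c(0, 0, 0), c(2, 0, 0), 0.5, 0.25)
  expect_equal(h$h1, c(1, 0, 0))
  expect_equal(h$h2, c(0.5, 0, 0))
  h0 <- candidate_intersections(c(1, 2, 3), c(4, 5, 6), 0, 1)
  expect_equal(h0$h1, c(1, 2, 3))
  expect_equal(h0$h2, c(4, 5, 6))
  expect_error(candidate_intersections(c(0, 0, 0), c(1, 0, 0), -0.1, 0.5),
               "\\[0, 1\\]")
  withr::local_seed(43)
  for (i in 1:20) {
    s1 <- rnorm(3); s2 <- rnorm(3); g <- runif(1)
    h <- candidate_intersections(s1, s2, g, g)$h1
    # collinear and at the right fraction
    expect_lt(abs(sqrt(sum((h - s1)^2)) / sqrt(sum((s2 - s1)^2)) - g),
              1e-12)
    cr <- pcmorph:::cross3(h - s1, s2 - s1)
    expect_lt(sqrt(sum(cr^2)), 1e-10)
  }
})

test_that("coarse_4pcs recovers identity and a known transform", {
  cl <- small_animal(density = 800)
  # with the whole target available the congruent set is exact
  tf0 <- coarse_4pcs(cl, cl, delta = 0.01, n_bases = 6, seed = 44,
                     target_subsample = n_points(cl))
  expect_lt(rotation_angle(tf0$G), 1e-6)
  expect_lt(sqrt(sum(tf0$p^2)), 1e-6)

  # 500-point capture: delta must sit near the subsampled point spacing
  cl5 <- small_animal(density = 250)
  truth <- rigid_transform(rotation_about_axis("b", 25 * pi / 180),
                           c(0.3, 0.1, -0.2))
  tgt <- apply_transform(truth, cl5)
  est <- coarse_4pcs(cl5, tgt, delta = 0.05, n_bases = 12, seed = 45)
  expect_lt(rotation_angle(est$G %*% t(truth$G)), 0.05)
  expect_lt(sqrt(sum((est$p - truth$p)^2)), 0.05)
})

test_that("coarse_4pcs fails loudly on non-overlapping clouds", {
  withr::local_seed(46)
  a <- point_cloud(matrix(runif(300), ncol = 3L))
  b <- point_cloud(matrix(runif(300) + 20, ncol = 3L))
  expect_error(coarse_4pcs(a, b, delta = 1e-4, n_bases = 4, seed = 1),
               "alignment failure")
  expect_error(coarse_4pcs(point_cloud(rbind(c(0, 0, 0))), a, delta = 0.1),
               "4 points")
})

test_that("icp is exact on identical clouds and recovers small motions", {
  cl <- small_animal(density = 800)
  res <- icp(cl, cl)
  expect_equal(res$error, 0)
  expect_lt(rotation_angle(res$transform$G), 1e-9)

  truth <- rigid_transform(rotation_about_axis(c(1, 2, 0.5), 12 * pi / 180),
                           c(0.05, -0.04, 0.08))
  res2 <- icp(cl, apply_transform(truth, cl), max_iter = 80)
  expect_lt(rotation_angle(res2$transform$G %*% t(truth$G)), 1e-3)
  expect_lt(sqrt(sum((res2$transform$p - truth$p)^2)), 1e-3)
  expect_lt(res2$error, 1e-10)
  expect_true(all(diff(res2$errors) <= 1e-12))
  expect_error(icp(point_cloud(matrix(numeric(0), 0, 3)), cl), "non-empty")
})

test_that("stitch concatenates, references and deduplicates", {
  cl <- make_ellipsoid(0.5, 0.5, 0.5, n_lat = 20, n_lon = 40)
  expect_equal(stitch(list(cl), list(rt_identity()))$points, cl$points)

  # two half-spheres with exact transforms rebuild the full bounding box
  left <- subset_cloud(cl, cl$points[, 3L] <= 0)
  right <- subset_cloud(cl, cl$points[, 3L] > 0)
  tf <- random_rigid()
  right_moved <- apply_transform(invert_transform(tf), right)
  merged <- stitch(list(left, right_moved), list(tf))
  expect_points_equal(apply(merged$points, 2L, range),
                      apply(cl$points, 2L, range), tol = 1e-9)

  dup <- bind_clouds(cl, cl)
  merged2 <- stitch(list(dup), list(rt_identity()), merge_radius = 1e-3)
  expect_equal(n_points(merged2), n_points(cl))
  expect_error(stitch(list(cl, cl, cl), list(rt_identity())), "transform")
})
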