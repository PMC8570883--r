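norm_fixture <- function() {
  # a normalised animal-like cloud standing on b = 0: ellipsoid body with a
  # head-side crest so the orientation is unambiguous
  ell <- make_ellipsoid(ra = 0.8, rb = 0.3, rc = 0.25, n_lat = 40,
                        n_lon = 80, center = c(0, 0.5, 0))
  crest <- make_ellipsoid(ra = 0.25, rb = 0.12, rc = 0.1, n_lat = 15,
                          n_lon = 30, center = c(0.45, 0.75, 0))
  bind_clouds(ell, crest)
}

test_that("normalize_pose is the identity on a normalised cloud", {
  cl <- norm_fixture()
  res <- normalize_pose(cl, ground_plane(c(0, 1, 0), 0))
  expect_lt(rotation_angle(res$transform$G), 1e-9)
  expect_lt(max(abs(res$transform$p)), 0.1)   # centroid recentring only
  expect_equal(res$ground$normal, c(0, 1, 0))
})

test_that("normalize_pose undoes a known yaw within 1e-6 rad", {
  cl <- norm_fixture()
  base <- normalize_pose(cl, ground_plane(c(0, 1, 0), 0))
  rot <- rigid_transform(rotation_about_axis("b", 30 * pi / 180),
                         c(0.3, 0, -0.2))
  moved <- apply_transform(rot, cl)
  res <- normalize_pose(moved, ground_plane(c(0, 1, 0), 0))
  # the two normalised clouds coincide
  expect_lt(max(abs(res$cloud$points - base$cloud$points)), 1e-6)
  # and the composed rotation equals the inverse of the applied yaw
  rel <- res$transform$G %*% rot$G %*% t(base$transform$G)
  expect_lt(rotation_angle(rel), 1e-6)
})

test_that("normalize_pose levels a tilted ground plane", {
  cl <- norm_fixture()
  tilt <- rigid_transform(rotation_about_axis("a", 10 * pi / 180))
  moved <- apply_transform(tilt, cl)
  gr <- ground_plane(drop(tilt$G %*% c(0, 1, 0)), 0)
  res <- normalize_pose(moved, gr)
  expect_equal(res$ground$normal, c(0, 1, 0), tolerance = 1e-9)
  expect_error(normalize_pose(make_ellipsoid(0.3, 0.3, 0.3),
                              ground_plane(c(0, 1, 0), 0)), "isotropic")
})

test_that("symmetry_plane: cross product, symmetric fit, equivariance", {
  cl <- norm_fixture()
  gr <- ground_plane(c(0, 1, 0), 0)
  model <- symmetry_plane(cl, gr)
  expect_equal(model$phi_p, c(0, 0, -1))
  expect_lt(abs(model$mu1), 1e-5)
  expect_lt(abs(model$mu0), 1e-3)

  shift <- apply_transform(rigid_transform(diag(3), c(0, 0, 0.37)), cl)
  model2 <- symmetry_plane(shift, gr)
  expect_equal(model2$mu0 - model$mu0, 0.37, tolerance = 1e-9)
  expect_equal(model2$c0_tail - model$c0_tail, 0.37, tolerance = 1e-9)
})

test_that("symmetry model on the synthetic animal recovers the axis", {
  # noiseless bilaterally symmetric animal: the fitted line is the axis
  g <- generate_animal(animal_spec(points_per_m2 = 3000))
  model <- symmetry_plane(g$cloud, g$ground)
  expect_lt(abs(model$mu0), 1e-3)
  expect_lt(abs(model$mu1), 1e-6)
})

test_that("reflection is an involutive isometry", {
  model <- structure(list(mu0 = 0.3, mu1 = 0.2), class = "symmetry_model")
  withr::local_seed(81)
  X <- matrix(rnorm(150), ncol = 3L)
  XR <- reflect_points(X, model)
  expect_points_equal(reflect_points(XR, model), X, tol = 1e-12)
  expect_points_equal(as.matrix(dist(XR)), as.matrix(dist(X)), tol = 1e-9)
  # b is untouched
  expect_equal(XR[, 2L], X[, 2L])
  # simple numeric case: c0 = 1 maps (1,2,3) to (1,2,-1)
  m0 <- structure(list(mu0 = 1, mu1 = 0), class = "symmetry_model")
  expect_equal(drop(reflect_points(rbind(c(1, 2, 3)), m0)), c(1, 2, -1))
})

test_that("mirroring a half-ellipsoid rebuilds the symmetric extent", {
  ell <- make_ellipsoid(ra = 0.8, rb = 0.4, rc = 0.3)
  half <- subset_cloud(ell, ell$points[, 3L] > 0)
  model <- structure(list(mu0 = 0, mu1 = 0), class = "symmetry_model")
  out <- mirror_cloud(half, model)
  expect_equal(abs(min(out$points[, 3L])), max(out$points[, 3L]),
               tolerance = 1e-9)
  expect_equal(n_points(out), 2L * n_points(half))
  expect_setequal(unique(out$labels), c("original", "mirrored"))
  expect_error(mirror_cloud(half, model, side = "negative"), "no points")
})

test_that("measure_body evaluates the formulas", {
  gr <- ground_plane(c(0, 1, 0), 0)
  model <- structure(list(mu0 = 0, mu1 = 0), class = "symmetry_model")
  kp <- structure(list(P1 = c(1, 0.5, 0.3), P4 = c(0, 0, 0.25),
                       P5 = c(3, 4, 0.25), P6 = c(0.5, 1.4, 0),
                       PU = c(1, 1.0, 0), PD = c(1, 0.2, 0)),
                  class = "keypoints")
  # 3-4-5 triangle between P4 and P5 (a and b components)
  bp <- measure_body(kp, model, gr)
  expect_equal(bp$diagonal_length, 5)
  expect_equal(bp$horizontal_length, 3)
  expect_equal(bp$shoulder_width, 0.5)    # twice |c4| = 0.25
  expect_equal(bp$abdominal_width, 0.6)
  expect_equal(bp$height, 1.4)
  expect_equal(bp$depth, 0.8)
  kp$P6 <- NULL
  expect_error(measure_body(kp, model, gr), "P6")
  expect_error(body_parameters(1, 2, 0.1, 0.1, 1, 0.5), "diagonal")
})

test_that("widths are invariant to longitudinal shifts and mirroring", {
  gr <- ground_plane(c(0, 1, 0), 0)
  model <- structure(list(mu0 = -0.1, mu1 = 0), class = "symmetry_model")
  kp <- structure(list(P1 = c(1, 0.5, 0.3), P4 = c(0.2, 0.6, 0.25),
                       P5 = c(-1, 0.5, -0.1), P6 = c(0.5, 1.4, 0),
                       PU = c(1, 1.0, 0), PD = c(1, 0.2, 0)),
                  class = "keypoints")
  bp <- measure_body(kp, model, gr)
  kp2 <- kp
  for (nm in c("P1", "P4", "P5", "P6", "PU", "PD")) {
    kp2[[nm]][1L] <- kp2[[nm]][1L] + 2.5            # translate along a
    kp2[[nm]][3L] <- 2 * (-0.1) - kp2[[nm]][3L]     # reflect across line
  }
  bp2 <- measure_body(kp2, model, gr)
  expect_equal(bp2$shoulder_width, bp$shoulder_width, tolerance = 1e-12)
  expect_equal(bp2$abdominal_width, bp$abdominal_width, tolerance = 1e-12)
})

test_that("chest_circumference matches analytic cross-sections", {
  cyl <- make_cylinder(r = 0.4, len = 0.2, ring_spacing = 0.015)
  got <- chest_circumference(cyl, a_center = 0.1, half_width = 0.02)
  expect_equal(got, 2 * pi * 0.4, tolerance = 0.01 * 2 * pi * 0.4)

  # homogeneity: scaling the cloud scales the estimate
  sc <- point_cloud(cyl$points * 2)
  got2 <- chest_circumference(sc, a_center = 0.2, half_width = 0.04)
  expect_equal(got2 / got, 2, tolerance = 0.02)

  # open section errors out with advice
  half <- subset_cloud(cyl, cyl$points[, 3L] > 0)
  expect_error(chest_circumference(half, 0.1, 0.02), "mirror")
  expect_error(chest_circumference(cyl, 10, 0.02), "points")
})

test_that("evaluate_measurements computes MAE and MRE", {
  t1 <- body_parameters(1, 1, 0.5, 0.6, 1.4, 0.8)
  expect_true(all(evaluate_measurements(t1, t1)$mae == 0))
  m1 <- body_parameters(1.1, 1, 0.5, 0.6, 1.4, 0.8)
  ev <- evaluate_measurements(m1, t1)
  expect_equal(ev$mae[ev$parameter == "diagonal_length"], 0.1)
  expect_equal(ev$mre_pct[ev$parameter == "diagonal_length"], 10)

  withr::local_seed(82)
  frames_t <- lapply(1:6, function(i) {
    body_parameters(runif(1, 1, 2), runif(1, 0.5, 1), runif(1, 0.3, 0.6),
                    runif(1, 0.4, 0.8), runif(1, 1, 1.5), runif(1, 0.5, 1))
  })
  frames_m <- lapply(frames_t, function(f) {
    f$height <- f$height + 0.02; f$depth <- f$depth * 1.05; f
  })
  ev2 <- evaluate_measurements(frames_m, frames_t)
  expect_equal(ev2$mae[ev2$parameter == "height"], 0.02, tolerance = 1e-12)
  expect_equal(ev2$mre_pct[ev2$parameter == "depth"], 5, tolerance = 1e-9)
  expect_error(evaluate_measurements(frames_m[1:2], frames_t), "differ")
})
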