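make_range <- function(a, v) data.frame(a = a, v = v, vs = v)

test_that("find_P1 picks the max-chord-distance point", {
  # semicircle on its chord: apex at distance r
  th <- seq(0, pi, length.out = 21)
  sil <- make_range(cos(th), sin(th))
  p1 <- find_P1(sil)
  expect_equal(p1$distance, 1, tolerance = 1e-9)
  expect_equal(p1$a, 0, tolerance = 1e-9)

  flat <- find_P1(make_range(1:5, rep(2, 5)))
  expect_true(flat$degenerate)

  withr::local_seed(71)
  for (i in 1:25) {
    a <- sort(runif(20)); v <- runif(20)
    sil <- make_range(a, v)
    got <- find_P1(sil)
    d <- abs((v[20] - v[1]) * (a - a[1]) - (a[20] - a[1]) * (v - v[1])) /
      sqrt((a[20] - a[1])^2 + (v[20] - v[1])^2)
    expect_equal(got$index, which.max(d))
  }
  expect_error(find_P1(make_range(c(0, 0), c(1, 2))), "at least 3")
})

test_that("slope_transition finds the first + to - flip of omega", {
  # single candidate at 45 degrees
  r <- make_range(c(0, 1), c(0, 1))
  omega <- atan((1 - 0) / (1 - 0))
  expect_equal(omega, pi / 4)

  rising <- make_range(0:10, (0:10) * 0.5)
  expect_error(slope_transition(rising, start = c(0, 0)),
               class = "pcm_not_found")

  # two-bump profile: abdomen bump then shoulder bump, saddle between
  a <- seq(0, 10, by = 0.25)
  v <- 1.2 * exp(-((a - 3) / 1.5)^2) + 0.9 * exp(-((a - 7) / 1.2)^2)
  prof <- make_range(a, v)
  start <- c(3, 0.6)
  got <- slope_transition(prof, start = start)
  # brute force: first omega < 0 after an earlier omega > 0
  cand <- which(a > 3)
  om <- atan((v[cand] - 0.6) / (a[cand] - 3))
  pos_seen <- cumsum(om > 0) > 0
  brute <- cand[which(om < 0 & c(FALSE, head(pos_seen, -1)))[1]]
  expect_equal(got$index, brute)
  # the flip happens in the saddle, between the bumps
  expect_gt(got$a, 3); expect_lt(got$a, 7)
})

test_that("the ordinate gate filters candidates before the scan", {
  a <- seq(0, 6, by = 0.5)
  v <- c(1, 0.9, 0.2, 0.1, 0.8, 0.9, 1.0, 0.9, 0.8, 0.3, 0.2, 0.1, 0.05)
  prof <- make_range(a, v)
  ungated <- slope_transition(prof, start = c(0, 0.85))
  gated <- slope_transition(prof, start = c(0, 0.85), gate_min = 0.5)
  expect_lt(ungated$a, gated$a)  # the gate skips the low early dip
})

test_that("find_P4 is the farthest point from the P2-P3 chord", {
  th <- seq(0, pi, length.out = 41)
  arc <- make_range(5 - 4 * cos(th), 2 + sin(th) * 3)
  P2 <- list(a = arc$a[1], v = arc$v[1])
  P3 <- list(a = arc$a[41], v = arc$v[41])
  got <- find_P4(arc, P2, P3)
  expect_equal(got$a, 5, tolerance = 1e-9)

  line <- make_range(0:10, 0:10)
  got2 <- find_P4(line, list(a = 0, v = 0), list(a = 10, v = 10))
  expect_true(got2$degenerate)

  withr::local_seed(72)
  for (i in 1:25) {
    a <- sort(runif(15)); v <- runif(15)
    prof <- make_range(a, v)
    P2 <- list(a = a[1], v = v[1]); P3 <- list(a = a[15], v = v[15])
    d <- abs((v[15] - v[1]) * (a - a[1]) - (a[15] - a[1]) * (v - v[1]))
    expect_equal(find_P4(prof, P2, P3)$index, which.max(d))
  }
})

test_that("find_P5 is the kNN centroid of the tail extreme", {
  withr::local_seed(73)
  pts <- matrix(runif(300, 1, 2), ncol = 3L)
  cl <- point_cloud(pts)
  expect_equal(find_P5(cl, k = 1), pts[which.min(pts[, 1L]), ])
  got <- find_P5(cl, k = 7)
  tail_pt <- pts[which.min(pts[, 1L]), ]
  d <- sqrt(rowSums(sweep(pts, 2L, tail_pt)^2))
  expect_equal(got, colMeans(pts[order(d)[1:7], ]))
  expect_gte(got[1L], min(pts[, 1L]))
  expect_warning(p5 <- find_P5(cl, k = 500), "clamping")
  expect_equal(p5, colMeans(pts))
})

test_that("find_P6 and find_PU_PD centre the slab extremes", {
  # flat-topped back: top at b = 2 over a plateau
  withr::local_seed(74)
  a <- runif(2000, 0, 4)
  b <- runif(2000, 0, 2)
  cl <- point_cloud(cbind(a, b, 0))
  p6 <- find_P6(cl, a_mid = 2, slab_width = 0.25, n_slabs = 2)
  expect_equal(p6[2L], 2, tolerance = 0.02)
  expect_true(abs(p6[1L] - 2) < 0.5)

  ud <- find_PU_PD(cl, a_P1 = 2, slab_width = 0.25, n_slabs = 2)
  expect_gt(ud$PU[2L], ud$PD[2L])
  expect_equal(ud$PU[2L] - ud$PD[2L], 2, tolerance = 0.04)
})

test_that("PU/PD on an ellipsoid give the analytic depth", {
  ell <- make_ellipsoid(ra = 0.8, rb = 0.4, rc = 0.3, n_lat = 60,
                        n_lon = 120)
  ud <- find_PU_PD(ell, a_P1 = 0, slab_width = 0.03, n_slabs = 2)
  expect_equal(ud$PU[2L] - ud$PD[2L], 0.8, tolerance = 0.02)
})

test_that("silhouette of an ellipsoid is the analytic outline", {
  ell <- make_ellipsoid(ra = 0.8, rb = 0.4, rc = 0.3, n_lat = 80,
                        n_lon = 160)
  sil <- silhouette(ell, slab_width = 0.05, smooth_window = 0)
  expect_lte(nrow(sil$top), 32L)  # point count <= slab count
  w_true <- 0.3 * sqrt(pmax(0, 1 - (sil$top$a / 0.8)^2))
  expect_lt(max(abs(sil$top$v - w_true)), 0.05)
  # single-slab cloud gives a single silhouette point
  thin <- subset_cloud(ell, abs(ell$points[, 1L]) < 0.02)
  sil1 <- silhouette(thin, slab_width = 1)
  expect_equal(nrow(sil1$top), 1L)
})

test_that("key-point detection is invariant to in-plane translation", {
  cl <- small_animal(density = 2500)
  kp1 <- suppressWarnings(locate_keypoints(cl, keypoint_config(slab_width = 0.03)))
  shift <- rigid_transform(diag(3), c(0.7, 0, -0.4))
  kp2 <- suppressWarnings(
    locate_keypoints(apply_transform(shift, cl),
                     keypoint_config(slab_width = 0.03)))
  for (nm in c("P1", "P4", "P5", "P6", "PU", "PD")) {
    expect_points_equal(rbind(kp2[[nm]]), rbind(kp1[[nm]] + shift$p),
                        tol = 1e-6)
  }
})

test_that("detected key points sit near the generator's ground truth", {
  g <- generate_animal(animal_spec(points_per_m2 = 4000))
  kp <- suppressWarnings(
    locate_keypoints(g$cloud, keypoint_config(slab_width = 0.03)))
  for (nm in c("P1", "P2", "P3", "P4", "P5", "PU", "PD")) {
    # within 2 slab widths of truth on the longitudinal axis
    expect_lt(abs(kp[[nm]][1L] - g$keypoints[[nm]][1L]), 0.06)
  }
  # P6 is defined by its height (its a is the centre of the slab window)
  expect_lt(abs(kp$P6[2L] - g$keypoints$P6[2L]), 0.01)
})
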