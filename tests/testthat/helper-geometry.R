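# Geometric fixtures built in code: cylinders, ellipsoids, rings, random
# rotations. All deterministic given the caller's seed.

# Cylinder surface along axis a: rings of radius r centred at (b0, 0).
make_cylinder <- function(r = 0.4, len = 0.6, ring_spacing = 0.02,
                          b0 = 0.5) {
  n_ring <- max(8L, round(2 * pi * r / ring_spacing))
  theta <- 2 * pi * (seq_len(n_ring) - 1L) / n_ring
  a <- seq(ring_spacing / 2, len, by = ring_spacing)
  g <- expand.grid(a = a, th = theta)
  point_cloud(cbind(g$a, b0 + r * cos(g$th), r * sin(g$th)))
}

# Ellipsoid surface with semi-axes (ra, rb, rc), sampled on a lat/long grid.
make_ellipsoid <- function(ra = 0.8, rb = 0.4, rc = 0.3, n_lat = 40,
                           n_lon = 80, center = c(0, 0, 0)) {
  lat <- seq(-pi / 2 + 0.02, pi / 2 - 0.02, length.out = n_lat)
  lon <- 2 * pi * (seq_len(n_lon) - 1L) / n_lon
  g <- expand.grid(lat = lat, lon = lon)
  point_cloud(cbind(center[1] + ra * cos(g$lat) * cos(g$lon),
                    center[2] + rb * sin(g$lat),
                    center[3] + rc * cos(g$lat) * sin(g$lon)))
}

random_rotation <- function() {
  ax <- rnorm(3)
  rotation_about_axis(ax, runif(1, 0, pi))
}

random_rigid <- function(max_angle = pi, max_trans = 1) {
  rigid_transform(rotation_about_axis(rnorm(3), runif(1, 0, max_angle)),
                  runif(3, -max_trans, max_trans))
}

# small animal cloud for registration tests
small_animal <- function(density = 1500, seed = 1) {
  generate_animal(animal_spec(points_per_m2 = density, seed = seed))$cloud
}

expect_points_equal <- function(x, y, tol = 1e-9) {
  expect_equal(dim(x), dim(y))
  expect_lt(max(abs(x - y)), tol)
}
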