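test_that("simplex sphere construction yields 3-connected duals of subdivided icosahedra", {
  m0 <- build_simplex_sphere(c(0, 0, 0), 5, 0)
  expect_equal(n_vertices(m0), 20L)
  expect_silent(validate_mesh(m0))
  expect_true(all(apply(m0$neighbours, 1L,
                        function(r) length(unique(r)) == 3L)))
  expect_equal(sqrt(rowSums(m0$vertices^2)), rep(5, 20), tolerance = 1e-9)

  m1 <- build_simplex_sphere(c(1, -2, 3), 2.5, 1)
  expect_equal(n_vertices(m1), 80L)
  expect_silent(validate_mesh(m1))
  d <- sqrt(rowSums(sweep(m1$vertices, 2L, c(1, -2, 3))^2))
  expect_equal(d, rep(2.5, 80), tolerance = 1e-9)

  expect_error(build_simplex_sphere(c(0, 0, 0), -1), "positive")
  expect_error(build_simplex_sphere(c(0, 0, 0), 0), "positive")
})

test_that("simplex angle is zero when flat, constant on spheres, monotone in normal lift", {
  # hand-built vertex with 3 neighbours in a plane
  flat <- structure(list(
    vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(-0.5, 0.9, 0),
                     c(-0.5, -0.9, 0)),
    neighbours = rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L),
                       c(1L, 2L, 3L)),
    faces = list(), vertex_faces = NULL, prev_vertices = NULL,
    ref_eps = NULL, ref_angle = NULL), class = "simplex_mesh")
  expect_equal(simplex_angle(flat, 1L), 0, tolerance = 1e-12)

  # a regular simplex sphere (dual icosahedron): one shared positive angle
  m <- build_simplex_sphere(c(0, 0, 0), 4, 0)
  ang <- simplex_angle(m)
  expect_true(all(ang > 0))
  expect_lt(diff(range(ang)), 1e-6)

  # lifting the central vertex along +normal increases the angle monotonically
  lifted <- flat
  angles <- vapply(seq(0.05, 0.5, length.out = 6L), function(h) {
    lifted$vertices[1L, ] <- c(0, 0, h)
    simplex_angle(lifted, 1L)
  }, numeric(1L))
  expect_true(all(diff(angles) > 0))
  expect_true(all(angles > 0))

  # degenerate (collinear) neighbours error
  degen <- flat
  degen$vertices[3L, ] <- c(2, 0, 0)
  degen$vertices[4L, ] <- c(3, 0, 0)
  expect_error(simplex_angle(degen, 1L), "degenerate")
})

test_that("normals point outward and mean curvature matches 1/r on spheres", {
  m <- build_simplex_sphere(c(2, 2, 2), 6, 2)
  n <- vertex_normal(m)
  expect_equal(row_norms_test(n), rep(1, n_vertices(m)), tolerance = 1e-12)
  radial <- sweep(m$vertices, 2L, c(2, 2, 2))
  radial <- radial / row_norms_test(radial)
  expect_true(all(rowSums(n * radial) > 0.99))
  expect_equal(mean_curvature(m), rep(1 / 6, n_vertices(m)),
               tolerance = 0.05 / 6)
})

test_that("simplex angle and curvature are invariant under rigid rotation", {
  set.seed(11)
  m <- build_simplex_sphere(c(0, 0, 0), 3, 1)
  m$vertices <- m$vertices + 0.2 * matrix(stats::rnorm(240), ncol = 3L)
  for (k in 1:3) {
    R <- random_rotation()
    mr <- transform_mesh(m, R, c(4, -1, 2))
    expect_equal(simplex_angle(mr), simplex_angle(m), tolerance = 1e-8)
    expect_equal(mean_curvature(mr), mean_curvature(m), tolerance = 1e-8)
  }
})

test_that("refinement multiplies vertices, preserves invariants and hugs the surface", {
  m <- build_simplex_sphere(c(10, 10, 10), 5, 1)
  r1 <- refine(m)
  expect_gte(n_vertices(r1), 2L * n_vertices(m))
  expect_silent(validate_mesh(r1))
  expect_true(all(apply(r1$neighbours, 1L,
                        function(r) length(unique(r)) == 3L)))
  dev <- abs(sqrt(rowSums(sweep(r1$vertices, 2L, c(10, 10, 10))^2)) - 5)
  expect_lt(max(dev) / 5, 0.05)
  r2 <- refine(r1)
  expect_gte(n_vertices(r2), 4L * n_vertices(m))
  # Euler characteristic of the dual triangulation stays 2
  for (mesh in list(m, r1, r2)) {
    V <- n_vertices(mesh)
    expect_equal(V - 3L * V / 2L + length(mesh$faces), 2L)
  }
})

test_that("rasterization recovers sphere volumes and commutes with voxel shifts", {
  g <- scalar_volume(array(0, c(20, 20, 20)))
  m <- build_simplex_sphere(c(9.5, 9.5, 9.5), 5, 2)
  vol <- sum(rasterize(m, g)$values)
  expect_lt(abs(vol - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.10)

  # mesh fully outside the grid -> empty mask
  far <- build_simplex_sphere(c(100, 100, 100), 5, 1)
  expect_equal(sum(rasterize(far, g)$values), 0L)

  # translating by exactly one voxel translates the mask
  a <- rasterize(build_simplex_sphere(c(9.5, 9.5, 9.5), 5, 1), g)$values
  b <- rasterize(build_simplex_sphere(c(10.5, 9.5, 9.5), 5, 1), g)$values
  expect_identical(a[1:19, , ], b[2:20, , ])

  # volume error shrinks at least twofold when resolution doubles
  mfine <- build_simplex_sphere(c(16, 16, 16), 10, 3)
  v1 <- sum(rasterize(mfine, scalar_volume(array(0, c(32, 32, 32))))$values)
  g2 <- scalar_volume(array(0, c(64, 64, 64)), spacing = c(0.5, 0.5, 0.5))
  v2 <- sum(rasterize(mfine, g2)$values) * 0.125
  truth <- mesh_volume_test(mfine)
  expect_lt(abs(v2 - truth), abs(v1 - truth) / 2 + 1e-9)
})

test_that("rasterization respects anisotropic spacing", {
  g <- scalar_volume(array(0, c(40, 20, 10)), spacing = c(0.5, 1, 2))
  m <- build_simplex_sphere(c(9.75, 9.5, 9), 5, 2)
  vol_mm3 <- sum(rasterize(m, g)$values) * prod(g$spacing)
  expect_lt(abs(vol_mm3 - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.10)
})

test_that("mesh OBJ round trip preserves geometry and simplex structure", {
  m <- build_simplex_sphere(c(1, 2, 3), 4, 1)
  path <- file.path(tempdir(), "mesh.obj")
  write_mesh(m, path)
  m2 <- read_mesh_obj(path)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-6)
  expect_identical(m2$neighbours, m$neighbours)
  expect_silent(validate_mesh(m2))
  # orientation survives: normals still point outward
  n <- vertex_normal(m2)
  radial <- sweep(m2$vertices, 2L, c(1, 2, 3))
  expect_true(all(rowSums(n * radial) > 0))
  vtk <- file.path(tempdir(), "mesh.vtk")
  write_mesh(m, vtk)
  expect_true(any(grepl("POLYGONS", readLines(vtk))))
})
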