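test_that("stage parameters enforce weight ranges and threshold ordering", {
  p <- stage_parameters()
  expect_equal(p$w_balloon, 0.08)
  expect_equal(p$smoothness_scale, 12L)
  expect_error(stage_parameters(w_balloon = 1.2), "\\[0, 1\\]")
  expect_error(stage_parameters(w_internal = -0.1), "\\[0, 1\\]")
  expect_error(stage_parameters(T_low = 2, T_high = 1), "T_low")
  expect_error(stage_parameters(smoothness_scale = 0), "smoothness_scale")
})

test_that("internal force vanishes at the reference configuration and restores tangent perturbations", {
  m <- build_simplex_sphere(c(0, 0, 0), 5, 1)
  p <- stage_parameters(smoothness_scale = 3L)
  f <- internal_force(m, p)
  expect_lt(max(row_norms_test(f)), 1e-10)

  # pure-tangent perturbation of one vertex is pushed back
  geo <- multiseg:::simplex_geometry(m)
  i <- 7L
  tangent <- c(-geo$n[i, 2L], geo$n[i, 1L], 0)
  tangent <- tangent / sqrt(sum(tangent^2))
  m2 <- m
  m2$vertices[i, ] <- m2$vertices[i, ] + 0.3 * tangent
  f2 <- internal_force(m2, p)
  expect_gt(sum(f2[i, ] * (-tangent)), 0)
})

test_that("larger smoothness scale damps radial noise faster", {
  set.seed(3)
  base <- build_simplex_sphere(c(0, 0, 0), 5, 1)
  noisy <- base
  noise <- 0.25 * matrix(stats::rnorm(3L * n_vertices(base)), ncol = 3L)
  noisy$vertices <- noisy$vertices + noise
  noisy$prev_vertices <- noisy$vertices
  run_internal <- function(mesh, scale) {
    p <- stage_parameters(smoothness_scale = scale, gamma = 1)
    nb <- multiseg:::vertex_neighbourhoods(mesh, scale)
    for (k in 1:10) {
      f <- internal_force(mesh, p, nb)
      mesh <- step_mesh(mesh, f, 0 * f, p)
    }
    stats::var(row_norms_test(mesh$vertices))
  }
  v12 <- run_internal(noisy, 12L)
  v3 <- run_internal(noisy, 3L)
  expect_lt(v12, v3)
})

test_that("gradient force points toward a step edge, is zero on uniform images, and breaks ties deterministically", {
  vals <- array(0, c(24, 24, 24))
  vals[13:24, , ] <- 100              # step edge at world x ~ 11.5
  img <- scalar_volume(vals)
  # vertices facing the edge sit ~2 voxels away from it
  m <- build_simplex_sphere(c(8.5, 11.5, 11.5), 1, 1)
  p <- stage_parameters()
  f <- gradient_force(img, m, p)
  geo <- multiseg:::simplex_geometry(m)
  facing <- geo$n[, 1L] > 0.9
  expect_true(any(facing))
  expect_true(all(f[facing, 1L] > 0))

  uni <- scalar_volume(array(7, c(24, 24, 24)))
  expect_equal(gradient_force(uni, m, p), matrix(0, n_vertices(m), 3L))

  # tie case: two voxels share the max gradient; nearer one wins
  g <- array(0, c(15, 15, 15))
  g[10, 8, 8] <- 5   # distance 2 from vertex voxel (8,8,8)
  g[11, 8, 8] <- 5   # distance 3
  gv <- scalar_volume(g)
  single <- build_simplex_sphere(c(7, 7, 7), 0.8, 0)
  single$vertices[1L, ] <- c(7, 7, 7)  # vertex voxel (8,8,8) 1-based
  fs <- multiseg:::search_force(gv, single, 3L, 0)
  # winning target is x = 9 (0-based), i.e. displacement along +x of ~2
  # projected on the normal; verify via the expected target voxel
  off <- multiseg:::offsets_within_radius(3L)
  gat <- multiseg:::gather_neighbourhood(gv, matrix(c(8L, 8L, 8L), 1L), off$offsets)
  best <- max.col(gat$vals, ties.method = "first")
  expect_equal(c(gat$cx[1L, best], gat$cy[1L, best], gat$cz[1L, best]),
               c(10L, 8L, 8L))

  # equal value and distance: lowest voxel index (smaller z/y/x) wins
  g2 <- array(0, c(15, 15, 15))
  g2[8, 8, 6] <- 5
  g2[8, 8, 10] <- 5
  gv2 <- scalar_volume(g2)
  gat2 <- multiseg:::gather_neighbourhood(gv2, matrix(c(8L, 8L, 8L), 1L),
                                          off$offsets)
  best2 <- max.col(gat2$vals, ties.method = "first")
  expect_equal(gat2$cz[1L, best2], 6L)
})

test_that("edge force finds a bright plane along the normal and truncates at the volume boundary", {
  vals <- array(0, c(24, 24, 24))
  vals[16, , ] <- 50                  # bright plane at x-index 16 (0-based 15)
  img <- scalar_volume(vals)
  m <- build_simplex_sphere(c(12.5, 11.5, 11.5), 2, 1)
  p <- stage_parameters(gradient_search_radius = 4L)
  f <- edge_force(img, m, p)
  geo <- multiseg:::simplex_geometry(m)
  facing <- geo$n[, 1L] > 0.95
  expect_true(all(rowSums(f[facing, , drop = FALSE] *
                          geo$n[facing, , drop = FALSE]) > 0))

  # a mesh poking out of the volume: no error, finite forces
  m2 <- build_simplex_sphere(c(1, 1, 1), 3, 1)
  expect_true(all(is.finite(edge_force(img, m2, p))))
})

test_that("balloon force is the pass-band indicator times the normal", {
  m <- build_simplex_sphere(c(5.5, 5.5, 5.5), 2, 1)
  p <- stage_parameters()   # T_low = -0.99, T_high = 1.0
  geo <- multiseg:::simplex_geometry(m)

  all_object <- scalar_volume(array(1.0, c(12, 12, 12)))
  expect_equal(balloon_force(all_object, m, p), geo$n, tolerance = 1e-12)

  all_gel <- scalar_volume(array(-1.0, c(12, 12, 12)))
  expect_equal(balloon_force(all_gel, m, p),
               matrix(0, n_vertices(m), 3L))

  # indicator property: any value inside the band gives the same force
  half <- scalar_volume(array(0.5, c(12, 12, 12)))
  expect_equal(balloon_force(half, m, p), geo$n, tolerance = 1e-12)
  # just below the band boundary: no force
  below <- scalar_volume(array(-0.995, c(12, 12, 12)))
  expect_equal(balloon_force(below, m, p),
               matrix(0, n_vertices(m), 3L))
})

test_that("balloon-only deformation inflates the mesh monotonically", {
  all_pass <- scalar_volume(array(1.0, c(30, 30, 30)))
  m <- build_simplex_sphere(c(14.5, 14.5, 14.5), 3, 1)
  p <- stage_parameters(w_gradient = 0, w_collision = 0, w_edge = 0,
                        w_balloon = 0.5, smoothness_scale = 3L)
  nb <- multiseg:::vertex_neighbourhoods(m, p$smoothness_scale)
  radii <- numeric(20L)
  for (k in 1:20) {
    f_int <- internal_force(m, p, nb)
    f_ext <- compose_external(p, balloon = balloon_force(all_pass, m, p))
    m <- step_mesh(m, f_int, f_ext, p)
    radii[k] <- mean(row_norms_test(sweep(m$vertices, 2L,
                                          c(14.5, 14.5, 14.5))))
  }
  expect_true(all(diff(c(3, radii)) > 0))
})

test_that("every external force is parallel to the vertex normal", {
  set.seed(21)
  img <- scalar_volume(array(stats::rnorm(13824, 50, 10), c(24, 24, 24)))
  classified <- scalar_volume(array(sample(c(-1, 1), 13824, TRUE),
                                    c(24, 24, 24)))
  energy <- binary_mask(array(sample(0:1, 13824, TRUE), c(24, 24, 24)))
  m <- build_simplex_sphere(c(11.5, 11.5, 11.5), 4, 1)
  m$vertices <- m$vertices + 0.3 * matrix(stats::rnorm(240), ncol = 3L)
  p <- stage_parameters()
  geo <- multiseg:::simplex_geometry(m)
  grad <- gradient_magnitude(img)
  for (f in list(gradient_force(img, m, p, gradient = grad),
                 edge_force(img, m, p),
                 balloon_force(classified, m, p),
                 collision_force(energy, img, m, p, gradient = grad))) {
    cr <- multiseg:::cross_rows(f, geo$n)
    expect_true(all(row_norms_test(cr) <= 1e-9 * pmax(row_norms_test(f), 1e-12)))
  }
})

test_that("the equation of motion handles the trivial cases exactly", {
  m <- build_simplex_sphere(c(0, 0, 0), 2, 0)
  zero <- matrix(0, n_vertices(m), 3L)
  p <- stage_parameters(gamma = 0.65)

  # no forces, no history: stationary
  m1 <- step_mesh(m, zero, zero, p)
  expect_identical(m1$vertices, m$vertices)

  # gamma = 1 kills inertia regardless of history
  m2 <- m
  m2$prev_vertices <- m2$prev_vertices + 5
  p1 <- stage_parameters(gamma = 1)
  m3 <- step_mesh(m2, zero, zero, p1)
  expect_identical(m3$vertices, m2$vertices)

  # single force, gamma = 1, unit weights: displacement exactly f
  pw <- stage_parameters(gamma = 1, w_internal = 1)
  f <- matrix(stats::rnorm(3L * n_vertices(m)), ncol = 3L)
  m4 <- step_mesh(m, f, 0 * f, pw)
  expect_equal(m4$vertices - m$vertices, f, tolerance = 1e-12)

  # non-finite forces abort with the vertex named
  fbad <- zero
  fbad[3L, 1L] <- NaN
  expect_error(step_mesh(m, fbad, zero, p), "vertex 3")
  expect_error(compose_external(p, gradient = fbad), "gradient.*vertex 3")
})
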