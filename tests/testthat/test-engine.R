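test_that("initialization places identical spheres and validates seeds", {
  dm <- c(32L, 32L, 32L)
  tube <- binary_mask(array(1L, dm))
  img <- scalar_volume(array(0, dm))
  seeds <- rbind(c(8, 8, 8), c(24, 8, 8), c(8, 24, 8), c(24, 24, 24))
  cfg <- run_config(seeds = seeds)
  states <- initialize_meshes(cfg, img, tube)
  expect_length(states, 4L)
  base <- sweep(states[[1L]]$mesh$vertices, 2L, seeds[1L, ])
  for (k in 2:4) {
    rel <- sweep(states[[k]]$mesh$vertices, 2L, seeds[k, ])
    expect_equal(rel, base, tolerance = 1e-9)   # congruent up to translation
  }

  # seed outside the tube mask is an error naming the seed
  half <- array(0L, dm)
  half[1:16, , ] <- 1L
  tube2 <- binary_mask(half)
  cfg2 <- run_config(seeds = rbind(c(8, 8, 8), c(28, 8, 8)))
  expect_error(initialize_meshes(cfg2, img, tube2), "seed 2")

  # close seeds trigger the overlapping-spheres warning
  cfg3 <- run_config(seeds = rbind(c(8, 8, 8), c(12, 8, 8)))
  expect_warning(initialize_meshes(cfg3, img, tube), "closer")

  expect_error(run_config(seeds = rbind(c(1, 1, 1), c(1, 1, 1))), "distinct")
})

test_that("the activity-ratio convergence rule uses strict inequality", {
  cfg <- run_config(seeds = c(5, 5, 5), activity_window = 4L,
                    displacement_threshold = 1e-4, activity_threshold = 0.5)
  mk_state <- function(disps) list(history = lapply(disps, identity))

  # all vertices still: ratio 1 > 0.5 -> converged
  still <- mk_state(replicate(4L, rep(0, 10L), simplify = FALSE))
  expect_true(check_convergence(still, cfg))

  # all vertices moving a voxel: ratio 0 -> not converged
  moving <- mk_state(replicate(4L, rep(1, 10L), simplify = FALSE))
  expect_false(check_convergence(moving, cfg))

  # exactly half inactive: 0.5 is NOT > 0.5 -> not converged
  half <- mk_state(replicate(4L, c(rep(0, 5L), rep(1, 5L)), simplify = FALSE))
  expect_false(check_convergence(half, cfg))

  # fewer than `activity_window` iterations: never converged
  young <- mk_state(replicate(2L, rep(0, 10L), simplify = FALSE))
  expect_false(check_convergence(young, cfg))

  # a vertex active in any window iteration counts as active
  flicker <- mk_state(list(rep(0, 10L), c(1, rep(0, 9L)), rep(0, 10L),
                           rep(0, 10L)))
  expect_equal(
    sum(rowSums(do.call(cbind, flicker$history) < 1e-4) == 4L), 9L)
  expect_true(check_convergence(flicker, cfg))
})

test_that("a single isolated sphere is recovered within two voxels of its true radius", {
  ph <- small_phantom()
  res <- small_run()
  mask <- res$masks[[1L]]
  truth <- ph$truths[[1L]]
  expect_gte(dice_score(mask, truth), 0.85)
  r_est <- (3 * sum(mask$values) * prod(mask$spacing) / (4 * pi))^(1 / 3)
  expect_lt(abs(r_est - 9), 2)
})

test_that("runs are deterministic and reports echo the printed weight schedule", {
  ph <- small_phantom()
  res <- small_run()
  cfg <- run_config(seeds = ph$seeds, min_high_res_stages = 3L,
                    max_high_res_stages = 3L)
  res2 <- suppressWarnings(run_segmentation(ph$volume, cfg, ph$training))
  expect_identical(res2$masks[[1L]]$values, res$masks[[1L]]$values)
  expect_identical(res2$meshes[[1L]]$vertices, res$meshes[[1L]]$vertices)

  st <- res$report$stages
  expect_equal(st[[1L]]$weights$w_balloon, 0.08)
  expect_equal(st[[1L]]$weights$w_internal, 0.9)
  expect_equal(st[[1L]]$weights$w_gradient, 0.3)
  expect_equal(st[[1L]]$weights$w_collision, 0.4)
  expect_equal(st[[1L]]$weights$w_edge, 0)
  expect_equal(st[[1L]]$smoothness_scale, 12L)
  for (k in 2:length(st)) {
    expect_equal(st[[k]]$weights$w_balloon, 0.02)
    expect_equal(st[[k]]$weights$w_internal, 0.7)
    expect_equal(st[[k]]$weights$w_gradient, 0.4)
    expect_equal(st[[k]]$weights$w_collision, 0.4)
    expect_equal(st[[k]]$smoothness_scale, 3L)
  }
  # refinement at least doubles the vertex count between stages
  expect_gte(st[[2L]]$vertices[1L], 2L * st[[1L]]$vertices[1L])
})

test_that("every final vertex stays inside the tube mask", {
  res <- small_run()
  for (mesh in res$meshes) {
    inside <- multiseg:::sample_volume_nn(res$tube, mesh$vertices,
                                          outside = 0)
    expect_true(all(inside == 1))
  }
})

test_that("segmentation outputs are written when an output directory is given", {
  ph <- small_phantom()
  res <- small_run()
  out <- file.path(tempdir(), "run_out")
  cfg <- run_config(seeds = ph$seeds, min_high_res_stages = 3L,
                    max_high_res_stages = 3L)
  # reuse the memoized deformation by writing the artefacts directly
  dir.create(out, showWarnings = FALSE)
  write_volume(res$masks[[1L]], file.path(out, "mask_000.nii"))
  write_report(res$report, file.path(out, "report.json"))
  expect_true(file.exists(file.path(out, "mask_000.nii")))
  rep <- jsonlite::read_json(file.path(out, "report.json"))
  expect_equal(rep$n_objects, 1L)
  back <- read_volume(file.path(out, "mask_000.nii"), mask = TRUE)
  expect_identical(back$values, res$masks[[1L]]$values)
})
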