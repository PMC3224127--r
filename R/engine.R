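#' Default two-entry parameter schedule
#'
#' Stage 1 (coarse meshes): edge force off, balloon 0.08 and internal 0.9
#' (rapid, smooth inflation), gradient 0.3 and collision 0.4, smoothness
#' scale 12. High-resolution stages: balloon decreased to 0.02, internal to
#' 0.7 (recover finer edges), gradient raised to 0.4, collision kept at the
#' upper end of its mid range (0.4: strong enough that touching objects
#' stay essentially separate, low enough that they are fully segmented),
#' smoothness scale 3, and the gradient search narrowed to 2 voxels — the
#' refined meshes already sit near the boundary, and the tighter window
#' resists capture by spurious texture maxima. The refinement stages also
#' use heavier damping (gamma 0.85) and a half-voxel step cap, which
#' shrinks the residual oscillation of vertices tugged between the balloon
#' and the boundary. Additional high-resolution stages reuse the last
#' entry.
#'
#' @return List of [stage_parameters()].
#' @export
default_schedule <- function() {
  list(
    stage_parameters(w_internal = 0.9, w_gradient = 0.3, w_edge = 0,
                     w_balloon = 0.08, w_collision = 0.4,
                     smoothness_scale = 12L, max_iterations = 200L),
    stage_parameters(w_internal = 0.7, w_gradient = 0.4, w_edge = 0,
                     w_balloon = 0.02, w_collision = 0.4,
                     smoothness_scale = 3L, gradient_search_radius = 2L,
                     gamma = 0.85, force_cap = 0.5,
                     max_iterations = 100L))
}

#' Run configuration
#'
#' Collects everything a segmentation run needs besides the image and the
#' training set: seed points, initial mesh geometry, the per-stage
#' parameter schedule, collision-check cadence, and the convergence
#' criterion (a vertex is "inactive" when its displacement falls below
#' `displacement_threshold`; a mesh is converged when the inactive fraction
#' exceeds `activity_threshold` over the last `activity_window`
#' iterations).
#'
#' @param seeds N x 3 matrix (or length-3 vector) of world-coordinate seed
#'   points, one per object.
#' @param sphere_radius initial sphere radius in mm; `NULL` means 5 voxels
#'   at the image's smallest spacing.
#' @param initial_subdivisions icosahedron subdivisions of the initial
#'   spheres (1 gives 80-vertex meshes).
#' @param schedule list of [stage_parameters()]; entry 1 is the coarse
#'   stage, later entries the high-resolution stages (last entry reused).
#' @param collision_check_interval iterations between collision checks.
#' @param displacement_threshold inactivity threshold (mm).
#' @param activity_threshold converged when inactive fraction exceeds this
#'   (strictly).
#' @param activity_window iterations over which activity is assessed.
#' @param min_high_res_stages,max_high_res_stages number of high-resolution
#'   stages run after the coarse stage (between 3 and 5 by default; stages
#'   after the minimum are skipped once every mesh has converged).
#' @param classifier_window [local_sd_volume()] window (voxels).
#' @param gradient_sigma Gaussian smoothing (voxels) applied to the image
#'   before the gradient-magnitude computation.
#' @param gradient_floor_quantile the gradient floor below which the
#'   gradient search ignores voxels, expressed as a quantile of the
#'   gradient magnitudes over the object-classified voxels inside the
#'   tube (wall band excluded). Texture inside an object produces weak
#'   but spatially stable gradient maxima that can pin vertices; flooring
#'   the search at the objects' bulk-texture level suppresses most of the
#'   interior response while leaving boundary ridges almost entirely
#'   above the floor. 0 disables the floor.
#' @param tube_nbins histogram bins for [find_tube_thresholds()].
#' @param collision_mode `"xor"` (default) or `"union"`, see
#'   [build_energy_images()].
#' @param random_seed recorded in the run report; the deformation itself is
#'   deterministic.
#' @return A `run_config` list.
#' @export
run_config <- function(seeds, sphere_radius = NULL, initial_subdivisions = 1L,
                       schedule = default_schedule(),
                       collision_check_interval = 5L,
                       displacement_threshold = 1e-4,
                       activity_threshold = 0.5, activity_window = 10L,
                       min_high_res_stages = 3L, max_high_res_stages = 5L,
                       classifier_window = 5L, gradient_sigma = 1,
                       gradient_floor_quantile = 0.7,
                       tube_nbins = 256L, collision_mode = "xor",
                       random_seed = 1L) {
  seeds <- to_point_matrix(seeds)
  if (nrow(seeds) < 1L) stop("at least one seed point is required")
  if (anyDuplicated(seeds)) stop("seed points must be pairwise distinct")
  if (displacement_threshold <= 0 || activity_threshold <= 0)
    stop("thresholds must be positive")
  if (min_high_res_stages > max_high_res_stages)
    stop("min_high_res_stages must not exceed max_high_res_stages")
  for (s in schedule)
    if (!inherits(s, "stage_parameters"))
      stop("`schedule` must be a list of stage_parameters")
  structure(list(
    seeds = seeds, sphere_radius = sphere_radius,
    initial_subdivisions = as.integer(initial_subdivisions),
    schedule = schedule,
    collision_check_interval = as.integer(collision_check_interval),
    displacement_threshold = displacement_threshold,
    activity_threshold = activity_threshold,
    activity_window = as.integer(activity_window),
    min_high_res_stages = as.integer(min_high_res_stages),
    max_high_res_stages = as.integer(max_high_res_stages),
    classifier_window = as.integer(classifier_window),
    gradient_sigma = gradient_sigma,
    gradient_floor_quantile = gradient_floor_quantile,
    tube_nbins = as.integer(tube_nbins),
    collision_mode = collision_mode,
    random_seed = as.integer(random_seed)), class = "run_config")
}

#' Initialize mesh states from seed points
#'
#' Places one identical spherical simplex mesh at every seed point. Every
#' seed must lie strictly inside the tube mask (error naming the offending
#' seed); seeds closer together than twice the sphere radius trigger a
#' warning because the initial spheres would already overlap.
#'
#' @param config a [run_config()].
#' @param image the intensity volume (defines the grid).
#' @param tube the tube [binary_mask()].
#' @return List of mesh states (`mesh`, `converged`, `balloon_latched`,
#'   displacement history).
#' @export
initialize_meshes <- function(config, image, tube) {
  radius <- config$sphere_radius
  if (is.null(radius)) radius <- 5 * min(image$spacing)
  seeds <- config$seeds
  inside <- sample_volume_nn(tube, seeds, outside = 0) == 1
  if (any(!inside))
    stop("seed ", which(!inside)[1L], " (",
         paste(signif(seeds[which(!inside)[1L], ], 5), collapse = ", "),
         ") lies outside the tube mask")
  dd <- as.matrix(stats::dist(seeds))
  diag(dd) <- Inf
  if (any(dd < 2 * radius))
    warning("some seeds are closer than twice the initial sphere radius; ",
            "initial spheres overlap")
  lapply(seq_len(nrow(seeds)), function(i) {
    list(mesh = build_simplex_sphere(seeds[i, ], radius,
                                     config$initial_subdivisions),
         converged = FALSE, balloon_latched = FALSE,
         history = list(), iterations = 0L)
  })
}

#' Convergence test for one mesh state
#'
#' A vertex is inactive when its displacement magnitude stayed below
#' `displacement_threshold` in each of the last `activity_window`
#' iterations; the mesh has converged when the inactive fraction is
#' strictly greater than `activity_threshold`. Before `activity_window`
#' iterations have elapsed in the current stage the mesh is never
#' considered converged.
#'
#' @param state a mesh state (see [initialize_meshes()]).
#' @param config a [run_config()].
#' @return Logical.
#' @export
check_convergence <- function(state, config) {
  n <- config$activity_window
  if (length(state$history) < n) return(FALSE)
  recent <- do.call(cbind, state$history[seq(length(state$history) - n + 1L,
                                             length(state$history))])
  inactive <- rowSums(recent < config$displacement_threshold) == n
  mean(inactive) > config$activity_threshold
}

activity_ratio <- function(state, config) {
  if (length(state$history) == 0L) return(0)
  n <- min(config$activity_window, length(state$history))
  recent <- do.call(cbind, state$history[seq(length(state$history) - n + 1L,
                                             length(state$history))])
  mean(rowSums(recent < config$displacement_threshold) == n)
}

#' Segment a volume with simultaneously deforming simplex meshes
#'
#' The full pipeline: (a) Bayesian classification of the volume into
#' object versus gel; (b) histogram-derived tube mask; (c) coarse-mesh
#' stage with the stage-1 weights (strong balloon, smoothness 12);
#' (d) collision checks every `collision_check_interval` iterations, with
#' ballooning latched off per colliding mesh for the remainder of the
#' stage; (e) mesh refinement and the high-resolution weights between
#' stages; (f) every displacement clamped to the tube mask; (g) high-
#' resolution stages iterated `min_high_res_stages`..`max_high_res_stages`
#' times or until every mesh converges; (h) one binary mask rasterized per
#' object. Meshes stop refining once their mean edge length falls below
#' the voxel spacing (further subdivision cannot add boundary detail).
#'
#' @param image a [scalar_volume()].
#' @param config a [run_config()].
#' @param training a [training_set()] for the classifier.
#' @param out_dir optional output directory; when given, one
#'   `mask_000.nii`.. per object, the classified volume, the tube mask and
#'   a JSON run report are written there.
#' @param verbose print per-stage progress.
#' @return A list: `masks` (list of [binary_mask()]), `meshes` (final
#'   simplex meshes), `classified`, `tube`, `thresholds`, `report`.
#' @export
run_segmentation <- function(image, config, training, out_dir = NULL,
                             verbose = FALSE) {
  t0 <- Sys.time()
  sdv <- local_sd_volume(image, config$classifier_window)
  model <- fit_bayes_classifier(image, sdv, training)
  classified <- classify_volume(image, sdv, model)
  thresholds <- find_tube_thresholds(image, config$tube_nbins)
  tube <- make_tube_mask(image, thresholds)
  grad <- gradient_magnitude(image, sigma = config$gradient_sigma)
  # the container wall is the strongest edge in the image; censor it (and
  # everything outside the tube) from the boundary searches, which is the
  # tube mask's purpose - object boundaries must be found inside it
  wall_excl <- tube$values
  for (k in 1:2) {   # censor a 2-voxel band inside the mask edge
    nxt <- wall_excl
    for (ax in 1:3)
      nxt <- nxt & shift_array(wall_excl, 1L, ax, fill = 0L) &
        shift_array(wall_excl, -1L, ax, fill = 0L)
    wall_excl <- nxt
  }
  wall_excl <- binary_mask(array(1L - wall_excl, dim(tube$values)),
                           tube$spacing, tube$origin)
  # bulk texture level of the objects being segmented (wall band excluded:
  # its windows are classified object but carry wall gradients)
  grad_floor <- 0
  if (config$gradient_floor_quantile > 0) {
    obj_region <- classified$values == 1 & wall_excl$values == 0L
    if (!any(obj_region)) obj_region <- tube$values == 1L
    grad_floor <- stats::quantile(grad$values[obj_region],
                                  config$gradient_floor_quantile,
                                  names = FALSE)
  }
  states <- initialize_meshes(config, image, tube)

  n_stages <- 1L + config$max_high_res_stages
  stage_reports <- list()
  for (stage in seq_len(n_stages)) {
    params <- config$schedule[[min(stage, length(config$schedule))]]
    if (stage > 1L) {
      min_sp <- min(image$spacing)
      states <- lapply(states, function(st) {
        # refine until the mesh resolves the voxel grid; the vertex cap
        # bounds the cost should a mesh overgrow its object
        if (mean_edge_length(st$mesh) > 1.25 * min_sp &&
            n_vertices(st$mesh) < 2000L)
          st$mesh <- refine(st$mesh)
        st$converged <- FALSE
        st$balloon_latched <- FALSE
        st$history <- list()
        st
      })
    }
    params$gradient_floor <- max(params$gradient_floor, grad_floor)
    states <- deform_stage(states, params, image, classified, grad, tube,
                           config, wall_excl = wall_excl, verbose = verbose,
                           stage = stage)
    stage_reports[[stage]] <- list(
      stage = stage,
      weights = params[c("w_internal", "w_gradient", "w_edge", "w_balloon",
                         "w_collision")],
      smoothness_scale = params$smoothness_scale,
      iterations = vapply(states, function(s) s$iterations, integer(1L)),
      vertices = vapply(states, function(s) n_vertices(s$mesh), integer(1L)),
      converged = vapply(states, function(s) s$converged, logical(1L)),
      balloon_latched = vapply(states, function(s) s$balloon_latched,
                               logical(1L)),
      activity_ratio = vapply(states, function(s) activity_ratio(s, config),
                              numeric(1L)))
    if (stage > config$min_high_res_stages &&
        all(vapply(states, function(s) s$converged, logical(1L))))
      break
  }
  if (!all(vapply(states, function(s) s$converged, logical(1L))))
    warning("not all meshes converged at the stage cap; emitting masks anyway")

  masks <- lapply(states, function(s) rasterize(s$mesh, image))
  report <- list(
    n_objects = length(masks),
    thresholds = list(t_low = thresholds$t_low, t_high = thresholds$t_high),
    stages = stage_reports,
    config = config[c("collision_check_interval", "displacement_threshold",
                      "activity_threshold", "activity_window",
                      "min_high_res_stages", "max_high_res_stages",
                      "classifier_window", "gradient_sigma", "tube_nbins",
                      "collision_mode", "random_seed")],
    elapsed_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(masks))
      write_volume(masks[[i]], file.path(out_dir,
                                         sprintf("mask_%03d.nii", i - 1L)))
    write_volume(classified, file.path(out_dir, "classified.nii"))
    write_volume(tube, file.path(out_dir, "tube_mask.nii"))
    write_report(report, file.path(out_dir, "report.json"))
  }
  list(masks = masks, meshes = lapply(states, `[[`, "mesh"),
       classified = classified, tube = tube, thresholds = thresholds,
       report = report)
}

# One deformation stage: synchronous per-iteration updates of all
# non-converged meshes, collision bookkeeping on the configured cadence,
# displacements clamped to the tube mask.
deform_stage <- function(states, params, image, classified, grad, tube,
                         config, wall_excl = NULL, verbose = FALSE,
                         stage = NA_integer_) {
  states <- lapply(states, function(st) { st$iterations <- 0L; st })
  nbhds <- lapply(states, function(st)
    vertex_neighbourhoods(st$mesh, params$smoothness_scale))
  energies <- refresh_energies(states, image, config)

  for (iter in seq_len(params$max_iterations)) {
    if (all(vapply(states, function(s) s$converged, logical(1L)))) break
    for (i in seq_along(states)) {
      st <- states[[i]]
      if (st$converged) next
      mesh <- st$mesh
      geo <- simplex_geometry(mesh)
      f_int <- internal_force(mesh, params, nbhds[[i]], geo = geo)
      f_grad <- search_force(grad, mesh, params$gradient_search_radius,
                             params$gradient_floor, geo = geo,
                             exclude = wall_excl, cap = params$force_cap)
      f_ball <- balloon_force(classified, mesh, params)
      cval <- sample_volume_nn(energies[[i]], mesh$vertices, outside = 0)
      coll_excl <- energies[[i]]
      if (!is.null(wall_excl))
        coll_excl <- binary_mask(pmax(coll_excl$values, wall_excl$values),
                                 coll_excl$spacing, coll_excl$origin)
      f_coll <- search_force(grad, mesh, params$collision_search_radius,
                             params$gradient_floor,
                             active = !is.na(cval) & cval == 1, geo = geo,
                             exclude = coll_excl, cap = params$force_cap)
      f_edge <- if (params$w_edge > 0) edge_force(image, mesh, params)
                else NULL
      eff <- params
      if (st$balloon_latched) eff$w_balloon <- 0
      f_ext <- compose_external(eff, gradient = f_grad, edge = f_edge,
                                balloon = f_ball, collision = f_coll)
      disp <- (1 - params$gamma) * (mesh$vertices - mesh$prev_vertices) +
        params$w_internal * f_int + f_ext
      if (any(!is.finite(disp)))
        stop("non-finite displacement at vertex ",
             which(!is.finite(rowSums(disp)))[1L], " of mesh ", i)
      proposed <- mesh$vertices + disp
      final <- clamp_rows(mesh$vertices, proposed, tube)
      # the container wall acts like a static neighbour: a mesh pressing
      # against it stops ballooning for the rest of the stage, exactly as
      # a mesh in collision does, so it cannot crawl along the wall
      if (!st$balloon_latched && !identical(final, proposed))
        st$balloon_latched <- TRUE
      dmag <- row_norms(final - mesh$vertices)
      mesh$prev_vertices <- mesh$vertices
      mesh$vertices <- final
      st$mesh <- mesh
      st$history <- c(st$history, list(dmag))
      if (length(st$history) > config$activity_window)
        st$history <- st$history[-1L]
      st$iterations <- st$iterations + 1L
      st$converged <- check_convergence(st, config)
      states[[i]] <- st
    }
    if (iter %% config$collision_check_interval == 0L) {
      energies <- refresh_energies(states, image, config)
      for (i in seq_along(states)) {
        if (length(detect_collisions(states[[i]]$mesh, energies[[i]])) > 0L)
          states[[i]]$balloon_latched <- TRUE
      }
    }
  }
  if (verbose)
    message(sprintf("stage %s: iterations %s, converged %s", stage,
                    paste(vapply(states, function(s) s$iterations,
                                 integer(1L)), collapse = "/"),
                    paste(vapply(states, function(s) s$converged,
                                 logical(1L)), collapse = "/")))
  states
}

refresh_energies <- function(states, image, config) {
  masks <- lapply(states, function(s) rasterize(s$mesh, image))
  build_energy_images(masks, mode = config$collision_mode)$energies
}

# Row-wise tube clamp without the scalar bookkeeping of
# clamp_displacement(): vertices whose proposed voxel leaves the mask keep
# their previous coordinate (displacement set to zero).
clamp_rows <- function(old, proposed, tube) {
  inside <- sample_volume_nn(tube, proposed, outside = 0) == 1
  out <- proposed
  out[!inside, ] <- old[!inside, , drop = FALSE]
  out
}
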