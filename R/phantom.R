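#' Phantom specification
#'
#' Describes a synthetic test volume that emulates the study conditions of
#' multi-specimen tube imaging: a bright cylindrical "tube" of gel on a
#' dark exterior, containing N ellipsoidal "embryo" objects, with a smooth
#' multiplicative bias field (gel inhomogeneity), overlapping object/gel
#' intensity distributions, and additive noise.
#'
#' Default intensities: background 10 +/- 4, gel 100 +/- 5, object
#' 130 +/- 10 (object texture is deliberately richer, so the local-SD
#' feature carries class information, while the bias field makes the raw
#' intensity histograms overlap regionally).
#'
#' @param grid_shape integer vector of 3 voxel counts.
#' @param spacing voxel spacing in mm.
#' @param tube_radius cylinder radius (mm); axis along z through the grid
#'   center.
#' @param tube_zrange length-2 z extent (mm) of the cylinder.
#' @param objects list of objects, each `list(center = c(x,y,z),
#'   semiaxes = c(a,b,c))` in mm (axis-aligned ellipsoids).
#' @param background_mean,background_sd,gel_mean,gel_sd,object_mean,object_sd
#'   class intensity distributions.
#' @param bias_amplitude peak relative amplitude of the multiplicative bias
#'   field (sum of 3 low-frequency separable cosine modes).
#' @param object_texture_scale spatial correlation length (Gaussian sigma,
#'   voxels) of the object texture; tissue texture is correlated at the
#'   millimeter scale rather than white. 0 gives white texture.
#' @param noise_sd additive Gaussian noise SD.
#' @param n_training training points drawn per class.
#' @param random_seed RNG seed; fixed seed makes the phantom byte-identical
#'   across runs.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L), spacing = c(1, 1, 1),
                         tube_radius = 26.556, tube_zrange = c(4, 59),
                         objects = list(), background_mean = 10,
                         background_sd = 4, gel_mean = 100, gel_sd = 5,
                         object_mean = 130, object_sd = 10,
                         bias_amplitude = 0.2, object_texture_scale = 0,
                         noise_sd = 3,
                         n_training = 25L, random_seed = 1L) {
  if (length(objects) < 1L) stop("at least one object is required")
  structure(as.list(environment()), class = "phantom_spec")
}

#' Standard layered tube phantom
#'
#' Deterministic layout mimicking a stacked-specimen tube: up to 4
#' ellipsoids per layer at the four diagonal positions around the tube
#' axis, sized so that ellipsoids adjacent within a layer touch each other
#' (tangent); the layer block is shifted off the tube axis so that one
#' ellipsoid per layer also touches the tube wall while the others keep a
#' clear gel margin. Layers are stacked along z; `n_objects = 32` gives
#' the full 8-layer packing.
#'
#' @param n_objects number of objects, 1..32.
#' @param random_seed RNG seed passed to the spec.
#' @return A [phantom_spec()].
#' @export
default_tube <- function(n_objects = 4L, random_seed = 1L) {
  n_objects <- as.integer(n_objects)
  if (n_objects < 1L || n_objects > 32L) stop("`n_objects` must be in 1..32")
  layers <- ceiling(n_objects / 4L)
  a <- 10      # xy semi-axis = half the center-to-center distance (tangency)
  cz_semi <- 13
  margin <- 6  # wall clearance of the non-touching objects
  overlap <- 0 # tangent wall contact; > 0 would clip a protruding object
  pitch <- 2 * cz_semi
  nz <- max(64L, as.integer(pitch * layers + 12L))
  zr <- c(4, nz - 5)
  cxy <- 31.5
  z0 <- zr[1L] + (diff(zr) - pitch * layers) / 2 + cz_semi
  shift <- (margin + overlap) / sqrt(2)
  offsets <- rbind(c(a, a), c(-a, a), c(a, -a), c(-a, -a)) +
    matrix(shift, 4L, 2L)   # slot 1 touches the wall
  objects <- vector("list", n_objects)
  for (i in seq_len(n_objects)) {
    layer <- (i - 1L) %/% 4L
    slot <- (i - 1L) %% 4L + 1L
    objects[[i]] <- list(
      center = c(cxy + offsets[slot, 1L], cxy + offsets[slot, 2L],
                 z0 + pitch * layer),
      semiaxes = c(a, a, cz_semi))
  }
  phantom_spec(grid_shape = c(64L, 64L, nz),
               tube_radius = sqrt(2) * a + a + margin,
               tube_zrange = zr, objects = objects,
               random_seed = random_seed)
}

# Run code with a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a phantom volume with ground truth
#'
#' Builds the volume `bias_field x N(class mean, class sd) + noise`, the
#' exact per-object truth masks (voxel centers strictly inside each
#' ellipsoid), the seed points (object centers), and a training set of
#' `n_training` random in-object plus `n_training` in-gel voxels. Object
#' specifications overlapping beyond tangency (any voxel claimed by two
#' objects) are an error.
#'
#' @param spec a [phantom_spec()].
#' @return A list: `volume` ([scalar_volume()]), `truths` (list of
#'   [binary_mask()]), `seeds` (N x 3 world coordinates), `training`
#'   ([training_set()]), and `tube` (the exact cylinder mask, useful for
#'   validating the histogram-derived tube mask).
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  dm <- as.integer(spec$grid_shape)
  sp <- spec$spacing
  xs <- (seq_len(dm[1L]) - 1) * sp[1L]
  ys <- (seq_len(dm[2L]) - 1) * sp[2L]
  zs <- (seq_len(dm[3L]) - 1) * sp[3L]
  X <- array(xs, dm)
  Y <- array(rep(ys, each = dm[1L]), dm)
  Z <- array(rep(zs, each = dm[1L] * dm[2L]), dm)
  cx <- (dm[1L] - 1) * sp[1L] / 2
  cy <- (dm[2L] - 1) * sp[2L] / 2
  tube <- (X - cx)^2 + (Y - cy)^2 <= spec$tube_radius^2 &
    Z >= spec$tube_zrange[1L] & Z <= spec$tube_zrange[2L]

  cls <- array(0L, dm)               # 0 background, 1 gel, 2 object
  cls[tube] <- 1L
  truths <- vector("list", length(spec$objects))
  claimed <- array(0L, dm)
  for (i in seq_along(spec$objects)) {
    ob <- spec$objects[[i]]
    inside <- ((X - ob$center[1L]) / ob$semiaxes[1L])^2 +
      ((Y - ob$center[2L]) / ob$semiaxes[2L])^2 +
      ((Z - ob$center[3L]) / ob$semiaxes[3L])^2 < 1
    # an ellipsoid protruding past the wall is clipped by the cylinder
    # (a specimen pressed flat against the container)
    inside <- inside & tube
    if (!any(inside))
      stop("object ", i, " lies entirely outside the tube")
    m <- array(0L, dm)
    m[inside] <- 1L
    claimed <- claimed + m
    truths[[i]] <- binary_mask(m, sp, c(0, 0, 0))
    cls[inside] <- 2L
  }
  if (any(claimed > 1L))
    stop("objects overlap beyond tangency tolerance")

  mu <- c(spec$background_mean, spec$gel_mean, spec$object_mean)[cls + 1L]
  sdv <- c(spec$background_sd, spec$gel_sd, spec$object_sd)[cls + 1L]

  vol <- with_local_seed(spec$random_seed, {
    bias <- bias_field(X / max(xs), Y / max(ys), Z / max(zs),
                       spec$bias_amplitude)
    n <- prod(dm)
    texture <- stats::rnorm(n)
    dim(texture) <- dm
    if (spec$object_texture_scale > 0) {
      # objects carry spatially correlated (tissue-like) texture; gel and
      # exterior noise stay white
      sm <- smooth_volume(scalar_volume(texture, sp),
                          spec$object_texture_scale)$values
      sm <- sm / stats::sd(sm)
      texture[cls == 2L] <- sm[cls == 2L]
    }
    values <- bias * (mu + sdv * texture) + spec$noise_sd * stats::rnorm(n)
    dim(values) <- dm

    # training points emulate manual selection: a user clicks well inside
    # each material, so candidates are eroded away from class boundaries
    n_tr <- spec$n_training
    obj_idx <- sample(class_core(cls == 2L, n_tr), n_tr)
    gel_idx <- sample(class_core(cls == 1L, n_tr), n_tr)
    coords <- arrayInd(c(obj_idx, gel_idx), dm) - 1L
    list(values = values,
         training = training_set(coords, rep(c("object", "gel"),
                                             each = n_tr)))
  })

  seeds <- t(vapply(spec$objects, function(ob) ob$center, numeric(3L)))
  list(volume = scalar_volume(vol$values, sp, c(0, 0, 0)),
       truths = truths,
       seeds = seeds,
       training = vol$training,
       tube = binary_mask(array(as.integer(tube), dm), sp, c(0, 0, 0)))
}

#' Perturb seed points within their objects
#'
#' Draws, for every seed, a random direction and a shift of up to
#' `max_shift` mm, truncated so the perturbed seed stays inside its truth
#' ellipsoid with `margin` mm to spare. This reproduces the seed-
#' sensitivity experiment: alternative seed sets lie within 10 voxels of
#' the originals but remain interior points of their objects (seeds placed
#' at object edges are the documented failure mode, not a robustness
#' target).
#'
#' @param seeds N x 3 matrix of object centers (world mm).
#' @param spec the [phantom_spec()] that generated the objects.
#' @param max_shift maximum displacement (mm).
#' @param margin minimum distance to the object boundary (mm).
#' @param seed RNG seed for the perturbation.
#' @return An N x 3 matrix of perturbed seeds.
#' @export
perturb_seeds <- function(seeds, spec, max_shift = 10, margin = 3,
                          seed = 1L) {
  seeds <- to_point_matrix(seeds)
  cxy <- (spec$grid_shape[1:2] - 1) * spec$spacing[1:2] / 2
  inside_tube <- function(p) {
    sqrt(sum((p[1:2] - cxy)^2)) <= spec$tube_radius - margin &&
      p[3L] >= spec$tube_zrange[1L] + margin &&
      p[3L] <= spec$tube_zrange[2L] - margin
  }
  with_local_seed(seed, {
    out <- seeds
    for (i in seq_len(nrow(seeds))) {
      u <- stats::rnorm(3L)
      u <- u / sqrt(sum(u^2))
      ax <- spec$objects[[i]]$semiaxes
      t_max <- 1 / sqrt(sum((u / ax)^2))   # boundary distance along u
      mag <- stats::runif(1L, 0.5, 1) * min(max_shift, max(t_max - margin, 0))
      while (mag > 0.5 && !inside_tube(seeds[i, ] + mag * u))
        mag <- 0.8 * mag                   # wall-pressed objects: stay interior
      out[i, ] <- seeds[i, ] + mag * u
    }
    out
  })
}

# Voxels of a class at least 3 voxels (6-connected erosion) from its
# boundary; the erosion is relaxed if too few voxels would remain.
class_core <- function(mask, n_min) {
  for (steps in 3:0) {
    cur <- mask
    for (k in seq_len(steps)) {
      nxt <- cur
      for (ax in 1:3)
        nxt <- nxt & shift_array(cur, 1L, ax, fill = 0) &
          shift_array(cur, -1L, ax, fill = 0)
      cur <- nxt
    }
    idx <- which(cur)
    if (length(idx) >= n_min) return(idx)
  }
  which(mask)
}

# Smooth multiplicative bias: sum of 3 separable cosine modes at 0.5, 1
# and 1.5 cycles per extent with random phases. The sum is scaled so the
# field varies by several percent almost everywhere (coherent regional
# inhomogeneity, not just rare extremes) and clipped to +/- amplitude.
bias_field <- function(U, V, W, amplitude) {
  modes <- 0
  freqs <- c(0.5, 1, 1.5)
  for (k in 1:3) {
    ph <- stats::runif(3L, 0, 2 * pi)
    modes <- modes + cos(2 * pi * freqs[k] * U + ph[1L]) *
      cos(2 * pi * freqs[k] * V + ph[2L]) *
      cos(2 * pi * freqs[k] * W + ph[3L])
  }
  1 + amplitude * pmax(pmin(modes / 1.2, 1), -1)
}
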