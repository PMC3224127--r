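#' Parameters of one deformation stage
#'
#' All force weights range from 0 (no strength) to 1 (highest strength).
#' The defaults are the first-stage settings of the segmentation schedule:
#' strong internal force (0.9) and fast ballooning (0.08) with the edge
#' force off, mid-range gradient (0.3) and collision (0.4) forces, and a
#' large smoothness scale (12) to keep the rapidly inflating coarse mesh
#' free of self-intersection. See [default_schedule()] for the high-
#' resolution stage that follows.
#'
#' @param w_internal,w_gradient,w_edge,w_balloon,w_collision force weights
#'   in `[0, 1]`.
#' @param smoothness_scale neighbourhood size (graph rings, >= 1) over which
#'   simplex angles are averaged by the internal force.
#' @param gamma damping factor in `[0, 1]`; `1 - gamma` is the fraction of
#'   the previous displacement carried over as inertia.
#' @param gradient_search_radius search radius in voxels for the gradient
#'   and edge forces.
#' @param collision_search_radius search radius in voxels for the gradient
#'   search around a collision point; values above 5 add no efficiency.
#' @param T_low,T_high pass band of the balloon indicator on the classified
#'   image; the defaults (-0.99, 1.0) admit only object-classified voxels
#'   given the classifier's -1/+1 label encoding.
#' @param gradient_floor minimum gradient magnitude required for the
#'   gradient (and collision) force to act.
#' @param force_cap maximum magnitude of one search-force step, in voxels.
#'   The search target may lie several voxels away; capping the per-step
#'   pull keeps all forces on the same scale, so a single strong image
#'   feature (e.g. the container wall) cannot run away with a mesh.
#' @param max_iterations per-stage iteration cap used by the engine.
#' @return A `stage_parameters` list.
#' @export
stage_parameters <- function(w_internal = 0.9, w_gradient = 0.3, w_edge = 0,
                             w_balloon = 0.08, w_collision = 0.4,
                             smoothness_scale = 12L, gamma = 0.65,
                             gradient_search_radius = 3L,
                             collision_search_radius = 5L,
                             T_low = -0.99, T_high = 1.0,
                             gradient_floor = 0, force_cap = 1,
                             max_iterations = 200L) {
  w <- c(w_internal = w_internal, w_gradient = w_gradient, w_edge = w_edge,
         w_balloon = w_balloon, w_collision = w_collision)
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1))
    stop("force weights must lie in [0, 1]")
  if (!is.finite(gamma) || gamma < 0 || gamma > 1)
    stop("`gamma` must lie in [0, 1]")
  if (smoothness_scale < 1) stop("`smoothness_scale` must be >= 1")
  if (!(T_low < T_high)) stop("`T_low` must be < `T_high`")
  structure(list(
    w_internal = w_internal, w_gradient = w_gradient, w_edge = w_edge,
    w_balloon = w_balloon, w_collision = w_collision,
    smoothness_scale = as.integer(smoothness_scale), gamma = gamma,
    gradient_search_radius = as.integer(gradient_search_radius),
    collision_search_radius = as.integer(collision_search_radius),
    T_low = T_low, T_high = T_high, gradient_floor = gradient_floor,
    force_cap = force_cap,
    max_iterations = as.integer(max_iterations)), class = "stage_parameters")
}

# Voxel offsets within a Euclidean radius, ordered by (distance, dz, dy,
# dx). With columns in this order, a first-tie argmax over candidate voxels
# implements the tie rule: highest value, then smallest distance to the
# vertex, then lowest voxel (linear array) index.
offsets_within_radius <- function(radius) {
  r <- as.integer(ceiling(radius))
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  d2 <- g$dx^2 + g$dy^2 + g$dz^2
  keep <- d2 <= radius^2
  g <- g[keep, , drop = FALSE]
  d2 <- d2[keep]
  ord <- order(d2, g$dz, g$dy, g$dx)
  m <- as.matrix(g[ord, , drop = FALSE])
  dimnames(m) <- NULL
  list(offsets = m, dist2 = d2[ord])
}

# Values of `vol` at (vertex voxel + offset) for every vertex: a V x K
# matrix with -Inf outside the grid. Also returns the voxel coordinate
# arrays for recovering the winning voxel's world position.
gather_neighbourhood <- function(vol, voxels, offsets) {
  dm <- dim(vol$values)
  V <- nrow(voxels)
  K <- nrow(offsets)
  cx <- outer(voxels[, 1L], offsets[, 1L], "+")
  cy <- outer(voxels[, 2L], offsets[, 2L], "+")
  cz <- outer(voxels[, 3L], offsets[, 3L], "+")
  ok <- cx >= 1L & cx <= dm[1L] & cy >= 1L & cy <= dm[2L] &
    cz >= 1L & cz <= dm[3L] & !is.na(cx)
  lin <- cx + dm[1L] * (cy - 1L) + dm[1L] * dm[2L] * (cz - 1L)
  vals <- matrix(-Inf, V, K)
  vals[ok] <- vol$values[lin[ok]]
  list(vals = vals, cx = cx, cy = cy, cz = cz, ok = ok)
}

# Project displacements onto the vertex normals: external forces act along
# the normal only.
along_normal <- function(disp, normals) {
  sweep(normals, 1L, rowSums(disp * normals), "*")
}

#' Internal force
#'
#' Restores each vertex toward the position implied by its stored reference
#' metric (barycentric) parameters in the plane of its three neighbours
#' (tangential component) and drives its simplex angle toward a smoothed
#' reference angle: the vertex's stored reference angle plus the mean
#' deviation from reference over a neighbourhood of `smoothness_scale`
#' rings (normal component). Averaging the deviation rather than the raw
#' angle smooths curvature noise at the configured scale while leaving a
#' mesh sitting exactly at its reference configuration force-free.
#' Degenerate (collinear) neighbour triples contribute zero force with a
#' warning.
#'
#' @param mesh a `simplex_mesh`.
#' @param params a [stage_parameters()] object.
#' @param neighbourhoods optional precomputed [vertex_neighbourhoods()] list
#'   for `params$smoothness_scale` (the engine caches this per stage).
#' @param geo optional precomputed geometry (internal use).
#' @return A `V x 3` matrix of force vectors (mm).
#' @export
internal_force <- function(mesh, params, neighbourhoods = NULL, geo = NULL) {
  if (is.null(geo)) geo <- simplex_geometry(mesh)
  if (is.null(neighbourhoods))
    neighbourhoods <- vertex_neighbourhoods(mesh, params$smoothness_scale)
  phi <- geo$phi
  if (any(geo$degenerate)) {
    warning("degenerate neighbour triple(s) at vertex ",
            paste(utils::head(which(geo$degenerate), 3L), collapse = ", "),
            "; internal force set to zero there")
    phi[geo$degenerate] <- 0
  }
  dev <- phi - mesh$ref_angle
  dev[!is.finite(dev)] <- 0
  phi_t <- mesh$ref_angle + vapply(neighbourhoods,
                                   function(ix) mean(dev[ix]), numeric(1L))
  p <- mesh$vertices
  nb <- mesh$neighbours
  fpos <- sweep(p[nb[, 1L], , drop = FALSE], 1L, mesh$ref_eps[, 1L], "*") +
    sweep(p[nb[, 2L], , drop = FALSE], 1L, mesh$ref_eps[, 2L], "*") +
    sweep(p[nb[, 3L], , drop = FALSE], 1L, mesh$ref_eps[, 3L], "*")
  rho_ref <- row_norms(fpos - geo$cc)
  h <- elevation_for_angle(geo$r, rho_ref, phi_t)
  target <- fpos + sweep(geo$n, 1L, h, "*")
  f <- target - p
  f[geo$degenerate, ] <- 0
  f[!is.finite(f)] <- 0
  f
}

# Height over the neighbour plane at in-plane distance `rho` from the
# circumcenter that realizes simplex angle `phi` (circumradius `r`): the
# positive/negative root of the circumscribed-sphere relation.
elevation_for_angle <- function(r, rho, phi) {
  h <- numeric(length(phi))
  nz <- is.finite(phi) & abs(phi) > 1e-12
  q <- r[nz] / tan(phi[nz])
  disc <- pmax(q^2 + r[nz]^2 - rho[nz]^2, 0)
  h[nz] <- -q + sign(phi[nz]) * sqrt(disc)
  h
}

#' External image forces
#'
#' All external forces act along the vertex normal. `gradient_force()`
#' searches a ball of `gradient_search_radius` voxels around each vertex for
#' the voxel of highest gradient magnitude and pulls the vertex toward it
#' (zero when no voxel exceeds `gradient_floor`; ties broken by distance to
#' the vertex, then lowest voxel index). `edge_force()` searches for the
#' brightest voxel along the normal line within the same radius.
#' `balloon_force()` is the inflation term `B(I(p)) n`, where the indicator
#' `B` is 1 exactly when the classified value at the vertex (nearest-
#' neighbour sample) lies in `[T_low, T_high]`. `collision_force()` is zero
#' outside the support of the mesh's collision energy image and otherwise
#' performs the gradient search in a `collision_search_radius` neighbourhood
#' of the collision point, pulling the vertex to the nearby true boundary;
#' the energy image acts as a binary thresholding operator on the search,
#' masking out voxels claimed by other meshes so the recovered boundary
#' lies on the vertex's own side.
#' Vertices outside the volume contribute zero force.
#'
#' @param image a [scalar_volume()]; for `gradient_force()` /
#'   `collision_force()` the gradient-magnitude volume may be supplied
#'   directly via `gradient` to avoid recomputation.
#' @param mesh a `simplex_mesh`.
#' @param params a [stage_parameters()].
#' @param gradient optional precomputed [gradient_magnitude()] volume.
#' @return A `V x 3` matrix of force vectors (mm), parallel to the normals.
#' @export
gradient_force <- function(image, mesh, params, gradient = NULL) {
  if (is.null(gradient)) gradient <- gradient_magnitude(image)
  search_force(gradient, mesh, params$gradient_search_radius,
               params$gradient_floor, cap = params$force_cap)
}

search_force <- function(grad, mesh, radius, floor_value,
                         active = NULL, geo = NULL, exclude = NULL,
                         cap = Inf) {
  if (is.null(geo)) geo <- simplex_geometry(mesh)
  V <- n_vertices(mesh)
  f <- matrix(0, V, 3L)
  rows <- if (is.null(active)) seq_len(V) else which(active)
  if (length(rows) == 0L) return(f)
  off <- offsets_within_radius(radius)
  vox <- nearest_voxel_index(grad, mesh$vertices[rows, , drop = FALSE])
  inside <- !is.na(vox[, 1L])
  if (!any(inside)) return(f)
  rows <- rows[inside]
  vox <- vox[inside, , drop = FALSE]
  g <- gather_neighbourhood(grad, vox, off$offsets)
  if (!is.null(exclude)) {
    ex <- gather_neighbourhood(exclude, vox, off$offsets)
    g$vals[ex$vals == 1] <- -Inf
  }
  best <- max.col(g$vals, ties.method = "first")
  sel <- cbind(seq_along(rows), best)
  bestval <- g$vals[sel]
  hit <- is.finite(bestval) & bestval > floor_value
  if (!any(hit)) return(f)
  tw <- voxel_to_world(grad, cbind(g$cx[sel], g$cy[sel], g$cz[sel]) - 1L)
  disp <- tw - mesh$vertices[rows, , drop = FALSE]
  disp[!hit, ] <- 0
  proj <- rowSums(disp * geo$n[rows, , drop = FALSE])
  cap_mm <- cap * min(grad$spacing)
  proj <- pmax(pmin(proj, cap_mm), -cap_mm)
  f[rows, ] <- sweep(geo$n[rows, , drop = FALSE], 1L, proj, "*")
  f
}

#' @rdname gradient_force
#' @export
edge_force <- function(image, mesh, params) {
  geo <- simplex_geometry(mesh)
  V <- n_vertices(mesh)
  R <- params$gradient_search_radius
  step <- min(image$spacing)
  ks <- seq(-R, R)
  ks <- ks[order(abs(ks), ks)]   # ties toward the smaller step, inward first
  vals <- matrix(-Inf, V, length(ks))
  for (j in seq_along(ks)) {
    pts <- mesh$vertices + ks[j] * step * geo$n
    vals[, j] <- sample_volume_nn(image, pts, outside = -Inf)
  }
  best <- max.col(vals, ties.method = "first")
  bestval <- vals[cbind(seq_len(V), best)]
  k_best <- ks[best]
  hit <- is.finite(bestval)
  f <- sweep(geo$n, 1L, ifelse(hit, k_best * step, 0), "*")
  f
}

#' @rdname gradient_force
#' @param classified the classified volume (object `+1`, background `-1`).
#' @export
balloon_force <- function(classified, mesh, params) {
  geo <- simplex_geometry(mesh)
  val <- sample_volume_nn(classified, mesh$vertices, outside = NA_real_)
  B <- as.numeric(!is.na(val) & val >= params$T_low & val <= params$T_high)
  sweep(geo$n, 1L, B, "*")
}

#' @rdname gradient_force
#' @param collision_energy the mesh's collision energy image (a
#'   [binary_mask()]; see [build_energy_images()]).
#' @export
collision_force <- function(collision_energy, image, mesh, params,
                            gradient = NULL) {
  if (is.null(gradient)) gradient <- gradient_magnitude(image)
  val <- sample_volume_nn(collision_energy, mesh$vertices, outside = 0)
  active <- !is.na(val) & val == 1
  search_force(gradient, mesh, params$collision_search_radius,
               params$gradient_floor, active = active,
               exclude = collision_energy, cap = params$force_cap)
}

#' Time-step update (equation of motion)
#'
#' Advances every vertex by
#' `p[t+1] = p[t] + (1 - gamma) (p[t] - p[t-1]) + w_internal F_int + F_ext`,
#' where `F_ext` is the weighted sum of the external force terms (see
#' [compose_external()]), and updates the stored previous positions.
#'
#' @param mesh a `simplex_mesh`.
#' @param f_int internal force matrix (`V x 3`), unweighted.
#' @param f_ext composed external force matrix (`V x 3`), already weighted.
#' @param params a [stage_parameters()].
#' @return The updated `simplex_mesh`.
#' @export
step_mesh <- function(mesh, f_int, f_ext, params) {
  disp <- (1 - params$gamma) * (mesh$vertices - mesh$prev_vertices) +
    params$w_internal * f_int + f_ext
  if (any(!is.finite(disp))) {
    bad <- which(!is.finite(rowSums(disp)))[1L]
    stop("non-finite displacement at vertex ", bad)
  }
  mesh$prev_vertices <- mesh$vertices
  mesh$vertices <- mesh$vertices + disp
  mesh
}

#' @rdname step_mesh
#' @param gradient,edge,balloon,collision unweighted force matrices
#'   (`V x 3`); `NULL` terms are treated as zero.
#' @return `compose_external()`: the weighted external force sum, with any
#'   non-finite term reported by name.
#' @export
compose_external <- function(params, gradient = NULL, edge = NULL,
                             balloon = NULL, collision = NULL) {
  terms <- list(gradient = gradient, edge = edge, balloon = balloon,
                collision = collision)
  weights <- c(gradient = params$w_gradient, edge = params$w_edge,
               balloon = params$w_balloon, collision = params$w_collision)
  out <- NULL
  for (nm in names(terms)) {
    tm <- terms[[nm]]
    if (is.null(tm)) next
    if (any(!is.finite(tm))) {
      bad <- which(!is.finite(rowSums(tm)))[1L]
      stop("non-finite ", nm, " force at vertex ", bad)
    }
    out <- if (is.null(out)) weights[[nm]] * tm else out + weights[[nm]] * tm
  }
  if (is.null(out)) stop("at least one external force term is required")
  out
}
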