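#' @useDynLib multiseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Triangulation primitives (the simplex mesh is built as the dual of a
# subdivided icosahedron; refinement re-dualizes a subdivided copy of the
# mesh's own dual triangulation).
# ---------------------------------------------------------------------------

icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  # enforce outward winding (unit sphere centered at the origin)
  for (f in seq_len(nrow(F))) {
    a <- V[F[f, 1L], ]; b <- V[F[f, 2L], ]; c3 <- V[F[f, 3L], ]
    if (sum(cross3(b - a, c3 - a) * (a + b + c3)) < 0)
      F[f, ] <- F[f, c(1L, 3L, 2L)]
  }
  list(V = V, F = F)
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Row-wise cross product of n x 3 matrices.
cross_rows <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

row_norms <- function(m) sqrt(rowSums(m^2))

# One 4-to-1 midpoint subdivision; child winding follows the parent's.
subdivide_tri <- function(V, F, project_unit = FALSE) {
  nv <- nrow(V)
  ea <- pmin(F[, c(1L, 2L, 3L)], F[, c(2L, 3L, 1L)])
  eb <- pmax(F[, c(1L, 2L, 3L)], F[, c(2L, 3L, 1L)])
  key <- paste(as.vector(ea), as.vector(eb))
  uk <- unique(key)
  mid_id <- nv + match(key, uk)
  dim(mid_id) <- dim(ea)
  first <- match(uk, key)
  mids <- (V[as.vector(ea)[first], , drop = FALSE] +
           V[as.vector(eb)[first], , drop = FALSE]) / 2
  V2 <- rbind(V, mids)
  if (project_unit) V2 <- V2 / row_norms(V2)
  a <- F[, 1L]; b <- F[, 2L]; c3 <- F[, 3L]
  ab <- mid_id[, 1L]; bc <- mid_id[, 2L]; ca <- mid_id[, 3L]
  F2 <- rbind(cbind(a, ab, ca), cbind(b, bc, ab), cbind(c3, ca, bc),
              cbind(ab, bc, ca))
  list(V = V2, F = F2)
}

# Dualize a closed triangulation: one simplex vertex per triangle (at the
# given positions), polygons (simplex faces) around each triangulation
# vertex, neighbour triples across shared edges. Neighbour column order is
# fixed per vertex so that the implied normal points to the same side as the
# triangulation face normal, which is outward by construction.
dual_from_tri <- function(V, F, positions) {
  nf <- nrow(F)
  # neighbour across edge k of face f, edges in order (a,b),(b,c),(c,a)
  ea <- pmin(F[, c(1L, 2L, 3L)], F[, c(2L, 3L, 1L)])
  eb <- pmax(F[, c(1L, 2L, 3L)], F[, c(2L, 3L, 1L)])
  key <- paste(as.vector(ea), as.vector(eb))
  face_of <- rep(seq_len(nf), 3L)
  ord <- order(key)
  k2 <- key[ord]; f2 <- face_of[ord]
  if (any(k2[seq(1L, length(k2), 2L)] != k2[seq(2L, length(k2), 2L)]))
    stop("triangulation is not a closed 2-manifold")
  partner <- integer(length(key))
  partner[ord[seq(1L, length(k2), 2L)]] <- f2[seq(2L, length(k2), 2L)]
  partner[ord[seq(2L, length(k2), 2L)]] <- f2[seq(1L, length(k2), 2L)]
  neighbours <- matrix(partner, nrow = nf, ncol = 3L)

  # orient: neighbour-triangle normal should match the face normal
  fn <- cross_rows(V[F[, 2L], , drop = FALSE] - V[F[, 1L], , drop = FALSE],
                   V[F[, 3L], , drop = FALSE] - V[F[, 1L], , drop = FALSE])
  p1 <- positions[neighbours[, 1L], , drop = FALSE]
  p2 <- positions[neighbours[, 2L], , drop = FALSE]
  p3 <- positions[neighbours[, 3L], , drop = FALSE]
  nn <- cross_rows(p2 - p1, p3 - p1)
  flip <- rowSums(nn * fn) < 0
  if (any(flip))
    neighbours[flip, 2:3] <- neighbours[flip, 3:2]

  # polygons: walk faces around every triangulation vertex
  vert_faces <- split(face_of, as.vector(F))
  vert_pos <- split(rep(1:3, each = nf), as.vector(F))
  faces <- vector("list", nrow(V))
  adj <- matrix(partner, nrow = nf, ncol = 3L)  # unflipped, edge-ordered
  for (v in seq_len(nrow(V))) {
    fs <- vert_faces[[v]]
    f0 <- fs[1L]
    cyc <- integer(length(fs))
    f <- f0
    for (j in seq_along(fs)) {
      cyc[j] <- f
      k <- which(F[f, ] == v)            # edge starting at v is edge k
      f <- adj[f, k]
    }
    faces[[v]] <- cyc
  }

  mesh <- structure(list(
    vertices = positions,
    neighbours = neighbours,
    faces = faces,
    vertex_faces = F,
    prev_vertices = positions,
    ref_eps = NULL,
    ref_angle = NULL), class = "simplex_mesh")
  # orient face cycles outward (positive enclosed volume), matching the
  # vertex-normal convention
  if (mesh_volume(mesh) < 0)
    mesh$faces <- lapply(mesh$faces, rev)
  set_reference_params(mesh)
}

# Store the metric (barycentric) parameters and simplex angle of the current
# geometry as the reference configuration for the internal force.
set_reference_params <- function(mesh) {
  geo <- simplex_geometry(mesh)
  p <- mesh$vertices
  p1 <- mesh$vertices[mesh$neighbours[, 1L], , drop = FALSE]
  p2 <- mesh$vertices[mesh$neighbours[, 2L], , drop = FALSE]
  p3 <- mesh$vertices[mesh$neighbours[, 3L], , drop = FALSE]
  u <- p2 - p1; v <- p3 - p1; w <- p - p1
  uu <- rowSums(u * u); vv <- rowSums(v * v); uv <- rowSums(u * v)
  wu <- rowSums(w * u); wv <- rowSums(w * v)
  det <- uu * vv - uv^2
  det[det < 1e-300] <- NA_real_
  s <- (wu * vv - wv * uv) / det
  t <- (wv * uu - wu * uv) / det
  mesh$ref_eps <- cbind(1 - s - t, s, t)
  mesh$ref_angle <- geo$phi
  mesh
}

# ---------------------------------------------------------------------------
# Construction
# ---------------------------------------------------------------------------

#' Build a spherical simplex mesh
#'
#' Constructs the dual of an icosahedron subdivided `subdivisions` times,
#' with every simplex vertex projected onto the sphere of the given center
#' and radius. Every vertex has exactly three neighbours; with
#' `subdivisions = 0` the mesh is the 20-vertex dual of the icosahedron
#' (a dodecahedron) and each subdivision multiplies the vertex count by 4.
#'
#' @param center world coordinates (mm) of the sphere center.
#' @param radius sphere radius in mm, strictly positive.
#' @param subdivisions number of 4-to-1 subdivisions of the icosahedron.
#' @return A `simplex_mesh`: vertex positions, ordered neighbour triples,
#'   polygon faces, and the reference metric parameters / simplex angles
#'   used by the internal force.
#' @export
build_simplex_sphere <- function(center, radius, subdivisions = 1L) {
  center <- as.numeric(center)
  if (length(center) != 3L || any(!is.finite(center)))
    stop("`center` must be a finite 3-D point")
  if (!is.finite(radius) || radius <= 0)
    stop("`radius` must be strictly positive")
  if (subdivisions < 0) stop("`subdivisions` must be >= 0")
  tri <- icosahedron()
  for (k in seq_len(subdivisions))
    tri <- subdivide_tri(tri$V, tri$F, project_unit = TRUE)
  centroids <- (tri$V[tri$F[, 1L], , drop = FALSE] +
                tri$V[tri$F[, 2L], , drop = FALSE] +
                tri$V[tri$F[, 3L], , drop = FALSE]) / 3
  pos <- centroids / row_norms(centroids) * radius
  pos <- sweep(pos, 2L, center, "+")
  Vw <- sweep(tri$V * radius, 2L, center, "+")
  dual_from_tri(Vw, tri$F, pos)
}

#' @export
print.simplex_mesh <- function(x, ...) {
  cat(sprintf("<simplex_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), length(x$faces)))
  invisible(x)
}

#' Number of vertices of a simplex mesh
#' @param mesh a `simplex_mesh`.
#' @return integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

# ---------------------------------------------------------------------------
# Differential geometry
# ---------------------------------------------------------------------------

# Per-vertex geometry of the whole mesh in one pass. For vertex p with
# neighbours p1..p3: n = unit normal of the neighbour plane (orientation
# fixed at construction); cc/r = circumcenter/radius of the neighbour
# triangle; d = signed height of p over the plane; rho = in-plane distance
# of p's projection from cc; phi = simplex angle, the signed angle of p on
# the circumscribed sphere of the four points (0 when coplanar).
simplex_geometry <- function(mesh) {
  p <- mesh$vertices
  p1 <- p[mesh$neighbours[, 1L], , drop = FALSE]
  p2 <- p[mesh$neighbours[, 2L], , drop = FALSE]
  p3 <- p[mesh$neighbours[, 3L], , drop = FALSE]
  u <- p2 - p1
  v <- p3 - p1
  m <- cross_rows(u, v)
  m2 <- rowSums(m^2)
  scale2 <- rowSums(u^2) * rowSums(v^2)
  degenerate <- m2 <= 1e-24 * pmax(scale2, 1e-300)
  n <- m / pmax(sqrt(m2), 1e-300)
  uu <- rowSums(u * u); vv <- rowSums(v * v)
  cc <- p1 + cross_rows(sweep(v, 1L, uu, "*") - sweep(u, 1L, vv, "*"), m) /
    (2 * pmax(m2, 1e-300))
  r <- row_norms(cc - p1)
  d <- rowSums((p - p1) * n)
  proj <- p - sweep(n, 1L, d, "*")
  rho <- row_norms(proj - cc)
  s <- sign(d)
  t <- (rho^2 + d^2 - r^2) / (2 * d)
  t[abs(d) < 1e-12 * pmax(r, 1e-300)] <- NA_real_
  phi <- ifelse(is.na(t), 0, atan2(r * s, -t * s))
  phi[degenerate] <- NA_real_
  list(n = n, cc = cc, r = r, d = d, rho = rho, phi = phi,
       degenerate = degenerate)
}

#' Simplex angle, vertex normal and mean curvature
#'
#' The simplex angle of a vertex is the signed angle encoding how far the
#' vertex lifts out of the plane of its three neighbours (0 when coplanar,
#' positive along the outward normal). The mean curvature at a vertex is
#' `sin(phi) / r` with `r` the circumradius of the neighbour triangle, which
#' equals `1/R` exactly on a sphere of radius `R`. Normals are unit vectors
#' oriented outward (fixed at construction time).
#'
#' @param mesh a `simplex_mesh`.
#' @param i vertex index or vector of indices; `NULL` for all vertices.
#' @return Numeric vector (angle in radians, curvature in 1/mm) or an
#'   `n x 3` matrix of unit normals.
#' @export
simplex_angle <- function(mesh, i = NULL) {
  geo <- simplex_geometry(mesh)
  idx <- if (is.null(i)) seq_len(n_vertices(mesh)) else check_vertex_index(mesh, i)
  if (any(geo$degenerate[idx]))
    stop("degenerate (collinear) neighbour triple at vertex ",
         idx[which(geo$degenerate[idx])[1L]])
  geo$phi[idx]
}

#' @rdname simplex_angle
#' @export
vertex_normal <- function(mesh, i = NULL) {
  geo <- simplex_geometry(mesh)
  idx <- if (is.null(i)) seq_len(n_vertices(mesh)) else check_vertex_index(mesh, i)
  if (any(geo$degenerate[idx]))
    stop("degenerate (collinear) neighbour triple at vertex ",
         idx[which(geo$degenerate[idx])[1L]])
  geo$n[idx, , drop = FALSE]
}

#' @rdname simplex_angle
#' @export
mean_curvature <- function(mesh, i = NULL) {
  geo <- simplex_geometry(mesh)
  idx <- if (is.null(i)) seq_len(n_vertices(mesh)) else check_vertex_index(mesh, i)
  if (any(geo$degenerate[idx]))
    stop("degenerate (collinear) neighbour triple at vertex ",
         idx[which(geo$degenerate[idx])[1L]])
  (sin(geo$phi) / geo$r)[idx]
}

check_vertex_index <- function(mesh, i) {
  i <- as.integer(i)
  if (any(is.na(i)) || any(i < 1L) || any(i > n_vertices(mesh)))
    stop("vertex index out of range")
  i
}

# Vertices within graph distance <= s of each vertex (including itself),
# used to average simplex angles at the configured smoothness scale.
vertex_neighbourhoods <- function(mesh, s) {
  nb <- mesh$neighbours
  V <- n_vertices(mesh)
  out <- vector("list", V)
  for (i in seq_len(V)) {
    seen <- i
    frontier <- i
    for (k in seq_len(s)) {
      nxt <- unique(as.vector(nb[frontier, ]))
      frontier <- setdiff(nxt, seen)
      if (length(frontier) == 0L) break
      seen <- c(seen, frontier)
    }
    out[[i]] <- seen
  }
  out
}

# Mean edge length in mm (edge = vertex-neighbour link).
mean_edge_length <- function(mesh) {
  p <- mesh$vertices
  tot <- 0
  for (k in 1:3)
    tot <- tot + sum(row_norms(p[mesh$neighbours[, k], , drop = FALSE] - p))
  tot / (3 * n_vertices(mesh))
}

# Signed enclosed volume (divergence theorem over the fan triangulation);
# positive for outward-oriented meshes.
mesh_volume <- function(mesh) {
  tris <- mesh_triangles(mesh)
  a <- tris[, 1:3, drop = FALSE]
  b <- tris[, 4:6, drop = FALSE]
  c3 <- tris[, 7:9, drop = FALSE]
  sum(rowSums(a * cross_rows(b, c3))) / 6
}

# Triangle soup (ntri x 9 world coords) from the polygon faces: a corner
# fan per face, so every triangle corner is an actual mesh vertex and the
# soup interpolates the surface. Winding follows the face cycles, which are
# oriented outward at construction.
mesh_triangles <- function(mesh) {
  p <- mesh$vertices
  nt <- sum(lengths(mesh$faces)) - 2L * length(mesh$faces)
  out <- matrix(0, nt, 9L)
  row <- 1L
  for (f in mesh$faces) {
    k <- length(f)
    idx <- row:(row + k - 3L)
    out[idx, 1:3] <- matrix(p[f[1L], ], k - 2L, 3L, byrow = TRUE)
    out[idx, 4:6] <- p[f[2:(k - 1L)], ]
    out[idx, 7:9] <- p[f[3:k], ]
    row <- row + k - 2L
  }
  out
}

# ---------------------------------------------------------------------------
# Validation, refinement, rasterization
# ---------------------------------------------------------------------------

#' Validate simplex mesh invariants
#'
#' Checks that every vertex has three distinct neighbours, the neighbour
#' relation is symmetric, and the dual triangulation is a closed 2-manifold
#' with the Euler characteristic of a sphere.
#'
#' @param mesh a `simplex_mesh`.
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_mesh <- function(mesh) {
  V <- n_vertices(mesh)
  nb <- mesh$neighbours
  if (!is.matrix(nb) || ncol(nb) != 3L || nrow(nb) != V)
    stop("neighbour table must be V x 3")
  if (any(nb < 1L | nb > V)) stop("neighbour index out of range")
  if (any(apply(nb, 1L, function(r) length(unique(r)) != 3L)))
    stop("a vertex has fewer than 3 distinct neighbours")
  for (k in 1:3) {
    j <- nb[, k]
    back <- nb[j, 1L] == seq_len(V) | nb[j, 2L] == seq_len(V) |
      nb[j, 3L] == seq_len(V)
    if (!all(back)) stop("neighbour relation is not symmetric")
  }
  n_faces <- length(mesh$faces)
  n_edges <- 3L * V / 2L
  if (V - n_edges + n_faces != 2L)
    stop("mesh is not a closed sphere-topology surface (Euler characteristic ",
         V - n_edges + n_faces, ")")
  invisible(TRUE)
}

#' Refine a simplex mesh
#'
#' Increases mesh resolution by subdividing the dual triangulation once
#' (4-to-1 midpoint subdivision), re-dualizing, and projecting the new
#' vertices onto the input surface. The vertex count grows by a factor of 4
#' (at least the required two-fold increase per deformation stage) and all
#' simplex-mesh invariants are preserved; reference parameters are
#' re-initialized from the refined geometry.
#'
#' @param mesh a valid closed `simplex_mesh`.
#' @param check_self_intersection if `TRUE`, run a triangle-triangle
#'   intersection scan on the input first and emit a warning diagnostic if
#'   the surface self-intersects (refinement still proceeds; there is no
#'   repair step).
#' @return The refined `simplex_mesh`.
#' @export
refine <- function(mesh, check_self_intersection = FALSE) {
  validate_mesh(mesh)
  if (check_self_intersection && mesh_self_intersects(mesh))
    warning("input mesh self-intersects; refining anyway (no repair step)")
  p <- mesh$vertices
  Vt <- t(vapply(mesh$faces, function(f) colMeans(p[f, , drop = FALSE]),
                 numeric(3L)))
  Ft <- mesh$vertex_faces
  tri <- subdivide_tri(Vt, Ft)
  centroids <- (tri$V[tri$F[, 1L], , drop = FALSE] +
                tri$V[tri$F[, 2L], , drop = FALSE] +
                tri$V[tri$F[, 3L], , drop = FALSE]) / 3
  pos <- project_interpolated(mesh, centroids)
  dual_from_tri(tri$V, tri$F, pos)
}

# Vertex indices (nt x 3) of the corner-fan triangle soup, aligned with
# mesh_triangles() rows.
mesh_triangle_indices <- function(mesh) {
  nt <- sum(lengths(mesh$faces)) - 2L * length(mesh$faces)
  out <- matrix(0L, nt, 3L)
  row <- 1L
  for (f in mesh$faces) {
    k <- length(f)
    idx <- row:(row + k - 3L)
    out[idx, 1L] <- f[1L]
    out[idx, 2L] <- f[2:(k - 1L)]
    out[idx, 3L] <- f[3:k]
    row <- row + k - 2L
  }
  out
}

# Closest point on the mesh surface, lifted by Phong tessellation: the flat
# closest point is re-expressed in barycentric coordinates of its triangle
# and blended with its projections onto the three vertex tangent planes, so
# refinement interpolates the curved surface implied by the vertex normals
# rather than the flat facets. alpha = 3/4 is the standard blend.
project_interpolated <- function(mesh, points, alpha = 0.75) {
  soup <- mesh_triangles(mesh)
  tidx <- mesh_triangle_indices(mesh)
  pr <- project_to_surface(points, soup)
  q <- pr[, 1:3, drop = FALSE]
  ti <- as.integer(pr[, 4L])
  vi <- tidx[ti, , drop = FALSE]
  normals <- simplex_geometry(mesh)$n
  P1 <- mesh$vertices[vi[, 1L], , drop = FALSE]
  P2 <- mesh$vertices[vi[, 2L], , drop = FALSE]
  P3 <- mesh$vertices[vi[, 3L], , drop = FALSE]
  u <- P2 - P1; v <- P3 - P1; w <- q - P1
  uu <- rowSums(u * u); vv <- rowSums(v * v); uv <- rowSums(u * v)
  det <- pmax(uu * vv - uv^2, 1e-300)
  b2 <- (rowSums(w * u) * vv - rowSums(w * v) * uv) / det
  b3 <- (rowSums(w * v) * uu - rowSums(w * u) * uv) / det
  b1 <- 1 - b2 - b3
  lift <- matrix(0, nrow(q), 3L)
  for (k in 1:3) {
    Pk <- mesh$vertices[vi[, k], , drop = FALSE]
    Nk <- normals[vi[, k], , drop = FALSE]
    pk <- q - sweep(Nk, 1L, rowSums((q - Pk) * Nk), "*")
    bk <- switch(k, b1, b2, b3)
    lift <- lift + sweep(pk, 1L, bk, "*")
  }
  (1 - alpha) * q + alpha * lift
}

# Brute-force (bbox-prefiltered) self-intersection scan over the fan
# triangulation; intended for diagnostics at coarse resolution.
mesh_self_intersects <- function(mesh) {
  tris <- mesh_triangles(mesh)
  nt <- nrow(tris)
  lo <- pmin(tris[, 1:3], tris[, 4:6], tris[, 7:9])
  hi <- pmax(tris[, 1:3], tris[, 4:6], tris[, 7:9])
  for (i in seq_len(nt - 1L)) {
    cand <- which(hi[, 1L] >= lo[i, 1L] & lo[, 1L] <= hi[i, 1L] &
                  hi[, 2L] >= lo[i, 2L] & lo[, 2L] <= hi[i, 2L] &
                  hi[, 3L] >= lo[i, 3L] & lo[, 3L] <= hi[i, 3L])
    cand <- cand[cand > i]
    for (j in cand) {
      if (triangles_share_point(tris[i, ], tris[j, ])) next
      if (tri_tri_intersect(tris[i, ], tris[j, ])) return(TRUE)
    }
  }
  FALSE
}

triangles_share_point <- function(t1, t2) {
  a <- matrix(t1, 3L, 3L, byrow = TRUE)
  b <- matrix(t2, 3L, 3L, byrow = TRUE)
  for (i in 1:3) for (j in 1:3)
    if (all(abs(a[i, ] - b[j, ]) < 1e-12)) return(TRUE)
  FALSE
}

tri_tri_intersect <- function(t1, t2) {
  a <- matrix(t1, 3L, 3L, byrow = TRUE)
  b <- matrix(t2, 3L, 3L, byrow = TRUE)
  seg_hits_tri <- function(p, q, tri) {
    u <- tri[2L, ] - tri[1L, ]; v <- tri[3L, ] - tri[1L, ]
    n <- cross3(u, v)
    d <- q - p
    den <- sum(n * d)
    if (abs(den) < 1e-14) return(FALSE)
    s <- sum(n * (tri[1L, ] - p)) / den
    if (s <= 0 || s >= 1) return(FALSE)
    x <- p + s * d - tri[1L, ]
    uu <- sum(u * u); vv <- sum(v * v); uv <- sum(u * v)
    det <- uu * vv - uv^2
    if (det < 1e-300) return(FALSE)
    su <- (sum(x * u) * vv - sum(x * v) * uv) / det
    tv <- (sum(x * v) * uu - sum(x * u) * uv) / det
    su > 0 && tv > 0 && su + tv < 1
  }
  for (k in 1:3) {
    if (seg_hits_tri(a[k, ], a[k %% 3L + 1L, ], b)) return(TRUE)
    if (seg_hits_tri(b[k, ], b[k %% 3L + 1L, ], a)) return(TRUE)
  }
  FALSE
}

#' Rasterize a simplex mesh to a binary mask
#'
#' Voxels whose centers lie inside the closed surface get value 1; inside-
#' ness is decided by the parity of ray crossings against the triangulated
#' surface (a fan over each polygon face). A self-intersecting mesh still
#' produces a mask by the parity rule, which may contain holes.
#'
#' @param mesh a closed `simplex_mesh`.
#' @param grid a [scalar_volume()] (or [binary_mask()]) defining the target
#'   grid; its values are ignored.
#' @return A [binary_mask()] on `grid`'s grid.
#' @export
rasterize <- function(mesh, grid) {
  validate_mesh(mesh)
  tris <- mesh_triangles(mesh)
  vox <- matrix(0, nrow(tris), 9L)
  for (k in 0:2) {
    cols <- k * 3L + 1:3
    vox[, cols] <- world_to_voxel(grid, tris[, cols, drop = FALSE])
  }
  dm <- dim(grid$values)
  m <- raster_parity(vox, as.integer(dm))
  binary_mask(array(m, dm), grid$spacing, grid$origin)
}
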