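#' Collision energy images
#'
#' For N meshes with rasterized binary masks `M_1..M_N` on a common grid,
#' the collision energy image of mesh i is the voxelwise exclusive-or of
#' all *other* masks: `C_i = M_j1 XOR M_j2 XOR ...` over `j != i`. A vertex
#' of mesh i standing in a voxel where `C_i = 1` is in collision (it has
#' entered territory claimed by an odd number of other meshes). With a
#' single mesh the energy is identically zero. The XOR is implemented
#' literally; `mode = "union"` is available for robustness experiments
#' where mutually overlapping other masks should still repel.
#'
#' @param masks list of [binary_mask()] objects on one common grid.
#' @param mode `"xor"` (the collision scheme) or `"union"`.
#' @return A `collision_energy_set`: the input `masks` and the list
#'   `energies` of N binary masks.
#' @export
build_energy_images <- function(masks, mode = c("xor", "union")) {
  mode <- match.arg(mode)
  if (length(masks) < 1L) stop("at least one mask is required")
  for (m in masks[-1L])
    if (!same_grid(masks[[1L]], m)) stop("masks are not on a common grid")
  total <- Reduce(`+`, lapply(masks, function(m) m$values))
  energies <- lapply(masks, function(m) {
    rest <- total - m$values
    e <- if (mode == "xor") rest %% 2L else pmin(rest, 1L)
    binary_mask(array(as.integer(e), dim(m$values)), m$spacing, m$origin)
  })
  structure(list(masks = masks, energies = energies, mode = mode),
            class = "collision_energy_set")
}

#' Detect colliding vertices
#'
#' Returns the indices of mesh vertices whose containing voxel has value 1
#' in the mesh's collision energy image. Vertices outside the grid are
#' treated as non-colliding.
#'
#' @param mesh a `simplex_mesh`.
#' @param energy the mesh's collision energy [binary_mask()].
#' @return Integer vector of colliding vertex indices (possibly empty).
#' @export
detect_collisions <- function(mesh, energy) {
  val <- sample_volume_nn(energy, mesh$vertices, outside = 0)
  which(!is.na(val) & val == 1)
}
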