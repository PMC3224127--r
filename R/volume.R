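#' 3-D scalar volume
#'
#' A minimal container for a 3-D image grid: an array of values plus the
#' voxel spacing (mm) and the world position of voxel `(0,0,0)`. Voxel
#' coordinates are 0-based and refer to voxel centers, so the world <->
#' voxel mapping is the affine `world = origin + voxel * spacing` applied
#' per axis.
#'
#' @param values numeric 3-D array.
#' @param spacing positive numeric vector of length 3, voxel size in mm.
#' @param origin numeric vector of length 3, world coordinates of the center
#'   of voxel `(0,0,0)`.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "scalar_volume")
}

#' Binary voxel mask
#'
#' A [scalar_volume()] whose values are restricted to 0/1, on a grid
#' identical to its source volume. Masks are the currency of the collision
#' energy images and of the final per-object segmentations.
#'
#' @inheritParams scalar_volume
#' @return An object of classes `binary_mask` and `scalar_volume`.
#' @export
binary_mask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  storage.mode(values) <- "integer"
  if (!all(values %in% c(0L, 1L)))
    stop("mask values must be 0 or 1")
  v <- scalar_volume(values, spacing, origin)
  class(v) <- c("binary_mask", class(v))
  v
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin %s\n",
              class(x)[1L], paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' Grid helpers
#'
#' `same_grid()` tests that two volumes share shape, spacing and origin.
#' `world_to_voxel()` / `voxel_to_world()` convert between world (mm)
#' coordinates and 0-based continuous voxel coordinates.
#'
#' @param a,b volumes.
#' @return `same_grid()` a logical scalar; the converters a matrix with one
#'   row per point.
#' @export
same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' @rdname same_grid
#' @param vol a [scalar_volume()].
#' @param points numeric matrix (n x 3) or length-3 vector.
#' @export
world_to_voxel <- function(vol, points) {
  p <- to_point_matrix(points)
  sweep(sweep(p, 2L, vol$origin, "-"), 2L, vol$spacing, "/")
}

#' @rdname same_grid
#' @export
voxel_to_world <- function(vol, points) {
  p <- to_point_matrix(points)
  sweep(sweep(p, 2L, vol$spacing, "*"), 2L, vol$origin, "+")
}

to_point_matrix <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  p <- as.matrix(points)
  if (ncol(p) != 3L) stop("points must have 3 columns")
  storage.mode(p) <- "double"
  dimnames(p) <- NULL
  p
}

# Nearest-voxel (1-based array) indices for world points; rows outside the
# grid get NA.
nearest_voxel_index <- function(vol, points) {
  v <- round(world_to_voxel(vol, points))
  dm <- dim(vol$values)
  outside <- v[, 1L] < 0 | v[, 1L] >= dm[1L] |
    v[, 2L] < 0 | v[, 2L] >= dm[2L] |
    v[, 3L] < 0 | v[, 3L] >= dm[3L]
  v[outside, ] <- NA_real_
  storage.mode(v) <- "integer"
  v + 1L
}

# Nearest-neighbour sample of a volume at world points (NA outside).
sample_volume_nn <- function(vol, points, outside = NA_real_) {
  idx <- nearest_voxel_index(vol, points)
  out <- rep(outside, nrow(idx))
  ok <- !is.na(idx[, 1L])
  if (any(ok)) out[ok] <- vol$values[idx[ok, , drop = FALSE]]
  out
}

#' Gaussian smoothing and gradient magnitude
#'
#' `smooth_volume()` applies a separable Gaussian kernel (sigma in voxels,
#' replicated edges). `gradient_magnitude()` returns the central-difference
#' gradient magnitude in intensity units per mm, optionally smoothing first;
#' it is the image feature that the gradient and collision forces search.
#'
#' @param vol a [scalar_volume()].
#' @param sigma Gaussian sigma in voxels; 0 disables smoothing.
#' @return A [scalar_volume()] on the same grid.
#' @export
smooth_volume <- function(vol, sigma = 1) {
  if (sigma <= 0) return(vol)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  out <- vol$values
  for (axis in 1:3) out <- convolve_axis(out, k, axis)
  scalar_volume(out, vol$spacing, vol$origin)
}

# Shift-and-add separable convolution with edge replication.
convolve_axis <- function(arr, kernel, axis) {
  r <- (length(kernel) - 1L) %/% 2L
  out <- array(0, dim(arr))
  for (j in seq_along(kernel)) {
    out <- out + kernel[j] * shift_array(arr, j - r - 1L, axis, replicate = TRUE)
  }
  out
}

# Shift an array by `by` voxels along `axis`; vacated voxels take either the
# edge value (replicate = TRUE) or `fill`.
shift_array <- function(arr, by, axis, replicate = FALSE, fill = 0) {
  if (by == 0L) return(arr)
  dm <- dim(arr)
  n <- dm[axis]
  src <- pmin(pmax(seq_len(n) - by, 1L), n)
  if (!replicate) {
    valid <- seq_len(n) - by >= 1L & seq_len(n) - by <= n
  }
  idx <- list(seq_len(dm[1L]), seq_len(dm[2L]), seq_len(dm[3L]))
  idx[[axis]] <- src
  out <- arr[idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE]
  if (!replicate && any(!valid)) {
    sel <- list(seq_len(dm[1L]), seq_len(dm[2L]), seq_len(dm[3L]))
    sel[[axis]] <- which(!valid)
    out[sel[[1L]], sel[[2L]], sel[[3L]]] <- fill
  }
  out
}

#' @rdname smooth_volume
#' @export
gradient_magnitude <- function(vol, sigma = 0) {
  v <- smooth_volume(vol, sigma)
  g2 <- array(0, dim(v$values))
  for (axis in 1:3) {
    fwd <- shift_array(v$values, -1L, axis, replicate = TRUE)
    bwd <- shift_array(v$values, 1L, axis, replicate = TRUE)
    g2 <- g2 + ((fwd - bwd) / (2 * v$spacing[axis]))^2
  }
  scalar_volume(sqrt(g2), vol$spacing, vol$origin)
}
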