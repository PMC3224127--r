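#' Histogram thresholds for the tube (container) mask
#'
#' Builds the intensity histogram of the image and derives the threshold
#' pair separating the sample container ("tube") from the dark exterior
#' background: the lower threshold is the mean intensity of the voxels in
#' the bin holding the first local minimum after the first (lowest-
#' intensity) highest peak, and the upper threshold is the data maximum.
#' Peak and minimum detection run on a lightly smoothed copy of the bin
#' counts (centered moving average), so shot noise in a broad background
#' mode cannot fake a premature minimum. Ties between equal-height peaks
#' resolve to the lower-intensity bin; the local minimum is the first bin
#' at higher intensity whose count is no larger than both neighbours.
#'
#' @param image a [scalar_volume()].
#' @param nbins number of histogram bins, >= 8.
#' @return A `histogram_thresholds` list with `t_low`, `t_high`, and the
#'   histogram (`breaks`, `counts`).
#' @export
find_tube_thresholds <- function(image, nbins = 256L) {
  nbins <- as.integer(nbins)
  if (nbins < 8L) stop("`nbins` must be >= 8")
  x <- as.vector(image$values)
  rng <- range(x)
  if (rng[1L] == rng[2L]) stop("image is constant; set thresholds manually")
  breaks <- seq(rng[1L], rng[2L], length.out = nbins + 1L)
  bin <- .bincode(x, breaks, right = TRUE, include.lowest = TRUE)
  counts <- tabulate(bin, nbins)
  # detect on smoothed counts (truncated centered moving average)
  h <- if (nbins >= 64L) 2L else 1L
  smoothed <- vapply(seq_len(nbins), function(j)
    mean(counts[max(1L, j - h):min(nbins, j + h)]), numeric(1L))
  peak <- which.max(smoothed)          # ties: lowest-intensity bin
  minimum <- NA_integer_
  if (peak + 1L <= nbins - 1L) {
    for (j in (peak + 1L):(nbins - 1L)) {
      if (smoothed[j] <= smoothed[j - 1L] && smoothed[j] <= smoothed[j + 1L]) {
        minimum <- j
        break
      }
    }
  }
  if (is.na(minimum))
    stop("no local minimum after the first highest peak; ",
         "the histogram is monotone there - supply thresholds manually")
  members <- which(bin == minimum)
  # mean intensity of the voxels in the minimum bin; an empty bin falls
  # back to its center
  t_low <- if (length(members) > 0L) mean(x[members])
           else (breaks[minimum] + breaks[minimum + 1L]) / 2
  structure(list(t_low = t_low, t_high = rng[2L],
                 breaks = breaks, counts = counts,
                 peak_bin = peak, minimum_bin = minimum),
            class = "histogram_thresholds")
}

#' Binary tube mask from thresholds
#'
#' Thresholds the original image to `[t_low, t_high]` and, by default,
#' keeps only the largest 26-connected component with internal holes
#' filled, so stray bright voxels outside the container do not join the
#' mask. The mask is the hard spatial constraint of the deformation: no
#' vertex displacement may leave it.
#'
#' @param image a [scalar_volume()].
#' @param thresholds a `histogram_thresholds` (or any list with `t_low`,
#'   `t_high`).
#' @param cleanup keep largest component and fill holes (default `TRUE`).
#' @return A [binary_mask()].
#' @export
make_tube_mask <- function(image, thresholds, cleanup = TRUE) {
  m <- image$values >= thresholds$t_low & image$values <= thresholds$t_high
  if (!any(m)) stop("thresholds produce an empty tube mask")
  m <- array(as.integer(m), dim(image$values))
  if (cleanup && !all(m == 1L)) {
    m <- largest_component(m, connectivity = 26L)
    m <- fill_holes(m)
  }
  binary_mask(m, image$spacing, image$origin)
}

# Positive half of the 26- or 6-neighbourhood offsets.
half_offsets <- function(connectivity) {
  if (connectivity == 6L) {
    rbind(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  } else {
    g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    ord <- g[, 3L] * 9L + g[, 2L] * 3L + g[, 1L]
    g[ord > 0L, , drop = FALSE]
  }
}

# Connected-component labels of the foreground of a 0/1 array (graph
# components over voxel adjacency).
label_components <- function(arr, connectivity = 26L) {
  dm <- dim(arr)
  fg <- which(arr == 1L)
  if (length(fg) == 0L) return(list(labels = integer(0), voxels = integer(0)))
  id <- array(0L, dm)
  id[fg] <- seq_along(fg)
  edges <- list()
  for (k in seq_len(nrow(half_offsets(connectivity)))) {
    off <- half_offsets(connectivity)[k, ]
    a <- shift_array(id, off[1L], 1L, fill = 0L)
    a <- shift_array(a, off[2L], 2L, fill = 0L)
    a <- shift_array(a, off[3L], 3L, fill = 0L)
    both <- id > 0L & a > 0L
    if (any(both)) edges[[length(edges) + 1L]] <- cbind(a[both], id[both])
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges) > 0L)
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)
  list(labels = comp$membership, voxels = fg, sizes = comp$csize)
}

largest_component <- function(arr, connectivity = 26L) {
  lab <- label_components(arr, connectivity)
  if (length(lab$voxels) == 0L) return(arr)
  keep <- which.max(lab$sizes)
  out <- array(0L, dim(arr))
  out[lab$voxels[lab$labels == keep]] <- 1L
  out
}

# Fill internal holes: background components (6-connectivity) that do not
# touch the array border become foreground.
fill_holes <- function(arr) {
  inv <- array(1L - arr, dim(arr))
  lab <- label_components(inv, connectivity = 6L)
  if (length(lab$voxels) == 0L) return(arr)
  dm <- dim(arr)
  coord <- arrayInd(lab$voxels, dm)
  border <- coord[, 1L] == 1L | coord[, 1L] == dm[1L] |
    coord[, 2L] == 1L | coord[, 2L] == dm[2L] |
    coord[, 3L] == 1L | coord[, 3L] == dm[3L]
  border_labels <- unique(lab$labels[border])
  hole <- !(lab$labels %in% border_labels)
  out <- arr
  out[lab$voxels[hole]] <- 1L
  out
}

#' Clamp a displacement to the tube mask
#'
#' Returns the new point if the voxel containing it has mask value 1
#' (points exactly on a mask voxel center are accepted); otherwise the
#' displacement is cancelled and the old point returned unchanged. Rows of
#' matrix input are clamped independently.
#'
#' @param point_old,point_new points (length-3 vectors or n x 3 matrices),
#'   world coordinates.
#' @param mask a [binary_mask()].
#' @return Points of the same shape as the input.
#' @export
clamp_displacement <- function(point_old, point_new, mask) {
  po <- to_point_matrix(point_old)
  pn <- to_point_matrix(point_new)
  if (nrow(po) != nrow(pn)) stop("point sets differ in length")
  old_in <- sample_volume_nn(mask, po, outside = 0) == 1
  if (any(!old_in))
    warning(sum(!old_in), " point(s) already outside the tube mask; ",
            "keeping their previous coordinates")
  new_in <- sample_volume_nn(mask, pn, outside = 0) == 1
  accept <- new_in & old_in
  out <- po
  out[accept, ] <- pn[accept, , drop = FALSE]
  if (is.null(dim(point_new)) || is.null(dim(point_old))) out[1L, ] else out
}
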