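#' Training set for the voxel classifier
#'
#' A labelled list of voxel coordinates for the two classes, object
#' (e.g. embryo) versus background gel. Coordinates are 0-based voxel
#' indices.
#'
#' @param coords integer matrix (n x 3) of 0-based voxel coordinates.
#' @param labels character vector of `"object"` / `"gel"`, one per row.
#' @return A `training_set` object.
#' @export
training_set <- function(coords, labels) {
  coords <- to_point_matrix(coords)
  labels <- as.character(labels)
  if (nrow(coords) != length(labels))
    stop("one label per coordinate row is required")
  if (!all(labels %in% c("object", "gel")))
    stop("labels must be 'object' or 'gel'")
  if (sum(labels == "object") < 2L || sum(labels == "gel") < 2L)
    stop("at least 2 training points per class are required")
  structure(list(coords = coords, labels = labels), class = "training_set")
}

#' Local standard deviation volume
#'
#' Per-voxel standard deviation of the image over a centered cubic window
#' (edge voxels use the truncated window). The local SD is the texture
#' feature that, together with raw intensity, feeds the Bayesian voxel
#' classifier.
#'
#' @param image a [scalar_volume()].
#' @param window odd window edge length in voxels, >= 3.
#' @return A [scalar_volume()] of local standard deviations.
#' @export
local_sd_volume <- function(image, window = 5L) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("`window` must be an odd integer >= 3")
  if (any(window > dim(image$values)))
    stop("`window` is larger than the volume")
  h <- window %/% 2L
  s1 <- box_sum(image$values, h)
  s2 <- box_sum(image$values^2, h)
  n <- box_sum(array(1, dim(image$values)), h)
  v <- pmax(s2 / n - (s1 / n)^2, 0)
  scalar_volume(sqrt(v), image$spacing, image$origin)
}

# Separable truncated box sum with half-width h per axis.
box_sum <- function(arr, h) {
  for (axis in 1:3) {
    out <- array(0, dim(arr))
    for (d in -h:h) out <- out + shift_array(arr, d, axis, fill = 0)
    arr <- out
  }
  arr
}

#' Fit the two-class Bayesian voxel classifier
#'
#' Fits one Gaussian per class to the 2-D feature vectors
#' (intensity, local SD) sampled at the training coordinates: per-class
#' feature centroid and covariance matrix, with class priors proportional
#' to the training counts. A singular covariance is ridge-regularized with
#' a diagnostic.
#'
#' @param image a [scalar_volume()].
#' @param sd_volume the matching [local_sd_volume()].
#' @param training a [training_set()].
#' @return A `class_model` with per-class `mean`, `cov` and `prior`.
#' @export
fit_bayes_classifier <- function(image, sd_volume, training) {
  if (!inherits(training, "training_set")) stop("`training` must be a training_set")
  if (!same_grid(image, sd_volume)) stop("image and SD volume grids differ")
  dm <- dim(image$values)
  co <- training$coords
  if (any(co < 0) || any(co[, 1L] >= dm[1L]) || any(co[, 2L] >= dm[2L]) ||
      any(co[, 3L] >= dm[3L]))
    stop("training coordinate outside the volume")
  idx <- co + 1L
  storage.mode(idx) <- "integer"
  feats <- cbind(intensity = image$values[idx], sd = sd_volume$values[idx])
  classes <- c("object", "gel")
  model <- lapply(classes, function(cl) {
    x <- feats[training$labels == cl, , drop = FALSE]
    mu <- colMeans(x)
    sigma <- stats::cov(x)
    sigma[!is.finite(sigma)] <- 0
    # ridge floor keeps the density proper for degenerate training sets
    ridge <- 1e-6 * max(mean(diag(sigma)), 1)
    if (!is.finite(det(sigma)) || det(sigma) < ridge^2) {
      message("covariance for class '", cl, "' is near-singular; ",
              "ridge-regularizing")
      sigma <- sigma + diag(ridge, 2L)
    }
    list(mean = mu, cov = sigma,
         prior = nrow(x) / nrow(feats))
  })
  names(model) <- classes
  structure(model, class = "class_model")
}

#' Classify every voxel by maximum a posteriori probability
#'
#' Evaluates both class posteriors (Gaussian likelihood times prior) at
#' every voxel's (intensity, local SD) feature vector and assigns the MAP
#' label, encoded as `+1.0` for object and `-1.0` for gel. Ties are broken
#' toward gel, so a vertex sitting on the decision boundary does not
#' balloon. With this encoding the balloon pass band
#' `T_low = -0.99, T_high = 1.0` admits exactly the object-classified
#' voxels.
#'
#' @param image a [scalar_volume()].
#' @param sd_volume the matching [local_sd_volume()].
#' @param model a fitted `class_model`.
#' @return A [scalar_volume()] of `+1` / `-1` labels.
#' @export
classify_volume <- function(image, sd_volume, model) {
  if (!inherits(model, "class_model")) stop("`model` must be a class_model")
  x1 <- as.vector(image$values)
  x2 <- as.vector(sd_volume$values)
  score <- function(cl) {
    mu <- model[[cl]]$mean
    sigma <- model[[cl]]$cov
    si <- solve(sigma)
    d1 <- x1 - mu[1L]
    d2 <- x2 - mu[2L]
    q <- si[1L, 1L] * d1^2 + 2 * si[1L, 2L] * d1 * d2 + si[2L, 2L] * d2^2
    -0.5 * q - 0.5 * log(det(sigma)) + log(model[[cl]]$prior)
  }
  lab <- ifelse(score("object") > score("gel"), 1, -1)
  scalar_volume(array(lab, dim(image$values)), image$spacing, image$origin)
}
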