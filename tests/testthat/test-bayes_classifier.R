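test_that("local SD volume matches analytic values and is shift invariant", {
  const <- scalar_volume(array(7, c(6, 6, 6)))
  expect_equal(max(local_sd_volume(const, 3)$values), 0)

  # 3-D checkerboard, window 3: interior windows hold 13 or 14 ones of 27
  idx <- expand.grid(x = 1:7, y = 1:7, z = 1:7)
  cb <- array(as.numeric((idx$x + idx$y + idx$z) %% 2L), c(7, 7, 7))
  vol <- scalar_volume(cb)
  sdv <- local_sd_volume(vol, 3)
  center <- sdv$values[4, 4, 4]
  p <- sum(cb[3:5, 3:5, 3:5]) / 27
  expect_equal(center, sqrt(p * (1 - p)), tolerance = 1e-12)

  shifted <- scalar_volume(cb + 100)
  expect_equal(local_sd_volume(shifted, 3)$values, sdv$values,
               tolerance = 1e-9)

  expect_error(local_sd_volume(vol, 4), "odd")
  expect_error(local_sd_volume(vol, 9), "larger than the volume")
})

test_that("fitting recovers centroids, priors and regularizes degenerate classes", {
  img <- scalar_volume(array(0, c(8, 8, 8)))
  img$values[1:4, , ] <- 10
  img$values[5:8, , ] <- 50
  sdv <- local_sd_volume(img, 3)
  coords <- rbind(cbind(1L, 1:5, 1L), cbind(6L, 1:5, 1L))
  tr <- training_set(coords, rep(c("gel", "object"), each = 5L))
  expect_message(model <- fit_bayes_classifier(img, sdv, tr), "ridge")
  expect_equal(unname(model$object$mean[1L]), 50)
  expect_equal(unname(model$gel$mean[1L]), 10)
  expect_equal(model$object$prior, 0.5)
  expect_equal(model$gel$prior, 0.5)

  # separated classes: every training point classified to its own class
  set.seed(2)
  img2 <- scalar_volume(array(c(rnorm(256, 10, 1), rnorm(256, 60, 2)),
                              c(8, 8, 8)))
  sdv2 <- local_sd_volume(img2, 3)
  co2 <- rbind(cbind(0:7, 0L, 0L), cbind(0:7, 7L, 7L))
  tr2 <- training_set(co2, rep(c("gel", "object"), each = 8L))
  m2 <- fit_bayes_classifier(img2, sdv2, tr2)
  cl <- classify_volume(img2, sdv2, m2)
  lab <- cl$values[co2 + 1L]
  expect_equal(lab, rep(c(-1, 1), each = 8L))

  expect_error(fit_bayes_classifier(img, sdv,
    training_set(rbind(c(0, 0, 99), coords[-1L, ]),
                 rep(c("gel", "object"), each = 5L))), "outside")
})

test_that("MAP labels are +1/-1 with ties broken toward gel", {
  model <- structure(list(
    object = list(mean = c(intensity = 10, sd = 1),
                  cov = diag(2), prior = 0.5),
    gel = list(mean = c(intensity = -10, sd = 1),
               cov = diag(2), prior = 0.5)), class = "class_model")
  img <- scalar_volume(array(c(-10, 10, 0), c(3, 1, 1)))
  sdv <- scalar_volume(array(1, c(3, 1, 1)))
  out <- classify_volume(img, sdv, model)
  expect_equal(as.vector(out$values), c(-1, 1, -1))  # exact tie -> gel
})

test_that("1-D decision boundary lands within half a voxel of the closed form", {
  # noiseless intensity ramp along x; constant SD feature by construction
  nx <- 64L
  img <- scalar_volume(array(rep(seq_len(nx) - 1, 8L * 8L), c(nx, 8, 8)))
  sdv <- scalar_volume(array(1, c(nx, 8, 8)))
  co <- rbind(cbind(10:19, 3L, 3L), cbind(40:49, 3L, 3L))
  tr <- training_set(co, rep(c("gel", "object"), each = 10L))
  model <- suppressMessages(fit_bayes_classifier(img, sdv, tr))

  # closed-form equal-posterior point of the two fitted 1-D Gaussians
  # (the SD feature is identical everywhere and cancels)
  mu1 <- model$gel$mean[1L]; s1 <- sqrt(model$gel$cov[1L, 1L])
  mu2 <- model$object$mean[1L]; s2 <- sqrt(model$object$cov[1L, 1L])
  roots <- polyroot(c(
    -mu1^2 / (2 * s1^2) + mu2^2 / (2 * s2^2) - log(s1) + log(s2),
    mu1 / s1^2 - mu2 / s2^2,
    -1 / (2 * s1^2) + 1 / (2 * s2^2)))
  roots <- Re(roots[abs(Im(roots)) < 1e-8])
  boundary <- roots[roots > mu1 & roots < mu2]
  expect_length(boundary, 1L)

  cl <- classify_volume(img, sdv, model)
  lab <- cl$values[, 4L, 4L]
  flip <- which(lab[-1L] != lab[-nx])[1L]
  crossing <- (flip - 1 + flip) / 2   # 0-based voxel midpoint of the flip
  expect_lt(abs(crossing - boundary), 0.5)
})

test_that("classification is invariant under joint affine intensity rescaling", {
  set.seed(9)
  img <- scalar_volume(array(rnorm(512, 30, 10), c(8, 8, 8)))
  sdv <- local_sd_volume(img, 3)
  co <- rbind(cbind(0:7, 0L, 0L), cbind(0:7, 7L, 7L))
  tr <- training_set(co, rep(c("gel", "object"), each = 8L))
  model <- fit_bayes_classifier(img, sdv, tr)
  cl <- classify_volume(img, sdv, model)

  a <- 2.5; b <- 40
  img2 <- scalar_volume(a * img$values + b, img$spacing, img$origin)
  sdv2 <- scalar_volume(a * sdv$values, img$spacing, img$origin)
  model2 <- fit_bayes_classifier(img2, sdv2, tr)
  cl2 <- classify_volume(img2, sdv2, model2)
  expect_equal(cl2$values, cl$values)
})

test_that("classified object region covers nearly all true object voxels on the standard phantom", {
  ph <- standard_phantom()
  sdv <- local_sd_volume(ph$volume, 5)
  model <- fit_bayes_classifier(ph$volume, sdv, ph$training)
  cl <- classify_volume(ph$volume, sdv, model)
  truth <- Reduce(`+`, lapply(ph$truths, function(m) m$values))
  coverage <- sum(cl$values == 1 & truth == 1) / sum(truth)
  expect_gte(coverage, 0.95)
})
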