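#' Read and write volumes as NIfTI
#'
#' Volumes are written with a diagonal sform/qform carrying the spacing and
#' origin, so `write_volume()` followed by `read_volume()` preserves grid
#' metadata and values bit-exactly for integer masks and to float64
#' precision for scalar volumes. Masks ([binary_mask()]) are stored as
#' uint8, scalar volumes as float.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param vol a [scalar_volume()] or [binary_mask()].
#' @return `read_volume()` a [scalar_volume()] (or [binary_mask()] when
#'   `mask = TRUE`); `write_volume()` the path, invisibly.
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  im <- RNifti::readNifti(path)
  aff <- RNifti::xform(im)
  spacing <- sqrt(colSums(aff[1:3, 1:3]^2))
  origin <- aff[1:3, 4L]
  off <- abs(aff[1:3, 1:3]) - diag(spacing)
  if (max(abs(off)) > 1e-4 * max(spacing))
    warning("non-axial orientation in ", path,
            "; using column norms as spacing")
  vals <- array(as.numeric(im), dim(im)[1:3])
  if (mask) binary_mask(array(as.integer(round(vals)), dim(vals)),
                        spacing, origin)
  else scalar_volume(vals, spacing, origin)
}

#' @rdname read_volume
#' @param mask read as a [binary_mask()].
#' @export
write_volume <- function(vol, path) {
  is_mask <- inherits(vol, "binary_mask")
  vals <- vol$values
  storage.mode(vals) <- "double"
  im <- RNifti::asNifti(vals)
  RNifti::pixdim(im) <- vol$spacing
  aff <- rbind(cbind(diag(vol$spacing), vol$origin), c(0, 0, 0, 1))
  aff <- structure(aff, code = 2L)
  im <- RNifti::`sform<-`(im, aff)
  im <- RNifti::`qform<-`(im, aff)
  RNifti::writeNifti(im, path,
                     datatype = if (is_mask) "uint8" else "double")
  invisible(path)
}

#' Seed points and training sets on disk
#'
#' Seeds live in a whitespace-separated text file with one `x y z` world
#' coordinate triple per line (blank lines and `#` comments ignored).
#' Training sets are CSV with columns `x,y,z,label`: 0-based voxel
#' coordinates and the class label `object` or `gel`.
#'
#' @param path file path.
#' @return `read_seeds()` an N x 3 numeric matrix; `read_training()` a
#'   [training_set()].
#' @export
read_seeds <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (length(keep) == 0L) stop("no seed points in ", path)
  rows <- lapply(keep, function(i) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) != 3L || any(is.na(vals)))
      stop("line ", i, " of ", path,
           " is not an `x y z` triple: '", lines[i], "'")
    vals
  })
  do.call(rbind, rows)
}

#' @rdname read_seeds
#' @param seeds N x 3 matrix of world coordinates.
#' @export
write_seeds <- function(seeds, path) {
  seeds <- to_point_matrix(seeds)
  writeLines(apply(seeds, 1L, paste, collapse = " "), path)
  invisible(path)
}

#' @rdname read_seeds
#' @export
read_training <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "z", "label")
  if (!all(need %in% names(df)))
    stop("training CSV needs columns x,y,z,label")
  training_set(as.matrix(df[, c("x", "y", "z")]), df$label)
}

#' @rdname read_seeds
#' @param training a [training_set()].
#' @export
write_training <- function(training, path) {
  df <- data.frame(x = training$coords[, 1L], y = training$coords[, 2L],
                   z = training$coords[, 3L], label = training$labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run reports and run configurations on disk
#'
#' Run reports serialize to JSON; run configurations are YAML files
#' mirroring the [run_config()] fields, with the stage schedule under a
#' `schedule:` list whose entries hold [stage_parameters()] fields.
#' Seeds may be given inline (`seeds:` as a list of triples) or left to
#' the caller.
#'
#' @param report a run report (from [run_segmentation()]).
#' @param path file path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @param seeds optional N x 3 seed matrix overriding any seeds in the
#'   file.
#' @export
read_run_config <- function(path, seeds = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(seeds)) {
    if (is.null(y$seeds)) stop("config has no seeds; supply `seeds`")
    seeds <- do.call(rbind, lapply(y$seeds, as.numeric))
  }
  schedule <- if (is.null(y$schedule)) default_schedule()
  else lapply(y$schedule, function(s) do.call(stage_parameters, s))
  args <- y[setdiff(names(y), c("seeds", "schedule"))]
  args <- args[names(args) %in% names(formals(run_config))]
  do.call(run_config, c(list(seeds = seeds, schedule = schedule), args))
}

#' Write a simplex mesh as OBJ or legacy VTK polydata
#'
#' The surface is stored as its polygon faces; a sidecar text file
#' (`<path>.neighbours`) stores the per-vertex ordered neighbour triples
#' (1-based), from which the simplex structure can be rebuilt on read.
#'
#' @param mesh a `simplex_mesh`.
#' @param path output path (`.obj` or `.vtk`).
#' @export
write_mesh <- function(mesh, path) {
  v <- mesh$vertices
  if (grepl("\\.obj$", path, ignore.case = TRUE)) {
    lines <- c(sprintf("v %.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L]),
               vapply(mesh$faces, function(f)
                 paste(c("f", f), collapse = " "), character(1L)))
  } else if (grepl("\\.vtk$", path, ignore.case = TRUE)) {
    sizes <- lengths(mesh$faces)
    lines <- c("# vtk DataFile Version 3.0", "simplex mesh surface",
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(v)),
               sprintf("%.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L]),
               sprintf("POLYGONS %d %d", length(sizes),
                       sum(sizes) + length(sizes)),
               vapply(mesh$faces, function(f)
                 paste(c(length(f), f - 1L), collapse = " "),
                 character(1L)))
  } else stop("unknown mesh format (use .obj or .vtk): ", path)
  writeLines(lines, path)
  writeLines(apply(mesh$neighbours, 1L, paste, collapse = " "),
             paste0(path, ".neighbours"))
  invisible(path)
}

#' @rdname write_mesh
#' @return `read_mesh_obj()` a `simplex_mesh` (requires the sidecar
#'   neighbour table written by [write_mesh()]).
#' @export
read_mesh_obj <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  side <- paste0(path, ".neighbours")
  if (!file.exists(side)) stop("missing neighbour sidecar: ", side)
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  vertices <- do.call(rbind, lapply(strsplit(sub("^v ", "", vl), "\\s+"),
                                    as.numeric))
  faces <- lapply(strsplit(sub("^f ", "", fl), "\\s+"), as.integer)
  neighbours <- do.call(rbind, lapply(strsplit(readLines(side), "\\s+"),
                                      as.integer))
  # rebuild the dual triangulation's corner order from the neighbour order,
  # so the stored outward orientation survives the round trip: corner k of
  # vertex i's dual triangle is the polygon shared with neighbours k-1 and k
  polys <- vector("list", nrow(vertices))
  for (fi in seq_along(faces))
    for (vi in faces[[fi]]) polys[[vi]] <- c(polys[[vi]], fi)
  vertex_faces <- matrix(0L, nrow(vertices), 3L)
  for (i in seq_len(nrow(vertices))) {
    nb <- neighbours[i, ]
    for (k in 1:3) {
      prev <- nb[if (k == 1L) 3L else k - 1L]
      shared <- intersect(intersect(polys[[i]], polys[[prev]]),
                          polys[[nb[k]]])
      if (length(shared) != 1L)
        stop("inconsistent mesh topology around vertex ", i)
      vertex_faces[i, k] <- shared
    }
  }
  mesh <- structure(list(
    vertices = vertices, neighbours = neighbours, faces = faces,
    vertex_faces = vertex_faces, prev_vertices = vertices,
    ref_eps = NULL, ref_angle = NULL), class = "simplex_mesh")
  mesh <- set_reference_params(mesh)
  validate_mesh(mesh)
  mesh
}
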