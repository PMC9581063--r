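#' Construct a density map
#'
#' A `density_map` is a 3D real-valued intensity grid together with the world
#' coordinate of voxel (0,0,0) (`origin`, in Angstrom) and the voxel edge
#' lengths (`voxel_size`, Angstrom per voxel along x, y, z). The world
#' coordinate of voxel (i,j,k) (0-based) is `origin + c(i,j,k) * voxel_size`.
#'
#' @param data 3D numeric array, all dimensions >= 1.
#' @param origin numeric length-3, world coordinate of voxel (0,0,0) in Angstrom.
#' @param voxel_size numeric length-3 (or scalar), Angstrom per voxel.
#' @return An object of class `density_map`.
#' @export
density_map <- function(data, origin = c(0, 0, 0), voxel_size = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  stopifnot(length(origin) == 3L, length(voxel_size) == 3L)
  if (any(!is.finite(origin)) || any(!is.finite(voxel_size)))
    stop("origin and voxel_size must be finite")
  structure(
    list(data = data, origin = as.numeric(origin),
         voxel_size = as.numeric(voxel_size)),
    class = "density_map"
  )
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<density_map> %d x %d x %d voxels, voxel size (%.3g, %.3g, %.3g) A, origin (%.3g, %.3g, %.3g) A\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
    x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  density range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.density_map <- function(x) dim(x$data)

#' World coordinates of voxel indices
#'
#' @param map a `density_map` (or `label_grid`).
#' @param ijk integer matrix (n x 3) of 0-based voxel indices.
#' @return numeric matrix (n x 3) of world coordinates in Angstrom.
#' @export
voxel_to_world <- function(map, ijk) {
  ijk <- rbind(ijk)
  sweep(sweep(ijk, 2, map$voxel_size, `*`), 2, map$origin, `+`)
}

#' Voxel indices (0-based, fractional) of world coordinates
#'
#' @inheritParams voxel_to_world
#' @param xyz numeric matrix (n x 3) of world coordinates in Angstrom.
#' @export
world_to_voxel <- function(map, xyz) {
  xyz <- rbind(xyz)
  sweep(sweep(xyz, 2, map$origin, `-`), 2, map$voxel_size, `/`)
}

#' Construct a voxel label grid
#'
#' A `label_grid` holds one class per voxel on the lattice of a companion
#' `density_map`: 0 = background, 1 = helix, 2 = sheet.
#'
#' @param labels 3D integer array with values in {0, 1, 2}.
#' @param origin,voxel_size lattice geometry, as in [density_map()].
#' @return An object of class `label_grid`.
#' @export
label_grid <- function(labels, origin = c(0, 0, 0), voxel_size = c(1, 1, 1)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  if (!all(labels %in% 0:2)) stop("labels must be 0 (background), 1 (helix) or 2 (sheet)")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  structure(
    list(labels = labels, origin = as.numeric(origin),
         voxel_size = as.numeric(voxel_size)),
    class = "label_grid"
  )
}

#' @export
print.label_grid <- function(x, ...) {
  d <- dim(x$labels)
  n <- tabulate(as.integer(x$labels) + 1L, nbins = 3L)
  cat(sprintf("<label_grid> %d x %d x %d voxels: %d background, %d helix, %d sheet\n",
              d[1], d[2], d[3], n[1], n[2], n[3]))
  invisible(x)
}

#' @export
dim.label_grid <- function(x) dim(x$labels)

# shared lattice check
same_lattice <- function(a, b, tol = 1e-6) {
  da <- if (inherits(a, "label_grid")) dim(a$labels) else dim(a$data)
  db <- if (inherits(b, "label_grid")) dim(b$labels) else dim(b$data)
  identical(da, db) &&
    all(abs(a$origin - b$origin) < tol) &&
    all(abs(a$voxel_size - b$voxel_size) < tol)
}
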