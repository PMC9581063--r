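# Preprocessing of component density maps for the network: resampling to a
# 1 A lattice, chain-envelope extraction, min-max normalization and padding.

#' Resample a density map to 1 Angstrom per voxel
#'
#' Values at the new lattice positions are obtained by trilinear interpolation
#' of the source grid; positions outside the source grid contribute 0. The
#' world extent is preserved to within one voxel, and a map that is already at
#' 1 A per voxel is returned unchanged.
#'
#' @param map a [density_map()] with positive voxel size.
#' @return A [density_map()] with `voxel_size = c(1, 1, 1)`.
#' @export
resample_to_unit <- function(map) {
  stopifnot(inherits(map, "density_map"))
  vs <- map$voxel_size
  if (any(vs <= 0)) stop("voxel size must be positive")
  if (all(vs == 1)) return(map)

  d <- dim(map$data)
  # target index t (0-based) sits at source index t / vs; keep the lattice
  # inside the source extent so no extrapolation is needed
  nd <- pmax(1L, as.integer(floor((d - 1L) * vs)) + 1L)

  # per-axis lower corner index and interpolation weight
  ax <- lapply(1:3, function(a) {
    s <- (0:(nd[a] - 1L)) / vs[a]           # 0-based source coordinate
    i0 <- pmin(floor(s), d[a] - 1L)
    f <- s - i0
    hi_ok <- i0 + 1L <= d[a] - 1L
    list(lo = as.integer(i0) + 1L,          # 1-based
         hi = as.integer(ifelse(hi_ok, i0 + 1L, i0)) + 1L,
         w1 = ifelse(hi_ok, f, 0))
  })

  out <- array(0, dim = nd)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wx <- if (dx == 0) 1 - ax[[1]]$w1 else ax[[1]]$w1
    wy <- if (dy == 0) 1 - ax[[2]]$w1 else ax[[2]]$w1
    wz <- if (dz == 0) 1 - ax[[3]]$w1 else ax[[3]]$w1
    if (all(wx == 0) || all(wy == 0) || all(wz == 0)) next
    ix <- if (dx == 0) ax[[1]]$lo else ax[[1]]$hi
    iy <- if (dy == 0) ax[[2]]$lo else ax[[2]]$hi
    iz <- if (dz == 0) ax[[3]]$lo else ax[[3]]$hi
    w <- outer(outer(wx, wy), wz)
    out <- out + w * map$data[ix, iy, iz, drop = FALSE]
  }
  density_map(out, origin = map$origin, voxel_size = c(1, 1, 1))
}

#' Extract the density component around a set of atoms
#'
#' Keeps voxels whose center lies within `radius` Angstrom of at least one
#' atom (inclusive boundary), zeroes all others, and crops to the tight
#' bounding box of the retained voxels. The origin is updated so world
#' coordinates are unchanged.
#'
#' @param map a [density_map()].
#' @param atoms numeric matrix (n x 3) of world coordinates in Angstrom.
#' @param radius envelope radius in Angstrom (default 5, the radius used to
#'   cut chain components out of full maps).
#' @return A cropped [density_map()].
#' @export
extract_component <- function(map, atoms, radius = 5) {
  stopifnot(inherits(map, "density_map"))
  atoms <- rbind(atoms)
  if (nrow(atoms) == 0L) stop("`atoms` must be non-empty")
  if (radius <= 0) stop("`radius` must be positive")

  keep <- sphere_mask(dim(map$data), map$origin, map$voxel_size, atoms, radius)
  if (!any(keep)) stop("empty component: no voxel center within ", radius,
                       " A of any atom")

  idx <- which(keep, arr.ind = TRUE)
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  cropped <- map$data * keep
  cropped <- cropped[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  density_map(cropped,
              origin = map$origin + (lo - 1L) * map$voxel_size,
              voxel_size = map$voxel_size)
}

# logical mask of voxels whose center is within `radius` of any point;
# per-point bounding boxes keep this linear in n_points * (2r+1)^3
sphere_mask <- function(dims, origin, voxel_size, points, radius) {
  mask <- array(FALSE, dim = dims)
  for (p in seq_len(nrow(points))) {
    ctr <- (points[p, ] - origin) / voxel_size      # 0-based fractional index
    rv <- radius / voxel_size
    lo <- pmax(ceiling(ctr - rv), 0)
    hi <- pmin(floor(ctr + rv), dims - 1L)
    if (any(lo > hi)) next
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    dx2 <- ((ix - ctr[1]) * voxel_size[1])^2
    dy2 <- ((iy - ctr[2]) * voxel_size[2])^2
    dz2 <- ((iz - ctr[3]) * voxel_size[3])^2
    d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    sub <- mask[ix + 1L, iy + 1L, iz + 1L, drop = FALSE]
    mask[ix + 1L, iy + 1L, iz + 1L] <- sub | (d2 <= radius^2 + 1e-9)
  }
  mask
}

#' Min-max normalize a density map to [0, 1]
#'
#' Maps densities to `(v - min) / (max - min)`. A constant map (zero range)
#' maps to all zeros. Idempotent on maps already spanning exactly [0, 1].
#'
#' @param map a [density_map()].
#' @return A [density_map()] with values in [0, 1].
#' @export
normalize_density <- function(map) {
  stopifnot(inherits(map, "density_map"))
  lo <- min(map$data); hi <- max(map$data)
  v <- if (hi > lo) (map$data - lo) / (hi - lo) else array(0, dim(map$data))
  density_map(v, origin = map$origin, voxel_size = map$voxel_size)
}

#' Zero-pad a map so every dimension is a multiple of `divisor`
#'
#' The network halves each dimension twice, so inputs must have dimensions
#' divisible by 4. Padding is split as evenly as possible per axis, with the
#' extra voxel on the "after" side, and the origin is shifted so that the
#' original voxels keep their world coordinates. Dimensions may not exceed
#' 100 voxels after padding (the design limit for component maps).
#'
#' @param map a [density_map()].
#' @param divisor positive integer (default 4).
#' @return A list with elements `map` (padded [density_map()]) and `pad`
#'   (a `pad_spec` with integer vectors `before` and `after`).
#' @export
pad_for_network <- function(map, divisor = 4L) {
  stopifnot(inherits(map, "density_map"))
  divisor <- as.integer(divisor)
  if (divisor < 1L) stop("`divisor` must be >= 1")
  d <- dim(map$data)
  total <- (divisor - d %% divisor) %% divisor
  newd <- d + total
  if (any(newd > 100L))
    stop("padded dimensions (", paste(newd, collapse = ", "),
         ") exceed the 100-voxel-per-dimension design limit for component maps")
  before <- total %/% 2L
  after <- total - before
  out <- array(0, dim = newd)
  out[before[1] + seq_len(d[1]), before[2] + seq_len(d[2]),
      before[3] + seq_len(d[3])] <- map$data
  pad <- structure(list(before = before, after = after), class = "pad_spec")
  list(map = density_map(out,
                         origin = map$origin - before * map$voxel_size,
                         voxel_size = map$voxel_size),
       pad = pad)
}

#' Remove padding added by [pad_for_network()]
#'
#' Exact inverse of the padding step: `unpad_map(pad_for_network(m)$map, pad)`
#' returns `m` bit for bit.
#'
#' @param map a padded [density_map()].
#' @param pad the `pad_spec` returned by [pad_for_network()].
#' @return The original [density_map()].
#' @export
unpad_map <- function(map, pad) {
  stopifnot(inherits(map, "density_map"), inherits(pad, "pad_spec"))
  d <- dim(map$data)
  keep <- lapply(1:3, function(a) (pad$before[a] + 1L):(d[a] - pad$after[a]))
  density_map(map$data[keep[[1]], keep[[2]], keep[[3]], drop = FALSE],
              origin = map$origin + pad$before * map$voxel_size,
              voxel_size = map$voxel_size)
}
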