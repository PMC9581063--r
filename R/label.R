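# Ground-truth voxel labeling: voxels within 3 A of a helix / sheet residue's
# Calpha atom are labeled as helix / sheet voxels; the rest are background.

#' Label voxels from residue annotations
#'
#' A voxel is labeled helix (resp. sheet) if its center lies within
#' `radius` Angstrom (inclusive) of the Calpha atom of at least one helix
#' (resp. sheet) residue; all other voxels are background. Voxels within
#' range of both a helix and a sheet Calpha are labeled helix, matching the
#' helix-before-sheet priority used everywhere ties arise in this package.
#' Calpha atoms outside the grid simply label no voxels.
#'
#' @param map a [density_map()] at 1 A per voxel defining the lattice.
#' @param annotations data.frame as returned by [parse_stride()] (columns
#'   `ss_class`, `x`, `y`, `z`).
#' @param radius labeling radius in Angstrom (default 3).
#' @return A [label_grid()] on the lattice of `map`.
#' @export
label_voxels <- function(map, annotations, radius = 3) {
  stopifnot(inherits(map, "density_map"))
  d <- dim(map$data)
  labs <- array(0L, dim = d)
  for (cls in c("sheet", "helix")) {        # helix written last -> helix wins
    sel <- annotations$ss_class == cls
    if (!any(sel)) next
    pts <- as.matrix(annotations[sel, c("x", "y", "z"), drop = FALSE])
    m <- sphere_mask(d, map$origin, map$voxel_size, pts, radius)
    labs[m] <- if (cls == "helix") 1L else 2L
  }
  label_grid(labs, origin = map$origin, voxel_size = map$voxel_size)
}
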