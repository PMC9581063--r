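# End-to-end prediction: one MRC component map in, helix and sheet mask MRC
# volumes out.

#' Hard labels from a probability grid
#'
#' Per-voxel argmax over the three class probabilities. Exact ties are
#' resolved with priority helix, then sheet, then background — the same tie
#' policy used for residue voting.
#'
#' @param probs a [probability_grid()].
#' @return A [label_grid()] on the same lattice.
#' @export
argmax_labels <- function(probs) {
  stopifnot(inherits(probs, "probability_grid"))
  m <- vol2mat(probs$probs)                # columns: background, helix, sheet
  pick <- max.col(m[, c(2L, 3L, 1L), drop = FALSE], ties.method = "first")
  labs <- c(1L, 2L, 0L)[pick]
  dim(labs) <- dim(probs$probs)[1:3]
  label_grid(labs, origin = probs$origin, voxel_size = probs$voxel_size)
}

#' Detect secondary structures in a component density map
#'
#' Full inference pipeline: read the MRC map, resample to 1 A per voxel,
#' min-max normalize, zero-pad to dimensions divisible by 4, run the network
#' in evaluation mode, take per-voxel argmax labels, remove the padding, and
#' write `<stem>_helix.mrc` and `<stem>_sheet.mrc` binary (0/1 float32) masks
#' carrying the input map's lattice. Component maps are limited to 100 voxels
#' per dimension after resampling.
#'
#' @param map_path input MRC file.
#' @param checkpoint_path model checkpoint (see [save_checkpoint()]).
#' @param out_dir output directory for the two mask files (created if
#'   missing).
#' @return A `segmentation_result`: list with `label_grid`, `helix_mask` and
#'   `sheet_mask` ([density_map()]s of 0/1), and the written `helix_path` /
#'   `sheet_path`.
#' @export
detect <- function(map_path, checkpoint_path, out_dir = ".") {
  model <- load_checkpoint(checkpoint_path)
  map <- resample_to_unit(read_mrc(map_path))
  if (any(dim(map$data) > 100L))
    stop("component map is ", paste(dim(map$data), collapse = " x "),
         " voxels after resampling; the design limit is 100 voxels in any dimension")
  pp <- pad_for_network(normalize_density(map))
  probs <- unet_forward(model, pp$map, training = FALSE)
  labs_padded <- argmax_labels(probs)
  labs <- crop_labels(labs_padded, pp$pad)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stem <- sub("\\.(mrc|map)$", "", basename(map_path), ignore.case = TRUE)
  helix <- density_map((labs$labels == 1L) * 1.0, origin = labs$origin,
                       voxel_size = labs$voxel_size)
  sheet <- density_map((labs$labels == 2L) * 1.0, origin = labs$origin,
                       voxel_size = labs$voxel_size)
  helix_path <- file.path(out_dir, paste0(stem, "_helix.mrc"))
  sheet_path <- file.path(out_dir, paste0(stem, "_sheet.mrc"))
  write_mrc(helix, helix_path)
  write_mrc(sheet, sheet_path)
  structure(list(label_grid = labs, helix_mask = helix, sheet_mask = sheet,
                 helix_path = helix_path, sheet_path = sheet_path),
            class = "segmentation_result")
}

# remove network padding from a label grid
crop_labels <- function(grid, pad) {
  d <- dim(grid$labels)
  keep <- lapply(1:3, function(a) (pad$before[a] + 1L):(d[a] - pad$after[a]))
  label_grid(grid$labels[keep[[1]], keep[[2]], keep[[3]], drop = FALSE],
             origin = grid$origin + pad$before * grid$voxel_size,
             voxel_size = grid$voxel_size)
}

#' Predict labels for an in-memory density map
#'
#' Convenience wrapper around the same pipeline as [detect()] but without
#' file I/O: resample, normalize, pad, forward, argmax, unpad.
#'
#' @param model a `unet_model`.
#' @param map a [density_map()].
#' @return A [label_grid()] on the (resampled) input lattice.
#' @export
predict_labels <- function(model, map) {
  map <- resample_to_unit(map)
  if (any(dim(map$data) > 100L))
    stop("component map exceeds the 100-voxel-per-dimension design limit")
  pp <- pad_for_network(normalize_density(map))
  probs <- unet_forward(model, pp$map, training = FALSE)
  crop_labels(argmax_labels(probs), pp$pad)
}
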