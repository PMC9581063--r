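# Seeded generator of synthetic medium-resolution density maps of idealized
# helices and beta-sheets with exact ground-truth labels and annotations —
# the desk-scale stand-in for experimental component maps.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Idealized alpha-helix Calpha trace
#'
#' Calpha atoms on an ideal alpha-helix: rise 1.5 A per residue, 100 degrees
#' rotation per residue, helix radius 2.3 A; the local trace (axis along z,
#' first Calpha at angle 0) is rigidly transformed by `orientation` and then
#' translated by `origin`. Consecutive Calpha atoms are 3.83 A apart.
#'
#' @param n_res number of residues (>= 4).
#' @param origin numeric length-3 translation (A).
#' @param orientation 3x3 rotation matrix.
#' @param chain_id,first_resno identifiers for the annotation rows.
#' @return Annotation data.frame (columns as [parse_stride()]) with
#'   `ss_class = "helix"`.
#' @export
make_helix <- function(n_res, origin = c(0, 0, 0), orientation = diag(3),
                       chain_id = "A", first_resno = 1L) {
  if (n_res < 4L) stop("a helix needs at least 4 residues")
  i <- seq_len(n_res) - 1L
  theta <- i * 100 * pi / 180
  local <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  xyz <- sweep(local %*% t(orientation), 2, origin, `+`)
  data.frame(chain_id = chain_id,
             residue_number = first_resno + i,
             residue_name = "ALA",
             ss_class = "helix",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Idealized antiparallel beta-sheet Calpha trace
#'
#' Strands run along the local x axis with a 3.3 A Calpha rise, neighboring
#' strands are 4.8 A apart along y and alternate direction (antiparallel).
#'
#' @param n_strands number of strands (>= 2).
#' @param strand_len residues per strand (>= 3).
#' @inheritParams make_helix
#' @return Annotation data.frame with `ss_class = "sheet"` and
#'   `n_strands * strand_len` rows.
#' @export
make_sheet <- function(n_strands, strand_len, origin = c(0, 0, 0),
                       orientation = diag(3), chain_id = "A",
                       first_resno = 1L) {
  if (n_strands < 2L) stop("a sheet needs at least 2 strands")
  if (strand_len < 3L) stop("strands need at least 3 residues")
  rows <- lapply(seq_len(n_strands), function(s) {
    j <- seq_len(strand_len) - 1L
    xs <- if (s %% 2L == 1L) j * 3.3 else (strand_len - 1L - j) * 3.3
    cbind(xs, (s - 1L) * 4.8, 0)
  })
  local <- do.call(rbind, rows)
  xyz <- sweep(local %*% t(orientation), 2, origin, `+`)
  n <- nrow(local)
  data.frame(chain_id = chain_id,
             residue_number = first_resno + seq_len(n) - 1L,
             residue_name = "VAL",
             ss_class = "sheet",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Simulate medium-resolution density from point scatterers
#'
#' Sum of isotropic Gaussians centered at the coordinates, with the full
#' width at half maximum equal to the nominal resolution
#' (`sigma = resolution / (2 sqrt(2 ln 2))`), sampled on a 1 A lattice that
#' extends `grid_padding` A beyond the coordinates, plus seeded Gaussian
#' noise with standard deviation `noise_sd` times the noise-free peak.
#'
#' @param coords numeric matrix (n x 3) of scatterer positions (A).
#' @param resolution nominal map resolution in A (between 4 and 12).
#' @param grid_padding margin around the coordinates in A.
#' @param noise_sd noise level as a fraction of the noise-free peak density.
#' @param seed RNG seed for the noise field.
#' @return A [density_map()] at 1 A per voxel.
#' @export
simulate_density <- function(coords, resolution = 6, grid_padding = 4,
                             noise_sd = 0.05, seed = 1L) {
  coords <- rbind(coords)
  if (nrow(coords) == 0L) stop("`coords` must be non-empty")
  if (resolution < 4 || resolution > 12)
    stop("`resolution` must be between 4 and 12 A")
  sigma <- resolution / (2 * sqrt(2 * log(2)))
  origin <- floor(apply(coords, 2, min)) - grid_padding
  dims <- as.integer(ceiling(apply(coords, 2, max)) - origin + grid_padding + 1)
  if (any(dims > 100L))
    stop("simulated grid would exceed 100 voxels per dimension")

  dat <- array(0, dim = dims)
  cut <- ceiling(4 * sigma)
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 1L))
  for (p in seq_len(nrow(coords))) {
    rng <- lapply(1:3, function(a) {
      which(abs(ax[[a]] - coords[p, a]) <= cut)
    })
    g <- lapply(1:3, function(a)
      exp(-((ax[[a]][rng[[a]]] - coords[p, a])^2) / (2 * sigma^2)))
    dat[rng[[1]], rng[[2]], rng[[3]]] <-
      dat[rng[[1]], rng[[2]], rng[[3]]] + outer(outer(g[[1]], g[[2]]), g[[3]])
  }
  if (noise_sd > 0) {
    peak <- max(dat)
    noise <- with_seed(seed, stats::rnorm(prod(dims), sd = noise_sd * peak))
    dat <- dat + array(noise, dim = dims)
  }
  density_map(dat, origin = origin, voxel_size = c(1, 1, 1))
}

# study conditions per quality level: map resolution (A) and noise fraction
quality_conditions <- function(level) {
  list(resolution = c(5, 7, 9)[level], noise_sd = c(0.05, 0.10, 0.15)[level])
}

random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a synthetic dataset of labeled component maps
#'
#' Each case contains a density map of one idealized structure (helix-only,
#' sheet-only, or a helix plus a sheet), the exact voxel labels produced by
#' [label_voxels()] from the generating annotations, the annotations
#' themselves, and a quality bin. Quality level 1/2/3 maps use resolution
#' 5/7/9 A and noise 5/10/15% of peak, so bins represent decreasing map
#' quality. Fully reproducible from `seed`.
#'
#' @param n_cases number of cases (>= 1).
#' @param mix named proportions for kinds `helix`, `sheet`, `mixed`.
#' @param quality_levels quality levels to cycle through (subset of 1:3).
#' @param seed RNG seed.
#' @return A list of `synthetic_case` lists with elements `map`, `labels`,
#'   `annotations`, `bin`, `kind`, `seed`.
#' @export
make_dataset <- function(n_cases, mix = c(helix = 0.4, sheet = 0.3, mixed = 0.3),
                         quality_levels = 1:3, seed = 1L) {
  if (n_cases < 1L) stop("`n_cases` must be >= 1")
  stopifnot(all(quality_levels %in% 1:3))
  kinds <- rep(names(mix), times = diff(round(cumsum(c(0, mix)) / sum(mix) * n_cases)))
  if (length(kinds) < n_cases)
    kinds <- c(kinds, rep("helix", n_cases - length(kinds)))
  with_seed(seed, {
    kinds <- sample(kinds)
    bins <- rep_len(quality_levels, n_cases)
    lapply(seq_len(n_cases), function(i) {
      rot <- random_rotation()
      ann <- switch(kinds[i],
        helix = make_helix(sample(8:16, 1), orientation = rot),
        sheet = make_sheet(sample(3:4, 1), sample(4:7, 1), orientation = rot),
        mixed = {
          h <- make_helix(sample(8:14, 1), orientation = rot)
          s <- make_sheet(3, sample(4:6, 1),
                          origin = rot %*% c(13, 0, 0), orientation = rot,
                          first_resno = max(h$residue_number) + 5L)
          rbind(h, s)
        })
      qc <- quality_conditions(bins[i])
      map <- simulate_density(as.matrix(ann[, c("x", "y", "z")]),
                              resolution = qc$resolution,
                              noise_sd = qc$noise_sd,
                              seed = sample.int(.Machine$integer.max, 1))
      labs <- label_voxels(map, ann)
      structure(list(map = map, labels = labs, annotations = ann,
                     bin = bins[i], kind = kinds[i], seed = seed),
                class = "synthetic_case")
    })
  })
}

#' Write a synthetic case to standard formats
#'
#' Writes the density map as MRC, the Calpha trace as a PDB file, and the
#' annotations as a STRIDE-style file with ASG records (codes H / E / C), so
#' downstream tools consume the same formats as for experimental data.
#'
#' @param case a `synthetic_case` from [make_dataset()].
#' @param dir output directory (created if missing).
#' @param stem file-name stem.
#' @return Named character vector of the written paths (`map`, `pdb`,
#'   `stride`), invisibly.
#' @export
write_synthetic_case <- function(case, dir, stem = "case") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  map_path <- file.path(dir, paste0(stem, ".mrc"))
  pdb_path <- file.path(dir, paste0(stem, ".pdb"))
  stride_path <- file.path(dir, paste0(stem, ".stride"))
  write_mrc(case$map, map_path)
  ann <- case$annotations
  bio3d::write.pdb(file = pdb_path,
                   xyz = as.numeric(t(as.matrix(ann[, c("x", "y", "z")]))),
                   resno = ann$residue_number,
                   resid = ann$residue_name,
                   chain = ann$chain_id,
                   elety = rep("CA", nrow(ann)))
  code <- c(helix = "H", sheet = "E", other = "C")[ann$ss_class]
  name <- c(helix = "AlphaHelix", sheet = "Strand", other = "Coil")[ann$ss_class]
  lines <- sprintf("ASG  %-3s %s %4d %4d    %s   %-11s   0.00   0.00   0.0",
                   ann$residue_name, ann$chain_id, ann$residue_number,
                   seq_len(nrow(ann)), code, name)
  writeLines(lines, stride_path)
  invisible(c(map = map_path, pdb = pdb_path, stride = stride_path))
}
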