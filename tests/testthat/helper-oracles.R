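# Independent brute-force oracles used across the suite. These deliberately
# use the slowest, most literal formulation of each definition so they stay
# independent of the package's implementations.

# per-voxel triple-loop labeling: nearest-annotation-free, priority helix
oracle_label_voxels <- function(dims, origin, voxel_size, annotations,
                                radius = 3) {
  labs <- array(0L, dim = dims)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      ctr <- origin + (c(i, j, k) - 1L) * voxel_size
      hit_helix <- FALSE; hit_sheet <- FALSE
      for (r in seq_len(nrow(annotations))) {
        d <- sqrt(sum((ctr - c(annotations$x[r], annotations$y[r],
                               annotations$z[r]))^2))
        if (d <= radius) {
          if (annotations$ss_class[r] == "helix") hit_helix <- TRUE
          if (annotations$ss_class[r] == "sheet") hit_sheet <- TRUE
        }
      }
      labs[i, j, k] <- if (hit_helix) 1L else if (hit_sheet) 2L else 0L
    }
  labs
}

# brute-force sphere count + priority vote
oracle_vote <- function(grid, ca, radius = 3) {
  dims <- dim(grid$labels)
  counts <- c(other = 0L, helix = 0L, sheet = 0L)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      ctr <- grid$origin + (c(i, j, k) - 1L) * grid$voxel_size
      if (sqrt(sum((ctr - ca)^2)) <= radius) {
        lab <- grid$labels[i, j, k]
        nm <- c("other", "helix", "sheet")[lab + 1L]
        counts[nm] <- counts[nm] + 1L
      }
    }
  if (sum(counts) == 0L) return("other")
  pri <- c(counts[["helix"]], counts[["sheet"]], counts[["other"]])
  c("helix", "sheet", "other")[which.max(pri)]
}

# F1 from an explicitly assembled confusion matrix
oracle_f1 <- function(pred, true, cls) {
  tab <- table(factor(pred %in% cls, c(FALSE, TRUE)),
               factor(true %in% cls, c(FALSE, TRUE)))
  tp <- tab["TRUE", "TRUE"]; fp <- tab["TRUE", "FALSE"]
  fn <- tab["FALSE", "TRUE"]
  if (tp + fp == 0 && tp + fn == 0) return(NA_real_)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

# exhaustive enumeration of all global alignments; lexicographic
# (score, identities, -length) optimum, identity over alignment length
oracle_nw <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  best <- NULL
  rec <- function(i, j, score, ident, len) {
    if (i > length(a) && j > length(b)) {
      cand <- c(score, ident, -len)
      if (is.null(best) ||
          cand[1] > best[1] ||
          (cand[1] == best[1] && (cand[2] > best[2] ||
            (cand[2] == best[2] && cand[3] > best[3]))))
        best <<- cand
      return(invisible())
    }
    if (i <= length(a) && j <= length(b)) {
      id <- a[i] == b[j] && a[i] != "X"
      rec(i + 1, j + 1, score + if (id) match else mismatch,
          ident + id, len + 1)
    }
    if (i <= length(a)) rec(i + 1, j, score + gap, ident, len + 1)
    if (j <= length(b)) rec(i, j + 1, score + gap, ident, len + 1)
  }
  rec(1L, 1L, 0, 0L, 0L)
  list(score = best[1], identities = best[2], length = -best[3],
       identity = 100 * best[2] / -best[3])
}

# small random annotation table inside a grid
random_annotations <- function(n, dims, origin = c(0, 0, 0)) {
  data.frame(
    chain_id = "A",
    residue_number = seq_len(n),
    residue_name = "ALA",
    ss_class = sample(c("helix", "sheet", "other"), n, replace = TRUE),
    x = origin[1] + runif(n, 0, dims[1] - 1),
    y = origin[2] + runif(n, 0, dims[2] - 1),
    z = origin[3] + runif(n, 0, dims[3] - 1),
    stringsAsFactors = FALSE
  )
}

random_label_grid <- function(dims, origin = c(0, 0, 0)) {
  label_grid(array(sample(0:2, prod(dims), replace = TRUE), dim = dims),
             origin = origin)
}

# tiny prepared training cases (alternating helix / sheet) for fast
# optimizer tests
tiny_cases <- function(n, seed, n_res = 6) {
  lapply(seq_len(n), function(i) {
    ann <- if (i %% 2L == 1L) make_helix(n_res) else make_sheet(2, 4)
    map <- simulate_density(as.matrix(ann[, c("x", "y", "z")]),
                            resolution = 5, grid_padding = 3,
                            noise_sd = 0.05, seed = seed + i)
    list(map = map, labels = label_voxels(map, ann), annotations = ann)
  })
}
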