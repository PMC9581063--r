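# Dataset curation: sequence-identity de-duplication, cylindrical-fit quality
# scoring and binning, and train/test screening.

#' Global-alignment percent identity (Needleman-Wunsch)
#'
#' Optimal global alignment under the scheme match +1, mismatch 0, gap -1;
#' identity is the number of identical aligned pairs divided by the alignment
#' length (including gap positions), as a percentage. Among co-optimal
#' alignments the one with the most identities (and then the shortest
#' alignment) defines the identity, so the value is well defined. "X" (and
#' any non-standard residue mapped to it) never counts as identical.
#'
#' @param seq_a,seq_b non-empty amino-acid sequences (single strings).
#' @param match,mismatch,gap scoring scheme (defaults +1 / 0 / -1).
#' @return A list with `identity` (percent), `score`, `identities` and
#'   `alignment_length`.
#' @export
nw_identity <- function(seq_a, seq_b, match = 1, mismatch = 0, gap = -1) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L) stop("sequences must be non-empty")

  # lexicographic DP over (score, identities, -length)
  S <- matrix(0, n + 1L, m + 1L)   # best score
  I <- matrix(0L, n + 1L, m + 1L)  # identities along that alignment
  L <- matrix(0L, n + 1L, m + 1L)  # alignment length
  S[, 1L] <- gap * (0:n); L[, 1L] <- 0:n
  S[1L, ] <- gap * (0:m); L[1L, ] <- 0:m
  for (i in seq_len(n)) {
    ident_row <- (a[i] == b) & a[i] != "X"
    sub_row <- ifelse(ident_row, match, mismatch)
    for (j in seq_len(m)) {
      sd <- S[i, j] + sub_row[j]; idd <- I[i, j] + ident_row[j]; ld <- L[i, j] + 1L
      su <- S[i, j + 1L] + gap;   idu <- I[i, j + 1L];           lu <- L[i, j + 1L] + 1L
      sl <- S[i + 1L, j] + gap;   idl <- I[i + 1L, j];           ll <- L[i + 1L, j] + 1L
      # pick diag/up/left by (score desc, identities desc, length asc)
      best <- 1L
      bs <- sd; bi <- idd; bl <- ld
      if (su > bs || (su == bs && (idu > bi || (idu == bi && lu < bl)))) {
        bs <- su; bi <- idu; bl <- lu
      }
      if (sl > bs || (sl == bs && (idl > bi || (idl == bi && ll < bl)))) {
        bs <- sl; bi <- idl; bl <- ll
      }
      S[i + 1L, j + 1L] <- bs; I[i + 1L, j + 1L] <- bi; L[i + 1L, j + 1L] <- bl
    }
  }
  list(identity = 100 * I[n + 1L, m + 1L] / L[n + 1L, m + 1L],
       score = S[n + 1L, m + 1L],
       identities = I[n + 1L, m + 1L],
       alignment_length = L[n + 1L, m + 1L])
}

#' De-duplicate near-identical chains within each protein
#'
#' Greedy retention in input order: a chain is dropped when its global
#' percent identity with an already-retained chain of the same protein
#' exceeds `threshold` (default 70%).
#'
#' @param chains data.frame with columns `chain_id`, `protein`, `sequence`.
#' @param threshold percent-identity cutoff.
#' @return `chains` with added columns `retained` (logical), `duplicate_of`
#'   and `identity` (vs. the retained chain that triggered removal).
#' @export
dedup_chains <- function(chains, threshold = 70) {
  stopifnot(all(c("chain_id", "protein", "sequence") %in% names(chains)))
  chains$retained <- TRUE
  chains$duplicate_of <- NA_character_
  chains$identity <- NA_real_
  for (prot in unique(chains$protein)) {
    idx <- which(chains$protein == prot)
    kept <- integer(0)
    for (i in idx) {
      dropped <- FALSE
      for (k in kept) {
        pid <- nw_identity(chains$sequence[i], chains$sequence[k])$identity
        if (pid > threshold) {
          chains$retained[i] <- FALSE
          chains$duplicate_of[i] <- chains$chain_id[k]
          chains$identity[i] <- pid
          dropped <- TRUE
          break
        }
      }
      if (!dropped) kept <- c(kept, i)
    }
  }
  chains
}

# contiguous helix segments of >= min_len residues
helix_segments <- function(annotations, min_len = 4L) {
  h <- annotations[annotations$ss_class == "helix", , drop = FALSE]
  if (nrow(h) == 0L) return(list())
  h <- h[order(h$chain_id, h$residue_number), , drop = FALSE]
  brk <- c(TRUE, diff(h$residue_number) != 1L |
                 h$chain_id[-1L] != h$chain_id[-nrow(h)])
  seg <- cumsum(brk)
  out <- split(h, seg)
  out[vapply(out, nrow, integer(1)) >= min_len]
}

#' Cylindrical-fit quality of a chain
#'
#' For each helix of at least 4 residues, an ideal cylinder is built around
#' the least-squares axis of the helix Calpha trace (radius 2.5 A, axial
#' extent spanning the Calpha projections). Voxels inside the cylinder are
#' the fit-predicted helix region; its F1 against the voxels labeled by that
#' helix's own residues (3 A Calpha spheres) scores the fit. The chain score
#' is the mean per-helix F1 and drives quality binning.
#'
#' @param truth a [label_grid()] (helix voxels = 1) or a [density_map()]
#'   with `threshold` giving the helix-region density cutoff.
#' @param annotations residue annotations (see [parse_stride()]).
#' @param radius cylinder radius in Angstrom.
#' @param threshold density cutoff when `truth` is a [density_map()].
#' @return A `chain_quality` list: `per_helix_f1`, `chain_score`,
#'   `n_helices`. With no qualifying helix the score is NA, with a warning
#'   (chain excluded from binning).
#' @export
cylindrical_fit <- function(truth, annotations, radius = 2.5, threshold = NULL) {
  segs <- helix_segments(annotations)
  if (length(segs) == 0L) {
    warning("chain has no helix of >= 4 residues; fit quality undefined")
    return(structure(list(per_helix_f1 = numeric(0), chain_score = NA_real_,
                          n_helices = 0L), class = "chain_quality"))
  }
  if (inherits(truth, "label_grid")) {
    dims <- dim(truth$labels); origin <- truth$origin; vs <- truth$voxel_size
  } else if (inherits(truth, "density_map")) {
    if (is.null(threshold))
      stop("`threshold` is required when `truth` is a density_map")
    dims <- dim(truth$data); origin <- truth$origin; vs <- truth$voxel_size
  } else stop("`truth` must be a label_grid or density_map")

  # world coordinates of all voxel centers
  gx <- origin[1] + (seq_len(dims[1]) - 1L) * vs[1]
  gy <- origin[2] + (seq_len(dims[2]) - 1L) * vs[2]
  gz <- origin[3] + (seq_len(dims[3]) - 1L) * vs[3]

  f1s <- vapply(segs, function(seg) {
    P <- as.matrix(seg[, c("x", "y", "z")])
    mu <- colMeans(P)
    axis <- svd(sweep(P, 2, mu))$v[, 1]
    tproj <- sweep(P, 2, mu) %*% axis
    # per-voxel axial and radial distance, via separable coordinates
    cx <- outer(outer(gx - mu[1], rep(1, dims[2])), rep(1, dims[3]))
    cy <- outer(outer(rep(1, dims[1]), gy - mu[2]), rep(1, dims[3]))
    cz <- outer(outer(rep(1, dims[1]), rep(1, dims[2])), gz - mu[3])
    t_vox <- cx * axis[1] + cy * axis[2] + cz * axis[3]
    r2 <- cx^2 + cy^2 + cz^2 - t_vox^2
    cyl <- (r2 <= radius^2 + 1e-9) & (t_vox >= min(tproj)) & (t_vox <= max(tproj))
    # this helix's own truth region: helix-supporting voxels near its trace
    helix_truth <- if (inherits(truth, "label_grid")) {
      (truth$labels == 1L) & sphere_mask(dims, origin, vs, P, 3)
    } else {
      (truth$data >= threshold) & sphere_mask(dims, origin, vs, P, 3 + radius)
    }
    tp <- sum(cyl & helix_truth); fp <- sum(cyl & !helix_truth)
    fn <- sum(!cyl & helix_truth)
    if (tp + fp + fn == 0L) return(NA_real_)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))

  structure(list(per_helix_f1 = unname(f1s), chain_score = mean(f1s),
                 n_helices = length(f1s)), class = "chain_quality")
}

#' Assign quality bins by tertile split of chain scores
#'
#' Top third of scores is Bin 1, middle third Bin 2, bottom third Bin 3.
#' Ties take the better (numerically smaller) bin; with all scores equal,
#' every chain lands in Bin 1.
#'
#' @param chain_scores numeric vector of chain fit scores.
#' @return Integer vector of bins in {1, 2, 3}.
#' @export
assign_bins <- function(chain_scores) {
  n <- length(chain_scores)
  if (n == 0L) stop("`chain_scores` must be non-empty")
  r <- rank(-chain_scores, ties.method = "min")
  as.integer(floor(3 * (r - 1) / n) + 1L)
}

#' Parse TM-align output for its two TM-scores
#'
#' TM-align prints one TM-score normalized by each chain length; both are
#' returned in printed order.
#'
#' @param path TM-align standard text output file.
#' @return Numeric length-2 vector of TM-scores.
#' @export
parse_tmalign <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tm_lines <- grep("^TM-score\\s*=", lines, value = TRUE)
  vals <- as.numeric(sub("^TM-score\\s*=\\s*([0-9.]+).*", "\\1", tm_lines))
  vals <- vals[is.finite(vals)]
  if (length(vals) < 2L)
    stop("expected two TM-score lines in ", path, ", found ", length(vals))
  vals[1:2]
}

is_unknown_seq <- function(s) {
  is.na(s) | s == "" | grepl("^[X]+$", toupper(s)) | toupper(s) == "UNK"
}

#' Screen test-set candidates against the training set
#'
#' Drops candidates with unknown sequences; drops candidates with more than
#' `identity_threshold` percent global sequence identity to any
#' known-sequence training chain; and, against each unknown-sequence training
#' chain, keeps a candidate only if at least one of the two TM-scores for the
#' pair is below `tm_threshold`.
#'
#' @param candidates data.frame with columns `chain_id`, `sequence`.
#' @param training_set data.frame with columns `chain_id`, `sequence`
#'   (`NA`/"UNK" marks unknown sequences).
#' @param tm_scores data.frame with columns `candidate`, `training`, `tm1`,
#'   `tm2` supplying both TM-score normalizations for every (candidate,
#'   unknown-sequence training chain) pair; missing required pairs raise an
#'   error listing them.
#' @param identity_threshold percent identity cutoff (default 35).
#' @param tm_threshold TM-score cutoff (default 0.5).
#' @return `candidates` with added columns `retained` and `reason`.
#' @export
screen_test_set <- function(candidates, training_set, tm_scores = NULL,
                            identity_threshold = 35, tm_threshold = 0.5) {
  stopifnot(all(c("chain_id", "sequence") %in% names(candidates)),
            all(c("chain_id", "sequence") %in% names(training_set)))
  candidates$retained <- TRUE
  candidates$reason <- NA_character_

  unk_train <- training_set$chain_id[is_unknown_seq(training_set$sequence)]
  known_train <- training_set[!is_unknown_seq(training_set$sequence), , drop = FALSE]

  # every (candidate, unknown training chain) pair needs TM-scores up front
  need <- expand.grid(
    candidate = candidates$chain_id[!is_unknown_seq(candidates$sequence)],
    training = unk_train, stringsAsFactors = FALSE)
  if (nrow(need) > 0L) {
    have <- if (is.null(tm_scores)) character(0) else
      paste(tm_scores$candidate, tm_scores$training)
    miss <- !(paste(need$candidate, need$training) %in% have)
    if (any(miss))
      stop("missing TM-scores for pair(s): ",
           paste(paste(need$candidate[miss], need$training[miss], sep = "/"),
                 collapse = ", "))
  }

  for (i in seq_len(nrow(candidates))) {
    if (is_unknown_seq(candidates$sequence[i])) {
      candidates$retained[i] <- FALSE
      candidates$reason[i] <- "unknown sequence"
      next
    }
    for (j in seq_len(nrow(known_train))) {
      pid <- nw_identity(candidates$sequence[i], known_train$sequence[j])$identity
      if (pid > identity_threshold) {
        candidates$retained[i] <- FALSE
        candidates$reason[i] <- sprintf("%.1f%% identity to training chain %s",
                                        pid, known_train$chain_id[j])
        break
      }
    }
    if (!candidates$retained[i]) next
    for (tc in unk_train) {
      row <- tm_scores[tm_scores$candidate == candidates$chain_id[i] &
                         tm_scores$training == tc, , drop = FALSE]
      if (min(row$tm1[1], row$tm2[1]) >= tm_threshold) {
        candidates$retained[i] <- FALSE
        candidates$reason[i] <- sprintf(
          "TM-scores (%.2f, %.2f) vs unknown-sequence training chain %s both >= %.2f",
          row$tm1[1], row$tm2[1], tc, tm_threshold)
        break
      }
    }
  }
  candidates
}
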