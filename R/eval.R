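# Voxel-level and residue-level F1 evaluation.
#
# Residue predictions are made by majority voting over the predicted labels
# of voxels within 3 A of the residue's Calpha atom, ties resolved with
# priority helix, then sheet, then other. A class F1 is NA only when the
# class is absent from both truth and prediction (undefined precision AND
# recall); when one side is empty but not the other, F1 is 0.

#' One-vs-rest F1 score for a class
#'
#' `F1 = 2TP / (2TP + FP + FN)`. Returns NA when the class occurs in neither
#' the truth nor the prediction (precision and recall both undefined); returns
#' 0 when only one of them lacks the class.
#'
#' @param pred_labels,true_labels equal-length vectors (or [label_grid()]s)
#'   of class labels.
#' @param class the class to score (an integer code or one of "background",
#'   "helix", "sheet").
#' @return F1 in [0, 1], or NA.
#' @export
f1_class <- function(pred_labels, true_labels, class) {
  if (inherits(pred_labels, "label_grid")) pred_labels <- pred_labels$labels
  if (inherits(true_labels, "label_grid")) true_labels <- true_labels$labels
  if (length(pred_labels) != length(true_labels))
    stop("prediction and truth have different lengths")
  if (is.character(pred_labels) || is.character(true_labels)) {
    if (!is.character(class))
      class <- c("background", "helix", "sheet")[class + 1L]
  } else if (is.character(class)) {
    class <- match(class, c("background", "helix", "sheet")) - 1L
  }
  p <- pred_labels == class
  t <- true_labels == class
  tp <- sum(p & t)
  fp <- sum(p & !t)
  fn <- sum(!p & t)
  if (tp + fp + fn == 0L) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

#' Majority-vote residue class from a predicted label grid
#'
#' Counts the predicted classes of all voxels whose center lies within
#' `radius` Angstrom of the Calpha coordinate and returns the most common
#' one; ties are resolved with priority helix, then sheet, then other. If no
#' grid voxel lies within the radius (Calpha outside the component) the vote
#' is "other", with a warning.
#'
#' @param grid a [label_grid()] at 1 A per voxel.
#' @param ca_coord numeric length-3 world coordinate of the Calpha atom.
#' @param radius voting radius in Angstrom (default 3).
#' @return One of "helix", "sheet", "other".
#' @export
vote_residue <- function(grid, ca_coord, radius = 3) {
  stopifnot(inherits(grid, "label_grid"))
  m <- sphere_mask(dim(grid$labels), grid$origin, grid$voxel_size,
                   rbind(ca_coord), radius)
  if (!any(m)) {
    warning("no voxel within ", radius, " A of Calpha at (",
            paste(signif(ca_coord, 4), collapse = ", "), "); voting 'other'")
    return("other")
  }
  votes <- tabulate(as.integer(grid$labels[m]) + 1L, nbins = 3L)
  # priority order helix(1), sheet(2), other(0) under ties
  pri <- c(votes[2], votes[3], votes[1])
  c("helix", "sheet", "other")[which.max(pri)]
}

#' Evaluate one case at voxel and residue level
#'
#' Voxel F1 scores compare the two label grids directly; residue F1 scores
#' compare [vote_residue()] predictions against the annotated classes.
#'
#' @param pred predicted [label_grid()].
#' @param truth_grid ground-truth [label_grid()] on the same lattice.
#' @param annotations residue annotations (see [parse_stride()]): columns
#'   `ss_class`, `x`, `y`, `z`.
#' @param case_id identifier recorded in the report row.
#' @return A one-row data.frame with residue counts (`n_helix`, `n_sheet`,
#'   `n_total`) and F1 columns `f1_voxel_helix`, `f1_voxel_sheet`,
#'   `f1_residue_helix`, `f1_residue_sheet` (NA where a class is absent from
#'   both truth and prediction).
#' @export
evaluate_case <- function(pred, truth_grid, annotations, case_id = "case") {
  stopifnot(inherits(pred, "label_grid"), inherits(truth_grid, "label_grid"))
  if (!identical(dim(pred$labels), dim(truth_grid$labels)))
    stop("prediction and truth grids are on different lattices")
  res_pred <- vapply(seq_len(nrow(annotations)), function(i)
    vote_residue(pred, c(annotations$x[i], annotations$y[i], annotations$z[i])),
    character(1))
  res_true <- annotations$ss_class
  data.frame(
    case_id = case_id,
    n_helix = sum(res_true == "helix"),
    n_sheet = sum(res_true == "sheet"),
    n_total = length(res_true),
    f1_voxel_helix = f1_class(pred$labels, truth_grid$labels, 1L),
    f1_voxel_sheet = f1_class(pred$labels, truth_grid$labels, 2L),
    f1_residue_helix = f1_class(res_pred, res_true, "helix"),
    f1_residue_sheet = f1_class(res_pred, res_true, "sheet"),
    stringsAsFactors = FALSE
  )
}

#' Residue-count weighted average of per-case F1 scores
#'
#' Each case's F1 is weighted by its number of residues of the class; cases
#' with NA F1 (class absent) carry zero residues of the class and are
#' excluded. Weights therefore sum to 1 over the cases with the class
#' present.
#'
#' @param cases data.frame of per-case rows from [evaluate_case()].
#' @param metric one of the F1 column names, e.g. `"f1_residue_helix"`.
#' @param class `"helix"` or `"sheet"`; selects the residue-count column.
#' @return The weighted average F1.
#' @export
weighted_average <- function(cases, metric, class = c("helix", "sheet")) {
  class <- match.arg(class)
  f1 <- cases[[metric]]
  n <- cases[[paste0("n_", class)]]
  keep <- !is.na(f1)
  if (!any(keep) || sum(n[keep]) == 0)
    stop("no case has a defined ", metric, " for class ", class)
  sum(n[keep] * f1[keep]) / sum(n[keep])
}

#' Evaluate a set of cases and summarize
#'
#' @param case_list list of lists with elements `pred`, `truth`,
#'   `annotations` and optionally `case_id`.
#' @return A list with `cases` (per-case data.frame) and `summary` (weighted
#'   average F1 per metric and class).
#' @export
evaluate_cases <- function(case_list) {
  rows <- lapply(seq_along(case_list), function(i) {
    cs <- case_list[[i]]
    evaluate_case(cs$pred, cs$truth, cs$annotations,
                  case_id = if (!is.null(cs$case_id)) cs$case_id else paste0("case", i))
  })
  cases <- do.call(rbind, rows)
  summ <- data.frame(
    metric = c("f1_voxel_helix", "f1_voxel_sheet",
               "f1_residue_helix", "f1_residue_sheet"),
    class = c("helix", "sheet", "helix", "sheet"),
    stringsAsFactors = FALSE
  )
  summ$weighted_f1 <- vapply(seq_len(nrow(summ)), function(i)
    tryCatch(weighted_average(cases, summ$metric[i], summ$class[i]),
             error = function(e) NA_real_), numeric(1))
  list(cases = cases, summary = summ)
}
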