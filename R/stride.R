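# Parsing of STRIDE secondary-structure assignments and joining with PDB
# Calpha coordinates to form per-residue ground-truth annotations.

#' Map a STRIDE one-letter code to a secondary-structure class
#'
#' H, G and I count as helix; B, b and E count as sheet (the lowercase "b"
#' is matched case-sensitively); every other code is "other".
#'
#' @param code character vector of STRIDE one-letter codes.
#' @return character vector over {"helix", "sheet", "other"}.
#' @export
stride_class <- function(code) {
  out <- rep("other", length(code))
  out[code %in% c("H", "G", "I")] <- "helix"
  out[code %in% c("B", "b", "E")] <- "sheet"
  out
}

#' Parse STRIDE output into per-residue annotations
#'
#' Reads the ASG records of a STRIDE output file and joins each residue with
#' its Calpha coordinate from the corresponding PDB file by (chain, residue
#' number). Residues listed by STRIDE but absent from the PDB raise an error;
#' residues present in the PDB but lacking a Calpha atom are dropped with a
#' warning.
#'
#' @param stride_path STRIDE output file (must contain ASG records).
#' @param pdb_path PDB file providing Calpha coordinates. May be omitted if
#'   `pdb` is given.
#' @param pdb optionally, an already-parsed `bio3d` pdb object.
#' @return A data.frame of residue annotations with columns `chain_id`,
#'   `residue_number`, `residue_name`, `ss_class`, `x`, `y`, `z`.
#' @export
parse_stride <- function(stride_path, pdb_path = NULL, pdb = NULL) {
  lines <- readLines(stride_path, warn = FALSE)
  asg <- lines[startsWith(lines, "ASG")]
  if (length(asg) == 0L) stop("no ASG records in ", stride_path)
  parts <- strsplit(trimws(asg), "[[:space:]]+")
  bad <- vapply(parts, length, integer(1)) < 6L
  if (any(bad)) stop("malformed ASG record(s) in ", stride_path)
  ann <- data.frame(
    chain_id = vapply(parts, `[`, "", 3L),
    residue_number = as.integer(vapply(parts, `[`, "", 4L)),
    residue_name = vapply(parts, `[`, "", 2L),
    ss_class = stride_class(vapply(parts, `[`, "", 6L)),
    stringsAsFactors = FALSE
  )
  if (anyNA(ann$residue_number))
    stop("non-numeric residue number in ASG records of ", stride_path)

  if (is.null(pdb)) {
    if (is.null(pdb_path)) stop("either `pdb_path` or `pdb` must be given")
    pdb <- bio3d::read.pdb(pdb_path, verbose = FALSE)
  }
  at <- pdb$atom
  key <- paste(ann$chain_id, ann$residue_number)
  res_key <- paste(at$chain, at$resno)
  missing_res <- !(key %in% res_key)
  if (any(missing_res))
    stop("residue(s) in STRIDE output absent from PDB: ",
         paste(unique(key[missing_res]), collapse = ", "))

  ca <- at[at$elety == "CA", , drop = FALSE]
  ca_key <- paste(ca$chain, ca$resno)
  hit <- match(key, ca_key)
  no_ca <- is.na(hit)
  if (any(no_ca)) {
    warning("dropping ", sum(no_ca), " residue(s) without a Calpha atom: ",
            paste(unique(key[no_ca]), collapse = ", "))
    ann <- ann[!no_ca, , drop = FALSE]
    hit <- hit[!no_ca]
  }
  ann$x <- ca$x[hit]
  ann$y <- ca$y[hit]
  ann$z <- ca$z[hit]
  if (any(!is.finite(as.matrix(ann[, c("x", "y", "z")]))))
    stop("non-finite Calpha coordinates after join")
  rownames(ann) <- NULL
  ann
}

#' Count residues per secondary-structure class
#'
#' Tallies helix, sheet and total residues from an annotation table — the
#' per-chain H/S/T counts reported alongside evaluation results.
#'
#' @param annotations data.frame as returned by [parse_stride()].
#' @return A list with integer elements `helix`, `sheet`, `total`.
#' @export
residue_class_counts <- function(annotations) {
  list(helix = sum(annotations$ss_class == "helix"),
       sheet = sum(annotations$ss_class == "sheet"),
       total = nrow(annotations))
}
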