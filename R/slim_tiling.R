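# Peptide-tiling contact-probability aggregation.
#
# A disordered region (e.g. a transactivation domain) is tiled into
# consecutive k-mers; each tile is co-folded with the receptor by an external
# structure-prediction service, which reports a peptide-residue x
# receptor-residue contact-probability matrix.  Per prediction, the contact
# probabilities of a peptide residue to a defined receptor pocket are
# summarised as log2(mean probability); per residue of the full sequence, the
# scores of all predictions covering it are averaged.  The result is a 1D
# interaction landscape highlighting short-linear-motif residues.

#' Tile a sequence region into consecutive k-mers
#'
#' @param sequence Amino-acid string (full-length protein).
#' @param region `c(start, end)`, 1-based inclusive, within the sequence;
#'   default the whole sequence.
#' @param k Tile length (default 10).
#' @param stride Offset between consecutive tiles (default 1).
#' @return Data.frame with one row per tile: `start`, `end` (coordinates on
#'   the full sequence) and `sequence`.  For stride 1 the number of tiles is
#'   `region length - k + 1`.
#' @export
tile_sequence <- function(sequence, region = NULL, k = 10L, stride = 1L) {
  n <- nchar(sequence)
  if (is.null(region)) region <- c(1L, n)
  stopifnot(length(region) == 2, region[1] >= 1, region[2] <= n,
            region[1] <= region[2], stride >= 1)
  len <- region[2] - region[1] + 1L
  if (k > len) {
    stop(sprintf("tile length k = %d exceeds region length %d", k, len),
         call. = FALSE)
  }
  starts <- seq.int(region[1], region[2] - k + 1L, by = stride)
  data.frame(
    start = starts,
    end = starts + k - 1L,
    sequence = substring(sequence, starts, starts + k - 1L),
    stringsAsFactors = FALSE
  )
}

#' Construct a tiling prediction
#'
#' One prediction for one tile: the peptide-residue x receptor-residue
#' contact-probability matrix, with row `i` corresponding to full-sequence
#' position `peptide_start + i - 1`.
#'
#' @param peptide_start,peptide_end Tile coordinates, 1-based inclusive, on
#'   the full-length sequence.
#' @param contact_matrix Numeric matrix in `[0, 1]`; `peptide_end -
#'   peptide_start + 1` rows, one column per receptor residue.
#' @param receptor_residue_ids Unique labels for the matrix columns (e.g.
#'   `"L256"`).
#' @return A `tiling_prediction` object.
#' @export
tiling_prediction <- function(peptide_start, peptide_end, contact_matrix,
                              receptor_residue_ids) {
  contact_matrix <- as.matrix(contact_matrix)
  tile_len <- peptide_end - peptide_start + 1L
  if (nrow(contact_matrix) != tile_len) {
    stop(sprintf(
      "contact matrix has %d row(s) for a tile of length %d (%d-%d)",
      nrow(contact_matrix), tile_len, peptide_start, peptide_end),
      call. = FALSE)
  }
  if (ncol(contact_matrix) != length(receptor_residue_ids)) {
    stop("one receptor residue id is required per matrix column",
         call. = FALSE)
  }
  if (anyDuplicated(receptor_residue_ids)) {
    stop("receptor residue ids must be unique", call. = FALSE)
  }
  if (any(is.na(contact_matrix)) || any(contact_matrix < 0) ||
      any(contact_matrix > 1)) {
    stop("contact probabilities must lie in [0, 1]", call. = FALSE)
  }
  colnames(contact_matrix) <- receptor_residue_ids
  structure(
    list(peptide_start = as.integer(peptide_start),
         peptide_end = as.integer(peptide_end),
         contact_matrix = contact_matrix,
         receptor_residue_ids = as.character(receptor_residue_ids)),
    class = "tiling_prediction"
  )
}

#' Read a tiling prediction from JSON
#'
#' Consumes the documented JSON schema: an object with `peptide_start`,
#' `peptide_end`, `receptor_residue_ids` (array of strings) and
#' `contact_matrix` (array of rows, one per peptide residue).  Outputs of
#' real prediction servers are converted into this schema by a thin adapter
#' upstream of this package.
#'
#' @param path Path to the JSON file.
#' @return A validated [tiling_prediction()].
#' @export
read_prediction_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("peptide_start", "peptide_end", "receptor_residue_ids",
                "contact_matrix")
  missing_fields <- setdiff(required, names(x))
  if (length(missing_fields) > 0) {
    stop("prediction JSON is missing field(s): ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  }
  mat <- x$contact_matrix
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  tiling_prediction(x$peptide_start, x$peptide_end, mat,
                    x$receptor_residue_ids)
}

#' Write a tiling prediction to JSON
#'
#' @param prediction A [tiling_prediction()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_prediction_json <- function(prediction, path) {
  stopifnot(inherits(prediction, "tiling_prediction"))
  mat <- prediction$contact_matrix
  dimnames(mat) <- NULL
  jsonlite::write_json(
    list(peptide_start = prediction$peptide_start,
         peptide_end = prediction$peptide_end,
         receptor_residue_ids = prediction$receptor_residue_ids,
         contact_matrix = mat),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor"
  )
  invisible(path)
}

#' Aggregate tiled contact predictions into a per-residue landscape
#'
#' Per prediction and peptide residue, the contact probabilities to the
#' pocket residues are reduced (mean by default) and log2-transformed with an
#' epsilon floor; per full-sequence residue, the scores of all predictions
#' covering it are averaged (arithmetic mean), giving the interaction
#' landscape of the tiled region.
#'
#' @param predictions List of [tiling_prediction()] objects.
#' @param pocket Character vector of receptor residue ids defining the
#'   binding pocket; must be present in every prediction.
#' @param epsilon Probability floor applied before the log2 (default `1e-6`),
#'   keeping scores finite for zero contact.
#' @param pocket_stat How the pocket residues are reduced per peptide
#'   residue: `"mean"` (default) or `"max"`.
#' @param log_mode `"log2_mean"` (default): `log2(max(stat(p), epsilon))`;
#'   `"mean_log2"`: `mean(log2(pmax(p, epsilon)))` over pocket residues.
#' @return Data.frame with one row per covered full-sequence residue:
#'   `position`, `score` (mean log2 contact score), `n_predictions`, and a
#'   list column `scores` holding the per-prediction values.
#' @export
aggregate_contacts <- function(predictions, pocket, epsilon = 1e-6,
                               pocket_stat = c("mean", "max"),
                               log_mode = c("log2_mean", "mean_log2")) {
  pocket_stat <- match.arg(pocket_stat)
  log_mode <- match.arg(log_mode)
  stat_fun <- if (pocket_stat == "mean") mean else max

  per_res <- list()
  for (pred in predictions) {
    stopifnot(inherits(pred, "tiling_prediction"))
    absent <- setdiff(pocket, pred$receptor_residue_ids)
    if (length(absent) > 0) {
      stop("prediction lacks pocket residue(s): ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    sub <- pred$contact_matrix[, pocket, drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      pos <- pred$peptide_start + i - 1L
      p <- sub[i, ]
      score <- if (log_mode == "log2_mean") {
        log2(max(stat_fun(p), epsilon))
      } else {
        mean(log2(pmax(p, epsilon)))
      }
      key <- as.character(pos)
      per_res[[key]] <- c(per_res[[key]], score)
    }
  }
  if (length(per_res) == 0) {
    return(data.frame(position = integer(0), score = numeric(0),
                      n_predictions = integer(0)))
  }
  positions <- sort(as.integer(names(per_res)))
  scores <- per_res[as.character(positions)]
  out <- data.frame(
    position = positions,
    score = vapply(scores, mean, numeric(1)),
    n_predictions = lengths(scores)
  )
  out$scores <- unname(scores)
  out
}

#' Receptor pocket residues of the SWIFT hydrophobic cage
#'
#' The six hydrophobic-pocket residues of the SMARCD2 SWIFT domain used as
#' the default contact-aggregation target set.
#'
#' @return Character vector of residue labels.
#' @export
swift_pocket_residues <- function() {
  c("L256", "I258", "V272", "W274", "F286", "V288")
}
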