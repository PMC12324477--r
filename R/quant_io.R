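# Peptide quantification table I/O.
#
# The quant table is the hand-off from upstream peptide identification and
# XIC integration: one row per peptide form x condition x replicate, with the
# integrated intensity of that form.  Modified forms (GEE adduct, +85.0522 Da,
# or its hydrolyzed product, +57.0209 Da) carry the candidate D/E site(s) the
# label may sit on; more than one candidate means MS/MS could not localize the
# label (an "ambiguous" observation).

.quant_columns <- c(
  "protein_id", "peptide_start", "peptide_end", "sequence",
  "condition", "replicate", "form", "candidate_sites", "intensity"
)

.form_levels <- c("unmodified", "GEE", "hydrolyzed")

.parse_candidate_sites <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(integer(0))
    as.integer(strsplit(trimws(s), ";", fixed = TRUE)[[1]])
  })
}

.format_candidate_sites <- function(sites) {
  vapply(sites, function(s) paste(s, collapse = ";"), character(1))
}

#' Read a peptide quantification table
#'
#' Reads a tab-separated table of integrated peptide-form intensities (one row
#' per peptide species x condition x replicate) and validates every row
#' against the peptide-observation invariants: coordinates are 1-based
#' inclusive with `peptide_start <= peptide_end`; intensities are
#' non-negative; `form` is one of `unmodified`, `GEE`, `hydrolyzed`;
#' unmodified rows carry no candidate sites; modified rows carry at least one
#' candidate site, each inside the peptide and on a D or E residue.
#' `candidate_sites` is encoded in the file as semicolon-separated 1-based
#' positions.
#'
#' @param path Path to the tab-separated quant table.
#' @param sequences Optional named character vector of subunit sequences (as
#'   from [read_subunit_fasta()]); when supplied, each peptide's sequence is
#'   checked against the subunit sequence at its coordinates.
#' @return A `data.frame` of validated observations, in file row order, with
#'   `candidate_sites` as a list column of integer vectors.
#' @seealso [write_quant_table()], [read_subunit_fasta()]
#' @export
read_quant_table <- function(path, sequences = NULL) {
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  missing_cols <- setdiff(.quant_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop("quant table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  obs <- data.frame(
    protein_id    = raw$protein_id,
    peptide_start = as.integer(raw$peptide_start),
    peptide_end   = as.integer(raw$peptide_end),
    sequence      = raw$sequence,
    condition     = raw$condition,
    replicate     = as.integer(raw$replicate),
    form          = raw$form,
    intensity     = as.numeric(raw$intensity),
    stringsAsFactors = FALSE
  )
  obs$candidate_sites <- .parse_candidate_sites(raw$candidate_sites)
  validate_observations(obs, sequences = sequences)
  obs
}

#' Write a peptide quantification table
#'
#' Inverse of [read_quant_table()]: writes the tab-separated representation,
#' with `candidate_sites` collapsed to semicolon-separated positions.
#'
#' @param observations Observation data.frame as returned by
#'   [read_quant_table()] or [simulate_quant()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(observations, path) {
  out <- observations[, setdiff(.quant_columns, "candidate_sites")]
  out$candidate_sites <- .format_candidate_sites(observations$candidate_sites)
  out <- out[, .quant_columns]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Validate peptide observations
#'
#' Checks the peptide-observation invariants (see [read_quant_table()]) and
#' stops with the offending row number on the first violation.
#'
#' @inheritParams write_quant_table
#' @param sequences Optional named character vector of subunit sequences.
#' @return `observations`, invisibly.
#' @export
validate_observations <- function(observations, sequences = NULL) {
  n <- nrow(observations)
  fail <- function(i, msg) {
    stop(sprintf("row %d: %s", i, msg), call. = FALSE)
  }
  for (i in seq_len(n)) {
    o <- observations[i, ]
    sites <- observations$candidate_sites[[i]]
    if (is.na(o$peptide_start) || is.na(o$peptide_end) ||
        o$peptide_start > o$peptide_end) {
      fail(i, "peptide_start must be <= peptide_end")
    }
    if (nchar(o$sequence) != o$peptide_end - o$peptide_start + 1L) {
      fail(i, sprintf("sequence length %d does not match coordinates %d-%d",
                      nchar(o$sequence), o$peptide_start, o$peptide_end))
    }
    if (!o$form %in% .form_levels) {
      fail(i, sprintf("unknown form '%s' (expected %s)", o$form,
                      paste(.form_levels, collapse = ", ")))
    }
    if (is.na(o$intensity) || o$intensity < 0) {
      fail(i, "intensity must be a non-negative number")
    }
    if (o$form == "unmodified") {
      if (length(sites) > 0) {
        fail(i, "unmodified forms must not carry candidate sites")
      }
    } else {
      if (length(sites) == 0) {
        fail(i, "modified forms must carry at least one candidate site")
      }
      if (any(sites < o$peptide_start | sites > o$peptide_end)) {
        fail(i, "candidate site outside peptide bounds")
      }
      letters_at <- substring(o$sequence, sites - o$peptide_start + 1L,
                              sites - o$peptide_start + 1L)
      if (!all(letters_at %in% c("D", "E"))) {
        bad <- sites[!letters_at %in% c("D", "E")][1]
        fail(i, sprintf(
          "candidate site %d is on residue '%s'; labels are restricted to D/E",
          bad, letters_at[!letters_at %in% c("D", "E")][1]))
      }
    }
    if (!is.null(sequences)) {
      if (!o$protein_id %in% names(sequences)) {
        fail(i, sprintf("protein_id '%s' not present in supplied sequences",
                        o$protein_id))
      }
      ref <- substring(sequences[[o$protein_id]], o$peptide_start,
                       o$peptide_end)
      if (!identical(ref, o$sequence)) {
        fail(i, sprintf(
          "peptide sequence does not match subunit '%s' at %d-%d",
          o$protein_id, o$peptide_start, o$peptide_end))
      }
    }
  }
  invisible(observations)
}

#' Read subunit sequences from a FASTA file
#'
#' @param path Path to an amino-acid FASTA file.
#' @return Named character vector of sequences; names are the first
#'   whitespace-delimited token of each FASTA header.
#' @export
read_subunit_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
}

#' Write subunit sequences to a FASTA file
#'
#' @param sequences Named character vector of amino-acid sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_subunit_fasta <- function(sequences, path) {
  aa <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
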