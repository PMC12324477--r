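# Projection of residue-level exposure changes onto structures and schematics.
#
# Exposure changes are point measurements at labeled D/E residues.  For
# visualization on a structure they are extended in windows of 11 aa centered
# on each label; where windows overlap, the covering labels' deltas are
# averaged per residue.  Labels whose exact site is ambiguous are first split
# into one observation per candidate site (same delta each - this stage
# splits observations, not intensity).  Labels on paralogs absent from the
# structure are remapped onto the paralog that is resolved; schematic (1D)
# tracks skip remapping to preserve paralog-specific signal.

#' Split ambiguous labels into per-site observations
#'
#' A label with `m` candidate sites becomes `m` observations, each carrying
#' the full delta value (observation splitting, not intensity splitting).
#'
#' @param labels Data.frame with a list column `candidate_sites` (integer
#'   vectors, each non-empty) and a numeric `delta` column; an optional
#'   `protein_id` column is carried through.
#' @return Data.frame with columns `position`, `delta` (and `protein_id` when
#'   present); one row per (label, candidate site).
#' @export
split_ambiguous <- function(labels) {
  m <- lengths(labels$candidate_sites)
  if (any(m == 0)) {
    stop("label(s) with empty candidate site list: row ",
         paste(which(m == 0), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    position = unlist(labels$candidate_sites),
    delta = rep(labels$delta, m)
  )
  if ("protein_id" %in% names(labels)) {
    out <- cbind(protein_id = rep(labels$protein_id, m), out,
                 stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Windowed exposure profile along a subunit
#'
#' Paints each label's delta over a window of `window` residues centered on
#' the label (truncated at the chain ends) and assigns every residue covered
#' by `k` windows the arithmetic mean of those `k` deltas.  Residues covered
#' by no window are missing (`NA`).  Stored values are never clipped;
#' clipping happens only at B-factor export.
#'
#' @param labels Data.frame with numeric columns `position` (1-based) and
#'   `delta` (percent change in exposure).
#' @param sequence_length Length of the subunit sequence.
#' @param window Odd window width in residues (default 11).
#' @param protein_id Optional subunit identifier stored on the profile.
#' @return An `exposure_profile` object: list with `protein_id`, `length`,
#'   `values` (numeric vector of length `sequence_length`), `window`, and the
#'   source `labels`.
#' @export
window_profile <- function(labels, sequence_length, window = 11L,
                           protein_id = NA_character_) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("window must be an odd positive integer (center undefined otherwise)",
         call. = FALSE)
  }
  if (nrow(labels) > 0 &&
      any(labels$position < 1L | labels$position > sequence_length)) {
    stop("label position outside [1, sequence_length]", call. = FALSE)
  }
  h <- (window - 1L) %/% 2L
  sums <- numeric(sequence_length)
  counts <- integer(sequence_length)
  for (i in seq_len(nrow(labels))) {
    p <- labels$position[i]
    idx <- max(1L, p - h):min(sequence_length, p + h)
    sums[idx] <- sums[idx] + labels$delta[i]
    counts[idx] <- counts[idx] + 1L
  }
  values <- ifelse(counts > 0L, sums / counts, NA_real_)
  structure(
    list(protein_id = protein_id, length = sequence_length, values = values,
         window = window, labels = labels[, c("position", "delta")]),
    class = "exposure_profile"
  )
}

#' @export
print.exposure_profile <- function(x, ...) {
  covered <- sum(!is.na(x$values))
  cat(sprintf(
    "exposure_profile: %s, %d aa, window %d, %d label(s), %d residue(s) covered\n",
    x$protein_id, x$length, x$window, nrow(x$labels), covered))
  invisible(x)
}

#' Define a paralog remapping
#'
#' @param source,target Character vectors of equal length: each source
#'   subunit maps onto one target (primary) subunit.  A source may appear
#'   only once (the mapping is functional).
#' @param position_maps Optional named list (by source subunit) of data.frames
#'   with columns `source_pos`, `target_pos` giving an explicit residue
#'   translation; sources without a table use identity numbering.
#' @return A `paralog_map` object.
#' @export
paralog_map <- function(source = character(0), target = character(0),
                        position_maps = NULL) {
  if (length(source) != length(target)) {
    stop("source and target must have the same length", call. = FALSE)
  }
  if (anyDuplicated(source)) {
    stop("paralog map must be functional: duplicated source subunit",
         call. = FALSE)
  }
  structure(list(pairs = data.frame(source = as.character(source),
                                    target = as.character(target),
                                    stringsAsFactors = FALSE),
                 position_maps = position_maps),
            class = "paralog_map")
}

#' Remap paralog labels onto primary subunits
#'
#' Labels observed on a paralog that is not resolved in the structure are
#' relocated to the resolved (primary) paralog and pooled with labels
#' observed there directly, before windowing.  Positions are translated
#' through the map's per-pair table when one is supplied, else copied
#' unchanged (identity numbering).  Positions absent from a supplied table
#' are dropped with a warning.
#'
#' @param labels Data.frame with columns `protein_id`, `position`, `delta`.
#' @param map A [paralog_map()].
#' @return Data.frame of the same shape with remapped `protein_id`/`position`.
#' @export
remap_paralogs <- function(labels, map) {
  stopifnot(inherits(map, "paralog_map"))
  if (nrow(map$pairs) == 0 || nrow(labels) == 0) return(labels)
  out <- labels
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(map$pairs))) {
    src <- map$pairs$source[i]
    tgt <- map$pairs$target[i]
    rows <- which(out$protein_id == src)
    if (length(rows) == 0) next
    tab <- map$position_maps[[src]]
    if (!is.null(tab)) {
      idx <- match(out$position[rows], tab$source_pos)
      unmapped <- rows[is.na(idx)]
      if (length(unmapped) > 0) {
        warning(sprintf(
          "%d label(s) on %s at position(s) %s have no mapping entry for %s and were dropped",
          length(unmapped), src,
          paste(out$position[unmapped], collapse = ", "), tgt),
          call. = FALSE)
        keep[unmapped] <- FALSE
      }
      mapped <- rows[!is.na(idx)]
      out$position[mapped] <- tab$target_pos[idx[!is.na(idx)]]
      out$protein_id[mapped] <- tgt
    } else {
      out$protein_id[rows] <- tgt
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-paralog schematic exposure profiles
#'
#' Windowed 1D tracks for subunit schematics: identical to [window_profile()]
#' per subunit, but run without paralog remapping so paralog-specific effects
#' are preserved (e.g. profiles for both members of a paralog pair).
#'
#' @param labels Data.frame with columns `protein_id`, `position`, `delta`.
#' @param sequence_lengths Named integer vector: subunit -> sequence length.
#'   Every subunit present in `labels` must be named.
#' @param window Odd window width (default 11).
#' @return Named list of `exposure_profile` objects, one per subunit in
#'   `sequence_lengths`.
#' @export
subunit_schematic_profile <- function(labels, sequence_lengths, window = 11L) {
  absent <- setdiff(unique(labels$protein_id), names(sequence_lengths))
  if (length(absent) > 0) {
    stop("no sequence length for subunit(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  profs <- lapply(names(sequence_lengths), function(su) {
    window_profile(labels[labels$protein_id == su, , drop = FALSE],
                   sequence_length = sequence_lengths[[su]],
                   window = window, protein_id = su)
  })
  stats::setNames(profs, names(sequence_lengths))
}

#' Define a structure chain mapping
#'
#' @param chain Character vector of structure chain identifiers.
#' @param subunit Subunit name each chain carries.
#' @param offset Integer added to the structure residue number to obtain the
#'   subunit sequence position (reconciles construct vs. structure numbering);
#'   default 0.
#' @return A data.frame with columns `chain`, `subunit`, `offset`.
#' @export
chain_map <- function(chain, subunit, offset = 0L) {
  data.frame(chain = as.character(chain), subunit = as.character(subunit),
             offset = as.integer(rep_len(offset, length(chain))),
             stringsAsFactors = FALSE)
}

#' Export exposure changes into the B-factor column of a PDB file
#'
#' Writes, for every atom of a mapped residue, the windowed exposure change
#' clamped to `clip` (default -30 to +30 percent) into the B-factor column
#' (two decimals).  Residues without a profile value - and all atoms on
#' unmapped chains - receive the sentinel `0.00` and are listed in a sidecar
#' report, because the PDB format has no missing-value encoding.  All other
#' file content is byte-preserved.
#'
#' @param pdb Path to the input PDB file (fixed-column dialect).
#' @param profiles Named list of [window_profile()] objects, keyed by subunit.
#' @param chains A [chain_map()]; every listed chain must occur in the file.
#' @param clip Numeric `c(low, high)` clamp applied at export only.
#' @param path Output PDB path.
#' @param sidecar Optional path for the tab-separated missing-residue report;
#'   default `paste0(path, ".missing.tsv")`; `NA` suppresses the file.
#' @return Invisibly, a list with `path` and `missing` (data.frame with
#'   `chain`, `resno`, `subunit`, `reason`).
#' @export
write_bfactor_pdb <- function(pdb, profiles, chains, clip = c(-30, 30),
                              path, sidecar = paste0(path, ".missing.tsv")) {
  stopifnot(length(clip) == 2, clip[1] < clip[2])
  lines <- readLines(pdb)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  atom_chain <- substr(lines[is_atom], 22, 22)
  absent <- setdiff(chains$chain, unique(atom_chain))
  if (length(absent) > 0) {
    stop("chain(s) not present in structure: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }

  missing <- list()
  note_missing <- function(ch, resno, su, reason) {
    key <- paste(ch, resno, sep = "\r")
    if (is.null(missing[[key]])) {
      missing[[key]] <<- data.frame(chain = ch, resno = resno, subunit = su,
                                    reason = reason, stringsAsFactors = FALSE)
    }
  }

  atom_idx <- which(is_atom)
  for (j in seq_along(atom_idx)) {
    i <- atom_idx[j]
    line <- lines[i]
    if (nchar(line) < 66) line <- formatC(line, width = -66)
    ch <- substr(line, 22, 22)
    resno <- suppressWarnings(as.integer(substr(line, 23, 26)))
    b <- NA_real_
    row <- match(ch, chains$chain)
    if (is.na(row)) {
      note_missing(ch, resno, NA_character_, "unmapped_chain")
    } else {
      su <- chains$subunit[row]
      pos <- resno + chains$offset[row]
      prof <- profiles[[su]]
      if (is.null(prof)) {
        note_missing(ch, resno, su, "no_profile")
      } else if (is.na(pos) || pos < 1L || pos > prof$length) {
        warning(sprintf(
          "chain %s residue %s maps outside the %s profile; skipped",
          ch, resno, su), call. = FALSE)
        note_missing(ch, resno, su, "position_out_of_range")
      } else if (is.na(prof$values[pos])) {
        note_missing(ch, resno, su, "no_value")
      } else {
        b <- clamp(prof$values[pos], clip[1], clip[2])
      }
    }
    if (is.na(b)) b <- 0
    substr(line, 61, 66) <- sprintf("%6.2f", b)
    lines[i] <- line
  }

  writeLines(lines, path)
  missing_df <- if (length(missing) > 0) {
    do.call(rbind, unname(missing))
  } else {
    data.frame(chain = character(0), resno = integer(0),
               subunit = character(0), reason = character(0))
  }
  if (!is.na(sidecar)) {
    utils::write.table(missing_df, sidecar, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(path = path, missing = missing_df))
}

#' Default paralog remapping of the cBAF structure
#'
#' Paralogs not resolved in the reference complex structure mapped onto the
#' resolved primary paralog, with identity residue numbering: ACTA2 to ACTB,
#' ARID1B to ARID1A, BCL7B/BCL7C to BCL7A, SMARCD2/SMARCD3 to SMARCD1.
#'
#' @return A [paralog_map()].
#' @export
default_paralog_map <- function() {
  paralog_map(
    source = c("ACTA2", "ARID1B", "BCL7B", "BCL7C", "SMARCD2", "SMARCD3"),
    target = c("ACTB", "ARID1A", "BCL7A", "BCL7A", "SMARCD1", "SMARCD1")
  )
}
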