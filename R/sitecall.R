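# Discrete site calling on windowed exposure tracks.
#
# Contiguous runs of same-signed exposure change are merged into discrete
# sites when they fall within a configurable gap of each other (default 20
# aa, the upper bound of the 10-20 aa merging range), provided no
# opposite-signed run intervenes.  Merged sites whose peak |change| falls
# below a noise threshold (default 1%) are discarded.  This replaces a
# manual, by-eye merging step with a deterministic, parameterised algorithm.

#' Call merged sites of exposure change on a windowed track
#'
#' Seeds are maximal runs of contiguous non-missing residues with the same
#' sign of exposure change.  Same-signed seeds separated by at most `gap`
#' residues are merged into one site; missing or zero-valued residues count
#' toward the separation but only an intervening opposite-signed seed whose
#' own peak reaches the noise floor breaks a merge (a sub-noise blip of the
#' opposite sign is noise, not a separating effect, and is itself discarded).
#' Sites whose peak |value| is below `noise` percent are omitted.  These
#' rules make the calling idempotent and the site count non-increasing in
#' both `gap` and `noise`.
#'
#' @param profile An [window_profile()] object, or a named list of them
#'   (results are concatenated).
#' @param gap Maximum separation (residues) between same-signed seeds that
#'   are still merged; the by-eye analysis this replaces used 10-20 aa.
#' @param noise Noise floor in percent: merged sites with
#'   `max |value| < noise` are discarded (default 1).
#' @return Data.frame of merged sites sorted by `(protein_id, start)`:
#'   `protein_id`, `start`, `end`, `sign` (`"gain"`/`"loss"`), `peak_value`
#'   (signed extremum inside the interval), `mean_value` (mean of non-missing
#'   track values inside the interval).
#' @export
call_merged_sites <- function(profile, gap = 20L, noise = 1.0) {
  if (!inherits(profile, "exposure_profile") && is.list(profile)) {
    out <- lapply(profile, call_merged_sites, gap = gap, noise = noise)
    out <- do.call(rbind, out)
    out <- out[order(out$protein_id, out$start), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  stopifnot(inherits(profile, "exposure_profile"), gap >= 0)
  v <- profile$values
  empty <- data.frame(protein_id = character(0), start = integer(0),
                      end = integer(0), sign = character(0),
                      peak_value = numeric(0), mean_value = numeric(0),
                      stringsAsFactors = FALSE)
  if (all(is.na(v))) return(empty)

  state <- rep("gap", length(v))
  state[!is.na(v) & v > 0] <- "gain"
  state[!is.na(v) & v < 0] <- "loss"
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seed <- r$values %in% c("gain", "loss")
  seeds <- data.frame(start = starts[seed], end = ends[seed],
                      sign = r$values[seed], stringsAsFactors = FALSE)
  if (nrow(seeds) == 0) return(empty)

  # signed extremum of each seed's own run; sub-noise opposite-signed seeds
  # are noise blips: they neither merge with nor break a run of the other
  # sign (they surface as singleton sites and are removed by the filter)
  seeds$peak <- vapply(seq_len(nrow(seeds)), function(k) {
    vals <- v[seeds$start[k]:seeds$end[k]]
    vals <- vals[!is.na(vals)]
    vals[which.max(abs(vals))]
  }, numeric(1))

  merged <- seeds[0, , drop = FALSE]
  cur <- seeds[1, , drop = FALSE]
  for (i in seq_len(nrow(seeds))[-1]) {
    s <- seeds[i, , drop = FALSE]
    if (s$sign == cur$sign && s$start - cur$end - 1L <= gap) {
      cur$end <- s$end
    } else if (s$sign != cur$sign && abs(s$peak) < noise) {
      merged <- rbind(merged, s)
    } else {
      merged <- rbind(merged, cur)
      cur <- s
    }
  }
  merged <- rbind(merged, cur)
  merged <- merged[order(merged$start), , drop = FALSE]

  merged$peak_value <- NA_real_
  merged$mean_value <- NA_real_
  for (k in seq_len(nrow(merged))) {
    vals <- v[merged$start[k]:merged$end[k]]
    vals <- vals[!is.na(vals)]
    merged$peak_value[k] <- vals[which.max(abs(vals))]
    merged$mean_value[k] <- mean(vals)
  }
  merged <- merged[abs(merged$peak_value) >= noise, , drop = FALSE]

  out <- data.frame(
    protein_id = rep(profile$protein_id, nrow(merged)),
    start = merged$start, end = merged$end, sign = merged$sign,
    peak_value = merged$peak_value, mean_value = merged$mean_value,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$protein_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify overlap between two merged-site sets
#'
#' A site in `a` overlaps a site in `b` when they lie on the same subunit,
#' share at least one residue, and have the same sign of exposure change
#' (consistent effects).  Every site lands in exactly one bin: overlapped,
#' `a`-exclusive, or `b`-exclusive - the disjoint partition summarised by a
#' Venn diagram.
#'
#' @param a,b Merged-site data.frames from [call_merged_sites()], in the same
#'   subunit coordinate space.
#' @return List with `overlapped_pairs` (data.frame of index pairs `a_idx`,
#'   `b_idx` into the inputs), `a_overlapped`, `b_overlapped`, `a_exclusive`,
#'   `b_exclusive` (row subsets of the inputs), and `counts` (named integer
#'   vector: `a_exclusive`, `overlapped_a`, `overlapped_b`, `b_exclusive`,
#'   `overlapped_pairs`).
#' @export
overlap_sites <- function(a, b) {
  pairs <- expand.grid(a_idx = seq_len(nrow(a)), b_idx = seq_len(nrow(b)))
  if (nrow(pairs) > 0) {
    ok <- a$protein_id[pairs$a_idx] == b$protein_id[pairs$b_idx] &
      a$sign[pairs$a_idx] == b$sign[pairs$b_idx] &
      pmax(a$start[pairs$a_idx], b$start[pairs$b_idx]) <=
        pmin(a$end[pairs$a_idx], b$end[pairs$b_idx])
    pairs <- pairs[ok, , drop = FALSE]
  }
  rownames(pairs) <- NULL
  a_hit <- seq_len(nrow(a)) %in% pairs$a_idx
  b_hit <- seq_len(nrow(b)) %in% pairs$b_idx
  list(
    overlapped_pairs = pairs,
    a_overlapped = a[a_hit, , drop = FALSE],
    b_overlapped = b[b_hit, , drop = FALSE],
    a_exclusive = a[!a_hit, , drop = FALSE],
    b_exclusive = b[!b_hit, , drop = FALSE],
    counts = c(a_exclusive = sum(!a_hit), overlapped_a = sum(a_hit),
               overlapped_b = sum(b_hit), b_exclusive = sum(!b_hit),
               overlapped_pairs = nrow(pairs))
  )
}

#' Distribution of exposure gains and losses across complex modules
#'
#' Filters differential-exposure sites to those with `|delta| >= cutoff`
#' (default 5 percent), tallies gains (`delta > 0`) and losses (`delta < 0`)
#' per module, and reports each (module, direction) cell as a proportion of
#' all retained sites, so the proportions sum to 1 per dataset.
#'
#' @param deltas Data.frame with columns `protein_id` and `delta_percent`
#'   (as from [differential_exposure()]).
#' @param assignment Named character vector mapping every subunit in `deltas`
#'   to a module label (see [default_module_assignment()]), or a data.frame
#'   with columns `subunit`, `module`.
#' @param cutoff Significance cutoff in percent (default 5).
#' @return Data.frame with one row per (module, direction): `module`,
#'   `direction`, `count`, `proportion`.  When no site survives the cutoff,
#'   counts and proportions are zero and a warning is raised.
#' @export
module_distribution <- function(deltas, assignment, cutoff = 5.0) {
  if (is.data.frame(assignment)) {
    assignment <- stats::setNames(assignment$module, assignment$subunit)
  }
  unassigned <- setdiff(unique(deltas$protein_id), names(assignment))
  if (length(unassigned) > 0) {
    stop("no module assignment for subunit(s): ",
         paste(unassigned, collapse = ", "), call. = FALSE)
  }
  modules <- unique(unname(assignment))
  sig <- deltas[abs(deltas$delta_percent) >= cutoff, , drop = FALSE]
  grid <- expand.grid(module = modules, direction = c("gain", "loss"),
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$module, modules), grid$direction), ]
  grid$count <- mapply(function(m, d) {
    in_mod <- assignment[sig$protein_id] == m
    if (d == "gain") sum(in_mod & sig$delta_percent > 0)
    else sum(in_mod & sig$delta_percent < 0)
  }, grid$module, grid$direction)
  total <- sum(grid$count)
  if (total == 0) {
    warning(sprintf("no site passed the %.4g%% cutoff; proportions set to 0",
                    cutoff), call. = FALSE)
    grid$proportion <- 0
  } else {
    grid$proportion <- grid$count / total
  }
  rownames(grid) <- NULL
  grid
}

#' Default Core/ATPase module assignment for cBAF subunits
#'
#' Editable default reflecting the cBAF architecture: the structural core
#' (SMARCC, SMARCD, SMARCB1, SMARCE1, ARID and DPF subunits) versus the
#' ATPase module (SMARCA2/4 with its actin-related and BCL7 partners).
#'
#' @return Named character vector: subunit -> `"Core"` or `"ATPase"`.
#' @export
default_module_assignment <- function() {
  c(
    SMARCC1 = "Core", SMARCC2 = "Core",
    SMARCD1 = "Core", SMARCD2 = "Core", SMARCD3 = "Core",
    SMARCB1 = "Core", SMARCE1 = "Core",
    ARID1A = "Core", ARID1B = "Core", ARID2 = "Core", DPF2 = "Core",
    SMARCA2 = "ATPase", SMARCA4 = "ATPase",
    ACTL6A = "ATPase", ACTB = "ATPase", ACTA2 = "ATPase",
    BCL7A = "ATPase", BCL7B = "ATPase", BCL7C = "ATPase",
    SS18 = "ATPase", SS18L1 = "ATPase"
  )
}
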