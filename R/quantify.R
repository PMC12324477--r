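# Residue-level rollup of peptide-form intensities.
#
# The readout of a covalent-labeling footprinting experiment is, per residue
# and condition, the modification fraction
#
#   % modified = I_modified / (I_modified + I_unmodified) * 100
#
# where I_modified sums the GEE-adduct and hydrolyzed-product channels of all
# peptide species whose label can sit on the residue, and I_unmodified sums
# the unmodified species of all peptides covering it.  Fractions are computed
# per replicate and then averaged; intensities from different peptides
# covering the same site are pooled within a replicate before the ratio is
# taken (XIC-summing).  An ambiguous label (m candidate sites) contributes
# intensity/m to each candidate site, which conserves total modified signal.

# positions (1-based on the subunit) of D/E residues inside a peptide
.de_positions <- function(sequence, peptide_start) {
  idx <- which(strsplit(sequence, "", fixed = TRUE)[[1]] %in% c("D", "E"))
  peptide_start - 1L + idx
}

# Long table of per-site, per-condition, per-replicate summed intensities:
# protein_id, position, residue, condition, replicate, i_mod, i_unmod,
# ambiguous.  Sites are all D/E positions covered by at least one observation.
.site_intensity_table <- function(observations) {
  dt <- data.table::as.data.table(
    observations[, c("protein_id", "peptide_start", "sequence", "condition",
                     "replicate", "form", "intensity")])
  dt$candidate_sites <- observations$candidate_sites

  mod <- dt[form != "unmodified"]
  if (nrow(mod) > 0) {
    m <- lengths(mod$candidate_sites)
    mod_long <- data.table::data.table(
      protein_id = rep(mod$protein_id, m),
      position   = unlist(mod$candidate_sites),
      condition  = rep(mod$condition, m),
      replicate  = rep(mod$replicate, m),
      weight     = rep(mod$intensity / m, m),
      ambiguous  = rep(m > 1L, m)
    )
    imod <- mod_long[, list(i_mod = sum(weight), ambiguous = any(ambiguous)),
                     by = list(protein_id, position, condition, replicate)]
  } else {
    imod <- data.table::data.table(
      protein_id = character(0), position = integer(0),
      condition = character(0), replicate = integer(0),
      i_mod = numeric(0), ambiguous = logical(0))
  }

  un <- dt[form == "unmodified"]
  if (nrow(un) > 0) {
    cov <- mapply(.de_positions, un$sequence, un$peptide_start,
                  SIMPLIFY = FALSE)
    k <- lengths(cov)
    un_long <- data.table::data.table(
      protein_id = rep(un$protein_id, k),
      position   = unlist(cov),
      condition  = rep(un$condition, k),
      replicate  = rep(un$replicate, k),
      intensity  = rep(un$intensity, k)
    )
    iun <- un_long[, list(i_unmod = sum(intensity)),
                   by = list(protein_id, position, condition, replicate)]
  } else {
    iun <- data.table::data.table(
      protein_id = character(0), position = integer(0),
      condition = character(0), replicate = integer(0), i_unmod = numeric(0))
  }

  tab <- merge(imod, iun,
               by = c("protein_id", "position", "condition", "replicate"),
               all = TRUE)
  tab$i_mod[is.na(tab$i_mod)] <- 0
  tab$i_unmod[is.na(tab$i_unmod)] <- 0
  tab$ambiguous[is.na(tab$ambiguous)] <- FALSE

  # residue letter at each site, from any peptide sequence covering it
  res_map <- .residue_letters(observations)
  tab <- merge(tab, res_map, by = c("protein_id", "position"), all.x = TRUE)
  data.table::setorder(tab, protein_id, position, condition, replicate)
  tab
}

# (protein_id, position) -> residue letter, taken from peptide sequences
.residue_letters <- function(observations) {
  pep <- unique(observations[, c("protein_id", "peptide_start", "sequence")])
  rows <- lapply(seq_len(nrow(pep)), function(i) {
    chars <- strsplit(pep$sequence[i], "", fixed = TRUE)[[1]]
    data.table::data.table(
      protein_id = pep$protein_id[i],
      position = pep$peptide_start[i] - 1L + seq_along(chars),
      residue = chars)
  })
  unique(data.table::rbindlist(rows))
}

#' Modification fraction of one residue in one condition/replicate
#'
#' Evaluates `% modified = 100 * I_modified / (I_modified + I_unmodified)`
#' for a single site.  `I_modified` sums the GEE and hydrolyzed channels of
#' every modified observation whose candidate set includes the site, after
#' equal ambiguity splitting (an observation with `m` candidate sites
#' contributes `intensity / m`); `I_unmodified` sums the unmodified forms of
#' every peptide covering the site.  Intensities from different peptides are
#' pooled before the ratio is taken.
#'
#' @param observations Observation data.frame (see [read_quant_table()]).
#' @param protein_id,position Site, 1-based on the subunit sequence.
#' @param condition,replicate Which experiment cell to evaluate.
#' @return Percent in `[0, 100]`, or `NA_real_` when the site has no signal
#'   in that condition/replicate (no coverage: missing, not 0%).
#' @export
modification_fraction <- function(observations, protein_id, position,
                                  condition, replicate) {
  keep <- observations$condition == condition &
    observations$replicate == replicate &
    observations$protein_id == protein_id
  obs <- observations[keep, , drop = FALSE]
  if (nrow(obs) == 0) return(NA_real_)

  modified <- obs$form != "unmodified"
  i_mod <- 0
  for (i in which(modified)) {
    sites <- obs$candidate_sites[[i]]
    if (position %in% sites) i_mod <- i_mod + obs$intensity[i] / length(sites)
  }
  covering <- !modified & obs$peptide_start <= position &
    obs$peptide_end >= position
  i_unmod <- sum(obs$intensity[covering])

  if (i_mod + i_unmod == 0) return(NA_real_)
  100 * i_mod / (i_mod + i_unmod)
}

#' Per-replicate residue modification fractions
#'
#' Rolls a full observation table up to one row per site x condition x
#' replicate.  Replicates in which a site has zero total intensity are
#' dropped (missing, never imputed).
#'
#' @inheritParams modification_fraction
#' @return A data.frame with columns `protein_id`, `position`, `residue`,
#'   `condition`, `replicate`, `percent`, `ambiguous`.
#' @export
fraction_table <- function(observations) {
  tab <- .site_intensity_table(observations)
  tab <- tab[tab$i_mod + tab$i_unmod > 0, ]
  tab$percent <- 100 * tab$i_mod / (tab$i_mod + tab$i_unmod)
  out <- as.data.frame(tab[, c("protein_id", "position", "residue",
                               "condition", "replicate", "percent",
                               "ambiguous")])
  out
}

#' Residue exposure summary per condition
#'
#' Averages per-replicate modification fractions into per-condition mean and
#' SD for every covered D/E site.  The ambiguous flag is set when any
#' contributing modified observation had more than one candidate site.
#'
#' @inheritParams modification_fraction
#' @return A data.frame with one row per site x condition: `protein_id`,
#'   `position`, `residue`, `condition`, `n_replicates`, `mean_percent`,
#'   `sd_percent`, `ambiguous`.
#' @export
residue_exposure <- function(observations) {
  ft <- data.table::as.data.table(fraction_table(observations))
  out <- ft[, list(
    n_replicates = .N,
    mean_percent = mean(percent),
    sd_percent   = stats::sd(percent),
    ambiguous    = any(ambiguous)
  ), by = list(protein_id, position, residue, condition)]
  data.table::setorder(out, protein_id, position, condition)
  as.data.frame(out)
}

#' Differential surface exposure between bound and unbound states
#'
#' For every site quantified in both conditions, computes
#' `delta_percent = mean bound % - mean unbound %` (means over replicates).
#' Negative values indicate reduced surface exposure upon binding
#' (protection: interface burial or conformational change).  Sites covered in
#' only one of the two conditions are excluded with a warning.
#'
#' @param exposure Either a per-condition summary from [residue_exposure()],
#'   or a raw observation table (recognised by its `form` column), in which
#'   case the summary is computed first.
#' @param bound_condition,unbound_condition Condition labels to contrast.
#' @return A data.frame with one row per site: `protein_id`, `position`,
#'   `residue`, `bound_condition`, `delta_percent`, per-condition
#'   mean/SD/n, and the combined `ambiguous` flag.
#' @export
differential_exposure <- function(exposure, bound_condition,
                                  unbound_condition = "unbound") {
  if ("form" %in% names(exposure)) exposure <- residue_exposure(exposure)
  b <- exposure[exposure$condition == bound_condition, ]
  u <- exposure[exposure$condition == unbound_condition, ]
  merged <- merge(b, u, by = c("protein_id", "position", "residue"),
                  suffixes = c("_bound", "_unbound"))
  n_lost <- nrow(b) + nrow(u) - 2L * nrow(merged)
  if (n_lost > 0) {
    warning(sprintf(
      "%d site(s) covered in only one of '%s'/'%s' were excluded",
      n_lost, bound_condition, unbound_condition), call. = FALSE)
  }
  out <- data.frame(
    protein_id      = merged$protein_id,
    position        = merged$position,
    residue         = merged$residue,
    bound_condition = bound_condition,
    delta_percent   = merged$mean_percent_bound - merged$mean_percent_unbound,
    mean_bound      = merged$mean_percent_bound,
    sd_bound        = merged$sd_percent_bound,
    n_bound         = merged$n_replicates_bound,
    mean_unbound    = merged$mean_percent_unbound,
    sd_unbound      = merged$sd_percent_unbound,
    n_unbound       = merged$n_replicates_unbound,
    ambiguous       = merged$ambiguous_bound | merged$ambiguous_unbound,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$protein_id, out$position), ]
  rownames(out) <- NULL
  out
}

#' Write a residue exposure table
#'
#' Tab-separated export of a [differential_exposure()] result.
#'
#' @param exposure Data.frame from [differential_exposure()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_exposure_table <- function(exposure, path) {
  utils::write.table(exposure, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
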