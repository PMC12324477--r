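# Synthetic ground-truth data for every pipeline stage.
#
# The generator emulates the structure of a triplicate labeling experiment:
# subunit sequences are digested in silico (trypsin/Lys-C rule), each peptide
# covering a D/E site yields an unmodified species plus per-site modified
# species split between the GEE-adduct and hydrolyzed-product channels, and
# intensities carry multiplicative lognormal noise.  Site-level modification
# fractions are planted (baseline per site, plus condition-specific deltas at
# chosen sites), so the pipeline's output can be compared against exact
# truth.  Everything is deterministic under the config seed.

#' Random protein-like sequence
#'
#' Draws an amino-acid sequence with a target density of labelable D/E
#' residues and enough K/R for a realistic tryptic digest.  Uses the current
#' RNG state.
#'
#' @param length Sequence length.
#' @param de_density Target combined frequency of D and E (default 0.15).
#' @return Amino-acid string.
#' @export
random_protein_sequence <- function(length, de_density = 0.15) {
  aa <- c("D", "E", "K", "R", "P", "A", "G", "L", "S", "V", "T", "I",
          "N", "Q", "F", "Y", "H", "M", "W", "C")
  rest <- 1 - de_density - 0.06 - 0.06 - 0.04
  prob <- c(de_density / 2, de_density / 2, 0.06, 0.06, 0.04,
            rep(rest / 15, 15))
  paste(sample(aa, length, replace = TRUE, prob = prob), collapse = "")
}

#' In-silico tryptic digest
#'
#' Applies the trypsin/Lys-C cleavage rule (cut after K or R, but not when
#' followed by P) and enumerates peptides with up to `missed_cleavages`
#' missed cleavage sites and length within bounds.  Deterministic; no
#' kinetics are modelled.
#'
#' @param sequence Amino-acid string.
#' @param missed_cleavages Maximum number of missed cleavages (default 2).
#' @param min_length,max_length Peptide length bounds (defaults 6 and 30).
#' @return Data.frame with one row per peptide: `start`, `end` (1-based
#'   inclusive), `sequence`, `missed`.
#' @export
digest <- function(sequence, missed_cleavages = 2L, min_length = 6L,
                   max_length = 30L) {
  stopifnot(nchar(sequence) > 0)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  after <- which(chars %in% c("K", "R"))
  after <- after[after == n | chars[pmin(after + 1L, n)] != "P"]
  bounds <- c(0L, after[after < n], n)
  frag_start <- bounds[-length(bounds)] + 1L
  frag_end <- bounds[-1]
  nfrag <- length(frag_start)
  rows <- list()
  for (i in seq_len(nfrag)) {
    for (mc in 0:missed_cleavages) {
      j <- i + mc
      if (j > nfrag) break
      len <- frag_end[j] - frag_start[i] + 1L
      if (len < min_length || len > max_length) next
      rows[[length(rows) + 1L]] <- data.frame(
        start = frag_start[i], end = frag_end[j],
        sequence = substring(sequence, frag_start[i], frag_end[j]),
        missed = mc, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      sequence = character(0), missed = integer(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end), ]
  rownames(out) <- NULL
  out
}

# nearest D/E position to a target coordinate, restricted to sites covered by
# at least one digest peptide (an uncovered site cannot be quantified, so it
# is not a valid place to plant a change)
.nearest_de <- function(sequence, near, missed_cleavages = 2L,
                        min_length = 6L, max_length = 30L) {
  dg <- digest(sequence, missed_cleavages = missed_cleavages,
               min_length = min_length, max_length = max_length)
  covered <- unique(unlist(mapply(.de_positions, dg$sequence, dg$start,
                                  SIMPLIFY = FALSE)))
  if (length(covered) == 0) {
    stop("no digest-covered D/E site available for planting", call. = FALSE)
  }
  covered <- sort(covered)
  covered[which.min(abs(covered - near))]
}

#' Build a simulation configuration
#'
#' Defines the study conditions of a synthetic labeling experiment.  The
#' default emulates a miniature two-module complex: two core-like subunits
#' (CORE1A with paralog CORE1B, and CORE2) plus one ATPase-like subunit
#' (ATP1); triplicate labeling (`n_replicates = 3`); an unbound state and two
#' bound states (`bound_NCP`, nominal molar ratio 1:5, and `bound_PU1`,
#' 1:8 - ratios recorded as metadata only); per-site baseline modification
#' fractions drawn from 1-60%; three planted protections of -30 points in
#' `bound_PU1` on CORE1A, one of which is shared with `bound_NCP`, plus one
#' planted gain of +30 on ATP1 in `bound_NCP`; 10% multiplicative intensity
#' CV; and ambiguity probability 0.2.  Planted sites draw their baseline from
#' `planted_baseline_range` (default 35-60%) so that a -30-point protection
#' is observable without truncation at 0.
#'
#' @param seed Integer seed; a fixed seed makes all generated artifacts
#'   byte-identical.
#' @param subunits Named character vector of subunit sequences; `NULL` for
#'   the default miniature complex (generated from `seed`).
#' @param paralog_pairs A [paralog_map()]; default maps CORE1B onto CORE1A.
#' @param module_assignment Named vector subunit -> module; default assigns
#'   CORE* to `"Core"` and ATP1 to `"ATPase"`.
#' @param n_replicates Replicates per condition (default 3).
#' @param conditions Condition labels; the first is the unbound reference.
#' @param baseline_range Range of per-site baseline fractions, percent.
#' @param planted_baseline_range Baseline range for planted sites, percent.
#' @param planted_changes Data.frame with columns `protein_id`, `position`,
#'   `delta_percent`, `condition`; `NULL` for the defaults described above.
#'   Positions must be D/E residues.
#' @param noise_cv Multiplicative intensity coefficient of variation.
#' @param ambiguity_prob Probability that a modified observation's candidate
#'   set is all D/E residues of its peptide (when it has more than one).
#' @param missed_cleavages,peptide_length Digest parameters.
#' @param abundance_meanlog,abundance_sdlog Lognormal peptide abundance.
#' @return A `simulation_config` object (list).
#' @export
simulation_config <- function(seed = 11L,
                              subunits = NULL,
                              paralog_pairs = NULL,
                              module_assignment = NULL,
                              n_replicates = 3L,
                              conditions = c("unbound", "bound_NCP",
                                             "bound_PU1"),
                              baseline_range = c(1, 60),
                              planted_baseline_range = c(35, 60),
                              planted_changes = NULL,
                              noise_cv = 0.10,
                              ambiguity_prob = 0.2,
                              missed_cleavages = 2L,
                              peptide_length = c(6L, 30L),
                              abundance_meanlog = log(1e6),
                              abundance_sdlog = 0.5) {
  set.seed(seed)
  if (is.null(subunits)) {
    core1a <- random_protein_sequence(300L)
    subunits <- c(
      CORE1A = core1a,
      CORE1B = .mutate_paralog(core1a, rate = 0.2),
      CORE2 = random_protein_sequence(250L),
      ATP1 = random_protein_sequence(400L)
    )
    if (is.null(paralog_pairs)) {
      paralog_pairs <- paralog_map(source = "CORE1B", target = "CORE1A")
    }
    if (is.null(module_assignment)) {
      module_assignment <- c(CORE1A = "Core", CORE1B = "Core",
                             CORE2 = "Core", ATP1 = "ATPase")
    }
  }
  if (is.null(paralog_pairs)) paralog_pairs <- paralog_map()
  if (is.null(module_assignment)) {
    module_assignment <- stats::setNames(rep("Core", length(subunits)),
                                         names(subunits))
  }
  if (is.null(planted_changes)) {
    pu1_sites <- vapply(c(60, 150, 240), function(near) {
      .nearest_de(subunits[["CORE1A"]], near, missed_cleavages,
                  peptide_length[1], peptide_length[2])
    }, integer(1))
    ncp_core <- pu1_sites[2]
    ncp_atp <- .nearest_de(subunits[["ATP1"]], 200, missed_cleavages,
                           peptide_length[1], peptide_length[2])
    planted_changes <- data.frame(
      protein_id = c(rep("CORE1A", 3), "CORE1A", "ATP1"),
      position = c(pu1_sites, ncp_core, ncp_atp),
      delta_percent = c(-30, -30, -30, -30, 30),
      condition = c(rep("bound_PU1", 3), "bound_NCP", "bound_NCP"),
      stringsAsFactors = FALSE
    )
  }
  # planted positions must be labelable
  for (i in seq_len(nrow(planted_changes))) {
    su <- planted_changes$protein_id[i]
    pos <- planted_changes$position[i]
    letter <- substring(subunits[[su]], pos, pos)
    if (!letter %in% c("D", "E")) {
      stop(sprintf("planted position %s:%d is '%s', not a D/E residue",
                   su, pos, letter), call. = FALSE)
    }
    if (!planted_changes$condition[i] %in% conditions[-1]) {
      stop("planted changes must target a bound condition", call. = FALSE)
    }
  }
  stopifnot(ambiguity_prob >= 0, ambiguity_prob <= 1, n_replicates >= 1)
  structure(list(
    seed = as.integer(seed), subunits = subunits,
    paralog_pairs = paralog_pairs, module_assignment = module_assignment,
    n_replicates = as.integer(n_replicates), conditions = conditions,
    baseline_range = baseline_range,
    planted_baseline_range = planted_baseline_range,
    planted_changes = planted_changes, noise_cv = noise_cv,
    ambiguity_prob = ambiguity_prob,
    missed_cleavages = as.integer(missed_cleavages),
    peptide_length = as.integer(peptide_length),
    abundance_meanlog = abundance_meanlog,
    abundance_sdlog = abundance_sdlog,
    metadata = list(molar_ratio = c(bound_NCP = "1:5", bound_PU1 = "1:8"),
                    labeling = c(complex_nM = 250, GEE_mM = 20, EDC_mM = 1))
  ), class = "simulation_config")
}

# paralog copy: substitute a fraction of positions, preserving D/E (shared
# label sites), K/R (digest pattern) and P
.mutate_paralog <- function(sequence, rate = 0.2) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  fixed <- chars %in% c("D", "E", "K", "R", "P")
  editable <- which(!fixed)
  n_sub <- floor(length(editable) * rate)
  idx <- sample(editable, n_sub)
  pool <- c("A", "G", "L", "S", "V", "T", "I", "N", "Q", "F", "Y", "H",
            "M", "W", "C")
  chars[idx] <- sample(pool, n_sub, replace = TRUE)
  paste(chars, collapse = "")
}

#' Simulate a quantification experiment with known truth
#'
#' Generates the peptide-level quant table a labeling experiment would
#' produce under the configured conditions, together with the exact truth
#' table it was generated from.  Each peptide species draws one lognormal
#' unmodified abundance `U` (a property of the digest, held fixed across
#' replicates and conditions); each D/E site `s` with true
#' fraction `f_s` contributes a modified species of intensity
#' `U * f_s / (100 - f_s)` (so that the modification-fraction formula
#' recovers `f_s` exactly in the noise-free case), split uniformly between
#' the GEE and hydrolyzed channels; every intensity is multiplied by
#' lognormal noise with the configured CV.  With probability
#' `ambiguity_prob`, a modified observation's candidate set is widened to all
#' D/E residues of its peptide.
#'
#' @param config A [simulation_config()].
#' @return List with `observations` (quant table, see [read_quant_table()]),
#'   `truth` (per site x condition: `protein_id`, `position`, `residue`,
#'   `condition`, `true_fraction`, `true_delta`), and `config`.
#' @export
simulate_quant <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cv <- config$noise_cv
  sdlog_noise <- sqrt(log(1 + cv^2))
  noise <- function() {
    if (cv <= 0) 1 else stats::rlnorm(1, -sdlog_noise^2 / 2, sdlog_noise)
  }

  # per-site baselines, then per-condition truth
  site_rows <- list()
  for (su in names(config$subunits)) {
    de <- .de_positions(config$subunits[[su]], 1L)
    if (length(de) == 0) next
    base <- stats::runif(length(de), config$baseline_range[1],
                         config$baseline_range[2])
    site_rows[[su]] <- data.frame(
      protein_id = su, position = de,
      residue = substring(config$subunits[[su]], de, de),
      baseline = base, stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, site_rows)
  rownames(sites) <- NULL
  planted <- config$planted_changes
  planted_key <- unique(paste(planted$protein_id, planted$position))
  for (key in planted_key) {
    i <- which(paste(sites$protein_id, sites$position) == key)
    sites$baseline[i] <- stats::runif(1, config$planted_baseline_range[1],
                                      config$planted_baseline_range[2])
  }

  truth <- do.call(rbind, lapply(config$conditions, function(cond) {
    f <- sites$baseline
    hit <- planted[planted$condition == cond, , drop = FALSE]
    if (nrow(hit) > 0) {
      idx <- match(paste(hit$protein_id, hit$position),
                   paste(sites$protein_id, sites$position))
      f[idx] <- clamp(f[idx] + hit$delta_percent, 0, 99)
    }
    data.frame(protein_id = sites$protein_id, position = sites$position,
               residue = sites$residue, condition = cond, true_fraction = f,
               stringsAsFactors = FALSE)
  }))
  unb <- truth[truth$condition == config$conditions[1], ]
  truth$true_delta <- truth$true_fraction -
    unb$true_fraction[match(paste(truth$protein_id, truth$position),
                            paste(unb$protein_id, unb$position))]
  rownames(truth) <- NULL

  frac_lookup <- stats::setNames(
    truth$true_fraction,
    paste(truth$protein_id, truth$position, truth$condition, sep = ":"))
  frac_of <- function(su, pos, cond) {
    frac_lookup[[paste(su, pos, cond, sep = ":")]]
  }

  digests <- lapply(config$subunits, digest,
                    missed_cleavages = config$missed_cleavages,
                    min_length = config$peptide_length[1],
                    max_length = config$peptide_length[2])

  # Peptide-species properties are drawn once and held fixed across
  # replicates and conditions: the species abundance (set by the digest and
  # the sample, with the noise CV as the only per-observation variation) and
  # the localization ambiguity of each site (set by the species'
  # fragmentation behaviour, not by the run).
  amb_flag <- new.env(parent = emptyenv())
  abundance <- new.env(parent = emptyenv())
  for (su in names(config$subunits)) {
    dg <- digests[[su]]
    for (pi in seq_len(nrow(dg))) {
      de <- .de_positions(dg$sequence[pi], dg$start[pi])
      if (length(de) == 0) next
      assign(paste(su, pi, sep = ":"),
             stats::rlnorm(1, config$abundance_meanlog,
                           config$abundance_sdlog), envir = abundance)
      if (length(de) < 2) next
      for (s in de) {
        assign(paste(su, pi, s, sep = ":"),
               stats::runif(1) < config$ambiguity_prob, envir = amb_flag)
      }
    }
  }

  rows <- list()
  emit <- function(su, pep, cond, rep_i, form, sites_vec, intensity) {
    rows[[length(rows) + 1L]] <<- list(
      protein_id = su, peptide_start = pep$start, peptide_end = pep$end,
      sequence = pep$sequence, condition = cond, replicate = rep_i,
      form = form, candidate_sites = list(sites_vec), intensity = intensity)
  }

  for (cond in config$conditions) {
    for (rep_i in seq_len(config$n_replicates)) {
      for (su in names(config$subunits)) {
        dg <- digests[[su]]
        for (pi in seq_len(nrow(dg))) {
          pep <- dg[pi, ]
          de <- .de_positions(pep$sequence, pep$start)
          if (length(de) == 0) next
          u_int <- get(paste(su, pi, sep = ":"), envir = abundance)
          emit(su, pep, cond, rep_i, "unmodified", integer(0),
               u_int * noise())
          for (s in de) {
            f <- frac_of(su, s, cond)
            if (f <= 0) next
            i_mod <- u_int * f / (100 - f) * noise()
            amb <- length(de) > 1 &&
              get(paste(su, pi, s, sep = ":"), envir = amb_flag)
            cand <- if (amb) de else s
            share <- stats::runif(1)
            emit(su, pep, cond, rep_i, "GEE", cand, i_mod * share)
            emit(su, pep, cond, rep_i, "hydrolyzed", cand,
                 i_mod * (1 - share))
          }
        }
      }
    }
  }

  observations <- data.frame(
    protein_id = vapply(rows, `[[`, character(1), "protein_id"),
    peptide_start = vapply(rows, `[[`, integer(1), "peptide_start"),
    peptide_end = vapply(rows, `[[`, integer(1), "peptide_end"),
    sequence = vapply(rows, `[[`, character(1), "sequence"),
    condition = vapply(rows, `[[`, character(1), "condition"),
    replicate = vapply(rows, `[[`, integer(1), "replicate"),
    form = vapply(rows, `[[`, character(1), "form"),
    intensity = vapply(rows, `[[`, numeric(1), "intensity"),
    stringsAsFactors = FALSE
  )
  observations$candidate_sites <- lapply(rows, function(r) {
    r$candidate_sites[[1]]
  })
  observations <- observations[, .quant_columns]

  list(observations = observations, truth = truth, config = config)
}

#' Simulate tiled contact predictions with planted hot residues
#'
#' Builds one contact matrix per k-mer tile of a region: rows for planted
#' residues draw their pocket contact probabilities from a Beta distribution
#' centered on `p_hot`, all other rows around `p_bg`.  Deterministic under
#' `seed`.
#'
#' @param tf_length Full sequence length (metadata; tiles never exceed
#'   `region`).
#' @param region `c(start, end)` of the tiled region on the full sequence.
#' @param k Tile length (default 10).
#' @param planted_residues Positions (within `region`) of high-contact
#'   residues.
#' @param p_hot,p_bg Mean contact probability at planted and background
#'   residues (defaults 0.8 and 0.01).
#' @param concentration Beta concentration parameter controlling jitter
#'   (default 50).
#' @param pocket Receptor residue labels for the matrix columns.
#' @param seed Integer seed.
#' @return List of [tiling_prediction()] objects, one per tile.
#' @export
simulate_contacts <- function(tf_length, region, k = 10L, planted_residues,
                              p_hot = 0.8, p_bg = 0.01, concentration = 50,
                              pocket = swift_pocket_residues(), seed = 1L) {
  stopifnot(region[2] <= tf_length,
            all(planted_residues >= region[1] &
                  planted_residues <= region[2]))
  set.seed(seed)
  starts <- seq.int(region[1], region[2] - k + 1L)
  lapply(starts, function(st) {
    mat <- matrix(NA_real_, nrow = k, ncol = length(pocket))
    for (i in seq_len(k)) {
      pos <- st + i - 1L
      p <- if (pos %in% planted_residues) p_hot else p_bg
      mat[i, ] <- stats::rbeta(length(pocket), p * concentration,
                               (1 - p) * concentration)
    }
    tiling_prediction(st, st + k - 1L, mat, pocket)
  })
}

#' Write a synthetic C-alpha trace PDB file
#'
#' Builds a minimal multi-chain structure (one CA atom per residue, poly-Ala,
#' dummy helical coordinates) in the fixed-column PDB dialect, for exercising
#' B-factor export.  The file is labelled synthetic in its header.
#'
#' @param chains Named integer vector: chain id -> residue count.
#' @param path Output file path.
#' @param first_resno First residue number of each chain (default 1).
#' @return `path`, invisibly.
#' @export
make_toy_pdb <- function(chains, path, first_resno = 1L) {
  lines <- c("HEADER    SYNTHETIC TOY STRUCTURE",
             "REMARK 999 GENERATED BY CLFOOTPRINT FOR TESTING")
  serial <- 0L
  for (ch in names(chains)) {
    for (r in seq_len(chains[[ch]])) {
      serial <- serial + 1L
      resno <- first_resno + r - 1L
      x <- 1.5 * r
      y <- 2.3 * cos(r / 3)
      z <- 2.3 * sin(r / 3)
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  ALA %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        serial, ch, resno, x, y, z, 1.00, 0.00))
    }
    lines <- c(lines, sprintf("TER   %5d      ALA %1s%4d", serial + 1L, ch,
                              first_resno + chains[[ch]] - 1L))
    serial <- serial + 1L
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}
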