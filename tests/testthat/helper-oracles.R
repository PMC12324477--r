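# Fixture builders and independent brute-force oracles.  The oracles are
# deliberately written as naive per-element loops, independent of the package
# implementation paths they check.

# one observation row (candidate sites as a list column)
obs_row <- function(protein_id, start, sequence, condition, replicate, form,
                    sites = integer(0), intensity) {
  data.frame(
    protein_id = protein_id, peptide_start = start,
    peptide_end = start + nchar(sequence) - 1L, sequence = sequence,
    condition = condition, replicate = as.integer(replicate), form = form,
    candidate_sites = I(list(as.integer(sites))), intensity = intensity,
    stringsAsFactors = FALSE
  )
}

obs_table <- function(...) {
  out <- do.call(rbind, list(...))
  rownames(out) <- NULL
  out
}

# brute-force %modified: loop over rows, no pooling shortcuts
oracle_fraction <- function(observations, protein_id, position, condition,
                            replicate) {
  i_mod <- 0
  i_unmod <- 0
  for (i in seq_len(nrow(observations))) {
    o <- observations[i, ]
    if (o$protein_id != protein_id || o$condition != condition ||
        o$replicate != replicate) next
    sites <- observations$candidate_sites[[i]]
    if (o$form == "unmodified") {
      if (o$peptide_start <= position && o$peptide_end >= position) {
        i_unmod <- i_unmod + o$intensity
      }
    } else if (position %in% sites) {
      i_mod <- i_mod + o$intensity / length(sites)
    }
  }
  if (i_mod + i_unmod == 0) return(NA_real_)
  100 * i_mod / (i_mod + i_unmod)
}

# brute-force windowed profile: for every residue, enumerate covering labels
oracle_window <- function(labels, sequence_length, window = 11L) {
  h <- (window - 1L) %/% 2L
  vapply(seq_len(sequence_length), function(r) {
    covering <- abs(labels$position - r) <= h
    if (!any(covering)) return(NA_real_)
    mean(labels$delta[covering])
  }, numeric(1))
}

# brute-force all-pairs overlap classification
oracle_overlap <- function(a, b) {
  pairs <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$protein_id[i] == b$protein_id[j] &&
          a$sign[i] == b$sign[j] &&
          max(a$start[i], b$start[j]) <= min(a$end[i], b$end[j])) {
        pairs[[length(pairs) + 1L]] <- c(i, j)
      }
    }
  }
  a_hit <- unique(vapply(pairs, `[`, numeric(1), 1))
  b_hit <- unique(vapply(pairs, `[`, numeric(1), 2))
  list(n_pairs = length(pairs), a_hit = sort(a_hit), b_hit = sort(b_hit))
}

# brute-force contact aggregation: per-residue score lists assembled by loops
oracle_aggregate <- function(predictions, pocket, epsilon = 1e-6) {
  acc <- list()
  for (p in predictions) {
    for (i in seq_len(nrow(p$contact_matrix))) {
      pos <- as.character(p$peptide_start + i - 1L)
      vals <- p$contact_matrix[i, pocket]
      score <- log2(max(mean(vals), epsilon))
      acc[[pos]] <- c(acc[[pos]], score)
    }
  }
  positions <- sort(as.integer(names(acc)))
  data.frame(
    position = positions,
    score = vapply(as.character(positions), function(k) mean(acc[[k]]),
                   numeric(1)),
    n_predictions = vapply(as.character(positions), function(k) {
      length(acc[[k]])
    }, integer(1))
  )
}

# random merged-site list on a handful of subunits
random_sites <- function(n, proteins = c("SU1", "SU2", "SU3"),
                         max_pos = 400L) {
  start <- sample.int(max_pos - 30L, n, replace = TRUE)
  data.frame(
    protein_id = sample(proteins, n, replace = TRUE),
    start = start,
    end = start + sample.int(30L, n, replace = TRUE),
    sign = sample(c("gain", "loss"), n, replace = TRUE),
    peak_value = stats::runif(n, 1, 40) *
      ifelse(sample(c(TRUE, FALSE), n, replace = TRUE), 1, -1),
    stringsAsFactors = FALSE
  )
}

# random label set for window-profile property tests
random_labels <- function(n, sequence_length) {
  data.frame(
    position = sample.int(sequence_length, n, replace = TRUE),
    delta = round(stats::runif(n, -40, 40), 2)
  )
}

# small two-subunit config for fast quantify tests
small_config <- function(seed = 3L, ...) {
  set.seed(seed + 100L)
  subs <- c(SU1 = random_protein_sequence(120L),
            SU2 = random_protein_sequence(100L))
  planted <- data.frame(
    protein_id = "SU1",
    position = .nearest_de_test(subs[["SU1"]], 60),
    delta_percent = -30, condition = "bound",
    stringsAsFactors = FALSE
  )
  simulation_config(
    seed = seed, subunits = subs,
    conditions = c("unbound", "bound"), planted_changes = planted, ...)
}

.nearest_de_test <- function(sequence, near) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  de <- which(chars %in% c("D", "E"))
  de[which.min(abs(de - near))]
}

# reconstruct an exposure_profile directly from a value track
profile_from_track <- function(values, protein_id = "SU1") {
  structure(
    list(protein_id = protein_id, length = length(values), values = values,
         window = 11L,
         labels = data.frame(position = integer(0), delta = numeric(0))),
    class = "exposure_profile"
  )
}
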