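test_that("modification fraction follows the intensity-ratio formula", {
  obs <- obs_table(
    obs_row("SU1", 10, "AAEDKA", "unbound", 1, "unmodified", , 75),
    obs_row("SU1", 10, "AAEDKA", "unbound", 1, "GEE", 12, 25)
  )
  expect_equal(modification_fraction(obs, "SU1", 12, "unbound", 1), 25.0)

  # no modified observation at the site -> 0%, not missing
  obs0 <- obs_row("SU1", 10, "AAEDKA", "unbound", 1, "unmodified", , 500)
  expect_equal(modification_fraction(obs0, "SU1", 12, "unbound", 1), 0.0)

  # GEE and hydrolyzed channels sum into the numerator
  obs2 <- obs_table(
    obs_row("SU1", 10, "AAEDKA", "unbound", 1, "unmodified", , 80),
    obs_row("SU1", 10, "AAEDKA", "unbound", 1, "GEE", 12, 10),
    obs_row("SU1", 10, "AAEDKA", "unbound", 1, "hydrolyzed", 12, 10)
  )
  expect_equal(modification_fraction(obs2, "SU1", 12, "unbound", 1), 20.0)
  expect_equal(modification_fraction(obs2, "SU1", 12, "unbound", 1),
               oracle_fraction(obs2, "SU1", 12, "unbound", 1))

  # no coverage at all -> missing, not 0
  expect_true(is.na(modification_fraction(obs2, "SU1", 12, "bound", 1)))
  expect_true(is.na(modification_fraction(obs2, "SU2", 12, "unbound", 1)))
})

test_that("ambiguous labels split intensity equally and conserve mass", {
  obs <- obs_table(
    obs_row("SU1", 10, "AAEDKA", "unbound", 1, "unmodified", , 90),
    obs_row("SU1", 10, "AAEDKA", "unbound", 1, "GEE", c(12, 13), 30)
  )
  f12 <- modification_fraction(obs, "SU1", 12, "unbound", 1)
  f13 <- modification_fraction(obs, "SU1", 13, "unbound", 1)
  # each candidate receives intensity/2 = 15 -> 15/(15+90)
  expect_equal(f12, 100 * 15 / 105)
  expect_equal(f12, f13)
  # mass conservation: assigned weights sum to the observation's intensity
  ft <- fraction_table(obs)
  tab <- clfootprint:::.site_intensity_table(obs)
  expect_equal(sum(tab$i_mod), 30)
  expect_true(all(ft$ambiguous))
})

test_that("intensities pool across peptides within a replicate", {
  # two peptides cover site 12 with very different abundances; pooling
  # (sum/sum) differs from averaging per-peptide fractions
  obs <- obs_table(
    obs_row("SU1", 10, "AAEDKA", "unbound", 1, "unmodified", , 900),
    obs_row("SU1", 10, "AAEDKA", "unbound", 1, "GEE", 12, 100),
    obs_row("SU1", 8, "KAAAEDK", "unbound", 1, "unmodified", , 10),
    obs_row("SU1", 8, "KAAAEDK", "unbound", 1, "GEE", 12, 90)
  )
  pooled <- 100 * (100 + 90) / (100 + 90 + 900 + 10)
  expect_equal(modification_fraction(obs, "SU1", 12, "unbound", 1), pooled)
  expect_false(isTRUE(all.equal(pooled, mean(c(10, 90)))))
})

test_that("fractions are bounded and invariant to per-replicate scaling", {
  cfg <- small_config(seed = 5)
  sim <- simulate_quant(cfg)
  ft <- fraction_table(sim$observations)
  expect_true(all(ft$percent >= 0 & ft$percent <= 100))

  scaled <- sim$observations
  sel <- scaled$replicate == 2L
  scaled$intensity[sel] <- scaled$intensity[sel] * 3.7
  expect_equal(fraction_table(scaled)$percent, ft$percent)

  d <- suppressWarnings(
    differential_exposure(sim$observations, "bound", "unbound"))
  expect_true(all(d$delta_percent >= -100 & d$delta_percent <= 100))
})

test_that("differential exposure is the difference of replicate means", {
  rows <- list()
  for (r in 1:3) {
    fb <- c(10, 12, 8)[r]
    fu <- c(40, 41, 39)[r]
    rows <- c(rows, list(
      obs_row("SU1", 10, "AAEDKA", "bound", r, "unmodified", , 100 - fb),
      obs_row("SU1", 10, "AAEDKA", "bound", r, "GEE", 12, fb),
      obs_row("SU1", 10, "AAEDKA", "unbound", r, "unmodified", , 100 - fu),
      obs_row("SU1", 10, "AAEDKA", "unbound", r, "GEE", 12, fu)
    ))
  }
  obs <- do.call(obs_table, rows)
  d <- differential_exposure(obs, "bound", "unbound")
  d12 <- d[d$position == 12L, ]
  expect_equal(d12$delta_percent, -30.0)
  expect_equal(d12$mean_unbound, 40.0)
  expect_equal(d12$n_bound, 3L)
  # the covered but never-modified neighbour D13 sits at 0% in both states
  expect_equal(d$delta_percent[d$position == 13L], 0.0)

  # identical condition contrasted with itself is zero everywhere
  d0 <- differential_exposure(obs, "unbound", "unbound")
  expect_true(all(d0$delta_percent == 0))

  # a site quantified in only one condition is excluded with a warning
  extra <- rbind(obs, obs_row("SU1", 20, "GGDAK", "bound", 1,
                              "unmodified", , 50))
  expect_warning(d1 <- differential_exposure(extra, "bound", "unbound"),
                 "excluded")
  expect_false(22 %in% d1$position)
})

test_that("noise-free unambiguous synthetic data is recovered exactly", {
  cfg <- small_config(seed = 9, noise_cv = 0, ambiguity_prob = 0)
  sim <- simulate_quant(cfg)
  ft <- fraction_table(sim$observations)
  truth_key <- paste(sim$truth$protein_id, sim$truth$position,
                     sim$truth$condition)
  truth_frac <- sim$truth$true_fraction[
    match(paste(ft$protein_id, ft$position, ft$condition), truth_key)]
  expect_equal(ft$percent, truth_frac, tolerance = 1e-12)

  d <- suppressWarnings(
    differential_exposure(sim$observations, "bound", "unbound"))
  tr_b <- sim$truth[sim$truth$condition == "bound", ]
  td <- tr_b$true_delta[match(paste(d$protein_id, d$position),
                              paste(tr_b$protein_id, tr_b$position))]
  expect_equal(d$delta_percent, td, tolerance = 1e-12)
})

test_that("planted -30 deltas are recovered within 5 points under 10% noise", {
  cfg <- simulation_config(seed = 11, ambiguity_prob = 0)
  sim <- simulate_quant(cfg)
  d <- suppressWarnings(
    differential_exposure(sim$observations, "bound_PU1", "unbound"))
  planted <- cfg$planted_changes[cfg$planted_changes$condition == "bound_PU1", ]
  rec <- d$delta_percent[match(paste(planted$protein_id, planted$position),
                               paste(d$protein_id, d$position))]
  expect_equal(length(rec), 3L)
  expect_true(all(abs(rec - planted$delta_percent) <= 5))
})
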