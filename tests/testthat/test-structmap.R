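test_that("ambiguous labels split into one observation per candidate site", {
  lab <- data.frame(delta = -12.0)
  lab$candidate_sites <- list(c(120L))
  expect_equal(split_ambiguous(lab),
               data.frame(position = 120L, delta = -12.0))

  lab2 <- data.frame(delta = -12.0)
  lab2$candidate_sites <- list(c(120L, 124L))
  out <- split_ambiguous(lab2)
  expect_equal(out$position, c(120L, 124L))
  expect_equal(out$delta, c(-12.0, -12.0))  # same delta, not divided

  # output count equals summed candidate multiplicity
  set.seed(42)
  n <- 50
  cand <- lapply(seq_len(n), function(i) {
    sort(sample.int(200L, sample(1:3, 1)))
  })
  lab3 <- data.frame(delta = stats::runif(n, -40, 40))
  lab3$candidate_sites <- cand
  expect_equal(nrow(split_ambiguous(lab3)), sum(lengths(cand)))

  bad <- data.frame(delta = 1)
  bad$candidate_sites <- list(integer(0))
  expect_error(split_ambiguous(bad), "empty candidate")
})

test_that("window profiles average overlapping 11-aa windows per residue", {
  # single label paints an 11-aa window, everything else missing
  p1 <- window_profile(data.frame(position = 100L, delta = -20), 300L)
  expect_true(all(p1$values[95:105] == -20))
  expect_true(all(is.na(p1$values[-(95:105)])))

  # overlapping windows: double-covered span takes the mean
  p2 <- window_profile(
    data.frame(position = c(100L, 104L), delta = c(-20, 10)), 300L)
  expect_true(all(p2$values[99:105] == -5))
  expect_true(all(p2$values[95:98] == -20))
  expect_true(all(p2$values[106:109] == 10))
  expect_equal(p2$values, oracle_window(p2$labels, 300L), tolerance = 1e-12)

  # windows truncate at chain ends
  p3 <- window_profile(data.frame(position = 3L, delta = 7), 50L)
  expect_true(all(!is.na(p3$values[1:8])))
  expect_true(all(is.na(p3$values[9:50])))

  expect_error(window_profile(data.frame(position = 1L, delta = 1), 10L,
                              window = 10L), "odd")
  expect_error(window_profile(data.frame(position = 11L, delta = 1), 10L),
               "outside")
})

test_that("window profiles match the brute-force per-residue oracle", {
  set.seed(7)
  for (i in 1:25) {
    len <- sample(100:500, 1)
    labels <- random_labels(sample(1:60, 1), len)
    prof <- window_profile(labels, len)
    expect_equal(prof$values, oracle_window(labels, len), tolerance = 1e-12)
  }
})

test_that("paralog labels remap onto the primary subunit and pool", {
  lab <- data.frame(protein_id = "SMARCD2", position = 289L, delta = -37.18,
                    stringsAsFactors = FALSE)
  out <- remap_paralogs(lab, default_paralog_map())
  expect_equal(out$protein_id, "SMARCD1")
  expect_equal(out$position, 289L)
  expect_equal(out$delta, -37.18)

  # empty map is the identity
  expect_identical(remap_paralogs(lab, paralog_map()), lab)

  # pooled paralog labels at one position average over the shared window
  both <- data.frame(protein_id = c("SMARCD1", "SMARCD2"),
                     position = c(289L, 289L), delta = c(-10, -30),
                     stringsAsFactors = FALSE)
  pooled <- remap_paralogs(both, default_paralog_map())
  prof <- window_profile(pooled[, c("position", "delta")], 500L,
                         protein_id = "SMARCD1")
  expect_true(all(prof$values[284:294] == -20))

  # identity remap of a single paralog equals windowing alone
  one <- data.frame(protein_id = "SMARCD1", position = 100L, delta = -15,
                    stringsAsFactors = FALSE)
  pr_direct <- window_profile(one[, c("position", "delta")], 400L)
  pr_remap <- window_profile(
    remap_paralogs(one, default_paralog_map())[, c("position", "delta")],
    400L)
  expect_identical(pr_direct$values, pr_remap$values)

  # explicit position tables translate, unmapped positions drop with warning
  pm <- paralog_map("P2", "P1", position_maps = list(
    P2 = data.frame(source_pos = c(10L, 20L), target_pos = c(15L, 25L))))
  lab2 <- data.frame(protein_id = "P2", position = c(10L, 33L),
                     delta = c(1, 2), stringsAsFactors = FALSE)
  expect_warning(out2 <- remap_paralogs(lab2, pm), "dropped")
  expect_equal(out2$position, 15L)
  expect_equal(out2$protein_id, "P1")
})

test_that("schematic profiles stay paralog-specific", {
  labels <- data.frame(
    protein_id = c("SMARCD1", "SMARCD2"),
    position = c(100L, 200L), delta = c(-20, 25),
    stringsAsFactors = FALSE)
  lens <- c(SMARCD1 = 500L, SMARCD2 = 500L)

  schematic <- subunit_schematic_profile(labels, lens)
  expect_equal(schematic$SMARCD2$values[200], 25)
  expect_true(is.na(schematic$SMARCD1$values[200]))

  # with remapping, the SMARCD2 signal moves onto SMARCD1 instead
  remapped <- remap_paralogs(labels, default_paralog_map())
  expect_false("SMARCD2" %in% remapped$protein_id)
  prof <- window_profile(
    remapped[remapped$protein_id == "SMARCD1", c("position", "delta")],
    500L, protein_id = "SMARCD1")
  expect_equal(prof$values[200], 25)

  # single-subunit input degenerates to window_profile
  single <- labels[1, ]
  s1 <- subunit_schematic_profile(single, lens["SMARCD1"])
  expect_identical(
    s1$SMARCD1$values,
    window_profile(single[, c("position", "delta")], 500L)$values)
})

test_that("B-factor export clips, round-trips, and byte-preserves the rest", {
  skip_if_not_installed("bio3d")
  pdb_in <- withr::local_tempfile(fileext = ".pdb")
  pdb_out <- withr::local_tempfile(fileext = ".pdb")
  make_toy_pdb(c(A = 120L, B = 80L, C = 60L), pdb_in)

  labels_a <- data.frame(position = c(30L, 60L, 90L),
                         delta = c(-45, 12.34, 28.6))
  labels_b <- data.frame(position = 40L, delta = 55)
  profs <- list(SUA = window_profile(labels_a, 120L, protein_id = "SUA"),
                SUB = window_profile(labels_b, 80L, protein_id = "SUB"))
  cm <- chain_map(c("A", "B"), c("SUA", "SUB"))

  res <- write_bfactor_pdb(pdb_in, profs, cm, path = pdb_out, sidecar = NA)
  parsed <- bio3d::read.pdb(pdb_out)
  atoms <- parsed$atom[parsed$atom$type == "ATOM", ]

  b_of <- function(ch, resno) atoms$b[atoms$chain == ch &
                                        atoms$resno == resno]
  # clipped at the -30 floor and +30 ceiling
  expect_equal(b_of("A", 30), -30.00)
  expect_equal(b_of("B", 40), 30.00)
  # in-range values round-trip at 2-decimal precision
  expect_equal(b_of("A", 60), 12.34)
  expect_equal(b_of("A", 90), 28.60)
  # full mapped-chain round trip equals the clamped profile at 2 decimals
  for (r in 1:120) {
    want <- profs$SUA$values[r]
    want <- if (is.na(want)) 0 else round(pmin(pmax(want, -30), 30), 2)
    expect_equal(b_of("A", r), want)
  }
  # unmapped chain gets the sentinel and shows up in the report
  expect_true(all(atoms$b[atoms$chain == "C"] == 0))
  expect_true(any(res$missing$reason == "unmapped_chain"))
  expect_true(any(res$missing$reason == "no_value"))

  # everything outside the B-factor column is byte-identical
  strip_b <- function(lines) {
    atom <- grepl("^(ATOM  |HETATM)", lines)
    lines[atom] <- paste0(substr(lines[atom], 1, 60),
                          substr(lines[atom], 67, nchar(lines[atom])))
    lines
  }
  expect_identical(strip_b(readLines(pdb_in)), strip_b(readLines(pdb_out)))

  expect_error(
    write_bfactor_pdb(pdb_in, profs, chain_map("Z", "SUA"), path = pdb_out),
    "chain.*Z")
})
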