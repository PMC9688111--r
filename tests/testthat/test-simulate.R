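test_that("configuration validation catches bad blueprints and motifs", {
  expect_error(simulation_config(n_taxa = 2), "at least 3")
  bad_blocks <- default_blueprint()
  bad_blocks$indel_rate[1] <- 0.1     # indels in a domain block
  expect_error(simulation_config(blocks = bad_blocks), "linker")
  expect_error(
    simulation_config(motifs = list(list(block = 2L, offset = 28L,
                                         configuration = "canonical",
                                         taxa = "sp01"))),
    "block boundary")
  expect_error(
    simulation_config(motifs = list(list(block = 2L, offset = 1L,
                                         configuration = "canonical",
                                         taxa = "spXX"))),
    "unknown taxa")
  expect_error(
    simulation_config(motifs = list(
      list(block = 2L, offset = 1L, configuration = "canonical",
           taxa = "sp01"),
      list(block = 2L, offset = 5L, configuration = "rx4", taxa = "sp01"))),
    "overlap")
  expect_error(simulation_config(tree = "fixed"), "newick")
})

test_that("noise-free limit: all rows equal the root, alignment gap-free", {
  blocks <- default_blueprint()
  blocks$rate <- 0
  blocks$indel_rate <- 0
  fam <- simulate_family(simulation_config(n_taxa = 4, blocks = blocks,
                                           seed = 2))
  seqs <- unname(fam$alignment$seqs)
  expect_equal(length(unique(seqs)), 1L)
  expect_false(any(grepl("-", seqs, fixed = TRUE)))
  expect_equal(fam$alignment$ncols, sum(blocks$length))
})

test_that("simulation is deterministic for a fixed seed", {
  cfg <- planted_family_config(seed = 99)
  f1 <- simulate_family(cfg)
  f2 <- simulate_family(cfg)
  expect_identical(f1$alignment$seqs, f2$alignment$seqs)
  expect_identical(f1$truth, f2$truth)
  expect_identical(ape::write.tree(f1$tree), ape::write.tree(f2$tree))
  # and writing the family to disk is byte-stable
  d1 <- tempfile(); d2 <- tempfile()
  write_family(f1, d1); write_family(f2, d2)
  for (f in c("family.afa", "family.fasta", "tree.nwk", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("the emitted truth table is consistent with the alignment", {
  set.seed(1)
  for (rep in 1:10) {
    fam <- simulate_family(planted_family_config(seed = 700 + rep))
    m <- as.matrix(fam$alignment)
    for (k in seq_len(nrow(fam$truth))) {
      row <- fam$truth[k, ]
      ch <- m[row$taxon, row$alignment_column]
      if (row$present) expect_equal(ch, "R")
      else expect_true(ch != "R")
      # residue_position indexes the same residue in the ungapped sequence
      ungapped <- gsub("-", "", fam$alignment$seqs[[row$taxon]])
      expect_equal(substr(ungapped, row$residue_position,
                          row$residue_position), ch)
      expect_identical(ungapped, fam$records[[row$taxon]]$residues)
    }
  }
})

test_that("planted canonical motifs are recovered exactly by scan+classify", {
  for (seed in c(11L, 12L, 13L)) {
    fam <- simulate_family(planted_family_config(seed = seed))
    ref_arg <- fam$truth$residue_position[fam$truth$taxon == "sp01"][1]
    for (tx in fam$alignment$ids) {
      v <- classify_tbm(tx, fam$alignment, "sp01", ref_arg,
                        nearby_window = 0L)$verdict
      expect_equal(v == "canonical_aligned",
                   fam$truth$present[fam$truth$taxon == tx],
                   info = paste("seed", seed, tx))
    }
  }
})

test_that("off-site plants are absent at window 0 and nearby at window 30", {
  cfg <- planted_family_config(
    seed = 3000,
    extra_motifs = list(list(block = 4L, offset = 5L,
                             configuration = "canonical",
                             taxa = c("sp05", "sp06"))))
  fam <- simulate_family(cfg)
  # classify sp05/sp06 against the FIRST motif's reference site: their own
  # plant sits in another linker far away, so it must not rescue them
  ref_arg <- fam$truth$residue_position[fam$truth$taxon == "sp01" &
                                        fam$truth$motif == 1L]
  for (tx in c("sp05", "sp06")) {
    expect_equal(classify_tbm(tx, fam$alignment, "sp01", ref_arg,
                              nearby_window = 0L)$verdict, "absent")
  }
  # a shifted plant 10 linker columns downstream in the SAME linker
  cfg2 <- simulation_config(
    n_taxa = 6L, seed = 3001,
    motifs = list(
      list(block = 2L, offset = 3L, configuration = "canonical",
           taxa = c("sp01", "sp02")),
      list(block = 2L, offset = 13L, configuration = "canonical",
           taxa = c("sp04"))))
  fam2 <- simulate_family(cfg2)
  ref_arg2 <- fam2$truth$residue_position[fam2$truth$taxon == "sp01" &
                                          fam2$truth$motif == 1L]
  expect_equal(classify_tbm("sp04", fam2$alignment, "sp01", ref_arg2,
                            nearby_window = 0L)$verdict, "absent")
  expect_equal(classify_tbm("sp04", fam2$alignment, "sp01", ref_arg2,
                            nearby_window = 30L)$verdict, "nearby_unaligned")
})

test_that("NJ on the true alignment recovers the generating topology", {
  skip_if_not_installed("phangorn")
  for (seed in c(21L, 22L, 23L)) {
    fam <- simulate_family(simulation_config(n_taxa = 6, seed = seed))
    tr <- neighbor_joining(distance_from_alignment(fam$alignment))
    expect_equal(phangorn::RF.dist(ape::unroot(tr),
                                   ape::unroot(fam$tree)), 0,
                 info = paste("seed", seed))
  }
})

test_that("background hit rate matches the analytic window probability", {
  blocks <- data.frame(kind = "linker", length = 400L, rate = 0,
                       indel_rate = 0)
  cfg <- simulation_config(n_taxa = 4, blocks = blocks, seed = 1)
  br <- background_scan_rate(cfg, n_families = 40, seed = 77)
  expect_equal(br$configuration, c("canonical", "rx4", "rx5"))
  # per-window probabilities under the uniform 20-letter model
  p_can <- (1 / 20) * (4 / 20) * (1 / 20)
  p_rx4 <- (1 / 20) * (16 / 20) * (1 / 20)   # rx4 label excludes canonical
  p_rx5 <- (1 / 20) * (1 / 20)
  # windows per 100 residues is slightly below 100 (edge effects); the CI
  # over 40 families absorbs that
  for (k in 1:3) {
    expected <- 100 * c(p_can, p_rx4, p_rx5)[k]
    expect_gt(expected, br$ci_lo[k] - 0.05)
    expect_lt(expected, br$ci_hi[k] + 0.05)
  }
  expect_error(background_scan_rate(planted_family_config(1), 5, 1),
               "no planted motifs")
})

test_that("an alphabet without arginine yields zero hits", {
  blocks <- data.frame(kind = "linker", length = 200L, rate = 0.5,
                       indel_rate = 0)
  cfg <- simulation_config(n_taxa = 4, blocks = blocks, seed = 5,
                           alphabet = setdiff(c("A", "C", "D", "E", "G"),
                                              "R"))
  br <- background_scan_rate(cfg, n_families = 5, seed = 8)
  expect_true(all(br$mean_rate == 0))
})

test_that("doubling sequence length roughly doubles the hit count", {
  mk <- function(len) {
    blocks <- data.frame(kind = "linker", length = len, rate = 0,
                         indel_rate = 0)
    cfg <- simulation_config(n_taxa = 4, blocks = blocks, seed = 1)
    br <- background_scan_rate(cfg, n_families = 30, seed = 55)
    # rate per 100 residues -> expected hits per sequence
    sum(br$mean_rate) * len / 100
  }
  h1 <- mk(250L)
  h2 <- mk(500L)
  expect_gt(h2 / h1, 1.5)
  expect_lt(h2 / h1, 2.5)
})
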