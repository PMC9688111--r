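test_that("pattern geometry: lengths and constrained positions", {
  pat <- tbm_patterns()
  expect_equal(vapply(pat, `[[`, integer(1), "length"),
               c(canonical = 8L, rx4 = 8L, rx5 = 9L))
  expect_equal(pat$canonical$constraints$`4`, c("A", "C", "G", "P"))
  expect_equal(pat$canonical$constraints$`6`, "G")
  expect_equal(pat$rx5$constraints$`7`, "G")
})

test_that("curated site sequences classify as printed", {
  # TRF1-type: position 4 in [ACGP] -> canonical
  h <- scan_tbm("RGCADGRD")
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 1L)
  expect_equal(h$configuration, "canonical")
  # Axin1-type: position 4 = V -> rx4 only
  h2 <- scan_tbm("RPPVPGEE")
  expect_equal(h2$configuration, "rx4")
  # no arginine, no hit
  expect_equal(nrow(scan_tbm("AAAAAAAA")), 0L)
  # concatenated sites give hits at both starts
  h3 <- scan_tbm(paste0("RGCADGRD", "RPPVPGEE"))
  expect_equal(h3$start, c(1L, 9L))
  expect_equal(h3$configuration, c("canonical", "rx4"))
})

test_that("one start can yield both a length-8 and a length-9 hit", {
  s <- "RVVVVGGAA"   # G at positions 6 and 7, position 4 outside [ACGP]
  h <- scan_tbm(s)
  expect_equal(h$length, c(8L, 9L))
  expect_equal(h$configuration, c("rx4", "rx5"))
})

test_that("X never satisfies a constrained position but passes wildcards", {
  expect_equal(nrow(scan_tbm("XAAAAGAA")), 0L)     # X in place of R
  expect_equal(nrow(scan_tbm("RAAAAXAA")), 0L)     # X in place of G
  h <- scan_tbm("RXXAXGXX")                        # X at wildcards + pos 4
  expect_equal(h$configuration, "canonical")       # pos 4 = A
  h2 <- scan_tbm("RXXXXGXX")                       # X at canonical pos 4
  expect_equal(h2$configuration, "rx4")
})

test_that("scanner equals the regex oracle on random sequences", {
  set.seed(1234)
  mismatches <- 0L
  for (rep in 1:1000) {
    s <- random_protein(sample(20:300, 1), x_rate = 0.02)
    mine <- scan_tbm(s)[, c("start", "length", "configuration")]
    rownames(mine) <- NULL
    if (!isTRUE(all.equal(mine, oracle_scan(s)))) mismatches <- mismatches + 1L
  }
  expect_equal(mismatches, 0L)
})

test_that("canonical hits are a subset of rx4 matches at the same starts", {
  set.seed(55)
  pat <- tbm_patterns()
  for (rep in 1:50) {
    s <- random_protein(150)
    all_hits <- scan_tbm(s)
    can <- all_hits$start[all_hits$configuration == "canonical"]
    rx4_only <- scan_tbm(s, pat["rx4"])
    expect_true(all(can %in% rx4_only$start))
  }
})

test_that("classification against the reference column works end to end", {
  # reference carries RGCADGRD at residues 5-12; ortholog identical
  ref <- paste0("AAAA", "RGCADGRD", "EEEE")
  aln <- new_alignment(c("hum", "ort", "del"),
                       c(ref, ref, paste0("AAAA", "AGCADARD", "EEEE")))
  pc <- classify_tbm("ort", aln, "hum", ref_arg = 5L)
  expect_equal(pc$verdict, "canonical_aligned")
  expect_equal(pc$ref_column, 5L)
  # motif ablated (R->A, G->A): absent
  expect_equal(classify_tbm("del", aln, "hum", ref_arg = 5L)$verdict,
               "absent")
  expect_error(classify_tbm("nope", aln, "hum", 5L), "not present")
  expect_error(classify_tbm("ort", aln, "hum", 99L), "outside")
})

test_that("relaxed motifs at the reference column give relaxed_aligned", {
  ref <- paste0("AAAA", "RPPVPGEE", "EEEE")
  aln <- new_alignment(c("hum", "ort"), c(ref, ref))
  expect_equal(classify_tbm("ort", aln, "hum", 5L)$verdict,
               "relaxed_aligned")
})

test_that("nearby window distinguishes shifted motifs from absent ones", {
  #              1234      5..12        13-22            23..30
  hum <- paste0("AAAA", "RGCADGRD", "AAAAAAAAAA", "AAAAAAAA")
  ort <- paste0("AAAA", "AGCADARD", "AAAAAAAAAA", "RGCADGRD")
  aln <- new_alignment(c("hum", "ort"), c(hum, ort))
  # ort motif starts at column 23, 18 columns from the reference column 5
  expect_equal(classify_tbm("ort", aln, "hum", 5L,
                            nearby_window = 0L)$verdict, "absent")
  expect_equal(classify_tbm("ort", aln, "hum", 5L,
                            nearby_window = 30L)$verdict, "nearby_unaligned")
  expect_equal(classify_tbm("ort", aln, "hum", 5L,
                            nearby_window = 17L)$verdict, "absent")
})

test_that("enlarging the window never worsens the verdict", {
  rank_of <- function(v) match(v, c("canonical_aligned", "relaxed_aligned",
                                    "nearby_unaligned", "absent"))
  set.seed(77)
  for (rep in 1:15) {
    fam <- simulate_family(planted_family_config(seed = 5000 + rep))
    ref_arg <- fam$truth$residue_position[fam$truth$taxon == "sp01"][1]
    for (tx in fam$alignment$ids) {
      verdicts <- vapply(c(0L, 10L, 30L, 60L), function(w)
        classify_tbm(tx, fam$alignment, "sp01", ref_arg,
                     nearby_window = w)$verdict, "")
      expect_true(all(diff(rank_of(verdicts)) <= 0L),
                  info = paste("seed", 5000 + rep, tx))
    }
  }
})

test_that("classification ignores alignment row order", {
  fam <- simulate_family(planted_family_config(seed = 31))
  aln <- fam$alignment
  perm <- sample(length(aln$ids))
  shuf <- new_alignment(aln$ids[perm], unname(aln$seqs[perm]))
  ref_arg <- fam$truth$residue_position[fam$truth$taxon == "sp01"][1]
  for (tx in aln$ids) {
    expect_equal(classify_tbm(tx, aln, "sp01", ref_arg)$verdict,
                 classify_tbm(tx, shuf, "sp01", ref_arg)$verdict)
  }
})

test_that("presence matrix recovers the planted pattern and handles gaps in coverage", {
  fam <- simulate_family(planted_family_config(seed = 88))
  ref_arg <- fam$truth$residue_position[fam$truth$taxon == "sp01"][1]
  binders <- data.frame(partner = "SIM", role = "simulated",
                        tbm = "RXXXXGXX", arg_position = ref_arg,
                        truncated = FALSE)
  species <- c(fam$alignment$ids, "missing_species")
  pm <- presence_matrix(binders, list(SIM = fam$alignment), species,
                        ref_species = "sp01", nearby_window = 0L)
  expect_s3_class(pm, "tbm_presence_matrix")
  expect_equal(nrow(pm), length(species))
  expect_equal(pm$verdict[pm$species == "missing_species"], "no_ortholog")
  got <- pm$verdict[match(fam$truth$taxon, pm$species)]
  expect_equal(got == "canonical_aligned", fam$truth$present)
  # partner with no alignment: warned, all no_ortholog
  binders2 <- rbind(binders,
                    within(binders, partner <- "ORPHAN"))
  expect_warning(pm2 <- presence_matrix(binders2, list(SIM = fam$alignment),
                                        species, ref_species = "sp01"),
                 "ORPHAN")
  expect_true(all(pm2$verdict[pm2$partner == "ORPHAN"] == "no_ortholog"))
})

test_that("a partner with two reference TBMs yields two sub-rows", {
  tb <- tbm_binders()
  two <- tb[tb$partner == "MERIT40", ]
  expect_equal(nrow(two), 2L)
  # toy alignment where the human row carries both MERIT40 motifs
  hum <- paste0(strrep("A", 27), "RSNPEGAE", strrep("A", 12), "RSEGEGEA",
                strrep("A", 10))
  aln <- new_alignment(c("h", "o"), c(hum, hum),
                       species = c("Homo_sapiens", "Mus_musculus"))
  two$arg_position <- c(28L, 48L)
  pm <- presence_matrix(two, list(MERIT40 = aln),
                        c("Homo_sapiens", "Mus_musculus"))
  expect_equal(nrow(pm), 4L)
  expect_equal(sort(unique(pm$site)), c(28L, 48L))
  expect_true(all(pm$verdict == "canonical_aligned"))
})

test_that("wide TSV writer emits one row per site and one column per species", {
  fam <- simulate_family(planted_family_config(seed = 12))
  ref_arg <- fam$truth$residue_position[fam$truth$taxon == "sp01"][1]
  binders <- data.frame(partner = "SIM", role = "s", tbm = "RXXXXGXX",
                        arg_position = ref_arg, truncated = FALSE)
  pm <- presence_matrix(binders, list(SIM = fam$alignment),
                        fam$alignment$ids, ref_species = "sp01")
  f <- tempfile(fileext = ".tsv")
  write_presence_tsv(pm, f)
  wide <- read.delim(f, check.names = FALSE)
  expect_equal(nrow(wide), 1L)
  expect_equal(names(wide), c("site", fam$alignment$ids))
})
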