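reg <- defaultRegistry()
fix <- tinyFixture()

test_that("membership expansion emits one occurrence per redundant member", {
  hits <- rbind(
    makeHit("Phy_Er", "GEN001_00001", pid = 80, qcov = 90, evalue = 1e-40,
            bitscore = 200),
    makeHit("Flr_Fp", "GEN002_00002", pid = 60, qcov = 85, evalue = 1e-30,
            bitscore = 150))
  occ <- expandMembers(hits, fix$membership, reg)
  # clusters of size 3 and 3 -> 6 occurrences
  expect_equal(nrow(occ), 6L)
  expect_equal(sum(occ$representative_id == "GEN001_00001"), 3L)
  expect_equal(occ$pathway_id[occ$query_id == "Phy_Er"][1], "phy")
  expect_equal(unique(occ$pid[occ$query_id == "Phy_Er"]), 80)
  expect_equal(occ$genome_id[occ$member_protein_id == "GEN004_00002"],
               "GEN004")

  # a representative that is its own sole member yields one occurrence
  solo <- makeHit("Phy_Er", "GEN001_00002", pid = 70, qcov = 90,
                  evalue = 1e-40, bitscore = 100)
  # GEN001_00002's cluster has 2 members in the fixture; use a fresh table
  mem1 <- data.frame(member_id = "X_00001", representative_id = "X_00001")
  one <- expandMembers(makeHit("Phy_Er", "X_00001", 70, 90, 1e-40, 100),
                       mem1, reg)
  expect_equal(nrow(one), 1L)

  # 2 hits with 3 and 5 members -> 8 occurrences (independent join oracle)
  memBig <- data.frame(
    member_id = c(paste0("A_0000", 1:3), paste0("B_0000", 1:5)),
    representative_id = c(rep("A_00001", 3), rep("B_00001", 5)))
  hits2 <- rbind(makeHit("Phy_Er", "A_00001", 70, 90, 1e-40, 100),
                 makeHit("Phy_Er", "B_00001", 60, 90, 1e-35, 90))
  occ2 <- expandMembers(hits2, memBig, reg)
  oracleCount <- 0L
  for (h in hits2$target_id)
    for (m in seq_len(nrow(memBig)))
      if (memBig$representative_id[m] == h) oracleCount <- oracleCount + 1L
  expect_equal(nrow(occ2), oracleCount)
  expect_equal(nrow(occ2), 8L)

  expect_error(
    expandMembers(makeHit("Phy_Er", "GHOST_1", 70, 90, 1e-40, 100),
                  fix$membership, reg),
    "GHOST_1")
})

test_that("metadata merge drops isolates and labels species", {
  hits <- makeHit("Phy_Er", "GEN001_00001", pid = 80, qcov = 90,
                  evalue = 1e-40, bitscore = 200)
  occ <- expandMembers(hits, fix$membership, reg)
  # cluster members live in GEN001 (MAG), GEN002 (MAG), GEN003 (Isolate)
  mags <- attachMetadata(occ, fix$metadata)
  expect_equal(sort(mags$genome_id), c("GEN001", "GEN002"))
  expect_true(all(mags$genome_type == "MAG"))
  expect_equal(unique(mags$species_name), "Alpha one")

  all_ <- attachMetadata(occ, fix$metadata, magsOnly = FALSE)
  expect_equal(nrow(all_), 3L)

  orphan <- occ
  orphan$genome_id[1] <- "GENXXX"
  expect_error(attachMetadata(orphan, fix$metadata), "GENXXX")
})

test_that("unclassified species aggregate under the genus label", {
  lin <- paste0("d__Bacteria;p__P;c__C;o__O;f__F;g__CAG-1427;s__")
  expect_equal(speciesLabel(lin), "CAG-1427 (unclassified)")
  expect_equal(speciesLabel("d__Bacteria;p__;c__;o__;f__;g__;s__"),
               "(unclassified)")
})

test_that("summaries respect the occurrence floor and match a brute tally", {
  set.seed(8)
  species <- sample(c("Alpha one", "Beta two", "Gamma three"), 120,
                    replace = TRUE)
  occ <- data.frame(
    member_protein_id = sprintf("G%03d_00001", 1:120),
    genome_id = sprintf("G%03d", sample(40, 120, replace = TRUE)),
    species_name = species,
    query_id = sample(c("Phy_Er", "Flr_Fp"), 120, replace = TRUE),
    pid = runif(120, 30, 100),
    stringsAsFactors = FALSE)
  edges <- c(30, 40, 50, 65, 80, 90, 100)
  summ <- summarizeOccurrences(occ, edges, minFreq = 1L)
  tally <- oracleGroupTally(occ, edges)
  expect_equal(nrow(summ), length(tally))
  for (i in seq_len(nrow(summ))) {
    key <- paste(summ$species[i], summ$query_id[i], summ$pid_bin[i],
                 sep = "|")
    expect_equal(summ$freq[i], tally[[key]])
  }
  expect_true(all(diff(summ$freq) <= 0))   # sorted by freq descending

  # occurrence floor: a group of 52 stays at minFreq 50, one of 49 does not
  occ2 <- data.frame(
    member_protein_id = sprintf("H%03d_00001", 1:101),
    genome_id = sprintf("H%03d", 1:101),
    species_name = rep(c("Alpha one", "Beta two"), c(52, 49)),
    query_id = "Phy_Er",
    pid = 55,
    stringsAsFactors = FALSE)
  s2 <- summarizeOccurrences(occ2, edges, minFreq = 50L)
  expect_equal(nrow(s2), 1L)
  expect_equal(s2$species, "Alpha one")
  expect_equal(s2$freq, 52L)
})

test_that("freq is conserved through the expansion join", {
  hits <- rbind(
    makeHit("Phy_Er", "GEN001_00001", 80, 90, 1e-40, 200),
    makeHit("Flr_Fp", "GEN002_00002", 60, 85, 1e-30, 150),
    makeHit("CHI_Er", "GEN001_00002", 45, 80, 1e-28, 120))
  occ <- attachMetadata(expandMembers(hits, fix$membership, reg),
                        fix$metadata, magsOnly = FALSE)
  summ <- summarizeOccurrences(occ, minFreq = 0L)
  matching <- sum(fix$membership$representative_id %in% hits$target_id)
  expect_equal(sum(summ$freq), matching)
})
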