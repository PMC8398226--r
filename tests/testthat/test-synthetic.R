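test_that("mutateToIdentity hits the nearest achievable identity exactly", {
  s <- oracleRandomPeptide(60)
  # identity case
  expect_identical(as.character(mutateToIdentity(s, 100, seed = 7)), s)

  m <- mutateToIdentity(s, 70, seed = 1)
  a <- strsplit(s, "")[[1]]
  b <- strsplit(as.character(m), "")[[1]]
  conserved <- sum(a == b)
  expect_equal(conserved, 42L)                      # 42 of 60 positions
  expect_equal(attr(m, "realized_pid"), 70)
  expect_equal(nchar(m), nchar(s))

  # determinism
  expect_identical(mutateToIdentity(s, 70, seed = 1),
                   mutateToIdentity(s, 70, seed = 1))

  # every touched position is a true mismatch at any target
  for (pid in c(35, 52.5, 91)) {
    mm <- mutateToIdentity(s, pid, seed = 3)
    bb <- strsplit(as.character(mm), "")[[1]]
    expect_equal(100 * sum(a == bb) / 60, attr(mm, "realized_pid"))
    expect_equal(attr(mm, "realized_pid"),
                 100 * (60 - round(60 * (1 - pid / 100))) / 60)
  }

  expect_error(mutateToIdentity(s, 0, 1), "targetPid")
  expect_error(mutateToIdentity(s, 101, 1), "targetPid")
  expect_error(mutateToIdentity("SHORTSEQ", 90, 1), "20 residues")
})

reg <- defaultRegistry()

test_that("generateCatalog respects carrier fractions and redundancy", {
  prof <- speciesProfile("Testus one", 10)
  imp <- implantSpec("Testus one", "phy", 85, 0.3)
  cat_ <- generateCatalog(list(prof), list(imp), reg, nSamples = 5,
                          backgroundPerGenome = 2, redundancy = 1, seed = 11)
  # exactly 3 of 10 genomes carry the single-role implant
  expect_equal(length(unique(cat_@truth$genome_id)), 3L)
  expect_equal(nrow(cat_@truth), 3L)

  # zero carrier fraction leaves no truth rows
  cat0 <- generateCatalog(list(prof),
                          list(implantSpec("Testus one", "phy", 85, 0)),
                          reg, nSamples = 5, backgroundPerGenome = 2,
                          redundancy = 1, seed = 11)
  expect_equal(nrow(cat0@truth), 0L)

  # redundancy: implanted members form one cluster; membership rows == copies
  imp2 <- implantSpec("Testus one", "phy", 85, 1, copiesPerGenome = 3L)
  cat2 <- generateCatalog(list(prof), list(imp2), reg, nSamples = 5,
                          backgroundPerGenome = 0, redundancy = 1, seed = 2)
  expect_equal(nrow(cat2@membership), 30L)           # 10 genomes x 3 copies
  expect_equal(length(cat2@representatives), 1L)     # one implant cluster
  expect_equal(nrow(cat2@truth), 30L)

  # background redundancy: mean cluster size ~ redundancy
  cat3 <- generateCatalog(list(speciesProfile("Testus one", 12)), list(),
                          reg, nSamples = 4, backgroundPerGenome = 5,
                          redundancy = 3, seed = 5)
  expect_equal(nrow(cat3@membership), 60L)
  expect_equal(length(cat3@representatives), 20L)    # 60 / 3
})

test_that("catalog bundles satisfy the conservation invariants", {
  profs <- list(speciesProfile("Alphus primus", 8, magFraction = 0.75),
                speciesProfile("Betus secundus", 5, sampleSpread = "shared"))
  imps <- list(implantSpec("Alphus primus", "c_deglycosylation_dgp", 70, 0.5))
  cat_ <- generateCatalog(profs, imps, reg, nSamples = 6,
                          backgroundPerGenome = 3, redundancy = 2, seed = 99)
  expect_equal(nrow(cat_@metadata), 13L)
  expect_true(all(cat_@membership$representative_id %in%
                    names(cat_@representatives)))
  expect_true(all(genomeOfProtein(cat_@membership$member_id) %in%
                    cat_@metadata$Genome))
  expect_true(all(cat_@truth$protein_id %in% cat_@membership$member_id))
  expect_equal(sum(cat_@metadata$Genome_type == "MAG"), round(0.75 * 8) + 5)
  # shared spread: one sample for the whole species
  beta <- cat_@metadata[grepl("Betus", cat_@metadata$Lineage), ]
  expect_equal(length(unique(beta$Sample_accession)), 1L)
  # validity holds
  expect_true(validObject(cat_))
})

test_that("same seed reproduces a byte-identical bundle; round-trip is lossless", {
  profs <- list(speciesProfile("Gammus tertius", 6))
  imps <- list(implantSpec("Gammus tertius", "flr", 80, 0.5))
  mk <- function() generateCatalog(profs, imps, reg, nSamples = 3,
                                   backgroundPerGenome = 2, redundancy = 2,
                                   seed = 123)
  c1 <- mk(); c2 <- mk()
  expect_identical(as.character(c1@representatives),
                   as.character(c2@representatives))
  expect_identical(c1@membership, c2@membership)
  expect_identical(c1@metadata, c2@metadata)
  expect_identical(c1@truth, c2@truth)

  d1 <- withr::local_tempdir()
  writeCatalog(c1, d1)
  rt <- readCatalog(d1)
  expect_identical(as.character(rt@representatives),
                   as.character(c1@representatives))
  expect_identical(rt@membership, c1@membership)
  expect_equal(rt@metadata, c1@metadata)
  expect_equal(rt@truth, c1@truth)

  # byte-identical files from a rewrite
  d2 <- withr::local_tempdir()
  writeCatalog(c2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("implant validation rejects unknown species, pathways and roles", {
  prof <- speciesProfile("Testus one", 4)
  expect_error(
    generateCatalog(list(prof), list(implantSpec("Nobody", "phy", 80, 1)),
                    reg, seed = 1),
    "unknown species")
  expect_error(
    generateCatalog(list(prof), list(implantSpec("Testus one", "nope", 80, 1)),
                    reg, seed = 1),
    "unknown pathway")
  expect_error(
    generateCatalog(list(prof),
                    list(implantSpec("Testus one", "phy", 80, 1,
                                     roles = "not_a_role")),
                    reg, seed = 1),
    "roles not in pathway")
})

test_that("background-only catalogs produce no hits at the class cutoffs", {
  cat_ <- generateCatalog(list(speciesProfile("Backgroundus solus", 6)),
                          list(), reg, nSamples = 3,
                          backgroundPerGenome = 4, redundancy = 2, seed = 77)
  hits <- searchCatalog(reg, cat_)
  filt <- applyThresholds(hits, filterConfig(), reg)
  expect_equal(nrow(filt), 0L)
})
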