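reg <- defaultRegistry()

test_that("threshold boundaries are inclusive exactly as stated", {
  # BtR: long class (1e-60); DZR_Si: short (1e-25); DgpB: c_degly (1e-20)
  hits <- rbind(
    makeHit("BtR", "T01", pid = 29.9, qcov = 80, evalue = 1e-70, bitscore = 200),
    makeHit("BtR", "T02", pid = 30.0, qcov = 75.0, evalue = 1e-60, bitscore = 200),
    makeHit("BtR", "T03", pid = 50, qcov = 74.9, evalue = 1e-70, bitscore = 200),
    makeHit("BtR", "T04", pid = 50, qcov = 75.0, evalue = 1e-59, bitscore = 200),
    makeHit("DZR_Si", "T05", pid = 50, qcov = 80, evalue = 1e-25, bitscore = 150),
    makeHit("DZR_Si", "T06", pid = 50, qcov = 80, evalue = 1e-22, bitscore = 150),
    makeHit("DgpB", "T07", pid = 50, qcov = 80, evalue = 1e-20, bitscore = 100),
    makeHit("DgpB", "T08", pid = 50, qcov = 80, evalue = 9e-20, bitscore = 100))
  kept <- applyThresholds(hits, filterConfig(), reg)
  # hand enumeration: T02 (all at boundary, inclusive), T05, T07 pass;
  # T01 PID below, T03 coverage below, T04/T06/T08 e-value above cutoff
  expect_identical(kept$target_id, c("T02", "T05", "T07"))
  expect_error(applyThresholds(makeHit("ghost", "T", 50, 80, 1e-70, 10),
                               filterConfig(), reg),
               "unknown query_id")
})

test_that("raising thresholds never increases the retained count", {
  set.seed(31)
  hits <- do.call(rbind, lapply(1:200, function(i)
    makeHit("BtR", sprintf("T%03d", i), pid = runif(1, 0, 100),
            qcov = runif(1, 0, 100), evalue = 10^runif(1, -90, -50),
            bitscore = runif(1, 50, 400))))
  n <- sapply(c(0, 30, 50, 70, 90), function(p)
    nrow(applyThresholds(hits, filterConfig(minPid = p), reg)))
  expect_true(all(diff(n) <= 0))
  n2 <- sapply(c(0, 50, 75, 95), function(q)
    nrow(applyThresholds(hits, filterConfig(minQcov = q), reg)))
  expect_true(all(diff(n2) <= 0))
})

test_that("filtering commutes with input order", {
  set.seed(55)
  hits <- do.call(rbind, lapply(1:50, function(i)
    makeHit("Phy_Er", sprintf("T%03d", i), pid = runif(1, 20, 40),
            qcov = runif(1, 60, 90), evalue = 10^runif(1, -40, -20),
            bitscore = runif(1, 50, 150))))
  perm <- hits[sample(nrow(hits)), ]
  a <- applyThresholds(hits, filterConfig(), reg)
  b <- applyThresholds(perm, filterConfig(), reg)
  expect_setequal(a$target_id, b$target_id)
})

test_that("best-bitscore dedup keeps one deterministic winner per target", {
  hits <- rbind(
    makeHit("BpGluA", "T1", pid = 60, qcov = 90, evalue = 1e-70, bitscore = 420),
    makeHit("BpGluB", "T1", pid = 70, qcov = 90, evalue = 1e-65, bitscore = 310),
    makeHit("BpGluA", "T2", pid = 55, qcov = 90, evalue = 1e-70, bitscore = 200),
    makeHit("BpGluB", "T2", pid = 48, qcov = 90, evalue = 1e-70, bitscore = 200),
    makeHit("BpGluA", "T3", pid = 50, qcov = 90, evalue = 1e-70, bitscore = 99))
  out <- bestHitPerTarget(hits)
  expect_equal(nrow(out), 3L)
  expect_equal(out$query_id[out$target_id == "T1"], "BpGluA")   # best bitscore
  expect_equal(out$pid[out$target_id == "T2"], 55)              # pid tie-break
  expect_equal(out$bitscore[out$target_id == "T3"], 99)         # single hit kept

  # equal bitscore AND pid: lexicographically smallest query wins
  tie <- rbind(
    makeHit("BpGluB", "T9", pid = 50, qcov = 90, evalue = 1e-70, bitscore = 100),
    makeHit("BpGluA", "T9", pid = 50, qcov = 90, evalue = 1e-70, bitscore = 100))
  expect_equal(bestHitPerTarget(tie)$query_id, "BpGluA")
})

test_that("dedup output is a unique-target subset of its input", {
  set.seed(77)
  qids <- c("BpGluA", "BpGluB", "BtR", "Phy_Er")
  hits <- do.call(rbind, lapply(1:120, function(i)
    makeHit(sample(qids, 1), sprintf("T%02d", sample(30, 1)),
            pid = runif(1, 30, 100), qcov = 90,
            evalue = 1e-70, bitscore = round(runif(1, 50, 400)))))
  out <- bestHitPerTarget(hits)
  expect_false(anyDuplicated(out$target_id) > 0)
  keys <- function(d) paste(d$query_id, d$target_id, d$bitscore)
  expect_true(all(keys(out) %in% keys(hits)))

  # pathway-scoped dedup keeps at most one hit per (pathway, target)
  byPathway <- bestHitPerTarget(hits, scope = "pathway", registry = reg)
  qt <- queryTable(reg)
  pw <- qt$pathway_id[match(byPathway$query_id, qt$query_id)]
  expect_false(anyDuplicated(paste(pw, byPathway$target_id)) > 0)
  expect_gte(nrow(byPathway), nrow(out))
})

test_that("PID binning is left-closed with a closed top bin", {
  edges <- c(30, 40, 50, 65, 80, 90, 100)
  expect_equal(as.character(pidBin(52, edges)), "50-65")
  expect_equal(as.character(pidBin(100, edges)), "90-100")
  expect_equal(as.character(pidBin(40, edges)), "40-50")
  expect_equal(as.character(pidBin(29.9, edges)), NA_character_)
  expect_error(pidBin(101, edges), "outside")
  expect_error(pidBin(50, c(30, 30, 50)), "strictly increasing")
})
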