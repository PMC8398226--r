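reg <- defaultRegistry()
rules <- pathwayRules(reg)

mkOcc <- function(genome, pathway, roles, pid = 80) {
  data.frame(genome_id = genome, pathway_id = pathway, role = roles,
             pid = pid, species_name = "Testus one",
             stringsAsFactors = FALSE)
}

test_that("co-occurrence calls follow the cluster requirements", {
  # complete dgpABC cluster in one genome
  occ <- mkOcc("G1", "c_deglycosylation_dgp", c("dgpA", "dgpB", "dgpC"))
  call <- callPathways(occ, rules)
  expect_true(call$present)
  expect_equal(call$roles_missing, "")

  # dfgABCE without dfgD still satisfies at-least-3-of-5
  occ2 <- mkOcc("G2", "c_deglycosylation_dfg", c("dfgA", "dfgB", "dfgC", "dfgE"))
  expect_true(callPathways(occ2, rules)$present)

  # dzr alone does not make an equol producer
  occ3 <- mkOcc("G3", "daidzein_equol", "dzr")
  expect_false(callPathways(occ3, rules)$present)
  # the racemase is optional: dzr+ddr+tdr suffice without it
  occ4 <- mkOcc("G4", "daidzein_equol", c("dzr", "ddr", "tdr"))
  expect_true(callPathways(occ4, rules)$present)

  # O-demethylase operon: AE at PID 38 fails the strict >40 floor
  occ5 <- rbind(mkOcc("G5", "o_demethylation", c("MT1", "MT2", "CP"), pid = 55),
                mkOcc("G5", "o_demethylation", "AE", pid = 38))
  expect_false(callPathways(occ5, rules)$present)
  occ6 <- rbind(mkOcc("G6", "o_demethylation", c("MT1", "MT2", "CP"), pid = 55),
                mkOcc("G6", "o_demethylation", "AE", pid = 40.5))
  expect_true(callPathways(occ6, rules)$present)

  expect_error(callPathways(mkOcc("G7", "unknown_pw", "x"), rules),
               "no rule")
})

test_that("rule evaluation equals brute-force subset enumeration", {
  cases <- list(
    list(rule = rules[["c_deglycosylation_dgp"]]),
    list(rule = rules[["c_deglycosylation_dfg"]]),
    list(rule = rules[["daidzein_equol"]]),
    list(rule = rules[["o_demethylation"]]))
  for (cs in cases) {
    rule <- cs$rule
    roles <- rule@roles
    k <- length(roles)
    for (mask in 0:(2^k - 1)) {
      found <- roles[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0]
      if (!length(found)) next     # no occurrence, no call emitted
      pid <- if (!is.na(rule@minPidOverride)) rule@minPidOverride + 5 else 80
      occ <- mkOcc("G1", rule@pathwayId, found, pid = pid)
      got <- callPathways(occ, rules)$present
      want <- oracleRuleSatisfied(rule@requirement, roles, rule@k, found)
      expect_identical(got, want,
                       info = sprintf("%s mask %d", rule@pathwayId, mask))
    }
  }
})

test_that("adding an occurrence never flips a present call to absent", {
  set.seed(14)
  roles <- rules[["c_deglycosylation_dfg"]]@roles
  for (i in 1:25) {
    found <- sample(roles, sample(length(roles), 1))
    occ <- mkOcc("G1", "c_deglycosylation_dfg", found)
    before <- callPathways(occ, rules)$present
    extra <- rbind(occ, mkOcc("G1", "c_deglycosylation_dfg",
                              sample(roles, 1)))
    after <- callPathways(extra, rules)$present
    expect_false(before && !after)
  }
})

test_that("species carrier statistics use metadata denominators", {
  lin <- paste0("d__Bacteria;p__P;c__C;o__O;f__F;g__Testus;s__Testus one")
  metadata <- data.frame(
    Genome = sprintf("G%02d", 1:10), Genome_type = "MAG",
    Sample_accession = sprintf("S%02d", 1:10), Lineage = lin,
    stringsAsFactors = FALSE)
  occ <- do.call(rbind, lapply(sprintf("G%02d", 1:3), function(g)
    mkOcc(g, "c_deglycosylation_dgp", c("dgpA", "dgpB", "dgpC"))))
  calls <- callPathways(occ, rules)
  st <- speciesCarrierStats(calls, metadata)
  expect_equal(st$n_carriers, 3L)
  expect_equal(st$n_total, 10L)
  expect_equal(st$carrier_fraction, 30)

  # zero carriers still reported with fraction 0
  calls0 <- callPathways(mkOcc("G01", "daidzein_equol", "dzr"), rules)
  st0 <- speciesCarrierStats(calls0, metadata)
  expect_equal(st0$n_carriers, 0L)
  expect_equal(st0$carrier_fraction, 0)

  expect_error(speciesCarrierStats(
    callPathways(mkOcc("GHOST", "chi", "CHI"), rules), metadata), "GHOST")
})

test_that("the partial-role report matches nested-loop enumeration", {
  occ <- rbind(
    mkOcc("G1", "daidzein_equol", c("dzr", "ddr")),
    mkOcc("G2", "daidzein_equol", "dzr"),
    mkOcc("G3", "daidzein_equol", "dzr"),
    mkOcc("G4", "daidzein_equol", c("dzr", "ddr", "tdr")))  # complete: excluded
  rep_ <- partialRoleReport(occ, "daidzein_equol", rules)
  expect_equal(rep_$n_genomes[rep_$signature == "{dzr}"], 2L)
  expect_equal(rep_$n_genomes[rep_$signature == "{ddr,dzr}"], 1L)
  expect_false("G4" %in% rep_$signature)
  expect_equal(sum(rep_$n_genomes), 3L)

  # brute-force check on a random fixture
  set.seed(21)
  roles <- c("dzr", "ddr", "tdr")
  occ2 <- do.call(rbind, lapply(1:30, function(i)
    mkOcc(sprintf("R%02d", i), "daidzein_equol",
          sample(roles, sample(3, 1)))))
  got <- partialRoleReport(occ2, "daidzein_equol", rules)
  oracle <- list()
  for (g in unique(occ2$genome_id)) {
    f <- sort(unique(occ2$role[occ2$genome_id == g]))
    if (length(f) == 3L) next
    key <- paste0("{", paste(f, collapse = ","), "}")
    oracle[[key]] <- (if (is.null(oracle[[key]])) 0L else oracle[[key]]) + 1L
  }
  expect_equal(sum(got$n_genomes), sum(unlist(oracle)))
  for (i in seq_len(nrow(got)))
    expect_equal(got$n_genomes[i], oracle[[got$signature[i]]])

  expect_error(partialRoleReport(occ, "phy", rules), ">= 2 roles")
})
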