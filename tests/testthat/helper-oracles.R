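# Independent brute-force oracles used to validate the pipeline. These are
# deliberately naive re-implementations (plain loops, no vectorization, no
# shared code with the package internals beyond the BLOSUM62 matrix data).

.oracleAA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

oracleRandomPeptide <- function(n) {
  paste(sample(.oracleAA, n, replace = TRUE), collapse = "")
}

.blosum62 <- local({
  data("BLOSUM62", package = "Biostrings", envir = environment())
  BLOSUM62
})

# Affine-gap local alignment best score, Gotoh-style three-state DP in plain
# loops. A gap of length L costs open + L * extend (first gapped position
# pays open + extend).
oracleLocalScore <- function(a, b, open = 11, extend = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(-Inf, n + 1, m + 1)   # ends in a match/mismatch
  X <- matrix(-Inf, n + 1, m + 1)   # ends in a gap in b (vertical)
  Y <- matrix(-Inf, n + 1, m + 1)   # ends in a gap in a (horizontal)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- .blosum62[av[i - 1], bv[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1],
                     Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

# Nested-loop group-by tally of occurrences per (species, query, bin label).
oracleGroupTally <- function(occ, binEdges) {
  out <- list()
  for (r in seq_len(nrow(occ))) {
    lab <- NA_character_
    for (k in seq_len(length(binEdges) - 1)) {
      lo <- binEdges[k]; hi <- binEdges[k + 1]
      inBin <- if (k == length(binEdges) - 1)
        occ$pid[r] >= lo && occ$pid[r] <= hi
      else occ$pid[r] >= lo && occ$pid[r] < hi
      if (inBin) { lab <- paste0(lo, "-", hi); break }
    }
    key <- paste(occ$species_name[r], occ$query_id[r], lab, sep = "|")
    if (is.null(out[[key]])) out[[key]] <- 0L
    out[[key]] <- out[[key]] + 1L
  }
  out
}

# Direct evaluation of a co-occurrence requirement on a role subset.
oracleRuleSatisfied <- function(requirement, memberRoles, k, foundRoles) {
  nFound <- 0L
  for (r in memberRoles) if (r %in% foundRoles) nFound <- nFound + 1L
  if (requirement == "ALL") nFound == length(memberRoles)
  else if (requirement == "AT_LEAST_K") nFound >= k
  else nFound >= 1L
}

# Exhaustive first-fit greedy clustering, re-implemented with plain loops;
# identity callback is injected so the clustering logic stays independent.
oracleFirstFit <- function(seqs, threshold, identityFun) {
  ids <- names(seqs)
  ord <- order(-nchar(seqs), ids)
  reps <- character(0)
  assign <- integer(0)
  for (id in ids[ord]) {
    cl <- 0L
    for (ci in seq_along(reps)) {
      if (identityFun(seqs[[id]], seqs[[reps[ci]]]) >= threshold) {
        cl <- ci; break
      }
    }
    if (cl == 0L) { reps <- c(reps, id); cl <- length(reps) }
    assign[id] <- cl
  }
  list(reps = reps, assign = assign)
}

# Tiny catalog used by several quantification/pathway tests: built by hand so
# the expected joins can be enumerated by hand.
tinyFixture <- function() {
  lin <- function(g, s) paste0(
    "d__Bacteria;p__TestPhylum;c__TestClass;o__TestOrder;f__TestFamily;g__",
    g, ";s__", s)
  metadata <- data.frame(
    Genome = c("GEN001", "GEN002", "GEN003", "GEN004"),
    Genome_type = c("MAG", "MAG", "Isolate", "MAG"),
    Sample_accession = c("SAMP01", "SAMP01", "SAMP02", "SAMP03"),
    Lineage = c(lin("Alpha", "Alpha one"), lin("Alpha", "Alpha one"),
                lin("Beta", "Beta two"), lin("Beta", "Beta two")),
    Completeness = 90, Contamination = 1,
    stringsAsFactors = FALSE)
  membership <- data.frame(
    member_id = c("GEN001_00001", "GEN002_00001", "GEN003_00001",
                  "GEN001_00002", "GEN004_00001", "GEN002_00002",
                  "GEN004_00002", "GEN004_00003"),
    representative_id = c("GEN001_00001", "GEN001_00001", "GEN001_00001",
                          "GEN001_00002", "GEN001_00002", "GEN002_00002",
                          "GEN002_00002", "GEN002_00002"),
    stringsAsFactors = FALSE)
  list(metadata = metadata, membership = membership)
}

# Hand-built hit rows in the package layout.
makeHit <- function(query_id, target_id, pid, qcov, evalue, bitscore,
                    qlen = 1000L) {
  span <- as.integer(round(qcov / 100 * qlen))
  data.frame(query_id = query_id, target_id = target_id, pid = pid,
             aln_length = span, mismatch = 0L, gapopen = 0L,
             qstart = 1L, qend = span, sstart = 1L, send = span,
             evalue = evalue, bitscore = bitscore, qlen = qlen,
             qcov = 100 * span / qlen, stringsAsFactors = FALSE)
}
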