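#' Aligner parameters
#'
#' Parameters of the reference local aligner and its e-value statistics:
#' substitution matrix, affine gap costs (a gap of length L costs
#' `gapOpen + L * gapExtend`), the Karlin-Altschul scale `lambda` and
#' constant `K`, the database size in residues, and the per-query hit cap.
#' Defaults mirror BLASTP's gapped BLOSUM62 defaults so the screen's e-value
#' regimes transfer: BLOSUM62, gap open 11, gap extend 1, lambda 0.267,
#' K 0.041, `maxTargets` 100000.
#'
#' @param matrix substitution matrix name (passed to
#'   [Biostrings::pairwiseAlignment()]).
#' @param gapOpen positive gap-opening cost.
#' @param gapExtend positive per-residue gap-extension cost
#'   (`gapExtend <= gapOpen`).
#' @param lambda Karlin-Altschul scale (> 0).
#' @param k Karlin-Altschul constant (> 0).
#' @param dbSize database size in residues used for e-values when the search
#'   does not supply one (`NA` = derive from the searched set).
#' @param maxTargets maximal number of hits kept per query.
#' @return A `list` of class `"AlignerParams"`.
#' @export
alignerParams <- function(matrix = "BLOSUM62", gapOpen = 11, gapExtend = 1,
                          lambda = 0.267, k = 0.041, dbSize = NA_real_,
                          maxTargets = 100000L) {
  stopifnot(gapOpen > 0, gapExtend > 0, gapExtend <= gapOpen,
            lambda > 0, k > 0, maxTargets >= 1)
  structure(list(matrix = matrix, gapOpen = gapOpen, gapExtend = gapExtend,
                 lambda = lambda, k = k, dbSize = dbSize,
                 maxTargets = as.integer(maxTargets)),
            class = "AlignerParams")
}

.checkResidues <- function(seq) {
  bad <- setdiff(strsplit(toupper(seq), "")[[1]], .AA20)
  if (length(bad))
    .stopf("invalid residue character(s): %s", paste(unique(bad), collapse = ", "))
  invisible(seq)
}

# Gap openings across both aligned strings (runs of '-')
.countGapOpens <- function(alignedA, alignedB) {
  n <- 0L
  for (s in c(alignedA, alignedB)) {
    r <- rle(strsplit(s, "", fixed = TRUE)[[1]] == "-")
    n <- n + sum(r$values)
  }
  n
}

#' Best local alignment of two protein sequences
#'
#' Affine-gap Smith-Waterman via [Biostrings::pairwiseAlignment()]
#' (`type = "local"`). Percent identity is identical aligned residue pairs
#' over aligned columns including gap columns, matching the BLAST tabular
#' `pident` convention; coordinates are 1-based inclusive.
#'
#' @param querySeq,subjectSeq amino-acid strings (standard 20-letter
#'   alphabet).
#' @param params an [alignerParams()] list.
#' @return A list with elements `score`, `pid`, `aln_length`, `n_match`,
#'   `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`, `send`.
#' @examples
#' alignLocal("MKVLITGGAGFIGSNLVRYLLA", "MKVLITGGAGFIGSNLVRYLLA")$pid
#' @export
alignLocal <- function(querySeq, subjectSeq, params = alignerParams()) {
  stopifnot(nzchar(querySeq), nzchar(subjectSeq))
  .checkResidues(querySeq)
  .checkResidues(subjectSeq)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(querySeq),
    subject = Biostrings::AAString(subjectSeq),
    type = "local", substitutionMatrix = params$matrix,
    gapOpening = params$gapOpen, gapExtension = params$gapExtend,
    scoreOnly = FALSE)
  ap <- as.character(Biostrings::alignedPattern(aln))
  as_ <- as.character(Biostrings::alignedSubject(aln))
  alnLen <- nchar(ap)
  nm <- Biostrings::nmatch(aln)
  list(score = Biostrings::score(aln),
       pid = if (alnLen > 0) 100 * nm / alnLen else 0,
       aln_length = alnLen,
       n_match = nm,
       mismatch = Biostrings::nmismatch(aln),
       gapopen = .countGapOpens(ap, as_),
       qstart = IRanges::start(Biostrings::pattern(aln)),
       qend = IRanges::end(Biostrings::pattern(aln)),
       sstart = IRanges::start(Biostrings::subject(aln)),
       send = IRanges::end(Biostrings::subject(aln)))
}

#' Bitscore and e-value from a raw alignment score
#'
#' Standard Karlin-Altschul conversion: `bitscore = (lambda * S - ln K) / ln 2`
#' and `evalue = m * n * 2^(-bitscore)` with search space `m * n = qlen *
#' subjectLen` (equivalently `E = K * m * n * exp(-lambda * S)`). The
#' bitscore is strictly increasing in the raw score and the e-value strictly
#' decreasing in the bitscore for a fixed search space.
#'
#' @param rawScore raw alignment score (>= 0).
#' @param params an [alignerParams()] list supplying `lambda` and `k`.
#' @param qlen query length in residues.
#' @param subjectLen subject/database size in residues.
#' @return A list with elements `bitscore` and `evalue`.
#' @export
hitStatistics <- function(rawScore, params, qlen, subjectLen) {
  stopifnot(rawScore >= 0, qlen > 0, subjectLen > 0)
  bitscore <- (params$lambda * rawScore - log(params$k)) / log(2)
  evalue <- qlen * subjectLen * 2^(-bitscore)
  list(bitscore = bitscore, evalue = evalue)
}

.HIT_COLUMNS <- c("query_id", "target_id", "pid", "aln_length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                  "bitscore", "qlen", "qcov")

emptyHits <- function() {
  out <- data.frame(query_id = character(0), target_id = character(0),
                    pid = numeric(0), aln_length = integer(0),
                    mismatch = integer(0), gapopen = integer(0),
                    qstart = integer(0), qend = integer(0),
                    sstart = integer(0), send = integer(0),
                    evalue = numeric(0), bitscore = numeric(0),
                    qlen = integer(0), qcov = numeric(0),
                    stringsAsFactors = FALSE)
  out
}

.checkHits <- function(hits) {
  if (!all(.HIT_COLUMNS %in% names(hits)))
    .stopf("hit table is missing columns: %s",
           paste(setdiff(.HIT_COLUMNS, names(hits)), collapse = ", "))
  invisible(hits)
}

#' Search a catalog with the registry's queries
#'
#' Aligns every (canonical) registry query against every representative
#' sequence with the reference local aligner, computes percent identity,
#' query coverage (`100 * (qend - qstart + 1) / qlen`), bitscore and
#' e-value, and emits hits whose e-value passes the query's class cutoff
#' (1e-60 long / 1e-25 short / 1e-20 C-deglycosylation). At most
#' `params$maxTargets` hits are kept per query (best bitscores first).
#'
#' @param registry an [EnzymeRegistry-class].
#' @param representatives a [MagCatalog-class], an
#'   [Biostrings::AAStringSet], or a path to a protein FASTA.
#' @param params an [alignerParams()] list.
#' @param canonicalOnly search only canonical queries (default `TRUE`).
#' @return A hit `data.frame` in the package's tabular layout (one best
#'   alignment per query-target pair).
#' @export
searchCatalog <- function(registry, representatives,
                          params = alignerParams(), canonicalOnly = TRUE) {
  stopifnot(is(registry, "EnzymeRegistry"))
  if (is(representatives, "MagCatalog"))
    reps <- representatives@representatives
  else if (is(representatives, "AAStringSet"))
    reps <- representatives
  else {
    if (!file.exists(representatives))
      .stopf("unreadable FASTA: %s", representatives)
    reps <- Biostrings::readAAStringSet(representatives)
    names(reps) <- vapply(strsplit(names(reps), "\\s+"), `[`, character(1), 1L)
  }
  if (canonicalOnly) registry <- canonicalRegistry(registry)
  qt <- queryTable(registry)
  if (nrow(qt) == 0L || length(reps) == 0L) return(emptyHits())
  dbSize <- if (is.na(params$dbSize)) sum(Biostrings::width(reps))
            else params$dbSize
  cutoffs <- evalueThreshold(registry, qt$query_id)

  res <- vector("list", nrow(qt))
  for (i in seq_len(nrow(qt))) {
    qid <- qt$query_id[i]
    qseq <- querySequences(registry)[[qid]]
    qlen <- length(qseq)
    # pattern = representative set, subject = query: subject coordinates are
    # query coordinates.
    aln <- Biostrings::pairwiseAlignment(
      pattern = reps, subject = qseq, type = "local",
      substitutionMatrix = params$matrix,
      gapOpening = params$gapOpen, gapExtension = params$gapExtend)
    sc <- Biostrings::score(aln)
    stat <- hitStatistics(pmax(sc, 0), params, qlen, dbSize)
    keep <- which(stat$evalue <= cutoffs[i] & sc > 0)
    if (!length(keep)) next
    ap <- as.character(Biostrings::alignedPattern(aln[keep]))
    as_ <- as.character(Biostrings::alignedSubject(aln[keep]))
    alnLen <- nchar(ap)
    nm <- Biostrings::nmatch(aln[keep])
    qstart <- IRanges::start(Biostrings::subject(aln))[keep]
    qend <- IRanges::end(Biostrings::subject(aln))[keep]
    hits <- data.frame(
      query_id = qid,
      target_id = names(reps)[keep],
      pid = 100 * nm / alnLen,
      aln_length = alnLen,
      mismatch = Biostrings::nmismatch(aln[keep]),
      gapopen = mapply(.countGapOpens, ap, as_, USE.NAMES = FALSE),
      qstart = qstart, qend = qend,
      sstart = IRanges::start(Biostrings::pattern(aln))[keep],
      send = IRanges::end(Biostrings::pattern(aln))[keep],
      evalue = stat$evalue[keep],
      bitscore = stat$bitscore[keep],
      qlen = qlen,
      qcov = 100 * (qend - qstart + 1) / qlen,
      stringsAsFactors = FALSE)
    if (nrow(hits) > params$maxTargets)
      hits <- hits[order(-hits$bitscore)[seq_len(params$maxTargets)], ]
    res[[i]] <- hits
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(emptyHits())
  rownames(out) <- NULL
  out
}
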