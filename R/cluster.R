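#' Pairwise sequence identity over the shorter sequence
#'
#' Identity definition used for clustering (the CD-hit convention): the
#' number of identical aligned residue pairs when the shorter sequence is
#' globally aligned into the longer one (ends-free in the longer sequence;
#' BLOSUM62, affine gaps 11/1), divided by the length of the shorter
#' sequence, times 100. This differs deliberately from the hit-filtering PID
#' (identities over aligned columns of a local alignment); both definitions
#' are documented side by side in the package vignette.
#'
#' @param a,b amino-acid strings.
#' @return Percent identity in `[0, 100]`.
#' @export
sequenceIdentity <- function(a, b) {
  .checkResidues(a)
  .checkResidues(b)
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(a), subject = Biostrings::AAString(b),
    type = "global-local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  100 * Biostrings::nmatch(aln) / nchar(a)
}

#' Greedy incremental sequence clustering
#'
#' CD-hit-style greedy clustering without CD-hit's word-filter heuristics:
#' sequences are sorted by decreasing length (ties by lexicographic ID),
#' each sequence joins the first existing cluster whose representative it
#' matches at `>= thresholdPid` percent identity ([sequenceIdentity()]),
#' otherwise it founds a new cluster. The representative of a cluster is its
#' founding (longest) member. Cluster sizes can be weighted, e.g. by the
#' redundant occurrence counts behind each hit sequence, mirroring how tree
#' node sizes are scaled by clustered plus redundant sequence counts.
#'
#' @param sequences named [Biostrings::AAStringSet] or named character
#'   vector.
#' @param thresholdPid clustering identity threshold in `(0, 100]`
#'   (default 90).
#' @param weights numeric vector of per-sequence weights, named by sequence
#'   ID or in `sequences` order; default 1 per sequence.
#' @return `data.frame` with columns `cluster_id`, `member_id`,
#'   `is_representative`, `weighted_size` (total cluster weight, repeated on
#'   each member row).
#' @export
greedyCluster <- function(sequences, thresholdPid = 90, weights = NULL) {
  stopifnot(thresholdPid > 0, thresholdPid <= 100)
  if (is(sequences, "AAStringSet")) {
    ids <- names(sequences)
    seqs <- as.character(sequences)
  } else {
    ids <- names(sequences)
    seqs <- unname(as.character(sequences))
  }
  if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids))
    .stopf("sequences must have unique non-empty names")
  if (!length(seqs)) .stopf("sequences must be non-empty")
  for (s in seqs) .checkResidues(s)
  if (is.null(weights)) weights <- rep(1, length(seqs))
  if (!is.null(names(weights))) weights <- weights[ids]
  stopifnot(length(weights) == length(seqs), !anyNA(weights))
  names(seqs) <- ids
  names(weights) <- ids

  ord <- order(-nchar(seqs), ids)
  repIds <- character(0)
  assign <- integer(length(seqs))
  names(assign) <- ids[ord]
  for (id in ids[ord]) {
    placed <- FALSE
    for (ci in seq_along(repIds)) {
      if (sequenceIdentity(seqs[[id]], seqs[[repIds[ci]]]) >= thresholdPid) {
        assign[id] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      repIds <- c(repIds, id)
      assign[id] <- length(repIds)
    }
  }
  wsum <- tapply(weights[names(assign)], assign, sum)
  out <- data.frame(
    cluster_id = sprintf("cluster_%03d", assign),
    member_id = names(assign),
    is_representative = names(assign) == repIds[assign],
    weighted_size = as.numeric(wsum[as.character(assign)]),
    stringsAsFactors = FALSE)
  out <- out[order(out$cluster_id, -out$is_representative, out$member_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export cluster representatives as FASTA
#'
#' One record per cluster representative, for downstream multiple alignment
#' and tree building; the header carries the cluster ID and weighted size
#' (`>rep_id cluster_id weighted_size=N`).
#'
#' @param clusters [greedyCluster()] output.
#' @param sequences the sequences that were clustered (named
#'   [Biostrings::AAStringSet] or character vector).
#' @param outPath output FASTA path.
#' @return Invisibly, `outPath`.
#' @export
exportClusterFasta <- function(clusters, sequences, outPath) {
  stopifnot(nrow(clusters) >= 1L)
  reps <- clusters[clusters$is_representative, , drop = FALSE]
  if (is(sequences, "AAStringSet")) sequences <- as.character(sequences)
  seqs <- sequences[reps$member_id]
  if (anyNA(seqs))
    .stopf("representative(s) missing from sequences: %s",
           paste(reps$member_id[is.na(seqs)], collapse = ", "))
  set <- Biostrings::AAStringSet(unname(seqs))
  names(set) <- sprintf("%s %s weighted_size=%g", reps$member_id,
                        reps$cluster_id, reps$weighted_size)
  Biostrings::writeXStringSet(set, outPath)
  invisible(outPath)
}
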