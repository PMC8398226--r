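#' Filter configuration for the hit screen
#'
#' Thresholds applied to the raw hit stream: minimum percent identity
#' (default 30), minimum query coverage (default 75%), and per-class e-value
#' cutoffs. All boundaries are inclusive ("at least" is taken literally:
#' retained hits satisfy `pid >= minPid`, `qcov >= minQcov`,
#' `evalue <= cutoff`).
#'
#' @param minPid minimum percent identity, in `[0, 100]`.
#' @param minQcov minimum query coverage percent, in `[0, 100]`.
#' @param evalueCutoffs named numeric vector of per-class cutoffs
#'   (`long`, `short`, `c_degly`).
#' @return A `list` of class `"FilterConfig"`.
#' @export
filterConfig <- function(minPid = 30, minQcov = 75,
                         evalueCutoffs = FlavoScreen::evalueCutoffs()) {
  stopifnot(minPid >= 0, minPid <= 100, minQcov >= 0, minQcov <= 100,
            all(c("long", "short", "c_degly") %in% names(evalueCutoffs)))
  structure(list(minPid = minPid, minQcov = minQcov,
                 evalueCutoffs = evalueCutoffs),
            class = "FilterConfig")
}

#' Apply PID, coverage and e-value thresholds to a hit stream
#'
#' Retains hits with `evalue <= ` the query's class cutoff, `pid >= minPid`
#' and `qcov >= minQcov`, preserving input order.
#'
#' @param hits a hit `data.frame` ([searchCatalog()] / [readTabularHits()]).
#' @param config a [filterConfig()] list.
#' @param registry an [EnzymeRegistry-class]; every `query_id` in `hits`
#'   must exist in it (its e-value class decides the cutoff).
#' @return The filtered hit `data.frame`.
#' @export
applyThresholds <- function(hits, config = filterConfig(),
                            registry = defaultRegistry()) {
  .checkHits(hits)
  if (nrow(hits) == 0L) return(hits)
  qt <- queryTable(registry)
  i <- match(hits$query_id, qt$query_id)
  if (anyNA(i))
    .stopf("hit references unknown query_id: %s",
           paste(unique(hits$query_id[is.na(i)]), collapse = ", "))
  cutoff <- unname(config$evalueCutoffs[qt$evalue_class[i]])
  keep <- hits$evalue <= cutoff & hits$pid >= config$minPid &
    hits$qcov >= config$minQcov
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best-bitscore deduplication across queries
#'
#' A representative protein matched by several queries would be counted more
#' than once downstream; only its best hit is kept. Exactly one hit per
#' `target_id` survives: the maximal bitscore, ties broken by higher PID,
#' then by lexicographically smallest `query_id` (deterministic).
#'
#' @param hits a filtered hit `data.frame`.
#' @param scope `"global"` (default: dedup across all queries, so a target
#'   contributes to at most one pathway) or `"pathway"` (dedup within each
#'   pathway group separately; requires `registry`).
#' @param registry an [EnzymeRegistry-class], needed for
#'   `scope = "pathway"`.
#' @return Deduplicated hit `data.frame` (a subset of the input rows),
#'   ordered by `target_id` within scope.
#' @export
bestHitPerTarget <- function(hits, scope = c("global", "pathway"),
                             registry = NULL) {
  scope <- match.arg(scope)
  .checkHits(hits)
  if (nrow(hits) == 0L) return(hits)
  if (scope == "pathway") {
    if (is.null(registry))
      .stopf("scope = 'pathway' requires a registry")
    qt <- queryTable(registry)
    grp <- paste(qt$pathway_id[match(hits$query_id, qt$query_id)],
                 hits$target_id, sep = "\r")
  } else {
    grp <- hits$target_id
  }
  ord <- order(grp, -hits$bitscore, -hits$pid, hits$query_id)
  out <- hits[ord, , drop = FALSE]
  out <- out[!duplicated(grp[ord]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bin a percent identity into labelled PID bins
#'
#' Bins are half-open `[edge_i, edge_{i+1})` with the top bin closed at its
#' upper edge, so PID 100 falls in the last bin. Labels are
#' `"<lo>-<hi>"`.
#'
#' @param pid numeric vector of percent identities in `[0, 100]`.
#' @param binEdges strictly increasing numeric vector of bin edges; values
#'   below the first edge yield `NA`.
#' @return Factor of bin labels with levels in bin order.
#' @examples
#' pidBin(c(52, 100, 40), c(30, 40, 50, 65, 80, 90, 100))
#' @export
pidBin <- function(pid, binEdges = c(30, 40, 50, 65, 80, 90, 100)) {
  if (any(pid < 0 | pid > 100))
    .stopf("pid outside [0, 100]")
  if (any(diff(binEdges) <= 0))
    .stopf("binEdges must be strictly increasing")
  labels <- paste0(binEdges[-length(binEdges)], "-", binEdges[-1L])
  cut(pid, breaks = binEdges, labels = labels, right = FALSE,
      include.lowest = TRUE)
}
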