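#' Load the curated enzyme query registry
#'
#' Reads a query FASTA (header first token = accession) and a manifest TSV
#' with columns `accession`, `query_id`, `enzyme_name`, `pathway_id`, `role`,
#' `evalue_class`, `canonical` (0/1), and assembles an
#' [EnzymeRegistry-class]. Pathway co-occurrence rules are instantiated
#' automatically: the puerarin-type C-deglycosylation cluster requires all
#' three catalytic subunits dgpABC; the Eubacterium cellulosolvens cluster
#' requires at least three of dfgABCDE; the daidzein-to-equol cluster
#' requires dzr, ddr and tdr in one genome with the dihydrodaidzein racemase
#' optional; the O-demethylase operon requires MT1, MT2, CP and AE, each at
#' PID strictly above 40; every other pathway is satisfied by any single
#' enzyme hit.
#'
#' The package ships a manifest of the characterized flavonoid-modifying
#' enzymes of human gut bacteria together with a synthetic stand-in FASTA
#' (see `system.file("extdata", package = "FlavoScreen")`). Queries flagged
#' non-canonical (the Slackia sp. NATTS, Lactococcus garvieae and Eggerthella
#' sp. YY7918 daidzein-pathway homologs, which are near-identical to the
#' Slackia isoflavoniconvertens set) are excluded from searches when
#' `canonicalOnly = TRUE` (the default used by [searchCatalog()]).
#'
#' @param queryFasta path to the query protein FASTA.
#' @param manifest path to the manifest TSV.
#' @return An [EnzymeRegistry-class].
#' @seealso [defaultRegistry()] for the shipped manifest.
#' @export
loadRegistry <- function(queryFasta, manifest) {
  man <- .readTsv(manifest)
  need <- c("accession", "query_id", "enzyme_name", "pathway_id", "role",
            "evalue_class", "canonical")
  if (!all(need %in% names(man)))
    .stopf("manifest is missing columns: %s",
           paste(setdiff(need, names(man)), collapse = ", "))
  if (anyDuplicated(man$query_id))
    .stopf("duplicate query_id in manifest: %s",
           paste(unique(man$query_id[duplicated(man$query_id)]), collapse = ", "))

  seqs <- Biostrings::readAAStringSet(queryFasta)
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)

  if (nrow(man) == 0L) {
    reg <- new("EnzymeRegistry",
               queries = data.frame(query_id = character(0),
                                    accession = character(0),
                                    enzyme_name = character(0),
                                    pathway_id = character(0),
                                    role = character(0),
                                    evalue_class = character(0),
                                    canonical = logical(0),
                                    length = integer(0),
                                    stringsAsFactors = FALSE),
               sequences = Biostrings::AAStringSet(),
               rules = list())
    return(reg)
  }

  missing <- setdiff(man$accession, names(seqs))
  if (length(missing))
    .stopf("manifest accessions missing from FASTA: %s",
           paste(missing, collapse = ", "))

  qseqs <- seqs[man$accession]
  names(qseqs) <- man$query_id
  queries <- data.frame(
    query_id = man$query_id,
    accession = man$accession,
    enzyme_name = man$enzyme_name,
    pathway_id = man$pathway_id,
    role = man$role,
    evalue_class = man$evalue_class,
    canonical = as.logical(as.integer(man$canonical)),
    length = Biostrings::width(qseqs),
    stringsAsFactors = FALSE
  )

  rules <- lapply(unique(queries$pathway_id), function(p) {
    roles <- unique(queries$role[queries$pathway_id == p & queries$canonical])
    if (!length(roles)) roles <- unique(queries$role[queries$pathway_id == p])
    .builtinRule(p, roles)
  })
  names(rules) <- unique(queries$pathway_id)

  new("EnzymeRegistry", queries = queries, sequences = qseqs, rules = rules)
}

# Rule construction per pathway; roles come from the manifest so pathways
# with unconventional role labels still validate.
.builtinRule <- function(pathwayId, roles) {
  switch(pathwayId,
    c_deglycosylation_dgp = PathwayRule(pathwayId, roles, "ALL"),
    c_deglycosylation_dfg = PathwayRule(pathwayId, roles, "AT_LEAST_K", k = 3L),
    daidzein_equol = PathwayRule(pathwayId,
                                 setdiff(roles, "racemase"), "ALL",
                                 optionalRoles = intersect(roles, "racemase")),
    o_demethylation = PathwayRule(pathwayId, roles, "ALL",
                                  minPidOverride = 40),
    PathwayRule(pathwayId, roles, "ANY")
  )
}

#' Registry of the shipped enzyme manifest
#'
#' Convenience loader for the curated manifest and synthetic query FASTA
#' installed with the package.
#'
#' @return An [EnzymeRegistry-class].
#' @export
defaultRegistry <- function() {
  loadRegistry(
    system.file("extdata", "query_sequences_synthetic.faa",
                package = "FlavoScreen", mustWork = TRUE),
    system.file("extdata", "enzyme_manifest.tsv",
                package = "FlavoScreen", mustWork = TRUE)
  )
}

#' @rdname EnzymeRegistry-class
#' @param object,x an `EnzymeRegistry`.
#' @export
setGeneric("queryTable", function(x) standardGeneric("queryTable"))

#' @rdname EnzymeRegistry-class
#' @export
setMethod("queryTable", "EnzymeRegistry", function(x) x@queries)

#' @rdname EnzymeRegistry-class
#' @export
setGeneric("querySequences", function(x) standardGeneric("querySequences"))

#' @rdname EnzymeRegistry-class
#' @export
setMethod("querySequences", "EnzymeRegistry", function(x) x@sequences)

#' @rdname EnzymeRegistry-class
#' @export
setGeneric("pathwayRules", function(x) standardGeneric("pathwayRules"))

#' @rdname EnzymeRegistry-class
#' @export
setMethod("pathwayRules", "EnzymeRegistry", function(x) x@rules)

#' Subset a registry to its canonical queries
#'
#' @param x an [EnzymeRegistry-class].
#' @return An `EnzymeRegistry` containing only canonical queries (rules for
#'   pathways that retain at least one query).
#' @export
canonicalRegistry <- function(x) {
  stopifnot(is(x, "EnzymeRegistry"))
  keep <- x@queries$canonical
  q <- x@queries[keep, , drop = FALSE]
  rownames(q) <- NULL
  new("EnzymeRegistry", queries = q,
      sequences = x@sequences[q$query_id],
      rules = x@rules[unique(q$pathway_id)])
}

#' Per-class e-value cutoffs of the screen
#'
#' The screen stratifies its BLAST-style e-value cutoff by pathway group:
#' 1e-60 for pathways of long queries (>350 aa: Fcr, O-glycosidases,
#' rhamnosidases), 1e-25 for pathways of short queries (150-350 aa:
#' daidzein-to-equol, CHI, O-demethylation, Phy, Flr, DfgCD) and 1e-20 for
#' the C-deglycosylation enzymes (which include two sequences below 150 aa).
#'
#' @return Named numeric vector with elements `long`, `short`, `c_degly`.
#' @export
evalueCutoffs <- function() {
  c(long = 1e-60, short = 1e-25, c_degly = 1e-20)
}

#' E-value threshold for a query
#'
#' @param registry an [EnzymeRegistry-class].
#' @param queryId one or more query IDs present in the registry.
#' @return Numeric vector of e-value cutoffs (one per `queryId`).
#' @examples
#' reg <- defaultRegistry()
#' evalueThreshold(reg, "BtR")   # rhamnosidase, long class: 1e-60
#' @export
evalueThreshold <- function(registry, queryId) {
  stopifnot(is(registry, "EnzymeRegistry"))
  i <- match(queryId, registry@queries$query_id)
  if (anyNA(i))
    .stopf("unknown query_id: %s", paste(queryId[is.na(i)], collapse = ", "))
  cls <- registry@queries$evalue_class[i]
  bad <- !cls %in% names(evalueCutoffs())
  if (any(bad)) .stopf("unknown evalue_class: %s", paste(unique(cls[bad]), collapse = ", "))
  unname(evalueCutoffs()[cls])
}
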