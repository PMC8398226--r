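#' @import methods
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet
#' @importFrom S4Vectors isSingleString
NULL

#' PathwayRule: a declarative multi-gene requirement
#'
#' A pathway rule states which enzyme roles must be detected in a single
#' genome for the genome to be called a carrier of the pathway. Requirements
#' are `"ALL"` (every member role), `"AT_LEAST_K"` (any `k` of the member
#' roles) or `"ANY"` (one role suffices; the single-enzyme case). Roles in
#' `optionalRoles` (e.g. the dihydrodaidzein racemase of the daidzein-to-equol
#' cluster) are never required. `minPidOverride`, when not `NA`, restricts the
#' evaluation to occurrences with percent identity strictly greater than the
#' override (used for the O-demethylase operon, PID > 40).
#'
#' @slot pathwayId single pathway identifier.
#' @slot roles character vector of member role labels.
#' @slot requirement one of `"ALL"`, `"AT_LEAST_K"`, `"ANY"`.
#' @slot k integer; number of roles required when `requirement == "AT_LEAST_K"`.
#' @slot optionalRoles roles attached to the pathway but never required.
#' @slot minPidOverride numeric PID floor (strict) or `NA`.
#'
#' @exportClass PathwayRule
setClass("PathwayRule",
  representation(
    pathwayId = "character",
    roles = "character",
    requirement = "character",
    k = "integer",
    optionalRoles = "character",
    minPidOverride = "numeric"
  ),
  prototype(optionalRoles = character(0), minPidOverride = NA_real_)
)

setValidity("PathwayRule", function(object) {
  msg <- character(0)
  if (length(object@pathwayId) != 1L || !nzchar(object@pathwayId))
    msg <- c(msg, "pathwayId must be a single non-empty string")
  if (!object@requirement %in% c("ALL", "AT_LEAST_K", "ANY"))
    msg <- c(msg, "requirement must be ALL, AT_LEAST_K or ANY")
  if (length(object@roles) < 1L)
    msg <- c(msg, "a rule needs at least one member role")
  if (object@requirement == "AT_LEAST_K") {
    if (length(object@k) != 1L || is.na(object@k) || object@k < 1L)
      msg <- c(msg, "k must be a positive integer for AT_LEAST_K")
    else if (object@k > length(object@roles))
      msg <- c(msg, "k cannot exceed the number of member roles")
  }
  if (length(intersect(object@optionalRoles, object@roles)) > 0L)
    msg <- c(msg, "optionalRoles must be disjoint from member roles")
  if (length(object@minPidOverride) != 1L)
    msg <- c(msg, "minPidOverride must be length 1 (possibly NA)")
  if (length(msg)) msg else TRUE
})

#' Construct a PathwayRule
#'
#' @param pathwayId pathway identifier.
#' @param roles member role labels.
#' @param requirement `"ALL"`, `"AT_LEAST_K"` or `"ANY"`.
#' @param k roles required under `"AT_LEAST_K"` (ignored otherwise).
#' @param optionalRoles roles never required.
#' @param minPidOverride strict PID floor applied when evaluating this rule,
#'   or `NA` for no override.
#' @return A [PathwayRule-class] object.
#' @examples
#' PathwayRule("c_deglycosylation_dgp", c("dgpA", "dgpB", "dgpC"), "ALL")
#' @export
PathwayRule <- function(pathwayId, roles, requirement = c("ALL", "AT_LEAST_K", "ANY"),
                        k = NA_integer_, optionalRoles = character(0),
                        minPidOverride = NA_real_) {
  requirement <- match.arg(requirement)
  new("PathwayRule", pathwayId = pathwayId, roles = as.character(roles),
      requirement = requirement, k = as.integer(k),
      optionalRoles = as.character(optionalRoles),
      minPidOverride = as.numeric(minPidOverride))
}

setMethod("show", "PathwayRule", function(object) {
  req <- switch(object@requirement,
    ALL = "ALL roles",
    AT_LEAST_K = sprintf("at least %d of %d roles", object@k, length(object@roles)),
    ANY = "ANY role")
  cat("PathwayRule <", object@pathwayId, ">: ", req, "\n", sep = "")
  cat("  roles: ", paste(object@roles, collapse = ", "), "\n", sep = "")
  if (length(object@optionalRoles))
    cat("  optional: ", paste(object@optionalRoles, collapse = ", "), "\n", sep = "")
  if (!is.na(object@minPidOverride))
    cat("  PID override: > ", object@minPidOverride, "\n", sep = "")
})

#' EnzymeRegistry: curated flavonoid-enzyme query set
#'
#' Holds the curated query proteins (one row per characterized enzyme with
#' accession, pathway membership, role, e-value class and canonical flag),
#' their amino-acid sequences, and one [PathwayRule-class] per pathway.
#'
#' @slot queries data.frame with columns `query_id`, `accession`,
#'   `enzyme_name`, `pathway_id`, `role`, `evalue_class`, `canonical`,
#'   `length`.
#' @slot sequences [Biostrings::AAStringSet] named by `query_id`.
#' @slot rules named list of [PathwayRule-class] objects, one per pathway.
#'
#' @exportClass EnzymeRegistry
setClass("EnzymeRegistry",
  representation(
    queries = "data.frame",
    sequences = "AAStringSet",
    rules = "list"
  )
)

.EVALUE_CLASS_BY_PATHWAY <- c(
  o_deglycosylation = "long",
  derhamnosylation = "long",
  fcr = "long",
  c_deglycosylation_dfg = "c_degly",
  c_deglycosylation_dgp = "c_degly",
  dfgCD = "short",
  daidzein_equol = "short",
  flr = "short",
  chi = "short",
  phy = "short",
  o_demethylation = "short"
)

setValidity("EnzymeRegistry", function(object) {
  msg <- character(0)
  q <- object@queries
  need <- c("query_id", "accession", "enzyme_name", "pathway_id", "role",
            "evalue_class", "canonical", "length")
  if (!all(need %in% names(q)))
    return(paste("queries is missing columns:",
                 paste(setdiff(need, names(q)), collapse = ", ")))
  if (anyDuplicated(q$query_id))
    msg <- c(msg, "duplicate query_id in registry")
  if (!setequal(names(object@sequences), q$query_id) &&
      !(nrow(q) == 0L && length(object@sequences) == 0L))
    msg <- c(msg, "sequences names must match query_id set exactly")
  else if (nrow(q) > 0L) {
    w <- Biostrings::width(object@sequences[q$query_id])
    if (!all(w == q$length))
      msg <- c(msg, "length column disagrees with sequence residue counts")
  }
  known <- q$pathway_id %in% names(.EVALUE_CLASS_BY_PATHWAY)
  if (!all(known))
    msg <- c(msg, paste("unknown pathway_id:",
                        paste(unique(q$pathway_id[!known]), collapse = ", ")))
  else if (!all(q$evalue_class == .EVALUE_CLASS_BY_PATHWAY[q$pathway_id]))
    msg <- c(msg, "evalue_class inconsistent with pathway_id mapping")
  if (!setequal(names(object@rules), unique(q$pathway_id)))
    msg <- c(msg, "exactly one rule per pathway_id present in queries required")
  if (!all(vapply(object@rules, is, logical(1), "PathwayRule")))
    msg <- c(msg, "rules must all be PathwayRule objects")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EnzymeRegistry", function(object) {
  q <- object@queries
  cat("EnzymeRegistry with ", nrow(q), " queries across ",
      length(unique(q$pathway_id)), " pathways\n", sep = "")
  tab <- table(q$pathway_id)
  for (p in names(tab))
    cat("  ", p, ": ", tab[[p]], " quer",
        if (tab[[p]] == 1L) "y" else "ies",
        " [", .EVALUE_CLASS_BY_PATHWAY[[p]], "]\n", sep = "")
  cat("  canonical queries: ", sum(q$canonical), "\n", sep = "")
})

#' MagCatalog: a UHGP-layout protein catalog
#'
#' Bundles the three files of a UHGP-style catalog: the non-redundant
#' representative protein sequences, the redundancy membership table mapping
#' every (redundant) protein ID to its representative, and the per-genome
#' metadata carrying genome type (MAG vs isolate), sample accession and GTDB
#' lineage. Synthetic catalogs additionally carry a truth table describing
#' the implanted enzyme homologs.
#'
#' @slot representatives [Biostrings::AAStringSet], one per non-redundant cluster.
#' @slot membership data.frame with columns `member_id`, `representative_id`
#'   (one row per member, representatives map to themselves).
#' @slot metadata data.frame with columns `Genome`, `Genome_type`,
#'   `Sample_accession`, `Lineage`, `Completeness`, `Contamination`.
#' @slot truth data.frame (zero rows for real catalogs) with columns
#'   `genome_id`, `sample_id`, `species_name`, `genome_type`, `pathway_id`,
#'   `role`, `implanted_pid_realized`, `protein_id`.
#'
#' @exportClass MagCatalog
setClass("MagCatalog",
  representation(
    representatives = "AAStringSet",
    membership = "data.frame",
    metadata = "data.frame",
    truth = "data.frame"
  )
)

.emptyTruth <- function() {
  data.frame(genome_id = character(0), sample_id = character(0),
             species_name = character(0), genome_type = character(0),
             pathway_id = character(0), role = character(0),
             implanted_pid_realized = numeric(0), protein_id = character(0),
             stringsAsFactors = FALSE)
}

setValidity("MagCatalog", function(object) {
  msg <- character(0)
  mem <- object@membership
  if (!all(c("member_id", "representative_id") %in% names(mem)))
    return("membership must have columns member_id, representative_id")
  meta <- object@metadata
  needMeta <- c("Genome", "Genome_type", "Sample_accession", "Lineage")
  if (!all(needMeta %in% names(meta)))
    return(paste("metadata is missing columns:",
                 paste(setdiff(needMeta, names(meta)), collapse = ", ")))
  if (!all(unique(mem$representative_id) %in% names(object@representatives)))
    msg <- c(msg, "every representative in membership must be in the FASTA")
  if (anyDuplicated(mem$member_id))
    msg <- c(msg, "duplicate member_id in membership")
  gid <- genomeOfProtein(mem$member_id)
  if (nrow(mem) && !all(gid %in% meta$Genome))
    msg <- c(msg, "every member protein's genome must appear in metadata")
  if (!all(meta$Genome_type %in% c("MAG", "Isolate")))
    msg <- c(msg, "Genome_type must be MAG or Isolate")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MagCatalog", function(object) {
  cat("MagCatalog: ", length(object@representatives),
      " representative proteins, ", nrow(object@membership),
      " member proteins, ", nrow(object@metadata), " genomes (",
      sum(object@metadata$Genome_type == "MAG"), " MAGs, ",
      sum(object@metadata$Genome_type == "Isolate"), " isolates), ",
      length(unique(object@metadata$Sample_accession)), " samples\n", sep = "")
  if (nrow(object@truth))
    cat("  synthetic: ", nrow(object@truth), " implanted proteins across ",
        length(unique(object@truth$pathway_id)), " pathways\n", sep = "")
})
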