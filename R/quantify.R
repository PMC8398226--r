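#' Expand non-redundant hits to all redundant member proteins
#'
#' Each deduplicated hit names one representative protein; this step emits
#' one occurrence per member of that representative's redundancy cluster
#' (the representative itself included), inheriting the representative's
#' PID, coverage, bitscore and query assignment. The total number of
#' occurrences equals the sum of member counts over the hit representatives,
#' which is the basis of the screen's "Freq" quantification.
#'
#' @param hits deduplicated hit `data.frame` ([bestHitPerTarget()]).
#' @param membership membership table: a path readable by
#'   [readMembership()], a `data.frame` with columns `member_id`,
#'   `representative_id`, or a [MagCatalog-class].
#' @param registry an [EnzymeRegistry-class]; attaches `pathway_id` and
#'   `role` of each hit's query.
#' @return Occurrence `data.frame` with columns `member_protein_id`,
#'   `representative_id`, `genome_id`, `query_id`, `pathway_id`, `role`,
#'   `pid`, `qcov`, `bitscore`.
#' @export
expandMembers <- function(hits, membership, registry = defaultRegistry()) {
  .checkHits(hits)
  if (is(membership, "MagCatalog")) membership <- membership@membership
  if (is.character(membership)) membership <- readMembership(membership)
  stopifnot(all(c("member_id", "representative_id") %in% names(membership)))
  qt <- queryTable(registry)
  qi <- match(hits$query_id, qt$query_id)
  if (anyNA(qi))
    .stopf("hit references unknown query_id: %s",
           paste(unique(hits$query_id[is.na(qi)]), collapse = ", "))

  missing <- setdiff(hits$target_id, membership$representative_id)
  if (length(missing))
    .stopf("representative(s) absent from membership table: %s",
           paste(missing, collapse = ", "))
  if (nrow(hits) == 0L) return(.emptyOccurrences())

  idx <- split(seq_len(nrow(membership)), membership$representative_id)
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    mi <- idx[[hits$target_id[i]]]
    data.frame(member_protein_id = membership$member_id[mi],
               representative_id = hits$target_id[i],
               genome_id = genomeOfProtein(membership$member_id[mi]),
               query_id = hits$query_id[i],
               pathway_id = qt$pathway_id[qi[i]],
               role = qt$role[qi[i]],
               pid = hits$pid[i], qcov = hits$qcov[i],
               bitscore = hits$bitscore[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.emptyOccurrences <- function() {
  data.frame(member_protein_id = character(0), representative_id = character(0),
             genome_id = character(0), query_id = character(0),
             pathway_id = character(0), role = character(0),
             pid = numeric(0), qcov = numeric(0), bitscore = numeric(0),
             stringsAsFactors = FALSE)
}

#' Attach genome metadata to occurrences and drop isolate genomes
#'
#' Merges occurrences with the genome metadata (genome type, sample
#' accession, GTDB lineage) on `genome_id` and, by default, discards
#' occurrences from genomes not labelled `MAG` — isolate genomes included in
#' the catalog are not counted by the screen. The species name is parsed
#' from the lineage; genomes unclassified at species rank are aggregated
#' under their genus label suffixed `"(unclassified)"`.
#'
#' @param occurrences occurrence `data.frame` from [expandMembers()].
#' @param metadata metadata: a path to a TSV with columns `Genome`,
#'   `Genome_type`, `Sample_accession`, `Lineage` (extras ignored), a
#'   `data.frame`, or a [MagCatalog-class].
#' @param magsOnly drop non-MAG genomes (default `TRUE`).
#' @param proteinGenomeMap optional explicit protein-to-genome map (named
#'   character vector) for catalogs whose protein IDs do not encode the
#'   genome ID.
#' @return Occurrence `data.frame` extended with `sample_accession`,
#'   `genome_type`, `species_name`.
#' @export
attachMetadata <- function(occurrences, metadata, magsOnly = TRUE,
                           proteinGenomeMap = NULL) {
  if (is(metadata, "MagCatalog")) metadata <- metadata@metadata
  if (is.character(metadata)) metadata <- .readTsv(metadata)
  need <- c("Genome", "Genome_type", "Sample_accession", "Lineage")
  stopifnot(all(need %in% names(metadata)))
  occ <- occurrences
  if (!is.null(proteinGenomeMap))
    occ$genome_id <- unname(proteinGenomeMap[occ$member_protein_id])
  i <- match(occ$genome_id, metadata$Genome)
  if (anyNA(i))
    .stopf("genome_id(s) missing from metadata: %s",
           paste(unique(occ$genome_id[is.na(i)]), collapse = ", "))
  occ$sample_accession <- metadata$Sample_accession[i]
  occ$genome_type <- metadata$Genome_type[i]
  occ$species_name <- speciesLabel(metadata$Lineage[i])
  if (magsOnly) occ <- occ[occ$genome_type == "MAG", , drop = FALSE]
  rownames(occ) <- NULL
  occ
}

#' Species label of a GTDB lineage
#'
#' The parsed species binomial, or `"<genus> (unclassified)"` when the
#' species rank is empty (empty genus as well yields `"(unclassified)"`).
#'
#' @param lineage character vector of GTDB lineage strings.
#' @return Character vector of species labels.
#' @export
speciesLabel <- function(lineage) {
  vapply(lineage, function(l) {
    rec <- parseLineage(l)
    if (nzchar(rec$species)) rec$species
    else trimws(paste(rec$genus, "(unclassified)"))
  }, character(1), USE.NAMES = FALSE)
}

#' Summarize occurrences per species, query and PID bin
#'
#' Groups MAG occurrences by `(species_name, query_id, pid_bin)` and counts
#' member occurrences (the screen's "Freq"; a two-copy genome contributes 2)
#' and distinct genomes with a hit. Groups below `minFreq` are removed —
#' mirroring the occurrence floors used for reporting (50, 20, 10 or 2
#' depending on the analysis). Sorted by decreasing `freq`.
#'
#' @param occurrences occurrence `data.frame` from [attachMetadata()].
#' @param binEdges PID bin edges, see [pidBin()].
#' @param minFreq minimal occurrence count for a group to be reported.
#' @return `data.frame` with columns `species`, `query_id`, `pid_bin`,
#'   `freq`, `n_genomes_with_hit`.
#' @export
summarizeOccurrences <- function(occurrences,
                                 binEdges = c(30, 40, 50, 65, 80, 90, 100),
                                 minFreq = 1L) {
  if (nrow(occurrences) == 0L)
    return(data.frame(species = character(0), query_id = character(0),
                      pid_bin = character(0), freq = integer(0),
                      n_genomes_with_hit = integer(0),
                      stringsAsFactors = FALSE))
  stopifnot("species_name" %in% names(occurrences))
  bin <- as.character(pidBin(occurrences$pid, binEdges))
  key <- paste(occurrences$species_name, occurrences$query_id, bin, sep = "\r")
  spl <- split(seq_len(nrow(occurrences)), key)
  out <- do.call(rbind, lapply(spl, function(ix) {
    data.frame(species = occurrences$species_name[ix[1L]],
               query_id = occurrences$query_id[ix[1L]],
               pid_bin = bin[ix[1L]],
               freq = length(ix),
               n_genomes_with_hit = length(unique(occurrences$genome_id[ix])),
               stringsAsFactors = FALSE)
  }))
  out <- out[out$freq >= minFreq, , drop = FALSE]
  out <- out[order(-out$freq, out$species, out$query_id, out$pid_bin), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
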