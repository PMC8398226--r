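#' Parse a GTDB lineage string
#'
#' Splits a 7-rank, prefix-tagged GTDB lineage
#' (`d__...;p__...;c__...;o__...;f__...;g__...;s__...`) into its ranks with
#' prefixes stripped. Missing ranks yield empty strings; ranks beyond those
#' present are empty. A string not starting with `d__` is a parse error.
#'
#' @param lineage a single lineage string.
#' @return A list with elements `domain`, `phylum`, `class_`, `order`,
#'   `family`, `genus`, `species`.
#' @examples
#' parseLineage(paste0("d__Bacteria;p__Bacteroidota;c__Bacteroidia;",
#'   "o__Bacteroidales;f__Bacteroidaceae;g__Bacteroides;",
#'   "s__Bacteroides uniformis"))$species
#' @export
parseLineage <- function(lineage) {
  stopifnot(length(lineage) == 1L)
  if (!startsWith(lineage, "d__"))
    .stopf("not a GTDB lineage (missing d__ prefix): %s", lineage)
  parts <- strsplit(lineage, ";", fixed = TRUE)[[1]]
  pref <- c("d__", "p__", "c__", "o__", "f__", "g__", "s__")
  vals <- character(7L)
  for (i in seq_along(pref)) {
    if (i <= length(parts)) {
      if (substr(parts[i], 1, 3) != pref[i])
        .stopf("rank %d of lineage lacks prefix %s: %s", i, pref[i], lineage)
      vals[i] <- trimws(substring(parts[i], 4L))
    }
  }
  list(domain = vals[1], phylum = vals[2], class_ = vals[3], order = vals[4],
       family = vals[5], genus = vals[6], species = vals[7])
}

#' Species prevalence and abundance across a catalog's metadata
#'
#' For each species in `speciesList`, counts the distinct metagenome samples
#' containing at least one MAG of that species (prevalence, as percent of
#' all distinct samples in the metadata — several MAGs of a species within
#' one sample count once) and the number of its MAGs (abundance, as percent
#' of all MAG rows). Matching against the parsed GTDB species is exact and
#' case-sensitive; species absent from the taxonomy get prevalence 0 and the
#' flag `not_in_taxonomy` — species without a sequenced genome, or lacking a
#' GTDB assignment, cannot be found by text matching.
#'
#' @param metadata metadata `data.frame`, path, or [MagCatalog-class].
#' @param speciesList character vector of species names (binomials).
#' @param dedupPerSample count a species once per sample (default `TRUE`);
#'   set `FALSE` to count MAG rows into `n_samples_with` without
#'   deduplication.
#' @return `data.frame` with columns `species`, `n_samples_with`,
#'   `n_samples_total`, `prevalence_pct`, `n_mags`, `n_mags_total`,
#'   `abundance_pct`, `flags`.
#' @export
computePrevalence <- function(metadata, speciesList, dedupPerSample = TRUE) {
  if (is(metadata, "MagCatalog")) metadata <- metadata@metadata
  if (is.character(metadata) && length(metadata) == 1L &&
      file.exists(metadata)) metadata <- .readTsv(metadata)
  stopifnot(is.data.frame(metadata), length(speciesList) >= 1L)
  mags <- metadata[metadata$Genome_type == "MAG", , drop = FALSE]
  species <- vapply(mags$Lineage,
                    function(l) parseLineage(l)$species, character(1),
                    USE.NAMES = FALSE)
  nSamplesTotal <- length(unique(metadata$Sample_accession))
  nMagsTotal <- nrow(mags)

  rows <- lapply(speciesList, function(sp) {
    hit <- species == sp
    nm <- sum(hit)
    ns <- if (dedupPerSample) length(unique(mags$Sample_accession[hit]))
          else nm
    data.frame(species = sp,
               n_samples_with = ns, n_samples_total = nSamplesTotal,
               prevalence_pct = 100 * ns / nSamplesTotal,
               n_mags = nm, n_mags_total = nMagsTotal,
               abundance_pct = 100 * nm / nMagsTotal,
               flags = if (nm == 0L) "not_in_taxonomy" else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Load the curated flavonoid-modifying species list
#'
#' Reads the package's curated fixture of gut bacterial species described to
#' modify flavonoids, with their modification class and flavonoid substrate
#' classes. A species appearing under several modification classes is
#' reported once with its classes merged, so prevalence counting never
#' double-counts a species. Provisional 16S-based species assignments are
#' carried as `note` annotations, not as fuzzy matching.
#'
#' @param fixture path to the TSV; defaults to the shipped fixture.
#' @return `data.frame` with columns `species`, `modification_classes`
#'   (semicolon-joined), `flavonoid_classes`, `prevalence_reported`,
#'   `notes`.
#' @export
loadCuratedSpecies <- function(fixture = system.file(
    "extdata", "curated_species.tsv", package = "FlavoScreen",
    mustWork = TRUE)) {
  tab <- .readTsv(fixture)
  if (nrow(tab) == 0L)
    return(data.frame(species = character(0),
                      modification_classes = character(0),
                      flavonoid_classes = character(0),
                      prevalence_reported = character(0),
                      notes = character(0), stringsAsFactors = FALSE))
  if (!"note" %in% names(tab)) tab$note <- ""
  tab$note[is.na(tab$note)] <- ""
  spl <- split(tab, tab$species)
  out <- do.call(rbind, lapply(spl, function(d) {
    data.frame(species = d$species[1L],
               modification_classes = paste(unique(d$modification_class),
                                            collapse = ";"),
               flavonoid_classes = paste(unique(unlist(strsplit(
                 d$flavonoid_classes, ",\\s*"))), collapse = "; "),
               prevalence_reported = d$prevalence_reported[1L],
               notes = paste(unique(d$note[nzchar(d$note)]), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$species), , drop = FALSE]
  rownames(out) <- NULL
  out
}
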