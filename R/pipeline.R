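#' Read a pipeline run configuration
#'
#' Loads a YAML run configuration and fills defaults. Recognized keys:
#'
#' * `paths`: `catalog_dir` (bundle directory) or individual `fasta` /
#'   `membership` / `metadata`; optional `query_fasta` + `manifest`
#'   (defaults to the shipped registry); `out_dir`; for the
#'   `external-file` engine, `hits` (an outfmt6+qlen TSV).
#' * `filter`: `min_pid` (30), `min_qcov` (75), `evalue_long` (1e-60),
#'   `evalue_short` (1e-25), `evalue_cdegly` (1e-20).
#' * `bin_edges` (30,40,50,65,80,90,100), `min_freq` (1),
#'   `dedup_scope` (`"global"`), `engine` (`"reference"` or
#'   `"external-file"`), `mags_only` (TRUE), `canonical_only` (TRUE),
#'   `seed` (1).
#' * `simulate`: `n_samples`, `background_per_genome`, `redundancy`,
#'   `species` (list of name / n_genomes / mag_fraction / sample_spread),
#'   `implants` (list of species / pathway / target_pid / carrier_fraction /
#'   roles / copies_per_genome / role_completeness).
#'
#' @param path YAML file path.
#' @return A named list of class `"RunConfig"`.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  asRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param cfg a named list with the keys above (defaults filled in).
#' @export
asRunConfig <- function(cfg = list()) {
  defaults <- list(
    paths = list(),
    filter = list(min_pid = 30, min_qcov = 75, evalue_long = 1e-60,
                  evalue_short = 1e-25, evalue_cdegly = 1e-20),
    bin_edges = c(30, 40, 50, 65, 80, 90, 100),
    min_freq = 1L,
    dedup_scope = "global",
    engine = "reference",
    mags_only = TRUE,
    canonical_only = TRUE,
    seed = 1L,
    simulate = list())
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
    else if (is.list(defaults[[k]]) && length(defaults[[k]]))
      for (k2 in names(defaults[[k]]))
        if (is.null(cfg[[k]][[k2]])) cfg[[k]][[k2]] <- defaults[[k]][[k2]]
  }
  stopifnot(cfg$engine %in% c("reference", "external-file"),
            cfg$dedup_scope %in% c("global", "pathway"))
  class(cfg) <- "RunConfig"
  cfg
}

.registryFromConfig <- function(config) {
  p <- config$paths
  if (!is.null(p$query_fasta) && !is.null(p$manifest))
    loadRegistry(p$query_fasta, p$manifest)
  else defaultRegistry()
}

#' Simulate a synthetic catalog bundle from a run configuration
#'
#' Delegates to [generateCatalog()] using the `simulate` block of the
#' configuration and writes the bundle (plus truth table) to
#' `paths$out_dir`.
#'
#' @param config a `RunConfig` ([readRunConfig()] / [asRunConfig()]).
#' @return The generated [MagCatalog-class], invisibly; files are written
#'   to `paths$out_dir`.
#' @export
runSimulate <- function(config) {
  sim <- config$simulate
  stopifnot(length(sim$species) >= 1L)
  profiles <- lapply(sim$species, function(s)
    speciesProfile(s$name, s$n_genomes,
                   magFraction = s$mag_fraction %||% 1,
                   sampleSpread = s$sample_spread %||% "distinct",
                   lineage = s$lineage %||% NULL))
  implants <- lapply(sim$implants %||% list(), function(im)
    implantSpec(im$species, im$pathway, im$target_pid, im$carrier_fraction,
                roles = im$roles %||% NULL,
                copiesPerGenome = im$copies_per_genome %||% 1L,
                roleCompleteness = im$role_completeness %||% 1))
  registry <- .registryFromConfig(config)
  catalog <- generateCatalog(
    profiles, implants, registry = registry,
    nSamples = sim$n_samples %||% 10L,
    backgroundPerGenome = sim$background_per_genome %||% 5L,
    redundancy = sim$redundancy %||% 1,
    seed = config$seed)
  outDir <- config$paths$out_dir
  if (!is.null(outDir)) writeCatalog(catalog, outDir)
  invisible(catalog)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the screening pipeline end to end
#'
#' Executes search (reference aligner, or an externally produced hit table
#' for the `external-file` engine), threshold filtering, best-bitscore
#' deduplication, membership expansion, metadata merge with MAG-only
#' filtering, occurrence summarization, pathway co-occurrence calling,
#' species carrier statistics, and prevalence/abundance over the curated
#' species list. All stage tables are written as TSVs under
#' `paths$out_dir`, together with a run-manifest JSON recording the
#' configuration, input checksums, the seed, and per-stage row counts.
#'
#' @param config a `RunConfig`; `paths` must provide the catalog (a
#'   `catalog_dir` bundle or `fasta`/`membership`/`metadata`) and
#'   `out_dir`.
#' @param catalog optionally, an in-memory [MagCatalog-class] overriding
#'   the configured paths.
#' @return Invisibly, a list with the stage tables (`hits`, `filtered`,
#'   `deduplicated`, `occurrences`, `summary`, `calls`, `carrier_stats`,
#'   `prevalence`) and the `manifest` list.
#' @export
runScreen <- function(config, catalog = NULL) {
  p <- config$paths
  registry <- .registryFromConfig(config)
  checksums <- list()
  if (is.null(catalog)) {
    if (!is.null(p$catalog_dir)) {
      catalog <- readCatalog(p$catalog_dir)
      checksums <- as.list(tools::md5sum(list.files(p$catalog_dir,
                                                    full.names = TRUE)))
    } else {
      stopifnot(!is.null(p$fasta), !is.null(p$membership),
                !is.null(p$metadata))
      reps <- Biostrings::readAAStringSet(p$fasta)
      names(reps) <- vapply(strsplit(names(reps), "\\s+"), `[`,
                            character(1), 1L)
      catalog <- new("MagCatalog", representatives = reps,
                     membership = readMembership(p$membership),
                     metadata = .readTsv(p$metadata),
                     truth = .emptyTruth())
      checksums <- as.list(tools::md5sum(c(p$fasta, p$membership,
                                           p$metadata)))
    }
  }

  if (config$engine == "external-file") {
    stopifnot(!is.null(p$hits))
    hits <- readTabularHits(p$hits)
    checksums[[p$hits]] <- unname(tools::md5sum(p$hits))
  } else {
    hits <- searchCatalog(registry, catalog,
                          canonicalOnly = isTRUE(config$canonical_only))
  }

  fc <- filterConfig(
    minPid = config$filter$min_pid, minQcov = config$filter$min_qcov,
    evalueCutoffs = c(long = config$filter$evalue_long,
                      short = config$filter$evalue_short,
                      c_degly = config$filter$evalue_cdegly))
  filtered <- applyThresholds(hits, fc, registry)
  dedup <- bestHitPerTarget(filtered, scope = config$dedup_scope,
                            registry = registry)
  occAll <- expandMembers(dedup, catalog, registry)
  occ <- attachMetadata(occAll, catalog, magsOnly = isTRUE(config$mags_only))
  summ <- summarizeOccurrences(occ, binEdges = config$bin_edges,
                               minFreq = config$min_freq)
  calls <- callPathways(occ, pathwayRules(registry))
  stats_ <- if (nrow(calls)) speciesCarrierStats(calls, catalog)
            else data.frame(species = character(0), pathway_id = character(0),
                            n_carriers = integer(0), n_total = integer(0),
                            carrier_fraction = numeric(0))
  curated <- loadCuratedSpecies()
  prev <- computePrevalence(catalog, curated$species)

  outDir <- p$out_dir
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeTabularHits(filtered, file.path(outDir, "filtered_hits.tsv"))
    .writeTsv(occ, file.path(outDir, "occurrences.tsv"))
    .writeTsv(summ, file.path(outDir, "species_summary.tsv"))
    .writeTsv(calls, file.path(outDir, "pathway_calls.tsv"))
    .writeTsv(stats_, file.path(outDir, "carrier_stats.tsv"))
    .writeTsv(prev, file.path(outDir, "prevalence.tsv"))
  }

  cfgPlain <- unclass(config)
  manifest <- list(
    seed = config$seed,
    engine = config$engine,
    config = cfgPlain,
    config_hash = unname(.md5OfObject(cfgPlain)),
    input_checksums = checksums,
    row_counts = list(
      raw_hits = nrow(hits), filtered = nrow(filtered),
      deduplicated = nrow(dedup), occurrences_all = nrow(occAll),
      occurrences_mag = nrow(occ), summary_groups = nrow(summ),
      pathway_calls = nrow(calls), carrier_stats = nrow(stats_),
      prevalence_rows = nrow(prev)))
  if (!is.null(outDir))
    jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(hits = hits, filtered = filtered, deduplicated = dedup,
                 occurrences = occ, summary = summ, calls = calls,
                 carrier_stats = stats_, prevalence = prev,
                 manifest = manifest))
}

.md5OfObject <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(x), collapse = "\n"), f)
  tools::md5sum(f)
}
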