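#' Evaluate pathway co-occurrence rules per genome
#'
#' For every genome with at least one occurrence of a pathway's roles, the
#' pathway's [PathwayRule-class] is evaluated on the set of roles found in
#' that genome: `ALL` requires every member role, `AT_LEAST_K` any `k` of
#' them, `ANY` a single role. Rules with a `minPidOverride` only consider
#' occurrences with PID strictly greater than the override, so e.g. the
#' O-demethylase operon is called complete only when MT1, MT2, CP and AE all
#' hit above 40 PID in the same MAG. A genome "has" a role if at least one
#' retained occurrence maps to it, regardless of copy number.
#'
#' @param occurrences occurrence `data.frame` ([attachMetadata()] output;
#'   [expandMembers()] output works too).
#' @param rules named list of [PathwayRule-class] objects (e.g.
#'   `pathwayRules(registry)`).
#' @return `data.frame` with one row per (genome, pathway) with >= 1 role
#'   hit: `genome_id`, `pathway_id`, `present`, `roles_found`,
#'   `roles_missing` (member roles only, comma-separated),
#'   `min_pid_among_roles`.
#' @export
callPathways <- function(occurrences, rules) {
  stopifnot(is.list(rules), all(vapply(rules, is, logical(1), "PathwayRule")))
  empty <- data.frame(genome_id = character(0), pathway_id = character(0),
                      present = logical(0), roles_found = character(0),
                      roles_missing = character(0),
                      min_pid_among_roles = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(occurrences) == 0L) return(empty)
  unknown <- setdiff(unique(occurrences$pathway_id), names(rules))
  if (length(unknown))
    .stopf("occurrences reference pathway(s) with no rule: %s",
           paste(unknown, collapse = ", "))

  key <- paste(occurrences$genome_id, occurrences$pathway_id, sep = "\r")
  spl <- split(seq_len(nrow(occurrences)), key)
  rows <- lapply(spl, function(ix) {
    gid <- occurrences$genome_id[ix[1L]]
    pid_ <- occurrences$pathway_id[ix[1L]]
    rule <- rules[[pid_]]
    roles <- occurrences$role[ix]
    pids <- occurrences$pid[ix]
    if (!is.na(rule@minPidOverride)) {
      keep <- pids > rule@minPidOverride
      roles <- roles[keep]; pids <- pids[keep]
    }
    found <- sort(unique(roles))
    if (!length(found)) return(NULL)
    memberFound <- intersect(rule@roles, found)
    present <- switch(rule@requirement,
      ALL = length(memberFound) == length(rule@roles),
      AT_LEAST_K = length(memberFound) >= rule@k,
      ANY = length(memberFound) >= 1L)
    data.frame(genome_id = gid, pathway_id = pid_, present = present,
               roles_found = paste(found, collapse = ","),
               roles_missing = paste(setdiff(rule@roles, found),
                                     collapse = ","),
               min_pid_among_roles = min(pids),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$genome_id, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Species-level pathway carrier statistics
#'
#' Per (species, pathway): the number of MAGs called pathway carriers over
#' the total number of MAGs of that species in the metadata — genomes with
#' zero hits still enter the denominator, which is what makes fractions like
#' "804 of 2819 MAGs" meaningful.
#'
#' @param calls [callPathways()] output.
#' @param metadata metadata `data.frame`, path, or [MagCatalog-class].
#' @param pathways pathways to report; defaults to those present in `calls`.
#' @return `data.frame` with columns `species`, `pathway_id`, `n_carriers`,
#'   `n_total`, `carrier_fraction` (percent).
#' @export
speciesCarrierStats <- function(calls, metadata,
                                pathways = unique(calls$pathway_id)) {
  if (is(metadata, "MagCatalog")) metadata <- metadata@metadata
  if (is.character(metadata)) metadata <- .readTsv(metadata)
  missing <- setdiff(unique(calls$genome_id), metadata$Genome)
  if (length(missing))
    .stopf("genome(s) in calls missing from metadata: %s",
           paste(missing, collapse = ", "))
  mags <- metadata[metadata$Genome_type == "MAG", , drop = FALSE]
  mags$species <- speciesLabel(mags$Lineage)

  out <- list()
  for (sp in unique(mags$species)) {
    total <- sum(mags$species == sp)
    gset <- mags$Genome[mags$species == sp]
    for (p in pathways) {
      carriers <- unique(calls$genome_id[calls$pathway_id == p &
                                           calls$present &
                                           calls$genome_id %in% gset])
      out[[length(out) + 1L]] <- data.frame(
        species = sp, pathway_id = p, n_carriers = length(carriers),
        n_total = total,
        carrier_fraction = 100 * length(carriers) / total,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$carrier_fraction, res$species, res$pathway_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Partial-cluster report: genomes carrying only a subset of a pathway's roles
#'
#' For a multi-gene pathway, counts genomes per species by the exact subset
#' of member roles they carry, excluding genomes with the complete role set.
#' This surfaces patterns like the many genomes hitting only the daidzein
#' reductase, which may explain daidzein-to-O-desmethylangolensin-only
#' phenotypes.
#'
#' @param occurrences occurrence `data.frame` with `species_name` attached.
#' @param pathwayId the pathway to report.
#' @param rules named list of [PathwayRule-class] objects.
#' @return `data.frame` with columns `species`, `signature` (e.g.
#'   `"{ddr,dzr}"`), `n_genomes`.
#' @export
partialRoleReport <- function(occurrences, pathwayId, rules) {
  rule <- rules[[pathwayId]]
  if (is.null(rule)) .stopf("no rule for pathway %s", pathwayId)
  if (length(rule@roles) < 2L)
    .stopf("partial-role report needs a pathway with >= 2 roles")
  occ <- occurrences[occurrences$pathway_id == pathwayId, , drop = FALSE]
  empty <- data.frame(species = character(0), signature = character(0),
                      n_genomes = integer(0), stringsAsFactors = FALSE)
  if (nrow(occ) == 0L) return(empty)
  spl <- split(occ, occ$genome_id)
  sigRows <- lapply(spl, function(d) {
    memberFound <- sort(intersect(unique(d$role), rule@roles))
    if (length(memberFound) == 0L ||
        length(memberFound) == length(rule@roles)) return(NULL)
    data.frame(species = d$species_name[1L],
               signature = paste0("{", paste(memberFound, collapse = ","), "}"),
               stringsAsFactors = FALSE)
  })
  sigRows <- sigRows[!vapply(sigRows, is.null, logical(1))]
  if (!length(sigRows)) return(empty)
  sig <- do.call(rbind, sigRows)
  key <- paste(sig$species, sig$signature, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(species = vapply(parts, `[`, character(1), 1L),
                    signature = vapply(parts, `[`, character(1), 2L),
                    n_genomes = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_genomes, out$species, out$signature), , drop = FALSE]
  rownames(out) <- NULL
  out
}
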