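#' Species profile for the synthetic catalog generator
#'
#' Describes one species' genome collection in a simulated catalog:
#' how many genomes, which fraction are MAGs (the rest isolate genomes), and
#' how the genomes spread over metagenome samples. With
#' `sampleSpread = "distinct"` genomes are placed on distinct samples
#' (cycling once the sample pool is exhausted); with `"shared"` all genomes
#' of the species fall into a single sample, which exercises the per-sample
#' deduplication in prevalence computation.
#'
#' @param speciesName GTDB-style binomial or placeholder
#'   (e.g. `"CAG-1427 sp000435475"`).
#' @param nGenomes number of genomes (>= 0).
#' @param magFraction fraction of genomes labelled MAG, in `[0, 1]`.
#' @param sampleSpread `"distinct"` or `"shared"`.
#' @param lineage full 7-rank GTDB lineage string; by default a synthetic
#'   lineage is built around `speciesName`.
#' @return A `list` of class `"SpeciesProfile"`.
#' @export
speciesProfile <- function(speciesName, nGenomes, magFraction = 1,
                           sampleSpread = c("distinct", "shared"),
                           lineage = NULL) {
  sampleSpread <- match.arg(sampleSpread)
  stopifnot(nGenomes >= 0, magFraction >= 0, magFraction <= 1)
  if (is.null(lineage)) {
    genus <- strsplit(speciesName, " ")[[1]][1]
    lineage <- paste0("d__Bacteria;p__Firmicutes_SYN;c__Clostridia_SYN;",
                      "o__Synthomonadales;f__Synthomonadaceae;g__", genus,
                      ";s__", speciesName)
  }
  .checkLineage(lineage)
  structure(list(species_name = speciesName, lineage = lineage,
                 n_genomes = as.integer(nGenomes),
                 mag_fraction = magFraction, sample_spread = sampleSpread),
            class = "SpeciesProfile")
}

.checkLineage <- function(lineage) {
  pref <- c("d__", "p__", "c__", "o__", "f__", "g__", "s__")
  parts <- strsplit(lineage, ";", fixed = TRUE)[[1]]
  if (length(parts) != 7L || !all(substr(parts, 1, 3) == pref))
    .stopf("lineage must contain the 7 GTDB rank prefixes in order: %s", lineage)
  invisible(lineage)
}

#' Implant specification for the synthetic catalog generator
#'
#' Describes homologs of one pathway's enzymes implanted into a fraction of a
#' species' genomes at a controlled percent identity to the canonical query
#' sequences.
#'
#' @param speciesName species receiving the implant (must match a profile).
#' @param pathwayId pathway whose roles are implanted.
#' @param targetPid target percent identity to the canonical query, in
#'   `(0, 100]`.
#' @param carrierFraction fraction of the species' genomes receiving the
#'   implant, in `[0, 1]`.
#' @param roles roles to implant; default all member roles of the pathway's
#'   rule (optional roles are not implanted unless requested).
#' @param copiesPerGenome gene copies per carrier genome (>= 1).
#' @param roleCompleteness probability that a carrier genome receives each
#'   role (1 = complete clusters; lower values simulate fragmented MAGs with
#'   partial clusters, sampled per genome and role).
#' @return A `list` of class `"ImplantSpec"`.
#' @export
implantSpec <- function(speciesName, pathwayId, targetPid, carrierFraction,
                        roles = NULL, copiesPerGenome = 1L,
                        roleCompleteness = 1) {
  stopifnot(targetPid > 0, targetPid <= 100,
            carrierFraction >= 0, carrierFraction <= 1,
            copiesPerGenome >= 1,
            roleCompleteness > 0, roleCompleteness <= 1)
  structure(list(species_name = speciesName, pathway_id = pathwayId,
                 roles = roles, target_pid = targetPid,
                 carrier_fraction = carrierFraction,
                 copies_per_genome = as.integer(copiesPerGenome),
                 role_completeness = roleCompleteness),
            class = "ImplantSpec")
}

#' Mutate a protein sequence to a target percent identity
#'
#' Substitutes residues at positions chosen without replacement until the
#' per-position identity to the input is the nearest achievable to
#' `targetPid` given the integer position count. Substitutions are drawn from
#' the 20-letter amino-acid alphabet excluding the original residue, so every
#' touched position is a true mismatch. Deterministic for fixed
#' `(sequence, targetPid, seed)`.
#'
#' @param sequence amino-acid string (length >= 20).
#' @param targetPid target percent identity in `(0, 100]`.
#' @param seed integer seed.
#' @return The mutated sequence, same length, with attribute `realized_pid`
#'   giving the exact per-position identity actually realized.
#' @examples
#' s <- strrep("ACDEFGHIKL", 6)
#' m <- mutateToIdentity(s, 70, seed = 1)
#' attr(m, "realized_pid")  # 70: 42 of 60 positions conserved
#' @export
mutateToIdentity <- function(sequence, targetPid, seed) {
  if (targetPid <= 0 || targetPid > 100)
    .stopf("targetPid must be in (0, 100], got %s", targetPid)
  if (nchar(sequence) < 20L)
    .stopf("sequence must have at least 20 residues")
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(ch)
  nsub <- round(L * (1 - targetPid / 100))
  withSeed(seed, {
    if (nsub > 0L) {
      pos <- sample.int(L, nsub)
      for (p in pos) ch[p] <- sample(setdiff(.AA20, ch[p]), 1L)
    }
  })
  out <- paste(ch, collapse = "")
  attr(out, "realized_pid") <- 100 * (L - nsub) / L
  out
}

#' Generate a synthetic UHGP-style catalog with implanted enzyme homologs
#'
#' Builds an in-memory [MagCatalog-class] emulating the UHGP-100 layout:
#' species-structured genome collections across samples, background proteins
#' grouped into redundancy clusters, and implanted flavonoid-enzyme homologs
#' at controlled identity, copy number and cluster completeness, together
#' with a machine-readable truth table.
#'
#' Background proteins are uniform random sequences of 100-600 residues;
#' their expected identity to any query is far below the screen's 30 PID
#' floor, giving a near-zero false-positive floor. All members of one
#' redundancy cluster carry an identical sequence (the UHGP-100 convention:
#' redundant IDs map to a representative of the identical amino-acid
#' sequence). Implanted homologs of the same species, role and target PID
#' form a single redundancy cluster, exercising membership expansion.
#'
#' @param profiles list of [speciesProfile()] objects.
#' @param implants list of [implantSpec()] objects (may be empty).
#' @param registry an [EnzymeRegistry-class] supplying canonical query
#'   sequences for the implants.
#' @param nSamples number of metagenome samples (>= 1).
#' @param backgroundPerGenome background proteins per genome.
#' @param redundancy mean redundancy-cluster size for background proteins
#'   (>= 1).
#' @param seed integer seed; the whole bundle is deterministic in it.
#' @return A [MagCatalog-class] whose `truth` slot holds one row per
#'   implanted protein copy.
#' @export
generateCatalog <- function(profiles, implants = list(),
                            registry = defaultRegistry(),
                            nSamples = 10L, backgroundPerGenome = 5L,
                            redundancy = 1, seed = 1L) {
  stopifnot(length(profiles) >= 1L, nSamples >= 1L, redundancy >= 1)
  if (inherits(profiles, "SpeciesProfile")) profiles <- list(profiles)
  if (inherits(implants, "ImplantSpec")) implants <- list(implants)
  stopifnot(all(vapply(profiles, inherits, logical(1), "SpeciesProfile")),
            all(vapply(implants, inherits, logical(1), "ImplantSpec")))
  if (sum(vapply(profiles, `[[`, integer(1), "n_genomes")) < 1L)
    .stopf("at least one genome required across profiles")
  profNames <- vapply(profiles, `[[`, character(1), "species_name")
  for (im in implants) {
    if (!im$species_name %in% profNames)
      .stopf("implant references unknown species: %s", im$species_name)
    if (!im$pathway_id %in% names(pathwayRules(registry)))
      .stopf("implant references unknown pathway: %s", im$pathway_id)
  }

  withSeed(seed, {
    samples <- sprintf("SAMP%06d", seq_len(nSamples))
    meta <- list(); gcount <- 0L
    genomesOf <- list()
    for (pr in profiles) {
      n <- pr$n_genomes
      if (n == 0L) { genomesOf[[pr$species_name]] <- character(0); next }
      gids <- sprintf("GUT_GENOME%06d", gcount + seq_len(n))
      gcount <- gcount + n
      samp <- switch(pr$sample_spread,
        distinct = samples[((seq_len(n) - 1L) %% nSamples) + 1L],
        shared = rep(samples[sample.int(nSamples, 1L)], n))
      nMag <- round(pr$mag_fraction * n)
      gtype <- rep("Isolate", n)
      if (nMag > 0L) gtype[sample.int(n, nMag)] <- "MAG"
      meta[[pr$species_name]] <- data.frame(
        Genome = gids, Genome_type = gtype, Sample_accession = samp,
        Lineage = pr$lineage, Completeness = 90.0, Contamination = 1.0,
        stringsAsFactors = FALSE)
      genomesOf[[pr$species_name]] <- gids
    }
    metadata <- do.call(rbind, meta)
    rownames(metadata) <- NULL

    protCounter <- integer(nrow(metadata))
    names(protCounter) <- metadata$Genome
    nextProt <- function(gid) {
      protCounter[gid] <<- protCounter[gid] + 1L
      sprintf("%s_%05d", gid, protCounter[gid])
    }

    repSeqs <- character(0)
    memMember <- character(0); memRep <- character(0)

    # Background clusters per species: identical sequences shared across
    # round-robin-assigned members to hit the requested mean cluster size.
    for (pr in profiles) {
      gids <- genomesOf[[pr$species_name]]
      B <- length(gids) * backgroundPerGenome
      if (B == 0L) next
      nClust <- max(1L, round(B / redundancy))
      templates <- vapply(sample(100:600, nClust, replace = TRUE),
                          randomProtein, character(1))
      clusterRep <- rep(NA_character_, nClust)
      j <- 0L
      for (gid in gids) {
        for (b in seq_len(backgroundPerGenome)) {
          j <- j + 1L
          ci <- ((j - 1L) %% nClust) + 1L
          pid_ <- nextProt(gid)
          if (is.na(clusterRep[ci])) {
            clusterRep[ci] <- pid_
            repSeqs[pid_] <- templates[ci]
          }
          memMember <- c(memMember, pid_)
          memRep <- c(memRep, clusterRep[ci])
        }
      }
    }

    truth <- .emptyTruth()
    qt <- queryTable(registry)
    for (im in implants) {
      rule <- pathwayRules(registry)[[im$pathway_id]]
      roles <- im$roles
      if (is.null(roles)) roles <- rule@roles
      known <- c(rule@roles, rule@optionalRoles)
      if (!all(roles %in% known))
        .stopf("implant roles not in pathway %s: %s", im$pathway_id,
               paste(setdiff(roles, known), collapse = ", "))
      gids <- genomesOf[[im$species_name]]
      nCarriers <- round(im$carrier_fraction * length(gids))
      if (nCarriers == 0L) next
      carriers <- sort(sample(gids, nCarriers))
      pr <- profiles[[match(im$species_name, profNames)]]
      metaSub <- metadata[match(carriers, metadata$Genome), ]

      for (role in roles) {
        cand <- qt[qt$pathway_id == im$pathway_id & qt$role == role &
                     qt$canonical, , drop = FALSE]
        if (nrow(cand) == 0L)
          cand <- qt[qt$pathway_id == im$pathway_id & qt$role == role, ,
                     drop = FALSE]
        if (nrow(cand) == 0L)
          .stopf("no query for pathway %s role %s", im$pathway_id, role)
        qseq <- as.character(querySequences(registry)[[cand$query_id[1L]]])
        mseed <- sample.int(.Machine$integer.max, 1L)
        mseq <- mutateToIdentity(qseq, im$target_pid, mseed)
        realized <- attr(mseq, "realized_pid")

        clusterRep <- NA_character_
        for (ci in seq_along(carriers)) {
          gid <- carriers[ci]
          if (im$role_completeness < 1 &&
              stats::runif(1) > im$role_completeness) next
          for (copy in seq_len(im$copies_per_genome)) {
            pid_ <- nextProt(gid)
            if (is.na(clusterRep)) {
              clusterRep <- pid_
              repSeqs[pid_] <- as.character(mseq)
            }
            memMember <- c(memMember, pid_)
            memRep <- c(memRep, clusterRep)
            truth <- rbind(truth, data.frame(
              genome_id = gid, sample_id = metaSub$Sample_accession[ci],
              species_name = im$species_name,
              genome_type = metaSub$Genome_type[ci],
              pathway_id = im$pathway_id, role = role,
              implanted_pid_realized = realized, protein_id = pid_,
              stringsAsFactors = FALSE))
          }
        }
      }
    }

    reps <- Biostrings::AAStringSet(repSeqs)
    membership <- data.frame(member_id = memMember, representative_id = memRep,
                             stringsAsFactors = FALSE)
    new("MagCatalog", representatives = reps, membership = membership,
        metadata = metadata, truth = truth)
  })
}

#' Write a catalog bundle to disk
#'
#' Emits the UHGP-layout files into `dir`: `representatives.faa` (one record
#' per non-redundant cluster), `membership.tsv` (member_id,
#' representative_id; header line included), `genomes-all_metadata.tsv`, and
#' `truth.tsv` when the catalog is synthetic.
#'
#' @param catalog a [MagCatalog-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
writeCatalog <- function(catalog, dir) {
  stopifnot(is(catalog, "MagCatalog"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "representatives.faa"),
    membership = file.path(dir, "membership.tsv"),
    metadata = file.path(dir, "genomes-all_metadata.tsv"),
    truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(catalog@representatives, paths[["fasta"]])
  .writeTsv(catalog@membership, paths[["membership"]])
  .writeTsv(catalog@metadata, paths[["metadata"]])
  if (nrow(catalog@truth)) .writeTsv(catalog@truth, paths[["truth"]])
  else paths <- paths[names(paths) != "truth"]
  invisible(paths)
}

#' Read a catalog bundle from disk
#'
#' Inverse of [writeCatalog()]; also accepts hand-built bundles with the same
#' file names. A missing `truth.tsv` yields an empty truth slot.
#'
#' @param dir directory containing the bundle.
#' @return A [MagCatalog-class].
#' @export
readCatalog <- function(dir) {
  fa <- file.path(dir, "representatives.faa")
  if (!file.exists(fa)) .stopf("no representatives.faa under %s", dir)
  reps <- Biostrings::readAAStringSet(fa)
  names(reps) <- vapply(strsplit(names(reps), "\\s+"), `[`, character(1), 1L)
  membership <- readMembership(file.path(dir, "membership.tsv"))
  metadata <- .readTsv(file.path(dir, "genomes-all_metadata.tsv"))
  tf <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(tf)) .readTsv(tf) else .emptyTruth()
  new("MagCatalog", representatives = reps, membership = membership,
      metadata = metadata, truth = truth)
}

#' Read a redundancy membership table
#'
#' Reads the UHGP `uhgp-*.tsv` dialect: tab-separated, member ID in column 1
#' and representative ID in column 2; any further columns are ignored. A
#' header line (first field `member_id`) is detected and skipped, so both the
#' package's own bundles and headerless UHGP files load.
#'
#' @param path path to the TSV.
#' @return data.frame with columns `member_id`, `representative_id`.
#' @export
readMembership <- function(path) {
  first <- readLines(path, n = 1L)
  hasHeader <- identical(strsplit(first, "\t")[[1]][1], "member_id")
  tab <- utils::read.delim(path, header = hasHeader, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2L) .stopf("membership table needs >= 2 columns: %s", path)
  out <- tab[, 1:2]
  names(out) <- c("member_id", "representative_id")
  out
}
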