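---
title: "Screening MAG protein catalogs for flavonoid-modifying enzymes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening MAG protein catalogs for flavonoid-modifying enzymes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FlavoScreen)
```

# The problem

Most dietary flavonoids reach the large intestine as glycosides, where gut
bacteria deglycosylate, reduce, demethylate or ring-cleave them, changing
their bioavailability and biological activity. Only a handful of the
responsible enzymes have been characterized biochemically, in a handful of
culturable species. Catalogs of metagenome-assembled genomes (MAGs) from
human gut samples make it possible to ask, in silico, which gut bacteria
*encode* homologs of those characterized enzymes, how often, and whether the
multi-gene systems (C-deglycosylation clusters, the daidzein-to-equol
reductase cluster, O-demethylase operons) co-occur within single genomes.

FlavoScreen implements that screen as a tested, reusable pipeline over
catalogs in the UHGP layout: a FASTA of non-redundant representative protein
sequences, a membership table mapping every redundant protein ID to its
representative, and per-genome metadata with genome type (MAG vs isolate),
sample accession and GTDB lineage.

# The query registry

The package ships a manifest of characterized flavonoid-modifying enzymes of
human gut bacteria: beta-glucosidases and alpha-L-rhamnosidases
(O-deglycosylation and derhamnosylation), the DfgABCDE and DgpABC
C-deglycosylation systems, the DfgCD deglycosylase pair, phloretin
hydrolases, flavone/flavonol reductases (Flr), flavanone/flavanonol-cleaving
reductases (Fcr), chalcone isomerases (CHI), the daidzein-to-equol
reductases (DZR, DDR, TDR) with the optional dihydrodaidzein racemase, and
the four components of a bacterial O-demethylase (MT1, MT2, corrinoid
protein, activating enzyme).

Because the daidzein-to-equol clusters of *Slackia isoflavoniconvertens*,
*Slackia* sp. NATTS, *Lactococcus garvieae* and *Eggerthella* sp. YY7918 are
nearly identical, only the *S. isoflavoniconvertens* reductases (plus the
*L. garvieae* racemase) are flagged canonical; the remaining homologs stay in
the manifest for provenance but are excluded from default searches. All
queries of a pathway are searched simultaneously, with the best-bitscore
deduplication resolving targets hit by several queries; searching query sets
independently is possible by subsetting the registry, but the simultaneous
default keeps a target counted exactly once.

**Synthetic query sequences.** The shipped FASTA
(`query_sequences_synthetic.faa`) contains *synthetic stand-in* sequences,
not the database records behind the manifest accessions: deterministic
pseudo-random amino-acid sequences whose lengths respect each enzyme's
length class, with the non-canonical daidzein homologs generated at about
88% identity to the canonical set. Every stage of the pipeline is agnostic
to query sequence content, and the synthetic generator implants homologs
derived from whatever registry it is given, so all structural and
statistical properties of the screen are exercised faithfully. To screen a
real catalog, point `loadRegistry()` at a FASTA of the true sequences
retrieved by accession.

## E-value regimes

The screen stratifies its e-value cutoff by pathway group rather than per
sequence: 1e-60 for pathways of long queries (>350 residues: Fcr,
O-glycosidases, rhamnosidases), 1e-25 for pathways of short queries
(150–350 residues: daidzein-to-equol, CHI, O-demethylation, Phy, Flr,
DfgCD), and 1e-20 for the C-deglycosylation enzymes, whose clusters contain
two sequences below 150 residues. Storing the class per pathway in the
manifest (instead of deriving it from sequence length) keeps the two short
C-deglycosylation members on the same cutoff as the rest of their cluster.

# Homology search

`searchCatalog()` provides a reference local aligner: affine-gap
Smith–Waterman (via `Biostrings::pairwiseAlignment`) with BLOSUM62, gap open
11, gap extension 1, and Karlin–Altschul statistics with the gapped defaults
lambda = 0.267, K = 0.041:

$$\mathrm{bit} = \frac{\lambda S - \ln K}{\ln 2}, \qquad
  E = m\,n\,2^{-\mathrm{bit}} = K\,m\,n\,e^{-\lambda S},$$

with search space $m\,n$ = query length x total residues in the searched
set. No length correction of the search space is applied; at the e-value
regimes used (1e-20 and below) this simplification does not move any
decision boundary in practice. The aligner is correctness-first: no seeding
or two-hit heuristics, one best alignment per query–target pair, intended
for desk-scale catalogs and for validating the pipeline. Production-scale
screens of a full UHGP release should use an external search tool and feed
its tabular output through `readTabularHits()` (the `external-file` engine),
which accepts the standard 12-column tabular dialect extended with the query
length as column 13.

Two definitions matter downstream and are fixed here:

* **PID** (hit filtering): identical aligned residue pairs / aligned columns
  *including gap columns* x 100 — the tabular `pident` convention, since the
  screen filters tabular output directly.
* **Query coverage**: `100 * (qend - qstart + 1) / qlen`, the alignment's
  span over the query. This is the simplest faithful reading of a "query
  coverage of at least 75%" filter.

Traceback tie-breaking among co-optimal alignments is delegated to the
underlying aligner and is deterministic; alignment *scores* (and therefore
every downstream filtering decision) are independent of the tie order.

# Filtering and deduplication

`applyThresholds()` retains hits with PID >= 30, query coverage >= 75% and
e-value <= the query's class cutoff. "At least" is taken literally: all
boundaries are inclusive. `bestHitPerTarget()` then keeps, per
representative, only the hit with the best bitscore, so a protein similar to
several queries is counted once. Ties are broken by higher PID, then by
lexicographically smallest query ID — the tie rule is a package choice made
for determinism. Deduplication is global across all queries by default
(a target can contribute to only one pathway, which slightly deflates
co-occurrence counts when two pathways share similar enzymes);
`scope = "pathway"` switches to within-pathway deduplication.

# Quantification ("Freq")

`expandMembers()` joins deduplicated hits back to all redundant member
proteins via the membership table; `attachMetadata()` merges genome
metadata, discards isolate genomes (the screen quantifies MAGs), and parses
species from the GTDB lineage; `summarizeOccurrences()` groups by (species,
query, PID bin) and counts member occurrences. Freq counts *protein
occurrences*, not genomes: a genome with two gene copies contributes 2,
which is what surfaces two-copy patterns such as duplicate flavone reductase
genes. Member protein IDs are parsed as `<genome_id>_<index>`; an explicit
protein-to-genome map is accepted for catalogs that deviate from that
convention. Genomes unclassified at species rank aggregate under
`"<genus> (unclassified)"`. PID bins are left-closed (`[lo, hi)`) with the
top bin closed, and each group carries the PID of its representative hit
into the bin.

# Pathway co-occurrence

Multi-enzyme reactions are only credible when the required genes co-occur in
one genome. `callPathways()` evaluates, per genome:

| pathway | requirement |
|---|---|
| DgpABC C-deglycosylation | all three catalytic subunits |
| DfgABCDE C-deglycosylation | at least three of five |
| daidzein-to-equol | dzr, ddr and tdr all present; racemase optional |
| O-demethylase operon | MT1, MT2, CP, AE all present, each at PID > 40 |
| single-enzyme pathways | any hit |

The O-demethylase PID floor is strict (`> 40`), applied per occurrence
before roles are collected — corrinoid proteins share B12-binding domains
with many unrelated proteins, and the floor suppresses such spurious
"complete" operons. A genome has a role if at least one retained occurrence
maps to it, regardless of copy number. `speciesCarrierStats()` divides
carriers by *all* MAGs of the species in the metadata, including genomes
with zero hits — that denominator is what makes statements like "only ~30%
of the species' MAGs carry the cluster" meaningful. `partialRoleReport()`
tabulates genomes carrying only a subset of roles (e.g. daidzein reductase
alone), per exact role-subset signature.

Gene adjacency is *not* evaluated: a genome with all three daidzein-pathway
genes scattered across contigs is called a carrier. Synteny or operon
structure checking is out of scope, and the caveat matters when interpreting
low-PID carriers.

# Prevalence and abundance

`computePrevalence()` matches a curated species list (shipped as a fixture
with modification classes) against the parsed lineages: prevalence is the
percent of distinct samples containing at least one MAG of the species —
several MAGs of one species in one sample count once ("prevalence across
individuals" is presence-based; the dedup is switchable) — and abundance is
the percent of all MAG rows. Matching is exact on the GTDB species string;
provisional 16S-based assignments are carried as annotations in the fixture,
never as fuzzy matching, so species without a sequenced genome or without a
GTDB assignment are reported with prevalence 0 and flagged
`not_in_taxonomy`.

# Greedy clustering

`greedyCluster()` prepares representative sequence sets for external
alignment/tree tools: sequences sorted by decreasing length, first-fit
assignment to the first cluster whose representative matches at >= the
threshold (default 90), exact dynamic-programming identity with no word-size
pre-filters. The clustering identity is *identical aligned pairs / length of
the shorter sequence* (the CD-hit convention) — deliberately different from
the filtering PID above; both definitions live side by side because they
serve different purposes (cluster membership vs alignment quality).
Weighted cluster sizes (sum of per-sequence weights, e.g. redundant
occurrence counts) support node-size scaling in downstream trees.

# The synthetic catalog generator

`generateCatalog()` emulates the UHGP layout with known ground truth:

* **Species structure**: each profile fixes genome count, MAG fraction and
  sample spread (`distinct` cycles genomes over samples; `shared` puts all
  of a species' genomes into one sample to exercise per-sample
  deduplication).
* **Redundancy**: all members of a cluster carry an identical sequence, as
  in a 100%-identity catalog; background proteins are grouped round-robin
  into clusters of the requested mean size.
* **Background**: uniform random sequences of 100–600 residues. Their
  expected identity to any query is far below 30 PID, giving a near-zero
  false-positive floor so filter tests are crisp. This is the principal
  idealization: real catalogs contain *related* non-target proteins
  (glycoside hydrolase families, B12-binding proteins) that produce
  borderline hits. Passing tests therefore demonstrate the pipeline's
  bookkeeping and threshold semantics, not the biological specificity of
  the thresholds on real data.
* **Implants**: `mutateToIdentity()` substitutes residues (never to the
  original) at seeded positions, so the realized identity is the nearest
  achievable to the target given integer position counts; the realized
  value, not the target, is recorded in the truth table to avoid off-by-one
  ambiguity. Implants of one (species, role, target PID) form a single
  redundancy cluster, exercising membership expansion. `roleCompleteness`
  < 1 drops each role from each carrier genome independently, simulating
  fragmented MAGs with partial clusters.

Substitution-only mutation means implants never test gapped-alignment
recovery; the measured PID of a local alignment can deviate from the
realized positional identity by a small margin (end trimming), observed
below 2 percentage points across the study grid.

# Problem sizes and reproducibility

The packaged study grid (used by the test suite and by
`scripts/acceptance.R`) is 10 species x 20 genomes with implants at
realized PID {55, 70, 85, 95}, carrier fractions {0.1, 0.3, 0.5, 1.0} and
cluster completeness {0.5, 1.0}, two background proteins per genome at mean
redundancy 2 — about 220 representative clusters searched by 41 canonical
queries, which the reference aligner completes in well under a minute on
one core. These sizes were chosen as the smallest grid that covers every
condition at least twice; all conclusions the tests draw are exact
(counting identities), so larger grids add runtime, not information.

All randomness flows from a single integer seed: the generator, the
mutator and every test fixture restore the caller's RNG state. Rerunning
`runSimulate()`/`runScreen()` with one configuration yields byte-identical
bundles and tables, and the run manifest records the seed, configuration
hash, input checksums and per-stage row counts.

# Known limitations

* The reference aligner is quadratic per pair and unsuited to
  280,000-genome catalogs; full-scale screens must use an external search
  engine via the `external-file` path (see the README's reproduction
  section).
* One HSP per query–target pair: proteins with repeated domains are scored
  by their single best local alignment.
* No synteny/operon checking; no abundance normalization by genome
  completeness or sample depth; no 16S extraction; GTDB names are taken
  verbatim from the metadata release they ship with.
* The curated species fixture encodes a literature snapshot; prevalence for
  species absent from the GTDB taxonomy is structurally zero and flagged,
  not imputed.
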