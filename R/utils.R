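#' Genome ID of a protein ID
#'
#' Member protein IDs follow the UHGP convention `<genome_id>_<index>` where
#' the index is the final underscore-delimited numeric field (e.g.
#' `GUT_GENOME000001_00123` belongs to `GUT_GENOME000001`). For catalogs that
#' do not follow the convention, [attachMetadata()] accepts an explicit
#' protein-to-genome map instead.
#'
#' @param proteinId character vector of protein IDs.
#' @return character vector of genome IDs.
#' @examples
#' genomeOfProtein("GUT_GENOME000001_00123")
#' @export
genomeOfProtein <- function(proteinId) {
  sub("_[0-9]+$", "", proteinId)
}

# Seeded RNG scope: runs expr under set.seed(seed) and restores the caller's
# RNG state, so package randomness never perturbs the user's stream.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Random protein of given length from the 20-letter alphabet (uses current RNG).
randomProtein <- function(length) {
  paste(sample(.AA20, length, replace = TRUE), collapse = "")
}

.readTsv <- function(path, ...) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

.writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
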