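#' Read BLAST-style tabular hits
#'
#' Parses the 12-column BLAST tabular dialect (`outfmt 6`: qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore)
#' extended with the query length as column 13 (`"outfmt6+qlen"`), or the
#' plain 12-column dialect with query lengths supplied through `qlenTable`.
#' Query coverage is computed as `100 * (qend - qstart + 1) / qlen`.
#'
#' @param path path to the tab-separated hit file (no header line).
#' @param dialect `"outfmt6+qlen"` (13 columns) or `"outfmt6"` (12 columns
#'   plus `qlenTable`).
#' @param qlenTable for `"outfmt6"`: named numeric vector or two-column
#'   data.frame mapping query IDs to lengths.
#' @param strict if `TRUE` (default) malformed rows (wrong column count or
#'   non-numeric fields) raise an error naming the line; if `FALSE` they are
#'   skipped with a warning.
#' @return A hit `data.frame` in the package's tabular layout.
#' @export
readTabularHits <- function(path, dialect = c("outfmt6+qlen", "outfmt6"),
                            qlenTable = NULL, strict = TRUE) {
  dialect <- match.arg(dialect)
  ncolExp <- if (dialect == "outfmt6+qlen") 13L else 12L
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(emptyHits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != ncolExp)

  numCols <- c(3:12, if (ncolExp == 13L) 13L)
  rows <- vector("list", length(lines))
  badNum <- integer(0)
  for (i in seq_along(fields)) {
    if (i %in% bad) next
    v <- fields[[i]]
    nums <- suppressWarnings(as.numeric(v[numCols]))
    if (anyNA(nums)) { badNum <- c(badNum, i); next }
    rows[[i]] <- c(v[1:2], as.list(nums))
  }
  allBad <- sort(c(bad, badNum))
  if (length(allBad)) {
    msg <- sprintf("malformed hit row(s) at line(s): %s in %s",
                   paste(utils::head(allBad, 10L), collapse = ", "), path)
    if (strict) .stopf("%s", msg) else warning(msg, call. = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(emptyHits())

  m <- do.call(rbind, lapply(rows, function(r) unlist(r[-(1:2)])))
  out <- data.frame(
    query_id = vapply(rows, `[[`, character(1), 1L),
    target_id = vapply(rows, `[[`, character(1), 2L),
    pid = m[, 1L], aln_length = as.integer(m[, 2L]),
    mismatch = as.integer(m[, 3L]), gapopen = as.integer(m[, 4L]),
    qstart = as.integer(m[, 5L]), qend = as.integer(m[, 6L]),
    sstart = as.integer(m[, 7L]), send = as.integer(m[, 8L]),
    evalue = m[, 9L], bitscore = m[, 10L],
    stringsAsFactors = FALSE)
  if (ncolExp == 13L) {
    out$qlen <- as.integer(m[, 11L])
  } else {
    if (is.null(qlenTable))
      .stopf("dialect 'outfmt6' requires qlenTable")
    if (is.data.frame(qlenTable))
      qlenTable <- stats::setNames(qlenTable[[2L]], qlenTable[[1L]])
    ql <- qlenTable[out$query_id]
    if (anyNA(ql))
      .stopf("qlenTable lacks lengths for: %s",
             paste(unique(out$query_id[is.na(ql)]), collapse = ", "))
    out$qlen <- as.integer(ql)
  }
  out$qcov <- 100 * (out$qend - out$qstart + 1) / out$qlen
  .checkHits(out)
  out
}

#' Write hits in the outfmt6+qlen dialect
#'
#' Writes the 13-column tab-separated layout read by [readTabularHits()]
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore qlen; no header). Floating-point fields are written with
#' full precision so a read-back reproduces the hit set exactly.
#'
#' @param hits a hit `data.frame`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeTabularHits <- function(hits, path) {
  .checkHits(hits)
  g <- function(x) sprintf("%.17g", x)
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%s\t%d",
                   hits$query_id, hits$target_id, g(hits$pid),
                   hits$aln_length, hits$mismatch, hits$gapopen,
                   hits$qstart, hits$qend, hits$sstart, hits$send,
                   g(hits$evalue), g(hits$bitscore), hits$qlen)
  writeLines(lines, path)
  invisible(path)
}
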