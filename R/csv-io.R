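## Readers and writers: tetramer CSV (CTD download dialect), interaction
## tables, hierarchy edge lists.  All RFC 4180 via utils::read.csv/write.csv.

## normalize a header name: case-insensitive, '.'/'_'/' ' interchangeable
.normHeader <- function(x) tolower(gsub("[._ ]", "", x))

#' Read a tetramer CSV in the CTD download dialect
#'
#' Reads a delimited text file with the eight tetramer columns
#' (Chemical, Chemical.ID, Gene, Gene.ID, Phenotype, Phenotype.ID, Disease,
#' Disease.ID).  Header matching is case-insensitive and accepts
#' underscore/space variants (\code{Chemical_ID}).  Unknown extra columns
#' are preserved as opaque annotations.  Every data row becomes one record
#' (no implicit deduplication).  Rows with an empty cell in a required
#' column are skipped and counted in \code{diagnostics()}.
#'
#' @param file path or connection.
#' @param sep field delimiter (default comma).
#' @return A \code{\link{TetramerSet}} whose \code{sourceLabel} is the file
#'   name.
#' @export
readTetramerCSV <- function(file, sep = ",") {
  df <- utils::read.csv(file, sep = sep, check.names = FALSE,
                        colClasses = "character", stringsAsFactors = FALSE)
  canon <- .tetramerCols()
  lut <- stats::setNames(canon, .normHeader(canon))
  normed <- .normHeader(names(df))
  hit <- !is.na(lut[normed])
  names(df)[hit] <- lut[normed[hit]]
  missing <- setdiff(canon, names(df))
  if (length(missing))
    stop("tetramer CSV is missing required column(s): ",
         paste(missing, collapse = ", "))
  diag <- list()
  if (nrow(df)) {
    bad <- rowSums(is.na(df[canon]) | df[canon] == "") > 0
    if (any(bad)) {
      diag$skippedRows <- sum(bad)
      diag$skippedRowNumbers <- which(bad)
      df <- df[!bad, , drop = FALSE]
    }
  }
  label <- if (is.character(file)) basename(file) else "connection"
  TetramerSet(df, sourceLabel = label, diagnostics = diag)
}

#' Write a tetramer CSV in the canonical dialect
#'
#' Emits a header row plus one row per record, canonical eight-column order
#' first and annotation columns after, RFC 4180 quoting.  Round-trips with
#' \code{\link{readTetramerCSV}}.
#'
#' @param set a \code{TetramerSet}.
#' @param file path or connection.
#' @return Invisibly, the number of data rows written.
#' @export
writeTetramerCSV <- function(set, file) {
  stopifnot(methods::is(set, "TetramerSet"))
  df <- tetramers(set)
  utils::write.csv(df, file, row.names = FALSE, quote = TRUE, na = "")
  invisible(nrow(df))
}

#' Read a curated-interaction table
#'
#' Expects columns \code{kind}, \code{subject_term}, \code{subject_id},
#' \code{object_term}, \code{object_id}; \code{kind} must be one of
#' \code{\link{interactionKinds}()}.  Delimiter is inferred from the file
#' extension (TSV/CSV) unless given.
#'
#' @param file path or connection.
#' @param sep delimiter; default \code{"\t"} for \code{.tsv} files, comma
#'   otherwise.
#' @param hierarchies optional named list of \code{TermHierarchy} to attach.
#' @return A \code{\link{CuratedDatabase}}.
#' @export
readInteractions <- function(file, sep = NULL, hierarchies = list()) {
  if (is.null(sep))
    sep <- if (is.character(file) && grepl("\\.tsv$", file, TRUE)) "\t" else ","
  df <- utils::read.csv(file, sep = sep, check.names = FALSE,
                        colClasses = "character", stringsAsFactors = FALSE)
  CuratedDatabase(df, hierarchies = hierarchies)
}

#' Write a curated-interaction table
#'
#' @param db a \code{CuratedDatabase}.
#' @param file path or connection.
#' @param sep delimiter (default tab).
#' @return Invisibly, the number of rows written.
#' @export
writeInteractions <- function(db, file, sep = "\t") {
  stopifnot(methods::is(db, "CuratedDatabase"))
  utils::write.table(db@interactions, file, sep = sep, row.names = FALSE,
                     quote = TRUE, qmethod = "double")
  invisible(nrow(db@interactions))
}

#' Read a term-hierarchy edge list
#'
#' Two-column delimited file (\code{parent_id}, \code{child_id}; header row
#' required, any column names accepted positionally).
#'
#' @param file path or connection.
#' @param nodeClass which node class the hierarchy describes.
#' @param sep delimiter; default \code{"\t"} for \code{.tsv} files, comma
#'   otherwise.
#' @return A \code{\link{TermHierarchy}}.
#' @export
readHierarchy <- function(file, nodeClass, sep = NULL) {
  if (is.null(sep))
    sep <- if (is.character(file) && grepl("\\.tsv$", file, TRUE)) "\t" else ","
  df <- utils::read.csv(file, sep = sep, check.names = FALSE,
                        colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("hierarchy edge list needs two columns (parent_id, child_id)")
  TermHierarchy(nodeClass,
                data.frame(parent = df[[1L]], child = df[[2L]],
                           stringsAsFactors = FALSE))
}

#' Export a dimer table as an edge-list CSV
#'
#' Four principal columns (\code{class}, \code{source}, \code{target},
#' \code{frequency}) using display labels, plus the source/target accession
#' columns, for use with external graph tools.
#'
#' @param table a \code{\link{DimerTable}}.
#' @param file path or connection.
#' @return Invisibly, the number of rows written.
#' @export
writeDimerCSV <- function(table, file) {
  stopifnot(methods::is(table, "DimerTable"))
  d <- dimers(table)
  out <- data.frame(
    class = d$class,
    source = if (table@useIds) d$source_id else d$source_term,
    target = if (table@useIds) d$target_id else d$target_term,
    frequency = d$frequency,
    source_id = d$source_id, target_id = d$target_id,
    stringsAsFactors = FALSE)
  utils::write.csv(out, file, row.names = FALSE, quote = TRUE)
  invisible(nrow(out))
}
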