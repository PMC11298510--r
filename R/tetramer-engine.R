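## Tetramer construction: the five-relation join, descendant expansion,
## merging, filtering and summary counts.

#' Expand accessions to include all hierarchy descendants
#'
#' Returns the transitive closure of the given root accessions under the
#' parent-to-child edges of a \code{TermHierarchy}: the roots themselves plus
#' every accession reachable from them.  A root absent from the hierarchy is
#' returned alone, with a note in the \code{"diagnostics"} attribute.
#'
#' @param hierarchy a \code{\link{TermHierarchy}}.
#' @param roots character vector of root accessions.
#' @return Sorted character vector of accessions (roots always included),
#'   with attribute \code{"diagnostics"} listing unknown roots, if any.
#' @examples
#' h <- TermHierarchy("chemical",
#'   data.frame(parent = "metals", child = c("copper", "iron")))
#' expandDescendants(h, "metals")  # metals, copper, iron
#' @export
expandDescendants <- function(hierarchy, roots) {
  stopifnot(methods::is(hierarchy, "TermHierarchy"))
  roots <- unique(as.character(roots))
  edges <- hierarchy@edges
  known <- unique(c(edges$parent, edges$child))
  notes <- character(0)
  unknown <- setdiff(roots, known)
  if (length(unknown))
    notes <- paste0("accession(s) not in ", hierarchy@nodeClass,
                    " hierarchy, returned unexpanded: ",
                    paste(unknown, collapse = ", "))
  kids <- split(edges$child, edges$parent)
  seen <- roots
  frontier <- roots
  while (length(frontier)) {
    nxt <- unique(unlist(kids[intersect(frontier, names(kids))],
                         use.names = FALSE))
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  out <- sort(unique(seen))
  if (length(notes)) attr(out, "diagnostics") <- notes
  out
}

## Resolve a QueryFilter against the database hierarchies: returns a named
## list of accession sets (NULL = unconstrained) plus diagnostics.
.resolveFilter <- function(filter, hierarchies) {
  sets <- list()
  notes <- character(0)
  for (cl in nodeClasses()) {
    acc <- methods::slot(filter, cl)
    if (length(acc) == 0L) { sets[cl] <- list(NULL); next }
    if (isTRUE(filter@descendants[[cl]]) && !is.null(hierarchies[[cl]])) {
      acc <- expandDescendants(hierarchies[[cl]], acc)
      notes <- c(notes, attr(acc, "diagnostics"))
    }
    sets[[cl]] <- unique(as.character(acc))
  }
  list(sets = sets, notes = notes)
}

#' Generate CGPD-tetramers by the five-relation join
#'
#' Enumerates every (chemical, gene, phenotype, disease) quadruple for which
#' all five supporting curated relations exist in the database: the
#' chemical-gene, chemical-phenotype and chemical-disease interactions, the
#' gene-phenotype annotation and the gene-disease association.  A quadruple
#' lacking any one of the five is never emitted.  The result is intersected
#' with the (optionally descendant-expanded) per-class accession filter,
#' deduplicated, and sorted case-insensitively by display term
#' (chemical, gene, phenotype, disease), ties broken by accession.
#'
#' Filter accessions that match nothing in the database are reported in the
#' returned set's \code{diagnostics()} as a warning, not an error.
#'
#' @param db a \code{\link{CuratedDatabase}}.
#' @param filter a \code{\link{queryFilter}} (default: unconstrained).
#' @return A \code{\link{TetramerSet}}.
#' @examples
#' db <- CuratedDatabase(data.frame(
#'   kind = c("chemical_gene", "chemical_phenotype", "chemical_disease",
#'            "gene_phenotype", "gene_disease"),
#'   subject_term = c("ozone", "ozone", "ozone", "PTGFR", "PTGFR"),
#'   subject_id   = c("C1", "C1", "C1", "G1", "G1"),
#'   object_term  = c("PTGFR", "inflammation", "asthma",
#'                    "inflammation", "asthma"),
#'   object_id    = c("G1", "P1", "D1", "P1", "D1")))
#' generateTetramers(db)   # one tetramer
#' @export
generateTetramers <- function(db, filter = queryFilter()) {
  stopifnot(methods::is(db, "CuratedDatabase"),
            methods::is(filter, "QueryFilter"))
  methods::validObject(db)
  it <- db@interactions
  res <- .resolveFilter(filter, db@hierarchies)
  diag <- list()

  tab <- function(wanted, a, b) {
    x <- it[it$kind == wanted,
            c("subject_id", "subject_term", "object_id", "object_term"),
            drop = FALSE]
    x <- data.table::as.data.table(x)
    data.table::setnames(x, c(paste0(a, "_id"), paste0(a, "_term"),
                              paste0(b, "_id"), paste0(b, "_term")))
    x
  }
  cg <- tab("chemical_gene", "c", "g")
  cp <- tab("chemical_phenotype", "c", "p")
  cd <- tab("chemical_disease", "c", "d")
  gp <- tab("gene_phenotype", "g", "p")
  gd <- tab("gene_disease", "g", "d")

  ## unknown filter accessions: present in no interaction and no hierarchy
  knownIds <- list(
    chemical  = unique(c(cg$c_id, cp$c_id, cd$c_id)),
    gene      = unique(c(cg$g_id, gp$g_id, gd$g_id)),
    phenotype = unique(c(cp$p_id, gp$p_id)),
    disease   = unique(c(cd$d_id, gd$d_id))
  )
  for (cl in nodeClasses()) {
    s <- res$sets[[cl]]
    if (is.null(s)) next
    hier <- db@hierarchies[[cl]]
    hierIds <- if (is.null(hier)) character(0) else
      unique(c(hier@edges$parent, hier@edges$child))
    unk <- setdiff(s, c(knownIds[[cl]], hierIds))
    if (length(unk)) {
      msg <- paste0("unknown ", cl, " filter accession(s): ",
                    paste(unk, collapse = ", "), " (match nothing)")
      warning(msg, call. = FALSE)
      diag$unknownFilterAccessions <- c(diag$unknownFilterAccessions, unk)
    }
  }
  diag <- c(diag, if (length(res$notes)) list(hierarchyNotes = res$notes))

  ## apply per-class constraints up front (pure optimization; the join is
  ## intersected with the same sets either way)
  keep <- function(x, col, cl) {
    s <- res$sets[[cl]]
    if (is.null(s)) x else x[x[[col]] %in% s, ]
  }
  cg <- keep(keep(cg, "c_id", "chemical"), "g_id", "gene")
  cp <- keep(keep(cp, "c_id", "chemical"), "p_id", "phenotype")
  cd <- keep(keep(cd, "c_id", "chemical"), "d_id", "disease")
  gp <- keep(keep(gp, "g_id", "gene"), "p_id", "phenotype")
  gd <- keep(keep(gd, "g_id", "gene"), "d_id", "disease")

  ## c-g x g-p |> require c-p |> x g-d |> require c-d
  cgp <- merge(cg[, c("c_id", "c_term", "g_id", "g_term")],
               gp[, c("g_id", "p_id", "p_term")],
               by = "g_id", allow.cartesian = TRUE)
  cgp <- merge(cgp, cp[, c("c_id", "p_id")], by = c("c_id", "p_id"))
  cgpd <- merge(cgp, gd[, c("g_id", "d_id", "d_term")],
                by = "g_id", allow.cartesian = TRUE)
  cgpd <- merge(cgpd, cd[, c("c_id", "d_id")], by = c("c_id", "d_id"))

  if (nrow(cgpd) == 0L) {
    return(TetramerSet(.emptyTetramerFrame(), sourceLabel = "generated",
                       diagnostics = diag))
  }
  df <- data.frame(
    Chemical = cgpd$c_term, `Chemical.ID` = cgpd$c_id,
    Gene = cgpd$g_term, `Gene.ID` = cgpd$g_id,
    Phenotype = cgpd$p_term, `Phenotype.ID` = cgpd$p_id,
    Disease = cgpd$d_term, `Disease.ID` = cgpd$d_id,
    check.names = FALSE, stringsAsFactors = FALSE)
  df <- df[!duplicated(.tetramerKey(df)), , drop = FALSE]
  ord <- order(tolower(df$Chemical), tolower(df$Gene), tolower(df$Phenotype),
               tolower(df$Disease), df$`Chemical.ID`, df$`Gene.ID`,
               df$`Phenotype.ID`, df$`Disease.ID`, method = "radix")
  df <- df[ord, , drop = FALSE]
  TetramerSet(df, sourceLabel = "generated", diagnostics = diag)
}

#' Merge tetramer sets
#'
#' Concatenates tetramer sets in input order.  With
#' \code{deduplicate = FALSE} (the default, matching a plain copy-and-paste
#' merge of downloaded query results) every input record is kept, so three
#' disjoint sets of 123, 122 and 136 records merge to 381.  With
#' \code{deduplicate = TRUE} only the first occurrence of each tetramer
#' (by its 4-tuple of accessions) is kept.
#'
#' @param sets list of \code{TetramerSet} (length >= 1).
#' @param deduplicate drop repeated tetramers, keeping first occurrences?
#' @return A \code{TetramerSet}; \code{sourceLabel} records all inputs.
#' @export
mergeTetramerSets <- function(sets, deduplicate = FALSE) {
  if (methods::is(sets, "TetramerSet")) sets <- list(sets)
  stopifnot(length(sets) >= 1L,
            all(vapply(sets, methods::is, TRUE, "TetramerSet")))
  dfs <- lapply(sets, tetramers)
  df <- as.data.frame(data.table::rbindlist(dfs, fill = TRUE),
                      check.names = FALSE, stringsAsFactors = FALSE)
  if (deduplicate && nrow(df))
    df <- df[!duplicated(.tetramerKey(df)), , drop = FALSE]
  labels <- vapply(sets, sourceLabel, character(1))
  labels <- labels[nzchar(labels)]
  TetramerSet(df, sourceLabel = paste(labels, collapse = " + "))
}

#' Filter a tetramer set by per-class accession constraints
#'
#' Keeps the records whose four slot accessions all fall inside the
#' (optionally descendant-expanded) per-class accession sets of the filter.
#' Unconstrained classes pass everything; record order is preserved.
#'
#' @param set a \code{TetramerSet}.
#' @param filter a \code{\link{queryFilter}}.
#' @param hierarchies optional named list of \code{TermHierarchy} per node
#'   class, used when the filter requests descendant expansion.
#' @return The filtered \code{TetramerSet}.
#' @export
filterTetramers <- function(set, filter, hierarchies = list()) {
  stopifnot(methods::is(set, "TetramerSet"), methods::is(filter, "QueryFilter"))
  res <- .resolveFilter(filter, hierarchies)
  df <- tetramers(set)
  keep <- rep(TRUE, nrow(df))
  for (cl in nodeClasses()) {
    s <- res$sets[[cl]]
    if (!is.null(s)) keep <- keep & df[[.idCol(cl)]] %in% s
  }
  TetramerSet(df[keep, , drop = FALSE], sourceLabel = sourceLabel(set))
}

#' Summary counts of a tetramer set
#'
#' Counts records, unique tetramers (by accession 4-tuple) and unique terms
#' per node class (by accession).
#'
#' @param set a \code{TetramerSet}.
#' @return Named list: \code{records}, \code{uniqueTetramers},
#'   \code{chemicals}, \code{genes}, \code{phenotypes}, \code{diseases}.
#' @examples
#' summarizeTetramers(ozoneToyTetramers())
#' @export
summarizeTetramers <- function(set) {
  stopifnot(methods::is(set, "TetramerSet"))
  df <- tetramers(set)
  list(
    records = nrow(df),
    uniqueTetramers = length(unique(.tetramerKey(df))),
    chemicals = length(unique(df$`Chemical.ID`)),
    genes = length(unique(df$`Gene.ID`)),
    phenotypes = length(unique(df$`Phenotype.ID`)),
    diseases = length(unique(df$`Disease.ID`))
  )
}
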