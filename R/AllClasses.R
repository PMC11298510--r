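## S4 classes: TermHierarchy, CuratedDatabase, QueryFilter, TetramerSet,
## DimerTable, ChordLayout.

#' TermHierarchy: an acyclic parent-to-child accession graph
#'
#' Holds the ontology structure of one node class as a set of directed
#' parent-to-child edges between accession identifiers.  Used for
#' descendant expansion of query terms (for example, expanding a query for
#' a chemical category such as metals to every descendant metal).
#'
#' @slot nodeClass one of \code{\link{nodeClasses}()}.
#' @slot edges a two-column \code{data.frame} with columns \code{parent}
#'   and \code{child} (accession strings).
#' @export
setClass("TermHierarchy",
  representation(nodeClass = "character", edges = "data.frame"))

setValidity("TermHierarchy", function(object) {
  msg <- character(0)
  if (length(object@nodeClass) != 1L || !object@nodeClass %in% nodeClasses())
    msg <- c(msg, "nodeClass must be one of chemical/gene/phenotype/disease")
  e <- object@edges
  if (!all(c("parent", "child") %in% names(e)))
    msg <- c(msg, "edges must have columns 'parent' and 'child'")
  else {
    if (nrow(e) > 0 && (any(!nzchar(e$parent)) || any(!nzchar(e$child))))
      msg <- c(msg, "edges contain empty accession strings")
    if (.hasCycle(e))
      msg <- c(msg, "hierarchy edges contain a cycle; must be acyclic")
  }
  if (length(msg)) msg else TRUE
})

## Kahn's algorithm: TRUE if the directed edge list has a cycle
.hasCycle <- function(edges) {
  if (nrow(edges) == 0L) return(FALSE)
  nodes <- unique(c(edges$parent, edges$child))
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(edges$child)
  indeg[names(tab)] <- as.integer(tab)
  queue <- nodes[indeg == 0L]
  removed <- 0L
  kids <- split(edges$child, edges$parent)
  while (length(queue)) {
    n <- queue[[1L]]; queue <- queue[-1L]; removed <- removed + 1L
    for (ch in kids[[n]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  removed < length(nodes)
}

#' @rdname TermHierarchy-class
#' @param nodeClass node class the hierarchy describes.
#' @param edges two-column data.frame (\code{parent}, \code{child}) of
#'   accession pairs; extra columns are dropped.
#' @return A \code{TermHierarchy} object.
#' @examples
#' h <- TermHierarchy("chemical",
#'   data.frame(parent = c("D008670", "D008670"),
#'              child  = c("D003300", "D007501")))
#' expandDescendants(h, "D008670")
#' @export
TermHierarchy <- function(nodeClass, edges = data.frame(parent = character(0),
                                                        child = character(0))) {
  edges <- data.frame(parent = as.character(edges$parent),
                      child = as.character(edges$child),
                      stringsAsFactors = FALSE)
  methods::new("TermHierarchy", nodeClass = nodeClass, edges = edges)
}

#' CuratedDatabase: five kinds of curated pairwise interactions
#'
#' A local stand-in for a curated interaction resource: a table of
#' subject-object relations of the five kinds required to support a
#' CGPD-tetramer, plus optional per-class term hierarchies.
#'
#' @slot interactions \code{data.frame} with columns \code{kind},
#'   \code{subject_term}, \code{subject_id}, \code{object_term},
#'   \code{object_id}.  Duplicate (kind, subject_id, object_id) triples are
#'   removed on construction.
#' @slot hierarchies named list of \code{TermHierarchy}, keyed by node class.
#' @export
setClass("CuratedDatabase",
  representation(interactions = "data.frame", hierarchies = "list"))

setValidity("CuratedDatabase", function(object) {
  msg <- character(0)
  need <- c("kind", "subject_term", "subject_id", "object_term", "object_id")
  it <- object@interactions
  if (!all(need %in% names(it))) {
    msg <- c(msg, paste("interactions must have columns:",
                        paste(setdiff(need, names(it)), collapse = ", ")))
  } else if (nrow(it) > 0) {
    bad <- which(!it$kind %in% interactionKinds())
    if (length(bad))
      msg <- c(msg, paste0("row ", bad[1L], ": unknown interaction kind '",
                           it$kind[bad[1L]], "'"))
    empty <- which(!nzchar(it$subject_id) | !nzchar(it$object_id))
    if (length(empty))
      msg <- c(msg, paste0("row ", empty[1L], ": empty accession identifier"))
    key <- paste(it$kind, it$subject_id, it$object_id, sep = "\t")
    if (anyDuplicated(key))
      msg <- c(msg, paste0("duplicate interaction at row ",
                           which(duplicated(key))[1L]))
  }
  for (nm in names(object@hierarchies)) {
    if (!nm %in% nodeClasses())
      msg <- c(msg, paste0("hierarchy key '", nm, "' is not a node class"))
    if (!methods::is(object@hierarchies[[nm]], "TermHierarchy"))
      msg <- c(msg, paste0("hierarchies[['", nm, "']] is not a TermHierarchy"))
  }
  if (length(msg)) msg else TRUE
})

#' @rdname CuratedDatabase-class
#' @param interactions data.frame of curated relations (columns \code{kind},
#'   \code{subject_term}, \code{subject_id}, \code{object_term},
#'   \code{object_id}).
#' @param hierarchies optional named list of \code{TermHierarchy} objects,
#'   keyed by node class.
#' @return A \code{CuratedDatabase}.
#' @export
CuratedDatabase <- function(interactions, hierarchies = list()) {
  cols <- c("kind", "subject_term", "subject_id", "object_term", "object_id")
  if (!all(cols %in% names(interactions)))
    stop("interactions must have columns: ",
         paste(setdiff(cols, names(interactions)), collapse = ", "))
  it <- interactions[cols]
  for (cc in cols) it[[cc]] <- as.character(it[[cc]])
  key <- paste(it$kind, it$subject_id, it$object_id, sep = "\t")
  it <- it[!duplicated(key), , drop = FALSE]
  rownames(it) <- NULL
  methods::new("CuratedDatabase", interactions = it, hierarchies = hierarchies)
}

#' QueryFilter: per-class accession constraints
#'
#' Restricts tetramer construction or filtering to given accessions per node
#' class.  An empty vector for a class means unconstrained.  When
#' \code{descendants} is \code{TRUE} for a class and a hierarchy is
#' available, the accession set is expanded to include all descendant terms.
#'
#' @slot chemical,gene,phenotype,disease character vectors of accessions
#'   (empty = unconstrained).
#' @slot descendants named logical of length 4: expand each class's set to
#'   hierarchy descendants?
#' @export
setClass("QueryFilter",
  representation(chemical = "character", gene = "character",
                 phenotype = "character", disease = "character",
                 descendants = "logical"))

setValidity("QueryFilter", function(object) {
  if (length(object@descendants) != 4L ||
      !identical(sort(names(object@descendants)), sort(nodeClasses())))
    return("descendants must be a named logical of the four node classes")
  TRUE
})

#' @rdname QueryFilter-class
#' @param chemical,gene,phenotype,disease accession vectors (empty =
#'   unconstrained).
#' @param descendants logical scalar or named logical per class: expand to
#'   hierarchy descendants.
#' @return A \code{QueryFilter}.
#' @export
queryFilter <- function(chemical = character(0), gene = character(0),
                        phenotype = character(0), disease = character(0),
                        descendants = FALSE) {
  if (length(descendants) == 1L && is.null(names(descendants)))
    descendants <- stats::setNames(rep(descendants, 4L), nodeClasses())
  methods::new("QueryFilter", chemical = as.character(chemical),
               gene = as.character(gene), phenotype = as.character(phenotype),
               disease = as.character(disease), descendants = descendants)
}

#' TetramerSet: an ordered collection of CGPD-tetramers
#'
#' Wraps a data.frame in the canonical eight-column tetramer layout
#' (Chemical, Chemical.ID, Gene, Gene.ID, Phenotype, Phenotype.ID, Disease,
#' Disease.ID).  Extra columns from input files are preserved as opaque
#' annotations.  A tetramer's identity is its 4-tuple of accessions; display
#' terms are presentation only.
#'
#' @slot records the tetramer data.frame.
#' @slot sourceLabel free-text provenance (e.g. the originating query/file).
#' @slot diagnostics list of parse/build diagnostics (e.g. skipped rows).
#' @export
setClass("TetramerSet",
  representation(records = "data.frame", sourceLabel = "character",
                 diagnostics = "list"))

setValidity("TetramerSet", function(object) {
  df <- object@records
  miss <- setdiff(.tetramerCols(), names(df))
  if (length(miss))
    return(paste("missing required columns:", paste(miss, collapse = ", ")))
  for (cc in .tetramerCols()) {
    v <- df[[cc]]
    if (!is.character(v))
      return(paste0("column '", cc, "' must be character"))
    if (anyNA(v) || any(!nzchar(v)))
      return(paste0("column '", cc, "' has empty values"))
  }
  TRUE
})

#' @rdname TetramerSet-class
#' @param records data.frame containing at least the eight canonical columns.
#' @param sourceLabel provenance string.
#' @param diagnostics list of diagnostics accumulated while building the set.
#' @return A \code{TetramerSet}.
#' @export
TetramerSet <- function(records = .emptyTetramerFrame(), sourceLabel = "",
                        diagnostics = list()) {
  records <- as.data.frame(records, check.names = FALSE,
                           stringsAsFactors = FALSE)
  for (cc in intersect(.tetramerCols(), names(records)))
    records[[cc]] <- as.character(records[[cc]])
  ## canonical columns first, annotations after
  extra <- setdiff(names(records), .tetramerCols())
  if (all(.tetramerCols() %in% names(records)))
    records <- records[c(.tetramerCols(), extra)]
  rownames(records) <- NULL
  methods::new("TetramerSet", records = records,
               sourceLabel = as.character(sourceLabel),
               diagnostics = diagnostics)
}

#' DimerTable: dimer edges with tetramer-support frequencies
#'
#' The decomposition of a (deduplicated) \code{TetramerSet} into its three
#' directed dimer classes.  Each unique tetramer contributes exactly one
#' chemical-gene, one gene-phenotype and one phenotype-disease occurrence, so
#' within every class the frequencies sum to the number of unique tetramers.
#'
#' @slot dimers data.frame with columns \code{class}, \code{source_term},
#'   \code{source_id}, \code{target_term}, \code{target_id},
#'   \code{frequency}.
#' @slot nTetramers number of unique tetramers the table was derived from.
#' @slot useIds were accession IDs (rather than terms) chosen as display
#'   labels at decomposition time?
#' @export
setClass("DimerTable",
  representation(dimers = "data.frame", nTetramers = "integer",
                 useIds = "logical"))

setValidity("DimerTable", function(object) {
  d <- object@dimers
  need <- c("class", "source_term", "source_id", "target_term", "target_id",
            "frequency")
  miss <- setdiff(need, names(d))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (nrow(d) > 0) {
    if (!all(d$class %in% dimerClasses()))
      return("unknown dimer class present")
    if (any(d$frequency < 1L))
      return("frequencies must be >= 1")
    key <- paste(d$class, d$source_id, d$target_id, sep = "\t")
    if (anyDuplicated(key))
      return("duplicate (class, source, target) dimer")
    ## conservation holds per class; degenerate tables carrying only a
    ## subset of the classes (e.g. a hand-built single-dimer case) are
    ## allowed, so only classes actually present are checked
    for (cl in unique(d$class)) {
      s <- sum(d$frequency[d$class == cl])
      if (s != object@nTetramers)
        return(paste0("frequency sum for ", cl, " (", s,
                      ") != nTetramers (", object@nTetramers, ")"))
    }
  } else if (object@nTetramers != 0L) {
    return("empty dimer table with nTetramers > 0")
  }
  TRUE
})

#' ChordLayout: full chord-diagram geometry
#'
#' Backend-independent geometry of a chord diagram on the unit circle:
#' angular sector spans per node, ribbon sub-spans per dimer, colors and
#' label anchors.  Angles are in degrees, measured counter-clockwise from
#' 3 o'clock (the usual mathematical convention); the diagram is laid out
#' clockwise, so within a sector \code{thetaEnd < thetaStart}.
#'
#' @slot sectors data.frame of per-node geometry (class, term, accession,
#'   label, weight, thetaStart, thetaEnd, span, color, labelAngle,
#'   labelRadius, fontSize).
#' @slot ribbons data.frame of per-dimer geometry (class, source/target
#'   accession and label, frequency, source and target angular sub-spans,
#'   color, opacity).
#' @slot config the layout configuration used (see \code{\link{layoutConfig}}).
#' @slot diagnostics character vector of warnings emitted during layout.
#' @export
setClass("ChordLayout",
  representation(sectors = "data.frame", ribbons = "data.frame",
                 config = "list", diagnostics = "character"))

setValidity("ChordLayout", function(object) {
  s <- object@sectors
  if (nrow(s) == 0) return("layout has no sectors")
  gap <- object@config$gapDegree
  total <- sum(s$span) + nrow(s) * gap
  if (abs(total - 360) > 1e-9)
    return(sprintf("sector spans + gaps = %.12f, expected 360", total))
  TRUE
})
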