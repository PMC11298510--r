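## Generics and accessors.

#' Extract the tetramer records of a TetramerSet
#' @param x a \code{TetramerSet}.
#' @return The underlying data.frame (canonical columns first).
#' @export
setGeneric("tetramers", function(x) standardGeneric("tetramers"))

#' @rdname tetramers
#' @export
setMethod("tetramers", "TetramerSet", function(x) x@records)

#' Provenance label of a TetramerSet
#' @param x a \code{TetramerSet}.
#' @return Character scalar.
#' @export
setGeneric("sourceLabel", function(x) standardGeneric("sourceLabel"))

#' @rdname sourceLabel
#' @export
setMethod("sourceLabel", "TetramerSet", function(x) x@sourceLabel)

#' Diagnostics accumulated while building an object
#' @param x a \code{TetramerSet} or \code{ChordLayout}.
#' @return A list (TetramerSet) or character vector (ChordLayout).
#' @export
setGeneric("diagnostics", function(x) standardGeneric("diagnostics"))

#' @rdname diagnostics
#' @export
setMethod("diagnostics", "TetramerSet", function(x) x@diagnostics)

#' @rdname diagnostics
#' @export
setMethod("diagnostics", "ChordLayout", function(x) x@diagnostics)

#' Dimer edge list of a DimerTable
#' @param x a \code{DimerTable}.
#' @return data.frame of dimers with frequencies.
#' @export
setGeneric("dimers", function(x) standardGeneric("dimers"))

#' @rdname dimers
#' @export
setMethod("dimers", "DimerTable", function(x) x@dimers)

#' Number of unique tetramers behind a DimerTable
#' @param x a \code{DimerTable}.
#' @return Integer scalar.
#' @export
setGeneric("nTetramers", function(x) standardGeneric("nTetramers"))

#' @rdname nTetramers
#' @export
setMethod("nTetramers", "DimerTable", function(x) x@nTetramers)

#' Sector geometry of a ChordLayout
#' @param x a \code{ChordLayout}.
#' @return data.frame of sectors.
#' @export
setGeneric("sectors", function(x) standardGeneric("sectors"))

#' @rdname sectors
#' @export
setMethod("sectors", "ChordLayout", function(x) x@sectors)

#' Ribbon geometry of a ChordLayout
#' @param x a \code{ChordLayout}.
#' @return data.frame of ribbons.
#' @export
setGeneric("ribbons", function(x) standardGeneric("ribbons"))

#' @rdname ribbons
#' @export
setMethod("ribbons", "ChordLayout", function(x) x@ribbons)

#' Curated interactions of a CuratedDatabase
#' @param x a \code{CuratedDatabase}.
#' @return data.frame of interactions.
#' @export
setGeneric("interactions", function(x) standardGeneric("interactions"))

#' @rdname interactions
#' @export
setMethod("interactions", "CuratedDatabase", function(x) x@interactions)

#' Term hierarchies attached to a CuratedDatabase
#' @param x a \code{CuratedDatabase}.
#' @return Named list of \code{TermHierarchy}.
#' @export
setGeneric("hierarchies", function(x) standardGeneric("hierarchies"))

#' @rdname hierarchies
#' @export
setMethod("hierarchies", "CuratedDatabase", function(x) x@hierarchies)

setMethod("length", "TetramerSet", function(x) nrow(x@records))

setMethod("show", "TetramerSet", function(object) {
  s <- summarizeTetramers(object)
  cat("TetramerSet with", s$records, "record(s) (",
      s$uniqueTetramers, "unique )\n")
  cat("  chemicals:", s$chemicals, " genes:", s$genes,
      " phenotypes:", s$phenotypes, " diseases:", s$diseases, "\n")
  if (nzchar(object@sourceLabel))
    cat("  source:", object@sourceLabel, "\n")
  invisible(object)
})

setMethod("show", "CuratedDatabase", function(object) {
  it <- object@interactions
  cat("CuratedDatabase with", nrow(it), "interaction(s)\n")
  if (nrow(it)) {
    tab <- table(factor(it$kind, levels = interactionKinds()))
    for (k in names(tab)) cat(sprintf("  %-20s %d\n", k, tab[[k]]))
  }
  if (length(object@hierarchies))
    cat("  hierarchies:", paste(names(object@hierarchies), collapse = ", "),
        "\n")
  invisible(object)
})

setMethod("show", "TermHierarchy", function(object) {
  cat("TermHierarchy (", object@nodeClass, ") with ", nrow(object@edges),
      " edge(s)\n", sep = "")
  invisible(object)
})

setMethod("show", "DimerTable", function(object) {
  cat("DimerTable from", object@nTetramers, "unique tetramer(s)\n")
  d <- object@dimers
  for (cl in dimerClasses())
    cat(sprintf("  %-18s %d dimer(s)\n", cl, sum(d$class == cl)))
  invisible(object)
})

setMethod("show", "ChordLayout", function(object) {
  cat("ChordLayout:", nrow(object@sectors), "sector(s),",
      nrow(object@ribbons), "ribbon(s), gap",
      object@config$gapDegree, "degree(s)\n")
  if (length(object@diagnostics))
    cat("  diagnostics:", paste(object@diagnostics, collapse = "; "), "\n")
  invisible(object)
})
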