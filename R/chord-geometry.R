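## Chord-diagram geometry: frequency-proportional sectors, gap handling,
## ribbon packing, label anchors.  Pure computation, no graphics device.

#' Layout configuration for chord-diagram geometry
#'
#' @param gapDegree angular gap in degrees between adjacent sectors
#'   (default 1).  The layout is feasible only while
#'   \code{nSectors * gapDegree < 360}.
#' @param startAngle degrees where the first chemical sector begins,
#'   measured counter-clockwise from 3 o'clock (default 90 = 12 o'clock).
#' @param labelMode \code{"term"} (display names) or \code{"id"}
#'   (accession identifiers); the compact ID mode helps large diagrams.
#' @param fontScale multiplicative label font-size factor (the familiar
#'   \code{cex} semantics): 0.5 halves the label size, 1.5 enlarges it by
#'   50\%.  Default 1.
#' @param baseFontSize nominal label size in points at \code{fontScale = 1}.
#' @param palette per-class gradient endpoints; see
#'   \code{\link{defaultPalettes}} and \code{\link{colorblindPalettes}}.
#' @param ribbonOpacity ribbon fill opacity in [0, 1].
#' @param sortWithinClass \code{"alphabetical"} (default) or
#'   \code{"weight"} (descending) sector order within each class.
#' @param tetramerWarnLimit emit a readability warning when more unique
#'   tetramers than this are laid out (default 1500).
#' @return Validated named list of configuration values.
#' @export
layoutConfig <- function(gapDegree = 1, startAngle = 90,
                         labelMode = c("term", "id"), fontScale = 1,
                         baseFontSize = 10, palette = defaultPalettes(),
                         ribbonOpacity = 0.7,
                         sortWithinClass = c("alphabetical", "weight"),
                         tetramerWarnLimit = 1500L) {
  labelMode <- match.arg(labelMode)
  sortWithinClass <- match.arg(sortWithinClass)
  stopifnot(gapDegree >= 0, fontScale > 0, baseFontSize > 0,
            ribbonOpacity >= 0, ribbonOpacity <= 1,
            tetramerWarnLimit >= 0)
  if (!identical(sort(names(palette)), sort(nodeClasses())))
    stop("palette must have exactly the four node-class entries")
  for (cl in nodeClasses())
    if (length(palette[[cl]]) != 2L)
      stop("palette[['", cl, "']] must give exactly two endpoint colors")
  list(gapDegree = gapDegree, startAngle = startAngle, labelMode = labelMode,
       fontScale = fontScale, baseFontSize = baseFontSize, palette = palette,
       ribbonOpacity = ribbonOpacity, sortWithinClass = sortWithinClass,
       tetramerWarnLimit = as.integer(tetramerWarnLimit))
}

#' Compute the chord-diagram layout of a dimer table
#'
#' Places one sector per node on the circle, clockwise from
#' \code{startAngle}, classes in chemical, gene, phenotype, disease order.
#' After subtracting one \code{gapDegree} per sector, the remaining
#' \code{360 - n * gap} degrees are divided among sectors proportionally to
#' node weight, so \code{span_i = (360 - n*gap) * w_i / sum(w)}.  Each
#' dimer becomes a ribbon with one angular sub-span inside its source
#' sector and one inside its target sector; within a sector, ribbons are
#' packed clockwise in the order of their partner sector's position
#' (ties by partner label), with width \code{span * frequency / weight},
#' so the sub-spans tile the sector exactly.
#'
#' Infeasible gaps (\code{n * gap >= 360}) raise a condition of class
#' \code{"cgpd_gap_infeasible"} whose message reports the largest feasible
#' gap (\code{360 / n}, exclusive); an empty table raises
#' \code{"cgpd_empty_input"}.  Laying out more unique tetramers than
#' \code{tetramerWarnLimit} emits a readability warning, not an error.
#'
#' @param table a \code{\link{DimerTable}}.
#' @param config a \code{\link{layoutConfig}}.
#' @return A \code{\link{ChordLayout}} with colors and label anchors
#'   assigned.
#' @examples
#' layout <- computeLayout(decomposeDimers(ozoneToyTetramers()))
#' sectors(layout)[, c("label", "weight", "span")]
#' @export
computeLayout <- function(table, config = layoutConfig()) {
  stopifnot(methods::is(table, "DimerTable"))
  d <- dimers(table)
  if (nrow(d) == 0L)
    stop(errorCondition("cannot lay out an empty dimer table",
                        class = "cgpd_empty_input"))
  diagnostics <- character(0)
  if (table@nTetramers > config$tetramerWarnLimit) {
    msg <- sprintf(paste0("%d unique tetramers exceed the practical ",
                          "readability limit of %d; consider narrowing the ",
                          "query, lowering fontScale, or labelMode = 'id'"),
                   table@nTetramers, config$tetramerWarnLimit)
    warning(msg, call. = FALSE)
    diagnostics <- c(diagnostics, msg)
  }

  w <- nodeWeights(table)
  w$label <- if (config$labelMode == "id") w$accession else w$term
  ## sector order: class order, then alphabetical label or descending weight
  ord <- if (config$sortWithinClass == "weight") {
    order(match(w$class, nodeClasses()), -w$weight, tolower(w$label),
          w$accession, method = "radix")
  } else {
    order(match(w$class, nodeClasses()), tolower(w$label), w$accession,
          method = "radix")
  }
  w <- w[ord, , drop = FALSE]
  n <- nrow(w)
  gap <- config$gapDegree
  if (n * gap >= 360) {
    maxGap <- 360 / n
    stop(errorCondition(
      sprintf(paste0("gap infeasible: %d sectors at gap %.6g degrees need ",
                     ">= 360 degrees, leaving no space to allocate sectors; ",
                     "choose gapDegree < %.6g"), n, gap, maxGap),
      class = "cgpd_gap_infeasible", maxFeasibleGap = maxGap))
  }
  total <- 360 - n * gap
  span <- total * w$weight / sum(w$weight)
  thetaStart <- numeric(n)
  cur <- config$startAngle
  for (i in seq_len(n)) {
    thetaStart[i] <- cur
    cur <- cur - span[i] - gap
  }
  s <- data.frame(class = w$class, term = w$term, accession = w$accession,
                  label = w$label, weight = w$weight,
                  thetaStart = thetaStart, thetaEnd = thetaStart - span,
                  span = span, color = NA_character_,
                  stringsAsFactors = FALSE)

  ## ribbons: pack each sector's incident dimers clockwise by partner position
  srcClass <- c(chemical_gene = "chemical", gene_phenotype = "gene",
                phenotype_disease = "phenotype")
  tgtClass <- c(chemical_gene = "gene", gene_phenotype = "phenotype",
                phenotype_disease = "disease")
  skey <- paste(s$class, s$accession, sep = "\t")
  d$srcSector <- match(paste(srcClass[d$class], d$source_id, sep = "\t"), skey)
  d$tgtSector <- match(paste(tgtClass[d$class], d$target_id, sep = "\t"), skey)
  d$sStart <- d$sEnd <- d$tStart <- d$tEnd <- NA_real_

  for (i in seq_len(n)) {
    ## incident dimers: rows where this sector is source, then target
    asSrc <- which(d$srcSector == i)
    asTgt <- which(d$tgtSector == i)
    inc <- data.frame(row = c(asSrc, asTgt),
                      end = rep(c("src", "tgt"), c(length(asSrc),
                                                   length(asTgt))),
                      partner = c(d$tgtSector[asSrc], d$srcSector[asTgt]),
                      stringsAsFactors = FALSE)
    if (nrow(inc) == 0L) next
    partnerLabel <- s$label[inc$partner]
    partnerAcc <- s$accession[inc$partner]
    inc <- inc[order(inc$partner, tolower(partnerLabel), partnerAcc,
                     method = "radix"), , drop = FALSE]
    freq <- d$frequency[inc$row]
    width <- s$span[i] * freq / s$weight[i]
    hi <- s$thetaStart[i] - c(0, cumsum(width))  # clockwise allocation
    for (j in seq_len(nrow(inc))) {
      r <- inc$row[j]
      if (inc$end[j] == "src") {
        d$sStart[r] <- hi[j]; d$sEnd[r] <- hi[j + 1L]
      } else {
        d$tStart[r] <- hi[j]; d$tEnd[r] <- hi[j + 1L]
      }
    }
  }

  rib <- data.frame(
    class = d$class,
    source_label = s$label[d$srcSector], source_id = d$source_id,
    target_label = s$label[d$tgtSector], target_id = d$target_id,
    frequency = d$frequency,
    sourceThetaStart = d$sStart, sourceThetaEnd = d$sEnd,
    targetThetaStart = d$tStart, targetThetaEnd = d$tEnd,
    color = NA_character_, opacity = config$ribbonOpacity,
    stringsAsFactors = FALSE)
  rib <- rib[order(match(rib$class, dimerClasses()), -rib$sourceThetaStart,
                   -rib$targetThetaStart, method = "radix"), , drop = FALSE]
  rownames(rib) <- NULL

  layout <- methods::new("ChordLayout", sectors = s, ribbons = rib,
                         config = config, diagnostics = diagnostics)
  layout <- assignColors(layout, config$palette, config$ribbonOpacity)
  placeLabels(layout, config)
}

#' Place label anchors on a chord layout
#'
#' Anchors each label at its sector's angular midpoint just outside the
#' outer radius (unit-circle radius 1.05), rotated to read radially.
#' The nominal font size is \code{baseFontSize * fontScale}, so
#' \code{fontScale = 0.5} halves and \code{fontScale = 1.5} enlarges labels
#' by 50 percent.  Label text follows \code{labelMode}: display terms or
#' accession identifiers.
#'
#' @param layout a \code{\link{ChordLayout}}.
#' @param config a \code{\link{layoutConfig}}; defaults to the layout's own.
#' @return The layout with \code{label}, \code{labelAngle},
#'   \code{labelRadius} and \code{fontSize} set on its sectors.
#' @export
placeLabels <- function(layout, config = layout@config) {
  stopifnot(methods::is(layout, "ChordLayout"))
  s <- layout@sectors
  s$label <- if (config$labelMode == "id") s$accession else s$term
  s$labelAngle <- (s$thetaStart + s$thetaEnd) / 2
  s$labelRadius <- 1.05
  s$fontSize <- config$baseFontSize * config$fontScale
  cfg <- layout@config
  cfg$labelMode <- config$labelMode
  cfg$fontScale <- config$fontScale
  cfg$baseFontSize <- config$baseFontSize
  methods::new("ChordLayout", sectors = s, ribbons = layout@ribbons,
               config = cfg, diagnostics = layout@diagnostics)
}

#' Serialize a chord layout to JSON
#'
#' A documented geometry dump (sectors, ribbons, config, diagnostics) for
#' golden-file tests and external renderers; read back with
#' \code{\link{readLayoutJSON}}.
#'
#' @param layout a \code{\link{ChordLayout}}.
#' @param file path; if \code{NULL}, the JSON string is returned.
#' @return Invisibly the file path, or the JSON string when
#'   \code{file = NULL}.
#' @export
writeLayoutJSON <- function(layout, file = NULL) {
  stopifnot(methods::is(layout, "ChordLayout"))
  obj <- list(sectors = layout@sectors, ribbons = layout@ribbons,
              config = layout@config, diagnostics = layout@diagnostics)
  js <- jsonlite::toJSON(obj, dataframe = "columns", digits = NA,
                         auto_unbox = TRUE, null = "null", pretty = TRUE)
  if (is.null(file)) return(as.character(js))
  writeLines(js, file)
  invisible(file)
}

#' Read a chord layout from its JSON geometry dump
#'
#' @param file path to a file written by \code{\link{writeLayoutJSON}}.
#' @return A \code{\link{ChordLayout}}.
#' @export
readLayoutJSON <- function(file) {
  obj <- jsonlite::fromJSON(file, simplifyVector = TRUE)
  cfg <- obj$config
  cfg$palette <- lapply(cfg$palette, as.character)
  methods::new("ChordLayout",
               sectors = as.data.frame(obj$sectors, stringsAsFactors = FALSE),
               ribbons = as.data.frame(obj$ribbons, stringsAsFactors = FALSE),
               config = cfg,
               diagnostics = as.character(obj$diagnostics))
}
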