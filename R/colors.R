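## Class palettes and gradient interpolation.

#' Default class palettes
#'
#' Ordered pairs of gradient endpoints (lighter to darker) per node class:
#' blues for chemicals, greens for genes, purples for phenotypes, reds for
#' diseases.  A gradient is interpolated from the first color to the second
#' across the nodes of the class.
#'
#' @return Named list of length-2 character vectors.
#' @export
defaultPalettes <- function() {
  list(chemical  = c("#9ECAE1", "#08519C"),
       gene      = c("#A1D99B", "#006D2C"),
       phenotype = c("#BCBDDC", "#54278F"),
       disease   = c("#FCAE91", "#A50F15"))
}

#' Colorblind-safe class palettes
#'
#' An alternative preset built from Okabe-Ito hues, for readers with
#' color-vision deficiencies.  Same structure as
#' \code{\link{defaultPalettes}}.
#'
#' @return Named list of length-2 character vectors.
#' @export
colorblindPalettes <- function() {
  list(chemical  = c("#9BD4F5", "#0072B2"),  # sky blue -> blue
       gene      = c("#B5E0D1", "#009E73"),  # pale -> bluish green
       phenotype = c("#E7C2E0", "#CC79A7"),  # pale -> reddish purple
       disease   = c("#F4C47A", "#D55E00"))  # pale -> vermillion
}

## parse one R color (name or hex) to an RGB triple; error names the entry
.parseColor <- function(col, what = "color") {
  rgb <- tryCatch(grDevices::col2rgb(col), error = function(e) NULL)
  if (is.null(rgb))
    stop("unparsable ", what, ": '", col, "'", call. = FALSE)
  as.numeric(rgb[, 1L])
}

#' Linear gradient between two colors
#'
#' Node \code{i} of \code{k} (0-indexed, in sector order) receives the
#' linear RGB interpolation at \code{i/(k-1)} between the two endpoint
#' colors; a single node receives the first endpoint exactly, and two nodes
#' receive the two endpoints exactly.
#'
#' @param endpoints character vector of two colors (R names or hex).
#' @param k number of colors to produce.
#' @return Character vector of \code{k} uppercase \code{#RRGGBB} values.
#' @examples
#' classGradient(c("black", "white"), 5)
#' @export
classGradient <- function(endpoints, k) {
  stopifnot(length(endpoints) == 2L, k >= 1L)
  a <- .parseColor(endpoints[1L], "palette color")
  b <- .parseColor(endpoints[2L], "palette color")
  if (k == 1L) t <- 0 else t <- (seq_len(k) - 1L) / (k - 1L)
  ch <- function(i) round((1 - t) * a[i] + t * b[i])
  toupper(grDevices::rgb(ch(1L), ch(2L), ch(3L), maxColorValue = 255))
}

#' Recolor a chord layout
#'
#' Assigns sector colors by interpolating each class's two palette endpoints
#' across that class's sectors (in sector order), and colors every ribbon
#' with its source sector's color so that chemical-gene ribbons read in the
#' chemical palette, gene-phenotype in the gene palette and
#' phenotype-disease in the phenotype palette.
#'
#' @param layout a \code{\link{ChordLayout}}.
#' @param palette named list of length-2 color vectors per node class
#'   (default \code{\link{defaultPalettes}}).
#' @param ribbonOpacity fill opacity applied to ribbons, in [0, 1].
#' @return The layout with updated \code{color} columns.
#' @export
assignColors <- function(layout, palette = defaultPalettes(),
                         ribbonOpacity = layout@config$ribbonOpacity) {
  stopifnot(methods::is(layout, "ChordLayout"))
  if (!identical(sort(names(palette)), sort(nodeClasses())))
    stop("palette must have exactly the four node-class entries")
  s <- layout@sectors
  for (cl in nodeClasses()) {
    idx <- which(s$class == cl)
    if (length(idx))
      s$color[idx] <- classGradient(palette[[cl]], length(idx))
  }
  r <- layout@ribbons
  if (nrow(r)) {
    key <- paste(s$class, s$accession, sep = "\t")
    srcClass <- c(chemical_gene = "chemical", gene_phenotype = "gene",
                  phenotype_disease = "phenotype")
    r$color <- s$color[match(paste(srcClass[r$class], r$source_id,
                                   sep = "\t"), key)]
    r$opacity <- ribbonOpacity
  }
  cfg <- layout@config
  cfg$palette <- palette
  cfg$ribbonOpacity <- ribbonOpacity
  methods::new("ChordLayout", sectors = s, ribbons = r, config = cfg,
               diagnostics = layout@diagnostics)
}
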