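## Shared constants and small helpers.

#' @importFrom data.table data.table as.data.table setnames rbindlist .N :=
NULL

.datatable.aware <- TRUE

#' Node classes in clockwise reading order
#'
#' The four node classes of a CGPD-tetramer, in the fixed clockwise reading
#' order chemical, gene, phenotype, disease.
#'
#' @return Character vector of the four class names.
#' @export
nodeClasses <- function() c("chemical", "gene", "phenotype", "disease")

#' The five curated interaction kinds
#'
#' One kind per pairwise supporting relation required for a tetramer.
#'
#' @return Character vector of length five.
#' @export
interactionKinds <- function() {
  c("chemical_gene", "chemical_phenotype", "chemical_disease",
    "gene_disease", "gene_phenotype")
}

#' The three dimer classes
#'
#' Directed adjacent pairs read clockwise out of a tetramer:
#' chemical to gene, gene to phenotype, phenotype to disease.
#'
#' @return Character vector of length three.
#' @export
dimerClasses <- function() c("chemical_gene", "gene_phenotype", "phenotype_disease")

## subject/object node classes per interaction kind
.kindClasses <- function(kind) {
  switch(kind,
    chemical_gene      = c("chemical", "gene"),
    chemical_phenotype = c("chemical", "phenotype"),
    chemical_disease   = c("chemical", "disease"),
    gene_disease       = c("gene", "disease"),
    gene_phenotype     = c("gene", "phenotype"),
    stop("unknown interaction kind: ", kind)
  )
}

## canonical tetramer CSV header, in column order
.tetramerCols <- function() {
  c("Chemical", "Chemical.ID", "Gene", "Gene.ID",
    "Phenotype", "Phenotype.ID", "Disease", "Disease.ID")
}

## ID column per node class
.idCol <- function(class) {
  c(chemical = "Chemical.ID", gene = "Gene.ID",
    phenotype = "Phenotype.ID", disease = "Disease.ID")[[class]]
}

.termCol <- function(class) {
  c(chemical = "Chemical", gene = "Gene",
    phenotype = "Phenotype", disease = "Disease")[[class]]
}

## tetramer identity key: the 4-tuple of accessions
.tetramerKey <- function(df) {
  paste(df[["Chemical.ID"]], df[["Gene.ID"]],
        df[["Phenotype.ID"]], df[["Disease.ID"]], sep = "\t")
}

## evaluate expr with a temporarily seeded RNG, restoring global state after
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## stable case-insensitive ordering by label, ties broken by accession
.orderLabels <- function(labels, accessions) {
  order(tolower(labels), accessions, method = "radix")
}

.emptyTetramerFrame <- function() {
  df <- as.data.frame(
    stats::setNames(rep(list(character(0)), 8L), .tetramerCols()),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  df
}
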