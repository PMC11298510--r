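## Dimer decomposition: tetramers -> directed class edges with
## tetramer-support frequencies, and per-node weights.

#' Decompose a tetramer set into dimers
#'
#' Each unique tetramer (by its accession 4-tuple) contributes exactly one
#' chemical-gene, one gene-phenotype and one phenotype-disease occurrence;
#' occurrences are aggregated by (class, source accession, target accession)
#' into frequencies.  Consequently, within every dimer class the
#' frequencies sum to the number of unique tetramers — the conservation
#' property that lets ribbons exactly tile their sectors downstream.
#'
#' Duplicated input records are collapsed before counting, so frequencies
#' count unique tetramers, not CSV rows.
#'
#' @param set a \code{\link{TetramerSet}}.
#' @param useIds use accession IDs instead of display terms as node labels
#'   downstream (presentation only; frequencies are unaffected).
#' @return A \code{\link{DimerTable}}.
#' @examples
#' decomposeDimers(ozoneToyTetramers())
#' @export
decomposeDimers <- function(set, useIds = FALSE) {
  stopifnot(methods::is(set, "TetramerSet"))
  df <- tetramers(set)
  df <- df[!duplicated(.tetramerKey(df)), , drop = FALSE]
  n <- nrow(df)
  if (n == 0L) {
    empty <- data.frame(class = character(0), source_term = character(0),
                        source_id = character(0), target_term = character(0),
                        target_id = character(0), frequency = integer(0),
                        stringsAsFactors = FALSE)
    return(methods::new("DimerTable", dimers = empty, nTetramers = 0L,
                        useIds = useIds))
  }
  one <- function(cl, sTerm, sId, tTerm, tId) {
    dt <- data.table::data.table(
      class = cl, source_term = df[[sTerm]], source_id = df[[sId]],
      target_term = df[[tTerm]], target_id = df[[tId]])
    dt[, list(source_term = source_term[1L], target_term = target_term[1L],
              frequency = .N),
       by = c("class", "source_id", "target_id")]
  }
  d <- data.table::rbindlist(list(
    one("chemical_gene", "Chemical", "Chemical.ID", "Gene", "Gene.ID"),
    one("gene_phenotype", "Gene", "Gene.ID", "Phenotype", "Phenotype.ID"),
    one("phenotype_disease", "Phenotype", "Phenotype.ID",
        "Disease", "Disease.ID")))
  d <- as.data.frame(d, stringsAsFactors = FALSE)
  d$frequency <- as.integer(d$frequency)
  d <- d[, c("class", "source_term", "source_id", "target_term", "target_id",
             "frequency")]
  ord <- order(match(d$class, dimerClasses()), tolower(d$source_term),
               d$source_id, tolower(d$target_term), d$target_id,
               method = "radix")
  d <- d[ord, , drop = FALSE]
  rownames(d) <- NULL
  methods::new("DimerTable", dimers = d, nTetramers = n, useIds = useIds)
}

#' Node weights of a dimer table
#'
#' A node's weight is the summed frequency of its incident dimers: chemicals
#' sum their outgoing chemical-gene frequencies, diseases their incoming
#' phenotype-disease frequencies, and the middle classes (genes,
#' phenotypes) sum both sides — incoming plus outgoing — so a middle node
#' weighs twice its tetramer-participation count.  This is the sector-length
#' definition under which ribbon widths exactly tile each sector of the
#' chord diagram.
#'
#' @param table a \code{\link{DimerTable}}.
#' @return data.frame with columns \code{class}, \code{term},
#'   \code{accession}, \code{label}, \code{weight}, one row per node that
#'   appears in any dimer.
#' @export
nodeWeights <- function(table) {
  stopifnot(methods::is(table, "DimerTable"))
  d <- dimers(table)
  srcClass <- c(chemical_gene = "chemical", gene_phenotype = "gene",
                phenotype_disease = "phenotype")
  tgtClass <- c(chemical_gene = "gene", gene_phenotype = "phenotype",
                phenotype_disease = "disease")
  ends <- rbind(
    data.frame(class = unname(srcClass[d$class]), term = d$source_term,
               accession = d$source_id, frequency = d$frequency,
               stringsAsFactors = FALSE),
    data.frame(class = unname(tgtClass[d$class]), term = d$target_term,
               accession = d$target_id, frequency = d$frequency,
               stringsAsFactors = FALSE))
  if (nrow(ends) == 0L)
    return(data.frame(class = character(0), term = character(0),
                      accession = character(0), label = character(0),
                      weight = integer(0), stringsAsFactors = FALSE))
  dt <- data.table::as.data.table(ends)
  w <- dt[, list(term = term[1L], weight = as.integer(sum(frequency))),
          by = c("class", "accession")]
  w <- as.data.frame(w, stringsAsFactors = FALSE)
  w$label <- if (table@useIds) w$accession else w$term
  w <- w[, c("class", "term", "accession", "label", "weight")]
  ord <- order(match(w$class, nodeClasses()), tolower(w$label), w$accession,
               method = "radix")
  w <- w[ord, , drop = FALSE]
  rownames(w) <- NULL
  w
}
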