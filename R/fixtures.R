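## Seeded synthetic fixtures: curated databases with brute-force oracle
## closures, tetramer tables, hierarchies, and the packaged toy example.
## All generators draw only integer-based RNG (sample) under a local seed,
## so the same seed gives identical output on every platform.

.synTerm <- function(class, i) {
  switch(class,
    chemical  = sprintf("chem%03d", i),
    gene      = sprintf("GENE%03d", i),
    phenotype = sprintf("phenotype %03d", i),
    disease   = sprintf("disease %02d", i))
}

.synId <- function(class, i) {
  prefix <- c(chemical = "C", gene = "G", phenotype = "P", disease = "D")
  sprintf("%s%04d", prefix[[class]], i)
}

#' Brute-force tetramer enumeration (reference oracle)
#'
#' Exhaustively checks every candidate (chemical, gene, phenotype, disease)
#' quadruple over the accessions present in the database for the presence
#' of all five supporting relations.  Quadratic and intended for small
#' inputs; it is the reference against which the join-based
#' \code{\link{generateTetramers}} is validated.
#'
#' @param db a \code{\link{CuratedDatabase}}.
#' @return A \code{\link{TetramerSet}}, sorted like
#'   \code{generateTetramers} output.
#' @export
bruteForceTetramers <- function(db) {
  stopifnot(methods::is(db, "CuratedDatabase"))
  it <- db@interactions
  cs <- unique(it$subject_id[it$kind %in%
         c("chemical_gene", "chemical_phenotype", "chemical_disease")])
  gs <- unique(c(it$object_id[it$kind == "chemical_gene"],
                 it$subject_id[it$kind %in% c("gene_phenotype",
                                              "gene_disease")]))
  ps <- unique(c(it$object_id[it$kind %in% c("chemical_phenotype",
                                             "gene_phenotype")]))
  ds <- unique(c(it$object_id[it$kind %in% c("chemical_disease",
                                             "gene_disease")]))
  if (!length(cs) || !length(gs) || !length(ps) || !length(ds))
    return(TetramerSet(sourceLabel = "brute-force"))
  pair <- function(kind) {
    x <- it[it$kind == kind, ]
    paste(x$subject_id, x$object_id, sep = "\t")
  }
  CG <- pair("chemical_gene"); CP <- pair("chemical_phenotype")
  CD <- pair("chemical_disease"); GP <- pair("gene_phenotype")
  GD <- pair("gene_disease")
  grid <- expand.grid(c = cs, g = gs, p = ps, d = ds,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  ok <- paste(grid$c, grid$g, sep = "\t") %in% CG &
        paste(grid$c, grid$p, sep = "\t") %in% CP &
        paste(grid$c, grid$d, sep = "\t") %in% CD &
        paste(grid$g, grid$p, sep = "\t") %in% GP &
        paste(grid$g, grid$d, sep = "\t") %in% GD
  grid <- grid[ok, , drop = FALSE]
  ## display terms: first curated occurrence of each accession
  lut <- local({
    key <- c(it$subject_id, it$object_id)
    val <- c(it$subject_term, it$object_term)
    keep <- !duplicated(key)
    stats::setNames(val[keep], key[keep])
  })
  df <- data.frame(
    Chemical = unname(lut[grid$c]), `Chemical.ID` = grid$c,
    Gene = unname(lut[grid$g]), `Gene.ID` = grid$g,
    Phenotype = unname(lut[grid$p]), `Phenotype.ID` = grid$p,
    Disease = unname(lut[grid$d]), `Disease.ID` = grid$d,
    check.names = FALSE, stringsAsFactors = FALSE)
  ord <- order(tolower(df$Chemical), tolower(df$Gene), tolower(df$Phenotype),
               tolower(df$Disease), df$`Chemical.ID`, df$`Gene.ID`,
               df$`Phenotype.ID`, df$`Disease.ID`, method = "radix")
  TetramerSet(df[ord, , drop = FALSE], sourceLabel = "brute-force")
}

#' Simulate a curated database with a known tetramer closure
#'
#' Fills each of the five interaction tables independently: every possible
#' subject-object pair is included with the given probability, and,
#' optionally, \code{plant} complete quadruples (all five supporting
#' relations) are added so that at least that many tetramers exist.
#' The expected tetramer closure is computed by exhaustive brute-force
#' enumeration (\code{\link{bruteForceTetramers}}) and returned alongside
#' the database, enabling oracle tests of the join.
#'
#' @param seed integer seed; the same seed reproduces the database exactly.
#' @param nChemicals,nGenes,nPhenotypes,nDiseases class cardinalities.
#' @param prob inclusion probability per pair; scalar or named per kind
#'   (\code{\link{interactionKinds}}).
#' @param plant number of guaranteed-complete quadruples to plant.
#' @return List with elements \code{database} (a
#'   \code{\link{CuratedDatabase}}) and \code{expected} (the brute-force
#'   \code{\link{TetramerSet}}).
#' @examples
#' fx <- simulateDatabase(seed = 1, plant = 7, prob = 0)
#' length(fx$expected)  # 7
#' @export
simulateDatabase <- function(seed, nChemicals = 10, nGenes = 20,
                             nPhenotypes = 20, nDiseases = 5, prob = 0.3,
                             plant = 0) {
  stopifnot(nChemicals >= 1, nGenes >= 1, nPhenotypes >= 1, nDiseases >= 1,
            all(prob >= 0), all(prob <= 1),
            plant <= nChemicals * nGenes * nPhenotypes * nDiseases)
  if (length(prob) == 1L)
    prob <- stats::setNames(rep(prob, 5L), interactionKinds())
  card <- c(chemical = nChemicals, gene = nGenes, phenotype = nPhenotypes,
            disease = nDiseases)
  .withSeed(seed, {
    rows <- list()
    for (kind in interactionKinds()) {
      cls <- .kindClasses(kind)
      nS <- card[[cls[1L]]]; nO <- card[[cls[2L]]]
      grid <- expand.grid(s = seq_len(nS), o = seq_len(nO),
                          KEEP.OUT.ATTRS = FALSE)
      ## integer draw: keep pair when a uniform integer in 1..1e6 falls
      ## below prob * 1e6 (avoids float-order dependence)
      keep <- sample.int(1000000L, nrow(grid), replace = TRUE) <=
        round(prob[[kind]] * 1000000L)
      grid <- grid[keep, , drop = FALSE]
      if (nrow(grid))
        rows[[kind]] <- data.frame(
          kind = kind,
          subject_term = .synTerm(cls[1L], grid$s),
          subject_id = .synId(cls[1L], grid$s),
          object_term = .synTerm(cls[2L], grid$o),
          object_id = .synId(cls[2L], grid$o),
          stringsAsFactors = FALSE)
    }
    if (plant > 0) {
      total <- nChemicals * nGenes * nPhenotypes * nDiseases
      picks <- sample.int(total, plant)
      q <- .decodeQuad(picks, nGenes, nPhenotypes, nDiseases)
      mk <- function(kind, cls1, i1, cls2, i2) data.frame(
        kind = kind,
        subject_term = .synTerm(cls1, i1), subject_id = .synId(cls1, i1),
        object_term = .synTerm(cls2, i2), object_id = .synId(cls2, i2),
        stringsAsFactors = FALSE)
      rows$planted <- rbind(
        mk("chemical_gene", "chemical", q$c, "gene", q$g),
        mk("chemical_phenotype", "chemical", q$c, "phenotype", q$p),
        mk("chemical_disease", "chemical", q$c, "disease", q$d),
        mk("gene_phenotype", "gene", q$g, "phenotype", q$p),
        mk("gene_disease", "gene", q$g, "disease", q$d))
    }
    it <- if (length(rows)) do.call(rbind, unname(rows)) else
      data.frame(kind = character(0), subject_term = character(0),
                 subject_id = character(0), object_term = character(0),
                 object_id = character(0), stringsAsFactors = FALSE)
    db <- CuratedDatabase(it)
    list(database = db, expected = bruteForceTetramers(db))
  })
}

## decode linear quadruple indices (1-based) into class indices
.decodeQuad <- function(idx, nGenes, nPhenotypes, nDiseases) {
  q <- idx - 1L
  d <- q %% nDiseases
  q <- q %/% nDiseases
  p <- q %% nPhenotypes
  q <- q %/% nPhenotypes
  g <- q %% nGenes
  c0 <- q %/% nGenes
  list(c = c0 + 1L, g = g + 1L, p = p + 1L, d = d + 1L)
}

.quadFrame <- function(q) {
  data.frame(
    Chemical = .synTerm("chemical", q$c),
    `Chemical.ID` = .synId("chemical", q$c),
    Gene = .synTerm("gene", q$g), `Gene.ID` = .synId("gene", q$g),
    Phenotype = .synTerm("phenotype", q$p),
    `Phenotype.ID` = .synId("phenotype", q$p),
    Disease = .synTerm("disease", q$d), `Disease.ID` = .synId("disease", q$d),
    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Simulate a tetramer table
#'
#' Draws \code{n} distinct tetramers uniformly from the cross product of the
#' class cardinalities, using synthetic accessions (C0001, G0001, P0001,
#' D0001 pattern).  Requesting more unique records than the cross product
#' holds raises a condition of class \code{"cgpd_infeasible_fixture"}.
#'
#' @param n number of (unique) tetramer records.
#' @param seed integer seed.
#' @param nChemicals,nGenes,nPhenotypes,nDiseases class cardinalities.
#' @return A \code{\link{TetramerSet}}.
#' @export
simulateTetramerTable <- function(n, seed, nChemicals = 5, nGenes = 30,
                                  nPhenotypes = 40, nDiseases = 3) {
  total <- nChemicals * nGenes * nPhenotypes * nDiseases
  if (n > total)
    stop(errorCondition(
      sprintf("cannot draw %d unique tetramers from %d possible quadruples",
              n, total), class = "cgpd_infeasible_fixture"))
  .withSeed(seed, {
    idx <- if (n > 0) sample.int(total, n) else integer(0)
    df <- if (n > 0) .quadFrame(.decodeQuad(idx, nGenes, nPhenotypes,
                                            nDiseases))
          else .emptyTetramerFrame()
    TetramerSet(df, sourceLabel = sprintf("simulated(n=%d,seed=%d)", n, seed))
  })
}

#' Simulate disjoint tetramer tables
#'
#' Draws \code{sum(sizes)} distinct tetramers and splits them into tables of
#' the requested sizes, so the tables are pairwise disjoint by construction
#' and their plain concatenation has exactly \code{sum(sizes)} unique
#' records (e.g. sizes 123, 122, 136 merge to 381).
#'
#' @param sizes integer vector of table sizes.
#' @param seed integer seed.
#' @param nChemicals,nGenes,nPhenotypes,nDiseases class cardinalities.
#' @return List of \code{\link{TetramerSet}}, one per size.
#' @export
simulateDisjointTables <- function(sizes, seed, nChemicals = 6, nGenes = 40,
                                   nPhenotypes = 60, nDiseases = 4) {
  total <- nChemicals * nGenes * nPhenotypes * nDiseases
  if (sum(sizes) > total)
    stop(errorCondition(
      sprintf("cannot draw %d unique tetramers from %d possible quadruples",
              sum(sizes), total), class = "cgpd_infeasible_fixture"))
  .withSeed(seed, {
    idx <- sample.int(total, sum(sizes))
    split <- rep(seq_along(sizes), sizes)
    lapply(seq_along(sizes), function(i) {
      q <- .decodeQuad(idx[split == i], nGenes, nPhenotypes, nDiseases)
      TetramerSet(.quadFrame(q),
                  sourceLabel = sprintf("simulated-part%d(seed=%d)", i, seed))
    })
  })
}

#' Simulate a tetramer table covering every term
#'
#' Like \code{\link{simulateTetramerTable}}, but guarantees that every
#' chemical, gene, phenotype and disease term appears at least once, so the
#' per-class unique counts equal the requested cardinalities exactly.  The
#' defaults mirror the shape of a typical category-query download — 309
#' tetramers over 2 chemicals, 61 genes, 87 phenotypes and 1 disease — with
#' entirely synthetic content (the accessions and terms are generated, not
#' curated).
#'
#' @param n number of unique records; must be at least
#'   \code{max(cardinalities)} and at most their product.
#' @param seed integer seed.
#' @param nChemicals,nGenes,nPhenotypes,nDiseases class cardinalities.
#' @return A \code{\link{TetramerSet}}.
#' @examples
#' summarizeTetramers(simulateCoveredTable(seed = 1))
#' @export
simulateCoveredTable <- function(n = 309, seed = 1, nChemicals = 2,
                                 nGenes = 61, nPhenotypes = 87,
                                 nDiseases = 1) {
  card <- c(nChemicals, nGenes, nPhenotypes, nDiseases)
  total <- prod(card)
  m <- max(card)
  if (n < m || n > total)
    stop(errorCondition(
      sprintf("need %d <= n <= %d for full coverage", m, total),
      class = "cgpd_infeasible_fixture"))
  encode <- function(c0, g, p, d)
    (((c0 - 1L) * nGenes + (g - 1L)) * nPhenotypes + (p - 1L)) *
      nDiseases + (d - 1L) + 1L
  j <- seq_len(m)
  cover <- encode((j - 1L) %% nChemicals + 1L, (j - 1L) %% nGenes + 1L,
                  (j - 1L) %% nPhenotypes + 1L, (j - 1L) %% nDiseases + 1L)
  .withSeed(seed, {
    rest <- setdiff(seq_len(total), cover)
    idx <- c(cover, if (n > m) sample(rest, n - m))
    idx <- sample(idx)  # shuffle so coverage rows are not a visible prefix
    df <- .quadFrame(.decodeQuad(idx, nGenes, nPhenotypes, nDiseases))
    TetramerSet(df, sourceLabel = sprintf("simulated-covered(n=%d,seed=%d)",
                                          n, seed))
  })
}

#' Simulate a term hierarchy
#'
#' Builds a rooted tree of the given depth and branching factor over
#' synthetic accessions, for descendant-expansion tests and demos.
#'
#' @param nodeClass which node class the hierarchy describes.
#' @param depth tree depth (root = depth 0).
#' @param branching children per internal node.
#' @return A \code{\link{TermHierarchy}}.
#' @export
simulateHierarchy <- function(nodeClass = "chemical", depth = 3,
                              branching = 3) {
  parents <- character(0); children <- character(0)
  level <- "H0001"
  counter <- 1L
  for (d in seq_len(depth)) {
    nxt <- character(0)
    for (p in level) {
      for (b in seq_len(branching)) {
        counter <- counter + 1L
        ch <- sprintf("H%04d", counter)
        parents <- c(parents, p); children <- c(children, ch)
        nxt <- c(nxt, ch)
      }
    }
    level <- nxt
  }
  TermHierarchy(nodeClass, data.frame(parent = parents, child = children,
                                      stringsAsFactors = FALSE))
}

#' The packaged three-tetramer worked example
#'
#' A minimal tetramer set for demonstrations: ozone paired with the genes
#' PTGFR and TFPI, the phenotypes inflammatory response and response to
#' lipopolysaccharide, and the disease airway obstruction — three tetramers
#' over one chemical, two genes, two phenotypes and one disease, with PTGFR
#' and response to lipopolysaccharide each supported by two of the three
#' tetramers so that their sectors visibly dominate the chord diagram.
#' The exact pairings are a plausible reconstruction assembled for this
#' package, not a curated download.
#'
#' @return A \code{\link{TetramerSet}} of three records.
#' @examples
#' summarizeTetramers(ozoneToyTetramers())
#' @export
ozoneToyTetramers <- function() {
  df <- data.frame(
    Chemical = rep("Ozone", 3L), `Chemical.ID` = rep("D010126", 3L),
    Gene = c("PTGFR", "PTGFR", "TFPI"),
    `Gene.ID` = c("5737", "5737", "7035"),
    Phenotype = c("inflammatory response", "response to lipopolysaccharide",
                  "response to lipopolysaccharide"),
    `Phenotype.ID` = c("GO:0006954", "GO:0032496", "GO:0032496"),
    Disease = rep("Airway Obstruction", 3L),
    `Disease.ID` = rep("D000402", 3L),
    check.names = FALSE, stringsAsFactors = FALSE)
  TetramerSet(df, sourceLabel = "packaged toy example")
}
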