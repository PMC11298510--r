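## Independent oracles and tiny fixtures used across the suite.
## These deliberately avoid the package's own join/tally/layout code paths.

## the minimal database: five interactions supporting exactly one quadruple
miniDb <- function() {
  CuratedDatabase(data.frame(
    kind = c("chemical_gene", "chemical_phenotype", "chemical_disease",
             "gene_phenotype", "gene_disease"),
    subject_term = c("chemA", "chemA", "chemA", "geneB", "geneB"),
    subject_id   = c("C1", "C1", "C1", "G1", "G1"),
    object_term  = c("geneB", "phenC", "disD", "phenC", "disD"),
    object_id    = c("G1", "P1", "D1", "P1", "D1"),
    stringsAsFactors = FALSE))
}

## loop-based reference join: nested loops + linear scans, no keys, no joins
oracleTetramers <- function(db) {
  it <- interactions(db)
  has <- function(kind, s, o)
    any(it$kind == kind & it$subject_id == s & it$object_id == o)
  term <- function(id) {
    i <- match(id, c(it$subject_id, it$object_id))
    c(it$subject_term, it$object_term)[i]
  }
  cs <- sort(unique(it$subject_id[startsWith(it$kind, "chemical_")]))
  gs <- sort(unique(c(it$object_id[it$kind == "chemical_gene"],
                      it$subject_id[startsWith(it$kind, "gene_")])))
  ps <- sort(unique(it$object_id[it$kind %in% c("chemical_phenotype",
                                                "gene_phenotype")]))
  ds <- sort(unique(it$object_id[it$kind %in% c("chemical_disease",
                                                "gene_disease")]))
  out <- list()
  for (c0 in cs) for (g in gs) for (p in ps) for (d in ds) {
    if (has("chemical_gene", c0, g) && has("chemical_phenotype", c0, p) &&
        has("chemical_disease", c0, d) && has("gene_phenotype", g, p) &&
        has("gene_disease", g, d)) {
      out[[length(out) + 1L]] <- data.frame(
        Chemical = term(c0), `Chemical.ID` = c0,
        Gene = term(g), `Gene.ID` = g,
        Phenotype = term(p), `Phenotype.ID` = p,
        Disease = term(d), `Disease.ID` = d,
        check.names = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(character(0))
  df <- do.call(rbind, out)
  sort(do.call(paste, c(df[c("Chemical.ID", "Gene.ID", "Phenotype.ID",
                             "Disease.ID")], sep = "|")))
}

tetramerKeys <- function(set) {
  df <- tetramers(set)
  do.call(paste, c(df[c("Chemical.ID", "Gene.ID", "Phenotype.ID",
                        "Disease.ID")], sep = "|"))
}

## table()-based reference dimer tally over unique tetramers
oracleDimerTally <- function(set) {
  df <- tetramers(set)
  df <- df[!duplicated(tetramerKeys(set)), , drop = FALSE]
  tally <- function(s, t) {
    tab <- table(paste(df[[s]], df[[t]], sep = "|"))
    out <- as.integer(tab)
    names(out) <- names(tab)
    out[order(names(out))]
  }
  list(chemical_gene = tally("Chemical.ID", "Gene.ID"),
       gene_phenotype = tally("Gene.ID", "Phenotype.ID"),
       phenotype_disease = tally("Phenotype.ID", "Disease.ID"),
       n = nrow(df))
}

## dimer table of the package, reshaped to match oracleDimerTally's output
packageDimerTally <- function(table) {
  d <- dimers(table)
  out <- lapply(stats::setNames(dimerClasses(), dimerClasses()), function(cl) {
    x <- d[d$class == cl, ]
    v <- as.integer(x$frequency)
    names(v) <- paste(x$source_id, x$target_id, sep = "|")
    v[order(names(v))]
  })
  out$n <- nTetramers(table)
  out
}

## a dimer table whose layout has exactly n sectors (n even), one per node
manyNodeTable <- function(nSectors) {
  stopifnot(nSectors %% 4 == 0)
  k <- nSectors / 4
  df <- data.frame(
    Chemical = sprintf("c%03d", 1:k), `Chemical.ID` = sprintf("C%03d", 1:k),
    Gene = sprintf("g%03d", 1:k), `Gene.ID` = sprintf("G%03d", 1:k),
    Phenotype = sprintf("p%03d", 1:k),
    `Phenotype.ID` = sprintf("P%03d", 1:k),
    Disease = sprintf("d%03d", 1:k), `Disease.ID` = sprintf("D%03d", 1:k),
    check.names = FALSE, stringsAsFactors = FALSE)
  decomposeDimers(TetramerSet(df))
}

## a dimer table with exactly two sectors joined by one dimer
twoNodeTable <- function() {
  d <- data.frame(class = "chemical_gene", source_term = "chemA",
                  source_id = "C1", target_term = "geneB", target_id = "G1",
                  frequency = 1L, stringsAsFactors = FALSE)
  new("DimerTable", dimers = d, nTetramers = 1L, useIds = FALSE)
}

## check that the ribbon sub-spans of every sector tile it exactly
expectTiling <- function(layout, tol = 1e-9) {
  s <- sectors(layout)
  r <- ribbons(layout)
  srcClass <- c(chemical_gene = "chemical", gene_phenotype = "gene",
                phenotype_disease = "phenotype")
  tgtClass <- c(chemical_gene = "gene", gene_phenotype = "phenotype",
                phenotype_disease = "disease")
  for (i in seq_len(nrow(s))) {
    spans <- rbind(
      data.frame(hi = r$sourceThetaStart, lo = r$sourceThetaEnd)[
        srcClass[r$class] == s$class[i] & r$source_id == s$accession[i], ],
      data.frame(hi = r$targetThetaStart, lo = r$targetThetaEnd)[
        tgtClass[r$class] == s$class[i] & r$target_id == s$accession[i], ])
    spans <- spans[order(-spans$hi), ]
    expect_gt(nrow(spans), 0)
    expect_equal(spans$hi[1], s$thetaStart[i], tolerance = tol)
    expect_equal(spans$lo[nrow(spans)], s$thetaEnd[i], tolerance = tol)
    if (nrow(spans) > 1)
      expect_equal(spans$lo[-nrow(spans)], spans$hi[-1], tolerance = tol)
    expect_true(all(spans$hi > spans$lo - tol))
  }
  invisible(TRUE)
}

.idColTest <- function(cls) {
  c(chemical = "Chemical.ID", gene = "Gene.ID", phenotype = "Phenotype.ID",
    disease = "Disease.ID")[[cls]]
}

rscriptBin <- function() file.path(R.home("bin"), "Rscript")

cliBin <- function() system.file("exec", "cgpdchord", package = "cgpdChord")

runCLI <- function(...) {
  out <- tempfile(); err <- tempfile()
  status <- system2(rscriptBin(), c(cliBin(), ...), stdout = out,
                    stderr = err)
  list(status = status, stdout = readLines(out, warn = FALSE),
       stderr = readLines(err, warn = FALSE))
}
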