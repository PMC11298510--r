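test_that("a tetramer exists only when all five supporting relations do", {
  db <- miniDb()
  got <- generateTetramers(db)
  expect_s4_class(got, "TetramerSet")
  expect_equal(length(got), 1L)
  expect_equal(tetramers(got)$`Chemical.ID`, "C1")
  expect_equal(tetramers(got)$`Disease.ID`, "D1")
  ## deleting any single one of the five relations kills the tetramer
  for (i in 1:5) {
    reduced <- CuratedDatabase(interactions(db)[-i, , drop = FALSE])
    expect_equal(length(generateTetramers(reduced)), 0L,
                 info = paste("missing", interactions(db)$kind[i]))
  }
})

test_that("the join equals brute-force enumeration on random databases", {
  for (seed in 1:6) {
    fx <- simulateDatabase(seed = seed)
    got <- generateTetramers(fx$database)
    expect_identical(tetramers(got), tetramers(fx$expected),
                     info = paste("seed", seed))
  }
  ## and both agree with a structurally different loop-based oracle
  fx <- simulateDatabase(seed = 42, nChemicals = 4, nGenes = 5,
                         nPhenotypes = 5, nDiseases = 3, prob = 0.4)
  expect_identical(sort(tetramerKeys(generateTetramers(fx$database))),
                   oracleTetramers(fx$database))
  expect_identical(sort(tetramerKeys(fx$expected)),
                   oracleTetramers(fx$database))
})

test_that("deleting one interaction removes exactly its dependent tetramers", {
  fx <- simulateDatabase(seed = 7, nChemicals = 4, nGenes = 6,
                         nPhenotypes = 6, nDiseases = 3, prob = 0.45)
  base <- tetramerKeys(generateTetramers(fx$database))
  it <- interactions(fx$database)
  for (i in seq_len(nrow(it))) {
    reduced <- CuratedDatabase(it[-i, , drop = FALSE])
    after <- tetramerKeys(generateTetramers(reduced))
    expect_true(all(after %in% base))
    removed <- setdiff(base, after)
    ## every removed tetramer used the deleted interaction; every kept one
    ## did not need it
    parts <- strsplit(removed, "|", fixed = TRUE)
    slotOf <- list(
      chemical_gene = c(1L, 2L), chemical_phenotype = c(1L, 3L),
      chemical_disease = c(1L, 4L), gene_phenotype = c(2L, 3L),
      gene_disease = c(2L, 4L))[[it$kind[i]]]
    for (p in parts) {
      expect_equal(p[slotOf[1L]], it$subject_id[i])
      expect_equal(p[slotOf[2L]], it$object_id[i])
    }
    ## and the reduction matches brute force on the reduced database
    expect_identical(sort(after),
                     sort(tetramerKeys(bruteForceTetramers(reduced))))
  }
})

test_that("adding interactions never removes tetramers", {
  fx <- simulateDatabase(seed = 11, prob = 0.25)
  base <- tetramerKeys(generateTetramers(fx$database))
  extra <- simulateDatabase(seed = 12, prob = 0.15)
  both <- CuratedDatabase(rbind(interactions(fx$database),
                                interactions(extra$database)))
  grown <- tetramerKeys(generateTetramers(both))
  expect_true(all(base %in% grown))
})

test_that("descendant expansion is the transitive closure including roots", {
  toy <- TermHierarchy("chemical",
    data.frame(parent = c("metals", "metals"),
               child = c("copper", "iron")))
  expect_setequal(expandDescendants(toy, "metals"),
                  c("metals", "copper", "iron"))
  ## a leaf expands to itself
  expect_equal(as.character(expandDescendants(toy, "copper")), "copper")
  ## an unknown root is returned alone with a diagnostic note
  got <- expandDescendants(toy, "plastics")
  expect_equal(as.character(got), "plastics")
  expect_match(attr(got, "diagnostics"), "plastics")
  ## random DAG: closure equals igraph reachability
  skip_if_not_installed("igraph")
  set.seed(99)
  n <- 200
  edges <- do.call(rbind, lapply(1:(n - 1), function(i) {
    kids <- which(stats::runif(n - i) < 0.02) + i
    if (length(kids)) data.frame(parent = paste0("N", i),
                                 child = paste0("N", kids))
  }))
  h <- TermHierarchy("phenotype", edges)
  g <- igraph::graph_from_data_frame(edges)
  for (root in paste0("N", c(1, 3, 17))) {
    want <- if (root %in% names(igraph::V(g))) {
      sort(names(igraph::subcomponent(g, root, mode = "out")))
    } else root
    expect_equal(sort(as.character(expandDescendants(h, root))), want,
                 info = root)
  }
})

test_that("hierarchies must be acyclic", {
  expect_error(TermHierarchy("gene",
    data.frame(parent = c("a", "b"), child = c("b", "a"))), "cycle")
})

test_that("query filters constrain generation and filtering identically", {
  fx <- simulateDatabase(seed = 21, prob = 0.35)
  full <- generateTetramers(fx$database)
  ## empty filter: identity
  expect_identical(tetramers(filterTetramers(full, queryFilter())),
                   tetramers(full))
  ## a concrete per-class filter equals row-by-row predicate evaluation
  filt <- queryFilter(chemical = c("C0001", "C0002"), disease = "D0001")
  viaGenerate <- generateTetramers(fx$database, filt)
  viaFilter <- filterTetramers(full, filt)
  df <- tetramers(full)
  keep <- df$`Chemical.ID` %in% c("C0001", "C0002") &
    df$`Disease.ID` %in% "D0001"
  expect_identical(sort(tetramerKeys(viaFilter)),
                   sort(tetramerKeys(full)[keep]))
  expect_setequal(tetramerKeys(viaGenerate), tetramerKeys(viaFilter))
  ## tightening a filter never adds tetramers
  tighter <- queryFilter(chemical = "C0001", disease = "D0001")
  expect_true(all(tetramerKeys(generateTetramers(fx$database, tighter)) %in%
                  tetramerKeys(viaGenerate)))
})

test_that("hierarchy-expanded filters pull in descendant accessions", {
  h <- TermHierarchy("chemical",
    data.frame(parent = "CAT", child = c("C0001", "C0002")))
  fx <- simulateDatabase(seed = 31, prob = 0.35)
  db <- CuratedDatabase(interactions(fx$database),
                        hierarchies = list(chemical = h))
  filt <- queryFilter(chemical = "CAT", descendants = TRUE)
  got <- generateTetramers(db, filt)
  want <- filterTetramers(generateTetramers(db),
                          queryFilter(chemical = c("CAT", "C0001", "C0002")))
  expect_setequal(tetramerKeys(got), tetramerKeys(want))
  ## without descendant expansion the category accession matches nothing
  expect_warning(none <- generateTetramers(db, queryFilter(chemical = "ZZZ")),
                 "unknown")
  expect_equal(length(none), 0L)
  expect_true("ZZZ" %in% diagnostics(none)$unknownFilterAccessions)
})

test_that("tetramer CSV writes and reads round-trip exactly", {
  set <- simulateTetramerTable(100, seed = 5)
  ## annotations survive the trip as opaque extra columns
  df <- tetramers(set)
  df$Evidence <- sprintf("ref%02d", seq_len(nrow(df)) %% 7)
  set <- TetramerSet(df, sourceLabel = sourceLabel(set))
  f <- tempfile(fileext = ".csv")
  expect_equal(writeTetramerCSV(set, f), 100L)
  back <- readTetramerCSV(f)
  expect_identical(tetramers(back), tetramers(set))
  ## a second trip is also an identity
  f2 <- tempfile(fileext = ".csv")
  writeTetramerCSV(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("reader accepts header dialect variants and flags bad input", {
  base <- tetramers(ozoneToyTetramers())
  f <- tempfile(fileext = ".csv")
  ## underscore + case variants of the canonical headers
  alt <- base
  names(alt) <- c("chemical", "Chemical_ID", "GENE", "gene_id",
                  "Phenotype", "PHENOTYPE ID", "disease", "Disease_Id")
  utils::write.csv(alt, f, row.names = FALSE)
  got <- readTetramerCSV(f)
  expect_identical(tetramers(got), base)
  expect_equal(length(got), 3L)
  ## missing required columns are named in the error
  utils::write.csv(base[, -c(2, 8)], f, row.names = FALSE)
  expect_error(readTetramerCSV(f), "Chemical.ID.*Disease.ID")
  ## header-only file: empty set, no error
  utils::write.csv(base[0, ], f, row.names = FALSE)
  expect_equal(length(readTetramerCSV(f)), 0L)
  ## empty required cells: row skipped and counted
  holey <- base
  holey$Gene[2] <- ""
  utils::write.csv(holey, f, row.names = FALSE)
  got <- readTetramerCSV(f)
  expect_equal(length(got), 2L)
  expect_equal(diagnostics(got)$skippedRows, 1L)
})

test_that("merge concatenates by default and deduplicates on request", {
  tabs <- simulateDisjointTables(c(123, 122, 136), seed = 8)
  merged <- mergeTetramerSets(tabs)
  expect_equal(length(merged), 381L)
  expect_equal(summarizeTetramers(merged)$uniqueTetramers, 381L)
  ## merging a set with itself then deduplicating is the identity
  one <- tabs[[1]]
  expect_identical(tetramers(mergeTetramerSets(list(one, one),
                                               deduplicate = TRUE)),
                   tetramers(one))
  expect_equal(length(mergeTetramerSets(list(one, one))), 246L)
  ## planted overlap: unique count = sum of sizes - k
  k <- 17
  df2 <- rbind(tetramers(tabs[[1]])[seq_len(k), ], tetramers(tabs[[2]]))
  withOverlap <- list(tabs[[1]], TetramerSet(df2))
  got <- mergeTetramerSets(withOverlap, deduplicate = TRUE)
  expect_equal(length(got), 123L + (122L + k) - k)
})

test_that("summaries count records and unique accessions per class", {
  expect_equal(summarizeTetramers(ozoneToyTetramers()),
               list(records = 3L, uniqueTetramers = 3L, chemicals = 1L,
                    genes = 2L, phenotypes = 2L, diseases = 1L))
  empty <- TetramerSet()
  expect_equal(unlist(summarizeTetramers(empty)),
               c(records = 0L, uniqueTetramers = 0L, chemicals = 0L,
                 genes = 0L, phenotypes = 0L, diseases = 0L))
  s <- summarizeTetramers(simulateCoveredTable(seed = 3))
  expect_equal(s, list(records = 309L, uniqueTetramers = 309L,
                       chemicals = 2L, genes = 61L, phenotypes = 87L,
                       diseases = 1L))
})
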