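test_that("two symmetric sectors at gap 1 each span 179 degrees", {
  layout <- computeLayout(twoNodeTable())
  s <- sectors(layout)
  expect_equal(nrow(s), 2L)
  expect_equal(s$span, c(179, 179), tolerance = 1e-12)
  ## the single ribbon covers both sectors entirely
  r <- ribbons(layout)
  expect_equal(nrow(r), 1L)
  expect_equal(r$sourceThetaStart, s$thetaStart[1], tolerance = 1e-12)
  expect_equal(r$sourceThetaEnd, s$thetaEnd[1], tolerance = 1e-12)
  expect_equal(r$targetThetaStart, s$thetaStart[2], tolerance = 1e-12)
  expect_equal(r$targetThetaEnd, s$thetaEnd[2], tolerance = 1e-12)
})

test_that("sector spans are weight-proportional and conserve the circle", {
  for (seed in c(3, 13)) {
    set <- simulateTetramerTable(120, seed = seed, nChemicals = 4,
                                 nGenes = 15, nPhenotypes = 25, nDiseases = 3)
    tab <- decomposeDimers(set)
    cfg <- layoutConfig(gapDegree = 0.5)
    layout <- computeLayout(tab, cfg)
    s <- sectors(layout)
    ## independent closed-form recomputation of every span
    w <- nodeWeights(tab)
    expected <- (360 - nrow(s) * 0.5) * s$weight / sum(w$weight)
    expect_equal(s$span, expected, tolerance = 1e-9)
    ## angle conservation to 1e-9 degrees
    expect_lt(abs(sum(s$span) + nrow(s) * 0.5 - 360), 1e-9)
    ## pairwise proportionality span_i/span_j = w_i/w_j
    i <- 1L; j <- nrow(s)
    expect_equal(s$span[i] / s$span[j], s$weight[i] / s$weight[j],
                 tolerance = 1e-9)
    ## sectors ordered clockwise by class then label, non-overlapping
    expect_identical(s$class, s$class[order(match(s$class, nodeClasses()))])
    expect_true(all(diff(s$thetaStart) < 0))
    expect_true(all(s$thetaStart - s$thetaEnd > 0))
    ## ribbons tile every sector exactly
    expectTiling(layout)
  }
})

test_that("ribbon widths are frequency-proportional within their sector", {
  tab <- decomposeDimers(ozoneToyTetramers())
  layout <- computeLayout(tab)
  s <- sectors(layout)
  r <- ribbons(layout)
  ## source-side width / sector span = frequency / node weight
  for (i in seq_len(nrow(r))) {
    src <- s[s$accession == r$source_id[i] &
             s$class == c(chemical_gene = "chemical",
                          gene_phenotype = "gene",
                          phenotype_disease = "phenotype")[[r$class[i]]], ]
    width <- r$sourceThetaStart[i] - r$sourceThetaEnd[i]
    expect_equal(width / src$span, r$frequency[i] / src$weight,
                 tolerance = 1e-9)
  }
})

test_that("layout fails exactly when sectors x gap reaches 360 degrees", {
  tab <- manyNodeTable(400)   # 100 tetramers -> 400 sectors
  expect_error(computeLayout(tab, layoutConfig(gapDegree = 1)),
               class = "cgpd_gap_infeasible")
  err <- tryCatch(computeLayout(tab, layoutConfig(gapDegree = 1)),
                  error = identity)
  expect_equal(err$maxFeasibleGap, 0.9)
  expect_match(conditionMessage(err), "0.9")
  expect_match(conditionMessage(err), "no space to allocate sectors")
  ## boundary: exactly 360/n fails, just under succeeds
  tab8 <- manyNodeTable(8)
  expect_error(computeLayout(tab8, layoutConfig(gapDegree = 45)),
               class = "cgpd_gap_infeasible")
  ok <- computeLayout(tab8, layoutConfig(gapDegree = 45 - 1e-6))
  expect_s4_class(ok, "ChordLayout")
  expect_lt(abs(sum(sectors(ok)$span) + 8 * (45 - 1e-6) - 360), 1e-9)
  ## empty input is a distinct error
  empty <- decomposeDimers(TetramerSet())
  expect_error(computeLayout(empty), class = "cgpd_empty_input")
})

test_that("layout is deterministic", {
  set <- simulateTetramerTable(60, seed = 20)
  tab <- decomposeDimers(set)
  cfg <- layoutConfig(gapDegree = 2, fontScale = 0.8)
  a <- computeLayout(tab, cfg)
  b <- computeLayout(tab, cfg)
  expect_identical(sectors(a), sectors(b))
  expect_identical(ribbons(a), ribbons(b))
})

test_that("gradient palettes interpolate linearly between the endpoints", {
  ## degenerate and two-node classes hit the endpoints exactly
  expect_equal(classGradient(c("black", "white"), 1), "#000000")
  expect_equal(classGradient(c("#123456", "#654321"), 2),
               c("#123456", "#654321"))
  ## five greys at 0/25/50/75/100 percent, closed form round(t*255)
  t <- (0:4) / 4
  want <- toupper(grDevices::rgb(round(t * 255), round(t * 255),
                                 round(t * 255), maxColorValue = 255))
  expect_equal(classGradient(c("black", "white"), 5), want)
  ## cross-check against grDevices' independent ramp (within 1/255/channel)
  ours <- grDevices::col2rgb(classGradient(c("#112233", "#DDEEFF"), 7))
  ref <- grDevices::col2rgb(
    grDevices::colorRampPalette(c("#112233", "#DDEEFF"), space = "rgb")(7))
  expect_true(all(abs(ours - ref) <= 1))
  ## unparsable colors are named in the error
  expect_error(classGradient(c("notacolor", "white"), 3), "notacolor")
})

test_that("sector and ribbon colors follow the class palettes", {
  layout <- computeLayout(decomposeDimers(ozoneToyTetramers()))
  s <- sectors(layout)
  pal <- defaultPalettes()
  ## single-node classes get the first endpoint; two-node classes both
  expect_equal(s$color[s$class == "chemical"], pal$chemical[1])
  expect_equal(s$color[s$class == "disease"], pal$disease[1])
  expect_setequal(s$color[s$class == "gene"], pal$gene)
  ## every ribbon carries its source sector's color
  r <- ribbons(layout)
  srcClass <- c(chemical_gene = "chemical", gene_phenotype = "gene",
                phenotype_disease = "phenotype")
  for (i in seq_len(nrow(r))) {
    src <- s$color[s$class == srcClass[[r$class[i]]] &
                   s$accession == r$source_id[i]]
    expect_equal(r$color[i], src)
  }
  ## re-coloring with another palette changes only colors
  re <- assignColors(layout, colorblindPalettes())
  expect_identical(sectors(re)[, setdiff(names(s), "color")],
                   s[, setdiff(names(s), "color")])
  expect_equal(sectors(re)$color[s$class == "chemical"],
               colorblindPalettes()$chemical[1])
})

test_that("font scaling and label mode follow the configuration", {
  tab <- decomposeDimers(ozoneToyTetramers())
  base <- computeLayout(tab, layoutConfig(fontScale = 1))
  half <- computeLayout(tab, layoutConfig(fontScale = 0.5))
  bigger <- computeLayout(tab, layoutConfig(fontScale = 1.5))
  expect_equal(sectors(half)$fontSize, sectors(base)$fontSize * 0.5)
  expect_equal(sectors(bigger)$fontSize, sectors(base)$fontSize * 1.5)
  ## id mode swaps labels to accessions (and re-sorts within class by them)
  ids <- computeLayout(tab, layoutConfig(labelMode = "id"))
  expect_setequal(sectors(ids)$label, sectors(ids)$accession)
  expect_true("D000402" %in% sectors(ids)$label)
  ## labels anchor at sector midpoints just outside the circle
  s <- sectors(base)
  expect_equal(s$labelAngle, (s$thetaStart + s$thetaEnd) / 2)
  expect_true(all(s$labelRadius > 1))
})

test_that("oversized tetramer sets trigger a readability warning", {
  set <- simulateTetramerTable(30, seed = 30)
  tab <- decomposeDimers(set)
  cfg <- layoutConfig(tetramerWarnLimit = 10)
  expect_warning(layout <- computeLayout(tab, cfg), "readability")
  expect_match(diagnostics(layout), "readability")
  ## below the limit: silent
  expect_silent(computeLayout(tab, layoutConfig(tetramerWarnLimit = 1500)))
})

test_that("weight-sorted sector order is available", {
  tab <- decomposeDimers(ozoneToyTetramers())
  byW <- sectors(computeLayout(tab, layoutConfig(sortWithinClass = "weight")))
  genes <- byW[byW$class == "gene", ]
  expect_identical(genes$label, c("PTGFR", "TFPI"))  # descending weight
})

test_that("layout JSON round-trips", {
  layout <- computeLayout(decomposeDimers(ozoneToyTetramers()))
  f <- tempfile(fileext = ".json")
  writeLayoutJSON(layout, f)
  back <- readLayoutJSON(f)
  expect_equal(sectors(back), sectors(layout), tolerance = 1e-12)
  expect_equal(ribbons(back), ribbons(layout), tolerance = 1e-12)
  expect_equal(back@config$gapDegree, layout@config$gapDegree)
})
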