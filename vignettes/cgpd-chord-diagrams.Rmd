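---
title: "From curated interactions to CGPD-tetramer chord diagrams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From curated interactions to CGPD-tetramer chord diagrams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgpdChord)
```

## The problem and the model

In environmental health, the molecular route from a chemical exposure to a
disease endpoint is usually unknown. Curated toxicogenomic resources record
pairwise relations — a chemical perturbs a gene, a chemical or gene is
linked to a phenotype (a non-disease biological process), a chemical or
gene is associated with a disease — and those pairwise facts can be
integrated into candidate step-wise mechanisms. A **CGPD-tetramer** is a
quadruple (Chemical, Gene, Phenotype, Disease) asserted only when *all
five* supporting pairwise relations exist simultaneously:

1. chemical–gene,
2. chemical–phenotype,
3. chemical–disease,
4. gene–phenotype,
5. gene–disease.

The conjunction is the whole point: each tetramer is a testable hypothesis
that the chemical acts through the gene to modulate the phenotype on the
way to the disease, and dropping any one of the five relations must drop
every tetramer that needed it. `generateTetramers()` implements this as a
relational join over a `CuratedDatabase`; `bruteForceTetramers()` is the
deliberately naive exhaustive enumerator kept in the package as the
reference implementation, and the test suite requires the two to agree
exactly on randomly generated databases.

Queries may use category terms. When a per-class hierarchy (an acyclic
parent→child accession graph) is supplied, `expandDescendants()` replaces a
query accession by itself plus its full transitive closure, so a query for
a chemical category such as *metals* matches every descendant metal. The
root is always included in the expansion: returning the safe superset costs
nothing when the root itself annotates no interaction, and avoids silently
dropping records when it does.

## From tetramers to a chord diagram

Tetramer queries typically return hundreds to thousands of rows, unwieldy
as tables. The package condenses a whole tetramer set into one circular
figure in three mechanical steps.

**Dimer decomposition.** Each *unique* tetramer (identity is the 4-tuple
of accessions; display terms are presentation only) contributes exactly one
chemical→gene, one gene→phenotype and one phenotype→disease occurrence.
`decomposeDimers()` aggregates occurrences into per-edge frequencies, so
within every dimer class the frequencies sum to the number of unique
tetramers. Duplicated rows — common after concatenating downloaded files —
are collapsed before counting, because frequencies are meant to count
mechanistic hypotheses, not file rows.

**Node weights.** A node's sector length must equal the total width of the
ribbons touching it, otherwise ribbons cannot tile their sector. We
therefore define weight as the summed frequency of *incident* dimers:
chemicals count their outgoing chemical→gene edges, diseases their incoming
phenotype→disease edges, and the middle classes (gene, phenotype) count
both sides, so a middle node weighs twice its tetramer-participation count.
A description such as "node length reflects term frequency" is compatible
with several definitions; the incident-ribbon sum is the only one under
which the diagram is exactly self-consistent, and `nodeWeights()` documents
it explicitly. The conservation identities (chemical and disease weights
sum to *n*, gene and phenotype weights to 2*n*) are asserted in the tests.

**Layout.** `computeLayout()` places sectors clockwise from 12 o'clock in
the fixed reading order chemical → gene → phenotype → disease,
alphabetically within class (a by-weight ordering is available via
`sortWithinClass = "weight"`; alphabetical is the default because that is
how tabular query results are ordered). With `n` sectors and gap `g`
degrees between neighbours, the usable circle is `360 − n·g` degrees and
each sector's span is that total times `weight/Σweight`. The layout is
feasible only while `n·g < 360`; beyond it there is literally no space to
allocate sectors, and rather than silently shrinking the gap the function
raises a `cgpd_gap_infeasible` condition that reports the largest feasible
gap (`360/n`, exclusive) so the caller can fix the configuration in one
step instead of iterating. Within a sector, ribbons are packed clockwise in
the order of their partner sector's position (ties by partner label) —
deterministic, and it keeps ribbons from crossing needlessly. Every angle
is computed in closed form; identical inputs give bit-identical layouts.

## Parameters that matter

* `gapDegree` (default 1°): inter-sector spacing. Large diagrams need
  smaller gaps; the feasibility bound above tells you how small.
* `fontScale` (default 1, alias `cex` on the command line): multiplies the
  nominal label size (`baseFontSize`, default 10 pt). 0.5 halves labels,
  1.5 enlarges them by 50%.
* `labelMode` (`"term"`/`"id"`): accession identifiers are much shorter
  than display terms and keep large diagrams readable.
* `palette`: two gradient endpoints per class, interpolated linearly in
  RGB across the class's sectors (first→second color). The defaults are
  blue (chemicals), green (genes), purple (phenotypes) and red (diseases);
  `colorblindPalettes()` ships an Okabe–Ito-based preset because hue-coded
  class identity is otherwise inaccessible to readers with color-vision
  deficiencies. Ribbons inherit their *source* sector's color at
  `ribbonOpacity` (default 0.7), so the three ribbon families read as
  blue, green and purple bands.
* `tetramerWarnLimit` (default 1500): above roughly 1,500 tetramers the
  figure stops being readable. This is a warning, not a cap — the geometry
  stays exact at any size; only legibility degrades.

## Numerical choices and degenerate inputs

Angles are in degrees, counter-clockwise-positive from 3 o'clock, so a
clockwise diagram has decreasing angles (`thetaEnd < thetaStart`). Angle
conservation (`Σ spans + n·gap = 360`) holds to 1e-9° and sector/ribbon
proportionality to 1e-9 relative — pure closed-form arithmetic, no
iteration. Color interpolation uses `round()` on each RGB channel; with
one node a class receives the first endpoint exactly, with two nodes both
endpoints exactly. An empty dimer table is a distinct `cgpd_empty_input`
error rather than an empty picture. A hand-built `DimerTable` may carry a
subset of the three classes (useful for geometric edge cases such as the
symmetric two-sector layout, whose sectors span exactly 179° at gap 1);
tables produced by `decomposeDimers()` always carry all three classes with
conserved sums.

The SVG renderer emits sector annuli, ribbons (two sector-edge arcs joined
by cubic Béziers whose control points sit at the circle center by default,
`controlRadiusFraction = 0`, the classic chord look) and labels, with all
coordinates printed at a fixed six decimals so output is byte-deterministic
and safe for golden-file comparison. PNG output redraws the same geometry
on the `png()` device (arcs sampled every 2°, Béziers at 24 points) — the
SVG remains the source of truth. The layout itself can be serialized with
`writeLayoutJSON()` and rendered later or elsewhere.

## What the synthetic generators emulate — and what they do not

All fixtures are generated in code, seeded, and drawn with integer-based
RNG only, so a seed reproduces a fixture exactly on any platform.

* `simulateDatabase()` fills each of the five interaction tables
  independently (default 10 chemicals × 20 genes × 20 phenotypes × 5
  diseases at inclusion probability 0.3, giving 20,000 candidate
  quadruples and a usefully non-trivial closure of a few dozen tetramers),
  optionally planting guaranteed-complete quadruples, and returns the
  brute-force closure alongside the database so every join test has an
  oracle by construction.
* `simulateDisjointTables(c(123, 122, 136))` mirrors the shape of three
  independent chemical–disease queries that concatenate to 381 records.
* `simulateCoveredTable()` (309 rows over 2 chemicals, 61 genes, 87
  phenotypes, 1 disease) mirrors the shape of a category query narrowed to
  one disease, guaranteeing every term appears so per-class unique counts
  equal the cardinalities exactly. It is a shape-level stand-in with
  synthetic accessions — it does not claim to reproduce any real curated
  download's contents.
* `ozoneToyTetramers()` is the worked three-tetramer example (ozone, PTGFR
  and TFPI, two inflammation-related phenotypes, airway obstruction) in
  which PTGFR and *response to lipopolysaccharide* each occur twice; the
  exact pairings are a plausible reconstruction assembled for this
  package.

What the generators deliberately do **not** emulate: curation semantics
(interaction action types, organisms, evidence counts — carried, if
present, only as opaque annotation columns), real accession namespaces, or
the correlation structure of genuine curated data (real chemical–gene
tables are far from independent Bernoulli draws). Passing tests therefore
demonstrate correctness of the join, counting and geometry contracts, not
fidelity of any statistical model of curated databases.

Problem sizes used by the test and acceptance runs — 100 random databases
of 20,000 candidate quadruples, tetramer tables of 40–500 rows, layouts up
to 400 sectors — were chosen as the scale at which the brute-force oracles
remain exhaustive while still exercising every code path; the pipeline
itself is vectorized and handles much larger inputs.

## Known limitations

* Labels get nominal font sizes; there is no text-extent measurement or
  collision avoidance beyond `fontScale` and ID mode.
* No statistical enrichment of dimers or nodes: prominent sectors are a
  visual aid, not a significance statement.
* Interaction records are treated as undirected presence/absence facts;
  qualifiers are ignored by the join.
* The merge default keeps duplicates (plain concatenation), matching how
  downloaded query files are combined by hand; pass `deduplicate = TRUE`
  when the union is wanted. `summarizeTetramers()` always reports both the
  record count and the unique count so the distinction stays visible.

## A worked example

```{r toy}
toy <- ozoneToyTetramers()
unlist(summarizeTetramers(toy))

tab <- decomposeDimers(toy)
dimers(tab)
nodeWeights(tab)[, c("label", "class", "weight")]

layout <- computeLayout(tab, layoutConfig(gapDegree = 1))
sectors(layout)[, c("label", "weight", "span")]

svg <- tempfile(fileext = ".svg")
renderChord(layout, svg)
```

The same pipeline is available from a shell via the installed script:

```
Rscript $(Rscript -e 'cat(system.file("exec","cgpdchord",package="cgpdChord"))') \
    plot tetramers.csv --out chord.svg --gap-degree 0.5 --cex 0.8
```
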