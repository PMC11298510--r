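# cgpdChord

Construction and chord-diagram visualization of **CGPD-tetramers** —
chemical–gene–phenotype–disease blocks built from curated toxicogenomic
interactions — for researchers tracing candidate molecular mechanisms
between an environmental exposure and a disease endpoint.

A tetramer (C, G, P, D) is asserted only when **five** independently
curated pairwise relations all exist: chemical–gene, chemical–phenotype,
chemical–disease, gene–phenotype and gene–disease. Each tetramer is a
step-wise mechanistic hypothesis: the chemical perturbs the gene, which
modulates the phenotype, which links to the disease. Queries typically
return hundreds of tetramers; the package condenses a whole set into one
chord diagram in which every term is a circumferential sector and every
adjacent pair (C→G, G→P, P→D) a ribbon, read clockwise.

The quantitative substrate: each unique tetramer contributes one dimer per
class, aggregated into frequencies *f*; a node's weight is the sum of its
incident dimer frequencies (so middle classes weigh twice their
participation count); with *n* sectors and gap *g* degrees, sector *i*
spans

    span_i = (360 − n·g) · w_i / Σw        (feasible iff n·g < 360)

and a ribbon occupies the fraction *f*/*w* of each sector it touches, so
ribbons exactly tile their sectors. Sector colors interpolate a two-color
gradient per class (blue chemicals, green genes, purple phenotypes, red
diseases by default; a colorblind-safe preset is included) and ribbons
inherit their source sector's color. Rendering is a self-contained SVG
writer (byte-deterministic, six-decimal coordinates) with optional PNG
rasterization.

The package also supplies the surrounding tooling: the five-relation join
over local interaction tables with ontology-descendant expansion of query
accessions, CSV readers/writers for the standard tetramer download dialect,
merge/filter/summary operations, seeded synthetic-data generators with
brute-force oracle closures, and a command-line interface.

## Worked example

A packaged three-tetramer toy set (ozone → {PTGFR, TFPI} → {inflammatory
response, response to lipopolysaccharide} → airway obstruction; the exact
pairings are a reconstruction assembled for this package):

```r
library(cgpdChord)
toy <- readTetramerCSV(system.file("extdata", "ozone_toy_synthetic.csv",
                                   package = "cgpdChord"))
unlist(summarizeTetramers(toy))
#>         records uniqueTetramers       chemicals           genes
#>               3               3               1               2
#>      phenotypes        diseases
#>               2               1

tab <- decomposeDimers(toy)
dimers(tab)[, c("class", "source_term", "target_term", "frequency")]
#>               class                    source_term                    target_term frequency
#> 1     chemical_gene                          Ozone                          PTGFR         2
#> 2     chemical_gene                          Ozone                           TFPI         1
#> 3    gene_phenotype                          PTGFR          inflammatory response         1
#> 4    gene_phenotype                          PTGFR response to lipopolysaccharide         1
#> 5    gene_phenotype                           TFPI response to lipopolysaccharide         1
#> 6 phenotype_disease          inflammatory response             Airway Obstruction         1
#> 7 phenotype_disease response to lipopolysaccharide             Airway Obstruction         2
```

Within each dimer class the frequencies sum to 3, the number of unique
tetramers. The layout turns weights into angular spans — with 6 sectors at
the default 1° gap, 354° are divided in proportion 3:4:2:2:4:3, so the
ozone sector spans 59° and PTGFR, participating in two tetramers, gets the
widest gene sector:

```r
layout <- computeLayout(tab)
sectors(layout)[, c("label", "class", "weight", "span")]
#>                            label     class weight  span
#> 1                          Ozone  chemical      3 59.00
#> 2                          PTGFR      gene      4 78.67
#> 3                           TFPI      gene      2 39.33
#> 4          inflammatory response phenotype      2 39.33
#> 5 response to lipopolysaccharide phenotype      4 78.67
#> 6             Airway Obstruction   disease      3 59.00

renderChord(layout, "toy.svg")
#> $sectors [1] 6   $ribbons [1] 7   $labels [1] 6
```

Overrepresented terms (ozone, PTGFR, response to lipopolysaccharide) are
immediately visible as the longest sectors — the point of the plot.

From a shell, the same pipeline:

```sh
CLI=$(Rscript -e 'cat(system.file("exec","cgpdchord",package="cgpdChord"))')
Rscript "$CLI" plot query1.csv query2.csv --out chord.svg \
    --gap-degree 0.5 --cex 0.8 --label-mode id
```

`plot` concatenates multiple downloaded query files before plotting
(pass them all on one line); `merge`, `summarize`, `generate` (the
five-relation join over local interaction tables) and `fixtures` (seeded
synthetic data) are also available. Run with `--help` for the full flag
list.

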