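# synthon

Data-driven retrosynthetic analysis for R: learn **reverse reaction
templates** from atom-mapped reaction corpora, and apply them to
deconstruct target molecules into **synthons** — the virtual reactants a
chemist would need to buy or make.

Synthetic route planning needs two ingredients: a source of transformation
rules and a way to apply them backwards. `synthon` derives the rules from
data. Given mapped forward reactions (for example a patent-reaction
extraction), the training phase standardizes each record, reverses it, and
detects its **reaction core**: every atom is typed by a configurable tuple
of atomic properties — atomic number *Z*, aromaticity *A*, connection
count *C*, formal charge *O*, ring bond count *R*, smallest ring size *S*,
unsaturation *U* (the default spec, written `ZACORSU`) — and an atom whose
tuple differs between its map-paired occurrences, or which appears or
disappears, is a *changing atom*. The core plus all atoms within a chosen
bond **radius** is serialized as a canonical labeled string, the
**signature**; reactions sharing a signature form one cluster with a
**support** count, and each cluster's smallest member becomes its template.
The design phase compiles each template into a substructure query, matches
it into a hypothesis molecule, replays the mapped edit script to produce
synthons, looks them up in a local building-block collection, and can
recurse into multi-step routes.

The package also ships a deterministic generator of decorated,
ground-truth-annotated reaction corpora from six classic families (ester
hydrolysis, Schotten–Baumann amide coupling, amide coupling from acid,
N-alkylation, nitro reduction, SnAr), so the whole pipeline is testable
with no external data.

## Worked example

Train a radius-0 repository on a generated 120-reaction corpus and
deconstruct acetanilide:

```r
library(synthon)

corp <- generate_corpus(per_family = 20, seed = 7)
rxns <- lapply(corp$lines, parse_reaction_line)
repo <- build_repository(rxns, radius = 0, min_support = 10)
repo
#> <rrt_repository> radius 0, atom types ZACORSU, min support 10
#>   6 template(s) from 120 signed reactions (120 input)

tidy(repo)[, c("signature", "support", "template_provenance")]
#> # A tibble: 6 × 3
#>   signature                                   support template_provenance
#>   <chr>                                         <int> <chr>
#> 1 N{12878599}>>Br{33059}.N{12878343}               20 rx0086
#> 2 N{33031}>>O{134250760}=N{134255367}O{28936}      20 rx0009
#> 3 N{33287}>>Cl{33041}.N{33031}                     20 rx0046
#> 4 N{33287}>>F{33033}.N{33031}                      20 rx0101
#> 5 N{33287}>>N{33031}.O{33032}                      20 rx0075
#> 6 O{33032}>>C{33030}O{33288}                       20 rx0029
```

Each signature reads `retro-input >> synthons`: atoms appear as
`symbol{label}` where the label packs the atom's enabled property tuple.
The six families condense to six clusters of support 20 each — the
`N{33287}>>Cl{33041}.N{33031}` row, for instance, is the amide
disconnection to an acid chloride plus an amine.

```r
routes <- design_routes("CC(=O)Nc1ccccc1", repo)   # acetanilide
routes[, c("depth", "support", "provenance", "synthons")]
#> # A tibble: 3 × 4
#>   depth support provenance synthons
#>   <int>   <int> <chr>      <chr>
#> 1     1      20 rx0046     C(C)(Cl)=O+c1(ccccc1)N
#> 2     1      20 rx0101     C(C)(N)=O+c1(ccccc1)F
#> 3     1      20 rx0075     C(C)(=O)O+c1(ccccc1)N
```

Acetanilide gets three one-step disconnections: acetyl chloride + aniline
(Schotten–Baumann), acetic acid + aniline (amide coupling), and — from the
SnAr template matching the N–aryl bond — fluorobenzene + acetamide. Every
route carries the provenance of the reaction that defined its template.
Supplying a building-block collection (`building_block_index()`) flags
synthon availability, and `max_depth > 1` expands unavailable synthons
recursively. `coverage_curve()` + `autoplot()` show how few signatures
cover most of a corpus; `glance(repo)` reports the pipeline stage counts.

A thin command-line wrapper (`inst/cli/synthon`) exposes the same steps as
`fixtures`, `standardize`, `sign`, `train` and `design` subcommands.

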