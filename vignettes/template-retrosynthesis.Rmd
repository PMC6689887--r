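---
title: "Template-based retrosynthetic analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-based retrosynthetic analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synthon)
```

## The method

`synthon` implements data-driven retrosynthetic analysis in two phases.

**Training.** A corpus of atom-mapped forward reactions is cleaned
(`standardize_reaction()`), reversed (`reverse_reaction()`), and condensed
into *reverse reaction templates* (RRTs). The condensation key is the
*extended reaction core*: every atom is assigned a type label combining a
configurable set of atomic properties; an atom whose label differs between
its two map-paired occurrences — or which has no counterpart on the other
side — is a *changing atom*, and the changing atoms form the reaction core.
A breadth-first (Morgan-style circular) expansion grows the core by `radius`
bonds, and the expanded core of both sides is serialized as a canonical
labeled string, the *signature* (`reaction_signature()`). Reactions sharing
a signature at the chosen radius form one cluster; string equality is the
entire grouping operation (`cluster_by_signature()`). Each cluster retains
its *support* (member count) and one representative template — the smallest
member, purely for readability, since any member carries the same
transformation (`select_template()`). The result is an `rrt_repository`.

**Design.** Each template is compiled into a substructure query
(`compile_query()`): the radius-expanded core of the retro-input side, with
every atom constrained to its full enabled-property tuple and every bond to
its order. Queries are matched into a hypothesis molecule
(`match_query()`), and each embedding drives the mapped edit script —
bonds broken/formed/reordered, atoms removed, leaving-group atoms grafted
on — producing synthons (`apply_template()`). Synthons can be looked up in
a local building-block collection and, optionally, recursively analyzed to
multi-step routes (`design_routes()`).

## Atom typing

The default property set is `Z,A,C,O,R,S,U`: atomic number, aromaticity,
connection count (heavy-atom degree), formal charge, ring bond count,
smallest ring size, and unsaturation. `PI` (pi-electron count) and `H`
(hydrogen count) are available but off by default. Two decisions here are
deliberately fixed and documented rather than configurable:

* **Aromaticity carries the ring-bond information that Kekulé forms would
  otherwise scatter.** Molecules are normalized *to* the aromatic form
  (Kekulé-written alternating 5/6-rings are perceived and flagged), and `U`
  counts only non-aromatic multiple bonds. A deterministic Kekulé
  assignment was considered and rejected: on symmetric rings the assignment
  can rotate relative to the atom mapping, creating phantom "changing"
  atoms in rings that do not react. With `A` carrying aromaticity and `U`
  ignoring aromatic bonds, a preserved ring never enters the core.
  Perception is deliberately conservative (isolated benzene-like 6-rings,
  lone-pair-heteroatom 5-rings); Kekulé-written *fused* aromatics are left
  as written, so corpora should use aromatic-form SMILES for fused systems.
* **Labels are packed mixed-radix.** Each property is encoded as a bounded
  non-negative integer and packed positionally with per-property bases
  (`Z` gets 128, etc.); the full product is 2^44, well inside the exactly
  representable integer range of a double. The packing is injective and
  decodable (`decode_atom_type()`), and a disabled property occupies a
  zero-width slot, which guarantees the coarsening property: removing a
  property can merge signature classes but never split them.

Stereochemistry is ignored throughout: maps, cores, signatures and queries
are all constitution-level.

## Canonicalization

Signatures and canonical SMILES both rest on a canonical atom ordering
computed by BLISS canonical graph labeling (via igraph) on a vertex-colored
graph: atoms are colored by their invariant (structural fields for SMILES,
the atom-type label for signatures) and each bond is subdivided by a dummy
vertex colored by bond order, so orders participate in the canonical form.
Emission then walks a spanning tree from the first-ranked atom, visiting
neighbours in rank order; ring-closure digits are allocated in traversal
order. The output is therefore a pure function of the labeled graph — the
property the permutation tests assert byte-for-byte. Exact graph
canonicalization was chosen over iterative Morgan refinement with manual
tie-breaking because refinement can stall on regular substructures and the
tie-break is exactly the hard part; BLISS solves it outright.

## The standardizer

Rules run in a fixed order (cheap structural rejections first, the mapping
repair before removals so it sees full context): duplicate-product removal
and the multi-fragment-product rejection; the no-change rejection (multiset
equality of canonical, map-stripped fragment SMILES — purification records);
duplicate-map repair or rejection; removal of fragments with no mapped or no
changing atoms; recording of appearing/disappearing atoms as annotations;
aromaticity normalization; duplicate-fragment removal; the 40-heavy-atom
product cap; and the alphanumeric-name check. The no-change test is
re-applied after cleanup as an empty-core check, so a record whose only
"transformation" lived in a removed spectator is still rejected.

The duplicate-map **repair is deliberately minimal**: all maps are
stripped, atoms are keyed by (element, degree, attached-element multiset),
and only key pairings unique on both sides are accepted; any unmatched
product atom fails the repair. A symmetric substrate therefore fails
loudly rather than being guessed at. Appearing/disappearing atoms are kept
as annotations, not synthesized leaving groups — the design phase treats
template atoms absent from the retro-input side as atoms to graft on
during deconstruction, which keeps the retrosynthetic path complete
without inventing chemistry at standardization time.

After reversal the pipeline runs a second pass with the multi-product and
no-change rejections disabled: the reversed "product" side is the original
multi-fragment reactant side by construction, and rejecting it would
reject every bimolecular reaction. The product-size cap is enforced on the
forward product only (equivalently, on the retro input).

## Query compilation: closure under edited bonds

The query atom set is the radius-expanded core *closed under incidence to
edited bonds* and the anchors of grafted atoms. The pure core can exclude
an atom whose bonds change but whose own property tuple does not — in an
amide disconnection to an acid chloride the carbonyl carbon swaps N for Cl
and keeps its connection count — and without that atom the edit script has
no anchor in the target. The closure adds at most the edited bonds'
endpoints (all within one bond of the core), so query sets remain nested
in radius and matching remains monotone: raising the radius never widens
the matched molecule set. Matching is label-exact backtracking
(monomorphism; bond orders must agree), honoring exactly the property set
stored in the repository, which travels with it so training and design can
never silently mix specs. Embeddings that differ only by molecular
symmetry produce identical synthon multisets and are deduplicated by
(signature, canonical synthon multiset).

`apply_template()` refuses chemically invalid results: after the edit
script runs, every touched atom's hydrogen count is recomputed from
charge-aware valence rules, and an atom exceeding every allowed valence
vetoes that embedding (skipped, not fatal).

## The synthetic corpus generator

`generate_corpus()` emulates a mapped patent-reaction extraction at desk
scale: single-product, fully mapped forward reactions from six families —
ester hydrolysis, amide coupling from acid chloride (Schotten–Baumann),
amide coupling from acid, N-alkylation of a cyclic secondary amine with a
benzylic bromide, nitro reduction, and SnAr. Members are decorated from a
fixed substituent alphabet (F, Cl, methyl, ethyl, methoxy, nitrile) at
three ring positions; the alphabet deliberately excludes hydroxyl, primary
amine and acyl groups so that each family's query motif occurs exactly
once per product and ground-truth cluster identity is provable, not
probable. Every member of a family shares the family's radius-0 signature
by construction; decorations split clusters at larger radii. The study
configuration is 6 × 100 members, seed-determined byte-for-byte; each
family's parameter grid supports several hundred to tens of thousands of
distinct members, and requesting more than the grid holds is an error
rather than a silent repeat.

The generator derives reactants from the constructed product by
family-specific graph surgery, sharing no code with the template engine —
that independence is what makes the round-trip test (template applied to
every member's product regenerates its reactant multiset, 600/600) a real
oracle rather than a self-consistency check. Defect injection corrupts a
chosen fraction of lines, one mode per standardizer rule (duplicate maps,
unmapped spectator, second product fragment, oversized product), with the
expected outcome recorded in the manifest. Chained pairs (an amide member
whose amine is a nitro-reduction member's product) give multi-step route
tests a known two-step truth.

What the generator does *not* emulate: mapping noise beyond the injected
modes, agents/condition records, stereochemistry, yields, and the breadth
of real medicinal chemistry. Passing tests on this corpus demonstrates the
machinery — core detection, canonicalization, clustering, template
application — not recall on patent-scale data, whose headline counts are
additionally sensitive to undisclosed canonicalization details of the
original tooling.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `radius` | 0–2 typical | Bond radius of the extended core; larger = more specific templates, more clusters, lower per-template support |
| `min_support` | 1 (training), 10 (study) | Minimum examples per retained template; confidence filter |
| atom-type spec | `Z,A,C,O,R,S,U` | Properties compared for core detection and matching |
| `max_product_heavy_atoms` | 40 | Standardizer product-size cap (forward product) |
| `max_depth` | 1 | Route recursion; >1 treats unavailable synthons as new hypotheses |
| `max_routes` | 100 | Per-target route cap (route counts grow quickly at radius 0) |

Route ordering is depth, then descending support, then signature text —
support is the only score; yield-style annotations have no public source
here, though the cluster annotation map is the extension point for them.

## Degenerate inputs and numerical corners

Empty agent sides, single-atom fragments, and one-member clusters are all
legal. An empty repository designs zero routes; a `min_support` above
every cluster yields a valid empty repository with a warning-free save and
load. Unparseable targets become per-target error records without
aborting a batch. Signature computation on a reaction with an empty core
is an error by contract — the standardizer rejects such records first.
Determinism is absolute in training (no randomness anywhere), so a
shuffled input file produces a byte-identical repository.

## Problem sizes used in the shipped checks

The test suite exercises a 6 × 20 corpus for unit-level properties and the
6 × 100 study corpus for the end-to-end checks (cluster structure,
round-trip fidelity, 200-permutation canonicality, refinement, coverage,
defect handling, and the Gleevec-class route-family check against
imatinib's public structure). These sizes were chosen so every claim the
package makes is recomputed from scratch on each run.

## Known limitations

* Aromatic perception does not kekulize or perceive fused Kekulé-written
  systems; corpora written in aromatic SMILES (as mapped USPTO extractions
  are) are unaffected.
* The atom-map repair saves only unambiguous cases by design.
* Substructure matching is monomorphic; with connection counts enabled
  (the default) this is effectively induced, but exotic specs without `C`
  relax it.
* No stereochemistry, no condition/yield modeling, no learned ranking —
  support ordering only.
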