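# obokit

Semantic query functions for OBO ontologies.

Biomedical ontologies encode far more than a vocabulary: the `is_a`
hierarchy and typed relations such as `part_of` carry the knowledge a
curator would use to answer questions like *"which organ does this cell
belong to?"* or *"which of the terms my project uses is nearest to the
term the user typed?"*. Answering them requires knowing *which* relations
to follow and *where* to stop — knowledge that is specific to each
ontology's curation guidelines. obokit packages that traversal knowledge
as a small set of semantic functions over a typed directed graph, so an
application (an expression-analysis pipeline, a phenotype database, a
search front-end) can call one function instead of re-implementing
ontology logic.

## What it computes

An ontology is loaded from an OBO 1.2 flat file into a graph
`G = (C, is_a, R)`: classes `C`, the acyclic subsumption hierarchy
`is_a ⊆ C × C` (multiple parents allowed) and typed relation edges
`R ⊆ C × C × Σ` for relation names `Σ` (`isPartOf`, `isCellOf`, ...).
A virtual root `thing` is inserted above all parentless classes and
defines **level 1**; the level of a class is its *longest* `is_a` path
distance from the root, `ℓ(c) = 1 + max{ℓ(p) : (c,p) ∈ is_a}`.

On this graph the package answers:

* **Field-restricted search** — case-insensitive substring match over
  labels and configured annotation fields (`search_cls`), optionally
  restricted to named fields only.
* **Ancestor mapping at a level** — `reduce_to_level(G, X, l)` maps each
  class to every ancestor occurring at position `l` on *some* root path
  (all paths are considered, so multi-parent classes map to several
  ancestors).
* **Cluster reduction** — `reduce_to_cluster_size(G, X, k)` repeatedly
  replaces the representatives farthest from the root by their parents,
  pooling members that meet, until at most `k` clusters remain.
* **Key-class rollup** — `organs_of` / `physiological_systems_of` walk
  upstream along a restricted relation set (`isPartOf`, `isPartOfOrgan`,
  `isCellOf` plus the hierarchy) and report every reached key class,
  where key classes are the `is_a` descendants of an anchor such as
  `organ`; relations outside the policy (e.g. `differentiatesInto`) are
  never crossed.
* **Set-restricted search** — `find_in_set` runs a level-synchronous BFS
  up- or downstream and stops at the first depth containing members of a
  stored class list, returning all members at that depth (inverse
  relations such as `hasPart` are generated on the fly).
* **Stage partitioning** — for staged anatomy ontologies,
  `stage_plugin` splits classes into stage-linked (*concrete*) and
  stage-free (*generic*) sets and `concrete_for_dev_stage` maps a
  generic structure plus a developmental stage to the matching concrete
  classes.

Stored class lists live in named flat-file partitions (`set_store`), and
everything is additionally reachable through a REST-style URL scheme
(`route`, served by `obo_serve`, consumed by a lazy-loading proxy client)
and through the `obokit` command line (`inst/cli/obokit`).

## Worked example

```r
library(obokit)

g <- make_fixture("fig2")          # a regulation-of-binding process slice
g
#> <ontology_graph 'fig2': 13 classes, 13 is_a edges, 0 relation edges, root 'thing'>

reduce_to_level(g, "negative_regulation_of_binding", 5)
#> $negative_regulation_of_binding
#> [1] "negative_regulation_of_molecular_function"
#> [2] "regulation_of_binding"
```

The class has two parents, hence two root paths, and both paths are
considered: at level 5 the two distinct ancestors are returned.

```r
for (cl in reduce_to_cluster_size(g, attr(g, "marked"), 2)) print(cl)
#> regulation_of_protein_binding <- {negative_regulation_of_protein_binding, regulation_of_cytokine_activity}
#> regulation_of_signaling <- {regulation_of_signaling}
```

The three marked classes (levels 5, 7 and 8) collapse to two clusters:
the deepest classes are mapped to their parents in two farthest-first
iterations while `regulation_of_signaling` is just copied, leaving
representatives at root distances 6 and 5.

```r
organs_of(make_fixture("fig3"), "Cell_2")
#> [1] "Organ_1" "Organ_2"
```

`Cell_2` reaches `Organ_1` by `isCellOf` and `Organ_2` via
`isPartOf`/`isPartOfOrgan`; `Organ_3` is *not* returned because the only
path to it crosses `differentiatesInto`, which the organ policy ignores.

The same answers are available from the shell:

```sh
$ obokit rollup fig3 Cell_2 --policy organs
Organ_1
Organ_2
```

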