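---
title: "Semantic query functions over OBO ontology graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic query functions over OBO ontology graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obokit)
```

## The model

obokit represents an ontology as a typed directed graph. Classes are
nodes carrying a label, free-form annotation fields and an obsolete
flag. The mandatory subsumption relation `is_a` is kept apart from all
other relations: it forms a directed acyclic hierarchy (multiple parents
allowed), while every other statement — `isPartOf`, `isCellOf`,
`isPartOfOrgan`, `differentiatesInto`, whatever the ontology defines —
is an edge in a separate typed relation table. This split matters
because every semantic function is parameterised by a *traversal
policy*: a direction, a set of relation names it may cross, and whether
it follows the hierarchy too. The policy is the whole contract; the
same breadth-first machinery serves organ rollup, stored-set search and
stage scanning, only the policy and stop rule differ.

A virtual root (`thing` by default) is inserted above all parentless
classes, so every class has at least one root path. The root marks
level 1, and the **level** of a class is its *longest* `is_a` distance
from the root. We use the longest-path convention for two reasons: it
is the one under which the documented example levels of the bundled
process-ontology fixture (5 for "regulation of signaling", 6 for its
protein-binding counterpart, 8 for the deepest marked class) come out,
and it makes the farthest-first clustering iteration well-founded — the
maximal level strictly decreases each round. The shortest-path reading
remains visible through `path_levels()`, which returns *every* position
a class occupies across all root paths; `reduce_to_level()` is defined
on those per-path positions, not on the scalar level.

Obsolete classes are parsed and kept (so lookups can still explain what
an id was) but are stripped of all edges at load time and excluded from
traversal and search. This is the usual OBO convention.

## The semantic functions

**Search** is deliberately plain: lower-cased substring match over the
label and the annotation fields named in the ontology's config. A
field restriction (`restrict_fields`, or `;field=` on the service URL)
excludes the label and all other fields. Substring rather than token
matching is used because anatomical compound names
(`vein_of_cerebellomedullary_cistern`) must be reachable from an inner
fragment; no ranking or stemming is attempted.

**`reduce_to_level(G, X, l)`** maps each input class to the set of
classes found at position `l` on at least one root path. An input
lying exactly at `l` on some path maps to itself. An input all of
whose root paths are shorter than `l` is *copied* to the result rather
than dropped — the same "just copied" behaviour the clustering variant
shows for shallow classes, and the choice that keeps the output a total
mapping over the input.

**`reduce_to_cluster_size(G, X, k)`** iterates: among the current
representatives, exactly those at the greatest root distance are
replaced by all their `is_a` parents; everything shallower is copied;
representatives that meet at the same parent pool their member lists.
The count is checked after each full iteration, so all farthest classes
of one round move together; with `k = 2` on the bundled fixture this
takes precisely two iterations and leaves representatives at root
distances 5 and 6. A member reached through a multi-parent
representative may legitimately appear in several clusters. Termination
is guaranteed because the maximal representative level strictly
decreases and at the root everything merges into one cluster.

**Key-class rollup** (`organs_of`, `physiological_systems_of`)
generalises to any anchor: the key set is the set of `is_a` descendants
of a configured anchor class (`organ`, `physiological_system`), and the
BFS follows only the partonomy policy (`isPartOf`, `isPartOfOrgan`,
`isCellOf`, plus the hierarchy upward). Reached key classes are
reported and — by default — not expanded further, so the most specific
organs are returned and an organ containing another organ does not drag
its container in; `expand_key_classes = TRUE` flips that choice for
ontologies where the coarser reading is wanted. Anchors are validated
when the plugin loads, not at query time.

**`find_in_set`** performs a level-synchronous BFS and stops in the
first iteration that touches the member set, returning *all* members at
that depth. Depth 0 counts: a start class that is itself a member is
its own answer. Path length is otherwise unbounded and a path may mix
any of the policy's relations with hierarchy steps. Downstream
traversal inverts the stored relation edges on the fly, so no `hasPart`
edges need to exist in the file.

**Stage partitioning** models staged anatomy ontologies that carry one
class per structure per developmental stage. Stages are the
descendants of a stage anchor (`developmental_stage`); *concrete*
classes are those from which some stage is reachable through any
mixture of `is_a`-upward and `isPartOf` steps (computed once at plugin
load by one reverse reachability sweep from the stages, and cached —
reload the plugin after editing the graph); *generic* classes are the
rest, excluding the root and the stage subtree, so the four sets
partition the non-obsolete classes. `concrete_for_dev_stage` expands a
generic structure downstream through subclass edges and the inverted
partonomy, then intersects with the classes concrete *for the queried
stage specifically* — recomputing stage reachability per stage id is
what keeps pupal classes out of larval queries. Generic-to-generic
partonomy edges take part in the downstream expansion like any other
`isPartOf` edge.

## Service, client and store

The REST façade is transport-agnostic: `route()` maps a path such as
`/fig2/functions/basic/searchCls;field=def/cistern` plus an Accept
header to a response, and `obo_serve()` merely mounts it on httpuv.
Matrix parameters (`;name=value` inside the function segment) carry
function arguments; a stored set is referenced as `;set=partition:list`
(colon, because a raw slash would split the path segment; `%2F` also
works). Responses come as JSON entities with navigable links, as plain
text one id per line, or as a minimal HTML anchor list. Domain errors
map to 404/400/409; the client keeps transport failures
(`obokit_transport_error`) distinct from not-found.

The client mirrors the original object-graph idea: `get_class()`
returns a proxy that knows only its id until a field or neighbour set
is first touched, at which point exactly one request per subresource is
made and memoized. The tests assert the request counts, not just the
results, so the laziness is part of the contract.

Stored lists live in a flat-file store, one JSON document per
partition. A partition is reachable only by its name — that is the
whole access-control model, matching desk-scale use. Ids are not
validated against any ontology at storage time, because lists are
routinely uploaded before their ontology loads; validation happens when
a query consumes the list.

## Fixtures and what the tests show

The named fixtures are minimal reconstructions: the figure-style graphs
are not shipped as data but generated by code
(`make_fixture("fig2")`, ...), each the smallest graph consistent with
the documented behaviour of its paired function, including the
two-iteration clustering trace (the auxiliary class
`positive_regulation_of_protein_binding` exists solely so that the
deepest input moves in both iterations). Property tests run against
seeded random rooted DAGs (5–50 nodes, at most two parents per node,
optional `isPartOf` edges with probability 0.3) and compare traversal
results with independent oracles: explicit root-path enumeration for
levels and ancestor mapping, and igraph shortest-path distances for the
minimum-depth set search. The acceptance script re-runs both
comparisons on 50 fresh DAGs per invocation under the caller's seed.

These graphs are small and clean by design. They do not emulate the
scale of real ontologies (tens of thousands of classes), cyclic or
near-cyclic curation errors beyond what the loader rejects, OWL-only
constructs, or annotation-quality noise; passing tests therefore
demonstrate the correctness of the traversal semantics, not performance
or robustness on a full released ontology. Real-ontology counts (for
instance how many classes an organ rollup visits) depend on the
ontology version and are deliberately not asserted anywhere.

## Numerical and degenerate-input choices

Neighbour lists and all result sets are returned in locale-independent
radix-sorted order, so output is byte-stable across platforms. Cycle
detection runs at graph construction and names a cycle member.
`add_virtual_root()` is idempotent when a sole root with the requested
label already exists. Empty search results, empty rollup results and
an unreachable member set are successes returning empty vectors, not
errors; empty *inputs* (a blank pattern, an empty cluster input,
`level < 1`) are argument errors. Dangling OBO edge targets are dropped
with a warning rather than failing the load, since real exports are
imperfect. The OBO writer emits terms sorted by id and round-trips
through the reader up to that canonical ordering.

## Limitations

OBO 1.2 only — OWL dialects, class expressions and DL reasoning are out
of scope, as are ranked search, typedef metadata beyond the relation
name, multi-user concurrency guarantees for the store, and any HTML
view beyond a linked listing.
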