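---
title: "Mapping long reads to pangenome variation graphs: models and methods"
author: "panmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping long reads to pangenome variation graphs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panmap)
```

`panmap` maps long sequencing reads to bidirected pangenome variation
graphs with a seed–chain–extend pipeline. This vignette describes the
models, the tunable parameters and their defaults, the numerical choices,
the design decisions that were genuinely open, and what the synthetic
study conditions do and do not establish about real data.

## The variation graph model

A variation graph is a bidirected sequence graph: nodes carry DNA strings,
each node has a *left* and a *right* side, and edges join sides. A valid
walk enters and exits opposite sides of each node it visits, so every
visit has an orientation; a forward visit spells the node sequence and a
backward visit its reverse complement. Haplotypes are embedded as named
walks, read and written as GFA v1 P/W lines; edges on L lines with
overlap `0M` or `*` are translated to side pairs (`1 + 2 +` joins 1.right
to 2.left). Offsets are 0-based and intervals half-open throughout, which
keeps the GAF output and all internal gap arithmetic in one convention.
Graphs whose edge set should be implied by the embedded walks can be
pruned with `prune_unsupported_edges()`.

```{r toy}
g <- example_graph("bubble")
walk_sequence(g, g$walks[[1]])
```

## Snarl decomposition

A *snarl* is a subgraph delimited by two boundary node sides that are
*separable* — cutting both boundary nodes into their component sides
disconnects the subgraph between the sides from the rest of the graph —
and *minimal* — no side strictly inside is separable with either
boundary. A *chain* is a maximal run of nodes with snarls between
consecutive nodes; chains nest inside snarls, giving the snarl tree.

The decomposition is deliberately definition-driven rather than
constructive: `snarl_decompose()` enumerates every separable side pair by
brute-force biedged reachability (a C++ kernel; one BFS per candidate
pair), marks minimal pairs, and then nests them greedily. The
decomposition of a graph is formally not unique — a cycle of bubbles
admits several readings — so a canonical tie-break fixes one: pairs with
smaller boundary node ids are preferred, and chains are oriented with the
lowest node id leftmost. Every consecutive node pair in a chain is joined
by a snarl object even when the snarl is trivial (empty content, the
direct edge between the boundary nodes inside it); this makes the edge
partition exact: every edge belongs to exactly one snarl. Self-loop edges
attach to the adjacent snarl on their side. Components with no separable
pair at all degenerate to single-node chains with their edges kept at the
component level; the distance index remains exact there because the
component record sees those edges directly.

The test suite verifies every emitted snarl against an independent plain-R
BFS oracle (separability, interior, minimality) on hundreds of simulated
graphs, and checks the node/edge partition invariants.

## The minimum-distance index

`min_distance(index, a, b)` returns the minimum number of bases strictly
between two graph positions over all walks that read `a` in its
orientation and later read `b`; 0 means `b` is the next base, `Inf` means
unreachable, and `d(a,a) = 0`. Counting only the bases *between* the
positions keeps read-gap versus graph-gap arithmetic sign-consistent in
chaining.

The index is hierarchical and built bottom-up on the snarl tree. Every
structure (chain, snarl, plus one record per connected component) is
contracted to a small directed graph over *oriented node* vertices
("finished node `n` forward"); edge weights include the target node's
length, child chains contribute their end-to-end summary matrices as
super-edges, and Dijkstra on the contracted graph yields the structure's
distance matrix. Cycles are handled exactly within the snarl that
contains them — the matrices simply encode them — and each structure also
stores its shortest proper cycle through every vertex, because the
Dijkstra matrix diagonal is 0 by convention and would otherwise hide
loops needed for same-node queries (a position reaching an earlier
position of its own node through a duplication loop, or the same node in
opposite orientation through an inversion U-turn).

A query propagates a vector of "bases from the position to each finished
vertex" up both positions' ancestor paths and combines the two at every
common structure: for any vertex `w` of a common structure, the walk can
be decomposed as (a → end of `w`) plus (start of `w` → b), counting `w`'s
node once. `min_distance_matrix()` batches the propagation for all-pairs
queries. Exactness is asserted against an independent igraph Dijkstra
oracle on the oriented-base graph for *all* position pairs of 100 random
graphs, including inversions and duplication cycles; orientation symmetry
`d(a,b) = d(rev(b), rev(a))` follows structurally and is also tested.

## Zip codes, the zip code forest, and chaining distances

A zip code records a position's path through the snarl tree: for each
level, the structure and the rank of the item within it, with chain
prefix offsets at chain levels and the node offset at the end. Sorting
seeds by `zip_sort_key()` groups them by shared ancestry and orders them
along chains without any graph access. `build_zip_tree()` lists the
sorted seeds together with the boundaries of every structure that
contains a seed, in a pre/post-order traversal, and labels adjacent items
with minimum distances from the index; `tree_distances()` streams the
predecessors of a seed with their distances, capped by a lookback count
(default 500) and a maximum distance.

Two deliberate deviations from an unrolled-copy design are worth stating.
First, the tree does not duplicate seeds inside cyclic snarls: distances
attached to the tree come from the exact hierarchical index, cycles
included, so every yielded distance equals the true minimum (the
soundness contract — never an undercount, never a link between
unreachable seeds, exact on acyclic graphs — holds with equality
everywhere). Chains that traverse a loop twice still work because anchors
carry read offsets: the same graph position appears as two anchors at two
read offsets, and the exact distance through the cycle links them.
Second, a single forest serves both strands: seed positions are oriented,
and the distance machinery is orientation-aware, so a read crossing an
inversion chains seamlessly from forward-strand to reverse-strand seeds.

For the mapper's inner loop, per-pair distance queries are replaced by
zip-code-derived *linear addresses*: every oriented node gets a prefix
address relative to its component's root chain (two per node, one per
strand frame), computed once from the index and cached. The graph
distance between co-linear anchors is then an address difference, and
anchors on parallel snarl alleles — recognizable from the first
divergence of their zip-code ancestries — get infinite link distance
unless the snarl's children are mutually reachable (cyclic, "tangled"
snarls). This is the cache-light arithmetic the zip codes exist for; the
explicit tree with edge labels is built when the caller asks for it.

## Seeding

The minimizer index stores `(w,k)`-minimizers of every embedded walk
sequence under a canonical (strand-folded) 64-bit hash — a fixed
splitmix64 finalizer over the 2-bit-packed k-mer, truncated to 52 bits so
hashes are exact R doubles. K-mers are taken from walk sequences, not
node labels, so seeds span node boundaries. Occurrences are deduplicated
by canonical graph position but remember a walk coordinate, which the
extension stage later follows. Defaults `k = 29`, `w = 11` suit long
reads at the package's scale; `hard_hit_cap = 500`, weight exponent 0.8
and `score_fraction = 0.9` govern the weighted selection: read minimizers
are weighted `1/(1+count)^0.8`, processed in decreasing weight, skipped
above the cap, and selection stops once the chosen minimizers hold 90% of
the total weight. Every emitted seed is an exact k-mer match between read
and graph, a property the tests check base by base.

## Chaining

Chaining maximizes newly covered read bases (no double counting across
overlapping anchors) minus a gap cost on `g = |read_gap − graph_gap|`:
cost `0` when `g = 0`, otherwise `c_lin·k·g + c_log·log2(g)` with
defaults `c_lin = 0.01`, `c_log = 0.5`. Two DP passes follow the
fragment/chain structure: pass 1 links anchors under tight gap limits
(60 bp in read and graph), pass 2 links the resulting fragments under
loose limits (10 kb both), and a final stitching step joins chains whose
link is invisible to the linear addresses but finite in the graph —
the loop-traversal case — using exact index queries. Ties break by
score, then leftmost read start. Four chains are carried to extension.

When the fragment and chain gap limits coincide, the first pass is a
single optimality-preserving DP and the best chain equals the exhaustive
maximum over all ordered anchor subsets; this is the regime in which the
500-trial enumeration check runs. With distinct limits the two-pass
composition is a deliberate heuristic (fragments are frozen before the
loose pass) and global optimality is not claimed.

## Extension

Between consecutive anchors the read gap is aligned against *local
haplotype strings*: subwalks of the embedded walks connecting the two
anchor positions (at most 16 distinct strings per link), scored with an
exact gap-affine wavefront kernel whose work scales with the alignment
cost rather than the product of lengths. The kernel converts the
match-bonus scoring (match 1, mismatch 4, gap open 6, gap extend 1 —
BWA-like defaults) to the cost-only wavefront formulation and converts
back, so its scores equal full DP exactly; a 1000-pair equivalence test
against an independent full-matrix DP asserts this. Alignment problems
longer than the configurable ceiling (2^16 bases at this scale), links no
haplotype connects, and wavefront failures fall back to a banded global
graph aligner: graph walks between the anchors are enumerated with cycles
unrolled up to the query length, walks within the band of the query
length are scored exactly, and the band doubles once on failure before
the link hard-fails. Tails beyond the terminal anchors extend with an
X-drop aligner (adaptive band re-centred on the best cell per row,
Dozeu-style) along candidate continuations; whatever does not extend is
soft-clipped.

Repeat k-mers store one walk copy in the index, so a chain can carry an
anchor whose recorded walk coordinate belongs to the wrong copy; the
extension re-anchors such seeds onto the gapless continuation of the
previous run when the graph position matches, and otherwise drops the
shorter of two irreconcilable runs and retries. The invariant the tests
enforce is that the reported score always equals the score recomputed
from the emitted CIGAR.

## MAPQ, output, and evaluation

`MAPQ = round(60·(primary − secondary)/(primary − min_possible))`,
clamped to 0–60, with 60 when no secondary alignment at a distinct
location exists (a secondary must share less than half its path nodes
with the primary). The formula is the package's own; its calibration is
validated empirically: on the study conditions below, the empirical error
among MAPQ-60 reads must stay within 1%, and the cumulative incorrect
fraction must be non-increasing from the highest MAPQ bin downwards.
Alignments are emitted as GAF (0-based half-open, `>`/`<` path strings,
`AS`/`tp`/`cs` tags); unmapped reads produce no record and are counted in
a summary attribute, since GAF has no unmapped convention.

## The synthetic study conditions

The generator applies non-overlapping events to a random backbone — SNP
sites at rate 0.002/bp, indels at 2e-4/bp (lengths 1–20), one 2 kb
inversion, one 800 bp tandem duplication (a back-edge; carriers traverse
the segment twice) — draws a per-site allele frequency from
Uniform(0.15, 0.85), and materializes 20 haplotype walks plus a
reference walk; edges derive from the walks, so generated graphs are
always walk-supported. These densities give a variant roughly every
450 bp, which at 20 haplotypes is a realistic local density for a
small pangenome panel, and they keep the 100 kb default graph at a size
(about 550 nodes) where every stage stays exhaustively testable. Reads
are drawn uniformly over haplotypes, positions and strands with uniform
lengths of 1–10 kb and parametric per-base errors; the two presets,
`hifi` (0.3% substitutions + 0.2% indels) and `ont` (3% + 2%), bracket
the error regimes of current long-read technologies without modelling
their context dependence. The acceptance conditions — at least 99% of
hifi-like and 97% of ont-like reads correctly placed at MAPQ ≥ 30 over
1,000 reads per preset, with a read counted correct when its projection
onto the source haplotype overlaps at least half of the truth interval —
run end to end in the test suite on fixed seeds.

What passing these tests shows: the pipeline is exact where exactness is
claimed (snarls, distances, kernel scores, chain optimality in the
single-DP regime) and accurate and calibrated under parametric error on
graphs with bubbles, nested sites, inversions and duplication cycles.
What it does not show: performance on learned, context-dependent error
profiles, on human-scale graphs where heuristic caps (hit cap, lookback,
haplotype enumeration limit) actually bind, on graphs with deeply nested
or very long cycles beyond the generator's event grammar, or surjection
onto linear references, which the package does not attempt.

## Known limitations

* The decomposition's greedy canonical nesting fixes one reading of
  formally non-unique regions; no equivalence with other toolkits' snarl
  trees is claimed.
* Chaining addresses are exact along root chains and within snarls below
  them, but anchors on a long allele of a bubble see the bubble's
  *minimum* traversal length in their address differences; the gap-cost
  tolerance absorbs the discrepancy, and extension realigns at base
  level.
* The banded graph aligner enumerates walks rather than running a banded
  DP over a DAG; at the fallback's scale (short links, few alleles) the
  two are score-equivalent, but the enumeration would not scale to long
  fallback problems in dense regions.
* One alignment per chain; no paired-end logic, no haplotype-consistency
  (recombination) scoring, no BAM/SAM surjection.
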