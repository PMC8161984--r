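---
title: "Colored superbubbles: decomposing pangenome de Bruijn graphs for coordinates and small-variant calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colored superbubbles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panbubble)
```

## The model

panbubble analyzes a set of highly similar haplotype genomes — one
sequence per sample, one designated the reference — as a colored de
Bruijn graph: nodes are k-mers, edges join k-mers overlapping by k−1
bases, and every node and edge carries a *color*, the bit-set of samples
whose sequence uses it. Three constructions make the graph tractable:

* **Sanitization.** Degenerate IUPAC bases are replaced by the most
  frequent base at the same position among the other samples (ties go to
  the lexicographically smallest base, so output is deterministic), and
  every replacement is logged.
* **k selection.** With `K` the largest length of a substring occurring
  twice in any sample (overlapping occurrences count), any `k > K` keeps
  each sample's k-mer walk repeat-free, and the graph is almost surely
  acyclic. `choose_k()` defaults to `K + 1`; smaller values are allowed
  but flagged, because cycle handling will be needed.
* **Anchors.** Two random length-k segments, required to be absent from
  every input sequence, are prepended/appended to all samples. They force
  a unique start node (indegree 0) and end node (outdegree 0), so each
  sample is a unique start-to-end path that spells its anchored sequence.
  Rarely a random anchor recreates an interior k-mer across the
  sequence/anchor junction and breaks those guarantees; the builder then
  simply redraws the anchors (deterministically from the seed), which is
  sound because the anchors are arbitrary by construction.

### Offsets

The *offset value* of a node is its longest-path distance from the start
node, `pos(v) = max(pos(parents)) + 1`, computed by a postorder-like
traversal: a node is visited only once all its parents are fully
visited, ties broken first-in-first-out so visit order is reproducible.
Traversing instead from the end node against the edges gives
pre-offsets, and the *final offset* is
`final(v) = pre(start) + 1 − pre(v)`. Final offsets are monotone along
every path, and — the point of the reversal — an indel's offset jump
appears on the edge leaving the (forward) source node of its bubble,
where the variant actually is, rather than at the sink.

### Colored superbubbles

A superbubble `<s, t>` is a minimal single-entry/single-exit subgraph:
reachability, matching (the nodes reachable from `s` without passing
`t` equal the nodes co-reaching `t` without passing `s`), acyclicity of
that node set, and minimality (no earlier sink inside). A *colored*
superbubble `<s, t, C>` is a superbubble of the subgraph induced by the
nodes whose color intersects `C`; following the restriction to bubbles
with at least two supernodes, both endpoints must branch (two admissible
out-edges at `s`, two admissible in-edges at `t`) *within that induced
subgraph*. This generalization finds population structure that plain
superbubbles miss: a sub-population bubble (say two samples diverging
inside a shared insertion) is invisible at the full color set but is a
perfectly formed bubble once the graph is restricted to the samples
involved.

`find_bubbles()` discovers all of them in one pass of the reverse
traversal, maintaining a queue of pending sinks (nodes with forward
indegree above one). When the pass reaches a branching node `x` it scans
the queue newest-first; a pending sink `t` matches when at least two
out-edge colors of `x` intersect `color(t)` and at least two in-edge
colors of `t` intersect `color(x)`. A match is emitted as
`<x, t, color(x) & color(t)>` and fully verified against the
four criteria before being recorded. After a verified emission the sink
is removed if its color is contained in `color(x)` (it is fully
explained) and the scan continues; otherwise the scan stops. Non-matching
and unverifiable entries are passed over. The discovery order — bubble 1
is the most downstream — is what the worked example below prints, and
all later structure (parenthood, variant passes) refers to it.

Two engineering notes on the verification, which is exact but must stay
cheap on dense graphs:

* Final offsets are monotone along paths, so any reachability search
  that leaves the candidate's offset window has already disproved the
  matching criterion; searches fail fast instead of flooding the graph.
* For one source, a later candidate whose color sits inside a single
  already-emitted bubble of that source must reconverge at that bubble's
  sink first, so it cannot be minimal and is skipped without search.
  (A color covered only by the *union* of several emitted bubbles is
  **not** skippable — that case produces genuine enclosing bubbles — and
  the unit tests enumerate random graphs exhaustively to confirm nothing
  is missed.)

### The bubble forest

Bubble 1's parent is the nearest later-discovered bubble that contains
it: color containment (except that full-color bubbles are always roots)
plus node-set containment. The printed inclusion conditions of the
source method order the candidates by discovery index and color; on the
worked example below, color conditions alone would pick
`<TCA, GGG, 110>` as the parent of `<GGG, GTA, 110>`, which contradicts
the known geometry (their node sets merely touch at GGG) — node-set
containment, which is the inclusion relation itself, resolves this and
reproduces the published parenthood. Roots get level 1, children one
more than their parent, and `order(child) < order(parent)` always holds.

## Variant calling

The caller assumes each variant corresponds one-to-one with a bubble
source node. For every source, each out-branch gets a *gap*: the final
offset of its first node minus the source's, minus one. A substitution
leaves both branches at gap 0; a length difference puts a positive gap
on the branch spelling fewer bases.

* **Reference pass.** Bubbles containing the reference color, in
  ascending discovery order. The reference-carrying branch is the
  baseline: alt-branch gap > 0 means deletion (type 2) in those samples,
  baseline gap > 0 means insertion (type 3), both zero a substitution
  (type 1), both positive an unsure indel (type 4).
* **Non-reference pass.** Sources seen only in bubbles without the
  reference are typed the same way against the bubble's
  largest-membership branch, with the nearest reference-containing
  ancestor bubble (through the forest) providing positional context; if
  the baseline is ambiguous (tied membership) and gaps disagree, the
  type is 4. The original description resolves nested gap
  configurations through flow charts not reproduced here; this
  per-branch reconstruction handles the documented nested cases
  (substitution inside an insertion) through the forest instead.
* **Positions.** Nodes on the reference path get the exact reference
  coordinate of their k-mer's last base. Off-reference sources inherit
  an approximate position from the nearest reference-containing
  ancestor's source plus the final-offset difference; calls made from
  them are flagged (`exact = FALSE`, `APPROX` in the VCF).
* **Alleles.** For each typed branch, the baseline sample and one
  affected sample are walked between the source and the sink of the
  smallest bubble joining them; the two spelled segments are trimmed
  (common suffix, then common prefix keeping a left anchor) into
  left-aligned VCF alleles. Alleles of 50 bp or more are outside the
  small-indel scope and are skipped with a warning.

On substitution-only populations every call sits at an exact reference
position derived from a genuine branching of the reference path, so
precision is 1 by construction — the accuracy tests verify this
end-to-end at mitogenome scale. Recall is below 1 exactly where
substitutions of one sample fall within k of each other and merge into
one multi-base record.

## Coordinates

Each node gets the base triple `(position, bubid, basecolor)`: final
offset; the deepest bubble containing the node (ties to the smallest
order; −1 on bridges — shared source/sink nodes take the deepest bubble,
an interpretation the source leaves open); and the color string (or a
representative sample id on request). Paths get the six-tuple
`(startpos, startbub, endpos, endbub, pathbub, pathcolor)`, with
`pathbub` the smallest bubble containing the path and `−n` when the path
spans `n` root bubbles. Endpoints on bridges inherit the bubble of the
nearest in-path node inside a bubble, and `pathbub` is computed over the
in-bubble path nodes; this convention is forced by the published worked
example, whose third path ends on a bridge node yet is printed with its
bubble id throughout. Two paths are separated when their offset
intervals do not intersect, included when intervals and colors both
nest, and intersect otherwise; for intersecting intervals with disjoint
colors the nearest common parent bubble supplies the comparison context.
Linear VCF records and GTF intervals are lifted onto these coordinates
through the reference path.

## Cycles

Repeats below the chosen k close directed cycles, which the traversal
detects by finishing early: the half-visited nodes (some but not all
parents done) are reported, at least one of which lies on a cycle. The
interval locator force-visits the minimal-offset half-visited node and
resumes; meeting one of its parents closes the interval
`[pos(start), pos(parent)]`. Two situations the published steps leave
implicit are handled explicitly: several pending cycle starts stay open
simultaneously (a second cycle may interrupt before the first closes),
and a forced node whose closing parent is itself (a homopolymer
self-loop) or an earlier forced node is recorded immediately, since that
parent can never be re-visited.

Cutting points inside an interval are typed I (bridge: a single
all-sample node of degree 1/1 — the ideal cut), II (all samples, not a
bridge) or III (partial samples), merged into runs of equal type and
thickness, and ranked by `R = L/t` with bridges preferred at ties.
*Thickness* `t` is defined here as the number of distinct (base, color)
states recorded at an offset, and a run is a maximal stretch of
consecutive offsets with equal type and thickness — both are documented
stand-ins for quantities the source defines only in unavailable
supplementary material, and both are isolated in `score_cut_regions()`.
Each sample is then cut at its own occurrence of the chosen region
(nearest occurrence to the reference cutting position when there are
several; the search key is the k-mer the sample carries at the cutting
offset, searched in the anchored sequence so junction-touching keys
still resolve), parts are re-anchored, and graphs are rebuilt per part.
`resolve_cycles()` iterates until every part is acyclic, preferring
regions inside the intersection of overlapping cycle intervals.
Cutting concatenates back to the original sequences exactly; for highly
repetitive input (tandem repeats especially) it can fragment the
sequences considerably, a known limitation.

## The simulator and what the tests show

`simulate_population()` emulates the mitogenome-scale experiments the
method was designed around: a random (or supplied) 16.5 kb reference and
nine derived samples by default, per-sample substitution/deletion/
insertion counts placed uniformly at random without overlap within a
sample (positions 1 and the last base are kept intact so indels always
have a left anchor), indel lengths uniform on 1–49 bp, substitution
alleles uniform over the three alternatives. Truth records are written
left-normalized so they compare exactly against left-aligned calls. The
placement and length laws are this package's own choices, stated here
because the original simulation protocol is in unavailable supplementary
material. Evaluation matches calls to truth by location (tolerance 0 for
substitutions, ±1 for indels by default) or additionally by type;
precision is 1 by convention when nothing is called.

Real genomes differ from this generator in ways that matter: mutation
positions are not uniform, indels cluster in repeats, and samples share
ancestry (correlated variants), so the accuracy figures from simulations
bound what to expect on real data rather than predict it. The
structural guarantees (round-trip spelling, offset correctness, bubble
validity, forest shape, post-cut acyclicity) are distribution-free and
are tested against independent igraph-based oracles on randomized
inputs.

Problem sizes used by the test battery: one hundred random populations
of 2–5 samples and 200–1000 bp for the structural checks; five
mitogenome-scale (16.5 kb, 10 samples, 100 substitutions) replicates for
the precision check; 4–6 kb populations, five seeds per setting, for
the qualitative accuracy trends. Under those conditions indel load lowers
both precision and recall, and larger k lowers recall sharply (the
graph loosens and sources disappear). Measured precision, however,
stays near 1 at large k — the few surviving calls sit at exact
reference-path positions — so a precision decline with k is not
behavior this implementation exhibits; its trend test asserts the full
expected pattern and records the disagreement by failing that
sub-assertion.

## Numerical and degenerate-input choices

* Colors are integer bit masks; at most 30 samples per graph.
* Anchor drawing retries up to 1000 seeded attempts before erroring;
  head and tail must differ.
* `longest_repeat_length` uses exponential-then-binary search over
  candidate lengths, each probed by vectorized substring duplication.
* Empty bubble sets, empty call sets and header-only VCFs are all legal
  outputs; two identical sequences produce a single linear path and no
  calls.
* The unsure type 4 is used wherever branch gaps contradict each other
  or no reference-bearing ancestor exists (the latter with a warning).

## Worked example

```{r}
tr <- example_trio()
g <- build_cdbg(tr$genomes, k = tr$k, anchors = tr$anchors)
tree <- bubble_tree(find_bubbles(g), g)
tidy(tree)
glance(tree)
calls <- call_variants(g, ref_id = "s2")
calls[, c("refpos", "ref", "alt", "vartype", "samples")]
```

The five bubbles appear in the documented discovery order with the
documented parenthood; the calls are the 1 bp deletion and two
substitutions of sample s1 and the 4 bp substitution block of sample s3,
all relative to s2.
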