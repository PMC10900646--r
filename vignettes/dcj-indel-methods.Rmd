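---
title: "Capping-free DCJ-indel distances: model, algorithms and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capping-free DCJ-indel distances: model, algorithms and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcjindel)
```

## The model

A genome is a set of linear and circular chromosomes over oriented
*markers* (genes or synteny blocks). Each marker has two *extremities*, a
tail and a head; neighbouring extremities on a chromosome form an
*adjacency*, and the outer extremities of linear chromosomes are
*telomeres*. Two genomes are compared under a *homology*: an equivalence
relation on markers (the *families*), implied here by shared token names
in the UniMoG text format. A family is *singular* when only one genome
holds it, and *ambiguous* when some genome holds more than one copy;
genomes with ambiguous families are called *natural*.

The evolutionary events modelled are the double-cut-and-join (DCJ) —
cut up to two adjacencies or telomeres and rejoin the loose ends, which
subsumes inversions, translocations, fusions, fissions and
excisions/integrations — and *restricted* insertions and deletions of
chromosome segments consisting solely of singular markers. The
restriction prevents "free lunch" scenarios that delete and reinsert
arbitrary matched material.

For a *resolved* homology (no ambiguity), the distance is read off the
component decomposition of the multi-relational diagram (MRD): the graph
on the extremities of both genomes whose edges are the adjacencies of
both genomes plus *extremity edges* between equivalent extremities.
When the homology is resolved this graph falls apart into simple cycles
and paths. Path endpoints are classified as telomeres (`A`/`B` by
genome) or *lava vertices* (`a`/`b`) — extremities of singular markers,
which are destined for indels. That yields ten path types plus cycles:
*viaducts* (two telomeres: `AoA`, `AB`, `BoB`), *piers* (telomere +
lava: `Aoa`, `Ab`, `Ba`, `Bob`) and *pontoons* (two lava: `aoa`, `ab`,
`bob`), with parity counted in extremity edges (`o` even, odd
otherwise). Parity is determined by the endpoint classes, a fact the
classifier asserts on every component.

With `n` matched markers, `c` cycles, `p_x` the path-type counts and
`s` circular singletons (circular chromosomes of only singular markers,
each settled by one indel and handled before classification), the
restricted DCJ-indel distance is

```
d = n - c + ceil( (p_ab + max(p_Aoa, p_Ba) + max(p_Ab, p_Bob) - p_AB) / 2 ) + s
```

with the mathematical ceiling (equal genomes give `ceil(-2/2) = -1`,
cancelling against `n - c`). `formula_distance()` evaluates the formula;
`resolved_distance()` runs the whole pipeline.

```{r formula}
gs <- parse_unimog(">A\n1 -2 |\n>B\n1 2 |")
m <- identity_matching(gs[[1]], gs[[2]])
resolved_distance(gs[[1]], gs[[2]], m)
```

## Operation theory: safe operations, bridges, recombinations

Writing a DCJ abstractly on component types (e.g.
`P_Aoa, P_Ba -> P_AB, P_aoa`), an operation is *safe* when it lowers the
distance formula by exactly 1 in every surrounding component
configuration. `safe_catalogue()` derives the catalogue rather than
hard-coding it: it enumerates every signature realizable by a single DCJ
— recombinations of two components (both repairings of the four
endpoints), fissions (a cut creating a same-genome telomere pair),
fusions (a join consuming one), cycle moves and the extraction family —
and evaluates the formula change over all surrounding contexts with 0–4
extra copies of each formula-relevant component type. Four copies
suffice because the formula is piecewise linear with breakpoints only at
the equalities inside the two `max` terms and at the ceiling parity;
beyond two extra copies the sign pattern of a change cannot move.
Exactly seven types survive.

Two conventions matter here:

* *Lava endpoints are conserved; telomeres are not.* A cut creates a
  same-genome telomere pair and a join consumes one, which is how a
  single even `A`-viaduct can split into two odd `AB`-viaducts.
* *Whole-component circularization* (joining the two same-genome
  telomeres of an even viaduct) lowers the formula by 1 unconditionally.
  It is the degenerate member of the generic cycle-extraction family
  `K -> K' + C` in which the residual component `K'` is empty, and is
  counted inside that single generic catalogue entry.

Sorting a *bridge* (a pier-to-pier chain of pontoons concatenated
through singular markers) by internal safe operations leaves at most its
two piers and one odd pontoon unsaturated — the *reduced bridge*.
Consecutive components share the genome of their connecting lava
vertices, so there are six pier pairs with equal lava genome and four
pier–odd-pontoon–pier triples: ten types
(`reduced_bridge_types()`). Two of them (`Aoa+Ba`, `Ab+Bob`) equal safe
operation sources and sort internally. Over the remaining eight,
`count_recombinations()` counts the pairings that supply a
recombination-enabling safe operation: 9 for the even-`A`-pier/odd-`B`-pier
operation, 9 for its mirror image, and `4 + choose(4, 2) = 10` for the
two-odd-pontoon operation.

## The capping-free ILP for natural genomes

For natural genomes the distance is minimized over *maximal matchings*
(per family, `min(|f_A|, |f_B|)` marker pairs). Equivalently, the ILP
selects a consistent *decomposition* of the MRD: extremity edges such
that every vertex is covered once, head and tail *sibling* edges agree,
and every unmatched marker is flagged by its *indel edge*. The classic
alternative — capping, which joins linear chromosome ends into circular
structures at solve time — blows up the search space
super-exponentially in the number of linear chromosomes; here each
telomere instead gets an inert *pseudo-cap* anchor vertex, which adds no
matching decisions.

The objective `n - c + q + s` is assembled from binary *report
variables* on adjacency edges:

* `y`/`z` machinery: `y` is equal along decomposition edges, bounded by
  the vertex id `ix`, and forced to 0 in components containing lava
  vertices; `z_v = 1` is only possible where `y_v = ix(v)`, i.e. at the
  minimum-id vertex of a lava-free component. Pseudo-caps receive the
  lowest ids (genome A before B), so the minimum of any lava-free path
  is a pseudo-cap and the minimum of a cycle is an ordinary vertex —
  which is what lets cycle reports live on ordinary adjacency edges and
  `A|B`-viaduct reports on A-pseudo-cap edges, each licensed at most
  once per component by the adjacent `z`.
* label variables `l` (0 = endpoint in genome A, 1 = genome B), pinned
  statically at pseudo-caps and dynamically at lava vertices, constant
  along edges except where an odd-path report is set; odd reports
  additionally require an actual label change at their edge, so even
  paths cannot pose as odd ones.
* pier reports live only on pseudo-cap edges of the matching genome; a
  pier report forces the component's `y` to 0, and a pseudo-cap whose
  `y` is 0 must report a pier — this pair of implications both blocks
  an even `A`-viaduct from faking an `A|B` report and forces even piers
  (which change no label) to be counted.
* odd-pontoon reports require a neighbouring selected indel edge. A
  label flip inside an odd pontoon can always be placed on the adjacency
  edge next to a lava endpoint, so the requirement never blocks a
  genuine count, while mis-reporting costs at least as much as honest
  reporting — feasible assignments may legally over-report only
  cost-increasing types.
* the integer `q` obeys `2q >= p_ab + alpha + beta - p_AB` for all four
  choices of `alpha` in `{p_Aoa, p_Ba}` and `beta` in `{p_Ab, p_Bob}`;
  minimization makes `q` exactly the ceiled fraction of the formula.
* per circular chromosome, an indicator is forced to 1 when all its
  indel edges are selected; their sum is `s`.

Family bounds `L_f <= matched pairs <= U_f` select the matching model:
maximum (`L = U = min`), intermediate (`L = 1, U = min`) and exemplar
(`L = U = 1`). The intermediate setting follows the matching-model
literature; a transposed rendering of the bounds table would violate
`L <= U`. Distances and matchings returned to the user are always
*recomputed* from the selected decomposition by the classifier and the
closed formula — solver report variables are never trusted directly.

The model is solver-agnostic: `write_lp()`/`write_mps()` export the
standard text dialects, and `solve_ilp()` drives either the GLPK
command-line solver or HiGHS (through `scipy.optimize.milp`); both
backends are exact, and the test suite checks they agree. Big-M
constants equal the largest vertex id, the smallest valid choice.

```{r ilp}
gs <- parse_unimog(">A\n1 1 2 |\n>B\n1 2 |")
res <- dcj_indel_ilp(gs[[1]], gs[[2]], model = "maximum")
res$distance
res$matching
```

## The brute-force oracles

The correctness surface of the package is dual-route: every headline
quantity is computed twice, by the implementation and by an independent
brute force.

`bfs_restricted_distance()` finds shortest restricted scenarios for tiny
pairs. It searches bidirectionally: any optimal scenario can be
reordered so that every deletion precedes every insertion (no marker is
both inserted and deleted in an optimal scenario, and a deletion of
singular material commutes backwards past operations on disjoint
material), so scenarios split into a DCJ-plus-deletion prefix from one
genome and — read backwards — a DCJ-plus-deletion prefix from the
other, meeting at a genome over the matched markers only. Insertions
therefore never need to be enumerated, which keeps each side's state
space tiny; deletions of arbitrary contiguous singular segments on
*both* sides still capture scenarios whose one insertion glues material
destined for several chromosomes. States are canonicalized (linear
chromosomes up to reversal, circular up to rotation and reversal,
chromosome order ignored) and the search terminates early once no
undiscovered meeting can beat the incumbent. Hitting the state or depth
cap yields an explicit *undecided* result, never a wrong number.

`enumerate_maximal_matchings()` and `min_distance_by_enumeration()`
provide the reference for the natural-genome problem by exhausting all
`choose(max, min) * min!` per-family pairings.

## The simulator

`evolve_pair()` emulates divergent evolution: a root of `n_markers`
distinct forward markers on `n_chromosomes` linear chromosomes
(`make_root()`), and `n_ops` operations split evenly between the two
lineages. Each operation's type is drawn with probability
`rate / (1 + sum(rates))` with DCJ rate 1 — at the reference setting of
10,000 operations with insertion 0.1, deletion 0.2 and duplication 0.4
that is 5882 DCJs in expectation. Indel and duplication lengths are
Zipf-distributed with shapes 4 and 6; sampling inverts a CDF truncated
at 10^6, whose tail mass is far below sampling noise for these shapes
(the empirical mean of Zipf(4) is checked against the exact
`zeta(3)/zeta(4)`).

Mechanics the protocol leaves open were fixed once, as follows: a DCJ
draws two cut sites uniformly (with replacement) from adjacencies and
telomeres and a valid reconnection uniformly — drawing one adjacency
twice is the single-cut fission, drawing one telomere twice is redrawn;
insertions add fresh families at a site drawn uniformly from
adjacencies, telomeres and "new circular chromosome"; deletions remove
a uniform-start segment capped at its chromosome, with the length
reduced when the genome would otherwise empty; duplications copy a
uniform-start segment, retaining families and descent, to a uniformly
drawn insertion site. The even lineage split and a single seeded PRNG
stream make a pair bit-for-bit reproducible from one seed.

The emitted ground-truth matching pairs surviving descendants of the
same root marker (injectively, lowest occurrence ids first). It is a
valid matching but not necessarily the distance-minimizing pairing of
duplicates — the minimized distance is bounded by the operation count,
the truth-matching distance need not be. What the simulator does *not*
emulate: sequence-level noise, missing orthology assignments,
rate heterogeneity along the genome, and assembly fragmentation; tests
passing on simulated pairs therefore validate the combinatorial
machinery, not robustness to annotation error.

## Numerical and scale choices

Everything in the package is exact integer combinatorics; the only
tolerances involved are MIP solver integrality tolerances, absorbed by
rounding recomputed objectives to integers. Degenerate inputs are
handled explicitly: empty chromosomes are rejected at parse time,
single-marker chromosomes produce telomere-lava vertices that classify
as even piers after pseudo-cap augmentation, and fully circular genome
pairs produce no pseudo-caps at all.

Test problem sizes were chosen to exhaust structure rather than scale:
the closed form is checked against the scenario search on *every*
canonical pair with up to 3 markers per genome over a two-family
alphabet under every maximal matching (with a canonical-instance cache
collapsing equivalent searches), and the ILP against the matching
enumeration on 200 random natural pairs with up to 6 markers and family
multiplicity up to 3, where enumeration is still exact.
Simulator runs in tests use tens of markers and operations; the
distributional checks (type frequencies, Zipf moments) use 10^5-10^6
draws directly.

## Known limitations

* The ILP targets exactness on small-to-moderate instances through
  standard open MIP backends; pushing capping-free formulations to
  genomes fragmented into thousands of linear chromosomes is a matter of
  solver horsepower and is out of scope here.
* The scenario oracle is a verification device for toy sizes only.
* Sorting scenarios themselves (sequences of operations realizing the
  distance) are not reconstructed; the package reports distances,
  component reports and matchings.
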