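---
title: "Assembly indices, the assembly equation, and selection dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly indices, the assembly equation, and selection dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assemblyr)
```

## The model

Assembly theory treats an object not as a point particle but as something
with a construction history: it is finite, distinguishable, persists, and can
be broken into elementary units. A pathway builds the object by recursively
joining structures, starting from the elementary units, with every structure
formed along the way returned to the assembly pool and reusable at no
further cost. The *assembly index* `a` of an object is the length of its
shortest pathway. Three object kinds are implemented:

* **strings** — elementary units are single characters and joining is
  concatenation (ordered, since concatenation does not commute);
* **homopolymers** — an integer chain length; joining adds lengths, so the
  assembly index of length `n` is exactly the minimal *addition chain*
  length for `n`;
* **molecular graphs** — heavy atoms with labelled bonds; bonds are the
  elementary units and a join forms the edge-disjoint union of two
  structures, fusing a declared set of shared atoms.

For any kind, `ceiling(log2(n)) <= a <= n - 1` for an object of size `n`:
a join at best doubles what exists, and unit-by-unit growth always works.

An ensemble of `N` unique objects with assembly indices `a_i` and copy
numbers `n_i` (total `N_T`) has *assembly*

    A = sum_i exp(a_i) * (n_i - 1) / N_T .

Singleton objects contribute nothing: only repeated copies of multi-step
objects witness a non-random generative process. `A` grows exponentially in
assembly index and linearly in any single copy number (the product `A * N_T`
has slope `exp(a_k)` in `n_k`, which the test suite checks to 1e-12).

```{r example}
assembly_index_string("ABRACADABRA")$index
assembly_A(ensemble(c("x", "y"), c(1, 2), c(2, 3)))  # (e + 2 e^2) / 5
```

## Exact searches

### Strings

A minimal pathway for a string only ever constructs substrings of the
target, so the search runs top-down: split the target into two parts, each
part elementary, already scheduled, or a new goal; iterative deepening on
the number of distinct constructed substrings guarantees the minimum with
bounded memory. This goal-directed formulation visits far fewer states than
enumerating bottom-up pool configurations, and the test suite proves
equality with a bottom-up pool-state brute force on every string of length
at most 8 over a two-letter alphabet. Splits are tried balanced-first in a
fixed order, so co-minimal pathways resolve deterministically. The exact
limit is 25 characters by default; beyond it the function refuses rather
than silently approximating, because no trustworthy heuristic for string
assembly indices is implemented.

### Homopolymers / addition chains

Exact minimal addition chains come from an iterative-deepening search over
strictly increasing chains (compiled code), pruned by the doubling bound.
Candidates are tried in ascending order, so the returned chain is the
lexicographically smallest minimal chain — ties never introduce
nondeterminism downstream (joint assembly spaces depend on this). The
default exact limit is `2^16`; above it the binary double-and-add chain
(length `floor(log2 n) + popcount(n) - 1`) is returned and flagged
`approximate`.

### Molecular graphs

The molecular search runs top-down from the bond-count upper bound `E - 1`,
looking for savings from duplicated substructures: matching two
edge-disjoint isomorphic connected subgraphs with `k` bonds and deleting
one copy's edges saves `k - 1` steps, because the deleted copy can be
obtained by one reuse of the other, which some pathway builds once.

A subtlety we consider essential: *not every match sequence corresponds to a
realizable pathway*. A structure is built exactly once; later uses are
opaque copies, so match regions must nest laminarly inside the first-built
("representative") copy of each reused structure, and a removal may never
swallow a region that must still be built. Unrestricted match sequences can
straddle region boundaries and overcount savings — diethyl phthalate is a
concrete counterexample, where unrestricted matching claims one saving too
many (index 7 instead of the correct 8). The implementation therefore uses
the unrestricted memoized search only as an upper bound and certifies the
index with a laminar witness search; the witness unfolds into an explicit
pathway that is replayed and length-checked on every call. Correctness is
established against an independent bottom-up oracle (minimal construction
sets over the connected-subgraph universe) on all small graphs (see
"Validation scale" below).

Isomorphism is decided by a canonical certificate (colour refinement with
full individualization branching over element and bond-order labels),
validated in the tests against igraph's VF2 on vertex-coloured subdivision
graphs. Aromatic bonds carry one uniform label, so any Kekulé drawing of an
aromatic ring canonicalizes identically; stereochemistry and charges are
ignored.

**Ring closure.** Joining a structure with an elementary bond while fusing
*both* bond endpoints closes a ring. The elementary-unit semantics admit
this, and it is enabled by default (`allow_ring_closure = TRUE`); disabling
it restricts joins to at most one fused atom, under which cyclic molecules
cannot be assembled at all and are rejected with an explanatory error. We
chose the permissive default because bond-by-bond construction of a ring is
physically meaningful and because the bond-count upper bound `E - 1`
otherwise fails for any cyclic molecule.

```{r dep}
dep <- parse_molecule(system.file("extdata", "diethyl_phthalate.sdf",
                                  package = "assemblyr"))
molecular_assembly_index(dep)$index
```

## Forward exploration and joint assembly spaces

Starting from one monomer, *undirected* exploration joins two members drawn
uniformly (with replacement) from the unique pool members; *directed*
exploration always uses the most recently created polymer as one operand.
Draws use the unique member types, not abundances, because the pool records
discovery; abundance-weighted draws are available as an option. "Observed"
means every length ever present in the pool at the end of a run.

The *joint assembly space* of the observed set is the union of one minimal
addition chain per observed length (deterministic tie-breaking makes the
contingent set a function of the observed set); its *exploration ratio* is
observed nodes over all nodes. Directed runs explore deep, narrow spaces:
lower ratio, higher maximum assembly index — the signal of selection. The
default experiment (25 paired seeded runs of 1000 steps) shows directed
ratios roughly twenty-fold below undirected ones with a one-sided sign test
far below the 0.01 level.

Numerical choices here: lengths are held as doubles, exact as integers up to
`2^53`; directed runs grow lengths exponentially (about `10^170` after 1000
steps), so chains for lengths above the experiment's exact-chain limit
(default 1024) use the flagged binary approximation — consistent with the
`log2(n)` leading-order behaviour of both bounds, and the reported
statistics include the `log2` approximation alongside the chain-based index.
Runs beyond roughly 3000 directed steps would overflow double range and are
not supported at default settings.

## Selection dynamics

Discovery follows the cascade `dN_{a+1}/dt = k_d (N_a)^alpha` over levels
`a = 1..a_max`, level 1 being the constant elementary basis. `alpha = 1` is
undirected, history-dependent expansion; `alpha < 1` means only a sublinear
subset of each level is available for reuse — selection. The deterministic
integrator (adaptive `lsoda`, rtol 1e-12, atol 1e-22; the extreme absolute
tolerance keeps deep levels relatively accurate at early times when they
hold values around 1e-10) reproduces the `alpha = 1` closed form
`N_a(t) = N_1 (k_d t)^(a-1)/(a-1)!` to better than 1e-6 relative error for
`a <= 10`, `k_d t <= 5`. The rate out of an empty level is zero (no
spontaneous creation at depth); an optional `activation` threshold of one
whole object makes the `alpha = 0` front advance one level per `1/k_d`,
matching piecewise-linear integration.

The stochastic engine realizes the cascade in continuous time. Each level
`a` exposes its first `ceiling(N_a^alpha)` objects (discovery order: early
objects stay reusable — historical contingency) and events select a level
proportionally to that available count. The selected object combines with a
partner drawn from the whole available pool, and the product is *new only
if that ordered pair has not combined before*: product identity is
combinatorial. This is what makes selection visible at matched event
counts — with `alpha = 1` the pair space is large and nearly every event
discovers something, while strong selection keeps recombining the same few
objects. With `N_1 = 100` the collision bias at `alpha = 1` is two orders
of magnitude below the Monte Carlo standard error at the validation scale
(25 runs to `k_d t = 2`, about 16,000 events), so the engine also matches
the closed form within 3 MC standard errors. The related polymer simulator
collides on *lengths* rather than pairs, so the two engines share the
selection law (`P_a` proportional to `N_a` at `alpha = 1`) but not the full
product-identity distribution; we test the law, not distributional identity.

Production adds copies of discovered objects at a homogeneous rate `k_p`
per object ("homogeneous kinetics": one rate constant across objects, and
deliberately not proportional to `n_i`, which would concentrate copies on
early low-index objects). Discovery and production compete for a total mass
budget `M`; every first copy and every produced copy consumes one unit, and
the run ends cleanly when `M` is spent. Ensemble assembly uses
`a_i = level - 1` (the elementary basis has index 0) over discovered
objects.

Timescales `tau_d = 1/k_d` and `tau_p = 1/k_p` classify three regimes with
configurable thresholds (`tau_d/tau_p < 0.1`: regime 1, singleton
explosion; `> 10`: regime 2, copy hoarding at low index; otherwise regime
3, where selection is possible). Under the study conditions used throughout
(`alpha = 0.6`, `N_1 = 100`, `M = 100`, `t_end = 200`, matched seeds), the
final assembly over the ratio grid `{0.01, 0.1, 1, 10, 100}` peaks at the
interior point `tau_d = tau_p` (about 4.1 against 0.6 and 3.0 at the
extremes). `M = 100` keeps the cascade shallow enough that the peak sits at
comparable timescales; larger budgets move it toward faster discovery but
keep it interior.

## Synthetic data

`make_fixtures()` generates all test inputs in code: strings with planted
repeated motifs (four repeats of a motif-plus-padding block, giving a
constructive index bound of `(block - 1) + 2`), homopolymer length sets,
random connected heavy-atom trees over C/N/O with single/double bonds and
capped valences, and ensembles with controlled index/copy mixtures. The
generator emulates the *combinatorial* features the methods exercise —
reusable motifs, duplicated fragments, copy-number contrast — not real
chemistry: no aromatic systems are generated (benzene and diethyl phthalate
are fixed structures in the tests), no stereochemistry, no realistic
abundance noise, and ensemble indices are assigned rather than measured.
Passing tests therefore validate the algorithms and their contracts, not
instrument-derived assembly measurements.

## Validation scale

Problem sizes were chosen so the full suite runs in minutes: string oracle
equivalence on all 510 strings of length <= 8 over {A, B}; addition chains
against exhaustive search for all n <= 64; molecular oracle equivalence on
every connected single/double-bond carbon graph with <= 5 bonds (266
isomorphism classes, including all cycles), every C/O/N labelling up to 3
bonds, and seeded samples of six C/O/N labellings per 4- and 5-bond shape —
the complete labelled 5-bond space (tens of thousands of classes) is
exercised by sampling rather than exhaustively, a deliberate scale choice;
random 6-8-bond graphs are cross-checked in the unit tests. Exploration
experiments use 25 paired runs of 1000 steps; stochastic-engine checks use
25 seeds and at least 10^4 events.

## Known limitations

* String indices beyond ~20 characters with little internal repetition can
  be slow (the search proves optimality; it never approximates), and inputs
  above 25 characters are refused by default.
* Molecular search cost grows quickly with bond count; the default exact
  limit is 30 bonds, and the 16-bond worked example takes a few seconds.
* The joint assembly space above the exact-chain limit mixes exact and
  binary-approximate chains; the `approximate` flag reports when.
* The co-assembly/shared-history variant of the assembly equation is an
  extension point, intentionally not implemented.
* Estimating `alpha` and `k_d` from experimental time series is out of
  scope; the simulators are phenomenological forward models.
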