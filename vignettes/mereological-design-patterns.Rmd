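---
title: "Grains, components and mixtures: the models behind mereocoll"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grains, components and mixtures: the models behind mereocoll}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mereocoll)
```

## The problem

Biomedical ontologies lean heavily on parthood. Two of its subrelations do
very different work: `has_grain` relates a collective to its multiply
occurring uniform parts (the H₂O molecules in a drop of water, the cows in
a herd), while `has_component` relates a compound to the segments of a
partition (the atoms of a molecule, the bones of a skull). Crossing two
independent properties — whether the parts at a granularity level are of
one sort (mono-sortal) or several, and whether their number is essential
(strict) or not (flexible) — yields four kinds of complex entity:

|                       | mono-sortal            | multi-sortal          |
|-----------------------|------------------------|-----------------------|
| **flexible in number**| a portion of water     | a hand                |
| **strict in number**  | a pair of kidneys      | a propanol molecule   |

`mereocoll` makes this machinery executable three ways: finite instance
models with the relations evaluated over them, a compiler from the design
patterns to OWL 2 class axioms, and a bounded-model oracle that checks the
subsumptions a description-logic reasoner could (or provably could not)
compute.

## Finite models and the executable relations

A `FiniteModel` is a set of typed entities with an acyclic direct-parthood
graph. `has_proper_part` is the transitive closure of the direct edges.
Candidate grains of an entity default to its *direct* parts — a water
portion's grains are molecules, never the atoms further down — and can be
overridden by an explicit designation.

The collective axioms are biconditionals: an entity is a collective of
base type `X` iff it has at least one grain and every grain instantiates
`X` (grain existence plus mono-sortality). Because they are biconditionals
we *derive* collective status rather than trusting an asserted `X_COLL`
label: `hasGrain(m, reg, x, y)` holds iff `y` is a candidate grain of `x`
and some declared type is instantiated by *all* grains of `x`. Three
consequences follow as theorems rather than assumptions and are checked by
`runPropertySuite()` on 500 seeded random models (≤ 8 entities each):
irreflexivity and asymmetry (from acyclicity of parthood) and propagation
through parthood in both directions (from transitivity). Non-transitivity
is witnessed, not universal: in the galaxy → star → molecule fixture the
galaxy collects stars and a star collects molecules, but the galaxy's
grains are not uniform molecules.

Empty collectives are rejected — allowing them would make any grainless
entity an instance of every collective type — while singleton collectives
are allowed.

### Partitions and components

A partition of a whole is a set of segments that are proper parts,
pairwise non-overlapping, and jointly exhaustive. In finite discrete
models two entities overlap iff their part-closures-including-self
intersect, so non-overlap is closure-disjointness. Exhaustion is read
through overlap, not set equality of closures: every proper part of the
whole must overlap some segment. The overlap reading matters for
partitions that crisscross granularity levels (half a protein chain into
monomers, the other half into atoms): the monomer that was "skipped over"
still overlaps its atoms' segments, so such partitions are valid, exactly
as intended.

Relativized componenthood is segment membership; an atom inside a segment
is not itself a component with respect to that partition. Unrelativized
componenthood collapses to proper parthood, because in a discrete model
every proper part extends to a partition by taking the remaining atoms as
singleton segments.

### Strictness without modality

A strict compound is defined modally — no segment can be added or removed
with the result still an instance of the type. We decide this through a
cardinality-based `TypeSpec` (per-component-type slots: `exactly(n)`,
`atLeast(n)`, `anyNumber`): a partitioned entity is a strict compound iff
its segments satisfy the spec and every single-segment removal and every
single-segment hypothetical addition of a slot type violates it. This
makes the definition decidable without a type-membership oracle. It gives
the right verdicts on the worked cases: H₂O under the water spec is
strict; a portion of water under "at least one water molecule" is not
(remove a molecule and a portion of water remains).

### Mono-sortality and the classifier

`classifyComplex()` crosses mono-sortality at a chosen level with spec
strictness. Mono-sortality is judged on each part's *minimal* asserted
types below the level type. Judging on any shared supertype would make
every complex mono-sortal at its own level and erase the phenomenon the
classifier exists for. The minimal-type reading reproduces all the
granularity and specificity flips: a water portion is mono-sortal at the
molecule level and multi-sortal at the atom level; an O₂/O₃ mixture is
multi-sortal at the molecule level yet mono-sortal at the atom level
(everything is an oxygen atom); a basket of fruits is a collective of
fruits and simultaneously a mixture of apples and pears.

## Class expressions and finite-model semantics

`dl-expr`/`dl-parse` implement a small Manchester-style language (`and`,
`or`, `not`, `some`, `only`, `exactly`/`min`/`max`) with the usual
precedence; `renderClassExpr()` is a normal form and `parseClassExpr()` its
inverse. Semantics are closed-world over a finite model: `not` is
complement within the entity set, a universal restriction over an entity
with no successors holds vacuously, and qualified cardinalities count
typed successors.

Roles are interpreted in one of two modes, and the distinction carries the
package's central negative result:

* **fol** — the first-order reading: `has_grain` is active only where the
  grains are uniform; `has_component` is proper parthood.
* **primitive** — the bare direct edges. This is all a DL reasoner ever
  sees of a primitive subrole: the uniformity and partition conditions
  that *define* the two relations are not expressible in OWL DL.

`isDLSafe()` implements the OWL 2 global restriction that number
restrictions may only use simple roles (no transitive role, transitive
subrole, or transitive inverse). That is why `has_proper_part exactly 3
Atom` — the natural "molecule with three atoms" query — is flagged, while
the same count through the non-transitive `has_component` is clean.

## The bounded subsumption oracle

True entailment over the first-order reading is undecidable in general,
so `boundedSubsumption()` enumerates *all* acyclic finite models up to a
size bound: every DAG shape (edges directed from lower to higher index,
which covers all DAGs up to relabelling since every DAG has a topological
order), every single-label typing from a caller-chosen vocabulary, labels
closed under `is_a`. TBox equivalences with an atomic side act as class
definitions; remaining axioms filter admissible models. The verdict is
either a concrete countermodel (re-checkable with `classExtension()`) or
bounded evidence "holds up to size *k*" — deliberately reported as such,
never as a proof. Enumeration is deterministic; no seeds are involved.

Default bound: size 4 with a four-type vocabulary (≈ 16 000 labelled
graphs per query, a few seconds). The worked mixture patterns need no
more than five entities, and every countermodel the shipped checks expect
already appears at size ≤ 4; exhaustive size-5 runs (≈ 10⁶ graphs per
query) remain available through the `maxSize` argument. A resource guard
(`maxModels`) stops runaway enumerations and marks the verdict partial.

## Mixtures: the propanol use case

Mixtures sit between the categories: a compound of *fractions*, each
fraction a collective of grains of one sort. `mixturePattern()` emits the
three representation variants — grain disjunction (`has_grain some (N or
I)`), grain supertype (`has_grain some Propanol_Molecule`), and compound
of fraction collectives with a closure conjunct (`has_component only
(Propanol_COLL or not Molecule)`) — plus a fourth, *reasoner-friendly*
spelling that uses `has_proper_part`/`proper_part_of` only:

* collective: `has_proper_part some Propanol_Molecule and has_proper_part
  only (Propanol_Molecule or not Molecule)`;
* mixture: a part of each isomer sort, and every part either a propanol
  collective or a proper part of one.

`buildPropanolOntology()` regenerates the full use case: the hierarchy
with two disjoint isomer classes, the grain-regime collective classes,
three mixture variant classes, and the proper-part rewrites. Axioms carry
a `regime` tag (`grain` vs `proper_part`) because the two regimes give
the same class names different definitions; `tboxFor()` loads one regime
at a time — loading both at once would *assert* the equivalence whose
derivability is the entire question.

Two results, both recomputed by the test suite and `demo-propanol`:

1. **Positive**: under the proper-part regime all three mixture variants
   are entailed subclasses of `Propanol_COLL` (bounded oracle, size 4).
2. **Negative control**: with `has_grain`/`has_component` as primitive
   subroles, the fraction-compound mixture is *not* subsumed by the
   grain-based collective — the oracle returns a four-entity
   countermodel in which the mixture's direct parts are fraction
   collectives rather than molecules.

### The disjointness decision

The positive entailment is sensitive to one auxiliary axiom that the
use case leaves implicit. Without `DisjointClasses(Propanol_COLL,
Molecule)` the oracle finds a four-entity countermodel: a *non-propanol*
molecule all of whose proper parts are propanol molecules satisfies the
collective definition, may sit inside a mixture, and then violates the
mixture's closure conjunct (it is a molecule but not a propanol
molecule). With the disjointness — collectives here are portions of
matter, not molecules — the subsumption holds in every enumerated model.
We ran the oracle both ways and ship the disjointness asserted by
default (`collectiveMoleculeDisjoint = TRUE`), with the flag exposed and
the no-disjointness countermodel kept reachable for inspection.

## Design choices worth knowing about

* **`_COLL` as a naming convention.** The collective-former is not a
  constructor inside OWL; `collName()`/`nCollName()` just fix the names
  (`Cow_COLL`, `Kidney_PAIR`) and the patterns generate the axioms. The
  registry deliberately leaves `X_COLL` unrelated to `X` in the
  hierarchy; whether `Entity_COLL` is an `Entity` is a modelling question
  the package does not prejudge.
* **Isomer disjointness is asserted explicitly.** The isomer pair is
  implied to be disjoint by the use case but nothing in the hierarchy
  forces it; the generated ontology says it outright.
* **Flat vs nested molecule spellings.** The flat spelling counts atoms
  as components directly; the nested one routes the hydrogens through a
  strict pair collective. They are offered as alternatives, but they are
  not extensionally identical across model shapes: the nested class
  requires an intermediate pair individual that the flat closure conjunct
  (`has_component only (H-Atom or O-Atom)`) excludes, under either role
  reading. What does hold — and what the suite asserts — is that each
  spelling accepts its canonical fixture shape and both reject hydrogen
  peroxide: the number-blindness cure does not depend on the spelling.
* **Hands and the one-finger consequence.** The flexible-compound
  pattern (`Hand subClassOf has_component some Finger_COLL`) entails
  that there is no hand without a finger. The pattern is emitted as
  written; the caveat lives here rather than in a silently patched
  axiom. No such worry arises for alcohol molecules: even methanol has a
  carbon atom.
* **Connectedness is ignored everywhere.** No spatial relation is
  modelled; gaseous and liquid water portions are the same collective.
  A corollary is that bunches of O, O₂ and O₃ cannot be told apart at
  the atomic level — which is precisely the granularity effect the
  classifier demonstrates.
* **Structure blindness is out of scope.** Isomers are distinguished by
  label only; bond topology would need mereotopology.

## What the fixtures do and do not show

The fixture generator emulates the worked examples at desk scale:
molecules with correct sum formulae (H₂O, H₂O₂, C₃H₈O isomers, methanol,
ethanol), a five-molecule water portion, hands with 4/5/6 fingers, small
herds and plasma samples (3–5 grains), and the galaxy chain. Passing
tests show that the formal machinery behaves as the theory says on models
of this shape; they say nothing about chemically valid structures, about
continuous portions of matter (models are finite and atomistic by
design), or about ontologies with role boxes richer than the four
mereological roles interpreted here.

Problem sizes used by the shipped checks, chosen once: property suite 500
models × ≤ 8 entities; oracle queries size ≤ 4 (positive) and ≤ 5
(countermodel searches, which exit early); all worked-example fixtures
≤ 17 entities. The external-reasoner cross-check (`checkWithExternalReasoner()`)
probes for ROBOT/HermiT and reports a structured skip when, as in a plain
R installation, no reasoner is present.
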