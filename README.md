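# mereocoll

Executable mereology for biomedical ontology engineering: collectives,
compounds and mixtures as finite models, design patterns and OWL axioms.

Ontologies for anatomy, cells and biomolecules lean on two subrelations of
`has_proper_part` that do different work. `has_grain` relates a collective
to its multiply occurring uniform parts (the H₂O molecules in a drop of
water, the cows in a herd); `has_component` relates a compound to the
segments of a partition (the atoms of a molecule, the bones of a skull).
Crossing mono-/multi-sortality of the parts at a granularity level with
whether their number is essential gives four kinds of complex entity —
flexible collectives (a portion of water), strict collectives (a pair of
kidneys), flexible compounds (a hand), strict compounds (a propanol
molecule). `mereocoll` is for ontology engineers and knowledge-representation
researchers who want this theory runnable rather than prose.

The package provides:

* **Finite instance models** (`buildModel`, `properParts`, `grainsOf`,
  `hasGrain`, `hasComponent`, `isValidPartition`, `isStrictCompound`) with
  the collective axioms — grain existence and mono-sortality,
  `x instance_of X_COLL ⟺ ∃y (y grain_of x) ∧ ∀g (g grain_of x → g
  instance_of X)` — evaluated exactly, and a four-way classifier
  (`classifyComplex`) whose mono-sortality is granularity- and
  specificity-dependent.
* **A small description logic** — Manchester-style parser/renderer,
  closed-world finite-model semantics (`classExtension`), and a simplicity
  checker (`isDLSafe`) for the OWL 2 rule that number restrictions must not
  use transitive roles (so `has_proper_part exactly 3 Atom` is flagged,
  `has_component exactly 3 Atom` is not).
* **A pattern compiler to OWL 2** (`collPattern`, `nCollPattern`,
  `moleculePattern`, `flexibleCompoundPattern`, `mixturePattern`,
  `emitOwl`, `readOwlFunctional`) and a regenerated propanol mixture
  ontology (`buildPropanolOntology`) with two disjoint isomer classes and
  three mixture representation variants.
* **A bounded-model subsumption oracle** (`boundedSubsumption`) that
  enumerates all acyclic typed models up to a size bound and returns
  either bounded evidence or a concrete countermodel — used to show that
  all three propanol mixture variants are classified as propanol
  collectives in the proper-part rewrite, and that the same inference
  provably fails when `has_grain`/`has_component` stay primitive.
* **Theorem checks** (`runPropertySuite`): irreflexivity, asymmetry and
  parthood-propagation of `has_grain` over 500 seeded random models, plus
  the galaxy/star/molecule non-transitivity witness.

## Worked example

```r
library(mereocoll)

ex <- makeExemplars()
for (nm in c("portion_of_water", "pair_of_kidneys", "hand",
             "propanol_molecule")) {
  e <- ex[[nm]]
  cat(sprintf("%-18s -> %s\n", nm,
              classifyComplex(e$model, ex$registry, e$focus, e$spec, e$level)))
}
#> portion_of_water   -> flexible_collective
#> pair_of_kidneys    -> strict_collective
#> hand               -> flexible_compound
#> propanol_molecule  -> strict_compound

w <- makeMolecule("H2O")
length(componentsAtLevel(w$model, w$registry, w$molecule, "Atom"))
#> [1] 3
isDLSafe("has_proper_part exactly 3 Atom")
#> [1] "number restriction 'has_proper_part exactly 3' uses non-simple role 'has_proper_part'"
```

The four exemplars land in the four categories, the water molecule has its
three atomic components, and the natural "molecule with exactly three
atoms" query is rejected as outside OWL DL because `has_proper_part` is
transitive — which is why the mixture patterns are rewritten through plain
parthood before a reasoner can classify them:

```r
ont <- buildPropanolOntology()
propanolSubsumptions(ont)[["Propanol_Mixture_3"]]
#> Subsumption holds up to size 4 (8202 models checked)

neg <- propanolNegativeControl()
neg
#> Subsumption fails: countermodel with 4 entities (witness 'e1')
neg@countermodel
#> FiniteModel: 4 entities, 4 direct-part edges
#>   e1 : N-Propanol_Molecule -> {e2, e3}
#>   e2 : Portion_of_Matter -> {e3}
#>   e3 : I-Propanol_Molecule -> {e4}
#>   e4 : N-Propanol_Molecule
```

The first verdict is the positive result: every mixture-of-fractions is a
propanol collective in every admissible model up to the bound. The second
is the negative control: with `has_grain`/`has_component` kept primitive —
all a DL reasoner can see of them — a countermodel exists, so the
subsumption is genuinely not derivable in that regime.

See `vignettes/mereological-design-patterns.Rmd` for the full account of
the semantics, the partition/overlap reading, the disjointness decision
behind the mixture entailment, and known limitations.

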