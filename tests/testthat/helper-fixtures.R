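# Shared helpers for the suite: tiny registries and models built in code.

chainModel <- function() {
  # a -> b -> c, three granularity levels
  buildModel(list(a = "Thing", b = "Thing", c = "Thing"),
             list(c("a", "b"), c("b", "c")))
}

fruitBasket <- function() {
  reg <- typeRegistry(c("Basket"),
                      isA = list(c("Apple", "Fruit"), c("Pear", "Fruit")))
  m <- buildModel(list(basket = "Basket", a = "Apple", p = "Pear"),
                  list(c("basket", "a"), c("basket", "p")))
  list(model = m, registry = reg)
}

waterSpec <- function()
  typeSpec("Water_Molecule",
           list(exactly("O-Atom", 1L), exactly("H-Atom", 2L)), closed = TRUE)

# both molecules in one model, for shared-extension checks
waterAndPeroxideModel <- function() {
  w <- makeMolecule("H2O", prefix = "w_")
  p <- makeMolecule("H2O2", prefix = "p_")
  buildModel(c(w$model@instanceOf, p$model@instanceOf),
             rbind(w$model@directPart, p$model@directPart))
}
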