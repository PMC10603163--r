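# Small in-code fixtures shared across tests.

compound_tbl <- function(ids, ctype = "metabolite", mass = NA_real_) {
  tibble::tibble(compound_id = ids, name = ids,
                 ctype = rep_len(ctype, length(ids)),
                 mass_da = rep_len(mass, length(ids)))
}

rxn <- function(id, layer, module = "m1", reversible = FALSE,
                reactants = character(0), products = character(0),
                catalysts = character(0), transporters = character(0)) {
  tibble::tibble(
    reaction_id = id, layer = layer, module = module, reversible = reversible,
    reactants = list(reactants), products = list(products),
    catalysts = list(catalysts), transporters = list(transporters)
  )
}

# toy 3-layer net: X produced in T, consumed in B; Y used twice within M
toy_net <- function() {
  compounds <- compound_tbl(c("A", "B1", "X", "Y", "Z"), mass = c(100, 200, 300, 400, 500))
  reactions <- dplyr::bind_rows(
    rxn("T:r1", "T", module = "elongation", reactants = "A", products = "X"),
    rxn("B:r1", "B", module = "protein_synthesis", reactants = "X", products = "B1"),
    rxn("M:r1", "M", module = "glycolysis", reactants = "Y", products = "Z"),
    rxn("M:r2", "M", module = "transport", reactants = "Z", products = "Y")
  )
  mlnet(compounds, reactions)
}

# a small synthetic configuration that keeps tests fast
small_config <- function(seed, ...) {
  synth_config(
    reactions = c(T = 60L, B = 60L, M = 80L),
    compounds = c(T = 150L, B = 150L, M = 160L),
    bridges = c(TM = 4L, MT = 5L, TB = 2L, BT = 2L, BM = 3L, MB = 3L),
    seed = seed,
    ...
  )
}

# random GPR expression over n_leaves protein ids, as text; depth-limited
random_gpr_text <- function(n_leaves, depth = 3) {
  leaves <- sprintf("g%02d", seq_len(n_leaves))
  build <- function(d, pool) {
    if (d == 0 || length(pool) == 1 || stats::runif(1) < 0.3) {
      return(sample(pool, 1))
    }
    k <- sample(2:min(3, length(pool)), 1)
    groups <- split(pool, sort(rep_len(seq_len(k), length(pool))))
    op <- sample(c(" and ", " or "), 1)
    paste0("(", paste(vapply(groups, function(g) build(d - 1, g), character(1)),
                      collapse = op), ")")
  }
  build(depth, leaves)
}
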