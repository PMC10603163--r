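aa <- sprintf("aa%02d", 1:20)

test_that("a monomer GPR yields one synthesis reaction and a catalyst link", {
  met <- rxn("M:r1", "M", reactants = "glc", products = "pyr")
  out <- build_biosynthesis_layer(met, c("M:r1" = "p1"), aa, "peptide")
  b <- out$reactions[out$reactions$layer == "B", ]
  expect_equal(nrow(b), 1L)
  expect_setequal(b$reactants[[1]], c(aa, "peptide"))
  expect_equal(b$products[[1]], "p1")
  m <- out$reactions[out$reactions$reaction_id == "M:r1", ]
  expect_equal(m$catalysts[[1]], "p1")
  expect_equal(m$layer, "M")   # catalyst attached in place, layer unchanged
})

test_that("an AND rule emits synthesis plus complex formation", {
  met <- rxn("M:r1", "M", reactants = "a", products = "b")
  out <- build_biosynthesis_layer(met, c("M:r1" = "(p1 and p2)"), aa, "peptide")
  b <- out$reactions[out$reactions$layer == "B", ]
  expect_equal(nrow(b), 3L)   # 2 synthesis + 1 formation
  form <- b[b$module == "complex_formation", ]
  expect_equal(form$products[[1]], "CPLX:p1_p2")
  expect_setequal(form$reactants[[1]], c("p1", "p2"))
  expect_equal(out$complexes$complex_id, "CPLX:p1_p2")
  m <- out$reactions[out$reactions$reaction_id == "M:r1", ]
  expect_equal(m$catalysts[[1]], "CPLX:p1_p2")
})

test_that("shared enzymes are synthesised once but attached everywhere", {
  mets <- dplyr::bind_rows(lapply(1:10, function(i) {
    rxn(sprintf("M:r%d", i), "M", reactants = "s", products = "t")
  }))
  gpr <- setNames(rep("p1", 10), mets$reaction_id)
  out <- build_biosynthesis_layer(mets, gpr, aa, "peptide")
  b <- out$reactions[out$reactions$layer == "B", ]
  expect_equal(nrow(b), 1L)   # deduplicated synthesis
  n_attach <- sum(vapply(out$reactions$catalysts, function(x) "p1" %in% x, logical(1)))
  expect_equal(n_attach, 10L)
  # without dedup: one synthesis copy per referencing reaction
  out2 <- build_biosynthesis_layer(mets, gpr, aa, "peptide", dedup = FALSE)
  expect_equal(sum(out2$reactions$layer == "B"), 10L)
})

test_that("biosynthesis building is idempotent and placeholder-complete", {
  gen <- generate_network(small_config(seed = 31))
  mets <- gen$net$reactions[gen$net$reactions$layer == "M", ]
  gpr <- setNames(gen$truth$gpr_table$gpr, gen$truth$gpr_table$reaction_id)
  out1 <- build_biosynthesis_layer(mets, gpr, aa, "peptide")
  out2 <- build_biosynthesis_layer(mets, gpr, aa, "peptide")
  expect_equal(out1$reactions$reaction_id, out2$reactions$reaction_id)
  syn <- out1$reactions[out1$reactions$module == "protein_synthesis", ]
  expect_true(all(vapply(syn$reactants, function(x) "peptide" %in% x, logical(1))))
  # every synthesis reaction is unique per protein
  expect_equal(anyDuplicated(unlist(syn$products)), 0L)
})

test_that("unresolved proteins are reported", {
  met <- rxn("M:r1", "M", reactants = "a", products = "b")
  expect_error(
    build_biosynthesis_layer(met, c("M:r1" = "p1 or px"), aa, "peptide",
                             known_proteins = "p1"),
    "px"
  )
  expect_error(
    build_biosynthesis_layer(met, c("M:zzz" = "p1"), aa, "peptide"),
    "M:zzz"
  )
})

test_that("TSV and BiGG JSON dialects load the same model", {
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "model.tsv")
  writeLines(c(
    "reaction_id\tmodule\treversible\treactants\tproducts\tgpr",
    "rxnA\tglycolysis\ttrue\tglc;atp\tg6p;adp\tp1 and p2",
    "rxnB\ttransport\tfalse\tglc_e\tglc\t"
  ), tsv)
  js <- file.path(dir, "model.json")
  jsonlite::write_json(list(reactions = list(
    list(id = "rxnA", metabolites = list(glc = -1, atp = -1, g6p = 1, adp = 1),
         gene_reaction_rule = "p1 and p2", subsystem = "glycolysis",
         lower_bound = -1000, upper_bound = 1000),
    list(id = "rxnB", metabolites = list(glc_e = -1, glc = 1),
         gene_reaction_rule = "", subsystem = "transport",
         lower_bound = 0, upper_bound = 1000)
  )), js, auto_unbox = TRUE)

  mt <- load_metabolic_model(tsv, "tsv")
  mj <- load_metabolic_model(js, "bigg_json")
  expect_equal(mt$reactions$reaction_id, mj$reactions$reaction_id)
  expect_equal(mt$reactions$module, mj$reactions$module)
  expect_equal(mt$reactions$reversible, mj$reactions$reversible)
  expect_equal(lapply(mt$reactions$reactants, sort), mj$reactions$reactants)
  expect_equal(lapply(mt$reactions$products, sort), mj$reactions$products)
  expect_equal(mt$gpr_map, mj$gpr_map)
  expect_true(all(mt$reactions$layer == "M"))
})

test_that("missing subsystem warns and falls back to unassigned", {
  dir <- withr::local_tempdir()
  js <- file.path(dir, "m.json")
  jsonlite::write_json(list(reactions = list(
    list(id = "r1", metabolites = list(a = -1, b = 1),
         lower_bound = 0, upper_bound = 1)
  )), js, auto_unbox = TRUE)
  expect_warning(m <- load_metabolic_model(js, "bigg_json"), "unassigned")
  expect_equal(m$reactions$module, "unassigned")
})

test_that("translation loader preserves module vocabulary and rejects duplicates", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "t.tsv")
  writeLines(c(
    "reaction_id\tmodule\treversible\treactants\tproducts\tcatalysts\ttransporters",
    "T:elo1\telongation\tfalse\tternary_cplx;rib_mrna\tpeptide;gdp\t\t",
    "T:ini1\tinitiation\tfalse\tmrna;ssu30\tic30\tif3\t"
  ), p)
  tr <- load_translation_reactions(p)
  expect_equal(tr$layer, c("T", "T"))
  expect_equal(tr$module, c("elongation", "initiation"))
  expect_gte(length(tr$reactants[[1]]) + length(tr$products[[1]]), 3L)
  writeLines(c(
    "reaction_id\tmodule\treversible\treactants\tproducts",
    "T:x\telongation\tfalse\ta\tb",
    "T:x\telongation\tfalse\tb\ta"
  ), p)
  expect_error(load_translation_reactions(p), "T:x")
})

test_that("complex masses sum distinct components once", {
  net <- mlnet(
    compound_tbl(c("c1", "c2", "cx", "cy", "cz"),
                 ctype = c("protein", "protein", "complex", "complex", "complex")),
    rxn("B:r1", "B", reactants = c("c1", "c2"), products = "cx") |>
      dplyr::bind_rows(rxn("B:r2", "B", reactants = "cx", products = "cy"),
                       rxn("B:r3", "B", reactants = "cy", products = "cz"))
  )
  masses <- tibble::tibble(compound_id = c("c1", "c2"), mass_da = c(100, 200))
  cmap <- tibble::tibble(
    complex_id = c("cx", "cy", "cz"),
    components = list(c("c1", "c2"), c("c1", "c1", "c2"), c("cx", "cy", "c1"))
  )
  out <- assign_masses(net, masses, cmap)
  m <- setNames(out$compounds$mass_da, out$compounds$compound_id)
  expect_equal(unname(m["cx"]), 300)
  expect_equal(unname(m["cy"]), 300)   # duplicate component counted once
  expect_equal(unname(m["cz"]), 300)   # nested: flat sum over unique leaves
  expect_length(attr(out, "unknown_mass"), 0)
})

test_that("nested complex masses equal brute-force unique-leaf summation", {
  set.seed(77)
  leaf_ids <- sprintf("L%02d", 1:12)
  leaf_mass <- setNames(runif(12, 50, 500), leaf_ids)
  # random two-level complex structure
  lower <- lapply(1:4, function(i) sample(leaf_ids, sample(2:4, 1)))
  names(lower) <- sprintf("CL%d", 1:4)
  upper <- lapply(1:3, function(i) {
    c(sample(names(lower), sample(1:2, 1)), sample(leaf_ids, sample(1:3, 1)))
  })
  names(upper) <- sprintf("CU%d", 1:3)
  cmap <- tibble::tibble(complex_id = c(names(lower), names(upper)),
                         components = c(lower, upper))
  all_ids <- c(leaf_ids, names(lower), names(upper))
  net <- mlnet(
    compound_tbl(all_ids),
    rxn("B:r1", "B", reactants = leaf_ids, products = c(names(lower), names(upper)))
  )
  out <- assign_masses(net, tibble::tibble(compound_id = leaf_ids, mass_da = unname(leaf_mass)), cmap)
  m <- setNames(out$compounds$mass_da, out$compounds$compound_id)
  # oracle: expand to unique leaves by repeated substitution
  flatten <- function(id) {
    comp <- cmap$components[cmap$complex_id == id]
    if (!length(comp)) return(id)
    unique(unlist(lapply(comp[[1]], flatten)))
  }
  for (id in c(names(lower), names(upper))) {
    expect_equal(unname(m[id]), sum(leaf_mass[flatten(id)]), info = id)
  }
})

test_that("cyclic complex composition is an error", {
  net <- mlnet(compound_tbl(c("u", "v")),
               rxn("B:r1", "B", reactants = "u", products = "v"))
  cmap <- tibble::tibble(complex_id = c("u", "v"), components = list("v", "u"))
  expect_error(assign_masses(net, tibble::tibble(compound_id = character(0), mass_da = numeric(0)), cmap),
               "cyclic")
})
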