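test_that("degree counts distinct reactions across all roles", {
  net <- toy_net()
  # Z: reactant of M:r2 and product of M:r1 -> 2 distinct reactions
  expect_equal(degree_of(net, "Z"), 2L)
  expect_equal(degree_of(net, "A"), 1L)
  expect_error(degree_of(net, "nope"), "unknown compound")

  # multiple roles within one reaction count once
  compounds <- compound_tbl(c("a", "b"))
  r <- dplyr::bind_rows(
    rxn("M:r1", "M", reactants = "a", products = c("a", "b"), catalysts = "a"),
    rxn("M:r2", "M", reactants = "a", products = "b"),
    rxn("M:r3", "M", reactants = "b", products = "a", catalysts = "a")
  )
  net2 <- mlnet(compounds, r)
  expect_equal(degree_of(net2, "a"), 3L)
})

test_that("degree sequences restrict to the selected layer", {
  compounds <- compound_tbl(c("x", "y", "z"))
  r <- dplyr::bind_rows(
    rxn("T:r1", "T", reactants = "x", products = "y"),
    rxn("T:r2", "T", reactants = "y", products = "x"),
    rxn("M:r1", "M", reactants = "x", products = "z"),
    rxn("M:r2", "M", reactants = "z", products = "x"),
    rxn("M:r3", "M", reactants = "x", products = "z", catalysts = "x"),
    rxn("M:r4", "M", reactants = "z", products = "x"),
    rxn("M:r5", "M", transporters = "x", products = "z")
  )
  net <- mlnet(compounds, r)
  dT <- degree_table(net, "T")
  dM <- degree_table(net, "M")
  expect_equal(dT$degree[dT$compound_id == "x"], 2L)
  expect_equal(dM$degree[dM$compound_id == "x"], 5L)
  expect_false("y" %in% dM$compound_id)   # y never reacts in M
  # one-reaction network: every participant has degree 1
  net1 <- mlnet(compound_tbl(c("p", "q", "s")),
                rxn("T:r1", "T", reactants = c("p", "q"), products = "s"))
  expect_equal(degree_sequence(net1), c(1L, 1L, 1L))
  expect_error(degree_sequence(net, "B"), "empty")
})

test_that("degree sum equals sum of distinct reaction participants", {
  gen <- generate_network(small_config(seed = 11))
  net <- gen$net
  total_deg <- sum(degree_sequence(net, "all"))
  e <- net_edges(net)
  participants <- e |>
    dplyr::distinct(reaction_id, compound_id) |>
    dplyr::count(reaction_id)
  expect_equal(total_deg, sum(participants$n))
})

test_that("planted hub degree matches a brute-force role-set scan", {
  gen <- generate_network(small_config(seed = 3))
  net <- gen$net
  hub <- degree_table(net, "all") |> dplyr::arrange(dplyr::desc(degree)) |> head(1)
  r <- net$reactions
  scan <- sum(vapply(seq_len(nrow(r)), function(i) {
    hub$compound_id %in% c(r$reactants[[i]], r$products[[i]],
                           r$catalysts[[i]], r$transporters[[i]])
  }, logical(1)))
  expect_equal(hub$degree, scan)
})

test_that("layer connectivity counts directed product-to-input sharing", {
  net <- toy_net()
  lc <- layer_connectivity_counts(net)
  get <- function(f, t) lc$n_compounds[lc$from == f & lc$to == t]
  expect_equal(get("T", "B"), 1L)   # X: product in T, reactant in B
  expect_equal(get("M", "M"), 2L)   # Y and Z each join two M reactions
  expect_equal(get("B", "T"), 0L)
  expect_equal(get("T", "M"), 0L)
})

test_that("connectivity counts are invariant to reaction insertion order", {
  gen <- generate_network(small_config(seed = 5))
  net <- gen$net
  lc1 <- layer_connectivity_counts(net)
  set.seed(99)
  net2 <- mlnet(net$compounds, net$reactions[sample(nrow(net$reactions)), ])
  lc2 <- layer_connectivity_counts(net2)
  expect_equal(lc1, lc2)
})

test_that("network is strictly bipartite with no dangling references", {
  gen <- generate_network(small_config(seed = 8))
  net <- gen$net
  e <- net_edges(net)
  expect_true(all(e$compound_id %in% net$compounds$compound_id))
  expect_true(all(e$reaction_id %in% net$reactions$reaction_id))
  # compound and reaction id namespaces never overlap
  expect_length(intersect(net$compounds$compound_id, net$reactions$reaction_id), 0)
  g <- as_igraph(net, directed = FALSE)
  cls <- igraph::V(g)$bipartite_class
  ends <- igraph::as_edgelist(g)
  cls_of <- setNames(cls, igraph::V(g)$name)
  expect_true(all(cls_of[ends[, 1]] != cls_of[ends[, 2]]))
  # constructor rejects dangling references
  expect_error(
    mlnet(compound_tbl("a"), rxn("M:r1", "M", reactants = "a", products = "ghost")),
    "unknown compound"
  )
})

test_that("TSV round trip preserves the network", {
  gen <- generate_network(small_config(seed = 13))
  net <- gen$net
  prefix <- file.path(withr::local_tempdir(), "net")
  paths <- write_network(net, prefix, format = "tsv")
  net2 <- read_network(paths[1], paths[2])
  expect_equal(sort(degree_sequence(net2)), sort(degree_sequence(net)))
  expect_equal(layer_connectivity_counts(net2), layer_connectivity_counts(net))
  expect_setequal(net2$compounds$compound_id, net$compounds$compound_id)
})

test_that("read_network reports malformed tables", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "bad.tsv")
  writeLines(c("reaction_id\tlayer\tmodule\treversible\treactants\tproducts\tcatalysts\ttransporters",
               "r1\tT\tm\tfalse\ta\tb\t\t",
               "r1\tT\tm\tfalse\tb\ta\t\t"), p)
  expect_error(read_network(p), "r1")
})

test_that("graph exports carry the bipartite attributes and full node/edge sets", {
  gen <- generate_network(small_config(seed = 21))
  net <- gen$net
  dir <- withr::local_tempdir()
  # exports are directed: a compound that is both input and output of one
  # reaction contributes two arcs
  in_mem_edges <- net_edges(net) |>
    dplyr::distinct(compound_id, reaction_id, direction) |>
    nrow()

  gml <- file.path(dir, "net.graphml")
  write_network(net, gml, format = "graphml")
  doc <- xml2::read_xml(gml)
  xml2::xml_ns_strip(doc)
  expect_length(xml2::xml_find_all(doc, "//node"),
                nrow(net$compounds) + nrow(net$reactions))
  expect_length(xml2::xml_find_all(doc, "//edge"), in_mem_edges)
  keys <- xml2::xml_attr(xml2::xml_find_all(doc, "//key"), "attr.name")
  expect_setequal(keys, c("bipartite_class", "layer", "module", "mass_da", "degree"))

  gexf <- file.path(dir, "net.gexf")
  write_network(net, gexf, format = "gexf")
  doc2 <- xml2::read_xml(gexf)
  xml2::xml_ns_strip(doc2)
  expect_length(xml2::xml_find_all(doc2, "//node"),
                nrow(net$compounds) + nrow(net$reactions))
  expect_length(xml2::xml_find_all(doc2, "//edge"), in_mem_edges)
  titles <- xml2::xml_attr(xml2::xml_find_all(doc2, "//attribute"), "title")
  expect_setequal(titles, c("bipartite_class", "layer", "module", "mass_da", "degree"))
})
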