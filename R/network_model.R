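#' Construct a multilayer bipartite reaction network
#'
#' The network couples three reaction layers — translation (`T`), polymer
#' biosynthesis (`B`) and metabolism (`M`) — in a single strictly bipartite
#' graph: one node class holds chemical compounds (metabolites, amino acids,
#' proteins, RNAs, complexes, ions, energy molecules and the generic peptide
#' placeholder), the other holds reactions. Edges exist only between a
#' compound and a reaction, with the compound's role (reactant, product,
#' catalyst or transporter) deciding direction: inputs point compound to
#' reaction, products point reaction to compound.
#'
#' @param compounds Tibble with columns `compound_id`, `name`, `ctype`
#'   (one of metabolite, amino_acid, energy_molecule, ion, protein, rna,
#'   complex, peptide_placeholder) and `mass_da` (positive or `NA` when
#'   unknown).
#' @param reactions Tibble with columns `reaction_id`, `layer` (`T`/`B`/`M`),
#'   `module`, `reversible` (logical) and list-columns `reactants`,
#'   `products`, `catalysts`, `transporters` of compound ids.
#' @return An object of class `mlnet`.
#' @export
mlnet <- function(compounds, reactions) {
  compounds <- as_tibble(compounds)
  reactions <- as_tibble(reactions)
  need_c <- c("compound_id", "name", "ctype", "mass_da")
  need_r <- c("reaction_id", "layer", "module", "reversible",
              "reactants", "products", "catalysts", "transporters")
  if (!all(need_c %in% names(compounds))) {
    abort(paste0("compounds must have columns: ", paste(need_c, collapse = ", ")))
  }
  if (!all(need_r %in% names(reactions))) {
    abort(paste0("reactions must have columns: ", paste(need_r, collapse = ", ")))
  }
  if (anyDuplicated(compounds$compound_id)) {
    abort(paste0("duplicate compound ids: ",
                 paste(unique(compounds$compound_id[duplicated(compounds$compound_id)]),
                       collapse = ", ")))
  }
  if (anyDuplicated(reactions$reaction_id)) {
    abort(paste0("duplicate reaction ids: ",
                 paste(unique(reactions$reaction_id[duplicated(reactions$reaction_id)]),
                       collapse = ", ")))
  }
  bad_layer <- setdiff(unique(reactions$layer), layer_codes)
  if (length(bad_layer)) abort(paste0("unknown layer code(s): ", paste(bad_layer, collapse = ", ")))
  bad_type <- setdiff(unique(compounds$ctype), compound_types)
  if (length(bad_type)) abort(paste0("unknown compound type(s): ", paste(bad_type, collapse = ", ")))
  if (any(!is.na(compounds$mass_da) & compounds$mass_da <= 0)) {
    abort("mass_da must be positive when known")
  }
  empty <- map_lgl(seq_len(nrow(reactions)), function(i) {
    length(reactions$reactants[[i]]) + length(reactions$products[[i]]) == 0L
  })
  if (any(empty)) {
    abort(paste0("reaction(s) with empty reactants and products: ",
                 paste(reactions$reaction_id[empty], collapse = ", ")))
  }
  referenced <- unique(unlist(reactions[c("reactants", "products", "catalysts", "transporters")],
                              use.names = FALSE))
  dangling <- setdiff(referenced, compounds$compound_id)
  if (length(dangling)) {
    abort(paste0("reactions reference unknown compound id(s): ",
                 paste(head(dangling, 10), collapse = ", ")))
  }
  structure(list(compounds = compounds, reactions = reactions), class = "mlnet")
}

#' @export
print.mlnet <- function(x, ...) {
  e <- net_edges(x)
  cat("<mlnet> multilayer bipartite reaction network\n")
  cat("  compounds:", nrow(x$compounds), " reactions:", nrow(x$reactions),
      " compound-reaction links:", nrow(distinct(e, .data$compound_id, .data$reaction_id)), "\n")
  tb <- table(x$reactions$layer)
  cat("  reactions per layer:",
      paste(sprintf("%s=%d", names(tb), as.integer(tb)), collapse = "  "), "\n")
  invisible(x)
}

#' Long edge table of a network
#'
#' One row per (reaction, compound, role) incidence. `direction` is `"in"`
#' for reactants, catalysts and transporters (they must be present for the
#' reaction to fire) and `"out"` for products.
#'
#' @param net An `mlnet`.
#' @return Tibble with columns `reaction_id`, `layer`, `module`,
#'   `reversible`, `compound_id`, `role`, `direction`.
#' @export
net_edges <- function(net) {
  stopifnot(inherits(net, "mlnet"))
  r <- net$reactions
  one_role <- function(role, dir) {
    ids <- r[[role]]
    nper <- lengths(ids)
    tibble(
      reaction_id = rep(r$reaction_id, nper),
      layer = rep(r$layer, nper),
      module = rep(r$module, nper),
      reversible = rep(r$reversible, nper),
      compound_id = unlist(ids, use.names = FALSE) %||% character(0),
      role = substr(role, 1, nchar(role) - 1L),
      direction = dir
    )
  }
  bind_rows(
    one_role("reactants", "in"),
    one_role("products", "out"),
    one_role("catalysts", "in"),
    one_role("transporters", "in")
  )
}

#' Layer membership of each compound
#'
#' A compound belongs to every layer in which at least one of its reactions
#' lies; cross-layer compounds are precisely what stitch the layers together.
#'
#' @param net An `mlnet`.
#' @return Tibble `compound_id`, `layers` (list-column of layer codes).
#' @export
compound_layers <- function(net) {
  net_edges(net) |>
    distinct(.data$compound_id, .data$layer) |>
    group_by(.data$compound_id) |>
    summarise(layers = list(sort(unique(.data$layer))), .groups = "drop")
}

#' Compound degree
#'
#' The degree of a compound is the number of *different* reactions that
#' involve it in any role (reactant, product, catalyst or transporter);
#' multiple roles within one reaction count once.
#'
#' @param net An `mlnet`.
#' @param compound_id Compound id (scalar).
#' @return Non-negative integer.
#' @export
degree_of <- function(net, compound_id) {
  stopifnot(length(compound_id) == 1L)
  if (!compound_id %in% net$compounds$compound_id) {
    abort(paste0("unknown compound id: ", compound_id))
  }
  e <- net_edges(net)
  n_distinct(e$reaction_id[e$compound_id == compound_id])
}

#' Per-compound degree table
#'
#' @param net An `mlnet`.
#' @param layer `"all"` (default) or one of `"T"`, `"B"`, `"M"`. With a layer
#'   the table is restricted to compounds participating in at least one
#'   reaction of that layer, and degree counts that layer's reactions only.
#' @return Tibble `compound_id`, `degree`, sorted by compound id. Compounds
#'   with no reaction at all appear with degree 0 only when `layer = "all"`.
#' @export
degree_table <- function(net, layer = "all") {
  stopifnot(inherits(net, "mlnet"))
  e <- net_edges(net)
  if (!identical(layer, "all")) {
    if (!layer %in% layer_codes) abort(paste0("unknown layer: ", layer))
    e <- filter(e, .data$layer == !!layer)
  }
  d <- e |>
    group_by(.data$compound_id) |>
    summarise(degree = n_distinct(.data$reaction_id), .groups = "drop")
  if (identical(layer, "all")) {
    d <- tibble(compound_id = net$compounds$compound_id) |>
      left_join(d, by = "compound_id") |>
      mutate(degree = ifelse(is.na(.data$degree), 0L, .data$degree))
  }
  arrange(d, .data$compound_id)
}

#' Degree sequence of a network or one of its layers
#'
#' @inheritParams degree_table
#' @return Integer vector of per-compound degrees.
#' @export
degree_sequence <- function(net, layer = "all") {
  d <- degree_table(net, layer)
  if (nrow(d) == 0L) abort("empty degree sequence: no compound matches the selection")
  as.integer(d$degree)
}

#' Cross- and within-layer compound connectivity counts
#'
#' For each ordered layer pair (X, Y), counts the distinct compounds that are
#' a product of at least one reaction in layer X and an input (reactant,
#' catalyst or transporter) of at least one reaction in layer Y. Self pairs
#' (X, X) instead count compounds participating in two or more distinct
#' reactions of that layer, i.e. compounds that join reactions within the
#' layer. The tallies are independent of one another.
#'
#' @param net An `mlnet`.
#' @return Tibble `from`, `to`, `n_compounds` covering all nine ordered pairs.
#' @export
layer_connectivity_counts <- function(net) {
  e <- net_edges(net)
  # reversible reactions can run backwards: every participant is then both
  # an input and an output of the reaction
  rev_extra <- e |>
    filter(.data$reversible, .data$role %in% c("reactant", "product")) |>
    mutate(direction = unname(c("in" = "out", "out" = "in")[.data$direction]))
  e <- bind_rows(e, rev_extra)
  outs <- e |> filter(.data$direction == "out") |> distinct(.data$compound_id, .data$layer)
  ins <- e |> filter(.data$direction == "in") |> distinct(.data$compound_id, .data$layer)
  grid <- tidyr::expand_grid(from = layer_codes, to = layer_codes)
  counts <- pmap(grid, function(from, to) {
    if (from == to) {
      within <- e |>
        filter(.data$layer == from) |>
        group_by(.data$compound_id) |>
        summarise(nr = n_distinct(.data$reaction_id), .groups = "drop")
      sum(within$nr >= 2L)
    } else {
      length(intersect(outs$compound_id[outs$layer == from],
                       ins$compound_id[ins$layer == to]))
    }
  })
  mutate(grid, n_compounds = as.integer(unlist(counts)))
}

#' Read a multilayer network from reaction and mass tables
#'
#' The reaction table is a TSV with header `reaction_id, layer, module,
#' reversible, reactants, products, catalysts, transporters`; the four role
#' fields are `;`-separated compound ids (empty allowed). The mass table is a
#' TSV `compound_id, name, ctype, mass_da` (`mass_da` may be `NA`). Compounds
#' referenced by reactions but absent from the mass table are created with
#' unknown mass and type `metabolite`.
#'
#' @param reaction_table_path,mass_table_path Paths to TSV files.
#' @return An `mlnet`.
#' @export
read_network <- function(reaction_table_path, mass_table_path = NULL) {
  rt <- readr::read_tsv(reaction_table_path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("reaction_id", "layer", "module", "reversible",
            "reactants", "products", "catalysts", "transporters")
  miss <- setdiff(need, names(rt))
  if (length(miss)) abort(paste0("reaction table missing column(s): ", paste(miss, collapse = ", ")))
  dup <- unique(rt$reaction_id[duplicated(rt$reaction_id)])
  if (length(dup)) abort(paste0("duplicate reaction_id in table: ", paste(dup, collapse = ", ")))
  reactions <- tibble(
    reaction_id = rt$reaction_id,
    layer = rt$layer,
    module = ifelse(is.na(rt$module) | !nzchar(rt$module), "unassigned", rt$module),
    reversible = tolower(rt$reversible) %in% c("true", "1", "yes"),
    reactants = split_ids(rt$reactants),
    products = split_ids(rt$products),
    catalysts = split_ids(rt$catalysts),
    transporters = split_ids(rt$transporters)
  )
  referenced <- unique(unlist(reactions[c("reactants", "products", "catalysts", "transporters")],
                              use.names = FALSE))
  if (!is.null(mass_table_path)) {
    mt <- readr::read_tsv(mass_table_path, show_col_types = FALSE,
                          col_types = readr::cols(
                            compound_id = readr::col_character(),
                            name = readr::col_character(),
                            ctype = readr::col_character(),
                            mass_da = readr::col_double()
                          ))
    compounds <- tibble(compound_id = mt$compound_id, name = mt$name,
                        ctype = mt$ctype, mass_da = mt$mass_da)
  } else {
    compounds <- tibble(compound_id = character(0), name = character(0),
                        ctype = character(0), mass_da = double(0))
  }
  extra <- setdiff(referenced, compounds$compound_id)
  if (length(extra)) {
    compounds <- bind_rows(compounds, tibble(
      compound_id = extra, name = extra, ctype = "metabolite", mass_da = NA_real_
    ))
  }
  mlnet(compounds, reactions)
}

#' Write a multilayer network
#'
#' `format = "tsv"` writes `<path>_reactions.tsv` and `<path>_compounds.tsv`
#' in the schemas read back by [read_network()] (round-trip stable up to row
#' order). `"graphml"` and `"gexf"` write a directed graph for Gephi-style
#' tools with node attributes `bipartite_class`, `layer`, `module`,
#' `mass_da` and `degree`.
#'
#' @param net An `mlnet`.
#' @param path Output path; for `"tsv"` a path prefix, otherwise the file.
#' @param format One of `"tsv"`, `"graphml"`, `"gexf"`.
#' @return The path(s) written, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv", "graphml", "gexf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    r <- net$reactions
    rt <- tibble(
      reaction_id = r$reaction_id, layer = r$layer, module = r$module,
      reversible = ifelse(r$reversible, "true", "false"),
      reactants = join_ids(r$reactants), products = join_ids(r$products),
      catalysts = join_ids(r$catalysts), transporters = join_ids(r$transporters)
    )
    p1 <- paste0(path, "_reactions.tsv")
    p2 <- paste0(path, "_compounds.tsv")
    readr::write_tsv(rt, p1)
    readr::write_tsv(net$compounds, p2)
    return(invisible(c(p1, p2)))
  }
  nodes <- network_node_table(net)
  edges <- net_edges(net) |>
    mutate(source = ifelse(.data$direction == "in", .data$compound_id, .data$reaction_id),
           target = ifelse(.data$direction == "in", .data$reaction_id, .data$compound_id)) |>
    distinct(.data$source, .data$target)
  txt <- if (format == "graphml") graphml_text(nodes, edges) else gexf_text(nodes, edges)
  writeLines(txt, path)
  invisible(path)
}

# shared node-attribute table for graph export
network_node_table <- function(net) {
  deg <- degree_table(net, "all")
  lay <- compound_layers(net)
  comp <- net$compounds |>
    left_join(deg, by = "compound_id") |>
    left_join(lay, by = "compound_id") |>
    mutate(layer_str = map_chr(.data$layers, function(l) paste(l %||% character(0), collapse = ";")))
  rdeg <- net_edges(net) |>
    group_by(.data$reaction_id) |>
    summarise(degree = n_distinct(.data$compound_id), .groups = "drop")
  bind_rows(
    tibble(id = comp$compound_id, bipartite_class = "compound",
           layer = comp$layer_str, module = "", mass_da = comp$mass_da,
           degree = comp$degree),
    tibble(id = net$reactions$reaction_id, bipartite_class = "reaction",
           layer = net$reactions$layer, module = net$reactions$module,
           mass_da = NA_real_,
           degree = rdeg$degree[match(net$reactions$reaction_id, rdeg$reaction_id)])
  )
}

graphml_text <- function(nodes, edges) {
  header <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
    "<key id=\"d0\" for=\"node\" attr.name=\"bipartite_class\" attr.type=\"string\"/>",
    "<key id=\"d1\" for=\"node\" attr.name=\"layer\" attr.type=\"string\"/>",
    "<key id=\"d2\" for=\"node\" attr.name=\"module\" attr.type=\"string\"/>",
    "<key id=\"d3\" for=\"node\" attr.name=\"mass_da\" attr.type=\"double\"/>",
    "<key id=\"d4\" for=\"node\" attr.name=\"degree\" attr.type=\"int\"/>",
    "<graph id=\"G\" edgedefault=\"directed\">"
  )
  mass <- ifelse(is.na(nodes$mass_da), "", sprintf("<data key=\"d3\">%g</data>", nodes$mass_da))
  node_lines <- sprintf(
    "<node id=\"%s\"><data key=\"d0\">%s</data><data key=\"d1\">%s</data><data key=\"d2\">%s</data>%s<data key=\"d4\">%d</data></node>",
    xml_escape(nodes$id), nodes$bipartite_class, xml_escape(nodes$layer),
    xml_escape(nodes$module), mass, as.integer(nodes$degree)
  )
  edge_lines <- sprintf("<edge source=\"%s\" target=\"%s\"/>",
                        xml_escape(edges$source), xml_escape(edges$target))
  c(header, node_lines, edge_lines, "</graph>", "</graphml>")
}

gexf_text <- function(nodes, edges) {
  header <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<gexf xmlns=\"http://www.gexf.net/1.2draft\" version=\"1.2\">",
    "<graph defaultedgetype=\"directed\">",
    "<attributes class=\"node\">",
    "<attribute id=\"0\" title=\"bipartite_class\" type=\"string\"/>",
    "<attribute id=\"1\" title=\"layer\" type=\"string\"/>",
    "<attribute id=\"2\" title=\"module\" type=\"string\"/>",
    "<attribute id=\"3\" title=\"mass_da\" type=\"double\"/>",
    "<attribute id=\"4\" title=\"degree\" type=\"integer\"/>",
    "</attributes>",
    "<nodes>"
  )
  mass <- ifelse(is.na(nodes$mass_da), "",
                 sprintf("<attvalue for=\"3\" value=\"%g\"/>", nodes$mass_da))
  node_lines <- sprintf(
    "<node id=\"%s\" label=\"%s\"><attvalues><attvalue for=\"0\" value=\"%s\"/><attvalue for=\"1\" value=\"%s\"/><attvalue for=\"2\" value=\"%s\"/>%s<attvalue for=\"4\" value=\"%d\"/></attvalues></node>",
    xml_escape(nodes$id), xml_escape(nodes$id), nodes$bipartite_class,
    xml_escape(nodes$layer), xml_escape(nodes$module), mass, as.integer(nodes$degree)
  )
  edge_lines <- sprintf("<edge id=\"e%d\" source=\"%s\" target=\"%s\"/>",
                        seq_len(nrow(edges)) - 1L,
                        xml_escape(edges$source), xml_escape(edges$target))
  c(header, node_lines, "</nodes>", "<edges>", edge_lines, "</edges>",
    "</graph>", "</gexf>")
}

#' Convert a network to an igraph graph
#'
#' Directed conversion uses the role semantics (inputs point into the
#' reaction, products out of it); reversible reactions are expanded to both
#' orientations so that directed analyses see both directions without
#' inflating compound degree.
#'
#' @param net An `mlnet`.
#' @param directed Build a directed graph (default `TRUE`).
#' @return An `igraph` object with vertex attributes `bipartite_class`,
#'   `layer` and `module`.
#' @export
as_igraph <- function(net, directed = TRUE) {
  nodes <- network_node_table(net)
  e <- net_edges(net)
  if (directed) {
    rev_extra <- e |>
      filter(.data$reversible, .data$role %in% c("reactant", "product")) |>
      mutate(direction = unname(c("in" = "out", "out" = "in")[.data$direction]))
    e <- bind_rows(e, rev_extra)
  }
  el <- e |>
    mutate(source = ifelse(.data$direction == "in", .data$compound_id, .data$reaction_id),
           target = ifelse(.data$direction == "in", .data$reaction_id, .data$compound_id)) |>
    distinct(.data$source, .data$target)
  g <- igraph::graph_from_data_frame(
    el, directed = directed,
    vertices = data.frame(name = nodes$id, bipartite_class = nodes$bipartite_class,
                          layer = nodes$layer, module = nodes$module,
                          stringsAsFactors = FALSE)
  )
  g
}
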