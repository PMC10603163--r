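#' Contract reactions into module nodes
#'
#' Collapses all reactions carrying one module label into a single module
#' node, and absorbs every compound whose incident reactions all share one
#' module into that module node. Compounds spanning two or more modules
#' survive as individual nodes with edges to each module they touch, so the
#' contracted network is still bipartite: module nodes on one side,
#' bridging compounds on the other. Edge direction is inherited from the
#' underlying roles — compound \eqn{\to} module when the compound is an
#' input (reactant/catalyst/transporter) of any reaction in the module,
#' module \eqn{\to} compound when it is a product of any; reversible
#' reactions contribute both directions.
#'
#' @param net An `mlnet`; every reaction must carry a module label.
#' @param layers Layers to include (default `c("T", "M")`, the
#'   translation–metabolism contraction; add `"B"` to include the polymer
#'   biosynthesis layer).
#' @return A `contracted_net`: list with `module_nodes` (character),
#'   `bridge_compounds` (character) and `edges` (tibble `from`, `to`).
#' @export
contract_by_module <- function(net, layers = c("T", "M")) {
  e <- net_edges(net) |> filter(.data$layer %in% !!layers)
  if (nrow(e) == 0L) abort("no reactions in the selected layers")
  if (any(is.na(e$module) | !nzchar(e$module))) {
    abort("unlabeled reaction(s): every reaction needs a module label before contraction")
  }
  rev_extra <- e |>
    filter(.data$reversible, .data$role %in% c("reactant", "product")) |>
    mutate(direction = unname(c("in" = "out", "out" = "in")[.data$direction]))
  e2 <- bind_rows(e, rev_extra)

  mods_per_compound <- e |>
    distinct(.data$compound_id, .data$module) |>
    group_by(.data$compound_id) |>
    summarise(n_mod = n(), .groups = "drop")
  bridges <- mods_per_compound$compound_id[mods_per_compound$n_mod >= 2L]

  edges <- e2 |>
    filter(.data$compound_id %in% bridges) |>
    mutate(from = ifelse(.data$direction == "in", .data$compound_id, .data$module),
           to = ifelse(.data$direction == "in", .data$module, .data$compound_id)) |>
    distinct(.data$from, .data$to)

  structure(
    list(module_nodes = sort(unique(e$module)),
         bridge_compounds = sort(bridges),
         edges = edges),
    class = "contracted_net"
  )
}

#' @export
print.contracted_net <- function(x, ...) {
  cat(sprintf("<contracted_net> %d module node(s), %d bridge compound(s), %d directed edge(s)\n",
              length(x$module_nodes), length(x$bridge_compounds), nrow(x$edges)))
  invisible(x)
}

#' Betweenness centrality
#'
#' \eqn{BC(n) = \sum_{s \ne n \ne t} \sigma_{st}(n) / \sigma_{st}}: the
#' number of times a node sits on a shortest path between two other nodes,
#' counting all shortest paths of a pair fractionally and summing over
#' ordered pairs in directed mode. All edges have unit length; unreachable
#' pairs contribute zero; values are unnormalised by default.
#'
#' @param graph A `contracted_net`, an `mlnet` (converted with reversible
#'   reactions expanded to both orientations), an igraph object, or an edge
#'   tibble with columns `from`, `to`.
#' @param directed Treat edges as directed (default `TRUE`). Undirected mode
#'   counts each unordered pair once.
#' @param normalized Rescale by the number of possible pairs.
#' @return Tibble `node_id`, `bc`, sorted by decreasing centrality.
#' @export
betweenness_centrality <- function(graph, directed = TRUE, normalized = FALSE) {
  g <- if (igraph::is_igraph(graph)) {
    graph
  } else if (inherits(graph, "mlnet")) {
    as_igraph(graph, directed = directed)
  } else if (inherits(graph, "contracted_net")) {
    igraph::graph_from_data_frame(graph$edges, directed = TRUE)
  } else {
    igraph::graph_from_data_frame(as_tibble(graph), directed = directed)
  }
  if (!directed && igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
  bc <- igraph::betweenness(g, directed = directed, normalized = normalized)
  tibble(node_id = names(bc), bc = as.numeric(bc)) |>
    arrange(dplyr::desc(.data$bc), .data$node_id)
}
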