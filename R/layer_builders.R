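#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over protein ids in which `and` denotes
#' the joint requirement of complex subunits and `or` denotes alternative
#' isozymes, e.g. `"(b0001 and b0002) or b0003"`. Keywords are
#' case-insensitive; parentheses group; `not` never occurs in GPRs.
#'
#' @param text GPR string.
#' @return A `gpr_expr`: nested list with `op` one of `"id"`, `"and"`, `"or"`
#'   and either `id` (leaf) or `args` (list of sub-expressions).
#' @export
parse_gpr <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- gpr_tokens(text)
  if (nrow(toks) == 0L) abort("empty GPR expression")
  st <- new.env(parent = emptyenv())
  st$i <- 1L
  expr <- gpr_parse_or(toks, st)
  if (st$i <= nrow(toks)) {
    abort(sprintf("GPR parse error at position %d: unexpected '%s'",
                  toks$pos[st$i], toks$tok[st$i]))
  }
  structure(expr, class = "gpr_expr")
}

gpr_tokens <- function(text) {
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1L) return(tibble(tok = character(0), pos = integer(0)))
  tok <- regmatches(text, gregexpr(pat, text))[[1]]
  tibble(tok = tok, pos = as.integer(m))
}

gpr_peek <- function(toks, st) if (st$i <= nrow(toks)) toks$tok[st$i] else NA_character_

gpr_parse_or <- function(toks, st) {
  args <- list(gpr_parse_and(toks, st))
  while (!is.na(gpr_peek(toks, st)) && tolower(gpr_peek(toks, st)) == "or") {
    st$i <- st$i + 1L
    args <- c(args, list(gpr_parse_and(toks, st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
}

gpr_parse_and <- function(toks, st) {
  args <- list(gpr_parse_atom(toks, st))
  while (!is.na(gpr_peek(toks, st)) && tolower(gpr_peek(toks, st)) == "and") {
    st$i <- st$i + 1L
    args <- c(args, list(gpr_parse_atom(toks, st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(toks, st) {
  tk <- gpr_peek(toks, st)
  if (is.na(tk)) abort("GPR parse error: unexpected end of expression (empty clause)")
  pos <- toks$pos[st$i]
  if (tk == "(") {
    st$i <- st$i + 1L
    inner <- gpr_parse_or(toks, st)
    if (is.na(gpr_peek(toks, st)) || gpr_peek(toks, st) != ")") {
      abort(sprintf("GPR parse error: unbalanced parenthesis opened at position %d", pos))
    }
    st$i <- st$i + 1L
    return(inner)
  }
  if (tk == ")" || tolower(tk) %in% c("and", "or")) {
    abort(sprintf("GPR parse error at position %d: unexpected '%s' (empty clause)", pos, tk))
  }
  st$i <- st$i + 1L
  list(op = "id", id = tk)
}

# evaluate a gpr expression under a truth assignment (named logical vector)
gpr_eval <- function(expr, assignment) {
  switch(expr$op,
    id = isTRUE(unname(assignment[expr$id])),
    and = all(map_lgl(expr$args, gpr_eval, assignment = assignment)),
    or = any(map_lgl(expr$args, gpr_eval, assignment = assignment))
  )
}

gpr_leaves <- function(expr) {
  if (expr$op == "id") return(expr$id)
  unique(unlist(lapply(expr$args, gpr_leaves)))
}

#' Enumerate alternative enzymes of a GPR expression
#'
#' Expands the rule to disjunctive normal form: each `or`-alternative becomes
#' one enzyme set whose members are the `and`-ed proteins (a singleton set is
#' a monomeric enzyme, a larger set a hetero-complex). Redundant alternatives
#' are removed so the result equals the minimal satisfying protein sets of
#' the rule: duplicates are dropped and any set containing another set as a
#' subset is absorbed.
#'
#' @param expr A `gpr_expr` from [parse_gpr()].
#' @return List of character vectors (each sorted), sorted for determinism.
#' @export
enzyme_alternatives <- function(expr) {
  sets <- gpr_dnf(expr)
  sets <- unique(lapply(sets, function(s) sort(unique(s))))
  # absorption: drop supersets of other alternatives
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i != j && keep[i] && all(sets[[j]] %in% sets[[i]]) &&
          length(sets[[j]]) < length(sets[[i]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  sets <- sets[keep]
  sets[order(map_chr(sets, paste, collapse = "\r"))]
}

gpr_dnf <- function(expr) {
  switch(expr$op,
    id = list(expr$id),
    or = do.call(c, lapply(expr$args, gpr_dnf)),
    and = {
      parts <- lapply(expr$args, gpr_dnf)
      Reduce(function(acc, nxt) {
        out <- list()
        for (a in acc) for (b in nxt) out <- c(out, list(c(a, b)))
        out
      }, parts)
    }
  )
}

#' Build the polymer biosynthesis layer from GPR rules
#'
#' The biosynthesis layer links metabolism back to translation: every enzyme
#' that catalyses a metabolic reaction must itself be synthesised from amino
#' acids by the translation machinery. For each protein appearing in any
#' enzyme alternative, one non-stoichiometric synthesis reaction is emitted
#' (`amino acids + peptide placeholder -> protein`); for each multi-member
#' alternative one complex-formation reaction (`members -> complex`) with a
#' deterministic complex id `CPLX:<sorted members joined by _>`. The
#' catalysing protein or complex is attached as a catalyst of the metabolic
#' reaction in place (the metabolic reaction keeps layer `M`). Synthesis and
#' formation reactions are deduplicated across metabolic reactions so that
#' shared enzymes do not inflate biosynthesis-layer degree; set
#' `dedup = FALSE` to emit one copy per referencing metabolic reaction.
#'
#' @param metabolic_reactions Reaction tibble (layer `M`) as in [mlnet()].
#' @param gpr_map Named character vector or list mapping metabolic
#'   `reaction_id` to a GPR string.
#' @param amino_acid_ids Character vector of amino-acid compound ids used as
#'   reactants of every synthesis reaction (composition is not tracked).
#' @param peptide_placeholder_id Id of the generic incomplete-peptide node.
#' @param known_proteins Optional character vector; when supplied, GPR leaves
#'   outside it raise an unresolved-protein error.
#' @param dedup Deduplicate synthesis/formation reactions (default `TRUE`).
#' @return List with `reactions` (the updated metabolic reactions followed by
#'   the new layer-`B` reactions), `proteins`, `complexes` (tibble
#'   `complex_id`, `components`).
#' @export
build_biosynthesis_layer <- function(metabolic_reactions, gpr_map,
                                     amino_acid_ids, peptide_placeholder_id,
                                     known_proteins = NULL, dedup = TRUE) {
  gpr_map <- gpr_map[!is.na(gpr_map) & nzchar(gpr_map)]
  bad <- setdiff(names(gpr_map), metabolic_reactions$reaction_id)
  if (length(bad)) {
    abort(paste0("gpr_map names are not metabolic reaction ids: ",
                 paste(head(bad, 10), collapse = ", ")))
  }
  alts_by_rxn <- lapply(gpr_map, function(s) enzyme_alternatives(parse_gpr(s)))
  all_proteins <- unique(unlist(alts_by_rxn, use.names = FALSE))
  if (!is.null(known_proteins)) {
    unknown <- setdiff(all_proteins, known_proteins)
    if (length(unknown)) {
      abort(paste0("GPR references unresolved protein id(s): ",
                   paste(unknown, collapse = ", ")))
    }
  }

  mk_syn <- function(protein, suffix = "") tibble(
    reaction_id = paste0("B:SYN_", protein, suffix), layer = "B",
    module = "protein_synthesis", reversible = FALSE,
    reactants = list(c(amino_acid_ids, peptide_placeholder_id)),
    products = list(protein), catalysts = list(character(0)),
    transporters = list(character(0))
  )
  cplx_id <- function(members) paste0("CPLX:", paste(sort(members), collapse = "_"))
  mk_form <- function(members, suffix = "") tibble(
    reaction_id = paste0("B:FORM_", paste(sort(members), collapse = "_"), suffix),
    layer = "B", module = "complex_formation", reversible = FALSE,
    reactants = list(sort(members)), products = list(cplx_id(members)),
    catalysts = list(character(0)), transporters = list(character(0))
  )

  new_reactions <- list()
  complexes <- list()
  reactions <- metabolic_reactions
  idx <- match(names(alts_by_rxn), reactions$reaction_id)
  for (k in seq_along(alts_by_rxn)) {
    alts <- alts_by_rxn[[k]]
    cats <- character(0)
    for (a in alts) {
      if (dedup) {
        for (p in a) new_reactions[[paste0("S", p)]] <- mk_syn(p)
      } else {
        for (p in a) {
          key <- paste0("S", p, "@", names(alts_by_rxn)[k])
          new_reactions[[key]] <- mk_syn(p, paste0("@", names(alts_by_rxn)[k]))
        }
      }
      if (length(a) > 1L) {
        id <- cplx_id(a)
        complexes[[id]] <- a
        key <- if (dedup) paste0("F", id) else paste0("F", id, "@", names(alts_by_rxn)[k])
        suffix <- if (dedup) "" else paste0("@", names(alts_by_rxn)[k])
        new_reactions[[key]] <- mk_form(a, suffix)
        cats <- c(cats, id)
      } else {
        cats <- c(cats, a)
      }
    }
    i <- idx[k]
    reactions$catalysts[[i]] <- unique(c(reactions$catalysts[[i]], cats))
  }
  list(
    reactions = bind_rows(reactions, bind_rows(unname(new_reactions))),
    proteins = sort(all_proteins),
    complexes = tibble(
      complex_id = names(complexes),
      components = unname(lapply(complexes, sort))
    )
  )
}

#' Load a genome-scale metabolic model
#'
#' Two dialects: `"tsv"` reads the package's reaction-table schema with an
#' extra `gpr` column; `"bigg_json"` reads the BiGG-style JSON subset
#' (`reactions[].id`, `.metabolites` (negative coefficient = reactant,
#' positive = product), `.gene_reaction_rule`, `.subsystem`,
#' `.lower_bound`/`.upper_bound` — a negative lower bound together with a
#' positive upper bound marks the reaction reversible).
#'
#' @param path Model file.
#' @param dialect `"tsv"` or `"bigg_json"`.
#' @return List with `reactions` (layer `M` tibble; module from the model's
#'   subsystem, `"unassigned"` with a warning when missing) and `gpr_map`
#'   (named character vector of verbatim GPR strings).
#' @export
load_metabolic_model <- function(path, dialect = c("tsv", "bigg_json")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    rt <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
    need <- c("reaction_id", "module", "reversible", "reactants", "products")
    miss <- setdiff(need, names(rt))
    if (length(miss)) abort(paste0("metabolic TSV missing column(s): ", paste(miss, collapse = ", ")))
    if (any(is.na(rt$module) | !nzchar(rt$module))) {
      warn("metabolic reactions without subsystem assigned module 'unassigned'")
    }
    reactions <- tibble(
      reaction_id = rt$reaction_id, layer = "M",
      module = ifelse(is.na(rt$module) | !nzchar(rt$module), "unassigned", rt$module),
      reversible = tolower(rt$reversible) %in% c("true", "1", "yes"),
      reactants = split_ids(rt$reactants), products = split_ids(rt$products),
      catalysts = split_ids(if ("catalysts" %in% names(rt)) rt$catalysts else NA),
      transporters = split_ids(if ("transporters" %in% names(rt)) rt$transporters else NA)
    )
    gpr <- if ("gpr" %in% names(rt)) ifelse(is.na(rt$gpr), "", rt$gpr) else rep("", nrow(rt))
    gpr_map <- setNames(gpr, rt$reaction_id)
  } else {
    m <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (is.null(m$reactions)) abort("bigg_json model has no 'reactions' field")
    rx <- m$reactions
    subsys <- map_chr(rx, function(r) r$subsystem %||% "")
    if (any(!nzchar(subsys))) {
      warn("metabolic reactions without subsystem assigned module 'unassigned'")
    }
    reactions <- tibble(
      reaction_id = map_chr(rx, function(r) r$id),
      layer = "M",
      module = ifelse(nzchar(subsys), subsys, "unassigned"),
      reversible = map_lgl(rx, function(r) {
        (r$lower_bound %||% 0) < 0 && (r$upper_bound %||% 0) > 0
      }),
      reactants = lapply(rx, function(r) {
        mets <- unlist(r$metabolites)
        sort(names(mets)[mets < 0])
      }),
      products = lapply(rx, function(r) {
        mets <- unlist(r$metabolites)
        sort(names(mets)[mets > 0])
      }),
      catalysts = rep(list(character(0)), length(rx)),
      transporters = rep(list(character(0)), length(rx))
    )
    gpr_map <- setNames(map_chr(rx, function(r) r$gene_reaction_rule %||% ""),
                        reactions$reaction_id)
  }
  dup <- unique(reactions$reaction_id[duplicated(reactions$reaction_id)])
  if (length(dup)) abort(paste0("duplicate metabolic reaction id(s): ", paste(dup, collapse = ", ")))
  list(reactions = reactions, gpr_map = gpr_map[nzchar(gpr_map)])
}

#' Load translation-layer reactions
#'
#' Reads the reaction-table TSV schema and tags every reaction with layer
#' `T`. Module labels (elongation, initiation, termination, machinery
#' biosynthesis, starvation response, plus assembly/charging labels) are
#' preserved verbatim; missing labels become `"unassigned"`.
#'
#' @param path Reaction-table TSV.
#' @return Reaction tibble with `layer = "T"`.
#' @export
load_translation_reactions <- function(path) {
  rt <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("reaction_id", "module", "reversible", "reactants", "products")
  miss <- setdiff(need, names(rt))
  if (length(miss)) abort(paste0("translation table missing column(s): ", paste(miss, collapse = ", ")))
  dup <- unique(rt$reaction_id[duplicated(rt$reaction_id)])
  if (length(dup)) abort(paste0("duplicate translation reaction id(s): ", paste(dup, collapse = ", ")))
  tibble(
    reaction_id = rt$reaction_id, layer = "T",
    module = ifelse(is.na(rt$module) | !nzchar(rt$module), "unassigned", rt$module),
    reversible = tolower(rt$reversible) %in% c("true", "1", "yes"),
    reactants = split_ids(rt$reactants), products = split_ids(rt$products),
    catalysts = split_ids(if ("catalysts" %in% names(rt)) rt$catalysts else NA),
    transporters = split_ids(if ("transporters" %in% names(rt)) rt$transporters else NA)
  )
}

#' Assign molecular masses, resolving complexes
#'
#' Leaf compounds take their mass from the table. A complex weighs the sum
#' of the masses of its *distinct* components — each component counts once
#' regardless of copy number, since assembly stoichiometry is not tracked.
#' Nested complexes are resolved recursively down to unique leaves. Compounds
#' whose mass cannot be resolved (including the peptide placeholder) are left
#' `NA` and reported via the `unknown_mass` attribute.
#'
#' @param net An `mlnet`.
#' @param mass_table Tibble `compound_id`, `mass_da` (extra columns ignored).
#' @param complex_components_map Optional tibble `complex_id`, `components`
#'   (list-column) describing complex composition.
#' @return The network with `mass_da` filled in; attribute `unknown_mass`
#'   holds the ids still unresolved.
#' @export
assign_masses <- function(net, mass_table, complex_components_map = NULL) {
  mass <- setNames(mass_table$mass_da, mass_table$compound_id)
  comp_map <- list()
  if (!is.null(complex_components_map) && nrow(complex_components_map) > 0L) {
    comp_map <- setNames(complex_components_map$components,
                         complex_components_map$complex_id)
  }
  leaves_of <- function(id, stack = character(0)) {
    if (id %in% stack) {
      abort(paste0("cyclic complex composition: ", paste(c(stack, id), collapse = " -> ")))
    }
    if (is.null(comp_map[[id]])) return(id)
    unique(unlist(lapply(unique(comp_map[[id]]), leaves_of, stack = c(stack, id))))
  }
  resolve <- function(id) {
    leaves <- leaves_of(id)
    vals <- unname(mass[leaves])
    if (length(vals) == 0L || anyNA(vals)) NA_real_ else sum(vals)
  }
  out <- net$compounds
  resolved <- map_dbl(out$compound_id, resolve)
  out$mass_da <- ifelse(is.na(resolved), out$mass_da, resolved)
  net$compounds <- out
  attr(net, "unknown_mass") <- out$compound_id[is.na(out$mass_da)]
  net
}
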