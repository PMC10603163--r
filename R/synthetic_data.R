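#' Configuration for the synthetic multilayer network generator
#'
#' Defaults emulate the curated Escherichia coli translation–biosynthesis–
#' metabolism network: per-layer reaction counts 1433 (T), 1455 (B) and
#' 2085 (M); per-layer heavy-tailed compound degree distributions with the
#' continuous-fit exponents observed for each layer (T 3.526, B 3.470,
#' M 2.290); sparse directed cross-layer compound sharing of the same order
#' as the curated counts (25 T-to-M and 27 M-to-T); and a trimodal
#' lognormal mass mixture centred near 240 Da (metabolites), 4e4 Da
#' (polypeptides) and 2e6 Da (ribonucleoprotein assemblies) with enforced
#' empty log-mass gaps between the modes. Per-layer compound counts are set
#' so that every reaction can draw at least two participants and the total
#' node count is of the same order as the curated network.
#'
#' @param reactions Named integer vector `c(T=, B=, M=)` of reaction counts.
#' @param compounds Named integer vector of per-layer compound counts.
#' @param degree_family Per-layer list: each element
#'   `list(family = "power_law", gamma =)` or
#'   `list(family = "exponential", lambda =)`, with optional `k_min`.
#' @param bridges Named integer vector of directed bridge-compound counts,
#'   names `"XY"` meaning X-to-Y, e.g. `c(TM = 25, MT = 27, ...)`.
#' @param mass_mixture Tibble/list of lognormal components with fields
#'   `median_da`, `sd_log10`, `weight` (weights sum to 1) and `ctype`.
#' @param mass_gaps List of `c(low, high)` log10-Da intervals kept empty by
#'   rejection sampling.
#' @param modules Per-layer character vectors of module labels.
#' @param reversible_fraction Fraction of within-layer reactions marked
#'   reversible (bridge attachment avoids reversible reactions so planted
#'   cross-layer counts stay exact).
#' @param n_amino_acids Amino-acid alphabet size for the GPR exercise table.
#' @param protein_pool,complex_fraction,isozyme_fraction GPR table mixture.
#' @param gpr_coverage Fraction of metabolic reactions given a GPR rule.
#' @param seed Mandatory integer seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(reactions = c(T = 1433L, B = 1455L, M = 2085L),
                         compounds = c(T = 2800L, B = 2800L, M = 2600L),
                         degree_family = list(
                           T = list(family = "power_law", gamma = 3.526),
                           B = list(family = "power_law", gamma = 3.470),
                           M = list(family = "power_law", gamma = 2.290)
                         ),
                         bridges = c(TM = 25L, MT = 27L, TB = 15L, BT = 15L,
                                     BM = 30L, MB = 30L),
                         mass_mixture = tibble(
                           median_da = c(240, 4e4, 2e6),
                           sd_log10 = c(0.35, 0.35, 0.25),
                           weight = c(0.55, 0.33, 0.12),
                           ctype = c("metabolite", "protein", "complex")
                         ),
                         mass_gaps = list(c(3.3, 3.7), c(5.3, 5.7)),
                         modules = list(
                           T = c("initiation", "elongation", "termination",
                                 "machinery_biosynthesis", "starvation_response",
                                 "trna_charging"),
                           B = c("protein_synthesis", "complex_formation"),
                           M = c("transport", "glycolysis", "tca_cycle",
                                 "amino_acid_metabolism", "nucleotide_metabolism",
                                 "cofactor_synthesis")
                         ),
                         reversible_fraction = 0.25,
                         n_amino_acids = 20L,
                         protein_pool = 300L,
                         complex_fraction = 0.3,
                         isozyme_fraction = 0.2,
                         gpr_coverage = 0.7,
                         seed = NULL) {
  if (is.null(seed)) abort("synth_config: seed is mandatory")
  # tolerate JSON-derived lists for the count fields
  reactions <- vapply(as.list(reactions), as.integer, integer(1))
  compounds <- vapply(as.list(compounds), as.integer, integer(1))
  bridges <- vapply(as.list(bridges), as.integer, integer(1))
  if (is.matrix(mass_gaps)) mass_gaps <- asplit(mass_gaps, 1)
  mass_mixture <- as_tibble(mass_mixture)
  stopifnot(all(reactions > 0), all(compounds > 0),
            abs(sum(mass_mixture$weight) - 1) < 1e-8)
  structure(
    list(reactions = reactions, compounds = compounds,
         degree_family = degree_family, bridges = bridges,
         mass_mixture = mass_mixture, mass_gaps = mass_gaps,
         modules = modules, reversible_fraction = reversible_fraction,
         n_amino_acids = n_amino_acids, protein_pool = protein_pool,
         complex_fraction = complex_fraction,
         isozyme_fraction = isozyme_fraction, gpr_coverage = gpr_coverage,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Sample degrees from a power-law distribution
#'
#' Continuous domain uses the closed-form inverse CDF
#' \eqn{k = k_{min} (1-u)^{-1/(\gamma-1)}}; discrete domain inverts the
#' zeta-distribution CDF built by direct summation (values beyond the table
#' limit are clamped, affecting a negligible fraction of draws).
#'
#' @param gamma Exponent, `> 1`.
#' @param k_min Lower cutoff.
#' @param n Sample size.
#' @param domain `"discrete"` or `"continuous"`.
#' @param seed Integer seed.
#' @return Numeric (continuous) or integer (discrete) vector of length `n`.
#' @export
sample_power_law_degrees <- function(gamma, k_min = 1, n,
                                     domain = c("discrete", "continuous"),
                                     seed = 1L) {
  domain <- match.arg(domain)
  if (gamma <= 1) abort("power-law exponent must exceed 1")
  set.seed(seed)
  u <- runif(n)
  if (domain == "continuous") return(plaw_inverse_cdf(u, gamma, k_min))
  k_max <- 1e6L
  ks <- seq.int(k_min, k_max)
  pmf <- ks^(-gamma)
  cdf <- cumsum(pmf) / hurwitz_zeta(gamma, k_min)
  idx <- findInterval(u, cdf) + 1L
  as.integer(ks[pmin(idx, length(ks))])
}

plaw_inverse_cdf <- function(u, gamma, k_min) k_min * (1 - u)^(-1 / (gamma - 1))

sample_exponential_degrees <- function(lambda, k_min = 1, n, seed = 1L) {
  set.seed(seed)
  as.integer(k_min + stats::rgeom(n, prob = 1 - exp(-lambda)))
}

sample_layer_degrees <- function(fam, n, seed) {
  k_min <- fam$k_min %||% 1
  if (fam$family == "power_law") {
    sample_power_law_degrees(fam$gamma, k_min, n, domain = "discrete", seed = seed)
  } else {
    sample_exponential_degrees(fam$lambda, k_min, n, seed = seed)
  }
}

#' Generate a synthetic GPR table
#'
#' Emits a mixture of monomer rules (`"p007"`), AND-complex rules
#' (`"(p001 and p002)"`) and OR-isozyme rules (`"p004 or p005"`) at the
#' requested fractions (remainder = monomers).
#'
#' @param n_reactions Number of rules to draw.
#' @param protein_pool Number of distinct protein ids available.
#' @param complex_fraction Fraction of AND-complex rules.
#' @param isozyme_fraction Fraction of OR-isozyme rules.
#' @param seed Integer seed.
#' @return Tibble `reaction_id`, `gpr`, `rule_type`.
#' @export
generate_gpr_table <- function(n_reactions, protein_pool,
                               complex_fraction = 0.3, isozyme_fraction = 0.2,
                               seed = 1L) {
  stopifnot(complex_fraction + isozyme_fraction <= 1)
  if (complex_fraction > 0 && protein_pool < 2) {
    abort("protein_pool must be at least 2 when complex rules are requested")
  }
  set.seed(seed)
  proteins <- sprintf("p%03d", seq_len(protein_pool))
  types <- sample(c("complex", "isozyme", "monomer"), n_reactions, replace = TRUE,
                  prob = c(complex_fraction, isozyme_fraction,
                           1 - complex_fraction - isozyme_fraction))
  gpr <- vapply(types, function(tp) {
    if (tp == "monomer") {
      sample(proteins, 1L)
    } else if (tp == "complex") {
      k <- if (protein_pool >= 3) sample(2:3, 1L) else 2L
      paste0("(", paste(sample(proteins, k), collapse = " and "), ")")
    } else {
      paste(sample(proteins, min(2L, protein_pool)), collapse = " or ")
    }
  }, character(1))
  tibble(reaction_id = sprintf("R%04d", seq_len(n_reactions)),
         gpr = unname(gpr), rule_type = types)
}

# lognormal mixture with rejection against forbidden log10-mass intervals
sample_masses <- function(n, mixture, gaps) {
  comp <- sample.int(nrow(mixture), n, replace = TRUE, prob = mixture$weight)
  lmu <- log10(mixture$median_da)[comp]
  lsd <- mixture$sd_log10[comp]
  lx <- rnorm(n, lmu, lsd)
  in_gap <- function(v) {
    bad <- rep(FALSE, length(v))
    for (g in gaps) bad <- bad | (v > g[1] & v < g[2])
    bad
  }
  for (tries in seq_len(1000L)) {
    bad <- in_gap(lx)
    if (!any(bad)) break
    lx[bad] <- rnorm(sum(bad), lmu[bad], lsd[bad])
  }
  list(mass = 10^lx, component = comp)
}

#' Generate a synthetic multilayer network with ground truth
#'
#' Realises each layer with a bipartite configuration model: compound
#' degrees are drawn from the configured family, compound stubs are matched
#' to reactions (every reaction receives at least one reactant and one
#' product; same-reaction stub collisions are rejected and reassigned, any
#' irreducible remainder is dropped), remaining stubs are assigned random
#' roles. Exactly the configured numbers of directed bridge compounds are
#' then planted between layer pairs (attached to irreversible reactions so
#' the planted cross-layer connectivity counts are exact). Masses come from
#' the configured lognormal mixture with rejection-enforced gaps; module
#' labels are drawn per reaction; a GPR table linking metabolic reactions to
#' a protein pool is emitted alongside (as ground truth for the biosynthesis
#' builder — its proteins are not injected into the emitted network, so
#' cross-layer connectivity stays exactly as planted).
#'
#' @param config A [synth_config()].
#' @return List with `net` (an [mlnet()]) and `truth` (planted degree
#'   families and sequences, bridge ids per ordered pair, mass component per
#'   compound, module labels, and the GPR table).
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  layer_seeds <- sample.int(.Machine$integer.max, 8L)

  all_reactions <- list()
  all_compounds <- list()
  truth_degrees <- list()

  for (li in seq_along(layer_codes)) {
    L <- layer_codes[li]
    n_r <- as.integer(config$reactions[[L]])
    n_c <- as.integer(config$compounds[[L]])
    fam <- config$degree_family[[L]]
    deg <- sample_layer_degrees(fam, n_c, seed = layer_seeds[li])
    deg <- pmax(deg, 1L)
    if (sum(deg) < 2L * n_r) {
      abort(sprintf(
        "layer %s infeasible: %d compound stubs cannot fill %d reactions (need >= %d)",
        L, sum(deg), n_r, 2L * n_r))
    }
    cid <- sprintf("%s:c%05d", L, seq_len(n_c))
    rid <- sprintf("%s:r%05d", L, seq_len(n_r))
    stubs <- sample(rep.int(seq_len(n_c), deg))
    # seed each reaction with one reactant and one product
    react1 <- stubs[seq_len(n_r)]
    prod1 <- stubs[seq.int(n_r + 1L, 2L * n_r)]
    clash <- which(react1 == prod1)
    if (length(clash) && n_r > 1L) {
      shift <- c(prod1[-1L], prod1[1L])
      prod1[clash] <- shift[clash]
    }
    rest <- if (length(stubs) > 2L * n_r) stubs[seq.int(2L * n_r + 1L, length(stubs))] else integer(0)
    rest_rxn <- if (length(rest)) sample.int(n_r, length(rest), replace = TRUE) else integer(0)
    rest_role <- if (length(rest)) {
      sample(c("reactant", "product", "catalyst", "transporter"), length(rest),
             replace = TRUE, prob = c(0.4, 0.4, 0.15, 0.05))
    } else character(0)
    assign_df <- bind_rows(
      tibble(rxn = seq_len(n_r), cmp = react1, role = "reactant"),
      tibble(rxn = seq_len(n_r), cmp = prod1, role = "product"),
      tibble(rxn = rest_rxn, cmp = rest, role = rest_role)
    )
    role_sets <- function(role_name) {
      sel <- assign_df[assign_df$role == role_name, ]
      sets <- split(sel$cmp, factor(sel$rxn, levels = seq_len(n_r)))
      lapply(sets, function(v) cid[sort(unique(v))])
    }
    reactions <- tibble(
      reaction_id = rid, layer = L,
      module = sample(config$modules[[L]], n_r, replace = TRUE),
      reversible = runif(n_r) < config$reversible_fraction,
      reactants = role_sets("reactant"),
      products = role_sets("product"),
      catalysts = role_sets("catalyst"),
      transporters = role_sets("transporter")
    )
    all_reactions[[L]] <- reactions
    all_compounds[[L]] <- tibble(compound_id = cid, name = cid)
    truth_degrees[[L]] <- tibble(compound_id = cid, planted_degree = as.integer(deg))
  }

  reactions <- bind_rows(all_reactions)
  compounds <- bind_rows(all_compounds)

  # plant directed bridge compounds between layer pairs
  bridge_truth <- list()
  for (pair in names(config$bridges)) {
    b <- as.integer(config$bridges[[pair]])
    if (b <= 0L) next
    from <- substr(pair, 1, 1)
    to <- substr(pair, 2, 2)
    irrev_from <- which(reactions$layer == from & !reactions$reversible)
    irrev_to <- which(reactions$layer == to & !reactions$reversible)
    if (length(irrev_from) == 0L || length(irrev_to) == 0L) {
      abort(sprintf("no irreversible reactions available to anchor %s bridges", pair))
    }
    ids <- sprintf("%s>%s:b%03d", from, to, seq_len(b))
    src <- irrev_from[sample.int(length(irrev_from), b, replace = b > length(irrev_from))]
    dst <- irrev_to[sample.int(length(irrev_to), b, replace = b > length(irrev_to))]
    for (i in seq_len(b)) {
      reactions$products[[src[i]]] <- c(reactions$products[[src[i]]], ids[i])
      reactions$reactants[[dst[i]]] <- c(reactions$reactants[[dst[i]]], ids[i])
    }
    compounds <- bind_rows(compounds, tibble(compound_id = ids, name = ids))
    bridge_truth[[pair]] <- ids
  }

  ms <- sample_masses(nrow(compounds), config$mass_mixture, config$mass_gaps)
  compounds$ctype <- config$mass_mixture$ctype[ms$component]
  compounds$mass_da <- ms$mass

  n_gpr <- round(config$gpr_coverage * config$reactions[["M"]])
  gpr_tab <- generate_gpr_table(n_gpr, config$protein_pool,
                                config$complex_fraction, config$isozyme_fraction,
                                seed = layer_seeds[4L])
  m_ids <- reactions$reaction_id[reactions$layer == "M"]
  gpr_tab$reaction_id <- sample(m_ids, n_gpr)

  net <- mlnet(compounds[, c("compound_id", "name", "ctype", "mass_da")], reactions)
  truth <- list(
    degree_family = config$degree_family,
    planted_degrees = bind_rows(truth_degrees),
    bridges = bridge_truth,
    mass_component = tibble(compound_id = compounds$compound_id,
                            component = ms$component),
    modules = reactions[, c("reaction_id", "module")],
    gpr_table = gpr_tab,
    amino_acid_ids = sprintf("aa%02d", seq_len(config$n_amino_acids)),
    seed = config$seed
  )
  list(net = net, truth = truth)
}
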