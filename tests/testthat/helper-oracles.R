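# Independent brute-force oracles, deliberately written without reusing the
# package's implementation paths (and without igraph).

# --- boolean-rule oracle: translate a GPR string to an R logical expression
# and evaluate it under every truth assignment of its variables.
gpr_truth_oracle <- function(text) {
  expr_txt <- gsub("\\bor\\b", "|", gsub("\\band\\b", "&", tolower(text)))
  vars <- sort(unique(regmatches(text, gregexpr("[^()[:space:]]+", text))[[1]]))
  vars <- setdiff(vars, c("and", "or", "AND", "OR"))
  parsed <- parse(text = expr_txt)[[1]]
  n <- length(vars)
  sat <- list()
  for (mask in 0:(2^n - 1)) {
    on <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    env <- as.list(setNames(on, tolower(vars)))
    if (isTRUE(eval(parsed, envir = env))) sat <- c(sat, list(vars[on]))
  }
  sat
}

# minimal satisfying variable sets from the full satisfying list
minimal_sets <- function(sat) {
  sat <- unique(lapply(sat, sort))
  keep <- vapply(seq_along(sat), function(i) {
    !any(vapply(seq_along(sat), function(j) {
      i != j && length(sat[[j]]) < length(sat[[i]]) && all(sat[[j]] %in% sat[[i]])
    }, logical(1)))
  }, logical(1))
  sets <- sat[keep]
  sets[order(vapply(sets, paste, character(1), collapse = "\r"))]
}

# --- betweenness oracle: all-pairs BFS distances and shortest-path counts,
# then sigma_st(n) = sigma_sn * sigma_nt when distances compose.
bc_oracle <- function(edges, nodes = NULL) {
  nodes <- nodes %||% sort(unique(c(edges$from, edges$to)))
  n <- length(nodes)
  adj <- lapply(nodes, function(v) match(edges$to[edges$from == v], nodes))
  D <- matrix(Inf, n, n)
  S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0; S[s, s] <- 1
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) for (w in adj[[v]]) {
        if (!is.finite(D[s, w])) {
          D[s, w] <- d
          nxt <- c(nxt, w)
        }
        if (D[s, w] == d) S[s, w] <- S[s, w] + S[s, v]
      }
      frontier <- unique(nxt)
    }
  }
  bc <- numeric(n)
  for (v in seq_len(n)) {
    through <- outer(D[, v], D[v, ], "+")
    ok <- is.finite(D) & (through == D) & (S > 0)
    ok[v, ] <- FALSE; ok[, v] <- FALSE
    diag(ok) <- FALSE
    num <- outer(S[, v], S[v, ])
    bc[v] <- sum((num / S)[ok])
  }
  setNames(bc, nodes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- discrete power-law MLE oracle: plain long-summation zeta on a gamma
# grid; the grid is cached per (range, k_min) so many samples reuse it.
plaw_grid_env <- new.env()
plaw_discrete_oracle <- function(k, k_min = 1, lo = 1.5, hi = 4, step = 2e-3) {
  key <- paste(lo, hi, step, k_min)
  if (is.null(plaw_grid_env[[key]])) {
    gs <- seq(lo, hi, by = step)
    js <- seq.int(k_min, 1e5)
    zs <- vapply(gs, function(g) sum(js^(-g)), numeric(1))
    plaw_grid_env[[key]] <- list(gs = gs, log_z = log(zs))
  }
  grid <- plaw_grid_env[[key]]
  S <- sum(log(k))
  nll <- grid$gs * S + length(k) * grid$log_z
  grid$gs[which.min(nll)]
}
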