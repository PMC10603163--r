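#' Joint mass–degree table of a network
#'
#' One row per compound with known molecular mass; degree is counted over
#' all layers. Compounds with unknown mass (notably the peptide placeholder)
#' are excluded and their count reported in the `n_unknown_mass` attribute.
#'
#' @param net An `mlnet` with masses assigned.
#' @return Tibble `compound_id`, `mass_da`, `degree`, `ctype`, `layers`
#'   (list-column).
#' @export
mass_degree_table <- function(net) {
  deg <- degree_table(net, "all")
  lay <- compound_layers(net)
  tab <- net$compounds |>
    left_join(deg, by = "compound_id") |>
    left_join(lay, by = "compound_id") |>
    mutate(layers = map(.data$layers, function(l) l %||% character(0)))
  n_unknown <- sum(is.na(tab$mass_da))
  out <- tab |>
    filter(!is.na(.data$mass_da)) |>
    select("compound_id", "mass_da", "degree", "ctype", "layers")
  structure(out, n_unknown_mass = n_unknown)
}

#' Histogram of compound masses on a log10 axis
#'
#' Bins are of equal width on the log10(mass) axis, anchored at the smallest
#' observed mass so that rescaling all masses by a power of ten shifts bin
#' edges rigidly by the same number of decades. Counts always sum to the
#' number of records; with `stratify_by`, per-stratum counts sum to the
#' unstratified totals bin by bin.
#'
#' @param records Mass–degree table from [mass_degree_table()] (any tibble
#'   with a `mass_da` column works; stratification needs the named column).
#' @param bin_width_log10 Bin width in decades (default 0.25).
#' @param stratify_by Optional column to stratify counts by (`"ctype"` or a
#'   layer indicator column).
#' @return Tibble `bin_low_da`, `bin_high_da`, `count` (plus the stratum
#'   column when stratified), with attribute `bin_width_log10`.
#' @export
log_mass_histogram <- function(records, bin_width_log10 = 0.25, stratify_by = NULL) {
  if (nrow(records) == 0L) abort("no mass records to histogram")
  stopifnot(bin_width_log10 > 0)
  lx <- log10(records$mass_da)
  lo <- min(lx)
  # right-open bins anchored at the smallest mass; the maximum falls inside
  # the last bin rather than on its edge
  n_bins <- floor((max(lx) - lo) / bin_width_log10 + 1e-9) + 1L
  edges <- lo + bin_width_log10 * seq.int(0L, n_bins)
  idx <- pmin(pmax(floor((lx - lo) / bin_width_log10 + 1e-9) + 1L, 1L), n_bins)
  base <- tibble(
    bin = seq_len(n_bins),
    bin_low_da = 10^edges[-length(edges)],
    bin_high_da = 10^edges[-1L]
  )
  if (is.null(stratify_by)) {
    counts <- tabulate(idx, nbins = n_bins)
    out <- mutate(base, count = as.integer(counts)) |> select(-"bin")
  } else {
    strata <- as.character(records[[stratify_by]])
    out <- tidyr::expand_grid(bin = seq_len(n_bins), stratum = sort(unique(strata))) |>
      left_join(
        tibble(bin = idx, stratum = strata) |>
          dplyr::count(.data$bin, .data$stratum, name = "count"),
        by = c("bin", "stratum")
      ) |>
      mutate(count = ifelse(is.na(.data$count), 0L, as.integer(.data$count))) |>
      left_join(base, by = "bin") |>
      select("bin_low_da", "bin_high_da", "stratum", "count")
  }
  structure(out, bin_width_log10 = bin_width_log10)
}

#' Detect modes and troughs of a log-mass histogram
#'
#' Formalises the visual reading of a multimodal mass distribution. A mode
#' is a local maximum of the binned counts whose height is at least
#' `prominence_fraction` of the global maximum and which is separated from
#' every higher retained mode by at least one bin with count below half its
#' own height. Troughs are the minimal-count bin runs between consecutive
#' retained modes; a trough containing one or more *empty* bins marks the
#' distribution as discontinuous (mass ranges with no reported molecule).
#'
#' @param histogram Unstratified histogram from [log_mass_histogram()].
#' @param prominence_fraction Minimum mode height as a fraction of the
#'   global maximum (default 0.05).
#' @return A `mass_mode_summary`: list with `modes` (tibble
#'   `center_mass_da`, `height`), `troughs` (tibble `low_mass_da`,
#'   `high_mass_da`, `min_count`, `empty_bin_count`), `discontinuous`,
#'   `bin_width_log10`.
#' @export
detect_modes_troughs <- function(histogram, prominence_fraction = 0.05) {
  h <- histogram
  if (nrow(h) < 3L) abort("need at least 3 bins to detect modes")
  cnt <- as.numeric(h$count)
  nb <- length(cnt)
  centers <- sqrt(h$bin_low_da * h$bin_high_da)   # geometric bin centre

  # local maxima (plateau-aware: strictly greater than nearest differing bins)
  is_peak <- vapply(seq_len(nb), function(i) {
    if (cnt[i] == 0) return(FALSE)
    l <- i - 1L
    while (l >= 1L && cnt[l] == cnt[i]) l <- l - 1L
    r <- i + 1L
    while (r <= nb && cnt[r] == cnt[i]) r <- r + 1L
    left_ok <- l < 1L || cnt[l] < cnt[i]
    right_ok <- r > nb || cnt[r] < cnt[i]
    # keep only the first bin of a plateau
    first_of_plateau <- i == 1L || cnt[i - 1L] != cnt[i]
    left_ok && right_ok && first_of_plateau
  }, logical(1))
  cand <- which(is_peak & cnt >= prominence_fraction * max(cnt))
  # separation rule, processed by descending height
  cand <- cand[order(-cnt[cand], cand)]
  kept <- integer(0)
  for (i in cand) {
    ok <- all(vapply(kept, function(j) {
      if (cnt[j] < cnt[i]) return(TRUE)   # only higher retained modes constrain
      rng <- if (j < i) seq.int(j, i) else seq.int(i, j)
      any(cnt[rng] < cnt[i] / 2)
    }, logical(1)))
    if (ok) kept <- c(kept, i)
  }
  kept <- sort(kept)

  troughs <- NULL
  if (length(kept) >= 2L) {
    troughs <- purrr::map_dfr(seq_len(length(kept) - 1L), function(s) {
      a <- kept[s]; b <- kept[s + 1L]
      between <- seq.int(a + 1L, b - 1L)
      mn <- min(cnt[between])
      run <- between[cnt[between] == mn]
      tibble(
        low_mass_da = h$bin_low_da[min(run)],
        high_mass_da = h$bin_high_da[max(run)],
        min_count = mn,
        empty_bin_count = sum(cnt[between] == 0)
      )
    })
  } else {
    troughs <- tibble(low_mass_da = double(0), high_mass_da = double(0),
                      min_count = double(0), empty_bin_count = integer(0))
  }
  structure(
    list(
      bin_width_log10 = attr(h, "bin_width_log10") %||% NA_real_,
      modes = tibble(center_mass_da = centers[kept], height = cnt[kept]),
      troughs = troughs,
      discontinuous = any(troughs$empty_bin_count >= 1)
    ),
    class = "mass_mode_summary"
  )
}

#' @export
print.mass_mode_summary <- function(x, ...) {
  cat(sprintf("<mass_mode_summary> %d mode(s), %d trough(s), discontinuous = %s\n",
              nrow(x$modes), nrow(x$troughs), x$discontinuous))
  if (nrow(x$modes)) {
    cat("  mode centres (Da):", paste(signif(x$modes$center_mass_da, 3), collapse = ", "), "\n")
  }
  invisible(x)
}
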