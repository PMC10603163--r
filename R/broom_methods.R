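#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a tail fit
#'
#' @param x A `tail_fit`.
#' @param ... Unused.
#' @return One-row tibble with the fitted family, domain, parameter,
#'   cutoff, tail size, log-likelihood and KS distance.
#' @export
tidy.tail_fit <- function(x, ...) {
  tibble(family = x$family, domain = x$domain, gamma = x$gamma,
         lambda = x$lambda, k_min = x$k_min, n_tail = x$n_tail,
         log_likelihood = x$log_likelihood, ks_distance = x$ks_distance)
}

#' Tidy a log-likelihood-ratio comparison
#'
#' @param x An `llr_comparison`.
#' @param ... Unused.
#' @return Two-row tibble (one per fitted family).
#' @export
tidy.llr_comparison <- function(x, ...) {
  bind_rows(tidy(x$power_law), tidy(x$exponential))
}

#' @rdname tidy.llr_comparison
#' @return For `glance`: one-row tibble with `R`, `p_value`, `preferred`,
#'   `k_min`, `n_tail`.
#' @export
glance.llr_comparison <- function(x, ...) {
  tibble(R = x$R, p_value = x$p_value, preferred = x$preferred,
         k_min = x$k_min, n_tail = x$n_tail)
}

#' Tidy a mass-mode summary
#'
#' @param x A `mass_mode_summary`.
#' @param ... Unused.
#' @return Tibble of modes (`center_mass_da`, `height`).
#' @export
tidy.mass_mode_summary <- function(x, ...) x$modes

#' @rdname tidy.mass_mode_summary
#' @export
glance.mass_mode_summary <- function(x, ...) {
  tibble(n_modes = nrow(x$modes), n_troughs = nrow(x$troughs),
         discontinuous = x$discontinuous,
         bin_width_log10 = x$bin_width_log10)
}

#' Tidy a pipeline report
#'
#' @param x A `pipeline_report`.
#' @param ... Unused.
#' @return The tail-fit table (one row per selection and domain).
#' @export
tidy.pipeline_report <- function(x, ...) x$tails

#' @rdname tidy.pipeline_report
#' @export
glance.pipeline_report <- function(x, ...) {
  tibble(
    n_nodes = x$counts$n_nodes_total, n_links = x$counts$n_links,
    n_compounds = x$counts$n_compounds, n_reactions = x$counts$n_reactions,
    n_mass_modes = nrow(x$mass$summary$modes),
    discontinuous = x$mass$summary$discontinuous,
    separation_t_vs_m = x$embedding$separation_t_vs_m
  )
}
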