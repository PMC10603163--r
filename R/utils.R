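#' @importFrom rlang abort warn %||% .data
#' @importFrom dplyr filter mutate select arrange group_by summarise ungroup
#'   distinct left_join inner_join anti_join bind_rows bind_cols n n_distinct pull rename
#'   across all_of row_number first
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_chr map_int map_dbl map_lgl map2 pmap imap keep
#' @importFrom stats optimize prcomp rnorm runif setNames sd dist quantile
#' @importFrom utils head tail
NULL

# split a ";"-separated role field into a character vector (empty -> character(0))
split_ids <- function(x) {
  out <- strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)
  lapply(out, function(v) unique(v[nzchar(v)]))
}

join_ids <- function(x) vapply(x, paste, character(1), collapse = ";")

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  gsub("'", "&apos;", x, fixed = TRUE)
}

compound_types <- c(
  "metabolite", "amino_acid", "energy_molecule", "ion",
  "protein", "rna", "complex", "peptide_placeholder"
)

layer_codes <- c("T", "B", "M")
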