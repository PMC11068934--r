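#' Published adipose Bayesian-network attributes
#'
#' Attributes of eight published sex- and depot-specific human adipose
#' Bayesian networks (two cohorts, STARNET and GTEx, by sex and by
#' subcutaneous/visceral depot): connected-gene count, directed edge count
#' and key-driver count per network. Bundled as a worked reference table for
#' summary arithmetic and report schemas.
#'
#' @return Data frame with columns `cohort`, `depot`, `sex`, `genes`,
#'   `edges`, `key_drivers`.
#' @export
adipose_network_attributes <- function() {
  utils::read.delim(system.file("extdata", "adipose_network_attributes.tsv",
                                package = "netkda"),
                    stringsAsFactors = FALSE)
}

#' Round half away from zero
#'
#' Unlike base [round()] (round-half-even), halves round up: 0.5 -> 1,
#' 690.5 -> 691.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Mean attributes across a set of networks
#'
#' Means of the connected-gene, edge and key-driver counts over the rows of
#' an attribute table (as produced per network by [run_group()] or bundled
#' by [adipose_network_attributes()]), rounded half-up to whole counts.
#'
#' @param attributes Data frame with numeric columns `genes`, `edges`,
#'   `key_drivers`.
#' @return Named numeric vector `genes`, `edges`, `key_drivers`.
#' @export
summarize_network_attributes <- function(attributes = adipose_network_attributes()) {
  need <- c("genes", "edges", "key_drivers")
  if (!all(need %in% names(attributes)))
    stop("attribute table needs columns: ", paste(need, collapse = ", "))
  vapply(attributes[need], function(x) round_half_up(mean(x)), numeric(1))
}
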