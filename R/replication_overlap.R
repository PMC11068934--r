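#' Permutation null for the overlap of two key-driver sets
#'
#' Mirrors the replication test between cohorts: from each network's gene
#' universe, draw (without replacement) as many random genes as that network
#' has key drivers, record the intersection size of the two draws, and
#' repeat. The empirical p-value for the observed number of shared key
#' drivers uses the add-one rule
#' `p = (1 + #\{null >= observed\}) / (1 + replicates)`, so it is never
#' exactly zero.
#'
#' @param universe_a,universe_b [gene_set()]s (or character vectors) of the
#'   genes eligible to be key drivers in each network (its connected genes).
#' @param n_a,n_b Number of genes to draw from each universe (the observed
#'   key-driver counts).
#' @param observed Observed number of shared key drivers.
#' @param replicates Number of null draws (default 10,000).
#' @param seed Integer seed.
#' @return An `overlap_test`: list with `observed`, `null_distribution`
#'   (integer vector), `null_mean`, `empirical_p`, `n_a`, `n_b`,
#'   `universe_sizes`, `replicates`, `seed`.
#' @export
overlap_null <- function(universe_a, universe_b, n_a, n_b, observed,
                         replicates = 10000, seed = 1) {
  if (inherits(universe_a, "gene_set")) universe_a <- universe_a$members
  if (inherits(universe_b, "gene_set")) universe_b <- universe_b$members
  universe_a <- unique(as.character(universe_a))
  universe_b <- unique(as.character(universe_b))
  stopifnot(replicates >= 1, observed >= 0)
  if (n_a > length(universe_a) || n_b > length(universe_b))
    stop("draw size exceeds universe size")
  set.seed(seed)
  null <- integer(replicates)
  for (i in seq_len(replicates)) {
    a <- sample(universe_a, n_a)
    b <- sample(universe_b, n_b)
    null[i] <- length(intersect(a, b))
  }
  structure(list(observed = as.integer(observed),
                 null_distribution = null,
                 null_mean = mean(null),
                 empirical_p = (1 + sum(null >= observed)) /
                   (1 + replicates),
                 n_a = as.integer(n_a), n_b = as.integer(n_b),
                 universe_sizes = c(a = length(universe_a),
                                    b = length(universe_b)),
                 replicates = as.integer(replicates), seed = seed),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "overlap_test: observed %d shared of draws %d/%d; null mean %.2f; p = %.4g\n",
    x$observed, x$n_a, x$n_b, x$null_mean, x$empirical_p))
  invisible(x)
}

#' Histogram data of an overlap null distribution
#'
#' Integer counts of the null overlap values, suitable for plotting the null
#' histogram with the observed value marked.
#'
#' @param test An `overlap_test`.
#' @return Data frame with columns `overlap` and `count`.
#' @export
overlap_null_histogram <- function(test) {
  tab <- table(test$null_distribution)
  data.frame(overlap = as.integer(names(tab)), count = as.integer(tab))
}
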