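#' Read / write a gene-by-sample expression matrix
#'
#' Tab-delimited layout: first column gene identifiers, header row of sample
#' identifiers, non-negative abundances (TPM scale).
#'
#' @param path File to read or write.
#' @return Numeric matrix (genes x samples) with row and column names.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression table needs a gene column and >= 1 sample")
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(df[[1]])
  validate_expression(mat)
  mat
}

#' @rdname read_expression
#' @param mat Expression matrix to write.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_expression <- function(mat, allow_negative = FALSE) {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("expression data must be a numeric matrix")
  if (nrow(mat) == 0L || ncol(mat) == 0L) stop("expression matrix is empty")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(mat))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(mat))) stop("duplicate sample identifiers")
  if (anyNA(mat)) stop("expression matrix contains missing values")
  if (!allow_negative && any(mat < 0)) stop("negative abundance values")
  invisible(mat)
}

#' Remove lowly expressed genes
#'
#' A gene is removed when its abundance is below `threshold` in more than
#' `fraction` of the samples (strictly greater than: a gene below threshold in
#' exactly `fraction` of samples is retained). The default reproduces the
#' common TPM filter: drop genes with < 0.1 TPM in > 80% of samples.
#'
#' @param mat Genes x samples numeric matrix.
#' @param threshold Abundance below which a sample counts as "low" (>= 0).
#' @param fraction Proportion of low samples above which the gene is dropped,
#'   in (0, 1).
#' @return The filtered matrix (same samples, subset of genes).
#' @export
filter_low_expression <- function(mat, threshold = 0.1, fraction = 0.8) {
  validate_expression(mat)
  stopifnot(threshold >= 0, fraction > 0, fraction < 1)
  low_frac <- rowMeans(mat < threshold)
  mat[low_frac <= fraction, , drop = FALSE]
}

#' Log-transform expression values
#'
#' Natural log of `x + offset`; with the default offset of 1 a zero TPM maps
#' to 0 and within-gene sample ranking is preserved.
#'
#' @param mat Genes x samples numeric matrix (non-negative).
#' @param offset Pseudo-abundance added before the log (default 1).
#' @return Matrix of the same shape.
#' @export
log_transform <- function(mat, offset = 1) {
  validate_expression(mat)
  stopifnot(offset > 0 || all(mat > 0))
  out <- log(mat + offset)
  validate_expression(out, allow_negative = TRUE)
  out
}

#' Split samples by a marker gene's expression
#'
#' Partitions samples into marker-high and marker-low groups, e.g. splitting
#' by XIST expression to confirm sex assignments. When `threshold` is NULL it
#' defaults to the midpoint between the two centers of a 2-means split of the
#' marker's values.
#'
#' @param mat Genes x samples matrix.
#' @param marker Gene identifier present in `mat`.
#' @param threshold Abundance cut point, or NULL for the 2-means midpoint.
#' @return List with elements `high` and `low` (submatrices over the same
#'   genes) and `threshold` (the cut used).
#' @export
split_by_marker <- function(mat, marker, threshold = NULL) {
  validate_expression(mat)
  if (!marker %in% rownames(mat)) stop("marker gene not found: ", marker)
  x <- mat[marker, ]
  if (is.null(threshold)) {
    ux <- unique(x)
    if (length(ux) < 2L)
      stop("marker '", marker, "' is constant; supply a threshold")
    km <- stats::kmeans(x, centers = range(ux), iter.max = 50)
    threshold <- mean(sort(km$centers[, 1]))
  }
  hi <- x >= threshold
  if (all(hi) || !any(hi))
    warning("marker split is degenerate: all samples on one side of ",
            format(threshold))
  list(high = mat[, hi, drop = FALSE],
       low = mat[, !hi, drop = FALSE],
       threshold = threshold)
}

DISCRETE_LEVELS <- c("low", "medium", "high")

# exact 1-D 3-means on distinct values `v` with multiplicities `w`: the
# optimal clusters are contiguous in sorted order, so search the two cut
# points minimizing within-cluster sum of squares via prefix sums
cuts_3means <- function(v, w) {
  m <- length(v)
  W <- cumsum(w)
  S <- cumsum(w * v)
  Q <- cumsum(w * v^2)
  seg <- function(i, j) {  # SS of values i..j (vectorized over i or j)
    W0 <- c(0, W)[i]; S0 <- c(0, S)[i]; Q0 <- c(0, Q)[i]
    (Q[j] - Q0) - (S[j] - S0)^2 / (W[j] - W0)
  }
  ab <- which(upper.tri(matrix(0, m - 1, m - 1)), arr.ind = TRUE)  # a < b
  a <- ab[, 1]; b <- ab[, 2]
  cost <- seg(rep(1L, length(a)), a) + seg(a + 1L, b) + seg(b + 1L, rep(m, length(b)))
  best <- which.min(cost)
  c(a[best], b[best])
}

#' Discretize expression into low / medium / high levels
#'
#' Per-gene one-dimensional 3-means clustering of the (typically
#' log-transformed) values across samples; clusters are relabeled low <
#' medium < high by ascending center, so level assignment is monotone in the
#' underlying value. In one dimension the k-means optimum is a contiguous
#' partition of the sorted values, so the exact global optimum is found by
#' minimizing the within-cluster sum of squares over the two cut points --
#' making the result deterministic and invariant to sample order.
#' Degenerate genes follow deterministic rules: a constant gene is all
#' "medium"; a gene with exactly two distinct values maps them to "low" and
#' "high" (with a warning).
#'
#' @param mat Genes x samples numeric matrix.
#' @param k Number of levels; only `k = 3` is supported.
#' @param seed Integer seed recorded for provenance (the exact optimum does
#'   not depend on it).
#' @return A `discrete_matrix`: integer matrix (1 = low, 2 = medium,
#'   3 = high) with a `levels` attribute and the discretization seed.
#' @export
discretize_kmeans <- function(mat, k = 3, seed = 1) {
  validate_expression(mat, allow_negative = TRUE)
  if (k != 3) stop("only k = 3 (low/medium/high) is supported")
  out <- matrix(NA_integer_, nrow(mat), ncol(mat),
                dimnames = dimnames(mat))
  degenerate <- character()
  for (i in seq_len(nrow(mat))) {
    x <- mat[i, ]
    ux <- sort(unique(x))
    if (length(ux) == 1L) {
      out[i, ] <- 2L
      degenerate <- c(degenerate, rownames(mat)[i])
    } else if (length(ux) == 2L) {
      out[i, ] <- ifelse(x == ux[1], 1L, 3L)
      degenerate <- c(degenerate, rownames(mat)[i])
    } else if (length(ux) == 3L) {
      out[i, ] <- findInterval(x, ux)
    } else {
      w <- tabulate(match(x, ux), length(ux))
      cut <- cuts_3means(ux, w)
      bounds <- (ux[cut] + ux[cut + 1L]) / 2  # midpoints between clusters
      out[i, ] <- 1L + findInterval(x, bounds)
    }
  }
  if (length(degenerate))
    warning(length(degenerate), " gene(s) with < 3 distinct values ",
            "discretized by the degenerate rule: ",
            paste(utils::head(degenerate, 5), collapse = ", "),
            if (length(degenerate) > 5) ", ..." else "")
  structure(out, levels = DISCRETE_LEVELS, seed = seed,
            class = c("discrete_matrix", "matrix", "array"))
}

#' Level labels of a discrete matrix
#' @param disc A `discrete_matrix`.
#' @return Character matrix with entries in low/medium/high.
#' @export
discrete_labels <- function(disc) {
  lab <- matrix(DISCRETE_LEVELS[disc], nrow(disc), ncol(disc),
                dimnames = dimnames(disc))
  lab
}

#' Write a discretized matrix (same layout as expression, entries are level
#' labels)
#' @inheritParams discrete_labels
#' @param path Output file.
#' @export
write_discrete <- function(disc, path) {
  df <- data.frame(gene = rownames(disc), discrete_labels(disc),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
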