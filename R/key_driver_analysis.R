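#' Default distance weights for the type-1 GeneScore
#'
#' Weights applied to the per-distance z-scores for d = 1..9: distances 1--3
#' weigh 1 and the weight halves at each further step. Their sum is 4.71875,
#' the GeneScore of a gene sitting exactly one network SD above the mean at
#' every distance. Profiling extends to distance 10 but the distance-10
#' count is unweighted.
#'
#' @return Numeric vector of length 9.
#' @export
kda_weights <- function() {
  c(1, 1, 1, 0.75, 0.5, 0.25, 0.125, 0.0625, 0.03125)
}

#' Downstream-count profile of every gene
#'
#' For each gene, counts its downstream genes at exact shortest-path
#' distances 1..`max_distance`, then summarizes the network with the mean
#' and population SD of those counts at each distance.
#'
#' @param net A non-empty `gene_network`.
#' @param max_distance Largest distance profiled (default 10).
#' @return A `kda_profile`: list with `counts` (genes x distances integer
#'   matrix), `network_mean` and `network_sd` (length-`max_distance`
#'   vectors), `max_distance`.
#' @export
downstream_profile <- function(net, max_distance = 10) {
  if (length(net$nodes) == 0L) stop("empty network")
  stopifnot(max_distance >= 1)
  d <- igraph::distances(as_igraph(net), mode = "out")
  d <- d[net$nodes, net$nodes, drop = FALSE]
  counts <- vapply(seq_len(max_distance),
                   function(k) rowSums(is.finite(d) & d == k),
                   numeric(length(net$nodes)))
  counts <- matrix(as.integer(counts), nrow = length(net$nodes),
                   dimnames = list(net$nodes, paste0("d", seq_len(max_distance))))
  nm <- colMeans(counts)
  ns <- sqrt(colMeans(counts^2) - nm^2)  # population SD
  ns[ns < 0] <- 0
  structure(list(counts = counts, network_mean = nm, network_sd = ns,
                 max_distance = max_distance),
            class = "kda_profile")
}

#' Type-1 key drivers: distance-weighted downstream z-scores
#'
#' Per gene and distance d, `Score_d = (G_d - NM_d) / NS_d` measures how
#' extreme the gene's downstream count is relative to the network (a
#' z-score); distances where the network SD is zero contribute 0. The
#' GeneScore is the weighted sum of `Score_d` for d = 1..9 using
#' [kda_weights()] (unless overridden). The top `decile` highest-scoring
#' genes are type-1 key drivers; all genes tied with the boundary score are
#' included.
#'
#' @param profile A `kda_profile` from [downstream_profile()].
#' @param weights Distance weights, length 9 for d = 1..9.
#' @param decile Fraction of genes declared type-1 (default 0.10).
#' @return List with `scores` (data frame: gene, per-distance z-scores,
#'   gene_score, type1 flag) and `type1` (character vector of key drivers).
#' @export
type1_scores <- function(profile, weights = kda_weights(), decile = 0.10) {
  stopifnot(inherits(profile, "kda_profile"), decile > 0, decile <= 1)
  nd <- length(weights)
  if (nd > ncol(profile$counts))
    stop("weights cover more distances than the profile (length ",
         nd, " > ", ncol(profile$counts), ")")
  G <- profile$counts[, seq_len(nd), drop = FALSE]
  nm <- profile$network_mean[seq_len(nd)]
  ns <- profile$network_sd[seq_len(nd)]
  z <- sweep(G, 2, nm, "-")
  z <- sweep(z, 2, ifelse(ns > 0, ns, Inf), "/")  # NS_d = 0 -> Score_d = 0
  gene_score <- as.numeric(z %*% weights)
  genes <- rownames(profile$counts)
  n_top <- ceiling(decile * length(genes))
  cutoff <- sort(gene_score, decreasing = TRUE)[n_top]
  type1 <- genes[gene_score >= cutoff]
  scores <- data.frame(gene = genes, G,
                       z, gene_score = gene_score,
                       type1 = gene_score >= cutoff,
                       stringsAsFactors = FALSE, check.names = FALSE)
  names(scores)[1 + nd + seq_len(nd)] <- paste0("score_d", seq_len(nd))
  scores <- scores[order(-scores$gene_score, scores$gene), ]
  rownames(scores) <- NULL
  list(scores = scores, type1 = type1)
}

#' Type-2 key drivers: GWAS-gene enrichment in downstream neighborhoods
#'
#' For each gene, its downstream neighborhood is the set of genes within
#' `radius` edges (default 4). A one-sided Fisher exact test (upper
#' hypergeometric tail) asks whether the neighborhood holds more GWAS
#' candidate genes than expected from their frequency in the network, over a
#' universe of all network genes excluding the focal gene. Genes with
#' p < `alpha` are type-2 key drivers.
#'
#' @param net A `gene_network`.
#' @param gwas A [gene_set()] (or character vector) of GWAS candidate genes;
#'   must intersect the network's genes.
#' @param radius Neighborhood radius in edges (default 4).
#' @param alpha Significance level (default 0.05).
#' @param adjust P-value adjustment method passed to [stats::p.adjust()]
#'   before thresholding (default "none"; use "BH" for
#'   Benjamini--Hochberg).
#' @return List with `table` (data frame: gene, neighborhood size, GWAS
#'   overlap, p, p_adj, significant) and `type2` (character vector).
#' @export
type2_enrichment <- function(net, gwas, radius = 4, alpha = 0.05,
                             adjust = "none") {
  if (inherits(gwas, "gene_set")) gwas <- gwas$members
  gwas <- unique(as.character(gwas))
  genes <- net$nodes
  in_gwas <- genes %in% gwas
  if (!any(in_gwas))
    stop("no GWAS gene is present in the network's gene universe")
  d <- igraph::distances(as_igraph(net), mode = "out")
  d <- d[genes, genes, drop = FALSE]
  nbhd <- is.finite(d) & d >= 1 & d <= radius
  N <- length(genes) - 1L            # universe excludes the focal gene
  K <- sum(in_gwas) - in_gwas        # GWAS genes other than the focal gene
  n_nb <- rowSums(nbhd)
  q <- as.integer(nbhd %*% in_gwas)
  p <- stats::phyper(q - 1, K, N - K, n_nb, lower.tail = FALSE)
  p_adj <- stats::p.adjust(p, method = adjust)
  sig <- p_adj < alpha
  tab <- data.frame(gene = genes, neighborhood = n_nb, gwas_overlap = q,
                    p = p, p_adj = p_adj, significant = sig,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$p, tab$gene), ]
  rownames(tab) <- NULL
  list(table = tab, type2 = tab$gene[tab$significant])
}

#' Full key-driver analysis of one network
#'
#' Runs [downstream_profile()], [type1_scores()] and [type2_enrichment()]
#' and returns the union of type-1 and type-2 key drivers with all
#' intermediates.
#'
#' @inheritParams type2_enrichment
#' @inheritParams type1_scores
#' @param max_distance Profiling depth (default 10).
#' @return A `key_driver_result`: list with `profile`, `scores`, `type1`,
#'   `enrichment`, `type2`, `key_drivers` (union) and `parameters`.
#' @export
key_drivers <- function(net, gwas, weights = kda_weights(), decile = 0.10,
                        radius = 4, alpha = 0.05, adjust = "none",
                        max_distance = 10) {
  profile <- downstream_profile(net, max_distance)
  t1 <- type1_scores(profile, weights, decile)
  t2 <- type2_enrichment(net, gwas, radius, alpha, adjust)
  structure(list(profile = profile, scores = t1$scores, type1 = t1$type1,
                 enrichment = t2$table, type2 = t2$type2,
                 key_drivers = sort(union(t1$type1, t2$type2)),
                 parameters = list(weights = weights, decile = decile,
                                   radius = radius, alpha = alpha,
                                   adjust = adjust,
                                   max_distance = max_distance)),
            class = "key_driver_result")
}

#' @export
print.key_driver_result <- function(x, ...) {
  cat(sprintf(
    "key_driver_result: %d genes -> %d type-1, %d type-2, %d key drivers\n",
    nrow(x$profile$counts), length(x$type1), length(x$type2),
    length(x$key_drivers)))
  invisible(x)
}

#' Key drivers replicated across two networks
#'
#' The intersection of the union key-driver sets of two analyses -- genes
#' called (type 1 or type 2) in both networks, e.g. in two independent
#' cohorts.
#'
#' @param result_a,result_b `key_driver_result` objects (or character
#'   vectors of key drivers).
#' @return Sorted character vector of shared key drivers.
#' @export
shared_key_drivers <- function(result_a, result_b) {
  a <- if (inherits(result_a, "key_driver_result"))
    result_a$key_drivers else as.character(result_a)
  b <- if (inherits(result_b, "key_driver_result"))
    result_b$key_drivers else as.character(result_b)
  sort(intersect(a, b))
}
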