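#' Simulate a ground-truth regulatory DAG with hub regulators
#'
#' Samples a topological order and attaches children preferentially to a
#' small set of designated hub regulators, giving a scale-free-like
#' out-degree distribution with clear hubs. Labels are planted so every
#' downstream analysis stage has known truth: `hubs` are the high-out-degree
#' regulators, `egenes` are the hubs plus a random tenth of the genes
#' (mimicking cis-eQTL support concentrated on upstream regulators), and
#' `gwas` genes are enriched by `gwas_enrichment`-fold among descendants of
#' half the hubs relative to the background rate.
#'
#' @param n_genes Number of genes (>= 10).
#' @param n_hubs Number of hub regulators (default 5).
#' @param edge_density Fraction of the `n_genes * (n_genes - 1) / 2` ordered
#'   pairs receiving an edge, in (0, 0.2); default 0.02.
#' @param seed Integer seed.
#' @param hub_weight Preferential-attachment weight of a hub relative to a
#'   non-hub when parents are drawn (default 30).
#' @param gwas_rate Background probability that a non-descendant gene is a
#'   GWAS candidate (default 0.05).
#' @param gwas_enrichment Fold enrichment of GWAS labels among descendants
#'   of the chosen hubs (default 5).
#' @return A `synthetic_truth`: list with `dag` (a `gene_network`, acyclic),
#'   `hubs`, `gwas` and `egenes` ([gene_set()]s), `order` (the topological
#'   order) and `params`.
#' @export
simulate_dag <- function(n_genes = 200, n_hubs = 5, edge_density = 0.02,
                         seed = 1, hub_weight = 30, gwas_rate = 0.05,
                         gwas_enrichment = 5) {
  stopifnot(n_genes >= 10, n_hubs >= 1, n_hubs < n_genes / 2)
  if (edge_density <= 0 || edge_density >= 0.2)
    stop("edge_density must lie in (0, 0.2)")
  if (gwas_rate * gwas_enrichment > 1)
    stop("gwas_rate * gwas_enrichment exceeds 1")
  set.seed(seed)
  genes <- sprintf("G%03d", seq_len(n_genes))
  ord <- sample(genes)                      # topological order
  hubs <- ord[seq_len(n_hubs)]              # early genes get descendants
  # several parentless roots, so no single gene is ancestral to everything
  # and hub descendant sets stay distinguishable
  n_roots <- max(n_hubs, ceiling(n_genes / 10))
  m <- max(n_genes - n_roots,
           round(edge_density * n_genes * (n_genes - 1) / 2))

  # every non-root gets one parent (connectivity), remaining edges by child
  # sampled uniformly among non-roots; parents drawn from earlier genes with
  # hubs up-weighted
  nr <- (n_roots + 1):n_genes
  child_idx <- c(nr, sample(nr, m - length(nr), replace = TRUE))
  parent <- character(length(child_idx))
  child <- ord[child_idx]
  w_all <- ifelse(ord %in% hubs, hub_weight, 1)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(child_idx)) {
    ci <- child_idx[i]
    tries <- 0L
    repeat {
      p <- sample.int(ci - 1L, 1L, prob = w_all[seq_len(ci - 1L)])
      key <- paste0(p, ">", ci)
      tries <- tries + 1L
      if (is.null(seen[[key]]) || tries > 10L) {  # duplicates dropped below
        seen[[key]] <- TRUE
        break
      }
    }
    parent[i] <- ord[p]
  }
  edges <- unique(data.frame(parent = parent, child = child,
                             confidence = 1, stringsAsFactors = FALSE))
  dag <- gene_network(edges, nodes = genes)
  stopifnot(dag$is_dag)

  # GWAS labels enriched among descendants of half the hubs
  target_hubs <- hubs[seq_len(ceiling(n_hubs / 2))]
  desc <- unique(unlist(lapply(target_hubs, function(h)
    downstream_within(dag, h, n_genes))))
  non_desc <- setdiff(genes, c(desc, hubs))
  gwas <- c(desc[stats::runif(length(desc)) < gwas_rate * gwas_enrichment],
            non_desc[stats::runif(length(non_desc)) < gwas_rate])
  egenes <- union(hubs, sample(genes, ceiling(n_genes / 10)))

  structure(list(dag = dag,
                 hubs = gene_set(hubs, "hubs"),
                 gwas = gene_set(gwas, "gwas"),
                 egenes = gene_set(egenes, "egenes"),
                 order = ord,
                 params = list(n_genes = n_genes, n_hubs = n_hubs,
                               edge_density = edge_density, seed = seed,
                               hub_weight = hub_weight,
                               gwas_rate = gwas_rate,
                               gwas_enrichment = gwas_enrichment)),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "synthetic_truth: %d genes, %d edges, %d hubs, %d gwas, %d egenes\n",
    n_nodes(x$dag), n_edges(x$dag), length(x$hubs$members),
    length(x$gwas$members), length(x$egenes$members)))
  invisible(x)
}

#' Simulate expression from a ground-truth DAG
#'
#' Linear structural-equation sampling along the topological order: each
#' gene's latent value is `effect` times the mean of its parents' latent
#' values plus Gaussian noise of SD `noise_sd` (root genes are standard
#' normal). Latent values are exponentiated onto a non-negative, TPM-like
#' scale, so `log_transform()` followed by `discretize_kmeans()` recovers
#' informative three-level variables.
#'
#' @param truth A `synthetic_truth` from [simulate_dag()].
#' @param n_samples Number of samples (>= 10).
#' @param effect Parent-to-child effect size (default 1); 0 makes all genes
#'   independent.
#' @param noise_sd Gaussian noise SD (> 0, default 0.5).
#' @param seed Integer seed.
#' @return Genes x samples numeric matrix (TPM-like scale).
#' @export
simulate_expression <- function(truth, n_samples = 500, effect = 1,
                                noise_sd = 0.5, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"), n_samples >= 10)
  if (noise_sd <= 0) stop("noise_sd must be positive")
  set.seed(seed)
  ord <- truth$order
  edges <- truth$dag$edges
  parents <- split(edges$parent, edges$child)
  z <- matrix(0, length(ord), n_samples,
              dimnames = list(ord, sprintf("S%04d", seq_len(n_samples))))
  for (g in ord) {
    pa <- parents[[g]]
    mu <- if (length(pa)) effect * colMeans(z[pa, , drop = FALSE]) else 0
    z[g, ] <- mu + stats::rnorm(n_samples,
                                sd = if (length(pa)) noise_sd else 1)
  }
  mat <- exp(z)[sort(ord), , drop = FALSE]  # log-normal, TPM-like
  mat
}

#' Two replicate cohorts from one ground truth
#'
#' Draws two independent expression cohorts from the same DAG with
#' cohort-specific noise realizations; sample sizes may differ to emulate
#' unbalanced cohorts or sub-sampling experiments.
#'
#' @inheritParams simulate_expression
#' @param n_samples_a,n_samples_b Sample sizes of the two cohorts.
#' @return List with matrices `a` and `b`.
#' @export
make_replicates <- function(truth, n_samples_a = 500, n_samples_b = 500,
                            effect = 1, noise_sd = 0.5, seed = 1) {
  a <- simulate_expression(truth, n_samples_a, effect, noise_sd,
                           seed = seed * 2 + 1)
  b <- simulate_expression(truth, n_samples_b, effect, noise_sd,
                           seed = seed * 2 + 2)
  colnames(a) <- paste0("A_", colnames(a))
  colnames(b) <- paste0("B_", colnames(b))
  list(a = a, b = b)
}

#' Scale-free diagnostic network with power-law out-degrees
#'
#' Builds a directed network whose parent out-degrees are drawn from a
#' truncated discrete power law P(k) proportional to k^-`exponent` over
#' k = 1..`max_degree`, each parent wired to distinct random targets
#' (configuration-model style). This is the reference graph for checking
#' that [degree_exponent()] reports exponents in the 2--3 band typical of
#' biological networks: on such graphs the log-log line fit is consistent,
#' whereas finite growth-model graphs deviate from a pure power law in the
#' tail and bias any unbinned line fit downward.
#'
#' @param n_parents Number of nodes with out-edges (default 1500).
#' @param exponent Power-law exponent of the out-degree distribution
#'   (default 2.5).
#' @param max_degree Truncation point of the degree distribution
#'   (default 12).
#' @param seed Integer seed.
#' @return A `gene_network`.
#' @export
simulate_scale_free <- function(n_parents = 1500, exponent = 2.5,
                                max_degree = 12, seed = 1) {
  stopifnot(n_parents >= 10, exponent > 1, max_degree >= 3)
  set.seed(seed)
  ks <- seq_len(max_degree)
  p <- ks^(-exponent)
  deg <- sample(ks, n_parents, replace = TRUE, prob = p / sum(p))
  nodes <- sprintf("N%05d", seq_len(n_parents + ceiling(n_parents / 2)))
  parents <- nodes[seq_len(n_parents)]
  edges <- do.call(rbind, lapply(seq_len(n_parents), function(i) {
    tgt <- sample(setdiff(nodes, parents[i]), deg[i])
    data.frame(parent = parents[i], child = tgt, stringsAsFactors = FALSE)
  }))
  gene_network(edges, nodes = nodes)
}
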