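# Brute-force oracles kept deliberately independent of the package internals
# (boolean matrix algebra and direct enumeration, no igraph).

# random DAG: edges only from earlier to later nodes in a shuffled order
random_dag <- function(n, p = 0.15, seed = 1) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  ord <- sample(ids)
  from <- character()
  to <- character()
  for (i in seq_len(n - 1)) {
    later <- ord[(i + 1):n]
    pick <- later[stats::runif(length(later)) < p]
    from <- c(from, rep(ord[i], length(pick)))
    to <- c(to, pick)
  }
  if (!length(from)) {
    from <- ord[1]
    to <- ord[2]
  }
  gene_network(data.frame(parent = from, child = to), nodes = ids)
}

# adjacency matrix of a gene_network in a fixed node order
adjacency_of <- function(net) {
  nodes <- net$nodes
  A <- matrix(FALSE, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  if (nrow(net$edges)) A[cbind(net$edges$parent, net$edges$child)] <- TRUE
  A
}

# all-pairs shortest-path distances by boolean matrix powers
oracle_distances <- function(net) {
  A <- adjacency_of(net)
  n <- nrow(A)
  D <- matrix(Inf, n, n, dimnames = dimnames(A))
  reach <- A
  d <- 1
  while (d <= n) {
    newly <- reach & is.infinite(D)
    D[newly] <- d
    if (!any(newly)) break
    reach <- (reach %*% A) > 0
    d <- d + 1
  }
  diag(D) <- 0
  D
}

oracle_downstream_at <- function(net, gene, d) {
  D <- oracle_distances(net)
  names(which(D[gene, ] == d & colnames(D) != gene))
}

oracle_downstream_within <- function(net, gene, radius) {
  D <- oracle_distances(net)
  names(which(D[gene, ] >= 1 & D[gene, ] <= radius))
}

# average local clustering by direct triangle counting on the undirected
# projection
oracle_clustering <- function(net) {
  A <- adjacency_of(net)
  U <- (A | t(A))
  diag(U) <- FALSE
  local <- vapply(seq_len(nrow(U)), function(i) {
    nb <- which(U[i, ])
    if (length(nb) < 2) return(0)
    links <- sum(U[nb, nb]) / 2
    links / choose(length(nb), 2)
  }, numeric(1))
  mean(local)
}

oracle_path_length <- function(net) {
  D <- oracle_distances(net)
  vals <- D[is.finite(D) & D > 0]
  mean(vals)
}

# upper hypergeometric tail by direct term summation:
# P(X >= q) with K successes in a universe of N, drawing n
oracle_hyper_tail <- function(q, K, N, n) {
  ks <- seq(max(q, 0), min(K, n))
  if (!length(ks)) return(0)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

# skeleton (unordered adjacency) of a network as "a~b" strings
skeleton_of <- function(net) {
  if (!nrow(net$edges)) return(character())
  unique(apply(net$edges[, 1:2], 1, function(e)
    paste(sort(e), collapse = "~")))
}

# small simulated cohort ready for structure learning
make_learning_fixture <- function(n_genes = 20, n_samples = 500, seed = 7,
                                  n_hubs = 2, edge_density = 0.15) {
  truth <- simulate_dag(n_genes = n_genes, n_hubs = n_hubs,
                        edge_density = edge_density, seed = seed)
  mat <- simulate_expression(truth, n_samples = n_samples, seed = seed)
  logged <- log_transform(mat)
  disc <- suppressWarnings(discretize_kmeans(logged, seed = seed))
  priors <- correlation_priors(logged, egenes = truth$egenes)
  list(truth = truth, mat = mat, logged = logged, disc = disc,
       priors = priors)
}
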