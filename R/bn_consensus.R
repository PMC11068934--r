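#' Correlation and eQTL priors for structure learning
#'
#' Computes all pairwise Pearson correlations on the continuous expression
#' data; gene pairs whose correlation p-value falls below `alpha` become
#' mutual candidate parents, restricting the structure search. Genes with a
#' cis-eQTL ("eGenes") are flagged so that edges leaving them can receive a
#' score bonus during learning, encoding that genetically regulated genes are
#' more likely to be parent nodes.
#'
#' @param mat Genes x samples numeric matrix (continuous, typically
#'   log-transformed).
#' @param alpha Two-sided significance level for the correlation screen
#'   (default 0.01).
#' @param egenes Character vector (or [gene_set()]) of eGene identifiers.
#' @return A `prior_set`: list with `candidates` (symmetric logical gene x
#'   gene matrix, TRUE where the pair is a candidate edge), `egene` (named
#'   logical vector), `alpha` and `n_samples`.
#' @export
correlation_priors <- function(mat, alpha = 0.01, egenes = character()) {
  validate_expression(mat, allow_negative = TRUE)
  stopifnot(alpha > 0, alpha < 1)
  n <- ncol(mat)
  if (n < 3L) stop("need at least 3 samples for a correlation screen")
  if (inherits(egenes, "gene_set")) egenes <- egenes$members
  sds <- apply(mat, 1, stats::sd)
  constant <- sds == 0
  if (any(constant))
    warning(sum(constant), " constant gene(s) excluded from candidate ",
            "relations: ", paste(utils::head(rownames(mat)[constant], 5),
                                 collapse = ", "))
  r <- suppressWarnings(stats::cor(t(mat)))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(r) >= 1] <- 0
  cand <- !is.na(p) & p < alpha
  diag(cand) <- FALSE
  cand[constant, ] <- FALSE
  cand[, constant] <- FALSE
  cand <- cand | t(cand)  # symmetry before orientation
  eg <- stats::setNames(rownames(mat) %in% egenes, rownames(mat))
  structure(list(candidates = cand, egene = eg, alpha = alpha,
                 n_samples = n),
            class = "prior_set")
}

#' @export
print.prior_set <- function(x, ...) {
  cat(sprintf("prior_set: %d genes, %d candidate pairs, %d eGenes (alpha=%g)\n",
              nrow(x$candidates), sum(x$candidates) / 2, sum(x$egene),
              x$alpha))
  invisible(x)
}

#' Structure-learning configuration
#'
#' @param n_seeds Number of independently seeded hill-climbing runs merged
#'   into the consensus. 25 is a desk-scale default; production runs use
#'   1,000.
#' @param consensus_fraction Minimum fraction of runs an edge must appear in
#'   to be retained (default 0.30, inclusive).
#' @param max_parents In-degree cap during learning (default 3).
#' @param egene_bonus Additive score reduction per edge whose parent is an
#'   eGene (default 1); larger values favor eGene parents more strongly.
#' @param alpha Correlation-prior significance level (default 0.01).
#' @param max_moves Upper bound on accepted hill-climbing moves per run.
#' @return A `learn_config` list.
#' @export
learn_config <- function(n_seeds = 25, consensus_fraction = 0.30,
                         max_parents = 3, egene_bonus = 1, alpha = 0.01,
                         max_moves = 100000) {
  stopifnot(n_seeds >= 1, consensus_fraction > 0, consensus_fraction <= 1,
            max_parents >= 1, egene_bonus >= 0, max_moves >= 1)
  structure(list(n_seeds = as.integer(n_seeds),
                 consensus_fraction = consensus_fraction,
                 max_parents = as.integer(max_parents),
                 egene_bonus = egene_bonus, alpha = alpha,
                 max_moves = as.integer(max_moves)),
            class = "learn_config")
}

# multinomial log-likelihood of child's levels given joint parent
# configurations; D is an integer matrix with entries 1..3, rows = genes
family_loglik <- function(D, child, parents) {
  x <- D[child, ]
  if (length(parents) == 0L) {
    cnt <- tabulate(x, 3L)
  } else {
    cfg <- rep(1L, ncol(D))
    mult <- 1L
    for (p in parents) {
      cfg <- cfg + (D[p, ] - 1L) * mult
      mult <- mult * 3L
    }
    cnt <- tabulate((cfg - 1L) * 3L + x, 3L^length(parents) * 3L)
    cnt <- matrix(cnt, nrow = 3L)
  }
  if (is.matrix(cnt)) {
    tot <- colSums(cnt)
    nz <- cnt > 0
    sum(cnt[nz] * log(cnt[nz] / rep(tot, each = 3L)[nz]))
  } else {
    nz <- cnt > 0
    sum(cnt[nz] * log(cnt[nz] / sum(cnt)))
  }
}

#' BIC score of one node family
#'
#' The family score of `node` given `parents` is
#' `bic = k * ln(n) - 2 * ln(L)`, where `L` is the maximized multinomial
#' likelihood of the node's three-level values under each joint parent
#' configuration (maximum-likelihood conditional-probability-table
#' estimates), `k = 2 * 3^|parents|` free parameters, and `n` the number of
#' samples. Lower is better; the total network score is the sum of family
#' scores minus the eGene bonus for each eGene-parented edge.
#'
#' @param disc A `discrete_matrix` from [discretize_kmeans()].
#' @param node Child gene identifier.
#' @param parents Character vector of parent gene identifiers (possibly
#'   empty).
#' @return A `family_score` list: `node`, `parents`, `log_likelihood`,
#'   `param_count`, `sample_count`, `bic`.
#' @export
family_bic <- function(disc, node, parents = character()) {
  if (!node %in% rownames(disc)) stop("unknown node: ", node)
  if (!all(parents %in% rownames(disc)))
    stop("unknown parent(s): ",
         paste(setdiff(parents, rownames(disc)), collapse = ", "))
  if (node %in% parents) stop("a node cannot be its own parent")
  D <- unclass(disc)
  ll <- family_loglik(D, match(node, rownames(disc)),
                      match(parents, rownames(disc)))
  k <- 2 * 3^length(parents)
  n <- ncol(disc)
  structure(list(node = node, parents = parents, log_likelihood = ll,
                 param_count = k, sample_count = n,
                 bic = k * log(n) - 2 * ll),
            class = "family_score")
}

# all single-parent family BICs at once: bic1[u, v] is the BIC of family
# (v | u). Uses 3x3 level contingency tables computed as indicator-matrix
# products, so the G^2 scores cost 9 BLAS multiplications.
pair_bic1 <- function(D) {
  G <- nrow(D)
  n <- ncol(D)
  ind <- lapply(1:3, function(l) (D == l) * 1)
  s_joint <- matrix(0, G, G)
  marg <- matrix(0, G, 3)
  for (a in 1:3) {
    ca <- rowSums(ind[[a]])
    marg[, a] <- ifelse(ca > 0, ca * log(ca), 0)
    for (b in 1:3) {
      N <- ind[[a]] %*% t(ind[[b]])  # parent level a, child level b
      s_joint <- s_joint + ifelse(N > 0, N * log(N), 0)
    }
  }
  # ll(v|u) = sum_ab N_ab log N_ab - sum_a N_a. log N_a.
  ll <- s_joint - rowSums(marg)
  6 * log(n) - 2 * ll
}

# TRUE if `to` is reachable from `from` along children lists (DFS)
reachable_idx <- function(children, from, to, n) {
  if (from == to) return(TRUE)
  seen <- logical(n)
  stack <- from
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (seen[v]) next
    seen[v] <- TRUE
    kids <- children[[v]]
    if (length(kids)) {
      if (any(kids == to)) return(TRUE)
      stack <- c(stack, kids[!seen[kids]])
    }
  }
  FALSE
}

#' Learn a single Bayesian network structure by hill climbing
#'
#' Greedy score-based search over edge additions, deletions and reversals,
#' restricted to the correlation-prior candidate pairs. The total score is
#' the sum of family BIC scores minus `egene_bonus` for every edge whose
#' parent is an eGene; at each step the move giving the largest score
#' decrease is applied, subject to acyclicity and an in-degree of at most
#' `max_parents`, until no move improves the score (or `config$max_moves`
#' is hit). Near-tied moves (within `1e-6`) are broken by a random order
#' drawn from `seed`, which is how independently seeded runs explore
#' different local optima before [consensus_merge()].
#'
#' @param disc A `discrete_matrix` (genes x samples, levels 1..3).
#' @param priors A `prior_set` over the same genes.
#' @param config A [learn_config()].
#' @param seed Integer seed for the tie-breaking order.
#' @return A `gene_network` DAG (edge confidence 1).
#' @export
learn_single <- function(disc, priors, config = learn_config(), seed = 1) {
  genes <- rownames(disc)
  if (length(genes) == 0L) stop("no genes to learn over")
  if (!identical(sort(genes), sort(rownames(priors$candidates))))
    stop("priors and data cover different genes")
  G <- length(genes)
  D <- unclass(disc)
  cand <- priors$candidates[genes, genes, drop = FALSE]
  eg <- priors$egene[genes]
  bonus <- config$egene_bonus
  maxp <- config$max_parents

  pairs <- which(cand, arr.ind = TRUE)  # ordered (u, v) candidates
  dimnames(pairs) <- NULL
  n_pairs <- nrow(pairs)
  if (n_pairs == 0L) return(gene_network(nodes = genes))
  pu <- pairs[, 1]
  pv <- pairs[, 2]
  by_child <- split(seq_len(n_pairs), pv)
  pair_id <- matrix(0L, G, G)
  pair_id[pairs] <- seq_len(n_pairs)

  parents <- rep(list(integer()), G)
  children <- rep(list(integer()), G)
  has_edge <- matrix(FALSE, G, G)
  n <- ncol(D)
  base <- vapply(seq_len(G), function(i)
    2 * log(n) - 2 * family_loglik(D, i, integer()), numeric(1))
  B1 <- pair_bic1(D)                    # all single-parent family scores
  score_cache <- new.env(hash = TRUE, parent = emptyenv())
  fam <- function(child, pa) {
    np <- length(pa)
    if (np == 0L) return(base[child])
    if (np == 1L) return(B1[pa, child])
    # pa order is state-determined, so unsorted keys stay consistent
    key <- paste0(child, "|", paste(pa, collapse = ","))
    val <- score_cache[[key]]
    if (is.null(val)) {
      val <- 2 * 3^np * log(n) - 2 * family_loglik(D, child, pa)
      score_cache[[key]] <- val
    }
    val
  }
  fscore <- base

  # Candidate-addition deltas, kept current per child; `closed` records why
  # a pair is not currently addable (1 edge present, 2 reverse edge present,
  # 3 child at max_parents, 4 would close a cycle) and `eff` carries +Inf
  # for closed pairs so the best open addition is a which.min away.
  set.seed(seed)
  tie_noise <- stats::runif(n_pairs, 0, 1e-7)  # seed-dependent tie-breaking
  add_delta <- function(i) {
    fam(pv[i], c(parents[[pv[i]]], pu[i])) - fscore[pv[i]] -
      bonus * eg[pu[i]] + tie_noise[i]
  }
  deltas <- B1[pairs] - fscore[pv] - bonus * eg[pu] + tie_noise
  closed <- integer(n_pairs)
  eff <- deltas
  close_pair <- function(i, code) {
    closed[i] <<- code
    eff[i] <<- Inf
  }
  open_pair <- function(i) {
    closed[i] <<- 0L
    eff[i] <<- deltas[i]
  }
  refresh_child <- function(v) {
    for (i in by_child[[as.character(v)]]) {
      deltas[i] <<- add_delta(i)
      if (closed[i] == 0L) eff[i] <<- deltas[i]
    }
  }
  reopen_blocked <- function() {      # cycle/in-degree blocks can lapse
    for (i in which(closed >= 3L)) open_pair(i)
  }

  moves <- 0L
  eps <- 1e-9
  repeat {
    best <- NULL
    best_delta <- -eps

    # deletions / reversals of current edges
    for (v in seq_len(G)) {
      for (u in parents[[v]]) {
        pa_del <- setdiff(parents[[v]], u)
        s_del <- fam(v, pa_del)
        d_del <- s_del - fscore[v] + bonus * eg[u]
        if (d_del < best_delta) {
          best <- list(kind = "del", u = u, v = v, s_del = s_del)
          best_delta <- d_del
        }
        if (length(parents[[u]]) < maxp && cand[v, u]) {
          s_u <- fam(u, c(parents[[u]], v))
          d_rev <- (s_del - fscore[v]) + (s_u - fscore[u]) +
            bonus * eg[u] - bonus * eg[v]
          if (d_rev < best_delta) {
            # acyclic only if no alternative directed path u ~> v remains
            children[[u]] <- setdiff(children[[u]], v)
            ok <- !reachable_idx(children, u, v, G)
            children[[u]] <- c(children[[u]], v)
            if (ok) {
              best <- list(kind = "rev", u = u, v = v, s_del = s_del,
                           s_u = s_u)
              best_delta <- d_rev
            }
          }
        }
      }
    }

    # additions: pop the best open pair, closing invalid ones as found
    repeat {
      i <- which.min(eff)
      if (eff[i] >= best_delta) break
      u <- pu[i]; v <- pv[i]
      if (has_edge[u, v]) close_pair(i, 1L)
      else if (has_edge[v, u]) close_pair(i, 2L)
      else if (length(parents[[v]]) >= maxp) close_pair(i, 3L)
      else if (reachable_idx(children, v, u, G)) close_pair(i, 4L)
      else {
        best <- list(kind = "add", u = u, v = v)
        best_delta <- eff[i]
        break
      }
    }

    if (is.null(best)) break
    u <- best$u; v <- best$v
    if (best$kind == "add") {
      parents[[v]] <- c(parents[[v]], u)
      children[[u]] <- c(children[[u]], v)
      has_edge[u, v] <- TRUE
      fscore[v] <- fam(v, parents[[v]])
      close_pair(pair_id[u, v], 1L)
      rid <- pair_id[v, u]
      if (rid > 0L && closed[rid] == 0L) close_pair(rid, 2L)
      refresh_child(v)
    } else if (best$kind == "del") {
      parents[[v]] <- setdiff(parents[[v]], u)
      children[[u]] <- setdiff(children[[u]], v)
      has_edge[u, v] <- FALSE
      fscore[v] <- best$s_del
      reopen_blocked()
      open_pair(pair_id[u, v])
      rid <- pair_id[v, u]
      if (rid > 0L && closed[rid] == 2L) open_pair(rid)
      refresh_child(v)
    } else {                                          # reversal
      children[[u]] <- setdiff(children[[u]], v)
      parents[[v]] <- setdiff(parents[[v]], u)
      parents[[u]] <- c(parents[[u]], v)
      children[[v]] <- c(children[[v]], u)
      has_edge[u, v] <- FALSE
      has_edge[v, u] <- TRUE
      fscore[v] <- best$s_del
      fscore[u] <- best$s_u
      reopen_blocked()
      close_pair(pair_id[v, u], 1L)
      close_pair(pair_id[u, v], 2L)
      refresh_child(v)
      refresh_child(u)
    }
    moves <- moves + 1L
    if (moves >= config$max_moves) break
  }

  ne <- sum(lengths(parents))
  if (ne == 0L) return(gene_network(nodes = genes))
  edges <- data.frame(
    parent = genes[unlist(parents, use.names = FALSE)],
    child = rep(genes, lengths(parents)),
    confidence = 1,
    stringsAsFactors = FALSE)
  gene_network(edges, nodes = genes)
}

#' Merge networks into a consensus by edge frequency
#'
#' An edge is retained iff it occurs in at least `fraction` of the input
#' networks (inclusive threshold); its confidence becomes that occurrence
#' frequency. The merged graph may contain cycles; follow with
#' [break_cycles()] to restore acyclicity.
#'
#' @param networks List of `gene_network`s over a shared gene universe.
#' @param fraction Minimum occurrence frequency in (0, 1] (default 0.30).
#' @return A `gene_network` whose node set is the union of the inputs'.
#' @export
consensus_merge <- function(networks, fraction = 0.30) {
  if (length(networks) == 0L) stop("no networks to merge")
  stopifnot(fraction > 0, fraction <= 1)
  all_nodes <- sort(unique(unlist(lapply(networks, `[[`, "nodes"))))
  keys <- unlist(lapply(networks, function(net)
    unique(paste(net$edges$parent, net$edges$child, sep = "\r"))))
  if (length(keys) == 0L) return(gene_network(nodes = all_nodes))
  freq <- table(keys) / length(networks)
  keep <- freq >= fraction - 1e-12
  if (!any(keep)) return(gene_network(nodes = all_nodes))
  pc <- strsplit(names(freq)[keep], "\r", fixed = TRUE)
  gene_network(data.frame(
    parent = vapply(pc, `[`, character(1), 1L),
    child = vapply(pc, `[`, character(1), 2L),
    confidence = as.numeric(freq[keep]),
    stringsAsFactors = FALSE), nodes = all_nodes)
}

#' Remove directed cycles from a consensus network
#'
#' While any directed cycle remains, the minimum-confidence edge lying on a
#' cycle (an edge inside a non-trivial strongly connected component) is
#' removed; ties break on the lexicographically smallest (parent, child)
#' pair. The result is a DAG; the removed edges are attached as the
#' `removed_edges` attribute (retrievable with [removed_edges()]).
#'
#' @param net A `gene_network` with confidence-weighted edges.
#' @return An acyclic `gene_network`.
#' @export
break_cycles <- function(net) {
  edges <- net$edges
  removed <- edges[0, ]
  repeat {
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = net$nodes)
    if (igraph::is_dag(g)) break
    comp <- igraph::components(g, mode = "strong")
    memb <- comp$membership[net$nodes]
    csize <- stats::setNames(comp$csize[memb], names(memb))
    on_cycle <- memb[edges$parent] == memb[edges$child] &
      csize[edges$parent] >= 2
    idx <- which(on_cycle)
    idx <- idx[order(edges$confidence[idx], edges$parent[idx],
                     edges$child[idx])][1]
    removed <- rbind(removed, edges[idx, ])
    edges <- edges[-idx, , drop = FALSE]
  }
  out <- gene_network(edges, nodes = net$nodes)
  rownames(removed) <- NULL
  attr(out, "removed_edges") <- removed
  out
}

#' @rdname break_cycles
#' @return `removed_edges()` returns the data frame of edges deleted by the
#'   last [break_cycles()] call (empty if none).
#' @export
removed_edges <- function(net) {
  r <- attr(net, "removed_edges")
  if (is.null(r)) net$edges[0, ] else r
}

#' Consensus Bayesian network from multi-seed hill climbing
#'
#' Runs [learn_single()] under `config$n_seeds` different seeds, merges the
#' resulting structures with [consensus_merge()] at
#' `config$consensus_fraction`, and removes any cycles with
#' [break_cycles()].
#'
#' @inheritParams learn_single
#' @param seed Base integer seed; run i uses `seed + i`.
#' @param keep_runs Keep the per-seed networks in the result (default FALSE).
#' @return A `consensus_fit` list: `network` (final DAG), `merged` (the
#'   thresholded consensus before cycle removal), `removed_edges`, `n_seeds`,
#'   `fraction`, and optionally `runs`.
#' @export
learn_consensus <- function(disc, priors, config = learn_config(), seed = 1,
                            keep_runs = FALSE) {
  runs <- lapply(seq_len(config$n_seeds),
                 function(i) learn_single(disc, priors, config, seed + i))
  merged <- consensus_merge(runs, config$consensus_fraction)
  dag <- break_cycles(merged)
  structure(list(network = dag, merged = merged,
                 removed_edges = removed_edges(dag),
                 n_seeds = config$n_seeds,
                 fraction = config$consensus_fraction,
                 runs = if (keep_runs) runs),
            class = "consensus_fit")
}

#' @export
print.consensus_fit <- function(x, ...) {
  cat(sprintf(
    "consensus_fit: %d seeds, threshold %.2f -> %d edges (%d cycle edges removed)\n",
    x$n_seeds, x$fraction, n_edges(x$network), nrow(x$removed_edges)))
  invisible(x)
}
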