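#' Run the full analysis for one sample group
#'
#' One end-to-end pass of the workflow for a single sex/depot/cohort group:
#' low-expression filtering, log transform, discretization, correlation/eQTL
#' priors, multi-seed consensus structure learning, topology diagnostics and
#' key-driver analysis. All parameters and the seed are recorded in the
#' returned log so runs are reproducible.
#'
#' @param mat Genes x samples expression matrix (TPM scale) for the group.
#' @param gwas GWAS candidate [gene_set()] (or character vector).
#' @param egenes eGene identifiers used as parent-node priors.
#' @param config A [learn_config()].
#' @param seed Integer seed driving discretization, learning and subsampling.
#' @param subsample Optional target sample count; samples are drawn without
#'   replacement before any other step (emulating cohort size-matching
#'   experiments).
#' @param filter_threshold,filter_fraction Low-expression filter settings
#'   (see [filter_low_expression()]).
#' @param kda Named list of overrides for [key_drivers()] parameters
#'   (`weights`, `decile`, `radius`, `alpha`, `adjust`).
#' @param out_dir Optional directory; when given, the consensus edge list,
#'   score and enrichment tables, topology report and key-driver list are
#'   written there as plain-text tables.
#' @return A `group_run`: list with `network` (consensus DAG), `fit`
#'   (the `consensus_fit`), `topology`, `kda` (`key_driver_result`),
#'   `summary` (one-row data frame: genes_connected, edges, key_drivers)
#'   and `log` (parameters, seed, dimensions).
#' @export
run_group <- function(mat, gwas, egenes = character(),
                      config = learn_config(), seed = 1, subsample = NULL,
                      filter_threshold = 0.1, filter_fraction = 0.8,
                      kda = list(), out_dir = NULL) {
  validate_expression(mat)
  if (!is.null(subsample)) {
    if (subsample > ncol(mat)) stop("subsample exceeds available samples")
    set.seed(seed)
    mat <- mat[, sort(sample.int(ncol(mat), subsample)), drop = FALSE]
  }
  filtered <- filter_low_expression(mat, filter_threshold, filter_fraction)
  logged <- log_transform(filtered)
  disc <- discretize_kmeans(logged, seed = seed)
  priors <- correlation_priors(logged, alpha = config$alpha, egenes = egenes)
  fit <- learn_consensus(disc, priors, config, seed = seed)
  net <- fit$network
  topo <- tryCatch(compare_to_random(net, n_random = 10, seed = seed),
                   error = function(e) NULL)
  kda_args <- utils::modifyList(
    list(net = net, gwas = gwas), kda)
  result <- do.call(key_drivers, kda_args)
  connected <- unique(c(net$edges$parent, net$edges$child))
  summary_row <- data.frame(genes_connected = length(connected),
                            edges = n_edges(net),
                            key_drivers = length(result$key_drivers))
  run <- structure(list(network = net, fit = fit, topology = topo,
                        kda = result, summary = summary_row,
                        log = list(seed = seed, config = config,
                                   subsample = subsample,
                                   filter_threshold = filter_threshold,
                                   filter_fraction = filter_fraction,
                                   n_genes_input = nrow(mat),
                                   n_genes_filtered = nrow(filtered),
                                   n_samples = ncol(mat))),
                   class = "group_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_edge_list(net, file.path(out_dir, "consensus_edges.tsv"))
    utils::write.table(result$scores, file.path(out_dir, "gene_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(result$enrichment,
                       file.path(out_dir, "type2_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_gene_set(result$key_drivers, file.path(out_dir, "key_drivers.txt"))
    if (!is.null(topo))
      write_topology_report(topo, file.path(out_dir, "topology.tsv"))
    utils::write.table(fit$removed_edges,
                       file.path(out_dir, "removed_cycle_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  run
}

#' @export
print.group_run <- function(x, ...) {
  cat("group_run:\n")
  print(x$summary)
  invisible(x)
}

#' Compare key drivers between two group runs
#'
#' Shared key drivers between two completed analyses plus the permutation
#' null for the size of that overlap: each network contributes a random draw
#' (of its key-driver count) from its connected genes, repeated
#' `replicates` times.
#'
#' @param run_a,run_b `group_run` objects from [run_group()].
#' @param replicates Null draws (default 10,000).
#' @param seed Integer seed.
#' @return List with `shared` (character vector), `overlap_test`
#'   (an `overlap_test`) and `summary` (one-row data frame).
#' @export
compare_cohorts <- function(run_a, run_b, replicates = 10000, seed = 1) {
  ka <- run_a$kda$key_drivers
  kb <- run_b$kda$key_drivers
  ua <- unique(c(run_a$network$edges$parent, run_a$network$edges$child))
  ub <- unique(c(run_b$network$edges$parent, run_b$network$edges$child))
  if (length(intersect(ua, ub)) == 0L)
    warning("the two runs share no connected gene identifiers")
  shared <- shared_key_drivers(ka, kb)
  test <- overlap_null(ua, ub, length(ka), length(kb),
                       observed = length(shared),
                       replicates = replicates, seed = seed)
  list(shared = shared, overlap_test = test,
       summary = data.frame(key_drivers_a = length(ka),
                            key_drivers_b = length(kb),
                            shared = length(shared),
                            null_mean = test$null_mean,
                            empirical_p = test$empirical_p))
}

#' Pairwise key-driver overlap matrix
#'
#' Overlap counts (and permutation p-values) for every pair in a named list
#' of group runs, mirroring replication comparisons across cohorts, sexes
#' and depots.
#'
#' @param runs Named list of `group_run` objects.
#' @inheritParams compare_cohorts
#' @return Data frame with one row per unordered pair: `a`, `b`, `shared`,
#'   `null_mean`, `empirical_p`.
#' @export
overlap_matrix <- function(runs, replicates = 10000, seed = 1) {
  stopifnot(length(runs) >= 2, !is.null(names(runs)))
  pairs <- utils::combn(names(runs), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    cc <- compare_cohorts(runs[[pairs[1, i]]], runs[[pairs[2, i]]],
                          replicates = replicates, seed = seed + i)
    data.frame(a = pairs[1, i], b = pairs[2, i], cc$summary)
  })
  do.call(rbind, rows)
}

#' Prioritize shared key drivers with annotation filters
#'
#' Applies the three-step selection used to turn replicated key drivers into
#' testable candidates, as pure set operations over a user-supplied
#' annotation table: (1) keep genes expressed in the target cell type,
#' (2) drop genes with known function in that tissue, (3) keep genes with
#' genetic evidence (GWAS candidate or mouse knockout phenotype). Genes
#' missing from the annotation table are treated as all-FALSE with a
#' warning.
#'
#' @param shared Character vector of (shared) key-driver genes.
#' @param annotations Data frame with columns `gene`,
#'   `expressed_in_target`, `known_function`, `gwas_candidate`,
#'   `mouse_phenotype` (logical flags).
#' @return List with `prioritized` (character vector) and `steps` (data
#'   frame of gene counts after each filter).
#' @export
prioritize_key_drivers <- function(shared, annotations) {
  need <- c("gene", "expressed_in_target", "known_function",
            "gwas_candidate", "mouse_phenotype")
  if (!all(need %in% names(annotations)))
    stop("annotation table needs columns: ", paste(need, collapse = ", "))
  shared <- unique(as.character(shared))
  missing <- setdiff(shared, annotations$gene)
  if (length(missing)) {
    warning(length(missing), " gene(s) missing from the annotation table ",
            "treated as flag-false: ",
            paste(utils::head(missing, 5), collapse = ", "))
    annotations <- rbind(annotations[need],
                         data.frame(gene = missing,
                                    expressed_in_target = FALSE,
                                    known_function = FALSE,
                                    gwas_candidate = FALSE,
                                    mouse_phenotype = FALSE))
  }
  ann <- annotations[match(shared, annotations$gene), ]
  step1 <- shared[ann$expressed_in_target %in% TRUE]
  ann1 <- ann[match(step1, ann$gene), ]
  step2 <- step1[!(ann1$known_function %in% TRUE)]
  ann2 <- ann[match(step2, ann$gene), ]
  step3 <- step2[(ann2$gwas_candidate %in% TRUE) |
                   (ann2$mouse_phenotype %in% TRUE)]
  list(prioritized = step3,
       steps = data.frame(
         step = c("input", "expressed_in_target", "novel_function",
                  "genetic_evidence"),
         n = c(length(shared), length(step1), length(step2),
               length(step3))))
}
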