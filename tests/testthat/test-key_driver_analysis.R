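test_that("downstream profiles enumerate the chain example", {
  chain <- gene_network(data.frame(parent = c("A", "B"), child = c("B", "C")))
  prof <- downstream_profile(chain)
  expect_equal(unname(prof$counts["A", 1:3]), c(1, 1, 0))
  expect_equal(unname(prof$counts["B", 1:2]), c(1, 0))
  expect_equal(sum(prof$counts["C", ]), 0)
  expect_equal(unname(prof$network_mean[1]), 2 / 3)
  # each edge is counted exactly once at distance 1
  expect_equal(sum(prof$counts[, 1]), n_edges(chain))

  net <- random_dag(25, p = 0.15, seed = 3)
  prof2 <- downstream_profile(net)
  expect_equal(sum(prof2$counts[, 1]), n_edges(net))
  # population SD
  expect_equal(unname(prof2$network_sd[1]),
               sqrt(mean((prof2$counts[, 1] - mean(prof2$counts[, 1]))^2)))
})

test_that("GeneScore weights sum to 4.71875 for unit z-scores", {
  counts <- matrix(0L, 10, 10,
                   dimnames = list(sprintf("g%02d", 1:10), paste0("d", 1:10)))
  counts["g01", 1:9] <- 1L
  profile <- structure(list(counts = counts,
                            network_mean = rep(0, 10),
                            network_sd = rep(1, 10),
                            max_distance = 10),
                       class = "kda_profile")
  t1 <- type1_scores(profile)
  expect_equal(t1$scores$gene_score[t1$scores$gene == "g01"], 4.71875)

  # linearity: doubling all weights doubles scores, same type-1 set
  t2 <- type1_scores(profile, weights = 2 * kda_weights())
  expect_equal(t2$scores$gene_score[order(t2$scores$gene)],
               2 * t1$scores$gene_score[order(t1$scores$gene)])
  expect_setequal(t2$type1, t1$type1)
  expect_error(type1_scores(profile, weights = rep(1, 11)), "distances")
})

test_that("degenerate and tied profiles follow the inclusion rules", {
  # identical profiles: all SDs zero, all scores zero, everyone tied in
  n <- 12
  counts <- matrix(3L, n, 10,
                   dimnames = list(sprintf("g%02d", 1:n), paste0("d", 1:10)))
  prof <- structure(list(counts = counts, network_mean = rep(3, 10),
                         network_sd = rep(0, 10), max_distance = 10),
                    class = "kda_profile")
  t1 <- type1_scores(prof)
  expect_true(all(t1$scores$gene_score == 0))
  expect_length(t1$type1, n)  # boundary ties are all included

  # without ties, exactly ceiling(decile * N) genes
  set.seed(8)
  net <- random_dag(40, p = 0.2, seed = 8)
  res <- type1_scores(downstream_profile(net))
  expect_gte(length(res$type1), ceiling(0.1 * 40))
})

test_that("a hub's GeneScore matches independent z-score arithmetic", {
  leaves <- sprintf("leaf%02d", 1:99)
  star <- gene_network(data.frame(parent = "hub", child = leaves))
  prof <- downstream_profile(star)
  res <- type1_scores(prof)
  # oracle: compute mean/SD of the d=1 counts by hand; only d=1 is nonzero
  g1 <- c(99, rep(0, 99))
  z <- (99 - mean(g1)) / sqrt(mean((g1 - mean(g1))^2))
  expect_equal(res$scores$gene_score[res$scores$gene == "hub"], z * 1)
  expect_true("hub" %in% res$type1)
})

test_that("type-2 p-values equal the exact hypergeometric tail", {
  # worked 2x2 example: universe 99 after excluding the focal gene,
  # 10 GWAS genes, neighborhood of 10 holding 5 of them
  p_expect <- oracle_hyper_tail(5, 10, 99, 10)
  nodes <- c("focal", sprintf("v%02d", 1:99))
  nb <- sprintf("v%02d", 1:10)
  gwas <- c(sprintf("v%02d", 6:10), sprintf("v%02d", 90:94))
  net <- gene_network(data.frame(parent = "focal", child = nb),
                      nodes = nodes)
  t2 <- type2_enrichment(net, gwas, radius = 1)
  expect_equal(t2$table$p[t2$table$gene == "focal"], p_expect,
               tolerance = 1e-12)

  # zero overlap and whole-universe neighborhoods are never enriched
  net0 <- gene_network(data.frame(parent = "f", child = c("a", "b")),
                       nodes = c("f", "a", "b", "g1", "g2"))
  t0 <- type2_enrichment(net0, c("g1", "g2"))
  expect_equal(t0$table$p[t0$table$gene == "f"], 1)
  chain_all <- gene_network(data.frame(parent = c("r", "m"),
                                       child = c("m", "g")))
  tall <- type2_enrichment(chain_all, "g", radius = 4)
  expect_equal(tall$table$p[tall$table$gene == "r"], 1)
  expect_error(type2_enrichment(net0, "absent"), "universe")
})

test_that("type-2 agrees with fisher.test and enumeration across whole networks", {
  for (s in 1:4) {
    net <- random_dag(sample(20:60, 1), p = 0.12, seed = 300 + s)
    set.seed(s)
    gwas <- sample(net$nodes, 8)
    t2 <- type2_enrichment(net, gwas)
    N <- length(net$nodes) - 1
    for (row in seq_len(nrow(t2$table))) {
      g <- t2$table$gene[row]
      K <- sum(gwas != g)
      n_nb <- t2$table$neighborhood[row]
      q <- t2$table$gwas_overlap[row]
      expect_equal(t2$table$p[row], oracle_hyper_tail(q, K, N, n_nb),
                   tolerance = 1e-12)
    }
    # spot-check one informative gene against fisher.test
    row <- which.max(t2$table$gwas_overlap)
    g <- t2$table$gene[row]
    inside <- downstream_within(net, g, 4)
    outside <- setdiff(net$nodes, c(inside, g))
    tab <- matrix(c(sum(inside %in% gwas), sum(!inside %in% gwas),
                    sum(outside %in% gwas), sum(!outside %in% gwas)), 2)
    expect_equal(t2$table$p[row],
                 fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("key drivers are the union of both types and shared sets intersect", {
  truth <- simulate_dag(n_genes = 120, n_hubs = 4, edge_density = 0.025,
                        seed = 17)
  res <- key_drivers(truth$dag, truth$gwas)
  expect_setequal(res$key_drivers, union(res$type1, res$type2))
  expect_true(all(truth$hubs$members %in% res$type1))

  expect_setequal(shared_key_drivers(c("A", "B", "C"), c("B", "C", "D")),
                  c("B", "C"))
  expect_length(shared_key_drivers(c("A"), c("B")), 0)
  other <- key_drivers(truth$dag, truth$gwas, decile = 0.2)
  sh <- shared_key_drivers(res, other)
  expect_true(all(sh %in% res$key_drivers))
  expect_true(all(sh %in% other$key_drivers))
})

test_that("BH adjustment is available for type-2 significance", {
  net <- random_dag(40, p = 0.15, seed = 23)
  set.seed(23)
  gwas <- sample(net$nodes, 10)
  raw <- type2_enrichment(net, gwas, adjust = "none")
  bh <- type2_enrichment(net, gwas, adjust = "BH")
  expect_equal(bh$table$p[order(bh$table$gene)],
               raw$table$p[order(raw$table$gene)])
  expect_true(all(bh$type2 %in% raw$type2))
})
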