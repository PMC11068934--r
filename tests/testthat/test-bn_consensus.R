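test_that("correlation priors flag dependent pairs and calibrate to alpha", {
  set.seed(1)
  n <- 100
  x <- rnorm(n)
  mat <- rbind(x = x, y = x + rnorm(n, sd = 0.2), z = rnorm(n))
  colnames(mat) <- sprintf("s%03d", 1:n)
  pri <- correlation_priors(mat, egenes = "x")
  expect_true(pri$candidates["x", "y"])
  expect_true(pri$candidates["y", "x"])   # symmetric
  expect_false(any(diag(pri$candidates))) # never own candidate
  expect_true(pri$egene["x"] && !pri$egene["y"])

  # false-positive rate of the screen near alpha for independent pairs
  hits <- 0; total <- 0
  for (s in 1:30) {
    set.seed(s)
    ind <- matrix(rnorm(20 * n), 20, n,
                  dimnames = list(sprintf("g%02d", 1:20),
                                  sprintf("s%03d", 1:n)))
    cp <- correlation_priors(ind)$candidates
    hits <- hits + sum(cp[upper.tri(cp)])
    total <- total + sum(upper.tri(cp))
  }
  expect_gt(hits / total, 0.002)
  expect_lt(hits / total, 0.03)

  # constant genes excluded with warning
  cmat <- rbind(mat, flat = rep(2, n))
  expect_warning(pc <- correlation_priors(cmat), "constant")
  expect_false(any(pc$candidates["flat", ]))
})

test_that("family BIC matches the closed forms", {
  # 90 samples spread uniformly over the three levels, no parents
  lv <- matrix(rep(1:3, each = 30), nrow = 1,
               dimnames = list("u", sprintf("s%02d", 1:90)))
  disc <- structure(lv, class = c("discrete_matrix", "matrix", "array"))
  fs <- family_bic(disc, "u")
  expect_equal(fs$log_likelihood, 90 * log(1 / 3))
  expect_equal(fs$param_count, 2)
  expect_equal(fs$bic, 2 * log(90) - 180 * log(1 / 3))

  # deterministic constant node: probability-1 outcomes
  const <- structure(matrix(2L, 1, 50, dimnames = list("c", sprintf("s%02d", 1:50))),
                     class = c("discrete_matrix", "matrix", "array"))
  fc <- family_bic(const, "c")
  expect_equal(fc$log_likelihood, 0)
  expect_equal(fc$bic, 2 * log(50))

  # invariant: bic = k ln n - 2 lnL and k = 2 * 3^|parents|
  set.seed(2)
  D <- structure(matrix(sample(1:3, 3 * 40, replace = TRUE), 3, 40,
                        dimnames = list(c("a", "b", "c"),
                                        sprintf("s%02d", 1:40))),
                 class = c("discrete_matrix", "matrix", "array"))
  f2 <- family_bic(D, "a", c("b", "c"))
  expect_equal(f2$param_count, 18)
  expect_equal(f2$bic, 18 * log(40) - 2 * f2$log_likelihood)
  expect_error(family_bic(D, "a", "a"), "own parent")
  expect_error(family_bic(D, "nope"), "unknown")
})

test_that("an independent parent worsens the family BIC at n = 500", {
  set.seed(3)
  D <- structure(matrix(sample(1:3, 2 * 500, replace = TRUE), 2, 500,
                        dimnames = list(c("child", "noise"),
                                        sprintf("s%03d", 1:500))),
                 class = c("discrete_matrix", "matrix", "array"))
  alone <- family_bic(D, "child")
  with_noise <- family_bic(D, "child", "noise")
  expect_gt(with_noise$param_count, alone$param_count)
  expect_gt(with_noise$bic, alone$bic)
})

test_that("hill climbing finds strong dependence and ignores independence", {
  set.seed(4)
  n <- 500
  a <- sample(1:3, n, replace = TRUE)
  b <- ifelse(runif(n) < 0.9, a, sample(1:3, n, replace = TRUE))
  D <- structure(rbind(A = a, B = b),
                 class = c("discrete_matrix", "matrix", "array"))
  colnames(D) <- sprintf("s%03d", 1:n)
  cand <- matrix(TRUE, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  diag(cand) <- FALSE
  pri <- structure(list(candidates = cand,
                        egene = c(A = FALSE, B = FALSE),
                        alpha = 0.01, n_samples = n),
                   class = "prior_set")
  net <- learn_single(D, pri, learn_config(), seed = 1)
  expect_equal(nrow(net$edges), 1)  # either orientation
  expect_true(net$is_dag)

  # mutually independent genes: (almost) no edges survive
  set.seed(5)
  Di <- structure(matrix(sample(1:3, 10 * 500, replace = TRUE), 10, 500,
                         dimnames = list(sprintf("g%02d", 1:10),
                                         sprintf("s%03d", 1:500))),
                  class = c("discrete_matrix", "matrix", "array"))
  candi <- matrix(TRUE, 10, 10, dimnames = dimnames(Di)[c(1, 1)])
  diag(candi) <- FALSE
  prii <- structure(list(candidates = candi,
                         egene = setNames(rep(FALSE, 10), rownames(Di)),
                         alpha = 0.01, n_samples = 500),
                    class = "prior_set")
  neti <- learn_single(Di, prii, learn_config(), seed = 1)
  expect_lte(nrow(neti$edges), ceiling(0.05 * 45))
})

test_that("total score decomposes over node families", {
  fx <- make_learning_fixture(n_genes = 12, n_samples = 200, seed = 21,
                              edge_density = 0.12)
  net <- learn_single(fx$disc, fx$priors, learn_config(egene_bonus = 0),
                      seed = 3)
  skip_if(nrow(net$edges) == 0)
  total_bic <- function(edges) {
    pa <- split(edges$parent, edges$child)
    sum(vapply(rownames(fx$disc), function(g)
      family_bic(fx$disc, g, if (g %in% names(pa)) pa[[g]] else character())$bic,
      numeric(1)))
  }
  e <- net$edges[1, ]
  before <- total_bic(net$edges)
  after <- total_bic(net$edges[-1, ])
  # removing one edge changes only the child's family score
  delta_child <- family_bic(fx$disc, e$child,
                            setdiff(net$edges$parent[net$edges$child == e$child],
                                    e$parent))$bic -
    family_bic(fx$disc, e$child,
               net$edges$parent[net$edges$child == e$child])$bic
  expect_equal(after - before, delta_child)
})

test_that("learned structures respect the in-degree cap and acyclicity", {
  fx <- make_learning_fixture(n_genes = 15, n_samples = 300, seed = 31,
                              edge_density = 0.15)
  for (s in 1:3) {
    net <- learn_single(fx$disc, fx$priors, learn_config(max_parents = 2),
                        seed = s)
    expect_true(net$is_dag)
    expect_lte(max(table(net$edges$child)), 2)
  }
})

test_that("the eGene bonus steers orientation toward eGene parents", {
  fx <- make_learning_fixture(n_genes = 15, n_samples = 300, seed = 41,
                              edge_density = 0.12)
  pri_big <- fx$priors
  cfg <- learn_config(egene_bonus = 50)  # exaggerated to make the pull visible
  net <- learn_single(fx$disc, pri_big, cfg, seed = 1)
  net0 <- learn_single(fx$disc, pri_big, learn_config(egene_bonus = 0),
                       seed = 1)
  frac_eg <- function(n) mean(n$edges$parent %in%
                                names(which(pri_big$egene)))
  skip_if(nrow(net$edges) == 0 || nrow(net0$edges) == 0)
  expect_gte(frac_eg(net), frac_eg(net0))
})

test_that("consensus merging thresholds edge frequencies", {
  mk <- function(...) gene_network(data.frame(...))
  n1 <- mk(parent = c("A", "B"), child = c("B", "C"))
  n2 <- mk(parent = c("A"), child = c("B"))
  n3 <- mk(parent = c("A", "C"), child = c("B", "D"))
  cons <- consensus_merge(list(n1, n2, n3), fraction = 0.30)
  conf <- setNames(cons$edges$confidence,
                   paste(cons$edges$parent, cons$edges$child))
  expect_equal(conf[["A B"]], 1)
  expect_equal(conf[["B C"]], 1 / 3)
  expect_equal(conf[["C D"]], 1 / 3)

  # limiting cases: intersection and union
  expect_equal(nrow(consensus_merge(list(n1, n2, n3), 1.0)$edges), 1)
  expect_equal(nrow(consensus_merge(list(n1, n2, n3), 1e-9)$edges), 3)

  # permutation invariance of the input list
  perm <- consensus_merge(list(n3, n1, n2), fraction = 0.30)
  o <- function(e) e[order(e$parent, e$child), ]
  expect_equal(o(perm$edges), o(cons$edges), ignore_attr = TRUE)
  expect_error(consensus_merge(list()), "no networks")
})

test_that("cycle breaking removes minimum-confidence cycle edges only", {
  two <- gene_network(data.frame(parent = c("A", "B"), child = c("B", "A"),
                                 confidence = c(0.9, 0.4)))
  fixed <- break_cycles(two)
  expect_true(fixed$is_dag)
  expect_equal(fixed$edges$parent, "A")
  expect_equal(removed_edges(fixed)$confidence, 0.4)

  tri <- gene_network(data.frame(parent = c("A", "B", "C", "A"),
                                 child = c("B", "C", "A", "D"),
                                 confidence = c(0.9, 0.8, 0.35, 0.5)))
  fixed3 <- break_cycles(tri)
  expect_true(fixed3$is_dag)
  expect_equal(nrow(removed_edges(fixed3)), 1)
  expect_equal(removed_edges(fixed3)$confidence, 0.35)
  expect_equal(n_edges(fixed3), 3)

  dag <- gene_network(data.frame(parent = c("A", "B"), child = c("B", "C")))
  same <- break_cycles(dag)
  expect_equal(same$edges, dag$edges, ignore_attr = TRUE)
  expect_equal(nrow(removed_edges(same)), 0)

  # tie on confidence: lexicographically smallest (parent, child) goes
  tie <- gene_network(data.frame(parent = c("X", "Y"), child = c("Y", "X"),
                                 confidence = c(0.5, 0.5)))
  ft <- break_cycles(tie)
  expect_equal(removed_edges(ft)$parent, "X")
})

test_that("consensus learning recovers a 20-gene synthetic structure", {
  fx <- make_learning_fixture(n_genes = 20, n_samples = 500, seed = 7,
                              n_hubs = 2, edge_density = 0.02)
  fit <- learn_consensus(fx$disc, fx$priors, learn_config(n_seeds = 25),
                         seed = 7)
  expect_true(fit$network$is_dag)
  true_skel <- skeleton_of(fx$truth$dag)
  got_skel <- skeleton_of(fit$network)
  expect_gte(mean(true_skel %in% got_skel), 0.6)
  expect_lte(mean(!(got_skel %in% true_skel)), 0.4)
  expect_true(all(fit$network$edges$confidence >= 0.3 - 1e-12))
})
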