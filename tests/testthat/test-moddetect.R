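test_that("two disjoint 5-cliques are recovered exactly at k = 2", {
  net <- two_cliques()
  W <- aggregate_layers(net)
  part <- spectral_partition(W, clustering_config(k_selection = "fixed",
                                                  k = 2, seed = 1))
  truth <- tibble::tibble(gene = part$assignment$gene,
                          module = ifelse(startsWith(part$assignment$gene, "a"),
                                          1L, 2L))
  expect_equal(adjusted_rand(part, truth), 1)
})

test_that("a complete graph at fixed k = 1 is a single module", {
  genes <- paste0("g", 1:4)
  edges <- t(combn(genes, 2))
  net <- gene_network(tibble::tibble(gene_a = edges[, 1], relation = "PP",
                                     gene_b = edges[, 2]))
  part <- spectral_partition(aggregate_layers(net),
                             clustering_config(k_selection = "fixed", k = 1,
                                               seed = 1))
  expect_equal(part$k, 1)
  expect_equal(unique(part$assignment$module), 1L)
})

test_that("modularity matches closed forms and igraph", {
  net <- two_cliques()
  W <- aggregate_layers(net)
  good <- tibble::tibble(
    gene = sort(c(paste0("a", 1:5), paste0("b", 1:5))),
    module = ifelse(startsWith(sort(c(paste0("a", 1:5), paste0("b", 1:5))),
                               "a"), 1L, 2L))
  expect_equal(modularity(W, good), 0.5)

  one <- dplyr::mutate(good, module = 1L)
  expect_equal(modularity(W, one), 0)

  skip_if_not_installed("igraph")
  M <- W$M
  diag(M) <- 0
  g <- igraph::graph_from_adjacency_matrix(M, mode = "undirected",
                                           weighted = TRUE)
  memb <- good$module[match(igraph::V(g)$name, good$gene)]
  expect_equal(modularity(W, good),
               igraph::modularity(g, memb, weights = igraph::E(g)$weight))
})

test_that("random partitions of a random graph have near-zero modularity", {
  set.seed(7)
  vals <- replicate(10, {
    n <- 40
    genes <- paste0("g", 1:n)
    pairs <- t(combn(genes, 2))
    keep <- stats::runif(nrow(pairs)) < 0.2
    net <- gene_network(tibble::tibble(gene_a = pairs[keep, 1],
                                       relation = "PP",
                                       gene_b = pairs[keep, 2]))
    W <- aggregate_layers(net)
    covered <- setdiff(W$genes, W$isolated)
    part <- tibble::tibble(gene = covered,
                           module = sample(1:4, length(covered),
                                           replace = TRUE))
    modularity(W, part)
  })
  expect_lt(abs(mean(vals)), 0.1)
})

test_that("select_k honors a forced range and the size-derived upper bound", {
  net <- two_cliques()
  W <- aggregate_layers(net)
  expect_equal(select_k(W, clustering_config(k_min = 2, k_max = 2, seed = 1)),
               2)

  sim <- easy_sim()
  W2 <- aggregate_layers(sim$network)
  part <- spectral_partition(
    W2, clustering_config(k_min = 2, k_max = 40, min_module_size = 12,
                          seed = 1, restarts = 3))
  # floor(60 / 12) = 5 caps the scan
  expect_true(all(part$k_scan$k <= 5))
})

test_that("modularity k-selection finds the planted count on an easy fixture", {
  sim <- easy_sim()
  W <- aggregate_layers(sim$network)
  part <- spectral_partition(W, clustering_config(k_min = 2, k_max = 6,
                                                  k_selection = "modularity",
                                                  seed = 1, restarts = 5))
  expect_equal(part$k, 3)
  expect_gte(adjusted_rand(part, sim$truth), 0.95)
})

test_that("identical seed gives an identical partition, and gene input order is irrelevant", {
  sim <- easy_sim()
  W <- aggregate_layers(sim$network)
  cfg <- clustering_config(k_min = 2, k_max = 5, seed = 11, restarts = 3)
  p1 <- spectral_partition(W, cfg)
  p2 <- spectral_partition(W, cfg)
  expect_identical(p1$assignment, p2$assignment)

  shuffled <- sim$network
  set.seed(99)
  shuffled$edges <- shuffled$edges[sample(nrow(shuffled$edges)), ]
  p3 <- spectral_partition(aggregate_layers(shuffled), cfg)
  expect_equal(adjusted_rand(p1, p3), 1)
})

test_that("partition quality degrades as p_out approaches p_in", {
  ari_at <- function(p_out) {
    sim <- simulate_multilayer(synth_config(n_genes = 60, k_true = 3,
                                            p_in = 0.6, p_out = p_out,
                                            seed = 5))
    W <- aggregate_layers(sim$network)
    part <- spectral_partition(W, clustering_config(k_min = 3, k_max = 3,
                                                    k_selection = "fixed",
                                                    k = 3, seed = 5,
                                                    restarts = 3))
    adjusted_rand(part, sim$truth)
  }
  expect_gte(ari_at(0.02) + 0.05, ari_at(0.45))
})

test_that("small modules merge into their strongest neighbour by default", {
  # two 6-cliques plus a pendant pair attached to clique a
  g1 <- paste0("a", 1:6)
  g2 <- paste0("b", 1:6)
  edges <- rbind(t(combn(g1, 2)), t(combn(g2, 2)),
                 c("a1", "x1"), c("x1", "x2"))
  net <- gene_network(tibble::tibble(gene_a = edges[, 1], relation = "PP",
                                     gene_b = edges[, 2]))
  W <- aggregate_layers(net)
  part <- spectral_partition(
    W, clustering_config(k_selection = "fixed", k = 3, seed = 2,
                         min_module_size = 3, refine = FALSE))
  sizes <- table(part$assignment$module)
  expect_true(all(sizes >= 3))
  kept <- spectral_partition(
    W, clustering_config(k_selection = "fixed", k = 3, seed = 2,
                         min_module_size = 3, refine = FALSE,
                         keep_small = TRUE))
  expect_equal(kept$k, 3)
})

test_that("contract violations raise classed errors", {
  net <- two_cliques()
  W <- aggregate_layers(net)
  expect_error(spectral_partition(W, clustering_config(k_selection = "fixed",
                                                       k = 99, seed = 1)),
               class = "xtn_contract_error")
  Wbad <- W
  Wbad$M[1, 2] <- Wbad$M[1, 2] + 1
  expect_error(spectral_partition(Wbad, clustering_config(seed = 1)),
               "symmetric", class = "xtn_contract_error")
  expect_error(modularity(W, tibble::tibble(gene = "zz", module = 1L)),
               class = "xtn_contract_error")
})
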