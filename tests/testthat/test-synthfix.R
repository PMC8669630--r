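test_that("degenerate probabilities produce exact cliques", {
  sim <- simulate_multilayer(synth_config(n_genes = 8, k_true = 2, p_in = 1,
                                          p_out = 0.000001,
                                          layer_specs = c(PP = 1), seed = 1))
  # p_out effectively 0 at this size and seed: two 4-cliques
  W <- aggregate_layers(sim$network)
  M <- W$M
  diag(M) <- 0
  memb <- sim$membership$module[match(W$genes, sim$membership$gene)]
  same <- outer(memb, memb, `==`)
  diag(same) <- FALSE
  expect_true(all(M[same] == 1))
  expect_true(all(M[!same & upper.tri(M, diag = TRUE)] == 0))
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- synth_config(n_genes = 80, k_true = 4, p_in = 0.4, p_out = 0.02,
                      seed = 9)
  s1 <- simulate_multilayer(cfg)
  s2 <- simulate_multilayer(cfg)
  expect_identical(s1$network$edges, s2$network$edges)
  g1 <- simulate_genesets(s1$truth, cfg)
  g2 <- simulate_genesets(s2$truth, cfg)
  expect_identical(g1$genesets$genes, g2$genesets$genes)
  expect_identical(g1$planted, g2$planted)

  p1 <- simulate_mode_pair(cfg)
  p2 <- simulate_mode_pair(cfg)
  expect_identical(p1$network_a$edges, p2$network_a$edges)
  expect_identical(p1$network_b$edges, p2$network_b$edges)
})

test_that("realized base edge counts match binomial moments", {
  n <- 200; k <- 10; p_in <- 0.3; p_out <- 0.01
  n_in_pairs <- k * choose(n / k, 2)
  n_out_pairs <- choose(n, 2) - n_in_pairs
  mu <- n_in_pairs * p_in + n_out_pairs * p_out
  sdv <- sqrt(n_in_pairs * p_in * (1 - p_in) +
              n_out_pairs * p_out * (1 - p_out))
  counts <- vapply(1:20, function(s) {
    sim <- simulate_multilayer(synth_config(n_genes = n, k_true = k,
                                            p_in = p_in, p_out = p_out,
                                            seed = s))
    nrow(sim$base_edges)
  }, 0)
  expect_true(all(abs(counts - mu) <= 4 * sdv))
  # and the mean of 20 seeds should sit much closer
  expect_lt(abs(mean(counts) - mu), 4 * sdv / sqrt(20))
})

test_that("layer retention thins the base graph as specified", {
  cfg <- synth_config(n_genes = 100, k_true = 5, p_in = 0.5, p_out = 0.02,
                      layer_specs = c(PP = 0.9, A = 0.5), seed = 4)
  sim <- simulate_multilayer(cfg)
  nb <- nrow(sim$base_edges)
  cen <- census(sim$network)$layers
  for (lab in cen$relation) {
    r <- cfg$layer_specs[[lab]]
    sdv <- sqrt(nb * r * (1 - r))
    expect_lt(abs(cen$n_edges[cen$relation == lab] - nb * r), 4 * sdv)
  }
})

test_that("enriched sets mirror their module at extreme fractions", {
  cfg <- synth_config(n_genes = 60, k_true = 3, p_in = 0.6, p_out = 0.02,
                      n_sets = 3, enriched_fraction = 1,
                      background_fraction = 0, seed = 2)
  sim <- simulate_multilayer(cfg)
  gs <- simulate_genesets(sim$truth, cfg)
  mods <- split(sim$truth$assignment$gene, sim$truth$assignment$module)
  for (i in seq_len(nrow(gs$planted))) {
    m <- as.character(gs$planted$module[i])
    set <- gs$genesets$genes[[match(gs$planted$set[i], gs$genesets$set)]]
    expect_setequal(set, mods[[m]])
  }

  none <- simulate_genesets(sim$truth,
                            synth_config(n_genes = 60, k_true = 3,
                                         p_in = 0.6, p_out = 0.02,
                                         n_sets = 0, seed = 2))
  expect_equal(nrow(none$genesets), 0)
})

test_that("bad generator configurations are rejected", {
  expect_error(synth_config(p_in = 0.1, p_out = 0.2),
               class = "xtn_usage_error")
  expect_error(synth_config(n_genes = 10, k_true = 11),
               class = "xtn_usage_error")
  expect_error(synth_config(enriched_fraction = 1.2),
               class = "xtn_usage_error")
  expect_error(synth_config(layer_specs = c(PP = 0)),
               class = "xtn_usage_error")
})

test_that("adjusted Rand index matches closed-form pair counts", {
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(2, 2, 7, 7)), 1)
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)

  skip_if_not_installed("mclust")
  set.seed(13)
  for (i in 1:20) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("ARI requires a shared gene universe", {
  a <- tibble::tibble(gene = c("x", "y"), module = 1:2)
  b <- tibble::tibble(gene = c("x", "z"), module = 1:2)
  expect_error(adjusted_rand(a, b), class = "xtn_contract_error")
})

test_that("simulate -> aggregate -> cluster -> annotate recovers planted pairs", {
  cfg <- synth_config(n_genes = 150, k_true = 6, p_in = 0.45, p_out = 0.01,
                      n_sets = 12, seed = 6)
  sim <- simulate_multilayer(cfg)
  gs <- simulate_genesets(sim$truth, cfg)
  W <- aggregate_layers(sim$network)
  part <- spectral_partition(W, clustering_config(k_min = 4, k_max = 8,
                                                  seed = 6))
  expect_gte(adjusted_rand(part, sim$truth), 0.9)
  rec <- annotate_modules(part, sim$network, gs$genesets,
                          element_mode = "genes")
  hits <- vapply(seq_len(nrow(gs$planted)), function(i) {
    rows <- rec[rec$pathway == gs$planted$set[i] & rec$passed, ]
    nrow(rows) > 0
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})
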