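test_that("network score matches hand-enumerated hypergeometric tails", {
  r <- network_score(10, 4, 3, 2)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(r$score, -log10(1 / 3), tolerance = 1e-9)

  expect_equal(network_score(10, 4, 3, 0)$p_value, 1)
  expect_equal(network_score(10, 4, 3, 0)$score, 0)
  expect_equal(network_score(50, 10, 0, 0)$p_value, 1)

  # exhaustive agreement with the brute-force oracle on a small grid
  for (N in c(5, 12, 23)) {
    for (G in 0:N) {
      for (s in c(0, 3, N %/% 2, N)) {
        f <- 0:min(G, s)
        got <- network_score(N, G, s, f)$p_value
        want <- vapply(f, function(ff) oracle_tail(N, G, s, ff), 0)
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
  }
})

test_that("extreme tails stay finite and accurate in log space", {
  r <- network_score(20000, 400, 400, 390)
  expect_gt(r$score, 300)
  expect_true(is.finite(r$score))
  expect_gte(r$p_value, 1e-320)
  # cross-check a deep but representable tail against phyper
  lp <- stats::phyper(49, 60, 940, 200, lower.tail = FALSE, log.p = TRUE)
  r2 <- network_score(1000, 60, 200, 50)
  expect_equal(r2$score, -lp / log(10), tolerance = 1e-9)
})

test_that("score is non-decreasing in f at fixed (N, G, s)", {
  sc <- network_score(40, 12, 9, 0:9)$score
  expect_true(all(diff(sc) >= 0))
})

test_that("the score threshold corresponds exactly to p = 1e-4", {
  expect_identical(-log10(1e-4), 4)
  rec <- tibble::tibble(p_value = c(1e-4, 10^-4.0000001),
                        score = -log10(c(1e-4, 10^-4.0000001)))
  passed <- rec$score > 4
  expect_equal(passed, c(FALSE, TRUE))
})

test_that("one-sided Fisher p equals the hypergeometric tail", {
  expect_equal(fisher_enrichment(10, 4, 3, 2), 1 / 3, tolerance = 1e-12)
  expect_equal(fisher_enrichment(10, 4, 3, 0), 1)

  set.seed(31)
  for (i in 1:60) {
    N <- sample(6:120, 1)
    G <- sample(0:N, 1)
    s <- sample(0:N, 1)
    f <- sample(0:min(G, s), 1)
    expect_equal(fisher_enrichment(N, G, s, f),
                 network_score(N, G, s, f)$p_value,
                 tolerance = 1e-12)
  }
})

test_that("invalid enrichment inputs are rejected naming the inequality", {
  expect_error(network_score(10, 11, 3, 1), "G <= N",
               class = "xtn_contract_error")
  expect_error(network_score(10, 4, 11, 1), "s <= N",
               class = "xtn_contract_error")
  expect_error(network_score(10, 4, 3, 4), "f <= min",
               class = "xtn_contract_error")
  expect_error(network_score(10, -1, 3, 1), class = "xtn_contract_error")
})

toy_reference <- function() {
  # 6-gene universe with 7 reference edges; module m = {A, B, C} has 2
  # internal edges; pathway P covers {A, B, C}
  read_edge_table(c("A\tPP\tB", "B\tPP\tC", "A\tPP\tD", "C\tPP\tD",
                    "D\tPP\tE", "E\tPP\tF", "D\tPP\tF"))
}

test_that("edge-mode module annotation equals hand enumeration", {
  ref <- toy_reference()
  part <- tibble::tibble(gene = c("A", "B", "C", "D", "E", "F"),
                         module = c(1L, 1L, 1L, 2L, 2L, 2L))
  gs <- geneset_collection(list(P = c("A", "B", "C")))
  rec <- annotate_modules(part, ref, gs, element_mode = "edges",
                          threshold = 4)
  r1 <- rec[rec$module == 1, ]
  expect_equal(r1$N, 7)   # reference edges
  expect_equal(r1$G, 2)   # AB, BC internal to module 1
  expect_equal(r1$s, 2)   # pathway-induced: AB, BC
  expect_equal(r1$f, 2)
  expect_equal(r1$p_value, oracle_tail(7, 2, 2, 2), tolerance = 1e-12)
})

test_that("module covering the whole universe cannot be enriched", {
  ref <- read_edge_table(c("A\tPP\tB", "B\tPP\tC", "C\tPP\tD"))
  part <- tibble::tibble(gene = c("A", "B", "C", "D"), module = 1L)
  gs <- geneset_collection(list(ALL = c("A", "B", "C", "D")))
  for (mode in c("edges", "genes")) {
    rec <- annotate_modules(part, ref, gs, element_mode = mode)
    expect_equal(rec$N, rec$G)
    expect_equal(rec$s, rec$f)
    expect_equal(rec$p_value, 1)
    expect_equal(rec$score, 0)
  }
})

test_that("pathway absent from the universe reports s = 0, p = 1", {
  ref <- read_edge_table("A\tPP\tB")
  part <- tibble::tibble(gene = c("A", "B"), module = 1L)
  gs <- geneset_collection(list(GONE = c("X", "Y")))
  rec <- annotate_modules(part, ref, gs, element_mode = "genes")
  expect_equal(rec$s, 0)
  expect_equal(rec$p_value, 1)
})

test_that("annotation matrix follows gene and pair-endpoint semantics", {
  terms <- geneset_collection(list(T1 = c("g1"), T2 = c("g2")))
  A <- build_annotation_matrix(c("g1", "g2", "g3"), terms)
  expect_equal(matrix(as.integer(A), nrow = 3),
               matrix(c(1L, 0L, 0L, 0L, 1L, 0L), nrow = 3))
  # marginals equal recomputed intersections
  expect_equal(unname(colSums(A)), c(1, 1))
  expect_equal(unname(rowSums(A)), c(1, 1, 0))

  pairs <- tibble::tibble(gene_a = c("g1", "g1"), gene_b = c("g2", "g3"))
  terms2 <- geneset_collection(list(T = c("g1", "g2")))
  B <- build_annotation_matrix(pairs, terms2)
  expect_equal(unname(unclass(B)[, 1]), c(1L, 0L))  # both endpoints needed
})

test_that("annotation-matrix marginals match set intersections on a simulation", {
  sim <- easy_sim()
  gs <- simulate_genesets(sim$truth, synth_config(n_genes = 60, k_true = 3,
                                                  p_in = 0.6, p_out = 0.02,
                                                  n_sets = 6, seed = 1))
  genes <- sim$network$genes$symbol
  A <- build_annotation_matrix(genes, gs$genesets)
  want <- vapply(gs$genesets$genes,
                 function(g) length(intersect(toupper(g), toupper(genes))),
                 0L)
  expect_equal(unname(colSums(A)), as.double(want))
})

test_that("composite network is the union of passing pathway subgraphs", {
  ref <- toy_reference()
  gs <- geneset_collection(list(P1 = c("A", "B", "C"),
                                P2 = c("B", "C", "D")))
  rec <- tibble::tibble(module = 1L, pathway = c("P1", "P2"),
                        score = c(10, 10), p_value = c(1e-10, 1e-10))
  comp <- compose_network(rec, gs, ref, threshold = 4)
  # P1 induces AB, BC; P2 induces BC, CD; union: AB, BC, CD
  expect_equal(nrow(comp$edges), 3)
  bc <- comp$edges[comp$edges$gene_a == "B" & comp$edges$gene_b == "C", ]
  expect_equal(bc$provenance, "P1;P2")

  one <- compose_network(rec[1, ], gs, ref, threshold = 4)
  expect_equal(nrow(one$edges), 2)

  expect_warning(empty <- compose_network(rec, gs, ref, threshold = 99),
                 "empty")
  expect_equal(nrow(empty$edges), 0)
})

test_that("report_top ranks by score with deterministic ties", {
  rec <- tibble::tibble(module = 1L,
                        pathway = c("zeta", "alpha", "mid"),
                        p_value = c(1e-6, 1e-6, 1e-3),
                        score = c(6, 6, 3))
  top <- report_top(rec, top_k = 25)
  expect_equal(top$pathway, c("alpha", "zeta", "mid"))
  expect_equal(nrow(report_top(rec, top_k = 2)), 2)

  many <- tibble::tibble(module = 1L, pathway = sprintf("p%02d", 1:30),
                         p_value = 10^-(1:30), score = 1:30)
  expect_equal(nrow(report_top(many)), 25)
  expect_equal(report_top(many)$score[1], 30)
})

test_that("planted gene sets light up their modules and only theirs", {
  cfg <- synth_config(n_genes = 120, k_true = 6, p_in = 0.5, p_out = 0.01,
                      n_sets = 12, seed = 3)
  sim <- simulate_multilayer(cfg)
  gs <- simulate_genesets(sim$truth, cfg)
  rec <- annotate_modules(sim$truth, sim$network, gs$genesets,
                          element_mode = "genes")
  planted_key <- paste(gs$planted$module, gs$planted$set)
  rec_key <- paste(rec$module, rec$pathway)
  expect_true(all(rec$passed[rec_key %in% planted_key]))
})
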