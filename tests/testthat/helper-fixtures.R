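# Small fixtures built in code, shared across test files.

# Two disjoint 5-cliques on one PP layer.
two_cliques <- function() {
  g1 <- paste0("a", 1:5)
  g2 <- paste0("b", 1:5)
  edges <- rbind(t(combn(g1, 2)), t(combn(g2, 2)))
  gene_network(tibble::tibble(gene_a = edges[, 1], relation = "PP",
                              gene_b = edges[, 2]))
}

# Brute-force hypergeometric upper tail by direct pmf summation with
# choose(); the independent oracle for the network score.
oracle_tail <- function(N, G, s, f) {
  i <- 0:min(G, s)
  pmf <- choose(G, i) * choose(N - G, s - i) / choose(N, s)
  if (f <= 0) return(1)
  sum(pmf[i >= f])
}

# Small planted-partition fixture that clusters in well under a second.
easy_sim <- function(seed = 1) {
  simulate_multilayer(synth_config(n_genes = 60, k_true = 3, p_in = 0.6,
                                   p_out = 0.02, seed = seed))
}
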