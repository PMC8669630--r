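#' Configuration for the synthetic multilayer benchmark generator
#'
#' The generator plants equal-sized modules in a stochastic-block base
#' graph (within-module pair probability `p_in`, between `p_out`; remainder
#' genes after integer division are spread round-robin) and copies each
#' base edge independently into each relation layer with that layer's
#' retention probability.  The defaults emulate one cell-death-mode
#' network: 600 genes in 27 modules with `p_in = 0.2`, `p_out = 0.005`, and
#' three relation layers (protein-protein binding, activation, expression)
#' of decreasing coverage.
#'
#' @param n_genes Number of genes (default 600).
#' @param k_true Number of planted modules (default 27).
#' @param p_in,p_out Within/between-module edge probabilities (defaults
#'   0.2 and 0.005; requires `0 <= p_out < p_in <= 1`).
#' @param layer_specs Named numeric vector of per-layer edge retention
#'   probabilities in (0, 1] (default `c(PP = 0.9, A = 0.7, E = 0.5)`).
#' @param shared_module_size Planted shared-module size for the paired-mode
#'   crosstalk fixture (default 20).
#' @param n_sets Number of gene sets generated by [simulate_genesets()]
#'   (default 40).
#' @param enriched_fraction Fraction of a module's genes seeding an
#'   enriched set (default 0.8).
#' @param background_fraction Fraction of an enriched set drawn from
#'   outside the module (default 0.2).
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_genes = 600, k_true = 27, p_in = 0.2,
                         p_out = 0.005,
                         layer_specs = c(PP = 0.9, A = 0.7, E = 0.5),
                         shared_module_size = 20, n_sets = 40,
                         enriched_fraction = 0.8,
                         background_fraction = 0.2, seed = 1) {
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    abort_usage("need 0 <= p_out < p_in <= 1")
  }
  if (any(layer_specs <= 0 | layer_specs > 1)) {
    abort_usage("layer retention probabilities must be in (0, 1]")
  }
  if (is.null(names(layer_specs)) || anyDuplicated(names(layer_specs))) {
    abort_usage("layer_specs must be uniquely named")
  }
  if (k_true < 1) abort_usage("k_true must be >= 1")
  if (k_true > n_genes) abort_usage("k_true exceeds n_genes")
  if (enriched_fraction < 0 || enriched_fraction > 1 ||
      background_fraction < 0 || background_fraction > 1) {
    abort_usage("set fractions must lie in [0, 1]")
  }
  structure(list(n_genes = as.integer(n_genes),
                 k_true = as.integer(k_true),
                 p_in = p_in, p_out = p_out, layer_specs = layer_specs,
                 shared_module_size = as.integer(shared_module_size),
                 n_sets = as.integer(n_sets),
                 enriched_fraction = enriched_fraction,
                 background_fraction = background_fraction,
                 seed = as.integer(seed)),
            class = "synth_config")
}

synth_symbols <- function(n, prefix = "G") {
  sprintf("%s%04d", prefix, seq_len(n))
}

# Planted equal-sized membership: sizes differ by at most one.
planted_membership <- function(n, k) {
  sort(rep_len(seq_len(k), n))
}

# Sample the base stochastic-block edge list for a membership vector.
sample_base_edges <- function(memb, p_in, p_out) {
  n <- length(memb)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pr <- ifelse(memb[ij[, 1]] == memb[ij[, 2]], p_in, p_out)
  keep <- rbinom(nrow(ij), 1, pr) == 1
  ij[keep, , drop = FALSE]
}

#' Simulate a multilayer network with planted modules
#'
#' @param cfg A [synth_config()].
#' @param mode Optional mode label attached to the network.
#' @param prefix Gene-symbol prefix (default `"G"`).
#' @return A list with `network` (a [gene_network()]), `truth` (a
#'   `module_partition` holding the planted assignment) and `base_edges`
#'   (the base-graph pair indices).
#' @examples
#' sim <- simulate_multilayer(synth_config(n_genes = 40, k_true = 4,
#'                                         p_in = 0.5, p_out = 0.01))
#' glance(sim$network)
#' @export
simulate_multilayer <- function(cfg = synth_config(), mode = NULL,
                                prefix = "G") {
  stopifnot(inherits(cfg, "synth_config"))
  genes <- synth_symbols(cfg$n_genes, prefix)
  memb <- planted_membership(cfg$n_genes, cfg$k_true)

  set.seed(sub_seed(cfg$seed, "edges"))
  base <- sample_base_edges(memb, cfg$p_in, cfg$p_out)

  set.seed(sub_seed(cfg$seed, "layers"))
  rows <- purrr::imap(as.list(cfg$layer_specs), function(r, lab) {
    keep <- rbinom(nrow(base), 1, r) == 1
    tibble(gene_a = genes[base[keep, 1]],
           relation = lab,
           gene_b = genes[base[keep, 2]])
  })
  edges <- dplyr::bind_rows(rows)

  net <- gene_network(edges,
                      genes = tibble(symbol = genes),
                      vocabulary = default_vocabulary(), mode = mode)
  covered <- sort(unique(c(edges$gene_a, edges$gene_b)), method = "radix")
  idx <- match(covered, genes)
  truth <- structure(list(
    assignment = tibble(gene = covered,
                        module = as.integer(memb[idx])),
    k = cfg$k_true,
    isolated = setdiff(genes, covered),
    quality = NA_real_,
    k_scan = NULL,
    config = NULL), class = "module_partition")
  list(network = net, truth = truth, base_edges = base,
       membership = tibble(gene = genes, module = as.integer(memb)))
}

#' Simulate gene sets with planted enrichment
#'
#' Builds `n_sets` pathway-style gene sets over the genes of a planted
#' partition.  The first `min(k_true, n_sets)` sets are enriched: each
#' takes `enriched_fraction` of one module's genes plus
#' `background_fraction` of its final size drawn from outside that module.
#' Remaining sets are drawn uniformly from the whole gene universe with
#' sizes matching the enriched sets.  The planted (module, set) pairs are
#' returned alongside.
#'
#' @param truth A `module_partition` (typically `simulate_multilayer()$truth`
#'   or the full `membership` table wrapped as a partition).
#' @param cfg A [synth_config()].
#' @return A list with `genesets` (a `geneset_collection`) and `planted`
#'   (tibble `module`, `set`).
#' @export
simulate_genesets <- function(truth, cfg = synth_config()) {
  asg <- if (inherits(truth, "module_partition")) truth$assignment
         else as_tibble(truth)
  set.seed(sub_seed(cfg$seed, "sets"))
  modules <- split(asg$gene, asg$module)
  universe <- asg$gene
  n_enriched <- min(length(modules), cfg$n_sets)
  sets <- list()
  planted <- tibble(module = integer(0), set = character(0))
  sizes <- integer(0)
  for (i in seq_len(n_enriched)) {
    mod <- modules[[i]]
    core_n <- max(1L, round(cfg$enriched_fraction * length(mod)))
    core <- sort(sample(mod, core_n))
    bg_n <- round(cfg$background_fraction * core_n /
                    max(1e-9, 1 - cfg$background_fraction))
    bg <- if (bg_n > 0) sample(setdiff(universe, mod), bg_n) else character(0)
    nm <- sprintf("SET%03d", i)
    sets[[nm]] <- c(core, bg)
    sizes <- c(sizes, length(sets[[nm]]))
    planted <- dplyr::bind_rows(planted,
                                tibble(module = as.integer(names(modules)[i]),
                                       set = nm))
  }
  for (i in seq_len(max(0, cfg$n_sets - n_enriched))) {
    nm <- sprintf("SET%03d", n_enriched + i)
    sz <- if (length(sizes)) sizes[1 + (i - 1) %% length(sizes)] else
      max(2L, round(length(universe) / 25))
    sets[[nm]] <- sort(sample(universe, min(sz, length(universe))))
  }
  if (length(sets) == 0) {
    return(list(genesets = geneset_collection(setNames(list(), character(0))),
                planted = planted))
  }
  list(genesets = geneset_collection(sets,
                                     descriptions = rep("synthetic set",
                                                        length(sets))),
       planted = planted)
}

#' Simulate two mode networks sharing one planted module
#'
#' Builds two planted-partition mode networks over overlapping gene
#' universes such that one module (of `shared_module_size` genes) appears
#' identically in both networks — the crosstalk fixture.  Other modules are
#' disjoint between the modes.
#'
#' @param cfg A [synth_config()]; `n_genes` and `k_true` apply to each mode
#'   network.
#' @param modes Length-2 character vector of mode labels.
#' @return A list with `network_a`, `truth_a`, `network_b`, `truth_b`,
#'   `shared_genes` and `shared_modules` (the module id of the shared
#'   module in each partition).
#' @export
simulate_mode_pair <- function(cfg = synth_config(),
                               modes = c("apoptosis", "autophagy")) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$n_genes
  sh <- cfg$shared_module_size
  total <- 2L * n - sh
  genes <- synth_symbols(total, "G")
  genes_a <- genes[seq_len(n)]
  genes_b <- genes[(n - sh + 1):total]
  shared <- genes[(n - sh + 1):n]

  memb_of <- function(n_genes, k, shared_n) {
    # the shared genes sit at the tail of mode A's vector and the head of
    # mode B's; make them exactly one planted module in each
    base <- planted_membership(n_genes - shared_n, k - 1)
    c(base, rep(k, shared_n))
  }
  memb_a <- memb_of(n, cfg$k_true, sh)
  memb_b <- rev(memb_of(n, cfg$k_true, sh))   # shared block first
  # relabel mode B so ids are 1..k with shared module id 1
  memb_b <- match(memb_b, unique(memb_b))

  build <- function(genes_m, memb, stream, mode) {
    set.seed(sub_seed(cfg$seed, paste0("edges_", stream)))
    base <- sample_base_edges(memb, cfg$p_in, cfg$p_out)
    set.seed(sub_seed(cfg$seed, paste0("layers_", stream)))
    rows <- purrr::imap(as.list(cfg$layer_specs), function(r, lab) {
      keep <- rbinom(nrow(base), 1, r) == 1
      tibble(gene_a = genes_m[base[keep, 1]],
             relation = lab,
             gene_b = genes_m[base[keep, 2]])
    })
    edges <- dplyr::bind_rows(rows)
    net <- gene_network(edges, genes = tibble(symbol = genes_m),
                        mode = mode)
    covered <- sort(unique(c(edges$gene_a, edges$gene_b)), method = "radix")
    truth <- structure(list(
      assignment = tibble(gene = covered,
                          module = as.integer(memb[match(covered, genes_m)])),
      k = max(memb), isolated = setdiff(genes_m, covered),
      quality = NA_real_, k_scan = NULL, config = NULL),
      class = "module_partition")
    list(net = net, truth = truth)
  }
  a <- build(genes_a, memb_a, "a", modes[1])
  b <- build(genes_b, memb_b, "b", modes[2])
  list(network_a = a$net, truth_a = a$truth,
       network_b = b$net, truth_b = b$truth,
       shared_genes = shared,
       shared_modules = c(a = cfg$k_true, b = 1L))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two partitions of the same gene
#' universe: 1 for identical partitions up to relabeling, about 0 for
#' independent random partitions.  Computed from the closed-form pair-count
#' contingency formula.
#'
#' @param a,b `module_partition` objects, data frames with columns `gene`
#'   and `module`, or plain label vectors of equal length.
#' @return The ARI (numeric scalar).
#' @examples
#' adjusted_rand(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1: same up to relabeling
#' @export
adjusted_rand <- function(a, b) {
  lab <- function(x) {
    if (inherits(x, "module_partition")) x <- x$assignment
    if (is.data.frame(x)) {
      x <- as_tibble(x)
      if (!all(c("gene", "module") %in% names(x))) {
        abort_usage("partition needs columns gene, module")
      }
      return(x)
    }
    tibble(gene = as.character(seq_along(x)), module = x)
  }
  ta <- lab(a)
  tb <- lab(b)
  if (!setequal(ta$gene, tb$gene)) {
    abort_contract("partitions cover different gene universes")
  }
  la <- ta$module
  lb <- tb$module[match(ta$gene, tb$gene)]
  tab <- table(la, lb)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (maxi - expected)
}
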