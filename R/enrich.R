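#' Hypergeometric network score
#'
#' The score of a (module, pathway) pair with universe size `N`, `G` focus
#' elements, pathway size `s` and overlap `f` is
#' `score = -log10(P(X >= f))` with `X` hypergeometric: the upper-tail
#' probability `1 - sum_{i=0}^{f-1} C(G, i) C(N-G, s-i) / C(N, s)`.
#' Elements are gene pairs (edges) or genes depending on the element mode of
#' the caller.  The tail is computed in log-space (log-gamma terms summed
#' from the smallest with Kahan compensation) so scores up to several
#' hundred are finite; the p-value is clamped to at least `1e-320`.
#' A score above 4 corresponds to `p < 1e-4`, the usual inclusion
#' threshold for composite-network assembly.
#'
#' @param N Universe size (count of pairwise genes or genes in the
#'   reference network).  Vectorized over all four arguments.
#' @param G Focus elements in the universe.
#' @param s Pathway elements in the universe.
#' @param f Focus elements in the pathway.
#' @return A tibble with columns `p_value` and `score`.
#' @examples
#' network_score(10, 4, 3, 2)  # p = 1/3
#' @export
network_score <- function(N, G, s, f) {
  n <- max(length(N), length(G), length(s), length(f))
  N <- as.integer(rep_len(N, n))
  G <- as.integer(rep_len(G, n))
  s <- as.integer(rep_len(s, n))
  f <- as.integer(rep_len(f, n))
  check_enrichment_input(N, G, s, f)
  lp <- hyper_tail_log(N, G, s, f)
  p <- pmax(exp(lp), 1e-320)
  tibble(p_value = p, score = -lp / log(10))
}

check_enrichment_input <- function(N, G, s, f) {
  bad <- function(cond, what) {
    if (any(cond)) {
      abort_contract(paste0("enrichment input violates ", what,
                            " (first offending row ", which(cond)[1], ")"))
    }
  }
  bad(is.na(N) | is.na(G) | is.na(s) | is.na(f), "non-missing integers")
  bad(N < 0 | G < 0 | s < 0 | f < 0, "non-negativity")
  bad(G > N, "G <= N")
  bad(s > N, "s <= N")
  bad(f > pmin(G, s), "f <= min(G, s)")
}

#' One-sided Fisher's exact enrichment p-value
#'
#' Exact one-sided (enrichment) p-value for the 2x2 table
#' `[[f, G-f], [s-f, N-G-s+f]]`, computed with [stats::fisher.test()].
#' For any valid input this equals the hypergeometric upper tail of
#' [network_score()]; the two are kept as independent routes.
#'
#' @inheritParams network_score
#' @return A numeric vector of p-values.
#' @export
fisher_enrichment <- function(N, G, s, f) {
  n <- max(length(N), length(G), length(s), length(f))
  N <- as.integer(rep_len(N, n)); G <- as.integer(rep_len(G, n))
  s <- as.integer(rep_len(s, n)); f <- as.integer(rep_len(f, n))
  check_enrichment_input(N, G, s, f)
  vapply(seq_len(n), function(i) {
    if (N[i] - G[i] - s[i] + f[i] < 0) return(1)  # overlap >= f is forced
    tab <- matrix(c(f[i], G[i] - f[i], s[i] - f[i],
                    N[i] - G[i] - s[i] + f[i]), 2, 2)
    fisher.test(tab, alternative = "greater")$p.value
  }, 0)
}

# Distinct reference edges as a canonical pair key tibble.
reference_pairs <- function(reference) {
  ed <- dplyr::distinct(reference$edges, .data$gene_a, .data$gene_b)
  ed
}

#' Score modules against pathway gene sets
#'
#' For every (module, pathway) pair, counts the enrichment inputs and
#' applies the hypergeometric network score.  In the default `"edges"`
#' element mode the universe is the reference network's distinct edge set:
#' `N` its size, `G` the module-internal reference edges, `s` the
#' pathway-induced reference edges, `f` their intersection.  In `"genes"`
#' mode the analogous gene counts are used.  A pathway with no element in
#' the universe is reported with `s = 0`, `p = 1`.  Benjamini-Hochberg
#' q-values are appended as an advisory column; the `passed` flag uses the
#' raw score threshold.
#'
#' @param partition A `module_partition` (or data frame `gene`, `module`).
#' @param reference A [gene_network()] used as the element universe.
#' @param genesets A `geneset_collection`.
#' @param element_mode `"edges"` (default) or `"genes"`.
#' @param threshold Score threshold for the `passed` flag (default 4,
#'   i.e. `p < 1e-4`).
#' @param strict_case Match pathway genes to network genes
#'   case-sensitively.
#' @return An `enrichment_table` tibble: `module`, `pathway`, `N`, `G`,
#'   `s`, `f`, `p_value`, `score`, `q_value`, `passed`.
#' @export
annotate_modules <- function(partition, reference, genesets,
                             element_mode = c("edges", "genes"),
                             threshold = 4, strict_case = FALSE) {
  element_mode <- match.arg(element_mode)
  asg <- if (inherits(partition, "module_partition")) partition$assignment
         else as_tibble(partition)
  if (!all(c("gene", "module") %in% names(asg))) {
    abort_usage("partition needs columns gene, module")
  }
  uni_genes <- gene_key(reference$genes$symbol, strict_case)
  part_genes <- gene_key(asg$gene, strict_case)
  if (!all(part_genes %in% uni_genes)) {
    abort_contract("partition genes are not a subset of the universe genes")
  }
  set_genes <- lapply(genesets$genes,
                      function(g) intersect(gene_key(g, strict_case), uni_genes))

  modules <- split(part_genes, asg$module)
  if (element_mode == "genes") {
    N <- length(uni_genes)
    grid <- tidyr::expand_grid(module = names(modules),
                               pathway = genesets$set)
    grid$G <- lengths(modules)[grid$module]
    grid$s <- lengths(set_genes)[match(grid$pathway, genesets$set)]
    grid$f <- purrr::map2_int(grid$module, grid$pathway, function(m, p) {
      length(intersect(modules[[m]], set_genes[[match(p, genesets$set)]]))
    })
    grid$N <- N
  } else {
    pairs <- reference_pairs(reference)
    pa <- gene_key(pairs$gene_a, strict_case)
    pb <- gene_key(pairs$gene_b, strict_case)
    N <- nrow(pairs)
    mod_of <- setNames(asg$module, part_genes)
    in_mod <- !is.na(mod_of[pa]) & !is.na(mod_of[pb]) &
      mod_of[pa] == mod_of[pb]
    edge_mod <- ifelse(in_mod, mod_of[pa], NA_integer_)
    grid <- tidyr::expand_grid(module = names(modules),
                               pathway = genesets$set)
    Gs <- table(factor(edge_mod, levels = names(modules)))
    grid$G <- as.integer(Gs[grid$module])
    sets_idx <- match(grid$pathway, genesets$set)
    edge_in_set <- lapply(set_genes, function(g) pa %in% g & pb %in% g)
    grid$s <- vapply(edge_in_set, sum, 0L)[sets_idx]
    grid$f <- purrr::map2_int(grid$module, sets_idx, function(m, si) {
      sum(edge_in_set[[si]] & !is.na(edge_mod) & edge_mod == as.integer(m))
    })
    grid$N <- N
  }

  ns <- network_score(grid$N, grid$G, grid$s, grid$f)
  out <- tibble(module = as.integer(grid$module),
                pathway = grid$pathway,
                N = as.integer(grid$N), G = as.integer(grid$G),
                s = as.integer(grid$s), f = as.integer(grid$f),
                p_value = ns$p_value, score = ns$score,
                q_value = p.adjust(ns$p_value, method = "BH"),
                passed = ns$score > threshold) |>
    dplyr::arrange(.data$module, dplyr::desc(.data$score), .data$pathway)
  attr(out, "threshold") <- threshold
  attr(out, "element_mode") <- element_mode
  class(out) <- c("enrichment_table", class(out))
  out
}

#' Binary element-by-term annotation matrix
#'
#' Cell `(e, t)` is 1 when element `e` belongs to term `t` and 0 otherwise
#' (0 is "unknown", not "absent").  An element is a gene, or a gene pair in
#' which case both endpoints must belong to the term.  Row profiles are the
#' comparison objects for mode-mode annotation similarity.
#'
#' @param elements Character vector of gene symbols, or a data frame with
#'   columns `gene_a`, `gene_b` for pair semantics.
#' @param terms A `geneset_collection` of annotation terms (pathways,
#'   cell-death modes, ...).
#' @param strict_case Case-sensitive symbol matching.
#' @return An `annotation_matrix`: binary integer matrix (rows = elements,
#'   columns = terms) with `elements` and `terms` attributes.
#' @export
build_annotation_matrix <- function(elements, terms, strict_case = FALSE) {
  pair_mode <- is.data.frame(elements)
  if (pair_mode) {
    if (!all(c("gene_a", "gene_b") %in% names(elements))) {
      abort_usage("pair elements need columns gene_a, gene_b")
    }
    rown <- paste(elements$gene_a, elements$gene_b, sep = "|")
    ka <- gene_key(elements$gene_a, strict_case)
    kb <- gene_key(elements$gene_b, strict_case)
  } else {
    rown <- elements
    ka <- kb <- gene_key(elements, strict_case)
  }
  if (length(rown) == 0) abort_usage("no elements to annotate")
  A <- vapply(terms$genes, function(g) {
    k <- gene_key(g, strict_case)
    as.integer(ka %in% k & kb %in% k)
  }, integer(length(rown)))
  A <- matrix(A, nrow = length(rown),
              dimnames = list(rown, terms$set))
  structure(A, class = c("annotation_matrix", "matrix"),
            elements = rown, terms = terms$set)
}

#' Assemble the composite network of passing pathways
#'
#' Takes the enrichment records passing the score threshold and returns the
#' union of the reference-induced subgraphs of their pathways, each edge
#' annotated with the contributing pathway names.  An empty record set gives
#' an empty composite with a warning.
#'
#' @param records An `enrichment_table` (or subset of its rows).
#' @param genesets The `geneset_collection` the records refer to.
#' @param reference The reference [gene_network()].
#' @param threshold Score threshold (default: the records' own threshold,
#'   falling back to 4).
#' @param strict_case Case-sensitive symbol matching.
#' @return A [gene_network()] whose edge `provenance` lists contributing
#'   pathways.
#' @export
compose_network <- function(records, genesets, reference, threshold = NULL,
                            strict_case = FALSE) {
  threshold <- threshold %||% attr(records, "threshold") %||% 4
  passing <- unique(records$pathway[records$score > threshold])
  if (length(passing) == 0) {
    warn("no record passes the threshold; composite network is empty")
    return(gene_network(tibble(gene_a = character(0),
                               relation = character(0),
                               gene_b = character(0)),
                        vocabulary = reference$vocabulary))
  }
  ed <- reference$edges
  ka <- gene_key(ed$gene_a, strict_case)
  kb <- gene_key(ed$gene_b, strict_case)
  keep <- rep(FALSE, nrow(ed))
  contrib <- vector("list", nrow(ed))
  for (pw in passing) {
    g <- gene_key(genesets$genes[[match(pw, genesets$set)]], strict_case)
    hit <- ka %in% g & kb %in% g
    keep <- keep | hit
    contrib[hit] <- lapply(contrib[hit], c, pw)
  }
  ed <- ed[keep, ]
  ed$provenance <- vapply(contrib[keep], paste, "", collapse = ";")
  gene_network(ed, vocabulary = reference$vocabulary,
               mode = reference$mode, strict_case = strict_case)
}

#' Rank enrichment records and keep the top hits
#'
#' Sorts records by score descending, breaking ties by smaller p-value and
#' then lexicographic pathway name, and returns at most `top_k` rows.
#'
#' @param records An `enrichment_table`.
#' @param top_k Maximum rows returned (default 25).
#' @return The ranked head of `records`.
#' @export
report_top <- function(records, top_k = 25) {
  records |>
    dplyr::arrange(dplyr::desc(.data$score), .data$p_value, .data$pathway) |>
    head(top_k)
}

#' @export
autoplot.enrichment_table <- function(object, top_k = 25, ...) {
  df <- report_top(object, top_k)
  df$label <- paste0("m", df$module, ": ", df$pathway)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$score,
    y = stats::reorder(.data$label, .data$score),
    fill = .data$passed)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = attr(object, "threshold") %||% 4,
                        linetype = "dashed") +
    ggplot2::labs(x = expression(-log[10] ~ p), y = NULL,
                  fill = "passed") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.annotation_matrix <- function(object, ...) {
  idx <- which(unclass(object) != 0, arr.ind = TRUE)
  df <- tibble(element = attr(object, "elements")[idx[, 1]],
               term = attr(object, "terms")[idx[, 2]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$element)) +
    ggplot2::geom_tile(fill = "grey20") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1))
}

#' Write enrichment records as TSV
#'
#' @param records An `enrichment_table`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_enrichment <- function(records, path) {
  write_xtsv(as_tibble(records), path)
}
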