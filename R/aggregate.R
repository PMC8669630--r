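#' Convex layer weights
#'
#' A layer-weight vector assigns a non-negative weight to every relation
#' layer of a network, summing to one.  `uniform_weights()` gives every
#' layer the same weight; `density_weights()` down-weights dense layers
#' (weight proportional to the reciprocal edge count, renormalized; a layer
#' with no edges gets weight zero before renormalization).
#'
#' @param net A [gene_network()].
#' @return A tibble with columns `relation` and `weight` summing to 1.
#' @examples
#' net <- read_edge_table(c("A\tPP\tB", "A\tA\tC", "B\tA\tC"))
#' uniform_weights(net)
#' density_weights(net)
#' @export
uniform_weights <- function(net) {
  labs <- sort(unique(net$edges$relation))
  if (length(labs) == 0) abort_usage("network has no layers")
  tibble(relation = labs, weight = 1 / length(labs))
}

#' @rdname uniform_weights
#' @export
density_weights <- function(net) {
  cnt <- census(net)$layers
  if (nrow(cnt) == 0) abort_usage("network has no layers")
  w <- ifelse(cnt$n_edges > 0, 1 / cnt$n_edges, 0)
  tibble(relation = cnt$relation, weight = w / sum(w))
}

check_weights <- function(weights, net) {
  weights <- as_tibble(weights)
  if (!all(c("relation", "weight") %in% names(weights))) {
    abort_usage("`weights` needs columns relation, weight")
  }
  labs <- unique(net$edges$relation)
  missing <- setdiff(labs, weights$relation)
  if (length(missing)) {
    abort_usage(paste0("weights missing layer(s): ",
                       paste(missing, collapse = ", ")))
  }
  if (any(weights$weight < 0)) abort_usage("negative layer weight")
  if (abs(sum(weights$weight) - 1) > 1e-12) {
    abort_usage("layer weights must sum to 1")
  }
  weights
}

#' Aggregate relation layers into a single weight matrix
#'
#' Forms the symmetric matrix `M` with `M[i, j] = sum_l w_l * A_l[i, j]`
#' for `i != j`, where `A_l` is layer `l`'s (undirected, weighted)
#' adjacency.  The diagonal is set to 1 for every present gene as a
#' node-presence indicator; it is bookkeeping only and is zeroed before any
#' spectral computation.  Genes are held in lexicographic order so the
#' matrix is invariant to the input order of edges.  Genes with zero degree
#' across all layers are flagged `isolated`.
#'
#' @param net A [gene_network()].
#' @param weights Layer weights (default [uniform_weights()]).
#' @return A `weight_matrix`: list with `genes` (ordered character vector),
#'   `M` (dense symmetric matrix with dimnames), `isolated` (character
#'   vector) and `weights`.
#' @examples
#' net <- read_edge_table(c("g1\tPP\tg2", "g1\tA\tg2", "g2\tA\tg3"))
#' aggregate_layers(net)$M
#' @export
aggregate_layers <- function(net, weights = NULL) {
  stopifnot(inherits(net, "gene_network"))
  genes <- sort(net$genes$symbol, method = "radix")
  n <- length(genes)
  M <- matrix(0, n, n, dimnames = list(genes, genes))
  if (n > 0 && nrow(net$edges) > 0) {
    weights <- check_weights(weights %||% uniform_weights(net), net)
    wmap <- setNames(weights$weight, weights$relation)
    i <- match(net$edges$gene_a, genes)
    j <- match(net$edges$gene_b, genes)
    w <- unname(wmap[net$edges$relation]) * net$edges$weight
    lin <- (pmax(i, j) - 1L) * n + pmin(i, j)  # upper-triangle linear index
    acc <- rowsum(w, lin)
    M[as.integer(rownames(acc))] <- acc[, 1]
    M <- M + t(M)
  } else {
    weights <- weights %||% tibble(relation = character(0), weight = double(0))
  }
  isolated <- genes[rowSums(M) == 0]
  if (n > 0) diag(M) <- 1
  structure(list(genes = genes, M = M, isolated = isolated,
                 weights = weights),
            class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("<weight_matrix: %d genes, %d isolated>\n",
              length(x$genes), length(x$isolated)))
  invisible(x)
}

#' @export
tidy.weight_matrix <- function(x, ...) {
  M <- x$M
  diag(M) <- 0
  idx <- which(upper.tri(M) & M != 0, arr.ind = TRUE)
  tibble(gene_a = x$genes[idx[, 1]],
         gene_b = x$genes[idx[, 2]],
         value = M[idx])
}

#' Tukey five-number degree summary
#'
#' Degree of a gene is its number of incident edges in the requested scope
#' (unweighted count by default; `weighted = TRUE` sums edge weights
#' instead).  Quartiles use linear interpolation between order statistics;
#' whiskers extend to the most extreme degree within 1.5 times the
#' interquartile range of the quartiles, and genes outside the whiskers are
#' reported as outliers.
#'
#' @param net A [gene_network()].
#' @param scope `"aggregate"` (distinct neighbours across all layers) or a
#'   single relation label.
#' @param weighted Sum edge weights instead of counting edges.
#' @return A `degree_summary`: list with `degrees` (tibble gene/degree),
#'   `stats` (one-row tibble with median, quartiles and whisker bounds) and
#'   `outliers` (character vector).
#' @examples
#' star <- read_edge_table(sprintf("hub\tPP\tleaf%d", 1:4))
#' degree_summary(star)$stats
#' @export
degree_summary <- function(net, scope = "aggregate", weighted = FALSE) {
  stopifnot(inherits(net, "gene_network"))
  ed <- net$edges
  if (!identical(scope, "aggregate")) {
    ed <- ed[ed$relation == scope, ]
  } else if (!weighted) {
    # aggregate degree counts distinct neighbours
    ed <- dplyr::distinct(ed, .data$gene_a, .data$gene_b)
    ed$weight <- 1
  }
  if (nrow(ed) == 0) abort_usage("no degrees to summarize")
  val <- if (weighted) ed$weight else rep(1, nrow(ed))
  deg <- tapply(c(val, val), c(ed$gene_a, ed$gene_b), sum)
  degrees <- tibble(gene = names(deg), degree = as.double(deg)) |>
    dplyr::arrange(.data$gene)
  q <- unname(quantile(degrees$degree, c(.25, .5, .75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- degrees$degree >= lo_fence & degrees$degree <= hi_fence
  stats <- tibble(scope = if (identical(scope, "aggregate")) "aggregate" else scope,
                  n = nrow(degrees),
                  q1 = q[1], median = q[2], q3 = q[3],
                  whisker_low = min(degrees$degree[inside]),
                  whisker_high = max(degrees$degree[inside]))
  structure(list(degrees = degrees, stats = stats,
                 outliers = degrees$gene[!inside]),
            class = "degree_summary")
}

#' @export
print.degree_summary <- function(x, ...) {
  print(x$stats)
  if (length(x$outliers)) {
    cat("outliers:", paste(x$outliers, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.degree_summary <- function(x, ...) {
  dplyr::mutate(x$degrees, outlier = .data$gene %in% x$outliers)
}

#' @export
glance.degree_summary <- function(x, ...) x$stats
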