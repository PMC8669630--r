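#' Hypergeometric crosstalk score of two modules
#'
#' Crosstalk between a module of one cell-death mode and a module of
#' another is scored by the hypergeometric overlap tail: with universe size
#' `U`, `p = P(|A intersect B| >= f)` for random draws of `|A|` and `|B|`
#' genes, and `score = -log10(p)`.  The statistic is symmetric in its
#' arguments.  An empty module gives `p = 1`, `score = 0` with a warning.
#'
#' @param module_a,module_b Character vectors of gene symbols.
#' @param universe_size Size `U` of the shared gene universe
#'   (`U >= |A union B|`).
#' @param strict_case Case-sensitive symbol matching.
#' @return A tibble with columns `n_shared`, `p_value` and `score`.
#' @examples
#' crosstalk_score(letters[1:5], letters[1:5], 20)  # p = 1 / choose(20, 5)
#' @export
crosstalk_score <- function(module_a, module_b, universe_size,
                            strict_case = FALSE) {
  a <- unique(gene_key(module_a, strict_case))
  b <- unique(gene_key(module_b, strict_case))
  if (length(a) == 0 || length(b) == 0) {
    warn("empty module in crosstalk_score; p = 1")
    return(tibble(n_shared = 0L, p_value = 1, score = 0))
  }
  if (universe_size < length(union(a, b))) {
    abort_contract("universe_size smaller than |A union B|")
  }
  f <- length(intersect(a, b))
  ns <- network_score(universe_size, length(a), length(b), f)
  tibble(n_shared = f, p_value = ns$p_value, score = ns$score)
}

#' Mode-mode crosstalk table
#'
#' Scores every module pair between two cell-death-mode partitions that
#' shares at least one gene or is connected by at least one bridging
#' reference edge.  Each record carries the shared-gene overlap statistics,
#' the bridging-edge count, and (when an annotation matrix is supplied) the
#' Jaccard similarity of the two modules' binary term profiles (a module's
#' profile marks a term when any member gene carries it).  Records are
#' sorted by score descending, ties by smaller p then module ids; records
#' with `score > threshold` are flagged.
#'
#' @param partition_a,partition_b `module_partition` objects (or data
#'   frames `gene`, `module`).
#' @param mode_a,mode_b Names of the two cell-death modes.
#' @param reference Optional [gene_network()] for bridging-edge counts.
#' @param annotation Optional `annotation_matrix` over genes for term
#'   profiles.
#' @param threshold Score threshold for the `passed` flag (default 4).
#' @param universe Optional character vector overriding the gene universe;
#'   defaults to the union of the two partitions' genes.
#' @param strict_case Case-sensitive symbol matching.
#' @return A `crosstalk_table` tibble: `mode_a`, `module_a`, `mode_b`,
#'   `module_b`, `n_shared`, `bridging_edges`, `p_value`, `score`,
#'   `jaccard_terms`, `passed`.
#' @export
crosstalk_table <- function(partition_a, partition_b,
                            mode_a = "A", mode_b = "B",
                            reference = NULL, annotation = NULL,
                            threshold = 4, universe = NULL,
                            strict_case = FALSE) {
  asg_a <- if (inherits(partition_a, "module_partition")) partition_a$assignment
           else as_tibble(partition_a)
  asg_b <- if (inherits(partition_b, "module_partition")) partition_b$assignment
           else as_tibble(partition_b)
  mods_a <- split(gene_key(asg_a$gene, strict_case), asg_a$module)
  mods_b <- split(gene_key(asg_b$gene, strict_case), asg_b$module)
  uni <- if (is.null(universe)) {
    union(unlist(mods_a), unlist(mods_b))
  } else {
    unique(gene_key(universe, strict_case))
  }
  if (!all(unlist(mods_a) %in% uni) || !all(unlist(mods_b) %in% uni)) {
    abort_contract("partitions are not contained in the shared gene universe")
  }
  U <- length(uni)

  bridge <- NULL
  if (!is.null(reference)) {
    ed <- reference_pairs(reference)
    bridge <- tibble(a = gene_key(ed$gene_a, strict_case),
                     b = gene_key(ed$gene_b, strict_case))
  }
  profile_of <- function(genes) {
    if (is.null(annotation)) return(NULL)
    rows <- match(genes, gene_key(attr(annotation, "elements"), strict_case))
    rows <- rows[!is.na(rows)]
    if (length(rows) == 0) return(rep(0L, ncol(annotation)))
    as.integer(colSums(unclass(annotation)[rows, , drop = FALSE]) > 0)
  }

  grid <- tidyr::expand_grid(ma = names(mods_a), mb = names(mods_b))
  rec <- purrr::pmap(grid, function(ma, mb) {
    ga <- mods_a[[ma]]
    gb <- mods_b[[mb]]
    f <- length(intersect(ga, gb))
    nbridge <- if (is.null(bridge)) 0L else
      sum((bridge$a %in% ga & bridge$b %in% gb) |
          (bridge$a %in% gb & bridge$b %in% ga))
    if (f == 0 && nbridge == 0) return(NULL)
    ns <- network_score(U, length(ga), length(gb), f)
    jac <- NA_real_
    if (!is.null(annotation)) {
      pa <- profile_of(ga)
      pb <- profile_of(gb)
      un <- sum(pa | pb)
      jac <- if (un == 0) 0 else sum(pa & pb) / un
    }
    tibble(mode_a = mode_a, module_a = as.integer(ma),
           mode_b = mode_b, module_b = as.integer(mb),
           n_shared = f, bridging_edges = as.integer(nbridge),
           p_value = ns$p_value, score = ns$score,
           jaccard_terms = jac)
  })
  out <- dplyr::bind_rows(rec)
  if (nrow(out) == 0) {
    out <- tibble(mode_a = character(0), module_a = integer(0),
                  mode_b = character(0), module_b = integer(0),
                  n_shared = integer(0), bridging_edges = integer(0),
                  p_value = double(0), score = double(0),
                  jaccard_terms = double(0))
  }
  out$passed <- out$score > threshold
  out <- dplyr::arrange(out, dplyr::desc(.data$score), .data$p_value,
                        .data$module_a, .data$module_b)
  class(out) <- c("crosstalk_table", class(out))
  out
}

#' Genes shared between cell-death-mode networks
#'
#' Lists genes present in at least two of the supplied mode networks: the
#' first place to look for crosstalk between modes.  Sorted by the number
#' of containing modes (descending), then symbol; the hallmark flag is
#' carried through (a gene is flagged when any network flags it).
#'
#' @param networks Named list of [gene_network()] objects (names are the
#'   mode labels; an unnamed list falls back to each network's own `mode`).
#' @param strict_case Case-sensitive symbol matching.
#' @return A tibble: `gene`, `modes` (semicolon-separated), `n_modes`,
#'   `hallmark`.
#' @export
crosstalk_genes <- function(networks, strict_case = FALSE) {
  if (length(networks) < 2) abort_usage("need at least 2 mode networks")
  labels <- purrr::map2_chr(networks, seq_along(networks), function(n, i) {
    nm <- names(networks)[i]
    if (!is.null(nm) && !is.na(nm) && nzchar(nm)) nm
    else n$mode %||% as.character(i)
  })
  per <- purrr::map2(networks, labels, function(net, lb) {
    tibble(key = gene_key(net$genes$symbol, strict_case),
           gene = net$genes$symbol,
           hallmark = net$genes$hallmark,
           mode = lb)
  })
  all <- dplyr::bind_rows(per)
  out <- all |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(gene = dplyr::first(.data$gene),
                     modes = paste(sort(unique(.data$mode)), collapse = ";"),
                     n_modes = dplyr::n_distinct(.data$mode),
                     hallmark = any(.data$hallmark),
                     .groups = "drop") |>
    dplyr::filter(.data$n_modes >= 2) |>
    dplyr::arrange(dplyr::desc(.data$n_modes), .data$gene) |>
    dplyr::select(!"key")
  out
}

#' Write a crosstalk table as TSV
#'
#' @param records A `crosstalk_table`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_crosstalk <- function(records, path) {
  write_xtsv(as_tibble(records), path)
}
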