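#' Construct a typed multilayer gene network
#'
#' A `gene_network` holds a shared gene vocabulary plus one undirected edge
#' layer per relation type.  Edges live in a single tidy tibble with a
#' `relation` column; a layer is the subset of rows sharing one relation
#' label.  Self-loops are rejected and duplicate `(a, b, relation)` records
#' are collapsed keeping the maximum weight.
#'
#' @param edges A data frame with columns `gene_a`, `relation`, `gene_b` and
#'   optionally `weight` (default 1) and `provenance`.
#' @param genes Optional data frame of node attributes with column `symbol`
#'   and optionally `hallmark` (logical), `modes` (semicolon-separated
#'   cell-death-mode names) and further free columns carried as opaque
#'   attributes.  Endpoints absent from `genes` are registered
#'   automatically.
#' @param vocabulary A relation vocabulary (see [default_vocabulary()]).
#' @param mode Optional cell-death-mode name for the whole network.
#' @param strict_case Match gene symbols case-sensitively (default matches
#'   case-insensitively, keeping the first-seen capitalization).
#' @return An object of class `gene_network` with elements `genes` (tibble),
#'   `edges` (tibble), `vocabulary` and `mode`.
#' @examples
#' net <- gene_network(data.frame(gene_a = "TP53", relation = "PP",
#'                                gene_b = "BAX"))
#' census(net)
#' @export
gene_network <- function(edges, genes = NULL,
                         vocabulary = default_vocabulary(),
                         mode = NULL, strict_case = FALSE) {
  vocabulary <- as_vocabulary(vocabulary)
  edges <- as_tibble(edges)
  need <- c("gene_a", "relation", "gene_b")
  if (!all(need %in% names(edges))) {
    abort_usage("`edges` needs columns gene_a, relation, gene_b")
  }
  if (!"weight" %in% names(edges)) edges$weight <- 1
  if (!"provenance" %in% names(edges)) edges$provenance <- NA_character_
  edges$weight <- as.double(edges$weight)
  if (any(is.na(edges$weight) | edges$weight < 0)) {
    abort_input("edge weights must be non-negative numbers")
  }
  bad <- !edges$relation %in% vocabulary$label
  if (any(bad)) {
    abort_input(paste0("unknown relation label(s): ",
                       paste(unique(edges$relation[bad]), collapse = ", ")))
  }

  ka <- gene_key(edges$gene_a, strict_case)
  kb <- gene_key(edges$gene_b, strict_case)
  if (any(ka == kb)) {
    abort_input("self-loops are not allowed in a gene network")
  }
  # orient each unordered pair canonically so deduplication is order-blind
  flip <- ka > kb
  a <- ifelse(flip, edges$gene_b, edges$gene_a)
  b <- ifelse(flip, edges$gene_a, edges$gene_b)
  edges$gene_a <- a
  edges$gene_b <- b

  reg <- register_genes(c(edges$gene_a, edges$gene_b), genes, strict_case)
  edges$gene_a <- reg$canon[gene_key(edges$gene_a, strict_case)]
  edges$gene_b <- reg$canon[gene_key(edges$gene_b, strict_case)]

  edges <- if (nrow(edges) == 0) edges else edges |>
    dplyr::group_by(.data$gene_a, .data$gene_b, .data$relation) |>
    dplyr::summarise(
      weight = max(.data$weight),
      provenance = if (all(is.na(.data$provenance))) NA_character_ else
        paste(unique(stats::na.omit(.data$provenance)), collapse = ";"),
      .groups = "drop") |>
    dplyr::arrange(.data$relation, .data$gene_a, .data$gene_b)

  structure(
    list(genes = reg$genes, edges = edges,
         vocabulary = vocabulary, mode = mode,
         strict_case = strict_case),
    class = "gene_network")
}

# Build the gene table: first-seen capitalization wins under case-insensitive
# matching; node-attribute rows are joined by the same key.
register_genes <- function(symbols, genes, strict_case) {
  sym_attr <- character(0)
  if (!is.null(genes)) {
    genes <- as_tibble(genes)
    if (!"symbol" %in% names(genes)) {
      abort_usage("`genes` needs a `symbol` column")
    }
    sym_attr <- genes$symbol
  }
  all_sym <- c(symbols, sym_attr)
  keys <- gene_key(all_sym, strict_case)
  first <- !duplicated(keys)
  canon <- setNames(all_sym[first], keys[first])

  tab <- tibble(symbol = unname(canon))
  tab$hallmark <- FALSE
  tab$modes <- ""
  if (!is.null(genes) && nrow(genes) > 0) {
    gk <- gene_key(genes$symbol, strict_case)
    idx <- match(gk, names(canon))
    if ("hallmark" %in% names(genes)) {
      hv <- as.logical(genes$hallmark)
      tab$hallmark[idx] <- ifelse(is.na(hv), FALSE, hv)
    }
    if ("modes" %in% names(genes)) {
      mv <- as.character(genes$modes)
      tab$modes[idx] <- ifelse(is.na(mv), "", mv)
    }
    extra <- setdiff(names(genes), c("symbol", "hallmark", "modes"))
    for (col in extra) {
      tab[[col]] <- genes[[col]][match(seq_len(nrow(tab)), idx)]
    }
  }
  if (any(!nzchar(tab$symbol))) abort_input("empty gene symbol")
  tab <- dplyr::arrange(tab, .data$symbol)
  list(genes = tab, canon = canon)
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network%s: %d genes, %d edges in %d layer(s)>\n",
              if (!is.null(x$mode)) paste0(" [", x$mode, "]") else "",
              nrow(x$genes), nrow(x$edges),
              dplyr::n_distinct(x$edges$relation)))
  invisible(x)
}

#' Read a typed edge table (TSV / SIF)
#'
#' Each non-comment line carries at least three tab-separated fields
#' `gene_a  relation  gene_b` and optionally `weight` and `provenance`
#' (SIF order `node relation node` is the same layout).  Comment lines start
#' with `#`.  Duplicate `(a, b, relation)` records collapse to a single edge
#' keeping the maximum weight; self-loops are rejected with a warning naming
#' the line; lines with fewer than three fields raise an error naming the
#' line.
#'
#' @param x A file path or a character vector of lines.
#' @param vocabulary Relation vocabulary the edges must belong to.
#' @param strict If `TRUE` (default) an unknown relation label is an error
#'   naming the line; if `FALSE` the record is skipped with a warning.
#' @param t_disambiguation How to read a bare `"T"` relation: `NA` (default)
#'   rejects it as ambiguous, `"TL"` reads it as translocation, `"TS"` as
#'   transcription.
#' @param mode,strict_case Passed to [gene_network()].
#' @return A [gene_network()].
#' @examples
#' read_edge_table(c("TP53\tPP\tBAX", "TP53\tA\tBBC3\t2"))
#' @export
read_edge_table <- function(x, vocabulary = default_vocabulary(),
                            strict = TRUE, t_disambiguation = NA,
                            mode = NULL, strict_case = FALSE) {
  vocabulary <- as_vocabulary(vocabulary)
  lines <- as_lines(x)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)

  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort_input(paste0("malformed edge line (fewer than 3 fields) at line ",
                       lineno[which(nf < 3)[1]]))
  }
  rec <- tibble(
    line = lineno,
    gene_a = vapply(fields, `[[`, "", 1),
    relation = vapply(fields, `[[`, "", 2),
    gene_b = vapply(fields, `[[`, "", 3),
    weight = vapply(fields, function(f)
      if (length(f) >= 4 && nzchar(f[4])) suppressWarnings(as.double(f[4]))
      else 1, 1.0),
    provenance = vapply(fields, function(f)
      if (length(f) >= 5) f[5] else NA_character_, ""))
  if (anyNA(rec$weight)) {
    abort_input(paste0("non-numeric weight at line ",
                       rec$line[which(is.na(rec$weight))[1]]))
  }

  if (!is.na(t_disambiguation)) {
    if (!t_disambiguation %in% c("TL", "TS")) {
      abort_usage("`t_disambiguation` must be NA, \"TL\" or \"TS\"")
    }
    rec$relation[rec$relation == "T"] <- t_disambiguation
  }

  unknown <- !rec$relation %in% vocabulary$label
  if (any(unknown)) {
    msg <- paste0("unknown relation label '",
                  rec$relation[unknown][1], "' at line ",
                  rec$line[unknown][1],
                  if (any(rec$relation[unknown] == "T"))
                    " (bare 'T' is ambiguous; set `t_disambiguation`)" else "")
    if (strict) abort_input(msg)
    warn(paste0(msg, "; ", sum(unknown), " record(s) skipped"))
    rec <- rec[!unknown, ]
  }

  loops <- gene_key(rec$gene_a, strict_case) == gene_key(rec$gene_b, strict_case)
  if (any(loops)) {
    warn(paste0("self-loop rejected at line ",
                paste(rec$line[loops], collapse = ", ")))
    rec <- rec[!loops, ]
  }

  gene_network(rec[, c("gene_a", "relation", "gene_b", "weight", "provenance")],
               vocabulary = vocabulary, mode = mode,
               strict_case = strict_case)
}

#' Write a network back to the edge-table format
#'
#' `write_network()` followed by [read_edge_table()] is the identity on
#' genes, layers and weights.
#'
#' @param net A [gene_network()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "gene_network"))
  df <- net$edges[, c("gene_a", "relation", "gene_b", "weight", "provenance")]
  df$provenance <- ifelse(is.na(df$provenance), "", df$provenance)
  write_xtsv(df, path)
}

#' Gene and per-layer edge counts
#'
#' @param net A [gene_network()].
#' @return A list with `n_genes` and a tibble `layers` of per-relation edge
#'   counts.
#' @export
census <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  layers <- net$edges |>
    dplyr::count(.data$relation, name = "n_edges") |>
    dplyr::arrange(.data$relation)
  list(n_genes = nrow(net$genes), layers = layers)
}

#' Read a node-attribute table
#'
#' Tab-separated columns: `symbol`, `hallmark` (0/1), `modes`
#' (semicolon-separated), then free columns (for example DSI/DPI/EI/Score
#' gene-disease association fields) carried through untouched.
#'
#' @param x A file path or character vector of lines.
#' @return A tibble suitable for the `genes` argument of [gene_network()].
#' @export
read_node_attributes <- function(x) {
  lines <- as_lines(x)
  hdr <- grepl("^\\s*#", lines)
  cols <- c("symbol", "hallmark", "modes")
  if (any(hdr)) {
    named <- strsplit(sub("^\\s*#\\s*", "", lines[hdr][1]), "\t")[[1]]
    if (length(named) >= 3) cols <- named[!named %in% sprintf("xtalknet=%s",
        as.character(utils::packageVersion("xtalknet")))]
  }
  body <- lines[!hdr & nzchar(trimws(lines))]
  if (length(body) == 0) return(tibble(symbol = character(0)))
  fields <- strsplit(body, "\t", fixed = TRUE)
  n <- max(lengths(fields))
  mat <- t(vapply(fields, function(f) c(f, rep(NA_character_, n - length(f))),
                  character(n)))
  colnames(mat) <- c(cols, paste0("attr", seq_len(max(0, n - length(cols)))))[seq_len(n)]
  out <- as_tibble(mat)
  if ("hallmark" %in% names(out)) out$hallmark <- out$hallmark %in% c("1", "TRUE", "true")
  out
}

#' @export
glance.gene_network <- function(x, ...) {
  tibble(n_genes = nrow(x$genes),
         n_edges = nrow(x$edges),
         n_layers = dplyr::n_distinct(x$edges$relation),
         n_hallmark = sum(x$genes$hallmark),
         mode = if (is.null(x$mode)) NA_character_ else x$mode)
}

#' @export
tidy.gene_network <- function(x, ...) {
  x$edges
}
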