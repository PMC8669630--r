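#' Read pathway gene sets in GMT format
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate genes within a line are collapsed; a line with fewer than three
#' fields or a duplicated set name is an error naming the line.
#'
#' @param x A file path or a character vector of lines.
#' @return A `geneset_collection`: a tibble with columns `set`,
#'   `description` and a list-column `genes`, one row per set.
#' @examples
#' read_gmt("S1\tapoptosis core\tTP53\tBAX\tBAX")
#' @export
read_gmt <- function(x) {
  lines <- as_lines(x)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort_input(paste0("GMT line with fewer than 3 fields at line ",
                       lineno[which(nf < 3)[1]]))
  }
  sets <- tibble(
    set = vapply(fields, `[[`, "", 1),
    description = vapply(fields, `[[`, "", 2),
    genes = lapply(fields, function(f) unique(f[-(1:2)])))
  if (anyDuplicated(sets$set)) {
    abort_input(paste0("duplicate gene-set name: ",
                       sets$set[duplicated(sets$set)][1]))
  }
  if (any(lengths(sets$genes) == 0)) {
    abort_input("empty gene set")
  }
  structure(sets, class = c("geneset_collection", class(sets)))
}

#' Build a gene-set collection from a named list
#'
#' @param sets Named list of character vectors of gene symbols.
#' @param descriptions Optional character vector parallel to `sets`.
#' @return A `geneset_collection` tibble.
#' @export
geneset_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    abort_usage("`sets` must be a uniquely named list")
  }
  if (any(lengths(sets) == 0)) abort_usage("empty gene set")
  out <- tibble(
    set = names(sets),
    description = descriptions %||% rep("", length(sets)),
    genes = lapply(unname(sets), unique))
  structure(out, class = c("geneset_collection", class(out)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a gene-set collection in GMT format
#'
#' @param sets A `geneset_collection`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$set[i], sets$description[i], sets$genes[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
tidy.geneset_collection <- function(x, ...) {
  tibble(set = rep(x$set, lengths(x$genes)),
         gene = unlist(x$genes, use.names = FALSE))
}
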