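#' The default 16-entry relation vocabulary
#'
#' Typed gene-gene interactions are classified into sixteen relation types
#' (protein-protein binding, activation, expression, regulation of binding,
#' phosphorylation, localization, membership, molecular cleavage,
#' translocation, inhibition, transcription, modification, protein-DNA,
#' ubiquitination, protein-RNA and chemical-protein interactions).  The
#' knowledge bases this vocabulary mirrors print both translocation and
#' transcription under the short code `"T"`; since labels must be unique
#' keys, the default vocabulary disambiguates them as `"TL"` (translocation)
#' and `"TS"` (transcription).  A bare `"T"` in an edge table is accepted
#' only with an explicit disambiguation flag (see [read_edge_table()]).
#'
#' Causal relations (activation, inhibition, ...) carry a `directed` flag as
#' metadata only: all layers are stored undirected because downstream
#' aggregation and spectral computation operate on symmetric structure.
#'
#' @return A tibble with columns `label`, `description` and `directed`,
#'   one row per relation type (16 rows).
#' @examples
#' default_vocabulary()
#' @export
default_vocabulary <- function() {
  tibble(
    label = c("PP", "A", "E", "RB", "P", "LO", "M", "MC",
              "TL", "I", "TS", "MO", "PD", "U", "PR", "CP"),
    description = c(
      "Protein-protein binding",
      "Activation",
      "Expression (includes metabolism/synthesis)",
      "Regulation of binding",
      "Phosphorylation",
      "Localization",
      "Membership",
      "Molecular cleavage",
      "Translocation",
      "Inhibition",
      "Transcription",
      "Modification",
      "Protein-DNA interactions",
      "Ubiquitination",
      "Protein-RNA interactions",
      "Chemical-protein interactions"),
    directed = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE,
                 TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  )
}

#' Coerce a data frame to a relation vocabulary
#'
#' @param x A data frame with columns `label` and `description`, and
#'   optionally `directed` (defaults to `FALSE`).
#' @return A validated vocabulary tibble.
#' @export
as_vocabulary <- function(x) {
  x <- as_tibble(x)
  if (!all(c("label", "description") %in% names(x))) {
    abort_usage("a vocabulary needs `label` and `description` columns")
  }
  if (!"directed" %in% names(x)) x$directed <- FALSE
  if (anyDuplicated(x$label)) {
    abort_usage(paste0("duplicate vocabulary labels: ",
                       paste(unique(x$label[duplicated(x$label)]),
                             collapse = ", ")))
  }
  x[, c("label", "description", "directed")]
}
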