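#' Multi-source intersection of miRNA-mRNA predictions
#'
#' Keeps a (miRNA, mRNA) pair only when it is predicted by *every* required
#' source and carries experimental evidence in at least one source; purely
#' computational predictions are dropped to limit false positives.
#'
#' @param table interaction tibble (see [read_interaction_table()]).
#' @param required_sources character vector of source names the pair must
#'   appear in; a required source entirely absent from the table triggers a
#'   warning (the intersection is then necessarily empty).
#' @return tibble of pairs: `mirna`, `target`, `n_sources`,
#'   `has_experimental_evidence` (all `TRUE` here), sorted by (mirna,
#'   target).
#' @export
intersect_mrna_predictions <- function(table, required_sources) {
  stopifnot(length(required_sources) >= 1L)
  tab <- dplyr::filter(tibble::as_tibble(table), .data$target_class == "mRNA")
  absent <- setdiff(required_sources, unique(tab$source))
  if (length(absent))
    warning("required source(s) absent from table: ",
            paste(absent, collapse = ", "), call. = FALSE)
  pairs <- tab |>
    dplyr::group_by(.data$mirna, .data$target) |>
    dplyr::summarise(
      n_sources = dplyr::n_distinct(.data$source[.data$source %in% required_sources]),
      has_experimental_evidence = any(.data$evidence == "experimental"),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_sources == length(unique(required_sources)),
                  .data$has_experimental_evidence) |>
    dplyr::arrange(.data$mirna, .data$target)
  pairs
}

#' Filter candidate miRNA-lncRNA interactions by subcellular localization
#'
#' A sponge must meet its miRNA in the cytoplasm, so lncRNAs annotated as
#' exclusively nuclear are excluded. lncRNAs annotated `cytoplasm` or
#' `both` are retained; `unknown` (or unannotated) localization is retained
#' but flagged, since only positive nuclear annotation contradicts the
#' ceRNA hypothesis.
#'
#' @param table interaction tibble restricted (internally) to lncRNA rows.
#' @return tibble of pairs: `mirna`, `target`, `n_sources`,
#'   `has_experimental_evidence`, `localization`, sorted by (mirna, target).
#' @export
filter_lncrna_interactions <- function(table) {
  tab <- dplyr::filter(tibble::as_tibble(table), .data$target_class == "lncRNA")
  tab$localization[is.na(tab$localization)] <- "unknown"
  tab <- dplyr::filter(tab, .data$localization != "nucleus")
  tab |>
    dplyr::group_by(.data$mirna, .data$target) |>
    dplyr::summarise(
      n_sources = dplyr::n_distinct(.data$source),
      has_experimental_evidence = any(.data$evidence == "experimental"),
      localization = .data$localization[1L],
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$mirna, .data$target)
}

#' Sponge-degree screen of candidate lncRNAs
#'
#' Retains lncRNAs negatively regulated by at least `min_degree` *distinct*
#' miRNAs (duplicate interaction rows with the same miRNA count once).
#'
#' @param pairs tibble of miRNA-lncRNA pairs with columns `mirna`,
#'   `target`.
#' @param min_degree minimum distinct-miRNA count (default 3).
#' @return sorted character vector of surviving lncRNA ids.
#' @export
sponge_degree_screen <- function(pairs, min_degree = 3L) {
  stopifnot(min_degree >= 1L)
  deg <- tibble::as_tibble(pairs) |>
    dplyr::distinct(.data$mirna, .data$target) |>
    dplyr::count(.data$target, name = "degree")
  sort(deg$target[deg$degree >= min_degree])
}
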