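#' Assemble lncRNA-miRNA-mRNA ceRNA triplets
#'
#' Joins the validated components on the shared miRNA: a triplet
#' (lncRNA, miRNA, mRNA) is emitted when the miRNA is selected (rising
#' anagen -> telogen), the lncRNA-miRNA and miRNA-mRNA pairs survive the
#' interaction filters, and both the lncRNA and the mRNA are
#' downregulated. Every valid combination is emitted (the network drawing
#' convention), so the triplet list is the exhaustive join. The
#' anticorrelation requirement is a direction-consistency constraint —
#' phase-wise direction of change, not a correlation coefficient.
#'
#' @param mirnas character vector of selected miRNA ids.
#' @param mrna_pairs tibble with columns `mirna`, `target` (mRNA pairs).
#' @param lncrna_pairs tibble with columns `mirna`, `target` (lncRNA
#'   pairs).
#' @param down_mrnas,down_lncrnas character vectors of downregulated ids.
#' @return a `cerna_network`: list with `triplets` (tibble `lncrna`,
#'   `mirna`, `mrna`, sorted lexicographically), deduplicated
#'   `mirna_mrna_edges` and `lncrna_mirna_edges` tibbles, and `nodes`
#'   (list of id vectors by class).
#' @export
assemble_network <- function(mirnas, mrna_pairs, lncrna_pairs,
                             down_mrnas, down_lncrnas) {
  mp <- tibble::as_tibble(mrna_pairs)
  lp <- tibble::as_tibble(lncrna_pairs)
  mp <- mp[mp$mirna %in% mirnas & mp$target %in% down_mrnas, c("mirna", "target")]
  lp <- lp[lp$mirna %in% mirnas & lp$target %in% down_lncrnas, c("mirna", "target")]
  names(mp) <- c("mirna", "mrna")
  names(lp) <- c("mirna", "lncrna")
  triplets <- dplyr::inner_join(lp, mp, by = "mirna",
                                relationship = "many-to-many")
  triplets <- dplyr::distinct(triplets[, c("lncrna", "mirna", "mrna")])
  triplets <- dplyr::arrange(triplets, .data$lncrna, .data$mirna, .data$mrna)
  new_cerna_network(triplets)
}

new_cerna_network <- function(triplets) {
  triplets <- tibble::as_tibble(triplets)[, c("lncrna", "mirna", "mrna")]
  mm <- dplyr::arrange(dplyr::distinct(triplets[, c("mirna", "mrna")]),
                       .data$mirna, .data$mrna)
  lm <- dplyr::arrange(dplyr::distinct(triplets[, c("lncrna", "mirna")]),
                       .data$lncrna, .data$mirna)
  structure(list(
    triplets = triplets,
    mirna_mrna_edges = mm,
    lncrna_mirna_edges = lm,
    nodes = list(
      mirnas = sort(unique(triplets$mirna)),
      mrnas = sort(unique(triplets$mrna)),
      lncrnas = sort(unique(triplets$lncrna))
    )
  ), class = "cerna_network")
}

#' Build a ceRNA network directly from a triplet table
#'
#' For worked examples and re-assembly from a network's own projections.
#'
#' @param triplets tibble/data frame with columns `lncrna`, `mirna`,
#'   `mrna`.
#' @return a `cerna_network`.
#' @export
cerna_network_from_triplets <- function(triplets) {
  t <- dplyr::arrange(dplyr::distinct(tibble::as_tibble(triplets)),
                      .data$lncrna, .data$mirna, .data$mrna)
  new_cerna_network(t)
}

#' @export
print.cerna_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf(paste0("<cerna_network> %d triplets | %d lncRNAs, %d miRNAs,",
                     " %d mRNAs | %d sponge edges, %d repression edges\n"),
              s$n_triplets, s$n_lncrnas, s$n_mirnas, s$n_mrnas,
              s$n_lncrna_mirna_edges, s$n_mirna_mrna_edges))
  invisible(x)
}

#' Summary counts of a ceRNA network
#'
#' @param network a `cerna_network`.
#' @return one-row tibble: `n_mirnas`, `n_mrnas`, `n_lncrnas`,
#'   `n_mirna_mrna_edges`, `n_lncrna_mirna_edges`, `n_triplets`.
#' @export
network_summary <- function(network) {
  stopifnot(inherits(network, "cerna_network"))
  tibble::tibble(
    n_mirnas = length(network$nodes$mirnas),
    n_mrnas = length(network$nodes$mrnas),
    n_lncrnas = length(network$nodes$lncrnas),
    n_mirna_mrna_edges = nrow(network$mirna_mrna_edges),
    n_lncrna_mirna_edges = nrow(network$lncrna_mirna_edges),
    n_triplets = nrow(network$triplets)
  )
}
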