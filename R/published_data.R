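#' Published per-phase miRNA expression means of the murine hair cycle
#'
#' The eleven mature miRNAs reported to rise monotonically from anagen
#' through catagen to telogen in the C57BL/6 dorsal-skin microarray study
#' this pipeline builds on, with their published per-phase mean intensities
#' (arbitrary microarray units) and microarray p-values. These values are
#' the worked example for the dual fold-change screen: feeding them to
#' [screen_mirnas()] as a one-sample-per-phase matrix reproduces the
#' published log2 FC(T/A) and log2 FC(C/A) columns and selects all eleven.
#'
#' @return tibble with columns `mirna`, `anagen`, `catagen`, `telogen`,
#'   `p_value`.
#' @export
hair_cycle_mirnas <- function() {
  path <- system.file("extdata", "hair_cycle_mirna_means.tsv",
                      package = "cernet", mustWork = TRUE)
  readr::read_tsv(path, col_types = "cdddd")
}

#' Published ceRNA axes of the murine hair follicle cycle
#'
#' The six validated lncRNA-miRNA-mRNA axes of the hair-cycle ceRNA
#' network, expanded into their individual triplets (shared-lncRNA and
#' shared-mRNA axes contribute one row per combination). Two lncRNAs
#' (Neat1, Tug1) sponge eight miRNAs that repress nine mRNAs.
#'
#' @return tibble with columns `lncrna`, `mirna`, `mrna`, one row per
#'   triplet.
#' @export
hair_cycle_axes <- function() {
  path <- system.file("extdata", "hair_cycle_cerna_axes.tsv",
                      package = "cernet", mustWork = TRUE)
  readr::read_tsv(path, col_types = "ccc")
}
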