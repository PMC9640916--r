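#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged per (sample, gene) first; then for
#' each sample, dCt = target Ct - reference-gene Ct; ddCt subtracts the
#' mean dCt of the calibrator group (per gene); relative expression is
#' `2^-ddCt`. Because the reference Ct is subtracted per sample, shifting
#' every Ct of a sample by a constant leaves the result unchanged.
#'
#' @param ct tibble/data frame with columns `sample`, `group`, `gene`,
#'   `ct` (and optionally `replicate`); the reference gene must be
#'   measured in every sample.
#' @param reference_gene endogenous-control gene id (e.g. Gapdh for
#'   mRNA/lncRNA assays, U6 for miRNA assays).
#' @param calibrator group label whose mean dCt anchors the scale
#'   (anagen in the hair-cycle design).
#' @return tibble: `sample`, `group`, `gene`, `ct_mean`, `delta_ct`,
#'   `delta_delta_ct`, `rel_expr` (reference-gene rows are omitted).
#' @export
relative_expression <- function(ct, reference_gene, calibrator) {
  ct <- tibble::as_tibble(ct)
  need <- setdiff(c("sample", "group", "gene", "ct"), names(ct))
  if (length(need))
    stop("Ct table missing column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(ct$ct <= 0)) stop("Ct values must be > 0", call. = FALSE)
  if (!calibrator %in% ct$group)
    stop("calibrator group not present: ", calibrator, call. = FALSE)
  agg <- ct |>
    dplyr::group_by(.data$sample, .data$group, .data$gene) |>
    dplyr::summarise(ct_mean = mean(.data$ct), .groups = "drop")
  ref <- dplyr::filter(agg, .data$gene == reference_gene)
  no_ref <- setdiff(unique(agg$sample), ref$sample)
  if (length(no_ref))
    stop("reference gene '", reference_gene, "' not measured in sample(s): ",
         paste(no_ref, collapse = ", "), call. = FALSE)
  tgt <- dplyr::filter(agg, .data$gene != reference_gene)
  tgt <- dplyr::left_join(
    tgt, dplyr::select(ref, "sample", ref_ct = "ct_mean"), by = "sample")
  tgt$delta_ct <- tgt$ct_mean - tgt$ref_ct
  cal <- tgt |>
    dplyr::filter(.data$group == calibrator) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(cal_dct = mean(.data$delta_ct), .groups = "drop")
  tgt <- dplyr::left_join(tgt, cal, by = "gene")
  if (anyNA(tgt$cal_dct))
    stop("gene(s) not measured in the calibrator group: ",
         paste(unique(tgt$gene[is.na(tgt$cal_dct)]), collapse = ", "),
         call. = FALSE)
  tgt$delta_delta_ct <- tgt$delta_ct - tgt$cal_dct
  tgt$rel_expr <- 2^(-tgt$delta_delta_ct)
  dplyr::arrange(
    dplyr::select(tgt, "sample", "group", "gene", "ct_mean",
                  "delta_ct", "delta_delta_ct", "rel_expr"),
    .data$gene, .data$group, .data$sample)
}

significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, Inf),
      labels = c("****", "***", "**", "*", "ns"))
}

#' Per-gene group comparison of relative expression
#'
#' Summarises 2^-ddCt values per gene and group (mean +/- SD) and tests
#' group differences: Welch's two-sided t for two groups, one-way ANOVA
#' for three or more. Significance bins follow the usual figure-legend
#' convention (`*` p < 0.05 through `****` p < 0.0001).
#'
#' @param rel tibble from [relative_expression()].
#' @param groups optional subset/order of group labels to compare
#'   (default: all groups present).
#' @return tibble with one row per gene: per-group `mean_<group>` and
#'   `sd_<group>` columns, `p_value`, `stars`.
#' @export
group_compare <- function(rel, groups = NULL) {
  rel <- tibble::as_tibble(rel)
  if (is.null(groups)) groups <- sort(unique(rel$group))
  rel <- dplyr::filter(rel, .data$group %in% groups)
  sizes <- dplyr::count(dplyr::distinct(rel, .data$group, .data$sample),
                        .data$group)
  small <- sizes$group[sizes$n < 2L]
  if (length(small))
    stop("fewer than 2 samples in group(s): ", paste(small, collapse = ", "),
         call. = FALSE)
  per_gene <- split(rel, rel$gene)
  rows <- lapply(per_gene, function(d) {
    stats_wide <- lapply(groups, function(g) {
      v <- d$rel_expr[d$group == g]
      stats::setNames(list(mean(v), stats::sd(v)),
                      paste0(c("mean_", "sd_"), g))
    })
    stats_wide <- unlist(stats_wide, recursive = FALSE)
    p <- if (length(groups) == 2L) {
      v1 <- d$rel_expr[d$group == groups[1L]]
      v2 <- d$rel_expr[d$group == groups[2L]]
      if (stats::sd(v1) == 0 && stats::sd(v2) == 0) {
        if (mean(v1) == mean(v2)) 1 else 0
      } else stats::t.test(v1, v2)$p.value
    } else {
      fit <- stats::oneway.test(rel_expr ~ group, data = d, var.equal = TRUE)
      p <- fit$p.value
      if (is.nan(p)) p <- 1  # zero between-group variance
      p
    }
    tibble::as_tibble(c(list(gene = d$gene[1L]), stats_wide,
                        list(p_value = p)))
  })
  out <- dplyr::bind_rows(rows)
  out$stars <- as.character(significance_stars(out$p_value))
  dplyr::arrange(out, .data$gene)
}
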