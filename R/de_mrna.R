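# Vectorized Welch two-sample t on the rows of a log2 matrix.
welch_t_rows <- function(log2_g1, log2_g2) {
  n1 <- ncol(log2_g1); n2 <- ncol(log2_g2)
  m1 <- rowMeans(log2_g1); m2 <- rowMeans(log2_g2)
  v1 <- rowSums((log2_g1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((log2_g2 - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  t <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * stats::pt(-abs(t), df)
  p[se2 == 0 & m1 == m2] <- 1
  p[se2 == 0 & m1 != m2] <- 0
  list(t = t, df = df, p = p)
}

# Paired t on per-pair log2 differences (columns matched by order).
paired_t_rows <- function(log2_g1, log2_g2) {
  if (ncol(log2_g1) != ncol(log2_g2))
    stop("paired mode needs equal group sizes", call. = FALSE)
  d <- log2_g2 - log2_g1
  n <- ncol(d)
  md <- rowMeans(d)
  vd <- rowSums((d - md)^2) / (n - 1L)
  t <- md / sqrt(vd / n)
  p <- 2 * stats::pt(-abs(t), n - 1L)
  p[vd == 0 & md == 0] <- 1
  p[vd == 0 & md != 0] <- 0
  list(t = t, df = rep(n - 1L, length(t)), p = p)
}

#' Two-group differential expression with fold-change thresholds
#'
#' Calls each gene up, down or unchanged between two phases (or any two
#' sample groups). The test is a two-sided Welch t-test on log2 values
#' (paired t in paired mode); fold change is the ratio of linear-scale
#' group means (`group2 / group1`). A gene is `up` when
#' p < `config$mrna_p` and FC > `config$mrna_fc`, `down` when
#' p < `config$mrna_p` and FC < 1/`config$mrna_fc`, else `unchanged` —
#' no multiple-testing gate enters the call, though BH q-values are
#' reported alongside.
#'
#' @param x a `phase_expr`.
#' @param group1,group2 phase labels; `group1` is the reference
#'   (denominator) group.
#' @param config a [run_config()].
#' @param paired use a paired t-test; samples are paired by column order
#'   within each group.
#' @return tibble with one row per gene: `gene_id`, `mean_group1`,
#'   `mean_group2`, `fc`, `log2fc`, `p_value`, `q_value`, `direction`,
#'   plus `neg_log10_p` for volcano plots.
#' @export
differential_expression <- function(x, group1, group2,
                                    config = run_config(), paired = FALSE) {
  stopifnot(inherits(x, "phase_expr"), inherits(config, "run_config"))
  x <- as_linear(x)
  i1 <- which(x$phases == group1)
  i2 <- which(x$phases == group2)
  if (length(i1) < 2L) stop("fewer than 2 samples in group: ", group1, call. = FALSE)
  if (length(i2) < 2L) stop("fewer than 2 samples in group: ", group2, call. = FALSE)
  vals <- pmax(x$values, config$expression_floor)
  lg <- log2(vals)
  tt <- if (paired) paired_t_rows(lg[, i1, drop = FALSE], lg[, i2, drop = FALSE])
        else welch_t_rows(lg[, i1, drop = FALSE], lg[, i2, drop = FALSE])
  m1 <- rowMeans(vals[, i1, drop = FALSE])
  m2 <- rowMeans(vals[, i2, drop = FALSE])
  fc <- m2 / m1
  p <- tt$p
  direction <- rep("unchanged", nrow(vals))
  direction[p < config$mrna_p & fc > config$mrna_fc] <- "up"
  direction[p < config$mrna_p & fc < 1 / config$mrna_fc] <- "down"
  tibble::tibble(
    gene_id = rownames(vals),
    mean_group1 = unname(m1), mean_group2 = unname(m2),
    fc = unname(fc), log2fc = unname(log2(fc)),
    p_value = unname(p),
    q_value = unname(stats::p.adjust(p, method = "BH")),
    neg_log10_p = unname(-log10(p)),
    direction = direction
  )
}

#' Intersect downregulated genes with candidate targets
#'
#' The Venn step of the cascade: genes that are both called `down` by
#' [differential_expression()] and present in the candidate target set.
#'
#' @param de tibble from [differential_expression()].
#' @param candidate_targets character vector of gene ids.
#' @return sorted character vector of gene ids.
#' @export
intersect_down_with_targets <- function(de, candidate_targets) {
  down <- de$gene_id[de$direction == "down"]
  sort(intersect(down, candidate_targets))
}
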