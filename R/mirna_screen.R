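#' Log2 fold change of two linear-scale means
#'
#' @param numerator_mean,denominator_mean strictly positive linear-scale
#'   expression values.
#' @return `log2(numerator_mean / denominator_mean)`; antisymmetric under
#'   swapping the arguments.
#' @export
log2_fold_change <- function(numerator_mean, denominator_mean) {
  if (any(numerator_mean <= 0) || any(denominator_mean <= 0))
    stop("fold change requires strictly positive means; ",
         "floor intensities (see run_config(expression_floor=)) first",
         call. = FALSE)
  log2(numerator_mean / denominator_mean)
}

#' Per-phase arithmetic means of one feature
#'
#' @param x a linear-scale `phase_expr`.
#' @param feature feature id present in `x`.
#' @return named numeric vector `c(anagen=, catagen=, telogen=)`.
#' @export
phase_means <- function(x, feature) {
  stopifnot(inherits(x, "phase_expr"))
  x <- as_linear(x)
  if (!feature %in% rownames(x$values))
    stop("feature not in matrix: ", feature, call. = FALSE)
  vapply(hair_cycle_phases(), function(ph) {
    idx <- x$phases == ph
    if (!any(idx)) stop("no samples in phase: ", ph, call. = FALSE)
    mean(x$values[feature, idx])
  }, numeric(1L))
}

# Vectorized one-way fixed-effects ANOVA across phase groups, computed on
# log2 values. Returns NA p for features with zero residual df.
anova_p_values <- function(values_log2, phases) {
  groups <- split(seq_along(phases), phases)
  k <- length(groups)
  n <- length(phases)
  grand <- rowMeans(values_log2)
  ss_between <- 0
  ss_within <- 0
  for (idx in groups) {
    gm <- rowMeans(values_log2[, idx, drop = FALSE])
    ss_between <- ss_between + length(idx) * (gm - grand)^2
    ss_within <- ss_within +
      rowSums((values_log2[, idx, drop = FALSE] - gm)^2)
  }
  df1 <- k - 1L
  df2 <- n - k
  if (df2 <= 0L) return(rep(NA_real_, nrow(values_log2)))
  f <- (ss_between / df1) / (ss_within / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  p[ss_within == 0 & ss_between == 0] <- 1
  p[ss_within == 0 & ss_between > 0] <- 0
  p
}

#' Screen miRNAs rising monotonically from anagen to telogen
#'
#' Implements the dual fold-change criterion: a miRNA is selected when its
#' p-value is below `config$mirna_p` and both log2 FC(telogen/anagen) and
#' log2 FC(catagen/anagen) strictly exceed `config$mirna_log2fc`. Fold
#' changes are computed on linear-scale phase means, floored at
#' `config$expression_floor`. p-values are taken from `p_values` when
#' supplied (the upstream microarray analysis is the usual provenance);
#' otherwise a one-way ANOVA across the three phases on log2 values is
#' computed as a stated substitute (requires replicates).
#'
#' @param x a `phase_expr` containing all three hair-cycle phases.
#' @param p_values optional named numeric vector of per-feature p-values.
#' @param config a [run_config()].
#' @return tibble with one row per feature: `mirna`, `mean_anagen`,
#'   `mean_catagen`, `mean_telogen`, `p_value`, `log2fc_TA`, `log2fc_CA`,
#'   `selected`; sorted by descending `log2fc_TA`, ties broken by id.
#' @export
screen_mirnas <- function(x, p_values = NULL, config = run_config()) {
  stopifnot(inherits(x, "phase_expr"), inherits(config, "run_config"))
  x <- as_linear(x)
  feats <- rownames(x$values)
  if (!length(feats)) {
    return(tibble::tibble(mirna = character(), mean_anagen = numeric(),
                          mean_catagen = numeric(), mean_telogen = numeric(),
                          p_value = numeric(), log2fc_TA = numeric(),
                          log2fc_CA = numeric(), selected = logical()))
  }
  for (ph in hair_cycle_phases())
    if (!any(x$phases == ph)) stop("no samples in phase: ", ph, call. = FALSE)
  means <- sapply(hair_cycle_phases(), function(ph)
    rowMeans(x$values[, x$phases == ph, drop = FALSE]))
  means <- pmax(means, config$expression_floor)
  if (is.null(p_values)) {
    floored <- pmax(x$values, config$expression_floor)
    p <- anova_p_values(log2(floored), x$phases)
    names(p) <- feats
  } else {
    missing_p <- setdiff(feats, names(p_values))
    if (length(missing_p))
      stop("no p-value supplied for: ", paste(utils::head(missing_p, 5),
                                              collapse = ", "), call. = FALSE)
    p <- as.numeric(p_values[feats])
  }
  fc_ta <- log2_fold_change(means[, "telogen"], means[, "anagen"])
  fc_ca <- log2_fold_change(means[, "catagen"], means[, "anagen"])
  out <- tibble::tibble(
    mirna = feats,
    mean_anagen = unname(means[, "anagen"]),
    mean_catagen = unname(means[, "catagen"]),
    mean_telogen = unname(means[, "telogen"]),
    p_value = unname(p),
    log2fc_TA = unname(fc_ta),
    log2fc_CA = unname(fc_ca),
    selected = unname(!is.na(p) & p < config$mirna_p &
      fc_ta > config$mirna_log2fc & fc_ca > config$mirna_log2fc)
  )
  dplyr::arrange(out, dplyr::desc(.data$log2fc_TA), .data$mirna)
}
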