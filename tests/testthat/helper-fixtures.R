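# Shared toy-data builders for the suite.

# features x samples phase_expr with samples_per_phase replicates, values
# supplied per feature per phase (linear scale).
toy_phase_expr <- function(per_phase_values, samples_per_phase = 1L,
                           scale = "linear") {
  feats <- rownames(per_phase_values)
  phases <- rep(cernet::hair_cycle_phases(), each = samples_per_phase)
  samples <- paste0(phases, "_", rep(seq_len(samples_per_phase), 3L))
  m <- matrix(NA_real_, nrow(per_phase_values), length(samples),
              dimnames = list(feats, samples))
  for (ph in cernet::hair_cycle_phases())
    m[, phases == ph] <- per_phase_values[, ph]
  cernet::phase_expression_matrix(m, stats::setNames(phases, samples),
                                  scale = scale)
}

# The published 11-miRNA per-phase means as a one-sample-per-phase matrix
# plus the published p-values.
published_mirna_fixture <- function() {
  tab <- cernet::hair_cycle_mirnas()
  m <- as.matrix(tab[, c("anagen", "catagen", "telogen")])
  rownames(m) <- tab$mirna
  list(expr = toy_phase_expr(m),
       p_values = stats::setNames(tab$p_value, tab$mirna),
       table = tab)
}

# Random interaction table over given id pools; plain tibble, already
# normalized ids.
random_interaction_table <- function(n_rows, mirnas, targets, sources,
                                     target_class = "mRNA") {
  loc <- if (target_class == "lncRNA")
    sample(c("nucleus", "cytoplasm", "both", "unknown"), n_rows,
           replace = TRUE) else rep(NA_character_, n_rows)
  tibble::tibble(
    mirna = sample(mirnas, n_rows, replace = TRUE),
    target = sample(targets, n_rows, replace = TRUE),
    target_class = target_class,
    source = sample(sources, n_rows, replace = TRUE),
    evidence = sample(c("experimental", "predicted"), n_rows, replace = TRUE),
    localization = loc
  ) |> dplyr::distinct(mirna, target, source, .keep_all = TRUE)
}

# Brute-force reference join for ceRNA assembly: triple loop over all
# (lncrna, mirna, mrna) combinations, checked against every rule.
brute_force_triplets <- function(mirnas, mrna_pairs, lncrna_pairs,
                                 down_mrnas, down_lncrnas) {
  all_lnc <- unique(lncrna_pairs$target)
  all_mrna <- unique(mrna_pairs$target)
  rows <- list()
  for (l in all_lnc) for (mi in unique(mirnas)) for (mr in all_mrna) {
    ok <- any(lncrna_pairs$mirna == mi & lncrna_pairs$target == l) &&
      any(mrna_pairs$mirna == mi & mrna_pairs$target == mr) &&
      l %in% down_lncrnas && mr %in% down_mrnas && mi %in% mirnas
    if (ok) rows[[length(rows) + 1L]] <-
        tibble::tibble(lncrna = l, mirna = mi, mrna = mr)
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out))
    return(tibble::tibble(lncrna = character(), mirna = character(),
                          mrna = character()))
  dplyr::arrange(dplyr::distinct(out), lncrna, mirna, mrna)
}
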