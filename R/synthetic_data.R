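#' Simulate a phase-annotated expression matrix with planted effects
#'
#' Baseline log2 abundances are drawn i.i.d. from N(`baseline_mean`,
#' `baseline_sd`). Planted "up" features rise monotonically across the
#' cycle: multiplied by `2^(0.6 * effect_log2fc)` in catagen and
#' `2^effect_log2fc` in telogen (emulating the anagen < catagen < telogen
#' pattern of the rising miRNAs); with `direction = "down"` the mirror
#' image is planted. i.i.d. N(0, `noise_sd_log2`) noise is added on the
#' log2 scale and the matrix is returned on the linear scale.
#'
#' @param n_features total feature count.
#' @param n_planted number of features carrying the planted effect
#'   (the first `n_planted` ids).
#' @param samples_per_phase replicate count per phase.
#' @param effect_log2fc planted telogen/anagen log2 fold change (> 0).
#' @param noise_sd_log2 residual noise SD on the log2 scale.
#' @param direction `"up"` (rising, miRNA-like) or `"down"` (falling,
#'   target-like).
#' @param prefix feature-id prefix.
#' @param baseline_mean,baseline_sd log2 baseline distribution.
#' @param seed integer seed; identical seeds give identical output.
#' @return list with `expr` (a linear-scale `phase_expr`) and `truth`
#'   (tibble `feature_id`, `planted`, `effect_log2fc`).
#' @export
simulate_expression <- function(n_features, n_planted, samples_per_phase = 3L,
                                effect_log2fc = 2, noise_sd_log2 = 0.2,
                                direction = c("up", "down"),
                                prefix = "feat", baseline_mean = 8,
                                baseline_sd = 2, seed = 1L) {
  direction <- match.arg(direction)
  if (n_planted > n_features) stop("n_planted > n_features", call. = FALSE)
  if (n_features < 1L || samples_per_phase < 1L)
    stop("invalid counts", call. = FALSE)
  if (effect_log2fc < 0) stop("effect_log2fc must be >= 0", call. = FALSE)
  withr::with_seed(seed, {
    phases <- rep(hair_cycle_phases(), each = samples_per_phase)
    samples <- paste0(phases, "_", rep(seq_len(samples_per_phase), times = 3L))
    feats <- sprintf("%s_%03d", prefix, seq_len(n_features))
    base <- stats::rnorm(n_features, baseline_mean, baseline_sd)
    sgn <- if (direction == "up") 1 else -1
    shift <- c(anagen = 0, catagen = 0.6, telogen = 1) * effect_log2fc * sgn
    m <- matrix(base, n_features, length(samples))
    planted <- seq_len(n_planted)
    for (j in seq_along(samples))
      m[planted, j] <- m[planted, j] + shift[[phases[j]]]
    m <- m + matrix(stats::rnorm(length(m), 0, noise_sd_log2),
                    n_features, length(samples))
    dimnames(m) <- list(feats, samples)
    expr <- phase_expression_matrix(2^m, stats::setNames(phases, samples),
                                    scale = "linear")
    truth <- tibble::tibble(
      feature_id = feats,
      planted = seq_len(n_features) %in% planted,
      effect_log2fc = ifelse(seq_len(n_features) %in% planted,
                             sgn * effect_log2fc, 0))
    list(expr = expr, truth = truth)
  })
}

#' Simulate multi-source miRNA target-prediction tables
#'
#' Planted interaction pairs from the truth manifest appear in every
#' source with experimental evidence (and, for lncRNAs, cytoplasmic
#' localization), so they survive the intersection + evidence +
#' localization filters. Decoy pairs are constructed to fail at least one
#' rule: each decoy is either assigned to a random strict subset of the
#' sources, or carried by all sources with `predicted`-only evidence, or
#' (for lncRNA decoys, with probability `nuclear_fraction`) annotated as
#' exclusively nuclear.
#'
#' @param planted_mrna_pairs tibble `mirna`, `target` of true miRNA-mRNA
#'   pairs.
#' @param planted_lncrna_pairs tibble `mirna`, `target` of true
#'   miRNA-lncRNA pairs.
#' @param sources character vector of source names (>= 3 to exercise the
#'   intersection rule).
#' @param n_decoys_per_class decoy pair count per target class.
#' @param nuclear_fraction probability a lncRNA decoy is made nuclear
#'   rather than source/evidence-deficient.
#' @param seed integer seed.
#' @return interaction tibble in [read_interaction_table()] layout.
#' @export
simulate_interaction_tables <- function(planted_mrna_pairs,
                                        planted_lncrna_pairs,
                                        sources = c("sourceA", "sourceB", "sourceC"),
                                        n_decoys_per_class = 50L,
                                        nuclear_fraction = 0.3,
                                        seed = 1L) {
  if (length(sources) < 3L)
    stop("need >= 3 sources to exercise the intersection rule", call. = FALSE)
  withr::with_seed(seed, {
    planted_rows <- function(pairs, class, loc) {
      if (!nrow(pairs)) return(NULL)
      tidyr::crossing(pairs, source = sources) |>
        dplyr::mutate(target_class = class, evidence = "experimental",
                      localization = loc)
    }
    decoy_rows <- function(pairs, class, n, decoy_prefix) {
      if (n < 1L) return(NULL)
      mirnas <- unique(pairs$mirna)
      if (!length(mirnas)) mirnas <- sprintf("miR-d%02d", 1:5)
      rows <- lapply(seq_len(n), function(i) {
        target <- sprintf("%s%03d", decoy_prefix, i)
        mirna <- sample(mirnas, 1L)
        mode <- if (class == "lncRNA" && stats::runif(1) < nuclear_fraction)
          "nuclear" else sample(c("subset", "predicted"), 1L)
        if (mode == "nuclear") {
          src <- sources; ev <- "experimental"; loc <- "nucleus"
        } else if (mode == "subset") {
          src <- sample(sources, sample(length(sources) - 1L, 1L))
          ev <- sample(c("experimental", "predicted"), 1L)
          loc <- if (class == "lncRNA") "cytoplasm" else NA_character_
        } else {
          src <- sources; ev <- "predicted"
          loc <- if (class == "lncRNA") "cytoplasm" else NA_character_
        }
        tibble::tibble(mirna = mirna, target = target, source = src,
                       target_class = class, evidence = ev,
                       localization = loc)
      })
      dplyr::bind_rows(rows)
    }
    tab <- dplyr::bind_rows(
      planted_rows(planted_mrna_pairs, "mRNA", NA_character_),
      planted_rows(planted_lncrna_pairs, "lncRNA", "cytoplasm"),
      decoy_rows(planted_mrna_pairs, "mRNA", n_decoys_per_class, "Decoygene"),
      decoy_rows(planted_lncrna_pairs, "lncRNA", n_decoys_per_class, "Decoylnc")
    )
    normalize_interaction_table(tab[, c("mirna", "target", "target_class",
                                        "source", "evidence", "localization")])
  })
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' Reference-gene Ct values are drawn around 18 cycles (SD 0.3 per
#' sample); each target gene adds a baseline dCt of ~5 cycles plus a
#' group-specific shift of `-log2(fold)` so that planted fold changes are
#' recovered by the 2^-ddCt method. Technical triplicates carry
#' N(0, 0.15) cycle noise.
#'
#' @param gene_fold tibble with columns `gene` and one fold-change column
#'   per group (relative to the calibrator), e.g.
#'   `tibble(gene = "Gspt1", anagen = 1, catagen = 0.5, telogen = 0.25)`.
#' @param groups group labels (columns of `gene_fold` to use).
#' @param n_per_group biological replicates per group.
#' @param reference_gene reference gene id added to every sample.
#' @param n_replicates technical replicates per (sample, gene).
#' @param seed integer seed.
#' @return Ct tibble: `sample`, `group`, `gene`, `replicate`, `ct`.
#' @export
simulate_ct_table <- function(gene_fold, groups = hair_cycle_phases(),
                              n_per_group = 3L, reference_gene = "Gapdh",
                              n_replicates = 3L, seed = 1L) {
  stopifnot(all(groups %in% names(gene_fold)), "gene" %in% names(gene_fold))
  withr::with_seed(seed, {
    rows <- list()
    for (g in groups) {
      for (s in seq_len(n_per_group)) {
        sample_id <- paste0(g, "_", s)
        ref_ct <- stats::rnorm(1, 18, 0.3)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          sample = sample_id, group = g, gene = reference_gene,
          replicate = seq_len(n_replicates),
          ct = ref_ct + stats::rnorm(n_replicates, 0, 0.15))
        for (i in seq_len(nrow(gene_fold))) {
          dct <- 5 - log2(gene_fold[[g]][i])
          rows[[length(rows) + 1L]] <- tibble::tibble(
            sample = sample_id, group = g, gene = gene_fold$gene[i],
            replicate = seq_len(n_replicates),
            ct = ref_ct + dct + stats::rnorm(n_replicates, 0, 0.15))
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Simulate the full synthetic input bundle with a truth manifest
#'
#' Generates every input the cascade consumes — miRNA, mRNA and lncRNA
#' phase expression matrices with planted effects, a decoy-laden
#' multi-source interaction table, a Ct table and a small gene-set
#' collection — together with the ground-truth manifest of planted
#' triplets. Planted miRNAs rise from anagen to telogen; the mRNAs and
#' lncRNAs they target fall. Planted triplets are laid out so each planted
#' lncRNA sponges five distinct miRNAs, comfortably above the
#' sponge-degree screen of three.
#'
#' @param n_mirnas,n_mrnas,n_lncrnas feature counts per class.
#' @param n_triplets planted triplet count.
#' @param samples_per_phase replicates per phase.
#' @param effect_log2fc planted log2 effect magnitude.
#' @param noise_sd_log2 log2 noise SD.
#' @param n_decoys_per_class decoy interaction pairs per target class.
#' @param nuclear_fraction see [simulate_interaction_tables()].
#' @param seed integer master seed (stage seeds are derived from it).
#' @return list with `mirna_expr`, `mrna_expr`, `lncrna_expr`
#'   (`phase_expr` objects), `interactions` (tibble), `ct` (tibble),
#'   `gene_sets` (named list), and `truth` (list with `triplets`,
#'   `up_mirnas`, `down_mrnas`, `down_lncrnas`, `seed`).
#' @export
simulate_cerna_bundle <- function(n_mirnas = 200L, n_mrnas = 2000L,
                                  n_lncrnas = 50L, n_triplets = 10L,
                                  samples_per_phase = 3L, effect_log2fc = 2.5,
                                  noise_sd_log2 = 0.2,
                                  n_decoys_per_class = 50L,
                                  nuclear_fraction = 0.3, seed = 42L) {
  n_lnc_planted <- max(1L, n_triplets %/% 5L)
  n_mir_planted <- n_triplets
  n_mrna_planted <- n_triplets
  stopifnot(n_mir_planted <= n_mirnas, n_mrna_planted <= n_mrnas,
            n_lnc_planted <= n_lncrnas)
  mir <- simulate_expression(n_mirnas, n_mir_planted, samples_per_phase,
                             effect_log2fc, noise_sd_log2, "up",
                             prefix = "miR-sim", seed = seed)
  mrna <- simulate_expression(n_mrnas, n_mrna_planted, samples_per_phase,
                              effect_log2fc, noise_sd_log2, "down",
                              prefix = "Gene", seed = seed + 1L)
  lnc <- simulate_expression(n_lncrnas, n_lnc_planted, samples_per_phase,
                             effect_log2fc, noise_sd_log2, "down",
                             prefix = "Lnc", seed = seed + 2L)
  up_mirnas <- normalize_mirna_id(mir$truth$feature_id[mir$truth$planted])
  down_mrnas <- normalize_gene_id(mrna$truth$feature_id[mrna$truth$planted])
  down_lncrnas <- normalize_gene_id(lnc$truth$feature_id[lnc$truth$planted])
  # triplet j: lncRNA block of 5 consecutive miRNAs each, mRNA j
  lnc_of <- down_lncrnas[pmin(((seq_len(n_triplets) - 1L) %/% 5L) + 1L,
                              n_lnc_planted)]
  triplets <- tibble::tibble(lncrna = lnc_of,
                             mirna = up_mirnas[seq_len(n_triplets)],
                             mrna = down_mrnas[seq_len(n_triplets)])
  interactions <- simulate_interaction_tables(
    planted_mrna_pairs = tibble::tibble(mirna = triplets$mirna,
                                        target = triplets$mrna),
    planted_lncrna_pairs = tibble::tibble(mirna = triplets$mirna,
                                          target = triplets$lncrna),
    n_decoys_per_class = n_decoys_per_class,
    nuclear_fraction = nuclear_fraction, seed = seed + 3L)
  fold_telogen <- 2^(-effect_log2fc)
  fold_catagen <- 2^(-0.6 * effect_log2fc)
  ct <- simulate_ct_table(
    tibble::tibble(gene = utils::head(down_mrnas, 3L), anagen = 1,
                   catagen = fold_catagen, telogen = fold_telogen),
    n_per_group = samples_per_phase, seed = seed + 4L)
  gene_sets <- withr::with_seed(seed + 5L, {
    all_genes <- normalize_gene_id(mrna$truth$feature_id)
    sets <- list(planted_set = down_mrnas)
    for (i in 1:5)
      sets[[paste0("random_set_", i)]] <- sample(all_genes, 50L)
    sets
  })
  list(mirna_expr = mir$expr, mrna_expr = mrna$expr, lncrna_expr = lnc$expr,
       interactions = interactions, ct = ct, gene_sets = gene_sets,
       truth = list(triplets = triplets, up_mirnas = up_mirnas,
                    down_mrnas = down_mrnas, down_lncrnas = down_lncrnas,
                    effect_log2fc = effect_log2fc,
                    noise_sd_log2 = noise_sd_log2, seed = seed))
}

#' Write a synthetic bundle to disk as pipeline input files
#'
#' Materializes every element of [simulate_cerna_bundle()] as the TSV /
#' GMT / YAML files the file-based pipeline consumes, plus the truth
#' manifest.
#'
#' @param bundle list from [simulate_cerna_bundle()].
#' @param dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
write_cerna_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_expression_matrix(bundle$mirna_expr, p("mirna_expr.tsv"), p("phases.tsv"))
  write_expression_matrix(bundle$mrna_expr, p("mrna_expr.tsv"))
  write_expression_matrix(bundle$lncrna_expr, p("lncrna_expr.tsv"))
  write_interaction_table(bundle$interactions, p("interactions.tsv"))
  readr::write_tsv(bundle$ct, p("ct.tsv"))
  write_gmt(bundle$gene_sets, p("gene_sets.gmt"))
  yaml::write_yaml(list(
    triplets = as.list(as.data.frame(bundle$truth$triplets)),
    up_mirnas = bundle$truth$up_mirnas,
    down_mrnas = bundle$truth$down_mrnas,
    down_lncrnas = bundle$truth$down_lncrnas,
    seed = bundle$truth$seed), p("truth.yaml"))
  paths <- list(mirna_expr = p("mirna_expr.tsv"), phases = p("phases.tsv"),
                mrna_expr = p("mrna_expr.tsv"), lncrna_expr = p("lncrna_expr.tsv"),
                interactions = p("interactions.tsv"), ct = p("ct.tsv"),
                gene_sets = p("gene_sets.gmt"), truth = p("truth.yaml"))
  invisible(paths)
}
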