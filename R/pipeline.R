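#' Run the full ceRNA inference cascade
#'
#' Chains the stages — miRNA dual fold-change screen, telogen-vs-anagen
#' differential expression of mRNAs and lncRNAs, multi-source target
#' intersection with evidence and localization filters, sponge-degree
#' screen, triplet assembly, and (when inputs are provided) enrichment and
#' qPCR quantification — with every stage communicating through files, so
#' each is independently inspectable and substitutable. Returns a run
#' manifest recording the configuration and each filter's input/output
#' counts.
#'
#' `config$paths` must name `mirna_expr`, `phases`, `mrna_expr`,
#' `lncrna_expr` and `interactions` (plus optional `mirna_pvals`, `ct`,
#' `gene_sets`, `reference_gene`, `calibrator`, `sources`), unless
#' `simulate = TRUE`, in which case a default synthetic bundle is written
#' under `outdir/inputs` with `config$seed` and used as input.
#'
#' @param config a [run_config()] (with a `paths` list) or path to a YAML
#'   config readable by [read_run_config()].
#' @param outdir output directory for stage files.
#' @param simulate generate the synthetic input bundle instead of
#'   requiring input paths.
#' @return the run manifest (list), invisibly written to
#'   `outdir/run_manifest.yaml`.
#' @export
run_cerna_pipeline <- function(config = run_config(), outdir, simulate = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$paths)) config$paths <- list()
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- config$paths

  if (simulate) {
    bundle <- simulate_cerna_bundle(seed = config$seed)
    paths <- write_cerna_bundle(bundle, file.path(outdir, "inputs"))
  } else {
    required <- c("mirna_expr", "phases", "mrna_expr", "lncrna_expr",
                  "interactions")
    missing_keys <- setdiff(required, names(paths))
    if (length(missing_keys))
      stop("config paths missing (and simulation disabled): ",
           paste(missing_keys, collapse = ", "), call. = FALSE)
    for (key in required)
      if (!file.exists(paths[[key]]))
        stop("input file for '", key, "' not found: ", paths[[key]],
             call. = FALSE)
  }
  counts <- list()
  out <- function(f) file.path(outdir, f)

  # -- stage 1: miRNA screen ------------------------------------------------
  mirna_expr <- read_expression_matrix(paths$mirna_expr, paths$phases)
  pvals <- NULL
  if (!is.null(paths$mirna_pvals)) {
    pv <- readr::read_tsv(paths$mirna_pvals, col_types = "cd")
    pvals <- stats::setNames(pv[[2L]], pv[[1L]])
  }
  screen <- screen_mirnas(mirna_expr, p_values = pvals, config = config)
  readr::write_tsv(screen, out("mirna_screen.tsv"))
  selected_mirnas <- normalize_mirna_id(screen$mirna[screen$selected])
  counts$mirna_screen <- c(input = nrow(screen),
                           selected = length(selected_mirnas))

  # -- stage 2: differential expression ------------------------------------
  de_gene <- function(path, label) {
    expr <- read_expression_matrix(path, paths$phases)
    de <- differential_expression(expr, "anagen", "telogen", config = config)
    de$gene_id <- normalize_gene_id(de$gene_id)
    readr::write_tsv(de, out(paste0("de_", label, ".tsv")))
    de
  }
  de_mrna <- de_gene(paths$mrna_expr, "mrna")
  de_lncrna <- de_gene(paths$lncrna_expr, "lncrna")
  down_mrnas <- normalize_gene_id(de_mrna$gene_id[de_mrna$direction == "down"])
  down_lncrnas <- normalize_gene_id(
    de_lncrna$gene_id[de_lncrna$direction == "down"])
  counts$de_mrna <- c(input = nrow(de_mrna), down = length(down_mrnas))
  counts$de_lncrna <- c(input = nrow(de_lncrna), down = length(down_lncrnas))

  # -- stage 3: target integration -----------------------------------------
  interactions <- read_interaction_table(paths$interactions)
  sources <- if (!is.null(paths$sources)) paths$sources
             else sort(unique(interactions$source))
  mrna_pairs <- intersect_mrna_predictions(interactions, sources)
  lncrna_pairs <- filter_lncrna_interactions(interactions)
  sponges <- sponge_degree_screen(lncrna_pairs, config$min_sponge_degree)
  readr::write_tsv(mrna_pairs, out("mrna_pairs.tsv"))
  readr::write_tsv(lncrna_pairs, out("lncrna_pairs.tsv"))
  counts$target_integration <- c(
    input_rows = nrow(interactions),
    mrna_pairs = nrow(mrna_pairs),
    lncrna_pairs = nrow(lncrna_pairs),
    sponge_lncrnas = length(sponges))

  # -- stage 4: ceRNA assembly ---------------------------------------------
  network <- assemble_network(
    mirnas = selected_mirnas,
    mrna_pairs = mrna_pairs,
    lncrna_pairs = lncrna_pairs,
    down_mrnas = intersect_down_with_targets(de_mrna, mrna_pairs$target),
    down_lncrnas = intersect(down_lncrnas, sponges))
  write_network_sif(network, out("network.sif"))
  readr::write_tsv(network$triplets, out("triplets.tsv"))
  summary_row <- network_summary(network)
  readr::write_tsv(summary_row, out("network_summary.tsv"))
  counts$cerna_assembly <- unlist(summary_row)

  # -- stage 5 (optional): enrichment of network mRNAs ---------------------
  if (!is.null(paths$gene_sets)) {
    sets <- read_gmt(paths$gene_sets)
    enr <- enrich(network$nodes$mrnas, sets)
    readr::write_tsv(enr, out("enrichment.tsv"))
    counts$enrichment <- c(sets_tested = nrow(enr),
                           significant = sum(enr$q_value < 0.05))
  }

  # -- stage 6 (optional): qPCR quantification -----------------------------
  if (!is.null(paths$ct)) {
    ct <- readr::read_tsv(paths$ct, col_types = readr::cols())
    ref <- if (!is.null(paths$reference_gene)) paths$reference_gene else "Gapdh"
    cal <- if (!is.null(paths$calibrator)) paths$calibrator else "anagen"
    rel <- relative_expression(ct, reference_gene = ref, calibrator = cal)
    readr::write_tsv(rel, out("qpcr_relative_expression.tsv"))
    readr::write_tsv(group_compare(rel), out("qpcr_group_stats.tsv"))
    counts$qpcr <- c(measurements = nrow(ct), quantified = nrow(rel))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cernet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = unclass(config)[setdiff(names(config), "paths")],
    inputs = lapply(paths, as.character),
    counts = lapply(counts, as.list)
  )
  yaml::write_yaml(manifest, out("run_manifest.yaml"))
  invisible(manifest)
}
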