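#' Canonical phase labels of the murine hair follicle cycle
#'
#' Growth (anagen), regression (catagen) and rest (telogen), the three
#' sample groups every phase-wise operation in the package understands.
#'
#' @return Character vector of the three phase labels.
#' @export
hair_cycle_phases <- function() c("anagen", "catagen", "telogen")

#' Normalize gene / lncRNA symbols
#'
#' Symbols are matched case-insensitively and stored in the murine
#' canonical case (first letter upper, rest lower), so that e.g.
#' `"gspt1"`, `"GSPT1"` and `"Gspt1"` collapse to one identifier.
#' Needed because public interaction tables mix murine and human
#' symbol conventions.
#'
#' @param x character vector of symbols.
#' @return character vector of canonicalized symbols.
#' @export
normalize_gene_id <- function(x) {
  x <- trimws(as.character(x))
  low <- tolower(x)
  paste0(toupper(substr(low, 1L, 1L)), substr(low, 2L, nchar(low)))
}

#' Normalize miRNA identifiers
#'
#' Strips species prefixes (`mmu-`, `hsa-`, `rno-`) and canonicalizes the
#' `miR-` capitalization, so murine and human spellings of the same mature
#' miRNA match.
#'
#' @param x character vector of miRNA ids.
#' @return character vector of canonicalized ids.
#' @export
normalize_mirna_id <- function(x) {
  x <- trimws(as.character(x))
  x <- sub("^(mmu|hsa|rno)-", "", x, ignore.case = TRUE)
  x <- tolower(x)
  sub("^mir", "miR", x)
}

#' Construct a phase-annotated expression matrix
#'
#' The central expression container: a features x samples numeric matrix
#' with one hair-cycle phase (or, more generally, group) label per sample
#' and a declared scale.
#'
#' @param values numeric matrix, rownames = feature ids, colnames = sample ids.
#' @param phases named character vector mapping every sample id to its
#'   phase label.
#' @param scale `"linear"` (non-negative intensities) or `"log2"`.
#' @param drop_missing_features drop features containing any missing cell
#'   instead of erroring. Imputation is deliberately not offered.
#' @return An object of class `phase_expr` with elements `values`,
#'   `phases` and `scale`.
#' @export
phase_expression_matrix <- function(values, phases, scale = c("linear", "log2"),
                                    drop_missing_features = FALSE) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      (ncol(values) > 0L && is.null(colnames(values))))
    stop("`values` must carry feature rownames and sample colnames", call. = FALSE)
  if (is.null(rownames(values))) rownames(values) <- character(0)
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup))
    stop("duplicated feature id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample id(s)", call. = FALSE)
  missing_phase <- setdiff(colnames(values), names(phases))
  if (length(missing_phase))
    stop("no phase label for sample(s): ", paste(missing_phase, collapse = ", "),
         call. = FALSE)
  phases <- as.character(phases[colnames(values)])
  names(phases) <- colnames(values)
  if (anyNA(values)) {
    if (drop_missing_features) {
      keep <- rowSums(is.na(values)) == 0L
      values <- values[keep, , drop = FALSE]
    } else {
      bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
      stop(sprintf("missing value at feature '%s', sample '%s'",
                   rownames(values)[bad[1L]], colnames(values)[bad[2L]]),
           call. = FALSE)
    }
  }
  if (scale == "linear" && any(values < 0))
    stop("linear-scale expression values must be >= 0", call. = FALSE)
  structure(list(values = values, phases = phases, scale = scale),
            class = "phase_expr")
}

#' @export
print.phase_expr <- function(x, ...) {
  cat(sprintf("<phase_expr> %d features x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  print(table(x$phases))
  invisible(x)
}

#' @export
dim.phase_expr <- function(x) dim(x$values)

#' Return a linear-scale copy of a phase expression matrix
#'
#' Matrices declared `log2` are de-logged; fold changes and phase means are
#' always computed on the linear scale.
#'
#' @param x a `phase_expr` object.
#' @return a `phase_expr` with `scale = "linear"`.
#' @export
as_linear <- function(x) {
  stopifnot(inherits(x, "phase_expr"))
  if (x$scale == "linear") return(x)
  phase_expression_matrix(2^x$values, x$phases, scale = "linear")
}

#' Read an expression matrix with its phase annotation
#'
#' Expects a strict tab-separated file: header row of sample ids, first
#' column of feature ids, numeric cells. The phase map is either a
#' two-column TSV (`sample`, `phase`) or a named character vector given
#' inline.
#'
#' @param path path to the expression TSV.
#' @param phase_map path to a phase-map TSV, or a named character vector
#'   `sample -> phase`.
#' @param scale declared scale of the stored values.
#' @param drop_missing_features see [phase_expression_matrix()].
#' @return a `phase_expr` object.
#' @export
read_expression_matrix <- function(path, phase_map, scale = c("linear", "log2"),
                                   drop_missing_features = FALSE) {
  scale <- match.arg(scale)
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()))
  if (ncol(df) < 2L)
    stop("expression file needs a feature-id column plus >= 1 sample column",
         call. = FALSE)
  feats <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(m), dim = dim(m), dimnames = dimnames(m)))
  bad <- which(is.na(num) & !is.na(m) & m != "NA", arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell '%s' at row %d, column '%s'",
                 m[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L],
                 colnames(m)[bad[1L, 2L]]), call. = FALSE)
  }
  rownames(num) <- feats
  if (is.character(phase_map) && length(phase_map) == 1L && is.null(names(phase_map))) {
    pm <- readr::read_tsv(phase_map, col_types = readr::cols(
      .default = readr::col_character()))
    if (!all(c("sample", "phase") %in% names(pm)))
      stop("phase map file must have columns 'sample' and 'phase'", call. = FALSE)
    phases <- stats::setNames(pm$phase, pm$sample)
  } else {
    phases <- phase_map
  }
  phase_expression_matrix(num, phases, scale = scale,
                          drop_missing_features = drop_missing_features)
}

#' Write an expression matrix and its phase map
#'
#' Inverse of [read_expression_matrix()]; writes the matrix TSV and,
#' optionally, a `sample`/`phase` TSV next to it.
#'
#' @param x a `phase_expr` object.
#' @param path output TSV path for the matrix.
#' @param phase_path optional output path for the phase map.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, phase_path = NULL) {
  stopifnot(inherits(x, "phase_expr"))
  df <- tibble::as_tibble(x$values, rownames = "feature_id")
  readr::write_tsv(df, path)
  if (!is.null(phase_path)) {
    readr::write_tsv(tibble::tibble(sample = names(x$phases),
                                    phase = unname(x$phases)), phase_path)
  }
  invisible(path)
}

interaction_columns <- c("mirna", "target", "target_class", "source",
                         "evidence", "localization")

#' Read a miRNA target-interaction table
#'
#' Tab-separated with columns `mirna`, `target`, `target_class`
#' (`mRNA`/`lncRNA`), `source`, `evidence` (`experimental`/`predicted`) and
#' an optional `localization` column (`nucleus`/`cytoplasm`/`both`/`unknown`,
#' lncRNA rows only). Identifiers are normalized
#' ([normalize_mirna_id()], [normalize_gene_id()]); rows are deduplicated on
#' (mirna, target, source).
#'
#' @param path path to the TSV.
#' @return tibble with the normalized interaction rows.
#' @export
read_interaction_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()))
  need <- setdiff(c("mirna", "target", "target_class", "source", "evidence"),
                  names(df))
  if (length(need))
    stop("interaction table missing column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!"localization" %in% names(df)) df$localization <- NA_character_
  normalize_interaction_table(df[interaction_columns])
}

#' Normalize an in-memory interaction table
#'
#' Applies the same identifier and category normalization and
#' deduplication as [read_interaction_table()].
#'
#' @param df data frame with the interaction-table columns.
#' @return normalized, deduplicated tibble.
#' @export
normalize_interaction_table <- function(df) {
  df <- tibble::as_tibble(df)
  if (!"localization" %in% names(df)) df$localization <- NA_character_
  cls <- tolower(trimws(df$target_class))
  bad <- setdiff(unique(cls), c("mrna", "lncrna"))
  if (length(bad))
    stop("unknown target_class value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  ev <- tolower(trimws(df$evidence))
  bad_ev <- setdiff(unique(ev), c("experimental", "predicted"))
  if (length(bad_ev))
    stop("unknown evidence value(s): ", paste(bad_ev, collapse = ", "),
         call. = FALSE)
  loc <- tolower(trimws(df$localization))
  loc[is.na(df$localization) | loc == ""] <- NA_character_
  bad_loc <- setdiff(stats::na.omit(unique(loc)),
                     c("nucleus", "cytoplasm", "both", "unknown"))
  if (length(bad_loc))
    stop("unknown localization value(s): ", paste(bad_loc, collapse = ", "),
         call. = FALSE)
  out <- tibble::tibble(
    mirna = normalize_mirna_id(df$mirna),
    target = normalize_gene_id(df$target),
    target_class = ifelse(cls == "mrna", "mRNA", "lncRNA"),
    source = trimws(df$source),
    evidence = ev,
    localization = loc
  )
  dplyr::distinct(out, .data$mirna, .data$target, .data$source,
                  .keep_all = TRUE)
}

#' Write an interaction table
#' @param df interaction tibble as returned by [read_interaction_table()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(df, path) {
  readr::write_tsv(df[interaction_columns], path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `set_id`, `description`,
#' then member gene ids. Members are normalized and deduplicated within a
#' set; empty sets are rejected.
#'
#' @param path path to the GMT file.
#' @return a named list of class `gene_set_collection`; each element is a
#'   character vector of members with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop("GMT line with fewer than 3 fields: ", substr(l, 1, 40), call. = FALSE)
    members <- unique(normalize_gene_id(parts[-(1:2)]))
    structure(members, description = parts[2L])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1L))
  if (anyDuplicated(names(sets)))
    stop("duplicated set id(s) in GMT", call. = FALSE)
  structure(sets, class = "gene_set_collection")
}

#' Write a GMT gene-set collection
#' @param sets named list of member vectors (a `gene_set_collection` or a
#'   plain named list).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    desc <- attr(sets[[i]], "description")
    if (is.null(desc)) desc <- names(sets)[i]
    paste(c(names(sets)[i], desc, sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Export a ceRNA network in SIF format
#'
#' One line per edge, `source<TAB>relation<TAB>target`, with relations
#' `lncrna_sponges_mirna` and `mirna_represses_mrna`, sorted
#' lexicographically so the export is deterministic. SIF is the minimal
#' Cytoscape interchange format.
#'
#' @param network a `cerna_network` (see [assemble_network()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_sif <- function(network, path) {
  stopifnot(inherits(network, "cerna_network"))
  lines <- character(0)
  if (nrow(network$lncrna_mirna_edges)) {
    lines <- c(lines, sprintf("%s\tlncrna_sponges_mirna\t%s",
                              network$lncrna_mirna_edges$lncrna,
                              network$lncrna_mirna_edges$mirna))
  }
  if (nrow(network$mirna_mrna_edges)) {
    lines <- c(lines, sprintf("%s\tmirna_represses_mrna\t%s",
                              network$mirna_mrna_edges$mirna,
                              network$mirna_mrna_edges$mrna))
  }
  writeLines(sort(lines), path)
  invisible(path)
}

#' Screening thresholds and pipeline settings
#'
#' Bundles every tunable threshold of the cascade. Defaults follow the
#' study design: miRNAs kept at p < 0.001 with both phase-wise
#' log2 FC > 1; genes called differential at t-test p < 0.05 with linear
#' FC > 2 or < 1/2; lncRNAs kept when sponged by >= 3 distinct miRNAs.
#'
#' @param mirna_p p-value threshold of the miRNA screen.
#' @param mirna_log2fc log2 fold-change threshold applied to both
#'   telogen/anagen and catagen/anagen ratios (strict `>`).
#' @param mrna_p differential-expression p threshold.
#' @param mrna_fc linear fold-change threshold (up if FC > `mrna_fc`, down
#'   if FC < 1/`mrna_fc`).
#' @param min_sponge_degree minimum number of distinct miRNAs targeting a
#'   candidate sponge lncRNA.
#' @param expression_floor linear intensities are floored here before
#'   ratios, a microarray background floor that avoids infinite fold
#'   changes.
#' @param seed integer seed used by simulation stages.
#' @return a `run_config` list.
#' @export
run_config <- function(mirna_p = 0.001, mirna_log2fc = 1,
                       mrna_p = 0.05, mrna_fc = 2,
                       min_sponge_degree = 3, expression_floor = 1,
                       seed = 42L) {
  stopifnot(mirna_p > 0, mirna_log2fc > 0, mrna_p > 0, mrna_fc > 0,
            min_sponge_degree >= 1, expression_floor > 0)
  structure(list(mirna_p = mirna_p, mirna_log2fc = mirna_log2fc,
                 mrna_p = mrna_p, mrna_fc = mrna_fc,
                 min_sponge_degree = as.integer(min_sponge_degree),
                 expression_floor = expression_floor,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a YAML run configuration
#'
#' Threshold fields missing from the file take the [run_config()] defaults;
#' any `paths:` mapping is carried through untouched.
#'
#' @param path path to a YAML file.
#' @return a `run_config` with an extra `paths` element (possibly empty).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  thr <- y[intersect(names(y), c("mirna_p", "mirna_log2fc", "mrna_p",
                                 "mrna_fc", "min_sponge_degree",
                                 "expression_floor", "seed"))]
  cfg <- do.call(run_config, thr)
  cfg$paths <- if (is.null(y$paths)) list() else y$paths
  cfg
}
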