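test_that("expression simulation is reproducible under a fixed seed", {
  a <- simulate_expression(50, 10, seed = 99)
  b <- simulate_expression(50, 10, seed = 99)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_expression(50, 10, seed = 100)
  expect_false(identical(a$expr$values, c_$expr$values))
  expect_error(simulate_expression(5, 10), "n_planted")
})

test_that("null simulation passes the dual screen only at the type-I rate", {
  sim <- simulate_expression(400, 0, effect_log2fc = 0, seed = 103)
  sc <- screen_mirnas(sim$expr)
  # the dual criterion stacks p < 0.001 on two fold-change cuts; with no
  # planted effect essentially nothing should pass
  expect_lte(sum(sc$selected), 2L)
})

test_that("planted fold changes land within sampling error of the target", {
  sim <- simulate_expression(100, 30, samples_per_phase = 3,
                             effect_log2fc = 2, noise_sd_log2 = 0.2,
                             seed = 107)
  sc <- screen_mirnas(sim$expr)
  planted <- sim$truth$feature_id[sim$truth$planted]
  fc <- sc$log2fc_TA[match(planted, sc$mirna)]
  se <- 0.2 * sqrt(2 / 3)           # SE of a difference of 3-sample means
  expect_true(all(abs(fc - 2) < 3 * se + 0.05))
  expect_lt(abs(mean(fc) - 2), 3 * se / sqrt(30))
  # monotone rise: catagen between anagen and telogen on average
  expect_lt(abs(mean(sc$log2fc_CA[match(planted, sc$mirna)]) - 1.2), 0.2)
})

test_that("interaction decoys fail at least one screening rule by design", {
  planted_m <- tibble::tibble(mirna = paste0("miR-", 1:6),
                              target = paste0("Gene", 1:6))
  planted_l <- tibble::tibble(mirna = paste0("miR-", 1:6),
                              target = rep(c("Lnc1", "Lnc2"), 3))
  tab <- simulate_interaction_tables(planted_m, planted_l,
                                     n_decoys_per_class = 40, seed = 109)
  sources <- sort(unique(tab$source))
  mp <- intersect_mrna_predictions(tab, sources)
  lp <- filter_lncrna_interactions(tab)
  survivors_l <- lp[lp$n_sources == 3 & lp$has_experimental_evidence, ]
  expect_equal(dplyr::arrange(mp[, c("mirna", "target")], mirna, target),
               dplyr::arrange(planted_m, mirna, target))
  expect_equal(dplyr::arrange(survivors_l[, c("mirna", "target")],
                              mirna, target),
               dplyr::arrange(dplyr::distinct(planted_l), mirna, target))
  # zero decoys: the filtered table is exactly the planted set
  tab0 <- simulate_interaction_tables(planted_m, planted_l,
                                      n_decoys_per_class = 0, seed = 109)
  expect_equal(nrow(tab0), (nrow(planted_m) + nrow(dplyr::distinct(planted_l))) * 3)
  expect_error(simulate_interaction_tables(planted_m, planted_l,
                                           sources = c("a", "b")), "3")
})

test_that("simulated Ct tables recover the planted folds by 2^-ddCt", {
  gf <- tibble::tibble(gene = "Gspt1", anagen = 1, catagen = 0.5,
                       telogen = 0.25)
  ct <- simulate_ct_table(gf, n_per_group = 4, seed = 113)
  rel <- relative_expression(ct, "Gapdh", "anagen")
  tel <- mean(rel$rel_expr[rel$group == "telogen"])
  expect_lt(abs(tel - 0.25), 0.07)
  ana <- mean(rel$rel_expr[rel$group == "anagen"])
  expect_lt(abs(ana - 1), 0.25)
  # no planted effect centers at 1
  flat <- simulate_ct_table(tibble::tibble(gene = "Gspt1", anagen = 1,
                                           catagen = 1, telogen = 1),
                            n_per_group = 4, seed = 113)
  relf <- relative_expression(flat, "Gapdh", "anagen")
  expect_lt(abs(mean(relf$rel_expr) - 1), 0.25)
  expect_identical(simulate_ct_table(gf, seed = 5),
                   simulate_ct_table(gf, seed = 5))
})

test_that("bundle outputs validate against the package readers", {
  bundle <- simulate_cerna_bundle(n_mirnas = 40, n_mrnas = 100,
                                  n_lncrnas = 12, n_triplets = 5,
                                  n_decoys_per_class = 10, seed = 127)
  d <- withr::local_tempdir()
  paths <- write_cerna_bundle(bundle, d)
  expect_silent({
    mir <- read_expression_matrix(paths$mirna_expr, paths$phases)
    tab <- read_interaction_table(paths$interactions)
    sets <- read_gmt(paths$gene_sets)
  })
  expect_equal(dim(mir), c(40L, 9L))
  expect_true(all(bundle$truth$triplets$mirna %in% tab$mirna))
  # every planted triplet component is present in the interaction table
  # with experimental evidence in all sources
  for (i in seq_len(nrow(bundle$truth$triplets))) {
    tr <- bundle$truth$triplets[i, ]
    rows <- tab[tab$mirna == tr$mirna & tab$target == tr$mrna, ]
    expect_equal(sort(unique(rows$source)), sort(unique(tab$source)))
    expect_true(all(rows$evidence == "experimental"))
  }
})
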