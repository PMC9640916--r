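simple_ct <- function() {
  # two groups, two samples each, one target + reference, no noise
  tibble::tibble(
    sample = rep(c("a1", "a2", "t1", "t2"), each = 2),
    group = rep(c("anagen", "anagen", "telogen", "telogen"), each = 2),
    gene = rep(c("Gapdh", "Gspt1"), 4),
    replicate = 1L,
    ct = c(18, 23, 18, 23,      # anagen: dCt = 5
           18, 25, 18, 25))     # telogen: dCt = 7
}

test_that("the 2^-ddCt arithmetic reproduces closed-form folds", {
  rel <- relative_expression(simple_ct(), "Gapdh", "anagen")
  tel <- rel[rel$group == "telogen", ]
  expect_equal(tel$delta_delta_ct, c(2, 2))
  expect_equal(tel$rel_expr, c(0.25, 0.25))   # 2^-2
  ana <- rel[rel$group == "anagen", ]
  expect_equal(ana$rel_expr, c(1, 1))         # at the calibrator mean
  # reference gene rows are not quantified
  expect_false("Gapdh" %in% rel$gene)
})

test_that("technical replicates are averaged before dCt", {
  ct <- simple_ct()
  ct2 <- dplyr::bind_rows(
    dplyr::mutate(ct, ct = ct + 0.3, replicate = 1L),
    dplyr::mutate(ct, ct = ct - 0.3, replicate = 2L))
  expect_equal(relative_expression(ct2, "Gapdh", "anagen")$rel_expr,
               relative_expression(ct, "Gapdh", "anagen")$rel_expr,
               tolerance = 1e-12)
})

test_that("per-sample Ct shifts cancel in the reference subtraction", {
  ct <- simple_ct()
  shifted <- dplyr::mutate(ct, ct = ct + ifelse(sample == "t1", 3.7, 0))
  expect_equal(relative_expression(shifted, "Gapdh", "anagen")$rel_expr,
               relative_expression(ct, "Gapdh", "anagen")$rel_expr,
               tolerance = 1e-12)
})

test_that("rel_expr strictly decreases in target Ct", {
  base <- simple_ct()
  bumped <- dplyr::mutate(base, ct = ct + ifelse(
    gene == "Gspt1" & sample == "t1", 1, 0))
  r0 <- relative_expression(base, "Gapdh", "anagen")
  r1 <- relative_expression(bumped, "Gapdh", "anagen")
  i <- r0$sample == "t1" & r0$gene == "Gspt1"
  expect_lt(r1$rel_expr[i], r0$rel_expr[i])
  expect_equal(r1$rel_expr[i], r0$rel_expr[i] / 2)
})

test_that("missing reference measurements are reported by sample", {
  ct <- dplyr::filter(simple_ct(), !(sample == "t2" & gene == "Gapdh"))
  expect_error(relative_expression(ct, "Gapdh", "anagen"), "t2")
  expect_error(relative_expression(simple_ct(), "Gapdh", "plucked"),
               "calibrator")
  expect_error(relative_expression(dplyr::mutate(simple_ct(), ct = ct - 30),
                                   "Gapdh", "anagen"), "> 0")
})

test_that("randomized Ct fixture matches independent spreadsheet arithmetic", {
  withr::with_seed(73, {
    genes <- c("Cdkn1a", "Notch1")
    groups <- hair_cycle_phases()
    rows <- expand.grid(sample = 1:3, group = groups, gene = c("Gapdh", genes),
                        replicate = 1:3, stringsAsFactors = FALSE)
    rows$sample <- paste0(rows$group, "_", rows$sample)
    rows$ct <- runif(nrow(rows), 15, 30)
    rel <- relative_expression(rows, "Gapdh", "anagen")
    # independent recomputation with base aggregate/merge only
    agg <- stats::aggregate(ct ~ sample + group + gene, rows, mean)
    ref <- agg[agg$gene == "Gapdh", c("sample", "ct")]
    for (g in genes) {
      sub <- merge(agg[agg$gene == g, ], ref, by = "sample")
      dct <- sub$ct.x - sub$ct.y
      cal <- mean(dct[sub$group == "anagen"])
      expected <- 2^(-(dct - cal))
      got <- rel[rel$gene == g, ]
      expect_equal(got$rel_expr[match(sub$sample, got$sample)], expected,
                   tolerance = 1e-12)
    }
  })
})

test_that("group comparison flags separation and handles identical groups", {
  rel_flat <- tibble::tibble(
    sample = paste0("s", 1:6),
    group = rep(c("anagen", "telogen"), each = 3),
    gene = "Gspt1",
    rel_expr = rep(1, 6))
  flat <- group_compare(rel_flat)
  expect_equal(flat$p_value, 1)
  expect_identical(flat$stars, "ns")

  rel_sep <- dplyr::mutate(rel_flat, rel_expr = c(1, 1.1, 0.9, 8, 8.1, 7.9))
  sep <- group_compare(rel_sep)
  oracle <- stats::t.test(c(8, 8.1, 7.9), c(1, 1.1, 0.9))$p.value
  expect_equal(sep$p_value, oracle, tolerance = 1e-10)
  expect_lt(sep$p_value, 0.001)
  expect_true(sep$stars %in% c("***", "****"))

  # three identical groups: between-group variance zero -> no signal
  rel3 <- tibble::tibble(
    sample = paste0("s", 1:9),
    group = rep(hair_cycle_phases(), each = 3),
    gene = "Gspt1", rel_expr = rep(c(1, 1.2, 0.8), 3))
  three <- group_compare(rel3)
  expect_gt(three$p_value, 0.99)
  expect_error(group_compare(rel_flat[-(1:2), ]), "anagen")
})

test_that("three-group ANOVA p matches stats::oneway.test", {
  withr::with_seed(79, {
    rel <- tibble::tibble(
      sample = paste0("s", 1:9),
      group = rep(hair_cycle_phases(), each = 3),
      gene = "Plk2", rel_expr = c(rnorm(3, 1, .2), rnorm(3, .6, .2),
                                  rnorm(3, .3, .2)))
    got <- group_compare(rel)
    oracle <- stats::oneway.test(rel_expr ~ group, rel, var.equal = TRUE)
    expect_equal(got$p_value, oracle$p.value, tolerance = 1e-12)
  })
})
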