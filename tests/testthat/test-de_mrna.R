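make_two_group_expr <- function(g1_values, g2_values, feats = NULL) {
  n1 <- ncol(g1_values); n2 <- ncol(g2_values)
  m <- cbind(g1_values, g2_values)
  if (is.null(feats)) feats <- paste0("g", seq_len(nrow(m)))
  rownames(m) <- feats
  colnames(m) <- c(paste0("a", seq_len(n1)), paste0("t", seq_len(n2)))
  phases <- stats::setNames(c(rep("anagen", n1), rep("telogen", n2)),
                            colnames(m))
  phase_expression_matrix(m, phases)
}

test_that("identical groups give fc = 1 and no call", {
  x <- make_two_group_expr(matrix(5, 1, 3), matrix(5, 1, 3))
  de <- differential_expression(x, "anagen", "telogen")
  expect_equal(de$fc, 1)
  expect_equal(de$log2fc, 0)
  expect_identical(de$direction, "unchanged")
})

test_that("Welch t and fold change match hand-computed oracle on a toy gene", {
  g1 <- matrix(c(1, 1, 1), 1)
  g2 <- matrix(c(8, 8.5, 7.5), 1)
  x <- make_two_group_expr(g1, g2)
  de <- differential_expression(x, "anagen", "telogen")
  expect_equal(de$fc, 8)                # linear mean ratio
  oracle <- stats::t.test(log2(c(8, 8.5, 7.5)), log2(c(1, 1, 1) * 1))
  # values of 1 hit the default intensity floor of 1, log2 = 0
  expect_equal(de$p_value, oracle$p.value, tolerance = 1e-12)
  expect_identical(de$direction, "up")
})

test_that("p-values agree with stats::t.test across random genes", {
  withr::with_seed(17, {
    m1 <- matrix(2^rnorm(40 * 4, 8, 1), 40, 4)
    m2 <- matrix(2^rnorm(40 * 5, 8.5, 1), 40, 5)
    x <- make_two_group_expr(m1, m2)
    de <- differential_expression(x, "anagen", "telogen")
    for (i in sample(40, 8)) {
      oracle <- stats::t.test(log2(m2[i, ]), log2(m1[i, ]))$p.value
      expect_equal(de$p_value[i], oracle, tolerance = 1e-10)
    }
    # paired mode against stats::t.test(paired = TRUE)
    xp <- make_two_group_expr(m1, m2[, 1:4])
    dep <- differential_expression(xp, "anagen", "telogen", paired = TRUE)
    for (i in sample(40, 5)) {
      oracle <- stats::t.test(log2(m2[i, 1:4]), log2(m1[i, ]),
                              paired = TRUE)$p.value
      expect_equal(dep$p_value[i], oracle, tolerance = 1e-10)
    }
  })
})

test_that("exchanging group labels inverts fold change and swaps calls", {
  withr::with_seed(23, {
    m1 <- matrix(2^rnorm(60 * 3, 8, 1), 60, 3)
    m2 <- matrix(2^rnorm(60 * 3, 8, 1.5), 60, 3)
    x <- make_two_group_expr(m1, m2)
    fwd <- differential_expression(x, "anagen", "telogen")
    rev <- differential_expression(x, "telogen", "anagen")
    expect_equal(rev$fc, 1 / fwd$fc, tolerance = 1e-12)
    expect_equal(rev$p_value, fwd$p_value, tolerance = 1e-12)
    expect_identical(rev$direction[fwd$direction == "up"],
                     rep("down", sum(fwd$direction == "up")))
    expect_identical(rev$direction[fwd$direction == "down"],
                     rep("up", sum(fwd$direction == "down")))
  })
})

test_that("groups with fewer than 2 samples are rejected by name", {
  m <- matrix(2^rnorm(10 * 4, 8, 1), 10, 4,
              dimnames = list(paste0("g", 1:10), c("a1", "a2", "t1", "c1")))
  x <- phase_expression_matrix(
    m, c(a1 = "anagen", a2 = "anagen", t1 = "telogen", c1 = "catagen"))
  expect_error(differential_expression(x, "anagen", "telogen"), "telogen")
})

test_that("null data yields ~5% type-I rate and up/down counts behave", {
  withr::with_seed(31, {
    n <- 2000L
    m1 <- matrix(2^rnorm(n * 5, 8, 1), n, 5)
    m2 <- matrix(2^rnorm(n * 5, 8, 1), n, 5)
    x <- make_two_group_expr(m1, m2)
    de <- differential_expression(x, "anagen", "telogen")
    rate <- mean(de$p_value < 0.05)
    se <- sqrt(0.05 * 0.95 / n)
    expect_lt(abs(rate - 0.05), 4 * se)
    # counts bounded and monotone non-increasing in the fc threshold
    for (f in c(1.5, 2, 3, 4)) {
      cfg <- run_config(mrna_fc = f)
      d <- differential_expression(x, "anagen", "telogen", config = cfg)
      expect_lte(sum(d$direction != "unchanged"), n)
    }
    counts <- vapply(c(1.5, 2, 3, 4), function(f) {
      d <- differential_expression(x, "anagen", "telogen",
                                   config = run_config(mrna_fc = f))
      sum(d$direction == "up")
    }, integer(1L))
    expect_true(all(diff(counts) <= 0L))
  })
})

test_that("planted 2.5x down-genes are recovered with sensitivity >= 0.9", {
  # 20 simulation replicates, n = 5/group, sigma 0.3 log2
  sens <- vapply(1:20, function(r) {
    withr::with_seed(4000 + r, {
      n <- 50L
      base <- rnorm(n, 8, 2)
      m1 <- matrix(base, n, 5) + matrix(rnorm(n * 5, 0, 0.3), n, 5)
      m2 <- matrix(base - log2(2.5), n, 5) + matrix(rnorm(n * 5, 0, 0.3), n, 5)
      x <- make_two_group_expr(2^m1, 2^m2)
      de <- differential_expression(x, "anagen", "telogen")
      mean(de$direction == "down")
    })
  }, numeric(1L))
  expect_gte(mean(sens), 0.9)
})

test_that("down/target intersection equals brute-force set logic", {
  de <- tibble::tibble(
    gene_id = paste0("g", 1:10),
    direction = rep(c("down", "up", "unchanged", "down", "down"), 2))
  targets <- c("g1", "g2", "g4", "g9", "zzz")
  got <- intersect_down_with_targets(de, targets)
  brute <- sort(Reduce(intersect, list(
    de$gene_id[de$direction == "down"], targets)))
  expect_identical(got, brute)
  expect_identical(intersect_down_with_targets(de, character(0)), character(0))
  down_all <- de$gene_id[de$direction == "down"]
  expect_identical(intersect_down_with_targets(de, down_all), sort(down_all))
})
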