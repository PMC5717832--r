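test_that("odds ratios reproduce from carrier tables and are antisymmetric", {
  expect_lt(abs(odds_ratio(26, 3990, 3, 2869) - 6.24), 0.01)
  expect_equal(round(odds_ratio(18, 3998, 6, 2866), 2), 2.15)
  expect_lt(abs(odds_ratio(4, 2132, 1, 1031) - 1.94), 0.01)
  expect_equal(round(odds_ratio(13, 1333, 13, 2657), 2), 1.99)
  expect_equal(odds_ratio(7, 100, 7, 100), 1)
  for (tab in list(c(5, 10, 3, 20), c(1, 7, 9, 2))) {
    expect_equal(odds_ratio(tab[1], tab[2], tab[3], tab[4]) *
                   odds_ratio(tab[3], tab[4], tab[1], tab[2]), 1)
  }
  expect_error(odds_ratio(0, 0, 0, 0), "all-zero")
})

test_that("the Woolf interval reproduces and brackets the point estimate", {
  ci <- woolf_ci(26, 3990, 3, 2869)
  expect_equal(round(as.numeric(ci), 1), c(1.9, 20.6))
  for (tab in list(c(5, 10, 3, 20), c(12, 88, 7, 93), c(26, 3990, 3, 2869))) {
    ci <- woolf_ci(tab[1], tab[2], tab[3], tab[4])
    or <- odds_ratio(tab[1], tab[2], tab[3], tab[4])
    expect_lt(ci[["low"]], or)
    expect_gt(ci[["high"]], or)
  }
  # symmetric table: interval symmetric about 1 on the log scale
  ci <- woolf_ci(100, 100, 100, 100)
  expect_equal(log(ci[["low"]]), -log(ci[["high"]]))
  # zero cells fall back to the Haldane correction, flagged
  ci0 <- woolf_ci(5, 10, 0, 15)
  expect_true(attr(ci0, "corrected"))
})

test_that("Fisher exact p values match hypergeometric enumeration", {
  expect_equal(signif(fisher_exact_two_sided(26, 3990, 3, 2869), 1), 4e-4)
  expect_equal(fisher_exact_two_sided(2, 2, 2, 2), 1)
  # independent enumeration: sum of table probabilities <= P(observed)
  enum_p <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    x <- max(0, k - n):min(k, m)
    pr <- dhyper(x, m, n, k)
    sum(pr[pr <= dhyper(a, m, n, k) * (1 + 1e-7)])
  }
  expect_equal(fisher_exact_two_sided(5, 0, 0, 5), enum_p(5, 0, 0, 5))
  expect_equal(fisher_exact_two_sided(5, 0, 0, 5), 2 / 252, tolerance = 1e-9)
  for (tab in list(c(3, 7, 5, 5), c(8, 2, 1, 9), c(4, 16, 9, 11))) {
    expect_equal(fisher_exact_two_sided(tab[1], tab[2], tab[3], tab[4]),
                 enum_p(tab[1], tab[2], tab[3], tab[4]), tolerance = 1e-8)
    # invariant under transposition
    expect_equal(fisher_exact_two_sided(tab[1], tab[2], tab[3], tab[4]),
                 fisher_exact_two_sided(tab[1], tab[3], tab[2], tab[4]))
  }
})

test_that("carrier_association assembles the 2x2 from counts and group sizes", {
  a <- carrier_association(26, 4016, 3, 2872)
  expect_equal(unname(a$table), c(26, 3990, 3, 2869))
  td <- tidy(a)
  expect_lt(abs(td$or - 6.24), 0.01)
  expect_equal(round(c(td$ci_low, td$ci_high), 1), c(1.9, 20.6))
  expect_error(carrier_association(10, 5, 0, 100), "exceed")
})

test_that("Woolf intervals achieve nominal coverage on simulated tables", {
  # 10^4 tables with known OR 2 (carrier prob 0.05 in controls)
  set.seed(42)
  n1 <- 2000; n0 <- 2000
  p0 <- 0.05; odds1 <- 2 * p0 / (1 - p0); p1 <- odds1 / (1 + odds1)
  a <- rbinom(1e4, n1, p1); c <- rbinom(1e4, n0, p0)
  b <- n1 - a; d <- n0 - c
  lor <- log((a * d) / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  cover <- mean(lor - 1.959964 * se <= log(2) & log(2) <= lor + 1.959964 * se)
  # vectorised arithmetic above is definitionally identical to woolf_ci;
  # spot-check agreement on one table, then assert coverage
  ci1 <- woolf_ci(a[1], b[1], c[1], d[1])
  expect_equal(as.numeric(ci1), exp(lor[1] + c(-1, 1) * 1.959964 * se[1]),
               tolerance = 1e-6)
  expect_lt(abs(cover - 0.95), 0.02)
})

test_that("identical pool counts give a null burden p value", {
  pc <- tibble(pool_id = sprintf("P%d", 1:20), count = 3L, pool_size = 20L,
               stratum = rep(c("case", "control"), each = 10))
  bt <- gene_burden_test(pc, n_perm = 99, seed = 1)
  expect_equal(bt$p, 1)
  expect_gte(bt$p, 0.5)
  expect_error(gene_burden_test(pc[c(1, 11, 12), ], n_perm = 9), "2 pools")
})

test_that("burden permutation p values are valid and deterministic", {
  set.seed(7)
  pc <- tibble(pool_id = sprintf("P%d", 1:30),
               count = rpois(30, 2), pool_size = 20L,
               stratum = rep(c("case", "control"), 15))
  b1 <- gene_burden_test(pc, n_perm = 199, seed = 5)
  b2 <- gene_burden_test(pc, n_perm = 199, seed = 5)
  expect_identical(b1$p, b2$p)
  expect_gte(b1$p, 1 / 200)
  expect_lte(b1$p, 1)
})

test_that("burden test detects a GCK-like case-control enrichment", {
  # 20 case carriers among ~4016 cases vs 1 among ~2872 controls spread
  # over screen-scale pools of 24
  ps <- map_dbl(1:20, function(r) {
    set.seed(400 + r)
    n_case_pools <- 168; n_ctrl_pools <- 120
    counts <- c(tabulate(sample(n_case_pools, 20, replace = TRUE),
                         n_case_pools),
                tabulate(sample(n_ctrl_pools, 1), n_ctrl_pools))
    pc <- tibble(pool_id = sprintf("P%d", seq_along(counts)),
                 count = counts, pool_size = 24L,
                 stratum = rep(c("case", "control"),
                               c(n_case_pools, n_ctrl_pools)))
    gene_burden_test(pc, n_perm = 999, seed = r)$p
  })
  expect_lt(median(ps), 0.02)
})

test_that("null burden p values are uniform at the nominal level", {
  # 1000 independent null genes over 60 pools with exchangeable labels.
  # Dense per-pool counts keep permutation ties rare; with sparse counts
  # the (r+1)/(n_perm+1) convention is conservative, never anticonservative.
  rejections <- map_dbl(1:1000, function(g) {
    set.seed(5000 + g)
    pc <- tibble(pool_id = sprintf("P%d", 1:60),
                 count = rpois(60, 20), pool_size = 20L,
                 stratum = rep(c("case", "control"), each = 30))
    gene_burden_test(pc, n_perm = 199, seed = 9000 + g)$p
  })
  expect_lt(abs(mean(rejections <= 0.05) - 0.05), 0.02)
  ks <- suppressWarnings(stats::ks.test(rejections, "punif"))
  expect_gt(ks$p.value, 0.01)
})
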