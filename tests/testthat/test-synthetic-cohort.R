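test_that("cohort generation respects sizes, onset grouping and determinism", {
  cfg <- cohort_config(n_cases = 4016, n_controls = 2872, n_variants = 50,
                       seed = 11)
  cohort <- generate_cohort(cfg)
  expect_equal(nrow(cohort$phenotypes), 6888)
  expect_equal(sum(cohort$phenotypes$status == "case"), 4016)
  expect_equal(sum(cohort$phenotypes$onset_group == "early"), 1346)
  # controls carry no age; early iff case and age < 40
  ph <- cohort$phenotypes
  expect_true(all(is.na(ph$age_at_diagnosis[ph$status == "control"])))
  expect_true(all((ph$onset_group == "early") ==
                    (ph$status == "case" &
                       !is.na(ph$age_at_diagnosis) &
                       ph$age_at_diagnosis < 40)))
  # bit-identical under the same seed
  again <- generate_cohort(cfg)
  expect_identical(cohort$phenotypes, again$phenotypes)
  expect_identical(cohort$genotypes, again$genotypes)
})

test_that("config validation rejects bad parameters", {
  expect_error(cohort_config(n_cases = 0), "positive")
  expect_error(cohort_config(pathogenic_or = 0.5), ">= 1")
  expect_error(cohort_config(error_rate = 0.05), "0.01")
})

test_that("a null pathogenic site is equally frequent in cases and controls", {
  reps <- map_dfr(1:200, function(r) {
    cfg <- cohort_config(n_cases = 500, n_controls = 500, n_variants = 0,
                         n_pathogenic = 1, pathogenic_af = 0.02,
                         pathogenic_or = 1, seed = 100 + r)
    cohort <- generate_cohort(cfg)
    carr <- cohort$phenotypes$id %in% cohort$genotypes$id
    tibble(case = sum(carr & cohort$phenotypes$status == "case"),
           ctrl = sum(carr & cohort$phenotypes$status == "control"))
  })
  # equal expected carrier counts; difference of two Bin(500, ~0.04) means
  expect_lt(abs(mean(reps$case) - mean(reps$ctrl)),
            3 * sqrt(2 * 500 * 0.04 * 0.96 / 200))
})

test_that("a pathogenic site with carrier OR 6 reproduces the effect size", {
  lors <- vapply(1:500, function(r) {
    cfg <- cohort_config(n_cases = 4016, n_controls = 2872, n_variants = 0,
                         n_pathogenic = 1, pathogenic_af = 5e-4,
                         pathogenic_or = 6, seed = 2000 + r)
    cohort <- generate_cohort(cfg)
    carr <- cohort$phenotypes$id %in% cohort$genotypes$id
    a <- sum(carr & cohort$phenotypes$status == "case")
    c <- sum(carr & cohort$phenotypes$status == "control")
    log(odds_ratio(a, 4016 - a, c, 2872 - c, haldane = TRUE))
  }, numeric(1))
  expect_lt(abs(mean(lors) - log(6)), 0.1 * log(6))
})

test_that("the default frequency spectrum is singleton-dominated", {
  n2 <- 2 * 3720  # chromosomes in a stage-1-sized cohort
  stats <- map_dfr(1:20, function(r) {
    af <- sample_site_frequency_spectrum(655, seed = 300 + r)
    ac <- rbinom(length(af), n2, af)  # summed Binomial(2, af) genotypes
    disc <- ac[ac >= 1]
    tibble(singleton = mean(disc == 1), low_af = mean(disc / n2 <= 0.001))
  })
  expect_gte(median(stats$singleton), 0.45)
  expect_gte(median(stats$low_af), 0.70)
  expect_lt(abs(median(stats$singleton) - 0.54), 0.07)
  expect_lt(abs(median(stats$low_af) - 0.81), 0.06)
})

test_that("a point-mass spectrum at one chromosome is singleton-dominated", {
  af <- sample_site_frequency_spectrum(2000, alpha = 1,
                                       f_min = 1 / 7440 - 1e-9,
                                       f_max = 1 / 7440, seed = 1)
  expect_true(all(abs(af - 1 / 7440) < 1e-8))
  set.seed(1)
  ac <- rbinom(2000, 7440, af)
  # expected allele count 1: discovered sites are Poisson(1) truncated at 0,
  # so 58% are singletons and nearly all have count <= 3
  expect_gt(mean(ac[ac >= 1] == 1), 0.5)
  expect_gt(mean(ac[ac >= 1] <= 3), 0.95)
})

test_that("pooled read counts follow the binomial error model", {
  # c = 1 of 2N = 40, depth 600, e = 0.005:
  # E[alt] = 600 (0.025 * 0.995 + 0.975 * 0.005 / 3) = 15.9
  cfg <- cohort_config(n_cases = 20, n_controls = 1, n_variants = 1,
                       depth_range = c(600, 600), depth_shape = 1e9,
                       n_low_coverage_exons = 0, seed = 5)
  # force exactly one carrier with dosage 1 among the 20 pool members
  cohort <- generate_cohort(cfg)
  ids <- cohort$phenotypes$id[cohort$phenotypes$status == "case"]
  cohort$genotypes <- tibble(id = ids[1], site = cohort$variants$site[1],
                             dosage = 1L)
  design <- tibble(pool_id = "P1", stage = 1L, stratum = "case", id = ids)
  draws <- map_dbl(1:200, function(r) {
    simulate_pool_read_counts(design, cohort, seed = r)$alt_count
  })
  expect_lt(abs(mean(draws) - 15.9), 3 * sqrt(15.9) / sqrt(200))

  # degenerate ends of the model
  cohort$genotypes <- tibble(id = ids, site = cohort$variants$site[1],
                             dosage = 2L)
  sat <- simulate_pool_read_counts(design, cohort, error_rate = 0, seed = 1)
  expect_equal(sat$alt_count, sat$depth)
  cohort$genotypes <- tibble(id = character(0), site = character(0),
                             dosage = integer(0))
  none <- simulate_pool_read_counts(design, cohort, error_rate = 0, seed = 1)
  expect_equal(none$alt_count, 0L)
})

test_that("pool members missing from the cohort are rejected", {
  cfg <- cohort_config(n_cases = 5, n_controls = 5, n_variants = 3, seed = 2)
  cohort <- generate_cohort(cfg)
  design <- tibble(pool_id = "P1", stage = 1L, stratum = "case",
                   id = c(cohort$phenotypes$id[1:4], "GHOST"))
  expect_error(simulate_pool_read_counts(design, cohort, seed = 1), "GHOST")
})
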