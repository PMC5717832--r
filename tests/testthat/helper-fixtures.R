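library(dplyr)
library(tibble)
library(purrr)

# explicit bindings so helper-defined functions resolve these regardless of
# how the suite is loaded (installed package vs pkgload)
tibble <- tibble::tibble
bind_rows <- dplyr::bind_rows
left_join <- dplyr::left_join
group_by <- dplyr::group_by
summarise <- dplyr::summarise
mutate <- dplyr::mutate
n <- dplyr::n
map <- purrr::map
map_chr <- purrr::map_chr
map_dbl <- purrr::map_dbl
map_dfr <- purrr::map_dfr

# Small single-pool simulation used across caller tests: one pool of
# `pool_size` individuals at the screen's coverage, with the default
# rare-variant spectrum over `n_sites` candidate sites.
simulate_single_pool <- function(seed, pool_size = 20, n_sites = 11000,
                                 depth_range = c(600, 600),
                                 error_rate = 0.005) {
  cfg <- cohort_config(n_cases = pool_size, n_controls = 1,
                       early_fraction = 0.5, n_variants = n_sites,
                       depth_range = depth_range, error_rate = error_rate,
                       seed = seed)
  cohort <- generate_cohort(cfg)
  ids <- cohort$phenotypes$id[cohort$phenotypes$status == "case"]
  design <- tibble(pool_id = "P1", stage = 1L, stratum = "case", id = ids)
  counts <- simulate_pool_read_counts(design, cohort, seed = seed + 5000L)
  list(cohort = cohort, design = design, counts = counts,
       truth = unique(cohort$genotypes$site[cohort$genotypes$id %in% ids]))
}

# Random decoding instance: individuals partitioned into stage-1 pools and
# (orthogonally re-paritioned) stage-3 pools, true carriers planted, pool
# counts implied by the truth. Optionally some pools are made low-coverage.
random_decoding_instance <- function(seed, n_ind = 12, pool_size1 = 3,
                                     pool_size3 = 4, n_carriers = NULL,
                                     p_low_coverage = 0.2) {
  set.seed(seed)
  ids <- sprintf("i%02d", seq_len(n_ind))
  d1 <- tibble(pool_id = paste0("A", (seq_len(n_ind) - 1) %/% pool_size1 + 1),
               stage = 1L, stratum = "case", id = ids)
  perm <- sample(ids)
  d3 <- tibble(pool_id = paste0("B", (seq_len(n_ind) - 1) %/% pool_size3 + 1),
               stage = 3L, stratum = "validation", id = perm)
  design <- bind_rows(d1, d3)
  if (is.null(n_carriers)) n_carriers <- sample(1:2, 1)
  carriers <- sample(ids, n_carriers)
  alleles <- setNames(sample(1:2, n_carriers, replace = TRUE,
                             prob = c(0.8, 0.2)), carriers)
  truth <- tibble(id = names(alleles), alleles = unname(alleles))
  calls <- design |>
    left_join(truth, by = "id") |>
    group_by(pool_id) |>
    summarise(est_count = sum(alleles, na.rm = TRUE),
              pool_size = n(), .groups = "drop") |>
    mutate(quality = ifelse(est_count > 0, 30, 0),
           depth = ifelse(runif(n()) < p_low_coverage, 50L, 600L))
  list(design = design, calls = calls, truth = truth)
}

# Exhaustive reference decoder: enumerates every dosage assignment in
# {0,1,2}^n and applies the parsimony rules independently of the search
# code (matrix arithmetic, no recursion).
oracle_decode <- function(site_calls, design, min_quality = 2,
                          min_depth_per_individual = 10) {
  conf <- site_calls$depth >= min_depth_per_individual * site_calls$pool_size
  pos <- site_calls$est_count >= 1 & site_calls$quality >= min_quality & conf
  neg <- conf & site_calls$est_count == 0
  members <- split(design$id, design$pool_id)
  cand <- sort(unique(unlist(members[site_calls$pool_id[pos]])))
  cand <- setdiff(cand, unique(unlist(members[site_calls$pool_id[neg]])))
  if (!any(pos) || !length(cand)) return(list(status = "discrepant", sols = list()))
  pools <- site_calls$pool_id[pos]
  target <- site_calls$est_count[pos]
  M <- vapply(pools, function(p) as.integer(cand %in% members[[p]]),
              integer(length(cand)))
  M <- matrix(M, nrow = length(cand))
  grid <- as.matrix(expand.grid(rep(list(0:2), length(cand))))
  feas <- grid[colSums(abs(t(grid %*% M) - target)) == 0, , drop = FALSE]
  if (!nrow(feas)) return(list(status = "discrepant", sols = list()))
  k <- rowSums(feas > 0)
  k_min <- min(k)
  sel <- feas[k == k_min, , drop = FALSE]
  tot <- rowSums(sel)
  sel <- sel[tot == min(tot), , drop = FALSE]
  if (any(sel == 2) && k_min < length(cand)) {
    extra <- feas[k == k_min + 1 & apply(feas <= 1, 1, all), , drop = FALSE]
    sel <- rbind(sel, extra)
  }
  sols <- lapply(seq_len(nrow(sel)), function(r) {
    a <- sel[r, ]
    tibble(id = cand[a > 0], alleles = as.integer(a[a > 0]))
  })
  status <- if (length(sols) == 1) "unique" else "ambiguous"
  list(status = status, sols = sols)
}

canon_solutions <- function(sols) {
  sort(vapply(sols, function(s) {
    o <- order(s$id)
    paste0(s$id[o], ":", s$alleles[o], collapse = ",")
  }, character(1)))
}

# FN/FP of variant discovery on one simulated pool at screen conditions
# (median depth 600x, error 0.005, default spectrum and thresholds).
pool_detection_rates <- function(seed, pool_size = 20, n_sites = 11000) {
  sim <- simulate_single_pool(seed, pool_size = pool_size, n_sites = n_sites)
  vt <- discover_variants(call_allele_counts(sim$counts))
  evaluate_calls(vt, sim$truth)
}

# End-to-end singleton decoding: cohort -> orthogonal two-stage pools ->
# reads -> calls -> decode; returns per-variant outcomes for true singletons
# with confident positive calls in both stages.
run_singleton_recovery <- function(seed = 21) {
  cfg <- cohort_config(n_cases = 480, n_controls = 1, early_fraction = 0.5,
                       n_variants = 80, af_alpha = 1, af_min = 1 / 962,
                       af_max = 1 / 960, n_low_coverage_exons = 0, seed = seed)
  cohort <- generate_cohort(cfg)
  ids <- cohort$phenotypes$id[cohort$phenotypes$status == "case"]
  ph <- cohort$phenotypes[cohort$phenotypes$status == "case", ]
  d1 <- design_stratified_pools(ph, 20, strata = "status", seed = seed + 1)
  d3 <- design_orthogonal_pools(d1, ids, 24, max_overlap = 1, seed = seed + 2)
  cohort$genotypes <- dplyr::filter(cohort$genotypes, id %in% ids)
  calls <- bind_rows(
    call_allele_counts(simulate_pool_read_counts(d1, cohort, seed = seed + 3)),
    call_allele_counts(simulate_pool_read_counts(d3, cohort, seed = seed + 4)))
  design <- bind_rows(d1, d3)
  truth <- cohort$genotypes |>
    group_by(site) |>
    summarise(ac = sum(dosage), carrier = id[1], .groups = "drop") |>
    dplyr::filter(ac == 1)
  confident <- calls |>
    dplyr::filter(site %in% truth$site) |>
    group_by(site) |>
    summarise(n_conf_pos = sum(est_count >= 1 & quality >= 2 &
                                 depth >= 10 * pool_size),
              .groups = "drop") |>
    dplyr::filter(n_conf_pos >= 2)
  map_chr(confident$site, function(s) {
    sol <- decode_carriers(dplyr::filter(calls, site == s), design)
    if (sol$status != "unique") return("not_unique")
    if (nrow(sol$solutions[[1]]) == 1 &&
        sol$solutions[[1]]$id == truth$carrier[truth$site == s] &&
        sol$solutions[[1]]$alleles == 1L) "correct" else "wrong"
  })
}

# Cohort allele-frequency recovery at AF >= 0.001: mean relative error of
# the estimated cohort AF against the realised (truth) AF.
run_af_recovery <- function(seed = 77) {
  af_levels <- c(0.001, 0.005, 0.02)
  cfg <- cohort_config(n_cases = 1880, n_controls = 1840, n_variants = 30,
                       n_low_coverage_exons = 0, seed = seed)
  cohort <- generate_cohort(cfg)
  cohort$variants$true_af <- rep(af_levels, length.out = 30)
  set.seed(seed)
  cohort$genotypes <- purrr::map_dfr(seq_len(30), function(j) {
    d <- rbinom(3720, 2, cohort$variants$true_af[j])
    k <- which(d > 0)
    tibble(id = cohort$phenotypes$id[k], site = cohort$variants$site[j],
           dosage = as.integer(d[k]))
  })
  design <- design_stratified_pools(cohort$phenotypes, 20,
                                    strata = "status", seed = seed + 1)
  counts <- simulate_pool_read_counts(design, cohort, seed = seed + 2)
  vt <- discover_variants(call_allele_counts(counts))
  truth_ac <- cohort$genotypes |>
    group_by(site) |>
    summarise(ac_true = sum(dosage), .groups = "drop")
  cmp <- dplyr::inner_join(vt, truth_ac, by = "site") |>
    mutate(af_true = ac_true / 7440)
  list(n = nrow(cmp),
       mean_rel_err = mean(abs(cmp$af - cmp$af_true) / cmp$af_true))
}
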