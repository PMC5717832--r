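#' Configuration for the end-to-end screen pipeline
#'
#' Collects stage definitions, caller thresholds, filter thresholds and
#' association settings for [run_pipeline()]. Defaults are a scaled-down
#' screen so a full run stays fast; pass a paper-scale [cohort_config()]
#' for a full-size simulation.
#'
#' @param cohort A [cohort_config()] (simulation source).
#' @param stage1_pool_size,stage3_pool_size Pool sizes for the discovery
#'   and orthogonal validation stages.
#' @param max_overlap Maximum members a validation pool may share with any
#'   discovery pool.
#' @param min_quality,min_depth_per_individual Caller thresholds.
#' @param rare_af,deleterious_af MAF thresholds for the gene-level rare
#'   filter (0.002) and the candidate-deleterious filter (0.0005).
#' @param onset_cutoff Early-onset age cutoff (years).
#' @param n_perm Burden-test permutations.
#' @param seed Master seed; stage seeds derive from it and are recorded in
#'   the output manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(n_cases = 480,
                                                   n_controls = 360,
                                                   n_variants = 80,
                                                   seed = 1L),
                            stage1_pool_size = 20,
                            stage3_pool_size = 24,
                            max_overlap = 1,
                            min_quality = 2,
                            min_depth_per_individual = 10,
                            rare_af = 0.002,
                            deleterious_af = 0.0005,
                            onset_cutoff = 40,
                            n_perm = 999,
                            seed = 1L) {
  stopifnot(rare_af > 0, deleterious_af > 0, onset_cutoff > 0, n_perm > 0)
  cohort$seed <- cohort$seed %||% seed
  structure(list(cohort = cohort, stage1_pool_size = stage1_pool_size,
                 stage3_pool_size = stage3_pool_size,
                 max_overlap = max_overlap, min_quality = min_quality,
                 min_depth_per_individual = min_depth_per_individual,
                 rare_af = rare_af, deleterious_af = deleterious_af,
                 onset_cutoff = onset_cutoff, n_perm = n_perm,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pooled-screen pipeline on a simulated cohort
#'
#' Simulate cohort -> build homogeneous discovery pools and orthogonal
#' validation pools -> simulate pooled reads for both stages -> estimate
#' per-pool allele counts -> discover variants and run coverage QC ->
#' decode carriers of rare variants -> tally carriers by onset subgroup ->
#' gene-level burden tests and a carrier-level association for the
#' pathogenic set. Every table is written as TSV into `out_dir` together
#' with a manifest of seeds and file hashes; a rerun with the same config
#' is bit-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with all in-memory results plus the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- config$seed + 0:9

  cohort <- generate_cohort(config$cohort)
  design1 <- design_stratified_pools(cohort$phenotypes,
                                     config$stage1_pool_size,
                                     strata = "status", stage = 1L,
                                     seed = seeds[2])
  case_ids <- cohort$phenotypes$id[cohort$phenotypes$status == "case"]
  design3 <- design_orthogonal_pools(design1, case_ids,
                                     config$stage3_pool_size,
                                     config$max_overlap, stage = 3L,
                                     seed = seeds[3])

  counts1 <- simulate_pool_read_counts(design1, cohort, seed = seeds[4])
  counts3 <- simulate_pool_read_counts(design3, cohort, seed = seeds[5])
  calls1 <- call_allele_counts(counts1, config$cohort$error_rate)
  calls3 <- call_allele_counts(counts3, config$cohort$error_rate)
  ann <- cohort$variants[c("site", "gene", "class")]
  variants <- discover_variants(
    dplyr::left_join(calls1, ann[, c("site", "gene")], by = "site"),
    config$min_quality, config$min_depth_per_individual)
  qc <- coverage_qc(counts1, config$min_depth_per_individual)

  both <- dplyr::bind_rows(calls1, calls3)
  rare_sites <- variants$site[variants$af < config$rare_af]
  carriers <- purrr::map(rare_sites, function(s) {
    decode_carriers(dplyr::filter(both, .data$site == s),
                    dplyr::bind_rows(design1, design3),
                    config$min_quality, config$min_depth_per_individual)
  })
  carrier_tbl <- purrr::map_dfr(carriers, tidy)
  resolved <- purrr::map_dfr(carriers, function(x) {
    if (x$status == "unique")
      dplyr::mutate(x$solutions[[1]], site = x$site) else NULL
  })
  tally <- if (nrow(resolved)) tally_carriers(resolved, cohort$phenotypes)
    else tibble::tibble()

  rare_ann <- dplyr::inner_join(variants, ann, by = c("site", "gene")) |>
    dplyr::filter(.data$class %in% c("missense", "inframe_indel"),
                  .data$af < config$rare_af)
  strata1 <- pool_sizes(design1)
  burden <- rare_ann |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_map(function(g, key) {
      pc <- calls1 |>
        dplyr::filter(.data$site %in% g$site) |>
        dplyr::group_by(.data$pool_id) |>
        dplyr::summarise(count = sum(.data$est_count), .groups = "drop") |>
        dplyr::right_join(strata1, by = "pool_id") |>
        dplyr::mutate(count = dplyr::coalesce(.data$count, 0L),
                      stratum = ifelse(grepl("case", .data$stratum),
                                       "case", "control"))
      dplyr::mutate(tidy(gene_burden_test(pc, config$n_perm,
                                          seed = seeds[6])),
                    gene = key$gene, .before = 1)
    }) |>
    dplyr::bind_rows()

  patho_sites <- cohort$variants$site[cohort$variants$pathogenic]
  assoc <- if (length(patho_sites)) {
    carr <- unique(cohort$genotypes$id[cohort$genotypes$site %in% patho_sites])
    st <- cohort$phenotypes$status[cohort$phenotypes$id %in% carr]
    tidy(carrier_association(sum(st == "case"), config$cohort$n_cases,
                             sum(st == "control"), config$cohort$n_controls))
  } else tibble::tibble()

  files <- list(
    phenotypes = write_phenotypes(cohort$phenotypes,
                                  file.path(out_dir, "phenotypes.tsv")),
    design_stage1 = write_pool_manifest(design1,
                                        file.path(out_dir, "design_stage1.tsv")),
    design_stage3 = write_pool_manifest(design3,
                                        file.path(out_dir, "design_stage3.tsv")),
    calls_stage1 = {
      readr::write_tsv(calls1, file.path(out_dir, "calls_stage1.tsv"))
      file.path(out_dir, "calls_stage1.tsv")
    },
    variants = {
      readr::write_tsv(variants, file.path(out_dir, "variants.tsv"))
      file.path(out_dir, "variants.tsv")
    },
    coverage = {
      readr::write_tsv(qc$pools, file.path(out_dir, "coverage_pools.tsv"))
      file.path(out_dir, "coverage_pools.tsv")
    },
    carriers = {
      readr::write_tsv(carrier_tbl, file.path(out_dir, "carriers.tsv"))
      file.path(out_dir, "carriers.tsv")
    },
    tally = {
      readr::write_tsv(tally, file.path(out_dir, "carrier_tally.tsv"))
      file.path(out_dir, "carrier_tally.tsv")
    },
    burden = {
      readr::write_tsv(burden, file.path(out_dir, "burden_tests.tsv"))
      file.path(out_dir, "burden_tests.tsv")
    },
    association = {
      readr::write_tsv(assoc, file.path(out_dir, "association.tsv"))
      file.path(out_dir, "association.tsv")
    })
  manifest <- tibble::tibble(
    file = basename(unlist(files)),
    md5 = unname(tools::md5sum(unlist(files))),
    seed = config$seed)
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(list(cohort = cohort, design1 = design1, design3 = design3,
                 calls1 = calls1, calls3 = calls3, variants = variants,
                 qc = qc, carriers = carriers, tally = tally,
                 burden = burden, association = assoc, manifest = manifest))
}
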