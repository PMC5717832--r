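#' Registries of previously reported pathogenic variants
#'
#' The package ships three curated registry fixtures transcribed from a
#' large pooled-sequencing case-control screen of monogenic diabetes genes:
#'
#' * `load_ptv_registry()`: protein-truncating variants in genes where
#'   heterozygous loss of function is pathogenic for diabetes, with carrier
#'   counts by subgroup.
#' * `load_gck_registry()`: every GCK missense (and in-frame indel) variant
#'   observed in the screen, with in-silico predictions, per-carrier age at
#'   diagnosis and prior-report provenance.
#' * `load_mody_missense_registry()`: previously reported likely-pathogenic
#'   missense variants in HNF1A, HNF4A, ABCC8 and INS with carrier counts
#'   by subgroup.
#'
#' Counts are distinct carriers (not alleles). Missing population
#' frequencies mean the variant is absent from the reference panels and
#' therefore passes rarity filters.
#'
#' @param path Optional path to a registry TSV of the same layout
#'   (defaults to the packaged fixture).
#' @param onset_cutoff Age (years) below which a case carrier counts as
#'   early-onset when ages are stored per carrier.
#' @return A tibble; the GCK and subgroup registries carry `cases`,
#'   `early_onset` and `controls` carrier-count columns, a `consequence`
#'   column, and `population_af` (maximum reference-panel frequency).
#' @name registries
NULL

registry_path <- function(file, path = NULL) {
  path %||% system.file("extdata", file, package = "poolscreen", mustWork = TRUE)
}

#' @rdname registries
#' @export
load_ptv_registry <- function(path = NULL) {
  readr::read_tsv(registry_path("ptv_registry.tsv", path),
                  col_types = readr::cols(
                    gene = "c", cdna = "c", protein = "c", cases = "i",
                    early_onset = "i", controls = "i", exac_af = "d",
                    dbsnp = "c", acmg_class = "i")) |>
    dplyr::mutate(consequence = infer_consequence(.data$cdna, .data$protein),
                  population_af = .data$exac_af)
}

#' @rdname registries
#' @export
load_gck_registry <- function(path = NULL, onset_cutoff = 40) {
  reg <- readr::read_tsv(registry_path("gck_missense_registry.tsv", path),
                         col_types = readr::cols(
                           gene = "c", cdna = "c", protein = "c",
                           polyphen2 = "c", sift = "c", mutationtaster = "c",
                           cadd = "d", case_ages = "c", control_carriers = "i",
                           prior_mody = "c", exac_af = "d", dbsnp = "c",
                           acmg_class = "i"))
  ages <- purrr::map(reg$case_ages, function(a) {
    if (is.na(a)) numeric(0) else as.numeric(strsplit(a, ";")[[1]])
  })
  reg |>
    dplyr::mutate(
      cases = lengths(ages),
      early_onset = vapply(ages, function(a) sum(a < onset_cutoff), integer(1)),
      controls = .data$control_carriers,
      prior_mody_report = !is.na(.data$prior_mody),
      consequence = infer_consequence(.data$cdna, .data$protein),
      population_af = .data$exac_af)
}

#' @rdname registries
#' @export
load_mody_missense_registry <- function(path = NULL) {
  readr::read_tsv(registry_path("mody_missense_registry.tsv", path),
                  col_types = readr::cols(
                    gene = "c", cdna = "c", protein = "c", cases = "i",
                    early_onset = "i", controls = "i", polyphen2 = "c",
                    sift = "c", mutationtaster = "c", cadd = "d",
                    prior_report = "c", exac_af = "d", dbsnp = "c",
                    acmg_class = "i")) |>
    dplyr::mutate(consequence = infer_consequence(.data$cdna, .data$protein),
                  population_af = .data$exac_af)
}
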