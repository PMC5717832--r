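#' Map a consequence annotation to a functional class
#'
#' Collapses annotation-style consequence strings into the classes used
#' throughout the screen: `synonymous`, `missense`, `missense-group`
#' (in-frame indels, analysed together with missense) and `ptv`
#' (protein-truncating: nonsense/stop-gain, canonical splice site,
#' frameshift). Unknown strings map to `unclassified`, never dropped.
#'
#' @param consequence Character vector of consequence terms (Annovar-style
#'   or plain: "stopgain", "frameshift deletion", "nonsynonymous SNV",
#'   "splicing", "nonframeshift deletion", "synonymous SNV", ...).
#' @return Character vector of functional classes.
#' @export
#' @examples
#' classify_functional(c("stopgain", "nonframeshift deletion", "synonymous SNV"))
classify_functional <- function(consequence) {
  if (any(is.na(consequence) | consequence == "")) {
    abort("consequence strings must be present.")
  }
  x <- tolower(consequence)
  dplyr::case_when(
    stringr::str_detect(x, "^synonymous") ~ "synonymous",
    stringr::str_detect(x, "stopgain|stop_gain|nonsense") ~ "ptv",
    stringr::str_detect(x, "frameshift") &
      !stringr::str_detect(x, "nonframeshift|non-frameshift|inframe") ~ "ptv",
    stringr::str_detect(x, "splic") ~ "ptv",
    stringr::str_detect(x, "nonframeshift|non-frameshift|inframe") ~ "missense-group",
    stringr::str_detect(x, "nonsynonymous|missense") ~ "missense",
    TRUE ~ "unclassified")
}

# consequence from HGVS-like cDNA/protein strings in the registry fixtures
infer_consequence <- function(cdna, protein) {
  dplyr::case_when(
    stringr::str_detect(protein, "\\*$") ~ "stopgain",
    stringr::str_detect(protein, "fs$") ~ "frameshift",
    stringr::str_detect(cdna, "[+-]\\d+[ACGT]") ~ "splicing",
    stringr::str_detect(cdna, "del|dup|ins") ~ "nonframeshift deletion",
    TRUE ~ "nonsynonymous SNV")
}

#' Keep rare variants only
#'
#' Strict-inequality minor-allele-frequency filter. Missing frequencies are
#' treated as "not observed" (0), so unseen variants pass.
#'
#' @param variants Tibble with an allele-frequency column.
#' @param af_threshold Exclusive upper bound (default 0.002, i.e. MAF < 0.2%).
#' @param af_col Which frequency to filter on ("population_af" or
#'   "cohort_af" or any column present).
#' @return The rare subset of `variants`.
#' @export
#' @examples
#' v <- tibble::tibble(site = c("a", "b"), population_af = c(0.0019, 0.002))
#' apply_rare_filter(v, 0.002)  # keeps only "a" (strict inequality)
apply_rare_filter <- function(variants, af_threshold = 0.002,
                              af_col = "population_af") {
  if (!af_col %in% names(variants)) {
    abort(paste0("no column `", af_col, "` in `variants`."))
  }
  af <- dplyr::coalesce(variants[[af_col]], 0)
  dplyr::filter(variants, af < af_threshold)
}

#' Flag candidate-deleterious missense variants
#'
#' Keeps variants predicted damaging by both leading in-silico tools
#' (PolyPhen2 not benign AND SIFT deleterious) with population minor allele
#' frequency below `af_threshold`. A side condition — MutationTaster
#' disease-causing and scaled CADD above 20 — is verified on the kept set
#' and any record failing it is reported in the `side_condition_ok` column
#' (and via a warning), not silently dropped.
#'
#' @param variants Tibble with polyphen2, sift, mutationtaster, cadd and
#'   population_af columns (normalised labels: "probably_damaging",
#'   "possibly_damaging", "benign"; "deleterious"/"tolerated";
#'   "disease_causing"/"polymorphism").
#' @param af_threshold Exclusive population-AF bound (default 0.0005).
#' @return Kept subset with a logical `side_condition_ok` column.
#' @export
flag_candidate_deleterious <- function(variants, af_threshold = 0.0005) {
  need <- c("polyphen2", "sift", "mutationtaster", "cadd", "population_af")
  if (!all(need %in% names(variants))) {
    abort(paste0("`variants` needs columns: ", paste(need, collapse = ", ")))
  }
  kept <- variants |>
    dplyr::filter(!is.na(.data$polyphen2), .data$polyphen2 != "benign",
                  .data$sift == "deleterious",
                  dplyr::coalesce(.data$population_af, 0) < af_threshold) |>
    dplyr::mutate(side_condition_ok =
                    dplyr::coalesce(.data$mutationtaster == "disease_causing" &
                                      .data$cadd > 20, FALSE))
  if (any(!kept$side_condition_ok)) {
    warn(sprintf("%d kept variant(s) fail the MutationTaster/CADD side condition",
                 sum(!kept$side_condition_ok)))
  }
  kept
}

#' Tally registry carriers by onset subgroup
#'
#' Sums per-variant carrier counts of a registry table into a subgroup
#' tally. Registries store distinct-carrier counts per variant, so the sum
#' assumes an individual carries at most one registry variant (true in the
#' packaged fixtures).
#'
#' @param registry Registry tibble with cases, early_onset and controls
#'   count columns (as returned by the `load_*_registry()` readers).
#' @return A `carrier_tally` one-row tibble: n_variants, cases, early,
#'   late, controls.
#' @export
tally_registry <- function(registry) {
  need <- c("cases", "early_onset", "controls")
  if (!all(need %in% names(registry))) {
    abort("registry must have cases/early_onset/controls counts.")
  }
  out <- tibble::tibble(
    n_variants = nrow(registry),
    cases = sum(registry$cases),
    early = sum(registry$early_onset),
    late = sum(registry$cases) - sum(registry$early_onset),
    controls = sum(registry$controls))
  class(out) <- unique(c("carrier_tally", class(out)))
  out
}

#' Tally resolved carriers by onset subgroup
#'
#' Counts distinct carrier individuals (an individual carrying two
#' variants of the set counts once) split by onset group.
#'
#' @param assignments Tibble of resolved carriers: columns id (and
#'   optionally site).
#' @param phenotypes Phenotype tibble with id and onset_group.
#' @return A `carrier_tally` one-row tibble: cases, early, late, controls
#'   carrier counts plus subgroup denominators.
#' @export
tally_carriers <- function(assignments, phenotypes) {
  ids <- unique(assignments$id)
  unknown <- setdiff(ids, phenotypes$id)
  if (length(unknown)) {
    abort(paste0("carrier ids absent from phenotypes: ",
                 paste(head(unknown, 3), collapse = ", ")))
  }
  ph <- phenotypes |> dplyr::mutate(carrier = .data$id %in% ids)
  grp <- function(g) sum(ph$carrier[ph$onset_group == g])
  out <- tibble::tibble(
    n_variants = if ("site" %in% names(assignments))
      dplyr::n_distinct(assignments$site) else NA_integer_,
    cases = sum(ph$carrier[ph$status == "case"]),
    early = grp("early"), late = grp("late"), controls = grp("control"),
    n_cases = sum(ph$status == "case"),
    n_early = sum(ph$onset_group == "early"),
    n_late = sum(ph$onset_group == "late"),
    n_controls = sum(ph$status == "control"))
  class(out) <- unique(c("carrier_tally", class(out)))
  out
}
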