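#' Configuration for a synthetic pooled-sequencing cohort
#'
#' Bundles every parameter of the synthetic-cohort generator. The defaults
#' describe a case-control screen of monogenic diabetes genes: 4016 cases
#' (1346 of them diagnosed before age 40) and 2872 controls, a rare-variant
#' site frequency spectrum dominated by singletons, per-pool median read
#' depth of 600-970x, and a small per-base miscall rate.
#'
#' @param n_cases,n_controls Number of case and control individuals.
#' @param early_fraction Fraction of cases diagnosed before `onset_cutoff`.
#' @param onset_cutoff Age (years) separating early- from late-onset cases;
#'   a case diagnosed exactly at the cutoff is late-onset.
#' @param n_variants Number of neutral variant sites to simulate.
#' @param class_weights Named probabilities over functional classes used to
#'   label neutral sites (`synonymous`, `missense`, `ptv`, `inframe_indel`).
#' @param af_alpha,af_min,af_max Site-frequency-spectrum model: true allele
#'   frequencies are drawn with density proportional to `f^-af_alpha` on
#'   `[af_min, af_max]`. The defaults are calibrated so that, conditional on
#'   being observed in a cohort of ~3720 individuals, about 54% of variants
#'   are singletons and >80% have cohort allele frequency at or below 0.001.
#' @param n_pathogenic Number of additional pathogenic sites.
#' @param pathogenic_af True population allele frequency of pathogenic sites.
#' @param pathogenic_or Carrier odds ratio (case vs control) for pathogenic
#'   sites; must be >= 1. Length 1 or `n_pathogenic`.
#' @param depth_range Range of per-pool median depth; each pool draws its
#'   median uniformly from this interval.
#' @param depth_shape Gamma shape for per-site depth dispersion around the
#'   pool median (mean-1 Gamma multiplier; larger is less dispersed).
#' @param n_exons Number of exons the simulated target is divided into;
#'   sites are assigned to exons uniformly.
#' @param n_low_coverage_exons Number of exons with systematically suppressed
#'   capture efficiency (all pools), emulating GC-rich/hard-to-capture exons.
#' @param low_coverage_scale Depth multiplier applied in suppressed exons.
#' @param error_rate Per-base miscall probability; miscalls are spread
#'   evenly over the three non-reference bases.
#' @param seed Integer seed; identical configs generate identical cohorts.
#'
#' @return A `cohort_config` list.
#' @export
#' @examples
#' cfg <- cohort_config(n_cases = 200, n_controls = 150, n_variants = 40, seed = 1)
cohort_config <- function(n_cases = 4016,
                          n_controls = 2872,
                          early_fraction = 1346 / 4016,
                          onset_cutoff = 40,
                          n_variants = 655,
                          class_weights = c(synonymous = 0.386, missense = 0.55,
                                            ptv = 0.034, inframe_indel = 0.03),
                          af_alpha = 1.57,
                          af_min = 1e-6,
                          af_max = 0.05,
                          n_pathogenic = 0,
                          pathogenic_af = 5e-4,
                          pathogenic_or = 1,
                          depth_range = c(600, 970),
                          depth_shape = 10,
                          n_exons = 215,
                          n_low_coverage_exons = 7,
                          low_coverage_scale = 0.05,
                          error_rate = 0.005,
                          seed = NULL) {
  if (n_cases < 1 || n_controls < 1) {
    abort("`n_cases` and `n_controls` must be positive.")
  }
  if (n_variants < 0 || n_pathogenic < 0) {
    abort("variant counts must be non-negative.")
  }
  if (any(pathogenic_or < 1)) {
    abort("`pathogenic_or` must be >= 1 for pathogenic sites.")
  }
  if (error_rate < 0 || error_rate > 0.01) {
    abort("`error_rate` must lie in [0, 0.01].")
  }
  if (early_fraction < 0 || early_fraction > 1) {
    abort("`early_fraction` must lie in [0, 1].")
  }
  structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         early_fraction = early_fraction, onset_cutoff = onset_cutoff,
         n_variants = as.integer(n_variants), class_weights = class_weights,
         af_alpha = af_alpha, af_min = af_min, af_max = af_max,
         n_pathogenic = as.integer(n_pathogenic),
         pathogenic_af = pathogenic_af, pathogenic_or = pathogenic_or,
         depth_range = depth_range, depth_shape = depth_shape,
         n_exons = as.integer(n_exons),
         n_low_coverage_exons = as.integer(n_low_coverage_exons),
         low_coverage_scale = low_coverage_scale,
         error_rate = error_rate, seed = seed),
    class = "cohort_config")
}

#' Draw true allele frequencies from the rare-variant spectrum model
#'
#' Samples allele frequencies with density proportional to `f^-alpha`
#' truncated to `[f_min, f_max]`, by inverse-CDF sampling. With the default
#' parameters, genotypes drawn for a cohort of ~3720 individuals yield,
#' among variants actually observed, roughly 54% singletons and >80% with
#' cohort allele frequency at or below 0.001.
#'
#' @param n_variants Number of frequencies to draw.
#' @param alpha,f_min,f_max Spectrum parameters (see [cohort_config()]).
#' @param seed Optional integer seed.
#' @return Numeric vector of true allele frequencies in `(0, 0.5]`.
#' @export
sample_site_frequency_spectrum <- function(n_variants, alpha = 1.57,
                                           f_min = 1e-6, f_max = 0.05,
                                           seed = NULL) {
  if (n_variants <= 0) abort("`n_variants` must be positive.")
  if (f_min <= 0 || f_max > 0.5 || f_min >= f_max) {
    abort("need 0 < f_min < f_max <= 0.5.")
  }
  if (alpha <= 0) abort("`alpha` must be positive.")
  with_seed(seed, {
    u <- runif(n_variants)
    if (abs(alpha - 1) < 1e-12) {
      exp(log(f_min) + u * (log(f_max) - log(f_min)))
    } else {
      a1 <- 1 - alpha
      (f_min^a1 + u * (f_max^a1 - f_min^a1))^(1 / a1)
    }
  })
}

#' Generate a synthetic case-control cohort with sparse genotypes
#'
#' Creates phenotypes, a sparse individual-by-variant genotype table and the
#' per-site truth record. Neutral sites draw genotypes as Binomial(2, AF)
#' independently of phenotype. Pathogenic sites draw carrier status
#' conditional on case/control status so that the carrier odds ratio equals
#' the configured effect size in expectation while the cohort sizes stay
#' exactly as configured: controls carry with the population probability
#' `q = 1 - (1 - AF)^2` and cases with odds `OR * q / (1 - q)`.
#'
#' @param config A [cohort_config()].
#' @return A `cohort` list with tibbles `phenotypes` (id, status,
#'   age_at_diagnosis, onset_group), `genotypes` (id, site, dosage; only
#'   non-reference entries are stored) and `variants` (site, gene, class,
#'   exon, true_af, pathogenic, effect_or).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_cases = 100, n_controls = 80,
#'                                         n_variants = 20, seed = 7))
#' cohort$phenotypes
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_cases + config$n_controls
    id <- sprintf("I%05d", seq_len(n))
    status <- rep(c("case", "control"), c(config$n_cases, config$n_controls))
    n_early <- round(config$early_fraction * config$n_cases)
    age <- rep(NA_real_, n)
    if (config$n_cases > 0) {
      early <- sample(seq_len(config$n_cases), n_early)
      a <- numeric(config$n_cases)
      a[early] <- floor(runif(n_early, 15, config$onset_cutoff))
      a[-early] <- floor(runif(config$n_cases - n_early, config$onset_cutoff, 76))
      age[seq_len(config$n_cases)] <- a
    }
    onset <- dplyr::case_when(
      status == "control" ~ "control",
      age < config$onset_cutoff ~ "early",
      TRUE ~ "late")
    phen <- tibble::tibble(id = id, status = status,
                           age_at_diagnosis = age, onset_group = onset)

    n_all <- config$n_variants + config$n_pathogenic
    variants <- tibble::tibble(
      site = character(0), gene = character(0), class = character(0),
      exon = integer(0), true_af = numeric(0), pathogenic = logical(0),
      effect_or = numeric(0))
    geno <- tibble::tibble(id = character(0), site = character(0),
                           dosage = integer(0))
    if (n_all > 0) {
      site <- sprintf("chr7:%d:A:G", 10000L + 10L * seq_len(n_all))
      cls <- c(
        if (config$n_variants > 0)
          sample(names(config$class_weights), config$n_variants, replace = TRUE,
                 prob = config$class_weights),
        rep("missense", config$n_pathogenic))
      af <- c(
        if (config$n_variants > 0)
          sample_site_frequency_spectrum(config$n_variants, config$af_alpha,
                                         config$af_min, config$af_max),
        rep_len(config$pathogenic_af, config$n_pathogenic))
      patho <- rep(c(FALSE, TRUE), c(config$n_variants, config$n_pathogenic))
      eff <- c(rep(1, config$n_variants),
               rep_len(config$pathogenic_or, config$n_pathogenic))
      variants <- tibble::tibble(
        site = site,
        gene = paste0("GENE", 1 + (seq_len(n_all) - 1L) %% 22L),
        class = cls,
        exon = 1L + (seq_len(n_all) - 1L) %% config$n_exons,
        true_af = af, pathogenic = patho, effect_or = eff)

      # vectorised over sites x individuals; only non-zero dosages are kept
      neut <- which(!variants$pathogenic)
      d_neut <- rbinom(n * length(neut), 2L,
                       rep(variants$true_af[neut], each = n))
      nz <- which(d_neut > 0L)
      geno <- tibble::tibble(
        id = id[(nz - 1L) %% n + 1L],
        site = variants$site[neut][(nz - 1L) %/% n + 1L],
        dosage = as.integer(d_neut[nz]))
      for (j in which(variants$pathogenic)) {
        f <- variants$true_af[j]
        or <- variants$effect_or[j]
        q <- 1 - (1 - f)^2
        q_case <- or * q / (1 - q) / (1 + or * q / (1 - q))
        d <- rbinom(n, 1L, ifelse(status == "case", q_case, q))
        k <- which(d > 0L)
        if (length(k)) {
          geno <- dplyr::bind_rows(geno, tibble::tibble(
            id = id[k], site = variants$site[j], dosage = 1L))
        }
      }
      geno <- dplyr::arrange(geno, .data$site, .data$id)
    }
    structure(list(phenotypes = phen, genotypes = geno, variants = variants,
                   config = config),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", sum(x$phenotypes$status == "case"), " cases / ",
      sum(x$phenotypes$status == "control"), " controls; ",
      nrow(x$variants), " variant sites (",
      sum(x$variants$pathogenic), " pathogenic)\n", sep = "")
  invisible(x)
}

#' Simulate pooled read counts for a pool design
#'
#' For every (pool, site) pair, total depth is drawn from the coverage model
#' (per-pool median uniform on `depth_range`, per-site Gamma dispersion,
#' suppressed low-coverage exons) and the number of alt-supporting reads is
#' Binomial(depth, p) with
#' `p = (c/2N) (1 - e) + (1 - c/2N) e/3`,
#' where `c` is the summed alt dosage of the pool members at the site, `2N`
#' twice the pool size and `e` the per-base miscall rate.
#'
#' @param design A pool design (long tibble: pool_id, stage, stratum, id).
#' @param cohort A `cohort` from [generate_cohort()], or a list with
#'   `genotypes` and `variants` tibbles of the same shape.
#' @param depth_range,depth_shape,low_coverage_exons,low_coverage_scale,error_rate
#'   Coverage/error model; defaults come from the cohort's config when
#'   present. `low_coverage_exons` is an integer vector of suppressed exons.
#' @param seed Optional integer seed.
#' @return Tibble with pool_id, site, exon, pool_size, depth, alt_count.
#' @export
simulate_pool_read_counts <- function(design, cohort,
                                      depth_range = NULL, depth_shape = NULL,
                                      low_coverage_exons = NULL,
                                      low_coverage_scale = NULL,
                                      error_rate = NULL, seed = NULL) {
  cfg <- cohort$config %||% cohort_config(n_cases = 1, n_controls = 1,
                                          n_variants = 0)
  depth_range <- depth_range %||% cfg$depth_range
  depth_shape <- depth_shape %||% cfg$depth_shape
  error_rate <- error_rate %||% cfg$error_rate
  if (is.null(low_coverage_exons)) {
    low_coverage_exons <-
      if (cfg$n_low_coverage_exons > 0 && cfg$n_exons > 0)
        seq_len(cfg$n_low_coverage_exons) else integer(0)
  }
  low_coverage_scale <- low_coverage_scale %||% cfg$low_coverage_scale

  missing <- setdiff(design$id, c(cohort$phenotypes$id %||% character(0),
                                  unique(cohort$genotypes$id)))
  if (!is.null(cohort$phenotypes) && length(setdiff(design$id,
                                                    cohort$phenotypes$id))) {
    abort(paste0("pool members missing from cohort: ",
                 paste(head(setdiff(design$id, cohort$phenotypes$id), 3),
                       collapse = ", ")))
  }

  pools <- design |>
    dplyr::count(.data$pool_id, name = "pool_size")
  with_seed(seed, {
    pool_median <- setNames(
      runif(nrow(pools), depth_range[1], depth_range[2]), pools$pool_id)

    # summed alt dosage per (pool, site); sparse, absent means 0
    psum <- design |>
      dplyr::inner_join(cohort$genotypes, by = "id",
                        relationship = "many-to-many") |>
      dplyr::group_by(.data$pool_id, .data$site) |>
      dplyr::summarise(c = sum(.data$dosage), .groups = "drop")

    grid <- tidyr::expand_grid(pool_id = pools$pool_id,
                               cohort$variants[, c("site", "exon")]) |>
      dplyr::left_join(pools, by = "pool_id") |>
      dplyr::left_join(psum, by = c("pool_id", "site")) |>
      dplyr::mutate(c = dplyr::coalesce(.data$c, 0L))

    m <- nrow(grid)
    med <- pool_median[grid$pool_id] *
      ifelse(grid$exon %in% low_coverage_exons, low_coverage_scale, 1)
    depth <- as.integer(round(med * rgamma(m, shape = depth_shape,
                                           rate = depth_shape)))
    frac <- grid$c / (2 * grid$pool_size)
    p <- frac * (1 - error_rate) + (1 - frac) * error_rate / 3
    alt <- rbinom(m, depth, p)
    grid |>
      dplyr::transmute(.data$pool_id, .data$site, .data$exon,
                       .data$pool_size, depth = depth, alt_count = alt)
  })
}
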