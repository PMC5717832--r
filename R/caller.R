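#' Estimate the alt allele count of a pool from read counts
#'
#' Maximum-likelihood allele count for pooled sequencing: the alt-read count
#' at a site is modelled as Binomial(depth, p_c) with
#' `p_c = (c/2N)(1 - e) + (1 - c/2N) e/3` for a pool carrying `c` of its
#' `2N` chromosomes as alt, and `e` the per-base miscall rate (spread evenly
#' over the three non-reference bases). The estimate is the `c` in `0..2N`
#' maximising the likelihood, ties broken toward the smaller count
#' (conservative for rare variants under a uniform prior the MAP equals this
#' MLE). Quality is the log10 likelihood ratio of the best model against the
#' zero-count model, so a confident reference call has quality 0.
#'
#' All arguments are vectorised and recycled.
#'
#' @param depth Total read depth (>= 0).
#' @param alt_count Alt-supporting reads (0 <= alt_count <= depth).
#' @param pool_2n Number of chromosomes in the pool (2 x pool size).
#' @param error_rate Per-base miscall probability.
#' @return Tibble with depth, alt_count, pool_2n, est_count, quality.
#' @export
#' @examples
#' estimate_pool_allele_count(600, 15, pool_2n = 40, error_rate = 0.005)
estimate_pool_allele_count <- function(depth, alt_count, pool_2n,
                                       error_rate = 0.005) {
  n <- max(length(depth), length(alt_count), length(pool_2n))
  depth <- rep_len(as.integer(depth), n)
  alt_count <- rep_len(as.integer(alt_count), n)
  pool_2n <- rep_len(as.integer(pool_2n), n)
  if (any(pool_2n <= 0)) abort("`pool_2n` must be positive.")
  if (any(depth < 0)) abort("`depth` must be non-negative.")
  if (any(alt_count < 0 | alt_count > depth)) {
    abort("`alt_count` must lie in [0, depth].")
  }
  est <- integer(n)
  qual <- numeric(n)
  for (n2 in unique(pool_2n)) {
    i <- which(pool_2n == n2)
    frac <- (0:n2) / n2
    p <- frac * (1 - error_rate) + (1 - frac) * error_rate / 3
    # log-likelihood matrix: rows = observations, cols = candidate counts
    ll <- vapply(p, function(pc) dbinom(alt_count[i], depth[i], pc, log = TRUE),
                 numeric(length(i)))
    ll <- matrix(ll, nrow = length(i))
    best <- max.col(ll, ties.method = "first") - 1L
    est[i] <- best
    qual[i] <- (ll[cbind(seq_along(i), best + 1L)] - ll[, 1]) / log(10)
  }
  tibble::tibble(depth = depth, alt_count = alt_count, pool_2n = pool_2n,
                 est_count = est, quality = qual)
}

#' Add allele-count estimates to a pooled read-count table
#'
#' Convenience wrapper over [estimate_pool_allele_count()] for a table of
#' per-(pool, site) read counts as produced by [simulate_pool_read_counts()]
#' or [read_pool_counts()].
#'
#' @param pool_counts Tibble with pool_id, site, pool_size, depth, alt_count.
#' @param error_rate Per-base miscall probability.
#' @return The input with est_count and quality columns appended.
#' @export
call_allele_counts <- function(pool_counts, error_rate = 0.005) {
  need <- c("pool_id", "site", "pool_size", "depth", "alt_count")
  if (!all(need %in% names(pool_counts))) {
    abort(paste0("`pool_counts` needs columns: ", paste(need, collapse = ", ")))
  }
  est <- estimate_pool_allele_count(pool_counts$depth, pool_counts$alt_count,
                                    2L * pool_counts$pool_size, error_rate)
  dplyr::bind_cols(pool_counts, est[c("est_count", "quality")])
}

#' Discover variant sites across pools and compute cohort allele frequency
#'
#' A site is reported as a variant when at least one pool has an estimated
#' allele count of 1 or more with quality at or above `min_quality` and
#' depth at or above `min_depth_per_individual` times the pool size. The
#' cohort allele count AC sums per-pool estimates over all pools passing
#' the depth criterion at the site, AN sums their chromosomes, and
#' AF = AC/AN.
#'
#' @param calls Output of [call_allele_counts()].
#' @param min_quality Minimum log10 likelihood-ratio quality.
#' @param min_depth_per_individual Depth required per pooled individual
#'   (default 10x, i.e. 200x for pools of 20).
#' @return A `variant_table` tibble: site, ac, an, af, n_pos_pools (plus
#'   gene/exon columns when present in `calls`).
#' @export
discover_variants <- function(calls, min_quality = 2,
                              min_depth_per_individual = 10) {
  calls <- calls |>
    dplyr::mutate(depth_ok = .data$depth >=
                    min_depth_per_individual * .data$pool_size,
                  positive = .data$est_count >= 1L &
                    .data$quality >= min_quality & .data$depth_ok)
  extra <- intersect(c("gene", "exon"), names(calls))
  out <- calls |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(extra), dplyr::first),
      ac = sum(.data$est_count[.data$depth_ok]),
      an = sum(2L * .data$pool_size[.data$depth_ok]),
      n_pos_pools = sum(.data$positive),
      .groups = "drop") |>
    dplyr::filter(.data$n_pos_pools >= 1L) |>
    dplyr::mutate(af = .data$ac / .data$an, .after = "an")
  class(out) <- unique(c("variant_table", class(out)))
  out
}

#' Coverage quality control for pooled target sequencing
#'
#' Summarises, per pool, the fraction of targeted bases reaching
#' `per_individual_threshold` reads per pooled individual (200x for pools
#' of 20 at the 10x default), and flags exons whose median per-pool depth
#' falls below that threshold in at least 90% of pools.
#'
#' @param depths Tibble with pool_id, site (or base), exon, pool_size, depth.
#' @param per_individual_threshold Required depth per individual.
#' @param flag_pool_fraction Fraction of pools that must be low for an exon
#'   to be flagged.
#' @return A `coverage_report` list with tibbles `pools` (pool_id,
#'   n_bases, fraction_covered) and `exons` (exon, median_depth,
#'   fraction_pools_low, flagged).
#' @export
coverage_qc <- function(depths, per_individual_threshold = 10,
                        flag_pool_fraction = 0.9) {
  if (any(depths$depth < 0)) abort("depths must be non-negative.")
  thr <- per_individual_threshold
  pools <- depths |>
    dplyr::group_by(.data$pool_id) |>
    dplyr::summarise(n_bases = dplyr::n(),
                     fraction_covered =
                       mean(.data$depth >= thr * .data$pool_size),
                     .groups = "drop")
  per_exon_pool <- depths |>
    dplyr::group_by(.data$exon, .data$pool_id) |>
    dplyr::summarise(med = median(.data$depth),
                     low = median(.data$depth) <
                       thr * .data$pool_size[1], .groups = "drop")
  exons <- per_exon_pool |>
    dplyr::group_by(.data$exon) |>
    dplyr::summarise(median_depth = median(.data$med),
                     fraction_pools_low = mean(.data$low), .groups = "drop") |>
    dplyr::mutate(flagged = .data$fraction_pools_low >= flag_pool_fraction)
  structure(list(pools = pools, exons = exons,
                 per_individual_threshold = thr), class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("<coverage_report> ", nrow(x$pools), " pools; fraction covered ",
      sprintf("%.2f-%.2f", min(x$pools$fraction_covered),
              max(x$pools$fraction_covered)), "; ",
      sum(x$exons$flagged), "/", nrow(x$exons), " exons flagged\n", sep = "")
  invisible(x)
}

#' @export
tidy.coverage_report <- function(x, ...) x$pools

#' @export
glance.coverage_report <- function(x, ...) {
  tibble::tibble(n_pools = nrow(x$pools),
                 min_fraction_covered = min(x$pools$fraction_covered),
                 max_fraction_covered = max(x$pools$fraction_covered),
                 n_exons_flagged = sum(x$exons$flagged))
}

#' Compare called variants against simulation truth
#'
#' @param called_sites Character vector (or `variant_table`) of called sites.
#' @param true_sites Character vector of sites truly segregating.
#' @return One-row tibble: n_true, n_called, n_overlap, sensitivity,
#'   fn_rate (missed true / true) and fp_rate (called-but-absent / called).
#' @export
evaluate_calls <- function(called_sites, true_sites) {
  if (is.data.frame(called_sites)) called_sites <- called_sites$site
  called_sites <- unique(called_sites)
  true_sites <- unique(true_sites)
  hit <- length(intersect(called_sites, true_sites))
  tibble::tibble(
    n_true = length(true_sites), n_called = length(called_sites),
    n_overlap = hit,
    sensitivity = if (length(true_sites)) hit / length(true_sites) else NA_real_,
    fn_rate = if (length(true_sites)) 1 - hit / length(true_sites) else NA_real_,
    fp_rate = if (length(called_sites))
      (length(called_sites) - hit) / length(called_sites) else 0)
}
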