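#' Odds ratio of a 2x2 carrier table
#'
#' Cross-product odds ratio `(a d)/(b c)` for the table
#' (a = exposed cases, b = unexposed cases, c = exposed controls,
#' d = unexposed controls). With `haldane = TRUE`, 0.5 is added to every
#' cell (used automatically when a zero cell would make the ratio
#' degenerate and `haldane = NA`).
#'
#' @param a,b,c,d Non-negative integer cells.
#' @param haldane FALSE (never correct), TRUE (always add 0.5), or NA
#'   (correct only when a zero cell is present).
#' @return The odds ratio (full precision; round for display).
#' @export
#' @examples
#' odds_ratio(26, 3990, 3, 2869)
odds_ratio <- function(a, b, c, d, haldane = FALSE) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) abort("cells must be non-negative.")
  if (all(cells == 0)) abort("all-zero table.")
  corr <- isTRUE(haldane) || (is.na(haldane) && any(cells == 0))
  if (corr) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}

#' Woolf (logit) confidence interval for an odds ratio
#'
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. Zero cells are
#' Haldane-corrected (0.5 added to all cells) and flagged via the
#' `corrected` attribute.
#'
#' @inheritParams odds_ratio
#' @param level Confidence level.
#' @return Length-2 vector (low, high).
#' @export
#' @examples
#' round(woolf_ci(26, 3990, 3, 2869), 1)
woolf_ci <- function(a, b, c, d, level = 0.95) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) abort("cells must be non-negative.")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  z <- qnorm(1 - (1 - level) / 2)
  lor <- log(cells[1] * cells[4] / (cells[2] * cells[3]))
  se <- sqrt(sum(1 / cells))
  out <- exp(lor + c(-1, 1) * z * se)
  names(out) <- c("low", "high")
  attr(out, "corrected") <- corrected
  out
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Point-probability convention: the p value sums hypergeometric
#' probabilities of all tables (with the observed margins) no more probable
#' than the observed one — the convention of [stats::fisher.test()], which
#' this wraps.
#'
#' @inheritParams odds_ratio
#' @return Two-sided p value.
#' @export
#' @examples
#' fisher_exact_two_sided(26, 3990, 3, 2869)
fisher_exact_two_sided <- function(a, b, c, d) {
  stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE))$p.value
}

#' Carrier-level case-control association
#'
#' Builds the 2x2 table from carrier counts and group sizes (non-carriers
#' are group size minus carriers), and reports the odds ratio with Woolf
#' confidence interval and Fisher exact p value.
#'
#' @param carriers_case,carriers_control Distinct carrier counts.
#' @param n_case,n_control Group sizes.
#' @param level Confidence level for the Woolf interval.
#' @return A `carrier_assoc` object; see [tidy()] for a tabular view.
#' @export
#' @examples
#' carrier_association(26, 4016, 3, 2872)
carrier_association <- function(carriers_case, n_case, carriers_control,
                                n_control, level = 0.95) {
  if (carriers_case > n_case || carriers_control > n_control) {
    abort("carrier counts cannot exceed group sizes.")
  }
  a <- carriers_case; b <- n_case - carriers_case
  c <- carriers_control; d <- n_control - carriers_control
  ci <- woolf_ci(a, b, c, d, level)
  structure(list(
    table = c(a = a, b = b, c = c, d = d),
    or = odds_ratio(a, b, c, d, haldane = NA),
    ci_low = ci[["low"]], ci_high = ci[["high"]], level = level,
    ci_corrected = attr(ci, "corrected"),
    p = fisher_exact_two_sided(a, b, c, d),
    method = "cross-product OR, Woolf CI, Fisher exact (two-sided)"),
    class = "carrier_assoc")
}

#' @export
print.carrier_assoc <- function(x, ...) {
  cat(sprintf("<carrier_assoc> OR %.2f (%d%% CI %.1f-%.1f), Fisher P = %.2g\n",
              x$or, round(100 * x$level), x$ci_low, x$ci_high, x$p))
  invisible(x)
}

#' @export
tidy.carrier_assoc <- function(x, ...) {
  tibble::tibble(a = x$table[["a"]], b = x$table[["b"]], c = x$table[["c"]],
                 d = x$table[["d"]], or = x$or, ci_low = x$ci_low,
                 ci_high = x$ci_high, p = x$p,
                 zero_cell_corrected = x$ci_corrected)
}

#' @export
glance.carrier_assoc <- function(x, ...) {
  tibble::tibble(or = x$or, p = x$p, method = x$method)
}

#' Permutation gene-burden test on pooled allele counts
#'
#' Aggregates rare-variant allele counts per pool for one gene and tests
#' whether case pools carry a higher rare-allele rate per chromosome than
#' control pools. The statistic is the rate difference
#' `sum(counts in case pools)/chromosomes(case) -
#'  sum(counts in control pools)/chromosomes(control)`; the one-sided p
#' value permutes case/control labels over pools (the pool is the
#' exchangeable unit), with the `(r + 1)/(n_perm + 1)` convention. When a
#' `stage` column is present, labels are permuted within stage.
#'
#' @param pool_counts Tibble with pool_id, count (summed rare alt alleles
#'   for the gene), pool_size, stratum ("case"/"control"), optionally stage.
#' @param n_perm Number of label permutations.
#' @param seed Optional integer seed.
#' @return A `burden_test` object with `statistic`, `p`, `n_perm` and the
#'   permutation null; see [tidy()]/[glance()].
#' @export
gene_burden_test <- function(pool_counts, n_perm = 999, seed = NULL) {
  need <- c("pool_id", "count", "pool_size", "stratum")
  if (!all(need %in% names(pool_counts))) {
    abort(paste0("`pool_counts` needs columns: ", paste(need, collapse = ", ")))
  }
  is_case <- pool_counts$stratum == "case"
  if (sum(is_case) < 2 || sum(!is_case) < 2) {
    abort("need at least 2 pools per group.")
  }
  cnt <- pool_counts$count
  an <- 2 * pool_counts$pool_size
  stage <- if ("stage" %in% names(pool_counts)) pool_counts$stage else
    rep(1L, nrow(pool_counts))

  rate_diff <- function(case_flag) {
    sum(cnt[case_flag]) / sum(an[case_flag]) -
      sum(cnt[!case_flag]) / sum(an[!case_flag])
  }
  obs <- rate_diff(is_case)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      perm <- logical(length(is_case))
      for (s in unique(stage)) {
        k <- which(stage == s)
        perm[k] <- sample(is_case[k])
      }
      rate_diff(perm)
    }, numeric(1))
  })
  p <- (sum(null >= obs) + 1) / (n_perm + 1)
  structure(list(statistic = obs, p = p, n_perm = n_perm, null = null,
                 n_case_pools = sum(is_case),
                 n_control_pools = sum(!is_case)),
            class = "burden_test")
}

#' @export
print.burden_test <- function(x, ...) {
  cat(sprintf("<burden_test> rate difference %.3g per chromosome; one-sided permutation P = %.4g (%d permutations)\n",
              x$statistic, x$p, x$n_perm))
  invisible(x)
}

#' @export
tidy.burden_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p = x$p, n_perm = x$n_perm,
                 n_case_pools = x$n_case_pools,
                 n_control_pools = x$n_control_pools)
}

#' @export
glance.burden_test <- function(x, ...) tidy(x)
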