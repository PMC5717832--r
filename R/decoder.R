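#' Decode the carriers of a rare variant from overlapping pool stages
#'
#' Identifies the individual carrier(s) of one variant by combining
#' variant-positive pools across sequencing stages. Because validation
#' pools are near-orthogonal to the discovery pools, the members shared
#' between positive pools pin down the carriers. "Parsimonious" is
#' operationalised as: minimum number of carrier individuals first, then
#' minimum total allele count. The search is exact (depth-first with
#' residual pruning, iteratively deepened over the carrier count) over the
#' union of members of positive pools.
#'
#' Constraints: every pool with a confident call at the site (depth at or
#' above `min_depth_per_individual` per member) must have its members' summed
#' allele count equal its estimated count; low-coverage pools are ignored.
#' When raw read counts (`alt_count`) accompany the calls, "equal" means
#' "within the plausible count set": any count whose log10 likelihood is
#' within `count_margin` of the maximum-likelihood count, which absorbs
#' binomial read noise around count boundaries while staying exact when the
#' data are decisive. Without read counts the estimated count is matched
#' exactly. Individuals may carry one or two alleles. When a minimal
#' solution involves a homozygous carrier and a larger all-heterozygous
#' explanation also fits, both are reported and the call is flagged
#' ambiguous rather than silently resolved.
#'
#' @param site_calls Per-pool calls for one site: tibble with pool_id,
#'   est_count, quality, depth, pool_size (any stage mix), optionally
#'   alt_count.
#' @param design Pool design covering the pools in `site_calls` (long
#'   tibble pool_id/id).
#' @param min_quality Quality at or above which a positive call is trusted.
#' @param min_depth_per_individual Depth per member below which a pool is
#'   treated as uninformative (its constraint is dropped).
#' @param count_margin Log10-likelihood window defining the plausible count
#'   set when `alt_count` is present.
#' @param error_rate Per-base miscall rate used for the likelihood window.
#' @return A `carrier_solution`: list with `site` (if present in input),
#'   `status` ("unique", "ambiguous" or "discrepant"), `solutions` (list of
#'   tibbles id/alleles) and `candidates`.
#' @export
#' @examples
#' design <- tibble::tibble(
#'   pool_id = rep(c("P7", "Q3"), each = 2), stage = rep(c(1L, 3L), each = 2),
#'   stratum = "case", id = c("i42", "i43", "i42", "i99"))
#' calls <- tibble::tibble(pool_id = c("P7", "Q3"), est_count = 1L,
#'                         quality = 30, depth = 600, pool_size = 2L)
#' decode_carriers(calls, design)
decode_carriers <- function(site_calls, design, min_quality = 2,
                            min_depth_per_individual = 10,
                            count_margin = 2, error_rate = 0.005) {
  missing <- setdiff(site_calls$pool_id, design$pool_id)
  if (length(missing)) {
    abort(paste0("pools absent from membership index: ",
                 paste(missing, collapse = ", ")))
  }
  members <- split(design$id, design$pool_id)
  confident <- site_calls$depth >=
    min_depth_per_individual * site_calls$pool_size
  positive <- site_calls$est_count >= 1L & site_calls$quality >= min_quality &
    confident
  neg_conf <- confident & site_calls$est_count == 0L

  pos_pools <- site_calls$pool_id[positive]
  candidates <- sort(unique(unlist(members[pos_pools])))
  # confident-negative pools exclude their members outright
  excluded <- unique(unlist(members[site_calls$pool_id[neg_conf]]))
  candidates <- setdiff(candidates, excluded)

  site <- if ("site" %in% names(site_calls)) site_calls$site[1] else NA_character_
  if (!length(pos_pools)) {
    return(new_carrier_solution(site, "discrepant", list(), candidates))
  }

  # constraint per positive pool: summed alleles of candidate members must
  # fall in the pool's plausible count interval
  cons <- lapply(pos_pools, function(p) intersect(members[[p]], candidates))
  if ("alt_count" %in% names(site_calls)) {
    iv <- allele_count_interval(site_calls$depth[positive],
                                site_calls$alt_count[positive],
                                2L * site_calls$pool_size[positive],
                                error_rate, count_margin)
    lo <- pmax(iv$lo, 1L)  # positivity already established by quality
    hi <- iv$hi
  } else {
    lo <- hi <- site_calls$est_count[positive]
  }
  if (any(lengths(cons) == 0L)) {
    return(new_carrier_solution(site, "discrepant", list(), candidates))
  }

  sols <- search_assignments(candidates, cons, lo, hi)
  if (!length(sols)) {
    return(new_carrier_solution(site, "discrepant", list(), candidates))
  }
  status <- if (length(sols) == 1L) "unique" else "ambiguous"
  new_carrier_solution(site, status, sols, candidates)
}

# Plausible allele-count interval for a pooled call: all counts whose log10
# likelihood is within `margin` of the maximum-likelihood count. The
# binomial likelihood is unimodal in the count, so the set is an interval.
allele_count_interval <- function(depth, alt_count, pool_2n,
                                  error_rate = 0.005, margin = 2) {
  n <- max(length(depth), length(alt_count), length(pool_2n))
  depth <- rep_len(depth, n); alt_count <- rep_len(alt_count, n)
  pool_2n <- rep_len(pool_2n, n)
  lo <- hi <- integer(n)
  for (i in seq_len(n)) {
    frac <- (0:pool_2n[i]) / pool_2n[i]
    p <- frac * (1 - error_rate) + (1 - frac) * error_rate / 3
    ll <- dbinom(alt_count[i], depth[i], p, log = TRUE) / log(10)
    keep <- which(ll >= max(ll) - margin)
    lo[i] <- min(keep) - 1L
    hi[i] <- max(keep) - 1L
  }
  tibble::tibble(lo = lo, hi = hi)
}

# Exact search: iterative deepening on the number of carriers; at the minimal
# cardinality all solutions with minimal total allele count are returned.
# If a minimal solution contains a homozygous (2-allele) carrier, solutions
# with one extra carrier are also enumerated so that a het-only alternative
# is surfaced as ambiguity instead of being silently dropped.
search_assignments <- function(candidates, cons, lo, hi) {
  nc <- length(candidates)
  pool_of <- lapply(cons, function(m) match(m, candidates))
  in_pools <- lapply(seq_len(nc), function(i)
    which(vapply(pool_of, function(p) i %in% p, logical(1))))

  enumerate_k <- function(k_max) {
    sols <- list()
    asum <- integer(length(pool_of))
    # remaining capacity: 2 alleles per unassigned member of each pool
    cap <- vapply(pool_of, function(p) 2L * length(p), integer(1))
    assign <- integer(nc)
    recurse <- function(i, used) {
      if (any(lo - asum > cap)) return()
      if (i > nc) {
        if (all(asum >= lo)) sols[[length(sols) + 1L]] <<- assign
        return()
      }
      for (d in 0:2) {
        if (d > 0 && used >= k_max) break
        ok <- TRUE
        for (p in in_pools[[i]]) {
          if (asum[p] + d > hi[p]) { ok <- FALSE; break }
        }
        if (ok) {
          for (p in in_pools[[i]]) {
            asum[p] <<- asum[p] + d
            cap[p] <<- cap[p] - 2L
          }
          assign[i] <<- d
          recurse(i + 1L, used + (d > 0))
          for (p in in_pools[[i]]) {
            asum[p] <<- asum[p] - d
            cap[p] <<- cap[p] + 2L
          }
          assign[i] <<- 0L
        }
      }
    }
    recurse(1L, 0L)
    sols
  }

  k_min <- NA
  sols <- list()
  for (k in 0:min(nc, sum(hi))) {
    sols <- enumerate_k(k)
    sols <- Filter(function(a) sum(a > 0) == k, sols)
    if (length(sols)) { k_min <- k; break }
  }
  if (!length(sols)) return(list())
  # secondary objective: minimal total allele count at minimal cardinality
  tot <- vapply(sols, sum, integer(1))
  sols_min <- sols[tot == min(tot)]
  # homozygote / extra-het tie: surface the larger het-only explanations
  if (any(vapply(sols_min, function(a) any(a == 2L), logical(1))) &&
      k_min < length(candidates)) {
    extra <- Filter(function(a) sum(a > 0) == k_min + 1L && all(a <= 1L),
                    enumerate_k(k_min + 1L))
    sols_min <- c(sols_min, extra)
  }
  lapply(sols_min, function(a) {
    tibble::tibble(id = candidates[a > 0L], alleles = a[a > 0L])
  })
}

new_carrier_solution <- function(site, status, solutions, candidates) {
  structure(list(site = site, status = status, solutions = solutions,
                 candidates = candidates),
            class = "carrier_solution")
}

#' @export
print.carrier_solution <- function(x, ...) {
  cat("<carrier_solution> ", x$site, ": ", x$status, sep = "")
  if (length(x$solutions)) {
    cat(" (", length(x$solutions), " minimal solution",
        if (length(x$solutions) > 1) "s", ")\n", sep = "")
    for (s in head(x$solutions, 5)) {
      cat("  ", paste0(s$id, "x", s$alleles, collapse = " + "), "\n", sep = "")
    }
  } else cat("\n")
  invisible(x)
}

#' @export
tidy.carrier_solution <- function(x, ...) {
  tibble::tibble(
    site = x$site, status = x$status, n_solutions = length(x$solutions),
    carriers = paste(
      vapply(x$solutions,
             function(s) paste0(s$id, "x", s$alleles, collapse = ";"),
             character(1)),
      collapse = " | "))
}

#' Check consistency of validation-stage counts with discovery stages
#'
#' Decodes the variant from the discovery stages (1-2) alone, computes the
#' set of validation-stage (stage 3) allele totals compatible with any
#' discovery-consistent carrier assignment restricted to the resequenced
#' individuals, and compares the observed stage-3 total against that set.
#'
#' @param stage12_calls,stage3_calls Per-pool calls for the site, split by
#'   stage (columns as in [decode_carriers()]).
#' @param design Combined pool design across stages.
#' @param sequenced_ids Individuals actually resequenced in stage 3.
#' @param min_quality,min_depth_per_individual As in [decode_carriers()].
#' @return List with `status` ("consistent", "discrepant" or
#'   "unresolvable"), `expected` (set of feasible stage-3 totals),
#'   `observed`, and the discovery-stage `solution`.
#' @export
check_stage_consistency <- function(stage12_calls, stage3_calls, design,
                                    sequenced_ids, min_quality = 2,
                                    min_depth_per_individual = 10) {
  conf12 <- stage12_calls$depth >=
    min_depth_per_individual * stage12_calls$pool_size
  pos12 <- stage12_calls$est_count >= 1L &
    stage12_calls$quality >= min_quality
  if (any(pos12 & !conf12) && !any(pos12 & conf12)) {
    # the only discovery evidence sits in low-coverage pools
    return(list(status = "unresolvable", expected = integer(0),
                observed = NA_integer_, solution = NULL))
  }
  sol <- decode_carriers(stage12_calls, design, min_quality,
                         min_depth_per_individual)
  if (sol$status == "discrepant") {
    return(list(status = "unresolvable", expected = integer(0),
                observed = NA_integer_, solution = sol))
  }
  expected <- sort(unique(vapply(sol$solutions, function(s) {
    sum(s$alleles[s$id %in% sequenced_ids])
  }, integer(1))))
  conf3 <- stage3_calls$depth >=
    min_depth_per_individual * stage3_calls$pool_size
  observed <- sum(stage3_calls$est_count[conf3])
  status <- if (observed %in% expected) "consistent" else "discrepant"
  list(status = status, expected = expected, observed = observed,
       solution = sol)
}

#' Summarise a phenotype attribute over candidate carriers
#'
#' Even when the carrier cannot be identified uniquely, the attribute values
#' over all candidate carriers can be informative: a single distinct value
#' means the attribute is identified although the individual is not.
#'
#' @param solution A `carrier_solution`.
#' @param phenotypes Phenotype tibble with an `id` column.
#' @param attribute Column name to summarise (e.g. "age_at_diagnosis").
#' @return Sorted vector of distinct attribute values over the union of
#'   carriers across solutions.
#' @export
summarize_partial_attributes <- function(solution, phenotypes, attribute) {
  if (!attribute %in% names(phenotypes)) {
    abort(paste0("unknown attribute: ", attribute))
  }
  ids <- unique(unlist(lapply(solution$solutions, function(s) s$id)))
  sort(unique(phenotypes[[attribute]][phenotypes$id %in% ids]))
}
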