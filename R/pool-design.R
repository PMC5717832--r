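#' Build phenotype-homogeneous DNA pools
#'
#' Partitions individuals into equal-size pools that are homogeneous with
#' respect to the chosen strata (e.g. case/control status, onset group):
#' each stratum is shuffled (after canonical sorting, so input order does
#' not matter) and chunked into `ceiling(stratum size / pool_size)` pools.
#' The final pool of a stratum may be smaller than `pool_size`.
#'
#' @param phenotypes Data frame with at least an `id` column plus the
#'   stratum columns.
#' @param pool_size Target number of individuals per pool (>= 2).
#' @param strata Character vector of column names defining homogeneity.
#' @param stage Integer stage label stored on every pool.
#' @param seed Optional integer seed for the within-stratum shuffle.
#' @return A `pool_design` tibble in long form: one row per pool member,
#'   columns pool_id, stage, stratum, id.
#' @export
#' @examples
#' ph <- tibble::tibble(id = sprintf("I%03d", 1:95),
#'                      status = rep(c("case", "control"), c(60, 35)))
#' design_stratified_pools(ph, pool_size = 20, strata = "status", seed = 1)
design_stratified_pools <- function(phenotypes, pool_size, strata = "status",
                                    stage = 1L, seed = NULL) {
  if (pool_size < 2) abort("`pool_size` must be >= 2.")
  if (!all(strata %in% names(phenotypes))) {
    abort("all `strata` columns must exist in `phenotypes`.")
  }
  if (anyDuplicated(phenotypes$id)) abort("duplicate individual ids.")
  lab <- do.call(paste, c(phenotypes[strata], sep = "/"))
  with_seed(seed, {
    out <- purrr::map_dfr(split(phenotypes$id, lab), function(ids) {
      if (length(ids) < pool_size) {
        warn(sprintf("stratum with %d individuals is smaller than pool_size %d; one short pool",
                     length(ids), pool_size))
      }
      ids <- sample(sort(ids))
      tibble::tibble(id = ids,
                     pool = (seq_along(ids) - 1L) %/% pool_size + 1L)
    }, .id = "stratum")
    out |>
      dplyr::mutate(pool_id = sprintf("S%d_%s_P%03d", stage,
                                      gsub("[^A-Za-z0-9]+", ".", .data$stratum),
                                      .data$pool),
                    stage = as.integer(stage)) |>
      dplyr::select("pool_id", "stage", "stratum", "id") |>
      dplyr::arrange(.data$pool_id, .data$id) |>
      new_pool_design()
  })
}

new_pool_design <- function(x) {
  class(x) <- unique(c("pool_design", class(x)))
  x
}

#' Number of pools and pool sizes of a design
#'
#' @param design A `pool_design` tibble.
#' @return Tibble with pool_id, stage, stratum, pool_size.
#' @export
pool_sizes <- function(design) {
  design |>
    dplyr::group_by(.data$pool_id) |>
    dplyr::summarise(stage = .data$stage[1], stratum = .data$stratum[1],
                     pool_size = dplyr::n(), .groups = "drop")
}

#' Build validation pools orthogonal to an existing design
#'
#' Re-pools a subset of already-pooled individuals such that every new pool
#' shares at most `max_overlap` members with every pool of the base design.
#' Construction is transversal-first and greedy: each new pool repeatedly
#' takes up to `max_overlap` members from the base pool with the most
#' members still unplaced, which keeps the feasibility invariant (no base
#' pool may hold more unplaced members than `max_overlap` times the number
#' of unfilled new pools). If a greedy pass fails verification it is
#' restarted with a reshuffled order (up to `max_restarts` times).
#'
#' @param base_design A `pool_design` covering all of `subset_ids`.
#' @param subset_ids Individuals to re-pool.
#' @param pool_size New pool size.
#' @param max_overlap Maximum members any (base pool, new pool) pair may
#'   share (>= 1).
#' @param stage Stage label for the new pools.
#' @param seed Optional integer seed.
#' @param max_restarts Greedy restarts before giving up.
#' @return A `pool_design` tibble (stratum is `"validation"`), carrying the
#'   verified maximum overlap with the base design as attribute
#'   `max_overlap_observed`.
#' @export
design_orthogonal_pools <- function(base_design, subset_ids, pool_size,
                                    max_overlap = 1L, stage = 3L, seed = NULL,
                                    max_restarts = 5L) {
  if (max_overlap < 1) abort("`max_overlap` must be >= 1.")
  subset_ids <- sort(unique(as.character(subset_ids)))
  unknown <- setdiff(subset_ids, base_design$id)
  if (length(unknown)) {
    abort(paste0("subset ids absent from base design: ",
                 paste(head(unknown, 3), collapse = ", ")))
  }
  n_new <- ceiling(length(subset_ids) / pool_size)
  # base pool membership of the subset (an individual can sit in several
  # base pools if the base design spans stages; constrain against all)
  groups <- split(base_design$id[base_design$id %in% subset_ids],
                  base_design$pool_id[base_design$id %in% subset_ids])
  groups <- lapply(groups, unique)
  if (anyDuplicated(unlist(groups))) {
    abort("each subset member must belong to exactly one base pool.")
  }
  too_big <- names(groups)[lengths(groups) > max_overlap * n_new]
  if (length(too_big)) {
    abort(paste0("infeasible: base pool ", too_big[1], " holds ",
                 length(groups[[too_big[1]]]), " subset members but at most ",
                 max_overlap * n_new, " can be spread over ", n_new,
                 " new pools (max_overlap ", max_overlap, ")."))
  }

  attempt <- function(groups) {
    remaining <- groups
    assign <- vector("list", n_new)
    sizes <- c(rep(pool_size, n_new - 1L),
               length(subset_ids) - pool_size * (n_new - 1L))
    for (j in seq_len(n_new)) {
      members <- character(sizes[j])
      taken <- integer(length(remaining))
      for (k in seq_len(sizes[j])) {
        rem <- lengths(remaining)
        open <- rem > 0L & taken < max_overlap
        if (!any(open)) return(NULL)
        g <- which.max(ifelse(open, rem, -1L))
        members[k] <- remaining[[g]][1]
        remaining[[g]] <- remaining[[g]][-1]
        taken[g] <- taken[g] + 1L
      }
      assign[[j]] <- members
    }
    assign
  }

  res <- NULL
  with_seed(seed, {
    for (r in seq_len(max_restarts + 1L)) {
      shuffled <- lapply(groups, sample)
      shuffled <- shuffled[sample(seq_along(shuffled))]
      res <- attempt(shuffled)
      if (!is.null(res)) break
    }
  })
  if (is.null(res)) {
    abort("could not construct an orthogonal design within the restart budget; relax `max_overlap` or `pool_size`.")
  }
  out <- purrr::imap_dfr(res, function(m, j) {
    tibble::tibble(pool_id = sprintf("S%d_val_P%03d", stage, j),
                   stage = as.integer(stage), stratum = "validation",
                   id = sort(m))
  }) |> new_pool_design()
  ov <- max_pairwise_overlap(base_design, out)
  if (ov > max_overlap) {
    abort(sprintf("internal error: constructed design has overlap %d > %d",
                  ov, max_overlap))
  }
  attr(out, "max_overlap_observed") <- ov
  out
}

#' Maximum pairwise pool overlap between two designs
#'
#' @param design_a,design_b Pool designs (long tibbles with pool_id, id).
#' @return Largest number of shared individuals over all pool pairs; 0 when
#'   the designs have no individual in common.
#' @export
max_pairwise_overlap <- function(design_a, design_b) {
  shared <- dplyr::inner_join(
    dplyr::distinct(tibble::as_tibble(design_a)[c("pool_id", "id")]),
    dplyr::distinct(tibble::as_tibble(design_b)[c("pool_id", "id")]),
    by = "id", relationship = "many-to-many")
  if (!nrow(shared)) return(0L)
  shared |>
    dplyr::count(.data$pool_id.x, .data$pool_id.y) |>
    dplyr::pull(.data$n) |>
    max() |>
    as.integer()
}
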