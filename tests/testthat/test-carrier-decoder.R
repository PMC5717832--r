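two_stage_design <- function() {
  # 8 individuals; stage-1 pools of 4, stage-3 pools of 2 (orthogonal)
  bind_rows(
    tibble(pool_id = rep(c("A1", "A2"), each = 4), stage = 1L,
           stratum = "case", id = sprintf("i%d", 1:8)),
    tibble(pool_id = rep(c("B1", "B2", "B3", "B4"), each = 2), stage = 3L,
           stratum = "validation",
           id = sprintf("i%d", c(1, 5, 2, 6, 3, 7, 4, 8))))
}

call_row <- function(pool_id, c, depth = 600, size = 4) {
  tibble(pool_id = pool_id, est_count = as.integer(c),
         quality = ifelse(c > 0, 30, 0), depth = depth, pool_size = size)
}

test_that("a singleton seen in two orthogonal pools is decoded uniquely", {
  design <- two_stage_design()
  calls <- bind_rows(call_row("A1", 1), call_row("B1", 1, size = 2))
  sol <- decode_carriers(calls, design)
  expect_equal(sol$status, "unique")
  expect_equal(sol$solutions[[1]]$id, "i1")  # A1 = {i1..i4}, B1 = {i1,i5}
  expect_equal(sol$solutions[[1]]$alleles, 1L)
})

test_that("count 2 split over two validation pools resolves both carriers", {
  design <- two_stage_design()
  calls <- bind_rows(call_row("A1", 2),
                     call_row("B1", 1, size = 2),   # {i1, i5} -> i1
                     call_row("B2", 1, size = 2))   # {i2, i6} -> i2
  sol <- decode_carriers(calls, design)
  expect_equal(sol$status, "unique")
  expect_setequal(sol$solutions[[1]]$id, c("i1", "i2"))
  expect_equal(sol$solutions[[1]]$alleles, c(1L, 1L))
})

test_that("an unexplainable positive pool is reported discrepant", {
  design <- two_stage_design()
  # stage 1 positive, but every validation pool that could hold the carrier
  # is confidently negative
  calls <- bind_rows(call_row("A1", 1),
                     call_row("B1", 0, size = 2), call_row("B2", 0, size = 2),
                     call_row("B3", 0, size = 2), call_row("B4", 0, size = 2))
  expect_equal(decode_carriers(calls, design)$status, "discrepant")
})

test_that("low-coverage negative pools do not constrain the solution", {
  design <- two_stage_design()
  calls <- bind_rows(call_row("A1", 1),
                     call_row("B1", 0, depth = 10, size = 2),
                     call_row("B2", 0, size = 2),
                     call_row("B3", 0, size = 2), call_row("B4", 0, size = 2))
  sol <- decode_carriers(calls, design)
  # i1 excluded by B2..B4? no: B1 covers {i1,i5} but is uninformative, so
  # candidates i1..i4 minus confident negatives {i2,i6,i3,i7,i4,i8} = {i1}
  expect_equal(sol$status, "unique")
  expect_equal(sol$solutions[[1]]$id, "i1")
})

test_that("pools missing from the membership index are an error", {
  design <- two_stage_design()
  expect_error(decode_carriers(call_row("NOPE", 1), design),
               "membership index")
})

test_that("homozygote/two-het ties are surfaced as ambiguity", {
  # one pool with count 2 and no orthogonal information: {i1 x2} and every
  # same-pool het pair explain the data; minimal solution is the homozygote
  # but the alternatives must be surfaced
  design <- tibble(pool_id = "A1", stage = 1L, stratum = "case",
                   id = c("i1", "i2"))
  sol <- decode_carriers(call_row("A1", 2, size = 2), design)
  expect_equal(sol$status, "ambiguous")
  canon <- canon_solutions(sol$solutions)
  expect_true("i1:2" %in% canon)             # single homozygous carrier
  expect_true("i1:1,i2:1" %in% canon)        # het-pair alternative
})

test_that("the search agrees with exhaustive enumeration on random instances", {
  for (s in 1:40) {
    inst <- random_decoding_instance(seed = s, n_ind = sample(6:12, 1))
    got <- decode_carriers(inst$calls, inst$design)
    want <- oracle_decode(inst$calls, inst$design)
    expect_equal(got$status, want$status, info = paste("seed", s))
    expect_equal(canon_solutions(got$solutions), canon_solutions(want$sols),
                 info = paste("seed", s))
  }
})

test_that("adding a consistent positive pool never increases ambiguity", {
  for (s in 1:20) {
    inst <- random_decoding_instance(seed = 100 + s, n_ind = 12,
                                     p_low_coverage = 0)
    calls <- inst$calls
    pos <- which(calls$est_count > 0)
    if (length(pos) < 2) next
    reduced <- calls[-pos[length(pos)], ]
    n_with <- length(decode_carriers(calls, inst$design)$solutions)
    n_without <- length(decode_carriers(reduced, inst$design)$solutions)
    expect_lte(n_with, max(n_without, 1))
  }
})

test_that("stage consistency compares observed stage-3 totals to the feasible set", {
  design <- two_stage_design()
  s12 <- call_row("A1", 1)
  # carrier i1 resequenced; expected total {1}, observed 1
  s3 <- bind_rows(call_row("B1", 1, size = 2),
                  call_row("B2", 0, size = 2), call_row("B3", 0, size = 2),
                  call_row("B4", 0, size = 2))
  chk <- check_stage_consistency(s12, s3, design, sequenced_ids = design$id)
  expect_equal(chk$status, "consistent")
  expect_equal(chk$observed, 1L)
  # observed exceeding every feasible expectation is discrepant
  s3_bad <- bind_rows(call_row("B1", 1, size = 2), call_row("B2", 1, size = 2),
                      call_row("B3", 1, size = 2))
  expect_equal(check_stage_consistency(s12, s3_bad, design,
                                       design$id)$status, "discrepant")
  # discovery evidence only in a low-coverage pool cannot be resolved
  s12_low <- call_row("A1", 1, depth = 20)
  expect_equal(check_stage_consistency(s12_low, s3, design,
                                       design$id)$status, "unresolvable")
})

test_that("partial attributes identify the phenotype even when the carrier is ambiguous", {
  ph <- tibble(id = c("i1", "i2", "i3"), status = "case",
               age_at_diagnosis = c(33, 33, 51), onset_group = "early")
  uniq <- structure(list(site = "s", status = "unique",
                         solutions = list(tibble(id = "i3", alleles = 1L)),
                         candidates = "i3"), class = "carrier_solution")
  expect_equal(summarize_partial_attributes(uniq, ph, "age_at_diagnosis"), 51)
  amb <- structure(list(site = "s", status = "ambiguous",
                        solutions = list(tibble(id = "i1", alleles = 1L),
                                         tibble(id = "i2", alleles = 1L)),
                        candidates = c("i1", "i2")),
                   class = "carrier_solution")
  expect_equal(summarize_partial_attributes(amb, ph, "age_at_diagnosis"), 33)
  expect_error(summarize_partial_attributes(amb, ph, "hba1c"), "unknown")
})

test_that("singleton carriers are recovered end to end through both stages", {
  # 480 cases in stage-1 pools of 20; orthogonal stage-3 pools of 24
  # (overlap <= 1); 80 planted singleton variants at screen coverage
  results <- run_singleton_recovery(seed = 21)
  expect_gt(length(results), 15)
  expect_gte(mean(results == "correct"), 0.95)
})
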