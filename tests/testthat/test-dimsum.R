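test_that("exact_min_distance matches the brute-force oracle on worked instances", {
  id3 <- signed_arrangement(c("B1", "B2", "B3"))
  expect_equal(exact_min_distance(id3, id3), 0L)

  one <- signed_arrangement("B1")
  one_f <- signed_arrangement("B1", signs = -1L)
  expect_equal(exact_min_distance(one, one_f), 1L)
  expect_equal(brute_min_distance(one, one_f), 1L)

  # Typha -> Anomochloa LSC block frame: two inversions
  typha <- signed_arrangement(c("D-LSC3", "D-LSC1", "D-LSC2"))
  anomo <- signed_arrangement(c("D-LSC2", "D-LSC3", "D-LSC1"),
                              signs = c(1L, -1L, -1L))
  expect_equal(brute_min_distance(typha, anomo), 2L)
  expect_equal(exact_min_distance(typha, anomo), 2L)

  # two-block lateral exchange: 2 without flip equivalence, 1 with
  src <- signed_arrangement(c("PoJo-SSC1", "PoJo-SSC2"))
  tgt <- signed_arrangement(c("PoJo-SSC2", "PoJo-SSC1"),
                            signs = c(1L, -1L))
  expect_equal(exact_min_distance(src, tgt), 2L)
  expect_equal(exact_min_distance(src, tgt, flip_equivalence = TRUE), 1L)
  expect_equal(brute_min_distance(src, tgt), 2L)
  expect_equal(brute_min_distance(src, tgt, flip_equivalence = TRUE), 1L)
})

test_that("exact_min_distance agrees with brute force on random instances", {
  for (seed in 1:12) {
    n <- 2L + seed %% 3L  # 2..4 blocks
    src <- random_arrangement(n, seed = seed)
    tgt <- plant_inversions(src, 1L + seed %% 4L,
                            seed = seed + 500)$arrangement
    for (flip in c(FALSE, TRUE)) {
      d_bfs <- exact_min_distance(src, tgt, flip_equivalence = flip)
      expect_equal(d_bfs, brute_min_distance(src, tgt, flip_equivalence = flip),
                   info = sprintf("seed %d flip %s", seed, flip))
    }
  }
})

test_that("the block-count cap refuses oversized exact searches", {
  big <- random_arrangement(9, seed = 1)
  expect_error(exact_min_distance(big, big), "dimsum")
  expect_equal(exact_min_distance(random_arrangement(9, seed = 1),
                                  random_arrangement(9, seed = 1),
                                  max_blocks = 9L), 0L)
})

test_that("enumerate_minimal_scenarios finds every shortest series", {
  a2 <- signed_arrangement(c("B1", "B2"))
  expect_identical(enumerate_minimal_scenarios(a2, a2),
                   list(data.frame(start = integer(0), end = integer(0))))

  one <- signed_arrangement("B1")
  scen <- enumerate_minimal_scenarios(one, signed_arrangement("B1", signs = -1L))
  expect_length(scen, 1L)
  expect_equal(scen[[1L]], data.frame(start = 1L, end = 1L))

  full_flip <- signed_arrangement(c("B2", "B1"), signs = c(-1L, -1L))
  scen <- enumerate_minimal_scenarios(a2, full_flip)
  expect_length(scen, 1L)
  expect_equal(scen[[1L]], data.frame(start = 1L, end = 2L))
  # brute force over all length-1 sequences agrees
  expect_length(brute_scenarios(a2, full_flip, 1L), 1L)

  # scenario sets match brute enumeration on random small instances
  for (seed in 1:6) {
    src <- random_arrangement(3, seed = seed)
    tgt <- plant_inversions(src, 2, seed = seed + 40)$arrangement
    d <- exact_min_distance(src, tgt)
    got <- enumerate_minimal_scenarios(src, tgt)
    want <- brute_scenarios(src, tgt, d)
    expect_setequal(vapply(got, scenario_key, character(1)),
                    vapply(want, scenario_key, character(1)))
    # every emitted scenario replays to the target and has length d
    for (s in got) {
      expect_equal(nrow(s), d)
      expect_true(arrangements_equal(apply_scenario(src, s), tgt))
    }
  }
})

test_that("dimsum reaches the endpoint and reports solutions soundly", {
  src <- signed_arrangement(c("B1", "B2"))
  tgt <- signed_arrangement(c("B2", "B1"), signs = c(1L, -1L))

  res <- dimsum(src, tgt, replicates = 10000, seed = 1)
  expect_s3_class(res, "dimsum_result")
  expect_equal(res$min_length, 2L)
  expect_equal(res$replicates_run, 10000L)
  expect_lte(sum(res$hits_by_length), res$replicates_run)
  expect_equal(min(as.integer(names(res$hits_by_length))), res$min_length)
  # every recorded solution replays to the target
  for (s in res$solutions[seq_len(min(50, length(res$solutions)))])
    expect_true(arrangements_equal(apply_scenario(src, s), tgt))
  # shortest recorded solution length equals min_length
  expect_equal(min(vapply(res$solutions, nrow, 1L)), res$min_length)

  # under flip equivalence one inversion suffices
  res_f <- dimsum(src, tgt, replicates = 10000, seed = 1,
                  flip_equivalence = TRUE)
  expect_equal(res_f$min_length, 1L)
  for (s in res_f$solutions[seq_len(min(50, length(res_f$solutions)))])
    expect_true(arrangements_equal(apply_scenario(src, s), tgt,
                                   flip_equivalence = TRUE))
})

test_that("dimsum handles the degenerate source == target endpoint", {
  a <- random_arrangement(3, seed = 4)
  res <- dimsum(a, a, replicates = 777, seed = 9)
  expect_equal(res$min_length, 0L)
  expect_identical(res$solutions,
                   list(data.frame(start = integer(0), end = integer(0))))
  expect_equal(unname(res$hits_by_length[["0"]]), 777L)
})

test_that("dimsum is bit-identical under a fixed seed and validates config", {
  src <- random_arrangement(3, seed = 2)
  tgt <- plant_inversions(src, 2, seed = 30)$arrangement
  r1 <- dimsum(src, tgt, replicates = 3000, seed = 123)
  r2 <- dimsum(src, tgt, replicates = 3000, seed = 123)
  expect_identical(r1, r2)
  r3 <- dimsum(src, tgt, replicates = 3000, seed = 124)
  expect_false(identical(r1$hits_by_length, r3$hits_by_length))

  expect_error(dimsum(src, tgt, replicates = 0), "replicates")
  expect_error(dimsum(src, tgt, max_steps = 0), "max_steps")
  expect_error(dimsum(src, random_arrangement(4, seed = 1)), "incomparable")
})

test_that("dimsum depends only on the relative signed permutation", {
  # relabeling both arrangements into the source frame leaves the search
  # unchanged, so identity-source runs cover all arrangement pairs
  src <- random_arrangement(3, seed = 77)
  tgt <- plant_inversions(src, 2, seed = 78)$arrangement
  rel <- relabel_against_reference(src, tgt)
  id <- signed_arrangement(paste0("B", 1:3))
  rel_arr <- signed_arrangement(paste0("B", abs(rel)),
                                signs = as.integer(sign(rel)))
  r_orig <- dimsum(src, tgt, replicates = 2000, seed = 5)
  r_rel <- dimsum(id, rel_arr, replicates = 2000, seed = 5)
  expect_identical(r_orig$min_length, r_rel$min_length)
  expect_identical(r_orig$hits_by_length, r_rel$hits_by_length)
  expect_identical(lapply(r_orig$solutions, scenario_key),
                   lapply(r_rel$solutions, scenario_key))
})

test_that("certify_parsimony fills exact_min from the oracle", {
  src <- signed_arrangement(c("B1", "B2"))
  tgt <- signed_arrangement(c("B2", "B1"), signs = c(1L, -1L))
  res <- certify_parsimony(dimsum(src, tgt, replicates = 5000, seed = 2))
  expect_equal(res$exact_min, 2L)
  expect_gte(res$min_length, res$exact_min)
})

test_that("breakpoint count and the reversal lower bound hold exhaustively", {
  id2 <- signed_arrangement(c("B1", "B2"))
  expect_equal(breakpoint_count(id2, id2), 0L)
  expect_equal(breakpoint_count(
    id2, signed_arrangement(c("B2", "B1"), signs = c(-1L, -1L))), 2L)

  # d >= ceiling(bp / 2) over every relative instance with n <= 4
  # (identity-source runs cover all pairs by relabeling invariance)
  for (n in 1:4) {
    id <- signed_arrangement(paste0("B", seq_len(n)))
    for (tgt in all_signed_arrangements(n)) {
      d <- exact_min_distance(id, tgt)
      bp <- breakpoint_count(id, tgt)
      expect_gte(d, ceiling(bp / 2))
      # flip monotonicity: equivalence classes can only be closer
      expect_lte(exact_min_distance(id, tgt, flip_equivalence = TRUE), d)
    }
  }
})
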