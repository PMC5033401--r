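test_that("generators are pure functions of their parameters and seed", {
  expect_identical(random_arrangement(5, seed = 3),
                   random_arrangement(5, seed = 3))
  expect_false(identical(random_arrangement(5, seed = 3),
                         random_arrangement(5, seed = 4)))
  a <- random_arrangement(4, seed = 1)
  expect_identical(plant_inversions(a, 3, seed = 9),
                   plant_inversions(a, 3, seed = 9))
  s1 <- synth_plastome(lsc_bp = 2000, ir_bp = 400, ssc_bp = 500,
                       n_genes = c(lsc = 4, ir = 2, ssc = 2), seed = 6,
                       min_ir_length = 200, k_events = 2)
  s2 <- synth_plastome(lsc_bp = 2000, ir_bp = 400, ssc_bp = 500,
                       n_genes = c(lsc = 4, ir = 2, ssc = 2), seed = 6,
                       min_ir_length = 200, k_events = 2)
  expect_identical(s1$record$sequence, s2$record$sequence)
  expect_identical(s1$sibling$sequence, s2$sibling$sequence)
  expect_identical(s1$truth$scenario, s2$truth$scenario)
})

test_that("random_arrangement draws orientations uniformly", {
  arr <- random_arrangement(10000, seed = 2024)
  expect_setequal(arr$labels, paste0("B", 1:10000))
  frac <- mean(arr$signs > 0)
  expect_lt(abs(frac - 0.5), 0.02)
})

test_that("n = 1 arrangements are a single signed block", {
  for (seed in 1:10) {
    a <- random_arrangement(1, seed = seed)
    expect_equal(a$labels, "B1")
    expect_true(a$signs %in% c(-1L, 1L))
  }
  expect_error(random_arrangement(0), "positive")
})

test_that("plant_inversions returns a replayable ground-truth scenario", {
  a <- random_arrangement(4, seed = 8)
  p0 <- plant_inversions(a, 0, seed = 1)
  expect_identical(p0$arrangement, a)
  expect_equal(nrow(p0$scenario), 0L)
  expect_error(plant_inversions(a, -1), ">= 0")

  for (seed in 1:20) {
    p <- plant_inversions(a, 3, seed = seed)
    expect_true(arrangements_equal(apply_scenario(a, p$scenario),
                                   p$arrangement))
  }
})

test_that("planted histories bound the exact distance (d <= k)", {
  hit_equality <- 0L
  for (seed in 1:100) {
    arr <- random_arrangement(4, seed = seed)
    p <- plant_inversions(arr, 3, seed = 1000 + seed)
    d <- exact_min_distance(arr, p$arrangement)
    expect_lte(d, 3L)
    if (d == 3L) hit_equality <- hit_equality + 1L
  }
  # non-redundant plants do reach the bound for a fair share of seeds
  expect_gt(hit_equality, 10L)
})

test_that("synth_plastome validates its parameters", {
  expect_error(synth_plastome(lsc_bp = 100, ir_bp = 400, ssc_bp = 500,
                              min_ir_length = 200), "LSC must be")
  expect_error(synth_plastome(ir_bp = 500, min_ir_length = 1000),
               "shorter than min_ir_length")
  expect_error(synth_plastome(lsc_bp = 50, ir_bp = 400, ssc_bp = 30,
                              n_genes = c(lsc = 40, ir = 2, ssc = 2),
                              min_ir_length = 200), "too short")
})

test_that("a zero-event sibling request yields no sibling; k events give one", {
  base <- synth_plastome(lsc_bp = 2500, ir_bp = 500, ssc_bp = 600,
                         n_genes = c(lsc = 6, ir = 2, ssc = 2), seed = 4,
                         min_ir_length = 200, k_events = 0)
  expect_null(base$sibling)

  sim <- synth_plastome(lsc_bp = 2500, ir_bp = 500, ssc_bp = 600,
                        n_genes = c(lsc = 6, ir = 2, ssc = 2), seed = 4,
                        min_ir_length = 200, n_blocks = 3, k_events = 2)
  expect_s3_class(sim$sibling, "plastome_record")
  expect_equal(nrow(sim$truth$scenario), 2L)
  # the emitted truth replays: source + scenario == target arrangement
  expect_true(arrangements_equal(
    apply_scenario(sim$truth$source_arr, sim$truth$scenario),
    sim$truth$target_arr))
  # sibling keeps the quadripartite layout and its planted IR
  map <- find_inverted_repeat(sim$sibling, min_ir_length = 200)
  expect_equal(unname(map$region_bp), c(2500L, 500L, 600L, 500L))
})

test_that("sibling gene order realises the planted block rearrangement", {
  sim <- synth_plastome(lsc_bp = 4000, ir_bp = 700, ssc_bp = 800,
                        n_genes = c(lsc = 12, ir = 3, ssc = 2), seed = 21,
                        min_ir_length = 300, n_blocks = 4, k_events = 2)
  map_a <- find_inverted_repeat(sim$record, min_ir_length = 300)
  map_b <- find_inverted_repeat(sim$sibling, min_ir_length = 300)
  go_a <- gene_order_from_features(sim$record, map_a, "LSC")
  go_b <- gene_order_from_features(sim$sibling, map_b, "LSC")
  bp <- collinear_blocks(go_a, go_b)
  # detected block distance is bounded by the planted event count
  expect_lte(exact_min_distance(bp$source, bp$target),
             nrow(sim$truth$scenario))
  # the sibling's gene order is exactly the truth arrangement applied to
  # the source gene order, block by block
  want <- character(0); want_str <- integer(0)
  tr <- sim$truth
  for (i in seq_along(tr$target_arr$labels)) {
    genes <- tr$block_members[[tr$target_arr$labels[i]]]
    src_idx <- match(genes, go_a$symbols)
    if (tr$target_arr$signs[i] > 0) {
      want <- c(want, genes); want_str <- c(want_str, go_a$strands[src_idx])
    } else {
      want <- c(want, rev(genes))
      want_str <- c(want_str, -rev(go_a$strands[src_idx]))
    }
  }
  expect_identical(go_b$symbols, want)
  expect_identical(go_b$strands, want_str)
})

test_that("worked fixtures encode the expected relative permutations", {
  fx <- plastome_fixtures()
  expect_named(fx, c("lsc_typha_anomochloa", "lsc_anomochloa_joinvillea",
                     "lsc_anomochloa_joinvillea_mirror", "ssc_pojo"))
  rel <- function(p) as.integer(relabel_against_reference(p$source, p$target))
  expect_equal(rel(fx$lsc_typha_anomochloa), c(3L, -1L, -2L))
  expect_equal(rel(fx$lsc_anomochloa_joinvillea), c(-2L, 1L))
  expect_equal(rel(fx$lsc_anomochloa_joinvillea_mirror), c(2L, -1L))
  expect_equal(rel(fx$ssc_pojo), c(-2L, 1L))
  # written fixtures read back identically
  dir <- withr::local_tempdir()
  plastome_fixtures(dir = dir)
  rt <- read_blocks_tsv(file.path(dir, "ssc_pojo.tsv"))
  expect_identical(rt$target$labels, fx$ssc_pojo$target$labels)
  expect_identical(rt$target$signs, fx$ssc_pojo$target$signs)
})
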