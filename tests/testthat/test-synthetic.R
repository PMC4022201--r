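small_cfg <- function(...) {
  generate_network(layer_sizes = rep(5L, 7), out_degree = 2,
                   distractor_fraction = 0.2, seed = 1, ...)
}

test_that("identical seeds give byte-identical serializations", {
  a <- small_cfg()
  b <- small_cfg()
  fa <- withr::local_tempfile(fileext = ".nt")
  fb <- withr::local_tempfile(fileext = ".nt")
  write_ntriples(a$graph, fa)
  write_ntriples(b$graph, fb)
  expect_identical(readLines(fa), readLines(fb))
  expect_identical(a$ground_truth, b$ground_truth)
  # a different seed actually changes the wiring
  c <- generate_network(layer_sizes = rep(5L, 7), out_degree = 2,
                        distractor_fraction = 0.2, seed = 2)
  expect_false(identical(a$graph, c$graph))
})

test_that("injective unit-degree wiring gives k disjoint paths", {
  k <- 6L
  ds <- generate_network(layer_sizes = rep(k, 7), out_degree = 1,
                         distractor_fraction = 0, injective = TRUE, seed = 3)
  expect_equal(nrow(ds$ground_truth), k)
  expect_equal(anyDuplicated(ds$ground_truth$source), 0L)
  expect_equal(anyDuplicated(ds$ground_truth$sink), 0L)
  expect_error(generate_network(layer_sizes = c(5L, 3L), classes = c("A", "B"),
                                properties = "p", out_degree = 2,
                                injective = TRUE, seed = 1), "injective")
})

test_that("generated ground truth equals the oracle on the generated graph", {
  for (seed in 1:5) {
    ds <- generate_network(layer_sizes = sample(2:6, 5, replace = TRUE),
                           classes = paste0("C", 1:5),
                           properties = paste0("p", 1:4),
                           out_degree = sample(1:3, 1),
                           distractor_fraction = 0.25, seed = seed)
    expect_equal(ds$ground_truth,
                 brute_force_associations(ds$graph, rrc_to_pcs(ds$chain)))
  }
})

test_that("distractors never change associations", {
  clean <- generate_network(layer_sizes = rep(5L, 7), out_degree = 2,
                            distractor_fraction = 0, seed = 9)
  noisy <- generate_network(layer_sizes = rep(5L, 7), out_degree = 2,
                            distractor_fraction = 0.3, seed = 9)
  expect_gt(nrow(noisy$graph), nrow(clean$graph))
  expect_identical(clean$ground_truth, noisy$ground_truth)
  expect_equal(pairs_of(efficient_reason(noisy$graph, noisy$chain)),
               noisy$ground_truth)
})

test_that("scaling replicates disjointly: counts scale, iterations do not", {
  base <- generate_network(layer_sizes = rep(4L, 7), out_degree = 1,
                           distractor_fraction = 0, injective = TRUE, seed = 5)
  expect_identical(scale_dataset(base, 1), base)
  doubled <- scale_dataset(base, 2)
  expect_equal(nrow(doubled$ground_truth), 2L * nrow(base$ground_truth))
  expect_equal(nrow(doubled$graph), 2L * nrow(base$graph))
  expect_equal(doubled$ground_truth,
               brute_force_associations(doubled$graph,
                                        rrc_to_pcs(doubled$chain)))
  tripled <- scale_dataset(small_cfg(), 3)
  expect_equal(tripled$ground_truth,
               brute_force_associations(tripled$graph,
                                        rrc_to_pcs(tripled$chain)))
  expect_equal(efficient_reason(tripled$graph, tripled$chain)$iterations,
               efficient_reason(small_cfg()$graph, small_cfg()$chain)$iterations)
  expect_error(scale_dataset(base, 0), "positive")
})

test_that("datasets write as N-Triples plus ground-truth TSV and chain config", {
  dir <- withr::local_tempdir()
  ds <- small_cfg()
  paths <- write_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  g <- read_ntriples(paths[["graph"]])
  expect_equal(dplyr::arrange(g, subject, predicate, object),
               dplyr::arrange(ds$graph, subject, predicate, object))
  gt <- readr::read_tsv(paths[["ground_truth"]], col_types = "cc",
                        progress = FALSE)
  expect_equal(tibble::as_tibble(gt), ds$ground_truth)
  chains <- read_chain_config(paths[["chains"]])
  expect_equal(chains$properties[[1]], rrc_to_pcs(ds$chain))
})
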