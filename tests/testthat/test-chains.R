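test_that("rule chains validate sequential classes and build the PCS", {
  ch <- herb_gene_chain()
  pcs <- rrc_to_pcs(ch)
  expect_length(pcs, 6L)
  expect_equal(pcs[[1]], "treatment")
  expect_equal(pcs[[6]], "symbol")
  expect_length(rrc_to_pcs(rule_chain("A", "p", "B")), 1L)
  expect_error(rule_chain(c("A", "C"), c("p", "q"), c("B", "D")),
               "sequential")
  expect_error(rule_chain("A", "p|q", "B"), "may not contain")
  expect_error(rrc_to_pcs(character()), "non-empty")
})

test_that("PID assignment follows position, -1 for absent, all positions for repeats", {
  pcs <- rrc_to_pcs(herb_gene_chain())
  expect_identical(assign_pid("treatment", pcs), 0L)
  expect_identical(assign_pid("geneSequence", pcs), -1L)
  expect_identical(assign_pid("symbol", pcs), 5L)   # last OPC of the 6-chain
  expect_identical(assign_pid("p", "p"), 0L)
  expect_identical(assign_pid("p", c("p", "q", "p")), c(0L, 2L))
  # always in {-1} union [0, length - 1]
  for (pred in c(pcs, "absent")) {
    pid <- assign_pid(pred, pcs)
    expect_true(all(pid == -1L | (pid >= 0L & pid <= length(pcs) - 1L)))
  }
})

test_that("OPC composition concatenates components associatively", {
  ab <- opc_compose("treatment", "possibleDrug")
  expect_equal(opc_components(ab)[[1]], c("treatment", "possibleDrug"))
  left <- opc_compose(opc_compose("a", "b"), "c")
  right <- opc_compose("a", opc_compose("b", "c"))
  expect_identical(opc_components(left), opc_components(right))
  pcs <- rrc_to_pcs(herb_gene_chain())
  folded <- Reduce(opc_compose, pcs)
  expect_length(opc_components(folded)[[1]], 6L)
})

test_that("merge_first_two shortens by one and reaches length 1 inductively", {
  p5 <- paste0("P", 0:4)
  expect_equal(merge_first_two(p5), c("P0|P1", "P2", "P3", "P4"))
  expect_length(merge_first_two(c("a", "b")), 1L)
  expect_error(merge_first_two("a"), "length 1")
  for (n in 2:9) {
    pcs <- paste0("q", seq_len(n))
    steps <- 0L
    while (length(pcs) > 1L) {
      pcs <- merge_first_two(pcs)
      steps <- steps + 1L
    }
    expect_equal(steps, n - 1L)
    expect_length(opc_components(pcs)[[1]], n)
  }
})

test_that("halve_pcs merges adjacent pairs, carries odd tails, halves in log steps", {
  p6 <- paste0("P", 0:5)
  expect_equal(halve_pcs(p6), c("P0|P1", "P2|P3", "P4|P5"))
  expect_equal(halve_pcs(c("A", "B", "C")), c("A|B", "C"))
  expect_equal(halve_pcs(c("A", "B")), "A|B")
  expect_error(halve_pcs("A"), "length 1")
  for (n in 2:10) {
    pcs <- paste0("q", seq_len(n))
    expect_length(halve_pcs(pcs), ceiling(n / 2))
    steps <- 0L
    while (length(pcs) > 1L) {
      pcs <- halve_pcs(pcs)
      steps <- steps + 1L
    }
    expect_equal(steps, ceiling(log2(n)))
    # no component ever reordered or dropped
    expect_equal(opc_components(pcs)[[1]], paste0("q", seq_len(n)))
  }
})

test_that("chain configs round-trip through YAML with validation", {
  path <- system.file("extdata", "chains_two.yaml", package = "chainreasoner")
  chains <- read_chain_config(path)
  expect_equal(chains$chain_id, c("herb_gene", "herb_ingredient"))
  expect_equal(chains$properties[[2]],
               c("treatment", "possibleDrug", "hasIngredient"))
  tmp <- withr::local_tempfile(fileext = ".yaml")
  chainreasoner:::write_chain_config(chains, tmp)
  expect_equal(read_chain_config(tmp), chains)

  dup <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(chains = list(
    list(id = "c", source_class = "A", sink_class = "B", properties = list("p")),
    list(id = "c", source_class = "A", sink_class = "B", properties = list("q"))
  )), dup)
  expect_error(read_chain_config(dup), "unique")
})
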