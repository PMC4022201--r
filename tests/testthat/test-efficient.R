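pcs0 <- rrc_to_pcs(herb_gene_chain())

test_that("parity join keys follow the odd/even rule", {
  # odd PID 1 keys on (0, subject)
  k1 <- parity_join_key(1L, "Disease_0", "Drug_0", 6L)
  expect_equal(parse_join_key(k1)[c("pid", "resource")],
               list(pid = 0L, resource = "Disease_0"))
  # even PID 0 keys on (0, object): same group as its odd partner
  k0 <- parity_join_key(0L, "Herb_0", "Disease_0", 6L)
  expect_equal(k0, k1)
  # even PID 2 keys on (2, object)
  k2 <- parity_join_key(2L, "Drug_0", "Target_0", 6L)
  expect_equal(parse_join_key(k2)[c("pid", "resource")],
               list(pid = 2L, resource = "Target_0"))
  # unpaired last even position of an odd-length PCS has no key
  expect_true(is.na(parity_join_key(2L, "Protein_0", "Gene_0", 3L)))
  expect_error(parity_join_key(-1L, "a", "b", 6L), "negative")
})

test_that("parity map keys all joinable triples and drops irrelevant ones", {
  mapped <- efficient_map(fixture_g0(), pcs0)
  expect_false("geneSequence" %in% mapped$predicate)
  expect_equal(nrow(mapped), 7L)              # all of T0..T6 keyed
  expect_true(all(!is.na(mapped$key)))        # even length: nothing unpaired
  # 6-chain positions partition into ceiling(6/2) = 3 parity pair-groups
  expect_equal(length(unique(mapped$key)), 3L)

  # odd-length PCS: the lone last OPC is passed through
  pcs1 <- halve_pcs(pcs0)
  g1 <- triple_graph("Protein_0", "classifiedWith|symbol", "Gene_0")
  m1 <- efficient_map(g1, pcs1)
  expect_true(is.na(m1$key))
})

test_that("parity reduce joins one even position with its odd successor", {
  key <- join_key(0L, "Disease_0")
  grp <- tibble::tibble(
    subject = c("Herb_0", "Herb_1", "Disease_0"),
    predicate = c("treatment", "treatment", "possibleDrug"),
    object = c("Disease_0", "Disease_0", "Drug_0"),
    pid = c(0L, 0L, 1L), chain_id = "")
  out <- efficient_reduce(key, grp, pcs0)
  expect_setequal(out$subject, c("Herb_0", "Herb_1"))
  expect_equal(unique(out$predicate), "treatment|possibleDrug")
  expect_equal(unique(out$object), "Drug_0")

  expect_equal(nrow(efficient_reduce(key, grp[grp$pid == 1L, ], pcs0)), 0L)

  grp2 <- tibble::tibble(subject = c("a", "b", "m", "m"),
                         predicate = "x", object = c("m", "m", "u", "v"),
                         pid = c(2L, 2L, 3L, 3L), chain_id = "")
  expect_equal(nrow(efficient_reduce(join_key(2L, "m"), grp2, pcs0)), 4L)
  bad <- dplyr::mutate(grp2, pid = c(2L, 2L, 5L, 3L))
  expect_error(efficient_reduce(join_key(2L, "m"), bad, pcs0), "outside")
})

test_that("parity reasoning reproduces the worked example pass by pass", {
  # first pass over the printed graph derives exactly the four composed
  # triples and leaves nothing in passthrough
  job <- run_job(fixture_g0(),
                 function(df) efficient_map(df, pcs0),
                 function(k, grp) efficient_reduce(k, grp, pcs0))
  expect_equal(job$n_groups, 3L)
  derived <- job$reduced[c("subject", "predicate", "object")]
  expect_equal(
    dplyr::arrange(derived, subject, predicate),
    dplyr::arrange(triple_graph(
      subject = c("Herb_0", "Herb_1", "Drug_0", "Protein_0"),
      predicate = c("treatment|possibleDrug", "treatment|possibleDrug",
                    "hasTarget|hasAccession", "classifiedWith|symbol"),
      object = c("Drug_0", "Drug_0", "Protein_0", "Gene_0")),
      subject, predicate))
  expect_equal(nrow(job$passthrough), 0L)

  res <- efficient_reason(fixture_g0(), herb_gene_chain())
  expect_equal(res$iterations, 3L)
  expect_equal(res$trace$derived, c(4L, 2L, 2L))
  expect_equal(pairs_of(res),
               tibble::tibble(source = c("Herb_0", "Herb_1"),
                              sink = c("Gene_0", "Gene_0")))
})

test_that("parity iteration count is ceiling(log2 N) regardless of content", {
  for (n in 1:10) {
    pcs <- paste0("p", seq_len(n))
    want <- if (n >= 2) ceiling(log2(n)) else 0L
    expect_equal(efficient_reason(triple_graph(), pcs)$iterations, want)
    expect_equal(efficient_reason(random_messy_graph(100 + n), pcs)$iterations,
                 want)
  }
  expect_equal(efficient_reason(triple_graph("a", "p", "b"),
                                c("p", "q"))$iterations, 1L)
})

test_that("naive, parity and oracle agree on messy graphs incl. repeated properties", {
  chains <- list(c("p", "q"), c("p", "q", "r"), c("p", "p"),
                 c("p", "q", "p", "r"), c("q", "q", "q"))
  for (seed in 1:6) {
    g <- random_messy_graph(seed)
    for (chain in chains) {
      want <- pairs_of(brute_force_associations(g, chain))
      expect_equal(pairs_of(naive_reason(g, chain)), want)
      expect_equal(pairs_of(efficient_reason(g, chain)), want)
    }
  }
})
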