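make_series <- function(id, values, potency = seq_along(values),
                        key = "*c1ccccc1", target = "T", doc = id) {
  analogue_series(id, target, doc, key, values, potency)
}

test_that("a target extending the query by one member ranks first with a
           single transfer value", {
  q <- make_series("Q", c("*C", "*CC", "*O"))
  ext <- make_series("E", c("*C", "*CC", "*O", "*Br"))
  other <- make_series("X", c("*F", "*Cl", "*N", "*I"))
  hits <- transfer_search(q, list(other, ext), identity_sim, k_min = 1L)
  expect_equal(hits[[1L]]$target_series_id, "E")
  expect_equal(hits[[1L]]$alignment$normalized_score, 1.0)
  expect_equal(hits[[1L]]$transfer_values, "*Br")
  expect_equal(hits[[1L]]$proposed_smiles,
               canonical_smiles("Brc1ccccc1"))
})

test_that("the length window and self-exclusion filter candidates", {
  q <- make_series("Q", c("*C", "*CC", "*O"))
  same_len <- make_series("S", c("*C", "*CC", "*O"))
  long5 <- make_series("L", c("*C", "*CC", "*O", "*Br", "*I"))
  db <- list(q, same_len, long5)
  hits <- transfer_search(q, db, identity_sim, k_min = 1L)
  expect_setequal(vapply(hits, `[[`, "", "target_series_id"), "L")
  hits0 <- transfer_search(q, db, identity_sim, k_min = 0L)
  expect_setequal(vapply(hits0, `[[`, "", "target_series_id"), c("S", "L"))
  expect_message(
    expect_length(transfer_search(q, db, identity_sim, k_min = 3L), 0L),
    "no candidate")
})

test_that("the planted partner is the top hit on a noisy fixture", {
  fx <- generate_compound_table(fixture_spec(n_decoys = 10L, seed = 21L))
  series <- build_series(fx$compounds)
  docs <- vapply(series, function(s) s$document_id, character(1))
  pt <- fx$ground_truth$partners
  qi <- match(paste0("DOC_", pt$query_series[1L]), docs)
  sim <- sim_from_matrix(build_similarity_matrix(
    unique(unlist(lapply(series, `[[`, "values"))), "cfr"))
  hits <- transfer_search(series[[qi]], series, sim, k_min = 1L, top_n = 3L)
  top_doc <- docs[match(hits[[1L]]$target_series_id,
                        vapply(series, `[[`, "", "series_id"))]
  expect_equal(top_doc, paste0("DOC_", pt$partner_series[1L]))
})

test_that("proposed analogues reattach correctly and never duplicate query
           members", {
  cuts <- enumerate_single_cuts("CCOc1ccc(-c2ccccc2)cc1")
  for (i in seq_len(nrow(cuts))) {
    rebuilt <- propose_transfer_analogues(cuts$key_smiles[i],
                                          cuts$value_smiles[i])
    expect_equal(rebuilt, canonical_smiles("CCOc1ccc(-c2ccccc2)cc1"))
  }
  # a transfer value equal to an existing member is dropped
  out <- propose_transfer_analogues("*c1ccccc1", c("*C", "*CC"),
                                    existing_values = "*C")
  expect_equal(out, canonical_smiles("CCc1ccccc1"))
  expect_length(propose_transfer_analogues("*c1ccccc1", "*C",
                                           existing_values = "*C"), 0L)
})

test_that("bioisostere counting matches planted alignments", {
  cooh <- canonical_smiles("*C(=O)O")
  tetra <- canonical_smiles("*c1nnn[nH]1")
  q <- make_series("Q", c("*C", "*CC", cooh))
  # target aligning tetrazole at the query's terminal position
  hit_t <- make_series("H1", c("*C", "*CC", tetra))
  # target whose transfer value is a bioisostere
  hit_x <- make_series("H2", c("*C", "*CC", "*O", tetra))
  miss <- make_series("M", c("*F", "*Cl", "*Br"))
  db <- list(hit_t, hit_x, miss)
  st <- bioisostere_alignment_stats(list(q), db, identity_sim,
                                    bioisostere_list = tetra,
                                    terminal_value_smiles = cooh)
  expect_equal(unname(st$counts), 2L)
  expect_equal(unname(st$histogram[["2"]]), 1L)
  expect_equal(sum(st$histogram), 1L)
  # empty bioisostere list counts nothing
  st0 <- bioisostere_alignment_stats(list(q), db, identity_sim,
                                     bioisostere_list = character(0),
                                     terminal_value_smiles = cooh)
  expect_equal(unname(st0$counts), 0L)
  # terminal mismatch is an input error naming the series
  bad <- make_series("BAD", c("*C", "*CC", "*O"))
  expect_error(
    bioisostere_alignment_stats(list(bad), db, identity_sim, tetra, cooh),
    "BAD")
})

test_that("the series exclusion helper removes qualifying series", {
  cooh <- canonical_smiles("*C(=O)O")
  with_c <- make_series("A", c("*C", "*CC", cooh))
  without <- make_series("B", c("*C", "*CC", "*O"))
  kept <- exclude_series_with_values(list(with_c, without), cooh)
  expect_length(kept, 1L)
  expect_equal(kept[[1L]]$series_id, "B")
})

test_that("the curated carboxyl bioisostere list loads 13 canonical entries", {
  bl <- carboxyl_bioisosteres()
  expect_length(bl, 13L)
  expect_true(all(nzchar(bl)))
  expect_equal(unname(canonical_smiles(bl)), unname(bl))
  expect_true("tetrazole" %in% names(bl))
})
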