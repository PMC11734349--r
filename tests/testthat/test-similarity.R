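test_that("MQN vectors have 42 non-negative integer-valued dimensions", {
  frags <- c("*C", "*CC", "*c1ccccc1", "*C(=O)O", "*S(N)(=O)=O",
             "*c1ccc2ccccc2c1", "*C1CCCCC1", "*[N+](=O)[O-]")
  for (f in frags) {
    v <- mqn_descriptors(f)
    expect_length(v, 42L)
    expect_true(all(v >= 0))
    expect_true(all(v == round(v)))
  }
  m <- mqn_descriptors(frags)
  expect_equal(dim(m), c(length(frags), 42L))
})

test_that("MQN counts for simple capped fragments match hand counting", {
  # methyl capped to methane: one carbon, one heavy atom, nothing else
  v <- mqn_descriptors("*C")
  expect_equal(unname(v[c("c", "hac")]), c(1, 1))
  expect_equal(sum(v), 2)
  # ethyl capped to ethane: 2 C, 1 acyclic single bond, 2 monovalent nodes
  v <- mqn_descriptors("*CC")
  expect_equal(unname(v[c("c", "hac", "asb", "asv")]), c(2, 2, 1, 2))
  # phenyl capped to benzene: 6 cyclic carbons, ring of 6
  v <- mqn_descriptors("*c1ccccc1")
  expect_equal(unname(v[c("c", "hac", "csb", "cdb", "r6", "cdv")]),
               c(6, 6, 3, 3, 1, 6))
  # carboxyl: 2 O acceptors (4 sites), 1 donor
  v <- mqn_descriptors("*C(=O)O")
  expect_equal(unname(v[c("ao", "hba", "hbam", "hbd", "hbdm")]),
               c(2, 2, 4, 1, 1))
})

test_that("MQN similarity follows its closed form and bounds", {
  a <- rep(0, 42)
  expect_equal(mqn_similarity(a, a), 1)
  b <- a; b[1] <- 42                 # mean |diff| = 1
  expect_equal(mqn_similarity(a, b), 0.5)
  b <- a; b[1] <- 21                 # mean |diff| = 0.5
  expect_equal(mqn_similarity(a, b), 2 / 3)
  expect_error(mqn_similarity(rep(0, 41), a), "42")
  # strictly decreasing in the mean absolute difference
  sims <- vapply(0:10, function(k) {
    b <- a; b[1] <- k; mqn_similarity(a, b)
  }, numeric(1))
  expect_true(all(diff(sims) < 0))
  expect_true(all(sims > 0 & sims <= 1))
})

test_that("Tanimoto follows set arithmetic with the empty-set convention", {
  expect_equal(tanimoto(c(1, 5, 9), c(1, 5, 9)), 1)
  expect_equal(tanimoto(c(1, 2), c(3, 4)), 0)
  expect_equal(tanimoto(c(1, 2, 3), c(2, 3, 9, 10)), 0.4)  # 2 / 5
  expect_equal(tanimoto(integer(0), integer(0)), 1)
  expect_equal(tanimoto(integer(0), c(1)), 0)
})

test_that("Morgan fingerprints are deterministic, bounded and kekulisation-stable", {
  fp1 <- morgan_fp("*c1ccccc1")
  expect_true(all(fp1 >= 0 & fp1 < 1024))
  expect_identical(fp1, morgan_fp("*c1ccccc1"))
  # same fragment entered with different atom order / kekulisation
  expect_identical(morgan_fp("*c1ccccc1"), morgan_fp("C1=CC=CC(=C1)*"))
  # different radius changes the bit set for a structured fragment
  expect_false(identical(morgan_fp("*CCO", radius = 0L),
                         morgan_fp("*CCO", radius = 2L)))
})

test_that("CFR similarity of methyl vs ethyl equals the hand-derived value", {
  # capped structures are methane and ethane. MQN difference: c 1, hac 1,
  # asb 1, asv 2 -> sum 5, similarity 1/(1 + 5/42) = 42/47. The Morgan bit
  # sets are disjoint (different atom environments), Tanimoto 0.
  expect_equal(mqn_similarity(mqn_descriptors("*C"), mqn_descriptors("*CC")),
               42 / 47)
  expect_equal(tanimoto(morgan_fp("*C"), morgan_fp("*CC")), 0)
  expect_equal(cfr_similarity("*C", "*CC"), 21 / 47)
})

test_that("CFR similarity is symmetric with unit self-similarity", {
  frags <- c("*C", "*CC", "*O", "*Cl", "*c1ccccc1", "*C(=O)O", "*C#N",
             "*C(F)(F)F", "*N", "*OC")
  for (f in frags) expect_equal(cfr_similarity(f, f), 1)
  for (i in 1:5) {
    p <- sample(frags, 2L)
    expect_equal(cfr_similarity(p[1L], p[2L]), cfr_similarity(p[2L], p[1L]))
  }
})

test_that("similarity matrices are symmetric with unit diagonal and match
           pairwise calls", {
  frags <- c("*C", "*CC", "*O", "*Cl", "*C#N")
  m <- build_similarity_matrix(frags, "cfr")
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 5L))
  expect_equal(rownames(m), frags)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(m[i, j], cfr_similarity(frags[i], frags[j]))
  }
  expect_equal(unname(build_similarity_matrix("*C", "cfr")),
               matrix(1, 1, 1))
  expect_error(build_similarity_matrix(c("*C", "*C"), "cfr"), "unique")
})

test_that("matrix construction is order-independent up to label permutation", {
  frags <- c("*C", "*CC", "*O", "*Cl", "*C#N")
  m1 <- build_similarity_matrix(frags, "cfr")
  perm <- c(3L, 1L, 5L, 2L, 4L)
  m2 <- build_similarity_matrix(frags[perm], "cfr")
  expect_equal(m2, m1[perm, perm])
})

test_that("EFV similarity matrices come from vector cosines", {
  vecs <- matrix(c(1, 0, 0, 1, 1, 1, -1, 0), 4L, 2L, byrow = TRUE,
                 dimnames = list(c("a", "b", "c", "d"), NULL))
  m <- build_similarity_matrix(c("a", "b", "c", "d"), "efv",
                               model = toy_model(vecs))
  expect_equal(m["a", "b"], 0)
  expect_equal(m["a", "c"], 1 / sqrt(2))
  expect_equal(m["a", "d"], -1)
  expect_error(build_similarity_matrix(c("a", "zz"), "efv",
                                       model = toy_model(vecs)), "zz")
  expect_error(build_similarity_matrix(c("a", "b"), "efv"), "model")
})

test_that("similarity matrices survive the TSV round trip", {
  frags <- c("*C", "*CC", "*O")
  m <- build_similarity_matrix(frags, "cfr")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_similarity_tsv(m, path)
  expect_equal(read_similarity_tsv(path), m)
})

test_that("a matrix-backed similarity function looks up pairs and errors on
           unknown labels", {
  m <- build_similarity_matrix(c("*C", "*CC"), "cfr")
  sim <- sim_from_matrix(m)
  expect_equal(sim("*C", "*CC"), m["*C", "*CC"])
  expect_equal(sim(c("*C", "*CC"), c("*CC", "*CC")),
               c(m["*C", "*CC"], 1))
  expect_error(sim("*O", "*C"), "\\*O")
})
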