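tiny_corpus <- list(c("*C", "*CC", "*Cl"), c("*C", "*O", "*Cl"),
                    c("*CC", "*O", "*Cl", "*Br"),
                    c("*O", "*Cl", "*Br"), c("*C", "*CC", "*O", "*Br"))

test_that("training honours the vocabulary and dimension contracts", {
  m <- train_efv(tiny_corpus, vector_size = 24L, epochs = 2L)
  expect_s3_class(m, "efv_model")
  expect_length(m$vocabulary, 5L)           # min_count 1 keeps every token
  expect_equal(dim(m$vectors), c(5L, 24L))
  expect_equal(rownames(m$vectors), m$vocabulary)
  # frequency-descending vocabulary order
  expect_false(is.unsorted(rev(m$counts)))
  # min_count drops rare tokens (*Br and *C occur 3 times, *Cl and *O four)
  m2 <- train_efv(tiny_corpus, vector_size = 8L, min_count = 4L, epochs = 1L)
  expect_true(all(m2$counts >= 4L))
  expect_setequal(m2$vocabulary, c("*Cl", "*O"))
})

test_that("training is bit-reproducible for a fixed seed", {
  m1 <- train_efv(tiny_corpus, vector_size = 32L, seed = 8L)
  m2 <- train_efv(tiny_corpus, vector_size = 32L, seed = 8L)
  expect_identical(m1$vectors, m2$vectors)
  m3 <- train_efv(tiny_corpus, vector_size = 32L, seed = 9L)
  expect_false(identical(m1$vectors, m3$vectors))
})

test_that("degenerate corpora raise input errors", {
  expect_error(train_efv(list()), "empty")
  expect_error(train_efv(tiny_corpus, vector_size = 0L), "vector_size")
  expect_error(train_efv(list(character(0))), "tokens")
})

test_that("cosine similarity obeys its closed forms and contracts", {
  a <- c(1, 2, 3)
  expect_equal(efv_cosine(a, a), 1)
  expect_equal(efv_cosine(c(1, 0), c(0, 1)), 0)
  expect_equal(efv_cosine(a, -a), -1)
  expect_error(efv_cosine(a, c(1, 2)), "length")
  expect_error(efv_cosine(a, c(0, 0, 0)), "zero-norm")
})

test_that("nearest-neighbour ranking matches brute force on hand-set vectors", {
  vecs <- matrix(c(1, 0,
                   0.9, 0.1,
                   0, 1,
                   -1, 0), 4L, 2L, byrow = TRUE,
                 dimnames = list(c("q", "near", "mid", "far"), NULL))
  m <- toy_model(vecs)
  r <- similar_fragments(m, "q", k = 3L)
  brute <- sort(vapply(c("near", "mid", "far"), function(t)
    efv_cosine(vecs["q", ], vecs[t, ]), numeric(1)), decreasing = TRUE)
  expect_equal(r$fragment, names(brute))
  expect_equal(r$score, unname(brute))
  expect_false("q" %in% r$fragment)
  expect_true(all(diff(r$score) <= 0))
  expect_error(similar_fragments(m, "absent"), "absent")
})

test_that("analogy ranking equals exhaustive cosine computation on a toy model", {
  set.seed(2)
  vecs <- matrix(rnorm(6L * 4L), 6L, 4L,
                 dimnames = list(paste0("t", 1:6), NULL))
  m <- toy_model(vecs)
  r <- analogy_query(m, "t1", "t2", "t3", k = 6L)
  target <- (vecs["t1", ] - vecs["t2", ]) + vecs["t3", ]
  brute <- sort(vapply(rownames(vecs), function(t)
    efv_cosine(target, vecs[t, ]), numeric(1)), decreasing = TRUE)
  expect_equal(r$fragment, names(brute))
  expect_equal(r$score, unname(brute), tolerance = 1e-12)
  expect_equal(r$rank, 1:6)
})

test_that("an analogy with a = b reduces to similarity search around c", {
  m <- train_efv(tiny_corpus, vector_size = 16L, epochs = 3L)
  r <- analogy_query(m, "*C", "*C", "*O", k = 3L)
  expect_equal(r$fragment[1L], "*O")
  expect_equal(r$score[1L], 1.0, tolerance = 1e-9)
  rs <- similar_fragments(m, "*O", k = 2L)
  expect_equal(r$fragment[2:3], rs$fragment[1:2])
})

test_that("tokens sharing contexts embed closer than unrelated tokens", {
  ranks_ok <- 0L
  n_seeds <- 10L
  cos_xy <- cos_xz <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    gen <- generate_analogy_corpus(n_sentences = 200L,
                                   n_filler_sentences = 40L, seed = 400L + s)
    m <- train_efv(gen$corpus, vector_size = 32L, epochs = 5L, seed = s)
    x <- gen$interchangeable$x[1L]; y <- gen$interchangeable$y[1L]
    z <- gen$unrelated[1L]
    cos_xy[s] <- efv_cosine(m$vectors[x, ], m$vectors[y, ])
    cos_xz[s] <- efv_cosine(m$vectors[x, ], m$vectors[z, ])
  }
  expect_gt(stats::median(cos_xy), stats::median(cos_xz))
})

test_that("planted analogy completions rank highly across seeds", {
  n_seeds <- 10L
  top_frac <- integer(n_seeds)
  for (s in seq_len(n_seeds)) {
    gen <- generate_analogy_corpus(n_sentences = 300L,
                                   n_filler_sentences = 40L, seed = 500L + s)
    m <- train_efv(gen$corpus, vector_size = 32L, epochs = 5L, seed = s)
    q <- gen$quadruples[1L, ]
    r <- analogy_query(m, q$a, q$b, q$c, k = length(m$vocabulary))
    pos <- r$rank[r$fragment == q$expected]
    cutoff <- max(2L, ceiling(0.05 * length(m$vocabulary)))
    top_frac[s] <- as.integer(pos <= cutoff)
  }
  expect_gt(mean(top_frac), 0.5)
})

test_that("models survive the word2vec text round trip", {
  m <- train_efv(tiny_corpus, vector_size = 12L, epochs = 2L)
  path <- withr::local_tempfile(fileext = ".w2v")
  write_word2vec(m, path)
  back <- read_word2vec(path)
  expect_equal(back$vocabulary, m$vocabulary)
  expect_equal(back$vectors, m$vectors, tolerance = 1e-15)
  hdr <- strsplit(readLines(path, n = 1L), " ")[[1L]]
  expect_equal(as.integer(hdr), c(5L, 12L))
  cfg <- withr::local_tempfile(fileext = ".json")
  write_model_config(m, cfg)
  expect_equal(jsonlite::fromJSON(cfg)$vector_size, 12L)
})
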