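test_that("self-alignment under unit self-similarity is perfect", {
  s <- c("*C", "*CC", "*O", "*Cl", "*Br")
  a <- align_series(s, s, identity_sim)
  expect_equal(a$raw_score, 5)
  expect_equal(a$normalized_score, 1.0)
  expect_equal(a$columns$query_index, 1:5)
  expect_equal(a$columns$target_index, 1:5)
  expect_equal(a$per_column_similarity, rep(1, 5))
})

test_that("the 2x2 example picks the two compatible matches", {
  S <- matrix(c(0.6, 0.2, 0.3, 0.9), 2L, 2L, byrow = TRUE,
              dimnames = list(c("X", "Y"), c("U", "V")))
  sim <- function(q, t) S[cbind(q, t)]
  a <- align_series(c("X", "Y"), c("U", "V"), sim)
  expect_equal(a$raw_score, 1.5)     # X-U (0.6) + Y-V (0.9)
  expect_equal(a$normalized_score, 0.75)
  expect_equal(a$per_column_similarity, c(0.6, 0.9))
})

test_that("a query contained in a longer target scores 1 with one gap", {
  a <- align_series(c("A", "B", "C"), c("A", "B", "C", "D"), identity_sim)
  expect_equal(a$raw_score, 3)
  expect_equal(a$normalized_score, 1.0)
  last <- a$columns[nrow(a$columns), ]
  expect_true(is.na(last$query_index) && last$target_index == 4L)
})

test_that("raw scores equal the exhaustive-enumeration maximum", {
  set.seed(7)
  for (rep in 1:60) {
    n <- sample(1:6, 1L); m <- sample(1:6, 1L)
    S <- matrix(runif(n * m), n, m)
    q <- paste0("q", 1:n); t <- paste0("t", 1:m)
    dimnames(S) <- list(q, t)
    a <- align_series(q, t, function(x, y) S[cbind(x, y)])
    expect_equal(a$raw_score, brute_force_alignment_score(S),
                 tolerance = 1e-12)
  }
})

test_that("scores are bounded and symmetric for similarities in [0,1]", {
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(2:6, 1L); m <- sample(2:6, 1L)
    S <- matrix(runif(n * m), n, m,
                dimnames = list(paste0("q", 1:n), paste0("t", 1:m)))
    sim <- function(x, y) S[cbind(x, y)]
    simT <- function(x, y) t(S)[cbind(x, y)]
    a <- align_series(rownames(S), colnames(S), sim)
    b <- align_series(colnames(S), rownames(S), simT)
    expect_gte(a$raw_score, 0)
    expect_lte(a$raw_score, min(n, m) + 1e-12)
    expect_gte(a$normalized_score, 0)
    expect_lte(a$normalized_score, 1 + 1e-12)
    expect_equal(a$raw_score, b$raw_score)
    # matched pairs strictly increasing in both indices
    mt <- a$columns[!is.na(a$columns$query_index) &
                      !is.na(a$columns$target_index), ]
    expect_true(all(diff(mt$query_index) > 0))
    expect_true(all(diff(mt$target_index) > 0))
    # raw score decomposes over matched columns
    expect_equal(a$raw_score, sum(a$per_column_similarity))
  }
})

test_that("raising a similarity never lowers the raw score", {
  set.seed(9)
  S <- matrix(runif(20), 4L, 5L,
              dimnames = list(paste0("q", 1:4), paste0("t", 1:5)))
  base <- align_series(rownames(S), colnames(S),
                       function(x, y) S[cbind(x, y)])$raw_score
  for (rep in 1:10) {
    S2 <- S
    i <- sample(4L, 1L); j <- sample(5L, 1L)
    S2[i, j] <- min(1, S2[i, j] + runif(1, 0, 0.5))
    up <- align_series(rownames(S2), colnames(S2),
                       function(x, y) S2[cbind(x, y)])$raw_score
    expect_gte(up, base - 1e-12)
  }
})

test_that("normalisation mode and clamping behave as configured", {
  S <- matrix(c(1, -0.5, -0.5, 1), 2L, 2L,
              dimnames = list(c("a", "b"), c("a", "b")))
  sim <- function(x, y) S[cbind(x, y)]
  a <- align_series(c("a", "b"), c("a", "b"), sim)
  expect_equal(a$raw_score, 2)
  expect_equal(align_series(c("a", "b"), c("a", "b", "zz"),
                            function(x, y) ifelse(x == y, 1, 0),
                            normalize = "max")$normalized_score, 2 / 3)
  # negative similarities pass through unless clamped
  neg <- align_series("a", "b", sim)
  expect_equal(neg$raw_score, 0)   # gap-only path beats the -0.5 match
  clamped <- align_series(c("b", "a"), c("a", "b"), sim, clamp = TRUE)
  expect_true(all(clamped$per_column_similarity >= 0))
})

test_that("non-finite similarities are rejected naming the pair", {
  bad <- function(q, t) ifelse(q == "q2" & t == "t1", NaN, 0.5)
  expect_error(align_series(c("q1", "q2"), c("t1", "t2"), bad), "q2.*t1")
})

test_that("the text rendering marks matches, mismatches and gaps", {
  a <- align_series(c("A", "B", "C"), c("A", "B", "C", "D"), identity_sim)
  txt <- alignment_to_text(a)
  expect_length(txt, 3L)
  expect_match(txt[2L], "\\| \\| \\| -")
  self <- alignment_to_text(align_series(c("A", "B"), c("A", "B"),
                                         identity_sim))
  expect_match(self[2L], "^\\s*\\| \\|\\s*$")
  s1 <- analogue_series("s1", "T", "D", "*c1ccccc1", c("*C", "*O"), c(5, 6))
  withpot <- align_series(s1, s1, identity_sim)
  expect_length(alignment_to_text(withpot), 5L)
  expect_output(print(withpot), "normalized")
})
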