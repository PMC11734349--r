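# Embedded fragment vectors: a continuous-bag-of-words word2vec model
# trained on analogue series treated as sentences of substituent tokens
# ordered by ascending potency. After training, each vocabulary token's row
# of the input weight matrix is its embedded fragment vector (EFV).

#' Corpus of substituent sentences from analogue series
#'
#' @param series list of [analogue_series()] objects.
#' @return list of character vectors (one potency-ascending token sequence
#'   per series), usable as the `corpus` of [train_efv()].
#' @export
series_corpus <- function(series) {
  lapply(series, function(s) s$values)
}

#' Train an embedded-fragment-vector model
#'
#' Trains a CBOW word2vec model over a corpus of token sequences. The
#' projection input is the mean of the context tokens' input vectors; the
#' learned input weight matrix (vocabulary x `vector_size`) holds the EFVs.
#' Training is single-threaded with an internal seeded generator, so a fixed
#' `seed` reproduces the embedding matrix bit for bit. Defaults follow the
#' usual word2vec settings: `vector_size` 100, `window` 5 (with dynamic
#' window shrinkage), `min_count` 1, `seed` 8, negative sampling with 5
#' noise words, 5 epochs, learning rate decaying linearly from 0.025 to
#' 1e-4. Sentences shorter than the window simply yield truncated contexts.
#'
#' @param corpus list of character vectors of fragment tokens (sentences);
#'   see [series_corpus()].
#' @param vector_size embedding dimension k (default 100).
#' @param window maximum one-sided context width (default 5).
#' @param min_count minimum corpus frequency for a token to enter the
#'   vocabulary (default 1).
#' @param seed integer seed for initialisation, window shrinkage and
#'   negative sampling (default 8).
#' @param negative number of negative samples per target (default 5).
#' @param epochs passes over the corpus (default 5).
#' @param alpha,alpha_min initial and floor learning rates.
#' @return object of class `efv_model`: `vocabulary` (tokens ordered by
#'   decreasing frequency, ties lexicographic), `vectors` (one EFV per row),
#'   `counts`, and `params` (all resolved hyperparameters).
#' @examples
#' m <- train_efv(list(c("*C", "*CC", "*Cl"), c("*C", "*O", "*Cl")),
#'                vector_size = 16, epochs = 2)
#' dim(m$vectors)
#' @export
train_efv <- function(corpus, vector_size = 100L, window = 5L, min_count = 1L,
                      seed = 8L, negative = 5L, epochs = 5L,
                      alpha = 0.025, alpha_min = 1e-4) {
  if (!length(corpus)) stop("corpus is empty", call. = FALSE)
  if (vector_size < 1L) stop("vector_size must be >= 1", call. = FALSE)
  stopifnot(is.list(corpus))
  tokens <- unlist(corpus, use.names = FALSE)
  if (!length(tokens)) stop("corpus has no tokens", call. = FALSE)
  tab <- table(tokens)
  freq <- as.integer(tab)
  names(freq) <- names(tab)
  freq <- freq[freq >= min_count]
  if (!length(freq)) stop("no token reaches min_count", call. = FALSE)
  # word2vec vocabulary order: frequency descending, ties lexicographic
  ord <- order(-freq, names(freq), method = "radix")
  vocab <- names(freq)[ord]
  counts <- unname(freq[ord])
  index <- stats::setNames(seq_along(vocab), vocab)
  sent_idx <- lapply(corpus, function(s) {
    ix <- index[s]
    as.integer(ix[!is.na(ix)]) - 1L
  })
  sent_idx <- sent_idx[lengths(sent_idx) > 0L]
  vecs <- cbow_train(sent_idx, counts, as.integer(vector_size),
                     as.integer(window), as.integer(negative),
                     as.integer(epochs), alpha, alpha_min, as.integer(seed))
  rownames(vecs) <- vocab
  structure(list(vocabulary = vocab, vectors = vecs, counts = counts,
                 params = list(vector_size = as.integer(vector_size),
                               window = as.integer(window),
                               min_count = as.integer(min_count),
                               architecture = "cbow",
                               seed = as.integer(seed),
                               workers = 1L,
                               negative = as.integer(negative),
                               epochs = as.integer(epochs),
                               alpha = alpha, alpha_min = alpha_min)),
            class = "efv_model")
}

#' @export
print.efv_model <- function(x, ...) {
  cat("EFV model (CBOW): vocabulary", length(x$vocabulary),
      "tokens, dimension", x$params$vector_size, "\n")
  cat("  window", x$params$window, "| min_count", x$params$min_count,
      "| seed", x$params$seed, "| negative", x$params$negative,
      "| epochs", x$params$epochs, "\n")
  invisible(x)
}

# EFV rows for tokens, with a lookup error naming the first missing token
efv_vectors <- function(model, tokens) {
  stopifnot(inherits(model, "efv_model"))
  ix <- match(tokens, model$vocabulary)
  if (anyNA(ix))
    stop("token not in model vocabulary: ", tokens[which(is.na(ix))[1L]],
         call. = FALSE)
  model$vectors[ix, , drop = FALSE]
}

#' Cosine similarity between two vectors
#'
#' `dot(a, b) / (||a|| ||b||)`, the EFV similarity measure; result in
#' `[-1, 1]`.
#'
#' @param a,b numeric vectors of equal length, neither all-zero.
#' @return cosine similarity.
#' @export
efv_cosine <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length", call. = FALSE)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero-norm vector", call. = FALSE)
  max(-1, min(1, sum(a * b) / (na * nb)))
}

rank_by_cosine <- function(model, target_vec) {
  v <- model$vectors
  nrm <- sqrt(rowSums(v^2))
  nrm[nrm == 0] <- NA_real_
  tv <- target_vec / sqrt(sum(target_vec^2))
  scores <- as.numeric(v %*% tv) / nrm
  scores[is.na(scores)] <- -Inf
  ord <- order(-scores, model$vocabulary, method = "radix")
  data.frame(fragment = model$vocabulary[ord], score = scores[ord],
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Most similar fragments to a query token
#'
#' Ranks the model vocabulary by cosine similarity of EFVs to the query's
#' EFV (the query itself is excluded) and returns the top `k`. Ties are
#' broken by token string for determinism.
#'
#' @param model an `efv_model`.
#' @param query_smiles token in the model vocabulary.
#' @param k number of neighbours (default 10).
#' @return data.frame `fragment`, `score` (non-increasing), `rank`.
#' @export
similar_fragments <- function(model, query_smiles, k = 10L) {
  stopifnot(k >= 1L)
  qv <- efv_vectors(model, query_smiles)[1L, ]
  r <- rank_by_cosine(model, qv)
  r <- r[r$fragment != query_smiles, , drop = FALSE]
  r$rank <- seq_len(nrow(r))
  utils::head(r, k)
}

#' Word-pair-relationship (analogy) query over fragment embeddings
#'
#' Ranks the whole vocabulary by cosine similarity to the composed vector
#' `(EFV(a) - EFV(b)) + EFV(c)`, the fragment analogue of word analogies
#' such as (Paris - France) + Italy = Rome. The input tokens are *not*
#' excluded from the ranking by default, so reported rank positions refer to
#' the full vocabulary; set `exclude_inputs = TRUE` to drop them.
#'
#' @param model an `efv_model`.
#' @param a_smiles,b_smiles,c_smiles vocabulary tokens forming the query
#'   `(a - b) + c`.
#' @param k number of top entries returned (default 10).
#' @param exclude_inputs drop a, b, c from the ranking (default `FALSE`).
#' @return data.frame `fragment`, `score`, `rank` (absolute positions over
#'   the full vocabulary ranking).
#' @export
analogy_query <- function(model, a_smiles, b_smiles, c_smiles, k = 10L,
                          exclude_inputs = FALSE) {
  stopifnot(k >= 1L)
  va <- efv_vectors(model, a_smiles)[1L, ]
  vb <- efv_vectors(model, b_smiles)[1L, ]
  vc <- efv_vectors(model, c_smiles)[1L, ]
  r <- rank_by_cosine(model, (va - vb) + vc)
  if (exclude_inputs) {
    r <- r[!(r$fragment %in% c(a_smiles, b_smiles, c_smiles)), , drop = FALSE]
  }
  utils::head(r, k)
}

#' Write / read a model in word2vec text format
#'
#' Header line `"<vocab> <dim>"`, then one line per token: the token followed
#' by its vector components. `read_word2vec` restores an `efv_model` (counts
#' and training parameters are not part of the format; parameters can be
#' sidecarred as JSON via `write_model_config`).
#'
#' @param model an `efv_model`.
#' @param path file path.
#' @export
write_word2vec <- function(model, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(length(model$vocabulary), model$params$vector_size), con)
  for (i in seq_along(model$vocabulary)) {
    writeLines(paste(model$vocabulary[i],
                     paste(formatC(model$vectors[i, ], format = "g", digits = 17),
                           collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_word2vec
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(lines[1L], " ", fixed = TRUE)[[1L]])
  n <- hdr[1L]; k <- hdr[2L]
  vocab <- character(n)
  vecs <- matrix(0, n, k)
  for (i in seq_len(n)) {
    tok <- strsplit(lines[i + 1L], " ", fixed = TRUE)[[1L]]
    vocab[i] <- tok[1L]
    vecs[i, ] <- as.numeric(tok[-1L])
  }
  rownames(vecs) <- vocab
  structure(list(vocabulary = vocab, vectors = vecs,
                 counts = rep(NA_integer_, n),
                 params = list(vector_size = k, architecture = "cbow")),
            class = "efv_model")
}

#' @rdname write_word2vec
#' @export
write_model_config <- function(model, path) {
  jsonlite::write_json(model$params, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
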