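# Conventional fragment representation (CFR) similarity: the arithmetic mean
# of Morgan-fingerprint Tanimoto and MQN descriptor similarity, combining a
# structural and a property view of small substituents.

#' CFR similarity between two fragments
#'
#' The mean of the Morgan fingerprint Tanimoto coefficient (radius 2, 1024
#' bits) and the MQN similarity of the two fragments; 1 for identical
#' fragments, bounded by `[0, 1]`.
#'
#' @param f1_smiles,f2_smiles fragment SMILES (one attachment point each).
#' @param radius,nbits fingerprint parameters, see [morgan_fp()].
#' @return similarity score in `[0, 1]`.
#' @examples
#' cfr_similarity("*C", "*CC")
#' @export
cfr_similarity <- function(f1_smiles, f2_smiles, radius = 2L, nbits = 1024L) {
  ft <- tanimoto(morgan_fp(f1_smiles, radius, nbits),
                 morgan_fp(f2_smiles, radius, nbits))
  fm <- mqn_similarity(mqn_descriptors(f1_smiles), mqn_descriptors(f2_smiles))
  (ft + fm) / 2
}

#' Global pairwise similarity matrix over a fragment set
#'
#' Builds the symmetric similarity matrix over a set of unique fragments,
#' either conventionally (`measure = "cfr"`, diagonal exactly 1) or from the
#' cosine similarity of embedded fragment vectors (`measure = "efv"`, values
#' in `[-1, 1]`; requires `model`).
#'
#' @param fragments character vector of unique fragment SMILES (the matrix
#'   label order).
#' @param measure `"cfr"` or `"efv"`.
#' @param model an [train_efv()] model, required for `measure = "efv"`; every
#'   fragment must be in its vocabulary.
#' @param radius,nbits fingerprint parameters for `measure = "cfr"`.
#' @return numeric matrix with `fragments` as row and column names.
#' @export
build_similarity_matrix <- function(fragments, measure = c("cfr", "efv"),
                                    model = NULL, radius = 2L, nbits = 1024L) {
  measure <- match.arg(measure)
  stopifnot(is.character(fragments), length(fragments) >= 1L)
  if (anyDuplicated(fragments))
    stop("fragments must be unique", call. = FALSE)
  n <- length(fragments)
  if (measure == "efv") {
    if (is.null(model)) stop("measure = 'efv' requires a model", call. = FALSE)
    vecs <- efv_vectors(model, fragments)
    nrm <- sqrt(rowSums(vecs^2))
    if (any(nrm == 0)) stop("zero-norm embedding vector", call. = FALSE)
    m <- tcrossprod(vecs / nrm)
    m[m > 1] <- 1; m[m < -1] <- -1
  } else {
    fps <- lapply(fragments, morgan_fp, radius = radius, nbits = nbits)
    mqs <- lapply(fragments, function(f) mqn_descriptors(f))
    m <- diag(1, n)
    if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      s <- (tanimoto(fps[[i]], fps[[j]]) +
              mqn_similarity(mqs[[i]], mqs[[j]])) / 2
      m[i, j] <- m[j, i] <- s
    }
  }
  dimnames(m) <- list(fragments, fragments)
  m
}

#' Similarity function backed by a precomputed matrix
#'
#' Wraps a labelled similarity matrix into the `function(q, t)` interface
#' used by [align_series()] and [transfer_search()]; unknown labels raise an
#' error naming the fragment.
#'
#' @param mat labelled square matrix from [build_similarity_matrix()].
#' @return a vectorised function of two fragment-SMILES arguments.
#' @export
sim_from_matrix <- function(mat) {
  labels <- rownames(mat)
  force(mat)
  function(q, t) {
    iq <- match(q, labels)
    it <- match(t, labels)
    if (anyNA(iq))
      stop("fragment not in similarity matrix: ", q[which(is.na(iq))[1L]],
           call. = FALSE)
    if (anyNA(it))
      stop("fragment not in similarity matrix: ", t[which(is.na(it))[1L]],
           call. = FALSE)
    mat[cbind(iq, it)]
  }
}

#' Write / read a similarity matrix as TSV
#'
#' Tab-separated with a header row and first column holding the fragment
#' SMILES labels.
#'
#' @param mat labelled square matrix.
#' @param path file path.
#' @export
write_similarity_tsv <- function(mat, path) {
  df <- data.frame(fragment = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_similarity_tsv
#' @export
read_similarity_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}
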