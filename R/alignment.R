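# Global alignment of two potency-ordered analogue series by dynamic
# programming over a substituent similarity function. With zero gap penalty
# (series are short compared to biological sequences) the recurrence is
#   D(i,j) = max( D(i-1,j-1) + s(q_i, t_j), D(i-1,j), D(i,j-1) ),
# D(0,0) = 0 and zero first row/column; the traceback from D(n,m) to the
# origin yields the alignment, preferring diagonal > up > left on ties.

#' Align two analogue series
#'
#' @param query,target [analogue_series()] objects (or plain character
#'   vectors of fragment tokens in potency-ascending order).
#' @param sim similarity function `function(q, t)` over fragment SMILES, e.g.
#'   [sim_from_matrix()] over a [build_similarity_matrix()]; must return
#'   finite values.
#' @param normalize denominator of the normalised score: `"min"` (default;
#'   a query perfectly contained in a longer target scores 1, the semantics
#'   transfer search needs), `"max"`, `"query"` or `"target"` length.
#' @param clamp clamp negative similarities to zero (relevant for EFV cosine
#'   similarity, which can be negative; default `FALSE`).
#' @return object of class `as_alignment`: `columns` (data.frame
#'   `query_index`, `target_index`, `NA` marking a gap), `raw_score`
#'   (`D(n,m)`), `normalized_score`, `per_column_similarity` (matched
#'   columns only), plus the two series.
#' @examples
#' sim <- function(q, t) as.numeric(q == t)
#' a <- align_series(c("*C", "*CC"), c("*C", "*CC", "*CCC"), sim)
#' a$normalized_score
#' @export
align_series <- function(query, target, sim,
                         normalize = c("min", "max", "query", "target"),
                         clamp = FALSE) {
  normalize <- match.arg(normalize)
  qv <- if (inherits(query, "analogue_series")) query$values else as.character(query)
  tv <- if (inherits(target, "analogue_series")) target$values else as.character(target)
  n <- length(qv); m <- length(tv)
  stopifnot(n >= 1L, m >= 1L)
  S <- matrix(as.numeric(mapply(sim, rep(qv, times = m), rep(tv, each = n))),
              n, m)
  if (any(!is.finite(S))) {
    bad <- which(!is.finite(S), arr.ind = TRUE)[1L, ]
    stop("similarity is not finite for pair (", qv[bad[1L]], ", ",
         tv[bad[2L]], ")", call. = FALSE)
  }
  if (clamp) S[S < 0] <- 0
  D <- matrix(0, n + 1L, m + 1L)
  # move: 1 diagonal, 2 up (gap in target), 3 left (gap in query)
  move <- matrix(0L, n + 1L, m + 1L)
  move[, 1L] <- 2L; move[1L, ] <- 3L; move[1L, 1L] <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      diag <- D[i, j] + S[i, j]
      up <- D[i, j + 1L]
      left <- D[i + 1L, j]
      best <- max(diag, up, left)
      D[i + 1L, j + 1L] <- best
      move[i + 1L, j + 1L] <-
        if (diag >= up && diag >= left) 1L else if (up >= left) 2L else 3L
    }
  }
  cols <- list()
  i <- n + 1L; j <- m + 1L
  while (i > 1L || j > 1L) {
    mv <- move[i, j]
    if (mv == 1L) {
      cols[[length(cols) + 1L]] <- c(i - 1L, j - 1L)
      i <- i - 1L; j <- j - 1L
    } else if (mv == 2L) {
      cols[[length(cols) + 1L]] <- c(i - 1L, NA_integer_)
      i <- i - 1L
    } else {
      cols[[length(cols) + 1L]] <- c(NA_integer_, j - 1L)
      j <- j - 1L
    }
  }
  cols <- do.call(rbind, rev(cols))
  columns <- data.frame(query_index = cols[, 1L], target_index = cols[, 2L])
  matched <- !is.na(columns$query_index) & !is.na(columns$target_index)
  per_col <- S[cols[matched, , drop = FALSE]]
  denom <- switch(normalize, min = min(n, m), max = max(n, m),
                  query = n, target = m)
  structure(list(
    query_id = if (inherits(query, "analogue_series")) query$series_id else NA_character_,
    target_id = if (inherits(target, "analogue_series")) target$series_id else NA_character_,
    query_values = qv, target_values = tv,
    query_potency = if (inherits(query, "analogue_series")) query$potency else rep(NA_real_, n),
    target_potency = if (inherits(target, "analogue_series")) target$potency else rep(NA_real_, m),
    columns = columns,
    raw_score = D[n + 1L, m + 1L],
    normalized_score = D[n + 1L, m + 1L] / denom,
    per_column_similarity = as.numeric(per_col),
    normalize = normalize), class = "as_alignment")
}

#' Text rendering of a series alignment
#'
#' One text column per alignment position, marking exact matches (`|`),
#' mismatches (`:`), and gaps (`-`), with member potencies where known.
#'
#' @param result an `as_alignment` from [align_series()].
#' @return character vector of lines (also printed by the `print` method).
#' @export
alignment_to_text <- function(result) {
  stopifnot(inherits(result, "as_alignment"))
  cols <- result$columns
  qtok <- ifelse(is.na(cols$query_index), "-", result$query_values[cols$query_index])
  ttok <- ifelse(is.na(cols$target_index), "-", result$target_values[cols$target_index])
  mark <- ifelse(is.na(cols$query_index) | is.na(cols$target_index), "-",
                 ifelse(qtok == ttok, "|", ":"))
  qpot <- ifelse(is.na(cols$query_index), "", ifelse(
    is.na(result$query_potency[cols$query_index]), "",
    sprintf("%.2f", result$query_potency[cols$query_index])))
  tpot <- ifelse(is.na(cols$target_index), "", ifelse(
    is.na(result$target_potency[cols$target_index]), "",
    sprintf("%.2f", result$target_potency[cols$target_index])))
  w <- pmax(nchar(qtok), nchar(ttok), nchar(qpot), nchar(tpot), 1L)
  pad <- function(x) paste(mapply(formatC, x, width = w,
                                  MoreArgs = list(flag = "-")),
                           collapse = " ")
  lines <- c(paste0("query : ", pad(qtok)),
             paste0("        ", pad(mark)),
             paste0("target: ", pad(ttok)))
  if (any(nzchar(qpot))) lines <- c(paste0("pIC50 : ", pad(qpot)), lines)
  if (any(nzchar(tpot))) lines <- c(lines, paste0("pIC50 : ", pad(tpot)))
  lines
}

#' @export
print.as_alignment <- function(x, ...) {
  cat("Series alignment",
      if (!is.na(x$query_id)) paste0("(", x$query_id, " vs ", x$target_id, ")"),
      "\n")
  cat("  raw score:", format(x$raw_score), " normalized (", x$normalize, "):",
      format(x$normalized_score), "\n", sep = " ")
  cat(paste0("  ", alignment_to_text(x)), sep = "\n")
  invisible(x)
}
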