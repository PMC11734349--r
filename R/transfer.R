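# SAR transfer search: align a potency-ordered query series against a series
# database, rank target series of length n+k by normalised alignment score,
# and read transfer analogues off the target positions beyond the query's
# terminal matched analogue.

# target positions beyond the query's last matched position
transfer_positions <- function(alignment) {
  cols <- alignment$columns
  matched <- which(!is.na(cols$query_index) & !is.na(cols$target_index))
  if (!length(matched)) return(integer(0))
  j_last <- max(cols$target_index[matched])
  m <- length(alignment$target_values)
  if (j_last >= m) integer(0) else seq.int(j_last + 1L, m)
}

#' Search a series database for SAR-transfer partners
#'
#' Candidate target series are those whose length lies in
#' `[n + k_min, n + k_max]` for a query of length `n` (series with the
#' query's own `series_id` are excluded); each candidate is aligned to the
#' query and candidates are ranked by normalised score (descending,
#' ties broken by `series_id`). For each of the `top_n` hits the substituents
#' at target positions beyond the query's last matched position are proposed
#' as transfer values, and — when the query carries a key fragment — as full
#' transfer-analogue molecules via [attach_fragments()].
#'
#' @param query an [analogue_series()].
#' @param db list of `analogue_series` (potency-ordered).
#' @param sim similarity function, see [align_series()].
#' @param k_min,k_max admissible target-length excess over the query length
#'   (defaults 1 and `Inf`; `k_min = 0` also admits equal lengths).
#' @param top_n number of hits returned (default 10).
#' @param normalize,clamp passed to [align_series()].
#' @param propose attach transfer values to the query key to propose full
#'   molecules (default `TRUE`).
#' @return list of hits, each with `target_series_id`, `alignment`,
#'   `transfer_values` and `proposed_smiles`; empty list (with a message)
#'   when no candidate survives the length filter.
#' @export
transfer_search <- function(query, db, sim, k_min = 1L, k_max = Inf,
                            top_n = 10L, normalize = "min", clamp = FALSE,
                            propose = TRUE) {
  stopifnot(inherits(query, "analogue_series"), top_n >= 1L, k_min >= 0L)
  n <- length(query$values)
  lens <- vapply(db, function(s) length(s$values), integer(1))
  ids <- vapply(db, function(s) s$series_id, character(1))
  keep <- lens >= n + k_min & lens <= n + k_max & ids != query$series_id
  if (!any(keep)) {
    message("no candidate series in the length window [",
            n + k_min, ", ", if (is.finite(k_max)) n + k_max else "Inf", "]")
    return(list())
  }
  cand <- db[keep]
  aligns <- lapply(cand, function(s)
    align_series(query, s, sim, normalize = normalize, clamp = clamp))
  scores <- vapply(aligns, function(a) a$normalized_score, numeric(1))
  ord <- order(-scores, vapply(cand, function(s) s$series_id, character(1)),
               method = "radix")
  ord <- utils::head(ord, top_n)
  lapply(ord, function(k) {
    a <- aligns[[k]]
    tpos <- transfer_positions(a)
    tvals <- setdiff(cand[[k]]$values[tpos], query$values)
    proposed <- character(0)
    if (propose && length(tvals) && !is.null(query$key_smiles) &&
        !is.na(query$key_smiles)) {
      proposed <- propose_transfer_analogues(query$key_smiles, tvals,
                                             existing_values = query$values)
    }
    list(target_series_id = cand[[k]]$series_id,
         alignment = a,
         transfer_values = tvals,
         proposed_smiles = proposed)
  })
}

#' Propose transfer-analogue molecules
#'
#' Attaches each transfer value fragment to the query series' key fragment,
#' canonicalises, and drops candidates that duplicate an existing query
#' member (by value fragment or by assembled molecule). Chemically invalid
#' attachments are skipped with a warning.
#'
#' @param query_key_smiles key fragment with one attachment point.
#' @param transfer_values substituent fragments with one attachment point.
#' @param existing_values value fragments already present in the query
#'   series (excluded from proposals).
#' @return character vector of canonical molecule SMILES.
#' @export
propose_transfer_analogues <- function(query_key_smiles, transfer_values,
                                       existing_values = character(0)) {
  transfer_values <- setdiff(unique(transfer_values), existing_values)
  if (!length(transfer_values)) return(character(0))
  smi <- attach_fragments(query_key_smiles, transfer_values)
  existing <- character(0)
  if (length(existing_values)) {
    existing <- suppressWarnings(attach_fragments(query_key_smiles, existing_values))
  }
  unique(smi[!is.na(smi) & !(smi %in% existing)])
}

#' Curated non-classical bioisosteres of the carboxyl group
#'
#' Reads the package's editable default list of carboxylic-acid replacements
#' (tetrazole, acylsulfonamide, sulfonamide, sulfonic and phosphonic acids,
#' hydroxamic acid, and related groups). The list is a curated configuration
#' file, not an authoritative reference set; users studying other functional
#' groups should supply their own.
#'
#' @param path optional path to a two-column (`smiles`, `name`) tab-separated
#'   file; defaults to the file shipped in `inst/extdata`.
#' @return character vector of canonical fragment SMILES (named by group).
#' @export
carboxyl_bioisosteres <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "carboxyl_bioisosteres.smi",
                        package = "sartransfer")
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  stats::setNames(canonical_smiles(df$smiles), df$name)
}

#' Exclude series containing given value fragments
#'
#' Helper for the bioisostere counting experiment: drops database series
#' containing any of the listed fragments (e.g. all series with a carboxyl
#' substituent).
#'
#' @param db list of `analogue_series`.
#' @param values fragments whose presence disqualifies a series.
#' @return filtered list.
#' @export
exclude_series_with_values <- function(db, values) {
  db[!vapply(db, function(s) any(s$values %in% values), logical(1))]
}

#' Bioisostere alignment statistics over query series
#'
#' For each query series ending in `terminal_value_smiles` (most potent
#' member), searches the database and counts, among the `top_n` best-scoring
#' alignments, those in which the query's terminal position is matched to
#' one of the listed bioisosteres or in which a transfer value is one of
#' them. Returns per-query counts and a histogram with bins
#' `0, 1, ..., 10, >=11`.
#'
#' @param queries list of `analogue_series`, each with the stated terminal
#'   value.
#' @param db list of `analogue_series` (pre-filtered so that no series
#'   contains `terminal_value_smiles`; see [exclude_series_with_values()]).
#' @param sim similarity function.
#' @param bioisostere_list canonical fragment SMILES counted as qualifying
#'   replacements (see [carboxyl_bioisosteres()]).
#' @param terminal_value_smiles the required terminal substituent of every
#'   query (canonical SMILES).
#' @param top_n alignments considered per query (default 100).
#' @param k_min minimum target-length excess (default 0: equal lengths
#'   admitted, transfer analogues then come from unmatched tails).
#' @param normalize,clamp passed to [align_series()].
#' @return list with `counts` (named integer vector per query) and
#'   `histogram` (integer vector over bins `0..10, >=11`).
#' @export
bioisostere_alignment_stats <- function(queries, db, sim, bioisostere_list,
                                        terminal_value_smiles, top_n = 100L,
                                        k_min = 0L, normalize = "min",
                                        clamp = FALSE) {
  counts <- integer(length(queries))
  names(counts) <- vapply(queries, function(q) q$series_id, character(1))
  for (qi in seq_along(queries)) {
    q <- queries[[qi]]
    if (q$values[length(q$values)] != terminal_value_smiles)
      stop("query ", q$series_id, " does not end in ", terminal_value_smiles,
           call. = FALSE)
    hits <- suppressMessages(
      transfer_search(q, db, sim, k_min = k_min, top_n = top_n,
                      normalize = normalize, clamp = clamp, propose = FALSE))
    n <- length(q$values)
    cnt <- 0L
    for (h in hits) {
      cols <- h$alignment$columns
      term_row <- which(cols$query_index == n & !is.na(cols$target_index))
      aligned_hit <- length(term_row) > 0L &&
        h$alignment$target_values[cols$target_index[term_row[1L]]] %in%
          bioisostere_list
      transfer_hit <- any(h$transfer_values %in% bioisostere_list)
      if (aligned_hit || transfer_hit) cnt <- cnt + 1L
    }
    counts[qi] <- cnt
  }
  bins <- c(as.character(0:10), ">=11")
  hist <- stats::setNames(integer(12L), bins)
  for (cnt in counts) {
    b <- if (cnt >= 11L) 12L else cnt + 1L
    hist[b] <- hist[b] + 1L
  }
  list(counts = counts, histogram = hist)
}
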