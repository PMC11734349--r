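# Analogue series: a shared core (key fragment) plus a potency-ordered
# sequence of substituents (value fragments). The value sequence is the
# "sentence" used for embedding training and series alignment.

#' Construct an analogue series
#'
#' @param series_id identifier.
#' @param target_id,document_id provenance identifiers.
#' @param key_smiles canonical core-fragment SMILES with one attachment point.
#' @param values character vector of canonical substituent SMILES, ordered by
#'   ascending potency.
#' @param potency numeric pIC50 values, non-decreasing, same length.
#' @param compound_id character vector of member compound identifiers.
#' @return an object of class `analogue_series`.
#' @export
analogue_series <- function(series_id, target_id, document_id, key_smiles,
                            values, potency, compound_id = NULL) {
  stopifnot(length(values) == length(potency))
  if (is.null(compound_id)) compound_id <- rep(NA_character_, length(values))
  if (anyDuplicated(values)) stop("value fragments must be distinct", call. = FALSE)
  if (is.unsorted(potency)) stop("potency must be non-decreasing", call. = FALSE)
  structure(list(series_id = as.character(series_id),
                 target_id = as.character(target_id),
                 document_id = as.character(document_id),
                 key_smiles = as.character(key_smiles),
                 values = as.character(values),
                 potency = as.numeric(potency),
                 compound_id = as.character(compound_id)),
            class = "analogue_series")
}

#' @export
length.analogue_series <- function(x) length(x$values)

#' @export
print.analogue_series <- function(x, ...) {
  cat("Analogue series", x$series_id, "\n")
  cat("  key:      ", x$key_smiles, "\n")
  cat("  target:   ", x$target_id, "  document:", x$document_id, "\n")
  cat("  members (", length(x$values), ", ascending potency):\n", sep = "")
  for (i in seq_along(x$values)) {
    cat(sprintf("    %2d. %-20s pIC50 %.2f\n", i, x$values[i], x$potency[i]))
  }
  invisible(x)
}

#' Assemble potency-ordered analogue series from fragmented compounds
#'
#' Fragments every compound with [enumerate_single_cuts()], groups the
#' resulting key fragments by `(target_id, document_id, key_smiles)` and
#' turns each group with at least `min_size` distinct value fragments into an
#' analogue series ordered by ascending potency. When two compounds in a
#' group yield the same value fragment only the most potent member is kept;
#' potency ties are broken by lexicographic order of the canonical value
#' SMILES so the resulting "sentences" are deterministic.
#'
#' @param compounds data.frame with columns `compound_id`, `smiles`,
#'   `potency` (pIC50), `target_id`, `document_id`.
#' @param min_size minimum number of members per series (default 3).
#' @param max_cut_bonds,max_value_atoms,max_value_fraction fragmentation
#'   parameters, see [enumerate_single_cuts()].
#' @return list of [analogue_series()] objects, ordered by
#'   `(target_id, document_id, key_smiles)`.
#' @export
build_series <- function(compounds, min_size = 3L, max_cut_bonds = 20L,
                         max_value_atoms = 12L, max_value_fraction = 0.30) {
  req <- c("compound_id", "smiles", "potency", "target_id", "document_id")
  missing <- setdiff(req, names(compounds))
  if (length(missing))
    stop("compounds table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!nrow(compounds)) return(list())
  cuts <- vector("list", nrow(compounds))
  for (i in seq_len(nrow(compounds))) {
    ci <- enumerate_single_cuts(compounds$smiles[i],
                                max_cut_bonds = max_cut_bonds,
                                max_value_atoms = max_value_atoms,
                                max_value_fraction = max_value_fraction,
                                compound_id = compounds$compound_id[i])
    if (nrow(ci)) {
      ci$compound_id <- as.character(compounds$compound_id[i])
      ci$potency <- compounds$potency[i]
      ci$target_id <- as.character(compounds$target_id[i])
      ci$document_id <- as.character(compounds$document_id[i])
      cuts[[i]] <- ci
    }
  }
  cuts <- do.call(rbind, cuts)
  if (is.null(cuts) || !nrow(cuts)) return(list())
  grp <- interaction(cuts$target_id, cuts$document_id, cuts$key_smiles,
                     drop = TRUE, lex.order = TRUE)
  out <- list()
  for (gname in levels(grp)) {
    gd <- cuts[grp == gname, , drop = FALSE]
    # duplicate values: keep highest potency; ties by compound_id for
    # determinism
    gd <- gd[order(gd$value_smiles, -gd$potency, gd$compound_id), , drop = FALSE]
    gd <- gd[!duplicated(gd$value_smiles), , drop = FALSE]
    if (nrow(gd) < min_size) next
    gd <- gd[order(gd$potency, gd$value_smiles), , drop = FALSE]
    out[[length(out) + 1L]] <- analogue_series(
      series_id = sprintf("AS%05d", length(out) + 1L),
      target_id = gd$target_id[1L],
      document_id = gd$document_id[1L],
      key_smiles = gd$key_smiles[1L],
      values = gd$value_smiles,
      potency = gd$potency,
      compound_id = gd$compound_id)
  }
  out
}

#' Write / read an analogue-series database as JSON Lines
#'
#' One series per line with fields `series_id`, `target_id`, `document_id`,
#' `key_smiles` and `members` (array of `{value_smiles, potency,
#' compound_id}`), the package's on-disk series format.
#'
#' @param series list of [analogue_series()] objects.
#' @param path file path.
#' @return `write_series_jsonl` returns `path` invisibly; `read_series_jsonl`
#'   returns a list of `analogue_series`.
#' @export
write_series_jsonl <- function(series, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (s in series) {
    rec <- list(series_id = s$series_id, target_id = s$target_id,
                document_id = s$document_id, key_smiles = s$key_smiles,
                members = data.frame(value_smiles = s$values,
                                     potency = s$potency,
                                     compound_id = s$compound_id,
                                     stringsAsFactors = FALSE))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_series_jsonl
#' @export
read_series_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e)
      stop("malformed JSONL at line ", i, " of ", path, ": ", conditionMessage(e),
           call. = FALSE))
    out[[i]] <- analogue_series(rec$series_id, rec$target_id, rec$document_id,
                                rec$key_smiles, rec$members$value_smiles,
                                rec$members$potency, rec$members$compound_id)
  }
  out
}
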