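#' @importFrom ChemmineOB convertFormat
NULL

# Single conversion through OpenBabel; returns character(1) or "" on failure.
ob_convert1 <- function(from, to, text) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(from, to, source = text)),
    error = function(e) ""
  )
  if (is.null(out) || length(out) == 0L) "" else out
}

strip_smiles_line <- function(x) {
  # OpenBabel emits "SMILES\ttitle\n"; keep the SMILES token only
  x <- sub("[\t ].*$", "", x)
  trimws(x)
}

#' Canonical SMILES
#'
#' Canonicalises SMILES strings through OpenBabel. Attachment points written
#' as the wildcard atom `*` are preserved, so substituent and core fragments
#' from different compounds compare equal as strings whenever they are the
#' same chemical fragment.
#'
#' @param smiles character vector of SMILES strings.
#' @param on_error `"stop"` (default) to raise an error naming the offending
#'   input, or `"na"` to return `NA` for unparsable entries.
#' @return character vector of canonical SMILES, same length as `smiles`.
#' @examples
#' canonical_smiles(c("OCC", "c1ccccc1C"))
#' @export
canonical_smiles <- function(smiles, on_error = c("stop", "na")) {
  on_error <- match.arg(on_error)
  stopifnot(is.character(smiles))
  out <- character(length(smiles))
  ok <- !is.na(smiles) & nzchar(smiles)
  uniq <- unique(smiles[ok])
  if (length(uniq)) {
    can <- vapply(uniq, function(s) {
      strip_smiles_line(ob_convert1("SMI", "CAN", s))
    }, character(1))
    bad <- uniq[!nzchar(can)]
    if (length(bad) && on_error == "stop") {
      stop("unparsable SMILES: ", paste(utils::head(bad, 5L), collapse = ", "),
           call. = FALSE)
    }
    can[!nzchar(can)] <- NA_character_
    out[ok] <- unname(can[smiles[ok]])
  }
  out[!ok] <- NA_character_
  out
}

# Batch canonicalisation for internally generated, known-valid molblocks.
# `blocks` is a character vector of V2000 molblocks whose title line carries
# a unique integer index; returns canonical SMILES in input order.
ob_blocks_to_smiles <- function(blocks) {
  if (!length(blocks)) return(character(0))
  sdf <- paste(blocks, collapse = "")
  out <- ob_convert1("SDF", "CAN", sdf)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  smi <- sub("^([^\t ]+).*$", "\\1", lines)
  idx <- as.integer(sub("^[^\t ]+[\t ]+", "", lines))
  res <- rep(NA_character_, length(blocks))
  keep <- !is.na(idx) & idx >= 1L & idx <= length(blocks)
  res[idx[keep]] <- smi[keep]
  if (anyNA(res)) {
    stop("OpenBabel failed to convert ", sum(is.na(res)),
         " internally generated molblock(s)", call. = FALSE)
  }
  res
}
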