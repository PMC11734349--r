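# Single-cut matched-molecular-pair fragmentation: every acyclic single bond
# between two heavy atoms is cut in turn, yielding a key (core) and a value
# (substituent) fragment, each carrying one attachment-point wildcard atom.

subgraph_with_star <- function(g, atoms, attach_atom) {
  atoms <- sort(atoms)
  remap <- integer(n_atoms(g))
  remap[atoms] <- seq_along(atoms)
  keep <- g$bond[, 1L] %in% atoms & g$bond[, 2L] %in% atoms
  bond <- g$bond[keep, , drop = FALSE]
  if (nrow(bond)) {
    bond[, 1L] <- remap[bond[, 1L]]
    bond[, 2L] <- remap[bond[, 2L]]
  }
  star <- length(atoms) + 1L
  bond <- rbind(bond, c(star, remap[attach_atom], 1L))
  mol_graph(c(g$symbol[atoms], "*"), c(g$charge[atoms], 0L), bond)
}

#' Enumerate single-cut fragmentations of a compound
#'
#' Cuts each acyclic single bond between two heavy atoms, producing key
#' (core) and value (substituent) fragments with one attachment-point
#' wildcard each. A fragment qualifies as a value if it has at most
#' `max_value_atoms` heavy atoms and at most `max_value_fraction` of the
#' source compound's heavy atoms; when both sides qualify, both orientations
#' are emitted. Compounds with more than `max_cut_bonds` cuttable bonds are
#' skipped (empty result), mirroring the usual matched-molecular-pair
#' fragmentation guard against combinatorial blow-up.
#'
#' @param smiles single SMILES string of the compound.
#' @param max_cut_bonds maximum number of cuttable bonds before the molecule
#'   is skipped (default 20).
#' @param max_value_atoms heavy-atom cap for a value fragment (default 12).
#' @param max_value_fraction cap on value heavy atoms as a fraction of the
#'   source compound's heavy atoms (default 0.30).
#' @param compound_id optional identifier used in error messages.
#' @return data.frame with columns `key_smiles`, `value_smiles`,
#'   `value_heavy_atoms`, `source_heavy_atoms` (zero rows if no cut passes).
#' @examples
#' enumerate_single_cuts("Cc1ccccc1")   # toluene: one cut
#' @export
enumerate_single_cuts <- function(smiles, max_cut_bonds = 20L,
                                  max_value_atoms = 12L,
                                  max_value_fraction = 0.30,
                                  compound_id = NULL) {
  stopifnot(length(smiles) == 1L)
  empty <- data.frame(key_smiles = character(0), value_smiles = character(0),
                      value_heavy_atoms = integer(0),
                      source_heavy_atoms = integer(0),
                      stringsAsFactors = FALSE)
  g <- tryCatch(smiles_to_graph(smiles), error = function(e) {
    stop("unparsable SMILES", if (!is.null(compound_id))
      paste0(" for compound '", compound_id, "'"), ": ", smiles, call. = FALSE)
  })
  nb <- nrow(g$bond)
  if (!nb) return(empty)
  ring <- ring_bond_flags(g)
  cuttable <- which(g$bond[, 3L] == 1L & !ring &
                      g$symbol[g$bond[, 1L]] != "*" &
                      g$symbol[g$bond[, 2L]] != "*")
  if (!length(cuttable) || length(cuttable) > max_cut_bonds) return(empty)
  total <- n_heavy(g)
  blocks <- character(0)
  rows <- list()
  for (b in cuttable) {
    comp <- components(g, skip_bond = b)
    a1 <- g$bond[b, 1L]; a2 <- g$bond[b, 2L]
    side1 <- which(comp == comp[a1])
    side2 <- which(comp == comp[a2])
    for (ori in 1:2) {
      v_atoms <- if (ori == 1L) side1 else side2
      k_atoms <- if (ori == 1L) side2 else side1
      v_attach <- if (ori == 1L) a1 else a2
      k_attach <- if (ori == 1L) a2 else a1
      ha <- length(v_atoms)
      if (ha > max_value_atoms || ha > max_value_fraction * total) next
      i0 <- length(blocks)
      blocks <- c(blocks,
                  write_molblock(subgraph_with_star(g, k_atoms, k_attach), as.character(i0 + 1L)),
                  write_molblock(subgraph_with_star(g, v_atoms, v_attach), as.character(i0 + 2L)))
      rows[[length(rows) + 1L]] <- c(ha, total)
    }
  }
  if (!length(rows)) return(empty)
  smi <- ob_blocks_to_smiles(blocks)
  m <- do.call(rbind, rows)
  data.frame(key_smiles = smi[seq(1L, length(smi), by = 2L)],
             value_smiles = smi[seq(2L, length(smi), by = 2L)],
             value_heavy_atoms = as.integer(m[, 1L]),
             source_heavy_atoms = as.integer(m[, 2L]),
             stringsAsFactors = FALSE)
}

#' Reattach a substituent to a core fragment
#'
#' Bonds the attachment-point neighbour of the key fragment to that of each
#' value fragment with a single bond, removing both wildcard atoms, and
#' returns canonical SMILES of the assembled molecules. This is the inverse
#' of [enumerate_single_cuts()]: reattaching a cut's value to its key
#' reproduces the source compound's canonical SMILES.
#'
#' @param key_smiles core fragment SMILES with exactly one `*` wildcard.
#' @param value_smiles character vector of substituent fragment SMILES, each
#'   with exactly one `*` wildcard.
#' @return character vector of canonical SMILES; `NA` (with a warning) for
#'   combinations that OpenBabel rejects.
#' @examples
#' attach_fragments("*c1ccccc1", "*CC")   # ethylbenzene
#' @export
attach_fragments <- function(key_smiles, value_smiles) {
  stopifnot(length(key_smiles) == 1L)
  gk <- smiles_to_graph(key_smiles)
  wk <- which(gk$symbol == "*")
  if (length(wk) != 1L)
    stop("key fragment must have exactly one attachment point: ", key_smiles,
         call. = FALSE)
  nk <- adjacency(gk)[[wk]]
  if (length(nk) != 1L)
    stop("attachment wildcard must have exactly one neighbour", call. = FALSE)
  keep_k <- setdiff(seq_len(n_atoms(gk)), wk)
  remap_k <- integer(n_atoms(gk)); remap_k[keep_k] <- seq_along(keep_k)
  bond_k <- gk$bond[gk$bond[, 1L] != wk & gk$bond[, 2L] != wk, , drop = FALSE]
  if (nrow(bond_k)) {
    bond_k[, 1L] <- remap_k[bond_k[, 1L]]
    bond_k[, 2L] <- remap_k[bond_k[, 2L]]
  }
  out <- rep(NA_character_, length(value_smiles))
  blocks <- character(0)
  block_of <- integer(0)
  for (i in seq_along(value_smiles)) {
    gv <- tryCatch(smiles_to_graph(value_smiles[i]), error = function(e) NULL)
    if (is.null(gv)) { warning("skipping unparsable value: ", value_smiles[i]); next }
    wv <- which(gv$symbol == "*")
    if (length(wv) != 1L) {
      warning("value fragment must have exactly one attachment point: ",
              value_smiles[i])
      next
    }
    nv <- adjacency(gv)[[wv]]
    if (length(nv) != 1L) { warning("bad attachment in ", value_smiles[i]); next }
    keep_v <- setdiff(seq_len(n_atoms(gv)), wv)
    remap_v <- integer(n_atoms(gv))
    remap_v[keep_v] <- seq_along(keep_v) + length(keep_k)
    bond_v <- gv$bond[gv$bond[, 1L] != wv & gv$bond[, 2L] != wv, , drop = FALSE]
    if (nrow(bond_v)) {
      bond_v[, 1L] <- remap_v[bond_v[, 1L]]
      bond_v[, 2L] <- remap_v[bond_v[, 2L]]
    }
    gm <- mol_graph(c(gk$symbol[keep_k], gv$symbol[keep_v]),
                    c(gk$charge[keep_k], gv$charge[keep_v]),
                    rbind(bond_k, bond_v,
                          c(remap_k[nk], remap_v[nv], 1L)))
    blocks <- c(blocks, write_molblock(gm, as.character(length(blocks) + 1L)))
    block_of <- c(block_of, i)
  }
  if (length(blocks)) out[block_of] <- ob_blocks_to_smiles(blocks)
  out
}

#' Filter and normalise a compound-activity table
#'
#' Applies the standard curation filters ahead of series extraction: keeps
#' rows whose standard relation is `"="` and whose assay confidence is at
#' least `min_confidence` (each filter is skipped when its column is absent
#' or `NULL`), and converts nanomolar IC50 values to pIC50 via
#' `pIC50 = 9 - log10(IC50[nM])` so all downstream potencies are pIC50
#' (ascending = more potent). Rows with non-positive IC50 are dropped with a
#' warning.
#'
#' @param rows data.frame holding at least `smiles` and `potency` columns
#'   (names configurable).
#' @param potency_column,smiles_column column names (defaults `"potency"`,
#'   `"smiles"`).
#' @param potency_units `"pIC50"` (default) or `"nM"`; alternatively the name
#'   of a per-row units column via `units_column`.
#' @param units_column optional column holding per-row units (`"nM"` or
#'   `"pIC50"`); overrides `potency_units`.
#' @param relation_column,confidence_column optional column names for the
#'   standard-relation and assay-confidence filters.
#' @param min_confidence minimum assay confidence retained (default 9).
#' @return the filtered data.frame with `potency` on the pIC50 scale.
#' @export
filter_activity_table <- function(rows,
                                  potency_column = "potency",
                                  smiles_column = "smiles",
                                  potency_units = c("pIC50", "nM"),
                                  units_column = NULL,
                                  relation_column = NULL,
                                  confidence_column = NULL,
                                  min_confidence = 9) {
  stopifnot(is.data.frame(rows))
  potency_units <- match.arg(potency_units)
  if (!is.null(relation_column) && relation_column %in% names(rows)) {
    rows <- rows[!is.na(rows[[relation_column]]) & rows[[relation_column]] == "=", ,
                 drop = FALSE]
  }
  if (!is.null(confidence_column) && confidence_column %in% names(rows)) {
    rows <- rows[!is.na(rows[[confidence_column]]) &
                   rows[[confidence_column]] >= min_confidence, , drop = FALSE]
  }
  pot <- as.numeric(rows[[potency_column]])
  units <- if (!is.null(units_column) && units_column %in% names(rows)) {
    as.character(rows[[units_column]])
  } else rep(potency_units, nrow(rows))
  is_nm <- tolower(units) == "nm"
  bad <- is_nm & (!is.finite(pot) | pot <= 0)
  if (any(bad)) {
    warning(sum(bad), " row(s) with non-positive IC50 dropped")
    rows <- rows[!bad, , drop = FALSE]
    pot <- pot[!bad]; is_nm <- is_nm[!bad]
  }
  pot[is_nm] <- 9 - log10(pot[is_nm])
  keep <- is.finite(pot)
  if (any(!keep)) {
    warning(sum(!keep), " row(s) with non-finite potency dropped")
    rows <- rows[keep, , drop = FALSE]
    pot <- pot[keep]
  }
  rows[[potency_column]] <- pot
  rows
}

#' Read a delimited compound-activity table
#'
#' Thin reader for CSV/TSV activity tables with configurable column names;
#' returns a data.frame with the standard internal columns `compound_id`,
#' `smiles`, `potency`, `target_id`, `document_id` (plus any optional
#' relation/confidence/units columns, renamed to `standard_relation`,
#' `assay_confidence`, `potency_units` when present).
#'
#' @param path file path; delimiter inferred from extension (`.tsv`/`.txt`
#'   tab, otherwise comma) unless `sep` is given.
#' @param columns named character vector mapping internal names to file
#'   column names; defaults assume the internal names are used as-is.
#' @param sep field separator override.
#' @return data.frame.
#' @export
read_activity_table <- function(path, columns = NULL, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, comment.char = "")
  std <- c(compound_id = "compound_id", smiles = "smiles", potency = "potency",
           target_id = "target_id", document_id = "document_id",
           standard_relation = "standard_relation",
           assay_confidence = "assay_confidence",
           potency_units = "potency_units")
  if (!is.null(columns)) std[names(columns)] <- columns
  for (internal in names(std)) {
    file_col <- std[[internal]]
    if (file_col %in% names(df) && internal != file_col) {
      names(df)[names(df) == file_col] <- internal
    }
  }
  required <- c("smiles", "potency")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("activity table ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}
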