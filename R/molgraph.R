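# Internal molecular graph: a light container parsed from a V2000 molblock.
# Fields: symbol (chr), charge (int), bond (matrix n_bonds x 3: a1, a2, order).
# OpenBabel writes kekulised molblocks; aromaticity is re-perceived here via a
# Hueckel-style electron count over the smallest set of smallest rings.

mol_graph <- function(symbol, charge, bond) {
  bond <- matrix(as.integer(bond), ncol = 3L,
                 dimnames = list(NULL, c("a1", "a2", "order")))
  structure(list(symbol = as.character(symbol),
                 charge = as.integer(charge),
                 bond = bond),
            class = "mol_graph")
}

n_atoms <- function(g) length(g$symbol)

parse_molblock <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) stop("molblock too short", call. = FALSE)
  na <- as.integer(substr(lines[4L], 1L, 3L))
  nb <- as.integer(substr(lines[4L], 4L, 6L))
  atoms <- lines[5L:(4L + na)]
  symbol <- trimws(substr(atoms, 32L, 34L))
  bond <- matrix(0L, nrow = nb, ncol = 3L)
  if (nb > 0L) {
    bl <- lines[(5L + na):(4L + na + nb)]
    bond <- cbind(as.integer(substr(bl, 1L, 3L)),
                  as.integer(substr(bl, 4L, 6L)),
                  as.integer(substr(bl, 7L, 9L)))
  }
  charge <- integer(na)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    tok <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "[ ]+")[[1]])
    k <- tok[1L]
    for (j in seq_len(k)) charge[tok[2L * j]] <- tok[2L * j + 1L]
  }
  mol_graph(symbol, charge, bond)
}

write_molblock <- function(g, title = "") {
  na <- n_atoms(g)
  nb <- nrow(g$bond)
  atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        0, 0, 0, g$symbol)
  bond_lines <- if (nb) sprintf("%3d%3d%3d  0  0  0  0",
                                g$bond[, 1L], g$bond[, 2L], g$bond[, 3L]) else character(0)
  chg_idx <- which(g$charge != 0L)
  chg_lines <- character(0)
  if (length(chg_idx)) {
    # at most 8 assignments per M CHG line
    parts <- split(chg_idx, ceiling(seq_along(chg_idx) / 8L))
    chg_lines <- vapply(parts, function(ix) {
      paste0("M  CHG", sprintf("%3d", length(ix)),
             paste0(sprintf("%4d%4d", ix, g$charge[ix]), collapse = ""))
    }, character(1))
  }
  paste0(paste(c(title, "  sartransfer", "",
                 sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb),
                 atom_lines, bond_lines, chg_lines, "M  END", "$$$$"),
               collapse = "\n"), "\n")
}

smiles_to_graph <- function(smiles) {
  sdf <- ob_convert1("SMI", "SDF", smiles)
  if (!nzchar(sdf)) stop("unparsable SMILES: ", smiles, call. = FALSE)
  parse_molblock(sdf)
}

graph_to_smiles <- function(g) {
  strip_smiles_line(ob_convert1("SDF", "CAN", write_molblock(g)))
}

# adjacency as list of integer neighbour vectors
adjacency <- function(g) {
  adj <- vector("list", n_atoms(g))
  for (i in seq_len(n_atoms(g))) adj[[i]] <- integer(0)
  if (nrow(g$bond)) {
    for (b in seq_len(nrow(g$bond))) {
      a1 <- g$bond[b, 1L]; a2 <- g$bond[b, 2L]
      adj[[a1]] <- c(adj[[a1]], a2)
      adj[[a2]] <- c(adj[[a2]], a1)
    }
  }
  adj
}

heavy_degree <- function(g) {
  deg <- integer(n_atoms(g))
  if (nrow(g$bond)) {
    t1 <- tabulate(g$bond[, 1L], nbins = n_atoms(g))
    t2 <- tabulate(g$bond[, 2L], nbins = n_atoms(g))
    deg <- t1 + t2
  }
  deg
}

n_heavy <- function(g) sum(g$symbol != "*")

# connected component ids, optionally ignoring one bond (by row index)
components <- function(g, skip_bond = 0L) {
  n <- n_atoms(g)
  comp <- integer(n)
  adj <- vector("list", n)
  if (nrow(g$bond)) for (b in seq_len(nrow(g$bond))) {
    if (b == skip_bond) next
    a1 <- g$bond[b, 1L]; a2 <- g$bond[b, 2L]
    adj[[a1]] <- c(adj[[a1]], a2)
    adj[[a2]] <- c(adj[[a2]], a1)
  }
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
    }
  }
  comp
}

# ring-membership flag per bond: bond is cyclic iff endpoints stay connected
# without it
ring_bond_flags <- function(g) {
  nb <- nrow(g$bond)
  flags <- logical(nb)
  if (!nb) return(flags)
  for (b in seq_len(nb)) {
    comp <- components(g, skip_bond = b)
    flags[b] <- comp[g$bond[b, 1L]] == comp[g$bond[b, 2L]]
  }
  flags
}

# Smallest set of smallest rings: for every ring bond take the shortest cycle
# through it (BFS avoiding the bond), then keep size-sorted rings until the
# cycle rank nb - na + n_components is reached, requiring each kept ring to
# contribute a bond not yet covered.
sssr <- function(g) {
  rb <- which(ring_bond_flags(g))
  if (!length(rb)) return(list())
  adj <- adjacency(g)
  rings <- list()
  for (b in rb) {
    a1 <- g$bond[b, 1L]; a2 <- g$bond[b, 2L]
    # BFS shortest path a1 -> a2 avoiding direct use of bond b
    prev <- integer(n_atoms(g)); prev[a1] <- -1L
    queue <- a1
    while (length(queue) && prev[a2] == 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if ((v == a1 && w == a2) || (v == a2 && w == a1)) next
        if (prev[w] == 0L && w != a1) { prev[w] <- v; queue <- c(queue, w) }
      }
    }
    if (prev[a2] == 0L) next
    path <- a2
    v <- a2
    while (prev[v] != -1L) { v <- prev[v]; path <- c(path, v) }
    rings[[length(rings) + 1L]] <- sort(path)
  }
  rings <- unique(rings)
  rings <- rings[order(lengths(rings))]
  n_comp <- max(components(g))
  rank <- nrow(g$bond) - n_atoms(g) + n_comp
  bond_key <- function(i, j) paste(min(i, j), max(i, j))
  ring_bonds <- function(atoms) {
    keep <- g$bond[, 1L] %in% atoms & g$bond[, 2L] %in% atoms
    idx <- which(keep)
    # only bonds actually on the cycle: both endpoints in ring set; for a
    # chordless shortest cycle this is exact
    vapply(idx, function(b) bond_key(g$bond[b, 1L], g$bond[b, 2L]), character(1))
  }
  chosen <- list()
  covered <- character(0)
  for (r in rings) {
    if (length(chosen) >= rank) break
    bks <- ring_bonds(r)
    if (any(!(bks %in% covered))) {
      chosen[[length(chosen) + 1L]] <- r
      covered <- union(covered, bks)
    }
  }
  chosen
}

default_valence <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L, F = 1L,
                     Cl = 1L, Br = 1L, I = 1L, B = 3L, Si = 4L, Se = 2L,
                     H = 1L, `*` = 0L)

# implicit hydrogen count per atom (simple valence model; charge adjusts N/O)
implicit_h <- function(g) {
  n <- n_atoms(g)
  bsum <- numeric(n)
  if (nrow(g$bond)) for (b in seq_len(nrow(g$bond))) {
    o <- g$bond[b, 3L]
    bsum[g$bond[b, 1L]] <- bsum[g$bond[b, 1L]] + o
    bsum[g$bond[b, 2L]] <- bsum[g$bond[b, 2L]] + o
  }
  h <- integer(n)
  for (i in seq_len(n)) {
    sym <- g$symbol[i]
    val <- default_valence[[sym]] %||% 0L
    if (sym %in% c("N", "O", "P")) val <- val + g$charge[i]
    if (sym == "C") val <- val - abs(g$charge[i])
    if (sym %in% c("S", "P")) {
      # allow hypervalent S(4,6) / P(5)
      steps <- if (sym == "S") c(2L, 4L, 6L) else c(3L, 5L)
      steps <- steps + g$charge[i]
      val <- steps[which(steps >= bsum[i])[1L]] %||% val
      if (is.na(val)) val <- bsum[i]
    }
    h[i] <- max(0L, as.integer(val - bsum[i]))
  }
  h
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

# Aromatic SSSR rings by a Hueckel-style count on the kekulised graph:
# in-ring double bonds contribute 2 pi electrons, ring N/O/S without any
# double bond contribute a lone pair; carbons must carry some double bond
# (in-ring or exocyclic) to be sp2. Rings of size 5 or 6 with exactly 6 pi
# electrons are flagged aromatic.
aromatic_info <- function(g) {
  rings <- sssr(g)
  arom_atom <- logical(n_atoms(g))
  arom_rings <- list()
  if (!length(rings)) return(list(rings = rings, aromatic = logical(0), atom = arom_atom))
  has_double <- logical(n_atoms(g))
  if (nrow(g$bond)) for (b in seq_len(nrow(g$bond))) {
    if (g$bond[b, 3L] >= 2L) {
      has_double[g$bond[b, 1L]] <- TRUE
      has_double[g$bond[b, 2L]] <- TRUE
    }
  }
  flags <- logical(length(rings))
  for (k in seq_along(rings)) {
    atoms <- rings[[k]]
    if (!(length(atoms) %in% c(5L, 6L))) next
    pi <- 0L
    ok <- TRUE
    for (b in seq_len(nrow(g$bond))) {
      if (g$bond[b, 1L] %in% atoms && g$bond[b, 2L] %in% atoms &&
          g$bond[b, 3L] == 2L) pi <- pi + 2L
      if (g$bond[b, 1L] %in% atoms && g$bond[b, 2L] %in% atoms &&
          g$bond[b, 3L] == 3L) ok <- FALSE
    }
    for (a in atoms) {
      sym <- g$symbol[a]
      if (sym %in% c("N", "O", "S", "Se")) {
        if (!has_double[a]) pi <- pi + 2L
      } else if (sym == "C") {
        if (!has_double[a] && g$charge[a] == 0L) ok <- FALSE
      } else {
        ok <- FALSE
      }
    }
    if (ok && pi == 6L) {
      flags[k] <- TRUE
      arom_atom[atoms] <- TRUE
    }
  }
  list(rings = rings, aromatic = flags, atom = arom_atom)
}

# Replace the single attachment wildcard by an implicit hydrogen: drop the
# wildcard atom and its bond. Descriptors are computed on the capped graph.
hcap_graph <- function(g) {
  w <- which(g$symbol == "*")
  if (!length(w)) return(g)
  keep <- setdiff(seq_len(n_atoms(g)), w)
  remap <- integer(n_atoms(g))
  remap[keep] <- seq_along(keep)
  bond <- g$bond[!(g$bond[, 1L] %in% w | g$bond[, 2L] %in% w), , drop = FALSE]
  bond[, 1L] <- remap[bond[, 1L]]
  bond[, 2L] <- remap[bond[, 2L]]
  mol_graph(g$symbol[keep], g$charge[keep], bond)
}
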