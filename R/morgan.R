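# Circular (Morgan/ECFP-style) fingerprints: iterative neighbourhood hashing
# of per-atom invariants up to a fixed radius, folded onto a fixed-width bit
# vector. Computed on the hydrogen-capped structure.

atomic_number <- c(H = 1L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L,
                   Si = 14L, P = 15L, S = 16L, Cl = 17L, Se = 34L,
                   Br = 35L, I = 53L)

#' Morgan (circular) fingerprint of a fragment
#'
#' Initial atom invariants combine atomic number, heavy-atom degree, implicit
#' hydrogen count, formal charge, ring membership and aromaticity; each
#' iteration re-hashes an atom's invariant together with the sorted
#' (bond-order, neighbour-invariant) pairs of its neighbours. All invariants
#' from radius 0 up to `radius` are folded modulo `nbits`. Bonds between two
#' aromatic atoms inside an aromatic ring are hashed with a dedicated
#' aromatic bond code so that the fingerprint does not depend on the
#' kekulisation. The attachment wildcard `*` is replaced by hydrogen first.
#'
#' @param fragment_smiles single fragment SMILES.
#' @param radius neighbourhood radius (default 2).
#' @param nbits folded width (default 1024).
#' @return sorted integer vector of on-bit indices in `[0, nbits)`.
#' @examples
#' morgan_fp("*c1ccccc1")
#' @export
morgan_fp <- function(fragment_smiles, radius = 2L, nbits = 1024L) {
  stopifnot(length(fragment_smiles) == 1L, radius >= 0L, nbits >= 1L)
  g <- hcap_graph(smiles_to_graph(fragment_smiles))
  n <- n_atoms(g)
  if (n == 0L) return(integer(0))
  deg <- heavy_degree(g)
  hs <- implicit_h(g)
  ai <- aromatic_info(g)
  in_ring <- logical(n)
  for (r in ai$rings) in_ring[r] <- TRUE
  anum <- unname(atomic_number[g$symbol])
  anum[is.na(anum)] <- 0L
  inv <- vapply(seq_len(n), function(i) {
    fnv1a_hash(c(anum[i], deg[i], hs[i], g$charge[i],
                 as.integer(in_ring[i]), as.integer(ai$atom[i])))
  }, numeric(1))

  # neighbour lists with bond codes (aromatic bonds get code 4)
  nb <- vector("list", n)
  if (nrow(g$bond)) for (b in seq_len(nrow(g$bond))) {
    a1 <- g$bond[b, 1L]; a2 <- g$bond[b, 2L]
    code <- g$bond[b, 3L]
    if (ai$atom[a1] && ai$atom[a2]) {
      for (rk in which(ai$aromatic)) {
        ring <- ai$rings[[rk]]
        if (a1 %in% ring && a2 %in% ring) { code <- 4L; break }
      }
    }
    nb[[a1]] <- rbind(nb[[a1]], c(code, a2))
    nb[[a2]] <- rbind(nb[[a2]], c(code, a1))
  }

  all_inv <- inv
  for (r in seq_len(radius)) {
    new_inv <- inv
    for (i in seq_len(n)) {
      if (is.null(nb[[i]])) next
      pairs <- cbind(nb[[i]][, 1L], inv[nb[[i]][, 2L]])
      pairs <- pairs[order(pairs[, 2L], pairs[, 1L]), , drop = FALSE]
      # split 32-bit invariants into half-words to stay in exact-int range
      flat <- as.integer(c(rbind(pairs[, 1L],
                                 pairs[, 2L] %% 65536,
                                 pairs[, 2L] %/% 65536)))
      new_inv[i] <- fnv1a_hash(c(r, as.integer(inv[i] %% 65536),
                                 as.integer(inv[i] %/% 65536), flat))
    }
    inv <- new_inv
    all_inv <- c(all_inv, inv)
  }
  sort(unique(as.integer(all_inv %% nbits)))
}

#' Tanimoto coefficient between two bit sets
#'
#' `|a n b| / |a u b|`; the Tanimoto of two empty fingerprints is defined as
#' 1 (identical empty sets), which arises only for the bare-hydrogen
#' fragment.
#'
#' @param a,b integer vectors of on-bit indices.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  a <- unique(a); b <- unique(b)
  un <- length(union(a, b))
  if (un == 0L) return(1)
  length(intersect(a, b)) / un
}
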