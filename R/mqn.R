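# Molecular quantum numbers: 42 integer counts of atom, bond, polarity and
# topology features spanning a property space for small fragments. Counts are
# computed on the hydrogen-capped structure (the attachment wildcard is
# replaced by an implicit hydrogen).

mqn_names <- c(
  "c", "f", "cl", "br", "i", "s", "p", "an", "cn", "ao", "co", "hac",
  "asb", "adb", "atb", "csb", "cdb", "ctb", "rbc",
  "hbam", "hba", "hbdm", "hbd", "neg", "pos",
  "asv", "adv", "atv", "aqv", "cdv", "ctv", "cqv",
  "r3", "r4", "r5", "r6", "r7", "r8", "r9", "rg10", "afr", "bfr")

#' MQN descriptor vector of a fragment
#'
#' Computes a 42-dimensional vector of molecular quantum numbers: atom counts
#' (carbon, halogens, sulfur, phosphorus, cyclic/acyclic nitrogen and oxygen,
#' heavy atoms), bond counts (acyclic and cyclic single/double/triple,
#' rotatable), polarity counts (hydrogen-bond acceptor/donor sites and atoms,
#' formal charges) and topology counts (acyclic/cyclic node valencies, ring
#' sizes 3--9 and >=10, atoms and bonds shared by two or more smallest
#' rings). The attachment wildcard `*`, if present, is replaced by a
#' hydrogen before counting.
#'
#' @param fragment_smiles character vector of fragment SMILES.
#' @return for a single input, a named integer vector of length 42; for
#'   several, a matrix with one row per fragment.
#' @examples
#' mqn_descriptors("*C")      # methyl: 1 carbon, 1 heavy atom
#' @export
mqn_descriptors <- function(fragment_smiles) {
  stopifnot(is.character(fragment_smiles), length(fragment_smiles) >= 1L)
  m <- t(vapply(fragment_smiles, function(s) mqn_one(s), numeric(42L)))
  dimnames(m) <- list(fragment_smiles, mqn_names)
  if (length(fragment_smiles) == 1L) m[1L, ] else m
}

mqn_one <- function(smiles) {
  g <- hcap_graph(smiles_to_graph(smiles))
  n <- n_atoms(g)
  v <- stats::setNames(numeric(42L), mqn_names)
  if (n == 0L) return(v)
  sym <- g$symbol
  deg <- heavy_degree(g)
  ai <- aromatic_info(g)
  rings <- ai$rings
  in_ring_atom <- logical(n)
  for (r in rings) in_ring_atom[r] <- TRUE
  rbf <- ring_bond_flags(g)
  hs <- implicit_h(g)

  v["c"] <- sum(sym == "C")
  v["f"] <- sum(sym == "F")
  v["cl"] <- sum(sym == "Cl")
  v["br"] <- sum(sym == "Br")
  v["i"] <- sum(sym == "I")
  v["s"] <- sum(sym == "S")
  v["p"] <- sum(sym == "P")
  v["an"] <- sum(sym == "N" & !in_ring_atom)
  v["cn"] <- sum(sym == "N" & in_ring_atom)
  v["ao"] <- sum(sym == "O" & !in_ring_atom)
  v["co"] <- sum(sym == "O" & in_ring_atom)
  v["hac"] <- n

  ord <- g$bond[, 3L]
  v["asb"] <- sum(!rbf & ord == 1L)
  v["adb"] <- sum(!rbf & ord == 2L)
  v["atb"] <- sum(!rbf & ord == 3L)
  v["csb"] <- sum(rbf & ord == 1L)
  v["cdb"] <- sum(rbf & ord == 2L)
  v["ctb"] <- sum(rbf & ord == 3L)
  if (nrow(g$bond)) {
    rot <- !rbf & ord == 1L &
      deg[g$bond[, 1L]] >= 2L & deg[g$bond[, 2L]] >= 2L
    v["rbc"] <- sum(rot)
  }

  acceptor <- (sym == "N" | sym == "O") & g$charge <= 0L
  v["hba"] <- sum(acceptor)
  v["hbam"] <- sum(ifelse(sym[acceptor] == "O", 2L, 1L))
  donor_h <- ifelse(sym %in% c("N", "O"), hs + pmax(0L, g$charge), 0L)
  v["hbd"] <- sum(donor_h > 0L)
  v["hbdm"] <- sum(donor_h)
  v["neg"] <- sum(g$charge < 0L)
  v["pos"] <- sum(g$charge > 0L)

  v["asv"] <- sum(!in_ring_atom & deg == 1L)
  v["adv"] <- sum(!in_ring_atom & deg == 2L)
  v["atv"] <- sum(!in_ring_atom & deg == 3L)
  v["aqv"] <- sum(!in_ring_atom & deg >= 4L)
  v["cdv"] <- sum(in_ring_atom & deg == 2L)
  v["ctv"] <- sum(in_ring_atom & deg == 3L)
  v["cqv"] <- sum(in_ring_atom & deg >= 4L)

  sizes <- lengths(rings)
  for (k in 3:9) v[paste0("r", k)] <- sum(sizes == k)
  v["rg10"] <- sum(sizes >= 10L)
  if (length(rings) >= 2L) {
    atom_cnt <- integer(n)
    for (r in rings) atom_cnt[r] <- atom_cnt[r] + 1L
    v["afr"] <- sum(atom_cnt >= 2L)
    bond_cnt <- integer(nrow(g$bond))
    for (r in rings) {
      inr <- g$bond[, 1L] %in% r & g$bond[, 2L] %in% r
      bond_cnt[inr] <- bond_cnt[inr] + 1L
    }
    v["bfr"] <- sum(bond_cnt >= 2L)
  }
  v
}

#' MQN similarity between two descriptor vectors
#'
#' `S = 1 / (1 + mean(|a - b|))`: 1 for identical vectors, strictly
#' decreasing in the mean absolute descriptor difference, always positive.
#'
#' @param a,b numeric vectors of length 42 (see [mqn_descriptors()]).
#' @return similarity score in `(0, 1]`.
#' @examples
#' mqn_similarity(mqn_descriptors("*C"), mqn_descriptors("*CC"))
#' @export
mqn_similarity <- function(a, b) {
  if (length(a) != 42L || length(b) != 42L)
    stop("MQN vectors must have length 42", call. = FALSE)
  1 / (1 + mean(abs(a - b)))
}
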