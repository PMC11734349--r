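# Shared helpers: brute-force oracles and small generators used across the
# suite. The oracles deliberately avoid the package's own algorithmic paths.

# Exhaustive maximum over all monotone partial matchings of a similarity
# matrix (zero gap penalty): independent oracle for the DP alignment score.
brute_force_alignment_score <- function(S) {
  n <- nrow(S); m <- ncol(S)
  rec <- function(qi, tj) {
    if (qi > n || tj > m) return(0)
    best <- rec(qi + 1L, tj)            # leave q_i unmatched
    for (j in tj:m) {
      best <- max(best, S[qi, j] + rec(qi + 1L, j + 1L))
    }
    best
  }
  rec(1L, 1L)
}

# All permutations of a vector (for factorial assignment brute force).
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  do.call(c, lapply(seq_along(v), function(i) {
    lapply(all_perms(v[-i]), function(p) c(v[i], p))
  }))
}

# Identity similarity over tokens.
identity_sim <- function(q, t) as.numeric(q == t)

# Random token series drawn from the fixture substituent vocabulary.
random_series <- function(len, tokens = c("*C", "*CC", "*CCC", "*O", "*OC",
                                          "*N", "*F", "*Cl", "*Br", "*C#N")) {
  sample(tokens, len, replace = FALSE)
}

# Tiny embedding model with hand-set vectors, bypassing training.
toy_model <- function(vectors) {
  structure(list(vocabulary = rownames(vectors), vectors = vectors,
                 counts = rep(1L, nrow(vectors)),
                 params = list(vector_size = ncol(vectors),
                               architecture = "cbow")),
            class = "efv_model")
}

# A small, chemically diverse molecule set for round-trip fragmentation
# checks (all parse with OpenBabel; several bear charges, rings, branches).
fixture_molecules <- function() {
  subs <- c("*C", "*CC", "*CCC", "*C(C)C", "*O", "*OC", "*N", "*F", "*Cl",
            "*Br", "*C#N", "*C(F)(F)F", "*CO")
  scafs <- c("*c1ccc(Oc2ccccc2)cc1", "*c1ccc(-c2ccccc2)cc1",
             "*c1ccc(C(=O)Nc2ccccc2)cc1", "*C1CCN(c2ccccc2)CC1")
  mols <- as.vector(outer(seq_along(scafs), seq_along(subs),
                          Vectorize(function(i, j)
                            attach_fragments(scafs[i], subs[j]))))
  unique(mols)
}

# Exact minimum assignment cost by exhaustive search over all ways of
# assigning the i-th point given a used-cell set (subset recursion over the
# full solution space; equivalent to enumerating every injective
# point-to-cell map). Independent of the shortest-augmenting-path solver.
min_assignment_exhaustive <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  best <- rep(Inf, 2^m)
  best[1L] <- 0
  sizes <- vapply(0:(2^m - 1L), function(s) sum(bitwAnd(s, 2^(0:(m - 1L))) > 0),
                  numeric(1))
  for (s in order(sizes)) {
    S <- s - 1L
    i <- sizes[s]                 # points 1..i already placed
    if (i >= n || !is.finite(best[s])) next
    for (j in seq_len(m)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(S, bit) > 0L) next
      s2 <- bitwOr(S, bit) + 1L
      val <- best[s] + cost[i + 1L, j]
      if (val < best[s2]) best[s2] <- val
    }
  }
  min(best[sizes == n])
}
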