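---
title: "Methods: analogue series alignment and SAR transfer with context-dependent fragment embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analogue series alignment and SAR transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and procedures implemented in
`sartransfer`, the assumptions behind them, the parameters that matter, and
the design decisions taken where more than one reasonable choice existed.

## The problem

Analogue series (AS) arise whenever medicinal chemists optimise a hit: a
shared core structure is decorated with a succession of substituents, and
the measured potencies order those substituents into a progression. Two
series — possibly on different cores and against different targets — that
pair corresponding substituents with a comparable potency progression are a
*SAR transfer* event: the longer series predicts which substituent would
extend the shorter one with a gain in potency. The package finds such pairs
by (i) extracting potency-ordered series from activity tables, (ii) scoring
substituent similarity, (iii) aligning series by dynamic programming, and
(iv) searching a series database for high-scoring longer partners.

## Series extraction

Compounds are fragmented at every acyclic single bond between two heavy
atoms (a single-cut matched-molecular-pair scheme). The side of a cut
qualifies as the *value* (substituent) fragment when it has at most 12 heavy
atoms and at most 30 % of the source compound's heavy atoms; the complement
is the *key* (core). When both sides qualify, both orientations are kept.
Molecules with more than 20 cuttable bonds are skipped — the usual guard
against combinatorial blow-up in matched-pair fragmentation. An activity
table is first reduced to rows with standard relation `"="` and assay
confidence at least 9 (when those columns exist), and nanomolar IC50 values
are converted once to pIC50 = 9 − log10(IC50/nM), so every internal potency
is a pIC50 and ascending order means increasing potency.

Series are groups of at least three compounds sharing `(target, document,
key)` with distinct value fragments, ordered by ascending potency. Grouping
by document prevents series assembled across unrelated publications.
Three decisions here are genuinely open and were fixed as follows:

- **Attachment points** are written as a single unlabeled wildcard atom
  (`*`) and every fragment is canonicalised after cutting, so identical
  substituents from different compounds compare equal as strings — string
  equality is the backbone of grouping, embedding vocabulary construction
  and alignment lookup.
- **Duplicate value fragments** within a group keep the most potent member
  (ties by compound identifier). This preserves the series' upper potency
  envelope, which is what transfer search reasons about.
- **Potency ties** order members by the lexicographic order of the
  canonical value SMILES, making the training "sentences" deterministic.

## Substituent similarity

Two measures are provided behind one interface.

**Conventional fragment representation (CFR).** The arithmetic mean of (a)
the Tanimoto coefficient over Morgan (circular) fingerprints with radius 2
folded to 1024 bits and (b) MQN similarity
`S = 1/(1 + mean(|MQN_i − MQN_j|))` over 42 molecular quantum number
descriptors (atom, bond, polarity and topology counts). Both components
have maximum 1 for identical fragments, so `cfr(f, f) = 1` exactly.
Because descriptors are undefined for a wildcard atom, the attachment point
is replaced by a hydrogen before any descriptor or fingerprint is computed
— the least-assuming completion, recorded prominently because printed
similarity values elsewhere may rest on a different convention. The
Tanimoto of two empty bit sets is defined as 1; it can only arise for the
bare-hydrogen fragment. The fingerprints and MQN counts are computed by
this package on its own molecular-graph layer (atom invariants hashed
iteratively over bond neighbourhoods; Hückel-style aromaticity perception
over the smallest set of smallest rings), with OpenBabel supplying parsing
and canonical SMILES. The implementations satisfy the documented contracts
(42 dimensions, determinism, kekulisation-stable bits) but are not intended
to be bit-compatible with any other toolkit's fingerprints or descriptor
values.

**Embedded fragment vectors (EFV).** Every series is a sentence whose words
are canonical value-fragment SMILES in ascending-potency order. A
continuous-bag-of-words word2vec model predicts a token from the mean of
its context tokens' input vectors; after training, the input weight matrix
(vocabulary × k) holds one embedded fragment vector per token. Pinned
hyperparameters: vector size 100, window 5 (with the customary per-token
dynamic window shrinkage), min_count 1, CBOW architecture, seed 8, one
worker. The training internals that remain open — objective, epochs,
learning rate — follow the reference word2vec defaults: negative sampling
with 5 noise words drawn from the unigram^0.75 distribution, 5 epochs, and
a learning rate decaying linearly from 0.025 to 1e-4; all of them are
recorded in the returned model object so runs are fully reproducible.
Training is single-threaded with an internal deterministic generator, so a
fixed seed yields bit-identical embeddings. Similarity is the cosine of two
EFVs, in [−1, 1].

**Analogy queries.** The vocabulary is ranked by cosine to
`(EFV(a) − EFV(b)) + EFV(c)`. Input tokens are *not* excluded by default:
reported rank positions then refer to the full vocabulary, which is the
convention that makes rank statements comparable across queries (an
exclusion flag exists). A degenerate query with `a = b` provably returns
`c` at rank 1 with cosine 1.

## Series alignment

With `s(q_i, t_j)` the substituent similarity, the alignment grid is filled
by

    D(i, j) = max{ D(i−1, j−1) + s(q_i, t_j),  D(i−1, j) − gap,  D(i, j−1) − gap }

with `D(0,0) = 0` and gap penalty 0 — series are short compared to
biological sequences, so gaps are free and the first row and column are
zero. The traceback from `D(n, m)` prefers diagonal over up over left on
ties, which favours matched columns and makes alignments deterministic.

The score is normalised by series length. Which length is not forced by the
recurrence; the package divides by `min(n, m)`, so a query perfectly
contained in a longer target scores exactly 1 — the semantics transfer
search needs. `max`, `query` and `target` denominators are available as
options. When similarities lie in [0, 1] the normalised score does too;
EFV cosines can be negative, in which case scores may leave that range
unless the clamp-at-zero option is used (negative similarities are not
clamped by default).

## Transfer search and the bioisostere statistic

A query of length *n* is aligned against all database series with length in
`[n + k_min, n + k_max]` (self-matches excluded); hits are ranked by
normalised score with ties broken by series identifier. Substituents at
target positions beyond the query's last matched position are *transfer
values*; attaching them to the query's key yields proposed transfer
analogues, de-duplicated against existing members and canonicalised.

The bioisostere counting experiment takes queries sharing one terminal
substituent (e.g. carboxyl), a database purged of series containing that
substituent, and a list of qualifying replacements. For each query it
counts, among the top 100 alignments, those where the terminal position is
matched to a listed bioisostere *or* a transfer value is listed — both
readings of "aligned with" are counted. The 13-entry default list of
non-classical carboxyl bioisosteres shipped in
`inst/extdata/carboxyl_bioisosteres.smi` is curated from standard
medicinal-chemistry practice and is deliberately a user-editable
configuration file, not a reference standard.

## Molecular grid maps

Fragment vectors are reduced to the top 10 principal components, then
embedded in 2D by exact t-SNE (perplexity 10, 3000 gradient iterations,
early exaggeration 12, momentum 0.5→0.8, adaptive gains). The initial
layout is drawn from a seeded generator and the optimisation is
deterministic, so maps are reproducible. For fewer than 31 points the
perplexity is reduced to `(n−1)/3` with a warning; fewer than 3 points is
an error.

Grid sizing follows `cols = floor(sqrt(n))`, `rows = ceiling(n / cols)` —
the near-square rule under which the 26,795-fragment vocabulary yields a
165 × 163 lattice with 100 dummy cells. (A rule that globally minimised
wasted cells would degenerate: any `n` admits a zero-waste `n × 1`
factorisation, and 26,795 = 233 × 115 exactly; the adopted rule is the one
that keeps the lattice near-square while wasting as few cells as that
column count allows.) Points are min-max normalised onto the lattice of cell centres —
so a perfect rectangular arrangement of points can reach assignment cost
0 — and assigned to distinct cells by a shortest-augmenting-path solver of
the Jonker–Volgenant family, minimising total squared Euclidean distance;
surplus cells become dummy cells. Dummies exist only at the assignment
stage; they take no part in the 2D embedding. Property layers (MW, LogP,
TPSA from OpenBabel's contribution models; heavy atoms, aromatic rings and
Fsp3 from the package's own perception) are attached per assigned cell.

## Synthetic fixtures

The generator emulates the structure the method assumes, not real potency
landscapes. Compounds are scaffold–substituent attachments over a pool of
8 scaffolds (10–15 heavy atoms) and 20 small substituents (1–4 heavy
atoms, so every planted cut passes both value filters); potency is
`base + effect(substituent) + Normal(0, σ)` with additive effects spaced
0.25 pIC50 apart and σ = 0.2 pIC50 by default — effect gaps comfortably
above the noise, so planted orderings survive sampling most of the time,
while decoys draw shuffled effects that destroy the shared progression.
Planted partner pairs put the same substituent sequence on two different
scaffolds, the partner extended by one extra top-effect member. At σ = 0
extraction provably recovers every planted series in exact effect order;
extraction may also surface additional genuine series (e.g. a shared ether
key when several substituents contain oxygen), which is correct behaviour,
so recovery tests assert containment rather than equality. The analogy
corpus pairs two token families position by position and draws each
sentence token from either family at random, making paired tokens
interchangeable in context; filler tokens live in separate sentences.

What passing these tests shows — and does not show: they demonstrate that
extraction inverts the generator, that alignment and assignment match
exhaustive enumeration, and that embedding similarity responds to planted
context structure. They do not demonstrate performance on real medicinal
chemistry data, where potency noise is not Gaussian, series share
substituent chemistry far more heavily, and vocabulary sizes are three
orders of magnitude larger.

## Numerical choices and problem sizes

- Alignment oracle checks enumerate all monotone matchings for series up to
  length 6 (500 random pairs); assignment optimality is checked against
  exhaustive search for up to 7 points.
- Transfer-partner recovery uses 20 generator seeds with 20 decoys at
  σ = 0.2 pIC50; embedding context checks use 10 seeds with corpora of
  200–300 sentences and 32-dimensional vectors. These sizes make the full
  suite run in a few minutes on one CPU while keeping every statistical
  margin wide.
- t-SNE uses 64-bit arithmetic throughout; determinism relies on fixed
  iteration order, not on tolerance thresholds.
- Degenerate inputs: empty corpora, all-zero vectors, non-finite
  similarities, grids smaller than the point count and unparsable SMILES
  all raise immediate errors naming the offending entity; unparsable
  fragments in property layers are skipped with a warning and flagged as
  `NA`.

## Known limitations

- OpenBabel's LogP/TPSA contribution models differ numerically from other
  toolkits'; property layers are comparable within a map, not across
  toolkits.
- Aromaticity perception is Hückel-style over 5- and 6-membered rings;
  exotic aromatic systems (azulenes, large annulenes) are treated as
  non-aromatic, which slightly perturbs fingerprints, MQN ring counts and
  Fsp3 for such fragments.
- Multi-cut fragmentation, stereochemistry-aware duplicate merging,
  skip-gram embeddings and local alignment are out of scope.
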