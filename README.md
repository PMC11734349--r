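# sartransfer

Analogue series (AS) — sets of compounds sharing a core structure (the *key*
fragment) and differing in one substituent (the *value* fragment) — are the
primary carriers of structure–activity relationship (SAR) information in
medicinal chemistry. Two series with corresponding substituents and a
comparable potency progression constitute a **SAR transfer** event: the longer
series suggests which substituent to attach next to the shorter series' core
to gain potency. `sartransfer` implements this search end to end for
computational and medicinal chemists:

1. **Series extraction** — single-cut matched-molecular-pair fragmentation of
   every acyclic single bond (value fragments capped at 12 heavy atoms and
   30 % of the source compound), grouping by target, publication and key
   fragment, with members ordered by ascending pIC50.
2. **Substituent similarity**, two ways:
   - *Conventional* (CFR): the mean of the Morgan-fingerprint Tanimoto
     coefficient (radius 2, 1024 bits) and MQN similarity
     `S = 1 / (1 + mean(|MQN_i − MQN_j|))` over the 42 molecular quantum
     number descriptors.
   - *Context-dependent* (EFV): each series is a "sentence" of substituent
     tokens ordered by potency; a CBOW word2vec model (vector size 100,
     window 5, min_count 1, seed 8, single worker) is trained on the corpus
     and each token's row of the input weight matrix is its embedded
     fragment vector. Similarity is the cosine
     `S = EFV_i · EFV_j / (‖EFV_i‖ ‖EFV_j‖)`, and word-pair-relationship
     queries `(a − b) + c` rank candidate substituents in context.
3. **Series alignment** — global dynamic programming with
   `D(i,j) = max{ D(i−1,j−1) + s(q_i,t_j), D(i−1,j) − gap, D(i,j−1) − gap }`,
   `D(0,0) = 0` and zero gap penalty; the traceback from `D(n,m)` yields the
   alignment and the score is normalised by series length into [0, 1].
4. **Transfer search** — a query of length *n* is aligned against database
   series of length *n + k*; top-ranked targets contribute substituents
   beyond the query's terminal analogue, which are reattached to the query
   key as proposed transfer analogues. A counting experiment reports how
   often listed non-classical bioisosteres pair with a chosen terminal group
   (e.g. carboxyl) across top-ranked alignments.
5. **Molecular grid maps** — PCA (top 10 components) → t-SNE (perplexity 10,
   3000 iterations) → Jonker–Volgenant linear assignment of fragments onto a
   near-square cell lattice, with MW, LogP, TPSA, heavy-atom, aromatic-ring
   and Fsp3 layers.

A synthetic-fixture module generates scaffold/substituent compound tables
with planted potency gradients, planted transfer partners and planted
analogy patterns, so everything is testable without external data.

Chemistry (SMILES parsing, canonicalisation, MW/LogP/TPSA) runs on OpenBabel
via `ChemmineOB`; fingerprints, MQN descriptors, CBOW training, t-SNE and
the assignment solver are implemented in the package (R and Rcpp).

## Worked example

```r
library(sartransfer)

fx     <- generate_compound_table(fixture_spec(seed = 1))  # 22 planted series
series <- build_series(fx$compounds)                       # extraction
q      <- series[[1]]                                      # a planted query
print(q)
#> Analogue series AS00001
#>   key:       *c1ccc(cc1)CCc1ccccc1
#>   target:    TGT_SER001   document: DOC_SER001
#>   members (6, ascending potency):
#>      1. *C                   pIC50 4.94
#>      2. *CC                  pIC50 5.26
#>      3. *C(C)C               pIC50 5.63
#>      4. *OC                  pIC50 6.61
#>      5. *F                   pIC50 7.20
#>      6. *Br                  pIC50 8.06

frags <- unique(unlist(lapply(series, `[[`, "values")))
sim   <- sim_from_matrix(build_similarity_matrix(frags, "cfr"))
hits  <- transfer_search(q, series, sim, k_min = 1, top_n = 3)
print(hits[[1]]$alignment)
#> Series alignment (AS00001 vs AS00002)
#>   raw score: 6  normalized ( min ): 1
#>   pIC50 : 4.94 5.26 5.63   6.61 7.20 8.06
#>   query : *C   *CC  *C(C)C *OC  *F   *Br  -
#>           |    |    |      |    |    |    -
#>   target: *C   *CC  *C(C)C *OC  *F   *Br  *S
#>   pIC50 : 4.69 5.19 5.64   6.37 7.49 7.62 9.74
hits[[1]]$proposed_smiles
#> [1] "Sc1ccc(cc1)CCc1ccccc1"
```

The top hit is the planted partner series on a different scaffold: all six
query substituents align exactly (normalised score 1), and the partner's
seventh, more potent member (`*S`, pIC50 9.7) is proposed as a transfer
analogue by attaching it to the query's own core.

Embeddings and grid maps follow the same pattern:

```r
model  <- train_efv(series_corpus(series))        # CBOW EFVs, deterministic
similar_fragments(model, "*Br", k = 5)            # context-dependent search
analogy_query(model, a, b, c, k = 10)             # (a - b) + c ranking
gm <- build_grid_map(model, seed = 1)             # PCA -> t-SNE -> assignment
plot(gm, layer = "LogP")
```

A thin CLI over the same functions lives at
`inst/scripts/sartransfer-cli.R` (stages `extract-series`,
`train-embeddings`, `simsearch`, `analogy`, `align`, `transfer-search`,
`gridmap`).

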