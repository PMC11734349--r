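# Synthetic fixtures: combinatorial scaffold + substituent compound tables
# with planted potency gradients, planted SAR-transfer partner pairs and
# planted analogy patterns, so the whole pipeline is testable without any
# external compound database. Substituent effects are additive in pIC50
# with Gaussian noise -- the simplest model producing the comparable potency
# progressions that SAR transfer assumes.

fixture_scaffolds <- c(
  "*c1ccc(Oc2ccccc2)cc1",
  "*c1ccc(-c2ccccc2)cc1",
  "*c1ccc(CNc2ccccc2)cc1",
  "*c1ccc(C(=O)Nc2ccccc2)cc1",
  "*C1CCN(c2ccccc2)CC1",
  "*c1ccc(CCc2ccccc2)cc1",
  "*c1ccc(NC(=O)c2ccccn2)cc1",
  "*c1ccc(COc2ccccc2)cc1")

fixture_substituents <- c(
  "*C", "*CC", "*CCC", "*C(C)C", "*CC(C)C", "*O", "*OC", "*OCC",
  "*N", "*NC", "*F", "*Cl", "*Br", "*I", "*C#N", "*C(F)(F)F",
  "*C=C", "*CO", "*S", "*SC")

#' Specification for a synthetic compound-table fixture
#'
#' @param n_partner_pairs planted SAR-transfer pairs: a query series and a
#'   longer partner series sharing the same substituent sequence and effect
#'   ordering on a different scaffold (default 1).
#' @param n_decoys decoy series with shuffled substituent effects
#'   (default 20).
#' @param series_length query-series length range (default `c(6, 8)`).
#' @param partner_extension extra top-potency members of each planted
#'   partner beyond the query length (default 1).
#' @param scaffold_base_potency baseline pIC50 per series (default 5).
#' @param substituent_effects named numeric vector of per-substituent
#'   `ΔpIC50` values; defaults to evenly spaced effects (0.25 pIC50 steps)
#'   over the built-in 20-substituent vocabulary.
#' @param noise_sd Gaussian potency noise, pIC50 units (default 0.2).
#' @param scaffolds pool of scaffold SMILES with one attachment point.
#' @param seed integer fixing all randomness.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_partner_pairs = 1L, n_decoys = 20L,
                         series_length = c(6L, 8L), partner_extension = 1L,
                         scaffold_base_potency = 5,
                         substituent_effects = NULL, noise_sd = 0.2,
                         scaffolds = fixture_scaffolds, seed = 1L) {
  if (is.null(substituent_effects)) {
    substituent_effects <- stats::setNames(
      seq(0, by = 0.25, length.out = length(fixture_substituents)),
      fixture_substituents)
  }
  stopifnot(noise_sd >= 0, n_partner_pairs >= 0L, n_decoys >= 0L,
            length(series_length) == 2L, partner_extension >= 0L)
  structure(list(n_partner_pairs = as.integer(n_partner_pairs),
                 n_decoys = as.integer(n_decoys),
                 series_length = as.integer(series_length),
                 partner_extension = as.integer(partner_extension),
                 scaffold_base_potency = scaffold_base_potency,
                 substituent_effects = substituent_effects,
                 noise_sd = noise_sd,
                 scaffolds = scaffolds,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

with_fixture_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic compound-activity table with ground truth
#'
#' Builds compounds as scaffold-substituent attachments. Potency is
#' `base + effect(substituent) + Normal(0, noise_sd)`. Planted partner pairs
#' are two series on different scaffolds (and different targets/documents)
#' sharing the same substituent set and effect ordering, the partner
#' carrying `partner_extension` extra top-effect members; decoy series draw
#' a random substituent subset whose effects are shuffled, destroying the
#' shared progression. At `noise_sd = 0` the potency order of every planted
#' series equals its effect order exactly.
#'
#' @param spec a [fixture_spec()].
#' @return list with `compounds` (data.frame in the activity-table dialect:
#'   `compound_id`, `smiles`, `potency` (pIC50), `target_id`,
#'   `document_id`) and `ground_truth` (per-series key, substituent order
#'   and role, plus the planted `partners` pairing table).
#' @export
generate_compound_table <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  effects <- spec$substituent_effects
  vocab <- names(effects)
  can_vocab <- canonical_smiles(vocab)
  can_scaf <- canonical_smiles(spec$scaffolds)
  with_fixture_seed(spec$seed, {
    series_plan <- list()
    partners <- data.frame(query_series = character(0),
                           partner_series = character(0),
                           stringsAsFactors = FALSE)
    add_series <- function(role, scaffold_i, subs_in_effect_order) {
      id <- sprintf("SER%03d", length(series_plan) + 1L)
      series_plan[[length(series_plan) + 1L]] <<- list(
        id = id, role = role, scaffold = spec$scaffolds[scaffold_i],
        key_smiles = can_scaf[scaffold_i],
        substituents = subs_in_effect_order)
      id
    }
    for (p in seq_len(spec$n_partner_pairs)) {
      len <- sample(seq(spec$series_length[1L], spec$series_length[2L]), 1L)
      ext <- spec$partner_extension
      subs <- sample(vocab, len + ext)
      subs <- subs[order(effects[subs])]
      scafs <- sample(seq_along(spec$scaffolds), 2L)
      qid <- add_series("query", scafs[1L], subs[seq_len(len)])
      pid <- add_series("partner", scafs[2L], subs)
      partners <- rbind(partners,
                        data.frame(query_series = qid, partner_series = pid,
                                   stringsAsFactors = FALSE))
    }
    for (d in seq_len(spec$n_decoys)) {
      len <- sample(seq(spec$series_length[1L], spec$series_length[2L]), 1L)
      subs <- sample(vocab, len)
      # shuffled effects: a random permutation of the subset's effect values
      add_series("decoy", sample(seq_along(spec$scaffolds), 1L), subs)
    }
    rows <- list()
    truth_series <- list()
    for (k in seq_along(series_plan)) {
      sp <- series_plan[[k]]
      subs <- sp$substituents
      eff <- if (sp$role == "decoy") sample(effects[subs]) else effects[subs]
      pot <- spec$scaffold_base_potency + as.numeric(eff) +
        stats::rnorm(length(subs), sd = spec$noise_sd)
      smi <- attach_fragments(sp$scaffold, subs)
      target <- paste0("TGT_", sp$id)
      doc <- paste0("DOC_", sp$id)
      rows[[k]] <- data.frame(
        compound_id = sprintf("%s_C%02d", sp$id, seq_along(subs)),
        smiles = smi, potency = pot, target_id = target, document_id = doc,
        stringsAsFactors = FALSE)
      truth_series[[k]] <- list(
        series_id = sp$id, role = sp$role, target_id = target,
        document_id = doc, key_smiles = sp$key_smiles,
        substituents_by_effect = unname(can_vocab[match(subs, vocab)]),
        effects = as.numeric(eff))
    }
    list(compounds = do.call(rbind, rows),
         ground_truth = list(series = truth_series, partners = partners,
                             substituent_effects =
                               stats::setNames(as.numeric(effects),
                                               unname(can_vocab))))
  })
}

#' Generate a corpus with planted analogy structure
#'
#' Two token families `A` and `B` are paired position by position; every
#' sentence is an ascending window over positions with each token drawn from
#' either family at random, so paired tokens occur in interchangeable
#' contexts. Filler tokens occur only in separate all-filler sentences
#' (unrelated contexts). Ground-truth quadruples `(a, b, c, expected)` state
#' that ranking the vocabulary by cosine to `(EFV(a) - EFV(b)) + EFV(c)`
#' should place `expected` highly.
#'
#' @param n_sentences number of patterned sentences (default 400).
#' @param n_filler_sentences all-filler sentences (default 80).
#' @param family_a,family_b paired token vocabularies (equal length >= 4).
#' @param fillers unrelated tokens.
#' @param sentence_length range of sentence lengths (default `c(3, 6)`).
#' @param seed integer seed.
#' @return list `corpus` (list of token vectors), `quadruples` (data.frame
#'   `a`, `b`, `c`, `expected`), `interchangeable` (data.frame `x`, `y` of
#'   same-context pairs), `unrelated` (filler tokens).
#' @export
generate_analogy_corpus <- function(n_sentences = 400L,
                                    n_filler_sentences = 80L,
                                    family_a = c("*C", "*CC", "*CCC",
                                                 "*C(C)C", "*CC(C)C",
                                                 "*C1CCCC1", "*C1CCCCC1",
                                                 "*CCCC"),
                                    family_b = c("*F", "*Cl", "*Br", "*I",
                                                 "*O", "*OC", "*N", "*C#N"),
                                    fillers = c("*CO", "*CCO", "*OCC", "*CS",
                                                "*CN", "*CCN"),
                                    sentence_length = c(3L, 6L),
                                    seed = 1L) {
  m <- length(family_a)
  stopifnot(length(family_b) == m, m >= 4L,
            sentence_length[1L] >= 3L, sentence_length[2L] <= m)
  with_fixture_seed(seed, {
    corpus <- vector("list", n_sentences + n_filler_sentences)
    for (s in seq_len(n_sentences)) {
      len <- sample(seq(sentence_length[1L], sentence_length[2L]), 1L)
      start <- sample(seq_len(m - len + 1L), 1L)
      pos <- seq.int(start, start + len - 1L)
      pick_b <- stats::runif(len) < 0.5
      corpus[[s]] <- ifelse(pick_b, family_b[pos], family_a[pos])
    }
    for (s in seq_len(n_filler_sentences)) {
      len <- sample(seq(3L, length(fillers)), 1L)
      corpus[[n_sentences + s]] <- sample(fillers, len)
    }
    pairs <- utils::combn(m, 2L)
    quadruples <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1L, k]; j <- pairs[2L, k]
      data.frame(a = family_b[j], b = family_a[j], c = family_a[i],
                 expected = family_b[i], stringsAsFactors = FALSE)
    }))
    list(corpus = corpus,
         quadruples = quadruples,
         interchangeable = data.frame(x = family_a, y = family_b,
                                      stringsAsFactors = FALSE),
         unrelated = fillers)
  })
}

#' Write a fixture compound table in the standard CSV dialect
#'
#' @param fixture result of [generate_compound_table()].
#' @param path CSV path for the compound table.
#' @param truth_path optional JSON path for the ground truth.
#' @export
write_fixture_csv <- function(fixture, path, truth_path = NULL) {
  utils::write.csv(fixture$compounds, path, row.names = FALSE, quote = FALSE)
  if (!is.null(truth_path)) {
    jsonlite::write_json(fixture$ground_truth, truth_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
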