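# Pipeline glue: a resolved run configuration plus one entry point per
# stage, each reading and writing the package's documented on-disk formats
# (activity CSV/TSV in, series JSON Lines, word2vec text models, TSV
# similarity matrices and grid maps). Every artifact gets a JSON sidecar
# with the resolved configuration and package version.

#' Assemble a run configuration
#'
#' Collects all tunable parameters of the pipeline with defaults matching
#' the package's standard settings (single-cut fragmentation with the
#' 12-atom / 30 percent value filters, Morgan radius 2 / 1024 bits, CBOW
#' with vector size 100 / window 5 / min_count 1 / seed 8, min-length
#' alignment normalisation, t-SNE perplexity 10 / 3000 iterations).
#' Unknown names are rejected.
#'
#' @param ... name = value overrides of the defaults.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    input = NULL, series = NULL, model = NULL, output = NULL,
    query = NULL, db = NULL,
    min_size = 3L, max_cut_bonds = 20L,
    max_value_atoms = 12L, max_value_fraction = 0.30,
    potency_units = "pIC50", relation_column = NULL, confidence_column = NULL,
    fp_radius = 2L, fp_nbits = 1024L,
    vector_size = 100L, window = 5L, min_count = 1L, embed_seed = 8L,
    negative = 5L, epochs = 5L,
    sim = "cfr", normalize = "min", clamp = FALSE,
    k_min = 1L, k_max = Inf, top_n = 10L,
    grid_seed = 1L, perplexity = 10, tsne_iter = 3000L,
    analogy_a = NULL, analogy_b = NULL, analogy_c = NULL, sim_query = NULL,
    k = 10L)
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(override)] <- override
  structure(cfg, class = "run_config")
}

write_sidecar <- function(path, config, stage) {
  meta <- list(stage = stage,
               package = "sartransfer",
               version = as.character(utils::packageVersion("sartransfer")),
               config = unclass(config))
  meta$config$k_max <- if (is.finite(config$k_max)) config$k_max else "Inf"
  jsonlite::write_json(meta, paste0(path, ".config.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
}

need <- function(config, field, stage) {
  v <- config[[field]]
  if (is.null(v)) stop("stage '", stage, "' requires config field '", field,
                       "'", call. = FALSE)
  if (field %in% c("input", "series", "model", "query", "db") &&
      !file.exists(v))
    stop("missing input file for '", field, "': ", v, call. = FALSE)
  v
}

pipeline_sim <- function(config, fragments) {
  if (config$sim == "efv") {
    model <- read_word2vec(need(config, "model", "similarity"))
    sim_from_matrix(build_similarity_matrix(fragments, "efv", model = model))
  } else {
    sim_from_matrix(build_similarity_matrix(fragments, "cfr",
                                            radius = config$fp_radius,
                                            nbits = config$fp_nbits))
  }
}

#' Run one pipeline stage
#'
#' Stages: `extract-series` (activity table -> series JSONL),
#' `train-embeddings` (series JSONL -> word2vec text model),
#' `simsearch` (model + query token -> top-k TSV),
#' `analogy` (model + three tokens -> top-k TSV),
#' `align` (two series files -> alignment JSON),
#' `transfer-search` (query + database JSONL -> hits JSONL),
#' `gridmap` (model -> grid-map TSV).
#'
#' @param config a [run_config()].
#' @param stage stage name (above).
#' @return the main output path, invisibly.
#' @export
run_pipeline <- function(config, stage) {
  stopifnot(inherits(config, "run_config"))
  stages <- c("extract-series", "train-embeddings", "simsearch", "analogy",
              "align", "transfer-search", "gridmap")
  if (!stage %in% stages)
    stop("unknown stage '", stage, "'; available: ",
         paste(stages, collapse = ", "), call. = FALSE)
  out <- need(config, "output", stage)

  if (stage == "extract-series") {
    tab <- read_activity_table(need(config, "input", stage))
    tab <- filter_activity_table(tab,
                                 potency_units = config$potency_units,
                                 relation_column = config$relation_column,
                                 confidence_column = config$confidence_column)
    series <- build_series(tab, min_size = config$min_size,
                           max_cut_bonds = config$max_cut_bonds,
                           max_value_atoms = config$max_value_atoms,
                           max_value_fraction = config$max_value_fraction)
    write_series_jsonl(series, out)
  } else if (stage == "train-embeddings") {
    series <- read_series_jsonl(need(config, "series", stage))
    model <- train_efv(series_corpus(series),
                       vector_size = config$vector_size,
                       window = config$window, min_count = config$min_count,
                       seed = config$embed_seed, negative = config$negative,
                       epochs = config$epochs)
    write_word2vec(model, out)
  } else if (stage == "simsearch") {
    model <- read_word2vec(need(config, "model", stage))
    res <- similar_fragments(model, need(config, "sim_query", stage),
                             k = config$k)
    utils::write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (stage == "analogy") {
    model <- read_word2vec(need(config, "model", stage))
    res <- analogy_query(model, need(config, "analogy_a", stage),
                         need(config, "analogy_b", stage),
                         need(config, "analogy_c", stage), k = config$k)
    utils::write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (stage == "align") {
    qs <- read_series_jsonl(need(config, "query", stage))
    ts <- read_series_jsonl(need(config, "db", stage))
    frags <- unique(c(unlist(lapply(qs, `[[`, "values")),
                      unlist(lapply(ts, `[[`, "values"))))
    sim <- pipeline_sim(config, frags)
    con <- file(out, "wt"); on.exit(close(con), add = TRUE)
    for (q in qs) for (t in ts) {
      a <- align_series(q, t, sim, normalize = config$normalize,
                        clamp = config$clamp)
      rec <- list(query_id = q$series_id, target_id = t$series_id,
                  raw_score = a$raw_score,
                  normalized_score = a$normalized_score,
                  columns = a$columns, text = alignment_to_text(a))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                  na = "null"), con)
    }
  } else if (stage == "transfer-search") {
    qs <- read_series_jsonl(need(config, "query", stage))
    db <- read_series_jsonl(need(config, "db", stage))
    frags <- unique(c(unlist(lapply(qs, `[[`, "values")),
                      unlist(lapply(db, `[[`, "values"))))
    sim <- pipeline_sim(config, frags)
    con <- file(out, "wt"); on.exit(close(con), add = TRUE)
    for (q in qs) {
      hits <- transfer_search(q, db, sim, k_min = config$k_min,
                              k_max = config$k_max, top_n = config$top_n,
                              normalize = config$normalize,
                              clamp = config$clamp)
      for (h in hits) {
        rec <- list(query_id = q$series_id,
                    target_series_id = h$target_series_id,
                    normalized_score = h$alignment$normalized_score,
                    raw_score = h$alignment$raw_score,
                    transfer_values = h$transfer_values,
                    proposed_smiles = h$proposed_smiles)
        writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
      }
    }
  } else if (stage == "gridmap") {
    model <- read_word2vec(need(config, "model", stage))
    gm <- build_grid_map(model, seed = config$grid_seed,
                         perplexity = config$perplexity,
                         max_iter = config$tsne_iter)
    write_grid_map(gm, out)
  }
  write_sidecar(out, config, stage)
  invisible(out)
}
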