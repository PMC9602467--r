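#' Default run configuration
#'
#' A plain, fully serializable list describing one end-to-end run:
#' synthetic cohort and effects, fixture lexicon sizes (or paths to real
#' lexicon/stopword files), augmentation plan, split specification,
#' backend and grid, plus one global seed. Stage seeds are derived from
#' the global seed by a fixed rule (`derive index per stage`), so any
#' stage can be reproduced in isolation.
#'
#' The default grid here is a deliberately small portion of the full
#' 18-setting grid so a complete run stays interactive on one CPU; pass
#' the full [hyperparam_grid()] values to explore all settings.
#'
#' @param seed Global integer seed.
#' @param mode `"replication"` (sample-level splitting, the replicated
#'   protocol) or `"leakage-safe"` (origin-level splitting).
#' @param backend Backend name; `"baseline"` is the shipped default.
#' @return A named list, the run configuration.
#' @export
default_run_config <- function(seed = 1L, mode = c("replication", "leakage-safe"),
                               backend = "baseline") {
  mode <- match.arg(mode)
  list(
    seed = as.integer(seed),
    cohort = list(n_healthy = 45, n_mci = 15,
                  mmse_mean_hc = 29.3, mmse_sd_hc = 0.7,
                  mmse_mean_mci = 25.9, mmse_sd_mci = 1.0,
                  age_mean = 73.7, age_sd = 4.1),
    effects = list(pronoun_rate_hc = 0.08, pronoun_rate_mci = 0.22,
                   ttr_hc = 0.7, ttr_mci = 0.5,
                   event_coverage_hc = 0.9, event_coverage_mci = 0.6,
                   mean_len = 80, len_sd = 15, filler_rate = 0.05),
    n_topic_words = 40,
    lexicon_path = NULL, stopwords_path = NULL,
    stopword_exclusions = character(),
    synonyms_per_word = 3, stopword_fraction = 0.1,
    recording_markers = character(), max_len = 512,
    plan = list(multiplier_mci = 30, multiplier_hc = 10,
                include_original = TRUE,
                eda = list(alpha = 0.05, p_delete = 0.05,
                           operator_policy = "CYCLE",
                           insertion_mode = "DUPLICATE")),
    split = list(test_fraction = 0.20, validation_fraction = 0.10,
                 n_repeats = 2,
                 mode = if (mode == "replication") "SAMPLE_LEVEL" else "ORIGIN_LEVEL"),
    backend = backend,
    grid = list(batch_sizes = c(16, 32), learning_rates = c(2e-5),
                n_epochs = 4, early_stopping = TRUE, patience = 1)
  )
}

#' Load a run configuration from YAML
#'
#' Fields present in the file override the defaults of
#' [default_run_config()]; everything else keeps its default.
#'
#' @param path Path to a YAML file.
#' @param seed Optional seed overriding both file and default.
#' @return A run configuration list.
#' @export
load_run_config <- function(path, seed = NULL) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_run_config(), user)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

cfg_templates <- function(config) default_task_templates(config$n_topic_words)

cfg_resources <- function(config, out_dir) {
  vocab <- template_vocabulary(cfg_templates(config))
  lexicon <- if (!is.null(config$lexicon_path)) {
    load_synonyms(config$lexicon_path)
  } else {
    generate_fixture_lexicon(vocab, config$synonyms_per_word,
                             derive_seed(config$seed, 20L))
  }
  stopwords <- if (!is.null(config$stopwords_path)) {
    load_stopwords(config$stopwords_path, config$stopword_exclusions)
  } else {
    generate_fixture_stopwords(vocab, config$stopword_fraction)
  }
  write_synonyms(lexicon, file.path(out_dir, "lexicon.tsv"))
  write_stopwords(stopwords, file.path(out_dir, "stopwords.txt"))
  list(lexicon = lexicon, stopwords = stopwords)
}

pipeline_stages <- function() {
  c("generate", "clean", "augment", "split", "train", "report")
}

#' Run the end-to-end pipeline
#'
#' Chains the stages generate, clean, augment, split, train, report,
#' writing every artifact into `out_dir`: the raw and cleaned corpus and
#' the augmented dataset (JSON lines), the lexicon and stopword files
#' actually used, the split indices, the leakage audit, the grid report,
#' per-sample predictions, the evaluation report, a per-stage log of
#' sample counts, and a manifest embedding the configuration hash. A
#' subset of stages can be re-run against an existing directory; each
#' stage reads its inputs from the artifacts of the previous one.
#' Re-running with the same configuration and seed reproduces identical
#' artifacts for the baseline backend.
#'
#' @param config A run configuration (see [default_run_config()]).
#' @param out_dir Output directory, created if needed.
#' @param stages Character vector of stages to run, in pipeline order.
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir,
                         stages = pipeline_stages()) {
  stopifnot(all(stages %in% pipeline_stages()))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  log_path <- file.path(out_dir, "log.txt")
  log_line <- function(...) {
    cat(paste0(format(Sys.time(), "%H:%M:%S"), " ", ..., "\n"),
        file = log_path, append = TRUE)
  }
  log_line("run config hash ", hash, " seed ", config$seed)

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      log_line("stage ", name, " FAILED: ", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if ("generate" %in% stages) run_stage("generate", function() {
    corpus <- generate_corpus(
      spec = do.call(cohort_spec, config$cohort),
      effects = do.call(linguistic_effects, config$effects),
      templates = cfg_templates(config),
      seed = derive_seed(config$seed, 1L)
    )
    write_corpus_jsonl(corpus, file.path(out_dir, "corpus.jsonl"))
    log_line("generate: ", nrow(corpus), " samples (",
             sum(corpus$label == "MCI"), " MCI)")
  })

  if ("clean" %in% stages) run_stage("clean", function() {
    corpus <- read_corpus_jsonl(file.path(out_dir, "corpus.jsonl"))
    corpus$text <- clean_transcript(corpus$text, config$recording_markers,
                                    config$max_len)
    write_corpus_jsonl(corpus, file.path(out_dir, "cleaned.jsonl"))
    log_line("clean: ", nrow(corpus), " samples cleaned")
  })

  if ("augment" %in% stages) run_stage("augment", function() {
    corpus <- read_corpus_jsonl(file.path(out_dir, "cleaned.jsonl"))
    res <- cfg_resources(config, out_dir)
    eda_cfg <- config$plan$eda
    eda_cfg$seed <- derive_seed(config$seed, 2L)
    plan <- augmentation_plan(config$plan$multiplier_mci,
                              config$plan$multiplier_hc,
                              do.call(eda_params, eda_cfg),
                              config$plan$include_original)
    augmented <- balance_augment(corpus, plan, res$lexicon, res$stopwords)
    write_corpus_jsonl(augmented, file.path(out_dir, "augmented.jsonl"))
    log_line("augment: ", nrow(augmented), " samples (",
             sum(augmented$label == "MCI"), " MCI / ",
             sum(augmented$label == "HEALTHY"), " HC)")
  })

  if ("split" %in% stages) run_stage("split", function() {
    augmented <- read_corpus_jsonl(file.path(out_dir, "augmented.jsonl"))
    sp <- config$split
    spec <- split_spec(sp$test_fraction, sp$validation_fraction,
                       sp$n_repeats, sp$mode,
                       seed = derive_seed(config$seed, 3L))
    splits <- make_splits(augmented, spec)
    write_splits_json(splits, augmented, file.path(out_dir, "splits.json"))
    audits <- lapply(splits, leakage_audit, dataset = augmented)
    jsonlite::write_json(
      list(config_hash = hash, mode = sp$mode, per_split = audits),
      file.path(out_dir, "leakage.json"), auto_unbox = TRUE, digits = NA)
    frac <- mean(vapply(audits, `[[`, numeric(1), "origin_overlap_frac"))
    log_line("split: ", length(splits), " repeats, mean origin-overlap ",
             round(frac, 3))
    message("Leakage audit (", sp$mode, "): mean fraction of test samples ",
            "sharing an origin with train = ", round(frac, 3))
  })

  if ("train" %in% stages) run_stage("train", function() {
    augmented <- read_corpus_jsonl(file.path(out_dir, "augmented.jsonl"))
    splits <- read_splits_json(file.path(out_dir, "splits.json"), augmented)
    backend <- resolve_backend(config$backend)
    grid <- do.call(hyperparam_grid, config$grid)
    report <- run_grid(augmented, splits, backend, grid,
                       seed = derive_seed(config$seed, 4L))
    utils::write.table(report, file.path(out_dir, "grid_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    best <- attr(report, "best")
    pred_rows <- list()
    for (ri in seq_along(splits)) {
      run <- train_eval(augmented, splits[[ri]], backend, best,
                        seed = derive_seed(config$seed, 5000L + ri))
      pred_rows[[ri]] <- tibble::tibble(
        repeat_id = ri, sample_id = run$sample_id, task = run$task,
        truth = run$truth, prediction = run$predictions
      )
    }
    preds <- dplyr::bind_rows(pred_rows)
    writeLines(vapply(seq_len(nrow(preds)), function(i) {
      jsonlite::toJSON(as.list(preds[i, ]), auto_unbox = TRUE, digits = NA)
    }, character(1)), file.path(out_dir, "predictions.jsonl"), useBytes = TRUE)
    log_line("train: grid of ", nrow(report), " settings; best batch_size=",
             best$batch_size, " lr=", best$learning_rate,
             " mean weighted F1=", round(best$mean_weighted_f1, 3))
  })

  if ("report" %in% stages) run_stage("report", function() {
    lines <- readLines(file.path(out_dir, "predictions.jsonl"))
    preds <- dplyr::bind_rows(lapply(lines, function(l) {
      tibble::as_tibble(jsonlite::fromJSON(l))
    }))
    report <- per_task_report(preds$prediction, preds$truth, preds$task)
    write_report_tsv(report, file.path(out_dir, "evaluation.tsv"))
    write_report_json(report, file.path(out_dir, "evaluation.json"))
    log_line("report: pooled over ", max(preds$repeat_id), " repeats, ",
             nrow(preds), " test predictions, weighted F1 ",
             round(report$weighted_f1, 3))
  })

  artifacts <- setdiff(list.files(out_dir), "manifest.json")
  jsonlite::write_json(
    list(config_hash = hash, seed = config$seed, stages = stages,
         artifacts = artifacts),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Read splits back from a JSON index file
#'
#' @param path Path written by [write_splits_json()].
#' @param dataset The corpus tibble to resolve sample ids against.
#' @return A list of index triples as produced by [make_splits()].
#' @export
read_splits_json <- function(path, dataset) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  splits <- lapply(payload$splits, function(tr) {
    lapply(tr, function(ids) {
      ix <- match(unlist(ids), dataset$sample_id)
      if (anyNA(ix)) stop("split references unknown sample ids", call. = FALSE)
      ix
    })
  })
  attr(splits, "spec") <- payload$spec
  splits
}

resolve_backend <- function(name) {
  switch(name,
    baseline = baseline_backend(),
    stop("unknown backend '", name, "'; available: baseline", call. = FALSE)
  )
}
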