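## End-to-end pipeline: simulate (or load) -> detect events -> estimate
## heart rate per chunk -> binarize -> features -> models, with a flat
## key=value configuration file and stamped, reproducible outputs.

#' Pipeline configuration
#'
#' Defaults equal the pipeline's canonical constants: 30 s chunks, |z| > 0.5
#' labels, 50 model runs, 500 search candidates, 5 CV folds, alpha = 0.05.
#'
#' @param mode `"simulate"` (generate synthetic sessions) or `"files"`
#'   (read `gaze_path`/`ppg_path`).
#' @param n_participants number of simulated participants.
#' @param duration_s simulated session length, seconds.
#' @param coupling simulator arousal coupling in `[0, 1]`.
#' @param chunk_s chunk length, seconds.
#' @param z_threshold binarization threshold on |z|.
#' @param scheme feature scheme: `"averaging"`, `"explosion"`, `"reduced"`.
#' @param n_runs repeated train/test splits for the models.
#' @param do_search run the random-forest hyperparameter search.
#' @param n_candidates,n_folds hyperparameter-search settings.
#' @param n_importance_repeats permutations per feature and run.
#' @param alpha significance level for the importance t-tests.
#' @param seed master seed.
#' @param out_dir output directory.
#' @param gaze_path,ppg_path input files for `mode = "files"`.
#' @param events_path,features_path,labels_path intermediate files used by
#'   the stage-wise CLI subcommands (`detect` -> `features` -> `fit`).
#' @return validated configuration list of class `oc_config`.
#' @export
pipeline_config <- function(mode = "simulate", n_participants = 2L,
                            duration_s = 7200, coupling = 1,
                            chunk_s = 30, z_threshold = 0.5,
                            scheme = "averaging", n_runs = 50L,
                            do_search = FALSE, n_candidates = 500L,
                            n_folds = 5L, n_importance_repeats = 10L,
                            alpha = 0.05, seed = 1L, out_dir = "oc_out",
                            gaze_path = "", ppg_path = "",
                            events_path = "", features_path = "",
                            labels_path = "") {
  cfg <- as.list(environment())
  if (!mode %in% c("simulate", "files")) stop("unknown mode: ", mode)
  if (!scheme %in% c("averaging", "explosion", "reduced"))
    stop("unknown scheme: ", scheme)
  stopifnot(chunk_s > 0, z_threshold >= 0, n_runs >= 1, n_candidates >= 1,
            n_folds >= 2, alpha > 0, alpha < 1)
  for (nm in c("n_participants", "n_runs", "n_candidates", "n_folds",
               "n_importance_repeats", "seed"))
    cfg[[nm]] <- as.integer(cfg[[nm]])
  cfg$do_search <- isTRUE(as.logical(cfg$do_search))
  structure(cfg, class = "oc_config")
}

#' Read / write a flat key=value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Unknown keys are
#' an error (a typo must not silently change a threshold). Values are
#' coerced to the type of the default.
#'
#' @param path file path.
#' @return for `read_config`, an `oc_config`; for `write_config`, the path.
#' @export
read_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  defaults <- pipeline_config()
  args <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 1L) stop("malformed config line: ", ln)
    key <- trimws(substr(ln, 1L, eq - 1L))
    val <- trimws(substr(ln, eq + 1L, nchar(ln)))
    if (!key %in% names(defaults)) stop("unknown config key: ", key)
    args[[key]] <- switch(class(defaults[[key]])[1],
                          integer = as.integer(val),
                          numeric = as.numeric(val),
                          logical = as.logical(val),
                          val)
  }
  do.call(pipeline_config, args)
}

#' @param config an `oc_config` object.
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  keys <- setdiff(names(config), NULL)
  writeLines(vapply(keys, function(k) paste(k, "=", config[[k]]),
                    character(1)), path)
  invisible(path)
}

## hash of the scientific configuration; the output location is excluded so
## identical analyses in different directories carry the same stamp
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  hash32(paste(names(cfg), unlist(cfg), collapse = ";"))
}

#' Per-label feature summary (distribution table)
#'
#' Median and SD of every feature column, split by label -- the tabular
#' analogue of per-label feature density plots.
#'
#' @param X feature matrix.
#' @param labels label vector aligned with the rows of `X`.
#' @return long data frame `feature`, `label`, `median`, `sd`, `n`.
#' @export
label_feature_summary <- function(X, labels) {
  X <- as.matrix(X)
  do.call(rbind, lapply(colnames(X), function(f) {
    do.call(rbind, lapply(unique(labels), function(l) {
      v <- X[labels == l, f]
      data.frame(feature = f, label = l, median = median(v), sd = sd(v),
                 n = length(v))
    }))
  }))
}

#' Run the full pipeline
#'
#' simulate (or load) -> detect oculomotor events -> chunk + heart rate ->
#' binarize -> feature matrix -> regressions, model pre-selection, optional
#' hyperparameter search, per-run permutation importances with t-tests.
#' Writes `labeled_chunks.csv`, `features_<scheme>.csv` (+ JSON sidecar),
#' `table1_regression.csv`, `table2_preselection.csv`, optionally
#' `table3_search.csv`, `fig1_label_summary.csv`, `importance.json` and
#' `run_log.json` into `config$out_dir`. Every CSV carries a comment header
#' with the configuration hash and master seed.
#'
#' @param config an `oc_config` from [pipeline_config()] / [read_config()].
#' @return invisibly, a list with the in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "oc_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- paste0("oculocardiac config_hash=", config_hash(config),
                  " seed=", config$seed)

  sessions <- load_sessions(config)
  chunks_list <- list()
  labeled_list <- list()
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    ev <- detect_events(s$gaze)
    ch <- make_chunks(ev, s$ppg, chunk_s = config$chunk_s,
                      participant_id = s$id)
    chunks_list[[s$id]] <- ch
    labeled_list[[s$id]] <- binarize_heart_rate(ch, config$z_threshold)
  }
  labeled <- do.call(rbind, labeled_list)
  if (is.null(labeled) || nrow(labeled) == 0L)
    stop("labeling stage produced an empty labeled set")
  rownames(labeled) <- NULL
  stamped_csv(labeled, file.path(config$out_dir, "labeled_chunks.csv"),
              stamp)

  X <- build_feature_matrix(chunks_list, labeled, config$scheme)
  fpath <- file.path(config$out_dir,
                     paste0("features_", config$scheme, ".csv"))
  stamped_csv(as.data.frame(unclass(X)), fpath, stamp)
  jsonlite::write_json(
    list(scheme = config$scheme, n_chunks = nrow(X), n_features = ncol(X),
         config_hash = config_hash(config), seed = config$seed),
    paste0(fpath, ".json"), auto_unbox = TRUE)

  table1 <- fit_regressions(X, labeled$bpm, seed = config$seed)
  stamped_csv(table1, file.path(config$out_dir, "table1_regression.csv"),
              stamp)

  presel <- model_preselection(X, labeled$label, n_runs = config$n_runs,
                               seed = config$seed)
  stamped_csv(presel$summary,
              file.path(config$out_dir, "table2_preselection.csv"), stamp)

  search <- NULL
  rf_params <- list()
  if (config$do_search) {
    search <- random_search_rf(X, labeled$label,
                               n_candidates = config$n_candidates,
                               n_runs = config$n_runs,
                               n_folds = config$n_folds,
                               seed = config$seed)
    stamped_csv(search$top_table,
                file.path(config$out_dir, "table3_search.csv"), stamp)
    rf_params <- list(
      n_trees = as.integer(round(mean(search$per_run$n_trees))),
      max_depth = as.integer(round(mean(search$per_run$max_depth))))
  }

  ## per-run permutation importances of the random-forest model
  imp <- matrix(NA_real_, config$n_runs, ncol(X),
                dimnames = list(NULL, colnames(X)))
  for (run in seq_len(config$n_runs)) {
    sp <- stratified_split(labeled$label, 0.8, config$seed + run)
    fit <- with_seed(config$seed + 50000L + run,
                     fit_classifier("rf", X[sp$train, , drop = FALSE],
                                    labeled$label[sp$train], rf_params))
    imp[run, ] <- permutation_importance(
      fit, X[sp$test, , drop = FALSE], labeled$label[sp$test],
      n_repeats = config$n_importance_repeats,
      seed = config$seed + 60000L + run)
  }
  imp_report <- importance_t_tests(imp, config$alpha)
  jsonlite::write_json(
    list(config_hash = config_hash(config), seed = config$seed,
         grand_mean = attr(imp_report, "grand_mean"),
         features = as.data.frame(imp_report)),
    file.path(config$out_dir, "importance.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)

  fig1 <- label_feature_summary(X, labeled$label)
  stamped_csv(fig1, file.path(config$out_dir, "fig1_label_summary.csv"),
              stamp)

  jsonlite::write_json(
    list(config = unclass(config), config_hash = config_hash(config),
         seed = config$seed,
         package_version = as.character(utils::packageVersion("oculocardiac")),
         r_version = R.version.string,
         timestamp = format(Sys.time(), tz = "UTC")),
    file.path(config$out_dir, "run_log.json"), auto_unbox = TRUE)

  invisible(list(labeled = labeled, features = X, table1 = table1,
                 preselection = presel, search = search,
                 importance = imp_report, importances = imp))
}

## sessions as a list of (id, gaze recording, ppg recording)
load_sessions <- function(config) {
  if (config$mode == "files") {
    if (!file.exists(config$gaze_path)) stop("gaze file not found: ",
                                             config$gaze_path)
    if (!file.exists(config$ppg_path)) stop("ppg file not found: ",
                                            config$ppg_path)
    return(list(list(id = "p1", gaze = read_gaze_tsv(config$gaze_path),
                     ppg = read_ppg_csv(config$ppg_path))))
  }
  lapply(seq_len(config$n_participants), function(p) {
    base <- sim_config(duration_s = config$duration_s,
                       coupling = config$coupling, seed = config$seed)
    ses <- simulate_session(participant_config(base, p))
    list(id = sprintf("p%02d", p), gaze = ses$gaze$recording,
         ppg = ses$ppg$recording)
  })
}
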