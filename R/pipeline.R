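#' Pipeline configuration
#'
#' Every seed is explicit; unknown keys are rejected so that typos in config
#' files fail loudly.
#'
#' @param disease "fabry-like" or "gaucher-like" (selects the bundled
#'   generator profile and names the per-disease index).
#' @param n_abstracts corpus size (default 200).
#' @param n_patients population size (default 500).
#' @param n_eval_patients patients queried and rated (default 20).
#' @param n_test,n_val segmenter split sizes (default 20/20).
#' @param epochs,lr,lambda_reg,batch_size,patience training hyperparameters.
#' @param lambda,swap_fraction augmentation parameters.
#' @param min_year publication-date filter (NA = off).
#' @param top_k results per query (default 3).
#' @param seed master seed; stage seeds are derived deterministically.
#' @param out_dir where \code{\link{run_pipeline}} writes artefacts (NULL =
#'   nothing written).
#' @return List with class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(disease = "fabry-like", n_abstracts = 200L,
                            n_patients = 500L, n_eval_patients = 20L,
                            n_test = 20L, n_val = 20L, epochs = 40L,
                            lr = 0.1, lambda_reg = 1.0, batch_size = 8L,
                            patience = 10L, lambda = 5, swap_fraction = 0.5,
                            min_year = NA_integer_, top_k = 3L, seed = 1L,
                            out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from JSON
#'
#' @param path JSON file whose keys are \code{\link{pipeline_config}}
#'   arguments; unknown keys raise an error.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(obj), known)
  if (length(bad) > 0) {
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(pipeline_config, obj)
}

stage_seed <- function(seed, k) (as.integer(seed) * 97L + k * 131L) %% 2000000000L

#' Run the full pipeline on synthetic data
#'
#' simulate -> train segmenter -> index -> build and route queries ->
#' search -> simulated ratings and precision -> stratification -> network.
#' Each stage is seeded from the master seed; re-running with the same
#' config reproduces every artefact. Stage failures abort with the stage
#' name and cause.
#'
#' @param config a \code{pipeline_config}.
#' @param verbose print stage progress.
#' @return A report list: \code{split_sizes}, \code{segmentation} (token and
#'   span F1 on the held-out test split), \code{precision} (P@3 table),
#'   \code{population} (group statistics), \code{network} (stats +
#'   modularity), plus the trained model, index and retrievals.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stage <- function(name, expr) {
    if (verbose) message("[", name, "]")
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  profile <- switch(config$disease,
                    "fabry-like" = fabry_like_profile(),
                    "gaucher-like" = gaucher_like_profile(),
                    stop("unknown disease profile: ", config$disease))

  corpus <- stage("simulate-corpus",
                  generate_corpus(profile, config$n_abstracts,
                                  seed = stage_seed(config$seed, 1L)))
  parts <- stage("split",
                 split_corpus(corpus, n_test = config$n_test,
                              n_val = config$n_val,
                              seed = stage_seed(config$seed, 2L)))
  aug <- augmentation_config(lambda = config$lambda,
                             swap_fraction = config$swap_fraction,
                             seed = stage_seed(config$seed, 3L))
  model <- stage("train",
                 train_segmenter(parts$train, parts$val, aug = aug,
                                 epochs = config$epochs, lr = config$lr,
                                 lambda_reg = config$lambda_reg,
                                 batch_size = config$batch_size,
                                 patience = config$patience,
                                 seed = stage_seed(config$seed, 3L),
                                 verbose = verbose))
  seg_metrics <- stage("evaluate-segmenter", {
    pred <- predict_corpus(model, parts$test)
    evaluate_f1(parts$test, pred)
  })
  index <- stage("index", {
    docs <- lapply(predict_corpus(model, corpus), structure_document)
    index_documents(docs)
  })
  population <- stage("simulate-population",
                      generate_population(profile, config$n_patients,
                                          seed = stage_seed(config$seed, 4L)))
  flags <- stage("stratify", label_atypical(population))
  stats_tab <- group_stats(population, flags)

  tables <- reference_table()
  cfg <- ranking_config(min_year = config$min_year, top_k = config$top_k)
  queries <- stage("build-queries", lapply(population, function(rec) {
    segment_query(build_query(rec, tables), model)
  }))
  retrievals <- stage("search", {
    res <- lapply(queries, function(q) {
      vapply(search_index(q, index, cfg), `[[`, character(1), "doc_id")
    })
    stats::setNames(res, vapply(population, `[[`, character(1), "patient_id"))
  })
  eval_ids <- sample_patients(names(retrievals),
                              n = config$n_eval_patients,
                              seed = stage_seed(config$seed, 5L))
  ratings <- stage("simulate-ratings",
                   generate_ratings(retrievals[eval_ids],
                                    seed = stage_seed(config$seed, 6L)))
  precision <- stage("precision", precision_report(ratings))
  net <- stage("network", build_network(retrievals))
  net_stats <- network_stats(net)
  comms <- stage("communities",
                 detect_communities(net, seed = stage_seed(config$seed, 7L)))

  report <- list(
    config = config,
    split_sizes = lengths(parts)[c("train", "val", "test")],
    segmentation = seg_metrics,
    precision = precision,
    population = stats_tab,
    network = c(net_stats, modularity = comms$modularity),
    model = model, index = index, retrievals = retrievals,
    ratings = ratings
  )
  if (!is.null(config$out_dir)) write_report(report, net, config$out_dir)
  report
}

write_report <- function(report, net, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_segmenter(report$model, file.path(out_dir, "segmenter.json"))
  utils::write.csv(report$precision, file.path(out_dir, "precision.csv"),
                   row.names = FALSE)
  utils::write.csv(report$population, file.path(out_dir, "population.csv"),
                   row.names = FALSE)
  utils::write.csv(report$ratings, file.path(out_dir, "ratings.csv"),
                   row.names = FALSE)
  write_network(net, file.path(out_dir, "network.graphml"),
                file.path(out_dir, "network_edges.csv"))
  run_log <- list(
    package_version = as.character(utils::packageVersion("zebracase")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = report$config[setdiff(names(report$config), "out_dir")],
    split_sizes = as.list(report$split_sizes),
    token_f1 = report$segmentation$token$f1,
    network = report$network
  )
  jsonlite::write_json(run_log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE, force = TRUE)
  invisible(out_dir)
}
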