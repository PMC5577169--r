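#' Configuration for the end-to-end pipeline
#'
#' @param seed integer seed; every stochastic stage derives its stream from
#'   it.
#' @param n_per_class sequences per strategy for the simulate stage.
#' @param spec [state_spec()] used by the train stage.
#' @param grid optional list of [state_spec()]; when given, the select stage
#'   picks `spec` by cross-validation.
#' @param k,repeats cross-validation settings for the evaluate stage.
#' @param classifiers subset of `c("dhmm", "logistic", "svm")` to evaluate.
#' @param restarts,refine training settings passed to [fit_dhmm()].
#' @param generator a [generator_config()]; built from `seed` and
#'   `n_per_class` when `NULL`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, n_per_class = 840L, spec = state_spec(3, 3),
                            grid = NULL, k = 5L, repeats = 10L,
                            classifiers = c("dhmm", "logistic", "svm"),
                            restarts = 10L, refine = TRUE, generator = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(generator))
    generator <- generator_config(n_per_class = n_per_class, seed = seed,
                                  aoi_mode = "chained")
  structure(list(seed = as.integer(seed), n_per_class = as.integer(n_per_class),
                 spec = spec, grid = grid, k = as.integer(k),
                 repeats = as.integer(repeats),
                 classifiers = match.arg(classifiers,
                                         c("dhmm", "logistic", "svm"),
                                         several.ok = TRUE),
                 restarts = as.integer(restarts), refine = refine,
                 generator = generator),
            class = "pipeline_config")
}

.out_path <- function(out_dir, name, overwrite) {
  p <- file.path(out_dir, name)
  if (file.exists(p) && !overwrite)
    stop("refusing to overwrite existing artifact: ", p,
         " (use overwrite = TRUE)")
  p
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- list(seed = config$seed, n_per_class = config$n_per_class,
              spec = unclass(config$spec), k = config$k,
              repeats = config$repeats, classifiers = config$classifiers,
              restarts = config$restarts, refine = config$refine)
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the analysis pipeline end-to-end
#'
#' Stages, each reading the previous stage's plain-file artifacts from
#' `out_dir` so any stage can be inspected or replaced:
#' \describe{
#'   \item{simulate}{raw fixation table (`raw_fixations.tsv`), AOI layout
#'     (`aoi_layout.json`) and train/test split (`split.json`).}
#'   \item{extract}{observation sequences (`sequences.tsv`) and summary
#'     features (`features.tsv`).}
#'   \item{select}{cross-validated state-count selection over `config$grid`
#'     (`state_selection.json`); updates the spec used by train.}
#'   \item{train}{Baum-Welch + discriminative fit on the training split
#'     (`dhmm_params.json`).}
#'   \item{classify}{per-trial posteriors on the test split
#'     (`posteriors.csv`).}
#'   \item{evaluate}{test-set confusion matrices for the toggled classifiers
#'     (`confusion.json`) and repeated-CV accuracies on the training split
#'     (`cv_accuracies.csv`).}
#'   \item{report}{plain-text report (`report.txt`) mirroring the
#'     confusion-matrix and parameter-table layouts.}
#' }
#' A run log (`run_log.json`) records the seed, a configuration hash and the
#' package version. Existing artifacts are never silently overwritten.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [pipeline_config()].
#' @param stages character vector of stages to run, in order.
#' @param overwrite allow replacing existing artifacts?
#' @return invisibly, a list with the main in-memory results of the stages
#'   that ran.
#' @export
run_pipeline <- function(out_dir, config,
                         stages = c("simulate", "extract", "train",
                                    "classify", "evaluate", "report"),
                         overwrite = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, c("simulate", "extract", "select", "train",
                                "classify", "evaluate", "report"),
                      several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(config_hash = .config_hash(config))

  if ("simulate" %in% stages) {
    corpus <- simulate_corpus(config$generator, raw = TRUE)
    write_fixation_table(corpus$raw,
                         .out_path(out_dir, "raw_fixations.tsv", overwrite))
    write_aoi_layout(config$generator$layout,
                     .out_path(out_dir, "aoi_layout.json", overwrite))
    jsonlite::write_json(list(is_train = corpus$is_train),
                         .out_path(out_dir, "split.json", overwrite))
    res$corpus <- corpus
  }

  if ("extract" %in% stages) {
    raw <- read_fixation_table(file.path(out_dir, "raw_fixations.tsv"))
    layout <- read_aoi_layout(file.path(out_dir, "aoi_layout.json"))
    seqs <- extract_sequences(raw, layout)
    write_sequences_tsv(seqs, .out_path(out_dir, "sequences.tsv", overwrite))
    write_feature_matrix(feature_matrix(seqs),
                         .out_path(out_dir, "features.tsv", overwrite))
    res$sequences <- seqs
  }

  seqs <- res$sequences %||%
    if (any(c("select", "train", "classify", "evaluate") %in% stages))
      read_sequences_tsv(file.path(out_dir, "sequences.tsv"))
  is_train <- if (!is.null(res$corpus)) res$corpus$is_train
    else if (file.exists(file.path(out_dir, "split.json")))
      jsonlite::read_json(file.path(out_dir, "split.json"),
                          simplifyVector = TRUE)$is_train

  if ("select" %in% stages) {
    if (is.null(config$grid)) stop("select stage needs config$grid")
    sel <- select_states(seqs[is_train], config$grid, k = config$k,
                         seed = config$seed, restarts = config$restarts,
                         refine = config$refine)
    jsonlite::write_json(list(spec = unclass(sel$spec), curve = sel$curve),
                         .out_path(out_dir, "state_selection.json", overwrite),
                         auto_unbox = TRUE, digits = NA)
    config$spec <- sel$spec
    res$selection <- sel
  }

  if ("train" %in% stages) {
    fit <- fit_dhmm(seqs[is_train], config$spec, restarts = config$restarts,
                    seed = config$seed, refine = config$refine)
    write_hmm_params(fit, .out_path(out_dir, "dhmm_params.json", overwrite))
    res$fit <- fit
  }

  if ("classify" %in% stages) {
    params <- res$fit %||% read_hmm_params(file.path(out_dir, "dhmm_params.json"))
    post <- classify_sequences(seqs[!is_train], params)
    utils::write.csv(post, .out_path(out_dir, "posteriors.csv", overwrite),
                     row.names = FALSE)
    res$posteriors <- post
  }

  if ("evaluate" %in% stages) {
    params <- res$fit %||% read_hmm_params(file.path(out_dir, "dhmm_params.json"))
    train_seqs <- seqs[is_train]
    test_seqs <- seqs[!is_train]
    labels_test <- vapply(test_seqs, function(s) s$strategy, character(1))
    X_train <- feature_matrix(train_seqs)
    X_test <- feature_matrix(test_seqs)
    conf <- list()
    cvrows <- list()
    if ("dhmm" %in% config$classifiers) {
      conf$dhmm <- confusion(classify_sequences(test_seqs, params)$label,
                             labels_test)
      labels_train <- vapply(train_seqs, function(s) s$strategy, character(1))
      cv <- cross_validate(function(d, l) {
        fit <- fit_dhmm(d, config$spec, restarts = max(2L, config$restarts %/% 5L),
                        seed = config$seed, refine = config$refine)
        function(td) classify_sequences(td, fit)$label
      }, train_seqs, labels_train, k = config$k, repeats = 1L,
      seed = config$seed)
      cvrows$dhmm <- data.frame(classifier = "dhmm", cv)
    }
    if ("logistic" %in% config$classifiers) {
      m <- fit_logistic(X_train)
      conf$logistic <- confusion(predict_logistic(m, X_test)$label, labels_test)
      cv <- cross_validate(function(d, l) {
        fit <- fit_logistic(d)
        function(td) predict_logistic(fit, td)$label
      }, X_train, X_train$strategy, k = config$k, repeats = config$repeats,
      seed = config$seed)
      cvrows$logistic <- data.frame(classifier = "logistic", cv)
    }
    if ("svm" %in% config$classifiers) {
      m <- fit_svm(X_train)
      conf$svm <- confusion(predict_svm(m, X_test)$label, labels_test)
      cv <- cross_validate(function(d, l) {
        fit <- fit_svm(d)
        function(td) predict_svm(fit, td)$label
      }, X_train, X_train$strategy, k = config$k, repeats = config$repeats,
      seed = config$seed)
      cvrows$svm <- data.frame(classifier = "svm", cv)
    }
    jsonlite::write_json(
      lapply(conf, function(cm) list(counts = cm$counts,
                                     total_accuracy = cm$total_accuracy,
                                     row_accuracy = cm$row_accuracy,
                                     col_accuracy = cm$col_accuracy)),
      .out_path(out_dir, "confusion.json", overwrite), digits = NA)
    utils::write.csv(do.call(rbind, cvrows),
                     .out_path(out_dir, "cv_accuracies.csv", overwrite),
                     row.names = FALSE)
    res$confusion <- conf
    res$cv <- cvrows
  }

  if ("report" %in% stages) {
    path <- .out_path(out_dir, "report.txt", overwrite)
    con <- file(path, "w")
    on.exit(close(con), add = TRUE)
    writeLines(sprintf("rotscan pipeline report (seed %d, config %s)",
                       config$seed, res$config_hash), con)
    conf <- res$confusion
    if (!is.null(conf)) for (nm in names(conf)) {
      writeLines(sprintf("\n== %s: test-set confusion matrix ==", nm), con)
      writeLines(utils::capture.output(print(conf[[nm]])), con)
    }
    fit <- res$fit
    if (!is.null(fit)) {
      writeLines("\n== fitted dHMM parameters ==", con)
      writeLines(utils::capture.output(print(fit)), con)
    }
    res$report <- path
  }

  jsonlite::write_json(
    list(seed = config$seed, config_hash = res$config_hash,
         package_version = as.character(utils::packageVersion("rotscan")),
         stages = stages),
    .out_path(out_dir, "run_log.json", overwrite), auto_unbox = TRUE)
  invisible(res)
}
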