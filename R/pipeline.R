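# End-to-end pipeline runner driven by a single configuration (YAML file
# or nested list) with per-stage sections.  Every JSON artifact embeds the
# seed, package version and an MD5 of the canonicalized configuration so a
# run can be traced back to its inputs.

config_md5 <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the REO signature pipeline from a configuration
#'
#' Stages (each optional, run in order when its section is present):
#' `simulate` (cohort generation; writes `matrix.tsv`, `labels.tsv`,
#' `truth.json`), `mine`/`select` (signature discovery via [reo_train()];
#' writes `reversal_pairs.tsv`, `accuracy_by_k.tsv`, `signature.json`),
#' `classify` (writes `predictions.tsv`), `evaluate` (writes
#' `report.json`).  Later stages read the earlier stages' outputs unless
#' the config points them at explicit `matrix` / `labels` / `signature`
#' paths.  Reruns with an identical config reproduce identical artifacts.
#'
#' @param config Path to a YAML config or an equivalent nested list.
#'   Recognised top-level keys: `out_dir`, `seed`, `simulate` (fields of
#'   [cohort_spec()]), `mine` (`threshold`, optional `matrix`, `labels`),
#'   `select` (`k_max`, `vote_rule`), `classify` (optional `matrix`,
#'   `signature`), `evaluate` (optional `labels`, `gc_adj_as`).
#' @param out_dir Output directory; overrides the config's `out_dir`.
#' @return Invisibly, a list with the in-memory artifacts (`cohort`,
#'   `fit`, `predictions`, `report`) and the written `paths`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  out_dir <- out_dir %||% config$out_dir %||% stop("no out_dir configured")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  md5 <- config_md5(config)
  provenance <- list(seed = seed, config_md5 = md5,
                     package = as.character(utils::packageVersion("reosig")))
  paths <- list()
  artifacts <- list()

  cohort <- NULL
  if (!is.null(config$simulate)) {
    cohort <- stage_try("simulate", {
      sim <- config$simulate
      sim$seed <- sim$seed %||% seed
      spec <- do.call(cohort_spec, sim)
      simulate_cohort(spec)
    })
    paths$matrix <- file.path(out_dir, "matrix.tsv")
    paths$labels <- file.path(out_dir, "labels.tsv")
    paths$truth <- file.path(out_dir, "truth.json")
    write_expression_matrix(cohort$matrix, paths$matrix)
    write_class_labels(cohort$labels, paths$labels)
    jsonlite::write_json(c(list(planted = cohort$truth,
                                purity = as.list(cohort$purity)),
                           provenance),
                         paths$truth, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    artifacts$cohort <- cohort
  }

  load_matrix <- function(section) {
    if (!is.null(section$matrix)) {
      if (!file.exists(section$matrix))
        stop("matrix file not found: ", section$matrix)
      read_expression_matrix(section$matrix)
    } else if (!is.null(cohort)) cohort$matrix
    else stop("no expression matrix available (configure a path or a simulate stage)")
  }
  load_labels <- function(section) {
    if (!is.null(section$labels)) {
      if (!file.exists(section$labels))
        stop("labels file not found: ", section$labels)
      read_class_labels(section$labels)
    } else if (!is.null(cohort)) cohort$labels
    else stop("no labels available (configure a path or a simulate stage)")
  }

  fit <- NULL
  if (!is.null(config$mine) || !is.null(config$select)) {
    fit <- stage_try("mine", {
      mine <- config$mine %||% list()
      sel <- config$select %||% list()
      reo_train(load_matrix(mine), load_labels(mine),
                threshold = mine$threshold %||% 0.99,
                k_max = sel$k_max,
                vote_rule = sel$vote_rule %||% "at_least_half")
    })
    stage_try("select", {
      paths$reversals <- file.path(out_dir, "reversal_pairs.tsv")
      utils::write.table(fit$reversals, paths$reversals, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      paths$accuracy <- file.path(out_dir, "accuracy_by_k.tsv")
      utils::write.table(
        data.frame(k = seq_along(fit$accuracy_by_k),
                   accuracy = fit$accuracy_by_k),
        paths$accuracy, sep = "\t", quote = FALSE, row.names = FALSE)
      paths$signature <- file.path(out_dir, "signature.json")
      write_signature(fit, paths$signature)
    })
    artifacts$fit <- fit
  }

  predictions <- NULL
  if (!is.null(config$classify)) {
    predictions <- stage_try("classify", {
      cls <- config$classify
      sig <- if (!is.null(cls$signature)) read_signature(cls$signature)
             else fit %||% stop("no signature available (configure a path or a mine/select stage)")
      classify_matrix(load_matrix(cls), sig)
    })
    paths$predictions <- file.path(out_dir, "predictions.tsv")
    utils::write.table(predictions, paths$predictions, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    artifacts$predictions <- predictions
  }

  if (!is.null(config$evaluate)) {
    report <- stage_try("evaluate", {
      ev <- config$evaluate
      preds <- predictions %||% stop("evaluate needs a classify stage")
      evaluate_predictions(preds, load_labels(ev),
                           gc_adj_as = ev$gc_adj_as %||% "GC")
    })
    paths$report <- file.path(out_dir, "report.json")
    jsonlite::write_json(c(unclass(report), provenance), paths$report,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    artifacts$report <- report
  }

  invisible(c(artifacts, list(paths = paths, provenance = provenance)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
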