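#' Run configuration for the end-to-end pipeline
#'
#' Validates the options of a full run. Expert-scribble mode requires a
#' scribble file; auto mode forbids one (scribbles are derived from a
#' non-spatial clustering by neighbour consensus).
#'
#' @param mode `"scribble"` or `"auto"`.
#' @param count_path,coord_path Input files (see [read_counts()]).
#' @param dialect Count dialect, `"csv"` or `"mtx10x"`.
#' @param platform `"visium"` or `"st"`.
#' @param s Number of domains.
#' @param p Number of principal components.
#' @param h Number of highly variable genes (default 2000).
#' @param scribble_path Scribble CSV (scribble mode only).
#' @param truth_path Optional reference labels CSV (`spot_id,label`) for ARI
#'   reporting; empty labels mean unannotated.
#' @param search A [search_config()]; `gamma` defaults by platform (3
#'   Visium, 2 ST).
#' @param train A [train_config()] (its alpha/beta are overridden by the
#'   grid search).
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @return A `run_config`.
#' @export
run_config <- function(mode = c("scribble", "auto"),
                       count_path, coord_path,
                       dialect = c("csv", "mtx10x"),
                       platform = c("visium", "st"),
                       s, p, h = 2000L,
                       scribble_path = NULL, truth_path = NULL,
                       search = NULL, train = train_config(),
                       out_dir, seed = 1L) {
  mode <- match.arg(mode)
  dialect <- match.arg(dialect)
  platform <- match.arg(platform)
  if (mode == "scribble" && is.null(scribble_path))
    stop("scribble mode requires a scribble_path")
  if (mode == "auto" && !is.null(scribble_path))
    stop("auto mode derives its own scribbles; scribble_path must be NULL")
  if (is.null(search))
    search <- search_config(gamma = if (platform == "visium") 3 else 2)
  train$seed <- as.integer(seed)
  structure(list(mode = mode, count_path = count_path,
                 coord_path = coord_path, dialect = dialect,
                 platform = platform, s = as.integer(s), p = as.integer(p),
                 h = as.integer(h), scribble_path = scribble_path,
                 truth_path = truth_path, search = search, train = train,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; `search` and `train`
#' sub-maps override the defaults of [search_config()] / [train_config()].
#'
#' @param path YAML file.
#' @param overrides Named list applied over the file's values.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path)
  y[names(overrides)] <- overrides
  sc <- do.call(search_config, as.list(y$search %||% list()))
  tc <- do.call(train_config, as.list(y$train %||% list()))
  y$search <- if (is.null(y$search)) NULL else sc
  y$train <- tc
  do.call(run_config, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_truth_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  lab <- df[[2]]
  lab[!nzchar(trimws(lab))] <- NA
  stats::setNames(lab, df[[1]])
}

#' Execute the full domain-identification pipeline
#'
#' Reads counts and coordinates, preprocesses to PCs on the rectangular
#' grid, obtains scribbles (from file, or from an mclust initial clustering
#' filtered by neighbour consensus in auto mode), grid-searches the
#' hyperparameters with the goodness score, and writes the selected labels,
#' the score table, and a JSON manifest that suffices to reproduce the run.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`). Output files: `labels.csv`
#'   (`spot_id,row,col,domain`), `score_table.csv`, `loss_trace.csv`,
#'   `auto_scribbles.csv` (auto mode), `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  inp <- stage("read", read_counts(config$count_path, config$coord_path,
                                   config$dialect, config$platform))
  pp <- stage("preprocess",
              preprocess(inp$counts, inp$coords, h = config$h, p = config$p))

  if (config$mode == "scribble") {
    scr <- stage("scribbles",
                 read_scribbles(config$scribble_path,
                                rownames(pp$pcs), config$s))
    init <- NULL
  } else {
    init <- stage("initial_cluster",
                  initial_cluster(pp$pcs, config$s, seed = config$seed))
    scr <- stage("auto_scribbles", auto_scribbles(init, pp$nbr, s = config$s))
    write_scribbles(scr, file.path(config$out_dir, "auto_scribbles.csv"))
  }

  truth <- if (!is.null(config$truth_path))
    read_truth_csv(config$truth_path) else NULL

  res <- stage("grid_search",
               grid_search(pp$grid, pp$pcs, pp$nbr, scr,
                           search = config$search, mode = config$mode,
                           train_cfg = config$train,
                           net_cfg = network_config(config$p, config$s),
                           truth = truth))

  gc_ <- pp$grid$spot_index
  labels_df <- data.frame(spot_id = names(res$best_labels),
                          row = gc_$grid_row[match(names(res$best_labels),
                                                   gc_$spot_id)],
                          col = gc_$grid_col[match(names(res$best_labels),
                                                   gc_$spot_id)],
                          domain = as.integer(res$best_labels))
  utils::write.csv(labels_df, file.path(config$out_dir, "labels.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(res$table, file.path(config$out_dir, "score_table.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(iteration = seq_along(res$best_fit$loss_trace),
                              loss = res$best_fit$loss_trace),
                   file.path(config$out_dir, "loss_trace.csv"),
                   row.names = FALSE, quote = FALSE)

  manifest <- list(
    mode = config$mode, platform = config$platform,
    s = config$s, p = config$p, h = config$h,
    seed = config$seed,
    alpha_grid = config$search$alpha_grid,
    beta_grid = if (config$mode == "auto") config$search$beta_grid else 0,
    gamma = config$search$gamma, lambda = config$search$lambda,
    max_iters = config$train$max_iters,
    learning_rate = config$train$learning_rate,
    momentum = config$train$momentum,
    n_spots = nrow(pp$pcs),
    n_runs = nrow(res$table),
    best_alpha = res$best_alpha, best_beta = res$best_beta,
    best_log_v = max(res$table$log_v),
    ari = if (!is.null(truth)) ari(res$best_labels, truth) else NULL,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("scribseg")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
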