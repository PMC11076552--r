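# Pipeline plumbing: YAML/flag-driven simulate, score and compare runs with
# mandatory seeds and fully-resolved configs written next to every output.

#' Read a run configuration
#'
#' Configurations are YAML files (flat or nested keys). CLI flags override
#' file values.
#'
#' @param path Path to a YAML config file, or `NULL`.
#' @param overrides Named list merged over the file's values.
#' @return A named list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  config <- if (!is.null(path)) yaml::read_yaml(path) else list()
  utils::modifyList(config, overrides)
}

write_resolved_config <- function(config, out) {
  yaml::write_yaml(config, paste0(out, ".config.yaml"))
}

require_fields <- function(config, fields, command) {
  missing <- setdiff(fields, names(config))
  if (length(missing))
    stop(command, " config is missing required fields: ",
         paste(missing, collapse = ", "))
}

write_case_csv <- function(table, out) {
  df <- data.frame(table$features, check.names = FALSE)
  df$label <- table$labels
  utils::write.csv(df, out, row.names = FALSE, quote = FALSE)
}

#' Read a labeled CSV into a case table
#'
#' All non-label columns must be numeric (run [preprocess()] first for
#' mixed-type data). Missing values may be encoded as empty fields or a
#' declared sentinel.
#'
#' @param path CSV path (UTF-8, header row, one case per row).
#' @param label_col Name of the label column.
#' @param na Strings treated as missing (default empty and `"?"`).
#' @return A [case_table()].
#' @export
read_case_csv <- function(path, label_col = "label", na = c("", "?", "NA")) {
  df <- utils::read.csv(path, check.names = FALSE, na.strings = na)
  if (!label_col %in% names(df))
    stop("label column '", label_col, "' not found in ", path)
  feats <- df[setdiff(names(df), label_col)]
  if (!all(vapply(feats, is.numeric, logical(1))))
    stop("non-numeric feature columns present; preprocess the data first")
  labels_raw <- df[[label_col]]
  levs <- sort(unique(labels_raw))
  case_table(as.matrix(feats), match(labels_raw, levs) - 1L,
             n_classes = length(levs),
             provenance = sprintf("read_case_csv: %s label_col=%s",
                                  path, label_col))
}

#' Generate a simulated dataset and write it to CSV
#'
#' Dispatches on `config$shape` (`"blobs"`, `"moons"`, `"circles"`), writes
#' the data CSV, a provenance sidecar (`<out>.provenance.txt`, key=value
#' lines) and the fully-resolved config (`<out>.config.yaml`). Re-running
#' with the same config reproduces the CSV byte for byte.
#'
#' @param config Named list (or [read_run_config()] result) with `shape`,
#'   `n_per_class`, `n_classes`, `seed`, `out`, and the shape parameter
#'   (`cluster_sd`, `noise_sd`, or `scale_factor` + optional `noise_sd`).
#' @return The generated [case_table()], invisibly.
#' @export
run_simulate <- function(config) {
  require_fields(config, c("shape", "n_per_class", "n_classes", "seed", "out"),
                 "simulate")
  table <- switch(config$shape,
    blobs = make_blobs(config$n_per_class, config$n_classes,
                       config$cluster_sd, config$seed),
    moons = make_moons(config$n_per_class, config$n_classes,
                       config$noise_sd, config$seed),
    circles = make_circles(config$n_per_class, config$n_classes,
                           config$scale_factor,
                           if (is.null(config$noise_sd)) 0.05 else config$noise_sd,
                           config$seed),
    stop("unknown shape '", config$shape,
         "'; valid shapes: blobs, moons, circles"))
  write_case_csv(table, config$out)
  noise <- switch(config$shape, blobs = config$cluster_sd,
                  moons = config$noise_sd,
                  circles = if (is.null(config$noise_sd)) 0.05 else config$noise_sd)
  writeLines(c(sprintf("shape=%s", config$shape),
               sprintf("n_per_class=%d", as.integer(config$n_per_class)),
               sprintf("n_classes=%d", as.integer(config$n_classes)),
               sprintf("noise=%g", noise),
               sprintf("seed=%d", as.integer(config$seed))),
             paste0(config$out, ".provenance.txt"))
  write_resolved_config(config, config$out)
  invisible(table)
}

#' Score a dataset with one difficulty metric and write a scores CSV
#'
#' Dispatches on `config$metric`: the three network metrics (`cdmc`,
#' `cddm`, `cdpu`) or any baseline (`kdn`, `dcp`, `td_p`, `td_u`, `cl`,
#' `cld`, `mv`, `cb`, `n1`, `n2`, `lsc`, `lsr`, `harmfulness`,
#' `usefulness`, `f1`). The output CSV has 0-based `case_index` (the row
#' order of the input CSV, the join key everywhere), `difficulty`, and
#' per-metric diagnostic columns. Per-case seeds derive from
#' `(seed, case_index)`, so `workers` never changes the result.
#'
#' @param config Named list with `metric`, `in` (data CSV), `label_col`,
#'   `seed`, `out`, optional `workers` and metric-specific settings
#'   (`mnn`, `n_models`, `epochs`, `patience`, `iters_a`, `iters_b`, `k`,
#'   `tune_iters`, `tune_scope`).
#' @return The [difficulty_vector()], invisibly.
#' @export
run_score <- function(config) {
  require_fields(config, c("metric", "in", "label_col", "seed", "out"),
                 "score")
  table <- read_case_csv(config[["in"]], config$label_col)
  workers <- if (is.null(config$workers)) 1L else as.integer(config$workers)
  seed <- as.integer(config$seed)
  grab <- function(name, default) {
    if (is.null(config[[name]])) default else config[[name]]
  }
  metric <- config$metric
  dv <- switch(metric,
    cdmc = cdmc_all(table, cdmc_options(
      n_models = grab("n_models", 20L), mnn = config$mnn,
      max_epochs = grab("epochs", 100L), patience = grab("patience", 10L),
      seed = seed), workers = workers),
    cddm = cddm_all(table,
      space_a = search_space(n_iterations = grab("iters_a", 5L)),
      space_b = search_space(n_iterations = grab("iters_b", 10L)),
      seed = seed, max_epochs = grab("epochs", 500L),
      patience = grab("patience", 50L)),
    cdpu = cdpu_all(table, cdpu_options(
      n_models = grab("n_models", 100L),
      space = search_space(n_iterations = grab("tune_iters", 100L)),
      max_epochs = grab("epochs", 100L), patience = grab("patience", 30L),
      tune_scope = grab("tune_scope", "case"), seed = seed),
      workers = workers),
    kdn = kdn(table, grab("k", 10L)),
    dcp = tree_metrics(table, seed)$dcp,
    td_p = tree_metrics(table, seed)$td_p,
    td_u = tree_metrics(table, seed)$td_u,
    cl = bayes_metrics(table)$cl,
    cld = bayes_metrics(table)$cld,
    mv = skew_metrics(table)$mv,
    cb = skew_metrics(table)$cb,
    n1 = distance_metrics(table)$n1,
    n2 = distance_metrics(table)$n2,
    lsc = distance_metrics(table)$lsc,
    lsr = distance_metrics(table)$lsr,
    harmfulness = distance_metrics(table)$harmfulness,
    usefulness = distance_metrics(table)$usefulness,
    f1 = f1_overlap(table),
    stop("unknown metric '", metric, "'"))
  df <- data.frame(case_index = seq_along(dv$scores) - 1L,
                   difficulty = dv$scores)
  if (is.data.frame(dv$diagnostics)) {
    df <- cbind(df, dv$diagnostics)
  } else if (is.data.frame(dv$diagnostics$per_case)) {
    df <- cbind(df, dv$diagnostics$per_case)
  }
  utils::write.csv(df, config$out, row.names = FALSE, quote = FALSE)
  write_resolved_config(config, config$out)
  invisible(dv)
}

#' Compare score files: correlation CSV and optional images
#'
#' Joins two or more score CSVs by `case_index`, computes the all-pairs
#' masked [correlation_table()], and writes it as CSV (two blocks, Pearson
#' then Spearman, masked cells empty). Optionally renders a heatmap of the
#' Spearman block and/or a difficulty scatter for a 2-feature dataset.
#'
#' @param config Named list with `inputs` (character vector of score CSVs),
#'   `out`, optional `names`, `alpha` (default 0.05), `heatmap` (image
#'   path), `scatter` (image path, needs `data` + `label_col` + `metric`).
#' @return The `correlation_table`, invisibly.
#' @export
run_compare <- function(config) {
  require_fields(config, c("inputs", "out"), "compare")
  files <- config$inputs
  stopifnot(length(files) >= 2)
  ids <- if (!is.null(config$names)) config$names
         else sub("\\.csv$", "", basename(files))
  tabs <- lapply(files, utils::read.csv)
  n0 <- nrow(tabs[[1]])
  for (t in tabs) {
    if (nrow(t) != n0) stop("score files have mismatched case counts")
  }
  vectors <- lapply(tabs, function(t)
    t$difficulty[order(t$case_index)])
  names(vectors) <- ids
  ct <- correlation_table(vectors,
                          alpha = if (is.null(config$alpha)) 0.05 else config$alpha)
  block <- function(m, label) {
    df <- data.frame(metric = rownames(m), m, check.names = FALSE)
    df <- cbind(block = label, df)
    df
  }
  out_df <- rbind(block(ct$pearson, "pearson"), block(ct$spearman, "spearman"))
  utils::write.csv(out_df, config$out, row.names = FALSE, na = "")
  if (!is.null(config$heatmap)) {
    df <- as.data.frame(as.table(ct$spearman))
    names(df) <- c("a", "b", "rho")
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                          fill = .data$rho)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_gradient(low = "#fee5d9", high = "#99000d",
                                   limits = c(0, 1), na.value = "white") +
      ggplot2::labs(x = NULL, y = NULL, fill = "rho") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(config$heatmap, p, width = 5, height = 4, dpi = 150)
  }
  write_resolved_config(config, config$out)
  invisible(ct)
}
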