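#' Construct a case table
#'
#' A `case_table` is the universal input of every difficulty metric in this
#' package: a fully numeric feature matrix, an integer class label per case
#' (coded `0..K-1`), and a free-text provenance record describing how the
#' table was produced (generator or loader, parameters, seed).
#'
#' @param features Numeric matrix, one row per case.
#' @param labels Integer vector of class labels in `0..n_classes-1`.
#' @param n_classes Number of classes `K >= 2`. Defaults to
#'   `max(labels) + 1`.
#' @param feature_names Optional character vector of column names.
#' @param provenance Free-text record of origin (kept as a character vector).
#' @return An object of class `case_table` with elements `features`,
#'   `labels`, `n_classes`, `feature_names`, `provenance`.
#' @examples
#' tab <- case_table(matrix(rnorm(20), 10, 2), rep(0:1, each = 5))
#' n_cases(tab)
#' @export
case_table <- function(features, labels, n_classes = NULL,
                       feature_names = NULL, provenance = character()) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.integer(labels)
  if (is.null(n_classes)) n_classes <- max(labels) + 1L
  n_classes <- as.integer(n_classes)
  if (is.null(feature_names)) {
    feature_names <- colnames(features)
    if (is.null(feature_names))
      feature_names <- paste0("feature_", seq_len(ncol(features)))
  }
  colnames(features) <- feature_names
  obj <- structure(
    list(features = features, labels = labels, n_classes = n_classes,
         feature_names = feature_names, provenance = as.character(provenance)),
    class = "case_table")
  validate_case_table(obj)
  obj
}

validate_case_table <- function(x) {
  stopifnot(inherits(x, "case_table"))
  if (anyNA(x$features))
    stop("case_table features must not contain missing values")
  if (length(x$labels) != nrow(x$features))
    stop("labels length must match the number of feature rows")
  if (x$n_classes < 2L)
    stop("a case_table needs at least 2 classes")
  if (any(x$labels < 0L | x$labels >= x$n_classes))
    stop("labels must lie in 0..n_classes-1")
  present <- sort(unique(x$labels))
  if (!identical(present, seq_len(x$n_classes) - 1L))
    stop("every class in 0..n_classes-1 must occur at least once")
  if (nrow(x$features) < x$n_classes)
    stop("need at least one case per class")
  invisible(x)
}

#' @rdname case_table
#' @param x A `case_table`.
#' @export
n_cases <- function(x) nrow(x$features)

#' @export
print.case_table <- function(x, ...) {
  cat(sprintf("case_table: %d cases x %d features, %d classes\n",
              nrow(x$features), ncol(x$features), x$n_classes))
  tabu <- table(x$labels)
  cat("  class sizes:", paste(sprintf("%s=%d", names(tabu), tabu),
                              collapse = ", "), "\n")
  if (length(x$provenance))
    cat("  provenance:", x$provenance[1], "\n")
  invisible(x)
}

#' Subset a case table by row index
#'
#' Labels are kept on the original `0..K-1` coding; classes absent from the
#' subset are allowed (the result is used for model fitting, not validated as
#' a fresh table).
#'
#' @param x A `case_table`.
#' @param idx Integer row indices (1-based).
#' @return A list with `features` and `labels` (a lightweight split, not a
#'   validated `case_table`).
#' @keywords internal
#' @export
ct_subset <- function(x, idx) {
  list(features = x$features[idx, , drop = FALSE],
       labels = x$labels[idx],
       n_classes = x$n_classes)
}

# Deterministic 31-bit seed derivation so per-case work can be farmed out to
# parallel workers without the worker count or case order changing results.
# Multipliers are small enough that all arithmetic stays exact in doubles.
derive_seed <- function(seed, ...) {
  h <- (as.double(seed) %% 2147483647) + 1
  for (k in c(...)) {
    h <- (h * 69069 + as.double(k) + 12345) %% 2147483647
  }
  as.integer(h)
}

#' Describe how raw columns become model-ready features
#'
#' A `feature_schema` records, per raw column, whether it is continuous or
#' categorical, how missing entries are imputed (`"mean"`, `"most_frequent"`,
#' or `"constant"` with a stated value), and implies the fixed downstream
#' rules: continuous columns are standardized (center 0, SD 1, population
#' divisor), categorical columns are one-hot encoded keeping all levels.
#'
#' @param kinds Named character vector mapping column name to
#'   `"continuous"` or `"categorical"`.
#' @param impute Named character vector mapping column name to
#'   `"mean"`, `"most_frequent"` or `"constant"`. Columns not named default
#'   to `"mean"` (continuous) / `"most_frequent"` (categorical).
#' @param constants Named numeric/character vector of fill values for columns
#'   with the `"constant"` rule.
#' @return An object of class `feature_schema`.
#' @export
feature_schema <- function(kinds, impute = character(), constants = character()) {
  stopifnot(is.character(kinds), !is.null(names(kinds)))
  bad <- setdiff(unique(kinds), c("continuous", "categorical"))
  if (length(bad)) stop("unknown column kind: ", paste(bad, collapse = ", "))
  rules <- ifelse(kinds == "continuous", "mean", "most_frequent")
  names(rules) <- names(kinds)
  rules[names(impute)] <- impute
  bad <- setdiff(unique(rules), c("mean", "most_frequent", "constant"))
  if (length(bad)) stop("unknown imputation rule: ", paste(bad, collapse = ", "))
  structure(list(kinds = kinds, impute = rules, constants = constants),
            class = "feature_schema")
}

#' Preprocess a raw mixed-type table into a case table
#'
#' Applies the schema's imputation rules, standardizes continuous columns to
#' mean 0 / SD 1 (population SD, computed over the full table), expands
#' categorical columns into one-hot indicators (all levels kept), and recodes
#' the labels to `0..K-1` in lexicographic order of the original values. The
#' label mapping is recorded in the provenance.
#'
#' @param raw_table A `data.frame` with feature columns and one label column.
#' @param schema A [feature_schema()] covering every non-label column.
#' @param label_column Name of the label column.
#' @return A [case_table()].
#' @export
preprocess <- function(raw_table, schema, label_column) {
  stopifnot(is.data.frame(raw_table), inherits(schema, "feature_schema"))
  if (!label_column %in% names(raw_table))
    stop("label column '", label_column, "' not found")
  feat_cols <- setdiff(names(raw_table), label_column)
  missing_cols <- setdiff(feat_cols, names(schema$kinds))
  if (length(missing_cols))
    stop("schema does not cover columns: ", paste(missing_cols, collapse = ", "))

  lab_raw <- raw_table[[label_column]]
  if (anyNA(lab_raw)) stop("missing values in the label column")
  levels_sorted <- sort(unique(as.character(lab_raw)))
  labels <- match(as.character(lab_raw), levels_sorted) - 1L

  blocks <- list()
  for (col in feat_cols) {
    v <- raw_table[[col]]
    rule <- schema$impute[[col]]
    kind <- schema$kinds[[col]]
    if (kind == "continuous") {
      v <- as.numeric(v)
      if (anyNA(v)) {
        fill <- switch(rule,
          mean = mean(v, na.rm = TRUE),
          most_frequent = as.numeric(names(sort(table(v), decreasing = TRUE))[1]),
          constant = as.numeric(schema$constants[[col]]))
        v[is.na(v)] <- fill
      }
      mu <- mean(v)
      sd_pop <- sqrt(mean((v - mu)^2))
      if (sd_pop < 1e-12)
        stop("continuous column '", col, "' has zero variance; cannot scale")
      blocks[[col]] <- matrix((v - mu) / sd_pop, ncol = 1,
                              dimnames = list(NULL, col))
    } else {
      v <- as.character(v)
      if (anyNA(v)) {
        fill <- switch(rule,
          most_frequent = names(sort(table(v), decreasing = TRUE))[1],
          constant = as.character(schema$constants[[col]]),
          mean = stop("mean imputation is not defined for categorical column '",
                      col, "'"))
        v[is.na(v)] <- fill
      }
      levs <- sort(unique(v))
      ind <- matrix(0, length(v), length(levs),
                    dimnames = list(NULL, paste0(col, "=", levs)))
      ind[cbind(seq_along(v), match(v, levs))] <- 1
      blocks[[col]] <- ind
    }
  }
  features <- do.call(cbind, blocks)
  case_table(features, labels, n_classes = length(levels_sorted),
             provenance = c(
               sprintf("preprocess: label_column=%s", label_column),
               sprintf("label_mapping: %s",
                       paste(sprintf("%s->%d", levels_sorted,
                                     seq_along(levels_sorted) - 1L),
                             collapse = ", "))))
}
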