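score_values <- function(x) {
  if (inherits(x, "difficulty_vector")) x$scores else as.numeric(x)
}

is_constant <- function(x) length(unique(x)) < 2L

#' Pearson and Spearman correlation between two difficulty vectors
#'
#' Pearson is computed on the raw scores, Spearman on average ranks, both
#' with two-sided p-values. If either input is constant, neither
#' coefficient is defined and the report carries an `undefined` flag (this
#' is the situation of simple datasets where a metric assigns every case
#' the same lowest difficulty).
#'
#' @param a,b [difficulty_vector()]s (or plain numeric vectors) of equal
#'   length computed on the same table.
#' @return A `correlation_report`: `pearson_r`, `pearson_p`,
#'   `spearman_rho`, `spearman_p`, `undefined`, `reason`.
#' @export
correlate <- function(a, b) {
  va <- score_values(a); vb <- score_values(b)
  if (length(va) != length(vb))
    stop("difficulty vectors have different lengths (", length(va), " vs ",
         length(vb), ")")
  if (is_constant(va) || is_constant(vb)) {
    return(structure(list(pearson_r = NA_real_, pearson_p = NA_real_,
                          spearman_rho = NA_real_, spearman_p = NA_real_,
                          undefined = TRUE, reason = "constant input"),
                     class = "correlation_report"))
  }
  pe <- stats::cor.test(va, vb, method = "pearson", alternative = "two.sided")
  sp <- suppressWarnings(
    stats::cor.test(va, vb, method = "spearman", alternative = "two.sided",
                    exact = FALSE))
  structure(list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
                 spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
                 undefined = FALSE, reason = NA_character_),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  if (x$undefined) {
    cat("correlation_report: undefined (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("correlation_report: pearson r = %.3f (p = %.3g), spearman rho = %.3f (p = %.3g)\n",
                x$pearson_r, x$pearson_p, x$spearman_rho, x$spearman_p))
  }
  invisible(x)
}

#' All-pairs correlation table with p-value masking
#'
#' Computes [correlate()] for every pair of vectors and masks (sets to
#' `NA`) any cell whose p-value is at or above `alpha` or whose correlation
#' is undefined — mirroring heatmaps where only correlations with
#' `p < 0.05` are displayed and constant metrics leave empty cells.
#'
#' @param vectors Named list of two or more [difficulty_vector()]s on one
#'   table.
#' @param alpha Significance level for masking (default 0.05).
#' @return A `correlation_table`: matrices `pearson` and `spearman` (masked)
#'   plus unmasked `pearson_full`, `spearman_full`, `pearson_p`,
#'   `spearman_p`.
#' @export
correlation_table <- function(vectors, alpha = 0.05) {
  stopifnot(length(vectors) >= 2)
  ids <- names(vectors)
  if (is.null(ids))
    ids <- vapply(vectors, function(v)
      if (inherits(v, "difficulty_vector")) v$metric else "v", character(1))
  k <- length(vectors)
  pe <- sp <- pe_p <- sp_p <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      r <- correlate(vectors[[i]], vectors[[j]])
      pe[i, j] <- r$pearson_r; sp[i, j] <- r$spearman_rho
      pe_p[i, j] <- r$pearson_p; sp_p[i, j] <- r$spearman_p
    }
  }
  mask <- function(m, p) { m[is.na(p) | p >= alpha] <- NA_real_; m }
  structure(list(pearson = mask(pe, pe_p), spearman = mask(sp, sp_p),
                 pearson_full = pe, spearman_full = sp,
                 pearson_p = pe_p, spearman_p = sp_p, alpha = alpha),
            class = "correlation_table")
}

#' @export
print.correlation_table <- function(x, ...) {
  cat("correlation_table (cells with p >=", x$alpha, "masked)\nPearson:\n")
  print(round(x$pearson, 3))
  cat("Spearman:\n")
  print(round(x$spearman, 3))
  invisible(x)
}

#' Difficulty enrichment inside a feature-space region
#'
#' Quantifies whether difficult cases concentrate in a region (typically
#' the class-overlap band): compares mean difficulty inside vs outside and
#' runs a one-sided Mann-Whitney test of inside > outside.
#'
#' @param table A [case_table()].
#' @param scores A [difficulty_vector()] (or numeric vector) for the table.
#' @param region Logical vector over cases, or a predicate function taking
#'   the feature matrix and returning one.
#' @return A list: `mean_inside`, `mean_outside`, `difference`, `p_value`,
#'   `n_inside`, `n_outside`.
#' @export
overlap_enrichment <- function(table, scores, region) {
  validate_case_table(table)
  s <- score_values(scores)
  inside <- if (is.function(region)) region(table$features) else as.logical(region)
  stopifnot(length(inside) == n_cases(table), length(s) == n_cases(table))
  if (!any(inside) || all(inside))
    stop("region must contain some but not all cases")
  p <- if (is_constant(s)) 1 else
    suppressWarnings(stats::wilcox.test(s[inside], s[!inside],
                                        alternative = "greater")$p.value)
  list(mean_inside = mean(s[inside]), mean_outside = mean(s[!inside]),
       difference = mean(s[inside]) - mean(s[!inside]),
       p_value = p, n_inside = sum(inside), n_outside = sum(!inside))
}

#' Export a 2-D difficulty scatter plot
#'
#' Writes a scatter of the two features colored by difficulty on a fixed
#' 0-1 scale (light = easy, dark red = hard), so plots of different metrics
#' and datasets are directly comparable.
#'
#' @param table A [case_table()] with exactly 2 features; for
#'   higher-dimensional data, pre-embed (e.g. t-SNE/FAMD) and build a 2-D
#'   table from the embedding.
#' @param scores A [difficulty_vector()] or numeric vector.
#' @param path Output image path (extension decides the device, e.g. .png).
#' @param width,height,dpi Image geometry passed to [ggplot2::ggsave()].
#' @return `path`, invisibly.
#' @export
export_scatter <- function(table, scores, path, width = 5, height = 4,
                           dpi = 150) {
  validate_case_table(table)
  if (ncol(table$features) != 2)
    stop("export_scatter needs exactly 2 features; pre-embed ",
         "higher-dimensional data to 2-D first")
  s <- score_values(scores)
  df <- data.frame(x = table$features[, 1], y = table$features[, 2],
                   difficulty = s)
  metric <- if (inherits(scores, "difficulty_vector")) scores$metric else "difficulty"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        colour = .data$difficulty)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_gradient(low = "#fee5d9", high = "#99000d",
                                   limits = c(0, 1), name = metric) +
    ggplot2::labs(x = table$feature_names[1], y = table$feature_names[2]) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = width, height = height, dpi = dpi)
  invisible(path)
}
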