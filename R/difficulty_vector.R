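#' Per-case difficulty scores
#'
#' Container tying a vector of per-case difficulty scores in `[0, 1]` to the
#' metric that produced them, per-metric diagnostics, and provenance.
#'
#' @param metric Metric identifier (e.g. `"cdmc"`, `"kdn"`).
#' @param scores Numeric vector, one score per case, each in `[0, 1]`.
#' @param diagnostics Per-metric record (list or data.frame), may be empty.
#' @param provenance Character record of source table, options and seed.
#' @return An object of class `difficulty_vector`.
#' @export
difficulty_vector <- function(metric, scores, diagnostics = list(),
                              provenance = character()) {
  scores <- as.numeric(scores)
  if (anyNA(scores)) stop("difficulty scores must not be missing")
  if (any(scores < -1e-12 | scores > 1 + 1e-12))
    stop("difficulty scores must lie in [0, 1]")
  structure(list(metric = as.character(metric),
                 scores = pmin(pmax(scores, 0), 1),
                 diagnostics = diagnostics,
                 provenance = as.character(provenance)),
            class = "difficulty_vector")
}

#' @export
print.difficulty_vector <- function(x, ...) {
  cat(sprintf("difficulty_vector [%s]: %d cases, mean %.3f, range [%.3f, %.3f]\n",
              x$metric, length(x$scores), mean(x$scores),
              min(x$scores), max(x$scores)))
  invisible(x)
}

# Run FUN(i) for each case index, sequentially or with forked workers.
# Results are identical across worker counts because every per-case seed is
# derived from (seed, index) before dispatch.
case_apply <- function(n, fun, workers = 1L) {
  if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(n), fun, mc.cores = workers)
  } else {
    lapply(seq_len(n), fun)
  }
}
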