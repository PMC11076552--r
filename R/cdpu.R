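#' Options for the predictive-uncertainty difficulty metric (CDpu)
#'
#' CDpu scores a case from the distribution of predicted probabilities an
#' ensemble of retrained networks assigns to it when left out: the distance
#' of the mean prediction from the 0/1 ground-truth indicator (location
#' factor) averaged with the spread normalized by the standard deviation of
#' the uniform distribution, `sqrt(1/12)` (distribution factor), capped at 1.
#'
#' @param n_models Networks in the ensemble (default 100; at least 2 so the
#'   SD is defined).
#' @param space A [search_space()] for hyperparameter tuning (default: the
#'   standard grid with 100 candidate evaluations).
#' @param max_epochs,patience Training budget (defaults 100 / 30; small
#'   datasets may warrant patience 10).
#' @param tune_scope `"case"` (default) tunes hyperparameters once per
#'   left-out case on a 70/30 split of the remainder; `"dataset"` tunes once
#'   on the full table and reuses the configuration for every case (cheaper).
#' @param train_fraction Training share of the tuning split (default 0.7).
#' @param seed Master seed; per-case seeds are derived from `(seed, index)`.
#' @return An object of class `cdpu_options`.
#' @export
cdpu_options <- function(n_models = 100L, space = search_space(n_iterations = 100L),
                         max_epochs = 100L, patience = 30L,
                         tune_scope = c("case", "dataset"),
                         train_fraction = 0.7, seed = 1L) {
  tune_scope <- match.arg(tune_scope)
  stopifnot(n_models >= 2, inherits(space, "search_space"))
  structure(list(n_models = as.integer(n_models), space = space,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 tune_scope = tune_scope,
                 train_fraction = train_fraction,
                 seed = as.integer(seed)),
            class = "cdpu_options")
}

#' CDpu score from a stack of predicted probability rows
#'
#' For each class `c` with ground-truth indicator `y_c` (1 for the true
#' class, 0 otherwise), the location factor is `|mu_c - y_c|` and the
#' distribution factor is `sigma_c / sqrt(1/12)`, where `mu_c` and `sigma_c`
#' are the mean and population SD of the `m` predicted probabilities for
#' class `c`. Each class scores `(location + distribution) / 2`; the binary
#' case uses the positive-class column only, the multi-class case averages
#' the class scores over all `K` classes. A raw value above 1 (possible for
#' bimodal probability stacks, whose SD exceeds the uniform SD) is capped
#' at 1.
#'
#' @param probs Numeric matrix, `m` ensemble draws x `K` classes; every row
#'   must lie on the probability simplex (tolerance 1e-6).
#' @param true_class Ground-truth class in `0..K-1`.
#' @return A `cdpu_score` list: `difficulty` (capped), `raw`, `capped`,
#'   per-class `mu`, `sigma`, `location`, `distribution`.
#' @examples
#' probs <- matrix(rep(c(0, 1), 5), ncol = 2, byrow = TRUE)
#' cdpu_score_from_probs(probs, true_class = 1)$difficulty  # 0
#' @export
cdpu_score_from_probs <- function(probs, true_class) {
  probs <- as.matrix(probs)
  m <- nrow(probs); K <- ncol(probs)
  if (m < 2) stop("need at least 2 probability draws (SD undefined)")
  if (K < 2) stop("need at least 2 class columns")
  if (any(probs < -1e-6 | probs > 1 + 1e-6) ||
      any(abs(rowSums(probs) - 1) > 1e-6))
    stop("probability rows must lie on the simplex (tolerance 1e-6)")
  if (true_class < 0 || true_class >= K) stop("true_class out of range")

  mu <- colMeans(probs)
  sigma <- sqrt(colMeans(sweep(probs, 2, mu)^2))  # population SD
  y <- as.numeric(seq_len(K) - 1 == true_class)
  location <- abs(mu - y)
  distribution <- sigma / sqrt(1 / 12)
  class_scores <- (location + distribution) / 2
  # binary: the positive-class column alone; multi-class: mean over classes
  raw <- unname(if (K == 2) class_scores[2] else mean(class_scores))
  structure(list(difficulty = min(raw, 1), raw = raw, capped = raw > 1,
                 mu = mu, sigma = sigma, location = location,
                 distribution = distribution),
            class = "cdpu_score")
}

resolve_cdpu_config <- function(train, val, opts, seed, n_classes) {
  tune(train, val, opts$space, seed,
       max_epochs = opts$max_epochs, patience = opts$patience)
}

#' CDpu difficulty of a single case
#'
#' Leaves case `index` out; tunes hyperparameters once on a stratified
#' 70/30 split of the remainder (unless `opts$tune_scope = "dataset"`, in
#' which case a pre-tuned configuration is reused); trains `opts$n_models`
#' networks, each on an independently shuffled copy of the remaining data
#' with its own seed (the shuffle determines that network's 70/30
#' train/validation split for early stopping); stacks the networks'
#' predicted probability rows for the left-out case and scores the stack
#' with [cdpu_score_from_probs()].
#'
#' @param table A [case_table()].
#' @param index Case index, 1-based.
#' @param opts A [cdpu_options()].
#' @param config Optional pre-tuned [net_config()] (used by [cdpu_all()] in
#'   `"dataset"` tuning scope).
#' @return A `cdpu_score` (see [cdpu_score_from_probs()]), with the
#'   probability stack attached as attribute `"probs"`.
#' @export
cdpu_case <- function(table, index, opts = cdpu_options(), config = NULL) {
  validate_case_table(table)
  n <- n_cases(table)
  if (index < 1 || index > n) stop("case index out of range: ", index)
  case_seed <- derive_seed(opts$seed, index)
  rest <- setdiff(seq_len(n), index)

  if (is.null(config)) {
    sp <- stratified_split(table$labels[rest], opts$train_fraction, case_seed)
    config <- resolve_cdpu_config(ct_subset(table, rest[sp$train]),
                                  ct_subset(table, rest[sp$val]),
                                  opts, derive_seed(case_seed, 11),
                                  table$n_classes)
  }

  x_test <- table$features[index, , drop = FALSE]
  n_rest <- length(rest)
  n_tr <- max(2L, round(opts$train_fraction * n_rest))
  probs <- matrix(NA_real_, opts$n_models, table$n_classes)
  for (m in seq_len(opts$n_models)) {
    mseed <- derive_seed(case_seed, 17, m)
    shuffled <- rest[withr::with_seed(mseed, sample(n_rest))]
    tr <- ct_subset(table, shuffled[seq_len(n_tr)])
    va <- ct_subset(table, shuffled[(n_tr + 1):n_rest])
    cfg <- config
    cfg$seed <- mseed
    if (length(unique(tr$labels)) < 2L) {
      # a shuffle starving the training split of a class: fall back to
      # a stratified draw from the same seed
      spv <- stratified_split(table$labels[rest], opts$train_fraction, mseed)
      tr <- ct_subset(table, rest[spv$train])
      va <- ct_subset(table, rest[spv$val])
    }
    net <- train_net(tr, va, cfg, n_classes = table$n_classes)
    probs[m, ] <- predict_proba(net, x_test)
  }
  score <- cdpu_score_from_probs(probs, table$labels[index])
  attr(score, "probs") <- probs
  score
}

#' CDpu difficulty of every case
#'
#' Applies [cdpu_case()] to each case with per-case seeds derived from
#' `(opts$seed, index)`; scores are independent of case order and worker
#' count. With `opts$tune_scope = "dataset"` the hyperparameters are tuned
#' once on the full table and reused.
#'
#' @inheritParams cdpu_case
#' @param workers Forked parallel workers (1 = sequential).
#' @return A [difficulty_vector()]; diagnostics hold per-case `raw`,
#'   `capped`, and per-class `mu`/`sigma` columns.
#' @export
cdpu_all <- function(table, opts = cdpu_options(), workers = 1L) {
  validate_case_table(table)
  config <- NULL
  if (opts$tune_scope == "dataset") {
    sp <- stratified_split(table$labels, opts$train_fraction,
                           derive_seed(opts$seed, 5))
    config <- resolve_cdpu_config(ct_subset(table, sp$train),
                                  ct_subset(table, sp$val),
                                  opts, derive_seed(opts$seed, 6),
                                  table$n_classes)
  }
  res <- case_apply(n_cases(table), function(i) {
    tryCatch(cdpu_case(table, i, opts, config = config),
             error = function(e) stop("cdpu failed at case ", i, ": ",
                                      conditionMessage(e)))
  }, workers)
  K <- table$n_classes
  diag <- data.frame(
    raw = vapply(res, `[[`, numeric(1), "raw"),
    capped = vapply(res, `[[`, logical(1), "capped"))
  for (k in seq_len(K)) {
    diag[[paste0("mu_", k - 1)]] <- vapply(res, function(s) s$mu[k], numeric(1))
    diag[[paste0("sigma_", k - 1)]] <- vapply(res, function(s) s$sigma[k],
                                              numeric(1))
  }
  difficulty_vector(
    "cdpu", vapply(res, `[[`, numeric(1), "difficulty"),
    diagnostics = diag,
    provenance = c(table$provenance,
                   sprintf("cdpu: n_models=%d tune_scope=%s seed=%d",
                           opts$n_models, opts$tune_scope, opts$seed)))
}
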