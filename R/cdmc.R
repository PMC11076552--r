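#' Options for the model-complexity difficulty metric (CDmc)
#'
#' CDmc scores a case by the smallest single-hidden-layer width at which an
#' ensemble of retrained networks reliably classifies it when left out.
#' Defaults follow the method's study conditions: 20 networks per width,
#' a 90% success threshold, maximum width (MNN) of 1% of the sample size,
#' ReLU activation, batch 32, 100 epochs.
#'
#' @param n_models Networks trained per width (default 20).
#' @param success_fraction Fraction of networks that must classify the
#'   left-out case correctly (default 0.9; the threshold count is
#'   `ceiling(success_fraction * n_models)`).
#' @param mnn Maximum number of neurons tried, and the normalization
#'   denominator. `NULL` (default) means `ceiling(0.01 * n)`, minimum 1.
#' @param train_fraction Fraction of the remaining cases used for training
#'   (the rest is validation; default 0.7, stratified by class).
#' @param learning_rate,batch_size,max_epochs,patience,activation Base
#'   network settings shared by every ensemble member.
#' @param seed Master seed; per-case seeds are derived from `(seed, index)`.
#' @return An object of class `cdmc_options`.
#' @export
cdmc_options <- function(n_models = 20L, success_fraction = 0.9, mnn = NULL,
                         train_fraction = 0.7, learning_rate = 0.01,
                         batch_size = 32L, max_epochs = 100L, patience = 10L,
                         activation = "relu", seed = 1L) {
  stopifnot(n_models >= 1, success_fraction > 0, success_fraction <= 1,
            is.null(mnn) || mnn >= 1, train_fraction > 0, train_fraction < 1)
  structure(list(n_models = as.integer(n_models),
                 success_fraction = success_fraction,
                 mnn = if (is.null(mnn)) NULL else as.integer(mnn),
                 train_fraction = train_fraction,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 activation = activation,
                 seed = as.integer(seed)),
            class = "cdmc_options")
}

resolve_mnn <- function(opts, n) {
  if (!is.null(opts$mnn)) return(opts$mnn)
  max(1L, as.integer(ceiling(0.01 * n)))
}

#' CDmc difficulty of a single case
#'
#' Leaves case `index` out, splits the remaining cases into
#' `train_fraction` / rest (stratified by class, drawn once per case), and
#' for hidden-layer widths `w = 1, 2, ..., mnn` trains `n_models`
#' single-hidden-layer networks with distinct seeds, counting how many
#' predict the left-out case's label. The search stops at the first width
#' where the count reaches `ceiling(success_fraction * n_models)`, or at
#' `mnn`. Difficulty is `w_stop / mnn`, in `(0, 1]`: easy cases are solved
#' by one neuron (score `1/mnn`), cases never solved score 1.
#'
#' @param table A [case_table()].
#' @param index Case index, 1-based.
#' @param opts A [cdmc_options()].
#' @return A list with `difficulty` and `diag` (a `cdmc_diagnostics` list:
#'   `neurons_used`, `solved`, `success_counts` per width tried).
#' @export
cdmc_case <- function(table, index, opts = cdmc_options()) {
  validate_case_table(table)
  n <- n_cases(table)
  if (index < 1 || index > n) stop("case index out of range: ", index)
  mnn <- resolve_mnn(opts, n)
  threshold <- as.integer(ceiling(opts$success_fraction * opts$n_models))
  case_seed <- derive_seed(opts$seed, index)

  rest <- setdiff(seq_len(n), index)
  split <- stratified_split(table$labels[rest], opts$train_fraction, case_seed)
  tr <- ct_subset(table, rest[split$train])
  va <- ct_subset(table, rest[split$val])
  x_test <- table$features[index, , drop = FALSE]
  y_test <- table$labels[index]

  counts <- integer(0)
  w_stop <- mnn
  solved <- FALSE
  for (w in seq_len(mnn)) {
    correct <- 0L
    for (m in seq_len(opts$n_models)) {
      cfg <- net_config(hidden_layer_sizes = w, activation = opts$activation,
                        learning_rate = opts$learning_rate,
                        batch_size = opts$batch_size,
                        max_epochs = opts$max_epochs,
                        patience = opts$patience,
                        seed = derive_seed(case_seed, w, m))
      net <- train_net(tr, va, cfg, n_classes = table$n_classes)
      if (predict_class(net, x_test) == y_test) correct <- correct + 1L
    }
    counts <- c(counts, correct)
    if (correct >= threshold) {
      w_stop <- w
      solved <- TRUE
      break
    }
  }
  list(difficulty = w_stop / mnn,
       diag = structure(list(neurons_used = w_stop, solved = solved,
                             success_counts = counts, mnn = mnn,
                             threshold = threshold),
                        class = "cdmc_diagnostics"))
}

#' CDmc difficulty of every case
#'
#' Applies [cdmc_case()] to each case with a per-case seed derived from
#' `(opts$seed, index)`, so scores are independent of case order and of the
#' worker count.
#'
#' @inheritParams cdmc_case
#' @param workers Forked parallel workers (1 = sequential; results are
#'   identical either way).
#' @return A [difficulty_vector()] whose diagnostics is a data.frame with
#'   `neurons_used` and `solved` per case.
#' @export
cdmc_all <- function(table, opts = cdmc_options(), workers = 1L) {
  validate_case_table(table)
  res <- case_apply(n_cases(table), function(i) {
    out <- tryCatch(cdmc_case(table, i, opts),
                    error = function(e) stop("cdmc failed at case ", i, ": ",
                                             conditionMessage(e)))
    list(d = out$difficulty, w = out$diag$neurons_used, s = out$diag$solved)
  }, workers)
  difficulty_vector(
    "cdmc",
    vapply(res, `[[`, numeric(1), "d"),
    diagnostics = data.frame(
      neurons_used = vapply(res, `[[`, integer(1), "w"),
      solved = vapply(res, `[[`, logical(1), "s")),
    provenance = c(table$provenance,
                   sprintf("cdmc: n_models=%d mnn=%d seed=%d",
                           opts$n_models, resolve_mnn(opts, n_cases(table)),
                           opts$seed)))
}
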