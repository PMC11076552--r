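#' Five-set rotation plan for the double-model difficulty metric (CDdm)
#'
#' Cases are assigned to five sets of (as near as possible) equal size,
#' stratified by class: within each class the cases are shuffled and dealt
#' round-robin, continuing the deal across classes so overall set sizes
#' differ by at most one. Over the five rotations every case is scored
#' exactly once.
#'
#' @param labels Integer class labels (any coding).
#' @param seed Integer seed; identical labels and seed give identical
#'   assignments.
#' @return An object of class `fold_plan` with `assignments` (values 0..4)
#'   and the rotation `schedule` (for rotation `r`: A-train sets
#'   `{r, r+1}`, A-predict / B-train sets `{r+2, r+3}`, B-predict set
#'   `{r+4}`, all mod 5).
#' @export
make_fold_plan <- function(labels, seed) {
  n <- length(labels)
  if (n < 10) stop("too few cases for a 5-set rotation: need n >= 10")
  order_all <- withr::with_seed(as.integer(seed), {
    unlist(lapply(sort(unique(labels)), function(cl) {
      idx <- which(labels == cl)
      if (length(idx) > 1) sample(idx) else idx
    }), use.names = FALSE)
  })
  assignments <- integer(n)
  assignments[order_all] <- (seq_len(n) - 1L) %% 5L
  schedule <- lapply(0:4, function(r) list(
    a_train = (r + 0:1) %% 5L,
    b_train = (r + 2:3) %% 5L,
    b_predict = (r + 4L) %% 5L))
  structure(list(assignments = assignments, schedule = schedule),
            class = "fold_plan")
}

#' CDdm difficulty of every case
#'
#' For each rotation of the five-set plan: Model A (a tuned network
#' classifying the original labels) is trained on two sets and predicts the
#' next two; a binary correctness target records whether A's argmax
#' prediction was right; Model B (a tuned network classifying correctness
#' from the original features) is trained on those two sets and scores the
#' held-out fifth set. A case's difficulty is Model B's predicted
#' probability that Model A misclassifies it, so values near 1 mean
#' difficult. If B's training target is degenerate (A was right on every
#' case, or wrong on every case), the held-out set receives that constant
#' observed incorrect-rate (0 or 1) and the event is logged.
#'
#' @param table A [case_table()].
#' @param plan A [make_fold_plan()] for `table$labels` (built automatically
#'   when `NULL`).
#' @param space_a,space_b [search_space()] grids for Models A and B; the
#'   default budgets are 5 and 10 candidate evaluations.
#' @param seed Master seed for tuning and training.
#' @param max_epochs,patience Training budget (defaults 500 / 50).
#' @return A [difficulty_vector()]; diagnostics hold, per case, the rotation
#'   that scored it and Model A's correctness from the case's two A-predict
#'   appearances, plus the per-rotation trained B models and degeneracy log.
#' @export
cddm_all <- function(table, plan = NULL,
                     space_a = search_space(n_iterations = 5L),
                     space_b = search_space(n_iterations = 10L),
                     seed = 1L, max_epochs = 500L, patience = 50L) {
  validate_case_table(table)
  n <- n_cases(table)
  if (is.null(plan)) plan <- make_fold_plan(table$labels, seed)
  stopifnot(inherits(plan, "fold_plan"), length(plan$assignments) == n)

  scores <- rep(NA_real_, n)
  scored_rotation <- rep(NA_integer_, n)
  a_correct <- vector("list", n)
  models_b <- vector("list", 5)
  degenerate <- logical(5)

  for (r in 0:4) {
    sch <- plan$schedule[[r + 1]]
    rseed <- derive_seed(seed, 1000, r)
    a_idx <- which(plan$assignments %in% sch$a_train)
    m_idx <- which(plan$assignments %in% sch$b_train)
    h_idx <- which(plan$assignments == sch$b_predict)

    sp <- stratified_split(table$labels[a_idx], 0.7, derive_seed(rseed, 1))
    tr_a <- ct_subset(table, a_idx[sp$train])
    va_a <- ct_subset(table, a_idx[sp$val])
    cfg_a <- tune(tr_a, va_a, space_a, derive_seed(rseed, 2),
                  max_epochs = max_epochs, patience = patience)
    net_a <- train_net(tr_a, va_a, cfg_a, n_classes = table$n_classes)

    pred_m <- predict_class(net_a, table$features[m_idx, , drop = FALSE])
    correct <- pred_m == table$labels[m_idx]
    for (k in seq_along(m_idx)) {
      a_correct[[m_idx[k]]] <- c(a_correct[[m_idx[k]]],
                                 stats::setNames(correct[k], paste0("r", r)))
    }

    if (length(unique(correct)) < 2L) {
      # degenerate correctness target: constant observed incorrect-rate
      degenerate[r + 1] <- TRUE
      scores[h_idx] <- mean(!correct)
    } else {
      y_b <- as.integer(!correct)  # class 1 = A was incorrect
      sp_b <- stratified_split(y_b, 0.7, derive_seed(rseed, 3))
      tr_b <- list(features = table$features[m_idx[sp_b$train], , drop = FALSE],
                   labels = y_b[sp_b$train], n_classes = 2L)
      va_b <- list(features = table$features[m_idx[sp_b$val], , drop = FALSE],
                   labels = y_b[sp_b$val])
      cfg_b <- tune(tr_b, va_b, space_b, derive_seed(rseed, 4),
                    max_epochs = max_epochs, patience = patience)
      net_b <- train_net(tr_b, va_b, cfg_b, n_classes = 2L)
      models_b[[r + 1]] <- net_b
      probs <- predict_proba(net_b, table$features[h_idx, , drop = FALSE])
      scores[h_idx] <- probs[, 2]
    }
    scored_rotation[h_idx] <- r
  }

  difficulty_vector(
    "cddm", scores,
    diagnostics = list(
      per_case = data.frame(rotation = scored_rotation,
                            model_a_correct = vapply(a_correct, function(v)
                              mean(as.numeric(v)), numeric(1))),
      a_correct = a_correct,
      models_b = models_b,
      degenerate_rotations = which(degenerate) - 1L),
    provenance = c(table$provenance,
                   sprintf("cddm: iters_a=%d iters_b=%d seed=%d",
                           space_a$n_iterations, space_b$n_iterations,
                           as.integer(seed))))
}

#' Score new cases with the trained CDdm correctness models
#'
#' CDdm needs no ground-truth label to score a new case once its Model B
#' networks are trained: the difficulty of a new feature vector is the mean
#' predicted probability of misclassification over the rotations' trained B
#' models (degenerate rotations contribute their constant rate).
#'
#' @param fit A `difficulty_vector` returned by [cddm_all()].
#' @param features Numeric matrix of new cases (training dimensionality).
#' @return Numeric vector of difficulty scores in `[0, 1]`.
#' @export
cddm_predict_new <- function(fit, features) {
  stopifnot(inherits(fit, "difficulty_vector"), fit$metric == "cddm")
  nets <- Filter(Negate(is.null), fit$diagnostics$models_b)
  if (!length(nets))
    stop("all rotations were degenerate; no Model B available")
  features <- as.matrix(features)
  m <- vapply(nets, function(nb) predict_proba(nb, features)[, 2],
              numeric(nrow(features)))
  rowMeans(matrix(m, nrow = nrow(features)))
}
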