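# Classical instance-hardness measures, each oriented so higher = harder.
# Orientation transforms are recorded in the provenance of each vector.

baseline_vector <- function(metric, scores, table, note) {
  difficulty_vector(metric, scores,
                    provenance = c(table$provenance,
                                   sprintf("%s orientation: %s", metric, note)))
}

#' k-Disagreeing Neighbors (kDN)
#'
#' Fraction of a case's `k` nearest neighbors (Euclidean, self excluded)
#' that belong to a different class.
#'
#' @param table A [case_table()].
#' @param k Neighborhood size (default 10; requires `n > k`).
#' @return A [difficulty_vector()] with metric id `"kdn"`.
#' @export
kdn <- function(table, k = 10L) {
  validate_case_table(table)
  n <- n_cases(table)
  if (n <= k) stop("kdn needs n > k (n = ", n, ", k = ", k, ")")
  D <- as.matrix(stats::dist(table$features))
  scores <- vapply(seq_len(n), function(i) {
    ord <- order(D[i, -i])
    nb <- setdiff(seq_len(n), i)[ord][seq_len(k)]
    mean(table$labels[nb] != table$labels[i])
  }, numeric(1))
  baseline_vector("kdn", scores, table, "raw (already difficulty-oriented)")
}

tree_depths <- function(fit) {
  node <- as.integer(rownames(fit$frame))[fit$where]
  floor(log2(node))
}

#' Decision-tree hardness measures: DCP, TD_P, TD_U
#'
#' Fits one unpruned CART tree (`cp = 0`, unlimited depth, leaves of at
#' least `minbucket` cases) and one cost-complexity-pruned tree (complexity
#' parameter chosen by 5-fold cross-validation). Disjunct Class Percentage
#' (DCP) difficulty is one minus the same-class fraction in the case's
#' unpruned-tree leaf; Tree Depth difficulty is the case's leaf depth
#' normalized by the tree's maximum leaf depth, for the pruned (TD_P) and
#' unpruned (TD_U) tree.
#'
#' @param table A [case_table()].
#' @param seed Seed for the cross-validated pruning.
#' @param minsplit,minbucket Growth limits of the "unpruned" tree; a tree
#'   grown to singleton leaves would make every leaf pure and DCP
#'   identically zero, so leaves aggregate a small neighborhood by default.
#' @return Named list of three [difficulty_vector()]s: `dcp`, `td_p`, `td_u`.
#' @export
tree_metrics <- function(table, seed = 1L, minsplit = 10L, minbucket = 5L) {
  validate_case_table(table)
  df <- data.frame(.y = factor(table$labels), table$features,
                   check.names = FALSE)
  if (length(unique(table$labels)) < 2L || all(apply(table$features, 2,
                                                     stats::var) < 1e-24))
    stop("degenerate tree input: constant labels or features")
  fit_u <- rpart::rpart(.y ~ ., df, method = "class",
                        control = rpart::rpart.control(
                          cp = 0, minsplit = minsplit, minbucket = minbucket,
                          maxdepth = 30, xval = 0))
  fit_cv <- withr::with_seed(as.integer(seed),
    rpart::rpart(.y ~ ., df, method = "class",
                 control = rpart::rpart.control(
                   cp = 0, minsplit = minsplit, minbucket = minbucket,
                   maxdepth = 30, xval = 5)))
  cp_best <- fit_cv$cptable[which.min(fit_cv$cptable[, "xerror"]), "CP"]
  fit_p <- rpart::prune(fit_cv, cp = cp_best)

  leaf_u <- fit_u$where
  same_frac <- vapply(seq_len(nrow(df)), function(i) {
    in_leaf <- leaf_u == leaf_u[i]
    mean(table$labels[in_leaf] == table$labels[i])
  }, numeric(1))

  norm_depth <- function(fit) {
    d <- tree_depths(fit)
    if (max(d) == 0) rep(0, length(d)) else d / max(d)
  }
  list(dcp = baseline_vector("dcp", 1 - same_frac, table,
                             "1 - same-class fraction in unpruned-tree leaf"),
       td_p = baseline_vector("td_p", norm_depth(fit_p), table,
                              "leaf depth / max depth (CV-pruned tree)"),
       td_u = baseline_vector("td_u", norm_depth(fit_u), table,
                              "leaf depth / max depth (unpruned tree)"))
}

# Gaussian Naive Bayes posteriors in the log domain; per-class, per-feature
# variances floored at 1e-9 (sample variance, divisor n_c - 1).
gnb_posteriors <- function(features, labels, n_classes) {
  n <- nrow(features)
  loglik <- matrix(0, n, n_classes)
  for (c in seq_len(n_classes) - 1L) {
    idx <- labels == c
    mu <- colMeans(features[idx, , drop = FALSE])
    v <- apply(features[idx, , drop = FALSE], 2, stats::var)
    v[is.na(v) | v < 1e-9] <- 1e-9
    ll <- sweep(features, 2, mu)
    loglik[, c + 1] <- log(mean(idx)) +
      rowSums(sweep(-ll^2, 2, 2 * v, "/") -
              matrix(0.5 * log(2 * pi * v), n, ncol(features), byrow = TRUE))
  }
  mx <- apply(loglik, 1, max)
  post <- exp(loglik - mx)
  post / rowSums(post)
}

#' Naive-Bayes hardness measures: CL and CLD
#'
#' Class Likelihood (CL) difficulty is one minus the normalized Gaussian
#' Naive Bayes posterior of the true class; Class Likelihood Difference
#' (CLD) difficulty is `(1 - (posterior_true - max posterior_other)) / 2`,
#' which maps the signed difference onto `[0, 1]`.
#'
#' @param table A [case_table()].
#' @return Named list of two [difficulty_vector()]s: `cl`, `cld`.
#' @export
bayes_metrics <- function(table) {
  validate_case_table(table)
  post <- gnb_posteriors(table$features, table$labels, table$n_classes)
  n <- n_cases(table)
  p_true <- post[cbind(seq_len(n), table$labels + 1L)]
  p_other <- vapply(seq_len(n), function(i)
    max(post[i, -(table$labels[i] + 1L)]), numeric(1))
  list(cl = baseline_vector("cl", 1 - p_true, table,
                            "1 - normalized true-class posterior"),
       cld = baseline_vector("cld", (1 - (p_true - p_other)) / 2, table,
                             "(1 - posterior margin) / 2"))
}

#' Class-skew hardness measures: MV and CB
#'
#' Minority Value (MV) difficulty is `1 - n_c / n_majority`; Class Balance
#' (CB) difficulty is `1 - n_c / n`, where `n_c` is the size of the case's
#' class. Both are constant within a class and uninformative on balanced
#' data.
#'
#' @param table A [case_table()].
#' @return Named list of two [difficulty_vector()]s: `mv`, `cb`.
#' @export
skew_metrics <- function(table) {
  validate_case_table(table)
  counts <- table(table$labels)
  n_c <- as.numeric(counts[as.character(table$labels)])
  list(mv = baseline_vector("mv", 1 - n_c / max(counts), table,
                            "1 - n_class / n_majority"),
       cb = baseline_vector("cb", 1 - n_c / n_cases(table), table,
                            "1 - n_class / n"))
}

#' Distance-based hardness measures: N1, N2, LSC, LSR, Harmfulness, Usefulness
#'
#' All six are built from one Euclidean distance matrix, the minimum
#' spanning tree, and the nearest-enemy structure. N1 is the fraction of a
#' case's MST edges that cross classes. N2 is the ratio of the distance to
#' the closest same-class neighbor over the distance to the closest
#' other-class neighbor, min-max rescaled to `[0, 1]`. The local set of a
#' case is the set of same-class cases nearer to it than its nearest enemy;
#' LSC difficulty is one minus the local set's relative cardinality, LSR
#' difficulty is one minus the local-set radius (nearest-enemy distance)
#' normalized by the dataset maximum, Harmfulness is the min-max-rescaled
#' count of cases whose nearest enemy is this case, and Usefulness
#' difficulty is one minus the fraction of other cases whose local set
#' contains this case.
#'
#' @param table A [case_table()] with at least 3 cases and 2 classes.
#' @return Named list of six [difficulty_vector()]s:
#'   `n1`, `n2`, `lsc`, `lsr`, `harmfulness`, `usefulness`.
#' @export
distance_metrics <- function(table) {
  validate_case_table(table)
  n <- n_cases(table)
  if (n < 3) stop("distance metrics need at least 3 cases")
  lab <- table$labels
  D <- as.matrix(stats::dist(table$features))

  st <- vegan::spantree(stats::dist(table$features))
  edges <- cbind(2:n, st$kid)
  cross <- lab[edges[, 1]] != lab[edges[, 2]]
  n1 <- vapply(seq_len(n), function(i) {
    inc <- edges[, 1] == i | edges[, 2] == i
    if (!any(inc)) 0 else mean(cross[inc])
  }, numeric(1))

  d_enemy <- numeric(n); enemy_of <- integer(n); d_friend <- numeric(n)
  for (i in seq_len(n)) {
    en <- which(lab != lab[i])
    fr <- setdiff(which(lab == lab[i]), i)
    d_enemy[i] <- min(D[i, en])
    enemy_of[i] <- en[which.min(D[i, en])]
    d_friend[i] <- if (length(fr)) min(D[i, fr]) else Inf
  }
  ratio <- d_friend / d_enemy
  if (any(!is.finite(ratio)))
    ratio[!is.finite(ratio)] <- max(ratio[is.finite(ratio)], 1)
  n2 <- minmax01(ratio)

  ls_size <- integer(n); in_sets <- integer(n)
  for (i in seq_len(n)) {
    members <- which(lab == lab[i] & D[i, ] < d_enemy[i])
    members <- setdiff(members, i)
    ls_size[i] <- length(members)
    in_sets[members] <- in_sets[members] + 1L
  }
  n_same <- as.numeric(table(lab)[as.character(lab)]) - 1
  lsc <- 1 - ls_size / pmax(n_same, 1)
  lsr <- 1 - d_enemy / max(d_enemy)
  harm <- minmax01(vapply(seq_len(n), function(i) sum(enemy_of == i),
                          numeric(1)))
  usef <- 1 - in_sets / (n - 1)

  list(n1 = baseline_vector("n1", n1, table, "fraction of cross-class MST edges"),
       n2 = baseline_vector("n2", n2, table,
                            "intra/extra nearest-distance ratio, min-max rescaled"),
       lsc = baseline_vector("lsc", lsc, table, "1 - |local set| / (n_class - 1)"),
       lsr = baseline_vector("lsr", lsr, table,
                             "1 - nearest-enemy distance / max"),
       harmfulness = baseline_vector("harmfulness", harm, table,
                                     "nearest-enemy in-degree, min-max rescaled"),
       usefulness = baseline_vector("usefulness", usef, table,
                                    "1 - fraction of local sets containing the case"))
}

minmax01 <- function(x) {
  rng <- range(x)
  if (diff(rng) < 1e-300) return(rep(0, length(x)))
  (x - rng[1]) / diff(rng)
}

#' Feature-overlap hardness measure: F1
#'
#' For every feature and unordered class pair, the overlap interval is
#' `[max of the two per-class minima, min of the two per-class maxima]`.
#' A case's score is the fraction of its features whose value lies inside
#' at least one class pair's (non-empty) overlap interval.
#'
#' @param table A [case_table()].
#' @return A [difficulty_vector()] with metric id `"f1"`.
#' @export
f1_overlap <- function(table) {
  validate_case_table(table)
  n <- n_cases(table); d <- ncol(table$features)
  classes <- seq_len(table$n_classes) - 1L
  in_overlap <- matrix(FALSE, n, d)
  for (j in seq_len(d)) {
    x <- table$features[, j]
    for (a in seq_along(classes)) {
      for (b in seq_along(classes)) {
        if (b <= a) next
        xa <- x[table$labels == classes[a]]
        xb <- x[table$labels == classes[b]]
        lo <- max(min(xa), min(xb)); hi <- min(max(xa), max(xb))
        if (lo <= hi) in_overlap[, j] <- in_overlap[, j] | (x >= lo & x <= hi)
      }
    }
  }
  baseline_vector("f1", rowMeans(in_overlap), table,
                  "fraction of features inside a class-pair overlap interval")
}

#' All fifteen baseline hardness measures
#'
#' Convenience wrapper running [kdn()], [tree_metrics()], [bayes_metrics()],
#' [skew_metrics()], [distance_metrics()] and [f1_overlap()].
#'
#' @param table A [case_table()].
#' @param seed Seed for the cross-validated tree pruning.
#' @param k Neighborhood size for kDN.
#' @return Named list of fifteen [difficulty_vector()]s.
#' @export
hardness_baselines <- function(table, seed = 1L, k = 10L) {
  c(list(kdn = kdn(table, k)),
    tree_metrics(table, seed),
    bayes_metrics(table),
    skew_metrics(table),
    distance_metrics(table),
    list(f1 = f1_overlap(table)))
}
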