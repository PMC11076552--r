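# Independent brute-force references used to check the package's
# implementations on tiny instances. These deliberately share no code with
# the implementation paths they verify.

# leave-one-out 1-nearest-neighbor error rate, by explicit loops
loo_1nn_error <- function(features, labels) {
  n <- nrow(features)
  wrong <- 0L
  for (i in seq_len(n)) {
    best <- Inf; best_j <- NA_integer_
    for (j in seq_len(n)) {
      if (j == i) next
      d <- sqrt(sum((features[i, ] - features[j, ])^2))
      if (d < best) { best <- d; best_j <- j }
    }
    if (labels[best_j] != labels[i]) wrong <- wrong + 1L
  }
  wrong / n
}

# ray-casting point-in-polygon (polygon given as hull vertex matrix)
point_in_polygon <- function(pt, poly) {
  n <- nrow(poly); inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > pt[2]) != (yj > pt[2]) &&
        pt[1] < (xj - xi) * (pt[2] - yi) / (yj - yi) + xi) inside <- !inside
    j <- i
  }
  inside
}

hulls_overlap <- function(pa, pb) {
  ha <- pa[grDevices::chull(pa), , drop = FALSE]
  hb <- pb[grDevices::chull(pb), , drop = FALSE]
  any(apply(pb, 1, point_in_polygon, poly = ha)) ||
    any(apply(pa, 1, point_in_polygon, poly = hb))
}

# kDN by explicit per-case loops
kdn_bruteforce <- function(features, labels, k) {
  n <- nrow(features)
  vapply(seq_len(n), function(i) {
    d <- vapply(seq_len(n), function(j)
      if (j == i) Inf else sqrt(sum((features[i, ] - features[j, ])^2)),
      numeric(1))
    nb <- order(d)[seq_len(k)]
    mean(labels[nb] != labels[i])
  }, numeric(1))
}

# Gaussian Naive Bayes posteriors by direct density products (log domain)
gnb_bruteforce <- function(features, labels, n_classes) {
  n <- nrow(features)
  post <- matrix(NA_real_, n, n_classes)
  for (i in seq_len(n)) {
    logp <- numeric(n_classes)
    for (c in seq_len(n_classes) - 1L) {
      idx <- which(labels == c)
      lp <- log(length(idx) / n)
      for (j in seq_len(ncol(features))) {
        mu <- mean(features[idx, j])
        v <- max(stats::var(features[idx, j]), 1e-9)
        if (is.na(v)) v <- 1e-9
        lp <- lp + stats::dnorm(features[i, j], mu, sqrt(v), log = TRUE)
      }
      logp[c + 1] <- lp
    }
    p <- exp(logp - max(logp))
    post[i, ] <- p / sum(p)
  }
  post
}

# Kruskal MST by exhaustive edge enumeration with union-find
mst_kruskal <- function(features) {
  n <- nrow(features)
  edges <- do.call(rbind, lapply(seq_len(n - 1), function(i)
    do.call(rbind, lapply((i + 1):n, function(j)
      c(i, j, sqrt(sum((features[i, ] - features[j, ])^2)))))))
  edges <- edges[order(edges[, 3]), , drop = FALSE]
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  picked <- matrix(0, 0, 3)
  for (e in seq_len(nrow(edges))) {
    ra <- find(edges[e, 1]); rb <- find(edges[e, 2])
    if (ra != rb) { parent[ra] <- rb; picked <- rbind(picked, edges[e, ]) }
    if (nrow(picked) == n - 1) break
  }
  picked
}

# all six distance-based measures by definition, in loops
distance_bruteforce <- function(features, labels) {
  n <- nrow(features)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sqrt(sum((features[i, ] - features[j, ])^2))
  mst <- mst_kruskal(features)
  n1 <- vapply(seq_len(n), function(i) {
    inc <- mst[, 1] == i | mst[, 2] == i
    mean(labels[mst[inc, 1]] != labels[mst[inc, 2]])
  }, numeric(1))
  d_en <- d_fr <- numeric(n); enemy <- integer(n)
  for (i in seq_len(n)) {
    en <- which(labels != labels[i]); fr <- setdiff(which(labels == labels[i]), i)
    d_en[i] <- min(D[i, en]); enemy[i] <- en[which.min(D[i, en])]
    d_fr[i] <- if (length(fr)) min(D[i, fr]) else Inf
  }
  mm <- function(x) if (diff(range(x)) == 0) rep(0, length(x)) else
    (x - min(x)) / diff(range(x))
  ls <- lapply(seq_len(n), function(i)
    setdiff(which(labels == labels[i] & D[i, ] < d_en[i]), i))
  n_same <- vapply(seq_len(n), function(i) sum(labels == labels[i]) - 1,
                   numeric(1))
  list(n1 = n1,
       n2 = mm(d_fr / d_en),
       lsc = 1 - lengths(ls) / pmax(n_same, 1),
       lsr = 1 - d_en / max(d_en),
       harmfulness = mm(vapply(seq_len(n), function(i) sum(enemy == i),
                               numeric(1))),
       usefulness = 1 - vapply(seq_len(n), function(i)
         sum(vapply(ls, function(s) i %in% s, logical(1))), numeric(1)) / (n - 1))
}

# textbook Pearson and Spearman (average ranks) with explicit formulas
pearson_bruteforce <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
spearman_bruteforce <- function(x, y) {
  pearson_bruteforce(rank(x, ties.method = "average"),
                     rank(y, ties.method = "average"))
}

# CDpu score by direct formula (population SD)
cdpu_bruteforce <- function(probs, true_class) {
  K <- ncol(probs)
  scores <- vapply(seq_len(K) - 1, function(c) {
    p <- probs[, c + 1]
    mu <- mean(p)
    sigma <- sqrt(mean((p - mu)^2))
    y <- as.numeric(c == true_class)
    (abs(mu - y) + sigma * sqrt(12)) / 2
  }, numeric(1))
  raw <- if (K == 2) scores[2] else mean(scores)
  min(raw, 1)
}

# small two-cluster table with one mislabeled case planted at the center
# of the opposite cluster; returns the table plus the planted index and the
# index of the opposite cluster's most central (median) case
planted_table <- function(n_per_class = 20, sd = 0.3, seed = 42) {
  tab <- make_blobs(n_per_class, 2, sd, seed = seed)
  center1 <- colMeans(tab$features[tab$labels == 1L, ])
  d1 <- apply(tab$features, 1, function(r) sqrt(sum((r - center1)^2)))
  median_idx <- which(tab$labels == 1L)[which.min(d1[tab$labels == 1L])]
  feats <- rbind(tab$features, center1 + c(0.01, -0.01))
  labs <- c(tab$labels, 0L)  # class-0 label planted inside class-1 cluster
  list(table = case_table(feats, labs, n_classes = 2L,
                          provenance = "planted mislabeled case"),
       planted = nrow(feats), median_idx = median_idx)
}

# AUC of scores for predicting a binary outcome, by the rank formula
auc_rank <- function(scores, positive) {
  r <- rank(scores)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
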