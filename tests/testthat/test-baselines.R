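grid_table <- function() {
  # 12-point two-class grid: class 0 on the left, class 1 on the right,
  # with one class-1 point inside the left block
  feats <- rbind(expand.grid(x = c(0, 1), y = c(0, 1, 2)),
                 expand.grid(x = c(5, 6), y = c(0, 1, 2)))
  feats <- as.matrix(feats)
  labs <- c(rep(0L, 5), 1L, rep(1L, 6))
  case_table(feats + matrix(stats::rnorm(24, 0, 1e-3), 12, 2), labs)
}

test_that("kdn matches its definition and the brute-force oracle", {
  tab <- grid_table()
  dv <- kdn(tab, k = 5L)
  expect_equal(dv$scores, kdn_bruteforce(tab$features, tab$labels, 5L))

  # definitional spot value: 3 of 10 neighbors disagreeing -> 0.3
  set.seed(2)
  tb <- make_blobs(30, 2, 4, seed = 2)
  dv10 <- kdn(tb, k = 10L)
  expect_equal(dv10$scores, kdn_bruteforce(tb$features, tb$labels, 10L))
  expect_true(all(dv10$scores %in% ((0:10) / 10)))

  expect_error(kdn(tb, k = 60L), "n > k")
})

test_that("kdn is zero when every neighborhood is pure", {
  tab <- make_blobs(20, 2, 0.01, seed = 3)
  expect_equal(kdn(tab, k = 10L)$scores, rep(0, 40))
})

test_that("tree stump matches the exhaustive-threshold oracle", {
  x <- matrix(as.numeric(1:10), ncol = 1)
  y <- c(0L, 0L, 0L, 0L, 1L, 0L, 1L, 1L, 1L, 1L)
  tab <- case_table(x, y, feature_names = "x")

  # oracle: with minbucket 5 on n = 10 the only legal split is x < 5.5;
  # certify it is also the best Gini split among all thresholds
  gini <- function(l) { p <- table(l) / length(l); 1 - sum(p^2) }
  gains <- vapply(1:9, function(k) {
    gini(y) - (k * gini(y[1:k]) + (10 - k) * gini(y[(k + 1):10])) / 10
  }, numeric(1))
  legal <- (1:9) >= 5 & (10 - 1:9) >= 5
  expect_equal(which(legal), 5L)
  expect_equal(which.max(ifelse(legal, gains, -Inf)), 5L)

  tm <- tree_metrics(tab, seed = 1)
  # leaf {1..5} holds 4 zeros + 1 one; leaf {6..10} holds 1 zero + 4 ones
  expect_equal(tm$dcp$scores, ifelse(1:10 %in% c(5, 6), 0.8, 0.2))
  expect_equal(tm$td_u$scores, rep(1, 10))  # both leaves at depth 1 = max
})

test_that("pure leaves give DCP zero and a root-only tree gives TD zero", {
  sep <- case_table(matrix(c(1:4, 101:104), ncol = 1), rep(0:1, each = 4))
  tm <- tree_metrics(sep, seed = 1, minsplit = 2L, minbucket = 2L)
  expect_equal(tm$dcp$scores, rep(0, 8))

  # n = 8 with minbucket 5 admits no split at all -> depth 0 everywhere
  tm0 <- tree_metrics(sep, seed = 1, minsplit = 10L, minbucket = 5L)
  expect_equal(tm0$td_u$scores, rep(0, 8))

  # constant labels are a degenerate tree input
  degen <- structure(list(features = matrix(as.numeric(1:8), 4),
                          labels = rep(0L, 4), n_classes = 1L,
                          feature_names = c("a", "b"),
                          provenance = character()),
                     class = "case_table")
  expect_error(tree_metrics(degen, seed = 1))
})

test_that("naive-bayes metrics match the log-domain brute-force reference", {
  set.seed(9)
  tab <- case_table(matrix(rnorm(20, sd = 2), 10, 2),
                    rep(0:1, each = 5))
  bm <- bayes_metrics(tab)
  post <- gnb_bruteforce(tab$features, tab$labels, 2)
  p_true <- post[cbind(1:10, tab$labels + 1)]
  p_other <- vapply(1:10, function(i) max(post[i, -(tab$labels[i] + 1)]),
                    numeric(1))
  expect_equal(bm$cl$scores, 1 - p_true, tolerance = 1e-9)
  expect_equal(bm$cld$scores, (1 - (p_true - p_other)) / 2, tolerance = 1e-9)
})

test_that("naive-bayes posteriors agree with an independent library", {
  skip_if_not_installed("e1071")
  tab <- make_blobs(25, 2, 3, seed = 10)
  fit <- e1071::naiveBayes(data.frame(tab$features), factor(tab$labels))
  ref <- predict(fit, data.frame(tab$features), type = "raw")
  p_true <- ref[cbind(seq_len(50), tab$labels + 1)]
  expect_equal(bayes_metrics(tab)$cl$scores, 1 - p_true, tolerance = 1e-6)
})

test_that("naive-bayes extremes behave definitionally", {
  # far-apart tight clusters: a case at its class mean has CL ~ 0 difficulty
  tab <- make_blobs(10, 2, 0.01, seed = 11)
  bm <- bayes_metrics(tab)
  expect_true(all(bm$cl$scores < 1e-6))
  # mirror-symmetric duplicate point with equal priors: posterior 0.5 for
  # both copies, hence CLD difficulty exactly 0.5
  feats <- rbind(c(-1, 0), c(-1, 1), c(0, 0.5), c(1, 0), c(1, 1), c(0, 0.5))
  tabe <- case_table(feats, c(0L, 0L, 0L, 1L, 1L, 1L))
  cld <- bayes_metrics(tabe)$cld$scores
  expect_equal(cld[c(3, 6)], c(0.5, 0.5), tolerance = 1e-9)
})

test_that("skew metrics follow the class-count ratios", {
  # balanced data: MV difficulty 0 everywhere (the uninformative case)
  bal <- make_blobs(10, 2, 1, seed = 12)
  expect_equal(skew_metrics(bal)$mv$scores, rep(0, 20))

  # 458/241 split: minority difficulty 1 - 241/458
  labs <- c(rep(0L, 458), rep(1L, 241))
  feats <- matrix(stats::rnorm(2 * 699), ncol = 2)
  tab <- case_table(feats, labs)
  sk <- skew_metrics(tab)
  expect_equal(unique(sk$mv$scores[labs == 1L]), 1 - 241 / 458)
  expect_equal(unique(sk$mv$scores[labs == 0L]), 0)
  expect_equal(unique(sk$cb$scores[labs == 0L]), 1 - 458 / 699)
})

test_that("distance metrics match the brute-force oracle on 9 points", {
  set.seed(13)
  feats <- matrix(stats::rnorm(18, sd = 2), 9, 2)
  labs <- c(0L, 0L, 0L, 1L, 1L, 1L, 2L, 2L, 2L)
  tab <- case_table(feats, labs)
  dm <- distance_metrics(tab)
  ref <- distance_bruteforce(feats, labs)
  for (m in names(ref)) {
    expect_equal(dm[[m]]$scores, ref[[m]], tolerance = 1e-12, label = m)
  }
})

test_that("distance metric extremes are definitional", {
  # two far-apart tight clusters: the MST has a single bridging cross-class
  # edge, so every interior point has N1 = 0
  tab <- make_blobs(10, 2, 0.01, seed = 14)
  dm <- distance_metrics(tab)
  expect_lte(sum(dm$n1$scores > 0), 2)
  expect_equal(sum(dm$n1$scores == 0), 18)

  # a case equidistant from its nearest friend and nearest enemy gets the
  # same N2 score as any other ratio-1 case (here: symmetric 6-point line)
  feats <- cbind(c(0, 1, 2, 10, 11, 12), 0)
  labs <- c(0L, 0L, 1L, 1L, 0L, 0L)
  ref <- distance_bruteforce(feats, labs)
  dm2 <- distance_metrics(case_table(feats, labs))
  expect_equal(dm2$n2$scores, ref$n2, tolerance = 1e-12)
})

test_that("f1 overlap fractions match hand-computed intervals", {
  # feature 1: class 0 in [0,3], class 1 in [2,5] -> overlap [2,3]
  # feature 2: class 0 in [0,1], class 1 in [10,11] -> no overlap
  feats <- rbind(c(0, 0), c(1, 1), c(2.5, 0.5), c(3, 1),
                 c(2, 10), c(2.5, 11), c(4, 10.5), c(5, 10))
  labs <- c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L)
  tab <- case_table(feats, labs)
  # cases with feature1 in [2,3]: rows 3, 4, 5, 6 -> score 1/2; others 0
  expect_equal(f1_overlap(tab)$scores,
               c(0, 0, 0.5, 0.5, 0.5, 0.5, 0, 0))

  # perfectly separated single feature: all zero
  sep <- case_table(matrix(c(1:4, 10:13), ncol = 1), rep(0:1, each = 4))
  expect_equal(f1_overlap(sep)$scores, rep(0, 8))

  # fully nested ranges: the nested class overlaps on every feature
  nest <- case_table(matrix(c(0, 10, 4, 5, 6), ncol = 1),
                     c(0L, 0L, 1L, 1L, 1L))
  expect_equal(f1_overlap(nest)$scores[3:5], rep(1, 3))
})

test_that("every baseline ranks a planted mislabeled case as hard", {
  pl <- planted_table(n_per_class = 12, sd = 0.25, seed = 15)
  tab <- pl$table; i <- pl$planted; j <- pl$median_idx
  dm <- distance_metrics(tab)
  strict <- list(kdn = kdn(tab, k = 5L),
                 dcp = tree_metrics(tab, seed = 1)$dcp,
                 cl = bayes_metrics(tab)$cl,
                 cld = bayes_metrics(tab)$cld,
                 n2 = dm$n2, harmfulness = dm$harmfulness,
                 usefulness = dm$usefulness)
  for (m in names(strict)) {
    expect_gt(strict[[m]]$scores[i], strict[[m]]$scores[j], label = m)
  }
  # an enemy planted at the cluster center also poisons its immediate
  # neighbors' neighborhood structure (it becomes their nearest enemy and
  # empties their local sets), so these can tie with the planted case
  weak <- list(td_p = tree_metrics(tab, seed = 1)$td_p,
               td_u = tree_metrics(tab, seed = 1)$td_u,
               f1 = f1_overlap(tab),
               n1 = dm$n1, lsc = dm$lsc, lsr = dm$lsr)
  for (m in names(weak)) {
    expect_gte(weak[[m]]$scores[i], weak[[m]]$scores[j], label = m)
  }
})

test_that("hardness_baselines returns all fifteen oriented vectors", {
  tab <- make_blobs(20, 2, 3, seed = 16)
  hb <- hardness_baselines(tab, seed = 1)
  expect_setequal(names(hb), c("kdn", "dcp", "td_p", "td_u", "cl", "cld",
                               "mv", "cb", "n1", "n2", "lsc", "lsr",
                               "harmfulness", "usefulness", "f1"))
  for (m in names(hb)) {
    expect_s3_class(hb[[m]], "difficulty_vector")
    expect_true(all(hb[[m]]$scores >= 0 & hb[[m]]$scores <= 1), label = m)
  }
})
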