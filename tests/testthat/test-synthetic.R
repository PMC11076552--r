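test_that("generators are reproducible and emit balanced classes", {
  cases <- list(
    list(f = make_blobs, args = list(50, 2, 2.0)),
    list(f = make_blobs, args = list(40, 3, 6.0)),
    list(f = make_moons, args = list(30, 2, 0.2)),
    list(f = make_moons, args = list(30, 3, 0.4)),
    list(f = make_circles, args = list(30, 2, 0.5)),
    list(f = make_circles, args = list(25, 3, 0.7)))
  for (cs in cases) {
    a <- do.call(cs$f, c(cs$args, seed = 7))
    b <- do.call(cs$f, c(cs$args, seed = 7))
    expect_identical(a, b)
    expect_false(identical(a, do.call(cs$f, c(cs$args, seed = 8))))
    expect_true(all(table(a$labels) == cs$args[[1]]))
    expect_equal(ncol(a$features), 2)
  }
})

test_that("generator sizes match the study designs", {
  expect_equal(n_cases(make_blobs(1000, 2, 2.0, seed = 1)), 2000)
  tab3 <- make_blobs(1000, 3, 6.0, seed = 1)
  expect_equal(n_cases(tab3), 3000)
  expect_true(all(table(tab3$labels) == 1000))
})

test_that("invalid generator parameters are rejected", {
  expect_error(make_blobs(0, 2, 2, seed = 1), "n_per_class")
  expect_error(make_blobs(10, 4, 2, seed = 1), "n_classes")
  expect_error(make_blobs(10, 2, -1, seed = 1), "cluster_sd")
  expect_error(make_moons(10, 2, -0.1, seed = 1), "noise_sd")
  expect_error(make_circles(10, 2, 1.5, seed = 1), "scale_factor")
  expect_error(make_circles(10, 2, 0, seed = 1), "scale_factor")
})

test_that("tight blobs are linearly separable under a 1-NN LOO oracle", {
  tab <- make_blobs(5, 2, 0.0001, seed = 3)
  expect_equal(loo_1nn_error(tab$features, tab$labels), 0)
})

test_that("blob overlap grows monotonically with cluster SD (1-NN oracle)", {
  errs <- vapply(c(2, 4, 6), function(sd)
    loo_1nn_error(make_blobs(200, 2, sd, seed = 11)$features,
                  make_blobs(200, 2, sd, seed = 11)$labels), numeric(1))
  expect_true(errs[1] < errs[2])
  expect_true(errs[2] < errs[3])
})

test_that("noiseless moons are disjoint; noisy 3-class moons overlap", {
  tab0 <- make_moons(100, 2, 0.0, seed = 1)
  d_between <- min(as.matrix(stats::dist(tab0$features))[
    tab0$labels == 0, tab0$labels == 1])
  expect_gt(d_between, 0)

  tab3 <- make_moons(100, 3, 0.4, seed = 2)
  pts <- function(c) tab3$features[tab3$labels == c, ]
  expect_true(hulls_overlap(pts(0), pts(1)))
  expect_true(hulls_overlap(pts(1), pts(2)))
})

test_that("circle radii follow powers of the scale factor", {
  tab <- make_circles(50, 2, 0.3, noise_sd = 0, seed = 1)
  r <- sqrt(rowSums(tab$features^2))
  expect_equal(r[tab$labels == 0], rep(1, 50), tolerance = 1e-12)
  expect_equal(r[tab$labels == 1], rep(0.3, 50), tolerance = 1e-12)

  tab3 <- make_circles(30, 3, 0.5, noise_sd = 0, seed = 1)
  r3 <- sqrt(rowSums(tab3$features^2))
  expect_equal(as.numeric(tapply(r3, tab3$labels, mean)),
               c(1, 0.5, 0.25), tolerance = 1e-12)
})

test_that("overlapping rings interleave in radius at high scale factor", {
  tab <- make_circles(100, 2, 0.7, noise_sd = 0.1, seed = 5)
  r <- sqrt(rowSums(tab$features^2))
  expect_true(min(r[tab$labels == 0]) < max(r[tab$labels == 1]))
})

test_that("preprocess imputes, scales, one-hot encodes, and recodes labels", {
  raw <- data.frame(
    bare = c(1:10, NA),
    kind = c(rep(c("a", "b", "c"), 3), "a", "b"),
    outcome = c(rep("benign", 6), rep("malignant", 5)))
  schema <- feature_schema(c(bare = "continuous", kind = "categorical"))
  tab <- preprocess(raw, schema, "outcome")

  # mean imputation then standardization: imputed value maps to 0
  expect_equal(unname(tab$features[11, "bare"]), 0, tolerance = 1e-12)
  expect_equal(mean(tab$features[, "bare"]), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(tab$features[, "bare"]^2)), 1, tolerance = 1e-9)

  onehot <- tab$features[, grepl("^kind=", colnames(tab$features))]
  expect_equal(ncol(onehot), 3)
  expect_true(all(rowSums(onehot) == 1))

  expect_equal(tab$labels, c(rep(0L, 6), rep(1L, 5)))
  expect_match(paste(tab$provenance, collapse = " "), "benign->0")
})

test_that("preprocess is idempotent on standardized continuous input", {
  x <- matrix(rnorm(60), 20, 3)
  x <- scale(x, center = TRUE, scale = apply(x, 2, function(v)
    sqrt(mean((v - mean(v))^2))))
  raw <- data.frame(x1 = x[, 1], x2 = x[, 2], x3 = x[, 3],
                    y = rep(c("u", "v"), 10))
  schema <- feature_schema(c(x1 = "continuous", x2 = "continuous",
                             x3 = "continuous"))
  tab <- preprocess(raw, schema, "y")
  expect_equal(unname(tab$features), unname(x[, 1:3]), tolerance = 1e-9)
})

test_that("preprocess rejects zero-variance continuous columns by name", {
  raw <- data.frame(flat = rep(2, 8), y = rep(c("a", "b"), 4))
  schema <- feature_schema(c(flat = "continuous"))
  expect_error(preprocess(raw, schema, "y"), "flat")
  expect_error(preprocess(raw, schema, "nope"), "label")
})

test_that("case_table enforces its invariants", {
  expect_error(case_table(matrix(c(1, NA, 3, 4), 2), c(0L, 1L)), "missing")
  expect_error(case_table(matrix(1:4, 2), c(0L, 0L)), "classes")
  expect_error(case_table(matrix(1:6, 3), c(0L, 0L, 2L)), "occur")
})
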