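make_split <- function(tab, seed = 1) {
  sp <- casedifficulty:::stratified_split(tab$labels, 0.7, seed)
  list(tr = ct_subset(tab, sp$train), va = ct_subset(tab, sp$val))
}

test_that("training reaches perfect accuracy on separable blobs", {
  tab <- make_blobs(100, 2, 0.0001, seed = 1)
  s <- make_split(tab)
  net <- train_net(s$tr, s$va, net_config(hidden_layer_sizes = 5, seed = 2))
  expect_equal(mean(predict_class(net, s$tr$features) == s$tr$labels), 1.0)
  # argmax on its own training set equals the true labels
  expect_identical(predict_class(net, tab$features), tab$labels)
})

test_that("probability outputs are simplex rows with binary complement", {
  tab <- make_blobs(60, 2, 3, seed = 4)
  s <- make_split(tab)
  net <- train_net(s$tr, s$va, net_config(max_epochs = 20, seed = 5))
  p <- predict_proba(net, tab$features)
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_true(all(p >= 0))
  expect_equal(p[, 2], 1 - p[, 1], tolerance = 1e-6)
  expect_error(predict_proba(net, tab$features[, 1, drop = FALSE]),
               "dimension")
})

test_that("epoch budget and early stopping behave as contracted", {
  tab <- make_blobs(50, 2, 2, seed = 6)
  s <- make_split(tab)
  one <- train_net(s$tr, s$va, net_config(max_epochs = 1, patience = 0, seed = 1))
  expect_equal(one$epochs_run, 1)

  # restore-best: the returned parameters reproduce the best recorded loss;
  # on overlapping data the validation loss plateaus and patience triggers
  s <- make_split(make_blobs(50, 2, 4, seed = 6))
  net <- train_net(s$tr, s$va, net_config(max_epochs = 500, patience = 5,
                                          learning_rate = 0.1, seed = 1))
  p <- predict_proba(net, s$va$features)
  loss <- -mean(log(pmax(p[cbind(seq_along(s$va$labels), s$va$labels + 1)],
                         1e-12)))
  expect_equal(loss, net$best_val_loss, tolerance = 1e-9)
  expect_lt(net$epochs_run, 500)
})

test_that("training is deterministic given the seed", {
  tab <- make_moons(40, 2, 0.2, seed = 2)
  s <- make_split(tab)
  cfg <- net_config(hidden_layer_sizes = c(8, 8), activation = "tanh",
                    max_epochs = 30, seed = 99)
  a <- train_net(s$tr, s$va, cfg)
  b <- train_net(s$tr, s$va, cfg)
  expect_identical(predict_proba(a, tab$features),
                   predict_proba(b, tab$features))
  cfg2 <- cfg; cfg2$seed <- 100L
  c <- train_net(s$tr, s$va, cfg2)
  expect_false(identical(predict_proba(a, tab$features),
                         predict_proba(c, tab$features)))
})

test_that("prediction is invariant to case order", {
  tab <- make_blobs(40, 2, 2, seed = 8)
  s <- make_split(tab)
  net <- train_net(s$tr, s$va, net_config(max_epochs = 20, seed = 3))
  perm <- sample(n_cases(tab))
  expect_equal(predict_proba(net, tab$features[perm, ]),
               predict_proba(net, tab$features)[perm, ], tolerance = 1e-12)
})

test_that("degenerate single-class training data is rejected", {
  tr <- list(features = matrix(rnorm(20), 10, 2), labels = rep(0L, 10))
  expect_error(train_net(tr, NULL, net_config(patience = 0)), "one class")
})

test_that("tune returns the best of the evaluated candidates", {
  tab <- make_blobs(60, 2, 2, seed = 9)
  s <- make_split(tab)

  single <- search_space(learning_rates = 0.03, batch_sizes = 32L,
                         n_hidden_layers = 2L, n_neurons = 10L,
                         activations = "tanh", n_iterations = 3L)
  cfg <- tune(s$tr, s$va, single, seed = 1, max_epochs = 10)
  expect_identical(cfg$hidden_layer_sizes, c(10L, 10L))
  expect_identical(cfg$activation, "tanh")
  expect_equal(cfg$learning_rate, 0.03)

  space <- search_space(n_iterations = 10L)
  cfg <- tune(s$tr, s$va, space, seed = 2, max_epochs = 15)
  losses <- attr(cfg, "all_losses")
  expect_length(losses, 10)
  expect_equal(attr(cfg, "val_loss"), min(losses))
  expect_lte(attr(cfg, "val_loss"), stats::median(losses))

  cfg2 <- tune(s$tr, s$va, space, seed = 2, max_epochs = 15)
  expect_identical(unclass(cfg)[names(unclass(cfg))],
                   unclass(cfg2)[names(unclass(cfg2))])
})
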