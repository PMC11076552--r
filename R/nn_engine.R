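#' Network hyperparameter configuration
#'
#' @param hidden_layer_sizes Integer vector, one entry per hidden layer.
#' @param activation `"relu"` or `"tanh"`.
#' @param learning_rate Adam step size (> 0).
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs (>= 1).
#' @param patience Early-stopping patience in epochs; 0 disables early
#'   stopping (trains for exactly `max_epochs`).
#' @param seed Integer seed controlling weight initialization and epoch
#'   shuffling.
#' @return An object of class `net_config`.
#' @export
net_config <- function(hidden_layer_sizes = 5L, activation = "relu",
                       learning_rate = 0.01, batch_size = 32L,
                       max_epochs = 100L, patience = 10L, seed = 1L) {
  hidden_layer_sizes <- as.integer(hidden_layer_sizes)
  stopifnot(length(hidden_layer_sizes) >= 1, all(hidden_layer_sizes >= 1),
            activation %in% c("relu", "tanh"),
            learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            patience >= 0)
  structure(list(hidden_layer_sizes = hidden_layer_sizes,
                 activation = activation,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "net_config")
}

#' Hyperparameter search grid
#'
#' The default grid is the tuning space used throughout: learning rate
#' 0.01/0.03/0.1, batch size 32/64/128, 1-3 hidden layers of 5/10/15/20
#' neurons (the same width in every layer), ReLU or tanh activation.
#'
#' @param learning_rates,batch_sizes,n_hidden_layers,n_neurons,activations
#'   Candidate values; all must be non-empty.
#' @param n_iterations Number of candidate configurations to evaluate.
#' @return An object of class `search_space`.
#' @export
search_space <- function(learning_rates = c(0.01, 0.03, 0.1),
                         batch_sizes = c(32L, 64L, 128L),
                         n_hidden_layers = 1:3,
                         n_neurons = c(5L, 10L, 15L, 20L),
                         activations = c("relu", "tanh"),
                         n_iterations = 10L) {
  stopifnot(length(learning_rates) > 0, length(batch_sizes) > 0,
            length(n_hidden_layers) > 0, length(n_neurons) > 0,
            length(activations) > 0, n_iterations >= 1)
  structure(list(learning_rates = learning_rates,
                 batch_sizes = as.integer(batch_sizes),
                 n_hidden_layers = as.integer(n_hidden_layers),
                 n_neurons = as.integer(n_neurons),
                 activations = activations,
                 n_iterations = as.integer(n_iterations)),
            class = "search_space")
}

act_code <- function(activation) match(activation, c("relu", "tanh")) - 1L

#' Train a feedforward classification network
#'
#' Fits a fully-connected softmax classifier with cross-entropy loss and the
#' Adam optimizer. With `patience > 0` and non-empty validation data,
#' training stops once validation loss has not improved for `patience`
#' epochs and the best-validation-loss parameters are restored.
#' Deterministic given `config$seed`.
#'
#' @param train,val Lists with `features` (numeric matrix) and `labels`
#'   (integers `0..K-1`), e.g. a [case_table()] or [ct_subset()]. `val` may
#'   be `NULL` only when `config$patience == 0`.
#' @param config A [net_config()].
#' @param n_classes Number of classes; defaults to `train$n_classes` or
#'   `max(labels) + 1`.
#' @return A `trained_net` with the fitted parameters, the config, and a
#'   training record (`epochs_run`, `best_val_loss`, `train_loss`).
#' @export
train_net <- function(train, val = NULL, config = net_config(),
                      n_classes = NULL) {
  if (is.null(n_classes))
    n_classes <- if (!is.null(train$n_classes)) train$n_classes
                 else max(train$labels) + 1L
  if (length(unique(train$labels)) < 2L)
    stop("degenerate training data: only one class present")
  if (is.null(val) || nrow(val$features) == 0) {
    if (config$patience > 0)
      stop("validation data required when patience > 0")
    xv <- matrix(0, 0, ncol(train$features)); yv <- integer(0)
  } else {
    stopifnot(ncol(val$features) == ncol(train$features))
    xv <- val$features; yv <- val$labels
  }
  fit <- mlp_train_cpp(train$features, train$labels, as.integer(n_classes),
                       xv, yv, config$hidden_layer_sizes,
                       act_code(config$activation), config$learning_rate,
                       config$batch_size, config$max_epochs, config$patience,
                       config$seed)
  structure(list(config = config, n_classes = as.integer(n_classes),
                 n_features = ncol(train$features),
                 weights = fit$weights, biases = fit$biases,
                 epochs_run = fit$epochs_run,
                 best_val_loss = fit$best_val_loss,
                 train_loss = fit$train_loss),
            class = "trained_net")
}

#' @export
print.trained_net <- function(x, ...) {
  cat(sprintf("trained_net: %d -> %s -> %d (%s), %d epochs, val loss %s\n",
              x$n_features,
              paste(x$config$hidden_layer_sizes, collapse = "-"),
              x$n_classes, x$config$activation, x$epochs_run,
              format(x$best_val_loss, digits = 4)))
  invisible(x)
}

#' Predicted class probabilities
#'
#' @param net A `trained_net`.
#' @param features Numeric matrix with the training dimensionality.
#' @return A numeric matrix (rows x K); each row is a probability simplex.
#' @export
predict_proba <- function(net, features) {
  stopifnot(inherits(net, "trained_net"))
  features <- as.matrix(features)
  if (ncol(features) != net$n_features)
    stop("feature dimension mismatch: expected ", net$n_features,
         " columns, got ", ncol(features))
  mlp_predict_cpp(net$weights, net$biases, act_code(net$config$activation),
                  features)
}

#' Predicted class labels (argmax rule)
#' @inheritParams predict_proba
#' @return Integer labels in `0..K-1`.
#' @export
predict_class <- function(net, features) {
  max.col(predict_proba(net, features), ties.method = "first") - 1L
}

pick1 <- function(x) if (length(x) == 1) x else sample(x, 1)

sample_config <- function(space, epochs, patience, seed) {
  net_config(
    hidden_layer_sizes = rep(pick1(space$n_neurons),
                             pick1(space$n_hidden_layers)),
    activation = pick1(space$activations),
    learning_rate = pick1(space$learning_rates),
    batch_size = pick1(space$batch_sizes),
    max_epochs = epochs, patience = patience, seed = seed)
}

#' Hyperparameter search by seeded random sampling over the grid
#'
#' Draws `space$n_iterations` candidate configurations uniformly from the
#' grid, trains each on `train` and scores it by validation cross-entropy
#' loss, and returns the configuration with the minimal validation loss
#' (ties broken by earlier evaluation order). Deterministic given `seed`.
#'
#' @inheritParams train_net
#' @param space A [search_space()].
#' @param seed Integer seed for candidate sampling and training.
#' @param max_epochs,patience Training budget applied to every candidate.
#' @return The best [net_config()], with attributes `val_loss` (its score)
#'   and `all_losses` (every candidate's score, in evaluation order).
#' @export
tune <- function(train, val, space, seed, max_epochs = 100L, patience = 10L) {
  stopifnot(inherits(space, "search_space"))
  candidates <- withr::with_seed(derive_seed(seed, 101), {
    lapply(seq_len(space$n_iterations), function(i)
      sample_config(space, max_epochs, patience, derive_seed(seed, 7, i)))
  })
  losses <- vapply(candidates, function(cfg) {
    net <- train_net(train, val, cfg)
    if (is.na(net$best_val_loss)) net$train_loss else net$best_val_loss
  }, numeric(1))
  best <- candidates[[which.min(losses)]]
  attr(best, "val_loss") <- min(losses)
  attr(best, "all_losses") <- losses
  best
}

# Stratified train/validation split of indices, deterministic given seed.
# Returns list(train=, val=) of 1-based indices into `labels`.
stratified_split <- function(labels, train_fraction = 0.7, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    tr <- unlist(lapply(unique(labels), function(cl) {
      idx <- which(labels == cl)
      n_tr <- max(1L, round(train_fraction * length(idx)))
      if (length(idx) == 1L) idx else sample(idx, n_tr)
    }), use.names = FALSE)
  })
  list(train = sort(tr), val = sort(setdiff(seq_along(labels), tr)))
}
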