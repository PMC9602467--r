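#' Hyperparameter grid
#'
#' The grid explored by the harness: six batch sizes crossed with three
#' learning rates, the epoch cap fixed at 4 with validation-based early
#' stopping. The small batch sizes (1-8) extend the encoder authors'
#' recommended 16/32 because long inputs favour smaller batches.
#'
#' @param batch_sizes Integer vector (default `c(1, 2, 4, 8, 16, 32)`).
#' @param learning_rates Numeric vector (default `c(5e-5, 3e-5, 2e-5)`).
#' @param n_epochs Epoch cap (default 4).
#' @param early_stopping Enable validation-based early stopping (default
#'   `TRUE`).
#' @param patience Number of consecutive non-improving validation
#'   evaluations tolerated before stopping (default 1).
#' @return An object of class `hyperparam_grid`.
#' @export
hyperparam_grid <- function(batch_sizes = c(1, 2, 4, 8, 16, 32),
                            learning_rates = c(5e-5, 3e-5, 2e-5),
                            n_epochs = 4, early_stopping = TRUE,
                            patience = 1) {
  stopifnot(length(batch_sizes) > 0, length(learning_rates) > 0,
            all(batch_sizes >= 1), all(learning_rates > 0),
            n_epochs >= 1, patience >= 0)
  structure(
    list(batch_sizes = as.integer(sort(batch_sizes)),
         learning_rates = as.numeric(learning_rates),
         n_epochs = as.integer(n_epochs),
         early_stopping = isTRUE(early_stopping),
         patience = as.integer(patience)),
    class = "hyperparam_grid"
  )
}

#' Enumerate grid configurations
#'
#' Cartesian product of batch sizes and learning rates in deterministic
#' order: batch size ascending, learning rate descending within batch.
#' The default grid yields 18 settings.
#'
#' @param grid A [hyperparam_grid()].
#' @return A tibble with one row per setting: `batch_size`,
#'   `learning_rate`, `n_epochs`, `early_stopping`, `patience`.
#' @export
grid_configs <- function(grid) {
  stopifnot(inherits(grid, "hyperparam_grid"))
  lr <- sort(grid$learning_rates, decreasing = TRUE)
  tibble::tibble(
    batch_size = rep(sort(grid$batch_sizes), each = length(lr)),
    learning_rate = rep(lr, times = length(grid$batch_sizes)),
    n_epochs = grid$n_epochs,
    early_stopping = grid$early_stopping,
    patience = grid$patience
  )
}

tf_features <- function(texts, vocab, tokenizer = whitespace_tokenizer()) {
  tok <- lapply(texts, tokenizer$tokenize)
  n <- length(texts)
  X <- matrix(0, n, length(vocab), dimnames = list(NULL, vocab))
  doc <- rep.int(seq_len(n), lengths(tok))
  pos <- match(unlist(tok), vocab)
  keep <- !is.na(pos)
  if (any(keep)) {
    tab <- table(doc = doc[keep], pos = pos[keep])
    X[cbind(as.integer(rownames(tab))[row(tab)], as.integer(colnames(tab))[col(tab)])] <- tab
  }
  len <- pmax(1, lengths(tok))
  X / len
}

logloss <- function(prob, y) {
  eps <- 1e-12
  -mean(y * log(prob + eps) + (1 - y) * log(1 - prob + eps))
}

#' Deterministic baseline classifier backend
#'
#' A desk-scale stand-in for a fine-tuned sentence encoder, satisfying
#' the same harness contract: binary logistic regression on
#' length-normalized term-frequency features over the training
#' vocabulary, trained by mini-batch stochastic gradient descent with L2
#' shrinkage. The grid's batch size is the SGD mini-batch size; the
#' grid's learning rate — quoted on the fine-tuning scale of 1e-5 — is
#' multiplied by `lr_scale` to reach this optimizer's working regime.
#' Fully deterministic given a seed, and fast enough to run the whole
#' default pipeline on one CPU in well under a minute.
#'
#' A backend is a list of four functions: `init(train, setting, seed)`
#' creating the model state, `fit_epoch(state, train)` performing one
#' training pass, `objective(state, data)` returning a
#' lower-is-better validation objective (here mean log-loss), and
#' `predict(state, data)` returning one label per row. `fit` never sees
#' test data; the harness [train_eval()] enforces that by construction.
#'
#' @param vocab_size Maximum vocabulary size, most frequent training
#'   tokens first (default 512).
#' @param l2 L2 penalty on the weights (default 1e-3).
#' @param lr_scale Factor mapping the grid's fine-tuning-scale learning
#'   rate onto the SGD step size (default 1e4).
#' @return A backend list with fields `name`, `init`, `fit_epoch`,
#'   `objective`, `predict`.
#' @export
baseline_backend <- function(vocab_size = 512, l2 = 1e-3, lr_scale = 1e4) {
  tokenizer <- whitespace_tokenizer()
  list(
    name = "baseline",
    init = function(train, setting, seed) {
      tok <- unlist(lapply(train$text, tokenizer$tokenize))
      freq <- sort(table(tok), decreasing = TRUE)
      vocab <- names(freq)[seq_len(min(vocab_size, length(freq)))]
      list(vocab = vocab,
           w = rep(0, length(vocab)), b = 0,
           lr = setting$learning_rate * lr_scale,
           batch = as.integer(setting$batch_size),
           seed = as.integer(seed), epoch = 0L)
    },
    fit_epoch = function(state, train) {
      X <- tf_features(train$text, state$vocab, tokenizer)
      y <- as.numeric(train$label == "MCI")
      state$epoch <- state$epoch + 1L
      withr::with_seed(derive_seed(state$seed, state$epoch), {
        ord <- sample.int(nrow(X))
        starts <- seq(1, nrow(X), by = state$batch)
        for (s in starts) {
          ix <- ord[s:min(s + state$batch - 1L, nrow(X))]
          eta <- drop(X[ix, , drop = FALSE] %*% state$w) + state$b
          p <- 1 / (1 + exp(-eta))
          err <- p - y[ix]
          grad_w <- drop(crossprod(X[ix, , drop = FALSE], err)) / length(ix) +
            l2 * state$w
          state$w <- state$w - state$lr * grad_w
          state$b <- state$b - state$lr * mean(err)
        }
      })
      state
    },
    objective = function(state, data) {
      X <- tf_features(data$text, state$vocab, tokenizer)
      p <- 1 / (1 + exp(-(drop(X %*% state$w) + state$b)))
      logloss(p, as.numeric(data$label == "MCI"))
    },
    predict = function(state, data) {
      X <- tf_features(data$text, state$vocab, tokenizer)
      p <- 1 / (1 + exp(-(drop(X %*% state$w) + state$b)))
      ifelse(p > 0.5, "MCI", "HEALTHY")
    }
  )
}

#' Train on one split and predict its test set
#'
#' Fits the backend on the training part with validation-based early
#' stopping, then predicts every test sample. The validation objective is
#' evaluated once before training and after every epoch; training stops
#' when it has failed to improve for more than `patience` consecutive
#' evaluations (if early stopping is enabled), capped at `n_epochs`. The
#' best-validation state is the one used for prediction. The backend
#' never receives test rows.
#'
#' @param dataset A corpus tibble.
#' @param split One index triple from [make_splits()].
#' @param backend A backend list (see [baseline_backend()]).
#' @param setting One row of [grid_configs()] (as a list or one-row data
#'   frame).
#' @param seed Integer seed handed to the backend.
#' @return A list with `predictions` (character), `truth`, `task` and
#'   `sample_id` vectors aligned to the test rows, plus `metadata`
#'   (`epochs_used`, `setting`, `seed`, part sizes).
#' @export
train_eval <- function(dataset, split, backend, setting, seed = 1L) {
  setting <- as.list(tibble::as_tibble(setting))
  train <- dataset[split$train, ]
  validation <- dataset[split$validation, ]
  test <- dataset[split$test, ]
  state <- tryCatch(
    backend$init(train, setting, seed),
    error = function(e) stop("backend '", backend$name, "' failed at init (",
                             "batch_size=", setting$batch_size,
                             ", learning_rate=", setting$learning_rate, "): ",
                             conditionMessage(e), call. = FALSE)
  )
  best_obj <- backend$objective(state, validation)
  best_state <- state
  bad <- 0L
  epochs_used <- 0L
  for (epoch in seq_len(setting$n_epochs)) {
    state <- backend$fit_epoch(state, train)
    epochs_used <- epoch
    obj <- backend$objective(state, validation)
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      best_state <- state
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (isTRUE(setting$early_stopping) && bad > setting$patience) break
    }
  }
  preds <- backend$predict(best_state, test)
  stopifnot(length(preds) == nrow(test), all(preds %in% c("HEALTHY", "MCI")))
  list(
    predictions = preds,
    truth = test$label,
    task = test$task,
    sample_id = test$sample_id,
    metadata = list(epochs_used = epochs_used, best_objective = best_obj,
                    setting = setting, seed = seed,
                    n_train = nrow(train), n_validation = nrow(validation),
                    n_test = nrow(test))
  )
}

#' Run the full hyperparameter grid over repeated splits
#'
#' For every grid setting, trains and evaluates on each split and
#' records the mean weighted F1 over repeats; the best setting (ties to
#' the first in grid order) is attached as attribute `"best"`.
#'
#' @param dataset A corpus tibble.
#' @param splits Result of [make_splits()].
#' @param backend A backend list.
#' @param grid A [hyperparam_grid()].
#' @param seed Integer seed; each (setting, repeat) pair gets a derived
#'   seed.
#' @return A tibble with one row per setting (`batch_size`,
#'   `learning_rate`, `mean_weighted_f1`, `mean_epochs_used`), best row
#'   attached as attribute `"best"`.
#' @export
run_grid <- function(dataset, splits, backend, grid, seed = 1L) {
  configs <- grid_configs(grid)
  scores <- numeric(nrow(configs))
  epochs <- numeric(nrow(configs))
  for (ci in seq_len(nrow(configs))) {
    f1s <- numeric(length(splits))
    eps <- numeric(length(splits))
    for (ri in seq_along(splits)) {
      run <- train_eval(dataset, splits[[ri]], backend, configs[ci, ],
                        seed = derive_seed(seed, ci * 1000L + ri))
      f1s[ri] <- weighted_f1(run$predictions, run$truth)
      eps[ri] <- run$metadata$epochs_used
    }
    scores[ci] <- mean(f1s)
    epochs[ci] <- mean(eps)
  }
  report <- dplyr::mutate(configs, mean_weighted_f1 = scores,
                          mean_epochs_used = epochs)
  attr(report, "best") <- report[which.max(scores), ]
  report
}
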