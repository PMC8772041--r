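# Fully-connected binary classifier.
#
# Implemented directly in base R matrix code: ReLU hidden layers of one
# shared width, a single sigmoid output unit, binary cross-entropy loss
# and Adam updates. Training standardizes the inputs (training-set
# statistics only, zero-variance columns scale-guarded to 1), holds out a
# stratified 10% of the training rows to monitor accuracy, and stops
# early when the monitored accuracy has not improved for
# `early_stop_patience` consecutive epochs; the weights at the stopping
# epoch are kept.

#' Model hyper-parameter configuration
#'
#' @param hidden_layers number of hidden layers (>= 1).
#' @param hidden_neurons neurons per hidden layer (all layers share one
#'   width).
#' @param batch_size minibatch size.
#' @param early_stop_patience epochs without monitored-accuracy
#'   improvement before stopping (default 10).
#' @param max_epochs training epoch cap (default 200).
#' @param learning_rate Adam step size (default 1e-3).
#' @param validation_fraction fraction of training rows held out
#'   (stratified) as the early-stopping monitor (default 0.1).
#' @param threshold probability cut-off for a positive call; the boundary
#'   probability itself is called positive (default 0.5).
#' @param seed integer seed making training deterministic.
#' @return a `mlp_config` list.
#' @export
mlp_config <- function(hidden_layers = 2L, hidden_neurons = 16L,
                       batch_size = 32L, early_stop_patience = 10L,
                       max_epochs = 200L, learning_rate = 1e-3,
                       validation_fraction = 0.1, threshold = 0.5,
                       seed = 1L) {
  stopifnot(is_count(hidden_layers), hidden_layers >= 1,
            is_count(hidden_neurons), hidden_neurons >= 1,
            is_count(batch_size), batch_size >= 1,
            threshold > 0, threshold < 1)
  structure(list(hidden_layers = as.integer(hidden_layers),
                 hidden_neurons = as.integer(hidden_neurons),
                 batch_size = as.integer(batch_size),
                 early_stop_patience = as.integer(early_stop_patience),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate,
                 validation_fraction = validation_fraction,
                 threshold = threshold, seed = as.integer(seed)),
            class = "mlp_config")
}

# stratified index sample of about `fraction` per class (at least 1)
stratified_holdout <- function(y, fraction) {
  unlist(lapply(split(seq_along(y), y), function(idx) {
    k <- max(1L, round(fraction * length(idx)))
    if (length(idx) == 1L) idx else sample(idx, k)
  }), use.names = FALSE)
}

mlp_init <- function(dims) {
  nl <- length(dims) - 1L
  W <- b <- vector("list", nl)
  for (l in seq_len(nl)) {
    # He-normal fan-in initialisation, suited to ReLU units
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L],
                                  sd = sqrt(2 / dims[l])),
                     dims[l], dims[l + 1L])
    b[[l]] <- numeric(dims[l + 1L])
  }
  list(W = W, b = b)
}

mlp_forward <- function(par, X) {
  nl <- length(par$W)
  A <- vector("list", nl + 1L)
  A[[1L]] <- X
  for (l in seq_len(nl)) {
    Z <- A[[l]] %*% par$W[[l]]
    Z <- Z + rep(par$b[[l]], each = nrow(Z))
    A[[l + 1L]] <- if (l < nl) pmax(Z, 0) else 1 / (1 + exp(-Z))
  }
  A
}

mlp_gradients <- function(par, A, y) {
  nl <- length(par$W)
  m <- length(y)
  dW <- db <- vector("list", nl)
  dZ <- (A[[nl + 1L]] - y) / m # sigmoid + cross-entropy
  for (l in rev(seq_len(nl))) {
    dW[[l]] <- crossprod(A[[l]], dZ)
    db[[l]] <- colSums(dZ)
    if (l > 1L) {
      dZ <- (dZ %*% t(par$W[[l]])) * (A[[l]] > 0)
    }
  }
  list(W = dW, b = db)
}

#' Train the fully-connected classifier
#'
#' @param X numeric feature matrix (rows = examples).
#' @param y logical or 0/1 labels, one per row; both classes must be
#'   present.
#' @param config a [mlp_config()].
#' @return a `trained_mlp` with the fitted weights, the training-set
#'   standardizer, the config, and the number of epochs run.
#' @export
train_mlp <- function(X, y, config = mlp_config()) {
  X <- as.matrix(X)
  y <- as.integer(as.logical(y))
  if (nrow(X) != length(y)) stop_ionsite("X rows must match y length")
  if (length(unique(y)) < 2L) {
    stop_ionsite("training labels contain a single class")
  }
  with_seed(config$seed, {
    mu <- colMeans(X)
    sdev <- sqrt(colMeans(sweep(X, 2L, mu)^2) * nrow(X) /
                   max(1L, nrow(X) - 1L))
    # zero-variance guard: constant columns carry no information and are
    # pinned to 0 both here and at predict time
    active <- is.finite(sdev) & sdev >= 1e-12
    sdev[!active] <- 1
    Xs <- sweep(sweep(X, 2L, mu), 2L, sdev, "/")
    Xs[, !active] <- 0

    val <- sort(stratified_holdout(y, config$validation_fraction))
    tr <- setdiff(seq_along(y), val)
    if (length(unique(y[tr])) < 2L) tr <- seq_along(y) # tiny-data fallback
    Xtr <- Xs[tr, , drop = FALSE]; ytr <- y[tr]
    Xval <- Xs[val, , drop = FALSE]; yval <- y[val]

    dims <- c(ncol(X), rep(config$hidden_neurons, config$hidden_layers), 1L)
    par <- mlp_init(dims)
    mW <- vW <- lapply(par$W, function(w) w * 0)
    mb <- vb <- lapply(par$b, function(w) w * 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0L
    best <- -Inf; wait <- 0L; epochs_run <- 0L

    for (epoch in seq_len(config$max_epochs)) {
      perm <- sample(length(ytr))
      starts <- seq(1L, length(ytr), by = config$batch_size)
      for (s in starts) {
        idx <- perm[s:min(s + config$batch_size - 1L, length(ytr))]
        A <- mlp_forward(par, Xtr[idx, , drop = FALSE])
        g <- mlp_gradients(par, A, ytr[idx])
        step <- step + 1L
        corr <- config$learning_rate *
          sqrt(1 - beta2^step) / (1 - beta1^step)
        for (l in seq_along(par$W)) {
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * g$W[[l]]
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * g$W[[l]]^2
          par$W[[l]] <- par$W[[l]] - corr * mW[[l]] / (sqrt(vW[[l]]) + eps)
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * g$b[[l]]
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * g$b[[l]]^2
          par$b[[l]] <- par$b[[l]] - corr * mb[[l]] / (sqrt(vb[[l]]) + eps)
        }
      }
      epochs_run <- epoch
      prob <- mlp_forward(par, Xval)[[length(par$W) + 1L]]
      acc <- mean((prob >= config$threshold) == yval)
      if (acc > best + 1e-12) {
        best <- acc; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$early_stop_patience) break
      }
    }
    structure(list(config = config, mu = mu, sd = sdev, active = active,
                   par = par, monitor_accuracy = best,
                   epochs_run = epochs_run, n_features = ncol(X),
                   feature_names = colnames(X)),
              class = "trained_mlp")
  })
}

#' @export
print.trained_mlp <- function(x, ...) {
  cat(sprintf(
    "<trained_mlp> %d features | %d x %d hidden | %d epochs | monitor acc %.3f\n",
    x$n_features, x$config$hidden_layers, x$config$hidden_neurons,
    x$epochs_run, x$monitor_accuracy))
  invisible(x)
}

#' Predict binding probabilities and calls
#'
#' @param object a `trained_mlp`.
#' @param X numeric matrix with the training column count.
#' @param ... ignored.
#' @return list with `prob` (numeric, in \[0, 1\]) and `call` (logical;
#'   `prob >= threshold`).
#' @export
predict.trained_mlp <- function(object, X, ...) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) return(list(prob = numeric(0), call = logical(0)))
  if (ncol(X) != object$n_features) {
    stop_ionsite("X has ", ncol(X), " columns; model expects ",
                 object$n_features)
  }
  Xs <- sweep(sweep(X, 2L, object$mu), 2L, object$sd, "/")
  Xs[, !object$active] <- 0
  prob <- as.vector(mlp_forward(object$par, Xs)[[length(object$par$W) + 1L]])
  list(prob = prob, call = prob >= object$config$threshold)
}

#' Save / load a trained model
#'
#' Serializes config, standardizer and weights to JSON text.
#'
#' @param model a `trained_mlp`.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` a
#'   `trained_mlp`.
#' @export
save_model <- function(model, path) {
  payload <- list(
    config = unclass(model$config), mu = model$mu, sd = model$sd,
    active = model$active,
    W = lapply(model$par$W, function(w) list(dim = dim(w),
                                             values = as.vector(w))),
    b = model$par$b, monitor_accuracy = model$monitor_accuracy,
    epochs_run = model$epochs_run, n_features = model$n_features,
    feature_names = model$feature_names
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- lapply(seq_len(nrow_or_len(p$W)), function(l) {
    w <- if (is.data.frame(p$W)) list(dim = p$W$dim[[l]],
                                      values = p$W$values[[l]])
         else p$W[[l]]
    matrix(w$values, w$dim[[1L]], w$dim[[2L]])
  })
  b <- if (is.list(p$b)) lapply(p$b, as.numeric) else list(as.numeric(p$b))
  structure(list(config = do.call(mlp_config, as.list(p$config)),
                 mu = as.numeric(p$mu), sd = as.numeric(p$sd),
                 active = as.logical(p$active),
                 par = list(W = W, b = b),
                 monitor_accuracy = p$monitor_accuracy,
                 epochs_run = p$epochs_run, n_features = p$n_features,
                 feature_names = p$feature_names),
            class = "trained_mlp")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

#' Coordinate-wise exhaustive hyper-parameter search
#'
#' Optimizes the three hyper-parameters one at a time, in the fixed order
#' hidden layers, hidden neurons, batch size. While one parameter sweeps
#' its grid exhaustively the others are held at their current values
#' (starting values `hidden_neurons = 32`, `batch_size = 32`); once a
#' parameter is optimized its best value is frozen for the later sweeps.
#' The objective is the pooled MCC of a stratified k-fold cross-validation
#' of the model on `(X, y)`; ties are broken toward the smaller
#' hyper-parameter value (grids are swept in increasing order and only a
#' strict improvement replaces the incumbent).
#'
#' @param X,y training data as in [train_mlp()].
#' @param grid named list of candidate values for `hidden_layers`,
#'   `hidden_neurons`, `batch_size`. Defaults to layers 1..8 and
#'   neurons/batch in 2, 4, ..., 128.
#' @param start named list of starting values for the parameters not yet
#'   optimized.
#' @param n_folds folds of the inner CV objective (default 3).
#' @param seed integer seed (fold assignment and training).
#' @param base_config template [mlp_config()] supplying all other
#'   training settings.
#' @param objective optional replacement objective
#'   `function(config) -> numeric`, mainly for testing the search
#'   contract.
#' @return list with `config` (the winning [mlp_config()]), `trace`
#'   (data.frame of every evaluation) and `n_evaluations`.
#' @export
coordinate_search <- function(X, y,
                              grid = list(
                                hidden_layers = 1:8,
                                hidden_neurons = c(2L, 4L, 8L, 16L, 32L,
                                                   64L, 128L),
                                batch_size = c(2L, 4L, 8L, 16L, 32L, 64L,
                                               128L)),
                              start = list(hidden_neurons = 32L,
                                           batch_size = 32L),
                              n_folds = 3L, seed = 1L,
                              base_config = mlp_config(),
                              objective = NULL) {
  order_ <- c("hidden_layers", "hidden_neurons", "batch_size")
  if (!all(order_ %in% names(grid)) || any(lengths(grid[order_]) == 0L)) {
    stop_ionsite("grid must provide values for hidden_layers, ",
                 "hidden_neurons and batch_size")
  }
  current <- list(hidden_layers = min(grid$hidden_layers),
                  hidden_neurons = start$hidden_neurons,
                  batch_size = start$batch_size)
  if (is.null(objective)) {
    objective <- function(cfg) {
      cv_mcc_objective(X, y, cfg, n_folds = n_folds, seed = seed)
    }
  }
  trace <- list()
  n_eval <- 0L
  for (param in order_) {
    best_val <- NULL
    best_obj <- -Inf
    for (v in sort(grid[[param]])) {
      cand <- current
      cand[[param]] <- v
      cfg <- base_config
      cfg$hidden_layers <- as.integer(cand$hidden_layers)
      cfg$hidden_neurons <- as.integer(cand$hidden_neurons)
      cfg$batch_size <- as.integer(cand$batch_size)
      cfg$seed <- derive_seed(seed, "tune", n_eval)
      obj <- objective(cfg)
      n_eval <- n_eval + 1L
      trace[[n_eval]] <- data.frame(
        param = param, hidden_layers = cand$hidden_layers,
        hidden_neurons = cand$hidden_neurons,
        batch_size = cand$batch_size, objective = obj)
      if (obj > best_obj) { # strict: earlier (smaller) value wins ties
        best_obj <- obj
        best_val <- v
      }
    }
    current[[param]] <- best_val
  }
  cfg <- base_config
  cfg$hidden_layers <- as.integer(current$hidden_layers)
  cfg$hidden_neurons <- as.integer(current$hidden_neurons)
  cfg$batch_size <- as.integer(current$batch_size)
  cfg$seed <- as.integer(seed)
  list(config = cfg, trace = do.call(rbind, trace),
       n_evaluations = n_eval)
}

# pooled-MCC objective over a stratified k-fold CV of the bare model
cv_mcc_objective <- function(X, y, cfg, n_folds, seed) {
  y <- as.logical(y)
  folds <- with_seed(derive_seed(seed, "cv"),
                     stratified_folds(y, n_folds))
  counts <- c(TP = 0, FP = 0, TN = 0, FN = 0)
  for (k in seq_len(n_folds)) {
    te <- folds == k
    fit <- train_mlp(X[!te, , drop = FALSE], y[!te], cfg)
    call <- predict(fit, X[te, , drop = FALSE])$call
    counts <- counts + confusion_counts(y[te], call)
  }
  metrics(counts[["TP"]], counts[["FP"]], counts[["TN"]],
          counts[["FN"]])$MCC
}
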