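# Evaluation protocol: confusion-matrix metrics, stratified fivefold
# cross-validation, averaged random undersampling, and the chain-level
# 80/20 independent split.

confusion_counts <- function(truth, call) {
  truth <- as.logical(truth); call <- as.logical(call)
  c(TP = sum(truth & call), FP = sum(!truth & call),
    TN = sum(!truth & !call), FN = sum(truth & !call))
}

#' Confusion-matrix metrics
#'
#' Sensitivity `Sn = TP / (TP + FN) * 100`, specificity
#' `Sp = TN / (TN + FP) * 100`, accuracy
#' `Acc = (TP + TN) / total * 100`, and the Matthews correlation
#' coefficient
#' `MCC = (TP * TN - FP * FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,
#' defined as 0 when any denominator factor vanishes. Sn/Sp are `NaN`
#' when their own denominator is zero (no example of that class).
#'
#' @param TP,FP,TN,FN non-negative integer counts, total > 0.
#' @return an `eval_result` list with the four counts and Sn, Sp, Acc
#'   (percentages) and MCC.
#' @export
#' @examples
#' metrics(TP = 20, FP = 5, TN = 80, FN = 10)
metrics <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_ionsite("confusion counts must be non-negative integers")
  }
  total <- sum(counts)
  if (total == 0) stop_ionsite("confusion counts are all zero")
  TP <- as.double(TP); FP <- as.double(FP)
  TN <- as.double(TN); FN <- as.double(FN)
  Sn <- if (TP + FN > 0) TP / (TP + FN) * 100 else NaN
  Sp <- if (TN + FP > 0) TN / (TN + FP) * 100 else NaN
  Acc <- (TP + TN) / total * 100
  denom <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  MCC <- if (denom > 0) (TP * TN - FP * FN) / sqrt(denom) else 0
  structure(list(TP = counts[["TP"]], FP = counts[["FP"]],
                 TN = counts[["TN"]], FN = counts[["FN"]],
                 Sn = Sn, Sp = Sp, Acc = Acc, MCC = MCC),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "TP=%d FP=%d TN=%d FN=%d | Sn=%.2f%% Sp=%.2f%% Acc=%.2f%% MCC=%.4f\n",
    x$TP, x$FP, x$TN, x$FN, x$Sn, x$Sp, x$Acc, x$MCC))
  invisible(x)
}

as_metric_row <- function(r) {
  data.frame(TP = r$TP, FP = r$FP, TN = r$TN, FN = r$FN, Sn = r$Sn,
             Sp = r$Sp, Acc = r$Acc, MCC = r$MCC)
}

# fold id per element, stratified within each label class
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# fold id per element with whole chains kept together, approximately
# balancing positive counts across folds
chain_folds <- function(chain_id, y, k) {
  ids <- sample(unique(chain_id)) # random order, then greedy balance
  pos_per_chain <- tapply(y, chain_id, sum)[ids]
  fold_of_chain <- integer(length(ids))
  load <- numeric(k)
  for (i in order(-pos_per_chain)) {
    f <- which.min(load)
    fold_of_chain[i] <- f
    load[f] <- load[f] + pos_per_chain[i] + 1e-3
  }
  fold_of_chain[match(chain_id, ids)]
}

#' The full encode-train-predict pipeline as a function
#'
#' Returns a pipeline closure `function(train_fs, test_fs, seed)` that
#' fits the ten PWMs and the classifier on the training fragments only
#' (no leakage of test windows into the matrices or the standardizer),
#' encodes both sets, and returns the binary calls for the test set.
#'
#' @param config a [mlp_config()] template; its seed is replaced by the
#'   per-call seed.
#' @param background PWM background mode, see [fit_pwms()].
#' @return a function usable as the `pipeline` of [kfold_cv()] and
#'   friends.
#' @export
dnn_pipeline <- function(config = mlp_config(),
                         background = c("empirical", "uniform")) {
  background <- match.arg(background)
  function(train_fs, test_fs, seed) {
    pwms <- fit_pwms(train_fs, background = background)
    Xtr <- encode(train_fs, pwms)
    Xte <- encode(test_fs, pwms)
    cfg <- config
    cfg$seed <- derive_seed(seed, "model")
    fit <- train_mlp(Xtr, train_fs$label, cfg)
    predict(fit, Xte)$call
  }
}

#' Stratified k-fold cross-validation
#'
#' Splits fragments into `k` stratified folds (or chain-grouped folds
#' with `group_by_chain = TRUE`), runs the pipeline with PWMs and
#' standardizer refitted inside every training fold, and reports per-fold
#' metrics plus metrics pooled over the summed confusion counts. Every
#' fragment is tested exactly once.
#'
#' @param fs a `fragment_set` containing both classes.
#' @param pipeline a function `(train_fs, test_fs, seed) -> logical
#'   calls`, e.g. [dnn_pipeline()].
#' @param k number of folds (default 5).
#' @param seed integer seed for the fold assignment and per-fold model
#'   seeds.
#' @param group_by_chain keep all fragments of a chain in one fold.
#' @return list with `pooled` (an `eval_result`), `per_fold`
#'   (data.frame) and `folds` (the fold id per fragment).
#' @export
kfold_cv <- function(fs, pipeline = dnn_pipeline(), k = 5L, seed = 1L,
                     group_by_chain = FALSE) {
  if (!is_count(k) || k < 2L) stop_ionsite("k must be an integer >= 2")
  y <- fs$label
  folds <- with_seed(derive_seed(seed, "cv"), {
    if (group_by_chain) chain_folds(fs$chain_id, y, k)
    else stratified_folds(y, k)
  })
  per_fold <- vector("list", k)
  counts <- c(TP = 0, FP = 0, TN = 0, FN = 0)
  tested <- integer(0)
  for (f in seq_len(k)) {
    te <- which(folds == f)
    tr <- which(folds != f)
    if (length(unique(y[tr])) < 2L || length(te) == 0L) {
      stop_ionsite("fold ", f, " leaves a single-class training set; ",
                   "use fewer folds or more positives")
    }
    call <- pipeline(fs[tr], fs[te], derive_seed(seed, "cv", f))
    cc <- confusion_counts(y[te], call)
    counts <- counts + cc
    per_fold[[f]] <- cbind(fold = f,
                           as_metric_row(metrics(cc[["TP"]], cc[["FP"]],
                                                 cc[["TN"]], cc[["FN"]])))
    tested <- c(tested, te)
  }
  stopifnot(length(tested) == length(y), !anyDuplicated(tested))
  list(pooled = metrics(counts[["TP"]], counts[["FP"]], counts[["TN"]],
                        counts[["FN"]]),
       per_fold = do.call(rbind, per_fold), folds = folds)
}

#' Averaged random-undersampling evaluation
#'
#' Repeatedly draws, without replacement, as many negative fragments as
#' there are positives, runs the pipeline's stratified k-fold CV on each
#' balanced set, and arithmetically averages the four metrics over the
#' repeats (default 10).
#'
#' @param fs a `fragment_set`; must hold at least as many negatives as
#'   positives and at least one positive.
#' @param pipeline as in [kfold_cv()].
#' @param repeats number of balanced redraws (default 10).
#' @param k CV folds per repeat (default 5).
#' @param seed integer seed; each repeat derives its own draw and CV
#'   seeds.
#' @return list with `average` (named numeric: mean Sn, Sp, Acc, MCC),
#'   `sd` (their dispersion across repeats) and `per_repeat`
#'   (data.frame).
#' @export
undersample_eval <- function(fs, pipeline = dnn_pipeline(),
                             repeats = 10L, k = 5L, seed = 1L) {
  pos <- which(fs$label)
  neg <- which(!fs$label)
  if (length(pos) == 0L) stop_ionsite("no positive fragments")
  if (length(neg) < length(pos)) {
    stop_ionsite("fewer negative than positive fragments; ",
                 "undersampling requires |N| >= |P|")
  }
  rows <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    draw <- with_seed(derive_seed(seed, "undersample", r),
                      sample(neg, length(pos)))
    balanced <- fs[sort(c(pos, draw))]
    cv <- kfold_cv(balanced, pipeline, k = k,
                   seed = derive_seed(seed, "cv", r))
    rows[[r]] <- cbind(repeat_ = r, as_metric_row(cv$pooled))
  }
  per_repeat <- do.call(rbind, rows)
  mets <- c("Sn", "Sp", "Acc", "MCC")
  list(average = colMeans(per_repeat[mets]),
       sd = apply(per_repeat[mets], 2L, stats::sd),
       per_repeat = per_repeat)
}

#' Chain-level train/test split
#'
#' Assigns whole chains to the training or test side; with `n` chains,
#' `floor(n * train_fraction)` go to training. No chain's fragments ever
#' straddle the split.
#'
#' @param chain_ids character vector of unique chain identifiers, or a
#'   list of [protein_chain] objects.
#' @param train_fraction fraction of chains used for training
#'   (default 0.8).
#' @param seed integer seed.
#' @return a `split_plan` list with `train` and `test` chain-id vectors.
#' @export
chain_split <- function(chain_ids, train_fraction = 0.8, seed = 1L) {
  if (is.list(chain_ids)) {
    chain_ids <- vapply(chain_ids, `[[`, "", "chain_id")
  }
  chain_ids <- unique(chain_ids)
  n <- length(chain_ids)
  if (n < 2L) stop_ionsite("need at least 2 chains to split")
  n_train <- floor(n * train_fraction)
  if (n_train < 1L || n_train >= n) {
    stop_ionsite("train_fraction leaves an empty side")
  }
  train <- with_seed(derive_seed(seed, "split"),
                     sample(chain_ids, n_train))
  structure(list(train = sort(train),
                 test = sort(setdiff(chain_ids, train)),
                 train_fraction = train_fraction, seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d train / %d test chains (fraction %.2f)\n",
              length(x$train), length(x$test), x$train_fraction))
  invisible(x)
}

#' Independent test on withheld chains
#'
#' Applies a [chain_split()] plan: the model is trained on balanced
#' undersampled draws from the training chains' fragments and evaluated
#' on every fragment of the withheld chains; metrics are averaged over
#' the repeats. A side without positive fragments raises a warning.
#'
#' @param fs a `fragment_set` covering all chains in the plan.
#' @param plan a `split_plan`.
#' @param pipeline as in [kfold_cv()].
#' @param repeats balanced training redraws (default 10).
#' @param seed integer seed.
#' @return list with `average`, `sd`, `per_repeat` as in
#'   [undersample_eval()], plus `n_train`/`n_test` fragment counts.
#' @export
independent_eval <- function(fs, plan, pipeline = dnn_pipeline(),
                             repeats = 10L, seed = 1L) {
  stopifnot(inherits(plan, "split_plan"))
  tr_idx <- which(fs$chain_id %in% plan$train)
  te_idx <- which(fs$chain_id %in% plan$test)
  if (length(te_idx) == 0L) stop_ionsite("test side has no fragments")
  train_fs <- fs[tr_idx]
  test_fs <- fs[te_idx]
  for (side in list(c("training", "train_fs"), c("test", "test_fs"))) {
    if (sum(get(side[[2L]])$label) == 0L) {
      warning("the ", side[[1L]], " side has no positive fragments",
              call. = FALSE)
    }
  }
  pos <- which(train_fs$label)
  neg <- which(!train_fs$label)
  rows <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    draw <- with_seed(derive_seed(seed, "undersample", r),
                      sample(neg, min(length(neg), length(pos))))
    balanced <- train_fs[sort(c(pos, draw))]
    call <- pipeline(balanced, test_fs, derive_seed(seed, "model", r))
    cc <- confusion_counts(test_fs$label, call)
    rows[[r]] <- cbind(repeat_ = r,
                       as_metric_row(metrics(cc[["TP"]], cc[["FP"]],
                                             cc[["TN"]], cc[["FN"]])))
  }
  per_repeat <- do.call(rbind, rows)
  mets <- c("Sn", "Sp", "Acc", "MCC")
  list(average = colMeans(per_repeat[mets]),
       sd = apply(per_repeat[mets], 2L, stats::sd),
       per_repeat = per_repeat,
       n_train = length(tr_idx), n_test = length(te_idx))
}
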