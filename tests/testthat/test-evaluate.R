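test_that("metrics reproduce hand-computed confusion values", {
  perfect <- metrics(TP = 50, FP = 0, TN = 50, FN = 0)
  expect_equal(perfect$Sn, 100)
  expect_equal(perfect$Sp, 100)
  expect_equal(perfect$Acc, 100)
  expect_equal(perfect$MCC, 1)

  chance <- metrics(TP = 5, FP = 5, TN = 5, FN = 5)
  expect_equal(chance$MCC, 0)
  expect_equal(chance$Acc, 50)

  m <- metrics(TP = 20, FP = 5, TN = 80, FN = 10)
  expect_equal(m$Sn, 66.6667, tolerance = 1e-4)
  expect_equal(m$Sp, 94.1176, tolerance = 1e-4)
  expect_equal(m$Acc, 86.9565, tolerance = 1e-4)
  expect_equal(m$MCC, 0.6471, tolerance = 1e-4)
})

test_that("a vanishing MCC denominator is defined as zero", {
  # no positive calls at all: TP + FP = 0
  m <- metrics(TP = 0, FP = 0, TN = 90, FN = 10)
  expect_equal(m$MCC, 0)
  expect_equal(m$Sn, 0)
  expect_error(metrics(0, 0, 0, 0), "all zero")
  expect_error(metrics(-1, 0, 5, 0), "non-negative")
})

test_that("metrics agree with a brute-force recount of raw pairs", {
  set.seed(31)
  for (rep in 1:20) {
    truth <- runif(80) < 0.3
    call <- xor(truth, runif(80) < 0.4)
    cc <- ionsite:::confusion_counts(truth, call)
    got <- metrics(cc[["TP"]], cc[["FP"]], cc[["TN"]], cc[["FN"]])
    want <- oracle_metrics(truth, call)
    expect_equal(got$TP + got$FP + got$TN + got$FN, 80)
    for (f in c("Sn", "Sp", "Acc", "MCC")) {
      expect_equal(got[[f]], want[[f]], tolerance = 1e-12)
    }
  }
})

test_that("fivefold CV tests each fragment exactly once and pools counts", {
  fs <- small_synthetic_fragments(seed = 5, n_chains = 20)
  majority <- function(train_fs, test_fs, seed) {
    rep(FALSE, n_fragments(test_fs))
  }
  cv <- kfold_cv(fs, majority, k = 5, seed = 2)
  expect_equal(length(cv$folds), n_fragments(fs))
  expect_setequal(unique(cv$folds), 1:5)
  expect_equal(cv$pooled$TP + cv$pooled$FP + cv$pooled$TN + cv$pooled$FN,
               n_fragments(fs))
  # the all-negative pipeline: Sn = 0, Sp = 100
  expect_equal(cv$pooled$Sn, 0)
  expect_equal(cv$pooled$Sp, 100)
  expect_equal(nrow(cv$per_fold), 5L)
  # stratification: every fold holds positives
  pos_per_fold <- tapply(fs$label, cv$folds, sum)
  expect_true(all(pos_per_fold >= 1))
})

test_that("chain-grouped CV never splits a chain across folds", {
  fs <- small_synthetic_fragments(seed = 8, n_chains = 25)
  cv <- kfold_cv(fs, center_rule_pipeline, k = 5, seed = 4,
                 group_by_chain = TRUE)
  folds_per_chain <- tapply(cv$folds, fs$chain_id,
                            function(f) length(unique(f)))
  expect_true(all(folds_per_chain == 1L))
  expect_equal(length(cv$folds), n_fragments(fs))
})

test_that("a deterministic per-fragment pipeline gives duplication-invariant pooled metrics", {
  fs <- small_synthetic_fragments(seed = 6, n_chains = 15)
  cv1 <- kfold_cv(fs, center_rule_pipeline, k = 5, seed = 3)
  doubled <- bind_fragment_sets(list(fs, fs))
  cv2 <- kfold_cv(doubled, center_rule_pipeline, k = 5, seed = 3)
  for (f in c("Sn", "Sp", "Acc", "MCC")) {
    expect_equal(cv2$pooled[[f]], cv1$pooled[[f]], tolerance = 1e-12)
  }
})

test_that("single-class folds and single-class data raise errors", {
  fs <- small_synthetic_fragments(seed = 5, n_chains = 10)
  all_neg <- fs[which(!fs$label)]
  expect_error(kfold_cv(all_neg, center_rule_pipeline, k = 5, seed = 1),
               "single-class")
  expect_error(kfold_cv(fs, center_rule_pipeline, k = 1, seed = 1),
               ">= 2")
})

test_that("undersampling repeats are exactly balanced and averaged", {
  fs <- small_synthetic_fragments(seed = 7, n_chains = 30)
  ratios <- numeric(0)
  recorder <- function(train_fs, test_fs, seed) {
    cnt <- count_classes(train_fs) + count_classes(test_fs)
    ratios <<- c(ratios, cnt[["n_positive"]] / cnt[["n_negative"]])
    center_rule_pipeline(train_fs, test_fs, seed)
  }
  res <- undersample_eval(fs, recorder, repeats = 4, k = 5, seed = 9)
  expect_equal(unique(ratios), 1) # every repeat's set is exactly 1:1
  expect_equal(nrow(res$per_repeat), 4L)
  expect_equal(unname(res$average["MCC"]),
               mean(res$per_repeat$MCC))
  # two master seeds draw different negatives
  res2 <- undersample_eval(fs, center_rule_pipeline, repeats = 2, k = 5,
                           seed = 10)
  res3 <- undersample_eval(fs, center_rule_pipeline, repeats = 2, k = 5,
                           seed = 11)
  expect_false(identical(res2$per_repeat$TN, res3$per_repeat$TN))
})

test_that("a single balanced repeat equals its own average", {
  fs <- small_synthetic_fragments(seed = 12, n_chains = 20)
  pos <- which(fs$label)
  neg <- which(!fs$label)[seq_along(pos)]
  balanced <- fs[sort(c(pos, neg))]
  res <- undersample_eval(balanced, center_rule_pipeline, repeats = 1,
                          k = 5, seed = 2)
  expect_equal(unname(res$average["MCC"]), res$per_repeat$MCC[[1]])
  expect_error(
    undersample_eval(fs[pos], center_rule_pipeline, seed = 1),
    "fewer negative")
})

test_that("chain splits are whole-chain, seeded and floor-sized", {
  ids <- sprintf("c%04d", 1:10)
  plan <- chain_split(ids, seed = 3)
  expect_length(plan$train, 8L)
  expect_length(plan$test, 2L)
  expect_length(intersect(plan$train, plan$test), 0L)
  expect_setequal(c(plan$train, plan$test), ids)
  expect_identical(plan, chain_split(ids, seed = 3))
  # the published-scale split: 1237 chains at 0.8 -> 989 train
  big <- chain_split(sprintf("c%04d", 1:1237), seed = 1)
  expect_length(big$train, 989L)
  expect_length(big$test, 248L)
  expect_error(chain_split("one"), "at least 2")
})

test_that("independent evaluation keeps withheld chains out of training", {
  fs <- small_synthetic_fragments(seed = 15, n_chains = 20)
  plan <- chain_split(unique(fs$chain_id), seed = 5)
  seen_train <- character(0)
  spy <- function(train_fs, test_fs, seed) {
    seen_train <<- union(seen_train, unique(train_fs$chain_id))
    center_rule_pipeline(train_fs, test_fs, seed)
  }
  res <- independent_eval(fs, plan, spy, repeats = 3, seed = 6)
  expect_length(intersect(seen_train, plan$test), 0L)
  expect_equal(res$n_test, sum(fs$chain_id %in% plan$test))
  expect_equal(nrow(res$per_repeat), 3L)
})

test_that("shuffled labels yield near-zero pooled MCC", {
  chains <- generate(generator_config(n_chains = 100,
                                      length_range = c(50, 120),
                                      binding_rate = 0.05, seed = 23))
  fs <- fragment_chains(chains)
  fs$label <- with(list(), {
    set.seed(derive_seed(23, "shuffle"))
    sample(fs$label)
  })
  res <- undersample_eval(fs, dnn_pipeline(), repeats = 2, k = 5,
                          seed = 23)
  expect_lt(abs(res$average[["MCC"]]), 0.1)
})
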