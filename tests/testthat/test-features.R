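test_that("composition sub-blocks are window class frequencies", {
  ch <- make_chain(sequence = strrep("A", 50))
  fs <- extract_fragments(ch)
  comp <- composition_features(fs)
  expect_equal(ncol(comp), 37L)
  # interior all-A fragment: frequency 1 at A, 0 elsewhere in the aa block
  mid <- 25L
  expect_equal(unname(comp[mid, "comp_aa_A"]), 1)
  expect_equal(sum(comp[mid, 1:21] > 0), 1L)
  # chain-start fragment has 4 pads: X frequency 4/9
  expect_equal(unname(comp[1, "comp_aa_X"]), 4 / 9)
  # every sub-block of every fragment sums to 1
  blocks <- list(1:21, 22:25, 26:30, 31:33, 34:37)
  for (b in blocks) {
    expect_equal(unname(rowSums(comp[, b])), rep(1, n_fragments(fs)))
  }
})

test_that("pseudo-count PWM matches the closed-form hand value", {
  # 100 fragments; class 'A' appears 5 times at site 1
  chains <- generate(generator_config(n_chains = 2, seed = 9))
  fs <- fragment_chains(chains)[1:100]
  target <- which(AA_LEVELS == "A")
  n_a <- sum(fs$aa[, 1] == target)
  pwm <- fit_pwm(fs, "aa", p0 = rep(1 / 21, 21), fitted_on = "positive")
  expect_equal(pwm$p[1, "A"],
               (n_a + sqrt(100) / 21) / (100 + sqrt(100)),
               ignore_attr = TRUE)
  # the printed hand evaluation: n_ij = 5, N_i = 100, q = 21
  expect_equal((5 + sqrt(100) / 21) / (100 + sqrt(100)), 0.0497835,
               tolerance = 1e-5)
  # p equal to background gives log-odds zero
  expect_equal(log(pwm$p[2, ] / pwm$p[2, ]), rep(0, 21),
               ignore_attr = TRUE)
})

test_that("every fitted PWM row is an exact probability distribution", {
  chains <- worked_example()
  fs <- fragment_chains(chains)
  pwms <- fit_pwms(fs)
  for (tr in c("aa", "ss", "rsa", "phi", "psi")) {
    for (side in c("positive", "negative")) {
      w <- pwms[[tr]][[side]]
      expect_lt(max(abs(rowSums(w$p) - 1)), 1e-12)
      expect_equal(sum(w$p0), 1, tolerance = 1e-12)
      expect_equal(w$m, log(w$p / rep(w$p0, each = w$L)),
                   ignore_attr = TRUE)
    }
  }
})

test_that("fit_pwm agrees element-wise with the brute-force tally oracle", {
  chains <- generate(generator_config(n_chains = 3, binding_rate = 0.1,
                                      seed = 21))
  fs <- fragment_chains(chains)
  for (seed in 1:3) {
    set.seed(seed)
    sub <- fs[sample(n_fragments(fs), 10)]
    for (tr in c("aa", "ss", "rsa", "phi", "psi")) {
      q <- length(ionsite:::track_levels(tr))
      p0 <- rep(1 / q, q)
      got <- fit_pwm(sub, tr, p0 = p0, fitted_on = "negative")
      want <- oracle_pwm(sub, tr, p0)
      expect_equal(got$p, want$p, tolerance = 1e-14, ignore_attr = TRUE)
      expect_equal(got$m, want$m, tolerance = 1e-14, ignore_attr = TRUE)
    }
  }
})

test_that("conservation block scores each site against both class PWMs", {
  chains <- worked_example()
  fs <- fragment_chains(chains)
  pwms <- fit_pwms(fs)
  cons <- conservation_features(fs, pwms)
  expect_equal(ncol(cons), 2 * 9 * 5)
  # spot-check one fragment against direct PWM lookups
  k <- 17L
  for (i in c(1L, 5L, 9L)) {
    j <- fs$aa[k, i]
    expect_equal(unname(cons[k, paste0("cons_aa_pos_", i)]),
                 unname(pwms$aa$positive$m[i, j]))
    expect_equal(unname(cons[k, paste0("cons_aa_neg_", i)]),
                 unname(pwms$aa$negative$m[i, j]))
  }
  # swapping the class training sets swaps the pos/neg halves
  swapped <- fs
  swapped$label <- !fs$label
  pwms_sw <- fit_pwms(swapped)
  cons_sw <- conservation_features(fs, pwms_sw)
  expect_equal(unname(cons_sw[, paste0("cons_ss_pos_", 1:9)]),
               unname(cons[, paste0("cons_ss_neg_", 1:9)]))
  expect_equal(unname(cons_sw[, paste0("cons_ss_neg_", 1:9)]),
               unname(cons[, paste0("cons_ss_pos_", 1:9)]))
})

test_that("a fragment scored on its own 1-fragment training set matches Eq closed form", {
  chains <- worked_example()
  fs <- fragment_chains(chains)
  one <- fs[which(fs$label)[1]]
  neg <- fs[which(!fs$label)[1:5]]
  train <- bind_fragment_sets(list(one, neg))
  pwms <- fit_pwms(train, background = "uniform")
  cons <- conservation_features(one, pwms)
  # with N = 1 the observed class has p = (1 + 1/q)/2; against p0 = 1/q
  q <- 21
  expected <- log(((1 + sqrt(1) / q) / (1 + sqrt(1))) / (1 / q))
  expect_equal(unname(cons[1, paste0("cons_aa_pos_", 1:9)]),
               rep(expected, 9))
})

test_that("entropy features reproduce hand-computed Shannon values", {
  mk <- function(seq) extract_fragments(
    protein_chain("e", seq, rep(FALSE, 9), rep("C", 9), rep(0.1, 9),
                  rep(-80, 9), rep(10, 9), min_length = 1), L = 9)
  ent_mid <- function(seq) entropy_features(mk(seq))[5, ]
  # uniform over the 3 charge classes
  expect_equal(unname(ent_mid("KKKDDDGGG")[["entropy_charge"]]), log2(3))
  # hand evaluation of -(5/9)log2(5/9) - (4/9)log2(4/9)
  expect_equal(unname(ent_mid("KKKKKDDDD")[["entropy_charge"]]),
               0.99108, tolerance = 1e-5)
  # a single hydropathy class has zero entropy
  expect_equal(unname(ent_mid("LIVAMFLIV")[["entropy_hydropathy"]]), 0)
  # pads are excluded: terminal window over 5 real residues
  e1 <- entropy_features(mk("KKKDDDGGG"))[1, ] # KKKDD visible
  expect_equal(unname(e1[["entropy_charge"]]),
               oracle_entropy(c("K", "K", "K", "D", "D"), charge_class))
})

test_that("entropy stays within its class-count bounds on random fragments", {
  fs <- small_synthetic_fragments(seed = 13, n_chains = 10)
  ent <- entropy_features(fs)
  expect_true(all(ent[, "entropy_charge"] >= 0 &
                    ent[, "entropy_charge"] <= log2(3) + 1e-12))
  expect_true(all(ent[, "entropy_hydropathy"] >= 0 &
                    ent[, "entropy_hydropathy"] <= log2(6) + 1e-12))
})

test_that("encode lays out 37 + 90 + 2 named columns deterministically", {
  chains <- worked_example()
  fs <- fragment_chains(chains)
  pwms <- fit_pwms(fs)
  X <- encode(fs, pwms)
  expect_equal(ncol(X), 129L)
  expect_true(all(startsWith(colnames(X)[1:37], "comp_")))
  expect_true(all(startsWith(colnames(X)[38:127], "cons_")))
  expect_equal(colnames(X)[128:129],
               c("entropy_hydropathy", "entropy_charge"))
  expect_identical(X, encode(fs, pwms))
  # PWMs fitted at a different window length are rejected
  fs7 <- fragment_chains(chains, L = 7)
  expect_error(encode(fs7, pwms), "L = ")
})

test_that("PWM sets round-trip exactly through their text serialization", {
  chains <- worked_example()
  fs <- fragment_chains(chains)
  pwms <- fit_pwms(fs)
  f <- withr_local_file("pwms.tsv")
  write_pwms(pwms, f)
  back <- read_pwms(f)
  for (tr in c("aa", "rsa")) {
    for (side in c("positive", "negative")) {
      expect_identical(back[[tr]][[side]]$m, pwms[[tr]][[side]]$m)
      expect_identical(back[[tr]][[side]]$p0, pwms[[tr]][[side]]$p0)
    }
  }
  expect_identical(conservation_features(fs, back),
                   conservation_features(fs, pwms))
})
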