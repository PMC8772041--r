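# Fixture builders and independent brute-force oracles. The oracles
# re-derive every quantity by explicit loops over the defining formulas
# and never call the vectorised implementation paths they check.

make_chain <- function(id = "c1", sequence = strrep("ADKE", 15),
                       binding = integer(0), ss = NULL, rsa = NULL,
                       phi = NULL, psi = NULL, min_length = 1) {
  n <- nchar(sequence)
  mask <- rep(FALSE, n)
  mask[binding] <- TRUE
  protein_chain(
    id, sequence, mask,
    ss = ss %||% rep(c("H", "E", "C"), length.out = n),
    rsa = rsa %||% rep(c(0.1, 0.3, 0.5, 0.7), length.out = n),
    phi = phi %||% rep(c(-100, 50), length.out = n),
    psi = psi %||% rep(c(-30, 60, 160), length.out = n),
    min_length = min_length
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# explicit tally-and-formula PWM: p_ij = (n_ij + sqrt(N_i)/q)/(N_i + sqrt(N_i))
oracle_pwm <- function(fs, track, p0) {
  lev <- switch(track, aa = AA_LEVELS, ss = SS_LEVELS, rsa = RSA_LEVELS,
                phi = PHI_LEVELS, psi = PSI_LEVELS)
  q <- length(lev)
  L <- fs$L
  n <- n_fragments(fs)
  p <- m <- matrix(NA_real_, L, q)
  for (i in seq_len(L)) {
    for (j in seq_len(q)) {
      nij <- 0
      for (k in seq_len(n)) {
        if (fs[[track]][k, i] == j) nij <- nij + 1
      }
      p[i, j] <- (nij + sqrt(n) / q) / (n + sqrt(n))
      m[i, j] <- log(p[i, j] / p0[j])
    }
  }
  list(p = p, m = m)
}

# entropy of tokens over a class labelling, pads excluded
oracle_entropy <- function(tokens, class_fun) {
  cls <- class_fun(tokens)
  cls <- cls[cls != "PAD"]
  H <- 0
  for (cnt in table(cls)) {
    pj <- cnt / length(cls)
    H <- H - pj * log2(pj)
  }
  H
}

# metrics recomputed from raw (truth, call) pairs by direct counting
oracle_metrics <- function(truth, call) {
  TP <- sum(truth & call); FP <- sum(!truth & call)
  TN <- sum(!truth & !call); FN <- sum(truth & !call)
  denom <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       Sn = TP / (TP + FN) * 100, Sp = TN / (TN + FP) * 100,
       Acc = (TP + TN) / (TP + FP + TN + FN) * 100,
       MCC = if (denom > 0) (TP * TN - FP * FN) / denom else 0)
}

# small planted-signal dataset shared by the slower protocol tests
small_synthetic_fragments <- function(seed = 5, n_chains = 60,
                                      binding_rate = 0.03) {
  chains <- generate(generator_config(
    n_chains = n_chains, length_range = c(50, 120),
    binding_rate = binding_rate, seed = seed))
  fragment_chains(chains)
}

withr_local_file <- function(name, env = parent.frame()) {
  file.path(withr::local_tempdir(.local_envir = env), name)
}

# deterministic training-free pipeline: calls positive when the center
# residue is acidic/amide (the planted signal), for protocol tests
center_rule_pipeline <- function(train_fs, test_fs, seed) {
  fragment_centers(test_fs) %in% c("D", "E", "N")
}
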