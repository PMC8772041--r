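# Fragment encoding: 37-dim class composition, 2L x 5 position-weight-
# matrix conservation scores, and 2 physicochemical entropy features
# (129 dimensions at L = 9).

#' Fit a pseudo-count position weight matrix for one track
#'
#' For window site i and class j, with `n_ij` the count of class j at
#' site i over the training fragments and `N_i` the number of fragments,
#' the smoothed probability is
#' `p_ij = (n_ij + sqrt(N_i)/q) / (N_i + sqrt(N_i))`
#' and the matrix element is the log-odds `m_ij = ln(p_ij / p0_j)`
#' against a background probability `p0_j`. The pad class participates in
#' the counts like any other class, so `q` is the track's class count
#' including PAD (21, 4, 5, 3, 4 for aa/ss/rsa/phi/psi).
#'
#' @param fs training fragments of a single label class.
#' @param track one of "aa", "ss", "rsa", "phi", "psi".
#' @param p0 background probabilities (length q, summing to 1). Default
#'   NULL computes the smoothed empirical class frequency over all sites
#'   of `fs` itself; [fit_pwms()] passes the combined-class background.
#' @param fitted_on label of the training class ("positive" or
#'   "negative"), recorded for provenance.
#' @return an object of class `pwm` with elements `m`, `p` (L x q
#'   matrices), `p0`, `track`, `q`, `L`, `fitted_on`.
#' @export
fit_pwm <- function(fs, track = .TRACKS, p0 = NULL,
                    fitted_on = c("positive", "negative")) {
  track <- match.arg(track)
  fitted_on <- match.arg(fitted_on)
  n <- n_fragments(fs)
  if (n == 0L) stop_ionsite("cannot fit a PWM on an empty training set")
  lev <- track_levels(track)
  q <- length(lev)
  mat <- fs[[track]]
  L <- fs$L
  counts <- vapply(seq_len(q), function(j) colSums(mat == j),
                   numeric(L)) # L x q
  counts <- matrix(counts, L, q)
  if (is.null(p0)) p0 <- background_probs(counts, q)
  if (length(p0) != q || abs(sum(p0) - 1) > 1e-8 || any(p0 <= 0)) {
    stop_ionsite("p0 must be ", q, " positive probabilities summing to 1")
  }
  Ni <- n # every fragment contributes one symbol per site (pads included)
  p <- (counts + sqrt(Ni) / q) / (Ni + sqrt(Ni))
  m <- log(p / rep(p0, each = L))
  dimnames(p) <- dimnames(m) <- list(NULL, lev)
  structure(list(track = track, q = q, L = L, m = m, p = p, p0 = p0,
                 fitted_on = fitted_on),
            class = "pwm")
}

# smoothed pooled class frequencies from an L x q count matrix
background_probs <- function(counts, q) {
  nj <- colSums(counts)
  N <- sum(nj)
  (nj + sqrt(N) / q) / (N + sqrt(N))
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> track %s (%s set): %d sites x %d classes\n",
              x$track, x$fitted_on, x$L, x$q))
  invisible(x)
}

#' Fit positive and negative PWMs for all five tracks
#'
#' Fits, for each annotation track, one PWM on the positive (binding)
#' fragments and one on the negative fragments. The background `p0` of
#' both is the smoothed class frequency over all sites of the combined
#' training set (`background = "empirical"`), or the uniform distribution
#' `1/q` (`background = "uniform"`).
#'
#' @param fs training `fragment_set` containing both classes.
#' @param background "empirical" (default) or "uniform".
#' @return an object of class `pwm_set`: a list with one
#'   `list(positive =, negative =)` pair per track.
#' @export
fit_pwms <- function(fs, background = c("empirical", "uniform")) {
  background <- match.arg(background)
  pos <- fs[fs$label]
  neg <- fs[!fs$label]
  if (n_fragments(pos) == 0L || n_fragments(neg) == 0L) {
    stop_ionsite("training set must contain both classes")
  }
  out <- lapply(.TRACKS, function(tr) {
    q <- length(track_levels(tr))
    p0 <- if (background == "uniform") {
      rep(1 / q, q)
    } else {
      counts <- vapply(seq_len(q), function(j) colSums(fs[[tr]] == j),
                       numeric(fs$L))
      background_probs(matrix(counts, fs$L, q), q)
    }
    list(positive = fit_pwm(pos, tr, p0 = p0, fitted_on = "positive"),
         negative = fit_pwm(neg, tr, p0 = p0, fitted_on = "negative"))
  })
  names(out) <- .TRACKS
  structure(out, class = "pwm_set", L = fs$L, background = background)
}

#' Class-composition features (37 dimensions at any L)
#'
#' Per-track class frequencies within the window, pads included: counts
#' divided by L. Sub-blocks: amino acids (21), secondary structure (4),
#' RSA class (5), phi class (3), psi class (4); each sub-block sums to 1.
#'
#' @param fs a `fragment_set`.
#' @return numeric matrix, one row per fragment, 37 named columns.
#' @export
composition_features <- function(fs) {
  blocks <- lapply(.TRACKS, function(tr) {
    lev <- track_levels(tr)
    mat <- fs[[tr]]
    block <- vapply(seq_along(lev), function(j) rowSums(mat == j),
                    numeric(n_fragments(fs))) / fs$L
    block <- matrix(block, n_fragments(fs), length(lev))
    colnames(block) <- paste("comp", tr, lev, sep = "_")
    block
  })
  do.call(cbind, blocks)
}

#' Positional conservation features (2L x 5 dimensions)
#'
#' For each track and window site i, looks up the fragment's class j(i)
#' in the positive-set PWM and in the negative-set PWM, giving L
#' positive-matrix log-odds scores followed by L negative-matrix scores
#' per track; tracks are laid out in the order aa, ss, rsa, phi, psi.
#'
#' @param fs a `fragment_set`.
#' @param pwms a `pwm_set` from [fit_pwms()] with matching window length.
#' @return numeric matrix, one row per fragment, `2 * L * 5` named
#'   columns.
#' @export
conservation_features <- function(fs, pwms) {
  stopifnot(inherits(pwms, "pwm_set"))
  if (attr(pwms, "L") != fs$L) {
    stop_ionsite("PWMs were fitted at L = ", attr(pwms, "L"),
                 " but fragments have L = ", fs$L)
  }
  n <- n_fragments(fs)
  L <- fs$L
  site <- rep(seq_len(L), each = n)
  blocks <- lapply(.TRACKS, function(tr) {
    cls <- as.vector(fs[[tr]])
    sc <- cbind(
      matrix(pwms[[tr]]$positive$m[cbind(site, cls)], n, L),
      matrix(pwms[[tr]]$negative$m[cbind(site, cls)], n, L)
    )
    colnames(sc) <- c(paste("cons", tr, "pos", seq_len(L), sep = "_"),
                      paste("cons", tr, "neg", seq_len(L), sep = "_"))
    sc
  })
  do.call(cbind, blocks)
}

#' Physicochemical information-entropy features (2 dimensions)
#'
#' Shannon entropy (base 2) of the distribution of the fragment's real
#' (non-pad) residues over the 6 hydropathy classes and over the 3 charge
#' classes. Pad/unknown positions are excluded from the counts, so the
#' normaliser N is the number of real residues in the window.
#'
#' @param fs a `fragment_set`.
#' @return numeric matrix with columns `entropy_hydropathy`,
#'   `entropy_charge`; values in `[0, log2(6)]` and `[0, log2(3)]`.
#' @export
entropy_features <- function(fs) {
  aa <- fs$aa
  # class index per AA_LEVELS entry; NA for the pad token
  hyd_map <- match(hydropathy_of(AA_LEVELS), .HYDROPATHY_CLASSES)
  chg_map <- match(charge_of(AA_LEVELS), .CHARGE_CLASSES)
  hyd_map[AA_LEVELS == "X"] <- NA_integer_
  chg_map[AA_LEVELS == "X"] <- NA_integer_
  cbind(
    entropy_hydropathy = class_entropy(hyd_map[aa], dim(aa),
                                       length(.HYDROPATHY_CLASSES)),
    entropy_charge = class_entropy(chg_map[aa], dim(aa),
                                   length(.CHARGE_CLASSES))
  )
}

class_entropy <- function(cls, dims, q) {
  cls <- array(cls, dims)
  counts <- vapply(seq_len(q),
                   function(j) rowSums(cls == j, na.rm = TRUE),
                   numeric(dims[[1L]]))
  counts <- matrix(counts, dims[[1L]], q)
  N <- rowSums(counts)
  if (any(N == 0)) {
    stop_ionsite("fragment with no real residues cannot have an entropy")
  }
  p <- counts / N
  plogp <- ifelse(p > 0, p * log2(p), 0)
  -rowSums(plogp)
}

#' Encode fragments into the full feature matrix
#'
#' Concatenates, in order: the 37 composition features, the `2 * L * 5`
#' conservation features and the 2 entropy features — 129 columns at the
#' default L = 9.
#'
#' @param fs a `fragment_set`.
#' @param pwms a `pwm_set` fitted at the same window length.
#' @return numeric matrix with one named row block per feature family.
#' @export
encode <- function(fs, pwms) {
  cbind(composition_features(fs),
        conservation_features(fs, pwms),
        entropy_features(fs))
}

#' Serialize / load a PWM set
#'
#' Writes all ten matrices as one tab-separated table with columns
#' track, fitted_on, site, class, m, p, p0 (long format), preceded by a
#' header line. Round-trips exactly at 17 significant digits.
#'
#' @param pwms a `pwm_set`.
#' @param path file path.
#' @return `write_pwms` returns `path` invisibly; `read_pwms` a
#'   `pwm_set`.
#' @export
write_pwms <- function(pwms, path) {
  stopifnot(inherits(pwms, "pwm_set"))
  rows <- character(0)
  for (tr in .TRACKS) {
    for (side in c("positive", "negative")) {
      w <- pwms[[tr]][[side]]
      grid <- expand.grid(site = seq_len(w$L), class = seq_len(w$q))
      rows <- c(rows, sprintf(
        "%s\t%s\t%d\t%d\t%s\t%s\t%s", tr, side, grid$site, grid$class,
        formatC(w$m[cbind(grid$site, grid$class)], digits = 17,
                format = "g"),
        formatC(w$p[cbind(grid$site, grid$class)], digits = 17,
                format = "g"),
        formatC(w$p0[grid$class], digits = 17, format = "g")))
    }
  }
  writeLines(c(sprintf("# pwm_set L=%d background=%s", attr(pwms, "L"),
                       attr(pwms, "background")),
               "track\tfitted_on\tsite\tclass\tm\tp\tp0", rows), path)
  invisible(path)
}

#' @rdname write_pwms
#' @export
read_pwms <- function(path) {
  lines <- readLines(path)
  meta <- regmatches(lines[[1L]],
                     regexec("L=(\\d+) background=(\\w+)", lines[[1L]]))[[1L]]
  L <- as.integer(meta[[2L]])
  tab <- utils::read.delim(text = lines[-(1:2)], header = FALSE,
                           col.names = c("track", "fitted_on", "site",
                                         "class", "m", "p", "p0"))
  out <- lapply(.TRACKS, function(tr) {
    lapply(c(positive = "positive", negative = "negative"), function(side) {
      d <- tab[tab$track == tr & tab$fitted_on == side, ]
      lev <- track_levels(tr)
      q <- length(lev)
      m <- p <- matrix(NA_real_, L, q, dimnames = list(NULL, lev))
      m[cbind(d$site, d$class)] <- d$m
      p[cbind(d$site, d$class)] <- d$p
      p0 <- numeric(q)
      p0[d$class] <- d$p0
      structure(list(track = tr, q = q, L = L, m = m, p = p, p0 = p0,
                     fitted_on = side), class = "pwm")
    })
  })
  names(out) <- .TRACKS
  structure(out, class = "pwm_set", L = L, background = meta[[3L]])
}
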