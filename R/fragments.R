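# Residue-centred window extraction.
#
# A fragment set is stored column-compressed: one integer matrix per
# annotation track (n fragments x L sites, entries indexing into the
# track's level vector), which keeps encoding vectorised. The last level
# of every track is the pad class, used for the (L-1)/2 pseudo residues
# appended at each chain end so that terminal residues can center a full
# window.

#' Extract residue-centred fragments from a chain
#'
#' Pads the chain with `(L - 1) / 2` pseudo residues at both ends and
#' excerpts one length-`L` window per residue. A fragment is labelled
#' positive when its center residue is a binding residue. Structure
#' tracks are discretized ([classify_rsa()], [classify_phi()],
#' [classify_psi()]) before windowing; pad positions take the PAD class
#' on every track.
#'
#' @param chain a [protein_chain] object.
#' @param L odd window length, `>= 1` (default 9).
#' @return a `fragment_set` with one fragment per residue.
#' @export
#' @examples
#' ch <- protein_chain("c1", strrep("ADKE", 15), rep(FALSE, 60),
#'                     rep("C", 60), rep(0.1, 60), rep(-80, 60),
#'                     rep(10, 60), min_length = 50)
#' fs <- extract_fragments(ch, L = 9)
#' n_fragments(fs)
extract_fragments <- function(chain, L = 9L) {
  stopifnot(inherits(chain, "protein_chain"))
  if (!is_count(L) || L < 1L || L %% 2L == 0L) {
    stop_ionsite("window length L must be an odd positive integer")
  }
  L <- as.integer(L)
  n <- nchar(chain$sequence)
  w <- (L - 1L) %/% 2L

  idx <- list(
    aa  = match(strsplit(chain$sequence, "")[[1]], AA_LEVELS),
    ss  = match(chain$ss, SS_LEVELS),
    rsa = match(classify_rsa(chain$rsa), RSA_LEVELS),
    phi = match(classify_phi(chain$phi), PHI_LEVELS),
    psi = match(classify_psi(chain$psi), PSI_LEVELS)
  )
  win <- outer(seq_len(n), seq_len(L) - 1L, `+`) # into padded vectors
  tracks <- lapply(.TRACKS, function(tr) {
    pad <- length(track_levels(tr)) # pad class is always the last level
    padded <- c(rep.int(pad, w), idx[[tr]], rep.int(pad, w))
    matrix(padded[win], n, L)
  })
  names(tracks) <- .TRACKS
  new_fragment_set(
    chain_id = rep(chain$chain_id, n),
    center = seq_len(n) - 1L,
    label = chain$binding_mask,
    tracks = tracks, L = L
  )
}

new_fragment_set <- function(chain_id, center, label, tracks, L) {
  structure(
    c(list(chain_id = chain_id, center = as.integer(center),
           label = label, L = as.integer(L)), tracks),
    class = "fragment_set"
  )
}

#' Number of fragments in a fragment set
#' @param fs a `fragment_set`.
#' @return integer count.
#' @export
n_fragments <- function(fs) length(fs$label)

#' @export
print.fragment_set <- function(x, ...) {
  cnt <- count_classes(x)
  cat(sprintf(
    "<fragment_set> %d fragments (L = %d) from %d chain(s): %d +, %d -\n",
    n_fragments(x), x$L, length(unique(x$chain_id)), cnt[["n_positive"]],
    cnt[["n_negative"]]))
  invisible(x)
}

#' Subset a fragment set
#' @param x a `fragment_set`.
#' @param i index vector.
#' @param ... ignored.
#' @export
`[.fragment_set` <- function(x, i, ...) {
  tracks <- lapply(.TRACKS, function(tr) x[[tr]][i, , drop = FALSE])
  names(tracks) <- .TRACKS
  new_fragment_set(
    chain_id = x$chain_id[i], center = x$center[i], label = x$label[i],
    tracks = tracks, L = x$L
  )
}

#' Combine fragment sets
#' @param sets `fragment_set` objects with equal window length.
#' @return a single `fragment_set`.
#' @export
bind_fragment_sets <- function(sets) {
  sets <- Filter(Negate(is.null), sets)
  if (length(sets) == 0L) stop_ionsite("no fragment sets to combine")
  Ls <- vapply(sets, function(s) s$L, 1L)
  if (length(unique(Ls)) != 1L) {
    stop_ionsite("fragment sets have differing window lengths")
  }
  tracks <- lapply(.TRACKS, function(tr)
    do.call(rbind, lapply(sets, `[[`, tr)))
  names(tracks) <- .TRACKS
  new_fragment_set(
    chain_id = unlist(lapply(sets, `[[`, "chain_id"), use.names = FALSE),
    center = unlist(lapply(sets, `[[`, "center"), use.names = FALSE),
    label = unlist(lapply(sets, `[[`, "label"), use.names = FALSE),
    tracks = tracks, L = Ls[[1L]]
  )
}

#' Extract fragments from a list of chains
#'
#' @param chains list of [protein_chain] objects.
#' @param L odd window length (default 9).
#' @param drop_x_centers drop fragments whose center residue is the
#'   unknown token 'X' (default FALSE: every residue centers a fragment).
#' @return a combined `fragment_set`.
#' @export
fragment_chains <- function(chains, L = 9L, drop_x_centers = FALSE) {
  fs <- bind_fragment_sets(lapply(chains, extract_fragments, L = L))
  if (drop_x_centers) {
    w <- (fs$L - 1L) %/% 2L
    keep <- fs$aa[, w + 1L] != length(AA_LEVELS)
    fs <- fs[keep]
  }
  fs
}

#' Count positive and negative fragments
#'
#' @param fs a `fragment_set`.
#' @return named integer vector `c(n_positive, n_negative)`.
#' @export
count_classes <- function(fs) {
  np <- sum(fs$label)
  c(n_positive = np, n_negative = length(fs$label) - np)
}

#' Center residue tokens of a fragment set
#'
#' @param fs a `fragment_set`.
#' @return character vector of one-letter residue tokens at each
#'   fragment's center site.
#' @export
fragment_centers <- function(fs) {
  w <- (fs$L - 1L) %/% 2L
  AA_LEVELS[fs$aa[, w + 1L]]
}
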