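# Categorical class schemes for residues and predicted structure values.
#
# The encoder works over a closed alphabet per annotation track; every
# track carries one extra PAD class for window positions that fall outside
# the chain (and, for the residue track, for non-standard residues mapped
# to 'X'). The class counts per track (21, 4, 5, 3, 4) are what give the
# 37-dimensional composition block its size.

#' Track alphabets
#'
#' Ordered class labels for the five annotation tracks. The last label of
#' every track is the pad/unknown class ('X' for residues, 'PAD'
#' elsewhere).
#'
#' @format Character vectors.
#' @name alphabets
NULL

#' @rdname alphabets
#' @export
AA_LEVELS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' @rdname alphabets
#' @export
SS_LEVELS <- c("H", "E", "C", "PAD")

#' @rdname alphabets
#' @export
RSA_LEVELS <- c("I", "II", "III", "IV", "PAD")

#' @rdname alphabets
#' @export
PHI_LEVELS <- c("I", "II", "PAD")

#' @rdname alphabets
#' @export
PSI_LEVELS <- c("I", "II", "III", "PAD")

.TRACKS <- c("aa", "ss", "rsa", "phi", "psi")

track_levels <- function(track) {
  switch(track,
    aa = AA_LEVELS, ss = SS_LEVELS, rsa = RSA_LEVELS,
    phi = PHI_LEVELS, psi = PSI_LEVELS,
    stop_ionsite("unknown track '", track, "'")
  )
}

#' Discretize relative solvent accessibility
#'
#' Maps RSA values in \[0, 1\] onto four intervals: I (0, 0.2\],
#' II (0.2, 0.45\], III (0.45, 0.6\], IV (0.6, 0.85\]. The printed
#' intervals leave x = 0 and x > 0.85 uncovered; those are clamped to the
#' nearest class (0 -> I, > 0.85 -> IV) so the mapper is total on \[0, 1\].
#'
#' @param x numeric vector of RSA values in \[0, 1\].
#' @return character vector over I, II, III, IV.
#' @export
#' @examples
#' classify_rsa(c(0.2, 0.5, 0.9))
classify_rsa <- function(x) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    stop_ionsite("RSA values must lie in [0, 1]")
  }
  out <- character(length(x))
  out[x <= 0.2] <- "I"
  out[x > 0.2 & x <= 0.45] <- "II"
  out[x > 0.45 & x <= 0.6] <- "III"
  out[x > 0.6] <- "IV"
  out
}

check_angle <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < -180 | x > 180)) {
    stop_ionsite(what, " angles must lie in [-180, 180] degrees")
  }
}

#' Discretize phi dihedral angles
#'
#' Class I on \[-180, -75\] degrees, class II on (-75, 180\].
#'
#' @param x numeric vector of angles in degrees, in \[-180, 180\].
#' @return character vector over I, II.
#' @export
classify_phi <- function(x) {
  check_angle(x, "phi")
  ifelse(x <= -75, "I", "II")
}

#' Discretize psi dihedral angles
#'
#' Class I on \[-180, 15\] degrees, II on (15, 135\], III on (135, 180\].
#'
#' @param x numeric vector of angles in degrees, in \[-180, 180\].
#' @return character vector over I, II, III.
#' @export
classify_psi <- function(x) {
  check_angle(x, "psi")
  out <- character(length(x))
  out[x <= 15] <- "I"
  out[x > 15 & x <= 135] <- "II"
  out[x > 135] <- "III"
  out
}

# per-residue physicochemical class maps, indexed by position in AA_LEVELS
.CHARGE_CLASSES <- c("positive", "negative", "neutral")
.HYDROPATHY_CLASSES <- c("strong_philic", "strong_phobic", "weak_philic",
                         "P", "G", "C")

charge_of <- function(aa) {
  ifelse(aa %in% c("K", "R", "H"), "positive",
    ifelse(aa %in% c("D", "E"), "negative", "neutral"))
}

hydropathy_of <- function(aa) {
  ifelse(aa %in% c("R", "D", "E", "N", "Q", "K", "H"), "strong_philic",
    ifelse(aa %in% c("L", "I", "V", "A", "M", "F"), "strong_phobic",
      ifelse(aa %in% c("S", "T", "Y", "W"), "weak_philic", aa)))
}

#' Charge class of a residue
#'
#' K, R and H are positively charged, D and E negatively charged, all
#' other amino acids neutral. The pad/unknown token 'X' maps to PAD.
#'
#' @param aa character vector of one-letter residue tokens over the
#'   21-symbol alphabet ([AA_LEVELS]).
#' @return character vector over positive, negative, neutral, PAD.
#' @export
charge_class <- function(aa) {
  bad <- setdiff(unique(aa), AA_LEVELS)
  if (length(bad)) stop_ionsite("unknown residue token(s): ",
                                paste(bad, collapse = ", "))
  ifelse(aa == "X", "PAD", charge_of(aa))
}

#' Hydropathy class of a residue
#'
#' R, D, E, N, Q, K, H are strongly hydrophilic; L, I, V, A, M, F strongly
#' hydrophobic; S, T, Y, W weakly hydrophilic; P, G and C each form their
#' own class. The pad/unknown token 'X' maps to PAD.
#'
#' @inheritParams charge_class
#' @return character vector over strong_philic, strong_phobic,
#'   weak_philic, P, G, C, PAD.
#' @export
hydropathy_class <- function(aa) {
  bad <- setdiff(unique(aa), AA_LEVELS)
  if (length(bad)) stop_ionsite("unknown residue token(s): ",
                                paste(bad, collapse = ", "))
  ifelse(aa == "X", "PAD", hydropathy_of(aa))
}
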