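# I/O for sequences, binding annotations, structure annotations and
# feature matrices.
#
# External files are 1-based (PDB/BioLip convention); everything inside
# the package is 0-based. Chains shorter than 50 residues are dropped at
# join time, mirroring the dataset inclusion rule.

MIN_CHAIN_LENGTH <- 50L
LIGANDS <- c("CA", "MG")

#' Construct a protein chain record
#'
#' Bundles a sequence with its per-residue binding mask and predicted
#' structure tracks and validates the type invariants (equal track
#' lengths, closed alphabet, in-range RSA and angles).
#'
#' @param chain_id chain identifier.
#' @param sequence amino-acid string over the 20 standard letters plus 'X'.
#' @param binding_mask logical vector, one entry per residue.
#' @param ss character vector over H, E, C.
#' @param rsa numeric vector in \[0, 1\].
#' @param phi,psi numeric vectors of dihedral angles in degrees,
#'   \[-180, 180\].
#' @param min_length minimum admissible chain length (default 50).
#' @return an object of class `protein_chain`.
#' @export
protein_chain <- function(chain_id, sequence, binding_mask, ss, rsa, phi,
                          psi, min_length = MIN_CHAIN_LENGTH) {
  n <- nchar(sequence)
  if (n < min_length) {
    stop_ionsite("chain ", chain_id, " has length ", n, " < ", min_length)
  }
  tokens <- strsplit(sequence, "")[[1]]
  if (!all(tokens %in% AA_LEVELS)) {
    stop_ionsite("chain ", chain_id, " contains tokens outside the ",
                 "21-letter alphabet")
  }
  lens <- c(length(binding_mask), length(ss), length(rsa), length(phi),
            length(psi))
  if (any(lens != n)) {
    stop_ionsite("chain ", chain_id,
                 ": all per-residue tracks must have length ", n)
  }
  if (!is.logical(binding_mask) || anyNA(binding_mask)) {
    stop_ionsite("chain ", chain_id, ": binding_mask must be logical")
  }
  if (!all(ss %in% c("H", "E", "C"))) {
    stop_ionsite("chain ", chain_id, ": ss labels must be in {H, E, C}")
  }
  if (any(rsa < 0 | rsa > 1)) {
    stop_ionsite("chain ", chain_id, ": rsa outside [0, 1]")
  }
  check_angle(phi, "phi")
  check_angle(psi, "psi")
  structure(
    list(chain_id = chain_id, sequence = sequence,
         binding_mask = binding_mask, ss = ss, rsa = rsa,
         phi = phi, psi = psi),
    class = "protein_chain"
  )
}

#' @export
print.protein_chain <- function(x, ...) {
  cat(sprintf("<protein_chain> %s: %d residues, %d binding\n",
              x$chain_id, nchar(x$sequence), sum(x$binding_mask)))
  invisible(x)
}

#' Read protein sequences from FASTA
#'
#' Sequences are uppercased; characters outside the 20 standard one-letter
#' codes are replaced by the unknown token 'X' with a warning.
#'
#' @param path path to a FASTA file.
#' @return a named character vector of sequences (names are chain ids,
#'   taken as the first whitespace-delimited word of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_ionsite("no such file: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop_ionsite("not a readable FASTA file: ", path,
                                     " (", conditionMessage(e), ")")
  )
  if (length(set) == 0L) stop_ionsite("FASTA file has no records: ", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  if (any(nchar(seqs) == 0L)) {
    stop_ionsite("FASTA record with empty sequence in ", path)
  }
  cleaned <- vapply(seqs, function(s) {
    tok <- strsplit(s, "")[[1]]
    bad <- !(tok %in% AA_LEVELS)
    if (any(bad)) tok[bad] <- "X"
    paste(tok, collapse = "")
  }, "")
  n_replaced <- sum(mapply(function(a, b) sum(strsplit(a, "")[[1]] !=
                                                strsplit(b, "")[[1]]),
                           seqs, cleaned))
  if (n_replaced > 0L) {
    warning(n_replaced, " non-standard residue(s) replaced by 'X'",
            call. = FALSE)
  }
  cleaned
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  invisible(path)
}

#' Read binding-site annotations
#'
#' Parses a BioLip-style tab-separated table with three columns: chain id,
#' ligand id (CA or MG) and a comma-separated list of 1-based binding
#' residue positions (possibly empty).
#'
#' @param path path to the annotation table.
#' @return a data.frame with columns `chain_id`, `ligand` and a
#'   list-column `positions` of increasing 1-based integer vectors.
#' @export
read_binding_annotations <- function(path) {
  if (!file.exists(path)) stop_ionsite("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_ionsite("empty annotation table: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) {
    stop_ionsite("annotation rows must have 3 tab-separated columns")
  }
  chain_id <- vapply(parts, `[`, "", 1L)
  ligand <- toupper(vapply(parts, `[`, "", 2L))
  bad <- setdiff(unique(ligand), LIGANDS)
  if (length(bad)) {
    stop_ionsite("unknown ligand token(s): ", paste(bad, collapse = ", "),
                 " (expected CA or MG)")
  }
  positions <- lapply(parts, function(p) {
    raw <- if (length(p) >= 3L) trimws(p[[3L]]) else ""
    if (!nzchar(raw)) return(integer(0))
    fields <- trimws(strsplit(raw, ",", fixed = TRUE)[[1]])
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals) || any(vals != as.integer(vals)) || any(vals < 1)) {
      stop_ionsite("non-integer or non-positive binding position in row '",
                   paste(p, collapse = "\t"), "'")
    }
    v <- as.integer(vals)
    if (is.unsorted(v, strictly = TRUE)) {
      stop_ionsite("binding positions must be strictly increasing")
    }
    v
  })
  out <- data.frame(chain_id = chain_id, ligand = ligand,
                    stringsAsFactors = FALSE)
  out$positions <- positions
  out
}

#' Write binding-site annotations
#'
#' @param annotations data.frame as returned by
#'   [read_binding_annotations()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_binding_annotations <- function(annotations, path) {
  pos <- vapply(annotations$positions, function(p)
    paste(p, collapse = ","), "")
  writeLines(paste(annotations$chain_id, annotations$ligand, pos,
                   sep = "\t"), path)
  invisible(path)
}

#' Read per-residue structure annotations
#'
#' Parses a tab-separated table of predicted structure values with columns
#' chain id, 1-based residue index, secondary-structure label (H/E/C),
#' relative solvent accessibility in \[0, 1\], and phi/psi angles in
#' degrees. Rows for each chain must cover residues 1..n contiguously.
#'
#' @param path path to the structure table.
#' @return a named list; each element holds `ss`, `rsa`, `phi`, `psi`
#'   vectors for one chain, ordered by residue.
#' @export
read_structure_annotations <- function(path) {
  if (!file.exists(path)) stop_ionsite("no such file: ", path)
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("chain_id", "pos", "ss", "rsa",
                                         "phi", "psi"))
  if (nrow(tab) == 0L) stop_ionsite("empty structure table: ", path)
  if (!all(tab$ss %in% c("H", "E", "C"))) {
    stop_ionsite("secondary-structure labels must be in {H, E, C}")
  }
  if (!is.numeric(tab$rsa) || any(tab$rsa < 0 | tab$rsa > 1)) {
    stop_ionsite("rsa outside [0, 1] in ", path)
  }
  check_angle(tab$phi, "phi")
  check_angle(tab$psi, "psi")
  out <- lapply(split(tab, tab$chain_id), function(d) {
    d <- d[order(d$pos), , drop = FALSE]
    if (!identical(as.integer(d$pos), seq_len(nrow(d)))) {
      stop_ionsite("chain ", d$chain_id[[1L]],
                   ": residue indices must be contiguous 1..n")
    }
    list(ss = d$ss, rsa = d$rsa, phi = d$phi, psi = d$psi)
  })
  out[unique(tab$chain_id)]
}

#' Write per-residue structure annotations
#'
#' @param structure named list of per-chain `ss`/`rsa`/`phi`/`psi` tracks.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure_annotations <- function(structure, path) {
  rows <- unlist(lapply(names(structure), function(id) {
    s <- structure[[id]]
    sprintf("%s\t%d\t%s\t%s\t%s\t%s", id, seq_along(s$ss), s$ss,
            formatC(s$rsa, digits = 17, format = "g"),
            formatC(s$phi, digits = 17, format = "g"),
            formatC(s$psi, digits = 17, format = "g"))
  }))
  writeLines(rows, path)
  invisible(path)
}

#' Join sequences, binding annotations and structure tracks into chains
#'
#' Builds [protein_chain] objects with the binding mask set from 1-based
#' annotation positions. Chains shorter than `min_length` residues are
#' dropped with a message. Annotations for the same chain (e.g. from both
#' ligands) are unioned unless `ligand` restricts them.
#'
#' @param sequences named character vector from [read_fasta()].
#' @param annotations data.frame from [read_binding_annotations()].
#' @param structure named list from [read_structure_annotations()].
#' @param ligand optional ligand filter, "CA" or "MG"; default keeps both.
#' @param min_length minimum chain length retained (default 50).
#' @return list of `protein_chain` objects.
#' @export
join_chains <- function(sequences, annotations, structure, ligand = NULL,
                        min_length = MIN_CHAIN_LENGTH) {
  if (!is.null(ligand)) {
    ligand <- match.arg(toupper(ligand), LIGANDS)
    annotations <- annotations[annotations$ligand == ligand, , drop = FALSE]
  }
  missing_seq <- setdiff(annotations$chain_id, names(sequences))
  if (length(missing_seq)) {
    stop_ionsite("annotated chain(s) missing from sequences: ",
                 paste(missing_seq, collapse = ", "))
  }
  missing_str <- setdiff(annotations$chain_id, names(structure))
  if (length(missing_str)) {
    stop_ionsite("annotated chain(s) missing from structure table: ",
                 paste(missing_str, collapse = ", "))
  }
  ids <- unique(annotations$chain_id)
  dropped <- 0L
  chains <- list()
  for (id in ids) {
    seq <- sequences[[id]]
    n <- nchar(seq)
    pos <- sort(unique(unlist(
      annotations$positions[annotations$chain_id == id])))
    if (length(pos) && max(pos) > n) {
      stop_ionsite("chain ", id, ": binding position ", max(pos),
                   " beyond chain length ", n)
    }
    if (n < min_length) {
      dropped <- dropped + 1L
      next
    }
    str <- structure[[id]]
    if (length(str$ss) != n) {
      stop_ionsite("chain ", id, ": structure table has ", length(str$ss),
                   " residues but sequence has ", n)
    }
    mask <- rep(FALSE, n)
    mask[pos] <- TRUE # 1-based file positions onto 1-based R vector
    chains[[id]] <- protein_chain(id, seq, mask, str$ss, str$rsa,
                                  str$phi, str$psi,
                                  min_length = min_length)
  }
  if (dropped > 0L) {
    message(dropped, " chain(s) shorter than ", min_length,
            " residues dropped")
  }
  chains
}

#' Write / read an encoded feature matrix
#'
#' Feature matrices are stored as tab-separated text with a header row
#' naming every feature column plus a final `label` column. Values are
#' printed with 17 significant digits, which round-trips IEEE doubles
#' exactly.
#'
#' @param path file path.
#' @param x numeric feature matrix with column names.
#' @param labels logical or 0/1 vector, one per row.
#' @return `write_feature_matrix` returns `path` invisibly;
#'   `read_feature_matrix` returns `list(x = matrix, labels = logical)`.
#' @export
write_feature_matrix <- function(path, x, labels) {
  if (is.null(dim(x))) stop_ionsite("x must be a matrix")
  if (nrow(x) != length(labels)) {
    stop_ionsite("labels length must equal nrow(x)")
  }
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("f", seq_len(ncol(x)))
  }
  header <- paste(c(colnames(x), "label"), collapse = "\t")
  if (nrow(x) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  chr <- matrix(formatC(x, digits = 17, format = "g"), nrow(x), ncol(x))
  body <- apply(cbind(chr, as.integer(labels)), 1L, paste,
                collapse = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) stop_ionsite("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stop_ionsite("empty feature-matrix file: ", path)
  cols <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  p <- length(cols) - 1L
  if (length(lines) == 1L) {
    m <- matrix(numeric(0), 0L, p, dimnames = list(NULL, cols[-(p + 1L)]))
    return(list(x = m, labels = logical(0)))
  }
  parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
  if (any(lengths(parts) != p + 1L)) {
    stop_ionsite("ragged rows in feature-matrix file: ", path)
  }
  vals <- matrix(as.numeric(unlist(parts)), ncol = p + 1L, byrow = TRUE)
  list(x = structure(vals[, seq_len(p), drop = FALSE],
                     dimnames = list(NULL, cols[seq_len(p)])),
       labels = vals[, p + 1L] != 0)
}
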