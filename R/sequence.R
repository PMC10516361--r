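# Sequence handling: FASTA IO, stitching structure-derived residues into a
# contiguous sequence, and window-contextualized extraction of residues and
# residue pairs.

AA1 <- c("A","C","D","E","F","G","H","I","K","L",
         "M","N","P","Q","R","S","T","V","W","Y","X")

# 3-letter -> 1-letter lookup built from the Biostrings code table
AA3TO1 <- local({
  m <- Biostrings::AMINO_ACID_CODE
  out <- stats::setNames(names(m), toupper(m))
  out[names(out) %in% toupper(m[AA1[AA1 != "X"]])]
})

#' Read protein sequences from FASTA
#'
#' Identifiers are taken from the header up to the first whitespace.
#' Internal whitespace inside sequence lines is removed with a warning;
#' duplicate identifiers are disambiguated by suffixing \code{.2},
#' \code{.3}, ... with a warning.
#'
#' @param path FASTA file path.
#' @return a named character vector of upper-case sequences (one element
#'   per record, in file order).
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  x <- toupper(as.character(seqs))
  if (any(grepl("[[:space:]]", x))) {
    warning("whitespace inside sequence lines removed")
    x <- gsub("[[:space:]]+", "", x)
  }
  if (any(!nzchar(x))) stop("zero-length sequence record in ", path)
  if (anyDuplicated(ids)) {
    warning("duplicate FASTA identifiers; suffixing duplicates")
    occ <- stats::ave(seq_along(ids), ids, FUN = seq_along)
    ids[occ > 1L] <- paste0(ids[occ > 1L], ".", occ[occ > 1L])
  }
  stats::setNames(x, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[k]), con)
    s <- seqs[[k]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Stitch structure-derived residues into a contiguous sequence
#'
#' Concatenates residue records in the given order, bridging crystallographic
#' numbering gaps, and returns the map from each output (sequence) position
#' back to its structure residue number.  Amino acids may be given as
#' 3-letter codes (case-insensitive) or 1-letter codes; unknown codes map to
#' \code{X} with a warning.
#'
#' @param records data.frame with columns \code{chain},
#'   \code{structure_residue_number} (or \code{resnum}) and \code{aa},
#'   ordered as in the structure.
#' @return list with \code{sequence} (character scalar) and \code{map}
#'   (data.frame: \code{pos}, \code{chain}, \code{structure_residue_number},
#'   \code{aa}).
#' @export
stitch_structure_sequence <- function(records) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("no residue records to stitch")
  num_col <- intersect(c("structure_residue_number", "resnum"),
                       names(records))[1L]
  if (is.na(num_col) || !all(c("chain", "aa") %in% names(records)))
    stop("records need columns chain, structure_residue_number (or resnum), aa")
  aa <- as.character(records$aa)
  one <- ifelse(nchar(aa) == 1L, toupper(aa), AA3TO1[toupper(aa)])
  bad <- is.na(one) | !(one %in% AA1)
  if (any(bad)) {
    warning("unknown residue code(s) mapped to X: ",
            paste(unique(aa[bad]), collapse = ", "))
    one[bad] <- "X"
  }
  map <- data.frame(pos = seq_len(nrow(records)),
                    chain = as.character(records$chain),
                    structure_residue_number = as.integer(records[[num_col]]),
                    aa = unname(one))
  list(sequence = paste(one, collapse = ""), map = map)
}

#' Extract window-contextualized residues or residue pairs
#'
#' For each target (a single residue index, or a row of a 2-column pair
#' matrix) returns the \code{2w+1} residue letters centered on each target
#' position; positions outside \code{1..L} yield the placeholder \code{'-'}
#' (distinct from the unknown-residue letter \code{X}).
#'
#' @param seq a character scalar sequence.
#' @param targets integer vector of residue indices, or a 2-column matrix
#'   of residue pairs.
#' @param w window half-width.
#' @return a data.frame with the center column(s) followed by context
#'   letter columns; for pairs, the two contexts are laid side by side
#'   (\code{p_m<w>...p_p<w>}, then \code{q_m<w>...q_p<w>}).
#' @export
extract_windowed <- function(seq, targets, w) {
  w <- check_halfwidth(w)
  stopifnot(is.character(seq), length(seq) == 1L)
  L <- nchar(seq)
  letters_ <- strsplit(seq, "")[[1L]]
  ctx <- function(center) {
    pos <- center + seq.int(-w, w)
    out <- rep("-", length(pos))
    ok <- pos >= 1L & pos <= L
    out[ok] <- letters_[pos[ok]]
    out
  }
  slot_names <- function(prefix) {
    off <- seq.int(-w, w)
    sprintf("%s%s%d", prefix, ifelse(off < 0, "m", "p"), abs(off))
  }
  if (is.matrix(targets) || is.data.frame(targets)) {
    targets <- as.matrix(targets)
    storage.mode(targets) <- "integer"
    if (ncol(targets) != 2L) stop("pair targets must have two columns")
    if (any(targets < 1L) || any(targets > L))
      stop("target out of range 1..L")
    cp <- do.call(rbind, lapply(seq_len(nrow(targets)), function(r)
      c(ctx(targets[r, 1L]), ctx(targets[r, 2L]))))
    df <- data.frame(p = targets[, 1L], q = targets[, 2L],
                     cp, stringsAsFactors = FALSE)
    names(df) <- c("p", "q", slot_names("p_"), slot_names("q_"))
  } else {
    targets <- as.integer(targets)
    if (any(is.na(targets)) || any(targets < 1L) || any(targets > L))
      stop("target out of range 1..L")
    cx <- do.call(rbind, lapply(targets, ctx))
    df <- data.frame(center = targets, cx, stringsAsFactors = FALSE)
    names(df) <- c("center", slot_names("c_"))
  }
  df
}
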