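# Structure <-> sequence residue mapping.  Experimentally resolved residues
# are often discontinuous (crystallographic gaps), so structure-derived
# numbering is reconciled with the full FASTA sequence by global
# (Needleman-Wunsch) alignment; aligned columns become map entries.

#' Map structure residue numbers to FASTA positions
#'
#' Globally aligns the structure-derived sequence against the FASTA
#' sequence (identity scoring: match +1, mismatch -1; affine gaps with
#' opening penalty 2 and extension penalty 1 per gap position) and reads
#' the correspondence off the alignment.  Both sequences derive from the
#' same protein, so no substitution matrix is used; aligned columns with
#' differing letters are still mapped but flagged as mismatches
#' (engineering artifacts such as point mutations), while gap columns go
#' to the unmapped lists.
#'
#' @param structure_seq character scalar: the stitched structure sequence.
#' @param structure_numbering integer vector of structure residue numbers,
#'   one per letter of \code{structure_seq}.
#' @param fasta_seq character scalar: the full sequence.
#' @param match,mismatch,gap_open,gap_ext alignment scores;
#'   \code{gap_open} and \code{gap_ext} are penalties (a gap of length n
#'   costs \code{gap_open + n * gap_ext}).
#' @return object of class \code{residue_map}: list with
#'   \itemize{
#'     \item \code{table}: data.frame \code{structure_number},
#'       \code{structure_aa}, \code{fasta_position}, \code{fasta_aa},
#'       \code{mismatch};
#'     \item \code{forward}: named integer vector, structure number ->
#'       FASTA position;
#'     \item \code{reverse}: named integer vector, FASTA position ->
#'       structure number;
#'     \item \code{unmapped_structure}, \code{unmapped_fasta}: integer
#'       vectors of positions aligned to gaps.
#'   }
#' @export
map_residues <- function(structure_seq, structure_numbering, fasta_seq,
                         match = 1, mismatch = -1,
                         gap_open = 2, gap_ext = 1) {
  if (!nzchar(structure_seq) || !nzchar(fasta_seq))
    stop("sequences must be non-empty")
  structure_numbering <- as.integer(structure_numbering)
  if (length(structure_numbering) != nchar(structure_seq))
    stop("structure_numbering length must equal nchar(structure_seq)")
  letters_all <- unique(strsplit(paste0(structure_seq, fasta_seq), "")[[1L]])
  submat <- matrix(mismatch, length(letters_all), length(letters_all),
                   dimnames = list(letters_all, letters_all))
  diag(submat) <- match
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::BString(structure_seq), Biostrings::BString(fasta_seq),
    type = "global", substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_ext)
  sa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  fa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  si <- cumsum(sa != "-")   # running structure index (1-based where not gap)
  fi <- cumsum(fa != "-")
  both <- sa != "-" & fa != "-"
  table <- data.frame(
    structure_number = structure_numbering[si[both]],
    structure_aa = sa[both],
    fasta_position = fi[both],
    fasta_aa = fa[both],
    mismatch = sa[both] != fa[both])
  forward <- stats::setNames(table$fasta_position,
                             table$structure_number)
  reverse <- stats::setNames(table$structure_number,
                             table$fasta_position)
  structure(list(
    table = table,
    forward = forward,
    reverse = reverse,
    unmapped_structure = structure_numbering[si[sa != "-" & fa == "-"]],
    unmapped_fasta = fi[fa != "-" & sa == "-"],
    score = Biostrings::score(aln)),
    class = "residue_map")
}

#' Write a residue map as TSV
#'
#' Four columns: structure number, structure residue, FASTA position,
#' FASTA residue; unmapped positions on either side appear with \code{'-'}
#' in the opposite columns.
#'
#' @param rm_ a \code{residue_map}.
#' @param path output path.
#' @export
write_residue_map <- function(rm_, path) {
  stopifnot(inherits(rm_, "residue_map"))
  tab <- rm_$table
  mapped <- data.frame(structure_number = as.character(tab$structure_number),
                       structure_aa = tab$structure_aa,
                       fasta_position = as.character(tab$fasta_position),
                       fasta_aa = tab$fasta_aa)
  un_s <- if (length(rm_$unmapped_structure))
    data.frame(structure_number = as.character(rm_$unmapped_structure),
               structure_aa = "-", fasta_position = "-", fasta_aa = "-")
    else NULL
  un_f <- if (length(rm_$unmapped_fasta))
    data.frame(structure_number = "-", structure_aa = "-",
               fasta_position = as.character(rm_$unmapped_fasta),
               fasta_aa = "-")
    else NULL
  out <- rbind(mapped, un_s, un_f)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @export
print.residue_map <- function(x, ...) {
  cat(sprintf(
    "residue map: %d aligned (%d mismatched), %d structure-only, %d fasta-only\n",
    nrow(x$table), sum(x$table$mismatch),
    length(x$unmapped_structure), length(x$unmapped_fasta)))
  invisible(x)
}
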