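# Cumulative correlation coefficient (cumuCC): a per-residue score built
# from the globally top-ranked residue-pair scores of a correlation matrix.
#
#   cumuCC_R = CC_R / c
#
# CC_R  : sum of the k highest pair scores (global ranking, descending)
#         restricted to the selected pairs that contain residue R;
# c     : the mean pair score, i.e. the sum of the matrix over all
#         L(L-1)/2 unordered pairs divided by that pair count;
# k     : floor(ratio * L), at least 1, capped at the pair count.

#' Cumulative correlation coefficient per residue
#'
#' Ranks all unordered residue pairs by their correlation score in
#' descending order (ties broken by ascending \code{(i, j)}), keeps the
#' top \code{k = floor(ratio * L)} pairs (at least 1, at most
#' \code{L(L-1)/2}), and scores each residue by the summed scores of the
#' selected pairs it participates in, normalized by the mean pair score
#' \code{c}.  Typical \code{ratio} values are 0.2, 0.5, 1, 1.5, 2, 5 and 10
#' (i.e. \code{k} of L/5 up to 10L).  The score is invariant under positive
#' rescaling of the matrix.
#'
#' @param cm a \code{\link{correlation_matrix}} with at least one nonzero
#'   pair (a zero mean pair score leaves the normalization undefined).
#' @param ratio positive multiplier of \code{L} setting the selection depth
#'   \code{k}.
#' @param per_residue if \code{TRUE}, select the \code{k} highest-scoring
#'   partners separately for each residue instead of globally (an opt-in
#'   variant; the global selection is the canonical one).
#' @return object of class \code{cumucc_result}: list with \code{scores}
#'   (numeric length \code{L}), \code{k_used}, \code{c}, and for the global
#'   variant \code{selected} (the chosen pairs with their scores).
#' @examples
#' cm <- correlation_matrix(4, data.frame(i = c(1, 1, 2), j = c(2, 3, 3),
#'                                        s = c(4, 3, 2)))
#' cumucc(cm, ratio = 0.5)$scores
#' @export
cumucc <- function(cm, ratio, per_residue = FALSE) {
  stopifnot(inherits(cm, "correlation_matrix"))
  if (length(ratio) != 1L || is.na(ratio) || ratio <= 0)
    stop("ratio must be a single positive number")
  L <- cm$L
  if (L < 2L) stop("cumuCC needs L >= 2")
  pr <- enumerate_pairs(L, 1L)
  s <- cm$M[pr]
  npairs <- nrow(pr)
  cc_norm <- sum(s) / npairs
  if (cc_norm == 0)
    stop("undefined normalization: the mean pair score c is 0")
  k <- min(max(1L, as.integer(floor(ratio * L))), npairs)
  if (per_residue) {
    scores <- vapply(seq_len(L), function(r) {
      mine <- cm$M[r, -r]
      kk <- min(k, length(mine))
      sum(sort(mine, decreasing = TRUE)[seq_len(kk)])
    }, numeric(1L)) / cc_norm
    return(structure(list(scores = scores, k_used = k, c = cc_norm,
                          selected = NULL, per_residue = TRUE),
                     class = "cumucc_result"))
  }
  ord <- order(-s, pr[, 1L], pr[, 2L])
  sel <- ord[seq_len(k)]
  cc <- numeric(L)
  inc <- tapply(c(s[sel], s[sel]), c(pr[sel, 1L], pr[sel, 2L]), sum)
  cc[as.integer(names(inc))] <- inc
  structure(list(scores = cc / cc_norm, k_used = k, c = cc_norm,
                 selected = data.frame(i = pr[sel, 1L], j = pr[sel, 2L],
                                       score = s[sel]),
                 per_residue = FALSE),
            class = "cumucc_result")
}

#' @export
print.cumucc_result <- function(x, ...) {
  cat(sprintf("cumuCC over %d residues: k = %d pairs %s, c = %.6g\n",
              length(x$scores), x$k_used,
              if (isTRUE(x$per_residue)) "per residue" else "selected globally",
              x$c))
  invisible(x)
}
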