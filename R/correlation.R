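# Correlation/coupling matrix container with constant-time keyed lookup.
# The matrix is stored dense (L x L numeric) so value(i, j) is a single
# subscripted read; symmetry and a zero diagonal are enforced at build time.

#' Correlation matrix container
#'
#' Wraps an \code{L x L} numeric matrix of residue-pair scores (for example
#' coevolutionary couplings).  Access is symmetric
#' (\code{value(i, j) == value(j, i)}), the diagonal is fixed at 0 and
#' absent pairs default to 0.  Negative scores are permitted.
#'
#' @param L sequence length.
#' @param pairs optional 3-column structure (i, j, score) of known pairs;
#'   may be a matrix or data.frame.  Later rows win on duplicates.
#' @return object of class \code{correlation_matrix} with fields \code{L}
#'   and \code{M} (dense symmetric matrix).
#' @export
correlation_matrix <- function(L, pairs = NULL) {
  L <- check_count(L, "L", min = 1)
  M <- matrix(0, L, L)
  if (!is.null(pairs) && NROW(pairs) > 0L) {
    pairs <- as.data.frame(pairs)
    i <- as.integer(pairs[[1L]]); j <- as.integer(pairs[[2L]])
    s <- as.numeric(pairs[[3L]])
    if (anyNA(i) || anyNA(j) || any(i < 1L) || any(j < 1L) ||
        any(i > L) || any(j > L))
      stop("pair indices must lie in 1..L")
    if (any(i == j)) stop("diagonal entries (i == j) are not allowed")
    if (anyNA(s)) stop("non-numeric score")
    M[cbind(i, j)] <- s
    M[cbind(j, i)] <- s
  }
  structure(list(L = L, M = M), class = "correlation_matrix")
}

#' Read a correlation matrix from whitespace-delimited text
#'
#' Accepts two dialects, auto-detected by column count: a minimal 3-column
#' \code{"i j score"} table, or a FreeContact/EVfold-style table
#' \code{"i aa_i j aa_j score ..."} with five or more columns, where the
#' score column is selectable (default: the fifth column).  Indices are
#' 1-based.  Rows with \code{i == j} are rejected; on duplicate \code{(i, j)}
#' rows the last one wins with a warning.
#'
#' @param path file path.
#' @param L sequence length; indices outside \code{1..L} are a format error.
#' @param score_col column holding the score; \code{NULL} selects column 3
#'   (3-column dialect) or column 5 (FreeContact dialect).
#' @return a \code{correlation_matrix}.
#' @export
load_correlation_matrix <- function(path, L, score_col = NULL) {
  L <- check_count(L, "L", min = 1)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(correlation_matrix(L))
  parts <- strsplit(lines, "[[:space:]]+")
  ncols <- unique(lengths(parts))
  if (length(ncols) != 1L)
    stop("ragged correlation file: rows differ in column count")
  if (ncols == 3L) {
    icol <- 1L; jcol <- 2L
    scol <- if (is.null(score_col)) 3L else as.integer(score_col)
  } else if (ncols >= 5L) {
    icol <- 1L; jcol <- 3L
    scol <- if (is.null(score_col)) 5L else as.integer(score_col)
  } else {
    stop("unsupported correlation dialect: ", ncols, " columns")
  }
  if (scol > ncols) stop("score_col exceeds available columns")
  fld <- function(k) vapply(parts, `[[`, character(1L), k)
  i <- suppressWarnings(as.integer(fld(icol)))
  j <- suppressWarnings(as.integer(fld(jcol)))
  s <- suppressWarnings(as.numeric(fld(scol)))
  if (anyNA(i) || anyNA(j)) stop("non-integer residue index")
  if (any(i < 1L | i > L | j < 1L | j > L))
    stop("residue index outside 1..", L)
  if (any(i == j)) stop("self-pair row (i == j) not allowed")
  key <- paste(pmin(i, j), pmax(i, j))
  if (anyDuplicated(key))
    warning("duplicate (i, j) rows in ", path, "; last occurrence wins")
  correlation_matrix(L, pairs = data.frame(i = i, j = j, s = s))
}

#' Look up pair scores
#'
#' Symmetric constant-time lookup; any index pair with an \code{NA} end
#' (a boundary placeholder) yields \code{NA}.
#'
#' @param cm a \code{correlation_matrix}.
#' @param i,j residue index vectors (recycled to common length).
#' @return numeric vector of scores.
#' @export
cm_value <- function(cm, i, j) {
  stopifnot(inherits(cm, "correlation_matrix"))
  n <- max(length(i), length(j))
  i <- rep_len(as.integer(i), n); j <- rep_len(as.integer(j), n)
  out <- rep(NA_real_, n)
  ok <- !is.na(i) & !is.na(j)
  out[ok] <- cm$M[cbind(i[ok], j[ok])]
  out
}

#' Write a correlation matrix in 3-column text form
#'
#' Emits one \code{"i j score"} line per unordered pair \code{i < j},
#' including zero entries, in ascending \code{(i, j)} order.
#'
#' @param cm a \code{correlation_matrix}.
#' @param path output path.
#' @param digits printed precision.
#' @export
write_correlation_matrix <- function(cm, path, digits = 6L) {
  stopifnot(inherits(cm, "correlation_matrix"))
  pr <- enumerate_pairs(cm$L, 1L)
  lines <- sprintf(paste0("%d\t%d\t%.", digits, "f"),
                   pr[, 1L], pr[, 2L], cm$M[pr])
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.correlation_matrix <- function(x, ...) {
  nz <- sum(x$M[upper.tri(x$M)] != 0)
  cat(sprintf("correlation matrix: L = %d, %d nonzero pairs\n", x$L, nz))
  invisible(x)
}
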