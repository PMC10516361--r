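# Feature assignment: map realized connections to correlation-matrix values.
#
# Two routes with identical contracts:
#   assign_hash         -- generates each center's connections on the fly and
#                          reads the dense matrix directly (one keyed lookup
#                          per connection; nothing corpus-wide materialized);
#   assign_materialized -- first builds the full 3D connection object
#                          (edges x centers x 2 end positions), then looks up.
# The second exists as the slower reference the first must agree with
# element-wise.

#' Assign correlation features via direct keyed lookup
#'
#' For every center (a residue pair with a bipartite template, or a single
#' residue with a unipartite template) the realized connections are generated
#' on the fly and each connection is mapped to its correlation-matrix value
#' by one constant-time subscripted read.  Out-of-range (placeholder-ended)
#' connections receive \code{placeholder_value}.  The total number of matrix
#' lookups is recorded, so scaling in the number of centers can be measured
#' by counting rather than timing; it grows linearly with the center count
#' for a fixed template.
#'
#' @param centers for a bipartite template, a 2-column matrix of residue
#'   pairs (as from \code{\link{enumerate_pairs}}); for a unipartite
#'   template, an integer vector of residue indices.
#' @param graph an \code{rrc_bipartite} or \code{rrc_unipartite} template.
#' @param cm a \code{\link{correlation_matrix}}; its \code{L} must cover
#'   every index any center can realize.
#' @param placeholder_value value given to out-of-range connections
#'   (default 0, neutral under summation).
#' @return object of class \code{rrc_features}: list with \code{centers}
#'   (data.frame of center coordinates), \code{values} (numeric matrix,
#'   one row per center, columns \code{f_000...}), \code{placeholder_value}
#'   and \code{n_lookups}.
#' @export
assign_hash <- function(centers, graph, cm, placeholder_value = 0) {
  prep <- prep_centers(centers, graph, cm)
  n <- nrow(prep$centers)
  t <- graph$t
  values <- matrix(placeholder_value, nrow = n, ncol = t)
  lookups <- 0L
  for (r in seq_len(n)) {
    conn <- realize_one(prep$centers[r, , drop = FALSE], graph, cm$L,
                        prep$kind)
    v <- cm_value(cm, conn[, 1L], conn[, 2L])
    lookups <- lookups + nrow(conn)
    v[is.na(v)] <- placeholder_value
    values[r, ] <- v
  }
  feature_table(prep$centers, values, placeholder_value, lookups)
}

#' Assign correlation features via a materialized connection object
#'
#' Identical contract to \code{\link{assign_hash}}, but first builds the
#' whole 3D connection array (template edges x centers x 2 end positions)
#' and only then performs the lookups.  Serves as the reference route that
#' the direct method must reproduce element-wise.
#'
#' @inheritParams assign_hash
#' @return an \code{rrc_features} object.
#' @export
assign_materialized <- function(centers, graph, cm, placeholder_value = 0) {
  prep <- prep_centers(centers, graph, cm)
  n <- nrow(prep$centers)
  t <- graph$t
  arr <- array(NA_integer_, dim = c(t, max(n, 0L), 2L))
  for (r in seq_len(n)) {
    conn <- realize_one(prep$centers[r, , drop = FALSE], graph, cm$L,
                        prep$kind)
    arr[, r, 1L] <- conn[, 1L]
    arr[, r, 2L] <- conn[, 2L]
  }
  values <- matrix(placeholder_value, nrow = n, ncol = t)
  lookups <- 0L
  for (r in seq_len(n)) {
    for (e in seq_len(t)) {
      v <- cm_value(cm, arr[e, r, 1L], arr[e, r, 2L])
      lookups <- lookups + 1L
      values[r, e] <- if (is.na(v)) placeholder_value else v
    }
  }
  feature_table(prep$centers, values, placeholder_value, lookups)
}

#' Write a feature table as headered TSV
#'
#' One row per center: the center coordinates followed by feature columns
#' \code{f_000...f_NNN}.
#'
#' @param ft an \code{rrc_features} object.
#' @param path output path.
#' @param digits printed precision.
#' @export
write_feature_table <- function(ft, path, digits = 6L) {
  stopifnot(inherits(ft, "rrc_features"))
  df <- cbind(ft$centers,
              as.data.frame(round(ft$values, digits)))
  names(df) <- c(names(ft$centers), colnames(ft$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @export
print.rrc_features <- function(x, ...) {
  cat(sprintf("feature table: %d centers x %d connection features (%d matrix lookups)\n",
              nrow(x$values), ncol(x$values), x$n_lookups))
  invisible(x)
}

# internal helpers -----------------------------------------------------------

feature_table <- function(centers, values, placeholder_value, n_lookups) {
  colnames(values) <- sprintf("f_%03d", seq_len(ncol(values)) - 1L)
  structure(list(centers = centers, values = values,
                 placeholder_value = placeholder_value,
                 n_lookups = n_lookups),
            class = "rrc_features")
}

prep_centers <- function(centers, graph, cm) {
  stopifnot(inherits(cm, "correlation_matrix"))
  if (inherits(graph, "rrc_bipartite")) {
    centers <- as.matrix(centers)
    if (length(centers) == 0L)
      centers <- matrix(integer(), ncol = 2L)
    if (ncol(centers) != 2L)
      stop("bipartite templates need 2-column (p, q) centers")
    storage.mode(centers) <- "integer"
    if (nrow(centers) > 0L) {
      if (anyNA(centers)) stop("NA in centers")
      if (any(centers[, 1L] >= centers[, 2L]))
        stop("centers must satisfy p < q")
      if (any(centers < 1L) || any(centers > cm$L))
        stop("center indices exceed the correlation matrix dimension L = ",
             cm$L)
    }
    list(centers = data.frame(p = centers[, 1L], q = centers[, 2L]),
         kind = "global")
  } else if (inherits(graph, "rrc_unipartite")) {
    centers <- as.integer(centers)
    if (anyNA(centers)) stop("NA in centers")
    if (length(centers) > 0L && (any(centers < 1L) || any(centers > cm$L)))
      stop("center indices exceed the correlation matrix dimension L = ",
           cm$L)
    list(centers = data.frame(center = centers), kind = "local")
  } else {
    stop("graph must be an rrc_bipartite or rrc_unipartite template")
  }
}

realize_one <- function(center_row, graph, L, kind) {
  if (kind == "global") {
    build_globrrcs(c(center_row$p, center_row$q), graph, L)$conn
  } else {
    build_locrrcs(center_row$center, graph, L)$conn
  }
}
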