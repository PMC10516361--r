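# Graph templates (bipartite and unipartite) and realized residue-residue
# connections.  All residue indices are 1-based; connections whose ends fall
# outside 1..L keep their slot but carry NA ends so that feature rows have a
# fixed width per graph.

#' Bipartite connection template
#'
#' A bipartite graph template is an ordered set of integer offset pairs
#' \code{(a, b)} relative to a central residue pair \code{(p, q)}: each offset
#' realizes the connection \code{(p + a, q + b)}.  Templates define which
#' residue pairs around a pair of interest contribute feature columns
#' (global residue-residue connections, GlobRRCs).
#'
#' @param offsets two-column integer matrix of offsets, one row per edge.
#' @param name template name, one of \code{"patch"}, \code{"memconp"},
#'   \code{"cross"}, \code{"custom"}.
#' @param distinct_ends if \code{TRUE}, a realized connection whose two ends
#'   resolve to the same residue is emitted with placeholder ends (used by
#'   the memconp template, whose edges must join two distinct residues).
#' @return an object of class \code{rrc_bipartite} with fields \code{name},
#'   \code{offsets} (ordered integer matrix) and \code{t} (edge count).
#' @export
bipartite_graph <- function(offsets, name = "custom", distinct_ends = FALSE) {
  offsets <- as.matrix(offsets)
  if (ncol(offsets) != 2L)
    stop("offsets must have two columns (a, b)")
  storage.mode(offsets) <- "integer"
  if (anyNA(offsets)) stop("offsets must be integers, no NA")
  if (anyDuplicated(paste(offsets[, 1L], offsets[, 2L])))
    stop("duplicate offsets in bipartite template")
  if (nrow(offsets) < 1L) stop("a bipartite template needs at least one edge")
  dimnames(offsets) <- list(NULL, c("a", "b"))
  structure(
    list(name = name, offsets = offsets, t = nrow(offsets),
         distinct_ends = isTRUE(distinct_ends)),
    class = c("rrc_bipartite", "rrc_graph"))
}

#' Square-patch bipartite template
#'
#' All offsets \code{(a, b)} with \code{|a| <= w} and \code{|b| <= w}: a
#' \code{(2w+1) x (2w+1)} square patch of connections centered on a residue
#' pair in contact-map context.  Offsets are ordered lexicographically by
#' \code{(a, b)} so feature columns are reproducible.
#'
#' @param w non-negative integer half-width; \code{w = 2} gives the 5 x 5
#'   patch with 25 edges.
#' @return an \code{rrc_bipartite} template with \code{t = (2w+1)^2} edges.
#' @examples
#' make_patch(2)$t  # 25
#' @export
make_patch <- function(w) {
  w <- check_halfwidth(w)
  rng <- seq.int(-w, w)
  offsets <- cbind(a = rep(rng, each = length(rng)),
                   b = rep(rng, times = length(rng)))
  bipartite_graph(offsets, name = "patch")
}

# The fixed helix-packing template: 25 offsets describing plausible
# connections between residues of two face-to-face packed helices
# (i and i+/-1, i+/-3, i+/-4 register positions), kept in its canonical
# published order.
MEMCONP_OFFSETS <- matrix(c(
   0,  0,   0,  1,   0, -1,   0,  3,   0, -3,   0,  4,   0, -4,
   1,  0,  -1,  0,   3,  0,  -3,  0,   3,  4,  -3,  4,   3, -4,
  -3, -4,   4,  0,  -4,  0,   4,  3,  -4,  3,   4, -3,  -4, -3,
   4,  4,  -4,  4,   4, -4,  -4, -4),
  ncol = 2L, byrow = TRUE, dimnames = list(NULL, c("a", "b")))

#' Helix-packing ('memconp') bipartite template
#'
#' The fixed 25-offset template modelling connections between residues of a
#' pair of membrane helices arranged face to face, as used for helix-helix
#' contact prediction.  Edges must join two distinct residues; a realized
#' connection collapsing onto a single residue is emitted with placeholder
#' ends to preserve the fixed edge count.
#'
#' @return an \code{rrc_bipartite} template with 25 edges in canonical order.
#' @export
make_memconp <- function() {
  bipartite_graph(MEMCONP_OFFSETS, name = "memconp", distinct_ends = TRUE)
}

#' Cross bipartite template
#'
#' The central row plus central column of the square patch: offsets
#' \code{(a, 0)} and \code{(0, b)} for \code{|a|, |b| <= w}, deduplicated at
#' the center, ordered lexicographically.  \code{t = 4w + 1}.
#'
#' @inheritParams make_patch
#' @return an \code{rrc_bipartite} template.
#' @export
make_cross <- function(w) {
  w <- check_halfwidth(w)
  rng <- seq.int(-w, w)
  offsets <- unique(rbind(cbind(rng, 0L), cbind(0L, rng)))
  offsets <- offsets[order(offsets[, 1L], offsets[, 2L]), , drop = FALSE]
  bipartite_graph(offsets, name = "cross")
}

#' Unipartite connection template over window slots
#'
#' A unipartite template lists edges between slots of a sliding window of
#' half-width \code{w} placed on a single residue of interest (local
#' residue-residue connections, LocRRCs).  Slots are numbered \code{0..2w},
#' slot \code{w} being the central residue.
#'
#' @param slot_edges two-column integer matrix of (slot_i, slot_j) pairs,
#'   values in \code{0..2w}; self-edges are rejected.
#' @param w window half-width the slots refer to.
#' @param name \code{"complete"} or \code{"custom"}.
#' @return an object of class \code{rrc_unipartite} with fields \code{name},
#'   \code{w}, \code{slot_edges} and \code{t}.
#' @export
unipartite_graph <- function(slot_edges, w, name = "custom") {
  w <- check_halfwidth(w)
  slot_edges <- as.matrix(slot_edges)
  if (length(slot_edges) == 0L)
    slot_edges <- matrix(integer(), ncol = 2L)
  if (ncol(slot_edges) != 2L)
    stop("slot_edges must have two columns (slot_i, slot_j)")
  storage.mode(slot_edges) <- "integer"
  if (anyNA(slot_edges)) stop("slot edges must be integers, no NA")
  if (any(slot_edges < 0L) || any(slot_edges > 2L * w))
    stop("slot coordinates must lie in 0..2w")
  if (any(slot_edges[, 1L] == slot_edges[, 2L]))
    stop("self-edges (slot_i == slot_j) are not allowed")
  if (anyDuplicated(paste(slot_edges[, 1L], slot_edges[, 2L])))
    stop("duplicate slot edges in unipartite template")
  dimnames(slot_edges) <- list(NULL, c("slot_i", "slot_j"))
  structure(
    list(name = name, w = w, slot_edges = slot_edges, t = nrow(slot_edges)),
    class = c("rrc_unipartite", "rrc_graph"))
}

#' Complete unipartite template
#'
#' All ordered pairs of distinct window slots among the \code{2w+1} slots of
#' a window of half-width \code{w}; this yields \code{(2w)(2w+1)} edges,
#' ordered by \code{(slot_i, slot_j)}.
#'
#' @inheritParams make_patch
#' @return an \code{rrc_unipartite} template.
#' @export
make_complete <- function(w) {
  w <- check_halfwidth(w)
  n <- 2L * w + 1L
  slots <- seq.int(0L, n - 1L)
  grid <- cbind(rep(slots, each = n), rep(slots, times = n))
  grid <- grid[grid[, 1L] != grid[, 2L], , drop = FALSE]
  unipartite_graph(grid, w = w, name = "complete")
}

#' Read a custom graph template from a plain-text file
#'
#' One edge per line, two whitespace-separated integers; \code{#} starts a
#' comment.  For \code{kind = "bipartite"} lines are offset pairs "a b";
#' for \code{kind = "unipartite"} lines are window-slot pairs
#' "slot_i slot_j" (requires \code{w}).
#'
#' @param path file path.
#' @param kind \code{"bipartite"} or \code{"unipartite"}.
#' @param w window half-width, required for unipartite templates.
#' @return an \code{rrc_bipartite} or \code{rrc_unipartite} template named
#'   \code{"custom"}.
#' @export
read_graph_spec <- function(path, kind = c("bipartite", "unipartite"), w = NULL) {
  kind <- match.arg(kind)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no edges in graph spec file: ", path)
  parts <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(parts) != 2L))
    stop("each edge line must carry exactly two integers")
  vals <- suppressWarnings(as.integer(unlist(parts)))
  if (anyNA(vals)) stop("non-integer edge coordinate in graph spec file")
  edges <- matrix(vals, ncol = 2L, byrow = TRUE)
  if (kind == "bipartite") {
    bipartite_graph(edges, name = "custom")
  } else {
    if (is.null(w)) stop("w is required for a unipartite graph spec")
    unipartite_graph(edges, w = w, name = "custom")
  }
}

#' Enumerate unordered residue pairs of interest
#'
#' All pairs \code{(p, q)} with \code{q - p >= min_sep}, ordered by
#' \code{(p, q)}.  At \code{min_sep = 1} the count is the closed form
#' \code{L(L-1)/2}.
#'
#' @param L sequence length, \code{>= 2}.
#' @param min_sep minimum sequence separation \code{q - p}, \code{>= 1}.
#' @return integer matrix with columns \code{p}, \code{q}.
#' @examples
#' nrow(enumerate_pairs(500))  # 124750
#' @export
enumerate_pairs <- function(L, min_sep = 1L) {
  L <- check_count(L, "L", min = 2)
  min_sep <- check_count(min_sep, "min_sep", min = 1)
  p <- rep.int(seq_len(L - min_sep), pmax(L - min_sep - seq_len(L - min_sep) + 1L, 0L))
  q <- unlist(lapply(seq_len(L - min_sep), function(i) seq.int(i + min_sep, L)),
              use.names = FALSE)
  cbind(p = as.integer(p), q = as.integer(q))
}

#' Realize global residue-residue connections (GlobRRCs) for one pair
#'
#' Applies a bipartite template to a central pair \code{(p, q)}: connection
#' \code{k} is \code{(p + a_k, q + b_k)}.  Ends outside \code{1..L} become
#' \code{NA} placeholders; the connection count always equals the template's
#' edge count, so downstream feature rows have fixed width.
#'
#' @param pair length-2 integer vector \code{c(p, q)} with \code{p < q}.
#' @param graph an \code{rrc_bipartite} template.
#' @param L sequence length.
#' @return an object of class \code{rrc_connections}: list with
#'   \code{center}, \code{kind = "global"}, \code{graph} name and
#'   \code{conn}, an integer matrix (columns \code{i}, \code{j}) with
#'   \code{NA} placeholder ends.
#' @export
build_globrrcs <- function(pair, graph, L) {
  stopifnot(inherits(graph, "rrc_bipartite"))
  L <- check_count(L, "L", min = 2)
  pair <- as.integer(pair)
  if (length(pair) != 2L || anyNA(pair))
    stop("pair must be two integers (p, q)")
  if (pair[1L] >= pair[2L]) stop("pair must satisfy p < q")
  if (pair[1L] < 1L || pair[2L] > L)
    stop("pair out of sequence range 1..L")
  i <- pair[1L] + graph$offsets[, 1L]
  j <- pair[2L] + graph$offsets[, 2L]
  i[i < 1L | i > L] <- NA_integer_
  j[j < 1L | j > L] <- NA_integer_
  if (graph$distinct_ends) {
    degen <- !is.na(i) & !is.na(j) & i == j
    i[degen] <- NA_integer_
    j[degen] <- NA_integer_
  }
  structure(list(center = pair, kind = "global", graph = graph$name,
                 conn = cbind(i = i, j = j)),
            class = "rrc_connections")
}

#' Realize local residue-residue connections (LocRRCs) for one residue
#'
#' Places a window of half-width \code{w} on a central residue; window slot
#' \code{s} maps to residue \code{center - w + s}.  Each slot edge of the
#' unipartite template becomes a connection between the two mapped residues;
#' out-of-range slots yield \code{NA} placeholder ends.  For the complete
#' template the count is \code{(2w)(2w+1)}.
#'
#' @param center residue index of interest, in \code{1..L}.
#' @param graph an \code{rrc_unipartite} template (carries \code{w}).
#' @param L sequence length.
#' @return an \code{rrc_connections} object with \code{kind = "local"}.
#' @export
build_locrrcs <- function(center, graph, L) {
  stopifnot(inherits(graph, "rrc_unipartite"))
  L <- check_count(L, "L", min = 1)
  center <- as.integer(center)
  if (length(center) != 1L || is.na(center)) stop("center must be one integer")
  if (center < 1L || center > L) stop("center out of sequence range 1..L")
  res <- center - graph$w + seq.int(0L, 2L * graph$w)  # slot -> residue
  res[res < 1L | res > L] <- NA_integer_
  conn <- cbind(i = res[graph$slot_edges[, 1L] + 1L],
                j = res[graph$slot_edges[, 2L] + 1L])
  if (nrow(graph$slot_edges) == 0L)
    conn <- matrix(integer(), ncol = 2L, dimnames = list(NULL, c("i", "j")))
  structure(list(center = center, kind = "local", graph = graph$name,
                 conn = conn),
            class = "rrc_connections")
}

#' @export
print.rrc_bipartite <- function(x, ...) {
  cat(sprintf("bipartite template '%s': %d offsets\n", x$name, x$t))
  invisible(x)
}

#' @export
print.rrc_unipartite <- function(x, ...) {
  cat(sprintf("unipartite template '%s' (w = %d): %d slot edges\n",
              x$name, x$w, x$t))
  invisible(x)
}

#' @export
print.rrc_connections <- function(x, ...) {
  cat(sprintf("%s connections for center (%s), graph '%s': %d edges, %d placeholder-ended\n",
              x$kind, paste(x$center, collapse = ","), x$graph,
              nrow(x$conn), sum(!stats::complete.cases(x$conn))))
  invisible(x)
}

# shared argument checks -----------------------------------------------------

check_halfwidth <- function(w) {
  if (length(w) != 1L || is.na(w) || w < 0 || w != as.integer(w))
    stop("w must be a single non-negative integer")
  as.integer(w)
}

check_count <- function(x, what, min) {
  if (length(x) != 1L || is.na(x) || x != as.integer(x) || x < min)
    stop(sprintf("%s must be a single integer >= %d", what, min))
  as.integer(x)
}
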