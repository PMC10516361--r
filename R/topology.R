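# Transmembrane topology: PDBTM-dialect XML parsing/writing, relabeling of
# non-membrane segments into cytoplasmic/extracellular using a predicted
# topology, per-residue encoding, and quality-control filtering.
#
# Region codes (PDBTM/TMDET style):
#   H alpha-helix  B beta-strand  C coil  I membrane-inside  L loop
#   F interfacial  U unknown      1 side1 2 side2
# Membrane-associated codes (H, B, F, I, C) pass through relabeling
# unchanged; only the side/loop/unknown codes (1, 2, L, U) are
# redistributed.

TOPO_CODES <- c(H = "alpha-helix", B = "beta-strand", C = "coil",
                I = "membrane-inside", L = "loop", F = "interfacial",
                U = "unknown", `1` = "side1", `2` = "side2")
TM_PASSTHROUGH <- c("H", "B", "F", "I", "C")
PRED_LABELS <- c("inside", "outside", "TM")

#' Parse a PDBTM-dialect topology XML file
#'
#' Expects \code{<chain id="A"><region beg="1" end="9" type="1"/>...}
#' elements (any root).  Segments are returned in document order.  An
#' unrecognized \code{type} attribute becomes code \code{U} with a warning;
#' \code{beg > end} is a format error.
#'
#' @param path XML file path.
#' @return data.frame of segments: \code{chain}, \code{beg}, \code{end},
#'   \code{code}.
#' @export
parse_topology_xml <- function(path) {
  doc <- xml2::read_xml(path)
  chains <- xml2::xml_find_all(doc, ".//chain")
  rows <- lapply(chains, function(ch) {
    id <- xml2::xml_attr(ch, "id")
    regs <- xml2::xml_find_all(ch, "./region")
    if (length(regs) == 0L) return(NULL)
    beg <- as.integer(xml2::xml_attr(regs, "beg"))
    end <- as.integer(xml2::xml_attr(regs, "end"))
    type <- xml2::xml_attr(regs, "type")
    if (anyNA(beg) || anyNA(end))
      stop("region without integer beg/end attribute in ", path)
    if (any(beg > end))
      stop("region with beg > end in ", path)
    unknown <- !(type %in% names(TOPO_CODES))
    if (any(unknown)) {
      warning("unknown region type(s) ",
              paste(unique(type[unknown]), collapse = ", "),
              " mapped to code U")
      type[unknown] <- "U"
    }
    data.frame(chain = id, beg = beg, end = end, code = type)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L)
    return(data.frame(chain = character(), beg = integer(),
                      end = integer(), code = character()))
  do.call(rbind, rows)
}

#' Write topology segments as PDBTM-dialect XML
#'
#' Emits the same dialect \code{\link{parse_topology_xml}} reads, so a
#' write/parse round trip reproduces the segment table.
#'
#' @param segments data.frame with \code{chain}, \code{beg}, \code{end},
#'   \code{code}.
#' @param path output path.
#' @export
write_topology_xml <- function(segments, path) {
  segments <- as.data.frame(segments)
  doc <- xml2::xml_new_root("topology")
  for (id in unique(segments$chain)) {
    ch <- xml2::xml_add_child(doc, "chain", id = id)
    sub <- segments[segments$chain == id, , drop = FALSE]
    for (r in seq_len(nrow(sub)))
      xml2::xml_add_child(ch, "region",
                          beg = as.character(sub$beg[r]),
                          end = as.character(sub$end[r]),
                          type = as.character(sub$code[r]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a predicted-topology segment table
#'
#' Three whitespace-separated columns per line: \code{beg end label}, with
#' \code{label} in \code{inside}, \code{outside}, \code{TM}.  Segments must
#' be ascending and non-overlapping.
#'
#' @param path file path.
#' @return data.frame: \code{beg}, \code{end}, \code{label}.
#' @export
read_predicted_topology <- function(path) {
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("beg", "end", "label"),
                          stringsAsFactors = FALSE)
  validate_predicted(df)
}

validate_predicted <- function(df) {
  df <- as.data.frame(df)
  names(df)[1:3] <- c("beg", "end", "label")
  df$beg <- as.integer(df$beg); df$end <- as.integer(df$end)
  if (anyNA(df$beg) || anyNA(df$end) || any(df$beg > df$end))
    stop("predicted topology needs integer beg <= end")
  if (!all(df$label %in% PRED_LABELS))
    stop("predicted labels must be one of: ",
         paste(PRED_LABELS, collapse = ", "))
  if (nrow(df) > 1L &&
      any(df$beg[-1L] <= df$end[-nrow(df)]))
    stop("predicted segments must be ascending and non-overlapping")
  df
}

#' Relabel non-membrane topology segments by a predicted topology
#'
#' Structure-derived topologies locate membrane-spanning segments but do not
#' say which side of the membrane a non-membrane segment lies on.  This
#' stacks each non-membrane segment (codes \code{1}, \code{2}, \code{L},
#' \code{U}) against an externally predicted inside/outside/TM topology and
#' relabels it \code{cytoplasmic} or \code{extracellular} according to the
#' predicted label covering the majority of its residues.  Membrane and
#' membrane-adjacent codes (\code{H}, \code{B}, \code{F}, \code{I},
#' \code{C}) pass through unchanged.  A residue-count tie, or no overlap
#' with any inside/outside segment, gives \code{unknown}.  Segment
#' boundaries are never altered.
#'
#' @param segments data.frame as from \code{\link{parse_topology_xml}}
#'   (single chain or multiple; numbering shared with \code{predicted}).
#' @param predicted data.frame as from
#'   \code{\link{read_predicted_topology}}.
#' @return the segment data.frame with \code{code} replaced by
#'   \code{cytoplasmic}/\code{extracellular}/\code{unknown} on relabeled
#'   rows.
#' @export
redistribute_nontm <- function(segments, predicted) {
  segments <- as.data.frame(segments)
  predicted <- validate_predicted(predicted)
  relabel <- !(segments$code %in% TM_PASSTHROUGH)
  for (r in which(relabel)) {
    res <- seq.int(segments$beg[r], segments$end[r])
    n_in <- 0L; n_out <- 0L
    for (p in seq_len(nrow(predicted))) {
      ov <- sum(res >= predicted$beg[p] & res <= predicted$end[p])
      if (predicted$label[p] == "inside")  n_in  <- n_in  + ov
      if (predicted$label[p] == "outside") n_out <- n_out + ov
    }
    segments$code[r] <-
      if (n_in > n_out) "cytoplasmic"
      else if (n_out > n_in) "extracellular"
      else "unknown"
  }
  segments
}

#' Encode topology as a per-residue label vector
#'
#' Each residue takes the code of its covering segment; uncovered residues
#' are \code{U}.  When segments overlap, the one later in document order
#' wins, with a warning.
#'
#' @param segments data.frame with \code{beg}, \code{end}, \code{code}
#'   (one chain).
#' @param L sequence length.
#' @return character vector of codes, length \code{L}.
#' @export
per_residue_topology <- function(segments, L) {
  L <- check_count(L, "L", min = 1)
  segments <- as.data.frame(segments)
  out <- rep("U", L)
  if (nrow(segments) == 0L) return(out)
  if (any(segments$beg < 1L) || any(segments$end > L))
    stop("segment outside 1..L")
  covered <- logical(L)
  overlapped <- FALSE
  for (r in seq_len(nrow(segments))) {
    idx <- seq.int(segments$beg[r], segments$end[r])
    if (any(covered[idx])) overlapped <- TRUE
    covered[idx] <- TRUE
    out[idx] <- segments$code[r]
  }
  if (overlapped)
    warning("overlapping segments: last in document order wins")
  out
}

# ---------------------------------------------------------------------------
# Quality control

#' Quality-control filter for structure records
#'
#' Applies per-record criteria on experimentation method, resolution,
#' sequence length, transmembrane-helix count and helix lengths.  A record
#' passes iff it satisfies every criterion that is set; a record missing a
#' field tested by a set criterion fails with reason
#' \code{"missing:<field>"}.  Adding a criterion can only shrink the
#' passing set.
#'
#' @param records data.frame with columns among \code{identifier},
#'   \code{method}, \code{resolution} (Angstrom, NA if not applicable),
#'   \code{length}, \code{tm_helix_count}, \code{tm_helix_lengths}
#'   (semicolon-joined integers).
#' @param criteria named list; recognized entries: \code{methods}
#'   (character vector of allowed methods), \code{max_resolution},
#'   \code{min_length}, \code{max_length}, \code{min_helices},
#'   \code{max_helices}, \code{min_helix_length},
#'   \code{max_helix_length}.  Unset entries are not tested.
#' @return list with \code{pass} (logical vector), \code{passing}
#'   (subset of records), and \code{reasons} (character vector,
#'   semicolon-joined violated criteria, \code{""} for passers).
#' @export
qc_filter <- function(records, criteria = list()) {
  records <- as.data.frame(records)
  known <- c("methods", "max_resolution", "min_length", "max_length",
             "min_helices", "max_helices", "min_helix_length",
             "max_helix_length")
  extra <- setdiff(names(criteria), known)
  if (length(extra)) stop("unknown criteria: ", paste(extra, collapse = ", "))
  chk_minmax <- function(lo, hi, what) {
    if (!is.null(criteria[[lo]]) && !is.null(criteria[[hi]]) &&
        criteria[[lo]] > criteria[[hi]])
      stop("contradictory criteria: ", lo, " > ", hi)
  }
  chk_minmax("min_length", "max_length")
  chk_minmax("min_helices", "max_helices")
  chk_minmax("min_helix_length", "max_helix_length")

  n <- nrow(records)
  reasons <- vector("list", n)
  need <- function(field, r) {
    # returns the value, or records the missing-field reason and NULL
    val <- if (field %in% names(records)) records[[field]][r] else NA
    if (length(val) == 0L || all(is.na(val))) {
      reasons[[r]] <<- c(reasons[[r]], paste0("missing:", field))
      return(NULL)
    }
    val
  }
  for (r in seq_len(n)) {
    if (!is.null(criteria$methods)) {
      v <- need("method", r)
      if (!is.null(v) && !(v %in% criteria$methods))
        reasons[[r]] <- c(reasons[[r]], "method")
    }
    if (!is.null(criteria$max_resolution)) {
      v <- need("resolution", r)
      if (!is.null(v) && v > criteria$max_resolution)
        reasons[[r]] <- c(reasons[[r]], "resolution")
    }
    if (!is.null(criteria$min_length) || !is.null(criteria$max_length)) {
      v <- need("length", r)
      if (!is.null(v) &&
          ((!is.null(criteria$min_length) && v < criteria$min_length) ||
           (!is.null(criteria$max_length) && v > criteria$max_length)))
        reasons[[r]] <- c(reasons[[r]], "length")
    }
    if (!is.null(criteria$min_helices) || !is.null(criteria$max_helices)) {
      v <- need("tm_helix_count", r)
      if (!is.null(v) &&
          ((!is.null(criteria$min_helices) && v < criteria$min_helices) ||
           (!is.null(criteria$max_helices) && v > criteria$max_helices)))
        reasons[[r]] <- c(reasons[[r]], "tm_helix_count")
    }
    if (!is.null(criteria$min_helix_length) ||
        !is.null(criteria$max_helix_length)) {
      v <- need("tm_helix_lengths", r)
      if (!is.null(v)) {
        lens <- as.integer(strsplit(as.character(v), ";")[[1L]])
        if ((!is.null(criteria$min_helix_length) &&
             any(lens < criteria$min_helix_length)) ||
            (!is.null(criteria$max_helix_length) &&
             any(lens > criteria$max_helix_length)))
          reasons[[r]] <- c(reasons[[r]], "tm_helix_length")
      }
    }
  }
  reason_str <- vapply(reasons, function(x)
    paste(unique(x), collapse = ";"), character(1L))
  pass <- !nzchar(reason_str)
  list(pass = pass, passing = records[pass, , drop = FALSE],
       reasons = reason_str)
}

#' Read QC criteria from a key-value config file
#'
#' A flat YAML mapping, e.g. \code{max_resolution: 3.0} and
#' \code{methods: [X-ray, EM]}.
#'
#' @param path config file path.
#' @return named list usable as \code{criteria} in \code{\link{qc_filter}}.
#' @export
read_qc_criteria <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("QC config must be a key-value mapping")
  cfg
}

#' Write QC results as TSV
#'
#' One row per record: identifier, pass flag, semicolon-joined reasons.
#'
#' @param records the records passed to \code{\link{qc_filter}}.
#' @param result the list returned by \code{\link{qc_filter}}.
#' @param path output path.
#' @export
write_qc_results <- function(records, result, path) {
  df <- data.frame(identifier = if ("identifier" %in% names(records))
                     records$identifier else seq_len(nrow(records)),
                   pass = result$pass, reasons = result$reasons)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
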