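# Seeded synthetic-fixture generator: produces a self-contained bundle of
# FASTA sequences, per-protein correlation matrices, topology XML, predicted
# topology tables and a QC metadata table, so every module is exercisable
# offline.  Regeneration with the same seed is byte-identical.

#' Generate a synthetic fixture bundle
#'
#' Writes, into \code{dir}:
#' \itemize{
#'   \item \code{sequences.fasta} — \code{n_proteins} random sequences of
#'     length \code{L} over the 20 canonical amino acids;
#'   \item \code{<id>.cor} — per-protein symmetric correlation matrices with
#'     independent uniform(0, 1) pair scores, with \code{n_spiked} randomly
#'     chosen "contact" pairs shifted upward by \code{spike} (emulating the
#'     high-coupling tail of coevolutionary matrices);
#'   \item \code{topology.xml} — one chain per protein with alternating
#'     side1 / TM-helix / side2 segments covering \code{1..L};
#'   \item \code{predicted_<id>.tsv} — an inside/outside/TM segment table
#'     agreeing with the XML (side1 = inside, side2 = outside) except that
#'     each non-TM predicted label is flipped independently with probability
#'     \code{corruption_rate};
#'   \item \code{qc.tsv} — randomized method/resolution/helix-count records;
#'   \item \code{manifest.yaml} — the seed and all generator parameters.
#' }
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed governing all randomness in the bundle.
#' @param L sequence length, \code{>= 10}.
#' @param n_proteins number of proteins.
#' @param n_spiked spiked high-scoring pairs per protein.
#' @param spike additive shift applied to spiked pair scores.
#' @param corruption_rate probability of flipping each predicted non-TM
#'   segment label.
#' @param n_qc rows in the QC metadata table.
#' @return invisibly, a list of the file paths plus the parsed manifest.
#' @export
generate_fixtures <- function(dir, seed, L = 60L, n_proteins = 2L,
                              n_spiked = 10L, spike = 1,
                              corruption_rate = 0, n_qc = 12L) {
  L <- check_count(L, "L", min = 10)
  n_proteins <- check_count(n_proteins, "n_proteins", min = 1)
  if (corruption_rate < 0 || corruption_rate > 1)
    stop("corruption_rate must lie in [0, 1]")
  if (n_spiked < 0 || n_spiked > L * (L - 1) / 2)
    stop("n_spiked must lie in 0..L(L-1)/2")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  aa20 <- AA1[AA1 != "X"]
  ids <- sprintf("synthetic_%02d", seq_len(n_proteins))
  seqs <- vapply(ids, function(id)
    paste(sample(aa20, L, replace = TRUE), collapse = ""), character(1L))
  fasta_path <- file.path(dir, "sequences.fasta")
  write_fasta(seqs, fasta_path)

  cor_paths <- character(n_proteins)
  for (k in seq_len(n_proteins)) {
    pr <- enumerate_pairs(L, 1L)
    s <- stats::runif(nrow(pr))
    if (n_spiked > 0L) {
      hit <- sample.int(nrow(pr), n_spiked)
      s[hit] <- s[hit] + spike
    }
    cm <- correlation_matrix(L, data.frame(i = pr[, 1L], j = pr[, 2L], s = s))
    cor_paths[k] <- file.path(dir, paste0(ids[k], ".cor"))
    write_correlation_matrix(cm, cor_paths[k])
  }

  # topology: side1 | H | side2 | H | side1 ... covering 1..L
  topo <- NULL
  pred_paths <- character(n_proteins)
  for (k in seq_len(n_proteins)) {
    segs <- alternating_topology(L)
    segs$chain <- LETTERS[k]
    topo <- rbind(topo, segs[, c("chain", "beg", "end", "code")])
    pred <- data.frame(
      beg = segs$beg, end = segs$end,
      label = c(`1` = "inside", `2` = "outside", H = "TM")[segs$code])
    flip <- pred$label != "TM" & stats::runif(nrow(pred)) < corruption_rate
    pred$label[flip] <- ifelse(pred$label[flip] == "inside",
                               "outside", "inside")
    pred_paths[k] <- file.path(dir, paste0("predicted_", ids[k], ".tsv"))
    utils::write.table(pred, pred_paths[k], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  topo_path <- file.path(dir, "topology.xml")
  write_topology_xml(topo, topo_path)

  qc <- data.frame(
    identifier = sprintf("qc_%03d", seq_len(n_qc)),
    method = sample(c("X-ray", "NMR", "EM"), n_qc, replace = TRUE),
    resolution = round(stats::runif(n_qc, 1.2, 4.5), 2L),
    length = sample(80:900, n_qc, replace = TRUE),
    tm_helix_count = sample(0:14, n_qc, replace = TRUE))
  qc$resolution[qc$method == "NMR"] <- NA
  qc$tm_helix_lengths <- vapply(qc$tm_helix_count, function(h)
    paste(sample(12:35, h, replace = TRUE), collapse = ";"), character(1L))
  qc_path <- file.path(dir, "qc.tsv")
  utils::write.table(qc, qc_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")

  manifest <- list(seed = seed, L = L, n_proteins = n_proteins,
                   n_spiked = n_spiked, spike = spike,
                   corruption_rate = corruption_rate, n_qc = n_qc,
                   ids = as.list(ids))
  manifest_path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)

  invisible(list(fasta = fasta_path, correlation = cor_paths,
                 topology = topo_path, predicted = pred_paths,
                 qc = qc_path, manifest = manifest_path,
                 parameters = manifest))
}

# Deterministic segment layout: repeat [side1, helix, side2, helix] blocks
# with fixed lengths until L is covered; the trailing partial segment keeps
# its scheduled code.
alternating_topology <- function(L) {
  codes <- c("1", "H", "2", "H")
  lens <- c(9L, 21L, 9L, 21L)
  beg <- integer(); end <- integer(); code <- character()
  pos <- 1L; k <- 0L
  while (pos <= L) {
    cyc <- k %% 4L + 1L
    e <- min(pos + lens[cyc] - 1L, L)
    beg <- c(beg, pos); end <- c(end, e); code <- c(code, codes[cyc])
    pos <- e + 1L; k <- k + 1L
  }
  data.frame(beg = beg, end = end, code = code)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
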