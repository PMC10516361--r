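# Brute-force oracles kept independent of the package's construction code:
# plain double loops over offsets/slots/pairs.

brute_patch_offsets <- function(w) {
  out <- NULL
  for (a in -w:w) for (b in -w:w) out <- rbind(out, c(a, b))
  out
}

brute_cross_offsets <- function(w) {
  out <- NULL
  for (a in -w:w) for (b in -w:w)
    if (a == 0 || b == 0) out <- rbind(out, c(a, b))
  out
}

brute_pairs <- function(L, min_sep = 1) {
  out <- NULL
  for (p in 1:(L - 1)) for (q in (p + 1):L)
    if (q - p >= min_sep) out <- rbind(out, c(p, q))
  out
}

brute_complete_slot_pairs <- function(w) {
  n <- 2 * w + 1
  out <- NULL
  for (i in 0:(n - 1)) for (j in 0:(n - 1))
    if (i != j) out <- rbind(out, c(i, j))
  if (is.null(out)) matrix(integer(), ncol = 2) else out
}

# uniform random correlation matrix over L residues
random_cm <- function(L, seed) {
  set.seed(seed)
  pr <- enumerate_pairs(L, 1)
  correlation_matrix(L, data.frame(i = pr[, 1], j = pr[, 2],
                                   s = runif(nrow(pr))))
}

random_seq <- function(L) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y"),
               L, replace = TRUE), collapse = "")
}

# Build a "structure" sequence by deleting up to n_del random substrings,
# returning the surviving original positions.  Deletions are resampled so
# that (a) the letter entering a gap never equals the letter leaving it,
# and (b) gaps are separated by at least 12 kept residues: either condition
# failing lets the optimal alignment shift score-neutrally under identity
# scoring, so "the original position" of a surviving residue would not be
# well defined.
delete_substrings <- function(seq, n_del, margin = 12L) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  keep <- rep(TRUE, L)
  for (d in seq_len(n_del)) {
    for (try in 1:200) {
      len <- sample(1:8, 1)
      lo <- margin + 1L
      hi <- L - len - margin
      if (hi < lo) break
      start <- sample(lo:hi, 1)
      idx <- start:(start + len - 1)
      guard <- max(1, start - margin):min(L, start + len - 1 + margin)
      slide_right <- ch[start] == ch[start + len]
      slide_left <- ch[start - 1] == ch[start + len - 1]
      if (!slide_right && !slide_left && all(keep[guard])) {
        keep[idx] <- FALSE
        break
      }
    }
  }
  list(seq = paste(ch[keep], collapse = ""),
       positions = which(keep))
}

# every graph family exercised by the equivalence checks
graph_menagerie <- function() {
  c(lapply(1:3, make_patch),
    list(make_memconp()),
    lapply(1:3, make_cross),
    lapply(1:3, make_complete))
}
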