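# Independent brute-force oracles used to cross-check package operations.
# These deliberately share no code with the implementations they verify.

# IUPAC code -> allowed bases
iupac_bases <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

revcomp_chr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
            S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
            D = "H", H = "D", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# naive sliding-window scan of one motif over one sequence, one strand
naive_scan_one <- function(seq, motif, max_mismatch) {
  s <- strsplit(seq, "")[[1]]
  m <- strsplit(motif, "")[[1]]
  L <- length(m); n <- length(s)
  if (n < L) return(integer())
  hits <- integer()
  for (p in 0:(n - L)) {
    mism <- 0L
    for (j in seq_len(L))
      if (!(s[p + j] %in% iupac_bases[[m[j]]])) mism <- mism + 1L
    if (mism <= max_mismatch) hits <- c(hits, p)
  }
  hits
}

# full naive scan matching the scan_promoters output contract
naive_scan <- function(seqs, motifs, max_mismatch = 0L,
                       both_strands = TRUE) {
  rows <- list()
  for (tf in names(motifs)) for (m in names(seqs)) {
    for (p in naive_scan_one(seqs[[m]], motifs[[tf]], max_mismatch))
      rows[[length(rows) + 1L]] <- data.frame(
        tf = tf, mirna = m, position = p, strand = "+",
        stringsAsFactors = FALSE)
    if (both_strands)
      for (p in naive_scan_one(seqs[[m]], revcomp_chr(motifs[[tf]]),
                               max_mismatch))
        rows[[length(rows) + 1L]] <- data.frame(
          tf = tf, mirna = m, position = p, strand = "-",
          stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tf = character(), mirna = character(),
               position = integer(), strand = character())
  out[order(out$mirna, out$position, out$strand, out$tf), , drop = FALSE]
}

# hand step-up FDR, written from the definition
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# exhaustive hypergeometric upper tail by enumerating all draws
enum_hyper_tail <- function(N, K, n, count) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # successes are items 1..K
  mean(hits >= count)
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# tiny two-stage design for unit tests
toy_design <- function(n_per = 3L) {
  stage_design(c("normal", "tumor"),
               stats::setNames(rep(c("normal", "tumor"), each = n_per),
                               c(paste0("n", seq_len(n_per)),
                                 paste0("t", seq_len(n_per)))))
}

toy_matrix <- function(values, samples, kind = "miRNA") {
  expression_matrix(matrix(values, nrow = length(values) / length(samples),
                           byrow = TRUE,
                           dimnames = list(
                             paste0("f", seq_len(length(values) /
                                                   length(samples))),
                             samples)), kind)
}
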