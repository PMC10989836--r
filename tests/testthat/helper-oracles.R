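# Independent brute-force oracles used to check the package's fast paths.
# They share no code with the implementation beyond base R.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A")

# Full expansion by recursive cartesian product.
oracle_expand <- function(primer) {
  sets <- ORACLE_IUPAC[strsplit(primer, "")[[1]]]
  out <- ""
  for (s in sets) out <- as.vector(outer(out, s, paste0))
  out
}

# Y-distance by explicit membership of the target base in the expanded
# symbol set, position by position.
oracle_y <- function(primer, target) {
  p <- strsplit(primer, "")[[1]]
  t <- strsplit(target, "")[[1]]
  which(vapply(seq_along(p), function(i)
    !all(ORACLE_IUPAC[[t[i]]] %in% ORACLE_IUPAC[[p[i]]]), logical(1)))
}

# Coverage by expansion matching: a row is covered iff some expansion
# member is within max_mismatch literal mismatches of it, none of which
# fall in the protected 3' tail.
oracle_coverage <- function(primer, rows, max_mismatch, protect) {
  members <- oracle_expand(primer)
  L <- nchar(primer)
  ok <- vapply(rows, function(r) {
    rch <- strsplit(r, "")[[1]]
    any(vapply(members, function(m) {
      d <- which(strsplit(m, "")[[1]] != rch)
      length(d) <= max_mismatch && !any(d > L - protect)
    }, logical(1)))
  }, logical(1))
  mean(ok)
}

# Best Viterbi score by enumerating all 4^L base paths.
oracle_best_path <- function(freq, nn) {
  L <- nrow(freq)
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(rep(list(1:4), L))
  best <- -Inf; best_seq <- NULL
  for (i in seq_len(nrow(grid))) {
    path <- as.integer(grid[i, ])
    sc <- sum(log(freq[cbind(1:L, path)] + 1))
    if (L > 1) for (j in 2:L) sc <- sc + log(nn[j - 1, path[j - 1], path[j]] + 1)
    if (sc > best + 1e-12) { best <- sc; best_seq <- path }
  }
  list(score = best, seq = paste(bases[best_seq], collapse = ""))
}

# All maximal antiparallel complementary runs >= min_run between plain x
# and y by direct pairing geometry (x[i+t] pairs y[j-t]).
oracle_dimer <- function(x, y, min_run) {
  cx <- strsplit(x, "")[[1]]; cy <- strsplit(y, "")[[1]]
  n <- length(cx); m <- length(cy)
  res <- list()
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (ORACLE_COMP[cx[i]] != cy[j]) next
    # maximal: no extension backwards
    if (i > 1 && j < m && ORACLE_COMP[cx[i - 1]] == cy[j + 1]) next
    len <- 0
    while (i + len <= n && j - len >= 1 &&
           ORACLE_COMP[cx[i + len]] == cy[j - len]) len <- len + 1
    if (len < min_run) next
    run <- cx[i:(i + len - 1)]
    res[[length(res) + 1]] <- data.frame(
      run_length = len, gc_count = sum(run %in% c("G", "C")),
      distance1 = n - (i + len - 1), distance2 = m - j)
  }
  if (length(res)) unique(do.call(rbind, res)) else
    data.frame(run_length = integer(0), gc_count = integer(0),
               distance1 = integer(0), distance2 = integer(0))
}

# Naive k-mer position scan of a text.
oracle_kmer_positions <- function(text, kmer) {
  k <- nchar(kmer); n <- nchar(text)
  if (n < k) return(integer(0))
  which(substring(text, 1:(n - k + 1), k:n) == kmer)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

random_primer <- function(n, n_degenerate = 2) {
  ch <- strsplit(random_dna(n), "")[[1]]
  pos <- sample(n, n_degenerate)
  ch[pos] <- sample(c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N"),
                    n_degenerate, replace = TRUE)
  paste(ch, collapse = "")
}
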