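# Nearest-neighbour degenerate primer design: frequency and NN count
# matrices, the Viterbi optimal base path, mismatch-tolerant coverage, and
# the greedy degeneracy-expansion loop.

.BASES <- c("A", "C", "G", "T")

#' Frequency and nearest-neighbour count matrices of a window
#'
#' Rows containing non-ACGT characters are excluded from both matrices
#' (their number is reported in attribute \code{n_excluded}).
#'
#' @param rows Character vector of equal-length plain sequences.
#' @return List with \code{freq} (L x 4 base counts), \code{nn} (array
#'   (L-1) x 4 x 4 of adjacent dinucleotide counts, previous base in dim 2)
#'   and \code{n} (number of contributing rows).
#' @export
build_matrices <- function(rows) {
  stopifnot(length(rows) >= 1)
  plain <- grepl("^[ACGT]+$", rows)
  n_excluded <- sum(!plain)
  rows <- rows[plain]
  if (!length(rows))
    stop("all rows contain ambiguous characters; window rejected",
         call. = FALSE)
  L <- nchar(rows[1])
  stopifnot(all(nchar(rows) == L))
  m <- do.call(rbind, strsplit(rows, ""))
  freq <- matrix(0L, L, 4, dimnames = list(NULL, .BASES))
  for (j in seq_len(L)) {
    tb <- table(factor(m[, j], levels = .BASES))
    freq[j, ] <- as.integer(tb)
  }
  nn <- array(0L, dim = c(max(L - 1L, 0L), 4, 4),
              dimnames = list(NULL, .BASES, .BASES))
  if (L > 1) for (j in seq_len(L - 1L)) {
    tb <- table(factor(m[, j], levels = .BASES),
                factor(m[, j + 1L], levels = .BASES))
    nn[j, , ] <- as.integer(tb)
  }
  structure(list(freq = freq, nn = nn, n = length(rows)),
            n_excluded = n_excluded)
}

#' Viterbi optimal primer path
#'
#' Finds the plain base path maximizing
#' \deqn{\sum_i \log(freq_i(b_i)+1) + \sum_i \log(nn_i(b_{i-1},b_i)+1)}
#' by dynamic programming; both the per-position base frequencies and the
#' weights between nearest-neighbour bases contribute.  Ties are broken
#' toward the lexicographically smaller base.
#'
#' @param mats List from [build_matrices()] (or separate \code{freq} /
#'   \code{nn} via the \code{nn} argument).
#' @param nn Optional NN array when \code{mats} is a frequency matrix.
#' @return Character scalar: the optimal plain sequence.
#' @export
viterbi_optimal <- function(mats, nn = NULL) {
  if (is.list(mats)) { freq <- mats$freq; nn <- mats$nn } else freq <- mats
  L <- nrow(freq)
  sc_f <- log(freq + 1)
  V <- matrix(-Inf, L, 4)
  back <- matrix(0L, L, 4)
  V[1, ] <- sc_f[1, ]
  if (L > 1) for (j in 2:L) {
    sc_nn <- log(nn[j - 1L, , ] + 1)   # prev x cur
    for (b in 1:4) {
      tot <- V[j - 1L, ] + sc_nn[, b]
      best <- which.max(tot)           # first (lexicographically smallest)
      V[j, b] <- tot[best] + sc_f[j, b]
      back[j, b] <- best
    }
  }
  path <- integer(L)
  path[L] <- which.max(V[L, ])
  if (L > 1) for (j in L:2) path[j - 1L] <- back[j, path[j]]
  paste(.BASES[path], collapse = "")
}

#' Coverage of a degenerate primer with mismatch tolerance
#'
#' A row is covered iff its Y-distance from the primer passes
#' [accept_mismatches()] under the given mismatch budget and 3'-protection.
#'
#' @param primer Character scalar over the IUPAC alphabet.
#' @param rows Character vector of plain sequences, same length as the
#'   primer.
#' @param max_mismatch Mismatch budget (0-2).
#' @param protect_3prime Protected 3'-terminal bases (0 disables).
#' @return List with \code{fraction}, \code{covered} (named logical),
#'   \code{mismatches} (per-row Y-distance length) and \code{strata}
#'   (list of covered row names by exact mismatch count 0..max_mismatch).
#' @export
coverage_with_errors <- function(primer, rows, max_mismatch = 1L,
                                 protect_3prime = 4L) {
  stopifnot(length(rows) >= 1)
  L <- nchar(primer)
  stopifnot(all(nchar(rows) == L))
  pidx <- .encode_seq(.normalize_seq(primer, "primer"))
  M <- .encode_rows(rows)
  cov <- .coverage_enc(pidx, M, max_mismatch, protect_3prime)
  names(cov$covered) <- rownames(M)
  strata <- lapply(0:max_mismatch, function(k)
    rownames(M)[cov$covered & cov$mism == k])
  names(strata) <- as.character(0:max_mismatch)
  list(fraction = mean(cov$covered), covered = cov$covered,
       mismatches = cov$mism, strata = strata)
}

# Fast inner coverage on encoded inputs (pidx: primer symbol indices,
# M: n x L matrix of target symbol indices).
.coverage_enc <- function(pidx, M, max_mismatch, protect_3prime) {
  L <- length(pidx)
  n <- nrow(M)
  mism <- matrix(FALSE, n, L)
  for (j in seq_len(L))
    mism[, j] <- !.IUPAC_CONTAIN[pidx[j], M[, j]]
  counts <- rowSums(mism)
  ok <- counts <= max_mismatch
  if (protect_3prime > 0) {
    prot <- (L - protect_3prime + 1L):L
    ok <- ok & rowSums(mism[, prot, drop = FALSE]) == 0L
  }
  list(covered = ok, mism = counts)
}

# Convert a per-position bitmask vector (A=1,G=2,C=4,T=8) to an IUPAC string.
.mask_to_primer <- function(mask) paste(.MASK_SYMBOL[mask], collapse = "")

#' Design degenerate primers for a window
#'
#' Starting from two seeds -- the most frequent window variant and the
#' Viterbi optimal path (when different) -- the primer is expanded
#' greedily: at each step the single (position, base) addition with the
#' largest gain in mismatch-tolerant coverage is merged into the code
#' (ties: smaller degeneracy increase, then the 5'-most position, then
#' alphabetical base).  Expansion stops when coverage reaches
#' \code{coverage_target}, when any further addition would exceed
#' \code{max_degeneracy}, or when no addition gains coverage.  All primers
#' visited on either path are pooled and the Pareto-best (coverage
#' descending, degeneracy ascending) are returned.
#'
#' @param rows Character vector of equal-length plain sequences (the
#'   window's surviving rows).
#' @param max_mismatch Mismatch budget for coverage (0-2).
#' @param protect_3prime Protected 3'-terminal bases.
#' @param coverage_target Stop once coverage-with-errors reaches this.
#' @param max_degeneracy Hard cap on primer degeneracy.
#' @return List of candidates ordered by (coverage desc, degeneracy asc);
#'   each has \code{primer}, \code{coverage}, \code{degeneracy},
#'   \code{strata} and \code{seed} ("frequent" or "viterbi").
#' @export
design_degenerate <- function(rows, max_mismatch = 1L, protect_3prime = 4L,
                              coverage_target = 0.95, max_degeneracy = 64) {
  stopifnot(length(rows) >= 1)
  plain <- grepl("^[ACGT]+$", rows)
  rows_p <- rows[plain]
  if (!length(rows_p))
    stop("no plain rows available for design", call. = FALSE)
  L <- nchar(rows_p[1])
  M <- .encode_rows(rows)          # coverage evaluated over all rows
  tab <- sort(table(rows_p), decreasing = TRUE)
  seed_freq <- names(tab)[1]
  mats <- build_matrices(rows_p)
  seed_vit <- viterbi_optimal(mats)
  seeds <- c(frequent = seed_freq)
  if (!identical(seed_vit, seed_freq)) seeds <- c(seeds, viterbi = seed_vit)

  visited <- list()
  for (sname in names(seeds)) {
    mask <- .BASE_WEIGHT[strsplit(seeds[[sname]], "")[[1]]]
    path <- .greedy_expand(mask, M, max_mismatch, protect_3prime,
                           coverage_target, max_degeneracy)
    for (st in path) { st$seed <- sname; visited[[length(visited) + 1L]] <- st }
  }
  # Pareto skyline (coverage desc, degeneracy asc): walking candidates in
  # that order, a candidate survives iff its degeneracy is strictly below
  # every already-kept one (equal-coverage/equal-degeneracy duplicates drop).
  cov <- vapply(visited, `[[`, numeric(1), "coverage")
  deg <- vapply(visited, `[[`, numeric(1), "degeneracy")
  ord <- order(-cov, deg)
  out <- list(); min_deg <- Inf
  for (i in ord) {
    if (deg[i] < min_deg) {
      out[[length(out) + 1L]] <- visited[[i]]
      min_deg <- deg[i]
    }
  }
  prim <- vapply(out, `[[`, character(1), "primer")
  out[!duplicated(prim)]
}

# Greedy single-(position, base) expansion from a plain seed mask.
# Returns the list of states visited (seed first, then after each step).
.greedy_expand <- function(mask, M, max_mismatch, protect_3prime,
                           coverage_target, max_degeneracy) {
  L <- length(mask)
  n <- nrow(M)
  eval_mask <- function(mk) {
    pidx <- match(.MASK_SYMBOL[mk], .IUPAC_SYMBOLS)
    cov <- .coverage_enc(pidx, M, max_mismatch, protect_3prime)
    mean(cov$covered)
  }
  state <- function(mk, cv) {
    pidx <- match(.MASK_SYMBOL[mk], .IUPAC_SYMBOLS)
    cc <- .coverage_enc(pidx, M, max_mismatch, protect_3prime)
    strata <- lapply(0:max_mismatch, function(k)
      rownames(M)[cc$covered & cc$mism == k])
    names(strata) <- as.character(0:max_mismatch)
    list(primer = .mask_to_primer(mk), coverage = cv,
         degeneracy = prod(floor(.IUPAC_VALUE[
           match(.MASK_SYMBOL[mk], .IUPAC_SYMBOLS)])),
         strata = strata)
  }
  cur_cov <- eval_mask(mask)
  path <- list(state(mask, cur_cov))
  deg_of <- function(mk) prod(.POPCNT[mk])
  repeat {
    if (cur_cov >= coverage_target) break
    cur_deg <- deg_of(mask)
    best <- NULL
    for (j in seq_len(L)) {
      k <- .POPCNT[mask[j]]
      new_deg <- cur_deg / k * (k + 1)
      if (new_deg > max_degeneracy) next
      for (b in c("A", "C", "G", "T")) {
        w <- .BASE_WEIGHT[[b]]
        if (bitwAnd(mask[j], w) != 0) next
        mk2 <- mask
        mk2[j] <- mask[j] + w
        cv <- eval_mask(mk2)
        gain <- cv - cur_cov
        if (gain <= 0) next
        cand <- list(mask = mk2, cov = cv, gain = gain,
                     dinc = new_deg - cur_deg, pos = j, base = b)
        if (is.null(best) ||
            gain > best$gain + 1e-12 ||
            (abs(gain - best$gain) <= 1e-12 &&
             (cand$dinc < best$dinc - 1e-12 ||
              (abs(cand$dinc - best$dinc) <= 1e-12 && cand$pos < best$pos))))
          best <- cand
      }
    }
    if (is.null(best)) break
    mask <- best$mask
    cur_cov <- best$cov
    path[[length(path) + 1L]] <- state(mask, cur_cov)
  }
  path
}

# Popcount over bitmasks 1..15.
.POPCNT <- vapply(1:15, function(m) sum(bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0),
                  numeric(1))
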