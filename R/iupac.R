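# IUPAC ambiguity-code algebra: the value table, degeneracy, expansion,
# containment, and the Hamming / Y-distance metrics used throughout the
# design and evaluation layers.

# Contained plain bases for each of the 15 IUPAC nucleotide codes.
.IUPAC_BASES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.IUPAC_SYMBOLS <- names(.IUPAC_BASES)

# Binary weights for the fractional part of the value encoding.
.BASE_WEIGHT <- c(A = 1, G = 2, C = 4, T = 8)

# Bitmask (A=1, G=2, C=4, T=8) for every symbol; used to merge codes.
.IUPAC_MASK <- vapply(.IUPAC_BASES, function(b) sum(.BASE_WEIGHT[b]), numeric(1))

# Reverse lookup: bitmask -> symbol.
.MASK_SYMBOL <- local({
  out <- character(15)
  out[.IUPAC_MASK] <- .IUPAC_SYMBOLS
  out
})

# Containment matrix: CONT[p, t] is TRUE iff every base of symbol t is a
# base of symbol p (for plain t: membership of t in p's base set).
.IUPAC_CONTAIN <- local({
  m <- matrix(FALSE, 15, 15, dimnames = list(.IUPAC_SYMBOLS, .IUPAC_SYMBOLS))
  for (p in .IUPAC_SYMBOLS)
    for (t in .IUPAC_SYMBOLS)
      m[p, t] <- all(.IUPAC_BASES[[t]] %in% .IUPAC_BASES[[p]])
  m
})

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                 R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                 B = "V", D = "H", H = "D", V = "B", N = "N")

#' IUPAC transition value table
#'
#' Builds the hash-style value table over the 15 IUPAC nucleotide codes that
#' underpins the nearest-neighbour design model.  Each plain base carries a
#' unique value \code{1 + w/16} with binary weights \code{w(A)=1, w(G)=2,
#' w(C)=4, w(T)=8}; a degenerate code's value is the sum of the values of
#' its contained plain bases.  The encoding guarantees:
#' \itemize{
#'   \item all 15 values are pairwise distinct;
#'   \item \code{floor(value(x))} equals the degeneracy of \code{x};
#'   \item \code{value(d) - value(b)} is itself a table value if and only if
#'     plain base \code{b} is contained in code \code{d}.
#' }
#'
#' @return Named numeric vector of length 15 (A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N).
#' @examples
#' tab <- iupac_table()
#' tab["R"] == tab["A"] + tab["G"]
#' floor(tab["N"])  # 4, the degeneracy of N
#' @export
iupac_table <- function() {
  vapply(.IUPAC_BASES, function(b) sum(1 + .BASE_WEIGHT[b] / 16), numeric(1))
}

.IUPAC_VALUE <- vapply(.IUPAC_BASES, function(b) sum(1 + .BASE_WEIGHT[b] / 16),
                       numeric(1))

# Normalize a primer/target string: uppercase, U->T; error (naming the
# offending character and position) on anything outside the 15-code alphabet.
.normalize_seq <- function(x, what = "sequence") {
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- which(!ch %in% .IUPAC_SYMBOLS)
  if (length(bad))
    stop(sprintf("invalid character '%s' at position %d of %s",
                 ch[bad[1]], bad[1], what), call. = FALSE)
  x
}

# Encode a sequence as integer symbol indices (1..15 into .IUPAC_SYMBOLS).
.encode_seq <- function(x) {
  idx <- match(strsplit(x, "", fixed = TRUE)[[1]], .IUPAC_SYMBOLS)
  if (anyNA(idx)) {
    p <- which(is.na(idx))[1]
    stop(sprintf("invalid character '%s' at position %d",
                 substr(x, p, p), p), call. = FALSE)
  }
  idx
}

# Encode several equal-length plain/degenerate sequences as an n x L matrix.
.encode_rows <- function(rows) {
  m <- t(vapply(rows, .encode_seq, integer(nchar(rows[1]))))
  rownames(m) <- if (is.null(names(rows))) as.character(seq_along(rows))
                 else names(rows)
  m
}

#' Degeneracy of a degenerate primer
#'
#' The number of plain (A/C/G/T-only) sequences the primer represents: the
#' product over positions of the per-symbol degeneracy (the integer part of
#' the symbol's table value).
#'
#' @param primer Character scalar over the IUPAC alphabet, 5'->3'.
#' @return Integer-valued numeric scalar, >= 1.
#' @examples
#' degeneracy("ACGT")  # 1
#' degeneracy("RN")    # 8
#' @export
degeneracy <- function(primer) {
  primer <- .normalize_seq(primer, "primer")
  if (nchar(primer) == 0L) stop("primer must be non-empty", call. = FALSE)
  prod(floor(.IUPAC_VALUE[.encode_seq(primer)]))
}

#' Expand a degenerate primer into plain sequences
#'
#' Returns the full expansion set when its size does not exceed \code{cap},
#' otherwise a deterministic, seed-controlled uniform sample of \code{cap}
#' distinct members (attribute \code{truncated} set to \code{TRUE}).
#'
#' @param primer Character scalar over the IUPAC alphabet.
#' @param cap Maximum number of members to return.
#' @param seed Integer seed controlling the sample when truncation occurs.
#' @return Character vector of plain sequences; attribute \code{truncated}.
#' @examples
#' expand_primer("R")   # "A" "G"
#' length(expand_primer("NN"))  # 16
#' @export
expand_primer <- function(primer, cap = Inf, seed = 1L) {
  primer <- .normalize_seq(primer, "primer")
  stopifnot(cap >= 1)
  sets <- .IUPAC_BASES[.encode_seq(primer)]
  deg <- prod(lengths(sets))
  if (deg <= cap) {
    if (deg == 1L) {
      out <- paste(vapply(sets, `[`, character(1), 1L), collapse = "")
    } else {
      grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
      out <- do.call(paste0, rev(grid))
    }
    attr(out, "truncated") <- FALSE
    return(out)
  }
  # Sample without enumerating: draw member indices in a local RNG scope.
  out <- .with_seed(seed, {
    picks <- unique(vapply(seq_len(cap * 2L), function(i) {
      paste(vapply(sets, sample, character(1), size = 1L), collapse = "")
    }, character(1)))
    picks[seq_len(min(cap, length(picks)))]
  })
  attr(out, "truncated") <- TRUE
  out
}

# Evaluate expr with a temporary RNG state seeded by `seed`.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Hamming distance between a primer and a target
#'
#' Counts positions where the literal symbols differ; a degenerate symbol
#' facing one of its contained bases (e.g. R over A) still counts as a
#' difference.  This is the naive metric that the Y-distance refines.
#'
#' @param primer,target Equal-length character scalars.
#' @return Integer count of literally differing positions.
#' @seealso [y_distance()]
#' @export
hamming_dist <- function(primer, target) {
  primer <- .normalize_seq(primer, "primer")
  target <- .normalize_seq(target, "target")
  if (nchar(primer) != nchar(target))
    stop("primer and target lengths differ", call. = FALSE)
  sum(strsplit(primer, "")[[1]] != strsplit(target, "")[[1]])
}

#' Y-distance between a degenerate primer and a target
#'
#' The ordered list of 1-based positions (from the primer's 5' end) at which
#' the target base is \emph{not contained} in the primer's degenerate
#' symbol; its length is the effective mismatch count.  Equivalently, a
#' position is reported when \code{value(primer symbol) - value(target
#' base)} is absent from the IUPAC value table.
#'
#' @param primer Character scalar over the IUPAC alphabet.
#' @param target Equal-length character scalar (plain, or IUPAC where
#'   containment means the target's base set is a subset of the primer's).
#' @return Integer vector of non-contained positions, strictly increasing.
#' @examples
#' y_distance("RRR", "AGC")  # 3: C is not contained in R
#' @export
y_distance <- function(primer, target) {
  primer <- .normalize_seq(primer, "primer")
  target <- .normalize_seq(target, "target")
  if (nchar(primer) != nchar(target))
    stop("primer and target lengths differ", call. = FALSE)
  pi <- .encode_seq(primer)
  ti <- .encode_seq(target)
  which(!.IUPAC_CONTAIN[cbind(pi, ti)])
}

#' Mismatch acceptance rule for a Y-distance
#'
#' A target is accepted iff the number of non-contained positions does not
#' exceed \code{max_mismatch} \emph{and} none of them falls within the
#' protected 3'-terminal region (\code{protect_3prime} bases counted from
#' the 3' end inclusive; 0 disables 3' protection).
#'
#' @param yd Integer vector of Y-distance positions (1-based, 5'->3').
#' @param max_mismatch Allowed mismatch count (0, 1 or 2).
#' @param protect_3prime Number of protected 3'-terminal bases.
#' @param primer_len Primer length in nt.
#' @return Logical scalar.
#' @export
accept_mismatches <- function(yd, max_mismatch, protect_3prime, primer_len) {
  stopifnot(max_mismatch >= 0, max_mismatch <= 2, protect_3prime >= 0)
  length(yd) <= max_mismatch && !any(yd > primer_len - protect_3prime)
}

#' Reverse complement of an IUPAC sequence
#'
#' @param x Character scalar over the IUPAC alphabet.
#' @return Character scalar, reverse-complemented (degenerate codes map to
#'   their complement codes, e.g. R -> Y).
#' @export
revcomp <- function(x) {
  x <- .normalize_seq(x)
  paste(rev(.COMPLEMENT[strsplit(x, "")[[1]]]), collapse = "")
}
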