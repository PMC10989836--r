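# Primer thermodynamics (nearest-neighbour Tm, GC) and the empirical
# primer-dimer loss function with risk classification.

#' Dimer loss function
#'
#' Empirical compatibility score for a complementary run between two
#' primers:
#' \deqn{loss = \log_{10}\frac{2^{length} \cdot 2^{GC}}
#'   {(2^{distance_1}-0.9)(2^{distance_2}-0.9)}}
#' where \code{length} is the run length, \code{gc_count} the number of G/C
#' nucleotides in the run, and the distances are measured from the run to
#' each primer's 3' end in nt.  Larger is worse; the denominator is
#' positive for all distances >= 0.
#'
#' @param run_length Complementary run length (nt, >= 1).
#' @param gc_count Number of G/C bases in the run.
#' @param distance1,distance2 Distance (nt) from the run to the 3' end of
#'   each primer.
#' @return Numeric loss (log10 scale), vectorized over its arguments.
#' @examples
#' dimer_loss(5, 3, 0, 0)   # ~4.41, high risk
#' dimer_loss(4, 2, 5, 6)   # ~-1.49, low risk
#' @export
dimer_loss <- function(run_length, gc_count, distance1, distance2) {
  stopifnot(all(run_length >= 1), all(distance1 >= 0), all(distance2 >= 0))
  log10(2^run_length * 2^gc_count /
          ((2^distance1 - 0.9) * (2^distance2 - 0.9)))
}

#' Classify a dimer loss value
#'
#' @param loss Numeric loss value(s).
#' @param high High-risk threshold (loss >= high).
#' @param low Low-risk threshold (loss <= low).
#' @return Character vector in \{"high", "medium", "low"\}.
#' @export
classify_dimer <- function(loss, high = 3.96, low = 3.0) {
  stopifnot(high > low)
  ifelse(loss >= high, "high", ifelse(loss <= low, "low", "medium"))
}

#' Scan two primers for complementary runs (dimers)
#'
#' Enumerates every ungapped antiparallel Watson-Crick complementary run of
#' at least \code{min_run} nt between primer \code{a} and primer \code{b}
#' at all offsets (equivalently: all maximal common substrings between
#' \code{a} and the reverse complement of \code{b}).  Degenerate primers
#' are evaluated over capped expansions and the worst case (maximum loss)
#' is kept.  Use \code{scan_dimer(a, a)} for self-dimers.
#'
#' @param a,b Primer strings (IUPAC alphabet allowed).
#' @param min_run Minimum run length to report.
#' @param expansion_cap Maximum expansion members per primer.
#' @param anchored If TRUE, keep only runs touching a 3' end
#'   (distance1 == 0 or distance2 == 0).
#' @param high,low Risk thresholds passed to [classify_dimer()].
#' @return data.frame of hits (run_length, gc_count, distance1, distance2,
#'   loss, risk) with attribute \code{loss_max} (-Inf when no hit).
#' @export
scan_dimer <- function(a, b, min_run = 4L, expansion_cap = 8L,
                       anchored = FALSE, high = 3.96, low = 3.0) {
  ea <- expand_primer(a, cap = expansion_cap)
  eb <- expand_primer(b, cap = expansion_cap)
  hits <- list()
  for (x in ea) for (y in eb) {
    h <- .scan_dimer_plain(x, y, min_run)
    if (nrow(h)) hits[[length(hits) + 1L]] <- h
  }
  out <- if (length(hits)) unique(do.call(rbind, hits)) else
    data.frame(run_length = integer(0), gc_count = integer(0),
               distance1 = integer(0), distance2 = integer(0))
  if (anchored && nrow(out))
    out <- out[out$distance1 == 0 | out$distance2 == 0, , drop = FALSE]
  if (nrow(out)) {
    out$loss <- dimer_loss(out$run_length, out$gc_count,
                           out$distance1, out$distance2)
    out <- out[order(-out$loss), , drop = FALSE]
    out$risk <- classify_dimer(out$loss, high, low)
    rownames(out) <- NULL
  } else {
    out$loss <- numeric(0); out$risk <- character(0)
  }
  attr(out, "loss_max") <- if (nrow(out)) max(out$loss) else -Inf
  out
}

# Maximal common substrings of length >= min_run between plain x and
# revcomp(y), reported with primer-frame distances:
#   distance1 = bases between the run and the 3' end of x,
#   distance2 = bases between the run and the 3' end of y.
.scan_dimer_plain <- function(x, y, min_run) {
  cx <- strsplit(x, "")[[1]]
  cy <- strsplit(revcomp(y), "")[[1]]
  n <- length(cx); m <- length(cy)
  res <- list()
  for (shift in (-(m - 1L)):(n - 1L)) {
    i0 <- max(1L, 1L + shift); i1 <- min(n, m + shift)
    if (i1 - i0 + 1L < min_run) next
    ix <- i0:i1
    iy <- ix - shift
    eq <- cx[ix] == cy[iy]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (t in which(r$values & r$lengths >= min_run)) {
      run_ix <- ix[starts[t]:ends[t]]
      len <- length(run_ix)
      gc <- sum(cx[run_ix] %in% c("G", "C"))
      d1 <- n - run_ix[len]
      # run start in revcomp(y) coordinates gives the distance to y's 3' end
      d2 <- iy[starts[t]] - 1L
      res[[length(res) + 1L]] <-
        data.frame(run_length = len, gc_count = gc,
                   distance1 = d1, distance2 = d2)
    }
  }
  if (length(res)) do.call(rbind, res) else
    data.frame(run_length = integer(0), gc_count = integer(0),
               distance1 = integer(0), distance2 = integer(0))
}

#' Headline loss between two primers
#'
#' @inheritParams scan_dimer
#' @return Maximum loss over all complementary runs (-Inf when none).
#' @export
pair_loss <- function(a, b, min_run = 4L, expansion_cap = 8L,
                      anchored = FALSE) {
  attr(scan_dimer(a, b, min_run, expansion_cap, anchored), "loss_max")
}

#' Dimer ratio at a loss threshold
#'
#' Fraction of observed dimer reads whose loss exceeds \code{L}; a
#' non-increasing step function of \code{L} used to locate the risk
#' threshold at its inflection.
#'
#' @param L Loss threshold.
#' @param dimer_losses Numeric vector of per-read loss values (non-empty).
#' @return Fraction in [0, 1].
#' @export
dimer_ratio <- function(L, dimer_losses) {
  if (!length(dimer_losses))
    stop("dimer_ratio undefined for an empty loss list", call. = FALSE)
  mean(dimer_losses > L)
}

# Allawi & SantaLucia unified nearest-neighbour parameters:
# dH (kcal/mol), dS (cal/mol/K) keyed by the top-strand dinucleotide.
.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

#' Nearest-neighbour melting temperature of a plain oligo
#'
#' Unified nearest-neighbour thermodynamics with terminal initiation
#' parameters, symmetry correction for self-complementary duplexes, and a
#' monovalent-salt entropy correction
#' \eqn{\Delta S' = \Delta S + 0.368 (N-1) \ln[\mathrm{Na}^+]}.  The duplex
#' concentration term uses \eqn{C_T/4} (non-self-complementary) or
#' \eqn{C_T/2} (self-complementary).
#'
#' @param seq Plain A/C/G/T sequence (>= 10 nt).
#' @param salt_mM Monovalent cation concentration in mM.
#' @param oligo_nM Total oligo concentration in nM.
#' @return Melting temperature in degrees Celsius.
#' @export
primer_tm <- function(seq, salt_mM = 50, oligo_nM = 50) {
  seq <- .normalize_seq(seq, "primer")
  if (!grepl("^[ACGT]+$", seq))
    stop("primer_tm requires a plain sequence; use tm_stats() for ",
         "degenerate primers", call. = FALSE)
  n <- nchar(seq)
  if (n < 10) stop("primer too short for NN Tm (need >= 10 nt)",
                   call. = FALSE)
  di <- substring(seq, 1:(n - 1L), 2:n)
  dH <- sum(.NN_DH[di])
  dS <- sum(.NN_DS[di])
  ends <- c(substr(seq, 1, 1), substr(seq, n, n))
  for (e in ends) {
    if (e %in% c("A", "T")) { dH <- dH + 2.3; dS <- dS + 4.1 }
    else { dH <- dH + 0.1; dS <- dS - 2.8 }
  }
  selfcomp <- identical(seq, revcomp(seq))
  if (selfcomp) dS <- dS - 1.4
  dS <- dS + 0.368 * (n - 1) * log(salt_mM / 1000)
  conc <- oligo_nM * 1e-9 / (if (selfcomp) 2 else 4)
  1000 * dH / (dS + 1.987 * log(conc)) - 273.15
}

#' Tm and GC statistics of a (possibly degenerate) primer
#'
#' Computes the nearest-neighbour Tm and the GC fraction for each member of
#' the primer's (capped) expansion and reports the extremes.
#'
#' @param primer Primer string over the IUPAC alphabet (>= 10 nt).
#' @param salt_mM,oligo_nM Reaction conditions, see [primer_tm()].
#' @param expansion_cap Maximum expansion members evaluated.
#' @return List with \code{tm_min}, \code{tm_max}, \code{gc_min},
#'   \code{gc_max}.
#' @export
tm_stats <- function(primer, salt_mM = 50, oligo_nM = 50,
                     expansion_cap = 64L) {
  members <- expand_primer(primer, cap = expansion_cap)
  tms <- vapply(members, primer_tm, numeric(1),
                salt_mM = salt_mM, oligo_nM = oligo_nM)
  gcs <- vapply(members, function(s)
    mean(strsplit(s, "")[[1]] %in% c("G", "C")), numeric(1))
  list(tm_min = min(tms), tm_max = max(tms),
       gc_min = min(gcs), gc_max = max(gcs))
}
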