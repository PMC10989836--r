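# In-silico PCR over the target collection, accumulated coverage
# reporting, and per-primer efficiency / read-assignment metrics.

# All accepted start offsets of `primer` on plain text `txt` under the
# Y-distance rules, vectorized over offsets.
.scan_sites_enc <- function(pidx, tenc, max_mismatch, protect) {
  L <- length(pidx)
  n <- length(tenc)
  if (n < L) return(integer(0))
  starts <- seq_len(n - L + 1L)
  idx <- outer(starts, 0:(L - 1L), `+`)        # offsets x L
  cont <- matrix(.IUPAC_CONTAIN[cbind(rep(pidx, each = length(starts)),
                                      tenc[idx])],
                 nrow = length(starts))
  mism <- !cont
  counts <- rowSums(mism)
  ok <- counts <= max_mismatch
  if (protect > 0) {
    prot <- (L - protect + 1L):L
    ok <- ok & rowSums(mism[, prot, drop = FALSE]) == 0L
  }
  starts[ok]
}

# Amplicon search for one pair on one (encoded) target orientation.
# fwd must sit upstream of the reverse primer's minus-strand site.
.find_amplicon <- function(fenc, renc, tenc, max_mismatch, protect,
                           min_product, max_product) {
  n <- length(tenc)
  f_sites <- .scan_sites_enc(fenc, tenc, max_mismatch, protect)
  if (!length(f_sites)) return(NULL)
  # reverse primer binds the minus strand: scan on the reverse-complemented
  # target, then convert to plus-strand intervals
  tenc_rc <- rev(match(.COMPLEMENT[.IUPAC_SYMBOLS[tenc]], .IUPAC_SYMBOLS))
  r_sites_rc <- .scan_sites_enc(renc, tenc_rc, max_mismatch, protect)
  if (!length(r_sites_rc)) return(NULL)
  Lr <- length(renc)
  r_right <- n - r_sites_rc + 1L               # plus-strand right end
  for (f in f_sites) {
    prods <- r_right - f + 1L
    ok <- which(prods >= min_product & prods <= max_product &
                  (r_right - Lr + 1L) > (f + length(fenc) - 1L))
    if (length(ok)) {
      j <- ok[which.min(prods[ok])]
      return(list(fwd_start = f, rev_end = r_right[j],
                  product = prods[j]))
    }
  }
  NULL
}

#' In-silico PCR of a primer set over a target collection
#'
#' Every target is scanned on both orientations for each accepted pair in
#' set order; a target is covered when some pair yields a valid amplicon
#' (both primers accepted under the Y-distance rules, product size within
#' range).  Coverage is reported per pair, accumulated in set order, and
#' overall.
#'
#' @param pset A \code{primer_set} from [greedy_combine()], or a
#'   data.frame with columns \code{fwd}, \code{rev} (and optionally
#'   \code{cluster_id}).
#' @param targets data.frame of records (\code{id}, \code{seq}).
#' @param params Parameter list; uses \code{max_mismatch},
#'   \code{coordinate} (3'-protection), \code{min_product},
#'   \code{max_product}.
#' @return List with \code{calls} (data.frame: target id, pair index,
#'   cluster, fwd_start, rev_end, product), \code{covered} (named logical
#'   per target), \code{accumulated} (data.frame: pair index, cumulative
#'   coverage fraction) and \code{coverage} (overall fraction).
#' @export
insilico_pcr <- function(pset, targets, params = default_config()) {
  pairs <- if (inherits(pset, "primer_set")) pset$accepted else pset
  if (is.null(pairs) || !nrow(pairs))
    stop("primer set has no accepted pairs", call. = FALSE)
  if (is.null(pairs$cluster_id)) pairs$cluster_id <- as.character(seq_len(nrow(pairs)))
  mm <- params$max_mismatch
  prot <- params$coordinate
  fenc <- lapply(pairs$fwd, .encode_seq)
  renc <- lapply(pairs$rev, .encode_seq)
  tencs <- lapply(targets$seq, .encode_seq)
  covered_by <- matrix(FALSE, nrow(targets), nrow(pairs))
  calls <- list()
  for (ti in seq_len(nrow(targets))) {
    tenc <- tencs[[ti]]
    tenc_rc <- rev(match(.COMPLEMENT[.IUPAC_SYMBOLS[tenc]], .IUPAC_SYMBOLS))
    for (pi in seq_len(nrow(pairs))) {
      hit <- .find_amplicon(fenc[[pi]], renc[[pi]], tenc, mm, prot,
                            params$min_product, params$max_product)
      strand <- "+"
      if (is.null(hit)) {
        hit <- .find_amplicon(fenc[[pi]], renc[[pi]], tenc_rc, mm, prot,
                              params$min_product, params$max_product)
        strand <- "-"
      }
      if (!is.null(hit)) {
        covered_by[ti, pi] <- TRUE
        calls[[length(calls) + 1L]] <-
          data.frame(target = targets$id[ti], pair = pi,
                     cluster_id = pairs$cluster_id[pi], strand = strand,
                     fwd_start = hit$fwd_start, rev_end = hit$rev_end,
                     product = hit$product, stringsAsFactors = FALSE)
      }
    }
  }
  covered <- apply(covered_by, 1, any)
  names(covered) <- targets$id
  accumulated <- data.frame(
    pair = seq_len(nrow(pairs)),
    cluster_id = pairs$cluster_id,
    cumulative_coverage = vapply(seq_len(nrow(pairs)), function(k)
      mean(apply(covered_by[, seq_len(k), drop = FALSE], 1, any)),
      numeric(1)))
  list(calls = if (length(calls)) do.call(rbind, calls) else NULL,
       covered = covered, accumulated = accumulated,
       coverage = mean(covered))
}

#' PCR efficiency of a primer relative to a perfect-match comparator
#'
#' @param reads_i Read count assigned to the primer's target region.
#' @param reads_c Read count of the perfect-match comparator (> 0).
#' @return \code{reads_i / reads_c}, unrounded.
#' @examples
#' pcr_efficiency(70, 100)  # 0.7
#' @export
pcr_efficiency <- function(reads_i, reads_c) {
  if (any(reads_c <= 0))
    stop("efficiency undefined: comparator read count must be > 0",
         call. = FALSE)
  reads_i / reads_c
}

#' Assign amplicon reads to their primers
#'
#' A read is assigned to the unique primer whose sequence matches the
#' read's 5' prefix under the Y-distance acceptance rules, allowing the
#' prefix to start within \code{slack} nt of the read start (ragged
#' starts).  Reads matching several primers are counted as ambiguous,
#' reads matching none as unassigned.
#'
#' @param reads Character vector of read sequences.
#' @param primers Named character vector of primers.
#' @param max_mismatch,protect Acceptance rules.
#' @param slack Maximum start offset tried (0..slack).
#' @return List with \code{counts} (data.frame: primer, stratum 0..2,
#'   reads), \code{assigned} (named character: read -> primer or NA),
#'   \code{ambiguous}, \code{unassigned} (counts).
#' @export
assign_reads_to_primers <- function(reads, primers, max_mismatch = 1L,
                                    protect = 4L, slack = 2L) {
  stopifnot(length(primers) >= 1)
  if (is.null(names(primers))) names(primers) <- paste0("P", seq_along(primers))
  assigned <- rep(NA_character_, length(reads))
  stratum <- rep(NA_integer_, length(reads))
  n_amb <- 0L
  for (ri in seq_along(reads)) {
    rd <- .normalize_seq(reads[[ri]], "read")
    hits <- character(0); best <- Inf
    for (pn in names(primers)) {
      p <- primers[[pn]]
      L <- nchar(p)
      found <- Inf
      for (off in 0:slack) {
        if (off + L > nchar(rd)) break
        yd <- y_distance(p, substr(rd, off + 1L, off + L))
        if (accept_mismatches(yd, max_mismatch, protect, L))
          found <- min(found, length(yd))
      }
      if (is.finite(found)) { hits <- c(hits, pn); best <- min(best, found) }
    }
    if (length(hits) == 1L) {
      assigned[ri] <- hits; stratum[ri] <- best
    } else if (length(hits) > 1L) n_amb <- n_amb + 1L
  }
  counts <- do.call(rbind, lapply(names(primers), function(pn) {
    data.frame(primer = pn,
               stratum = 0:max_mismatch,
               reads = vapply(0:max_mismatch, function(k)
                 sum(assigned == pn & stratum == k, na.rm = TRUE),
                 numeric(1)),
               stringsAsFactors = FALSE)
  }))
  list(counts = counts, assigned = assigned,
       ambiguous = n_amb,
       unassigned = sum(is.na(assigned)) - n_amb)
}
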