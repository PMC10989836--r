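# Per-cluster multiple sequence alignment and primer-length window
# extraction with the gap-shift rule and the entropy filter.

#' Align the sequences of a cluster
#'
#' Produces a multiple alignment of the cluster subsample.  The built-in
#' engine runs a center-star alignment around the first sequence (the
#' cluster representative) using global pairwise alignments; alternatively
#' an external \command{mafft} binary can be invoked.  Both engines are
#' deterministic.
#'
#' @param seqs Named character vector of sequences; the first element is
#'   treated as the center/representative.
#' @param engine \code{"builtin"} (center-star) or \code{"mafft"}.
#' @param mafft_path Path to the mafft executable (config key
#'   \code{mafft_path}).
#' @return Object of class \code{cluster_alignment}: list with \code{rows}
#'   (named character vector of equal-length gapped rows) and \code{ncol}.
#' @export
align_cluster <- function(seqs, engine = c("builtin", "mafft"),
                          mafft_path = "mafft") {
  engine <- match.arg(engine)
  stopifnot(length(seqs) >= 1)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (length(seqs) == 1L || length(unique(seqs)) == 1L) {
    rows <- seqs
    return(structure(list(rows = rows, ncol = nchar(seqs[[1]])),
                     class = "cluster_alignment"))
  }
  rows <- if (engine == "mafft") .align_mafft(seqs, mafft_path)
          else .align_center_star(seqs)
  structure(list(rows = rows, ncol = nchar(rows[[1]])),
            class = "cluster_alignment")
}

.align_mafft <- function(seqs, mafft_path) {
  if (Sys.which(mafft_path) == "")
    stop("external aligner not found; set config key 'mafft_path' ",
         "or use aligner: builtin", call. = FALSE)
  tin <- tempfile(fileext = ".fa"); tout <- tempfile(fileext = ".fa")
  on.exit(unlink(c(tin, tout)))
  write_fasta(data.frame(id = names(seqs), seq = unname(seqs)), tin)
  status <- system2(mafft_path, c("--auto", "--thread", "1", "--quiet", tin),
                    stdout = tout)
  if (status != 0L) stop("mafft failed with status ", status, call. = FALSE)
  ali <- read_fasta_gapped(tout)
  out <- toupper(ali$seq)
  names(out) <- ali$id
  out[names(seqs)]
}

# Gap-tolerant FASTA reader for aligned sequences.
#' Read an aligned (gapped) FASTA file
#'
#' @param path Path to an aligned FASTA file ('-' gaps preserved).
#' @return data.frame with columns \code{id} and \code{seq}.
#' @export
read_fasta_gapped <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  data.frame(id = ids, seq = toupper(as.character(set)),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Center-star alignment: globally align every member to the center, then
# merge the pairwise alignments on a master gap profile.
.align_center_star <- function(seqs) {
  center <- seqs[[1]]
  others <- seqs[-1]
  n_center <- nchar(center)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                     mismatch = -1,
                                                     baseOnly = FALSE)
  aligned <- lapply(others, function(s) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(s), Biostrings::DNAString(center),
      type = "global", substitutionMatrix = submat,
      gapOpening = 6, gapExtension = 1)
    list(member = as.character(Biostrings::alignedPattern(pa)),
         center = as.character(Biostrings::alignedSubject(pa)))
  })
  # Insertion profile: ins[j + 1] = max run of member-insertions after
  # center position j (j = 0 allows insertions before the first base).
  ins <- integer(n_center + 1L)
  per_aln <- lapply(aligned, function(al) {
    cc <- strsplit(al$center, "")[[1]]
    mm <- strsplit(al$member, "")[[1]]
    pos <- 0L
    runs <- integer(n_center + 1L)
    segs <- vector("list", n_center + 1L)   # member insertion segments
    cols <- character(n_center)             # member char at center position
    buf <- character(0)
    for (t in seq_along(cc)) {
      if (cc[t] == "-") {
        buf <- c(buf, mm[t])
      } else {
        runs[pos + 1L] <- length(buf)
        segs[[pos + 1L]] <- buf
        buf <- character(0)
        pos <- pos + 1L
        cols[pos] <- mm[t]
      }
    }
    runs[pos + 1L] <- length(buf)
    segs[[pos + 1L]] <- buf
    list(runs = runs, segs = segs, cols = cols)
  })
  for (al in per_aln) ins <- pmax(ins, al$runs)

  centers <- strsplit(center, "")[[1]]
  build_row <- function(cols, segs) {
    pieces <- character(0)
    for (j in 0:n_center) {
      seg <- segs[[j + 1L]]
      pad <- ins[j + 1L] - length(seg)
      pieces <- c(pieces, seg, rep("-", pad),
                  if (j < n_center) cols[j + 1L])
    }
    paste(pieces, collapse = "")
  }
  center_row <- build_row(centers, rep(list(character(0)), n_center + 1L))
  member_rows <- vapply(per_aln, function(al) build_row(al$cols, al$segs),
                        character(1))
  out <- c(center_row, member_rows)
  names(out) <- c(names(seqs)[1], names(others))
  out
}

#' Reverse-complement a cluster alignment
#'
#' Used to design reverse-strand primers on the same alignment.
#'
#' @param alignment A \code{cluster_alignment}.
#' @return A \code{cluster_alignment} with every row reverse-complemented
#'   (gaps preserved, order of rows unchanged).
#' @export
revcomp_alignment <- function(alignment) {
  rows <- vapply(alignment$rows, function(r) {
    ch <- rev(strsplit(r, "")[[1]])
    paste(ifelse(ch == "-", "-", .COMPLEMENT[ch]), collapse = "")
  }, character(1))
  structure(list(rows = rows, ncol = alignment$ncol),
            class = "cluster_alignment")
}

#' Extract primer-length windows from an alignment
#'
#' For every alignment start column and every row: gaps are stripped and,
#' when the window begins on a gap, the window shifts to the row's next
#' base; the window is then extended rightward along the row's ungapped
#' sequence until \code{primer_len} bases are collected.  Rows that run out
#' of sequence are dropped from that window; windows in which more than
#' half of the rows were dropped are discarded.
#'
#' @param alignment A \code{cluster_alignment}.
#' @param primer_len Window length in nt (>= 15).
#' @return List of windows; each is a list with \code{start} (1-based
#'   alignment column), \code{length}, \code{seqs} (named character vector
#'   of surviving row extractions), \code{n_dropped}, \code{entropy} (bits)
#'   and \code{rep_start} (1-based start on the first row's ungapped
#'   sequence).
#' @export
extract_windows <- function(alignment, primer_len) {
  stopifnot(primer_len >= 15)
  rows <- alignment$rows
  nc <- alignment$ncol
  if (nc < primer_len) return(list())
  ungapped <- gsub("-", "", rows, fixed = TRUE)
  n_starts <- nc - primer_len + 1L
  # Per row: map column -> 1-based start position in the ungapped sequence
  # applying the gap-shift rule, then extract all windows in one call.
  ext <- lapply(seq_along(rows), function(i) {
    ch <- strsplit(rows[[i]], "")[[1]]
    nong <- ch != "-"
    cum <- cumsum(nong)
    begin <- ifelse(nong, cum, cum + 1L)[seq_len(n_starts)]
    out <- substring(ungapped[[i]], begin, begin + primer_len - 1L)
    out[nchar(out) < primer_len] <- NA_character_
    list(ext = out, begin = begin)
  })
  mat <- do.call(rbind, lapply(ext, `[[`, "ext"))
  rownames(mat) <- names(rows)
  rep_begin <- ext[[1]]$begin
  lapply(seq_len(n_starts), function(s) {
    col <- mat[, s]
    keep <- !is.na(col)
    if (sum(keep) == 0 || sum(!keep) > length(col) / 2) return(NULL)
    seqs <- col[keep]
    list(start = s, length = primer_len, seqs = seqs,
         n_dropped = sum(!keep), entropy = window_entropy(seqs),
         rep_start = rep_begin[s])
  }) -> wins
  Filter(Negate(is.null), wins)
}

#' Entropy of a window's variant distribution
#'
#' Shannon entropy (bits) of the empirical distribution of the distinct
#' extracted subsequences across rows.  0 when all rows agree; windows
#' above the configured cutoff (default 3.6 bits, roughly a dozen
#' equi-frequent variants) are unsuitable for degenerate design.
#'
#' @param seqs Character vector of per-row window subsequences.
#' @return Entropy in bits.
#' @export
window_entropy <- function(seqs) {
  stopifnot(length(seqs) >= 1)
  p <- table(seqs) / length(seqs)
  -sum(p * log2(p))
}
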