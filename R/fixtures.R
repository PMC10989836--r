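# Synthetic sequence-family generator: reproducible stand-ins for diverse
# target collections, with planted conserved primer sites and truth tables
# so clustering, design and coverage recovery are testable without
# downloads.

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

.mutate_sites <- function(seq, sites, rate) {
  if (!length(sites) || rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- sites[stats::runif(length(sites)) < rate]
  for (p in hit) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

#' Generate a synthetic panel of sequence families
#'
#' Each family descends from an independent random ancestor by
#' independent per-site point mutation.  Two primer-length regions per
#' ancestor (a forward and a reverse primer site flanking an amplifiable
#' product) are planted as conserved: they mutate at \code{conserved_rate}
#' while the rest of the sequence mutates at \code{div_rate}.  Independent
#' ancestors put inter-family identity near 25%, far below any clustering
#' threshold in use.
#'
#' @param n_families Number of families.
#' @param seqs_per_family Sequences per family.
#' @param seq_len Sequence length (nt).
#' @param div_rate Per-site mutation probability outside conserved regions.
#' @param conserved_rate Per-site mutation probability inside the planted
#'   primer regions.
#' @param primer_len Length of the perfect-match control primers taken
#'   from each ancestor.
#' @param site_len Width of each planted conserved region (nt); sized to
#'   accommodate the full primer-length range a designer scans.
#' @param fwd_pos,rev_pos 1-based start of the planted forward site and of
#'   the reverse site (plus-strand coordinates of the site's left end).
#' @param seed Integer seed; the full output is reproducible.
#' @return List with \code{records} (data.frame id, seq, length),
#'   \code{truth} (data.frame id, family, fwd_start, rev_start),
#'   \code{controls} (data.frame family, fwd, rev: perfect-match control
#'   primers from each ancestor) and \code{ancestors} (named character).
#' @export
synth_panel <- function(n_families = 8L, seqs_per_family = 50L,
                        seq_len = 500L, div_rate = 0.05,
                        conserved_rate = 0.01, primer_len = 20L,
                        site_len = 30L, fwd_pos = 101L, rev_pos = 351L,
                        seed = 1L) {
  stopifnot(site_len >= primer_len,
            rev_pos + site_len - 1L <= seq_len,
            fwd_pos + site_len - 1L < rev_pos)
  .with_seed(seed, {
    cons <- c(fwd_pos:(fwd_pos + site_len - 1L),
              rev_pos:(rev_pos + site_len - 1L))
    backg <- setdiff(seq_len(seq_len), cons)
    recs <- list(); truth <- list(); ctrl <- list(); anc <- character(0)
    for (f in seq_len(n_families)) {
      fam <- sprintf("F%02d", f)
      ancestor <- .rand_dna(seq_len)
      anc[fam] <- ancestor
      ctrl[[f]] <- data.frame(
        family = fam,
        fwd = substr(ancestor, fwd_pos, fwd_pos + primer_len - 1L),
        rev = revcomp(substr(ancestor, rev_pos, rev_pos + primer_len - 1L)),
        stringsAsFactors = FALSE)
      for (s in seq_len(seqs_per_family)) {
        id <- sprintf("%s_s%03d", fam, s)
        sq <- .mutate_sites(ancestor, backg, div_rate)
        sq <- .mutate_sites(sq, cons, conserved_rate)
        recs[[length(recs) + 1L]] <-
          data.frame(id = id, seq = sq, length = nchar(sq),
                     stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <-
          data.frame(id = id, family = fam, fwd_start = fwd_pos,
                     rev_start = rev_pos, stringsAsFactors = FALSE)
      }
    }
    list(records = do.call(rbind, recs), truth = do.call(rbind, truth),
         controls = do.call(rbind, ctrl), ancestors = anc)
  })
}

#' Write a synthetic panel to disk
#'
#' Writes the panel FASTA plus plain-text truth tables (family labels,
#' planted site coordinates, perfect-match control primers).
#'
#' @param panel A panel from [synth_panel()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "targets.fasta"),
             truth = file.path(dir, "truth.tsv"),
             controls = file.path(dir, "control_primers.tsv"))
  write_fasta(panel$records, paths["fasta"])
  utils::write.table(panel$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(panel$controls, paths["controls"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Simulate amplicon reads from a primer pool
#'
#' Each read starts with one expansion member of its source primer
#' (optionally offset by up to \code{slack} random leading bases) followed
#' by random sequence, emulating amplicon reads that begin at the primer.
#'
#' @param primers Named character vector of primers.
#' @param n_per Reads per primer.
#' @param read_len Read length (nt).
#' @param mismatch_rate Per-site mutation probability applied to the primer
#'   prefix of each read.
#' @param slack Maximum number of random leading bases.
#' @param seed Integer seed.
#' @return data.frame with \code{read}, \code{seq}, \code{source}.
#' @export
synth_reads <- function(primers, n_per = 20L, read_len = 75L,
                        mismatch_rate = 0, slack = 0L, seed = 1L) {
  if (is.null(names(primers))) names(primers) <- paste0("P", seq_along(primers))
  .with_seed(seed, {
    out <- list()
    for (pn in names(primers)) {
      members <- expand_primer(primers[[pn]], cap = 16L)
      for (i in seq_len(n_per)) {
        pre <- if (slack > 0) .rand_dna(sample(0:slack, 1L)) else ""
        core <- sample(members, 1L)
        core <- .mutate_sites(core, seq_len(nchar(core)), mismatch_rate)
        tail_len <- max(read_len - nchar(pre) - nchar(core), 0L)
        out[[length(out) + 1L]] <- data.frame(
          read = sprintf("%s_r%03d", pn, i),
          seq = substr(paste0(pre, core, .rand_dna(tail_len)), 1, read_len),
          source = pn, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}

#' The ten-target degeneracy demonstration set
#'
#' A compact, fully synthetic set of ten 20-nt target sequences built
#' around a shared core with nine biallelic positions: two "common"
#' variant positions each recur in five sequences and seven singleton
#' variants occur once each.  Covering all ten targets with a single
#' degenerate primer and no mismatch tolerance forces a code at every
#' variable position (degeneracy \eqn{2^9 = 512}), whereas allowing one
#' mismatch admits a primer of degeneracy 4 (codes at the two common
#' positions only).  It illustrates how mismatch tolerance collapses the
#' degeneracy a primer needs.
#'
#' @return Character vector of ten named sequences; attributes \code{core}
#'   (the shared backbone) and \code{variant_positions}.
#' @export
example_ten_targets <- function() {
  core <- "ACGTACGTACGTACGTACGT"
  mut <- function(seq, pos, base) {
    ch <- strsplit(seq, "")[[1]]; ch[pos] <- base
    paste(ch, collapse = "")
  }
  a <- 5L; b <- 13L                      # common variant positions (A -> G)
  singles <- c(2L, 3L, 7L, 9L, 11L, 15L, 16L)
  sbase <- function(p) if (substr(core, p, p) == "T") "A" else "T"
  seqs <- c(
    t01 = mut(mut(core, a, "G"), singles[1], sbase(singles[1])),
    t02 = mut(mut(core, a, "G"), singles[2], sbase(singles[2])),
    t03 = mut(mut(core, a, "G"), singles[3], sbase(singles[3])),
    t04 = mut(mut(core, b, "G"), singles[4], sbase(singles[4])),
    t05 = mut(mut(core, b, "G"), singles[5], sbase(singles[5])),
    t06 = mut(mut(core, b, "G"), singles[6], sbase(singles[6])),
    t07 = mut(core, a, "G"),
    t08 = mut(core, b, "G"),
    t09 = mut(mut(core, a, "G"), b, "G"),
    t10 = mut(core, singles[7], sbase(singles[7])))
  attr(seqs, "core") <- core
  attr(seqs, "variant_positions") <- sort(c(a, b, singles))
  seqs
}

#' Degenerate primer / target worked example
#'
#' A published degenerate capsid primer (23 nt, degeneracy 192) paired
#' with a synthetic target constructed so that the literal symbol
#' (Hamming) distance is 6 while only one position -- the 17th -- carries a
#' base not contained in the primer's code.  It illustrates why literal
#' symbol comparison overstates the difference between a degenerate primer
#' and a near-perfect target, which the Y-distance corrects.
#'
#' @return List with \code{primer} and \code{target} (the target is
#'   synthetic, built for illustration).
#' @export
example_degenerate_mismatch <- function() {
  list(primer = "CCRCCNGCATRHCCRTTRTACAT",
       target = "CCACCNGCATGACCATCGTACAT")
}
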