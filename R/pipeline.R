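# Single-command pipeline: cluster -> align -> design -> pair -> combine ->
# evaluate, with TSV artifacts and a machine-readable run manifest.

#' Design candidate primers for one cluster
#'
#' Aligns the cluster subsample, scans primer-length windows on both
#' strands, filters them by entropy, designs degenerate primers for the
#' lowest-entropy windows, and annotates Tm statistics and plus-strand
#' coordinates on the representative.
#'
#' @param records Record data.frame covering the cluster members.
#' @param cluster A cluster object (with its \code{subsample} set).
#' @param config Validated parameter list.
#' @return List with \code{fwd} and \code{rev} candidate lists (see
#'   [enumerate_pairs()]) and \code{n_rows} (subsample size).
#' @export
design_cluster_candidates <- function(records, cluster,
                                      config = default_config()) {
  ids <- unique(c(cluster$representative, cluster$subsample))
  seqs <- stats::setNames(records$seq[match(ids, records$id)], ids)
  aln <- align_cluster(seqs, engine = config$aligner,
                       mafft_path = config$mafft_path)
  rep_len <- nchar(gsub("-", "", aln$rows[[1]], fixed = TRUE))
  out <- list(fwd = list(), rev = list())
  for (strand in c("+", "-")) {
    al <- if (strand == "+") aln else revcomp_alignment(aln)
    wins <- list()
    for (len in config$primer_len_min:config$primer_len_max) {
      ws <- extract_windows(al, len)
      ws <- Filter(function(w) w$entropy <= config$entropy_max, ws)
      wins <- c(wins, ws)
    }
    if (!length(wins)) next
    ent <- vapply(wins, `[[`, numeric(1), "entropy")
    st <- vapply(wins, `[[`, numeric(1), "start")
    ln <- vapply(wins, `[[`, numeric(1), "length")
    # Two-way diversified selection.  Within each primer length, windows
    # are taken in entropy order but capped per locus (no more than two
    # kept windows overlapping), so one well-conserved region cannot claim
    # the whole budget; lengths are then interleaved so every scanned
    # length stays represented (Tm matching across loci of different GC
    # content relies on length diversity).
    by_len <- lapply(sort(unique(ln)), function(l) {
      idx <- which(ln == l)
      idx <- idx[order(ent[idx], st[idx])]
      kept <- integer(0)
      for (i in idx) {
        n_over <- sum(st[kept] < st[i] + ln[i] & st[i] < st[kept] + ln[kept])
        if (n_over < 2L) kept <- c(kept, i)
      }
      kept
    })
    kept <- integer(0); r <- 1L
    while (length(kept) < config$max_windows && any(lengths(by_len) >= r)) {
      for (g in seq_along(by_len)) {
        if (length(by_len[[g]]) >= r) kept <- c(kept, by_len[[g]][r])
        if (length(kept) >= config$max_windows) break
      }
      r <- r + 1L
    }
    wins <- wins[kept]
    cands <- lapply(wins, function(w) {
      cand <- tryCatch(
        design_degenerate(w$seqs, config$max_mismatch, config$coordinate,
                          config$coverage_target, config$max_degeneracy)[[1]],
        error = function(e) NULL)
      if (is.null(cand)) return(NULL)
      covered <- unique(unlist(cand$strata, use.names = FALSE))
      start_plus <- if (strand == "+") w$rep_start else
        rep_len - (w$rep_start + w$length - 1L) + 1L
      tm <- tryCatch(tm_stats(cand$primer, config$salt_mM, config$oligo_nM),
                     error = function(e) list(tm_min = NA_real_,
                                              tm_max = NA_real_))
      list(primer = cand$primer, start = start_plus, length = w$length,
           strand = strand, coverage = cand$coverage, covered = covered,
           degeneracy = cand$degeneracy, entropy = w$entropy,
           tm_min = tm$tm_min, tm_max = tm$tm_max)
    })
    cands <- Filter(Negate(is.null), cands)
    if (strand == "+") out$fwd <- cands else out$rev <- cands
  }
  out$n_rows <- length(ids)
  out
}

.stage <- function(name, log, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  log(sprintf("stage %-10s %.1fs", name, proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full primer-panel design pipeline
#'
#' Executes clustering, per-cluster alignment and degenerate design, pair
#' enumeration, optional host-specificity screening, greedy set assembly,
#' and in-silico PCR evaluation over the full input, writing all artifacts
#' to \code{outdir}.  Re-runs with the same seed and input reproduce
#' byte-identical primer output files.
#'
#' @param input Path to the target multi-FASTA.
#' @param outdir Output directory (created).
#' @param config Named list of parameter overrides (see
#'   [default_config()]), or a validated list.
#' @param host Optional host FASTA path (overrides \code{config$host}).
#' @return Invisibly, a list with \code{set} (the \code{primer_set}),
#'   \code{evaluation}, \code{clusters} and \code{paths}.
#' @export
run_pipeline <- function(input, outdir, config = list(), host = NULL) {
  cfg <- validate_config(config)
  if (!is.null(host)) cfg$host <- host
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outdir, "run.log")
  cat("", file = logfile)
  log <- function(...) cat(paste0(..., "\n"), file = logfile, append = TRUE)
  timings <- list()

  records <- .stage("input", log, read_fasta(input))
  derep <- .stage("derep", log, dereplicate(records))
  clusters <- .stage("cluster", log,
                     cluster_by_identity(derep$records, cfg$identity))
  sizes <- stats::setNames(vapply(clusters, function(cl)
    length(cl$members), numeric(1)),
    vapply(clusters, `[[`, character(1), "cluster_id"))
  log(sprintf("%d records, %d after dereplication, %d clusters",
              nrow(records), nrow(derep$records), length(clusters)))

  keep <- if (isTRUE(cfg$drop))
    vapply(clusters, function(cl)
      length(cl$members) >= cfg$min_cluster_size, logical(1))
  else rep(TRUE, length(clusters))
  design_clusters <- clusters[keep]

  cluster_pairs <- .stage("design", log, {
    out <- list()
    for (i in seq_along(design_clusters)) {
      cl <- subsample_cluster(design_clusters[[i]], cfg$subsample_n,
                              seed = cfg$seed + i)
      cands <- design_cluster_candidates(derep$records, cl, cfg)
      if (!length(cands$fwd) || !length(cands$rev)) {
        log(sprintf("cluster %s: no candidates on one strand; uncovered",
                    cl$cluster_id))
        next
      }
      pairs <- tryCatch(
        enumerate_pairs(cands$fwd, cands$rev, cands$n_rows, cfg),
        error = function(e) NULL)
      if (is.null(pairs) || !nrow(pairs)) {
        log(sprintf("cluster %s: no valid pair; uncovered", cl$cluster_id))
        next
      }
      out[[cl$cluster_id]] <- pairs
    }
    out
  })
  if (!length(cluster_pairs))
    stop("stage 'design' failed: no cluster produced a valid primer pair",
         call. = FALSE)

  host_index <- NULL
  if (!is.null(cfg$host))
    host_index <- .stage("hostindex", log,
                         build_host_index(read_fasta(cfg$host)))

  pset <- .stage("combine", log,
                 greedy_combine(cluster_pairs, sizes, cfg, host_index))

  evaln <- .stage("evaluate", log, insilico_pcr(pset, records, cfg))

  paths <- .stage("write", log,
                  .write_artifacts(outdir, records, derep, clusters, pset,
                                   evaln, cfg))
  log(sprintf("overall in-silico coverage: %.4f", evaln$coverage))
  manifest <- list(
    config = cfg[!vapply(cfg, is.null, logical(1))],
    seed = cfg$seed,
    input = unname(tools::md5sum(input)),
    n_records = nrow(records),
    n_clusters = length(clusters),
    coverage = evaln$coverage,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("primerpanel")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(set = pset, evaluation = evaln, clusters = clusters,
                 records = records, paths = paths))
}

.write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.write_artifacts <- function(outdir, records, derep, clusters, pset, evaln,
                             cfg) {
  paths <- c()
  paths["clusters"] <- .write_tsv(clusters_to_table(clusters),
                                  file.path(outdir, "clusters.tsv"))
  if (nrow(derep$aliases))
    paths["aliases"] <- .write_tsv(derep$aliases,
                                   file.path(outdir, "aliases.tsv"))
  primer_rows <- function(pairs) {
    do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      data.frame(cluster_id = pairs$cluster_id[i], role = c("F", "R"),
                 sequence = c(pairs$fwd[i], pairs$rev[i]),
                 degeneracy = c(degeneracy(pairs$fwd[i]),
                                degeneracy(pairs$rev[i])),
                 product = pairs$product[i],
                 pair_coverage = pairs$coverage[i],
                 internal_loss = round(pairs$internal_loss[i], 4),
                 stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(pset$accepted))
    paths["final_set"] <- .write_tsv(primer_rows(pset$accepted),
                                     file.path(outdir, "final_set.tsv"))
  if (!is.null(pset$alternates))
    paths["alternates"] <- .write_tsv(primer_rows(pset$alternates),
                                      file.path(outdir, "alternates.tsv"))
  lm <- pset$loss_matrix
  if (length(lm)) {
    lmd <- data.frame(primer = rownames(lm), round(lm, 4),
                      check.names = FALSE)
    paths["loss_matrix"] <- .write_tsv(lmd,
                                       file.path(outdir, "loss_matrix.tsv"))
  }
  paths["accumulation"] <- .write_tsv(
    transform(evaln$accumulated,
              cumulative_coverage = round(cumulative_coverage, 6)),
    file.path(outdir, "accumulation.tsv"))
  cov_tab <- data.frame(target = names(evaln$covered),
                        covered = unname(evaln$covered))
  paths["coverage_report"] <- .write_tsv(cov_tab,
                                         file.path(outdir,
                                                   "coverage_report.tsv"))
  paths
}
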