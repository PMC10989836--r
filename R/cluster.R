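# FASTA ingestion, dereplication, greedy identity clustering, and
# per-cluster subsampling.

#' Read a nucleotide FASTA file
#'
#' Records are returned in file order with sequences normalized to
#' uppercase and U converted to T.  Duplicated ids are disambiguated
#' deterministically by appending \code{.2}, \code{.3}, ... with a warning.
#'
#' @param path Path to a (multi-)FASTA file.
#' @return A data.frame with columns \code{id}, \code{seq}, \code{length}.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("FASTA parse error in ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (length(set) == 0L)
    stop("FASTA file contains no records: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    warning("duplicated FASTA ids disambiguated: ",
            paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
    ids <- make.unique(ids, sep = ".")
  }
  seqs <- chartr("uU", "TT", toupper(as.character(set)))
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for record ", ids[which(nchar(seqs) == 0L)[1]],
         call. = FALSE)
  data.frame(id = ids, seq = unname(seqs), length = nchar(seqs),
             stringsAsFactors = FALSE)
}

#' Write records to FASTA
#'
#' @param records data.frame with columns \code{id} and \code{seq}.
#' @param path Output path.
#' @param width Line wrap width.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(records, path, width = 70L) {
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Collapse exact-duplicate sequences
#'
#' Identical sequences are collapsed to the first-seen record; the mapping
#' from collapsed (alias) ids to the kept representative is retained so
#' that downstream coverage accounting can re-expand it.  Strand-distinct
#' duplicates (reverse complements) are not collapsed.
#'
#' @param records data.frame as returned by [read_fasta()].
#' @return List with \code{records} (dereplicated data.frame) and
#'   \code{aliases} (data.frame \code{id}, \code{kept_id}; zero rows when
#'   all sequences are distinct).
#' @export
dereplicate <- function(records) {
  first <- !duplicated(records$seq)
  kept <- records[first, , drop = FALSE]
  key <- match(records$seq, kept$seq)
  aliases <- data.frame(id = records$id[!first],
                        kept_id = kept$id[key[!first]],
                        stringsAsFactors = FALSE)
  rownames(kept) <- NULL
  list(records = kept, aliases = aliases)
}

# Distinct k-mers of a sequence.
.kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

# Identity estimate between a sequence and a representative from the shared
# k-mer fraction f on the shorter sequence: a per-site identity p retains a
# k-mer with probability ~ p^k, so p is estimated as f^(1/k).
.kmer_identity <- function(km_query, km_ref, k) {
  if (!length(km_query)) return(0)
  f <- mean(km_query %in% km_ref)
  if (f <= 0) 0 else f^(1 / k)
}

#' Greedy identity-based clustering
#'
#' Records are sorted by length descending (ties by id) and assigned
#' incrementally: each record joins the first existing cluster whose
#' representative matches it at an estimated identity of at least
#' \code{identity}, otherwise it founds a new cluster.  Identity between a
#' record and a representative is estimated from the fraction of the
#' shorter sequence's k-mers shared with the representative (a per-site
#' identity \eqn{p} retains a k-mer with probability \eqn{p^k}).  The
#' procedure is deterministic given the input set.
#'
#' @param records Dereplicated data.frame of records.
#' @param identity Identity threshold in (0, 1].
#' @param k K-mer size for the identity estimate.
#' @return List of clusters; each is a list with \code{cluster_id},
#'   \code{representative} (id), \code{members} (character vector of ids)
#'   and \code{subsample} (ids used for alignment; initially all members).
#' @export
cluster_by_identity <- function(records, identity = 0.8, k = 12L) {
  stopifnot(identity > 0, identity <= 1)
  ord <- order(-records$length, records$id)
  recs <- records[ord, , drop = FALSE]
  reps_km <- list()
  reps_id <- character(0)
  membership <- integer(nrow(recs))
  km_cache <- lapply(recs$seq, .kmer_set, k = k)
  for (i in seq_len(nrow(recs))) {
    kmi <- km_cache[[i]]
    placed <- FALSE
    for (ci in seq_along(reps_id)) {
      # the query is never longer than the representative (length order)
      if (.kmer_identity(kmi, reps_km[[ci]], k) >= identity) {
        membership[i] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps_km[[length(reps_km) + 1L]] <- kmi
      reps_id <- c(reps_id, recs$id[i])
      membership[i] <- length(reps_id)
    }
  }
  lapply(seq_along(reps_id), function(ci) {
    members <- recs$id[membership == ci]
    structure(list(cluster_id = sprintf("C%03d", ci),
                   representative = reps_id[ci],
                   members = members,
                   subsample = members),
              class = "primer_cluster")
  })
}

#' Subsample a cluster for alignment
#'
#' Keeps all members when the cluster is small; otherwise draws a uniform,
#' seed-reproducible sample of size \code{n} that always includes the
#' representative.
#'
#' @param cluster A cluster from [cluster_by_identity()].
#' @param n Maximum number of sequences to keep.
#' @param seed Integer seed.
#' @return The cluster with its \code{subsample} field set.
#' @export
subsample_cluster <- function(cluster, n = 500L, seed = 1L) {
  stopifnot(n >= 1)
  m <- cluster$members
  if (length(m) <= n) {
    cluster$subsample <- m
    return(cluster)
  }
  others <- setdiff(m, cluster$representative)
  picked <- .with_seed(seed, sample(others, n - 1L))
  cluster$subsample <- c(cluster$representative, picked)
  cluster
}

#' Estimate within-cluster identity
#'
#' Mean estimated identity between up to \code{n} sampled members and the
#' cluster representative, mirroring a quick average-identity validation
#' pass over each cluster.
#'
#' @param cluster A cluster object.
#' @param records Record data.frame covering the cluster members.
#' @param n Number of members to sample.
#' @param k K-mer size.
#' @param seed Integer seed for the sample.
#' @return Numeric scalar in [0, 1] (1 for singleton clusters).
#' @export
cluster_identity_estimate <- function(cluster, records, n = 60L, k = 12L,
                                      seed = 1L) {
  others <- setdiff(cluster$members, cluster$representative)
  if (!length(others)) return(1)
  if (length(others) > n)
    others <- .with_seed(seed, sample(others, n))
  rep_seq <- records$seq[match(cluster$representative, records$id)]
  km_rep <- .kmer_set(rep_seq, k)
  mean(vapply(others, function(id) {
    s <- records$seq[match(id, records$id)]
    .kmer_identity(.kmer_set(s, k), km_rep, k)
  }, numeric(1)))
}

#' Cluster table as a data.frame
#'
#' @param clusters List of clusters.
#' @return data.frame with columns \code{cluster_id}, \code{representative},
#'   \code{member_id}; writable/readable as the cluster-table TSV.
#' @export
clusters_to_table <- function(clusters) {
  do.call(rbind, lapply(clusters, function(cl)
    data.frame(cluster_id = cl$cluster_id,
               representative = cl$representative,
               member_id = cl$members, stringsAsFactors = FALSE)))
}

#' Rebuild clusters from a cluster table
#'
#' Accepts externally produced cluster assignments (TSV with columns
#' \code{cluster_id}, \code{representative}, \code{member_id}).
#'
#' @param tab data.frame in the [clusters_to_table()] layout.
#' @return List of cluster objects.
#' @export
table_to_clusters <- function(tab) {
  lapply(split(tab, tab$cluster_id), function(d) {
    structure(list(cluster_id = d$cluster_id[1],
                   representative = d$representative[1],
                   members = d$member_id,
                   subsample = d$member_id),
              class = "primer_cluster")
  })
}
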