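# Candidate primer-pair formation, host specificity screening, and greedy
# assembly of the minimal compatible intercluster primer set.

#' Enumerate candidate primer pairs for a cluster
#'
#' Combines forward (plus-strand) and reverse (minus-strand) candidate
#' primers, keeping combinations whose product on the representative lies
#' within the configured size range, whose Tm difference is within
#' \code{tm_diff_max}, and whose internal dimer loss (forward-reverse and
#' both self-dimers, worst case) is below \code{loss_high}.  Pairs are
#' ranked by pair coverage (descending), total degeneracy (ascending) and
#' internal loss (ascending).
#'
#' Each candidate is a list with fields \code{primer}, \code{start}
#' (1-based, plus strand, of the site's 5'-most base on the
#' representative), \code{length}, \code{coverage}, \code{covered}
#' (character vector of covered row ids), \code{degeneracy}, \code{tm_min},
#' \code{tm_max}.  For reverse candidates \code{start} refers to the
#' plus-strand position of the site's leftmost base.
#'
#' @param fwd,rev Lists of forward / reverse candidates.
#' @param n_rows Number of rows used for coverage (cluster subsample size).
#' @param params Parameter list, see [default_config()]; uses
#'   \code{min_product}, \code{max_product}, \code{tm_diff_max},
#'   \code{loss_high}, \code{loss_low}, \code{min_run},
#'   \code{dimer_expansion_cap}, \code{max_pairs_per_cluster}.
#' @return data.frame of ranked pairs with a \code{covered} list-column of
#'   row ids amplified by both primers.
#' @export
enumerate_pairs <- function(fwd, rev, n_rows, params = default_config()) {
  if (!length(fwd) || !length(rev))
    stop("cluster has no forward or no reverse candidates", call. = FALSE)
  combos <- expand.grid(f = seq_along(fwd), r = seq_along(rev))
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    F <- fwd[[combos$f[i]]]; R <- rev[[combos$r[i]]]
    rev_left <- R$start
    rev_right <- R$start + R$length - 1L
    product <- rev_right - F$start + 1L
    if (is.na(product) || product < params$min_product ||
        product > params$max_product) return(NULL)
    if (F$start + F$length - 1L >= rev_left) return(NULL)  # overlap
    # midpoint Tm of each primer's expansion range
    dtm <- abs((F$tm_min + F$tm_max) / 2 - (R$tm_min + R$tm_max) / 2)
    if (dtm > params$tm_diff_max) return(NULL)
    covered <- intersect(F$covered, R$covered)
    data.frame(fwd = F$primer, rev = R$primer,
               fwd_start = F$start, rev_end = rev_right,
               product = product, tm_diff = dtm,
               coverage = length(covered) / n_rows,
               total_degeneracy = F$degeneracy + R$degeneracy,
               covered = I(list(covered)),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(fwd = character(0), rev = character(0),
                      fwd_start = integer(0), rev_end = integer(0),
                      product = integer(0), tm_diff = numeric(0),
                      coverage = numeric(0), total_degeneracy = numeric(0),
                      internal_loss = numeric(0)))
  d <- do.call(rbind, rows)
  d <- d[order(-d$coverage, d$total_degeneracy), , drop = FALSE]
  # dimer vetting walks the ranking lazily (self-dimer losses cached per
  # primer) and stops once the per-cluster shortlist is full
  self_cache <- new.env(parent = emptyenv())
  self_loss <- function(p) {
    if (is.null(self_cache[[p]]))
      self_cache[[p]] <- pair_loss(p, p, params$min_run,
                                   params$dimer_expansion_cap)
    self_cache[[p]]
  }
  keep <- integer(0)
  loss <- numeric(0)
  for (i in seq_len(nrow(d))) {
    il <- max(self_loss(d$fwd[i]), self_loss(d$rev[i]))
    if (il < params$loss_high)
      il <- max(il, pair_loss(d$fwd[i], d$rev[i], params$min_run,
                              params$dimer_expansion_cap))
    if (il < params$loss_high) {
      keep <- c(keep, i)
      loss <- c(loss, il)
      if (length(keep) >= params$max_pairs_per_cluster) break
    }
  }
  d <- d[keep, , drop = FALSE]
  d$internal_loss <- loss
  d <- d[order(-d$coverage, d$total_degeneracy, d$internal_loss), ,
         drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Build a host k-mer seed index
#'
#' Indexes every k-mer of both strands of the host sequences with its
#' (sequence id, offset, strand) so that a primer's 3'-terminal 9-mer can
#' seed candidate off-target sites in O(1).
#'
#' @param host data.frame of host records (\code{id}, \code{seq}).
#' @param k Seed length (default 9, the 3'-terminal seed width).
#' @return Object of class \code{host_index}: environment-backed hash of
#'   k-mer -> data.frame(id, pos, strand), plus host sequences.
#' @export
build_host_index <- function(host, k = 9L) {
  env <- new.env(parent = emptyenv(), size = 4096L)
  seqs <- stats::setNames(host$seq, host$id)
  for (id in host$id) {
    s <- seqs[[id]]
    n <- nchar(s)
    if (n < k) next
    for (strand in c("+", "-")) {
      txt <- if (strand == "+") s else revcomp(s)
      kms <- substring(txt, 1:(n - k + 1L), k:n)
      for (p in seq_along(kms)) {
        key <- kms[p]
        hit <- data.frame(id = id, pos = p, strand = strand,
                          stringsAsFactors = FALSE)
        env[[key]] <- if (is.null(env[[key]])) hit else rbind(env[[key]], hit)
      }
    }
  }
  structure(list(table = env, seqs = seqs, k = k), class = "host_index")
}

#' Query a host index for a k-mer
#'
#' @param index A \code{host_index}.
#' @param kmer Character scalar of length \code{index$k}.
#' @return data.frame(id, pos, strand); zero rows when absent.
#' @export
query_host_index <- function(index, kmer) {
  hit <- index$table[[kmer]]
  if (is.null(hit))
    data.frame(id = character(0), pos = integer(0), strand = character(0))
  else hit
}

# All verified sites of one primer on the host: the 3'-terminal k-mer must
# match exactly (seed), and the full primer must match with at most
# `max_mismatch` mismatches, all located at least `protect` bases from the
# primer's 3' end.  Returns plus-strand site intervals with orientation.
.host_sites <- function(primer, index, max_mismatch = 1L, protect = 4L,
                        expansion_cap = 64L) {
  L <- nchar(primer)
  k <- index$k
  tail_k <- substr(primer, L - k + 1L, L)
  seeds <- unique(expand_primer(tail_k, cap = expansion_cap))
  out <- list()
  for (sd in seeds) {
    hits <- query_host_index(index, sd)
    if (!nrow(hits)) next
    for (h in seq_len(nrow(hits))) {
      id <- hits$id[h]; pos <- hits$pos[h]; strand <- hits$strand[h]
      txt <- if (strand == "+") index$seqs[[id]] else revcomp(index$seqs[[id]])
      start <- pos + k - L            # full-site start in strand coords
      if (start < 1L) next
      site <- substr(txt, start, pos + k - 1L)
      yd <- y_distance(primer, site)
      if (!accept_mismatches(yd, max_mismatch, protect, L)) next
      n <- nchar(index$seqs[[id]])
      if (strand == "+") {
        left <- start; right <- pos + k - 1L
      } else {
        left <- n - (pos + k - 1L) + 1L; right <- n - start + 1L
      }
      out[[length(out) + 1L]] <-
        data.frame(id = id, left = left, right = right, strand = strand,
                   mismatches = length(yd), stringsAsFactors = FALSE)
    }
  }
  if (length(out)) unique(do.call(rbind, out)) else
    data.frame(id = character(0), left = integer(0), right = integer(0),
               strand = character(0), mismatches = integer(0))
}

#' Host specificity screen of a primer pair
#'
#' Seeds each primer's 3'-terminal 9-mer against the host index, verifies
#' full-length sites allowing at most one mismatch located at least 4 nt
#' from the 3' end, and counts one off-target unit per host locus where a
#' plus-strand site and a downstream minus-strand site (from either primer)
#' face each other within the product-size cap.
#'
#' @param fwd,rev Primer strings.
#' @param index A \code{host_index}.
#' @param max_product Maximum amplifiable product size in the host.
#' @param max_mismatch,protect Site verification rules.
#' @return List with \code{units} (integer count) and \code{loci}
#'   (data.frame: id, fwd_left, rev_right, product).
#' @export
specificity_screen <- function(fwd, rev, index, max_product = 1500L,
                               max_mismatch = 1L, protect = 4L) {
  sites <- rbind(.host_sites(fwd, index, max_mismatch, protect),
                 .host_sites(rev, index, max_mismatch, protect))
  loci <- list()
  if (nrow(sites)) {
    plus <- sites[sites$strand == "+", , drop = FALSE]
    minus <- sites[sites$strand == "-", , drop = FALSE]
    if (nrow(plus) && nrow(minus)) {
      for (i in seq_len(nrow(plus))) for (j in seq_len(nrow(minus))) {
        if (plus$id[i] != minus$id[j]) next
        if (minus$left[j] <= plus$left[i]) next
        product <- minus$right[j] - plus$left[i] + 1L
        if (product > max_product) next
        if (product < plus$right[i] - plus$left[i] + 1L) next
        loci[[length(loci) + 1L]] <-
          data.frame(id = plus$id[i], fwd_left = plus$left[i],
                     rev_right = minus$right[j], product = product,
                     stringsAsFactors = FALSE)
      }
    }
  }
  loci <- if (length(loci)) unique(do.call(rbind, loci)) else
    data.frame(id = character(0), fwd_left = integer(0),
               rev_right = integer(0), product = integer(0))
  list(units = nrow(loci), loci = loci)
}

#' Greedily combine per-cluster pairs into one compatible primer set
#'
#' Clusters are processed in decreasing size order (ties by cluster id).
#' For each cluster the highest-ranked pair is accepted whose primers all
#' have dimer loss below \code{loss_high} (or \code{<= loss_low} in strict
#' mode) against every already-accepted primer, and at most
#' \code{max_offtarget} host units when a host index is supplied; on
#' failure the next-ranked pair is tried.  A cluster whose pairs are
#' exhausted enters the set uncovered, its best pair exported as a
#' cluster-specific alternate.  Remaining vetted pairs are exported as
#' alternates.
#'
#' @param cluster_pairs Named list (cluster_id -> ranked pair data.frame
#'   from [enumerate_pairs()]).
#' @param cluster_sizes Named integer vector of cluster sizes.
#' @param params Parameter list; uses \code{loss_high}, \code{loss_low},
#'   \code{dimer_strict}, \code{min_run}, \code{dimer_expansion_cap},
#'   \code{max_offtarget}, \code{max_alternates}, \code{max_product}.
#' @param host_index Optional \code{host_index} for specificity screening.
#' @return Object of class \code{primer_set}: list with \code{accepted}
#'   (data.frame, one row per covered cluster, in acceptance order),
#'   \code{alternates}, \code{uncovered} (cluster ids), and
#'   \code{loss_matrix} (pairwise loss audit over all accepted primers).
#' @export
greedy_combine <- function(cluster_pairs, cluster_sizes,
                           params = default_config(), host_index = NULL) {
  if (!length(cluster_pairs)) stop("no cluster pairs supplied", call. = FALSE)
  ids <- names(cluster_pairs)
  ord <- ids[order(-cluster_sizes[ids], ids)]
  limit <- if (isTRUE(params$dimer_strict)) params$loss_low else
    params$loss_high
  cmp <- if (isTRUE(params$dimer_strict))
    function(l) l <= limit else function(l) l < limit
  accepted <- list()
  accepted_primers <- character(0)
  alternates <- list()
  uncovered <- character(0)
  for (cid in ord) {
    pairs <- cluster_pairs[[cid]]
    chosen <- NULL
    vetted <- integer(0)
    if (nrow(pairs)) for (i in seq_len(nrow(pairs))) {
      ok <- TRUE
      for (p in c(pairs$fwd[i], pairs$rev[i])) {
        for (q in accepted_primers) {
          if (!cmp(pair_loss(p, q, params$min_run,
                             params$dimer_expansion_cap))) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok && !is.null(host_index)) {
        units <- specificity_screen(pairs$fwd[i], pairs$rev[i], host_index,
                                    params$max_product)$units
        if (units > params$max_offtarget) ok <- FALSE
      }
      if (ok && is.null(chosen)) {
        chosen <- i
      } else if (ok) {
        vetted <- c(vetted, i)
      }
      if (!is.null(chosen) && length(vetted) >= params$max_alternates) break
    }
    if (is.null(chosen)) {
      uncovered <- c(uncovered, cid)
      if (nrow(pairs)) {
        alt <- pairs[1, , drop = FALSE]; alt$cluster_id <- cid
        alternates[[length(alternates) + 1L]] <- alt
      }
      next
    }
    acc <- pairs[chosen, , drop = FALSE]
    acc$cluster_id <- cid
    accepted[[length(accepted) + 1L]] <- acc
    accepted_primers <- c(accepted_primers,
                          stats::setNames(acc$fwd, paste0(cid, "_F")),
                          stats::setNames(acc$rev, paste0(cid, "_R")))
    if (length(vetted)) {
      alt <- pairs[vetted, , drop = FALSE]; alt$cluster_id <- cid
      alternates[[length(alternates) + 1L]] <- alt
    }
  }
  accepted <- if (length(accepted)) do.call(rbind, accepted) else NULL
  alternates <- if (length(alternates)) do.call(rbind, alternates) else NULL
  lm <- loss_matrix(accepted_primers, params)
  structure(list(accepted = accepted, alternates = alternates,
                 uncovered = uncovered, primers = accepted_primers,
                 loss_matrix = lm),
            class = "primer_set")
}

#' Pairwise dimer-loss matrix over a primer pool
#'
#' Independent audit of a primer set: the headline loss for every ordered
#' primer pair (including self-dimers on the diagonal).
#'
#' @param primers Named character vector of primers.
#' @param params Parameter list (uses \code{min_run},
#'   \code{dimer_expansion_cap}).
#' @return Numeric matrix of losses (-Inf when no complementary run).
#' @export
loss_matrix <- function(primers, params = default_config()) {
  n <- length(primers)
  m <- matrix(-Inf, n, n, dimnames = list(names(primers), names(primers)))
  if (n == 0) return(m)
  for (i in seq_len(n)) for (j in i:n) {
    l <- pair_loss(primers[[i]], primers[[j]], params$min_run,
                   params$dimer_expansion_cap)
    m[i, j] <- l; m[j, i] <- l
  }
  m
}
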