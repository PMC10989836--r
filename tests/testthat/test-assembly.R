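# Pair enumeration, host seed index, specificity screen, greedy assembly.

make_cand <- function(primer, start, coverage, covered, strand = "+",
                      tm = 55) {
  list(primer = primer, start = start, length = nchar(primer),
       strand = strand, coverage = coverage, covered = covered,
       degeneracy = degeneracy(primer), tm_min = tm, tm_max = tm)
}

test_that("pair enumeration filters by product size and Tm and ranks by
           coverage", {
  cfg <- default_config()
  ids <- sprintf("r%02d", 1:10)
  fwd <- list(
    make_cand("ACGTTGCAACGGATCATCAG", 10, 1.0, ids),
    make_cand("ACGTTGCAACGGATCATCAT", 12, 0.8, ids[1:8]))
  rev <- list(
    make_cand("TGCAATCGGATATTGCCAGT", 300, 1.0, ids),
    # product far beyond range
    make_cand("TGCAATCGGATATTGCATGT", 5000, 1.0, ids),
    # Tm far off
    make_cand("TGCAATCGGATATTGCACGT", 300, 1.0, ids, tm = 80))
  pairs <- enumerate_pairs(fwd, rev, 10, cfg)
  expect_true(all(pairs$product <= cfg$max_product))
  expect_true(all(pairs$tm_diff <= cfg$tm_diff_max))
  expect_equal(pairs$coverage[1], 1.0)
  # ranking oracle: independent re-sort
  expect_identical(order(-pairs$coverage, pairs$total_degeneracy,
                         pairs$internal_loss),
                   seq_len(nrow(pairs)))
  expect_error(enumerate_pairs(list(), rev, 10, cfg), "no forward")
})

test_that("the host index stores every k-mer of both strands", {
  set.seed(17)
  host <- data.frame(id = "h1", seq = random_dna(100))
  idx <- build_host_index(host, k = 9)
  # 100 - 9 + 1 = 92 plus-strand positions indexed
  n_plus <- sum(vapply(ls(idx$table), function(k)
    sum(idx$table[[k]]$strand == "+"), numeric(1)))
  expect_equal(n_plus, 92)
  # absent k-mer: empty hit set
  expect_equal(nrow(query_host_index(idx, "NNNNNNNNN")), 0L)
  # positions agree with a naive scan
  host2 <- data.frame(id = "h2", seq = random_dna(1000))
  idx2 <- build_host_index(host2, k = 9)
  for (i in 1:20) {
    p <- sample(992, 1)
    km <- substr(host2$seq, p, p + 8)
    hits <- query_host_index(idx2, km)
    expect_setequal(hits$pos[hits$strand == "+"],
                    oracle_kmer_positions(host2$seq, km))
  }
})

test_that("the specificity screen counts planted amplifiable loci", {
  set.seed(18)
  fwd <- random_dna(20); rev <- random_dna(20)
  insert <- paste0(fwd, random_dna(200), revcomp(rev))
  host <- data.frame(
    id = c("bg", "planted"),
    seq = c(random_dna(2000),
            paste0(random_dna(700), insert, random_dna(1060))))
  idx <- build_host_index(host, k = 9)
  res <- specificity_screen(fwd, rev, idx, max_product = 1500)
  expect_gte(res$units, 1L)
  expect_true(all(res$loci$id == "planted"))
  expect_equal(res$loci$fwd_left[1], 701L)
  expect_equal(res$loci$product[1], 240L)
  # a host sharing no 9-mer with either primer yields zero units
  clean <- data.frame(id = "c", seq = paste(rep("AC", 500), collapse = ""))
  idx_clean <- build_host_index(clean, k = 9)
  expect_equal(specificity_screen(fwd, rev, idx_clean, 1500)$units, 0L)
})

test_that("greedy combination keeps compatible pairs in size order and
           falls back on dimer conflict", {
  cfg <- default_config()
  ids <- sprintf("r%02d", 1:10)
  mk_pairs <- function(fwd, rev, coverage = 1) {
    F <- make_cand(fwd, 10, coverage, ids)
    R <- make_cand(rev, 300, coverage, ids)
    enumerate_pairs(list(F), list(R), 10, cfg)
  }
  # mutually compatible one-pair clusters: all accepted, size order
  pairs <- list(
    A = mk_pairs("ATCGTAGCATCAGCATTACG", "TGGATCAGATTCACAGTAGA"),
    B = mk_pairs("CATTAGACCAGATACAGTGG", "ACCTTGAGTGTCAGATGGAT"),
    C = mk_pairs("GATTACAGGATCATGACTGG", "TGATAGACAGGTTGACTGTG"))
  sizes <- c(A = 5, B = 50, C = 20)
  pset <- greedy_combine(pairs, sizes, cfg)
  expect_equal(pset$accepted$cluster_id, c("B", "C", "A"))
  expect_length(pset$uncovered, 0L)
  expect_lt(max(pset$loss_matrix), cfg$loss_high)

  # engineer a high-risk conflict: cluster D's top pair carries the exact
  # reverse complement of an accepted primer; its rank-2 pair is benign
  clash <- revcomp("ATCGTAGCATCAGCATTACG")
  benign <- "TTGGACTGTACTCACAGACA"
  F1 <- make_cand(clash, 10, 1.0, ids)
  F2 <- make_cand(benign, 12, 0.9, ids[1:9])
  R <- make_cand("AGGATGACAGTTACAGGTTC", 300, 1.0, ids)
  d_pairs <- enumerate_pairs(list(F1, F2), list(R), 10, cfg)
  expect_equal(d_pairs$fwd[1], clash)   # clash ranks first internally
  pairs$D <- d_pairs
  sizes["D"] <- 1
  pset2 <- greedy_combine(pairs, sizes, cfg)
  acc_d <- pset2$accepted[pset2$accepted$cluster_id == "D", ]
  expect_equal(acc_d$fwd, benign)
  # post-condition audit: the accepted set is dimer-compatible throughout
  expect_lt(max(pset2$loss_matrix), cfg$loss_high)
})

test_that("greedy assembly is deterministic and incremental", {
  cfg <- default_config()
  ids <- sprintf("r%02d", 1:10)
  mk_pairs <- function(fwd, rev) {
    enumerate_pairs(list(make_cand(fwd, 10, 1, ids)),
                    list(make_cand(rev, 300, 1, ids)), 10, cfg)
  }
  pairs <- list(
    A = mk_pairs("ATCGTAGCATCAGCATTACG", "TGGATCAGATTCACAGTAGA"),
    B = mk_pairs("CATTAGACCAGATACAGTGG", "ACCTTGAGTGTCAGATGGAT"))
  sizes <- c(A = 5, B = 50, C = 20)
  p1 <- greedy_combine(pairs, sizes, cfg)
  p2 <- greedy_combine(pairs, sizes, cfg)
  expect_identical(p1$accepted, p2$accepted)
  # adding a cluster never removes previously accepted pairs
  pairs$C <- mk_pairs("GATTACAGGATCATGACTGG", "TGATAGACAGGTTGACTGTG")
  p3 <- greedy_combine(pairs, sizes, cfg)
  for (cid in p1$accepted$cluster_id)
    expect_true(cid %in% p3$accepted$cluster_id)
  keep3 <- p3$accepted[p3$accepted$cluster_id %in% c("A", "B"),
                       c("fwd", "rev")]
  expect_equal(keep3, p1$accepted[, c("fwd", "rev")],
               ignore_attr = TRUE)
})

test_that("dimer vetting during assembly reduces high-risk pairs versus a
           naive top-rank combination", {
  set.seed(19)
  cfg <- default_config()
  ids <- sprintf("r%02d", 1:10)
  # 12 clusters; each cluster's top-ranked pair carries an engineered
  # complementary 3' tail (dimer-prone), its runner-up is a clean primer
  tail_seq <- "GGGCCC"
  pairs <- list(); sizes <- c(); naive <- character(0)
  for (i in 1:12) {
    risky <- paste0(random_dna(14), tail_seq)
    clean1 <- random_dna(20)
    F1 <- make_cand(risky, 10, 1.0, ids)
    F2 <- make_cand(clean1, 12, 0.9, ids[1:9])
    rev_p <- random_dna(20)
    R <- make_cand(rev_p, 300, 1.0, ids)
    # naive combination takes the top-coverage pair with no dimer check
    naive <- c(naive, risky, rev_p)
    p <- enumerate_pairs(list(F1, F2), list(R), 10, cfg)
    if (!nrow(p)) next
    cid <- sprintf("K%02d", i)
    pairs[[cid]] <- p
    sizes[cid] <- 13 - i
  }
  pset <- greedy_combine(pairs, sizes, cfg)
  audited <- pset$loss_matrix
  frac_high <- function(primers) {
    n <- length(primers); cnt <- 0; tot <- 0
    for (a in seq_len(n)) for (b in a:n) {
      tot <- tot + 1
      if (pair_loss(primers[a], primers[b]) >= cfg$loss_high) cnt <- cnt + 1
    }
    cnt / tot
  }
  vetted <- pset$primers
  expect_lt(max(audited), cfg$loss_high)
  # the engineered complementary tails make the naive panel dimer-ridden;
  # assembly with dimer examination eliminates high-risk pairs
  expect_gt(frac_high(naive), 0.1)
  expect_lt(frac_high(vetted), frac_high(naive))
})
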