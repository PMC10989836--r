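# Dimer loss function, complementary-run scanning, risk classes, Tm.

test_that("the loss function reproduces its closed form", {
  # log10(2^5 * 2^3 / (2^0-0.9)^2) = log10(256/0.01)
  expect_equal(dimer_loss(5, 3, 0, 0), log10(256 / 0.01), tolerance = 1e-12)
  expect_equal(dimer_loss(5, 3, 0, 0), 4.4082, tolerance = 1e-4)
  expect_equal(dimer_loss(4, 2, 5, 6), log10(64 / (31.1 * 63.1)),
               tolerance = 1e-12)
  expect_equal(dimer_loss(4, 2, 5, 6), -1.4866, tolerance = 1e-4)
})

test_that("the loss is monotone on a parameter grid", {
  for (len in 4:8) for (gc in 0:3) for (d in 0:4) {
    # increasing run length or GC strictly increases loss
    expect_gt(dimer_loss(len + 1, gc, d, d), dimer_loss(len, gc, d, d))
    expect_gt(dimer_loss(len, gc + 1, d, d), dimer_loss(len, gc, d, d))
    # increasing either distance strictly decreases it
    expect_lt(dimer_loss(len, gc, d + 1, d), dimer_loss(len, gc, d, d))
    expect_lt(dimer_loss(len, gc, d, d + 1), dimer_loss(len, gc, d, d))
  }
})

test_that("risk classification matches the thresholds", {
  expect_equal(classify_dimer(4.41), "high")
  expect_equal(classify_dimer(-1.49), "low")
  expect_equal(classify_dimer(3.5), "medium")
  expect_equal(classify_dimer(3.96), "high")
  expect_equal(classify_dimer(3.0), "low")
})

test_that("dimer scanning finds forced geometries", {
  p <- "AAAAACCCGGAAAAA"
  hits <- scan_dimer(p, revcomp(p))
  # a primer against its exact reverse complement: full-length run at
  # zero distance from both 3' ends, the maximal possible loss
  expect_equal(max(hits$run_length), nchar(p))
  top <- hits[which.max(hits$loss), ]
  expect_equal(top$distance1, 0L)
  expect_equal(top$distance2, 0L)
  expect_equal(top$loss, dimer_loss(15, 5, 0, 0))
  # no complementarity at all
  none <- scan_dimer(paste(rep("A", 20), collapse = ""),
                     paste(rep("C", 20), collapse = ""))
  expect_equal(nrow(none), 0L)
  expect_equal(attr(none, "loss_max"), -Inf)
})

test_that("dimer scanning equals brute-force run enumeration and is
           symmetric", {
  set.seed(15)
  for (i in 1:10) {
    x <- random_dna(20); y <- random_dna(20)
    got <- scan_dimer(x, y, min_run = 4)
    oracle <- oracle_dimer(x, y, 4)
    key <- function(d) sort(do.call(paste,
      c(d[c("run_length", "gc_count", "distance1", "distance2")], sep = ":")))
    expect_identical(key(got), key(oracle))
    # symmetry: (a, b) maps to (b, a) with the distances swapped
    swapped <- scan_dimer(y, x, min_run = 4)
    key_sw <- sort(do.call(paste, c(list(swapped$run_length,
                                         swapped$gc_count,
                                         swapped$distance2,
                                         swapped$distance1), sep = ":")))
    expect_identical(key(got), key_sw)
  }
})

test_that("degenerate primers are scanned over their expansions,
           worst case first", {
  # R expands to A or G; only the G member forms the GGGG/CCCC run
  a <- "TTTTTTTTTTTTGRGG"
  b <- "TTTTTTTTTTTTCCCC"
  hits <- scan_dimer(a, b, min_run = 4, expansion_cap = 4)
  expect_gte(attr(hits, "loss_max"), dimer_loss(4, 4, 0, 0) - 1e-9)
})

test_that("the dimer ratio is a non-increasing step function on [0, 1]", {
  losses <- c(-2, 0.5, 1.2, 3.1, 4.4, 4.4, 6)
  expect_equal(dimer_ratio(-10, losses), 1)
  expect_equal(dimer_ratio(10, losses), 0)
  expect_equal(dimer_ratio(3.0, losses), 4 / 7)   # counting oracle
  expect_equal(dimer_ratio(4.4, losses), 1 / 7)   # strict inequality
  grid <- seq(-3, 7, by = 0.25)
  vals <- vapply(grid, dimer_ratio, numeric(1), dimer_losses = losses)
  expect_true(all(diff(vals) <= 0))
  expect_true(all(vals >= 0 & vals <= 1))
  expect_error(dimer_ratio(1, numeric(0)), "empty")
})

test_that("nearest-neighbour Tm matches an independent reference
           calculator", {
  # frozen values from a published NN implementation under identical
  # conditions (unified parameters, 50 mM Na+, 50 nM total oligo)
  ref <- c(ACGTACGTACGTACGTACGT = 53.0967, ATATATATATATATATATAT = 24.1928,
           GCGCGCGCGCGCGCGCGCGC = 77.1644, AGGCTTACGATCGGATCCAT = 52.4878,
           TTGACCTAGGCATCAGTACA = 49.6848, CCGGAATTCCGGAATTCCGG = 55.4094,
           ACACACACACACACACACAC = 53.4323, GATTACAGATTACAGATTAC = 40.3457,
           TGCATGCATGCATGCATGCA = 56.7738, AAGGTTCCAAGGTTCCAAGG = 51.7012)
  for (s in names(ref))
    expect_equal(primer_tm(s), unname(ref[s]), tolerance = 0.5)
})

test_that("Tm is duplex-symmetric and GC-monotone", {
  set.seed(16)
  for (i in 1:5) {
    s <- random_dna(20)
    expect_equal(primer_tm(s), primer_tm(revcomp(s)), tolerance = 1e-9)
  }
  # replacing an A/T pair by G/C raises Tm
  low <- "ATATATGGCCATATATACAT"
  high <- "ATATATGGCCATATATACGC"
  expect_gt(primer_tm(high), primer_tm(low))
  expect_error(primer_tm("ACGTACG"), "too short")
  expect_error(primer_tm("ACGTACGTACGTACGTACRT"), "plain")
})

test_that("Tm statistics of degenerate primers bracket their expansion", {
  st <- tm_stats("ACGTACGTACRTACGTACGT")
  expect_lte(st$tm_min, st$tm_max)
  members <- expand_primer("ACGTACGTACRTACGTACGT")
  tms <- vapply(members, primer_tm, numeric(1))
  expect_equal(st$tm_min, min(tms))
  expect_equal(st$tm_max, max(tms))
  expect_lte(st$gc_min, st$gc_max)
})
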