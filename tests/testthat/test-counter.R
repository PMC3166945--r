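toy_cfg <- function(...) count_config(n_kmers = 16, k = 3, ...)

test_that("pass 1 stages singletons in the filter and tables repeats", {
  p1 <- count_pass1(c("ACGT", "ACGT"), toy_cfg())
  expect_identical(p1$table$kmer, "ACG") # tabled on its 2nd observation
  expect_identical(p1$table$count, 0L)   # placeholder until pass 2
  expect_equal(p1$stats$n_occurrences, 4)

  p1 <- count_pass1("ACGTA", count_config(n_kmers = 16, k = 5))
  expect_equal(nrow(p1$table), 0L) # single occurrence stays in the filter
})

test_that("pass 2 recounts tabled k-mers exactly and prunes the cutoff", {
  reads <- c("ACGT", "ACGT")
  p1 <- count_pass1(reads, toy_cfg())
  out <- count_pass2(reads, p1$table, cutoff = 2)
  expect_identical(as_plain(out), data.frame(kmer = "ACG", count = 4L))
  # a staged false-positive singleton is removed
  fake <- kmer_table(c("ACG", "AAA"), c(0L, 0L), k = 3)
  out <- count_pass2(c(reads, "AAAT"), fake, cutoff = 2)
  expect_false("AAA" %in% out$kmer) # "AAA" occurs once -> pruned
  expect_equal(attr(out, "stats")$n_removed, 1)
})

test_that("exact counting matches the hand-traced example", {
  tab <- count_exact(c("ACGT", "ACGT", "TTTT"), toy_cfg())
  expect_identical(tab$kmer, c("AAA", "ACG")) # "TTT" canonicalizes to "AAA"
  expect_identical(tab$count, c(2L, 4L))
  # all-unique input gives an empty table
  tab <- count_exact("ACGTTCAAG", count_config(n_kmers = 16, k = 5))
  expect_equal(nrow(tab), 0L)
})

test_that("counts saturate at the configured cap", {
  reads <- rep("ACG", 300)
  tab <- count_exact(reads, toy_cfg())
  expect_identical(tab$count, 255L)
  tab <- count_exact(reads, toy_cfg(max_count = 1000))
  expect_identical(tab$count, 300L)
})

test_that("exact counting equals the brute-force oracle on simulated reads", {
  for (case in list(list(C = 8, alpha = 0, cutoff = 2, seed = 41),
                    list(C = 12, alpha = 0.01, cutoff = 2, seed = 42),
                    list(C = 15, alpha = 0.01, cutoff = 3, seed = 43),
                    list(C = 20, alpha = 0.02, cutoff = 5, seed = 44))) {
    reads <- sim_read_set(G = 5000, C = case$C, alpha = case$alpha,
                          seed = case$seed)
    oracle <- naive_count_oracle(reads, k = 31)
    cfg <- count_config(n_kmers = nrow(oracle), k = 31, cutoff = case$cutoff)
    got <- count_exact(reads, cfg)
    truth <- oracle[oracle$count >= case$cutoff, ]
    expect_identical(got$kmer, truth$kmer)
    expect_identical(got$count, truth$count)
    # pass-1 guarantee: the staged table is a superset of the truth
    staged <- count_pass1(reads, cfg)$table
    expect_true(all(truth$kmer %in% staged$kmer))
  }
})

test_that("a badly undersized filter inflates pass 1 but never the result", {
  reads <- sim_read_set(G = 4000, C = 10, alpha = 0.01, seed = 45)
  oracle <- naive_count_oracle(reads, k = 25)
  truth <- oracle[oracle$count >= 2, ]
  good <- count_config(n_kmers = nrow(oracle), k = 25, cutoff = 2)
  tiny <- count_config(n_kmers = nrow(oracle), k = 25, cutoff = 2,
                       bits_per_kmer = 0.25, d = 2)
  got_good <- count_exact(reads, good)
  got_tiny <- count_exact(reads, tiny)
  expect_identical(as_plain(got_tiny), as_plain(got_good))
  expect_identical(got_tiny$kmer, truth$kmer)
  expect_gt(attr(got_tiny, "stats")$n_staged,
            attr(got_good, "stats")$n_staged)
})

test_that("exact counts are invariant to read order and strand", {
  reads <- sim_read_set(G = 3000, C = 8, alpha = 0.01, seed = 46)$sequence
  cfg <- count_config(n_kmers = 5000, k = 21, cutoff = 2)
  base <- count_exact(reads, cfg)
  set.seed(46)
  shuffled <- count_exact(sample(reads), cfg)
  expect_identical(as_plain(base), as_plain(shuffled))
  flipped <- count_exact(str_revcomp(reads), cfg)
  expect_identical(as_plain(base), as_plain(flipped))
})

test_that("one-pass counts overshoot by at most one, via filter false positives", {
  # hand trace: no false positive possible for the first k-mer seen
  tab <- count_approximate(c("ACGT", "ACGT"), toy_cfg())
  expect_identical(as_plain(tab), data.frame(kmer = "ACG", count = 4L))

  # a deliberately tiny filter forces false positives: every reported count
  # is the truth or the truth plus one, and some singletons slip in with 2
  reads <- sim_read_set(G = 3000, C = 10, alpha = 0.02, seed = 47)
  oracle <- naive_count_oracle(reads, k = 21)
  cfg <- count_config(n_kmers = nrow(oracle), k = 21, cutoff = 2,
                      bits_per_kmer = 0.5, d = 2)
  tab <- count_approximate(reads, cfg)
  m <- merge(as_plain(tab), as_plain(oracle), by = "kmer")
  diffs <- m$count.x - m$count.y
  expect_true(all(diffs %in% c(0L, 1L)))
  expect_gt(sum(diffs == 1L), 0L)
  expect_true(all(oracle$kmer[oracle$count >= 2] %in% tab$kmer))
})

test_that("pass-1 table size matches the staged-plus-false-positive model", {
  reads <- sim_read_set(G = 20000, C = 12, alpha = 0.01, seed = 48)
  k <- 31
  oracle <- naive_count_oracle(reads, k = k)
  cfg <- count_config(n_kmers = nrow(oracle), k = k, cutoff = 2)
  p1 <- count_pass1(reads, cfg)
  p <- predict_first_fp(reads$sequence, k, m = p1$filter$m, d = p1$filter$d)
  expected <- sum(oracle$count >= 2) + sum(p[oracle$kmer[oracle$count < 2]])
  se <- sqrt(sum(p * (1 - p)))
  expect_lt(abs(nrow(p1$table) - expected), 3 * se)
})

test_that("configuration errors are caught up front", {
  expect_error(count_config(k = 31), "n_kmers")
  expect_error(count_config(n_kmers = 10, cutoff = 1), "at least 2")
  expect_error(count_config(n_kmers = 10, cutoff = 3, mode = "approximate"),
               "cutoff = 2")
  expect_error(count_config(n_kmers = 10, cutoff = 5, max_count = 4),
               "max_count")
  cfg3 <- count_config(n_kmers = 10, k = 3, cutoff = 3)
  expect_error(count_approximate(c("ACGT"), cfg3), "cutoff = 2")
})

test_that("higher cutoffs count through the counting filter", {
  reads <- c(rep("ACGT", 3), rep("AAAA", 2), "TGCA")
  cfg <- count_config(n_kmers = 16, k = 3, cutoff = 3)
  tab <- count_exact(reads, cfg)
  # ACG appears 6x (two windows per ACGT read), AAA 4x, TGC/GCA once each
  expect_identical(tab$kmer, c("AAA", "ACG"))
  expect_identical(tab$count, c(4L, 6L))
  cfg5 <- count_config(n_kmers = 16, k = 3, cutoff = 5)
  expect_identical(count_exact(reads, cfg5)$kmer, "ACG")
})
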