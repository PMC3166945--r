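test_that("hash indices are deterministic, in range, and double-hashed", {
  x <- kmer_encode("ACGTACGTACGTACGTACGTA")
  h1 <- make_hashes(x, d = 5, m = 1009, seed = 42)
  h2 <- make_hashes(x, d = 5, m = 1009, seed = 42)
  expect_identical(h1, h2)
  expect_length(h1, 5L)
  expect_true(all(h1 >= 0 & h1 < 1009))
  # double hashing: a smaller d yields a prefix of a larger d's indices
  expect_identical(make_hashes(x, d = 1, m = 1009, seed = 42), h1[1])
  expect_identical(make_hashes(x, d = 3, m = 1009, seed = 42), h1[1:3])
  # different seeds give different index sets
  expect_false(identical(h1, make_hashes(x, d = 5, m = 1009, seed = 43)))
})

test_that("hash indices are uniform on [0, m)", {
  set.seed(21)
  m <- 256
  kmers <- kmer_encode(random_dna(20000, 16))
  idx <- vapply(seq_len(20000),
                function(i) make_hashes(kmers[i], d = 1, m = m, seed = 0),
                numeric(1))
  counts <- tabulate(idx + 1, nbins = m)
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.01)
})

test_that("a Bloom filter never forgets an inserted key", {
  set.seed(22)
  bf <- bloom_filter(m = 2048, d = 4)
  expect_false(any(bloom_contains(bf, random_dna(50, 21))))
  keys <- unique(random_dna(300, 21))
  bloom_insert(bf, keys)
  expect_true(all(bloom_contains(bf, keys)))
  # single insert sets between 1 and d bits; reinsert changes nothing
  bf2 <- bloom_filter(m = 2048, d = 4)
  bloom_insert(bf2, "ACGTACGTACGTACGTACGTA")
  n1 <- kbloom:::cpp_bloom_n_set(bf2$ptr)
  expect_true(n1 >= 1 && n1 <= 4)
  bloom_insert(bf2, "ACGTACGTACGTACGTACGTA")
  expect_equal(kbloom:::cpp_bloom_n_set(bf2$ptr), n1)
})

test_that("empirical false-positive rate matches the analytic formula", {
  set.seed(23)
  for (cfg in list(list(ratio = 8, d = 5), list(ratio = 4, d = 3))) {
    n <- 20000
    pool <- unique(random_dna(n + 25000, 31))
    ins <- pool[seq_len(n)]
    probe <- pool[n + seq_len(20000)]
    bf <- bloom_filter(n = n, bits_per_kmer = cfg$ratio, d = cfg$d)
    bloom_insert(bf, ins)
    hit <- mean(bloom_contains(bf, probe))
    p <- false_positive_rate(n, bf$m, cfg$d)
    se <- sqrt(p * (1 - p) / length(probe))
    expect_lt(abs(hit - p), 3 * se)
  }
})

test_that("analytic false-positive rate reproduces its closed form", {
  expect_equal(false_positive_rate(1e6, 8e6, 5), (1 - exp(-5 / 8))^5)
  expect_equal(false_positive_rate(0, 64, 3), 0)
  expect_equal(false_positive_rate(1000, 1000, 1), 1 - exp(-1))
  expect_error(false_positive_rate(10, 0, 3), "m")
  expect_error(false_positive_rate(10, 64, 0), "d")
  # increasing in n, decreasing in m
  n <- c(1e3, 1e4, 1e5, 1e6)
  expect_true(all(diff(false_positive_rate(n, 1e6, 4)) > 0))
  m <- c(1e5, 1e6, 1e7)
  expect_true(all(diff(false_positive_rate(1e5, m, 4)) < 0))
})

test_that("optimal_d minimizes over the grid and brackets (m/n) log 2", {
  expect_equal(optimal_d(1e6, 4e6), 3L)
  expect_equal(optimal_d(1e6, 1e6), 1L)
  expect_equal(optimal_d(1e6, 8e6), 6L)
  for (ratio in 1:16) {
    d <- optimal_d(1000, 1000 * ratio)
    analytic <- ratio * log(2)
    expect_true(d >= max(1, floor(analytic)) && d <= ceiling(analytic),
                info = paste("ratio", ratio))
    # no other d on the grid does better
    fp <- false_positive_rate(1000, 1000 * ratio, 1:64)
    expect_equal(d, which.min(fp))
  }
})

test_that("counting-filter counters saturate at c - 1 and gate the cutoff", {
  cb <- counting_bloom_filter(m = 4096, cutoff = 4, d = 3)
  x <- "ACGTACGTACGTACGTACGTA"
  expect_false(cbf_at_cutoff(cb, x))
  expect_equal(cbf_min_count(cb, x), 0L)
  cbf_insert(cb, x)
  expect_equal(cbf_min_count(cb, x), 1L)
  cbf_insert(cb, x)
  expect_equal(cbf_min_count(cb, x), 2L)
  expect_false(cbf_at_cutoff(cb, x))
  cbf_insert(cb, x)
  expect_true(cbf_at_cutoff(cb, x))
  for (i in 1:5) cbf_insert(cb, x) # saturation: never exceeds c - 1
  expect_equal(cbf_min_count(cb, x), 3L)
  expect_equal(cb$bits_per_counter, 2L)
})

test_that("counting-filter min-count upper-bounds min(occurrences, c - 1)", {
  set.seed(24)
  keys <- random_dna(400, 15)
  history <- sample(keys, 3000, replace = TRUE)
  cb <- counting_bloom_filter(m = 8192, cutoff = 8, d = 3)
  for (x in history) cbf_insert(cb, x)
  truth <- table(history)
  got <- cbf_min_count(cb, names(truth))
  expect_true(all(got >= pmin(as.integer(truth), 7L)))
  # every key meeting the cutoff is reported at the cutoff (no false negatives)
  meets <- as.integer(truth) >= 7L
  expect_true(all(cbf_at_cutoff(cb, names(truth))[meets]))
})

test_that("a counting filter with c = 2 behaves exactly like a Bloom filter", {
  set.seed(25)
  keys <- random_dna(500, 21)
  history <- sample(keys, 1500, replace = TRUE)
  bf <- bloom_filter(m = 4096, d = 3, seed = 9)
  cb <- counting_bloom_filter(m = 4096, cutoff = 2, d = 3, seed = 9)
  for (x in history) {
    expect_identical(cbf_at_cutoff(cb, x), bloom_contains(bf, x))
    bloom_insert(bf, x)
    cbf_insert(cb, x)
  }
  probes <- random_dna(500, 21)
  expect_identical(cbf_at_cutoff(cb, probes), bloom_contains(bf, probes))
})

test_that("filter constructors validate their geometry", {
  expect_error(bloom_filter(), "either `n` or `m`")
  expect_error(bloom_filter(n = -5), "positive")
  expect_error(bloom_filter(m = 64, d = 65), "1..64")
  expect_error(counting_bloom_filter(m = 64, cutoff = 1), "at least 2")
  # m is rounded up to a whole 64-bit word
  expect_equal(bloom_filter(m = 65, d = 1)$m, 128)
  expect_equal(bloom_filter(n = 100, bits_per_kmer = 4, d = 3)$m, 448)
})
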