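#' Bloom filter over packed k-mers
#'
#' A bit array of `m` bits probed by `d` hash positions per key, produced by
#' double hashing: two seeded 64-bit hashes `u`, `v` of the packed k-mer
#' bytes (`v` forced odd) give `index_i = (u + i * v) mod m` for
#' `i = 0 .. d - 1`. Insertion sets the `d` bits; a membership query reports
#' `TRUE` iff all `d` bits are set, so an inserted key is never missed (no
#' false negatives) but a never-inserted key may collide with bits set by
#' others (a false positive, at the rate given by [false_positive_rate()]).
#'
#' The filter state lives behind an external pointer, so [bloom_insert()]
#' modifies the filter in place (reference semantics) and returns it
#' invisibly.
#'
#' @param n Expected number of distinct keys; used to size the filter as
#'   `m = bits_per_kmer * n` and, when `d = "auto"`, to choose the hash
#'   count via [optimal_d()]. May be omitted when `m` and `d` are given.
#' @param bits_per_kmer Bits of filter per expected key (default 4, giving
#'   `d = 3` under `d = "auto"`).
#' @param d Number of hash functions (1..64), or `"auto"`.
#' @param seed Integer seed of the hash family (default 0).
#' @param m Exact number of bits, overriding `bits_per_kmer * n`; rounded up
#'   to a multiple of 64 for word-aligned storage.
#' @param bf A `bloom_filter` object.
#' @param x K-mers: a `packed_kmer` or a character vector (all the same
#'   length).
#'
#' @return [bloom_filter()] returns a `bloom_filter`. [bloom_insert()]
#'   returns the filter invisibly; [bloom_contains()] returns a logical
#'   vector, one entry per key in `x`.
#'
#' @examples
#' bf <- bloom_filter(n = 1000, bits_per_kmer = 8, d = 5)
#' bloom_insert(bf, c("ACGTACGT", "TTTTACGT"))
#' bloom_contains(bf, c("ACGTACGT", "ACGTACGA"))
#' @export
bloom_filter <- function(n = NULL, bits_per_kmer = 4, d = "auto", seed = 0,
                         m = NULL) {
  m <- filter_size(n, bits_per_kmer, m)
  d <- resolve_d(d, n, m)
  structure(
    list(ptr = cpp_bloom_new(m, d, seed), m = m, d = d, seed = seed),
    class = "bloom_filter"
  )
}

#' @rdname bloom_filter
#' @export
bloom_insert <- function(bf, x) {
  stopifnot(inherits(bf, "bloom_filter"))
  cpp_bloom_insert(bf$ptr, unclass_bytes(as_packed(x)))
  invisible(bf)
}

#' @rdname bloom_filter
#' @export
bloom_contains <- function(bf, x) {
  stopifnot(inherits(bf, "bloom_filter"))
  cpp_bloom_contains(bf$ptr, unclass_bytes(as_packed(x)))
}

#' @export
print.bloom_filter <- function(x, ...) {
  cat(sprintf("<bloom_filter> m = %s bits, d = %d, seed = %s, %s bits set\n",
              format(x$m, big.mark = ","), x$d, format(x$seed),
              format(cpp_bloom_n_set(x$ptr), big.mark = ",")))
  invisible(x)
}

#' Counting Bloom filter with a coverage cutoff
#'
#' Replaces each bit of a Bloom filter with a saturating counter of
#' `b = ceiling(log2(c))` bits, where `c >= 2` is the coverage cutoff.
#' Insertion increments each of the key's `d` counters, capped at `c - 1`
#' (saturation, never wrap-around); [cbf_at_cutoff()] reports `TRUE` iff all
#' `d` counters equal `c - 1`, i.e. the key has (apparently) been seen at
#' least `c - 1` times. [cbf_min_count()] returns the minimum of the `d`
#' counters, an upper bound on `min(occurrences, c - 1)` for any key. With
#' `c = 2` the structure behaves exactly like [bloom_filter()].
#'
#' @inheritParams bloom_filter
#' @param cutoff Coverage cutoff `c` (2..256). `bits_per_kmer` counts
#'   counters per expected key here, mirroring the plain filter's sizing.
#' @param cbf A `counting_bloom_filter` object.
#' @return [counting_bloom_filter()] returns a `counting_bloom_filter`;
#'   [cbf_insert()] returns it invisibly; [cbf_at_cutoff()] a logical
#'   vector; [cbf_min_count()] an integer vector.
#' @examples
#' cb <- counting_bloom_filter(n = 100, cutoff = 4, d = 3)
#' for (i in 1:3) cbf_insert(cb, "ACGTACG")
#' cbf_at_cutoff(cb, "ACGTACG") # TRUE: all counters saturated at c - 1 = 3
#' @export
counting_bloom_filter <- function(n = NULL, cutoff = 2, bits_per_kmer = 4,
                                  d = "auto", seed = 0, m = NULL) {
  cutoff <- as.integer(cutoff)
  if (is.na(cutoff) || cutoff < 2L) stop("cutoff must be at least 2")
  m <- filter_size(n, bits_per_kmer, m)
  d <- resolve_d(d, n, m)
  b <- ceiling(log2(cutoff))
  structure(
    list(ptr = cpp_cbf_new(m, cutoff, d, seed), m = m, d = d, seed = seed,
         cutoff = cutoff, bits_per_counter = as.integer(max(1, b))),
    class = "counting_bloom_filter"
  )
}

#' @rdname counting_bloom_filter
#' @export
cbf_insert <- function(cbf, x) {
  stopifnot(inherits(cbf, "counting_bloom_filter"))
  cpp_cbf_insert(cbf$ptr, unclass_bytes(as_packed(x)))
  invisible(cbf)
}

#' @rdname counting_bloom_filter
#' @export
cbf_at_cutoff <- function(cbf, x) {
  stopifnot(inherits(cbf, "counting_bloom_filter"))
  cpp_cbf_at_cutoff(cbf$ptr, unclass_bytes(as_packed(x)))
}

#' @rdname counting_bloom_filter
#' @export
cbf_min_count <- function(cbf, x) {
  stopifnot(inherits(cbf, "counting_bloom_filter"))
  cpp_cbf_min_count(cbf$ptr, unclass_bytes(as_packed(x)))
}

#' @export
print.counting_bloom_filter <- function(x, ...) {
  cat(sprintf(
    "<counting_bloom_filter> m = %s counters of %d bit(s), cutoff = %d, d = %d, seed = %s\n",
    format(x$m, big.mark = ","), x$bits_per_counter, x$cutoff, x$d,
    format(x$seed)))
  invisible(x)
}

#' Hash positions of one k-mer
#'
#' The `d` filter indices a key maps to, exposed for inspection and testing.
#' Deterministic in `(x, d, m, seed)`; indices are 0-based in `[0, m)`.
#'
#' @param x A single k-mer (length-1 character vector or `packed_kmer`).
#' @param d Number of hash functions (1..64).
#' @param m Filter size the indices are reduced into.
#' @param seed Hash-family seed (default 0).
#' @return A numeric vector of `d` indices in `[0, m)`.
#' @export
make_hashes <- function(x, d, m, seed = 0) {
  x <- as_packed(x)
  if (length(x) != 1L) stop("`x` must be a single k-mer")
  cpp_make_hashes(unclass_bytes(x)[, 1L], as.integer(d), m, seed)
}

#' Bloom filter false-positive rate
#'
#' The probability that a never-inserted key is reported present by a Bloom
#' filter of `m` bits holding `n` keys with `d` hash functions,
#' `(1 - exp(-d * n / m))^d`. At one byte per key (`m = 8 n`) and `d = 5`
#' this is about 2.17%.
#'
#' @param n Number of distinct keys stored (>= 0).
#' @param m Number of bits (>= 1).
#' @param d Number of hash functions (>= 1).
#' @return The false-positive probability, in `[0, 1)`; 0 when `n = 0`.
#' @examples
#' false_positive_rate(1e6, 8e6, 5) # ~0.0217
#' @export
false_positive_rate <- function(n, m, d) {
  if (any(m < 1)) stop("m must be at least 1")
  if (any(d < 1)) stop("d must be at least 1")
  if (any(n < 0)) stop("n must be non-negative")
  (1 - exp(-d * n / m))^d
}

#' Optimal number of hash functions
#'
#' The integer `d` in 1..64 minimizing [false_positive_rate()] for a filter
#' of `m` bits holding `n` keys (ties broken toward smaller `d`). Brute
#' force over the grid rather than rounding `(m/n) * log(2)`, so the
#' boundary cases come out exactly; at 4 bits per key the answer is 3.
#'
#' @param n Number of distinct keys (>= 1).
#' @param m Number of bits (>= 1).
#' @return An integer in 1..64.
#' @examples
#' optimal_d(1e6, 4e6) # 3
#' @export
optimal_d <- function(n, m) {
  stopifnot(n >= 1, m >= 1)
  d <- 1:64
  fp <- false_positive_rate(n, m, d)
  d[which.min(fp)]
}

# m from n * bits_per_kmer (or explicit), rounded up to a 64-bit word.
filter_size <- function(n, bits_per_kmer, m) {
  if (is.null(m)) {
    if (is.null(n)) stop("either `n` or `m` must be given to size the filter")
    if (n <= 0) stop("the expected k-mer count `n` must be positive")
    if (bits_per_kmer <= 0) stop("bits_per_kmer must be positive")
    m <- n * bits_per_kmer
  }
  64 * ceiling(m / 64)
}

resolve_d <- function(d, n, m) {
  if (identical(d, "auto")) {
    if (is.null(n)) stop("`d = \"auto\"` needs the expected k-mer count `n`")
    return(optimal_d(n, m))
  }
  d <- as.integer(d)
  if (is.na(d) || d < 1L || d > 64L) stop("d must be an integer in 1..64")
  d
}
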