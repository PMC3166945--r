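#' Configure a counting run
#'
#' Bundles the parameters of a counting run: the k-mer length, the coverage
#' cutoff, the user's estimate of the number of distinct k-mers (which sizes
#' the staging filter -- the estimate may be wrong; an under-estimate only
#' inflates the pass-1 table with false positives, never the final counts),
#' and the filter geometry.
#'
#' @param n_kmers Estimated number of distinct k-mers in the input
#'   (required; sizes the filter).
#' @param k K-mer length (default 31).
#' @param cutoff Minimum multiplicity `c` for a k-mer to be reported
#'   (default 2, i.e. drop singletons).
#' @param bits_per_kmer Filter bits (or counters, for `cutoff > 2`) per
#'   expected k-mer (default 4; with `d = "auto"` this yields `d = 3`).
#' @param d Number of hash functions, or `"auto"` (the default) for the
#'   value minimizing the false-positive rate.
#' @param seed Hash-family seed (default 0).
#' @param mode `"exact"` (two passes; exact counts, no false positives) or
#'   `"approximate"` (one pass, `cutoff = 2` only; per-k-mer counts may
#'   overshoot by 1 and a few singleton false positives may be reported).
#' @param max_count Saturation cap of the stored counts (default 255, a
#'   1-byte counter).
#' @return A `count_config` list.
#' @examples
#' cfg <- count_config(n_kmers = 1e5, k = 21, cutoff = 2)
#' @export
count_config <- function(n_kmers, k = 31, cutoff = 2, bits_per_kmer = 4,
                         d = "auto", seed = 0, mode = c("exact", "approximate"),
                         max_count = 255L) {
  mode <- match.arg(mode)
  k <- as.integer(k)
  cutoff <- as.integer(cutoff)
  max_count <- as.integer(max_count)
  if (missing(n_kmers) || is.null(n_kmers) || !is.finite(n_kmers) || n_kmers <= 0)
    stop("`n_kmers`, a positive estimate of the number of distinct k-mers, is required")
  if (k < 1L) stop("k must be at least 1")
  if (cutoff < 2L) stop("cutoff must be at least 2")
  if (mode == "approximate" && cutoff != 2L)
    stop("approximate one-pass mode supports cutoff = 2 only")
  if (max_count < cutoff) stop("max_count must be at least the cutoff")
  structure(
    list(k = k, n_kmers = n_kmers, cutoff = cutoff,
         bits_per_kmer = bits_per_kmer, d = d, seed = seed, mode = mode,
         max_count = max_count),
    class = "count_config"
  )
}

new_filter <- function(config) {
  if (config$cutoff == 2L) {
    bloom_filter(n = config$n_kmers, bits_per_kmer = config$bits_per_kmer,
                 d = config$d, seed = config$seed)
  } else {
    counting_bloom_filter(n = config$n_kmers, cutoff = config$cutoff,
                          bits_per_kmer = config$bits_per_kmer,
                          d = config$d, seed = config$seed)
  }
}

#' First pass: stage k-mers and table candidates
#'
#' Streams every canonical k-mer occurrence in read order. If the staging
#' filter already reports the k-mer at the cutoff (plain membership for
#' `cutoff = 2`; all counters at `c - 1` otherwise) the k-mer is added to
#' the candidate table with a placeholder count of 0; otherwise it is
#' inserted into the filter. Afterwards the table is guaranteed to contain
#' every k-mer occurring at least `cutoff` times, plus a predictable set of
#' filter false positives that [count_pass2()] removes.
#'
#' @param reads Input reads: paths to FASTA/FASTQ files (optionally
#'   gzipped), a data frame with a `sequence` column (e.g. from
#'   [read_sequences()]), or a character vector of sequences.
#' @param config A [count_config()].
#' @return A list with `table` (a candidate [kmer_table] with counts 0),
#'   `filter` (the staging filter), and `stats` (`n_occurrences`,
#'   `n_filter_inserts`, `n_staged`).
#' @seealso [count_exact()] for the full two-pass pipeline.
#' @export
count_pass1 <- function(reads, config) {
  stopifnot(inherits(config, "count_config"))
  reads <- as_read_sequences(reads)
  filter <- new_filter(config)
  counting <- inherits(filter, "counting_bloom_filter")
  res <- cpp_pass1(reads, config$k, filter$ptr, counting, config$cutoff)
  tab <- kmer_table(
    kmers = cpp_decode(res$keys, config$k),
    counts = rep(0L, ncol(res$keys)),
    k = config$k, sort = TRUE
  )
  list(
    table = tab, filter = filter,
    stats = list(n_occurrences = res$n_occurrences,
                 n_filter_inserts = res$n_filter_inserts,
                 n_staged = nrow(tab))
  )
}

#' Second pass: exact recount and false-positive pruning
#'
#' Re-streams the same reads, counting occurrences of exactly the k-mers
#' tabled by [count_pass1()] (counts saturate at `max_count`), then removes
#' every key whose exact count is below the cutoff. The result has no false
#' positives and no false negatives for multiplicity >= `cutoff`.
#'
#' @inheritParams count_pass1
#' @param table The candidate [kmer_table] from [count_pass1()] (produced
#'   from the same reads with the same `k`).
#' @param cutoff Minimum multiplicity to retain.
#' @param max_count Count saturation cap (default 255).
#' @return A finalized [kmer_table]; the number of pruned false positives is
#'   available as `attr(x, "stats")$n_removed`.
#' @export
count_pass2 <- function(reads, table, cutoff = 2L, max_count = 255L) {
  stopifnot(inherits(table, "kmer_table"))
  reads <- as_read_sequences(reads)
  k <- attr(table, "k", exact = TRUE)
  keys <- if (nrow(table) > 0) cpp_encode(table$kmer) else
    matrix(raw(0), nrow = (2 * k + 7) %/% 8, ncol = 0)
  res <- cpp_pass2(reads, k, keys, as.integer(cutoff), as.integer(max_count))
  out <- kmer_table(cpp_decode(res$keys, k), res$counts, k = k, sort = TRUE)
  attr(out, "stats") <- list(n_removed = res$n_removed)
  out
}

#' Exact two-pass k-mer counting
#'
#' The full pipeline: [count_pass1()] stages canonical k-mers in a Bloom
#' filter and tables those seen at least `cutoff` times (plus filter false
#' positives); [count_pass2()] recounts the tabled k-mers exactly and prunes
#' everything below the cutoff. The result equals the brute-force tally of
#' canonical k-mers restricted to counts >= `cutoff` (up to saturation at
#' `max_count`), for any input and any filter size -- an undersized filter
#' only inflates the intermediate table.
#'
#' @inheritParams count_pass1
#' @return A [kmer_table] (tibble with columns `kmer`, `count`, sorted by
#'   k-mer). `attr(x, "stats")` records `n_occurrences` (canonical k-mer
#'   instances streamed), `n_staged` (pass-1 table size), `n_removed`
#'   (pruned false positives) and `n_final`.
#' @examples
#' cfg <- count_config(n_kmers = 10, k = 3, cutoff = 2)
#' count_exact(c("ACGT", "ACGT", "TTTT"), cfg) # ACG x4 (via CGT), AAA x2
#' @export
count_exact <- function(reads, config) {
  stopifnot(inherits(config, "count_config"))
  reads <- as_read_sequences(reads)
  p1 <- count_pass1(reads, config)
  out <- count_pass2(reads, p1$table, cutoff = config$cutoff,
                     max_count = config$max_count)
  attr(out, "stats") <- list(
    n_occurrences = p1$stats$n_occurrences,
    n_staged = p1$stats$n_staged,
    n_removed = attr(out, "stats")$n_removed,
    n_final = nrow(out)
  )
  out
}

#' One-pass approximate k-mer counting
#'
#' A single sweep for `cutoff = 2`: the first time the filter claims a
#' k-mer has been seen before, it is tabled with count 2; every later
#' occurrence increments the count. For every reported k-mer the count is
#' either exact or one too high -- it overshoots by exactly 1 when the
#' k-mer entered the table through a filter false positive on its first
#' occurrence (singletons reported this way carry count 2). Every k-mer of
#' true multiplicity >= 2 is reported.
#'
#' @inheritParams count_pass1
#' @return A [kmer_table]; `attr(x, "stats")$n_occurrences` gives the number
#'   of canonical k-mer instances streamed.
#' @export
count_approximate <- function(reads, config) {
  stopifnot(inherits(config, "count_config"))
  if (config$cutoff != 2L)
    stop("approximate one-pass mode supports cutoff = 2 only")
  reads <- as_read_sequences(reads)
  filter <- bloom_filter(n = config$n_kmers,
                         bits_per_kmer = config$bits_per_kmer,
                         d = config$d, seed = config$seed)
  res <- cpp_count_approx(reads, config$k, filter$ptr, config$max_count)
  out <- kmer_table(cpp_decode(res$keys, config$k), res$counts,
                    k = config$k, sort = TRUE)
  attr(out, "stats") <- list(n_occurrences = res$n_occurrences,
                             n_final = nrow(out))
  out
}

#' K-mer count tables
#'
#' A tibble with columns `kmer` (canonical k-mer strings) and `count`
#' (integer), sorted by k-mer for deterministic output, carrying the k-mer
#' length in `attr(x, "k")`.
#'
#' @param kmers Character vector of canonical k-mers.
#' @param counts Integer counts, same length.
#' @param k K-mer length.
#' @param sort Sort rows by k-mer (byte order; the default).
#' @return A `kmer_table`.
#' @export
kmer_table <- function(kmers = character(), counts = integer(), k, sort = TRUE) {
  stopifnot(length(kmers) == length(counts))
  counts <- as.integer(counts)
  if (sort && length(kmers)) {
    o <- order(kmers, method = "radix")
    kmers <- kmers[o]
    counts <- counts[o]
  }
  out <- tibble::tibble(kmer = kmers, count = counts)
  attr(out, "k") <- as.integer(k)
  class(out) <- c("kmer_table", class(out))
  out
}

# Accept file paths, a record data frame, or bare sequences.
as_read_sequences <- function(reads) {
  if (is.data.frame(reads)) {
    if (!"sequence" %in% names(reads))
      stop("read data frame must have a `sequence` column")
    return(as.character(reads$sequence))
  }
  if (is.character(reads)) {
    if (length(reads) > 0 && all(file.exists(reads)))
      return(read_sequences(reads)$sequence)
    return(reads)
  }
  stop("`reads` must be file paths, a record data frame, or a character vector of sequences")
}
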