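#' Simulate a random genome
#'
#' A uniform i.i.d. sequence over A, C, G, T -- the statistical structure
#' assumed by the coverage/error calculations in [expected_spurious_kmers()]
#' (repeats arise only by chance).
#'
#' @param genome_length Number of bases (>= 1).
#' @param seed Optional integer; when given, the draw is made under a local
#'   RNG seed so results are reproducible without disturbing the session RNG.
#' @return A single DNA string of the requested length.
#' @export
simulate_genome <- function(genome_length, seed = NULL) {
  stopifnot(genome_length >= 1)
  with_opt_seed(seed, {
    paste(sample(DNA_BASES, genome_length, replace = TRUE), collapse = "")
  })
}

DNA_BASES <- c("A", "C", "G", "T")

#' Simulate shotgun reads with uniform substitution errors
#'
#' Draws `round(coverage * G / l)` single-end reads of length `l` with start
#' positions uniform on the genome (forward strand only -- canonical k-mer
#' counting makes strand irrelevant), then substitutes each base
#' independently with probability `error_rate`, replacing it by one of the
#' other three bases uniformly. No indels, no position-dependent error rate:
#' exactly the error model behind [expected_spurious_kmers()].
#'
#' @param genome A DNA string (e.g. from [simulate_genome()]).
#' @param coverage Target fold coverage `C` (> 0).
#' @param read_length Read length `l` (<= genome length).
#' @param error_rate Per-base substitution probability in `[0, 1]` (default 0).
#' @param seed Optional integer for a local, reproducible draw.
#' @return A tibble with columns `id`, `sequence`, `quality` (constant
#'   "I"), and `start` (1-based template start on the genome, kept so tests
#'   can locate each read's error positions).
#' @export
simulate_reads <- function(genome, coverage, read_length, error_rate = 0,
                           seed = NULL) {
  stopifnot(is.character(genome), length(genome) == 1L)
  G <- nchar(genome)
  l <- as.integer(read_length)
  if (l > G) stop("read_length must not exceed the genome length")
  check_theory(coverage, G, l, 1, error_rate)
  n <- round(coverage * G / l)
  with_opt_seed(seed, {
    starts <- sample.int(G - l + 1L, n, replace = TRUE)
    reads <- substring(genome, starts, starts + l - 1L)
    if (error_rate > 0 && n > 0) {
      ch <- matrix(unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE),
                   nrow = l)
      hit <- which(runif(length(ch)) < error_rate)
      if (length(hit)) {
        code <- match(ch[hit], DNA_BASES)
        shift <- sample.int(3L, length(hit), replace = TRUE)
        ch[hit] <- DNA_BASES[((code - 1L + shift) %% 4L) + 1L]
        reads <- do.call(paste0, asplit(ch, 1L))
      }
    }
    tibble::tibble(
      id = sprintf("read%06d", seq_len(n)),
      sequence = reads,
      quality = strrep("I", l),
      start = starts
    )
  })
}

#' Brute-force canonical k-mer tally
#'
#' The reference counter every guarantee is tested against: enumerate all
#' ACGT-only windows of width `k`, canonicalize each with
#' [Biostrings::reverseComplement()] (an independent route from the packed
#' codec used by the counting engine), and tally by direct accumulation --
#' no filter, no saturation.
#'
#' @inheritParams count_pass1
#' @param k K-mer length.
#' @return A [kmer_table] with exact, uncapped counts.
#' @export
naive_count_oracle <- function(reads, k) {
  reads <- toupper(as_read_sequences(reads))
  k <- as.integer(k)
  stopifnot(k >= 1L)
  win <- lapply(reads, function(s) {
    L <- nchar(s)
    if (L < k) return(character())
    st <- seq_len(L - k + 1L)
    substring(s, st, st + k - 1L)
  })
  win <- unlist(win, use.names = FALSE)
  if (length(win)) win <- win[!grepl("[^ACGT]", win)]
  if (!length(win)) return(kmer_table(character(), integer(), k = k))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(win)))
  can <- ifelse(win <= rc, win, rc)
  dt <- data.table::data.table(kmer = can)
  tal <- dt[, list(count = .N), by = "kmer"]
  kmer_table(tal$kmer, tal$count, k = k, sort = TRUE)
}

with_opt_seed <- function(seed, code) {
  if (is.null(seed)) force(code)
  else withr::with_seed(as.integer(seed), code)
}
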