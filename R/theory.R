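#' Expected number of error-derived (spurious) k-mers
#'
#' Under shotgun sequencing of a genome of length `G` at fold coverage `C`
#' with reads of length `l` and a uniform per-base substitution error rate
#' `alpha`, each read carries `l - k + 1` windows of width `k` and a window
#' is error-free with probability `(1 - alpha)^k`. The expected number of
#' k-mer instances containing at least one error is therefore
#'
#'   `(C * G / l) * (l - k + 1) * (1 - (1 - alpha)^k)`
#'
#' This treats every erroneous window as a new, spurious k-mer, ignoring the
#' rare event that the same error recurs, and assumes a position-independent
#' error rate. The count grows linearly in coverage, which is why singleton
#' k-mers come to dominate memory at depth.
#'
#' @param coverage Fold coverage `C` (> 0).
#' @param genome_length Genome length `G` in bases (> 0).
#' @param read_length Read length `l` in bases (>= k).
#' @param k K-mer length (>= 1).
#' @param error_rate Per-base substitution probability `alpha` in `[0, 1]`.
#' @return The expected number of spurious k-mer instances.
#' @examples
#' expected_spurious_kmers(1, 1e6, 100, 31, 0.01) # ~1.87e5
#' @export
expected_spurious_kmers <- function(coverage, genome_length, read_length, k,
                                    error_rate) {
  check_theory(coverage, genome_length, read_length, k, error_rate)
  (coverage * genome_length / read_length) *
    (read_length - k + 1) * (1 - (1 - error_rate)^k)
}

#' Coverage at which spurious k-mers overtake the genome
#'
#' Solves [expected_spurious_kmers()] `= G` for the coverage `C`; the genome
#' length cancels, leaving `l / ((l - k + 1) * (1 - (1 - alpha)^k))`. At a
#' 1% error rate, 100 bp reads and k = 31 the crossover sits near 5.3-fold
#' coverage: beyond that, error-derived k-mers outnumber the genome's own.
#'
#' @inheritParams expected_spurious_kmers
#' @return The crossover fold coverage; decreasing in `error_rate` and `k`.
#' @examples
#' crossover_coverage(100, 31, 0.01) # ~5.34
#' @export
crossover_coverage <- function(read_length, k, error_rate) {
  check_theory(1, 1, read_length, k, error_rate)
  if (error_rate == 0)
    stop("error_rate = 0 produces no spurious k-mers; the crossover does not exist")
  read_length / ((read_length - k + 1) * (1 - (1 - error_rate)^k))
}

check_theory <- function(coverage, genome_length, read_length, k, error_rate) {
  stopifnot(coverage > 0, genome_length > 0, k >= 1)
  if (error_rate < 0 || error_rate > 1)
    stop("error_rate must be in [0, 1]")
  if (read_length < k)
    stop("read_length must be at least k (reads shorter than k carry no k-mers)")
  invisible(TRUE)
}
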