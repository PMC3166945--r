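#' Packed k-mers
#'
#' A `packed_kmer` is a vector of k-mers stored 2 bits per base
#' (A=00, C=01, G=10, T=11, first base most significant), right-aligned in
#' `ceiling(2k/8)` bytes. With this encoding, unsigned integer order on the
#' packed value equals lexicographic order on the sequence (A < C < G < T),
#' so the canonical-k-mer rule reduces to a byte comparison. Internally the
#' vector is a raw matrix with one column per k-mer.
#'
#' @param x For [kmer_encode()], a character vector of DNA strings, all of
#'   the same length k (case-insensitive, A/C/G/T only). Elsewhere, a
#'   `packed_kmer` object.
#'
#' @return [kmer_encode()], [kmer_revcomp()] and [kmer_canonical()] return a
#'   `packed_kmer`; [kmer_decode()] returns an uppercase character vector.
#'
#' @examples
#' x <- kmer_encode(c("ACGT", "GTTT"))
#' kmer_decode(kmer_revcomp(x))   # "ACGT" "AAAC"
#' kmer_decode(kmer_canonical(x)) # "ACGT" "AAAC"
#' @name packed_kmer
NULL

new_packed_kmer <- function(bytes, k) {
  structure(bytes, k = as.integer(k), class = "packed_kmer")
}

#' @rdname packed_kmer
#' @export
kmer_encode <- function(x) {
  if (!is.character(x)) stop("`x` must be a character vector of DNA strings")
  new_packed_kmer(cpp_encode(x), nchar(x[[1L]]))
}

#' @rdname packed_kmer
#' @export
kmer_decode <- function(x) {
  x <- as_packed(x)
  cpp_decode(unclass_bytes(x), kmer_k(x))
}

#' @rdname packed_kmer
#' @export
kmer_revcomp <- function(x) {
  x <- as_packed(x)
  new_packed_kmer(cpp_revcomp(unclass_bytes(x), kmer_k(x)), kmer_k(x))
}

#' @rdname packed_kmer
#' @export
kmer_canonical <- function(x) {
  x <- as_packed(x)
  new_packed_kmer(cpp_canonical(unclass_bytes(x), kmer_k(x)), kmer_k(x))
}

#' Stream canonical k-mers from a read
#'
#' Slides a window of width `k` over `sequence` (0-based, half-open windows,
#' one per position `0 .. nchar - k`) and returns the canonical form of each
#' window, in read order. Windows containing any non-ACGT character
#' (N, IUPAC ambiguity codes, gaps) are skipped; reads shorter than `k`
#' yield nothing.
#'
#' @param sequence A single DNA string (case-insensitive).
#' @param k Window width in bases (>= 1).
#' @param as Return canonical k-mers as a character vector (default) or as a
#'   `packed_kmer` object.
#' @return Canonical k-mers, one per retained window.
#' @examples
#' extract_kmers("ACGNT", 3) # "ACG" -- windows touching the N are skipped
#' @export
extract_kmers <- function(sequence, k, as = c("character", "packed")) {
  as <- match.arg(as)
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  k <- as.integer(k)
  if (k < 1L) stop("k must be at least 1")
  pk <- new_packed_kmer(cpp_extract(sequence, k), k)
  if (as == "character") kmer_decode(pk) else pk
}

kmer_k <- function(x) attr(x, "k", exact = TRUE)

unclass_bytes <- function(x) {
  b <- unclass(x)
  attr(b, "k") <- NULL
  b
}

# Coerce character input (encoding on the fly) or pass a packed_kmer through.
as_packed <- function(x, k = NULL) {
  if (inherits(x, "packed_kmer")) {
    if (!is.null(k) && kmer_k(x) != k)
      stop("packed k-mer has k = ", kmer_k(x), ", expected k = ", k)
    return(x)
  }
  if (is.character(x)) {
    pk <- kmer_encode(x)
    if (!is.null(k) && kmer_k(pk) != k)
      stop("k-mer string has length ", kmer_k(pk), ", expected k = ", k)
    return(pk)
  }
  stop("expected a packed_kmer or a character vector of k-mers")
}

#' @export
length.packed_kmer <- function(x) ncol(x)

#' @export
`[.packed_kmer` <- function(x, i) {
  new_packed_kmer(unclass_bytes(x)[, i, drop = FALSE], kmer_k(x))
}

#' @export
as.character.packed_kmer <- function(x, ...) kmer_decode(x)

#' @export
print.packed_kmer <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<packed_kmer> k = %d, n = %d\n", kmer_k(x), n))
  if (n > 0) {
    shown <- kmer_decode(x[seq_len(min(n, 6L))])
    cat(" ", paste(shown, collapse = " "),
        if (n > 6L) sprintf("... (%d more)", n - 6L) else "", "\n")
  }
  invisible(x)
}
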