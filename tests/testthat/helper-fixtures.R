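# Shared fixtures: random k-mer generators, a string-level reverse
# complement independent of the packed codec, and tiny FASTA/FASTQ writers.

random_dna <- function(n, len) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

all_kmers <- function(k) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                              stringsAsFactors = FALSE))
}

# character-level reverse complement (oracle route, no packed codec)
str_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

str_canonical <- function(x) {
  rc <- str_revcomp(x)
  ifelse(x <= rc, x, rc)
}

# hex string per packed k-mer so string order mirrors packed integer order
packed_hex <- function(x) {
  b <- unclass(x)
  attr(b, "k") <- NULL
  apply(b, 2, function(col) paste(as.character(col), collapse = ""))
}

write_toy_fasta <- function(seqs, path = tempfile(fileext = ".fa"),
                            width = NULL) {
  lines <- unlist(lapply(seq_along(seqs), function(i) {
    s <- seqs[i]
    body <- if (is.null(width)) s else {
      st <- seq(1, nchar(s), by = width)
      substring(s, st, pmin(st + width - 1, nchar(s)))
    }
    c(paste0(">seq", i), body)
  }))
  writeLines(lines, path)
  path
}

write_toy_fastq <- function(seqs, path = tempfile(fileext = ".fq"),
                            quals = NULL) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  lines <- unlist(lapply(seq_along(seqs), function(i) {
    c(paste0("@read", i), seqs[i], "+", quals[i])
  }))
  writeLines(lines, path)
  path
}

gzip_copy <- function(path) {
  out <- paste0(tempfile(), ".gz")
  con <- gzfile(out, "wb")
  writeBin(readBin(path, "raw", n = file.size(path)), con)
  close(con)
  out
}

# Prediction of the probability that each distinct canonical k-mer's first
# occurrence is a staging-filter false positive: the analytic rate at the
# filter load present when it is first probed. The load grows with the
# number of distinct k-mers *seen* (a key swallowed by a false positive
# would have set no new bits anyway), so key number i is probed against an
# expected load of i - 1.
predict_first_fp <- function(reads, k, m, d) {
  stream <- unlist(lapply(reads, extract_kmers, k = k), use.names = FALSE)
  firsts <- stream[!duplicated(stream)]
  p <- (1 - exp(-d * (seq_along(firsts) - 1) / m))^d
  names(p) <- firsts
  p
}

# column-only view of a count table, for comparisons that ignore attributes
as_plain <- function(x) data.frame(kmer = as.character(x$kmer),
                                   count = as.integer(x$count))

sim_read_set <- function(G, C, l = 100, alpha = 0, seed = 1) {
  genome <- simulate_genome(G, seed = seed)
  simulate_reads(genome, coverage = C, read_length = l, error_rate = alpha,
                 seed = seed + 1000)
}
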