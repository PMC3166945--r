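#' Read sequencing reads from FASTA/FASTQ files
#'
#' Reads one or more FASTA or FASTQ files, optionally gzip-compressed. The
#' format is auto-detected from the first non-empty character of each file
#' (`>` FASTA, `@` FASTQ) and gzip from the file's magic bytes (handled
#' transparently by the connection). Multi-line FASTA is supported; FASTQ
#' qualities are carried along but ignored by the counters. Records are
#' returned fully materialized, in file order, so the two counting passes
#' can re-iterate over them freely.
#'
#' @param paths Character vector of file paths.
#' @return A tibble with columns `id`, `sequence` and `quality` (`NA` for
#'   FASTA records). An empty file yields no rows and a warning.
#' @export
read_sequences <- function(paths) {
  stopifnot(is.character(paths), length(paths) >= 1)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input file not found: ", paste(missing, collapse = ", "))
  out <- lapply(paths, read_one_file)
  do.call(rbind, out)
}

read_one_file <- function(path) {
  fmt <- detect_format(path)
  if (is.na(fmt)) {
    warning("no sequence records in ", path)
    return(tibble::tibble(id = character(), sequence = character(),
                          quality = character()))
  }
  if (fmt == "fasta") {
    set <- parse_guard(path, Biostrings::readDNAStringSet(path, format = "fasta"))
    if (length(set) == 0) warning("no sequence records in ", path)
    return(tibble::tibble(
      id = if (is.null(names(set))) rep(NA_character_, length(set)) else
        unname(names(set)),
      sequence = unname(as.character(set)),
      quality = rep(NA_character_, length(set))
    ))
  }
  read_fastq_file(path)
}

# Four-line-record FASTQ reader that validates record structure (the
# installed XStringSet parser silently accepts quality lines whose length
# does not match the sequence).
read_fastq_file <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) %% 4L != 0L)
    stop("parse error in ", path, ": truncated FASTQ record near line ",
         length(lines))
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop("parse error in ", path, ": line ", 4L * (bad[1] - 1L) + 1L,
         " does not start a FASTQ record with '@'")
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop("parse error in ", path, ": expected '+' separator at line ",
         4L * (bad[1] - 1L) + 3L)
  bad <- which(nchar(qual) != nchar(seqs) | nchar(seqs) == 0L)
  if (length(bad))
    stop("parse error in ", path, ": quality length does not match sequence ",
         "length for the record at line ", 4L * (bad[1] - 1L) + 1L)
  tibble::tibble(id = substring(hdr, 2L), sequence = seqs, quality = qual)
}

parse_guard <- function(path, expr) {
  tryCatch(expr, error = function(e)
    stop("parse error in ", path, ": ", conditionMessage(e), call. = FALSE))
}

# First non-empty character decides the format; gzfile() reads plain files
# and gzip alike. NA means the file holds no non-empty line.
detect_format <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) return(NA_character_)
    line <- trimws(line)
    if (nzchar(line)) break
  }
  ch <- substr(line, 1L, 1L)
  if (ch == ">") return("fasta")
  if (ch == "@") return("fastq")
  stop("cannot detect format of ", path,
       ": first non-empty character is '", ch, "' (expected '>' or '@')")
}

#' Write and read k-mer count tables
#'
#' The TSV format is one line per k-mer, `<kmer>\t<count>`, no header,
#' sorted lexicographically (byte order) for reproducible diffs. The binary
#' dump is little-endian: magic `"KBCT"`, a 1-byte format version, `k` and
#' the entry count as 32-bit integers, then per entry the packed k-mer
#' (`ceiling(2k/8)` bytes, big-endian within the k-mer so byte order equals
#' lexicographic order) followed by a 1-byte count capped at 255.
#'
#' @param table A [kmer_table] (or any data frame with `kmer` and `count`
#'   columns plus a `k` attribute).
#' @param path Output (input) file path.
#' @param format `"tsv"` or `"binary"`; [read_counts()] also accepts
#'   `"auto"` (sniff the magic bytes).
#' @return [write_counts()] returns the number of records written,
#'   invisibly. [read_counts()] returns a [kmer_table].
#' @export
write_counts <- function(table, path, format = c("tsv", "binary")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(table), all(c("kmer", "count") %in% names(table)))
  o <- order(table$kmer, method = "radix")
  kmers <- table$kmer[o]
  counts <- as.integer(table$count[o])
  if (format == "tsv") {
    writeLines(if (length(kmers)) paste0(kmers, "\t", counts) else character(),
               path)
  } else {
    k <- attr(table, "k", exact = TRUE)
    if (is.null(k)) {
      if (!length(kmers)) stop("cannot infer k from an empty table; set attr(table, \"k\")")
      k <- nchar(kmers[1])
    }
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw("KBCT"), con)
    writeBin(as.raw(1L), con)
    writeBin(as.integer(c(k, length(kmers))), con, size = 4L,
             endian = "little")
    if (length(kmers)) {
      bytes <- cpp_encode(kmers)
      payload <- rbind(bytes, matrix(as.raw(pmin(counts, 255L)), nrow = 1L))
      writeBin(as.vector(payload), con)
    }
  }
  invisible(length(kmers))
}

#' @rdname write_counts
#' @export
read_counts <- function(path, format = c("auto", "tsv", "binary")) {
  format <- match.arg(format)
  if (format == "auto") {
    head4 <- readBin(path, "raw", n = 4L)
    format <- if (identical(head4, charToRaw("KBCT"))) "binary" else "tsv"
  }
  if (format == "tsv") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
      return(kmer_table(character(), integer(), k = NA_integer_))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    kmers <- vapply(parts, `[[`, character(1), 1L)
    counts <- as.integer(vapply(parts, `[[`, character(1), 2L))
    return(kmer_table(kmers, counts, k = nchar(kmers[1])))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4L)
  if (!identical(magic, charToRaw("KBCT")))
    stop("not a kbloom binary count file: ", path)
  version <- as.integer(readBin(con, "raw", n = 1L))
  if (version != 1L) stop("unsupported binary count format version ", version)
  hdr <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
  k <- hdr[1]
  n <- hdr[2]
  if (n == 0L) return(kmer_table(character(), integer(), k = k))
  nb <- (2L * k + 7L) %/% 8L
  payload <- readBin(con, "raw", n = n * (nb + 1L))
  if (length(payload) != n * (nb + 1L))
    stop("truncated binary count file: ", path)
  mat <- matrix(payload, nrow = nb + 1L)
  kmers <- cpp_decode(mat[seq_len(nb), , drop = FALSE], k)
  counts <- as.integer(mat[nb + 1L, ])
  kmer_table(kmers, counts, k = k)
}

#' Write reads as FASTQ
#'
#' Writes records (e.g. from [simulate_reads()]) as four-line FASTQ;
#' gzip-compressed when `path` ends in `.gz`.
#'
#' @param records Data frame with `id`, `sequence` and `quality` columns.
#' @param path Output path.
#' @return The number of records written, invisibly.
#' @export
write_fastq <- function(records, path) {
  stopifnot(is.data.frame(records),
            all(c("id", "sequence", "quality") %in% names(records)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  n <- nrow(records)
  if (n) {
    lines <- character(4L * n)
    lines[seq(1L, by = 4L, length.out = n)] <- paste0("@", records$id)
    lines[seq(2L, by = 4L, length.out = n)] <- records$sequence
    lines[seq(3L, by = 4L, length.out = n)] <- "+"
    lines[seq(4L, by = 4L, length.out = n)] <- records$quality
    writeLines(lines, con)
  }
  invisible(n)
}
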