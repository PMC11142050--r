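# small shared helpers: seeded RNG streams, sequence primitives, FASTA/FASTQ IO

DNA <- c("A", "C", "G", "T")

#' Derive a reproducible sub-seed for a named stage
#'
#' All randomness in the package flows from one integer seed; each stage
#' (panel, individual, reads, subsampling, ...) draws from its own derived
#' stream so stages are independently reproducible.
#'
#' @param seed Integer master seed.
#' @param stage Character stage label.
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((abs(seed) * 48271 + h) %% 2147483647)
}

random_dna <- function(n) {
  paste(sample(DNA, n, replace = TRUE), collapse = "")
}

#' Reverse-complement DNA strings
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) cpp_revcomp(x)

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# substitute a base with a different random base
other_base <- function(b) {
  vapply(b, function(x) sample(setdiff(DNA, x), 1L), character(1), USE.NAMES = FALSE)
}

#' Read paired FASTQ files into a read-pair tibble
#'
#' @param r1,r2 Paths to mate-1 and mate-2 FASTQ files (optionally gzipped).
#' @return A tibble with columns `read_id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pairs <- function(r1, r2) {
  parse_fq <- function(path) {
    ln <- readr::read_lines(path, progress = FALSE)
    if (length(ln) %% 4L != 0L)
      stop("malformed FASTQ (line count not a multiple of 4): ", path)
    i <- seq(1L, length(ln), by = 4L)
    bad <- which(!startsWith(ln[i], "@"))
    if (length(bad))
      stop("malformed FASTQ record '", ln[i[bad[1]]], "' in ", path)
    tibble::tibble(
      read_id = sub("/[12]$", "", sub("^@", "", sub("\\s.*$", "", ln[i]))),
      seq = ln[i + 1L], qual = ln[i + 3L])
  }
  a <- parse_fq(r1); b <- parse_fq(r2)
  if (nrow(a) != nrow(b)) stop("R1 and R2 have different numbers of records")
  tibble::tibble(read_id = a$read_id, seq1 = a$seq, qual1 = a$qual,
                 seq2 = b$seq, qual2 = b$qual)
}

#' Write a read-pair tibble to paired FASTQ files
#'
#' @param pairs Read-pair tibble (`read_id`, `seq1`, `qual1`, `seq2`, `qual2`).
#' @param r1,r2 Output paths; a `.gz` suffix triggers gzip compression.
#' @return Invisibly, the input `pairs`.
#' @export
write_fastq_pairs <- function(pairs, r1, r2) {
  emit <- function(id, s, q, path, mate) {
    readr::write_lines(
      as.vector(rbind(paste0("@", id, "/", mate), s, "+", q)), path)
  }
  emit(pairs$read_id, pairs$seq1, pairs$qual1, r1, 1L)
  emit(pairs$read_id, pairs$seq2, pairs$qual2, r2, 2L)
  invisible(pairs)
}

#' Write sequences to a FASTA file
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ln <- readr::read_lines(path, progress = FALSE)
  hd <- grepl("^>", ln)
  if (!any(hd)) stop("no FASTA headers in ", path)
  grp <- cumsum(hd)
  nm <- sub("^>", "", sub("\\s.*$", "", ln[hd]))
  seqs <- vapply(split(ln[!hd], grp[!hd]), paste, character(1), collapse = "")
  stats::setNames(toupper(unname(seqs)), nm)
}

#' Write intervals as a BED file (0-based half-open)
#' @param bed Tibble with `chrom`, `start`, `end` and optionally `name`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(bed, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(bed))
  readr::write_tsv(bed[cols], path, col_names = FALSE)
  invisible(path)
}

# N-free assembled length of a consensus string
nonN_length <- function(x) {
  nchar(x) - stringr::str_count(x, stringr::fixed("N"))
}
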