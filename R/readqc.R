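# read quality control: poly-G artifact removal, seeded subsampling,
# leading/trailing + sliding-window quality trimming with a length floor

#' Read-QC configuration
#'
#' Defaults follow the common short-read practice for two-channel Illumina
#' chemistry: drop pairs carrying a >= 20 bp G homopolymer (the poly-G
#' artifact), strip leading/trailing bases below Q3 or N, truncate at the
#' first 4 bp window of mean quality <= 15, and drop mates shorter than
#' 40 bp.
#'
#' @param min_g_run Minimum consecutive-G run marking an artifact read.
#' @param n_pairs Optional number of pairs to randomly retain (seeded).
#' @param seed Integer seed for subsampling.
#' @param lead_trail_q Leading/trailing quality floor.
#' @param window Sliding-window width in bp.
#' @param window_q Mean window quality at or below which the read is
#'   truncated at the window start.
#' @param min_len Minimum surviving mate length in bp.
#' @return A `qc_config` list.
#' @export
qc_config <- function(min_g_run = 20L, n_pairs = NULL, seed = 1L,
                      lead_trail_q = 3L, window = 4L, window_q = 15,
                      min_len = 40L) {
  stopifnot(min_g_run >= 1L, min_len >= 1L, window >= 1L)
  structure(list(min_g_run = as.integer(min_g_run), n_pairs = n_pairs,
                 seed = as.integer(seed), lead_trail_q = as.integer(lead_trail_q),
                 window = as.integer(window), window_q = window_q,
                 min_len = as.integer(min_len)),
            class = "qc_config")
}

#' Drop read pairs containing a long G homopolymer
#'
#' A pair is dropped whole when either mate contains a run of at least
#' `min_g_run` consecutive guanines; survivor order is preserved.
#'
#' @param pairs Read-pair tibble.
#' @param min_g_run Minimum run length (default 20).
#' @return Filtered read-pair tibble.
#' @export
filter_g_homopolymer <- function(pairs, min_g_run = 20L) {
  if (nrow(pairs) == 0L) return(pairs)
  run <- strrep("G", min_g_run)
  bad <- stringr::str_detect(pairs$seq1, stringr::fixed(run)) |
    stringr::str_detect(pairs$seq2, stringr::fixed(run))
  pairs[!bad, ]
}

#' Randomly subsample read pairs with a seed
#'
#' Mates are kept together; the same seed always selects the same pairs. If
#' `n_pairs` meets or exceeds the available pairs the input passes through
#' with a warning.
#'
#' @param pairs Read-pair tibble.
#' @param n_pairs Number of pairs to keep.
#' @param seed Integer seed.
#' @return Subsampled read-pair tibble (input order preserved).
#' @export
subsample_pairs <- function(pairs, n_pairs, seed = 1L) {
  if (n_pairs >= nrow(pairs)) {
    if (n_pairs > nrow(pairs))
      warning("requested ", n_pairs, " pairs but only ", nrow(pairs),
              " available; passing all through")
    return(pairs)
  }
  keep <- withr::with_seed(derive_seed(seed, "subsample"),
                           sort(sample.int(nrow(pairs), n_pairs)))
  pairs[keep, ]
}

#' Quality-trim read pairs
#'
#' Per mate: strip leading/trailing bases with quality below
#' `cfg$lead_trail_q` or base N; then scan `cfg$window`-bp windows 5' to 3'
#' and truncate at the start of the first window whose mean quality is
#' `<= cfg$window_q`; finally drop mates shorter than `cfg$min_len`. A pair
#' survives only if both mates survive.
#'
#' @param pairs Read-pair tibble.
#' @param cfg A [qc_config()].
#' @return Trimmed read-pair tibble.
#' @export
trim_reads <- function(pairs, cfg = qc_config()) {
  if (nrow(pairs) == 0L) return(pairs)
  if (any(nchar(pairs$seq1) != nchar(pairs$qual1)) ||
      any(nchar(pairs$seq2) != nchar(pairs$qual2))) {
    bad <- which(nchar(pairs$seq1) != nchar(pairs$qual1) |
                   nchar(pairs$seq2) != nchar(pairs$qual2))[1]
    stop("malformed FASTQ record '", pairs$read_id[bad],
         "': sequence and quality lengths differ")
  }
  t1 <- cpp_trim_batch(pairs$seq1, pairs$qual1, cfg$lead_trail_q,
                       cfg$window, cfg$window_q)
  t2 <- cpp_trim_batch(pairs$seq2, pairs$qual2, cfg$lead_trail_q,
                       cfg$window, cfg$window_q)
  len1 <- t1$end - t1$start + 1L
  len2 <- t2$end - t2$start + 1L
  keep <- len1 >= cfg$min_len & len2 >= cfg$min_len
  out <- pairs[keep, ]
  out$seq1 <- substring(out$seq1, t1$start[keep], t1$end[keep])
  out$qual1 <- substring(out$qual1, t1$start[keep], t1$end[keep])
  out$seq2 <- substring(out$seq2, t2$start[keep], t2$end[keep])
  out$qual2 <- substring(out$qual2, t2$start[keep], t2$end[keep])
  out
}

#' Run the full read-QC stage
#'
#' Applies, in order: poly-G pair filtering, optional seeded subsampling,
#' and quality trimming. Adapter removal is assumed done upstream.
#'
#' @param pairs Read-pair tibble.
#' @param cfg A [qc_config()].
#' @return The surviving read pairs, with a `qc_summary` attribute tibble
#'   (`stage`, `pairs_in`, `pairs_out`).
#' @export
qc_reads <- function(pairs, cfg = qc_config()) {
  stages <- list()
  n0 <- nrow(pairs)
  pairs <- filter_g_homopolymer(pairs, cfg$min_g_run)
  stages[[1]] <- tibble::tibble(stage = "g_homopolymer", pairs_in = n0,
                                pairs_out = nrow(pairs))
  if (!is.null(cfg$n_pairs)) {
    n1 <- nrow(pairs)
    pairs <- subsample_pairs(pairs, cfg$n_pairs, cfg$seed)
    stages[[2]] <- tibble::tibble(stage = "subsample", pairs_in = n1,
                                  pairs_out = nrow(pairs))
  }
  n2 <- nrow(pairs)
  pairs <- trim_reads(pairs, cfg)
  stages[[length(stages) + 1L]] <- tibble::tibble(
    stage = "trim", pairs_in = n2, pairs_out = nrow(pairs))
  attr(pairs, "qc_summary") <- dplyr::bind_rows(stages)
  pairs
}
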