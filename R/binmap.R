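# seed-and-extend read mapping to guides, mapped/unmapped binning, and
# superblock partitioning of the mapped fraction

#' Mapper scoring parameters
#'
#' End-to-end (query-global) alignment scoring. The acceptance rule is the
#' score-threshold function `score >= min_score_per_base * read_length`
#' (default -0.6, i.e. a 150 bp read must score at least -90); the individual
#' match/mismatch/gap constants mirror common end-to-end short-read mapper
#' defaults and are declared configuration.
#'
#' @param match,mismatch,gap_open,gap_ext Alignment scores (match 0,
#'   mismatch -6, gap open -5, gap extend -3 per base).
#' @param min_score_per_base Acceptance threshold per query base.
#' @return A `map_scoring` list.
#' @export
map_scoring <- function(match = 0, mismatch = -6, gap_open = -5,
                        gap_ext = -3, min_score_per_base = -0.6) {
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_ext = gap_ext, min_score_per_base = min_score_per_base),
            class = "map_scoring")
}

#' Build a seed index over one or more target sequences
#'
#' Exact-match lookup from every forward `seed_k`-mer to its target
#' positions; queries are searched in both orientations.
#'
#' @param targets Named character vector of target sequences (a single guide
#'   or a contig set).
#' @param seed_k Seed k-mer length.
#' @return A `mhc_seed_index` (external pointer plus metadata).
#' @export
index_targets <- function(targets, seed_k = 15L) {
  stopifnot(length(targets) >= 1L, !is.null(names(targets)))
  if (min(nchar(targets)) < seed_k)
    stop("seed_k (", seed_k, ") exceeds the shortest target length (",
         min(nchar(targets)), ")")
  ptr <- cpp_index_build(unname(targets), names(targets), as.integer(seed_k))
  structure(list(ptr = ptr, k = as.integer(seed_k),
                 target_names = names(targets),
                 target_lengths = nchar(targets)),
            class = "mhc_seed_index")
}

#' @rdname index_targets
#' @param guide A single guide sequence (character) or one-row panel slice.
#' @param name Target name used in alignments.
#' @export
index_guide <- function(guide, seed_k = 15L, name = "guide") {
  if (is.data.frame(guide)) {
    name <- guide$id[1]
    guide <- guide$sequence[1]
  }
  index_targets(stats::setNames(guide, name), seed_k)
}

#' Seed-index summary statistics
#' @param index A `mhc_seed_index`.
#' @return List with `n_positions` (forward seed positions indexed) and
#'   `n_distinct` (distinct forward seed k-mers).
#' @export
index_stats <- function(index) {
  cpp_index_stats(index$ptr)
}

#' Map reads against a seed index
#'
#' Best end-to-end alignment of each query (both orientations) under the
#' [map_scoring()] scheme; a query is accepted iff its score meets the
#' threshold function. Ties break to the leftmost target start, then the
#' plus strand. For small target sets the mapper switches to full dynamic
#' programming, making accept/reject decisions exact in that regime.
#'
#' @param reads Character vector of read sequences (or a tibble with a
#'   `seq` column).
#' @param index A `mhc_seed_index`.
#' @param scoring A [map_scoring()].
#' @return Alignment tibble: `query_id`, `mapped`, `target_id`,
#'   `target_start`, `target_end` (0-based half-open), `strand`, `score`,
#'   `matches`, `cigar`.
#' @export
map_reads <- function(reads, index, scoring = map_scoring()) {
  ids <- names(reads)
  if (is.data.frame(reads)) {
    ids <- reads$read_id
    reads <- reads$seq
  }
  if (is.null(ids)) ids <- as.character(seq_along(reads))
  df <- cpp_map_batch(reads, index$ptr, scoring$match, scoring$mismatch,
                      scoring$gap_open, scoring$gap_ext,
                      scoring$min_score_per_base)
  tibble::tibble(
    query_id = ids,
    mapped = df$mapped,
    target_id = index$target_names[df$tid],
    target_start = df$tstart, target_end = df$tend,
    strand = df$strand, score = df$score, matches = df$matches,
    cigar = df$cigar)
}

#' Map a single read
#' @param read A single read sequence.
#' @inheritParams map_reads
#' @return One-row alignment tibble (`mapped == FALSE` rows carry NAs:
#'   unmapped is a value, not an error).
#' @export
map_read <- function(read, index, scoring = map_scoring()) {
  map_reads(stats::setNames(read, "read"), index, scoring)
}

#' Bin read pairs against a guide
#'
#' Both mates are mapped; a pair lands in the mapped bin when either mate
#' maps (mate-rescue semantics), otherwise in the unmapped bin. Both bins
#' preserve pairing and order.
#'
#' @param pairs Read-pair tibble.
#' @param index A `mhc_seed_index` over the guide (or a guide sequence,
#'   which will be indexed on the fly).
#' @param scoring A [map_scoring()].
#' @return List: `mapped`, `unmapped` (read-pair tibbles), `alignments`
#'   (per-mate alignment tibble with `mate` column), `counts`.
#' @export
bin_reads <- function(pairs, index, scoring = map_scoring()) {
  if (is.character(index)) index <- index_guide(index)
  a1 <- map_reads(stats::setNames(pairs$seq1, pairs$read_id), index, scoring)
  a2 <- map_reads(stats::setNames(pairs$seq2, pairs$read_id), index, scoring)
  a1$mate <- 1L
  a2$mate <- 2L
  is_mapped <- a1$mapped | a2$mapped
  aln <- dplyr::bind_rows(a1, a2)
  list(mapped = pairs[is_mapped, ],
       unmapped = pairs[!is_mapped, ],
       alignments = aln[aln$mapped, ],
       counts = tibble::tibble(pairs_in = nrow(pairs),
                               pairs_mapped = sum(is_mapped),
                               pairs_unmapped = sum(!is_mapped)))
}

#' Partition mapped reads into overlapping superblocks
#'
#' The guide region covered by mapped reads is tiled into fixed spans with a
#' fixed overlap; each mapped pair is assigned to every superblock its
#' footprint (min to max aligned coordinate over both mates) intersects.
#' This is a deterministic simplification of coverage-contiguity block
#' building: the downstream role (localized de novo assembly) is identical.
#'
#' @param alignments Alignment tibble from [bin_reads()] (mapped mates).
#' @param target_span Superblock span in bp.
#' @param overlap Overlap between consecutive superblocks in bp.
#' @return Tibble: `superblock_id`, `start`, `end`, `read_ids` (list
#'   column of pair ids), `n_pairs`, `est_coverage`.
#' @export
build_superblocks <- function(alignments, target_span = 50000L,
                              overlap = 5000L) {
  if (overlap >= target_span)
    stop("overlap (", overlap, ") must be smaller than target_span (",
         target_span, ")")
  aln <- alignments[alignments$mapped, ]
  if (nrow(aln) == 0L) {
    return(tibble::tibble(superblock_id = character(), start = integer(),
                          end = integer(), read_ids = list(),
                          n_pairs = integer(), est_coverage = numeric()))
  }
  foot <- aln |>
    dplyr::group_by(.data$query_id) |>
    dplyr::summarise(fstart = min(.data$target_start),
                     fend = max(.data$target_end),
                     bp = sum(.data$target_end - .data$target_start),
                     .groups = "drop")
  lo <- min(foot$fstart)
  hi <- max(foot$fend)
  step <- target_span - overlap
  starts <- seq(lo, max(lo, hi - 1L), by = step)
  # drop trailing tiles fully contained in the previous one
  starts <- starts[starts < hi]
  tiles <- tibble::tibble(
    start = as.integer(starts),
    end = as.integer(pmin(starts + target_span, hi)))
  tiles <- tiles[tiles$end > tiles$start, ]
  if (nrow(tiles) >= 2L && tiles$end[nrow(tiles)] == tiles$end[nrow(tiles) - 1L])
    tiles <- tiles[-nrow(tiles), ]
  res <- vector("list", nrow(tiles))
  for (i in seq_len(nrow(tiles))) {
    hitidx <- which(foot$fstart < tiles$end[i] & foot$fend > tiles$start[i])
    res[[i]] <- tibble::tibble(
      superblock_id = sprintf("sb%03d", i),
      start = tiles$start[i], end = tiles$end[i],
      read_ids = list(foot$query_id[hitidx]),
      n_pairs = length(hitidx),
      est_coverage = sum(foot$bp[hitidx]) / (tiles$end[i] - tiles$start[i]))
  }
  dplyr::bind_rows(res)
}

#' Write alignments as a PAF-like TSV
#' @param alignments Alignment tibble.
#' @param qlen Named vector of query lengths (optional).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_paf <- function(alignments, path, qlen = NULL) {
  aln <- alignments[alignments$mapped, ]
  out <- tibble::tibble(
    query = aln$query_id,
    qlen = if (is.null(qlen)) NA_integer_ else unname(qlen[aln$query_id]),
    qstart = 0L,
    qend = if (is.null(qlen)) NA_integer_ else unname(qlen[aln$query_id]),
    strand = aln$strand,
    target = aln$target_id,
    tstart = aln$target_start,
    tend = aln$target_end,
    matches = aln$matches,
    block_len = aln$target_end - aln$target_start,
    score = aln$score)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}
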