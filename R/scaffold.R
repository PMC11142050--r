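# pileup polishing, paired-end scaffolding with gap estimation, guide-based
# ordering/orientation with score filtering, and consensus emission

map_batch_raw <- function(seqs, index, scoring = map_scoring()) {
  cpp_map_batch(seqs, index$ptr, scoring$match, scoring$mismatch,
                scoring$gap_open, scoring$gap_ext, scoring$min_score_per_base)
}

#' Polish contigs by pileup majority vote
#'
#' Reads are mapped back onto the contigs; at any column covered by at least
#' `min_depth` reads where an alternative base (or a length-1 indel) is
#' supported by more than `maj_frac` of the covering reads, the consensus is
#' corrected. Columns below the depth floor are never edited.
#'
#' @param contigs Contig tibble.
#' @param pairs Read-pair tibble from the same BMH bin.
#' @param min_depth Minimum covering reads for an edit.
#' @param maj_frac Majority fraction an alternative must exceed.
#' @param scoring A [map_scoring()].
#' @return Contig tibble with corrected sequences; edit counts in
#'   `attr(, "polish_edits")`.
#' @export
polish_contigs <- function(contigs, pairs, min_depth = 5L, maj_frac = 0.5,
                           scoring = map_scoring()) {
  if (nrow(contigs) == 0L || nrow(pairs) == 0L) {
    attr(contigs, "polish_edits") <- c(n_sub = 0L, n_ins = 0L, n_del = 0L)
    return(contigs)
  }
  idx <- index_targets(stats::setNames(contigs$sequence, contigs$id))
  seqs <- c(pairs$seq1, pairs$seq2)
  df <- map_batch_raw(seqs, idx, scoring)
  ok <- which(df$mapped)
  res <- cpp_pileup_polish(contigs$sequence, df$tid[ok], df$tstart[ok],
                           df$strand[ok], df$cigar[ok], seqs[ok],
                           as.integer(min_depth), maj_frac)
  out <- contigs
  out$sequence <- as.character(res$sequence)
  out$length <- nchar(out$sequence)
  attr(out, "polish_edits") <- c(n_sub = res$n_sub, n_ins = res$n_ins,
                                 n_del = res$n_del)
  out
}

#' Scaffold contigs with paired-end links
#'
#' Contigs are linked when at least `min_support` pairs straddle them with
#' consistent orientation; the gap is `max(min_gap, round(insert_mean - d1 -
#' d2))` averaged over supporting links. Orientation conflicts between two
#' contigs keep only the majority link class; branching links at a contig
#' end keep the most-supported partner (ties stay unlinked), so scaffolds
#' are strictly linear chains.
#'
#' @param contigs Contig tibble (ideally polished).
#' @param pairs Read-pair tibble.
#' @param insert_mean,insert_sd Insert-size statistics (from the simulator
#'   config or estimated from same-contig pairs).
#' @param min_support Minimum consistent straddling pairs per link.
#' @param min_gap Minimum emitted gap (N run) length.
#' @param scoring A [map_scoring()].
#' @return Scaffold tibble: `id`, `sequence`, `parts` (list column of
#'   `contig_id`, `strand`), `gaps` (list column of N-run lengths).
#' @export
scaffold_paired <- function(contigs, pairs, insert_mean, insert_sd = NULL,
                            min_support = 3L, min_gap = 10L,
                            scoring = map_scoring()) {
  stopifnot(nrow(contigs) >= 1L)
  if (nrow(contigs) == 1L || nrow(pairs) == 0L) {
    return(single_scaffolds(contigs))
  }
  idx <- index_targets(stats::setNames(contigs$sequence, contigs$id))
  a1 <- map_batch_raw(pairs$seq1, idx, scoring)
  a2 <- map_batch_raw(pairs$seq2, idx, scoring)
  both <- which(a1$mapped & a2$mapped & a1$tid != a2$tid)
  lens <- contigs$length
  if (!length(both)) return(single_scaffolds(contigs))

  links <- tibble::tibble(
    ca = a1$tid[both], cb = a2$tid[both],
    # attach end: '+' mate points off the east end, '-' off the west end
    ea = ifelse(a1$strand[both] == "+", "E", "W"),
    eb = ifelse(a2$strand[both] == "+", "E", "W"),
    d1 = ifelse(a1$strand[both] == "+", lens[a1$tid[both]] - a1$tstart[both],
                a1$tend[both]),
    d2 = ifelse(a2$strand[both] == "+", lens[a2$tid[both]] - a2$tstart[both],
                a2$tend[both]))
  # canonical ordering of the pair so (A,B) and (B,A) pool together
  flip <- links$ca > links$cb
  links <- tibble::tibble(
    ca = ifelse(flip, links$cb, links$ca),
    cb = ifelse(flip, links$ca, links$cb),
    ea = ifelse(flip, links$eb, links$ea),
    eb = ifelse(flip, links$ea, links$eb),
    gap = insert_mean - links$d1 - links$d2)

  grp <- links |>
    dplyr::count(.data$ca, .data$cb, .data$ea, .data$eb, name = "support")
  # orientation conflicts: keep only a clear majority class per contig pair
  grp <- grp |>
    dplyr::group_by(.data$ca, .data$cb) |>
    dplyr::mutate(total = sum(.data$support)) |>
    dplyr::slice_max(.data$support, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$support > .data$total / 2,
                  .data$support >= min_support) |>
    dplyr::select(-"total")
  if (nrow(grp) == 0L) return(single_scaffolds(contigs))
  gapmean <- links |>
    dplyr::inner_join(grp, by = c("ca", "cb", "ea", "eb")) |>
    dplyr::group_by(.data$ca, .data$cb, .data$ea, .data$eb) |>
    dplyr::summarise(gap = mean(.data$gap), .groups = "drop")
  grp <- dplyr::inner_join(grp, gapmean, by = c("ca", "cb", "ea", "eb"))

  # branching resolution: each contig end may participate in one link
  grp <- grp[order(-grp$support), ]
  used <- character(0)
  keep <- logical(nrow(grp))
  for (r in seq_len(nrow(grp))) {
    e <- c(paste0(grp$ca[r], grp$ea[r]), paste0(grp$cb[r], grp$eb[r]))
    if (any(e %in% used)) next
    # tie detection: another link with equal support sharing an end stays out
    tie <- which(grp$support == grp$support[r] & seq_len(nrow(grp)) != r &
                   (paste0(grp$ca, grp$ea) %in% e |
                      paste0(grp$cb, grp$eb) %in% e))
    if (length(tie)) { used <- c(used, e); next }
    keep[r] <- TRUE
    used <- c(used, e)
  }
  grp <- grp[keep, ]
  if (nrow(grp) == 0L) return(single_scaffolds(contigs))

  build_chains(contigs, grp, min_gap)
}

single_scaffolds <- function(contigs) {
  tibble::tibble(
    id = sprintf("scaf%03d", seq_len(nrow(contigs))),
    sequence = contigs$sequence,
    parts = lapply(seq_len(nrow(contigs)), function(i)
      tibble::tibble(contig_id = contigs$id[i], strand = "+")),
    gaps = rep(list(integer(0)), nrow(contigs)))
}

# assemble linear chains from end-disjoint links
build_chains <- function(contigs, grp, min_gap) {
  n <- nrow(contigs)
  # adjacency on (contig, end)
  adj <- list()
  key <- function(c, e) paste0(c, e)
  for (r in seq_len(nrow(grp))) {
    adj[[key(grp$ca[r], grp$ea[r])]] <- list(to = grp$cb[r], end = grp$eb[r],
                                             gap = grp$gap[r])
    adj[[key(grp$cb[r], grp$eb[r])]] <- list(to = grp$ca[r], end = grp$ea[r],
                                             gap = grp$gap[r])
  }
  linked <- unique(c(grp$ca, grp$cb))
  visited <- rep(FALSE, n)
  scaf <- list()
  for (c0 in seq_len(n)) {
    if (visited[c0]) next
    if (!(c0 %in% linked)) {
      visited[c0] <- TRUE
      scaf[[length(scaf) + 1L]] <- list(
        parts = tibble::tibble(contig_id = contigs$id[c0], strand = "+"),
        gaps = integer(0),
        sequence = contigs$sequence[c0])
      next
    }
    # find a terminus: an end with no link, preferring W so we walk eastward
    start_end <- NULL
    for (e in c("W", "E")) {
      if (is.null(adj[[key(c0, e)]])) { start_end <- e; break }
    }
    if (is.null(start_end)) start_end <- "W" # cycle: break arbitrarily
    # walk from the terminus through links
    cur <- c0
    # orientation: if the free end is W, contig is forward (we exit east)
    cur_strand <- if (start_end == "W") "+" else "-"
    parts <- tibble::tibble(contig_id = contigs$id[cur], strand = cur_strand)
    gaps <- integer(0)
    seqs <- list(orient_seq(contigs$sequence[cur], cur_strand))
    visited[cur] <- TRUE
    repeat {
      exit_end <- if (cur_strand == "+") "E" else "W"
      lk <- adj[[key(cur, exit_end)]]
      if (is.null(lk) || visited[lk$to]) break
      nxt <- lk$to
      nxt_strand <- if (lk$end == "W") "+" else "-"
      gaps <- c(gaps, max(min_gap, as.integer(round(lk$gap))))
      parts <- dplyr::bind_rows(parts, tibble::tibble(
        contig_id = contigs$id[nxt], strand = nxt_strand))
      seqs[[length(seqs) + 1L]] <- orient_seq(contigs$sequence[nxt], nxt_strand)
      visited[nxt] <- TRUE
      cur <- nxt
      cur_strand <- nxt_strand
    }
    pieces <- character(2L * length(seqs) - 1L)
    pieces[seq(1L, length(pieces), by = 2L)] <- unlist(seqs)
    if (length(gaps))
      pieces[seq(2L, length(pieces), by = 2L)] <- strrep("N", gaps)
    scaf[[length(scaf) + 1L]] <- list(parts = parts, gaps = gaps,
                                      sequence = paste(pieces, collapse = ""))
  }
  tibble::tibble(
    id = sprintf("scaf%03d", seq_along(scaf)),
    sequence = vapply(scaf, `[[`, character(1), "sequence"),
    parts = lapply(scaf, `[[`, "parts"),
    gaps = lapply(scaf, `[[`, "gaps"))
}

orient_seq <- function(s, strand) if (strand == "+") s else revcomp(s)

#' Score a scaffold's placement on a guide
#'
#' The scaffold is cut into windows that are mapped end-to-end on the guide.
#' Each aligned window implies a scaffold start position on the guide;
#' implied positions are clustered, and the location score is the aligned bp
#' supporting the modal placement cluster divided by total aligned bp. The
#' orientation score is the aligned bp on the modal strand divided by total
#' aligned bp.
#'
#' @param scaffold_seq Scaffold sequence (may contain N gaps).
#' @param guide_index A `mhc_seed_index` over the guide (or guide sequence).
#' @param window Window size in bp.
#' @param scoring A [map_scoring()].
#' @return One-row tibble: `location_score`, `orientation_score`,
#'   `assigned_start`, `assigned_strand`, `aligned_bp`.
#' @export
score_placement <- function(scaffold_seq, guide_index, window = 400L,
                            scoring = map_scoring()) {
  if (is.character(guide_index)) guide_index <- index_guide(guide_index)
  L <- nchar(scaffold_seq)
  starts <- seq(1L, L, by = window)
  chunks <- substring(scaffold_seq, starts, pmin(starts + window - 1L, L))
  keepc <- nchar(chunks) >= min(window, L) &
    !stringr::str_detect(chunks, "NNNNN")
  chunks <- chunks[keepc]
  offs <- starts[keepc] - 1L
  none <- tibble::tibble(location_score = 0, orientation_score = 0,
                         assigned_start = NA_integer_,
                         assigned_strand = NA_character_, aligned_bp = 0L)
  if (!length(chunks)) return(none)
  df <- map_batch_raw(chunks, guide_index, scoring)
  ok <- df$mapped
  if (!any(ok)) return(none)
  clen <- nchar(chunks)[ok]
  impl <- ifelse(df$strand[ok] == "+",
                 df$tstart[ok] - offs[ok],
                 df$tstart[ok] - (L - offs[ok] - clen))
  strand <- df$strand[ok]
  total <- sum(clen)

  # cluster implied starts: sort, split where neighbours jump > tolerance
  tol <- 5000 + 0.1 * L
  o <- order(impl)
  brk <- cumsum(c(0, diff(impl[o]) > tol))
  bp_by_cluster <- tapply(clen[o], brk, sum)
  modal <- as.integer(names(bp_by_cluster)[which.max(bp_by_cluster)])
  in_modal <- o[brk == modal]
  loc <- sum(clen[in_modal]) / total
  bp_strand <- tapply(clen, strand, sum)
  modal_strand <- names(bp_strand)[which.max(bp_strand)]
  orient <- max(bp_strand) / total
  wstart <- stats::weighted.mean(impl[in_modal], clen[in_modal])
  tibble::tibble(location_score = loc, orientation_score = orient,
                 assigned_start = as.integer(round(wstart)),
                 assigned_strand = modal_strand,
                 aligned_bp = as.integer(total))
}

#' Order, orient and filter scaffolds along the guide
#'
#' Applies the placement filter — a scaffold is demoted to the unplaced set
#' when `location_score < 0.1`, or when `location_score < 0.3` and
#' `orientation_score < 0.75` — then orders survivors by assigned guide
#' start, reverse-complements minus-strand scaffolds, and concatenates them
#' with inter-scaffold N gaps sized from guide spacing (minimum `min_gap`).
#'
#' @param scaffolds Scaffold tibble from [scaffold_paired()].
#' @param guide Guide sequence (character) or `mhc_seed_index`.
#' @param min_gap Minimum inter-scaffold gap.
#' @param window Placement window size.
#' @param scoring A [map_scoring()].
#' @return An `mhc_assembly`: list with `consensus` (single placed sequence),
#'   `placements` (tibble with scores and 0-based guide coordinates),
#'   `unplaced` (tibble of demoted scaffolds with their scores).
#' @export
place_and_filter <- function(scaffolds, guide, min_gap = 10L, window = 400L,
                             scoring = map_scoring()) {
  idx <- if (is.character(guide)) index_guide(guide) else guide
  sc <- dplyr::bind_rows(lapply(scaffolds$sequence, score_placement,
                                guide_index = idx, window = window,
                                scoring = scoring))
  sc$scaffold_id <- scaffolds$id
  sc$length <- nchar(scaffolds$sequence)
  fail <- sc$location_score < 0.1 |
    (sc$location_score < 0.3 & sc$orientation_score < 0.75)
  placed <- which(!fail)
  placed <- placed[order(sc$assigned_start[placed])]
  unplaced <- scaffolds[fail, ]
  unplaced_scores <- sc[fail, ]

  if (!length(placed)) {
    out <- list(consensus = "",
                placements = sc[0, ],
                unplaced = dplyr::bind_cols(
                  unplaced[, c("id", "sequence")],
                  unplaced_scores[, c("location_score", "orientation_score")]))
    class(out) <- "mhc_assembly"
    return(out)
  }
  seqs <- character(0)
  gaps <- integer(0)
  max_end <- NULL # rightmost guide coordinate covered so far: scaffolds
  # nested inside an earlier, larger scaffold's span must not shrink it,
  # or the following gap would re-insert already-covered guide distance
  for (i in placed) {
    s <- orient_seq(scaffolds$sequence[i], sc$assigned_strand[i])
    if (!is.null(max_end)) {
      gap <- max(min_gap, sc$assigned_start[i] - max_end)
      gaps <- c(gaps, gap)
    }
    seqs <- c(seqs, s)
    max_end <- max(max_end %||% -Inf, sc$assigned_start[i] + nchar(s))
  }
  pieces <- character(2L * length(seqs) - 1L)
  pieces[seq(1L, length(pieces), by = 2L)] <- seqs
  if (length(gaps))
    pieces[seq(2L, length(pieces), by = 2L)] <- strrep("N", gaps)
  out <- list(
    consensus = paste(pieces, collapse = ""),
    placements = sc[placed, c("scaffold_id", "assigned_start",
                              "assigned_strand", "location_score",
                              "orientation_score", "length", "aligned_bp")],
    unplaced = dplyr::bind_cols(
      unplaced[, c("id", "sequence")],
      unplaced_scores[, c("location_score", "orientation_score")]))
  class(out) <- "mhc_assembly"
  out
}

#' @export
print.mhc_assembly <- function(x, ...) {
  cat("<mhc_assembly>\n")
  cat("  placed consensus:", nchar(x$consensus), "bp (",
      nonN_length(x$consensus), "non-N )\n")
  cat("  placed scaffolds:", nrow(x$placements), "\n")
  cat("  unplaced scaffolds:", nrow(x$unplaced), "\n")
  invisible(x)
}

#' Write an assembly (consensus plus unplaced scaffolds) as FASTA
#'
#' One record for the ordered, continuous placed consensus, plus one record
#' per unplaced scaffold.
#'
#' @param assembly An `mhc_assembly`.
#' @param path Output path.
#' @param name Consensus record name.
#' @return Invisibly, `path`.
#' @export
write_assembly_fasta <- function(assembly, path, name = "consensus") {
  seqs <- c(stats::setNames(assembly$consensus, name),
            stats::setNames(assembly$unplaced$sequence,
                            paste0("unplaced_", assembly$unplaced$id)))
  write_fasta(seqs[nchar(seqs) > 0], path)
}

#' Write placements as an AGP-like table (1-based inclusive)
#' @param assembly An `mhc_assembly`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_placements <- function(assembly, path) {
  p <- assembly$placements
  out <- tibble::tibble(
    object = "consensus",
    start = p$assigned_start + 1L,
    end = p$assigned_start + p$length,
    part = p$scaffold_id,
    strand = p$assigned_strand,
    location_score = p$location_score,
    orientation_score = p$orientation_score)
  readr::write_tsv(out, path)
  invisible(path)
}
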