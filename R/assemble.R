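# de Bruijn contig assembly per superblock / unmapped pool, graph cleaning,
# cross-mapping contig filtering, and supercontig merging

#' Build a de Bruijn graph over canonical k-mers
#'
#' Nodes are canonical k-mers of both mates with occurrence coverage; edges
#' are (k-1)-overlap adjacencies. `k` must be odd (so no k-mer equals its
#' own reverse complement); the default k = 51 is used for both the
#' guide-mapped and unmapped read pools.
#'
#' @param reads Character vector of read sequences, or a read-pair tibble
#'   (both mates are used).
#' @param k Odd k-mer size.
#' @return A `mhc_dbg` object (external pointer plus `k`).
#' @export
build_debruijn <- function(reads, k = 51L) {
  if (is.data.frame(reads)) reads <- c(reads$seq1, reads$seq2)
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("k must be odd")
  if (all(nchar(reads) < k))
    stop("all reads are shorter than k = ", k, "; use a smaller k")
  structure(list(ptr = cpp_dbg_build(reads, k), k = k), class = "mhc_dbg")
}

#' Graph summary statistics
#' @param g A `mhc_dbg`.
#' @return List with `n_nodes` and the node `coverage` vector.
#' @export
dbg_stats <- function(g) cpp_dbg_stats(g$ptr)

#' Graph node table (small graphs)
#' @param g A `mhc_dbg`.
#' @return Tibble of canonical `kmer` and `coverage`.
#' @export
dbg_nodes <- function(g) tibble::as_tibble(cpp_dbg_nodes(g$ptr))

#' Clean a de Bruijn graph
#'
#' Iteratively, to a fixpoint: (1) remove nodes with coverage below
#' `cov_cutoff` (`"auto"` = `max(2, ceiling(median coverage / 10))`), (2)
#' clip dead-end tip paths shorter than `tip_len` bp, (3) pop bubbles whose
#' two branch sequences are at least `bubble_ident` identical, keeping the
#' higher-coverage branch.
#'
#' @param g A `mhc_dbg` (modified in place and returned).
#' @param tip_len Maximum tip length in bp (default `2 * k`).
#' @param bubble_ident Minimum branch identity for popping.
#' @param cov_cutoff Numeric cutoff or `"auto"`.
#' @param bubble_pop_ratio Asymmetric bubbles (minor branch at most this
#'   fraction of the major branch's coverage) are treated as noise and
#'   popped. Balanced bubbles are popped only when both branches run below
#'   ~75% of the graph-wide median coverage — the diploid heterozygous
#'   signature (each allele at half depth) — and kept when both branches
#'   carry full expected coverage, the signature of genuine two-copy
#'   sequence (near-identical tandem units) whose collapse would weld
#'   repeat copies into false contractions.
#' @param bubble_low_cov Minor branches at or below this coverage are always
#'   poppable.
#' @param max_rounds Safety cap on cleaning rounds.
#' @return The cleaned graph, invisibly the same object.
#' @export
simplify_graph <- function(g, tip_len = NULL, bubble_ident = 0.95,
                           cov_cutoff = "auto", bubble_pop_ratio = 0.5,
                           bubble_low_cov = 5, max_rounds = 8L) {
  if (is.null(tip_len)) tip_len <- 2L * g$k
  if (identical(cov_cutoff, "auto")) {
    cov <- cpp_dbg_stats(g$ptr)$coverage
    cov_cutoff <- if (length(cov)) max(2, ceiling(median(cov) / 10)) else 0
  }
  bubble_cap <- max(400L, 4L * g$k)
  for (round in seq_len(max_rounds)) {
    changed <- 0L
    changed <- changed + cpp_dbg_drop_low_cov(g$ptr, cov_cutoff)
    changed <- changed + cpp_dbg_clip_tips(g$ptr, as.integer(tip_len))
    cov_now <- cpp_dbg_stats(g$ptr)$coverage
    expected <- if (length(cov_now)) median(cov_now) else -1
    changed <- changed + cpp_dbg_pop_bubbles(g$ptr, bubble_ident, bubble_cap,
                                             bubble_pop_ratio, bubble_low_cov,
                                             expected)
    if (changed == 0L) break
  }
  invisible(g)
}

#' Extract contigs from a (cleaned) de Bruijn graph
#'
#' Maximal non-branching paths are spelled into sequences with their mean
#' k-mer coverage.
#'
#' @param g A `mhc_dbg`.
#' @param min_contig_len Minimum emitted contig length in bp.
#' @param origin Label recorded in the `origin` column (`"mapped"` or
#'   `"unmapped"`).
#' @param superblock_id Optional superblock label.
#' @return Contig tibble: `id`, `sequence`, `length`, `coverage`, `origin`,
#'   `superblock_id`.
#' @export
extract_contigs <- function(g, min_contig_len = 100L, origin = "mapped",
                            superblock_id = NA_character_) {
  res <- cpp_dbg_contigs(g$ptr, as.integer(min_contig_len))
  n <- length(res$sequence)
  if (n == 0L) {
    return(tibble::tibble(id = character(), sequence = character(),
                          length = integer(), coverage = numeric(),
                          origin = character(),
                          superblock_id = character()))
  }
  tibble::tibble(
    id = sprintf("%s_%s_c%04d",
                 ifelse(is.na(superblock_id), origin, superblock_id),
                 substr(origin, 1, 3), seq_len(n)),
    sequence = res$sequence,
    length = nchar(res$sequence),
    coverage = res$coverage,
    origin = origin,
    superblock_id = superblock_id)
}

#' Assemble one read pool into contigs
#'
#' Convenience wrapper: build, clean, extract.
#'
#' @param reads Character vector of reads or read-pair tibble.
#' @param k Odd k-mer size.
#' @inheritParams extract_contigs
#' @param ... Passed to [simplify_graph()].
#' @return Contig tibble.
#' @export
assemble_pool <- function(reads, k = 51L, min_contig_len = 100L,
                          origin = "mapped", superblock_id = NA_character_,
                          ...) {
  n <- if (is.data.frame(reads)) 2L * nrow(reads) else length(reads)
  empty <- tibble::tibble(id = character(), sequence = character(),
                          length = integer(), coverage = numeric(),
                          origin = character(), superblock_id = character())
  if (n == 0L) return(empty)
  if (is.data.frame(reads)) reads <- c(reads$seq1, reads$seq2)
  if (all(nchar(reads) < k)) return(empty)
  g <- build_debruijn(reads, k)
  simplify_graph(g, ...)
  out <- extract_contigs(g, min_contig_len, origin, superblock_id)
  rm(g)
  out
}

#' Remove unmapped-pool contigs that cross-map elsewhere
#'
#' A contig from the unmapped pool is removed when it aligns to the
#' alternative BMH guide or to any decoy sequence with >= `min_ident`
#' identity over >= `min_cover` of its length. Implemented by windowed
#' end-to-end mapping: the contig is cut into `window`-bp chunks and the
#' mapped fraction is the covered length. With no alternative guide and no
#' decoys the input passes through unchanged.
#'
#' @param contigs Contig tibble (unmapped origin).
#' @param alt_bmh Optional alternative guide sequence (character).
#' @param decoy Optional named character vector of decoy sequences.
#' @param min_ident Identity within a window for it to count as aligned.
#' @param min_cover Fraction of contig length that must align for removal.
#' @param window Window size in bp.
#' @return Filtered contig tibble with a `cross_map` attribute tibble
#'   logging removals.
#' @export
filter_cross_mapping <- function(contigs, alt_bmh = NULL, decoy = NULL,
                                 min_ident = 0.9, min_cover = 0.5,
                                 window = 100L) {
  targets <- c(
    if (!is.null(alt_bmh)) stats::setNames(alt_bmh, "alt_bmh"),
    decoy)
  if (is.null(targets) || length(targets) == 0L || nrow(contigs) == 0L) {
    attr(contigs, "cross_map") <- tibble::tibble(id = character(),
                                                 frac_aligned = numeric())
    return(contigs)
  }
  idx <- index_targets(targets)
  # identity >= min_ident within a window <=> mismatch score floor
  sc <- map_scoring(min_score_per_base = -6 * (1 - min_ident))
  frac <- vapply(seq_len(nrow(contigs)), function(i) {
    s <- contigs$sequence[i]
    L <- nchar(s)
    starts <- seq(1L, L, by = window)
    chunks <- substring(s, starts, pmin(starts + window - 1L, L))
    chunks <- chunks[nchar(chunks) >= min(window, L)]
    if (!length(chunks)) return(0)
    m <- map_reads(chunks, idx, sc)
    sum(nchar(chunks)[m$mapped]) / L
  }, numeric(1))
  removed <- frac >= min_cover
  out <- contigs[!removed, ]
  attr(out, "cross_map") <- tibble::tibble(id = contigs$id,
                                           frac_aligned = frac,
                                           removed = removed)
  out
}

#' Merge contigs into non-redundant supercontigs
#'
#' Greedy overlap-layout merging in descending length order: suffix-prefix
#' overlaps of at least `min_ovl` bp at `min_ident` identity are joined
#' (overlap sequence taken from the higher-coverage contig), and contigs
#' contained in another at `min_ident` are removed. Only unambiguous
#' overlaps are merged: a contig end with two incompatible qualifying
#' partners is left unjoined, so repeat-induced junctions stay apart rather
#' than being collapsed into false joins.
#'
#' @param contigs Contig tibble.
#' @param min_ovl Minimum overlap length in bp.
#' @param min_ident Minimum overlap identity.
#' @return Merged contig tibble with a `merge_log` attribute tibble.
#' @export
merge_supercontigs <- function(contigs, min_ovl = 40L, min_ident = 0.95) {
  if (nrow(contigs) == 0L) stop("no contigs to merge")
  work <- contigs
  log <- list()
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 200L) break
    act <- merge_pass(work, min_ovl, min_ident)
    if (is.null(act)) break
    work <- act$contigs
    log[[length(log) + 1L]] <- act$log
  }
  attr(work, "merge_log") <- if (length(log)) dplyr::bind_rows(log) else
    tibble::tibble(kept = character(), absorbed = character(),
                   type = character(), overlap = integer(),
                   identity = numeric())
  work
}

# one merge pass: finds all qualifying overlap/containment candidates, then
# applies the best unambiguous action; returns NULL at fixpoint
merge_pass <- function(contigs, min_ovl, min_ident) {
  n <- nrow(contigs)
  if (n <= 1L) return(NULL)
  cand <- tibble::as_tibble(
    cpp_overlap_candidates(contigs$sequence, k = 16L, min_votes = 2L))
  if (nrow(cand) == 0L) return(NULL)

  acts <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (i == j) next
    si <- contigs$sequence[i]
    sj <- if (cand$j_strand[r] == 0L) contigs$sequence[j] else
      revcomp(contigs$sequence[j])
    li <- nchar(si); lj <- nchar(sj)
    off <- cand$offset[r]
    if (off >= 0 && off + lj <= li) {
      ident <- cpp_segment_identity(si, off, sj, 0L, lj)
      if (ident >= min_ident)
        acts[[length(acts) + 1L]] <- tibble::tibble(
          type = "containment", i = i, j = j, strand = cand$j_strand[r],
          offset = off, ovl = lj, ident = ident)
    } else if (off > 0 && off < li && off + lj > li) {
      ovl <- li - off
      if (ovl >= min_ovl) {
        ident <- cpp_segment_identity(si, off, sj, 0L, ovl)
        if (ident >= min_ident)
          acts[[length(acts) + 1L]] <- tibble::tibble(
            type = "overlap", i = i, j = j, strand = cand$j_strand[r],
            offset = off, ovl = ovl, ident = ident)
      }
    }
  }
  if (!length(acts)) return(NULL)
  acts <- dplyr::bind_rows(acts)

  # containments are always safe to apply (absorb j into i); for mutual
  # containment (near-identical contigs) the first-seen survivor wins
  cont <- acts[acts$type == "containment" & acts$i != acts$j, ]
  if (nrow(cont)) {
    drop <- integer(0)
    kept <- integer(0)
    idrow <- integer(0)
    for (r in seq_len(nrow(cont))) {
      i <- cont$i[r]; j <- cont$j[r]
      if (i %in% drop || j %in% drop) next
      drop <- c(drop, j); kept <- c(kept, i); idrow <- c(idrow, r)
    }
    if (length(drop)) {
      lg <- tibble::tibble(kept = contigs$id[kept],
                           absorbed = contigs$id[drop],
                           type = "containment",
                           overlap = contigs$length[drop],
                           identity = cont$ident[idrow])
      return(list(contigs = contigs[-drop, ], log = lg))
    }
  }

  ovl <- acts[acts$type == "overlap", ]
  if (nrow(ovl) == 0L) return(NULL)
  # ambiguity: a suffix of i may qualify with several j (or vice versa)
  ovl <- ovl[!duplicated(ovl[, c("i", "j")]), ]
  amb_i <- ovl$i[duplicated(ovl$i)]
  amb_j <- ovl$j[duplicated(ovl$j)]
  ovl <- ovl[!(ovl$i %in% amb_i) & !(ovl$j %in% amb_j), ]
  if (nrow(ovl) == 0L) return(NULL)
  # apply all pairwise merges that do not reuse a contig within this pass
  ovl <- ovl[order(-ovl$ovl), ]
  used <- integer(0)
  newrows <- list()
  lg <- list()
  for (r in seq_len(nrow(ovl))) {
    a <- ovl[r, ]
    i <- a$i; j <- a$j
    if (i %in% used || j %in% used) next
    si <- contigs$sequence[i]
    sj <- if (a$strand == 0L) contigs$sequence[j] else
      revcomp(contigs$sequence[j])
    # overlap region from the higher-coverage contig
    head_part <- substr(si, 1L, a$offset)
    ovl_part <- if (contigs$coverage[i] >= contigs$coverage[j])
      substr(si, a$offset + 1L, nchar(si)) else substr(sj, 1L, a$ovl)
    tail_part <- substr(sj, a$ovl + 1L, nchar(sj))
    merged <- paste0(head_part, ovl_part, tail_part)
    newrows[[length(newrows) + 1L]] <- tibble::tibble(
      id = paste0(contigs$id[i], "+"),
      sequence = merged, length = nchar(merged),
      coverage = stats::weighted.mean(contigs$coverage[c(i, j)],
                                      contigs$length[c(i, j)]),
      origin = if (contigs$origin[i] == contigs$origin[j])
        contigs$origin[i] else "mixed",
      superblock_id = NA_character_)
    lg[[length(lg) + 1L]] <- tibble::tibble(
      kept = contigs$id[i], absorbed = contigs$id[j],
      type = "overlap", overlap = a$ovl, identity = a$ident)
    used <- c(used, i, j)
  }
  if (!length(newrows)) return(NULL)
  list(contigs = dplyr::bind_rows(c(newrows, list(contigs[-used, ]))),
       log = dplyr::bind_rows(lg))
}
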