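# validation machinery: anchor alignment of assembly vs truth, error calling
# and classification (base-call vs SV, repeat/tandem attribution), het-switch
# attribution, assembly statistics, unique-kmer read diagnostics, and
# VCF-style variant emission/merging

#' Anchor-align an assembly to a truth sequence
#'
#' Finds maximal runs of seed-mers unique in both sequences (both
#' orientations of the assembly are tried; the dominant one is used), keeps
#' runs of at least `min_anchor` bp, chains them colinearly by weighted
#' longest-increasing-subsequence, and pairwise-aligns inter-anchor
#' segments. Inter-anchor segments whose assembly side contains an N run are
#' classified as assembly gaps (missing sequence), not errors; sequence
#' outside the first/last anchor is classified `unaligned`.
#'
#' @param assembly Assembly sequence (may contain N gaps).
#' @param truth Truth sequence.
#' @param min_anchor Minimum anchor length in bp.
#' @param seed_k Seed-mer size used to detect unique exact matches.
#' @param max_dp Maximum cell count for inter-anchor dynamic programming;
#'   larger segment pairs are reported as paired insertion/deletion blocks.
#' @return An `mhc_anchor_alignment`: `orientation`, `anchors` (tibble
#'   `apos`, `tpos`, `len`), `events` (tibble `type`, `apos`, `tpos`, `len`,
#'   `ref`, `alt`), `assembly_len` (non-N bp), `aligned_bp`.
#' @export
anchor_align <- function(assembly, truth, min_anchor = 100L, seed_k = 63L,
                         max_dp = 4e6) {
  stopifnot(nchar(assembly) > 0L, nchar(truth) > 0L)
  fwd <- tibble::as_tibble(cpp_unique_anchors(assembly, truth,
                                              seed_k, min_anchor))
  rev_asm <- revcomp(assembly)
  rev <- tibble::as_tibble(cpp_unique_anchors(rev_asm, truth,
                                              seed_k, min_anchor))
  orientation <- if (sum(rev$length) > sum(fwd$length)) "-" else "+"
  if (orientation == "-") {
    assembly <- rev_asm
    anc <- rev
  } else anc <- fwd
  if (nrow(anc) == 0L)
    stop("no anchors of >= ", min_anchor,
         " bp found: sequences appear unrelated")
  keep <- cpp_chain_anchors(anc$astart, anc$bstart, anc$length)
  anc <- anc[keep, ]
  # trim residual overlaps so coordinates are strictly monotone
  if (nrow(anc) >= 2L) {
    for (i in 2:nrow(anc)) {
      ov <- max(anc$astart[i - 1] + anc$length[i - 1] - anc$astart[i],
                anc$bstart[i - 1] + anc$length[i - 1] - anc$bstart[i], 0)
      anc$astart[i] <- anc$astart[i] + ov
      anc$bstart[i] <- anc$bstart[i] + ov
      anc$length[i] <- anc$length[i] - ov
    }
    anc <- anc[anc$length > 0, ]
  }

  events <- list()
  add <- function(ev) events[[length(events) + 1L]] <<- ev
  aend <- anc$astart + anc$length
  bend <- anc$bstart + anc$length
  # leading/trailing unaligned ends (not counted as errors)
  if (anc$astart[1] > 0 || anc$bstart[1] > 0)
    add(tibble::tibble(type = "unaligned", apos = 0L, tpos = 0L,
                       len = as.integer(max(anc$astart[1], anc$bstart[1])),
                       ref = "", alt = ""))
  la <- nchar(assembly); lt <- nchar(truth)
  n <- nrow(anc)
  if (aend[n] < la || bend[n] < lt)
    add(tibble::tibble(type = "unaligned", apos = aend[n], tpos = bend[n],
                       len = as.integer(max(la - aend[n], lt - bend[n])),
                       ref = "", alt = ""))

  if (n >= 2L) {
    for (i in 2:n) {
      a0 <- aend[i - 1]; a1 <- anc$astart[i]
      t0 <- bend[i - 1]; t1 <- anc$bstart[i]
      seg_a <- substr(assembly, a0 + 1L, a1)
      seg_t <- substr(truth, t0 + 1L, t1)
      sla <- nchar(seg_a); slt <- nchar(seg_t)
      if (sla == 0L && slt == 0L) next
      if (grepl("N", seg_a, fixed = TRUE)) {
        add(tibble::tibble(type = "assembly_gap", apos = a0, tpos = t0,
                           len = as.integer(max(sla, slt)), ref = "", alt = ""))
        next
      }
      if (sla == 0L || slt == 0L) {
        if (sla > 0L)
          add(tibble::tibble(type = "ins", apos = a0, tpos = t0,
                             len = sla, ref = "", alt = seg_a))
        if (slt > 0L)
          add(tibble::tibble(type = "del", apos = a0, tpos = t0,
                             len = slt, ref = seg_t, alt = ""))
        next
      }
      if (as.double(sla) * slt <= max_dp) {
        add(segment_events(seg_a, seg_t, a0, t0))
      } else {
        # dissimilar large replacement: paired indel blocks
        add(tibble::tibble(type = "ins", apos = a0, tpos = t0,
                           len = sla, ref = "", alt = seg_a))
        add(tibble::tibble(type = "del", apos = a0, tpos = t0,
                           len = slt, ref = seg_t, alt = ""))
      }
    }
  }
  ev <- if (length(events)) dplyr::bind_rows(events) else
    tibble::tibble(type = character(), apos = integer(), tpos = integer(),
                   len = integer(), ref = character(), alt = character())
  structure(list(
    orientation = orientation,
    anchors = tibble::tibble(apos = anc$astart, tpos = anc$bstart,
                             len = anc$length),
    events = dplyr::arrange(ev, .data$apos),
    assembly_len = nonN_length(assembly),
    aligned_bp = sum(anc$length),
    assembly = assembly, truth = truth),
    class = "mhc_anchor_alignment")
}

# walk a global alignment of an inter-anchor segment pair into events
segment_events <- function(seg_a, seg_t, a0, t0) {
  r <- cpp_align_global(seg_a, seg_t, 0, -6, -5, -3)
  ops <- parse_cigar(r$cigar)
  out <- list()
  ap <- a0; tp <- t0
  ai <- 0L; ti <- 0L # local offsets
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; ln <- ops$len[i]
    if (op == "M") {
      ai <- ai + ln; ti <- ti + ln
    } else if (op == "X") {
      for (x in seq_len(ln)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          type = "snp", apos = a0 + ai + x - 1L, tpos = t0 + ti + x - 1L,
          len = 1L, ref = substr(seg_t, ti + x, ti + x),
          alt = substr(seg_a, ai + x, ai + x))
      }
      ai <- ai + ln; ti <- ti + ln
    } else if (op == "I") {
      out[[length(out) + 1L]] <- tibble::tibble(
        type = "ins", apos = a0 + ai, tpos = t0 + ti, len = ln,
        ref = "", alt = substr(seg_a, ai + 1L, ai + ln))
      ai <- ai + ln
    } else if (op == "D") {
      out[[length(out) + 1L]] <- tibble::tibble(
        type = "del", apos = a0 + ai, tpos = t0 + ti, len = ln,
        ref = substr(seg_t, ti + 1L, ti + ln), alt = "")
      ti <- ti + ln
    }
  }
  dplyr::bind_rows(out)
}

parse_cigar <- function(cig) {
  if (is.na(cig) || cig == "")
    return(tibble::tibble(op = character(), len = integer()))
  lens <- as.integer(stringr::str_extract_all(cig, "\\d+")[[1]])
  ops <- stringr::str_extract_all(cig, "[A-Z=]")[[1]]
  tibble::tibble(op = ops, len = lens)
}

# smallest period of a string (failure-function method)
smallest_period <- function(s) {
  n <- nchar(s)
  if (n < 2L) return(n)
  ch <- seq_chars(s)
  f <- integer(n)
  k <- 0L
  for (i in 2:n) {
    while (k > 0L && ch[k + 1L] != ch[i]) k <- f[k]
    if (ch[k + 1L] == ch[i]) k <- k + 1L
    f[i] <- k
  }
  n - f[n]
}

# does `motif` match the truth sequence immediately before/after tpos?
tandem_adjacent <- function(truth, tpos, motif, min_ident = 0.8) {
  p <- nchar(motif)
  if (p == 0L) return(FALSE)
  before <- if (tpos - p >= 0L) substr(truth, tpos - p + 1L, tpos) else ""
  after <- if (tpos + p <= nchar(truth)) substr(truth, tpos + 1L, tpos + p) else ""
  sim <- function(x) nchar(x) == p &&
    cpp_segment_identity(x, 0L, motif, 0L, p) >= min_ident
  sim(before) || sim(after)
}

#' Call and classify assembly errors against a truth sequence
#'
#' Single-base substitutions are base-call errors; indels of >= 1 bp are
#' structural-variant (SV) errors. An SV whose sequence is repetition of a
#' <= 100 bp motif present immediately adjacent in the truth is a tandem
#' expansion/contraction; an SV overlapping the repeat mask (by >= 1 bp) is
#' repeat-associated and labelled repeat expansion/contraction; remaining
#' SVs are plain insertions/deletions. Each error percentage is 100 x
#' (summed event bp of the category) / `assembly_len`; assembly gaps and
#' unaligned ends are excluded from the numerators.
#'
#' @param aln An `mhc_anchor_alignment` from [anchor_align()].
#' @param repeat_bed Optional repeat mask tibble in truth coordinates
#'   (`start`, `end`, 0-based half-open).
#' @param assembly_len Denominator bp; defaults to the alignment's non-N
#'   assembly length.
#' @return An `mhc_error_report`: `assembly_len`, `base_call_error_pct`,
#'   `nonrepeat_sv_error_pct`, `repeat_sv_error_pct`, `total_error_pct`, and
#'   the `events` tibble (`type`, `apos`, `tpos`, `len`,
#'   `repeat_associated`).
#' @export
call_errors <- function(aln, repeat_bed = NULL, assembly_len = NULL) {
  stopifnot(inherits(aln, "mhc_anchor_alignment"))
  if (is.null(assembly_len)) assembly_len <- aln$assembly_len
  ev <- aln$events
  ev <- ev[ev$type %in% c("snp", "ins", "del"), ]
  truth_overlap <- function(tpos, len) {
    if (is.null(repeat_bed) || nrow(repeat_bed) == 0L)
      return(rep(FALSE, length(tpos)))
    hi <- tpos + pmax(len, 1L)
    vapply(seq_along(tpos), function(i)
      any(repeat_bed$start < hi[i] & repeat_bed$end > tpos[i]),
      logical(1))
  }
  if (nrow(ev)) {
    typ <- character(nrow(ev))
    rep_assoc <- logical(nrow(ev))
    for (i in seq_len(nrow(ev))) {
      if (ev$type[i] == "snp") {
        typ[i] <- "snp"
        rep_assoc[i] <- FALSE
        next
      }
      sv_seq <- if (ev$type[i] == "ins") ev$alt[i] else ev$ref[i]
      is_ins <- ev$type[i] == "ins"
      over <- truth_overlap(ev$tpos[i],
                            if (is_ins) 0L else ev$len[i])
      p <- smallest_period(sv_seq)
      tandem <- p >= 1L && p <= 100L &&
        tandem_adjacent(aln$truth, ev$tpos[i], substr(sv_seq, 1L, p))
      typ[i] <- if (tandem) {
        if (is_ins) "tandem_expansion" else "tandem_contraction"
      } else if (over) {
        if (is_ins) "repeat_expansion" else "repeat_contraction"
      } else if (is_ins) "insertion" else "deletion"
      rep_assoc[i] <- over
    }
    ev$type <- typ
    ev$repeat_associated <- rep_assoc
  } else {
    ev$repeat_associated <- logical(0)
  }
  snp_bp <- sum(ev$len[ev$type == "snp"])
  sv <- ev[ev$type != "snp", ]
  rep_bp <- sum(sv$len[sv$repeat_associated])
  nonrep_bp <- sum(sv$len[!sv$repeat_associated])
  base_pct <- 100 * snp_bp / assembly_len
  nonrep_pct <- 100 * nonrep_bp / assembly_len
  rep_pct <- 100 * rep_bp / assembly_len
  structure(list(
    assembly_len = assembly_len,
    base_call_error_pct = base_pct,
    nonrepeat_sv_error_pct = nonrep_pct,
    repeat_sv_error_pct = rep_pct,
    total_error_pct = base_pct + nonrep_pct + rep_pct,
    events = ev[, c("type", "apos", "tpos", "len", "ref", "alt",
                    "repeat_associated")]),
    class = "mhc_error_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Attribute assembly mismatches to true error vs heterozygous inclusion
#'
#' Every SNP mismatch of the assembly against its primary truth haplotype is
#' checked against the homologous base of the other phased haplotype: if the
#' assembly base equals the other haplotype's allele, the mismatch is an
#' improper inclusion of the heterozygous allele rather than a true error.
#'
#' @param report An `mhc_error_report` (or events tibble with `type`,
#'   `tpos`, `alt`).
#' @param truth_primary The truth haplotype the assembly was measured
#'   against.
#' @param truth_other The other phased haplotype.
#' @return List: `true_error_fraction`, `het_inclusion_fraction`,
#'   `n_mismatches`, `no_mismatches` flag. Fractions sum to 1 when
#'   mismatches exist, and are both 0 (flagged) otherwise.
#' @export
attribute_het_switch <- function(report, truth_primary, truth_other) {
  ev <- if (inherits(report, "mhc_error_report")) report$events else report
  snp <- ev[ev$type == "snp", ]
  if (nrow(snp) == 0L) {
    return(list(true_error_fraction = 0, het_inclusion_fraction = 0,
                n_mismatches = 0L, no_mismatches = TRUE))
  }
  # coordinate lift other -> primary through their own anchor alignment;
  # positions inside inter-anchor gaps (the het sites themselves sit there)
  # are interpolated from the preceding anchor end
  oaln <- anchor_align(truth_other, truth_primary)
  anc <- oaln$anchors
  lift <- function(tpos) {
    hit <- which(anc$tpos <= tpos & tpos < anc$tpos + anc$len)
    if (length(hit))
      return(anc$apos[hit[1]] + (tpos - anc$tpos[hit[1]]))
    prev <- which(anc$tpos + anc$len <= tpos)
    nxt <- which(anc$tpos > tpos)
    if (!length(prev) || !length(nxt)) return(NA_integer_)
    p <- prev[length(prev)]
    op <- anc$apos[p] + anc$len[p] + (tpos - (anc$tpos[p] + anc$len[p]))
    if (op >= anc$apos[nxt[1]]) return(NA_integer_) # indel-shifted gap
    op
  }
  het <- vapply(seq_len(nrow(snp)), function(i) {
    op <- lift(snp$tpos[i])
    if (is.na(op)) return(FALSE)
    substr(truth_other, op + 1L, op + 1L) == snp$alt[i]
  }, logical(1))
  list(true_error_fraction = mean(!het),
       het_inclusion_fraction = mean(het),
       n_mismatches = nrow(snp),
       no_mismatches = FALSE)
}

#' Assembly summary statistics
#'
#' N50 is the length of the shortest contig in the minimal set of longest
#' contigs whose summed length covers at least half the total assembly
#' length.
#'
#' @param contigs Contig tibble (or a numeric vector of lengths).
#' @return One-row tibble: `n_contigs`, `n50`, `total_len`.
#' @export
assembly_stats <- function(contigs) {
  lens <- if (is.data.frame(contigs)) contigs$length else contigs
  if (length(lens) == 0L) stop("no contigs")
  sl <- sort(lens, decreasing = TRUE)
  n50 <- sl[which(cumsum(as.double(sl)) >= sum(as.double(sl)) / 2)[1]]
  tibble::tibble(n_contigs = length(lens), n50 = n50, total_len = sum(lens))
}

#' Unique k-mer ratio of a read set
#'
#' The number of distinct (canonical) k-mers occurring exactly once across
#' the read set, divided by the number of reads of length >= k. At k equal
#' to the read length this measures how much of the read content is
#' sequence seen only once — a proxy for novel/divergent content.
#'
#' @param pairs Read-pair tibble (both mates used) or character vector.
#' @param k K-mer size (default 150).
#' @return A single ratio.
#' @export
unique_kmer_ratio <- function(pairs, k = 150L) {
  reads <- if (is.data.frame(pairs)) c(pairs$seq1, pairs$seq2) else pairs
  if (!any(nchar(reads) >= k))
    stop("no read reaches length k = ", k)
  cs <- cpp_kmer_census(reads, as.integer(k), TRUE)
  cs$n_singleton / cs$n_reads_used
}

#' Call variants of a consensus against a reference
#'
#' SNPs and indels from the anchor alignment are emitted as VCF-style
#' records on 1-based reference coordinates; indels are left-normalized and
#' anchored on the preceding reference base.
#'
#' @param consensus Consensus sequence.
#' @param reference Reference sequence.
#' @param chrom Reference name for the records.
#' @return Variant tibble: `chrom`, `pos`, `ref`, `alt`.
#' @export
call_variants_vs_reference <- function(consensus, reference, chrom = "ref") {
  aln <- anchor_align(consensus, reference)
  ev <- aln$events
  ev <- ev[ev$type %in% c("snp", "ins", "del"), ]
  if (nrow(ev) == 0L) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character()))
  }
  rows <- lapply(seq_len(nrow(ev)), function(i) {
    tp <- ev$tpos[i]
    if (ev$type[i] == "snp") {
      return(tibble::tibble(chrom = chrom, pos = tp + 1L,
                            ref = ev$ref[i], alt = ev$alt[i]))
    }
    if (ev$type[i] == "ins") {
      s <- ev$alt[i]
      # shift left while the inserted suffix matches the preceding base
      while (tp > 0L &&
             substr(s, nchar(s), nchar(s)) == substr(reference, tp, tp)) {
        s <- paste0(substr(reference, tp, tp), substr(s, 1L, nchar(s) - 1L))
        tp <- tp - 1L
      }
      anchor <- if (tp >= 1L) substr(reference, tp, tp) else ""
      return(tibble::tibble(chrom = chrom, pos = tp, ref = anchor,
                            alt = paste0(anchor, s)))
    }
    d <- ev$ref[i]
    while (tp > 0L &&
           substr(d, nchar(d), nchar(d)) == substr(reference, tp, tp)) {
      d <- paste0(substr(reference, tp, tp), substr(d, 1L, nchar(d) - 1L))
      tp <- tp - 1L
    }
    anchor <- if (tp >= 1L) substr(reference, tp, tp) else ""
    tibble::tibble(chrom = chrom, pos = tp, ref = paste0(anchor, d),
                   alt = anchor)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out[out$pos >= 1L, ], .data$pos)
}

#' Merge per-haplotype variant records into per-individual genotypes
#'
#' A variant present in both haplotype call sets (same position and alleles)
#' becomes one homozygous record (`1/1`); present in one, a heterozygous
#' record (`0/1`); two different alt alleles at one site become a single
#' multi-allelic record with genotype `1/2`.
#'
#' @param records_a,records_b Variant tibbles from
#'   [call_variants_vs_reference()] for haplotypes A and B.
#' @return Variant tibble with a `gt` column.
#' @export
merge_haplotype_variants <- function(records_a, records_b) {
  refs <- unique(c(records_a$chrom, records_b$chrom))
  if (length(refs) > 1L)
    stop("mismatched reference ids: ", paste(refs, collapse = ", "))
  if (nrow(records_a) == 0L && nrow(records_b) == 0L) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          gt = character()))
  }
  key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt)
  ka <- key(records_a); kb <- key(records_b)
  hom <- records_a[ka %in% kb, ]
  if (nrow(hom)) hom$gt <- "1/1"
  only_a <- records_a[!(ka %in% kb), ]
  only_b <- records_b[!(kb %in% ka), ]
  het <- dplyr::bind_rows(only_a, only_b)
  if (nrow(het)) het$gt <- "0/1"
  out <- dplyr::bind_rows(hom, het)
  # conflicting alts at one site -> single 1/2 record
  sitekey <- paste(out$chrom, out$pos, out$ref)
  dup <- sitekey[duplicated(sitekey)]
  if (length(dup)) {
    keep <- !(sitekey %in% dup)
    merged <- lapply(unique(dup), function(sk) {
      rows <- out[sitekey == sk, ]
      tibble::tibble(chrom = rows$chrom[1], pos = rows$pos[1],
                     ref = rows$ref[1],
                     alt = paste(rows$alt, collapse = ","), gt = "1/2")
    })
    out <- dplyr::bind_rows(out[keep, ], dplyr::bind_rows(merged))
  }
  dplyr::arrange(out, .data$chrom, .data$pos)
}

#' Write variant records as a minimal VCF v4.2 file
#' @param records Variant tibble (with or without `gt`).
#' @param path Output path.
#' @param sample Sample name for the genotype column.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(records, path, sample = "sample") {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  sample))
  gt <- if ("gt" %in% names(records)) records$gt else rep("1/1", nrow(records))
  body <- if (nrow(records)) {
    paste(records$chrom, records$pos, ".", records$ref, records$alt,
          ".", "PASS", ".", "GT", gt, sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Alignment discontinuities between chained anchors
#'
#' For each adjacent anchor pair the assembly-side and truth-side gaps are
#' compared; `break_size = abs(t_gap - a_gap)` measures structural
#' discontinuity (the class II cassette check of the structural-variation
#' dotplots is `max(break_size)` over the region).
#'
#' @param aln An `mhc_anchor_alignment`.
#' @return Tibble: `apos`, `tpos`, `a_gap`, `t_gap`, `break_size`.
#' @export
alignment_breaks <- function(aln) {
  anc <- aln$anchors
  if (nrow(anc) < 2L) {
    return(tibble::tibble(apos = integer(), tpos = integer(),
                          a_gap = integer(), t_gap = integer(),
                          break_size = integer()))
  }
  i <- 2:nrow(anc)
  a_gap <- anc$apos[i] - (anc$apos[i - 1] + anc$len[i - 1])
  t_gap <- anc$tpos[i] - (anc$tpos[i - 1] + anc$len[i - 1])
  tibble::tibble(apos = anc$apos[i], tpos = anc$tpos[i],
                 a_gap = a_gap, t_gap = t_gap,
                 break_size = abs(t_gap - a_gap))
}
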