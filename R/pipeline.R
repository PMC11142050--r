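# end-to-end per-individual driver: QC -> BMH assignment -> binning ->
# superblock + unmapped-pool assembly -> cross-filter -> merge -> polish ->
# scaffold -> place/filter -> reports

#' Warn when estimated sequencing depth is too low for full assembly
#'
#' Below 25x average MHC coverage assemblies fragment and full-length
#' consensus sequences are not achieved; 30x or higher is recommended.
#'
#' @param estimated_depth Estimated per-haplotype fold coverage.
#' @return Invisibly, one of `"hard"`, `"soft"`, `"none"`; a warning is
#'   raised below 25x and an advisory message between 25x and 30x.
#' @export
warn_low_depth <- function(estimated_depth) {
  level <- if (estimated_depth < 25) {
    warning("estimated depth ", round(estimated_depth, 1),
            "x is below 25x: assemblies at this coverage are fragmented ",
            "and will not produce full-length consensus sequences",
            call. = FALSE)
    "hard"
  } else if (estimated_depth < 30) {
    message("estimated depth ", round(estimated_depth, 1),
            "x is below the recommended 30x; assembly may be incomplete")
    "soft"
  } else "none"
  invisible(level)
}

# median insert size from pairs with both mates on the same target
estimate_insert <- function(a1, a2) {
  both <- which(a1$mapped & a2$mapped & a1$tid == a2$tid &
                  a1$strand != a2$strand)
  if (length(both) < 20L) return(NULL)
  ins <- pmax(a1$tend[both], a2$tend[both]) - pmin(a1$tstart[both],
                                                   a2$tstart[both])
  list(mean = stats::median(ins), sd = stats::mad(ins))
}

#' Run the full haplotype-guided assembly for one individual
#'
#' Executes read QC, BMH assignment (from a provided DRB1 genotype or the
#' naive k-mer caller), per-BMH read binning, superblock de novo assembly of
#' guide-mapped reads plus separate assembly of the unmapped pool,
#' cross-mapping contig filtering, supercontig merging, pileup polishing,
#' paired-end scaffolding, and guide-based ordering/orientation with score
#' filtering. Heterozygous individuals get one full assembly pass per BMH;
#' their mapped read pairs are partitioned to the better-scoring BMH (ties
#' contribute to both), emulating trio binning with proxy-parental guides.
#' Re-running with an identical configuration reproduces identical output.
#'
#' @param pairs Read-pair tibble.
#' @param panel A `mhc_guide_panel`.
#' @param genotype DRB1 first-field genotype (character vector of two allele
#'   groups) or NULL to run the naive caller.
#' @param c4_status Optional per-haplotype C4 tibble (see [assign_bmh()]).
#' @param truth Optional `mhc_individual` for evaluation mode.
#' @param reference Optional named character (one sequence) against which
#'   per-haplotype variants are called and merged.
#' @param qc A [qc_config()].
#' @param scoring A [map_scoring()].
#' @param k_mapped,k_unmapped Odd de Bruijn k for the mapped/unmapped pools.
#' @param target_span,overlap Superblock tiling parameters (bp).
#' @param insert_mean,insert_sd Insert statistics; estimated from
#'   same-contig pairs when NULL.
#' @param min_contig_len Minimum contig length.
#' @param id Individual identifier.
#' @param verbose Print per-stage progress.
#' @return An `mhc_run`: `assignment`, `genotype`, `qc_summary`,
#'   `depth_estimate`, `bmh` (named per-guide list with `assembly`,
#'   `contigs`, `stats`, and in evaluation mode `error_report` and
#'   `het_attribution`), and `variants` (merged per-individual records when
#'   `reference` is given).
#' @export
run_individual <- function(pairs, panel, genotype = NULL, c4_status = NULL,
                           truth = NULL, reference = NULL,
                           qc = qc_config(), scoring = map_scoring(),
                           k_mapped = 51L, k_unmapped = 51L,
                           target_span = 50000L, overlap = 5000L,
                           insert_mean = NULL, insert_sd = NULL,
                           min_contig_len = 100L, id = "individual",
                           verbose = TRUE) {
  say <- function(...) if (verbose) message("[", id, "] ", ...)

  say("read QC (", nrow(pairs), " pairs in)")
  pairs <- qc_reads(pairs, qc)
  qc_summary <- attr(pairs, "qc_summary")
  say("QC done (", nrow(pairs), " pairs out)")

  if (is.null(genotype)) {
    say("naive DRB1 genotyping")
    gt <- naive_drb1_genotype(pairs, drb1_exemplar_panel(panel))
    if (gt$status == "no_call")
      stop("naive genotyper made no call; provide an explicit genotype")
    genotype <- gt$alleles
  }
  dr_classes <- assign_dr_class(genotype)
  bmh <- assign_bmh(dr_classes, c4_status, panel)
  say("BMH assignment: ", paste(bmh$guide_ids, collapse = ", "))

  guides <- panel[match(bmh$guide_ids, panel$id), ]
  total_bp <- sum(nchar(pairs$seq1)) + sum(nchar(pairs$seq2))
  depth_est <- total_bp / (2 * mean(guides$length))
  warn_low_depth(depth_est)

  # map all pairs against every BMH guide
  maps <- list()
  for (g in seq_len(nrow(guides))) {
    idx <- index_guide(guides[g, ])
    maps[[g]] <- list(
      a1 = map_batch_raw(pairs$seq1, idx, scoring),
      a2 = map_batch_raw(pairs$seq2, idx, scoring))
  }
  pair_mapped <- lapply(maps, function(m) m$a1$mapped | m$a2$mapped)
  pair_score <- lapply(maps, function(m) {
    s1 <- ifelse(m$a1$mapped, m$a1$score, 0)
    s2 <- ifelse(m$a2$mapped, m$a2$score, 0)
    miss <- (!m$a1$mapped) * -1e6 + (!m$a2$mapped) * -1e6
    s1 + s2 + miss
  })

  n_bmh <- nrow(guides)
  if (n_bmh == 1L) {
    bins <- list(which(pair_mapped[[1]]))
    unmapped_idx <- which(!pair_mapped[[1]])
  } else {
    s1 <- pair_score[[1]]; s2 <- pair_score[[2]]
    m1 <- pair_mapped[[1]]; m2 <- pair_mapped[[2]]
    bins <- list(which(m1 & (!m2 | s1 >= s2)),
                 which(m2 & (!m1 | s2 >= s1)))
    unmapped_idx <- which(!m1 & !m2)
  }
  say("binning: ", paste(lengths(bins), collapse = "/"), " pairs per BMH, ",
      length(unmapped_idx), " unmapped")

  if (is.null(insert_mean)) {
    est <- estimate_insert(maps[[1]]$a1, maps[[1]]$a2)
    if (is.null(est)) {
      insert_mean <- 500; insert_sd <- 50
    } else {
      insert_mean <- est$mean
      if (is.null(insert_sd)) insert_sd <- est$sd
    }
  }
  if (is.null(insert_sd)) insert_sd <- 50

  say("assembling unmapped pool (", length(unmapped_idx), " pairs)")
  unmapped_contigs <- assemble_pool(pairs[unmapped_idx, ], k = k_unmapped,
                                    min_contig_len = min_contig_len,
                                    origin = "unmapped")

  used_haps <- integer(0)
  per_bmh <- list()
  for (g in seq_len(n_bmh)) {
    gid <- guides$id[g]
    say("BMH ", gid, ": superblock assembly")
    bin_pairs <- pairs[bins[[g]], ]
    aln <- tibble::tibble(
      query_id = rep(pairs$read_id, 2L),
      mapped = c(maps[[g]]$a1$mapped, maps[[g]]$a2$mapped),
      target_start = c(maps[[g]]$a1$tstart, maps[[g]]$a2$tstart),
      target_end = c(maps[[g]]$a1$tend, maps[[g]]$a2$tend))
    aln <- aln[aln$mapped & aln$query_id %in% bin_pairs$read_id, ]
    sblocks <- build_superblocks(aln, target_span, overlap)

    ctg <- list()
    for (s in seq_len(nrow(sblocks))) {
      sb_pairs <- bin_pairs[bin_pairs$read_id %in% sblocks$read_ids[[s]], ]
      ctg[[s]] <- assemble_pool(sb_pairs, k = k_mapped,
                                min_contig_len = min_contig_len,
                                origin = "mapped",
                                superblock_id = sblocks$superblock_id[s])
    }
    mapped_contigs <- dplyr::bind_rows(ctg)
    # prefix ids with the BMH so the two passes never collide
    alt_seq <- if (n_bmh == 2L) guides$sequence[[3L - g]] else NULL
    say("BMH ", gid, ": cross-filtering + merging (",
        nrow(mapped_contigs), " mapped contigs, ",
        nrow(unmapped_contigs), " unmapped contigs)")
    un_f <- filter_cross_mapping(unmapped_contigs, alt_bmh = alt_seq)
    all_ctg <- dplyr::bind_rows(mapped_contigs, un_f)
    if (nrow(all_ctg) == 0L) {
      per_bmh[[gid]] <- list(assembly = NULL, contigs = all_ctg,
                             stats = NULL)
      next
    }
    all_ctg$id <- paste0(gid, "_", all_ctg$id)
    merged <- merge_supercontigs(all_ctg)
    say("BMH ", gid, ": polishing (", nrow(merged), " supercontigs)")
    polished <- polish_contigs(merged, bin_pairs, scoring = scoring)
    say("BMH ", gid, ": scaffolding")
    scaf <- scaffold_paired(polished, bin_pairs, insert_mean, insert_sd,
                            scoring = scoring)
    assembly <- place_and_filter(scaf, guides$sequence[[g]],
                                 scoring = scoring)
    stats <- assembly_stats(merged)

    entry <- list(assembly = assembly, contigs = merged, stats = stats,
                  scaffolds = scaf)
    if (!is.null(truth)) {
      hap_idx <- setdiff(which(truth$source_guides == gid), used_haps)
      if (length(hap_idx)) {
        hap_idx <- hap_idx[1]
        used_haps <- c(used_haps, hap_idx)
        hap_lab <- c("a", "b")[hap_idx]
        hap_seq <- if (hap_lab == "a") truth$hap_a else truth$hap_b
        other_seq <- if (hap_lab == "a") truth$hap_b else truth$hap_a
        say("BMH ", gid, ": evaluation vs truth haplotype ", hap_lab)
        taln <- anchor_align(assembly$consensus, hap_seq)
        rbed <- truth$repeats[truth$repeats$hap == hap_lab, ]
        entry$error_report <- call_errors(taln, repeat_bed = rbed)
        entry$het_attribution <- attribute_het_switch(
          entry$error_report, hap_seq, other_seq)
        entry$truth_hap <- hap_lab
        entry$truth_alignment <- taln
      }
    }
    if (!is.null(reference)) {
      entry$variants <- call_variants_vs_reference(
        assembly$consensus, reference[[1]],
        chrom = names(reference)[1] %||% "ref")
    }
    per_bmh[[gid]] <- entry
  }

  variants <- NULL
  if (!is.null(reference)) {
    vsets <- lapply(per_bmh, `[[`, "variants")
    vsets <- vsets[!vapply(vsets, is.null, logical(1))]
    if (length(vsets) == 2L) {
      variants <- merge_haplotype_variants(vsets[[1]], vsets[[2]])
    } else if (length(vsets) == 1L) {
      variants <- merge_haplotype_variants(vsets[[1]], vsets[[1]])
    }
  }

  structure(list(
    id = id, assignment = bmh, genotype = genotype,
    qc_summary = qc_summary, depth_estimate = depth_est,
    insert_mean = insert_mean, insert_sd = insert_sd,
    bmh = per_bmh, variants = variants),
    class = "mhc_run")
}

#' @export
print.mhc_run <- function(x, ...) {
  cat("<mhc_run>", x$id, "\n")
  cat("  genotype:", paste(x$genotype, collapse = "/"),
      " BMH:", paste(names(x$bmh), collapse = ", "), "\n")
  cat("  estimated depth:", round(x$depth_estimate, 1), "x\n")
  for (g in names(x$bmh)) {
    b <- x$bmh[[g]]
    if (is.null(b$assembly)) { cat("  ", g, ": no assembly\n"); next }
    cat("  ", g, ": consensus", nonN_length(b$assembly$consensus),
        "non-N bp,", b$stats$n_contigs, "contigs, N50", b$stats$n50, "\n")
    if (!is.null(b$error_report))
      cat(sprintf("     error vs truth hap %s: total %.4f%%\n",
                  b$truth_hap, b$error_report$total_error_pct))
  }
  invisible(x)
}
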