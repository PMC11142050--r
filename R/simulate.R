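# synthetic MHC-like panel, diploid individuals, and paired-end reads
#
# The generator builds a shared ancestor backbone and derives guide haplotypes
# from it: class II structural cassettes of class-specific size (the
# DR2/DR3/DR4/DR8 structural blocks driven by the DRB paralogs), a tandem C4
# block with copy-number and long/short variation, interspersed repeat
# elements, an allele-group-specific DRB1 block, and private backbone SNPs.
# Everything is seed-deterministic with full truth tracking.

DR_CLASSES <- c("DR1", "DR2", "DR3", "DR4", "DR8")

# class II cassette sizes (bp): relative structure only is biological truth
# (DR4 carries the most extra sequence, DR8 none); sizes are desk-scale picks.
CASSETTE_LEN <- c(DR1 = 3000L, DR2 = 8000L, DR3 = 6000L, DR4 = 14000L, DR8 = 0L)

C4_UNIT_LEN <- 5000L
C4_LONG_INSERT_LEN <- 1000L
DRB1_BLOCK_LEN <- 1000L

REPEAT_FAMILIES <- c(AluSim = 300L, LineSim = 1000L, MerSim = 600L)
REPEAT_COPY_DIVERGENCE <- 0.1

# default C4 (c4a, c4b, long_forms) per haplotype class; duplicates of a class
# in one panel cycle through variants so BMH choice can use C4 status
C4_DEFAULT <- list(c(1L, 1L, 1L), c(1L, 0L, 0L), c(2L, 1L, 1L), c(1L, 1L, 0L))

mutate_copy <- function(seq, rate) {
  n <- nchar(seq)
  pos <- which(runif(n) < rate)
  if (!length(pos)) return(seq)
  ch <- seq_chars(seq)
  ch[pos] <- other_base(ch[pos])
  paste(ch, collapse = "")
}

#' Default HLA-DRB1 allele-group to DR-haplotype-class table
#'
#' First-field DRB1 allele groups map onto the structural DR haplotype
#' classes through linkage with the DRB3/DRB4/DRB5 paralogs. The table is an
#' editable default: pass your own mapping to [assign_dr_class()] to override.
#'
#' @return A tibble with columns `allele_group` and `dr_class`.
#' @export
default_dr_class_table <- function() {
  tibble::tribble(
    ~allele_group, ~dr_class,
    "01", "DR1", "10", "DR1",
    "15", "DR2", "16", "DR2",
    "03", "DR3", "11", "DR3", "12", "DR3", "13", "DR3", "14", "DR3",
    "04", "DR4", "07", "DR4", "09", "DR4",
    "08", "DR8")
}

# representative allele group embedded in a guide of a given class
class_representative_group <- function(dr_class) {
  tab <- default_dr_class_table()
  vapply(dr_class, function(cl) tab$allele_group[tab$dr_class == cl][1],
         character(1), USE.NAMES = FALSE)
}

make_exemplars <- function(seed) {
  tab <- default_dr_class_table()
  out <- vapply(tab$allele_group, function(g) {
    withr::with_seed(derive_seed(seed, paste0("drb1exemplar:", g)),
                     random_dna(DRB1_BLOCK_LEN))
  }, character(1))
  stats::setNames(out, tab$allele_group)
}

place_repeats <- function(base_len, repeat_density, reserved) {
  # sample non-overlapping repeat copies over the ancestor until the density
  # target is met; returns tibble(start, end, family, sequence)
  if (repeat_density <= 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          family = character(), sequence = character()))
  }
  consensus <- lapply(REPEAT_FAMILIES, function(L) random_dna(L))
  target_bp <- repeat_density * base_len
  placed_bp <- 0
  rows <- list()
  occupied <- reserved
  tries <- 0L
  while (placed_bp < target_bp && tries < 50000L) {
    tries <- tries + 1L
    fam <- sample(names(REPEAT_FAMILIES), 1L)
    L <- REPEAT_FAMILIES[[fam]]
    s <- sample.int(base_len - L, 1L) - 1L # 0-based
    e <- s + L
    clash <- any(s < occupied$end & e > occupied$start)
    if (clash) next
    occupied <- dplyr::bind_rows(occupied, tibble::tibble(start = s, end = e))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      start = s, end = e, family = fam,
      sequence = mutate_copy(consensus[[fam]], REPEAT_COPY_DIVERGENCE))
    placed_bp <- placed_bp + L
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$start)
}

build_c4_block <- function(c4a, c4b, long_forms, unit_a, long_insert) {
  n_units <- c4a + c4b
  ab <- c(rep("A", c4a), rep("B", c4b))
  # C4B: a handful of substitutions relative to C4A (the genes are
  # near-identical; this is their defining property)
  unit_b <- unit_a
  bpos <- withr::with_seed(7L, sample.int(nchar(unit_a), 10L))
  ch <- seq_chars(unit_a)
  ch[bpos] <- vapply(ch[bpos], function(x) setdiff(DNA, x)[1], character(1))
  unit_b <- paste(ch, collapse = "")
  seqs <- character(n_units)
  lens <- integer(n_units)
  for (i in seq_len(n_units)) {
    u <- if (ab[i] == "A") unit_a else unit_b
    if (i <= long_forms) {
      u <- paste0(substr(u, 1L, 2500L), long_insert,
                  substr(u, 2501L, nchar(u)))
    }
    seqs[i] <- u
    lens[i] <- nchar(u)
  }
  list(sequence = paste(seqs, collapse = ""), unit_lens = lens)
}

#' Generate a synthetic MHC-like guide haplotype panel
#'
#' Builds `n` guide haplotypes from one shared ancestor backbone. Guides
#' differ by: a DR-class-specific class II cassette inserted at a fixed locus
#' (DR4 largest, DR8 absent, so class II structure orders guide lengths); a
#' tandem C4 block of 1-3 near-identical ~5 kb units with long/short forms
#' distinguished by an internal ~1 kb insertion; a 1 kb allele-group-specific
#' DRB1 block; interspersed repeat elements shared through the ancestor; and
#' private backbone substitutions at `backbone_divergence`, reflecting the
#' SNP-level divergence real MHC reference haplotypes carry on top of their
#' structural differences.
#'
#' @param n Number of guides.
#' @param base_len Ancestor backbone length in bp (>= 50 kb recommended for
#'   assembly experiments).
#' @param dr_mix Character vector of DR classes, recycled to length `n`.
#' @param repeat_density Fraction of the backbone occupied by interspersed
#'   repeat copies (each copy ~10% diverged from its family consensus).
#' @param backbone_divergence Per-bp substitution rate applied privately to
#'   each guide's backbone.
#' @param seed Integer seed; panels are byte-identical for identical seeds.
#' @return A `mhc_guide_panel` tibble with columns `id`, `dr_class`,
#'   `drb1_group`, `c4a`, `c4b`, `c4_long`, `length`, `sequence`; repeat truth
#'   intervals are in `attr(panel, "repeats")` (0-based half-open) and the
#'   DRB1 exemplar sequences in `attr(panel, "drb1_exemplars")`.
#' @export
generate_guide_panel <- function(n = 8L, base_len = 300000L,
                                 dr_mix = c("DR2", "DR3", "DR4", "DR8",
                                            "DR1", "DR2", "DR3", "DR4"),
                                 repeat_density = 0.2,
                                 backbone_divergence = 0.004,
                                 seed = 1L) {
  stopifnot(n >= 1L, base_len >= 1000L)
  bad <- setdiff(dr_mix, DR_CLASSES)
  if (length(bad))
    stop("invalid dr_class value(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(DR_CLASSES, collapse = ", "), ")")
  dr_mix <- rep_len(dr_mix, n)

  drb1_locus <- as.integer(floor(0.35 * base_len))     # 0-based
  cassette_locus <- as.integer(floor(0.40 * base_len))
  c4_locus <- as.integer(floor(0.55 * base_len))
  reserved <- tibble::tibble(
    start = c(drb1_locus - 200L, cassette_locus - 200L, c4_locus - 200L),
    end = c(drb1_locus + DRB1_BLOCK_LEN + 200L, cassette_locus + 200L,
            c4_locus + 200L))

  anc <- withr::with_seed(derive_seed(seed, "ancestor"), {
    a <- random_dna(base_len)
    reps <- place_repeats(base_len, repeat_density, reserved)
    if (nrow(reps)) {
      for (i in seq_len(nrow(reps))) {
        substr(a, reps$start[i] + 1L, reps$end[i]) <- reps$sequence[i]
      }
    }
    list(seq = a, repeats = reps[, c("start", "end", "family")])
  })

  cassettes <- withr::with_seed(derive_seed(seed, "cassettes"), {
    lapply(CASSETTE_LEN, function(L) if (L > 0) random_dna(L) else "")
  })
  c4_parts <- withr::with_seed(derive_seed(seed, "c4"), {
    list(unit = random_dna(C4_UNIT_LEN), long = random_dna(C4_LONG_INSERT_LEN))
  })
  exemplars <- make_exemplars(seed)

  rows <- vector("list", n)
  rep_rows <- vector("list", n)
  for (i in seq_len(n)) {
    cl <- dr_mix[i]
    k <- sum(dr_mix[seq_len(i)] == cl) # occurrence index within class
    c4cfg <- C4_DEFAULT[[(k - 1L) %% length(C4_DEFAULT) + 1L]]
    grp <- class_representative_group(cl)
    id <- sprintf("guide%02d_%s", i, cl)

    backbone <- withr::with_seed(derive_seed(seed, paste0("backbone:", i)), {
      mutate_copy(anc$seq, backbone_divergence)
    })
    # DRB1 block: same-length substitution, no coordinate shift
    substr(backbone, drb1_locus + 1L, drb1_locus + DRB1_BLOCK_LEN) <-
      exemplars[[grp]]

    cas <- cassettes[[cl]]
    c4 <- build_c4_block(c4cfg[1], c4cfg[2], c4cfg[3], c4_parts$unit,
                         c4_parts$long)
    seqs <- paste0(
      substr(backbone, 1L, cassette_locus),
      cas,
      substr(backbone, cassette_locus + 1L, c4_locus),
      c4$sequence,
      substr(backbone, c4_locus + 1L, base_len))

    d_cas <- nchar(cas)
    d_c4 <- nchar(c4$sequence)
    shift <- function(p) {
      p + ifelse(p >= c4_locus, d_cas + d_c4,
                 ifelse(p >= cassette_locus, d_cas, 0L))
    }
    reps <- anc$repeats
    guide_reps <- tibble::tibble(
      guide_id = id,
      start = as.integer(shift(reps$start)), end = as.integer(shift(reps$end)),
      family = reps$family)
    # C4 units annotated as repeat truth (tandem near-identical copies)
    unit_starts <- c4_locus + d_cas + cumsum(c(0L, utils::head(c4$unit_lens, -1L)))
    guide_reps <- dplyr::bind_rows(guide_reps, tibble::tibble(
      guide_id = id, start = as.integer(unit_starts),
      end = as.integer(unit_starts + c4$unit_lens), family = "C4Sim"))

    rows[[i]] <- tibble::tibble(
      id = id, dr_class = cl, drb1_group = grp,
      c4a = c4cfg[1], c4b = c4cfg[2], c4_long = c4cfg[3],
      length = nchar(seqs), sequence = seqs)
    rep_rows[[i]] <- dplyr::arrange(guide_reps, .data$start)
  }

  panel <- dplyr::bind_rows(rows)
  stopifnot(all(panel$length == nchar(panel$sequence)))
  attr(panel, "repeats") <- dplyr::bind_rows(rep_rows)
  attr(panel, "drb1_exemplars") <- exemplars
  attr(panel, "params") <- list(
    n = n, base_len = base_len, dr_mix = dr_mix,
    repeat_density = repeat_density,
    backbone_divergence = backbone_divergence, seed = seed,
    drb1_locus = drb1_locus, cassette_locus = cassette_locus,
    c4_locus = c4_locus)
  class(panel) <- c("mhc_guide_panel", class(panel))
  panel
}

#' Repeat truth intervals of a guide panel
#' @param panel A `mhc_guide_panel`.
#' @return Tibble `guide_id`, `start`, `end`, `family` (0-based half-open).
#' @export
panel_repeats <- function(panel) attr(panel, "repeats")

#' DRB1 first-field exemplar sequences of a panel
#'
#' One exemplar sequence per allele group of the class table, generated from
#' the panel seed. These are the reference sequences the naive stand-in
#' genotyper matches read k-mers against.
#'
#' @param panel A `mhc_guide_panel`.
#' @return Named character vector (allele group -> sequence).
#' @export
drb1_exemplar_panel <- function(panel) attr(panel, "drb1_exemplars")

#' Simulate a diploid individual from two guide haplotypes
#'
#' Each haplotype is its guide mutated at the stated rates; every introduced
#' change is recorded so truth can be reconstructed exactly.
#'
#' @param panel A `mhc_guide_panel`.
#' @param guide_pair Character vector of two guide ids (may be identical for
#'   a structurally homozygous individual).
#' @param divergence Per-bp substitution rate of each haplotype from its
#'   guide (must be < 0.1; larger values break the binning assumptions).
#' @param indel_rate Per-bp small-indel rate (lengths 1-10).
#' @param seed Integer seed.
#' @param id Individual identifier.
#' @return An `mhc_individual` list: `hap_a`/`hap_b` sequences,
#'   `source_guides`, `truth_variants` (0-based guide coordinates),
#'   `drb1_genotype`, `c4_status`, and `repeats` lifted to haplotype
#'   coordinates.
#' @export
simulate_individual <- function(panel, guide_pair, divergence = 0.005,
                                indel_rate = 5e-4, seed = 1L, id = "sim1") {
  stopifnot(length(guide_pair) == 2L)
  if (divergence >= 0.1)
    stop("divergence >= 0.1 is rejected: unrealistic and breaks guide binning")
  missing <- setdiff(guide_pair, panel$id)
  if (length(missing))
    stop("guide id(s) not in panel: ", paste(missing, collapse = ", "))

  g <- lapply(guide_pair, function(gid) panel[panel$id == gid, ])
  haps <- list()
  tv <- list()
  reps <- list()
  for (h in 1:2) {
    gseq <- g[[h]]$sequence
    hap_lab <- c("a", "b")[h]
    res <- withr::with_seed(derive_seed(seed, paste0("hap:", hap_lab)), {
      mutate_haplotype(gseq, divergence, indel_rate)
    })
    haps[[h]] <- res$seq
    res$variants$hap <- rep(hap_lab, nrow(res$variants))
    tv[[h]] <- res$variants
    prep <- panel_repeats(panel)
    prep <- prep[prep$guide_id == g[[h]]$id, ]
    reps[[h]] <- tibble::tibble(
      hap = hap_lab,
      start = lift_position(prep$start, res$variants),
      end = lift_position(prep$end, res$variants),
      family = prep$family)
  }
  structure(list(
    id = id,
    hap_a = haps[[1]], hap_b = haps[[2]],
    source_guides = guide_pair,
    truth_variants = dplyr::bind_rows(tv)[, c("hap", "pos", "ref", "alt", "class")],
    drb1_genotype = sort(c(g[[1]]$drb1_group, g[[2]]$drb1_group)),
    dr_classes = sort(unique(c(g[[1]]$dr_class, g[[2]]$dr_class))),
    c4_status = tibble::tibble(
      hap = c("a", "b"),
      c4a = c(g[[1]]$c4a, g[[2]]$c4a),
      c4b = c(g[[1]]$c4b, g[[2]]$c4b),
      long = c(g[[1]]$c4_long, g[[2]]$c4_long)),
    repeats = dplyr::bind_rows(reps)),
    class = "mhc_individual")
}

# draw substitution and small-indel events and apply them; returns the
# mutated sequence and the truth event table (0-based guide coordinates)
mutate_haplotype <- function(gseq, divergence, indel_rate) {
  L <- nchar(gseq)
  snp_pos <- which(runif(L) < divergence) - 1L
  ind_pos <- which(runif(L) < indel_rate) - 1L
  ind_pos <- setdiff(ind_pos, snp_pos)
  ch <- seq_chars(gseq)

  ev <- list()
  if (length(snp_pos)) {
    ref <- ch[snp_pos + 1L]
    alt <- other_base(ref)
    ev[[1L]] <- tibble::tibble(pos = snp_pos, ref = ref, alt = alt,
                               class = "snp")
  }
  if (length(ind_pos)) {
    len <- pmin(1L + stats::rgeom(length(ind_pos), 0.5), 10L)
    is_ins <- runif(length(ind_pos)) < 0.5
    ins_alt <- vapply(len, random_dna, character(1))
    ev[[2L]] <- tibble::tibble(
      pos = ind_pos,
      ref = ifelse(is_ins, "",
                   substring(gseq, ind_pos + 1L, pmin(ind_pos + len, L))),
      alt = ifelse(is_ins, ins_alt, ""),
      class = ifelse(is_ins, "ins", "del"))
  }
  empty <- tibble::tibble(pos = integer(), ref = character(),
                          alt = character(), class = character())
  variants <- dplyr::arrange(dplyr::bind_rows(empty, ev), .data$pos)
  if (nrow(variants)) {
    # drop events that overlap a preceding deletion span
    endpt <- variants$pos + nchar(variants$ref) +
      ifelse(variants$class == "ins", 1L, 0L)
    endpt <- pmax(endpt, variants$pos + 1L)
    keep <- rep(TRUE, nrow(variants))
    reach <- -1L
    for (i in seq_len(nrow(variants))) {
      if (variants$pos[i] < reach) { keep[i] <- FALSE; next }
      reach <- max(reach, endpt[i])
    }
    variants <- variants[keep, ]
  }
  list(seq = apply_variants(gseq, variants), variants = variants)
}

#' Reconstruct a haplotype from its guide and truth variants
#'
#' The round-trip contract of the simulator: applying `truth_variants` to the
#' source guide reproduces the haplotype byte-for-byte.
#'
#' @param guide_seq Guide sequence.
#' @param variants Tibble with `pos` (0-based), `ref`, `alt`, `class`
#'   (`snp`/`ins`/`del`); insertions sit immediately before `pos`.
#' @return The reconstructed haplotype sequence.
#' @export
apply_variants <- function(guide_seq, variants) {
  if (is.null(variants) || nrow(variants) == 0L) return(guide_seq)
  variants <- dplyr::arrange(variants, .data$pos,
                             match(.data$class, c("ins", "snp", "del")))
  pieces <- character(2L * nrow(variants) + 1L)
  prev <- 0L
  pi <- 1L
  for (i in seq_len(nrow(variants))) {
    pos <- variants$pos[i]
    pieces[pi] <- substr(guide_seq, prev + 1L, pos)
    pi <- pi + 1L
    cls <- variants$class[i]
    if (cls == "snp") {
      pieces[pi] <- variants$alt[i]; prev <- pos + 1L
    } else if (cls == "ins") {
      pieces[pi] <- variants$alt[i]; prev <- pos
    } else {
      pieces[pi] <- ""; prev <- pos + nchar(variants$ref[i])
    }
    pi <- pi + 1L
  }
  pieces[pi] <- substr(guide_seq, prev + 1L, nchar(guide_seq))
  paste(pieces, collapse = "")
}

# lift 0-based guide positions through the truth indels to hap coordinates
lift_position <- function(pos, variants) {
  if (is.null(variants) || nrow(variants) == 0L) return(as.integer(pos))
  ind <- variants[variants$class != "snp", ]
  if (nrow(ind) == 0L) return(as.integer(pos))
  delta <- ifelse(ind$class == "ins", nchar(ind$alt), -nchar(ind$ref))
  vapply(pos, function(p) {
    as.integer(p + sum(delta[ind$pos < p]))
  }, integer(1))
}

#' Read-simulation configuration
#'
#' @param depth Per-haplotype fold coverage.
#' @param read_len Read length in bp.
#' @param insert_mean,insert_sd Insert-size distribution (outer distance).
#' @param base_error Per-base substitution error probability; baseline FASTQ
#'   qualities encode this rate (Q37 when zero).
#' @param g_run_rate Probability that a read is replaced by a poly-G artifact
#'   (a >= 20 bp terminal G run, the known Illumina two-channel artifact).
#' @param lowq_tail_rate Probability that a read receives a short low-quality
#'   (Q2) scrambled tail, exercising quality trimming; disabled when
#'   `base_error` is zero so error-free simulations stay pristine.
#' @param seed Integer seed.
#' @return A validated `read_sim_config` list.
#' @export
read_sim_config <- function(depth = 30, read_len = 150L, insert_mean = 500,
                            insert_sd = 50, base_error = 0.001,
                            g_run_rate = 0.001, lowq_tail_rate = 0.02,
                            seed = 1L) {
  stopifnot(depth > 0, read_len >= 20L, read_len <= insert_mean,
            base_error >= 0, base_error <= 1,
            g_run_rate >= 0, g_run_rate <= 1,
            lowq_tail_rate >= 0, lowq_tail_rate <= 1)
  structure(list(depth = depth, read_len = as.integer(read_len),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 base_error = base_error, g_run_rate = g_run_rate,
                 lowq_tail_rate = lowq_tail_rate, seed = as.integer(seed)),
            class = "read_sim_config")
}

#' Simulate paired-end reads from a diploid individual
#'
#' Fragments are drawn uniformly from both haplotypes (proportional to
#' length), with Gaussian insert sizes, per-base substitution errors at
#' `cfg$base_error`, optional low-quality tails, and poly-G artifact reads at
#' `cfg$g_run_rate`. The pair count is
#' `round(depth * total_hap_len / (2 * read_len))`.
#'
#' @param ind An `mhc_individual` (or any list with `hap_a`, `hap_b`, `id`).
#' @param cfg A [read_sim_config()].
#' @return Read-pair tibble (`read_id`, `seq1`, `qual1`, `seq2`, `qual2`)
#'   with a `truth` attribute (`read_id`, `hap`, `start`, `insert`,
#'   `flipped`, `g_artifact`) and the config in `attr(, "config")`.
#' @export
simulate_reads <- function(ind, cfg = read_sim_config()) {
  stopifnot(inherits(cfg, "read_sim_config"))
  haps <- c(a = ind$hap_a, b = ind$hap_b)
  lens <- nchar(haps)
  rl <- cfg$read_len
  n_pairs <- as.integer(round(cfg$depth * sum(lens) / (2 * rl)))

  withr::with_seed(derive_seed(cfg$seed, "reads"), {
    hap <- sample(c("a", "b"), n_pairs, replace = TRUE, prob = lens)
    hlen <- lens[hap]
    insert <- pmin(hlen, pmax(rl, round(rnorm(n_pairs, cfg$insert_mean,
                                              cfg$insert_sd))))
    start <- floor(runif(n_pairs) * (hlen - insert + 1)) # 0-based
    flipped <- runif(n_pairs) < 0.5

    frag_left <- substring(haps[hap], start + 1L, start + rl)
    frag_right <- revcomp(substring(haps[hap], start + insert - rl + 1L,
                                    start + insert))
    seq1 <- ifelse(flipped, frag_right, frag_left)
    seq2 <- ifelse(flipped, frag_left, frag_right)

    q <- if (cfg$base_error > 0) {
      max(2L, min(37L, as.integer(round(-10 * log10(cfg$base_error)))))
    } else 37L
    qual <- strrep(intToUtf8(q + 33L), rl)
    qual1 <- rep(qual, n_pairs)
    qual2 <- rep(qual, n_pairs)

    inject_errors <- function(s) {
      nerr <- rbinom(length(s), rl, cfg$base_error)
      idx <- which(nerr > 0L)
      for (i in idx) {
        p <- sample.int(rl, nerr[i])
        ch <- seq_chars(s[i])
        ch[p] <- other_base(ch[p])
        s[i] <- paste(ch, collapse = "")
      }
      s
    }
    if (cfg$base_error > 0) {
      seq1 <- inject_errors(seq1)
      seq2 <- inject_errors(seq2)
      if (cfg$lowq_tail_rate > 0) {
        add_tail <- function(s, q) {
          sel <- which(runif(length(s)) < cfg$lowq_tail_rate)
          for (i in sel) {
            t <- sample.int(10L, 1L)
            substr(s[i], rl - t + 1L, rl) <- random_dna(t)
            substr(q[i], rl - t + 1L, rl) <- strrep(intToUtf8(2L + 33L), t)
          }
          list(s = s, q = q)
        }
        r1 <- add_tail(seq1, qual1); seq1 <- r1$s; qual1 <- r1$q
        r2 <- add_tail(seq2, qual2); seq2 <- r2$s; qual2 <- r2$q
      }
    }
    g1 <- runif(n_pairs) < cfg$g_run_rate
    g2 <- runif(n_pairs) < cfg$g_run_rate
    poly_g <- function(s, sel) {
      for (i in which(sel)) {
        keep <- sample.int(rl - 20L, 1L) - 1L
        s[i] <- paste0(substr(s[i], 1L, keep), strrep("G", rl - keep))
      }
      s
    }
    seq1 <- poly_g(seq1, g1)
    seq2 <- poly_g(seq2, g2)

    pairs <- tibble::tibble(
      read_id = sprintf("%s_p%06d", ind$id, seq_len(n_pairs)),
      seq1 = seq1, qual1 = qual1, seq2 = seq2, qual2 = qual2)
    attr(pairs, "truth") <- tibble::tibble(
      read_id = pairs$read_id, hap = hap, start = as.integer(start),
      insert = as.integer(insert), flipped = flipped,
      g_artifact = g1 | g2)
    attr(pairs, "config") <- cfg
    pairs
  })
}
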