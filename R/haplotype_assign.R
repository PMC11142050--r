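# best-matching-haplotype (BMH) assignment from DRB1 first-field genotype and
# C4 status, plus a deliberately naive k-mer stand-in genotyper

#' Map a DRB1 first-field genotype to DR haplotype classes
#'
#' @param genotype Character vector of two first-field allele groups (e.g.
#'   `c("03", "04")`), or a list with an `alleles` element.
#' @param table Allele-group to DR-class mapping; defaults to
#'   [default_dr_class_table()] and is fully user-overridable.
#' @return Character vector of 1 or 2 DR classes.
#' @export
assign_dr_class <- function(genotype, table = default_dr_class_table()) {
  alleles <- if (is.list(genotype)) genotype$alleles else genotype
  stopifnot(length(alleles) == 2L)
  miss <- setdiff(alleles, table$allele_group)
  if (length(miss))
    stop("allele group(s) not in class table: ", paste(miss, collapse = ", "))
  sort(unique(table$dr_class[match(alleles, table$allele_group)]))
}

#' Assign best-matching guide haplotypes (BMHs)
#'
#' One guide per DR class: a structurally homozygous individual gets a single
#' BMH, a heterozygous one gets two (and downstream assembly runs once per
#' BMH). Within a DR class, guides are ranked by C4 agreement: exact
#' copy-number match (`c4a` and `c4b`) beats a long/short-form match, which
#' beats the class default (first guide of the class).
#'
#' @param dr_classes Character vector of 1 or 2 DR classes.
#' @param c4_status Optional tibble with columns `c4a`, `c4b`, `long`, one
#'   row per expected haplotype (matched to `dr_classes` in order), or NULL.
#' @param panel A `mhc_guide_panel`.
#' @return A `bmh_assignment` list: `guide_ids`, `dr_classes`, `rationale`.
#' @export
assign_bmh <- function(dr_classes, c4_status = NULL, panel) {
  dr_classes <- sort(unique(dr_classes))
  absent <- setdiff(dr_classes, panel$dr_class)
  if (length(absent))
    stop("DR class(es) absent from panel: ", paste(absent, collapse = ", "),
         "; available: ", paste(sort(unique(panel$dr_class)), collapse = ", "))
  rationale <- character(0)
  guide_ids <- character(0)
  for (i in seq_along(dr_classes)) {
    cl <- dr_classes[i]
    cand <- panel[panel$dr_class == cl, ]
    pick <- cand$id[1]
    why <- "class default (first guide of class)"
    if (!is.null(c4_status) && nrow(c4_status) >= i) {
      st <- c4_status[i, ]
      exact <- cand$c4a == st$c4a & cand$c4b == st$c4b
      longm <- cand$c4_long == st$long
      score <- 2L * exact + 1L * longm
      pick <- cand$id[which.max(score)]
      why <- c("class default", "long/short C4 match",
               "exact C4 copy match", "exact C4 copy + long/short match")[
                 max(score) + 1L]
    }
    guide_ids <- c(guide_ids, pick)
    rationale <- c(rationale, sprintf("%s -> %s (%s)", cl, pick, why))
  }
  structure(list(guide_ids = guide_ids, dr_classes = dr_classes,
                 rationale = rationale),
            class = "bmh_assignment")
}

#' Naive k-mer DRB1 first-field genotyper (stand-in)
#'
#' A deliberately simple stand-in for a dedicated HLA genotyper, provided so
#' simulated pipelines can run end to end without external calls: for every
#' allele group it counts reads containing at least one k-mer unique to that
#' group's exemplar sequences, calls the top group, and adds the runner-up as
#' a heterozygous call when its count reaches at least 25% of the top count
#' (an invented threshold). Not suitable for clinical HLA typing.
#'
#' @param pairs Read-pair tibble.
#' @param allele_panel Named character vector of exemplar sequences, names
#'   being first-field allele groups (see [drb1_exemplar_panel()]), or a
#'   FASTA path.
#' @param k K-mer size (must not exceed the read length).
#' @return A `dr_genotype` list: `alleles` (length 2, NA on no-call),
#'   `source = "naive_caller"`, `status` (`"called"`/`"no_call"`), and the
#'   per-group hit `counts`.
#' @export
naive_drb1_genotype <- function(pairs, allele_panel, k = 31L) {
  if (is.character(allele_panel) && length(allele_panel) == 1L &&
      file.exists(allele_panel))
    allele_panel <- read_fasta(allele_panel)
  stopifnot(length(allele_panel) >= 1L, !is.null(names(allele_panel)))
  reads <- c(pairs$seq1, pairs$seq2)
  no_call <- structure(list(alleles = c(NA_character_, NA_character_),
                            source = "naive_caller", status = "no_call",
                            counts = integer(0)),
                       class = "dr_genotype")
  if (length(reads) == 0L) return(no_call)
  if (k > max(nchar(reads)))
    stop("k exceeds the read length")
  counts <- cpp_group_kmer_hits(reads, unname(allele_panel),
                                names(allele_panel), as.integer(k))
  counts <- sort(counts, decreasing = TRUE)
  if (length(counts) == 0L || counts[1] == 0L) return(no_call)
  top <- names(counts)[1]
  second <- if (length(counts) >= 2L && counts[2] >= 0.25 * counts[1])
    names(counts)[2] else top
  structure(list(alleles = sort(c(top, second)), source = "naive_caller",
                 status = "called", counts = counts),
            class = "dr_genotype")
}

#' Read a genotype table (TSV)
#'
#' Expected columns: `individual_id`, `drb1_a`, `drb1_b`, `c4a_copies`,
#' `c4b_copies`, `c4_long`, `c4_short`.
#'
#' @param path TSV path.
#' @return Tibble of genotypes (allele groups as zero-padded character).
#' @export
read_genotype_tsv <- function(path) {
  g <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         drb1_a = readr::col_character(),
                         drb1_b = readr::col_character(),
                         .default = readr::col_guess()))
  need <- c("individual_id", "drb1_a", "drb1_b")
  miss <- setdiff(need, names(g))
  if (length(miss))
    stop("genotype table is missing column(s): ", paste(miss, collapse = ", "))
  g
}
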