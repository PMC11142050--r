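# shared fixtures: everything is generated in code, nothing is stored

rnd_dna <- function(n, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

mutate_seq <- function(s, positions, to = NULL) {
  ch <- strsplit(s, "")[[1]]
  for (p in positions) {
    ch[p] <- if (is.null(to)) setdiff(c("A", "C", "G", "T"), ch[p])[1] else to
  }
  paste(ch, collapse = "")
}

# read-pair tibble from parallel vectors, Q37 qualities unless given
make_pairs <- function(seq1, seq2, qual1 = NULL, qual2 = NULL) {
  q <- function(s) strrep(rawToChar(as.raw(37 + 33)), nchar(s))
  tibble::tibble(
    read_id = sprintf("p%04d", seq_along(seq1)),
    seq1 = seq1,
    qual1 = if (is.null(qual1)) vapply(seq1, q, character(1), USE.NAMES = FALSE) else qual1,
    seq2 = seq2,
    qual2 = if (is.null(qual2)) vapply(seq2, q, character(1), USE.NAMES = FALSE) else qual2)
}

qual_string <- function(qs) intToUtf8(qs + 33L)

# error-free uniform tiling read pairs over a sequence (insert = 2*read_len)
tile_pairs <- function(s, read_len = 100L, step = 10L, insert = 300L) {
  L <- nchar(s)
  starts <- seq(1L, L - insert + 1L, by = step)
  make_pairs(
    substring(s, starts, starts + read_len - 1L),
    vapply(substring(s, starts + insert - read_len, starts + insert - 1L),
           function(x) mhcforge::revcomp(x), character(1), USE.NAMES = FALSE))
}

# small standard diploid simulation used across tests
small_sim <- function(base_len = 40000L, depth = 30, divergence = 0.005,
                      indel_rate = 5e-4, base_error = 0.001, seed = 3L,
                      dr_mix = c("DR3", "DR4"), repeat_density = 0.2) {
  panel <- generate_guide_panel(n = length(dr_mix), base_len = base_len,
                                dr_mix = dr_mix,
                                repeat_density = repeat_density, seed = seed)
  ind <- simulate_individual(panel, panel$id[1:2], divergence = divergence,
                             indel_rate = indel_rate,
                             seed = derive_seed(seed, "ind"))
  reads <- simulate_reads(ind, read_sim_config(
    depth = depth, base_error = base_error,
    seed = derive_seed(seed, "reads")))
  list(panel = panel, ind = ind, reads = reads)
}
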