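# Shared builders and an independent profiling oracle.

# the 2x2 library design at a given depth
libs4 <- function(depth, ...) list(
  library_spec("iDNA", repaired = FALSE, target_depth = depth, ...),
  library_spec("iDNA", repaired = TRUE, target_depth = depth, ...),
  library_spec("eDNA", repaired = FALSE, target_depth = depth, ...),
  library_spec("eDNA", repaired = TRUE, target_depth = depth, ...))

# a minimal alignment table (SAM orientation sequences)
toy_aln <- function(seq, pos, flag = 0L, rname = "ref", cigar = NULL) {
  n <- max(length(seq), length(pos), length(flag))
  seq <- rep_len(seq, n); pos <- rep_len(pos, n); flag <- rep_len(flag, n)
  data.frame(qname = sprintf("r%03d", seq_len(n)), flag = as.integer(flag),
             rname = rname, pos = as.integer(pos), mapq = 60L,
             cigar = if (is.null(cigar)) paste0(nchar(seq), "M") else cigar,
             seq = seq,
             stringsAsFactors = FALSE)
}

# Brute-force per-column substitution tally, written independently of the
# package implementation: plain character vectors, explicit per-read loops,
# manual complementation. Ungapped M-only alignments.
oracle_profile <- function(aln, refs, max_pos = 25L) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  opp5 <- ct5 <- opp3 <- ga3 <- integer(max_pos)
  for (i in seq_len(nrow(aln))) {
    ref <- strsplit(refs[[aln$rname[i]]], "")[[1]]
    len <- nchar(aln$seq[i])
    rseg <- ref[aln$pos[i]:(aln$pos[i] + len - 1L)]
    qseg <- strsplit(aln$seq[i], "")[[1]]
    if (bitwAnd(aln$flag[i], 16L)) { # reorient to read direction
      rseg <- rev(unname(comp[rseg]))
      qseg <- rev(unname(comp[qseg]))
    }
    for (p in seq_len(min(max_pos, len))) {
      if (rseg[p] == "C") {
        opp5[p] <- opp5[p] + 1L
        if (qseg[p] == "T") ct5[p] <- ct5[p] + 1L
      }
      p3 <- len - p + 1L
      if (rseg[p3] == "G") {
        opp3[p] <- opp3[p] + 1L
        if (qseg[p3] == "A") ga3[p] <- ga3[p] + 1L
      }
    }
  }
  list(opp5 = opp5, ct5 = ct5, opp3 = opp3, ga3 = ga3)
}

# single damaged population sequenced deep enough for profile recovery
simulate_damaged_library <- function(n_fragments, n_reads, seed,
                                     delta_ss = 0.3, delta_ds = 0.01,
                                     q = 0.6, genome_length = 50000L,
                                     seq_error_rate = 0.001) {
  sp <- population_spec("dmg", genome_length, gc_fraction = 0.5,
                        vitality = "dead_intact",
                        damage = damage_params(delta_ss = delta_ss,
                                               delta_ds = delta_ds,
                                               overhang_decay = q,
                                               frag_mu = log(200),
                                               frag_sigma = 0.5))
  g <- generate_reference_genomes(sp, seed = seed)
  fr <- simulate_taphonomy(g[["dmg"]], sp, n_fragments = n_fragments,
                           seed = seed + 1L)
  depth <- n_reads * 100 / genome_length
  lib <- sequence_library(fr, g, library_spec("iDNA", target_depth = depth,
                                              block_prob = 0,
                                              seq_error_rate = seq_error_rate,
                                              seed = seed + 2L))
  list(genomes = g, fragments = fr, lib = lib)
}

subset_fragments_head <- function(fr, n) {
  paleomic:::subset_fragments(fr, seq_len(nrow(fr$fragments)) <= n)
}

# a bare sequencing_library built from a truth table (for stats tests)
fake_library <- function(truth) {
  structure(list(reads = data.frame(qname = truth$qname,
                                    rname = truth$genome_id,
                                    stringsAsFactors = FALSE),
                 truth = truth,
                 spec = library_spec("iDNA"),
                 genome_lengths = c(g = 1000L)),
            class = "sequencing_library")
}

# a coverage_profile built directly from a depth vector
fake_coverage <- function(depths, bin_size = 1000L, smoothing = 1L) {
  structure(list(genome_id = "g", bin_size = as.integer(bin_size),
                 smoothing_window = as.integer(smoothing),
                 depths = as.numeric(depths),
                 smoothed = paleomic:::circular_ma(as.numeric(depths),
                                                   as.integer(smoothing)),
                 genome_length = as.integer(bin_size * length(depths))),
            class = "coverage_profile")
}
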