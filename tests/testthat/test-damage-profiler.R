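# Mis-incorporation profiling and damage-model fitting.

test_that("hand-counted toy alignments give exact frequencies", {
  refs <- c(ref = paste0("C", strrep("A", 19)))
  aln <- toy_aln(c(rep("CAAAAAAAAA", 7), rep("TAAAAAAAAA", 3)), pos = 1)
  prof <- substitution_profile(aln, refs, max_pos = 5)
  expect_equal(prof$ct5[1], 0.3)
  expect_equal(prof$opportunities5[1], 10L)
  expect_equal(prof$ct5_count[1], 3L)
  # zero-mismatch reads give zero frequency wherever defined
  prof0 <- substitution_profile(toy_aln(rep("CAAAAAAAAA", 5), pos = 1),
                                refs, max_pos = 5)
  expect_true(all(prof0$ct5[!is.na(prof0$ct5)] == 0))
})

test_that("reverse-strand reads are profiled in read orientation", {
  refs <- c(ref = paste0(strrep("A", 9), "G", strrep("A", 5)))
  # minus read over positions 1..10; read 5' base pairs the reference G
  intact <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("CTTTTTTTTT")))
  damaged <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("TTTTTTTTTT")))
  prof_i <- substitution_profile(toy_aln(intact, pos = 1, flag = 16L), refs)
  expect_equal(prof_i$opportunities5[1], 1L)
  expect_equal(prof_i$ct5[1], 0)
  prof_d <- substitution_profile(toy_aln(damaged, pos = 1, flag = 16L), refs)
  expect_equal(prof_d$ct5[1], 1)
})

test_that("profile equals an independent brute-force tally on small read sets", {
  out <- simulate_damaged_library(n_fragments = 60, n_reads = 50, seed = 201)
  aln <- out$lib$reads
  expect_lte(nrow(aln), 50)
  prof <- substitution_profile(out$lib, out$genomes)
  ora <- oracle_profile(aln, as.list(out$genomes))
  expect_identical(prof$opportunities5, ora$opp5)
  expect_identical(prof$ct5_count, ora$ct5)
  expect_identical(prof$opportunities3, ora$opp3)
  expect_identical(prof$ga3_count, ora$ga3)
})

test_that("indel and soft-clip CIGARs skip the affected columns", {
  refs <- c(ref = strrep("C", 20))
  aln <- toy_aln("TTTTTT", pos = 1, cigar = "3M1D3M")
  prof <- substitution_profile(aln, refs, max_pos = 10)
  expect_equal(prof$opportunities5[1:6], rep(1L, 6))
  expect_equal(sum(prof$opportunities5), 6L)
  expect_equal(prof$ct5[1:6], rep(1, 6))

  clip <- toy_aln("GGTTT", pos = 1, cigar = "2S3M")
  prof2 <- substitution_profile(clip, refs, max_pos = 10)
  expect_equal(sum(prof2$opportunities5), 3L)
  expect_equal(prof2$ct5[1:3], rep(1, 3))

  ins <- toy_aln("TTATT", pos = 1, cigar = "2M1I2M")
  prof3 <- substitution_profile(ins, refs, max_pos = 10)
  expect_equal(sum(prof3$opportunities5), 4L)
})

test_that("profiler recovers the simulated decay and fit recovers parameters", {
  out <- simulate_damaged_library(n_fragments = 30000, n_reads = 20000,
                                  seed = 211)
  prof <- substitution_profile(out$lib, out$genomes)
  expect_lt(abs(prof$ct5[1] - 0.3), 0.02)
  # geometric decay dominates counting noise over the first offsets
  expect_true(all(diff(prof$ct5[1:6]) < 0))
  expect_lt(prof$ct5[25], 0.03)

  fit <- fit_damage_model(prof)
  expect_true(fit$converged)
  expect_lt(abs(fit$delta_ss_hat - 0.3), 0.04)
  expect_lt(abs(fit$delta_ds_hat - 0.01), 0.01)
  expect_lt(abs(fit$q_hat - 0.6), 0.07)
})

test_that("noiseless profiles invert exactly and flat profiles are flagged", {
  mk_prof <- function(y, opp = 1000L) {
    structure(list(genome_id = "g", library_id = "l", max_pos = length(y),
                   ct5 = y, ga3 = rep(NA_real_, length(y)),
                   ct5_count = as.integer(round(y * opp)),
                   ga3_count = integer(length(y)),
                   opportunities5 = rep(opp, length(y)),
                   opportunities3 = integer(length(y)), n_reads = opp),
              class = "damage_profile")
  }
  p <- 1:25
  y <- 0.01 + (0.3 - 0.01) * 0.6^(p - 1)
  fit <- fit_damage_model(mk_prof(y))
  expect_lt(abs(fit$delta_ss_hat - 0.3), 1e-6)
  expect_lt(abs(fit$delta_ds_hat - 0.01), 1e-6)
  expect_lt(abs(fit$q_hat - 0.6), 1e-6)
  expect_true(fit$q_identifiable)

  flat <- fit_damage_model(mk_prof(rep(0.02, 25)))
  expect_lt(abs(flat$delta_ds_hat - 0.02), 1e-6)
  expect_lt(abs(flat$delta_ss_hat - 0.02), 1e-3)
  expect_false(flat$q_identifiable)

  short <- mk_prof(rep(0.02, 4))
  expect_error(fit_damage_model(short), "5 defined")
})

test_that("damage score is the terminal 5' frequency; undefined propagates", {
  out <- simulate_damaged_library(n_fragments = 500, n_reads = 500, seed = 221)
  prof <- substitution_profile(out$lib, out$genomes)
  expect_identical(damage_score(prof), prof$ct5[1])
  empty <- substitution_profile(out$lib$reads[0, ], out$genomes)
  expect_true(is.na(damage_score(empty)))
})

test_that("a living population scores below 0.01", {
  sp <- population_spec("liv", 40000L, vitality = "living")
  g <- generate_reference_genomes(sp, seed = 231)
  fr <- simulate_taphonomy(g[["liv"]], sp, n_fragments = 4000, seed = 232)
  lib <- sequence_library(fr, g, library_spec("iDNA", target_depth = 10,
                                              block_prob = 0, seed = 233))
  prof <- substitution_profile(lib, g)
  expect_lt(damage_score(prof), 0.01)
})

test_that("one-ended simulation leaves the other channel at the error floor", {
  sp <- population_spec("sym", 40000L, vitality = "dead_intact",
                        damage = damage_params(delta_ss = 0.3, delta_ds = 0.01,
                                               overhang_decay = 0.6,
                                               frag_mu = log(80),
                                               frag_sigma = 0.2))
  g <- generate_reference_genomes(sp, seed = 241)
  spec <- library_spec("iDNA", target_depth = 15, block_prob = 0,
                       seq_error_rate = 0, seed = 243)
  fr5 <- simulate_taphonomy(g[["sym"]], sp, n_fragments = 8000, seed = 242,
                            ends = "five")
  prof5 <- substitution_profile(sequence_library(fr5, g, spec), g)
  expect_gt(prof5$ct5[1], 0.2)
  expect_true(all(prof5$ga3 == 0, na.rm = TRUE))

  fr3 <- simulate_taphonomy(g[["sym"]], sp, n_fragments = 8000, seed = 242,
                            ends = "three")
  prof3 <- substitution_profile(sequence_library(fr3, g, spec), g)
  expect_gt(prof3$ga3[1], 0.2)
  expect_true(all(prof3$ct5 == 0, na.rm = TRUE))
})

test_that("a missing reference is an error", {
  aln <- toy_aln("ACGT", pos = 1, rname = "nope")
  expect_error(substitution_profile(aln, c(ref = "ACGTACGT")), "nope")
})
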