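# Reference-genome generation and the taphonomy simulator.

test_that("generated genomes have the requested length and GC, deterministically", {
  sp <- population_spec("g1", 10000L, gc_fraction = 0.5)
  g1 <- generate_reference_genomes(sp, seed = 7)
  g2 <- generate_reference_genomes(sp, seed = 7)
  expect_identical(g1, g2)
  expect_equal(nchar(g1[["g1"]]), 10000L)
  expect_lt(abs(gc_content(g1[["g1"]]) - 0.5), 0.02)

  sp65 <- population_spec("hi_gc", 100000L, gc_fraction = 0.65)
  g <- generate_reference_genomes(sp65, seed = 3)
  expect_lt(abs(gc_content(g[["hi_gc"]]) - 0.65), 0.01)

  expect_error(population_spec("bad", 100), "genome_length")
  expect_error(population_spec("bad", 10000, gc_fraction = 1.2), "gc_fraction")
})

test_that("zero lesion rates yield fragments without lesions", {
  sp <- population_spec("liv", 20000L, vitality = "living")
  g <- generate_reference_genomes(sp, seed = 1)
  fr <- simulate_taphonomy(g[["liv"]], sp, n_fragments = 500, seed = 2)
  expect_equal(nrow(fr$lesions), 0L)
  expect_true(all(fr$fragments$start >= 0))
  expect_true(all(fr$fragments$end <= 20000L))
  expect_true(all(fr$fragments$length >= 30L))
})

test_that("fragment lengths follow the truncated lognormal regime", {
  sp <- population_spec("old", 50000L, vitality = "dead_intact",
                        damage = damage_params(frag_mu = log(200),
                                               frag_sigma = 0.5))
  g <- generate_reference_genomes(sp, seed = 5)
  fr <- simulate_taphonomy(g[["old"]], sp, n_fragments = 10000, seed = 6)
  expect_lt(abs(median(fr$fragments$length) - 200), 15)
})

test_that("terminal deamination probability matches delta_ss at offset zero", {
  # an all-C genome makes every offset-0 site an opportunity
  genome <- strrep("C", 2000)
  sp <- population_spec("allc", 2000L, vitality = "dead_intact",
                        damage = damage_params(delta_ss = 0.3, delta_ds = 0.01,
                                               overhang_decay = 0.6,
                                               frag_mu = log(40),
                                               frag_sigma = 0))
  fr <- simulate_taphonomy(genome, sp, n_fragments = 100000, seed = 9,
                           ends = "five")
  # minus-strand fragments read all-G and carry no C channel
  n_plus <- sum(fr$fragments$strand == "+")
  hits0 <- sum(fr$lesions$kind == "deam_C" & fr$lesions$offset == 0L)
  expect_lt(abs(hits0 / n_plus - 0.3), 0.01)
})

test_that("deaminations sit on reference-C (fragment strand) positions only", {
  sp <- population_spec("mix", 20000L, vitality = "dead_intact")
  g <- generate_reference_genomes(sp, seed = 11)
  fr <- simulate_taphonomy(g[["mix"]], sp, n_fragments = 200, seed = 12)
  le <- fr$lesions[fr$lesions$kind %in% c("deam_C", "deam_G"), ]
  frm <- fr$fragments[match(le$frag_id, fr$fragments$frag_id), ]
  for (i in seq_len(nrow(le))) {
    fseq <- substring(g[["mix"]], frm$start[i] + 1L, frm$end[i])
    if (frm$strand[i] == "-") {
      fseq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fseq)))
    }
    base <- substring(fseq, le$offset[i] + 1L, le$offset[i] + 1L)
    expect_identical(base, if (le$kind[i] == "deam_C") "C" else "G")
  }
})

test_that("switching one end off silences its deamination channel", {
  sp <- population_spec("sym", 20000L, vitality = "dead_intact")
  g <- generate_reference_genomes(sp, seed = 21)
  five <- simulate_taphonomy(g[["sym"]], sp, n_fragments = 300, seed = 22,
                             ends = "five")
  three <- simulate_taphonomy(g[["sym"]], sp, n_fragments = 300, seed = 22,
                              ends = "three")
  expect_false(any(five$lesions$kind == "deam_G"))
  expect_false(any(three$lesions$kind == "deam_C"))
})

test_that("iDNA/eDNA partitioning routes by vitality and conserves fragments", {
  sp <- population_spec("p", 20000L, vitality = "dead_intact")
  g <- generate_reference_genomes(sp, seed = 31)
  fr <- simulate_taphonomy(g[["p"]], sp, n_fragments = 1000, seed = 32)

  part <- partition_idna_edna(fr, vitality = "lysed", leakage = 0, seed = 33)
  expect_equal(nrow(part$iDNA$fragments), 0L)
  expect_equal(nrow(part$eDNA$fragments), 1000L)

  part <- partition_idna_edna(fr, vitality = "dead_intact", leakage = 0.2,
                              seed = 34)
  expect_lt(abs(nrow(part$eDNA$fragments) - 200), 3 * sqrt(1000 * 0.2 * 0.8))
  # disjoint and jointly exhaustive
  expect_equal(sort(c(part$iDNA$fragments$frag_id, part$eDNA$fragments$frag_id)),
               sort(fr$fragments$frag_id))
  expect_length(intersect(part$iDNA$fragments$frag_id,
                          part$eDNA$fragments$frag_id), 0)
  expect_error(partition_idna_edna(fr, vitality = "undead"), "vitality")
})

test_that("repair removes lesions at rate rho without mutating the input", {
  sp <- population_spec("r", 20000L, vitality = "dead_intact",
                        damage = damage_params(delta_ss = 0.4, delta_ds = 0.05,
                                               overhang_decay = 0.6,
                                               nick_rate = 0.01,
                                               blocker_rate = 0.01,
                                               frag_mu = log(200),
                                               frag_sigma = 0.4))
  g <- generate_reference_genomes(sp, seed = 41)
  fr <- simulate_taphonomy(g[["r"]], sp, n_fragments = 2000, seed = 42)
  n0 <- nrow(fr$lesions)
  expect_gt(n0, 5000)

  same <- apply_repair(fr, rho = 0, seed = 43)
  expect_identical(same$lesions, fr$lesions)
  none <- apply_repair(fr, rho = 1, seed = 44)
  expect_equal(nrow(none$lesions), 0L)
  half <- apply_repair(fr, rho = 0.5, seed = 45)
  expect_lt(abs(nrow(half$lesions) - n0 / 2), 3 * sqrt(n0 / 4))
  expect_equal(nrow(fr$lesions), n0) # untouched
  expect_error(apply_repair(fr, rho = 1.5), "rho")
})

test_that("library conversion fails per blocking lesion at rate pi", {
  sp <- population_spec("b", 40000L, vitality = "dead_intact",
                        damage = damage_params(frag_mu = log(200),
                                               frag_sigma = 0))
  g <- generate_reference_genomes(sp, seed = 51)
  fr <- simulate_taphonomy(g[["b"]], sp, n_fragments = 4000, seed = 52)
  # exactly two blockers on every fragment
  fr$lesions <- data.frame(
    frag_id = rep(fr$fragments$frag_id, each = 2),
    offset = rep(c(10L, 50L), times = 4000),
    kind = "blocker", stringsAsFactors = FALSE)
  lib <- sequence_library(fr, g, library_spec("iDNA", target_depth = 50,
                                              block_prob = 0.5, seed = 53))
  n_conv <- length(unique(lib$truth$frag_id))
  expect_lt(abs(n_conv - 4000 * 0.25), 3 * sqrt(4000 * 0.25 * 0.75))

  # pi = 0: every fragment converts and is seen
  fr$lesions <- fr$lesions[0, ]
  fr2 <- subset_fragments_head(fr, 500)
  lib2 <- sequence_library(fr2, g, library_spec("iDNA", target_depth = 25,
                                                block_prob = 0, seed = 54))
  expect_equal(length(unique(lib2$truth$frag_id)), 500L)
})

test_that("sequencing is deterministic and reads map to true fragments", {
  sp <- population_spec("d", 20000L, vitality = "dead_intact")
  g <- generate_reference_genomes(sp, seed = 61)
  fr <- simulate_taphonomy(g[["d"]], sp, n_fragments = 800, seed = 62)
  spec <- library_spec("iDNA", target_depth = 3, seed = 63)
  lib1 <- sequence_library(fr, g, spec)
  lib2 <- sequence_library(fr, g, spec)
  expect_identical(lib1$reads, lib2$reads)

  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  s1 <- tempfile(fileext = ".sam"); s2 <- tempfile(fileext = ".sam")
  write_fastq(lib1, f1); write_fastq(lib2, f2)
  write_sam(lib1, s1); write_sam(lib2, s2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_identical(unname(tools::md5sum(s1)), unname(tools::md5sum(s2)))

  # every read's SAM interval sits inside its source fragment
  tr <- lib1$truth
  rd <- lib1$reads
  expect_true(all(rd$pos - 1L >= tr$frag_start))
  expect_true(all(rd$pos - 1L + rd$read_len <= tr$frag_end))

  # SAM round trip preserves the core columns
  back <- read_sam(s1)
  expect_equal(nrow(back), nrow(rd))
  expect_setequal(back$qname, rd$qname)
  m <- match(rd$qname, back$qname)
  expect_identical(back$seq[m], rd$seq)
  expect_identical(back$pos[m], rd$pos)
})

test_that("fragments shorter than the read length are clipped with a warning", {
  sp <- population_spec("s", 20000L, vitality = "dead_intact",
                        damage = damage_params(frag_mu = log(50),
                                               frag_sigma = 0.1))
  g <- generate_reference_genomes(sp, seed = 71)
  fr <- simulate_taphonomy(g[["s"]], sp, n_fragments = 200, seed = 72)
  expect_warning(
    lib <- sequence_library(fr, g, library_spec("iDNA", target_depth = 0.5,
                                                block_prob = 0, seed = 73)),
    "clipped")
  expect_true(all(lib$reads$read_len == lib$truth$frag_len))
})

test_that("more blocking damage never increases conversion", {
  sp0 <- population_spec("m", 40000L, vitality = "dead_intact",
                         damage = damage_params(frag_mu = log(200),
                                                frag_sigma = 0.3))
  g <- generate_reference_genomes(sp0, seed = 81)
  conv_frac <- sapply(c(0, 0.005, 0.02), function(rate) {
    dp <- damage_params(blocker_rate = rate, frag_mu = log(200),
                        frag_sigma = 0.3)
    sp <- population_spec("m", 40000L, vitality = "dead_intact", damage = dp)
    fr <- simulate_taphonomy(g[["m"]], sp, n_fragments = 2000, seed = 82)
    lib <- sequence_library(fr, g, library_spec("iDNA", target_depth = 20,
                                                block_prob = 0.9, seed = 83))
    length(unique(lib$truth$frag_id)) / 2000
  })
  expect_true(all(diff(conv_frac) < 0))
})
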