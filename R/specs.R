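#' Lesion-process parameters for one simulated population
#'
#' Post-mortem DNA alteration is modelled with the standard ancient-DNA
#' phenomenology: fragments carry single-stranded overhangs at their termini
#' in which cytosine deamination is strongly enriched, decaying geometrically
#' into the duplex interior. A cytosine at 0-based distance `p` from the
#' fragment 5' end deaminates with probability
#' `delta_ds + (delta_ss - delta_ds) * overhang_decay^p`, and symmetrically a
#' guanine near the 3' end (a complementary-strand cytosine) with the same
#' law in the 3' offset. Strand breaks (`nick_rate`) and polymerase-blocking
#' lesions such as abasic sites and dimers (`blocker_rate`) accrue as Poisson
#' processes per base pair; they do not change read bases but abort library
#' conversion (see [sequence_library()]).
#'
#' @param delta_ss per-site deamination probability in single-stranded
#'   overhang context, in `[0, 1]`.
#' @param delta_ds per-site deamination probability in duplex DNA, in
#'   `[0, 1]`; must not exceed `delta_ss`.
#' @param overhang_decay geometric persistence `q` of the overhang effect,
#'   in `[0, 1)`.
#' @param nick_rate single-strand breaks per bp, `>= 0`.
#' @param blocker_rate blocking lesions (abasic sites, dimers) per bp, `>= 0`.
#' @param frag_mu,frag_sigma log-scale mean and sd of the lognormal
#'   fragment-length distribution (bp). The realized length is truncated to
#'   `[30, genome_length]`.
#' @return an object of class `damage_params`.
#' @export
#' @examples
#' damage_params(delta_ss = 0.3, delta_ds = 0.01, overhang_decay = 0.6,
#'               frag_mu = log(200), frag_sigma = 0.5)
damage_params <- function(delta_ss = 0, delta_ds = 0, overhang_decay = 0.5,
                          nick_rate = 0, blocker_rate = 0,
                          frag_mu = log(12000), frag_sigma = 0.4) {
  stopifnot(delta_ss >= 0, delta_ss <= 1, delta_ds >= 0, delta_ds <= 1,
            overhang_decay >= 0, overhang_decay < 1,
            nick_rate >= 0, blocker_rate >= 0,
            is.finite(frag_mu), frag_sigma >= 0)
  if (delta_ss < delta_ds) {
    stop("delta_ss must be >= delta_ds (overhang deamination dominates)")
  }
  structure(list(delta_ss = delta_ss, delta_ds = delta_ds,
                 overhang_decay = overhang_decay, nick_rate = nick_rate,
                 blocker_rate = blocker_rate, frag_mu = frag_mu,
                 frag_sigma = frag_sigma),
            class = "damage_params")
}

#' Ground-truth description of one simulated genome population
#'
#' A population couples a reference genome (to be generated) with its vitality
#' class, lesion process, relative abundance, and replication state. The three
#' vitality classes mirror the pools co-extracted from sediment: `living`
#' (metabolically active cells that keep their DNA intact), `dead_intact`
#' (structurally intact dead cells whose iDNA accumulates damage), and
#' `lysed` (cells whose remains persist only as extracellular DNA).
#'
#' @param genome_id identifier, unique within a scenario.
#' @param genome_length genome size in bp (`>= 1000`; `>= 10000` recommended
#'   so realized GC tracks the target).
#' @param gc_fraction target GC content, in the open interval (0, 1).
#' @param relative_abundance non-negative weight controlling the population's
#'   share of fragments and reads.
#' @param vitality one of `"living"`, `"dead_intact"`, `"lysed"`.
#' @param damage a [damage_params()] object. Defaults to an intact-DNA
#'   process (zero lesion rates, >10 kb fragments) for `living`, and to a
#'   heavily damaged short-fragment process for the two dead classes.
#' @param ptr peak-to-trough replication ratio `>= 1`; 1 means no ongoing
#'   replication, values above 1 skew fragment density from origin to
#'   terminus.
#' @param ori_position,ter_position 0-based coordinates of the replication
#'   origin and terminus; must differ.
#' @return an object of class `population_spec`.
#' @export
#' @examples
#' population_spec("young_living", 4e4, 0.55, vitality = "living")
population_spec <- function(genome_id, genome_length, gc_fraction = 0.5,
                            relative_abundance = 1,
                            vitality = c("living", "dead_intact", "lysed"),
                            damage = NULL, ptr = 1,
                            ori_position = 0,
                            ter_position = floor(genome_length / 2)) {
  vitality <- match.arg(vitality)
  stopifnot(is.character(genome_id), length(genome_id) == 1L, nzchar(genome_id))
  if (!is.numeric(genome_length) || genome_length < 1000) {
    stop("genome_length must be >= 1000 bp")
  }
  if (!(gc_fraction > 0 && gc_fraction < 1)) {
    stop("gc_fraction must lie strictly between 0 and 1")
  }
  stopifnot(relative_abundance >= 0, ptr >= 1)
  if (is.null(damage)) {
    damage <- if (vitality == "living") {
      damage_params()
    } else {
      damage_params(delta_ss = 0.3, delta_ds = 0.01, overhang_decay = 0.6,
                    nick_rate = 0.005, blocker_rate = 0.01,
                    frag_mu = log(200), frag_sigma = 0.5)
    }
  }
  stopifnot(inherits(damage, "damage_params"))
  if (vitality == "living" &&
      (damage$delta_ss > 0.05 || damage$blocker_rate > 0.001)) {
    warning("living population '", genome_id,
            "' carries substantial damage rates; living DNA is expected to ",
            "be near-intact (delta_ss, blocker_rate ~ 0)")
  }
  ori_position <- as.integer(ori_position)
  ter_position <- as.integer(ter_position)
  if (identical(ori_position, ter_position)) {
    stop("ori_position and ter_position must differ")
  }
  stopifnot(ori_position >= 0, ori_position < genome_length,
            ter_position >= 0, ter_position < genome_length)
  structure(list(genome_id = genome_id,
                 genome_length = as.integer(genome_length),
                 gc_fraction = gc_fraction,
                 relative_abundance = relative_abundance,
                 vitality = vitality, damage = damage, ptr = ptr,
                 ori_position = ori_position, ter_position = ter_position),
            class = "population_spec")
}

#' Sequencing-library design for one simulated metagenome
#'
#' One library corresponds to one cell of the 2x2 experimental design:
#' iDNA or eDNA fraction, with or without in-vitro repair. `block_prob` is
#' the per-lesion probability that a blocking lesion (abasic site, dimer,
#' nick) aborts library conversion of its fragment; `repair_efficiency` is
#' the per-lesion removal probability applied by [apply_repair()] before
#' sequencing when `repaired = TRUE`.
#'
#' @param fraction `"iDNA"` or `"eDNA"`.
#' @param repaired logical; was the pool treated with the repair cocktail?
#' @param read_length read length in bp, `>= 30`.
#' @param target_depth expected fold-coverage of the pooled metagenome.
#' @param repair_efficiency rho, per-lesion repair probability in `[0, 1]`.
#' @param block_prob pi, per-blocking-lesion conversion-failure probability
#'   in `[0, 1]`.
#' @param seq_error_rate independent per-base substitution error rate in
#'   `[0, 1)`.
#' @param downsample factor in `(0, 1]` multiplying the read count; repaired
#'   libraries can be set to 0.8 to mimic their lower read yield.
#' @param seed integer seed of the library's random stream.
#' @return an object of class `library_spec`.
#' @export
#' @examples
#' library_spec("iDNA", repaired = TRUE, target_depth = 15, seed = 7)
library_spec <- function(fraction = c("iDNA", "eDNA"), repaired = FALSE,
                         read_length = 100L, target_depth = 10,
                         repair_efficiency = 1, block_prob = 0.9,
                         seq_error_rate = 0.001, downsample = 1,
                         seed = 1L) {
  fraction <- match.arg(fraction)
  stopifnot(is_flag(repaired), read_length >= 30, target_depth >= 0,
            repair_efficiency >= 0, repair_efficiency <= 1,
            block_prob >= 0, block_prob <= 1,
            seq_error_rate >= 0, seq_error_rate < 1,
            downsample > 0, downsample <= 1,
            is.numeric(seed), length(seed) == 1L)
  structure(list(fraction = fraction, repaired = repaired,
                 read_length = as.integer(read_length),
                 target_depth = target_depth,
                 repair_efficiency = repair_efficiency,
                 block_prob = block_prob, seq_error_rate = seq_error_rate,
                 downsample = downsample, seed = as.integer(seed),
                 library_id = paste0(fraction,
                                     if (repaired) "_repaired" else "_unrepaired")),
            class = "library_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("<population_spec> %s: %s, %d bp, GC %.2f, abundance %.3g, ptr %.2f\n",
              x$genome_id, x$vitality, x$genome_length, x$gc_fraction,
              x$relative_abundance, x$ptr))
  d <- x$damage
  cat(sprintf("  damage: delta_ss %.3g, delta_ds %.3g, q %.2f, nick %.3g/bp, blocker %.3g/bp, frag ~lognormal(%.2f, %.2f)\n",
              d$delta_ss, d$delta_ds, d$overhang_decay, d$nick_rate,
              d$blocker_rate, d$frag_mu, d$frag_sigma))
  invisible(x)
}

#' @export
print.library_spec <- function(x, ...) {
  cat(sprintf("<library_spec> %s: %d nt reads, %.3gx depth, rho %.2f, pi %.2f, err %.3g, seed %d\n",
              x$library_id, x$read_length, x$target_depth,
              x$repair_efficiency, x$block_prob, x$seq_error_rate, x$seed))
  invisible(x)
}
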