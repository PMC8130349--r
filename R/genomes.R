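#' Generate random reference genomes for a set of populations
#'
#' Bases are drawn i.i.d. with `P(G) = P(C) = gc_fraction / 2` and
#' `P(A) = P(T) = (1 - gc_fraction) / 2`, so for genomes of 10 kb and above
#' the realized GC content lies within about +/- 0.02 of the target. Each
#' genome gets its own child seed derived from `seed` and its `genome_id`,
#' so the set is deterministic and order-independent.
#'
#' @param specs a list of [population_spec()] objects (a single spec is
#'   accepted too).
#' @param seed master integer seed.
#' @return a named character vector of genome sequences, FASTA-writable via
#'   [write_fasta()].
#' @export
#' @examples
#' g <- generate_reference_genomes(population_spec("g1", 10000), seed = 7)
#' nchar(g[["g1"]])
generate_reference_genomes <- function(specs, seed) {
  if (inherits(specs, "population_spec")) specs <- list(specs)
  stopifnot(length(specs) > 0, all(vapply(specs, inherits, TRUE, "population_spec")))
  ids <- vapply(specs, `[[`, character(1), "genome_id")
  if (anyDuplicated(ids)) stop("duplicate genome_id in specs")
  genomes <- vapply(specs, function(sp) {
    with_seed(derive_seed(seed, paste0("genome-", sp$genome_id)), {
      p <- c(A = (1 - sp$gc_fraction) / 2, C = sp$gc_fraction / 2,
             G = sp$gc_fraction / 2, T = (1 - sp$gc_fraction) / 2)
      paste(sample(names(p), sp$genome_length, replace = TRUE, prob = p),
            collapse = "")
    })
  }, character(1))
  names(genomes) <- ids
  genomes
}

#' Realized GC fraction of a sequence
#' @param x a character string (DNA).
#' @return numeric fraction of G + C.
#' @export
gc_content <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  f <- Biostrings::letterFrequency(Biostrings::DNAString(x), c("G", "C"))
  sum(f) / nchar(x)
}

#' Write genome sequences to FASTA
#' @param genomes named character vector of sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path) {
  x <- Biostrings::DNAStringSet(genomes)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
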