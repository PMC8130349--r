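# Post-mortem DNA alteration: fragmentation, deamination, blocking lesions.
#
# Internal coordinates are 0-based half-open on the genome; lesion offsets are
# 0-based from the fragment's own 5' end (minus-strand fragments are
# reverse-complemented before lesion placement, so offsets are always in
# fragment orientation).

new_fragments <- function(fragments, lesions, vitality = NA_character_,
                          age_yr = NA_real_) {
  stopifnot(is.data.frame(fragments), is.data.frame(lesions))
  structure(list(fragments = fragments, lesions = lesions),
            vitality = vitality, age_yr = age_yr,
            class = "taphonomy_fragments")
}

#' @export
print.taphonomy_fragments <- function(x, ...) {
  cat(sprintf("<taphonomy_fragments> %d fragments (%s genome%s), %d lesions\n",
              nrow(x$fragments),
              paste(unique(x$fragments$genome_id), collapse = ", "),
              if (length(unique(x$fragments$genome_id)) > 1) "s" else "",
              nrow(x$lesions)))
  if (nrow(x$fragments)) {
    cat(sprintf("  median length %.0f bp; lesion kinds: %s\n",
                stats::median(x$fragments$length),
                if (nrow(x$lesions)) paste(names(table(x$lesions$kind)),
                                           collapse = ", ") else "none"))
  }
  invisible(x)
}

subset_fragments <- function(x, keep) {
  fr <- x$fragments[keep, , drop = FALSE]
  le <- x$lesions[x$lesions$frag_id %in% fr$frag_id, , drop = FALSE]
  rownames(fr) <- rownames(le) <- NULL
  new_fragments(fr, le, attr(x, "vitality"), attr(x, "age_yr"))
}

#' Pool fragment sets from several populations
#' @param ... `taphonomy_fragments` objects (or a single list of them).
#' @return one pooled `taphonomy_fragments` object.
#' @export
pool_fragments <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1]], "taphonomy_fragments")) {
    xs <- xs[[1]]
  }
  xs <- Filter(Negate(is.null), xs)
  stopifnot(all(vapply(xs, inherits, TRUE, "taphonomy_fragments")))
  new_fragments(do.call(rbind, lapply(xs, `[[`, "fragments")),
                do.call(rbind, lapply(xs, `[[`, "lesions")))
}

# ptr-skewed fragment start positions: replication of a circular chromosome
# makes expected copy number decay log-linearly with circular distance from
# the origin, reaching 1/ptr at the terminus.
sample_starts <- function(n, L, lens, ptr, ori) {
  max_start <- pmax(L - lens, 0L)
  if (ptr <= 1) return(floor(runif(n) * (max_start + 1)))
  cell <- max(100L, min(1000L, floor(L / 50)))
  centers <- seq(cell / 2, L, by = cell)
  d <- abs(centers - ori)
  d <- pmin(d, L - d) # circular distance
  w <- exp(-log(ptr) * 2 * d / L)
  idx <- sample.int(length(centers), n, replace = TRUE, prob = w)
  pos <- (idx - 1L) * cell + floor(runif(n) * cell)
  pmin(pos, max_start)
}

#' Simulate taphonomic alteration of one genome into damaged fragments
#'
#' Draws `n_fragments` fragments with lognormal lengths (truncated to
#' `[30, genome_length]`), start positions that follow the population's
#' replication skew (`ptr`), and random strands; then places lesions:
#' cytosine deamination with probability
#' `delta_ds + (delta_ss - delta_ds) * q^p` at 0-based 5' offset `p`
#' (and the mirrored process on guanines from the 3' end, i.e.
#' complementary-strand deamination), plus Poisson nicks and blocking
#' lesions. Populations with all lesion rates at zero skip sequence
#' inspection entirely, so intact high-molecular-weight DNA is cheap to
#' simulate.
#'
#' @param genome a single genome sequence (character or `DNAString`).
#' @param spec the [population_spec()] of the population.
#' @param age_yr non-negative age annotation in years (the lesion intensity
#'   itself is set by `spec$damage`; the racemization module is the explicit
#'   age clock).
#' @param n_fragments number of fragments to draw.
#' @param seed integer seed (`NULL` = use current RNG state).
#' @param ends which fragment ends carry the overhang-enriched deamination
#'   process; `"both"` (default) gives the canonical 5' C-to-T / 3' G-to-A
#'   symmetry, `"five"`/`"three"` switch one process off (used for symmetry
#'   checks).
#' @param chunk_size fragments per internal processing chunk.
#' @return a `taphonomy_fragments` object: `$fragments` (frag_id, genome_id,
#'   start, end, length, strand) and `$lesions` (frag_id, offset, kind) with
#'   kinds `deam_C`, `deam_G`, `nick`, `blocker`.
#' @export
#' @examples
#' sp <- population_spec("g1", 20000, vitality = "dead_intact")
#' g <- generate_reference_genomes(sp, seed = 1)
#' fr <- simulate_taphonomy(g[["g1"]], sp, n_fragments = 100, seed = 2)
#' fr
simulate_taphonomy <- function(genome, spec, age_yr = 0, n_fragments = 1000,
                               seed = NULL, ends = c("both", "five", "three"),
                               chunk_size = 5000L) {
  ends <- match.arg(ends)
  genome <- as.character(genome)
  stopifnot(length(genome) == 1L)
  if (!nzchar(genome)) stop("empty genome")
  if (!is.numeric(age_yr) || age_yr < 0) stop("age_yr must be >= 0")
  stopifnot(inherits(spec, "population_spec"), n_fragments >= 0)
  L <- nchar(genome)
  d <- spec$damage
  with_seed(seed, {
    n <- as.integer(n_fragments)
    lens <- as.integer(round(rlnorm(n, d$frag_mu, d$frag_sigma)))
    lens <- pmin(pmax(lens, 30L), L)
    start <- as.integer(sample_starts(n, L, lens, spec$ptr, spec$ori_position))
    end <- start + lens
    strand <- sample(c("+", "-"), n, replace = TRUE)
    frag_id <- sprintf("%s:%06d", spec$genome_id, seq_len(max(n, 0L)))
    fr <- data.frame(frag_id = frag_id, genome_id = spec$genome_id,
                     start = start, end = end, length = lens,
                     strand = strand, stringsAsFactors = FALSE)

    lesion_list <- list()
    # Poisson strand breaks and blocking lesions, uniform over the fragment
    for (kind in c("nick", "blocker")) {
      rate <- if (kind == "nick") d$nick_rate else d$blocker_rate
      if (rate > 0 && n > 0) {
        counts <- rpois(n, rate * lens)
        tot <- sum(counts)
        if (tot > 0) {
          idx <- rep.int(seq_len(n), counts)
          lesion_list[[kind]] <- data.frame(
            frag_id = frag_id[idx],
            offset = as.integer(floor(runif(tot) * lens[idx])),
            kind = kind, stringsAsFactors = FALSE)
        }
      }
    }

    # site-exact deamination; skipped entirely when both rates are zero
    if ((d$delta_ss > 0 || d$delta_ds > 0) && n > 0) {
      for (lo in seq(1L, n, by = chunk_size)) {
        hi <- min(lo + chunk_size - 1L, n)
        sel <- lo:hi
        seqs <- substring(genome, start[sel] + 1L, end[sel])
        neg <- strand[sel] == "-"
        if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
        clens <- lens[sel]
        chars <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
        off5 <- sequence(clens) - 1L
        fidx <- rep.int(sel, clens)
        off3 <- rep.int(clens, clens) - 1L - off5
        amp <- d$delta_ss - d$delta_ds
        out <- list()
        if (ends %in% c("both", "five")) {
          isC <- chars == "C"
          p5 <- d$delta_ds + amp * d$overhang_decay^off5
          hitC <- isC & (runif(length(chars)) < p5)
          if (any(hitC)) {
            out$C <- data.frame(frag_id = frag_id[fidx[hitC]],
                                offset = off5[hitC], kind = "deam_C",
                                stringsAsFactors = FALSE)
          }
        }
        if (ends %in% c("both", "three")) {
          isG <- chars == "G"
          p3 <- d$delta_ds + amp * d$overhang_decay^off3
          hitG <- isG & (runif(length(chars)) < p3)
          if (any(hitG)) {
            out$G <- data.frame(frag_id = frag_id[fidx[hitG]],
                                offset = off5[hitG], kind = "deam_G",
                                stringsAsFactors = FALSE)
          }
        }
        if (length(out)) {
          lesion_list[[paste0("deam", lo)]] <- do.call(rbind, out)
        }
      }
    }

    lesions <- if (length(lesion_list)) {
      do.call(rbind, lesion_list)
    } else {
      data.frame(frag_id = character(0), offset = integer(0),
                 kind = character(0), stringsAsFactors = FALSE)
    }
    rownames(lesions) <- NULL
    new_fragments(fr, lesions, spec$vitality, age_yr)
  })
}

#' Partition fragments into iDNA and eDNA pools
#'
#' Routing follows the vitality class: lysed remains are extracellular by
#' definition; intact dead cells hold their DNA intracellularly but leak a
#' fraction; living cells keep their DNA with a small recently-expired
#' leakage into the eDNA pool. The two pools are disjoint and jointly
#' exhaustive.
#'
#' @param fragments a `taphonomy_fragments` object.
#' @param vitality vitality class; defaults to the one recorded on
#'   `fragments`.
#' @param leakage probability that a fragment is routed to the minority pool
#'   (eDNA for `living`/`dead_intact`, iDNA for `lysed`). Defaults: living
#'   0.23 (reproducing a young-stratum eDNA/iDNA mass ratio of ~0.3),
#'   dead_intact 0.2, lysed 0.
#' @param seed integer seed (`NULL` = current RNG state).
#' @return a list with elements `iDNA` and `eDNA`, each a
#'   `taphonomy_fragments` object.
#' @export
partition_idna_edna <- function(fragments, vitality = NULL, leakage = NULL,
                                seed = NULL) {
  stopifnot(inherits(fragments, "taphonomy_fragments"))
  vitality <- vitality %||% attr(fragments, "vitality")
  if (is.null(vitality) || is.na(vitality) ||
      !vitality %in% c("living", "dead_intact", "lysed")) {
    stop("unknown vitality: ", deparse(vitality))
  }
  leakage <- leakage %||%
    switch(vitality, living = 0.23, dead_intact = 0.2, lysed = 0)
  stopifnot(leakage >= 0, leakage <= 1)
  with_seed(seed, {
    n <- nrow(fragments$fragments)
    leak <- runif(n) < leakage
    home_idna <- vitality %in% c("living", "dead_intact")
    to_idna <- if (home_idna) !leak else leak
    list(iDNA = subset_fragments(fragments, to_idna),
         eDNA = subset_fragments(fragments, !to_idna))
  })
}

#' Apply in-vitro enzymatic repair to a fragment pool
#'
#' Models a glycosylase/endonuclease repair cocktail: every lesion
#' (deaminated cytosine, blocking lesion, nick) is independently reverted or
#' removed with probability `rho`. Deaminated cytosines revert to the
#' reference base (glycosylase excision plus strand-templated fill-in), so a
#' repaired lesion leaves no trace in reads. The input object is not
#' modified.
#'
#' @param fragments a `taphonomy_fragments` object.
#' @param rho per-lesion repair efficiency in `[0, 1]`; 0 is the identity,
#'   1 removes every lesion.
#' @param seed integer seed (`NULL` = current RNG state).
#' @return a new `taphonomy_fragments` object with the surviving lesions.
#' @export
apply_repair <- function(fragments, rho, seed = NULL) {
  stopifnot(inherits(fragments, "taphonomy_fragments"))
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho > 1) {
    stop("rho must be a single value in [0, 1]")
  }
  with_seed(seed, {
    le <- fragments$lesions
    keep <- if (nrow(le)) runif(nrow(le)) >= rho else logical(0)
    new_fragments(fragments$fragments, le[keep, , drop = FALSE],
                  attr(fragments, "vitality"), attr(fragments, "age_yr"))
  })
}
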