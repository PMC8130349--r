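# Library conversion and sequencing of taphonomically processed fragments.

#' Convert and sequence a fragment pool into a read library
#'
#' A fragment enters the library with probability
#' `(1 - block_prob)^n_blocking` where `n_blocking` counts its surviving
#' blocking lesions (nicks, abasic sites/dimers) -- damaged templates fail
#' conversion, which is what in-vitro repair rescues. Converted fragments are
#' then sampled with replacement until the library reaches `target_depth`
#' fold-coverage of the pooled reference in expectation. Each read is the
#' first `read_length` bases of its fragment (5' end; ligation-style library,
#' so terminal damage is read-visible); fragments shorter than the read
#' length yield full-length clipped reads. Surviving deaminated cytosines
#' read as T (and the 3' guanine analogue as A); independent sequencing
#' errors are added at `seq_error_rate`. Alignment records carry the true
#' coordinates (1-based in SAM convention).
#'
#' @param fragments a `taphonomy_fragments` pool (possibly pooled across
#'   populations with [pool_fragments()]).
#' @param genome_map named character vector / `DNAStringSet` / FASTA path of
#'   reference genomes; depth is computed against their total length.
#' @param spec a [library_spec()].
#' @return an object of class `sequencing_library` with elements `reads`
#'   (qname, flag, rname, pos, mapq, cigar, seq in reference orientation,
#'   read_len, strand), `truth` (per-read ground truth: fragment id and
#'   coordinates, lesion and error counts) and `spec`.
#' @export
#' @examples
#' sp <- population_spec("g1", 20000, vitality = "dead_intact")
#' g <- generate_reference_genomes(sp, seed = 1)
#' fr <- simulate_taphonomy(g[["g1"]], sp, n_fragments = 500, seed = 2)
#' lib <- sequence_library(fr, g, library_spec("iDNA", target_depth = 2, seed = 3))
#' lib
sequence_library <- function(fragments, genome_map, spec) {
  stopifnot(inherits(fragments, "taphonomy_fragments"),
            inherits(spec, "library_spec"))
  genome_map <- as_reference_map(genome_map)
  fr <- fragments$fragments
  le <- fragments$lesions
  missing_g <- setdiff(unique(fr$genome_id), names(genome_map))
  if (length(missing_g)) {
    stop("genome_map lacks sequences for: ", paste(missing_g, collapse = ", "))
  }
  rl <- spec$read_length
  with_seed(spec$seed, {
    n <- nrow(fr)
    n_reads <- as.integer(round(spec$target_depth * sum(nchar(genome_map)) /
                                  rl * spec$downsample))
    nb <- integer(n)
    if (n > 0 && nrow(le)) {
      blocking <- le$kind %in% c("nick", "blocker", "abasic")
      nb <- as.integer(table(factor(le$frag_id[blocking], levels = fr$frag_id)))
    }
    conv <- if (n > 0) runif(n) < (1 - spec$block_prob)^nb else logical(0)
    pool <- which(conv)
    if (n_reads > 0 && length(pool) == 0L) {
      warning("no fragment survived library conversion; empty library")
    }
    if (n > 0 && all(fr$length < rl)) {
      warning("read_length exceeds every fragment length; emitting ",
              "full-length clipped reads")
    }
    if (n_reads == 0L || length(pool) == 0L) {
      return(empty_library(spec))
    }

    pick <- pool[sample.int(length(pool), n_reads, replace = TRUE)]
    u <- sort(unique(pick))
    rlen_u <- pmin(rl, fr$length[u])
    gseq <- genome_map[fr$genome_id[u]]
    plus <- fr$strand[u] == "+"
    tmpl <- character(length(u))
    tmpl[plus] <- substring(gseq[plus], fr$start[u][plus] + 1L,
                            fr$start[u][plus] + rlen_u[plus])
    if (any(!plus)) {
      tmpl[!plus] <- revcomp(substring(gseq[!plus],
                                       fr$end[u][!plus] - rlen_u[!plus] + 1L,
                                       fr$end[u][!plus]))
    }
    # surviving deamination within the read window changes the read base
    n_deam_read <- integer(length(u))
    if (nrow(le)) {
      lu <- match(le$frag_id, fr$frag_id[u])
      inwin <- !is.na(lu) & le$kind %in% c("deam_C", "deam_G") &
        le$offset < rlen_u[ifelse(is.na(lu), 1L, lu)]
      if (any(inwin)) {
        li <- which(inwin)
        for (k in li) {
          i <- lu[k]
          o <- le$offset[k] + 1L
          substr(tmpl[i], o, o) <- if (le$kind[k] == "deam_C") "T" else "A"
        }
        tb <- table(factor(lu[li], levels = seq_along(u)))
        n_deam_read <- as.integer(tb)
      }
    }

    ui <- match(pick, u)
    seqs <- tmpl[ui]
    rlen <- rlen_u[ui]
    # independent per-base sequencing errors
    n_err <- if (spec$seq_error_rate > 0) {
      rbinom(n_reads, rlen, spec$seq_error_rate)
    } else integer(n_reads)
    if (any(n_err > 0)) {
      bases <- c("A", "C", "G", "T")
      for (i in which(n_err > 0)) {
        at <- sample.int(rlen[i], n_err[i])
        for (o in at) {
          old <- substr(seqs[i], o, o)
          substr(seqs[i], o, o) <- sample(setdiff(bases, old), 1L)
        }
      }
    }

    strand <- fr$strand[pick]
    pos <- ifelse(strand == "+", fr$start[pick] + 1L,
                  fr$end[pick] - rlen + 1L)
    seq_sam <- seqs
    neg <- strand == "-"
    if (any(neg)) seq_sam[neg] <- revcomp(seqs[neg])
    qname <- sprintf("%s_r%07d", spec$library_id, seq_len(n_reads))
    reads <- data.frame(qname = qname,
                        flag = ifelse(neg, 16L, 0L),
                        rname = fr$genome_id[pick],
                        pos = as.integer(pos), mapq = 60L,
                        cigar = paste0(rlen, "M"),
                        seq = seq_sam, read_len = as.integer(rlen),
                        strand = strand, stringsAsFactors = FALSE)
    truth <- data.frame(qname = qname, frag_id = fr$frag_id[pick],
                        genome_id = fr$genome_id[pick],
                        frag_start = fr$start[pick], frag_end = fr$end[pick],
                        strand = strand, frag_len = fr$length[pick],
                        n_deam_read = n_deam_read[ui], n_block = nb[pick],
                        n_seq_error = n_err, stringsAsFactors = FALSE)
    structure(list(reads = reads, truth = truth, spec = spec,
                   genome_lengths = setNames(nchar(genome_map),
                                             names(genome_map))),
              class = "sequencing_library")
  })
}

empty_library <- function(spec, genome_lengths = integer(0)) {
  cols <- data.frame(qname = character(0), flag = integer(0),
                     rname = character(0), pos = integer(0), mapq = integer(0),
                     cigar = character(0), seq = character(0),
                     read_len = integer(0), strand = character(0),
                     stringsAsFactors = FALSE)
  truth <- data.frame(qname = character(0), frag_id = character(0),
                      genome_id = character(0), frag_start = integer(0),
                      frag_end = integer(0), strand = character(0),
                      frag_len = integer(0), n_deam_read = integer(0),
                      n_block = integer(0), n_seq_error = integer(0),
                      stringsAsFactors = FALSE)
  structure(list(reads = cols, truth = truth, spec = spec,
                 genome_lengths = genome_lengths),
            class = "sequencing_library")
}

#' @export
print.sequencing_library <- function(x, ...) {
  cat(sprintf("<sequencing_library> %s: %d reads over %d genome(s)\n",
              x$spec$library_id, nrow(x$reads),
              length(unique(x$reads$rname))))
  invisible(x)
}

#' Subset a sequencing library to one genome
#' @param lib a `sequencing_library`.
#' @param genome_id genome to keep.
#' @return a `sequencing_library` with only that genome's reads.
#' @export
subset_library <- function(lib, genome_id) {
  stopifnot(inherits(lib, "sequencing_library"))
  keep <- lib$reads$rname == genome_id
  structure(list(reads = lib$reads[keep, , drop = FALSE],
                 truth = lib$truth[keep, , drop = FALSE],
                 spec = lib$spec, genome_lengths = lib$genome_lengths),
            class = "sequencing_library")
}
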