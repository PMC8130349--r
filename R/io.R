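# Plain-text interchange: FASTQ, SAM, BED, TSV.

#' Write library reads as FASTQ (Phred+33)
#'
#' Reads are written in sequencing (read) orientation with a constant
#' quality placeholder, since base qualities are not simulated.
#'
#' @param lib a `sequencing_library`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(lib, path) {
  stopifnot(inherits(lib, "sequencing_library"))
  r <- lib$reads
  seq_read <- r$seq
  neg <- r$strand == "-"
  if (any(neg)) seq_read[neg] <- revcomp(r$seq[neg])
  x <- Biostrings::DNAStringSet(seq_read)
  names(x) <- r$qname
  quals <- Biostrings::BStringSet(strrep("I", r$read_len))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Write library alignments as headered SAM
#'
#' @param lib a `sequencing_library`.
#' @param path output file path.
#' @param sort_by_coord sort records by (reference, position)?
#' @return `path`, invisibly.
#' @export
write_sam <- function(lib, path, sort_by_coord = TRUE) {
  stopifnot(inherits(lib, "sequencing_library"))
  r <- lib$reads
  gl <- lib$genome_lengths
  hdr <- c(sprintf("@HD\tVN:1.6\tSO:%s",
                   if (sort_by_coord) "coordinate" else "unsorted"),
           sprintf("@SQ\tSN:%s\tLN:%d", names(gl), as.integer(gl)))
  if (sort_by_coord && nrow(r)) {
    r <- r[order(match(r$rname, names(gl)), r$pos, r$qname), , drop = FALSE]
  }
  recs <- if (nrow(r)) {
    paste(r$qname, r$flag, r$rname, r$pos, r$mapq, r$cigar, "*", 0L, 0L,
          r$seq, strrep("I", r$read_len), sep = "\t")
  } else character(0)
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read a SAM file into an alignment table
#'
#' Parses the 11 mandatory columns of (possibly headerless) plain-text SAM.
#' Unmapped records (flag bit 0x4 or missing position) are dropped.
#'
#' @param path SAM file path.
#' @return a data.frame with columns qname, flag, rname, pos, mapq, cigar,
#'   seq, read_len, strand.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(empty_library(NULL)$reads)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(f) < 11L
  if (any(bad)) stop("malformed SAM record at line(s): ",
                     paste(head(which(bad)), collapse = ", "))
  g <- function(i) vapply(f, `[[`, character(1), i)
  out <- data.frame(qname = g(1), flag = as.integer(g(2)), rname = g(3),
                    pos = as.integer(g(4)), mapq = as.integer(g(5)),
                    cigar = g(6), seq = g(10), stringsAsFactors = FALSE)
  out <- out[!bitwAnd(out$flag, 4L) & out$rname != "*" & out$pos > 0L, ,
             drop = FALSE]
  out$read_len <- nchar(out$seq)
  out$strand <- ifelse(bitwAnd(out$flag, 16L) > 0L, "-", "+")
  rownames(out) <- NULL
  out
}

#' Read dnaA/dif (or ori/ter) locus annotations from BED
#'
#' @param path BED3+ file path (0-based half-open intervals; column 4, when
#'   present, is the locus name).
#' @return a data.frame with chrom, start, end, name.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 3L)) stop("BED records need at least 3 columns")
  data.frame(chrom = vapply(f, `[[`, character(1), 1),
             start = as.integer(vapply(f, `[[`, character(1), 2)),
             end = as.integer(vapply(f, `[[`, character(1), 3)),
             name = vapply(f, function(x) if (length(x) >= 4) x[[4]] else NA_character_,
                           character(1)),
             stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# coerce library / data.frame / SAM path to the internal alignment table
as_alignments <- function(alignments) {
  if (inherits(alignments, "sequencing_library")) return(alignments$reads)
  if (is.character(alignments) && length(alignments) == 1L) {
    if (!file.exists(alignments)) stop("no such file: ", alignments)
    return(read_sam(alignments))
  }
  if (is.data.frame(alignments)) {
    need <- c("rname", "pos", "cigar", "seq")
    if (!all(need %in% names(alignments))) {
      stop("alignment table needs columns: ", paste(need, collapse = ", "))
    }
    a <- alignments
    if (is.null(a$flag)) a$flag <- 0L
    if (is.null(a$strand)) {
      a$strand <- ifelse(bitwAnd(as.integer(a$flag), 16L) > 0L, "-", "+")
    }
    if (is.null(a$read_len)) a$read_len <- nchar(a$seq)
    return(a)
  }
  stop("cannot interpret 'alignments'")
}
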