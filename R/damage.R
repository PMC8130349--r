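# Position-specific nucleotide mis-incorporation profiling.

cigar_ops <- function(cigar) {
  n <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  list(n = n, op = op)
}

ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    if (grepl("^[0-9]+M$", cg)) return(as.integer(sub("M$", "", cg)))
    co <- cigar_ops(cg)
    sum(co$n[co$op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

# aligned (ref, query) column strings in *reference forward* orientation for
# one gapped/clipped read; insertions and deletions drop their columns,
# soft-clipped bases are excluded.
aligned_columns <- function(seq, pos, cigar, ref) {
  co <- cigar_ops(cigar)
  q <- 1L
  r <- pos
  rb <- qb <- character(0)
  for (i in seq_along(co$op)) {
    len <- co$n[i]
    switch(co$op[i],
           M = , `=` = , X = {
             rb <- c(rb, substring(ref, r, r + len - 1L))
             qb <- c(qb, substring(seq, q, q + len - 1L))
             q <- q + len; r <- r + len
           },
           I = , S = { q <- q + len },
           D = , N = { r <- r + len },
           H = NULL,
           stop("unsupported CIGAR op: ", co$op[i]))
  }
  list(ref = paste(rb, collapse = ""), query = paste(qb, collapse = ""))
}

#' Position-specific substitution profile from read alignments
#'
#' Counts, for every aligned read position within `max_pos` of the read's
#' 5' end, how often the reference base is C and how often that C is read as
#' T (the cytosine-deamination signature), and symmetrically reference-G
#' read-as-A within `max_pos` of the read's 3' end (the complementary-strand
#' signature). Offsets are 1-based from the respective read end, in read
#' orientation; reverse-strand alignments are reoriented accordingly.
#' Only C-to-T (resp. G-to-A) mismatches count toward the numerator; indel
#' columns are skipped; soft-clipped bases are excluded; overlapping reads
#' are counted independently.
#'
#' @param alignments a `sequencing_library`, an alignment data.frame, or a
#'   SAM file path.
#' @param references named character vector / `DNAStringSet` / FASTA path.
#' @param max_pos number of terminal positions profiled (default 25).
#' @param min_mapq minimum mapping quality (default 0; simulated alignments
#'   are true).
#' @return an object of class `damage_profile` with per-offset opportunity
#'   and substitution counts and frequencies `ct5`, `ga3` (NA where no
#'   opportunity was observed).
#' @export
#' @examples
#' refs <- c(g1 = "ACGTACGTCCGGAATT")
#' aln <- data.frame(qname = "r1", flag = 0L, rname = "g1", pos = 1L,
#'                   mapq = 60L, cigar = "8M", seq = "ACGTACGT")
#' substitution_profile(aln, refs, max_pos = 5)
substitution_profile <- function(alignments, references, max_pos = 25L,
                                 min_mapq = 0) {
  a <- as_alignments(alignments)
  refs <- as_reference_map(references)
  P <- as.integer(max_pos)
  stopifnot(P >= 1)
  if (!is.null(a$mapq)) a <- a[a$mapq >= min_mapq, , drop = FALSE]
  missing_ref <- setdiff(unique(a$rname), names(refs))
  if (length(missing_ref)) {
    stop("reference absent for: ", paste(missing_ref, collapse = ", "))
  }
  opp5 <- ct5n <- opp3 <- ga3n <- integer(P)

  if (nrow(a)) {
    simple <- grepl("^[0-9]+M$", a$cigar)
    groups <- split(seq_len(nrow(a)), a$rname)
    for (g in names(groups)) {
      idx <- groups[[g]]
      ref <- refs[[g]]
      si <- idx[simple[idx]]
      if (length(si)) {
        len <- a$read_len[si]
        refseg <- substring(ref, a$pos[si], a$pos[si] + len - 1L)
        qseg <- a$seq[si]
        neg <- a$strand[si] == "-"
        if (any(neg)) {
          refseg[neg] <- revcomp(refseg[neg])
          qseg[neg] <- revcomp(qseg[neg])
        }
        for (p in seq_len(P)) {
          ok <- len >= p
          rb5 <- substring(refseg[ok], p, p)
          qb5 <- substring(qseg[ok], p, p)
          isC <- rb5 == "C"
          opp5[p] <- opp5[p] + sum(isC)
          ct5n[p] <- ct5n[p] + sum(isC & qb5 == "T")
          i3 <- len[ok] - p + 1L
          rb3 <- substring(refseg[ok], i3, i3)
          qb3 <- substring(qseg[ok], i3, i3)
          isG <- rb3 == "G"
          opp3[p] <- opp3[p] + sum(isG)
          ga3n[p] <- ga3n[p] + sum(isG & qb3 == "A")
        }
      }
      for (i in idx[!simple[idx]]) {
        cols <- aligned_columns(a$seq[i], a$pos[i], a$cigar[i], ref)
        rseg <- cols$ref
        qseg <- cols$query
        if (a$strand[i] == "-") {
          rseg <- revcomp(rseg)
          qseg <- revcomp(qseg)
        }
        len <- nchar(rseg)
        for (p in seq_len(min(P, len))) {
          if (substring(rseg, p, p) == "C") {
            opp5[p] <- opp5[p] + 1L
            if (substring(qseg, p, p) == "T") ct5n[p] <- ct5n[p] + 1L
          }
          i3 <- len - p + 1L
          if (substring(rseg, i3, i3) == "G") {
            opp3[p] <- opp3[p] + 1L
            if (substring(qseg, i3, i3) == "A") ga3n[p] <- ga3n[p] + 1L
          }
        }
      }
    }
  }

  freq <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  structure(list(genome_id = paste(sort(unique(a$rname)), collapse = ","),
                 library_id = if (inherits(alignments, "sequencing_library"))
                   alignments$spec$library_id else NA_character_,
                 max_pos = P,
                 ct5 = freq(ct5n, opp5), ga3 = freq(ga3n, opp3),
                 ct5_count = ct5n, ga3_count = ga3n,
                 opportunities5 = opp5, opportunities3 = opp3,
                 n_reads = nrow(a)),
            class = "damage_profile")
}

#' @export
print.damage_profile <- function(x, ...) {
  cat(sprintf("<damage_profile> %s (%s): %d reads, %d terminal positions\n",
              x$genome_id, x$library_id %||% "?", x$n_reads, x$max_pos))
  cat(sprintf("  ct5[1..5]: %s\n",
              paste(sprintf("%.4f", head(x$ct5, 5)), collapse = " ")))
  invisible(x)
}

#' Convert a damage profile to a tidy table
#' @param profile a `damage_profile`.
#' @return data.frame with offset, opportunities, counts and frequencies for
#'   both read ends.
#' @export
profile_table <- function(profile) {
  stopifnot(inherits(profile, "damage_profile"))
  data.frame(offset = seq_len(profile$max_pos),
             opportunities5 = profile$opportunities5,
             ct_count = profile$ct5_count, ct5 = profile$ct5,
             opportunities3 = profile$opportunities3,
             ga_count = profile$ga3_count, ga3 = profile$ga3)
}

#' Scalar damage score of a profile
#'
#' The score is the C-to-T frequency at the terminal 5' position, the most
#' damage-enriched coordinate; profiles whose terminal position has no
#' reference-C opportunity return `NA` (undefined scores propagate).
#'
#' @param profile a `damage_profile`.
#' @return a single numeric in `[0, 1]`, or `NA`.
#' @export
damage_score <- function(profile) {
  stopifnot(inherits(profile, "damage_profile"))
  profile$ct5[1]
}

#' Fit the overhang-decay deamination model to a damage profile
#'
#' Least-squares fit of `ct5[p] ~ delta_ds + (delta_ss - delta_ds) *
#' q^(p - 1)` over the defined offsets, box-constrained to the parameter
#' domains. A deterministic grid over `q` (with the amplitude profiled out
#' by linear least squares) seeds a quasi-Newton refinement, so the fit has
#' no random element. A flat profile leaves `q` unidentifiable; the fit then
#' returns the common level for both deltas with `q_identifiable = FALSE`.
#'
#' @param profile a `damage_profile` with at least 5 defined 5' offsets.
#' @return an object of class `damage_fit` with `delta_ss_hat`,
#'   `delta_ds_hat`, `q_hat`, `rss`, `converged`, `q_identifiable`.
#' @export
fit_damage_model <- function(profile) {
  stopifnot(inherits(profile, "damage_profile"))
  p <- seq_len(profile$max_pos)
  y <- profile$ct5
  ok <- !is.na(y)
  if (sum(ok) < 5) stop("need >= 5 defined profile positions to fit")
  p <- p[ok]
  y <- y[ok]

  fit_given_q <- function(q) {
    x <- q^(p - 1)
    xm <- cbind(1, x)
    cf <- tryCatch(solve(crossprod(xm), crossprod(xm, y))[, 1],
                   error = function(e) c(mean(y), 0))
    dds <- min(max(cf[1], 0), 1)
    amp <- min(max(cf[2], 0), 1 - dds)
    c(dds = dds, amp = amp)
  }
  rss_of <- function(dds, amp, q) sum((y - (dds + amp * q^(p - 1)))^2)

  grid <- seq(0.02, 0.98, by = 0.02)
  best <- NULL
  best_rss <- Inf
  for (q in grid) {
    cf <- fit_given_q(q)
    r <- rss_of(cf["dds"], cf["amp"], q)
    if (r < best_rss) {
      best_rss <- r
      best <- c(cf, q = q)
    }
  }
  obj <- function(par) rss_of(par[1], par[2], par[3])
  opt <- tryCatch(
    optim(best, obj, method = "L-BFGS-B",
          lower = c(0, 0, 1e-6), upper = c(1, 1, 1 - 1e-6)),
    error = function(e) list(par = best, value = best_rss, convergence = 1L))
  par <- opt$par
  if (opt$value > best_rss) { # keep the best grid point on non-convergence
    par <- best
    opt$value <- best_rss
    opt$convergence <- 1L
  }
  structure(list(delta_ds_hat = unname(par[1]),
                 delta_ss_hat = unname(min(par[1] + par[2], 1)),
                 q_hat = unname(par[3]),
                 rss = unname(opt$value),
                 converged = opt$convergence == 0L,
                 q_identifiable = unname(par[2]) > 5e-3),
            class = "damage_fit")
}

#' @export
print.damage_fit <- function(x, ...) {
  cat(sprintf("<damage_fit> delta_ss %.4f, delta_ds %.4f, q %.3f (rss %.3g%s%s)\n",
              x$delta_ss_hat, x$delta_ds_hat, x$q_hat, x$rss,
              if (x$converged) "" else ", not converged",
              if (x$q_identifiable) "" else ", q unidentifiable"))
  invisible(x)
}

#' @export
coef.damage_fit <- function(object, ...) {
  c(delta_ss = object$delta_ss_hat, delta_ds = object$delta_ds_hat,
    q = object$q_hat)
}

#' @export
predict.damage_fit <- function(object, offsets = 1:25, ...) {
  object$delta_ds_hat +
    (object$delta_ss_hat - object$delta_ds_hat) * object$q_hat^(offsets - 1)
}

#' Write a damage-model fit as JSON
#' @param fit a `damage_fit`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_damage_fit <- function(fit, path) {
  stopifnot(inherits(fit, "damage_fit"))
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
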