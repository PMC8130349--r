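# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed and a label
#'
#' One master seed per scenario is fanned out to per-operation streams by a
#' fixed label, so that toggling one stage (e.g. repair) does not perturb the
#' random draws of another (e.g. fragment generation). Pure integer
#' arithmetic on doubles below 2^53, reduced mod 2^31 - 1, so the derivation
#' is identical across platforms.
#'
#' @param seed master seed, a single integer.
#' @param label character label of the child stream.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "seq-iDNA")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label),
            length(label) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.double(seed) %% m
  for (code in utf8ToInt(label)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}

# vectorized reverse complement on plain character vectors
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# coerce a reference collection (named character vector, DNAStringSet, or
# FASTA path) to a named character vector
as_reference_map <- function(references) {
  if (is.character(references) && length(references) == 1L &&
      file.exists(references) && is.null(names(references))) {
    references <- Biostrings::readDNAStringSet(references)
  }
  if (methods::is(references, "DNAStringSet")) {
    refs <- as.character(references)
    names(refs) <- sub("\\s.*$", "", names(references))
    return(refs)
  }
  if (is.character(references)) {
    if (is.null(names(references)) || any(!nzchar(names(references)))) {
      stop("references must be named by genome_id")
    }
    return(references)
  }
  stop("cannot interpret 'references' as a genome sequence map")
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

stop_field <- function(field, msg) {
  stop(sprintf("%s: %s", field, msg), call. = FALSE)
}
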