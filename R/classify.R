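# Integration of per-genome evidence into paleoecological calls.

#' Balanced spectral counts with even sharing of non-unique spectra
#'
#' Protein abundance from MS/MS spectral counting: a spectrum matching a
#' single protein contributes 1 to it; a spectrum matching n proteins
#' contributes 1/n to each. Totals are conserved: the balanced counts sum to
#' the number of spectra.
#'
#' @param peptide_map a list, one element per spectrum, each a character
#'   vector of matching protein ids (length >= 1).
#' @return named numeric vector of balanced counts per protein.
#' @export
#' @examples
#' balanced_spectral_counts(list("A", "A", "A", "A", c("A", "B"), c("A", "B")))
#' # A = 5, B = 1
balanced_spectral_counts <- function(peptide_map) {
  stopifnot(is.list(peptide_map))
  if (!length(peptide_map)) return(setNames(numeric(0), character(0)))
  if (any(lengths(peptide_map) < 1L)) {
    stop("every spectrum must match at least one protein")
  }
  prot <- unlist(peptide_map, use.names = FALSE)
  w <- rep(1 / lengths(peptide_map), lengths(peptide_map))
  out <- tapply(w, prot, sum)
  setNames(as.numeric(out), names(out))
}

#' Default classification thresholds
#' @param damage_max damage-score bound below which a fraction counts as
#'   undamaged (default 0.1, the descriptive bound separating young-stratum
#'   genomes).
#' @param delta_max bound on |delta completeness| for a negligible repair
#'   effect (default 0.05; a documented free parameter).
#' @return named list of thresholds.
#' @export
classification_thresholds <- function(damage_max = 0.1, delta_max = 0.05) {
  if (!(damage_max > 0 && damage_max < 1 && delta_max > 0 && delta_max < 1)) {
    stop("thresholds must lie in (0, 1)")
  }
  list(damage_max = damage_max, delta_max = delta_max)
}

#' Classify one population as living or fossil from its evidence vector
#'
#' Decision table over per-fraction evidence:
#' \enumerate{
#'   \item presence only in the eDNA fraction -> `fossil_extracellular`
#'     (extracellular remains of lysed cells);
#'   \item presence in iDNA (with or without eDNA) with unrepaired damage
#'     below `damage_max` AND |delta completeness| below `delta_max` in
#'     every present fraction -> `living` (intact, repair-indifferent DNA);
#'   \item presence in iDNA with damage or repair gain at/above threshold in
#'     some present fraction -> `fossil_intracellular` (dead but
#'     structurally intact cells);
#'   \item anything else (undefined scores, conflicting fractions) ->
#'     `ambiguous`.
#' }
#' Protein evidence is advisory and upgrade-only: `protein_expressed = TRUE`
#' promotes `ambiguous` to `living` only when the damage clause of rule 2
#' holds. The rationale records every rule evaluated.
#'
#' @param evidence a list or one-row data.frame with fields `bin_id`,
#'   `idna_present`, `edna_present` (logical), `idna_damage`, `edna_damage`
#'   (unrepaired damage scores, NA allowed), `idna_delta`, `edna_delta`
#'   (repaired minus unrepaired completeness), and optional
#'   `protein_expressed`, `growth_valid`.
#' @param thresholds see [classification_thresholds()].
#' @return an object of class `paleo_call`: `bin_id`, `label`, `rationale`.
#' @export
#' @examples
#' classify_population(list(bin_id = "b1", idna_present = TRUE,
#'                          edna_present = TRUE, idna_damage = 0.02,
#'                          edna_damage = 0.03, idna_delta = 0.01,
#'                          edna_delta = -0.01))
classify_population <- function(evidence,
                                thresholds = classification_thresholds()) {
  e <- as.list(evidence)
  stopifnot(!is.null(e$bin_id))
  thresholds <- do.call(classification_thresholds,
                        thresholds[c("damage_max", "delta_max")])
  idna <- isTRUE(as.logical(e$idna_present))
  edna <- isTRUE(as.logical(e$edna_present))
  if (!idna && !edna) stop("population absent from both fractions")
  num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  dmg <- c(iDNA = num(e$idna_damage), eDNA = num(e$edna_damage))
  dlt <- c(iDNA = num(e$idna_delta), eDNA = num(e$edna_delta))
  present <- c(iDNA = idna, eDNA = edna)

  rationale <- character(0)
  note <- function(id, ok) {
    rationale <<- c(rationale, paste0(id, ":", if (isTRUE(ok)) "satisfied"
                                      else "violated"))
  }

  r1 <- edna && !idna
  note("R1_edna_only", r1)
  damage_low <- all(!is.na(dmg[present])) &&
    all(dmg[present] < thresholds$damage_max)
  delta_small <- all(!is.na(dlt[present])) &&
    all(abs(dlt[present]) < thresholds$delta_max)
  r2 <- idna && damage_low && delta_small
  note("R2_intact_repair_indifferent", r2)
  damaged <- any(!is.na(dmg[present]) & dmg[present] >= thresholds$damage_max)
  gained <- any(!is.na(dlt[present]) & dlt[present] >= thresholds$delta_max)
  r3 <- idna && (damaged || gained)
  note("R3_idna_damaged", r3)

  label <- if (r1) "fossil_extracellular"
  else if (r2) "living"
  else if (r3) "fossil_intracellular"
  else "ambiguous"

  if (label == "ambiguous" && isTRUE(as.logical(e$protein_expressed)) &&
      damage_low) {
    label <- "living"
    note("R5_protein_upgrade", TRUE)
  } else {
    note("R4_ambiguous", label == "ambiguous")
  }
  structure(list(bin_id = e$bin_id, label = label, rationale = rationale),
            class = "paleo_call")
}

#' @export
print.paleo_call <- function(x, ...) {
  cat(sprintf("<paleo_call> %s -> %s\n  %s\n", x$bin_id, x$label,
              paste(x$rationale, collapse = "; ")))
  invisible(x)
}

#' Classify every row of an evidence table
#' @param evidence data.frame, one row per bin, columns as in
#'   [classify_population()].
#' @param thresholds see [classification_thresholds()].
#' @return data.frame with bin_id, label, rationale (collapsed).
#' @export
classify_assemblage <- function(evidence,
                                thresholds = classification_thresholds()) {
  stopifnot(is.data.frame(evidence), nrow(evidence) > 0)
  calls <- lapply(seq_len(nrow(evidence)), function(i) {
    classify_population(evidence[i, , drop = FALSE], thresholds)
  })
  data.frame(bin_id = vapply(calls, `[[`, character(1), "bin_id"),
             label = vapply(calls, `[[`, character(1), "label"),
             rationale = vapply(calls, function(x)
               paste(x$rationale, collapse = ";"), character(1)),
             stringsAsFactors = FALSE)
}

#' Summarize an assemblage of calls, optionally against ground truth
#'
#' @param calls data.frame from [classify_assemblage()] (or with columns
#'   `bin_id`, `label`).
#' @param ground_truth optional named character vector mapping bin_id to the
#'   simulated vitality (`living`, `dead_intact`, `lysed`).
#' @return list with `counts` (per-label tally); with truth also
#'   `confusion` (vitality x label) and `accuracy` under the natural mapping
#'   living->living, dead_intact->fossil_intracellular,
#'   lysed->fossil_extracellular.
#' @export
summarize_assemblage <- function(calls, ground_truth = NULL) {
  stopifnot(is.data.frame(calls), nrow(calls) > 0,
            all(c("bin_id", "label") %in% names(calls)))
  labels <- c("living", "fossil_intracellular", "fossil_extracellular",
              "ambiguous")
  counts <- table(factor(calls$label, levels = labels))
  out <- list(counts = counts)
  if (!is.null(ground_truth)) {
    truth <- ground_truth[calls$bin_id]
    if (anyNA(truth)) stop("ground_truth lacks entries for some bins")
    expected <- c(living = "living", dead_intact = "fossil_intracellular",
                  lysed = "fossil_extracellular")[truth]
    out$confusion <- table(vitality = truth,
                           label = factor(calls$label, levels = labels))
    out$accuracy <- mean(calls$label == expected)
  }
  out
}
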