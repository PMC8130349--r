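# Spectral-count aggregation and the living/fossil decision table.

test_that("balanced spectral counts share non-unique spectra evenly", {
  out <- balanced_spectral_counts(
    c(replicate(4, "A", simplify = FALSE),
      replicate(2, c("A", "B"), simplify = FALSE)))
  expect_equal(out[["A"]], 5)
  expect_equal(out[["B"]], 1)

  uniq <- balanced_spectral_counts(list("A", "B", "B", "C"))
  expect_equal(unname(uniq[c("A", "B", "C")]), c(1, 2, 1))

  expect_length(balanced_spectral_counts(list()), 0)
  expect_error(balanced_spectral_counts(list("A", character(0))),
               "at least one")
})

test_that("balanced counts conserve the total number of spectra", {
  set.seed(501)
  prots <- LETTERS[1:6]
  for (i in 1:20) {
    n <- sample(1:40, 1)
    pm <- replicate(n, sample(prots, sample(1:3, 1)), simplify = FALSE)
    expect_equal(sum(balanced_spectral_counts(pm)), n)
  }
})

ev <- function(...) {
  defaults <- list(bin_id = "b", idna_present = TRUE, edna_present = TRUE,
                   idna_damage = 0.02, edna_damage = 0.03,
                   idna_delta = 0.01, edna_delta = -0.01)
  utils::modifyList(defaults, list(...))
}

test_that("the decision table reproduces the canonical calls", {
  expect_equal(classify_population(ev())$label, "living")
  expect_equal(classify_population(ev(idna_damage = 0.25,
                                      idna_delta = 0.2))$label,
               "fossil_intracellular")
  expect_equal(classify_population(ev(idna_present = FALSE,
                                      idna_damage = NA,
                                      idna_delta = NA,
                                      edna_damage = 0.4))$label,
               "fossil_extracellular")
  # eDNA-only is fossil_extracellular regardless of damage
  expect_equal(classify_population(ev(idna_present = FALSE,
                                      idna_damage = NA, idna_delta = NA,
                                      edna_damage = 0.01))$label,
               "fossil_extracellular")
  # low damage but a large negative delta is conflicting evidence
  amb <- classify_population(ev(edna_delta = -0.3))
  expect_equal(amb$label, "ambiguous")
  expect_true(any(grepl("R2.*violated", amb$rationale)))
  # undefined scores cannot be called living
  expect_equal(classify_population(ev(edna_damage = NA))$label, "ambiguous")
  expect_error(classify_population(ev(idna_present = FALSE,
                                      edna_present = FALSE)), "absent")
  expect_error(classify_population(ev(), thresholds = list(damage_max = 0,
                                                           delta_max = 0.05)),
               "thresholds")
})

test_that("protein evidence upgrades only damage-consistent ambiguity", {
  up <- classify_population(ev(edna_delta = -0.3, protein_expressed = TRUE))
  expect_equal(up$label, "living")
  expect_true(any(grepl("protein_upgrade", up$rationale)))
  no_up <- classify_population(ev(idna_damage = 0.5, idna_delta = -0.3,
                                  protein_expressed = TRUE))
  expect_false(no_up$label == "living")
})

test_that("every evidence vector maps to exactly one label, monotonically", {
  dmg_grid <- c(0.0, 0.05, 0.09, 0.11, 0.3, 0.8)
  labels <- c("living", "fossil_intracellular", "fossil_extracellular",
              "ambiguous")
  for (ed in c(0.01, 0.2)) {
    for (dd in c(0, 0.04, 0.1)) {
      seq_labels <- sapply(dmg_grid, function(d)
        classify_population(ev(idna_damage = d, edna_damage = ed,
                               idna_delta = dd))$label)
      expect_true(all(seq_labels %in% labels))
      # increasing iDNA damage can only move away from 'living'
      liv <- seq_labels == "living"
      expect_true(all(diff(liv) <= 0))
    }
  }
})

test_that("assemblage summaries tally labels and score against truth", {
  calls <- data.frame(bin_id = c("a", "b", "c"),
                      label = c("living", "fossil_intracellular",
                                "fossil_extracellular"),
                      stringsAsFactors = FALSE)
  truth <- c(a = "living", b = "dead_intact", c = "lysed")
  s <- summarize_assemblage(calls, truth)
  expect_equal(s$accuracy, 1)
  expect_equal(unname(s$counts["living"]), 1L)
  expect_equal(sum(s$confusion), 3L)

  all_living <- data.frame(bin_id = sprintf("b%02d", 1:14), label = "living",
                           stringsAsFactors = FALSE)
  s2 <- summarize_assemblage(all_living)
  expect_equal(unname(s2$counts["living"]), 14L)
  expect_error(summarize_assemblage(calls, truth[1:2]), "lacks")
})
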