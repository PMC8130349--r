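# Scenario orchestration: simulate -> profile -> assay -> classify -> report.

#' Assemble a scenario configuration
#'
#' A scenario bundles the simulated community (populations), the 2x2
#' iDNA/eDNA x repair library design, classification thresholds, optional
#' racemization observations, and one master seed from which every random
#' stream is derived.
#'
#' @param populations list of [population_spec()] objects.
#' @param libraries list of [library_spec()] objects; exactly one repaired
#'   and one unrepaired library per fraction.
#' @param seed master integer seed.
#' @param thresholds see [classification_thresholds()].
#' @param fragment_redundancy fragments drawn per population, expressed as
#'   fold-coverage of the genome in read-sized footprints (default 5). This
#'   sets the finite distinct-template pool that survives taphonomy; it is
#'   what makes unrepaired fossil libraries breadth-limited (the regime in
#'   which repair visibly rescues completeness) while intact living DNA
#'   saturates.
#' @param leakage optional named list overriding partition leakage per
#'   vitality class.
#' @param racemization optional list with elements `params`
#'   ([arrhenius_params()] or a list of its arguments), `dl0`, `ages`
#'   (named by depth) and `observed` (data.frame with depth, dl_bulk,
#'   dl_cells).
#' @param heterogeneity strain-admixture fraction forwarded to
#'   [grid_index()] validity (default 0).
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(populations, libraries, seed,
                            thresholds = classification_thresholds(),
                            fragment_redundancy = 5,
                            leakage = NULL, racemization = NULL,
                            heterogeneity = 0) {
  cfg <- structure(list(populations = populations, libraries = libraries,
                        seed = seed, thresholds = thresholds,
                        fragment_redundancy = fragment_redundancy,
                        leakage = leakage, racemization = racemization,
                        heterogeneity = heterogeneity),
                   class = "scenario_config")
  validate_scenario(cfg)
  cfg
}

#' Validate a scenario configuration
#'
#' Checks the structural invariants of a scenario and fails with the field
#' path of the first violation.
#'
#' @param config a `scenario_config` (or bare list with the same fields).
#' @return the config, invisibly, if valid.
#' @export
validate_scenario <- function(config) {
  cfg <- unclass(config)
  if (is.null(cfg$seed) || !is.numeric(cfg$seed) || length(cfg$seed) != 1L) {
    stop_field("seed", "a single integer master seed is required")
  }
  if (!length(cfg$populations)) {
    stop_field("populations", "at least one population_spec is required")
  }
  for (i in seq_along(cfg$populations)) {
    if (!inherits(cfg$populations[[i]], "population_spec")) {
      stop_field(sprintf("populations[%d]", i), "not a population_spec")
    }
  }
  ids <- vapply(cfg$populations, `[[`, character(1), "genome_id")
  if (anyDuplicated(ids)) {
    stop_field("populations", paste("duplicate genome_id:",
                                    ids[duplicated(ids)][1]))
  }
  ab <- vapply(cfg$populations, `[[`, numeric(1), "relative_abundance")
  if (sum(ab) <= 0) {
    stop_field("populations", "relative abundances must sum to a positive value")
  }
  if (!length(cfg$libraries)) {
    stop_field("libraries", "library_spec list is required")
  }
  for (i in seq_along(cfg$libraries)) {
    if (!inherits(cfg$libraries[[i]], "library_spec")) {
      stop_field(sprintf("libraries[%d]", i), "not a library_spec")
    }
  }
  for (fr in c("iDNA", "eDNA")) {
    for (rep in c(TRUE, FALSE)) {
      n <- sum(vapply(cfg$libraries, function(l)
        l$fraction == fr && l$repaired == rep, logical(1)))
      if (n != 1L) {
        stop_field(sprintf("libraries[%s, repaired=%s]", fr, rep),
                   sprintf("exactly one library required, found %d", n))
      }
    }
  }
  do.call(classification_thresholds,
          cfg$thresholds[c("damage_max", "delta_max")])
  if (!is.null(cfg$racemization)) {
    rz <- cfg$racemization
    if (is.null(rz$ages) || is.null(rz$observed)) {
      stop_field("racemization", "needs both 'ages' and 'observed'")
    }
  }
  invisible(config)
}

#' The bundled three-population study scenario
#'
#' One population per vitality class, mirroring the contrast the field
#' observes across a permafrost chronosequence: a living population with
#' intact high-molecular-weight DNA and mild replication skew; an intact
#' dead (fossil) population with heavily deaminated, blocked, short-fragment
#' DNA; and a lysed population of the same damage regime routed entirely to
#' the eDNA pool. Libraries follow the 2x2 design at 15x depth with
#' complete repair (rho = 1) and strong conversion blocking (pi = 0.9).
#'
#' @param seed master integer seed.
#' @param genome_length per-population genome size (default 40 kb, chosen
#'   for fast desk-scale simulation).
#' @param target_depth library fold-coverage (default 15).
#' @return a `scenario_config`.
#' @export
default_scenario <- function(seed = 1L, genome_length = 40000L,
                             target_depth = 15) {
  fossil_damage <- damage_params(delta_ss = 0.3, delta_ds = 0.01,
                                 overhang_decay = 0.6, nick_rate = 0.005,
                                 blocker_rate = 0.01, frag_mu = log(200),
                                 frag_sigma = 0.5)
  pops <- list(
    population_spec("young_living", genome_length, gc_fraction = 0.55,
                    vitality = "living", ptr = 1.3),
    population_spec("fossil_aerobe", genome_length, gc_fraction = 0.45,
                    vitality = "dead_intact", damage = fossil_damage),
    population_spec("lysed_relic", genome_length, gc_fraction = 0.5,
                    vitality = "lysed", damage = fossil_damage))
  libs <- list(
    library_spec("iDNA", repaired = FALSE, target_depth = target_depth),
    library_spec("iDNA", repaired = TRUE, target_depth = target_depth),
    library_spec("eDNA", repaired = FALSE, target_depth = target_depth),
    library_spec("eDNA", repaired = TRUE, target_depth = target_depth))
  racem <- list(
    params = arrhenius_params(),
    dl0 = 0,
    ages = c("3.4" = 26000, "5.8" = 100000, "14.8" = 100000),
    observed = data.frame(depth = c(3.4, 5.8, 14.8),
                          dl_bulk = c(0.12, 0.22, 0.29),
                          dl_cells = c(0.06, 0.10, 0.15)))
  scenario_config(pops, libs, seed = seed, racemization = racem)
}

#' Load a scenario configuration from YAML
#' @param path YAML file path.
#' @return a `scenario_config`.
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  pops <- lapply(y$populations, function(p) {
    dmg <- if (!is.null(p$damage)) do.call(damage_params, p$damage)
    do.call(population_spec,
            c(p[setdiff(names(p), "damage")], list(damage = dmg)))
  })
  libs <- lapply(y$libraries, function(l) do.call(library_spec, l))
  thr <- if (!is.null(y$thresholds)) {
    do.call(classification_thresholds, y$thresholds)
  } else classification_thresholds()
  racem <- if (!is.null(y$racemization)) {
    rz <- y$racemization
    list(params = do.call(arrhenius_params,
                          rz[intersect(names(rz),
                                       c("Ea", "A", "T_kelvin", "T_celsius"))]),
         dl0 = rz$dl0 %||% 0,
         ages = unlist(rz$ages),
         observed = do.call(rbind, lapply(rz$observed, as.data.frame)))
  }
  scenario_config(pops, libs, seed = y$seed, thresholds = thr,
                  fragment_redundancy = y$fragment_redundancy %||% 5,
                  leakage = y$leakage, racemization = racem,
                  heterogeneity = y$heterogeneity %||% 0)
}

mean_depth_of <- function(lib, genome_id, L) {
  r <- lib$reads[lib$reads$rname == genome_id, , drop = FALSE]
  if (!nrow(r)) return(0)
  sum(r$read_len) / L
}

#' Run a full scenario end-to-end
#'
#' Generates genomes, simulates taphonomy and pool partitioning, sequences
#' the 2x2 library design, profiles damage, computes the repair assay,
#' growth indices and racemization report, and classifies every population.
#' All randomness is derived from the master seed by fixed labels, so a
#' rerun of the same configuration is byte-identical (and the repaired /
#' unrepaired libraries of a fraction share their sampling stream, making
#' the 1:1-line contrast paired).
#'
#' @param config a `scenario_config`.
#' @param out_dir optional output directory; when given, FASTA/FASTQ/SAM,
#'   TSV reports and a checksum manifest are written (partial outputs are
#'   removed on failure).
#' @return an object of class `scenario_result`.
#' @export
run_scenario <- function(config, out_dir = NULL) {
  validate_scenario(config)
  seed <- config$seed
  pops <- config$populations
  ids <- vapply(pops, `[[`, character(1), "genome_id")
  names(pops) <- ids
  read_len <- max(vapply(config$libraries, `[[`, integer(1), "read_length"))

  genomes <- generate_reference_genomes(pops, seed)

  ab <- vapply(pops, `[[`, numeric(1), "relative_abundance")
  w <- ab / mean(ab)
  pools <- list(iDNA = list(), eDNA = list())
  truth_vitality <- setNames(vapply(pops, `[[`, character(1), "vitality"), ids)
  for (id in ids) {
    sp <- pops[[id]]
    footprint <- min(exp(sp$damage$frag_mu), read_len)
    # fragment_redundancy models the attrition-limited template pool of
    # relic DNA; living cells continuously shed fresh intact templates, so
    # their distinct-template pool is not similarly limited
    pool_scale <- if (sp$vitality == "living") 4 else 1
    n_frag <- ceiling(config$fragment_redundancy * pool_scale * w[[id]] *
                        sp$genome_length / footprint)
    fr <- simulate_taphonomy(genomes[[id]], sp, n_fragments = n_frag,
                             seed = derive_seed(seed, paste0("taphonomy-", id)))
    leak <- if (!is.null(config$leakage)) config$leakage[[sp$vitality]]
    part <- partition_idna_edna(fr, leakage = leak,
                                seed = derive_seed(seed, paste0("partition-", id)))
    pools$iDNA[[id]] <- part$iDNA
    pools$eDNA[[id]] <- part$eDNA
  }
  pool_mass <- vapply(pools, function(pl)
    sum(vapply(pl, function(x) sum(x$fragments$length), numeric(1))), numeric(1))

  libs <- list()
  for (ls in config$libraries) {
    pool <- pool_fragments(pools[[ls$fraction]])
    if (ls$repaired) {
      pool <- apply_repair(pool, ls$repair_efficiency,
                           seed = derive_seed(seed, paste0("repair-", ls$fraction)))
    }
    # sampling stream keyed by fraction only: repair toggling must not
    # perturb the read-sampling randomness
    ls$seed <- derive_seed(seed, paste0("seq-", ls$fraction))
    libs[[ls$library_id]] <- sequence_library(pool, genomes, ls)
  }

  profiles <- list()
  evidence <- list()
  records <- list()
  for (id in ids) {
    L <- pops[[id]]$genome_length
    ev <- list(bin_id = id)
    for (fr in c("iDNA", "eDNA")) {
      unrep <- libs[[paste0(fr, "_unrepaired")]]
      rep_ <- libs[[paste0(fr, "_repaired")]]
      sub_u <- subset_library(unrep, id)
      sub_r <- subset_library(rep_, id)
      present <- nrow(sub_u$reads) > 0 || nrow(sub_r$reads) > 0
      prof_u <- substitution_profile(sub_u, genomes[id])
      prof_r <- substitution_profile(sub_r, genomes[id])
      prof_u$genome_id <- prof_r$genome_id <- id
      prof_u$library_id <- paste0(fr, "_unrepaired")
      prof_r$library_id <- paste0(fr, "_repaired")
      profiles[[paste(id, fr, "unrepaired", sep = "_")]] <- prof_u
      profiles[[paste(id, fr, "repaired", sep = "_")]] <- prof_r
      cu <- completeness(sub_u, L)
      cr <- completeness(sub_r, L)
      key <- tolower(fr)
      ev[[paste0(key, "_present")]] <- present
      ev[[paste0(key, "_damage")]] <- damage_score(prof_u)
      ev[[paste0(key, "_damage_repaired")]] <- damage_score(prof_r)
      ev[[paste0(key, "_delta")]] <- if (present) cr - cu else NA_real_
      if (present) {
        records[[paste(id, fr)]] <- data.frame(
          bin_id = id, fraction = fr,
          completeness_unrepaired = cu, completeness_repaired = cr,
          mean_depth_unrepaired = mean_depth_of(unrep, id, L),
          mean_depth_repaired = mean_depth_of(rep_, id, L),
          stringsAsFactors = FALSE)
      }
    }
    evidence[[id]] <- as.data.frame(ev, stringsAsFactors = FALSE)
  }
  evidence <- do.call(rbind, evidence)
  records <- if (length(records)) do.call(rbind, records) else NULL
  rownames(evidence) <- NULL
  if (!is.null(records)) rownames(records) <- NULL

  comparison <- if (!is.null(records) && nrow(records) >= 3) {
    tryCatch(repair_gain_regression(records), error = function(e) NULL)
  }

  calls <- classify_assemblage(evidence, config$thresholds)
  assemblage <- summarize_assemblage(calls, truth_vitality)

  growth <- list()
  idna_unrep <- libs$iDNA_unrepaired
  for (id in ids) {
    sub <- subset_library(idna_unrep, id)
    if (nrow(sub$reads) == 0) next
    sp <- pops[[id]]
    prof <- tryCatch(coverage_profile(sub, sp$genome_length, genome_id = id),
                     error = function(e) NULL)
    if (is.null(prof)) next
    growth[[id]] <- grid_index(prof, dnaA_pos = sp$ori_position,
                               dif_pos = sp$ter_position,
                               heterogeneity = config$heterogeneity)
  }

  racem <- if (!is.null(config$racemization)) {
    rz <- config$racemization
    racemization_report(rz$observed, rz$ages,
                        rz$params %||% arrhenius_params(), rz$dl0 %||% 0)
  }

  lib_stats <- lapply(libs, library_stats)

  result <- structure(list(
    config = config, genomes = genomes, libraries = libs,
    profiles = profiles, evidence = evidence,
    completeness_records = records, repair_comparison = comparison,
    calls = calls, assemblage = assemblage, growth = growth,
    racemization = racem, library_stats = lib_stats,
    edna_idna_mass_ratio = unname(pool_mass["eDNA"] / pool_mass["iDNA"]),
    truth_vitality = truth_vitality), class = "scenario_result")

  if (!is.null(out_dir)) {
    write_scenario_outputs(result, out_dir)
  }
  result
}

growth_table <- function(growth) {
  if (!length(growth)) {
    return(data.frame(genome_id = character(0), grid_value = numeric(0),
                      dnaA_ori_ratio = numeric(0), ter_dif_ratio = numeric(0),
                      valid = logical(0)))
  }
  data.frame(genome_id = names(growth),
             grid_value = vapply(growth, `[[`, numeric(1), "grid_value"),
             dnaA_ori_ratio = vapply(growth, `[[`, numeric(1), "dnaA_ori_ratio"),
             ter_dif_ratio = vapply(growth, `[[`, numeric(1), "ter_dif_ratio"),
             valid = vapply(growth, `[[`, logical(1), "valid"),
             row.names = NULL, stringsAsFactors = FALSE)
}

write_scenario_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop("scenario output failed (partial files removed): ",
         conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    p <- function(...) {
      fp <- file.path(out_dir, paste0(...))
      written <<- c(written, fp)
      fp
    }
    write_fasta(result$genomes, p("references.fasta"))
    for (lib in result$libraries) {
      idb <- lib$spec$library_id
      write_fastq(lib, p(idb, ".fastq"))
      write_sam(lib, p(idb, ".sam"))
      write_tsv(lib$truth, p(idb, "_truth.tsv"))
    }
    prof_tab <- do.call(rbind, lapply(result$profiles, function(pr) {
      cbind(genome_id = pr$genome_id, library_id = pr$library_id,
            profile_table(pr))
    }))
    write_tsv(prof_tab, p("damage_profiles.tsv"))
    write_tsv(result$evidence, p("evidence.tsv"))
    write_tsv(result$calls, p("calls.tsv"))
    if (!is.null(result$completeness_records)) {
      write_tsv(result$completeness_records, p("completeness_records.tsv"))
    }
    if (!is.null(result$racemization)) {
      write_tsv(result$racemization, p("racemization.tsv"))
    }
    write_tsv(growth_table(result$growth), p("growth_index.tsv"))
    if (!is.null(result$repair_comparison)) {
      cmpj <- result$repair_comparison
      jsonlite::write_json(
        list(slope = cmpj$slope, intercept = cmpj$intercept,
             pearson_r = cmpj$pearson_r, n_bins = cmpj$n_bins,
             mean_delta = cmpj$mean_delta,
             per_bin_delta = as.list(cmpj$per_bin_delta)),
        p("repair_comparison.json"), auto_unbox = TRUE, digits = NA)
    }
    manifest_path <- file.path(out_dir, "manifest.json")
    files <- setdiff(list.files(out_dir, full.names = TRUE), manifest_path)
    manifest <- list(
      seed = result$config$seed,
      n_populations = length(result$config$populations),
      n_libraries = length(result$libraries),
      checksums = as.list(setNames(unname(tools::md5sum(files)),
                                   basename(files))))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA)
    written <<- c(written, manifest_path)
  }, error = on_fail)
  invisible(out_dir)
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %d populations, %d libraries, seed %d\n",
              length(x$config$populations), length(x$libraries),
              x$config$seed))
  cat("  calls:\n")
  for (i in seq_len(nrow(x$calls))) {
    cat(sprintf("    %-15s -> %s (truth: %s)\n", x$calls$bin_id[i],
                x$calls$label[i], x$truth_vitality[x$calls$bin_id[i]]))
  }
  if (!is.null(x$assemblage$accuracy)) {
    cat(sprintf("  vitality->label accuracy: %.2f\n", x$assemblage$accuracy))
  }
  if (!is.null(x$repair_comparison)) {
    cat(sprintf("  repair regression: slope %.3f, r %.3f, mean delta %+.4f\n",
                x$repair_comparison$slope, x$repair_comparison$pearson_r,
                x$repair_comparison$mean_delta))
  }
  cat(sprintf("  eDNA/iDNA mass ratio: %.3f\n", x$edna_idna_mass_ratio))
  invisible(x)
}
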