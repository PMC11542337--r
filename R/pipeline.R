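#' Screen configuration
#'
#' Single configuration object driving both halves of the pipeline (growth
#' screen and high-content analysis). All randomness in a run flows from
#' \code{seed}, split deterministically per stage.
#'
#' @param drugs List of \code{drug_spec}s (default the packaged 12-drug
#'   panel).
#' @param interactions List of \code{interaction_spec}s.
#' @param c1,fold,n_doses Equimolar dilution design (top dose uM, fold
#'   factor, dose count).
#' @param n_replicates Replicates per condition.
#' @param x0 Seeded cells per well.
#' @param growth_doublings Control doublings over the assay.
#' @param noise_cv Count noise coefficient of variation.
#' @param dss_t Minimum activity level for the sensitivity score (percent).
#' @param cutoffs Synergy cutoffs (\code{ci_max}, \code{eob_min},
#'   \code{ddss_min} on the 0-1 score scale).
#' @param cs_threshold Confidence threshold for dominance calls.
#' @param n_cells_per_well Cells sampled per treatment for the high-content
#'   branch.
#' @param timepoints_h Endpoint(s) in hours; high-content timepoints are
#'   analyzed independently.
#' @param seed Root integer seed.
#' @return List of class \code{screen_config}.
#' @export
screen_config <- function(drugs = default_screen_drugs(),
                          interactions = list(),
                          c1 = 10, fold = 3.5, n_doses = 6L,
                          n_replicates = 4L, x0 = 3000,
                          growth_doublings = 3, noise_cv = 0.05,
                          dss_t = 10,
                          cutoffs = list(ci_max = 1, eob_min = 0,
                                         ddss_min = 0),
                          cs_threshold = 0.9,
                          n_cells_per_well = 300L,
                          timepoints_h = 72, seed = 1L) {
  doses <- make_dilution_series(c1, n_doses, fold)
  stopifnot(n_replicates >= 1, noise_cv >= 0,
            cs_threshold > 0, cs_threshold <= 1)
  structure(list(drugs = drugs, interactions = interactions, doses = doses,
                 n_replicates = n_replicates, x0 = x0,
                 growth_doublings = growth_doublings, noise_cv = noise_cv,
                 dss_t = dss_t, cutoffs = cutoffs,
                 cs_threshold = cs_threshold,
                 n_cells_per_well = n_cells_per_well,
                 timepoints_h = timepoints_h, seed = as.integer(seed)),
            class = "screen_config")
}

# deterministic per-stage seed derivation, kept within 32-bit range
stage_seed <- function(seed, stage) {
  # double arithmetic: products stay exact below 2^53 before the modulo
  as.integer((as.numeric(seed) * 7919 + as.numeric(stage) * 104729) %%
               2147483647)
}

#' Run the growth-based synergy screen
#'
#' Simulates (or accepts) an equimolar plate, computes per-condition mean
#' growth rates, scores every pair (EOB sums, Loewe CI, DSS triple and
#' delta DSS), classifies synergy at the configured cutoffs, and summarizes
#' the Venn counts across the three methods. Re-running with the same
#' config reproduces the outputs exactly.
#'
#' @param cfg A \code{screen_config}.
#' @param plate Optional pre-existing tidy plate table; simulated from the
#'   config when NULL.
#' @return List of class \code{synergy_report}: \code{plate},
#'   \code{gr_table}, \code{records} (per-pair scores and flags),
#'   \code{venn}, \code{config}.
#' @export
run_synergy_screen <- function(cfg, plate = NULL) {
  stopifnot(inherits(cfg, "screen_config"))
  if (is.null(plate))
    plate <- simulate_plate(cfg$drugs, cfg$interactions, cfg$doses,
                            n_replicates = cfg$n_replicates, x0 = cfg$x0,
                            growth_doublings = cfg$growth_doublings,
                            noise_cv = cfg$noise_cv,
                            timepoint_h = cfg$timepoints_h[1],
                            seed = stage_seed(cfg$seed, 1L))
  gr <- gr_table(plate)
  records <- synergy_screen(plate, dss_t = cfg$dss_t, cutoffs = cfg$cutoffs)
  venn <- venn_counts(
    data.frame(ci = records$ci, eob_sum = records$eob_sum_all,
               ddss = records$ddss),
    cutoffs = cfg$cutoffs)
  structure(list(plate = plate, gr_table = gr, records = records,
                 venn = venn, config = cfg),
            class = "synergy_report")
}

simulate_hc_tables <- function(cfg, timepoint) {
  registry <- hc_feature_registry()
  drugs <- cfg$drugs
  names(drugs) <- vapply(drugs, function(d) d$name, character(1))
  n_doses <- length(cfg$doses)
  # dose scaling of the phenotype follows the drug's own inhibition curve
  scaling <- function(spec, i) hill_inhibition(cfg$doses[i], spec)
  seed0 <- stage_seed(cfg$seed, 2L + match(timepoint, cfg$timepoints_h))
  counter <- 0L
  nxt <- function() {
    counter <<- counter + 1L
    (seed0 + counter) %% 2147483647L
  }
  tables <- list()
  tables[["DMSO"]] <- simulate_feature_table(
    "DMSO", cfg$n_cells_per_well, shift = numeric(length(registry)),
    registry = registry, seed = nxt())
  for (rep in seq_len(cfg$n_replicates)) {
    for (d in drugs) for (i in seq_len(n_doses)) {
      id <- sprintf("%s|C%d|r%d", d$name, i, rep)
      tables[[id]] <- simulate_feature_table(
        id, cfg$n_cells_per_well, shift = d$phenotype_shift,
        dose_scaling = scaling(d, i), registry = registry, seed = nxt())
    }
    nm <- names(drugs)
    for (a in seq_len(length(nm) - 1L)) for (b in (a + 1L):length(nm)) {
      da <- drugs[[a]]; db <- drugs[[b]]
      for (i in seq_len(n_doses)) {
        # combination phenotype: inhibition-weighted blend of the two
        # components' shifts, so the stronger phenotype dominates
        wa <- scaling(da, i) * sqrt(sum(da$phenotype_shift^2))
        wb <- scaling(db, i) * sqrt(sum(db$phenotype_shift^2))
        tot <- wa + wb
        mix <- if (tot == 0) numeric(length(registry)) else
          (wa * da$phenotype_shift * scaling(da, i) +
             wb * db$phenotype_shift * scaling(db, i)) / tot
        id <- sprintf("%s+%s|C%d|r%d", da$name, db$name, i, rep)
        tables[[id]] <- simulate_feature_table(
          id, cfg$n_cells_per_well, shift = mix, dose_scaling = 1,
          registry = registry, seed = nxt())
      }
    }
  }
  tables
}

#' Run the high-content dominance analysis
#'
#' Builds (or accepts) per-cell feature tables for every treatment,
#' converts them to signed KS profiles against vehicle control, fits the
#' shrinkage LDA on the single-drug profiles at the second-highest dose
#' (C2), assigns each combination profile its nearest single-drug class,
#' scores assignment confidence, and calls dominance categories and
#' per-class statistics. Timepoints are analyzed independently.
#'
#' @param cfg A \code{screen_config}.
#' @param feature_tables Optional named list of per-cell feature tables
#'   (names \code{"DMSO"}, \code{"DRUG|Ci|rj"},
#'   \code{"A+B|Ci|rj"}); simulated from the config when NULL.
#' @param timepoint Timepoint to analyze (default the first configured).
#' @return List of class \code{hc_report}: \code{profiles} (matrix),
#'   \code{profile_meta}, \code{lda}, \code{calls}, \code{statistics},
#'   \code{statistics_all}, \code{config}.
#' @export
run_hc_analysis <- function(cfg, feature_tables = NULL,
                            timepoint = cfg$timepoints_h[1]) {
  stopifnot(inherits(cfg, "screen_config"))
  if (is.null(feature_tables))
    feature_tables <- simulate_hc_tables(cfg, timepoint)
  if (!"DMSO" %in% names(feature_tables))
    stop("missing vehicle control: feature_tables must include 'DMSO'")
  registry <- hc_feature_registry()
  control <- feature_tables[["DMSO"]]
  ids <- setdiff(names(feature_tables), "DMSO")
  profs <- t(vapply(ids, function(id)
    as.numeric(ks_profile(feature_tables[[id]], control, registry)),
    numeric(length(registry))))
  colnames(profs) <- registry

  meta <- do.call(rbind, lapply(strsplit(ids, "|", fixed = TRUE),
                                function(p)
    data.frame(treatment = p[1], dose = p[2], replicate = p[3],
               stringsAsFactors = FALSE)))
  meta$is_combo <- grepl("+", meta$treatment, fixed = TRUE)
  drug_class <- stats::setNames(
    vapply(cfg$drugs, function(d) d$drug_class, character(1)),
    vapply(cfg$drugs, function(d) d$name, character(1)))

  train <- which(!meta$is_combo & meta$dose == "C2")
  model <- lda_fit(profs[train, , drop = FALSE],
                   drug_class[meta$treatment[train]],
                   shrinkage = 0.5, ids = ids[train])
  pools <- training_distance_pools(model)

  refs_idx <- which(!meta$is_combo)
  refs <- lda_transform(model, profs[refs_idx, , drop = FALSE])
  ref_ids <- ids[refs_idx]
  ref_classes <- unname(drug_class[meta$treatment[refs_idx]])

  combo_idx <- which(meta$is_combo)
  calls <- lapply(combo_idx, function(i) {
    comp <- strsplit(meta$treatment[i], "+", fixed = TRUE)[[1]]
    q <- lda_transform(model, profs[i, ])[1, ]
    cl <- dominance_call(q, comp, unname(drug_class[comp]),
                         refs, ref_ids, ref_classes,
                         pools$same, pools$diff,
                         cs_threshold = cfg$cs_threshold)
    cl$treatment <- meta$treatment[i]
    cl$dose <- meta$dose[i]
    cl$replicate <- meta$replicate[i]
    cl
  })
  structure(list(profiles = profs, profile_meta = meta, lda = model,
                 calls = calls,
                 statistics = dominance_statistics(calls,
                                                   cfg$cs_threshold),
                 statistics_all = dominance_statistics(calls),
                 timepoint = timepoint, config = cfg),
            class = "hc_report")
}

#' @export
print.synergy_report <- function(x, ...) {
  cat("Equimolar synergy screen:", nrow(x$records), "pairs,",
      length(unique(x$gr_table$drug_a[is.na(x$gr_table$drug_b) &
                                        x$gr_table$dose_a_uM > 0])),
      "single drugs\n")
  cat(sprintf("Venn: Loewe %d | Bliss %d | AUC %d | all three %d\n",
              x$venn["loewe"], x$venn["bliss"], x$venn["auc"],
              x$venn["all_three"]))
  invisible(x)
}

#' @export
print.hc_report <- function(x, ...) {
  cats <- table(vapply(x$calls, `[[`, character(1), "category"))
  cat("High-content dominance analysis:", length(x$calls), "calls\n")
  print(cats)
  invisible(x)
}
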