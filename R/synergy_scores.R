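#' Excess over Bliss independence from growth rates
#'
#' EOB = (1 - GRcom) - (1 - GRa) - (1 - GRb) + (1 - GRa)(1 - GRb): the
#' observed combined inhibition minus the Bliss product-rule prediction on
#' the (1 - GR) scale. Positive values indicate synergy, negative values
#' antagonism. The same expression applies with relative growth (RG) in
#' place of GR, where it reduces to RGa RGb - RGcom. No clamping is applied
#' (1 - GR may exceed 1 under net kill); set \code{clamp = TRUE} to restrict
#' the inhibitions to [0, 1] first.
#'
#' @param gr_com,gr_a,gr_b Growth rates of the combination and the two
#'   single agents (vectorized).
#' @param clamp Clamp the three (1 - GR) terms to [0, 1] before combining.
#' @return Signed excess over Bliss.
#' @export
eob <- function(gr_com, gr_a, gr_b, clamp = FALSE) {
  ic <- 1 - gr_com; ia <- 1 - gr_a; ib <- 1 - gr_b
  if (clamp) {
    ic <- pmin(pmax(ic, 0), 1); ia <- pmin(pmax(ia, 0), 1)
    ib <- pmin(pmax(ib, 0), 1)
  }
  ic - ia - ib + ia * ib
}

#' Summed excess over Bliss across the dilution series
#'
#' @param eob_per_dose Numeric vector of per-dose EOB values ordered C1
#'   (highest dose) to C6 (lowest).
#' @return Named list with \code{high3} (sum over C1-C3), \code{low3} (sum
#'   over C4-C6), and \code{all}.
#' @export
eob_sums <- function(eob_per_dose) {
  if (length(eob_per_dose) != 6)
    stop("expected 6 dose levels ordered C1 (highest) to C6 (lowest)")
  list(high3 = sum(eob_per_dose[1:3]), low3 = sum(eob_per_dose[4:6]),
       all = sum(eob_per_dose))
}

#' Loewe combination index
#'
#' CI = IC50_a(a+b) / IC50_a + IC50_b(a+b) / IC50_b, the sum of
#' dose-reduction ratios of each component at the combination's half-maximal
#' effect. CI < 1 indicates synergy; a sham combination (a drug with itself)
#' gives CI = 1. In the equimolar design the combination series is fit once
#' on the per-component dose axis, so its IC50 serves as both combination
#' IC50s.
#'
#' @param ic50_a_comb,ic50_b_comb IC50s (uM) of drugs A and B within the
#'   combination.
#' @param ic50_a,ic50_b Single-agent IC50s (uM).
#' @return CI, or \code{NA_real_} when any input IC50 is undefined.
#' @export
loewe_ci <- function(ic50_a_comb, ic50_a, ic50_b_comb, ic50_b) {
  if (anyNA(c(ic50_a_comb, ic50_a, ic50_b_comb, ic50_b))) return(NA_real_)
  if (any(c(ic50_a_comb, ic50_a, ic50_b_comb, ic50_b) <= 0))
    stop("IC50s must be positive")
  ic50_a_comb / ic50_a + ic50_b_comb / ic50_b
}

#' Classify a combination's synergy flags
#'
#' Applies the three-method rule: Loewe-synergistic when CI < \code{ci_max},
#' Bliss-synergistic when the summed EOB exceeds \code{eob_min}, and
#' AUC-synergistic when the delta sensitivity score exceeds
#' \code{ddss_min}; \code{all_three} is their conjunction. All inequalities
#' are strict; an undefined CI fails the Loewe criterion. The defaults (1,
#' 0, 0) give the permissive rule; stricter published cutoffs (e.g. CI <
#' 0.6 with EOB > 0.2) are reachable through the arguments.
#'
#' @param ci Combination index (may be NA).
#' @param eob_sum_all Summed EOB across all doses.
#' @param ddss Delta drug sensitivity score on the same scale as
#'   \code{ddss_min}.
#' @param cutoffs Named list with \code{ci_max}, \code{eob_min},
#'   \code{ddss_min}.
#' @return Named logical vector: \code{loewe_synergistic,
#'   bliss_synergistic, auc_synergistic, all_three}.
#' @export
classify_synergy <- function(ci, eob_sum_all, ddss,
                             cutoffs = list(ci_max = 1, eob_min = 0,
                                            ddss_min = 0)) {
  loewe <- !is.na(ci) & ci < cutoffs$ci_max
  bliss <- !is.na(eob_sum_all) & eob_sum_all > cutoffs$eob_min
  auc <- !is.na(ddss) & ddss > cutoffs$ddss_min
  c(loewe_synergistic = loewe, bliss_synergistic = bliss,
    auc_synergistic = auc, all_three = loewe & bliss & auc)
}

#' Venn counts of synergistic combinations
#'
#' Counts combinations called synergistic by each of the three methods and
#' by all three jointly, given per-pair scores.
#'
#' @param records \code{data.frame} with columns \code{ci},
#'   \code{eob_sum} (or \code{eob_sum_all}), and \code{ddss} (or
#'   \code{ddss_pct}).
#' @param cutoffs As in \code{\link{classify_synergy}}; \code{ddss_min} is
#'   interpreted on the same scale as the ddss column.
#' @return Named integer vector: \code{loewe, bliss, auc, all_three}.
#' @export
venn_counts <- function(records,
                        cutoffs = list(ci_max = 1, eob_min = 0,
                                       ddss_min = 0)) {
  eobcol <- if ("eob_sum_all" %in% names(records)) "eob_sum_all" else "eob_sum"
  ddsscol <- if ("ddss" %in% names(records)) "ddss" else "ddss_pct"
  flags <- t(mapply(function(ci, e, d)
    classify_synergy(ci, e, d, cutoffs),
    records$ci, records[[eobcol]], records[[ddsscol]]))
  counts <- colSums(flags)
  c(loewe = unname(counts["loewe_synergistic"]),
    bliss = unname(counts["bliss_synergistic"]),
    auc = unname(counts["auc_synergistic"]),
    all_three = unname(counts["all_three"]))
}

#' Load the packaged pairwise synergy score matrix
#'
#' A transcription of the published 66-pair score table (CI by Loewe
#' additivity, summed EOB by Bliss independence, delta DSS in percent by the
#' AUC method) for a 12-drug, 6-class screen, shipped as a plain-text
#' fixture. The \code{paper_flag} column carries the published per-pair
#' synergy annotation: "a" = synergistic by all three methods, "b" = by EOB
#' and delta DSS, "c" = by CI and delta DSS.
#'
#' @return \code{data.frame} with 66 rows.
#' @export
load_reference_scores <- function() {
  path <- system.file("extdata", "pairwise_synergy_scores.csv",
                      package = "synscreen", mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$paper_flag[is.na(out$paper_flag)] <- ""
  out
}

#' Checkerboard excess-over-Bliss matrix
#'
#' Computes EOB for every cell of a dose-matrix (checkerboard) relative
#' growth surface. The input matrix must include the single-agent margins:
#' row 1 is drug B alone across its doses, column 1 is drug A alone, and
#' cell (1, 1) the vehicle (RG = 1). EOB(i, j) = RGa(i) RGb(j) - RGcom(i,
#' j), so margins have EOB 0 against themselves and positive entries mark
#' synergy.
#'
#' @param rg_matrix Numeric matrix of relative growth, rows indexed by drug
#'   A dose (first row dose 0), columns by drug B dose (first column dose 0).
#' @param dose_a,dose_b Optional dose vectors (first element 0) used for
#'   dimnames.
#' @return List of class \code{checkerboard_eob} with \code{rg_matrix} and
#'   \code{eob_matrix}.
#' @export
checkerboard_eob <- function(rg_matrix, dose_a = NULL, dose_b = NULL) {
  if (!is.matrix(rg_matrix)) stop("rg_matrix must be a matrix")
  if (!is.null(dose_a) && dose_a[1] != 0 || !is.null(dose_b) && dose_b[1] != 0)
    stop("missing margin: first dose of each axis must be 0 (single agents)")
  if (abs(rg_matrix[1, 1] - 1) > 0.2)
    warning("vehicle cell (1,1) of the RG matrix is far from 1")
  rg_a <- rg_matrix[, 1]   # drug A alone down the rows
  rg_b <- rg_matrix[1, ]   # drug B alone across the columns
  eob_m <- outer(rg_a, rg_b) - rg_matrix
  if (!is.null(dose_a)) rownames(eob_m) <- rownames(rg_matrix) <- dose_a
  if (!is.null(dose_b)) colnames(eob_m) <- colnames(rg_matrix) <- dose_b
  structure(list(rg_matrix = rg_matrix, eob_matrix = eob_m),
            class = "checkerboard_eob")
}

#' Score every pair of an equimolar screen
#'
#' Full synergy analysis of a plate: per-condition mean growth rates, 4PL
#' fits of every single drug and every equimolar pair on the per-component
#' dose axis, then per-pair EOB sums, Loewe CI, DSS triple and delta DSS,
#' and the three-method synergy flags.
#'
#' @param plate Tidy plate table (see \code{\link{simulate_plate}}).
#' @param dss_t Minimum activity level for the sensitivity score (percent).
#' @param scale Response scale for the 4PL fits: \code{"log2"} (default)
#'   fits percent growth-rate inhibition via \code{\link{gr_inhibition}},
#'   under which a Hill-type growth-rate inhibition is an exact 4PL with
#'   midpoint at the true IC50; \code{"linear"} fits the affine map
#'   \code{\link{inhibition_from_gr}}.
#' @param cutoffs Synergy cutoffs passed to \code{\link{classify_synergy}}
#'   (\code{ddss_min} on the 0-1 score scale).
#' @param outlier_filter Apply the replicate outlier rule.
#' @return \code{data.frame} with one row per pair: EOB per-dose sums, CI,
#'   IC50s, DSS scores, delta DSS, and logical flag columns.
#' @export
synergy_screen <- function(plate, dss_t = 10,
                           cutoffs = list(ci_max = 1, eob_min = 0,
                                          ddss_min = 0),
                           outlier_filter = TRUE,
                           scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  to_inh <- if (scale == "log2") gr_inhibition else inhibition_from_gr
  gr <- gr_table(plate, outlier_filter = outlier_filter)
  gr <- gr[gr$dose_a_uM > 0, ]
  singles <- gr[is.na(gr$drug_b), ]
  combos <- gr[!is.na(gr$drug_b), ]
  doses <- sort(unique(singles$dose_a_uM), decreasing = TRUE)
  cfg <- dss_config(t = dss_t, cmin = log10(min(doses)),
                    cmax = log10(max(doses)))

  fit_one <- function(sub) {
    sub <- sub[order(sub$dose_a_uM), ]
    fit_4pl(log10(sub$dose_a_uM), to_inh(sub$gr_mean))
  }
  single_fit <- lapply(split(singles, singles$drug_a), fit_one)
  single_gr <- function(drug, dose) {
    m <- singles[singles$drug_a == drug & singles$dose_a_uM == dose, ]
    if (nrow(m) != 1) NA_real_ else m$gr_mean
  }

  pairs <- unique(combos[, c("drug_a", "drug_b")])
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    a <- pairs$drug_a[k]; b <- pairs$drug_b[k]
    sub <- combos[combos$drug_a == a & combos$drug_b == b, ]
    sub <- sub[order(-sub$dose_a_uM), ]
    eob_d <- vapply(seq_len(nrow(sub)), function(i)
      eob(sub$gr_mean[i], single_gr(a, sub$dose_a_uM[i]),
          single_gr(b, sub$dose_b_uM[i])), numeric(1))
    sums <- if (length(eob_d) == 6) eob_sums(eob_d) else
      list(high3 = NA_real_, low3 = NA_real_, all = sum(eob_d))

    comb_fit <- fit_one(sub)
    fa <- single_fit[[a]]; fb <- single_fit[[b]]
    ic_comb <- ic50(comb_fit); ic_a <- ic50(fa); ic_b <- ic50(fb)
    ci <- loewe_ci(ic_comb, ic_a, ic_comb, ic_b)
    d_a <- dss(fa, cfg); d_b <- dss(fb, cfg); d_c <- dss(comb_fit, cfg)
    dd <- delta_dss(d_c, d_a, d_b)
    flags <- classify_synergy(ci, sums$all, dd, cutoffs)
    data.frame(drug_a = a, drug_b = b,
               eob_sum_high3 = sums$high3, eob_sum_low3 = sums$low3,
               eob_sum_all = sums$all, ci = ci,
               ic50_a = ic_a, ic50_b = ic_b, ic50_comb = ic_comb,
               dss_a = d_a, dss_b = d_b, dss_comb = d_c, ddss = dd,
               loewe_synergistic = flags[["loewe_synergistic"]],
               bliss_synergistic = flags[["bliss_synergistic"]],
               auc_synergistic = flags[["auc_synergistic"]],
               all_three = flags[["all_three"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
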