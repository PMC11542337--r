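#' Normalized growth rate from a count triplet
#'
#' GR = 2^(log2(Xc/Xo) / log2(Xdc/Xo)) - 1, where \code{xc} is the endpoint
#' count under drug, \code{xo} the shared pre-treatment count, and
#' \code{xdc} the endpoint count of vehicle-treated wells. GR = 1 means
#' untreated growth, 0 cytostasis, and -1 complete kill. Counts of zero are
#' floored to 1 with a warning (the log of zero is undefined; screens report
#' counts down to single digits).
#'
#' @param xc,xo,xdc Positive cell counts (vectorized over \code{xc}).
#' @return Growth rate value(s) in [-1, Inf), practically [-1, ~1].
#' @examples
#' growth_rate(500, 250, 1000)  # 2^0.5 - 1
#' @export
growth_rate <- function(xc, xo, xdc) {
  if (any(xc == 0)) {
    warning("zero counts floored to 1 before GR")
    xc <- pmax(xc, 1)
  }
  if (any(c(xc, xo, xdc) <= 0)) stop("counts must be positive")
  if (any(xdc == xo)) stop("undefined normalizer: control did not grow (Xdc = Xo)")
  2^(log2(xc / xo) / log2(xdc / xo)) - 1
}

#' Relative growth from a luminescence triplet
#'
#' RG = (LSd - LSm) / (LSc - LSm): 1 for vehicle-level signal, 0 for
#' blank-medium-level signal.
#'
#' @param ls_d Signal of the drug-treated wells (vectorized).
#' @param ls_m Signal of blank medium.
#' @param ls_c Signal of vehicle-treated wells.
#' @return Relative growth fraction(s).
#' @export
relative_growth <- function(ls_d, ls_m, ls_c) {
  if (any(ls_c <= ls_m))
    stop("degenerate control: vehicle signal must exceed blank medium")
  (ls_d - ls_m) / (ls_c - ls_m)
}

#' Replicate outlier filter
#'
#' Removes at most one replicate: the most deviant one, and only if it
#' diverges from the replicate mean by more than one sample standard
#' deviation (computed over all replicates, candidate included). The rule is
#' applied once and does not iterate, so it is idempotent.
#'
#' @param counts Numeric vector of replicate measurements (length >= 3).
#' @return List with \code{kept} (the retained values) and \code{removed}
#'   (integer index of the removed replicate, or \code{integer(0)}).
#' @export
filter_outlier_replicates <- function(counts) {
  if (length(counts) < 3)
    stop("insufficient replicates: outlier rule needs >= 3")
  dev <- abs(counts - mean(counts))
  s <- stats::sd(counts)
  worst <- which.max(dev)
  if (s > 0 && dev[worst] > s)
    list(kept = counts[-worst], removed = worst)
  else
    list(kept = counts, removed = integer(0))
}

#' Per-condition growth-rate table
#'
#' Collapses a tidy plate table (as produced by \code{\link{simulate_plate}}
#' or read from CSV) to mean growth rate per treatment condition. The
#' pre-treatment count Xo is the mean of the time-zero wells; Xdc is the
#' mean endpoint vehicle count (after outlier filtering). Within each
#' condition the replicate outlier rule is applied to the raw counts, GR is
#' computed per surviving replicate, and the mean and SD are reported.
#'
#' @param plate Plate \code{data.frame} with columns \code{drug_a,
#'   dose_a_uM, drug_b, dose_b_uM, timepoint_h, replicate, count}.
#' @param outlier_filter Apply the one-replicate outlier rule (default TRUE;
#'   skipped automatically for conditions with < 3 replicates).
#' @return \code{data.frame} with one row per (drug_a, dose_a, drug_b,
#'   dose_b, timepoint) and columns \code{gr_mean, gr_sd,
#'   n_replicates_used, outliers_removed}.
#' @export
gr_table <- function(plate, outlier_filter = TRUE) {
  t0 <- plate[plate$timepoint_h == 0, ]
  if (nrow(t0) == 0) stop("missing control: no time-zero wells in plate")
  xo <- mean(t0$count)
  end <- plate[plate$timepoint_h > 0, ]
  veh <- end[end$drug_a == "DMSO" | end$dose_a_uM == 0, ]
  if (nrow(veh) == 0) stop("missing control: no vehicle wells in plate")

  key <- function(df) paste(df$drug_a, df$dose_a_uM,
                            ifelse(is.na(df$drug_b), "", df$drug_b),
                            ifelse(is.na(df$dose_b_uM), 0, df$dose_b_uM),
                            df$timepoint_h, sep = "\r")
  xdc_counts <- veh$count
  if (outlier_filter && length(xdc_counts) >= 3)
    xdc_counts <- filter_outlier_replicates(xdc_counts)$kept
  xdc <- mean(xdc_counts)

  groups <- split(end, key(end))
  out <- lapply(groups, function(g) {
    counts <- g$count
    removed <- 0L
    if (outlier_filter && length(counts) >= 3) {
      f <- filter_outlier_replicates(counts)
      counts <- f$kept
      removed <- length(f$removed)
    }
    gr <- growth_rate(counts, xo, xdc)
    data.frame(drug_a = g$drug_a[1], dose_a_uM = g$dose_a_uM[1],
               drug_b = g$drug_b[1], dose_b_uM = g$dose_b_uM[1],
               timepoint_h = g$timepoint_h[1],
               gr_mean = mean(gr), gr_sd = stats::sd(gr),
               n_replicates_used = length(counts),
               outliers_removed = removed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$drug_a, out$drug_b, -out$dose_a_uM), ]
}
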