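#' Map growth rate to percent inhibition
#'
#' Affine adapter from the growth-rate scale to the 0-100 percent inhibition
#' scale the sensitivity-score normalization presumes: GR = 1 (untreated
#' growth) maps to 0 percent, GR = -1 (complete kill) to 100 percent, GR = 0
#' (cytostasis) to 50 percent. Output is clamped to [0, 100].
#'
#' @param gr Growth rate value(s).
#' @return Percent inhibition in [0, 100].
#' @export
inhibition_from_gr <- function(gr) {
  if (any(!is.finite(gr))) stop("gr must be finite")
  pmin(pmax(50 * (1 - gr), 0), 100)
}

#' Growth-rate inhibition percentage
#'
#' Logarithmic adapter from growth rate to percent inhibition of growth:
#' 100 (1 - log2(1 + GR)), clamped to [0, 100]. GR = 1 (untreated growth)
#' maps to 0 percent and GR = 0 (cytostasis) to 100 percent: on this scale
#' a cytostatic dose fully inhibits growth, and net kill (GR < 0) saturates
#' at 100. Because GR = 2^(g_drug/g_control) - 1, this recovers the
#' fractional reduction of the exponential growth rate itself, so a
#' Hill-type inhibition of the growth rate appears as an exact
#' four-parameter logistic in log dose with midpoint at the true IC50 --
#' the scale the screen fits by default.
#'
#' @param gr Growth rate value(s), > -1 for a finite log (values at or
#'   below -1 clamp to 100).
#' @return Percent growth-rate inhibition in [0, 100].
#' @export
gr_inhibition <- function(gr) {
  if (any(!is.finite(gr))) stop("gr must be finite")
  out <- ifelse(gr <= -1 + 1e-12, 100, 100 * (1 - log2(1 + gr)))
  pmin(pmax(out, 0), 100)
}

# numerically stable log10(1 + 10^z)
log1p10 <- function(z) {
  ifelse(z > 0, z + log1p(10^(-z)) / log(10), log1p(10^z) / log(10))
}

fourpl_curve <- function(x, a, b, c, d) d + (a - d) / (1 + 10^(b * (c - x)))

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of y = d + (a - d) / (1 + 10^(b (c - x))) with x the
#' log10 dose (uM) and y the percent inhibition: a is the maximal response,
#' d the minimal response, b the (positive) slope, and c the log10 IC50.
#' Levenberg-Marquardt with box constraints keeps b > 0 so inhibition
#' increases with dose (canonical orientation, avoiding the (a, d)-swap
#' degeneracy). Initialization: a = max(y), d = min(y), b = 1, c at the dose
#' whose response is nearest the midpoint. Degenerate inputs (e.g. flat
#' responses) return a best-effort fit flagged \code{converged = FALSE}.
#'
#' @param x Numeric vector of log10 doses; at least 4 distinct values.
#' @param y Responses (percent inhibition), same length as x.
#' @param weights Optional non-negative case weights.
#' @return Object of class \code{fourpl_fit}: list with elements \code{a, b,
#'   c, d, rss, converged, x_range}.
#' @export
fit_4pl <- function(x, y, weights = NULL) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 4)
    stop("insufficient data: need >= 4 distinct doses")
  if (is.null(weights)) weights <- rep(1, length(x))
  x_range <- range(x)

  mid <- (max(y) + min(y)) / 2
  span <- max(diff(range(y)), 1e-8)
  sw <- sqrt(weights)
  # parameter vector ordered (a, d, b, c)
  resid_fn <- function(p) sw * (y - fourpl_curve(x, p[1], p[3], p[4], p[2]))
  lower <- c(min(y) - span, min(y) - span, 1e-3, x_range[1] - 3)
  upper <- c(max(y) + span, max(y) + span, 20, x_range[2] + 3)

  # Levenberg-Marquardt from a small start grid; the 4PL surface has flat
  # degenerate ridges (b -> 0) that can trap a single start
  c0s <- unique(c(x[which.min(abs(y - mid))], stats::median(x)))
  best <- NULL
  for (c0 in c0s) for (b0 in c(0.5, 1, 2)) {
    p0 <- pmin(pmax(c(max(y), min(y), b0, c0), lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(par = fit$par, rss = rss,
                   converged = fit$info %in% 1:4)
  }
  if (is.null(best)) {
    # best-effort fallback (pathological series)
    p <- c(mean(y), mean(y), 1e-3, mean(x_range))
    best <- list(par = p, rss = sum(resid_fn(p)^2), converged = FALSE)
  }
  p <- best$par
  structure(list(a = p[1], b = p[3], c = p[4], d = p[2],
                 rss = best$rss,
                 converged = isTRUE(best$converged) && p[1] >= p[2],
                 x_range = x_range),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf(
    "4PL fit: a=%.3f d=%.3f b=%.3f c=%.3f (IC50=%.4g uM) rss=%.4g%s\n",
    x$a, x$d, x$b, x$c, 10^x$c, x$rss,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Relative IC50 from a 4PL fit
#'
#' Returns 10^c, the dose at the curve midpoint (relative IC50, the common
#' nonlinear-regression default). Flagged undefined (NA) when the fit did
#' not converge, the fitted span a - d is below \code{min_span} percent, or
#' c falls more than one log10 unit outside the fitted dose range.
#'
#' @param fit A \code{fourpl_fit}.
#' @param min_span Minimal response span (percent) for a defined IC50.
#' @return IC50 in uM, or \code{NA_real_} when undefined.
#' @export
ic50 <- function(fit, min_span = 10) {
  if (!fit$converged) return(NA_real_)
  if ((fit$a - fit$d) < min_span) return(NA_real_)
  if (fit$c < fit$x_range[1] - 1 || fit$c > fit$x_range[2] + 1)
    return(NA_real_)
  10^fit$c
}

#' Effective concentration at a response fraction
#'
#' Closed-form inverse of the fitted curve: the dose at which the response
#' reaches d + p (a - d), i.e. x = c - log10(1/p - 1) / b. EC50 (p = 0.5)
#' coincides with the relative IC50.
#'
#' @param fit A \code{fourpl_fit}.
#' @param p Response fraction in (0, 1).
#' @return Concentration in uM.
#' @export
ecp <- function(fit, p) {
  if (p <= 0 || p >= 1) stop("p must lie strictly between 0 and 1")
  10^(fit$c - log10(1 / p - 1) / fit$b)
}

#' Closed-form area under a 4PL curve
#'
#' Integrates y(x) between log10 doses x1 and x2 using the antiderivative
#' Y(x) = (a - d) log10(1 + 10^(b (c - x))) / b + a x, returning
#' Y(x2) - Y(x1) in percent x log10(uM) units. Agrees with adaptive
#' quadrature of the curve to near machine precision. For a flat fit
#' (a = d) with b at its bound, the exact rectangle a (x2 - x1) is used.
#'
#' @param fit A \code{fourpl_fit}.
#' @param x1,x2 Integration bounds in log10 uM, x2 > x1.
#' @return Area under the curve.
#' @export
auc_closed_form <- function(fit, x1, x2) {
  if (x2 <= x1) stop("x2 must exceed x1")
  if (fit$b == 0) {
    if (fit$a == fit$d) return(fit$a * (x2 - x1))
    stop("invalid fit: b = 0 with a != d")
  }
  Y <- function(x) (fit$a - fit$d) * log1p10(fit$b * (fit$c - x)) / fit$b +
    fit$a * x
  Y(x2) - Y(x1)
}

#' Drug sensitivity score configuration
#'
#' @param t Minimum activity level (percent) at which integration begins
#'   (default 10).
#' @param cmin,cmax Log10 uM bounds of the screened dose window.
#' @return List of class \code{dss_config}.
#' @export
dss_config <- function(t = 10, cmin, cmax) {
  if (t < 0 || t >= 100) stop("t must lie in [0, 100)")
  if (cmax <= cmin) stop("cmax must exceed cmin")
  structure(list(t = t, cmin = cmin, cmax = cmax), class = "dss_config")
}

#' Drug sensitivity score
#'
#' Normalized area under the fitted inhibition curve above the minimum
#' activity level t:
#' DSS = (AUC - t (x2 - x1)) / ((100 - t) (Cmax - Cmin)), where x1 is the
#' dose at which the fitted curve crosses t (closed form; Cmin if the curve
#' starts above t) and x2 = Cmax. Zero when the curve never reaches t on the
#' screened window; clamped at zero otherwise (no negative sensitivity).
#'
#' @param fit A \code{fourpl_fit}.
#' @param cfg A \code{dss_config}.
#' @return Score in [0, 1].
#' @export
dss <- function(fit, cfg) {
  t <- cfg$t; cmin <- cfg$cmin; cmax <- cfg$cmax
  a <- fit$a; b <- fit$b; cc <- fit$c; d <- fit$d
  if (a <= t) return(0)                   # never reaches the activity level
  x1 <- if (d >= t) cmin else cc - log10((a - d) / (t - d) - 1) / b
  x1 <- min(max(x1, cmin), cmax)
  if (x1 >= cmax) return(0)
  auc <- auc_closed_form(fit, x1, cmax)
  max((auc - t * (cmax - x1)) / ((100 - t) * (cmax - cmin)), 0)
}

#' Delta drug sensitivity score
#'
#' DSS of the combination minus the better of the two single-agent scores;
#' positive values indicate synergy.
#'
#' @param dss_comb,dss_a,dss_b Scores in [0, 1].
#' @return Signed score.
#' @export
delta_dss <- function(dss_comb, dss_a, dss_b) {
  dss_comb - pmax(dss_a, dss_b)
}
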