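# Independent oracles and small shared fixtures for the test suite.

# exhaustive two-sample KS statistic: sup over all observed thresholds of
# the ECDF gap (right-continuous step functions attain the sup at sample
# points)
brute_force_ks <- function(a, b) {
  th <- sort(unique(c(a, b)))
  max(abs(vapply(th, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

# adaptive-quadrature oracle for the 4PL area
quadrature_auc <- function(fit, x1, x2) {
  stats::integrate(function(x)
    fit$d + (fit$a - fit$d) / (1 + 10^(fit$b * (fit$c - x))),
    x1, x2, rel.tol = 1e-11, abs.tol = 1e-11)$value
}

# random plausible 4PL parameter draw (inhibition scale)
random_4pl <- function() {
  d <- stats::runif(1, 0, 20)
  structure(list(a = stats::runif(1, d + 30, 110), b = stats::runif(1, 0.3, 5),
                 c = stats::runif(1, -2, 2), d = d,
                 rss = 0, converged = TRUE, x_range = c(-3, 3)),
            class = "fourpl_fit")
}

# two-drug noiseless plate and its per-dose EOB vector (C1 -> C6)
plate_eob_per_dose <- function(drugs, interactions = list(), noise_cv = 0,
                               seed = 1) {
  pl <- simulate_plate(drugs, interactions, noise_cv = noise_cv, seed = seed)
  gr <- gr_table(pl)
  s <- gr[is.na(gr$drug_b) & gr$dose_a_uM > 0, ]
  cmb <- gr[!is.na(gr$drug_b), ]
  cmb <- cmb[order(-cmb$dose_a_uM), ]
  vapply(seq_len(nrow(cmb)), function(i) {
    ga <- s$gr_mean[s$drug_a == cmb$drug_a[i] &
                      s$dose_a_uM == cmb$dose_a_uM[i]]
    gb <- s$gr_mean[s$drug_a == cmb$drug_b[i] &
                      s$dose_a_uM == cmb$dose_b_uM[i]]
    eob(cmb$gr_mean[i], ga, gb)
  }, numeric(1))
}

# single-drug Hill inhibition, duplicated here as an independent check
hill_truth <- function(dose, ic50, h = 1, imax = 1) {
  ifelse(dose <= 0, 0, imax / (1 + (ic50 / dose)^h))
}

# profiles for well-separated synthetic classes: class centroids are
# sep-scaled unit vectors on disjoint feature blocks, unit Gaussian noise
separated_class_profiles <- function(n_classes = 6, n_per_class = 8,
                                     p = 30, sep = 5, seed = 1) {
  set.seed(seed)
  blocks <- split(seq_len(p), rep(seq_len(n_classes), length.out = p))
  centroids <- t(vapply(seq_len(n_classes), function(k) {
    v <- numeric(p)
    v[blocks[[k]]] <- sep / sqrt(length(blocks[[k]]))
    v
  }, numeric(p)))
  x <- do.call(rbind, lapply(seq_len(n_classes), function(k)
    sweep(matrix(stats::rnorm(n_per_class * p), n_per_class), 2,
          centroids[k, ], `+`)))
  list(profiles = x,
       classes = rep(paste0("class", seq_len(n_classes)),
                     each = n_per_class))
}

# 12-drug panel in which one class's phenotype shifts are `factor` times
# larger than every other class's
panel_with_dominant_class <- function(dominant = "PROT", factor = 5) {
  drugs <- default_screen_drugs()
  p <- length(hc_feature_registry())
  classes <- c("mTOR", "MT", "HSP", "PROT", "DNA", "HDAC")
  block <- split(seq_len(p), rep(seq_along(classes), length.out = p))
  lapply(drugs, function(d) {
    s <- numeric(p)
    mag <- if (d$drug_class == dominant) factor else 1
    s[block[[match(d$drug_class, classes)]]] <- mag
    drug_spec(d$name, d$drug_class, d$ic50_true, d$hill_slope_true,
              d$max_inhibition_true, s)
  })
}
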