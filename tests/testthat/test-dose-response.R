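test_that("growth-rate to inhibition adapters hit their anchors", {
  expect_equal(inhibition_from_gr(1), 0)
  expect_equal(inhibition_from_gr(-1), 100)
  expect_equal(inhibition_from_gr(0), 50)
  expect_equal(inhibition_from_gr(2), 0)      # clamped
  expect_equal(gr_inhibition(1), 0)
  expect_equal(gr_inhibition(0), 100)         # cytostasis = full growth stop
  expect_equal(gr_inhibition(-0.5), 100)      # net kill saturates
  expect_equal(gr_inhibition(2^0.5 - 1), 50)  # half the growth exponent
  expect_error(inhibition_from_gr(NaN), "finite")
})

test_that("4PL fit recovers exact logistic data and flags degenerate input", {
  x <- seq(-2, 2, length.out = 8)
  y <- 0 + (100 - 0) / (1 + 10^(1 * (0 - x)))
  f <- fit_4pl(x, y)
  expect_true(f$converged)
  expect_equal(c(f$a, f$b, f$c, f$d), c(100, 1, 0, 0), tolerance = 1e-6)

  y2 <- 5 + (87 - 5) / (1 + 10^(2.2 * (-0.7 - x)))
  f2 <- fit_4pl(x, y2)
  expect_equal(c(f2$a, f2$b, f2$c, f2$d), c(87, 2.2, -0.7, 5),
               tolerance = 1e-6)

  flat <- fit_4pl(x, rep(40, 8))
  expect_true(!flat$converged || (flat$a - flat$d) < 1)
  expect_true(is.na(ic50(flat)))
  expect_error(fit_4pl(c(0, 0, 1, 1), c(1, 1, 2, 2)), "distinct doses")
})

test_that("IC50 and ECp invert the fitted curve", {
  f <- structure(list(a = 100, b = 1, c = 0, d = 0, rss = 0,
                      converged = TRUE, x_range = c(-2, 2)),
                 class = "fourpl_fit")
  expect_equal(ic50(f), 1)
  f$c <- -0.5
  expect_equal(ic50(f), 0.3162278, tolerance = 1e-6)
  expect_equal(ecp(f, 0.5), 10^f$c)
  f$c <- 0
  expect_equal(ecp(f, 0.2), 0.25, tolerance = 1e-4)  # x = -log10(4)
  f$b <- 2   # doubling the slope halves the log-distance from c
  expect_equal(log10(ecp(f, 0.2)), -log10(4) / 2, tolerance = 1e-12)
  # out-of-range fits give undefined IC50
  f_out <- structure(list(a = 100, b = 1, c = 4, d = 0, rss = 0,
                          converged = TRUE, x_range = c(-2, 2)),
                     class = "fourpl_fit")
  expect_true(is.na(ic50(f_out)))
  expect_error(ecp(f, 1.2), "between 0 and 1")

  set.seed(3)
  for (i in 1:50) {   # ecp is the exact closed-form inverse
    g <- random_4pl()
    p <- runif(1, 0.05, 0.95)
    x <- log10(ecp(g, p))
    y <- g$d + (g$a - g$d) / (1 + 10^(g$b * (g$c - x)))
    expect_equal(y, g$d + p * (g$a - g$d), tolerance = 1e-12)
  }
})

test_that("closed-form AUC matches its exact values and a quadrature oracle", {
  f <- structure(list(a = 100, b = 1, c = 0, d = 0, rss = 0,
                      converged = TRUE, x_range = c(-2, 2)),
                 class = "fourpl_fit")
  expect_equal(auc_closed_form(f, -2, 2), 200, tolerance = 1e-9)
  flat <- structure(list(a = 30, b = 0, c = 0, d = 30, rss = 0,
                         converged = TRUE, x_range = c(-2, 2)),
                    class = "fourpl_fit")
  expect_equal(auc_closed_form(flat, -1, 3), 30 * 4)
  bad <- flat; bad$d <- 10
  expect_error(auc_closed_form(bad, -1, 3), "invalid fit")
  expect_error(auc_closed_form(f, 2, -2), "exceed")
  set.seed(4)
  for (i in 1:50) {
    g <- random_4pl()
    x1 <- runif(1, -3, 0); x2 <- x1 + runif(1, 0.5, 4)
    expect_lt(abs(auc_closed_form(g, x1, x2) - quadrature_auc(g, x1, x2)),
              1e-8 * (x2 - x1) * 100)
  }
})

test_that("DSS normalizes the effective-inhibition area as defined", {
  cfg <- dss_config(t = 10, cmin = -2, cmax = 2)
  weak <- structure(list(a = 8, b = 1, c = 0, d = 0, rss = 0,
                         converged = TRUE, x_range = c(-2, 2)),
                    class = "fourpl_fit")
  expect_equal(dss(weak, cfg), 0)      # never reaches the activity level
  full <- structure(list(a = 100, b = 0, c = 0, d = 100, rss = 0,
                         converged = TRUE, x_range = c(-2, 2)),
                    class = "fourpl_fit")
  expect_equal(dss(full, cfg), 1)      # complete inhibition everywhere
  f <- structure(list(a = 100, b = 1, c = 0, d = 0, rss = 0,
                      converged = TRUE, x_range = c(-2, 2)),
                 class = "fourpl_fit")
  # closed form via the crossing dose x1 = -log10(9), checked against
  # direct quadrature of the same definition
  x1 <- -log10(9)
  expected <- (quadrature_auc(f, x1, 2) - 10 * (2 - x1)) / (90 * 4)
  expect_equal(dss(f, cfg), expected, tolerance = 1e-9)
  expect_equal(dss(f, cfg), 0.462, tolerance = 1e-3)
  # monotone: raising the activity floor cannot raise the score
  ts <- seq(5, 50, by = 5)
  scores <- vapply(ts, function(t)
    dss(f, dss_config(t, -2, 2)), numeric(1))
  expect_true(all(diff(scores) <= 1e-12))
  expect_error(dss_config(t = 100, -2, 2), "t must")
  expect_error(dss_config(10, 2, -2), "cmax")
})

test_that("delta DSS compares the combination to the better single agent", {
  expect_equal(delta_dss(0.5, 0.5, 0.3), 0)
  expect_equal(delta_dss(0.7, 0.5, 0.3), 0.2)
  expect_equal(delta_dss(0.2, 0.5, 0.6), -0.4)
})

test_that("noiseless single-drug series round-trip through the 4PL fit", {
  drugs <- default_screen_drugs()
  pl <- simulate_plate(drugs, noise_cv = 0, seed = 1)
  gr <- gr_table(pl)
  s <- gr[is.na(gr$drug_b) & gr$dose_a_uM > 0, ]
  for (d in drugs) {
    sub <- s[s$drug_a == d$name, ]
    sub <- sub[order(sub$dose_a_uM), ]
    f <- fit_4pl(log10(sub$dose_a_uM), gr_inhibition(sub$gr_mean))
    expect_equal(10^f$c, d$ic50_true, tolerance = 0.01)
    expect_equal(f$b, d$hill_slope_true, tolerance = 0.02)
  }
})
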