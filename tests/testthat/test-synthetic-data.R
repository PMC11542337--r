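test_that("dilution series follows the serial-dilution design", {
  d <- make_dilution_series(10, 6, 3.5)
  expect_equal(unname(d), c(10, 2.857143, 0.8163265, 0.2332362, 0.06663892,
                            0.01903969), tolerance = 1e-6)
  expect_named(d, paste0("C", 1:6))
  expect_true(all(diff(d) < 0))
  expect_equal(unname(make_dilution_series(1, 3, 2)), c(1, 0.5, 0.25))
  expect_error(make_dilution_series(5, 1), "n_doses")
  expect_error(make_dilution_series(-1, 6), "positive")
  expect_error(make_dilution_series(1, 6, fold = 1), "fold")
})

test_that("spec constructors validate their invariants", {
  expect_error(drug_spec("A", "mTOR", ic50_true = -1), "ic50")
  expect_error(drug_spec("A", "mTOR", 1, max_inhibition_true = 1.2), "max_inhibition")
  expect_error(drug_spec("A", "mTOR", 1, phenotype_shift = c(1, NA)), "finite")
  expect_error(interaction_spec("A", "B", "bliss_independent", 0.1), "eob_offset")
  expect_error(interaction_spec("A", "B", "synergistic", -0.2), "synergistic")
  expect_error(interaction_spec("A", "B", eob_offset = 2), "<= 1")
})

test_that("plate counts follow the Hill growth model at the midpoint", {
  d <- drug_spec("X", "mTOR", ic50_true = 1, hill_slope_true = 1.3,
                 max_inhibition_true = 1)
  pl <- simulate_plate(list(d), doses = c(C1 = 10, C2 = 3, C3 = 1, C4 = 0.3),
                       n_replicates = 2, x0 = 1000, growth_doublings = 4,
                       noise_cv = 0, seed = 1)
  at_ic50 <- pl[pl$drug_a == "X" & pl$dose_a_uM == 1, "count"]
  expect_equal(at_ic50, rep(1000 * 2^2, 2))  # I = 0.5 at the IC50
  veh <- pl[pl$drug_a == "DMSO" & pl$timepoint_h > 0, "count"]
  expect_equal(veh, rep(1000 * 2^4, 2))
  t0 <- pl[pl$timepoint_h == 0, "count"]
  expect_equal(t0, rep(1000, 2))
})

test_that("plate simulation is reproducible and validates interactions", {
  drugs <- default_screen_drugs()[1:3]
  p1 <- simulate_plate(drugs, noise_cv = 0.1, seed = 7)
  p2 <- simulate_plate(drugs, noise_cv = 0.1, seed = 7)
  expect_identical(p1, p2)
  p3 <- simulate_plate(drugs, noise_cv = 0.1, seed = 8)
  expect_false(identical(p1$count, p3$count))
  expect_error(
    simulate_plate(drugs, list(interaction_spec("DEF", "ZZZ"))),
    "unknown drug")
})

test_that("Bliss-independent pairs give near-zero downstream EOB, and an
           interaction offset shifts EOB by about its value", {
  drugs <- list(drug_spec("A", "mTOR", 0.82, 1, 1),
                drug_spec("B", "HDAC", 0.82, 1, 1))
  e0 <- plate_eob_per_dose(drugs)
  expect_lt(max(abs(e0)), 0.02)

  it <- list(interaction_spec("A", "B", "synergistic", eob_offset = 0.2))
  e1 <- plate_eob_per_dose(drugs, it)
  doses <- make_dilution_series(10, 6, 3.5)
  ok <- hill_truth(doses, 0.82) < 0.8   # both singles below 80% inhibition
  expect_lt(abs(mean(e1[ok]) - 0.2), 0.05)
})

test_that("feature tables shift by the requested effect size", {
  reg <- hc_feature_registry()
  expect_length(reg, 30)
  ctrl <- simulate_feature_table("DMSO", 10000, seed = 1)
  shift <- numeric(30); shift[4] <- 1
  trt <- simulate_feature_table("drugX", 10000, shift = shift, seed = 2)
  ks4 <- signed_ks(trt[[reg[4]]], ctrl[[reg[4]]])
  expect_equal(ks4, 0.3829, tolerance = 0.02)  # max gap N(1,1) vs N(0,1)
  others <- vapply(reg[-4], function(f)
    abs(signed_ks(trt[[f]], ctrl[[f]])), numeric(1))
  expect_lt(max(others), 0.05)

  half <- simulate_feature_table("drugX", 50000, shift = shift,
                                 dose_scaling = 0.5, seed = 3)
  expect_equal(mean(half[[reg[4]]]), 0.5, tolerance = 0.03)
  expect_error(simulate_feature_table("x", 10, shift = c(1, 2)), "shift length")
  expect_identical(simulate_feature_table("x", 50, seed = 4),
                   simulate_feature_table("x", 50, seed = 4))
})

test_that("synthetic fields carry exact truth and honest intensities", {
  expect_equal(nrow(simulate_images(0, c(64, 64), snr = 10)$truth), 0)
  img <- simulate_images(150, c(256, 256), snr = 10, seed = 3)
  expect_equal(nrow(img$truth), 150)
  expect_true(all(img$truth$y >= 1 & img$truth$y <= 256 &
                    img$truth$x >= 1 & img$truth$x <= 256))
  expect_true(all(img$pixels >= 0 & img$pixels <= 2^16 - 1))
  # channel-1 photon budget: total minus background matches the truth's
  # integrated per-cell intensity
  tot <- sum(img$pixels[, , 1]) - sum(img$background)
  expect_equal(tot, sum(img$truth$integrated_ch1), tolerance = 0.05)
  expect_error(simulate_images(500, c(48, 48), min_separation = 12),
               "capacity")
})

test_that("different seeds shuffle centroids but keep the field statistics", {
  a <- simulate_images(1000, c(768, 768), snr = 10, seed = 1)
  b <- simulate_images(1000, c(768, 768), snr = 10, seed = 2)
  expect_false(any(a$truth$x[1:50] == b$truth$x[1:50]))
  # same marginal distribution of coordinates (uniform over the field)
  expect_gt(suppressWarnings(stats::ks.test(a$truth$x, b$truth$x))$p.value,
            0.01)
  expect_gt(suppressWarnings(stats::ks.test(a$truth$y, b$truth$y))$p.value,
            0.01)
  expect_identical(simulate_images(20, c(128, 128), seed = 9)$truth,
                   simulate_images(20, c(128, 128), seed = 9)$truth)
})
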