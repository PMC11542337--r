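test_that("signed KS equals a brute-force ECDF scan with the median sign", {
  expect_equal(signed_ks(1:10, 1:10), 0)
  expect_error(signed_ks(numeric(0), 1:3), "insufficient")
  set.seed(21)
  x <- rnorm(10000, 1); y <- rnorm(10000, 0)
  expect_equal(signed_ks(x, y), 2 * pnorm(0.5) - 1, tolerance = 0.02)
  expect_equal(signed_ks(y, x), -signed_ks(x, y), tolerance = 0.02)
  for (i in 1:40) {
    n1 <- sample(2:50, 1); n2 <- sample(2:50, 1)
    a <- if (runif(1) < 0.3) sample(1:8, n1, TRUE) else rnorm(n1, runif(1, -1, 1))
    b <- if (runif(1) < 0.3) sample(1:8, n2, TRUE) else rnorm(n2)
    expect_equal(abs(signed_ks(a, b)), brute_force_ks(a, b))
  }
})

test_that("KS profiles line up with the feature registry", {
  reg <- hc_feature_registry()
  ctrl <- simulate_feature_table("DMSO", 400, seed = 1)
  same <- simulate_feature_table("DMSO2", 400, seed = 2)
  prof0 <- ks_profile(same, ctrl)
  expect_length(prof0, length(reg))
  expect_lt(max(abs(prof0)), 0.12)    # null KS noise band at n = 400

  shift <- numeric(30); shift[7] <- 2
  trt <- simulate_feature_table("X", 400, shift = shift, seed = 3)
  prof <- ks_profile(trt, ctrl)
  expect_equal(unname(which.max(abs(prof))), 7L)
  expect_gt(prof[7], 0.5)
  expect_lt(max(abs(prof[-7])), 0.12)
  expect_error(ks_profile(trt[, 1:10], ctrl), "registry mismatch")
})

test_that("PCA embedding matches an eigen-decomposition oracle", {
  set.seed(31)
  # rank-1 data: first component explains everything
  base <- rnorm(30)
  line <- outer(rnorm(12), base) +
    matrix(rnorm(12 * 30, sd = 1e-8), 12)
  expect_warning(pc1 <- pca_embed(line, n_components = 15), "rank")
  expect_gt(pca_embed(line, 1)$explained_variance[1], 0.999)

  x <- matrix(rnorm(40 * 30), 40)
  pc <- pca_embed(x, 5)
  ev <- eigen(stats::cov(x), symmetric = TRUE)$values
  expect_equal(pc$explained_variance, (ev / sum(ev))[1:5], tolerance = 1e-10)
  expect_equal(unname(crossprod(pc$rotation)), diag(5), tolerance = 1e-10)
  expect_true(all(diff(pc$explained_variance) <= 1e-12))
  expect_error(pca_embed(x[1, , drop = FALSE]), "at least 2")
})

test_that("shrinkage LDA separates classes and collapses under permutation", {
  sim <- separated_class_profiles(n_classes = 6, n_per_class = 8, sep = 5,
                                  seed = 41)
  model <- lda_fit(sim$profiles, sim$classes, shrinkage = 0.5)
  expect_equal(ncol(model$projection), 5)   # classes - 1
  expect_gt(model$fisher_criterion, 10)
  # nearest-class-mean classification of the training set
  sc <- lda_transform(model, sim$profiles)
  pred <- model$classes[apply(sc, 1, function(v)
    which.min(colSums((t(model$class_means) - v)^2)))]
  expect_gte(mean(pred == sim$classes), 0.95)

  set.seed(42)
  perm <- lda_fit(sim$profiles, sample(sim$classes), shrinkage = 0.5)
  expect_lt(perm$fisher_criterion, model$fisher_criterion / 5)
  expect_error(lda_fit(sim$profiles[1:9, ], c(rep("a", 8), "b")),
               "insufficient class size")
})

test_that("shrinkage-free LDA agrees with an established implementation", {
  set.seed(43)
  # well-conditioned regime: n >> p so plain within-class scatter works
  sim <- separated_class_profiles(n_classes = 3, n_per_class = 30, p = 5,
                                  sep = 3, seed = 44)
  model <- lda_fit(sim$profiles, sim$classes, shrinkage = 0)
  ref <- MASS::lda(sim$profiles, grouping = sim$classes)
  v1 <- model$projection[, 1] / sqrt(sum(model$projection[, 1]^2))
  v2 <- ref$scaling[, 1] / sqrt(sum(ref$scaling[, 1]^2))
  expect_gt(abs(sum(v1 * v2)), 0.999)   # same discriminant direction
})

test_that("nearest-neighbor assignment is exact with a documented tie-break", {
  set.seed(51)
  refs <- matrix(rnorm(40), 20, 2)
  ids <- sprintf("ref%02d", 20:1)
  classes <- rep(c("a", "b"), 10)
  q <- rnorm(2)
  nn <- knn_assign(q, refs, ids, classes)
  d <- sqrt(colSums((t(refs) - q)^2))
  expect_equal(nn$distance, min(d))
  expect_equal(nn$index, which.min(d))
  expect_equal(knn_assign(refs[7, ], refs, ids, classes)$distance, 0)
  # exact tie resolves to the lexicographically smaller id
  tie_refs <- rbind(c(1, 0), c(-1, 0))
  expect_equal(knn_assign(c(0, 0), tie_refs, c("zeta", "alpha"),
                          c("x", "y"))$id, "alpha")
  expect_error(knn_assign(c(0, 0, 0), refs, ids, classes), "dimension")
})

test_that("confidence score behaves like a posterior over match distance", {
  set.seed(61)
  same_d <- abs(rnorm(100, 0, 0.5))
  diff_d <- abs(rnorm(100, 6, 1))
  expect_gt(confidence_score(0, same_d, diff_d), 0.99)
  expect_lt(confidence_score(10, same_d, diff_d), 0.01)
  expect_equal(confidence_score(3, same_d, same_d), 0.5)  # equal densities
  grid <- seq(0.6, 9, by = 0.3)
  cs <- confidence_score(grid, same_d, diff_d)
  expect_true(all(cs >= 0 & cs <= 1))
  expect_true(all(diff(cs) <= 1e-9))  # non-increasing beyond the mode
  expect_warning(ind <- confidence_score(1, rep(1, 5), rep(3, 5)),
                 "degenerate")
  expect_equal(ind, 1)
})

test_that("dominance calls cover the four published interaction patterns", {
  set.seed(71)
  refs <- rbind(c(0, 0), c(0.2, 0), c(5, 5), c(5.2, 5))
  ids <- c("a1|C2", "a2|C2", "b1|C2", "b2|C2")
  classes <- c("A", "A", "B", "B")
  same_d <- abs(rnorm(60, 0.3, 0.15))
  diff_d <- abs(rnorm(60, 7, 1.5))
  call_at <- function(q) dominance_call(q, c("drugA", "drugB"), c("A", "B"),
                                        refs, ids, classes, same_d, diff_d)
  on_a <- call_at(c(0.05, 0))          # sits on drug A's profile
  expect_equal(on_a$category, "dominant")
  expect_equal(on_a$dominant_drug, "drugA")
  expect_gt(on_a$confidence, 0.9)
  mid <- call_at(c(2.5, 2.5))          # midway between the two classes
  expect_equal(mid$category, "codominant")
  far <- call_at(c(1.5, 0))   # beyond the within-class spread of either
  expect_equal(far$category, "interactive")
  # confident match to a class outside the combination
  other <- dominance_call(c(0.05, 0), c("drugB", "drugC"), c("B", "C"),
                          refs, ids, classes, same_d, diff_d)
  expect_equal(other$category, "unassigned")
})

test_that("dominance statistics aggregate per class with a no-data state", {
  set.seed(81)
  mk_call <- function(cat, dom, comps, classes, cs)
    structure(list(category = cat, dominant_drug = dom, components = comps,
                   component_classes = classes, confidence = cs),
              class = "dominance_call")
  calls <- list(mk_call("dominant", "p1", c("p1", "m1"), c("P", "M"), 0.99),
                mk_call("dominant", "p2", c("p2", "m1"), c("P", "M"), 0.95),
                mk_call("interactive", NA, c("p1", "m2"), c("P", "M"), 0.2))
  st <- dominance_statistics(calls)
  expect_equal(st$pct_dominant[st$class == "P"], 2 / 3 * 100)
  expect_equal(st$pct_dominant[st$class == "M"], 0)
  st_hi <- dominance_statistics(calls, cs_filter = 0.9)
  expect_equal(st_hi$pct_dominant[st_hi$class == "P"], 100)
  none <- dominance_statistics(calls, cs_filter = 1.1)
  expect_equal(nrow(none), 0)   # no data is reported as no rows, not 0%
})

test_that("concentration traces order doses and flag endpoints", {
  sim <- separated_class_profiles(n_classes = 3, n_per_class = 6, sep = 4,
                                  seed = 91)
  model <- lda_fit(sim$profiles, sim$classes)
  prof <- sim$profiles[1:6, ]
  tr <- concentration_trace(prof, dose_index = c(1, 2, 3, 4, 5, 6), model)
  expect_equal(nrow(tr), 6)
  expect_equal(tr$dose_index, 6:1)    # lowest dose first
  expect_equal(tr$endpoint[1], "lowest_dose")
  expect_equal(tr$endpoint[6], "highest_dose")
  gap <- concentration_trace(prof[c(1, 2, 5), ], c(1, 2, 5), model)
  expect_equal(attr(gap, "gaps"), c(3, 4))
  expect_error(concentration_trace(prof[1, , drop = FALSE], 1, model),
               "2 dose levels")
  # a vehicle-like series of null profiles collapses near the origin
  null_prof <- matrix(rnorm(6 * 30, sd = 0.01), 6)
  tr0 <- concentration_trace(null_prof, 1:6, model)
  spread0 <- max(dist(as.matrix(tr0[, c("LD1", "LD2")])))
  spread1 <- max(dist(as.matrix(tr[, c("LD1", "LD2")])))
  expect_lt(spread0, spread1 / 5)
})
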