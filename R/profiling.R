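#' Signed two-sample Kolmogorov-Smirnov statistic
#'
#' Magnitude is the supremum over thresholds of the absolute difference
#' between the treated and control empirical CDFs; the sign is that of the
#' median difference (treated minus control), so positive values mean the
#' treated population shifted upward. Identical samples give 0.
#'
#' @param treated,control Non-empty numeric samples.
#' @return Signed statistic in [-1, 1].
#' @export
signed_ks <- function(treated, control) {
  if (length(treated) == 0 || length(control) == 0)
    stop("insufficient cells: both samples must be non-empty")
  d <- unname(suppressWarnings(
    stats::ks.test(treated, control)$statistic))
  s <- sign(stats::median(treated) - stats::median(control))
  if (s == 0) s <- 1   # pure spread changes count as positive
  if (d == 0) 0 else s * d
}

#' KS profile of a treatment against vehicle control
#'
#' One signed KS statistic per registry feature, comparing the treated
#' per-cell feature table with the matched vehicle-control table.
#'
#' @param features,control Per-cell feature tables sharing the same feature
#'   registry columns.
#' @param registry Feature names (default the packaged registry).
#' @return Object of class \code{ks_profile}: named numeric vector of
#'   signed KS values with attributes \code{n_cells} and \code{n_control}.
#' @export
ks_profile <- function(features, control, registry = hc_feature_registry()) {
  missing_f <- setdiff(registry, names(features))
  missing_c <- setdiff(registry, names(control))
  if (length(missing_f) || length(missing_c))
    stop("feature registry mismatch: missing ",
         paste(union(missing_f, missing_c), collapse = ", "))
  vals <- vapply(registry, function(f)
    signed_ks(features[[f]], control[[f]]), numeric(1))
  structure(vals, class = "ks_profile",
            n_cells = nrow(features), n_control = nrow(control))
}

#' Principal component embedding of KS profiles
#'
#' Mean-centered PCA of a profile matrix; successive components maximize
#' the remaining variance, and explained-variance fractions are
#' non-increasing.
#'
#' @param profiles Numeric matrix, one row per profile.
#' @param n_components Number of components to keep (reduced with a warning
#'   if above the matrix rank).
#' @return List with \code{scores}, \code{rotation},
#'   \code{explained_variance} (fractions), \code{center}.
#' @export
pca_embed <- function(profiles, n_components = 2L) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2) stop("need at least 2 profiles")
  pc <- stats::prcomp(profiles, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > 1e-12)
  if (n_components > rank) {
    warning("n_components reduced to rank ", rank)
    n_components <- rank
  }
  idx <- seq_len(n_components)
  list(scores = pc$x[, idx, drop = FALSE],
       rotation = pc$rotation[, idx, drop = FALSE],
       explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[idx],
       center = pc$center)
}

#' Fit a shrinkage linear discriminant model
#'
#' Fisher LDA with the pooled within-class scatter shrunk toward a scaled
#' identity, S_w(lambda) = (1 - lambda) S_w + lambda (tr(S_w)/p) I, which
#' keeps the model defined when the profile dimension exceeds the training
#' count (the usual regime: the training set is the single-drug profiles at
#' the second-highest dose). Components are the leading eigenvectors of
#' solve(S_w(lambda)) S_b, at most (number of classes - 1).
#'
#' @param profiles Numeric matrix of training profiles (rows).
#' @param classes Class label per row; every class needs >= 2 profiles.
#' @param shrinkage Regularization intensity lambda in [0, 1] (default 0.5).
#' @param ids Optional training profile identifiers.
#' @return Object of class \code{lda_model}: projection matrix, grand mean,
#'   class means in component space, class labels, Fisher criterion of the
#'   first component, and training metadata.
#' @export
lda_fit <- function(profiles, classes, shrinkage = 0.5, ids = NULL) {
  profiles <- as.matrix(profiles)
  classes <- as.character(classes)
  tab <- table(classes)
  if (length(tab) < 2) stop("need >= 2 classes")
  if (any(tab < 2))
    stop("insufficient class size: every class needs >= 2 training profiles (",
         paste(names(tab)[tab < 2], collapse = ", "), ")")
  if (shrinkage < 0 || shrinkage > 1) stop("shrinkage must lie in [0, 1]")
  p <- ncol(profiles)
  grand <- colMeans(profiles)
  cls <- names(tab)
  means <- t(vapply(cls, function(g)
    colMeans(profiles[classes == g, , drop = FALSE]), numeric(p)))

  sw <- matrix(0, p, p); sb <- matrix(0, p, p)
  for (g in cls) {
    xg <- profiles[classes == g, , drop = FALSE]
    xc <- sweep(xg, 2, means[g, ])
    sw <- sw + crossprod(xc)
    db <- means[g, ] - grand
    sb <- sb + nrow(xg) * tcrossprod(db)
  }
  sw <- sw / (nrow(profiles) - length(cls))
  sb <- sb / nrow(profiles)
  sw_reg <- (1 - shrinkage) * sw +
    shrinkage * (sum(diag(sw)) / p) * diag(p)

  eig <- eigen(solve(sw_reg, sb))
  k <- min(length(cls) - 1L, sum(Re(eig$values) > 1e-10))
  proj <- Re(eig$vectors[, seq_len(k), drop = FALSE])
  proj <- sweep(proj, 2, sqrt(colSums(proj^2)), `/`)
  scores <- sweep(profiles, 2, grand) %*% proj
  class_means <- t(vapply(cls, function(g)
    colMeans(scores[classes == g, , drop = FALSE]), numeric(k)))
  # Fisher criterion on component 1: between-class over within-class variance
  s1 <- scores[, 1]
  wvar <- sum(vapply(cls, function(g) {
    v <- s1[classes == g]
    sum((v - mean(v))^2)
  }, numeric(1))) / (length(s1) - length(cls))
  bvar <- sum(vapply(cls, function(g)
    sum(classes == g) * (mean(s1[classes == g]) - mean(s1))^2,
    numeric(1))) / (length(cls) - 1)
  structure(list(projection = proj, center = grand,
                 class_means = class_means, classes = cls,
                 shrinkage = shrinkage,
                 fisher_criterion = bvar / max(wvar, 1e-12),
                 training_scores = scores, training_classes = classes,
                 training_ids = ids),
            class = "lda_model")
}

#' Project profiles into an LDA component space
#'
#' @param model An \code{lda_model}.
#' @param profiles Numeric matrix or vector of profiles in registry order.
#' @return Matrix of component-space coordinates.
#' @export
lda_transform <- function(model, profiles) {
  profiles <- if (is.null(dim(profiles))) matrix(profiles, nrow = 1) else
    as.matrix(profiles)
  if (ncol(profiles) != length(model$center))
    stop("dimension mismatch with the fitted model")
  sweep(profiles, 2, model$center) %*% model$projection
}

#' Nearest single-drug reference of a query profile
#'
#' 1-nearest-neighbor assignment by Euclidean distance in LDA component
#' space; exact ties break deterministically toward the lexicographically
#' smallest reference id.
#'
#' @param query Coordinate vector in component space.
#' @param references Matrix of reference coordinates (one row each).
#' @param ref_ids Reference identifiers.
#' @param ref_classes Reference class labels.
#' @return List: \code{id}, \code{class}, \code{distance}, \code{index}.
#' @export
knn_assign <- function(query, references, ref_ids, ref_classes) {
  references <- as.matrix(references)
  if (nrow(references) == 0) stop("references must be non-empty")
  if (length(query) != ncol(references))
    stop("dimension mismatch between query and references")
  d <- sqrt(colSums((t(references) - query)^2))
  best <- which(d <= min(d) + 1e-12)
  if (length(best) > 1) best <- best[order(ref_ids[best])][1]
  list(id = ref_ids[best], class = ref_classes[best],
       distance = unname(d[best]), index = unname(best))
}

#' Bayesian confidence score of a nearest-neighbor assignment
#'
#' Posterior probability that an assignment at distance d is a within-class
#' match: CS = f_s(d) pi / (f_s(d) pi + f_d(d) (1 - pi)), where f_s and f_d
#' are Gaussian kernel density estimates of the within-class and
#' between-class training distance distributions and pi is the prior
#' probability of a correct assignment. Larger distances give lower
#' confidence wherever the density ratio is monotone. Degenerate training
#' distances (all identical) fall back to an indicator score with a
#' warning.
#'
#' @param distance Query-to-neighbor distance (vectorized).
#' @param same_class_distances Training distances between profiles of the
#'   same class.
#' @param diff_class_distances Training distances between profiles of
#'   different classes.
#' @param prior Prior probability of a correct assignment (default 0.5).
#' @return Confidence score(s) in [0, 1].
#' @export
confidence_score <- function(distance, same_class_distances,
                             diff_class_distances, prior = 0.5) {
  if (!length(same_class_distances) || !length(diff_class_distances))
    stop("both training distance samples must be non-empty")
  if (stats::sd(same_class_distances) == 0 &&
      stats::sd(diff_class_distances) == 0) {
    warning("degenerate training distances; falling back to indicator score")
    mid <- (mean(same_class_distances) + mean(diff_class_distances)) / 2
    return(as.numeric(distance <= mid))
  }
  dens_at <- function(sample, x) {
    if (stats::sd(sample) == 0)
      sample <- sample + stats::median(abs(sample - mean(sample)) + 1e-8) *
        c(-1, 1)[seq_along(sample) %% 2 + 1]
    de <- stats::density(sample, bw = "nrd0", from = 0,
                         to = max(c(sample, x)) * 1.5 + 1e-9)
    pmax(stats::approx(de$x, de$y, xout = x, rule = 2)$y, 1e-300)
  }
  fs <- dens_at(same_class_distances, distance)
  fd <- dens_at(diff_class_distances, distance)
  cs <- fs * prior / (fs * prior + fd * (1 - prior))
  pmin(pmax(cs, 0), 1)
}

training_distance_pools <- function(model) {
  sc <- model$training_scores
  cl <- model$training_classes
  n <- nrow(sc)
  same <- numeric(0); diff <- numeric(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((sc[i, ] - sc[j, ])^2))
    if (cl[i] == cl[j]) same <- c(same, d) else diff <- c(diff, d)
  }
  list(same = same, diff = diff)
}

#' Dominance call for one drug combination
#'
#' Given a combination profile's nearest single-drug assignment and its
#' confidence score: if the score passes \code{cs_threshold} and the
#' assigned class matches one component, that component is dominant (the
#' other recessive); a confident match to neither component is reported as
#' \code{unassigned}. Below the threshold the call is \code{codominant}
#' when the two nearest distinct single-drug classes are exactly the two
#' component classes with a distance ratio at most
#' \code{codominance_ratio}, else \code{interactive}.
#'
#' @param query Combination coordinates in LDA space.
#' @param components Character vector of the two component drug names.
#' @param component_classes Character vector of their two drug classes.
#' @param references,ref_ids,ref_classes Single-drug reference coordinates
#'   and labels (as in \code{\link{knn_assign}}).
#' @param same_d,diff_d Training distance pools for the confidence score.
#' @param cs_threshold Confidence threshold for a reliable call (default
#'   0.9).
#' @param codominance_ratio Maximum nearest/second-nearest class distance
#'   ratio for a codominant call (default 1.5).
#' @param prior Prior passed to \code{\link{confidence_score}}.
#' @return List of class \code{dominance_call}: \code{knn_class},
#'   \code{knn_id}, \code{distance}, \code{confidence}, \code{category} in
#'   \{dominant, recessive is implicit, codominant, interactive,
#'   unassigned\}, and \code{dominant_drug} (NA unless dominant).
#' @export
dominance_call <- function(query, components, component_classes,
                           references, ref_ids, ref_classes,
                           same_d, diff_d, cs_threshold = 0.9,
                           codominance_ratio = 1.5, prior = 0.5) {
  nn <- knn_assign(query, references, ref_ids, ref_classes)
  cs <- confidence_score(nn$distance, same_d, diff_d, prior)
  category <- "interactive"; dominant <- NA_character_
  if (cs >= cs_threshold) {
    hit <- match(nn$class, component_classes)
    if (!is.na(hit)) {
      category <- "dominant"
      dominant <- components[hit]
    } else {
      category <- "unassigned"
    }
  } else {
    # nearest distance per class
    dists <- sqrt(colSums((t(as.matrix(references)) - query)^2))
    cls_d <- vapply(split(dists, ref_classes), min, numeric(1))
    ord <- order(cls_d)
    two <- names(cls_d)[ord[1:2]]
    if (setequal(two, unique(component_classes)) &&
        cls_d[ord[2]] <= codominance_ratio * cls_d[ord[1]])
      category <- "codominant"
  }
  structure(list(knn_class = nn$class, knn_id = nn$id,
                 distance = nn$distance, confidence = unname(cs),
                 category = category, dominant_drug = dominant,
                 components = components,
                 component_classes = component_classes),
            class = "dominance_call")
}

#' Per-class dominance statistics
#'
#' For each drug class, the fraction of its combinations in which that class
#' was called dominant, over all calls and over calls passing the
#' confidence filter. Classes with no qualifying combinations are reported
#' as \code{NA} (no data), not 0.
#'
#' @param calls List of \code{dominance_call} objects.
#' @param cs_filter Optional confidence threshold restricting the calls.
#' @return \code{data.frame} with columns \code{class},
#'   \code{n_combinations}, \code{n_dominant}, \code{pct_dominant}.
#' @export
dominance_statistics <- function(calls, cs_filter = NULL) {
  if (!is.null(cs_filter))
    calls <- Filter(function(cl) cl$confidence >= cs_filter, calls)
  classes <- sort(unique(unlist(lapply(calls, `[[`, "component_classes"))))
  if (length(calls) == 0)
    return(data.frame(class = character(0), n_combinations = integer(0),
                      n_dominant = integer(0), pct_dominant = numeric(0),
                      stringsAsFactors = FALSE))
  rows <- lapply(classes, function(g) {
    involved <- Filter(function(cl) g %in% cl$component_classes, calls)
    n <- length(involved)
    ndom <- sum(vapply(involved, function(cl)
      cl$category == "dominant" &&
        cl$component_classes[match(cl$dominant_drug, cl$components)] == g,
      logical(1)))
    data.frame(class = g, n_combinations = n, n_dominant = ndom,
               pct_dominant = if (n == 0) NA_real_ else 100 * ndom / n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Concentration trace of one treatment in LDA space
#'
#' Projects the treatment's mean profile at each available dose and orders
#' the vertices from the lowest to the highest dose, flagging the endpoints
#' the way dose-trajectory plots mark them.
#'
#' @param profiles Matrix of profiles with one row per dose.
#' @param dose_index Integer dose index per row (1 = C1 highest).
#' @param model An \code{lda_model}.
#' @return \code{data.frame} of ordered vertices (lowest dose first) with
#'   component coordinates and endpoint flags; attribute \code{gaps} lists
#'   missing dose indices within the spanned range.
#' @export
concentration_trace <- function(profiles, dose_index, model) {
  if (length(unique(dose_index)) < 2)
    stop("need >= 2 dose levels for a trace")
  profiles <- as.matrix(profiles)
  agg <- t(vapply(split(seq_along(dose_index), dose_index), function(i)
    colMeans(profiles[i, , drop = FALSE]), numeric(ncol(profiles))))
  idx <- as.integer(rownames(agg))
  coords <- lda_transform(model, agg)
  ord <- order(idx, decreasing = TRUE)   # lowest dose (largest index) first
  out <- data.frame(dose_index = idx[ord], coords[ord, , drop = FALSE])
  names(out)[-1] <- paste0("LD", seq_len(ncol(coords)))
  out$endpoint <- ""
  out$endpoint[1] <- "lowest_dose"
  out$endpoint[nrow(out)] <- "highest_dose"
  attr(out, "gaps") <- setdiff(seq(min(idx), max(idx)), idx)
  out
}
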