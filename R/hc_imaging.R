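#' Morphological background subtraction
#'
#' Estimates the background of a fluorescence channel by grayscale
#' morphological opening with a disc larger than the objects of interest
#' (the rolling-ball equivalent) and subtracts it, flooring at zero. A flat
#' image maps to (approximately) zero, and the operation is idempotent up to
#' quantization.
#'
#' @param channel Numeric matrix of intensities.
#' @param radius Disc radius in pixels; must exceed the typical nucleus
#'   radius.
#' @return Background-subtracted matrix, same shape.
#' @export
subtract_background <- function(channel, radius) {
  if (radius <= 0) stop("radius must be positive")
  mx <- max(channel)
  if (mx <= 0) return(channel * 0)
  brush <- EBImage::makeBrush(2 * as.integer(radius) + 1, shape = "disc")
  # grayscale morphology operates on the [0, 1] scale
  bg <- EBImage::opening(channel / mx, brush) * mx
  pmax(channel - bg, 0)
}

#' Segment nuclei from the nuclear channel
#'
#' Deterministic recipe: Gaussian smoothing, Otsu threshold, then a
#' distance-transform watershed to split touching nuclei, discarding
#' objects below \code{min_area}. Expects a background-subtracted input.
#'
#' @param nuclear_channel Numeric matrix (background-subtracted channel 1).
#' @param min_area Minimum object area in px^2.
#' @param sigma Gaussian smoothing sigma in px.
#' @param tolerance Watershed merge tolerance on the distance transform
#'   (px); smaller values split touching nuclei more aggressively.
#' @return List of class \code{label_map}: \code{labels} (integer matrix, 0
#'   background, objects 1..n contiguously), \code{n_objects}, and
#'   \code{provenance} (parameters used).
#' @export
segment_nuclei <- function(nuclear_channel, min_area = 9, sigma = 2,
                           tolerance = 0.2) {
  mx <- max(nuclear_channel)
  if (mx <= 0) {
    return(structure(list(labels = matrix(0L, nrow(nuclear_channel),
                                          ncol(nuclear_channel)),
                          n_objects = 0L,
                          provenance = list(min_area = min_area,
                                            sigma = sigma,
                                            tolerance = tolerance,
                                            threshold = NA)),
                     class = "label_map"))
  }
  sm <- EBImage::gblur(nuclear_channel / mx, sigma = sigma)
  th <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  mask <- sm > th
  labels <- EBImage::watershed(EBImage::distmap(mask), tolerance = tolerance)
  labels <- matrix(as.integer(EBImage::imageData(labels)),
                   nrow(nuclear_channel), ncol(nuclear_channel))
  sizes <- tabulate(labels)
  keep <- which(sizes >= min_area)
  relabel <- integer(max(labels, 1L))
  relabel[keep] <- seq_along(keep)
  labels[labels > 0] <- relabel[labels[labels > 0]]
  structure(list(labels = labels, n_objects = length(keep),
                 provenance = list(min_area = min_area, sigma = sigma,
                                   tolerance = tolerance, threshold = th)),
            class = "label_map")
}

# Laplacian-of-Gaussian kernel (negative at center; sign-flipped so bright
# spots give positive responses after filtering)
log_kernel <- function(sigma) {
  half <- ceiling(3 * sigma)
  g <- outer(-half:half, -half:half, function(y, x)
    (1 - (x^2 + y^2) / (2 * sigma^2)) * exp(-(x^2 + y^2) / (2 * sigma^2)))
  g - mean(g)
}

#' Count cells by bright-spot detection
#'
#' Emulates microscope-software spot counting: a Laplacian-of-Gaussian
#' blob filter at the nucleus scale followed by local-maximum detection at a
#' threshold relative to the strongest response. The relative threshold
#' makes the count invariant to global intensity rescaling.
#'
#' @param nuclear_channel Numeric matrix (background-subtracted channel 1).
#' @param spot_sigma LoG scale in px (approximately the nucleus radius).
#' @param threshold Relative response threshold in (0, 1).
#' @return Integer spot count.
#' @export
count_cells_brightspot <- function(nuclear_channel, spot_sigma = 3,
                                   threshold = 0.2) {
  if (max(nuclear_channel) <= 0) return(0L)
  resp <- EBImage::filter2(nuclear_channel, log_kernel(spot_sigma))
  resp <- pmax(resp, 0)
  if (max(resp) <= 0) return(0L)
  resp <- resp / max(resp)   # grayscale morphology needs the [0, 1] scale
  # local maxima: pixels equal to the maximum of their neighborhood
  brush <- EBImage::makeBrush(2 * ceiling(spot_sigma) + 1, shape = "disc")
  dil <- EBImage::dilate(resp, brush)
  peaks <- (resp >= dil - 1e-9) & (resp > threshold)
  # collapse plateaus: one count per connected peak component
  as.integer(max(EBImage::bwlabel(peaks)))
}

shannon_entropy <- function(v, bins = 16) {
  if (length(v) < 2 || diff(range(v)) == 0) return(0)
  p <- tabulate(cut(v, bins, labels = FALSE), bins) / length(v)
  p <- p[p > 0]
  -sum(p * log2(p))
}

cooccurrence_stats <- function(img, mask, levels = 8) {
  v <- img[mask]
  if (length(v) < 2 || diff(range(v)) == 0)
    return(c(contrast = 0, homogeneity = 1))
  q <- matrix(NA_integer_, nrow(img), ncol(img))
  q[mask] <- as.integer(cut(v, levels, labels = FALSE))
  # horizontal 1-px offset pairs inside the mask
  a <- q[, -ncol(q)]; b <- q[, -1]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(c(contrast = 0, homogeneity = 1))
  d <- abs(a[ok] - b[ok])
  c(contrast = mean(d^2), homogeneity = mean(1 / (1 + d)))
}

gradient_magnitude <- function(img) {
  gx <- img; gy <- img
  gx[] <- 0; gy[] <- 0
  gx[, -1] <- img[, -1] - img[, -ncol(img)]
  gy[-1, ] <- img[-1, ] - img[-nrow(img), ]
  sqrt(gx^2 + gy^2)
}

hull_area <- function(ys, xs) {
  if (length(ys) < 3) return(length(ys))
  h <- grDevices::chull(xs, ys)
  hx <- xs[h]; hy <- ys[h]
  n <- length(h)
  abs(sum(hx * hy[c(2:n, 1)] - hx[c(2:n, 1)] * hy)) / 2 + length(h) / 2 + 1
}

#' Extract the per-cell feature table
#'
#' Computes the 30-feature registry (see \code{\link{hc_feature_registry}})
#' for every segmented nucleus of a three-channel field: intensity
#' statistics (channel 1 over the nucleus mask, channels 2-3 over the cell
#' mask grown from the nucleus seeds in channel 3), nucleus and cell
#' morphology, gradient and co-occurrence texture, intensity entropy, and
#' the channel-2 mass displacement. Cells touching the image border are
#' excluded from the table but reported in the QC attribute.
#'
#' @param image A \code{synthetic_image} or a rows x cols x 3 numeric
#'   array.
#' @param labels A \code{label_map} from \code{\link{segment_nuclei}} run on
#'   channel 1 of the same field.
#' @return \code{data.frame} with one row per retained cell and one column
#'   per registry feature, plus a \code{cell} id column. Attribute
#'   \code{qc}: list(n_objects, border_dropped, parameters).
#' @export
extract_features <- function(image, labels) {
  px <- if (inherits(image, "synthetic_image")) image$pixels else image
  if (length(dim(px)) != 3 || dim(px)[3] != 3)
    stop("image must have three channels")
  lm <- labels$labels
  if (!all(dim(lm) == dim(px)[1:2]))
    stop("shape mismatch between labels and image")
  n <- labels$n_objects
  registry <- hc_feature_registry()
  if (n == 0) {
    out <- as.data.frame(matrix(numeric(0), 0, length(registry),
                                dimnames = list(NULL, registry)))
    out <- cbind(data.frame(cell = integer(0)), out)
    attr(out, "qc") <- list(n_objects = 0L, border_dropped = 0L)
    return(out)
  }
  ch1 <- px[, , 1]; ch2 <- px[, , 2]; ch3 <- px[, , 3]

  # cell-body mask: grow nucleus seeds through channel 3 above its Otsu level
  mx3 <- max(ch3)
  cell_mask <- ch3 / max(mx3, 1e-9) >
    EBImage::otsu(EBImage::Image(ch3 / max(mx3, 1e-9)), range = c(0, 1))
  cell_mask <- cell_mask | (lm > 0)
  cells <- EBImage::propagate(ch3, EBImage::Image(lm), mask = cell_mask)
  cells <- matrix(as.integer(EBImage::imageData(cells)), nrow(lm), ncol(lm))

  g1 <- gradient_magnitude(ch1); g2 <- gradient_magnitude(ch2)
  g3 <- gradient_magnitude(ch3)
  h <- nrow(lm); w <- ncol(lm)

  border_dropped <- 0L
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    nuc <- lm == k
    idx <- which(nuc, arr.ind = TRUE)
    if (any(idx[, 1] %in% c(1L, h)) || any(idx[, 2] %in% c(1L, w))) {
      border_dropped <- border_dropped + 1L
      next
    }
    cel <- cells == k
    if (!any(cel)) cel <- nuc
    cidx <- which(cel, arr.ind = TRUE)

    istats <- function(chan, mask) {
      v <- chan[mask]
      c(mean(v), stats::median(v), sum(v), if (length(v) > 1) stats::sd(v) else 0)
    }
    i1 <- istats(ch1, nuc); i2 <- istats(ch2, cel); i3 <- istats(ch3, cel)

    nuc_area <- sum(nuc)
    # perimeter: count of 4-neighbor background contacts
    pad <- matrix(FALSE, h + 2, w + 2); pad[2:(h + 1), 2:(w + 1)] <- nuc
    per <- sum(pad[2:(h + 1), 2:(w + 1)] &
                 !(pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
                     pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]))
    mu_y <- mean(idx[, 1]); mu_x <- mean(idx[, 2])
    cyy <- stats::var(idx[, 1]); cxx <- stats::var(idx[, 2])
    cxy <- if (nuc_area > 1) stats::cov(idx[, 1], idx[, 2]) else 0
    tr <- cyy + cxx; det <- cyy * cxx - cxy^2
    disc <- sqrt(max(tr^2 / 4 - det, 0))
    l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
    ecc <- if (l1 <= 0) 0 else sqrt(max(1 - l2 / l1, 0))
    solidity <- min(nuc_area / hull_area(idx[, 1], idx[, 2]), 1)
    cell_area <- sum(cel)

    gstats <- function(g, mask) {
      v <- g[mask]
      c(mean(v), if (length(v) > 1) stats::sd(v) else 0)
    }
    tex1 <- cooccurrence_stats(ch1, nuc)
    # mass displacement of channel 2 over the cell mask
    wsum <- sum(ch2[cel])
    md <- if (wsum > 0) {
      wy <- sum(ch2[cel] * cidx[, 1]) / wsum
      wx <- sum(ch2[cel] * cidx[, 2]) / wsum
      sqrt((wy - mean(cidx[, 1]))^2 + (wx - mean(cidx[, 2]))^2)
    } else 0

    vals <- c(i1, i2, i3,
              nuc_area, per, ecc, solidity, cell_area, nuc_area / cell_area,
              gstats(g1, nuc), gstats(g2, cel), gstats(g3, cel),
              shannon_entropy(ch1[nuc]), shannon_entropy(ch2[cel]),
              shannon_entropy(ch3[cel]),
              tex1[["contrast"]], tex1[["homogeneity"]], md)
    rows[[k]] <- c(cell = k, stats::setNames(vals, registry))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- as.data.frame(do.call(rbind, rows))
  attr(out, "qc") <- list(n_objects = n, border_dropped = border_dropped,
                          parameters = labels$provenance)
  out
}
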