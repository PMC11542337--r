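#' Drug specification for simulated screens
#'
#' Describes one compound in a simulated equimolar combination screen: its
#' class, true Hill dose-response parameters, and the per-feature phenotype
#' shift it induces in the high-content branch.
#'
#' @param name Drug identifier (character scalar).
#' @param drug_class Drug class label; the default screen uses
#'   \code{"mTOR"}, \code{"MT"}, \code{"HSP"}, \code{"PROT"}, \code{"DNA"},
#'   \code{"HDAC"}, but any label is accepted.
#' @param ic50_true True half-maximal inhibitory concentration (uM), > 0.
#' @param hill_slope_true True Hill slope (dimensionless, > 0).
#' @param max_inhibition_true Maximal fractional inhibition in [0, 1].
#' @param phenotype_shift Numeric vector of per-feature effect sizes
#'   (standardized units) with one entry per registry feature, or NULL for
#'   no phenotypic effect.
#' @return An object of class \code{drug_spec}.
#' @export
drug_spec <- function(name, drug_class, ic50_true, hill_slope_true = 1,
                      max_inhibition_true = 1, phenotype_shift = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(drug_class), length(drug_class) == 1L)
  if (!is.numeric(ic50_true) || ic50_true <= 0)
    stop("ic50_true must be a positive concentration (uM)")
  if (!is.numeric(hill_slope_true) || hill_slope_true <= 0)
    stop("hill_slope_true must be > 0")
  if (max_inhibition_true < 0 || max_inhibition_true > 1)
    stop("max_inhibition_true must lie in [0, 1]")
  if (!is.null(phenotype_shift) && any(!is.finite(phenotype_shift)))
    stop("phenotype_shift must be finite")
  structure(list(name = name, drug_class = drug_class,
                 ic50_true = ic50_true, hill_slope_true = hill_slope_true,
                 max_inhibition_true = max_inhibition_true,
                 phenotype_shift = phenotype_shift),
            class = "drug_spec")
}

#' Interaction specification for a simulated drug pair
#'
#' Ground-truth interaction between two drugs, defined on the fractional
#' inhibition scale. \code{bliss_independent} pairs combine by the Bliss
#' product rule; \code{synergistic}/\code{antagonistic} pairs add a signed
#' offset to the Bliss-predicted inhibition; \code{loewe_additive} pairs are
#' sham-like dose-additive combinations solved from the components' Hill
#' curves.
#'
#' @param drug_a,drug_b Names of the two drugs.
#' @param mode One of \code{"bliss_independent"}, \code{"synergistic"},
#'   \code{"antagonistic"}, \code{"loewe_additive"}.
#' @param eob_offset Signed fraction added to the Bliss-predicted inhibition
#'   (must be 0 for \code{bliss_independent} and \code{loewe_additive}).
#' @return An object of class \code{interaction_spec}.
#' @export
interaction_spec <- function(drug_a, drug_b,
                             mode = c("bliss_independent", "synergistic",
                                      "antagonistic", "loewe_additive"),
                             eob_offset = 0) {
  mode <- match.arg(mode)
  if (abs(eob_offset) > 1) stop("|eob_offset| must be <= 1")
  if (mode %in% c("bliss_independent", "loewe_additive") && eob_offset != 0)
    stop("eob_offset must be 0 for mode ", mode)
  if (mode == "synergistic" && eob_offset <= 0)
    stop("synergistic mode requires eob_offset > 0")
  if (mode == "antagonistic" && eob_offset >= 0)
    stop("antagonistic mode requires eob_offset < 0")
  structure(list(drug_a = drug_a, drug_b = drug_b, mode = mode,
                 eob_offset = eob_offset),
            class = "interaction_spec")
}

#' Serial dilution series
#'
#' Builds the screen's dilution design: \code{n_doses} concentrations from
#' the top dose \code{c1} downward by a constant fold factor. Index 1 is the
#' highest dose (labeled C1) and the last index the lowest (C6 in the default
#' 6-dose, 3.5-fold design).
#'
#' @param c1 Highest concentration (uM), > 0.
#' @param n_doses Number of dose levels, >= 2.
#' @param fold Dilution factor between consecutive doses, > 1.
#' @return Named numeric vector of descending doses (names C1, C2, ...).
#' @examples
#' make_dilution_series(10, 6, 3.5)
#' @export
make_dilution_series <- function(c1, n_doses = 6L, fold = 3.5) {
  if (!is.numeric(c1) || c1 <= 0) stop("c1 must be a positive concentration")
  if (!is.numeric(fold) || fold <= 1) stop("fold must be > 1")
  if (n_doses < 2) stop("n_doses must be >= 2")
  doses <- c1 / fold^(seq_len(n_doses) - 1L)
  names(doses) <- paste0("C", seq_len(n_doses))
  doses
}

#' Default 12-drug screen panel
#'
#' Two drugs in each of six classes (mTOR, MT, HSP90, proteasome, DNA,
#' HDAC), mirroring a medium-scale equimolar combination screen. True IC50s
#' are stated relative to the shared 10 uM / 3.5-fold / 6-dose equimolar
#' axis so that most fall between the 3rd and 4th dilution steps; they are
#' invented defaults (no published per-drug potencies exist for this
#' simulated panel) and are meant to be overridden where real calibration is
#' available. Phenotype shift magnitudes are ordered
#' PROT > HSP ~ HDAC > DNA > mTOR > MT so that dominance in the high-content
#' branch has a known ground truth.
#'
#' @param feature_registry Character vector of feature names used to size the
#'   per-drug phenotype shift vectors.
#' @param shift_scale Multiplier applied to all phenotype shifts.
#' @return List of \code{drug_spec} objects.
#' @export
default_screen_drugs <- function(feature_registry = hc_feature_registry(),
                                 shift_scale = 1) {
  p <- length(feature_registry)
  # class phenotype templates: each class perturbs its own block of features
  classes <- c("mTOR", "MT", "HSP", "PROT", "DNA", "HDAC")
  magnitude <- c(mTOR = 1.0, MT = 0.8, HSP = 2.0, PROT = 2.5,
                 DNA = 1.2, HDAC = 2.0)
  block <- split(seq_len(p), rep(seq_along(classes), length.out = p))
  shift_for <- function(cls, jitter) {
    s <- numeric(p)
    idx <- block[[match(cls, classes)]]
    s[idx] <- magnitude[[cls]] * jitter
    s * shift_scale
  }
  mk <- function(name, cls, ic50, h, imax, jitter)
    drug_spec(name, cls, ic50, h, imax, shift_for(cls, jitter))
  list(
    mk("DEF",  "mTOR", 0.90, 1.1, 0.95, +1.0),
    mk("INK",  "mTOR", 0.60, 1.2, 1.00, +0.9),
    mk("PAC",  "MT",   1.20, 1.0, 0.90, +1.0),
    mk("VIN",  "MT",   0.70, 1.1, 0.95, +1.1),
    mk("AAG",  "HSP",  1.00, 1.0, 1.00, +1.0),
    mk("AUY",  "HSP",  0.50, 1.3, 1.00, +0.9),
    mk("PS",   "PROT", 0.40, 1.5, 1.00, +1.0),
    mk("MG",   "PROT", 0.80, 1.2, 1.00, +1.1),
    mk("ETO",  "DNA",  1.50, 0.9, 0.95, +1.0),
    mk("GEM",  "DNA",  0.60, 1.0, 1.00, +0.9),
    mk("PAN",  "HDAC", 0.30, 1.2, 1.00, +1.0),
    mk("SAHA", "HDAC", 1.10, 1.0, 1.00, +1.1)
  )
}

# Hill inhibition I(x) = Imax / (1 + (IC50/x)^h); I(0) = 0.
hill_inhibition <- function(dose, spec) {
  ifelse(dose <= 0, 0,
         spec$max_inhibition_true /
           (1 + (spec$ic50_true / dose)^spec$hill_slope_true))
}

# Loewe dose-additive combined inhibition for an equimolar pair at
# per-component dose d: solve d/D_a(I) + d/D_b(I) = 1 where D(I) is the
# inverse Hill curve. Requires I below both drugs' Imax.
loewe_additive_inhibition <- function(dose, spec_a, spec_b) {
  if (dose <= 0) return(0)
  inv_hill <- function(I, s) {
    # dose producing inhibition I; Inf when I >= Imax
    if (I >= s$max_inhibition_true) return(Inf)
    s$ic50_true * (I / (s$max_inhibition_true - I))^(1 / s$hill_slope_true)
  }
  f <- function(I) dose / inv_hill(I, spec_a) + dose / inv_hill(I, spec_b) - 1
  upper <- min(spec_a$max_inhibition_true, spec_b$max_inhibition_true)
  # if the dose-equivalence sum still exceeds 1 at maximal inhibition the
  # response saturates there; otherwise the root is interior
  if (f(upper * (1 - 1e-12)) > 0) return(upper)
  stats::uniroot(f, c(0, upper * (1 - 1e-12)), tol = 1e-12)$root
}

combined_inhibition <- function(dose, spec_a, spec_b, inter) {
  ia <- hill_inhibition(dose, spec_a)
  ib <- hill_inhibition(dose, spec_b)
  if (!is.null(inter) && inter$mode == "loewe_additive") {
    loewe_additive_inhibition(dose, spec_a, spec_b)
  } else {
    off <- if (is.null(inter)) 0 else inter$eob_offset
    min(max(ia + ib - ia * ib + off, 0), 1)
  }
}

#' Simulate an equimolar combination screen plate
#'
#' Generates endpoint cell counts for every single drug and every unordered
#' drug pair at equimolar per-component doses, plus vehicle-control wells and
#' the shared pre-treatment (time-zero) count. Counts follow
#' \code{x0 * 2^(g * (1 - I)) * eps} where \code{I} is the ground-truth
#' fractional inhibition (Hill for singles; Bliss product rule plus any
#' interaction offset, or Loewe dose additivity, for pairs), \code{g} the
#' number of control doublings over the assay, and \code{eps} multiplicative
#' lognormal noise with the requested coefficient of variation.
#'
#' @param drugs List of \code{drug_spec} objects.
#' @param interactions List of \code{interaction_spec} objects (pairs not
#'   listed default to Bliss independence).
#' @param doses Equimolar dose vector (uM), descending, e.g. from
#'   \code{make_dilution_series}.
#' @param n_replicates Replicates per condition (default 4).
#' @param x0 Pre-treatment cell count per well.
#' @param growth_doublings Control population doublings over the assay.
#' @param noise_cv Coefficient of variation of the multiplicative count
#'   noise (0 for a noiseless plate).
#' @param timepoint_h Endpoint in hours (annotation only).
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A tidy \code{data.frame} of well records with columns
#'   \code{plate, well, drug_a, dose_a_uM, drug_b, dose_b_uM, timepoint_h,
#'   replicate, count}. Vehicle wells have drug "DMSO" at dose 0; time-zero
#'   wells carry \code{timepoint_h = 0}.
#' @export
simulate_plate <- function(drugs, interactions = list(),
                           doses = make_dilution_series(10, 6, 3.5),
                           n_replicates = 4L, x0 = 3000,
                           growth_doublings = 3, noise_cv = 0.05,
                           timepoint_h = 72, seed = 1L) {
  stopifnot(noise_cv >= 0, n_replicates >= 1)
  names(drugs) <- vapply(drugs, function(d) d$name, character(1))
  for (it in interactions) {
    if (!all(c(it$drug_a, it$drug_b) %in% names(drugs)))
      stop("interaction references unknown drug: ",
           paste(setdiff(c(it$drug_a, it$drug_b), names(drugs)),
                 collapse = ", "))
  }
  inter_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")
  imap <- stats::setNames(interactions,
                          vapply(interactions,
                                 function(it) inter_key(it$drug_a, it$drug_b),
                                 character(1)))
  set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  noise <- function(n) if (noise_cv == 0) rep(1, n) else
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)

  rows <- list()
  add <- function(drug_a, dose_a, drug_b, dose_b, inhib, tp) {
    counts <- if (tp == 0) rep(x0, n_replicates) else
      x0 * 2^(growth_doublings * (1 - inhib)) * noise(n_replicates)
    rows[[length(rows) + 1L]] <<- data.frame(
      plate = 1L, well = NA_character_,
      drug_a = drug_a, dose_a_uM = dose_a,
      drug_b = drug_b, dose_b_uM = dose_b,
      timepoint_h = tp, replicate = seq_len(n_replicates),
      count = counts, stringsAsFactors = FALSE)
  }

  add("DMSO", 0, NA_character_, NA_real_, 0, 0)   # shared time-zero round
  add("DMSO", 0, NA_character_, NA_real_, 0, timepoint_h)
  for (d in drugs)
    for (x in doses)
      add(d$name, x, NA_character_, NA_real_, hill_inhibition(x, d),
          timepoint_h)
  nm <- names(drugs)
  if (length(nm) >= 2) {
    for (i in seq_len(length(nm) - 1L)) for (j in (i + 1L):length(nm)) {
      a <- drugs[[i]]; b <- drugs[[j]]
      it <- imap[[inter_key(a$name, b$name)]]
      for (x in doses)
        add(a$name, x, b$name, x, combined_inhibition(x, a, b, it),
            timepoint_h)
    }
  }
  out <- do.call(rbind, rows)
  out$well <- sprintf("W%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Feature registry for the high-content branch
#'
#' Thirty named per-cell features spanning intensity, morphology, and
#' texture for the three reporter channels (nuclear, protein, whole-cell),
#' namespaced as \code{channel.group.metric}. A desk-scale registry: large
#' enough to give KS profiles discriminative structure, small enough to keep
#' simulated screens fast.
#'
#' @return Character vector of 30 feature names.
#' @export
hc_feature_registry <- function() {
  c(paste0("ch", rep(1:3, each = 4), ".intensity.",
           rep(c("mean", "median", "total", "sd"), 3)),
    "nuc.morph.area", "nuc.morph.perimeter", "nuc.morph.eccentricity",
    "nuc.morph.solidity", "cell.morph.area", "nuc.morph.cell_ratio",
    paste0("ch", rep(1:3, each = 2), ".texture.gradient_",
           rep(c("mean", "sd"), 3)),
    paste0("ch", 1:3, ".texture.entropy"),
    "ch1.texture.contrast", "ch1.texture.homogeneity",
    "ch2.intensity.mass_displacement")
}

#' Simulate a per-cell feature table
#'
#' Draws one row per cell from a Gaussian base distribution per feature,
#' translated by \code{dose_scaling * shift} standard deviations. This is the
#' direct fixture for the profiling branch, bypassing image simulation.
#'
#' @param treatment Treatment label stored in the table.
#' @param n_cells Number of cells (rows).
#' @param base_mean,base_sd Per-feature location and scale of the control
#'   distribution (recycled to registry length).
#' @param shift Per-feature effect size vector (standardized units); length
#'   must equal the registry length.
#' @param dose_scaling Fraction in [0, 1] scaling the shift (dose response of
#'   the phenotype).
#' @param registry Feature name registry.
#' @param seed Integer seed.
#' @return \code{data.frame} with a \code{treatment} column and one column
#'   per registry feature.
#' @export
simulate_feature_table <- function(treatment, n_cells, base_mean = 0,
                                   base_sd = 1, shift = NULL,
                                   dose_scaling = 1,
                                   registry = hc_feature_registry(),
                                   seed = 1L) {
  p <- length(registry)
  if (is.null(shift)) shift <- numeric(p)
  if (length(shift) != p)
    stop("shift length (", length(shift), ") must equal registry size (",
         p, ")")
  if (dose_scaling < 0 || dose_scaling > 1)
    stop("dose_scaling must lie in [0, 1]")
  base_mean <- rep_len(base_mean, p)
  base_sd <- rep_len(base_sd, p)
  set.seed(seed)
  m <- matrix(stats::rnorm(n_cells * p), nrow = n_cells)
  m <- sweep(m, 2, base_sd, `*`)
  m <- sweep(m, 2, base_mean + dose_scaling * shift * base_sd, `+`)
  colnames(m) <- registry
  cbind(data.frame(treatment = rep(treatment, n_cells),
                   stringsAsFactors = FALSE),
        as.data.frame(m))
}

#' Simulate a three-channel fluorescence field
#'
#' Renders a synthetic microscopy field with Gaussian-profile nuclei in
#' channel 1, a per-cell reporter intensity in channel 2 drawn from a
#' treatment-shifted distribution, and larger correlated whole-cell blobs in
#' channel 3, over an additive linear background gradient with
#' Poisson-Gaussian noise scaled so that the nuclear spot signal-to-noise
#' ratio is approximately \code{snr}.
#'
#' @param n_cells Number of cells to place (>= 0).
#' @param field_shape Integer c(rows, cols) in pixels.
#' @param snr Peak nuclear amplitude divided by background noise SD (> 0).
#' @param nucleus_radius Gaussian sigma of a nucleus (px).
#' @param cell_radius Gaussian sigma of the whole-cell blob (px).
#' @param min_separation Minimum center-to-center distance (px); use smaller
#'   values to allow overlap. Placement fails with a capacity error when the
#'   field cannot hold \code{n_cells} at this separation.
#' @param ch2_shift Standardized shift of the channel-2 per-cell mean
#'   intensity relative to control (treatment effect).
#' @param bit_depth Integer bit depth of the output (intensities clamped to
#'   \code{[0, 2^bit_depth - 1]}).
#' @param seed Integer seed.
#' @return An object of class \code{synthetic_image}: list with
#'   \code{pixels} (rows x cols x 3 array), \code{truth} (data.frame of cell
#'   records), \code{pixel_size}, \code{bit_depth}, and the background/noise
#'   parameters used.
#' @export
simulate_images <- function(n_cells, field_shape = c(256L, 256L), snr = 10,
                            nucleus_radius = 3, cell_radius = 7,
                            min_separation = 4 * nucleus_radius,
                            ch2_shift = 0, bit_depth = 16L, seed = 1L) {
  if (n_cells < 0) stop("n_cells must be >= 0")
  if (snr <= 0) stop("snr must be > 0")
  set.seed(seed)
  h <- field_shape[1]; w <- field_shape[2]
  margin <- ceiling(3 * nucleus_radius) + 1
  if (h - 2 * margin < 1 || w - 2 * margin < 1)
    stop("field too small for the nucleus radius")

  # rejection-sample centers at the separation constraint
  cy <- numeric(0); cx <- numeric(0); tries <- 0L
  max_tries <- max(2000L, 400L * max(n_cells, 1L))
  while (length(cy) < n_cells) {
    if (tries >= max_tries)
      stop("capacity error: cannot place ", n_cells,
           " cells at min_separation ", min_separation)
    y <- stats::runif(1, margin, h - margin)
    x <- stats::runif(1, margin, w - margin)
    if (!length(cy) || all((cy - y)^2 + (cx - x)^2 >= min_separation^2)) {
      cy <- c(cy, y); cx <- c(cx, x)
    }
    tries <- tries + 1L
  }

  noise_sd <- 20
  amp1 <- snr * noise_sd
  maxval <- 2^bit_depth - 1
  xx_row <- matrix(seq_len(w), h, w, byrow = TRUE)
  bg_level <- 4 * noise_sd
  background <- bg_level * (0.5 + 0.5 * (xx_row - 1) / max(w - 1, 1))

  ch1 <- matrix(0, h, w); ch2 <- matrix(0, h, w); ch3 <- matrix(0, h, w)
  amp2 <- pmax(amp1 * (1 + 0.25 * (ch2_shift + stats::rnorm(max(n_cells, 1)))),
               0.1 * amp1)[seq_len(max(n_cells, 0))]
  amp3 <- amp1 * stats::runif(max(n_cells, 1), 0.6, 1)[seq_len(max(n_cells, 0))]
  if (n_cells > 0) {
    ext <- ceiling(4 * cell_radius)   # render window; tails beyond are ~0
    for (k in seq_len(n_cells)) {
      ry <- max(1, floor(cy[k]) - ext):min(h, ceiling(cy[k]) + ext)
      rx <- max(1, floor(cx[k]) - ext):min(w, ceiling(cx[k]) + ext)
      d2 <- outer((ry - cy[k])^2, (rx - cx[k])^2, `+`)
      ch1[ry, rx] <- ch1[ry, rx] + amp1 * exp(-d2 / (2 * nucleus_radius^2))
      g_c <- exp(-d2 / (2 * cell_radius^2))
      ch2[ry, rx] <- ch2[ry, rx] + amp2[k] * g_c
      ch3[ry, rx] <- ch3[ry, rx] + amp3[k] * g_c
    }
  }
  addnoise <- function(signal) {
    out <- signal + background
    out <- out + stats::rnorm(length(out), 0, noise_sd) +
      (stats::rpois(length(out), pmax(out, 0)) - pmax(out, 0)) * 0.1
    matrix(pmin(pmax(out, 0), maxval), h, w)
  }
  pixels <- array(0, c(h, w, 3))
  pixels[, , 1] <- addnoise(ch1)
  pixels[, , 2] <- addnoise(ch2)
  pixels[, , 3] <- addnoise(ch3)

  truth <- if (n_cells > 0) data.frame(
    cell = seq_len(n_cells), y = cy, x = cx,
    nucleus_radius = nucleus_radius,
    amp_ch1 = amp1, amp_ch2 = amp2, amp_ch3 = amp3,
    integrated_ch1 = amp1 * 2 * pi * nucleus_radius^2)
  else data.frame(cell = integer(0), y = numeric(0), x = numeric(0),
                  nucleus_radius = numeric(0), amp_ch1 = numeric(0),
                  amp_ch2 = numeric(0), amp_ch3 = numeric(0),
                  integrated_ch1 = numeric(0))
  structure(list(pixels = pixels, truth = truth, pixel_size = 0.65,
                 bit_depth = bit_depth, background = background,
                 noise_sd = noise_sd, amp1 = amp1),
            class = "synthetic_image")
}

#' Write a synthetic image and its ground truth to disk
#'
#' @param img A \code{synthetic_image}.
#' @param tiff_path Output TIFF path (three pages, one per channel); requires
#'   the \pkg{tiff} package.
#' @param truth_path Optional CSV path for the truth table.
#' @return Invisibly, the paths written.
#' @export
write_synthetic_image <- function(img, tiff_path, truth_path = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF files")
  maxval <- 2^img$bit_depth - 1
  pages <- lapply(1:3, function(k) img$pixels[, , k] / maxval)
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 16L)
  if (!is.null(truth_path))
    utils::write.csv(img$truth, truth_path, row.names = FALSE)
  invisible(c(tiff_path, truth_path))
}
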