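#' Nuclear morphometry
#'
#' Segmentation of the nuclear channel and per-nucleus geometry: centroid
#' in physical coordinates, axial angle from second central moments,
#' aspect ratio, area and mean marker intensity. Angles are measured
#' counterclockwise from the lateral (tongue-jaw) axis in a frame with y
#' increasing dorsally; sections from the right shelf are mirrored so that
#' "toward the tongue" is the +x direction on both sides.
#'
#' @name morphometry
NULL

#' Segmentation parameters
#'
#' @param smooth_sigma_um Gaussian smoothing sigma before thresholding.
#' @param threshold_method `"otsu"` (per-section global Otsu) or `"fixed"`.
#' @param fixed_threshold intensity threshold when `threshold_method =
#'   "fixed"`.
#' @param min_area_um2,max_area_um2 retained object area range.
#' @param split_method `"distance_watershed"` to split touching nuclei via
#'   a distance-transform watershed, or `"none"` for connected components.
#' @param watershed_tolerance minimum object depth passed to the watershed.
#' @param aspect_min aspect ratio below which a nucleus carries no reliable
#'   axis (`angle_defined = FALSE`).
#' @return list of class `segmentation_params`.
#' @export
segmentation_params <- function(smooth_sigma_um = 0.8,
                                threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                min_area_um2 = 10, max_area_um2 = 150,
                                split_method = c("distance_watershed", "none"),
                                watershed_tolerance = 1,
                                aspect_min = 1.2) {
  threshold_method <- match.arg(threshold_method)
  split_method <- match.arg(split_method)
  if (threshold_method == "fixed" && is.null(fixed_threshold))
    stop("`fixed_threshold` required with threshold_method = 'fixed'")
  if (min_area_um2 <= 0 || min_area_um2 >= max_area_um2)
    stop("need 0 < min_area_um2 < max_area_um2")
  structure(list(smooth_sigma_um = smooth_sigma_um,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 split_method = split_method,
                 watershed_tolerance = watershed_tolerance,
                 aspect_min = aspect_min),
            class = "segmentation_params")
}

#' Segment nuclei from the nuclear channel
#'
#' Gaussian smoothing, global threshold (Otsu by default), hole filling,
#' optional distance-transform watershed to split touching nuclei, then an
#' area filter. Labels are consecutive positive integers; 0 is background.
#'
#' @param nuclear intensity matrix in \[0, 1\] (or a `ps_section`).
#' @param pixel_size_um um per pixel (taken from the section if one is
#'   given).
#' @param params a [segmentation_params()].
#' @return integer label matrix.
#' @export
segment_nuclei <- function(nuclear, pixel_size_um = NULL,
                           params = segmentation_params()) {
  if (inherits(nuclear, "ps_section")) {
    pixel_size_um <- nuclear$pixel_size_um
    nuclear <- nuclear$nuclear
  }
  stopifnot(is.matrix(nuclear), !is.null(pixel_size_um), pixel_size_um > 0)
  if (var(as.vector(nuclear)) == 0) {
    warning("nuclear channel has zero variance; returning empty labeling")
    return(matrix(0L, nrow(nuclear), ncol(nuclear)))
  }
  img <- nuclear
  if (params$smooth_sigma_um > 0)
    img <- EBImage::imageData(
      EBImage::gblur(img, sigma = params$smooth_sigma_um / pixel_size_um))
  th <- if (params$threshold_method == "otsu")
    EBImage::otsu(img, range = c(0, 1)) else params$fixed_threshold
  mask <- img > th
  mask <- EBImage::fillHull(mask)
  labels <- if (params$split_method == "distance_watershed") {
    dm <- EBImage::distmap(mask)
    EBImage::imageData(EBImage::watershed(dm, tolerance = params$watershed_tolerance))
  } else {
    EBImage::imageData(EBImage::bwlabel(mask))
  }
  labels <- matrix(as.integer(labels), nrow(labels))
  # area filter in physical units, then relabel consecutively
  if (max(labels) > 0) {
    px_area <- pixel_size_um^2
    areas <- tabulate(labels) * px_area
    keep <- which(areas >= params$min_area_um2 & areas <= params$max_area_um2)
    remap <- integer(max(labels))
    remap[keep] <- seq_along(keep)
    pos <- labels > 0
    labels[pos] <- remap[labels[pos]]
  }
  labels
}

#' Per-nucleus geometry and marker intensity
#'
#' For each label: centroid in um (physical frame, y up; right-shelf
#' sections are mirrored in x so tongue-ward is +x), area, axial angle
#' `theta = atan2(2 mu11, mu20 - mu02) / 2` from the second central
#' moments mapped to \[0, 180), aspect ratio `sqrt(lambda1 / lambda2)` of
#' the moment matrix, and the mean marker intensity over the nucleus
#' pixels. Nuclei with aspect below `aspect_min` carry `angle_defined =
#' FALSE`; labels touching the image border are retained but flagged.
#'
#' @param labels integer label matrix from [segment_nuclei()].
#' @param marker marker-channel matrix (same dimensions), or `NULL`.
#' @param pixel_size_um um per pixel.
#' @param ps_side `"left"` or `"right"`; right sections are mirrored.
#' @param aspect_min minimum aspect ratio for a defined axis.
#' @return data.frame with one row per nucleus: `nucleus_id`, `x_um`,
#'   `y_um`, `area_um2`, `theta_deg`, `aspect_ratio`, `angle_defined`,
#'   `marker_mean`, `border`, `region`, `positive`.
#' @export
nucleus_features <- function(labels, marker = NULL, pixel_size_um,
                             ps_side = c("left", "right"),
                             aspect_min = 1.2) {
  ps_side <- match.arg(ps_side)
  stopifnot(is.matrix(labels), pixel_size_um > 0)
  nr <- nrow(labels); nc <- ncol(labels)
  idx <- which(labels > 0)
  empty <- data.frame(nucleus_id = character(), x_um = numeric(),
                      y_um = numeric(), area_um2 = numeric(),
                      theta_deg = numeric(), aspect_ratio = numeric(),
                      angle_defined = logical(), marker_mean = numeric(),
                      border = logical(), region = character(),
                      positive = logical(), stringsAsFactors = FALSE)
  if (length(idx) == 0) return(empty)
  lab <- labels[idx]
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  px <- pixel_size_um
  x <- (col - 0.5) * px
  y <- (nr - row + 0.5) * px
  if (ps_side == "right") x <- nc * px - x   # mirror: tongue-ward -> +x
  n <- rowsum(rep(1, length(lab)), lab)
  ids <- as.integer(rownames(n))
  sx <- rowsum(x, lab) / n; sy <- rowsum(y, lab) / n
  mu20 <- rowsum(x^2, lab) / n - sx^2
  mu02 <- rowsum(y^2, lab) / n - sy^2
  mu11 <- rowsum(x * y, lab) / n - sx * sy
  theta <- (0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi) %% 180
  tr <- mu20 + mu02
  disc <- sqrt(pmax((mu20 - mu02)^2 + 4 * mu11^2, 0))
  l1 <- (tr + disc) / 2
  l2 <- pmax((tr - disc) / 2, .Machine$double.eps)
  aspect <- sqrt(l1 / l2)
  marker_mean <- if (is.null(marker)) rep(NA_real_, length(ids)) else
    as.vector(rowsum(marker[idx], lab) / n)
  border <- as.vector(
    rowsum(as.numeric(row == 1L | row == nr | col == 1L | col == nc), lab) > 0)
  data.frame(nucleus_id = sprintf("n%04d", ids),
             x_um = as.vector(sx), y_um = as.vector(sy),
             area_um2 = as.vector(n) * px^2,
             theta_deg = as.vector(theta),
             aspect_ratio = as.vector(aspect),
             angle_defined = as.vector(aspect) >= aspect_min,
             marker_mean = marker_mean, border = border,
             region = NA_character_, positive = NA,
             stringsAsFactors = FALSE)
}

# Otsu threshold on a numeric vector (between-class variance maximization
# over a binned histogram); used for per-section positivity calls.
otsu_threshold <- function(x, n_bins = 256) {
  rng <- range(x)
  if (diff(rng) == 0) return(Inf)
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins)
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h); total <- w[n_bins]
  m <- cumsum(h * mids); mt <- m[n_bins]
  w1 <- w[-n_bins]; w2 <- total - w1
  valid <- w1 > 0 & w2 > 0
  bcv <- rep(-Inf, n_bins - 1)
  bcv[valid] <- ((mt * w1 - m[-n_bins] * total)^2 /
                   (w1 * w2 * total^2))[valid]
  mids[which.max(bcv)]
}

#' Classify marker-positive nuclei
#'
#' Per-section positivity call on the per-nucleus mean marker intensities:
#' Otsu's threshold on the means by default (staining intensity varies
#' section to section, so the threshold is never global), or a fixed
#' threshold. The threshold used is attached as attribute `threshold`.
#'
#' @param nuclei feature table from [nucleus_features()].
#' @param method `"otsu_on_means"` or `"fixed"`.
#' @param threshold fixed threshold when `method = "fixed"`.
#' @return the feature table with the `positive` column filled.
#' @export
classify_positive <- function(nuclei, method = c("otsu_on_means", "fixed"),
                              threshold = NULL) {
  method <- match.arg(method)
  if (nrow(nuclei) == 0) return(nuclei)
  if (any(is.na(nuclei$marker_mean)))
    stop("`marker_mean` must be populated before positivity calls")
  th <- if (method == "fixed") {
    if (is.null(threshold)) stop("`threshold` required for fixed method")
    threshold
  } else {
    if (length(unique(nuclei$marker_mean)) == 1) {
      warning("all marker means identical; classifying all nuclei negative")
      Inf
    } else otsu_threshold(nuclei$marker_mean)
  }
  nuclei$positive <- nuclei$marker_mean > th
  attr(nuclei, "threshold") <- th
  nuclei
}

#' Match segmented nuclei to ground truth
#'
#' Greedy nearest-centroid matching at a distance tolerance; reports
#' precision, recall and F1. Used to score segmentation against the
#' synthetic generator's ground truth.
#'
#' @param nuclei segmented feature table.
#' @param truth ground-truth table from [simulate_section()].
#' @param tol_um matching tolerance (default 5 um).
#' @param ps_side side the features were extracted under; right-side
#'   features are mirrored back before matching.
#' @param width_um section width, needed to undo the mirror.
#' @return list with `f1`, `precision`, `recall`, `n_matched` and the
#'   matched index pairs.
#' @export
match_to_truth <- function(nuclei, truth, tol_um = 5,
                           ps_side = "left", width_um = NULL) {
  x <- nuclei$x_um
  if (ps_side == "right") {
    if (is.null(width_um)) stop("`width_um` required to unmirror right side")
    x <- width_um - x
  }
  if (nrow(nuclei) == 0 || nrow(truth) == 0)
    return(list(f1 = 0, precision = 0, recall = 0, n_matched = 0,
                pairs = cbind(integer(0), integer(0))))
  d <- outer(x, truth$x_um, "-")^2 + outer(nuclei$y_um, truth$y_um, "-")^2
  d <- sqrt(d)
  pairs <- matrix(integer(0), 0, 2)
  repeat {
    m <- which.min(d)
    if (!length(m) || d[m] > tol_um) break
    i <- (m - 1) %% nrow(d) + 1; j <- (m - 1) %/% nrow(d) + 1
    pairs <- rbind(pairs, c(i, j))
    d[i, ] <- Inf; d[, j] <- Inf
  }
  tp <- nrow(pairs)
  precision <- tp / nrow(nuclei); recall <- tp / nrow(truth)
  f1 <- if (tp == 0) 0 else 2 * precision * recall / (precision + recall)
  list(f1 = f1, precision = precision, recall = recall, n_matched = tp,
       pairs = pairs)
}
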