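#' Synthetic two-channel PS section images
#'
#' Emulates a coronal palatal-shelf cryosection: a nuclear channel with
#' elliptical nuclei whose axial orientations follow region-specific
#' doubled-angle von Mises distributions, and a marker channel that is
#' either nuclear (KI-67-like positivity) or a regional intensity field
#' (p-MLC-like). A label mask assigns pixels to hinge / lingual / buccal /
#' epithelium, and a ground-truth table records every placed nucleus, so
#' segmentation, orientation and regional metrics all have
#' parameter-recovery tests.
#'
#' @name synthetic_section
NULL

REGION_LABELS <- c(hinge = 1L, lingual = 2L, buccal = 3L, epithelium = 4L)
MESENCHYME <- c("hinge", "lingual", "buccal")

# default coronal-section geometry (micrometres, y up, tongue-ward = +x):
# a 4 um outside margin, a ventral epithelial strip, a dorsal hinge band,
# and the ventral mesenchyme split into lingual (tongue side, high x) and
# buccal (cheek side, low x).
default_region_polygons <- function(width_um, height_um,
                                    margin_um = 4, epith_um = 8,
                                    hinge_frac = 0.4) {
  w <- width_um; h <- height_um; m <- margin_um
  y_ep <- m + epith_um
  y_hinge <- h - m - hinge_frac * (h - 2 * m)
  rect <- function(x0, x1, y0, y1)
    cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
  list(hinge = rect(m, w - m, y_hinge, h - m),
       lingual = rect(w / 2, w - m, y_ep, y_hinge),
       buccal = rect(m, w / 2, y_ep, y_hinge),
       epithelium = rect(m, w - m, m, y_ep))
}

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Specify a synthetic section
#'
#' All lengths are micrometres; intensities are fractions of the 16-bit
#' full scale. Defaults describe a 250 x 200 um mid-palate field at 0.5
#' um/pixel with about 1.5 nuclei per 1000 um^2, nuclear major axes of
#' 8-12 um at aspect ratios 1.5-2.5, and signal-to-noise around 10.
#'
#' @param width_um,height_um physical extent of the section.
#' @param pixel_size_um sampling (um per pixel).
#' @param regions named list of polygons (`hinge`, `lingual`, `buccal`,
#'   `epithelium`), each an n x 2 matrix of x/y vertices in um; defaults to
#'   a schematic coronal layout.
#' @param nucleus_density nuclei per 1000 um^2 of mesenchyme.
#' @param major_len_um,aspect_range uniform sampling ranges for the full
#'   major-axis length and the major/minor aspect ratio of each nucleus.
#' @param orientation named list per mesenchymal region:
#'   `c(mu = axial mean in degrees, kappa = concentration)`.
#' @param marker_mode `"nuclear_fraction"` (KI-67-like: a designed fraction
#'   of nuclei is marker-bright) or `"regional_field"` (p-MLC-like: the
#'   marker channel is a per-region intensity field).
#' @param positive_fraction named per-region probability that a nucleus is
#'   marker-positive (nuclear_fraction mode).
#' @param region_intensity named per-region mean marker intensity
#'   (regional_field mode).
#' @param intensity background / nuclear foreground / marker foreground
#'   levels as fractions of full scale.
#' @param psf_sigma_um Gaussian point-spread sigma applied to both channels.
#' @param noise_sd additive Gaussian noise SD (intensity fraction); the
#'   default gives SNR of about 10 on the nuclear foreground.
#' @param gain_sd lognormal SD of a per-section staining gain applied to
#'   both channels (section-to-section variability).
#' @param region_jitter_sd lognormal SD of per-section, per-region
#'   variability of the marker signal (biological replicate scatter).
#' @param min_sep_factor hard-core placement distance as a multiple of the
#'   mean major-axis length.
#' @param seed default seed used when [simulate_section()] is called
#'   without one.
#' @return object of class `section_spec`.
#' @export
section_spec <- function(width_um = 250, height_um = 200, pixel_size_um = 0.5,
                         regions = NULL,
                         nucleus_density = 1.5,
                         major_len_um = c(8, 12), aspect_range = c(1.5, 2.5),
                         orientation = list(hinge = c(mu = 60, kappa = 2),
                                            lingual = c(mu = 75, kappa = 3),
                                            buccal = c(mu = 90, kappa = 6)),
                         marker_mode = c("nuclear_fraction", "regional_field"),
                         positive_fraction = c(hinge = 0.30, lingual = 0.45,
                                               buccal = 0.30),
                         region_intensity = c(hinge = 0.375, lingual = 0.20,
                                              buccal = 0.25),
                         intensity = c(background = 0.05, nuclear_fg = 0.60,
                                       marker_fg = 0.70),
                         psf_sigma_um = 0.6, noise_sd = 0.06,
                         gain_sd = 0.05, region_jitter_sd = 0.10,
                         min_sep_factor = 0.8, seed = 1L) {
  marker_mode <- match.arg(marker_mode)
  if (pixel_size_um <= 0) stop("`pixel_size_um` must be positive")
  if (nucleus_density < 0) stop("`nucleus_density` must be non-negative")
  if (is.null(regions))
    regions <- default_region_polygons(width_um, height_um)
  if (!all(MESENCHYME %in% names(regions)))
    stop("`regions` must include hinge, lingual and buccal polygons")
  for (r in MESENCHYME) {
    o <- orientation[[r]]
    if (is.null(o) || o["kappa"] < 0)
      stop("orientation for region ", r, " needs mu and kappa >= 0")
  }
  if (any(positive_fraction < 0 | positive_fraction > 1))
    stop("`positive_fraction` values must lie in [0, 1]")
  structure(list(width_um = width_um, height_um = height_um,
                 pixel_size_um = pixel_size_um, regions = regions,
                 nucleus_density = nucleus_density,
                 major_len_um = major_len_um, aspect_range = aspect_range,
                 orientation = orientation, marker_mode = marker_mode,
                 positive_fraction = positive_fraction,
                 region_intensity = region_intensity,
                 intensity = intensity, psf_sigma_um = psf_sigma_um,
                 noise_sd = noise_sd, gain_sd = gain_sd,
                 region_jitter_sd = region_jitter_sd,
                 min_sep_factor = min_sep_factor, seed = as.integer(seed)),
            class = "section_spec")
}

# rasterize region polygons onto the pixel grid (row 1 = top of image).
# Earlier entries of REGION_LABELS win where polygons share an edge.
rasterize_regions <- function(spec) {
  px <- spec$pixel_size_um
  nc <- round(spec$width_um / px); nr <- round(spec$height_um / px)
  xs <- (seq_len(nc) - 0.5) * px
  ys <- (nr - seq_len(nr) + 0.5) * px
  pts <- cbind(rep(xs, each = nr), rep(ys, times = nc))
  mask <- matrix(0L, nr, nc)
  for (r in names(REGION_LABELS)) {
    poly <- spec$regions[[r]]
    if (is.null(poly)) next
    inside <- mgcv::in.out(rbind(poly, poly[1, ]), pts)
    sel <- inside & mask == 0L
    mask[sel] <- REGION_LABELS[[r]]
  }
  mask
}

# uniform points in a polygon by bounding-box rejection
sample_in_polygon <- function(n, poly, reject = function(x, y) FALSE,
                              max_tries = 500, region = "?") {
  bb <- apply(poly, 2, range)
  out <- matrix(NA_real_, n, 2)
  ring <- rbind(poly, poly[1, ])
  for (i in seq_len(n)) {
    for (try in seq_len(max_tries)) {
      p <- c(runif(1, bb[1, 1], bb[2, 1]), runif(1, bb[1, 2], bb[2, 2]))
      if (mgcv::in.out(ring, matrix(p, 1)) && !reject(p[1], p[2])) {
        out[i, ] <- p; break
      }
    }
    if (is.na(out[i, 1]))
      stop("could not place nucleus ", i, " in region '", region,
           "': rejection budget exhausted (density too high?)")
  }
  out
}

# paint a filled rotated ellipse into `img` (physical frame, y up)
fill_ellipse <- function(img, px, cx, cy, a, b, theta_deg, value) {
  nr <- nrow(img); nc <- ncol(img)
  th <- theta_deg * pi / 180
  r_ext <- max(a, b)
  j0 <- max(1L, floor((cx - r_ext) / px)); j1 <- min(nc, ceiling((cx + r_ext) / px))
  i1 <- min(nr, ceiling(nr - (cy - r_ext) / px + 0.5))
  i0 <- max(1L, floor(nr - (cy + r_ext) / px + 0.5))
  if (j0 > j1 || i0 > i1) return(img)
  jj <- j0:j1; ii <- i0:i1
  xg <- (jj - 0.5) * px - cx
  yg <- (nr - ii + 0.5) * px - cy
  dx <- matrix(xg, length(ii), length(jj), byrow = TRUE)
  dy <- matrix(yg, length(ii), length(jj))
  u <- (cos(th) * dx + sin(th) * dy) / a
  v <- (-sin(th) * dx + cos(th) * dy) / b
  sub <- img[ii, jj, drop = FALSE]
  sub[u^2 + v^2 <= 1] <- value
  img[ii, jj] <- sub
  img
}

#' Simulate a two-channel section with ground truth
#'
#' Places nuclei region by region with hard-core rejection sampling,
#' renders them as filled rotated ellipses in the nuclear channel, builds
#' the marker channel according to the marker mode, then applies the
#' Gaussian PSF, a per-section staining gain, and additive noise clipped to
#' the valid intensity range.
#'
#' @param spec a [section_spec()].
#' @param seed integer seed (defaults to `spec$seed`); fixed seed gives
#'   bit-identical output.
#' @return list of class `ps_section`: `nuclear` and `marker` intensity
#'   matrices in \[0, 1\], integer `mask` (0 outside, 1 hinge, 2 lingual,
#'   3 buccal, 4 epithelium), `truth` (one row per placed nucleus),
#'   `expected` (per-region expected order parameter and marker design),
#'   `pixel_size_um` and `marker_mode`.
#' @export
simulate_section <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "section_spec"))
  set.seed(seed)
  px <- spec$pixel_size_um
  mask <- rasterize_regions(spec)
  nr <- nrow(mask); nc <- ncol(mask)
  mean_major <- mean(spec$major_len_um)
  d_min <- spec$min_sep_factor * mean_major
  placed <- matrix(numeric(0), 0, 2)
  rows <- list()
  for (r in MESENCHYME) {
    poly <- spec$regions[[r]]
    n <- rpois(1, spec$nucleus_density * polygon_area(poly) / 1000)
    if (n == 0) next
    reject <- function(x, y) {
      nrow(placed) > 0 &&
        min((placed[, 1] - x)^2 + (placed[, 2] - y)^2) < d_min^2
    }
    for (i in seq_len(n)) {
      p <- sample_in_polygon(1, poly, reject, region = r)
      placed <- rbind(placed, p)
      o <- spec$orientation[[r]]
      theta <- sample_axial_angles(o[["mu"]], o[["kappa"]], 1)
      major <- runif(1, spec$major_len_um[1], spec$major_len_um[2])
      aspect <- runif(1, spec$aspect_range[1], spec$aspect_range[2])
      positive <- if (spec$marker_mode == "nuclear_fraction")
        runif(1) < spec$positive_fraction[[r]] else NA
      rows[[length(rows) + 1L]] <- data.frame(
        region = r, x_um = p[1], y_um = p[2], theta_deg = theta,
        major_um = major, minor_um = major / aspect, aspect = aspect,
        positive = positive, stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region = character(), x_um = numeric(), y_um = numeric(),
               theta_deg = numeric(), major_um = numeric(),
               minor_um = numeric(), aspect = numeric(), positive = logical())
  if (nrow(truth))
    truth <- cbind(nucleus_id = sprintf("n%04d", seq_len(nrow(truth))), truth)
  rownames(truth) <- NULL

  bg <- spec$intensity[["background"]]
  nuc <- matrix(bg, nr, nc)
  for (i in seq_len(nrow(truth))) {
    bright <- spec$intensity[["nuclear_fg"]] * runif(1, 0.85, 1.15)
    nuc <- fill_ellipse(nuc, px, truth$x_um[i], truth$y_um[i],
                        truth$major_um[i] / 2, truth$minor_um[i] / 2,
                        truth$theta_deg[i], bright)
  }
  jit <- exp(rnorm(length(MESENCHYME), 0, spec$region_jitter_sd))
  names(jit) <- MESENCHYME
  if (spec$marker_mode == "nuclear_fraction") {
    mark <- matrix(bg, nr, nc)
    pos <- which(!is.na(truth$positive) & truth$positive)
    for (i in pos) {
      bright <- spec$intensity[["marker_fg"]] * jit[[truth$region[i]]] *
        runif(1, 0.85, 1.15)
      mark <- fill_ellipse(mark, px, truth$x_um[i], truth$y_um[i],
                           truth$major_um[i] / 2, truth$minor_um[i] / 2,
                           truth$theta_deg[i], bright)
    }
  } else {
    mark <- matrix(bg, nr, nc)
    for (r in MESENCHYME)
      mark[mask == REGION_LABELS[[r]]] <- spec$region_intensity[[r]] * jit[[r]]
  }
  gain <- exp(rnorm(1, 0, spec$gain_sd))
  nuc <- nuc * gain; mark <- mark * gain
  if (spec$psf_sigma_um > 0) {
    s <- spec$psf_sigma_um / px
    nuc <- EBImage::imageData(EBImage::gblur(nuc, sigma = s))
    mark <- EBImage::imageData(EBImage::gblur(mark, sigma = s))
  }
  if (spec$noise_sd > 0) {
    nuc <- nuc + rnorm(length(nuc), 0, spec$noise_sd)
    mark <- mark + rnorm(length(mark), 0, spec$noise_sd)
  }
  nuc <- pmin(pmax(nuc, 0), 1); mark <- pmin(pmax(mark, 0), 1)

  expected <- data.frame(
    region = MESENCHYME,
    expected_S = vapply(MESENCHYME, function(r)
      expected_order_parameter(spec$orientation[[r]][["kappa"]]), 0),
    mu_deg = vapply(MESENCHYME, function(r)
      spec$orientation[[r]][["mu"]], 0),
    designed_positive_fraction = if (spec$marker_mode == "nuclear_fraction")
      unname(spec$positive_fraction[MESENCHYME]) else NA_real_,
    designed_intensity = if (spec$marker_mode == "regional_field")
      unname(spec$region_intensity[MESENCHYME]) else NA_real_,
    stringsAsFactors = FALSE)
  structure(list(nuclear = nuc, marker = mark, mask = mask, truth = truth,
                 expected = expected, pixel_size_um = px,
                 marker_mode = spec$marker_mode, seed = seed, spec = spec),
            class = "ps_section")
}

#' Write / read a simulated section as TIFF + CSV
#'
#' The image is a two-page 16-bit TIFF (page 1 nuclear, page 2 marker); the
#' mask a single-page 8-bit label TIFF (labels 0-4); the ground truth a
#' CSV. Pixel size is not stored in the TIFF and must accompany the files
#' (the pipeline records it in the run manifest).
#'
#' @param section a `ps_section`.
#' @param image_path,mask_path,truth_path output paths (`NULL` to skip the
#'   ground truth).
#' @export
write_section_tiff <- function(section, image_path, mask_path,
                               truth_path = NULL) {
  tiff::writeTIFF(list(section$nuclear, section$marker), image_path,
                  bits.per.sample = 16, compression = "none")
  tiff::writeTIFF(section$mask / 255, mask_path,
                  bits.per.sample = 8, compression = "none")
  if (!is.null(truth_path))
    write.csv(section$truth, truth_path, row.names = FALSE)
  invisible(image_path)
}

#' @rdname write_section_tiff
#' @param pixel_size_um pixel size of the stored section.
#' @param marker_mode marker interpretation of channel 2.
#' @return `read_section_tiff` returns a `ps_section` without ground truth.
#' @export
read_section_tiff <- function(image_path, mask_path, pixel_size_um,
                              marker_mode = "nuclear_fraction") {
  pages <- tiff::readTIFF(image_path, all = TRUE)
  if (length(pages) < 2)
    stop("section TIFF must have 2 pages (nuclear, marker)")
  mask <- round(tiff::readTIFF(mask_path) * 255)
  if (!all(dim(mask) == dim(pages[[1]])))
    stop(sprintf("mask dimensions (%d x %d) do not match image (%d x %d)",
                 nrow(mask), ncol(mask), nrow(pages[[1]]), ncol(pages[[1]])))
  structure(list(nuclear = pages[[1]], marker = pages[[2]],
                 mask = matrix(as.integer(mask), nrow(mask)),
                 truth = NULL, pixel_size_um = pixel_size_um,
                 marker_mode = marker_mode),
            class = "ps_section")
}
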