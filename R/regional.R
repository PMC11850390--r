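#' Regional quantification
#'
#' Assignment of nuclei to the hinge / lingual / buccal mesenchymal
#' regions and the deviation-from-mean metrics: per-region KI-67 positive
#' fraction minus the section-wide fraction (per nucleus), and per-region
#' p-MLC mean intensity minus the section-wide mean (per pixel). Group and
#' region contrasts use Welch t-tests with the section as the independent
#' unit.
#'
#' @name regional_quant
NULL

#' Assign nuclei to mask regions
#'
#' The region is the mask label at the nucleus centroid pixel; epithelium
#' (label 4) and outside (0) map to `"excluded"`, as do centroids that fall
#' outside the image bounds (with a warning).
#'
#' @param nuclei feature table from [nucleus_features()].
#' @param mask integer region mask (0 outside, 1 hinge, 2 lingual,
#'   3 buccal, 4 epithelium).
#' @param pixel_size_um um per pixel of the mask.
#' @param ps_side side the features were extracted under; right-side
#'   centroids are mirrored back to the raster frame for the lookup.
#' @return the feature table with the `region` column filled.
#' @export
assign_regions <- function(nuclei, mask, pixel_size_um,
                           ps_side = c("left", "right")) {
  ps_side <- match.arg(ps_side)
  if (nrow(nuclei) == 0) return(nuclei)
  px <- pixel_size_um
  nr <- nrow(mask); nc <- ncol(mask)
  x <- nuclei$x_um
  if (ps_side == "right") x <- nc * px - x
  col <- pmax(1L, pmin(nc, as.integer(ceiling(x / px))))
  row <- pmax(1L, pmin(nr, as.integer(ceiling(nr - nuclei$y_um / px))))
  oob <- x < 0 | x > nc * px | nuclei$y_um < 0 | nuclei$y_um > nr * px
  if (any(oob))
    warning(sum(oob), " centroid(s) outside image bounds; excluded")
  lab <- mask[cbind(row, col)]
  region_names <- c("excluded", names(REGION_LABELS))[lab + 1L]
  region_names[lab == REGION_LABELS[["epithelium"]]] <- "excluded"
  region_names[oob] <- "excluded"
  nuclei$region <- region_names
  nuclei
}

new_region_deviation <- function(section_id, metric, region, value,
                                 section_mean, n_basis) {
  data.frame(section_id = section_id, region = region, metric = metric,
             value = value, section_mean = section_mean,
             deviation = value - section_mean, n_basis = n_basis,
             stringsAsFactors = FALSE)
}

#' Regional proliferation deviation (KI-67)
#'
#' Per-region marker-positive fraction minus the section-wide fraction
#' over all non-excluded nuclei. The fraction (rather than the raw count)
#' makes sections of different sizes comparable; raw positive counts are
#' emitted alongside. Empty regions are omitted with a warning.
#'
#' @param nuclei feature table with `region` and `positive` filled.
#' @param section_id label recorded on the output rows.
#' @return data.frame of `RegionDeviation` rows (`metric =
#'   "ki67_fraction"`), with an extra `n_positive` column.
#' @export
proliferation_deviation <- function(nuclei, section_id = "section") {
  use <- nuclei[!is.na(nuclei$region) & nuclei$region != "excluded", ]
  if (nrow(use) == 0) stop("no non-excluded nuclei")
  if (any(is.na(use$positive))) stop("positivity must be classified first")
  section_mean <- mean(use$positive)
  regions <- intersect(MESENCHYME, unique(use$region))
  missing <- setdiff(MESENCHYME, regions)
  if (length(missing))
    warning("region(s) with no nuclei omitted: ",
            paste(missing, collapse = ", "))
  out <- do.call(rbind, lapply(regions, function(r) {
    sel <- use$region == r
    d <- new_region_deviation(section_id, "ki67_fraction", r,
                              mean(use$positive[sel]), section_mean,
                              sum(sel))
    d$n_positive <- sum(use$positive[sel])
    d
  }))
  rownames(out) <- NULL
  out
}

#' Regional intensity deviation (p-MLC)
#'
#' Per-region mean marker intensity over mesenchymal pixels minus the mean
#' over all mesenchymal pixels (epithelium and outside excluded). Regions
#' absent from the mask are omitted.
#'
#' @param marker marker-channel matrix (or a `ps_section`, whose marker
#'   channel and mask are used).
#' @param mask integer region mask.
#' @param section_id label recorded on the output rows.
#' @return data.frame of `RegionDeviation` rows (`metric =
#'   "pmlc_intensity"`).
#' @export
intensity_deviation <- function(marker, mask = NULL, section_id = "section") {
  if (inherits(marker, "ps_section")) {
    mask <- marker$mask
    marker <- marker$marker
  }
  stopifnot(is.matrix(marker), all(dim(marker) == dim(mask)))
  mes <- mask %in% REGION_LABELS[MESENCHYME]
  if (!any(mes)) stop("mask contains no mesenchymal pixels")
  section_mean <- mean(marker[mes])
  rows <- lapply(MESENCHYME, function(r) {
    sel <- mask == REGION_LABELS[[r]]
    if (!any(sel)) return(NULL)
    new_region_deviation(section_id, "pmlc_intensity", r,
                         mean(marker[sel]), section_mean, sum(sel))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare regional values across sections
#'
#' Welch t-test on per-section values, the section being the independent
#' unit. Either a two-group contrast within one region (`groups` gives the
#' two levels of `deviations$group`) or a two-region contrast
#' (`regions` gives the two region names, optionally within one group).
#'
#' @param deviations stacked `RegionDeviation` rows across sections; a
#'   `group` column is required for group contrasts.
#' @param region region for a between-group contrast.
#' @param groups character pair of group labels.
#' @param regions character pair of region labels for a within-group
#'   region contrast.
#' @param group optional single group to restrict a region contrast to.
#' @param value_col column carrying the per-section value (default
#'   `"deviation"`).
#' @return a `ps_test`; contrasts with fewer than 2 sections per side are
#'   refused.
#' @export
group_compare <- function(deviations, region = NULL, groups = NULL,
                          regions = NULL, group = NULL,
                          value_col = "deviation") {
  if (!is.null(groups)) {
    stopifnot(length(groups) == 2, !is.null(region),
              "group" %in% names(deviations))
    a <- deviations[deviations$region == region &
                      deviations$group == groups[1], value_col]
    b <- deviations[deviations$region == region &
                      deviations$group == groups[2], value_col]
    label <- paste0(region, ": ", groups[1], " vs ", groups[2])
  } else if (!is.null(regions)) {
    stopifnot(length(regions) == 2)
    d <- deviations
    if (!is.null(group)) d <- d[d$group == group, ]
    a <- d[d$region == regions[1], value_col]
    b <- d[d$region == regions[2], value_col]
    label <- paste0(regions[1], " vs ", regions[2])
  } else stop("give either `groups` (with `region`) or `regions`")
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 sections per side of the contrast (", label, ")")
  res <- welch_t_test(a, b)
  res$note <- label
  res
}
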