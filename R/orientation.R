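#' Orientation statistics on nuclear angles
#'
#' Regional wedge-diagram numbers (axial mean and SD), the global and
#' neighborhood-local nematic order parameter S, and the signed tilt of the
#' mean axis toward the tongue. Only nuclei with a defined axis
#' (`angle_defined`) enter these statistics.
#'
#' @name orientation_stats
NULL

#' Local nematic order parameter
#'
#' For each nucleus, `S_i` is the global order parameter of the
#' angle-defined neighbors within `radius_um` of its centroid (the nucleus
#' itself excluded); `S_i` is undefined when fewer than `min_neighbors`
#' neighbors are available. The per-region value is the mean of the defined
#' `S_i` over nuclei assigned to that region.
#'
#' @param nuclei feature table with centroids, angles and regions.
#' @param radius_um neighborhood radius (default 25 um, about two cell
#'   diameters).
#' @param min_neighbors minimum neighbors for a defined `S_i` (default 4).
#' @return list with `per_nucleus` (nucleus_id, n_neighbors, S_local) and
#'   `per_region` (region, S_local_mean, n_used).
#' @export
order_parameter_local <- function(nuclei, radius_um = 25, min_neighbors = 4) {
  n <- nrow(nuclei)
  S_local <- rep(NA_real_, n)
  n_nb <- integer(n)
  def <- which(!is.na(nuclei$angle_defined) & nuclei$angle_defined)
  if (length(def) >= 2 && n >= 1) {
    for (i in seq_len(n)) {
      d2 <- (nuclei$x_um[def] - nuclei$x_um[i])^2 +
        (nuclei$y_um[def] - nuclei$y_um[i])^2
      nb <- def[d2 <= radius_um^2 & def != i]
      n_nb[i] <- length(nb)
      if (length(nb) >= max(min_neighbors, 2))
        S_local[i] <- order_parameter_global(nuclei$theta_deg[nb])
    }
  }
  per_nucleus <- data.frame(nucleus_id = nuclei$nucleus_id,
                            n_neighbors = n_nb, S_local = S_local,
                            stringsAsFactors = FALSE)
  regions <- if ("region" %in% names(nuclei))
    setdiff(unique(nuclei$region), c(NA, "excluded")) else character(0)
  per_region <- do.call(rbind, lapply(regions, function(r) {
    sel <- which(nuclei$region == r & !is.na(S_local))
    data.frame(region = r,
               S_local_mean = if (length(sel)) mean(S_local[sel]) else NA_real_,
               n_used = length(sel), stringsAsFactors = FALSE)
  }))
  if (is.null(per_region))
    per_region <- data.frame(region = character(), S_local_mean = numeric(),
                             n_used = integer())
  list(per_nucleus = per_nucleus, per_region = per_region)
}

#' Signed tilt of the mean axis toward the tongue
#'
#' In the side-normalized frame (tongue-ward = +x, dorsal = +y) the tilt is
#' `90 - mean_angle_deg`: 0 for a perfectly dorsoventral (vertical) mean
#' axis, +90 for a horizontal axis pointing at the tongue, negative when
#' the axis leans away from the tongue. For raw right-shelf angles (not
#' mirrored), pass `ps_side = "right"` to flip the sign convention.
#'
#' @param mean_angle_deg axial mean angle in \[0, 180).
#' @param ps_side side of the frame the angle was measured in;
#'   side-normalized angles (the package default) use `"left"`.
#' @return signed tilt in degrees, in \[-90, 90\].
#' @export
tilt_toward_tongue <- function(mean_angle_deg, ps_side = c("left", "right")) {
  ps_side <- match.arg(ps_side)
  if (any(!is.finite(mean_angle_deg))) return(NA_real_)
  tilt <- 90 - (mean_angle_deg %% 180)
  if (ps_side == "right") tilt <- -tilt
  tilt
}

#' Per-region orientation summary (wedge-diagram numbers)
#'
#' Axial mean angle and SD, global order parameter, neighborhood-local
#' order parameter and tongue-ward tilt for each mesenchymal region, using
#' only angle-defined nuclei.
#'
#' @param nuclei feature table with regions assigned (angles already
#'   side-normalized).
#' @param radius_um,min_neighbors passed to [order_parameter_local()].
#' @return data.frame with one row per region: `region`, `n_used`,
#'   `mean_angle_deg`, `axial_sd_deg`, `S_global`, `S_local_mean`,
#'   `tilt_deg`.
#' @export
orientation_summary <- function(nuclei, radius_um = 25, min_neighbors = 4) {
  loc <- order_parameter_local(nuclei, radius_um, min_neighbors)
  regions <- setdiff(unique(nuclei$region), c(NA, "excluded"))
  rows <- lapply(sort(regions), function(r) {
    sel <- nuclei$region == r & nuclei$angle_defined
    ang <- nuclei$theta_deg[sel]
    if (sum(sel) < 2) {
      return(data.frame(region = r, n_used = sum(sel),
                        mean_angle_deg = NA_real_, axial_sd_deg = NA_real_,
                        S_global = NA_real_, S_local_mean = NA_real_,
                        tilt_deg = NA_real_, stringsAsFactors = FALSE))
    }
    ms <- axial_mean_sd(ang)
    lrow <- loc$per_region[loc$per_region$region == r, ]
    data.frame(region = r, n_used = ms$n,
               mean_angle_deg = ms$mean_angle_deg,
               axial_sd_deg = ms$axial_sd_deg,
               S_global = ms$R2,
               S_local_mean = if (nrow(lrow)) lrow$S_local_mean else NA_real_,
               tilt_deg = if (ms$defined) tilt_toward_tongue(ms$mean_angle_deg)
                          else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
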