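#' End-to-end pipeline runs
#'
#' Orchestration from raw inputs (or simulation) to result tables. Every
#' run writes its outputs under a single directory together with a JSON
#' manifest recording the seed and the full parameter set, so a fixed
#' config + seed reproduces a run exactly. A thin command-line wrapper
#' over these functions ships in `inst/cli/palatelev`.
#'
#' @name pipeline_cli
NULL

write_manifest <- function(out_dir, command, params, extra = list()) {
  manifest <- c(list(command = command, package = "palatelev",
                     version = as.character(utils::packageVersion("palatelev")),
                     params = params), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
}

#' Read a pipeline configuration file
#'
#' YAML or JSON (decided by extension), returned as a nested list. The
#' schema mirrors the arguments of [cohort_design()], [section_spec()] and
#' [segmentation_params()].
#'
#' @param path config file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

#' Simulate a cohort and write it to disk
#'
#' @param design a [cohort_design()].
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @return path of the records CSV, invisibly.
#' @export
run_simulate_cohort <- function(design, out_dir, seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  records <- simulate_cohort(design, seed)
  path <- file.path(out_dir, "records.csv")
  write.csv(records, path, row.names = FALSE)
  write_manifest(out_dir, "simulate-cohort",
                 list(seed = seed, strata = design$strata,
                      p_left_given_unilateral = design$p_left_given_unilateral),
                 list(n_records = nrow(records)))
  invisible(path)
}

#' Simulate a section and write image, mask and ground truth
#'
#' @param spec a [section_spec()].
#' @param out_dir output directory.
#' @param seed integer seed (defaults to `spec$seed`).
#' @return list of written paths, invisibly.
#' @export
run_simulate_section <- function(spec, out_dir, seed = spec$seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  section <- simulate_section(spec, seed)
  paths <- list(image = file.path(out_dir, "section.tif"),
                mask = file.path(out_dir, "mask.tif"),
                truth = file.path(out_dir, "truth.csv"))
  write_section_tiff(section, paths$image, paths$mask, paths$truth)
  params <- unclass(spec)
  params$regions <- lapply(params$regions, function(p) apply(p, 2, c))
  write_manifest(out_dir, "simulate-section", c(params, list(seed = seed)),
                 list(n_nuclei = nrow(section$truth)))
  invisible(paths)
}

#' Staging statistics end to end
#'
#' Tabulates a records table (or CSV path), writes the stage table and
#' integer percentages, sex contrasts for every stratum observed in both
#' sexes, an elevation-window report per strain, and the side-preference
#' test over unilateral records.
#'
#' @param records embryo records data.frame or CSV path.
#' @param out_dir output directory.
#' @param completion_threshold passed to [elevation_window()].
#' @return list of result data.frames, invisibly; all are also written as
#'   CSV.
#' @export
run_stage_stats <- function(records, out_dir, completion_threshold = 0.75) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(records)) records <- read_embryo_records(records)
  tab <- tabulate_stages(records)
  pct <- stage_percentages(tab)
  tab_sex <- tabulate_stages(records, by_sex = TRUE)
  # sex contrasts wherever both sexes were scored
  strata <- unique(as.data.frame(tab)[, c("strain", "age_days")])
  contrasts <- list()
  for (i in seq_len(nrow(strata))) {
    st <- strata[i, ]
    sexes <- tab_sex$sex[tab_sex$strain == st$strain &
                           tab_sex$age_days == st$age_days]
    if (!all(c("male", "female") %in% sexes)) next
    for (g in c("elevated_vs_rest", "unelevated_vs_rest")) {
      res <- sex_contrast(tab_sex, st$strain, st$age_days, grouping = g)
      contrasts[[length(contrasts) + 1L]] <- data.frame(
        strain = st$strain, age_days = st$age_days, grouping = g,
        odds_ratio = res$statistic, p_value = res$p_value,
        degenerate = res$degenerate, stringsAsFactors = FALSE)
    }
  }
  contrasts <- if (length(contrasts)) do.call(rbind, contrasts) else
    data.frame(strain = character(), age_days = numeric(),
               grouping = character(), odds_ratio = numeric(),
               p_value = numeric(), degenerate = logical())
  windows <- do.call(rbind, lapply(unique(tab$strain), function(s) {
    if (sum(tab$strain == s) < 2) return(NULL)
    w <- tryCatch(
      suppressWarnings(elevation_window(tab, s, completion_threshold)),
      error = function(e) NULL)
    if (is.null(w)) return(NULL)
    as.data.frame(w, stringsAsFactors = FALSE)
  }))
  side <- side_preference(records)
  side_df <- data.frame(n_left = unname(side$statistic),
                        n_unilateral = unname(side$table_or_n[["n"]]),
                        p_value = side$p_value, degenerate = side$degenerate)
  write.csv(as.data.frame(tab), file.path(out_dir, "stage_table.csv"),
            row.names = FALSE)
  write.csv(pct, file.path(out_dir, "stage_percentages.csv"), row.names = FALSE)
  write.csv(contrasts, file.path(out_dir, "sex_contrasts.csv"), row.names = FALSE)
  if (!is.null(windows))
    write.csv(windows, file.path(out_dir, "elevation_windows.csv"),
              row.names = FALSE)
  write.csv(side_df, file.path(out_dir, "side_preference.csv"), row.names = FALSE)
  write_manifest(out_dir, "stage-stats",
                 list(completion_threshold = completion_threshold,
                      n_records = nrow(records)))
  invisible(list(stage_table = tab, percentages = pct,
                 sex_contrasts = contrasts, windows = windows,
                 side_preference = side_df))
}

#' Quantify one section end to end
#'
#' Segments the nuclear channel, extracts features, assigns regions,
#' classifies positivity (nuclear-marker mode), and writes the nucleus
#' table, the per-region orientation summary and the regional deviation
#' table, together with a provenance JSON recording parameters, chosen
#' thresholds and counts.
#'
#' @param section a `ps_section`, or the path of a two-page section TIFF.
#' @param mask mask matrix or label-TIFF path (ignored when `section` is a
#'   `ps_section`).
#' @param out_dir output directory.
#' @param pixel_size_um pixel size (required when reading from TIFF).
#' @param marker_mode `"nuclear_fraction"` (KI-67) or `"regional_field"`
#'   (p-MLC).
#' @param ps_side shelf side of the section.
#' @param params a [segmentation_params()].
#' @param section_id label for the output rows.
#' @param radius_um,min_neighbors local order parameter settings.
#' @return list with `nuclei`, `orientation`, `deviations`, invisibly.
#' @export
run_quantify_section <- function(section, mask = NULL, out_dir,
                                 pixel_size_um = NULL,
                                 marker_mode = NULL,
                                 ps_side = "left",
                                 params = segmentation_params(),
                                 section_id = "section",
                                 radius_um = 25, min_neighbors = 4) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(section)) {
    if (is.null(pixel_size_um))
      stop("`pixel_size_um` is required when reading a section from TIFF")
    section <- read_section_tiff(section, mask, pixel_size_um,
                                 marker_mode %||% "nuclear_fraction")
  }
  stopifnot(inherits(section, "ps_section"))
  marker_mode <- marker_mode %||% section$marker_mode
  px <- section$pixel_size_um
  if (!all(dim(section$mask) == dim(section$nuclear)))
    stop(sprintf("mask (%d x %d) does not match image (%d x %d)",
                 nrow(section$mask), ncol(section$mask),
                 nrow(section$nuclear), ncol(section$nuclear)))
  labels <- segment_nuclei(section$nuclear, px, params)
  nuclei <- nucleus_features(labels, section$marker, px, ps_side = ps_side,
                             aspect_min = params$aspect_min)
  nuclei <- assign_regions(nuclei, section$mask, px, ps_side = ps_side)
  threshold <- NA_real_
  if (marker_mode == "nuclear_fraction" && nrow(nuclei) > 0) {
    nuclei <- classify_positive(nuclei)
    threshold <- attr(nuclei, "threshold")
  }
  orient <- orientation_summary(nuclei, radius_um, min_neighbors)
  deviations <- if (marker_mode == "nuclear_fraction") {
    proliferation_deviation(nuclei, section_id)
  } else {
    intensity_deviation(section$marker, section$mask, section_id)
  }
  write.csv(nuclei, file.path(out_dir, "nuclei.csv"), row.names = FALSE)
  write.csv(orient, file.path(out_dir, "orientation_summary.csv"),
            row.names = FALSE)
  write.csv(deviations, file.path(out_dir, "region_deviations.csv"),
            row.names = FALSE)
  write_manifest(out_dir, "quantify-section",
                 list(pixel_size_um = px, marker_mode = marker_mode,
                      ps_side = ps_side, segmentation = unclass(params),
                      radius_um = radius_um, min_neighbors = min_neighbors),
                 list(n_nuclei = nrow(nuclei),
                      positivity_threshold = threshold,
                      n_regions = nrow(deviations)))
  invisible(list(nuclei = nuclei, orientation = orient,
                 deviations = deviations))
}

#' Compare groups of quantified sections
#'
#' Stacks per-section regional deviation tables (which must carry a
#' `group` column) and runs the requested Welch contrasts: every region
#' between the two groups, and optionally all region pairs within each
#' group.
#'
#' @param deviations stacked deviation rows with a `group` column, or a
#'   vector of CSV paths.
#' @param out_dir output directory.
#' @param within_regions also contrast region pairs within each group.
#' @return data.frame of contrasts (one row each), invisibly; written as
#'   `contrasts.csv`.
#' @export
run_compare_groups <- function(deviations, out_dir, within_regions = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(deviations))
    deviations <- do.call(rbind, lapply(deviations, read.csv,
                                        stringsAsFactors = FALSE))
  if (!"group" %in% names(deviations))
    stop("deviation rows must carry a `group` column")
  groups <- unique(deviations$group)
  if (length(groups) != 2) stop("need exactly 2 groups")
  rows <- list()
  for (r in intersect(MESENCHYME, unique(deviations$region))) {
    res <- tryCatch(group_compare(deviations, region = r, groups = groups),
                    error = function(e) NULL)
    if (is.null(res)) next
    rows[[length(rows) + 1L]] <- data.frame(
      contrast = res$note, region = r, t = res$statistic, df = res$df,
      p_value = res$p_value, stringsAsFactors = FALSE)
  }
  if (within_regions) {
    prs <- utils::combn(MESENCHYME, 2)
    for (g in groups) for (k in seq_len(ncol(prs))) {
      res <- tryCatch(group_compare(deviations, regions = prs[, k], group = g),
                      error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <- data.frame(
        contrast = paste0(g, ": ", res$note), region = NA_character_,
        t = res$statistic, df = res$df, p_value = res$p_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contrast = character(), region = character(), t = numeric(),
               df = numeric(), p_value = numeric())
  write.csv(out, file.path(out_dir, "contrasts.csv"), row.names = FALSE)
  write_manifest(out_dir, "compare-groups",
                 list(groups = groups, within_regions = within_regions),
                 list(n_contrasts = nrow(out)))
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
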