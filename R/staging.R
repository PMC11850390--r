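#' Staging analytics for palatal shelf elevation cohorts
#'
#' Tabulation of elevation stages over strain/age(/sex) strata, integer
#' percentage summaries, exact sex contrasts, elevation-window estimation
#' and the left/right side-preference test.
#'
#' @name staging_analysis
NULL

# round half away from zero (the reporting convention for the printed
# integer percentages; base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Construct a stage table
#'
#' One row per stratum with counts of the three stages. Counts may be `NA`
#' for partially reported strata as long as `n_total` is given; when all
#' three counts are present they must sum to `n_total`.
#'
#' @param df data.frame with columns `strain`, `age_days`, `sex`
#'   (use `"all"` for pooled rows), `n_unelevated`, `n_unilateral`,
#'   `n_elevated`, `n_total`.
#' @return the validated data.frame with class `stage_table`.
#' @export
stage_table <- function(df) {
  need <- c("strain", "age_days", "sex", "n_unelevated", "n_unilateral",
            "n_elevated", "n_total")
  if (!all(need %in% names(df)))
    stop("stage table needs columns: ", paste(need, collapse = ", "))
  cnt <- df[, c("n_unelevated", "n_unilateral", "n_elevated")]
  full <- stats::complete.cases(cnt)
  if (any(abs(rowSums(cnt[full, , drop = FALSE]) - df$n_total[full]) > 0))
    stop("stage counts must sum to n_total")
  if (any(df$n_total < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  class(df) <- c("stage_table", "data.frame")
  df
}

#' Tabulate elevation stages per stratum
#'
#' Counts records by strain and age (and sex when `by_sex = TRUE`); strata
#' with zero records are omitted, so the stratum totals always partition
#' the valid input records.
#'
#' @param records embryo records as produced by [simulate_cohort()] or
#'   [read_embryo_records()].
#' @param by_sex also stratify by sex (default FALSE pools sexes as
#'   `"all"`).
#' @return a [stage_table()].
#' @export
tabulate_stages <- function(records, by_sex = FALSE) {
  if (nrow(records) == 0) stop("no records to tabulate")
  validate_embryo_records(records)
  key <- if (by_sex) interaction(records$strain, records$age_days,
                                 records$sex, drop = TRUE)
         else interaction(records$strain, records$age_days, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(records)), key), function(idx) {
    r <- records[idx, ]
    data.frame(strain = r$strain[1], age_days = r$age_days[1],
               sex = if (by_sex) r$sex[1] else "all",
               n_unelevated = sum(r$stage == "bilat_unelevated"),
               n_unilateral = sum(r$stage == "unilateral"),
               n_elevated = sum(r$stage == "bilat_elevated"),
               n_total = nrow(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$strain, out$age_days, out$sex), ]
  rownames(out) <- NULL
  stage_table(out)
}

#' Integer stage percentages per stratum
#'
#' `100 * count / n_total` rounded half-away-from-zero to an integer,
#' matching the convention of printed staging reports; the raw fractions
#' are returned alongside. Strata with `n_total = 0` are skipped with a
#' warning.
#'
#' @param table a [stage_table()].
#' @return data.frame with the stratum key, integer percentage columns
#'   `pct_*` and fraction columns `frac_*`.
#' @export
stage_percentages <- function(table) {
  stopifnot(inherits(table, "stage_table"))
  tb <- as.data.frame(table)
  if (any(tb$n_total == 0)) {
    warning("skipping stratum with n_total = 0")
    tb <- tb[tb$n_total > 0, ]
  }
  out <- tb[, c("strain", "age_days", "sex")]
  for (s in c("unelevated", "unilateral", "elevated")) {
    frac <- tb[[paste0("n_", s)]] / tb$n_total
    out[[paste0("frac_", s)]] <- frac
    out[[paste0("pct_", s)]] <- as.integer(round_half_away(100 * frac))
  }
  out
}

#' Exact sex contrast within a stratum
#'
#' Builds the 2x2 table of sex by stage group for one strain/age stratum
#' and returns the two-sided Fisher exact test. The default grouping
#' `elevated_vs_rest` contrasts embryos that completed elevation
#' (bilaterally elevated) against all others; `unelevated_vs_rest`
#' contrasts embryos that had not initiated elevation against all others.
#'
#' @param table a sex-stratified [stage_table()] (from
#'   `tabulate_stages(..., by_sex = TRUE)` or built directly).
#' @param strain,age_days stratum selector.
#' @param grouping `"elevated_vs_rest"` or `"unelevated_vs_rest"`.
#' @param sexes the two sex labels to contrast (default male vs female).
#' @return a `ps_test` with the 2x2 table attached (rows = sexes, columns =
#'   group / rest).
#' @export
sex_contrast <- function(table, strain, age_days,
                         grouping = c("elevated_vs_rest", "unelevated_vs_rest"),
                         sexes = c("male", "female")) {
  stopifnot(inherits(table, "stage_table"))
  grouping <- match.arg(grouping)
  tb <- as.data.frame(table)
  sel <- tb$strain == strain & tb$age_days == age_days & tb$sex %in% sexes
  rows <- tb[sel, ]
  if (nrow(rows) != 2)
    stop("need exactly one row per sex for stratum ", strain, " E", age_days)
  rows <- rows[match(sexes, rows$sex), ]
  col <- if (grouping == "elevated_vs_rest") "n_elevated" else "n_unelevated"
  grp <- rows[[col]]
  if (any(is.na(grp)))
    stop("stage count ", col, " is not available for this stratum")
  m <- cbind(group = grp, rest = rows$n_total - grp)
  rownames(m) <- sexes
  res <- fisher_exact_two_sided(m)
  res$note <- paste0(grouping, " @ ", strain, " E", age_days)
  res
}

#' Elevation window of a strain
#'
#' The window runs from the latest sampled age at which the cohort is still
#' (essentially all) unelevated to the earliest sampled age at which the
#' elevated percentage reaches the completion threshold. Both ends are
#' sampled ages — no interpolation — and the thresholds are applied to the
#' half-away-rounded integer percentages, the same convention in which
#' staging results are reported. `onset_age` is the earliest age with any
#' non-unelevated embryo.
#'
#' @param table a pooled [stage_table()] (sex = "all").
#' @param strain strain to analyse (must appear at >= 2 ages).
#' @param completion_threshold elevated fraction defining completion
#'   (default 0.75).
#' @param start_threshold unelevated fraction defining the pre-elevation
#'   state (default 0.95; tolerates rare early outliers).
#' @return list with `strain`, `onset_age`, `window_start_age`,
#'   `completion_age`, `window_hours` and a `complete` flag.
#' @export
elevation_window <- function(table, strain, completion_threshold = 0.75,
                             start_threshold = 0.95) {
  stopifnot(inherits(table, "stage_table"))
  tb <- as.data.frame(table)
  tb <- tb[tb$strain == strain & tb$sex == "all", ]
  tb <- tb[order(tb$age_days), ]
  if (nrow(tb) < 2) stop("need at least 2 sampled ages for strain ", strain)
  pct_elev <- round_half_away(100 * tb$n_elevated / tb$n_total)
  pct_unel <- round_half_away(100 * tb$n_unelevated / tb$n_total)
  non_unel <- tb$n_unilateral + tb$n_elevated
  onset_idx <- which(!is.na(non_unel) & non_unel > 0)
  onset <- if (length(onset_idx)) tb$age_days[min(onset_idx)] else NA_real_
  comp_idx <- which(!is.na(pct_elev) &
                      pct_elev >= round_half_away(100 * completion_threshold))
  completion <- if (length(comp_idx)) tb$age_days[min(comp_idx)] else NA_real_
  start_idx <- which(!is.na(pct_unel) &
                       pct_unel >= round_half_away(100 * start_threshold))
  if (!is.na(completion))
    start_idx <- start_idx[tb$age_days[start_idx] < completion]
  start <- if (length(start_idx)) tb$age_days[max(start_idx)] else NA_real_
  complete <- !is.na(start) && !is.na(completion)
  if (!complete)
    warning("elevation window for ", strain, " could not be bounded ",
            "(threshold never reached at the sampled ages)")
  list(strain = strain, onset_age = onset, window_start_age = start,
       completion_age = completion,
       window_hours = if (complete) (completion - start) * 24 else NA_real_,
       complete = complete)
}

#' Left/right side preference among unilateral records
#'
#' Two-sided exact binomial test of the left-side count against
#' Binomial(n, 1/2) over the unilaterally elevated records.
#'
#' @param records embryo records (non-unilateral records are ignored).
#' @return a `ps_test`; degenerate with p = 1 when no unilateral records
#'   exist.
#' @export
side_preference <- function(records) {
  uni <- records[records$stage == "unilateral", ]
  n <- nrow(uni)
  if (n == 0) {
    return(new_test_result("Exact binomial test", NA_real_, NA_real_, 1,
                           table_or_n = c(k = 0, n = 0), degenerate = TRUE,
                           note = "no unilateral records"))
  }
  binomial_test_two_sided(sum(uni$side == "left"), n)
}

#' Bundled reference staging tallies
#'
#' Stage counts for time-restricted C57BL/6J and FVB/NJ cohorts scored at
#' 3-h intervals around elevation, as reported in the source staging study;
#' pooled rows (`sex = "all"`) and the sex-split rows needed for the sex
#' contrasts. Counts that were not reported per stage are `NA` (the row
#' total is always present).
#'
#' @return a [stage_table()].
#' @export
reference_stage_table <- function() {
  path <- system.file("extdata", "staging_counts.csv", package = "palatelev",
                      mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  stage_table(df)
}
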