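#' Synthetic staging cohorts
#'
#' Simulation of time-restricted embryo cohorts scored into the three
#' elevation stages, used for parameter-recovery and calibration tests of
#' the staging analytics.
#'
#' @name synthetic_cohort
NULL

PS_STAGES <- c("bilat_unelevated", "unilateral", "bilat_elevated")
PS_SIDES <- c("left", "right", "none")

#' Describe a cohort design
#'
#' A cohort design is a set of strata (strain x sex x embryonic age), each
#' with an embryo count and a multinomial over the three elevation stages,
#' plus the probability that a unilaterally elevated embryo has its left
#' shelf up.
#'
#' @param strata data.frame with columns `strain`, `sex`, `age_days`,
#'   `n_embryos`, `p_unelevated`, `p_unilateral`, `p_elevated`.
#' @param p_left_given_unilateral probability of the left side among
#'   unilateral records (default 0.5).
#' @return object of class `cohort_design`.
#' @export
cohort_design <- function(strata, p_left_given_unilateral = 0.5) {
  need <- c("strain", "sex", "age_days", "n_embryos",
            "p_unelevated", "p_unilateral", "p_elevated")
  if (!all(need %in% names(strata)))
    stop("`strata` must have columns: ", paste(need, collapse = ", "))
  pr <- strata[, c("p_unelevated", "p_unilateral", "p_elevated")]
  if (any(pr < 0) || any(abs(rowSums(pr) - 1) > 1e-9))
    stop("each stage probability triple must be non-negative and sum to 1")
  if (any(strata$n_embryos < 0) || any(strata$n_embryos != round(strata$n_embryos)))
    stop("`n_embryos` must be non-negative integers")
  if (any(strata$age_days < 13 | strata$age_days > 15))
    stop("`age_days` must lie in [13, 15]")
  if (p_left_given_unilateral < 0 || p_left_given_unilateral > 1)
    stop("`p_left_given_unilateral` must lie in [0, 1]")
  structure(list(strata = strata,
                 p_left_given_unilateral = p_left_given_unilateral),
            class = "cohort_design")
}

#' Simulate a staged embryo cohort
#'
#' Draws exactly `n_embryos` records per stratum, with the elevation stage
#' drawn from the stratum's multinomial and a side drawn only for
#' unilateral records. Litters of about 8 embryos are assigned within each
#' stratum for bookkeeping (litter effects are recorded, not modelled).
#'
#' @param design a [cohort_design()].
#' @param seed integer seed; a fixed seed reproduces the cohort exactly.
#' @return data.frame of embryo records with columns `embryo_id`,
#'   `litter_id`, `strain`, `sex`, `age_days`, `stage`, `side`.
#' @export
simulate_cohort <- function(design, seed) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(seed)
  st <- design$strata
  pieces <- vector("list", nrow(st))
  for (i in seq_len(nrow(st))) {
    n <- st$n_embryos[i]
    if (n == 0) { pieces[[i]] <- NULL; next }
    probs <- c(st$p_unelevated[i], st$p_unilateral[i], st$p_elevated[i])
    stage <- sample(PS_STAGES, n, replace = TRUE, prob = probs)
    side <- rep("none", n)
    uni <- stage == "unilateral"
    if (any(uni))
      side[uni] <- ifelse(runif(sum(uni)) < design$p_left_given_unilateral,
                          "left", "right")
    pieces[[i]] <- data.frame(
      embryo_id = sprintf("s%02d_e%03d", i, seq_len(n)),
      litter_id = sprintf("s%02d_L%02d", i, ceiling(seq_len(n) / 8)),
      strain = st$strain[i], sex = st$sex[i], age_days = st$age_days[i],
      stage = stage, side = side, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(embryo_id = character(), litter_id = character(),
                      strain = character(), sex = character(),
                      age_days = numeric(), stage = character(),
                      side = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read or write embryo staging records
#'
#' CSV with header `embryo_id,litter_id,strain,sex,age_days,stage,side`.
#' `stage` takes values `bilat_unelevated`, `unilateral`, `bilat_elevated`;
#' `side` is `left`/`right` for unilateral records and `none` otherwise.
#'
#' @param records data.frame of embryo records.
#' @param path file path.
#' @return `read_embryo_records` returns the validated records data.frame.
#' @export
write_embryo_records <- function(records, path) {
  validate_embryo_records(records)
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embryo_records
#' @export
read_embryo_records <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  validate_embryo_records(rec)
  rec
}

validate_embryo_records <- function(records) {
  need <- c("embryo_id", "litter_id", "strain", "sex", "age_days",
            "stage", "side")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (nrow(records) == 0) return(invisible(records))
  bad_stage <- !records$stage %in% PS_STAGES
  if (any(bad_stage))
    stop("unknown stage value(s): ",
         paste(unique(records$stage[bad_stage]), collapse = ", "))
  uni <- records$stage == "unilateral"
  if (any(uni & !records$side %in% c("left", "right")))
    stop("unilateral records must carry side = left or right")
  if (any(!uni & records$side != "none"))
    stop("non-unilateral records must carry side = none")
  if (any(records$age_days < 13 | records$age_days > 15))
    stop("`age_days` must lie in [13, 15]")
  invisible(records)
}
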