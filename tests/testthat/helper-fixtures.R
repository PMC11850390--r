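# shared fixtures and small oracles, built in code at test time

# expand stratum counts into individual embryo records (sides alternate for
# unilateral records so the expansion is deterministic)
expand_stage_counts <- function(strain, age_days, n_unelevated, n_unilateral,
                                n_elevated, sex = "unknown") {
  stage <- rep(c("bilat_unelevated", "unilateral", "bilat_elevated"),
               c(n_unelevated, n_unilateral, n_elevated))
  n <- length(stage)
  side <- rep("none", n)
  uni <- which(stage == "unilateral")
  side[uni] <- rep(c("left", "right"), length.out = length(uni))
  data.frame(embryo_id = sprintf("%s_E%g_%03d", gsub("/", "", strain),
                                 age_days, seq_len(n)),
             litter_id = "L1", strain = strain, sex = sex,
             age_days = age_days, stage = stage, side = side,
             stringsAsFactors = FALSE)
}

# the reference C57BL/6J + FVB/NJ tallies expanded to records (pooled rows)
reference_records <- function() {
  tab <- as.data.frame(reference_stage_table())
  tab <- tab[tab$sex == "all" & stats::complete.cases(
    tab[, c("n_unelevated", "n_unilateral", "n_elevated")]), ]
  do.call(rbind, lapply(seq_len(nrow(tab)), function(i)
    expand_stage_counts(tab$strain[i], tab$age_days[i], tab$n_unelevated[i],
                        tab$n_unilateral[i], tab$n_elevated[i])))
}

# small, fast section spec for unit tests
small_section_spec <- function(...) {
  section_spec(width_um = 120, height_um = 100, pixel_size_um = 1, ...)
}

# axial distance in degrees, in [0, 90]
axial_dist <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# independent Fisher oracle: hypergeometric pmf by ratio recurrence (plain
# arithmetic, no log-space), then the point-probability two-sided sum
fisher_p_enum <- function(a, b, c, d) {
  N <- a + b + c + d; K <- a + b; n <- a + c
  lo <- max(0, n + K - N); hi <- min(n, K)
  ks <- lo:hi
  pmf <- numeric(length(ks)); pmf[1] <- 1
  if (length(ks) > 1) {
    for (i in seq_len(length(ks) - 1)) {
      k <- ks[i]
      pmf[i + 1] <- pmf[i] * (K - k) * (n - k) / ((k + 1) * (N - K - n + k + 1))
    }
  }
  pmf <- pmf / sum(pmf)
  min(1, sum(pmf[pmf <= pmf[a - lo + 1] * (1 + 1e-7)]))
}
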