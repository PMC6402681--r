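# ------------------------------------------------------------------------
# Per-year cohort statistics, replicate aggregation and summary
# quantities: corrected genetic gain, cross-engine ratios and the number
# of Monte Carlo repetitions required for a given precision.
# ------------------------------------------------------------------------

#' Corrected genetic gain
#'
#' Divides the yearly gain columns by the respective initial genetic
#' standard deviations so that maternal, direct and performance-criterion
#' gains are comparable: maternal by `sqrt(sigma2_Am)`, direct by
#' `sqrt(sigma2_Ad)`, and the performance criterion by
#' `sqrt(sigma2_Ad + sigma2_Am + sigma_Amd)` (the initial standard
#' deviation of `PC = TBV_Qm + TBV_Wd` in an unselected population, where
#' the covariance enters once).
#'
#' @param stats A per-year statistics data frame from [run_simulation()]
#'   (or an aggregated one with the same gain columns).
#' @param params The [bee_params()] the run used.
#' @return `stats` with additional columns `corr_m`, `corr_d`, `corr_PC`.
#' @export
corrected_gain <- function(stats, params) {
  stopifnot(inherits(params, "bee_params"))
  div_pc <- sqrt(params$sigma2_Ad + params$sigma2_Am + params$sigma_Amd)
  stats$corr_m <- stats$mean_m_BQ / sqrt(params$sigma2_Am)
  stats$corr_d <- stats$mean_d_BQ / sqrt(params$sigma2_Ad)
  stats$corr_PC <- stats$mean_PC / div_pc
  stats
}

#' Minimum number of Monte Carlo repetitions
#'
#' `N_min = ceiling((s * z_{1 - alpha/2} / e)^2)`: with this many
#' repetitions the estimated mean deviates from the true expectation by
#' less than `e` with confidence `1 - alpha`, when a single repetition has
#' standard deviation `s`.
#'
#' @param s Standard deviation of the outcome across repetitions (>= 0).
#' @param e Tolerated error of the mean (> 0); for a "10 percent" rule use
#'   `e = 0.1 * mean`.
#' @param alpha Error probability (default 0.01, i.e. 99 percent
#'   confidence).
#' @return Integer (vectorized over `s` and `e`).
#' @examples
#' required_repetitions(s = 0.598, e = 0.78)  # 4
#' @export
required_repetitions <- function(s, e, alpha = 0.01) {
  if (any(s < 0)) stop("s must be non-negative", call. = FALSE)
  if (any(e <= 0)) stop("e must be positive", call. = FALSE)
  if (any(alpha <= 0 | alpha >= 1)) stop("alpha must be in (0, 1)",
                                         call. = FALSE)
  as.integer(ceiling((s * qnorm(1 - alpha / 2) / e)^2))
}

#' Aggregate replicate runs
#'
#' Across-replicate mean and standard deviation of every per-year
#' statistic.
#'
#' @param runs List of `bee_sim` objects (or of their `stats` data
#'   frames) from replicate runs of one scenario.
#' @return Data frame with one row per year and, per statistic `x`,
#'   columns `x_mean` and `x_sd`.
#' @export
aggregate_replicates <- function(runs) {
  stats <- lapply(runs, function(r) if (inherits(r, "bee_sim")) r$stats else r)
  stopifnot(length(stats) >= 1L,
            all(vapply(stats, nrow, 1L) == nrow(stats[[1L]])))
  cols <- setdiff(names(stats[[1L]]), "year")
  out <- data.frame(year = stats[[1L]]$year, n_replicates = length(stats))
  for (cl in cols) {
    m <- vapply(stats, function(s) s[[cl]], numeric(nrow(out)))
    m <- matrix(m, nrow = nrow(out))
    out[[paste0(cl, "_mean")]] <- rowMeans(m)
    out[[paste0(cl, "_sd")]] <- apply(m, 1L, sd)
  }
  out
}

#' Cross-engine ratio table
#'
#' Ratios of mean gain and mean PC variance between two aggregated
#' scenarios (typically infinitesimal over finite-locus) at selected
#' years.
#'
#' @param num,den Aggregated data frames from [aggregate_replicates()]
#'   (numerator and denominator scenario).
#' @param years Years at which to report ratios.
#' @return Data frame with columns `year`, `gain_PC_ratio`,
#'   `gain_d_ratio`, `gain_m_ratio`, `var_PC_ratio`.
#' @export
cross_model_ratios <- function(num, den, years) {
  i <- match(years, num$year); j <- match(years, den$year)
  if (anyNA(i) || anyNA(j)) stop("requested year not present", call. = FALSE)
  data.frame(year = years,
             gain_PC_ratio = num$mean_PC_mean[i] / den$mean_PC_mean[j],
             gain_d_ratio = num$mean_d_BQ_mean[i] / den$mean_d_BQ_mean[j],
             gain_m_ratio = num$mean_m_BQ_mean[i] / den$mean_m_BQ_mean[j],
             var_PC_ratio = num$var_PC_mean[i] / den$var_PC_mean[j])
}

#' Share of effectively single-effect loci
#'
#' Audit of a finite-locus founder setup: the fraction of loci whose
#' smaller absolute allele-substitution effect (direct vs. maternal) is
#' below `threshold` times the larger one, i.e. loci that in practice
#' affect only one of the two trait components.
#'
#' @param locus_set A `locus_set`.
#' @param threshold Minor/major effect ratio below which a locus counts as
#'   single-effect (default 0.1).
#' @return Fraction in `[0, 1]`.
#' @export
single_effect_share <- function(locus_set, threshold = 0.1) {
  a <- abs(locus_set$E1 - locus_set$E2)
  mean(pmin(a[, 1L], a[, 2L]) < threshold * pmax(a[, 1L], a[, 2L]))
}

#' Write per-year statistics as CSV
#'
#' @param stats Data frame (per-run or aggregated).
#' @param path Output path.
#' @export
write_year_stats <- function(stats, path) {
  write.table(stats, path, sep = ",", row.names = FALSE, quote = FALSE,
              na = "")
  invisible(path)
}
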