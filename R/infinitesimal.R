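# ------------------------------------------------------------------------
# Infinitesimal genetic engine: founder breeding values and
# Mendelian-sampling inheritance with exact inbreeding correction.
# All functions are vectorized over individuals (n draws at once).
# ------------------------------------------------------------------------

# n draws from N(0, Sigma_A) as an n x 2 matrix
rmvn_sigma <- function(params, n) {
  matrix(rnorm(2L * n), n, 2L, dimnames = list(NULL, c("d", "m"))) %*%
    t(params$Sigma_chol)
}

#' Founder breeding values under the infinitesimal model
#'
#' Base-population queens receive bivariate true breeding values drawn from
#' `N((0,0)', Sigma_A)`.
#'
#' @param params A [bee_params()] object.
#' @param n Number of founder queens.
#' @return Numeric `n x 2` matrix (columns `d`, `m`).
#' @export
inf_founder_tbv <- function(params, n = 1L) {
  rmvn_sigma(params, n)
}

#' Queen inheritance with Mendelian sampling
#'
#' A daughter queen of breeding queen B (inbreeding `F_B`) and sire drone D
#' receives `TBV_Q = (TBV_B + TBV_D + sqrt(1 - F_B) * Phi) / 2` with
#' `Phi ~ N(0, Sigma_A)`. Because the Mendelian term sits inside the
#' halving, its variance contribution is `(1 - F_B) Sigma_A / 4` --
#' exactly the Mendelian-sampling variance implied by the haplodiploid
#' relationship matrix (the sire drone passes his whole genome and
#' contributes no sampling variance).
#'
#' @param tbv_B,tbv_D `n x 2` matrices (or length-2 vectors) of dam and
#'   sire-drone TBVs.
#' @param F_B Dam inbreeding coefficients in `[0, 1]` (scalar or length n).
#' @param params A [bee_params()] object.
#' @return `n x 2` matrix of daughter TBVs.
#' @export
inf_inherit_queen <- function(tbv_B, tbv_D, F_B, params) {
  tbv_B <- rbind(tbv_B); tbv_D <- rbind(tbv_D)
  n <- nrow(tbv_B)
  if (any(F_B < 0 | F_B > 1))
    stop("inbreeding coefficients must lie in [0, 1]", call. = FALSE)
  phi <- rmvn_sigma(params, n)
  (tbv_B + tbv_D + sqrt(1 - F_B) * phi) / 2
}

#' Drone inheritance with Mendelian sampling
#'
#' A drone of dam Q (inbreeding `F_Q`) receives
#' `TBV_D = TBV_Q + sqrt(1 - F_Q) * Phi`, `Phi ~ N(0, Sigma_A)`. Drones of
#' a non-inbred founder dam therefore have TBV variance `2 Sigma_A`,
#' matching their relationship-matrix diagonal of 2.
#'
#' @param tbv_Q `n x 2` matrix (or length-2 vector) of dam TBVs.
#' @param F_Q Dam inbreeding coefficients (scalar or length n).
#' @param params A [bee_params()] object.
#' @return `n x 2` matrix of drone TBVs.
#' @export
inf_inherit_drone <- function(tbv_Q, F_Q, params) {
  tbv_Q <- rbind(tbv_Q)
  n <- nrow(tbv_Q)
  if (any(F_Q < 0 | F_Q > 1))
    stop("inbreeding coefficients must lie in [0, 1]", call. = FALSE)
  tbv_Q + sqrt(1 - F_Q) * rmvn_sigma(params, n)
}

#' Worker-group true breeding value
#'
#' The worker group of a queen mated to a set of drones receives the mean
#' of the queen's TBV and the average drone TBV,
#' `TBV_W = (TBV_Q + mean(TBV_D)) / 2`, componentwise. Shared by both
#' genetic engines (the infinite-worker limit of averaging over the
#' colony's workers).
#'
#' @param tbv_Q Length-2 vector (or 1 x 2 matrix), the queen's TBV.
#' @param drone_tbvs Matrix with one row per mate (typically 12 rows).
#' @return Length-2 named numeric vector (`d`, `m`).
#' @export
worker_group_tbv <- function(tbv_Q, drone_tbvs) {
  tbv_Q <- drop(rbind(tbv_Q))
  drone_tbvs <- rbind(drone_tbvs)
  stopifnot(length(tbv_Q) == 2L, ncol(drone_tbvs) == 2L)
  setNames((tbv_Q + colMeans(drone_tbvs)) / 2, c("d", "m"))
}
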