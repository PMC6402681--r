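#' Genetic parameters for a directly and maternally influenced trait
#'
#' Bundles the 2x2 additive genetic covariance matrix of the direct (worker)
#' and maternal (queen) effect together with the residual variance of the
#' colony performance test. These parameters define the founder distribution
#' of breeding values, the Mendelian-sampling variance of the infinitesimal
#' engine, and the (never re-estimated) covariance structure used by the
#' yearly BLUP evaluation.
#'
#' @param sigma2_Ad Direct (worker) additive genetic variance, trait units^2.
#' @param sigma2_Am Maternal (queen) additive genetic variance, trait units^2.
#' @param sigma_Amd Additive covariance between direct and maternal effects.
#'   Must satisfy `abs(sigma_Amd) < sqrt(sigma2_Ad * sigma2_Am)`.
#' @param sigma2_E Residual variance of the colony phenotype, trait units^2.
#'
#' @return An object of class `bee_params`: a list with the four scalars,
#'   the assembled covariance matrix `Sigma` (rows/columns ordered direct,
#'   maternal), its inverse `Sigma_inv` and Cholesky-type square root
#'   `Sigma_chol` (lower triangular, `Sigma_chol %*% t(Sigma_chol) == Sigma`).
#'
#' @examples
#' p <- bee_params(sigma2_Ad = 2, sigma2_Am = 1, sigma_Amd = -0.25)
#' p$Sigma
#' cov2cor(p$Sigma)[1, 2]   # genetic correlation r_md = -0.18 (rounded)
#' @export
bee_params <- function(sigma2_Ad = 2, sigma2_Am = 1, sigma_Amd = -0.25,
                       sigma2_E = 1) {
  stopifnot(is.numeric(sigma2_Ad), is.numeric(sigma2_Am),
            is.numeric(sigma_Amd), is.numeric(sigma2_E),
            length(sigma2_Ad) == 1L, length(sigma2_Am) == 1L,
            length(sigma_Amd) == 1L, length(sigma2_E) == 1L)
  if (sigma2_Ad <= 0 || sigma2_Am <= 0)
    stop("additive variances must be positive", call. = FALSE)
  if (sigma2_E <= 0)
    stop("residual variance sigma2_E must be positive", call. = FALSE)
  if (abs(sigma_Amd) >= sqrt(sigma2_Ad * sigma2_Am))
    stop("sigma_Amd violates |sigma_Amd| < sqrt(sigma2_Ad * sigma2_Am); ",
         "Sigma_A would not be positive definite", call. = FALSE)
  Sigma <- matrix(c(sigma2_Ad, sigma_Amd, sigma_Amd, sigma2_Am), 2L, 2L,
                  dimnames = list(c("d", "m"), c("d", "m")))
  structure(
    list(sigma2_Ad = sigma2_Ad, sigma2_Am = sigma2_Am,
         sigma_Amd = sigma_Amd, sigma2_E = sigma2_E,
         Sigma = Sigma,
         Sigma_inv = solve(Sigma),
         Sigma_chol = t(chol(Sigma))),
    class = "bee_params")
}

#' @export
print.bee_params <- function(x, ...) {
  cat("Genetic parameters (direct/maternal trait):\n")
  cat(sprintf("  sigma2_Ad = %g, sigma2_Am = %g, sigma_Amd = %g, sigma2_E = %g\n",
              x$sigma2_Ad, x$sigma2_Am, x$sigma_Amd, x$sigma2_E))
  cat(sprintf("  r_md = %.3f, h2_d = %.3f, h2_m = %.3f\n",
              x$sigma_Amd / sqrt(x$sigma2_Ad * x$sigma2_Am),
              x$sigma2_Ad / (x$sigma2_Ad + x$sigma2_Am + x$sigma2_E),
              x$sigma2_Am / (x$sigma2_Ad + x$sigma2_Am + x$sigma2_E)))
  invisible(x)
}

# Symmetric PSD matrix square root via eigendecomposition.
sym_sqrt <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

# Symmetric inverse square root; eigenvalues below `tol` raise a
# degenerate-draw condition so callers can redraw.
sym_inv_sqrt <- function(M, tol = 1e-12) {
  e <- eigen(M, symmetric = TRUE)
  if (any(e$values < tol))
    stop(structure(
      class = c("beesim_degenerate_draw", "error", "condition"),
      list(message = "realized variance matrix is numerically singular",
           call = NULL)))
  e$vectors %*% ((1 / sqrt(e$values)) * t(e$vectors))
}
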