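#' @importFrom stats rbinom rbeta rnorm rexp runif var cor sd qnorm setNames
#' @importFrom utils read.table write.table
NULL

# ------------------------------------------------------------------------
# Finite-locus genetic engine: founder QTL construction calibrated to the
# additive covariance Sigma_A, genome representation, gamete sampling and
# true breeding values.
#
# Loci are unlinked and biallelic, so a diploid genome is fully described
# by the per-locus count (0, 1, 2) of allele a1: the two strands are
# exchangeable and a gamete only depends on the genotype at each locus.
# Haploid drone genomes are 0/1 indicators of allele a1.
# ------------------------------------------------------------------------

#' Sample founder allele frequencies
#'
#' Draws per-locus allele frequencies from the U-shaped Beta(0.5, 0.5)
#' distribution commonly used for founder QTL frequencies. Draws that
#' underflow to exactly 0 or 1 are redrawn so every locus is segregating.
#'
#' @param n_loci Number of biallelic loci (>= 1).
#' @return A list with numeric vectors `p1` and `p2` (`p1 + p2 == 1`).
#' @export
sample_allele_frequencies <- function(n_loci) {
  if (!is.numeric(n_loci) || length(n_loci) != 1L || n_loci < 1)
    stop("n_loci must be a single integer >= 1", call. = FALSE)
  n_loci <- as.integer(n_loci)
  p1 <- rbeta(n_loci, 0.5, 0.5)
  bad <- which(p1 <= 0 | p1 >= 1)
  while (length(bad)) {
    p1[bad] <- rbeta(length(bad), 0.5, 0.5)
    bad <- bad[p1[bad] <= 0 | p1[bad] >= 1]
  }
  list(p1 = p1, p2 = 1 - p1)
}

#' Sample raw bivariate QTL effect vectors
#'
#' Draws `n` independent effect vectors from the mixture
#' `0.95 * Laplace(0, Sigma_A) + 0.05 * Normal(0, Sigma_A)`. The
#' multivariate symmetric Laplace component is realized as a Gaussian scale
#' mixture `sqrt(W) * z` with `W ~ Exponential(mean 1)` and
#' `z ~ N(0, Sigma_A)`, so both mixture components have covariance exactly
#' `Sigma_A` and the mixture is zero-mean with heavy tails
#' (marginal excess kurtosis 0.95 * 3 within the Laplace component).
#'
#' @param params A [bee_params()] object (supplies `Sigma_A`).
#' @param n Number of vectors to draw.
#' @return An `n x 2` matrix; columns are the direct and maternal effect.
#' @export
sample_effect_vector <- function(params, n = 1L) {
  stopifnot(inherits(params, "bee_params"), n >= 1)
  z <- matrix(rnorm(2L * n), n, 2L) %*% t(params$Sigma_chol)
  lap <- runif(n) < 0.95
  scl <- ifelse(lap, sqrt(rexp(n)), 1)
  z * scl
}

#' Preliminary allele effects before variance calibration
#'
#' Converts raw effect vectors into frequency-dependent allele effects with
#' zero expected effect at every locus,
#' `E1~ = (p2 - p1 + 1) e / sqrt(n)` and `E2~ = (p2 - p1 - 1) e / sqrt(n)`.
#' The `1/sqrt(n)` scaling makes the expected total additive variance over
#' all `n` loci equal `Sigma_A`: the per-locus diploid variance is
#' `2 p1 p2 (E1~ - E2~)(E1~ - E2~)' = 8 p1 p2 e e' / n` and
#' `E[8 p1 p2] = 1` under Beta(0.5, 0.5) frequencies.
#'
#' @param p1,p2 Allele frequency vectors (`p1 + p2 == 1`).
#' @param n_loci Total locus count `n` used in the scaling.
#' @param e Raw effect matrix (`length(p1) x 2`), see
#'   [sample_effect_vector()].
#' @return List with matrices `E1` and `E2` (each `length(p1) x 2`)
#'   satisfying `p1 * E1 + p2 * E2 == 0` row-wise.
#' @export
preliminary_effects <- function(p1, p2, n_loci, e) {
  stopifnot(length(p1) == length(p2), all(abs(p1 + p2 - 1) < 1e-12),
            all(p1 >= 0 & p1 <= 1))
  e <- rbind(e)  # allow a single vector
  stopifnot(nrow(e) == length(p1), ncol(e) == 2L)
  s <- sqrt(n_loci)
  list(E1 = ((p2 - p1 + 1) / s) * e,
       E2 = ((p2 - p1 - 1) / s) * e)
}

#' Realized additive genetic variance of a locus set
#'
#' Hardy-Weinberg additive variance summed over loci:
#' `sum_l 2 p1 p2 alpha alpha'` with allele substitution effect
#' `alpha = E1 - E2`.
#'
#' @param locus_set A `locus_set` object (see [build_founder_locus_set()])
#'   or a list with fields `p1`, `p2`, `E1`, `E2`.
#' @return Symmetric 2x2 matrix.
#' @export
realized_variance <- function(locus_set) {
  if (is.null(locus_set$p1) || length(locus_set$p1) == 0L)
    stop("empty locus set", call. = FALSE)
  a <- locus_set$E1 - locus_set$E2
  w <- 2 * locus_set$p1 * locus_set$p2
  crossprod(a, w * a)
}

#' Post-correction of allele effects to exact founder variance
#'
#' Replaces every allele effect by
#' `Sigma_A^{1/2} %*% SigmaTilde_A^{-1/2} %*% E~` (symmetric PSD matrix
#' roots), so that the realized additive variance of the corrected locus
#' set equals `Sigma_A` exactly. The per-locus zero-mean property is
#' preserved because the correction is a common linear map.
#'
#' @param params A [bee_params()] object.
#' @param locus_set Locus set with preliminary effects.
#' @return The locus set with corrected `E1`, `E2`.
#' @export
apply_post_correction <- function(params, locus_set) {
  St <- realized_variance(locus_set)
  Tm <- sym_sqrt(params$Sigma) %*% sym_inv_sqrt(St)
  locus_set$E1 <- locus_set$E1 %*% t(Tm)
  locus_set$E2 <- locus_set$E2 %*% t(Tm)
  locus_set
}

#' Build a founder locus set calibrated to Sigma_A
#'
#' Composes frequency sampling, raw effect sampling, the preliminary
#' frequency-dependent transformation and the variance post-correction.
#' The result generates founder populations whose additive genetic
#' variance equals `Sigma_A` to numerical precision.
#'
#' @param params A [bee_params()] object.
#' @param n_loci Number of loci (200 and 400 are the standard choices).
#' @return An object of class `locus_set`: list with `n_loci`, `p1`, `p2`
#'   and `n_loci x 2` effect matrices `E1`, `E2` (columns direct, maternal).
#' @examples
#' set.seed(1)
#' ls200 <- build_founder_locus_set(bee_params(), 200)
#' realized_variance(ls200)  # equals Sigma_A within 1e-8
#' @export
build_founder_locus_set <- function(params, n_loci) {
  fr <- sample_allele_frequencies(n_loci)
  e <- sample_effect_vector(params, n_loci)
  pre <- preliminary_effects(fr$p1, fr$p2, n_loci, e)
  ls <- structure(list(n_loci = as.integer(n_loci), p1 = fr$p1, p2 = fr$p2,
                       E1 = pre$E1, E2 = pre$E2),
                  class = "locus_set")
  apply_post_correction(params, ls)
}

#' @export
print.locus_set <- function(x, ...) {
  cat(sprintf("Founder locus set: %d unlinked biallelic loci\n", x$n_loci))
  cat("Realized additive variance:\n")
  print(realized_variance(x))
  invisible(x)
}

#' Sample founder diploid genomes
#'
#' Each of the two alleles at every locus is drawn independently as allele
#' `a1` with probability `p1`.
#'
#' @param locus_set A `locus_set`.
#' @param n Number of genomes.
#' @return Integer matrix `n x n_loci` of allele-`a1` counts (0, 1 or 2).
#' @export
sample_founder_genome <- function(locus_set, n = 1L) {
  nl <- locus_set$n_loci
  matrix(rbinom(n * nl, 2L, rep(locus_set$p1, each = n)), n, nl)
}

#' Gamete and offspring genome sampling
#'
#' With unlinked loci, a gamete transmits at every locus one of the dam's
#' two alleles with equal probability; a genotype with allele count 0 or 2
#' transmits deterministically. Queens combine a dam gamete with the single
#' allele of the sire drone; drones are a single dam gamete. No mutation.
#'
#' @param genome Integer matrix of diploid allele counts (rows = dams).
#' @param dam_gamete,sire Haploid 0/1 matrices of equal dimension.
#' @return `sample_gamete` and `make_drone_genome`: 0/1 integer matrix of
#'   the same dimension as `genome`; `make_queen_genome`: allele-count
#'   matrix `dam_gamete + sire`.
#' @export
sample_gamete <- function(genome) {
  genome <- rbind(genome)
  het <- genome == 1L
  g <- (genome == 2L) + 0L
  g[het] <- rbinom(sum(het), 1L, 0.5)
  g
}

#' @rdname sample_gamete
#' @export
make_queen_genome <- function(dam_gamete, sire) {
  stopifnot(all(dim(rbind(dam_gamete)) == dim(rbind(sire))))
  rbind(dam_gamete) + rbind(sire)
}

#' @rdname sample_gamete
#' @export
make_drone_genome <- function(genome) {
  sample_gamete(genome)
}

#' True breeding values under the finite-locus model
#'
#' A diploid TBV is the sum of the allele effects over the whole genome.
#' A haploid drone's TBV is twice the sum of the effects of its single
#' genome, matching the convention of treating drones as diploid but fully
#' homozygous; this puts drone and queen TBVs on the same scale.
#'
#' @param genome Integer matrix: allele-`a1` counts (diploid) or 0/1
#'   indicators (haploid); one row per individual.
#' @param locus_set The `locus_set` the genome belongs to.
#' @param ploidy `"diploid"` or `"haploid"`.
#' @return Numeric matrix `n x 2` (columns `d`, `m`).
#' @export
tbv_fl <- function(genome, locus_set, ploidy = c("diploid", "haploid")) {
  ploidy <- match.arg(ploidy)
  genome <- rbind(genome)
  stopifnot(ncol(genome) == locus_set$n_loci)
  alpha <- locus_set$E1 - locus_set$E2
  base2 <- 2 * colSums(locus_set$E2)
  tbv <- if (ploidy == "diploid") {
    genome %*% alpha
  } else {
    2 * (genome %*% alpha)
  }
  tbv <- sweep(tbv, 2L, -base2)
  colnames(tbv) <- c("d", "m")
  tbv
}

#' Export / import a locus set as TSV
#'
#' Columns `locus_id, p1, E1_d, E1_m, E2_d, E2_m`; values written with 17
#' significant digits so a round trip is lossless.
#'
#' @param locus_set A `locus_set`.
#' @param path File path.
#' @return `read_locus_set` returns a `locus_set`.
#' @export
write_locus_set <- function(locus_set, path) {
  df <- data.frame(locus_id = seq_len(locus_set$n_loci),
                   p1 = locus_set$p1,
                   E1_d = locus_set$E1[, 1L], E1_m = locus_set$E1[, 2L],
                   E2_d = locus_set$E2[, 1L], E2_m = locus_set$E2[, 2L])
  num <- vapply(df, function(col) format(col, digits = 17, scientific = TRUE),
                character(nrow(df)))
  out <- rbind(colnames(df), num)
  writeLines(apply(out, 1L, paste, collapse = "\t"), path)
  invisible(path)
}

#' @rdname write_locus_set
#' @export
read_locus_set <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  structure(list(n_loci = nrow(df), p1 = df$p1, p2 = 1 - df$p1,
                 E1 = cbind(df$E1_d, df$E1_m),
                 E2 = cbind(df$E2_d, df$E2_m)),
            class = "locus_set")
}
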