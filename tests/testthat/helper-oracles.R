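# Independent oracles used by the test suite: gene-dropping estimates of
# identity by descent, a dense generalized-least-squares solver for the
# mixed model, small random haplodiploid pedigrees, and a brute-force
# enumeration of drone genomes on tiny locus sets.

# Monte Carlo allele transmission through a pedigree. Returns the two
# allele-label matrices (replicates x nodes); worker groups are left out
# (their coancestry is bilinear in their members by definition).
gene_drop <- function(ped, nrep = 1e5L) {
  n <- ped$n
  a1 <- a2 <- matrix(0L, nrep, n)
  lab <- 0L
  for (i in seq_len(n)) {
    role <- ped$role[i]
    if (role == 1L) {                       # queen
      if (is.na(ped$dam[i])) {
        a1[, i] <- lab + 1L
        a2[, i] <- lab + 2L
        lab <- lab + 2L
      } else {
        B <- ped$dam[i]; D <- ped$sire[i]
        pick <- stats::runif(nrep) < 0.5
        a1[, i] <- ifelse(pick, a1[, B], a2[, B])
        a2[, i] <- a1[, D]                  # drone passes his whole genome
      }
    } else if (role == 2L) {                # drone: one random dam allele
      P <- ped$dam[i]
      pick <- stats::runif(nrep) < 0.5
      a1[, i] <- ifelse(pick, a1[, P], a2[, P])
      a2[, i] <- a1[, i]
    }
  }
  list(a1 = a1, a2 = a2)
}

# IBD probability estimate for a pair, with its Monte Carlo standard error
gd_kinship <- function(gd, a, b) {
  v <- ((gd$a1[, a] == gd$a1[, b]) + (gd$a1[, a] == gd$a2[, b]) +
          (gd$a2[, a] == gd$a1[, b]) + (gd$a2[, a] == gd$a2[, b])) / 4
  c(f = mean(v), se = stats::sd(v) / sqrt(length(v)))
}

# Small random haplodiploid pedigree with queens, drones and a few worker
# groups (ids ordered so parents precede offspring).
random_pedigree <- function(n_base = 5L, n_gen = 3L, queens_per_gen = 4L,
                            drones_per_gen = 6L, n_wg = 3L) {
  ped <- ped_new()
  queens <- ped_add_queens(ped, n_base)
  drones <- integer(0L)
  for (g in seq_len(n_gen)) {
    drones <- c(drones,
                ped_add_drones(ped, drones_per_gen,
                               dam = sample(queens, drones_per_gen,
                                            replace = TRUE),
                               birth_year = g))
    for (k in seq_len(queens_per_gen))
      queens <- c(queens,
                  ped_add_queens(ped, 1L, dam = sample(queens, 1L),
                                 sire = sample(drones, 1L), birth_year = g))
  }
  for (k in seq_len(n_wg)) {
    q <- sample(queens, 1L)
    dr <- sample(drones, 4L, replace = FALSE)
    ped_add_worker_group(ped, q, dr, birth_year = n_gen)
  }
  ped
}

# Iterative (non-recursive) tabular coancestry over a whole pedigree:
# an implementation of the haplodiploid rules independent of the
# package's memoized recursion. O(n^2), dense.
dense_kinship <- function(ped) {
  n <- ped$n
  f <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- seq_len(i - 1L)
    role <- ped$role[i]
    if (role == 1L) {
      B <- ped$dam[i]
      if (is.na(B)) {
        f[i, i] <- 0.5
      } else {
        D <- ped$sire[i]
        if (length(j)) f[i, j] <- f[j, i] <- 0.5 * (f[B, j] + f[D, j])
        f[i, i] <- 0.5 * (1 + f[B, D])
      }
    } else if (role == 2L) {
      P <- ped$dam[i]
      if (length(j)) f[i, j] <- f[j, i] <- f[P, j]
      f[i, i] <- 1
    } else {
      m <- ped_members(ped, i)
      w <- c(0.5, rep(0.5 / (length(m) - 1L), length(m) - 1L))
      if (length(j)) f[i, j] <- f[j, i] <- as.numeric(w %*% f[m, j])
      f[i, i] <- as.numeric(w %*% f[m, m] %*% w)
    }
  }
  f
}

# Dense GLS solution of the same mixed model solve_blup() solves:
# y = 1 mu + Z u + e, u ~ N(0, A (x) Sigma_A), worker groups carried with
# an eps diagonal. Exact for any (small) problem; O(n^2) memory.
gls_blup <- function(ped, records, params, eps = 1e-8) {
  n <- ped$n
  A <- 2 * dense_kinship(ped)
  wg <- which(ped$role[seq_len(n)] == 3L)
  A[cbind(wg, wg)] <- A[cbind(wg, wg)] + eps
  G <- kronecker(A, params$Sigma)           # node-major (d, m)
  nrec <- nrow(records)
  Z <- matrix(0, nrec, 2L * n)
  Z[cbind(seq_len(nrec), 2L * (records$worker_group_id - 1L) + 1L)] <- 1
  Z[cbind(seq_len(nrec), 2L * (records$queen_id - 1L) + 2L)] <- 1
  V <- Z %*% G %*% t(Z) + diag(params$sigma2_E, nrec)
  Vi <- solve(V)
  y <- records$value
  mu <- sum(Vi %*% y) / sum(Vi)
  u <- as.numeric(G %*% t(Z) %*% Vi %*% (y - mu))
  list(mu = mu,
       ebv_d = u[seq(1L, 2L * n, by = 2L)],
       ebv_m = u[seq(2L, 2L * n, by = 2L)])
}

# Exact distribution of drone TBVs of one dam on a tiny locus set:
# enumerate every gamete of the dam (heterozygous loci segregate) and
# return the exact mean and covariance of the doubled haploid TBV.
enumerate_drone_tbv <- function(dam_counts, locus_set) {
  het <- which(dam_counts == 1L)
  base <- as.integer(dam_counts == 2L)
  combos <- if (length(het)) {
    as.matrix(expand.grid(rep(list(0L:1L), length(het))))
  } else {
    matrix(0L, 1L, 0L)
  }
  tbvs <- t(apply(combos, 1L, function(h) {
    g <- base
    g[het] <- h
    tbv_fl(g, locus_set, ploidy = "haploid")
  }))
  p <- rep(1 / nrow(combos), nrow(combos))
  m <- colSums(p * tbvs)
  cv <- crossprod(tbvs - rep(m, each = nrow(tbvs)), p * (tbvs - rep(m, each = nrow(tbvs))))
  list(mean = m, cov = cv)
}


# A small mated pedigree with phenotyped colonies, built by hand:
# `n_col` founder queens each mated to 12 drones from a shared pool of
# DPQs, plus a worker group and one record per colony.
blup_fixture <- function(n_col = 20, n_dpq = 6, seed = 1) {
  set.seed(seed)
  ped <- ped_new()
  dpqs <- ped_add_queens(ped, n_dpq)
  queens <- ped_add_queens(ped, n_col)
  wgs <- integer(n_col)
  for (i in seq_len(n_col)) {
    dr <- ped_add_drones(ped, 12, dam = sample(dpqs, 12, replace = TRUE))
    wgs[i] <- ped_add_worker_group(ped, queens[i], dr)
  }
  records <- data.frame(queen_id = queens, worker_group_id = wgs,
                        value = rnorm(n_col, 1, 1.5))
  list(ped = ped, records = records)
}
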