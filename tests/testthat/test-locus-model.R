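test_that("founder allele frequencies follow Beta(0.5, 0.5)", {
  set.seed(1)
  fr <- sample_allele_frequencies(200)
  expect_length(fr$p1, 200)
  expect_equal(fr$p1 + fr$p2, rep(1, 200))
  expect_true(all(fr$p1 > 0 & fr$p1 < 1))

  big <- sample_allele_frequencies(1e5)$p1
  # Beta(0.5, 0.5): mean 1/2, variance ab/((a+b)^2 (a+b+1)) = 1/8
  expect_lt(abs(mean(big) - 0.5), 3 * sqrt(0.125 / 1e5))
  expect_lt(abs(var(big) - 0.125), 0.005)

  expect_error(sample_allele_frequencies(0), "n_loci")
})

test_that("raw effect vectors have covariance Sigma_A and heavy tails", {
  set.seed(2)
  p <- bee_params(sigma_Amd = -0.25)
  e <- sample_effect_vector(p, 5e4)
  expect_lt(max(abs(colMeans(e))), 0.05)
  expect_lt(max(abs(cov(e) - p$Sigma)), 0.1)
  exkurt <- apply(e, 2, function(x) mean((x - mean(x))^4) / var(x)^2 - 3)
  expect_true(all(exkurt > 1))   # mixture excess kurtosis ~ 2.85

  expect_error(sample_effect_vector(list(Sigma = diag(2)), 10))
})

test_that("preliminary effects are zero-mean at every locus", {
  e <- cbind(c(1, -2, 0.5), c(0.3, 1, -1))
  # p1 = p2 = 1/2: E1 = e / sqrt(n), E2 = -e / sqrt(n)
  pe <- preliminary_effects(rep(0.5, 3), rep(0.5, 3), 3, e)
  expect_equal(pe$E1, e / sqrt(3))
  expect_equal(pe$E2, -e / sqrt(3))

  set.seed(3)
  p1 <- runif(3)
  pe <- preliminary_effects(p1, 1 - p1, 3, e)
  expect_equal(p1 * pe$E1 + (1 - p1) * pe$E2,
               matrix(0, 3, 2), ignore_attr = TRUE)

  pe <- preliminary_effects(1, 0, 1, e[1, , drop = FALSE])
  expect_equal(pe$E1, matrix(0, 1, 2), ignore_attr = TRUE)
})

test_that("realized variance matches the Hardy-Weinberg sum over loci", {
  # single locus, p = 1/2, n = 1: alpha = 2e, Sigma~ = 2 p1 p2 alpha alpha'
  # = 2 e e'
  e <- matrix(c(0.7, -0.4), 1, 2)
  pe <- preliminary_effects(0.5, 0.5, 1, e)
  ls1 <- list(n_loci = 1L, p1 = 0.5, p2 = 0.5, E1 = pe$E1, E2 = pe$E2)
  expect_equal(realized_variance(ls1), 2 * crossprod(e), ignore_attr = TRUE)

  # duplicating every locus doubles the realized variance
  ls2 <- list(n_loci = 2L, p1 = rep(0.5, 2), p2 = rep(0.5, 2),
              E1 = rbind(pe$E1, pe$E1), E2 = rbind(pe$E2, pe$E2))
  expect_equal(realized_variance(ls2), 2 * realized_variance(ls1))

  expect_error(realized_variance(list(p1 = numeric(0))), "empty")

  # expectation over frequency and effect draws is Sigma_A
  set.seed(4)
  p <- bee_params(sigma_Amd = -0.25)
  draws <- replicate(400, {
    fr <- sample_allele_frequencies(100)
    e <- sample_effect_vector(p, 100)
    pe <- preliminary_effects(fr$p1, fr$p2, 100, e)
    realized_variance(list(p1 = fr$p1, p2 = fr$p2, E1 = pe$E1, E2 = pe$E2))
  })
  expect_lt(max(abs(apply(draws, 1:2, mean) - p$Sigma)), 0.15)
})

test_that("post-correction calibrates the variance exactly", {
  p <- bee_params(sigma_Amd = -0.25)
  set.seed(5)
  ls <- build_founder_locus_set(p, 200)
  expect_lt(max(abs(realized_variance(ls) - p$Sigma)), 1e-8)

  # already calibrated -> the transformation is the identity
  ls2 <- apply_post_correction(p, ls)
  expect_equal(ls2$E1, ls$E1, tolerance = 1e-10)

  # zero-mean preserved
  expect_lt(max(abs(ls$p1 * ls$E1 + ls$p2 * ls$E2)), 1e-12)

  # diagonal case: per-trait scalar rescaling by sqrt(sigma2 / sigma2~)
  pd <- bee_params(sigma2_Ad = 3, sigma2_Am = 0.5, sigma_Amd = 0)
  a <- 0.8; b <- 0.3
  lsd <- list(n_loci = 2L, p1 = rep(0.5, 2), p2 = rep(0.5, 2),
              E1 = rbind(c(a, 0), c(0, b)), E2 = rbind(c(-a, 0), c(0, -b)))
  st <- realized_variance(lsd)          # diag(2 a^2, 2 b^2)
  out <- apply_post_correction(pd, lsd)
  expect_equal(out$E1[1, 1], a * sqrt(3 / st[1, 1]))
  expect_equal(out$E1[2, 2], b * sqrt(0.5 / st[2, 2]))
})

test_that("founder locus sets are deterministic given the seed", {
  p <- bee_params()
  set.seed(11); ls1 <- build_founder_locus_set(p, 400)
  set.seed(11); ls2 <- build_founder_locus_set(p, 400)
  expect_identical(ls1, ls2)
  expect_equal(ls1$n_loci, 400L)
  expect_lt(max(abs(realized_variance(ls1) - p$Sigma)), 1e-8)
})

test_that("founder genomes reproduce the specified frequencies", {
  p <- bee_params()
  set.seed(6)
  ls <- build_founder_locus_set(p, 50)
  ls$p1 <- rep(1, 50); ls$p2 <- rep(0, 50)
  expect_true(all(sample_founder_genome(ls, 5) == 2L))

  ls$p1 <- rep(0.3, 50); ls$p2 <- rep(0.7, 50)
  G <- sample_founder_genome(ls, 1e4)
  expect_lt(abs(mean(G[, 1]) / 2 - 0.3), 3 * sqrt(0.3 * 0.7 / 2e4))

  ls$p1 <- rep(0.5, 50); ls$p2 <- rep(0.5, 50)
  G <- sample_founder_genome(ls, 1e4)
  expect_lt(abs(mean(G == 1L) - 0.5), 0.02)   # heterozygosity 2 p1 p2
})

test_that("gametes are Mendelian and conserve alleles", {
  hom <- matrix(c(2L, 0L, 2L, 0L), 1)
  expect_equal(sample_gamete(hom), matrix(c(1L, 0L, 1L, 0L), 1),
               ignore_attr = TRUE)

  set.seed(7)
  het <- matrix(1L, 1e4, 1)
  g <- sample_gamete(het)
  expect_lt(abs(mean(g) - 0.5), 3 * sqrt(0.25 / 1e4))

  dam_g <- matrix(c(1L, 0L), 1, 2)
  sire <- matrix(c(1L, 1L), 1, 2)
  q <- make_queen_genome(dam_g, sire)
  expect_equal(q, matrix(c(2L, 1L), 1, 2), ignore_attr = TRUE)
  # no mutation: offspring counts bounded by parental contributions
  expect_true(all(q >= sire & q <= sire + 1L))
})

test_that("drone TBVs are doubled haploid values consistent with the dam", {
  p <- bee_params(sigma_Amd = -0.25)
  set.seed(8)
  ls <- build_founder_locus_set(p, 3)
  dam <- c(1L, 2L, 1L)

  oracle <- enumerate_drone_tbv(dam, ls)
  # the expected drone TBV equals the dam's diploid TBV
  expect_equal(oracle$mean, drop(tbv_fl(dam, ls)), ignore_attr = TRUE)

  g <- sample_gamete(matrix(rep(dam, each = 2e4), 2e4))
  tb <- tbv_fl(g, ls, ploidy = "haploid")
  expect_lt(max(abs(colMeans(tb) - oracle$mean)), 0.05)
  expect_lt(max(abs(cov(tb) - oracle$cov)), 0.05)

  # all-a1 genome: diploid TBV equals the doubled haploid TBV
  allele1 <- rep(1L, 3)
  expect_equal(tbv_fl(2L * allele1, ls), tbv_fl(allele1, ls, "haploid"))
})

test_that("founder cohorts realize Sigma_A and inheritance is drift-free", {
  p <- bee_params(sigma_Amd = -0.25)
  set.seed(9)
  ls <- build_founder_locus_set(p, 200)
  G <- sample_founder_genome(ls, 2000)
  expect_lt(max(abs(cov(tbv_fl(G, ls)) - p$Sigma)), 0.2)

  # allele frequencies among offspring of random mating match parents
  freq_parent <- colMeans(G[1:200, ]) / 2
  gam1 <- sample_gamete(G[1:200, ])
  gam2 <- sample_gamete(G[201:400, ])
  kids <- make_queen_genome(gam1, gam2)
  freq_mid <- (freq_parent + colMeans(G[201:400, ]) / 2) / 2
  se <- sqrt(freq_mid * (1 - freq_mid) / 400)
  expect_lt(mean(abs(colMeans(kids) / 2 - freq_mid) > 3 * pmax(se, 1e-3)),
            0.02)
})

test_that("locus sets round-trip through TSV losslessly", {
  p <- bee_params()
  set.seed(10)
  ls <- build_founder_locus_set(p, 25)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_locus_set(ls, path)
  back <- read_locus_set(path)
  expect_equal(back$p1, ls$p1, tolerance = 0)
  expect_equal(back$E1, ls$E1, tolerance = 0, ignore_attr = TRUE)
  expect_equal(back$E2, ls$E2, tolerance = 0, ignore_attr = TRUE)
})
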