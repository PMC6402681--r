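test_that("kinship base cases follow the haplodiploid rules", {
  ped <- ped_new()
  q1 <- ped_add_queens(ped, 1); q2 <- ped_add_queens(ped, 1)
  d1 <- ped_add_drones(ped, 1, dam = q1)

  expect_equal(kinship(ped, q1, q2), 0)
  expect_equal(kinship(ped, q1, q1), 0.5)
  expect_equal(kinship(ped, d1, d1), 1)         # drone diagonal a = 2
  # a queen and her own drone son: f = f(Q, Q) = (1 + F_Q) / 2
  expect_equal(kinship(ped, q1, d1), 0.5)
  expect_equal(inbreeding(ped, q1), 0)
  expect_error(kinship(ped, q1, 99), "missing-node")
})

test_that("super sisters and half sisters have a = 0.75 and 0.25", {
  ped <- ped_new()
  B <- ped_add_queens(ped, 1)
  P1 <- ped_add_queens(ped, 1); P2 <- ped_add_queens(ped, 1)
  dS <- ped_add_drones(ped, 1, dam = P1)        # shared sire drone
  dA <- ped_add_drones(ped, 1, dam = P1)        # distinct drones,
  dB <- ped_add_drones(ped, 1, dam = P2)        # unrelated dams
  s1 <- ped_add_queens(ped, 1, dam = B, sire = dS)
  s2 <- ped_add_queens(ped, 1, dam = B, sire = dS)
  h1 <- ped_add_queens(ped, 1, dam = B, sire = dA)
  h2 <- ped_add_queens(ped, 1, dam = B, sire = dB)

  expect_equal(2 * kinship(ped, s1, s2), 0.75)
  expect_equal(2 * kinship(ped, h1, h2), 0.25)
  # same dam, different drones of the same DPQ: intermediate 2f = 0.5
  expect_equal(2 * kinship(ped, s1, h1), 0.5)
})

test_that("inbreeding recursion handles mother-son mating", {
  ped <- ped_new()
  B <- ped_add_queens(ped, 1)
  son <- ped_add_drones(ped, 1, dam = B)
  daughter <- ped_add_queens(ped, 1, dam = B, sire = son)
  expect_equal(inbreeding(ped, daughter), 0.5)  # f(B, drone(B)) = (1+0)/2
})

test_that("gene-dropping agrees with the kinship recursion", {
  set.seed(1)
  ped <- random_pedigree(n_base = 5, n_gen = 3, queens_per_gen = 4,
                         n_wg = 0)
  gd <- gene_drop(ped, nrep = 1e5)
  ids <- seq_len(ped$n)
  pairs <- cbind(sample(ids, 40, replace = TRUE),
                 sample(ids, 40, replace = TRUE))
  for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    est <- gd_kinship(gd, a, b)
    expect_lt(abs(kinship(ped, a, b) - est["f"]),
              3 * max(est["se"], 1e-3))
  }
})

test_that("worker-group kinship is bilinear in its members", {
  ped <- ped_new()
  q <- ped_add_queens(ped, 1)
  dpq <- ped_add_queens(ped, 1)
  dr <- ped_add_drones(ped, 12, dam = dpq)
  out <- ped_add_queens(ped, 1)
  w <- ped_add_worker_group(ped, q, dr)

  # f(W, X) = 1/2 f(Q, X) + sum 1/24 f(D_k, X)
  manual <- 0.5 * kinship(ped, q, out) +
    sum(vapply(dr, function(d) kinship(ped, d, out), numeric(1))) / 24
  expect_equal(kinship(ped, w, out), manual)
  # f(W, Q) = 1/2 f(Q,Q) + 1/2 f(drones, Q) = 1/4 here
  expect_equal(kinship(ped, w, q), 0.25)
  # f(W, W): queen term 1/8 + cross 0 + drone block (12 + 132/2)/576
  expect_equal(kinship(ped, w, w), 0.25 * 0.5 + (12 + 132 * 0.5) / 576)
})

test_that("relationship matrices are PSD and invert correctly", {
  set.seed(2)
  for (rep in 1:3) {
    ped <- random_pedigree(n_base = 4, n_gen = 3, queens_per_gen = 3,
                           n_wg = if (rep == 1) 0 else 2)
    A <- build_relationship_matrix(ped)
    expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values),
              -1e-9)
    Ainv <- build_sparse_A_inverse(ped, eps = 1e-8)
    if (rep == 1) {
      # no worker groups: A is nonsingular and A %*% Ainv = I
      expect_lt(max(abs(A %*% as.matrix(Ainv) - diag(ped$n))), 1e-6)
    } else {
      # worker groups make A singular; the eps-regularized A matches
      wg <- which(ped$role[seq_len(ped$n)] == 3L)
      A[cbind(wg, wg)] <- A[cbind(wg, wg)] + 1e-8
      expect_lt(max(abs(A %*% as.matrix(Ainv) - diag(ped$n))), 1e-4)
    }
  }
})

test_that("memoized recursion agrees with an iterative tabular pass", {
  set.seed(5)
  ped <- random_pedigree(n_base = 4, n_gen = 2, queens_per_gen = 3,
                         n_wg = 2)
  f_tab <- dense_kinship(ped)
  expect_equal(build_relationship_matrix(ped), 2 * f_tab,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("a founder's drone son gives the analytic 2x2 inverse block", {
  ped <- ped_new()
  P <- ped_add_queens(ped, 1)
  D <- ped_add_drones(ped, 1, dam = P)
  Ainv <- as.matrix(build_sparse_A_inverse(ped))
  expect_equal(Ainv, matrix(c(2, -1, -1, 1), 2), ignore_attr = TRUE)
})

test_that("pedigrees of unrelated base queens invert to the identity", {
  ped <- ped_new()
  ped_add_queens(ped, 7)
  expect_equal(as.matrix(build_sparse_A_inverse(ped)), diag(7),
               ignore_attr = TRUE)
})

test_that("memoization is transparent and ids are order-checked", {
  set.seed(3)
  ped <- random_pedigree()
  a <- ped$n - 1L; b <- ped$n
  cold <- kinship(ped, a, b)
  warm <- kinship(ped, a, b)
  expect_identical(cold, warm)
  expect_error(ped_add_queens(ped, 1, dam = ped$n + 5L, sire = 1L))
})

test_that("pedigree export has the documented columns and exact F", {
  set.seed(4)
  ped <- random_pedigree(n_wg = 1)
  df <- ped_df(ped)
  expect_named(df, c("id", "role", "birth_year", "dam_id", "sire_drone_id",
                     "F"))
  qs <- df$id[df$role == "queen" & !is.na(df$dam_id)]
  for (q in qs)
    expect_equal(df$F[q], kinship(ped, ped$dam[q], ped$sire[q]))
  path <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(ped, path)
  back <- read.csv(path)
  expect_equal(nrow(back), ped$n)
})
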