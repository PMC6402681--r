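test_that("a single record is absorbed by the overall mean", {
  fx <- blup_fixture(n_col = 1)
  fit <- solve_blup(fx$ped, fx$records[1, ], bee_params())
  expect_equal(fit$mu, fx$records$value[1], tolerance = 1e-8)
  expect_lt(max(abs(c(fit$ebv$ebv_d, fit$ebv$ebv_m))), 1e-7)
  expect_error(solve_blup(fx$ped, fx$records[0, ], bee_params()),
               "empty-evaluation")
})

test_that("sparse MME solutions match the dense GLS oracle", {
  p <- bee_params(sigma_Amd = -0.25)
  # hand-built mated pedigree
  fx <- blup_fixture(n_col = 25, seed = 2)
  fit <- solve_blup(fx$ped, fx$records, p)
  ora <- gls_blup(fx$ped, fx$records, p)
  expect_equal(fit$mu, ora$mu, tolerance = 1e-6)
  expect_lt(max(abs(fit$ebv$ebv_d - ora$ebv_d[fit$ebv$id])), 1e-6)
  expect_lt(max(abs(fit$ebv$ebv_m - ora$ebv_m[fit$ebv$id])), 1e-6)

  # multi-year scheme pedigree with selection, inbreeding and drones that
  # sired queens (so both retained and marginalized drones occur)
  sim <- small_sim()
  fit <- solve_blup(sim$pedigree, sim$records, sim$params)
  ora <- gls_blup(sim$pedigree, sim$records, sim$params)
  expect_equal(fit$mu, ora$mu, tolerance = 1e-6)
  expect_lt(max(abs(fit$ebv$ebv_d - ora$ebv_d[fit$ebv$id])), 1e-6)
  expect_lt(max(abs(fit$ebv$ebv_m - ora$ebv_m[fit$ebv$id])), 1e-6)
})

test_that("EBVs shrink to zero as residual variance dominates", {
  fx <- blup_fixture(n_col = 15, seed = 3)
  fit <- solve_blup(fx$ped, fx$records,
                    bee_params(sigma2_E = 1e8))
  expect_lt(max(abs(c(fit$ebv$ebv_d, fit$ebv$ebv_m))), 1e-3)

  # nearly noiseless records: fitted colony values approach the phenotypes
  fit0 <- solve_blup(fx$ped, fx$records, bee_params(sigma2_E = 1e-6))
  w <- match(fx$records$worker_group_id, fit0$ebv$id)
  q <- match(fx$records$queen_id, fit0$ebv$id)
  fitted <- fit0$mu + fit0$ebv$ebv_d[w] + fit0$ebv$ebv_m[q]
  expect_lt(max(abs(fitted - fx$records$value)), 1e-3)
})

test_that("record order does not change the solutions", {
  fx <- blup_fixture(n_col = 18, seed = 4)
  p <- bee_params()
  fit1 <- solve_blup(fx$ped, fx$records, p)
  fit2 <- solve_blup(fx$ped, fx$records[sample(18), ], p)
  expect_equal(fit1$mu, fit2$mu, tolerance = 1e-9)
  expect_equal(fit1$ebv, fit2$ebv, tolerance = 1e-9)
})

test_that("the selection criterion sums worker-group EBVs and ignores shifts", {
  fx <- blup_fixture(n_col = 12, seed = 5)
  p <- bee_params()
  fit <- solve_blup(fx$ped, fx$records, p)
  sc <- selection_criterion(fit, fx$records$worker_group_id)
  idx <- match(fx$records$worker_group_id, fit$ebv$id)
  expect_equal(sc, fit$ebv$ebv_d[idx] + fit$ebv$ebv_m[idx])

  shifted <- fx$records
  shifted$value <- shifted$value + 5
  fit2 <- solve_blup(fx$ped, shifted, p)
  expect_equal(fit2$mu, fit$mu + 5, tolerance = 1e-7)
  expect_equal(selection_criterion(fit2, fx$records$worker_group_id), sc,
               tolerance = 1e-7)
  expect_error(selection_criterion(fit, 10000), "missing-node")
})

test_that("expected relationship mode gives consistent evaluations", {
  cfg <- small_config(years = 4, pedigree_mode = "expected")
  sim_e <- run_simulation(cfg, bee_params(), seed = 42)
  sim_x <- small_sim()
  expect_true(all(is.finite(sim_e$ebv$ebv$ebv_d)))
  sc_e <- selection_criterion(sim_e$ebv,
                              sim_e$records$worker_group_id[1:40])
  sc_x <- selection_criterion(sim_x$ebv,
                              sim_x$records$worker_group_id[1:40])
  # the two paternity treatments must broadly agree on early colonies
  expect_gt(cor(sc_e, sc_x), 0.8)

  # base-population worker group: station of 8 unrelated DPQs gives the
  # drone-sampling diagonal (1 - mean f-block) / 24 = (1 - 1/16) / 24
  ped <- sim_e$pedigree
  wg1 <- which(ped$role[seq_len(ped$n)] == 3L)[1]
  expect_equal(ped$d_exp[wg1], (1 - 1 / 16) / 24, tolerance = 1e-12)
})

test_that("EBV export carries SC for worker groups", {
  fx <- blup_fixture(n_col = 5, seed = 6)
  fit <- solve_blup(fx$ped, fx$records, bee_params())
  path <- withr::local_tempfile(fileext = ".csv")
  write_ebv(fit, path)
  back <- read.csv(path)
  expect_true(all(c("entity_id", "role", "ebv_d", "ebv_m", "SC") %in%
                    names(back)))
  wrow <- back[back$role == "worker_group", ]
  expect_equal(wrow$SC, wrow$ebv_d + wrow$ebv_m)
})
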