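test_that("configuration invariants are enforced before simulating", {
  expect_error(bee_config(n_dams_bq = 50), "n_dams_bq")
  expect_error(bee_config(n_bq_per_year = 0, n_dams_bq = 0), "positive")
  expect_error(bee_config(engine = "FL300"))
  cfg <- bee_config()
  expect_equal(cfg$n_dams_bq * cfg$daughters_per_dam, cfg$n_bq_per_year)
  expect_equal(bee_config(engine = "FL400")$n_loci, 400L)
})

test_that("truncation selection takes the top k with deterministic ties", {
  expect_equal(select_truncation(c(10L, 11L, 12L), c(3, 2, 1), 2),
               c(10L, 11L))
  expect_equal(select_truncation(c(5L, 6L), c(1, 2), 2), c(6L, 5L))
  expect_equal(select_truncation(c(9L, 3L, 7L), c(1, 1, 1), 2), c(3L, 7L))
  expect_error(select_truncation(1:3, 1:3, 4), "configuration")
  expect_error(select_truncation(1:3, c(1, NA, 2), 2), "evaluated")
})

test_that("sister groups map to one station each", {
  set.seed(1)
  s <- assign_sister_groups(60, 4)
  expect_length(s, 60)
  expect_true(all(s %in% 1:4))
  expect_equal(assign_sister_groups(5, 1), rep(1L, 5))
  # roughly uniform over many groups
  tab <- table(assign_sister_groups(4000, 4))
  expect_true(all(abs(tab / 1000 - 1) < 0.2))
})

test_that("base population matches the scheme definition", {
  sim <- cached_run("base_default_inf",
                    run_simulation(bee_config(years = 3, engine = "INF"),
                                   bee_params(), seed = 5))
  ped <- sim$pedigree
  ids <- seq_len(ped$n)
  base_queens <- ids[ped$role[ids] == 1L & is.na(ped$dam[ids])]
  # 2 x 300 base BQs; 3 years x 4 stations x 8 base DPQs
  expect_equal(length(base_queens), 600 + 96)
  expect_equal(as.integer(table(ped$by[base_queens])),
               c(300L + 32L, 300L + 32L, 32L))
  expect_true(all(ped$F[base_queens] == 0))
  # unrelated founders
  expect_equal(kinship(ped, base_queens[1], base_queens[2]), 0)
})

test_that("the yearly loop produces the documented cohorts and colonies", {
  sim <- small_sim()  # 20 BQs/year, 5 years
  ped <- sim$pedigree
  ids <- seq_len(ped$n)
  bqs_by_year <- table(ped$by[ids[ped$role[ids] == 1L]])
  # colonies for cohorts 1-4 only (tested in years 2-5)
  expect_equal(sort(unique(sim$records$year)), 2:5)
  expect_equal(as.integer(table(sim$records$year)), rep(20L, 4))
  # each colony phenotyped exactly once
  expect_false(any(duplicated(sim$records$queen_id)))
  # years 1-2 are base cohorts; the year-3 BQ cohort is the first with
  # specified dams, which are two-year-old BQs
  qs <- ids[ped$role[ids] == 1L]
  expect_true(all(is.na(ped$dam[qs[ped$by[qs] <= 2L]])))
  q3 <- qs[ped$by[qs] == 3L & !is.na(ped$dam[qs])]
  expect_length(q3, 20L)
  expect_true(all(ped$by[ped$dam[q3]] == 1L))
})

test_that("matings follow the station structure", {
  sim <- small_sim()
  ped <- sim$pedigree
  qs <- sim$records$queen_id
  for (q in qs[1:10]) {
    mates <- ped_mates(ped, q)
    expect_length(mates, 12L)
    expect_true(all(ped$role[mates] == 2L))
    # all drone dams belong to the queen's assigned station
    expect_true(all(ped$dam[mates] %in% ped_station(ped, q)))
    expect_length(ped_station(ped, q), 8L)
  }
  # full sisters share their mating station
  full <- qs[!is.na(ped$dam[qs])]
  by_dam <- split(full, ped$dam[full])
  by_dam <- by_dam[lengths(by_dam) > 1]
  for (sis in by_dam)
    expect_length(unique(lapply(sis, function(s)
      sort(ped_station(ped, s)))), 1L)
})

test_that("colony phenotypes decompose into PC plus residual", {
  sim <- small_sim()
  ped <- sim$pedigree
  w <- sim$records$worker_group_id
  q <- sim$records$queen_id
  # worker-group TBV satisfies the queen/mates average exactly
  for (i in 1:15) {
    mates <- ped_mates(ped, q[i])
    expect_equal(ped$tbv_d[w[i]],
                 0.5 * (ped$tbv_d[q[i]] + mean(ped$tbv_d[mates])),
                 tolerance = 1e-12)
  }
  expect_equal(sim$records$pc, ped$tbv_m[q] + ped$tbv_d[w])
  resid <- sim$records$value - sim$records$pc
  expect_lt(abs(var(resid) - sim$params$sigma2_E),
            4 * sim$params$sigma2_E / sqrt(length(resid)))
})

test_that("identical seeds give bit-identical trajectories", {
  cfg <- small_config(years = 4, engine = "FL200")
  s1 <- run_simulation(cfg, bee_params(), seed = 9)
  s2 <- run_simulation(cfg, bee_params(), seed = 9)
  expect_identical(s1$stats, s2$stats)
  expect_identical(s1$records, s2$records)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(s1$pedigree, p1); write_pedigree(s2$pedigree, p2)
  expect_identical(readLines(p1), readLines(p2))
  s3 <- run_simulation(cfg, bee_params(), seed = 10)
  expect_false(identical(s1$stats, s3$stats))
})

test_that("selection responds and inbreeding accumulates", {
  runs <- smoke_runs("INF")
  agg <- runs$aggregate
  sel_years <- which(!is.na(agg$dam_sc_selected_mean))
  expect_true(all(agg$dam_sc_selected_mean[sel_years] >=
                    agg$dam_sc_cohort_mean[sel_years]))
  # mean F of BQ cohorts non-decreasing over years within MC noise:
  # year-to-year dips must stay inside 3 standard errors of the
  # across-replicate difference
  ny <- nrow(agg)
  dF <- diff(agg$mean_F_mean)
  n <- agg$n_replicates[1]
  se <- sqrt(agg$mean_F_sd[-1]^2 + agg$mean_F_sd[-ny]^2) / sqrt(n)
  expect_true(all(dF > -3 * se - 1e-8))
  expect_gt(agg$mean_F_mean[ny], agg$mean_F_mean[5])
  # genetic progress happened
  expect_gt(agg$mean_PC_mean[ny], 2)
})
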