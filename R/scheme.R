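# ------------------------------------------------------------------------
# The yearly breeding-program engine.
#
# Each simulated year: (1) queen production (base rules in early years,
# truncation-selected dams afterwards: 2-year-old breeding queens (BQs)
# as dams of the next BQ generation, 3-year-old BQs as dams of complete
# mating stations of 8 drone-producing queens (DPQs)); (2) mating of all
# new BQs, full-sister groups to a common random station, 12 drones per
# queen with dams uniform over the station's DPQs; (3) colony production
# and performance test of the one-year-old BQ cohort; (4) yearly BLUP on
# all records to date. Events 3 and 4 start in year 2.
#
# Kinship among the queens alive in the last four cohorts is maintained as
# a dense matrix updated generation-wise from parent rows (with the
# shared-sire-drone correction), which gives exact pedigree inbreeding
# coefficients without recursion in the hot path.
# ------------------------------------------------------------------------

#' Breeding scheme configuration
#'
#' Population and selection structure of a closed honeybee breeding
#' program. The defaults describe the small program: 300 new breeding
#' queens and 4 mating stations per year, the best 60 two-year-old BQs
#' each producing 5 daughters, stations of 8 DPQs, 12 drones per mating.
#' The large program uses 1000 BQs, 10 stations and 200 dams.
#'
#' @param n_bq_per_year New breeding queens per year (300 or 1000).
#' @param n_stations_per_year Mating stations set up per year (4 or 10).
#' @param n_dams_bq Selected BQ dams per year; must satisfy
#'   `n_dams_bq * daughters_per_dam == n_bq_per_year`.
#' @param daughters_per_dam Daughters per selected BQ dam (5).
#' @param n_dpq_per_station Drone-producing queens per station (8).
#' @param drones_per_mating Drones each queen mates with (12).
#' @param dam_age_bq,dam_age_dpq Age (years) at which BQs serve as dams of
#'   BQs (2) and of DPQ stations (3).
#' @param years Number of simulated years.
#' @param engine Genetic engine: `"INF"` (infinitesimal), `"FL200"` or
#'   `"FL400"` (finite locus with 200/400 unlinked loci).
#' @param pedigree_mode Relationship mode of the BLUP evaluation:
#'   `"expected"` (default; paternity averaged over the station's DPQs,
#'   as in field evaluations, where individual paternity is
#'   unobservable) or `"exact"` (realized sire drones). Inheritance and
#'   inbreeding always use the exact tracked pedigree; the mode only
#'   affects the relationship matrix behind the yearly BLUP.
#' @return An object of class `bee_config`.
#' @export
bee_config <- function(n_bq_per_year = 300L, n_stations_per_year = 4L,
                       n_dams_bq = 60L, daughters_per_dam = 5L,
                       n_dpq_per_station = 8L, drones_per_mating = 12L,
                       dam_age_bq = 2L, dam_age_dpq = 3L, years = 20L,
                       engine = c("INF", "FL200", "FL400"),
                       pedigree_mode = c("expected", "exact")) {
  engine <- match.arg(engine)
  pedigree_mode <- match.arg(pedigree_mode)
  cfg <- list(n_bq_per_year = as.integer(n_bq_per_year),
              n_stations_per_year = as.integer(n_stations_per_year),
              n_dams_bq = as.integer(n_dams_bq),
              daughters_per_dam = as.integer(daughters_per_dam),
              n_dpq_per_station = as.integer(n_dpq_per_station),
              drones_per_mating = as.integer(drones_per_mating),
              dam_age_bq = as.integer(dam_age_bq),
              dam_age_dpq = as.integer(dam_age_dpq),
              years = as.integer(years),
              engine = engine,
              n_loci = switch(engine, FL200 = 200L, FL400 = 400L, NULL),
              pedigree_mode = pedigree_mode)
  counts <- unlist(cfg[c("n_bq_per_year", "n_stations_per_year", "n_dams_bq",
                         "daughters_per_dam", "n_dpq_per_station",
                         "drones_per_mating", "years")])
  if (any(counts < 1L))
    stop("configuration error: all counts must be positive", call. = FALSE)
  if (cfg$n_dams_bq * cfg$daughters_per_dam != cfg$n_bq_per_year)
    stop("configuration error: n_dams_bq * daughters_per_dam must equal ",
         "n_bq_per_year", call. = FALSE)
  if (cfg$dam_age_bq != 2L || cfg$dam_age_dpq != 3L)
    stop("configuration error: the scheme supports dam ages 2 (BQ) and 3 ",
         "(DPQ stations)", call. = FALSE)
  structure(cfg, class = "bee_config")
}

#' @export
print.bee_config <- function(x, ...) {
  cat(sprintf(
    "Breeding scheme: %d BQs/year (best %d x %d daughters), %d stations x %d DPQs,\n  %d drones/mating, engine %s, %d years, %s relationships\n",
    x$n_bq_per_year, x$n_dams_bq, x$daughters_per_dam,
    x$n_stations_per_year, x$n_dpq_per_station, x$drones_per_mating,
    x$engine, x$years, x$pedigree_mode))
  invisible(x)
}

#' Truncation selection
#'
#' Top-`k` candidates by selection criterion; ties broken by smaller id
#' for reproducibility.
#'
#' @param candidate_ids Candidate ids.
#' @param sc Selection-criterion values (same length).
#' @param k Number to select.
#' @return The selected ids, best first.
#' @export
select_truncation <- function(candidate_ids, sc, k) {
  stopifnot(length(candidate_ids) == length(sc))
  if (length(candidate_ids) < k)
    stop("configuration error: fewer candidates than required selections",
         call. = FALSE)
  if (anyNA(sc))
    stop("candidates must have evaluated selection criteria", call. = FALSE)
  candidate_ids[order(-sc, candidate_ids)][seq_len(k)]
}

#' Assign full-sister groups to mating stations
#'
#' Every sister group is mapped to one uniformly chosen station of the
#' current year; all members mate there. The assignment ignores breeding
#' values (no inbreeding avoidance).
#'
#' @param n_groups Number of sister groups.
#' @param n_stations Number of stations available this year.
#' @return Integer vector of station indices, one per group.
#' @export
assign_sister_groups <- function(n_groups, n_stations) {
  stopifnot(n_groups >= 1L, n_stations >= 1L)
  sample.int(n_stations, n_groups, replace = TRUE)
}

# ---- alive-kinship bookkeeping ------------------------------------------

k_add_founders <- function(st, ids) {
  A <- length(st$kids); M <- length(ids)
  st$K <- rbind(cbind(st$K, matrix(0, A, M)),
                cbind(matrix(0, M, A), diag(0.5, M)))
  st$kids <- c(st$kids, ids)
  if (st$mode == "expected") {
    Ae <- length(st$keids)
    st$Kexp <- rbind(cbind(st$Kexp, matrix(0, Ae, M)),
                     cbind(matrix(0, M, Ae), diag(0.5, M)))
    st$keids <- c(st$keids, ids)
  }
  rep(0, M)
}

# Add queens (dam B_i, sire drone D_i with drone-dam P_i) to the alive
# kinship; returns exact inbreeding coefficients f(B_i, P_i).
k_add_queens <- function(st, ids, dam, sire, pdam) {
  K <- st$K
  b <- match(dam, st$kids); p <- match(pdam, st$kids)
  if (anyNA(b) || anyNA(p))
    stop("internal error: parent left the alive-kinship window", call. = FALSE)
  M <- length(ids)
  Rows <- 0.5 * K[b, , drop = FALSE] + 0.5 * K[p, , drop = FALSE]
  Kbb <- K[b, b, drop = FALSE]
  Kbp <- K[b, p, drop = FALSE]
  Kpp <- K[p, p, drop = FALSE]
  NN <- 0.25 * (Kbb + Kbp + t(Kbp) + Kpp)
  same <- outer(sire, sire, "==") & !diag(TRUE, M)
  NN[same] <- NN[same] + 0.25 * (1 - Kpp[same])
  Fnew <- K[cbind(b, p)]
  diag(NN) <- 0.5 * (1 + Fnew)
  st$K <- rbind(cbind(K, t(Rows)), cbind(Rows, NN))
  st$kids <- c(st$kids, ids)
  if (st$mode == "expected") kexp_add_queens(st, ids, dam)
  Fnew
}

# Expected-mode kinship: paternal side of a queen is the mean over her
# dam's mating station. Also stores the expected-mode Mendelian diagonal.
# All daughters of one dam share her station, so the update only needs
# one station-mean row per distinct dam.
kexp_add_queens <- function(st, ids, dam) {
  K <- st$Kexp
  M <- length(ids)
  b <- match(dam, st$keids)
  if (anyNA(b))
    stop("internal error: parent left the alive-kinship window", call. = FALSE)
  ud <- unique(dam)
  di <- match(dam, ud)
  ub <- match(ud, st$keids)
  nd <- length(ud)
  srow <- matrix(0, nd, ncol(K))   # station-mean kinship row per dam
  m4 <- Fbar_d <- numeric(nd)
  plist <- vector("list", nd)
  for (k in seq_len(nd)) {
    P <- ped_lget(st$ped$station, ud[k])
    pj <- match(P, st$keids)
    if (anyNA(pj))
      stop("internal error: station left the alive-kinship window",
           call. = FALSE)
    plist[[k]] <- pj
    srow[k, ] <- colMeans(K[pj, , drop = FALSE])
    m4[k] <- mean(K[pj, pj])
    Fbar_d[k] <- mean(K[ub[k], pj])
  }
  Rows <- 0.5 * K[b, , drop = FALSE] + 0.5 * srow[di, , drop = FALSE]
  # NN[i, j] = 0.5 Rows[i, b_j] + 0.5 mean(Rows[i, P_j])
  Tm <- vapply(seq_len(nd), function(k)
    rowMeans(Rows[, plist[[k]], drop = FALSE]), numeric(M))
  Tm <- matrix(Tm, nrow = M)
  NN <- 0.5 * Rows[, b, drop = FALSE] + 0.5 * Tm[, di, drop = FALSE]
  NN <- (NN + t(NN)) / 2
  diag(NN) <- 0.5 * (1 + Fbar_d[di])
  st$Kexp <- rbind(cbind(K, t(Rows)), cbind(Rows, NN))
  st$keids <- c(st$keids, ids)
  st$ped$d_exp[ids] <- 1 - 0.5 * K[cbind(b, b)] - 0.5 * m4[di]
  invisible(NULL)
}

k_prune <- function(st, min_by) {
  keep <- st$ped$by[st$kids] >= min_by
  st$K <- st$K[keep, keep, drop = FALSE]
  st$kids <- st$kids[keep]
  if (st$mode == "expected") {
    keep <- st$ped$by[st$keids] >= min_by
    st$Kexp <- st$Kexp[keep, keep, drop = FALSE]
    st$keids <- st$keids[keep]
  }
}

# ---- engine dispatch -----------------------------------------------------

eng_founders <- function(st, n, year, dpq = FALSE) {
  ids <- ped_add_queens(st$ped, n, birth_year = year, F = 0)
  if (st$cfg$engine == "INF") {
    tbv <- inf_founder_tbv(st$par, n)
  } else {
    G <- sample_founder_genome(st$locus_set, n)
    for (i in seq_len(n)) ped_lset(st$geno, ids[i], G[i, ])
    tbv <- tbv_fl(G, st$locus_set)
  }
  st$ped$tbv_d[ids] <- tbv[, 1L]
  st$ped$tbv_m[ids] <- tbv[, 2L]
  k_add_founders(st, ids)
  ids
}

# Create daughter queens of dams `dam` sired by stored drones `sire`.
eng_queens <- function(st, dam, sire, year) {
  ped <- st$ped
  pdam <- ped$dam[sire]
  ids <- ped_add_queens(ped, length(dam), dam = dam, sire = sire,
                        birth_year = year, F = NA_real_)
  if (st$cfg$engine == "INF") {
    tbv_B <- cbind(ped$tbv_d[dam], ped$tbv_m[dam])
    tbv_D <- cbind(ped$tbv_d[sire], ped$tbv_m[sire])
    tbv <- inf_inherit_queen(tbv_B, tbv_D, ped$F[dam], st$par)
  } else {
    ud <- unique(dam)
    damG <- do.call(rbind, ped_lmget(st$geno, ud))[match(dam, ud), ,
                                                 drop = FALSE]
    ridx <- vapply(seq_along(sire), function(i)
      match(sire[i], ped_lget(ped$mates, dam[i])), integer(1L))
    sireG <- do.call(rbind, lapply(seq_along(sire), function(i)
      ped_lget(st$drone_geno, dam[i])[ridx[i], ]))
    G <- make_queen_genome(sample_gamete(damG), sireG)
    for (i in seq_along(ids)) ped_lset(st$geno, ids[i], G[i, ])
    tbv <- tbv_fl(G, st$locus_set)
  }
  ped$tbv_d[ids] <- tbv[, 1L]
  ped$tbv_m[ids] <- tbv[, 2L]
  ped$F[ids] <- k_add_queens(st, ids, dam, sire, pdam)
  ids
}

# Create drones of queen dams `dam` (vectorized over drones).
eng_drones <- function(st, dam, year) {
  ped <- st$ped
  ids <- ped_add_drones(ped, length(dam), dam = dam, birth_year = year)
  if (st$cfg$engine == "INF") {
    tbv_Q <- cbind(ped$tbv_d[dam], ped$tbv_m[dam])
    tbv <- inf_inherit_drone(tbv_Q, ped$F[dam], st$par)
    G <- NULL
  } else {
    ud <- unique(dam)
    damG <- do.call(rbind, ped_lmget(st$geno, ud))[match(dam, ud), ,
                                                 drop = FALSE]
    G <- sample_gamete(damG)
    tbv <- tbv_fl(G, st$locus_set, ploidy = "haploid")
  }
  ped$tbv_d[ids] <- tbv[, 1L]
  ped$tbv_m[ids] <- tbv[, 2L]
  list(ids = ids, geno = G)
}

# ---- state ---------------------------------------------------------------

#' Initialize a simulation state
#'
#' Sets up the mutable simulation state (pedigree, kinship window, genome
#' store, record store). Used by [run_simulation()]; exposed for stepwise
#' runs via [run_year()].
#'
#' @param config A [bee_config()].
#' @param params A [bee_params()].
#' @param locus_set Optional pre-built [build_founder_locus_set()] locus
#'   set (finite-locus engines); built on the fly when `NULL`.
#' @return An environment of class `bee_state`.
#' @export
bee_init_state <- function(config, params, locus_set = NULL) {
  stopifnot(inherits(config, "bee_config"), inherits(params, "bee_params"))
  st <- new.env(parent = emptyenv())
  st$cfg <- config
  st$par <- params
  st$mode <- config$pedigree_mode
  if (config$engine != "INF") {
    if (is.null(locus_set))
      locus_set <- build_founder_locus_set(params, config$n_loci)
    stopifnot(inherits(locus_set, "locus_set"),
              locus_set$n_loci == config$n_loci)
  }
  st$locus_set <- locus_set
  st$ped <- ped_new(4096L)
  st$K <- matrix(0, 0L, 0L); st$kids <- integer(0L)
  st$Kexp <- matrix(0, 0L, 0L); st$keids <- integer(0L)
  st$geno <- new.env(parent = emptyenv())        # queen id -> allele counts
  st$drone_geno <- new.env(parent = emptyenv())  # queen id -> 12 x n gametes
  st$cohort_bq <- list()     # year -> BQ ids
  st$stations <- list()      # current year's stations: list of DPQ id vectors
  st$dpq_prev <- integer(0L) # last year's DPQs (genomes pruned next year)
  st$sc <- numeric(0L)       # latest SC by queen id
  st$rec <- list(queen_id = integer(0L), worker_group_id = integer(0L),
                 year = integer(0L), value = numeric(0L),
                 pc = numeric(0L), sc_true = numeric(0L))
  st$stats <- list()
  st$year <- 0L
  class(st) <- "bee_state"
  st
}

sc_of <- function(st, ids) {
  out <- rep(NA_real_, length(ids))
  known <- ids <= length(st$sc)
  out[known] <- st$sc[ids[known]]
  out
}

#' Advance the simulation by one year
#'
#' Runs the yearly event sequence (queen production, mating, performance
#' test of the one-year-old cohort, BLUP evaluation) on a [bee_init_state()]
#' state.
#'
#' @param st A `bee_state`.
#' @param verbose Print per-year progress to stderr.
#' @return The state, invisibly.
#' @export
run_year <- function(st, verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  cfg <- st$cfg; ped <- st$ped
  t <- st$year + 1L
  st$year <- t

  # drop genomes and kinship rows no longer needed: DPQ genomes only serve
  # drone production in their own year; BQ genomes and stored drone genomes
  # until the queen's last year as a dam (age 3)
  drop_keys <- function(env, ids) {
    keys <- as.character(ids)
    rm(list = keys[vapply(keys, exists, logical(1L), envir = env,
                          inherits = FALSE)], envir = env)
  }
  drop_keys(st$geno, st$dpq_prev)
  st$dpq_prev <- integer(0L)
  if (t > 4L) {
    drop_keys(st$geno, st$cohort_bq[[t - 4L]])
    drop_keys(st$drone_geno, st$cohort_bq[[t - 4L]])
    k_prune(st, t - 3L)
  }

  # --- (1a) mating stations of the year -------------------------------
  sel_dpq_sc <- NA_real_
  dpq_ids <- integer(0L)
  if (t <= 3L) {
    st$stations <- lapply(seq_len(cfg$n_stations_per_year), function(s)
      eng_founders(st, cfg$n_dpq_per_station, t))
    dpq_ids <- unlist(st$stations)
  } else {
    cands <- st$cohort_bq[[t - cfg$dam_age_dpq]]
    dams <- select_truncation(cands, sc_of(st, cands),
                              cfg$n_stations_per_year)
    sel_dpq_sc <- mean(sc_of(st, dams))
    st$stations <- lapply(dams, function(dm) {
      sires <- ped_lget(ped$mates, dm)[sample.int(cfg$drones_per_mating,
                                          cfg$n_dpq_per_station,
                                          replace = TRUE)]
      eng_queens(st, rep(dm, cfg$n_dpq_per_station), sires, t)
    })
    dpq_ids <- unlist(st$stations)
  }

  # --- (1b) new breeding queens ----------------------------------------
  sel_bq_sc <- cand_bq_sc <- NA_real_
  if (t <= 2L) {
    bqs <- eng_founders(st, cfg$n_bq_per_year, t)
    groups <- seq_along(bqs)           # base queens: singleton sister groups
    group_of <- seq_along(bqs)
  } else {
    cands <- st$cohort_bq[[t - cfg$dam_age_bq]]
    cand_sc <- sc_of(st, cands)
    dams <- select_truncation(cands, cand_sc, cfg$n_dams_bq)
    sel_bq_sc <- mean(sc_of(st, dams))
    cand_bq_sc <- mean(cand_sc)
    dam_vec <- rep(dams, each = cfg$daughters_per_dam)
    sire_vec <- vapply(dam_vec, function(dm)
      ped_lget(ped$mates, dm)[sample.int(cfg$drones_per_mating, 1L)],
      integer(1L))
    bqs <- eng_queens(st, dam_vec, sire_vec, t)
    group_of <- rep(seq_along(dams), each = cfg$daughters_per_dam)
    groups <- seq_along(dams)
  }
  st$cohort_bq[[t]] <- bqs

  # --- (2) queen mating -------------------------------------------------
  station_of_group <- assign_sister_groups(length(groups),
                                           cfg$n_stations_per_year)
  station_of_bq <- station_of_group[group_of]
  ndr <- cfg$drones_per_mating
  drone_dams <- unlist(lapply(station_of_bq, function(s)
    st$stations[[s]][sample.int(cfg$n_dpq_per_station, ndr, replace = TRUE)]))
  dr <- eng_drones(st, drone_dams, t)
  for (i in seq_along(bqs)) {
    rows <- (i - 1L) * ndr + seq_len(ndr)
    ped_lset(ped$mates, bqs[i], dr$ids[rows])
    ped_lset(ped$station, bqs[i], st$stations[[station_of_bq[i]]])
    if (!is.null(dr$geno))
      ped_lset(st$drone_geno, bqs[i], dr$geno[rows, , drop = FALSE])
  }
  st$dpq_prev <- dpq_ids
  # genetic values of the cohort's prospective colonies, known at mating
  drm <- matrix(dr$ids, nrow = length(bqs), byrow = TRUE)
  coh_Wd <- 0.5 * (ped$tbv_d[bqs] +
                     rowMeans(matrix(ped$tbv_d[drm], nrow = length(bqs))))
  coh_pc <- ped$tbv_m[bqs] + coh_Wd

  # --- (3) colony production and performance test ----------------------
  n_col <- 0L
  if (t >= 2L) {
    qs <- st$cohort_bq[[t - 1L]]
    n_col <- length(qs)
    mat <- matrix(unlist(ped_lmget(ped$mates, qs)), nrow = n_col,
                  byrow = TRUE)
    tbvW_d <- 0.5 * (ped$tbv_d[qs] +
                       rowMeans(matrix(ped$tbv_d[mat], nrow = n_col)))
    tbvW_m <- 0.5 * (ped$tbv_m[qs] +
                       rowMeans(matrix(ped$tbv_m[mat], nrow = n_col)))
    wg <- integer(n_col)
    for (i in seq_len(n_col))
      wg[i] <- ped_add_worker_group(ped, qs[i], mat[i, ], t)
    ped$tbv_d[wg] <- tbvW_d
    ped$tbv_m[wg] <- tbvW_m
    if (st$mode == "expected") {
      for (i in seq_len(n_col)) {
        P <- match(ped_lget(ped$station, qs[i]), st$keids)
        ped$d_exp[wg[i]] <- (1 - mean(st$Kexp[P, P])) / (2 * ndr)
      }
    }
    pc <- ped$tbv_m[qs] + tbvW_d
    y <- pc + rnorm(n_col, 0, sqrt(st$par$sigma2_E))
    st$rec$queen_id <- c(st$rec$queen_id, qs)
    st$rec$worker_group_id <- c(st$rec$worker_group_id, wg)
    st$rec$year <- c(st$rec$year, rep(t, n_col))
    st$rec$value <- c(st$rec$value, y)
    st$rec$pc <- c(st$rec$pc, pc)
    st$rec$sc_true <- c(st$rec$sc_true, tbvW_d + tbvW_m)
  }

  # --- (4) breeding value estimation -----------------------------------
  bias_sc <- acc_d <- acc_m <- NA_real_
  if (t >= 2L) {
    recs <- data.frame(queen_id = st$rec$queen_id,
                       worker_group_id = st$rec$worker_group_id,
                       value = st$rec$value)
    fit <- solve_blup(ped, recs, st$par, mode = st$mode)
    ed <- em <- rep(NA_real_, ped$n)
    ed[fit$ebv$id] <- fit$ebv$ebv_d
    em[fit$ebv$id] <- fit$ebv$ebv_m
    all_w <- st$rec$worker_group_id
    sc_est_all <- ed[all_w] + em[all_w]
    sc <- st$sc
    length(sc) <- ped$n
    sc[st$rec$queen_id] <- sc_est_all
    st$sc <- sc
    st$ebv <- fit
    this <- st$rec$year == t
    if (any(this)) {
      w_t <- all_w[this]
      bias_sc <- mean(sc_est_all[this]) / mean(st$rec$sc_true[this])
      acc_d <- cor(ed[w_t], ped$tbv_d[w_t])
      acc_m <- cor(em[w_t], ped$tbv_m[w_t])
    }
  }

  # --- (5) cohort / colony statistics ----------------------------------
  this <- if (t >= 2L) which(st$rec$year == t) else integer(0L)
  st$stats[[t]] <- data.frame(
    year = t,
    n_bq = length(bqs),
    mean_d_BQ = mean(ped$tbv_d[bqs]),
    mean_m_BQ = mean(ped$tbv_m[bqs]),
    mean_F = mean(ped$F[bqs]),
    mean_PC = mean(coh_pc),
    var_PC = var(coh_pc),
    n_colonies = n_col,
    mean_PC_tested = if (length(this)) mean(st$rec$pc[this]) else NA_real_,
    var_PC_tested = if (length(this)) var(st$rec$pc[this]) else NA_real_,
    bias_SC = bias_sc,
    acc_d = acc_d,
    acc_m = acc_m,
    wq_excess = mean(coh_Wd - ped$tbv_d[bqs]),
    dam_sc_selected = sel_bq_sc,
    dam_sc_cohort = cand_bq_sc,
    dpq_dam_sc_selected = sel_dpq_sc)
  if (verbose)
    message(sprintf("year %3d: %d nodes, %d records, %.2fs", t, ped$n,
                    length(st$rec$value), proc.time()[["elapsed"]] - t0))
  invisible(st)
}

#' Run a breeding-program simulation
#'
#' Executes the full yearly event loop for `config$years` years and
#' returns the per-year statistics, the pedigree and the phenotype
#' records. Identical seeds give bit-identical results.
#'
#' @param config A [bee_config()].
#' @param params A [bee_params()].
#' @param seed Integer seed for the run (set once at the start).
#' @param locus_set Optional pre-built locus set for finite-locus engines,
#'   allowing several runs to share one founder allele distribution.
#' @param verbose Print per-year progress.
#' @return An object of class `bee_sim`: list with `stats` (one row per
#'   year, see Details), `records`, the final `ebv` fit, `config`,
#'   `params`, `locus_set`, `seed` and the `pedigree` state.
#'
#' @details The `stats` data frame contains, per year: the mean direct and
#' maternal true breeding value and mean inbreeding of the year's BQ
#' cohort; the mean and variance of the performance criterion
#' `PC = TBV_Qm + TBV_Wd` over that cohort's colonies (`mean_PC`,
#' `var_PC`; the genetic part of a colony is fixed at mating, so these
#' align with the cohort of the same year) and over the colonies
#' performance-tested in the year (`mean_PC_tested`, `var_PC_tested`, the
#' previous cohort); the ratio of mean estimated to mean true selection
#' criterion over the tested colonies (`bias_SC`); the correlations of
#' worker-group estimated and true breeding values (`acc_d`, `acc_m`);
#' the mean excess of worker-group over queen direct TBV (`wq_excess`);
#' and selection bookkeeping (mean SC of selected dams vs. their cohort).
#' @examples
#' \donttest{
#' sim <- run_simulation(bee_config(years = 6, engine = "INF"), bee_params(),
#'                       seed = 1)
#' sim$stats[, c("year", "mean_d_BQ", "mean_m_BQ", "mean_PC", "mean_F")]
#' }
#' @export
run_simulation <- function(config, params = bee_params(), seed = NULL,
                           locus_set = NULL, verbose = FALSE) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  st <- bee_init_state(config, params, locus_set)
  for (t in seq_len(config$years)) run_year(st, verbose = verbose)
  structure(
    list(stats = do.call(rbind, st$stats),
         records = data.frame(queen_id = st$rec$queen_id,
                              worker_group_id = st$rec$worker_group_id,
                              year = st$rec$year, value = st$rec$value,
                              pc = st$rec$pc, sc_true = st$rec$sc_true),
         ebv = st$ebv,
         config = config, params = params,
         locus_set = st$locus_set, seed = seed,
         pedigree = st$ped),
    class = "bee_sim")
}

#' @export
print.bee_sim <- function(x, ...) {
  ny <- nrow(x$stats)
  cat(sprintf("Breeding simulation (%s, %d BQs/year, %d years)\n",
              x$config$engine, x$config$n_bq_per_year, ny))
  cat(sprintf("  final gains: maternal %.2f, direct %.2f, PC %.2f; mean F %.3f\n",
              x$stats$mean_m_BQ[ny], x$stats$mean_d_BQ[ny],
              x$stats$mean_PC[ny], x$stats$mean_F[ny]))
  invisible(x)
}
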