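# ------------------------------------------------------------------------
# Bivariate pedigree BLUP of direct (worker) and maternal (queen) effects
# from colony phenotypes.
#
# Model: y = 1 mu + Z_d u_d(worker group) + Z_m u_m(queen) + e with the
# stacked bivariate genetic effect u ~ N(0, A (x) Sigma_A) and
# e ~ N(0, I sigma2_E). Genetic parameters are fixed (never re-estimated).
# The mixed-model equations are solved by a direct sparse Cholesky
# factorization (CHOLMOD through the Matrix package), with A^-1 assembled
# from the regression-on-parents decomposition A^-1 = U' D^-1 U.
#
# Exact relationship mode: every realized sire drone is a pedigree node.
# Drones without offspring at evaluation time enter the model only through
# the 1/24 weight in their worker group, so they are marginalized exactly:
# the worker group keeps their dams as parents and receives the summed
# drone Mendelian variance sum((1 - F_dam)) / 576 as its residual
# diagonal. This leaves the solutions of all remaining effects unchanged
# and keeps the equations well conditioned; the marginalized drones' EBVs
# are recovered afterwards from the worker-group residual.
#
# Expected relationship mode: paternity is averaged over the mating
# station's DPQs; drones drop out, queens regress on (dam, station) and
# worker groups on (queen, station) with the drone-sampling diagonal
# (1 - mean station coancestry) / 24.
# ------------------------------------------------------------------------

#' Solve the bivariate BLUP mixed-model equations
#'
#' Estimates direct and maternal breeding values for all pedigree nodes
#' from colony phenotypes, with a single overall mean as the only fixed
#' effect and genetic (co)variances taken from `params` as-is.
#'
#' @param ped A `bee_pedigree` containing every phenotyped queen and
#'   worker group along with all their ancestors.
#' @param records Data frame of phenotype records with columns `queen_id`,
#'   `worker_group_id` and `value` (one row per tested colony).
#' @param params A [bee_params()] object; supplies `Sigma_A` and
#'   `sigma2_E`.
#' @param mode `"exact"` (realized sire drones, default) or `"expected"`
#'   (paternity averaged over the mating station's 8 DPQs).
#' @return An object of class `bee_ebv`: list with the overall mean `mu`
#'   and a data frame `ebv` with columns `id`, `role`, `ebv_d`, `ebv_m`
#'   covering every queen and worker group (and, in exact mode, every
#'   drone).
#' @examples
#' ped <- ped_new()
#' dpq <- ped_add_queens(ped, 1)
#' q <- ped_add_queens(ped, 1)
#' d <- ped_add_drones(ped, 12, dam = dpq)
#' w <- ped_add_worker_group(ped, q, d)
#' r <- data.frame(queen_id = q, worker_group_id = w, value = 3.2)
#' fit <- solve_blup(ped, r, bee_params())
#' fit$mu          # a single record is absorbed by the mean
#' @export
solve_blup <- function(ped, records, params, mode = c("exact", "expected")) {
  mode <- match.arg(mode)
  if (is.null(records) || nrow(records) == 0L)
    stop("empty-evaluation error: no phenotype records", call. = FALSE)
  stopifnot(all(c("queen_id", "worker_group_id", "value") %in%
                  names(records)))
  ids <- seq_len(ped$n)
  role <- ped$role[ids]
  q <- as.integer(records$queen_id)
  w <- as.integer(records$worker_group_id)
  ped_check_ids(ped, c(q, w))
  if (any(ped$role[q] != ROLE_QUEEN) || any(ped$role[w] != ROLE_WORKER))
    stop("records must reference a queen and her worker group",
         call. = FALSE)

  if (mode == "exact") {
    # drones with offspring stay; the rest are marginalized into their
    # worker group's residual diagonal
    fold <- logical(ped$n)
    fold[role == ROLE_DRONE] <- TRUE
    sires <- ped$sire[role == ROLE_QUEEN]
    fold[sires[!is.na(sires)]] <- FALSE
    nodes <- ids[!fold]
  } else {
    fold <- NULL
    nodes <- ids[role != ROLE_DRONE]
  }
  N <- length(nodes)
  map <- integer(ped$n)
  map[nodes] <- seq_len(N)

  reg <- if (mode == "exact")
    ped_regression(ped, nodes, map, fold = fold)
  else
    ped_regression_expected(ped, nodes, map)
  Ainv <- Matrix::crossprod(Matrix::Diagonal(x = 1 / sqrt(reg$d)) %*% reg$U)
  Ginv <- Matrix::kronecker(Ainv, params$Sigma_inv)  # node-major (d, m)

  # design: column 1 the mean, then 2x2 (d, m) blocks per node
  col_of <- function(id, comp) 1L + 2L * (map[id] - 1L) + comp
  nrec <- nrow(records)
  P <- 1L + 2L * N
  W <- Matrix::sparseMatrix(
    i = rep.int(seq_len(nrec), 3L),
    j = c(rep(1L, nrec), col_of(q, 2L), col_of(w, 1L)),
    x = rep(1, 3L * nrec), dims = c(nrec, P))
  y <- as.numeric(records$value)

  lhs <- Matrix::crossprod(W) / params$sigma2_E +
    Matrix::bdiag(Matrix::Matrix(0, 1L, 1L, sparse = TRUE), Ginv)
  rhs <- Matrix::crossprod(W, y) / params$sigma2_E
  sol <- as.numeric(Matrix::solve(Matrix::forceSymmetric(lhs, "U"), rhs))

  mu <- sol[1L]
  u <- matrix(sol[-1L], ncol = 2L, byrow = TRUE)
  ebv_d <- ebv_m <- rep(NA_real_, ped$n)
  ebv_d[nodes] <- u[, 1L]
  ebv_m[nodes] <- u[, 2L]

  if (mode == "exact" && any(fold)) {
    # recover marginalized drone EBVs from the worker-group residuals:
    # eta_w = u_w - b' u_parents; phi_k = (1 - F_damk)/24 / d_w * eta_w
    eta <- as.matrix(reg$U %*% u)          # rows = local node positions
    fids <- ids[fold]
    ebv_d[fids] <- ebv_d[ped$dam[fids]]
    ebv_m[fids] <- ebv_m[ped$dam[fids]]
    wgs <- ids[role == ROLE_WORKER]
    for (wg in wgs) {
      m <- ped_lget(ped$wg_members, wg)
      dr <- m[-1L][fold[m[-1L]]]
      if (!length(dr)) next
      a <- 0.5 / (length(m) - 1L)
      coef <- a * (1 - ped_F_of(ped, ped$dam[dr])) / reg$d[map[wg]]
      ebv_d[dr] <- ebv_d[dr] + coef * eta[map[wg], 1L]
      ebv_m[dr] <- ebv_m[dr] + coef * eta[map[wg], 2L]
    }
  }

  keep <- if (mode == "exact") ids else ids[role != ROLE_DRONE]
  structure(
    list(mu = mu, mode = mode,
         ebv = data.frame(id = keep, role = ROLE_NAMES[ped$role[keep]],
                          ebv_d = ebv_d[keep], ebv_m = ebv_m[keep])),
    class = "bee_ebv")
}

# Expected-mode regression decomposition over queens + worker groups.
ped_regression_expected <- function(ped, ids, map) {
  role <- ped$role[ids]
  N <- length(ids)
  d <- numeric(N)
  ti <- tj <- tx <- list()
  k <- 0L
  add <- function(i, j, x) {
    k <<- k + 1L
    ti[[k]] <<- i; tj[[k]] <<- j; tx[[k]] <<- x
  }
  qs <- ids[role == ROLE_QUEEN]
  add(map[qs], map[qs], rep(1, length(qs)))
  for (qq in qs) {
    B <- ped$dam[qq]
    if (is.na(B)) {
      d[map[qq]] <- 1
      next
    }
    P <- ped_station_of_dam(ped, qq)
    if (map[B] == 0L || any(map[P] == 0L))
      stop("missing-node error: parents of requested nodes must be included",
           call. = FALSE)
    d[map[qq]] <- ped_d_exp_queen(ped, qq)
    add(rep(map[qq], 1L + length(P)), c(map[B], map[P]),
        c(-0.5, rep(-0.5 / length(P), length(P))))
  }
  ws <- ids[role == ROLE_WORKER]
  for (wg in ws) {
    qq <- ped_lget(ped$wg_members, wg)[1L]
    P <- ped_lget(ped$station, qq)
    if (is.null(P))
      stop("expected mode requires station information for mated queens",
           call. = FALSE)
    if (map[qq] == 0L || any(map[P] == 0L))
      stop("missing-node error: parents of requested nodes must be included",
           call. = FALSE)
    d[map[wg]] <- ped_d_exp_wg(ped, wg)
    add(rep(map[wg], 2L + length(P)), c(map[wg], map[qq], map[P]),
        c(1, -0.5, rep(-0.5 / length(P), length(P))))
  }
  U <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(N, N))
  list(U = U, d = d)
}

#' Selection criterion of a colony
#'
#' The selection criterion (SC) is the sum of the worker group's estimated
#' direct and maternal breeding values.
#'
#' @param ebv A `bee_ebv` object from [solve_blup()].
#' @param worker_group_id Worker-group ids (vectorized).
#' @return Numeric vector of SC values.
#' @export
selection_criterion <- function(ebv, worker_group_id) {
  stopifnot(inherits(ebv, "bee_ebv"))
  idx <- match(worker_group_id, ebv$ebv$id)
  if (anyNA(idx))
    stop("missing-node error: worker group not in the evaluation",
         call. = FALSE)
  ebv$ebv$ebv_d[idx] + ebv$ebv$ebv_m[idx]
}

#' Export estimated breeding values as CSV
#'
#' Columns `entity_id, role, ebv_d, ebv_m, SC` (SC filled for worker
#' groups only).
#'
#' @param ebv A `bee_ebv` object.
#' @param path Output path.
#' @export
write_ebv <- function(ebv, path) {
  df <- ebv$ebv
  sc <- ifelse(df$role == "worker_group", df$ebv_d + df$ebv_m, NA_real_)
  out <- data.frame(entity_id = df$id, role = df$role,
                    ebv_d = df$ebv_d, ebv_m = df$ebv_m, SC = sc)
  write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE,
              na = "")
  invisible(path)
}

#' @export
print.bee_ebv <- function(x, ...) {
  cat(sprintf("BLUP evaluation (%s relationship mode): %d entities, mu = %.4f\n",
              x$mode, nrow(x$ebv), x$mu))
  invisible(x)
}
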