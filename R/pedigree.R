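# ------------------------------------------------------------------------
# Exact haplodiploid pedigree bookkeeping.
#
# Nodes are queens, individually tracked haploid drones, and worker groups
# (deterministic linear combinations of a queen and her 12 mates). Ids are
# strictly increasing with creation time, so for any pair the node with the
# larger id can never be an ancestor of the other; kinship recursion always
# unfolds the larger id.
#
# Coancestry conventions (f = probability of identity by descent of two
# randomly drawn alleles, one per individual; numerator relationship
# a = 2 f):
#   base queens:            f(X, X) = 1/2, f(X, Y) = 0
#   queen Q = (dam B, sire drone D):
#                           f(Q, X) = (f(B, X) + f(D, X)) / 2,
#                           f(Q, Q) = (1 + f(B, D)) / 2
#   drone D (dam P):        f(D, X) = f(P, X), f(D, D) = 1
#                           (a drone carries a single genome and transmits
#                           it whole; equivalently diploid-homozygous)
#   worker group:           bilinear in member weights
#                           (queen 1/2, each of k drones 1/(2k))
# ------------------------------------------------------------------------

ROLE_QUEEN <- 1L
ROLE_DRONE <- 2L
ROLE_WORKER <- 3L
ROLE_NAMES <- c("queen", "drone", "worker_group")

#' Create an empty haplodiploid pedigree
#'
#' @param n_hint Initial storage capacity (grown automatically).
#' @return An environment of class `bee_pedigree`.
#' @export
ped_new <- function(n_hint = 256L) {
  ped <- new.env(parent = emptyenv())
  ped$n <- 0L
  ped$cap <- as.integer(max(n_hint, 16L))
  ped$role <- integer(ped$cap)
  ped$by <- integer(ped$cap)
  ped$dam <- rep(NA_integer_, ped$cap)
  ped$sire <- rep(NA_integer_, ped$cap)
  ped$F <- rep(NA_real_, ped$cap)
  ped$tbv_d <- rep(NA_real_, ped$cap)
  ped$tbv_m <- rep(NA_real_, ped$cap)
  ped$d_exp <- rep(NA_real_, ped$cap)     # expected-mode Mendelian diagonal
  # id-keyed hash stores (environments: O(1) in-place assignment)
  ped$wg_members <- new.env(parent = emptyenv())  # worker group -> members
  ped$station <- new.env(parent = emptyenv())     # mated queen -> 8 DPQs
  ped$mates <- new.env(parent = emptyenv())       # mated queen -> 12 drones
  ped$memo <- new.env(parent = emptyenv())
  ped$memo_exp <- new.env(parent = emptyenv())
  class(ped) <- "bee_pedigree"
  ped
}

ped_grow <- function(ped, need) {
  while (ped$n + need > ped$cap) {
    newcap <- ped$cap * 2L
    for (f in c("role", "by", "dam", "sire")) {
      v <- ped[[f]]
      length(v) <- newcap
      ped[[f]] <- v
    }
    for (f in c("F", "tbv_d", "tbv_m", "d_exp")) {
      v <- ped[[f]]
      length(v) <- newcap
      ped[[f]] <- v
    }
    ped$cap <- newcap
  }
}

ped_add_nodes <- function(ped, n, role, birth_year, dam = NA_integer_,
                          sire = NA_integer_, F = NA_real_) {
  ped_grow(ped, n)
  ids <- ped$n + seq_len(n)
  if (!all(is.na(dam)) && any(dam >= ids[1L], na.rm = TRUE))
    stop("pedigree-order error: parents must be created before offspring",
         call. = FALSE)
  if (!all(is.na(sire)) && any(sire >= ids[1L], na.rm = TRUE))
    stop("pedigree-order error: parents must be created before offspring",
         call. = FALSE)
  ped$role[ids] <- role
  ped$by[ids] <- as.integer(birth_year)
  ped$dam[ids] <- as.integer(dam)
  ped$sire[ids] <- as.integer(sire)
  ped$F[ids] <- F
  ped$n <- ped$n + n
  ids
}

#' Add nodes to a pedigree
#'
#' Queens outside the base population need both a dam (queen) and a sire
#' drone; drones have a dam only; a worker group is the deterministic
#' combination of its queen (weight 1/2) and her mates (equal weights
#' summing to 1/2). Ids are assigned in creation order.
#'
#' @param ped A [ped_new()] pedigree.
#' @param n Number of nodes to add (queens/drones).
#' @param dam,sire Parent ids (vectors recycled to length `n`); `NA` for
#'   base-population queens.
#' @param birth_year Integer year.
#' @param F Known inbreeding coefficients; computed lazily when `NA`.
#' @param queen,drones Worker-group members.
#' @return Integer vector of new ids (scalar for the worker group).
#' @export
ped_add_queens <- function(ped, n = 1L, dam = NA_integer_, sire = NA_integer_,
                           birth_year = 0L, F = NA_real_) {
  if (any(is.na(dam) != is.na(sire)))
    stop("queens need either both parents or none", call. = FALSE)
  if (!all(is.na(sire)) && any(ped$role[sire[!is.na(sire)]] != ROLE_DRONE))
    stop("a queen's sire must be a drone", call. = FALSE)
  F <- rep_len(F, n)
  F[is.na(dam) & is.na(F)] <- 0
  ped_add_nodes(ped, n, ROLE_QUEEN, birth_year, rep_len(dam, n),
                rep_len(sire, n), F)
}

#' @rdname ped_add_queens
#' @export
ped_add_drones <- function(ped, n = 1L, dam, birth_year = 0L) {
  dam <- rep_len(dam, n)
  if (any(is.na(dam)) || any(ped$role[dam] != ROLE_QUEEN))
    stop("every drone needs a queen dam", call. = FALSE)
  ped_add_nodes(ped, n, ROLE_DRONE, birth_year, dam)
}

#' @rdname ped_add_queens
#' @export
ped_add_worker_group <- function(ped, queen, drones, birth_year = 0L) {
  stopifnot(length(queen) == 1L, length(drones) >= 1L)
  if (ped$role[queen] != ROLE_QUEEN || any(ped$role[drones] != ROLE_DRONE))
    stop("worker group needs one queen and her drone mates", call. = FALSE)
  id <- ped_add_nodes(ped, 1L, ROLE_WORKER, birth_year)
  ped_lset(ped$wg_members, id, c(queen, drones))
  id
}

ped_check_ids <- function(ped, ids) {
  if (any(is.na(ids)) || any(ids < 1L) || any(ids > ped$n))
    stop("missing-node error: unknown pedigree id", call. = FALSE)
}

# accessors for the id-keyed hash stores
ped_lget <- function(env, id) {
  get0(as.character(id), envir = env, inherits = FALSE)
}
ped_lset <- function(env, id, value) {
  assign(as.character(id), value, envir = env)
}
ped_lmget <- function(env, ids) {
  mget(as.character(ids), envir = env, ifnotfound = list(NULL))
}

#' Mates, station and worker-group members of a node
#'
#' Lookup helpers for the per-queen mating records (12 drone ids, 8
#' station DPQ ids, set at mating) and worker-group member lists
#' (queen first, then her mates). Return `NULL` when not set.
#'
#' @param ped A `bee_pedigree`.
#' @param id Node id.
#' @return Integer vector of node ids, or `NULL`.
#' @export
ped_mates <- function(ped, id) ped_lget(ped$mates, id)

#' @rdname ped_mates
#' @export
ped_station <- function(ped, id) ped_lget(ped$station, id)

#' @rdname ped_mates
#' @export
ped_members <- function(ped, id) ped_lget(ped$wg_members, id)

wg_weights <- function(k) c(0.5, rep(0.5 / (k - 1L), k - 1L))

#' Coancestry (kinship) of two pedigree nodes
#'
#' Exact recursive coancestry through individually tracked drones,
#' memoized on ordered id pairs. Satisfies `f(D, D) = 1` for drones,
#' `f(Q, Q) = (1 + F_Q) / 2` for queens, and bilinearity for worker
#' groups. The numerator (additive) relationship is `2 * kinship()`.
#'
#' @param ped A `bee_pedigree`.
#' @param a,b Node ids.
#' @return Coancestry value in `[0, 1]`.
#' @export
kinship <- function(ped, a, b) {
  ped_check_ids(ped, c(a, b))
  kin_rec(ped, as.integer(a), as.integer(b))
}

kin_rec <- function(ped, a, b) {
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  key <- paste0(a, ":", b)
  hit <- ped$memo[[key]]
  if (!is.null(hit)) return(hit)
  role_b <- ped$role[b]
  val <-
    if (a == b) {
      if (role_b == ROLE_QUEEN) {
        if (is.na(ped$dam[b])) 0.5
        else 0.5 * (1 + kin_rec(ped, ped$dam[b], ped$sire[b]))
      } else if (role_b == ROLE_DRONE) {
        1
      } else {
        m <- ped_lget(ped$wg_members, b)
        w <- wg_weights(length(m))
        s <- 0
        for (i in seq_along(m))
          for (j in seq_along(m))
            s <- s + w[i] * w[j] * kin_rec(ped, m[i], m[j])
        s
      }
    } else {
      if (role_b == ROLE_QUEEN) {
        if (is.na(ped$dam[b])) 0
        else 0.5 * (kin_rec(ped, a, ped$dam[b]) +
                    kin_rec(ped, a, ped$sire[b]))
      } else if (role_b == ROLE_DRONE) {
        kin_rec(ped, a, ped$dam[b])
      } else {
        m <- ped_lget(ped$wg_members, b)
        w <- wg_weights(length(m))
        sum(w * vapply(m, function(mi) kin_rec(ped, a, mi), numeric(1L)))
      }
    }
  ped$memo[[key]] <- val
  val
}

#' Inbreeding coefficient of a queen
#'
#' The coancestry of the queen's parents; base-population queens have
#' `F = 0`. Values stored at creation time (as the simulation engine does)
#' are returned directly; otherwise `F` is computed from the pedigree and
#' cached.
#'
#' @param ped A `bee_pedigree`.
#' @param id Queen id.
#' @return Inbreeding coefficient in `[0, 1]`.
#' @export
inbreeding <- function(ped, id) {
  ped_check_ids(ped, id)
  if (ped$role[id] != ROLE_QUEEN)
    stop("inbreeding is defined for queens", call. = FALSE)
  if (!is.na(ped$F[id])) return(ped$F[id])
  Fq <- if (is.na(ped$dam[id])) 0 else kin_rec(ped, ped$dam[id], ped$sire[id])
  ped$F[id] <- Fq
  Fq
}

#' Dense numerator relationship matrix
#'
#' `A[a, b] = 2 * kinship(a, b)` over the requested nodes; worker-group
#' rows expand bilinearly over member weights. Symmetric positive
#' semidefinite (exactly singular when worker groups are included, since
#' they are linear combinations of their members).
#'
#' @param ped A `bee_pedigree`.
#' @param ids Node ids (default: all nodes).
#' @return Dense symmetric matrix.
#' @export
build_relationship_matrix <- function(ped, ids = seq_len(ped$n)) {
  ped_check_ids(ped, ids)
  n <- length(ids)
  A <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in i:n)
      A[i, j] <- A[j, i] <- 2 * kin_rec(ped, ids[i], ids[j])
  dimnames(A) <- list(ids, ids)
  A
}

ped_F_of <- function(ped, ids) {
  Fv <- ped$F[ids]
  miss <- which(is.na(Fv))
  for (k in miss) Fv[k] <- inbreeding(ped, ids[k])
  Fv
}

# Regression-on-parents decomposition A^-1 = U' D^-1 U over the nodes in
# `ids` (`map`: pedigree id -> local position, 0 = excluded).
#
# Rows of U: node diagonal 1, parents with weight -b. Mendelian diagonals
# D: founder queens 1; queens (1 - F_dam)/4; drones 1 - F_dam. Worker
# groups regress on their members (queen 1/2, each of k mates 1/(2k));
# when `fold` marks drones as marginalized, a worker group's folded mates
# are replaced by their dams and the exactly marginalized drone Mendelian
# variance sum((1 - F_dam) / (2k)^2) over folded mates becomes the
# worker-group diagonal; otherwise the group is an exact combination and
# receives the regularization `wg_eps`.
ped_regression <- function(ped, ids, map, wg_eps = 1e-8, fold = NULL) {
  role <- ped$role[ids]
  N <- length(ids)
  d <- numeric(N)
  ti <- tj <- tx <- vector("list", 5L)

  qs <- ids[role == ROLE_QUEEN]
  if (length(qs)) {
    ti[[1L]] <- map[qs]; tj[[1L]] <- map[qs]; tx[[1L]] <- rep(1, length(qs))
    fou <- is.na(ped$dam[qs])
    d[map[qs[fou]]] <- 1
    qn <- qs[!fou]
    if (length(qn)) {
      B <- ped$dam[qn]; D <- ped$sire[qn]
      if (any(map[B] == 0L) || any(map[D] == 0L))
        stop("missing-node error: parents of requested nodes must be included",
             call. = FALSE)
      d[map[qn]] <- 0.25 * (1 - ped_F_of(ped, B))
      ti[[2L]] <- c(map[qn], map[qn])
      tj[[2L]] <- c(map[B], map[D])
      tx[[2L]] <- rep(-0.5, 2L * length(qn))
    }
  }
  ds <- ids[role == ROLE_DRONE]
  if (length(ds)) {
    P <- ped$dam[ds]
    if (any(map[P] == 0L))
      stop("missing-node error: parents of requested nodes must be included",
           call. = FALSE)
    d[map[ds]] <- 1 - ped_F_of(ped, P)
    ti[[3L]] <- c(map[ds], map[ds])
    tj[[3L]] <- c(map[ds], map[P])
    tx[[3L]] <- c(rep(1, length(ds)), rep(-1, length(ds)))
  }
  ws <- ids[role == ROLE_WORKER]
  if (length(ws)) {
    mem <- ped_lmget(ped$wg_members, ws)
    klen <- lengths(mem)
    flat <- unlist(mem)
    wrow <- rep.int(map[ws], klen)
    wt <- rep.int(0.5 / (klen - 1L), klen)
    isq <- sequence(klen) == 1L
    wt[isq] <- 0.5
    par <- flat
    dvec <- rep(wg_eps, length(ws))
    if (!is.null(fold)) {
      fm <- !isq & fold[flat]
      if (any(fm)) {
        par[fm] <- ped$dam[flat[fm]]
        contrib <- wt[fm]^2 * (1 - ped_F_of(ped, par[fm]))
        agg <- rowsum(contrib, wrow[fm])
        loc <- match(as.integer(rownames(agg)), map[ws])
        dvec[loc] <- pmax(dvec[loc], agg[, 1L])
      }
    }
    if (any(map[par] == 0L))
      stop("missing-node error: parents of requested nodes must be included",
           call. = FALSE)
    d[map[ws]] <- dvec
    ti[[4L]] <- map[ws]; tj[[4L]] <- map[ws]; tx[[4L]] <- rep(1, length(ws))
    ti[[5L]] <- wrow; tj[[5L]] <- map[par]; tx[[5L]] <- -wt
  }
  U <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(N, N))
  # fully inbred parents give a zero Mendelian diagonal; floor it so the
  # (then deterministic) regression acts as a hard constraint
  list(U = U, d = pmax(d, 1e-12))
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson-style assembly from per-node regressions on parents: a queen
#' regresses with weights (1/2, 1/2) on her dam and sire drone, with
#' Mendelian diagonal `(1 - F_dam) / 4`; a drone regresses with weight 1 on
#' his dam with diagonal `1 - F_dam`; a worker group regresses on its
#' members with its bilinear weights. Worker groups are exact linear
#' combinations, which would make `A` singular, so their residual diagonal
#' is the regularization `eps`.
#'
#' @param ped A `bee_pedigree`.
#' @param ids Node ids, ancestors included (default: all nodes).
#' @param eps Worker-group residual diagonal.
#' @return Sparse symmetric matrix (class `dgCMatrix`) with
#'   `A %*% Ainv ~ I` on the requested nodes.
#' @export
build_sparse_A_inverse <- function(ped, ids = seq_len(ped$n), eps = 1e-8) {
  ped_check_ids(ped, ids)
  ids <- sort(as.integer(ids))
  map <- integer(ped$n)
  map[ids] <- seq_along(ids)
  reg <- ped_regression(ped, ids, map, wg_eps = eps)
  Ainv <- Matrix::crossprod(Matrix::Diagonal(x = 1 / sqrt(reg$d)) %*% reg$U)
  dimnames(Ainv) <- list(ids, ids)
  Ainv
}

#' Expectation-based coancestry (paternity averaged over the station)
#'
#' Coancestry under the "expected" relationship mode used optionally by the
#' BLUP evaluation: the paternal side of a queen is not her realized sire
#' drone but the average over the 8 drone-producing queens of her dam's
#' mating station, mirroring field practice where individual paternity is
#' unobservable. Defined on queens only.
#'
#' @param ped A `bee_pedigree` whose mated queens carry station
#'   information (as built by [run_simulation()]).
#' @param a,b Queen ids.
#' @return Expected coancestry value.
#' @export
kinship_expected <- function(ped, a, b) {
  ped_check_ids(ped, c(a, b))
  if (ped$role[a] != ROLE_QUEEN || ped$role[b] != ROLE_QUEEN)
    stop("expected-mode kinship is defined for queens", call. = FALSE)
  kexp_rec(ped, as.integer(a), as.integer(b))
}

kexp_rec <- function(ped, a, b) {
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  key <- paste0(a, ":", b)
  hit <- ped$memo_exp[[key]]
  if (!is.null(hit)) return(hit)
  B <- ped$dam[b]
  val <-
    if (is.na(B)) {
      if (a == b) 0.5 else 0
    } else {
      P <- ped_station_of_dam(ped, b)
      if (a == b) {
        0.5 * (1 + mean(vapply(P, function(p) kexp_rec(ped, B, p),
                               numeric(1L))))
      } else {
        0.5 * kexp_rec(ped, a, B) +
          mean(vapply(P, function(p) kexp_rec(ped, a, p), numeric(1L))) / 2
      }
    }
  ped$memo_exp[[key]] <- val
  val
}

# DPQ set of the station the queen's dam was mated on
ped_station_of_dam <- function(ped, id) {
  B <- ped$dam[id]
  st <- ped_lget(ped$station, B)
  if (is.null(st)) {
    # fall back to the dams of the dam's stored mates
    mt <- ped_lget(ped$mates, B)
    if (is.null(mt))
      stop("expected mode requires station information for mated queens",
           call. = FALSE)
    st <- unique(ped$dam[mt])
  }
  st
}

# Expected-mode Mendelian diagonal of a queen:
#   d = 1 - f(B, B) / 2 - mean(f-block over the dam's station) / 2
ped_d_exp_queen <- function(ped, id) {
  if (!is.na(ped$d_exp[id])) return(ped$d_exp[id])
  if (is.na(ped$dam[id])) return(1)
  B <- ped$dam[id]
  P <- ped_station_of_dam(ped, id)
  blk <- outer(P, P, Vectorize(function(x, y) kexp_rec(ped, x, y)))
  d <- 1 - 0.5 * kexp_rec(ped, B, B) - 0.5 * mean(blk)
  ped$d_exp[id] <- d
  d
}

# Expected-mode residual diagonal of a worker group (drone Mendelian
# sampling within the mating): d = (1 - mean f-block of the queen's own
# station, self-kinships on the diagonal) / 24, for 12 mates.
ped_d_exp_wg <- function(ped, id) {
  if (!is.na(ped$d_exp[id])) return(ped$d_exp[id])
  q <- ped_lget(ped$wg_members, id)[1L]
  P <- ped_lget(ped$station, q)
  if (is.null(P))
    stop("expected mode requires station information for mated queens",
         call. = FALSE)
  n_dr <- length(ped_lget(ped$wg_members, id)) - 1L
  blk <- outer(P, P, Vectorize(function(x, y) kexp_rec(ped, x, y)))
  d <- (1 - mean(blk)) / (2 * n_dr)
  ped$d_exp[id] <- d
  d
}

#' Pedigree as a data frame / CSV export
#'
#' One row per node with columns `id, role, birth_year, dam_id,
#' sire_drone_id, F` (1-based ids, empty fields for unknown parents).
#' Worker groups carry their queen as `dam_id`.
#'
#' @param ped A `bee_pedigree`.
#' @param path Output CSV path.
#' @return `ped_df` returns the data frame; `write_pedigree` its path.
#' @export
ped_df <- function(ped) {
  ids <- seq_len(ped$n)
  dam <- ped$dam[ids]
  wgs <- ids[ped$role[ids] == ROLE_WORKER]
  dam[wgs] <- vapply(wgs, function(w) ped_lget(ped$wg_members, w)[1L],
                     integer(1L))
  Fv <- ped$F[ids]
  need <- which(is.na(Fv) & ped$role[ids] == ROLE_QUEEN)
  for (q in need) Fv[q] <- inbreeding(ped, q)
  data.frame(id = ids,
             role = ROLE_NAMES[ped$role[ids]],
             birth_year = ped$by[ids],
             dam_id = dam,
             sire_drone_id = ped$sire[ids],
             F = Fv)
}

#' @rdname ped_df
#' @export
write_pedigree <- function(ped, path) {
  df <- ped_df(ped)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
              na = "")
  invisible(path)
}

#' @export
print.bee_pedigree <- function(x, ...) {
  tab <- table(factor(ROLE_NAMES[x$role[seq_len(x$n)]], levels = ROLE_NAMES))
  cat(sprintf("Haplodiploid pedigree: %d nodes (%s)\n", x$n,
              paste(sprintf("%d %ss", as.integer(tab), names(tab)),
                    collapse = ", ")))
  invisible(x)
}
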